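test_that("pair enumeration on hand-checkable forests", {
  # chain A -> B -> C
  ch <- chain_forest(3)
  expect_equal(pairset_keys(pairs_at_distance(ch, 1)),
               c("p1|p2", "p2|p3"))
  expect_equal(pairset_keys(pairs_at_distance(ch, 2)), "p1|p3")
  expect_equal(nrow(pairs_at_distance(ch, 3)$pairs), 0)

  # star: 1 seed, 3 recruitees; siblings are distance 2 but not lineal
  p <- toy_participants(c("s", "a", "b", "c"))
  e <- data.frame(recruiter_id = rep("s", 3), recruitee_id = c("a", "b", "c"))
  star <- rds_forest(p, e)
  expect_equal(pairset_keys(pairs_at_distance(star, 2)),
               c("a|b", "a|c", "b|c"))
  expect_equal(nrow(pairs_at_distance(star, 2, mode = "lineal-only")$pairs), 0)
  expect_equal(nrow(pairs_at_distance(star, 1, mode = "lineal-only")$pairs), 3)
})

test_that("pair enumeration equals the BFS oracle on random forests", {
  set.seed(55)
  for (rep in 1:10) {
    f <- random_forest_fixture(sample(30:120, 1))
    D <- bfs_dist_oracle(f$participants$id, f$edges)
    for (d in list(1, 2, 3, "4+")) {
      expect_equal(pairset_keys(pairs_at_distance(f, d)),
                   oracle_pair_keys(D, if (identical(d, "4+")) "4+" else d))
    }
    # distance-1 pair count always equals the edge count
    expect_equal(nrow(pairs_at_distance(f, 1)$pairs), nrow(f$edges))
    # lineal pairs: path length equals wave difference (ancestor oracle)
    wave <- setNames(f$participants$wave, f$participants$id)
    ps3 <- pairs_at_distance(f, 3, mode = "lineal-only")
    if (nrow(ps3$pairs) > 0) {
      expect_true(all(abs(wave[ps3$pairs$id_b] - wave[ps3$pairs$id_a]) == 3))
    }
  }
})

test_that("correlations: algebraic identities and guard rails", {
  # binary attribute identical within every pair -> phi = 1:
  # two disjoint chains, one per sex
  p <- rbind(toy_participants(paste0("f", 1:3), sex = "female"),
             toy_participants(paste0("m", 1:3), sex = "male"))
  e <- data.frame(recruiter_id = c("f1", "f2", "m1", "m2"),
                  recruitee_id = c("f2", "f3", "m2", "m3"))
  f2 <- rds_forest(p, e)
  ps2 <- pairs_at_distance(f2, 1)
  expect_equal(correlate_pairs(f2, ps2, "sex", method = "phi")$estimate, 1)

  # phi equals Pearson on the 0/1 coding, exactly
  set.seed(66)
  f3 <- generate_forest(country_profile("NL-like"),
                        generator_config(150, 3, rng_seed = 44))
  ps3 <- pairs_at_distance(f3, 1)
  phi <- correlate_pairs(f3, ps3, "sex", method = "phi")
  pea <- correlate_pairs(f3, ps3, "sex", method = "pearson")
  expect_equal(phi$estimate, pea$estimate, tolerance = 1e-12)

  # zero variance in a margin is an error
  allf <- rds_forest(toy_participants(c("a", "b"), sex = "female"),
                     data.frame(recruiter_id = "a", recruitee_id = "b"))
  expect_error(correlate_pairs(allf, pairs_at_distance(allf, 1), "sex",
                               method = "phi"),
               class = "rdsmix_correlation_error")

  # estimate invariant to pair orientation and node relabelling
  r1 <- correlate_pairs(f3, ps3, "age")
  ps_rev <- ps3
  ps_rev$pairs <- ps_rev$pairs[rev(seq_len(nrow(ps_rev$pairs))),
                               c("id_b", "id_a")]
  names(ps_rev$pairs) <- c("id_a", "id_b")
  expect_equal(correlate_pairs(f3, ps_rev, "age")$estimate, r1$estimate)
  expect_true(abs(r1$estimate) <= 1)
  expect_true(r1$ci_95[1] <= r1$estimate && r1$estimate <= r1$ci_95[2])
})

test_that("age assortativity weakens as the homophily kernel widens", {
  ests <- vapply(c(2, 8, 20), function(sd) {
    prof <- country_profile("NL-like", homophily = list(age_sd = sd),
                            recruitment = list(invite_prob = 1,
                                               success_prob = 1,
                                               max_invites = 2),
                            complete_prob = 1)
    f <- generate_forest(prof, generator_config(300, 2, rng_seed = 71))
    correlate_pairs(f, pairs_at_distance(f, 1), "age")$estimate
  }, numeric(1))
  expect_true(all(diff(ests) < 0))
})

test_that("sex association decays geometrically with link distance", {
  # stationary symmetric binary chain: distance-d phi ~ (2q-1)^d
  q <- 0.8
  prof <- country_profile("NL-like",
                          homophily = list(sex_stay_prob = q),
                          seed_sex_split = c(female = 0.5),
                          recruitment = list(invite_prob = 1,
                                             success_prob = 1,
                                             max_invites = 2),
                          complete_prob = 1)
  f <- generate_forest(prof, generator_config(100, 4, rng_seed = 72))
  for (d in 1:3) {
    ps <- pairs_at_distance(f, d)
    expect_gte(nrow(ps$pairs), 2000)
    est <- correlate_pairs(f, ps, "sex", method = "phi")$estimate
    expect_lt(abs(est - (2 * q - 1)^d), 0.05)
  }
})

test_that("log and quintile transforms are applied before correlating", {
  set.seed(77)
  f <- generate_forest(country_profile("NL-like"),
                       generator_config(200, 3, rng_seed = 73))
  ps <- pairs_at_distance(f, 1)
  raw <- correlate_pairs(f, ps, "degree")
  lg <- correlate_pairs(f, ps, "degree", transform = "log")
  expect_false(identical(raw$estimate, lg$estimate))
  ct <- correlate_pairs(f, ps, "degree", method = "spearman",
                        transform = "categorize")
  expect_true(abs(ct$estimate) <= 1)
  # degrees are assigned independently of the network: near-random mixing
  expect_lt(abs(lg$estimate), 0.1)
})

test_that("cluster bootstrap produces an interval around the estimate", {
  f <- generate_forest(country_profile("NL-like"),
                       generator_config(150, 3, rng_seed = 74))
  ps <- pairs_at_distance(f, 1)
  r <- correlate_pairs(f, ps, "age", ci_method = "cluster-bootstrap", B = 200)
  expect_true(r$ci_95[1] < r$estimate && r$estimate < r$ci_95[2])
})

test_that("recruiter-recruitee intensity matrix counts ordered pairs", {
  p <- toy_participants(c("s", "a", "b", "c", "d"),
                        age = c(20, 22, 41, 20, 63))
  e <- data.frame(recruiter_id = c("s", "s", "a", "b"),
                  recruitee_id = c("a", "b", "c", "d"))
  f <- rds_forest(p, e)
  m <- recruiter_recruitee_matrix(f, "age", breaks = c(15, 30, 50, 70))
  # hand count: s(20)->a(22) and a(22)->c(20) in [15,30)x[15,30);
  # s(20)->b(41) in [15,30)x[30,50); b(41)->d(63) in [30,50)x[50,70)
  expect_equal(unname(m$counts[1, 1]), 2)
  expect_equal(unname(m$counts[1, 2]), 1)
  expect_equal(unname(m$counts[2, 3]), 1)
  expect_equal(sum(m$counts), 4)
  expect_equal(sum(m$proportions), 1)

  expect_error(recruiter_recruitee_matrix(f, "age", breaks = c(15, 30)),
               class = "rdsmix_bin_error")

  # perfect homophily concentrates all mass on the diagonal
  prof <- country_profile("NL-like",
                          homophily = list(age_sd = 0, sex_stay_prob = 1),
                          complete_prob = 1)
  fh <- generate_forest(prof, generator_config(40, 3, rng_seed = 75))
  mh <- recruiter_recruitee_matrix(fh, "age", breaks = seq(10, 80, 5))
  expect_equal(sum(diag(mh$counts)), sum(mh$counts))
})

test_that("age-direction proportions aggregate the tallies by age group", {
  p <- toy_participants(c("a", "b"), age = c(22, 47),
                        loc_work = c(10, 8), eating_count = c(4, 0))
  p$loc_younger <- c(2, 8); p$loc_same <- c(5, 0); p$loc_older <- c(3, 0)
  p$eat_younger <- c(0, 0); p$eat_same <- c(4, 0); p$eat_older <- c(0, 0)
  f <- rds_forest(p, NULL)
  ad <- age_direction_proportions(f, age_breaks = c(10, 30, 60))
  loc <- ad[ad$context == "locations", ]
  expect_equal(loc$younger, c(0.2, 1.0))
  expect_equal(loc$same, c(0.5, 0.0))
  expect_equal(rowSums(loc[, c("younger", "same", "older")]), c(1, 1),
               ignore_attr = TRUE)
  eat <- ad[ad$context == "eating", ]
  expect_equal(eat$same[1], 1)  # all eating tallies in "same"
})
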