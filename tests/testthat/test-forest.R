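test_that("waves and trees are derived by BFS from the seeds", {
  p <- toy_participants(c("s", "a", "b"))
  e <- data.frame(recruiter_id = c("s", "s"), recruitee_id = c("a", "b"))
  f <- rds_forest(p, e)
  expect_equal(f$participants$wave, c(0L, 1L, 1L))
  expect_equal(unique(f$participants$tree_id), "s")

  # wave(child) = wave(parent) + 1 everywhere on a generated forest
  g <- generate_forest(country_profile("NL-like"),
                       generator_config(30, 4, rng_seed = 5))
  wave <- setNames(g$participants$wave, g$participants$id)
  expect_equal(unname(wave[g$edges$recruitee_id]),
               unname(wave[g$edges$recruiter_id]) + 1L)
})

test_that("structural violations raise distinct, named validation errors", {
  p <- toy_participants(c("a", "b", "c"))
  two_parents <- data.frame(recruiter_id = c("a", "c"),
                            recruitee_id = c("b", "b"))
  expect_error(rds_forest(p, two_parents), class = "rdsmix_multiparent_error")
  expect_error(rds_forest(p, two_parents), "b")

  cycle <- data.frame(recruiter_id = c("a", "b", "c"),
                      recruitee_id = c("b", "c", "a"))
  expect_error(rds_forest(p, cycle), class = "rdsmix_cycle_error")

  unknown <- data.frame(recruiter_id = "a", recruitee_id = "zz")
  expect_error(rds_forest(p, unknown), class = "rdsmix_unknown_id_error")
  expect_error(rds_forest(p, unknown), "zz")

  p_bad <- toy_participants("a", loc_work = -1)
  expect_error(rds_forest(p_bad, NULL), class = "rdsmix_count_error")

  p5 <- toy_participants(c("r", paste0("k", 1:5)))
  fan5 <- data.frame(recruiter_id = "r", recruitee_id = paste0("k", 1:5))
  expect_error(rds_forest(p5, fan5), class = "rdsmix_fanout_error")
})

test_that("a generated survey round-trips through write_survey/load_survey", {
  f <- generate_forest(country_profile("TH-like"),
                       generator_config(25, 3, rng_seed = 9))
  dir <- withr::local_tempdir()
  write_survey(f, dir)
  f2 <- load_survey(file.path(dir, "participants.csv"),
                    file.path(dir, "edges.csv"))
  expect_equal(f2$participants, f$participants)
  expect_equal(f2$edges, f$edges)
})

test_that("degree sums location and travel contacts and excludes eating", {
  p <- toy_participants("a", loc_work = 5, eating_count = 4)
  p$loc_home <- 2
  p$tra_bus <- 3
  expect_equal(compute_degree(p), 10L)
  expect_equal(compute_degree(toy_participants("z")), 0L)

  # independent re-summation over a generated table
  g <- generate_forest(country_profile("NL-like"),
                       generator_config(40, 2, rng_seed = 3))
  gp <- g$participants
  manual <- rowSums(gp[, grep("^(loc_work|loc_school|loc_shop|loc_leisure|tra_)",
                              names(gp))])
  expect_equal(compute_degree(g), as.integer(manual))
})

test_that("degree filter removes outliers, re-roots orphans, is idempotent", {
  p <- toy_participants(paste0("p", 1:4), loc_work = c(0, 2300, 5, 7))
  e <- data.frame(recruiter_id = c("p1", "p2", "p3"),
                  recruitee_id = c("p2", "p3", "p4"))
  f <- rds_forest(p, e)

  filt <- filter_records(f, max_degree = 2200)
  expect_false("p2" %in% filt$participants$id)
  expect_equal(attr(filt, "n_removed"), 1L)
  # p3 is promoted to a new seed; BFS oracle on the surviving edges agrees
  expect_equal(filt$participants$wave[filt$participants$id == "p3"], 0L)
  expect_equal(filt$participants$wave[filt$participants$id == "p4"], 1L)

  expect_identical(filter_records(filt, max_degree = 2200)$participants,
                   filt$participants)

  # threshold Inf is the identity
  same <- filter_records(f, max_degree = Inf)
  expect_equal(same$participants, f$participants)

  # drop mode removes the whole descendant subtree
  dropped <- filter_records(f, max_degree = 2200, orphans = "drop")
  expect_equal(dropped$participants$id, "p1")
})

test_that("orphan re-rooting preserves wave offsets on a generated forest", {
  g <- generate_forest(country_profile("NL-like"),
                       generator_config(50, 4, rng_seed = 21))
  gp <- g$participants
  victim <- gp$id[gp$wave == 1][1]
  expect_false(is.na(victim))  # this seeded forest does reach wave 1
  g$participants$loc_work[gp$id == victim] <-
    g$participants$loc_work[gp$id == victim] + 5000L
  g <- rds_forest(g$participants[, setdiff(names(gp),
                                           c("wave", "tree_id", "degree"))],
                  g$edges)
  filt <- filter_records(g, max_degree = 2200)
  # children of the removed node are wave-0 seeds now
  kids <- g$edges$recruitee_id[g$edges$recruiter_id == victim]
  if (length(kids) > 0) {
    expect_true(all(filt$participants$wave[
      filt$participants$id %in% kids] == 0))
  }
  # oracle: recomputed BFS waves equal stored waves
  D <- bfs_dist_oracle(filt$participants$id, filt$edges)
  seeds <- filt$participants$id[filt$participants$wave == 0]
  oracle_wave <- apply(D[, seeds, drop = FALSE], 1, min)
  expect_equal(unname(oracle_wave[filt$participants$id]),
               as.numeric(filt$participants$wave))
})

test_that("symptom classification follows the two fixed triples", {
  expect_equal(as.character(classify_symptoms("fever;headache;muscle_pain")),
               "ILI")
  expect_equal(as.character(classify_symptoms("runny_nose;sore_throat;cough")),
               "common_cold")
  expect_equal(as.character(classify_symptoms("")), "neither")
  expect_equal(as.character(classify_symptoms(
    "fever;headache;muscle_pain;runny_nose;sore_throat;cough")), "both")
  # a triple plus extras still classifies
  expect_equal(as.character(classify_symptoms("fever;headache;muscle_pain;sneezing")),
               "ILI")
  expect_error(classify_symptoms("fevr"), class = "rdsmix_symptom_error")
})

test_that("sample summary matches generator bookkeeping and is row-order invariant", {
  f <- generate_forest(country_profile("NL-like"),
                       generator_config(60, 3, rng_seed = 17))
  s <- summarize_sample(f)
  p <- f$participants
  g <- function(item) s[s$item == item, ]

  expect_equal(g("total_participants")$count, nrow(p))
  expect_equal(g("complete_responses")$count, sum(p$complete))
  expect_equal(g("complete_responses")$pct,
               pct(sum(p$complete), nrow(p)))
  expect_equal(g("female")$count + g("male")$count, nrow(p))
  expect_equal(g("max_wave")$count, max(p$wave))
  complete_ids <- p$id[p$complete]
  expect_equal(g("recruiter_recruitee_pairs")$count,
               sum(f$edges$recruiter_id %in% complete_ids &
                     f$edges$recruitee_id %in% complete_ids))
  expect_equal(g("two_plus_symptoms")$count, sum(count_symptoms(p) >= 2))

  # row order must not matter
  shuffled <- p[sample(nrow(p)), , drop = FALSE]
  f2 <- rds_forest(shuffled[, setdiff(names(p),
                                      c("wave", "tree_id", "degree"))],
                   f$edges)
  s2 <- summarize_sample(f2)
  expect_equal(s2[order(s2$item), c("count", "pct")],
               s[order(s$item), c("count", "pct")],
               ignore_attr = TRUE)

  # seeds-only forest: zero pairs, max wave 0
  seeds_only <- rds_forest(toy_participants(c("x", "y")), NULL)
  s3 <- summarize_sample(seeds_only)
  expect_equal(s3[s3$item == "max_wave", "count"], 0)
  expect_equal(s3[s3$item == "recruiter_recruitee_pairs", "count"], 0)
})

test_that("graphml export writes a readable graph with node attributes", {
  f <- generate_forest(country_profile("NL-like"),
                       generator_config(10, 2, rng_seed = 2))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(f, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(f$participants))
  expect_true(all(c("wave", "degree", "age_group") %in%
                    igraph::vertex_attr_names(g)))
})
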