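test_that("stepwise correlations: perfect homophily and internal consistency", {
  prof <- country_profile("NL-like",
                          homophily = list(age_sd = 0, sex_stay_prob = 1),
                          recruitment = list(invite_prob = 1,
                                             success_prob = 1,
                                             max_invites = 1),
                          complete_prob = 1)
  f <- generate_forest(prof, generator_config(30, 3, rng_seed = 81))
  steps <- stepwise_correlations(f, "sex")
  expect_equal(steps$estimate, rep(1, 3))

  # consistency with correlate_pairs on the same ordered wave stratum
  g <- generate_forest(chain_profile(complete_prob = 1),
                       generator_config(200, 3, rng_seed = 82))
  steps_g <- stepwise_correlations(g, "age")
  wave <- setNames(g$participants$wave, g$participants$id)
  e0 <- g$edges[wave[g$edges$recruiter_id] == 0, ]
  ps <- structure(list(distance_label = "1",
                       pairs = data.frame(id_a = e0$recruiter_id,
                                          id_b = e0$recruitee_id)),
                  class = "pair_set")
  r <- correlate_pairs(g, ps, "age", symmetrize = FALSE)
  expect_equal(steps_g$estimate[1], r$estimate, tolerance = 1e-12)
})

test_that("independent attributes give near-zero stepwise estimates", {
  set.seed(83)
  vals <- matrix(rnorm(1000 * 4, 30, 10), 1000, 4)
  f <- chains_forest(vals)
  steps <- stepwise_correlations(f, "age")
  expect_true(all(abs(steps$estimate) < 0.07))
  mc <- markov_check_numeric(f, "age")
  expect_lt(abs(mc$r_direct), 0.07)
  expect_lt(abs(mc$r_predicted), 0.01)
})

test_that("AR(1) chains: direct correlation matches rho^3 and the product", {
  set.seed(84)
  rho <- 0.6
  n <- 3000
  vals <- matrix(0, n, 4)
  vals[, 1] <- rnorm(n, 30, 10)
  for (w in 2:4) {
    vals[, w] <- 30 + rho * (vals[, w - 1] - 30) +
      rnorm(n, 0, 10 * sqrt(1 - rho^2))
  }
  f <- chains_forest(vals)
  mc <- markov_check_numeric(f, "age")
  expect_equal(mc$n_direct, n)
  expect_lt(abs(mc$r_direct - rho^3), 0.055)
  expect_lt(abs(mc$r_direct - mc$r_predicted), 0.05)
})

test_that("insufficient chain depth is an error, shallow depth warns", {
  f <- chain_forest(3)  # only reaches wave 2
  expect_error(markov_check_numeric(f, "age"),
               class = "rdsmix_markov_error")
  set.seed(88)
  g <- chains_forest(matrix(rnorm(5 * 4, 30, 8), 5, 4))
  expect_warning(markov_check_numeric(g, "age"), "unstable")
})

test_that("transition matrix estimation recovers the generating kernel", {
  prof <- country_profile("NL-like",
                          homophily = list(age_sd = 0, sex_stay_prob = 1),
                          complete_prob = 1)
  f <- generate_forest(prof, generator_config(40, 3, rng_seed = 85))
  tm <- estimate_transition_matrix(f, "sex")
  expect_equal(unclass(tm$P), diag(2), ignore_attr = TRUE)

  q <- 0.75
  prof2 <- chain_profile(complete_prob = 1,
                         homophily = list(sex_stay_prob = q),
                         seed_sex_split = c(female = 0.5))
  f2 <- generate_forest(prof2, generator_config(1500, 3, rng_seed = 86))
  tm2 <- estimate_transition_matrix(f2, "sex")
  expect_equal(rowSums(tm2$P), c(1, 1), ignore_attr = TRUE)
  expect_lt(max(abs(diag(tm2$P) - q)), 0.03)

  # a state never seen as recruiter stays as a uniform row, with a warning
  p <- toy_participants(c("a", "b", "c"), sex = c("female", "female", "male"))
  e <- data.frame(recruiter_id = c("a", "b"), recruitee_id = c("b", "c"))
  expect_warning(tm3 <- estimate_transition_matrix(rds_forest(p, e), "sex"),
                 "male")
  expect_equal(unname(tm3$P["male", ]), c(0.5, 0.5))
})

test_that("matrix powers: closed forms and row-stochasticity", {
  mk <- function(q, marginal = c(0.5, 0.5)) {
    structure(list(states = c("a", "b"),
                   P = matrix(c(q, 1 - q, 1 - q, q), 2, byrow = TRUE),
                   marginal = marginal, n_pairs = NA),
              class = "transition_matrix")
  }
  expect_equal(matrix_power_phi(mk(1), 5), 1)
  expect_equal(matrix_power_phi(mk(0.5), 3), 0)
  # symmetric chain with uniform marginal: phi at power 3 is (2q-1)^3
  for (q in c(0.6, 0.75, 0.9)) {
    expect_equal(matrix_power_phi(mk(q), 3), (2 * q - 1)^3,
                 tolerance = 1e-12)
  }
  # powers of a row-stochastic matrix stay row-stochastic
  P <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE)
  Pp <- diag(2)
  for (s in 1:12) {
    Pp <- Pp %*% P
    expect_lt(max(abs(rowSums(Pp) - 1)), 1e-10)
  }
  # 3 states are out of phi's scope
  tm3 <- structure(list(states = c("a", "b", "c"), P = diag(3),
                        marginal = rep(1 / 3, 3)),
                   class = "transition_matrix")
  expect_error(matrix_power_phi(tm3, 3), class = "rdsmix_markov_error")
})

test_that("direct distance-3 phi approaches the cubed-matrix phi", {
  q <- 0.7
  prof <- chain_profile(complete_prob = 1,
                        homophily = list(sex_stay_prob = q),
                        seed_sex_split = c(female = 0.5))
  f <- generate_forest(prof, generator_config(2000, 3, rng_seed = 87))
  tm <- estimate_transition_matrix(f, "sex")
  predicted <- matrix_power_phi(tm, 3)
  steps <- stepwise_correlations(f, "sex")
  # direct phi between wave-0 and wave-3 chain members
  vals <- setNames(as.numeric(f$participants$sex == "female"),
                   f$participants$id)
  wave <- setNames(f$participants$wave, f$participants$id)
  w3 <- names(wave)[wave == 3]
  parent <- setNames(f$edges$recruiter_id, f$edges$recruitee_id)
  anc <- parent[parent[parent[w3]]]
  direct <- cor(vals[anc], vals[w3])
  expect_lt(abs(direct - predicted), 0.05)
  expect_lt(abs(direct - (2 * q - 1)^3), 0.06)
})
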