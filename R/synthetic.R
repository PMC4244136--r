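#' @importFrom stats rnorm rbinom rnbinom runif plogis qnorm pnorm
NULL

# Country profiles ------------------------------------------------------------

#' Built-in country profiles for the synthetic generator
#'
#' Returns the full parameter set controlling one synthetic webRDS survey.
#' The two built-in profiles reproduce the published sample conditions:
#' negative-binomial total-degree distributions with
#' (mu = 25.65, k = 1.00) for `"NL-like"` and (mu = 58.51, k = 0.83) for
#' `"TH-like"`, setting splits, eating-contact and household distributions,
#' symptom-class prevalences, seed demographics, recruitment-method shares
#' and completion rates taken from the published per-country tables.
#' Where no value was printed (within-setting sub-splits, homophily kernel
#' widths, branching coefficients) the defaults are documented choices, made
#' once, at values typical for student-seeded online chain-referral surveys.
#'
#' @param name `"NL-like"` or `"TH-like"`.
#' @param ... named overrides; nested lists are merged field-by-field
#'   (e.g. `homophily = list(age_sd = 4)` replaces only `age_sd`).
#' @return object of class `country_profile` (a named list).
#' @examples
#' country_profile("NL-like")$degree_mu  # 25.65
#' country_profile("TH-like", homophily = list(age_sd = 4))
#' @export
country_profile <- function(name = c("NL-like", "TH-like"), ...) {
  name <- match.arg(name)
  base <- if (name == "NL-like") {
    list(
      name = name, country = "NL",
      degree_mu = 25.65, degree_k = 1.00,
      # expected share of degree at locations vs travelling (means 21.4 / 4.2)
      setting_split = c(locations = 21.4 / 25.6, travel = 4.2 / 25.6),
      location_shares = c(work = 0.40, school = 0.25, shop = 0.20,
                          leisure = 0.15),
      transport_shares = c(bus = 0.40, train = 0.30, car = 0.30),
      # eating contacts: mean 7.3, variance 106.5 -> k = mu^2/(v - mu)
      eating_mu = 7.3, eating_k = 7.3^2 / (106.5 - 7.3),
      household_dist = c(`1` = 0.30, `2` = 0.28, `3` = 0.12, `4` = 0.12,
                         `5` = 0.10, `6` = 0.08),
      symptom_prevalence = c(ili = 0.019, cold = 0.074, both = 0.005,
                             other_multi = 0.298, single = 0.20),
      seed_age_dist = list(mean = 26.7, sd = 6, min = 19, max = 53),
      seed_sex_split = c(female = 0.621),
      seed_education_dist = c(high_school = 0.059, vocational = 0.042,
                              higher = 0.899),
      homophily = list(age_sd = 8, sex_stay_prob = 0.65,
                       education_stay = 0.5),
      recruitment = list(
        invite_coef = c(intercept = 0.0, degree = 0.01, female = 0.5),
        invite_prob = NULL, success_prob = 0.30, max_invites = 4),
      method_probs = c(facebook = 0.104, indirect_email = 0.526,
                       direct_email = 0.370),
      complete_prob = 0.899,
      age_range = c(14, 80)
    )
  } else {
    list(
      name = name, country = "TH",
      degree_mu = 58.51, degree_k = 0.83,
      setting_split = c(locations = 40.9 / 58.5, travel = 17.6 / 58.5),
      location_shares = c(work = 0.40, school = 0.25, shop = 0.20,
                          leisure = 0.15),
      transport_shares = c(bus = 0.40, train = 0.30, car = 0.30),
      eating_mu = 11.8, eating_k = 11.8^2 / (225.0 - 11.8),
      household_dist = c(`1` = 0.10, `2` = 0.20, `3` = 0.25, `4` = 0.20,
                         `5` = 0.15, `6` = 0.10),
      symptom_prevalence = c(ili = 0.032, cold = 0.059, both = 0.005,
                             other_multi = 0.203, single = 0.20),
      seed_age_dist = list(mean = 26.2, sd = 6, min = 14, max = 48),
      seed_sex_split = c(female = 0.614),
      seed_education_dist = c(high_school = 0.153, vocational = 0.008,
                              higher = 0.839),
      homophily = list(age_sd = 8, sex_stay_prob = 0.65,
                       education_stay = 0.5),
      recruitment = list(
        invite_coef = c(intercept = 0.0, degree = 0.01, female = 0.5),
        invite_prob = NULL, success_prob = 0.30, max_invites = 4),
      method_probs = c(facebook = 0.836, indirect_email = 0.050,
                       direct_email = 0.114),
      complete_prob = 0.856,
      age_range = c(14, 80)
    )
  }
  prof <- utils::modifyList(base, list(...))
  .validate_profile(prof)
  structure(prof, class = "country_profile")
}

.validate_profile <- function(p) {
  stopifnot(p$degree_mu > 0, p$degree_k > 0, p$eating_k > 0)
  q <- p$homophily$sex_stay_prob
  if (q < 0.5 || q > 1) {
    .rds_stop("rdsmix_profile_error", "sex_stay_prob must be in [0.5, 1]")
  }
  for (vec in list(p$household_dist, p$seed_education_dist, p$method_probs)) {
    if (abs(sum(vec) - 1) > 1e-6) {
      .rds_stop("rdsmix_profile_error",
                "probability vector does not sum to 1: ",
                paste(names(vec), collapse = ","))
    }
  }
  if (sum(p$symptom_prevalence) > 1 + 1e-8) {
    .rds_stop("rdsmix_profile_error", "symptom-class prevalences exceed 1")
  }
  invisible(TRUE)
}

#' Generator run configuration
#'
#' @param n_seeds number of wave-0 participants (>= 1).
#' @param max_waves deepest recruitment generation to create (>= 0).
#' @param markov_order 1 (recruitee attributes depend on the recruiter only)
#'   or 2 (each recruitee's attribute kernel is centred, with probability
#'   1/2 each, on the recruiter or the grand-recruiter).
#' @param rng_seed optional integer; when given, [generate_forest()] is
#'   bit-reproducible.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_seeds, max_waves, markov_order = 1,
                             rng_seed = NULL) {
  stopifnot(n_seeds >= 1, max_waves >= 0, markov_order %in% c(1, 2))
  structure(list(n_seeds = as.integer(n_seeds),
                 max_waves = as.integer(max_waves),
                 markov_order = as.integer(markov_order),
                 rng_seed = rng_seed),
            class = "generator_config")
}

# helpers ---------------------------------------------------------------------

# integer ages from a normal kernel truncated to [lo, hi], by rejection
.rtrunc_age <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(round(pmin(pmax(mean, lo), hi)))
  out <- numeric(n)
  todo <- seq_len(n)
  mean <- rep_len(mean, n)
  while (length(todo) > 0) {
    draw <- rnorm(length(todo), mean[todo], sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  round(out)
}

# one multinomial draw per row (sizes and, optionally, probabilities vary by
# row), via the sequential-binomial decomposition; exactly conserves size
.rmultinom_rows <- function(size, prob) {
  n <- length(size)
  if (is.null(dim(prob))) prob <- matrix(prob, n, length(prob), byrow = TRUE)
  J <- ncol(prob)
  out <- matrix(0L, n, J, dimnames = list(NULL, colnames(prob)))
  remaining <- as.integer(size)
  for (j in seq_len(J - 1)) {
    tail <- rowSums(prob[, j:J, drop = FALSE])
    pj <- ifelse(tail > 0, prob[, j] / tail, 0)
    out[, j] <- rbinom(n, remaining, pmin(pmax(pj, 0), 1))
    remaining <- remaining - out[, j]
  }
  out[, J] <- remaining
  out
}

#' Decompose a total degree into per-setting contact counts
#'
#' Splits each degree multinomially over the location and transport types
#' according to the profile's setting split (so location + travel counts sum
#' to the degree exactly), draws the independent eating-contact count, and
#' fills in younger/same/older age-direction tallies for the locations and
#' eating contexts. The probability that a reported contact is younger grows
#' with the participant's own age.
#'
#' @param degree integer vector of total degrees (>= 0).
#' @param profile a [country_profile()].
#' @param age participant ages (recycled), used for the direction tallies.
#' @return data.frame with `loc_*`, `tra_*`, `eating_count` and the six
#'   tally columns; `rowSums` of the `loc_*`/`tra_*` columns equal `degree`.
#' @export
decompose_contacts <- function(degree, profile, age = 30) {
  stopifnot(all(degree >= 0))
  n <- length(degree)
  age <- rep_len(age, n)
  split <- profile$setting_split / sum(profile$setting_split)
  probs <- c(split["locations"] * profile$location_shares /
               sum(profile$location_shares),
             split["travel"] * profile$transport_shares /
               sum(profile$transport_shares))
  counts <- .rmultinom_rows(degree, matrix(probs, n, length(probs),
                                           byrow = TRUE))
  colnames(counts) <- c(paste0("loc_", names(profile$location_shares)),
                        paste0("tra_", names(profile$transport_shares)))
  eating <- rnbinom(n, mu = profile$eating_mu, size = profile$eating_k)

  tally <- function(total) {
    p_young_raw <- plogis((age - 30) / 12)
    probs <- cbind(younger = 0.65 * p_young_raw,
                   same = 0.35,
                   older = 0.65 * (1 - p_young_raw))
    .rmultinom_rows(total, probs)
  }
  loc_total <- rowSums(counts[, grep("^loc_", colnames(counts)),
                              drop = FALSE])
  lt <- tally(loc_total)
  et <- tally(eating)
  out <- data.frame(counts, eating_count = eating,
                    loc_younger = lt[, 1], loc_same = lt[, 2],
                    loc_older = lt[, 3],
                    eat_younger = et[, 1], eat_same = et[, 2],
                    eat_older = et[, 3])
  rownames(out) <- NULL
  out
}

# education transition matrix: stay with prob s, otherwise redraw from the
# marginal -- keeps the seed education distribution stationary along chains
.education_transition <- function(profile) {
  if (!is.null(profile$homophily$education_transition)) {
    M <- profile$homophily$education_transition
    stopifnot(all(abs(rowSums(M) - 1) < 1e-8))
    if (is.null(dimnames(M))) {
      dimnames(M) <- list(.education_levels, .education_levels)
    }
    return(M)
  }
  s <- profile$homophily$education_stay
  marg <- profile$seed_education_dist[.education_levels]
  M <- s * diag(3) + (1 - s) * matrix(marg, 3, 3, byrow = TRUE)
  dimnames(M) <- list(.education_levels, .education_levels)
  M
}

# Forest generation -----------------------------------------------------------

#' Generate a synthetic webRDS survey
#'
#' Simulates the chain-referral design wave by wave. Seeds draw demographics
#' from the profile's seed distributions; every participant decides whether
#' to request invitations via a logistic model in degree and sex (the signal
#' the recruitment model recovers), sends up to `max_invites` invitations,
#' each succeeding independently; recruitees inherit attributes through
#' homophily kernels: age = reference age + Normal(0, `age_sd`) truncated to
#' the profile age range, sex kept with probability `sex_stay_prob`,
#' education drawn from the reference's transition-matrix row. With
#' `markov_order = 1` the reference is always the direct recruiter, making
#' the attribute process along every chain first-order Markov by
#' construction; with `markov_order = 2` each recruitee (from wave 2 on)
#' picks the recruiter or the grand-recruiter as reference with probability
#' 1/2 each, a minimal higher-order deviation. Degrees are i.i.d.
#' negative-binomial(mu, k), independent of demographics, and are decomposed
#' into per-setting counts by [decompose_contacts()].
#'
#' @param profile a [country_profile()].
#' @param config a [generator_config()].
#' @return a validated [rds_forest()].
#' @examples
#' f <- generate_forest(country_profile("NL-like"),
#'                      generator_config(n_seeds = 20, max_waves = 3,
#'                                       rng_seed = 1))
#' f
#' @export
generate_forest <- function(profile, config) {
  stopifnot(inherits(profile, "country_profile"),
            inherits(config, "generator_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  hom <- profile$homophily
  edu_M <- .education_transition(profile)
  rng_range <- profile$age_range
  rec <- profile$recruitment

  n0 <- config$n_seeds
  current <- data.frame(
    id = sprintf("%s-%06d", profile$country, seq_len(n0)),
    age = .rtrunc_age(n0, profile$seed_age_dist$mean, profile$seed_age_dist$sd,
                      profile$seed_age_dist$min, profile$seed_age_dist$max),
    sex = ifelse(runif(n0) < profile$seed_sex_split[["female"]],
                 "female", "male"),
    education = sample(names(profile$seed_education_dist), n0, replace = TRUE,
                       prob = profile$seed_education_dist),
    recruitment_method = "seed",
    wave = 0L,
    parent_age = NA_real_, parent_sex = NA_character_,
    parent_education = NA_character_,
    stringsAsFactors = FALSE
  )

  next_id <- n0 + 1L
  cohorts <- list()
  edges <- list()

  for (w in 0:config$max_waves) {
    nw <- nrow(current)
    # degrees are drawn here so the invitation decision can depend on them;
    # the per-setting decomposition for all cohorts happens after the loop
    current$degree_draw <- rnbinom(nw, mu = profile$degree_mu,
                                   size = profile$degree_k)
    invite_p <- if (!is.null(rec$invite_prob)) {
      rep_len(rec$invite_prob, nw)
    } else {
      b <- rec$invite_coef
      plogis(b[["intercept"]] + b[["degree"]] * current$degree_draw +
               b[["female"]] * (current$sex == "female"))
    }
    current$requested_invitations <- runif(nw) < invite_p
    # the deepest wave still records its invitation intent but recruits nobody
    n_child <- if (w < config$max_waves) {
      ifelse(current$requested_invitations,
             rbinom(nw, rec$max_invites, rec$success_prob), 0L)
    } else {
      integer(nw)
    }
    cohorts[[w + 1]] <- current
    if (sum(n_child) == 0) break

    idx <- rep(seq_len(nw), n_child)
    parent <- current[idx, , drop = FALSE]
    nk <- nrow(parent)

    # reference ancestor for the homophily kernels
    ref_age <- parent$age
    ref_sex <- parent$sex
    ref_edu <- parent$education
    if (config$markov_order == 2 && w >= 1) {
      use_grand <- runif(nk) < 0.5 & !is.na(parent$parent_age)
      ref_age[use_grand] <- parent$parent_age[use_grand]
      ref_sex[use_grand] <- parent$parent_sex[use_grand]
      ref_edu[use_grand] <- parent$parent_education[use_grand]
    }

    child_sex <- ifelse(runif(nk) < hom$sex_stay_prob, ref_sex,
                        ifelse(ref_sex == "female", "male", "female"))
    child_edu <- vapply(ref_edu, function(e) {
      sample(.education_levels, 1, prob = edu_M[e, ])
    }, character(1))
    children <- data.frame(
      id = sprintf("%s-%06d", profile$country,
                   seq(next_id, length.out = nk)),
      age = .rtrunc_age(nk, ref_age, hom$age_sd, rng_range[1], rng_range[2]),
      sex = child_sex,
      education = unname(child_edu),
      recruitment_method = sample(names(profile$method_probs), nk,
                                  replace = TRUE, prob = profile$method_probs),
      wave = w + 1L,
      parent_age = parent$age, parent_sex = parent$sex,
      parent_education = parent$education,
      stringsAsFactors = FALSE
    )
    next_id <- next_id + nk
    edges[[w + 1]] <- data.frame(recruiter_id = parent$id,
                                 recruitee_id = children$id,
                                 stringsAsFactors = FALSE)
    current <- children
  }
  all_p <- do.call(rbind, cohorts)
  edges <- if (length(edges)) do.call(rbind, edges) else NULL

  n <- nrow(all_p)
  contacts <- decompose_contacts(all_p$degree_draw, profile, all_p$age)
  hh <- as.integer(sample(names(profile$household_dist), n, replace = TRUE,
                          prob = profile$household_dist))
  hh_sym <- ifelse(runif(n) < 0.08, NA_integer_,
                   rbinom(n, hh, 0.10))
  participants <- data.frame(
    id = all_p$id,
    country = profile$country,
    age = all_p$age,
    sex = all_p$sex,
    education = all_p$education,
    household_size = hh,
    household_symptomatic = hh_sym,
    symptoms = .draw_symptoms(n, profile$symptom_prevalence),
    recording_day = sample(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"),
                           n, replace = TRUE),
    contacts,
    recruitment_method = all_p$recruitment_method,
    requested_invitations = all_p$requested_invitations,
    complete = runif(n) < profile$complete_prob,
    stringsAsFactors = FALSE
  )
  rds_forest(participants, edges)
}

# symptom sets by class: the ILI and cold triples, both, a 2-symptom draw
# that cannot complete a triple, a single symptom, or none
.draw_symptoms <- function(n, prev) {
  classes <- c(names(prev), "none")
  probs <- c(prev, none = 1 - sum(prev))
  cls <- sample(classes, n, replace = TRUE, prob = probs)
  all_sym <- symptom_list()
  vapply(cls, function(cl) {
    switch(cl,
      ili = paste(.ili_triple, collapse = ";"),
      cold = paste(.cold_triple, collapse = ";"),
      both = paste(c(.ili_triple, .cold_triple), collapse = ";"),
      other_multi = paste(sample(all_sym, 2), collapse = ";"),
      single = sample(all_sym, 1),
      none = "")
  }, character(1), USE.NAMES = FALSE)
}
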