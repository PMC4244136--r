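# Effective contact rate C = m + v/m (Anderson & May): under proportionate
# mixing the basic reproduction number is proportional to C, so the
# variance-to-mean ratio of individual contact rates quantifies how much
# heterogeneity inflates transmission beyond the mean contact rate.

#' Effective contact rate from individual contact rates
#'
#' Computes the sample mean `m`, sample variance `v` (n-1 denominator) and
#' the effective contact rate `C = m + v/m` of a vector of individual
#' contact rates. `C >= m` always, with equality iff the rates are constant.
#'
#' @param counts non-negative contact rates, `n >= 2`, not all zero.
#' @param category optional label (e.g. `"degree"`, `"household"`).
#' @return object of class `contact_rate_summary`: `category`, `m`, `v`,
#'   `C`, `n`.
#' @examples
#' effective_contact_rate(c(1, 2, 3, 10))
#' @export
effective_contact_rate <- function(counts, category = NA_character_) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) {
    .rds_stop("rdsmix_ecr_error",
              "need at least 2 observations for a variance")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    .rds_stop("rdsmix_ecr_error", "contact rates must be non-negative")
  }
  m <- mean(counts)
  if (m == 0) {
    .rds_stop("rdsmix_ecr_error",
              "all contact rates are zero: C undefined (m = 0)")
  }
  effective_contact_from_moments(m, var(counts), category = category,
                                 n = length(counts))
}

#' Effective contact rate from printed moments
#'
#' The printed-inputs path: takes a mean and variance directly (for example
#' from a published table) and returns `C = m + v/m`.
#'
#' @param m mean contact rate (> 0).
#' @param v variance of contact rates (>= 0).
#' @param category optional label.
#' @param n sample size behind the moments, if known.
#' @return a `contact_rate_summary`.
#' @examples
#' effective_contact_from_moments(25.65, 2212.2)$C  # 111.895...
#' @export
effective_contact_from_moments <- function(m, v, category = NA_character_,
                                           n = NA_integer_) {
  if (is.na(m) || m <= 0) {
    .rds_stop("rdsmix_ecr_error", "mean contact rate must be positive")
  }
  if (is.na(v) || v < 0) {
    .rds_stop("rdsmix_ecr_error", "variance must be non-negative")
  }
  structure(list(category = category, m = m, v = v, C = m + v / m, n = n),
            class = "contact_rate_summary")
}

#' @export
print.contact_rate_summary <- function(x, ...) {
  cat(sprintf("Effective contact rate%s: m = %.2f, v = %.1f, C = %.1f%s\n",
              if (is.na(x$category)) "" else paste0(" (", x$category, ")"),
              x$m, x$v, round_half_up(x$C, 1),
              if (is.na(x$n)) "" else paste0(" (n = ", x$n, ")")))
  invisible(x)
}

#' Compare effective contact rates between scenarios
#'
#' For intervention what-ifs: e.g. restricting all contacts to the household
#' replaces the degree-based rate by the household-members rate.
#'
#' @param full a `contact_rate_summary` for the unrestricted scenario.
#' @param restricted a `contact_rate_summary` for the restricted scenario.
#' @return list with `C_full`, `C_restricted`, `reduction_factor`
#'   (`C_full / C_restricted`).
#' @export
scenario_comparison <- function(full, restricted) {
  stopifnot(inherits(full, "contact_rate_summary"),
            inherits(restricted, "contact_rate_summary"))
  list(C_full = full$C, C_restricted = restricted$C,
       reduction_factor = full$C / restricted$C)
}

#' Effective contact rates per contact category
#'
#' One summary per contact category of the survey: total degree (locations +
#' travel), contacts at locations only, contacts while travelling only,
#' contacts while eating, and household members (household size as the
#' contact rate).
#'
#' @param forest an `rds_forest`, ideally already passed through
#'   [filter_records()].
#' @param complete_only restrict to complete responses (default `TRUE`,
#'   matching the completeness convention of the distribution fits).
#' @return data.frame with columns `category`, `mean`, `variance`, `C`, `n`.
#' @export
category_summaries <- function(forest, complete_only = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  p <- forest$participants
  if (complete_only) p <- p[p$complete, , drop = FALSE]
  loc <- rowSums(p[, .loc_cols(p), drop = FALSE])
  tra <- rowSums(p[, .tra_cols(p), drop = FALSE])
  cats <- list(degree = loc + tra, locations = loc, travel = tra,
               eating = p$eating_count, household = p$household_size)
  out <- lapply(names(cats), function(cat) {
    s <- effective_contact_rate(cats[[cat]], category = cat)
    data.frame(category = cat, mean = s$m, variance = s$v, C = s$C,
               n = s$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
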