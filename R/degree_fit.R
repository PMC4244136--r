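#' @importFrom stats dnbinom optimize quantile ks.test
NULL

#' Fit a negative-binomial distribution to degree counts
#'
#' Maximum-likelihood fit of the ecology-convention negative binomial with
#' mean `mu` and dispersion `k` (variance `mu + mu^2/k`; smaller `k` means
#' more overdispersion). The likelihood is profiled: the MLE of `mu` is the
#' sample mean for every `k`, so only `k` is searched, on a bounded interval.
#' Confidence intervals are percentile intervals over `B` parametric
#' bootstrap replicates (simulate `n` counts from the fitted distribution,
#' refit).
#'
#' @param counts non-negative integer vector, `n >= 10`, at least two
#'   distinct values (with all counts equal `k` is unidentifiable).
#' @param B number of bootstrap replicates (default 1000). `B = 0` skips the
#'   bootstrap (CIs are `NA`).
#' @param conf confidence level for the percentile intervals.
#' @param k_bounds search interval for `k`.
#' @return object of class `negbin_fit`: list with `mu`, `k`, `ci_mu`,
#'   `ci_k`, `loglik`, `n`, `B`.
#' @examples
#' set.seed(1)
#' fit_negbin(rnbinom(500, mu = 25, size = 1), B = 50)
#' @export
fit_negbin <- function(counts, B = 1000, conf = 0.95,
                       k_bounds = c(1e-3, 1e3)) {
  counts <- as.numeric(counts)
  if (length(counts) < 10) {
    .rds_stop("rdsmix_fit_error", "need at least 10 observations")
  }
  if (any(!.is_count(counts))) {
    .rds_stop("rdsmix_count_error", "counts must be non-negative integers")
  }
  if (length(unique(counts)) < 2) {
    .rds_stop("rdsmix_fit_error",
              "all counts are equal: dispersion k is unidentifiable")
  }
  est <- .nb_mle(counts, k_bounds)
  n <- length(counts)

  ci_mu <- ci_k <- c(NA_real_, NA_real_)
  if (B > 0) {
    boots <- vapply(seq_len(B), function(b) {
      sim <- rnbinom(n, mu = est$mu, size = est$k)
      if (length(unique(sim)) < 2) return(c(mean(sim), NA_real_))
      bfit <- .nb_mle(sim, k_bounds)
      c(bfit$mu, bfit$k)
    }, numeric(2))
    alpha <- (1 - conf) / 2
    ci_mu <- unname(quantile(boots[1, ], c(alpha, 1 - alpha), na.rm = TRUE))
    ci_k <- unname(quantile(boots[2, ], c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(list(mu = est$mu, k = est$k, ci_mu = ci_mu, ci_k = ci_k,
                 loglik = est$loglik, n = n, B = B, conf = conf),
            class = "negbin_fit")
}

# profile likelihood in k with mu fixed at the sample mean
.nb_mle <- function(counts, k_bounds) {
  mu <- mean(counts)
  prof <- function(logk) {
    sum(dnbinom(counts, size = exp(logk), mu = mu, log = TRUE))
  }
  opt <- optimize(prof, interval = log(k_bounds), maximum = TRUE,
                  tol = 1e-8)
  list(mu = mu, k = exp(opt$maximum), loglik = opt$objective)
}

#' @export
print.negbin_fit <- function(x, ...) {
  cat("Negative-binomial fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mu = %.2f [%.2f-%.2f]\n", x$mu, x$ci_mu[1], x$ci_mu[2]))
  cat(sprintf("  k  = %.2f [%.2f-%.2f]\n", x$k, x$ci_k[1], x$ci_k[2]))
  cat(sprintf("  log-likelihood = %.2f (B = %d bootstrap replicates)\n",
              x$loglik, x$B))
  invisible(x)
}

#' Kolmogorov-Smirnov two-sample test
#'
#' Classical two-sample KS statistic with the asymptotic p-value, as used to
#' compare the seed age distributions between country samples.
#'
#' @param a,b numeric vectors.
#' @return object of class `two_sample_test` with `statistic`, `p_value`,
#'   `method`, `p_method`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  structure(list(statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 method = "KS-two-sample", p_method = "asymptotic"),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3), " (", x$p_method, ")\n",
      sep = "")
  invisible(x)
}

#' Matched empirical quantiles for Q-Q comparison
#'
#' @param a,b numeric vectors.
#' @param n_quantiles number of probability points (equally spaced via
#'   [stats::ppoints()]).
#' @return data.frame with `prob`, `quantile_a`, `quantile_b`.
#' @export
qq_pairs <- function(a, b, n_quantiles = 100) {
  stopifnot(length(a) > 0, length(b) > 0, n_quantiles >= 1)
  probs <- stats::ppoints(n_quantiles)
  data.frame(prob = probs,
             quantile_a = unname(quantile(a, probs, type = 7)),
             quantile_b = unname(quantile(b, probs, type = 7)))
}
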