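#' @importFrom stats glm binomial glm.control predict coef vcov logLik
NULL

#' Logistic model of the intention to recruit
#'
#' Fits the drivers of online peer-recruitment: the binary outcome is
#' whether a participant requested invitations for recruitees on the last
#' survey page, modelled on degree, age, sex (indicator for female),
#' education (ordered codes 1-3) and household size. Fitting is
#' maximum-likelihood via iteratively reweighted least squares (convergence
#' when the relative change falls below 1e-8, at most 100 iterations);
#' standard errors come from the inverse observed information. The model can
#' be refit without the seeds (`subset = "excluding-seeds"`) to measure
#' their influence on the outcome.
#'
#' @param forest an `rds_forest` (or participant data.frame with the model
#'   columns and `requested_invitations`).
#' @param subset `"all"` or `"excluding-seeds"` (drops wave-0 rows).
#' @param log_degree model `log(degree + 1)` instead of raw degree.
#' @return object of class `logistic_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `n`, `converged`, `subset`, and the underlying `glm` fit.
#' @export
fit_logistic <- function(forest, subset = c("all", "excluding-seeds"),
                         log_degree = FALSE) {
  subset <- match.arg(subset)
  p <- if (inherits(forest, "rds_forest")) forest$participants else forest
  if (subset == "excluding-seeds") {
    if (is.null(p$wave)) .rds_stop("rdsmix_model_error",
                                   "wave column needed to exclude seeds")
    p <- p[p$wave > 0, , drop = FALSE]
  }
  df <- data.frame(
    y = as.numeric(p$requested_invitations),
    degree = if (inherits(forest, "rds_forest") || "degree" %in% names(p)) {
      p$degree
    } else {
      compute_degree(p)
    },
    age = p$age,
    female = as.numeric(p$sex == "female"),
    education = as.numeric(factor(p$education, levels = .education_levels)),
    household_size = p$household_size
  )
  if (log_degree) df$degree <- log(df$degree + 1)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$y)) < 2) {
    .rds_stop("rdsmix_model_error",
              "outcome has a single class in this subset: model undefined")
  }
  # constant covariates carry no information and would alias the intercept
  preds <- c("degree", "age", "female", "education", "household_size")
  keep <- preds[vapply(df[preds], function(v) stats::sd(v) > 0, logical(1))]
  if (length(keep) < length(preds)) {
    message("dropping constant covariate(s): ",
            paste(setdiff(preds, keep), collapse = ", "))
  }
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  fit <- glm(stats::as.formula(paste("y ~", rhs)),
             family = binomial(), data = df,
             control = glm.control(epsilon = 1e-8, maxit = 100))
  se <- sqrt(diag(vcov(fit)))
  if (!fit$converged || any(!is.finite(se)) || any(se > 100)) {
    worst <- names(se)[which.max(se)]
    .rds_stop("rdsmix_separation_error",
              "fit did not converge to finite standard errors ",
              "(likely separation on '", worst, "')")
  }
  structure(list(coefficients = coef(fit), se = se, vcov = vcov(fit),
                 loglik = as.numeric(logLik(fit)), n = nrow(df),
                 converged = fit$converged, subset = subset,
                 log_degree = log_degree, glm = fit, data = df),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Intention-to-recruit logistic model (", x$subset, ", n = ", x$n,
      ")\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$se,
               z = x$coefficients / x$se,
               p = 2 * pnorm(-abs(x$coefficients / x$se)))
  print(round(tab, 4))
  invisible(x)
}

#' Predicted recruitment probability as a function of degree
#'
#' Inverse-logit of the linear predictor along a degree grid, holding the
#' other covariates at a fixed profile (defaults: medians for numeric
#' covariates, female = 1). The 95% band is formed on the link scale from
#' the linear predictor's standard error and then transformed, so it always
#' stays within \[0, 1\] and contains the point estimate.
#'
#' @param fit a converged [fit_logistic()] result.
#' @param grid degree values at which to predict; defaults to 100 points
#'   over the observed degree range. Values outside the observed range
#'   trigger a warning, not an error.
#' @param profile named list fixing `age`, `female`, `education`,
#'   `household_size`.
#' @return data.frame of class `prediction_curve`: `degree`, `fit`,
#'   `lower`, `upper`.
#' @export
probability_vs_degree <- function(fit, grid = NULL, profile = list()) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) {
    .rds_stop("rdsmix_model_error", "fit did not converge")
  }
  obs <- fit$data$degree
  if (is.null(grid)) grid <- seq(min(obs), max(obs), length.out = 100)
  if (any(grid < min(obs) | grid > max(obs))) {
    warning("degree grid extends outside the observed range [",
            min(obs), ", ", max(obs), "]", call. = FALSE)
  }
  defaults <- list(age = median(fit$data$age), female = 1,
                   education = median(fit$data$education),
                   household_size = median(fit$data$household_size))
  profile <- utils::modifyList(defaults, profile)
  newdata <- data.frame(degree = grid, age = profile$age,
                        female = profile$female,
                        education = profile$education,
                        household_size = profile$household_size)
  pr <- predict(fit$glm, newdata = newdata, type = "link", se.fit = TRUE)
  z <- qnorm(0.975)
  out <- data.frame(degree = grid,
                    fit = plogis(pr$fit),
                    lower = plogis(pr$fit - z * pr$se.fit),
                    upper = plogis(pr$fit + z * pr$se.fit))
  attr(out, "profile") <- profile
  class(out) <- c("prediction_curve", "data.frame")
  out
}
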