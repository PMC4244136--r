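#' Round half-up
#'
#' Rounds with ties going away from zero (the convention used in the survey
#' summary tables), unlike [base::round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.05, 0.15, 117.55), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage with table-style rounding
#'
#' @param count numerator count.
#' @param denom denominator count.
#' @param digits decimal places (default 1, as in the study tables).
#' @return percentage, rounded half-up.
#' @examples
#' pct(322, 358)  # 89.9
#' @export
pct <- function(count, denom, digits = 1) {
  round_half_up(100 * count / denom, digits)
}

# stop with a classed validation error so callers can test for the failure mode
.rds_stop <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "rdsmix_error")))
}

.is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & abs(x - round(x)) < 1e-8
}
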