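# First-order Markov check on recruitment chains: if a recruitee's
# attributes depend only on the direct recruiter, the seed-to-wave-3
# correlation should match the product of the three stepwise correlations
# (numeric attributes) or the phi coefficient implied by the cubed one-step
# transition matrix (binary attributes).

#' Stepwise recruiter-recruitee correlations by wave
#'
#' For each recruitment step `w -> w+1` up to `max_wave`, the correlation of
#' an attribute over the ordered (recruiter, recruitee) pairs whose
#' recruiter sits in wave `w`. Pearson's r for numeric attributes, phi for
#' binary ones (chosen automatically unless `method` is given). Ordered
#' pairs are used (no symmetrization): the construct is the association
#' between earlier-wave and later-wave members of a chain.
#'
#' @param forest an `rds_forest`.
#' @param attribute attribute name (see [correlate_pairs()]).
#' @param max_wave deepest recruiter wave considered (default 3, matching
#'   the limited depth of real recruitment trees).
#' @param method correlation method; `NULL` picks phi for binary values,
#'   Pearson otherwise.
#' @param complete_only drop pairs involving an incomplete response.
#' @return data.frame with columns `step` (e.g. `"0-1"`), `estimate`,
#'   `n_pairs`; steps with no pairs are reported with `NA`.
#' @export
stepwise_correlations <- function(forest, attribute, max_wave = 3,
                                  method = NULL, complete_only = TRUE) {
  stopifnot(inherits(forest, "rds_forest"), max_wave >= 1)
  p <- forest$participants
  vals <- setNames(.attribute_values(forest, attribute), p$id)
  method <- method %||% .auto_method(vals)
  wave <- setNames(p$wave, p$id)
  complete <- setNames(p$complete, p$id)
  edges <- forest$edges

  out <- lapply(seq_len(max_wave) - 1L, function(w) {
    e <- edges[wave[edges$recruiter_id] == w, , drop = FALSE]
    if (complete_only && nrow(e) > 0) {
      e <- e[complete[e$recruiter_id] & complete[e$recruitee_id], ,
             drop = FALSE]
    }
    x <- vals[e$recruiter_id]
    y <- vals[e$recruitee_id]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    est <- if (n >= 2) .pair_cor(x[ok], y[ok], method, symmetrize = FALSE)
           else NA_real_
    data.frame(step = paste0(w, "-", w + 1), estimate = est, n_pairs = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "attribute") <- attribute
  attr(out, "method") <- method
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.auto_method <- function(vals) {
  u <- unique(vals[!is.na(vals)])
  if (length(u) <= 2) "phi" else "pearson"
}

#' First-order Markov check for a numeric attribute
#'
#' Compares the direct correlation between wave-0 ancestors and their
#' wave-`max_wave` lineal descendants (`r_direct`) with the product of the
#' stepwise correlations (`r_predicted`). Under a first-order recruitment
#' process with linear dependence the two agree up to sampling error; a
#' systematic excess of `r_direct` indicates that recruitees resemble
#' earlier-wave recruiters beyond what the direct link explains. Both values
#' are reported; no automatic verdict is issued.
#'
#' @param forest an `rds_forest`.
#' @param attribute numeric attribute (default `"age"`).
#' @param max_wave chain depth of the check (default 3).
#' @param complete_only drop pairs involving an incomplete response.
#' @return object of class `markov_check`: `attribute`, `r_direct`,
#'   `r_predicted`, `steps` (the stepwise table), `n_direct`.
#' @export
markov_check_numeric <- function(forest, attribute = "age", max_wave = 3,
                                 complete_only = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  steps <- stepwise_correlations(forest, attribute, max_wave = max_wave,
                                 method = "pearson",
                                 complete_only = complete_only)
  pairs <- .lineal_pairs(forest, from_wave = 0, to_wave = max_wave)
  p <- forest$participants
  if (complete_only) {
    complete <- setNames(p$complete, p$id)
    pairs <- pairs[complete[pairs$ancestor] & complete[pairs$descendant], ,
                   drop = FALSE]
  }
  vals <- setNames(.attribute_values(forest, attribute), p$id)
  x <- vals[pairs$ancestor]
  y <- vals[pairs$descendant]
  ok <- !is.na(x) & !is.na(y)
  n_direct <- sum(ok)
  if (n_direct < 2) {
    .rds_stop("rdsmix_markov_error",
              "no wave-0 to wave-", max_wave, " lineal pairs: ",
              "forest not deep enough for the check")
  }
  if (n_direct < 20) {
    warning("only ", n_direct, " wave-0 to wave-", max_wave,
            " pairs: direct correlation is unstable", call. = FALSE)
  }
  r_direct <- .pair_cor(x[ok], y[ok], "pearson", symmetrize = FALSE)
  r_predicted <- prod(steps$estimate)
  structure(list(attribute = attribute, r_direct = r_direct,
                 r_predicted = r_predicted, steps = steps,
                 n_direct = n_direct, max_wave = max_wave),
            class = "markov_check")
}

# ancestor-descendant pairs exactly `to_wave - from_wave` steps apart,
# found by walking parent pointers up from the descendants
.lineal_pairs <- function(forest, from_wave, to_wave) {
  p <- forest$participants
  parent <- setNames(forest$edges$recruiter_id, forest$edges$recruitee_id)
  desc <- p$id[p$wave == to_wave]
  anc <- desc
  for (s in seq_len(to_wave - from_wave)) anc <- parent[anc]
  data.frame(ancestor = unname(anc), descendant = desc,
             stringsAsFactors = FALSE)
}

#' @export
print.markov_check <- function(x, ...) {
  cat("Markov check for '", x$attribute, "' (waves 0-", x$max_wave, ")\n",
      sep = "")
  cat(sprintf("  r_direct    = %.3f (%d pairs)\n", x$r_direct, x$n_direct))
  cat(sprintf("  r_predicted = %.3f (product of %s)\n", x$r_predicted,
              paste(sprintf("%.3f", x$steps$estimate), collapse = " * ")))
  invisible(x)
}

#' Estimate the one-step transition matrix of a categorical attribute
#'
#' Row-normalized counts of recruiter-state to recruitee-state over all
#' recruitment edges, with the marginal state distribution taken from the
#' wave-0 participants (the comparison of interest starts at the seeds).
#' A state that never appears as a recruiter yields an empty row, which is
#' left uniform with a warning.
#'
#' @param forest an `rds_forest`.
#' @param attribute categorical attribute (e.g. `"sex"`).
#' @param complete_only drop pairs involving an incomplete response.
#' @return object of class `transition_matrix`: `states`, `P`
#'   (row-stochastic), `marginal`, `n_pairs`.
#' @export
estimate_transition_matrix <- function(forest, attribute = "sex",
                                       complete_only = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  p <- forest$participants
  raw <- if (attribute %in% c("sex", "education")) {
    setNames(as.character(p[[attribute]]), p$id)
  } else {
    setNames(as.character(.attribute_values(forest, attribute)), p$id)
  }
  states <- sort(unique(raw[!is.na(raw)]))
  edges <- forest$edges
  if (complete_only) {
    complete <- setNames(p$complete, p$id)
    edges <- edges[complete[edges$recruiter_id] &
                     complete[edges$recruitee_id], , drop = FALSE]
  }
  if (nrow(edges) == 0) {
    .rds_stop("rdsmix_markov_error", "no recruitment pairs to estimate from")
  }
  counts <- table(factor(raw[edges$recruiter_id], levels = states),
                  factor(raw[edges$recruitee_id], levels = states))
  P <- unclass(counts)
  empty <- rowSums(P) == 0
  if (any(empty)) {
    warning("state(s) never observed as recruiter: ",
            paste(states[empty], collapse = ", "),
            "; row(s) left uniform", call. = FALSE)
    P[empty, ] <- 1
  }
  P <- P / rowSums(P)
  marg_tab <- table(factor(raw[p$id[p$wave == 0]], levels = states))
  marginal <- as.numeric(marg_tab) / sum(marg_tab)
  names(marginal) <- states
  structure(list(states = states, P = P, marginal = marginal,
                 n_pairs = nrow(edges)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("One-step transition matrix (", x$n_pairs, " pairs)\n", sep = "")
  print(round(x$P, 3))
  cat("wave-0 marginal:", paste(sprintf("%s = %.3f", x$states, x$marginal),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Phi coefficient implied by a power of a 2-state transition matrix
#'
#' Forms the joint two-way table `J = diag(marginal) P^power` and returns
#' its phi coefficient - the correlation a first-order chain would produce
#' between states `power` recruitment steps apart. For the symmetric chain
#' with stay-probability q and uniform marginal this equals `(2q-1)^power`.
#'
#' @param tm a [estimate_transition_matrix()] result (2 states only; phi is
#'   a 2x2 statistic).
#' @param power number of steps (>= 1), default 3.
#' @return the phi coefficient (numeric scalar).
#' @export
matrix_power_phi <- function(tm, power = 3) {
  stopifnot(inherits(tm, "transition_matrix"), power >= 1)
  if (length(tm$states) != 2) {
    .rds_stop("rdsmix_markov_error",
              "phi is defined for 2 states; got ", length(tm$states))
  }
  Pp <- diag(2)
  for (s in seq_len(power)) Pp <- Pp %*% tm$P
  J <- diag(tm$marginal) %*% Pp
  r <- rowSums(J)
  cl <- colSums(J)
  (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) / sqrt(prod(r) * prod(cl))
}
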