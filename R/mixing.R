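#' @importFrom stats cor pchisq
NULL

# Attribute resolution --------------------------------------------------------

# numeric coding of the attributes used in the mixing and Markov analyses:
# sex -> 1 if female, education -> ordered codes 1..3, two_plus_symptoms ->
# 0/1, degree/eating_count/age as reported
.attribute_values <- function(forest, attribute) {
  p <- forest$participants
  switch(attribute,
    degree = p$degree,
    age = p$age,
    eating_count = p$eating_count,
    sex = as.numeric(p$sex == "female"),
    education = as.numeric(factor(p$education, levels = .education_levels)),
    two_plus_symptoms = as.numeric(count_symptoms(p) >= 2),
    {
      if (!attribute %in% names(p)) {
        .rds_stop("rdsmix_attribute_error", "unknown attribute: ", attribute)
      }
      as.numeric(p[[attribute]])
    })
}

# Pair enumeration ------------------------------------------------------------

#' Enumerate pairs at a given link distance in the recruitment forest
#'
#' All unordered pairs of participants in the same tree whose (unique)
#' tree-path length equals `d`; distances of four or more links are lumped
#' into the `"4+"` class. `mode = "lineal-only"` keeps only
#' ancestor-descendant pairs, i.e. pairs whose path length equals their wave
#' difference.
#'
#' @param forest an `rds_forest`.
#' @param d 1, 2, 3, or `"4+"` (aliases: `">=4"`, `4`, `Inf`).
#' @param mode `"all-pairs"` (default; includes siblings and cousins) or
#'   `"lineal-only"`.
#' @return object of class `pair_set`: list with `distance_label`, `pairs`
#'   (data.frame `id_a`, `id_b`; `id_a` is the shallower-wave member) and
#'   `mode`.
#' @export
pairs_at_distance <- function(forest, d, mode = c("all-pairs",
                                                  "lineal-only")) {
  stopifnot(inherits(forest, "rds_forest"))
  mode <- match.arg(mode)
  lumped <- is.character(d) && d %in% c("4+", ">=4", "\u22654") ||
    (is.numeric(d) && (d >= 4 || is.infinite(d)))
  if (!lumped && !(is.numeric(d) && d %in% 1:3)) {
    .rds_stop("rdsmix_distance_error",
              "d must be 1, 2, 3 or the lumped class \"4+\"")
  }
  label <- if (lumped) "4+" else as.character(d)

  p <- forest$participants
  if (nrow(forest$edges) == 0) {
    return(structure(list(distance_label = label,
                          pairs = data.frame(id_a = character(0),
                                             id_b = character(0)),
                          mode = mode), class = "pair_set"))
  }
  g <- igraph::graph_from_data_frame(forest$edges, directed = FALSE,
                                     vertices = data.frame(name = p$id))
  # pairs only exist within a tree: work component by component so memory
  # stays linear in tree size, not quadratic in the whole survey
  by_tree <- split(p$id, p$tree_id)
  id_a <- id_b <- character(0)
  dist_val <- numeric(0)
  for (tree_ids in by_tree) {
    if (length(tree_ids) < 2) next
    D <- igraph::distances(g, v = tree_ids, to = tree_ids)
    sel <- if (lumped) is.finite(D) & D >= 4 else D == d
    sel[lower.tri(sel, diag = TRUE)] <- FALSE
    idx <- which(sel, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    id_a <- c(id_a, rownames(D)[idx[, 1]])
    id_b <- c(id_b, colnames(D)[idx[, 2]])
    dist_val <- c(dist_val, D[idx])
  }
  wave <- setNames(p$wave, p$id)
  if (mode == "lineal-only") {
    keep <- dist_val == abs(wave[id_a] - wave[id_b])
    id_a <- id_a[keep]
    id_b <- id_b[keep]
  }
  # canonical orientation: shallower wave first (ties broken by id)
  swap <- wave[id_b] < wave[id_a] |
    (wave[id_b] == wave[id_a] & id_b < id_a)
  tmp <- id_a[swap]
  id_a[swap] <- id_b[swap]
  id_b[swap] <- tmp
  ord <- order(id_a, id_b)
  structure(list(distance_label = label,
                 pairs = data.frame(id_a = id_a[ord], id_b = id_b[ord],
                                    stringsAsFactors = FALSE),
                 mode = mode),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat("<pair_set> distance ", x$distance_label, " (", x$mode, "): ",
      nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}

# Correlations ----------------------------------------------------------------

#' Attribute correlation over a set of linked pairs
#'
#' Computes the mixing correlation for one attribute over the pairs of a
#' [pairs_at_distance()] set: Pearson's r for integer attributes, the phi
#' coefficient for binary attributes (Pearson on 0/1 coding), or Spearman's
#' rank correlation for ordinal ones. For unordered pairs the estimate is
#' computed on the symmetrized pair list (each pair entered in both
#' orientations) so it is orientation-free; the CI and p-value use the
#' number of distinct pairs. Incomplete responses are excluded by default
#' (they stay in the forest for structure, not for attribute analyses).
#'
#' The asymptotic CI is Fisher-z for r and the rank correlation; for phi the
#' p-value is the 1-df chi-square of `n * phi^2`. These treat pairs as
#' independent, which the recruitment-tree dependence structure violates; a
#' cluster bootstrap over trees is available via
#' `ci_method = "cluster-bootstrap"`.
#'
#' @param forest an `rds_forest`.
#' @param pairset a `pair_set`.
#' @param attribute attribute name (`"age"`, `"degree"`, `"sex"`,
#'   `"education"`, `"eating_count"`, `"two_plus_symptoms"`, or any numeric
#'   participant column).
#' @param method `"pearson"`, `"spearman"` or `"phi"`.
#' @param transform `"none"`, `"log"` (natural log of value + 1, since zero
#'   degrees occur) or `"categorize"` (quintile bins of the pooled values).
#' @param symmetrize enter each pair in both orientations (default `TRUE`;
#'   set `FALSE` for ordered recruiter-to-recruitee analyses).
#' @param complete_only drop pairs involving an incomplete response.
#' @param ci_method `"asymptotic"` or `"cluster-bootstrap"` (percentile CI
#'   over `B` resamples of whole trees).
#' @param B bootstrap replicates for the cluster bootstrap.
#' @return object of class `mixing_correlation`: `attribute`, `method`,
#'   `transform`, `distance_label`, `estimate`, `ci_95`, `p_value`,
#'   `n_pairs`.
#' @export
correlate_pairs <- function(forest, pairset, attribute,
                            method = c("pearson", "spearman", "phi"),
                            transform = c("none", "log", "categorize"),
                            symmetrize = TRUE, complete_only = TRUE,
                            ci_method = c("asymptotic", "cluster-bootstrap"),
                            B = 1000) {
  stopifnot(inherits(forest, "rds_forest"), inherits(pairset, "pair_set"))
  method <- match.arg(method)
  transform <- match.arg(transform)
  ci_method <- match.arg(ci_method)

  p <- forest$participants
  vals <- .attribute_values(forest, attribute)
  names(vals) <- p$id
  vals <- .apply_transform(vals, transform)

  pairs <- pairset$pairs
  if (complete_only) {
    complete <- setNames(p$complete, p$id)
    pairs <- pairs[complete[pairs$id_a] & complete[pairs$id_b], ,
                   drop = FALSE]
  }
  x <- vals[pairs$id_a]
  y <- vals[pairs$id_b]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) {
    .rds_stop("rdsmix_correlation_error",
              "fewer than 2 pairs with complete attribute data")
  }
  est <- .pair_cor(x, y, method, symmetrize)
  if (is.na(est)) {
    .rds_stop("rdsmix_correlation_error",
              "zero variance in a margin: correlation undefined for ",
              attribute)
  }

  # inference on the number of distinct pairs, not the symmetrized count
  if (method == "phi") {
    p_value <- pchisq(n * est^2, df = 1, lower.tail = FALSE)
  } else {
    z <- atanh(min(max(est, -1 + 1e-12), 1 - 1e-12))
    p_value <- 2 * pnorm(-abs(z) * sqrt(max(n - 3, 1)))
  }
  ci <- if (ci_method == "asymptotic") {
    z <- atanh(min(max(est, -1 + 1e-12), 1 - 1e-12))
    se <- 1 / sqrt(max(n - 3, 1))
    tanh(z + c(-1, 1) * qnorm(0.975) * se)
  } else {
    .cluster_bootstrap_ci(forest, pairs[ok, , drop = FALSE], vals, method,
                          symmetrize, B)
  }
  structure(list(attribute = attribute, method = method,
                 transform = transform,
                 distance_label = pairset$distance_label,
                 estimate = est, ci_95 = ci, p_value = p_value,
                 n_pairs = n, ci_method = ci_method),
            class = "mixing_correlation")
}

.apply_transform <- function(vals, transform) {
  switch(transform,
    none = vals,
    log = log(vals + 1),
    categorize = {
      br <- unique(quantile(vals, seq(0, 1, 0.2), na.rm = TRUE))
      setNames(as.numeric(cut(vals, breaks = br, include.lowest = TRUE)),
               names(vals))
    })
}

.pair_cor <- function(x, y, method, symmetrize) {
  if (symmetrize) {
    X <- c(x, y); Y <- c(y, x)
  } else {
    X <- x; Y <- y
  }
  if (stats::sd(X) == 0 || stats::sd(Y) == 0) return(NA_real_)
  if (method == "spearman") {
    cor(X, Y, method = "spearman")
  } else {
    cor(X, Y)  # phi is Pearson on 0/1 coding
  }
}

.cluster_bootstrap_ci <- function(forest, pairs, vals, method, symmetrize,
                                  B) {
  tree <- setNames(forest$participants$tree_id, forest$participants$id)
  pair_tree <- tree[pairs$id_a]
  trees <- unique(pair_tree)
  by_tree <- split(seq_len(nrow(pairs)), pair_tree)
  ests <- vapply(seq_len(B), function(b) {
    take <- unlist(by_tree[sample(trees, length(trees), replace = TRUE)],
                   use.names = FALSE)
    if (length(take) < 2) return(NA_real_)
    .pair_cor(vals[pairs$id_a[take]], vals[pairs$id_b[take]], method,
              symmetrize)
  }, numeric(1))
  unname(quantile(ests, c(0.025, 0.975), na.rm = TRUE))
}

#' @export
print.mixing_correlation <- function(x, ...) {
  cat(sprintf("%s (%s%s), distance %s: %.3f [%.3f-%.3f], p = %.3g, %d pairs\n",
              x$attribute, x$method,
              if (x$transform != "none") paste0(", ", x$transform) else "",
              x$distance_label, x$estimate, x$ci_95[1], x$ci_95[2],
              x$p_value, x$n_pairs))
  invisible(x)
}

# Matrices --------------------------------------------------------------------

#' Recruiter-recruitee contact intensity matrix
#'
#' Counts of ordered distance-1 (recruiter, recruitee) pairs per attribute
#' bin, plus the same matrix normalized to proportions of the total.
#'
#' @param forest an `rds_forest`.
#' @param attribute attribute to bin (default `"age"`).
#' @param breaks bin breaks covering the attribute range (default 5-year
#'   bins, ages 10-80).
#' @param complete_only restrict to pairs where both completed the survey.
#' @return object of class `contact_intensity_matrix`: list with `counts`,
#'   `proportions` (summing to 1), `breaks`, `attribute`.
#' @export
recruiter_recruitee_matrix <- function(forest, attribute = "age",
                                       breaks = seq(10, 80, 5),
                                       complete_only = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  p <- forest$participants
  vals <- setNames(.attribute_values(forest, attribute), p$id)
  edges <- forest$edges
  if (complete_only) {
    complete <- setNames(p$complete, p$id)
    edges <- edges[complete[edges$recruiter_id] &
                     complete[edges$recruitee_id], , drop = FALSE]
  }
  vr <- vals[edges$recruiter_id]
  ve <- vals[edges$recruitee_id]
  br <- cut(vr, breaks, right = FALSE, include.lowest = FALSE)
  be <- cut(ve, breaks, right = FALSE, include.lowest = FALSE)
  out_of_range <- is.na(br) | is.na(be)
  if (any(out_of_range)) {
    off <- unique(c(edges$recruiter_id[is.na(br)],
                    edges$recruitee_id[is.na(be)]))
    .rds_stop("rdsmix_bin_error", attribute,
              " value outside the bin range for record(s): ",
              paste(head(off, 5), collapse = ", "))
  }
  counts <- table(recruiter = br, recruitee = be)
  structure(list(counts = unclass(counts),
                 proportions = unclass(counts) / sum(counts),
                 breaks = breaks, attribute = attribute),
            class = "contact_intensity_matrix")
}

#' Age-direction proportions of reported contacts
#'
#' For each participant age group and each context (contacts at locations,
#' contacts while eating), the proportion of reported contact persons that
#' were younger than, the same age as, or older than the participant,
#' aggregated from the per-participant tallies.
#'
#' @param forest an `rds_forest`.
#' @param age_breaks participant age-group breaks (default 5-year bins,
#'   10-80).
#' @return data.frame with columns `context`, `age_group`, `younger`,
#'   `same`, `older` (row proportions summing to 1) and `n_contacts`.
#' @export
age_direction_proportions <- function(forest, age_breaks = seq(10, 80, 5)) {
  stopifnot(inherits(forest, "rds_forest"))
  p <- forest$participants
  grp <- cut(p$age, age_breaks, right = FALSE)
  ctx <- list(locations = c("loc_younger", "loc_same", "loc_older"),
              eating = c("eat_younger", "eat_same", "eat_older"))
  out <- lapply(names(ctx), function(context) {
    cols <- ctx[[context]]
    agg <- rowsum(p[, cols], grp, na.rm = TRUE)
    tot <- rowSums(agg)
    props <- agg / ifelse(tot > 0, tot, NA)
    data.frame(context = context, age_group = rownames(agg),
               younger = props[, 1], same = props[, 2], older = props[, 3],
               n_contacts = tot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
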