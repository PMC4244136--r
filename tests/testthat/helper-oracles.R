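# Fixture builders and independent oracles used across the suite.

# minimal valid participant table; any column can be overridden
toy_participants <- function(ids, ...) {
  n <- length(ids)
  base <- data.frame(
    id = as.character(ids), country = "NL", age = 30, sex = "female",
    education = "higher", household_size = 2,
    loc_work = 0, tra_bus = 0, eating_count = 0,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# a single recruitment chain p1 -> p2 -> ... with given attribute values
chain_forest <- function(n, age = NULL, sex = NULL, ...) {
  ids <- paste0("p", seq_len(n))
  p <- toy_participants(ids, ...)
  if (!is.null(age)) p$age <- age
  if (!is.null(sex)) p$sex <- sex
  e <- data.frame(recruiter_id = ids[-n], recruitee_id = ids[-1],
                  stringsAsFactors = FALSE)
  rds_forest(p, e)
}

# forest made of many parallel chains of length `len + 1` (waves 0..len),
# carrying per-node numeric values in `age`; values given as a matrix with
# one row per chain
chains_forest <- function(values) {
  n_chain <- nrow(values)
  len <- ncol(values)
  ids <- outer(seq_len(n_chain), seq_len(len),
               function(i, w) paste0("c", i, "w", w - 1))
  p <- toy_participants(as.vector(ids), age = as.vector(values))
  e <- do.call(rbind, lapply(seq_len(len - 1), function(w) {
    data.frame(recruiter_id = ids[, w], recruitee_id = ids[, w + 1],
               stringsAsFactors = FALSE)
  }))
  rds_forest(p, e)
}

# random forest over n nodes with fan-out <= 4, for structural oracles
random_forest_fixture <- function(n, n_seeds = max(1, n %/% 20)) {
  ids <- paste0("n", seq_len(n))
  parent <- rep(NA_character_, n)
  fanout <- integer(n)
  for (i in seq_len(n)[-seq_len(n_seeds)]) {
    cand <- which(fanout[seq_len(i - 1)] < 4)
    j <- if (length(cand) == 1) cand else sample(cand, 1)
    parent[i] <- ids[j]
    fanout[j] <- fanout[j] + 1
  }
  e <- data.frame(recruiter_id = parent[!is.na(parent)],
                  recruitee_id = ids[!is.na(parent)],
                  stringsAsFactors = FALSE)
  rds_forest(toy_participants(ids, age = sample(15:70, n, replace = TRUE)), e)
}

# hand-written BFS all-pairs shortest-path oracle over the undirected edges
bfs_dist_oracle <- function(ids, edges) {
  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- idx[[edges$recruiter_id[r]]]
    b <- idx[[edges$recruitee_id[r]]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  for (s in idx) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# canonical "a|b" keys of the unordered pairs at distance d (or >= 4)
oracle_pair_keys <- function(D, d) {
  sel <- if (identical(d, "4+")) is.finite(D) & D >= 4 else D == d
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  a <- rownames(D)[idx[, 1]]
  b <- colnames(D)[idx[, 2]]
  sort(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

pairset_keys <- function(ps) {
  sort(paste(pmin(ps$pairs$id_a, ps$pairs$id_b),
             pmax(ps$pairs$id_a, ps$pairs$id_b), sep = "|"))
}

# brute-force Scholz-Stephens A2akN (midrank version), written directly from
# the distinct-value formula with explicit counting loops
adk_brute <- function(samples) {
  pooled <- unlist(samples)
  N <- length(pooled)
  z <- sort(unique(pooled))
  total <- 0
  for (i in seq_along(samples)) {
    x <- samples[[i]]
    ni <- length(x)
    inner <- 0
    for (j in seq_along(z)) {
      lj <- sum(pooled == z[j])
      fij <- sum(x == z[j])
      Mij <- sum(x <= z[j])
      Bj <- sum(pooled <= z[j])
      Maij <- Mij - fij / 2
      Baj <- Bj - lj / 2
      den <- Baj * (N - Baj) - N * lj / 4
      if (den > 0) {
        inner <- inner + (lj / N) * (N * Maij - ni * Baj)^2 / den
      }
    }
    total <- total + inner / ni
  }
  (N - 1) / N * total
}

# log-likelihood / gradient maximizer for the logistic model, independent of
# the IRLS route: quasi-Newton ascent on the explicit Bernoulli likelihood
logistic_oracle <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(beta) {
    eta <- drop(X %*% beta)
    -drop(t(X) %*% (y - plogis(eta)))
  }
  opt <- optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  opt$par
}

# profile with deterministic full-success chain recruitment (one recruitee
# per participant), used to grow deep chains for the Markov analyses
chain_profile <- function(name = "NL-like", ...) {
  country_profile(name,
                  recruitment = list(invite_prob = 1, success_prob = 1,
                                     max_invites = 1, invite_coef = NULL),
                  ...)
}
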