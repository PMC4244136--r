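#' @importFrom stats var median setNames complete.cases
#' @importFrom utils read.csv write.csv head
NULL

# Column dialect -------------------------------------------------------------
#
# One row per participant, UTF-8, comma-delimited, header row. Per-setting
# contact counts live in prefixed columns: `loc_<type>` (contacts at
# locations), `tra_<type>` (contacts while travelling). Symptoms are
# semicolon-joined tokens from the fixed questionnaire list.

.required_participant_cols <- c(
  "id", "country", "age", "sex", "education", "household_size", "eating_count"
)

.education_levels <- c("high_school", "vocational", "higher")

.recruitment_methods <- c("facebook", "indirect_email", "direct_email", "seed")

#' Fixed symptom list
#'
#' The questionnaire's symptom checklist. The first six tokens define the two
#' symptom classes: influenza-like illness (fever + headache + muscle pain)
#' and common cold (runny nose + sore throat + cough).
#'
#' @return character vector of valid symptom tokens.
#' @export
symptom_list <- function() {
  c("fever", "headache", "muscle_pain",
    "runny_nose", "sore_throat", "cough",
    "sneezing", "chills", "fatigue")
}

.ili_triple  <- c("fever", "headache", "muscle_pain")
.cold_triple <- c("runny_nose", "sore_throat", "cough")

.loc_cols <- function(participants) {
  grep("^loc_(?!younger$|same$|older$)", names(participants),
       value = TRUE, perl = TRUE)
}

.tra_cols <- function(participants) {
  grep("^tra_", names(participants), value = TRUE)
}

# Forest class ----------------------------------------------------------------

#' Construct and validate a recruitment forest
#'
#' Bundles a participant table and a recruiter-to-recruitee edge table into a
#' validated `rds_forest`. Waves (recruitment generations) and tree membership
#' are derived by breadth-first traversal from the seeds (participants with no
#' recruiter); they are never trusted from the input.
#'
#' Validation enforces the chain-referral design: every participant has at
#' most one recruiter, the edges form a forest (no cycles), nobody recruits
#' more than four recruitees, and all contact counts are non-negative
#' integers.
#'
#' @param participants data.frame, one row per participant. Required columns:
#'   `id`, `country`, `age`, `sex`, `education`, `household_size`,
#'   `eating_count`, plus at least one `loc_*` or `tra_*` contact-count
#'   column. Optional columns (`symptoms`, `recording_day`,
#'   `household_symptomatic`, `recruitment_method`, `requested_invitations`,
#'   `complete`, age-direction tallies `loc_younger`/`loc_same`/`loc_older`
#'   and `eat_younger`/`eat_same`/`eat_older`) are filled with defaults when
#'   absent.
#' @param edges data.frame with columns `recruiter_id`, `recruitee_id`.
#' @return An object of class `rds_forest`: a list with elements
#'   `participants` (the table with derived columns `wave`, `tree_id`,
#'   `degree`) and `edges`.
#' @seealso [load_survey()], [compute_degree()], [filter_records()]
#' @examples
#' p <- data.frame(id = c("s", "a", "b"), country = "NL",
#'                 age = c(25, 30, 22), sex = c("female", "male", "female"),
#'                 education = "higher", household_size = 2,
#'                 loc_work = c(5, 2, 0), tra_bus = c(1, 0, 3),
#'                 eating_count = 2)
#' e <- data.frame(recruiter_id = c("s", "s"), recruitee_id = c("a", "b"))
#' f <- rds_forest(p, e)
#' f$participants$wave  # 0 1 1
#' @export
rds_forest <- function(participants, edges = NULL) {
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(recruiter_id = character(0),
                        recruitee_id = character(0),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)

  missing_cols <- setdiff(.required_participant_cols, names(participants))
  if (length(missing_cols) > 0) {
    .rds_stop("rdsmix_schema_error",
              "participant table lacks required column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  if (!all(c("recruiter_id", "recruitee_id") %in% names(edges))) {
    .rds_stop("rdsmix_schema_error",
              "edge table must have columns recruiter_id, recruitee_id")
  }
  participants$id <- as.character(participants$id)
  edges$recruiter_id <- as.character(edges$recruiter_id)
  edges$recruitee_id <- as.character(edges$recruitee_id)

  if (anyDuplicated(participants$id)) {
    .rds_stop("rdsmix_schema_error", "duplicated participant id(s): ",
              paste(unique(participants$id[duplicated(participants$id)]),
                    collapse = ", "))
  }

  participants <- .fill_optional_columns(participants)
  .validate_counts(participants)
  .validate_edges(participants, edges)

  bfs <- .assign_waves(participants$id, edges)
  participants$wave <- bfs$wave
  participants$tree_id <- bfs$tree_id
  participants$degree <- compute_degree(participants)

  structure(list(participants = participants, edges = edges),
            class = "rds_forest")
}

.fill_optional_columns <- function(participants) {
  n <- nrow(participants)
  defaults <- list(
    symptoms = "", recording_day = NA_character_,
    household_symptomatic = NA_integer_,
    recruitment_method = NA_character_, requested_invitations = NA,
    complete = TRUE,
    loc_younger = NA_integer_, loc_same = NA_integer_, loc_older = NA_integer_,
    eat_younger = NA_integer_, eat_same = NA_integer_, eat_older = NA_integer_
  )
  for (col in names(defaults)) {
    if (!col %in% names(participants)) participants[[col]] <- rep(defaults[[col]], n)
  }
  participants$symptoms[is.na(participants$symptoms)] <- ""
  participants$complete <- as.logical(participants$complete)
  participants$requested_invitations <- as.logical(participants$requested_invitations)
  participants
}

.validate_counts <- function(participants) {
  count_cols <- c(.loc_cols(participants), .tra_cols(participants),
                  "eating_count")
  if (length(count_cols) == 1) {
    .rds_stop("rdsmix_schema_error",
              "no loc_* or tra_* contact-count columns present")
  }
  for (col in count_cols) {
    bad <- !.is_count(participants[[col]])
    if (any(bad)) {
      .rds_stop("rdsmix_count_error", "malformed count in column '", col,
                "' for record(s): ",
                paste(head(participants$id[bad], 5), collapse = ", "))
    }
  }
  bad_hh <- !(.is_count(participants$household_size) &
                participants$household_size >= 1)
  if (any(bad_hh)) {
    .rds_stop("rdsmix_count_error",
              "household_size must be an integer >= 1 for record(s): ",
              paste(head(participants$id[bad_hh], 5), collapse = ", "))
  }
  bad_edu <- !is.na(participants$education) &
    !participants$education %in% .education_levels
  if (any(bad_edu)) {
    .rds_stop("rdsmix_schema_error",
              "unknown education level for record(s): ",
              paste(head(participants$id[bad_edu], 5), collapse = ", "),
              " (expected ", paste(.education_levels, collapse = " < "), ")")
  }
  # age-direction tallies may not exceed the context total (when reported)
  loc_total <- rowSums(participants[, .loc_cols(participants), drop = FALSE])
  .validate_tallies(participants, c("loc_younger", "loc_same", "loc_older"),
                    loc_total, "locations")
  .validate_tallies(participants, c("eat_younger", "eat_same", "eat_older"),
                    participants$eating_count, "eating")
  invisible(TRUE)
}

.validate_tallies <- function(participants, cols, total, context) {
  tal <- participants[, cols, drop = FALSE]
  reported <- stats::complete.cases(tal)
  if (!any(reported)) return(invisible(TRUE))
  s <- rowSums(tal[reported, , drop = FALSE])
  bad <- s > total[reported] + 1e-8
  if (any(bad)) {
    .rds_stop("rdsmix_count_error",
              "age-direction tallies exceed the ", context,
              " contact total for record(s): ",
              paste(head(participants$id[reported][bad], 5), collapse = ", "))
  }
  invisible(TRUE)
}

.validate_edges <- function(participants, edges) {
  ids <- participants$id
  unknown <- setdiff(c(edges$recruiter_id, edges$recruitee_id), ids)
  if (length(unknown) > 0) {
    .rds_stop("rdsmix_unknown_id_error",
              "edge references unknown participant id(s): ",
              paste(head(unknown, 5), collapse = ", "))
  }
  self <- edges$recruiter_id == edges$recruitee_id
  if (any(self)) {
    .rds_stop("rdsmix_self_edge_error", "self-recruitment edge for id(s): ",
              paste(head(edges$recruiter_id[self], 5), collapse = ", "))
  }
  multi <- unique(edges$recruitee_id[duplicated(edges$recruitee_id)])
  if (length(multi) > 0) {
    .rds_stop("rdsmix_multiparent_error",
              "participant(s) with more than one recruiter: ",
              paste(head(multi, 5), collapse = ", "))
  }
  fanout <- table(edges$recruiter_id)
  over <- names(fanout)[fanout > 4]
  if (length(over) > 0) {
    .rds_stop("rdsmix_fanout_error",
              "participant(s) recruiting more than 4 recruitees: ",
              paste(head(over, 5), collapse = ", "))
  }
  invisible(TRUE)
}

# Breadth-first wave/tree assignment from seeds; unreached nodes (only
# possible through a cycle, given the single-recruiter check) are an error.
.assign_waves <- function(ids, edges) {
  wave <- setNames(rep(NA_integer_, length(ids)), ids)
  tree <- setNames(rep(NA_character_, length(ids)), ids)
  children <- split(edges$recruitee_id, factor(edges$recruiter_id, levels = ids))
  seeds <- setdiff(ids, edges$recruitee_id)
  wave[seeds] <- 0L
  tree[seeds] <- seeds
  frontier <- seeds
  w <- 0L
  while (length(frontier) > 0) {
    nxt <- unlist(children[frontier], use.names = FALSE)
    if (length(nxt) == 0) break
    parent_of <- rep(frontier, lengths(children[frontier]))
    w <- w + 1L
    wave[nxt] <- w
    tree[nxt] <- tree[parent_of]
    frontier <- nxt
  }
  unreached <- ids[is.na(wave)]
  if (length(unreached) > 0) {
    .rds_stop("rdsmix_cycle_error",
              "cycle detected in recruitment edges involving id(s): ",
              paste(head(unreached, 5), collapse = ", "))
  }
  list(wave = unname(wave[ids]), tree_id = unname(tree[ids]))
}

#' @export
print.rds_forest <- function(x, ...) {
  p <- x$participants
  cat("<rds_forest> ", nrow(p), " participants, ", nrow(x$edges),
      " recruitment edges\n", sep = "")
  cat("  countries: ", paste(sort(unique(p$country)), collapse = ", "), "\n",
      sep = "")
  cat("  seeds: ", sum(p$wave == 0), ", max wave: ", max(p$wave),
      ", trees: ", length(unique(p$tree_id)), "\n", sep = "")
  invisible(x)
}

# I/O -------------------------------------------------------------------------

#' Load a survey dataset from delimited text
#'
#' Reads the participant and edge tables (UTF-8, comma-delimited, header row)
#' and returns a validated [rds_forest()] with waves assigned by breadth-first
#' traversal from the seeds.
#'
#' @param participant_file path to participants.csv.
#' @param edge_file path to edges.csv (may reference an empty table).
#' @return an `rds_forest`.
#' @export
load_survey <- function(participant_file, edge_file) {
  participants <- read.csv(participant_file, stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  edges <- read.csv(edge_file, stringsAsFactors = FALSE,
                    colClasses = "character")
  rds_forest(participants, edges)
}

#' Write a survey dataset to delimited text
#'
#' Writes `participants.csv` and `edges.csv` in the dialect read by
#' [load_survey()]. Derived columns (`wave`, `tree_id`, `degree`) are written
#' too; they are recomputed, not trusted, on reload.
#'
#' @param forest an `rds_forest`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_survey <- function(forest, dir) {
  stopifnot(inherits(forest, "rds_forest"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "participants.csv")
  ep <- file.path(dir, "edges.csv")
  write.csv(forest$participants, pp, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  write.csv(forest$edges, ep, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(c(participants = pp, edges = ep))
}

#' Export the recruitment forest as GraphML
#'
#' Node attributes carried along: wave, degree, and 10-year age group, for
#' network-diagram rendering in external tools.
#'
#' @param forest an `rds_forest`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_graphml <- function(forest, path) {
  stopifnot(inherits(forest, "rds_forest"))
  p <- forest$participants
  g <- igraph::graph_from_data_frame(
    forest$edges, directed = TRUE,
    vertices = data.frame(
      name = p$id, wave = p$wave, degree = p$degree,
      age_group = as.character(cut(p$age, breaks = seq(0, 120, 10),
                                   right = FALSE)),
      stringsAsFactors = FALSE
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# Derived variables -----------------------------------------------------------

#' Compute participant degree
#'
#' A participant's degree is the total number of contact persons reported for
#' the recording day: the sum of the contacts at different locations
#' (`loc_*` columns) and while travelling (`tra_*` columns). Contacts while
#' eating and household members are tallied separately and are *not* part of
#' the degree.
#'
#' @param x an `rds_forest` or a participant data.frame.
#' @return integer vector of degrees, one per participant.
#' @examples
#' p <- data.frame(id = "a", country = "NL", age = 30, sex = "female",
#'                 education = "higher", household_size = 2,
#'                 loc_work = 5, loc_home = 2, tra_bus = 3, eating_count = 4)
#' compute_degree(p)  # 10: eating contacts are excluded
#' @export
compute_degree <- function(x) {
  p <- if (inherits(x, "rds_forest")) x$participants else x
  cols <- c(.loc_cols(p), .tra_cols(p))
  as.integer(round(rowSums(p[, cols, drop = FALSE])))
}

#' Classify reported symptoms
#'
#' Influenza-like illness (ILI) is the co-occurrence of fever, headache and
#' muscle pain; common cold is the co-occurrence of runny nose, sore throat
#' and cough. A participant reporting both triples is classified `both`.
#'
#' @param x an `rds_forest`, a participant data.frame, or a character vector
#'   of semicolon-joined symptom strings.
#' @return factor with levels `ILI`, `common_cold`, `both`, `neither`.
#' @examples
#' classify_symptoms("fever;headache;muscle_pain")  # ILI
#' classify_symptoms("")                            # neither
#' @export
classify_symptoms <- function(x) {
  symptoms <- if (inherits(x, "rds_forest")) {
    x$participants$symptoms
  } else if (is.data.frame(x)) {
    x$symptoms
  } else {
    as.character(x)
  }
  symptoms[is.na(symptoms)] <- ""
  toks <- strsplit(symptoms, ";", fixed = TRUE)
  toks <- lapply(toks, function(t) t[nzchar(t)])
  unknown <- setdiff(unique(unlist(toks)), symptom_list())
  if (length(unknown) > 0) {
    .rds_stop("rdsmix_symptom_error", "unknown symptom label(s): ",
              paste(unknown, collapse = ", "))
  }
  ili  <- vapply(toks, function(t) all(.ili_triple %in% t), logical(1))
  cold <- vapply(toks, function(t) all(.cold_triple %in% t), logical(1))
  cls <- ifelse(ili & cold, "both",
                ifelse(ili, "ILI", ifelse(cold, "common_cold", "neither")))
  factor(cls, levels = c("ILI", "common_cold", "both", "neither"))
}

#' Count reported symptoms
#'
#' @param x as in [classify_symptoms()].
#' @return integer vector: number of distinct symptoms reported.
#' @export
count_symptoms <- function(x) {
  symptoms <- if (inherits(x, "rds_forest")) {
    x$participants$symptoms
  } else if (is.data.frame(x)) x$symptoms else as.character(x)
  symptoms[is.na(symptoms)] <- ""
  toks <- strsplit(symptoms, ";", fixed = TRUE)
  vapply(toks, function(t) length(unique(t[nzchar(t)])), integer(1))
}

# Filtering -------------------------------------------------------------------

#' Filter implausible or incomplete records
#'
#' Removes participants whose degree exceeds `max_degree` (default 2200,
#' above which reported totals indicate a misread contact definition) and,
#' optionally, incomplete responses. Edges incident to removed participants
#' are dropped. Children of a removed participant are, by default, promoted
#' to seeds (wave 0) so that link distances *within* the surviving subtrees
#' stay meaningful; `orphans = "drop"` instead removes the whole descendant
#' subtree.
#'
#' The operation is idempotent: filtering an already-filtered forest with the
#' same settings is a no-op.
#'
#' @param forest an `rds_forest`.
#' @param max_degree degree threshold; participants strictly above it are
#'   removed. Use `Inf` to disable.
#' @param require_complete also drop records with `complete == FALSE`.
#' @param orphans `"promote"` (default) re-roots the children of removed
#'   participants as new seeds; `"drop"` removes their entire subtrees.
#' @return a filtered, revalidated `rds_forest` with attribute `n_removed`.
#' @export
filter_records <- function(forest, max_degree = 2200,
                           require_complete = FALSE,
                           orphans = c("promote", "drop")) {
  stopifnot(inherits(forest, "rds_forest"), max_degree > 0)
  orphans <- match.arg(orphans)
  p <- forest$participants
  remove <- p$degree > max_degree
  if (require_complete) remove <- remove | !p$complete

  if (orphans == "drop" && any(remove)) {
    # propagate removal down the tree: a child of a removed node is removed
    parent <- setNames(forest$edges$recruiter_id, forest$edges$recruitee_id)
    removed_ids <- p$id[remove]
    repeat {
      newly <- forest$edges$recruitee_id[
        forest$edges$recruiter_id %in% removed_ids &
          !forest$edges$recruitee_id %in% removed_ids]
      if (length(newly) == 0) break
      removed_ids <- c(removed_ids, newly)
    }
    remove <- p$id %in% removed_ids
  }

  keep_ids <- p$id[!remove]
  edges <- forest$edges[forest$edges$recruiter_id %in% keep_ids &
                          forest$edges$recruitee_id %in% keep_ids, ,
                        drop = FALSE]
  out <- rds_forest(p[!remove, setdiff(names(p), c("wave", "tree_id", "degree")),
                      drop = FALSE],
                    edges)
  attr(out, "n_removed") <- sum(remove)
  out
}

# Summary table ---------------------------------------------------------------

#' Tabulate sample characteristics per country
#'
#' Reproduces the study-table style per-country counts and percentages:
#' participation totals, complete responses, seed participation and
#' recruitment success, recruiter-recruitee pair counts, wave depth,
#' recruitment-method shares, and symptom-class shares. Percentages are
#' rounded half-up to one decimal.
#'
#' Denominators follow the table's conventions: complete responses out of all
#' participants; seeds completing and seeds recruiting out of the number of
#' *invited* seeds (supply `n_invited_seeds`; otherwise the seeds present in
#' the data are used as denominator); trees with two or more waves out of
#' seeds who recruited; recruitment-method shares out of successfully
#' recruited participants (wave > 0, completed).
#'
#' @param forest an `rds_forest`.
#' @param n_invited_seeds optional named integer vector (names = country
#'   labels) of invited seed counts, which are not observable from the
#'   response data alone.
#' @return data.frame with columns `country`, `item`, `count`, `denom`,
#'   `pct` (percent, `NA` for count-only rows such as `max_wave`).
#' @export
summarize_sample <- function(forest, n_invited_seeds = NULL) {
  stopifnot(inherits(forest, "rds_forest"))
  p <- forest$participants
  edges <- forest$edges
  out <- lapply(sort(unique(p$country)), function(ctry) {
    pc <- p[p$country == ctry, , drop = FALSE]
    ec <- edges[edges$recruiter_id %in% pc$id, , drop = FALSE]
    n_total <- nrow(pc)
    n_complete <- sum(pc$complete)
    seeds <- pc[pc$wave == 0, , drop = FALSE]
    n_seeds <- nrow(seeds)
    n_invited <- if (!is.null(n_invited_seeds) && ctry %in% names(n_invited_seeds)) {
      n_invited_seeds[[ctry]]
    } else {
      n_seeds
    }
    complete_ids <- pc$id[pc$complete]
    # "successfully recruited" = the recruitee completed the questionnaire
    succ_edges <- ec[ec$recruitee_id %in% complete_ids, , drop = FALSE]
    recruiting_seeds <- unique(succ_edges$recruiter_id[
      succ_edges$recruiter_id %in% seeds$id])
    n_rec_seeds <- length(recruiting_seeds)
    n_pairs <- sum(ec$recruiter_id %in% complete_ids &
                     ec$recruitee_id %in% complete_ids)
    tree_waves <- tapply(pc$wave, pc$tree_id, max)
    n_trees2 <- sum(tree_waves >= 2)
    recruited <- pc[pc$wave > 0 & pc$complete, , drop = FALSE]
    n_recruited <- nrow(recruited)
    cls <- classify_symptoms(pc)
    nsym <- count_symptoms(pc)

    row <- function(item, count, denom = NA_real_) {
      data.frame(country = ctry, item = item, count = count, denom = denom,
                 pct = if (is.na(denom)) NA_real_ else pct(count, denom),
                 stringsAsFactors = FALSE)
    }
    method_rows <- do.call(rbind, lapply(
      c("facebook", "indirect_email", "direct_email"), function(m) {
        row(paste0("recruited_by_", m),
            sum(recruited$recruitment_method == m, na.rm = TRUE), n_recruited)
      }))
    rbind(
      row("total_participants", n_total),
      row("complete_responses", n_complete, n_total),
      row("seeds_completed", n_seeds, n_invited),
      row("seeds_recruiting", n_rec_seeds, n_invited),
      row("recruiter_recruitee_pairs", n_pairs),
      row("max_wave", max(pc$wave)),
      row("trees_two_plus_waves", n_trees2,
          if (n_rec_seeds > 0) n_rec_seeds else NA_real_),
      method_rows,
      row("female", sum(pc$sex == "female", na.rm = TRUE),
          sum(!is.na(pc$sex))),
      row("male", sum(pc$sex == "male", na.rm = TRUE), sum(!is.na(pc$sex))),
      row("education_higher", sum(pc$education == "higher", na.rm = TRUE),
          sum(!is.na(pc$education))),
      row("education_vocational",
          sum(pc$education == "vocational", na.rm = TRUE),
          sum(!is.na(pc$education))),
      row("education_high_school",
          sum(pc$education == "high_school", na.rm = TRUE),
          sum(!is.na(pc$education))),
      row("two_plus_symptoms", sum(nsym >= 2), n_total),
      row("ili_symptoms", sum(cls %in% c("ILI", "both")), n_total),
      row("common_cold_symptoms", sum(cls %in% c("common_cold", "both")),
          n_total)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
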