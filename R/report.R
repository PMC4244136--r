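# Pipeline entry points: generate a synthetic dataset, run the full analysis
# over a dataset, or compute the effective-contact-rate table from printed
# moments. A thin command-line wrapper around these functions lives in
# inst/cli/rdsmix.

#' Generate and write a synthetic survey dataset
#'
#' Writes `participants.csv`, `edges.csv` and `metadata.yaml` (profile name,
#' configuration, seed, package version) in the dialect read by
#' [load_survey()]. With the same seed the files are bit-identical across
#' runs.
#'
#' @param out_dir output directory (created if needed).
#' @param profile a [country_profile()] or a profile name.
#' @param n_seeds,max_waves,markov_order see [generator_config()].
#' @param seed RNG seed recorded in the metadata.
#' @return the generated `rds_forest`, invisibly.
#' @export
rds_generate <- function(out_dir, profile = "NL-like", n_seeds = 100,
                         max_waves = 5, markov_order = 1, seed = 1) {
  if (is.character(profile)) profile <- country_profile(profile)
  config <- generator_config(n_seeds = n_seeds, max_waves = max_waves,
                             markov_order = markov_order, rng_seed = seed)
  forest <- generate_forest(profile, config)
  write_survey(forest, out_dir)
  meta <- list(profile = profile$name, country = profile$country,
               n_seeds = n_seeds, max_waves = max_waves,
               markov_order = markov_order, seed = seed,
               n_participants = nrow(forest$participants),
               n_edges = nrow(forest$edges),
               package_version = as.character(utils::packageVersion("rdsmix")))
  yaml::write_yaml(meta, file.path(out_dir, "metadata.yaml"))
  invisible(forest)
}

#' Run the full analysis pipeline
#'
#' Loads (or accepts) a survey dataset, applies the degree filter, and runs
#' the enabled stages, writing one CSV per output next to a run log:
#' `summary.csv` (sample tabulations), `fits.csv`/`tests.csv`/`qq.csv`
#' (degree distributions; the two-sample tests require two countries),
#' `mixing.csv` (correlations by link distance), `markov.csv` (first-order
#' check), `ecr.csv` (effective contact rates), `recruit_fit.csv` and
#' `curve.csv` (recruitment model), plus `forest.graphml`. Any stage failure
#' propagates with the stage name. Reruns with the same seed produce
#' identical numeric outputs.
#'
#' @param input an `rds_forest`, or a directory containing
#'   `participants.csv` and `edges.csv`.
#' @param out_dir output directory (created if needed).
#' @param max_degree degree filter threshold (default 2200).
#' @param require_complete drop incomplete responses at the filter stage.
#' @param stages character vector of stages to run; default all of
#'   `"summary"`, `"fits"`, `"mixing"`, `"markov"`, `"ecr"`, `"recruit"`.
#' @param seed RNG seed for the bootstrap/permutation stages.
#' @param B bootstrap replicates for the distribution fits.
#' @param n_invited_seeds optional named vector for [summarize_sample()].
#' @return invisibly, a named list with the in-memory stage results.
#' @export
rds_analyze <- function(input, out_dir, max_degree = 2200,
                        require_complete = FALSE,
                        stages = c("summary", "fits", "mixing", "markov",
                                   "ecr", "recruit"),
                        seed = 1, B = 1000, n_invited_seeds = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  log_lines <- c(
    paste0("rdsmix ", utils::packageVersion("rdsmix"), " / ",
           R.version.string),
    paste0("seed: ", seed, "; B: ", B, "; max_degree: ", max_degree,
           "; require_complete: ", require_complete),
    paste0("stages: ", paste(stages, collapse = ", "))
  )
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  forest <- run_stage("load", {
    if (inherits(input, "rds_forest")) input
    else load_survey(file.path(input, "participants.csv"),
                     file.path(input, "edges.csv"))
  })
  n_before <- nrow(forest$participants)
  forest <- run_stage("filter", {
    filter_records(forest, max_degree = max_degree,
                   require_complete = require_complete)
  })
  log_lines <- c(log_lines,
                 paste0("participants: ", n_before, " loaded, ",
                        attr(forest, "n_removed"), " removed by filter"))
  p <- forest$participants
  countries <- sort(unique(p$country))
  results <- list(forest = forest)
  wcsv <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  if ("summary" %in% stages) {
    results$summary <- run_stage("summary", {
      s <- summarize_sample(forest, n_invited_seeds = n_invited_seeds)
      wcsv(s, "summary.csv")
      s
    })
  }

  if ("fits" %in% stages) {
    results$fits <- run_stage("fits", {
      fits <- lapply(countries, function(ctry) {
        deg <- p$degree[p$country == ctry & p$complete]
        fit <- fit_negbin(deg, B = B)
        data.frame(country = ctry, mu = fit$mu, k = fit$k,
                   mu_lo = fit$ci_mu[1], mu_hi = fit$ci_mu[2],
                   k_lo = fit$ci_k[1], k_hi = fit$ci_k[2],
                   loglik = fit$loglik, n = fit$n)
      })
      fits <- do.call(rbind, fits)
      wcsv(fits, "fits.csv")
      if (length(countries) >= 2) {
        degs <- lapply(countries, function(ctry)
          p$degree[p$country == ctry & p$complete])
        ad <- ad_ksample(degs)
        ks <- ks_two_sample(degs[[1]], degs[[2]])
        tests <- data.frame(
          method = c(ad$method, ks$method),
          statistic = c(ad$statistic, ks$statistic),
          p_value = c(ad$p_value, ks$p_value),
          p_method = c(ad$p_method, ks$p_method))
        wcsv(tests, "tests.csv")
        qq <- qq_pairs(degs[[1]], degs[[2]])
        names(qq) <- c("prob", paste0("quantile_", countries[1:2]))
        wcsv(qq, "qq.csv")
      } else {
        log_lines <- c(log_lines,
                       "fits: single country, two-sample tests skipped")
      }
      fits
    })
  }

  if ("mixing" %in% stages) {
    results$mixing <- run_stage("mixing", {
      specs <- list(
        list(attribute = "age", method = "pearson", transform = "none"),
        list(attribute = "sex", method = "phi", transform = "none"),
        list(attribute = "education", method = "spearman",
             transform = "none"),
        list(attribute = "degree", method = "pearson", transform = "log"),
        list(attribute = "degree", method = "spearman",
             transform = "categorize"),
        list(attribute = "eating_count", method = "pearson",
             transform = "log"),
        list(attribute = "two_plus_symptoms", method = "phi",
             transform = "none"))
      rows <- list()
      for (ctry in countries) {
        sub <- .subset_country(forest, ctry)
        for (d in list(1, 2, 3, "4+")) {
          ps <- pairs_at_distance(sub, d)
          for (sp in specs) {
            row <- tryCatch({
              r <- correlate_pairs(sub, ps, sp$attribute,
                                   method = sp$method,
                                   transform = sp$transform)
              data.frame(country = ctry, attribute = sp$attribute,
                         method = sp$method, transform = sp$transform,
                         distance = ps$distance_label,
                         estimate = r$estimate, ci_lo = r$ci_95[1],
                         ci_hi = r$ci_95[2], p_value = r$p_value,
                         n_pairs = r$n_pairs)
            }, error = function(e) NULL)
            if (!is.null(row)) rows[[length(rows) + 1]] <- row
          }
        }
      }
      mixing <- do.call(rbind, rows)
      wcsv(mixing, "mixing.csv")
      mixing
    })
  }

  if ("markov" %in% stages) {
    results$markov <- run_stage("markov", {
      rows <- list()
      for (ctry in countries) {
        sub <- .subset_country(forest, ctry)
        age_row <- tryCatch({
          mc <- markov_check_numeric(sub, "age")
          data.frame(country = ctry, attribute = "age",
                     r_direct = mc$r_direct, r_predicted = mc$r_predicted,
                     step_01 = mc$steps$estimate[1],
                     step_12 = mc$steps$estimate[2],
                     step_23 = mc$steps$estimate[3],
                     n_direct = mc$n_direct)
        }, error = function(e) NULL)
        sex_row <- tryCatch({
          steps <- stepwise_correlations(sub, "sex")
          tm <- estimate_transition_matrix(sub, "sex")
          pairs03 <- .lineal_pairs(sub, 0, 3)
          vals <- setNames(.attribute_values(sub, "sex"),
                           sub$participants$id)
          x <- vals[pairs03$ancestor]; y <- vals[pairs03$descendant]
          ok <- !is.na(x) & !is.na(y)
          data.frame(country = ctry, attribute = "sex",
                     r_direct = .pair_cor(x[ok], y[ok], "phi", FALSE),
                     r_predicted = matrix_power_phi(tm, 3),
                     step_01 = steps$estimate[1],
                     step_12 = steps$estimate[2],
                     step_23 = steps$estimate[3],
                     n_direct = sum(ok))
        }, error = function(e) NULL)
        rows <- c(rows, list(age_row), list(sex_row))
      }
      markov <- do.call(rbind, rows)
      if (!is.null(markov)) wcsv(markov, "markov.csv")
      markov
    })
  }

  if ("ecr" %in% stages) {
    results$ecr <- run_stage("ecr", {
      rows <- lapply(countries, function(ctry) {
        s <- category_summaries(.subset_country(forest, ctry))
        cbind(country = ctry, s)
      })
      ecr <- do.call(rbind, rows)
      wcsv(ecr, "ecr.csv")
      ecr
    })
  }

  if ("recruit" %in% stages) {
    results$recruit <- run_stage("recruit", {
      rows <- list()
      curves <- list()
      for (ctry in countries) {
        sub <- .subset_country(forest, ctry)
        for (ss in c("all", "excluding-seeds")) {
          fit <- tryCatch(fit_logistic(sub, subset = ss),
                          error = function(e) NULL)
          if (is.null(fit)) next
          rows[[length(rows) + 1]] <- data.frame(
            country = ctry, subset = ss,
            term = names(fit$coefficients),
            estimate = unname(fit$coefficients), se = unname(fit$se),
            p_value = 2 * pnorm(-abs(fit$coefficients / fit$se)),
            n = fit$n)
          for (fem in c(0, 1)) {
            cu <- probability_vs_degree(fit, profile = list(female = fem))
            curves[[length(curves) + 1]] <- data.frame(
              country = ctry, subset = ss,
              sex = ifelse(fem == 1, "female", "male"), cu)
          }
        }
      }
      fit_df <- do.call(rbind, rows)
      if (!is.null(fit_df)) wcsv(fit_df, "recruit_fit.csv")
      curve_df <- do.call(rbind, curves)
      if (!is.null(curve_df)) wcsv(curve_df, "curve.csv")
      fit_df
    })
  }

  run_stage("export", export_graphml(forest, file.path(out_dir,
                                                       "forest.graphml")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

.subset_country <- function(forest, ctry) {
  p <- forest$participants
  keep <- p$country == ctry
  ids <- p$id[keep]
  edges <- forest$edges[forest$edges$recruiter_id %in% ids &
                          forest$edges$recruitee_id %in% ids, , drop = FALSE]
  rds_forest(p[keep, setdiff(names(p), c("wave", "tree_id", "degree")),
               drop = FALSE], edges)
}

#' Effective contact rates from a moments table or a dataset
#'
#' The table-of-rates entry point. In printed-inputs mode, `moments` is a
#' data.frame with columns `category`, `mean`, `variance` (and optionally
#' `country`); `C = mean + variance/mean` is computed per row. Given an
#' `rds_forest` instead, the per-category summaries are computed from the
#' data via [category_summaries()].
#'
#' @param moments data.frame of printed moments, or an `rds_forest`.
#' @param out optional path to write the resulting CSV.
#' @return data.frame with the input columns plus `C` and `C_rounded`
#'   (half-up, 1 decimal, the table display convention).
#' @examples
#' rds_table2(data.frame(category = "degree", mean = 25.65,
#'                       variance = 2212.2))
#' @export
rds_table2 <- function(moments, out = NULL) {
  if (inherits(moments, "rds_forest")) {
    tab <- category_summaries(moments)
    tab <- data.frame(category = tab$category, mean = tab$mean,
                      variance = tab$variance)
  } else {
    tab <- as.data.frame(moments)
  }
  if (!all(c("category", "mean", "variance") %in% names(tab))) {
    .rds_stop("rdsmix_schema_error",
              "moments need columns category, mean, variance")
  }
  tab$C <- mapply(function(m, v) effective_contact_from_moments(m, v)$C,
                  tab$mean, tab$variance)
  tab$C_rounded <- round_half_up(tab$C, 1)
  if (!is.null(out)) write.csv(tab, out, row.names = FALSE)
  tab
}
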