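#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Run the full sociality-and-siring analysis pipeline
#'
#' From a (synthetic or file-based) observation log: siring windows with
#' relatedness exclusions; maximum-likelihood Elo fit; window sociality
#' metrics; the male-by-event design table; null-model selection (or a
#' fixed null); the full-dataset sociality model comparison and its
#' gregariousness and raw-count variants; the alpha-bond comparison on
#' non-alpha siring events; the coalition-network betweenness analysis;
#' and, optionally, the dyadic probit social relations model of coalition
#' formation.
#'
#' @param log an `obs_log`, or `NULL` to simulate from `config`.
#' @param config a [sim_config()] used when `log` is `NULL`.
#' @param select_null run the all-subsets null-model selection; otherwise
#'   use `null_terms`.
#' @param null_terms fixed null-model terms when `select_null = FALSE`
#'   (the non-social terms selected for this system: relatedness, Elo
#'   score, age).
#' @param model_sets which comparisons to run (subset of `"table1"`,
#'   `"table1_greg"`, `"table1_raw"`, `"table2"`, `"table2_excl_alpha"`,
#'   `"beta_variant"`).
#' @param run_srm fit the social relations model (the slowest stage).
#' @param srm_iter,srm_chains MCMC budget for the SRM stage.
#' @param quadrature_points adaptive Gauss-Hermite points for GLMM fits.
#' @param seed seed for stochastic stages.
#' @return a `pansoc_report` list with the design table, comparison
#'   tables, coalition regression and SRM summaries.
#' @export
run_pipeline <- function(log = NULL, config = sim_config(),
                         select_null = TRUE,
                         null_terms = c("relatedness", "elo_z", "age_z"),
                         model_sets = c("table1", "table2"),
                         run_srm = FALSE, srm_iter = 3000, srm_chains = 3,
                         quadrature_points = 15, seed = 1) {
  truth <- NULL
  if (is.null(log)) {
    config$seed <- config$seed %||% seed
    sim <- simulate_community(config)
    log <- sim$log
    truth <- sim$truth
  }
  set.seed(seed)
  windows <- siring_windows(log) |>
    apply_siring_event_exclusions(log$relatedness)
  elo <- fit_elo_ml(log$pantgrunts, ids = log$roster$id[log$roster$sex == "male"])
  soc <- compute_sociality(log, windows, elo = elo)
  design <- build_design_table(windows, soc$males, elo, log$roster)

  null_sel <- NULL
  if (select_null) {
    null_sel <- select_null_model(design, quadrature_points = quadrature_points)
    null_terms <- null_sel$null_terms
  }

  comparisons <- list()
  if ("table1" %in% model_sets) {
    comparisons$table1 <- compare_sociality_models(
      design, null_terms, table1_measures(), quadrature_points)
  }
  if ("table1_greg" %in% model_sets) {
    comparisons$table1_greg <- compare_sociality_models(
      design, c(null_terms, "z_gregariousness_min"), table1_measures(),
      quadrature_points)
  }
  if ("table1_raw" %in% model_sets) {
    comparisons$table1_raw <- compare_sociality_models(
      design, null_terms, table1_measures(raw_counts = TRUE),
      quadrature_points)
  }
  # alpha-bond comparisons are restricted to events sired by non-alpha males
  non_alpha <- dplyr::left_join(design, soc$info, by = "event_id") |>
    dplyr::group_by(.data$event_id) |>
    dplyr::filter(!any(.data$outcome == 1 & .data$male_id == .data$alpha_id)) |>
    dplyr::ungroup() |>
    dplyr::select(-"alpha_id", -"beta_id")
  if ("table2" %in% model_sets && dplyr::n_distinct(non_alpha$event_id) >= 3) {
    comparisons$table2 <- compare_sociality_models(
      non_alpha, null_terms, table2_model_set(), quadrature_points)
  }
  if ("table2_excl_alpha" %in% model_sets &&
      dplyr::n_distinct(non_alpha$event_id) >= 3) {
    comparisons$table2_excl_alpha <- compare_sociality_models(
      non_alpha, null_terms, table2_model_set(exclude_alpha = TRUE),
      quadrature_points)
  }
  if ("beta_variant" %in% model_sets &&
      dplyr::n_distinct(non_alpha$event_id) >= 3) {
    comparisons$beta_variant <- compare_sociality_models(
      non_alpha, null_terms, table2_model_set(target = "beta"),
      quadrature_points)
  }

  # coalition analyses on non-overlapping calendar years
  dyadic <- dyadize_coalitions(log$coalitions)
  networks <- build_yearly_networks(dyadic)
  betw <- coalition_betweenness(networks)
  yearly_ties <- yearly_strong_ties(log)
  bt_data <- dplyr::inner_join(betw, yearly_ties, by = c("year", "id"))
  coalition_fit <- if (nrow(bt_data) >= 3) {
    betweenness_vs_strong_ties(bt_data)
  } else NULL

  srm <- NULL
  if (run_srm) {
    dy <- build_dyad_year_table(log, elo)
    srm <- fit_srm_probit(dy, n_iter = srm_iter,
                          burn_in = min(1000, srm_iter %/% 5),
                          n_chains = srm_chains, seed = seed)
  }

  structure(list(windows = windows, elo = elo, sociality = soc,
                 design = design, null_selection = null_sel,
                 null_terms = null_terms, comparisons = comparisons,
                 betweenness = bt_data, coalition_fit = coalition_fit,
                 srm = srm, truth = truth, seed = seed),
            class = "pansoc_report")
}

#' Per-male strong-association-tie counts in calendar years
#'
#' Recomputes the count of strong association ties in non-overlapping
#' calendar-year windows (used by the coalition betweenness analysis to
#' avoid pseudoreplicating overlapping siring windows).
#'
#' @param log an `obs_log`.
#' @param min_age minimum male age at mid-year.
#' @return tibble `year`, `id`, `n_strong_assoc_ties`.
#' @export
yearly_strong_ties <- function(log, min_age = 11) {
  years <- sort(unique(as.integer(format(log$arrivals$date, "%Y"))))
  males <- dplyr::filter(log$roster, .data$sex == "male")
  daily <- daily_tables(log)
  purrr::map(years, function(yr) {
    start <- as.Date(sprintf("%d-01-01", yr))
    end <- as.Date(sprintf("%d-01-01", yr + 1))
    mid <- as.Date(sprintf("%d-07-01", yr))
    present <- males$id[age_years(males$birth_date, mid) >= min_age &
                          males$birth_date <= start &
                          (is.na(males$death_date) | males$death_date >= end)]
    if (length(present) < 2) return(NULL)
    dm <- dyad_metrics(log, present, start, end, daily = daily)
    purrr::map(present, function(m) {
      tibble::tibble(year = yr, id = m,
                     n_strong_assoc_ties =
                       association_measures(dm, m)$n_strong_assoc_ties)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' @export
print.pansoc_report <- function(x, ...) {
  cat("<pansoc_report>\n")
  cat(sprintf("  %d siring events, %d design rows, null: %s\n",
              nrow(x$windows), nrow(x$design),
              paste(x$null_terms, collapse = " + ")))
  for (nm in names(x$comparisons)) {
    best <- x$comparisons[[nm]]$model[1]
    cat(sprintf("  %s: best model '%s' (dAICc = %.2f)\n", nm, best,
                x$comparisons[[nm]]$dAICc[1]))
  }
  if (!is.null(x$coalition_fit)) {
    g <- glance(x$coalition_fit)
    cat(sprintf("  betweenness ~ strong ties: slope %.3f, F = %.2f\n",
                g$slope, g$f.statistic))
  }
  if (!is.null(x$srm)) {
    cat(sprintf("  SRM: max PSRF %.3f\n", max(x$srm$psrf$psrf)))
  }
  invisible(x)
}

#' Planted-effect recovery experiment
#'
#' Simulates `n_replicates` communities and summarizes how often the
#' analysis recovers the planted effects: (a) the strong-tie-count model
#' beats the null (negative AICc difference), (b) the two-term CSI-with-
#' alpha + strong-ties model is the best alpha-bond model, and (c) the
#' betweenness-on-strong-ties slope is positive. Uses the fixed non-social
#' null (relatedness + Elo + age).
#'
#' @param n_replicates simulated communities.
#' @param seed integer; each replicate derives its own sub-seed.
#' @param config base [sim_config()] (its `siring_coefs` carry the
#'   planted effects).
#' @param what analyses to run per replicate (`"ties"`, `"table2"`,
#'   `"coalition"`).
#' @param quadrature_points passed to GLMM fits (default Laplace, adequate
#'   for rate summaries over many replicates).
#' @param reuse_sim_metrics reuse the generator's pass-two window metrics
#'   and generation-k Elo trajectory (identical pipeline computations)
#'   instead of recomputing them with a freshly ML-fitted Elo.
#' @return a `recovery_summary` list: per-replicate tibble `replicates`
#'   and named `rates`.
#' @export
recovery_experiment <- function(n_replicates = 20, seed = 1,
                                config = sim_config(),
                                what = c("ties", "table2", "coalition"),
                                quadrature_points = 1,
                                reuse_sim_metrics = TRUE) {
  reps <- purrr::map(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- (seed * 7919L + i * 104729L) %% 2147483562L
    sim <- simulate_community(cfg)
    log <- sim$log
    windows <- siring_windows(log) |>
      apply_siring_event_exclusions(log$relatedness)
    if (reuse_sim_metrics) {
      elo <- sim$metrics$elo
      soc <- sim$metrics
    } else {
      elo <- fit_elo_ml(log$pantgrunts,
                        ids = log$roster$id[log$roster$sex == "male"])
      soc <- compute_sociality(log, windows, elo = elo)
    }
    design <- suppressMessages(
      build_design_table(windows, soc$males, elo, log$roster))
    null_terms <- c("relatedness", "elo_z", "age_z")
    out <- tibble::tibble(replicate = i, n_events = nrow(windows))
    if ("ties" %in% what) {
      f0 <- fit_binomial_glmm(design, null_terms, quadrature_points)
      f1 <- fit_binomial_glmm(design, c(null_terms, "z_n_strong_assoc_ties"),
                              quadrature_points)
      out$dAICc_ties <- f1$aicc - f0$aicc
      out$ties_beats_null <- out$dAICc_ties < 0
    }
    if ("table2" %in% what) {
      non_alpha <- dplyr::left_join(design, soc$info, by = "event_id") |>
        dplyr::group_by(.data$event_id) |>
        dplyr::filter(!any(.data$outcome == 1 & .data$male_id == .data$alpha_id)) |>
        dplyr::ungroup()
      cmp <- compare_sociality_models(non_alpha, null_terms,
                                      table2_model_set(), quadrature_points)
      out$table2_best <- cmp$model[1]
      out$table2_two_term_best <-
        cmp$model[1] == "CSI with alpha + count of strong association ties"
      mm <- dplyr::filter(soc$males, !is.na(.data$z_csi_with_alpha))
      out$cor_ties_csi_alpha <- tryCatch(
        stats::cor(mm$z_n_strong_assoc_ties, mm$z_csi_with_alpha,
                   use = "complete.obs"),
        error = function(e) NA_real_)
    }
    if ("coalition" %in% what) {
      dyadic <- dyadize_coalitions(log$coalitions)
      networks <- suppressMessages(build_yearly_networks(dyadic))
      betw <- coalition_betweenness(networks)
      bt <- dplyr::inner_join(betw, yearly_strong_ties(log),
                              by = c("year", "id"))
      if (nrow(bt) >= 3) {
        g <- glance(betweenness_vs_strong_ties(bt))
        out$coalition_slope <- g$slope
        out$coalition_f <- g$f.statistic
        out$coalition_p <- g$p.value
      }
    }
    out
  })
  reps <- dplyr::bind_rows(reps)
  rates <- list()
  if ("ties" %in% what) {
    rates$ties_beats_null <- mean(reps$ties_beats_null)
    rates$median_dAICc_ties <- stats::median(reps$dAICc_ties)
  }
  if ("table2" %in% what) {
    rates$table2_two_term_best <- mean(reps$table2_two_term_best)
    rates$mean_cor_ties_csi_alpha <- mean(reps$cor_ties_csi_alpha, na.rm = TRUE)
  }
  if ("coalition" %in% what && "coalition_slope" %in% names(reps)) {
    rates$coalition_slope_positive <- mean(reps$coalition_slope > 0, na.rm = TRUE)
    rates$coalition_significant <-
      mean(reps$coalition_slope > 0 & reps$coalition_p < 0.05, na.rm = TRUE)
  }
  structure(list(replicates = reps, rates = rates, seed = seed),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> %d replicates\n", nrow(x$replicates)))
  for (nm in names(x$rates)) cat(sprintf("  %-28s %.3f\n", nm, x$rates[[nm]]))
  invisible(x)
}
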