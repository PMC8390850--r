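#' Build the male-by-siring-event design table
#'
#' One row per candidate male per siring event, with the binomial outcome
#' (1 for the sire, 0 for every other eligible male), the non-social terms
#' (relatedness to the mother, within-window Z-scaled Elo score, male age
#' Z-scaled across the whole dataset and its square, count of
#' reproductive-age males) and every Z-standardized sociality measure.
#'
#' @param windows siring windows with a `candidates` list-column (from
#'   [apply_siring_event_exclusions()]).
#' @param sociality `males` tibble from [compute_sociality()].
#' @param elo an `elo_fit` or `elo_trajectory`.
#' @param roster roster tibble.
#' @param impute_missing replace missing Z-scaled sociality values (dyads
#'   removed by sampling filters) with 0, the within-window mean.
#' @return tibble with `event_id`, `male_id`, `outcome` and predictor
#'   columns; exactly one `outcome = 1` per event.
#' @export
build_design_table <- function(windows, sociality, elo, roster,
                               impute_missing = TRUE) {
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    cand <- windows$candidates[[i]]
    ids <- cand$id
    ev <- windows$event_id[i]
    if (!windows$sire_id[i] %in% ids) {
      stop("event ", ev, ": sire ", windows$sire_id[i],
           " is not among eligible candidates")
    }
    st <- elo_standings(elo, ids, windows$conception_date[i])
    tibble::tibble(
      event_id = ev,
      male_id = ids,
      outcome = as.integer(ids == windows$sire_id[i]),
      relatedness = cand$r,
      elo_z = st$scores$z[match(ids, st$scores$id)],
      age = age_years(roster$birth_date[match(ids, roster$id)],
                      windows$conception_date[i]),
      n_repro_males = length(ids)
    )
  })
  design <- dplyr::bind_rows(rows)
  design$age_z <- as.numeric(scale(design$age))
  design$age2_z <- design$age_z^2
  soc <- dplyr::select(sociality, "event_id", male_id = "id",
                       dplyr::starts_with("z_"))
  design <- dplyr::left_join(design, soc, by = c("event_id", "male_id"))
  if (impute_missing) {
    zcols <- grep("^z_", names(design), value = TRUE)
    n_imp <- sum(is.na(design[zcols]))
    if (n_imp > 0) {
      message(sprintf("design table: %d missing standardized value(s) set to 0", n_imp))
      design <- dplyr::mutate(design, dplyr::across(
        dplyr::starts_with("z_"), ~ dplyr::coalesce(.x, 0)))
    }
  }
  design
}

#' Fit a binomial random-intercept GLMM for siring success
#'
#' Logit-link binomial mixed model with a random intercept for male
#' identity, fitted by maximum likelihood via adaptive Gauss-Hermite
#' quadrature (`quadrature_points = 1` is the Laplace approximation).
#' Parameter count for information criteria is the number of fixed effects
#' (intercept included) plus one random-intercept variance.
#'
#' @param design design table from [build_design_table()].
#' @param fixed_terms character vector of predictor column names (may be
#'   empty: intercept-only null).
#' @param quadrature_points adaptive Gauss-Hermite points.
#' @return a `siring_glmm` wrapping the `glmerMod` fit with `terms`, `n`,
#'   `k`, `loglik`, `aicc` fields.
#' @export
fit_binomial_glmm <- function(design, fixed_terms = character(0),
                              quadrature_points = 15) {
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  f <- as.formula(paste("outcome ~", rhs, "+ (1 | male_id)"))
  fit <- withCallingHandlers(
    lme4::glmer(f, data = design, family = stats::binomial(),
                nAGQ = quadrature_points,
                control = lme4::glmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("failed to converge|unable to evaluate", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fe <- lme4::fixef(fit)
  if (any(abs(fe) > 15)) {
    warning("fit_binomial_glmm: extreme coefficient(s) for ",
            paste(names(fe)[abs(fe) > 15], collapse = ", "),
            " - possible complete separation")
  }
  ll <- logLik(fit)
  k <- length(fe) + 1L
  n <- nrow(design)
  structure(list(fit = fit, terms = fixed_terms, n = n, k = k,
                 loglik = as.numeric(ll), aicc = aicc(as.numeric(ll), k, n)),
            class = "siring_glmm")
}

#' Small-sample-corrected AIC
#'
#' `AICc = -2 * loglik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik log-likelihood (or a `siring_glmm`).
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return a single number; errors when `n <= k + 1`.
#' @examples
#' aicc(-100, 3, 50)
#' @export
aicc <- function(loglik, k = NULL, n = NULL) {
  if (inherits(loglik, "siring_glmm")) return(loglik$aicc)
  if (n <= k + 1) stop("AICc undefined: n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`; interpretable as conditional model
#' probabilities within the compared set.
#'
#' @param aiccs vector of AICc values.
#' @return weights summing to 1.
#' @examples
#' akaike_weights(c(100, 102))
#' @export
akaike_weights <- function(aiccs) {
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Prune models nested one term above a better-supported model
#'
#' Adding a pure-noise term to a well-fitting model tends to produce a
#' model about 2 AICc points worse that can still enter a naive top set;
#' such models are removed: any model that equals a better-supported
#' (lower-AICc) model plus exactly one extra term is dropped.
#'
#' @param models tibble with list-column `terms` and column `AICc`.
#' @return `models` with a logical `pruned` column.
#' @export
prune_nested <- function(models) {
  n <- nrow(models)
  pruned <- logical(n)
  for (i in seq_len(n)) {
    ti <- models$terms[[i]]
    for (j in seq_len(n)) {
      if (j == i || models$AICc[j] >= models$AICc[i]) next
      tj <- models$terms[[j]]
      if (length(ti) == length(tj) + 1 && all(tj %in% ti)) {
        pruned[i] <- TRUE
        break
      }
    }
  }
  dplyr::mutate(models, pruned = pruned)
}

#' Select the non-social null model
#'
#' Fits all subsets of the five non-social candidate terms (random
#' intercept for male identity always included), ranks them by AICc,
#' removes models that are a better-supported model plus one extra term
#' (see [prune_nested()]), and reports the top set within `delta_max` AICc
#' points of the best remaining model with Akaike weights. The best
#' remaining model becomes the null for the sociality comparisons.
#'
#' @param design design table.
#' @param candidates candidate term names.
#' @param delta_max top-set width in AICc points.
#' @param quadrature_points passed to [fit_binomial_glmm()].
#' @return list with `table` (all 2^p models: `model`, `terms`, `df`,
#'   `AICc`, `pruned`, `in_top`, `weight`) and `null_terms`.
#' @export
select_null_model <- function(design,
                              candidates = c("relatedness", "elo_z", "age_z",
                                             "age2_z", "n_repro_males"),
                              delta_max = 6, quadrature_points = 15) {
  subsets <- purrr::map(0:(2^length(candidates) - 1), function(mask) {
    candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1)) > 0]
  })
  fits <- purrr::map(subsets, fit_binomial_glmm, design = design,
                     quadrature_points = quadrature_points)
  tab <- tibble::tibble(
    model = purrr::map_chr(subsets, ~ if (length(.x)) paste(.x, collapse = " + ") else "(intercept only)"),
    terms = subsets,
    df = purrr::map_int(fits, "k"),
    AICc = purrr::map_dbl(fits, "aicc")
  ) |> prune_nested()
  kept <- dplyr::filter(tab, !.data$pruned)
  best <- min(kept$AICc)
  tab$in_top <- !tab$pruned & tab$AICc - best <= delta_max
  tab$weight <- NA_real_
  tab$weight[tab$in_top] <- akaike_weights(tab$AICc[tab$in_top])
  tab <- dplyr::arrange(tab, .data$AICc)
  list(table = tab, null_terms = tab$terms[[1]])
}

#' Table 1 sociality measure set
#'
#' The 15 within-window Z-standardized individual sociality measures
#' compared one at a time against the null: four association measures,
#' eight grooming measures, three CSI measures. `raw_counts = TRUE` swaps
#' the two strong-association measures for their raw joint-arrival-count
#' variants.
#'
#' @param raw_counts use raw-count strong-tie variants.
#' @return named character vector (labels -> design column names).
#' @export
table1_measures <- function(raw_counts = FALSE) {
  m <- c(
    "Count of all association ties" = "z_n_assoc_ties",
    "Sum of all association indices" = "z_sum_sri_all",
    "Count of strong association ties" = "z_n_strong_assoc_ties",
    "Sum of strong assn. indices" = "z_sum_sri_strong",
    "Total time spent grooming" = "z_groom_total_min",
    "Overall grooming rate" = "z_groom_rate_overall",
    "Total grooming partners" = "z_n_groom_partners",
    "Count of strong grooming time partners" = "z_n_strong_groom_time_ties",
    "Sum of grooming times above mean" = "z_sum_groom_time_strong",
    "Mean grooming rate across all partners" = "z_mean_groom_rate",
    "Count of strong grooming rate partners" = "z_n_strong_groom_rate_ties",
    "Sum of grooming rates above the mean" = "z_sum_groom_rate_strong",
    "Sum of top 3 CSI values" = "z_sum_top3_csi",
    "Count of high CSI ties" = "z_n_strong_csi_ties",
    "Sum of CSI values above the mean" = "z_sum_strong_csi"
  )
  if (raw_counts) {
    m[["Count of strong association ties"]] <- "z_n_strong_raw_ties"
    m[["Sum of strong assn. indices"]] <- "z_sum_raw_strong"
  }
  m
}

#' Table 2 alpha-bond model set
#'
#' The eight models of the alpha-concession analysis: null; each of three
#' bond-with-alpha measures alone; the count of strong association ties
#' alone; and each alpha-bond measure plus the strong-tie count.
#'
#' @param exclude_alpha use the strong-tie count excluding the alpha male.
#' @param target "alpha" or "beta" (second-ranked male variant).
#' @return named list of character vectors of added terms.
#' @export
table2_model_set <- function(exclude_alpha = FALSE, target = "alpha") {
  ties <- if (exclude_alpha) "z_n_strong_assoc_excl_alpha" else "z_n_strong_assoc_ties"
  csi <- paste0("z_csi_with_", target)
  sri <- paste0("z_sri_with_", target)
  grm <- paste0("z_groom_rate_with_", target)
  list(
    "Null model" = character(0),
    "CSI with alpha" = csi,
    "Association rate with alpha" = sri,
    "Grooming rate with alpha" = grm,
    "Count of strong association ties" = ties,
    "CSI with alpha + count of strong association ties" = c(csi, ties),
    "Association rate with alpha + count of strong association ties" = c(sri, ties),
    "Grooming rate with alpha + count of strong association ties" = c(grm, ties)
  )
}

#' Compare sociality models against the null
#'
#' Fits the null model and the null augmented with each entry of
#' `model_set`, and reports df, AICc, the AICc difference from the null
#' (negative = better than null) and Akaike weights over the set.
#'
#' @param design design table.
#' @param null_terms character vector of null-model terms.
#' @param model_set either a named character vector (each measure added
#'   alone, as in [table1_measures()]) or a named list of term vectors
#'   (as in [table2_model_set()]).
#' @param quadrature_points passed to [fit_binomial_glmm()].
#' @return a `pansoc_comparison` tibble (`model`, `df`, `AICc`, `dAICc`,
#'   `weight`, `beats_null`) sorted by AICc, with the fitted models in
#'   attribute `fits`.
#' @export
compare_sociality_models <- function(design, null_terms, model_set,
                                     quadrature_points = 15) {
  if (!is.list(model_set)) {
    model_set <- as.list(model_set)
  }
  if (!"Null model" %in% names(model_set)) {
    model_set <- c(list("Null model" = character(0)), model_set)
  }
  missing_cols <- setdiff(unique(unlist(model_set)), names(design))
  if (length(missing_cols)) {
    stop("measure column(s) absent from design: ",
         paste(missing_cols, collapse = ", "))
  }
  fits <- purrr::map(model_set, function(extra) {
    fit_binomial_glmm(design, c(null_terms, extra), quadrature_points)
  })
  a <- purrr::map_dbl(fits, "aicc")
  a_null <- a[["Null model"]]
  a <- unname(a)
  tab <- tibble::tibble(
    model = names(model_set),
    df = purrr::map_int(fits, "k"),
    AICc = a,
    dAICc = a - a_null,
    weight = akaike_weights(a),
    beats_null = a - a_null < 0
  ) |> dplyr::arrange(.data$AICc)
  structure(tab, class = c("pansoc_comparison", class(tab)), fits = fits,
            null_terms = null_terms)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing term `j` on the remaining
#' fixed terms; perfectly collinear terms are reported as `Inf`.
#'
#' @param design design table.
#' @param terms two or more predictor column names.
#' @return tibble `term`, `vif`.
#' @export
vif_terms <- function(design, terms) {
  stopifnot(length(terms) >= 2)
  vifs <- vapply(terms, function(tm) {
    f <- as.formula(paste(tm, "~", paste(setdiff(terms, tm), collapse = " + ")))
    r2 <- suppressWarnings(summary(lm(f, data = design))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(vifs))) {
    warning("vif_terms: perfectly collinear term(s): ",
            paste(terms[is.infinite(vifs)], collapse = ", "))
  }
  tibble::tibble(term = terms, vif = unname(vifs))
}

#' @export
tidy.siring_glmm <- function(x, conf.level = 0.95, exponentiate = TRUE, ...) {
  s <- summary(x$fit)$coefficients
  zq <- qnorm(1 - (1 - conf.level) / 2)
  est <- s[, "Estimate"]
  se <- s[, "Std. Error"]
  out <- tibble::tibble(
    term = rownames(s), estimate = est, std.error = se,
    statistic = s[, "z value"], p.value = s[, "Pr(>|z|)"],
    conf.low = est - zq * se, conf.high = est + zq * se
  )
  if (exponentiate) {
    out$odds.ratio <- exp(out$estimate)
    out$or.conf.low <- exp(out$conf.low)
    out$or.conf.high <- exp(out$conf.high)
  }
  out
}

#' @export
glance.siring_glmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, df = x$k, nobs = x$n,
    AICc = x$aicc,
    ranef.sd = sqrt(unname(lme4::VarCorr(x$fit)$male_id[1]))
  )
}

#' @export
print.siring_glmm <- function(x, ...) {
  cat(sprintf("<siring_glmm> %s | AICc = %.2f (k = %d, n = %d)\n",
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "intercept only",
              x$aicc, x$k, x$n))
  invisible(x)
}

#' @describeIn compare_sociality_models plot method: AICc difference from
#'   the null for each model.
#' @param object a `pansoc_comparison`.
#' @param ... unused.
#' @export
autoplot.pansoc_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dAICc,
                                   stats::reorder(.data$model, -.data$dAICc),
                                   fill = .data$beats_null)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Delta * "AICc vs null"), y = NULL) +
    ggplot2::theme_minimal()
}
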