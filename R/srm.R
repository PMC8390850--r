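#' Build the dyad-year table for the coalition-formation analysis
#'
#' One record per male dyad per calendar year in which both members were
#' reproductive-age (at mid-year). The outcome is whether the dyad formed
#' at least one coalition that year. Dyadic covariates — minutes observed
#' in the same party, joint arrivals in small parties, dyadic grooming
#' rate, absolute difference in cardinal Elo score, absolute age
#' difference — are Z-scaled within year. Individual covariates enter
#' symmetrically: the dyad sum of (within-year scaled) cardinal Elo scores
#' and the counts of members in the prime (20-30 y) and old (>30 y) age
#' categories.
#'
#' @param log an `obs_log`.
#' @param elo an `elo_fit` or `elo_trajectory`.
#' @param years calendar years to include (default: all years with
#'   arrivals).
#' @param min_age minimum male age in years at mid-year.
#' @return tibble, one row per dyad-year.
#' @export
build_dyad_year_table <- function(log, elo, years = NULL, min_age = 11) {
  if (is.null(years)) {
    years <- sort(unique(as.integer(format(log$arrivals$date, "%Y"))))
  }
  dyadic_co <- dyadize_coalitions(log$coalitions)
  males <- dplyr::filter(log$roster, .data$sex == "male")
  out <- purrr::map(years, function(yr) {
    start <- as.Date(sprintf("%d-01-01", yr))
    end <- as.Date(sprintf("%d-01-01", yr + 1))
    mid <- as.Date(sprintf("%d-07-01", yr))
    age <- age_years(males$birth_date, mid)
    present <- males$id[age >= min_age &
                          males$birth_date <= start &
                          (is.na(males$death_date) | males$death_date >= end)]
    if (length(present) < 2) return(NULL)
    dm <- dyad_metrics(log, present, start, end)
    st <- score_at_date(elo, present, mid)
    sc <- setNames(st$score, st$id)
    age_of <- setNames(age, males$id)[present]
    cat_of <- cut(age_of, c(-Inf, 20, 30, Inf), labels = c("young", "prime", "old"),
                  right = FALSE)
    names(cat_of) <- present
    co_pairs <- dyadic_co |>
      dplyr::filter(.data$year == yr) |>
      dplyr::mutate(key = dyad_key(.data$id_a, .data$id_b))
    dm |>
      dplyr::transmute(
        year = yr,
        id_a = .data$id_a, id_b = .data$id_b,
        outcome = as.integer(.data$key %in% co_pairs$key),
        time_obs = .data$time_together_min,
        joint_arrivals = .data$joint,
        groom_rate = dplyr::coalesce(.data$groom_rate, 0),
        elo_abs_diff = abs(sc[.data$id_a] - sc[.data$id_b]),
        age_abs_diff = abs(age_of[.data$id_a] - age_of[.data$id_b]),
        elo_sum_z = NA_real_,
        elo_a = sc[.data$id_a], elo_b = sc[.data$id_b],
        n_prime = (cat_of[.data$id_a] == "prime") + (cat_of[.data$id_b] == "prime"),
        n_old = (cat_of[.data$id_a] == "old") + (cat_of[.data$id_b] == "old")
      )
  })
  out <- dplyr::bind_rows(out)
  z_in_year <- function(x, year) {
    stats::ave(x, year, FUN = function(v) suppressWarnings(z_standardize(v)))
  }
  out |>
    dplyr::mutate(
      time_obs_z = z_in_year(.data$time_obs, .data$year),
      joint_arrivals_z = z_in_year(.data$joint_arrivals, .data$year),
      groom_rate_z = z_in_year(.data$groom_rate, .data$year),
      elo_abs_diff_z = z_in_year(.data$elo_abs_diff, .data$year),
      age_abs_diff_z = z_in_year(.data$age_abs_diff, .data$year),
      elo_sum_z = z_in_year(.data$elo_a + .data$elo_b, .data$year)
    )
}

#' Fit the symmetric binary-probit social relations model
#'
#' Gibbs sampler for
#' `z_d = x_d' beta + a_i + a_j + eps_d`, `y_d = 1{z_d > 0}`,
#' `eps ~ N(0, 1)`, `a_i ~ N(0, sigma_a^2)`: latent utilities by truncated
#' normal draws, conjugate normal update for `beta` (prior `N(0, 10^2 I)`),
#' sequential normal updates for the additive actor effects — row and
#' column effects constrained equal, as appropriate for an undirected
#' outcome — and a conjugate inverse-gamma update (shape 2, rate 1) for
#' the actor-effect variance. Repeated dyads across years share a single
#' actor effect per male. Results are summarized per chain and averaged
#' across chains; convergence is assessed with [gelman_rubin()].
#'
#' @param records dyad-year tibble (see [build_dyad_year_table()]); must
#'   contain `id_a`, `id_b`, `outcome` and the covariate columns.
#' @param covariates names of covariate columns entering `x_d` (an
#'   intercept is always prepended).
#' @param n_iter,burn_in MCMC iterations and burn-in per chain.
#' @param n_chains independent chains (different seeds).
#' @param seed integer seed.
#' @param prior_var prior variance of each regression coefficient.
#' @param ig_shape,ig_rate inverse-gamma prior on `sigma_a^2`.
#' @return an `srm_fit`: chains (coefficient draws), posterior summary
#'   averaged across chains, PSRF per parameter.
#' @export
fit_srm_probit <- function(records,
                           covariates = c("time_obs_z", "joint_arrivals_z",
                                          "groom_rate_z", "elo_abs_diff_z",
                                          "age_abs_diff_z", "elo_sum_z",
                                          "n_prime", "n_old"),
                           n_iter = 9000, burn_in = 1000, n_chains = 3,
                           seed = 1, prior_var = 100, ig_shape = 2,
                           ig_rate = 1) {
  stopifnot(n_iter > 0, burn_in >= 0, burn_in < n_iter)
  if (nrow(records) < 30) {
    warning("fit_srm_probit: fewer than 30 dyad-year records")
  }
  y <- as.integer(records$outcome)
  if (all(y == 0) || all(y == 1)) {
    stop("fit_srm_probit: outcome has no variation")
  }
  covariates <- intersect(covariates, names(records))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(records[covariates]))
  if (any(!is.finite(X))) stop("fit_srm_probit: non-finite covariate values")
  actors <- sort(unique(c(records$id_a, records$id_b)))
  ia <- match(records$id_a, actors) - 1L
  ib <- match(records$id_b, actors) - 1L
  pn <- c("(Intercept)", covariates)

  chains <- purrr::map(seq_len(n_chains), function(ch) {
    set.seed(seed + 1000L * ch)
    res <- srm_gibbs_cpp(y, X, ia, ib, length(actors), n_iter, burn_in,
                         prior_var, ig_shape, ig_rate)
    colnames(res$beta) <- pn
    colnames(res$actor) <- actors
    res
  })

  draw_mat <- function(res) cbind(res$beta, sigma2_a = res$sigma2_a)
  psrf <- if (n_chains >= 2) {
    gelman_rubin(purrr::map(chains, draw_mat))
  } else {
    list(term = c(pn, "sigma2_a"),
         psrf = rep(NA_real_, length(pn) + 1), mpsrf = NA_real_)
  }
  per_chain <- purrr::map(chains, function(res) {
    d <- draw_mat(res)
    tibble::tibble(term = colnames(d),
                   estimate = colMeans(d),
                   conf.low = apply(d, 2, quantile, 0.025),
                   conf.high = apply(d, 2, quantile, 0.975))
  })
  summary <- dplyr::bind_rows(per_chain) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop") |>
    dplyr::arrange(match(.data$term, c(pn, "sigma2_a")))
  summary$psrf <- psrf$psrf[match(summary$term, psrf$term)]
  actor_means <- colMeans(do.call(rbind, purrr::map(chains, "actor")))
  structure(list(summary = summary, chains = chains, psrf = psrf,
                 actor_effects = tibble::tibble(id = actors,
                                                effect = unname(actor_means)),
                 n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
                 seed = seed, n_records = nrow(records)),
            class = "srm_fit")
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Split-free PSRF from parallel chains: with within-chain variance `W` and
#' between-chain variance `B/n`,
#' `PSRF = sqrt(((n - 1) / n * W + B / n) / W)`. Values near 1 indicate the
#' chains have mixed; also returns the multivariate PSRF (largest
#' eigenvalue form).
#'
#' @param chains list of >= 2 draw matrices (iterations x parameters),
#'   equal dimensions.
#' @return list with `term`/`psrf` tibble columns and `mpsrf`.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stop("gelman_rubin: need at least 2 chains")
  chains <- purrr::map(chains, as.matrix)
  dims <- purrr::map(chains, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1) {
    stop("gelman_rubin: chains must have equal dimensions")
  }
  n <- nrow(chains[[1]])
  m <- length(chains)
  means <- do.call(rbind, purrr::map(chains, colMeans)) # m x p
  vars <- do.call(rbind, purrr::map(chains, ~ apply(.x, 2, var)))
  W <- colMeans(vars)
  B_n <- apply(means, 2, var) # = B / n
  vplus <- (n - 1) / n * W + B_n
  psrf <- ifelse(W > 0, sqrt(vplus / W), 1)
  # multivariate version: largest eigenvalue of W^-1 B/n
  mpsrf <- tryCatch({
    p <- ncol(chains[[1]])
    Wm <- Reduce(`+`, purrr::map(chains, ~ cov(.x))) / m
    Bm <- cov(means) # = B / n
    lam <- max(Re(eigen(solve(Wm, Bm), only.values = TRUE)$values))
    sqrt((n - 1) / n + (m + 1) / m * lam)
  }, error = function(e) NA_real_)
  list(term = colnames(chains[[1]]) %||% paste0("par", seq_len(ncol(chains[[1]]))),
       psrf = unname(psrf), mpsrf = mpsrf)
}

#' @export
tidy.srm_fit <- function(x, ...) x$summary

#' @export
glance.srm_fit <- function(x, ...) {
  tibble::tibble(n_records = x$n_records, n_chains = x$n_chains,
                 n_iter = x$n_iter, burn_in = x$burn_in,
                 max_psrf = max(x$psrf$psrf), mpsrf = x$psrf$mpsrf)
}

#' @export
print.srm_fit <- function(x, ...) {
  cat(sprintf("<srm_fit> %d records, %d chains x %d iterations (burn-in %d), max PSRF %.3f\n",
              x$n_records, x$n_chains, x$n_iter, x$burn_in, max(x$psrf$psrf)))
  print(x$summary)
  invisible(x)
}

#' @describeIn fit_srm_probit plot method: posterior means and 95%
#'   credible intervals of the regression coefficients.
#' @param object an `srm_fit`.
#' @param ... unused.
#' @export
autoplot.srm_fit <- function(object, ...) {
  df <- dplyr::filter(object$summary, .data$term != "sigma2_a")
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior mean (95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}
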