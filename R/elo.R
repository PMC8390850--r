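#' Sequential Elo scores from pant-grunt interactions
#'
#' Pant-grunts are a formal, unidirectional signal of submission: the actor
#' (giver) loses, the recipient wins. After each interaction the winner's
#' expected-win probability is
#' `E = 1 / (1 + 10^((R_loser - R_winner) / scale))` (classical base-10
#' logistic with scale 400) and scores update by `k * (1 - E)`, the winner
#' gaining exactly what the loser concedes. Individuals enter at their
#' entry score on first appearance.
#'
#' @param pantgrunts tibble with `date`, optional `time_min`, `actor_id`,
#'   `recipient_id`. Events are processed in date (then time) order.
#' @param k update constant (> 0).
#' @param entry_scores single number, or named vector by id; default 1000.
#' @param scale logistic scale of the expectation.
#' @param ids optional full id set (individuals that may appear).
#' @return an `elo_trajectory`: tibble with one row per event (`date`,
#'   `winner_id`, `loser_id`, `e_winner`, `winner_score`, `loser_score` —
#'   post-update), with the configuration, final scores and the negative
#'   log-likelihood as attributes.
#' @export
elo_update_sequence <- function(pantgrunts, k, entry_scores = 1000,
                                scale = 400, ids = NULL) {
  ev <- prep_elo_events(pantgrunts, ids)
  entry <- expand_entry(entry_scores, ev$ids)
  if (nrow(ev$events) == 0) {
    traj <- tibble::tibble(date = as.Date(character(0)),
                           winner_id = character(0), loser_id = character(0),
                           e_winner = numeric(0), winner_score = numeric(0),
                           loser_score = numeric(0))
    return(structure(traj, class = c("elo_trajectory", class(traj)),
                     ids = ev$ids, entry_scores = entry, k = k, scale = scale,
                     nll = 0, final_scores = entry))
  }
  res <- elo_replay_cpp(ev$events$w_idx - 1L, ev$events$l_idx - 1L,
                        unname(entry[ev$ids]), k, scale)
  traj <- tibble::tibble(
    date = ev$events$date,
    winner_id = ev$events$winner_id,
    loser_id = ev$events$loser_id,
    e_winner = res$e_winner,
    winner_score = res$winner_post,
    loser_score = res$loser_post
  )
  structure(traj, class = c("elo_trajectory", class(traj)),
            ids = ev$ids, entry_scores = entry, k = k, scale = scale,
            nll = res$nll, final_scores = setNames(res$final_scores, ev$ids))
}

prep_elo_events <- function(pantgrunts, ids = NULL) {
  pg <- tibble::as_tibble(pantgrunts)
  if (nrow(pg) && any(pg$actor_id == pg$recipient_id)) {
    stop("pant-grunt event with identical actor and recipient")
  }
  if (!"time_min" %in% names(pg)) pg$time_min <- NA_real_
  pg <- dplyr::arrange(pg, .data$date, !is.na(.data$time_min), .data$time_min)
  all_ids <- sort(unique(c(ids, pg$actor_id, pg$recipient_id)))
  events <- tibble::tibble(
    date = pg$date,
    winner_id = pg$recipient_id,
    loser_id = pg$actor_id,
    w_idx = match(pg$recipient_id, all_ids),
    l_idx = match(pg$actor_id, all_ids)
  )
  list(events = events, ids = all_ids)
}

expand_entry <- function(entry_scores, ids) {
  if (is.null(names(entry_scores))) {
    stopifnot(length(entry_scores) == 1)
    return(setNames(rep(entry_scores, length(ids)), ids))
  }
  out <- setNames(rep(1000, length(ids)), ids)
  out[names(entry_scores)] <- entry_scores
  out
}

#' Negative log-likelihood of an Elo parameterization
#'
#' `-sum(log E_winner)` accumulated over the event sequence with scores
#' current at each event — the objective minimized by [fit_elo_ml()].
#'
#' @inheritParams elo_update_sequence
#' @return a single number.
#' @export
elo_negative_log_likelihood <- function(pantgrunts, k, entry_scores = 1000,
                                        scale = 400, ids = NULL) {
  ev <- prep_elo_events(pantgrunts, ids)
  if (nrow(ev$events) == 0) return(0)
  entry <- expand_entry(entry_scores, ev$ids)
  elo_nll_cpp(ev$events$w_idx - 1L, ev$events$l_idx - 1L,
              unname(entry[ev$ids]), k, scale)
}

#' Maximum-likelihood Elo fit
#'
#' Optimizes the update constant `k` (bounded) and, optionally, the
#' per-individual entry scores by minimizing the sequence negative
#' log-likelihood. Entry scores are centered at 1000 for identifiability
#' (the likelihood depends only on score differences); the optimizer is
#' bounded quasi-Newton (L-BFGS-B) started from three deterministic `k`
#' values.
#'
#' @inheritParams elo_update_sequence
#' @param optimize_entry fit per-individual entry scores as well as `k`.
#' @param k_bounds lower/upper bounds for `k`.
#' @param entry_bound entry scores are kept within `1000 +/- entry_bound`.
#' @return an `elo_fit` list: `k`, `entry_scores`, `nll`, `trajectory`,
#'   `convergence`, `n_events`.
#' @export
fit_elo_ml <- function(pantgrunts, optimize_entry = TRUE,
                       k_bounds = c(1, 400), scale = 400, ids = NULL,
                       entry_bound = 1500) {
  ev <- prep_elo_events(pantgrunts, ids)
  n <- nrow(ev$events)
  if (n < 20) warning("fit_elo_ml: fewer than 20 events; estimates will be unstable")
  if (n == 0) stop("fit_elo_ml: no events")
  m <- length(ev$ids)
  w <- ev$events$w_idx - 1L
  l <- ev$events$l_idx - 1L

  # parameter vector: k, then m - 1 free entry-score offsets (last offset
  # is minus their sum, keeping the mean at 1000)
  entries_from <- function(par) {
    if (!optimize_entry) return(rep(1000, m))
    d <- par[-1]
    1000 + c(d, -sum(d))
  }
  obj <- function(par) {
    elo_nll_cpp(w, l, entries_from(par), par[1], scale)
  }
  starts <- c(20, 100, 300)
  starts <- pmin(pmax(starts, k_bounds[1]), k_bounds[2])
  npar <- if (optimize_entry) m else 1L
  lower <- c(k_bounds[1], rep(-entry_bound, npar - 1))
  upper <- c(k_bounds[2], rep(entry_bound, npar - 1))
  fits <- lapply(starts, function(k0) {
    tryCatch(
      optim(c(k0, rep(0, npar - 1)), obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("fit_elo_ml: optimization failed from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  entry <- setNames(entries_from(best$par), ev$ids)
  traj <- elo_update_sequence(pantgrunts, k = best$par[1], entry_scores = entry,
                              scale = scale, ids = ev$ids)
  structure(list(k = best$par[1], entry_scores = entry, nll = best$value,
                 trajectory = traj, convergence = best$convergence,
                 n_events = n, optimize_entry = optimize_entry, scale = scale),
            class = "elo_fit")
}

#' @export
print.elo_fit <- function(x, ...) {
  cat(sprintf("<elo_fit> k = %.2f, nll = %.2f over %d events, %d individuals\n",
              x$k, x$nll, x$n_events, length(x$entry_scores)))
  invisible(x)
}

#' Elo score of individuals at a date
#'
#' Returns each individual's last post-update score strictly before `date`;
#' individuals with no prior interaction get their entry score, flagged in
#' the `entered` column.
#'
#' @param trajectory an `elo_trajectory` or `elo_fit`.
#' @param ids ids to score.
#' @param date query date.
#' @return tibble `id`, `score`, `entered`.
#' @export
score_at_date <- function(trajectory, ids, date) {
  if (inherits(trajectory, "elo_fit")) trajectory <- trajectory$trajectory
  entry <- attr(trajectory, "entry_scores")
  before <- trajectory[trajectory$date < date, ]
  long <- dplyr::bind_rows(
    tibble::tibble(id = before$winner_id, score = before$winner_score,
                   ord = seq_len(nrow(before))),
    tibble::tibble(id = before$loser_id, score = before$loser_score,
                   ord = seq_len(nrow(before)))
  )
  last <- long |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_max(.data$ord, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  score_of <- setNames(last$score, last$id)
  tibble::tibble(
    id = ids,
    score = ifelse(ids %in% names(score_of), unname(score_of[ids]),
                   unname(entry[ids])),
    entered = ids %in% names(score_of)
  )
}

#' Window-standardized Elo scores and alpha/beta identification
#'
#' Z-standardizes the scores of the given males at a date (scores vary in
#' level between periods as males enter and die, so comparisons are within
#' window) and identifies the alpha (highest score) and beta (second).
#'
#' @inheritParams score_at_date
#' @return list with `scores` (tibble `id`, `score`, `z`), `alpha`, `beta`.
#' @export
elo_standings <- function(trajectory, ids, date) {
  sc <- score_at_date(trajectory, ids, date)
  sc$z <- suppressWarnings(z_standardize(sc$score))
  ord <- order(sc$score, decreasing = TRUE)
  list(scores = sc,
       alpha = sc$id[ord[1]],
       beta = if (length(ids) >= 2) sc$id[ord[2]] else NA_character_)
}

#' @describeIn elo_update_sequence plot method: score trajectories by male.
#' @param object an `elo_trajectory`.
#' @param ... unused.
#' @export
autoplot.elo_trajectory <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(date = object$date, id = object$winner_id,
                   score = object$winner_score),
    tibble::tibble(date = object$date, id = object$loser_id,
                   score = object$loser_score)
  ) |> dplyr::arrange(.data$date)
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$score,
                                     colour = .data$id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = NULL, y = "Elo score", colour = "male") +
    ggplot2::theme_minimal()
}
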