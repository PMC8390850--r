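#' Simple ratio association index
#'
#' `SRI = J / (N_a + N_b - J)` where `J` is the dyad's count of joint
#' arrivals and `N_a`, `N_b` the members' qualifying arrival counts. The
#' denominator convention corrects for differing observation effort between
#' the two males.
#'
#' @param joint joint-arrival count.
#' @param n_a,n_b qualifying arrival counts of each member.
#' @return the index in `[0, 1]`; `NA` when both counts are zero (the dyad
#'   is unobserved).
#' @examples
#' compute_sri(4, 10, 8) # 4/14
#' @export
compute_sri <- function(joint, n_a, n_b) {
  denom <- n_a + n_b - joint
  out <- ifelse(denom > 0, joint / denom, NA_real_)
  bad <- !is.na(out) & (joint > pmin(n_a, n_b))
  if (any(bad)) stop("compute_sri: joint exceeds a member's arrival count")
  out
}

#' Detect dyadic joint arrivals within a window
#'
#' Two males arrive jointly on a day when their first-of-day arrivals are at
#' most `max_gap_min` minutes apart and both arrivals occurred in parties of
#' at most `max_party` individuals. (Individuals already present at the
#' start of a focal follow are recorded as arrivals at the follow start
#' time, so shared start-presence counts as a zero-gap joint arrival.)
#' A male's qualifying arrival count is his number of first-of-day arrivals
#' in parties of at most `max_party`.
#'
#' @param arrivals arrivals tibble with `is_first_of_day` flags
#'   (see [mark_first_arrivals()]).
#' @param ids male ids to score.
#' @param start_date,end_date window bounds; dates `d` with
#'   `start_date <= d < end_date` are used.
#' @param max_gap_min maximum separation of the two arrivals, minutes.
#' @param max_party maximum party size at each arrival.
#' @return list with `pairs` (tibble `id_a`, `id_b`, `joint` for every
#'   unordered pair of `ids`) and `counts` (tibble `id`, `n_arrivals`).
#' @export
detect_joint_arrivals <- function(arrivals, ids, start_date, end_date,
                                  max_gap_min = 5, max_party = 4) {
  stopifnot(length(ids) >= 1)
  a <- dplyr::filter(arrivals,
                     .data$is_first_of_day,
                     .data$individual_id %in% ids,
                     .data$date >= start_date, .data$date < end_date)
  q <- dplyr::filter(a, .data$party_size_at_arrival <= max_party)
  counts <- tibble::tibble(id = ids) |>
    dplyr::left_join(dplyr::count(q, .data$individual_id, name = "n_arrivals"),
                     by = c(id = "individual_id")) |>
    dplyr::mutate(n_arrivals = dplyr::coalesce(.data$n_arrivals, 0L))
  pairs_all <- if (length(ids) >= 2) {
    cmb <- combn(sort(ids), 2)
    tibble::tibble(id_a = cmb[1, ], id_b = cmb[2, ])
  } else {
    tibble::tibble(id_a = character(0), id_b = character(0))
  }
  joint <- dplyr::inner_join(
    dplyr::select(q, "date", id_a = "individual_id", t_a = "time_min"),
    dplyr::select(q, "date", id_b = "individual_id", t_b = "time_min"),
    by = "date", relationship = "many-to-many") |>
    dplyr::filter(.data$id_a < .data$id_b,
                  abs(.data$t_a - .data$t_b) <= max_gap_min) |>
    dplyr::count(.data$id_a, .data$id_b, name = "joint")
  pairs <- dplyr::left_join(pairs_all, joint, by = c("id_a", "id_b")) |>
    dplyr::mutate(joint = dplyr::coalesce(.data$joint, 0L))
  list(pairs = pairs, counts = counts)
}

#' Classify strong ties
#'
#' A tie is strong when its index value is strictly above the mean over the
#' comparison scope — all same-window dyads that pass the relevant sampling
#' filter, zero-valued dyads included.
#'
#' @param values numeric dyadic values (the scope).
#' @return logical vector; ties at the mean are not strong.
#' @examples
#' classify_strong(c(0.1, 0.2, 0.6)) # only 0.6
#' @export
classify_strong <- function(values) {
  if (length(values) == 0) return(logical(0))
  values > mean(values, na.rm = TRUE)
}

#' Apply the sampling filters to dyadic metrics
#'
#' Association-based measures exclude dyads observed together for fewer
#' than `min_together` minutes in the window, or in which either male had
#' `max_poor_arrivals` or fewer qualifying arrivals. Grooming-rate and
#' CSI measures additionally require at least `min_focal` minutes of
#' co-presence while one member was the focal individual.
#'
#' @param dm dyadic metrics tibble (see [dyad_metrics()]).
#' @param min_together minimum total co-presence minutes.
#' @param max_poor_arrivals a male with this many arrivals or fewer fails.
#' @param min_focal minimum focal co-presence minutes for rate measures.
#' @return `dm` with logical `passes_assoc` and `passes_groom` columns.
#' @export
apply_sampling_filters <- function(dm, min_together = 1800,
                                   max_poor_arrivals = 20, min_focal = 600) {
  dplyr::mutate(
    dm,
    passes_assoc = .data$time_together_min >= min_together &
      .data$n_arrivals_a > max_poor_arrivals &
      .data$n_arrivals_b > max_poor_arrivals,
    passes_groom = .data$passes_assoc & .data$focal_time_min >= min_focal
  )
}

#' Precompute per-day aggregate tables for a log
#'
#' Aggregates co-presence and grooming to one row per dyad-day and
#' precomputes each male's daily focal co-presence minutes with other males
#' (interval union across partners). Window-level metrics then reduce to
#' date-range sums, which makes repeated window computations cheap.
#'
#' @param log an `obs_log`.
#' @param male_ids partner set for the focal-minute union (default: all
#'   roster males).
#' @return list of tibbles `pairs`, `groom`, `focal_union`.
#' @export
daily_tables <- function(log, male_ids = NULL) {
  if (is.null(male_ids)) {
    male_ids <- log$roster$id[log$roster$sex == "male"]
  }
  cp0 <- log$copresence
  ka <- pmin(cp0$individual_a, cp0$individual_b)
  kb <- pmax(cp0$individual_a, cp0$individual_b)
  dur <- cp0$end_min - cp0$start_min
  gkey <- paste(cp0$date, ka, kb, sep = "\r")
  sums <- rowsum(cbind(total = dur, focal = dur * cp0$focal_is_member), gkey)
  first <- match(rownames(sums), gkey)
  pairs <- tibble::tibble(date = cp0$date[first], id_a = ka[first],
                          id_b = kb[first],
                          total_min = unname(sums[, "total"]),
                          focal_min = unname(sums[, "focal"]))
  groom <- log$grooming |>
    dplyr::mutate(id_a = pmin(.data$groomer_id, .data$groomee_id),
                  id_b = pmax(.data$groomer_id, .data$groomee_id)) |>
    dplyr::group_by(.data$date, .data$id_a, .data$id_b) |>
    dplyr::summarise(groom_min = sum(.data$end_min - .data$start_min),
                     .groups = "drop")
  cp <- dplyr::filter(log$copresence, .data$focal_is_member,
                      .data$individual_a %in% male_ids,
                      .data$individual_b %in% male_ids)
  long <- dplyr::bind_rows(
    dplyr::select(cp, id = "individual_a", "date", "start_min", "end_min"),
    dplyr::select(cp, id = "individual_b", "date", "start_min", "end_min")
  )
  focal_union <- if (nrow(long)) {
    grp <- split(seq_len(nrow(long)), paste(long$id, long$date))
    vals <- vapply(grp, function(ix) {
      union_minutes(long$start_min[ix], long$end_min[ix])
    }, numeric(1))
    first <- vapply(grp, `[`, integer(1), 1)
    tibble::tibble(id = long$id[first], date = long$date[first],
                   focal_male_min = unname(vals))
  } else {
    tibble::tibble(id = character(0), date = as.Date(character(0)),
                   focal_male_min = numeric(0))
  }
  list(pairs = pairs, groom = groom, focal_union = focal_union)
}

# total minutes of merged (possibly overlapping) intervals
union_minutes <- function(s, e) {
  if (length(s) == 1) return(e - s)
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else cur_e <- max(cur_e, e[i])
  }
  tot + (cur_e - cur_s)
}

# window sums per unordered pair of `ids` from the daily pair table
window_pair_minutes <- function(pairs_daily, ids, start_date, end_date) {
  pairs_daily |>
    dplyr::filter(.data$date >= start_date, .data$date < end_date,
                  .data$id_a %in% ids, .data$id_b %in% ids) |>
    dplyr::mutate(key = dyad_key(.data$id_a, .data$id_b)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(total_min = sum(.data$total_min),
                     focal_min = sum(.data$focal_min), .groups = "drop")
}

#' Per-dyad sociality metrics for one window
#'
#' Computes, for every unordered pair of `ids`, the joint-arrival count and
#' qualifying arrival counts, the simple ratio index, total and focal
#' co-presence minutes, dyadic grooming minutes and grooming rate (grooming
#' minutes over focal co-presence minutes, since grooming is recorded only
#' for focal individuals), the sampling-filter flags, and the composite
#' sociality index (CSI): the mean of the dyad's SRI and grooming rate,
#' each scaled by its window mean over filter-passing dyads, so the mean
#' CSI in a window is 1 by construction.
#'
#' @param log an `obs_log`.
#' @param ids male ids in the window.
#' @param start_date,end_date window bounds (`start <= date < end`).
#' @param max_gap_min,max_party joint-arrival rule (see
#'   [detect_joint_arrivals()]).
#' @param min_together,max_poor_arrivals,min_focal sampling filters (see
#'   [apply_sampling_filters()]).
#' @param daily optional precomputed [daily_tables()] (for repeated
#'   window computations on the same log).
#' @return tibble with one row per dyad.
#' @export
dyad_metrics <- function(log, ids, start_date, end_date,
                         max_gap_min = 5, max_party = 4,
                         min_together = 1800, max_poor_arrivals = 20,
                         min_focal = 600, daily = NULL) {
  if (is.null(daily)) daily <- daily_tables(log)
  ja <- detect_joint_arrivals(log$arrivals, ids, start_date, end_date,
                              max_gap_min, max_party)
  n_of <- setNames(ja$counts$n_arrivals, ja$counts$id)
  dm <- ja$pairs |>
    dplyr::mutate(key = dyad_key(.data$id_a, .data$id_b),
                  n_arrivals_a = unname(n_of[.data$id_a]),
                  n_arrivals_b = unname(n_of[.data$id_b]),
                  sri = compute_sri(.data$joint, .data$n_arrivals_a,
                                    .data$n_arrivals_b))

  wp <- window_pair_minutes(daily$pairs, ids, start_date, end_date)
  gm <- daily$groom |>
    dplyr::filter(.data$date >= start_date, .data$date < end_date,
                  .data$id_a %in% ids, .data$id_b %in% ids) |>
    dplyr::mutate(key = dyad_key(.data$id_a, .data$id_b)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(groom_min = sum(.data$groom_min), .groups = "drop")

  dm <- dm |>
    dplyr::left_join(
      dplyr::select(wp, "key", time_together_min = "total_min",
                    focal_time_min = "focal_min"), by = "key") |>
    dplyr::left_join(gm, by = "key") |>
    dplyr::mutate(
      time_together_min = dplyr::coalesce(.data$time_together_min, 0),
      focal_time_min = dplyr::coalesce(.data$focal_time_min, 0),
      groom_min = dplyr::coalesce(.data$groom_min, 0),
      groom_rate = ifelse(.data$focal_time_min > 0,
                          .data$groom_min / .data$focal_time_min, NA_real_)
    ) |>
    apply_sampling_filters(min_together, max_poor_arrivals, min_focal)

  # composite sociality index over groom-filter-passing dyads
  sc <- dm$passes_groom & !is.na(dm$sri) & !is.na(dm$groom_rate)
  dm$csi <- NA_real_
  if (any(sc)) {
    m_sri <- mean(dm$sri[sc])
    m_rate <- mean(dm$groom_rate[sc])
    if (m_sri > 0 && m_rate > 0) {
      dm$csi[sc] <- 0.5 * (dm$sri[sc] / m_sri + dm$groom_rate[sc] / m_rate)
    } else if (m_sri > 0 || m_rate > 0) {
      # one component degenerate: CSI reduces to the informative component
      warning("dyad_metrics: a CSI component has window mean 0; using the other component")
      dm$csi[sc] <- if (m_sri > 0) dm$sri[sc] / m_sri else dm$groom_rate[sc] / m_rate
    } else {
      warning("dyad_metrics: both CSI components have window mean 0; CSI undefined")
    }
  }
  dm
}

dyads_of <- function(dm, male) {
  dplyr::filter(dm, .data$id_a == male | .data$id_b == male) |>
    dplyr::mutate(partner = ifelse(.data$id_a == male, .data$id_b, .data$id_a))
}

#' Association measures for one male
#'
#' The four association-based sociality measures, from the dyads that pass
#' the association sampling filter: count of all association ties
#' (SRI > 0), sum of all SRI values, count of strong ties (SRI strictly
#' above the window mean over all filter-passing dyads), and the sum of the
#' strong SRI values; plus the same two strong-tie measures computed on raw
#' joint-arrival counts (robustness variant).
#'
#' @param dm window dyadic metrics (see [dyad_metrics()]).
#' @param male male id; must appear in `dm`.
#' @return one-row tibble.
#' @export
association_measures <- function(dm, male) {
  if (!male %in% c(dm$id_a, dm$id_b)) stop("male ", male, " absent from window")
  scope <- dplyr::filter(dm, .data$passes_assoc)
  mean_sri <- if (nrow(scope)) mean(scope$sri, na.rm = TRUE) else NaN
  mean_joint <- if (nrow(scope)) mean(scope$joint) else NaN
  d <- dplyr::filter(dyads_of(dm, male), .data$passes_assoc)
  tibble::tibble(
    n_assoc_ties = sum(d$sri > 0, na.rm = TRUE),
    sum_sri_all = sum(d$sri, na.rm = TRUE),
    n_strong_assoc_ties = sum(d$sri > mean_sri, na.rm = TRUE),
    sum_sri_strong = sum(d$sri[!is.na(d$sri) & d$sri > mean_sri]),
    n_strong_raw_ties = sum(d$joint > mean_joint),
    sum_raw_strong = sum(d$joint[d$joint > mean_joint])
  )
}

#' Grooming measures for one male
#'
#' Eight measures of grooming effort and grooming-relationship strength.
#' Time-based measures use dyads passing the association filter; rate-based
#' measures additionally require 600 focal minutes together (the grooming
#' filter). The overall grooming rate divides the male's total grooming
#' minutes by his total focal minutes in parties with at least one other
#' male (`focal_male_min`).
#'
#' @param dm window dyadic metrics.
#' @param male male id.
#' @param focal_male_min total focal co-presence minutes of `male` with at
#'   least one other male (union over partners; see
#'   [male_focal_minutes()]).
#' @return one-row tibble with `groom_total_min`, `groom_rate_overall`,
#'   `n_groom_partners`, `n_strong_groom_time_ties`,
#'   `sum_groom_time_strong`, `mean_groom_rate`, `n_strong_groom_rate_ties`,
#'   `sum_groom_rate_strong`.
#' @export
grooming_measures <- function(dm, male, focal_male_min = NA_real_) {
  if (!male %in% c(dm$id_a, dm$id_b)) stop("male ", male, " absent from window")
  scope_t <- dplyr::filter(dm, .data$passes_assoc)
  scope_r <- dplyr::filter(dm, .data$passes_groom, !is.na(.data$groom_rate))
  mean_time <- if (nrow(scope_t)) mean(scope_t$groom_min) else NaN
  mean_rate <- if (nrow(scope_r)) mean(scope_r$groom_rate) else NaN
  dt <- dplyr::filter(dyads_of(dm, male), .data$passes_assoc)
  dr <- dplyr::filter(dyads_of(dm, male), .data$passes_groom, !is.na(.data$groom_rate))
  total <- sum(dt$groom_min)
  tibble::tibble(
    groom_total_min = total,
    groom_rate_overall = if (!is.na(focal_male_min) && focal_male_min > 0)
      total / focal_male_min else 0,
    n_groom_partners = sum(dt$groom_min > 0),
    n_strong_groom_time_ties = sum(dt$groom_min > mean_time),
    sum_groom_time_strong = sum(dt$groom_min[dt$groom_min > mean_time]),
    mean_groom_rate = if (nrow(dr)) mean(dr$groom_rate) else 0,
    n_strong_groom_rate_ties = sum(dr$groom_rate > mean_rate),
    sum_groom_rate_strong = sum(dr$groom_rate[dr$groom_rate > mean_rate])
  )
}

#' CSI measures for one male
#'
#' Individual measures built from the dyadic composite sociality index:
#' the sum of the male's top three CSI values, the count of CSI values
#' strictly above the window mean, and the sum of those above-mean values.
#'
#' @param dm window dyadic metrics.
#' @param male male id.
#' @return one-row tibble.
#' @export
csi_measures <- function(dm, male) {
  if (!male %in% c(dm$id_a, dm$id_b)) stop("male ", male, " absent from window")
  scope <- dplyr::filter(dm, !is.na(.data$csi))
  mean_csi <- if (nrow(scope)) mean(scope$csi) else NaN
  d <- dplyr::filter(dyads_of(dm, male), !is.na(.data$csi))
  tibble::tibble(
    sum_top3_csi = sum(sort(d$csi, decreasing = TRUE)[seq_len(min(3, nrow(d)))]),
    n_strong_csi_ties = sum(d$csi > mean_csi),
    sum_strong_csi = sum(d$csi[d$csi > mean_csi])
  )
}

#' Gregariousness: co-presence minutes with reproductive-age partners
#'
#' Sums the dyadic co-presence minutes a male was observed with other males
#' older than 10 and females older than 11 (ages at the window end),
#' a control for overall sociability.
#'
#' @param copresence co-presence interval tibble.
#' @param roster roster tibble.
#' @param male male id.
#' @param start_date,end_date window bounds.
#' @return total minutes (scalar).
#' @export
gregariousness <- function(copresence, roster, male, start_date, end_date) {
  age <- age_years(roster$birth_date, end_date)
  ok <- (roster$sex == "male" & age > 10) | (roster$sex == "female" & age > 11)
  partners <- setdiff(roster$id[ok], male)
  cp <- dplyr::filter(copresence,
                      .data$date >= start_date, .data$date < end_date,
                      (.data$individual_a == male & .data$individual_b %in% partners) |
                        (.data$individual_b == male & .data$individual_a %in% partners))
  sum(cp$end_min - cp$start_min)
}

#' Bond measures with a specific partner (alpha or beta male)
#'
#' Returns the male's SRI, dyadic grooming rate, and CSI with the target
#' male, and the count of strong association ties excluding the target.
#' Values are `NA` when the dyad did not pass the relevant sampling filter.
#'
#' @param dm window dyadic metrics.
#' @param male male id.
#' @param target target male id (e.g. the alpha at the conception date).
#' @return one-row tibble (`sri_with`, `groom_rate_with`, `csi_with`,
#'   `n_strong_assoc_excl`).
#' @export
partner_specific_bond <- function(dm, male, target) {
  stopifnot(male != target)
  am <- association_measures(dm, male)
  d <- dplyr::filter(dyads_of(dm, male), .data$partner == target)
  scope <- dplyr::filter(dm, .data$passes_assoc)
  mean_sri <- if (nrow(scope)) mean(scope$sri, na.rm = TRUE) else NaN
  if (nrow(d) == 0) {
    return(tibble::tibble(sri_with = NA_real_, groom_rate_with = NA_real_,
                          csi_with = NA_real_,
                          n_strong_assoc_excl = am$n_strong_assoc_ties))
  }
  target_strong <- isTRUE(d$passes_assoc & !is.na(d$sri) & d$sri > mean_sri)
  tibble::tibble(
    sri_with = ifelse(d$passes_assoc, d$sri, NA_real_),
    groom_rate_with = ifelse(d$passes_groom, d$groom_rate, NA_real_),
    csi_with = d$csi,
    n_strong_assoc_excl = am$n_strong_assoc_ties - as.integer(target_strong)
  )
}

#' Per-male focal co-presence minutes with other males
#'
#' For each male, the union (not sum) of focal-member co-presence intervals
#' with other males in the window — the denominator of the overall
#' grooming rate. Overlapping intervals with different partners on the same
#' day are merged before summing.
#'
#' @param copresence co-presence tibble.
#' @param ids male ids.
#' @param start_date,end_date window bounds.
#' @return tibble `id`, `focal_male_min`.
#' @export
male_focal_minutes <- function(copresence, ids, start_date, end_date) {
  cp <- dplyr::filter(copresence,
                      .data$focal_is_member,
                      .data$date >= start_date, .data$date < end_date,
                      .data$individual_a %in% ids, .data$individual_b %in% ids)
  long <- dplyr::bind_rows(
    dplyr::select(cp, id = "individual_a", "date", "start_min", "end_min"),
    dplyr::select(cp, id = "individual_b", "date", "start_min", "end_min")
  )
  out <- long |>
    dplyr::group_by(.data$id, .data$date) |>
    dplyr::summarise(m = union_minutes(.data$start_min, .data$end_min),
                     .groups = "drop") |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(focal_male_min = sum(.data$m), .groups = "drop")
  dplyr::left_join(tibble::tibble(id = ids), out, by = "id") |>
    dplyr::mutate(focal_male_min = dplyr::coalesce(.data$focal_male_min, 0))
}

# window gregariousness for every male at once, from the daily pair table
gregariousness_all <- function(pairs_daily, roster, ids, start_date, end_date) {
  age <- age_years(roster$birth_date, end_date)
  ok <- (roster$sex == "male" & age > 10) | (roster$sex == "female" & age > 11)
  qualified <- roster$id[ok]
  w <- dplyr::filter(pairs_daily,
                     .data$date >= start_date, .data$date < end_date)
  long <- dplyr::bind_rows(
    dplyr::select(w, id = "id_a", partner = "id_b", "total_min"),
    dplyr::select(w, id = "id_b", partner = "id_a", "total_min")
  ) |>
    dplyr::filter(.data$id %in% ids, .data$partner %in% qualified) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(gregariousness_min = sum(.data$total_min), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(id = ids), long, by = "id")
  dplyr::mutate(out, gregariousness_min = dplyr::coalesce(.data$gregariousness_min, 0))
}

#' Per-male sociality vectors for one window
#'
#' Assembles every individual sociality measure — association, grooming,
#' CSI, gregariousness and (optionally) alpha/beta-specific bond measures —
#' for all males in a window, in raw and within-window Z-standardized form
#' (`z_` prefix).
#'
#' @param log an `obs_log`.
#' @param dm window dyadic metrics from [dyad_metrics()].
#' @param ids male ids.
#' @param start_date,end_date window bounds.
#' @param alpha_id,beta_id top- and second-ranked male at the window end
#'   (optional; `NULL` skips the partner-specific measures).
#' @param daily optional precomputed [daily_tables()].
#' @return tibble, one row per male.
#' @export
sociality_vectors <- function(log, dm, ids, start_date, end_date,
                              alpha_id = NULL, beta_id = NULL, daily = NULL) {
  if (is.null(daily)) {
    fm <- male_focal_minutes(log$copresence,
                             log$roster$id[log$roster$sex == "male"],
                             start_date, end_date)
  } else {
    fm <- daily$focal_union |>
      dplyr::filter(.data$date >= start_date, .data$date < end_date) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(focal_male_min = sum(.data$focal_male_min),
                       .groups = "drop")
  }
  fm_of <- setNames(fm$focal_male_min, fm$id)
  pairs_daily <- if (is.null(daily)) daily_tables(log)$pairs else daily$pairs
  greg <- gregariousness_all(pairs_daily, log$roster, ids, start_date, end_date)

  # both-direction view of the dyad table, vectorized over males
  long <- dplyr::bind_rows(
    dplyr::mutate(dm, id = .data$id_a, partner = .data$id_b),
    dplyr::mutate(dm, id = .data$id_b, partner = .data$id_a)
  )
  scope_a <- dplyr::filter(dm, .data$passes_assoc)
  scope_r <- dplyr::filter(dm, .data$passes_groom, !is.na(.data$groom_rate))
  scope_c <- dplyr::filter(dm, !is.na(.data$csi))
  mean_sri <- if (nrow(scope_a)) mean(scope_a$sri, na.rm = TRUE) else NaN
  mean_joint <- if (nrow(scope_a)) mean(scope_a$joint) else NaN
  mean_time <- if (nrow(scope_a)) mean(scope_a$groom_min) else NaN
  mean_rate <- if (nrow(scope_r)) mean(scope_r$groom_rate) else NaN
  mean_csi <- if (nrow(scope_c)) mean(scope_c$csi) else NaN

  la <- dplyr::filter(long, .data$passes_assoc)
  assoc <- la |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_assoc_ties = sum(.data$sri > 0, na.rm = TRUE),
      sum_sri_all = sum(.data$sri, na.rm = TRUE),
      n_strong_assoc_ties = sum(.data$sri > mean_sri, na.rm = TRUE),
      sum_sri_strong = sum(.data$sri[!is.na(.data$sri) & .data$sri > mean_sri]),
      n_strong_raw_ties = sum(.data$joint > mean_joint),
      sum_raw_strong = sum(.data$joint[.data$joint > mean_joint]),
      groom_total_min = sum(.data$groom_min),
      n_groom_partners = sum(.data$groom_min > 0),
      n_strong_groom_time_ties = sum(.data$groom_min > mean_time),
      sum_groom_time_strong = sum(.data$groom_min[.data$groom_min > mean_time]),
      .groups = "drop")
  lr <- dplyr::filter(long, .data$passes_groom, !is.na(.data$groom_rate))
  rate <- lr |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      mean_groom_rate = mean(.data$groom_rate),
      n_strong_groom_rate_ties = sum(.data$groom_rate > mean_rate),
      sum_groom_rate_strong = sum(.data$groom_rate[.data$groom_rate > mean_rate]),
      .groups = "drop")
  lc <- dplyr::filter(long, !is.na(.data$csi))
  csi <- lc |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      sum_top3_csi = sum(sort(.data$csi, decreasing = TRUE)[
        seq_len(min(3, dplyr::n()))]),
      n_strong_csi_ties = sum(.data$csi > mean_csi),
      sum_strong_csi = sum(.data$csi[.data$csi > mean_csi]),
      .groups = "drop")

  out <- tibble::tibble(id = ids) |>
    dplyr::left_join(assoc, by = "id") |>
    dplyr::left_join(rate, by = "id") |>
    dplyr::left_join(csi, by = "id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ dplyr::coalesce(.x, 0))) |>
    dplyr::mutate(fm = unname(fm_of[.data$id]),
                  groom_rate_overall = ifelse(!is.na(.data$fm) & .data$fm > 0,
                                              .data$groom_total_min / .data$fm,
                                              0)) |>
    dplyr::select(-"fm") |>
    dplyr::left_join(greg, by = "id")

  add_partner_cols <- function(out, target, suffix) {
    lt <- dplyr::filter(long, .data$partner == target)
    lt <- lt[match(out$id, lt$id), ]
    strong_with <- !is.na(lt$passes_assoc) & lt$passes_assoc &
      !is.na(lt$sri) & lt$sri > mean_sri
    out[[paste0("sri_with_", suffix)]] <-
      ifelse(!is.na(lt$passes_assoc) & lt$passes_assoc, lt$sri, NA_real_)
    out[[paste0("groom_rate_with_", suffix)]] <-
      ifelse(!is.na(lt$passes_groom) & lt$passes_groom, lt$groom_rate, NA_real_)
    out[[paste0("csi_with_", suffix)]] <- lt$csi
    if (suffix == "alpha") {
      out$n_strong_assoc_excl_alpha <-
        out$n_strong_assoc_ties - as.integer(strong_with)
      out$n_strong_assoc_excl_alpha[out$id == target] <-
        out$n_strong_assoc_ties[out$id == target]
    }
    out
  }
  if (!is.null(alpha_id)) out <- add_partner_cols(out, alpha_id, "alpha")
  if (!is.null(beta_id)) out <- add_partner_cols(out, beta_id, "beta")

  num_cols <- setdiff(names(out)[vapply(out, is.numeric, logical(1))], "id")
  for (col in num_cols) {
    out[[paste0("z_", col)]] <- suppressWarnings(z_standardize(out[[col]]))
  }
  out
}

#' Sociality metrics for every siring window
#'
#' Runs [dyad_metrics()] and [sociality_vectors()] across all windows,
#' identifying the alpha and beta male at each conception date from an Elo
#' trajectory when one is supplied.
#'
#' @param log an `obs_log`.
#' @param windows tibble from [siring_windows()] /
#'   [apply_siring_event_exclusions()].
#' @param elo optional `elo_trajectory` for alpha/beta identification.
#' @param ... filter and rule parameters passed to [dyad_metrics()].
#' @return list of two tibbles, `dyads` and `males`, each with an
#'   `event_id` column.
#' @export
compute_sociality <- function(log, windows, elo = NULL, ...) {
  daily <- daily_tables(log)
  per_window <- purrr::map(seq_len(nrow(windows)), function(i) {
    ids <- windows$eligible[[i]]
    s <- windows$start_date[i]
    e <- windows$conception_date[i]
    dm <- dyad_metrics(log, ids, s, e, ..., daily = daily)
    alpha <- beta <- NULL
    if (!is.null(elo)) {
      st <- elo_standings(elo, ids, e)
      alpha <- st$alpha
      beta <- st$beta
    }
    sv <- sociality_vectors(log, dm, ids, s, e, alpha_id = alpha,
                            beta_id = beta, daily = daily)
    list(dyads = dplyr::mutate(dm, event_id = windows$event_id[i], .before = 1),
         males = dplyr::mutate(sv, event_id = windows$event_id[i], .before = 1),
         info = tibble::tibble(event_id = windows$event_id[i],
                               alpha_id = alpha %||% NA_character_,
                               beta_id = beta %||% NA_character_))
  })
  list(dyads = dplyr::bind_rows(purrr::map(per_window, "dyads")),
       males = dplyr::bind_rows(purrr::map(per_window, "males")),
       info = dplyr::bind_rows(purrr::map(per_window, "info")))
}
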