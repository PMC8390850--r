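#' Assemble and validate an observation log
#'
#' Bundles the eight behavioral tables of a long-term observation dataset —
#' roster, party arrivals, dyadic co-presence intervals, grooming bouts,
#' pant-grunt dominance interactions, coalitionary aggression, paternity
#' records and pairwise genetic relatedness — into a validated `obs_log`
#' object. All cross-references (ids, dates) are checked, invariants of each
#' table are enforced, and derived fields are populated: conception dates
#' (birth minus gestation) and the first-arrival-of-day flag.
#'
#' @param roster tibble with `id`, `sex` ("male"/"female"), `birth_date`,
#'   and optional `death_date`, `sterile_from` (Date, NA allowed),
#'   `genotyped` (logical, default TRUE).
#' @param arrivals tibble with `date`, `time_min` (minutes since midnight),
#'   `individual_id`, `party_size_at_arrival`, `focal_id`.
#' @param copresence tibble with `date`, `focal_id`, `individual_a`,
#'   `individual_b`, `start_min`, `end_min`.
#' @param grooming tibble with `date`, `start_min`, `end_min`, `groomer_id`,
#'   `groomee_id`, `focal_id`.
#' @param pantgrunts tibble with `date`, optional `time_min`, `actor_id`
#'   (the subordinate, who gives the pant-grunt), `recipient_id`.
#' @param coalitions tibble with `date`, `actor_ids` and `target_ids`
#'   (`;`-separated id lists), `aggression_type` (directed_display, chase,
#'   attack).
#' @param paternities tibble with `offspring_id`, `mother_id`, `sire_id`,
#'   `birth_date`.
#' @param relatedness long tibble `id_a`, `id_b`, `r` (symmetric lookup).
#' @param gestation_days gestation length used to derive conception dates.
#' @return an `obs_log`: a named list of validated tibbles.
#' @export
observation_log <- function(roster, arrivals, copresence, grooming,
                            pantgrunts, coalitions, paternities, relatedness,
                            gestation_days = 226) {
  roster <- tibble::as_tibble(roster)
  if (!"death_date" %in% names(roster)) roster$death_date <- as.Date(NA)
  if (!"sterile_from" %in% names(roster)) roster$sterile_from <- as.Date(NA)
  if (!"genotyped" %in% names(roster)) roster$genotyped <- TRUE

  log <- list(
    roster = roster,
    arrivals = tibble::as_tibble(arrivals),
    copresence = tibble::as_tibble(copresence),
    grooming = tibble::as_tibble(grooming),
    pantgrunts = tibble::as_tibble(pantgrunts),
    coalitions = tibble::as_tibble(coalitions),
    paternities = tibble::as_tibble(paternities),
    relatedness = tibble::as_tibble(relatedness)
  )
  validate_observation_log(log)
  log$paternities <- derive_conception_dates(log$paternities, gestation_days)
  log$arrivals <- mark_first_arrivals(log$arrivals)
  if (!"focal_is_member" %in% names(log$copresence)) {
    log$copresence$focal_is_member <-
      log$copresence$focal_id == log$copresence$individual_a |
      log$copresence$focal_id == log$copresence$individual_b
  }
  structure(log, class = c("obs_log", "list"))
}

fail_row <- function(table, rows, what) {
  stop(sprintf("%s: %s (row %s)", table, what,
               paste(utils::head(rows, 5), collapse = ", ")), call. = FALSE)
}

need_cols <- function(df, table, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", table,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

check_ids <- function(ids, known, table) {
  bad <- which(!is.na(ids) & !(ids %in% known))
  if (length(bad)) fail_row(table, bad, paste0("unknown id '", ids[bad[1]], "'"))
}

#' Validate an observation log's tables
#'
#' Checks column presence, invariants (ordered dates, positive durations,
#' distinct dyad members, 2-3 coalition actors with 1-3 disjoint targets,
#' arrival times within the day) and that every id appearing in an event
#' table is on the roster. Errors name the offending table and row.
#'
#' @param log a list of the eight tables (see [observation_log()]).
#' @return invisibly TRUE.
#' @export
validate_observation_log <- function(log) {
  need_cols(log$roster, "roster", c("id", "sex", "birth_date"))
  r <- log$roster
  if (anyDuplicated(r$id)) fail_row("roster", which(duplicated(r$id)), "duplicate id")
  if (!all(r$sex %in% c("male", "female"))) {
    fail_row("roster", which(!r$sex %in% c("male", "female")), "sex must be male/female")
  }
  bad <- which(!is.na(r$death_date) & r$death_date < r$birth_date)
  if (length(bad)) fail_row("roster", bad, "death_date before birth_date")
  bad <- which(!is.na(r$sterile_from) & r$sterile_from < r$birth_date)
  if (length(bad)) fail_row("roster", bad, "sterile_from before birth_date")
  ids <- r$id

  need_cols(log$arrivals, "arrivals",
            c("date", "time_min", "individual_id", "party_size_at_arrival", "focal_id"))
  a <- log$arrivals
  if (nrow(a)) {
    bad <- which(a$time_min < 0 | a$time_min >= 1440)
    if (length(bad)) fail_row("arrivals", bad, "time_min outside [0, 1440)")
    bad <- which(a$party_size_at_arrival < 1)
    if (length(bad)) fail_row("arrivals", bad, "party_size_at_arrival < 1")
    check_ids(a$individual_id, ids, "arrivals")
    check_ids(a$focal_id, ids, "arrivals")
  }

  need_cols(log$copresence, "copresence",
            c("date", "focal_id", "individual_a", "individual_b", "start_min", "end_min"))
  cp <- log$copresence
  if (nrow(cp)) {
    bad <- which(cp$end_min <= cp$start_min)
    if (length(bad)) fail_row("copresence", bad, "end_min <= start_min")
    bad <- which(cp$individual_a == cp$individual_b)
    if (length(bad)) fail_row("copresence", bad, "individual_a == individual_b")
    check_ids(c(cp$individual_a, cp$individual_b, cp$focal_id), ids, "copresence")
  }

  need_cols(log$grooming, "grooming",
            c("date", "start_min", "end_min", "groomer_id", "groomee_id", "focal_id"))
  g <- log$grooming
  if (nrow(g)) {
    bad <- which(g$groomer_id == g$groomee_id)
    if (length(bad)) fail_row("grooming", bad, "groomer == groomee")
    bad <- which(g$end_min <= g$start_min)
    if (length(bad)) fail_row("grooming", bad, "non-positive bout duration")
    check_ids(c(g$groomer_id, g$groomee_id, g$focal_id), ids, "grooming")
  }

  need_cols(log$pantgrunts, "pantgrunts", c("date", "actor_id", "recipient_id"))
  p <- log$pantgrunts
  if (nrow(p)) {
    bad <- which(p$actor_id == p$recipient_id)
    if (length(bad)) fail_row("pantgrunts", bad, "actor == recipient")
    check_ids(c(p$actor_id, p$recipient_id), ids, "pantgrunts")
  }

  need_cols(log$coalitions, "coalitions", c("date", "actor_ids", "target_ids"))
  co <- log$coalitions
  if (nrow(co)) {
    actors <- strsplit(co$actor_ids, ";", fixed = TRUE)
    targets <- strsplit(co$target_ids, ";", fixed = TRUE)
    na <- lengths(actors)
    nt <- lengths(targets)
    bad <- which(!(na %in% c(2L, 3L)))
    if (length(bad)) fail_row("coalitions", bad, "coalitions must have 2 or 3 actors")
    bad <- which(nt < 1L | nt > 3L)
    if (length(bad)) fail_row("coalitions", bad, "coalitions must have 1-3 targets")
    bad <- which(purrr::map2_lgl(actors, targets, ~ length(intersect(.x, .y)) > 0))
    if (length(bad)) fail_row("coalitions", bad, "actors and targets overlap")
    check_ids(unlist(c(actors, targets)), ids, "coalitions")
  }

  need_cols(log$paternities, "paternities",
            c("offspring_id", "mother_id", "sire_id", "birth_date"))
  if (nrow(log$paternities)) {
    check_ids(c(log$paternities$mother_id, log$paternities$sire_id), ids, "paternities")
  }

  need_cols(log$relatedness, "relatedness", c("id_a", "id_b", "r"))
  invisible(TRUE)
}

#' Derive conception dates from birth dates
#'
#' Conception is back-dated from birth by the mean gestation length
#' (226 days for this population).
#'
#' @param paternities tibble with a `birth_date` column.
#' @param gestation_days days of gestation to subtract.
#' @return the tibble with a `conception_date` column.
#' @examples
#' derive_conception_dates(tibble::tibble(birth_date = as.Date("2000-01-01")))
#' @export
derive_conception_dates <- function(paternities, gestation_days = 226) {
  dplyr::mutate(tibble::as_tibble(paternities),
                conception_date = .data$birth_date - gestation_days)
}

#' Flag each individual's first arrival of the day
#'
#' Association is measured from first arrivals only, which mitigates
#' autocorrelation from repeated party changes within a day. Exact duplicate
#' rows (same individual, date and time) are dropped with a warning. For
#' every (individual, date) with any arrival, exactly one row is flagged:
#' the earliest by `time_min`.
#'
#' @param arrivals arrivals tibble.
#' @return the tibble with a logical `is_first_of_day` column.
#' @export
mark_first_arrivals <- function(arrivals) {
  arrivals <- tibble::as_tibble(arrivals)
  if (nrow(arrivals) == 0) {
    arrivals$is_first_of_day <- logical(0)
    return(arrivals)
  }
  dup <- duplicated(arrivals[c("individual_id", "date", "time_min")])
  if (any(dup)) {
    warning(sprintf("mark_first_arrivals: dropped %d duplicate arrival row(s)", sum(dup)))
    arrivals <- arrivals[!dup, ]
  }
  arrivals |>
    dplyr::group_by(.data$individual_id, .data$date) |>
    dplyr::mutate(is_first_of_day = dplyr::row_number(.data$time_min) == 1L) |>
    dplyr::ungroup()
}

#' Males eligible to sire at a conception date
#'
#' A male is a candidate sire if he was alive and at least `min_age_years`
#' old on the conception date (the youngest known sire in this population
#' was 11.4), and not known to be sterile by then. Optionally restricted to
#' genotyped males (ungenotyped males cannot enter paternity models).
#'
#' @param roster roster tibble.
#' @param conception_date Date.
#' @param min_age_years minimum age in years (days / 365.25).
#' @param require_genotyped drop males with `genotyped = FALSE`.
#' @return character vector of male ids; errors if empty.
#' @export
eligible_males <- function(roster, conception_date, min_age_years = 11,
                           require_genotyped = TRUE) {
  r <- dplyr::filter(
    roster,
    .data$sex == "male",
    .data$birth_date <= conception_date,
    is.na(.data$death_date) | .data$death_date >= conception_date,
    is.na(.data$sterile_from) | .data$sterile_from > conception_date,
    age_years(.data$birth_date, conception_date) >= min_age_years
  )
  if (require_genotyped) r <- dplyr::filter(r, .data$genotyped)
  if (nrow(r) == 0) {
    stop("no eligible candidate sires on ", format(conception_date), call. = FALSE)
  }
  r$id
}

# symmetric relatedness lookup; NA when the pair is absent
rel_lookup <- function(relatedness, a, b) {
  key <- dyad_key(relatedness$id_a, relatedness$id_b)
  r <- setNames(relatedness$r, key)
  unname(r[dyad_key(a, b)])
}

#' Build siring windows from paternity records
#'
#' Each siring event defines a one-year analysis window: the `window_days`
#' days preceding the conception date (dates `d` with
#' `start_date <= d < conception_date`). The eligible-male set is resolved
#' per event.
#'
#' @param log an `obs_log`.
#' @param window_days window length in days.
#' @param min_age_years,require_genotyped passed to [eligible_males()].
#' @return tibble with one row per siring event: `event_id`, ids, dates and
#'   an `eligible` list-column of male ids.
#' @export
siring_windows <- function(log, window_days = 365, min_age_years = 11,
                           require_genotyped = TRUE) {
  p <- log$paternities
  tibble::tibble(
    event_id = seq_len(nrow(p)),
    offspring_id = p$offspring_id,
    mother_id = p$mother_id,
    sire_id = p$sire_id,
    conception_date = p$conception_date,
    start_date = p$conception_date - window_days,
    eligible = purrr::map(p$conception_date, function(d) {
      eligible_males(log$roster, d, min_age_years, require_genotyped)
    })
  )
}

#' Apply relatedness-based siring-event exclusions
#'
#' Events missing four or more mother-by-candidate relatedness values are
#' dropped entirely. Events with 1-3 missing values are retained, with the
#' missing dyads imputed by the event-wise mean of the available candidate
#' values (flagged in the output).
#'
#' @param windows output of [siring_windows()].
#' @param relatedness long relatedness tibble.
#' @param max_missing largest number of missing values an event may carry
#'   and still be retained.
#' @return the windows tibble, filtered, with a `candidates` list-column of
#'   tibbles (`id`, `r`, `r_imputed`).
#' @export
apply_siring_event_exclusions <- function(windows, relatedness, max_missing = 3) {
  cand <- purrr::map2(windows$eligible, windows$mother_id, function(ids, mom) {
    r <- rel_lookup(relatedness, rep(mom, length(ids)), ids)
    tibble::tibble(id = ids, r = r, r_imputed = is.na(r))
  })
  n_missing <- purrr::map_int(cand, ~ sum(.x$r_imputed))
  drop <- n_missing > max_missing
  if (any(drop)) {
    message(sprintf("dropping %d siring event(s) with > %d missing relatedness values",
                    sum(drop), max_missing))
  }
  out <- windows[!drop, ]
  out$candidates <- purrr::map(cand[!drop], function(tb) {
    if (any(tb$r_imputed)) tb$r[tb$r_imputed] <- mean(tb$r, na.rm = TRUE)
    tb
  })
  out
}

#' @export
print.obs_log <- function(x, ...) {
  cat("<obs_log>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

log_tables <- c("roster", "arrivals", "copresence", "grooming",
                "pantgrunts", "coalitions", "paternities", "relatedness")

#' Read an observation log from a directory of CSV tables
#'
#' Expects `roster.csv`, `arrivals.csv`, `copresence.csv`, `grooming.csv`,
#' `pantgrunts.csv`, `coalitions.csv`, `paternities.csv`,
#' `relatedness.csv` (UTF-8, headers). Dates must be ISO-8601; unparseable
#' dates raise an error naming the file.
#'
#' @param dir directory containing the eight CSV files.
#' @param gestation_days passed to [observation_log()].
#' @return a validated `obs_log`.
#' @export
read_observation_log <- function(dir, gestation_days = 226) {
  read1 <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
    df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
    for (col in intersect(names(df),
                          c("date", "birth_date", "death_date", "sterile_from",
                            "conception_date"))) {
      parsed <- as.Date(df[[col]], format = "%Y-%m-%d")
      bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(parsed))
      if (length(bad)) {
        stop(sprintf("%s.csv: unparseable date '%s' (row %d)",
                     name, df[[col]][bad[1]], bad[1]), call. = FALSE)
      }
      df[[col]] <- parsed
    }
    df
  }
  tabs <- lapply(setNames(log_tables, log_tables), read1)
  observation_log(tabs$roster, tabs$arrivals, tabs$copresence, tabs$grooming,
                  tabs$pantgrunts, tabs$coalitions, tabs$paternities,
                  tabs$relatedness, gestation_days = gestation_days)
}

#' Write an observation log to a directory of CSV tables
#'
#' @param log an `obs_log`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_observation_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in log_tables) {
    df <- as.data.frame(log[[nm]])
    # derived columns are regenerated on read
    df <- df[, setdiff(names(df), c("is_first_of_day", "focal_is_member",
                                    "conception_date")), drop = FALSE]
    write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
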