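#' Configuration for the synthetic community generator
#'
#' Defines the study conditions the generator emulates: a community of
#' around a dozen reproductive-age males observed by near-daily focal
#' follows over a decade, with fission-fusion party arrivals shaped by
#' latent dyadic bonds, grooming conditioned on bonds, pant-grunts driven
#' by latent dominance abilities, coalitions whose probability rises with
#' bond strength, and siring events whose log-odds depend on rank,
#' strong-tie count, bond with the alpha, and relatedness (computed from
#' the generated logs themselves; see [simulate_community()]).
#'
#' @param n_males,n_females community composition.
#' @param n_years study length in years.
#' @param follows_per_year focal-follow days per year.
#' @param bond_density probability a male dyad is bonded.
#' @param bond_arrival_boost multiplier on the joint-arrival (same
#'   arrival-cluster) probability for bonded dyads.
#' @param p_join_base daily same-cluster probability for an unbonded,
#'   co-attending dyad.
#' @param groom_rate_base grooming-bout hazard per co-presence minute for
#'   unbonded dyads; with 8-minute mean bouts the default gives dyadic
#'   grooming rates of the order of half a percent of focal time together.
#' @param groom_bond_boost hazard multiplier for groom-bonded dyads.
#' @param groom_bond_overlap probability that a dyad's grooming affinity
#'   copies its association bond (otherwise drawn independently at
#'   `bond_density`); the default keeps association and grooming channels
#'   only weakly coupled, as observed for this system (dyadic association
#'   and grooming correlate at R^2 below 0.1).
#' @param male_attend_prob,female_attend_prob daily attendance
#'   probabilities.
#' @param pg_per_year pant-grunt interactions per year.
#' @param coalition_base_prob expected dyadic coalitions per dyad-year for
#'   an unbonded dyad.
#' @param coalition_bond_coef log-linear boost of the dyadic coalition
#'   rate for bonded dyads.
#' @param p_triad probability a coalition event includes a third actor.
#' @param conception_rate conceptions per female per year (one per
#'   interbirth interval of ~5.5 years).
#' @param siring_coefs named list `beta_rank`, `beta_strong_ties`,
#'   `beta_alpha_csi` (log-odds per within-window SD) and
#'   `beta_relatedness` (log-odds per unit relatedness); defaults follow
#'   the effect-size regime reported for this system (odds ratios near
#'   1.6 and 1.4 per SD for strong ties and alpha-CSI), a positive rank
#'   effect, and inbreeding avoidance for maternal relatives.
#' @param k_true Elo update constant used when the generator converts
#'   pant-grunts into the rank covariate of the siring model.
#' @param start_date first study day.
#' @param seed integer seed (`NULL`: use the current RNG state).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_males = 13, n_females = 20, n_years = 10,
                       follows_per_year = 300,
                       bond_density = 0.3, bond_arrival_boost = 3,
                       p_join_base = 0.03,
                       groom_rate_base = 4.5e-4, groom_bond_boost = 3,
                       groom_bond_overlap = 0.15,
                       male_attend_prob = 0.6, female_attend_prob = 0.35,
                       pg_per_year = 150,
                       coalition_base_prob = 0.07, coalition_bond_coef = 2.5,
                       p_triad = 0.2,
                       conception_rate = 1 / 5.5,
                       siring_coefs = list(beta_rank = 0.5,
                                           beta_strong_ties = 0.49,
                                           beta_alpha_csi = 0.36,
                                           beta_relatedness = -2),
                       k_true = 100,
                       start_date = as.Date("2000-01-01"),
                       seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_males >= 4, cfg$n_years >= 2, cfg$follows_per_year > 0,
            cfg$bond_density >= 0, cfg$bond_density <= 1,
            cfg$p_join_base >= 0, cfg$p_join_base <= 1,
            cfg$conception_rate >= 0, cfg$conception_rate <= 1)
  structure(cfg, class = c("sim_config", "list"))
}

#' Simulate a synthetic chimpanzee community
#'
#' Two-pass generation. Pass one draws the behavioral logs: follow days;
#' male attendance; arrival clusters (a random graph whose edges are more
#' likely for bonded dyads — connected components arrive together, seconds
#' to minutes apart, in parties whose size at each arrival is the number
#' already present); all-day co-presence after parties fuse in the
#' afternoon; grooming bouts as a Poisson process over focal co-presence
#' minutes with exponential durations; pant-grunts whose direction follows
#' `P(i submits to j) = pnorm(ability_j - ability_i)`; coalitions sampled
#' dyad-wise with bond-dependent rates; and a relatedness matrix with a
#' realistic kinship mixture. Pass two runs the real measurement pipeline
#' (Elo scores at `k_true`, window sociality metrics) on those logs and
#' draws each event's sire from a multinomial whose log-odds are
#' `beta_rank * z(rank) + beta_strong_ties * z(ties) +
#' beta_alpha_csi * z(csi_alpha) + beta_relatedness * r`, so the planted
#' effects are expressed in the very statistics the analysis measures.
#'
#' @param config a [sim_config()].
#' @return list with `log` (a validated `obs_log`) and `truth` (latent
#'   bond matrix, abilities, generating coefficients, per-event
#'   sire-selection table).
#' @export
simulate_community <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  nm <- config$n_males
  nf <- config$n_females
  males <- sprintf("M%02d", seq_len(nm))
  females <- sprintf("F%02d", seq_len(nf))
  start <- config$start_date

  roster <- tibble::tibble(
    id = c(males, females),
    sex = c(rep("male", nm), rep("female", nf)),
    birth_date = start - round(c(runif(nm, 12, 32), runif(nf, 12, 35)) * 365.25),
    death_date = as.Date(NA), sterile_from = as.Date(NA), genotyped = TRUE
  )
  abilities <- setNames(rnorm(nm), males)
  # two latent bond channels: association bonds shape party arrivals and
  # coalitions; grooming affinities (weakly overlapping) shape grooming
  bond <- matrix(0L, nm, nm, dimnames = list(males, males))
  up <- upper.tri(bond)
  bond[up] <- rbinom(sum(up), 1, config$bond_density)
  bond <- bond + t(bond)
  gbond <- matrix(0L, nm, nm, dimnames = list(males, males))
  copy <- runif(sum(up)) < config$groom_bond_overlap
  gbond[up] <- ifelse(copy, bond[up], rbinom(sum(up), 1, config$bond_density))
  gbond <- gbond + t(gbond)

  # follow days
  n_days_total <- round(config$n_years * 365.25)
  days_by_year <- purrr::map(seq_len(config$n_years), function(y) {
    lo <- round((y - 1) * 365.25)
    hi <- min(round(y * 365.25), n_days_total) - 1
    sort(sample(lo:hi, min(config$follows_per_year, hi - lo + 1)))
  })
  day_off <- unlist(days_by_year)
  dates <- start + day_off
  nd <- length(dates)

  att_m <- matrix(runif(nd * nm) < config$male_attend_prob, nd, nm)
  # guarantee at least two males per follow day (a focal must have partners)
  few <- which(rowSums(att_m) < 2)
  for (d in few) att_m[d, sample(nm, 2)] <- TRUE
  att_f <- matrix(runif(nd * nf) < config$female_attend_prob, nd, nf)

  # ---- arrival clusters -------------------------------------------------
  pair_idx <- which(up, arr.ind = TRUE)
  p_edge <- pmin(config$p_join_base *
                   ifelse(bond[up] == 1, config$bond_arrival_boost, 1), 0.95)
  edges <- purrr::map(seq_len(nrow(pair_idx)), function(k) {
    i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
    both <- which(att_m[, i] & att_m[, j])
    hit <- both[runif(length(both)) < p_edge[k]]
    if (!length(hit)) return(NULL)
    tibble::tibble(day = hit, i = i, j = j)
  })
  edges <- dplyr::bind_rows(edges)
  inst <- which(att_m, arr.ind = TRUE) # (day, male) attending instances
  vname <- function(day, male) paste0(day, "_", male)
  verts <- vname(inst[, 1], inst[, 2])
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) data.frame(from = vname(edges$day, edges$i),
                                    to = vname(edges$day, edges$j))
        else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership[verts]

  arr <- tibble::tibble(day = inst[, 1], male = inst[, 2], comp = unname(comp),
                        shuffle = runif(length(verts)))
  comp_start <- setNames(runif(max(comp), 360, 840), seq_len(max(comp)))
  arr <- arr |>
    dplyr::arrange(.data$comp, .data$shuffle) |>
    dplyr::group_by(.data$comp) |>
    dplyr::mutate(position = dplyr::row_number(),
                  gap = runif(dplyr::n(), 0.5, 1.5),
                  time_min = comp_start[.data$comp[1]] + cumsum(.data$gap) - .data$gap[1]) |>
    dplyr::ungroup()

  focal_of_day <- vapply(seq_len(nd), function(d) {
    present <- which(att_m[d, ])
    males[present[sample.int(length(present), 1)]]
  }, character(1))

  arrivals <- tibble::tibble(
    date = dates[arr$day],
    time_min = round(arr$time_min, 2),
    individual_id = males[arr$male],
    party_size_at_arrival = arr$position,
    focal_id = focal_of_day[arr$day]
  )

  # ---- co-presence ------------------------------------------------------
  fusion <- runif(nd, 845, 880)
  day_end <- runif(nd, 960, 1050)
  m_long <- tibble::tibble(day = arr$day, id = males[arr$male],
                           t = pmin(arr$time_min, fusion[arr$day]),
                           comp = arr$comp)
  mm <- dplyr::inner_join(m_long, m_long, by = "day", suffix = c("_a", "_b"),
                          relationship = "many-to-many") |>
    dplyr::filter(.data$id_a < .data$id_b) |>
    dplyr::mutate(start_min = ifelse(.data$comp_a == .data$comp_b,
                                     pmax(.data$t_a, .data$t_b),
                                     fusion[.data$day]))
  f_inst <- which(att_f, arr.ind = TRUE)
  f_long <- tibble::tibble(day = f_inst[, 1], id = females[f_inst[, 2]])
  mf <- dplyr::inner_join(dplyr::select(m_long, "day", "id"), f_long,
                          by = "day", suffix = c("_a", "_b"),
                          relationship = "many-to-many") |>
    dplyr::mutate(start_min = fusion[.data$day])
  copresence <- dplyr::bind_rows(
    dplyr::select(mm, "day", "id_a", "id_b", "start_min"),
    dplyr::select(mf, "day", "id_a", "id_b", "start_min")
  ) |>
    dplyr::mutate(date = dates[.data$day],
                  focal_id = focal_of_day[.data$day],
                  individual_a = .data$id_a, individual_b = .data$id_b,
                  end_min = day_end[.data$day]) |>
    dplyr::select("date", "focal_id", "individual_a", "individual_b",
                  "start_min", "end_min")

  # ---- grooming ---------------------------------------------------------
  bidx <- function(a, b) bond[cbind(match(a, males), match(b, males))]
  gbidx <- function(a, b) gbond[cbind(match(a, males), match(b, males))]
  gsrc <- mm |>
    dplyr::filter(focal_of_day[.data$day] == .data$id_a |
                    focal_of_day[.data$day] == .data$id_b) |>
    dplyr::mutate(dur = day_end[.data$day] - .data$start_min,
                  hazard = config$groom_rate_base *
                    ifelse(gbidx(.data$id_a, .data$id_b) == 1,
                           config$groom_bond_boost, 1),
                  n_bouts = rpois(dplyr::n(), .data$dur * .data$hazard)) |>
    dplyr::filter(.data$n_bouts > 0)
  grooming <- if (nrow(gsrc)) {
    gb <- gsrc[rep(seq_len(nrow(gsrc)), gsrc$n_bouts), ]
    b_start <- runif(nrow(gb), gb$start_min, day_end[gb$day] - 2)
    b_dur <- pmax(1, pmin(rexp(nrow(gb), 1 / 8), day_end[gb$day] - b_start))
    swap <- runif(nrow(gb)) < 0.5
    tibble::tibble(
      date = dates[gb$day],
      start_min = round(b_start, 2),
      end_min = round(b_start + b_dur, 2),
      groomer_id = ifelse(swap, gb$id_a, gb$id_b),
      groomee_id = ifelse(swap, gb$id_b, gb$id_a),
      focal_id = focal_of_day[gb$day]
    )
  } else {
    tibble::tibble(date = as.Date(character(0)), start_min = numeric(0),
                   end_min = numeric(0), groomer_id = character(0),
                   groomee_id = character(0), focal_id = character(0))
  }

  # ---- pant-grunts ------------------------------------------------------
  n_pg <- config$pg_per_year * config$n_years
  pg_day <- sample(which(rowSums(att_m) >= 2), n_pg, replace = TRUE)
  pg_pair <- t(vapply(pg_day, function(d) {
    present <- which(att_m[d, ])
    present[sample.int(length(present), 2)]
  }, integer(2)))
  p_i_submits <- pnorm(abilities[pg_pair[, 2]] - abilities[pg_pair[, 1]])
  i_sub <- runif(n_pg) < p_i_submits
  pantgrunts <- tibble::tibble(
    date = dates[pg_day],
    time_min = round(runif(n_pg, 400, 1000), 2),
    actor_id = males[ifelse(i_sub, pg_pair[, 1], pg_pair[, 2])],
    recipient_id = males[ifelse(i_sub, pg_pair[, 2], pg_pair[, 1])]
  ) |> dplyr::arrange(.data$date, .data$time_min)

  # ---- coalitions -------------------------------------------------------
  dyads <- tibble::tibble(a = males[pair_idx[, 1]], b = males[pair_idx[, 2]],
                          bonded = bond[up])
  co_rows <- purrr::map(seq_len(config$n_years), function(y) {
    n_ev <- rpois(nrow(dyads), config$coalition_base_prob *
                    exp(config$coalition_bond_coef * dyads$bonded))
    idx <- rep(seq_len(nrow(dyads)), n_ev)
    if (!length(idx)) return(NULL)
    yr_days <- days_by_year[[y]]
    purrr::map(idx, function(k) {
      actors <- c(dyads$a[k], dyads$b[k])
      if (runif(1) < config$p_triad) {
        others <- setdiff(males, actors)
        wgt <- exp(config$coalition_bond_coef *
                     (bidx(rep(dyads$a[k], length(others)), others) +
                        bidx(rep(dyads$b[k], length(others)), others)))
        actors <- c(actors, sample(others, 1, prob = wgt))
      }
      targets <- sample(setdiff(males, actors), sample(1:2, 1))
      tibble::tibble(
        date = start + sample(yr_days, 1),
        actor_ids = paste(sort(actors), collapse = ";"),
        target_ids = paste(sort(targets), collapse = ";"),
        aggression_type = sample(c("directed_display", "chase", "attack"), 1)
      )
    }) |> dplyr::bind_rows()
  })
  coalitions <- dplyr::bind_rows(co_rows)

  # ---- relatedness ------------------------------------------------------
  all_ids <- roster$id
  pr <- t(combn(all_ids, 2))
  kin_class <- sample(1:4, nrow(pr), replace = TRUE,
                      prob = c(0.55, 0.25, 0.15, 0.05))
  rel_r <- c(runif(nrow(pr), -0.05, 0.05), runif(nrow(pr), 0.05, 0.15),
             0.25 + runif(nrow(pr), -0.03, 0.03),
             0.5 + runif(nrow(pr), -0.02, 0.02))[
               (kin_class - 1) * nrow(pr) + seq_len(nrow(pr))]
  relatedness <- tibble::tibble(id_a = pr[, 1], id_b = pr[, 2],
                                r = round(rel_r, 4))

  # ---- conceptions ------------------------------------------------------
  conc <- purrr::map(2:config$n_years, function(y) {
    who <- females[runif(nf) < config$conception_rate]
    if (!length(who)) return(NULL)
    lo <- round((y - 1) * 365.25)
    hi <- round(y * 365.25) - 1
    tibble::tibble(mother_id = who,
                   conception_date = start + sample(lo:hi, length(who),
                                                    replace = TRUE))
  }) |> dplyr::bind_rows()
  if (nrow(conc) == 0) stop("no conceptions generated; raise conception_rate")
  conc <- dplyr::arrange(conc, .data$conception_date)
  paternities <- tibble::tibble(
    offspring_id = sprintf("O%03d", seq_len(nrow(conc))),
    mother_id = conc$mother_id,
    sire_id = NA_character_,
    birth_date = conc$conception_date + 226
  )

  log <- observation_log(roster, arrivals, copresence, grooming, pantgrunts,
                         coalitions, paternities, relatedness)

  # ---- pass two: sire selection from measured statistics ---------------
  traj <- elo_update_sequence(pantgrunts, k = config$k_true, ids = males)
  daily <- daily_tables(log)
  cf <- config$siring_coefs
  truth_rows <- purrr::map(seq_len(nrow(paternities)), function(i) {
    cdate <- conc$conception_date[i]
    ids <- eligible_males(roster, cdate)
    st <- elo_standings(traj, ids, cdate)
    dm <- dyad_metrics(log, ids, cdate - 365, cdate, daily = daily)
    sv <- sociality_vectors(log, dm, ids, cdate - 365, cdate,
                            alpha_id = st$alpha, daily = daily)
    r <- rel_lookup(relatedness, rep(conc$mother_id[i], length(ids)), ids)
    r[is.na(r)] <- 0
    z_ties <- sv$z_n_strong_assoc_ties[match(ids, sv$id)]
    z_csi <- sv$z_csi_with_alpha[match(ids, sv$id)]
    z_csi[is.na(z_csi)] <- 0
    eta <- cf$beta_rank * st$scores$z[match(ids, st$scores$id)] +
      cf$beta_strong_ties * z_ties +
      cf$beta_alpha_csi * z_csi +
      cf$beta_relatedness * r
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    sire <- sample(ids, 1, prob = p)
    list(sel = tibble::tibble(event_id = i, male_id = ids, eta = eta, p = p,
                              alpha_id = st$alpha, sire = sire),
         males = dplyr::mutate(sv, event_id = i, .before = 1),
         info = tibble::tibble(event_id = i, alpha_id = st$alpha,
                               beta_id = st$beta))
  })
  truth_tab <- dplyr::bind_rows(purrr::map(truth_rows, "sel"))
  sires <- truth_tab |>
    dplyr::distinct(.data$event_id, .data$sire)
  log$paternities$sire_id <- sires$sire[match(seq_len(nrow(paternities)),
                                              sires$event_id)]

  list(log = log,
       truth = list(bond = bond, groom_bond = gbond, abilities = abilities,
                    coefs = cf, k_true = config$k_true,
                    selection = truth_tab, config = config),
       # pass-two measurement products (computed with the pipeline's own
       # functions); replicate experiments may reuse them instead of
       # recomputing identical window metrics
       metrics = list(males = dplyr::bind_rows(purrr::map(truth_rows, "males")),
                      info = dplyr::bind_rows(purrr::map(truth_rows, "info")),
                      elo = traj))
}

#' Hand-written toy observation log
#'
#' A tiny four-male, two-siring-event log whose every metric can be checked
#' by hand. Joint qualifying first arrivals by dyad in the window preceding
#' each conception (gap <= 5 min, party size <= 4):
#'
#' | dyad  | joint | | male | qualifying arrivals |
#' |-------|-------|-|------|---------------------|
#' | A-B   | 2     | | A    | 3                   |
#' | A-C   | 1     | | B    | 3                   |
#' | B-C   | 1     | | C    | 3                   |
#' | A-D, B-D, C-D | 0 | | D | 1                |
#'
#' so e.g. SRI(A,B) = 2 / (3 + 3 - 2) = 0.5. Day 5's arrivals are in a
#' party of five (never qualifying) and male A arrives twice on day 1 (the
#' second arrival is ignored). The two pant-grunt days order the males
#' D < C < B < A. Day 6 carries one triadic coalition (A;B;C -> D).
#'
#' @return a validated `obs_log`.
#' @export
make_toy_fixture <- function() {
  d <- function(x) as.Date("2010-01-01") + x
  roster <- tibble::tibble(
    id = c("A", "B", "C", "D", "FX", "FY"),
    sex = c(rep("male", 4), "female", "female"),
    birth_date = as.Date(c("1990-06-01", "1992-03-15", "1994-08-20",
                           "1996-11-05", "1995-01-01", "1993-07-07")),
    death_date = as.Date(NA), sterile_from = as.Date(NA), genotyped = TRUE
  )
  arrivals <- tibble::tibble(
    date = d(c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4, 4, 5, 5, 5)),
    time_min = c(480, 483, 700, 490, 500, 504, 610, 480, 481, 520, 523,
                 600, 601, 602),
    individual_id = c("A", "B", "A", "C", "A", "B", "D", "B", "C", "A", "C",
                      "A", "B", "D"),
    party_size_at_arrival = c(1, 2, 4, 3, 1, 2, 3, 1, 2, 1, 2, 5, 5, 5),
    focal_id = "A"
  )
  copresence <- tibble::tibble(
    date = d(c(1, 1, 1, 2, 2, 3, 4, 5)),
    focal_id = c("A", "A", "A", "A", "A", "B", "A", "C"),
    individual_a = c("A", "A", "B", "A", "A", "B", "A", "A"),
    individual_b = c("B", "C", "C", "B", "D", "C", "C", "B"),
    start_min = c(483, 490, 490, 504, 610, 481, 523, 602),
    end_min = c(900, 900, 900, 1000, 1000, 881, 923, 1002)
  )
  grooming <- tibble::tibble(
    date = d(c(1, 2, 3)),
    start_min = c(500, 520, 500),
    end_min = c(530, 560, 510),
    groomer_id = c("A", "B", "B"),
    groomee_id = c("B", "A", "C"),
    focal_id = c("A", "A", "B")
  )
  pantgrunts <- tibble::tibble(
    date = d(c(1, 1, 1, 2, 2, 2)),
    time_min = c(500, 510, 520, 500, 510, 520),
    actor_id = c("B", "C", "D", "C", "D", "D"),
    recipient_id = c("A", "B", "C", "A", "B", "A")
  )
  coalitions <- tibble::tibble(
    date = d(c(6, 40)),
    actor_ids = c("A;B;C", "A;B"),
    target_ids = c("D", "C;D"),
    aggression_type = c("chase", "directed_display")
  )
  paternities <- tibble::tibble(
    offspring_id = c("O1", "O2"),
    mother_id = c("FX", "FY"),
    sire_id = c("A", "B"),
    birth_date = d(c(60, 90)) + 226
  )
  pr <- t(combn(roster$id, 2))
  relatedness <- tibble::tibble(
    id_a = pr[, 1], id_b = pr[, 2],
    r = c(0.25, 0.05, 0, 0.1, 0, 0.5, 0.02, 0, 0.12, 0.01, 0.25, 0,
          0.03, 0.06, 0)
  )
  observation_log(roster, arrivals, copresence, grooming, pantgrunts,
                  coalitions, paternities, relatedness)
}

#' Simulate a pant-grunt stream from a known Elo process
#'
#' Individuals start from entry scores spread by their latent abilities;
#' at each event a random pair meets, the outcome is drawn from the
#' current-score Elo expectation, and scores update with `k_true`. Used
#' for maximum-likelihood recovery checks.
#'
#' @param n_events number of interactions.
#' @param n_ind number of males.
#' @param k_true generating update constant.
#' @param entry_spread SD (in Elo points) of ability-implied entry scores.
#' @param scale logistic scale.
#' @return list: `pantgrunts` tibble, `abilities`, `final_scores`.
#' @export
sim_elo_stream <- function(n_events = 2000, n_ind = 13, k_true = 100,
                           entry_spread = 400, scale = 400) {
  ids <- sprintf("M%02d", seq_len(n_ind))
  abilities <- setNames(rnorm(n_ind), ids)
  entry <- 1000 + entry_spread * (abilities - mean(abilities))
  res <- elo_stream_cpp(n_events, unname(entry), k_true, scale)
  pg <- tibble::tibble(
    date = as.Date("2000-01-01") + seq_len(n_events),
    actor_id = ids[res$loser],
    recipient_id = ids[res$winner]
  )
  list(pantgrunts = pg, abilities = abilities,
       final_scores = setNames(res$final_scores, ids))
}

#' Simulate a male-by-event siring design table directly
#'
#' Draws per-male standardized predictors and a sire per event from the
#' multinomial log-odds model, bypassing the behavioral layer; used for
#' coefficient-recovery checks of the mixed-model machinery.
#'
#' @param n_events number of siring events.
#' @param n_males candidate males per event.
#' @param beta named coefficients on the standardized predictors
#'   (predictor columns are generated N(0,1) per male-event).
#' @param ranef_sd SD of a per-male latent intercept.
#' @return design tibble with `event_id`, `male_id`, `outcome` and one
#'   column per predictor.
#' @export
sim_design <- function(n_events = 200, n_males = 12,
                       beta = c(x1 = 0.5), ranef_sd = 0) {
  males <- sprintf("M%02d", seq_len(n_males))
  u <- rnorm(n_males, 0, ranef_sd)
  rows <- purrr::map(seq_len(n_events), function(ev) {
    X <- matrix(rnorm(n_males * length(beta)), n_males)
    colnames(X) <- names(beta)
    eta <- drop(X %*% beta) + u
    p <- exp(eta - max(eta))
    sire <- sample.int(n_males, 1, prob = p / sum(p))
    out <- tibble::as_tibble(X)
    out$event_id <- ev
    out$male_id <- males
    out$outcome <- as.integer(seq_len(n_males) == sire)
    out
  })
  dplyr::bind_rows(rows)
}

#' Simulate dyad-year records from the social relations probit model
#'
#' @param n_actors number of males.
#' @param n_years replicated years (all dyads each year).
#' @param beta named coefficients (excluding intercept) on N(0,1) dyadic
#'   covariates.
#' @param intercept probit intercept.
#' @param sigma_a actor-effect SD.
#' @return list: `records` tibble and `truth`.
#' @export
sim_srm_records <- function(n_actors = 15, n_years = 10,
                            beta = c(x1 = 0.17), intercept = -1,
                            sigma_a = 0.3) {
  ids <- sprintf("M%02d", seq_len(n_actors))
  a <- setNames(rnorm(n_actors, 0, sigma_a), ids)
  pr <- t(combn(ids, 2))
  rows <- purrr::map(seq_len(n_years), function(y) {
    X <- matrix(rnorm(nrow(pr) * length(beta)), nrow(pr))
    colnames(X) <- names(beta)
    z <- intercept + drop(X %*% beta) + a[pr[, 1]] + a[pr[, 2]] +
      rnorm(nrow(pr))
    out <- tibble::as_tibble(X)
    out$year <- y
    out$id_a <- pr[, 1]
    out$id_b <- pr[, 2]
    out$outcome <- as.integer(z > 0)
    out
  })
  list(records = dplyr::bind_rows(rows),
       truth = list(beta = beta, intercept = intercept, sigma_a = sigma_a,
                    actor_effects = a))
}
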