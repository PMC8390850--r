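# Random small observation logs with adversarial structure (duplicate
# arrivals, second-of-day arrivals, large parties, unobserved dyads) for
# oracle-equivalence checks. Filter thresholds are passed explicitly so the
# tiny logs exercise the same code paths as full-scale data.

random_small_log <- function(seed) {
  set.seed(seed)
  n_m <- sample(4:6, 1)
  males <- sprintf("m%d", seq_len(n_m))
  roster <- tibble::tibble(
    id = c(males, "f1"),
    sex = c(rep("male", n_m), "female"),
    birth_date = as.Date("1990-01-01") + sample(0:2000, n_m + 1),
    death_date = as.Date(NA), sterile_from = as.Date(NA), genotyped = TRUE
  )
  n_days <- sample(5:10, 1)
  arr <- purrr::map(seq_len(n_days), function(d) {
    who <- sample(males, sample(2:n_m, 1))
    k <- length(who)
    tibble::tibble(
      date = as.Date("2010-01-01") + d,
      time_min = round(runif(k, 400, 460), 1),
      individual_id = who,
      party_size_at_arrival = sample(1:6, k, replace = TRUE),
      focal_id = who[1]
    )
  }) |> dplyr::bind_rows()
  # occasional second-of-day arrivals
  extra <- arr[sample(nrow(arr), ceiling(nrow(arr) / 4)), ]
  extra$time_min <- extra$time_min + runif(nrow(extra), 10, 300)
  arrivals <- dplyr::bind_rows(arr, extra)

  cp <- arr |>
    dplyr::group_by(date) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) return(tibble::tibble())
      cmb <- combn(g$individual_id, 2)
      tibble::tibble(
        focal_id = g$focal_id[1],
        individual_a = cmb[1, ], individual_b = cmb[2, ],
        start_min = round(runif(ncol(cmb), 460, 500), 1),
        end_min = round(runif(ncol(cmb), 600, 1000), 1)
      )
    }) |> dplyr::ungroup()

  gr <- cp[runif(nrow(cp)) < 0.4 & cp$focal_id == cp$individual_a, ]
  grooming <- if (nrow(gr)) {
    tibble::tibble(
      date = gr$date,
      start_min = gr$start_min + 5,
      end_min = gr$start_min + 5 + round(runif(nrow(gr), 2, 40), 1),
      groomer_id = gr$individual_a, groomee_id = gr$individual_b,
      focal_id = gr$focal_id
    )
  } else {
    tibble::tibble(date = as.Date(character(0)), start_min = numeric(0),
                   end_min = numeric(0), groomer_id = character(0),
                   groomee_id = character(0), focal_id = character(0))
  }

  pg_pairs <- t(replicate(8, sample(males, 2)))
  pantgrunts <- tibble::tibble(
    date = as.Date("2010-01-01") + sample(seq_len(n_days), 8, replace = TRUE),
    time_min = round(runif(8, 400, 1000), 1),
    actor_id = pg_pairs[, 1], recipient_id = pg_pairs[, 2]
  )
  coalitions <- tibble::tibble(
    date = as.Date("2010-01-05"),
    actor_ids = paste(sample(males, sample(2:3, 1)), collapse = ";"),
    target_ids = "f1", aggression_type = "chase"
  )
  coalitions$target_ids <- setdiff(males, strsplit(coalitions$actor_ids, ";")[[1]])[1]
  paternities <- tibble::tibble(
    offspring_id = "o1", mother_id = "f1", sire_id = males[1],
    birth_date = as.Date("2010-01-01") + n_days + 226
  )
  pr <- t(combn(roster$id, 2))
  relatedness <- tibble::tibble(id_a = pr[, 1], id_b = pr[, 2],
                                r = round(runif(nrow(pr), 0, 0.3), 3))
  suppressWarnings(
    observation_log(roster, arrivals, cp, grooming, pantgrunts, coalitions,
                    paternities, relatedness))
}

# loose thresholds so tiny logs keep (most) dyads
toy_filters <- list(min_together = 100, max_poor_arrivals = 0, min_focal = 100)

toy_dyad_metrics <- function(log, ids, start, end) {
  suppressWarnings(
    dyad_metrics(log, ids, start, end,
                 min_together = toy_filters$min_together,
                 max_poor_arrivals = toy_filters$max_poor_arrivals,
                 min_focal = toy_filters$min_focal))
}

rel_lookup_test <- function(rel, mom, ids) {
  vapply(ids, function(id) {
    hit <- rel$r[(rel$id_a == mom & rel$id_b == id) |
                   (rel$id_b == mom & rel$id_a == id)]
    if (length(hit)) hit[1] else NA_real_
  }, numeric(1))
}
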