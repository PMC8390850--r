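# shared small community to keep the generator tests quick
small_cfg <- function(seed, ...) {
  sim_config(n_years = 2, follows_per_year = 120, n_females = 8,
             conception_rate = 0.6, seed = seed, ...)
}

test_that("simulation is deterministic given a seed", {
  s1 <- simulate_community(small_cfg(123))
  s2 <- simulate_community(small_cfg(123))
  for (tab in c("arrivals", "copresence", "grooming", "pantgrunts",
                "coalitions", "paternities", "relatedness")) {
    expect_identical(as.data.frame(s1$log[[tab]]), as.data.frame(s2$log[[tab]]),
                     info = tab)
  }
  expect_identical(s1$truth$bond, s2$truth$bond)
  s3 <- simulate_community(small_cfg(124))
  expect_false(identical(s1$log$arrivals, s3$log$arrivals))
})

test_that("generated logs satisfy the domain invariants", {
  sim <- simulate_community(small_cfg(77))
  expect_true(validate_observation_log(sim$log))
  a <- sim$log$arrivals
  per <- tapply(a$is_first_of_day, paste(a$individual_id, a$date), sum)
  expect_true(all(per == 1))
  expect_true(all(sim$log$copresence$end_min > sim$log$copresence$start_min))
  expect_true(all(sim$log$paternities$conception_date ==
                    sim$log$paternities$birth_date - 226))
  # pant-grunt direction tracks latent ability
  pg <- sim$log$pantgrunts
  ab <- sim$truth$abilities
  frac_up <- mean(ab[pg$recipient_id] > ab[pg$actor_id])
  expect_gt(frac_up, 0.6)
  # every sire is an eligible male of its window
  w <- siring_windows(sim$log)
  expect_true(all(purrr::map2_lgl(w$sire_id, w$eligible, ~ .x %in% .y)))
})

test_that("bonded dyads associate more; the boost is monotone", {
  mean_sri_by_bond <- function(boost, seeds) {
    out <- purrr::map(seeds, function(s) {
      sim <- simulate_community(small_cfg(s, bond_arrival_boost = boost))
      log <- sim$log
      ids <- log$roster$id[log$roster$sex == "male"]
      dm <- dyad_metrics(log, ids, min(log$arrivals$date),
                         max(log$arrivals$date) + 1,
                         min_together = 0, max_poor_arrivals = 0)
      bonded <- sim$truth$bond[cbind(dm$id_a, dm$id_b)] == 1
      c(bonded = mean(dm$sri[bonded], na.rm = TRUE),
        unbonded = mean(dm$sri[!bonded], na.rm = TRUE))
    })
    colMeans(do.call(rbind, out))
  }
  seeds <- 1:6
  no_boost <- mean_sri_by_bond(1, seeds)
  boosted <- mean_sri_by_bond(3, seeds)
  stronger <- mean_sri_by_bond(6, seeds)
  # boost 1: bonded and unbonded dyads are exchangeable
  expect_lt(abs(no_boost["bonded"] - no_boost["unbonded"]),
            0.33 * no_boost["unbonded"])
  # monotone separation as the boost grows
  expect_gt(boosted["bonded"], no_boost["bonded"])
  expect_gt(stronger["bonded"], boosted["bonded"])
  expect_gt(boosted["bonded"], 1.5 * boosted["unbonded"])
})

test_that("with all siring betas zero the sire is uniform over candidates", {
  cfg <- small_cfg(55, siring_coefs = list(beta_rank = 0, beta_strong_ties = 0,
                                           beta_alpha_csi = 0,
                                           beta_relatedness = 0))
  sel <- purrr::map(1:12, function(i) {
    cfg$seed <- 1000 + i
    simulate_community(cfg)$truth$selection
  }) |> dplyr::bind_rows()
  expect_true(all(abs(sel$eta) < 1e-12))
  # chi-square goodness of fit against uniform sire choice
  n_events <- dplyr::n_distinct(paste(sel$event_id, sel$sire, sel$p))
  counts <- table(factor(sel$sire[!duplicated(paste(sel$event_id, sel$sire))],
                         levels = sprintf("M%02d", 1:13)))
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("toy fixture is stable, hand-checkable and round-trips", {
  log <- make_toy_fixture()
  expect_equal(sum(log$roster$sex == "male"), 4)
  expect_equal(nrow(log$paternities), 2)
  dir <- withr::local_tempdir()
  write_observation_log(log, dir)
  back <- read_observation_log(dir)
  expect_equal(as.data.frame(back$arrivals), as.data.frame(log$arrivals))
  # SRI from the docstring table: SRI(A, B) = 2 / (3 + 3 - 2)
  w <- siring_windows(log)
  ja <- detect_joint_arrivals(log$arrivals, c("A", "B"), w$start_date[1],
                              w$conception_date[1])
  expect_equal(compute_sri(ja$pairs$joint, 3, 3), 0.5)
})

test_that("truth record aligns with roster and planted coefficients", {
  sim <- simulate_community(small_cfg(9))
  males <- sim$log$roster$id[sim$log$roster$sex == "male"]
  expect_equal(dim(sim$truth$bond), c(length(males), length(males)))
  expect_identical(sim$truth$bond, t(sim$truth$bond))
  expect_setequal(names(sim$truth$abilities), males)
  expect_equal(sim$truth$coefs$beta_strong_ties, 0.49)
  # per-event selection probabilities are a proper distribution
  sums <- tapply(sim$truth$selection$p, sim$truth$selection$event_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
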