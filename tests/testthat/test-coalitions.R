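test_that("coalition dyadization expands triads into three pairs", {
  co <- tibble::tibble(
    date = as.Date("2005-03-01") + 0:2,
    actor_ids = c("A;B;C", "A;B", "C;D;E"),
    target_ids = c("D", "C;D", "A"),
    aggression_type = "chase"
  )
  out <- dyadize_coalitions(co)
  expect_equal(nrow(out), 3 + 1 + 3)
  expect_setequal(paste(out$id_a, out$id_b)[out$date == co$date[1]],
                  c("A B", "A C", "B C"))
  expect_equal(sum(out$date == co$date[2]), 1)
  # 10 triadic events -> 30 dyadic records; oracle agreement
  co10 <- tibble::tibble(date = as.Date("2005-01-01") + 1:10,
                         actor_ids = "X;Y;Z", target_ids = "W",
                         aggression_type = "attack")
  out10 <- dyadize_coalitions(co10)
  expect_equal(nrow(out10), 30)
  orc <- oracle_dyadize(co10)
  expect_equal(nrow(out10), nrow(orc))
  expect_error(dyadize_coalitions(tibble::tibble(
    date = as.Date("2005-01-01"), actor_ids = "A", target_ids = "B")),
    "2 or 3")
})

test_that("yearly networks keep only years with enough coalition dyads", {
  mk <- function(year, n_dyads) {
    tibble::tibble(date = as.Date(sprintf("%d-06-01", year)),
                   year = year,
                   id_a = sprintf("a%d", seq_len(n_dyads)),
                   id_b = sprintf("b%d", seq_len(n_dyads)))
  }
  recs <- dplyr::bind_rows(mk(2001, 7), mk(2002, 8), mk(2003, 12))
  expect_message(nets <- build_yearly_networks(recs), "2001")
  expect_setequal(unique(nets$year), c(2002, 2003))
  expect_equal(sum(nets$year == 2002), 8)
})

test_that("betweenness matches closed forms on canonical graphs", {
  path <- tibble::tibble(year = 2000, id_a = c("A", "B"), id_b = c("B", "C"),
                         n_events = 1)
  b <- coalition_betweenness(path)
  expect_equal(b$betweenness[b$id == "B"], 1)
  expect_equal(sum(b$betweenness[b$id != "B"]), 0)
  star <- tibble::tibble(year = 2000, id_a = "hub",
                         id_b = paste0("s", 1:4), n_events = 1)
  bs <- coalition_betweenness(star)
  expect_equal(bs$betweenness[bs$id == "hub"], 4 * 3 / 2)
  cmb <- combn(paste0("k", 1:5), 2)
  complete <- tibble::tibble(year = 2000, id_a = cmb[1, ], id_b = cmb[2, ],
                             n_events = 2)
  expect_true(all(coalition_betweenness(complete)$betweenness == 0))
})

test_that("betweenness equals path-enumeration oracle on 100 random graphs", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(3:7, 1)
    adj <- matrix(0L, n, n)
    up <- which(upper.tri(adj), arr.ind = TRUE)
    on <- runif(nrow(up)) < runif(1, 0.25, 0.8)
    adj[up[on, , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    ids <- sprintf("v%d", 1:n)
    el <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    net <- tibble::tibble(year = 1, id_a = ids[el[, 1]], id_b = ids[el[, 2]],
                          n_events = 1)
    b <- coalition_betweenness(net)
    got <- setNames(rep(0, n), ids)
    got[b$id] <- b$betweenness
    expect_equal(unname(got), oracle_betweenness(adj), tolerance = 1e-9,
                 info = paste("graph", rep))
  }
})

test_that("betweenness regression recovers slope, CI and F", {
  d <- tibble::tibble(year = rep(2000:2004, each = 6),
                      id = rep(sprintf("m%d", 1:6), 5))
  set.seed(9)
  d$n_strong_assoc_ties <- rpois(nrow(d), 4)
  # exact linear relation on the within-year z-scale -> slope 2, perfect fit
  d$betweenness <- 2 * stats::ave(d$n_strong_assoc_ties, d$year,
                                  FUN = function(v) (v - mean(v)) / sd(v))
  expect_warning(fit <- betweenness_vs_strong_ties(d), "perfect")
  expect_equal(glance(fit)$slope, 2, tolerance = 1e-9)
  expect_true(glance(fit)$perfect_fit)
  # permutation oracle: slope centred at zero under shuffling
  d$betweenness <- d$betweenness + rnorm(nrow(d))
  slopes <- replicate(100, {
    dd <- d
    dd$betweenness <- sample(dd$betweenness)
    glance(suppressWarnings(betweenness_vs_strong_ties(dd)))$slope
  })
  expect_lt(abs(mean(slopes)), 0.15)
  expect_error(betweenness_vs_strong_ties(d[1:2, ]), "at least 3")
})

test_that("planted bond-coalition coupling yields positive significant slopes", {
  # replicate-level check at reduced scale; the full 20-seed rate is part
  # of the acceptance suite
  ok <- 0
  for (s in 1:3) {
    sim <- simulate_community(sim_config(seed = 300 + s))
    dy <- dyadize_coalitions(sim$log$coalitions)
    nets <- suppressMessages(build_yearly_networks(dy))
    bt <- dplyr::inner_join(coalition_betweenness(nets),
                            yearly_strong_ties(sim$log),
                            by = c("year", "id"))
    g <- glance(betweenness_vs_strong_ties(bt))
    ok <- ok + (g$slope > 0)
  }
  expect_gte(ok, 2)
})
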