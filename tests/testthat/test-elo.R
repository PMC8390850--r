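mk_pg <- function(actor, recipient) {
  tibble::tibble(date = as.Date("2000-01-01") + seq_along(actor),
                 actor_id = actor, recipient_id = recipient)
}

test_that("single updates follow the closed-form Elo rule", {
  # equal scores, k = 16: winner +8, loser -8
  tr <- elo_update_sequence(mk_pg("b", "a"), k = 16)
  expect_equal(tr$e_winner[1], 0.5)
  expect_equal(tr$winner_score[1], 1008)
  expect_equal(tr$loser_score[1], 992)
  # winner 400 points above loser: E = 10/11, gain = k/11
  tr2 <- elo_update_sequence(mk_pg("b", "a"), k = 16,
                             entry_scores = c(a = 1400, b = 1000))
  expect_equal(tr2$e_winner[1], 10 / 11)
  expect_equal(tr2$winner_score[1], 1400 + 16 / 11)
  # empty event list -> empty trajectory
  tr0 <- elo_update_sequence(mk_pg(character(0), character(0)), k = 16)
  expect_equal(nrow(tr0), 0)
  # same individual on both sides is rejected
  expect_error(elo_update_sequence(mk_pg("a", "a"), k = 16), "identical")
})

test_that("scores are conserved and NLL matches replay accumulation", {
  set.seed(1)
  n <- 200
  ids <- letters[1:6]
  pg <- tibble::tibble(
    date = as.Date("2000-01-01") + seq_len(n),
    actor_id = sample(ids, n, replace = TRUE),
    recipient_id = NA_character_
  )
  pg$recipient_id <- vapply(pg$actor_id,
                            function(a) sample(setdiff(ids, a), 1), "x")
  tr <- elo_update_sequence(pg, k = 50)
  expect_equal(sum(attr(tr, "final_scores")), 1000 * length(ids))
  # direct NLL equals the replay-accumulated one
  expect_equal(elo_negative_log_likelihood(pg, k = 50), attr(tr, "nll"),
               tolerance = 1e-10)
  expect_equal(attr(tr, "nll"), -sum(log(tr$e_winner)), tolerance = 1e-10)
  # k = 0: scores never move, NLL = n log 2 at equal entries
  expect_equal(elo_negative_log_likelihood(pg, k = 0), n * log(2))
  # raising a consistent winner's entry score lowers the NLL
  pg_dom <- mk_pg(rep(c("b", "c"), 10), rep("a", 20))
  nll_flat <- elo_negative_log_likelihood(pg_dom, k = 20)
  nll_up <- elo_negative_log_likelihood(
    pg_dom, k = 20, entry_scores = c(a = 1200, b = 900, c = 900))
  expect_lt(nll_up, nll_flat)
})

test_that("three-male hand trace reproduces sequential updates", {
  # a beats b, then b beats c, then c beats a; k = 32, scale 400
  pg <- mk_pg(c("b", "c", "a"), c("a", "b", "c"))
  tr <- elo_update_sequence(pg, k = 32)
  # manual trace
  e1 <- 0.5
  ra <- 1000 + 32 * (1 - e1); rb <- 1000 - 32 * (1 - e1)
  e2 <- 1 / (1 + 10^((1000 - rb) / 400))
  rb2 <- rb + 32 * (1 - e2); rc <- 1000 - 32 * (1 - e2)
  e3 <- 1 / (1 + 10^((ra - rc) / 400))
  rc2 <- rc + 32 * (1 - e3); ra2 <- ra - 32 * (1 - e3)
  expect_equal(tr$winner_score, c(ra, rb2, rc2))
  expect_equal(tr$loser_score, c(rb, rc, ra2))
  expect_equal(tr$e_winner, c(e1, e2, e3))
  # score queries: strictly before a date; unseen ids get entry scores
  sc <- score_at_date(tr, c("a", "b", "c"), tr$date[2])
  expect_equal(sc$score[sc$id == "a"], ra)
  expect_equal(sc$score[sc$id == "c"], 1000)
  expect_false(sc$entered[sc$id == "c"])
  st <- elo_standings(tr, c("a", "b", "c"), tr$date[3] + 1)
  expect_equal(st$alpha, "c") # c ends highest after winning as underdog
  expect_equal(mean(st$scores$z), 0)
})

test_that("ML fitting recovers k and ranks on simulated streams", {
  # note: at k = 100 the generating process is a score diffusion, so the
  # recoverable rank state is the true end-of-stream scores (initial
  # ability anchors wash out over 2000 events for any estimator)
  ks <- numeric(5)
  rho <- numeric(5)
  for (s in 1:5) {
    set.seed(s)
    stream <- sim_elo_stream(n_events = 2000, n_ind = 13, k_true = 100)
    fit <- fit_elo_ml(stream$pantgrunts, optimize_entry = TRUE)
    ks[s] <- fit$k
    fin <- attr(fit$trajectory, "final_scores")
    rho[s] <- cor(fin[names(stream$final_scores)], stream$final_scores,
                  method = "spearman")
  }
  expect_lt(abs(median(ks) - 100), 25)
  expect_true(all(rho > 0.8))
})

test_that("entry-score optimization is identified and nested in k-only fits", {
  set.seed(2)
  stream <- sim_elo_stream(n_events = 600, n_ind = 8, k_true = 60)
  fit_k <- fit_elo_ml(stream$pantgrunts, optimize_entry = FALSE)
  fit_full <- fit_elo_ml(stream$pantgrunts, optimize_entry = TRUE)
  expect_gte(fit_k$nll, fit_full$nll)
  expect_equal(mean(fit_full$entry_scores), 1000)
  # a male who wins every interaction gets the top fitted entry score
  pg <- mk_pg(rep(c("b", "c", "d"), 12), rep("a", 36))
  fit_dom <- suppressWarnings(fit_elo_ml(pg, optimize_entry = TRUE))
  expect_equal(names(which.max(fit_dom$entry_scores)), "a")
  expect_warning(fit_elo_ml(pg[1:10, ]), "fewer than 20")
})

test_that("higher generating k produces more volatile rating streams", {
  vol <- vapply(c(20, 200), function(k) {
    set.seed(7)
    stream <- sim_elo_stream(n_events = 1500, n_ind = 10, k_true = k,
                             entry_spread = 200)
    tr <- elo_update_sequence(stream$pantgrunts, k = k)
    mean(abs(diff(tr$winner_score)))
  }, numeric(1))
  expect_gt(vol[2], vol[1])
})
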