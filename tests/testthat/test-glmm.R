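test_that("AICc and Akaike weights match closed forms", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46)
  expect_error(aicc(-100, 3, 4), "n <= k")
  expect_equal(akaike_weights(c(100, 102)),
               c(exp(0), exp(-1)) / (exp(0) + exp(-1)))
  expect_equal(round(akaike_weights(c(0, 2)), 3), c(0.731, 0.269))
  expect_equal(akaike_weights(500), 1)
  expect_equal(sum(akaike_weights(runif(7, 100, 120))), 1)
  # AICc converges to AIC for large n
  expect_lt(abs(aicc(-100, 3, 1e6) - (200 + 6)), 0.01)
})

test_that("VIF follows the 1/(1-R^2) closed form and flags collinearity", {
  set.seed(1)
  n <- 4000
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  d <- tibble::tibble(x1 = x1, x2 = x2, x3 = rnorm(n))
  v <- vif_terms(d, c("x1", "x2"))
  expect_equal(v$vif, rep(1 / (1 - cor(x1, x2)^2), 2), tolerance = 1e-9)
  expect_equal(v$vif[1], 5.26, tolerance = 0.06 * 5.26)
  v3 <- vif_terms(d, c("x1", "x3"))
  expect_true(all(v3$vif < 1.01))
  d$x4 <- d$x1
  expect_warning(vc <- vif_terms(d, c("x1", "x4")), "collinear")
  expect_true(all(is.infinite(vc$vif)))
})

test_that("design table has one success per event and resolves predictors", {
  log <- make_toy_fixture()
  w <- siring_windows(log) |> apply_siring_event_exclusions(log$relatedness)
  elo <- elo_update_sequence(log$pantgrunts, k = 32,
                             ids = c("A", "B", "C", "D"))
  soc <- compute_sociality(log, w, elo = elo,
                           min_together = 100, max_poor_arrivals = 0,
                           min_focal = 100)
  design <- suppressMessages(build_design_table(w, soc$males, elo, log$roster))
  expect_equal(nrow(design), sum(lengths(w$eligible)))
  per_event <- tapply(design$outcome, design$event_id, sum)
  expect_true(all(per_event == 1))
  expect_equal(design$relatedness[design$event_id == 1],
               unname(rel_lookup_test(log$relatedness, "FX", c("A", "B", "C", "D"))))
  # age is Z-scaled across the whole design
  expect_equal(mean(design$age_z), 0, tolerance = 1e-12)
  # a sire outside the candidate set is an error naming the event
  w2 <- w
  w2$sire_id[1] <- "ZZ"
  expect_error(build_design_table(w2, soc$males, elo, log$roster), "event 1")
})

test_that("sigma -> 0 mixed fits match plain logistic regression", {
  set.seed(3)
  design <- sim_design(n_events = 150, n_males = 8,
                       beta = c(x1 = 0.8, x2 = -0.3), ranef_sd = 0)
  fit <- fit_binomial_glmm(design, c("x1", "x2"), quadrature_points = 15)
  glm_fit <- glm(outcome ~ x1 + x2, family = binomial(), data = design)
  expect_equal(unname(lme4::fixef(fit$fit)), unname(coef(glm_fit)),
               tolerance = 1e-3)
  # quadrature refinement barely moves the log-likelihood
  f1 <- fit_binomial_glmm(design, c("x1", "x2"), quadrature_points = 1)
  f25 <- fit_binomial_glmm(design, c("x1", "x2"), quadrature_points = 25)
  expect_lt(abs(f1$loglik - f25$loglik), 0.05)
})

test_that("planted coefficients are recovered without material bias", {
  set.seed(11)
  est <- replicate(10, {
    design <- sim_design(n_events = 200, n_males = 12, beta = c(x1 = 0.5),
                         ranef_sd = 0.2)
    fit <- fit_binomial_glmm(design, "x1", quadrature_points = 1)
    unname(lme4::fixef(fit$fit)["x1"])
  })
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("nested-model pruning removes best-plus-one-term models", {
  models <- tibble::tibble(
    model = c("a", "a+b", "a+c", "a+b+c"),
    terms = list("a", c("a", "b"), c("a", "c"), c("a", "b", "c")),
    AICc = c(100, 102, 99, 101)
  )
  out <- prune_nested(models)
  # a+b is best(a)+1 -> pruned; a beats nothing above it; a+c is better
  # than a so not pruned; a+b+c is a+c plus one term and worse -> pruned
  expect_equal(out$pruned, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("null-model selection keeps planted terms and drops nuisance", {
  set.seed(21)
  design <- sim_design(n_events = 250, n_males = 10,
                       beta = c(relatedness = 0, elo_z = 0.8, age_z = 0,
                                age2_z = 0, n_repro_males = 0),
                       ranef_sd = 0)
  sel <- select_null_model(design, quadrature_points = 1)
  expect_equal(nrow(sel$table), 32)
  expect_true("elo_z" %in% sel$null_terms)
  expect_false("age2_z" %in% sel$null_terms)
  kept <- sel$table[sel$table$in_top, ]
  expect_equal(sum(kept$weight), 1)
  expect_true(all(kept$AICc - min(kept$AICc) <= 6))
})

test_that("comparison tables have the study's row structure", {
  expect_length(table1_measures(), 15)
  expect_length(table2_model_set(), 8)
  raw <- table1_measures(raw_counts = TRUE)
  expect_true("z_n_strong_raw_ties" %in% raw)
  set.seed(5)
  design <- sim_design(n_events = 120, n_males = 8,
                       beta = c(z_a = 0.6, z_b = 0, z_c = 0))
  cmp <- compare_sociality_models(design, character(0),
                                  c(A = "z_a", B = "z_b", C = "z_c"),
                                  quadrature_points = 1)
  expect_equal(nrow(cmp), 4) # null + three measures
  expect_equal(cmp$dAICc[cmp$model == "Null model"], 0)
  expect_equal(sum(cmp$weight), 1)
  expect_equal(cmp$model[1], "A")
  expect_true(cmp$beats_null[cmp$model == "A"])
  expect_error(compare_sociality_models(design, character(0), c(X = "z_x"),
                                        quadrature_points = 1),
               "absent")
})
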