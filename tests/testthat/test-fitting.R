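# Polynomial surface fitting, nested F-tests and model selection.

test_that("design matrices carry exactly the published term sets", {
  d1 <- build_design(data.frame(dose_norm = 0.5, time_norm = 0.5), order = 1L)
  expect_equal(unname(d1[1, ]), c(1, 0.5, 0.5))
  expect_equal(colnames(d1), c("(Intercept)", "Dose", "Time"))

  d2 <- build_design(data.frame(dose_norm = 0.5, time_norm = 0.5), order = 2L)
  expect_equal(unname(d2[1, ]), c(1, 0.25, 0.25, 0.25, 0.5, 0.5))

  d3 <- build_design(data.frame(dose_norm = runif(20), time_norm = runif(20)),
                     order = 3L)
  expect_equal(ncol(d3), 10L)
  expect_equal(colnames(d3)[1:5],
               c("(Intercept)", "Dose3", "Dose2Time", "DoseTime2", "Time3"))

  expect_error(build_design(data.frame(dose_norm = rep(0.5, 9),
                                       time_norm = runif(9)), order = 1L),
               "distinct doses")
  expect_error(build_design(data.frame(dose_norm = runif(5),
                                       time_norm = runif(5)), order = 2L),
               "fewer observations")
})

test_that("exact data are fitted with zero residual", {
  des <- data.frame(dose_norm = rep(c(0, 0.5, 1), 4),
                    time_norm = rep(c(0, 1/3, 2/3, 1), each = 3))
  y_plane <- 0.2 + 0.7 * des$dose_norm - 0.3 * des$time_norm
  fits <- fit_all_orders(y_plane, des)
  expect_lt(fits$order1$rss, 1e-20)
  expect_equal(unname(fits$order1$beta[, 1]), c(0.2, 0.7, -0.3),
               tolerance = 1e-10)
  y_const <- rep(0.42, nrow(des))
  fc <- fit_all_orders(y_const, des)
  expect_equal(unname(fc$constant$beta[1, 1]), 0.42)
  expect_lt(fc$constant$rss, 1e-25)
})

test_that("RSS is non-increasing along the nested order sequence", {
  set.seed(21)
  for (i in 1:20) {
    des <- random_design(30L)
    y <- rnorm(30)
    fits <- fit_all_orders(y, des)
    rss <- vapply(fits, `[[`, numeric(1L), "rss")
    expect_true(all(diff(rss) <= 1e-12))
  }
})

test_that("coefficients, RSS and F tests match the normal-equations oracle", {
  set.seed(99)
  for (i in 1:50) {
    des <- random_design(40L)
    y <- rnorm(40)
    fits <- fit_all_orders(y, des)
    oracles <- list()
    for (o in 1:3) {
      X <- build_design(des, order = o)
      oracles[[o]] <- ne_fit(X, y)
      f <- fits[[paste0("order", o)]]
      expect_equal(unname(f$beta[, 1]), unname(oracles[[o]]$beta),
                   tolerance = 1e-8)
      expect_equal(f$rss, oracles[[o]]$rss, tolerance = 1e-8)
    }
    an <- nested_anova(fits)
    rss0 <- sum((y - mean(y))^2)
    rss_seq <- c(rss0, vapply(oracles, `[[`, numeric(1L), "rss"))
    df_seq <- 40 - c(1, 3, 6, 10)
    for (k in 1:3) {
      f_or <- ((rss_seq[k] - rss_seq[k + 1]) / (df_seq[k] - df_seq[k + 1])) /
        (rss_seq[k + 1] / df_seq[k + 1])
      step <- an$steps[[k]]
      expect_equal(step$f, f_or, tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(step$p, f_tail_beta(f_or, df_seq[k] - df_seq[k + 1],
                                       df_seq[k + 1]),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("nested F arithmetic matches the closed-form hand example", {
  # n = 12, RSS_r = 2 on 10 df vs RSS_f = 1 on 8 df -> F = 4 on (2, 8)
  out <- nested_f(2, 10, 1, 8)
  expect_equal(out$f, 4)
  expect_equal(out$p, f_tail_beta(4, 2, 8), tolerance = 1e-12)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 8)

  # identical fits -> F = 0, p = 1
  z <- nested_f(1.5, 10, 1.5, 8)
  expect_equal(z$f, 0)
  expect_equal(z$p, 1)

  # perfect full fit -> p at the floor
  lim <- nested_f(2, 10, 0, 8)
  expect_equal(lim$p, 1e-300)

  expect_error(nested_f(2, 10, 1, 0), "saturated")
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3L))
  expect_equal(adjust_pvalues(rep(0.2, 5L)), rep(0.2, 5L))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_equal(adjust_pvalues(p), p.adjust(p, "BH"))
  expect_true(all(adjust_pvalues(p) >= p))
  expect_error(adjust_pvalues(c(0.5, 1.2)))
})

test_that("noiseless responsive genes select their true order", {
  des <- experiment_design(seed = 31L)
  specs <- list(
    lin = surface_spec("linear", c(0, 0.8, 0.4), noise_sd = 0),
    p2 = surface_spec("poly2", c(0, 0.9, 0.5, -0.7, 0.3, 0.2), noise_sd = 0)
  )
  sim <- simulate_experiment(specs, des)
  fits <- fit_dose_time(sim$lfc)
  expect_equal(fits$genes$lin$order, 1L)
  expect_equal(fits$genes$p2$order, 2L)
  expect_equal(fits$genes$lin$pvalue, 1e-300)
})

test_that("pure-noise genes are gated out in at least 99% of cases", {
  specs <- lapply(1:1000, function(i)
    surface_spec("constant", 0, noise_sd = 0.1))
  sim <- simulate_experiment(specs, experiment_design(seed = 13L))
  fits <- fit_dose_time(sim$lfc, alpha = 0.01)
  expect_gte(mean(fits$table$order == "constant"), 0.99)
})

test_that("aliased cubic dose term is dropped, not fatal, on 3-dose designs", {
  # with 3 dose levels Dose^3 is a linear combination of 1, Dose, Dose^2
  sim <- simulate_experiment(list(g = preset_spec("poly3", noise_sd = 0.05)),
                             experiment_design(seed = 17L))
  fits <- fit_all_orders(sim$lfc$values, sim$lfc$design)
  expect_equal(fits$order3$rank, 9L)
  # exactly one pure-dose term is redundant (which one depends on pivoting)
  expect_length(fits$order3$aliased, 1L)
  expect_true(fits$order3$aliased %in% c("Dose", "Dose2", "Dose3"))
  expect_equal(fits$order3$df_resid, 108L - 9L)
})

test_that("fitted values from the selected surface reproduce the stored RSS", {
  sim <- simulate_experiment(list(g = preset_spec("poly2")),
                             experiment_design(seed = 23L))
  fits <- fit_dose_time(sim$lfc)
  fit <- fits$genes$g
  pred <- predict(fit, sim$lfc$design$dose_norm, sim$lfc$design$time_norm,
                  units = "normalized")
  expect_equal(sum((sim$lfc$values["g", ] - pred)^2), fit$rss,
               tolerance = 1e-10)
  # original-unit prediction agrees through the normalization round trip
  pred2 <- predict(fit, sim$lfc$design$dose, sim$lfc$design$time)
  expect_equal(pred, pred2, tolerance = 1e-10)
})
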