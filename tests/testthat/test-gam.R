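test_that("boundary transform maps [0,1] strictly inside (0,1)", {
  expect_equal(boundary_transform(0, 1000), 0.0005)
  expect_equal(boundary_transform(1, 1000), 0.9995)
  expect_equal(boundary_transform(0.5, 17), 0.5)
  y <- seq(0, 1, by = 0.1)
  yt <- boundary_transform(y)
  expect_true(all(yt > 0 & yt < 1))
  expect_equal(inverse_boundary_transform(yt, length(y)), y)
  expect_error(boundary_transform(1.2), "lie in")
})

test_that("the intercept-only fit matches a brute-force beta MLE", {
  set.seed(2)
  y <- boundary_transform(rbeta(400, 2, 5))
  f0 <- fit_beta_gam(data.frame(maa = y), "maa", character(0))
  # oracle: grid over the mean, profiling the precision numerically
  loglik <- function(mu, phi) sum(dbeta(y, mu * phi, (1 - mu) * phi,
                                        log = TRUE))
  mus <- seq(0.2, 0.4, by = 1e-5)
  prof <- vapply(mus, function(m)
    stats::optimize(function(p) loglik(m, p), c(0.5, 200),
                    maximum = TRUE)$objective, 0)
  mu_hat <- mus[which.max(prof)]
  expect_equal(mean(fitted(f0$fit)), mu_hat, tolerance = 5e-4)
  expect_true(all(fitted(f0$fit) > 0 & fitted(f0$fit) < 1))
})

test_that("a known diel smooth is recovered through the logit link", {
  d <- simulate_gam_data(n = 5000, phi = 20, seed = 3)
  f <- fit_beta_gam(d, "maa", c("hour_of_day", "day"))
  terms <- predict(f$fit, type = "terms")
  sm <- terms[, grep("hour_of_day", colnames(terms), fixed = TRUE)]
  expect_gte(cor(sm, attr(d, "true_smooth")), 0.95)
  expect_lt(abs(f$phi - 20) / 20, 0.2)
  expect_true(all(fitted(f$fit) > 0 & fitted(f$fit) < 1))
})

test_that("a near-constant response explains no deviance and shrinks
           the smooth", {
  set.seed(6)
  d <- data.frame(maa = boundary_transform(pmin(pmax(
    0.5 + rnorm(500, sd = 0.02), 0), 1)),
    hour_of_day = sample(0:23, 500, TRUE))
  f <- fit_beta_gam(d, "maa", "hour_of_day")
  expect_lt(f$dev_expl, 0.02)
  # shrunk toward the smooth's unpenalized null space (the thin-plate
  # linear part is never penalized, so ~1-2 edf is the floor)
  smooth_edf <- sum(f$fit$edf[-1])
  expect_lt(smooth_edf, 2.5)
})

test_that("all-subsets tables are well-formed and ranked", {
  d <- simulate_gam_data(n = 600, seed = 4)
  sel <- all_subsets_selection(d, "maa", c("hour_of_day", "day"))
  expect_equal(nrow(sel$table), 4)
  expect_equal(sel$table$delta_aicc[1], 0)
  expect_true(!is.unsorted(sel$table$delta_aicc))
  # single candidate: exactly null + full
  sel1 <- all_subsets_selection(d, "maa", "day")
  expect_equal(nrow(sel1$table), 2)
  # duplicated predictor: singleton models tie in AICc
  d$day2 <- d$day
  sel2 <- all_subsets_selection(d, "maa", c("day", "day2"))
  singles <- sel2$table[sel2$table$n_predictors == 1, ]
  expect_equal(diff(singles$aicc), 0, tolerance = 1e-6)
})

test_that("AICc ranking ignores predictor order and affine rescaling", {
  d <- simulate_gam_data(n = 600, seed = 9)
  a <- all_subsets_selection(d, "maa", c("hour_of_day", "day"))
  b <- all_subsets_selection(d, "maa", c("day", "hour_of_day"))
  expect_equal(a$table$aicc[order(a$table$predictors)],
               b$table$aicc[order(b$table$predictors)], tolerance = 1e-8)
  d2 <- d
  d2$hour_of_day <- (d2$hour_of_day - 12) / 24
  c_ <- all_subsets_selection(d2, "maa", c("hour_of_day", "day"))
  expect_equal(sort(a$table$aicc), sort(c_$table$aicc), tolerance = 1e-3)
})

test_that("explained-deviance contributions isolate informative predictors", {
  d <- simulate_gam_data(n = 3000, seed = 10)
  set.seed(10)
  d$noise <- rnorm(nrow(d))
  dev <- deviance_by_predictor(d, "maa", c("hour_of_day", "day", "noise"),
                               smooth_terms = "hour_of_day")
  expect_lt(abs(dev$contribution[dev$predictor == "noise"]), 0.01)
  expect_gt(dev$contribution[dev$predictor == "hour_of_day"],
            dev$contribution[dev$predictor == "noise"])
  # a sole informative predictor carries ~ all of the explained deviance
  d1 <- simulate_gam_data(n = 2000, seed = 12, day_effects = c(
    day_of = 0, day_after = 0, second_day_after = 0))
  full <- fit_beta_gam(d1, "maa", "hour_of_day")
  dev1 <- deviance_by_predictor(d1, "maa", "hour_of_day")
  expect_equal(dev1$contribution, full$dev_expl, tolerance = 0.02)
})

test_that("Durbin-Watson behaves as expected on white and AR(1) noise", {
  set.seed(14)
  dws <- replicate(50, residual_autocorrelation(rnorm(1000), n_perm = 10)$dw)
  expect_gt(mean(dws), 1.9)
  expect_lt(mean(dws), 2.1)
  # AR(1): DW ~ 2(1 - rho)
  e <- as.numeric(arima.sim(list(ar = 0.5), 2000))
  r <- residual_autocorrelation(e, n_perm = 200, seed = 3)
  expect_equal(r$dw, 1.0, tolerance = 0.1)
  expect_lt(r$p_value, 0.05)
  expect_gt(r$acf[1], 0.4)
  # white noise: permutation p is non-significant most of the time
  rw <- residual_autocorrelation(rnorm(500), n_perm = 500, seed = 4)
  expect_gt(rw$p_value, 0.01)
  # DW is invariant to reversing the residual order
  x <- rnorm(300)
  expect_equal(residual_autocorrelation(x, n_perm = 10)$dw,
               residual_autocorrelation(rev(x), n_perm = 10)$dw)
  expect_warning(residual_autocorrelation(rnorm(30)), "fewer than 50")
})

test_that("the simulator-to-GAM table has the documented structure", {
  ev <- make_event_schedule(3, as.Date("2014-09-20"), spacing_days = 10)
  ev$size_ordinal <- c(1L, 2L, 3L)
  st <- simulate_training_study(3, activity_params(seed = 15), ev)
  tab <- build_gam_table(st$hourly, ev)
  expect_true(all(tab$maa >= 0 & tab$maa <= 1))
  expect_setequal(levels(tab$day), c("day_before", "day_of", "day_after",
                                     "second_day_after"))
  expect_true(all(tab$season %in% c("autumn", "winter", "spring", "summer")))
  expect_true(all(tab$hours_since_explosion >= 0))
  # September/October events are autumn
  expect_true(all(tab$season == "autumn"))
  y <- boundary_transform(tab$maa)
  expect_true(all(y > 0 & y < 1))
})
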