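test_that("expression filter applies the zero-fraction rule inclusively", {
  expect_false(filterExpressed(c(0, 0, 0, 1), 0.5))   # 75% zeros
  expect_true(filterExpressed(c(1, 2, 3, 4), 0.5))
  expect_true(filterExpressed(c(0, 0, 1, 1), 0.5))    # boundary: exactly half
  expect_error(filterExpressed(numeric(0)), "empty")
  expect_error(filterExpressed(c(1, 0), 1), "max_zero_fraction")
})

test_that("median split puts ties in the low group and rejects degenerate vectors", {
  sp <- medianSplit(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
  expect_equal(sp$median, 2.5)
  expect_setequal(sp$group_a, c("s1", "s2"))
  expect_setequal(sp$group_b, c("s3", "s4"))

  sp3 <- medianSplit(c(a = 1, b = 2, c = 3))
  expect_equal(sp3$median, 2)
  expect_setequal(sp3$group_a, c("a", "b"))     # tie at the median goes low
  expect_identical(sp3$group_b, "c")

  expect_error(medianSplit(c(a = 5, b = 5, c = 5, d = 5)), "degenerate")
})

test_that("Kaplan-Meier estimates match hand-worked product limits", {
  # deaths at t=1 and t=2, two censored at t=3: S(1)=3/4, S(2)=3/4*2/3=1/2
  km <- kmEstimate(c(1, 2, 3, 3), c(1, 1, 0, 0))
  expect_equal(km$time, c(1, 2))
  expect_equal(km$n_risk, c(4, 3))
  expect_equal(km$surv, c(0.75, 0.5))

  all_cens <- kmEstimate(c(2, 5, 9), c(0, 0, 0))
  expect_equal(nrow(all_cens), 0)               # S(t) = 1 everywhere

  one <- kmEstimate(1, 1)
  expect_equal(one$surv, 0)

  set.seed(4)
  km2 <- kmEstimate(rexp(50) + 0.1, rbinom(50, 1, 0.6))
  expect_true(all(diff(km2$surv) <= 0))
  expect_true(all(km2$surv <= 1))
})

test_that("Kaplan-Meier agrees with the survival package on random fixtures", {
  skip_if_not_installed("survival")
  for (s in 1:25) {
    r <- rand_surv(sample(5:60, 1), seed = 200 + s)
    km <- kmEstimate(r$time, r$event)
    fit <- survival::survfit(survival::Surv(r$time, r$event) ~ 1)
    idx <- match(km$time, fit$time)
    expect_lt(max(abs(km$surv - fit$surv[idx])), 1e-8)
    expect_equal(km$n_risk, fit$n.risk[idx])
    expect_equal(km$n_event, fit$n.event[idx])
  }
})

test_that("log-rank is null for identical groups and exact on the single-event-time fixture", {
  r <- rand_surv(20, seed = 31)
  same <- logrankTest(r$time, r$event, r$time, r$event)
  expect_lt(same$chi_square, 1e-12)
  expect_equal(same$hazard_ratio, 1.0)
  expect_equal(same$p_value, 1.0)

  # group A: 5 deaths at t=1; group B: 5 censored at t=10.
  # Single event time with 10 at risk: E_a = 5 * 5/10 = 2.5, so
  # chi2 = (5-2.5)^2/2.5 + (0-2.5)^2/2.5 = 5, and the B rate of 0 makes
  # the O/E hazard ratio infinite.
  lr <- logrankTest(rep(1, 5), rep(1, 5), rep(10, 5), rep(0, 5))
  expect_identical(lr$obs_a, 5L)
  expect_equal(lr$exp_a, 2.5)
  expect_equal(lr$exp_b, 2.5)
  expect_equal(lr$chi_square, 5)
  expect_true(lr$hr_infinite)
  expect_identical(lr$hazard_ratio, Inf)

  expect_error(logrankTest(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("log-rank observed/expected bookkeeping matches survdiff to 1e-8", {
  skip_if_not_installed("survival")
  for (s in 1:40) {
    na <- sample(4:30, 1); nb <- sample(4:30, 1)
    a <- rand_surv(na, seed = 500 + s)
    b <- rand_surv(nb, seed = 900 + s)
    if (sum(a$event) + sum(b$event) == 0) next
    lr <- logrankTest(a$time, a$event, b$time, b$event)
    grp <- rep(c("a", "b"), c(na, nb))
    sd <- survival::survdiff(
      survival::Surv(c(a$time, b$time), c(a$event, b$event)) ~ grp)
    expect_lt(abs(lr$exp_a - sd$exp[1]), 1e-8)
    expect_lt(abs(lr$exp_b - sd$exp[2]), 1e-8)
    expect_identical(c(lr$obs_a, lr$obs_b), as.integer(sd$obs))
    # same statistic recomputed from the reference's expected counts
    chi_ref <- (sd$obs[1] - sd$exp[1])^2 / sd$exp[1] +
      (sd$obs[2] - sd$exp[2])^2 / sd$exp[2]
    expect_lt(abs(lr$chi_square - chi_ref), 1e-8)
    expect_lt(abs(lr$var_oe - sd$var[1, 1]), 1e-8)
  }
})

test_that("swapping groups inverts the hazard ratio and preserves the statistic", {
  for (s in 1:10) {
    a <- rand_surv(15, seed = 50 + s)
    b <- rand_surv(12, seed = 150 + s)
    ab <- logrankTest(a$time, a$event, b$time, b$event)
    ba <- logrankTest(b$time, b$event, a$time, a$event)
    expect_equal(ab$chi_square, ba$chi_square, tolerance = 1e-12)
    expect_equal(ab$hazard_ratio, 1 / ba$hazard_ratio, tolerance = 1e-12)
    expect_equal(ab$exp_a + ab$exp_b, ab$obs_a + ab$obs_b, tolerance = 1e-9)
  }
})

test_that("the prognostic screen flags planted effects and skips degenerate features", {
  spec <- syntheticSpec(n_samples = 300L, n_features = 20L, n_drivers = 4L,
                        hazard_log_ratio = log(3), censor_rate = 0.2,
                        seed = 60L)
  sim <- generateExpression(spec)
  drv <- sim$drivers[spec$survival_driver]
  clin <- generateSurvival(spec, exprValues(sim$expr)[, drv])

  scr <- prognosticScreen(sim$expr, clin,
                          features = c(drv, sim$drivers[2]), alpha = 0.05)
  row <- scr[scr$feature_id == drv, ]
  expect_true(row$analyzable)
  expect_true(row$prognostic)
  expect_lt(row$hazard_ratio, 1)    # low expression of the driver protects
  expect_equal(row$obs_a + row$obs_b, sum(clin$event))

  # a constant feature fails the split and is reported, not fatal
  v <- exprValues(sim$expr)
  v[, 2] <- 0
  scr2 <- prognosticScreen(ExprMatrix(v, normalized = TRUE), clin,
                           features = featureIDs(sim$expr)[2])
  expect_false(scr2$analyzable)
  expect_false(scr2$prognostic)
  expect_true(is.na(scr2$p_value))

  # samples without clinical rows are dropped with a message, not an error
  expect_message(
    prognosticScreen(sim$expr, clin[-(1:5), ], features = drv),
    "5 expression sample")

  # mostly-zero features are excluded by the expression filter
  v[, 3] <- 0
  v[1:10, 3] <- 0.5
  scr3 <- prognosticScreen(ExprMatrix(v, normalized = TRUE), clin,
                           features = featureIDs(sim$expr)[3])
  expect_false(scr3$analyzable)
})

test_that("BH adjustment and the CI-based HR rule only ever tighten the screen", {
  spec <- syntheticSpec(n_samples = 200L, n_features = 30L, n_drivers = 5L,
                        hazard_log_ratio = 0, seed = 61L)
  sim <- generateExpression(spec)
  clin <- generateSurvival(spec, exprValues(sim$expr)[, sim$drivers[1]])
  plain <- prognosticScreen(sim$expr, clin)
  bh <- prognosticScreen(sim$expr, clin, p_adjust = "BH")
  ci <- prognosticScreen(sim$expr, clin, hr_rule = "ci")
  expect_lte(sum(bh$prognostic), sum(plain$prognostic))
  expect_lte(sum(ci$prognostic), sum(plain$prognostic))
  expect_identical(plain$feature_id, featureIDs(sim$expr))
})
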