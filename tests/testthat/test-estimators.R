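test_that("IVW pooling reduces to the single SNP and to the mean under equal weights", {
  one <- make_instruments(0.08, 0.005, -0.02, 0.01)
  wr1 <- wald_ratios(one)
  fit1 <- ivw_pool(wr1)
  expect_equal(fit1$beta, wr1$ratio)
  expect_equal(fit1$se, sqrt(wr1$variance))
  expect_equal(fit1$n_snps, 1)

  equal <- data.frame(rsid = c("a", "b", "c"), ratio = c(0.2, 0.4, 0.6),
                      ci_low = NA, ci_high = NA, variance = 0.01,
                      fieller_case = "bounded")
  expect_equal(ivw_pool(equal)$beta, 0.4)
})

test_that("IVW matches an independently coded weighted-mean oracle", {
  est <- data.frame(rsid = c("a", "b", "c"), ratio = c(0.1, 0.3, 0.5),
                    ci_low = NA, ci_high = NA,
                    variance = c(0.01, 0.04, 0.04), fieller_case = "bounded")
  # spreadsheet arithmetic: weights 100, 25, 25
  oracle_beta <- (100 * 0.1 + 25 * 0.3 + 25 * 0.5) / 150
  oracle_se <- sqrt(1 / 150)
  fit <- ivw_pool(est)
  expect_equal(fit$beta, oracle_beta)
  expect_equal(fit$se, oracle_se)
  expect_equal(fit$ci_low, oracle_beta - qnorm(0.975) * oracle_se)
})

test_that("IVW under Fieller weights refuses unbounded cases and offers the fallback", {
  inst <- make_instruments(c(0.08, 0.004), 0.005, c(-0.02, 0.001), 0.01)
  wr <- wald_ratios(inst)
  expect_true(any(wr$fieller_case != "bounded"))
  expect_error(ivw_pool(wr), "first_order_delta")
  fit <- ivw_pool(wr, mr_config(weight_scheme = "first_order_delta"),
                  instruments = inst)
  expect_true(is.finite(fit$beta))
})

test_that("IVW with first-order weights equals no-intercept weighted regression", {
  set.seed(33)
  for (i in 1:10) {
    j <- sample(4:12, 1)
    inst <- make_instruments(runif(j, 0.03, 0.09), 0.006,
                             rnorm(j, -0.01, 0.02), runif(j, 0.008, 0.02))
    fit <- ivw_pool(wald_ratios(inst),
                    mr_config(weight_scheme = "first_order_delta"),
                    instruments = inst)
    slope <- coef(lm(beta_y ~ 0 + beta_x, data = inst,
                     weights = 1 / inst$se_y^2))[[1]]
    expect_equal(fit$beta, slope, tolerance = 1e-10)
  }
})

test_that("Egger regression interpolates collinear points exactly", {
  inst <- make_instruments(c(0.03, 0.05, 0.08), 0.005,
                           0.02 + 0.5 * c(0.03, 0.05, 0.08), 0.01)
  fit <- egger_regression(inst)
  expect_equal(fit$egger_intercept, 0.02, tolerance = 1e-12)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)

  # no pleiotropy, no noise: intercept 0, slope = true effect
  inst2 <- make_instruments(c(0.03, 0.05, 0.08, 0.06), 0.005,
                            0.3 * c(0.03, 0.05, 0.08, 0.06), 0.01)
  fit2 <- egger_regression(inst2)
  expect_equal(fit2$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(fit2$beta, 0.3, tolerance = 1e-12)
})

test_that("Egger coefficients match the normal-equations oracle", {
  set.seed(55)
  for (i in 1:10) {
    j <- 6
    inst <- make_instruments(runif(j, 0.03, 0.09), 0.006,
                             rnorm(j, -0.01, 0.02), runif(j, 0.008, 0.02))
    fit <- egger_regression(inst)
    oracle <- wls_normal_equations(inst$beta_x, inst$beta_y,
                                   1 / inst$se_y^2)
    expect_equal(fit$beta, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se_slope, tolerance = 1e-10)
    expect_equal(fit$egger_intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$egger_intercept_se, oracle$se_intercept,
                 tolerance = 1e-10)
    # two-sided t test with J - 2 df
    expect_equal(fit$egger_intercept_p,
                 2 * pt(abs(oracle$intercept / oracle$se_intercept),
                        df = j - 2, lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("Egger orients instruments to positive exposure effects first", {
  inst <- make_instruments(c(0.03, 0.05, 0.08, 0.06), 0.005,
                           c(0.011, 0.02, 0.03, 0.019), 0.01)
  flipped <- inst
  flipped$beta_x[2] <- -inst$beta_x[2]
  flipped$beta_y[2] <- -inst$beta_y[2]
  expect_equal(egger_regression(flipped)$beta, egger_regression(inst)$beta)
  expect_error(egger_regression(inst[1:2, ]), "at least 3")
})

test_that("Egger with the intercept forced to zero is IVW with first-order weights", {
  set.seed(77)
  inst <- make_instruments(runif(8, 0.03, 0.09), 0.006,
                           rnorm(8, -0.015, 0.02), runif(8, 0.008, 0.02))
  ivw <- ivw_pool(wald_ratios(inst),
                  mr_config(weight_scheme = "first_order_delta"),
                  instruments = inst)
  forced <- coef(lm(beta_y ~ 0 + beta_x, data = inst,
                    weights = 1 / inst$se_y^2))[[1]]
  expect_equal(ivw$beta, forced, tolerance = 1e-10)
})

test_that("weighted median reduces to the interpolated sample median under equal weights", {
  inst <- make_instruments(rep(0.05, 5), 0.005,
                           0.05 * c(0.1, 0.2, 0.3, 0.4, 0.5), 0.01)
  fit <- weighted_median_mr(inst, mr_config(bootstrap_reps = 100))
  expect_equal(fit$beta, 0.3)

  # any J: equal weights give the midpoint-interpolated median
  set.seed(9)
  for (j in c(2, 4, 7, 10)) {
    ratios <- sort(rnorm(j))
    inst_j <- make_instruments(rep(0.05, j), 0.005, 0.05 * ratios, 0.01)
    fit_j <- weighted_median_mr(inst_j, mr_config(bootstrap_reps = 100))
    s <- (seq_len(j) - 0.5) / j
    expected <- approx(s, ratios, xout = 0.5, ties = "ordered")$y
    expect_equal(fit_j$beta, expected)
  }
})

test_that("weighted median point estimate matches the cumulative-weight scan oracle", {
  set.seed(13)
  for (i in 1:5) {
    j <- 4
    inst <- make_instruments(runif(j, 0.03, 0.09), 0.006,
                             rnorm(j, -0.01, 0.004), runif(j, 0.008, 0.02))
    fit <- weighted_median_mr(inst, mr_config(bootstrap_reps = 100))
    oracle <- weighted_median_scan_oracle(inst$beta_y / inst$beta_x,
                                          inst$beta_x^2 / inst$se_y^2)
    expect_equal(fit$beta, oracle, tolerance = 2e-6)
  }
})

test_that("a dominant instrument makes the weighted median unavailable", {
  # normalized information weights (0.6, 0.2, 0.2)
  w_target <- c(0.6, 0.2, 0.2)
  se_y <- 0.01
  beta_x <- sqrt(w_target * se_y^2) # beta_x^2/se_y^2 proportional to w
  inst <- make_instruments(beta_x, 0.001, c(0.01, 0.02, 0.03), se_y)
  fit <- weighted_median_mr(inst, mr_config(bootstrap_reps = 100))
  expect_false(fit$available)
  expect_true(is.na(fit$beta))
  # just below the threshold: available
  inst_ok <- make_instruments(sqrt(c(0.45, 0.35, 0.2) * se_y^2), 0.001,
                              c(0.01, 0.02, 0.03), se_y)
  expect_true(weighted_median_mr(inst_ok,
                                 mr_config(bootstrap_reps = 100))$available)
})

test_that("the bootstrap SE is reproducible under a fixed seed and reps", {
  inst <- make_instruments(c(0.04, 0.06, 0.08, 0.05), 0.006,
                           c(-0.01, -0.015, -0.02, -0.008), 0.012)
  cfg <- mr_config(bootstrap_reps = 500, seed = 314)
  f1 <- weighted_median_mr(inst, cfg)
  f2 <- weighted_median_mr(inst, cfg)
  expect_identical(f1$se, f2$se)
  f3 <- weighted_median_mr(inst, mr_config(bootstrap_reps = 500, seed = 315))
  expect_false(identical(f1$se, f3$se))
  # the bootstrap must not disturb the global RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(weighted_median_mr(inst, cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("tied ratios are broken deterministically by rsid", {
  inst <- make_instruments(c(0.05, 0.05, 0.05), 0.005,
                           c(0.01, 0.01, 0.02), 0.01,
                           rsid = c("b", "a", "c"))
  inst_perm <- inst[c(3, 1, 2), ]
  expect_identical(
    weighted_median_mr(inst, mr_config(bootstrap_reps = 100))$beta,
    weighted_median_mr(inst_perm, mr_config(bootstrap_reps = 100))$beta)
})

test_that("rescaling the exposure rescales every pooled estimate inversely", {
  set.seed(21)
  inst <- make_instruments(runif(6, 0.03, 0.09), 0.006,
                           rnorm(6, -0.015, 0.01), runif(6, 0.008, 0.02))
  cfg <- mr_config(bootstrap_reps = 300)
  c_scale <- 2.5
  scaled <- inst
  scaled$beta_x <- inst$beta_x * c_scale
  scaled$se_x <- inst$se_x * c_scale

  expect_equal(ivw_pool(wald_ratios(scaled), cfg)$beta,
               ivw_pool(wald_ratios(inst), cfg)$beta / c_scale,
               tolerance = 1e-10)
  expect_equal(egger_regression(scaled, cfg)$beta,
               egger_regression(inst, cfg)$beta / c_scale,
               tolerance = 1e-10)
  expect_equal(weighted_median_mr(scaled, cfg)$beta,
               weighted_median_mr(inst, cfg)$beta / c_scale,
               tolerance = 1e-10)
})
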