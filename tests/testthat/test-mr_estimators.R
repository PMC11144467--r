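test_that("Wald ratio arithmetic and IVW limit case", {
  h <- make_instruments(beta_exp = 0.5, beta_out = 0.25, se_out = 0.05)
  w <- wald_ratio(h)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(make_instruments(0.5, 0, 0.05))$beta, 0)
  # IVW with a single instrument is the Wald ratio
  iv <- ivw(h)
  expect_equal(iv$beta, w$beta)
  expect_equal(iv$se, w$se)
  expect_error(wald_ratio(make_instruments(0, 0.1, 0.05)), "degenerate")
})

test_that("IVW matches hand arithmetic and is exact on proportional data", {
  # identical ratios -> beta equals the ratio, Q = 0
  h <- make_instruments(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2), rep(0.01, 3))
  iv <- ivw(h)
  expect_equal(iv$beta, 0.5)
  expect_equal(iv$cochran_Q, 0, tolerance = 1e-20)
  # fixed-effect SE oracle: (sum bx^2/se^2)^(-1/2) = 1/sqrt(2100)
  ivf <- ivw(h, variance_model = "fixed")
  expect_equal(ivf$se, 1 / sqrt(2100), tolerance = 1e-12)
  # with Q = 0 the random-effects inflation floors at 1
  expect_equal(iv$se, ivf$se)
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  for (seed in 1:50) {
    set.seed(100 + seed)
    k <- sample(3:30, 1)
    bx <- rnorm(k, 0.1, 0.05)
    sey <- runif(k, 0.01, 0.1)
    by <- 0.3 * bx + rnorm(k, 0, sey)
    h <- make_instruments(bx, by, sey)
    fit <- lm(by ~ bx - 1, weights = 1 / sey^2)
    iv <- ivw(h, variance_model = "fixed")
    expect_equal(iv$beta, unname(coef(fit)), tolerance = 1e-10)
    # lm's SE is sigma-scaled; dividing it out recovers the fixed-effect SE
    s <- summary(fit)
    expect_equal(iv$se, unname(s$coefficients[1, 2] / s$sigma),
                 tolerance = 1e-10)
    # Q equals the weighted residual sum of squares
    expect_equal(iv$cochran_Q, sum((by - coef(fit) * bx)^2 / sey^2),
                 tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers exact linear data and matches a WLS oracle", {
  bx <- c(0.05, 0.1, 0.2, 0.3, 0.45)
  by <- 0.1 + 0.5 * bx
  h <- make_instruments(bx, by, rep(0.02, 5))
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.1, tolerance = 1e-10)
  expect_equal(eg$slope$df_used, 3)

  # random noisy instances vs lm with weights (dispersion > 1 regime,
  # where the floored multiplicative model coincides with lm's scaling)
  for (seed in 1:20) {
    set.seed(200 + seed)
    k <- sample(5:40, 1)
    bx <- abs(rnorm(k, 0.15, 0.05)) + 0.01
    sey <- runif(k, 0.005, 0.02)
    by <- 0.05 + 0.4 * bx + rnorm(k, 0, 5 * sey)   # residual dispersion >> 1
    h <- make_instruments(bx, by, sey)
    eg <- mr_egger(h)
    fit <- summary(lm(by ~ bx, weights = 1 / sey^2))
    expect_equal(eg$intercept$beta, unname(fit$coefficients[1, 1]), tolerance = 1e-8)
    expect_equal(eg$slope$beta, unname(fit$coefficients[2, 1]), tolerance = 1e-8)
    if (fit$sigma > 1) {
      expect_equal(eg$intercept$se, unname(fit$coefficients[1, 2]), tolerance = 1e-8)
      expect_equal(eg$slope$se, unname(fit$coefficients[2, 2]), tolerance = 1e-8)
      expect_equal(eg$slope$pvalue,
                   unname(fit$coefficients[2, 4]), tolerance = 1e-8)
    }
  }
})

test_that("estimators are invariant to jointly flipping instrument signs", {
  set.seed(42)
  k <- 12
  bx <- rnorm(k, 0.1, 0.05)
  sey <- runif(k, 0.01, 0.05)
  by <- 0.3 * bx + rnorm(k, 0, sey)
  h1 <- make_instruments(bx, by, sey)
  flip <- rep(c(1, -1), length.out = k)
  h2 <- make_instruments(bx * flip, by * flip, sey)
  expect_equal(ivw(h2)$beta, ivw(h1)$beta, tolerance = 1e-12)
  expect_equal(ivw(h2)$se, ivw(h1)$se, tolerance = 1e-12)
  e1 <- mr_egger(h1); e2 <- mr_egger(h2)
  expect_equal(e2$slope$beta, e1$slope$beta, tolerance = 1e-12)
  expect_equal(e2$intercept$beta, e1$intercept$beta, tolerance = 1e-12)
  wm1 <- weighted_median(h1, n_boot = 0)
  wm2 <- weighted_median(h2, n_boot = 0)
  expect_equal(wm2$beta, wm1$beta, tolerance = 1e-12)
})

test_that("weighted median interpolates correctly and stays in range", {
  # equal weights, symmetric ratios
  h <- make_instruments(c(1, 1, 1), c(0.4, 0.5, 0.6), rep(1, 3))
  expect_equal(weighted_median(h, n_boot = 0)$beta, 0.5)
  # all ratios equal c -> estimate c, bootstrap SE -> 0 with tiny SEs
  h2 <- make_instruments(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15),
                         rep(1e-8, 3), se_exp = rep(1e-8, 3))
  wm <- weighted_median(h2, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.5, tolerance = 1e-8)
  expect_lt(wm$se, 1e-5)
  # estimate always lies within [min ratio, max ratio]
  for (seed in 1:20) {
    set.seed(300 + seed)
    k <- sample(3:15, 1)
    bx <- rnorm(k, 0.2, 0.1); bx[abs(bx) < 0.01] <- 0.05
    by <- rnorm(k, 0, 0.2)
    sey <- runif(k, 0.01, 0.1)
    est <- weighted_median(make_instruments(bx, by, sey), n_boot = 0)$beta
    ratios <- by / bx
    expect_gte(est, min(ratios))
    expect_lte(est, max(ratios))
  }
})

test_that("sensitivity estimators signal unavailability below 3 instruments", {
  h <- make_instruments(c(0.1, 0.2), c(0.05, 0.1), c(0.01, 0.01))
  eg <- mr_egger(h)
  expect_true(is_unavailable(eg$slope))
  expect_true(is_unavailable(eg$intercept))
  expect_true(is_unavailable(weighted_median(h)))
  expect_false(is_unavailable(ivw(h)))
  # degenerate exposure spread is a hard error, not unavailability
  h3 <- make_instruments(c(0.1, 0.1, 0.1), c(0.05, 0.06, 0.04), rep(0.01, 3))
  expect_error(mr_egger(h3), "degenerate")
})

test_that("Wald p-values follow the declared reference distribution", {
  expect_equal(wald_pvalue(0, 1), 1)
  expect_equal(wald_pvalue(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_pvalue(2, 1, df = 10), 2 * pt(2, 10, lower.tail = FALSE))
  expect_error(wald_pvalue(1, 0), "se")
  # t reference is heavier-tailed than normal at any finite df
  expect_gt(wald_pvalue(2, 1, df = 5), wald_pvalue(2, 1))
})

test_that("odds-ratio conversion respects the lowering convention", {
  e <- ivw(make_instruments(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2), rep(0.01, 3)))
  orr <- to_odds_ratio(e, report_lowering = FALSE)
  orl <- to_odds_ratio(e, report_lowering = TRUE)
  expect_equal(orl$or_point, 1 / orr$or_point, tolerance = 1e-12)
  expect_true(orl$or_low < orl$or_point && orl$or_point < orl$or_high)

  # zero effect -> OR 1, CI symmetric in log space
  e0 <- ivw(make_instruments(c(0.1, 0.2, 0.3), c(0, 0, 0), rep(0.01, 3)))
  or0 <- to_odds_ratio(e0)
  expect_equal(or0$or_point, 1)
  expect_equal(log(or0$or_high), -log(or0$or_low), tolerance = 1e-12)

  # published-style headline: beta = -ln(2.70) on the raising scale with the
  # SE implied by a 1.30-5.63 interval reports OR 2.70 (1.30-5.63) per unit lower
  se <- (log(5.63) - log(1.30)) / (2 * qnorm(0.975))
  est <- structure(list(method = "ivw", beta = -log(2.70), se = se,
                        pvalue = wald_pvalue(log(2.70), se),
                        ci_low = -log(2.70) - 1.96 * se,
                        ci_high = -log(2.70) + 1.96 * se,
                        k = 22L, cochran_Q = NA_real_, df_used = Inf),
                   class = "mr_estimate")
  orp <- to_odds_ratio(est, report_lowering = TRUE)
  expect_equal(orp$or_point, 2.70, tolerance = 1e-6)
  expect_equal(orp$or_low, 1.30, tolerance = 0.01)
  expect_equal(orp$or_high, 5.63, tolerance = 0.02)
})
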