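test_that("omega scales LD by outcome SEs", {
  instr <- instrument_set(c("a", "b"), bx = c(0.2, 0.3), sx = c(0.02, 0.02),
                          by = c(0.01, 0.02), sy = c(0.1, 0.2),
                          ld = matrix(c(1, 0.5, 0.5, 1), 2))
  om <- omega(instr)
  expect_equal(unname(om), matrix(c(0.01, 0.01, 0.01, 0.04), 2))

  # identity LD -> diagonal
  i2 <- instrument_set(c("a", "b"), bx = c(0.2, 0.3), sx = c(0.02, 0.02),
                       by = c(0.01, 0.02), sy = c(0.1, 0.1), ld = diag(2))
  expect_equal(unname(omega(i2)), 0.01 * diag(2))

  set.seed(1)
  instr3 <- random_instrument_set(6)
  om3 <- omega(instr3)
  expect_silent(chol(om3))
  expect_equal(solve(om3) %*% om3, diag(6), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("single-variant fit is the Wald ratio", {
  instr <- instrument_set("a", bx = 0.5, sx = 0.01, by = -0.1, sy = 0.05,
                          ld = matrix(1))
  f <- fit_ivw(instr)
  expect_equal(f$method, "Wald")
  expect_equal(f$slope, -0.2)
  expect_equal(f$slope_se, 0.1)
  expect_true(is.na(f$q_stat))
  expect_equal(f$slope_ci, c(-0.2 - 1.96 * 0.1, -0.2 + 1.96 * 0.1))
})

test_that("identity-LD IVW equals fixed-effect Wald-ratio meta-analysis", {
  for (seed in 1:30) {
    set.seed(seed)
    J <- sample(3:10, 1)
    instr <- random_instrument_set(J, ld = diag(J))
    f <- fit_ivw(instr)
    o <- oracle_wald_meta(instr$bx, instr$by, instr$sy)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$slope_se, o$se, tolerance = 1e-10)
  }
})

test_that("correlated-LD IVW and Egger match the brute-force GLS oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    J <- sample(3:12, 1)
    instr <- random_instrument_set(J)
    fi <- fit_ivw(instr)
    oi <- oracle_ivw(instr)
    expect_equal(fi$slope, oi$slope, tolerance = 1e-10)
    expect_equal(fi$slope_se, oi$se, tolerance = 1e-10)
    expect_equal(fi$q_stat, oi$q, tolerance = 1e-10)

    fe <- fit_egger(instr)
    oe <- oracle_egger(instr)
    expect_equal(fe$slope, oe$slope, tolerance = 1e-10)
    expect_equal(fe$intercept, oe$intercept, tolerance = 1e-10)
    expect_equal(fe$slope_se, oe$slope_se, tolerance = 1e-10)
    expect_equal(fe$intercept_se, oe$intercept_se, tolerance = 1e-10)
    expect_equal(fe$q_stat, oe$q, tolerance = 1e-10)
  }
})

test_that("exact linear data give slope = alpha, zero intercept and zero Q", {
  set.seed(12)
  ld <- random_ld(6)
  bx <- rnorm(6, 0, 0.3)
  instr <- instrument_set(sprintf("v%d", 1:6), bx = bx, sx = rep(0.01, 6),
                          by = 0.35 * bx, sy = runif(6, 0.01, 0.05), ld = ld)
  fi <- fit_ivw(instr)
  expect_equal(fi$slope, 0.35, tolerance = 1e-12)
  expect_equal(fi$q_stat, 0, tolerance = 1e-10)
  fe <- fit_egger(instr)
  expect_equal(fe$slope, 0.35, tolerance = 1e-8)
  expect_equal(fe$intercept, 0, tolerance = 1e-8)
  expect_equal(fe$q_stat, 0, tolerance = 1e-10)
})

test_that("a constant pleiotropy offset loads on the Egger intercept", {
  set.seed(13)
  bx <- abs(rnorm(7, 0.3, 0.1)) # already positively oriented
  instr <- instrument_set(sprintf("v%d", 1:7), bx = bx, sx = rep(0.01, 7),
                          by = 0.02 + 0.4 * bx, sy = runif(7, 0.02, 0.05),
                          ld = diag(7))
  fe <- fit_egger(instr)
  expect_equal(fe$intercept, 0.02, tolerance = 1e-10)
  expect_equal(fe$slope, 0.4, tolerance = 1e-10)
})

test_that("estimators are equivariant under rescaling of bx or by", {
  set.seed(21)
  instr <- random_instrument_set(8)
  f0 <- fit_ivw(instr)
  up <- instr; up$bx <- instr$bx * 2.5
  f1 <- fit_ivw(up)
  expect_equal(f1$slope, f0$slope / 2.5, tolerance = 1e-12)
  expect_equal(f1$slope_se, f0$slope_se / 2.5, tolerance = 1e-12)
  vp <- instr; vp$by <- instr$by * 1.7
  f2 <- fit_ivw(vp)
  expect_equal(f2$slope, f0$slope * 1.7, tolerance = 1e-12)
})

test_that("fits are invariant to allele-orientation flips", {
  for (seed in 1:10) {
    set.seed(seed)
    instr <- random_instrument_set(7)
    flip <- runif(7) < 0.5
    flipped <- flip_orientation(instr, flip)
    f0 <- fit_ivw(instr); f1 <- fit_ivw(flipped)
    expect_equal(f1$slope, f0$slope, tolerance = 1e-10)
    expect_equal(f1$slope_se, f0$slope_se, tolerance = 1e-10)
    expect_equal(f1$q_stat, f0$q_stat, tolerance = 1e-10)
    e0 <- fit_egger(instr); e1 <- fit_egger(flipped)
    expect_equal(e1$slope, e0$slope, tolerance = 1e-10)
    expect_equal(e1$intercept, e0$intercept, tolerance = 1e-10)
    # double flip is the identity
    back <- flip_orientation(flipped, flip)
    expect_equal(back$bx, instr$bx)
    expect_equal(unname(back$ld), unname(instr$ld))
  }
})

test_that("leverage sums to the parameter count and outlier stats decompose Q", {
  for (seed in 1:40) {
    set.seed(seed)
    J <- sample(4:12, 1)
    instr <- random_instrument_set(J)
    for (m in c("ivw", "egger")) {
      lo <- leverage_outliers(instr, m)
      f <- if (m == "ivw") fit_ivw(instr) else fit_egger(instr)
      expect_equal(sum(lo$leverage), if (m == "ivw") 1 else 2, tolerance = 1e-8)
      expect_equal(sum(lo$outlier_stat), f$q_stat, tolerance = 1e-8)
    }
    # Egger never fits worse than IVW
    expect_gte(fit_ivw(instr)$q_stat - fit_egger(instr)$q_stat, -1e-8)
  }
})

test_that("independence closed forms for leverage and outlier statistics hold", {
  set.seed(50)
  J <- 6
  instr <- random_instrument_set(J, ld = diag(J))
  lo <- leverage_outliers(instr, "ivw")
  w <- instr$bx^2 / instr$sy^2
  expect_equal(lo$leverage, w / sum(w), tolerance = 1e-12)
  f <- fit_ivw(instr)
  expect_equal(lo$outlier_stat, (instr$by - f$slope * instr$bx)^2 / instr$sy^2,
               tolerance = 1e-12)

  # equal weights: leverage = 1/J each, 3x mean threshold prunes nothing
  eq <- instrument_set(sprintf("v%d", 1:4), bx = rep(0.3, 4), sx = rep(0.01, 4),
                       by = rnorm(4, 0.06, 0.001), sy = rep(0.02, 4), ld = diag(4))
  lo_eq <- leverage_outliers(eq, "ivw")
  expect_equal(lo_eq$leverage, rep(0.25, 4), tolerance = 1e-12)
  expect_true(all(lo_eq$leverage <= 3 * mean(lo_eq$leverage)))
})

test_that("pruning removes a constructed outlier first and is deterministic", {
  fx <- fixture_suite(2024)
  clean <- sim_instrument_set(fx$clean)
  pr <- prune_instruments(clean, "ivw")
  expect_equal(nrow(pr$log), 0)
  expect_equal(pr$instruments$variant_ids, clean$variant_ids)

  spiked <- sim_instrument_set(fx$outlier_spiked)
  pr2 <- prune_instruments(spiked, "ivw")
  expect_gte(nrow(pr2$log), 1)
  expect_equal(pr2$log$variant_id[1], fx$outlier_spiked$truth$spiked_id)

  pr3 <- prune_instruments(spiked, "ivw")
  expect_identical(pr2$log, pr3$log)
})

test_that("model selection follows the Q-difference rule with strict exceedance", {
  set.seed(61)
  instr <- random_instrument_set(8)
  fi <- fit_ivw(instr)
  fe <- fit_egger(instr)
  # degenerate equality case
  fi0 <- fi; fe0 <- fe
  fe0$q_stat <- fi$q_stat
  ch0 <- select_model(fi0, fe0)
  expect_equal(ch0$q_diff, 0)
  expect_equal(ch0$chosen, "IVW")

  # boundary: q_diff exactly at the 0.95 chi-square(1) quantile -> IVW
  crit <- qchisq(0.95, 1)
  fe1 <- fe; fe1$q_stat <- fi$q_stat - crit
  ch1 <- select_model(fi, fe1)
  expect_equal(ch1$q_diff, crit, tolerance = 1e-12)
  expect_equal(ch1$chosen, "IVW")
  fe2 <- fe; fe2$q_stat <- fi$q_stat - crit - 1e-6
  expect_equal(select_model(fi, fe2)$chosen, "Egger")
  expect_equal(ch1$q_diff_p, pchisq(crit, 1, lower.tail = FALSE), tolerance = 1e-12)

  # mismatched variant sets violate the contract
  other <- random_instrument_set(9)
  expect_error(select_model(fi, fit_egger(other)), "same variant set")
})

test_that("mr_fit front end prunes, fits both models and records the choice", {
  fx <- fixture_suite(77)
  instr <- sim_instrument_set(fx$clean)
  f <- mr_fit(instr)
  expect_s3_class(f, "mr_fit")
  expect_false(is.null(f$model_choice))
  expect_equal(f$method, f$model_choice$chosen)
  # no-prune on clean data gives the identical result
  f2 <- mr_fit(instr, prune = FALSE)
  expect_equal(f2$slope, f$slope)

  fi <- mr_fit(instr, method = "ivw")
  expect_equal(fi$method, "IVW")
  fe <- mr_fit(instr, method = "egger")
  expect_equal(fe$method, "Egger")
})

test_that("degenerate estimator inputs raise contract errors", {
  expect_error(fit_ivw(instrument_set("a", bx = 0, sx = 0.1, by = 0, sy = 0.1,
                                      ld = matrix(1))), "degenerate")
  i2 <- instrument_set(c("a", "b"), bx = c(0.1, 0.2), sx = c(0.1, 0.1),
                       by = c(0, 0), sy = c(0.1, 0.1), ld = diag(2))
  expect_error(fit_egger(i2), "at least 3")
  i3 <- instrument_set(letters[1:3], bx = rep(0.2, 3), sx = rep(0.1, 3),
                       by = rnorm(3), sy = rep(0.1, 3), ld = diag(3))
  expect_error(fit_egger(i3), "collinear")
})

test_that("mr_fit methods expose coefficients, intervals and residuals", {
  set.seed(71)
  instr <- random_instrument_set(6)
  f <- fit_egger(instr)
  expect_named(coef(f), c("intercept", "slope"))
  ci <- confint(f, parm = c("intercept", "slope"))
  expect_equal(unname(ci["slope", ]),
               unname(c(f$slope - qnorm(0.975) * f$slope_se,
                        f$slope + qnorm(0.975) * f$slope_se)))
  r <- residuals(f, type = "whitened")
  expect_equal(sum(r^2), f$q_stat, tolerance = 1e-10)
  expect_output(print(summary(f)), "Coefficients")
  expect_silent({
    pdf(NULL)
    plot(f)
    dev.off()
  })
})
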