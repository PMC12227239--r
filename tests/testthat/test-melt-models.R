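test_that("logistic4 matches direct arithmetic and its asymptotes", {
  # midpoint: at T = tm with plateau 0 the curve is half the top
  expect_equal(logistic4(50, top = 1, plateau = 0, slope = 0.5, tm = 50),
               0.5)
  # independent evaluation of the closed form
  expect_equal(logistic4(54, top = 1, plateau = 0.2, slope = 0.5, tm = 50),
               0.2 + 0.8 / (1 + exp(0.5 * 4)))
  expect_equal(logistic4(-1e6, 1, 0.2, 0.5, 50), 1)
  expect_equal(logistic4(1e6, 1, 0.2, 0.5, 50), 0.2)
  expect_error(logistic4(50, 1, 0, -1, 50), "slope")
})

test_that("fit_melt_curve recovers noiseless generating parameters", {
  temps <- seq(30, 72, length.out = 10)
  y <- logistic4(temps, top = 1, plateau = 0, slope = 0.6, tm = 52)
  fit <- fit_melt_curve(temps, y / y[1])
  expect_equal(fit$flag, "ok")
  expect_equal(fit$tm, 52, tolerance = 1e-3)
  # with a nonzero plateau the half-initial Tm differs from the
  # inflection; both are reported and the half-initial one is the Tm
  y2 <- logistic4(temps, top = 1, plateau = 0.3, slope = 0.6, tm = 52)
  fit2 <- fit_melt_curve(temps, y2)
  expect_equal(unname(fit2$par["tm_infl"]), 52, tolerance = 1e-2)
  expect_gt(fit2$tm, 52)
  half <- logistic4(fit2$tm, fit2$par["top"], fit2$par["plateau"],
                    fit2$par["slope"], fit2$par["tm_infl"])
  expect_equal(unname(half), unname(fit2$fitted[1] / 2), tolerance = 1e-6)
})

test_that("fit_melt_curve flags degenerate and insufficient input", {
  temps <- seq(30, 72, length.out = 10)
  expect_equal(fit_melt_curve(temps, rep(1, 10))$flag, "degenerate")
  expect_equal(fit_melt_curve(temps[1:4], c(1, 0.9, 0.5, 0.1))$flag,
               "insufficient_data")
  fit <- fit_melt_curve(temps, rep(1, 10))
  expect_true(is.na(fit$tm))
})

test_that("melt_fit methods are consistent with the stored fit", {
  temps <- seq(30, 72, length.out = 10)
  set.seed(11)
  y <- logistic4(temps, 1, 0.05, 0.5, 50) * exp(rnorm(10, 0, 0.03))
  fit <- fit_melt_curve(temps, y, protein_id = "P1")
  expect_s3_class(fit, "melt_fit")
  expect_named(coef(fit), c("top", "plateau", "slope", "tm_infl"))
  expect_equal(predict(fit), fit$fitted)
  expect_equal(residuals(fit), y - fit$fitted)
  expect_output(print(fit), "P1")
})

test_that("4PL fitter agrees with the dense grid-search oracle", {
  temps <- seq(30, 72, length.out = 10)
  set.seed(42)
  n_ok <- 0; n_tot <- 30
  for (i in seq_len(n_tot)) {
    tm <- runif(1, 40, 62); sl <- runif(1, 0.3, 1)
    pl <- runif(1, 0, 0.25)
    y <- logistic4(temps, 1, pl, sl, tm) * exp(rnorm(10, 0, 0.05))
    fit <- fit_melt_curve(temps, y)
    orc <- oracle_fit_4pl(temps, y)
    if (is.finite(fit$tm) && is.finite(orc["tm"]) &&
        abs(fit$tm - orc["tm"]) < 0.05) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_tot, 0.99 * 0.9)  # small-sample check; the full
  # 200-profile comparison runs in the acceptance suite
  expect_gte(n_ok, 29)
})

test_that("bootstrap Tm CI follows the PSM-count rule and is seeded", {
  temps <- seq(30, 72, length.out = 10)
  frac <- logistic4(temps, 1, 0, 0.6, 50)
  mk <- function(n, noise) {
    set.seed(99)
    matrix(rep(frac, each = n), nrow = n) *
      matrix(exp(rnorm(n * 10, 0, noise)), nrow = n) * 1e5
  }
  # fewer than eight PSMs: CI withheld
  expect_null(bootstrap_tm_ci(mk(7, 0.1), temps, n_boot = 20, seed = 1))
  # identical PSMs: zero-width interval at the point estimate
  ci0 <- bootstrap_tm_ci(mk(9, 0), temps, n_boot = 20, seed = 1)
  expect_equal(ci0[1], ci0[2], tolerance = 1e-6)
  expect_equal(ci0[1], 50, tolerance = 1e-3)
  ci1 <- bootstrap_tm_ci(mk(9, 0.2), temps, n_boot = 30, seed = 7)
  ci2 <- bootstrap_tm_ci(mk(9, 0.2), temps, n_boot = 30, seed = 7)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], ci1[2])
})

test_that("bootstrap CI covers the true Tm at near-nominal rate", {
  # the percentile bootstrap mildly undercovers at 10 PSMs (long-run
  # coverage ~0.88 for a nominal 0.95); the check is that intervals are
  # calibrated to near-nominal, not degenerate
  temps <- seq(30, 72, length.out = 10)
  frac <- logistic4(temps, 1, 0, 0.6, 50)
  hits <- 0; n_sim <- 40
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    mat <- matrix(rep(frac, each = 10), nrow = 10) *
      matrix(exp(rnorm(100, 0, 0.15)), nrow = 10) * 1e5
    ci <- bootstrap_tm_ci(mat, temps, n_boot = 60, seed = s)
    if (!is.null(ci) && ci[1] <= 50 && 50 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.75)
  expect_lte(hits / n_sim, 1)
})

test_that("mean residue ellipticity follows the normalization formula", {
  expect_equal(mean_residue_ellipticity(0, 0.1, 0.25, 200), 0)
  expect_equal(mean_residue_ellipticity(-5, 0.1, 0.25, 200),
               100 * -5 / (0.1 * 0.25 * 200))
  # doubling the residue count halves the result
  expect_equal(mean_residue_ellipticity(-5, 0.1, 0.25, 400),
               mean_residue_ellipticity(-5, 0.1, 0.25, 200) / 2)
  expect_error(mean_residue_ellipticity(1, 0, 1, 10), "positive")
})

test_that("two-state signal is half-unfolded at Tm and model 2 nests model 1", {
  for (tm in c(40, 55, 70)) for (dH in c(30, 80, 150))
    expect_equal(two_state_signal(tm, tm, dH, model = 1), 0.5)
  tg <- seq(10, 80, by = 5)
  expect_equal(two_state_signal(tg, 48, 90, model = 2,
                                bF = 1, mF = 0, bU = 0, mU = 0),
               two_state_signal(tg, 48, 90, model = 1))
  # independent evaluation of the closed form
  tK <- 322; tmK <- 320; dH <- 100
  f_expected <- 1 / (1 + exp(-dH / 1.987e-3 * (1 / tK - 1 / tmK)))
  expect_equal(two_state_signal(322 - 273.15, 320 - 273.15, 100, model = 1),
               f_expected)
  # monotone decreasing fraction folded
  f <- two_state_signal(seq(0, 90, by = 2), 50, 60, model = 1)
  expect_true(all(diff(f) < 0))
  expect_error(two_state_signal(50, 50, -5), "dH")
})

test_that("fit_two_state recovers parameters and is translation equivariant", {
  tr <- simulate_cd_trace(tm = 48, dH = 75, noise_sd = 0, model = 2,
                          baselines = c(bF = 1, mF = -0.002, bU = 0.1,
                                        mU = 0.001))
  fit <- fit_two_state(tr$temperature, tr$signal, model = 2)
  expect_equal(fit$flag, "ok")
  expect_equal(fit$tm, 48, tolerance = 0.05)
  expect_equal(fit$dH, 75, tolerance = 75 * 0.01)
  # translation: shifting the generating Tm shifts the fitted Tm equally
  tr2 <- simulate_cd_trace(tm = 53, dH = 75, noise_sd = 0, model = 2,
                           baselines = c(bF = 1, mF = -0.002, bU = 0.1,
                                         mU = 0.001))
  fit2 <- fit_two_state(tr2$temperature, tr2$signal, model = 2)
  expect_equal(fit2$tm - fit$tm, 5, tolerance = 0.1)
  # pure noise is flagged
  set.seed(4)
  noise <- rnorm(60)
  fitn <- fit_two_state(seq(4, 63, by = 1), noise, model = 1)
  expect_true(fitn$flag != "ok")
})

test_that("normalize_secondary_structure scales by the minimum", {
  v <- c(-200, -1000, -400)
  nv <- normalize_secondary_structure(v)
  expect_equal(nv[2], 1)
  expect_equal(normalize_secondary_structure(3 * v), nv)
  expect_error(normalize_secondary_structure(c(0, 1)), "zero")
})

test_that("fit_it50 finds the half-maximum temperature", {
  temps <- seq(25, 60, length.out = 12)
  # symmetric curve: IT50 equals the midpoint parameter
  y <- 1 / (1 + 10^(-0.15 * (45 - temps)))
  fit <- fit_it50(temps, y)
  expect_equal(fit$flag, "ok")
  expect_equal(fit$it50, 45, tolerance = 0.01)
  # scale invariance of IT50
  fit_scaled <- fit_it50(temps, 7.3 * y)
  expect_equal(fit_scaled$it50, fit$it50, tolerance = 0.01)
  # asymmetric curve: IT50 equals the numeric root of the generating curve
  g <- function(t) 0.05 + 0.95 / (1 + 10^(-0.12 * (48 - t)))^2
  ya <- g(temps)
  fita <- fit_it50(temps, ya)
  fmax <- max(g(seq(25, 60, length.out = 512)))
  it50_true <- uniroot(function(t) g(t) - fmax / 2, c(25, 60))$root
  expect_equal(fita$it50, it50_true, tolerance = 0.05)
  # constant response: no crossing
  expect_equal(fit_it50(temps, rep(1, 12))$flag %in%
                 c("no_half_crossing", "no_convergence"), TRUE)
  # bootstrap CI is seeded and brackets the estimate
  set.seed(2)
  yn <- y + rnorm(12, 0, 0.02)
  f1 <- fit_it50(temps, yn, n_boot = 40, seed = 5)
  f2 <- fit_it50(temps, yn, n_boot = 40, seed = 5)
  expect_identical(f1$ci, f2$ci)
  expect_true(f1$ci[1] <= f1$it50 && f1$it50 <= f1$ci[2])
})
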