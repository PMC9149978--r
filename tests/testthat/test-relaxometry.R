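# T1 / T2 / rho estimators: exact noiseless recovery, flagged degeneracies,
# noise behaviour against independent oracles, and map-level fitting.

test_that("fit_t1 recovers T1 exactly from noiseless full-model signals", {
  sig <- oracle_tr_series(300, 80, 500, 20, std_tr_grid)
  f <- fit_t1(std_tr_grid, sig, te = 20)
  expect_true(f$valid)
  expect_lt(abs(f$t1 - 300) / 300, 0.001)
  expect_equal(f$c3, 1 / f$t1)
  # C1 is the TR -> Inf plateau rho exp(-TE/T2).
  expect_equal(f$c1, 500 * exp(-20 / 80), tolerance = 1e-6)
  expect_named(coef(f), c("c1", "c2", "c3", "t1"))
})

test_that("fit_t1 rejects degenerate input and flags non-identifiable fits", {
  expect_error(fit_t1(std_tr_grid, rep(5, 8), te = 20),
               class = "pseudoMR_degenerate_fit")
  expect_error(fit_t1(c(100, 100, 200, 300), 1:4, te = 20),
               class = "pseudoMR_structural_error")
  expect_error(fit_t1(std_tr_grid, -oracle_tr_series(300, 80, 500, 20, std_tr_grid),
                      te = 20), class = "pseudoMR_domain_error")
})

test_that("fit_t1 under noise tracks a grid-search least-squares oracle", {
  # Oracle: variable-projection least squares over a fine T1 grid (linear
  # solve for C1, C2 at each candidate T1) — independent of the LM path.
  oracle_fit_t1 <- function(trs, y) {
    t1_grid <- exp(seq(log(30), log(8000), length.out = 400))
    best <- Inf; best_t1 <- NA
    for (t1 in t1_grid) {
      X <- cbind(1, exp(-trs / t1))
      rss <- sum(stats::lm.fit(X, y)$residuals^2)
      if (rss < best) { best <- rss; best_t1 <- t1 }
    }
    best_t1
  }
  clean <- oracle_tr_series(300, 80, 500, 20, std_tr_grid)
  set.seed(41)
  err_lm <- err_or <- numeric(120)
  for (i in seq_along(err_lm)) {
    y <- pmax(clean + rnorm(8, 0, 0.01 * max(clean)), 0)
    err_lm[i] <- abs(fit_t1(std_tr_grid, y, 20)$t1 - 300) / 300
    err_or[i] <- abs(oracle_fit_t1(std_tr_grid, y) - 300) / 300
  }
  # The LM fit should do at least as well as the coarse oracle (small
  # margin for the oracle's grid resolution).
  expect_lt(median(err_lm), median(err_or) * 1.2 + 0.005)
  expect_lt(median(err_lm), 0.05)
})

test_that("fit_t2 is exact on log-linear data and flags bad designs", {
  sig <- 500 * exp(-std_te_grid / 100)
  f <- fit_t2(std_te_grid, sig)
  expect_true(f$valid)
  expect_equal(f$t2, 100, tolerance = 1e-10)
  expect_equal(f$n_used, 9L)

  # Exact line through two distinct points plus a consistent third.
  f2 <- fit_t2(c(10, 110, 60), exp(c(-0.1, -1.1, -0.6)))
  expect_equal(f2$c2, -0.01, tolerance = 1e-12)
  expect_equal(f2$t2, 100, tolerance = 1e-9)

  # Flags, not errors: too few positive points; increasing signals.
  expect_false(fit_t2(c(10, 20, 30), c(5, 0, -1))$valid)
  expect_false(fit_t2(c(10, 20, 30, 40), c(1, 2, 3, 4))$valid)
})

test_that("fit_t2 scale invariance and the full-model bias match closed forms", {
  sig <- 500 * exp(-std_te_grid / 70)
  expect_equal(fit_t2(std_te_grid, sig)$t2,
               fit_t2(std_te_grid, 13.7 * sig)$t2, tolerance = 1e-12)

  # Under the full model the saturation factor depends weakly on TE, so the
  # log-linear estimate is biased; the bias must equal that of a
  # closed-form OLS oracle applied to exact full-model signals.
  t1 <- 400; t2 <- 100; tr <- 2000
  sig_full <- vapply(std_te_grid, function(te)
    oracle_se_signal(t1, t2, 600, te, tr), numeric(1))
  ly <- log(sig_full)
  slope <- sum((std_te_grid - mean(std_te_grid)) * (ly - mean(ly))) /
    sum((std_te_grid - mean(std_te_grid))^2)
  t2_oracle <- -1 / slope
  f <- fit_t2(std_te_grid, sig_full)
  expect_equal(f$t2, t2_oracle, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(t2_oracle, t2, tolerance = 1e-4)))  # bias is real
})

test_that("fit_rho matches the zero-intercept least-squares closed form", {
  # Noiseless self-consistency.
  sig <- oracle_tr_series(520, 95, 750, 20, std_tr_grid)
  f <- fit_rho(std_tr_grid, sig, te = 20, t1 = 520, t2 = 95)
  expect_equal(f$rho, 750, tolerance = 1e-10)

  # All-zero signals give rho = 0.
  expect_equal(fit_rho(std_tr_grid, rep(0, 8), 20, 520, 95)$rho, 0)

  # Hand-computed zero-intercept OLS: rho-hat = sum(A x) / sum(x^2), with
  # x evaluated by the independent oracle and A chosen off the line.
  trs <- c(400, 1000, 3000)
  x <- vapply(trs, function(tr) oracle_se_signal(450, 80, 1, 20, tr), numeric(1))
  A <- c(5, 8, 9.5)
  expect_equal(fit_rho(trs, A, te = 20, t1 = 450, t2 = 80)$rho,
               sum(A * x) / sum(x^2), tolerance = 1e-12)

  # Linearity: scaling the signals scales rho-hat.
  expect_equal(fit_rho(std_tr_grid, 3 * sig, 20, 520, 95)$rho, 3 * 750,
               tolerance = 1e-9)
})

test_that("random tissues are recovered within 0.5% from noiseless series", {
  set.seed(17)
  for (i in 1:30) {
    t1 <- runif(1, 200, 2000); t2 <- runif(1, 40, 300); rho <- runif(1, 100, 1000)
    tr_sig <- oracle_tr_series(t1, t2, rho, 20, std_tr_grid)
    # TE series from the simplified model, under which the log-linear T2
    # estimator is exact (see vignette on the full-model T2 bias).
    te_sig <- rho * (1 - exp(-2000 / t1)) * exp(-std_te_grid / t2)
    f1 <- fit_t1(std_tr_grid, tr_sig, 20)
    f2 <- fit_t2(std_te_grid, te_sig)
    f3 <- fit_rho(std_tr_grid, tr_sig, 20, f1$t1, f2$t2)
    expect_lt(abs(f1$t1 - t1) / t1, 0.005)
    expect_lt(abs(f2$t2 - t2) / t2, 0.005)
    expect_lt(abs(f3$rho - rho) / rho, 0.005)
  }
})

test_that("compute_parameter_maps recovers a noiseless two-tissue phantom", {
  ph <- two_tissue_phantom()
  trs <- simulate_mr_series(ph, data.frame(te = 20, tr = std_tr_grid))
  tes <- simulate_mr_series(ph, data.frame(te = std_te_grid, tr = 2000),
                            signal_model = "simplified")
  maps <- compute_parameter_maps(trs, tes, ph$truth_maps$mask)
  for (v in c("t1", "t2", "rho")) {
    rel <- abs(maps[[v]] - ph$truth_maps[[v]]) / ph$truth_maps[[v]]
    expect_lt(max(rel[maps$mask]), 0.005)
  }
  expect_true(all(c("t1_rms", "t2_rms", "rho_rms") %in% names(maps$fit_quality)))
})

test_that("a single-pixel mask reproduces the scalar fits", {
  ph <- two_tissue_phantom()
  trs <- simulate_mr_series(ph, data.frame(te = 20, tr = std_tr_grid))
  tes <- simulate_mr_series(ph, data.frame(te = std_te_grid, tr = 2000))
  mask1 <- matrix(FALSE, 48, 48); mask1[14, 24] <- TRUE
  maps <- compute_parameter_maps(trs, tes, mask1)
  f1 <- fit_t1(trs$tr, vapply(trs$images, function(im) im[14, 24], numeric(1)), 20)
  f2 <- fit_t2(tes$te, vapply(tes$images, function(im) im[14, 24], numeric(1)))
  f3 <- fit_rho(trs$tr, vapply(trs$images, function(im) im[14, 24], numeric(1)),
                20, f1$t1, f2$t2)
  expect_equal(maps$t1[14, 24], f1$t1)
  expect_equal(maps$t2[14, 24], f2$t2)
  expect_equal(maps$rho[14, 24], f3$rho)
  expect_error(compute_parameter_maps(trs, tes, matrix(FALSE, 48, 48)),
               class = "pseudoMR_structural_error")
})

test_that("noisy map medians stay within a scalar Monte-Carlo tolerance", {
  # Establish the tolerance by Monte-Carlo on the scalar fits at the same
  # noise level, then require the map's per-tissue medians to respect it.
  ph <- two_tissue_phantom()
  noise <- 0.02 * 500
  trs <- simulate_mr_series(ph, data.frame(te = 20, tr = std_tr_grid),
                            noise_sd = noise, seed = 5)
  tes <- simulate_mr_series(ph, data.frame(te = std_te_grid, tr = 2000),
                            noise_sd = noise, seed = 6)
  maps <- suppressMessages(compute_parameter_maps(trs, tes, ph$truth_maps$mask))

  set.seed(9)
  mc <- replicate(60, {
    y <- pmax(oracle_tr_series(300, 60, 500, 20, std_tr_grid) +
                rnorm(8, 0, noise), 0)
    abs(fit_t1(std_tr_grid, y, 20)$t1 - 300) / 300
  })
  tol_med <- 3 * median(mc) + 0.02  # generous band around the scalar MC error
  sel <- ph$label_map == 1 & maps$mask
  expect_lt(abs(median(maps$t1[sel]) - 300) / 300, tol_med)
  sel2 <- ph$label_map == 2 & maps$mask
  expect_lt(abs(median(maps$t1[sel2]) - 900) / 900, tol_med)
})
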