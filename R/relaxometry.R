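# Per-pixel estimation of T1, T2 and proton density from spin-echo series.
#
# The variable-TR series at fixed TE follows A(TR) = C1 + C2 exp(-TR/T1)
# exactly under the full spin-echo model; (C1, C2, T1) are found by
# Levenberg-Marquardt nonlinear least squares. The variable-TE series at
# fixed TR is log-linearised, ln A = C1 + C2 TE with T2 = -1/C2, which is
# exact under the TE << TR simplification. Proton density is the
# zero-intercept least-squares slope of signal on the fully specified
# saturation-decay factor.

#' Fit T1 from a variable-TR spin-echo series
#'
#' Fits \eqn{A(TR) = C_1 + C_2 e^{-TR/T_1}} to one pixel's signals by
#' Levenberg-Marquardt nonlinear least squares. Initialisation:
#' `C1 = max(signal)`, `C2 = min - max`, and T1 seeded by log-linearising
#' `C1 - A` against TR; T1 is bounded to `[1, 20000]` ms. A fit that fails
#' to converge is returned with `valid = FALSE` rather than raising, so
#' map-level fitting can flag and drop the pixel.
#'
#' @param tr_values Repetition times, ms; >= 4 distinct values.
#' @param signals Non-negative signal amplitudes, parallel to `tr_values`.
#' @param te Echo time of the series, ms (metadata; the TE dependence is
#'   absorbed by C1 and C2).
#' @param max_iter Maximum LM iterations.
#' @return Object of class `t1_fit`: `c1`, `c2`, `c3` (= 1/T1, 1/ms), `t1`
#'   (ms), `residual_rms`, `valid`, `status`.
#' @examples
#' tr <- c(100, 200, 400, 800, 1250, 2000, 4000, 5000)
#' sig <- sapply(tr, function(r)
#'   spin_echo_signal(tissue_params(300, 80, 500), seq_params(20, r)))
#' fit_t1(tr, sig, te = 20)
#' @export
fit_t1 <- function(tr_values, signals, te, max_iter = 200) {
  check_finite(tr_values, "tr_values"); check_finite(signals, "signals")
  if (length(tr_values) != length(signals))
    pmr_error("tr_values and signals lengths differ", "pseudoMR_structural_error")
  if (length(unique(tr_values)) < 4L)
    pmr_error("T1 fit needs >= 4 distinct TR values", "pseudoMR_structural_error")
  if (any(signals < 0))
    pmr_error("signals must be non-negative", "pseudoMR_domain_error")
  if (diff(range(signals)) == 0)
    pmr_error("constant signal series: T1 unidentifiable", "pseudoMR_degenerate_fit")

  o <- order(tr_values)
  tr <- tr_values[o]; y <- signals[o]

  c1_0 <- max(y)
  c2_0 <- min(y) - max(y)
  # Log-linearise C1 - A ~ |C2| exp(-TR/T1) for a T1 starting value.
  d <- c1_0 - y
  pos <- d > max(d) * 1e-8
  t1_0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(d[pos]) ~ tr[pos]))[2]
    if (is.finite(sl) && sl < 0) min(max(-1 / sl, 1), 20000) else mean(range(tr))
  } else mean(range(tr))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ C1 + C2 * exp(-tr / T1),
      start = list(C1 = c1_0, C2 = c2_0, T1 = t1_0),
      lower = c(-Inf, -Inf, 1), upper = c(Inf, Inf, 20000),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    res <- list(c1 = NA_real_, c2 = NA_real_, c3 = NA_real_, t1 = NA_real_,
                residual_rms = NA_real_, valid = FALSE,
                status = conditionMessage(fit))
    return(structure(res, class = "t1_fit"))
  }
  cf <- stats::coef(fit)
  t1 <- unname(cf[["T1"]])
  rms <- sqrt(mean(stats::residuals(fit)^2))
  valid <- is.finite(t1) && t1 > 0
  structure(list(c1 = unname(cf[["C1"]]), c2 = unname(cf[["C2"]]),
                 c3 = 1 / t1, t1 = t1, residual_rms = rms,
                 valid = valid, status = if (valid) "converged" else "invalid T1"),
            class = "t1_fit")
}

#' @export
print.t1_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("T1 fit: T1 = %.4g ms (C1 = %.4g, C2 = %.4g, C3 = %.3g /ms), residual RMS %.3g\n",
                x$t1, x$c1, x$c2, x$c3, x$residual_rms))
  else cat("T1 fit: invalid (", x$status, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.t1_fit <- function(object, ...) {
  c(c1 = object$c1, c2 = object$c2, c3 = object$c3, t1 = object$t1)
}

#' Fit T2 from a variable-TE spin-echo series
#'
#' Ordinary least squares of \eqn{\ln A} on TE over the points with
#' strictly positive signal; \eqn{T_2 = -1/\mathrm{slope}}. Exact under the
#' TE << TR simplified signal model; under the full model the saturation
#' factor's weak TE dependence biases T2 slightly low for long T1 (see the
#' methods vignette). Fewer than 3 usable points or a non-negative slope
#' yield `valid = FALSE` flags rather than errors.
#'
#' @param te_values Echo times, ms.
#' @param signals Signal amplitudes, parallel to `te_values`.
#' @return Object of class `t2_fit`: `c1` (log-signal intercept), `c2`
#'   (slope, 1/ms; T2 = -1/c2), `t2` (ms), `residual_rms` (log-signal
#'   units), `n_used`, `valid`, `status`.
#' @export
fit_t2 <- function(te_values, signals) {
  check_finite(te_values, "te_values"); check_finite(signals, "signals")
  if (length(te_values) != length(signals))
    pmr_error("te_values and signals lengths differ", "pseudoMR_structural_error")
  keep <- signals > 0
  bad <- function(status) structure(
    list(c1 = NA_real_, c2 = NA_real_, t2 = NA_real_, residual_rms = NA_real_,
         n_used = sum(keep), valid = FALSE, status = status), class = "t2_fit")
  if (sum(keep) < 3L) return(bad("fewer than 3 positive signals"))
  te <- te_values[keep]; ly <- log(signals[keep])
  if (length(unique(te)) < 2L) return(bad("degenerate TE design"))
  fit <- stats::lm(ly ~ te)
  cf <- stats::coef(fit)
  if (!is.finite(cf[2]) || cf[2] >= 0) return(bad("non-negative log-slope: invalid T2"))
  structure(list(c1 = unname(cf[1]), c2 = unname(cf[2]), t2 = -1 / unname(cf[2]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_used = sum(keep), valid = TRUE, status = "ok"),
            class = "t2_fit")
}

#' @export
print.t2_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("T2 fit: T2 = %.4g ms (slope %.3g /ms, %d points), residual RMS %.3g\n",
                x$t2, x$c2, x$n_used, x$residual_rms))
  else cat("T2 fit: invalid (", x$status, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.t2_fit <- function(object, ...) {
  c(c1 = object$c1, c2 = object$c2, t2 = object$t2)
}

#' Fit proton density given T1 and T2
#'
#' With T1 and T2 known, the full spin-echo model is linear through the
#' origin in rho: \eqn{A_i = \rho x_i} with
#' \eqn{x_i = (1 - 2e^{-(TR_i - TE/2)/T_1} + e^{-TR_i/T_1})e^{-TE/T_2}}.
#' Returns the zero-intercept least-squares slope
#' \eqn{\hat\rho = \sum A_i x_i / \sum x_i^2}.
#'
#' @param tr_values Repetition times of the series, ms.
#' @param signals Signal amplitudes, parallel to `tr_values`.
#' @param te Echo time of the series, ms.
#' @param t1,t2 Previously estimated relaxation times, ms.
#' @return Object of class `rho_fit`: `rho`, `residual_rms`, `valid`, `status`.
#' @export
fit_rho <- function(tr_values, signals, te, t1, t2) {
  check_finite(tr_values, "tr_values"); check_finite(signals, "signals")
  check_finite(te, "te"); check_finite(t1, "t1"); check_finite(t2, "t2")
  if (length(tr_values) != length(signals))
    pmr_error("tr_values and signals lengths differ", "pseudoMR_structural_error")
  if (!length(tr_values))
    pmr_error("rho fit needs >= 1 point", "pseudoMR_structural_error")
  if (t1 <= 0 || t2 <= 0)
    pmr_error("t1 and t2 must be positive", "pseudoMR_domain_error")
  x <- se_signal_kernel(t1, t2, 1, te, tr_values)
  sxx <- sum(x^2)
  if (sxx == 0)
    pmr_error("degenerate design: all saturation factors zero", "pseudoMR_degenerate_fit")
  rho <- sum(signals * x) / sxx
  rms <- sqrt(mean((signals - rho * x)^2))
  valid <- is.finite(rho) && rho >= 0
  structure(list(rho = rho, residual_rms = rms, valid = valid,
                 status = if (valid) "ok" else "negative rho"),
            class = "rho_fit")
}

#' @export
print.rho_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("rho fit: rho = %.4g a.u., residual RMS %.3g\n", x$rho, x$residual_rms))
  else cat("rho fit: invalid (", x$status, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.rho_fit <- function(object, ...) c(rho = object$rho)

#' Estimate T1/T2/rho maps from two spin-echo series
#'
#' Runs [fit_t1()], [fit_t2()] and [fit_rho()] at every masked pixel: T1
#' from the variable-TR series, T2 from the variable-TE series, then rho
#' from the variable-TR series using the fitted T1/T2. Pixels where any fit
#' fails (non-convergence, invalid T2 slope, negative rho, degenerate
#' signals) are dropped from the output mask; the count of dropped pixels
#' is reported via `message()`. The returned maps carry `fit_quality`
#' residual grids (`t1_rms`, `t2_rms` in log-signal units, `rho_rms`).
#'
#' @param tr_series [acquisition_series()] of kind `variable_tr`.
#' @param te_series [acquisition_series()] of kind `variable_te`.
#' @param mask Logical matrix of pixels to fit; must match the series shape.
#' @return [parameter_maps()] whose mask excludes failed pixels.
#' @export
compute_parameter_maps <- function(tr_series, te_series, mask) {
  if (!inherits(tr_series, "acquisition_series") || tr_series$kind != "variable_tr")
    pmr_error("tr_series must be an acquisition_series of kind 'variable_tr'",
              "pseudoMR_structural_error")
  if (!inherits(te_series, "acquisition_series") || te_series$kind != "variable_te")
    pmr_error("te_series must be an acquisition_series of kind 'variable_te'",
              "pseudoMR_structural_error")
  if (!is.matrix(mask)) pmr_error("mask must be a matrix", "pseudoMR_structural_error")
  check_same_dim(mask, tr_series$images[[1]], "mask vs tr_series")
  check_same_dim(mask, te_series$images[[1]], "mask vs te_series")
  mask <- mask & !is.na(mask)
  idx <- which(mask)
  if (!length(idx)) pmr_error("empty mask", "pseudoMR_structural_error")

  d <- dim(mask)
  t1m <- t2m <- rhom <- matrix(NA_real_, d[1], d[2])
  q1 <- q2 <- q3 <- matrix(NA_real_, d[1], d[2])
  ok <- matrix(FALSE, d[1], d[2])
  te_fixed <- tr_series$te[1]

  # Pull each series into a pixels x images matrix once; per-pixel loops
  # then index rows.
  tr_sig <- vapply(tr_series$images, function(im) im[idx], numeric(length(idx)))
  te_sig <- vapply(te_series$images, function(im) im[idx], numeric(length(idx)))
  if (length(idx) == 1L) { tr_sig <- matrix(tr_sig, 1); te_sig <- matrix(te_sig, 1) }

  n_fail <- 0L
  for (j in seq_along(idx)) {
    p <- idx[j]
    f1 <- tryCatch(fit_t1(tr_series$tr, pmax(tr_sig[j, ], 0), te = te_fixed),
                   pseudoMR_error = function(e) NULL)
    f2 <- tryCatch(fit_t2(te_series$te, te_sig[j, ]),
                   pseudoMR_error = function(e) NULL)
    good <- !is.null(f1) && !is.null(f2) && f1$valid && f2$valid
    if (good) {
      f3 <- tryCatch(fit_rho(tr_series$tr, tr_sig[j, ], te = te_fixed,
                             t1 = f1$t1, t2 = f2$t2),
                     pseudoMR_error = function(e) NULL)
      good <- !is.null(f3) && f3$valid
    }
    if (good) {
      ok[p] <- TRUE
      t1m[p] <- f1$t1; t2m[p] <- f2$t2; rhom[p] <- f3$rho
      q1[p] <- f1$residual_rms; q2[p] <- f2$residual_rms; q3[p] <- f3$residual_rms
    } else n_fail <- n_fail + 1L
  }
  if (n_fail) message(sprintf("compute_parameter_maps: %d of %d pixels failed to fit and were masked out",
                              n_fail, length(idx)))
  if (!any(ok)) pmr_error("all pixels failed to fit", "pseudoMR_degenerate_fit")
  parameter_maps(t1m, t2m, rhom, ok,
                 fit_quality = list(t1_rms = q1, t2_rms = q2, rho_rms = q3))
}
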