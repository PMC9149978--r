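#' Per-pixel intrinsic parameter maps
#'
#' Container for co-registered T1, T2 and proton-density maps over a masked
#' region. Values must be finite and positive (rho >= 0) wherever the mask
#' is TRUE; pixels outside the mask are stored as NA.
#'
#' @param t1,t2,rho Numeric matrices of a common shape (ms, ms, a.u.).
#' @param mask Logical matrix of the same shape marking valid pixels.
#' @param fit_quality Optional named list of per-pixel residual grids
#'   (e.g. `t1_rms`, `t2_rms`, `rho_rms`), each matching the map shape.
#' @return An object of class `parameter_maps`.
#' @export
parameter_maps <- function(t1, t2, rho, mask, fit_quality = NULL) {
  if (!is.matrix(t1) || !is.matrix(t2) || !is.matrix(rho) || !is.matrix(mask))
    pmr_error("maps and mask must be matrices", "pseudoMR_structural_error")
  check_same_dim(t1, mask, "t1 vs mask")
  check_same_dim(t2, mask, "t2 vs mask")
  check_same_dim(rho, mask, "rho vs mask")
  mask <- mask & !is.na(mask)
  storage.mode(mask) <- "logical"
  inm <- which(mask)
  if (length(inm)) {
    if (any(!is.finite(t1[inm])) || any(t1[inm] <= 0) ||
        any(!is.finite(t2[inm])) || any(t2[inm] <= 0) ||
        any(!is.finite(rho[inm])) || any(rho[inm] < 0))
      pmr_error("in-mask map values must be finite with t1, t2 > 0 and rho >= 0",
                "pseudoMR_domain_error")
  }
  t1[!mask] <- NA_real_; t2[!mask] <- NA_real_; rho[!mask] <- NA_real_
  if (!is.null(fit_quality)) {
    stopifnot(is.list(fit_quality))
    for (g in fit_quality) check_same_dim(g, mask, "fit_quality vs mask")
  }
  structure(list(t1 = t1, t2 = t2, rho = rho, mask = mask,
                 fit_quality = fit_quality),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("Parameter maps: %d x %d grid, %d masked pixels\n",
              nrow(x$mask), ncol(x$mask), n))
  if (n) {
    f <- function(v) sprintf("median %.4g [%.4g, %.4g]",
                             median(v, na.rm = TRUE),
                             min(v, na.rm = TRUE), max(v, na.rm = TRUE))
    cat("  T1  (ms):  ", f(x$t1), "\n")
    cat("  T2  (ms):  ", f(x$t2), "\n")
    cat("  rho (a.u.):", f(x$rho), "\n")
  }
  invisible(x)
}

#' @export
summary.parameter_maps <- function(object, ...) {
  v <- function(m) summary(m[object$mask])
  out <- rbind(T1 = v(object$t1), T2 = v(object$t2), rho = v(object$rho))
  structure(list(stats = out, n = sum(object$mask), dim = dim(object$mask)),
            class = "summary.parameter_maps")
}

#' @export
print.summary.parameter_maps <- function(x, ...) {
  cat(sprintf("Parameter maps over %d pixels (%d x %d grid)\n",
              x$n, x$dim[1], x$dim[2]))
  print(x$stats)
  invisible(x)
}

#' @export
plot.parameter_maps <- function(x, which = c("t1", "t2", "rho"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  lab <- c(t1 = "T1 (ms)", t2 = "T2 (ms)", rho = "rho (a.u.)")
  for (w in which) {
    m <- x[[w]]
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                    main = lab[[w]], useRaster = TRUE, ...)
  }
  invisible(x)
}
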