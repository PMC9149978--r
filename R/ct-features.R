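# Windowed CT-number statistics. A raw CT number does not identify tissue
# (different tissues overlap in HU), so each pixel is characterised by the
# mean and standard deviation of the CT numbers in a small centred window —
# two local-texture features that together separate tissues far better
# than intensity alone.

#' Windowed CT-number mean and standard deviation maps
#'
#' For every in-mask pixel, computes the mean (mu) and sample standard
#' deviation (sigma, n-1 denominator) of the CT numbers over the in-mask
#' pixels inside a centred `window_size` x `window_size` window. Only
#' in-mask neighbours contribute, so statistics near the region boundary
#' are not contaminated by surrounding tissue; pixels with fewer than
#' `min_count` in-mask neighbours are dropped from the output mask.
#'
#' @param ct Numeric matrix of CT numbers (HU).
#' @param mask Logical matrix of the region of interest.
#' @param window_size Odd window side length >= 3 (default 5).
#' @param min_count Minimum in-mask window pixels to keep a pixel (default 6;
#'   sigma needs at least 2).
#' @return Object of class `ct_features`: matrices `mu`, `sigma`, `n`
#'   (in-mask window counts), logical `mask` (pixels retained), and
#'   `window_size`.
#' @export
ct_window_features <- function(ct, mask, window_size = 5, min_count = 6) {
  if (!is.matrix(ct) || !is.matrix(mask))
    pmr_error("ct and mask must be matrices", "pseudoMR_structural_error")
  check_same_dim(ct, mask, "ct vs mask")
  if (window_size < 3 || window_size %% 2 != 1)
    pmr_error("window_size must be an odd integer >= 3", "pseudoMR_domain_error")
  if (min_count < 2) pmr_error("min_count must be >= 2 (sd needs 2 points)",
                               "pseudoMR_domain_error")
  mask <- mask & !is.na(mask)
  if (!any(mask)) pmr_error("empty mask", "pseudoMR_structural_error")
  check_finite(ct[mask], "ct (in-mask)")

  half <- (window_size - 1L) / 2L
  w <- mask + 0
  cw <- ct * w
  n <- window_sum(w, half)
  s1 <- window_sum(cw, half)
  s2 <- window_sum(cw * ct, half)

  keep <- mask & n >= min_count
  if (!any(keep)) pmr_error("all pixels dropped by min_count", "pseudoMR_empty_feature")

  mu <- sg <- matrix(NA_real_, nrow(ct), ncol(ct))
  mu[keep] <- s1[keep] / n[keep]
  ssq <- pmax(s2[keep] - s1[keep]^2 / n[keep], 0)  # guard tiny negatives
  sg[keep] <- sqrt(ssq / (n[keep] - 1))
  nm <- matrix(NA_real_, nrow(ct), ncol(ct)); nm[keep] <- n[keep]
  structure(list(mu = mu, sigma = sg, n = nm, mask = keep,
                 window_size = as.integer(window_size)),
            class = "ct_features")
}

#' @export
print.ct_features <- function(x, ...) {
  cat(sprintf("CT window features (%d x %d window): %d pixels\n",
              x$window_size, x$window_size, sum(x$mask)))
  cat(sprintf("  mu    (HU): %.4g .. %.4g\n",
              min(x$mu, na.rm = TRUE), max(x$mu, na.rm = TRUE)))
  cat(sprintf("  sigma (HU): %.4g .. %.4g\n",
              min(x$sigma, na.rm = TRUE), max(x$sigma, na.rm = TRUE)))
  invisible(x)
}
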