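# Similarity metrics between real and synthetic image regions: the slope of
# the least-squares line relating the two region vectors, and the
# percentage root-mean-square difference (PRD).

#' Extract a masked region as a vector
#'
#' Deterministic row-major extraction (rows scanned left to right, top row
#' first) of in-mask pixel values, so real/synthetic regions extracted with
#' the same mask are element-wise comparable.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same shape; must select >= 1 pixel.
#' @return Numeric vector of in-mask values in row-major order.
#' @export
region_to_vector <- function(image, mask) {
  if (!is.matrix(image) || !is.matrix(mask))
    pmr_error("image and mask must be matrices", "pseudoMR_structural_error")
  check_same_dim(image, mask, "image vs mask")
  mask <- mask & !is.na(mask)
  if (!any(mask)) pmr_error("empty mask", "pseudoMR_structural_error")
  flatten_row_major(image)[flatten_row_major(mask)]
}

#' Regression slope between real and synthetic vectors
#'
#' Ordinary least-squares fit of the synthetic values (dependent) on the
#' real values (independent), with intercept. A slope of 1 and intercept of
#' 0 indicate identical signals up to noise; a slope of k with zero
#' intercept indicates a pure scale difference of k.
#'
#' @param real,synthetic Equal-length numeric vectors, n >= 2.
#' @return List with `slope` and `intercept`.
#' @export
similarity_slope <- function(real, synthetic) {
  check_finite(real, "real"); check_finite(synthetic, "synthetic")
  if (length(real) != length(synthetic) || length(real) < 2L)
    pmr_error("need equal-length vectors with n >= 2", "pseudoMR_structural_error")
  if (diff(range(real)) == 0)
    pmr_error("real vector is constant: slope undefined", "pseudoMR_degenerate_fit")
  cf <- stats::coef(stats::lm(synthetic ~ real))
  list(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Percentage root-mean-square difference
#'
#' \deqn{PRD = 100\sqrt{\sum_i (real_i - synthetic_i)^2 / \sum_i real_i^2}.}
#' 0 for identical vectors; invariant to scaling both vectors together.
#' With `normalization = "scale"` the synthetic vector is first multiplied
#' by the least-squares scale factor
#' \eqn{\sum real_i\,synthetic_i / \sum synthetic_i^2}, removing any global
#' gain difference (e.g. unknown receiver amplification) before comparison.
#'
#' @param real,synthetic Equal-length numeric vectors; `real` not all zero.
#' @param normalization `"none"` (default) or `"scale"`.
#' @return PRD in percent.
#' @export
prd <- function(real, synthetic, normalization = c("none", "scale")) {
  normalization <- match.arg(normalization)
  check_finite(real, "real"); check_finite(synthetic, "synthetic")
  if (length(real) != length(synthetic))
    pmr_error("vectors must have equal length", "pseudoMR_structural_error")
  if (sum(real^2) == 0)
    pmr_error("all-zero real vector: PRD undefined", "pseudoMR_degenerate_fit")
  if (normalization == "scale") {
    s2 <- sum(synthetic^2)
    if (s2 > 0) synthetic <- synthetic * sum(real * synthetic) / s2
  }
  100 * sqrt(sum((real - synthetic)^2) / sum(real^2))
}

#' Slope + PRD similarity report for two masked images
#'
#' Convenience wrapper: extracts both regions with [region_to_vector()] and
#' computes [similarity_slope()] and [prd()].
#'
#' @param real_image,synthetic_image Numeric matrices of one shape.
#' @param mask Logical matrix selecting the compared region.
#' @param normalization Passed to [prd()].
#' @return Object of class `similarity_report`: `slope`, `intercept`,
#'   `prd` (percent), `n`, `normalization`.
#' @export
compare_regions <- function(real_image, synthetic_image, mask,
                            normalization = c("none", "scale")) {
  normalization <- match.arg(normalization)
  r <- region_to_vector(real_image, mask)
  s <- region_to_vector(synthetic_image, mask)
  sl <- similarity_slope(r, s)
  structure(list(slope = sl$slope, intercept = sl$intercept,
                 prd = prd(r, s, normalization), n = length(r),
                 normalization = normalization),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("Similarity over %d pixels%s:\n", x$n,
              if (x$normalization == "scale") " (scale-normalized PRD)" else ""))
  cat(sprintf("  slope = %.4g, intercept = %.4g, PRD = %.3g%%\n",
              x$slope, x$intercept, x$prd))
  invisible(x)
}
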