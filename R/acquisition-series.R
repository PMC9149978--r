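#' Ordered spin-echo acquisition series
#'
#' A set of co-registered same-shape images each tagged with its TE/TR. Two
#' calibrated kinds are recognised: `variable_tr` (TE fixed, TR varied; used
#' for T1 and rho estimation; needs >= 4 images) and `variable_te` (TR
#' fixed, TE varied; used for T2 estimation; needs >= 3 images). `custom`
#' holds any sequence list (e.g. weighted-image reference acquisitions)
#' without the fitting-series constraints. Images are sorted by the varying
#' parameter; duplicates of the varying parameter are rejected and the
#' fixed parameter must agree across the series to within `fixed_tol`.
#'
#' @param images List of numeric matrices sharing one shape.
#' @param te,tr Numeric vectors parallel to `images`, ms.
#' @param kind `"variable_tr"`, `"variable_te"`, or `"custom"`.
#' @param fixed_tol Tolerance (ms) for equality of the fixed parameter.
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(images, te, tr,
                               kind = c("variable_tr", "variable_te", "custom"),
                               fixed_tol = 1e-6) {
  kind <- match.arg(kind)
  if (!is.list(images) || !length(images) || !all(vapply(images, is.matrix, TRUE)))
    pmr_error("'images' must be a non-empty list of matrices", "pseudoMR_structural_error")
  if (length(te) != length(images) || length(tr) != length(images))
    pmr_error("te and tr must parallel 'images'", "pseudoMR_structural_error")
  d <- dim(images[[1]])
  for (im in images) check_same_dim(im, images[[1]], "series images")
  mapply(function(e, r) seq_params(e, r), te, tr)  # per-image validity

  if (kind != "custom") {
    varying <- if (kind == "variable_tr") tr else te
    fixed <- if (kind == "variable_tr") te else tr
    need <- if (kind == "variable_tr") 4L else 3L
    if (length(images) < need)
      pmr_error(sprintf("%s series needs >= %d images", kind, need),
                "pseudoMR_structural_error")
    if (diff(range(fixed)) > fixed_tol)
      pmr_error(sprintf("fixed parameter varies by more than %g ms across %s series",
                        fixed_tol, kind), "pseudoMR_structural_error")
    if (anyDuplicated(varying))
      pmr_error("duplicate values of the varying parameter", "pseudoMR_structural_error")
    o <- order(varying)
    images <- images[o]; te <- te[o]; tr <- tr[o]
  }
  structure(list(images = images, te = te, tr = tr, kind = kind, dim = d),
            class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  cat(sprintf("Acquisition series (%s): %d images of %d x %d\n",
              x$kind, length(x$images), x$dim[1], x$dim[2]))
  cat("  TE (ms):", paste(signif(x$te, 4), collapse = ", "), "\n")
  cat("  TR (ms):", paste(signif(x$tr, 4), collapse = ", "), "\n")
  invisible(x)
}

# Signals of one pixel across a series, in series order.
series_pixel <- function(series, idx) {
  vapply(series$images, function(im) im[idx], numeric(1))
}
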