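# Readers/writers and series manifests. Supported formats: NIfTI-1
# (read/write, via RNifti), delimited text grids (read/write), PNG masks
# (read/write, 0/255). Pixel-coordinate convention throughout the package:
# matrices indexed [row, col], 1-based, pixel-centre; vectorised regions
# are row-major.

image_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else if (grepl("\\.png$", low)) "png"
  else if (grepl("\\.(txt|tsv|csv|dat)$", low)) "text"
  else pmr_error(sprintf("cannot infer image format from '%s' (expect .nii[.gz], .png, .txt/.tsv/.csv)",
                         path), "pseudoMR_format_error")
}

#' Read a 2D image
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`), delimited text (`.txt`/`.tsv`:
#' tab-separated; `.csv`: comma-separated) or PNG (first channel, scaled to
#' 0..255) into a numeric matrix. The format is inferred from the
#' extension unless given.
#'
#' @param path Input file.
#' @param format `"auto"` (default), `"nifti"`, `"text"`, or `"png"`.
#' @return Numeric matrix; NIfTI pixel spacing, when present, is attached
#'   as attribute `pixdim`.
#' @export
read_image <- function(path, format = "auto") {
  if (!file.exists(path))
    pmr_error(sprintf("file not found: %s", path), "pseudoMR_format_error")
  fmt <- if (identical(format, "auto")) image_format(path) else format
  out <- switch(fmt,
    nifti = {
      v <- RNifti::readNifti(path)
      m <- as.matrix(drop(as.array(v)))
      if (length(dim(m)) != 2L)
        pmr_error("expected a single 2D slice", "pseudoMR_format_error")
      attr(m, "pixdim") <- RNifti::pixdim(v)[1:2]
      m
    },
    text = {
      sep <- if (grepl("\\.csv$", tolower(path))) "," else "\t"
      as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    },
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1]
      a * 255
    },
    pmr_error(sprintf("unsupported format '%s'", fmt), "pseudoMR_format_error"))
  if (anyNA(out) || any(!is.finite(out)))
    pmr_error("image contains non-finite values", "pseudoMR_format_error")
  dimnames(out) <- NULL
  out
}

#' Write a 2D image
#'
#' Counterpart of [read_image()]. NIfTI volumes are written as 32-bit
#' float; text grids keep full double precision; PNG expects values in
#' 0..255 (masks: 0/255).
#'
#' @param image Numeric matrix.
#' @param path Output file; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!is.matrix(image)) pmr_error("image must be a matrix", "pseudoMR_structural_error")
  fmt <- image_format(path)
  switch(fmt,
    nifti = RNifti::writeNifti(RNifti::asNifti(image, datatype = "float"), path),
    text = {
      sep <- if (grepl("\\.csv$", tolower(path))) "," else "\t"
      # %.17g keeps every double bit-exact through the text round trip.
      chr <- matrix(sprintf("%.17g", image), nrow(image), ncol(image))
      utils::write.table(chr, path, sep = sep, row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    },
    png = png::writePNG(pmin(pmax(image / 255, 0), 1), path))
  invisible(path)
}

#' Write a binary mask as PNG (0/255)
#' @param mask Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_image((mask & !is.na(mask)) * 255, path)
}

#' Apply the DICOM-style HU rescale
#'
#' CT pixel data are stored as unsigned integers and converted to
#' Hounsfield units with the affine rescale `HU = slope * stored +
#' intercept` carried in the acquisition metadata.
#'
#' @param stored Stored pixel values.
#' @param slope Rescale slope (default 1).
#' @param intercept Rescale intercept (default -1024).
#' @return CT numbers in HU.
#' @export
apply_hu_rescale <- function(stored, slope = 1, intercept = -1024) {
  check_finite(stored, "stored")
  slope * stored + intercept
}

#' Write parameter maps as delimited text grids
#'
#' Emits `<prefix>_t1.tsv`, `<prefix>_t2.tsv`, `<prefix>_rho.tsv` and
#' `<prefix>_mask.tsv` (0/1).
#'
#' @param maps [parameter_maps()].
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_parameter_maps <- function(maps, prefix) {
  if (!inherits(maps, "parameter_maps"))
    pmr_error("'maps' must be parameter_maps", "pseudoMR_structural_error")
  paths <- paste0(prefix, "_", c("t1", "t2", "rho", "mask"), ".tsv")
  z <- function(m) { m[is.na(m)] <- 0; m }
  write_image(z(maps$t1), paths[1])
  write_image(z(maps$t2), paths[2])
  write_image(z(maps$rho), paths[3])
  write_image(maps$mask * 1, paths[4])
  invisible(paths)
}

#' Read parameter maps written by [write_parameter_maps()]
#' @param prefix Path prefix used at write time.
#' @return [parameter_maps()].
#' @export
read_parameter_maps <- function(prefix) {
  paths <- paste0(prefix, "_", c("t1", "t2", "rho", "mask"), ".tsv")
  mask <- read_image(paths[4]) > 0
  parameter_maps(read_image(paths[1]), read_image(paths[2]),
                 read_image(paths[3]), mask)
}

#' Read a spin-echo series manifest
#'
#' A manifest is a JSON file listing the images of one acquisition session:
#' `{"slice_id": ..., "entries": [{"path": ..., "te_ms": ..., "tr_ms": ...,
#' "role": "t1_series"|"t2_series"|"reference"|"ct"}, ...]}`. Paths are
#' resolved relative to the manifest's directory. Role consistency is
#' validated: `t1_series` entries must share one TE, `t2_series` entries
#' one TR.
#'
#' @param path Manifest JSON file.
#' @return List with `slice_id` and data frame `entries` (absolute paths).
#' @export
read_series_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(man$entries) || !nrow(as.data.frame(man$entries)))
    pmr_error("manifest has no entries", "pseudoMR_format_error")
  e <- as.data.frame(man$entries)
  need <- c("path", "te_ms", "tr_ms", "role")
  if (!all(need %in% names(e)))
    pmr_error(sprintf("manifest entries need fields: %s", paste(need, collapse = ", ")),
              "pseudoMR_format_error")
  e$path <- ifelse(grepl("^/", e$path), e$path,
                   file.path(dirname(normalizePath(path)), e$path))
  missing <- !file.exists(e$path)
  if (any(missing))
    pmr_error(sprintf("manifest paths missing: %s",
                      paste(basename(e$path[missing]), collapse = ", ")),
              "pseudoMR_format_error")
  t1e <- e[e$role == "t1_series", ]
  if (nrow(t1e) && length(unique(t1e$te_ms)) != 1L)
    pmr_error("t1_series entries must share one TE", "pseudoMR_format_error")
  t2e <- e[e$role == "t2_series", ]
  if (nrow(t2e) && length(unique(t2e$tr_ms)) != 1L)
    pmr_error("t2_series entries must share one TR", "pseudoMR_format_error")
  list(slice_id = man$slice_id, entries = e)
}

#' Load an acquisition series from a manifest role
#'
#' @param manifest Output of [read_series_manifest()].
#' @param role `"t1_series"` (variable TR) or `"t2_series"` (variable TE).
#' @return [acquisition_series()].
#' @export
load_acquisition_series <- function(manifest, role = c("t1_series", "t2_series")) {
  role <- match.arg(role)
  e <- manifest$entries[manifest$entries$role == role, ]
  if (!nrow(e)) pmr_error(sprintf("no '%s' entries in manifest", role),
                          "pseudoMR_format_error")
  images <- lapply(e$path, read_image)
  acquisition_series(images, te = e$te_ms, tr = e$tr_ms,
                     kind = if (role == "t1_series") "variable_tr" else "variable_te")
}

#' Write a series manifest
#'
#' @param entries Data frame with `path`, `te_ms`, `tr_ms`, `role`.
#' @param slice_id Identifier string.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_series_manifest <- function(entries, slice_id, path) {
  jsonlite::write_json(list(slice_id = slice_id, entries = entries), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
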