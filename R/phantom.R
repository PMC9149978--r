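# Digital tri-modality phantom: a 2D slice of tissue-mimicking inserts with
# known (T1, T2, rho, HU mean, HU texture sd) per tissue, from which
# co-registered CT acquisitions and spin-echo MR series are simulated.
# This is the package's ground-truth test harness: every tissue parameter
# is known exactly, so estimator bias and end-to-end mapping fidelity can
# be measured.

#' Specify one phantom tissue insert
#'
#' @param label Tissue name.
#' @param geometry Placement rule in pixel coordinates (row/col, 1-based,
#'   pixel-centre): `list(type = "ellipse", center = c(r, c), radii = c(a, b))`
#'   or `list(type = "rect", center = c(r, c), half = c(hr, hc))`.
#' @param t1,t2 Relaxation times, ms (> 0).
#' @param rho Proton density, arbitrary units (>= 0).
#' @param hu_mean Mean CT number, HU.
#' @param hu_texture_sd Within-tissue CT heterogeneity (sd of the smoothed
#'   texture field), HU (>= 0).
#' @return Object of class `tissue_spec`.
#' @export
tissue_spec <- function(label, geometry, t1, t2, rho, hu_mean, hu_texture_sd) {
  tissue_params(t1, t2, rho)  # validates
  check_finite(hu_mean, "hu_mean"); check_finite(hu_texture_sd, "hu_texture_sd")
  if (hu_texture_sd < 0) pmr_error("hu_texture_sd must be >= 0", "pseudoMR_domain_error")
  if (!is.list(geometry) || is.null(geometry$type) ||
      !geometry$type %in% c("ellipse", "rect"))
    pmr_error("geometry must be list(type = 'ellipse'|'rect', ...)", "pseudoMR_spec_error")
  structure(list(label = label, geometry = geometry, t1 = t1, t2 = t2,
                 rho = rho, hu_mean = hu_mean, hu_texture_sd = hu_texture_sd),
            class = "tissue_spec")
}

#' Default multi-tissue abdominal phantom specification
#'
#' Five soft-tissue inserts with literature-plausible 1.5 T abdominal
#' values. Liver and spleen deliberately overlap in mean HU (both around
#' 50-55 HU) but differ strongly in texture sd, so raw intensity cannot
#' separate them while windowed (mu, sigma) features can — the premise of
#' the mapping model. The tissue set is chosen so that every pair is
#' separable in the (mu, sigma) plane given the sampling noise of 5 x 5
#' window statistics (mu-hat sd is sigma/5, sigma-hat sd is roughly
#' sigma/7); tissues close in mean HU are far apart in texture sd and vice
#' versa. Geometries are disjoint blobs on an air background.
#'
#' @param shape Grid dimensions `c(rows, cols)` used to scale placements.
#' @param layout `"a"` (default) or `"b"`: two different non-overlapping
#'   arrangements of the same tissue set, for train-on-A / test-on-B
#'   experiments.
#' @return List of [tissue_spec()] objects.
#' @export
default_tissue_specs <- function(shape = c(128, 128), layout = c("a", "b")) {
  layout <- match.arg(layout)
  r <- shape[1]; c <- shape[2]
  at <- function(fr, fc) c(round(fr * r), round(fc * c))
  sz <- function(fa, fb) c(round(fa * r), round(fb * c))
  pos <- if (layout == "a") {
    list(liver  = list(at(0.30, 0.30), sz(0.20, 0.22)),
         spleen = list(at(0.30, 0.75), sz(0.13, 0.13)),
         fat    = list(at(0.72, 0.22), sz(0.12, 0.14)),
         cyst   = list(at(0.66, 0.58), sz(0.08, 0.08)),
         kidney = list(at(0.78, 0.82), sz(0.11, 0.10)))
  } else {
    list(liver  = list(at(0.62, 0.66), sz(0.22, 0.20)),
         spleen = list(at(0.70, 0.20), sz(0.12, 0.14)),
         fat    = list(at(0.26, 0.74), sz(0.13, 0.12)),
         cyst   = list(at(0.22, 0.40), sz(0.09, 0.07)),
         kidney = list(at(0.38, 0.14), sz(0.10, 0.11)))
  }
  ell <- function(name, t1, t2, rho, hu, tex)
    tissue_spec(name, list(type = "ellipse", center = pos[[name]][[1]],
                           radii = pos[[name]][[2]]),
                t1, t2, rho, hu, tex)
  list(
    ell("liver",  t1 = 580,  t2 = 45,  rho = 700, hu = 55,   tex = 6),
    ell("spleen", t1 = 1050, t2 = 80,  rho = 750, hu = 50,   tex = 22),
    ell("fat",    t1 = 260,  t2 = 85,  rho = 900, hu = -100, tex = 8),
    ell("cyst",   t1 = 1400, t2 = 180, rho = 850, hu = 15,   tex = 4),
    ell("kidney", t1 = 690,  t2 = 55,  rho = 720, hu = 35,   tex = 10)
  )
}

geometry_mask <- function(geom, shape) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  if (geom$type == "ellipse") {
    ((rr - geom$center[1]) / geom$radii[1])^2 +
      ((cc - geom$center[2]) / geom$radii[2])^2 <= 1
  } else {
    abs(rr - geom$center[1]) <= geom$half[1] & abs(cc - geom$center[2]) <= geom$half[2]
  }
}

#' Build a digital phantom slice with known ground truth
#'
#' Rasterises the tissue geometries onto a grid (geometries may not
#' overlap), assigns each tissue its true T1/T2/rho, and lays down a
#' noiseless CT image: per-tissue mean HU plus a seeded, spatially smoothed
#' zero-mean texture field standardised within each tissue to exactly the
#' tissue's `hu_texture_sd`. Spatial smoothing (Gaussian, sd
#' `texture_correlation` pixels) gives the texture a finite correlation
#' length so that small windows see the tissue-characteristic sigma — the
#' premise that makes local CT statistics informative about tissue
#' identity. Background pixels take `background_hu`.
#'
#' @param specs List of [tissue_spec()]; geometries must be disjoint.
#' @param shape Grid dimensions, each >= 32 (default 128 x 128).
#' @param texture_correlation Gaussian smoothing sd of the texture field,
#'   pixels (default 0.5). Must stay well below the feature window size:
#'   correlation lengths approaching the window scale shrink the effective
#'   number of independent samples per window, so the windowed sd both
#'   under-measures the tissue sd and disperses widely around it.
#' @param background_hu HU outside all tissues (default -1000, air).
#' @param seed RNG seed; output is deterministic given the seed.
#' @return Object of class `phantom_slice`: `label_map` (integer matrix,
#'   0 = background), `labels` (tissue names), `truth_maps`
#'   ([parameter_maps()]), `truth_ct` (noiseless HU matrix), `shape`, `seed`.
#' @export
make_phantom <- function(specs, shape = c(128, 128), texture_correlation = 0.5,
                         background_hu = -1000, seed = 1) {
  if (any(shape < 32)) pmr_error("shape must be at least 32 x 32", "pseudoMR_spec_error")
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "tissue_spec")))
    pmr_error("'specs' must be a list of tissue_spec objects", "pseudoMR_spec_error")
  label_map <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(specs)) {
    g <- geometry_mask(specs[[i]]$geometry, shape)
    if (any(label_map[g] != 0L))
      pmr_error(sprintf("geometry of tissue '%s' overlaps an earlier tissue",
                        specs[[i]]$label), "pseudoMR_spec_error")
    label_map[g] <- i
  }
  t1 <- t2 <- rho <- matrix(NA_real_, shape[1], shape[2])
  truth_ct <- matrix(background_hu, shape[1], shape[2])
  texture <- with_seed(seed, {
    raw <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    if (texture_correlation > 0) EBImage::gblur(raw, sigma = texture_correlation)
    else raw
  })
  texture <- matrix(as.numeric(texture), shape[1], shape[2])
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    in_t <- label_map == i
    t1[in_t] <- s$t1; t2[in_t] <- s$t2; rho[in_t] <- s$rho
    tex <- texture[in_t]
    # Standardise within tissue: zero mean, exactly the requested sd.
    if (s$hu_texture_sd > 0 && sum(in_t) >= 2 && stats::sd(tex) > 0)
      tex <- (tex - mean(tex)) / stats::sd(tex) * s$hu_texture_sd
    else tex <- rep(0, sum(in_t))
    truth_ct[in_t] <- s$hu_mean + tex
  }
  mask <- label_map > 0L
  structure(list(label_map = label_map,
                 labels = vapply(specs, `[[`, "", "label"),
                 truth_maps = parameter_maps(t1, t2, rho, mask),
                 truth_ct = truth_ct, shape = shape, seed = seed),
            class = "phantom_slice")
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat(sprintf("Digital phantom slice: %d x %d, %d tissues, seed %d\n",
              x$shape[1], x$shape[2], length(x$labels), x$seed))
  for (i in seq_along(x$labels))
    cat(sprintf("  %-8s %5d px\n", x$labels[i], sum(x$label_map == i)))
  invisible(x)
}

#' Simulate a repeated-acquisition CT scan of a phantom
#'
#' Each repeat is the noiseless CT plus independent zero-mean Gaussian
#' noise; the returned image is the pixel-wise mean over repeats, which
#' reduces the residual noise sd by a factor of sqrt(n_repeats) — the
#' standard multiple-acquisition averaging used to raise CT SNR before
#' feature extraction.
#'
#' @param phantom A [make_phantom()] slice.
#' @param noise_sd Per-acquisition noise sd, HU (>= 0).
#' @param n_repeats Number of repeated acquisitions (default 9).
#' @param seed RNG seed.
#' @return List of class `ct_acquisition`: `average` (matrix) and `repeats`
#'   (array `shape x n_repeats`).
#' @export
simulate_ct <- function(phantom, noise_sd = 5, n_repeats = 9, seed = 1) {
  if (!inherits(phantom, "phantom_slice"))
    pmr_error("'phantom' must come from make_phantom()", "pseudoMR_structural_error")
  if (noise_sd < 0 || n_repeats < 1)
    pmr_error("need noise_sd >= 0 and n_repeats >= 1", "pseudoMR_domain_error")
  d <- phantom$shape
  reps <- with_seed(seed, {
    array(rep(phantom$truth_ct, n_repeats) +
            stats::rnorm(prod(d) * n_repeats, 0, noise_sd),
          dim = c(d, n_repeats))
  })
  avg <- apply(reps, c(1, 2), mean)
  structure(list(average = avg, repeats = reps, noise_sd = noise_sd,
                 n_repeats = n_repeats), class = "ct_acquisition")
}

#' Simulate a spin-echo MR image series of a phantom
#'
#' Evaluates the spin-echo forward model on the phantom's true parameter
#' maps for each requested (TE, TR) and adds seeded noise. Gaussian noise
#' is additive on the signal; Rician noise is the magnitude of the signal
#' plus a complex Gaussian (the magnitude-reconstruction noise model, which
#' biases low-signal pixels upward).
#'
#' @param phantom A [make_phantom()] slice.
#' @param seq_list Data frame with columns `te`, `tr` (ms), or a list of
#'   [seq_params()].
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param noise_sd Noise sd in signal units (>= 0).
#' @param seed RNG seed.
#' @param signal_model `"full"` (default) or `"simplified"` forward model.
#' @return [acquisition_series()]; kind auto-detected (`variable_tr`,
#'   `variable_te`, or `custom`).
#' @export
simulate_mr_series <- function(phantom, seq_list,
                               noise_model = c("gaussian", "rician"),
                               noise_sd = 0, seed = 1,
                               signal_model = c("full", "simplified")) {
  noise_model <- match.arg(noise_model)
  signal_model <- match.arg(signal_model)
  if (!inherits(phantom, "phantom_slice"))
    pmr_error("'phantom' must come from make_phantom()", "pseudoMR_structural_error")
  if (noise_sd < 0) pmr_error("noise_sd must be >= 0", "pseudoMR_domain_error")
  if (is.data.frame(seq_list)) {
    te <- seq_list$te; tr <- seq_list$tr
  } else {
    te <- vapply(seq_list, function(s) as_seq(s)$te, numeric(1))
    tr <- vapply(seq_list, function(s) as_seq(s)$tr, numeric(1))
  }
  kind <- if (length(te) >= 4 && length(unique(te)) == 1L && !anyDuplicated(tr))
    "variable_tr"
  else if (length(te) >= 3 && length(unique(tr)) == 1L && !anyDuplicated(te))
    "variable_te"
  else "custom"

  images <- with_seed(seed, {
    lapply(seq_along(te), function(i) {
      clean <- synthesize_weighted_image(phantom$truth_maps,
                                         seq_params(te[i], tr[i]),
                                         simplified = signal_model == "simplified")
      if (noise_sd == 0) return(clean)
      d <- dim(clean)
      if (noise_model == "gaussian") {
        clean + matrix(stats::rnorm(prod(d), 0, noise_sd), d[1], d[2])
      } else {
        re <- clean + matrix(stats::rnorm(prod(d), 0, noise_sd), d[1], d[2])
        im <- matrix(stats::rnorm(prod(d), 0, noise_sd), d[1], d[2])
        sqrt(re^2 + im^2)
      }
    })
  })
  acquisition_series(images, te, tr, kind = kind)
}
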