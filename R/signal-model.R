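#' Acquisition contrast parameters for one spin-echo image
#'
#' Bundles the echo time and repetition time of a spin-echo acquisition and
#' validates the physical constraints `0 < TE < TR`. All times in the
#' package are milliseconds.
#'
#' @param te Echo time in ms.
#' @param tr Repetition time in ms.
#' @return An object of class `seq_params`: a list with elements `te`, `tr`.
#' @examples
#' seq_params(te = 20, tr = 2000)
#' @export
seq_params <- function(te, tr) {
  check_finite(te, "te"); check_finite(tr, "tr")
  if (length(te) != 1L || length(tr) != 1L)
    pmr_error("te and tr must be scalars", "pseudoMR_domain_error")
  if (te <= 0 || tr <= 0 || te >= tr)
    pmr_error("require 0 < te < tr (ms)", "pseudoMR_domain_error")
  structure(list(te = te, tr = tr), class = "seq_params")
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf("Spin-echo sequence: TE = %g ms, TR = %g ms\n", x$te, x$tr))
  invisible(x)
}

#' Intrinsic tissue contrast parameters
#'
#' T1 and T2 relaxation times (ms) and proton density (arbitrary units;
#' scanner gain is an unknown constant scale, so no absolute calibration is
#' attempted). Components may be vectors of a common length.
#'
#' @param t1 Longitudinal relaxation time(s), ms, > 0.
#' @param t2 Transverse relaxation time(s), ms, > 0.
#' @param rho Proton density value(s), arbitrary units, >= 0.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(t1, t2, rho) {
  check_finite(t1, "t1"); check_finite(t2, "t2"); check_finite(rho, "rho")
  if (any(t1 <= 0) || any(t2 <= 0))
    pmr_error("t1 and t2 must be positive", "pseudoMR_domain_error")
  if (any(rho < 0))
    pmr_error("rho must be non-negative", "pseudoMR_domain_error")
  n <- max(length(t1), length(t2), length(rho))
  structure(list(t1 = rep_len(t1, n), t2 = rep_len(t2, n), rho = rep_len(rho, n)),
            class = "tissue_params")
}

as_tissue <- function(tissue) {
  if (inherits(tissue, "tissue_params")) return(tissue)
  if (is.list(tissue) && all(c("t1", "t2", "rho") %in% names(tissue)))
    return(tissue_params(tissue$t1, tissue$t2, tissue$rho))
  pmr_error("'tissue' must be tissue_params() or a list with t1, t2, rho",
            "pseudoMR_domain_error")
}

as_seq <- function(seq) {
  if (inherits(seq, "seq_params")) return(seq)
  if (is.list(seq) && all(c("te", "tr") %in% names(seq)))
    return(seq_params(seq$te, seq$tr))
  pmr_error("'seq' must be seq_params() or a list with te, tr",
            "pseudoMR_domain_error")
}

# Vectorised kernel of the steady-state spin-echo amplitude:
#   rho * (1 - 2 exp(-(TR - TE/2)/T1) + exp(-TR/T1)) * exp(-TE/T2)
se_signal_kernel <- function(t1, t2, rho, te, tr) {
  rho * (1 - 2 * exp(-(tr - te / 2) / t1) + exp(-tr / t1)) * exp(-te / t2)
}

#' Steady-state spin-echo signal amplitude
#'
#' Forward model of the spin-echo sequence: the echo amplitude for tissue
#' with relaxation times T1, T2 and proton density rho acquired at echo time
#' TE and repetition time TR is
#' \deqn{A = \rho\,(1 - 2e^{-(TR-TE/2)/T1} + e^{-TR/T1})\,e^{-TE/T2}.}
#' The saturation factor can be negative when TR is short relative to T1;
#' magnitude-reconstructed MR images are non-negative, so by default the
#' signal is clamped at zero from below. Set `clamp = FALSE` for the signed
#' value.
#'
#' @param tissue [tissue_params()] (components may be vectors).
#' @param seq [seq_params()].
#' @param clamp Clamp negative amplitudes to 0 (magnitude mode, default).
#' @return Numeric signal amplitude(s), arbitrary units.
#' @examples
#' spin_echo_signal(tissue_params(500, 100, 1000), seq_params(20, 2000))
#' @seealso [spin_echo_signal_simplified()] for the TE << TR approximation.
#' @export
spin_echo_signal <- function(tissue, seq, clamp = TRUE) {
  tissue <- as_tissue(tissue); seq <- as_seq(seq)
  s <- se_signal_kernel(tissue$t1, tissue$t2, tissue$rho, seq$te, seq$tr)
  if (clamp) pmax(s, 0) else s
}

#' Simplified spin-echo signal (TE << TR)
#'
#' Approximation of [spin_echo_signal()] valid when the echo time is small
#' relative to the repetition time:
#' \deqn{A = \rho\,(1 - e^{-TR/T1})\,e^{-TE/T2}.}
#' This is the model underlying the log-linear T2 estimator.
#'
#' @inheritParams spin_echo_signal
#' @return Numeric signal amplitude(s).
#' @export
spin_echo_signal_simplified <- function(tissue, seq) {
  tissue <- as_tissue(tissue); seq <- as_seq(seq)
  tissue$rho * (1 - exp(-seq$tr / tissue$t1)) * exp(-seq$te / tissue$t2)
}

#' Synthesize a weighted spin-echo image from parameter maps
#'
#' Applies the spin-echo forward model pixel-wise to T1/T2/rho maps at the
#' requested TE/TR; the choice of TE and TR sets the weighting (short
#' TE/short TR: T1-weighted; long TE/long TR: T2-weighted; short TE/long
#' TR: proton-density-weighted). Pixels outside the map mask are set to 0.
#'
#' @param maps [parameter_maps()].
#' @param seq [seq_params()].
#' @param clamp Clamp negative amplitudes (default TRUE).
#' @param simplified Use the TE << TR approximation instead of the full
#'   model (default FALSE).
#' @return Numeric matrix with the shape of the maps.
#' @export
synthesize_weighted_image <- function(maps, seq, clamp = TRUE, simplified = FALSE) {
  if (!inherits(maps, "parameter_maps"))
    pmr_error("'maps' must be a parameter_maps object", "pseudoMR_structural_error")
  seq <- as_seq(seq)
  out <- matrix(0, nrow(maps$mask), ncol(maps$mask))
  idx <- which(maps$mask)
  if (length(idx)) {
    tis <- tissue_params(maps$t1[idx], maps$t2[idx], maps$rho[idx])
    out[idx] <- if (simplified) spin_echo_signal_simplified(tis, seq)
                else spin_echo_signal(tis, seq, clamp = clamp)
  }
  out
}
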