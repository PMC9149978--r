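# Internal helpers shared across modules.

#' @importFrom stats rnorm runif quantile median coef lm optimize sd
NULL

pmr_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pseudoMR_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Run code with a temporary RNG seed
#'
#' Seeds the RNG locally and restores the caller's RNG state on exit, so
#' every stochastic operation in the package is reproducible from an
#' explicit per-call seed without touching global state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Scalar/vector finiteness check with a uniform error message.
check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    pmr_error(sprintf("'%s' must be finite numeric", name), "pseudoMR_domain_error")
  invisible(x)
}

check_same_dim <- function(a, b, what) {
  if (!identical(dim(a), dim(b)))
    pmr_error(sprintf("shape mismatch: %s", what), "pseudoMR_structural_error")
  invisible(NULL)
}

# Shifted copy of a matrix: entry [i, j] <- m[i + dr, j + dc], zero-filled
# outside. Used for exact (non-FFT) moving-window sums.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) + dr
  src_c <- seq_len(nc) + dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Sum of m over a centred (2h+1)x(2h+1) window at every pixel, exact
# arithmetic (no FFT), zero outside the image.
window_sum <- function(m, half) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -half:half)
    for (dc in -half:half)
      acc <- acc + shift_matrix(m, dr, dc)
  acc
}

# Row-major flattening helpers: R matrices are column-major, the package's
# documented vector order is row-major (rows scanned left-to-right, top row
# first).
flatten_row_major <- function(m) as.vector(t(m))
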