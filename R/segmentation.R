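# Intensity-based fuzzy C-means segmentation of a CT slice, used to extract
# the organ region before relaxometry and mapping. Implemented in-package
# because the pipeline needs a recorded per-iteration objective trace,
# seeded quantile initialisation and full determinism.

#' Fuzzy C-means segmentation of an image
#'
#' Alternating optimisation of the fuzzy C-means objective
#' \deqn{J = \sum_i \sum_k u_{ik}^m (x_i - c_k)^2}
#' over memberships u and centroids c, on pixel intensity alone. Centroids
#' are initialised at evenly spaced intensity quantiles jittered by the
#' seeded RNG, which makes the result deterministic given `seed`. Iteration
#' stops when the largest centroid shift falls below `tol` or after
#' `max_iter` sweeps; the objective value of every sweep is recorded.
#'
#' @param image Numeric matrix of intensities (e.g. CT numbers, HU).
#' @param n_clusters Number of clusters k >= 2; must not exceed the number
#'   of distinct intensities.
#' @param m Fuzziness exponent > 1 (default 2, standard practice).
#' @param tol Convergence threshold on the maximum centroid shift (default 1e-5).
#' @param max_iter Maximum sweeps (default 300).
#' @param seed RNG seed for the centroid jitter (default 1).
#' @return Object of class `fcm_partition`: `memberships` (pixels x k, rows
#'   sum to 1), `centroids`, `labels` (matrix of hard assignments by
#'   maximum membership), `objective` (trace, one value per sweep),
#'   `fuzziness_m`, `iterations`, `converged`, `dim`.
#' @export
fcm_segment <- function(image, n_clusters, m = 2, tol = 1e-5, max_iter = 300,
                        seed = 1) {
  if (!is.matrix(image)) pmr_error("image must be a matrix", "pseudoMR_structural_error")
  check_finite(as.vector(image), "image")
  if (n_clusters < 2) pmr_error("n_clusters must be >= 2", "pseudoMR_domain_error")
  if (m <= 1) pmr_error("fuzziness m must be > 1", "pseudoMR_domain_error")
  x <- as.vector(image)
  ux <- unique(x)
  if (length(ux) < n_clusters)
    pmr_error("n_clusters exceeds the number of distinct intensities",
              "pseudoMR_degenerate_cluster")

  # Quantile initialisation with a small seeded jitter to break ties
  # between equal quantiles on coarsely quantised images.
  p <- (seq_len(n_clusters) - 0.5) / n_clusters
  cen <- as.numeric(stats::quantile(x, p, names = FALSE))
  span <- diff(range(x))
  cen <- with_seed(seed, cen + stats::runif(n_clusters, -1, 1) * 1e-3 * span)

  expo <- 2 / (m - 1)
  n <- length(x)
  obj <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, cen, function(a, b) (a - b)^2)
    # Membership update: u_ik = d_ik^{-1/(m-1)} normalised over clusters;
    # pixels coincident with a centroid get crisp membership there.
    zero <- d2 < .Machine$double.xmin
    w <- d2^(-expo / 2)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      w[hit, ] <- 0
      w[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    u <- w / rowSums(w)
    um <- u^m
    obj <- c(obj, sum(um * d2))
    cen_new <- colSums(um * x) / colSums(um)
    shift <- max(abs(cen_new - cen))
    cen <- cen_new
    if (shift < tol) { converged <- TRUE; break }
  }
  labels <- matrix(max.col(u, ties.method = "first"), nrow(image), ncol(image))
  structure(list(memberships = u, centroids = cen, labels = labels,
                 objective = obj, fuzziness_m = m, iterations = length(obj),
                 converged = converged, dim = dim(image)),
            class = "fcm_partition")
}

#' @export
print.fcm_partition <- function(x, ...) {
  cat(sprintf("Fuzzy C-means partition: %d clusters, m = %g, %d iterations%s\n",
              length(x$centroids), x$fuzziness_m, x$iterations,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  cat("  centroids:", paste(signif(sort(x$centroids), 5), collapse = ", "), "\n")
  cat(sprintf("  final objective: %.6g\n", x$objective[length(x$objective)]))
  invisible(x)
}

#' Extract a binary region mask from a fuzzy partition
#'
#' Selects one cluster of an [fcm_segment()] partition and returns the mask
#' of pixels hard-assigned to it. The target organ cluster must be chosen
#' by the user (by centroid rank, explicit index, or a seed pixel known to
#' lie inside the organ). Optionally keeps only the largest 4-connected
#' component, removing speckle.
#'
#' @param partition An `fcm_partition`.
#' @param rule Cluster selection: `"highest"`/`"lowest"` (centroid rank), an
#'   integer cluster index, or `list(seed_pixel = c(row, col))`.
#' @param largest_component Keep only the largest 4-connected component.
#' @return Logical matrix.
#' @export
extract_region_mask <- function(partition, rule = "highest",
                                largest_component = FALSE) {
  if (!inherits(partition, "fcm_partition"))
    pmr_error("'partition' must come from fcm_segment()", "pseudoMR_structural_error")
  k <- length(partition$centroids)
  sel <- if (identical(rule, "highest")) which.max(partition$centroids)
  else if (identical(rule, "lowest")) which.min(partition$centroids)
  else if (is.numeric(rule) && length(rule) == 1L) as.integer(rule)
  else if (is.list(rule) && !is.null(rule$seed_pixel)) {
    px <- rule$seed_pixel
    if (length(px) != 2L || any(px < 1) || px[1] > partition$dim[1] ||
        px[2] > partition$dim[2])
      pmr_error("seed_pixel out of bounds", "pseudoMR_structural_error")
    partition$labels[px[1], px[2]]
  } else pmr_error("unrecognised selection rule", "pseudoMR_structural_error")
  if (is.na(sel) || sel < 1L || sel > k)
    pmr_error(sprintf("cluster index %s out of range 1..%d", sel, k),
              "pseudoMR_structural_error")
  mask <- partition$labels == sel
  if (!any(mask)) pmr_error("selected cluster is empty", "pseudoMR_empty_mask")
  if (largest_component) {
    lab <- EBImage::bwlabel(mask + 0)
    areas <- tabulate(lab[lab > 0])
    mask <- lab == which.max(areas)
  }
  mask
}
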