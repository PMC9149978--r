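# The CT -> MR translation model: three scattered-data surfaces over the
# (mu, sigma) feature plane, one per intrinsic parameter (T1, T2, rho).
# Surfaces are either Delaunay-triangulation piecewise-linear interpolants
# or nearest-neighbour lookups; queries outside the training convex hull
# fall back to the nearest training point (or are dropped).

mapping_key <- function(mu, sigma) sprintf("%.17g|%.17g", mu, sigma)

#' Fit the CT-to-MR parameter mapping model
#'
#' Learns the three mapping surfaces (mu, sigma) -> T1, T2, rho from the
#' windowed CT features and the fitted parameter maps of a training slice.
#' Duplicate (mu, sigma) feature pairs are first aggregated by averaging
#' their parameter values (an interpolant needs single-valued nodes; local
#' CT statistics genuinely map one-to-many onto tissue parameters).
#' `mode = "piecewise_linear"` builds Delaunay-triangulation-based linear
#' interpolants over the feature plane; `mode = "nearest"` uses
#' nearest-neighbour lookup. Both modes reproduce the aggregated training
#' value exactly at every training point.
#'
#' @param features [ct_window_features()] output of the training CT slice.
#' @param maps [parameter_maps()] fitted from the co-registered MR series.
#' @param mode `"piecewise_linear"` (default) or `"nearest"`.
#' @param fallback Handling of queries outside the convex hull of the
#'   training features in piecewise-linear mode: `"nearest"` (default) or
#'   `"drop"` (mark invalid).
#' @return Object of class `ct_mapping` with a `training` data frame
#'   (`mu`, `sigma`, `t1`, `t2`, `rho`), `mode`, `fallback`, `n_raw`
#'   (pixel count before aggregation), `provenance`.
#' @seealso [predict.ct_mapping()], [apply_mapping()], [write_mapping()].
#' @export
build_mapping <- function(features, maps,
                          mode = c("piecewise_linear", "nearest"),
                          fallback = c("nearest", "drop")) {
  mode <- match.arg(mode); fallback <- match.arg(fallback)
  if (!inherits(features, "ct_features"))
    pmr_error("'features' must come from ct_window_features()", "pseudoMR_structural_error")
  if (!inherits(maps, "parameter_maps"))
    pmr_error("'maps' must be a parameter_maps object", "pseudoMR_structural_error")
  check_same_dim(features$mask, maps$mask, "features vs maps")
  shared <- features$mask & maps$mask
  if (!any(shared)) pmr_error("features and maps share no masked pixels",
                              "pseudoMR_structural_error")
  idx <- which(shared)
  df <- data.frame(mu = features$mu[idx], sigma = features$sigma[idx],
                   t1 = maps$t1[idx], t2 = maps$t2[idx], rho = maps$rho[idx])
  # Aggregate duplicate feature nodes by averaging parameter values.
  key <- mapping_key(df$mu, df$sigma)
  if (anyDuplicated(key)) {
    agg <- rowsum(as.matrix(df), group = key, reorder = FALSE)
    cnt <- as.vector(table(factor(key, levels = rownames(agg))))
    df <- as.data.frame(agg / cnt)
  }
  if (mode == "piecewise_linear") {
    if (nrow(df) < 3L)
      pmr_error("piecewise_linear mode needs >= 3 feature points",
                "pseudoMR_degenerate_geometry")
    if (qr(cbind(1, df$mu, df$sigma))$rank < 3L)
      pmr_error("training (mu, sigma) points are collinear; use mode = 'nearest'",
                "pseudoMR_degenerate_geometry")
  }
  structure(list(training = df, mode = mode, fallback = fallback,
                 n_raw = length(idx), provenance = "training slice"),
            class = "ct_mapping")
}

#' @export
print.ct_mapping <- function(x, ...) {
  cat(sprintf("CT-to-MR mapping model (%s interpolation, %s fallback)\n",
              x$mode, x$fallback))
  cat(sprintf("  %d feature nodes (aggregated from %d pixels)\n",
              nrow(x$training), x$n_raw))
  cat(sprintf("  mu range %.4g .. %.4g HU, sigma range %.4g .. %.4g HU\n",
              min(x$training$mu), max(x$training$mu),
              min(x$training$sigma), max(x$training$sigma)))
  invisible(x)
}

#' @export
summary.ct_mapping <- function(object, ...) {
  tr <- object$training
  cat(sprintf("CT-to-MR mapping model: mode = %s, fallback = %s\n",
              object$mode, object$fallback))
  cat(sprintf("  nodes: %d (from %d training pixels)\n", nrow(tr), object$n_raw))
  print(summary(tr))
  invisible(object)
}

#' @export
plot.ct_mapping <- function(x, parameter = c("t1", "t2", "rho"), ...) {
  parameter <- match.arg(parameter)
  v <- x$training[[parameter]]
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[cut(v, 64, labels = FALSE)]
  plot(x$training$mu, x$training$sigma, col = col, pch = 16,
       xlab = "window mean (HU)", ylab = "window sd (HU)",
       main = sprintf("%s over the (mu, sigma) plane", toupper(parameter)), ...)
  invisible(x)
}

# Nearest training node for each query, exact Euclidean search in the
# (mu, sigma) plane via a kd-tree.
nearest_node <- function(train_mu, train_sigma, q_mu, q_sigma) {
  FNN::get.knnx(cbind(train_mu, train_sigma), cbind(q_mu, q_sigma), k = 1)$nn.index[, 1]
}

#' Evaluate a CT-to-MR mapping at feature points
#'
#' Evaluates the three mapping surfaces at query (mu, sigma) locations.
#' Queries that coincide exactly with a training node return the node value
#' directly (machine-precision node exactness); other queries are
#' interpolated per the model's mode. In piecewise-linear mode, queries
#' outside the convex hull of the training features use the model's
#' fallback: nearest training node, or NA when `fallback = "drop"`.
#'
#' @param object A `ct_mapping` model.
#' @param newdata Data frame (or list) with numeric `mu` and `sigma`.
#' @param ... Unused.
#' @return Data frame with columns `t1`, `t2`, `rho` (NA where dropped).
#' @export
predict.ct_mapping <- function(object, newdata, ...) {
  mu <- newdata$mu; sigma <- newdata$sigma
  if (is.null(mu) || is.null(sigma) || length(mu) != length(sigma))
    pmr_error("newdata must provide equal-length mu and sigma", "pseudoMR_structural_error")
  tr <- object$training
  nq <- length(mu)
  out <- matrix(NA_real_, nq, 3, dimnames = list(NULL, c("t1", "t2", "rho")))
  if (!nq) return(as.data.frame(out))

  # Exact-node short circuit guarantees node exactness in both modes.
  hit <- match(mapping_key(mu, sigma), mapping_key(tr$mu, tr$sigma))
  exact <- !is.na(hit)
  if (any(exact))
    out[exact, ] <- as.matrix(tr[hit[exact], c("t1", "t2", "rho")])

  rest <- which(!exact)
  if (length(rest)) {
    if (object$mode == "nearest") {
      nn <- nearest_node(tr$mu, tr$sigma, mu[rest], sigma[rest])
      out[rest, ] <- as.matrix(tr[nn, c("t1", "t2", "rho")])
    } else {
      for (p in c("t1", "t2", "rho")) {
        z <- interp::interpp(tr$mu, tr$sigma, tr[[p]],
                             xo = mu[rest], yo = sigma[rest],
                             duplicate = "error")$z
        out[rest, p] <- z
      }
      oob <- rest[is.na(out[rest, "t1"])]
      if (length(oob) && object$fallback == "nearest") {
        nn <- nearest_node(tr$mu, tr$sigma, mu[oob], sigma[oob])
        out[oob, ] <- as.matrix(tr[nn, c("t1", "t2", "rho")])
      }
    }
  }
  as.data.frame(out)
}

#' Apply a mapping model to a feature map
#'
#' Evaluates the fitted mapping surfaces at every in-mask pixel of a CT
#' feature map, producing synthetic T1/T2/rho parameter maps for that
#' slice. Pixels dropped by the `"drop"` fallback are removed from the
#' output mask.
#'
#' @param model A `ct_mapping` model from [build_mapping()].
#' @param features [ct_window_features()] output for the target CT slice.
#' @return [parameter_maps()] over the feature mask.
#' @export
apply_mapping <- function(model, features) {
  if (!inherits(model, "ct_mapping"))
    pmr_error("'model' must be a ct_mapping", "pseudoMR_structural_error")
  if (!inherits(features, "ct_features"))
    pmr_error("'features' must come from ct_window_features()", "pseudoMR_structural_error")
  idx <- which(features$mask)
  pr <- predict(model, data.frame(mu = features$mu[idx], sigma = features$sigma[idx]))
  d <- dim(features$mask)
  t1 <- t2 <- rho <- matrix(NA_real_, d[1], d[2])
  t1[idx] <- pr$t1; t2[idx] <- pr$t2; rho[idx] <- pr$rho
  ok <- features$mask & !is.na(t1) & !is.na(t2) & !is.na(rho)
  if (!any(ok)) pmr_error("no valid pixels after mapping", "pseudoMR_empty_mask")
  parameter_maps(t1, t2, rho, ok)
}

#' Serialize a mapping model to JSON
#'
#' Writes the training nodes, mode and fallback rule so the stored mapping
#' functions can be reloaded with [read_mapping()] and applied to new CT
#' slices later.
#'
#' @param model A `ct_mapping`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(model, path) {
  if (!inherits(model, "ct_mapping"))
    pmr_error("'model' must be a ct_mapping", "pseudoMR_structural_error")
  obj <- list(format = "pseudoMR_mapping", version = 1L,
              mode = model$mode, fallback = model$fallback,
              n_raw = model$n_raw, provenance = model$provenance,
              training = as.list(model$training))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mapping model from JSON
#'
#' @param path File written by [write_mapping()].
#' @return A `ct_mapping` model.
#' @export
read_mapping <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pseudoMR_mapping"))
    pmr_error("not a pseudoMR mapping file", "pseudoMR_format_error")
  structure(list(training = as.data.frame(obj$training), mode = obj$mode,
                 fallback = obj$fallback, n_raw = obj$n_raw,
                 provenance = obj$provenance),
            class = "ct_mapping")
}
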