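# Independent oracles used across tests. Each is coded directly from the
# defining formula, separately from the package implementation.

# Spin-echo amplitude, written with the exponents expanded term by term.
oracle_se_signal <- function(t1, t2, rho, te, tr) {
  sat <- 1 - 2 * exp(-(tr - te / 2) / t1) + exp(-tr / t1)
  decay <- exp(-te / t2)
  rho * sat * decay
}

# Signals of one tissue across a TR grid (fixed TE) under the full model.
oracle_tr_series <- function(t1, t2, rho, te, trs) {
  vapply(trs, function(tr) oracle_se_signal(t1, t2, rho, te, tr), numeric(1))
}

# Textbook fuzzy C-means update loop on a 1D intensity vector with given
# initial centroids, run for a fixed number of sweeps.
oracle_fcm <- function(x, centroids, m, n_iter) {
  obj <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    u <- matrix(0, length(x), length(centroids))
    for (i in seq_along(x)) {
      d2 <- (x[i] - centroids)^2
      if (any(d2 == 0)) {
        u[i, d2 == 0] <- 1 / sum(d2 == 0)
      } else {
        for (k in seq_along(centroids))
          u[i, k] <- 1 / sum((d2[k] / d2)^(1 / (m - 1)))
      }
    }
    obj[it] <- sum(u^m * outer(x, centroids, function(a, b) (a - b)^2))
    centroids <- colSums(u^m * x) / colSums(u^m)
  }
  list(centroids = centroids, objective = obj, memberships = u)
}

# Exhaustive nearest training point in the (mu, sigma) plane.
oracle_nearest <- function(train_mu, train_sigma, q_mu, q_sigma) {
  vapply(seq_along(q_mu), function(i) {
    which.min((train_mu - q_mu[i])^2 + (train_sigma - q_sigma[i])^2)
  }, integer(1))
}

# 4-connected components by breadth-first flood fill.
oracle_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask & lab == 0L)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= ncol(mask)) {
          q <- (d[2] - 1L) * nr + d[1]
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

# Two-tissue phantom helpers used by several files: a small slice with two
# rectangular inserts of known parameters.
two_tissue_phantom <- function(shape = c(48, 48), seed = 1) {
  specs <- list(
    tissue_spec("bright", list(type = "rect", center = c(14, 24), half = c(9, 18)),
                t1 = 300, t2 = 60, rho = 500, hu_mean = 60, hu_texture_sd = 5),
    tissue_spec("dark", list(type = "rect", center = c(36, 24), half = c(9, 18)),
                t1 = 900, t2 = 150, rho = 800, hu_mean = -40, hu_texture_sd = 12)
  )
  make_phantom(specs, shape, seed = seed)
}

# Noiseless variable-TR / variable-TE series at the standard grids.
std_tr_grid <- c(100, 200, 400, 800, 1250, 2000, 4000, 5000)
std_te_grid <- c(10, 15, 25, 40, 60, 90, 130, 180, 240)
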