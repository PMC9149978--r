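# The (mu, sigma) -> {T1, T2, rho} mapping surfaces.

# Build a small ct_features / parameter_maps pair directly from vectors,
# bypassing the window machinery, so interpolation behaviour is isolated.
features_from_points <- function(mu, sigma) {
  n <- length(mu)
  d <- c(1, n)
  structure(list(mu = matrix(mu, 1), sigma = matrix(sigma, 1),
                 n = matrix(25, 1, n), mask = matrix(TRUE, 1, n),
                 window_size = 5L), class = "ct_features")
}
maps_from_values <- function(t1, t2, rho) {
  n <- length(t1)
  parameter_maps(matrix(t1, 1), matrix(t2, 1), matrix(rho, 1),
                 matrix(TRUE, 1, n))
}

test_that("both modes reproduce training values exactly at the nodes", {
  set.seed(5)
  mu <- runif(40, 0, 100); sigma <- runif(40, 1, 20)
  t1 <- 300 + 8 * mu; t2 <- 40 + 3 * sigma; rho <- 500 + mu + sigma
  f <- features_from_points(mu, sigma); m <- maps_from_values(t1, t2, rho)
  for (mode in c("piecewise_linear", "nearest")) {
    mdl <- build_mapping(f, m, mode = mode)
    pr <- predict(mdl, data.frame(mu = mu, sigma = sigma))
    expect_identical(pr$t1, t1)
    expect_identical(pr$t2, t2)
    expect_identical(pr$rho, rho)
  }
})

test_that("piecewise-linear mode is linear on a simplex edge and affine-exact", {
  f <- features_from_points(c(0, 10, 0), c(0, 0, 10))
  m <- maps_from_values(c(100, 200, 300), c(10, 20, 30), c(1, 2, 3))
  mdl <- build_mapping(f, m, mode = "piecewise_linear")
  # Midpoint of the edge joining nodes 1 and 2.
  pr <- predict(mdl, data.frame(mu = 5, sigma = 0))
  expect_equal(pr$t1, 150, tolerance = 1e-9)
  expect_equal(pr$rho, 1.5, tolerance = 1e-9)

  # Any globally affine surface is reproduced inside the convex hull.
  set.seed(6)
  mu <- runif(60, 0, 50); sigma <- runif(60, 0, 15)
  v <- function(a, b, c) a + b * mu + c * sigma
  mdl2 <- build_mapping(features_from_points(mu, sigma),
                        maps_from_values(v(200, 6, 2), v(50, 1, 4), v(400, 3, 9)),
                        mode = "piecewise_linear")
  qmu <- runif(50, 10, 40); qsg <- runif(50, 3, 12)
  inside <- qmu > 10 & qmu < 40  # queries drawn well inside the hull
  pr2 <- predict(mdl2, data.frame(mu = qmu, sigma = qsg))
  expect_equal(pr2$t1, 200 + 6 * qmu + 2 * qsg, tolerance = 1e-6)
  expect_equal(pr2$t2, 50 + 1 * qmu + 4 * qsg, tolerance = 1e-6)
  expect_equal(pr2$rho, 400 + 3 * qmu + 9 * qsg, tolerance = 1e-6)
})

test_that("out-of-hull queries fall back to the exhaustive nearest node", {
  set.seed(7)
  mu <- runif(25, 20, 60); sigma <- runif(25, 5, 15)
  t1 <- 200 + 5 * mu
  mdl <- build_mapping(features_from_points(mu, sigma),
                       maps_from_values(t1, t1 / 4, t1 * 2),
                       mode = "piecewise_linear", fallback = "nearest")
  qmu <- c(0, 100, 50, -10); qsg <- c(0, 30, 100, 7)   # all far outside
  pr <- predict(mdl, data.frame(mu = qmu, sigma = qsg))
  nn <- oracle_nearest(mu, sigma, qmu, qsg)
  expect_equal(pr$t1, t1[nn])

  # fallback = "drop" marks them invalid instead.
  mdl2 <- build_mapping(features_from_points(mu, sigma),
                        maps_from_values(t1, t1 / 4, t1 * 2),
                        mode = "piecewise_linear", fallback = "drop")
  pr2 <- predict(mdl2, data.frame(mu = qmu[1:2], sigma = qsg[1:2]))
  expect_true(all(is.na(pr2$t1)))
})

test_that("degenerate geometry and duplicate nodes are handled", {
  # Collinear points cannot triangulate; the error suggests nearest mode.
  f <- features_from_points(1:5, rep(2, 5))
  m <- maps_from_values(101:105, 11:15, 21:25)
  expect_error(build_mapping(f, m, mode = "piecewise_linear"),
               regexp = "nearest", class = "pseudoMR_degenerate_geometry")
  expect_s3_class(build_mapping(f, m, mode = "nearest"), "ct_mapping")

  # Duplicate (mu, sigma) pairs are averaged before interpolation.
  f2 <- features_from_points(c(0, 0, 10, 0), c(0, 0, 0, 10))
  m2 <- maps_from_values(c(100, 200, 300, 400), c(10, 30, 50, 70), c(1, 3, 5, 7))
  mdl <- build_mapping(f2, m2, mode = "nearest")
  expect_equal(nrow(mdl$training), 3)
  pr <- predict(mdl, data.frame(mu = 0, sigma = 0))
  expect_equal(pr$t1, 150)
  expect_equal(pr$t2, 20)
})

test_that("apply_mapping round-trips the training slice exactly", {
  ph <- two_tissue_phantom()
  ct <- simulate_ct(ph, noise_sd = 4, n_repeats = 9, seed = 3)
  feats <- ct_window_features(ct$average, ph$truth_maps$mask)
  maps <- parameter_maps(ph$truth_maps$t1, ph$truth_maps$t2, ph$truth_maps$rho,
                         feats$mask)
  for (mode in c("piecewise_linear", "nearest")) {
    mdl <- build_mapping(feats, maps, mode = mode)
    back <- apply_mapping(mdl, feats)
    expect_identical(back$mask, feats$mask)
    expect_equal(back$t1[back$mask], maps$t1[back$mask], tolerance = 1e-12)
    expect_equal(back$t2[back$mask], maps$t2[back$mask], tolerance = 1e-12)
    expect_equal(back$rho[back$mask], maps$rho[back$mask], tolerance = 1e-12)
  }
})

test_that("training-slice regeneration yields near-unity slope and small PRD", {
  ph <- two_tissue_phantom()
  ct <- simulate_ct(ph, noise_sd = 4, n_repeats = 9, seed = 8)
  feats <- ct_window_features(ct$average, ph$truth_maps$mask)
  maps <- parameter_maps(ph$truth_maps$t1, ph$truth_maps$t2, ph$truth_maps$rho,
                         feats$mask)
  mdl <- build_mapping(feats, maps, mode = "piecewise_linear")
  regen <- apply_mapping(mdl, feats)
  for (v in c("t1", "t2", "rho")) {
    rep_v <- compare_regions(maps[[v]], regen[[v]], regen$mask)
    expect_gte(rep_v$slope, 0.95)
    expect_lte(rep_v$slope, 1.05)
    expect_lt(rep_v$prd, 1)
  }
})

test_that("mapping models survive JSON serialization", {
  set.seed(10)
  mu <- runif(15, 0, 50); sigma <- runif(15, 1, 9)
  mdl <- build_mapping(features_from_points(mu, sigma),
                       maps_from_values(300 + mu, 40 + sigma, 600 - mu),
                       mode = "piecewise_linear")
  path <- tempfile(fileext = ".json")
  write_mapping(mdl, path)
  mdl2 <- read_mapping(path)
  q <- data.frame(mu = runif(20, 5, 45), sigma = runif(20, 2, 8))
  expect_equal(predict(mdl2, q), predict(mdl, q), tolerance = 1e-12)
  expect_identical(mdl2$mode, mdl$mode)
})

test_that("a mapping learned on one slice transfers to a second geometry", {
  pa <- two_tissue_phantom(seed = 1)
  # Same tissues, different arrangement.
  specs_b <- list(
    tissue_spec("bright", list(type = "ellipse", center = c(30, 14), radii = c(12, 9)),
                300, 60, 500, 60, 5),
    tissue_spec("dark", list(type = "ellipse", center = c(16, 34), radii = c(10, 11)),
                900, 150, 800, -40, 12))
  pb <- make_phantom(specs_b, c(48, 48), seed = 2)
  ct_a <- simulate_ct(pa, noise_sd = 4, seed = 5)
  ct_b <- simulate_ct(pb, noise_sd = 4, seed = 6)
  fa <- ct_window_features(ct_a$average, pa$truth_maps$mask)
  fb <- ct_window_features(ct_b$average, pb$truth_maps$mask)
  maps_a <- parameter_maps(pa$truth_maps$t1, pa$truth_maps$t2, pa$truth_maps$rho,
                           fa$mask)
  mdl <- build_mapping(fa, maps_a, mode = "piecewise_linear")
  maps_b <- apply_mapping(mdl, fb)
  for (i in 1:2) {
    sel <- pb$label_map == i & maps_b$mask
    truth <- c(300, 900)[i]
    expect_lt(abs(median(maps_b$t1[sel]) - truth) / truth, 0.05)
  }
})
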