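# End-to-end orchestration: simulate (or load) a slice, segment, fit the
# parameter maps, extract CT features, build the mapping model, synthesize
# weighted images for a target slice, and evaluate similarity. Every stage
# logs its parameters and output checksums; identical config + seed gives
# identical artifacts.

pipeline_log <- function(state, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  message(line)
  c(state, line)
}

file_checksum <- function(path) unname(tools::md5sum(path))

#' Run the CT-to-MR synthesis pipeline from a configuration
#'
#' Executes the full workflow on a simulated phantom pair: stage order is
#' simulate -> segment -> fit-maps -> extract-features -> build-mapping ->
#' synthesize -> evaluate. The mapping model is trained on slice A and
#' applied to slice B (a different arrangement of the same tissue set), so
#' the evaluation measures generalization to unseen geometry, not training
#' fit. Artifacts (CT images, masks, parameter-map grids, the mapping
#' model JSON, synthesized images, similarity reports) are written under
#' `out_dir`; a `log.txt` records every stage's parameters and the MD5
#' checksum of every written file.
#'
#' @param config Path to a YAML configuration or an equivalent named list.
#'   See `system.file("extdata", "demo-pipeline.yaml", package =
#'   "pseudoMR")` for the schema; `seed` is required.
#' @param out_dir Output directory (created if needed). Defaults to
#'   `config$out_dir`, or a tempdir subdirectory if unset.
#' @return Invisibly, a list with the phantom pair, fitted maps, mapping
#'   model, synthesized images and a data frame `reports` of slope/PRD per
#'   weighting.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) pmr_error("config must be a YAML path or a list",
                                  "pseudoMR_config_error")
  req <- function(name, where = config) {
    if (is.null(where[[name]]))
      pmr_error(sprintf("config field missing: %s", name), "pseudoMR_config_error")
    where[[name]]
  }
  seed <- as.integer(req("seed"))
  phant <- req("phantom")
  shape <- rep_len(as.integer(phant$shape %||% 128L), 2L)
  mapping_cfg <- req("mapping")
  mode <- req("mode", mapping_cfg)
  if (!mode %in% c("piecewise_linear", "nearest"))
    pmr_error("config field mapping.mode must be 'piecewise_linear' or 'nearest'",
              "pseudoMR_config_error")
  ct_cfg <- config$ct %||% list()
  mr_cfg <- config$mr %||% list()
  seg_cfg <- config$segmentation %||% list()
  if (is.null(out_dir)) out_dir <- config$out_dir %||% tempfile("pseudoMR-run-")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  written <- character(0)
  emit <- function(obj, name, writer = write_image) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    written <<- c(written,
                  if (file.exists(p)) p
                  else paste0(p, "_", c("t1", "t2", "rho", "mask"), ".tsv"))
    p
  }

  # --- stage: simulate-phantom -------------------------------------------
  specs_a <- default_tissue_specs(shape, layout = "a")
  specs_b <- default_tissue_specs(shape, layout = "b")
  pa <- make_phantom(specs_a, shape, seed = seed)
  pb <- make_phantom(specs_b, shape, seed = seed + 1L)
  ct_noise <- ct_cfg$noise_sd %||% 5
  ct_rep <- ct_cfg$n_repeats %||% 9
  ct_a <- simulate_ct(pa, ct_noise, ct_rep, seed = seed + 2L)
  ct_b <- simulate_ct(pb, ct_noise, ct_rep, seed = seed + 3L)
  emit(ct_a$average, "ct_a.tsv"); emit(ct_b$average, "ct_b.tsv")
  log <- pipeline_log(log, "simulate-phantom",
                      "shape=%dx%d ct_noise_sd=%g n_repeats=%d seed=%d",
                      shape[1], shape[2], ct_noise, ct_rep, seed)

  # --- stage: segment -----------------------------------------------------
  k <- seg_cfg$n_clusters %||% 2
  part_a <- fcm_segment(ct_a$average, n_clusters = k, seed = seed + 4L)
  part_b <- fcm_segment(ct_b$average, n_clusters = k, seed = seed + 5L)
  mask_a <- extract_region_mask(part_a, rule = "highest")
  mask_b <- extract_region_mask(part_b, rule = "highest")
  emit(mask_a, "mask_a.png", write_mask); emit(mask_b, "mask_b.png", write_mask)
  log <- pipeline_log(log, "segment", "k=%d mask_a=%d px mask_b=%d px",
                      k, sum(mask_a), sum(mask_b))

  # --- stage: fit-maps (slice A, from simulated MR series) ---------------
  tr_grid <- mr_cfg$tr_grid %||% c(100, 200, 400, 800, 1250, 2000, 4000, 5000)
  te_grid <- mr_cfg$te_grid %||% c(10, 15, 25, 40, 60, 90, 130, 180, 240)
  te_fix <- mr_cfg$te_fixed %||% 20
  tr_fix <- mr_cfg$tr_fixed %||% 2000
  mr_noise <- mr_cfg$noise_sd %||% 0
  tr_series <- simulate_mr_series(pa, data.frame(te = te_fix, tr = tr_grid),
                                  noise_sd = mr_noise, seed = seed + 6L)
  te_series <- simulate_mr_series(pa, data.frame(te = te_grid, tr = tr_fix),
                                  noise_sd = mr_noise, seed = seed + 7L)
  maps_a <- compute_parameter_maps(tr_series, te_series, mask_a)
  emit(maps_a, "maps_a", write_parameter_maps)
  log <- pipeline_log(log, "fit-maps",
                      "TRs=%s (TE=%g) TEs=%s (TR=%g) noise_sd=%g -> %d px",
                      paste(tr_grid, collapse = ","), te_fix,
                      paste(te_grid, collapse = ","), tr_fix, mr_noise,
                      sum(maps_a$mask))

  # --- stage: extract-features -------------------------------------------
  wsz <- mapping_cfg$window_size %||% 5
  mc <- mapping_cfg$min_count %||% 6
  feat_a <- ct_window_features(ct_a$average, mask_a, wsz, mc)
  feat_b <- ct_window_features(ct_b$average, mask_b, wsz, mc)
  log <- pipeline_log(log, "extract-features", "window=%dx%d min_count=%d",
                      wsz, wsz, mc)

  # --- stage: build-mapping ----------------------------------------------
  model <- build_mapping(feat_a, maps_a, mode = mode,
                         fallback = mapping_cfg$fallback %||% "nearest")
  emit(model, "mapping.json", write_mapping)
  log <- pipeline_log(log, "build-mapping", "mode=%s nodes=%d",
                      mode, nrow(model$training))

  # --- stage: synthesize (slice B) ---------------------------------------
  maps_b <- apply_mapping(model, feat_b)
  emit(maps_b, "maps_b", write_parameter_maps)
  weightings <- config$weightings %||%
    list(list(name = "t1w", te = 10, tr = 500),
         list(name = "t2w", te = 130, tr = 2000),
         list(name = "pdw", te = 10, tr = 4000))
  reports <- NULL
  for (w in weightings) {
    sq <- seq_params(w$te, w$tr)
    syn <- synthesize_weighted_image(maps_b, sq)
    ref <- synthesize_weighted_image(pb$truth_maps, sq)
    emit(syn, sprintf("synthetic_%s.tsv", w$name))
    rep_w <- compare_regions(ref, syn, maps_b$mask)
    reports <- rbind(reports, data.frame(
      weighting = w$name, te = w$te, tr = w$tr, slope = rep_w$slope,
      intercept = rep_w$intercept, prd = rep_w$prd, n = rep_w$n))
    log <- pipeline_log(log, "evaluate", "%s (TE=%g TR=%g): slope=%.4g PRD=%.3g%%",
                        w$name, w$te, w$tr, rep_w$slope, rep_w$prd)
  }
  jsonlite::write_json(reports, file.path(out_dir, "similarity.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  written <- c(written, file.path(out_dir, "similarity.json"))

  sums <- vapply(written, file_checksum, character(1))
  log <- c(log, sprintf("[checksum] %s %s", basename(written), sums))
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(list(phantom_a = pa, phantom_b = pb, mask_a = mask_a,
                 mask_b = mask_b, maps_a = maps_a, maps_b = maps_b,
                 model = model, reports = reports, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
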