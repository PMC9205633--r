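#' Pipeline configuration
#'
#' Collects every stage parameter in one validated list.  Window-type
#' defaults are expressed relative to the expected cell diameter (px):
#' the median-filter window is about one cell radius, and the background,
#' seed-search, footprint and dilation windows are about one diameter.
#'
#' @param fps frames per second.
#' @param cell_diameter expected cell diameter in pixels; drives window
#'   defaults.
#' @param denoise_wnd odd median window (px); default: cell radius,
#'   rounded up to odd.
#' @param background_wnd opening-disc diameter (px); default: one cell
#'   diameter.
#' @param chunk_nfm,max_shift,fallback_thres motion-correction controls.
#' @param wnd_size,step_size rolling max-projection window for seeding.
#' @param max_wnd local-maximum neighbourhood diameter (px); default: one
#'   cell diameter.
#' @param diff_thres seed intensity threshold (0-255 scale).
#' @param noise_freq signal/noise cutoff (Hz) used across the pipeline.
#' @param pnr_thres peak-to-noise threshold.
#' @param ks_sig KS-test significance threshold.
#' @param merge_dist,merge_corr seed-merge thresholds (px, correlation).
#' @param sim_thres cosine-similarity threshold for footprint
#'   initialization.
#' @param init_wnd footprint-initialization window radius (px); default:
#'   one cell diameter.
#' @param dl_wnd spatial-update dilation diameter (px); default: one cell
#'   diameter.
#' @param sparse_spatial,sparse_temporal l1 multipliers for the spatial
#'   and temporal updates.
#' @param ar_order AR model order (1 or 2).
#' @param jac_thres Jaccard grouping threshold.
#' @param unit_merge_corr trace-correlation threshold for merging units
#'   between CNMF iterations.
#' @param iters number of spatial+temporal update cycles (default 2).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 30, cell_diameter = 8,
                            denoise_wnd = NULL, background_wnd = NULL,
                            chunk_nfm = 3, max_shift = 10,
                            fallback_thres = 5,
                            wnd_size = 1000, step_size = 200,
                            max_wnd = NULL, diff_thres = 3,
                            noise_freq = 1, pnr_thres = 1, ks_sig = 0.05,
                            merge_dist = NULL, merge_corr = 0.8,
                            sim_thres = 0.5, init_wnd = NULL,
                            dl_wnd = NULL, sparse_spatial = 0.1,
                            sparse_temporal = 0.008, ar_order = 2,
                            jac_thres = 0.2, unit_merge_corr = 0.9,
                            iters = 2) {
  radius <- max(1, round(cell_diameter / 2))
  denoise_wnd <- denoise_wnd %||% (radius + (radius + 1) %% 2)
  background_wnd <- background_wnd %||% cell_diameter
  max_wnd <- max_wnd %||% cell_diameter
  merge_dist <- merge_dist %||% radius
  init_wnd <- init_wnd %||% cell_diameter
  dl_wnd <- dl_wnd %||% cell_diameter
  cfg <- list(fps = fps, cell_diameter = cell_diameter,
              denoise_wnd = denoise_wnd, background_wnd = background_wnd,
              chunk_nfm = chunk_nfm, max_shift = max_shift,
              fallback_thres = fallback_thres, wnd_size = wnd_size,
              step_size = step_size, max_wnd = max_wnd,
              diff_thres = diff_thres, noise_freq = noise_freq,
              pnr_thres = pnr_thres, ks_sig = ks_sig,
              merge_dist = merge_dist, merge_corr = merge_corr,
              sim_thres = sim_thres, init_wnd = init_wnd,
              dl_wnd = dl_wnd, sparse_spatial = sparse_spatial,
              sparse_temporal = sparse_temporal, ar_order = ar_order,
              jac_thres = jac_thres, unit_merge_corr = unit_merge_corr,
              iters = iters)
  stopifnot(fps > 0, noise_freq > 0, noise_freq < fps / 2,
            denoise_wnd %% 2 == 1, iters >= 1, ar_order %in% c(1, 2),
            sparse_spatial >= 0, sparse_temporal >= 0, chunk_nfm >= 2)
  structure(cfg, class = "pipeline_config")
}

#' Run the full source-extraction pipeline
#'
#' Executes preprocessing, rigid motion correction, seed initialization
#' and `iters` cycles of spatial followed by temporal CNMF updates, with
#' unit merging between (never after) iterations.  Intermediates can be
#' persisted to a chunked store.
#'
#' @param video a [video_array()].
#' @param config a [pipeline_config()].
#' @param store_path optional directory: persists intermediates and the
#'   final model plus a JSON run report.
#' @param motion_mask optional [crop_mask()] for motion estimation.
#' @return list with `model` (a [cnmf_model()]), `shifts`, `seeds`, and a
#'   machine-readable `report` (parameters and unit counts per stage).
#' @export
run_pipeline <- function(video, config = pipeline_config(),
                         store_path = NULL, motion_mask = NULL) {
  t0 <- proc.time()[3]
  counts <- list()
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", nm,
                   conditionMessage(e)), call. = FALSE))
  }
  pp <- stage("preprocess", preprocess_video(
    video, denoise_wnd = config$denoise_wnd,
    background_wnd = config$background_wnd))
  if (!is.null(store_path))
    persist_array(pp, file.path(store_path, "preprocessed.zarr"))
  shifts <- stage("motion", estimate_motion(
    pp, chunk_nfm = config$chunk_nfm, max_shift = config$max_shift,
    fallback_thres = config$fallback_thres, mask = motion_mask))
  mc <- stage("motion", apply_shifts(pp, shifts))
  pp <- NULL  # release the uncorrected copy
  seeds <- stage("initialization", {
    s <- seeds_init(mc, wnd_size = config$wnd_size,
                    step_size = config$step_size,
                    max_wnd = config$max_wnd,
                    diff_thres = config$diff_thres)
    s <- pnr_refine(mc, s, noise_freq = config$noise_freq,
                    thres = config$pnr_thres)
    s <- ks_refine(mc, s, sig = config$ks_sig)
    seeds_merge(mc, s, thres_dist = config$merge_dist,
                thres_corr = config$merge_corr,
                noise_freq = config$noise_freq)
  })
  counts$seeds_total <- nrow(seeds)
  counts$seeds_active <- sum(seed_active(seeds))
  model <- stage("initialization", {
    A <- init_spatial(mc, seeds, thres_corr = config$sim_thres,
                      wnd = config$init_wnd)
    C <- init_temporal(mc, A)
    bg <- init_background(mc, A, C)
    cnmf_model(A, C, b = bg$b, f = bg$f, fps = config$fps)
  })
  counts$units_init <- dim(model$A)[3]
  sn <- stage("cnmf", estimate_noise(mc, noise_freq = config$noise_freq))
  for (it in seq_len(config$iters)) {
    model <- stage("cnmf", update_spatial(
      mc, model, sn, dl_wnd = config$dl_wnd,
      sparse_penalty = config$sparse_spatial))
    counts[[sprintf("units_spatial_%d", it)]] <- dim(model$A)[3]
    model <- stage("cnmf", update_temporal(
      mc, model, p = config$ar_order, noise_freq = config$noise_freq,
      sparse_penalty = config$sparse_temporal,
      jac_thres = config$jac_thres))
    counts[[sprintf("units_temporal_%d", it)]] <- dim(model$A)[3]
    if (it < config$iters) {
      model <- stage("cnmf", unit_merge(model, config$unit_merge_corr))
      counts[[sprintf("units_merged_%d", it)]] <- dim(model$A)[3]
    }
  }
  report <- list(parameters = unclass(config), unit_counts = counts,
                 n_frames = dim(video)[1],
                 dims = dim(video)[2:3],
                 elapsed_s = unname(proc.time()[3] - t0))
  if (!is.null(store_path)) {
    export_model(model, store_path)
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
               file.path(store_path, "report.json"))
    utils::write.csv(as.data.frame(seeds),
                     file.path(store_path, "seeds.csv"), row.names = FALSE)
  }
  list(model = model, shifts = shifts, seeds = seeds, report = report)
}

#' Export a model to a chunked store plus CSV tables
#'
#' Writes `A`, `C`, `S`, `b`, `f` as Zarr-layout arrays and the per-unit
#' temporal-fit table as CSV.
#'
#' @param model a [cnmf_model()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
export_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  persist_array(model$A, file.path(path, "A.zarr"),
                dims = c("height", "width", "unit"))
  persist_array(model$C, file.path(path, "C.zarr"),
                dims = c("frame", "unit"))
  persist_array(model$S, file.path(path, "S.zarr"),
                dims = c("frame", "unit"))
  persist_array(model$b, file.path(path, "b.zarr"),
                dims = c("height", "width"))
  persist_array(model$f, file.path(path, "f.zarr"), dims = "frame")
  if (!is.null(model$fits))
    utils::write.csv(model$fits, file.path(path, "units.csv"),
                     row.names = FALSE)
  invisible(path)
}
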