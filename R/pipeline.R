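#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' conventional defaults: 0.009-0.08 Hz band, 38-frame head/tail trims,
#' 25-frame detection window, FD threshold 0.5 mm with a 30-frame scrub
#' tail, minimum 60 events per run, k = 12 sub-clusters with 100 restarts,
#' 50-frame GLM trims, 50-frame occurrence smoothing, and PMI exclusions of
#' 100 frames at the run edges and lags up to 100 frames.
#'
#' @param window_size detection window in frames (odd).
#' @param k number of k-means sub-clusters.
#' @param n_init k-means restarts.
#' @param fd_threshold FD scrub threshold (mm).
#' @param scrub_after frames masked after a motion spike.
#' @param min_ts minimum events per run.
#' @param low_hz,high_hz bandpass edges (Hz).
#' @param trim head/tail frames dropped before detection.
#' @param glm_trim head/tail frames dropped from GLM designs.
#' @param smooth_w occurrence smoothing width (frames).
#' @param t_trim,tau_min PMI fitting exclusions (frames).
#' @param tau_max largest PMI lag (frames).
#' @param seed master seed.
#' @return a named list of class `tsync_config`.
#' @export
pipeline_config <- function(window_size = 25L, k = 12L, n_init = 100L,
                            fd_threshold = 0.5, scrub_after = 30L, min_ts = 60L,
                            low_hz = 0.009, high_hz = 0.08, trim = 38L,
                            glm_trim = 50L, smooth_w = 50L, t_trim = 100L,
                            tau_min = 100L, tau_max = 300L, seed = 1L) {
  structure(list(window_size = as.integer(window_size), k = as.integer(k),
                 n_init = as.integer(n_init), fd_threshold = fd_threshold,
                 scrub_after = as.integer(scrub_after), min_ts = as.integer(min_ts),
                 low_hz = low_hz, high_hz = high_hz, trim = as.integer(trim),
                 glm_trim = as.integer(glm_trim), smooth_w = as.integer(smooth_w),
                 t_trim = as.integer(t_trim), tau_min = as.integer(tau_min),
                 tau_max = as.integer(tau_max), seed = as.integer(seed)),
            class = "tsync_config")
}

#' Run the full analysis pipeline on a set of runs
#'
#' Executes preprocessing (bandpass, trim, optional motion scrubbing),
#' sliding-window PCA detection, pooled TSP clustering with sub-cluster
#' pairing, occurrence timecourses, PMI decomposition, and (when voxel data
#' are attached) the event-coded GLM, writing each stage's tables plus a
#' JSON provenance record into `out_dir`. Any stage failure aborts with the
#' stage name; files written before the failure remain as a partial
#' manifest.
#'
#' @param runs list of [roi_timeseries()] objects (or paths to ROI TSV
#'   files readable by [read_roi_tsv()]).
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param motion optional list of motion matrices (one per run).
#' @param voxel_ts optional list of voxel x frame matrices (one per run)
#'   for the GLM stage.
#' @return invisibly, a list with the fitted objects (`events`, `model`,
#'   `occ`, `pmi`, per-run `glm`) and the manifest of written files.
#' @export
run_pipeline <- function(runs, out_dir, config = pipeline_config(),
                         motion = NULL, voxel_ts = NULL) {
  stopifnot(inherits(config, "tsync_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(path) manifest <<- c(manifest, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs: %s)",
                   name, conditionMessage(e),
                   if (length(manifest)) paste(basename(manifest), collapse = ", ") else "none"),
           call. = FALSE))
  }
  runs <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    if (is.character(r)) r <- read_roi_tsv(r)
    if (is.na(r$run_id)) r$run_id <- sprintf("run%02d", i)
    r
  })

  events_by_run <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    ts <- stage("preprocess", {
      x <- bandpass(runs[[i]], config$low_hz, config$high_hz)
      trim_frames(x, config$trim, config$trim)
    })
    mask <- NULL
    if (!is.null(motion)) {
      fd <- stage("preprocess", framewise_displacement(motion[[i]]))
      full_mask <- scrub_mask(fd, config$fd_threshold, config$scrub_after)
      mask <- full_mask[(config$trim + 1L):(length(full_mask) - config$trim)]
    }
    ev <- stage("detect", detect_ts(swpca(ts, config$window_size), mask = mask))
    events_by_run[[i]] <- ev
    f <- file.path(out_dir, sprintf("events_%s.tsv", ev$run_id))
    write_events_tsv(ev, f); emit(f)
  }

  counts <- vapply(events_by_run, function(e) nrow(e$events), 0L)
  names(counts) <- vapply(events_by_run, function(e) e$run_id, "")
  keep_tab <- exclude_low_ts_runs(counts, config$min_ts)
  f <- file.path(out_dir, "run_exclusion.tsv")
  utils::write.table(keep_tab, f, sep = "\t", row.names = FALSE, quote = FALSE); emit(f)
  kept <- which(keep_tab$kept)
  if (!length(kept)) stop("pipeline stage 'detect' failed: no run retained ",
                          sprintf("(all below %d events)", config$min_ts))

  model <- stage("cluster", {
    tsp_all <- do.call(cbind, lapply(events_by_run[kept], `[[`, "tsp"))
    m <- fit_kmeans_corr(tsp_all, k = config$k, n_init = config$n_init,
                         seed = config$seed)
    off <- 0L
    run_ids <- integer(0)
    for (i in kept) {
      n <- nrow(events_by_run[[i]]$events)
      events_by_run[[i]]$events$sub_cluster <- m$labels[off + seq_len(n)]
      run_ids <- c(run_ids, rep(i, n))
      off <- off + n
    }
    tm <- transition_matrix(m$labels, k = config$k, runs = run_ids)
    pair_subclusters(m, tm)
  })
  f <- file.path(out_dir, "centroids.tsv")
  utils::write.table(model$centroids, f, sep = "\t", row.names = FALSE,
                     col.names = paste0("sc", seq_len(model$k)), quote = FALSE); emit(f)
  f <- file.path(out_dir, "model.json")
  jsonlite::write_json(list(k = model$k, inertia = model$inertia, seed = model$seed,
                            sizes = model$sizes, pairing = model$pairing),
                       f, auto_unbox = TRUE, digits = NA); emit(f)

  n_frames <- events_by_run[[kept[1L]]]$n_frames
  occ <- stage("pmi", {
    ev_df <- do.call(rbind, lapply(kept, function(i) {
      e <- events_by_run[[i]]
      data.frame(run = e$run_id,
                 frame = e$events$center - e$frame_offset,
                 sub_cluster = e$events$sub_cluster)
    }))
    occurrence_timecourse(ev_df, n_frames, smooth_w = config$smooth_w,
                          pairing = model$pairing)
  })
  pmi <- stage("pmi", {
    tau_max <- min(config$tau_max, n_frames - 1L)
    if (length(occ$clusters) >= 2L && n_frames > 2L * config$t_trim + 10L &&
        tau_max > config$tau_min)
      suppressWarnings(pmi_decompose_all(occ, tau_max, t_trim = config$t_trim,
                                         tau_min = config$tau_min))
    else NULL
  })
  if (!is.null(pmi) && nrow(pmi)) {
    f <- file.path(out_dir, "pmi_coefficients.tsv")
    utils::write.table(data.frame(pair = rownames(pmi), pmi), f, sep = "\t",
                       row.names = FALSE, quote = FALSE); emit(f)
  }

  glms <- NULL
  if (!is.null(voxel_ts)) {
    glms <- stage("sap", lapply(seq_along(kept), function(j) {
      i <- kept[j]
      e <- events_by_run[[i]]
      des <- build_design(data.frame(frame = e$events$center,
                                     sub_cluster = e$events$sub_cluster),
                          n_frames = ncol(voxel_ts[[i]]), tr = e$tr,
                          trim = config$glm_trim,
                          sub_clusters = seq_len(config$k))
      run_glm(voxel_ts[[i]], des)
    }))
  }

  f <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(list(config = unclass(config),
                            n_runs = length(runs), kept_runs = keep_tab$run[kept],
                            ts_counts = as.list(counts),
                            r_version = as.character(getRversion())),
                       f, auto_unbox = TRUE, digits = NA); emit(f)
  invisible(list(events = events_by_run, model = model, occ = occ, pmi = pmi,
                 glm = glms, manifest = manifest))
}
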