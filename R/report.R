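# Workflow entry points tying the modules into the full analysis sequence:
# simulate -> analyze (frames -> register -> plethysmo) -> validate
# (observer comparison) -> summarize (cohort statistics).  Each run writes
# its outputs, a timestamped plain-text log and a machine-readable
# manifest into a per-run directory.

.log_line <- function(log_path, stage, msg) {
  line <- sprintf("%s  [%s]  %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(line)
}

.write_manifest <- function(out_dir, config) {
  manifest <- list(
    package = "retpulse",
    version = as.character(utils::packageVersion("retpulse")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a synthetic recording to disk
#'
#' Renders a scene and writes the frame stack (PNG sequence), beat-time
#' CSV, ground-truth cluster-amplitude CSV and full-resolution truth mask
#' PNG under `out_dir`.
#'
#' @param spec a [scene_spec], or the name of a [preset_scenes()] entry.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the spec's RNG seed when non-NULL.
#' @return invisibly, the [generate()] result.
#' @export
run_simulate <- function(spec = "clean", out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  if (is.character(spec)) {
    presets <- preset_scenes()
    if (!spec %in% names(presets))
      stop("run_simulate: unknown preset '", spec, "'", call. = FALSE)
    spec <- presets[[spec]]
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  .log_line(log_path, "simulate", sprintf("rendering %dx%d x %d frames",
                                          spec$height, spec$width,
                                          spec$n_frames))
  sim <- generate(spec)
  write_stack(sim$stack, file.path(out_dir, "frames"))
  write_beats(sim$beats, file.path(out_dir, "beats.csv"))
  write_mask(sim$truth$mask_full, file.path(out_dir, "truth_mask.png"))
  tr <- sim$truth$cluster_amplitude
  utils::write.csv(
    data.frame(row = rep(seq_len(nrow(tr)) - 1L, times = ncol(tr)),
               col = rep(seq_len(ncol(tr)) - 1L, each = nrow(tr)),
               amplitude = as.vector(tr)),
    file.path(out_dir, "truth_amplitude.csv"), row.names = FALSE)
  write_scene_json(spec, file.path(out_dir, "scene.json"))
  .write_manifest(out_dir, list(command = "simulate", seed = spec$seed))
  .log_line(log_path, "simulate", "done")
  invisible(sim)
}

#' Run the amplitude-map analysis
#'
#' Full sequence: read stack and beats, align to a reference frame, crop to
#' the commonly visible region, transform the green channel, cluster,
#' regress and write `amplitude.csv` plus `heatmap.png`. The log records
#' the displacement index, illumination index, cluster count and failed-fit
#' count.
#'
#' @param stack_path frame stack path (or a [frame_stack] object).
#' @param beats_path beat-time CSV path (or a [beat_times] object).
#' @param out_dir output directory.
#' @param skip_alignment bypass registration (for pre-aligned or jitter-free
#'   input).
#' @param reference_index reference frame for alignment.
#' @param cluster_size,n_harmonics,scale_factor,phase_grid analysis
#'   parameters (see [cluster_means()], [amplitude_map()],
#'   [beer_lambert_transform()]).
#' @param fps frames per second when reading from disk.
#' @return invisibly, a list with `map` (the `amplitude_map`),
#'   `illumination`, `displacement`, and `stack` (the analyzed stack).
#' @export
run_analyze <- function(stack_path, beats_path, out_dir,
                        skip_alignment = FALSE, reference_index = 1L,
                        cluster_size = 5L, n_harmonics = 2L,
                        scale_factor = 68, phase_grid = 1000L, fps = 25) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  stack <- if (inherits(stack_path, "frame_stack")) stack_path
           else read_stack(stack_path, fps = fps)
  beats <- if (inherits(beats_path, "beat_times")) beats_path
           else read_beats(beats_path)
  .log_line(log_path, "frames", sprintf("%d frames, %dx%d px",
                                        length(stack), stack$height,
                                        stack$width))
  illum <- illumination_index(stack)
  .log_line(log_path, "frames", sprintf("illumination mean %.2f sd %.3f",
                                        illum$mean_intensity,
                                        illum$sd_intensity))
  disp <- 0
  if (!skip_alignment) {
    ar <- align_stack(stack, reference_index)
    disp <- displacement_index(ar)
    .log_line(log_path, "register",
              sprintf("displacement index %.2f px (max dx %.2f, dy %.2f); crop [%s]",
                      disp, ar$max_dx, ar$max_dy,
                      paste(ar$crop_box, collapse = ",")))
    write_transforms(ar, file.path(out_dir, "transforms.csv"))
    stack <- crop_common(ar)
  } else {
    .log_line(log_path, "register", "skipped (pre-aligned input)")
  }
  phase <- compute_phase(stack, beats)
  green <- extract_green(stack)
  transformed <- lapply(green, beer_lambert_transform,
                        scale_factor = scale_factor,
                        bit_depth = stack$bit_depth)
  cube <- cluster_means(transformed, phase = phase,
                        cluster_size = cluster_size)
  .log_line(log_path, "plethysmo", sprintf("%d x %d = %d clusters",
                                           cube$n_rows, cube$n_cols,
                                           cube$n_rows * cube$n_cols))
  map <- amplitude_map(cube, beats, n_harmonics = n_harmonics,
                       phase_grid = phase_grid)
  .log_line(log_path, "plethysmo", sprintf("failed fits: %d",
                                           sum(map$failed)))
  write_amplitude_csv(map, file.path(out_dir, "amplitude.csv"))
  write_heatmap_png(map, file.path(out_dir, "heatmap.png"))
  .write_manifest(out_dir, list(
    command = "analyze", skip_alignment = skip_alignment,
    cluster_size = cluster_size, n_harmonics = n_harmonics,
    scale_factor = scale_factor, phase_grid = phase_grid))
  .log_line(log_path, "analyze", "done")
  invisible(list(map = map, illumination = illum, displacement = disp,
                 stack = stack))
}

#' Compare an amplitude map against observer masks
#'
#' Computes the threshold-sweep ROC, AUC, ideal threshold and critical
#' amplitudes per observer; Cohen's kappa when two masks are given; writes
#' `roc_<observer>.csv`, an overlay PNG at the requested threshold, and
#' `summary.json`.
#'
#' @param map an `amplitude_map` or an `amplitude.csv` path.
#' @param masks named list/character vector of observer masks
#'   (full-resolution binary matrices or PNG paths).
#' @param out_dir output directory.
#' @param threshold overlay threshold; default the first observer's ideal.
#' @param thresholds integer thresholds for the sweep.
#' @return invisibly, list of per-observer `roc_result`s plus `kappa`.
#' @export
run_validate <- function(map, masks, out_dir, threshold = NULL,
                         thresholds = 0:40) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  if (is.character(map)) {
    df <- utils::read.csv(map)
    amp <- matrix(0, max(df$row) + 1L, max(df$col) + 1L)
    amp[cbind(df$row + 1L, df$col + 1L)] <- df$amplitude
  } else {
    amp <- if (inherits(map, "amplitude_map")) map$amplitude else map
  }
  if (is.null(names(masks)))
    names(masks) <- paste0("observer", seq_along(masks))
  grids <- lapply(masks, function(m) {
    full <- if (is.character(m)) read_mask(m) else m
    g <- downscale_mask(full)
    if (!all(dim(g) == dim(amp)))
      stop("run_validate: observer mask grid does not match amplitude map",
           call. = FALSE)
    g
  })
  rocs <- list()
  for (nm in names(grids)) {
    roc <- roc_sweep(amp, grids[[nm]], thresholds)
    rocs[[nm]] <- roc
    write_roc_csv(roc, file.path(out_dir, paste0("roc_", nm, ".csv")))
    .log_line(log_path, "validate",
              sprintf("%s: auc %.4f, ideal threshold %d, critical amplitude %.2f",
                      nm, roc$auc, roc$ideal_threshold,
                      roc$critical_amplitude))
  }
  kappa <- NULL
  if (length(grids) >= 2L) {
    kappa <- cohens_kappa(grids[[1L]], grids[[2L]])
    .log_line(log_path, "validate", sprintf("kappa %.4f", kappa))
  }
  if (is.null(threshold)) threshold <- rocs[[1L]]$ideal_threshold
  write_overlay_png(amp, grids[[1L]], threshold,
                    file.path(out_dir, "overlay.png"))
  summary <- list(
    observers = lapply(rocs, function(r)
      list(auc = r$auc, ideal_threshold = r$ideal_threshold,
           critical_amplitude = r$critical_amplitude,
           n_regions = nrow(r$regions))),
    kappa = kappa, overlay_threshold = threshold)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out_dir, list(command = "validate",
                                overlay_threshold = threshold))
  invisible(c(rocs, list(kappa = kappa)))
}

#' Summarize per-eye results across a cohort
#'
#' Reads a per-eye results CSV (see [read_eye_records()]), computes medians
#' and back-transformed log-scale confidence intervals, and writes
#' `summary.json` plus a markdown table.
#'
#' @param records_path per-eye CSV path or a data.frame.
#' @param out_dir output directory.
#' @param confidence confidence level (default 0.95).
#' @return invisibly, the [summarize_eyes()] result.
#' @export
run_summarize <- function(records_path, out_dir, confidence = 0.95) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (is.data.frame(records_path)) records_path
             else read_eye_records(records_path)
  s <- summarize_eyes(records, confidence)
  out <- list(
    n_eyes = s$n_eyes,
    auc_median = s$auc_median,
    ideal_threshold = s$ideal_threshold,
    critical_amplitude = s$critical_amplitude,
    transform = s$transform)
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c(
    "| quantity | median | ci_low | ci_high | n |",
    "|---|---|---|---|---|",
    sprintf("| ideal threshold (units) | %g | %.1f | %.1f | %d |",
            s$ideal_threshold$median, s$ideal_threshold$ci_low,
            s$ideal_threshold$ci_high, s$n_eyes),
    sprintf("| critical amplitude (units) | %g | %.1f | %.1f | %d |",
            s$critical_amplitude$median, s$critical_amplitude$ci_low,
            s$critical_amplitude$ci_high, s$n_eyes),
    sprintf("| AU-ROC | %.2f | | | %d |", s$auc_median, s$n_eyes))
  writeLines(md, file.path(out_dir, "summary.md"))
  .write_manifest(out_dir, list(command = "summarize",
                                confidence = confidence))
  invisible(s)
}
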