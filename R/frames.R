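# ---- FrameStack -------------------------------------------------------------

#' Construct a frame stack
#'
#' A `frame_stack` is a time-ordered sequence of RGB fundus video frames with
#' a nominal frame rate. Frames are stored as `H x W x 3` integer arrays in
#' native camera units (8-bit by default); timestamps are `index / fps`
#' seconds, starting at 0.
#'
#' @param frames list of `H x W x 3` numeric arrays, all the same size.
#' @param fps frames per second (default 25, the usual fundus video rate).
#' @param bit_depth camera bit depth; intensities lie in `[0, 2^bit_depth - 1]`.
#' @return An object of class `frame_stack` with fields `frames`,
#'   `timestamps`, `fps`, `height`, `width`, `bit_depth`.
#' @export
frame_stack <- function(frames, fps = 25, bit_depth = 8) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("frame_stack: need at least 2 frames", call. = FALSE)
  dims <- lapply(frames, dim)
  d0 <- dims[[1L]]
  if (is.null(d0) || length(d0) != 3L || d0[3L] != 3L)
    stop("frame_stack: frames must be H x W x 3 RGB arrays", call. = FALSE)
  same <- vapply(dims, function(d) length(d) == 3L && all(d == d0), logical(1))
  if (!all(same))
    stop("frame_stack: frames have mixed dimensions", call. = FALSE)
  if (fps <= 0) stop("frame_stack: fps must be > 0", call. = FALSE)
  structure(list(
    frames = frames,
    timestamps = (seq_along(frames) - 1) / fps,
    fps = fps,
    height = d0[1L], width = d0[2L],
    bit_depth = bit_depth
  ), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames, %d x %d px, %.6g fps, %d-bit (%.2f s)\n",
              length(x$frames), x$height, x$width, x$fps, x$bit_depth,
              utils::tail(x$timestamps, 1)))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Read a frame stack from disk
#'
#' Accepts either a multi-page TIFF file or a directory of numbered
#' PNG/TIFF frames (lexicographic filename order defines time order).
#' Pixel values are returned in native integer units.
#'
#' @param path multi-page TIFF file, or directory of `frame_*.png`/`.tif`.
#' @param fps frames per second used to assign timestamps.
#' @param bit_depth camera bit depth of the stored images.
#' @return A [frame_stack].
#' @export
read_stack <- function(path, fps = 25, bit_depth = 8) {
  maxval <- 2^bit_depth - 1
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L)
      stop("read_stack: need at least 2 frames in ", path, call. = FALSE)
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE))
        png::readPNG(f) else tiff::readTIFF(f)
      .as_rgb_int(img, maxval, f)
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("read_stack: need at least 2 pages in ", path, call. = FALSE)
    frames <- lapply(pages, .as_rgb_int, maxval = maxval, src = path)
  } else {
    stop("read_stack: path not found: ", path, call. = FALSE)
  }
  d0 <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) all(dim(f) == d0), logical(1))
  if (!all(ok))
    stop("read_stack: frames have mixed sizes", call. = FALSE)
  frame_stack(frames, fps = fps, bit_depth = bit_depth)
}

# readPNG/readTIFF return [0,1] doubles; rescale to integer camera units.
.as_rgb_int <- function(img, maxval, src) {
  if (length(dim(img)) == 2L)
    stop("read_stack: greyscale image (need RGB): ", src, call. = FALSE)
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3L] != 3L)
    stop("read_stack: unsupported channel count in ", src, call. = FALSE)
  round(img * maxval)
}

#' Write a frame stack to disk
#'
#' Writes either a multi-page TIFF (when `path` ends in `.tif`/`.tiff`) or a
#' directory of `frame_%04d.png` files. The round trip through
#' [read_stack()] preserves pixel values exactly.
#'
#' @param stack a [frame_stack].
#' @param path output file or directory.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  maxval <- 2^stack$bit_depth - 1
  norm <- lapply(stack$frames, function(f) f / maxval)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(norm))
      png::writePNG(norm[[i]], file.path(path, sprintf("frame_%04d.png", i)))
  }
  invisible(path)
}

#' Extract the green channel of every frame
#'
#' @param stack a [frame_stack].
#' @return list of `H x W` matrices, values unchanged from the stored frames.
#' @export
extract_green <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  lapply(stack$frames, function(f) f[, , 2L])
}

# ---- BeatTimes --------------------------------------------------------------

#' Cardiac beat-onset times
#'
#' @param onsets strictly increasing beat-onset times in seconds; at least 4
#'   onsets are required so that at least 3 full cardiac cycles are bounded.
#' @return An object of class `beat_times`.
#' @export
beat_times <- function(onsets) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 4L)
    stop("beat_times: need >= 4 onsets (>= 3 complete cycles)", call. = FALSE)
  d <- diff(onsets)
  if (any(d <= 0))
    stop("beat_times: onsets must be strictly increasing", call. = FALSE)
  if (any(d <= 0.2))
    stop("beat_times: cycle length <= 0.2 s is implausible", call. = FALSE)
  structure(list(onsets = onsets), class = "beat_times")
}

#' Read beat times from CSV
#'
#' The file must have a header column `time_s`, one row per beat onset.
#'
#' @param path CSV file path.
#' @return A [beat_times] object.
#' @export
read_beats <- function(path) {
  if (!file.exists(path))
    stop("read_beats: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df))
    stop("read_beats: CSV must have a 'time_s' column", call. = FALSE)
  beat_times(df$time_s)
}

#' Write beat times to CSV
#' @param beats a [beat_times] object.
#' @param path output CSV path.
#' @export
write_beats <- function(beats, path) {
  utils::write.csv(data.frame(time_s = beats$onsets), path, row.names = FALSE)
  invisible(path)
}

# ---- PhaseVector ------------------------------------------------------------

#' Map each frame to a cardiac phase
#'
#' Phase is normalized per cycle: a frame at time `t` in
#' `[onset_k, onset_{k+1})` gets phase `(t - onset_k) / (onset_{k+1} - onset_k)`
#' and cycle index `k` (1-based). Frames before the first onset or at/after
#' the last onset are flagged excluded and take part in no regression.
#'
#' @param stack a [frame_stack].
#' @param beats a [beat_times] object; must bound at least 3 complete cycles
#'   that overlap the stack's time range.
#' @return An object of class `phase_vector` with fields `phase` (in `[0,1)`,
#'   `NA` for excluded frames), `cycle_index`, `included` (logical), and
#'   `time` (frame timestamps).
#' @export
compute_phase <- function(stack, beats) {
  stopifnot(inherits(stack, "frame_stack"), inherits(beats, "beat_times"))
  t <- stack$timestamps
  on <- beats$onsets
  k <- findInterval(t, on)                 # 0 = before first onset
  included <- k >= 1L & t < on[length(on)]
  phase <- rep(NA_real_, length(t))
  ki <- k[included]
  phase[included] <- (t[included] - on[ki]) / (on[ki + 1L] - on[ki])
  # coverage: count complete cycles with at least one included frame
  cycles_hit <- length(unique(ki))
  if (cycles_hit < 3L)
    stop("compute_phase: fewer than 3 complete cardiac cycles overlap the stack",
         call. = FALSE)
  structure(list(phase = phase,
                 cycle_index = ifelse(included, k, NA_integer_),
                 included = included,
                 time = t),
            class = "phase_vector")
}
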