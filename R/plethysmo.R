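# Core photo-plethysmographic signal model.
#
# Green-channel intensities are converted to absorbance-scale values by a
# Beer-Lambert negative-log transform (haemoglobin path length is
# proportional to -log transmittance), averaged over non-overlapping
# 5x5-pixel clusters, and each cluster time series is fit by harmonic
# regression on cardiac phase with a continuous piecewise-linear time term
# absorbing patient movement and slow illumination drift.  Pulsation
# amplitude is the peak-to-trough range of the fitted periodic component.

#' Beer-Lambert absorbance transform
#'
#' Converts green-channel intensity to absorbance-scale "paper units":
#' `value = scale_factor * (-log10(I / maxval))`. The scale factor 68
#' converts the base-10 absorbance to a nominal half optical path length in
#' microns through haemoglobin (values remain arbitrary units; no absolute
#' micron calibration is claimed). Zero intensities are clamped to half the
#' least count so the transform stays finite.
#'
#' @param green numeric vector/matrix of raw green intensities.
#' @param scale_factor multiplier applied to the negative log (default 68).
#' @param bit_depth camera bit depth defining `maxval = 2^bit_depth - 1`.
#' @return transformed values, same shape as `green`; 0 at full
#'   transmittance, strictly decreasing in intensity.
#' @export
beer_lambert_transform <- function(green, scale_factor = 68, bit_depth = 8) {
  if (any(green < 0)) stop("beer_lambert_transform: negative intensity",
                           call. = FALSE)
  maxval <- 2^bit_depth - 1
  inorm <- pmax(green / maxval, 1 / (2 * maxval))
  out <- scale_factor * (-log10(inorm))
  if (is.matrix(green)) dim(out) <- dim(green)
  out
}

#' Cluster means over a 5x5 tiling
#'
#' Breaks each transformed frame into non-overlapping `cluster_size` x
#' `cluster_size` tiles anchored at the top-left pixel, dropping any
#' trailing remainder rows/columns, and stores the arithmetic mean of each
#' tile. The result is a `cluster_cube` with one layer per retained frame.
#'
#' @param transformed list of `H x W` matrices of transformed green values
#'   (one per frame), or a [frame_stack] whose green channel will be
#'   transformed with [beer_lambert_transform()] defaults.
#' @param phase a [compute_phase()] result carried along for regression.
#' @param cluster_size tile side in pixels (default 5).
#' @return A `cluster_cube`: `values` is an `n_rows x n_cols x n_frames`
#'   array (paper units), plus `phase`, `cluster_size`, `n_rows`, `n_cols`.
#' @export
cluster_means <- function(transformed, phase = NULL, cluster_size = 5L) {
  if (inherits(transformed, "frame_stack"))
    transformed <- lapply(extract_green(transformed), beer_lambert_transform,
                          bit_depth = transformed$bit_depth)
  stopifnot(is.list(transformed))
  h <- nrow(transformed[[1L]]); w <- ncol(transformed[[1L]])
  if (h < cluster_size || w < cluster_size)
    stop("cluster_means: frame smaller than one cluster", call. = FALSE)
  nr <- h %/% cluster_size; nc <- w %/% cluster_size
  vals <- vapply(transformed, function(m) {
    m <- m[seq_len(nr * cluster_size), seq_len(nc * cluster_size)]
    # block means: average rows within bands, then columns
    rowband <- matrix(colMeans(matrix(m, nrow = cluster_size)), nrow = nr)
    t(matrix(colMeans(matrix(t(rowband), nrow = cluster_size)), nrow = nc))
  }, matrix(0, nr, nc))
  vals <- array(vals, c(nr, nc, length(transformed)))  # 1x1 grids lose dims
  structure(list(values = vals, phase = phase,
                 cluster_size = as.integer(cluster_size),
                 n_rows = nr, n_cols = nc),
            class = "cluster_cube")
}

# harmonic + linear-spline design matrix for the included frames
.harmonic_design <- function(phase, beats, n_harmonics) {
  inc <- phase$included
  ph <- phase$phase[inc]
  tt <- phase$time[inc]
  X <- matrix(1, sum(inc), 1L)
  colnames(X) <- "intercept"
  for (k in seq_len(n_harmonics)) {
    X <- cbind(X, cos(2 * pi * k * ph), sin(2 * pi * k * ph))
    colnames(X)[ncol(X) - 1:0] <- paste0(c("cos", "sin"), k)
  }
  # continuous piecewise-linear time basis, knots at interior beat onsets
  knots <- beats$onsets[-c(1L, length(beats$onsets))]
  Xs <- cbind(tt, outer(tt, knots, function(t, k) pmax(t - k, 0)))
  colnames(Xs) <- c("t", if (length(knots)) paste0("spline", seq_along(knots)))
  X <- cbind(X, Xs)
  list(X = X, included = inc, n_harmonics = n_harmonics)
}

#' Harmonic regression of one cluster time series on cardiac phase
#'
#' Ordinary least squares of the series on an intercept, `cos(2*pi*k*phase)`
#' and `sin(2*pi*k*phase)` for `k = 1..n_harmonics`, and a continuous
#' piecewise-linear function of absolute time with knots at the interior
#' beat onsets (one linear segment per cardiac cycle) which absorbs
#' movement artefact and slow drift. Only frames inside complete cardiac
#' cycles enter the fit.
#'
#' @param series numeric vector, one value per frame of the stack.
#' @param phase a `phase_vector` from [compute_phase()].
#' @param beats the [beat_times] used to compute `phase`.
#' @param n_harmonics number of harmonics (default 2; the second captures
#'   the dicrotic shape of the pulse wave).
#' @return A `harmonic_fit` with `coefficients`, `harmonics` (data.frame of
#'   `a_k`, `b_k`), `residual_variance`, `n_harmonics`, and
#'   `periodic` — function of phase evaluating the fitted periodic
#'   component (harmonics only, intercept and spline excluded).
#' @export
fit_harmonic <- function(series, phase, beats, n_harmonics = 2L) {
  des <- .harmonic_design(phase, beats, n_harmonics)
  y <- series[des$included]
  if (length(y) < ncol(des$X) + 1L)
    stop("fit_harmonic: fewer observations than regression parameters",
         call. = FALSE)
  fit <- stats::lm.fit(des$X, y)
  if (any(is.na(fit$coefficients)))
    stop("fit_harmonic: rank-deficient design", call. = FALSE)
  cf <- fit$coefficients
  a <- cf[paste0("cos", seq_len(n_harmonics))]
  b <- cf[paste0("sin", seq_len(n_harmonics))]
  rv <- sum(fit$residuals^2) / max(1L, length(y) - ncol(des$X))
  structure(list(
    coefficients = cf,
    harmonics = data.frame(k = seq_len(n_harmonics), a = unname(a),
                           b = unname(b)),
    residual_variance = rv,
    n_harmonics = n_harmonics,
    periodic = function(ph) {
      out <- numeric(length(ph))
      for (k in seq_len(n_harmonics))
        out <- out + a[k] * cos(2 * pi * k * ph) + b[k] * sin(2 * pi * k * ph)
      out
    }), class = "harmonic_fit")
}

# peak-to-trough range of the periodic component given harmonic coefficients;
# dense phase grid plus analytic-derivative sign-change refinement
.amplitude_from_harmonics <- function(a, b, phase_grid = 1000L) {
  K <- length(a)
  if (all(abs(c(a, b)) < .Machine$double.eps^0.75)) return(0)
  ph <- seq(0, 1, length.out = phase_grid + 1L)[-(phase_grid + 1L)]
  cval <- function(p) {
    out <- 0
    for (k in seq_len(K))
      out <- out + a[k] * cos(2 * pi * k * p) + b[k] * sin(2 * pi * k * p)
    out
  }
  dval <- function(p) {
    out <- 0
    for (k in seq_len(K))
      out <- out + 2 * pi * k * (-a[k] * sin(2 * pi * k * p) +
                                   b[k] * cos(2 * pi * k * p))
    out
  }
  v <- cval(ph)
  d <- dval(ph)
  # refine each derivative sign change to a root, evaluate the extremum there
  sgn <- sign(d)
  flips <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  extrema <- v
  if (length(flips)) {
    roots <- vapply(flips, function(i)
      stats::uniroot(dval, c(ph[i], ph[i + 1L]), tol = 1e-12)$root, 0)
    extrema <- c(extrema, cval(roots))
  }
  max(extrema) - min(extrema)
}

#' Pulsation amplitude of a fitted cluster
#'
#' Amplitude is the peak-to-trough range of the fitted periodic component
#' `c(phase)` over one cardiac cycle, with extrema located where the
#' analytic derivative changes sign (refined from a 1000-point phase grid).
#' The intercept and the movement spline are excluded: they model artefact,
#' not pulsation.
#'
#' @param fit a `harmonic_fit` from [fit_harmonic()].
#' @param phase_grid number of phase grid points (default 1000).
#' @return non-negative amplitude in paper units.
#' @export
amplitude_from_fit <- function(fit, phase_grid = 1000L) {
  stopifnot(inherits(fit, "harmonic_fit"))
  .amplitude_from_harmonics(fit$harmonics$a, fit$harmonics$b, phase_grid)
}

#' Per-cluster pulsation amplitude map
#'
#' Fits the harmonic regression independently to every cluster of the cube
#' and extracts the peak-to-trough amplitude of each periodic component.
#' All clusters share one design matrix, so the least-squares problem is
#' solved with a single QR decomposition. Clusters whose fit fails get
#' amplitude 0 and are flagged.
#'
#' @param cube a `cluster_cube` from [cluster_means()] (must carry `phase`).
#' @param beats the [beat_times] for the recording.
#' @param n_harmonics harmonics in the regression (default 2).
#' @param phase_grid phase grid resolution for amplitude extraction.
#' @return An `amplitude_map`: `amplitude` is an `n_rows x n_cols` matrix
#'   (paper units), `failed` a logical matrix of failed fits, plus grid
#'   geometry fields.
#' @export
amplitude_map <- function(cube, beats, n_harmonics = 2L, phase_grid = 1000L) {
  stopifnot(inherits(cube, "cluster_cube"))
  if (is.null(cube$phase))
    stop("amplitude_map: cluster_cube carries no phase information",
         call. = FALSE)
  des <- .harmonic_design(cube$phase, beats, n_harmonics)
  nr <- cube$n_rows; nc <- cube$n_cols
  nf <- dim(cube$values)[3L]
  Y <- t(matrix(cube$values, nr * nc, nf))[des$included, , drop = FALSE]
  qrX <- qr(des$X)
  if (qrX$rank < ncol(des$X))
    stop("amplitude_map: rank-deficient harmonic design", call. = FALSE)
  B <- qr.coef(qrX, Y)                          # p x (nr*nc)
  rownames(B) <- colnames(des$X)
  a <- B[paste0("cos", seq_len(n_harmonics)), , drop = FALSE]
  b <- B[paste0("sin", seq_len(n_harmonics)), , drop = FALSE]
  amp <- numeric(nr * nc)
  failed <- logical(nr * nc)
  for (j in seq_len(nr * nc)) {
    aj <- a[, j]; bj <- b[, j]
    if (any(!is.finite(c(aj, bj)))) {
      failed[j] <- TRUE
      amp[j] <- 0
    } else {
      amp[j] <- .amplitude_from_harmonics(aj, bj, phase_grid)
    }
  }
  if (mean(failed) > 0.10)
    stop(sprintf("amplitude_map: %.1f%% of cluster fits failed",
                 100 * mean(failed)), call. = FALSE)
  if (any(failed))
    warning(sprintf("amplitude_map: %d cluster fits failed (amplitude set to 0)",
                    sum(failed)), call. = FALSE)
  structure(list(amplitude = matrix(amp, nr, nc),
                 failed = matrix(failed, nr, nc),
                 n_rows = nr, n_cols = nc,
                 cluster_size = cube$cluster_size),
            class = "amplitude_map")
}

#' Whole-frame illumination index
#'
#' Mean and standard deviation across frames of the whole-frame average raw
#' green intensity; the standard deviation indexes how varied the
#' illumination was during the recording.
#'
#' @param stack a [frame_stack].
#' @return An `illumination_index` list: `mean_intensity`, `sd_intensity`,
#'   `frame_means`.
#' @export
illumination_index <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  fm <- vapply(extract_green(stack), mean, 0)
  structure(list(mean_intensity = mean(fm),
                 sd_intensity = stats::sd(fm),
                 frame_means = fm),
            class = "illumination_index")
}

#' Write an amplitude map as CSV
#'
#' Long format: `row`, `col` (0-based cluster indices), `amplitude`.
#'
#' @param map an `amplitude_map`.
#' @param path output CSV path.
#' @export
write_amplitude_csv <- function(map, path) {
  df <- data.frame(
    row = rep(seq_len(map$n_rows) - 1L, times = map$n_cols),
    col = rep(seq_len(map$n_cols) - 1L, each = map$n_rows),
    amplitude = as.vector(map$amplitude))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render an amplitude map as a heat-map PNG
#'
#' Perceptually uniform (viridis) ramp over a fixed 0-40 unit scale so maps
#' from different runs are comparable; values above the scale maximum are
#' saturated.
#'
#' @param map an `amplitude_map`.
#' @param path output PNG path.
#' @param zmax top of the colour scale (default 40 units).
#' @export
write_heatmap_png <- function(map, path, zmax = 40) {
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- pmin(pmax(round(map$amplitude / zmax * 255) + 1, 1), 256)
  rgbv <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(0, c(map$n_rows, map$n_cols, 3))
  img[, , 1] <- matrix(rgbv[1, ], map$n_rows, map$n_cols)
  img[, , 2] <- matrix(rgbv[2, ], map$n_rows, map$n_cols)
  img[, , 3] <- matrix(rgbv[3, ], map$n_rows, map$n_cols)
  png::writePNG(img, path)
  invisible(path)
}
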