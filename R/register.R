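# Intensity-based affine registration of fundus video frames.
#
# Each frame is warped towards a reference frame by the affine transform
# (tx, ty, rot, shear, scale) minimizing the mean squared green-channel
# difference.  Warping uses bilinear interpolation with an explicit per-pixel
# validity flag for source coordinates that fall outside the moving frame, so
# the common-area crop is exact.

# Affine map from reference pixel coords to moving-frame coords, about the
# image centre:  src = scale * R(rot) * Shear(shear) * (dst - c) + c + (tx,ty)
# where x = column, y = row.  A frame whose content is displaced by (+tx,+ty)
# pixels relative to the reference is brought back by these parameters.
.affine_matrix <- function(par) {
  rot <- par[["rot"]]; shear <- par[["shear"]]; scale <- par[["scale"]]
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L, 2L)
  S <- matrix(c(1, 0, shear, 1), 2L, 2L)
  scale * R %*% S
}

.identity_par <- c(tx = 0, ty = 0, rot = 0, shear = 0, scale = 1)

#' Warp an image by an affine transform
#'
#' Samples `img` at affine-transformed coordinates with bilinear
#' interpolation. Pixels whose source coordinates fall outside `img` are
#' returned as 0 and flagged invalid.
#'
#' @param img numeric matrix (one channel).
#' @param par named vector `c(tx, ty, rot, shear, scale)`; rotation in
#'   radians about the image centre, translations in pixels.
#' @return list with `img` (warped matrix) and `valid` (logical matrix).
#' @export
warp_affine <- function(img, par) {
  par <- .full_par(par)
  h <- nrow(img); w <- ncol(img)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  A <- .affine_matrix(par)
  # destination grid, centred
  xs <- rep(seq_len(w), each = h) - cx
  ys <- rep(seq_len(h), times = w) - cy
  sx <- A[1, 1] * xs + A[1, 2] * ys + cx + par[["tx"]]
  sy <- A[2, 1] * xs + A[2, 2] * ys + cy + par[["ty"]]
  valid <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  x0 <- pmin(pmax(floor(sx), 1), w - 1)
  y0 <- pmin(pmax(floor(sy), 1), h - 1)
  fx <- sx - x0; fy <- sy - y0
  i00 <- y0 + (x0 - 1) * h
  v <- (1 - fx) * ((1 - fy) * img[i00]     + fy * img[i00 + 1]) +
       fx       * ((1 - fy) * img[i00 + h] + fy * img[i00 + h + 1])
  v[!valid] <- 0
  list(img = matrix(v, h, w), valid = matrix(valid, h, w))
}

.full_par <- function(par) {
  out <- .identity_par
  if (is.null(names(par))) {
    out[seq_along(par)] <- par
  } else {
    out[names(par)] <- par
  }
  out
}

# block-mean downsample by integer factor (trailing remainder cropped)
.downsample <- function(img, f) {
  if (f <= 1L) return(img)
  h <- (nrow(img) %/% f) * f; w <- (ncol(img) %/% f) * f
  img <- img[seq_len(h), seq_len(w)]
  m <- matrix(img, nrow = f)
  m <- colMeans(m)                       # (h/f) * w values
  m <- matrix(m, nrow = h %/% f)
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w %/% f))
}

# integer translation estimate via FFT cross-correlation (mean-removed)
.xcorr_shift <- function(ref, mov) {
  h <- nrow(ref); w <- ncol(ref)
  r <- ref - mean(ref); m <- mov - mean(mov)
  cc <- Re(stats::fft(stats::fft(m) * Conj(stats::fft(r)), inverse = TRUE))
  k <- which.max(cc) - 1L
  dy <- k %% h; dx <- k %/% h
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(tx = dx, ty = dy)
}

.mse_objective <- function(par, ref, mov) {
  wp <- warp_affine(mov, par)
  n <- sum(wp$valid)
  if (n < 0.25 * length(ref)) return(1e12)
  sum((wp$img[wp$valid] - ref[wp$valid])^2) / n
}

# register one moving frame to the reference green channel
.register_frame <- function(ref, mov) {
  if (identical(dim(ref), dim(mov)) && isTRUE(all.equal(ref, mov)))
    return(.identity_par)
  f <- max(1L, floor(min(dim(ref)) / 64))
  ref_s <- .downsample(ref, f); mov_s <- .downsample(mov, f)
  init <- .xcorr_shift(ref_s, mov_s) * f
  # coarse: translation + rotation at reduced resolution
  p0 <- c(tx = init[["tx"]] / f, ty = init[["ty"]] / f, rot = 0)
  o1 <- stats::optim(p0, function(p) .mse_objective(p, ref_s, mov_s),
                     method = "Nelder-Mead",
                     control = list(maxit = 300, reltol = 1e-8))
  # mid: full affine at half resolution
  ref_m <- .downsample(ref, 2L); mov_m <- .downsample(mov, 2L)
  p1 <- c(tx = o1$par[["tx"]] * f / 2, ty = o1$par[["ty"]] * f / 2,
          rot = o1$par[["rot"]], shear = 0, scale = 1)
  o2 <- stats::optim(p1, function(p) .mse_objective(p, ref_m, mov_m),
                     method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-10,
                                    parscale = c(1, 1, 0.01, 0.01, 0.01)))
  # fine: short polish at native resolution
  p2 <- o2$par; p2[c("tx", "ty")] <- p2[c("tx", "ty")] * 2
  o3 <- stats::optim(p2, function(p) .mse_objective(p, ref, mov),
                     method = "Nelder-Mead",
                     control = list(maxit = 150, reltol = 1e-9,
                                    parscale = c(1, 1, 0.01, 0.01, 0.01)))
  .full_par(o3$par)
}

#' Align all frames of a stack to a reference frame
#'
#' Affine registration (translation, rotation, shear, scale) of every frame
#' to the reference frame, driven by mean-squared green-channel difference
#' with a multi-resolution search (FFT cross-correlation translation
#' initializer, then Nelder-Mead refinement). All three colour channels are
#' warped by the recovered transform.
#'
#' @param stack a [frame_stack].
#' @param reference_index index of the reference frame (default 1).
#' @return An `alignment_result` with fields `aligned` (warped
#'   [frame_stack]), `valid` (list of logical matrices flagging in-view
#'   pixels), `transforms` (data.frame: frame, tx, ty, rot, shear, scale),
#'   `max_dx`, `max_dy` (maximum pairwise translation spans, px),
#'   `reference_index`, and `crop_box` (largest all-valid rectangle,
#'   `c(row0, col0, row1, col1)` half-open, 0-based).
#' @export
align_stack <- function(stack, reference_index = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (reference_index < 1L || reference_index > n)
    stop("align_stack: reference_index out of range", call. = FALSE)
  green <- extract_green(stack)
  ref <- green[[reference_index]]
  pars <- vector("list", n)
  aligned <- vector("list", n)
  valid <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == reference_index) {
      pars[[i]] <- .identity_par
      aligned[[i]] <- stack$frames[[i]]
      valid[[i]] <- matrix(TRUE, stack$height, stack$width)
      next
    }
    p <- tryCatch(.register_frame(ref, green[[i]]),
                  error = function(e)
                    stop(sprintf("align_stack: registration failed on frame %d: %s",
                                 i, conditionMessage(e)), call. = FALSE))
    pars[[i]] <- p
    fr <- stack$frames[[i]]
    out <- array(0, dim(fr))
    wv <- NULL
    for (ch in 1:3) {
      wp <- warp_affine(fr[, , ch], p)
      out[, , ch] <- wp$img
      wv <- wp$valid
    }
    aligned[[i]] <- out
    valid[[i]] <- wv
  }
  tf <- do.call(rbind, lapply(pars, function(p) as.data.frame(as.list(p))))
  tf <- cbind(frame = seq_len(n), tf)
  max_dx <- diff(range(tf$tx))
  max_dy <- diff(range(tf$ty))
  astack <- frame_stack(aligned, fps = stack$fps, bit_depth = stack$bit_depth)
  structure(list(aligned = astack, valid = valid, transforms = tf,
                 max_dx = max_dx, max_dy = max_dy,
                 reference_index = reference_index,
                 crop_box = .largest_valid_box(Reduce(`&`, valid))),
            class = "alignment_result")
}

# largest all-TRUE axis-aligned rectangle (histogram-stack algorithm);
# returns c(row0, col0, row1, col1), half-open, 0-based
.largest_valid_box <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  heights <- integer(w)
  best <- c(0L, 0L, 0L, 0L); best_area <- 0L
  for (r in seq_len(h)) {
    heights <- ifelse(mask[r, ], heights + 1L, 0L)
    # largest rectangle in histogram via stack
    st_col <- integer(0); st_h <- integer(0)
    for (cidx in seq_len(w + 1L)) {
      cur <- if (cidx <= w) heights[cidx] else 0L
      start <- cidx
      while (length(st_h) && utils::tail(st_h, 1) > cur) {
        hh <- utils::tail(st_h, 1); cc <- utils::tail(st_col, 1)
        st_h <- st_h[-length(st_h)]; st_col <- st_col[-length(st_col)]
        area <- hh * (cidx - cc)
        if (area > best_area) {
          best_area <- area
          best <- c(r - hh, cc - 1L, r, cidx - 1L)
        }
        start <- cc
      }
      st_col <- c(st_col, start); st_h <- c(st_h, cur)
    }
  }
  if (best_area == 0L)
    stop("crop_common: no pixel is valid in every frame", call. = FALSE)
  as.integer(best)
}

#' Recording movement index
#'
#' The Pythagorean combination of the maximum horizontal and vertical
#' frame displacements over the recording:
#' `sqrt(max_dx^2 + max_dy^2)`, in pixels.
#'
#' @param x an `alignment_result`, or the maximum horizontal displacement.
#' @param dy maximum vertical displacement when `x` is numeric.
#' @return displacement index in pixels.
#' @export
displacement_index <- function(x, dy = NULL) {
  if (inherits(x, "alignment_result")) {
    sqrt(x$max_dx^2 + x$max_dy^2)
  } else {
    stopifnot(is.numeric(x), is.numeric(dy))
    sqrt(x^2 + dy^2)
  }
}

#' Crop an aligned stack to the commonly visible region
#'
#' Returns the largest axis-aligned rectangle whose pixels are in view in
#' every warped frame, removing portions of image not consistently visible
#' in all frames.
#'
#' @param result an `alignment_result` from [align_stack()].
#' @return A [frame_stack] containing no out-of-view pixels.
#' @export
crop_common <- function(result) {
  stopifnot(inherits(result, "alignment_result"))
  b <- result$crop_box
  rows <- (b[1] + 1L):b[3]; cols <- (b[2] + 1L):b[4]
  frames <- lapply(result$aligned$frames,
                   function(f) f[rows, cols, , drop = FALSE])
  frame_stack(frames, fps = result$aligned$fps,
              bit_depth = result$aligned$bit_depth)
}

#' Export recovered transforms as CSV
#' @param result an `alignment_result`.
#' @param path output CSV path.
#' @export
write_transforms <- function(result, path) {
  utils::write.csv(result$transforms, path, row.names = FALSE)
  invisible(path)
}
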