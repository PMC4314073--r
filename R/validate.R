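# Observer-comparison framework.
#
# Observer outlines of pulsating regions (full-resolution binary masks) are
# reduced 5:1 onto the cluster grid, the amplitude map is segmented at every
# integer threshold 0..40, and the resulting confusion counts trace an
# empirical ROC per observer.  The ideal threshold maximizes
# sensitivity x specificity; the critical amplitude of an observer region is
# the maximum amplitude inside it — the ceiling above which that whole
# region would be missed.

#' Reduce a full-resolution observer mask onto the cluster grid
#'
#' A cluster is marked pulsatile if the observer considered at least one of
#' its pixels to be pulsating (logical OR pooling over each
#' `cluster_size` x `cluster_size` tile; same tiling origin as
#' [cluster_means()], trailing remainder dropped).
#'
#' @param mask binary `H x W` matrix (1 = observer-outlined pulsation).
#' @param cluster_size tile side in pixels (default 5).
#' @return binary cluster-grid matrix.
#' @export
downscale_mask <- function(mask, cluster_size = 5L) {
  mask <- (mask != 0) * 1L
  h <- nrow(mask); w <- ncol(mask)
  if (h < cluster_size || w < cluster_size)
    stop("downscale_mask: mask smaller than one cluster", call. = FALSE)
  nr <- h %/% cluster_size; nc <- w %/% cluster_size
  m <- mask[seq_len(nr * cluster_size), seq_len(nc * cluster_size)]
  rowband <- matrix(colSums(matrix(m, nrow = cluster_size)), nrow = nr)
  s <- t(matrix(colSums(matrix(t(rowband), nrow = cluster_size)), nrow = nc))
  (s > 0) * 1L
}

#' Threshold an amplitude map into a binary pulsation grid
#'
#' Amplitude values strictly greater than the threshold are pulsating;
#' values less than or equal to the threshold are non-pulsatile.
#'
#' @param map an `amplitude_map` (or a plain numeric matrix of amplitudes).
#' @param threshold amplitude threshold in paper units.
#' @return binary cluster-grid matrix.
#' @export
segment <- function(map, threshold) {
  amp <- if (inherits(map, "amplitude_map")) map$amplitude else map
  (amp > threshold) * 1L
}

#' Confusion counts between a segmentation and an observer grid
#'
#' @param segmented binary cluster grid from [segment()].
#' @param observer binary observer cluster grid from [downscale_mask()].
#' @param threshold the threshold used (carried into the result).
#' @return list `(threshold, TP, FP, FN, TN)`; counts sum to the number of
#'   clusters.
#' @export
confusion <- function(segmented, observer, threshold = NA) {
  if (!all(dim(segmented) == dim(observer)))
    stop("confusion: grid shapes differ", call. = FALSE)
  p <- segmented != 0; o <- observer != 0
  list(threshold = threshold,
       TP = sum(p & o), FP = sum(p & !o),
       FN = sum(!p & o), TN = sum(!p & !o))
}

#' Rates from confusion counts
#'
#' `tpr = TP/(TP+FN)`, `fpr = FP/(FP+TN)`; sensitivity is the TPR and
#' specificity is `1 - FPR`. A zero denominator yields `NA` with an
#' `undefined` flag rather than a silent 0.
#'
#' @param counts a [confusion()] result.
#' @return list `(tpr, fpr, sensitivity, specificity, undefined)`.
#' @export
rates <- function(counts) {
  tpr <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
         else NA_real_
  fpr <- if (counts$FP + counts$TN > 0) counts$FP / (counts$FP + counts$TN)
         else NA_real_
  list(tpr = tpr, fpr = fpr, sensitivity = tpr, specificity = 1 - fpr,
       undefined = is.na(tpr) || is.na(fpr))
}

#' Empirical AUC by trapezoidal integration
#'
#' Points are anchored with (0,0) and (1,1), sorted by FPR (ties ordered by
#' TPR, consistent with the monotone threshold sweep) and integrated with
#' the trapezoid rule; tied-FPR points have zero width and contribute
#' nothing, so a threshold sweep that revisits the same FPR at several TPR
#' values traces the standard empirical staircase.
#'
#' @param fpr,tpr numeric vectors of ROC points (undefined points dropped).
#' @return area under the curve in `[0, 1]`.
#' @export
auc_empirical <- function(fpr, tpr) {
  ok <- is.finite(fpr) & is.finite(tpr)
  fpr <- fpr[ok]; tpr <- tpr[ok]
  if (length(fpr) < 1L)
    stop("auc_empirical: no defined ROC points", call. = FALSE)
  x <- c(fpr, 0, 1); y <- c(tpr, 0, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Full threshold-sweep ROC against one observer
#'
#' Sweeps integer thresholds (default 0..40), computing confusion counts
#' and rates at each, the empirical AUC, the ideal threshold (maximum
#' product of sensitivity and specificity, ties to the lowest threshold),
#' and the critical amplitudes of the observer's regions.
#'
#' @param map an `amplitude_map`.
#' @param observer binary observer cluster grid.
#' @param thresholds integer thresholds to sweep (default `0:40`).
#' @return A `roc_result` with `table` (data.frame: threshold, TP, FP, FN,
#'   TN, tpr, fpr), `auc`, `ideal_threshold`, `regions` (data.frame:
#'   region_id, n_clusters, critical_amplitude), and `critical_amplitude`
#'   (eye-level value, the minimum over regions).
#' @export
roc_sweep <- function(map, observer, thresholds = 0:40) {
  amp <- if (inherits(map, "amplitude_map")) map$amplitude else map
  if (!all(dim(amp) == dim(observer)))
    stop("roc_sweep: map and observer grids differ in shape", call. = FALSE)
  rows <- lapply(thresholds, function(th) {
    cc <- confusion(segment(amp, th), observer, th)
    r <- rates(cc)
    data.frame(threshold = th, TP = cc$TP, FP = cc$FP, FN = cc$FN,
               TN = cc$TN, tpr = r$tpr, fpr = r$fpr)
  })
  tab <- do.call(rbind, rows)
  auc <- auc_empirical(tab$fpr, tab$tpr)
  it <- ideal_threshold(tab)
  crit <- critical_amplitude(amp, observer)
  structure(list(table = tab, auc = auc, ideal_threshold = it,
                 regions = crit$regions,
                 critical_amplitude = crit$eye_level),
            class = "roc_result")
}

#' Ideal detection threshold
#'
#' The threshold maximizing the product of sensitivity and specificity;
#' ties are broken toward the lowest threshold (favouring sensitivity).
#'
#' @param tab data.frame with columns `threshold`, `tpr`, `fpr` (a
#'   `roc_result$table`), or a `roc_result`.
#' @return integer threshold in paper units.
#' @export
ideal_threshold <- function(tab) {
  if (inherits(tab, "roc_result")) tab <- tab$table
  prod <- tab$tpr * (1 - tab$fpr)
  ok <- is.finite(prod)
  if (!any(ok)) stop("ideal_threshold: no defined rates", call. = FALSE)
  tabok <- tab[ok, ]
  tabok$threshold[which.max(prod[ok])]    # which.max takes the first maximum
}

# 8-connected component labelling of a binary grid (union-find)
.label_8connected <- function(grid) {
  h <- nrow(grid); w <- ncol(grid)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(w)) for (rr in seq_len(h)) {
    if (!grid[rr, cc]) next
    nb <- integer(0)
    if (rr > 1 && grid[rr - 1, cc]) nb <- c(nb, lab[rr - 1, cc])
    if (cc > 1) {
      if (grid[rr, cc - 1]) nb <- c(nb, lab[rr, cc - 1])
      if (rr > 1 && grid[rr - 1, cc - 1]) nb <- c(nb, lab[rr - 1, cc - 1])
      if (rr < h && grid[rr + 1, cc - 1]) nb <- c(nb, lab[rr + 1, cc - 1])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[rr, cc] <- nxt
    } else {
      roots <- vapply(nb, find, 0L)
      r0 <- min(roots)
      lab[rr, cc] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  # flatten labels to 1..n
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, 0L)
    uniq <- sort(unique(roots))
    remap <- match(roots, uniq)
    idx <- lab > 0L
    lab[idx] <- remap[lab[idx]]
  }
  lab
}

#' Critical amplitude of observer-outlined regions
#'
#' Observer-positive clusters are grouped into 8-connected regions; the
#' critical amplitude of a region is the maximum map amplitude inside it —
#' choosing a detection threshold above that value misses the whole region.
#' The eye-level critical amplitude is the minimum over regions: the lowest
#' such ceiling.
#'
#' @param map an `amplitude_map` or numeric amplitude matrix.
#' @param observer binary observer cluster grid.
#' @return list with `regions` (data.frame: region_id, n_clusters,
#'   critical_amplitude), `eye_level`, and `labels` (the label matrix).
#' @export
critical_amplitude <- function(map, observer) {
  amp <- if (inherits(map, "amplitude_map")) map$amplitude else map
  if (!all(dim(amp) == dim(observer)))
    stop("critical_amplitude: shapes differ", call. = FALSE)
  lab <- .label_8connected(observer != 0)
  n <- max(lab)
  if (n == 0L)
    return(list(regions = data.frame(region_id = integer(0),
                                     n_clusters = integer(0),
                                     critical_amplitude = numeric(0)),
                eye_level = NA_real_, labels = lab))
  regions <- data.frame(
    region_id = seq_len(n),
    n_clusters = as.integer(tabulate(lab[lab > 0], n)),
    critical_amplitude = vapply(seq_len(n),
                                function(i) max(amp[lab == i]), 0))
  list(regions = regions,
       eye_level = min(regions$critical_amplitude),
       labels = lab)
}

#' Cohen's kappa between two binary cluster grids
#'
#' Chance-corrected agreement with marginal-product expected agreement:
#' `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param maskA,maskB binary cluster grids of identical shape.
#' @return kappa; `NA` with a warning when both graders are constant
#'   (`p_e = 1`).
#' @export
cohens_kappa <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB)))
    stop("cohens_kappa: shapes differ", call. = FALSE)
  a <- maskA != 0; b <- maskB != 0
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    warning("cohens_kappa: expected agreement is 1 (kappa undefined)",
            call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Read an observer mask PNG
#'
#' 8-bit PNG convention: 0 = background, 255 = pulsating (any non-zero
#' value counts as pulsating).
#'
#' @param path PNG file.
#' @return binary `H x W` matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  (img > 0) * 1L
}

#' Write an observer mask PNG
#' @param mask binary matrix.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Write a ROC table as CSV
#' @param roc a `roc_result`.
#' @param path output CSV path.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(roc$table, path, row.names = FALSE)
  invisible(path)
}

#' Render a detection/observer overlay PNG
#'
#' Yellow where detection and observer agree on pulsation, green where only
#' the objective detection fires, red where the observer noted pulsation
#' but the amplitude is at or below threshold, dark grey elsewhere.
#'
#' @param map an `amplitude_map` or amplitude matrix.
#' @param observer binary observer cluster grid.
#' @param threshold detection threshold in paper units.
#' @param path output PNG path.
#' @export
write_overlay_png <- function(map, observer, threshold, path) {
  amp <- if (inherits(map, "amplitude_map")) map$amplitude else map
  det <- amp > threshold
  obs <- observer != 0
  h <- nrow(amp); w <- ncol(amp)
  img <- array(0.15, c(h, w, 3))
  set_col <- function(img, sel, rgb) {
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[sel] <- rgb[ch]; img[, , ch] <- plane
    }
    img
  }
  img <- set_col(img, det & obs,  c(1, 1, 0))
  img <- set_col(img, det & !obs, c(0, 0.8, 0))
  img <- set_col(img, !det & obs, c(1, 0, 0))
  png::writePNG(img, path)
  invisible(path)
}
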