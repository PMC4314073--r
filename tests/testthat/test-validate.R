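test_that("mask downscaling ORs each 5x5 block", {
  # exactly one annotated pixel marks the whole cluster
  m <- matrix(0L, 10, 10)
  m[7, 3] <- 1L
  g <- downscale_mask(m)
  expect_equal(g, matrix(c(0L, 1L, 0L, 0L), 2, 2))
  # all-zero mask
  expect_true(all(downscale_mask(matrix(0L, 15, 15)) == 0))
  # random mask vs brute-force per-block OR oracle
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(rbinom(20 * 25, 1, 0.08), 20, 25)
    g <- downscale_mask(m)
    for (i in 1:4) for (j in 1:5) {
      block <- m[(5 * i - 4):(5 * i), (5 * j - 4):(5 * j)]
      expect_equal(g[i, j], as.integer(any(block == 1)))
    }
  }
  # trailing remainder dropped: 12x11 -> 2x2
  expect_equal(dim(downscale_mask(matrix(0L, 12, 11))), c(2, 2))
})

test_that("segmentation uses a strict greater-than rule", {
  m <- matrix(c(5.1, 5.0, 4.9, 40), 2, 2)
  s <- segment(m, 5)
  expect_equal(s[1, 1], 1L)   # 5.1 > 5
  expect_equal(s[2, 1], 0L)   # 5.0 <= 5
  expect_equal(s[1, 2], 0L)
  expect_equal(s[2, 2], 1L)
  # threshold 40 on a map maxing at 39 -> all zero
  expect_true(all(segment(matrix(39, 3, 3), 40) == 0))
})

test_that("confusion counts match a nested-loop oracle", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  cc <- confusion(a, a)
  expect_equal(cc$TP, 2); expect_equal(cc$FP, 0)
  expect_equal(cc$FN, 0); expect_equal(cc$TN, 2)
  cc2 <- confusion(matrix(1, 2, 2), matrix(0, 2, 2))
  expect_equal(cc2$FP, 4)
  set.seed(11)
  p <- matrix(rbinom(400, 1, 0.4), 20, 20)
  o <- matrix(rbinom(400, 1, 0.3), 20, 20)
  cc3 <- confusion(p, o)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:20) for (j in 1:20) {
    if (p[i, j] && o[i, j]) tp <- tp + 1
    else if (p[i, j] && !o[i, j]) fp <- fp + 1
    else if (!p[i, j] && o[i, j]) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(cc3$TP, tp); expect_equal(cc3$FP, fp)
  expect_equal(cc3$FN, fn); expect_equal(cc3$TN, tn)
  expect_equal(cc3$TP + cc3$FP + cc3$FN + cc3$TN, 400)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("rates follow the TP/(TP+FN), FP/(FP+TN) formulas", {
  r <- rates(list(TP = 3, FN = 1, FP = 0, TN = 10))
  expect_equal(r$tpr, 0.75)
  expect_equal(r$fpr, 0)
  expect_equal(r$specificity, 1)
  r2 <- rates(list(TP = 1, FN = 1, FP = 1, TN = 1))
  expect_equal(r2$tpr, 0.5); expect_equal(r2$fpr, 0.5)
  # zero denominator flags undefined instead of silently returning 0
  r3 <- rates(list(TP = 0, FN = 0, FP = 2, TN = 2))
  expect_true(r3$undefined)
  expect_true(is.na(r3$tpr))
})

test_that("TPR and FPR are non-increasing in threshold", {
  set.seed(19)
  amp <- matrix(runif(600, 0, 40), 20, 30)
  obs <- matrix(rbinom(600, 1, 0.35), 20, 30)
  roc <- roc_sweep(amp, obs)
  expect_true(all(diff(roc$table$tpr) <= 1e-12))
  expect_true(all(diff(roc$table$fpr) <= 1e-12))
  expect_true(all(roc$table$tpr >= 0 & roc$table$tpr <= 1))
  expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
})

test_that("empirical AUC matches oracles", {
  # chance diagonal from the two corner points alone
  expect_equal(auc_empirical(c(0, 1), c(0, 1)), 0.5)
  expect_error(auc_empirical(numeric(0), numeric(0)), "no defined")
  # perfectly separable synthetic map
  amp <- matrix(0, 10, 10); amp[3:5, 3:7] <- 20
  obs <- (amp > 0) * 1L
  expect_equal(roc_sweep(amp, obs)$auc, 1.0)
  # randomized sweeps against trapezoid integration by pROC
  skip_if_not_installed("pROC")
  set.seed(23)
  for (rep in 1:5) {
    amp <- matrix(pmin(rexp(500, 1 / 8), 40), 20, 25)
    obs <- matrix(as.integer(runif(500) < plogis((amp - 6) / 4)), 20, 25)
    mine <- roc_sweep(amp, obs)$auc
    ref <- as.numeric(suppressMessages(
      pROC::auc(as.vector(obs), as.vector(floor(amp)))))
    expect_equal(mine, ref, tolerance = 0.02)
  }
})

test_that("label permutations of a fixed map average AUC 0.5", {
  set.seed(29)
  amp <- matrix(runif(1000, 0, 40), 40, 25)
  obs <- matrix(rbinom(1000, 1, 0.3), 40, 25)
  aucs <- replicate(200, roc_sweep(amp, matrix(sample(obs), 40, 25))$auc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("ideal threshold maximizes sens x spec with ties to the lowest", {
  tab <- data.frame(threshold = 0:2, tpr = c(0.4, 1, 0.8),
                    fpr = c(0.8, 0.5, 0.5))
  # products: 0.08, 0.5, 0.4
  expect_equal(ideal_threshold(tab), 1)
  # tie at thresholds 4 and 6 -> 4, and matches a brute-force scan
  tab2 <- data.frame(threshold = c(2, 4, 6, 8),
                     tpr = c(0.5, 0.9, 0.9, 0.2),
                     fpr = c(0.5, 0.1, 0.1, 0.1))
  prod <- tab2$tpr * (1 - tab2$fpr)
  expect_equal(ideal_threshold(tab2),
               tab2$threshold[which(prod == max(prod))[1]])
  expect_equal(ideal_threshold(tab2), 4)
})

test_that("ideal threshold on separable data sits in the amplitude gap", {
  # true clusters span (9, 12], false span [0, 7]: any threshold in [7, 9)
  # separates; the product scan must agree with brute force
  set.seed(37)
  amp <- matrix(0, 10, 10)
  truth <- matrix(0L, 10, 10)
  truth[2:4, 2:8] <- 1L
  amp[truth == 1] <- runif(sum(truth), 9.5, 12)
  amp[truth == 0] <- runif(sum(truth == 0), 0, 7)
  roc <- roc_sweep(amp, truth)
  brute <- sapply(0:40, function(th) {
    cc <- confusion(segment(amp, th), truth)
    r <- rates(cc)
    r$sensitivity * r$specificity
  })
  expect_equal(roc$ideal_threshold, (0:40)[which.max(brute)])
  expect_true(roc$ideal_threshold %in% 7:9)
  r <- rates(confusion(segment(amp, roc$ideal_threshold), truth))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
})

test_that("critical amplitude is the min over region maxima", {
  amp <- matrix(0, 8, 8)
  obs <- matrix(0L, 8, 8)
  # region 1: three clusters with amplitudes 3, 7, 12.3
  obs[2, 2:4] <- 1L; amp[2, 2:4] <- c(3, 7, 12.3)
  # region 2 (diagonally separated): max 18.2
  obs[6:7, 6] <- 1L; amp[6:7, 6] <- c(18.2, 11)
  ca <- critical_amplitude(amp, obs)
  expect_equal(nrow(ca$regions), 2)
  expect_setequal(ca$regions$critical_amplitude, c(12.3, 18.2))
  expect_equal(ca$eye_level, 12.3)
  # at any integer threshold below the eye-level value every region keeps a
  # detected cluster; above it, some region is entirely missed
  for (th in 0:floor(ca$eye_level)) {
    det <- segment(amp, th)
    for (i in 1:2) expect_gt(sum(det[ca$labels == i]), 0)
  }
  det2 <- segment(amp, ceiling(ca$eye_level))
  missed <- vapply(1:2, function(i) sum(det2[ca$labels == i]) == 0,
                   logical(1))
  expect_true(any(missed))
})

test_that("8-connected labelling joins diagonal clusters", {
  obs <- matrix(0L, 5, 5)
  obs[1, 1] <- 1L; obs[2, 2] <- 1L; obs[3, 3] <- 1L  # one diagonal region
  obs[5, 5] <- 1L                                    # separate
  ca <- critical_amplitude(matrix(1, 5, 5), obs)
  expect_equal(nrow(ca$regions), 2)
  expect_equal(sort(ca$regions$n_clusters), c(1, 3))
  # empty mask flags no regions
  ca0 <- critical_amplitude(matrix(1, 5, 5), matrix(0L, 5, 5))
  expect_equal(nrow(ca0$regions), 0)
  expect_true(is.na(ca0$eye_level))
})

test_that("Cohen's kappa: identity, hand example, and independence null", {
  m <- matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_equal(cohens_kappa(m, m), 1)
  # counts: both+ 40, A+B- 10, A-B+ 10, both- 40 -> p_o 0.8, p_e 0.5
  a <- matrix(c(rep(1, 50), rep(0, 50)), 10, 10)
  b <- matrix(c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40)), 10, 10)
  expect_equal(cohens_kappa(a, b), 0.6)
  # independent random masks, 1e4 clusters
  set.seed(41)
  x <- matrix(rbinom(1e4, 1, 0.4), 100, 100)
  y <- matrix(rbinom(1e4, 1, 0.4), 100, 100)
  expect_lt(abs(cohens_kappa(x, y)), 0.05)
  # both constant -> undefined
  expect_warning(k <- cohens_kappa(matrix(1, 3, 3), matrix(1, 3, 3)),
                 "undefined")
  expect_true(is.na(k))
})

test_that("mask PNG round trip and ROC CSV export", {
  m <- matrix(rbinom(200, 1, 0.2), 10, 20)
  p <- tempfile(fileext = ".png")
  write_mask(m, p)
  expect_equal(read_mask(p), m)
  set.seed(3)
  amp <- matrix(runif(100, 0, 20), 10, 10)
  obs <- matrix(rbinom(100, 1, 0.3), 10, 10)
  roc <- roc_sweep(amp, obs)
  pc <- tempfile(fileext = ".csv")
  write_roc_csv(roc, pc)
  df <- read.csv(pc)
  expect_equal(nrow(df), 41)
  expect_named(df, c("threshold", "TP", "FP", "FN", "TN", "tpr", "fpr"))
})

test_that("overlay colours follow the agreement semantics", {
  amp <- matrix(c(10, 2, 10, 2), 2, 2)
  obs <- matrix(c(1, 1, 0, 0), 2, 2)
  p <- tempfile(fileext = ".png")
  write_overlay_png(amp, obs, 5, p)
  img <- png::readPNG(p)
  expect_equal(img[1, 1, ], c(1, 1, 0))       # detected & observed: yellow
  expect_equal(img[2, 1, ], c(1, 0, 0))       # observed only: red
  expect_equal(img[1, 2, ], c(0, 0.8, 0))     # detected only: green
})
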