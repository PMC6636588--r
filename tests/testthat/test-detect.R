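test_that("smoothing is identity at fwhm 0, mean-preserving in-mask, Gaussian on a delta", {
  set.seed(3)
  d <- c(14, 12, 10)
  x <- array(rnorm(prod(d)), d)
  expect_identical(smooth_map(x, 0, 2), x)
  # constant map inside a mask stays constant (renormalized smoothing)
  mask <- array(FALSE, d); mask[4:10, 3:9, 3:8] <- TRUE
  cm <- array(0, d); cm[mask] <- 7
  sm <- smooth_map(cm, 6, 2, mask)
  expect_equal(sm[mask], rep(7, sum(mask)), tolerance = 1e-12)
  expect_true(all(sm[!mask] == 0))
  # unmasked delta reproduces the separable discrete Gaussian in closed form
  d2 <- c(21, 21, 21)
  delta <- array(0, d2); delta[11, 11, 11] <- 1
  out <- smooth_map(delta, 6, 1)
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  r <- ceiling(3 * sigma)
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  expected <- array(0, d2)
  for (i in -r:r) for (j in -r:r) for (k in -r:r)
    expected[11 + i, 11 + j, 11 + k] <- k1[i + r + 1] * k1[j + r + 1] * k1[k + r + 1]
  expect_lt(max(abs(out - expected)), 1e-6)
  expect_error(smooth_map(x, -1, 2), "non-negative")
})

test_that("z-score maps are exact and flag zero-variance voxels undefined", {
  d <- c(6, 5, 4)
  maps <- lapply(1:5, function(i) array(i, d))
  cohort <- control_cohort(maps, "toy")
  expect_equal(cohort$mean_map[1], 3)
  z <- zscore_map(cohort$mean_map, cohort)
  expect_true(all(z == 0))
  z2 <- zscore_map(cohort$mean_map + 2 * cohort$sd_map, cohort)
  expect_equal(z2, array(2, d))
  # zero-variance voxel -> undefined
  maps0 <- lapply(1:4, function(i) { m <- array(i, d); m[1, 1, 1] <- 5; m })
  c0 <- control_cohort(maps0)
  z3 <- zscore_map(maps0[[1]], c0)
  expect_true(is.na(z3[1, 1, 1]))
  expect_false(anyNA(z3[-1]))
  expect_error(zscore_map(array(0, c(2, 2, 2)), cohort), "grid")
  # n-adjusted variant divides by sd * sqrt(1 + 1/n)
  za <- zscore_map(cohort$mean_map + 2 * cohort$sd_map, cohort, n_adjusted = TRUE)
  expect_equal(za[2], 2 / sqrt(1 + 1 / 5))
})

test_that("BH cutoff matches its definition and stats::p.adjust", {
  expect_equal(fdr_threshold(c(0.001, 0.01, 0.02, 0.05), 0.05), 0.05)
  expect_equal(fdr_threshold(rep(1, 10), 0.05), 0)
  expect_equal(fdr_threshold(0.04, 0.05), 0.04)  # m = 1: raw threshold
  set.seed(8)
  for (i in 1:20) {
    p <- c(runif(80), runif(20)^4)
    cut <- fdr_threshold(p, 0.05)
    expect_equal(cut, bf_fdr_cutoff(p, 0.05))
    # rejection set identical to BH adjustment
    expect_identical(p <= cut, p.adjust(p, "BH") <= 0.05)
  }
  expect_error(fdr_threshold(numeric(0), 0.05), "nonempty")
  expect_error(fdr_threshold(c(0.5, 1.2), 0.05), "0, 1")
})

test_that("cluster extent boundary behaves exactly at k", {
  d <- c(12, 12, 12)
  mask <- array(TRUE, d)
  # a contiguous 29-voxel blob at high z: one short of the extent threshold
  z <- array(0, d)
  z[3:6, 3:5, 3:5][1:29] <- 8
  prm29 <- detection_params(0, "uncorrected", 0.001, 30L)
  expect_length(threshold_map(z, prm29, mask)$clusters, 0)
  z[3:6, 3:5, 3:5][1:30] <- 8
  cl <- threshold_map(z, prm29, mask)
  expect_length(cl$clusters, 1)
  expect_identical(cl$clusters[[1]]$size, 30L)
  # flat z-map: no clusters under any mode
  z0 <- array(0, d)
  for (mode in c("uncorrected", "FDR", "FWE"))
    expect_length(threshold_map(z0, detection_params(0, mode, 0.05, 1L), mask)$clusters, 0)
  expect_error(threshold_map(z0, prm29, array(FALSE, d)), "empty test mask")
})

test_that("thresholding and clustering match the brute-force oracle", {
  set.seed(21)
  for (i in 1:30) {
    d <- c(12, 12, 12)
    z <- array(rnorm(prod(d), sd = 2), d)
    mask <- array(runif(prod(d)) > 0.1, d)
    k <- sample(1:5, 1)
    conn <- sample(c(6L, 18L, 26L), 1)
    prm <- detection_params(0, "uncorrected", 0.01, k, connectivity = conn)
    got <- threshold_map(z, prm, mask)
    want <- bf_threshold_cluster(z, 0.01, k, mask, TRUE, conn)
    got_sets <- vapply(got$clusters, function(cl) paste(cl$voxels, collapse = ","), "")
    want_sets <- vapply(want, paste, "", collapse = ",")
    expect_setequal(got_sets, want_sets)
  }
})

test_that("parenchyma filter drops extra-parenchymal and cortex-distant peaks", {
  d <- c(12, 12, 12)
  vent <- array(FALSE, d); vent[6:7, 6:7, 6:7] <- TRUE
  atlas <- toy_atlas(d, ventricle = vent)
  gm <- array(FALSE, d); gm[, , 10:12] <- TRUE   # cortex = top slab
  mk_cl <- function(vox_idx) {
    structure(list(clusters = list(list(voxels = vox_idx, size = length(vox_idx),
                                        peak_voxel = as.integer(qmlm:::vox_coords(vox_idx[1], d)),
                                        peak_index = vox_idx[1], peak_z = 5)),
                   params_used = detection_params(0, "uncorrected", 0.001, 1L),
                   n_tests = prod(d), grid_shape = d), class = "qm_clusters")
  }
  # peak in ventricle label: removed
  vent_idx <- which(vent)[1]
  expect_length(parenchyma_filter(mk_cl(vent_idx), atlas, gm, 5, 1)$clusters, 0)
  # peak in cortical GM: retained
  gm_idx <- which(gm)[1]
  expect_length(parenchyma_filter(mk_cl(gm_idx), atlas, gm, 5, 1)$clusters, 1)
  # WM peak at known distance d from cortex: retained iff d <= cutoff,
  # against the brute-force distance oracle
  for (depth in 1:6) {
    vox <- c(3L, 3L, 10L - depth)
    idx <- vox[1] + (vox[2] - 1L) * d[1] + (vox[3] - 1L) * d[1] * d[2]
    dist <- bf_min_dist_mm(vox, gm, 1)
    kept <- length(parenchyma_filter(mk_cl(idx), atlas, gm, 3.5, 1)$clusters) == 1
    expect_identical(kept, dist <= 3.5)
  }
  # atlas without excluded labels is rejected
  bad <- atlas; bad$table <- bad$table[bad$table$lobe != "none", ]
  expect_error(parenchyma_filter(mk_cl(gm_idx), bad, gm, 5, 1), "excluded")
})

test_that("cluster counts are monotone in p and k, and FDR nests in uncorrected", {
  set.seed(13)
  for (i in 1:8) {
    d <- c(10, 11, 12)
    z <- smooth_map(array(rnorm(prod(d), sd = 3), d), 3, 1)
    mask <- array(TRUE, d)
    n_cl <- function(p, k, mode = "uncorrected")
      length(threshold_map(z, detection_params(0, mode, p, k), mask)$clusters)
    # lowering p never increases surviving clusters... at fixed k
    expect_gte(n_cl(0.05, 2), n_cl(0.01, 2))
    expect_gte(n_cl(0.01, 2), n_cl(0.001, 2))
    # raising k never increases surviving clusters
    expect_gte(n_cl(0.01, 1), n_cl(0.01, 5))
    expect_gte(n_cl(0.01, 5), n_cl(0.01, 20))
    # every FDR-significant voxel is significant uncorrected at the cutoff
    p <- 2 * pnorm(-abs(z))
    cut <- fdr_threshold(as.vector(p), 0.05)
    fdr_vox <- unlist(lapply(threshold_map(z, detection_params(0, "FDR", 0.05, 1L),
                                           mask)$clusters, `[[`, "voxels"))
    if (length(fdr_vox)) expect_true(all(p[fdr_vox] <= cut))
    unc_vox <- unlist(lapply(threshold_map(z, detection_params(0, "uncorrected",
                                                               max(cut, 1e-12), 1L),
                                           mask)$clusters, `[[`, "voxels"))
    expect_true(all(fdr_vox %in% unc_vox))
  }
})
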