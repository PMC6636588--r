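mk_clusters <- function(d, vox_sets, atlas = NULL, zs = NULL) {
  cls <- lapply(seq_along(vox_sets), function(i) {
    vox <- vox_sets[[i]]
    list(voxels = vox, size = length(vox),
         peak_voxel = as.integer(qmlm:::vox_coords(vox[1], d)),
         peak_index = vox[1], peak_z = if (is.null(zs)) 5 else zs[i])
  })
  structure(list(clusters = cls,
                 params_used = detection_params(0, "uncorrected", 0.001, 1L),
                 n_tests = prod(d), grid_shape = d), class = "qm_clusters")
}

test_that("cluster region assignment uses the peak with majority fallback", {
  d <- c(10, 10, 10)
  atlas <- toy_atlas(d)
  # entirely within the left half -> (frontal, left)
  cl <- mk_clusters(d, list(1:20))
  expect_identical(assign_cluster_region(cl$clusters[[1]], atlas),
                   c(lobe = "frontal", side = "left"))
  # peak on the right decides even when most voxels are on the left
  right_idx <- which(atlas$labels == 21L)
  left_idx <- which(atlas$labels == 11L)
  cl2 <- mk_clusters(d, list(c(right_idx[1], left_idx[1:40])))
  expect_identical(assign_cluster_region(cl2$clusters[[1]], atlas)[["side"]], "right")
  # peak on excluded tissue falls back to the majority label
  vent <- array(FALSE, d); vent[5, 5, 5] <- TRUE
  atlas_v <- toy_atlas(d, ventricle = vent)
  vent_idx <- which(vent)
  cl3 <- mk_clusters(d, list(c(vent_idx, right_idx[1:10])))
  expect_identical(assign_cluster_region(cl3$clusters[[1]], atlas_v)[["side"]], "right")
  # fully unlabeled cluster is an error
  atlas_bg <- atlas; atlas_bg$labels[] <- 0L
  expect_error(assign_cluster_region(cl$clusters[[1]], atlas_bg), "no labeled")
})

test_that("assignments match a brute-force peak/majority lookup on random clusters", {
  set.seed(17)
  d <- c(10, 12, 10)
  atlas <- toy_atlas(d)
  for (i in 1:25) {
    vox <- sample(prod(d), sample(3:40, 1))
    cl <- mk_clusters(d, list(vox))$clusters[[1]]
    lab <- atlas$labels[cl$peak_index]
    row <- match(lab, atlas$table$label)
    if (atlas$table$lobe[row] == "none") {
      labs <- atlas$labels[vox]
      labs <- labs[labs %in% atlas$table$label[atlas$table$lobe != "none"]]
      if (!length(labs)) next
      cnt <- table(labs)
      row <- match(as.integer(names(cnt)[which.max(cnt)]), atlas$table$label)
    }
    expect_identical(assign_cluster_region(cl, atlas),
                     c(lobe = atlas$table$lobe[row], side = atlas$table$side[row]))
  }
})

test_that("concordance follows the SLF/NSLF and unlateralized matching rules", {
  d <- c(10, 10, 10)
  atlas <- toy_atlas(d)
  left <- which(atlas$labels == 11L); right <- which(atlas$labels == 21L)
  cl <- mk_clusters(d, list(left[1:5]))
  # matching lobe+side -> concordant
  sc <- score_concordance(cl, ez_hypothesis("SLF", list(c("frontal", "left"))), atlas)
  expect_identical(sc$subject_call, "concordant")
  # wrong side -> discordant only
  sc2 <- score_concordance(cl, ez_hypothesis("SLF", list(c("frontal", "right"))), atlas)
  expect_identical(sc2$subject_call, "discordant_only")
  # unlateralized region matches either side
  sc3 <- score_concordance(cl, ez_hypothesis("SLF", list(c("frontal", "unlateralized"))), atlas)
  expect_identical(sc3$subject_call, "concordant")
  # NSLF: verdicts are NA regardless of findings
  sc4 <- score_concordance(cl, ez_hypothesis("NSLF"), atlas)
  expect_identical(sc4$subject_call, "NA_NSLF")
  expect_true(is.na(sc4$per_cluster[[1]]$concordant))
  # no clusters -> no findings
  sc5 <- score_concordance(mk_clusters(d, list()),
                           ez_hypothesis("SLF", list(c("frontal", "left"))), atlas)
  expect_identical(sc5$subject_call, "no_findings")
  # multi-lobe region sets are expressible
  sc6 <- score_concordance(cl, ez_hypothesis("SLF", list(c("temporal", "left"),
                                                         c("frontal", "left"))), atlas)
  expect_identical(sc6$subject_call, "concordant")
  # construction invariants
  expect_error(ez_hypothesis("SLF"), "at least one")
  expect_error(ez_hypothesis("NSLF", list(c("frontal", "left"))), "no regions")
})

test_that("verdicts are exhaustive and symmetric under side relabeling", {
  set.seed(23)
  d <- c(10, 10, 10)
  atlas <- toy_atlas(d)
  flip <- function(s) c(left = "right", right = "left", none = "none",
                        unlateralized = "unlateralized")[[s]]
  atlas_f <- atlas
  atlas_f$table$side <- vapply(atlas$table$side, flip, "")
  for (i in 1:10) {
    cl <- mk_clusters(d, lapply(1:3, function(j) sample(prod(d), 8)))
    ez <- ez_hypothesis("SLF", list(c("frontal", sample(c("left", "right"), 1))))
    ez_f <- ez_hypothesis("SLF", list(c(ez$regions[[1]][1], flip(ez$regions[[1]][2]))))
    sc <- score_concordance(cl, ez, atlas)
    sc_f <- score_concordance(cl, ez_f, atlas_f)
    expect_identical(sc$subject_call, sc_f$subject_call)
    # every cluster gets exactly one verdict; counts sum to cluster count
    expect_length(sc$per_cluster, 3)
    expect_identical(unname(sum(sc$counts)), 3L)
  }
})

test_that("cohort tabulation keeps any-region positives >= concordant, rowwise", {
  d <- c(10, 10, 10)
  atlas <- toy_atlas(d)
  left <- which(atlas$labels == 11L)
  cl1 <- mk_clusters(d, list(left[1:5]))
  cl0 <- mk_clusters(d, list())
  ezL <- ez_hypothesis("SLF", list(c("frontal", "left")))
  ezR <- ez_hypothesis("SLF", list(c("frontal", "right")))
  results <- list(
    T2 = list(score_concordance(cl1, ezL, atlas),
              score_concordance(cl1, ezR, atlas),
              score_concordance(cl0, ezL, atlas),
              "failure"),
    MD = list(score_concordance(cl0, ezL, atlas),
              score_concordance(cl1, ezL, atlas),
              score_concordance(cl1, ez_hypothesis("NSLF"), atlas),
              score_concordance(cl1, ezR, atlas)))
  tab <- qmlm:::tabulate_concordance(results)
  expect_identical(tab$n_available, c(3L, 4L))
  expect_identical(tab$n_failed, c(1L, 0L))
  expect_true(all(tab$any_region_positive >= tab$concordant))
  expect_equal(tab$pct_positive, 100 * tab$any_region_positive / tab$n_available)
})
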