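## Single-subject voxel-based detection: control-cohort summaries, z-score
## maps, significance thresholding (uncorrected / FDR / FWE-Bonferroni),
## cluster-extent filtering by 26/18/6-connectivity, and removal of
## non-parenchymal findings.

#' Control cohort of one quantitative modality
#'
#' Stacks aligned maps across controls and precomputes voxelwise mean and
#' (sample, n-1) standard deviation summaries.
#'
#' @param maps list of aligned 3D arrays, one per control; n >= 2.
#' @param modality free-text tag (e.g. "T2", "WGJS").
#' @return \code{qm_cohort}: \code{maps}, \code{mean_map}, \code{sd_map},
#'   \code{n}, \code{modality}.
#' @export
control_cohort <- function(maps, modality = "map") {
  if (!is.list(maps) || length(maps) < 2L)
    stop("a control cohort needs at least 2 maps", call. = FALSE)
  d <- dim(maps[[1L]])
  for (m in maps) if (any(dim(m) != d)) stop("cohort maps have mismatched grids", call. = FALSE)
  n <- length(maps)
  X <- vapply(maps, as.vector, numeric(prod(d)))
  mu <- rowMeans(X)
  sd <- sqrt(pmax(rowSums((X - mu)^2), 0) / (n - 1L))
  structure(list(maps = maps,
                 mean_map = array(mu, d), sd_map = array(sd, d),
                 n = n, modality = modality),
            class = "qm_cohort")
}

## Leave-one-out mean/sd without restacking: from cohort sums.
cohort_loo_summary <- function(cohort, i) {
  n <- cohort$n
  if (n < 3L) stop("leave-one-out needs a cohort of >= 3", call. = FALSE)
  xi <- cohort$maps[[i]]
  mu_all <- cohort$mean_map
  mu <- (mu_all * n - xi) / (n - 1L)
  ## sum of squares about the LOO mean, from the full-cohort summaries
  ss_all <- cohort$sd_map^2 * (n - 1L)
  ss <- ss_all - (xi - mu_all)^2 * n / (n - 1L)
  list(mean_map = mu, sd_map = sqrt(pmax(ss, 0) / (n - 2L)), n = n - 1L)
}

#' Detection parameters
#'
#' The tunable surface of the detector: Gaussian smoothing FWHM (mm),
#' p-value mode and level, and minimum cluster extent.
#'
#' @param smoothing_fwhm_mm Gaussian smoothing FWHM, mm, >= 0.
#' @param p_mode \code{"uncorrected"}, \code{"FDR"} (Benjamini-Hochberg) or
#'   \code{"FWE"} (Bonferroni).
#' @param p_value significance level in (0, 1).
#' @param cluster_k minimum suprathreshold cluster size in voxels, >= 1.
#' @param two_sided test both signal increase and decrease (default TRUE).
#' @param connectivity cluster connectivity: 26 (default), 18 or 6.
#' @return \code{qm_detection_params}.
#' @export
detection_params <- function(smoothing_fwhm_mm = 6, p_mode = c("uncorrected", "FDR", "FWE"),
                             p_value = 0.001, cluster_k = 30L, two_sided = TRUE,
                             connectivity = 26L) {
  p_mode <- match.arg(p_mode)
  if (!is.numeric(p_value) || p_value <= 0 || p_value >= 1)
    stop("'p_value' must be in (0, 1)", call. = FALSE)
  if (cluster_k < 1L) stop("'cluster_k' must be >= 1", call. = FALSE)
  if (smoothing_fwhm_mm < 0) stop("'smoothing_fwhm_mm' must be >= 0", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L)) stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  structure(list(smoothing_fwhm_mm = smoothing_fwhm_mm, p_mode = p_mode,
                 p_value = p_value, cluster_k = as.integer(cluster_k),
                 two_sided = isTRUE(two_sided), connectivity = as.integer(connectivity)),
            class = "qm_detection_params")
}

#' @export
format.qm_detection_params <- function(x, ...) {
  sprintf("fwhm=%gmm, %s p<=%g, k=%d, %s, conn=%d", x$smoothing_fwhm_mm,
          x$p_mode, x$p_value, x$cluster_k,
          if (x$two_sided) "two-sided" else "one-sided", x$connectivity)
}

#' @export
print.qm_detection_params <- function(x, ...) {
  cat("<qm_detection_params> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Voxelwise z-score map of a subject against a control cohort
#'
#' \code{z = (x - mean) / sd} per voxel. Voxels with zero cohort sd are
#' undefined (\code{NA}) and excluded from testing. With
#' \code{n_adjusted = TRUE} the denominator is \code{sd * sqrt(1 + 1/n)}
#' (Crawford-Howell-style small-cohort adjustment).
#'
#' @param subject_map 3D array; must not be a member of the cohort (for
#'   leave-one-out the caller rebuilds the cohort without the subject).
#' @param cohort a \code{\link{control_cohort}} or a list with
#'   \code{mean_map}, \code{sd_map}, \code{n}.
#' @param n_adjusted apply the \code{sqrt(1 + 1/n)} variance inflation.
#' @return 3D array of z-scores, \code{NA} where undefined.
#' @export
zscore_map <- function(subject_map, cohort, n_adjusted = FALSE) {
  stop_if_not_vol3d(subject_map)
  if (any(dim(subject_map) != dim(cohort$mean_map)))
    stop("subject map grid does not match the cohort", call. = FALSE)
  if (!is.null(cohort$n) && cohort$n < 2L) stop("cohort must have n >= 2", call. = FALSE)
  den <- cohort$sd_map
  if (n_adjusted) den <- den * sqrt(1 + 1 / cohort$n)
  z <- array(NA_real_, dim(subject_map))
  ok <- cohort$sd_map > 0
  z[ok] <- (subject_map[ok] - cohort$mean_map[ok]) / den[ok]
  z
}

#' Benjamini-Hochberg FDR p-value cutoff
#'
#' Step-up rule: the cutoff is the largest sorted p-value \code{p_(i)} with
#' \code{p_(i) <= i * q / m}; every p-value at or below the cutoff is
#' rejected. Returns 0 when nothing passes (no p-value is <= 0 except exact
#' zeros, which are always rejected).
#'
#' @param p_values numeric vector in [0, 1]; must be nonempty.
#' @param q FDR level in (0, 1).
#' @return scalar p-value cutoff.
#' @export
fdr_threshold <- function(p_values, q) {
  if (length(p_values) == 0L) stop("'p_values' must be nonempty", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)", call. = FALSE)
  p <- sort(p_values[!is.na(p_values)])
  m <- length(p)
  ok <- which(p <= seq_len(m) * q / m)
  if (!length(ok)) return(0)
  p[max(ok)]
}

## Connected components of a voxel index set via igraph; offsets are the
## half-neighborhood of the requested connectivity.
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  off <- off[keep, , drop = FALSE]
  ## one of each +/- pair suffices for an undirected graph
  off[off[, 3L] > 0 | (off[, 3L] == 0 & off[, 2L] > 0) |
      (off[, 3L] == 0 & off[, 2L] == 0 & off[, 1L] > 0), , drop = FALSE]
}

label_components <- function(idx, d, connectivity = 26L) {
  if (!length(idx)) return(integer(0))
  co <- vox_coords(idx, d)
  off <- connectivity_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(co, 2L, off[r, ], "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] & nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    if (!any(ok)) next
    nb_idx <- vox_index(nb[ok, , drop = FALSE], d)
    hit <- match(nb_idx, idx)
    found <- !is.na(hit)
    from <- c(from, which(ok)[found])
    to <- c(to, hit[found])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(idx)]
}

#' Threshold a z-map and extract suprathreshold clusters
#'
#' Converts z-scores to standard-normal p-values (two-sided if requested),
#' applies the significance rule of \code{params$p_mode} over the tested
#' voxels (uncorrected: \code{p <= p_value}; FDR: Benjamini-Hochberg at
#' level \code{p_value}; FWE: Bonferroni, \code{p <= p_value / n_tests}),
#' groups surviving voxels into connected clusters and discards clusters
#' smaller than \code{cluster_k}. The tested-voxel set is \code{test_mask}
#' voxels with a defined z-score, so undefined voxels are not counted as
#' tests.
#'
#' @param zmap 3D array of z-scores (NA = undefined).
#' @param params \code{\link{detection_params}}.
#' @param test_mask logical/0-1 3D array of voxels eligible for testing.
#' @return \code{qm_clusters}: list of clusters (voxel indices, size, peak
#'   voxel, peak |z|), sorted by size descending, plus the parameters and
#'   test count.
#' @export
threshold_map <- function(zmap, params, test_mask) {
  stop_if_not_vol3d(zmap)
  d <- dim(zmap)
  if (any(dim(test_mask) != d)) stop("test mask grid does not match the z-map", call. = FALSE)
  tested <- which(test_mask != 0 & !is.na(zmap))
  if (!length(tested)) stop("empty test mask: no voxels to test", call. = FALSE)
  z <- zmap[tested]
  p <- if (params$two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
  sig <- switch(params$p_mode,
                uncorrected = p <= params$p_value,
                FDR = p <= fdr_threshold(p, params$p_value),
                FWE = p <= params$p_value / length(p))
  surv <- tested[sig]
  clusters <- list()
  if (length(surv)) {
    memb <- label_components(surv, d, params$connectivity)
    for (cl in split(seq_along(surv), memb)) {
      if (length(cl) < params$cluster_k) next
      vox <- surv[cl]
      pk <- vox[which.max(abs(zmap[vox]))]
      clusters[[length(clusters) + 1L]] <-
        list(voxels = sort(vox), size = length(vox),
             peak_voxel = as.integer(vox_coords(pk, d)),
             peak_index = pk, peak_z = zmap[pk])
    }
    if (length(clusters))
      clusters <- clusters[order(vapply(clusters, `[[`, 0L, "size"), decreasing = TRUE)]
  }
  structure(list(clusters = clusters, params_used = params,
                 n_tests = length(tested), grid_shape = d),
            class = "qm_clusters")
}

#' @export
print.qm_clusters <- function(x, ...) {
  cat("<qm_clusters> ", length(x$clusters), " cluster(s) over ", x$n_tests,
      " tested voxels [", format(x$params_used), "]\n", sep = "")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d voxels, peak |z|=%.2f at (%d, %d, %d)%s\n", i, cl$size,
                abs(cl$peak_z), cl$peak_voxel[1L], cl$peak_voxel[2L], cl$peak_voxel[3L],
                if (!is.null(cl$lobe)) sprintf(" [%s %s]", cl$side, cl$lobe) else ""))
  }
  invisible(x)
}

#' @export
summary.qm_clusters <- function(object, ...) {
  data.frame(
    cluster = seq_along(object$clusters),
    size = vapply(object$clusters, `[[`, 0L, "size"),
    peak_z = vapply(object$clusters, `[[`, 0, "peak_z"),
    lobe = vapply(object$clusters, function(cl) cl$lobe %||% NA_character_, ""),
    side = vapply(object$clusters, function(cl) cl$side %||% NA_character_, ""),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove findings outside the cerebral parenchyma
#'
#' Clusters whose peak voxel carries an excluded atlas label (background,
#' CSF, ventricles, brainstem, cerebellum - any label whose lobe is
#' \code{"none"}), or whose peak lies farther than \code{cortex_distance_mm}
#' from the nearest gray-matter voxel, are removed.
#'
#' @param clusters \code{qm_clusters}.
#' @param atlas list with \code{labels} (integer 3D array) and \code{table}
#'   (data.frame with columns label, lobe, side).
#' @param gm_mask logical 3D array of gray-matter voxels (cortex proximity
#'   reference).
#' @param cortex_distance_mm maximum allowed peak-to-cortex distance, mm.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @return filtered \code{qm_clusters}.
#' @export
parenchyma_filter <- function(clusters, atlas, gm_mask, cortex_distance_mm = 5,
                              voxel_size_mm = 1) {
  stopifnot(inherits(clusters, "qm_clusters"))
  check_atlas(atlas)
  d <- clusters$grid_shape
  if (any(dim(atlas$labels) != d)) stop("atlas grid does not match clusters", call. = FALSE)
  gm_idx <- which(gm_mask != 0)
  if (!length(gm_idx)) stop("gray-matter mask is empty", call. = FALSE)
  gm_co <- vox_coords(gm_idx, d)
  excluded <- atlas$table$label[atlas$table$lobe == "none"]
  keep <- vapply(clusters$clusters, function(cl) {
    lab <- atlas$labels[cl$peak_index]
    if (!lab %in% atlas$table$label)
      stop(sprintf("atlas table is missing label %d", lab), call. = FALSE)
    if (lab %in% excluded) return(FALSE)
    pk <- cl$peak_voxel
    d2 <- (gm_co[, 1L] - pk[1L])^2 + (gm_co[, 2L] - pk[2L])^2 + (gm_co[, 3L] - pk[3L])^2
    sqrt(min(d2)) * voxel_size_mm <= cortex_distance_mm
  }, logical(1L))
  out <- clusters
  out$clusters <- clusters$clusters[keep]
  out
}

check_atlas <- function(atlas) {
  if (is.null(atlas$labels) || is.null(atlas$table))
    stop("atlas must have 'labels' and 'table'", call. = FALSE)
  if (!all(c("label", "lobe", "side") %in% names(atlas$table)))
    stop("atlas table must have columns label, lobe, side", call. = FALSE)
  if (!any(atlas$table$lobe == "none"))
    stop("atlas table has no excluded (lobe = 'none') labels", call. = FALSE)
  if (!any(atlas$table$lobe != "none"))
    stop("atlas table has no lobe labels", call. = FALSE)
  invisible(atlas)
}
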