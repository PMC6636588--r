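## False-positive calibration: leave-one-out comparison of each control
## against the rest of the cohort, and selection of detection parameters
## achieving a target subject-level false-positive rate.

## Surviving (post-parenchyma-filter) cluster sizes per control under
## leave-one-out, at cluster_k = 1: the flag decision for any extent
## threshold k is then `any(sizes >= k)`, since the extent criterion and the
## peak-based parenchyma filter commute. Controls whose z-map has no
## testable voxel (zero-variance cohort) yield no clusters.
loo_surviving_sizes <- function(sm_cohort, params, atlas, gm_mask, test_mask,
                                voxel_size_mm, cortex_distance_mm) {
  p1 <- params
  p1$cluster_k <- 1L
  lapply(seq_len(sm_cohort$n), function(i) {
    loo <- cohort_loo_summary(sm_cohort, i)
    z <- zscore_map(sm_cohort$maps[[i]], loo)
    if (!any(test_mask != 0 & !is.na(z))) return(integer(0))
    cl <- threshold_map(z, p1, test_mask)
    cl <- parenchyma_filter(cl, atlas, gm_mask, cortex_distance_mm, voxel_size_mm)
    vapply(cl$clusters, `[[`, 0L, "size")
  })
}

smooth_cohort <- function(cohort, fwhm_mm, voxel_size_mm, mask) {
  if (fwhm_mm == 0) return(cohort)
  control_cohort(lapply(cohort$maps, smooth_map, fwhm_mm = fwhm_mm,
                        voxel_size_mm = voxel_size_mm, mask = mask),
                 modality = cohort$modality)
}

#' Leave-one-out false-positive flags over a control cohort
#'
#' For each control i the cohort summaries are rebuilt without i, and the
#' full detection chain (smooth, z-score, threshold and cluster, parenchyma
#' filter) is run on i's map; the control is flagged when at least one
#' cluster survives. Maps in the cohort are taken unsmoothed; smoothing is
#' applied here per \code{params$smoothing_fwhm_mm} (pass
#' \code{presmoothed = TRUE} if the cohort already holds smoothed maps).
#'
#' @param cohort \code{\link{control_cohort}} of unsmoothed maps; n >= 3.
#' @param params \code{\link{detection_params}}.
#' @param atlas lobe/side atlas (labels + table).
#' @param gm_mask logical 3D array, gray-matter reference for the
#'   parenchyma filter.
#' @param test_mask logical 3D array of voxels to test.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param cortex_distance_mm parenchyma-filter distance, mm.
#' @param presmoothed set TRUE when cohort maps are already smoothed.
#' @return list with \code{n_flagged} and integer vector \code{flagged}.
#' @export
loo_flag_count <- function(cohort, params, atlas, gm_mask, test_mask,
                           voxel_size_mm, cortex_distance_mm = 5,
                           presmoothed = FALSE) {
  stopifnot(inherits(cohort, "qm_cohort"))
  if (cohort$n < 3L) stop("leave-one-out calibration needs >= 3 controls", call. = FALSE)
  sm <- if (presmoothed) cohort
  else smooth_cohort(cohort, params$smoothing_fwhm_mm, voxel_size_mm, test_mask)
  sizes <- loo_surviving_sizes(sm, params, atlas, gm_mask, test_mask,
                               voxel_size_mm, cortex_distance_mm)
  flagged <- which(vapply(sizes, function(s) any(s >= params$cluster_k), logical(1L)))
  list(n_flagged = length(flagged), flagged = flagged)
}

#' Default calibration grid of detection parameters
#'
#' Crosses the three p-value modes used in practice (uncorrected <= 0.001,
#' FWE <= 0.05, FDR <= 0.05) with a ladder of cluster-extent minima, at one
#' smoothing FWHM.
#'
#' @param fwhm_mm smoothing FWHM shared by all grid points.
#' @param cluster_k integer vector of cluster-extent minima; the default
#'   ladder spans small to large extents so the smallest extent reaching
#'   the target rate can be found within the grid.
#' @return list of \code{\link{detection_params}}.
#' @export
default_detection_grid <- function(fwhm_mm = 6,
                                   cluster_k = c(10L, 20L, 30L, 40L, 55L, 80L,
                                                 120L, 200L, 350L, 600L)) {
  grid <- list()
  for (ps in list(list(mode = "uncorrected", p = 0.001),
                  list(mode = "FWE", p = 0.05),
                  list(mode = "FDR", p = 0.05)))
    for (k in cluster_k)
      grid[[length(grid) + 1L]] <- detection_params(fwhm_mm, ps$mode, ps$p, k)
  grid
}

## leniency order of p-modes for tie-breaking: lower = less restrictive
p_mode_rank <- c(uncorrected = 1L, FDR = 2L, FWE = 3L)

#' Calibrate detection parameters to a target false-positive rate
#'
#' Evaluates \code{\link{loo_flag_count}} at every grid point (grid points
#' sharing a smoothing FWHM and p-setting reuse one thresholding pass, since
#' the extent criterion only re-filters cluster sizes). Among parameter sets
#' whose leave-one-out false-positive rate is at or below
#' \code{target_rate}, the one with the smallest cluster-extent threshold is
#' chosen (the lowest cluster threshold reaching the target rate),
#' tie-broken by the less restrictive p-setting (uncorrected before FDR
#' before FWE, then larger p-value), then by grid order. If no grid point is
#' admissible the minimum-rate point is returned and flagged
#' \code{admissible = FALSE}.
#'
#' @inheritParams loo_flag_count
#' @param target_rate target fraction of controls flagged, in (0, 1);
#'   default 0.10.
#' @param search_grid nonempty list of \code{\link{detection_params}}.
#' @return \code{qm_calibration}: \code{chosen_params},
#'   \code{flagged_controls}, \code{fp_rate}, \code{admissible}, \code{n},
#'   and \code{grid_evaluated} (data.frame of every grid point with its
#'   rate).
#' @export
calibrate_fp <- function(cohort, target_rate = 0.10, search_grid = default_detection_grid(),
                         atlas = NULL, gm_mask = NULL, test_mask = NULL,
                         voxel_size_mm = 1, cortex_distance_mm = 5) {
  stopifnot(inherits(cohort, "qm_cohort"))
  if (!length(search_grid)) stop("'search_grid' must be nonempty", call. = FALSE)
  if (target_rate <= 0 || target_rate >= 1) stop("'target_rate' must be in (0, 1)", call. = FALSE)
  if (cohort$n < 3L) stop("leave-one-out calibration needs >= 3 controls", call. = FALSE)

  sm_cache <- list()   # smoothed cohorts, keyed by fwhm
  sz_cache <- list()   # per-control surviving cluster sizes, keyed by p-setting
  rows <- vector("list", length(search_grid))
  flags <- vector("list", length(search_grid))
  for (gi in seq_along(search_grid)) {
    prm <- search_grid[[gi]]
    fk <- format(prm$smoothing_fwhm_mm)
    if (is.null(sm_cache[[fk]]))
      sm_cache[[fk]] <- smooth_cohort(cohort, prm$smoothing_fwhm_mm,
                                      voxel_size_mm, test_mask)
    pk <- paste(fk, prm$p_mode, prm$p_value, prm$two_sided, prm$connectivity)
    if (is.null(sz_cache[[pk]]))
      sz_cache[[pk]] <- loo_surviving_sizes(sm_cache[[fk]], prm, atlas, gm_mask,
                                            test_mask, voxel_size_mm,
                                            cortex_distance_mm)
    fl <- which(vapply(sz_cache[[pk]], function(s) any(s >= prm$cluster_k), logical(1L)))
    flags[[gi]] <- fl
    rows[[gi]] <- data.frame(grid_index = gi, fwhm_mm = prm$smoothing_fwhm_mm,
                             p_mode = prm$p_mode, p_value = prm$p_value,
                             cluster_k = prm$cluster_k,
                             n_flagged = length(fl),
                             fp_rate = length(fl) / cohort$n,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)

  admissible <- tab$fp_rate <= target_rate
  if (any(admissible)) {
    cand <- tab[admissible, , drop = FALSE]
    ord <- order(cand$cluster_k, p_mode_rank[cand$p_mode], -cand$p_value, cand$grid_index)
    chosen <- cand$grid_index[ord[1L]]
    ok <- TRUE
  } else {
    ord <- order(tab$fp_rate, tab$grid_index)
    chosen <- tab$grid_index[ord[1L]]
    ok <- FALSE
  }
  structure(list(chosen_params = search_grid[[chosen]],
                 flagged_controls = flags[[chosen]],
                 fp_rate = tab$fp_rate[tab$grid_index == chosen],
                 admissible = ok, target_rate = target_rate, n = cohort$n,
                 grid_evaluated = tab),
            class = "qm_calibration")
}

#' @export
print.qm_calibration <- function(x, ...) {
  cat("<qm_calibration> n = ", x$n, " controls, target FP rate ",
      format(x$target_rate), "\n", sep = "")
  cat("  chosen: ", format(x$chosen_params), "\n", sep = "")
  cat(sprintf("  achieved FP rate: %.3f (%d/%d flagged)%s\n", x$fp_rate,
              length(x$flagged_controls), x$n,
              if (x$admissible) "" else " [no grid point met the target]"))
  invisible(x)
}

#' @export
summary.qm_calibration <- function(object, ...) object$grid_evaluated
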