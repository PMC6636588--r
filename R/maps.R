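## Quantitative map computation: multi-echo T2 relaxometry (log-linear fit),
## magnetization transfer ratio, and the gray-white junction (WGJS) map.
## Mean diffusivity and cortical thickness are consumed as precomputed maps
## and only validated here.

#' Voxelwise T2 relaxometry by log-linear fitting
#'
#' Fits \code{ln(S) = -TE/T2 + ln(S0)} per masked voxel by ordinary least
#' squares of the log-signal on echo time, giving \code{T2 = -1/slope} and
#' \code{S0 = exp(intercept)}. Voxels with any nonpositive signal, a
#' non-decaying fit (slope >= 0), or a fitted T2 above \code{t2_max} are
#' cleared from the valid mask and set to the sentinel value -1 rather than
#' clamped, so fit failures stay visible. The ceiling exists because decay
#' times much longer than the echo train (here TE <= 100 ms against
#' CSF-like T2 of ~2000 ms) leave the slope indistinguishable from zero and
#' the estimate unbounded; such voxels are flagged unreliable rather than
#' propagated.
#'
#' @param echo_series 4D array (x, y, z, echo).
#' @param te_ms strictly increasing echo times, ms; >= 2 echoes.
#' @param mask logical/0-1 3D array of voxels to fit (default: all).
#' @param t2_max validity ceiling on fitted T2, ms; \code{Inf} disables it.
#' @return \code{qm_t2fit}: list with \code{t2_map} (ms), \code{s0_map},
#'   \code{valid_mask}.
#' @export
fit_t2_map <- function(echo_series, te_ms, mask = NULL, t2_max = 1000) {
  if (!is.array(echo_series) || length(dim(echo_series)) != 4L)
    stop("'echo_series' must be a 4D array (x, y, z, echo)", call. = FALSE)
  ne <- dim(echo_series)[4L]
  if (length(te_ms) != ne) stop("length of 'te_ms' must match 4th dimension", call. = FALSE)
  if (ne < 2L) stop("at least 2 echoes are required", call. = FALSE)
  if (any(diff(te_ms) <= 0)) stop("'te_ms' must be strictly increasing", call. = FALSE)
  d <- dim(echo_series)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  if (any(dim(mask) != d)) stop("mask dimensions do not match echo series", call. = FALSE)
  idx <- which(mask != 0)

  S <- matrix(echo_series, prod(d), ne)[idx, , drop = FALSE]
  pos <- rowSums(S <= 0) == 0L
  lnS <- log(pmax(S, .Machine$double.xmin))
  te_c <- te_ms - mean(te_ms)
  slope <- as.vector(lnS %*% te_c) / sum(te_c^2)
  intercept <- rowMeans(lnS) - slope * mean(te_ms)
  ok <- pos & slope < -1 / t2_max

  t2 <- array(-1, d); s0 <- array(-1, d); valid <- array(FALSE, d)
  t2[idx[ok]] <- -1 / slope[ok]
  s0[idx[ok]] <- exp(intercept[ok])
  valid[idx[ok]] <- TRUE
  structure(list(t2_map = t2, s0_map = s0, valid_mask = valid),
            class = "qm_t2fit")
}

#' @export
print.qm_t2fit <- function(x, ...) {
  v <- x$t2_map[x$valid_mask]
  cat("<qm_t2fit> ", sum(x$valid_mask), " valid voxels",
      if (length(v)) sprintf("; median T2 = %.1f ms", stats::median(v)), "\n", sep = "")
  invisible(x)
}

#' Magnetization transfer ratio map
#'
#' \code{MTR = (MToff - MTon) / MToff * 100} per masked voxel. Voxels with
#' \code{MToff <= 0} are set to \code{NA} and dropped from the valid mask
#' (attribute \code{valid_mask}).
#'
#' @param mt_off,mt_on aligned 3D arrays.
#' @param mask logical/0-1 3D array (default: all).
#' @return 3D array of MTR in percent, \code{NA} where undefined, with a
#'   \code{valid_mask} attribute.
#' @export
compute_mtr <- function(mt_off, mt_on, mask = NULL) {
  stop_if_not_vol3d(mt_off); stop_if_not_vol3d(mt_on)
  if (any(dim(mt_off) != dim(mt_on))) stop("MT volumes have mismatched shapes", call. = FALSE)
  d <- dim(mt_off)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (any(dim(mask) != d)) stop("mask dimensions do not match MT volumes", call. = FALSE)
  valid <- (mask != 0) & (mt_off > 0)
  out <- array(NA_real_, d)
  out[valid] <- (mt_off[valid] - mt_on[valid]) / mt_off[valid] * 100
  attr(out, "valid_mask") <- valid
  out
}

#' Gray-white junction mask from T1-weighted intensities
#'
#' Binary GM and WM masks are voxels with tissue probability above
#' \code{prob_threshold}; the junction mask is every brain voxel whose
#' T1-weighted intensity falls in the interval
#' \code{[Mean_GM - SD_GM, Mean_WM + SD_WM]}, with the means and SDs taken
#' from this subject's own masks, so the rule is invariant to global
#' intensity scaling.
#'
#' @param t1w 3D intensity array.
#' @param tpm list with 3D probability arrays \code{gm}, \code{wm}.
#' @param prob_threshold tissue-probability cutoff in (0,1), default 0.9.
#' @param brain_mask optional logical 3D array restricting the junction mask.
#' @return \code{qm_junction}: \code{gm_mask}, \code{wm_mask},
#'   \code{interval_low}, \code{interval_high}, \code{junction_mask}.
#' @export
junction_mask <- function(t1w, tpm, prob_threshold = 0.9, brain_mask = NULL) {
  stop_if_not_vol3d(t1w)
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stop("'prob_threshold' must be in (0, 1)", call. = FALSE)
  if (any(dim(tpm$gm) != dim(t1w)) || any(dim(tpm$wm) != dim(t1w)))
    stop("tissue probability maps do not match the T1 volume", call. = FALSE)
  gm <- tpm$gm > prob_threshold
  wm <- tpm$wm > prob_threshold
  if (!any(gm)) stop("empty GM mask: cannot estimate the intensity interval", call. = FALSE)
  if (!any(wm)) stop("empty WM mask: cannot estimate the intensity interval", call. = FALSE)
  mean_gm <- mean(t1w[gm]); sd_gm <- stats::sd(t1w[gm])
  mean_wm <- mean(t1w[wm]); sd_wm <- stats::sd(t1w[wm])
  if (is.na(sd_gm)) sd_gm <- 0
  if (is.na(sd_wm)) sd_wm <- 0
  lo <- mean_gm - sd_gm; hi <- mean_wm + sd_wm
  jm <- t1w >= lo & t1w <= hi
  if (!is.null(brain_mask)) jm <- jm & (brain_mask != 0)
  structure(list(gm_mask = gm, wm_mask = wm,
                 interval_low = lo, interval_high = hi,
                 junction_mask = jm),
            class = "qm_junction")
}

#' Convolved junction map
#'
#' Each voxel is the count of junction-mask voxels within its
#' \code{kernel_size^3} cubic neighborhood: convolution of the binary mask
#' with a unitary 3D box kernel, zero-padded at the borders. Counts are in
#' \code{[0, kernel_size^3]}.
#'
#' @param jmask binary 3D array (a junction mask).
#' @param kernel_size odd edge length of the box kernel, default 5.
#' @return 3D numeric array of neighborhood counts.
#' @export
junction_map <- function(jmask, kernel_size = 5L) {
  stop_if_not_vol3d(jmask)
  if (kernel_size %% 2L == 0L) stop("'kernel_size' must be odd", call. = FALSE)
  round(box_count(jmask, kernel_size))
}

#' Validate a precomputed scalar map for pass-through
#'
#' Mean diffusivity and cortical thickness arrive precomputed; this checks
#' grid alignment and non-negativity inside the brain mask and returns the
#' map unchanged.
#'
#' @param map 3D array.
#' @param modality \code{"MD"} or \code{"thickness"}.
#' @param brain_mask logical 3D array on the same grid.
#' @return \code{map}, unchanged.
#' @export
validate_passthrough <- function(map, modality = c("MD", "thickness"), brain_mask) {
  modality <- match.arg(modality)
  stop_if_not_vol3d(map)
  if (any(dim(map) != dim(brain_mask)))
    stop(sprintf("%s map grid does not match the brain mask", modality), call. = FALSE)
  bad <- which(brain_mask != 0 & map < 0)
  if (length(bad)) {
    v <- vox_coords(bad[1L], dim(map))
    stop(sprintf("negative %s value inside the brain mask at voxel (%d, %d, %d)",
                 modality, v[1L], v[2L], v[3L]), call. = FALSE)
  }
  map
}
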