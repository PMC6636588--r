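# Brute-force oracles implemented from the operation definitions,
# independent of the package's vectorized code paths, plus small fixtures.

# neighborhood count by direct summation over all kernel offsets
bf_box_conv <- function(mask, kernel_size) {
  d <- dim(mask)
  r <- (kernel_size - 1L) %/% 2L
  out <- array(0, d)
  m <- array(as.numeric(mask != 0), d)
  for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
    src_i <- seq_len(d[1]) + di; src_j <- seq_len(d[2]) + dj; src_k <- seq_len(d[3]) + dk
    oi <- which(src_i >= 1 & src_i <= d[1]); oj <- which(src_j >= 1 & src_j <= d[2])
    ok <- which(src_k >= 1 & src_k <= d[3])
    out[oi, oj, ok] <- out[oi, oj, ok] + m[src_i[oi], src_j[oj], src_k[ok]]
  }
  out
}

# junction rule applied voxel by voxel
bf_junction_mask <- function(t1w, tpm, prob_threshold, brain_mask) {
  gm <- tpm$gm > prob_threshold; wm <- tpm$wm > prob_threshold
  lo <- mean(t1w[gm]) - sd(t1w[gm]); hi <- mean(t1w[wm]) + sd(t1w[wm])
  out <- array(FALSE, dim(t1w))
  for (v in seq_along(t1w))
    out[v] <- brain_mask[v] && t1w[v] >= lo && t1w[v] <= hi
  out
}

# per-voxel p test + stack-based flood fill at the given connectivity
bf_threshold_cluster <- function(zmap, p_value, cluster_k, test_mask,
                                 two_sided = TRUE, connectivity = 26L) {
  d <- dim(zmap)
  p <- if (two_sided) 2 * pnorm(-abs(zmap)) else pnorm(-zmap)
  sig <- array(FALSE, d)
  idx <- which(test_mask != 0 & !is.na(zmap))
  sig[idx] <- p[idx] <= p_value
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- off[switch(as.character(connectivity),
                    "6" = rowSums(abs(off)) == 1,
                    "18" = rowSums(abs(off)) <= 2,
                    "26" = rep(TRUE, nrow(off))), , drop = FALSE]
  seen <- array(FALSE, d)
  clusters <- list()
  for (start in which(sig)) {
    if (seen[start]) next
    stack <- start; seen[start] <- TRUE; members <- integer(0)
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      members <- c(members, v)
      v0 <- v - 1L
      ci <- v0 %% d[1] + 1L; cj <- (v0 %/% d[1]) %% d[2] + 1L; ck <- v0 %/% (d[1] * d[2]) + 1L
      for (r in seq_len(nrow(off))) {
        ni <- ci + off[r, 1]; nj <- cj + off[r, 2]; nk <- ck + off[r, 3]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
        nv <- ni + (nj - 1L) * d[1] + (nk - 1L) * d[1] * d[2]
        if (sig[nv] && !seen[nv]) { seen[nv] <- TRUE; stack <- c(stack, nv) }
      }
    }
    if (length(members) >= cluster_k)
      clusters[[length(clusters) + 1L]] <- sort(members)
  }
  clusters
}

# Benjamini-Hochberg by its step-up definition, loop form
bf_fdr_cutoff <- function(p, q) {
  p <- sort(p)
  m <- length(p)
  cut <- 0
  for (i in seq_len(m)) if (p[i] <= i * q / m) cut <- p[i]
  cut
}

# minimum Euclidean distance from a voxel to a mask, plain loop
bf_min_dist_mm <- function(voxel, mask, voxel_size_mm) {
  idx <- which(mask != 0)
  d <- dim(mask)
  best <- Inf
  for (v in idx) {
    v0 <- v - 1L
    ci <- v0 %% d[1] + 1L; cj <- (v0 %/% d[1]) %% d[2] + 1L; ck <- v0 %/% (d[1] * d[2]) + 1L
    dist <- sqrt((ci - voxel[1])^2 + (cj - voxel[2])^2 + (ck - voxel[3])^2) * voxel_size_mm
    if (dist < best) best <- dist
  }
  best
}

# reduced-size phantom spec for fast unit tests
small_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(24L, 28L, 24L), seed = seed, ...)
}

# spec with all between-subject SDs and all noise set to zero
degenerate_spec <- function(seed = 1L, grid_shape = c(16L, 18L, 16L)) {
  tp <- default_tissue_params()
  for (tis in names(tp)) for (f in names(tp[[tis]])) tp[[tis]][[f]][2] <- 0
  phantom_spec(grid_shape = grid_shape, tissue_params = tp,
               noise_sd = c(echo = 0, mt = 0, md = 0, thickness = 0, t1w = 0),
               seed = seed)
}

# minimal hand-built atlas on an arbitrary grid: left/right split along
# axis 1, single "frontal" lobe, plus label 1 = ventricle (excluded)
toy_atlas <- function(d, ventricle = NULL) {
  lab <- array(0L, d)
  lab[seq_len(floor(d[1] / 2)), , ] <- 11L
  lab[(floor(d[1] / 2) + 1):d[1], , ] <- 21L
  if (!is.null(ventricle)) lab[ventricle] <- 1L
  list(labels = lab,
       table = data.frame(label = c(0L, 1L, 11L, 21L),
                          lobe = c("none", "none", "frontal", "frontal"),
                          side = c("none", "none", "left", "right"),
                          stringsAsFactors = FALSE))
}
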