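## Synthetic brain phantoms: concentric smoothed ellipsoids (ventricular CSF
## core, WM interior, GM ribbon, CSF rim) carrying per-tissue quantitative
## parameters, smooth between-subject random fields, channel noise, and
## insertable focal lesions. Everything downstream of acquisition is
## exercised on these phantoms, so the generator is first-class, tested code.

CHANNEL_FIELDS <- c("t2", "s0", "satfrac", "pd", "md", "t1w", "thickness")

#' Default per-tissue parameters for the phantom generator
#'
#' Literature-typical 3T values, \code{c(mean, sd)} per field and tissue:
#' \code{t2} (ms), \code{s0} and \code{pd} (a.u. signal), \code{satfrac}
#' (MT saturation fraction, unitless), \code{md} (10^-3 mm^2/s), \code{t1w}
#' (a.u. intensity), \code{thickness} (mm, cortical ribbon only). The sd is
#' the between-subject standard deviation of the spatially smooth random
#' field added per subject.
#'
#' @return named list with elements \code{gm}, \code{wm}, \code{csf}.
#' @export
default_tissue_params <- function() {
  list(
    gm = list(t2 = c(100, 5),   s0 = c(1000, 30), satfrac = c(0.35, 0.02),
              pd = c(900, 30),  md = c(0.85, 0.05), t1w = c(400, 20),
              thickness = c(2.7, 0.3)),
    wm = list(t2 = c(80, 4),    s0 = c(1000, 30), satfrac = c(0.45, 0.02),
              pd = c(800, 25),  md = c(0.75, 0.05), t1w = c(600, 20),
              thickness = c(0, 0)),
    csf = list(t2 = c(2000, 100), s0 = c(1100, 40), satfrac = c(0.02, 0.01),
               pd = c(1100, 40), md = c(3.0, 0.2),  t1w = c(150, 15),
               thickness = c(0, 0))
  )
}

#' Specification of a synthetic brain phantom cohort
#'
#' @param grid_shape integer vector of 3 positive voxel counts.
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @param tissue_params per-tissue \code{c(mean, sd)} parameters, see
#'   \code{\link{default_tissue_params}}.
#' @param noise_sd additive noise standard deviation per observed channel
#'   (named: echo, mt, md, thickness, t1w), in each channel's own units.
#' @param noise_type \code{"gaussian"} (default) or \code{"rician"}; Rician
#'   noise is applied to the magnitude channels (echoes, MT pair) only.
#' @param te_ms strictly increasing echo times of the multi-echo series, ms.
#' @param between_subject_smoothness_mm FWHM of the Gaussian random field
#'   that carries between-subject variability; 0 gives voxelwise white
#'   variability.
#' @param seed integer; subject i is generated from \code{seed + i}, so any
#'   subject is reproducible in isolation.
#' @return object of class \code{qm_phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(48L, 56L, 48L),
                         voxel_size_mm = 3,
                         tissue_params = default_tissue_params(),
                         noise_sd = c(echo = 10, mt = 10, md = 0.02,
                                      thickness = 0.05, t1w = 8),
                         noise_type = c("gaussian", "rician"),
                         te_ms = c(20, 40, 60, 80, 100),
                         between_subject_smoothness_mm = 12,
                         seed = 1L) {
  noise_type <- match.arg(noise_type)
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_size_mm = voxel_size_mm,
                         tissue_params = tissue_params,
                         noise_sd = noise_sd, noise_type = noise_type,
                         te_ms = te_ms,
                         between_subject_smoothness_mm = between_subject_smoothness_mm,
                         seed = as.integer(seed)),
                    class = "qm_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  g <- spec$grid_shape
  if (length(g) != 3L || any(!is.finite(g)) || any(g < 1L))
    stop("invalid phantom spec: 'grid_shape' must be 3 positive integers", call. = FALSE)
  if (!is.numeric(spec$voxel_size_mm) || spec$voxel_size_mm <= 0)
    stop("invalid phantom spec: 'voxel_size_mm' must be positive", call. = FALSE)
  if (length(spec$te_ms) < 2L || any(diff(spec$te_ms) <= 0))
    stop("invalid phantom spec: 'te_ms' must be >= 2 strictly increasing echo times", call. = FALSE)
  for (nm in c("echo", "mt", "md", "thickness", "t1w"))
    if (is.na(spec$noise_sd[nm]) || spec$noise_sd[nm] < 0)
      stop(sprintf("invalid phantom spec: 'noise_sd[%s]' must be >= 0", nm), call. = FALSE)
  if (spec$between_subject_smoothness_mm < 0)
    stop("invalid phantom spec: 'between_subject_smoothness_mm' must be >= 0", call. = FALSE)
  for (tis in c("gm", "wm", "csf")) {
    tp <- spec$tissue_params[[tis]]
    if (is.null(tp)) stop(sprintf("invalid phantom spec: 'tissue_params$%s' missing", tis), call. = FALSE)
    for (f in CHANNEL_FIELDS) {
      v <- tp[[f]]
      if (is.null(v) || length(v) != 2L || any(!is.finite(v)))
        stop(sprintf("invalid phantom spec: 'tissue_params$%s$%s' must be c(mean, sd)", tis, f), call. = FALSE)
      if (v[2L] < 0)
        stop(sprintf("invalid phantom spec: 'tissue_params$%s$%s' sd must be >= 0", tis, f), call. = FALSE)
    }
    if (tp$t2[1L] <= 0)
      stop(sprintf("invalid phantom spec: 'tissue_params$%s$t2' mean must be > 0", tis), call. = FALSE)
    if (tp$satfrac[1L] < 0 || tp$satfrac[1L] >= 1)
      stop(sprintf("invalid phantom spec: 'tissue_params$%s$satfrac' mean must be in [0,1)", tis), call. = FALSE)
  }
  invisible(spec)
}

## Deterministic geometry shared by all subjects of a spec: normalized
## ellipsoidal radius, hard tissue labels (0 bg, 1 CSF, 2 GM, 3 WM),
## smoothed tissue probability maps, brain mask, and a lobe/side atlas.
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  semi <- pmax(d / 2 - 3, 2)
  i <- array(rep(seq_len(d[1L]), times = d[2L] * d[3L]), d)
  j <- array(rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]), d)
  k <- array(rep(seq_len(d[3L]), each = d[1L] * d[2L]), d)
  r <- sqrt(((i - ctr[1L]) / semi[1L])^2 + ((j - ctr[2L]) / semi[2L])^2 +
            ((k - ctr[3L]) / semi[3L])^2)
  lab <- array(0L, d)
  lab[r <= 1]    <- 1L            # CSF rim
  lab[r <= 0.92] <- 2L            # GM ribbon
  lab[r <= 0.72] <- 3L            # WM interior
  lab[r <= 0.18] <- 1L            # ventricular CSF
  brain <- r <= 1

  ## tissue probability maps: smoothed hard indicators, renormalized so
  ## gm + wm + csf <= 1 everywhere
  sm <- function(ind) smooth_map(array(as.numeric(ind), d), 4, spec$voxel_size_mm)
  p_gm <- sm(lab == 2L); p_wm <- sm(lab == 3L); p_csf <- sm(lab == 1L)
  s <- p_gm + p_wm + p_csf
  over <- s > 1
  p_gm[over] <- p_gm[over] / s[over]
  p_wm[over] <- p_wm[over] / s[over]
  p_csf[over] <- p_csf[over] / s[over]

  ## atlas: parenchyma (GM+WM) split into lobe x side octants; CSF labelled
  ## separately (ventricle vs rim) so the parenchyma filter has excluded labels
  atlas_lab <- array(0L, d)
  atlas_lab[r <= 1] <- 1L                      # CSF rim
  atlas_lab[r <= 0.18] <- 2L                   # ventricle
  paren <- lab == 2L | lab == 3L
  side_right <- i >= ctr[1L]
  ant <- j >= ctr[2L]; sup <- k >= ctr[3L]
  lobe_code <- ifelse(ant & sup, 1L, ifelse(ant & !sup, 2L, ifelse(!ant & sup, 3L, 4L)))
  atlas_lab[paren] <- (10L + 10L * side_right[paren]) + lobe_code[paren]
  atlas_table <- data.frame(
    label = c(0L, 1L, 2L, 11:14, 21:24),
    lobe = c("none", "none", "none",
             rep(c("frontal", "temporal", "parietal", "occipital"), 2L)),
    side = c("none", "none", "none", rep("left", 4L), rep("right", 4L)),
    stringsAsFactors = FALSE)

  list(r = r, tissue_label = lab, brain_mask = brain,
       tpm = list(gm = p_gm, wm = p_wm, csf = p_csf),
       atlas = list(labels = atlas_lab, table = atlas_table))
}

## Unit-variance spatially smooth Gaussian random field (interior variance
## normalized analytically; edges slightly under-dispersed, documented).
smooth_unit_field <- function(d, fwhm_mm, voxel_size_mm) {
  z <- array(stats::rnorm(prod(d)), d)
  if (fwhm_mm == 0) return(z)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  kk <- gaussian_kernel_1d(sigma_vox)
  conv_separable(z, kk) / sqrt(sum(kk^2))^3
}

tissue_value_map <- function(lab, tissue_params, field, stat) {
  ## stat: 1 = mean, 2 = sd; label codes 1 csf, 2 gm, 3 wm
  lut <- c(0, tissue_params$csf[[field]][stat], tissue_params$gm[[field]][stat],
           tissue_params$wm[[field]][stat])
  array(lut[lab + 1L], dim(lab))
}

## Latent (pre-noise) per-channel fields for one subject; RNG state is the
## caller's responsibility.
draw_latent <- function(spec, geom) {
  d <- spec$grid_shape
  lat <- list()
  for (f in CHANNEL_FIELDS) {
    g <- smooth_unit_field(d, spec$between_subject_smoothness_mm, spec$voxel_size_mm)
    lat[[f]] <- tissue_value_map(geom$tissue_label, spec$tissue_params, f, 1L) +
      tissue_value_map(geom$tissue_label, spec$tissue_params, f, 2L) * g
  }
  lat$t2 <- pmax(lat$t2, 1)
  lat$satfrac <- pmin(pmax(lat$satfrac, 0), 0.999)
  lat$thickness <- pmax(lat$thickness, 0)
  lat
}

draw_noise <- function(spec) {
  d <- spec$grid_shape; n <- prod(d); ne <- length(spec$te_ms)
  rician <- spec$noise_type == "rician"
  noise <- list(echo = array(stats::rnorm(n * ne, sd = spec$noise_sd["echo"]), c(d, ne)),
                mt_off = array(stats::rnorm(n, sd = spec$noise_sd["mt"]), d),
                mt_on = array(stats::rnorm(n, sd = spec$noise_sd["mt"]), d),
                md = array(stats::rnorm(n, sd = spec$noise_sd["md"]), d),
                thickness = array(stats::rnorm(n, sd = spec$noise_sd["thickness"]), d),
                t1w = array(stats::rnorm(n, sd = spec$noise_sd["t1w"]), d))
  if (rician) {
    noise$echo_q <- array(stats::rnorm(n * ne, sd = spec$noise_sd["echo"]), c(d, ne))
    noise$mt_off_q <- array(stats::rnorm(n, sd = spec$noise_sd["mt"]), d)
    noise$mt_on_q <- array(stats::rnorm(n, sd = spec$noise_sd["mt"]), d)
  }
  noise
}

## Observed channels from latent + frozen noise: keeps lesion insertion and
## generation consistent (re-derivation with unchanged latent is bit-identical).
derive_observed <- function(spec, geom, lat, noise) {
  d <- spec$grid_shape; ne <- length(spec$te_ms)
  rician <- spec$noise_type == "rician"
  mag <- function(signal, n1, n2) if (rician) sqrt((signal + n1)^2 + n2^2) else signal + n1
  echo <- array(0, c(d, ne))
  for (e in seq_len(ne)) {
    s <- lat$s0 * exp(-spec$te_ms[e] / lat$t2)
    n1 <- noise$echo[, , , e, drop = FALSE]; dim(n1) <- d
    if (rician) { n2 <- noise$echo_q[, , , e, drop = FALSE]; dim(n2) <- d } else n2 <- NULL
    echo[, , , e] <- mag(s, n1, n2)
  }
  mt_off <- mag(lat$pd, noise$mt_off, noise$mt_off_q)
  mt_on <- mag(lat$pd * (1 - lat$satfrac), noise$mt_on, noise$mt_on_q)
  ribbon <- geom$tissue_label == 2L
  list(echo_series = echo,
       mt_off = mt_off, mt_on = mt_on,
       md_map = pmax(lat$md + noise$md, 0),
       thickness_map = pmax(lat$thickness + noise$thickness, 0) * ribbon,
       t1w = lat$t1w + noise$t1w)
}

#' Generate a cohort of synthetic subjects
#'
#' Subject \code{i} is drawn from RNG seed \code{spec$seed + i}, so cohorts
#' are reproducible and extensible without regenerating earlier subjects.
#' Echo signals follow \code{S = S0 * exp(-TE/T2)} voxelwise from the
#' subject's smooth random-field T2/S0 before noise, and
#' \code{MTon = MToff * (1 - saturation_fraction)} before noise.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n_subjects number of subjects, >= 1.
#' @return list of \code{qm_subject} objects.
#' @export
generate_phantom <- function(spec, n_subjects) {
  validate_phantom_spec(spec)
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("'n_subjects' must be >= 1", call. = FALSE)
  geom <- phantom_geometry(spec)
  lapply(seq_len(n_subjects), function(i) generate_subject(spec, geom, i))
}

generate_subject <- function(spec, geom, i) {
  set.seed(spec$seed + i)
  lat <- draw_latent(spec, geom)
  noise <- draw_noise(spec)
  obs <- derive_observed(spec, geom, lat, noise)
  structure(c(obs, list(
    te_ms = spec$te_ms,
    tpm = geom$tpm,
    brain_mask = geom$brain_mask,
    atlas = geom$atlas,
    tissue_label = geom$tissue_label,
    voxel_size_mm = spec$voxel_size_mm,
    grid_shape = spec$grid_shape,
    latent = lat, noise = noise, spec = spec,
    subject_id = sprintf("sub-%03d", i))), class = "qm_subject")
}

#' Lesion specification
#'
#' A spherical focal perturbation of one latent channel. \code{delta} is
#' expressed in multiples of the between-subject standard deviation of that
#' channel at each affected voxel (its tissue's sd), mimicking an effect-size
#' parameterization.
#'
#' @param center_voxel integer grid coordinate (i, j, k) of the sphere centre.
#' @param radius_mm sphere radius, mm; must be > 0.
#' @param channel one of \code{"t2"}, \code{"mtr"}, \code{"md"},
#'   \code{"thickness"}, \code{"t1w"}.
#' @param delta signed offset in units of local between-subject sd.
#' @return object of class \code{qm_lesion_spec}.
#' @export
lesion_spec <- function(center_voxel, radius_mm, channel, delta) {
  channel <- match.arg(channel, c("t2", "mtr", "md", "thickness", "t1w"))
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("'radius_mm' must be > 0", call. = FALSE)
  structure(list(center_voxel = as.numeric(center_voxel), radius_mm = radius_mm,
                 channel = channel, delta = delta), class = "qm_lesion_spec")
}

lesion_channel_field <- c(t2 = "t2", mtr = "satfrac", md = "md",
                          thickness = "thickness", t1w = "t1w")

#' Insert a focal lesion into a synthetic subject
#'
#' Offsets the targeted latent channel inside the lesion sphere by
#' \code{delta} local between-subject standard deviations, then re-derives
#' the affected observed volumes from the frozen noise realization. Voxels
#' outside the sphere, and all untargeted channels, are bit-identical to the
#' input.
#'
#' @param subject a \code{qm_subject} from \code{\link{generate_phantom}}.
#' @param lesion a \code{\link{lesion_spec}}.
#' @return modified \code{qm_subject}.
#' @export
insert_lesion <- function(subject, lesion) {
  stopifnot(inherits(subject, "qm_subject"), inherits(lesion, "qm_lesion_spec"))
  d <- subject$grid_shape
  ctr <- lesion$center_voxel
  if (any(ctr < 1) || any(ctr > d)) stop("lesion centre outside the grid", call. = FALSE)
  i <- array(rep(seq_len(d[1L]), times = d[2L] * d[3L]), d)
  j <- array(rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]), d)
  k <- array(rep(seq_len(d[3L]), each = d[1L] * d[2L]), d)
  vs <- subject$voxel_size_mm
  sphere <- ((i - ctr[1L])^2 + (j - ctr[2L])^2 + (k - ctr[3L])^2) * vs^2 <=
    lesion$radius_mm^2
  if (!any(sphere & subject$brain_mask))
    stop("lesion sphere does not intersect the brain mask", call. = FALSE)

  f <- lesion_channel_field[[lesion$channel]]
  sd_map <- tissue_value_map(subject$tissue_label, subject$spec$tissue_params, f, 2L)
  lat <- subject$latent
  lat[[f]] <- lat[[f]] + lesion$delta * sd_map * sphere
  if (f == "t2") lat$t2 <- pmax(lat$t2, 1)
  if (f == "satfrac") lat$satfrac <- pmin(pmax(lat$satfrac, 0), 0.999)
  if (f == "thickness") lat$thickness <- pmax(lat$thickness, 0)

  geom <- list(tissue_label = subject$tissue_label)
  obs <- derive_observed(subject$spec, geom, lat, subject$noise)
  out <- subject
  out$latent <- lat
  affected <- switch(lesion$channel,
                     t2 = "echo_series", mtr = "mt_on", md = "md_map",
                     thickness = "thickness_map", t1w = "t1w")
  out[[affected]] <- obs[[affected]]
  out$lesion <- lesion
  out$lesion_mask <- sphere
  out
}

#' @export
print.qm_subject <- function(x, ...) {
  cat("<qm_subject> ", x$subject_id, "\n", sep = "")
  cat("  grid: ", paste(x$grid_shape, collapse = " x "),
      " @ ", x$voxel_size_mm, " mm\n", sep = "")
  cat("  echoes: TE = ", paste(x$te_ms, collapse = ", "), " ms\n", sep = "")
  cat("  brain voxels: ", sum(x$brain_mask), "\n", sep = "")
  if (!is.null(x$lesion))
    cat("  lesion: ", x$lesion$channel, " delta=", x$lesion$delta,
        " r=", x$lesion$radius_mm, " mm (", sum(x$lesion_mask), " voxels)\n", sep = "")
  invisible(x)
}
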