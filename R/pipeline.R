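## Pipeline orchestration: simulate -> quantitative maps -> calibrate ->
## detect -> concordance, as a configured, logged, reproducible run.

#' Compute one quantitative measure map for a subject
#'
#' Dispatches to the map modules: \code{T2} (log-linear relaxometry fit),
#' \code{MTR}, \code{WGJS} (junction mask + box-kernel convolution),
#' \code{MD} and \code{CThk} (validated pass-through). Returns the map and
#' the voxel set on which the measure is defined and tested.
#'
#' @param subject \code{qm_subject}.
#' @param measure one of \code{"T2"}, \code{"MTR"}, \code{"WGJS"},
#'   \code{"MD"}, \code{"CThk"}.
#' @return list with \code{map} (3D array) and \code{mask} (logical 3D
#'   array of tested voxels).
#' @export
measure_map <- function(subject, measure = c("T2", "MTR", "WGJS", "MD", "CThk")) {
  measure <- match.arg(measure)
  bm <- subject$brain_mask
  switch(measure,
    T2 = {
      fit <- fit_t2_map(subject$echo_series, subject$te_ms, bm)
      list(map = fit$t2_map, mask = fit$valid_mask)
    },
    MTR = {
      m <- compute_mtr(subject$mt_off, subject$mt_on, bm)
      vm <- attr(m, "valid_mask")
      m[!vm] <- 0
      attr(m, "valid_mask") <- NULL
      list(map = m, mask = vm)
    },
    WGJS = {
      ja <- junction_mask(subject$t1w, subject$tpm, 0.9, bm)
      list(map = junction_map(ja$junction_mask, 5L), mask = bm)
    },
    MD = list(map = validate_passthrough(subject$md_map, "MD", bm), mask = bm),
    CThk = {
      ribbon <- subject$tpm$gm > 0.5
      list(map = validate_passthrough(subject$thickness_map, "thickness", bm),
           mask = ribbon & bm)
    })
}

#' Per-measure default detection parameters
#'
#' The parameterization used in individualized postprocessing practice:
#' cortical thickness at 10 mm FWHM with FDR 0.05 (no cluster-extent
#' criterion beyond 1 voxel), WGJS at 8 mm with uncorrected p <= 0.001 and
#' k = 30, and T2/MTR/MD at 6 mm with FWE 0.05 and k = 55/30/40.
#'
#' @return named list of \code{\link{detection_params}}.
#' @export
default_measure_params <- function() {
  list(CThk = detection_params(10, "FDR", 0.05, 1L),
       WGJS = detection_params(8, "uncorrected", 0.001, 30L),
       T2 = detection_params(6, "FWE", 0.05, 55L),
       MTR = detection_params(6, "FWE", 0.05, 30L),
       MD = detection_params(6, "FWE", 0.05, 40L))
}

#' Run configuration for the full pipeline
#'
#' Inputs may be in-memory subjects or directories written by
#' \code{\link{write_subject}}. Per-measure detection parameters may be
#' given explicitly; measures without parameters are calibrated on the
#' control cohort to \code{target_fp_rate} over
#' \code{\link{default_detection_grid}} at that measure's default FWHM.
#'
#' @param controls list of \code{qm_subject}s, or a directory of subject
#'   subdirectories.
#' @param patients list of \code{list(subject =, ez =)} entries (ez a
#'   \code{\link{ez_hypothesis}}), or a directory of subject
#'   subdirectories each containing an \code{ez.json}.
#' @param measures character subset of CThk, WGJS, T2, MTR, MD.
#' @param params named list of \code{\link{detection_params}} per measure;
#'   \code{NULL} entries (or missing measures) are calibrated.
#' @param target_fp_rate calibration target, fraction of controls flagged.
#' @param cortex_distance_mm parenchyma-filter distance, mm.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic; the seed governs any simulation used to build inputs).
#' @param out optional output directory for the report TSVs and manifest.
#' @return \code{qm_run_config}.
#' @export
run_config <- function(controls, patients, measures = c("T2", "WGJS"),
                       params = default_measure_params(),
                       target_fp_rate = 0.10, cortex_distance_mm = 5,
                       seed = 1L, out = NULL) {
  measures <- match.arg(measures, c("CThk", "WGJS", "T2", "MTR", "MD"),
                        several.ok = TRUE)
  if (!length(measures)) stop("'measures' must be nonempty", call. = FALSE)
  structure(list(controls = controls, patients = patients, measures = measures,
                 params = params, target_fp_rate = target_fp_rate,
                 cortex_distance_mm = cortex_distance_mm, seed = as.integer(seed),
                 out = out),
            class = "qm_run_config")
}

#' Read a run configuration from YAML
#'
#' Maps a YAML document with keys \code{controls}, \code{patients} (paths),
#' \code{measures}, \code{params} (per measure: fwhm, p_mode, p, k),
#' \code{target_fp_rate}, \code{cortex_distance_mm}, \code{seed},
#' \code{out} onto \code{\link{run_config}}.
#'
#' @param file YAML path.
#' @return \code{qm_run_config}.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  prm <- default_measure_params()
  for (nm in names(y$params)) {
    p <- y$params[[nm]]
    prm[[nm]] <- detection_params(p$fwhm, p$p_mode, p$p, p$k)
  }
  run_config(controls = y$controls, patients = y$patients,
             measures = unlist(y$measures),
             params = prm,
             target_fp_rate = y$target_fp_rate %||% 0.10,
             cortex_distance_mm = y$cortex_distance_mm %||% 5,
             seed = y$seed %||% 1L, out = y$out)
}

load_controls <- function(controls) {
  if (is.character(controls)) {
    dirs <- sort(list.dirs(controls, recursive = FALSE))
    lapply(dirs, read_subject)
  } else controls
}

load_patients <- function(patients) {
  if (is.character(patients)) {
    dirs <- sort(list.dirs(patients, recursive = FALSE))
    lapply(dirs, function(dd)
      list(subject = read_subject(dd), ez = read_ez(file.path(dd, "ez.json"))))
  } else patients
}

#' Run the full multimodal detection pipeline over a cohort
#'
#' For every requested measure: computes the measure map for each control
#' and patient, smooths, builds (or calibrates) the detection parameters,
#' compares every patient to the control cohort voxelwise, filters
#' non-parenchymal clusters and scores concordance against each patient's
#' EZ hypothesis. A per-subject stage failure is recorded as a
#' postprocessing failure without aborting the cohort; failed subjects are
#' excluded from the denominator of that measure's percentages. The run is
#' deterministic given the configuration.
#'
#' @param config \code{\link{run_config}}.
#' @return \code{qm_report}: per-subject-by-measure calls, a cohort summary
#'   table, calibration results and the run manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qm_run_config"))
  controls <- load_controls(config$controls)
  patients <- load_patients(config$patients)
  if (length(controls) < 3L) stop("invalid config: need >= 3 controls", call. = FALSE)
  ref <- controls[[1L]]
  atlas <- ref$atlas
  gm_mask <- ref$tpm$gm > 0.5
  vs <- ref$voxel_size_mm

  results <- list()
  detail <- list()
  calibrations <- list()
  used_params <- list()
  for (meas in config$measures) {
    ctrl_maps <- lapply(controls, function(s)
      tryCatch(measure_map(s, meas), error = function(e) NULL))
    keep <- !vapply(ctrl_maps, is.null, logical(1L))
    if (sum(keep) < 3L) stop(sprintf("measure %s: fewer than 3 usable controls", meas), call. = FALSE)
    ctrl_maps <- ctrl_maps[keep]
    test_mask <- Reduce(`&`, lapply(ctrl_maps, `[[`, "mask"))
    cohort <- control_cohort(lapply(ctrl_maps, `[[`, "map"), modality = meas)

    prm <- config$params[[meas]]
    if (is.null(prm)) {
      fwhm <- default_measure_params()[[meas]]$smoothing_fwhm_mm
      cal <- calibrate_fp(cohort, config$target_fp_rate,
                          default_detection_grid(fwhm), atlas, gm_mask,
                          test_mask, vs, config$cortex_distance_mm)
      calibrations[[meas]] <- cal
      prm <- cal$chosen_params
    }
    used_params[[meas]] <- prm

    sm_maps <- lapply(cohort$maps, smooth_map, fwhm_mm = prm$smoothing_fwhm_mm,
                      voxel_size_mm = vs, mask = test_mask)
    sm_cohort <- control_cohort(sm_maps, meas)

    results[[meas]] <- lapply(patients, function(pat) {
      tryCatch({
        mm <- measure_map(pat$subject, meas)
        sm <- smooth_map(mm$map, prm$smoothing_fwhm_mm, vs, test_mask)
        z <- zscore_map(sm, sm_cohort)
        cl <- threshold_map(z, prm, test_mask & mm$mask)
        cl <- parenchyma_filter(cl, atlas, gm_mask, config$cortex_distance_mm, vs)
        cl$clusters <- lapply(cl$clusters, function(c1) {
          reg <- assign_cluster_region(c1, atlas)
          c1$lobe <- reg[["lobe"]]; c1$side <- reg[["side"]]
          c1
        })
        list(clusters = cl, concordance = score_concordance(cl, pat$ez, atlas))
      }, error = function(e) structure("failure", message = conditionMessage(e)))
    })
    detail[[meas]] <- results[[meas]]
    results[[meas]] <- lapply(results[[meas]], function(r)
      if (is.character(r)) "failure" else r$concordance)
  }

  rows <- list()
  for (meas in config$measures)
    for (si in seq_along(patients)) {
      r <- results[[meas]][[si]]
      failed <- is.character(r)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = patients[[si]]$subject$subject_id, measure = meas,
        status = if (failed) "failure" else r$subject_call,
        n_clusters = if (failed) NA_integer_ else length(r$per_cluster),
        n_concordant = if (failed) NA_integer_ else unname(r$counts["concordant"]),
        stringsAsFactors = FALSE)
    }
  per_subject <- do.call(rbind, rows)

  ## overall row: a subject is positive when any measure found clusters
  overall <- vapply(seq_along(patients), function(si) {
    st <- per_subject$status[per_subject$subject == patients[[si]]$subject$subject_id]
    nc <- per_subject$n_clusters[per_subject$subject == patients[[si]]$subject$subject_id]
    if (any(st == "concordant")) "concordant"
    else if (any(st == "discordant_only") ||
             any(st == "NA_NSLF" & !is.na(nc) & nc > 0)) "discordant_only"
    else if (all(st == "failure")) "failure"
    else if (any(st == "NA_NSLF")) "NA_NSLF"
    else "no_findings"
  }, "")
  overall_df <- data.frame(subject = vapply(patients, function(p) p$subject$subject_id, ""),
                           overall = overall, stringsAsFactors = FALSE)

  summary_tab <- tabulate_concordance(results)
  manifest <- list(package_version = as.character(utils::packageVersion("qmlm")),
                   seed = config$seed, measures = config$measures,
                   target_fp_rate = config$target_fp_rate,
                   cortex_distance_mm = config$cortex_distance_mm,
                   n_controls = length(controls), n_patients = length(patients),
                   params = lapply(used_params, function(p)
                     list(fwhm_mm = p$smoothing_fwhm_mm, p_mode = p$p_mode,
                          p_value = p$p_value, cluster_k = p$cluster_k,
                          two_sided = p$two_sided, connectivity = p$connectivity)))

  report <- structure(list(per_subject = per_subject, overall = overall_df,
                           summary = summary_tab, calibrations = calibrations,
                           params = used_params, detail = detail,
                           manifest = manifest),
                      class = "qm_report")
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' Write a cohort report to disk
#'
#' TSV tables (per-subject-by-measure, overall, summary) and a JSON run
#' manifest, all byte-deterministic for a given configuration.
#'
#' @param report \code{qm_report}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wt(report$per_subject, "report_per_subject.tsv")
  wt(report$overall, "report_overall.tsv")
  wt(report$summary, "report_summary.tsv")
  jsonlite::write_json(report$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.qm_report <- function(x, ...) {
  cat("<qm_report> ", x$manifest$n_patients, " patient(s), ",
      x$manifest$n_controls, " control(s)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.qm_report <- function(object, ...) object$summary
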