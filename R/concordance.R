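## Lobe-level agreement between detected clusters and the electroclinical
## epileptogenic-zone (EZ) hypothesis from video-EEG.

#' Electroclinical EZ hypothesis
#'
#' Either \code{SLF} (suspected location for the focus) with a nonempty set
#' of (lobe, side) regions, or \code{NSLF} (no suspected location). A region
#' side of \code{"unlateralized"} matches either hemisphere; a regional
#' descriptor spanning lobes (e.g. temporo-occipital) is expressed as
#' several (lobe, side) pairs.
#'
#' @param status \code{"SLF"} or \code{"NSLF"}.
#' @param regions for SLF, a list of \code{c(lobe, side)} pairs.
#' @return \code{qm_ez}.
#' @export
ez_hypothesis <- function(status = c("SLF", "NSLF"), regions = list()) {
  status <- match.arg(status)
  if (status == "SLF" && length(regions) == 0L)
    stop("an SLF hypothesis needs at least one (lobe, side) region", call. = FALSE)
  if (status == "NSLF" && length(regions) > 0L)
    stop("an NSLF hypothesis has no regions", call. = FALSE)
  regions <- lapply(regions, function(r) {
    r <- as.character(r)
    if (length(r) != 2L) stop("each region must be c(lobe, side)", call. = FALSE)
    r
  })
  structure(list(status = status, regions = regions), class = "qm_ez")
}

#' Assign a cluster to an anatomical lobe and side
#'
#' The cluster takes the (lobe, side) of its peak voxel; if the peak falls
#' on excluded tissue (lobe \code{"none"}), the majority label over the
#' cluster's voxels decides instead.
#'
#' @param cluster one element of a \code{qm_clusters} object.
#' @param atlas list with \code{labels} and \code{table}.
#' @return named character vector \code{c(lobe, side)}.
#' @export
assign_cluster_region <- function(cluster, atlas) {
  check_atlas(atlas)
  tab <- atlas$table
  lab <- atlas$labels[cluster$peak_index]
  row <- match(lab, tab$label)
  if (is.na(row)) stop(sprintf("atlas table is missing label %d", lab), call. = FALSE)
  if (tab$lobe[row] == "none") {
    labs <- atlas$labels[cluster$voxels]
    labs <- labs[labs %in% tab$label[tab$lobe != "none"]]
    if (!length(labs)) stop("cluster has no labeled parenchymal voxels", call. = FALSE)
    cnt <- table(labs)
    lab <- as.integer(names(cnt)[which.max(cnt)])
    row <- match(lab, tab$label)
  }
  c(lobe = tab$lobe[row], side = tab$side[row])
}

#' Score cluster-EZ concordance for one subject
#'
#' For an SLF hypothesis, a cluster is concordant when its (lobe, side)
#' matches any hypothesized region; an unlateralized region matches either
#' side. The subject-level call is \code{concordant} if at least one cluster
#' is concordant, \code{discordant_only} if clusters exist but none match,
#' \code{no_findings} without clusters, and \code{NA_NSLF} when no focus
#' location was hypothesized (no concordance is defined).
#'
#' @param clusters \code{qm_clusters} (after parenchyma filtering).
#' @param ez \code{\link{ez_hypothesis}}.
#' @param atlas list with \code{labels} and \code{table}.
#' @return \code{qm_concordance}: per-cluster verdicts, the subject call,
#'   and category counts.
#' @export
score_concordance <- function(clusters, ez, atlas) {
  stopifnot(inherits(clusters, "qm_clusters"), inherits(ez, "qm_ez"))
  per <- lapply(seq_along(clusters$clusters), function(i) {
    reg <- assign_cluster_region(clusters$clusters[[i]], atlas)
    verdict <- if (ez$status == "NSLF") NA else {
      any(vapply(ez$regions, function(r) {
        r[1L] == reg[["lobe"]] && (r[2L] == "unlateralized" || r[2L] == reg[["side"]])
      }, logical(1L)))
    }
    list(cluster = i, lobe = reg[["lobe"]], side = reg[["side"]], concordant = verdict)
  })
  conc <- vapply(per, function(x) isTRUE(x$concordant), logical(1L))
  subject_call <- if (ez$status == "NSLF") "NA_NSLF"
  else if (!length(per)) "no_findings"
  else if (any(conc)) "concordant"
  else "discordant_only"
  counts <- c(concordant = sum(conc),
              discordant = sum(vapply(per, function(x) isFALSE(x$concordant), logical(1L))),
              not_applicable = sum(vapply(per, function(x) is.na(x$concordant), logical(1L))))
  structure(list(per_cluster = per, subject_call = subject_call, counts = counts,
                 ez = ez), class = "qm_concordance")
}

#' @export
print.qm_concordance <- function(x, ...) {
  cat("<qm_concordance> subject call: ", x$subject_call, "\n", sep = "")
  for (p in x$per_cluster)
    cat(sprintf("  cluster %d: %s %s -> %s\n", p$cluster, p$side, p$lobe,
                if (is.na(p$concordant)) "NA" else if (p$concordant) "concordant" else "discordant"))
  invisible(x)
}

## Cohort tabulation: one row per measure, columns in the style of a
## findings table (positives / with-data, concordant, discordant-only,
## failures). `results` is a list: results[[measure]][[subject]] is either a
## qm_concordance or the string "failure".
tabulate_concordance <- function(results) {
  rows <- lapply(names(results), function(meas) {
    rs <- results[[meas]]
    failed <- vapply(rs, is.character, logical(1L))
    calls <- vapply(rs[!failed], function(r) r$subject_call, "")
    has_cl <- vapply(rs[!failed], function(r) length(r$per_cluster) > 0L, logical(1L))
    n_avail <- sum(!failed)
    pos <- sum(calls %in% c("concordant", "discordant_only") |
                 (calls == "NA_NSLF" & has_cl))
    data.frame(measure = meas,
               n_available = n_avail,
               n_failed = sum(failed),
               any_region_positive = pos,
               concordant = sum(calls == "concordant"),
               discordant_only = sum(calls == "discordant_only"),
               no_findings = sum(calls == "no_findings"),
               nslf = sum(calls == "NA_NSLF"),
               pct_positive = if (n_avail) 100 * pos / n_avail else NA_real_,
               pct_concordant = if (n_avail) 100 * sum(calls == "concordant") / n_avail else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
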