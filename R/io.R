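## File-format I/O: subjects as NIfTI-1 volumes with a JSON sidecar, the
## atlas as a NIfTI label volume plus a TSV label table, EZ hypotheses and
## cluster sets as JSON.

nifti_write <- function(arr, file, voxel_size_mm) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- rep(voxel_size_mm, min(nd, 3L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write a subject to a directory of NIfTI files
#'
#' One NIfTI per channel, the atlas as a label volume plus a TSV table
#' (columns label, lobe, side), and a JSON sidecar carrying the echo-time
#' list, voxel size and subject id. Latent generator state is not written;
#' a written-then-read subject carries observed channels only.
#'
#' @param subject \code{qm_subject}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- subject$voxel_size_mm
  w <- function(x, name) nifti_write(x, file.path(dir, paste0(name, ".nii.gz")), vs)
  w(subject$echo_series, "echo")
  w(subject$mt_on, "mt_on"); w(subject$mt_off, "mt_off")
  w(subject$md_map, "md"); w(subject$thickness_map, "thickness")
  w(subject$t1w, "t1w")
  w(subject$tpm$gm, "tpm_gm"); w(subject$tpm$wm, "tpm_wm"); w(subject$tpm$csf, "tpm_csf")
  w(array(as.numeric(subject$brain_mask), subject$grid_shape), "brain_mask")
  w(array(as.numeric(subject$atlas$labels), subject$grid_shape), "atlas")
  utils::write.table(subject$atlas$table, file.path(dir, "atlas_labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(te_ms = subject$te_ms, voxel_size_mm = vs,
                            subject_id = subject$subject_id),
                       file.path(dir, "sidecar.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject from a directory written by \code{\link{write_subject}}
#'
#' @param dir subject directory.
#' @return \code{qm_subject} carrying observed channels (no generator state).
#' @export
read_subject <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) stop(sprintf("missing volume '%s' in %s", name, dir), call. = FALSE)
    x <- RNifti::readNifti(f)
    array(as.numeric(x), dim(x))
  }
  echo <- rd("echo")
  d <- dim(echo)[1:3]
  atlas_tab <- utils::read.table(file.path(dir, "atlas_labels.tsv"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
  structure(list(
    echo_series = echo, te_ms = as.numeric(side$te_ms),
    mt_on = rd("mt_on"), mt_off = rd("mt_off"),
    md_map = rd("md"), thickness_map = rd("thickness"), t1w = rd("t1w"),
    tpm = list(gm = rd("tpm_gm"), wm = rd("tpm_wm"), csf = rd("tpm_csf")),
    brain_mask = rd("brain_mask") != 0,
    atlas = list(labels = array(as.integer(round(rd("atlas"))), d), table = atlas_tab),
    voxel_size_mm = as.numeric(side$voxel_size_mm), grid_shape = d,
    subject_id = as.character(side$subject_id)), class = "qm_subject")
}

#' Read an EZ hypothesis from JSON
#'
#' Expected form: \code{{"status": "SLF", "regions": [["frontal","left"]]}}
#' or \code{{"status": "NSLF"}}.
#'
#' @param file JSON path.
#' @return \code{\link{ez_hypothesis}}.
#' @export
read_ez <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = FALSE)
  regions <- lapply(x$regions, function(r) as.character(unlist(r)))
  ez_hypothesis(x$status, regions)
}

#' Write a cluster set as JSON plus a NIfTI cluster-label volume
#'
#' @param clusters \code{qm_clusters}.
#' @param path output stem; writes \code{<path>.json} and
#'   \code{<path>_labels.nii.gz}.
#' @param voxel_size_mm voxel size for the label volume header.
#' @return invisibly, the JSON path.
#' @export
write_clusters <- function(clusters, path, voxel_size_mm = 1) {
  lab <- array(0L, clusters$grid_shape)
  for (i in seq_along(clusters$clusters)) lab[clusters$clusters[[i]]$voxels] <- i
  nifti_write(array(as.numeric(lab), clusters$grid_shape),
              paste0(path, "_labels.nii.gz"), voxel_size_mm)
  out <- list(params = unclass(clusters$params_used), n_tests = clusters$n_tests,
              clusters = lapply(clusters$clusters, function(cl)
                list(size = cl$size, peak_voxel = cl$peak_voxel,
                     peak_z = cl$peak_z, lobe = cl$lobe, side = cl$side)))
  jsonlite::write_json(out, paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paste0(path, ".json"))
}
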