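#' Write a cine dataset as NIfTI volumes with a JSON sidecar
#'
#' Writes `<prefix>_mag.nii.gz` and `<prefix>_phase.nii.gz` (frames on the
#' 4th axis) and `<prefix>_meta.json` holding the acquisition metadata
#' (VENC, frame times, RR interval, pixel size, slice thickness, vessel
#' seeds, slice kind).
#'
#' @param dataset a [cine_dataset()]
#' @param prefix file path prefix
#' @return (invisibly) the three file paths
#' @export
write_cine_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "cine_dataset"))
  d <- dim(dataset$magnitude)
  to4d <- function(a) array(a, dim = c(d[1], d[2], 1, d[3]))
  pix <- c(dataset$pixel_mm, dataset$slice_thickness_mm)
  mag_f <- paste0(prefix, "_mag.nii.gz")
  ph_f <- paste0(prefix, "_phase.nii.gz")
  meta_f <- paste0(prefix, "_meta.json")
  RNifti::writeNifti(RNifti::asNifti(to4d(dataset$magnitude),
                                     pixdim = pix), mag_f)
  RNifti::writeNifti(RNifti::asNifti(to4d(dataset$phase),
                                     pixdim = pix), ph_f)
  jsonlite::write_json(
    list(slice_kind = dataset$slice_kind,
         venc_cm_s = dataset$venc_cm_s,
         frame_times_ms = dataset$frame_times_ms,
         rr_ms = dataset$rr_ms,
         pixel_mm = dataset$pixel_mm,
         slice_thickness_mm = dataset$slice_thickness_mm,
         vessel_seeds = dataset$vessel_seeds),
    meta_f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(mag_f, ph_f, meta_f))
}

#' Read a cine dataset written by [write_cine_dataset()]
#'
#' Any dataset following the same sidecar convention can be read.
#'
#' @param prefix file path prefix used at write time
#' @return a [cine_dataset()]
#' @export
read_cine_dataset <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  drop3 <- function(a) {
    a <- as.array(a)
    array(a, dim = dim(a)[c(1, 2, 4)])
  }
  mag <- drop3(RNifti::readNifti(paste0(prefix, "_mag.nii.gz")))
  ph <- drop3(RNifti::readNifti(paste0(prefix, "_phase.nii.gz")))
  seeds <- lapply(meta$vessel_seeds, as.numeric)
  cine_dataset(meta$slice_kind, mag, ph, meta$venc_cm_s,
               meta$frame_times_ms, meta$rr_ms, meta$pixel_mm,
               meta$slice_thickness_mm, seeds)
}
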