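#' Read CEST inputs from NIfTI + YAML sidecar
#'
#' @param cest_path 4D CEST stack (.nii/.nii.gz), one volume per offset.
#' @param s0_path 3D unsaturated reference volume.
#' @param mask_path 3D brain mask.
#' @param config_path YAML sidecar with `offsets_ppm` (ascending) and
#'   optionally `s0_offset_ppm` (default -150).
#' @return List with `cest_4d`, `s0`, `mask`, `offsets`, `s0_offset`.
#' @export
read_cest_inputs <- function(cest_path, s0_path, mask_path, config_path) {
  y <- yaml::read_yaml(config_path)
  if (is.null(y$offsets_ppm)) abort("config must list `offsets_ppm`")
  offs <- as.numeric(y$offsets_ppm)
  img <- RNifti::readNifti(cest_path)
  cest <- array(img, dim = dim(img))
  list(
    cest_4d = cest,
    s0 = as.array(RNifti::readNifti(s0_path)),
    mask = as.array(RNifti::readNifti(mask_path)) > 0,
    offsets = offs,
    s0_offset = y$s0_offset_ppm %||% -150
  )
}

#' Write APTw maps as NIfTI
#'
#' Writes `aptw.nii.gz` and `aptw_fs.nii.gz` (percent) and `b0.nii.gz` (ppm)
#' into `dir`, annotating the unit in the NIfTI description field.
#'
#' @param maps An [compute_aptw_maps()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_aptw_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "aptw_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  units <- c(aptw = "percent", aptw_fs = "percent", b0 = "ppm")
  paths <- vapply(names(units), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- RNifti::asNifti(maps[[nm]])
    img$descrip <- unname(units[nm])
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}

#' Write perfusion maps as NIfTI and the AIF as CSV
#'
#' @param maps A [compute_perfusion_maps()] result.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_perfusion_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "perfusion_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  units <- c(cbf = "relative/s", cbv = "relative", ccbv = "relative",
             k2 = "1/min", mtt = "s")
  paths <- vapply(names(units), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- RNifti::asNifti(maps[[nm]])
    img$descrip <- unname(units[nm])
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  aif_path <- file.path(dir, "aif.csv")
  write.csv(data.frame(t = maps$aif$t, c = maps$aif$c), aif_path,
            row.names = FALSE)
  invisible(c(paths, aif = aif_path))
}

#' Write the cohort report tables as CSV
#'
#' @param report A [cohort_report()] result.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(report), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(report[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
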