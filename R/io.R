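#' Read and write BOLD runs, maps and masks (NIfTI-1)
#'
#' Runs are 4D NIfTI volumes with the TR stored in `pixdim[4]`; maps and
#' masks are 3D. A written run reads back with identical values and voxel
#' dimensions.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param tr Repetition time override in seconds; by default taken from the
#'   NIfTI header.
#' @return `read_bold()` returns a [bold_run()].
#' @export
read_bold <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stopf("'%s' is %dD; a BOLD run must be a 4D NIfTI volume", path, length(d))
  tr <- tr %||% RNifti::pixdim(img)[4]
  assert_that(is.finite(tr) && tr > 0,
              "no usable TR in '%s' header; pass tr explicitly", path)
  bold_run(as.array(img), tr)
}

#' @rdname read_bold
#' @param run A [bold_run()].
#' @param voxel_dims Spatial voxel dimensions in mm.
#' @export
write_bold <- function(run, path, voxel_dims = c(1.875, 1.875, 5)) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(voxel_dims, run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_bold
#' @export
read_tissue <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stopf("'%s' must be a 3D tissue label volume", path)
  vals <- as.array(img)
  if (!all(vals %in% 0:2))
    stopf("'%s' contains labels outside {0, 1, 2}", path)
  tissue_volume(vals, RNifti::pixdim(img)[1:3])
}

#' @rdname read_bold
#' @param tissue A [tissue_volume()].
#' @export
write_tissue <- function(tissue, path) {
  stopifnot(inherits(tissue, "tissue_volume"))
  img <- RNifti::asNifti(tissue$labels)
  RNifti::pixdim(img) <- tissue$voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_bold
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stopf("'%s' must be a 3D mask", path)
  vals <- as.array(img)
  if (!all(vals %in% c(0, 1))) stopf("'%s' is not a binary mask", path)
  array(vals == 1, dim(vals))
}

#' @rdname read_bold
#' @param x 3D numeric array or [cvr_map()] (`NA` stored as `NaN`).
#' @export
write_map <- function(x, path, voxel_dims = c(1.875, 1.875, 5)) {
  vals <- if (inherits(x, "cvr_map")) x$values else x
  assert_that(is.numeric(vals) && length(dim(vals)) == 3L, "map must be a 3D array")
  vals[is.na(vals)] <- NaN
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_bold
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stopf("'%s' must be a 3D map", path)
  as.array(img)
}

# Write a phantom subject to NIfTI + JSON sidecar.
write_phantom <- function(subj, dir) {
  stopifnot(inherits(subj, "cvr_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vd <- subj$spec$voxel_dims
  for (i in 1:2) {
    write_bold(subj$bh_runs[[i]], file.path(dir, sprintf("bh_run%d.nii.gz", i)), vd)
    write_bold(subj$rs_runs[[i]], file.path(dir, sprintf("rs_run%d.nii.gz", i)), vd)
  }
  write_tissue(subj$tissue, file.path(dir, "tissue.nii.gz"))
  write_map(subj$truth$cvr_amplitude, file.path(dir, "truth_cvr_amplitude.nii.gz"), vd)
  write_map(subj$truth$alff_amplitude, file.path(dir, "truth_alff_amplitude.nii.gz"), vd)
  write_map(subj$truth$lag_map + 0, file.path(dir, "truth_lag.nii.gz"), vd)
  write_map(subj$truth$responsive_mask + 0, file.path(dir, "truth_responsive.nii.gz"), vd)
  spec <- subj$spec
  spec$lesion <- spec$lesion %||% NULL
  jsonlite::write_json(unclass(spec), file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run manifest
#'
#' Collects the file paths and metadata of one subject's datasets and checks
#' that all referenced volumes exist and share grid dimensions.
#'
#' @param subject Subject identifier.
#' @param bh_paths,rs_paths Character vectors (length 2) of 4D run paths.
#' @param tissue_path Path to the 3D tissue label volume.
#' @param tr Repetition time in seconds.
#' @param seed Integer seed recorded with the manifest.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(subject, bh_paths, rs_paths, tissue_path, tr = 2, seed = 1L) {
  paths <- c(bh_paths, rs_paths, tissue_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("missing files: %s", paste(missing, collapse = ", "))
  grids <- lapply(paths, function(p) dim(RNifti::readNifti(p))[1:3])
  assert_that(all(vapply(grids, identical, TRUE, grids[[1]])),
              "referenced volumes do not share grid dimensions")
  structure(list(subject = subject, bh_paths = bh_paths, rs_paths = rs_paths,
                 tissue_path = tissue_path, tr = tr, seed = as.integer(seed)),
            class = "run_manifest")
}
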