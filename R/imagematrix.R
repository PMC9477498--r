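#' Subjects-by-voxels image matrix
#'
#' The container for one modality's vectorised images: a numeric matrix with
#' one row per subject and one column per in-mask voxel, plus the grid
#' geometry needed to map columns back to 3D space. Grey-matter probability
#' (GMV) and normalised FDG uptake maps share this representation.
#'
#' @param values Numeric matrix, subjects x in-mask voxels.
#' @param grid A [brain_grid()].
#' @param mask Logical vector over all grid voxels; `sum(mask)` must equal
#'   `ncol(values)`. Default: all voxels in-mask.
#' @param modality `"GMV"` or `"FDG"`.
#' @param subject_ids Optional character vector of row identities.
#' @return An object of class `image_matrix`.
#' @export
image_matrix <- function(values, grid, mask = NULL,
                         modality = c("GMV", "FDG"),
                         subject_ids = rownames(values)) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(mask)) mask <- rep(TRUE, grid$n_voxels)
  mask <- as.logical(mask)
  stopifnot(length(mask) == grid$n_voxels)
  if (ncol(values) != sum(mask))
    abort("ncol(values) must equal the number of in-mask voxels")
  if (!is.null(subject_ids)) rownames(values) <- subject_ids
  structure(
    list(values = values, grid = grid, mask = mask, modality = modality),
    class = "image_matrix"
  )
}

#' @export
print.image_matrix <- function(x, ...) {
  cat("<image_matrix> ", x$modality, ": ", nrow(x$values), " subjects x ",
      ncol(x$values), " voxels (grid ",
      paste(x$grid$dims, collapse = "x"), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.image_matrix <- function(x) dim(x$values)

# Embed a per-voxel vector (length = in-mask voxels) into the full grid,
# filling background with `fill`.
embed_map <- function(imat_or_grid, v, mask = NULL, fill = 0) {
  if (inherits(imat_or_grid, "image_matrix")) {
    grid <- imat_or_grid$grid; mask <- imat_or_grid$mask
  } else grid <- imat_or_grid
  if (is.null(mask)) mask <- rep(TRUE, grid$n_voxels)
  full <- rep(fill, grid$n_voxels)
  full[mask] <- v
  array(full, dim = grid$dims)
}

# NIfTI round-trip helpers ---------------------------------------------------

nifti_from_vector <- function(grid, v_full) {
  img <- array(as.numeric(v_full), dim = grid$dims)
  aff <- grid$affine
  RNifti::`sform<-`(RNifti::asNifti(img), structure(aff, code = 2L))
}

#' Write a per-voxel map as NIfTI-1
#'
#' @param v Numeric vector over in-mask voxels (or full grid).
#' @param grid A [brain_grid()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param mask Logical in-brain mask; needed when `v` covers only in-mask
#'   voxels.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(v, grid, path, mask = NULL) {
  if (length(v) != grid$n_voxels) {
    if (is.null(mask)) abort("mask required for masked vectors")
    v <- embed_map(grid, v, mask)
  }
  RNifti::writeNifti(nifti_from_vector(grid, v), path)
  invisible(path)
}

#' Read a directory of per-subject NIfTI images into an image matrix
#'
#' @param paths Character vector of NIfTI files, one per subject, in row
#'   order.
#' @param mask Optional logical mask over grid voxels; default all voxels.
#' @param modality `"GMV"` or `"FDG"`.
#' @param subject_ids Optional subject identifiers.
#' @return An [image_matrix()].
#' @export
read_image_matrix <- function(paths, mask = NULL,
                              modality = c("GMV", "FDG"),
                              subject_ids = NULL) {
  modality <- match.arg(modality)
  first <- RNifti::readNifti(paths[[1]])
  dims <- dim(first)
  stopifnot(length(dims) == 3)
  grid <- brain_grid(dims, affine = RNifti::xform(first))
  if (is.null(mask)) mask <- rep(TRUE, grid$n_voxels)
  vals <- matrix(NA_real_, length(paths), sum(mask))
  vals[1, ] <- as.numeric(first)[mask]
  if (length(paths) > 1) {
    for (i in 2:length(paths))
      vals[i, ] <- as.numeric(RNifti::readNifti(paths[[i]]))[mask]
  }
  image_matrix(vals, grid, mask, modality, subject_ids)
}
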