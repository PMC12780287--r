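#' Short-axis LGE image stack
#'
#' Container for a 3D short-axis late gadolinium enhancement stack: a
#' real-valued intensity array with in-plane spacing, slice thickness and the
#' signal convention. Inversion-recovery (`"IR"`) stacks are magnitude images
#' and must be non-negative; phase-sensitive (`"PSIR"`) stacks preserve the
#' sign of the recovered magnetization and may contain negative values.
#'
#' @param voxels numeric array, `dim = c(rows, cols, slices)` (a matrix is
#'   accepted as a single slice).
#' @param spacing in-plane pixel spacing in mm, length-2 `(row, col)` or a
#'   single value used for both.
#' @param thickness slice thickness in mm.
#' @param convention `"IR"` or `"PSIR"`.
#' @return an object of class `lge_stack`.
#' @export
lge_stack <- function(voxels, spacing = c(1.5, 1.5), thickness = 8,
                      convention = c("IR", "PSIR")) {
  convention <- match.arg(convention)
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) stop("'voxels' must be a 3D array (rows, cols, slices)")
  if (dim(voxels)[3L] < 1L) stop("a stack needs at least one slice")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(spacing <= 0) || thickness <= 0)
    stop("pixel spacing and slice thickness must be strictly positive")
  if (convention == "IR" && any(voxels < 0, na.rm = TRUE))
    stop("IR stacks are magnitude images and cannot contain negative intensities")
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         thickness = as.numeric(thickness), convention = convention),
    class = "lge_stack"
  )
}

#' @export
print.lge_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<lge_stack> %d x %d x %d slices, %.2f x %.2f mm, %.1f mm thick, %s\n",
              d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$thickness,
              x$convention))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.lge_stack <- function(x) dim(x$voxels)

# Volume of one voxel in mL (mm^3 / 1000).
voxel_volume_ml <- function(stack) {
  prod(stack$spacing) * stack$thickness / 1000
}

# mm coordinates of voxel centers; pixel (0,0) center at the origin.
grid_coords <- function(stack) {
  d <- dim(stack$voxels)
  list(x = (seq_len(d[2L]) - 1) * stack$spacing[2L],
       y = (seq_len(d[1L]) - 1) * stack$spacing[1L])
}

# Matrices of x/y center coordinates for one slice.
grid_xy <- function(stack) {
  g <- grid_coords(stack)
  d <- dim(stack$voxels)
  list(x = matrix(g$x, d[1L], d[2L], byrow = TRUE),
       y = matrix(g$y, d[1L], d[2L]))
}

#' Read a stack from a NIfTI-1 file
#'
#' Spacing and slice thickness are taken from the header `pixdim`. The signal
#' convention is not part of NIfTI; by default it is inferred from the sign of
#' the data (any negative voxel implies PSIR).
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param convention `"auto"`, `"IR"` or `"PSIR"`.
#' @return an [lge_stack].
#' @export
read_stack <- function(path, convention = c("auto", "IR", "PSIR")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("stack file not found: ", path)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L) pd <- c(pd, 1)
  if (any(pd[1:3] <= 0)) stop("non-positive voxel spacing in NIfTI header: ", path)
  if (convention == "auto") convention <- if (any(vox < 0)) "PSIR" else "IR"
  lge_stack(vox, spacing = pd[1:2], thickness = pd[3L], convention = convention)
}

#' Write a stack (or any numeric array) to NIfTI-1
#'
#' @param stack an [lge_stack] or a numeric array (then `spacing`/`thickness`
#'   default to 1 mm).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (inherits(stack, "lge_stack")) {
    arr <- stack$voxels
    pd <- c(stack$spacing, stack$thickness)
  } else {
    arr <- stack
    pd <- c(1, 1, 1)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
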