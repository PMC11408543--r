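#' Voxel grid definition
#'
#' A `grid_spec` fixes the sampling lattice shared by all volumes and
#' streamline paths in a study: the number of voxels per axis, the isotropic
#' voxel edge length, and the world-space position of the first voxel.
#' Every lesion mask, parcellation and streamline atlas in an analysis must
#' live on the same grid; operations that combine them check this.
#'
#' @param dims integer vector of length 3, voxels per axis (each >= 8).
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @param origin numeric length 3, world coordinate (mm) of voxel (1,1,1).
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' g <- grid_spec(c(32, 32, 32))
grid_spec <- function(dims, voxel_size_mm = 1, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(is.finite(dims)))
  if (any(dims < 8L))
    stop("all grid dimensions must be >= 8 voxels (got ",
         paste(dims, collapse = "x"), ")")
  stopifnot(is.numeric(voxel_size_mm), length(voxel_size_mm) == 1,
            voxel_size_mm > 0)
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(list(dims = dims, voxel_size_mm = as.numeric(voxel_size_mm),
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s voxels, %.3g mm isotropic\n",
              paste(x$dims, collapse = " x "), x$voxel_size_mm))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Label volume on a voxel grid
#'
#' Wraps a 3D non-negative integer array (brain mask, lesion mask or
#' parcellation) together with its [grid_spec()].
#'
#' @param values 3D array of non-negative integers.
#' @param grid a [grid_spec()] whose `dims` match `dim(values)`.
#' @return An object of class `label_volume` (the array, with a `grid`
#'   attribute).
#' @export
label_volume <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (!identical(dim(values), NULL) && length(dim(values)) != 3)
    stop("values must be a 3D array")
  if (!identical(as.integer(dim(values)), grid$dims))
    stop("array dimensions ", paste(dim(values), collapse = "x"),
         " do not match grid ", paste(grid$dims, collapse = "x"))
  if (any(values < 0)) stop("label values must be >= 0")
  storage.mode(values) <- "integer"
  structure(values, grid = grid, class = c("label_volume", "array"))
}

#' @export
print.label_volume <- function(x, ...) {
  g <- attr(x, "grid")
  nz <- sum(x != 0L)
  cat(sprintf("<label_volume> %s, %d nonzero voxels, %d labels\n",
              paste(g$dims, collapse = " x "), nz,
              length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

vol_grid <- function(x) attr(x, "grid")

is_binary_volume <- function(x) all(x == 0L | x == 1L)

# linear (1-based) index of voxel rows [i j k] on a grid
voxel_linear_index <- function(vox, dims) {
  if (is.null(dim(vox))) vox <- matrix(vox, ncol = 3)
  1L + (vox[, 1L] - 1L) + dims[1L] * ((vox[, 2L] - 1L) +
                                        dims[2L] * (vox[, 3L] - 1L))
}

#' Read / write a label volume as NIfTI
#'
#' Volumes are stored with the grid's voxel size on the NIfTI `pixdim` so a
#' round trip preserves the grid. Voxel values are written as integers.
#'
#' @param x a [label_volume()].
#' @param path output file; `.nii` or `.nii.gz`.
#' @return `write_nifti_volume` returns `path` invisibly;
#'   `read_nifti_volume` returns a [label_volume()].
#' @export
write_nifti_volume <- function(x, path) {
  stopifnot(inherits(x, "label_volume"))
  g <- vol_grid(x)
  arr <- array(as.integer(x), dim = g$dims)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(g$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @param grid optional [grid_spec()] to validate against; inferred from the
#'   header when omitted.
#' @export
read_nifti_volume <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.array(img))), dim = dim(img)[1:3])
  vs <- RNifti::pixdim(img)[1]
  if (is.null(grid)) grid <- grid_spec(dim(arr), voxel_size_mm = vs)
  else if (!identical(as.integer(dim(arr)), grid$dims))
    stop("volume in ", path, " (", paste(dim(arr), collapse = "x"),
         ") does not match expected grid (",
         paste(grid$dims, collapse = "x"), ")")
  label_volume(arr, grid)
}

# 6-neighbourhood offsets as a 6 x 3 integer matrix
.offsets6 <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                   c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))

# neighbours of a voxel matrix (n x 3) under 6-connectivity, clipped to grid
.neighbors6 <- function(vox, dims) {
  n <- nrow(vox)
  out <- vox[rep(seq_len(n), each = 6L), , drop = FALSE] +
    .offsets6[rep(1:6, times = n), , drop = FALSE]
  keep <- out[, 1] >= 1L & out[, 1] <= dims[1] &
    out[, 2] >= 1L & out[, 2] <= dims[2] &
    out[, 3] >= 1L & out[, 3] <= dims[3]
  out[keep, , drop = FALSE]
}
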