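#' 3D volume with a voxel-to-world affine
#'
#' A `volume_grid` couples a 3D numeric array with a 4x4 affine mapping
#' 0-based voxel indices to world coordinates in millimetres (the NIfTI
#' convention). All geometric operations in the package work in world mm.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix, voxel-index -> world-mm; must be
#'   invertible.
#' @return An object of class `volume_grid` with fields `data`, `affine`,
#'   `shape`.
#' @export
volume_grid <- function(data, affine = diag(4)) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd != 3L)
    stop("volume must be 3-D; got a ", nd, "-dimensional array", call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (!all(is.finite(affine)))
    stop("affine contains non-finite entries", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine is singular (zero voxel volume)", call. = FALSE)
  structure(list(data = data, affine = affine, shape = dim(data)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, voxel volume %.4g mm^3\n",
              class(x)[1L], paste(x$shape, collapse = "x"), voxel_volume(x)))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#'
#' @param grid a `volume_grid`.
#' @return |det| of the affine's 3x3 linear part, in mm^3.
#' @export
voxel_volume <- function(grid) {
  abs(det(grid$affine[1:3, 1:3]))
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [volume_grid()] with the file's data and voxel-to-world affine.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("volume file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L)
    stop("expected a 3-D volume, but '", basename(path), "' is ",
         length(d), "-dimensional", call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  # singleton trailing dimensions are dropped by the NIfTI store; restore them
  dat <- array(as.array(img), c(d, rep(1L, 3L - length(d))))
  volume_grid(dat, aff)
}

#' Write a volume as NIfTI-1
#'
#' The affine is stored as the sform (code 2) so that it round-trips exactly.
#'
#' @param grid a `volume_grid`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(grid$data)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Map world-mm points to nearest voxel indices
#'
#' Applies the inverse affine, then rounds each coordinate half-up
#' (`floor(x + 0.5)`): a point belongs to the voxel whose center is closest.
#' Indices are 0-based and may fall outside the grid; callers decide how to
#' treat out-of-bounds indices.
#'
#' @param points numeric length-3 vector or n x 3 matrix of world-mm points.
#' @param grid a `volume_grid`.
#' @return integer voxel indices, same shape as `points`.
#' @export
world_to_voxel <- function(points, grid) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  inv <- solve(grid$affine)
  ijk <- cbind(p, 1) %*% t(inv)
  idx <- floor(ijk[, 1:3, drop = FALSE] + 0.5)
  storage.mode(idx) <- "integer"
  if (is.matrix(points)) idx else idx[1L, ]
}

#' Map 0-based voxel indices to world-mm coordinates of voxel centers
#'
#' @param idx length-3 vector or n x 3 matrix of 0-based voxel indices.
#' @param grid a `volume_grid`.
#' @return world coordinates (mm), same shape as `idx`.
#' @export
voxel_to_world <- function(idx, grid) {
  m <- if (is.matrix(idx)) idx else matrix(idx, ncol = 3L)
  w <- cbind(m, 1) %*% t(grid$affine)
  w <- w[, 1:3, drop = FALSE]
  if (is.matrix(idx)) w else w[1L, ]
}

#' Binary mask on a voxel grid
#'
#' Numeric input is binarized at `> threshold` (default 0.5), which tolerates
#' interpolation artefacts introduced when masks are resampled between
#' spaces.
#'
#' @param x a `volume_grid` or a 3D array.
#' @param affine affine, used when `x` is a bare array.
#' @param threshold binarization cut; voxels strictly above become 1.
#' @return a `binary_mask` (also a `volume_grid`) with data in \{0, 1\}.
#' @export
binary_mask <- function(x, affine = diag(4), threshold = 0.5) {
  g <- if (inherits(x, "volume_grid")) x else volume_grid(x, affine)
  d <- array(as.numeric(g$data > threshold), dim = g$shape)
  structure(list(data = d, affine = g$affine, shape = g$shape),
            class = c("binary_mask", "volume_grid"))
}

#' Read a NIfTI file as a binary mask
#'
#' @inheritParams read_volume
#' @param threshold binarization cut applied on load.
#' @export
read_mask <- function(path, threshold = 0.5) {
  binary_mask(read_volume(path), threshold = threshold)
}

#' Morphological dilation by a physical radius
#'
#' A voxel in the output is set iff the center of some originally-set voxel
#' lies within Euclidean distance `radius` (world mm) of its center. With
#' `radius = 0` the mask is returned unchanged. Anisotropic voxels are
#' honoured: distances are measured in mm, not voxel units.
#'
#' @param mask a `binary_mask`.
#' @param radius dilation radius in mm, >= 0.
#' @return the dilated `binary_mask`.
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("dilation radius must be a single non-negative number (mm)",
         call. = FALSE)
  if (radius == 0) return(mask)
  A <- mask$affine[1:3, 1:3]
  Ainv <- solve(A)
  # per-axis bound on integer offsets: |d_i| <= ||row_i(A^-1)|| * radius
  bnd <- ceiling(radius * sqrt(rowSums(Ainv^2)) + 1e-9)
  off <- as.matrix(expand.grid(-bnd[1]:bnd[1], -bnd[2]:bnd[2], -bnd[3]:bnd[3]))
  dist <- sqrt(colSums((A %*% t(off))^2))
  off <- off[dist <= radius + 1e-9, , drop = FALSE]

  set <- which(mask$data == 1, arr.ind = TRUE)
  if (nrow(set) == 0L) return(mask)
  out <- array(0, dim = mask$shape)
  sh <- mask$shape
  for (k in seq_len(nrow(off))) {
    s <- set + matrix(off[k, ], nrow(set), 3L, byrow = TRUE)
    ok <- s[, 1] >= 1 & s[, 1] <= sh[1] &
          s[, 2] >= 1 & s[, 2] <= sh[2] &
          s[, 3] >= 1 & s[, 3] <= sh[3]
    if (any(ok)) out[s[ok, , drop = FALSE]] <- 1
  }
  binary_mask(out, mask$affine, threshold = 0.5)
}

# grids must share shape and affine before voxelwise combination
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(a$shape, b$shape))
    stop(what, " are on different grids: shapes ",
         paste(a$shape, collapse = "x"), " vs ",
         paste(b$shape, collapse = "x"), call. = FALSE)
  if (max(abs(a$affine - b$affine)) > 1e-6)
    stop(what, " are on different grids: affines differ", call. = FALSE)
  invisible(TRUE)
}
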