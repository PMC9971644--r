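#' A 3D scalar field with voxel dimensions
#'
#' The basic container passed between all processing stages: a 3D numeric
#' array plus voxel dimensions in mm. All multi-volume operations require
#' their inputs to share one grid (shape and voxel dimensions); volumes are
#' assumed co-registered, since spatial registration is outside the scope of
#' this package.
#'
#' @param data A 3D numeric array.
#' @param voxel_dims Numeric length-3 vector `(dx, dy, dz)` in mm, all
#'   strictly positive.
#' @return An object of class `volume_grid` with elements `data` and
#'   `voxel_dims`.
#' @export
#' @examples
#' v <- volume_grid(array(0, dim = c(4, 4, 4)), c(1, 1, 1))
#' grid_shape(v)
volume_grid <- function(data, voxel_dims = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("'voxel_dims' must be three strictly positive values (mm)")
  structure(list(data = data, voxel_dims = voxel_dims),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @param x An object.
#' @export
is_volume_grid <- function(x) inherits(x, "volume_grid")

#' @rdname volume_grid
#' @param v A `volume_grid`.
#' @export
grid_shape <- function(v) dim(v$data)

#' @rdname volume_grid
#' @export
voxel_volume <- function(v) prod(v$voxel_dims)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels at %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_dims, 4), collapse = "x")))
  rng <- suppressWarnings(range(x$data, na.rm = TRUE))
  cat(sprintf("  range [%g, %g], %d NA/NaN\n", rng[1], rng[2],
              sum(!is.finite(x$data) & !is.infinite(x$data))))
  invisible(x)
}

# Internal: abort unless all volumes share one grid.
assert_same_grid <- function(..., .what = "volumes") {
  vols <- list(...)
  ref <- vols[[1L]]
  for (v in vols[-1L]) {
    if (!identical(dim(v$data), dim(ref$data)))
      stop(sprintf("grid mismatch: %s differ in shape (%s vs %s)", .what,
                   paste(dim(ref$data), collapse = "x"),
                   paste(dim(v$data), collapse = "x")))
    if (max(abs(v$voxel_dims - ref$voxel_dims)) > 1e-6)
      stop(sprintf("grid mismatch: %s differ in voxel dimensions", .what))
  }
  invisible(TRUE)
}

# Internal: build a volume on the same grid as `like`.
like_volume <- function(data, like) {
  if (is.null(dim(data))) dim(data) <- dim(like$data)
  volume_grid(data, like$voxel_dims)
}

#' Read a NIfTI-1 volume
#'
#' Reads a NIfTI-1 file into a [volume_grid()] (or a list of them for a 4D
#' series). Voxel dimensions are taken from the header. A 4D file read
#' without `series = TRUE` is an error, so that a stage expecting a single
#' volume fails loudly rather than silently taking the first frame.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param series If `TRUE`, a 4D file is returned as a list of 3D
#'   `volume_grid`s (one per frame); a 3D file yields a list of length 1.
#' @return A `volume_grid`, or a list of them when `series = TRUE`.
#' @export
read_volume <- function(path, series = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  if (length(d) < 3L) {
    d <- c(d, rep(1L, 3L - length(d)))
    dim(img) <- d
  }
  if (any(pd[1:3] <= 0)) stop("non-positive voxel dimensions in header: ", path)
  vd <- as.numeric(pd[1:3])
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop RNifti header attributes
  if (length(d) == 3L) {
    v <- volume_grid(arr, vd)
    return(if (series) list(v) else v)
  }
  if (length(d) == 4L) {
    if (!series)
      stop("4D input (", d[4], " frames): ", path,
           "; pass series = TRUE to read a volume series")
    return(lapply(seq_len(d[4]), function(i)
      volume_grid(arr[, , , i, drop = TRUE], vd)))
  }
  stop("unsupported NIfTI dimensionality (", length(d), "D): ", path)
}

#' Write a NIfTI-1 volume
#'
#' Writes a [volume_grid()] (or a list of them, as a 4D series) to NIfTI-1.
#' Values are stored as 32-bit float by default; use `datatype = "double"`
#' where bit-exact round trips are needed.
#'
#' @param v A `volume_grid` or a list of same-grid `volume_grid`s.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype Storage type passed to [RNifti::writeNifti()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "double") {
  if (is_volume_grid(v)) {
    arr <- v$data
    vd <- v$voxel_dims
  } else if (is.list(v) && length(v) > 0 && all(vapply(v, is_volume_grid, TRUE))) {
    do.call(assert_same_grid, c(v, list(.what = "series volumes")))
    arr <- array(unlist(lapply(v, `[[`, "data"), use.names = FALSE),
                 dim = c(dim(v[[1L]]$data), length(v)))
    vd <- v[[1L]]$voxel_dims
  } else {
    stop("'v' must be a volume_grid or a non-empty list of volume_grids")
  }
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vd, if (length(dim(arr)) == 4L) 1)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
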