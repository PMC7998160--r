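#' Volume geometry
#'
#' Describes the sampling grid of a 3D image volume: voxel spacing in mm,
#' grid dimensions in voxels, and the origin offset in mm. The package-wide
#' axis convention is axial slices with x/y in-plane and z increasing
#' caudally (slice index grows head-to-foot); voxel indices are 1-based in R.
#'
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm; all
#'   strictly positive.
#' @param dim Integer length-3, grid size `(nx, ny, nz)` in voxels; all
#'   strictly positive.
#' @param origin Numeric length-3, mm offset of the first voxel centre.
#' @return An object of class `vol_geometry`.
#' @examples
#' vol_geometry(c(1.6, 1.6, 5.0), c(64, 64, 50))
#' @export
vol_geometry <- function(spacing, dim, origin = c(0, 0, 0)) {
  spacing <- as.numeric(spacing)
  dim <- as.integer(dim)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(dim) == 3, length(origin) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacings must be finite and > 0", call. = FALSE)
  }
  if (any(is.na(dim)) || any(dim <= 0L)) {
    stop("grid dimensions must be > 0", call. = FALSE)
  }
  structure(
    list(spacing = spacing, dim = dim, origin = origin, axes = "LPS-axial-z-caudal"),
    class = "vol_geometry"
  )
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat(sprintf(
    "<vol_geometry> %d x %d x %d voxels, %.4g x %.4g x %.4g mm, origin (%g, %g, %g)\n",
    x$dim[1], x$dim[2], x$dim[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' Voxel volume of a geometry
#'
#' @param geometry A [vol_geometry()].
#' @return Voxel volume dx*dy*dz in mm^3.
#' @export
voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "vol_geometry"))
  prod(geometry$spacing)
}

# Geometry equality to within float representation of the spacings/origin.
geom_equal <- function(a, b, tol = 1e-6) {
  inherits(a, "vol_geometry") && inherits(b, "vol_geometry") &&
    all(a$dim == b$dim) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin), abs(b$origin)))
}

# In-plane (x/y) compatibility for station stacking.
geom_inplane_equal <- function(a, b, tol = 1e-6) {
  all(a$dim[1:2] == b$dim[1:2]) &&
    all(abs(a$spacing[1:2] - b$spacing[1:2]) <= tol) &&
    abs(a$spacing[3] - b$spacing[3]) <= tol
}

stop_geometry_conflict <- function(what = "volumes") {
  stop(sprintf("geometry conflict: %s do not share one geometry", what),
       call. = FALSE)
}

check_array3 <- function(x, geometry, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3) {
    stop(sprintf("%s must be a 3D array", what), call. = FALSE)
  }
  if (!all(dim(x) == geometry$dim)) stop_geometry_conflict(what)
  invisible(x)
}

#' Binary 3D mask
#'
#' A binary segmentation aligned to a study volume's grid. Voxels are stored
#' as a logical array; geometry must match the volume the mask annotates.
#'
#' @param voxels Logical (or coercible) 3D array.
#' @param geometry A [vol_geometry()] matching `dim(voxels)`.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(voxels, geometry) {
  stopifnot(inherits(geometry, "vol_geometry"))
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop("mask voxels must be a 3D array", call. = FALSE)
  }
  storage <- array(as.logical(voxels), dim = dim(voxels))
  if (anyNA(storage)) stop("mask contains NA voxels", call. = FALSE)
  check_array3(storage, geometry, "mask")
  structure(list(voxels = storage, geometry = geometry), class = "mask3d")
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d> %d/%d voxels set (%.4g ml)\n",
              mask_count(x), prod(x$geometry$dim),
              mask_count(x) * voxel_volume(x$geometry) / 1000))
  invisible(x)
}

#' Number of set voxels in a mask
#' @param mask A [mask3d()].
#' @return Integer count of TRUE voxels.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "mask3d"))
  sum(mask$voxels)
}
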