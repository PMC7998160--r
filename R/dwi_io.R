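#' DWI station
#'
#' One acquisition station of a whole-body DWI examination: a set of 3D
#' signal volumes indexed by b-value, sharing a single geometry.
#'
#' @param signals Named list of 3D arrays; names are b-values in s/mm^2.
#' @param geometry A [vol_geometry()] shared by all b-value volumes.
#' @param station_index Ordinal station position, cranial to caudal (1 = most
#'   cranial).
#' @return An object of class `dwi_station`.
#' @export
dwi_station <- function(signals, geometry, station_index = 1L) {
  stopifnot(is.list(signals), inherits(geometry, "vol_geometry"))
  b <- suppressWarnings(as.numeric(names(signals)))
  if (length(signals) < 2 || anyNA(b) || anyDuplicated(b) > 0 || any(b < 0)) {
    stop("a station needs >= 2 distinct non-negative b-values", call. = FALSE)
  }
  for (nm in names(signals)) {
    check_array3(signals[[nm]], geometry, sprintf("b=%s volume", nm))
    if (any(signals[[nm]] < 0, na.rm = TRUE)) {
      stop("signal intensities must be non-negative", call. = FALSE)
    }
  }
  signals <- signals[order(b)]
  structure(
    list(signals = signals, geometry = geometry,
         station_index = as.integer(station_index)),
    class = "dwi_station"
  )
}

#' Multi-station DWI study
#'
#' An ordered collection of [dwi_station()]s, cranial to caudal. Stations
#' must share in-plane geometry and b-values; their z-extents are treated as
#' contiguous and non-overlapping.
#'
#' @param stations List of [dwi_station()], any order; sorted by
#'   `station_index` on construction.
#' @return An object of class `dwi_study`.
#' @export
dwi_study <- function(stations) {
  stopifnot(is.list(stations), length(stations) >= 1)
  ok <- vapply(stations, inherits, logical(1), "dwi_station")
  if (!all(ok)) stop("all elements must be dwi_station objects", call. = FALSE)
  idx <- vapply(stations, function(s) s$station_index, integer(1))
  if (anyDuplicated(idx) > 0) {
    stop("duplicate station indices", call. = FALSE)
  }
  stations <- stations[order(idx)]
  g1 <- stations[[1]]$geometry
  b1 <- names(stations[[1]]$signals)
  for (s in stations[-1]) {
    if (!geom_inplane_equal(g1, s$geometry)) {
      stop("unstackable stations: in-plane geometry mismatch", call. = FALSE)
    }
    if (!identical(b1, names(s$signals))) {
      stop("incomplete study: stations carry different b-values", call. = FALSE)
    }
  }
  structure(list(stations = stations), class = "dwi_study")
}

#' @export
print.dwi_study <- function(x, ...) {
  nb <- names(x$stations[[1]]$signals)
  cat(sprintf("<dwi_study> %d station(s), b = {%s} s/mm^2\n",
              length(x$stations), paste(nb, collapse = ", ")))
  for (s in x$stations) {
    cat(sprintf("  station %d: %d x %d x %d voxels\n", s$station_index,
                s$geometry$dim[1], s$geometry$dim[2], s$geometry$dim[3]))
  }
  invisible(x)
}

#' B-values of a study
#' @param study A [dwi_study()].
#' @return Sorted numeric vector of b-values (s/mm^2).
#' @export
study_b_values <- function(study) {
  stopifnot(inherits(study, "dwi_study"))
  as.numeric(names(study$stations[[1]]$signals))
}

nifti_geometry <- function(img) {
  d <- dim(img)
  if (length(d) != 3) stop("expected a 3D NIfTI volume", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("unusable mask file: geometry metadata missing or invalid",
         call. = FALSE)
  }
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  vol_geometry(sp, d, origin = xf[1:3, 4])
}

write_nifti_volume <- function(arr, geometry, path, datatype = "float32") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geometry$spacing
  aff <- diag(c(geometry$spacing, 1))
  aff[1:3, 4] <- geometry$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a multi-station DWI study from NIfTI volumes
#'
#' Expects one NIfTI-1 volume per station per b-value, described by a
#' plain-text sidecar table (whitespace- or tab-separated) with columns
#' `filename`, `bvalue` (s/mm^2) and optionally `station` (defaults to 1).
#' Stations are sorted cranial to caudal by their station index.
#'
#' @param path Directory containing the volumes and sidecar, or the sidecar
#'   file itself.
#' @param b_table Sidecar filename, relative to `path` when `path` is a
#'   directory. Default `"bvalues.tsv"`.
#' @return A [dwi_study()].
#' @seealso [write_dwi_series()] for the inverse, [assemble_body_volume()].
#' @export
read_dwi_series <- function(path, b_table = "bvalues.tsv") {
  if (dir.exists(path)) {
    sidecar <- file.path(path, b_table)
    root <- path
  } else {
    sidecar <- path
    root <- dirname(path)
  }
  if (!file.exists(sidecar)) {
    stop(sprintf("incomplete study: sidecar b-value table not found at %s",
                 sidecar), call. = FALSE)
  }
  tab <- utils::read.table(sidecar, header = TRUE, stringsAsFactors = FALSE)
  need <- c("filename", "bvalue")
  if (!all(need %in% names(tab))) {
    stop("incomplete study: sidecar must have columns filename, bvalue",
         call. = FALSE)
  }
  if (is.null(tab$station)) tab$station <- 1L
  if (anyDuplicated(tab[c("station", "bvalue")]) > 0) {
    stop("incomplete study: duplicate (station, b-value) entries",
         call. = FALSE)
  }
  stations <- lapply(sort(unique(tab$station)), function(st) {
    rows <- tab[tab$station == st, , drop = FALSE]
    if (length(unique(rows$bvalue)) < 2) {
      stop(sprintf("incomplete study: station %s has < 2 b-values", st),
           call. = FALSE)
    }
    vols <- list()
    geom <- NULL
    for (i in seq_len(nrow(rows))) {
      f <- file.path(root, rows$filename[i])
      if (!file.exists(f)) {
        stop(sprintf("incomplete study: missing volume %s", rows$filename[i]),
             call. = FALSE)
      }
      img <- RNifti::readNifti(f)
      g <- nifti_geometry(img)
      if (is.null(geom)) {
        geom <- g
      } else if (!all(g$dim == geom$dim) ||
                 any(abs(g$spacing - geom$spacing) > 1e-4)) {
        stop_geometry_conflict(sprintf("b-value volumes of station %s", st))
      }
      vols[[as.character(rows$bvalue[i])]] <- as.array(img)
    }
    dwi_station(vols, geom, station_index = as.integer(st))
  })
  dwi_study(stations)
}

#' Write a DWI study as NIfTI volumes plus sidecar b-value table
#'
#' Inverse of [read_dwi_series()]: one float32 NIfTI per station per b-value
#' and a `bvalues.tsv` sidecar (`filename  bvalue  station`).
#'
#' @param study A [dwi_study()].
#' @param dir Output directory (created if needed).
#' @param datatype NIfTI storage type; default `"float64"` keeps the
#'   round-trip voxel-exact.
#' @return Invisibly, the sidecar path.
#' @export
write_dwi_series <- function(study, dir, datatype = "float64") {
  stopifnot(inherits(study, "dwi_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in study$stations) {
    for (bn in names(s$signals)) {
      fn <- sprintf("station%d_b%s.nii", s$station_index, bn)
      write_nifti_volume(s$signals[[bn]], s$geometry, file.path(dir, fn),
                         datatype = datatype)
      rows[[length(rows) + 1]] <- data.frame(
        filename = fn, bvalue = as.numeric(bn), station = s$station_index)
    }
  }
  sidecar <- file.path(dir, "bvalues.tsv")
  utils::write.table(do.call(rbind, rows), sidecar, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(sidecar)
}

#' Fuse contiguous stations into one body volume
#'
#' Concatenates the selected stations along z, in cranial-to-caudal order,
#' into a single fused station. Pure rearrangement: voxel intensities are
#' copied, never interpolated, so the fused volume has `nz` equal to the sum
#' of the station slice counts. This is how the head/neck station is dropped
#' and the three body blocks (upper thorax to mid-thighs) are analysed as one
#' volume.
#'
#' @param study A [dwi_study()].
#' @param include Integer vector of station indices to retain, e.g. `2:4`.
#'   Default: all stations.
#' @return A [dwi_study()] with a single fused station (index 1).
#' @export
assemble_body_volume <- function(study, include = NULL) {
  stopifnot(inherits(study, "dwi_study"))
  idx <- vapply(study$stations, function(s) s$station_index, integer(1))
  if (is.null(include)) include <- idx
  if (!all(include %in% idx)) {
    stop("requested station indices not present in study", call. = FALSE)
  }
  keep <- study$stations[match(sort(include), idx)]
  g1 <- keep[[1]]$geometry
  for (s in keep[-1]) {
    if (!geom_inplane_equal(g1, s$geometry)) {
      stop("unstackable stations: in-plane geometry mismatch", call. = FALSE)
    }
  }
  nz <- sum(vapply(keep, function(s) s$geometry$dim[3], integer(1)))
  fused_geom <- vol_geometry(g1$spacing, c(g1$dim[1:2], nz), g1$origin)
  bnames <- names(keep[[1]]$signals)
  fused <- lapply(bnames, function(bn) {
    slabs <- lapply(keep, function(s) s$signals[[bn]])
    arr <- array(0, dim = fused_geom$dim)
    z0 <- 0L
    for (sl in slabs) {
      arr[, , z0 + seq_len(dim(sl)[3])] <- sl
      z0 <- z0 + dim(sl)[3]
    }
    arr
  })
  names(fused) <- bnames
  dwi_study(list(dwi_station(fused, fused_geom, station_index = 1L)))
}

# Single fused station accessor with a clear failure when not yet fused.
fused_station <- function(study) {
  stopifnot(inherits(study, "dwi_study"))
  if (length(study$stations) != 1) {
    stop("study has multiple stations; call assemble_body_volume() first",
         call. = FALSE)
  }
  study$stations[[1]]
}

#' Write / read a binary mask as NIfTI-1
#'
#' Masks are stored as 0/1 uint8 volumes; the write-read round trip is
#' voxel-exact. Reading rejects files without usable spacing metadata.
#'
#' @param mask A [mask3d()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_mask()` returns the path invisibly; `read_mask()` returns a
#'   [mask3d()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask3d"))
  arr <- array(as.integer(mask$voxels), dim = dim(mask$voxels))
  write_nifti_volume(arr, mask$geometry, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("unusable mask file: %s not found", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  geom <- nifti_geometry(img)
  mask3d(as.array(img) != 0, geom)
}
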