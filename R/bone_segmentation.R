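#' Threshold a computed b-value image into a mask
#'
#' Selects all voxels with intensity greater than or equal to the threshold
#' (inclusive comparison). This is the scriptable equivalent of the
#' interactive signal-intensity threshold observers adjust on the computed
#' high-b-value image to isolate bright bone marrow; an empty result is
#' legal.
#'
#' @param computed A [computed_dwi()].
#' @param threshold Non-negative intensity threshold.
#' @return A [mask3d()].
#' @export
threshold_mask <- function(computed, threshold) {
  stopifnot(inherits(computed, "computed_dwi"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  mask3d(computed$volume >= threshold, computed$geometry)
}

#' Ellipsoid mask edit
#'
#' A single subtractive editing step, mirroring manual cleanup of a
#' threshold mask: either full-depth cutting of an ellipse drawn on a
#' projection (the edit removes everything along the axis perpendicular to
#' that plane) or a single-slice elliptical cut.
#'
#' Modes: `full_depth_axial_projection` (ellipse in x/y, cuts through all z),
#' `full_depth_coronal_projection` (ellipse in x/z, cuts through all y),
#' `full_depth_sagittal_projection` (ellipse in y/z, cuts through all x),
#' `single_slice` (ellipse in x/y at one z slice).
#'
#' @param center Length-3 voxel coordinates (x, y, z); for full-depth modes
#'   the coordinate along the cut axis is ignored.
#' @param semi_axes Length-3 positive semi-axes (rx, ry, rz) in voxels; the
#'   component along the cut axis is ignored for full-depth modes.
#' @param mode One of the four modes above.
#' @param slice_index Required for `single_slice`: the z slice (1-based).
#' @return An object of class `ellipsoid_edit`.
#' @export
ellipsoid_edit <- function(center, semi_axes,
                           mode = c("full_depth_axial_projection",
                                    "full_depth_coronal_projection",
                                    "full_depth_sagittal_projection",
                                    "single_slice"),
                           slice_index = NULL) {
  mode <- match.arg(mode)
  center <- as.numeric(center)
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 3, length(semi_axes) == 3)
  if (any(semi_axes <= 0)) stop("semi-axes must be > 0", call. = FALSE)
  if (mode == "single_slice") {
    if (is.null(slice_index) || length(slice_index) != 1 || slice_index < 1) {
      stop("single_slice mode requires a valid slice_index", call. = FALSE)
    }
    slice_index <- as.integer(slice_index)
  } else {
    slice_index <- NULL
  }
  structure(list(center = center, semi_axes = semi_axes, mode = mode,
                 slice_index = slice_index),
            class = "ellipsoid_edit")
}

# In-plane elliptical membership over two index axes.
ellipse_member <- function(n1, n2, c1, c2, r1, r2) {
  u <- (seq_len(n1) - c1) / r1
  v <- (seq_len(n2) - c2) / r2
  outer(u^2, v^2, `+`) <= 1
}

#' Apply one ellipsoid edit to a mask
#'
#' Removal is purely subtractive: the output mask is a subset of the input.
#' Edits extending beyond the volume are clipped at the bounds.
#'
#' @param mask A [mask3d()].
#' @param edit An [ellipsoid_edit()].
#' @return The edited [mask3d()].
#' @export
apply_edit <- function(mask, edit) {
  stopifnot(inherits(mask, "mask3d"), inherits(edit, "ellipsoid_edit"))
  d <- mask$geometry$dim
  v <- mask$voxels
  ce <- edit$center
  r <- edit$semi_axes
  switch(edit$mode,
    full_depth_axial_projection = {
      m <- ellipse_member(d[1], d[2], ce[1], ce[2], r[1], r[2])
      v <- v & !array(m, dim = d)  # recycles xy plane along z
    },
    full_depth_coronal_projection = {
      m <- ellipse_member(d[1], d[3], ce[1], ce[3], r[1], r[3])
      cut <- aperm(array(m, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
      v <- v & !cut
    },
    full_depth_sagittal_projection = {
      m <- ellipse_member(d[2], d[3], ce[2], ce[3], r[2], r[3])
      cut <- aperm(array(m, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
      v <- v & !cut
    },
    single_slice = {
      z <- edit$slice_index
      if (z >= 1 && z <= d[3]) {
        m <- ellipse_member(d[1], d[2], ce[1], ce[2], r[1], r[2])
        v[, , z] <- v[, , z] & !m
      }
    }
  )
  mask3d(v, mask$geometry)
}

#' Apply an ordered edit script
#'
#' Left-fold of [apply_edit()] over the script. Because every edit is
#' subtractive and position-fixed, replaying a script on its own output is a
#' no-op (idempotence).
#'
#' @param mask A [mask3d()].
#' @param script A list of [ellipsoid_edit()]s (possibly empty).
#' @return The edited [mask3d()].
#' @export
apply_edit_script <- function(mask, script) {
  stopifnot(inherits(mask, "mask3d"), is.list(script))
  for (e in script) mask <- apply_edit(mask, e)
  mask
}

#' Serialize / deserialize an edit script as JSON
#'
#' Edit scripts are plain JSON (one entry per edit: mode, center, semi-axes,
#' optional slice) so that an observer's cleanup is replayable.
#'
#' @param script List of [ellipsoid_edit()]s.
#' @param path JSON file path.
#' @return `write_edit_script()` the path invisibly; `read_edit_script()` the
#'   script.
#' @export
write_edit_script <- function(script, path) {
  entries <- lapply(script, function(e) {
    out <- list(mode = e$mode, center = e$center, semi_axes = e$semi_axes)
    if (!is.null(e$slice_index)) out$slice_index <- e$slice_index
    out
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(entries, function(e) {
    ellipsoid_edit(unlist(e$center), unlist(e$semi_axes), e$mode,
                   slice_index = e$slice_index)
  })
}
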