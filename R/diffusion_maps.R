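#' Voxelwise ADC map
#'
#' Container for an apparent diffusion coefficient volume in um^2/s together
#' with a per-voxel validity flag. Invalid voxels (non-positive signal at any
#' b-value, or a negative fitted slope) carry value 0 and `valid = FALSE`.
#'
#' @param values 3D numeric array, ADC in um^2/s, non-negative where valid.
#' @param valid 3D logical array, same shape.
#' @param geometry A [vol_geometry()].
#' @param b_values Numeric vector, the b-values the fit used (s/mm^2).
#' @return An object of class `adc_map`.
#' @export
adc_map <- function(values, valid, geometry, b_values) {
  check_array3(values, geometry, "ADC values")
  check_array3(valid, geometry, "ADC validity flags")
  if (any(values[valid] < 0)) {
    stop("valid ADC values must be non-negative", call. = FALSE)
  }
  structure(
    list(values = values, valid = valid, geometry = geometry,
         b_values = sort(as.numeric(b_values))),
    class = "adc_map"
  )
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf(
    "<adc_map> %d x %d x %d voxels, %.1f%% valid, b = {%s} s/mm^2\n",
    x$geometry$dim[1], x$geometry$dim[2], x$geometry$dim[3],
    100 * mean(x$valid), paste(x$b_values, collapse = ", ")))
  invisible(x)
}

#' Fit the voxelwise ADC map by mono-exponential regression
#'
#' Fits S(b) = S0 * exp(-b * ADC) per voxel. With exactly two b-values the
#' closed form ADC = ln(S_b1 / S_b2) / (b2 - b1) is used; with more, ordinary
#' least squares on log-signal versus b. The fitted coefficient (mm^2/s) is
#' converted once to um^2/s (factor 1e6), the unit used by the lesion window.
#'
#' Voxels with any non-positive signal are flagged invalid with value 0.
#' Negative fitted ADCs (signal increasing with b, non-physical) are clamped
#' to 0 and flagged invalid; an exactly flat decay gives ADC 0 and stays
#' valid.
#'
#' @param study A single-station (fused) [dwi_study()]; see
#'   [assemble_body_volume()].
#' @return An [adc_map()] in um^2/s.
#' @examples
#' g <- vol_geometry(c(1.6, 1.6, 5), c(2, 2, 1))
#' s <- list("50" = array(1000, c(2, 2, 1)),
#'           "900" = array(1000 * exp(-0.85), c(2, 2, 1)))
#' st <- dwi_study(list(dwi_station(s, g)))
#' fit_adc(st)$values[1, 1, 1]  # 1000 um^2/s
#' @export
fit_adc <- function(study) {
  station <- fused_station(study)
  b <- as.numeric(names(station$signals))
  if (length(b) < 2) stop("underdetermined fit: need >= 2 b-values",
                          call. = FALSE)
  sig <- lapply(station$signals, function(a) a * 1.0)
  positive <- Reduce(`&`, lapply(sig, function(a) a > 0))

  if (length(b) == 2) {
    adc_mm2 <- array(0, dim = station$geometry$dim)
    adc_mm2[positive] <- log(sig[[1]][positive] / sig[[2]][positive]) /
      (b[2] - b[1])
  } else {
    # vectorized log-linear least squares: slope of log S on b, negated
    bc <- b - mean(b)
    denom <- sum(bc^2)
    num <- array(0, dim = station$geometry$dim)
    logs <- lapply(sig, function(a) {
      l <- array(0, dim = dim(a)); l[positive] <- log(a[positive]); l
    })
    logbar <- Reduce(`+`, logs) / length(b)
    for (i in seq_along(b)) num <- num + bc[i] * (logs[[i]] - logbar)
    adc_mm2 <- -num / denom
  }

  valid <- positive & (adc_mm2 >= 0)
  values <- adc_mm2 * 1e6
  values[!valid] <- 0
  adc_map(values, valid, station$geometry, b)
}

#' Computed (synthesized) b-value image
#'
#' @param volume 3D intensity array, non-negative.
#' @param b_target Target b-value in s/mm^2.
#' @param geometry A [vol_geometry()].
#' @return An object of class `computed_dwi`.
#' @export
computed_dwi <- function(volume, b_target, geometry) {
  check_array3(volume, geometry, "computed volume")
  stopifnot(is.numeric(b_target), length(b_target) == 1, b_target >= 0)
  structure(list(volume = volume, b_target = b_target, geometry = geometry),
            class = "computed_dwi")
}

#' Synthesize a computed high-b-value image
#'
#' Extrapolates the mono-exponential decay from the lowest acquired b-value:
#' S(b_target) = S(b_low) * exp(-(b_target - b_low) * ADC). Voxels with an
#' invalid ADC are set to 0. By construction, with a two-point fitted map a
#' `b_target` equal to an acquired b-value reproduces that acquired volume at
#' every valid voxel.
#'
#' The default target of 1000 s/mm^2 reflects where observers typically place
#' the computed image for bone-versus-soft-tissue contrast (cohort mean
#' choices cluster just above 1000 s/mm^2).
#'
#' @param study Single-station (fused) [dwi_study()].
#' @param adc [adc_map()] aligned to `study`.
#' @param b_target Target b-value (s/mm^2), at least the lowest acquired b.
#' @return A [computed_dwi()].
#' @export
synthesize_computed_b <- function(study, adc, b_target = 1000) {
  station <- fused_station(study)
  stopifnot(inherits(adc, "adc_map"))
  if (!geom_equal(station$geometry, adc$geometry)) {
    stop_geometry_conflict("study and ADC map")
  }
  b <- as.numeric(names(station$signals))
  if (b_target < min(b)) {
    stop("b_target must be >= the lowest acquired b-value", call. = FALSE)
  }
  s_low <- station$signals[[1]] * 1.0
  out <- s_low * exp(-(b_target - min(b)) * adc$values * 1e-6)
  out[!adc$valid] <- 0
  computed_dwi(out, b_target, station$geometry)
}

#' Export an ADC map as NIfTI-1
#'
#' Writes the ADC values (um^2/s, float32) with invalid voxels as 0.
#'
#' @param adc An [adc_map()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_adc_map <- function(adc, path) {
  stopifnot(inherits(adc, "adc_map"))
  write_nifti_volume(adc$values, adc$geometry, path, datatype = "float32")
  invisible(path)
}
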