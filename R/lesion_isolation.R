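#' ADC window for lesion isolation
#'
#' The fixed ADC band separating active bone metastases from normal fatty
#' marrow (below) and necrotic lesion or cyst (above). Defaults are the
#' standard 650 and 1400 um^2/s thresholds.
#'
#' @param low Lower threshold, um^2/s.
#' @param high Upper threshold, um^2/s; must exceed `low`.
#' @return An object of class `adc_window`.
#' @export
adc_window <- function(low = 650, high = 1400) {
  stopifnot(is.numeric(low), is.numeric(high),
            length(low) == 1, length(high) == 1)
  if (!(low >= 0 && low < high)) {
    stop("require 0 <= low < high", call. = FALSE)
  }
  structure(list(low = low, high = high), class = "adc_window")
}

#' Classify bone-mask voxels by ADC band
#'
#' Partitions the bone-mask voxels into three classes by the ADC window:
#' `normal` (ADC < low), `lesion` (low <= ADC <= high, closed interval) and
#' `necrotic_or_cyst` (ADC > high). Voxels with an invalid ADC fit are
#' assigned to `normal`, i.e. excluded from the lesion class, since no
#' defensible ADC exists for them. The three classes always partition the
#' bone mask exactly.
#'
#' @param bone_mask A [mask3d()] of the segmented bone marrow.
#' @param adc An [adc_map()] aligned to the mask.
#' @param window An [adc_window()]; default 650-1400 um^2/s.
#' @return An object of class `classified_mask` with a label array
#'   (0 = outside mask, 1 = normal, 2 = lesion, 3 = necrotic_or_cyst),
#'   the geometry, the window, and per-class counts.
#' @export
classify_adc <- function(bone_mask, adc, window = adc_window()) {
  stopifnot(inherits(bone_mask, "mask3d"), inherits(adc, "adc_map"),
            inherits(window, "adc_window"))
  if (!geom_equal(bone_mask$geometry, adc$geometry)) {
    stop_geometry_conflict("bone mask and ADC map")
  }
  labels <- array(0L, dim = adc$geometry$dim)
  inmask <- bone_mask$voxels
  v <- adc$values
  labels[inmask] <- 1L
  lesion <- inmask & adc$valid & v >= window$low & v <= window$high
  necro <- inmask & adc$valid & v > window$high
  labels[lesion] <- 2L
  labels[necro] <- 3L
  counts <- c(normal = sum(labels == 1L), lesion = sum(labels == 2L),
              necrotic_or_cyst = sum(labels == 3L))
  structure(
    list(labels = labels, geometry = adc$geometry, window = window,
         counts = counts),
    class = "classified_mask"
  )
}

#' @export
print.classified_mask <- function(x, ...) {
  cat(sprintf(
    "<classified_mask> window [%g, %g] um^2/s: normal %d | lesion %d | necrotic_or_cyst %d\n",
    x$window$low, x$window$high,
    x$counts[["normal"]], x$counts[["lesion"]], x$counts[["necrotic_or_cyst"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classified mask into per-class counts
#'
#' @param x A `classified_mask`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `n_voxels`, `volume_ml`.
#' @method tidy classified_mask
#' @export
tidy.classified_mask <- function(x, ...) {
  vv <- voxel_volume(x$geometry) / 1000
  tibble::tibble(
    class = names(x$counts),
    n_voxels = as.integer(x$counts),
    volume_ml = as.integer(x$counts) * vv
  )
}

#' Extract the lesion mask from a classification
#'
#' @param classified A `classified_mask` from [classify_adc()].
#' @return A [mask3d()] of lesion-labelled voxels (possibly empty).
#' @export
lesion_mask <- function(classified) {
  stopifnot(inherits(classified, "classified_mask"))
  mask3d(classified$labels == 2L, classified$geometry)
}
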