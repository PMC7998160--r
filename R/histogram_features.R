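#' Histogram binning scheme
#'
#' Uniform bins over a fixed ADC range, used for the entropy calculation.
#' Defaults: 64 bins over the lesion window 650-1400 um^2/s. Values outside
#' the range are clipped into the edge bins so that every value is counted.
#'
#' @param range Length-2 numeric, `[lo, hi]` in um^2/s with `lo < hi`.
#' @param n_bins Number of bins, >= 1.
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme <- function(range = c(650, 1400), n_bins = 64) {
  range <- as.numeric(range)
  stopifnot(length(range) == 2, is.numeric(n_bins), length(n_bins) == 1)
  if (!(range[1] < range[2])) stop("require lo < hi", call. = FALSE)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  structure(list(range = range, n_bins = as.integer(n_bins)),
            class = "bin_scheme")
}

#' Histogram counts over a bin scheme
#'
#' Assigns each value to a uniform bin over `bins$range`; out-of-range values
#' are clipped into the first or last bin, so the counts always sum to the
#' number of values.
#'
#' @param values Numeric vector (um^2/s).
#' @param bins A [bin_scheme()].
#' @return Integer vector of length `n_bins`.
#' @export
adc_histogram <- function(values, bins = bin_scheme()) {
  stopifnot(inherits(bins, "bin_scheme"))
  values <- values[!is.na(values)]
  if (length(values) == 0) return(integer(bins$n_bins))
  lo <- bins$range[1]
  w <- (bins$range[2] - lo) / bins$n_bins
  idx <- floor((values - lo) / w) + 1
  idx <- pmin(pmax(idx, 1), bins$n_bins)
  tabulate(idx, nbins = bins$n_bins)
}

#' Shannon entropy of histogram counts, in bits
#'
#' -sum p_i log2 p_i over non-empty bins, where p_i are the normalized
#' counts. A single occupied bin gives 0; counts of all zero are undefined
#' and return `NA`.
#'
#' @param counts Non-negative integer vector.
#' @return Entropy in bits, or `NA_real_` if all counts are zero.
#' @export
shannon_entropy <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

# population central moment of order k
pop_moment <- function(x, k) mean((x - mean(x))^k)

#' First-order ADC-histogram statistics of a segmentation
#'
#' Computes the nine per-segmentation statistics used to quantify skeletal
#' tumour burden: segmentation volume (ml), mean, standard deviation
#' (sample, n-1), median, 5th and 95th percentiles (linear interpolation
#' between order statistics) of the ADC values in um^2/s, Fisher-Pearson
#' skewness g1 = m3 / m2^1.5, excess kurtosis m4 / m2^2 - 3 (both population
#' moments), and Shannon entropy of the binned normalized histogram in bits.
#'
#' Degenerate inputs are flagged, not raised: an empty mask yields Volume 0,
#' n 0 and `NA` statistics; a constant-valued region yields Std 0, Entropy 0
#' and `NA` skewness/kurtosis (zero variance).
#'
#' Only voxels with a valid ADC fit contribute.
#'
#' @param adc An [adc_map()].
#' @param lesion A [mask3d()] aligned to `adc` (typically from
#'   [lesion_mask()]).
#' @param bins A [bin_scheme()] for the entropy term.
#' @return A one-row tibble with columns `n_voxels`, `volume_ml`, `mean_adc`,
#'   `std_adc`, `median_adc`, `p5_adc`, `p95_adc`, `skewness_adc`,
#'   `kurtosis_adc`, `entropy_adc`.
#' @export
compute_features <- function(adc, lesion, bins = bin_scheme()) {
  stopifnot(inherits(adc, "adc_map"), inherits(lesion, "mask3d"))
  if (!geom_equal(adc$geometry, lesion$geometry)) {
    stop_geometry_conflict("ADC map and lesion mask")
  }
  sel <- lesion$voxels & adc$valid
  x <- adc$values[sel]
  feature_row(x, n_voxels = sum(sel),
              vox_ml = voxel_volume(adc$geometry) / 1000, bins = bins)
}

# Shared by compute_features() and the phantom truth table: statistics of a
# bare ADC sample with a known voxel volume.
feature_row <- function(x, n_voxels, vox_ml, bins = bin_scheme()) {
  if (length(x) == 0) {
    return(tibble::tibble(
      n_voxels = 0L, volume_ml = 0, mean_adc = NA_real_, std_adc = NA_real_,
      median_adc = NA_real_, p5_adc = NA_real_, p95_adc = NA_real_,
      skewness_adc = NA_real_, kurtosis_adc = NA_real_, entropy_adc = NA_real_
    ))
  }
  m2 <- pop_moment(x, 2)
  qs <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  tibble::tibble(
    n_voxels = as.integer(n_voxels),
    volume_ml = n_voxels * vox_ml,
    mean_adc = mean(x),
    std_adc = if (length(x) > 1) stats::sd(x) else 0,
    median_adc = qs[2],
    p5_adc = qs[1],
    p95_adc = qs[3],
    skewness_adc = if (m2 > 0) pop_moment(x, 3) / m2^1.5 else NA_real_,
    kurtosis_adc = if (m2 > 0) pop_moment(x, 4) / m2^2 - 3 else NA_real_,
    entropy_adc = shannon_entropy(adc_histogram(x, bins))
  )
}

#' Plot the ADC histogram with the classification bands
#'
#' Displays the in-mask ADC distribution with the normal-marrow, lesion and
#' necrosis/cyst bands shaded, mirroring the histogram view used when
#' isolating metastases.
#'
#' @param adc An [adc_map()].
#' @param bone_mask A [mask3d()] restricting the histogram.
#' @param window An [adc_window()].
#' @param binwidth Histogram bin width in um^2/s.
#' @return A ggplot object.
#' @export
plot_adc_histogram <- function(adc, bone_mask, window = adc_window(),
                               binwidth = 25) {
  stopifnot(inherits(adc, "adc_map"), inherits(bone_mask, "mask3d"))
  sel <- bone_mask$voxels & adc$valid
  df <- tibble::tibble(adc = adc$values[sel])
  xmax <- max(df$adc, window$high * 1.2)
  bands <- tibble::tibble(
    xmin = c(0, window$low, window$high),
    xmax = c(window$low, window$high, xmax),
    class = factor(c("normal marrow", "lesion", "necrotic or cyst"),
                   levels = c("normal marrow", "lesion", "necrotic or cyst"))
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$class),
      alpha = 0.2) +
    ggplot2::geom_histogram(data = df, ggplot2::aes(x = .data$adc),
                            binwidth = binwidth, colour = "grey20",
                            fill = "grey40") +
    ggplot2::scale_fill_manual(values = c("normal marrow" = "gold",
                                          "lesion" = "red3",
                                          "necrotic or cyst" = "seagreen")) +
    ggplot2::labs(x = expression(ADC ~ (mu * m^2 / s)), y = "voxels",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
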