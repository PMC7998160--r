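#' Tissue specification for the whole-body phantom
#'
#' One tissue class occupying a geometric primitive (axis-aligned box or
#' ellipsoid) in voxel space, with a baseline signal `S0` and a truncated
#' normal ADC distribution. By default the truncation band follows the ADC
#' classification bands: marrow below 650 um^2/s, lesion within
#' `[650, 1400]`, necrosis above 1400 (and all tissues above 0), so the
#' noiseless phantom classifies exactly.
#'
#' @param label One of `marrow`, `lesion`, `necrosis`, `soft_confounder`,
#'   `background`.
#' @param shape `"box"`, `"ellipsoid"` or `"everywhere"` (background fill).
#' @param center Length-3 voxel coordinates (ignored for `everywhere`).
#' @param half_size Length-3: box half-widths or ellipsoid semi-axes in
#'   voxels.
#' @param S0 Baseline signal at b = 0, arbitrary units, >= 0.
#' @param adc_mean,adc_sd ADC distribution parameters in um^2/s.
#' @param adc_band Optional length-2 truncation band; defaults by label.
#' @param cut_mode For confounders: the projection mode of the ellipsoid cut
#'   a careful observer would use to remove this tissue (see
#'   [ellipsoid_edit()]), or `NA` for none.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(label, shape, center = c(0, 0, 0), half_size = c(1, 1, 1),
                        S0, adc_mean, adc_sd = 0, adc_band = NULL,
                        cut_mode = NA_character_) {
  label <- match.arg(label, c("marrow", "lesion", "necrosis",
                              "soft_confounder", "background"))
  shape <- match.arg(shape, c("box", "ellipsoid", "everywhere"))
  stopifnot(S0 >= 0, adc_mean >= 0, adc_sd >= 0)
  if (is.null(adc_band)) {
    adc_band <- switch(label,
      marrow = c(0, 650),
      lesion = c(650, 1400),
      necrosis = c(1400, Inf),
      c(0, Inf))
  }
  structure(
    list(label = label, shape = shape, center = as.numeric(center),
         half_size = as.numeric(half_size), S0 = S0, adc_mean = adc_mean,
         adc_sd = adc_sd, adc_band = as.numeric(adc_band),
         cut_mode = cut_mode),
    class = "tissue_spec"
  )
}

tissue_member <- function(spec, dim) {
  if (spec$shape == "everywhere") return(array(TRUE, dim = dim))
  cx <- spec$center; h <- spec$half_size
  x <- seq_len(dim[1]); y <- seq_len(dim[2]); z <- seq_len(dim[3])
  if (spec$shape == "box") {
    inx <- abs(x - cx[1]) <= h[1]
    iny <- abs(y - cx[2]) <= h[2]
    inz <- abs(z - cx[3]) <= h[3]
    outer(outer(inx, iny, `&`), inz, `&`)
  } else {
    u2 <- ((x - cx[1]) / h[1])^2
    v2 <- ((y - cx[2]) / h[2])^2
    w2 <- ((z - cx[3]) / h[3])^2
    outer(outer(u2, v2, `+`), w2, `+`) <= 1
  }
}

# Projection-plane cutting edit that covers a tissue primitive, with margin.
confounder_cut <- function(spec) {
  if (is.na(spec$cut_mode)) return(NULL)
  scale <- if (spec$shape == "box") sqrt(2) * 1.1 else 1.2
  ellipsoid_edit(spec$center, spec$half_size * scale, mode = spec$cut_mode)
}

# Truncated normal draws by inverse-CDF, exact and vectorized.
rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Default phantom tissue list
#'
#' A desk-scale whole-body torso: a spine-like marrow column running through
#' all three stations with three embedded lesion ellipsoids and one necrotic
#' focus; a broad soft-tissue body block (high-ADC, mostly suppressed on the
#' computed high-b image); and three confounders that survive thresholding
#' and must be edited away, mirroring the tissues that typically pollute a
#' threshold mask: a spinal-cord-like posterior column, a spleen-like
#' ellipsoid and a lymph-node-like nodule. ADC means follow the field's
#' ranges (fatty marrow well below 650 um^2/s, active lesions around
#' 940-1030 um^2/s, necrosis above 1400).
#'
#' @param dim Fused-volume grid (default 64 x 64 x 150 voxels, i.e. three
#'   stations of 50 axial slices).
#' @return List of [tissue_spec()]s, background first, nested tissues last.
#' @export
default_phantom_tissues <- function(dim = c(64, 64, 150)) {
  zc <- dim[3] / 2 + 0.5
  list(
    tissue_spec("background", "everywhere", S0 = 0, adc_mean = 0),
    tissue_spec("soft_confounder", "box", center = c(dim[1] / 2, dim[2] / 2, zc),
                half_size = c(26, 24, dim[3] / 2), S0 = 470,
                adc_mean = 3000, adc_sd = 250, adc_band = c(2600, Inf)),
    tissue_spec("soft_confounder", "box", center = c(dim[1] / 2, 46, zc),
                half_size = c(2, 2, dim[3] / 2), S0 = 600,
                adc_mean = 900, adc_sd = 80,
                cut_mode = "full_depth_axial_projection"),
    tissue_spec("soft_confounder", "ellipsoid", center = c(14, 20, 25),
                half_size = c(6, 7, 8), S0 = 650,
                adc_mean = 850, adc_sd = 90,
                cut_mode = "full_depth_coronal_projection"),
    tissue_spec("soft_confounder", "ellipsoid", center = c(48, 40, 60),
                half_size = c(3, 3, 4), S0 = 620,
                adc_mean = 950, adc_sd = 70,
                cut_mode = "full_depth_coronal_projection"),
    tissue_spec("marrow", "box", center = c(dim[1] / 2, dim[2] / 2, zc),
                half_size = c(5, 5, dim[3] / 2), S0 = 450,
                adc_mean = 350, adc_sd = 60),
    tissue_spec("lesion", "ellipsoid", center = c(dim[1] / 2, dim[2] / 2, 30),
                half_size = c(4, 4, 5), S0 = 550, adc_mean = 1000, adc_sd = 120),
    tissue_spec("lesion", "ellipsoid", center = c(dim[1] / 2, dim[2] / 2, 75),
                half_size = c(4, 4, 5), S0 = 550, adc_mean = 1000, adc_sd = 120),
    tissue_spec("lesion", "ellipsoid", center = c(dim[1] / 2, dim[2] / 2, 120),
                half_size = c(4, 4, 5), S0 = 550, adc_mean = 1000, adc_sd = 120),
    tissue_spec("necrosis", "ellipsoid", center = c(dim[1] / 2, dim[2] / 2, 100),
                half_size = c(2.5, 2.5, 3), S0 = 500, adc_mean = 1700,
                adc_sd = 150)
  )
}

#' Generate a synthetic multi-station DWI study with known truth
#'
#' Builds per-voxel `S0` and true ADC volumes from the tissue list, simulates
#' the diffusion signal S(b) = S0 exp(-b ADC 1e-6) at each b-value, corrupts
#' it with Rician noise of scale `noise_sigma` (magnitude MR model:
#' sqrt((S + e1)^2 + e2^2) with e ~ N(0, sigma)), and splits the fused volume
#' into contiguous stations of `slices_per_station` axial slices. The same
#' seed reproduces the output bit for bit.
#'
#' Overlapping primitives: with `overlap = "error"` any voxel claimed by two
#' tissues aborts with an ambiguous-assignment error; with `"nest"` the later
#' tissue in the list wins, which is how the default phantom embeds lesions
#' in the marrow column and the marrow column in the body block.
#'
#' @param tissues List of [tissue_spec()]s; default [default_phantom_tissues()].
#' @param dim Fused grid dimensions in voxels.
#' @param spacing Voxel spacing in mm; default 1.6 x 1.6 x 5.0.
#' @param slices_per_station Station thickness in slices (default 50).
#' @param b_values Acquired b-values, s/mm^2 (default 50 and 900).
#' @param noise_sigma Rician noise scale in intensity units (0 = noiseless).
#'   For the default tissues, sigma = 11 gives SNR about 20 for lesion signal
#'   at b = 900.
#' @param seed Integer RNG seed.
#' @param nominal_threshold The intensity threshold a careful observer would
#'   pick on the computed b = 1000 image (default 41).
#' @param overlap `"nest"` (default for the default phantom) or `"error"`.
#' @return A list with class `wb_phantom`: `study` (a [dwi_study()]) and
#'   `truth` (class `phantom_truth`: per-tissue masks, true ADC and S0
#'   volumes, per-class truth features, the confounder cut list and the
#'   nominal threshold).
#' @export
generate_phantom <- function(tissues = default_phantom_tissues(dim),
                             dim = c(64, 64, 150),
                             spacing = c(1.6, 1.6, 5.0),
                             slices_per_station = 50,
                             b_values = c(50, 900),
                             noise_sigma = 0,
                             seed = 1,
                             nominal_threshold = 41,
                             overlap = c("nest", "error")) {
  overlap <- match.arg(overlap)
  stopifnot(noise_sigma >= 0, length(b_values) >= 2,
            dim[3] %% slices_per_station == 0)
  dim <- as.integer(dim)
  set.seed(as.integer(seed))

  is_bg <- vapply(tissues, function(t) t$shape == "everywhere", logical(1))
  assign_id <- array(0L, dim = dim)
  for (i in seq_along(tissues)) {
    member <- tissue_member(tissues[[i]], dim)
    if (overlap == "error" && !is_bg[i]) {
      prev <- assign_id[member]
      if (any(prev > 0L & !is_bg[pmax(prev, 1L)])) {
        stop("ambiguous tissue assignment: overlapping tissue primitives",
             call. = FALSE)
      }
    }
    assign_id[member] <- i
  }

  s0 <- array(0, dim = dim)
  adc_true <- array(0, dim = dim)
  for (i in seq_along(tissues)) {
    sp <- tissues[[i]]
    idx <- which(assign_id == i)
    if (length(idx) == 0) next
    s0[idx] <- sp$S0
    lo <- max(0, sp$adc_band[1])
    adc_true[idx] <- rtnorm(length(idx), sp$adc_mean, sp$adc_sd,
                            lo, sp$adc_band[2])
  }

  geom <- vol_geometry(spacing, dim)
  b_values <- sort(b_values)
  signals <- lapply(b_values, function(b) {
    s <- s0 * exp(-b * adc_true * 1e-6)
    if (noise_sigma > 0) {
      e1 <- array(stats::rnorm(length(s), 0, noise_sigma), dim = dim)
      e2 <- array(stats::rnorm(length(s), 0, noise_sigma), dim = dim)
      s <- sqrt((s + e1)^2 + e2^2)
    }
    s
  })
  names(signals) <- as.character(b_values)

  n_st <- dim[3] %/% slices_per_station
  stations <- lapply(seq_len(n_st), function(st) {
    zr <- ((st - 1) * slices_per_station + 1):(st * slices_per_station)
    g <- vol_geometry(spacing, c(dim[1:2], slices_per_station),
                      origin = c(0, 0, (st - 1) * slices_per_station * spacing[3]))
    dwi_station(lapply(signals, function(a) a[, , zr, drop = FALSE]),
                g, station_index = st)
  })

  labels <- vapply(tissues, function(t) t$label, character(1))
  masks <- lapply(unique(labels), function(lb) {
    mask3d(array(assign_id %in% which(labels == lb), dim = dim), geom)
  })
  names(masks) <- unique(labels)

  vox_ml <- voxel_volume(geom) / 1000
  features <- dplyr::bind_rows(lapply(
    setdiff(unique(labels), "background"), function(lb) {
      idx <- masks[[lb]]$voxels
      dplyr::mutate(
        feature_row(adc_true[idx], sum(idx), vox_ml),
        class = lb, .before = 1)
    }))

  cuts <- Filter(Negate(is.null), lapply(tissues, confounder_cut))

  truth <- structure(
    list(tissues = tissues, masks = masks, adc_true = adc_true, s0 = s0,
         features = features, confounder_cuts = cuts,
         nominal_threshold = nominal_threshold, geometry = geom,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_truth"
  )
  structure(list(study = dwi_study(stations), truth = truth),
            class = "wb_phantom")
}

#' @export
print.wb_phantom <- function(x, ...) {
  cat("<wb_phantom>\n")
  print(x$study)
  cat(sprintf("  truth: %s; noise sigma %g, seed %d\n",
              paste(names(x$truth$masks), collapse = ", "),
              x$truth$noise_sigma, x$truth$seed))
  invisible(x)
}

#' Observer behaviour specification
#'
#' Parameterizes a simulated observer: a systematic threshold offset, random
#' threshold jitter across cases/sessions, the probability of missing each
#' confounder cut during editing, a Poisson rate of spurious extra edits, and
#' a per-session threshold drift. All randomness is seeded.
#'
#' @param threshold_bias Systematic threshold offset (intensity units).
#' @param threshold_jitter SD of the random threshold perturbation (>= 0).
#' @param edit_miss_prob Probability in `[0, 1]` of omitting each confounder
#'   cut.
#' @param edit_extra_rate Poisson mean of spurious single-slice edits.
#' @param session_effect SD of an additional per-session threshold drift.
#' @param seed Integer seed for this observer.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(threshold_bias = 0, threshold_jitter = 0,
                          edit_miss_prob = 0, edit_extra_rate = 0,
                          session_effect = 0, seed = 1) {
  stopifnot(threshold_jitter >= 0, session_effect >= 0,
            edit_miss_prob >= 0, edit_miss_prob <= 1, edit_extra_rate >= 0)
  structure(
    list(threshold_bias = threshold_bias, threshold_jitter = threshold_jitter,
         edit_miss_prob = edit_miss_prob, edit_extra_rate = edit_extra_rate,
         session_effect = session_effect, seed = as.integer(seed)),
    class = "observer_spec"
  )
}

#' Simulate one observer's bone segmentation
#'
#' Draws a threshold (nominal + bias + jitter + session drift), composes an
#' edit script that applies each of the phantom's confounder cuts with
#' probability `1 - edit_miss_prob` plus Poisson-many spurious single-slice
#' edits, and applies it to the thresholded computed image. Deterministic for
#' a fixed `(seed, session)`.
#'
#' @param truth A `phantom_truth` (from [generate_phantom()]).
#' @param computed A [computed_dwi()] on the phantom's fused grid.
#' @param obs An [observer_spec()].
#' @param session Reading-session index (1 or 2).
#' @return List: `threshold`, `script` (list of [ellipsoid_edit()]), and the
#'   edited bone `mask` ([mask3d()]).
#' @export
simulate_observer <- function(truth, computed, obs, session = 1L) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(computed, "computed_dwi"),
            inherits(obs, "observer_spec"))
  if (!geom_equal(truth$geometry, computed$geometry)) {
    stop_geometry_conflict("phantom truth and computed image")
  }
  set.seed((obs$seed %% 100000L) * 4096L + 31L * as.integer(session))
  thr <- truth$nominal_threshold + obs$threshold_bias +
    stats::rnorm(1, 0, obs$threshold_jitter)
  if (obs$session_effect > 0) thr <- thr + stats::rnorm(1, 0, obs$session_effect)
  thr <- max(0, thr)

  keep <- stats::runif(length(truth$confounder_cuts)) >= obs$edit_miss_prob
  script <- truth$confounder_cuts[keep]

  n_extra <- stats::rpois(1, obs$edit_extra_rate)
  d <- truth$geometry$dim
  for (i in seq_len(n_extra)) {
    ctr <- c(stats::runif(1, 1, d[1]), stats::runif(1, 1, d[2]), 0)
    sa <- c(stats::runif(1, 2, 6), stats::runif(1, 2, 6), 1)
    script[[length(script) + 1]] <- ellipsoid_edit(
      ctr, sa, mode = "single_slice",
      slice_index = sample.int(d[3], 1))
  }

  mask <- apply_edit_script(threshold_mask(computed, thr), script)
  list(threshold = thr, script = script, mask = mask)
}

#' Simulate a two-way subjects-by-raters measurement table
#'
#' y_ij = mu + s_i + r_j + e_ij with independent normal components of the
#' stated SDs; the standard test harness for the agreement statistics, whose
#' absolute-agreement ICC truth is
#' sigma_s^2 / (sigma_s^2 + sigma_r^2 + sigma_e^2).
#'
#' @param n Subjects (rows).
#' @param k Raters (columns).
#' @param sigma_subject,sigma_rater,sigma_error Component SDs (>= 0).
#' @param mu Grand mean.
#' @param seed Integer seed.
#' @return Numeric `n x k` matrix with rater column names.
#' @export
generate_measurement_matrix <- function(n, k, sigma_subject, sigma_rater,
                                        sigma_error, mu = 1000, seed = 1) {
  stopifnot(n >= 2, k >= 2, sigma_subject >= 0, sigma_rater >= 0,
            sigma_error >= 0)
  set.seed(as.integer(seed))
  s <- stats::rnorm(n, 0, sigma_subject)
  r <- stats::rnorm(k, 0, sigma_rater)
  e <- matrix(stats::rnorm(n * k, 0, sigma_error), n, k)
  m <- mu + outer(s, r, `+`) + e
  colnames(m) <- paste0("rater", seq_len(k))
  m
}

#' Export a phantom to disk
#'
#' Writes the study as NIfTI volumes with the sidecar b-value table (see
#' [write_dwi_series()]), each truth tissue mask as a binary NIfTI, and the
#' truth feature table as CSV.
#'
#' @param phantom A `wb_phantom`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
export_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "wb_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dwi_series(phantom$study, dir)
  for (lb in setdiff(names(phantom$truth$masks), "background")) {
    write_mask(phantom$truth$masks[[lb]],
               file.path(dir, sprintf("truth_mask_%s.nii", lb)))
  }
  utils::write.csv(phantom$truth$features,
                   file.path(dir, "truth_features.csv"), row.names = FALSE)
  invisible(dir)
}
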