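# Fixtures are generated in code; nothing is read from disk.

table1_spacing <- c(1.6, 1.6, 5.0)

# Two-b-value study with constant signal volumes.
const_study <- function(s_low, s_high, b = c(50, 900), dim = c(3, 3, 2),
                        spacing = table1_spacing) {
  g <- vol_geometry(spacing, dim)
  sig <- list(array(s_low, dim), array(s_high, dim))
  names(sig) <- as.character(b)
  dwi_study(list(dwi_station(sig, g)))
}

# Study from explicit per-b arrays.
array_study <- function(arrays_by_b, spacing = table1_spacing) {
  d <- dim(arrays_by_b[[1]])
  g <- vol_geometry(spacing, d)
  dwi_study(list(dwi_station(arrays_by_b, g)))
}

# ADC map holding given values everywhere, all valid.
const_adc <- function(values, dim, spacing = table1_spacing) {
  g <- vol_geometry(spacing, dim)
  v <- array(values, dim)
  adc_map(v, array(TRUE, dim), g, c(50, 900))
}

rand_mask <- function(dim, p = 0.3, spacing = table1_spacing) {
  g <- vol_geometry(spacing, dim)
  mask3d(array(stats::runif(prod(dim)) < p, dim), g)
}

# The default phantom is expensive enough to share across tests.
phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(noise_sigma = 0, seed = 1) {
  key <- sprintf("s%g_seed%d", noise_sigma, seed)
  if (is.null(phantom_cache[[key]])) {
    phantom_cache[[key]] <- generate_phantom(noise_sigma = noise_sigma,
                                             seed = seed)
  }
  phantom_cache[[key]]
}

cached_fused <- function(noise_sigma = 0, seed = 1) {
  key <- sprintf("f%g_seed%d", noise_sigma, seed)
  if (is.null(phantom_cache[[key]])) {
    ph <- cached_phantom(noise_sigma, seed)
    fused <- assemble_body_volume(ph$study)
    adc <- fit_adc(fused)
    computed <- synthesize_computed_b(fused, adc, 1000)
    phantom_cache[[key]] <- list(ph = ph, fused = fused, adc = adc,
                                 computed = computed)
  }
  phantom_cache[[key]]
}

# O(n^2) Kendall tau-b with tie correction, by direct pair counting.
tau_b_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) sum(sapply(table(v), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}
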