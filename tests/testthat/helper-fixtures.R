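# Shared fixtures for the test suite. Everything is generated in code,
# seeded, and kept small: full-scale runs live in test-acceptance.R only.

# a small cohort that is still long enough for the delta-band FIR
small_cohort <- function(n_per_class = 2, duration_s = 8, seed = 42,
                         effect_size = 1) {
  generate_cohort(cohort_spec(n_per_class = n_per_class,
                              duration_s = duration_s, seed = seed,
                              effect_size = effect_size))
}

# a fast feature spec for short fixtures
fast_fspec <- function(analysis_seconds = Inf, ...) {
  feature_spec(sampen_max_n = 500, specent_nperseg = 256,
               analysis_seconds = analysis_seconds, ...)
}

# independent O(N^2) sample-entropy oracle: direct double loop over
# templates, Chebyshev distance, self-matches included
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  M <- n - m
  A <- 0L
  B <- 0L
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  -log(A / B)
}

# FFT peak location of a signal, in cycles/sample (spectral oracle)
fft_peak <- function(x) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))[seq_len(n %/% 2)]^2
  (which.max(p) - 1) / n
}

# power of x within [low, high) cycles/sample, from the periodogram
band_power <- function(x, low, high) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  sum(p[f >= low & f < high])
}

# ideal (brick-wall) narrow-band filter around f0, the oracle a single
# VMD mode of a pure tone must match
ideal_narrowband <- function(x, f0, half_width = 0.02) {
  n <- length(x)
  xf <- fft(x)
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  xf[abs(f - f0) > half_width] <- 0
  Re(fft(xf, inverse = TRUE)) / n
}

# a feature table built directly from a values matrix (bypasses signal
# processing; for classifier and selection tests)
toy_table <- function(values, labels, crs_r = NULL, gcs = NULL,
                      approach = "raw") {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(
    list(values = values, feature_names = colnames(values),
         labels = labels,
         subject_ids = paste0("s", seq_len(nrow(values))),
         crs_r = if (is.null(crs_r)) rep(NA_real_, nrow(values)) else crs_r,
         gcs = if (is.null(gcs)) rep(NA_real_, nrow(values)) else gcs,
         approach = approach),
    class = "feature_table"
  )
}
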