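#' Specification of a synthetic disorders-of-consciousness cohort
#'
#' Describes the stochastic model behind [generate_cohort()]: three classes
#' (coma, UWS, MCS) of 17-channel EEG-like recordings built from
#' \itemize{
#'   \item a 1/f ("pink") background with per-subject lognormal amplitude
#'     jitter,
#'   \item per-band narrow-band oscillations: band-limited noise carriers
#'     about 1.5 Hz wide, centered at a subject-specific peak frequency
#'     inside each canonical band (individual peak frequencies are a
#'     robust feature of real EEG), mixed at class-specific band-power
#'     fractions, with the posterior channels given extra alpha weight.
#'     Peak positions carry the classic spectral-slowing gradient: within
#'     each band the peak sits lower for coma and higher for MCS
#'     (`peak_position`), so part of the class signal lives in frequency
#'     placement rather than band power,
#'   \item a broadband white component whose power, relative to the
#'     oscillatory power, increases coma < UWS < MCS -- the complexity
#'     gradient that makes MCS signals the most entropic,
#'   \item class-consistent CRS-R and GCS scores drawn uniformly from
#'     class ranges.
#' }
#' `effect_size` scales every between-class difference: 0 collapses all
#' classes onto the cohort-average spectral profile (an exchangeable null),
#' 1 gives the stated class profiles.
#'
#' @param n_per_class Subjects per class (default 15, a 45-subject cohort).
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param effect_size Non-negative scale on all between-class differences.
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @param artifact_rate Blink artifacts per minute (frontal-weighted
#'   low-frequency transients); 0 disables.
#' @param subject_sigma Lognormal sigma of the per-subject jitter applied
#'   to the band-power fractions and the complexity ratio -- the
#'   inter-subject variability that keeps class profiles from being
#'   noise-free templates.
#' @param channel_sigma Lognormal sigma of the additional per-channel
#'   jitter of band fractions and broadband power (topographic
#'   variability).
#' @param channel_effect_range Range of the per-channel attenuation of
#'   the class effect: each channel draws a factor uniformly from this
#'   range and carries only that fraction of its subject's deviation from
#'   the cohort-mean profile (spatially heterogeneous pathology). Single-
#'   channel features then correlate only moderately with the clinical
#'   scores while the multichannel ensemble retains the class signal. Each subject additionally draws a 1/f
#'   background exponent (normal around 1, sd 0.2) and one peak frequency
#'   per band for its narrow-band carriers, mirroring the individual
#'   aperiodic-slope and peak-frequency variability of real EEG.
#' @param band_fractions 3 x 5 matrix of relative band powers (rows coma,
#'   UWS, MCS; columns delta..gamma), each row summing to 1.
#' @param complexity_ratio Named numeric: broadband-to-oscillation power
#'   ratio per class, increasing coma < UWS < MCS.
#' @param crsr_range,gcs_range 3 x 2 matrices of per-class score ranges
#'   (rows coma, UWS, MCS).
#' @param posterior_alpha_gain Alpha-band amplitude multiplier for the
#'   posterior channels (P3, Pz, P4, O1, O2).
#' @param peak_position Named numeric: fractional position of each class's
#'   carrier peak within a band (0 = lower edge, 1 = upper edge),
#'   increasing coma < UWS < MCS (spectral slowing in reverse); subjects
#'   jitter around their class value (sd 0.1).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 15, fs = 256, duration_s = 60,
                        effect_size = 1, seed = 1L, artifact_rate = 0,
                        subject_sigma = 0.5, channel_sigma = 0.4,
                        band_fractions = default_band_fractions(),
                        complexity_ratio = c(coma = 0.15, UWS = 0.45,
                                             MCS = 1.0),
                        crsr_range = rbind(coma = c(0, 2), UWS = c(3, 8),
                                           MCS = c(9, 20)),
                        gcs_range = rbind(coma = c(3, 7), UWS = c(6, 9),
                                          MCS = c(9, 12)),
                        posterior_alpha_gain = 1.5,
                        peak_position = c(coma = 0.3, UWS = 0.5,
                                          MCS = 0.7),
                        channel_effect_range = c(0.25, 1)) {
  if (effect_size < 0) stop("effect_size must be >= 0")
  stopifnot(n_per_class >= 1, fs > 0, duration_s > 0,
            nrow(band_fractions) == 3, ncol(band_fractions) == 5)
  if (any(abs(rowSums(band_fractions) - 1) > 1e-8))
    stop("band-power fractions must sum to 1 per class")
  if (!(complexity_ratio["coma"] < complexity_ratio["UWS"] &&
        complexity_ratio["UWS"] < complexity_ratio["MCS"]))
    stop("complexity ratio must increase coma < UWS < MCS")
  if (!(peak_position["coma"] <= peak_position["UWS"] &&
        peak_position["UWS"] <= peak_position["MCS"]))
    stop("peak positions must be non-decreasing coma <= UWS <= MCS")
  structure(
    list(n_per_class = as.integer(n_per_class), fs = fs,
         duration_s = duration_s, effect_size = effect_size,
         seed = as.integer(seed), artifact_rate = artifact_rate,
         subject_sigma = subject_sigma, channel_sigma = channel_sigma,
         band_fractions = band_fractions,
         complexity_ratio = complexity_ratio,
         crsr_range = crsr_range, gcs_range = gcs_range,
         posterior_alpha_gain = posterior_alpha_gain,
         peak_position = peak_position,
         channel_effect_range = channel_effect_range),
    class = "cohort_spec"
  )
}

#' Default class spectral profiles
#'
#' Relative band powers over delta/theta/alpha/beta/gamma for the three
#' classes: coma is delta-dominant with little alpha; MCS has a clear
#' alpha/beta presence; UWS is intermediate -- the graded profile reported
#' throughout the resting-state DOC literature.
#'
#' @return 3 x 5 matrix, rows coma/UWS/MCS, rows summing to 1.
#' @export
default_band_fractions <- function() {
  m <- rbind(
    coma = c(delta = 0.70, theta = 0.16, alpha = 0.05, beta = 0.05,
             gamma = 0.04),
    UWS = c(delta = 0.55, theta = 0.20, alpha = 0.12, beta = 0.08,
            gamma = 0.05),
    MCS = c(delta = 0.34, theta = 0.24, alpha = 0.24, beta = 0.12,
            gamma = 0.06)
  )
  m / rowSums(m)
}

# unit-variance 1/f^slope-power noise via frequency-domain shaping
pink_noise <- function(n, slope = 1) {
  white <- stats::rnorm(n)
  xf <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # two-sided frequency index
  xf <- xf / f^(slope / 2)
  xf[1] <- 0
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  x / stats::sd(x)
}

# unit-variance band-limited noise carrier (ideal spectral mask)
band_noise <- function(n, low_hz, high_hz, fs) {
  white <- stats::rnorm(n)
  xf <- stats::fft(white)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)             # fold to two-sided
  keep <- f >= low_hz & f <= high_hz
  xf[!keep] <- 0
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# gaussian-shaped low-frequency blink transient, ~0.4 s wide
blink_pulse <- function(n, center, fs, amp = 120) {
  t <- (seq_len(n) - center) / fs
  amp * exp(-t^2 / (2 * 0.12^2))
}

#' Generate a synthetic disorders-of-consciousness cohort
#'
#' Draws `3 * n_per_class` labeled recordings from the generative model in
#' [cohort_spec()]. Fully deterministic given the spec (including the
#' seed): identical specs give bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return List of [recording()] objects (coma subjects first, then UWS,
#'   then MCS).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- round(spec$fs * spec$duration_s)
  chans <- doc_channels()
  posterior <- c("P3", "Pz", "P4", "O1", "O2")
  frontal <- c("F3", "Fz", "F4", "F7", "F8")
  bands <- eeg_bands()
  e <- spec$effect_size

  mean_frac <- colMeans(spec$band_fractions)
  mean_rho <- mean(spec$complexity_ratio)

  withr_seed(spec$seed, {
    cohort <- list()
    sid <- 0L
    for (cls in c("coma", "UWS", "MCS")) {
      frac_e <- pmax(mean_frac + e * (spec$band_fractions[cls, ] -
                                        mean_frac), 0)
      frac_e <- frac_e / sum(frac_e)
      rho_e <- max(mean_rho + e * (spec$complexity_ratio[cls] - mean_rho),
                   1e-3)
      q_e <- mean(spec$peak_position) +
        e * (spec$peak_position[cls] - mean(spec$peak_position))
      for (s in seq_len(spec$n_per_class)) {
        sid <- sid + 1L
        jitter <- exp(stats::rnorm(1, 0, 0.2))
        # inter-subject variability: each subject perturbs the class
        # spectral profile and complexity ratio multiplicatively
        frac_s <- frac_e * exp(stats::rnorm(length(frac_e), 0,
                                            spec$subject_sigma))
        frac_s <- frac_s / sum(frac_s)
        rho_s <- rho_e * exp(stats::rnorm(1, 0, spec$subject_sigma))
        # subject-specific aperiodic slope and per-band peak frequencies
        slope_s <- min(max(stats::rnorm(1, 1, 0.2), 0.5), 1.5)
        bw <- bands$high_hz - bands$low_hz
        carrier_w <- pmax(1.5, 0.15 * bw)
        q_s <- pmin(pmax(stats::rnorm(nrow(bands), q_e, 0.1), 0.1), 0.9)
        fp_s <- bands$low_hz + q_s * bw
        data <- matrix(0, length(chans), n)
        for (ci in seq_along(chans)) {
          w <- rep(1, nrow(bands))
          names(w) <- bands$name
          if (chans[ci] %in% posterior)
            w["alpha"] <- spec$posterior_alpha_gain
          # spatially heterogeneous effect: this channel carries only a
          # random fraction of the subject's deviation from the cohort mean
          a_ch <- stats::runif(1, spec$channel_effect_range[1],
                               spec$channel_effect_range[2])
          frac_base <- mean_frac + a_ch * (frac_s - mean_frac)
          rho_base <- exp(log(mean_rho) + a_ch * (log(rho_s) -
                                                    log(mean_rho)))
          q_base <- mean(spec$peak_position) +
            a_ch * (q_s - mean(spec$peak_position))
          frac_ch <- pmax(frac_base, 1e-4) * w^2 *
            exp(stats::rnorm(length(frac_s), 0, spec$channel_sigma))
          frac_ch <- frac_ch / sum(frac_ch)
          rho_ch <- rho_base * exp(stats::rnorm(1, 0, spec$channel_sigma))
          q_ch <- pmin(pmax(q_base + stats::rnorm(nrow(bands), 0, 0.05),
                            0.05), 0.95)
          fp_ch <- bands$low_hz + q_ch * bw
          osc <- rep(0, n)
          for (b in seq_len(nrow(bands))) {
            lo <- max(fp_ch[b] - carrier_w[b] / 2, bands$low_hz[b])
            hi <- min(fp_ch[b] + carrier_w[b] / 2, bands$high_hz[b])
            osc <- osc + sqrt(frac_ch[b]) * band_noise(n, lo, hi, spec$fs)
          }
          x <- jitter * pink_noise(n, slope_s) + osc +
            sqrt(rho_ch) * stats::rnorm(n)
          data[ci, ] <- 20 * x
        }
        if (spec$artifact_rate > 0) {
          n_blinks <- stats::rpois(1, spec$artifact_rate *
                                     spec$duration_s / 60)
          if (n_blinks > 0) {
            centers <- stats::runif(n_blinks, 1, n)
            for (ctr in centers) {
              pulse <- blink_pulse(n, ctr, spec$fs)
              for (ch in frontal)
                data[match(ch, chans), ] <- data[match(ch, chans), ] + pulse
            }
          }
        }
        crs_r <- sample(seq.int(spec$crsr_range[cls, 1],
                                spec$crsr_range[cls, 2]), 1)
        gcs <- sample(seq.int(spec$gcs_range[cls, 1],
                              spec$gcs_range[cls, 2]), 1)
        cohort[[sid]] <- recording(
          data, fs = spec$fs, channel_names = chans,
          subject_id = sprintf("%s%02d", cls, s), label = cls,
          crs_r = crs_r, gcs = gcs)
      }
    }
    cohort
  })
}

#' Deterministic mixture of tones in noise
#'
#' Test fixture for the decomposition solver: a sum of cosines with seeded
#' random phases plus Gaussian noise.
#'
#' @param freqs_hz Tone frequencies, all below `fs / 2`.
#' @param amps Amplitudes, one per tone.
#' @param fs Sampling rate in Hz.
#' @param duration_s Duration in seconds.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Seed for phases and noise.
#' @param random_phase Use seeded random phases (default); `FALSE` gives
#'   cosine phase 0 for exactness checks.
#' @return Numeric signal of length `round(fs * duration_s)`.
#' @export
generate_tone_mixture <- function(freqs_hz, amps = rep(1, length(freqs_hz)),
                                  fs = 256, duration_s = 4, noise_sd = 0,
                                  seed = 1L, random_phase = TRUE) {
  if (any(freqs_hz >= fs / 2))
    stop("tone frequencies must be below the Nyquist frequency")
  stopifnot(length(amps) == length(freqs_hz))
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1) / fs
  withr_seed(seed, {
    phases <- if (random_phase) stats::runif(length(freqs_hz), 0, 2 * pi)
              else rep(0, length(freqs_hz))
    x <- rep(0, n)
    for (i in seq_along(freqs_hz))
      x <- x + amps[i] * cos(2 * pi * freqs_hz[i] * t + phases[i])
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    x
  })
}
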