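#' The 17-channel scalp montage used throughout the pipeline
#'
#' Subset of the 10-20 system retained for disorders-of-consciousness
#' analysis (frontal, central, temporal, parietal and occipital electrodes
#' available in every recording).
#'
#' @return Character vector of 17 channel labels.
#' @export
doc_channels <- function() {
  c("F3", "Fz", "F4", "F7", "F8", "Cz", "C3", "C4",
    "T3", "T4", "T5", "T6", "P3", "Pz", "P4", "O1", "O2")
}

#' Construct a multichannel EEG recording
#'
#' Container for one subject's EEG: a channels x samples matrix in
#' microvolts plus sampling rate, channel labels and (optionally) the
#' clinical annotation used downstream -- the consciousness category and
#' the CRS-R / GCS behavioral scores.
#'
#' @param data Numeric matrix, channels x samples, finite.
#' @param fs Sampling rate in Hz (default 256).
#' @param channel_names Labels, one per row of `data`.
#' @param subject_id Identifier string.
#' @param label One of `"coma"`, `"UWS"`, `"MCS"`, or `NA`.
#' @param crs_r Coma Recovery Scale-Revised total score (integer >= 0) or
#'   `NA`.
#' @param gcs Glasgow Coma Scale score (integer in 3..15) or `NA`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs = 256, channel_names = rownames(data),
                      subject_id = "s1", label = NA_character_,
                      crs_r = NA_integer_, gcs = NA_integer_) {
  data <- as.matrix(data)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names must have one entry per data row")
  if (!all(is.finite(data))) stop("recording data must be finite")
  stopifnot(fs > 0)
  if (!is.na(label) && !label %in% c("coma", "UWS", "MCS"))
    stop("label must be one of coma, UWS, MCS (or NA)")
  if (!is.na(crs_r) && crs_r < 0) stop("crs_r must be >= 0")
  if (!is.na(gcs) && (gcs < 3 || gcs > 15)) stop("gcs must be in [3, 15]")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         subject_id = as.character(subject_id), label = label,
         crs_r = crs_r, gcs = gcs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording %s: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    if (!is.na(x$label))
      sprintf("; label = %s, CRS-R = %s, GCS = %s", x$label, x$crs_r, x$gcs)
    else ""))
  invisible(x)
}

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' the referenced data have zero mean over channels at each time point.
#'
#' @param rec An [recording()] with at least 2 channels.
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2)
    stop("average referencing needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Default EEG frequency band table
#'
#' The five canonical bands: delta 0.5-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-40 Hz.
#'
#' @return Data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(0.5, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 40),
    stringsAsFactors = FALSE
  )
}

# Hamming-window FIR band-pass design (window method). Cutoffs sit at the
# band edges (-6 dB points); the order follows the Hamming transition-width
# rule order ~= 3.3 / (transition width / fs), with transition width
# min(2 Hz, lower band edge) so narrow low-frequency bands get the
# resolution they need. Returns an odd-length symmetric (type I) impulse
# response.
fir_bandpass_design <- function(low_hz, high_hz, fs, transition_hz = NULL) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  if (is.null(transition_hz)) transition_hz <- min(2, low_hz)
  order <- ceiling(3.3 / (transition_hz / fs))
  if (order %% 2 == 1) order <- order + 1
  m <- order
  n <- 0:m
  fc1 <- low_hz / fs
  fc2 <- high_hz / fs
  arg <- n - m / 2
  ideal <- ifelse(arg == 0, 2 * (fc2 - fc1),
                  (sin(2 * pi * fc2 * arg) - sin(2 * pi * fc1 * arg)) /
                    (pi * arg))
  h <- ideal * (0.54 - 0.46 * cos(2 * pi * n / m))
  # normalize unity gain at the band center
  f0 <- (fc1 + fc2) / 2
  gain <- abs(sum(h * exp(-2i * pi * f0 * n)))
  structure(list(h = h / gain, low_hz = low_hz, high_hz = high_hz, fs = fs,
                 transition_hz = transition_hz),
            class = "fir_filter")
}

#' Frequency response of a designed FIR filter
#'
#' @param filt A filter from the internal Hamming-window designer (as
#'   returned in the `filter` attribute of [bandpass()]).
#' @param freqs_hz Frequencies at which to evaluate the single-pass
#'   response.
#' @return Complex response values.
#' @keywords internal
fir_response <- function(filt, freqs_hz) {
  n <- seq_along(filt$h) - 1
  vapply(freqs_hz, function(f) {
    sum(filt$h * exp(-2i * pi * (f / filt$fs) * n))
  }, complex(1))
}

#' Minimum stopband attenuation of a band-pass design, in dB
#'
#' Measures the single-pass magnitude response of the Hamming-window FIR on
#' a dense grid and reports the worst-case stopband attenuation relative to
#' the passband peak. The transition band (width `transition_hz`) is
#' centered on each cutoff, so the stopband starts half a transition width
#' outside each band edge.
#'
#' @param low_hz,high_hz,fs Band edges and sampling rate.
#' @param transition_hz Transition width override (default: design rule).
#' @return Attenuation in dB (positive; ~53 for a Hamming design).
#' @export
stopband_attenuation_db <- function(low_hz, high_hz, fs,
                                    transition_hz = NULL) {
  filt <- fir_bandpass_design(low_hz, high_hz, fs, transition_hz)
  tw <- filt$transition_hz
  grid <- seq(0, fs / 2, length.out = 8192)
  mag <- abs(fir_response(filt, grid))
  pass <- grid >= low_hz + tw / 2 & grid <= high_hz - tw / 2
  stop_ <- grid <= max(low_hz - tw / 2, 0) | grid >= high_hz + tw / 2
  -20 * log10(max(mag[stop_]) / max(mag[pass]))
}

# Zero-phase band-pass of a single channel: forward-backward application of
# the symmetric FIR, realized in the frequency domain as multiplication by
# |H|^2 after mirror padding (the padding absorbs the circular wrap-around
# of length ntaps at each end).
zero_phase_filter <- function(x, filt) {
  n <- length(x)
  ntaps <- length(filt$h)
  if (ntaps > n)
    stop(sprintf(
      "signal too short for the designed filter (%d taps > %d samples); use a shorter filter (wider transition band) or a longer signal",
      ntaps, n))
  pad <- ntaps
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq.int(n - pad + 1L, n)]))
  np <- length(xp)
  nfft <- stats::nextn(np, 2)
  hp <- c(filt$h, rep(0, nfft - ntaps))
  xpp <- c(xp, rep(0, nfft - np))
  y <- Re(stats::fft(stats::fft(xpp) * Mod(stats::fft(hp))^2,
                     inverse = TRUE)) / nfft
  y[seq.int(pad + 1L, pad + n)]
}

#' Zero-phase FIR band-pass filter
#'
#' Filters every channel with a Hamming-window FIR band-pass applied
#' forward-backward, so the output has zero phase distortion (no lag) and
#' the single-pass stopband attenuation (about 53 dB for the Hamming
#' window) is applied twice. Signal length is preserved.
#'
#' @param rec An [recording()].
#' @param low_hz,high_hz Band edges, `0 < low < high < fs/2`.
#' @param transition_hz Optional transition-width override in Hz; default is
#'   `min(2, low_hz)`.
#' @return The filtered recording, with the filter design attached as
#'   attribute `"filter"`.
#' @export
bandpass <- function(rec, low_hz, high_hz, transition_hz = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  filt <- fir_bandpass_design(low_hz, high_hz, rec$fs, transition_hz)
  filtered <- t(apply(rec$data, 1, zero_phase_filter, filt = filt))
  rownames(filtered) <- rec$channel_names
  rec$data <- filtered
  attr(rec, "filter") <- filt
  rec
}

#' Decompose a recording into canonical frequency bands
#'
#' Applies one zero-phase Hamming-window FIR band-pass per band and returns
#' one recording per band, all with the shape of the input.
#'
#' @param rec An [recording()].
#' @param bands Band table as from [eeg_bands()].
#' @return Named list of filtered recordings, one per band.
#' @export
extract_bands <- function(rec, bands = eeg_bands()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(bands) || nrow(bands) == 0) stop("empty band table")
  out <- lapply(seq_len(nrow(bands)), function(i) {
    bandpass(rec, bands$low_hz[i], bands$high_hz[i])
  })
  names(out) <- bands$name
  out
}

#' Subset and reorder channels
#'
#' @param rec An [recording()].
#' @param wanted Channel labels to keep, in the desired order.
#' @return The recording restricted to `wanted`, in that order.
#' @export
select_channels <- function(rec, wanted = doc_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(wanted, rec$channel_names)
  if (length(missing))
    stop("channels not present in recording: ",
         paste(missing, collapse = ", "))
  idx <- match(wanted, rec$channel_names)
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_names <- rec$channel_names[idx]
  rec
}

#' Standard preprocessing: average reference then broadband band-pass
#'
#' Average-references the recording, band-passes it (default 0.1-45 Hz,
#' removing drift and line noise), and restricts it to the 17-channel
#' montage if those channels are present.
#'
#' @param rec An [recording()].
#' @param broadband Length-2 numeric, broadband edges in Hz.
#' @param channels Channel subset to retain (default [doc_channels()];
#'   `NULL` keeps all).
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, broadband = c(0.1, 45),
                                 channels = doc_channels()) {
  rec <- average_reference(rec)
  rec <- bandpass(rec, broadband[1], broadband[2])
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  rec
}
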