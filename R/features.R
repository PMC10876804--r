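#' Parameters of the four statistical features
#'
#' @param sampen_m Embedding (template) length for sample entropy.
#' @param sampen_r_factor Sample-entropy tolerance as a fraction of the
#'   component's standard deviation.
#' @param sampen_max_n Cap on the number of samples entering the O(N^2)
#'   sample-entropy count; longer components use their first
#'   `sampen_max_n` samples. 1000 points at 256 Hz (~4 s) is ample for a
#'   stable estimate at `m = 2` and keeps the quadratic count affordable
#'   across 17 channels x 5 components x 45 subjects.
#' @param specent_nperseg Segment length of the Welch averaged periodogram
#'   behind spectral entropy.
#' @param specent_normalized Divide the spectral entropy by the log of the
#'   bin count so it lies in \[0, 1\].
#' @param specent_window Taper for the Welch segments; `"rect"` is exact
#'   for bin-aligned test tones.
#' @param log_base Logarithm base for both entropies: `"e"` or `"2"`.
#' @param analysis_seconds Length of the analysis segment taken from the
#'   start of each recording before feature computation (`Inf` = whole
#'   recording).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(sampen_m = 2, sampen_r_factor = 0.2,
                         sampen_max_n = 1000, specent_nperseg = 512,
                         specent_normalized = TRUE,
                         specent_window = c("hamming", "rect"),
                         log_base = c("e", "2"),
                         analysis_seconds = 60) {
  specent_window <- match.arg(specent_window)
  log_base <- match.arg(log_base)
  stopifnot(sampen_m >= 1, sampen_r_factor > 0, sampen_max_n > 2,
            specent_nperseg >= 8, analysis_seconds > 0)
  structure(
    list(sampen_m = as.integer(sampen_m),
         sampen_r_factor = sampen_r_factor,
         sampen_max_n = as.integer(sampen_max_n),
         specent_nperseg = as.integer(specent_nperseg),
         specent_normalized = isTRUE(specent_normalized),
         specent_window = specent_window, log_base = log_base,
         analysis_seconds = analysis_seconds),
    class = "feature_spec"
  )
}

# Welch averaged periodogram: mean-detrended, tapered segments with 50%
# overlap, one-sided. Returns the power in each of nperseg/2 + 1 bins.
welch_psd <- function(x, nperseg = 512, window = "hamming") {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- if (window == "hamming")
    0.54 - 0.46 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))
  else rep(1, nperseg)
  nb <- nperseg %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[seq.int(s, s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg)[seq_len(nb)])^2
  }
  acc / length(starts)
}

#' Spectral entropy of a signal
#'
#' Shannon entropy of the normalized power spectral distribution: the Welch
#' power estimate is normalized to sum to one and
#' \eqn{E_S = -\sum_f P(f) \log P(f)} is computed over the non-zero bins.
#' With `specent_normalized = TRUE` the value is divided by the log of the
#' bin count, giving a value in \[0, 1\] (1 = flat, white-noise-like
#' spectrum; near 0 = a single dominant rhythm). A constant signal carries
#' no spectral power after detrending and returns 0 by convention.
#'
#' @param signal Numeric vector, at least `spec$specent_nperseg` samples
#'   (shorter inputs fall back to a single full-length segment).
#' @param spec A [feature_spec()].
#' @return Scalar entropy.
#' @export
spectral_entropy <- function(signal, spec = feature_spec()) {
  p <- welch_psd(signal, spec$specent_nperseg, spec$specent_window)
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p / tot
  logf <- if (spec$log_base == "2") log2 else log
  h <- -sum(p[p > 0] * logf(p[p > 0]))
  if (spec$specent_normalized) h <- h / logf(length(p))
  h
}

#' Sample entropy of a signal
#'
#' The negative log of the conditional probability that two subsequences
#' matching for `m` points (Chebyshev distance within tolerance `r`) still
#' match at point `m + 1`. Template counts include self-matches, so the
#' ratio is always defined and a constant series scores exactly 0. The
#' tolerance defaults to `sampen_r_factor` times the standard deviation of
#' the (truncated) signal unless an absolute tolerance is supplied.
#'
#' @param signal Numeric vector of length greater than `m + 1`. Only the
#'   first `spec$sampen_max_n` samples enter the quadratic count.
#' @param spec A [feature_spec()].
#' @param r Absolute tolerance overriding the sd-scaled default. A
#'   constant series scores 0 for any non-negative tolerance.
#' @return Scalar entropy (natural log by default; `Inf` if no template
#'   pair survives at length `m + 1`).
#' @export
sample_entropy <- function(signal, spec = feature_spec(), r = NULL) {
  m <- spec$sampen_m
  if (length(signal) <= m + 1) stop("signal too short for sample entropy")
  x <- signal[seq_len(min(length(signal), spec$sampen_max_n))]
  if (is.null(r)) {
    s <- stats::sd(x)
    r <- if (s > 0) spec$sampen_r_factor * s else 0
  }
  v <- sampen_count_cpp(as.numeric(x), m, r)
  if (spec$log_base == "2" && is.finite(v)) v / log(2) else v
}

#' Skewness (population third standardized moment)
#'
#' \eqn{E[(x - \mu)^3] / \sigma^3} with population (biased) moments. A
#' constant signal returns 0 by convention.
#'
#' @param signal Numeric vector.
#' @return Scalar skewness.
#' @export
skewness <- function(signal) {
  m2 <- mean((signal - mean(signal))^2)
  if (m2 == 0) return(0)
  mean((signal - mean(signal))^3) / m2^1.5
}

#' Pearson (non-excess) kurtosis
#'
#' \eqn{E[(x - \mu)^4] / (E[(x - \mu)^2])^2}; 3 for a Gaussian. A constant
#' signal has no defined kurtosis and returns `NA` (such degenerate
#' components are rejected by [extract_features()]).
#'
#' @param signal Numeric vector.
#' @return Scalar kurtosis, or `NA` for a constant input.
#' @export
kurtosis <- function(signal) {
  m2 <- mean((signal - mean(signal))^2)
  if (m2 == 0) return(NA_real_)
  mean((signal - mean(signal))^4) / m2^2
}

feature_funs <- function(spec) {
  list(
    specent = function(x) spectral_entropy(x, spec),
    sampen = function(x) sample_entropy(x, spec),
    skew = skewness,
    kurt = kurtosis
  )
}

#' Extract per-subject feature vectors under one signal representation
#'
#' Computes the four statistical features (spectral entropy, sample
#' entropy, skewness, kurtosis) for every channel component of every
#' recording, under one of three representations:
#' \describe{
#'   \item{raw}{each channel as-is: 17 x 4 = 68 features,}
#'   \item{bands}{each channel filtered into the five canonical bands:
#'     17 x 5 x 4 = 340 features,}
#'   \item{vmd}{the five variational modes of each channel (indexed `m1`
#'     to `mK` by ascending center frequency): 17 x 5 x 4 = 340 features.}
#' }
#' Feature columns are named `approach/channel/component/feature` and the
#' ordering is deterministic. Recordings are truncated to the first
#' `spec$analysis_seconds` before decomposition and feature computation.
#'
#' @param cohort List of [recording()] objects sharing channel set and
#'   sampling rate.
#' @param approach `"raw"`, `"bands"` or `"vmd"`.
#' @param spec A [feature_spec()].
#' @param vmd_cfg A [vmd_config()] (vmd approach only).
#' @param bands Band table (bands approach only).
#' @return An object of class `feature_table`: list with `values`
#'   (subjects x features matrix), `feature_names`, `labels`,
#'   `subject_ids`, `crs_r`, `gcs`, `approach`.
#' @export
extract_features <- function(cohort, approach = c("raw", "bands", "vmd"),
                             spec = feature_spec(), vmd_cfg = vmd_config(),
                             bands = eeg_bands()) {
  approach <- match.arg(approach)
  stopifnot(length(cohort) >= 1)
  chans <- cohort[[1]]$channel_names
  fs <- cohort[[1]]$fs
  for (rec in cohort) {
    if (!identical(rec$channel_names, chans))
      stop("all recordings must share the same channel set and order")
    if (rec$fs != fs) stop("all recordings must share the sampling rate")
  }
  funs <- feature_funs(spec)
  comp_names <- switch(approach,
    raw = "raw",
    bands = bands$name,
    vmd = paste0("m", seq_len(vmd_cfg$n_modes))
  )
  feature_names <- as.vector(vapply(chans, function(ch)
    as.vector(vapply(comp_names, function(cp)
      paste(approach, ch, cp, names(funs), sep = "/"),
      character(length(funs)))),
    character(length(comp_names) * length(funs))))

  n_keep <- function(rec) min(ncol(rec$data),
                              floor(spec$analysis_seconds * rec$fs))
  rows <- lapply(cohort, function(rec) {
    seg <- rec$data[, seq_len(n_keep(rec)), drop = FALSE]
    rec_seg <- recording(seg, fs = rec$fs, channel_names = rec$channel_names,
                         subject_id = rec$subject_id)
    comps <- switch(approach,
      raw = function(ch) list(raw = rec_seg$data[ch, ]),
      bands = local({
        per_band <- extract_bands(rec_seg, bands)
        function(ch) lapply(per_band, function(b) b$data[ch, ])
      }),
      vmd = function(ch) {
        ms <- vmd_decompose(rec_seg$data[ch, ], vmd_cfg)
        stats::setNames(
          lapply(seq_len(nrow(ms$modes)), function(i) ms$modes[i, ]),
          comp_names)
      }
    )
    unlist(lapply(chans, function(ch) {
      cl <- comps(ch)
      unlist(lapply(cl, function(x) vapply(funs, function(f) f(x), 0)))
    }), use.names = FALSE)
  })
  values <- do.call(rbind, rows)
  colnames(values) <- feature_names
  if (any(!is.finite(values)))
    stop("non-finite feature values (degenerate constant component?) in ",
         paste(unique(feature_names[colSums(!is.finite(values)) > 0]),
               collapse = ", "))
  structure(
    list(values = values, feature_names = feature_names,
         labels = vapply(cohort, function(r) r$label, ""),
         subject_ids = vapply(cohort, function(r) r$subject_id, ""),
         crs_r = vapply(cohort, function(r) as.numeric(r$crs_r), 0),
         gcs = vapply(cohort, function(r) as.numeric(r$gcs), 0),
         approach = approach),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table (%s approach): %d subjects x %d features\n",
              x$approach, nrow(x$values), ncol(x$values)))
  if (!all(is.na(x$labels)))
    print(table(x$labels))
  invisible(x)
}

#' Write a feature table as CSV
#'
#' First columns are `subject_id`, `label`, `crs_r`, `gcs`; remaining
#' columns are the named features.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject_id = table$subject_ids, label = table$labels,
                   crs_r = table$crs_r, gcs = table$gcs,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
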