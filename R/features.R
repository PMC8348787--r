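# The 43-feature window descriptor.
#
# Thirteen feature families over one window of N samples (N = 50 or 100 at
# 50 Hz): mean (3 acc axes + temperature), population standard deviation,
# pairwise cosine similarity between acc axes, gyroscope RMS, skewness,
# kurtosis, max, min, zero-crossing count, six FFT-magnitude features of
# the mean-removed acceleration magnitude, histogram entropy, grouped-data
# first quartile, and the absolute time difference between the maximum and
# minimum peak. Family widths: 4+3+3+3+3+3+3+3+3+6+3+3+3 = 43.
#
# Degenerate windows are legal (a subject laying still produces a constant
# signal); every family defines a finite value for them.

#' Feature-extraction specification
#'
#' Tunable parameters of the 43-feature extractor. Defaults follow the
#' package's canonical definitions; the `literal_*` switches reproduce the
#' printed-formula variants (skewness without the 1/N factor, entropy with
#' an extra 1/N factor) for cross-checking.
#'
#' @param entropy_bins number of equal-width histogram bins for the entropy
#'   features (default 16).
#' @param q1_bins number of equal-width classes for the grouped-data first
#'   quartile (default 10).
#' @param med_band,high_band half-open frequency bands (Hz, `(lo, hi]`)
#'   averaged for the `medf` and `highf` spectral features.
#' @param literal_skewness if `TRUE`, omit the 1/N normalisation from
#'   skewness (summed third standardised moment).
#' @param literal_entropy if `TRUE`, scale entropy by an extra 1/N.
#' @param peak_as_frequency if `TRUE`, report `peakf` as the frequency (Hz)
#'   of the largest spectral magnitude instead of the magnitude itself.
#' @return An object of class `mpar_feature_spec`; its `names` field is the
#'   canonical 43-name order of [feature_names()].
#' @export
feature_spec <- function(entropy_bins = 16L, q1_bins = 10L,
                         med_band = c(5, 15), high_band = c(15, 25),
                         literal_skewness = FALSE, literal_entropy = FALSE,
                         peak_as_frequency = FALSE) {
  stopifnot(entropy_bins >= 2, q1_bins >= 2,
            med_band[1] < med_band[2], high_band[1] < high_band[2])
  structure(
    list(names = feature_names(),
         entropy_bins = as.integer(entropy_bins),
         q1_bins = as.integer(q1_bins),
         med_band = med_band, high_band = high_band,
         literal_skewness = isTRUE(literal_skewness),
         literal_entropy = isTRUE(literal_entropy),
         peak_as_frequency = isTRUE(peak_as_frequency)),
    class = "mpar_feature_spec"
  )
}

#' Window mean
#'
#' Arithmetic mean `(1/N) * sum(S_i)` of one channel's window samples;
#' separates slow-moving from fast-moving activities when applied to the
#' accelerometer axes and carries the 1 Hz temperature level.
#'
#' @param samples numeric vector, length >= 1.
#' @return The mean.
#' @export
f_mean <- function(samples) {
  if (!length(samples)) stop("empty window", call. = FALSE)
  sum(samples) / length(samples)
}

#' Window standard deviation (population form)
#'
#' `sqrt((1/N) * sum((S_i - mu)^2))` — the population form with divisor N,
#' not the sample form with N-1.
#'
#' @param samples numeric vector, length >= 1.
#' @return The population standard deviation.
#' @export
f_std <- function(samples) {
  if (!length(samples)) stop("empty window", call. = FALSE)
  mu <- mean(samples)
  sqrt(sum((samples - mu)^2) / length(samples))
}

#' Cosine similarity between two axes
#'
#' `(a . b) / (||a|| ||b||)`, the cross-correlation of two accelerometer
#' axes in cosine form; distinguishes activities whose motion lives on
#' different axes. Returns 0 when either vector has zero norm (a fully
#' degenerate window).
#'
#' @param a,b numeric vectors of equal length.
#' @return Value in `[-1, 1]`.
#' @export
f_cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  # clamp against floating round-off at +/-1
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Root mean square of a gyroscope axis
#'
#' `sqrt((1/N) * sum(G_i^2))`; captures the amount of angular movement
#' along one gyroscope axis.
#'
#' @param samples numeric vector, length >= 1.
#' @return The RMS.
#' @export
f_rms <- function(samples) {
  if (!length(samples)) stop("empty window", call. = FALSE)
  sqrt(sum(samples^2) / length(samples))
}

#' Window skewness
#'
#' Third standardised moment `(1/N) * sum(((S_i - mu)/sigma)^3)` with the
#' population sigma; measures asymmetry of the in-window distribution.
#' A constant window (sigma = 0) returns 0. With `literal = TRUE` the 1/N
#' factor is omitted (summed form).
#'
#' @param samples numeric vector, length >= 2.
#' @param literal omit the 1/N normalisation.
#' @return The skewness.
#' @export
f_skewness <- function(samples, literal = FALSE) {
  stopifnot(length(samples) >= 2)
  mu <- mean(samples)
  sg <- sqrt(mean((samples - mu)^2))
  if (sg == 0) return(0)
  s <- sum(((samples - mu) / sg)^3)
  if (literal) s else s / length(samples)
}

#' Window kurtosis
#'
#' `sum((S_i - mu)^4) / (N * sigma^4)` with the population sigma — the
#' (non-excess) fourth standardised moment; measures tailedness. A constant
#' window returns 0.
#'
#' @param samples numeric vector, length >= 2.
#' @return The kurtosis.
#' @export
f_kurtosis <- function(samples) {
  stopifnot(length(samples) >= 2)
  mu <- mean(samples)
  sg2 <- mean((samples - mu)^2)
  if (sg2 == 0) return(0)
  sum((samples - mu)^4) / (length(samples) * sg2^2)
}

#' Window extrema
#'
#' @param samples numeric vector, length >= 1.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
f_minmax <- function(samples) {
  if (!length(samples)) stop("empty window", call. = FALSE)
  c(min = min(samples), max = max(samples))
}

#' Zero-crossing count
#'
#' Number of adjacent sample pairs with a strict sign change:
#' `(S_i < 0 & S_{i+1} > 0) | (S_i > 0 & S_{i+1} < 0)`. Samples exactly at
#' zero produce no crossing.
#'
#' @param samples numeric vector, length >= 2.
#' @return Non-negative integer count.
#' @export
f_zero_crossings <- function(samples) {
  stopifnot(length(samples) >= 2)
  a <- samples[-length(samples)]
  b <- samples[-1]
  sum((a < 0 & b > 0) | (a > 0 & b < 0))
}

#' Six FFT-magnitude features of the acceleration magnitude
#'
#' Computes the DFT `H(k) = sum_n x(n) exp(-2i pi k n / N)` of the
#' mean-removed acceleration magnitude `m_i = sqrt(ax^2 + ay^2 + az^2)` and
#' summarises the one-sided magnitude spectrum `|H(k)|, k = 1..floor(N/2)`
#' (bin k maps to `k * fs / N` Hz) as: `peakf` the largest magnitude,
#' `lowf1..lowf3` the magnitudes of the first three non-DC bins, `medf` the
#' mean magnitude over the mid band and `highf` over the high band
#' (defaults `(5, 15]` and `(15, 25]` Hz). Mean removal zeroes the DC term,
#' so a constant window scores 0 on all six.
#'
#' @param acc N x 3 matrix of accelerometer samples (columns x, y, z).
#' @param fs sampling rate in Hz.
#' @param spec a [feature_spec()] (band edges, `peak_as_frequency`).
#' @return Named numeric vector `peakf, lowf1, lowf2, lowf3, medf, highf`.
#' @export
f_fft_features <- function(acc, fs = 50, spec = feature_spec()) {
  acc <- as.matrix(acc)
  n <- nrow(acc)
  if (n < 4) stop("window too short for spectral features (N >= 4)", call. = FALSE)
  m <- sqrt(rowSums(acc^2))
  x <- m - mean(m)
  mags <- Mod(stats::fft(x))[2:(n %/% 2 + 1)]  # k = 1 .. floor(N/2)
  freqs <- seq_along(mags) * fs / n
  in_band <- function(band) freqs > band[1] & freqs <= band[2]
  peak <- if (spec$peak_as_frequency) freqs[which.max(mags)] else max(mags)
  band_mean <- function(sel) if (any(sel)) mean(mags[sel]) else 0
  c(peakf = peak,
    lowf1 = mags[1], lowf2 = mags[2], lowf3 = mags[3],
    medf = band_mean(in_band(spec$med_band)),
    highf = band_mean(in_band(spec$high_band)))
}

#' Histogram entropy of a window
#'
#' Shannon entropy `-sum(p_i * log2(p_i))` of the occupancy proportions of
#' a B-bin equal-width histogram over the window range (empty bins are
#' skipped). Separates static activities, whose samples concentrate in one
#' bin, from dynamic ones that spread across bins. A constant window (zero
#' range) returns 0. With `literal = TRUE` the result carries an extra 1/N
#' factor.
#'
#' @param samples numeric vector, length >= 1.
#' @param bins number of equal-width bins (default 16).
#' @param literal apply the extra 1/N scaling.
#' @return Non-negative entropy in bits.
#' @export
f_entropy <- function(samples, bins = 16L, literal = FALSE) {
  n <- length(samples)
  if (!n) stop("empty window", call. = FALSE)
  rng <- range(samples)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(samples, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  p <- tabulate(idx, nbins = bins) / n
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (literal) h / n else h
}

#' Grouped-data first quartile
#'
#' The first quartile estimated from a binned frequency table,
#' `Q1 = l + (h/f) * (N/4 - C)`: the window range is divided into B
#' equal-width classes; `l` is the lower bound of the class containing the
#' `ceiling(N/4)`-th ordered sample, `h` the class width, `f` that class's
#' frequency and `C` the cumulative frequency below it. A constant window
#' returns the constant.
#'
#' @param samples numeric vector, length >= 4.
#' @param bins number of equal-width classes (default 10).
#' @return The grouped-data Q1 estimate.
#' @export
f_quartile_q1 <- function(samples, bins = 10L) {
  n <- length(samples)
  stopifnot(n >= 4)
  rng <- range(samples)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(samples, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  cum <- cumsum(counts)
  r <- ceiling(n / 4)
  j <- which(cum >= r)[1]
  l <- breaks[j]
  h <- (rng[2] - rng[1]) / bins
  f <- counts[j]
  C <- if (j > 1) cum[j - 1] else 0
  l + (h / f) * (n / 4 - C)
}

#' Time between the maximum and minimum peak
#'
#' `|t(argmax) - t(argmin)|` in seconds, with ties on either extremum
#' resolved to the first occurrence. A constant window returns 0.
#'
#' @param samples numeric vector, length >= 1.
#' @param fs sampling rate in Hz.
#' @return Absolute time difference in seconds.
#' @export
f_peak_time_diff <- function(samples, fs = 50) {
  if (!length(samples)) stop("empty window", call. = FALSE)
  abs(which.max(samples) - which.min(samples)) / fs
}

#' Extract the 43-feature vector from one window
#'
#' Applies the thirteen feature families to the window's channels in the
#' canonical [feature_names()] order: means of the three accelerometer axes
#' and temperature; acc standard deviations; cosine similarity of the acc
#' axis pairs (x,y), (x,z), (y,z); gyroscope RMS per axis; acc skewness,
#' kurtosis, max, min and zero crossings per axis; the six spectral
#' features of the acceleration magnitude; and acc entropy, grouped first
#' quartile and peak-time difference per axis.
#'
#' @param window an `mpar_window` from [segment()].
#' @param spec a [feature_spec()].
#' @return Named numeric vector of length 43 with attributes
#'   `activity_label`, `subject_id` and `start_time`.
#' @export
extract_feature_vector <- function(window, spec = feature_spec()) {
  if (is.null(window$acc) || is.null(window$gyro) || is.null(window$temp)) {
    stop("window is missing a required channel", call. = FALSE)
  }
  acc <- window$acc
  gyr <- window$gyro
  fs <- window$fs
  col_stats <- function(m, fun) vapply(seq_len(ncol(m)), function(j) fun(m[, j]), 0)
  v <- c(
    col_stats(acc, f_mean), f_mean(window$temp),
    col_stats(acc, f_std),
    f_cosine_similarity(acc[, 1], acc[, 2]),
    f_cosine_similarity(acc[, 1], acc[, 3]),
    f_cosine_similarity(acc[, 2], acc[, 3]),
    col_stats(gyr, f_rms),
    col_stats(acc, function(s) f_skewness(s, literal = spec$literal_skewness)),
    col_stats(acc, f_kurtosis),
    col_stats(acc, function(s) f_minmax(s)[["max"]]),
    col_stats(acc, function(s) f_minmax(s)[["min"]]),
    col_stats(acc, f_zero_crossings),
    f_fft_features(acc, fs = fs, spec = spec),
    col_stats(acc, function(s) f_entropy(s, bins = spec$entropy_bins,
                                         literal = spec$literal_entropy)),
    col_stats(acc, function(s) f_quartile_q1(s, bins = spec$q1_bins)),
    col_stats(acc, function(s) f_peak_time_diff(s, fs = fs))
  )
  names(v) <- spec$names
  structure(v,
            activity_label = window$activity_label,
            subject_id = window$subject_id,
            start_time = window$start_time)
}

#' Extract a feature table from a sequence of windows
#'
#' Maps [extract_feature_vector()] over the windows, preserving window
#' order and carrying each window's subject id and activity label into the
#' two key columns.
#'
#' @param windows list of `mpar_window` objects (possibly from several
#'   recordings).
#' @param spec a [feature_spec()].
#' @return data.frame with columns `subject_id`, `activity_label` and the
#'   43 canonical feature columns; zero rows for an empty window list.
#' @export
extract_feature_table <- function(windows, spec = feature_spec()) {
  fn <- feature_names()
  if (!length(windows)) {
    out <- stats::setNames(
      as.data.frame(matrix(numeric(0), 0, 2 + length(fn))),
      c("subject_id", "activity_label", fn)
    )
    out$subject_id <- character(0)
    out$activity_label <- character(0)
    return(out)
  }
  mat <- t(vapply(windows, function(w) as.numeric(extract_feature_vector(w, spec)),
                  numeric(length(fn))))
  colnames(mat) <- fn
  cbind(
    data.frame(
      subject_id = vapply(windows, `[[`, "", "subject_id"),
      activity_label = vapply(windows, `[[`, "", "activity_label"),
      stringsAsFactors = FALSE
    ),
    as.data.frame(mat)
  )
}
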