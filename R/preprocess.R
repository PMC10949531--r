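#' Zero-phase Butterworth bandpass filter
#'
#' Bandpass-filters continuous multichannel data with a Butterworth design
#' applied forward and backward (zero phase, so ERP latencies are preserved;
#' the effective order is doubled). Typical ERP work bands are 1.0-12.5 Hz.
#'
#' @param x numeric matrix `[channels x samples]` (a vector is treated as
#'   one channel).
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, `(low, high)` cutoff frequencies in Hz.
#' @param order Butterworth design order (default 4, per filtering pass).
#' @return filtered matrix of the same shape.
#' @export
eeg_bandpass <- function(x, fs, band, order = 4) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("`band` must be (low, high) with 0 < low < high")
  if (band[2] >= fs / 2)
    stop_named("band_outside_nyquist", "upper band edge must be below fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  out <- t(apply(x, 1L, function(ch) signal::filtfilt(bf, ch)))
  if (vec) out[1L, ] else out
}

#' Resample continuous data
#'
#' Anti-aliased downsampling of each channel: a zero-phase low-pass
#' (Butterworth, cutoff at 0.45 of the target rate) removes content above
#' the new Nyquist frequency, and the filtered signal is evaluated at the
#' output sample times by cubic spline interpolation. In-band spectra are
#' preserved; the output length is `floor(N * fs_out / fs_in)` and output
#' sample `k` sits at time `(k-1)/fs_out`.
#'
#' @param x numeric matrix `[channels x samples]` or vector.
#' @param fs_in,fs_out input and output sampling rates in Hz (positive;
#'   `fs_out <= fs_in`).
#' @return resampled matrix (or vector).
#' @export
eeg_resample <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  if (fs_out > fs_in) stop("`fs_out` must not exceed `fs_in`")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n_out <- floor(ncol(x) * fs_out / fs_in)
  if (fs_out == fs_in) {
    out <- x[, seq_len(n_out), drop = FALSE]
  } else {
    bf <- signal::butter(8, 0.9 * fs_out / fs_in, type = "low")
    t_in <- (seq_len(ncol(x)) - 1) / fs_in
    t_out <- (seq_len(n_out) - 1) / fs_out
    out <- t(apply(x, 1L, function(ch) {
      mu <- mean(ch)  # filter the demeaned signal: smaller edge transients, exact DC
      lp <- signal::filtfilt(bf, ch - mu) + mu
      stats::spline(t_in, lp, xout = t_out)$y
    }))
    if (n_out == 1L) out <- matrix(t(out), nrow = nrow(x))
  }
  if (vec) out[1L, ] else out
}

# Convert a half-open [start, stop) second window to 0-based sample offsets.
window_to_samples <- function(window, fs) {
  i0 <- round_hafz(window[1] * fs)
  i1 <- round_hafz(window[2] * fs)
  c(i0, i1)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over a baseline window
#' (half-open `[start, stop)` in seconds relative to event onset; e.g. the
#' 116 ms interval before onset is `c(-0.116, 0)`).
#'
#' @param epochs an [epoch_array].
#' @param window length-2 numeric baseline window in seconds.
#' @return a baseline-corrected [epoch_array].
#' @export
baseline_correct <- function(epochs, window = c(-0.116, 0)) {
  m <- dim(epochs$data)[2]
  off <- window_to_samples(window - epochs$t0, epochs$fs)
  idx <- seq.int(off[1] + 1L, off[2])  # 1-based sample indices
  if (off[2] <= off[1] || any(idx < 1L) || any(idx > m))
    stop_named("empty_baseline_window",
               "baseline window is empty or outside the epoch after rounding")
  bl <- apply(epochs$data[, idx, , drop = FALSE], c(1L, 3L), mean)
  epochs$data <- sweep_baseline(epochs$data, matrix(bl, dim(epochs$data)[1]))
  epochs
}

sweep_baseline <- function(data, bl) {
  d <- dim(data)
  data - aperm(array(bl, c(d[1], d[3], d[2])), c(1L, 3L, 2L))
}

#' Extract epochs from a continuous recording
#'
#' Cuts fixed-length windows around event onsets. The window is half-open
#' `[start, stop)` in seconds relative to onset and is converted to samples
#' by rounding half away from zero, so a window `(0, 0.8)` at 50 Hz yields
#' 40 samples starting at the onset sample.
#'
#' @param continuous numeric matrix `[channels x samples]`.
#' @param fs sampling rate in Hz.
#' @param onsets integer vector of 1-based onset sample indices.
#' @param window length-2 numeric window in seconds relative to onset.
#' @param channel_names optional channel labels.
#' @return an [epoch_array] with `t0 = ` the (snapped) window start.
#' @export
extract_epochs <- function(continuous, fs, onsets, window,
                           channel_names = NULL) {
  if (is.null(dim(continuous))) continuous <- matrix(continuous, nrow = 1L)
  off <- window_to_samples(window, fs)
  m <- off[2] - off[1]
  if (m < 2L) stop("window too short after rounding to samples")
  N <- ncol(continuous)
  first <- onsets + off[1]
  last <- onsets + off[2] - 1L
  if (any(first < 1L) || any(last > N))
    stop_named("epoch_out_of_bounds",
               "an epoch window extends outside the recording")
  dat <- array(0, c(nrow(continuous), m, length(onsets)))
  for (e in seq_along(onsets))
    dat[, , e] <- continuous[, seq.int(first[e], last[e]), drop = FALSE]
  epoch_array(dat, fs, channel_names, t0 = off[1] / fs)
}
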