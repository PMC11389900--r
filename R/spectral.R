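## Single-trial Morlet time-frequency decomposition, decibel baseline
## normalization, and signal-to-noise estimation.

#' Spectral decomposition configuration
#'
#' Frequencies run 1-40 Hz in 1 Hz steps by default; the number of wavelet
#' cycles grows linearly from 2 at the lowest frequency to 10 at the highest
#' ("width" of the Morlet family, dimensionless); the output time grid is
#' decimated to 50 ms steps; the decibel baseline is the pre-event window
#' (-0.4, -0.1) s.
#'
#' @param freqs_hz analysis frequencies, strictly increasing, Hz
#' @param n_cycles_range (low, high) cycles at the lowest/highest frequency;
#'   interpolated linearly in frequency
#' @param t_step_s output time step, seconds
#' @param baseline_window_s decibel baseline window, seconds relative to lock
#' @return configuration list of class "spectralConfig"
#' @export
spectralConfig <- function(freqs_hz = 1:40, n_cycles_range = c(2, 10),
                           t_step_s = 0.05,
                           baseline_window_s = c(-0.4, -0.1)) {
  if (is.unsorted(freqs_hz, strictly = TRUE))
    stop("freqs_hz must be strictly increasing")
  n_cycles <- if (length(freqs_hz) == 1L) n_cycles_range[1] else
    n_cycles_range[1] + (n_cycles_range[2] - n_cycles_range[1]) *
      (freqs_hz - freqs_hz[1]) / (freqs_hz[length(freqs_hz)] - freqs_hz[1])
  if (any(n_cycles < 1)) stop("n_cycles must be >= 1 everywhere")
  cfg <- list(freqs_hz = freqs_hz, n_cycles = n_cycles, t_step_s = t_step_s,
              baseline_window_s = baseline_window_s)
  class(cfg) <- c("spectralConfig", "list")
  cfg
}

## Complex Morlet kernel at frequency f with n cycles, sampled at sfreq.
## Gaussian SD sigma_t = n / (2 pi f); support truncated at +-3 sigma_t; the
## Gaussian envelope is normalized to unit area so a unit-amplitude tone
## yields |conv| ~ 0.5 at its own frequency.
morletKernel <- function(f, n_cycles, sfreq) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3 * sigma_t * sfreq)
  t <- (-half:half) / sfreq
  exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2)) /
    (sigma_t * sqrt(2 * pi) * sfreq)
}

#' Single-trial Morlet time-frequency decomposition
#'
#' Convolves every trial and channel with a complex Morlet wavelet per
#' frequency (frequency-domain convolution with zero padding) and returns
#' squared magnitude, decimated to the configured output time grid. Output
#' samples within half the wavelet support of either epoch edge are NA
#' (edge-invalid) and are excluded from any window average downstream.
#'
#' @param epochs an [EEGEpochs-class]
#' @param cfg a [spectralConfig()]
#' @return raw-power [TrialTFR-class], trials x channels x freqs x times
#' @export
morletTFR <- function(epochs, cfg = spectralConfig()) {
  d <- epochsData(epochs)
  sf <- samplingRate(epochs)
  ns <- dim(d)[3]
  t_all <- epochTimes(epochs)
  f_lo <- cfg$freqs_hz[1]
  min_len <- 2 * ceiling(3 * (cfg$n_cycles[1] / (2 * pi * f_lo)) * sf) + 1L
  if (ns < min_len)
    stop("epoch too short for the lowest frequency (", f_lo, " Hz): need >= ",
         min_len, " samples, have ", ns)

  # output grid: multiples of t_step within the epoch, anchored at t = 0
  steps <- seq(ceiling(t_all[1] / cfg$t_step_s),
               floor(t_all[ns] / cfg$t_step_s))
  out_times <- steps * cfg$t_step_s
  out_idx <- round((out_times - t_all[1]) * sf) + 1L

  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_f <- length(cfg$freqs_hz)
  # signal matrix: samples x (trial*channel), FFT once
  sig <- matrix(aperm(d, c(3, 1, 2)), nrow = ns)
  power <- array(NA_real_, c(n_tr, n_ch, n_f, length(out_times)))

  for (k in seq_len(n_f)) {
    w <- morletKernel(cfg$freqs_hz[k], cfg$n_cycles[k], sf)
    half <- (length(w) - 1L) %/% 2L
    nfft <- stats::nextn(ns + length(w) - 1L, 2)
    wf <- fft(c(w, rep(0, nfft - length(w))))
    sf_mat <- stats::mvfft(rbind(sig, matrix(0, nfft - ns, ncol(sig))))
    conv <- stats::mvfft(sf_mat * wf, inverse = TRUE) / nfft
    # 'same' alignment: sample s of the signal is row s + half of the full conv
    center <- conv[half + seq_len(ns), , drop = FALSE]
    pw <- Mod(center)^2
    valid <- out_idx > half & out_idx <= ns - half
    if (any(valid)) {
      sel <- pw[out_idx[valid], , drop = FALSE]
      block <- array(NA_real_, c(length(out_idx), n_tr, n_ch))
      block[valid, , ] <- array(sel, c(sum(valid), n_tr, n_ch))
      power[, , k, ] <- aperm(block, c(2, 3, 1))
    }
  }
  newTFR(power, cfg$freqs_hz, out_times, "raw_power", lockType(epochs),
         channelLabels(epochs), trialIds(epochs))
}

windowIndices <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (!length(idx)) stop("window [", window[1], ", ", window[2],
                         "] selects no time bins")
  idx
}

#' Decibel baseline normalization
#'
#' `dB(trial, ch, f, t) = 10 * log10(power / mean baseline power)` where the
#' baseline mean is taken over the baseline window of the SAME trial, channel
#' and frequency (per-trial normalization).
#'
#' @param tfr raw-power [TrialTFR-class]
#' @param baseline_window (start, end) seconds relative to the lock event
#' @param on_invalid what to do with frequencies whose baseline window
#'   contains edge-invalid (NA) samples: "error" (default) or "drop" them
#'   from the output
#' @return dB-units [TrialTFR-class]
#' @export
dbNormalize <- function(tfr, baseline_window = c(-0.4, -0.1),
                        on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (tfrUnits(tfr) != "raw_power") stop("tfr is already normalized")
  p <- tfrPower(tfr)
  bidx <- windowIndices(tfrTimes(tfr), baseline_window)
  bl <- p[, , , bidx, drop = FALSE]
  bad_f <- which(apply(is.na(bl), 3L, any))
  if (length(bad_f)) {
    if (on_invalid == "error")
      stop("baseline window is edge-invalid at frequencies: ",
           paste(tfrFreqs(tfr)[bad_f], collapse = ", "),
           " Hz (use on_invalid = \"drop\" or longer epochs)")
    keep <- setdiff(seq_along(tfrFreqs(tfr)), bad_f)
    if (!length(keep)) stop("no frequency has a clean baseline")
    p <- p[, , keep, , drop = FALSE]
    bl <- bl[, , keep, , drop = FALSE]
    freqs <- tfrFreqs(tfr)[keep]
  } else freqs <- tfrFreqs(tfr)
  bmean <- array(rowMeans(matrix(bl, ncol = dim(bl)[4])), dim(bl)[1:3])
  if (any(bmean == 0)) stop("zero baseline mean power")
  db <- 10 * log10(sweep(p, c(1, 2, 3), bmean, "/"))
  newTFR(db, freqs, tfrTimes(tfr), "dB", lockType(tfr), channelLabels(tfr),
         trialIds(tfr))
}

#' Signal-to-noise ratio of trial-averaged power
#'
#' Per channel and frequency: the mean over trials and window time bins of
#' raw power, divided by the standard error of the trial mean over the window
#' (cross-trial SD of window-averaged power / sqrt(n trials)). Edge-invalid
#' bins are excluded from the window average.
#'
#' @param tfr raw-power [TrialTFR-class]
#' @param window_s averaging window, seconds relative to the lock event
#' @return channels x freqs matrix of SNR values
#' @export
computeSNR <- function(tfr, window_s = c(0, 4)) {
  if (nTrials(tfr) < 2L) stop("need >= 2 trials")
  p <- tfrPower(tfr)
  widx <- windowIndices(tfrTimes(tfr), window_s)
  win <- p[, , , widx, drop = FALSE]
  # per-trial window mean, trials x channels x freqs
  tm <- array(rowMeans(matrix(win, ncol = dim(win)[4]), na.rm = TRUE),
              dim(win)[1:3])
  if (any(!is.finite(tm))) stop("window is entirely edge-invalid somewhere")
  n_tr <- dim(tm)[1]
  m <- matrix(tm, nrow = n_tr)
  mu <- colMeans(m)
  se <- sqrt(colSums((m - rep(mu, each = n_tr))^2) / (n_tr - 1)) / sqrt(n_tr)
  mu <- matrix(mu, dim(tm)[2], dim(tm)[3])
  se <- matrix(se, dim(tm)[2], dim(tm)[3])
  if (any(se == 0)) stop("zero cross-trial SD: SNR undefined")
  out <- mu / se
  dimnames(out) <- list(channelLabels(tfr), tfrFreqs(tfr))
  out
}

#' Frequencies of a named band
#'
#' @param band band name in the band definition list
#' @param band_defs named list of (low, high) edges; defaults to the
#'   package's band set (delta 1-3, theta 4-7, alpha 8-14, beta 15-25,
#'   gamma 26-40 Hz)
#' @return two-element (low, high) numeric
#' @export
bandEdges <- function(band, band_defs = synthParams()$band_defs) {
  if (!band %in% names(band_defs)) stop("unknown band: ", band)
  band_defs[[band]]
}
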