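## The core statistic: cross-trial relative variance of single-trial power,
## with band/window/cluster aggregation, within-trial variability, and the
## median-split diagnostic. Sample variance (ddof 1) throughout; log base 10
## for the ratio, consistent with the decibel convention of the pipeline.

#' Cross-trial relative variance
#'
#' For every channel, frequency and time bin, the across-trial variance of
#' single-trial power is expressed relative to the mean across-trial variance
#' over a pre-event baseline window:
#' `relvar(ch, f, t) = log10( Var_trials(P(., ch, f, t)) /
#' mean_{t_b in baseline} Var_trials(P(., ch, f, t_b)) )`.
#' By default the statistic is computed on dB-normalized power; raw power is
#' accepted for sensitivity analyses. The ratio is exactly invariant to
#' global rescaling of power.
#'
#' @param tfr a [TrialTFR-class] (dB by convention; raw accepted)
#' @param baseline_window (start, end) seconds relative to the lock event
#' @return a [VariabilityMap-class]
#' @export
relativeVariance <- function(tfr, baseline_window = c(-0.4, -0.1)) {
  if (nTrials(tfr) < 2L) stop("need >= 2 trials to estimate variance")
  p <- tfrPower(tfr)
  n <- dim(p)[1]
  m <- matrix(p, nrow = n)                  # trials x (ch*f*t)
  mu <- colMeans(m)
  v <- array(colSums((m - rep(mu, each = n))^2) / (n - 1), dim(p)[2:4])
  bidx <- windowIndices(tfrTimes(tfr), baseline_window)
  bvar <- apply(v[, , bidx, drop = FALSE], c(1, 2), mean)
  if (any(bvar == 0, na.rm = TRUE)) stop("zero baseline variance")
  rel <- log10(sweep(v, c(1, 2), bvar, "/"))
  new("VariabilityMap", relvar = rel, channels = channelLabels(tfr),
      freqs = tfrFreqs(tfr), times = tfrTimes(tfr),
      nTrials = nTrials(tfr), baselineWindow = as.numeric(baseline_window),
      sourceUnits = tfrUnits(tfr))
}

#' Aggregate a variability map over band, window and channel cluster
#'
#' Averages over the band's frequency bins, then the window's time bins, then
#' the cluster's channels (channel average last, so the statistic is computed
#' per channel first and only then averaged within the cluster).
#'
#' @param map a [VariabilityMap-class]
#' @param band (low, high) Hz, e.g. `bandEdges("beta")`
#' @param window_s (start, end) seconds
#' @param cluster a [clusterSpec()] or character vector of channel labels
#' @return scalar aggregate, log10-ratio units
#' @export
aggregateVariability <- function(map, band, window_s, cluster) {
  channels <- if (is.list(cluster)) cluster$channels else cluster
  chi <- match(channels, channelLabels(map))
  if (anyNA(chi)) stop("cluster channels not in map: ",
                       paste(channels[is.na(chi)], collapse = ", "))
  fi <- which(tfrFreqs(map) >= band[1] & tfrFreqs(map) <= band[2])
  if (!length(fi)) stop("band selects no frequencies")
  ti <- windowIndices(tfrTimes(map), window_s)
  r <- relvarValues(map)[chi, fi, ti, drop = FALSE]
  if (all(is.na(r))) stop("selection is entirely NA")
  per_channel <- apply(r, 1L, mean, na.rm = TRUE)
  mean(per_channel)
}

#' Within-trial variability of band power
#'
#' Variance over time bins (sample variance, ddof 1) of band-averaged
#' normalized power within a window, per trial. Channels are averaged before
#' the time variance when more than one is selected.
#'
#' @param tfr dB-units [TrialTFR-class]
#' @param window_s (start, end) seconds
#' @param band (low, high) Hz; defaults to all frequencies in the object
#' @param channels channel subset; defaults to all
#' @return numeric vector, one variance per trial
#' @export
withinTrialVariability <- function(tfr, window_s, band = NULL,
                                   channels = NULL) {
  p <- tfrPower(tfr)
  ti <- windowIndices(tfrTimes(tfr), window_s)
  if (length(ti) < 2L) stop("window has fewer than 2 time bins")
  fi <- if (is.null(band)) seq_along(tfrFreqs(tfr)) else
    which(tfrFreqs(tfr) >= band[1] & tfrFreqs(tfr) <= band[2])
  chi <- if (is.null(channels)) seq_along(channelLabels(tfr)) else
    match(channels, channelLabels(tfr))
  sub <- p[, chi, fi, ti, drop = FALSE]
  series <- apply(sub, c(1, 4), mean, na.rm = TRUE)  # trials x times
  apply(series, 1L, var)
}

#' Median-split variance diagnostic
#'
#' Splits per-trial window-averaged power at the participant's median
#' (strictly above the median goes to the high set) and returns the sample
#' variance of each subset. Under right-skewed (e.g. lognormal) power the
#' high half has the larger variance, tying mean power changes to
#' cross-trial variability changes.
#'
#' @param power_trials per-trial window-averaged power values
#' @return named list: var_high, var_low, n_high, n_low
#' @export
medianSplitVariance <- function(power_trials) {
  x <- power_trials[!is.na(power_trials)]
  if (length(x) < 4L) stop("need >= 4 trials")
  if (all(x == x[1])) stop("all values identical: split undefined")
  med <- median(x)
  hi <- x[x > med]
  lo <- x[x <= med]
  if (length(hi) < 2L || length(lo) < 2L)
    stop("degenerate split: a subset has fewer than 2 trials")
  list(var_high = var(hi), var_low = var(lo),
       n_high = length(hi), n_low = length(lo))
}

#' Per-trial band power in a window
#'
#' Mean over band frequencies, window time bins and (optionally) channels of
#' single-trial power -- the trial-wise quantity used by the lagged
#' single-trial models.
#'
#' @param tfr a [TrialTFR-class]
#' @param band (low, high) Hz
#' @param window_s (start, end) seconds
#' @param channels channel labels; defaults to all
#' @return numeric vector, one value per trial, named by trial id
#' @export
trialBandPower <- function(tfr, band, window_s, channels = NULL) {
  p <- tfrPower(tfr)
  fi <- which(tfrFreqs(tfr) >= band[1] & tfrFreqs(tfr) <= band[2])
  if (!length(fi)) stop("band selects no frequencies")
  ti <- windowIndices(tfrTimes(tfr), window_s)
  chi <- if (is.null(channels)) seq_along(channelLabels(tfr)) else
    match(channels, channelLabels(tfr))
  if (anyNA(chi)) stop("unknown channels requested")
  sub <- p[, chi, fi, ti, drop = FALSE]
  out <- rowMeans(matrix(sub, nrow = dim(sub)[1]), na.rm = TRUE)
  names(out) <- trialIds(tfr)
  out
}
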