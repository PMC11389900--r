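## Trial-level cleaning: threshold / improbability / kurtosis rejection,
## reaction-time filtering, and phase-locked (evoked) subtraction.

newRejectionReport <- function(trial_ids, reasons) {
  kept <- lengths(reasons) == 0L
  rep <- list(trial_id = trial_ids, kept = kept, reasons = reasons,
              fraction_kept = mean(kept))
  class(rep) <- "rejectionReport"
  rep
}

#' @export
print.rejectionReport <- function(x, ...) {
  cat(sprintf("rejectionReport: %d/%d trials kept (%.1f%%)\n",
              sum(x$kept), length(x$kept), 100 * x$fraction_kept))
  tab <- table(unlist(x$reasons))
  if (length(tab)) for (r in names(tab))
    cat(sprintf("  %-14s %d\n", r, tab[[r]]))
  invisible(x)
}

mergeReports <- function(a, b) {
  stopifnot(identical(a$trial_id, b$trial_id))
  reasons <- mapply(function(x, y) union(x, y), a$reasons, b$reasons,
                    SIMPLIFY = FALSE)
  newRejectionReport(a$trial_id, reasons)
}

#' Reject trials exceeding a voltage threshold
#'
#' A trial is flagged iff any sample on any channel exceeds `threshold_uv`
#' in absolute value.
#'
#' @param epochs an [EEGEpochs-class] in microvolts
#' @param threshold_uv rejection threshold, microvolts
#' @return a rejection report (trial_id, kept, reasons, fraction_kept)
#' @export
rejectAmplitude <- function(epochs, threshold_uv = 100) {
  d <- epochsData(epochs)
  if (any(!is.finite(d))) stop("epochs contain non-finite samples")
  bad <- apply(abs(d) > threshold_uv, 1L, any)
  newRejectionReport(trialIds(epochs),
                     lapply(bad, function(b) if (b) "amplitude" else character()))
}

sampleKurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}

#' Reject improbable and kurtotic trials
#'
#' Per channel, each trial receives (a) the negative log-likelihood of its
#' samples under the channel's kernel-smoothed empirical sample distribution
#' (an improbability index) and (b) its sample excess kurtosis. Both are
#' z-scored across trials per channel; a trial is flagged when |z| exceeds
#' `z_threshold` on either measure on any channel. This is a kernel-density
#' approximation of joint-probability artifact rejection; exact numerical
#' parity with other toolboxes is not a goal.
#'
#' @param epochs an [EEGEpochs-class]
#' @param z_threshold flagging threshold in SD units
#' @return rejection report with reasons "improbability" / "kurtosis"
#' @export
rejectImprobableKurtotic <- function(epochs, z_threshold = 8) {
  d <- epochsData(epochs)
  n <- dim(d)[1]
  if (n < 10L) stop("need at least 10 trials to estimate distributions")
  nch <- dim(d)[2]
  zsafe <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  flag_imp <- matrix(FALSE, n, nch)
  flag_kur <- matrix(FALSE, n, nch)
  for (ch in seq_len(nch)) {
    pooled <- as.vector(d[, ch, ])
    dens <- density(pooled, n = 512)
    logf <- function(x) {
      f <- stats::approx(dens$x, dens$y, xout = x, rule = 2)$y
      log(pmax(f, .Machine$double.xmin))
    }
    nll <- vapply(seq_len(n), function(i) -mean(logf(d[i, ch, ])), 0)
    kur <- vapply(seq_len(n), function(i) sampleKurtosis(d[i, ch, ]), 0)
    flag_imp[, ch] <- abs(zsafe(nll)) > z_threshold
    flag_kur[, ch] <- abs(zsafe(kur)) > z_threshold
  }
  reasons <- lapply(seq_len(n), function(i) {
    r <- character()
    if (any(flag_imp[i, ])) r <- c(r, "improbability")
    if (any(flag_kur[i, ])) r <- c(r, "kurtosis")
    r
  })
  newRejectionReport(trialIds(epochs), reasons)
}

#' Filter behavioral trials on reaction time
#'
#' Removes trials with RT slower than `max_rt_s` or farther than `sd_mult`
#' standard deviations from the participant's own mean RT. The mean and SD
#' are computed once on the participant's pre-filter data, over correct and
#' incorrect trials jointly; restriction to correct trials (for RT
#' averaging) is the consumer's job.
#'
#' @param behavior per-participant behavioral data.frame with an `rt_s`
#'   column
#' @param max_rt_s absolute slow-RT cutoff, seconds
#' @param sd_mult outlier cutoff in SD units
#' @return the filtered behavioral table; removed rows carry attribute
#'   "removed" (their trial_id and reason)
#' @export
filterRT <- function(behavior, max_rt_s = 5, sd_mult = 3) {
  if (nrow(behavior) == 0L) stop("empty behavioral table")
  if (any(behavior$rt_s <= 0)) stop("non-positive reaction times")
  m <- mean(behavior$rt_s)
  s <- sd(behavior$rt_s)
  slow <- behavior$rt_s > max_rt_s
  out <- if (is.na(s) || s == 0) rep(FALSE, nrow(behavior))
         else abs(behavior$rt_s - m) > sd_mult * s
  keep <- !(slow | out)
  res <- behavior[keep, , drop = FALSE]
  removed <- data.frame(
    trial_id = behavior$trial_id[!keep],
    reason = ifelse(slow[!keep], "rt_slow", "rt_outlier"))
  attr(res, "removed") <- removed
  res
}

#' Subtract phase-locked (evoked) activity
#'
#' For every condition (set size), subtracts the per-condition trial-average
#' waveform from each member trial, leaving only non-phase-locked activity.
#' After subtraction the per-condition trial average is exactly zero to
#' numerical tolerance.
#'
#' @param epochs an [EEGEpochs-class]
#' @param condition_labels per-trial condition (e.g. set size), length =
#'   number of trials
#' @return [EEGEpochs-class] with evoked components removed
#' @export
subtractERP <- function(epochs, condition_labels) {
  d <- epochsData(epochs)
  if (length(condition_labels) != dim(d)[1])
    stop("condition_labels must have one entry per trial")
  for (cond in unique(condition_labels)) {
    idx <- which(condition_labels == cond)
    if (length(idx) < 2L)
      stop("condition ", cond, " has fewer than 2 trials; ",
           "subtraction would zero the trial")
    avg <- colMeans(d[idx, , , drop = FALSE], dims = 1L)
    for (i in idx) d[i, , ] <- d[i, , ] - avg
  }
  newEpochs(d, epochs@sfreq, epochs@tmin, epochs@lock, epochs@channels,
            epochs@trialIds)
}

#' Subset epochs to kept trials
#'
#' @param epochs an [EEGEpochs-class]
#' @param report rejection report (or logical keep vector)
#' @return [EEGEpochs-class] restricted to kept trials
#' @export
dropRejected <- function(epochs, report) {
  keep <- if (is.list(report)) report$kept else report
  d <- epochsData(epochs)[keep, , , drop = FALSE]
  newEpochs(d, epochs@sfreq, epochs@tmin, epochs@lock, epochs@channels,
            trialIds(epochs)[keep])
}

#' Serialize a rejection report as tab-separated values
#'
#' @param report rejection report
#' @param path output path
#' @export
writeRejectionReport <- function(report, path) {
  df <- data.frame(trial_id = report$trial_id, kept = report$kept,
                   reasons = vapply(report$reasons, paste, "", collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
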