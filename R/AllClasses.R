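#' @import methods
#' @importFrom stats var sd median qlogis plogis rnorm runif rbinom rlnorm
#'   quantile fft t.test pt qt p.adjust complete.cases coef density lm
#'   setNames rgamma formula as.formula logLik anova vcov pchisq pnorm
#'   model.matrix
#' @importFrom utils read.delim write.table head combn modifyList read.table
NULL

## ---------------------------------------------------------------------------
## Central containers. Trial-resolved EEG objects are dense 3-D/4-D arrays;
## none of the genomic Bioconductor containers fit, so these are free-standing
## S4 classes with validity checks and accessors.
## ---------------------------------------------------------------------------

#' Task schedule for a delayed match-to-sample session
#'
#' Holds the experiment configuration, the ordered per-trial event table and
#' the seed it was generated from. Create with [generateSchedule()].
#'
#' @slot config validated configuration list, see [taskConfig()]
#' @slot trials data.frame with one row per trial (block_index,
#'   trial_index_global, set_size, is_match, stim_onsets_s, maintenance_onset_s,
#'   probe_onset_s, iti_s); onsets are seconds from first stimulus of the trial
#' @slot seed integer seed the schedule was drawn with
#' @export
setClass("TaskSchedule",
  representation(config = "list", trials = "data.frame", seed = "integer"))

setValidity("TaskSchedule", function(object) {
  tr <- object@trials
  cfg <- object@config
  msgs <- character()
  need <- c("block_index", "trial_index_global", "set_size", "is_match",
            "maintenance_onset_s", "probe_onset_s", "iti_s")
  if (!all(need %in% names(tr)))
    msgs <- c(msgs, paste("trials lacks columns:",
                          paste(setdiff(need, names(tr)), collapse = ", ")))
  else {
    if (nrow(tr) != cfg$n_blocks * cfg$trials_per_block)
      msgs <- c(msgs, "trial count != n_blocks * trials_per_block")
    if (any(duplicated(tr$trial_index_global)))
      msgs <- c(msgs, "duplicate trial_index_global")
  }
  if (length(msgs)) msgs else TRUE
})

#' Epoched multichannel EEG
#'
#' A trials x channels x samples voltage array (microvolts) with its sampling
#' rate, epoch time origin and lock event.
#'
#' @slot data numeric array, trials x channels x samples, microvolts
#' @slot sfreq sampling rate, Hz
#' @slot tmin epoch start in seconds relative to the lock event
#' @slot lock one of "stimulus", "maintenance", "response"
#' @slot channels channel labels (10-20 names)
#' @slot trialIds integer trial ids aligned to the generating [TaskSchedule]
#' @export
setClass("EEGEpochs",
  representation(data = "array", sfreq = "numeric", tmin = "numeric",
                 lock = "character", channels = "character",
                 trialIds = "integer"))

setValidity("EEGEpochs", function(object) {
  d <- object@data
  msgs <- character()
  if (length(dim(d)) != 3L)
    return("data must be a 3-D array (trials x channels x samples)")
  if (anyNA(d)) msgs <- c(msgs, "data contains NA")
  if (dim(d)[2] != length(object@channels))
    msgs <- c(msgs, "channel dimension does not match channel labels")
  if (dim(d)[1] != length(object@trialIds))
    msgs <- c(msgs, "trial dimension does not match trialIds")
  if (anyDuplicated(object@trialIds))
    msgs <- c(msgs, "trialIds must be unique")
  if (is.unsorted(object@trialIds))
    msgs <- c(msgs, "trialIds must be sorted")
  if (!object@lock %in% c("stimulus", "maintenance", "response"))
    msgs <- c(msgs, "unknown lock type")
  if (length(msgs)) msgs else TRUE
})

#' Single-trial time-frequency representation
#'
#' Trials x channels x frequencies x times power, either raw (units
#' "raw_power", squared microvolts) or decibel baseline-normalized
#' (units "dB"). Edge samples where the analysis wavelet was not fully
#' supported are NA.
#'
#' @slot power numeric 4-D array, trials x channels x freqs x times
#' @slot freqs frequencies, Hz
#' @slot times output time grid, seconds relative to the lock event
#' @slot units "raw_power" or "dB"
#' @slot lock lock event of the epochs the TFR was computed on
#' @slot channels channel labels
#' @slot trialIds trial ids
#' @export
setClass("TrialTFR",
  representation(power = "array", freqs = "numeric", times = "numeric",
                 units = "character", lock = "character",
                 channels = "character", trialIds = "integer"))

setValidity("TrialTFR", function(object) {
  p <- object@power
  msgs <- character()
  if (length(dim(p)) != 4L)
    return("power must be 4-D (trials x channels x freqs x times)")
  if (dim(p)[3] != length(object@freqs)) msgs <- c(msgs, "freq dim mismatch")
  if (dim(p)[4] != length(object@times)) msgs <- c(msgs, "time dim mismatch")
  if (dim(p)[2] != length(object@channels)) msgs <- c(msgs, "channel dim mismatch")
  if (dim(p)[1] != length(object@trialIds)) msgs <- c(msgs, "trial dim mismatch")
  if (!object@units %in% c("raw_power", "dB"))
    msgs <- c(msgs, "units must be raw_power or dB")
  if (object@units == "raw_power" && any(p < 0, na.rm = TRUE))
    msgs <- c(msgs, "raw power must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Cross-trial relative-variance map
#'
#' Channels x frequencies x times map of the cross-trial variance of
#' single-trial power expressed as a log10 ratio to the mean variance over a
#' pre-event baseline window. See [relativeVariance()].
#'
#' @slot relvar numeric 3-D array, channels x freqs x times (log10-ratio units)
#' @slot channels,freqs,times grid labels
#' @slot nTrials number of trials the variances were estimated from
#' @slot baselineWindow two-element window (s) the denominator was averaged over
#' @slot sourceUnits units of the power the map was computed on
#' @export
setClass("VariabilityMap",
  representation(relvar = "array", channels = "character", freqs = "numeric",
                 times = "numeric", nTrials = "integer",
                 baselineWindow = "numeric", sourceUnits = "character"))

setValidity("VariabilityMap", function(object) {
  r <- object@relvar
  if (length(dim(r)) != 3L) return("relvar must be 3-D")
  msgs <- character()
  if (dim(r)[1] != length(object@channels)) msgs <- c(msgs, "channel dim mismatch")
  if (dim(r)[2] != length(object@freqs)) msgs <- c(msgs, "freq dim mismatch")
  if (dim(r)[3] != length(object@times)) msgs <- c(msgs, "time dim mismatch")
  if (object@nTrials < 2L) msgs <- c(msgs, "nTrials must be >= 2")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Generics + accessors
## ---------------------------------------------------------------------------

#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @export
setGeneric("lockType", function(x) standardGeneric("lockType"))
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))
#' @export
setGeneric("epochsData", function(x) standardGeneric("epochsData"))
#' @export
setGeneric("tfrPower", function(x) standardGeneric("tfrPower"))
#' @export
setGeneric("tfrFreqs", function(x) standardGeneric("tfrFreqs"))
#' @export
setGeneric("tfrTimes", function(x) standardGeneric("tfrTimes"))
#' @export
setGeneric("tfrUnits", function(x) standardGeneric("tfrUnits"))
#' @export
setGeneric("relvarValues", function(x) standardGeneric("relvarValues"))
#' @export
setGeneric("scheduleTrials", function(x) standardGeneric("scheduleTrials"))
#' @export
setGeneric("scheduleConfig", function(x) standardGeneric("scheduleConfig"))

#' @describeIn TaskSchedule per-trial event table
#' @param x object
#' @export
setMethod("scheduleTrials", "TaskSchedule", function(x) x@trials)
#' @describeIn TaskSchedule configuration list
#' @export
setMethod("scheduleConfig", "TaskSchedule", function(x) x@config)
#' @describeIn TaskSchedule number of trials
#' @export
setMethod("nTrials", "TaskSchedule", function(x) nrow(x@trials))

#' @describeIn EEGEpochs number of trials
#' @param x object
#' @export
setMethod("nTrials", "EEGEpochs", function(x) dim(x@data)[1])
#' @describeIn EEGEpochs channel labels
#' @export
setMethod("channelLabels", "EEGEpochs", function(x) x@channels)
#' @describeIn EEGEpochs sampling rate (Hz)
#' @export
setMethod("samplingRate", "EEGEpochs", function(x) x@sfreq)
#' @describeIn EEGEpochs sample times (s) relative to the lock event
#' @export
setMethod("epochTimes", "EEGEpochs",
  function(x) x@tmin + (seq_len(dim(x@data)[3]) - 1L) / x@sfreq)
#' @describeIn EEGEpochs lock event
#' @export
setMethod("lockType", "EEGEpochs", function(x) x@lock)
#' @describeIn EEGEpochs trial ids
#' @export
setMethod("trialIds", "EEGEpochs", function(x) x@trialIds)
#' @describeIn EEGEpochs raw voltage array (trials x channels x samples)
#' @export
setMethod("epochsData", "EEGEpochs", function(x) x@data)

#' @describeIn TrialTFR number of trials
#' @param x object
#' @export
setMethod("nTrials", "TrialTFR", function(x) dim(x@power)[1])
#' @describeIn TrialTFR channel labels
#' @export
setMethod("channelLabels", "TrialTFR", function(x) x@channels)
#' @describeIn TrialTFR power array (trials x channels x freqs x times)
#' @export
setMethod("tfrPower", "TrialTFR", function(x) x@power)
#' @describeIn TrialTFR frequency grid (Hz)
#' @export
setMethod("tfrFreqs", "TrialTFR", function(x) x@freqs)
#' @describeIn TrialTFR output time grid (s)
#' @export
setMethod("tfrTimes", "TrialTFR", function(x) x@times)
#' @describeIn TrialTFR power units
#' @export
setMethod("tfrUnits", "TrialTFR", function(x) x@units)
#' @describeIn TrialTFR lock event
#' @export
setMethod("lockType", "TrialTFR", function(x) x@lock)
#' @describeIn TrialTFR trial ids
#' @export
setMethod("trialIds", "TrialTFR", function(x) x@trialIds)

#' @describeIn VariabilityMap relative-variance array (channels x freqs x times)
#' @param x object
#' @export
setMethod("relvarValues", "VariabilityMap", function(x) x@relvar)
#' @describeIn VariabilityMap channel labels
#' @export
setMethod("channelLabels", "VariabilityMap", function(x) x@channels)
#' @describeIn VariabilityMap frequency grid (Hz)
#' @export
setMethod("tfrFreqs", "VariabilityMap", function(x) x@freqs)
#' @describeIn VariabilityMap time grid (s)
#' @export
setMethod("tfrTimes", "VariabilityMap", function(x) x@times)

setMethod("show", "TaskSchedule", function(object) {
  cfg <- object@config
  cat("TaskSchedule:", nrow(object@trials), "trials in", cfg$n_blocks,
      "blocks of", cfg$trials_per_block, "\n")
  cat("  set sizes:", paste(cfg$set_sizes, collapse = ", "),
      "| seed:", object@seed, "\n")
})

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat("EEGEpochs:", d[1], "trials x", d[2], "channels x", d[3], "samples\n")
  cat(sprintf("  %g Hz, %s-locked, t = [%.3f, %.3f] s\n", object@sfreq,
              object@lock, object@tmin,
              object@tmin + (d[3] - 1) / object@sfreq))
})

setMethod("show", "TrialTFR", function(object) {
  d <- dim(object@power)
  cat("TrialTFR (", object@units, "): ", d[1], " trials x ", d[2],
      " channels x ", d[3], " freqs x ", d[4], " times\n", sep = "")
  cat(sprintf("  f = [%g, %g] Hz, t = [%.3f, %.3f] s, %s-locked\n",
              min(object@freqs), max(object@freqs), min(object@times),
              max(object@times), object@lock))
})

setMethod("show", "VariabilityMap", function(object) {
  d <- dim(object@relvar)
  cat("VariabilityMap:", d[1], "channels x", d[2], "freqs x", d[3], "times",
      sprintf("(n = %d trials, on %s)\n", object@nTrials, object@sourceUnits))
})

## internal constructors -----------------------------------------------------

newEpochs <- function(data, sfreq, tmin, lock, channels, trial_ids) {
  new("EEGEpochs", data = data, sfreq = sfreq, tmin = tmin, lock = lock,
      channels = channels, trialIds = as.integer(trial_ids))
}

newTFR <- function(power, freqs, times, units, lock, channels, trial_ids) {
  new("TrialTFR", power = power, freqs = freqs, times = times, units = units,
      lock = lock, channels = channels, trialIds = as.integer(trial_ids))
}
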