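## Delayed match-to-sample task schedule generation.

#' Task configuration
#'
#' Builds and validates the configuration of a delayed match-to-sample
#' working-memory session. The defaults are the study design this package
#' targets: 30 blocks of 24 trials (720 trials evenly divided among set sizes
#' 1, 2 and 4), 200 ms stimuli separated by a 1,000 ms ISI, a 3,000 ms
#' maintenance delay, a 200 ms probe, feedback 500 ms after the response for
#' 1,000 ms, and an inter-trial interval jittered uniformly between 1.2 and
#' 1.6 s. Probe matches occur with probability 0.5.
#'
#' @param n_blocks number of blocks
#' @param trials_per_block trials per block; must be divisible by the number
#'   of set sizes so each block is exactly balanced
#' @param set_sizes memory loads (items to remember)
#' @param stim_duration_s stimulus duration, seconds
#' @param isi_s interstimulus interval, seconds
#' @param delay_s maintenance delay between last stimulus offset + ISI and
#'   probe onset, seconds
#' @param probe_duration_s probe duration, seconds
#' @param feedback_delay_s response-to-feedback delay, seconds
#' @param feedback_duration_s feedback duration, seconds
#' @param iti_range_s length-2 numeric, uniform jitter bounds for the
#'   inter-trial interval, seconds
#' @param match_probability probability that the probe matches a memorized item
#' @return validated configuration list of class "taskConfig"
#' @export
#' @examples
#' cfg <- taskConfig()
#' cfg$n_blocks * cfg$trials_per_block  # 720
taskConfig <- function(n_blocks = 30L, trials_per_block = 24L,
                       set_sizes = c(1L, 2L, 4L),
                       stim_duration_s = 0.2, isi_s = 1.0, delay_s = 3.0,
                       probe_duration_s = 0.2, feedback_delay_s = 0.5,
                       feedback_duration_s = 1.0,
                       iti_range_s = c(1.2, 1.6),
                       match_probability = 0.5) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              set_sizes = as.integer(set_sizes),
              stim_duration_s = stim_duration_s, isi_s = isi_s,
              delay_s = delay_s, probe_duration_s = probe_duration_s,
              feedback_delay_s = feedback_delay_s,
              feedback_duration_s = feedback_duration_s,
              iti_range_s = as.numeric(iti_range_s),
              match_probability = match_probability)
  validateTaskConfig(cfg)
  class(cfg) <- c("taskConfig", "list")
  cfg
}

validateTaskConfig <- function(cfg) {
  if (cfg$n_blocks < 1L || cfg$trials_per_block < 1L)
    stop("n_blocks and trials_per_block must be positive")
  if (length(cfg$set_sizes) < 1L || anyDuplicated(cfg$set_sizes))
    stop("set_sizes must be a non-empty set of distinct counts")
  if (cfg$trials_per_block %% length(cfg$set_sizes) != 0L)
    stop("trials_per_block (", cfg$trials_per_block,
         ") is not divisible by the number of set sizes (",
         length(cfg$set_sizes), ")")
  durs <- c(cfg$stim_duration_s, cfg$isi_s, cfg$delay_s, cfg$probe_duration_s,
            cfg$feedback_delay_s, cfg$feedback_duration_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all durations must be positive and finite")
  if (length(cfg$iti_range_s) != 2L || cfg$iti_range_s[1] >= cfg$iti_range_s[2])
    stop("iti_range_s must be (low, high) with low < high")
  if (cfg$match_probability < 0 || cfg$match_probability > 1)
    stop("match_probability must lie in [0, 1]")
  invisible(cfg)
}

#' Generate a task schedule
#'
#' Draws a full session: within every block each set size occurs exactly
#' `trials_per_block / length(set_sizes)` times in a seeded uniform random
#' order, probe match flags are independent Bernoulli draws, and inter-trial
#' intervals are uniform on `iti_range_s`. Each trial's clock starts at its
#' first stimulus onset (0 s); stimuli are spaced `stim_duration_s + isi_s`
#' apart, the maintenance delay starts one ISI after the last stimulus offset,
#' and the probe appears `delay_s` later.
#'
#' @param config a [taskConfig()]
#' @param seed integer seed; the schedule is byte-identical for a fixed seed
#' @return a [TaskSchedule-class]
#' @export
#' @examples
#' sched <- generateSchedule(taskConfig(), seed = 1)
#' nTrials(sched)  # 720
generateSchedule <- function(config = taskConfig(), seed) {
  if (missing(seed)) stop("seed is required")
  validateTaskConfig(config)
  seed <- as.integer(seed)
  n_sizes <- length(config$set_sizes)
  per_size <- config$trials_per_block %/% n_sizes
  spacing <- config$stim_duration_s + config$isi_s

  rows <- withSeed(seed, {
    out <- vector("list", config$n_blocks)
    g <- 0L
    for (b in seq_len(config$n_blocks)) {
      sizes <- sample(rep(config$set_sizes, per_size))
      match <- runif(config$trials_per_block) < config$match_probability
      iti <- runif(config$trials_per_block,
                   config$iti_range_s[1], config$iti_range_s[2])
      onsets <- lapply(sizes, function(s) spacing * (seq_len(s) - 1L))
      maint <- vapply(onsets, function(o) o[length(o)] + spacing, 0)
      out[[b]] <- data.frame(
        block_index = b - 1L,
        trial_index_global = g + seq_len(config$trials_per_block) - 1L,
        set_size = sizes,
        is_match = match,
        stim_onsets_s = I(onsets),
        maintenance_onset_s = maint,
        probe_onset_s = maint + config$delay_s,
        iti_s = iti)
      g <- g + config$trials_per_block
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  new("TaskSchedule", config = unclass(config), trials = rows, seed = seed)
}

## Evaluate expr under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so library code never perturbs user randomness.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic stream of derived seeds, kept inside 32-bit range.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

#' Export a schedule as a BIDS-events-like table
#'
#' Writes one row per event (stimulus, maintenance, probe) with columns
#' onset, duration, trial_index, block, set_size, is_match, event_type.
#' Onsets are seconds from the trial's first stimulus.
#'
#' @param schedule a [TaskSchedule-class]
#' @param path output path for the tab-separated table
#' @export
writeEventsTable <- function(schedule, path) {
  tr <- scheduleTrials(schedule)
  cfg <- scheduleConfig(schedule)
  ev <- lapply(seq_len(nrow(tr)), function(i) {
    stim <- tr$stim_onsets_s[[i]]
    data.frame(
      onset = c(stim, tr$maintenance_onset_s[i], tr$probe_onset_s[i]),
      duration = c(rep(cfg$stim_duration_s, length(stim)), cfg$delay_s,
                   cfg$probe_duration_s),
      trial_index = tr$trial_index_global[i],
      block = tr$block_index[i],
      set_size = tr$set_size[i],
      is_match = tr$is_match[i],
      event_type = c(rep("stimulus", length(stim)), "maintenance", "probe"))
  })
  write.table(do.call(rbind, ev), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read back an events table written by [writeEventsTable()]
#'
#' @param path events file
#' @return data.frame of events
#' @export
readEventsTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a task configuration as a key: value text file
#'
#' @param config a [taskConfig()]
#' @param path file path
#' @export
writeTaskConfig <- function(config, path) {
  validateTaskConfig(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeTaskConfig
#' @export
readTaskConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(taskConfig, raw)
}
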