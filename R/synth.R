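## Synthetic epoched EEG with planted cross-trial variance structure.
##
## Generative model, per trial:
##   x(t) = 1/f noise + phase-locked evoked transient + beta burst
## where the beta burst is a Hann-windowed constant-frequency sinusoid with
## uniform random phase (non-phase-locked, so it survives phase-locked
## subtraction) and amplitude exp(a), a ~ Normal(mu, sigma) per condition.
## Cross-trial amplitude variance is the planted quantity the downstream
## relative-variance statistic must recover. Behavioral accuracy is coupled
## to the PREVIOUS trial's post-response log-amplitude through a logistic
## model (the planted N+1 effect), and the post-response amplitude spread may
## be keyed on the trial's own correctness (the planted correct/incorrect
## variability contrast).

frontalCluster <- c("Fz", "AFz", "F1", "F2", "FCz")
centroparietalCluster <- c("CPz", "Cz", "CP1", "CP2", "Pz")

#' Channel clusters used throughout the analyses
#'
#' The frontal cluster is Fz plus its immediate neighbours (AFz, F1, F2, FCz);
#' the centroparietal cluster is CPz plus Cz, CP1, CP2 and Pz.
#'
#' @param name "frontal" or "centroparietal"
#' @return list with elements `name` and `channels`
#' @export
clusterSpec <- function(name = c("frontal", "centroparietal")) {
  name <- match.arg(name)
  list(name = name,
       channels = if (name == "frontal") frontalCluster else centroparietalCluster)
}

condMatrix <- function(younger, older, set_sizes = c(1, 2, 4)) {
  m <- rbind(younger = younger, older = older)
  colnames(m) <- as.character(set_sizes)
  m
}

#' Parameters of the synthetic-EEG generator
#'
#' All planted effects are explicit parameters. Log-amplitudes of the beta
#' burst are Normal per condition, so burst amplitudes are lognormal
#' (positive support, multiplicative cross-trial variability). Defaults plant
#' the qualitative study pattern at a size recoverable with roughly 20
#' synthetic participants per group: a load-dependent *decrease* of
#' maintenance amplitude spread in the younger group (sigma 0.36, 0.27, 0.16
#' over loads 1, 2, 4) against a flat older group (0.26); a positive coupling
#' of previous-trial post-response log-amplitude with current-trial accuracy
#' in the older group only (`n_plus_1_beta`); and a larger post-response
#' amplitude spread on correct (0.40) than incorrect (0.25) trials.
#'
#' @param montage channel labels; default the 10 analysis channels
#'   (frontal + centroparietal clusters)
#' @param sfreq_hz sampling rate, Hz
#' @param noise_exponent power-law exponent of the 1/f background (power
#'   spectrum ~ 1/f^exponent)
#' @param noise_scale RMS of the background noise, microvolts
#' @param erp_amplitude amplitude of the phase-locked evoked transient,
#'   microvolts
#' @param band_defs named list of (low, high) band edges, Hz
#' @param beta_center_hz carrier frequency of the planted burst, Hz
#' @param beta_scale_uv microvolts of burst amplitude per unit exp(log-amplitude)
#' @param maint_amp_mu,maint_amp_sigma group x set-size matrices of
#'   maintenance-burst log-amplitude mean and cross-trial SD
#' @param post_amp_mu,post_amp_sigma group x correctness ("incorrect",
#'   "correct") matrices for the post-response burst
#' @param baseline_amp_sigma trial-level SD of the baseline log-power offset
#'   (common to all time bins of a trial)
#' @param power_jitter_sd within-trial, per-time-bin log-power noise SD used
#'   by the band-power simulation mode
#' @param accuracy_base_logit group x set-size matrix of baseline accuracy
#'   logits
#' @param n_plus_1_beta named vector (younger, older): logit slope of current
#'   accuracy on previous-trial centered post-response log-amplitude
#' @param rt_mean_s,rt_sd_s group x set-size matrices of reaction-time mean/SD
#'   (lognormal, seconds)
#' @param participant_logit_sd SD of per-participant accuracy intercepts
#' @param participant_sigma_sd SD of per-participant log multipliers on all
#'   amplitude sigmas (shared across conditions)
#' @param participant_mu_sd SD of per-participant offsets on amplitude means
#' @return validated parameter list of class "synthParams"
#' @export
synthParams <- function(
    montage = c(frontalCluster, centroparietalCluster),
    sfreq_hz = 250,
    noise_exponent = 1,
    noise_scale = 10,
    erp_amplitude = 5,
    band_defs = list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 14),
                     beta = c(15, 25), gamma = c(26, 40)),
    beta_center_hz = 20,
    beta_scale_uv = 5,
    maint_amp_mu = condMatrix(c(0, 0, 0), c(0, 0, 0)),
    maint_amp_sigma = condMatrix(c(0.36, 0.27, 0.16), c(0.26, 0.26, 0.26)),
    post_amp_mu = cbind(incorrect = c(younger = 0.2, older = 0.2),
                        correct = c(younger = 0.2, older = 0.2)),
    post_amp_sigma = cbind(incorrect = c(younger = 0.25, older = 0.25),
                           correct = c(younger = 0.40, older = 0.40)),
    baseline_amp_sigma = 0.25,
    power_jitter_sd = 0.2,
    accuracy_base_logit = condMatrix(qlogis(c(0.95, 0.88, 0.78)),
                                     qlogis(c(0.93, 0.84, 0.72))),
    n_plus_1_beta = c(younger = 0, older = 1.0),
    rt_mean_s = condMatrix(c(0.70, 0.80, 0.95), c(0.90, 1.05, 1.25)),
    rt_sd_s = condMatrix(c(0.18, 0.20, 0.24), c(0.22, 0.26, 0.31)),
    participant_logit_sd = 0.3,
    participant_sigma_sd = 0.05,
    participant_mu_sd = 0.1) {
  p <- mget(names(formals()))
  validateSynthParams(p)
  class(p) <- c("synthParams", "list")
  p
}

validateSynthParams <- function(p) {
  sig <- c(p$maint_amp_sigma, p$post_amp_sigma, p$baseline_amp_sigma,
           p$power_jitter_sd, p$participant_logit_sd, p$participant_sigma_sd,
           p$participant_mu_sd)
  if (any(!is.finite(sig)) || any(sig < 0))
    stop("all sigma parameters must be finite and >= 0")
  hi <- max(vapply(p$band_defs, max, 0))
  if (p$sfreq_hz < 2 * hi)
    stop("sfreq_hz violates Nyquist for the highest band edge (", hi, " Hz)")
  edges <- do.call(rbind, p$band_defs)
  if (any(edges < 1) || any(edges > 40))
    stop("band definitions must lie within [1, 40] Hz")
  o <- order(edges[, 1])
  if (any(edges[o, , drop = FALSE][-nrow(edges), 2] >=
          edges[o, , drop = FALSE][-1, 1]))
    stop("band definitions must be non-overlapping")
  if (!all(c("younger", "older") %in% rownames(p$maint_amp_sigma)))
    stop("group rows must be named younger/older")
  invisible(p)
}

#' Null-effect parameter set
#'
#' Same generator with every planted effect removed: amplitude sigmas equal
#' across groups, loads and correctness, no lag coupling, identical accuracy
#' logits across groups. Used for type-I-error calibration.
#'
#' @param sigma common cross-trial log-amplitude SD
#' @param ... passed on to [synthParams()]
#' @return "synthParams" list
#' @export
synthParamsNull <- function(sigma = 0.26, ...) {
  synthParams(
    maint_amp_sigma = condMatrix(rep(sigma, 3), rep(sigma, 3)),
    post_amp_sigma = cbind(incorrect = c(younger = sigma, older = sigma),
                           correct = c(younger = sigma, older = sigma)),
    n_plus_1_beta = c(younger = 0, older = 0),
    accuracy_base_logit = condMatrix(qlogis(c(0.95, 0.88, 0.78)),
                                     qlogis(c(0.95, 0.88, 0.78))),
    ...)
}

checkGroup <- function(params, group) {
  if (!group %in% rownames(params$maint_amp_sigma))
    stop("unknown group: ", group)
  group
}

## Per-participant random modifiers, drawn from a seed-derived stream so that
## every public op sees the same participant for the same seed.
participantEffects <- function(params, seed) {
  withSeed(deriveSeed(seed, 104729), list(
    logit = rnorm(1, 0, params$participant_logit_sd),
    sigma_mult = exp(rnorm(1, 0, params$participant_sigma_sd)),
    mu_off = rnorm(1, 0, params$participant_mu_sd)))
}

#' Draw one participant's trial chain: amplitudes + behavior, jointly
#'
#' Runs the generative chain in trial order. Maintenance log-amplitudes are
#' drawn per (group, set size); then, trial by trial, accuracy is drawn from
#' the logistic model using the previous trial's already-drawn post-response
#' log-amplitude (no lag term on the first trial of each block), and the
#' current trial's post-response log-amplitude is drawn with the SD keyed on
#' that accuracy. This makes the N+1 coupling and the correctness-keyed
#' variance effect coexist; with `n_plus_1_beta = 0` it reduces to drawing
#' correctness first and amplitudes afterwards.
#'
#' @param schedule a [TaskSchedule-class]
#' @param params a [synthParams()]
#' @param group "younger" or "older"
#' @param seed integer seed
#' @return list with `amplitudes` (data.frame: trial_id, set_size,
#'   maintenance, post_response log-amplitudes) and `behavior` (data.frame:
#'   trial_id, block_index, set_size, accuracy, rt_s, group)
#' @export
simulateParticipant <- function(schedule, params, group, seed) {
  checkGroup(params, group)
  tr <- scheduleTrials(schedule)
  n <- nrow(tr)
  eff <- participantEffects(params, seed)
  ss <- as.character(tr$set_size)
  mu_m <- params$maint_amp_mu[group, ss] + eff$mu_off
  sd_m <- params$maint_amp_sigma[group, ss] * eff$sigma_mult
  base <- params$accuracy_base_logit[group, ss] + eff$logit
  beta_lag <- params$n_plus_1_beta[[group]]
  mu_p <- params$post_amp_mu[group, ] + eff$mu_off
  sd_p <- params$post_amp_sigma[group, ] * eff$sigma_mult
  mu_p_center <- mean(mu_p)

  withSeed(deriveSeed(seed, 1L), {
    a_maint <- rnorm(n, mu_m, sd_m)
    a_post <- numeric(n)
    acc <- integer(n)
    for (i in seq_len(n)) {
      lag <- if (i > 1L && tr$block_index[i] == tr$block_index[i - 1L])
        beta_lag * (a_post[i - 1L] - mu_p_center) else 0
      acc[i] <- rbinom(1L, 1L, plogis(base[i] + lag))
      key <- if (acc[i] == 1L) "correct" else "incorrect"
      a_post[i] <- rnorm(1L, mu_p[[key]], sd_p[[key]])
    }
    rt_mu <- params$rt_mean_s[group, ss]
    rt_sd <- params$rt_sd_s[group, ss]
    rt <- rlnorm(n, log(rt_mu^2 / sqrt(rt_mu^2 + rt_sd^2)),
                 sqrt(log(1 + rt_sd^2 / rt_mu^2)))
    list(
      amplitudes = data.frame(trial_id = tr$trial_index_global,
                              set_size = tr$set_size,
                              maintenance = a_maint, post_response = a_post),
      behavior = data.frame(trial_id = tr$trial_index_global,
                            block_index = tr$block_index,
                            set_size = tr$set_size,
                            accuracy = acc, rt_s = rt,
                            group = group))
  })
}

#' Draw per-trial burst log-amplitudes
#'
#' Log-amplitudes are Normal(mu, sigma) per (group, set size) for the
#' maintenance phase and per (group, correctness) for the post-response
#' phase; the cross-trial variance of maintenance log-amplitudes therefore
#' equals sigma^2(group, set size) in expectation. Deterministic for a fixed
#' seed and identical to the amplitude half of [simulateParticipant()].
#'
#' @inheritParams simulateParticipant
#' @return amplitude data.frame (trial_id, set_size, maintenance,
#'   post_response)
#' @export
sampleAmplitudes <- function(schedule, params, group, seed) {
  simulateParticipant(schedule, params, group, seed)$amplitudes
}

#' Simulate behavior given an amplitude table
#'
#' Stand-alone behavioral model: current-trial accuracy follows
#' `logistic(base_logit(group, set size) + n_plus_1_beta * centered previous
#' post-response log-amplitude)`; the first trial of each block carries no
#' lag term. Reaction times are lognormal with the configured per-condition
#' mean and SD. Centering of the lagged amplitude uses the participant's own
#' mean post-response amplitude.
#'
#' @inheritParams simulateParticipant
#' @param amplitudes amplitude table from [sampleAmplitudes()]
#' @return behavioral data.frame (trial_id, block_index, set_size, accuracy,
#'   rt_s, group)
#' @export
simulateBehavior <- function(schedule, amplitudes, params, group, seed) {
  checkGroup(params, group)
  tr <- scheduleTrials(schedule)
  if (!identical(amplitudes$trial_id, tr$trial_index_global))
    stop("amplitudes are not aligned to the schedule")
  n <- nrow(tr)
  eff <- participantEffects(params, seed)
  ss <- as.character(tr$set_size)
  base <- params$accuracy_base_logit[group, ss] + eff$logit
  beta_lag <- params$n_plus_1_beta[[group]]
  a_post <- amplitudes$post_response
  prev_same_block <- c(FALSE, tr$block_index[-1] == tr$block_index[-n])
  lag <- numeric(n)
  lag[prev_same_block] <- beta_lag *
    (a_post[which(prev_same_block) - 1L] - mean(a_post))
  withSeed(deriveSeed(seed, 2L), {
    acc <- rbinom(n, 1L, plogis(base + lag))
    rt_mu <- params$rt_mean_s[group, ss]
    rt_sd <- params$rt_sd_s[group, ss]
    rt <- rlnorm(n, log(rt_mu^2 / sqrt(rt_mu^2 + rt_sd^2)),
                 sqrt(log(1 + rt_sd^2 / rt_mu^2)))
    data.frame(trial_id = tr$trial_index_global,
               block_index = tr$block_index, set_size = tr$set_size,
               accuracy = acc, rt_s = rt, group = group)
  })
}

## ---------------------------------------------------------------------------
## Waveform rendering
## ---------------------------------------------------------------------------

## FFT-shaped 1/f noise; each column standardized to the requested RMS so the
## target spectral slope is preserved exactly in shape.
onefNoise <- function(n_samples, n_series, sfreq, exponent, scale) {
  if (scale == 0) return(matrix(0, n_samples, n_series))
  w <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  f <- seq(0, sfreq - sfreq / n_samples, length.out = n_samples)
  f <- pmin(f, sfreq - f)  # two-sided frequency axis
  h <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n_samples
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/") * scale
}

hannWindow <- function(t, t0, t1) {
  u <- (t - t0) / (t1 - t0)
  ifelse(u >= 0 & u <= 1, 0.5 - 0.5 * cos(2 * pi * u), 0)
}

## Phase-locked evoked transient: 300 ms Hann-gated 5 Hz half-wave, fixed phase.
evokedWave <- function(t, onset, amplitude) {
  amplitude * hannWindow(t, onset, onset + 0.3) * sin(2 * pi * 5 * (t - onset))
}

#' Render epoched waveforms from an amplitude table
#'
#' Produces a maintenance-locked and a response-locked [EEGEpochs-class]
#' pair. Each trial and channel is 1/f background noise plus a phase-locked
#' evoked transient (at probe onset for maintenance-locked epochs, at the
#' response for response-locked epochs) plus a Hann-windowed sinusoid at
#' `beta_center_hz` with uniform random phase per trial, whose amplitude is
#' `beta_scale_uv * exp(log-amplitude)`. The maintenance burst spans 0-3 s
#' after maintenance onset; the post-response burst spans 0.1-0.5 s after the
#' response. Analysis spans are -0.5..3.5 s and -0.5..1.0 s; `pad_s` extra
#' seconds are rendered on each side so that wavelet edge-invalid samples do
#' not intrude into the baseline window.
#'
#' @inheritParams simulateParticipant
#' @param amplitudes amplitude table from [sampleAmplitudes()]
#' @param behavior behavioral table (for response times); simulated
#'   internally from the same seed when NULL
#' @param pad_s rendering pad on each side of the analysis span, seconds
#' @return list with elements `maintenance` and `response` ([EEGEpochs-class])
#' @export
renderEpochs <- function(schedule, amplitudes, params, group, seed,
                         behavior = NULL, pad_s = 0.5) {
  hi <- max(vapply(params$band_defs, max, 0))
  if (params$sfreq_hz < 2 * max(hi, params$beta_center_hz))
    stop("sfreq_hz violates Nyquist")
  tr <- scheduleTrials(schedule)
  if (!identical(amplitudes$trial_id, tr$trial_index_global))
    stop("amplitudes are not aligned to the schedule")
  if (is.null(behavior))
    behavior <- simulateBehavior(schedule, amplitudes, params, group, seed)
  n <- nrow(tr)
  nch <- length(params$montage)
  sf <- params$sfreq_hz

  renderLock <- function(tmin, tmax, burst_win, a, evoked_onset, sub_seed) {
    ns <- round((tmax - tmin) * sf) + 1L
    t <- tmin + (seq_len(ns) - 1L) / sf
    withSeed(deriveSeed(seed, sub_seed), {
      noise <- onefNoise(ns, n * nch, sf, params$noise_exponent,
                         params$noise_scale)
      phase <- runif(n, 0, 2 * pi)
      arr <- array(0, c(n, nch, ns))
      win <- hannWindow(t, burst_win[1], burst_win[2])
      ev <- evokedWave(t, evoked_onset, params$erp_amplitude)
      for (i in seq_len(n)) {
        burst <- params$beta_scale_uv * exp(a[i]) * win *
          sin(2 * pi * params$beta_center_hz * t + phase[i])
        for (ch in seq_len(nch))
          arr[i, ch, ] <- noise[, (i - 1L) * nch + ch] + ev + burst
      }
      arr
    })
  }

  maint <- renderLock(-0.5 - pad_s, 3.5 + pad_s, c(0, 3),
                      amplitudes$maintenance, evoked_onset = 3.0,
                      sub_seed = 11L)
  resp <- renderLock(-0.5 - pad_s, 1.0 + pad_s, c(0.1, 0.5),
                     amplitudes$post_response, evoked_onset = 0,
                     sub_seed = 12L)
  list(
    maintenance = newEpochs(maint, sf, -0.5 - pad_s, "maintenance",
                            params$montage, tr$trial_index_global),
    response = newEpochs(resp, sf, -0.5 - pad_s, "response",
                         params$montage, tr$trial_index_global))
}

#' Inject artifact spikes into selected trials
#'
#' Adds a one-sample voltage spike to one channel of each named trial, for
#' exercising amplitude rejection.
#'
#' @param epochs an [EEGEpochs-class]
#' @param trial_idx trial positions (1-based) to corrupt
#' @param amplitude_uv spike amplitude, microvolts
#' @param seed seed for spike placement
#' @return corrupted [EEGEpochs-class]
#' @export
injectSpikes <- function(epochs, trial_idx, amplitude_uv = 150, seed = 1) {
  d <- epochsData(epochs)
  withSeed(seed, {
    for (i in trial_idx) {
      ch <- sample.int(dim(d)[2], 1L)
      s <- sample.int(dim(d)[3], 1L)
      d[i, ch, s] <- d[i, ch, s] + amplitude_uv
    }
  })
  newEpochs(d, epochs@sfreq, epochs@tmin, epochs@lock, epochs@channels,
            epochs@trialIds)
}

## ---------------------------------------------------------------------------
## Band-power simulation mode + analytic oracle
## ---------------------------------------------------------------------------

#' Simulate band-power time courses directly from the amplitude model
#'
#' Skips waveform rendering: draws single-trial band power on the 50 ms
#' output grid straight from the generative model,
#' `log P(t) = 2*a_baseline + 2*a_phase*h(t) + eps(t)`, where `a_baseline ~
#' Normal(0, baseline_amp_sigma)` is a trial-level offset, `h(t)` indicates
#' the phase window (0-3 s maintenance-locked, 0.1-0.5 s response-locked) and
#' `eps ~ Normal(0, power_jitter_sd)` is independent per time bin. The result
#' is a raw-power [TrialTFR-class] with a single frequency bin at the beta
#' carrier, suitable for the full dbNormalize / relativeVariance / aggregate
#' path. Used for replicate-scale simulation studies where rendering and
#' decomposing waveforms would dominate runtime.
#'
#' @inheritParams renderEpochs
#' @param lock "maintenance" or "response"
#' @param t_step_s output grid step, seconds
#' @return raw-power [TrialTFR-class] (trials x channels x 1 freq x times)
#' @export
simulateBandPower <- function(schedule, amplitudes, params, group, seed,
                              lock = c("maintenance", "response"),
                              t_step_s = 0.05) {
  lock <- match.arg(lock)
  tr <- scheduleTrials(schedule)
  n <- nrow(tr)
  nch <- length(params$montage)
  if (lock == "maintenance") {
    times <- seq(-0.45, 3.45, by = t_step_s)
    win <- c(0, 3); a <- amplitudes$maintenance; sub <- 21L
  } else {
    times <- seq(-0.45, 0.95, by = t_step_s)
    win <- c(0.1, 0.5); a <- amplitudes$post_response; sub <- 22L
  }
  nt <- length(times)
  h <- as.numeric(times >= win[1] & times <= win[2])
  withSeed(deriveSeed(seed, sub), {
    a_b <- rnorm(n * nch, 0, params$baseline_amp_sigma)
    eps <- array(rnorm(n * nch * nt, 0, params$power_jitter_sd), c(n, nch, nt))
    logp <- array(0, c(n, nch, nt))
    for (ch in seq_len(nch))
      logp[, ch, ] <- 2 * a_b[(ch - 1L) * n + seq_len(n)] +
        outer(2 * a, h) + eps[, ch, ]
    p <- exp(logp)
    dim(p) <- c(n, nch, 1L, nt)
    newTFR(p, freqs = params$beta_center_hz, times = times,
           units = "raw_power", lock = lock, channels = params$montage,
           trial_ids = tr$trial_index_global)
  })
}

#' Expected relative variance under the generative model
#'
#' Closed-form oracle for the cross-trial relative-variance statistic implied
#' by the lognormal amplitude model of [simulateBandPower()], for use as
#' ground truth in recovery tests.
#'
#' In "dB" mode (variance computed on per-trial decibel-normalized power with
#' an n-bin baseline) the trial-level baseline offset cancels and, to first
#' order in the jitter variance,
#' `relvar = log10((4*sigma^2 + tau^2*(1 + 1/n_b)) / (tau^2*(1 - 1/n_b)))`
#' with `tau = power_jitter_sd`. In "raw_power" mode the exact lognormal
#' variance ratio is returned.
#'
#' @param params a [synthParams()]
#' @param group group name
#' @param set_size set size (maintenance phase) -- ignored for post_response
#' @param phase "maintenance" or "post_response"
#' @param mode units the variance is computed on
#' @param n_baseline_bins number of time bins averaged in the per-trial
#'   baseline (dB mode)
#' @param correctness "correct" or "incorrect" (post_response phase)
#' @return expected relative variance, log10-ratio units
#' @export
expectedRelVar <- function(params, group, set_size = 1,
                           phase = c("maintenance", "post_response"),
                           mode = c("dB", "raw_power"),
                           n_baseline_bins = 7L,
                           correctness = "correct") {
  phase <- match.arg(phase)
  mode <- match.arg(mode)
  checkGroup(params, group)
  if (phase == "maintenance") {
    sigma <- params$maint_amp_sigma[group, as.character(set_size)]
    mu <- params$maint_amp_mu[group, as.character(set_size)]
  } else {
    sigma <- params$post_amp_sigma[group, correctness]
    mu <- params$post_amp_mu[group, correctness]
  }
  tau2 <- params$power_jitter_sd^2
  sb2 <- params$baseline_amp_sigma^2
  if (mode == "dB") {
    if (tau2 == 0) stop("zero baseline variance: power_jitter_sd is 0")
    nb <- n_baseline_bins
    log10((4 * sigma^2 + tau2 * (1 + 1 / nb)) / (tau2 * (1 - 1 / nb)))
  } else {
    if (tau2 == 0 && sb2 == 0)
      stop("zero baseline variance: both jitter and baseline sigma are 0")
    lnvar <- function(m, s2) (exp(s2) - 1) * exp(2 * m + s2)
    log10(lnvar(2 * mu, 4 * sb2 + 4 * sigma^2 + tau2) /
          lnvar(0, 4 * sb2 + tau2))
  }
}
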