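test_that("amplitude draws honor the planted condition structure", {
  sched <- generateSchedule(taskConfig(), seed = 2)  # 240 trials/condition
  p0 <- synthParams(maint_amp_sigma =
                      trialvar:::condMatrix(c(0, 0, 0), c(0, 0, 0)),
                    participant_sigma_sd = 0, participant_mu_sd = 0)
  a0 <- sampleAmplitudes(sched, p0, "younger", seed = 5)
  # zero sigma: every trial of a condition shares the same amplitude
  expect_true(all(tapply(a0$maintenance, a0$set_size,
                         function(x) diff(range(x))) < 1e-12))

  p <- synthParams(participant_sigma_sd = 0, participant_mu_sd = 0)
  a <- sampleAmplitudes(sched, p, "younger", seed = 5)
  sds <- tapply(a$maintenance, a$set_size, sd)
  planted <- p$maint_amp_sigma["younger", ]
  # recovered SDs close to planted, and decreasing with load
  expect_true(all(abs(sds - planted) / planted < 0.2))
  expect_true(sds["1"] > sds["2"] && sds["2"] > sds["4"])

  expect_identical(a, sampleAmplitudes(sched, p, "younger", seed = 5))
  expect_error(sampleAmplitudes(sched, p, "child", 5), "unknown group")
})

test_that("behavior simulation matches the logistic model", {
  sched <- generateSchedule(taskConfig(n_blocks = 100), seed = 3)
  p <- synthParams(n_plus_1_beta = c(younger = 0, older = 0),
                   participant_logit_sd = 0)
  a <- sampleAmplitudes(sched, p, "younger", seed = 9)
  beh <- simulateBehavior(sched, a, p, "younger", seed = 9)
  for (s in c(1, 2, 4)) {
    target <- plogis(p$accuracy_base_logit["younger", as.character(s)])
    obs <- mean(beh$accuracy[beh$set_size == s])
    n <- sum(beh$set_size == s)
    expect_lt(abs(obs - target), 3 * sqrt(target * (1 - target) / n))
  }
  expect_true(all(beh$rt_s > 0))
})

test_that("saturated logits and planted lag coupling behave as specified", {
  sched <- generateSchedule(taskConfig(n_blocks = 30), seed = 4)
  sat <- synthParams(accuracy_base_logit =
                       trialvar:::condMatrix(rep(10, 3), rep(10, 3)),
                     participant_logit_sd = 0)
  a <- sampleAmplitudes(sched, sat, "older", seed = 6)
  beh <- simulateBehavior(sched, a, sat, "older", seed = 6)
  expect_gt(mean(beh$accuracy), 0.999)

  # positive lag coupling: lagged amplitude correlates with accuracy
  p <- synthParams(n_plus_1_beta = c(younger = 0, older = 1.0),
                   participant_logit_sd = 0)
  big <- generateSchedule(taskConfig(n_blocks = 420), seed = 5)
  sim <- simulateParticipant(big, p, "older", seed = 8)
  tr <- scheduleTrials(big)
  n <- nrow(tr)
  same_block <- tr$block_index[-1] == tr$block_index[-n]
  r <- cor(sim$amplitudes$post_response[-n][same_block],
           sim$behavior$accuracy[-1][same_block])
  expect_gt(r, 0.02)
})

test_that("rendered epochs contain the planted spectral structure", {
  sched <- generateSchedule(taskConfig(n_blocks = 1, trials_per_block = 3,
                                       set_sizes = 1L), seed = 1)
  # pure-tone case: no noise, no evoked, burst only
  p <- synthParams(noise_scale = 0, erp_amplitude = 0,
                   montage = "Fz", participant_sigma_sd = 0,
                   participant_mu_sd = 0)
  sim <- simulateParticipant(sched, p, "younger", 3)
  ep <- renderEpochs(sched, sim$amplitudes, p, "younger", 3,
                     behavior = sim$behavior)$maintenance
  tfr <- morletTFR(ep, spectralConfig(freqs_hz = seq(5, 40)))
  mid <- which.min(abs(tfrTimes(tfr) - 1.5))
  peak <- tfrFreqs(tfr)[which.max(tfrPower(tfr)[1, 1, , mid])]
  expect_equal(peak, p$beta_center_hz)

  # all-zero params give all-zero epochs
  pz <- synthParams(noise_scale = 0, erp_amplitude = 0, beta_scale_uv = 0,
                    montage = "Fz")
  epz <- renderEpochs(sched, sim$amplitudes, pz, "younger", 3,
                      behavior = sim$behavior)$maintenance
  expect_true(all(epochsData(epz) == 0))
})

test_that("background noise follows the configured 1/f exponent", {
  p <- synthParams(erp_amplitude = 0, beta_scale_uv = 0)
  sched <- smallSchedule(n_blocks = 2, trials_per_block = 12)
  sim <- simulateParticipant(sched, p, "younger", 5)
  ep <- renderEpochs(sched, sim$amplitudes, p, "younger", 5,
                     behavior = sim$behavior)$maintenance
  d <- epochsData(ep)
  ns <- dim(d)[3]
  spec <- 0
  for (i in seq_len(dim(d)[1])) for (ch in 1:2)
    spec <- spec + Mod(fft(d[i, ch, ]))^2
  f <- (seq_len(ns) - 1) * samplingRate(ep) / ns
  sel <- f >= 2 & f <= 40
  slope <- -coef(lm(log10(spec[sel]) ~ log10(f[sel])))[[2]]
  expect_lt(abs(slope - p$noise_exponent), 0.2)
})

test_that("phase-locked subtraction removes the evoked average", {
  sched <- generateSchedule(taskConfig(n_blocks = 3, trials_per_block = 24),
                            seed = 6)
  p <- synthParams()
  sim <- simulateParticipant(sched, p, "younger", 6)
  ep <- renderEpochs(sched, sim$amplitudes, p, "younger", 6,
                     behavior = sim$behavior)$maintenance
  m_before <- colMeans(epochsData(ep), dims = 1)
  out <- subtractERP(ep, scheduleTrials(sched)$set_size)
  m_after <- colMeans(epochsData(out), dims = 1)
  expect_gt(sqrt(sum(m_before^2)) / max(sqrt(sum(m_after^2)), 1e-300), 10)
})

test_that("the analytic relative-variance oracle matches Monte Carlo", {
  p <- synthParams()
  set.seed(12)
  n <- 1e5; nb <- 7L
  for (s in c(1, 4)) {
    sig <- p$maint_amp_sigma["younger", as.character(s)]
    a <- rnorm(n, 0, sig)
    eps_w <- rnorm(n, 0, p$power_jitter_sd)
    epsb <- matrix(rnorm(n * nb, 0, p$power_jitter_sd), n, nb)
    m <- log(rowMeans(exp(epsb)))
    k <- 10 / log(10)
    mc_db <- log10(var(k * (2 * a + eps_w - m)) / var(k * (epsb[, 1] - m)))
    ev <- expectedRelVar(p, "younger", s, "maintenance", "dB",
                         n_baseline_bins = nb)
    expect_lt(abs(ev - mc_db) / abs(mc_db), 0.02)

    ab <- rnorm(n, 0, p$baseline_amp_sigma)
    w_raw <- exp(2 * ab + 2 * a + eps_w)
    b_raw <- exp(2 * ab + epsb[, 1])
    mc_raw <- log10(var(w_raw) / var(b_raw))
    ev_raw <- expectedRelVar(p, "younger", s, "maintenance", "raw_power")
    expect_lt(abs(ev_raw - mc_raw) / abs(mc_raw), 0.05)
  }
  degenerate <- synthParams(power_jitter_sd = 0)
  expect_error(expectedRelVar(degenerate, "younger", 1, "maintenance", "dB"),
               "zero baseline variance")
})

test_that("band-power simulation agrees with the analytic oracle", {
  p <- synthParams(participant_sigma_sd = 0, participant_mu_sd = 0)
  sched <- generateSchedule(taskConfig(), seed = 4)  # 240 trials/condition
  sim <- simulateParticipant(sched, p, "younger", 4)
  db <- dbNormalize(simulateBandPower(sched, sim$amplitudes, p, "younger",
                                      4, "maintenance"), c(-0.4, -0.1))
  for (s in c(1, 2, 4)) {
    map <- relativeVariance(subsetTrials(db, sim$behavior$set_size == s),
                            c(-0.4, -0.1))
    agg <- aggregateVariability(map, c(15, 25), c(0, 3),
                                clusterSpec("frontal"))
    ev <- expectedRelVar(p, "younger", s, "maintenance", "dB",
                         n_baseline_bins = 7L)
    expect_lt(abs(agg - ev), 0.05)
  }
})

test_that("parameter validation catches inconsistent settings", {
  expect_error(synthParams(sfreq_hz = 60), "Nyquist")
  expect_error(synthParams(power_jitter_sd = -1), "sigma")
  expect_error(synthParams(band_defs = list(a = c(1, 10), b = c(5, 20))),
               "non-overlapping")
})
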