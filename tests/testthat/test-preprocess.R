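test_that("amplitude rejection flags exactly the threshold violations", {
  set.seed(1)
  d <- array(runif(20 * 2 * 50, -50, 50), c(20, 2, 50))
  ep <- makeEpochs(d)
  r <- rejectAmplitude(ep, 100)
  expect_true(all(r$kept))
  expect_equal(r$fraction_kept, 1)

  d2 <- d
  d2[7, 1, 13] <- 101
  r2 <- rejectAmplitude(makeEpochs(d2), 100)
  expect_equal(which(!r2$kept), 7L)
  expect_equal(r2$reasons[[7]], "amplitude")

  d3 <- d
  d3[5, 1, 2] <- NaN
  expect_error(rejectAmplitude(makeEpochs(d3)), "non-finite|NA")
})

test_that("injected spike trials are all caught", {
  sched <- smallSchedule(n_blocks = 2, trials_per_block = 12)
  p <- synthParams(noise_scale = 5, erp_amplitude = 2)
  sim <- simulateParticipant(sched, p, "younger", 2)
  ep <- renderEpochs(sched, sim$amplitudes, p, "younger", 2,
                     behavior = sim$behavior)$maintenance
  bad <- c(2, 5, 11, 17, 23)
  spiked <- injectSpikes(ep, bad, amplitude_uv = 150, seed = 9)
  r <- rejectAmplitude(spiked, 100)
  expect_equal(which(!r$kept), bad)
})

test_that("improbability/kurtosis rejection isolates heavy-tailed trials", {
  set.seed(3)
  d <- array(rnorm(200 * 1 * 300), c(200, 1, 300))
  d[57, 1, ] <- rt(300, df = 1)
  r <- rejectImprobableKurtotic(makeEpochs(d), z_threshold = 8)
  expect_false(r$kept[57])
  expect_true("kurtosis" %in% r$reasons[[57]])

  # degenerate: identical trials, all z are zero
  d0 <- array(rep(sin(seq_len(50)), each = 12), c(12, 1, 50))
  expect_true(all(rejectImprobableKurtotic(makeEpochs(d0), 8)$kept))
  # vacuous threshold
  expect_true(all(rejectImprobableKurtotic(makeEpochs(d), Inf)$kept))
  expect_error(rejectImprobableKurtotic(makeEpochs(d[1:5, , , drop = FALSE])),
               "10 trials")
})

test_that("rejection is idempotent and order-invariant", {
  set.seed(4)
  d <- array(rnorm(40 * 2 * 80, sd = 30), c(40, 2, 80))
  d[c(3, 31), 2, 10] <- 150
  ep <- makeEpochs(d)
  r1 <- rejectAmplitude(ep, 100)
  kept <- dropRejected(ep, r1)
  expect_true(all(rejectAmplitude(kept, 100)$kept))
  # permuting trials permutes but does not change the kept set
  perm <- sample(40)
  rp <- rejectAmplitude(makeEpochs(d[perm, , , drop = FALSE]), 100)
  expect_setequal(perm[!rp$kept], which(!r1$kept))
})

test_that("RT filtering applies the absolute and SD rules", {
  beh <- data.frame(trial_id = 1:4, rt_s = c(0.5, 0.6, 0.7, 6.0))
  out <- filterRT(beh)
  expect_equal(out$trial_id, 1:3)
  expect_equal(attr(out, "removed")$reason, "rt_slow")

  same <- data.frame(trial_id = 1:5, rt_s = rep(0.8, 5))
  expect_equal(nrow(filterRT(same)), 5L)

  # planted 3.5-SD outliers are exactly the removals
  set.seed(1)
  rt <- rnorm(1000, 0.8, 0.08)
  planted <- sample(1000, 10)
  rt[planted] <- mean(rt) + 3.5 * sd(rt)
  out2 <- filterRT(data.frame(trial_id = 1:1000, rt_s = rt),
                   max_rt_s = 5, sd_mult = 3)
  expect_setequal(attr(out2, "removed")$trial_id, planted)
  expect_error(filterRT(data.frame(trial_id = integer(), rt_s = numeric())),
               "empty")
})

test_that("phase-locked subtraction zeroes condition means and keeps
           induced power", {
  set.seed(6)
  tt <- seq(0, 2, by = 1 / 250)
  n <- 500
  d <- array(0, c(n, 1, length(tt)))
  for (i in seq_len(n)) d[i, 1, ] <- sin(2 * pi * 20 * tt + runif(1, 0, 2 * pi))
  labels <- rep(c(1, 2), each = n / 2)
  out <- subtractERP(makeEpochs(d), labels)
  for (cond in c(1, 2)) {
    avg <- colMeans(epochsData(out)[labels == cond, , , drop = FALSE],
                    dims = 1)
    expect_lt(max(abs(avg)), 1e-10)
  }
  # induced (random-phase) single-trial power barely changes
  expect_lt(abs(mean(epochsData(out)^2) - mean(d^2)) / mean(d^2), 0.05)

  # fully evoked case: identical trials go to zero
  dv <- array(rep(sin(2 * pi * 5 * tt), each = 10), c(10, 1, length(tt)))
  outv <- subtractERP(makeEpochs(dv), rep(1, 10))
  expect_lt(max(abs(epochsData(outv))), 1e-12)

  expect_error(subtractERP(makeEpochs(d), c(99, labels[-1])),
               "fewer than 2")
})
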