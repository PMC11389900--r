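test_that("relative variance matches the brute-force loop oracle", {
  tfr <- randomTFR(n_tr = 5, n_ch = 3, n_f = 4, n_t = 12, seed = 7)
  map <- relativeVariance(tfr, baseline_window = c(-0.3, -0.1))
  oracle <- oracleRelVar(tfrPower(tfr), tfrTimes(tfr), c(-0.3, -0.1))
  expect_lt(max(abs(relvarValues(map) - oracle)), 1e-12)
})

test_that("relative variance identity, decade, and error cases", {
  # window variance equal to baseline variance -> 0 everywhere
  set.seed(8)
  base <- rlnorm(20)
  p <- array(rep(base, 10), c(20, 1, 1, 10))
  tfr <- makeTFR(p, 20, seq(-0.4, 0.5, by = 0.1))
  expect_lt(max(abs(relvarValues(relativeVariance(tfr, c(-0.4, -0.1))))),
            1e-12)
  # variance x10 in the window -> log10 ratio 1
  p2 <- p
  p2[, , , 6:10] <- p[, , , 6:10] * sqrt(10)
  tfr2 <- makeTFR(p2, 20, seq(-0.4, 0.5, by = 0.1))
  rv <- relvarValues(relativeVariance(tfr2, c(-0.4, -0.1)))
  expect_equal(unique(round(as.vector(rv[, , 6:10]), 10)), 1)

  one <- makeTFR(p[1, , , , drop = FALSE], 20, seq(-0.4, 0.5, by = 0.1))
  expect_error(relativeVariance(one, c(-0.4, -0.1)), ">= 2 trials")
  flat <- makeTFR(array(1, c(5, 1, 1, 10)), 20, seq(-0.4, 0.5, by = 0.1))
  expect_error(relativeVariance(flat, c(-0.4, -0.1)), "zero baseline")
})

test_that("relative variance is exactly invariant to global power rescaling", {
  tfr <- randomTFR(n_tr = 6, n_ch = 2, n_f = 3, n_t = 10, seed = 9)
  sc <- makeTFR(tfrPower(tfr) * 123.4, tfrFreqs(tfr), tfrTimes(tfr))
  a <- relvarValues(relativeVariance(tfr, c(-0.3, -0.1)))
  b <- relvarValues(relativeVariance(sc, c(-0.3, -0.1)))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("aggregation nests frequency, time, then channels", {
  tfr <- randomTFR(n_tr = 5, n_ch = 5, n_f = 4, n_t = 12, seed = 10,
                   units = "dB")
  map <- relativeVariance(tfr, c(-0.3, -0.1))
  band <- c(15, 16); win <- c(0.1, 0.5)
  got <- aggregateVariability(map, band, win, channelLabels(map))
  r <- relvarValues(map)
  fi <- which(tfrFreqs(map) >= band[1] & tfrFreqs(map) <= band[2])
  ti <- which(tfrTimes(map) >= win[1] & tfrTimes(map) <= win[2])
  acc <- 0
  for (ch in 1:5) {
    s <- 0; k <- 0
    for (f in fi) for (t in ti) { s <- s + r[ch, f, t]; k <- k + 1 }
    acc <- acc + s / k
  }
  expect_lt(abs(got - acc / 5), 1e-12)

  # constant field and single-active-channel arithmetic
  cm <- map
  cm@relvar[] <- 0
  cm@relvar[2, , ] <- 1
  expect_equal(aggregateVariability(cm, band, win, channelLabels(map)), 0.2)
  cm@relvar[] <- 3.14
  expect_equal(aggregateVariability(cm, band, win, channelLabels(map)), 3.14)
  expect_error(aggregateVariability(map, c(99, 100), win,
                                    channelLabels(map)), "no frequencies")
})

test_that("within-trial variability is the time variance of band power", {
  # two-bin series {0, 2} dB -> sample variance 2
  p <- array(0, c(1, 1, 1, 2)); p[1, 1, 1, 2] <- 2
  tfr <- makeTFR(p, 20, c(0.1, 0.2), units = "dB")
  expect_equal(unname(withinTrialVariability(tfr, c(0, 0.3))), 2)

  const <- makeTFR(array(5, c(3, 1, 1, 8)), 20, seq(0, 3.5, by = 0.5),
                   units = "dB")
  expect_equal(unname(withinTrialVariability(const, c(0, 3.5))), rep(0, 3))

  set.seed(11)
  pr <- array(rnorm(10 * 2 * 3 * 9), c(10, 2, 3, 9))
  tfr2 <- makeTFR(pr, 15:17, seq(0, 4, by = 0.5), units = "dB")
  got <- withinTrialVariability(tfr2, c(0, 4), band = c(15, 17))
  for (i in 1:10)
    expect_lt(abs(got[i] - var(apply(pr[i, , , ], 3, mean))), 1e-12)
  expect_error(withinTrialVariability(tfr2, c(0, 0.4)), "fewer than 2")
})

test_that("median split behaves on hand cases and skewed power", {
  got <- medianSplitVariance(c(1, 2, 3, 4))
  expect_equal(got$var_high, 0.5)
  expect_equal(got$var_low, 0.5)
  expect_equal(got$n_high, 2L)

  set.seed(12)
  x <- rlnorm(1e4)
  ms <- medianSplitVariance(x)
  expect_gt(ms$var_high, ms$var_low)
  expect_error(medianSplitVariance(rep(1, 10)), "identical")
  expect_error(medianSplitVariance(c(1, 2, 3)), ">= 4")
})

test_that("planted variance ordering is recovered across replicates", {
  p <- synthParams(participant_sigma_sd = 0, participant_mu_sd = 0)
  ordered <- logical(12)
  for (r in seq_len(12)) {
    sched <- generateSchedule(taskConfig(), seed = 100 + r)
    sim <- simulateParticipant(sched, p, "younger", 100 + r)
    db <- dbNormalize(simulateBandPower(sched, sim$amplitudes, p, "younger",
                                        100 + r, "maintenance"),
                      c(-0.4, -0.1))
    agg <- vapply(c(1, 2, 4), function(s)
      aggregateVariability(
        relativeVariance(subsetTrials(db, sim$behavior$set_size == s),
                         c(-0.4, -0.1)),
        c(15, 25), c(0, 3), clusterSpec("frontal")), 0)
    ordered[r] <- agg[1] > agg[2] && agg[2] > agg[3]
  }
  expect_gte(sum(ordered), 10)
})
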