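test_that("a pure tone localizes at its frequency and scales as amplitude^2", {
  sf <- 250
  tt <- seq(-1, 3, by = 1 / sf)
  d <- array(0, c(3, 1, length(tt)))
  for (i in 1:3) d[i, 1, ] <- c(1, 2, 4)[i] * sin(2 * pi * 20 * tt)
  tfr <- morletTFR(makeEpochs(d, sf, tmin = -1),
                   spectralConfig(freqs_hz = 5:40))
  avg <- apply(tfrPower(tfr)[1, 1, , ], 1, mean, na.rm = TRUE)
  expect_equal(tfrFreqs(tfr)[which.max(avg)], 20)
  mid <- which.min(abs(tfrTimes(tfr) - 1))
  fi <- which(tfrFreqs(tfr) == 20)
  p <- tfrPower(tfr)[, 1, fi, mid]
  expect_lt(abs(p[2] / p[1] - 4), 0.04)
  expect_lt(abs(p[3] / p[2] - 4), 0.04)
})

test_that("zero signal yields zero power and short epochs are refused", {
  d <- array(0, c(2, 1, 1001))
  tfr <- morletTFR(makeEpochs(d), spectralConfig(freqs_hz = 10:20))
  expect_true(all(tfrPower(tfr) == 0 | is.na(tfrPower(tfr))))
  expect_error(morletTFR(makeEpochs(array(0, c(2, 1, 100))),
                         spectralConfig(freqs_hz = 1:40)),
               "epoch too short")
})

test_that("the FFT path equals direct time-domain convolution", {
  set.seed(1)
  sf <- 250
  d <- array(rnorm(2 * 1 * 600), c(2, 1, 600))
  cfg <- spectralConfig(freqs_hz = c(8, 14, 20, 35))
  tfr <- morletTFR(makeEpochs(d, sf, tmin = -1), cfg)
  idx <- round((tfrTimes(tfr) - (-1)) * sf) + 1
  for (tr in 1:2) for (k in seq_along(cfg$freqs_hz)) {
    po <- oracleMorletPower(d[tr, 1, ], cfg$freqs_hz[k], cfg$n_cycles[k],
                            sf)[idx]
    pm <- tfrPower(tfr)[tr, 1, k, ]
    expect_identical(is.na(pm), is.na(po))
    ok <- !is.na(pm)
    expect_lt(max(abs(pm[ok] - po[ok]) / pmax(abs(po[ok]), 1e-30)), 1e-8)
  }
})

test_that("decibel normalization matches its defining formula", {
  tfr <- randomTFR(n_tr = 4, n_ch = 2, n_f = 3, n_t = 12, seed = 2)
  db <- dbNormalize(tfr, baseline_window = c(-0.3, -0.1))
  p <- tfrPower(tfr)
  bidx <- which(tfrTimes(tfr) >= -0.3 & tfrTimes(tfr) <= -0.1)
  for (i in 1:4) for (ch in 1:2) for (f in 1:3) {
    expected <- 10 * log10(p[i, ch, f, ] / mean(p[i, ch, f, bidx]))
    expect_lt(max(abs(tfrPower(db)[i, ch, f, ] - expected)), 1e-10)
  }
  # identity and decade cases
  flat <- makeTFR(array(1, c(2, 1, 1, 10)), 20, seq(-0.4, 0.5, by = 0.1))
  expect_true(all(tfrPower(dbNormalize(flat, c(-0.4, -0.1))) == 0))
  dec <- array(1, c(2, 1, 1, 10)); dec[, , , 6:10] <- 10
  dtfr <- makeTFR(dec, 20, seq(-0.4, 0.5, by = 0.1))
  expect_equal(unique(as.vector(
    tfrPower(dbNormalize(dtfr, c(-0.4, -0.1)))[, , , 6:10])), 10)
  # global power rescaling leaves dB untouched
  sc <- makeTFR(tfrPower(tfr) * 7.3, tfrFreqs(tfr), tfrTimes(tfr))
  expect_equal(tfrPower(dbNormalize(sc, c(-0.3, -0.1))), tfrPower(db))
})

test_that("SNR equals window mean over standard error of the trial mean", {
  # two-point hand computation: window means {1, 3} -> mean 2, SE 1, SNR 2
  p <- array(0, c(2, 1, 1, 6))
  p[1, 1, 1, ] <- 1; p[2, 1, 1, ] <- 3
  tfr <- makeTFR(p, 20, seq(0, 2.5, by = 0.5))
  expect_equal(as.vector(computeSNR(tfr, c(0, 2.5))), 2)

  set.seed(3)
  pr <- array(rlnorm(100 * 2 * 2 * 8), c(100, 2, 2, 8))
  tfr2 <- makeTFR(pr, c(15, 25), seq(0, 3.5, by = 0.5))
  got <- computeSNR(tfr2, c(0, 3.5))
  for (ch in 1:2) for (f in 1:2) {
    wm <- apply(pr[, ch, f, ], 1, mean)
    expect_lt(abs(got[ch, f] - mean(wm) / (sd(wm) / 10)), 1e-12)
  }
  ident <- makeTFR(array(1, c(3, 1, 1, 4)), 20, seq(0, 1.5, by = 0.5))
  expect_error(computeSNR(ident, c(0, 1.5)), "zero cross-trial SD")
})
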