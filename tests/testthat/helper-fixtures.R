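# Shared fixtures and independent oracles, all built in code.

# epochs holding an arbitrary trials x channels x samples array
makeEpochs <- function(d, sfreq = 250, tmin = 0, lock = "maintenance",
                       channels = paste0("ch", seq_len(dim(d)[2]))) {
  trialvar:::newEpochs(d, sfreq, tmin, lock, channels, seq_len(dim(d)[1]))
}

# TFR holding an arbitrary trials x channels x freqs x times array
makeTFR <- function(p, freqs, times, units = "raw_power",
                    lock = "maintenance",
                    channels = paste0("ch", seq_len(dim(p)[2]))) {
  trialvar:::newTFR(p, freqs, times, units, lock, channels,
                    seq_len(dim(p)[1]))
}

randomTFR <- function(n_tr = 5, n_ch = 3, n_f = 4, n_t = 12, seed = 1,
                      units = "raw_power") {
  set.seed(seed)
  p <- array(exp(rnorm(n_tr * n_ch * n_f * n_t)), c(n_tr, n_ch, n_f, n_t))
  makeTFR(p, freqs = seq_len(n_f) + 14, times = seq(-0.3, by = 0.1,
                                                    length.out = n_t),
          units = units)
}

# independent direct time-domain Morlet convolution (loop, no FFT)
oracleMorletPower <- function(x, f, n_cycles, sfreq) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3 * sigma_t * sfreq)
  tt <- (-half:half) / sfreq
  w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2)) /
    (sigma_t * sqrt(2 * pi) * sfreq)
  n <- length(x)
  out <- rep(NA_complex_, n)
  if (n >= 2 * half + 1)
    for (s in (half + 1):(n - half))
      out[s] <- sum(x[(s + half):(s - half)] * w)
  Mod(out)^2
}

# brute-force loop version of the relative-variance map
oracleRelVar <- function(p, times, baseline) {
  d <- dim(p)
  v <- array(NA_real_, d[2:4])
  for (ch in seq_len(d[2])) for (f in seq_len(d[3])) for (t in seq_len(d[4]))
    v[ch, f, t] <- var(p[, ch, f, t])
  bidx <- which(times >= baseline[1] & times <= baseline[2])
  out <- array(NA_real_, d[2:4])
  for (ch in seq_len(d[2])) for (f in seq_len(d[3])) {
    bv <- mean(v[ch, f, bidx])
    for (t in seq_len(d[4])) out[ch, f, t] <- log10(v[ch, f, t] / bv)
  }
  out
}

# exhaustive two-sample permutation p for the Welch t (independent of the
# package's implementation)
oraclePermP <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  tstat <- function(x, y) (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  obs <- tstat(a, b)
  ts <- apply(idx, 2, function(j) tstat(pool[j], pool[-j]))
  mean(abs(ts) >= abs(obs) - 1e-12)
}

smallSchedule <- function(n_blocks = 2, trials_per_block = 6, seed = 1)
  generateSchedule(taskConfig(n_blocks = n_blocks,
                              trials_per_block = trials_per_block),
                   seed = seed)
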