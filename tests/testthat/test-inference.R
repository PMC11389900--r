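test_that("per-participant OLS slope matches the hand computation", {
  vals <- data.frame(participant = rep(c("a", "b"), each = 3),
                     set_size = rep(c(1, 2, 4), 2),
                     value = c(3, 2, 1, 3, 2, 1))
  # identical slopes: degenerate SD, p reported as 1 with a warning
  expect_warning(res <- loadSlopeTest(vals), "degenerate")
  expect_equal(unname(res$slopes), rep(-27 / 42, 2), tolerance = 1e-12)
  expect_equal(res$p, 1)

  bad <- vals[-1, ]
  expect_error(loadSlopeTest(bad), "per set size")
})

test_that("the slope test detects a planted population slope", {
  set.seed(20)
  hits <- 0
  for (r in 1:50) {
    slopes <- rnorm(20, -0.08, 0.05)
    vals <- do.call(rbind, lapply(1:20, function(i)
      data.frame(participant = i, set_size = c(1, 2, 4),
                 value = slopes[i] * c(1, 2, 4) + rnorm(3, 0, 0.01))))
    if (loadSlopeTest(vals)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 40)  # >= 80% power at the planted effect size
})

test_that("permutation t test agrees with exhaustive enumeration", {
  a <- c(1, 2); b <- c(10, 11)
  res <- permutationTTest(a, b)
  expect_true(res$exact)
  expect_equal(res$p, oraclePermP(a, b))

  set.seed(21)
  a2 <- rnorm(5); b2 <- rnorm(5) + 1
  res2 <- permutationTTest(a2, b2)   # 252 assignments -> exact mode
  expect_true(res2$exact)
  expect_equal(res2$p, oraclePermP(a2, b2))

  # identical multisets: p = 1
  expect_equal(permutationTTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(permutationTTest(c(1, 1), c(1, 1)), "degenerate")
})

test_that("Monte-Carlo permutation p respects its resolution and detects
           a planted shift", {
  set.seed(22)
  ps <- vapply(1:5, function(r) {
    a <- rnorm(100); b <- rnorm(100) + 0.8
    permutationTTest(a, b, n_perm = 10000, seed = r)$p
  }, 0)
  expect_true(all(ps < 0.001))
  expect_true(all(ps >= 1 / 10001))
})

test_that("cluster permutation finds planted clusters and nothing on
           sub-threshold fields", {
  chain <- adjacencyFromEdges(data.frame(a = paste0("c", 1:9),
                                         b = paste0("c", 2:10)))
  # sub-threshold field: per-channel t all below the forming threshold
  set.seed(23)
  repeat {
    d0 <- matrix(rnorm(20 * 10, 0, 1), 20, 10,
                 dimnames = list(NULL, paste0("c", 1:10)))
    tv <- colMeans(d0) / (apply(d0, 2, sd) / sqrt(20))
    if (max(abs(tv)) < qt(0.975, 19)) break
  }
  r0 <- channelClusterPermutation(d0, chain, n_perm = 100, seed = 1)
  expect_length(r0$clusters, 0)

  # planted effect on channels 1-3 of the chain
  hits <- 0
  for (r in 1:20) {
    set.seed(300 + r)
    d <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(NULL, paste0("c", 1:10)))
    d[, 1:3] <- d[, 1:3] + 1.2
    res <- channelClusterPermutation(d, chain, n_perm = 200, seed = r)
    if (length(res$clusters)) {
      top <- res$clusters[[1]]$channels
      if (all(paste0("c", 1:3) %in% top) &&
          all(top %in% paste0("c", 1:4))) hits <- hits + 1
    }
  }
  expect_gte(hits, 17)

  # uniform strong effect: one cluster covering every channel
  dall <- matrix(rnorm(20 * 10) + 3, 20, 10,
                 dimnames = list(NULL, paste0("c", 1:10)))
  rall <- channelClusterPermutation(dall, chain, n_perm = 100, seed = 2)
  expect_length(rall$clusters, 1)
  expect_setequal(rall$clusters[[1]]$channels, paste0("c", 1:10))
  expect_error(channelClusterPermutation(
    d0[, 1:3], chain[1:2, 1:2], n_perm = 10), "cover")

  # the bundled montage adjacency parses to the built-in neighbor graph
  f <- system.file("extdata", "montage_adjacency.tsv", package = "trialvar")
  adj <- readAdjacency(f)
  def <- defaultAdjacency()
  expect_identical(adj[rownames(def), colnames(def)], def)
})

test_that("subsampled contrast is unbiased under the null and degenerate
           when sizes match", {
  set.seed(24)
  correct <- rlnorm(500); incorrect <- rlnorm(100)
  res <- subsampledContrast(correct, incorrect, n_iter = 400, seed = 3)
  se <- sd(res$iter_correct) / sqrt(res$n_iter) + sd(incorrect) / 5
  expect_lt(abs(res$mean_diff), 3 * max(se, 0.3))

  eq <- subsampledContrast(1:10, 11:20, seed = 4)
  expect_equal(sd(eq$iter_correct), 0)
  expect_error(subsampledContrast(1:3, 1:5), "swap the roles")

  # planted variance ratio: positive mean difference in most replicates
  pos <- 0
  for (r in 1:40) {
    set.seed(400 + r)
    res2 <- subsampledContrast(rnorm(300, sd = sqrt(1.5)), rnorm(60),
                               n_iter = 100, seed = r)
    if (res2$mean_diff > 0) pos <- pos + 1
  }
  expect_gte(pos, 34)
})

test_that("lagged design drops block boundaries and broken chains", {
  beh <- data.frame(trial_id = 0:9, block_index = rep(0:1, each = 5),
                    set_size = rep(c(1, 2, 4, 1, 2), 2),
                    accuracy = rep(1, 10), rt_s = rep(0.5, 10),
                    group = "younger",
                    maintenance = rnorm(10), post_response = rnorm(10))
  one <- buildLaggedDesign(beh[beh$block_index == 0, ])
  expect_equal(nrow(one), 4L)
  two <- buildLaggedDesign(beh)
  expect_equal(nrow(two), 8L)
  expect_false(5 %in% two$trial_id[two$trial_id - 1 %in% c(4)])

  # rejecting trial 3 (id 2) of a 6-trial block removes its row and its
  # successor's lag
  beh6 <- data.frame(trial_id = 0:5, block_index = 0,
                     set_size = 1, accuracy = 1, rt_s = 0.5,
                     group = "younger", maintenance = rnorm(6),
                     post_response = rnorm(6))
  kept <- beh6[beh6$trial_id != 2, ]
  lag <- buildLaggedDesign(kept)
  expect_equal(nrow(lag), 3L)
  expect_setequal(lag$trial_id, c(1, 4, 5))
  expect_equal(lag$post_power_prev[lag$trial_id == 4],
               kept$post_response[kept$trial_id == 3])
})

test_that("mixed-model fits report sane coefficient tables", {
  set.seed(25)
  d <- data.frame(participant = factor(rep(1:10, each = 6)),
                  group = rep(c("younger", "older"), each = 30),
                  set_size = rep(c(1, 2, 4), 20))
  d$value <- 5
  fit0 <- fitMixedModel(d, modelSpec("value", "group * set_size",
                                     "(1 | participant)", "normal"))
  est <- fit0$coefficients
  expect_lt(max(abs(est$estimate[est$term != "(Intercept)"])), 1e-8)

  d$value <- rnorm(60) + as.numeric(d$group == "younger") * d$set_size
  fit <- fitMixedModel(d, modelSpec("value", "group * set_size",
                                    "(1 | participant)", "normal"))
  expect_true(fit$converged)
  expect_true("group:set_size" %in% rownames(fit$anova))
  expect_lt(fit$anova["group:set_size", "Pr(>F)"], 0.01)
})

test_that("group x load interaction power and the N+1 machinery", {
  # planted interaction: younger slope -0.07, older 0, noise SD 0.05
  set.seed(26)
  hits <- 0
  for (r in 1:30) {
    rows <- do.call(rbind, lapply(1:40, function(i) {
      g <- if (i <= 20) "younger" else "older"
      sl <- if (g == "younger") -0.07 else 0
      data.frame(participant = i, group = g, set_size = c(1, 2, 4),
                 value = 0.5 + sl * c(1, 2, 4) + rnorm(3, 0, 0.05))
    }))
    fit <- fitGroupVariability(rows)
    if (fit$anova["group:set_size", "Pr(>F)"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 24)

  # constant lag predictor is refused
  beh <- data.frame(trial_id = 0:49, block_index = 0, set_size = 1,
                    accuracy = rbinom(50, 1, 0.8), rt_s = 0.5,
                    group = "older", maintenance = rnorm(50),
                    post_response = 1)
  lag <- buildLaggedDesign(beh)
  expect_error(fitNPlus1(lag), "no variance")
})

test_that("N-N models use the stated families and refuse bad domains", {
  sched <- generateSchedule(taskConfig(n_blocks = 10), seed = 27)
  p <- synthParamsNull()
  sims <- lapply(1:4, function(i) {
    s <- simulateParticipant(sched, p, "younger", 500 + i)
    cbind(s$behavior, s$amplitudes[, c("maintenance", "post_response")],
          participant = paste0("p", i))
  })
  d <- do.call(rbind, sims)
  fits <- fitNN(d, fast = TRUE)
  expect_named(fits, c("accuracy_on_power", "rt_on_power",
                       "power_on_accuracy", "power_on_rt"))
  expect_equal(fits$rt_on_power$spec$family, "gamma")
  expect_equal(fits$accuracy_on_power$spec$link, "logit")
  # planted-null couplings: the power coefficients should be ns here
  expect_gt(coefRow(fits$accuracy_on_power, "post_power_c")$p, 0.001)

  bad <- d; bad$rt_s[3] <- -1
  expect_error(fitNN(bad), "non-positive")
})
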