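## Orchestration: configuration, multi-participant simulation, the analysis
## battery, and the end-to-end waveform pipeline with persisted outputs.

#' Subset trials of an epochs or TFR object
#'
#' @param x [EEGEpochs-class] or [TrialTFR-class]
#' @param idx logical or integer trial positions
#' @return object of the same class
#' @export
subsetTrials <- function(x, idx) {
  if (is(x, "EEGEpochs")) {
    newEpochs(x@data[idx, , , drop = FALSE], x@sfreq, x@tmin, x@lock,
              x@channels, x@trialIds[idx])
  } else if (is(x, "TrialTFR")) {
    newTFR(x@power[idx, , , , drop = FALSE], x@freqs, x@times, x@units,
           x@lock, x@channels, x@trialIds[idx])
  } else stop("unsupported class: ", class(x)[1])
}

#' Analysis run configuration
#'
#' Bundles the task design, generator parameters, spectral settings, the
#' analysis windows (maintenance 0-3 s; post-response 0.1-0.5 s, first
#' 100 ms discarded against motor artifacts; per-item encoding 0-1.2 s;
#' decibel/variance baseline -0.4..-0.1 s), channel clusters and seeds.
#'
#' @param task a [taskConfig()]
#' @param synth a [synthParams()]
#' @param spectral a [spectralConfig()]
#' @param windows named list: maintenance, post_response, encoding_item,
#'   baseline -- (start, end) seconds
#' @param cluster analysis [clusterSpec()]
#' @param n_per_group synthetic participants per group
#' @param groups group names to simulate
#' @param seed master seed; required (every stochastic stage derives its
#'   stream from it)
#' @param mode "power" (band-power simulation, replicate-scale studies) or
#'   "waveform" (full rendering + Morlet decomposition)
#' @param out_dir output directory for persisted stage outputs (NULL: do not
#'   persist)
#' @return validated list of class "runConfig"
#' @export
runConfig <- function(task = taskConfig(), synth = synthParams(),
                      spectral = spectralConfig(),
                      windows = list(maintenance = c(0, 3),
                                     post_response = c(0.1, 0.5),
                                     encoding_item = c(0, 1.2),
                                     baseline = c(-0.4, -0.1)),
                      cluster = clusterSpec("frontal"),
                      n_per_group = 20L, groups = c("younger", "older"),
                      seed = NULL, mode = c("power", "waveform"),
                      out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(seed) || !is.finite(seed))
    stop("seed is required before any compute")
  need <- c("maintenance", "post_response", "encoding_item", "baseline")
  if (!all(need %in% names(windows)))
    stop("windows must name: ", paste(need, collapse = ", "))
  if (windows$maintenance[2] > 3.5 || windows$post_response[2] > 1.0)
    stop("analysis windows exceed the epoch spans")
  validateTaskConfig(task)
  validateSynthParams(synth)
  cfg <- list(task = task, synth = synth, spectral = spectral,
              windows = windows, cluster = cluster,
              n_per_group = as.integer(n_per_group), groups = groups,
              seed = as.integer(seed), mode = mode, out_dir = out_dir)
  class(cfg) <- c("runConfig", "list")
  cfg
}

## Per-participant variability aggregates + per-trial band powers from a
## pair of dB-normalized TFRs. Shared by the power and waveform paths.
participantSummaries <- function(db_m, db_r, behavior, windows, cluster,
                                 band = c(15, 25)) {
  sizes <- sort(unique(behavior$set_size))
  relAgg <- function(tfr, window) {
    vapply(sizes, function(s) {
      sub <- subsetTrials(tfr, behavior$set_size == s)
      map <- relativeVariance(sub, windows$baseline)
      aggregateVariability(map, band, window, cluster)
    }, 0)
  }
  v_m <- relAgg(db_m, windows$maintenance)
  v_r <- relAgg(db_r, windows$post_response)
  powers <- data.frame(
    trial_id = trialIds(db_m),
    maintenance = trialBandPower(db_m, band, windows$maintenance,
                                 cluster$channels),
    post_response = trialBandPower(db_r, band, windows$post_response,
                                   cluster$channels))
  list(variability = data.frame(set_size = rep(sizes, 2),
                                phase = rep(c("maintenance", "post_response"),
                                            each = length(sizes)),
                                value = c(v_m, v_r)),
       powers = powers)
}

#' Simulate a multi-participant study
#'
#' Draws `n_per_group` synthetic participants per group, each with their own
#' seeded schedule, amplitude/behavior chain and band-power (or waveform)
#' data, and reduces each to the per-condition variability aggregates and
#' per-trial band powers the inference battery consumes.
#'
#' @param config a [runConfig()]
#' @return list of class "studyData": `variability` (participant, group,
#'   set_size, phase, value), `trials` (behavior + per-trial maintenance /
#'   post-response band power), `config`
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  var_rows <- list(); trial_rows <- list()
  k <- 0L
  band <- bandEdges("beta", config$synth$band_defs)
  for (g in config$groups) {
    for (p in seq_len(config$n_per_group)) {
      k <- k + 1L
      pid <- sprintf("%s_%02d", substr(g, 1, 1), p)
      sp <- deriveSeed(config$seed, k)
      sched <- generateSchedule(config$task, seed = sp)
      sim <- simulateParticipant(sched, config$synth, g, sp)
      if (config$mode == "power") {
        tfr_m <- simulateBandPower(sched, sim$amplitudes, config$synth, g,
                                   sp, "maintenance")
        tfr_r <- simulateBandPower(sched, sim$amplitudes, config$synth, g,
                                   sp, "response")
        db_m <- dbNormalize(tfr_m, config$windows$baseline)
        db_r <- dbNormalize(tfr_r, config$windows$baseline)
        beh <- sim$behavior
      } else {
        ep <- renderEpochs(sched, sim$amplitudes, config$synth, g, sp,
                           behavior = sim$behavior)
        keep <- preprocessEpochs(ep, sim$behavior)
        beh <- sim$behavior[keep$kept, ]
        db_m <- dbNormalize(morletTFR(keep$maintenance, config$spectral),
                            config$windows$baseline, on_invalid = "drop")
        db_r <- dbNormalize(morletTFR(keep$response, config$spectral),
                            config$windows$baseline, on_invalid = "drop")
      }
      s <- participantSummaries(db_m, db_r, beh, config$windows,
                                config$cluster, band)
      s$variability$participant <- pid
      s$variability$group <- g
      tr <- merge(beh, s$powers, by = "trial_id")
      tr$participant <- pid
      var_rows[[k]] <- s$variability
      trial_rows[[k]] <- tr
    }
  }
  res <- list(variability = do.call(rbind, var_rows),
              trials = do.call(rbind, trial_rows), config = config)
  class(res) <- "studyData"
  res
}

## Waveform-path cleaning: amplitude + improbability/kurtosis rejection
## (union over both locks) and per-set-size phase-locked subtraction.
preprocessEpochs <- function(ep, behavior, threshold_uv = 100,
                             z_threshold = 8) {
  rep_m <- mergeReports(rejectAmplitude(ep$maintenance, threshold_uv),
                        rejectImprobableKurtotic(ep$maintenance, z_threshold))
  rep_r <- mergeReports(rejectAmplitude(ep$response, threshold_uv),
                        rejectImprobableKurtotic(ep$response, z_threshold))
  kept <- rep_m$kept & rep_r$kept
  m <- dropRejected(ep$maintenance, kept)
  r <- dropRejected(ep$response, kept)
  labels <- behavior$set_size[kept]
  list(maintenance = subtractERP(m, labels),
       response = subtractERP(r, labels),
       kept = kept, report = mergeReports(rep_m, rep_r))
}

#' Run the inference battery on simulated (or assembled) study data
#'
#' Computes, per group, the load-slope test on maintenance variability; the
#' group x set-size linear mixed model; the N+1 lagged accuracy GLMM (pooled
#' with a group x lag interaction, plus separate per-group fits); and the
#' correct/incorrect subsampled contrast of post-response log-variance at
#' the highest load, with a one-sample t test across participants per group.
#'
#' @param study "studyData" from [simulateStudy()]
#' @param alpha nominal level used by [recoveryPattern()]
#' @param per_group also fit per-group N+1 models
#' @param accuracy_model also fit the accuracy ~ group x variability GLMM
#' @param n_iter subsampling iterations for the contrast
#' @param fast nAGQ = 0 for the GLMM fits
#' @return list of class "studyResult"
#' @export
analyzeStudy <- function(study, alpha = 0.05, per_group = TRUE,
                         accuracy_model = FALSE, n_iter = 200, fast = TRUE) {
  v <- study$variability
  trials <- study$trials
  groups <- unique(v$group)
  maint <- v[v$phase == "maintenance", ]

  slopes <- lapply(setNames(groups, groups), function(g)
    loadSlopeTest(maint[maint$group == g, ]))
  interaction_fit <- if (length(groups) > 1L)
    fitGroupVariability(maint) else NULL

  lagged <- buildLaggedDesign(trials)
  nplus1 <- list(pooled = fitNPlus1(lagged, fast = fast))
  if (per_group && length(groups) > 1L)
    for (g in groups) nplus1[[g]] <- fitNPlus1(lagged, group = g, fast = fast)

  hi_load <- max(trials$set_size)
  contrast_rows <- lapply(split(trials[trials$set_size == hi_load, ],
                                trials$participant[trials$set_size == hi_load]),
    function(dp) {
      corr <- dp$post_response[dp$accuracy == 1]
      inc <- dp$post_response[dp$accuracy == 0]
      if (length(inc) < 2L || length(corr) < length(inc)) return(NULL)
      sc <- subsampledContrast(corr, inc,
                               statistic = function(x) log10(var(x)),
                               n_iter = n_iter,
                               seed = deriveSeed(study$config$seed,
                                                 match(dp$participant[1],
                                                       unique(trials$participant))))
      data.frame(participant = dp$participant[1], group = dp$group[1],
                 diff = sc$mean_diff)
    })
  contrast <- do.call(rbind, contrast_rows)
  contrast_tests <- lapply(setNames(groups, groups), function(g) {
    d <- contrast$diff[contrast$group == g]
    if (length(d) < 3L) return(NULL)
    t.test(d, mu = 0)
  })

  acc_fit <- NULL
  if (accuracy_model) {
    agg <- do.call(rbind, lapply(split(trials,
                                       list(trials$participant,
                                            trials$set_size), drop = TRUE),
      function(dp) data.frame(participant = dp$participant[1],
                              group = dp$group[1],
                              set_size = dp$set_size[1],
                              accuracy = mean(dp$accuracy))))
    agg <- merge(agg, setNames(maint[, c("participant", "set_size", "value")],
                               c("participant", "set_size", "variability")))
    acc_fit <- tryCatch(fitAccuracyOnVariability(agg, fast = fast),
                        error = function(e) NULL)
  }

  res <- list(slopes = slopes, interaction = interaction_fit,
              nplus1 = nplus1, contrast = contrast,
              contrast_tests = contrast_tests,
              accuracy_model = acc_fit, alpha = alpha, groups = groups)
  class(res) <- "studyResult"
  res
}

#' Does a study result show the planted qualitative pattern?
#'
#' Three components, judged at `alpha`: (a) a significant negative
#' maintenance variability slope in the younger group while the older group
#' shows no significant negative slope; (b) a significant positive lag
#' (previous-trial post-response power) coefficient in the older group's
#' separate N+1 model while the younger group shows no significant positive
#' one; (c) a positive correct-minus-incorrect post-response log-variance
#' contrast (significant one-sample t) in both groups.
#'
#' @param res "studyResult" from [analyzeStudy()]
#' @param alpha significance level for every component
#' @return named logical vector: slope_pattern, lag_pattern,
#'   contrast_pattern, all
#' @export
recoveryPattern <- function(res, alpha = 0.05) {
  sl_y <- res$slopes$younger; sl_o <- res$slopes$older
  a <- !is.na(sl_y$p) && sl_y$p < alpha && sl_y$mean_slope < 0 &&
    !(isTRUE(sl_o$p < alpha) && sl_o$mean_slope < 0)
  lag_y <- coefRow(res$nplus1$younger, "post_power_prev_c")
  lag_o <- coefRow(res$nplus1$older, "post_power_prev_c")
  b <- lag_o$estimate > 0 && lag_o$p < alpha &&
    !(lag_y$estimate > 0 && lag_y$p < alpha)
  ct_y <- res$contrast_tests$younger; ct_o <- res$contrast_tests$older
  ok_ct <- function(ct) !is.null(ct) && unname(ct$estimate) > 0 &&
    ct$p.value < alpha
  c_ <- ok_ct(ct_y) && ok_ct(ct_o)
  c(slope_pattern = a, lag_pattern = b, contrast_pattern = c_,
    all = a && b && c_)
}

#' Simulate and analyze in one call
#'
#' @param config a [runConfig()]
#' @param ... passed to [analyzeStudy()]
#' @return "studyResult" with the study data attached as `$study`
#' @export
runStudy <- function(config, ...) {
  study <- simulateStudy(config)
  res <- analyzeStudy(study, ...)
  res$study <- study
  res
}

## ---------------------------------------------------------------------------
## Headline tables, persistence, full pipeline
## ---------------------------------------------------------------------------

#' Flatten a study result into headline tables
#'
#' @param res "studyResult"
#' @return named list of data.frames: slopes, interaction, nplus1, contrast
#' @export
headlineTables <- function(res) {
  slopes <- do.call(rbind, lapply(names(res$slopes), function(g) {
    s <- res$slopes[[g]]
    data.frame(group = g, mean_slope = s$mean_slope, t = s$t, df = s$df,
               p = s$p, cohens_d = s$cohens_d)
  }))
  inter <- if (!is.null(res$interaction)) {
    a <- res$interaction$anova
    cbind(term = rownames(a), as.data.frame(a), row.names = NULL)
  } else data.frame()
  np <- do.call(rbind, lapply(names(res$nplus1), function(m) {
    tab <- res$nplus1[[m]]$coefficients
    cbind(model = m, tab[grepl("post_power_prev_c", tab$term), ,
                         drop = FALSE])
  }))
  rownames(np) <- NULL
  ct <- do.call(rbind, lapply(names(res$contrast_tests), function(g) {
    tt <- res$contrast_tests[[g]]
    if (is.null(tt)) return(NULL)
    data.frame(group = g, mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  list(slopes = slopes, interaction = inter, nplus1 = np, contrast = ct)
}

## cheap deterministic provenance hash (31-bit polynomial rolling hash)
fnvHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

writeTSV <- function(df, path) {
  write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline and persist every headline output
#'
#' simulate -> preprocess -> time-frequency -> variability -> stats ->
#' report, fully deterministic given the config seed. Writes variability,
#' behavioral, slope, interaction, N+1 and contrast tables plus a
#' provenance record (config hash, seed, per-file hashes) to
#' `config$out_dir`.
#'
#' @param config a [runConfig()]; `out_dir` may be NULL to skip persistence
#' @param ... passed to [analyzeStudy()]
#' @return list of class "runReport": tables, files, provenance
#' @export
runPipeline <- function(config, ...) {
  res <- runStudy(config, ...)
  tabs <- headlineTables(res)
  tabs$variability <- res$study$variability
  tabs$behavior <- res$study$trials[, setdiff(names(res$study$trials),
                                              c("maintenance",
                                                "post_response"))]
  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tabs)) {
      f <- file.path(config$out_dir, paste0(nm, ".tsv"))
      writeTSV(tabs[[nm]], f)
      files[nm] <- f
    }
    prov <- list(seed = config$seed, mode = config$mode,
                 config_hash = fnvHash(yaml::as.yaml(
                   config[c("task", "windows", "n_per_group", "groups",
                            "mode")])),
                 file_hashes = lapply(files, function(f)
                   fnvHash(readLines(f))))
    yaml::write_yaml(prov, file.path(config$out_dir, "provenance.yaml"))
    files["provenance"] <- file.path(config$out_dir, "provenance.yaml")
  }
  rep <- list(tables = tabs, files = files, result = res)
  class(rep) <- "runReport"
  rep
}

#' @export
print.studyResult <- function(x, ...) {
  cat("studyResult (groups:", paste(x$groups, collapse = ", "), ")\n")
  for (g in names(x$slopes))
    cat(sprintf("  %s mean maintenance slope: %.4f (p = %.3g)\n", g,
                x$slopes[[g]]$mean_slope, x$slopes[[g]]$p))
  invisible(x)
}
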