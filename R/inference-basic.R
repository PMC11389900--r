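## Slope, permutation, cluster-permutation and subsampling procedures.

#' Load-slope test
#'
#' Ordinary least squares of a per-participant statistic on numeric set size
#' (memory load), followed by a two-tailed one-sample t test of the
#' per-participant slopes against zero at the population level. Set size is
#' entered numerically (1, 2, 4), i.e. the test asks for a linear trend of
#' the statistic across loads.
#'
#' @param values data.frame with columns `participant`, `set_size`, `value`;
#'   every participant must contribute every set size
#' @return list of class "slopeResult": per-participant slopes/intercepts,
#'   mean_slope, t, df, p, cohens_d
#' @export
loadSlopeTest <- function(values) {
  need <- c("participant", "set_size", "value")
  if (!all(need %in% names(values))) stop("values needs columns: ",
                                          paste(need, collapse = ", "))
  sizes <- sort(unique(values$set_size))
  tab <- table(values$participant, values$set_size)
  if (any(tab != 1L))
    stop("every participant must have exactly one value per set size")
  participants <- rownames(tab)
  fits <- t(vapply(participants, function(p) {
    d <- values[values$participant == p, ]
    x <- d$set_size; y <- d$value
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    c(slope = b, intercept = mean(y) - b * mean(x))
  }, c(slope = 0, intercept = 0)))
  slopes <- fits[, "slope"]
  n <- length(slopes)
  res <- list(participants = participants, slopes = slopes,
              intercepts = fits[, "intercept"],
              mean_slope = mean(slopes), df = n - 1L)
  if (sd(slopes) == 0) {
    # all slopes identical: t undefined (0/0); report p = 1 by contract
    warning("degenerate slope SD; p set to 1")
    res$t <- NA_real_; res$p <- 1; res$cohens_d <- NA_real_
  } else {
    tt <- t.test(slopes, mu = 0)
    res$t <- unname(tt$statistic)
    res$p <- tt$p.value
    res$cohens_d <- mean(slopes) / sd(slopes)
  }
  class(res) <- "slopeResult"
  res
}

#' @export
print.slopeResult <- function(x, ...) {
  cat(sprintf("slopeResult: mean slope = %.4f, t(%d) = %s, p = %.4g\n",
              x$mean_slope, x$df,
              if (is.na(x$t)) "NA" else sprintf("%.3f", x$t), x$p))
  invisible(x)
}

welchT <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

#' Permutation t test
#'
#' Two-sample Welch t statistic with a label-shuffling null. When the total
#' number of distinct label assignments `choose(na+nb, na)` is at most
#' `exact_limit`, the null is enumerated exhaustively and the p value is the
#' exact proportion of assignments with |t| at least the observed (the
#' identity assignment guarantees p >= 1/total). Otherwise `n_perm` random
#' shuffles are drawn and `p = (k + 1) / (n_perm + 1)`, two-tailed by |t|.
#'
#' @param a,b numeric samples, each of length >= 2
#' @param n_perm number of random permutations
#' @param seed integer seed
#' @param alpha nominal level carried in the result
#' @param exact_limit enumeration threshold on the number of assignments
#' @return list of class "permutationResult": observed, p, n_perm, exact,
#'   alpha
#' @export
permutationTTest <- function(a, b, n_perm = 10000, seed = 1, alpha = 0.001,
                             exact_limit = 1e4) {
  if (length(a) < 2L || length(b) < 2L) stop("both groups need >= 2 values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) stop("degenerate variance in both groups")
    stop("degenerate variance in both groups; t undefined")
  }
  pool <- c(a, b)
  na <- length(a); nb <- length(b)
  obs <- welchT(a, b)
  n_total <- choose(na + nb, na)
  if (n_total <= exact_limit) {
    idx <- combn(na + nb, na)
    ts <- apply(idx, 2L, function(j) welchT(pool[j], pool[-j]))
    ts[!is.finite(ts)] <- Inf  # degenerate splits count as extreme
    p <- mean(abs(ts) >= abs(obs) - 1e-12)
    res <- list(observed = obs, p = p, n_perm = n_total, exact = TRUE,
                alpha = alpha)
  } else {
    ts <- withSeed(seed, vapply(seq_len(n_perm), function(i) {
      j <- sample.int(na + nb, na)
      welchT(pool[j], pool[-j])
    }, 0))
    k <- sum(abs(ts) >= abs(obs) - 1e-12)
    res <- list(observed = obs, p = (k + 1) / (n_perm + 1), n_perm = n_perm,
                exact = FALSE, alpha = alpha)
  }
  class(res) <- "permutationResult"
  res
}

#' @export
print.permutationResult <- function(x, ...) {
  cat(sprintf("permutationResult: t = %.3f, p = %.4g (%s, %d assignments)\n",
              x$observed, x$p, if (x$exact) "exact" else "Monte Carlo",
              x$n_perm))
  invisible(x)
}

## Connected components among `active` nodes of an adjacency matrix (BFS).
connectedComponents <- function(adj, active) {
  comp <- integer(0)
  seen <- rep(FALSE, length(active))
  names(seen) <- active
  out <- list()
  for (v in active) {
    if (seen[[v]]) next
    queue <- v; members <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (seen[[u]]) next
      seen[[u]] <- TRUE
      members <- c(members, u)
      nbr <- intersect(colnames(adj)[adj[u, ] > 0], active)
      queue <- c(queue, nbr[!vapply(nbr, function(w) seen[[w]], TRUE)])
    }
    out[[length(out) + 1L]] <- members
  }
  out
}

#' Sensor-space cluster-based permutation test
#'
#' Paired (one-sample) t per channel on per-participant condition
#' differences; channels whose |t| exceeds the two-tailed critical value at
#' `cluster_alpha` are joined into connected clusters under the neighbor
#' graph, separately for positive and negative effects. Cluster mass is the
#' sum of t values. The null distribution of the maximum |mass| is built by
#' sign-flipping participants; each observed cluster's p is the proportion of
#' null max-masses at least its own.
#'
#' @param diffs participants x channels matrix of condition differences,
#'   with channel column names
#' @param adjacency symmetric 0/1 adjacency matrix with matching
#'   dimnames, or a two-column edge data.frame (see [adjacencyFromEdges()])
#' @param n_perm number of sign-flip permutations
#' @param cluster_alpha cluster-forming threshold (two-tailed) for the
#'   per-channel t values
#' @param alpha test level carried in the result
#' @param seed integer seed
#' @return list of class "clusterPermResult": clusters (channels, mass, p),
#'   channel_t, threshold, alpha
#' @export
channelClusterPermutation <- function(diffs, adjacency, n_perm = 10000,
                                      cluster_alpha = 0.05, alpha = 0.001,
                                      seed = 1) {
  if (is.data.frame(adjacency)) adjacency <- adjacencyFromEdges(adjacency)
  chans <- colnames(diffs)
  if (is.null(chans)) stop("diffs must have channel column names")
  if (!all(chans %in% rownames(adjacency)))
    stop("neighbor graph does not cover all channels")
  if (!nrow(adjacency)) stop("empty neighbor graph")
  adjacency <- adjacency[chans, chans, drop = FALSE]
  n <- nrow(diffs)
  tcrit <- qt(1 - cluster_alpha / 2, df = n - 1L)

  chanT <- function(d) {
    m <- colMeans(d)
    s <- apply(d, 2L, sd)
    ifelse(s == 0, 0, m / (s / sqrt(n)))
  }
  clustersOf <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      active <- chans[sgn * tv > tcrit]
      if (length(active))
        out <- c(out, lapply(connectedComponents(adjacency, active),
                             function(m) list(channels = m,
                                              mass = sum(tv[m]))))
    }
    out
  }

  t_obs <- chanT(diffs)
  names(t_obs) <- chans
  obs <- clustersOf(t_obs)
  null_max <- withSeed(seed, vapply(seq_len(n_perm), function(i) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    cl <- clustersOf(chanT(diffs * flips))
    if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass"))) else 0
  }, 0))
  clusters <- lapply(obs, function(cl) {
    cl$p <- mean(null_max >= abs(cl$mass))
    cl
  })
  if (length(clusters))
    clusters <- clusters[order(-abs(vapply(clusters, `[[`, 0, "mass")))]
  res <- list(clusters = clusters, channel_t = t_obs, threshold = tcrit,
              alpha = alpha, n_perm = n_perm)
  class(res) <- "clusterPermResult"
  res
}

#' @export
print.clusterPermResult <- function(x, ...) {
  cat("clusterPermResult:", length(x$clusters), "cluster(s)\n")
  for (cl in x$clusters)
    cat(sprintf("  mass = %.2f, p = %.4g: %s\n", cl$mass, cl$p,
                paste(cl$channels, collapse = " ")))
  invisible(x)
}

#' Build an adjacency matrix from a two-column edge list
#'
#' @param edges data.frame or two-column matrix of channel label pairs
#' @param channels optional full channel set (isolated channels allowed)
#' @return symmetric 0/1 adjacency matrix with dimnames
#' @export
adjacencyFromEdges <- function(edges, channels = NULL) {
  e <- as.matrix(edges[, 1:2])
  chans <- if (is.null(channels)) sort(unique(as.vector(e))) else channels
  adj <- matrix(0L, length(chans), length(chans),
                dimnames = list(chans, chans))
  for (i in seq_len(nrow(e))) {
    adj[e[i, 1], e[i, 2]] <- 1L
    adj[e[i, 2], e[i, 1]] <- 1L
  }
  adj
}

#' Read an adjacency edge list from a two-column text file
#'
#' @param path whitespace- or tab-separated file with two channel labels per
#'   line
#' @param channels optional full channel set
#' @export
readAdjacency <- function(path, channels = NULL) {
  adjacencyFromEdges(read.table(path, header = FALSE,
                                stringsAsFactors = FALSE), channels)
}

#' Default neighbor graph for the 10-channel analysis montage
#'
#' Chain-plus-hub adjacency within each cluster: Fz neighbors AFz, F1, F2 and
#' FCz; CPz neighbors Cz, CP1, CP2 and Pz; FCz-Cz links the clusters.
#'
#' @return adjacency matrix
#' @export
defaultAdjacency <- function() {
  adjacencyFromEdges(data.frame(
    a = c("Fz", "Fz", "Fz", "Fz", "AFz", "F1", "F2", "FCz",
          "CPz", "CPz", "CPz", "CPz", "Cz", "CP1", "CP2"),
    b = c("AFz", "F1", "F2", "FCz", "F1", "F2", "FCz", "Cz",
          "Cz", "CP1", "CP2", "Pz", "CP1", "CP2", "Pz")))
}

#' Subsampled contrast between unequal-sized trial sets
#'
#' Each iteration draws `length(incorrect)` values from `correct` without
#' replacement, evaluates `statistic` on the subsample and on the full
#' incorrect set, and records the difference; the across-iteration average is
#' the bias-matched contrast (both sides see the same trial count, so
#' small-sample bias of the statistic cancels).
#'
#' @param correct per-trial values of the larger (correct) set
#' @param incorrect per-trial values of the smaller (incorrect) set
#' @param statistic function of a numeric vector; default sample variance
#' @param n_iter number of subsampling iterations
#' @param seed integer seed
#' @return list: mean_diff, iter_correct, incorrect_stat, n_iter
#' @export
subsampledContrast <- function(correct, incorrect, statistic = stats::var,
                               n_iter = 200, seed = 1) {
  nc <- length(correct); ni <- length(incorrect)
  if (ni < 2L) stop("incorrect set needs >= 2 trials")
  if (nc < ni)
    stop("n_correct < n_incorrect: swap the roles explicitly if intended")
  s_inc <- statistic(incorrect)
  iter <- withSeed(seed, vapply(seq_len(n_iter), function(i)
    statistic(sample(correct, ni)), 0))
  list(mean_diff = mean(iter) - s_inc, iter_correct = iter,
       incorrect_stat = s_inc, n_iter = n_iter)
}
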