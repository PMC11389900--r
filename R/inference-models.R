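## Mixed-model design construction, lag alignment, and reporting. Numerical
## optimization is delegated to lme4 / lmerTest; this module owns the
## designs (coding, centering, lag alignment) and faithful reporting.

#' Mixed / fixed-effects model specification
#'
#' @param response response column name
#' @param fixed character string of fixed-effect terms, e.g.
#'   `"group * set_size"`
#' @param random character string of random-effect terms, e.g.
#'   `"(1 | participant)"`, or NULL for a fixed-effects model
#' @param family "normal", "gamma" or "binomial"
#' @param link "identity", "inverse" or "logit"
#' @return validated list of class "modelSpec"
#' @export
modelSpec <- function(response, fixed, random = NULL,
                      family = c("normal", "gamma", "binomial"),
                      link = NULL) {
  family <- match.arg(family)
  link <- if (is.null(link))
    switch(family, normal = "identity", gamma = "inverse", binomial = "logit")
  else link
  ok <- list(normal = "identity", gamma = c("inverse", "identity", "log"),
             binomial = "logit")
  if (!link %in% ok[[family]])
    stop("link ", link, " not supported for family ", family)
  spec <- list(response = response, fixed = fixed, random = random,
               family = family, link = link)
  class(spec) <- "modelSpec"
  spec
}

specFormula <- function(spec) {
  rhs <- if (is.null(spec$random)) spec$fixed
         else paste(spec$fixed, "+", spec$random)
  as.formula(paste(spec$response, "~", rhs))
}

#' Fit a (generalized) mixed or fixed-effects model
#'
#' Dispatches to `lmerTest::lmer` (normal + random effects), `lme4::glmer`
#' (gamma / binomial + random effects), or `lm`/`glm` otherwise. Returns a
#' uniform coefficient table plus marginal tests for interaction terms
#' (Satterthwaite F for linear mixed models, Wald chi-square otherwise) and
#' a convergence flag; downstream consumers must refuse non-converged fits.
#'
#' @param data model data.frame; grouping factors named in `spec$random`
#'   must be present
#' @param spec a [modelSpec()]
#' @param fast for GLMMs, use the faster nAGQ = 0 approximation
#' @return list of class "modelFit": coefficients (term, estimate, se,
#'   statistic, p), anova (marginal tests), converged, logLik, model
#' @export
fitMixedModel <- function(data, spec, fast = FALSE) {
  vars <- all.vars(specFormula(spec))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("columns missing from data: ",
                         paste(miss, collapse = ", "))
  fml <- specFormula(spec)
  mixed <- !is.null(spec$random)
  fam <- switch(spec$family,
                normal = NULL,
                gamma = stats::Gamma(link = spec$link),
                binomial = stats::binomial(link = spec$link))
  converged <- TRUE
  # boundary (singular) fits are converged; only genuine optimizer failure
  # clears the flag
  fit <- withCallingHandlers(
    {
      if (mixed && spec$family == "normal")
        lmerTest::lmer(fml, data = data, REML = TRUE)
      else if (mixed)
        lme4::glmer(fml, data = data, family = fam,
                    nAGQ = if (fast) 0L else 1L)
      else if (spec$family == "normal") lm(fml, data = data)
      else stats::glm(fml, data = data, family = fam)
    },
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE) &&
          !grepl("singular", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (mixed && !is.null(fit@optinfo$conv$lme4$code)) converged <- FALSE

  smry <- summary(fit)
  co <- if (mixed) smry$coefficients else coef(smry)
  tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    statistic = co[, 3],
                    p = co[, ncol(co)], row.names = NULL)
  if (!("Pr(>|t|)" %in% colnames(co)) && !("Pr(>|z|)" %in% colnames(co))) {
    # plain lm()/lmer without p column fallback: Wald normal approximation
    tab$p <- 2 * pnorm(-abs(tab$statistic))
  }
  an <- tryCatch({
    if (mixed && spec$family == "normal") as.data.frame(anova(fit))
    else waldAnova(fit)
  }, error = function(e) NULL)
  res <- list(coefficients = tab, anova = an, converged = converged,
              logLik = as.numeric(logLik(fit)), spec = spec, model = fit)
  class(res) <- "modelFit"
  res
}

## Wald chi-square marginal tests per term (type-III style, from the
## coefficient covariance), for GLM(M)s.
waldAnova <- function(fit) {
  b <- if (isS4(fit)) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  asg <- attr(model.matrix(fit), "assign")
  if (is.null(asg)) return(NULL)
  labs <- attr(stats::terms(fit), "term.labels")
  out <- lapply(seq_along(labs), function(k) {
    j <- which(asg == k)
    if (!length(j)) return(NULL)
    w <- tryCatch(drop(t(b[j]) %*% solve(V[j, j, drop = FALSE]) %*% b[j]),
                  error = function(e) NA_real_)
    data.frame(term = labs[k], chisq = w, df = length(j),
               p = pchisq(w, length(j), lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' @export
print.modelFit <- function(x, ...) {
  cat("modelFit (", x$spec$family, "/", x$spec$link, ")",
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Pull one coefficient row from a model fit
#'
#' @param fit a "modelFit"
#' @param term coefficient name (exact match or unique substring)
#' @export
coefRow <- function(fit, term) {
  tab <- fit$coefficients
  i <- which(tab$term == term)
  if (!length(i)) i <- grep(term, tab$term, fixed = TRUE)
  if (length(i) != 1L) stop("term '", term, "' not found uniquely")
  tab[i, ]
}

## ---------------------------------------------------------------------------
## Lagged (N+1) and same-trial (N-N) designs
## ---------------------------------------------------------------------------

#' Build the lagged single-trial design
#'
#' Pairs every trial n with the post-response power and set size of trial
#' n-1. Pairs spanning a block boundary are dropped, and preprocessing
#' rejections break the chain: a removed trial deletes both its own row and
#' the lag of its successor (only globally consecutive trials within the
#' same block and participant are paired).
#'
#' @param behavior behavioral data.frame (trial_id, block_index, set_size,
#'   accuracy, rt_s, group, optionally participant); may already carry
#'   `maintenance` / `post_response` power columns
#' @param trial_powers data.frame (trial_id, maintenance, post_response)
#'   of per-trial band power, aligned by trial id (and participant, when
#'   present); rejected trials simply absent; NULL if the power columns are
#'   already in `behavior`
#' @return data.frame with columns participant, group, trial_id, accuracy,
#'   rt_s, set_size, maint_power, set_size_prev, post_power_prev
#' @export
buildLaggedDesign <- function(behavior, trial_powers = NULL) {
  if (!"participant" %in% names(behavior)) behavior$participant <- "p1"
  d <- mergePowers(behavior, trial_powers)
  d <- d[order(d$participant, d$trial_id), ]
  out <- lapply(split(d, d$participant), function(dp) {
    if (is.unsorted(dp$trial_id, strictly = TRUE))
      stop("unordered or duplicated trials")
    n <- nrow(dp)
    if (n < 2L) return(NULL)
    cur <- 2:n
    ok <- dp$trial_id[cur] == dp$trial_id[cur - 1L] + 1L &
      dp$block_index[cur] == dp$block_index[cur - 1L]
    cur <- cur[ok]
    data.frame(participant = dp$participant[cur], group = dp$group[cur],
               trial_id = dp$trial_id[cur], accuracy = dp$accuracy[cur],
               rt_s = dp$rt_s[cur], set_size = dp$set_size[cur],
               maint_power = dp$maintenance[cur],
               set_size_prev = dp$set_size[cur - 1L],
               post_power_prev = dp$post_response[cur - 1L])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Join per-trial powers onto behavior; trial ids restart per participant,
## so the participant column joins too whenever both tables carry it.
mergePowers <- function(behavior, trial_powers) {
  if (is.null(trial_powers)) {
    if (!all(c("maintenance", "post_response") %in% names(behavior)))
      stop("behavior lacks power columns and trial_powers is NULL")
    return(behavior)
  }
  by <- intersect(c("participant", "trial_id"),
                  intersect(names(behavior), names(trial_powers)))
  merge(behavior, trial_powers, by = by)
}

## participant-mean centering of continuous single-trial predictors;
## stabilizes logit fits and matches the centered generative lag coupling.
centerWithin <- function(x, participant) {
  x - stats::ave(x, participant)
}

#' Fit the N+1 lagged accuracy model
#'
#' Logit-link binomial mixed model of current-trial accuracy on
#' participant-mean-centered current maintenance power, current and previous
#' set size (numeric), centered previous-trial post-response power and,
#' when both groups are present, age group and its interaction with the lag
#' term. `formula = "reduced"` (default) fits the additive model with the
#' group x lag interaction and random participant intercepts -- the
#' estimable desk-scale design. `formula = "paper"` builds the full
#' five-way-interaction specification with random slopes; at small n it
#' frequently fails to converge and is flagged accordingly.
#'
#' @param lagged design from [buildLaggedDesign()]
#' @param group restrict to one group (separate-group model) or NULL
#' @param formula "reduced" or "paper"
#' @param fast nAGQ = 0 approximation (see [fitMixedModel()])
#' @return "modelFit"; the lag coefficient is named `post_power_prev_c`
#' @export
fitNPlus1 <- function(lagged, group = NULL, formula = c("reduced", "paper"),
                      fast = FALSE) {
  formula <- match.arg(formula)
  if (!is.null(group)) lagged <- lagged[lagged$group == group, ]
  if (!nrow(lagged)) stop("empty lagged design")
  lagged$maint_power_c <- centerWithin(lagged$maint_power, lagged$participant)
  lagged$post_power_prev_c <- centerWithin(lagged$post_power_prev,
                                           lagged$participant)
  if (var(lagged$post_power_prev_c) == 0)
    stop("lag predictor has no variance")
  two_groups <- length(unique(lagged$group)) > 1L
  fixed <- if (formula == "paper") {
    paste("set_size * maint_power_c * set_size_prev * post_power_prev_c",
          if (two_groups) "* group" else "")
  } else {
    paste("set_size + maint_power_c + set_size_prev + post_power_prev_c",
          if (two_groups) "+ group + group:post_power_prev_c" else "")
  }
  random <- if (formula == "paper")
    "(1 + set_size + maint_power_c + set_size_prev + post_power_prev_c | participant)"
  else "(1 | participant)"
  spec <- modelSpec("accuracy", fixed, random, "binomial", "logit")
  fitMixedModel(lagged, spec, fast = fast)
}

#' Same-trial (N-N) control models
#'
#' Four fits relating the current trial's post-response power to the same
#' trial's behavior: accuracy ~ power (binomial/logit), RT ~ power
#' (gamma/inverse, correct trials only), and the reverse models power ~
#' accuracy and power ~ RT (normal/identity). Power is
#' participant-mean-centered; set size is a numeric covariate; all models
#' carry random participant intercepts.
#'
#' @param behavior behavioral data.frame incl. participant, set_size,
#'   accuracy, rt_s
#' @param trial_powers data.frame (trial_id, post_response), or NULL if the
#'   power columns are already in `behavior`
#' @param fast nAGQ = 0 approximation
#' @return named list of four "modelFit"s: accuracy_on_power, rt_on_power,
#'   power_on_accuracy, power_on_rt
#' @export
fitNN <- function(behavior, trial_powers = NULL, fast = FALSE) {
  if (!"participant" %in% names(behavior)) behavior$participant <- "p1"
  d <- mergePowers(behavior, trial_powers)
  if (any(d$rt_s <= 0)) stop("non-positive reaction times")
  d$post_power_c <- centerWithin(d$post_response, d$participant)
  dc <- d[d$accuracy == 1, ]
  list(
    accuracy_on_power = fitMixedModel(d,
      modelSpec("accuracy", "set_size + post_power_c", "(1 | participant)",
                "binomial"), fast = fast),
    rt_on_power = fitMixedModel(dc,
      modelSpec("rt_s", "set_size + post_power_c", "(1 | participant)",
                "gamma", "inverse"), fast = fast),
    power_on_accuracy = fitMixedModel(d,
      modelSpec("post_power_c", "set_size + accuracy", "(1 | participant)",
                "normal")),
    power_on_rt = fitMixedModel(d,
      modelSpec("post_power_c", "set_size + rt_s", "(1 | participant)",
                "normal")))
}

#' Group-by-load model of cross-trial variability
#'
#' The population-level specification `variability ~ group * set_size +
#' (1 | participant)` with numeric set size, fitted as a linear mixed model;
#' the marginal Satterthwaite F of the interaction asks whether load-dependent
#' variability changes differ between age groups.
#'
#' @param data data.frame with columns participant, group, set_size, value
#' @return "modelFit" (anova holds the marginal F tests)
#' @export
fitGroupVariability <- function(data) {
  fitMixedModel(data, modelSpec("value", "group * set_size",
                                "(1 | participant)", "normal"))
}

#' Accuracy-on-variability model
#'
#' `mean accuracy ~ group * variability + (1 | set_size)`: between-person
#' behavioral relevance of the variability statistic, with per-set-size
#' random intercepts. Accuracy, a negatively skewed proportion, uses a
#' gamma / inverse response by default; `family = "normal"` gives the
#' identity-link check.
#'
#' @param data data.frame with columns participant, group, set_size,
#'   variability, accuracy (per participant x set size means)
#' @param family "gamma" (inverse link) or "normal"
#' @param fast nAGQ = 0 approximation for the gamma fit
#' @return "modelFit"
#' @export
fitAccuracyOnVariability <- function(data, family = c("gamma", "normal"),
                                     fast = FALSE) {
  family <- match.arg(family)
  spec <- modelSpec("accuracy", "group * variability", "(1 | set_size)",
                    family)
  fitMixedModel(data, spec, fast = fast)
}
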