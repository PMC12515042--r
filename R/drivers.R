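# Environmental driver analysis of module abundances.

#' Published predictor grouping
#'
#' The four groups of environmental predictors used for variance
#' partitioning: climate (MAT, MDR, PSEA, AI), soil properties (pH,
#' conductivity, sand), soil nutrient concentrations (NH4, NO3, PO4, Ca, B,
#' K, Mg, Zn, Fe, Mn, Mo) and potential ecosystem carbon sink (NDVI, SOC).
#' Any configured nutrient set is accepted; groups are intersected with the
#' columns actually present in the data at use time.
#'
#' @return named list of character vectors.
#' @export
defaultPredictorGroups <- function() {
  list(climate = c("MAT", "MDR", "PSEA", "AI"),
       soil_properties = c("pH", "conductivity", "sand"),
       soil_nutrients = c("NH4", "NO3", "PO4", "Ca", "B", "K", "Mg", "Zn",
                          "Fe", "Mn", "Mo"),
       carbon_sink = c("NDVI", "SOC"))
}

#' Iterative variance-inflation-factor filter
#'
#' Repeatedly drops the predictor with the largest VIF until all VIFs are at
#' or below `threshold`. `VIF_v = 1 / (1 - R2_v)` where `R2_v` comes from
#' regressing `v` on the other retained predictors; perfectly collinear
#' variables (infinite VIF) are dropped first.
#'
#' @param predictors data.frame or matrix of numeric predictors (no missing
#'   values).
#' @param threshold VIF cutoff (default 5).
#' @return list: `retained` (character), `dropped` (character, in drop
#'   order), `vif` (named numeric, final VIFs of retained variables).
#' @export
vifFilter <- function(predictors, threshold = 5) {
  x <- as.matrix(predictors)
  if (anyNA(x)) stop("predictors must be complete")
  if (ncol(x) < 2) stop("need >= 2 predictors")
  vars <- colnames(x)
  dropped <- character(0)
  vifOf <- function(v, others) {
    if (!length(others)) return(1)
    # perfect fits (infinite VIF) are expected and handled; silence the
    # "essentially perfect fit" advisory
    r2 <- suppressWarnings(
      summary(lm(x[, v] ~ x[, others, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    vifs <- vapply(vars, function(v) vifOf(v, setdiff(vars, v)), numeric(1))
    if (all(vifs <= threshold) || length(vars) <= 1) break
    worst <- names(which.max(vifs))
    dropped <- c(dropped, worst)
    vars <- setdiff(vars, worst)
  }
  list(retained = vars, dropped = dropped,
       vif = vapply(vars, function(v) vifOf(v, setdiff(vars, v)),
                    numeric(1)))
}

# Internal: fit y ~ fixed + (1 | group) and compute variance components and
# marginal/conditional R2. `data` must hold standardized predictors.
lmmFitOnce <- function(data, fixedVars, REML = TRUE) {
  rhs <- if (length(fixedVars)) {
    paste(paste0("`", fixedVars, "`"), collapse = " + ")
  } else "1"
  fml <- as.formula(paste(".y ~", rhs, "+ (1 | .group)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = data, REML = REML,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigmaU <- vc$vcov[vc$grp == ".group"]
  sigmaE <- vc$vcov[vc$grp == "Residual"]
  fixedPred <- predict(fit, re.form = NA)
  varF <- if (length(fixedVars)) var(fixedPred) else 0
  denom <- varF + sigmaU + sigmaE
  list(model = fit, var_fixed = varF, var_group = sigmaU,
       var_resid = sigmaE,
       R2m = if (denom > 0) varF / denom else 0,
       R2c = if (denom > 0) (varF + sigmaU) / denom else 0)
}

#' Fit a random-intercept driver model
#'
#' Linear mixed model `y = X beta + u_g + eps` with the CWP species as a
#' categorical random intercept, fitted by REML (default) or ML. Predictors
#' are standardized to zero mean / unit variance unless `standardize =
#' FALSE`. Marginal and conditional coefficients of determination follow
#' `R2m = var(X beta) / (var(X beta) + s2_u + s2_e)` and
#' `R2c = (var(X beta) + s2_u) / (var(X beta) + s2_u + s2_e)`.
#' A vanishing random-intercept variance is reported via the `singular`
#' flag, not an error.
#'
#' @param response numeric vector (per-site module abundance).
#' @param predictors data.frame of numeric candidate predictors (same row
#'   order as `response`).
#' @param group grouping labels (CWP species per site).
#' @param fixedVars which predictor columns enter the fixed part (default
#'   all).
#' @param REML logical.
#' @param standardize standardize predictors before fitting.
#' @return list of class `cwp_lmm`: `model`, `coefficients`, `var_fixed`,
#'   `var_group`, `var_resid`, `R2m`, `R2c`, `singular`, `data`,
#'   `fixed_vars`.
#' @export
fitDriverLMM <- function(response, predictors, group,
                         fixedVars = colnames(predictors), REML = TRUE,
                         standardize = TRUE) {
  stopifnot(length(response) == nrow(predictors),
            length(group) == length(response))
  if (length(unique(group)) < 2) stop("need >= 2 grouping levels")
  x <- as.data.frame(predictors)
  if (standardize) {
    for (v in colnames(x)) x[[v]] <- as.numeric(scale(x[[v]]))
  }
  data <- cbind(.y = response, .group = factor(group), x)
  ans <- lmmFitOnce(data, fixedVars, REML = REML)
  ans$coefficients <- lme4::fixef(ans$model)
  ans$singular <- lme4::isSingular(ans$model)
  ans$data <- data
  ans$fixed_vars <- fixedVars
  class(ans) <- "cwp_lmm"
  ans
}

#' Backward AIC selection of fixed effects
#'
#' Starting from all candidate predictors, repeatedly removes the single
#' fixed term whose removal most decreases the AIC, stopping when no removal
#' helps. Comparisons use ML fits (REML likelihoods are not comparable
#' across fixed structures); the final model is refitted by REML. An empty
#' fixed set is a legal endpoint.
#'
#' @param response,predictors,group,standardize as in [fitDriverLMM()].
#' @param candidates candidate predictor columns (default all).
#' @return the final REML `cwp_lmm` fit with an `aic_trace` data.frame
#'   (`step`, `dropped`, `aic`, `n_terms`) attached.
#' @export
backwardAIC <- function(response, predictors, group,
                        candidates = colnames(predictors),
                        standardize = TRUE) {
  x <- as.data.frame(predictors)
  if (standardize) {
    for (v in colnames(x)) x[[v]] <- as.numeric(scale(x[[v]]))
  }
  data <- cbind(.y = response, .group = factor(group), x)
  current <- candidates
  aicNow <- AIC(lmmFitOnce(data, current, REML = FALSE)$model)
  trace <- data.frame(step = 0L, dropped = NA_character_, aic = aicNow,
                      n_terms = length(current), stringsAsFactors = FALSE)
  step <- 0L
  while (length(current)) {
    aics <- vapply(current, function(v) {
      AIC(lmmFitOnce(data, setdiff(current, v), REML = FALSE)$model)
    }, numeric(1))
    if (min(aics) >= aicNow) break
    drop <- names(which.min(aics))
    current <- setdiff(current, drop)
    aicNow <- min(aics)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = drop,
                                     aic = aicNow,
                                     n_terms = length(current)))
  }
  fit <- fitDriverLMM(response, predictors, group, fixedVars = current,
                      REML = TRUE, standardize = standardize)
  fit$aic_trace <- trace
  fit
}

#' Parametric bootstrap confidence intervals for fixed effects
#'
#' Simulates responses from the fitted model, refits each replicate, and
#' takes percentile 2.5/97.5 intervals of the fixed coefficients.
#' Non-converging replicates are dropped and counted; more than 20%
#' failures aborts with advice to inspect the model.
#'
#' @param fit a `cwp_lmm` from [fitDriverLMM()] / [backwardAIC()].
#' @param nBoot bootstrap replicates (the published setting is 1000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return data.frame: `term`, `estimate`, `lower`, `upper`,
#'   `n_failed` attribute.
#' @export
bootstrapCI <- function(fit, nBoot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "cwp_lmm"))
  set.seed(seed)
  sims <- simulate(fit$model, nsim = nBoot)
  est <- lme4::fixef(fit$model)
  draws <- matrix(NA_real_, nrow = nBoot, ncol = length(est),
                  dimnames = list(NULL, names(est)))
  nFail <- 0L
  for (b in seq_len(nBoot)) {
    rb <- tryCatch(
      suppressWarnings(suppressMessages(lme4::refit(fit$model, sims[[b]]))),
      error = function(e) NULL)
    if (is.null(rb)) { nFail <- nFail + 1L; next }
    draws[b, ] <- lme4::fixef(rb)
  }
  if (nFail > 0.2 * nBoot)
    stop("more than 20% of bootstrap replicates failed to converge; ",
         "inspect the model", call. = FALSE)
  a <- (1 - level) / 2
  ok <- !is.na(draws[, 1])
  out <- data.frame(
    term = names(est), estimate = as.numeric(est),
    lower = apply(draws[ok, , drop = FALSE], 2, quantile, probs = a),
    upper = apply(draws[ok, , drop = FALSE], 2, quantile, probs = 1 - a),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_failed") <- nFail
  out
}

#' Hierarchical partitioning of the marginal R2 over predictor groups
#'
#' Decomposes the full model's marginal coefficient of determination into
#' per-group contributions by averaging, over all orderings of the groups,
#' the increment in `R2m` when the group enters (Shapley averaging over the
#' `2^g` subset models, all sharing the random structure). The unique part
#' of a group is `R2m(all) - R2m(all minus group)`; shared = total -
#' unique. Totals sum exactly to the full model's `R2m`.
#'
#' @param fit a `cwp_lmm` (its `fixed_vars` define the model terms).
#' @param groups named list mapping group name -> predictor names; model
#'   terms must each belong to exactly one group.
#' @return data.frame: `group`, `total`, `unique`, `shared`, plus
#'   attributes `R2m`, `var_group_fraction`, `residual_fraction`.
#' @export
partitionR2 <- function(fit, groups = defaultPredictorGroups()) {
  stopifnot(inherits(fit, "cwp_lmm"))
  terms <- fit$fixed_vars
  groups <- lapply(groups, intersect, terms)
  inGroups <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(inGroups)) stop("predictor groups must be disjoint")
  orphan <- setdiff(terms, inGroups)
  if (length(orphan))
    stop("model term(s) not assigned to any group: ",
         paste(orphan, collapse = ", "))
  gNames <- names(groups)
  g <- length(gNames)
  if (g > 6) stop("at most 6 groups (2^g subset fits)")
  # R2m of every subset of groups
  subsetsR2 <- new.env()
  keyOf <- function(sel) paste0("k:", paste(sort(sel), collapse = "|"))
  r2of <- function(sel) {
    key <- keyOf(sel)
    if (!is.null(subsetsR2[[key]])) return(subsetsR2[[key]])
    vars <- unlist(groups[sel], use.names = FALSE)
    r2 <- lmmFitOnce(fit$data, vars, REML = TRUE)$R2m
    subsetsR2[[key]] <- r2
    r2
  }
  full <- r2of(gNames)
  out <- data.frame(group = gNames, total = NA_real_, unique = NA_real_,
                    shared = NA_real_, stringsAsFactors = FALSE)
  fact <- factorial(g)
  for (i in seq_along(gNames)) {
    gi <- gNames[i]
    if (!length(groups[[gi]])) {  # group with no selected terms
      out$total[i] <- 0; out$unique[i] <- 0; out$shared[i] <- 0
      next
    }
    rest <- setdiff(gNames, gi)
    total <- 0
    for (sz in 0:length(rest)) {
      sets <- if (sz == 0) list(character(0)) else
        combn(rest, sz, simplify = FALSE)
      wgt <- factorial(sz) * factorial(g - sz - 1) / fact
      for (s in sets) {
        total <- total + wgt * (r2of(c(s, gi)) - r2of(s))
      }
    }
    out$total[i] <- total
    out$unique[i] <- full - r2of(rest)
    out$shared[i] <- total - out$unique[i]
  }
  attr(out, "R2m") <- full
  denom <- fit$var_fixed + fit$var_group + fit$var_resid
  attr(out, "var_group_fraction") <- fit$var_group / denom
  attr(out, "residual_fraction") <- fit$var_resid / denom
  out
}

#' Anderson-Darling normality check of model residuals
#'
#' A2 statistic on the model residuals with the estimated-parameters
#' correction and the composite-normality p-value approximation.
#'
#' @param fit a `cwp_lmm`, or a numeric vector of residuals.
#' @return list: `statistic` (A2), `p_value` (`NA` for constant residuals).
#' @export
residualNormality <- function(fit) {
  r <- if (inherits(fit, "cwp_lmm")) resid(fit$model) else as.numeric(fit)
  if (length(r) < 8) stop("need >= 8 residuals")
  if (sd(r) == 0) return(list(statistic = NA_real_, p_value = NA_real_))
  ad <- nortest::ad.test(r)
  list(statistic = unname(ad$statistic), p_value = ad$p.value)
}

#' Significance stars at the published display levels
#'
#' @param p numeric vector of p-values.
#' @return character vector: `***` < 0.001, `**` < 0.01, `*` < 0.05,
#'   `.` < 0.1, empty otherwise.
#' @export
significanceStars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", ""), right = FALSE) |>
    as.character()
}
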