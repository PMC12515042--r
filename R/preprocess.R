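# Environmental imputation, rarefaction, and derived matrices.

#' Impute missing environmental cells by chained predictive mean matching
#'
#' Fills each missing cell with an *observed* value of the same variable,
#' donated by a case whose predicted mean (from a linear regression of the
#' target on all other variables) is among the `nDonors` nearest to the
#' missing case's prediction; one donor is drawn at random per cell. The
#' chained-equation sweep over variables is repeated `nCycles` times (the
#' published setting is 999 cycles producing a single completed dataset;
#' tests use far fewer since the chain stabilises quickly). Observed cells
#' are never modified.
#'
#' @param env data.frame with `site_id` plus numeric variables, possibly
#'   containing `NA` cells.
#' @param nCycles number of chained-equation cycles.
#' @param nDonors donor pool size.
#' @param seed integer seed.
#' @return `env` with all missing cells filled.
#' @export
imputePMM <- function(env, nCycles = 999L, nDonors = 5L, seed = 1L) {
  vars <- setdiff(colnames(env), "site_id")
  if (length(vars) < 2) stop("need >= 2 variables for chained imputation")
  x <- as.matrix(env[, vars, drop = FALSE])
  miss <- is.na(x)
  if (!any(miss)) return(env)
  for (v in vars) {
    obs <- sum(!miss[, v])
    if (obs == 0) stop("variable entirely missing: ", v, call. = FALSE)
    if (obs < nDonors)
      stop("variable ", v, " has fewer than ", nDonors, " observed values",
           call. = FALSE)
  }
  set.seed(seed)
  # initialise missing cells with column means of observed values
  for (v in vars) {
    x[miss[, v], v] <- mean(x[!miss[, v], v])
  }
  targets <- vars[colSums(miss) > 0]
  for (cycle in seq_len(nCycles)) {
    for (v in targets) {
      mi <- miss[, v]
      others <- setdiff(vars, v)
      X <- cbind(1, x[, others, drop = FALSE])
      fit <- tryCatch(qr.solve(X[!mi, , drop = FALSE], x[!mi, v]),
                      error = function(e) NULL)
      if (is.null(fit)) {  # rank-deficient design: fall back to least squares
        fit <- qr.coef(qr(X[!mi, , drop = FALSE]), x[!mi, v])
        fit[is.na(fit)] <- 0
      }
      pred <- drop(X %*% fit)
      predObs <- pred[!mi]
      yObs <- x[!mi, v]
      for (i in which(mi)) {
        d <- abs(predObs - pred[i])
        pool <- order(d)[seq_len(min(nDonors, length(d)))]
        x[i, v] <- yObs[pool[sample.int(length(pool), 1)]]
      }
    }
  }
  out <- env
  out[, vars] <- as.data.frame(x)
  stopifnot(!anyNA(out[, vars]))
  # observed cells untouched
  stopifnot(all(out[, vars][!miss] == env[, vars][!miss]))
  out
}

#' Convert Walkley-Black soil organic carbon to dry-combustion scale
#'
#' Applies the established conversion factor of 1.15 to SOC values measured
#' by the Walkley-Black wet oxidation method, putting them on the dry
#' combustion scale used for the rest of the survey. Apply only to columns
#' flagged as Walkley-Black measurements.
#'
#' @param soc numeric vector of Walkley-Black SOC values.
#' @return numeric vector on the dry-combustion scale.
#' @export
socWalkleyBlackToDryCombustion <- function(soc) {
  stopifnot(is.numeric(soc))
  soc * 1.15
}

#' Rarefy a count table to a fixed depth
#'
#' Subsamples every sample's reads without replacement to exactly `depth`
#' reads (a single recorded draw per sample). Samples whose total is below
#' `depth` are dropped and reported in the `dropped` attribute.
#'
#' @param counts matrix or `SummarizedExperiment` (taxa x samples).
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @return same container type as the input, with column sums all equal to
#'   `depth`; dropped sample ids in `attr(, "dropped")` (matrix input) or
#'   `metadata()$dropped` (`SummarizedExperiment` input).
#' @export
rarefyCounts <- function(counts, depth, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  m <- countsMatrix(counts)
  checkCountsMatrix(m)
  tot <- colSums(m)
  keep <- tot >= depth
  dropped <- colnames(m)[!keep]
  m <- m[, keep, drop = FALSE]
  set.seed(seed)
  out <- m
  for (j in seq_len(ncol(m))) {
    if (tot[keep][j] == depth) next  # already at depth: returned unchanged
    # inputs are validated integer counts; rrarefy's "observed counts"
    # heuristic warning misfires on sparse columns
    out[, j] <- drop(suppressWarnings(vegan::rrarefy(m[, j], depth)))
  }
  storage.mode(out) <- "integer"
  stopifnot(all(colSums(out) == depth), all(out <= m))
  if (is(counts, "SummarizedExperiment")) {
    se <- counts[, keep]
    SummarizedExperiment::assay(se, "counts") <- out
    metadata(se)$dropped <- dropped
    metadata(se)$depth <- as.integer(depth)
    return(se)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Relative abundance table
#'
#' @param counts matrix or `SummarizedExperiment` (taxa x samples), every
#'   sample total > 0.
#' @return numeric matrix of proportions; columns sum to 1.
#' @export
relativeAbundance <- function(counts) {
  m <- countsMatrix(counts)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    stop("zero-total sample(s): ", paste(zero, collapse = ", "),
         " (drop or rarefy first)", call. = FALSE)
  sweep(m, 2, tot, `/`)
}

#' Presence-absence matrix
#'
#' @param counts matrix or `SummarizedExperiment` (taxa x samples).
#' @return integer 0/1 matrix; entry 1 iff count > 0.
#' @export
presenceMatrix <- function(counts) {
  m <- countsMatrix(counts)
  out <- (m > 0) + 0L
  dimnames(out) <- dimnames(m)
  out
}
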