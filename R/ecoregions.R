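# Edaphoclimatic ecoregion delineation.

#' Principal component analysis of the edaphoclimatic table
#'
#' PCA on centred and scaled variables (unit variance, denominator n-1),
#' i.e. an eigendecomposition of the correlation matrix. A deterministic
#' sign convention is applied: within each component the loading of largest
#' magnitude is made positive. Squared cosines (per-variable quality of
#' representation, used to interpret the axes) are returned alongside
#' loadings, scores, eigenvalues and variance fractions.
#'
#' @param env complete data.frame with `site_id` plus numeric variables, or
#'   a plain numeric matrix.
#' @return list of class `cwp_pca`: `loadings`, `scores`, `eigenvalues`,
#'   `variance_fraction`, `squared_cosines`, `center`, `scale`.
#' @export
runPCA <- function(env) {
  if (is.data.frame(env)) {
    x <- as.matrix(env[, setdiff(colnames(env), "site_id"), drop = FALSE])
    rownames(x) <- if ("site_id" %in% colnames(env)) env$site_id else
      rownames(env)
  } else {
    x <- as.matrix(env)
  }
  if (anyNA(x)) stop("PCA input must be complete (impute first)")
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 sites and >= 2 variables")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant variable(s) cannot be scaled: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: largest-magnitude loading positive per component
  for (c in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, c]))
    if (p$rotation[i, c] < 0) {
      p$rotation[, c] <- -p$rotation[, c]
      p$x[, c] <- -p$x[, c]
    }
  }
  ev <- p$sdev^2
  # squared cosine of variable v on axis c: (loading * sdev)^2, i.e. squared
  # correlation between the variable and the component
  corvc <- sweep(p$rotation, 2, p$sdev, `*`)
  cos2 <- corvc^2
  structure(list(loadings = p$rotation, scores = p$x, eigenvalues = ev,
                 variance_fraction = ev / sum(ev), squared_cosines = cos2,
                 center = p$center, scale = p$scale),
            class = "cwp_pca")
}

#' Eigenvalue-weighted PCA scores for clustering
#'
#' Rescales each retained score column to unit variance and multiplies it by
#' the square root of its eigenvalue, so that squared Euclidean distances on
#' the result equal eigenvalue-weighted distances in PC space (the weighting
#' used ahead of the K-means cascade). Columns with eigenvalue ~0 become
#' identically zero.
#'
#' @param pca result of [runPCA()].
#' @param nAxes number of leading axes to keep (default 5).
#' @return sites x nAxes numeric matrix; `var(column c) == eigenvalue_c`.
#' @export
weightScores <- function(pca, nAxes = 5L) {
  if (nAxes <= 0) stop("nAxes must be positive")
  if (nAxes > ncol(pca$scores)) stop("nAxes exceeds available components")
  s <- pca$scores[, seq_len(nAxes), drop = FALSE]
  out <- s
  for (c in seq_len(nAxes)) {
    sdc <- sd(s[, c])
    out[, c] <- if (sdc < 1e-12) 0 else
      s[, c] / sdc * sqrt(pca$eigenvalues[c])
  }
  out
}

# Calinski-Harabasz index for a labelled point set:
# CH(k) = [B/(k-1)] / [W/(n-k)] with B, W the between/within sums of squares.
calinskiHarabasz <- function(points, labels) {
  n <- nrow(points)
  k <- length(unique(labels))
  grand <- colMeans(points)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    pg <- points[labels == g, , drop = FALSE]
    cg <- colMeans(pg)
    W <- W + sum(sweep(pg, 2, cg)^2)
    B <- B + nrow(pg) * sum((cg - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' K-means cascade with Calinski-Harabasz model selection
#'
#' Runs best-of-`nStarts` K-means for every candidate `k`, scores each
#' partition with the Calinski-Harabasz index `CH(k) = [B/(k-1)]/[W/(n-k)]`,
#' and selects the `k` maximising CH (ties broken toward smaller `k`).
#' Cluster labels are relabelled by descending cluster size for determinism.
#'
#' @param points numeric matrix (typically [weightScores()] output).
#' @param kRange integer vector of candidate cluster counts, all >= 2.
#' @param nStarts random restarts per k.
#' @param seed integer seed.
#' @return list of class `cwp_ecoregions`: `labels` (named by row),
#'   `k_selected`, `ch_values`, `within_ss`.
#' @export
selectEcoregions <- function(points, kRange = 2:10, nStarts = 25L,
                             seed = 1L) {
  points <- as.matrix(points)
  if (any(kRange < 2)) stop("k = 1 is not allowed (CH undefined)")
  if (nrow(points) <= max(kRange))
    stop("need more sites than the largest candidate k")
  set.seed(seed)
  kRange <- sort(unique(as.integer(kRange)))
  ch <- setNames(numeric(length(kRange)), kRange)
  wss <- setNames(numeric(length(kRange)), kRange)
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    km <- kmeans(points, centers = kRange[i], nstart = nStarts,
                 iter.max = 100)
    fits[[i]] <- km
    ch[i] <- calinskiHarabasz(points, km$cluster)
    wss[i] <- km$tot.withinss
  }
  best <- which.max(ch)  # which.max takes the first maximum: smaller k wins
  km <- fits[[best]]
  # relabel clusters by descending size (ties by original label)
  sizes <- table(km$cluster)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  labels <- setNames(as.integer(relabel[as.character(km$cluster)]),
                     rownames(points))
  structure(list(labels = labels, k_selected = kRange[best],
                 ch_values = ch, within_ss = wss),
            class = "cwp_ecoregions")
}

#' Per-CWP tests of PCA axis positions
#'
#' For each CWP species and each of the first `nAxes` components: a Wilcoxon
#' signed-rank test of the species' site scores against zero (exact
#' distribution for n <= 25, normal approximation with continuity correction
#' above), plus a one-way linear model across species per axis with all
#' pairwise mean comparisons Bonferroni-adjusted and summarised as a compact
#' letter display.
#'
#' @param scores sites x components score matrix (rownames = site ids).
#' @param sites site table with `site_id` and `cwp_species`.
#' @param nAxes number of leading axes to test.
#' @param alpha significance level for the letter display.
#' @return data.frame with one row per CWP x axis: `cwp_species`, `axis`,
#'   `median`, `wilcoxon_p`, `letter`.
#' @export
testAxisDifferences <- function(scores, sites, nAxes = 2L, alpha = 0.05) {
  nAxes <- min(nAxes, ncol(scores))
  sites <- sites[match(rownames(scores), sites$site_id), ]
  stopifnot(!anyNA(sites$site_id))
  out <- list()
  for (ax in seq_len(nAxes)) {
    v <- scores[, ax]
    grp <- factor(sites$cwp_species)
    # pairwise Bonferroni letters from a one-way linear model
    fit <- lm(v ~ grp)
    emm <- emmeans::emmeans(fit, "grp")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "bonferroni"))
    lv <- levels(grp)
    pmat <- matrix(NA_real_, length(lv), length(lv),
                   dimnames = list(lv, lv))
    for (r in seq_len(nrow(prs))) {
      nm <- strsplit(prs$contrast[r], " - ")[[1]]
      nm <- gsub("^\\(|\\)$", "", nm)
      pmat[nm[1], nm[2]] <- pmat[nm[2], nm[1]] <- prs$p.value[r]
    }
    letterMap <- insertAbsorbLetters(pmat, alpha = alpha)
    for (g in lv) {
      x <- v[grp == g]
      wp <- if (length(x) < 2 || all(x == 0)) NA_real_ else {
        suppressWarnings(
          wilcox.test(x, mu = 0, exact = length(x) <= 25,
                      correct = TRUE)$p.value)
      }
      out[[length(out) + 1L]] <- data.frame(
        cwp_species = g, axis = ax, median = median(x),
        wilcoxon_p = wp, letter = letterMap[[g]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
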