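# Biogeography of network modules: standardized abundances, completeness,
# and per-group comparisons.

#' Standardize core-taxon reads within each population
#'
#' Row-wise z-score across taxa within each site:
#' `z_ij = (x_ij - mean_i) / sd_i`, where the mean and (sample, n-1)
#' standard deviation are taken over the taxa of site `i`. This balances the
#' contribution of phylotypes to module abundances regardless of module
#' size. Sites with zero spread get an all-zero row and a warning. The
#' alternative convention — standardizing each taxon across populations —
#' is available via `margin = "taxon"`.
#'
#' @param x sites x taxa numeric matrix of (rarefied) reads of core taxa.
#' @param margin `"site"` (default, the published formula) or `"taxon"`.
#' @return list: `z` (same shape as `x`), `row_means`, `row_sds`.
#' @export
moduleZscore <- function(x, margin = c("site", "taxon")) {
  margin <- match.arg(margin)
  x <- as.matrix(x)
  if (margin == "taxon") x <- t(x)
  if (ncol(x) < 2)
    stop("need >= 2 ", if (margin == "site") "taxa" else "sites",
         " to standardize")
  mu <- rowMeans(x)
  sds <- apply(x, 1, sd)
  z <- (x - mu) / sds
  if (any(sds == 0)) {
    warning("zero-spread row(s) standardized to 0: ",
            paste(rownames(x)[sds == 0], collapse = ", "))
    z[sds == 0, ] <- 0
  }
  if (margin == "taxon") z <- t(z)
  list(z = z, row_means = mu, row_sds = sds)
}

#' Mean standardized abundance per module and population
#'
#' Averages the z-scores of each module's taxa within each site, yielding
#' the site x module response used by the driver models.
#'
#' @param z sites x taxa z-score matrix ([moduleZscore()]`$z`).
#' @param membership named vector taxon -> module id.
#' @return sites x modules numeric matrix (column names = module ids);
#'   empty modules give `NA` columns.
#' @export
moduleAbundance <- function(z, membership) {
  miss <- setdiff(colnames(z), names(membership))
  if (length(miss))
    stop("membership does not cover taxa: ", paste(head(miss, 5),
                                                   collapse = ", "))
  mods <- sort(unique(as.integer(membership[colnames(z)])))
  out <- matrix(NA_real_, nrow = nrow(z), ncol = length(mods),
                dimnames = list(rownames(z), as.character(mods)))
  for (m in mods) {
    taxa <- colnames(z)[membership[colnames(z)] == m]
    if (length(taxa)) out[, as.character(m)] <-
        rowMeans(z[, taxa, drop = FALSE])
  }
  out
}

#' Module completeness per population and ecoregion
#'
#' Completeness of module `m` in population `p` is the proportion of the
#' module's nodes present in `p`; the ecoregion value is the mean over the
#' ecoregion's populations.
#'
#' @param presence taxa x sites 0/1 matrix.
#' @param membership named vector taxon -> module id (only these taxa are
#'   scored; restrict to main modules upstream if desired).
#' @param ecoregions named vector site -> ecoregion label.
#' @return list: `by_population` (data.frame site_id, ecoregion, module,
#'   completeness) and `by_ecoregion` (data.frame ecoregion, module,
#'   mean_completeness, n_populations).
#' @export
moduleCompleteness <- function(presence, membership, ecoregions) {
  taxa <- intersect(names(membership), rownames(presence))
  if (!length(taxa)) stop("membership and presence share no taxa")
  sitesIds <- colnames(presence)
  if (!all(sitesIds %in% names(ecoregions)))
    stop("every site needs an ecoregion label")
  mods <- sort(unique(as.integer(membership[taxa])))
  rows <- list()
  for (m in mods) {
    mt <- taxa[membership[taxa] == m]
    if (!length(mt)) { warning("empty module ", m, " excluded"); next }
    comp <- colSums(presence[mt, , drop = FALSE] > 0) / length(mt)
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sitesIds, ecoregion = ecoregions[sitesIds], module = m,
      completeness = as.numeric(comp), row.names = NULL,
      stringsAsFactors = FALSE)
  }
  byPop <- do.call(rbind, rows)
  agg <- aggregate(completeness ~ ecoregion + module, byPop, mean)
  nPop <- aggregate(site_id ~ ecoregion, unique(byPop[, c("site_id",
                                                          "ecoregion")]),
                    length)
  names(agg)[3] <- "mean_completeness"
  names(nPop)[2] <- "n_populations"
  byEco <- merge(agg, nPop, by = "ecoregion")
  byEco <- byEco[order(byEco$ecoregion, byEco$module), ]
  rownames(byEco) <- NULL
  list(by_population = byPop, by_ecoregion = byEco)
}

#' Compare a per-population metric across groups
#'
#' One-way linear model of the metric on the group factor, all pairwise
#' comparisons of group means Bonferroni-adjusted (estimated marginal
#' means), and a compact letter display: groups sharing a letter are not
#' significantly different at `alpha`. Groups with a single observation are
#' excluded with a warning.
#'
#' @param values numeric vector (e.g. module completeness or mean z per
#'   population).
#' @param groups factor or character vector of the same length (CWP species,
#'   ecoregion, or module labels).
#' @param alpha significance level.
#' @return list: `letters` (named by group), `pairwise` (data.frame of
#'   contrasts with Bonferroni-adjusted p), `group_means`.
#' @export
compareGroups <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  tiny <- names(sizes)[sizes < 2]
  if (length(tiny)) {
    warning("group(s) with a single observation excluded: ",
            paste(tiny, collapse = ", "))
    keep <- !(groups %in% tiny)
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need >= 2 groups with >= 2 values")
  grp <- factor(groups)
  fit <- lm(values ~ grp)
  emm <- emmeans::emmeans(fit, "grp")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "bonferroni"))
  lv <- levels(grp)
  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (r in seq_len(nrow(prs))) {
    nm <- strsplit(prs$contrast[r], " - ")[[1]]
    nm <- gsub("^\\(|\\)$", "", nm)
    pmat[nm[1], nm[2]] <- pmat[nm[2], nm[1]] <- prs$p.value[r]
  }
  means <- tapply(values, grp, mean)
  list(letters = insertAbsorbLetters(pmat, alpha = alpha),
       pairwise = prs, group_means = means)
}
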