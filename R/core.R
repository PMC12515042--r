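# Core community selection and cross-CWP overlap structure.

#' Select the per-kingdom core community
#'
#' Two-step criterion: (1) keep the `ceiling(topFraction * S)` taxa of
#' highest mean relative abundance, the mean taken over *all* samples with
#' zeros included (taxa tied with the boundary value are all kept, so the
#' step is order-free); (2) within that subset, keep taxa present (count >
#' 0) in at least one sample of at least `minCwps` distinct CWP species.
#'
#' @param relAbund taxa x samples proportion matrix ([relativeAbundance()]).
#' @param presence taxa x samples 0/1 matrix ([presenceMatrix()]).
#' @param sites site table mapping sample ids to `cwp_species`.
#' @param topFraction abundance criterion (default 0.10).
#' @param minCwps prevalence criterion (default 4).
#' @param kingdom kingdom tag carried into the result.
#' @return a [CoreSet-class]; its `stats` slot reports, for every
#'   abundance-passing taxon, the mean relative abundance and CWP prevalence.
#' @export
selectCore <- function(relAbund, presence, sites, topFraction = 0.10,
                       minCwps = 4L, kingdom = "") {
  if (!nrow(relAbund) || !ncol(relAbund)) stop("empty table")
  stopifnot(identical(dimnames(relAbund), dimnames(presence)))
  common <- intersect(colnames(relAbund), sites$site_id)
  if (length(common) < ncol(relAbund))
    stop("sample(s) absent from the site table: ",
         paste(setdiff(colnames(relAbund), sites$site_id), collapse = ", "),
         call. = FALSE)
  if (minCwps > length(unique(sites$cwp_species)))
    stop("minCwps exceeds the number of CWP species")
  cwpOf <- setNames(sites$cwp_species, sites$site_id)[colnames(presence)]
  S <- nrow(relAbund)
  meanAb <- rowMeans(relAbund)
  nKeep <- ceiling(topFraction * S)
  cut <- sort(meanAb, decreasing = TRUE)[nKeep]
  step1 <- names(meanAb)[meanAb >= cut]  # ties at the boundary all included
  prev <- vapply(step1, function(tx) {
    length(unique(cwpOf[presence[tx, ] > 0]))
  }, integer(1))
  core <- step1[prev >= minCwps]
  stats <- data.frame(taxon = step1, mean_rel_abund = meanAb[step1],
                      cwp_prevalence = prev, in_core = step1 %in% core,
                      row.names = NULL, stringsAsFactors = FALSE)
  stats <- stats[order(-stats$mean_rel_abund, stats$taxon), ]
  readShare <- sum(meanAb[core]) / sum(meanAb)
  new("CoreSet", kingdom = kingdom, taxa = core, stats = stats,
      topFraction = topFraction, minCwps = as.integer(minCwps),
      readShare = readShare, richnessShare = length(core) / S)
}

#' Cross-CWP overlap signatures of the core community
#'
#' For every observed presence signature (the exact set of CWP species a
#' core taxon occurs in) the number of core taxa carrying it — the
#' intersection counts behind an UpSet plot. Signatures with zero taxa are
#' omitted; counts partition the core, so they sum to its size.
#'
#' @param core a [CoreSet-class].
#' @param presence taxa x samples 0/1 matrix.
#' @param sites site table mapping sample ids to `cwp_species`.
#' @return data.frame: `signature` (CWP names joined by `&`), `degree`
#'   (number of species in the signature), `count`.
#' @export
overlapCounts <- function(core, presence, sites) {
  taxa <- coreTaxa(core)
  if (!length(taxa)) stop("empty core set")
  cwpOf <- setNames(sites$cwp_species, sites$site_id)[colnames(presence)]
  sigs <- vapply(taxa, function(tx) {
    sp <- sort(unique(cwpOf[presence[tx, ] > 0]))
    paste(sp, collapse = "&")
  }, character(1))
  tab <- table(sigs)
  out <- data.frame(signature = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$degree, -out$count, out$signature), ]
}
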