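# Probabilistic co-presence testing and network construction.

#' Exact probability of at least the observed number of co-presences
#'
#' Under independent random placement of two taxa's presences across `N`
#' sites (taxon a present in `nA` sites, taxon b in `nB`), the number of
#' shared sites follows a hypergeometric distribution. This returns the
#' exact upper tail, inclusive of the observed value:
#' `P(J >= jObs) = sum_{j >= jObs} C(nA, j) C(N - nA, nB - j) / C(N, nB)`.
#' Terms are accumulated in log space so the computation is stable for `N`
#' in the tens of thousands. Symmetric in the two taxa.
#'
#' @param N number of sites.
#' @param nA,nB presence counts of the two taxa.
#' @param jObs observed co-presences (may be a vector).
#' @param lower if `TRUE`, return the lower tail `P(J <= jObs)` instead
#'   (used to flag significant segregation).
#' @return numeric vector of tail probabilities in (0, 1].
#' @export
copresencePvalue <- function(N, nA, nB, jObs, lower = FALSE) {
  stopifnot(length(N) == 1, length(nA) == 1, length(nB) == 1)
  if (nA < 0 || nB < 0 || nA > N || nB > N)
    stop("need 0 <= nA, nB <= N")
  jMin <- max(0, nA + nB - N)
  jMax <- min(nA, nB)
  if (any(jObs < jMin | jObs > jMax))
    stop("jObs outside the feasible range [", jMin, ", ", jMax, "]")
  js <- jMin:jMax
  logTerms <- lchoose(nA, js) + lchoose(N - nA, nB - js) - lchoose(N, nB)
  # log-space suffix sums: log P(J >= j) for every feasible j
  m <- max(logTerms)
  w <- exp(logTerms - m)
  upperLog <- m + log(rev(cumsum(rev(w))))
  lowerLog <- m + log(cumsum(w))
  idx <- match(jObs, js)
  p <- exp(if (lower) lowerLog[idx] else upperLog[idx])
  pmin(p, 1)
}

#' Build a co-occurrence network from a presence-absence matrix
#'
#' Tests every unordered pair of taxa for excess co-presence with the exact
#' hypergeometric tail and connects pairs with `p < alpha`. Taxa present in
#' zero or in all sites are skipped (the test is uninformative for them) but
#' retained as isolated nodes. Only positive (co-presence) associations
#' become edges; significant segregations (lower tail below `alpha`) are
#' recorded in the `tests` slot.
#'
#' @param presence taxa x sites 0/1 matrix of core taxa.
#' @param alpha edge significance level (default 0.05).
#' @param kingdom kingdom tag.
#' @param fdr if `TRUE`, apply Benjamini-Hochberg correction to the upper
#'   tail p-values before thresholding (off by default: raw `p < alpha`).
#' @return a [CooccurrenceNetwork-class] with modules unset.
#' @export
buildNetwork <- function(presence, alpha = 0.05, kingdom = "", fdr = FALSE) {
  stopifnot(is.matrix(presence))
  if (nrow(presence) < 2) stop("need >= 2 taxa")
  if (ncol(presence) < 2) stop("need >= 2 sites")
  presence <- (presence > 0) + 0L
  N <- ncol(presence)
  prev <- rowSums(presence)
  informative <- prev > 0 & prev < N
  taxa <- rownames(presence)
  testTaxa <- taxa[informative]
  if (length(testTaxa) >= 2) {
    pairs <- combn(testTaxa, 2)
    pa <- presence[testTaxa, , drop = FALSE]
    jmat <- tcrossprod(pa)  # co-presence counts for all pairs at once
    nP <- ncol(pairs)
    pu <- numeric(nP); pl <- numeric(nP); jv <- integer(nP)
    for (q in seq_len(nP)) {
      a <- pairs[1, q]; b <- pairs[2, q]
      jv[q] <- jmat[a, b]
      pu[q] <- copresencePvalue(N, prev[[a]], prev[[b]], jv[q])
      pl[q] <- copresencePvalue(N, prev[[a]], prev[[b]], jv[q], lower = TRUE)
    }
    tests <- data.frame(taxon_a = pairs[1, ], taxon_b = pairs[2, ],
                        n_a = as.integer(prev[pairs[1, ]]),
                        n_b = as.integer(prev[pairs[2, ]]),
                        j_obs = jv, p_upper = pu, p_lower = pl,
                        stringsAsFactors = FALSE)
  } else {
    tests <- data.frame(taxon_a = character(0), taxon_b = character(0),
                        n_a = integer(0), n_b = integer(0),
                        j_obs = integer(0), p_upper = numeric(0),
                        p_lower = numeric(0))
  }
  pAdj <- if (fdr && nrow(tests)) p.adjust(tests$p_upper, "BH") else
    tests$p_upper
  sig <- if (nrow(tests)) pAdj < alpha else logical(0)
  edges <- tests[sig, c("taxon_a", "taxon_b", "j_obs", "p_upper")]
  names(edges)[4] <- "p_value"
  rownames(edges) <- NULL
  tests$segregation <- tests$p_lower < alpha
  new("CooccurrenceNetwork", kingdom = kingdom, nodes = taxa,
      edges = edges, tests = tests, membership = integer(0),
      modularity = NA_real_, mainModules = integer(0), alpha = alpha)
}

#' Detect modules with short random walks (walktrap)
#'
#' Runs walktrap agglomeration (default walk length 4) on the network and
#' keeps the cut maximising modularity. Module ids are ordered by descending
#' module size; isolated nodes form singleton modules. Modularity is
#' reported on the full graph; an edgeless network gets modularity 0 by
#' convention.
#'
#' @param net a [CooccurrenceNetwork-class] from [buildNetwork()].
#' @param steps random-walk length.
#' @param seed integer seed (walktrap is deterministic; the seed guards any
#'   tie-breaking done by the backend).
#' @return the network with `membership`, `modularity` set.
#' @export
detectModules <- function(net, steps = 4L, seed = 1L) {
  stopifnot(is(net, "CooccurrenceNetwork"))
  g <- asIgraph(net)
  set.seed(seed)
  if (igraph::ecount(g) == 0) {
    mem <- setNames(seq_along(net@nodes), net@nodes)
    net@membership <- mem
    net@modularity <- 0
    return(net)
  }
  wt <- igraph::cluster_walktrap(g, steps = steps)
  memRaw <- igraph::membership(wt)
  mod <- igraph::modularity(g, memRaw)
  # relabel module ids by descending size (ties by smallest member name)
  sizes <- table(memRaw)
  firstName <- vapply(names(sizes), function(m) {
    min(net@nodes[memRaw == as.integer(m)])
  }, character(1))
  ord <- order(-as.integer(sizes), firstName)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  mem <- setNames(as.integer(relabel[as.character(memRaw)]), net@nodes)
  net@membership <- mem
  net@modularity <- mod
  validObject(net)
  net
}

#' Flag main modules
#'
#' Modules with at least `minSize` nodes are flagged "main"; the rest form a
#' residual class for downstream reporting.
#'
#' @param net a network with modules set.
#' @param minSize minimum node count for a main module.
#' @return the network with `mainModules` set.
#' @export
mainModules <- function(net, minSize = 5L) {
  stopifnot(is(net, "CooccurrenceNetwork"), length(net@membership) > 0)
  sizes <- table(net@membership)
  net@mainModules <- sort(as.integer(names(sizes)[sizes >= minSize]))
  net
}
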