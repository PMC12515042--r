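#' Pipeline run configuration
#'
#' Holds every tunable constant of the pipeline. The defaults reproduce the
#' published analysis settings: rarefaction depths of 12000/8000/5000/250
#' reads for bacteria/fungi/protists/invertebrates, core selection keeping
#' the top 10% of phylotypes by mean relative abundance that occur in at
#' least 4 CWP species, co-presence edges at raw P < 0.05, walktrap with
#' 4-step walks, ecoregion K-means over k = 2..10 on the first 5 weighted PCA
#' axes, a VIF threshold of 5, 1000 bootstrap simulations, and predictive
#' mean matching with 999 chained cycles and 5 donors.
#'
#' @slot seed integer root seed for all randomness.
#' @slot rarefactionDepths named integer vector, reads per sample by kingdom.
#' @slot coreTopFraction proportion in (0, 1]: abundance criterion.
#' @slot coreMinCwps integer: prevalence criterion (distinct CWP species).
#' @slot edgeAlpha significance level for network edges.
#' @slot walktrapSteps random-walk length for module detection.
#' @slot kmeansKRange integer vector of candidate cluster numbers (all > 1).
#' @slot nPcaAxes number of PCA axes entering the clustering.
#' @slot vifThreshold variance inflation factor cutoff.
#' @slot nBootstrap parametric bootstrap replicates for coefficient CIs.
#' @slot imputeCycles chained-equation cycles for PMM imputation.
#' @slot imputeDonors PMM donor pool size.
#' @export
setClass("RunConfig", representation(
  seed = "integer",
  rarefactionDepths = "integer",
  coreTopFraction = "numeric",
  coreMinCwps = "integer",
  edgeAlpha = "numeric",
  walktrapSteps = "integer",
  kmeansKRange = "integer",
  nPcaAxes = "integer",
  vifThreshold = "numeric",
  nBootstrap = "integer",
  imputeCycles = "integer",
  imputeDonors = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (length(object@coreTopFraction) != 1 || is.na(object@coreTopFraction) ||
      object@coreTopFraction <= 0 || object@coreTopFraction > 1)
    msg <- c(msg, "coreTopFraction must be in (0, 1]")
  if (object@edgeAlpha <= 0 || object@edgeAlpha >= 1)
    msg <- c(msg, "edgeAlpha must be in (0, 1)")
  pos <- c(coreMinCwps = object@coreMinCwps,
           walktrapSteps = object@walktrapSteps,
           nPcaAxes = object@nPcaAxes, vifThreshold = object@vifThreshold,
           nBootstrap = object@nBootstrap, imputeCycles = object@imputeCycles,
           imputeDonors = object@imputeDonors)
  if (any(is.na(pos)) || any(pos <= 0))
    msg <- c(msg, "all thresholds must be strictly positive")
  if (any(object@rarefactionDepths <= 0))
    msg <- c(msg, "rarefaction depths must be strictly positive")
  if (any(object@kmeansKRange < 2))
    msg <- c(msg, "kmeansKRange must not contain k < 2 (CH undefined at k = 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param seed integer root seed.
#' @param rarefactionDepths named integer vector of per-kingdom depths.
#' @param coreTopFraction,coreMinCwps core-selection criteria.
#' @param edgeAlpha,walktrapSteps network settings.
#' @param kmeansKRange,nPcaAxes ecoregion clustering settings.
#' @param vifThreshold,nBootstrap driver-model settings.
#' @param imputeCycles,imputeDonors PMM imputation settings.
#' @return a validated [RunConfig-class] object.
#' @examples
#' cfg <- runConfig(seed = 1)
#' cfg@rarefactionDepths
#' @export
runConfig <- function(seed = 1L,
                      rarefactionDepths = c(bacteria = 12000L, fungi = 8000L,
                                            protists = 5000L,
                                            invertebrates = 250L),
                      coreTopFraction = 0.10, coreMinCwps = 4L,
                      edgeAlpha = 0.05, walktrapSteps = 4L,
                      kmeansKRange = 2:10, nPcaAxes = 5L,
                      vifThreshold = 5, nBootstrap = 1000L,
                      imputeCycles = 999L, imputeDonors = 5L) {
  obj <- new("RunConfig", seed = as.integer(seed),
             rarefactionDepths = setNames(as.integer(rarefactionDepths),
                                          names(rarefactionDepths)),
             coreTopFraction = coreTopFraction,
             coreMinCwps = as.integer(coreMinCwps),
             edgeAlpha = edgeAlpha, walktrapSteps = as.integer(walktrapSteps),
             kmeansKRange = as.integer(kmeansKRange),
             nPcaAxes = as.integer(nPcaAxes), vifThreshold = vifThreshold,
             nBootstrap = as.integer(nBootstrap),
             imputeCycles = as.integer(imputeCycles),
             imputeDonors = as.integer(imputeDonors))
  validObject(obj)
  obj
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig (seed ", object@seed, ")\n", sep = "")
  cat("  rarefaction depths:",
      paste(names(object@rarefactionDepths), object@rarefactionDepths,
            sep = "=", collapse = ", "), "\n")
  cat("  core: top ", object@coreTopFraction * 100, "% of taxa, >= ",
      object@coreMinCwps, " CWPs\n", sep = "")
  cat("  network: alpha ", object@edgeAlpha, ", walktrap steps ",
      object@walktrapSteps, "\n", sep = "")
  cat("  ecoregions: k in {", paste(range(object@kmeansKRange),
                                    collapse = ".."),
      "} on ", object@nPcaAxes, " weighted PCA axes\n", sep = "")
  cat("  drivers: VIF <= ", object@vifThreshold, ", ", object@nBootstrap,
      " bootstrap reps\n", sep = "")
  cat("  imputation: ", object@imputeCycles, " PMM cycles, ",
      object@imputeDonors, " donors\n", sep = "")
})

#' Core community of a kingdom
#'
#' The per-kingdom set of phylotypes passing both selection criteria: they
#' rank in the top fraction of taxa by mean relative abundance (zeros
#' included) and occur in at least `minCwps` distinct CWP species.
#'
#' @slot kingdom character tag.
#' @slot taxa character vector of core phylotype ids.
#' @slot stats data.frame with one row per *abundance-passing* taxon:
#'   `taxon`, `mean_rel_abund`, `cwp_prevalence`, `in_core`.
#' @slot topFraction,minCwps the thresholds used.
#' @slot readShare proportion of total reads carried by the core.
#' @slot richnessShare proportion of total taxa in the core.
#' @export
setClass("CoreSet", representation(
  kingdom = "character", taxa = "character", stats = "data.frame",
  topFraction = "numeric", minCwps = "integer",
  readShare = "numeric", richnessShare = "numeric"
))

setValidity("CoreSet", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@taxa)) msg <- c(msg, "duplicated core taxa")
  if (!all(object@taxa %in% object@stats$taxon))
    msg <- c(msg, "core taxa missing from stats table")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoreSet-class core phylotype ids.
#' @param x,object a `CoreSet`.
#' @export
coreTaxa <- function(x) x@taxa

setMethod("show", "CoreSet", function(object) {
  cat("CoreSet<", object@kingdom, ">: ", length(object@taxa),
      " core phylotypes (top ", object@topFraction * 100, "%, >= ",
      object@minCwps, " CWPs)\n", sep = "")
  cat("  share of richness ", round(object@richnessShare * 100, 1),
      "%, share of reads ", round(object@readShare * 100, 1), "%\n", sep = "")
})

#' Probabilistic co-occurrence network
#'
#' Nodes are core phylotypes; edges join pairs whose observed number of
#' co-presences across sites exceeds what independent random placement would
#' give (exact hypergeometric upper tail below `alpha`). Modules are walktrap
#' communities; `mainModules` flags the modules of at least the configured
#' size.
#'
#' @slot kingdom character tag.
#' @slot nodes character node ids (isolated nodes retained).
#' @slot edges data.frame: `taxon_a`, `taxon_b`, `j_obs`, `p_value`.
#' @slot tests data.frame of all informative pair tests (including
#'   non-significant ones and significant segregations, flagged).
#' @slot membership named integer vector, node -> module id (ids ordered by
#'   descending module size).
#' @slot modularity graph modularity of the module partition.
#' @slot mainModules integer ids of modules flagged as "main".
#' @slot alpha edge significance level used.
#' @export
setClass("CooccurrenceNetwork", representation(
  kingdom = "character", nodes = "character", edges = "data.frame",
  tests = "data.frame", membership = "integer", modularity = "numeric",
  mainModules = "integer", alpha = "numeric"
))

setValidity("CooccurrenceNetwork", function(object) {
  msg <- character(0)
  if (nrow(object@edges)) {
    if (any(object@edges$taxon_a == object@edges$taxon_b))
      msg <- c(msg, "self edges are not allowed")
    if (!all(c(object@edges$taxon_a, object@edges$taxon_b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(object@membership) &&
      !setequal(names(object@membership), object@nodes))
    msg <- c(msg, "module membership must cover exactly the node set")
  if (length(object@modularity) && !is.na(object@modularity) &&
      (object@modularity < -0.5 - 1e-9 || object@modularity > 1 + 1e-9))
    msg <- c(msg, "modularity out of [-0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CooccurrenceNetwork-class edge table.
#' @param x,object a `CooccurrenceNetwork`.
#' @export
networkEdges <- function(x) x@edges

#' @describeIn CooccurrenceNetwork-class node -> module id map.
#' @export
moduleMembership <- function(x) x@membership

#' @describeIn CooccurrenceNetwork-class modularity of the partition.
#' @export
networkModularity <- function(x) x@modularity

#' @describeIn CooccurrenceNetwork-class ids of main (large) modules.
#' @export
mainModuleIds <- function(x) x@mainModules

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat("CooccurrenceNetwork<", object@kingdom, ">: ", length(object@nodes),
      " nodes, ", nrow(object@edges), " edges (alpha ", object@alpha, ")\n",
      sep = "")
  if (length(object@membership)) {
    sizes <- sort(table(object@membership), decreasing = TRUE)
    cat("  ", length(sizes), " modules (sizes ",
        paste(head(sizes, 6), collapse = ", "),
        if (length(sizes) > 6) ", ..." else "", "), modularity ",
        round(object@modularity, 3), "\n", sep = "")
    if (length(object@mainModules))
      cat("  main modules:", paste(object@mainModules, collapse = ", "), "\n")
  }
})

# igraph view of a network (positive significant edges only).
asIgraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net@nodes), name = net@nodes)
  if (nrow(net@edges)) {
    g <- igraph::add_edges(
      g, rbind(match(net@edges$taxon_a, net@nodes),
               match(net@edges$taxon_b, net@nodes)),
      j_obs = net@edges$j_obs, p_value = net@edges$p_value)
  }
  g
}
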