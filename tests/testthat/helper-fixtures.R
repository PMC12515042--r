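# Shared fixtures, generated in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

# Reduced-scale synthetic survey (the study design with smaller taxon counts).
cachedStudy <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulateStudy(seed = 42,
                                     kingdoms = kingdomDefaults(reduced = TRUE))
  }
  .fixtures$study
}

pipelineConfig <- function() {
  runConfig(seed = 42, imputeCycles = 10L, nBootstrap = 99L)
}

# Full pipeline run on the cached study (written to a session temp dir).
cachedPipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    st <- cachedStudy()
    .fixtures$pipelineDir <- file.path(tempdir(), "cwpsoil-pipeline-run")
    .fixtures$pipeline <- suppressWarnings(
      runPipeline(st$counts, st$sites, st$env, pipelineConfig(),
                  outDir = .fixtures$pipelineDir, verbose = FALSE))
  }
  .fixtures$pipeline
}

cachedPipelineDir <- function() {
  cachedPipeline()
  .fixtures$pipelineDir
}

# Small deterministic count matrix with named dims.
toyCounts <- function(values, nTaxa, nSamples,
                      taxa = sprintf("t%02d", seq_len(nTaxa)),
                      samples = sprintf("s%02d", seq_len(nSamples))) {
  matrix(as.integer(values), nrow = nTaxa, ncol = nSamples,
         dimnames = list(taxa, samples))
}

# Site table mapping samples to CWP species round-robin.
toySites <- function(samples, nCwps = 2L) {
  data.frame(site_id = samples,
             cwp_species = rep(sprintf("cwp%02d", seq_len(nCwps)),
                               length.out = length(samples)),
             latitude = 0, longitude = 0, stringsAsFactors = FALSE)
}

# Adjusted Rand index between two labelings (independent of the package).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- sumi * sumj / choose(n, 2)
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}

# Exact upper-tail co-presence probability by direct rational arithmetic:
# integer numerator sums over binomial coefficients divided by C(N, nB).
# Independent of the package's log-space implementation.
bruteForceTail <- function(N, nA, nB, j) {
  js <- max(0, nA + nB - N):min(nA, nB)
  terms <- choose(nA, js) * choose(N - nA, nB - js)
  sum(terms[js >= j]) / choose(N, nB)
}
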