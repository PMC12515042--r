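# Synthetic survey generator with planted ground truth.
#
# The generator emulates the processed tables of a 125-population,
# 10-species CWP survey: four latent ecoregions driven by two edaphoclimatic
# gradients, per-kingdom count tables with a dominant prevalent core,
# ecoregion-linked co-occurrence modules, and module abundances linearly
# coupled to environmental predictors with a CWP-level random intercept.
# Everything planted is recorded in a `truth` list so downstream stages have
# ground-truth recovery tests.

#' Simulate site metadata for a CWP survey
#'
#' Partitions `nSites` populations across `nCwps` wild progenitor species
#' (10-15 populations per species at the default 125/10 design), concentrates
#' each species' populations in one or two latent ecoregions, and draws
#' coordinates around per-ecoregion centres.
#'
#' @param nSites number of wild populations.
#' @param nCwps number of CWP species.
#' @param kEcoregions number of latent ecoregions.
#' @param seed integer seed.
#' @return list with `sites` (data.frame: site_id, cwp_species, latitude,
#'   longitude) and `truth` (list with `k_ecoregions`, `site_ecoregion`,
#'   `cwp_ecoregion`).
#' @export
simulateSites <- function(nSites = 125L, nCwps = 10L, kEcoregions = 4L,
                          seed = 1L) {
  if (nSites < nCwps || nCwps < 1) stop("need nSites >= nCwps >= 1")
  if (kEcoregions < 1) stop("need kEcoregions >= 1")
  if (kEcoregions > nSites) stop("more ecoregions than sites")
  set.seed(seed)
  # populations per species: floor + remainder spread over random species
  base <- nSites %/% nCwps
  counts <- rep(base, nCwps)
  extra <- nSites - base * nCwps
  if (extra > 0) {
    idx <- sample.int(nCwps, extra)
    counts[idx] <- counts[idx] + 1L
  }
  cwpNames <- sprintf("cwp%02d", seq_len(nCwps))
  cwp <- rep(cwpNames, counts)
  # each species has a primary ecoregion; half the species also use a
  # secondary one for ~25% of their populations (species straddle ecoregions)
  primary <- rep(seq_len(kEcoregions), length.out = nCwps)
  secondary <- as.integer(ifelse(runif(nCwps) < 0.5 & kEcoregions > 1,
                                 (primary %% kEcoregions) + 1L, primary))
  eco <- integer(nSites)
  pos <- 1L
  for (i in seq_len(nCwps)) {
    n_i <- counts[i]
    nSec <- if (secondary[i] != primary[i]) max(0L, round(0.25 * n_i)) else 0L
    eco[pos:(pos + n_i - 1L)] <- c(rep(primary[i], n_i - nSec),
                                   rep(secondary[i], nSec))
    pos <- pos + n_i
  }
  # guarantee every ecoregion is represented
  for (e in seq_len(kEcoregions)) {
    if (!any(eco == e)) eco[sample.int(nSites, 1)] <- e
  }
  centres <- cbind(lat = seq(-40, 40, length.out = kEcoregions),
                   lon = seq(-100, 100, length.out = kEcoregions))
  lat <- pmin(90, pmax(-90, centres[eco, "lat"] + rnorm(nSites, 0, 3)))
  lon <- pmin(180, pmax(-180, centres[eco, "lon"] + rnorm(nSites, 0, 3)))
  sites <- data.frame(site_id = sprintf("site%03d", seq_len(nSites)),
                      cwp_species = cwp, latitude = lat, longitude = lon,
                      stringsAsFactors = FALSE)
  validateSiteTable(sites)
  truth <- list(k_ecoregions = as.integer(kEcoregions),
                site_ecoregion = setNames(eco, sites$site_id),
                cwp_ecoregion = setNames(primary, cwpNames))
  list(sites = sites, truth = truth)
}

# Canonical 18 edaphoclimatic variables with realistic centres and scales.
# Linear in the two latent gradients, so the noise-free table has rank 2.
envVariableScales <- function(nVars) {
  canon <- data.frame(
    var = c("MAP", "MAT", "TSEA", "PSEA", "MDR", "AI", "pH", "conductivity",
            "sand", "SOC", "totalC", "totalN", "NH4", "NO3", "PO4", "Ca",
            "K", "NDVI"),
    centre = c(900, 16, 600, 45, 11, 0.8, 6.5, 1.2, 50, 2.5, 3.5, 0.35,
               12, 20, 8, 450, 260, 0.45),
    stringsAsFactors = FALSE)
  canon$scale <- canon$centre / 7  # keeps bounded variables inside range
  if (nVars <= nrow(canon)) return(canon[seq_len(nVars), ])
  extra <- data.frame(var = sprintf("env%02d", seq_len(nVars - nrow(canon))),
                      centre = 10, scale = 10 / 7)
  rbind(canon, extra)
}

#' Simulate an edaphoclimatic table with two latent gradients
#'
#' Each variable is a linear combination of two latent factors whose levels
#' are set by ecoregion centroids (plus site-level jitter), with additive
#' Gaussian noise, rescaled to realistic units per variable. Cells are then
#' blanked completely at random at `missingFraction` and recorded in the
#' truth object.
#'
#' @param sites site table from [simulateSites()].
#' @param truth truth list from [simulateSites()].
#' @param nVars number of variables (default 18).
#' @param noiseSd Gaussian noise standard deviation on the latent scale.
#' @param missingFraction proportion of cells blanked at random.
#' @param seed integer seed.
#' @return list with `env` (data.frame, site_id + variables) and updated
#'   `truth` (adds `gradient_loadings`, `env_centroids`, `missing_mask`,
#'   `latent_factors`).
#' @export
simulateEnvironment <- function(sites, truth, nVars = 18L, noiseSd = 0.5,
                                missingFraction = 0.04, seed = 1L) {
  if (nVars < 2) stop("need nVars >= 2")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (missingFraction < 0 || missingFraction >= 1)
    stop("missingFraction must be in [0, 1)")
  set.seed(seed)
  n <- nrow(sites)
  k <- truth$k_ecoregions
  eco <- truth$site_ecoregion[sites$site_id]
  # well-separated ecoregion centroids on a circle in the 2-D latent space
  ang <- 2 * pi * (seq_len(k) - 1) / max(k, 2) + pi / 4
  centroids <- 3 * cbind(cos(ang), sin(ang))
  jitterSd <- if (noiseSd > 0) 0.25 else 0
  f <- centroids[eco, , drop = FALSE] +
    matrix(rnorm(2 * n, 0, jitterSd), n, 2)
  loadings <- matrix(rnorm(2L * nVars), nVars, 2)
  loadings <- loadings / sqrt(rowSums(loadings^2))  # unit loading rows
  raw <- f %*% t(loadings) + matrix(rnorm(n * nVars, 0, noiseSd), n, nVars)
  sc <- envVariableScales(nVars)
  env <- sweep(sweep(raw, 2, sc$scale, `*`), 2, sc$centre, `+`)
  colnames(env) <- sc$var
  mask <- matrix(runif(n * nVars) < missingFraction, n, nVars)
  env[mask] <- NA_real_
  out <- data.frame(site_id = sites$site_id, env, check.names = FALSE,
                    stringsAsFactors = FALSE)
  stopifnot(all(out$sand >= 0 & out$sand <= 100, na.rm = TRUE),
            all(out$AI > 0, na.rm = TRUE))
  truth$gradient_loadings <- loadings
  truth$env_centroids <- centroids
  truth$latent_factors <- f
  truth$missing_mask <- which(mask, arr.ind = TRUE)
  list(env = out, truth = truth)
}

#' Default per-kingdom count simulation settings
#'
#' Richness, planted-core fraction, module count, and sequencing depth per
#' kingdom. Depths are set comfortably above the rarefaction depths so few
#' samples are lost.
#'
#' @param reduced logical; if `TRUE`, use reduced taxon counts suitable for
#'   fast end-to-end runs (the planted structure is unchanged).
#' @return named list of per-kingdom config lists.
#' @export
kingdomDefaults <- function(reduced = FALSE) {
  full <- list(
    bacteria = list(nTaxa = 2000L, coreFraction = 0.02, nModules = 2L,
                    depthMean = 24000, overdispersion = 0.02),
    fungi = list(nTaxa = 1500L, coreFraction = 0.02, nModules = 2L,
                 depthMean = 16000, overdispersion = 0.02),
    protists = list(nTaxa = 800L, coreFraction = 0.02, nModules = 2L,
                    depthMean = 10000, overdispersion = 0.02),
    invertebrates = list(nTaxa = 300L, coreFraction = 0.03, nModules = 2L,
                         depthMean = 600, overdispersion = 0.02))
  if (reduced) {
    small <- c(bacteria = 400L, fungi = 300L, protists = 200L,
               invertebrates = 200L)
    frac <- c(bacteria = 0.08, fungi = 0.08, protists = 0.09,
              invertebrates = 0.09)
    for (k in names(full)) {
      full[[k]]$nTaxa <- small[[k]]
      full[[k]]$coreFraction <- frac[[k]]  # keeps planted core ~2-3 dozen
    }
  }
  full
}

#' Simulate a per-kingdom phylotype count table with planted structure
#'
#' Planted core taxa (a `coreFraction` minority of taxa) receive high mean
#' relative abundance and broad prevalence across CWP species; the remaining
#' taxa are rare and geographically restricted to the sites of 1-3 species.
#' A subset of the core is organised into disjoint modules, each tied to one
#' ecoregion: module taxa are almost always present (and abundance-boosted)
#' in their ecoregion and only sporadically present elsewhere, planting both
#' a co-occurrence signal and an ecoregion completeness gradient. Counts are
#' Dirichlet-multinomial per sample (gamma-weight construction) at lognormal
#' sequencing depths.
#'
#' @param sites site table.
#' @param truth truth list (needs `site_ecoregion`).
#' @param kingdom kingdom tag, e.g. `"bacteria"`.
#' @param cfg list with `nTaxa`, `coreFraction`, `nModules`, `depthMean`,
#'   `overdispersion` (see [kingdomDefaults()]).
#' @param seed integer seed.
#' @return list with `counts` (a `SummarizedExperiment`) and updated `truth`
#'   (adds, under `truth$kingdoms[[kingdom]]`: `core_taxa`,
#'   `module_membership`, `module_ecoregion`).
#' @export
simulateCounts <- function(sites, truth, kingdom = "bacteria",
                           cfg = kingdomDefaults()[[kingdom]], seed = 1L) {
  cfg <- modifyList(kingdomDefaults()[["bacteria"]], cfg)
  if (cfg$nTaxa < 10) stop("need nTaxa >= 10")
  if (cfg$nModules < 1) stop("need nModules >= 1")
  if (cfg$coreFraction >= 1) stop("coreFraction must be < 1")
  set.seed(seed)
  n <- nrow(sites)
  eco <- truth$site_ecoregion[sites$site_id]
  k <- truth$k_ecoregions
  S <- cfg$nTaxa
  pre <- toupper(substr(kingdom, 1, 1))
  taxa <- sprintf("%s%05d", pre, seq_len(S))
  nCore <- max(cfg$nModules * 4L, round(cfg$coreFraction * S))
  coreTaxa <- taxa[seq_len(nCore)]
  # modules: disjoint subsets of the core, each tied to one ecoregion
  nModTaxa <- floor(0.6 * nCore / cfg$nModules)
  membership <- integer(0)
  for (m in seq_len(cfg$nModules)) {
    ids <- coreTaxa[((m - 1) * nModTaxa + 1):(m * nModTaxa)]
    membership <- c(membership, setNames(rep(m, length(ids)), ids))
  }
  moduleEco <- setNames(((seq_len(cfg$nModules) - 1) %% k) + 1L,
                        seq_len(cfg$nModules))
  # base mean relative abundances: core carries ~60% of the mass
  baseCore <- rep(0.60 / nCore, nCore)
  rareMass <- rlnorm(S - nCore, 0, 1)
  baseRare <- 0.40 * rareMass / sum(rareMass)
  base <- c(baseCore, baseRare)
  # presence probabilities
  pPres <- matrix(0, nrow = S, ncol = n, dimnames = list(taxa, NULL))
  pPres[seq_len(nCore), ] <- 0.92           # shared core: ubiquitous
  for (tx in names(membership)) {           # module taxa: ecoregion-linked
    inEco <- eco == moduleEco[[as.character(membership[[tx]])]]
    pPres[tx, ] <- ifelse(inEco, 0.95, 0.25)
  }
  cwpIdx <- as.integer(factor(sites$cwp_species))
  nCwp <- max(cwpIdx)
  for (i in seq.int(nCore + 1L, S)) {       # rare taxa: 1-3 home species
    nHome <- sample.int(3L, 1L)
    home <- sample.int(nCwp, min(nHome, nCwp))
    pPres[i, ] <- ifelse(cwpIdx %in% home, 0.30, 0)
  }
  # abundance multiplier for module taxa inside their ecoregion
  mult <- matrix(1, nrow = S, ncol = n, dimnames = list(taxa, NULL))
  for (tx in names(membership)) {
    inEco <- eco == moduleEco[[as.character(membership[[tx]])]]
    mult[tx, inEco] <- 6
  }
  tau <- 1 / cfg$overdispersion  # Dirichlet concentration scale
  depths <- pmax(1L, round(rlnorm(n, log(cfg$depthMean), 0.2)))
  counts <- matrix(0L, nrow = S, ncol = n,
                   dimnames = list(taxa, sites$site_id))
  for (j in seq_len(n)) {
    b <- runif(S) < pPres[, j]
    if (!any(b)) b[sample.int(S, 1)] <- TRUE
    shape <- base[b] * mult[b, j] * tau
    w <- rgamma(sum(b), shape = shape, rate = 1)
    w[w <= 0 | !is.finite(w)] <- 1e-12
    counts[b, j] <- as.integer(rmultinom(1, depths[j], prob = w))
  }
  # generation-time invariant: every planted core taxon spans >= 4 CWP
  # species (or all of them, in designs with fewer than 4)
  prevCwp <- vapply(coreTaxa, function(tx) {
    length(unique(sites$cwp_species[counts[tx, ] > 0]))
  }, integer(1))
  stopifnot(all(prevCwp >= min(4L, nCwp)))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(sites, row.names = sites$site_id))
  metadata(se)$kingdom <- kingdom
  if (is.null(truth$kingdoms)) truth$kingdoms <- list()
  truth$kingdoms[[kingdom]] <- list(core_taxa = coreTaxa,
                                    module_membership = membership,
                                    module_ecoregion = moduleEco)
  list(counts = se, truth = truth)
}

#' Simulate a module-abundance response from a linear mixed model
#'
#' Generates `y_i = sum_g beta_g x_ig + u_cwp(i) + eps_i` with
#' `u ~ N(0, sigmaCwp^2)` and `eps ~ N(0, sigmaResid^2)`, using standardized
#' environmental predictors. Used for LMM parameter-recovery tests
#' independently of the count simulator.
#'
#' @param sites site table (supplies the CWP grouping).
#' @param env complete environment table.
#' @param effects named numeric vector of slopes on standardized predictors.
#' @param sigmaCwp random-intercept standard deviation.
#' @param sigmaResid residual standard deviation.
#' @param seed integer seed.
#' @return list with `response` (named numeric by site), `intercepts`
#'   (named by CWP species) and `effects` echoed back.
#' @export
simulateModuleResponse <- function(sites, env, effects, sigmaCwp = 0.5,
                                   sigmaResid = 0.5, seed = 1L) {
  bad <- setdiff(names(effects), colnames(env))
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  env <- env[match(sites$site_id, env$site_id), , drop = FALSE]
  x <- scale(as.matrix(env[, names(effects), drop = FALSE]))
  cwps <- sort(unique(sites$cwp_species))
  u <- setNames(rnorm(length(cwps), 0, sigmaCwp), cwps)
  y <- drop(x %*% effects) + u[sites$cwp_species] +
    rnorm(nrow(sites), 0, sigmaResid)
  list(response = setNames(as.numeric(y), sites$site_id),
       intercepts = u, effects = effects)
}

#' Simulate the full survey (preset)
#'
#' One call generating the study-design tables: 125 populations of 10 CWP
#' species in 4 ecoregions, an 18-variable edaphoclimatic table with 4%
#' missing cells, and four kingdom count tables with planted cores and
#' ecoregion-linked modules.
#'
#' @param seed integer root seed (split per stage/kingdom internally).
#' @param nSites,nCwps,kEcoregions,nVars,noiseSd,missingFraction study design.
#' @param kingdoms per-kingdom configs, see [kingdomDefaults()].
#' @param outDir optional directory; when given, all tables plus a TSV truth
#'   summary are written there.
#' @return list with `sites`, `env`, `counts` (named list of
#'   `SummarizedExperiment`s) and `truth`.
#' @export
simulateStudy <- function(seed = 1L, nSites = 125L, nCwps = 10L,
                          kEcoregions = 4L, nVars = 18L, noiseSd = 0.5,
                          missingFraction = 0.04,
                          kingdoms = kingdomDefaults(), outDir = NULL) {
  st <- simulateSites(nSites, nCwps, kEcoregions,
                      seed = stageSeed(seed, "sites"))
  ev <- simulateEnvironment(st$sites, st$truth, nVars = nVars,
                            noiseSd = noiseSd,
                            missingFraction = missingFraction,
                            seed = stageSeed(seed, "environment"))
  truth <- ev$truth
  counts <- list()
  for (kg in names(kingdoms)) {
    ct <- simulateCounts(st$sites, truth, kingdom = kg, cfg = kingdoms[[kg]],
                         seed = stageSeed(seed, "counts", kg))
    truth <- ct$truth
    counts[[kg]] <- ct$counts
  }
  out <- list(sites = st$sites, env = ev$env, counts = counts, truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(st$sites, file.path(outDir, "sites.tsv"))
    writeTsv(ev$env, file.path(outDir, "environment.tsv"))
    for (kg in names(counts)) {
      writeCountTable(counts[[kg]], file.path(outDir,
                                              paste0("counts_", kg, ".tsv")))
    }
    tr <- data.frame(site_id = names(truth$site_ecoregion),
                     ecoregion = as.integer(truth$site_ecoregion))
    writeTsv(tr, file.path(outDir, "truth_ecoregions.tsv"))
    mods <- do.call(rbind, lapply(names(truth$kingdoms), function(kg) {
      ki <- truth$kingdoms[[kg]]
      data.frame(kingdom = kg, taxon = ki$core_taxa,
                 module = as.integer(ki$module_membership[ki$core_taxa]),
                 stringsAsFactors = FALSE)
    }))
    writeTsv(mods, file.path(outDir, "truth_core_modules.tsv"))
  }
  out
}
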