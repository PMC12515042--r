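# End-to-end pipeline: impute -> rarefy -> ecoregions -> core -> network ->
# module stats -> drivers.

#' Run the full analysis pipeline
#'
#' Chains every stage on a set of input tables: PMM imputation of the
#' environment table, per-kingdom rarefaction, ecoregion delineation
#' (PCA + weighted scores + K-means/Calinski-Harabasz), core-community
#' selection, co-occurrence network construction with walktrap modules,
#' module completeness / standardized module abundances, and mixed-model
#' driver analysis per kingdom and main module. All randomness derives from
#' `config@seed` via deterministic per-stage sub-seeds, so two runs with the
#' same config and inputs are identical. Every sample id must appear in the
#' site table; any orphan sample is a hard error.
#'
#' @param counts named list (by kingdom) of count containers (matrix or
#'   `SummarizedExperiment`) or file paths to TSV count tables.
#' @param sites site data.frame or TSV path.
#' @param env environment data.frame or TSV path.
#' @param config a [RunConfig-class] (defaults reproduce the published
#'   settings).
#' @param outDir optional output directory; when given, all stage outputs
#'   are written as TSV/graph files.
#' @param predictorGroups named list for variance partitioning.
#' @param mainModuleMinSize minimum size for a "main" module.
#' @param verbose log per-stage progress and record counts.
#' @return list with `config`, `env_imputed`, `rarefied`, `pca`,
#'   `ecoregions`, `core`, `networks`, `module_stats`, `drivers`, `log`.
#' @export
runPipeline <- function(counts, sites, env, config = runConfig(),
                        outDir = NULL,
                        predictorGroups = defaultPredictorGroups(),
                        mainModuleMinSize = 5L, verbose = TRUE) {
  validObject(config)
  logLines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    logLines <<- c(logLines, msg)
    if (verbose) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.character(sites)) sites <- readSiteTable(sites)
  sites <- validateSiteTable(sites)
  if (is.character(env)) env <- readEnvTable(env)
  counts <- lapply(counts, function(ct) {
    if (is.character(ct)) readCountTable(ct) else ct
  })
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named list (kingdom names)")
  say("seed ", config@seed, "; config hash ",
      sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e6)
  for (kg in names(counts)) {
    orphans <- setdiff(colnames(countsMatrix(counts[[kg]])), sites$site_id)
    if (length(orphans))
      stop("samples absent from the site table (", kg, "): ",
           paste(head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(sites$site_id %in% env$site_id))
    stop("sites missing from the environment table")

  # -- impute ---------------------------------------------------------------
  envImp <- stage("impute", imputePMM(env, nCycles = config@imputeCycles,
                                      nDonors = config@imputeDonors,
                                      seed = stageSeed(config@seed,
                                                       "impute")))
  say("impute: ", nrow(envImp), " sites x ",
      ncol(envImp) - 1L, " variables complete")

  # -- rarefy ---------------------------------------------------------------
  rarefied <- list()
  for (kg in names(counts)) {
    depth <- config@rarefactionDepths[[kg]]
    if (is.null(depth) || is.na(depth))
      stop("no rarefaction depth configured for kingdom ", kg)
    rarefied[[kg]] <- stage("rarefy",
      rarefyCounts(counts[[kg]], depth,
                   seed = stageSeed(config@seed, "rarefy", kg)))
    dropped <- if (is(rarefied[[kg]], "SummarizedExperiment"))
      metadata(rarefied[[kg]])$dropped else attr(rarefied[[kg]], "dropped")
    say("rarefy[", kg, "]: depth ", depth, ", ",
        ncol(countsMatrix(rarefied[[kg]])), " samples kept, ",
        length(dropped), " dropped")
  }

  # -- ecoregions -----------------------------------------------------------
  pca <- stage("ecoregions", runPCA(envImp))
  w <- weightScores(pca, min(config@nPcaAxes, ncol(pca$scores)))
  eco <- stage("ecoregions",
    selectEcoregions(w, kRange = config@kmeansKRange,
                     seed = stageSeed(config@seed, "ecoregions")))
  say("ecoregions: k = ", eco$k_selected, " (CH max), sizes ",
      paste(table(eco$labels), collapse = "/"))
  axisTests <- stage("ecoregions",
    testAxisDifferences(pca$scores, sites, nAxes = 2L))

  # -- core + network + module stats per kingdom ----------------------------
  coreSets <- list(); nets <- list(); moduleStats <- list(); drivers <- list()
  ecoOf <- eco$labels
  for (kg in names(rarefied)) {
    m <- countsMatrix(rarefied[[kg]])
    rel <- relativeAbundance(m)
    pres <- presenceMatrix(m)
    core <- stage("core",
      selectCore(rel, pres, sites, topFraction = config@coreTopFraction,
                 minCwps = config@coreMinCwps, kingdom = kg))
    coreSets[[kg]] <- core
    say("core[", kg, "]: ", length(coreTaxa(core)), " of ", nrow(m),
        " taxa; read share ", round(core@readShare * 100, 1), "%")
    if (length(coreTaxa(core)) < 2) {
      say("core[", kg, "]: fewer than 2 core taxa; skipping network stage")
      next
    }
    net <- stage("network",
      buildNetwork(pres[coreTaxa(core), , drop = FALSE],
                   alpha = config@edgeAlpha, kingdom = kg))
    net <- stage("network",
      detectModules(net, steps = config@walktrapSteps,
                    seed = stageSeed(config@seed, "walktrap", kg)))
    net <- mainModules(net, minSize = mainModuleMinSize)
    nets[[kg]] <- net
    say("network[", kg, "]: ", nrow(networkEdges(net)), " edges, ",
        length(unique(moduleMembership(net))), " modules (",
        length(mainModuleIds(net)), " main), modularity ",
        round(networkModularity(net), 3))

    # completeness on main modules; z-scores over all core taxa, then
    # averaged per main module
    memAll <- moduleMembership(net)
    mem <- memAll[memAll %in% mainModuleIds(net)]
    if (!length(mem)) next
    comp <- stage("modules",
      moduleCompleteness(pres, mem, ecoOf[colnames(pres)]))
    zres <- stage("modules",
      moduleZscore(t(m[names(memAll), , drop = FALSE])))
    modAbAll <- stage("modules", moduleAbundance(zres$z, memAll))
    modAb <- modAbAll[, colnames(modAbAll) %in%
                        as.character(mainModuleIds(net)), drop = FALSE]
    moduleStats[[kg]] <- list(completeness = comp, z = zres$z,
                              module_abundance = modAb)

    # drivers: one LMM per main module
    predVars <- intersect(unlist(predictorGroups),
                          setdiff(colnames(envImp), "site_id"))
    predAll <- envImp[match(colnames(m), envImp$site_id), predVars,
                      drop = FALSE]
    vf <- stage("drivers", vifFilter(predAll,
                                     threshold = config@vifThreshold))
    grpOf <- sites$cwp_species[match(colnames(m), sites$site_id)]
    kgDrivers <- list()
    for (mod in colnames(modAb)) {
      y <- modAb[, mod]
      fit <- stage("drivers",
        backwardAIC(y, predAll[, vf$retained, drop = FALSE], grpOf))
      ci <- if (length(fit$fixed_vars)) {
        stage("drivers",
          bootstrapCI(fit, nBoot = config@nBootstrap,
                      seed = stageSeed(config@seed,
                                       paste0("bootstrap/", mod), kg)))
      } else NULL
      part <- stage("drivers", partitionR2(fit, predictorGroups))
      nt <- residualNormality(fit)
      kgDrivers[[mod]] <- list(fit = fit, ci = ci, partition = part,
                               normality = nt, vif = vf)
      say("drivers[", kg, "/module ", mod, "]: ",
          length(fit$fixed_vars), " terms retained, R2m ",
          round(fit$R2m, 3), ", R2c ", round(fit$R2c, 3))
    }
    drivers[[kg]] <- kgDrivers
  }

  res <- list(config = config, sites = sites, env_imputed = envImp,
              rarefied = rarefied, pca = pca, weighted_scores = w,
              ecoregions = eco, axis_tests = axisTests, core = coreSets,
              networks = nets, module_stats = moduleStats,
              drivers = drivers, log = logLines)
  if (!is.null(outDir)) writePipelineOutputs(res, outDir)
  res
}

# Write every stage's outputs as plain-text tables/graph files.
writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeLines(res$log, file.path(outDir, "pipeline.log"))
  writeTsv(res$env_imputed, file.path(outDir, "environment_imputed.tsv"))
  sc <- data.frame(site_id = rownames(res$pca$scores), res$pca$scores,
                   check.names = FALSE)
  writeTsv(sc, file.path(outDir, "pca_scores.tsv"))
  ld <- data.frame(variable = rownames(res$pca$loadings), res$pca$loadings,
                   check.names = FALSE)
  writeTsv(ld, file.path(outDir, "pca_loadings.tsv"))
  writeTsv(data.frame(k = as.integer(names(res$ecoregions$ch_values)),
                      calinski_harabasz = res$ecoregions$ch_values,
                      within_ss = res$ecoregions$within_ss),
           file.path(outDir, "ch_curve.tsv"))
  writeTsv(data.frame(site_id = names(res$ecoregions$labels),
                      ecoregion = as.integer(res$ecoregions$labels)),
           file.path(outDir, "ecoregions.tsv"))
  writeTsv(res$axis_tests, file.path(outDir, "axis_tests.tsv"))
  for (kg in names(res$rarefied)) {
    writeCountTable(res$rarefied[[kg]],
                    file.path(outDir, paste0("rarefied_", kg, ".tsv")))
  }
  for (kg in names(res$core)) {
    cs <- res$core[[kg]]
    writeTsv(cs@stats, file.path(outDir, paste0("core_", kg, ".tsv")))
  }
  summ <- do.call(rbind, lapply(names(res$core), function(kg) {
    cs <- res$core[[kg]]
    data.frame(kingdom = kg, n_core = length(coreTaxa(cs)),
               richness_share = cs@richnessShare,
               read_share = cs@readShare)
  }))
  if (!is.null(summ)) writeTsv(summ, file.path(outDir, "core_summary.tsv"))
  for (kg in names(res$networks)) {
    net <- res$networks[[kg]]
    writeNetwork(net, file.path(outDir, paste0("network_", kg, ".tsv")),
                 "edge-list-tsv")
    writeNetwork(net, file.path(outDir, paste0("network_", kg, ".graphml")),
                 "graphml")
    mem <- moduleMembership(net)
    writeTsv(data.frame(taxon = names(mem), module = as.integer(mem),
                        main = as.integer(mem) %in% mainModuleIds(net)),
             file.path(outDir, paste0("modules_", kg, ".tsv")))
  }
  nsum <- do.call(rbind, lapply(names(res$networks), function(kg) {
    net <- res$networks[[kg]]
    data.frame(kingdom = kg, nodes = length(net@nodes),
               edges = nrow(networkEdges(net)),
               modularity = networkModularity(net))
  }))
  if (!is.null(nsum)) writeTsv(nsum, file.path(outDir,
                                               "network_summary.tsv"))
  for (kg in names(res$module_stats)) {
    ms <- res$module_stats[[kg]]
    writeTsv(ms$completeness$by_ecoregion,
             file.path(outDir, paste0("completeness_", kg, ".tsv")))
    ma <- data.frame(site_id = rownames(ms$module_abundance),
                     ms$module_abundance, check.names = FALSE)
    writeTsv(ma, file.path(outDir, paste0("module_abundance_", kg, ".tsv")))
  }
  for (kg in names(res$drivers)) {
    for (mod in names(res$drivers[[kg]])) {
      d <- res$drivers[[kg]][[mod]]
      if (!is.null(d$ci)) {
        ci <- d$ci
        ci$stars <- significanceStars(
          2 * pnorm(-abs(ci$estimate /
                           pmax((ci$upper - ci$lower) / (2 * 1.96), 1e-12))))
        writeTsv(ci, file.path(outDir, paste0("drivers_coefficients_", kg,
                                              "_m", mod, ".tsv")))
      }
      writeTsv(d$partition,
               file.path(outDir, paste0("drivers_partition_", kg, "_m", mod,
                                        ".tsv")))
      writeTsv(d$fit$aic_trace,
               file.path(outDir, paste0("aic_trace_", kg, "_m", mod,
                                        ".tsv")))
    }
  }
  invisible(outDir)
}
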