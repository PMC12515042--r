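# Readers and writers for the pipeline's table and graph formats.

#' Read a phylotype count table
#'
#' Reads a taxa-by-samples count table from TSV (first column taxon ids,
#' remaining columns one per sample) or BIOM JSON. The result is a
#' [SummarizedExperiment::SummarizedExperiment] with a `"counts"` assay and
#' the kingdom tag in `metadata()`.
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom-json"`.
#' @param kingdom optional kingdom tag stored in the object metadata.
#' @return a `SummarizedExperiment` of non-negative integer counts.
#' @export
readCountTable <- function(path, format = c("tsv", "biom-json"),
                           kingdom = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "tsv") {
    if (file.size(path) == 0) stop("empty count table file: ", path,
                                   call. = FALSE)
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2) stop("count table needs a taxon column plus >= 1 sample",
                           call. = FALSE)
    taxa <- df[[1]]
    samples <- colnames(df)[-1]
    if (anyDuplicated(samples))
      stop("duplicated sample column: ",
           paste(unique(samples[duplicated(samples)]), collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(taxa))
      stop("duplicated taxon id: ",
           paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
           call. = FALSE)
    m <- matrix(0, nrow = length(taxa), ncol = length(samples),
                dimnames = list(taxa, samples))
    for (j in seq_along(samples)) {
      v <- suppressWarnings(as.numeric(df[[j + 1]]))
      bad <- which(is.na(v) | v < 0 | v != round(v))
      if (length(bad))
        stop("negative or non-numeric count at [", taxa[bad[1]], ", ",
             samples[j], "]: '", df[[j + 1]][bad[1]], "'", call. = FALSE)
      m[, j] <- v
    }
  } else {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    checkCountsMatrix(m, "BIOM table")
  }
  storage.mode(m) <- "integer"
  se <- SummarizedExperiment(assays = list(counts = m))
  metadata(se)$kingdom <- kingdom
  se
}

#' Write a count table as TSV
#'
#' Inverse of [readCountTable()] for the TSV format; `read(write(x))` returns
#' an identical matrix.
#'
#' @param counts matrix or `SummarizedExperiment` with a `"counts"` assay.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(counts, path) {
  m <- countsMatrix(counts)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  ok <- tryCatch(write.table(df, path, sep = "\t", quote = FALSE,
                             row.names = FALSE), error = function(e) e)
  if (inherits(ok, "error")) stop("cannot write ", path, ": ",
                                  conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read the site metadata table
#'
#' TSV with columns `site_id`, `cwp_species`, `latitude`, `longitude` and
#' optionally `ecoregion`.
#'
#' @param path input TSV.
#' @return a validated data.frame.
#' @export
readSiteTable <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  validateSiteTable(df)
}

# Shared validity contract for site tables (also used by the simulator).
validateSiteTable <- function(df) {
  need <- c("site_id", "cwp_species", "latitude", "longitude")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$site_id))
    stop("duplicated site_id in site table", call. = FALSE)
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]", call. = FALSE)
  if (any(table(df$cwp_species) < 1))
    stop("every CWP species needs >= 1 site", call. = FALSE)
  df$site_id <- as.character(df$site_id)
  df$cwp_species <- as.character(df$cwp_species)
  df
}

#' Read an edaphoclimatic table
#'
#' TSV with a `site_id` column followed by numeric environmental variables;
#' missing cells allowed (empty or `NA`).
#'
#' @param path input TSV.
#' @return a data.frame with `site_id` plus numeric columns.
#' @export
readEnvTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  if (!"site_id" %in% colnames(df))
    stop("environment table missing site_id column", call. = FALSE)
  if (anyDuplicated(df$site_id))
    stop("duplicated site_id in environment table", call. = FALSE)
  for (v in setdiff(colnames(df), "site_id")) {
    if (!is.numeric(df[[v]]))
      stop("environment variable ", v, " is not numeric", call. = FALSE)
  }
  df$site_id <- as.character(df$site_id)
  df
}

#' Write an environment or generic results table as TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-occurrence network to disk
#'
#' The edge-list TSV carries node ids, observed co-presences, the exact tail
#' p-value and module labels (plus a node table side file is not needed:
#' isolated nodes are kept in a `#nodes` header comment). GraphML goes
#' through igraph and stores the same attributes.
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param path output file.
#' @param format `"edge-list-tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("edge-list-tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(net, "CooccurrenceNetwork"))
  if (format == "edge-list-tsv") {
    mem <- net@membership
    con <- tryCatch(file(path, "w"), error = function(e) {
      stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE)
    })
    on.exit(close(con))
    # header comments preserve isolated nodes and module labels losslessly
    writeLines(paste0("#kingdom\t", net@kingdom), con)
    writeLines(paste0("#alpha\t", format(net@alpha, digits = 17)), con)
    writeLines(paste0("#modularity\t", format(net@modularity, digits = 17)),
               con)
    writeLines(paste0("#main_modules\t",
                      paste(net@mainModules, collapse = ",")), con)
    for (nd in net@nodes) {
      writeLines(paste0("#node\t", nd, "\t",
                        if (length(mem)) mem[[nd]] else NA), con)
    }
    writeLines("taxon_a\ttaxon_b\tj_obs\tp_value\tmodule_a\tmodule_b", con)
    if (nrow(net@edges)) {
      e <- net@edges
      lines <- paste(e$taxon_a, e$taxon_b, e$j_obs,
                     format(e$p_value, digits = 17),
                     if (length(mem)) mem[e$taxon_a] else NA,
                     if (length(mem)) mem[e$taxon_b] else NA, sep = "\t")
      writeLines(lines, con)
    }
  } else {
    g <- asIgraph(net)
    if (length(net@membership))
      igraph::V(g)$module <- net@membership[igraph::V(g)$name]
    ok <- tryCatch(igraph::write_graph(g, path, format = "graphml"),
                   error = function(e) e)
    if (inherits(ok, "error")) stop("cannot write ", path, ": ",
                                    conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read a network written by [writeNetwork()]
#'
#' @param path edge-list TSV produced by `writeNetwork(..., "edge-list-tsv")`.
#' @return a [CooccurrenceNetwork-class]; round-trips losslessly (node set,
#'   edge set, modules, modularity).
#' @export
readNetwork <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getv <- function(key) {
    m <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (!length(m)) return(character(0))
    sub(paste0("^#", key, "\t"), "", m)
  }
  kingdom <- getv("kingdom")
  alpha <- as.numeric(getv("alpha"))
  modularity <- as.numeric(getv("modularity"))
  mm <- getv("main_modules")
  mainModules <- if (length(mm) && nzchar(mm)) {
    as.integer(strsplit(mm, ",")[[1]])
  } else integer(0)
  nodeLines <- strsplit(getv("node"), "\t")
  nodes <- vapply(nodeLines, `[`, character(1), 1)
  mem <- suppressWarnings(
    setNames(as.integer(vapply(nodeLines, `[`, character(1), 2)), nodes))
  if (all(is.na(mem))) mem <- integer(0)
  edf <- if (length(body) > 1) {
    read.delim(text = paste(body, collapse = "\n"))
  } else {
    data.frame(taxon_a = character(0), taxon_b = character(0),
               j_obs = integer(0), p_value = numeric(0))
  }
  new("CooccurrenceNetwork", kingdom = kingdom, nodes = nodes,
      edges = data.frame(taxon_a = as.character(edf$taxon_a),
                         taxon_b = as.character(edf$taxon_b),
                         j_obs = as.integer(edf$j_obs),
                         p_value = as.numeric(edf$p_value)),
      tests = data.frame(), membership = mem,
      modularity = if (length(modularity)) modularity else NA_real_,
      mainModules = mainModules,
      alpha = if (length(alpha)) alpha else NA_real_)
}
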