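# Internal helpers shared across stages.

#' Derive a per-stage seed from the pipeline root seed
#'
#' All randomness in the pipeline flows from a single root seed. Each stage
#' (and each kingdom within a stage) gets its own deterministic sub-seed so
#' stages can be re-run in isolation and still reproduce the full-pipeline
#' results.
#'
#' @param seed integer root seed.
#' @param stage character stage label (e.g. `"rarefy"`).
#' @param sub optional character sub-label (e.g. a kingdom name).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stageSeed <- function(seed, stage, sub = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  key <- paste0(stage, "/", sub)
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Compact letter display by insert-and-absorb. `pmat` is a symmetric matrix of
# adjusted p-values with group names on dimnames; groups sharing a letter are
# not significantly different at `alpha`. Ties at exactly alpha count as
# non-significant.
insertAbsorbLetters <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  k <- length(groups)
  if (k == 1L) return(setNames("a", groups))
  # each column of `sets` is a logical membership vector for one letter class
  sets <- matrix(TRUE, nrow = k, ncol = 1, dimnames = list(groups, NULL))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      p <- pmat[groups[i], groups[j]]
      if (is.na(p) || p > alpha) next  # non-significant: may share letters
      viol <- which(sets[i, ] & sets[j, ])
      for (v in viol) {
        # duplicate the violating class, removing i from one copy, j from other
        a <- sets[, v]; b <- sets[, v]
        a[i] <- FALSE; b[j] <- FALSE
        sets <- cbind(sets[, -v, drop = FALSE], a, b)
        # absorb classes that are subsets of another
        keep <- rep(TRUE, ncol(sets))
        for (u in seq_len(ncol(sets))) {
          for (w in seq_len(ncol(sets))) {
            if (u != w && keep[u] && keep[w] &&
                all(sets[, u] <= sets[, w]) && any(sets[, u] < sets[, w])) {
              keep[u] <- FALSE
            }
          }
        }
        sets <- sets[, keep, drop = FALSE]
      }
    }
  }
  # order letter classes by first member for a stable display
  ord <- order(apply(sets, 2, function(s) which(s)[1]))
  sets <- sets[, ord, drop = FALSE]
  letters_used <- letters[seq_len(ncol(sets))]
  out <- vapply(seq_len(k), function(i) {
    paste0(letters_used[sets[i, ]], collapse = "")
  }, character(1))
  setNames(out, groups)
}

# Validate a counts matrix: integer-valued, non-negative, unique dimnames.
checkCountsMatrix <- function(m, what = "count table") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must have taxon row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(what, ": duplicated taxon ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(what, ": duplicated sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(what, ": negative or non-numeric count at [",
         rownames(m)[bad[1, 1]], ", ", colnames(m)[bad[1, 2]], "]",
         call. = FALSE)
  }
  invisible(m)
}

# Extract the counts matrix from a SummarizedExperiment or plain matrix.
countsMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) as.matrix(assay(x, "counts")) else
    as.matrix(x)
}

# Kingdom tag of a count container ("" when untagged).
kingdomOf <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    k <- metadata(x)$kingdom
    if (is.null(k)) "" else k
  } else ""
}
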