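#' Featurize a compound at a concentration
#'
#' Builds the model's conditioning vector: a folded binary Morgan fingerprint
#' (radius 2, 512 bits by default) with the micromolar concentration appended
#' as the final element, giving a 513-length vector. Compound pairs (two
#' SMILES joined by `"|"`) are encoded as the bitwise OR of the member
#' fingerprints. Concentration enters un-logged by default; set
#' `logConcentration = TRUE` to append `log10(concentration)` instead.
#'
#' @param record a list or one-row data.frame with fields `compound_id` and
#'   `smiles` (and optionally `moa_class`, `targets`).
#' @param concentrationUm positive concentration in micromolar.
#' @param nBits,radius fingerprint folding length and Morgan radius.
#' @param logConcentration append log10(uM) instead of raw uM.
#' @return numeric vector of length `nBits + 1` with attributes
#'   `compound_id` and `concentration_um`.
#' @export
featurizeCompound <- function(record, concentrationUm, nBits = 512L, radius = 2L,
                              logConcentration = FALSE) {
  if (is.data.frame(record)) record <- as.list(record[1, ])
  stopifnot(!is.null(record$compound_id), !is.null(record$smiles))
  if (!is.numeric(concentrationUm) || length(concentrationUm) != 1L ||
      !is.finite(concentrationUm) || concentrationUm <= 0) {
    stopf("concentration must be a single positive number (compound '%s')", record$compound_id)
  }
  bits <- morganFingerprints(record$smiles, nBits = nBits, radius = radius,
                             ids = record$compound_id)[1, ]
  conc <- if (logConcentration) log10(concentrationUm) else concentrationUm
  v <- c(as.numeric(bits), conc)
  attr(v, "compound_id") <- record$compound_id
  attr(v, "concentration_um") <- concentrationUm
  v
}

#' Z-score expression per gene, or apply frozen training statistics
#'
#' Standardizes a samples x genes matrix gene-wise. When `stats` is omitted
#' the matrix's own per-gene mean and population standard deviation
#' (divisor N) are used and returned for reuse on new cohorts; when supplied
#' (e.g. training-fold statistics) they are applied unchanged. Genes with
#' zero spread are set to all-zeros with a warning so the gene axis stays
#' fixed across cohorts.
#'
#' @param x numeric matrix, samples in rows, genes in columns (dimnames kept).
#' @param stats optional list with numeric vectors `mean` and `sd` (per gene).
#' @return list with `values` (standardized matrix) and `stats`.
#' @export
standardizeExpression <- function(x, stats = NULL) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x))
  if (is.null(stats)) {
    if (nrow(x) < 2L) stopf("need >= 2 samples to estimate standardization statistics")
    stats <- list(mean = colMeans(x), sd = colPopSd(x))
    names(stats$mean) <- names(stats$sd) <- colnames(x)
  } else {
    stopifnot(length(stats$mean) == ncol(x), length(stats$sd) == ncol(x))
  }
  zero <- stats$sd <= 0 | !is.finite(stats$sd)
  if (any(zero)) {
    warning(sprintf("%d zero-spread gene(s) set to 0 after standardization", sum(zero)))
  }
  sdSafe <- ifelse(zero, 1, stats$sd)
  z <- sweep(sweep(x, 2L, stats$mean, "-"), 2L, sdSafe, "/")
  z[, zero] <- 0
  list(values = z, stats = stats)
}

#' Align a cohort's gene axis to a reference gene list
#'
#' Reorders/subsets columns to exactly `referenceGenes`; genes absent from the
#' cohort are imputed with the supplied reference per-gene mean (zero for a
#' standardized reference). Errors when the matched fraction falls below
#' `minMatched`, which usually indicates a mismatched cohort.
#'
#' @param x samples x genes matrix with gene column names.
#' @param referenceGenes character vector defining the output gene axis.
#' @param referenceMeans per-reference-gene imputation values (default 0).
#' @param minMatched minimum tolerated matched fraction (default 0.5).
#' @return list with `values` (samples x reference genes), `matchedFraction`,
#'   and `imputedGenes`.
#' @export
harmonizeGenes <- function(x, referenceGenes, referenceMeans = NULL, minMatched = 0.5) {
  x <- as.matrix(x)
  stopifnot(length(referenceGenes) >= 1L, !is.null(colnames(x)))
  if (is.null(referenceMeans)) referenceMeans <- rep(0, length(referenceGenes))
  stopifnot(length(referenceMeans) == length(referenceGenes))
  hit <- referenceGenes %in% colnames(x)
  frac <- mean(hit)
  if (frac < minMatched) {
    stopf("only %.1f%% of reference genes found (< %.0f%%): cohort likely mismatched",
          100 * frac, 100 * minMatched)
  }
  out <- matrix(rep(referenceMeans, each = nrow(x)),
                nrow = nrow(x), ncol = length(referenceGenes),
                dimnames = list(rownames(x), referenceGenes))
  out[, hit] <- x[, referenceGenes[hit], drop = FALSE]
  list(values = out, matchedFraction = frac, imputedGenes = referenceGenes[!hit])
}

#' Leakage-free cross-validation folds grouped by sample
#'
#' Partitions distinct sample (cell line) identifiers into `k` folds of sizes
#' differing by at most one, so that all examples from one cell line share a
#' fold and no cell line can leak between training and testing.
#'
#' @param sampleIds character vector (duplicates allowed; folds are assigned
#'   to the distinct values).
#' @param k number of folds (default 5).
#' @param seed integer seed making the shuffle deterministic.
#' @return named integer vector mapping each distinct sample id to a fold
#'   in `0:(k-1)`.
#' @export
makeCvSplits <- function(sampleIds, k = 5L, seed = 1L) {
  ids <- unique(as.character(sampleIds))
  k <- as.integer(k)
  if (length(ids) < k) stopf("%d distinct samples < %d folds", length(ids), k)
  set.seed(as.integer(seed))
  shuffled <- sample(ids)
  folds <- rep_len(seq_len(k) - 1L, length(ids))  # round-robin: sizes differ by <= 1
  stats::setNames(folds[order(match(ids, shuffled))], ids)
}

#' Read an expression table from TSV/CSV
#'
#' @param path file path; delimiter inferred from extension (.csv vs .tsv/.txt).
#' @param genesInRows set TRUE when rows are genes and columns samples.
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
readExpression <- function(path, genesInRows = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (genesInRows) t(m) else m
}

#' Write an expression matrix (samples x genes) as a genes x samples TSV
#' @param x samples x genes matrix.
#' @param path output path.
#' @export
writeExpression <- function(x, path) {
  m <- t(as.matrix(x))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a compound table (CSV: compound_id, smiles[, moa_class, targets])
#'
#' `targets` is a semicolon-separated list of gene symbols.
#' @param path CSV path.
#' @return data.frame with a list-column `targets`.
#' @export
readCompounds <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "smiles") %in% names(df)))
  if (anyDuplicated(df$compound_id)) stopf("duplicate compound_id in %s", path)
  if (!is.null(df$targets)) {
    df$targets <- I(lapply(strsplit(as.character(df$targets), ";", fixed = TRUE),
                           function(v) v[nzchar(v)]))
  }
  df
}

# Fingerprint matrix for a compound table (rows = compound ids).
compoundFingerprints <- function(compounds, nBits = 512L, radius = 2L) {
  morganFingerprints(compounds$smiles, nBits = nBits, radius = radius,
                     ids = compounds$compound_id)
}
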