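# Integrated-gradients attribution at the predicted IC50, per-cell-line
# adjustment, and the two control-model soundness checks (random
# initialization and label permutation).

#' Integrated gradients for one expression/compound input
#'
#' Left-endpoint Riemann approximation of the path integral of input
#' gradients along the straight line from zero-vector baselines to the query
#' inputs: attribution_i = (x_i - 0) * mean_k d f / d x_i evaluated at
#' k/steps * x for k = 0, ..., steps - 1. Both input blocks are attributed;
#' gradients are taken in inference mode. For an ensemble the member
#' attributions are averaged.
#'
#' @param model trained [FilmModel-class] or [FilmEnsemble-class].
#' @param expression raw expression vector on the model's gene axis (frozen
#'   standardization is applied internally; attribution is w.r.t. the
#'   standardized coordinates the network actually consumes).
#' @param compound 513-length compound vector (bits + concentration in uM).
#' @param steps number of interpolation steps (default 50).
#' @param compoundId identifier (straw variant code lookup).
#' @return list(gene = per-gene attributions, compound = per-compound-feature
#'   attributions, prediction = f(x, n), baselinePrediction = f(0, 0)).
#' @export
integratedGradients <- function(model, expression, compound, steps = 50L,
                                compoundId = NULL) {
  stopifnot(steps >= 2L)
  if (is(model, "FilmEnsemble")) {
    parts <- lapply(model@models, integratedGradients, expression, compound,
                    steps = steps, compoundId = compoundId)
    return(list(
      gene = rowMeans(vapply(parts, `[[`, parts[[1]]$gene, "gene")),
      compound = rowMeans(vapply(parts, `[[`, parts[[1]]$compound, "compound")),
      prediction = mean(vapply(parts, `[[`, 0, "prediction")),
      baselinePrediction = mean(vapply(parts, `[[`, 0, "baselinePrediction"))))
  }
  stopifnot(is(model, "FilmModel"))
  cfg <- model@config
  x <- as.numeric(if (is.matrix(expression)) expression[1, ] else expression)
  if (length(x) != cfg$nGenes) stopf("expression length %d != %d genes", length(x), cfg$nGenes)
  xs <- as.numeric(standardizeExpression(matrix(x, 1), stats = model@frozenStats)$values)
  n <- as.numeric(compound)
  if (length(n) != cfg$nCompoundFeatures) stopf("compound vector length %d != %d", length(n), cfg$nCompoundFeatures)
  if (cfg$variant == "straw") {
    cid <- compoundId %||% attr(compound, "compound_id")
    if (is.null(cid) || !cid %in% rownames(model@strawCodes)) {
      stopf("straw variant needs a known compoundId")
    }
    n <- c(model@strawCodes[cid, ], n[length(n)])
  }
  # the network consumes log10(conc) when the flag is on; the path and the
  # attribution are taken in that input space
  if (cfg$logConcentration) n[length(n)] <- log10(n[length(n)])
  alphas <- (seq_len(steps) - 1L) / steps  # left endpoints: 0, ..., (m-1)/m
  Xp <- outer(alphas, xs)
  Np <- outer(alphas, n)
  gr <- .nnInputGradientsRawConc(model, Xp, Np)
  if (!all(is.finite(gr$dX)) || !all(is.finite(gr$dN))) {
    stopf("non-finite gradients in integrated-gradients path")
  }
  geneAttr <- xs * colMeans(gr$dX)
  compAttr <- n * colMeans(gr$dN)
  names(geneAttr) <- model@geneIds
  f1 <- .nnForwardRawConc(model, matrix(xs, 1), matrix(n, 1))
  f0 <- .nnForwardRawConc(model, matrix(0, 1, length(xs)), matrix(0, 1, length(n)))
  list(gene = geneAttr, compound = compAttr,
       prediction = f1, baselinePrediction = f0)
}

# Forward/gradients where N is already in the network's own concentration
# coordinates (log10 applied upstream), bypassing the usual transform.
.nnForwardRawConc <- function(model, X, N) {
  m2 <- model; m2@config$logConcentration <- FALSE
  nnForward(m2, X, N, train = FALSE)$yhat
}

.nnInputGradientsRawConc <- function(model, X, N) {
  m2 <- model; m2@config$logConcentration <- FALSE
  nnInputGradients(m2, X, N)
}

#' Attribute every pair at its predicted IC50
#'
#' For each cell line x compound pair with a defined IC50, computes the
#' integrated-gradients attribution with the compound concentration set to
#' that pair's IC50, and collects the gene-block attributions into a raw
#' [AttributionMatrix-class]. Pairs lacking an IC50 are skipped and reported
#' via the `skipped` attribute.
#'
#' @param model trained model or ensemble.
#' @param expression raw samples x genes matrix.
#' @param fitTable pair table with sample_id, compound_id, ic50_um (e.g.
#'   from [fitCohortCurves()]).
#' @param fingerprints fingerprint matrix (rows = compound ids).
#' @param steps integrated-gradients steps.
#' @return raw [AttributionMatrix-class]; skipped pairs in
#'   `attr(x, "skipped")`.
#' @export
attributeAtIc50 <- function(model, expression, fitTable, fingerprints, steps = 50L) {
  ok <- is.finite(fitTable$ic50_um) & fitTable$ic50_um > 0
  skipped <- fitTable[!ok, c("sample_id", "compound_id")]
  use <- fitTable[ok, , drop = FALSE]
  if (!nrow(use)) stopf("no pairs with a defined IC50 to attribute")
  vals <- matrix(NA_real_, nrow(use), ncol(expression),
                 dimnames = list(NULL, colnames(expression)))
  for (i in seq_len(nrow(use))) {
    cid <- as.character(use$compound_id[i])
    cv <- c(fingerprints[cid, ], use$ic50_um[i])
    ig <- integratedGradients(model, expression[as.character(use$sample_id[i]), ],
                              cv, steps = steps, compoundId = cid)
    vals[i, ] <- ig$gene
  }
  out <- new("AttributionMatrix", values = vals,
             meta = data.frame(cell_line_id = as.character(use$sample_id),
                               compound_id = as.character(use$compound_id),
                               ic50_um = use$ic50_um),
             adjusted = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Adjust attributions for cell-line-specific effects
#'
#' Z-scores each gene's attribution within each cell line's rows (population
#' standard deviation), removing cell-line-specific location/scale so that
#' rows are comparable across cell lines. Zero-spread entries are set to 0.
#' Idempotent.
#'
#' @param raw an [AttributionMatrix-class].
#' @return adjusted [AttributionMatrix-class].
#' @export
adjustAttributions <- function(raw) {
  stopifnot(is(raw, "AttributionMatrix"))
  vals <- raw@values
  for (cl in unique(raw@meta$cell_line_id)) {
    i <- which(raw@meta$cell_line_id == cl)
    if (length(i) < 2L) stopf("cell line '%s' has a single attributed row; cannot standardize", cl)
    m <- vals[i, , drop = FALSE]
    mu <- colMeans(m)
    sdv <- colPopSd(m)
    z <- sweep(sweep(m, 2L, mu, "-"), 2L, ifelse(sdv > 0, sdv, 1), "/")
    z[, sdv <= 0] <- 0
    vals[i, ] <- z
  }
  new("AttributionMatrix", values = vals, meta = raw@meta, adjusted = TRUE)
}

# Per-row Pearson correlation between two row-aligned attribution matrices.
.rowCorrelations <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b))
  vapply(seq_len(nrow(a)), function(i) {
    if (popSd(a[i, ]) == 0 || popSd(b[i, ]) == 0) return(NA_real_)
    cor(a[i, ], b[i, ])
  }, numeric(1))
}

#' Soundness check: attributions of a randomly initialized control model
#'
#' Builds an architecturally identical but untrained model (fresh random
#' weights; identity batch-norm buffers and frozen stats copied from the
#' true model so only the learned weights differ), attributes the same
#' pairs, and reports the per-row Pearson correlation with the true model's
#' attributions, for the raw and adjusted variants. A sound attribution
#' method yields near-zero adjusted correlations.
#'
#' @param model the trained (true) model or ensemble.
#' @param expression raw samples x genes matrix.
#' @param fitTable pair table with ic50_um (same pairs as the true
#'   attributions).
#' @param fingerprints fingerprint matrix.
#' @param trueAttr raw [AttributionMatrix-class] from the true model.
#' @param seed seed for the random reinitialization.
#' @param steps integrated-gradients steps.
#' @return list(raw, adjusted): per-row correlation vectors; plus the
#'   control attribution matrices as attributes.
#' @export
soundnessRandomInit <- function(model, expression, fitTable, fingerprints,
                                trueAttr, seed = 99L, steps = 50L) {
  ref <- if (is(model, "FilmEnsemble")) model@models[[1]] else model
  cfg <- ref@config
  cfg$seed <- as.integer(seed)
  class(cfg) <- "filmSensConfig"
  ctrl <- buildModel(cfg, ref@geneIds,
                     compoundIds = rownames(ref@strawCodes %||% fingerprints))
  ctrl@frozenStats <- ref@frozenStats
  ctrl@trained <- TRUE  # inference mode works with init buffers
  ctrlAttr <- attributeAtIc50(ctrl, expression, fitTable, fingerprints, steps = steps)
  .soundnessReport(trueAttr, ctrlAttr)
}

#' Soundness check: attributions of a label-permuted control model
#'
#' Permutes the viability labels (seeded; the multiset of labels is
#' preserved), trains an architecturally identical model on the permuted
#' data, attributes the same pairs, and reports per-row correlations with
#' the true attributions. The permuted model's held-out R^2 should be near
#' zero and its adjusted attributions uncorrelated with the true model's.
#'
#' @param config the true model's [modelConfig()].
#' @param expression raw samples x genes matrix.
#' @param examples training examples (labels will be permuted).
#' @param fingerprints fingerprint matrix.
#' @param fitTable pair table with ic50_um for attribution.
#' @param trueAttr raw [AttributionMatrix-class] from the true model.
#' @param hyper training hyperparameters.
#' @param seed permutation seed.
#' @param steps integrated-gradients steps.
#' @return as [soundnessRandomInit()], plus `model` (the permuted-label
#'   model) as an attribute.
#' @export
soundnessLabelPermutation <- function(config, expression, examples, fingerprints,
                                      fitTable, trueAttr, hyper = list(),
                                      seed = 7L, steps = 50L) {
  set.seed(deriveSeed(seed, "label-permutation"))
  permEx <- examples
  permEx$viability <- sample(permEx$viability)
  ctrl <- trainModel(config, expression, permEx, fingerprints, hyper)
  ctrlAttr <- attributeAtIc50(ctrl, expression, fitTable, fingerprints, steps = steps)
  rep <- .soundnessReport(trueAttr, ctrlAttr)
  attr(rep, "model") <- ctrl
  rep
}

.soundnessReport <- function(trueAttr, ctrlAttr) {
  stopifnot(is(trueAttr, "AttributionMatrix"), !trueAttr@adjusted)
  rawR <- .rowCorrelations(trueAttr@values, ctrlAttr@values)
  adjR <- .rowCorrelations(adjustAttributions(trueAttr)@values,
                           adjustAttributions(ctrlAttr)@values)
  out <- list(raw = rawR, adjusted = adjR)
  attr(out, "controlAttr") <- ctrlAttr
  out
}

#' Write / read an attribution matrix as CSV
#'
#' Metadata columns first, then one column per gene; values round-trip to
#' better than 1e-12.
#'
#' @param x an [AttributionMatrix-class].
#' @param path CSV path.
#' @export
writeAttributions <- function(x, path) {
  df <- cbind(x@meta, adjusted = x@adjusted,
              as.data.frame(x@values, check.names = FALSE))
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAttributions
#' @export
readAttributions <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  metaCols <- c("cell_line_id", "compound_id", "ic50_um", "adjusted")
  vals <- as.matrix(df[, setdiff(names(df), metaCols), drop = FALSE])
  storage.mode(vals) <- "double"
  new("AttributionMatrix", values = vals,
      meta = data.frame(cell_line_id = as.character(df$cell_line_id),
                        compound_id = as.character(df$compound_id),
                        ic50_um = as.numeric(df$ic50_um)),
      adjusted = isTRUE(all(df$adjusted)))
}
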