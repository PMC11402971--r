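setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Trained (or untrained) conditional viability model
#'
#' Container for one FiLM-family regressor: architecture/variant
#' configuration, weight store, per-epoch training log, the frozen per-gene
#' expression statistics of its training fold, and its gene axis.
#'
#' @slot config list; see [modelConfig()].
#' @slot params named list of weight matrices/vectors and batch-norm buffers.
#' @slot trainingLog data.frame with per-epoch train/validation loss.
#' @slot frozenStats list(mean, sd) per gene, or empty before training.
#' @slot geneIds character vector defining the expression input axis.
#' @slot strawCodes matrix of per-compound random binary codes (straw
#'   variant only), or NULL.
#' @slot trained logical.
#' @exportClass FilmModel
setClass("FilmModel", representation(
  config = "list", params = "list", trainingLog = "data.frame",
  frozenStats = "list", geneIds = "character",
  strawCodes = "matrixOrNULL", trained = "logical"
))

#' Cross-validation ensemble of conditional viability models
#'
#' @slot models list of [FilmModel-class] objects, one per fold.
#' @slot foldR2 per-fold held-out coefficient of determination.
#' @slot foldIds integer fold indices.
#' @exportClass FilmEnsemble
setClass("FilmEnsemble", representation(
  models = "list", foldR2 = "numeric", foldIds = "integer"
))

#' Log-logistic dose-response fit
#'
#' Four-parameter log-logistic curve
#' \eqn{v(x) = c + (d - c) / (1 + \exp(b (\ln x - \ln e)))} with fallback
#' provenance: `nParams` records whether the 4-, 3- (c = 0) or 2-parameter
#' (c = 0, d = 1) family was used, and `qcStatus` the QC/fit verdict.
#'
#' @slot b,cLower,dUpper,eMid numeric curve parameters (eMid in uM).
#' @slot nParams integer in {2, 3, 4} (NA when no fit succeeded).
#' @slot pointsUsed number of concentration points retained by QC.
#' @slot qcStatus one of "pass", "rejected_min_points",
#'   "rejected_high_min_viability", "fit_failed", "filtered_ec50_range".
#' @slot covariance covariance matrix of the free parameters, or NULL.
#' @slot residualDf residual degrees of freedom of the fit.
#' @slot points data.frame(concentration_um, viability) actually fitted.
#' @exportClass DoseResponseFit
setClass("DoseResponseFit", representation(
  b = "numeric", cLower = "numeric", dUpper = "numeric", eMid = "numeric",
  nParams = "integer", pointsUsed = "integer", qcStatus = "character",
  covariance = "matrixOrNULL", residualDf = "numeric", points = "data.frame"
))

setValidity("DoseResponseFit", function(object) {
  ok <- object@qcStatus %in% c("pass", "rejected_min_points",
                               "rejected_high_min_viability", "fit_failed",
                               "filtered_ec50_range")
  if (!ok) return("invalid qcStatus")
  if (identical(object@qcStatus, "pass") &&
      (!is.finite(object@eMid) || object@eMid <= 0)) {
    return("passing fit must have a positive finite eMid")
  }
  TRUE
})

#' Integrated-gradients attribution matrix
#'
#' Rows are (cell line, compound-at-IC50) pairs, columns genes. The
#' `adjusted` variant is z-scored per gene within each cell line's rows to
#' remove cell-line-specific magnitude effects.
#'
#' @slot values pair-samples x genes matrix.
#' @slot meta data.frame(cell_line_id, compound_id, ic50_um), row-aligned.
#' @slot adjusted logical.
#' @exportClass AttributionMatrix
setClass("AttributionMatrix", representation(
  values = "matrix", meta = "data.frame", adjusted = "logical"
))

setValidity("AttributionMatrix", function(object) {
  if (nrow(object@values) != nrow(object@meta)) return("meta rows must match value rows")
  if (!all(c("cell_line_id", "compound_id") %in% names(object@meta))) {
    return("meta needs cell_line_id and compound_id")
  }
  TRUE
})

#' Synthetic pharmacogenomic cohort with planted ground truth
#'
#' @slot expression samples x genes matrix of raw (unstandardized) abundances.
#' @slot compounds data.frame(compound_id, smiles, moa_class, targets).
#' @slot viability data.frame(sample_id, compound_id, concentration_um, viability).
#' @slot groundTruth list: per-compound target sets, true log10-IC50 matrix,
#'   link weights, planted interaction modules.
#' @slot graph data.frame(node_a, node_b, score) interaction edge list.
#' @slot config the generating [syntheticConfig()] list.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", representation(
  expression = "matrix", compounds = "data.frame", viability = "data.frame",
  groundTruth = "list", graph = "data.frame", config = "list"
))

setMethod("show", "FilmModel", function(object) {
  cat(sprintf("FilmModel variant='%s' (%s), %d genes, %s\n",
              object@config$variant,
              if (object@trained) "trained" else "untrained",
              length(object@geneIds),
              sprintf("%d parameters", countLeaves(object@params))))
  if (nrow(object@trainingLog)) {
    cat(sprintf("  epochs: %d, final val MSE: %.4g\n",
                max(object@trainingLog$epoch),
                object@trainingLog$val_loss[nrow(object@trainingLog)]))
  }
})

setMethod("show", "FilmEnsemble", function(object) {
  cat(sprintf("FilmEnsemble of %d models; fold R2: %s\n", length(object@models),
              paste(sprintf("%.3f", object@foldR2), collapse = ", ")))
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("DoseResponseFit [%s] nParams=%s b=%.3g c=%.3g d=%.3g e=%.4g uM (%d points)\n",
              object@qcStatus, object@nParams, object@b, object@cLower,
              object@dUpper, object@eMid, object@pointsUsed))
})

setMethod("show", "AttributionMatrix", function(object) {
  cat(sprintf("AttributionMatrix (%s): %d pairs x %d genes, %d cell lines\n",
              if (object@adjusted) "adjusted" else "raw",
              nrow(object@values), ncol(object@values),
              length(unique(object@meta$cell_line_id))))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d cell lines x %d genes, %d compounds (%d MOA classes), %d viability examples\n",
              nrow(object@expression), ncol(object@expression),
              nrow(object@compounds),
              length(unique(object@compounds$moa_class)),
              nrow(object@viability)))
})

# ---- accessors ----

#' @describeIn FilmModel-class model variant string.
#' @param object a FilmModel.
#' @export
modelVariant <- function(object) object@config$variant

#' Gene identifiers defining a model's or cohort's expression axis
#' @param object FilmModel, FilmEnsemble or SyntheticCohort.
#' @export
geneIds <- function(object) {
  if (is(object, "FilmModel")) return(object@geneIds)
  if (is(object, "FilmEnsemble")) return(object@models[[1]]@geneIds)
  if (is(object, "SyntheticCohort")) return(colnames(object@expression))
  stopf("no gene axis for class %s", class(object)[1])
}

#' Curve parameters of a dose-response fit as a named vector
#' @param fit a DoseResponseFit.
#' @export
fitParams <- function(fit) {
  c(b = fit@b, c = fit@cLower, d = fit@dUpper, e = fit@eMid)
}

#' QC/fit verdict of a dose-response fit
#' @param fit a DoseResponseFit.
#' @export
qcStatus <- function(fit) fit@qcStatus

#' Attribution values / metadata / adjustment flag
#' @param x an AttributionMatrix.
#' @export
attrValues <- function(x) x@values

#' @rdname attrValues
#' @export
attrMeta <- function(x) x@meta

#' @rdname attrValues
#' @export
isAdjusted <- function(x) x@adjusted

#' Cohort component accessors
#' @param x a SyntheticCohort.
#' @export
cohortExpression <- function(x) x@expression

#' @rdname cohortExpression
#' @export
cohortCompounds <- function(x) x@compounds

#' @rdname cohortExpression
#' @export
cohortViability <- function(x) x@viability

#' @rdname cohortExpression
#' @export
cohortGraph <- function(x) x@graph

#' @rdname cohortExpression
#' @export
groundTruth <- function(x) x@groundTruth
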