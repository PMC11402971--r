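# Synthetic pharmacogenomics generator: cohorts with planted ground truth so
# every pipeline stage (training, dose-response fitting, attribution,
# interpretation) has an oracle to test against.

#' Synthetic cohort configuration
#'
#' The default cohort emulates the structure of a large-scale viability
#' screen matched to basal transcriptomes: 8 cell lines x 500 genes,
#' 24 compounds in 6 MOA classes of 4 compounds sharing a planted target
#' set, Hill slope 2, additive Gaussian viability noise (sd 0.05), with
#' each (cell, compound) pair's true log10-IC50 linear in the z-scored
#' expression of the compound's target genes.
#'
#' @param nCellLines,nGenes,nCompounds,nMoaClasses cohort dimensions.
#' @param targetsPerClass planted target genes per MOA class (default 4).
#' @param hillSlope Hill coefficient h of the true response curves.
#' @param noiseSd additive viability noise standard deviation.
#' @param linkWeightSd spread of the per-target IC50 link weights.
#' @param backgroundDensity background edge density of the interaction graph.
#' @param seed master seed; the cohort is bit-reproducible given it.
#' @return config list of class "filmSensSynthConfig".
#' @export
syntheticConfig <- function(nCellLines = 8L, nGenes = 500L, nCompounds = 24L,
                            nMoaClasses = 6L, targetsPerClass = 4L,
                            hillSlope = 2, noiseSd = 0.05,
                            linkWeightSd = 0.5, backgroundDensity = 0.004,
                            seed = 7L) {
  stopifnot(nMoaClasses <= nCompounds, targetsPerClass >= 1L,
            nMoaClasses * targetsPerClass <= nGenes, hillSlope > 0, noiseSd >= 0)
  cfg <- list(nCellLines = as.integer(nCellLines), nGenes = as.integer(nGenes),
              nCompounds = as.integer(nCompounds), nMoaClasses = as.integer(nMoaClasses),
              targetsPerClass = as.integer(targetsPerClass), hillSlope = hillSlope,
              noiseSd = noiseSd, linkWeightSd = linkWeightSd,
              backgroundDensity = backgroundDensity, seed = as.integer(seed))
  class(cfg) <- "filmSensSynthConfig"
  cfg
}

#' The bundled drug-like SMILES list
#' @return data.frame(smiles, family) of ~50 public drug-like structures
#'   used to give synthetic compounds real, fingerprintable chemistry.
#' @export
bundledSmiles <- function() {
  read.csv(system.file("extdata", "druglike_smiles.csv", package = "filmSens"),
           stringsAsFactors = FALSE)
}

#' Generate a synthetic pharmacogenomic cohort with planted ground truth
#'
#' Expression is per-gene Gaussian with random cell-line offsets. Each MOA
#' class receives a disjoint planted target-gene set shared by all its
#' compounds; the true log10-IC50 of a (cell, compound) pair is a
#' compound-specific intercept plus a weighted sum of the cell's z-scored
#' target expression, clipped to the interior of the default grid's log
#' range. Viability on the 32-point grid follows a Hill curve
#' 1 / (1 + (conc / IC50)^h) plus Gaussian noise, clipped at 0. The
#' interaction graph is a sparse random background with a clique planted on
#' each target set (scores > 0.7 so they survive the high-confidence
#' filter). Compound SMILES are drawn (seeded, without replacement) from the
#' bundled drug-like list, so fingerprinting runs on real chemistry.
#'
#' @param config a [syntheticConfig()].
#' @param grid concentration grid for the viability examples.
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(config = syntheticConfig(), grid = defaultGrid()) {
  stopifnot(inherits(config, "filmSensSynthConfig"))
  set.seed(deriveSeed(config$seed, "cohort"))
  nc <- config$nCellLines; ng <- config$nGenes; nd <- config$nCompounds
  cells <- sprintf("CL%02d", seq_len(nc))
  genes <- sprintf("G%04d", seq_len(ng))
  # expression: per-gene mean + spread, cell-line standard-normal offsets
  geneMean <- rnorm(ng, mean = 6, sd = 2)
  geneSd <- pmax(0.2, rnorm(ng, mean = 0.8, sd = 0.3))
  z <- matrix(rnorm(nc * ng), nc, ng, dimnames = list(cells, genes))
  expr <- sweep(sweep(z, 2L, geneSd, "*"), 2L, geneMean, "+")
  # z-scores as the generator's link covariate (population sd across cells)
  zstd <- scale(expr, center = TRUE, scale = apply(expr, 2L, popSd))

  # compounds: round-robin MOA classes, disjoint target sets, real SMILES
  classes <- sprintf("MOA%02d", seq_len(config$nMoaClasses))
  moa <- classes[((seq_len(nd) - 1L) %% config$nMoaClasses) + 1L]
  targetPool <- sample(genes, config$nMoaClasses * config$targetsPerClass)
  classTargets <- split(targetPool, rep(classes, each = config$targetsPerClass))
  smiPool <- bundledSmiles()$smiles
  if (nd > length(smiPool)) stopf("at most %d synthetic compounds supported", length(smiPool))
  smiles <- sample(smiPool, nd)
  compounds <- data.frame(compound_id = sprintf("CPD%03d", seq_len(nd)),
                          smiles = smiles, moa_class = moa,
                          stringsAsFactors = FALSE)
  compounds$targets <- I(unname(classTargets[moa]))

  # true log10-IC50: compound intercept + weighted z-scored target expression,
  # clipped to the interior of the grid's log range
  lgRange <- range(log10(grid))
  interior <- c(lgRange[1] + 0.5, lgRange[2] - 0.5)
  alpha <- runif(nd, -1.5, 1.5)
  w <- lapply(classes, function(cl) {
    stats::setNames(rnorm(config$targetsPerClass, sd = config$linkWeightSd),
                    classTargets[[cl]])
  })
  names(w) <- classes
  logIc50 <- matrix(NA_real_, nc, nd, dimnames = list(cells, compounds$compound_id))
  for (j in seq_len(nd)) {
    wj <- w[[moa[j]]]
    logIc50[, j] <- alpha[j] + as.numeric(zstd[, names(wj), drop = FALSE] %*% wj)
  }
  logIc50 <- pmin(pmax(logIc50, interior[1]), interior[2])

  # viability surface on the grid
  h <- config$hillSlope
  ex <- expand.grid(sample_id = cells, compound_id = compounds$compound_id,
                    concentration_um = grid, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  ic <- 10^logIc50[cbind(ex$sample_id, ex$compound_id)]
  v <- 1 / (1 + (ex$concentration_um / ic)^h)
  if (config$noiseSd > 0) v <- v + rnorm(length(v), sd = config$noiseSd)
  ex$viability <- pmax(v, 0)

  # interaction graph: sparse background + planted cliques on target sets
  nPairs <- ng * (ng - 1) / 2
  nBg <- stats::rbinom(1L, nPairs, config$backgroundDensity)
  ut <- which(upper.tri(matrix(FALSE, ng, ng)))
  pick <- arrayInd(sample(ut, nBg), c(ng, ng))
  bg <- data.frame(node_a = genes[pick[, 1]], node_b = genes[pick[, 2]],
                   score = runif(nBg, 0.15, 1))
  planted <- do.call(rbind, lapply(classes, function(cl) {
    tg <- classTargets[[cl]]
    prs <- utils::combn(sort(tg), 2L)
    data.frame(node_a = prs[1, ], node_b = prs[2, ],
               score = runif(ncol(prs), 0.75, 1))
  }))
  graph <- rbind(planted, bg)
  a <- pmin(graph$node_a, graph$node_b); b <- pmax(graph$node_a, graph$node_b)
  graph <- graph[!duplicated(paste(a, b)), , drop = FALSE]

  gt <- list(classTargets = classTargets,
             compoundTargets = stats::setNames(unname(classTargets[moa]), compounds$compound_id),
             logIc50 = logIc50, linkWeights = w, alpha = stats::setNames(alpha, compounds$compound_id),
             plantedModules = classTargets, hillSlope = h)
  new("SyntheticCohort", expression = expr, compounds = compounds,
      viability = ex, groundTruth = gt, graph = graph, config = unclass(config))
}

#' Planted ground-truth IC50 of a (cell, compound) pair
#' @param cohort a [SyntheticCohort-class].
#' @param cell cell line id.
#' @param compound compound id.
#' @return true IC50 in uM.
#' @export
oracleIc50 <- function(cohort, cell, compound) {
  gt <- cohort@groundTruth
  if (!cell %in% rownames(gt$logIc50)) stopf("unknown cell line '%s'", cell)
  if (!compound %in% colnames(gt$logIc50)) stopf("unknown compound '%s'", compound)
  10^gt$logIc50[cell, compound]
}

#' Planted target-gene set of a compound
#' @param cohort a [SyntheticCohort-class].
#' @param compound compound id.
#' @return character vector of target genes.
#' @export
oracleTargets <- function(cohort, compound) {
  gt <- cohort@groundTruth
  if (!compound %in% names(gt$compoundTargets)) stopf("unknown compound '%s'", compound)
  gt$compoundTargets[[compound]]
}

#' True noiseless viability of a pair at given concentrations
#' @param cohort a [SyntheticCohort-class].
#' @param cell,compound pair identifiers.
#' @param conc concentrations in uM.
#' @return numeric viabilities.
#' @export
oracleViability <- function(cohort, cell, compound, conc = defaultGrid()) {
  ic <- oracleIc50(cohort, cell, compound)
  1 / (1 + (conc / ic)^cohort@groundTruth$hillSlope)
}

#' Write a cohort to disk in plain-text formats
#'
#' Expression as genes x samples TSV, compounds and viability as CSV, the
#' interaction graph as TSV, and the ground truth as JSON.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             compounds = file.path(dir, "compounds.csv"),
             viability = file.path(dir, "viability.csv"),
             graph = file.path(dir, "ppi.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  writeExpression(cohort@expression, paths["expression"])
  cmp <- cohort@compounds
  cmp$targets <- vapply(cmp$targets, paste, "", collapse = ";")
  write.csv(cmp, paths["compounds"], row.names = FALSE)
  write.csv(cohort@viability, paths["viability"], row.names = FALSE)
  write.table(cohort@graph, paths["graph"], sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort@groundTruth
  jsonlite::write_json(list(classTargets = gt$classTargets,
                            logIc50 = as.data.frame(gt$logIc50),
                            cells = rownames(gt$logIc50),
                            alpha = as.list(gt$alpha),
                            hillSlope = gt$hillSlope),
                       paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
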