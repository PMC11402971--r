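# Stage orchestration behind the command-line surface: each stage reads its
# upstream artifacts from the run directory, writes new versioned outputs
# (inputs are never mutated), and records a manifest with the config hash,
# seed, and input hashes.

.pipelineStages <- c("simulate", "train", "predict", "fit-curves", "attribute", "interpret")

#' Default run configuration
#'
#' Nested parameter blocks for every pipeline stage; values here are the
#' package defaults and can be overridden by a JSON config file or direct
#' list manipulation. Every random operation derives its seed from the
#' global `seed` plus the stage name.
#'
#' @param seed global seed.
#' @return nested config list.
#' @export
defaultRunConfig <- function(seed = 7L) {
  list(
    seed = as.integer(seed),
    synthetic = list(),                    # overrides for syntheticConfig()
    model = list(variant = "film",
                 geneEncoderWidths = c(128L, 64L), embeddingDim = 32L,
                 compoundEncoderWidths = c(64L), nFilmLayers = 2L,
                 dropout = 0.1, logConcentration = TRUE),
    hyper = list(lr = 2e-3, batchSize = 256L, maxEpochs = 120L, patience = 12L),
    cv = list(k = 4L),
    qc = list(relIncrease = 0.20, minPoints = 16L, minViabilityGate = 0.4),
    attribution = list(steps = 50L),
    interpret = list(resolution = 1, knn = 15L, scoreFilter = 0.7)
  )
}

.readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  base <- defaultRunConfig(config$seed %||% 7L)
  known <- names(base)
  bad <- setdiff(names(config), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  utils::modifyList(base, config)
}

.writeManifest <- function(outDir, stage, cfg, inputs) {
  cfgFile <- tempfile(); on.exit(unlink(cfgFile))
  jsonlite::write_json(cfg, cfgFile, digits = NA, auto_unbox = TRUE)
  manifest <- list(stage = stage, seed = cfg$seed,
                   config_hash = unname(tools::md5sum(cfgFile)),
                   inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, paste0("manifest_", stage, ".json")),
                       digits = NA, auto_unbox = TRUE)
}

.needs <- function(path, producer) {
  if (!file.exists(path)) {
    stopf("missing upstream artifact '%s': run the '%s' stage first", path, producer)
  }
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort to disk), `train` (grouped
#' cross-validation ensemble), `predict` (dose-response curves for every
#' pair), `fit-curves` (QC + log-logistic fits + pharmacodynamics),
#' `attribute` (integrated gradients at the predicted IC50, raw and
#' adjusted), `interpret` (CCS filtering, K-means AMI, Leiden clusters,
#' differential attribution, target-module connectivity). Each stage writes
#' its outputs plus a manifest under `outDir` and never modifies its inputs.
#'
#' @param stage one of the stage names above.
#' @param config a config list, path to a JSON config, or NULL for defaults.
#' @param outDir run directory (created if needed).
#' @param verbose print progress.
#' @return invisible list of produced artifact paths.
#' @export
runStage <- function(stage, config = NULL, outDir = "filmSens-run", verbose = FALSE) {
  stage <- match.arg(stage, .pipelineStages)
  cfg <- .readRunConfig(config %||% list())
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  op <- options(filmSens.verbose = verbose); on.exit(options(op))
  paths <- list(
    cohortDir = file.path(outDir, "cohort"),
    model = file.path(outDir, "model.rds"),
    curves = file.path(outDir, "curves.csv"),
    fits = file.path(outDir, "fits.csv"),
    attrRaw = file.path(outDir, "attributions_raw.csv"),
    attrAdj = file.path(outDir, "attributions_adjusted.csv"),
    interpret = file.path(outDir, "interpretation.json")
  )
  produced <- switch(
    stage,
    "simulate" = {
      sc <- do.call(syntheticConfig, utils::modifyList(list(seed = cfg$seed), cfg$synthetic))
      cohort <- generateCohort(sc)
      vmessage("simulated cohort: ", nrow(cohort@viability), " examples")
      writeCohort(cohort, paths$cohortDir)
    },
    "train" = {
      expr <- readExpression(.needs(file.path(paths$cohortDir, "expression.tsv"), "simulate"))
      compounds <- readCompounds(file.path(paths$cohortDir, "compounds.csv"))
      viab <- read.csv(file.path(paths$cohortDir, "viability.csv"))
      fp <- compoundFingerprints(compounds)
      m <- cfg$model
      mc <- modelConfig(m$variant, nGenes = ncol(expr),
                        geneEncoderWidths = m$geneEncoderWidths,
                        compoundEncoderWidths = m$compoundEncoderWidths,
                        embeddingDim = m$embeddingDim, nFilmLayers = m$nFilmLayers,
                        dropout = m$dropout, logConcentration = m$logConcentration,
                        seed = deriveSeed(cfg$seed, "model"))
      splits <- makeCvSplits(rownames(expr), k = cfg$cv$k, seed = deriveSeed(cfg$seed, "cv"))
      ens <- crossValidate(mc, expr, viab, fp, splits, cfg$hyper)
      vmessage("fold R2: ", paste(sprintf("%.3f", ens@foldR2), collapse = ", "))
      saveModel(ens, paths$model)
      jsonlite::write_json(list(fold_r2 = ens@foldR2), file.path(outDir, "fold_r2.json"),
                           digits = NA)
      c(paths$model, file.path(outDir, "fold_r2.json"))
    },
    "predict" = {
      expr <- readExpression(.needs(file.path(paths$cohortDir, "expression.tsv"), "simulate"))
      compounds <- readCompounds(file.path(paths$cohortDir, "compounds.csv"))
      fp <- compoundFingerprints(compounds)
      ens <- loadModel(.needs(paths$model, "train"))
      grid <- defaultGrid()
      ex <- expand.grid(sample_id = rownames(expr),
                        compound_id = compounds$compound_id,
                        concentration_um = grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
      ex$viability <- predictExamples(ens, expr, ex, fp)
      write.csv(ex, paths$curves, row.names = FALSE)
      paths$curves
    },
    "fit-curves" = {
      curves <- read.csv(.needs(paths$curves, "predict"))
      rows <- list()
      for (key in unique(paste(curves$sample_id, curves$compound_id, sep = "::"))) {
        pc <- strsplit(key, "::", fixed = TRUE)[[1]]
        pts <- curves[curves$sample_id == pc[1] & curves$compound_id == pc[2],
                      c("concentration_um", "viability")]
        qc <- qcCurve(pts, relIncrease = cfg$qc$relIncrease,
                      minPoints = cfg$qc$minPoints,
                      minViabilityGate = cfg$qc$minViabilityGate)
        fit <- if (qc$qcStatus == "pass") fitLogLogistic(qc$points) else NULL
        rows[[key]] <- data.frame(
          sample_id = pc[1], compound_id = pc[2],
          qc_status = if (is.null(fit)) qc$qcStatus else fit@qcStatus,
          n_params = if (is.null(fit)) NA_integer_ else fit@nParams,
          b = if (is.null(fit)) NA_real_ else fit@b,
          c = if (is.null(fit)) NA_real_ else fit@cLower,
          d = if (is.null(fit)) NA_real_ else fit@dUpper,
          e = if (is.null(fit)) NA_real_ else fit@eMid,
          ic50_um = if (!is.null(fit) && fit@qcStatus == "pass") deriveIc50(fit) else NA_real_,
          auc = deriveAuc(pts))
      }
      tab <- do.call(rbind, rows); rownames(tab) <- NULL
      writeFits(tab, paths$fits)
      paths$fits
    },
    "attribute" = {
      expr <- readExpression(.needs(file.path(paths$cohortDir, "expression.tsv"), "simulate"))
      compounds <- readCompounds(file.path(paths$cohortDir, "compounds.csv"))
      fp <- compoundFingerprints(compounds)
      ens <- loadModel(.needs(paths$model, "train"))
      fits <- read.csv(.needs(paths$fits, "fit-curves"))
      raw <- attributeAtIc50(ens, expr, fits, fp, steps = cfg$attribution$steps)
      adj <- adjustAttributions(raw)
      writeAttributions(raw, paths$attrRaw)
      writeAttributions(adj, paths$attrAdj)
      c(paths$attrRaw, paths$attrAdj)
    },
    "interpret" = {
      compounds <- readCompounds(.needs(file.path(paths$cohortDir, "compounds.csv"), "simulate"))
      adj <- readAttributions(.needs(paths$attrAdj, "attribute"))
      graph <- readInteractionGraph(.needs(file.path(paths$cohortDir, "ppi.tsv"), "simulate"),
                                    scoreFilter = cfg$interpret$scoreFilter)
      ccs <- buildCcs(adj, compounds)
      ami <- kmeansAmi(ccs$attr@values, ccs$labels,
                       seed = deriveSeed(cfg$seed, "ami"))
      leiden <- leidenClusters(adj@values, resolution = cfg$interpret$resolution,
                               k = cfg$interpret$knn, seed = deriveSeed(cfg$seed, "leiden"))
      profiles <- clusterTargetProfile(leiden, adj@meta$compound_id, compounds,
                                       seed = deriveSeed(cfg$seed, "ctp"))
      conn <- lapply(profiles, function(tg) {
        if (length(tg) < 2L) return(NULL)
        nullRes <- connectivityNull(graph, tg, pool = colnames(adj@values),
                                    nDraws = 1000L, seed = deriveSeed(cfg$seed, "null"))
        list(targets = tg, connectivity = nullRes$observed, p = nullRes$p)
      })
      out <- list(ccs_classes = ccs$classes, kmeans_ami = ami,
                  leiden_sizes = as.list(table(leiden)),
                  module_connectivity = conn)
      jsonlite::write_json(out, paths$interpret, digits = NA, auto_unbox = TRUE)
      paths$interpret
    })
  .writeManifest(outDir, stage, cfg, unlist(paths, use.names = FALSE))
  invisible(produced)
}
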