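# Shared fixtures: tiny deterministic objects built in code, and a memoised
# micro cohort + micro trained model so several test files can reuse them
# without retraining.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a noiseless log-logistic curve on the default grid
llCurve <- function(b = 1, c = 0, d = 1, e = 0.5, grid = defaultGrid()) {
  data.frame(concentration_um = grid,
             viability = c + (d - c) / (1 + exp(b * (log(grid) - log(e)))))
}

# micro synthetic cohort: small enough for seconds-scale training
microCohort <- function() {
  memo("microCohort", generateCohort(
    syntheticConfig(nCellLines = 6L, nGenes = 40L, nCompounds = 8L,
                    nMoaClasses = 4L, targetsPerClass = 2L, seed = 21L)))
}

microConfig <- function(variant = "film", seed = 5L, ...) {
  modelConfig(variant, nGenes = 40L, geneEncoderWidths = c(24L),
              compoundEncoderWidths = c(24L), embeddingDim = 12L,
              nFilmLayers = 2L, dropout = 0.05, logConcentration = TRUE,
              seed = seed, ...)
}

microFingerprints <- function() {
  memo("microFp", filmSens:::compoundFingerprints(cohortCompounds(microCohort())))
}

# a briefly trained film model on the micro cohort (shared across files)
microModel <- function() {
  memo("microModel", {
    ch <- microCohort()
    trainModel(microConfig(), cohortExpression(ch), cohortViability(ch),
               microFingerprints(),
               hyper = list(lr = 3e-3, batchSize = 128L, maxEpochs = 25L,
                            patience = 25L, seed = 5L))
  })
}

# tiny interaction graph with a planted triangle
toyGraph <- function() {
  interactionGraph(data.frame(
    node_a = c("A", "A", "B", "C", "D"),
    node_b = c("B", "C", "C", "D", "E"),
    score = c(0.9, 0.85, 0.8, 0.95, 0.2)), scoreFilter = 0.7)
}
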