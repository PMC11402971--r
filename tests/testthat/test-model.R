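# The conditional model: FiLM arithmetic, variant construction, training
# behavior, prediction determinism, R^2, and grouped cross-validation.

test_that("filmModulate is the stated affine map", {
  expect_equal(filmModulate(c(1, 2), c(1, 1), c(0, 0)), c(1, 2))   # identity
  expect_equal(filmModulate(c(1, 2), c(3, 0), c(0, 5)), c(3, 5))
  expect_equal(filmModulate(c(7, -4), c(0, 0), c(2, 3)), c(2, 3))  # annihilation
  m <- matrix(1:6, 2)
  expect_equal(filmModulate(m, c(1, 1, 1), c(0, 0, 0)), m)
  expect_error(filmModulate(c(1, 2), c(1, 1, 1), c(0, 0)), "mismatch")
})

test_that("the scale variant has beta = 0 and the shift variant gamma = 1", {
  genes <- paste0("g", 1:40)
  cv <- c(rep(0, 19), 1, rep(0, 492), 2.5)  # arbitrary 513-length input
  for (v in c("scale", "shift")) {
    cfg <- modelConfig(v, nGenes = 40L, geneEncoderWidths = c(16L),
                       compoundEncoderWidths = c(16L), embeddingDim = 8L,
                       nFilmLayers = 2L, dropout = 0, seed = 2L)
    m <- buildModel(cfg, genes)
    cp <- conditioningParams(m, cv)
    expect_length(cp, 2L)
    for (layer in cp) {
      if (v == "scale") expect_equal(layer$beta, rep(0, 8))
      if (v == "shift") expect_equal(layer$gamma, rep(1, 8))
    }
  }
})

test_that("straw codes are fixed per compound and distinct across compounds", {
  cfg <- microConfig("straw")
  ids <- cohortCompounds(microCohort())$compound_id
  m1 <- buildModel(cfg, geneIds(microCohort()), compoundIds = ids)
  m2 <- buildModel(cfg, geneIds(microCohort()), compoundIds = ids)
  expect_identical(m1@strawCodes, m2@strawCodes)        # seeded lookup
  expect_identical(anyDuplicated(m1@strawCodes), 0L)    # no two codes equal
  expect_error(buildModel(cfg, geneIds(microCohort())), "compoundIds")
})

test_that("the concatenation baseline matches the FiLM parameter count", {
  cfg <- modelConfig("film", nGenes = 500L, seed = 1L)   # paper-scale widths
  film <- filmSens:::.filmParamCount(cfg)
  cfgC <- modelConfig("concatenation", nGenes = 500L, seed = 1L)
  mC <- buildModel(cfgC, paste0("g", 1:500))
  concat <- sum(vapply(filmSens:::flattenLeaves(mC@params), length, 1L))
  expect_lt(abs(concat - film) / film, 0.10)
})

test_that("predictions are scalar, deterministic, and batch-order invariant", {
  m <- microModel()
  ch <- microCohort()
  expr <- cohortExpression(ch)
  fp <- microFingerprints()
  cv <- c(fp[1, ], 1.0)
  p1 <- predictViability(m, expr[1, ], cv, compoundId = rownames(fp)[1])
  expect_length(p1, 1L)
  expect_true(is.finite(p1))
  expect_identical(p1, predictViability(m, expr[1, ], cv, compoundId = rownames(fp)[1]))
  # batch-order invariance
  N <- cbind(fp[rep(1:4, each = 3), ], rep(c(0.1, 1, 10), 4))
  X <- expr[rep(1:2, 6), ]
  pAll <- predictViability(m, X, N)
  perm <- sample(seq_len(12))
  expect_equal(predictViability(m, X[perm, ], N[perm, ]), pAll[perm],
               tolerance = 1e-6)
  expect_error(predictViability(m, expr[1, 1:10], cv), "genes")
})

test_that("a FiLM generator frozen to identity makes predictions compound-invariant", {
  m <- microModel()
  for (j in seq_along(m@params$filmGens)) {
    m@params$filmGens[[j]]$W[] <- 0
    m@params$filmGens[[j]]$b[] <- 0
  }
  expr <- cohortExpression(microCohort())[1, ]
  fp <- microFingerprints()
  pA <- predictViability(m, expr, c(fp[1, ], 5))
  pB <- predictViability(m, expr, c(fp[3, ], 5))
  expect_equal(pA, pB)
  # but still depends on concentration only through the (dead) generator path
  pC <- predictViability(m, expr, c(fp[1, ], 50))
  expect_equal(pA, pC)
})

test_that("r2Score matches hand arithmetic", {
  expect_equal(r2Score(c(0, 1, 2), c(0, 1, 2)), 1)
  y <- c(0, 1, 2)
  expect_equal(r2Score(y, rep(mean(y), 3)), 0)
  expect_equal(r2Score(c(0, 1, 2), c(0, 1, 1)), 0.5)
  expect_error(r2Score(c(1, 1), c(1, 2)), "variance")
})

test_that("training reduces the loss and is seed-deterministic", {
  ch <- microCohort()
  m <- microModel()
  log <- m@trainingLog
  expect_gt(nrow(log), 5L)
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
  # determinism: identical seeds -> identical loss series
  m2 <- trainModel(microConfig(), cohortExpression(ch), cohortViability(ch),
                   microFingerprints(),
                   hyper = list(lr = 3e-3, batchSize = 128L, maxEpochs = 3L,
                                patience = 25L, seed = 5L))
  m3 <- trainModel(microConfig(), cohortExpression(ch), cohortViability(ch),
                   microFingerprints(),
                   hyper = list(lr = 3e-3, batchSize = 128L, maxEpochs = 3L,
                                patience = 25L, seed = 5L))
  expect_identical(m2@trainingLog, m3@trainingLog)
  expect_error(trainModel(microConfig(), cohortExpression(ch),
                          cohortViability(ch)[0, ], microFingerprints()),
               "empty")
})

test_that("a trained model beats the label mean on its own cohort", {
  ch <- microCohort()
  r2 <- evaluateR2(microModel(), cohortExpression(ch), cohortViability(ch),
                   microFingerprints())
  expect_gt(r2, 0.3)
})

test_that("grouped cross-validation never leaks cell lines and averages members", {
  ch <- microCohort()
  expr <- cohortExpression(ch)
  viab <- cohortViability(ch)
  splits <- makeCvSplits(rownames(expr), k = 2L, seed = 8L)
  ens <- crossValidate(microConfig(seed = 9L), expr, viab, microFingerprints(),
                       splits, hyper = list(maxEpochs = 8L, batchSize = 128L,
                                            lr = 3e-3, patience = 8L))
  expect_s4_class(ens, "FilmEnsemble")
  expect_length(ens@models, 2L)
  expect_length(ens@foldR2, 2L)
  # ensemble prediction = arithmetic mean of member predictions
  fp <- microFingerprints()
  cv <- c(fp[2, ], 0.5)
  pm <- vapply(ens@models, predictViability, numeric(1), expr[1, ], cv)
  expect_equal(predictViability(ens, expr[1, ], cv), mean(pm))
})

test_that("checkpoints round-trip exactly", {
  m <- microModel()
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m2@config, m@config)
  expect_identical(m2@geneIds, m@geneIds)
  expr <- cohortExpression(microCohort())[2, ]
  fp <- microFingerprints()
  expect_identical(predictViability(m, expr, c(fp[1, ], 3)),
                   predictViability(m2, expr, c(fp[1, ], 3)))
  expect_error(loadModel(system.file("DESCRIPTION", package = "filmSens")))
})

test_that("NaN-producing hyperparameters abort with a diagnostic", {
  ch <- microCohort()
  expect_error(
    trainModel(microConfig(), cohortExpression(ch), cohortViability(ch),
               microFingerprints(),
               hyper = list(lr = 1e200, batchSize = 128L, maxEpochs = 5L,
                            patience = 5L, seed = 1L)),
    "loss")
})
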