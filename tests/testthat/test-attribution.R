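# Integrated gradients and attribution post-processing.

# a hand-built exactly-linear model: empty hidden chain + linear head, so
# f([x, n]) = w . [x, n] and integrated gradients have a closed form
linearSurrogate <- function(nGenes = 6L, nComp = 5L, seed = 1L) {
  cfg <- modelConfig("concatenation", nGenes = nGenes,
                     geneEncoderWidths = c(4L), compoundEncoderWidths = c(4L),
                     embeddingDim = 4L, dropout = 0,
                     nCompoundFeatures = nComp, seed = seed)
  m <- buildModel(cfg, paste0("g", seq_len(nGenes)))
  set.seed(seed)
  w <- rnorm(nGenes + nComp)
  m@params <- list(mainChain = list(),
                   head = list(W = matrix(w, ncol = 1L), b = 0.3))
  m@frozenStats <- list(mean = rep(0, nGenes), sd = rep(1, nGenes))
  m@trained <- TRUE
  attr(m, "w") <- w
  m
}

test_that("integrated gradients are exact for a linear model at any step count", {
  m <- linearSurrogate()
  w <- attr(m, "w")
  x <- c(0.5, -1, 2, 0, 1.5, -0.2)
  n <- c(1, 0, 1, 0, 2.5)
  for (steps in c(2L, 7L, 50L)) {
    ig <- integratedGradients(m, x, n, steps = steps)
    expect_equal(unname(ig$gene), w[1:6] * x, tolerance = 1e-12)
    expect_equal(ig$compound, w[7:11] * n, tolerance = 1e-12)
    expect_equal(sum(ig$gene) + sum(ig$compound),
                 ig$prediction - ig$baselinePrediction, tolerance = 1e-10)
  }
})

test_that("integrated gradients of a constant model vanish", {
  m <- linearSurrogate()
  m@params$head$W[] <- 0
  ig <- integratedGradients(m, rnorm(6), c(1, 1, 0, 0, 2))
  expect_equal(unname(ig$gene), rep(0, 6))
  expect_equal(ig$compound, rep(0, 5))
})

test_that("completeness error behaves like a quadrature error on a trained model", {
  # the 50-step Riemann sum carries O(1/steps) error on a kinked ReLU
  # gradient path: absolute gaps should be small relative to the
  # prediction scale and collapse by ~an order of magnitude at 8x steps
  m <- microModel()
  ch <- microCohort()
  expr <- cohortExpression(ch)
  fp <- microFingerprints()
  set.seed(30)
  gap <- function(steps, x, cv) {
    ig <- integratedGradients(m, x, cv, steps = steps)
    abs(sum(ig$gene) + sum(ig$compound) - (ig$prediction - ig$baselinePrediction))
  }
  g50 <- g400 <- numeric(10)
  for (i in 1:10) {
    x <- expr[sample(nrow(expr), 1), ]
    cv <- c(fp[sample(nrow(fp), 1), ], 10^runif(1, -2, 2))
    g50[i] <- gap(50L, x, cv)
    g400[i] <- gap(400L, x, cv)
  }
  expect_lt(median(g50), 0.05)          # small on the viability scale
  expect_lt(mean(g400), mean(g50) / 2)  # refinement
})

test_that("refining the path shrinks the completeness gap", {
  m <- microModel()
  ch <- microCohort()
  fp <- microFingerprints()
  cv <- c(fp[2, ], 1.0)
  gap <- function(steps) {
    ig <- integratedGradients(m, cohortExpression(ch)[3, ], cv, steps = steps)
    abs(sum(ig$gene) + sum(ig$compound) - (ig$prediction - ig$baselinePrediction))
  }
  expect_lte(gap(100L), gap(50L) + 1e-12)
})

test_that("attribution at IC50 yields one deterministic row per usable pair", {
  m <- microModel()
  ch <- microCohort()
  expr <- cohortExpression(ch)
  fp <- microFingerprints()
  fitTable <- expand.grid(sample_id = rownames(expr)[1:3],
                          compound_id = rownames(fp)[1:4],
                          stringsAsFactors = FALSE)
  fitTable$ic50_um <- c(rep(1, 10), NA, NA)  # two pairs lack an IC50
  am <- attributeAtIc50(m, expr, fitTable, fp)
  expect_equal(nrow(attrValues(am)), 10L)
  expect_false(isAdjusted(am))
  expect_equal(nrow(attr(am, "skipped")), 2L)
  am2 <- attributeAtIc50(m, expr, fitTable, fp)
  expect_identical(attrValues(am), attrValues(am2))
  # row content does not depend on which other rows are present
  am1 <- attributeAtIc50(m, expr, fitTable[1:3, ], fp)
  expect_equal(attrValues(am1)[1, ], attrValues(am)[1, ])
})

test_that("adjustment centers and scales per cell line and is idempotent", {
  set.seed(17)
  vals <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("g", 1:5)))
  meta <- data.frame(cell_line_id = rep(c("A", "B"), each = 4),
                     compound_id = paste0("c", rep(1:4, 2)), ic50_um = 1)
  raw <- new("AttributionMatrix", values = vals, meta = meta, adjusted = FALSE)
  adj <- adjustAttributions(raw)
  expect_true(isAdjusted(adj))
  for (cl in c("A", "B")) {
    sub <- attrValues(adj)[meta$cell_line_id == cl, ]
    expect_lt(max(abs(colMeans(sub))), 1e-8)
    expect_lt(max(abs(apply(sub, 2, filmSens:::popSd) - 1)), 1e-8)
  }
  again <- adjustAttributions(adj)
  expect_lt(max(abs(attrValues(again) - attrValues(adj))), 1e-8)
  # location invariance: per-cell-line offsets cancel
  shifted <- raw
  shifted@values[meta$cell_line_id == "B", ] <-
    shifted@values[meta$cell_line_id == "B", ] + 5
  expect_equal(attrValues(adjustAttributions(shifted)), attrValues(adj))
  # single-row cell line cannot be standardized
  solo <- new("AttributionMatrix", values = vals[1:3, ],
              meta = data.frame(cell_line_id = c("A", "A", "B"),
                                compound_id = paste0("c", 1:3), ic50_um = 1),
              adjusted = FALSE)
  expect_error(adjustAttributions(solo), "single")
})

test_that("self-comparison yields perfect correlations and full coverage", {
  set.seed(18)
  vals <- matrix(rnorm(6 * 7), 6, 7, dimnames = list(NULL, paste0("g", 1:7)))
  meta <- data.frame(cell_line_id = rep(c("A", "B"), each = 3),
                     compound_id = paste0("c", rep(1:3, 2)), ic50_um = 1)
  raw <- new("AttributionMatrix", values = vals, meta = meta, adjusted = FALSE)
  rep <- filmSens:::.soundnessReport(raw, raw)
  expect_length(rep$raw, 6L)
  expect_length(rep$adjusted, 6L)
  expect_equal(rep$raw, rep(1, 6), tolerance = 1e-12)
})

test_that("attribution matrices round-trip through CSV to 1e-12", {
  set.seed(19)
  vals <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(NULL, paste0("g", 1:6)))
  meta <- data.frame(cell_line_id = rep(c("A", "B"), 2),
                     compound_id = paste0("c", 1:4), ic50_um = c(0.5, 1, 2, 4))
  am <- new("AttributionMatrix", values = vals, meta = meta, adjusted = FALSE)
  path <- tempfile(fileext = ".csv")
  writeAttributions(am, path)
  back <- readAttributions(path)
  expect_lt(max(abs(attrValues(back) - vals)), 1e-12)
  expect_identical(attrMeta(back)$compound_id, meta$compound_id)
  expect_false(isAdjusted(back))
})

test_that("label permutation preserves the label multiset", {
  ch <- microCohort()
  viab <- cohortViability(ch)
  set.seed(filmSens:::deriveSeed(7L, "label-permutation"))
  perm <- sample(viab$viability)
  expect_identical(sort(perm), sort(viab$viability))
  expect_false(identical(perm, viab$viability))
})
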