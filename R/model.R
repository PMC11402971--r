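#' Model architecture configuration
#'
#' Defaults mirror the published architecture: a transcriptome encoder with
#' hidden layers [2048, 512, 256], a compound encoder with hidden layers
#' [256, 128], both projecting to an embedding of size g = c = 128, and two
#' FiLM layers whose generators predict per-feature scale (gamma) and shift
#' (beta) parameters from the compound embedding. Variants: `"film"` (full
#' conditional model), `"scale"` (beta held at 0), `"shift"` (gamma held at
#' 1), `"concatenation"` (plain MLP on the concatenated feature vector with a
#' comparable parameter count), and `"straw"` (structural ablation: each
#' compound's fingerprint replaced by a fixed random binary code).
#'
#' @param variant one of "film", "scale", "shift", "concatenation", "straw".
#' @param nGenes expression input dimension.
#' @param geneEncoderWidths hidden widths of the transcriptome encoder.
#' @param compoundEncoderWidths hidden widths of the compound encoder.
#' @param embeddingDim shared embedding size g = c.
#' @param nFilmLayers number of FiLM layers (>= 1 for conditioning variants).
#' @param dropout dropout rate in [0, 1).
#' @param nCompoundFeatures length of the compound vector (512 bits + 1
#'   concentration = 513).
#' @param logConcentration transform the concentration feature to log10(uM)
#'   inside the model (default FALSE: raw micromolar).
#' @param seed integer seed for weight initialization (and straw codes).
#' @return a validated config list of class "filmSensConfig".
#' @export
modelConfig <- function(variant = c("film", "scale", "shift", "concatenation", "straw"),
                        nGenes,
                        geneEncoderWidths = c(2048L, 512L, 256L),
                        compoundEncoderWidths = c(256L, 128L),
                        embeddingDim = 128L,
                        nFilmLayers = 2L,
                        dropout = 0.1,
                        nCompoundFeatures = 513L,
                        logConcentration = FALSE,
                        seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(isCount(nGenes), isCount(embeddingDim), isCount(nCompoundFeatures),
            dropout >= 0, dropout < 1)
  if (variant != "concatenation" && !isCount(nFilmLayers)) {
    stopf("nFilmLayers must be a positive integer for conditioning variants")
  }
  cfg <- list(variant = variant, nGenes = as.integer(nGenes),
              geneEncoderWidths = as.integer(geneEncoderWidths),
              compoundEncoderWidths = as.integer(compoundEncoderWidths),
              embeddingDim = as.integer(embeddingDim),
              nFilmLayers = as.integer(nFilmLayers),
              dropout = dropout,
              nCompoundFeatures = as.integer(nCompoundFeatures),
              logConcentration = isTRUE(logConcentration),
              seed = as.integer(seed))
  class(cfg) <- "filmSensConfig"
  cfg
}

# Parameter count of a linear/bn chain given its layer widths.
.chainParamCount <- function(inDim, widths, bn = TRUE) {
  n <- 0
  for (w in widths) {
    n <- n + inDim * w + w + if (bn) 2 * w else 0
    inDim <- w
  }
  n
}

.filmParamCount <- function(cfg) {
  g <- cfg$embeddingDim
  n <- .chainParamCount(cfg$nGenes, c(cfg$geneEncoderWidths, g)) +
    .chainParamCount(cfg$nCompoundFeatures, c(cfg$compoundEncoderWidths, g))
  genOut <- switch(cfg$variant, film = 2L * g, scale = g, shift = g, 2L * g)
  n + cfg$nFilmLayers * (g * genOut + genOut +      # generator
                           .chainParamCount(g, g)) + # post-FiLM linear block
    (g + 1)                                          # head
}

# Widths for the concatenation baseline: the FiLM gene-encoder widths scaled
# by a common factor so total trainable parameters match within 10%.
.concatWidths <- function(cfg) {
  target <- .filmParamCount(modelConfig("film", cfg$nGenes,
                                        geneEncoderWidths = cfg$geneEncoderWidths,
                                        compoundEncoderWidths = cfg$compoundEncoderWidths,
                                        embeddingDim = cfg$embeddingDim,
                                        nFilmLayers = cfg$nFilmLayers,
                                        dropout = cfg$dropout,
                                        nCompoundFeatures = cfg$nCompoundFeatures,
                                        seed = cfg$seed))
  base <- c(cfg$geneEncoderWidths, cfg$embeddingDim)
  inDim <- cfg$nGenes + cfg$nCompoundFeatures
  countFor <- function(s) {
    w <- pmax(2L, as.integer(round(base * s)))
    .chainParamCount(inDim, w) + w[length(w)] + 1
  }
  lo <- 0.05; hi <- 20
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    if (countFor(mid) < target) lo <- mid else hi <- mid
  }
  s <- sqrt(lo * hi)
  pmax(2L, as.integer(round(base * s)))
}

#' Build an untrained conditional viability model
#'
#' @param config a [modelConfig()] list.
#' @param geneIdList character vector naming the expression input axis.
#' @param compoundIds compound identifiers (required for the straw variant,
#'   whose per-compound random binary codes are fixed at build time).
#' @return an untrained [FilmModel-class].
#' @export
buildModel <- function(config, geneIdList, compoundIds = NULL) {
  stopifnot(inherits(config, "filmSensConfig"))
  if (length(geneIdList) != config$nGenes) {
    stopf("geneIdList length %d != config nGenes %d", length(geneIdList), config$nGenes)
  }
  set.seed(deriveSeed(config$seed, "init"))
  g <- config$embeddingDim
  dr <- config$dropout
  params <- list()
  if (config$variant == "concatenation") {
    widths <- .concatWidths(config)
    inDim <- config$nGenes + config$nCompoundFeatures
    chain <- list()
    for (i in seq_along(widths)) {
      chain[[paste0("l", i)]] <- makeBlock(inDim, widths[i], drop = dr)
      inDim <- widths[i]
    }
    params$mainChain <- chain
    params$head <- list(W = heInit(inDim, 1L), b = 0)
  } else {
    gw <- c(config$geneEncoderWidths, g)
    cw <- c(config$compoundEncoderWidths, g)
    geneChain <- list(); inDim <- config$nGenes
    for (i in seq_along(gw)) {
      geneChain[[paste0("l", i)]] <- makeBlock(inDim, gw[i], drop = dr)
      inDim <- gw[i]
    }
    compChain <- list(); inDim <- config$nCompoundFeatures
    for (i in seq_along(cw)) {
      compChain[[paste0("l", i)]] <- makeBlock(inDim, cw[i], drop = dr)
      inDim <- cw[i]
    }
    genOut <- switch(config$variant, scale = g, shift = g, 2L * g)
    filmGens <- list(); filmBlocks <- list()
    for (j in seq_len(config$nFilmLayers)) {
      # near-identity start: gamma ~ 1, beta ~ 0
      filmGens[[paste0("g", j)]] <- list(W = matrix(rnorm(g * genOut, sd = 1e-2), g, genOut),
                                         b = rep(0, genOut))
      filmBlocks[[paste0("b", j)]] <- makeBlock(g, g, drop = dr)
    }
    params$geneChain <- geneChain
    params$compChain <- compChain
    params$filmGens <- filmGens
    params$filmBlocks <- filmBlocks
    params$head <- list(W = heInit(g, 1L), b = 0)
  }
  strawCodes <- NULL
  if (config$variant == "straw") {
    if (is.null(compoundIds)) stopf("straw variant needs compoundIds at build time")
    set.seed(deriveSeed(config$seed, "straw"))
    nb <- config$nCompoundFeatures - 1L
    strawCodes <- matrix(as.integer(runif(length(compoundIds) * nb) < 0.5),
                         nrow = length(compoundIds), ncol = nb,
                         dimnames = list(as.character(compoundIds), NULL))
  }
  new("FilmModel", config = unclass(config), params = params,
      trainingLog = data.frame(), frozenStats = list(),
      geneIds = as.character(geneIdList), strawCodes = strawCodes,
      trained = FALSE)
}

#' Feature-wise linear modulation
#'
#' The FiLM operation: an elementwise affine transform of a hidden
#' representation, `gamma * hidden + beta`.
#'
#' @param hidden numeric vector (or matrix with features in columns).
#' @param gamma,beta numeric vectors of the same feature length.
#' @return modulated vector/matrix.
#' @export
filmModulate <- function(hidden, gamma, beta) {
  nf <- if (is.matrix(hidden)) ncol(hidden) else length(hidden)
  if (length(gamma) != nf || length(beta) != nf) {
    stopf("FiLM shape mismatch: hidden has %d features, gamma %d, beta %d",
          nf, length(gamma), length(beta))
  }
  if (is.matrix(hidden)) {
    sweep(sweep(hidden, 2L, gamma, "*"), 2L, beta, "+")
  } else {
    gamma * hidden + beta
  }
}

# gamma/beta matrices for one FiLM layer from generator output.
.filmParamsFromGen <- function(gout, variant, g) {
  switch(variant,
         scale = list(gamma = 1 + gout, beta = gout * 0),
         shift = list(gamma = gout * 0 + 1, beta = gout),
         list(gamma = 1 + gout[, seq_len(g), drop = FALSE],
              beta = gout[, g + seq_len(g), drop = FALSE]))
}

# Full forward pass. X: batch x genes (standardized), N: batch x 513 (raw
# concentration; the log10 flag is applied here). Returns yhat plus caches
# needed for the corresponding backward pass.
nnForward <- function(model, X, N, train = FALSE) {
  cfg <- model@config
  if (cfg$logConcentration) N[, ncol(N)] <- log10(N[, ncol(N)])
  p <- model@params
  if (cfg$variant == "concatenation") {
    Z <- cbind(X, N)
    r <- chainForward(p$mainChain, Z, train)
    yhat <- r$out %*% p$head$W + p$head$b
    return(list(yhat = as.numeric(yhat), p = `[[<-`(p, "mainChain", r$chain),
                cache = list(main = r$caches, headIn = r$out, N = N)))
  }
  g <- cfg$embeddingDim
  rg <- chainForward(p$geneChain, X, train)
  rc <- chainForward(p$compChain, N, train)
  p$geneChain <- rg$chain; p$compChain <- rc$chain
  h <- rg$out
  filmCaches <- vector("list", cfg$nFilmLayers)
  blockCaches <- vector("list", cfg$nFilmLayers)
  for (j in seq_len(cfg$nFilmLayers)) {
    gen <- p$filmGens[[j]]
    gout <- rc$out %*% gen$W + rep(gen$b, each = nrow(N))
    fp <- .filmParamsFromGen(gout, cfg$variant, g)
    hf <- fp$gamma * h + fp$beta
    rb <- blockForward(p$filmBlocks[[j]], hf, train)
    filmCaches[[j]] <- list(hIn = h, gamma = fp$gamma)
    blockCaches[[j]] <- rb$cache
    p$filmBlocks[[j]] <- rb$blk
    h <- rb$out
  }
  yhat <- h %*% p$head$W + p$head$b
  list(yhat = as.numeric(yhat), p = p,
       cache = list(gene = rg$caches, comp = rc$caches, compOut = rc$out,
                    film = filmCaches, block = blockCaches, headIn = h, N = N))
}

# Training-mode backward pass from dyhat (batch vector). Returns parameter
# gradients in the same nested shape as model@params (trainable leaves).
nnBackward <- function(model, cache, dyhat, inputGrads = FALSE) {
  cfg <- model@config
  p <- model@params
  dy <- matrix(dyhat, ncol = 1L)
  grads <- list()
  if (cfg$variant == "concatenation") {
    grads$head <- list(W = crossprod(cache$headIn, dy), b = sum(dy))
    dh <- dy %*% t(p$head$W)
    r <- chainBackward(p$mainChain, cache$main, dh, inputGrad = inputGrads)
    grads$mainChain <- r$grads
    out <- list(grads = grads)
    if (inputGrads) {
      out$dX <- r$dx[, seq_len(cfg$nGenes), drop = FALSE]
      out$dN <- r$dx[, cfg$nGenes + seq_len(cfg$nCompoundFeatures), drop = FALSE]
    }
    return(out)
  }
  g <- cfg$embeddingDim
  grads$head <- list(W = crossprod(cache$headIn, dy), b = sum(dy))
  dh <- dy %*% t(p$head$W)
  dcomp <- matrix(0, nrow(dy), g)
  grads$filmGens <- vector("list", cfg$nFilmLayers)
  grads$filmBlocks <- vector("list", cfg$nFilmLayers)
  names(grads$filmGens) <- names(p$filmGens)
  names(grads$filmBlocks) <- names(p$filmBlocks)
  for (j in rev(seq_len(cfg$nFilmLayers))) {
    rb <- blockBackward(p$filmBlocks[[j]], cache$block[[j]], dh)
    grads$filmBlocks[[j]] <- rb$grads
    dhf <- rb$dx
    fc <- cache$film[[j]]
    dgamma <- dhf * fc$hIn
    dbeta <- dhf
    dgout <- switch(cfg$variant,
                    scale = dgamma, shift = dbeta, cbind(dgamma, dbeta))
    gen <- p$filmGens[[j]]
    grads$filmGens[[j]] <- list(W = crossprod(cache$compOut, dgout),
                                b = colSums(dgout))
    dcomp <- dcomp + dgout %*% t(gen$W)
    dh <- dhf * fc$gamma
  }
  rg <- chainBackward(p$geneChain, cache$gene, dh, inputGrad = inputGrads)
  rc <- chainBackward(p$compChain, cache$comp, dcomp, inputGrad = inputGrads)
  grads$geneChain <- rg$grads
  grads$compChain <- rc$grads
  out <- list(grads = grads)
  if (inputGrads) {
    out$dX <- rg$dx
    out$dN <- rc$dx
  }
  out
}

# Inference-mode gradient of the prediction w.r.t. both input blocks.
# Note: when logConcentration is on, the gradient is reported w.r.t. the
# log10-transformed concentration feature actually fed to the network.
nnInputGradients <- function(model, X, N) {
  fw <- nnForward(model, X, N, train = FALSE)
  cfg <- model@config
  p <- model@params
  ones <- matrix(1, length(fw$yhat), 1L)
  if (cfg$variant == "concatenation") {
    dh <- ones %*% t(p$head$W)
    dz <- chainEvalBackward(p$mainChain, fw$cache$main, dh)
    return(list(yhat = fw$yhat,
                dX = dz[, seq_len(cfg$nGenes), drop = FALSE],
                dN = dz[, cfg$nGenes + seq_len(cfg$nCompoundFeatures), drop = FALSE]))
  }
  g <- cfg$embeddingDim
  dh <- ones %*% t(p$head$W)
  dcomp <- matrix(0, nrow(ones), g)
  for (j in rev(seq_len(cfg$nFilmLayers))) {
    dhf <- blockEvalBackward(p$filmBlocks[[j]], fw$cache$block[[j]], dh)
    fc <- fw$cache$film[[j]]
    dgout <- switch(cfg$variant,
                    scale = dhf * fc$hIn, shift = dhf,
                    cbind(dhf * fc$hIn, dhf))
    dcomp <- dcomp + dgout %*% t(p$filmGens[[j]]$W)
    dh <- dhf * fc$gamma
  }
  dX <- chainEvalBackward(p$geneChain, fw$cache$gene, dh)
  dN <- chainEvalBackward(p$compChain, fw$cache$comp, dcomp)
  list(yhat = fw$yhat, dX = dX, dN = dN)
}

#' Inspect the conditioning parameters generated for a compound vector
#'
#' Runs the compound encoder and FiLM generators in inference mode and
#' returns the per-layer scale (gamma) and shift (beta) vectors. For the
#' "scale" variant beta is identically 0; for "shift" gamma is identically 1.
#'
#' @param model a trained or untrained conditioning-variant [FilmModel-class].
#' @param compoundVector numeric vector of length `nCompoundFeatures`
#'   (fingerprint bits + raw concentration in uM).
#' @return list of per-layer lists with elements `gamma`, `beta`, `layer`.
#' @export
conditioningParams <- function(model, compoundVector) {
  cfg <- model@config
  if (cfg$variant == "concatenation") stopf("concatenation variant has no conditioning parameters")
  N <- matrix(as.numeric(compoundVector), nrow = 1L)
  if (ncol(N) != cfg$nCompoundFeatures) stopf("compound vector must have length %d", cfg$nCompoundFeatures)
  if (cfg$logConcentration) N[, ncol(N)] <- log10(N[, ncol(N)])
  rc <- chainForward(model@params$compChain, N, train = FALSE)
  g <- cfg$embeddingDim
  lapply(seq_len(cfg$nFilmLayers), function(j) {
    gen <- model@params$filmGens[[j]]
    gout <- rc$out %*% gen$W + rep(gen$b, each = 1L)
    fp <- .filmParamsFromGen(gout, cfg$variant, g)
    list(gamma = as.numeric(fp$gamma), beta = as.numeric(fp$beta), layer = j)
  })
}

# ---- data assembly ----

# Build (X, N, y) matrices for a set of examples. `expression` must already
# be standardized on the model's gene axis; fingerprints rows are compound
# ids. The straw variant substitutes its fixed random codes for the bits.
assembleBatch <- function(model, expressionStd, examples, fingerprints) {
  cfg <- model@config
  sid <- as.character(examples$sample_id)
  cid <- as.character(examples$compound_id)
  missS <- setdiff(unique(sid), rownames(expressionStd))
  if (length(missS)) stopf("examples reference unknown sample(s): %s", paste(head(missS, 3), collapse = ", "))
  bits <- if (cfg$variant == "straw") {
    missing <- setdiff(unique(cid), rownames(model@strawCodes))
    if (length(missing)) stopf("straw codes missing for compound(s): %s", paste(head(missing, 3), collapse = ", "))
    model@strawCodes[cid, , drop = FALSE]
  } else {
    missC <- setdiff(unique(cid), rownames(fingerprints))
    if (length(missC)) stopf("examples reference unknown compound(s): %s", paste(head(missC, 3), collapse = ", "))
    fingerprints[cid, , drop = FALSE]
  }
  X <- expressionStd[sid, , drop = FALSE]
  N <- cbind(bits, examples$concentration_um)
  y <- if (!is.null(examples$viability)) as.numeric(examples$viability)
  list(X = unname(X), N = unname(N), y = y)
}

#' Train a conditional viability model
#'
#' Minimizes mean-squared error between predicted and observed viability
#' with Adam, early-stopping on an internal validation split (a random
#' fraction of the training examples) and restoring the best weights.
#' Expression is standardized per gene with statistics frozen from the
#' supplied (training) samples only; the statistics are stored in the model
#' and re-applied at prediction time.
#'
#' @param config a [modelConfig()].
#' @param expression raw samples x genes matrix (rownames = sample ids)
#'   covering at least the training samples.
#' @param examples data.frame(sample_id, compound_id, concentration_um,
#'   viability).
#' @param fingerprints compounds x bits binary matrix (rownames = compound
#'   ids), e.g. from [morganFingerprints()].
#' @param hyper list: lr (1e-3), batchSize (256), maxEpochs (100),
#'   patience (10), valFraction (0.1), seed (config seed).
#' @return a trained [FilmModel-class].
#' @export
trainModel <- function(config, expression, examples, fingerprints,
                       hyper = list()) {
  hp <- utils::modifyList(list(lr = 1e-3, batchSize = 256L, maxEpochs = 100L,
                               patience = 10L, valFraction = 0.1,
                               seed = config$seed), hyper)
  if (nrow(examples) == 0L) stopf("empty training set")
  expression <- as.matrix(expression)
  expression <- expression[intersect(rownames(expression), unique(as.character(examples$sample_id))), ,
                           drop = FALSE]
  std <- standardizeExpression(expression)
  model <- buildModel(config, colnames(expression),
                      compoundIds = unique(as.character(examples$compound_id)))
  model@frozenStats <- std$stats
  ab <- assembleBatch(model, std$values, examples, fingerprints)

  set.seed(deriveSeed(hp$seed, "train"))
  n <- nrow(ab$X)
  nVal <- max(1L, floor(hp$valFraction * n))
  valIdx <- sample.int(n, nVal)
  trIdx <- setdiff(seq_len(n), valIdx)
  Xtr <- ab$X[trIdx, , drop = FALSE]; Ntr <- ab$N[trIdx, , drop = FALSE]; ytr <- ab$y[trIdx]
  Xva <- ab$X[valIdx, , drop = FALSE]; Nva <- ab$N[valIdx, , drop = FALSE]; yva <- ab$y[valIdx]

  flat <- flattenLeaves(model@params)
  paths <- leafPaths(flat)
  state <- adamInit(flat)
  bestVal <- Inf; bestFlat <- flat; bestBuffers <- model@params; wait <- 0L
  log <- data.frame()
  nb <- ceiling(length(trIdx) / hp$batchSize)
  for (epoch in seq_len(hp$maxEpochs)) {
    ord <- sample.int(nrow(Xtr))
    epochLoss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[(((b - 1L) * hp$batchSize + 1L):min(b * hp$batchSize, length(ord)))]
      if (length(idx) < 2L) next  # batch norm needs >= 2 rows
      fw <- nnForward(model, Xtr[idx, , drop = FALSE], Ntr[idx, , drop = FALSE], train = TRUE)
      model@params <- fw$p  # updated batch-norm buffers
      err <- fw$yhat - ytr[idx]
      loss <- mean(err^2)
      if (!is.finite(loss)) stopf("NaN/Inf training loss at epoch %d (lr too high?)", epoch)
      epochLoss <- epochLoss + loss * length(idx)
      bw <- nnBackward(model, fw$cache, 2 * err / length(idx))
      gflat <- extractFlat(bw$grads, paths)
      st <- adamStep(flat, gflat, state, hp$lr)
      flat <- st$flat; state <- st$state
      model@params <- assignFlat(model@params, flat, paths)
    }
    valPred <- nnForward(model, Xva, Nva, train = FALSE)$yhat
    valLoss <- mean((valPred - yva)^2)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = epochLoss / length(trIdx),
                                 val_loss = valLoss))
    if (valLoss < bestVal - 1e-7) {
      bestVal <- valLoss; bestFlat <- flat; bestBuffers <- model@params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }
  model@params <- assignFlat(bestBuffers, bestFlat)
  model@trainingLog <- log
  model@trained <- TRUE
  model
}

#' Predict viability for expression/compound inputs
#'
#' Applies the model's frozen per-gene standardization to the raw expression
#' input, then runs the network in inference mode (deterministic: batch-norm
#' running statistics, no dropout). For an ensemble, member predictions are
#' averaged.
#'
#' @param model a trained [FilmModel-class] or [FilmEnsemble-class].
#' @param expression raw expression: a named vector on the model's gene axis
#'   or a samples x genes matrix.
#' @param compound a 513-length compound vector (from [featurizeCompound()])
#'   or an n x 513 matrix row-aligned with `expression`. For the straw
#'   variant pass `examples`/`fingerprints` instead so codes can be looked up.
#' @param compoundId compound identifier (needed by the straw variant).
#' @return numeric vector of predicted viabilities.
#' @export
predictViability <- function(model, expression, compound, compoundId = NULL) {
  if (is(model, "FilmEnsemble")) {
    preds <- vapply(model@models, predictViability, numeric(
      if (is.matrix(expression)) nrow(expression) else 1L),
      expression, compound, compoundId)
    return(if (is.matrix(preds)) rowMeans(preds) else mean(preds))
  }
  stopifnot(is(model, "FilmModel"))
  X <- if (is.matrix(expression)) expression else matrix(expression, nrow = 1L,
                                                         dimnames = list(NULL, names(expression)))
  if (ncol(X) != length(model@geneIds)) {
    stopf("expression has %d genes; model expects %d", ncol(X), length(model@geneIds))
  }
  N <- if (is.matrix(compound)) compound else matrix(as.numeric(compound), nrow = 1L)
  if (nrow(N) == 1L && nrow(X) > 1L) N <- N[rep(1L, nrow(X)), , drop = FALSE]
  if (ncol(N) != model@config$nCompoundFeatures) {
    stopf("compound vector length %d != %d", ncol(N), model@config$nCompoundFeatures)
  }
  if (model@config$variant == "straw") {
    cid <- compoundId %||% attr(compound, "compound_id")
    if (is.null(cid)) stopf("straw variant needs compoundId to look up its code")
    if (!cid %in% rownames(model@strawCodes)) stopf("no straw code for compound '%s'", cid)
    N[, -ncol(N)] <- matrix(model@strawCodes[cid, ], nrow(N), ncol(N) - 1L, byrow = TRUE)
  }
  Xs <- standardizeExpression(X, stats = model@frozenStats)$values
  nnForward(model, unname(Xs), unname(N), train = FALSE)$yhat
}

# Batch prediction over an examples table (internal workhorse).
predictExamples <- function(model, expression, examples, fingerprints) {
  if (is(model, "FilmEnsemble")) {
    preds <- vapply(model@models, predictExamples, numeric(nrow(examples)),
                    expression, examples, fingerprints)
    return(if (is.matrix(preds)) rowMeans(preds) else mean(preds))
  }
  Xs <- standardizeExpression(as.matrix(expression)[, model@geneIds, drop = FALSE],
                              stats = model@frozenStats)$values
  ab <- assembleBatch(model, Xs, examples, fingerprints)
  nnForward(model, ab$X, ab$N, train = FALSE)$yhat
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot.
#'
#' @param observed,predicted numeric vectors of equal length; `observed`
#'   must have positive variance.
#' @return scalar R^2.
#' @export
r2Score <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  if (popSd(observed) == 0) stopf("observed values have zero variance; R^2 undefined")
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' Coefficient of determination on held-out examples
#'
#' R^2 = 1 - SS_res / SS_tot against the held-out viability labels.
#'
#' @param model trained [FilmModel-class] or [FilmEnsemble-class].
#' @param expression raw samples x genes matrix.
#' @param examples held-out examples (>= 2, with label variance > 0).
#' @param fingerprints compound fingerprint matrix.
#' @return scalar R^2.
#' @export
evaluateR2 <- function(model, expression, examples, fingerprints) {
  if (nrow(examples) < 2L) stopf("need >= 2 held-out examples")
  y <- as.numeric(examples$viability)
  pred <- predictExamples(model, expression, examples, fingerprints)
  r2Score(y, pred)
}

#' Grouped cross-validation of a model configuration
#'
#' Trains one model per fold, each never seeing its test fold's cell lines,
#' and reports per-fold held-out R^2. The resulting ensemble predicts with
#' the arithmetic mean of its members.
#'
#' @param config a [modelConfig()].
#' @param expression raw samples x genes matrix.
#' @param examples full examples table.
#' @param fingerprints fingerprint matrix.
#' @param splits named fold vector from [makeCvSplits()].
#' @param hyper training hyperparameters, see [trainModel()].
#' @return a [FilmEnsemble-class]; fold summary via `foldR2` slot
#'   (mean +/- standard error printed by `show`).
#' @export
crossValidate <- function(config, expression, examples, fingerprints, splits, hyper = list()) {
  folds <- sort(unique(splits))
  sid <- as.character(examples$sample_id)
  models <- list(); r2 <- numeric(0)
  for (f in folds) {
    testSamples <- names(splits)[splits == f]
    trainEx <- examples[!(sid %in% testSamples), , drop = FALSE]
    testEx <- examples[sid %in% testSamples, , drop = FALSE]
    cfgF <- config; cfgF$seed <- deriveSeed(config$seed, paste0("fold", f))
    m <- trainModel(cfgF, expression[!(rownames(expression) %in% testSamples), , drop = FALSE],
                    trainEx, fingerprints, hyper)
    models[[length(models) + 1L]] <- m
    r2 <- c(r2, evaluateR2(m, expression, testEx, fingerprints))
  }
  new("FilmEnsemble", models = models, foldR2 = r2, foldIds = as.integer(folds))
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding config, weights, frozen expression
#' statistics and the gene-id list; config and gene list round-trip
#' bit-exactly.
#'
#' @param model a [FilmModel-class] or [FilmEnsemble-class].
#' @param path file path.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(format = "filmSens-checkpoint-1", object = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "filmSens-checkpoint-1")) stopf("not a filmSens checkpoint: %s", path)
  x$object
}
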