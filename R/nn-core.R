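# Minimal dense-network engine: linear/ReLU/batch-norm/dropout blocks with
# explicit forward/backward passes and an Adam optimizer. Written against
# base R matrix ops (BLAS); supports gradients w.r.t. inputs in inference
# mode, which integrated-gradients attribution requires.

.bnEps <- 1e-5
.bnMomentum <- 0.1  # running = (1 - mom) * running + mom * batch

heInit <- function(fanIn, fanOut) {
  matrix(rnorm(fanIn * fanOut, sd = sqrt(2 / fanIn)), fanIn, fanOut)
}

# A block = linear -> ReLU -> batch norm -> dropout. `act`/`bn`/`drop` can be
# disabled (the output head is a bare linear layer).
makeBlock <- function(fanIn, fanOut, drop = 0, act = TRUE, bn = TRUE) {
  list(W = heInit(fanIn, fanOut), b = rep(0, fanOut),
       bnGamma = if (bn) rep(1, fanOut), bnBeta = if (bn) rep(0, fanOut),
       rm = if (bn) rep(0, fanOut), rv = if (bn) rep(1, fanOut),
       drop = drop, act = act, bn = bn)
}

# column-recycling helpers: much faster than sweep() in the hot loop
.addCols <- function(x, v) x + rep(v, each = nrow(x))
.mulCols <- function(x, v) x * rep(v, each = nrow(x))

blockForward <- function(blk, x, train) {
  z <- .addCols(x %*% blk$W, blk$b)
  a <- if (blk$act) z * (z > 0) else z
  cache <- list(x = x, z = z)
  if (blk$bn) {
    if (train) {
      mu <- colMeans(a)
      va <- colMeans(a^2) - mu^2
      blk$rm <- (1 - .bnMomentum) * blk$rm + .bnMomentum * mu
      blk$rv <- (1 - .bnMomentum) * blk$rv + .bnMomentum * va
    } else {
      mu <- blk$rm; va <- blk$rv
    }
    invstd <- 1 / sqrt(va + .bnEps)
    xhat <- .mulCols(.addCols(a, -mu), invstd)
    out <- .addCols(.mulCols(xhat, blk$bnGamma), blk$bnBeta)
    cache$xhat <- xhat; cache$invstd <- invstd
  } else {
    out <- a
  }
  if (train && blk$drop > 0) {
    mask <- (matrix(runif(length(out)), nrow(out)) >= blk$drop) / (1 - blk$drop)
    out <- out * mask
    cache$mask <- mask
  }
  list(out = out, cache = cache, blk = blk)
}

# Training-mode backward. Returns input gradient and parameter gradients.
blockBackward <- function(blk, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  grads <- list()
  if (blk$bn) {
    xhat <- cache$xhat
    grads$bnGamma <- colSums(dout * xhat)
    grads$bnBeta <- colSums(dout)
    dxhat <- .mulCols(dout, blk$bnGamma)
    m <- nrow(dout)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    da <- .mulCols(m * dxhat -
                     rep(s1, each = m) -
                     xhat * rep(s2, each = m),
                   cache$invstd) / m
  } else {
    da <- dout
  }
  dz <- if (blk$act) da * (cache$z > 0) else da
  grads$W <- crossprod(cache$x, dz)
  grads$b <- colSums(dz)
  list(dx = dz %*% t(blk$W), grads = grads)
}

# Inference-mode backward: batch norm is a frozen affine map; dropout is
# identity; only the input gradient is computed (used by integrated
# gradients).
blockEvalBackward <- function(blk, cache, dout) {
  da <- if (blk$bn) {
    .mulCols(dout, blk$bnGamma / sqrt(blk$rv + .bnEps))
  } else dout
  dz <- if (blk$act) da * (cache$z > 0) else da
  dz %*% t(blk$W)
}

chainForward <- function(chain, x, train) {
  caches <- vector("list", length(chain))
  for (i in seq_along(chain)) {
    r <- blockForward(chain[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
    chain[[i]] <- r$blk
  }
  list(out = x, caches = caches, chain = chain)
}

chainBackward <- function(chain, caches, dout, inputGrad = TRUE) {
  grads <- vector("list", length(chain))
  names(grads) <- names(chain)
  for (i in rev(seq_along(chain))) {
    r <- blockBackward(chain[[i]], caches[[i]], dout)
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  list(dx = if (inputGrad) dout, grads = grads)
}

chainEvalBackward <- function(chain, caches, dout) {
  for (i in rev(seq_along(chain))) {
    dout <- blockEvalBackward(chain[[i]], caches[[i]], dout)
  }
  dout
}

# ---- nested parameter utilities ----

# Flatten the trainable leaves of a nested parameter list into a flat named
# list; paths use "\r" so layer names can contain dots.
flattenLeaves <- function(x, prefix = "") {
  if (is.list(x) && !is.null(names(x)) &&
      !all(names(x) %in% c("W", "b", "bnGamma", "bnBeta", "rm", "rv", "drop", "act", "bn"))) {
    out <- list()
    for (nm in names(x)) {
      out <- c(out, flattenLeaves(x[[nm]], paste0(prefix, nm, "\r")))
    }
    return(out)
  }
  # a block or bare linear: keep trainable leaves only
  out <- list()
  for (nm in intersect(names(x), c("W", "b", "bnGamma", "bnBeta"))) {
    if (!is.null(x[[nm]])) out[[paste0(prefix, nm)]] <- x[[nm]]
  }
  out
}

# Precompute the list-paths of the trainable leaves so the hot loop can
# read/write them without re-parsing key strings.
leafPaths <- function(flat) {
  lapply(names(flat), function(key) strsplit(key, "\r", fixed = TRUE)[[1]])
}

assignFlat <- function(params, flat, paths = leafPaths(flat)) {
  for (i in seq_along(flat)) params[[paths[[i]]]] <- flat[[i]]
  params
}

# Extract the same leaves from an identically shaped nested list (used to
# flatten per-step gradients without rebuilding key strings).
extractFlat <- function(nested, paths) {
  out <- lapply(paths, function(p) nested[[p]])
  names(out) <- vapply(paths, paste, "", collapse = "\r")
  out
}

adamInit <- function(flat) {
  list(t = 0,
       m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0))
}

adamStep <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  stopifnot(length(grads) == length(flat))
  for (k in seq_along(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    flat[[k]] <- flat[[k]] - lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

countLeaves <- function(params) sum(vapply(flattenLeaves(params), length, 1L))
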