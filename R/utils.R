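#' @keywords internal
"_PACKAGE"

#' @importFrom methods new is validObject slot
#' @importFrom stats rnorm runif sd cor optim nls coef vcov pt qt kmeans
#'   wilcox.test p.adjust phyper predict ks.test
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

# Derive a stage-specific 32-bit seed from a global seed, so every random
# operation in a pipeline is reproducible yet decorrelated across stages.
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  bytes <- utf8ToInt(paste0(stage, ":", format(seed, scientific = FALSE)))
  acc <- as.double(seed) %% 2147483647
  for (b in bytes) acc <- (acc * 31 + b) %% 2147483647
  as.integer(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vmessage <- function(..., verbose = getOption("filmSens.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[filmSens] ", ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Population standard deviation (divisor N), used for all frozen feature
# statistics so that stored stats are exactly reproducible.
popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

colPopSd <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(m^2) - mu^2)
}

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
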