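# Morgan fingerprinting through the rdkit toolkit (invoked via the `python`
# interpreter on PATH); results are memoised per (smiles, n_bits, radius).

.fpCache <- new.env(parent = emptyenv())

pythonBinary <- function() {
  bin <- getOption("filmSens.python", Sys.which("python"))
  if (!nzchar(bin)) stopf("no `python` interpreter found on PATH (needed for Morgan fingerprints)")
  bin
}

# Low-level batch call: character vector of single-structure SMILES ->
# list of integer vectors of 0-based on-bit indices (NULL = unparseable).
.morganOnBits <- function(smiles, nBits = 512L, radius = 2L) {
  keys <- paste0(nBits, ":", radius, ":", smiles)
  need <- !vapply(keys, exists, logical(1), envir = .fpCache)
  if (any(need)) {
    script <- system.file("python", "morgan_fp.py", package = "filmSens")
    stopifnot(nzchar(script))
    req <- jsonlite::toJSON(
      list(smiles = I(unique(smiles[need])), n_bits = nBits, radius = radius),
      auto_unbox = TRUE
    )
    infile <- tempfile(fileext = ".json"); on.exit(unlink(infile), add = TRUE)
    writeLines(req, infile)
    res <- system2(pythonBinary(), script, stdout = TRUE, stderr = FALSE, stdin = infile)
    bits <- jsonlite::fromJSON(paste(res, collapse = ""), simplifyVector = FALSE)
    usmi <- unique(smiles[need])
    for (i in seq_along(usmi)) {
      v <- bits[[i]]
      assign(paste0(nBits, ":", radius, ":", usmi[i]),
             if (is.null(v)) NULL else as.integer(unlist(v)),
             envir = .fpCache)
    }
  }
  lapply(keys, function(k) .fpCache[[k]])
}

#' Morgan (ECFP-style) circular fingerprints for a set of SMILES
#'
#' Folded binary Morgan fingerprints computed with the rdkit toolkit.
#' Compound *pairs* may be encoded as two SMILES joined by `"|"`; the pair
#' fingerprint is the bitwise OR of the two member fingerprints.
#'
#' @param smiles character vector of SMILES (optionally `"A|B"` pairs).
#' @param nBits fingerprint length after folding (default 512).
#' @param radius Morgan radius (default 2, i.e. ECFP4-equivalent).
#' @param ids optional row names for the returned matrix.
#' @return binary 0/1 integer matrix `length(smiles)` x `nBits`.
#' @export
morganFingerprints <- function(smiles, nBits = 512L, radius = 2L, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  nBits <- as.integer(nBits); radius <- as.integer(radius)
  parts <- strsplit(smiles, "|", fixed = TRUE)
  flat <- unlist(parts)
  onbits <- .morganOnBits(flat, nBits, radius)
  out <- matrix(0L, nrow = length(smiles), ncol = nBits)
  k <- 0L
  for (i in seq_along(parts)) {
    for (j in seq_along(parts[[i]])) {
      k <- k + 1L
      ob <- onbits[[k]]
      if (is.null(ob)) {
        id <- if (!is.null(ids)) ids[i] else smiles[i]
        stopf("unparseable SMILES for compound '%s': %s", id, parts[[i]][j])
      }
      out[i, ob + 1L] <- 1L
    }
  }
  if (!is.null(ids)) rownames(out) <- ids
  out
}
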