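# Dose-response machinery: the default concentration grid, the QC cascade,
# log-logistic fitting with 4 -> 3 -> 2 parameter fallback, and derived
# pharmacodynamics (IC50, AUC, ED50 comparisons).

#' Default 32-point concentration grid
#'
#' 32 log10-uniformly spaced concentrations from 1e-3 to 300 micromolar
#' inclusive — the screening grid used for in-silico dose-response curves.
#'
#' @return sorted numeric vector of length 32 (uM).
#' @export
defaultGrid <- function() {
  10^seq(log10(1e-3), log10(300), length.out = 32L)
}

#' Predict an in-silico dose-response curve
#'
#' One ensemble-averaged viability prediction per grid concentration for a
#' single cell line x compound pair.
#'
#' @param model trained [FilmModel-class] or [FilmEnsemble-class].
#' @param expression raw expression vector (or 1-row matrix) on the model's
#'   gene axis.
#' @param fingerprint 512-length bit vector for the compound (ignored except
#'   for its id by the straw variant).
#' @param compoundId compound identifier.
#' @param grid concentrations in uM (default [defaultGrid()]).
#' @return data.frame(concentration_um, viability).
#' @export
predictCurve <- function(model, expression, fingerprint, compoundId,
                         grid = defaultGrid()) {
  x <- if (is.matrix(expression)) expression[1, ] else expression
  X <- matrix(rep(x, each = length(grid)), nrow = length(grid))
  N <- cbind(matrix(as.numeric(fingerprint), length(grid), length(fingerprint), byrow = TRUE),
             grid)
  v <- predictViability(model, X, N, compoundId = compoundId)
  data.frame(concentration_um = grid, viability = v)
}

#' Quality-control cascade for a dose-response curve
#'
#' Recursively checks the four largest concentrations' viabilities against
#' the fifth largest: if any shows an increase of at least `relIncrease`
#' (relative by default, i.e. v >= (1 + relIncrease) * v_ref; set
#' `absolute = TRUE` for v >= v_ref + relIncrease), the single largest point
#' is dropped and the rule re-applied to the remaining points. After the
#' loop the curve is rejected when fewer than `minPoints` remain or when the
#' minimum kept viability exceeds `minViabilityGate` (no real response).
#'
#' @param points data.frame(concentration_um, viability) sorted by
#'   concentration, at least 5 points.
#' @param relIncrease hook threshold (default 0.20).
#' @param minPoints minimum points required for fitting (default 16).
#' @param minViabilityGate maximum allowed minimum viability (default 0.4).
#' @param absolute use the absolute reading of the increase rule.
#' @return list(points = kept data.frame, qcStatus = "pass" |
#'   "rejected_min_points" | "rejected_high_min_viability", nDropped).
#' @export
qcCurve <- function(points, relIncrease = 0.20, minPoints = 16L,
                    minViabilityGate = 0.4, absolute = FALSE) {
  stopifnot(is.data.frame(points), nrow(points) >= 5L,
            all(c("concentration_um", "viability") %in% names(points)))
  pts <- points[order(points$concentration_um), , drop = FALSE]
  nDropped <- 0L
  repeat {
    n <- nrow(pts)
    if (n < 5L) break
    vTop4 <- pts$viability[(n - 3L):n]
    vRef <- pts$viability[n - 4L]
    hook <- if (absolute) any(vTop4 >= vRef + relIncrease)
            else any(vTop4 >= (1 + relIncrease) * vRef)
    if (!hook) break
    pts <- pts[-n, , drop = FALSE]
    nDropped <- nDropped + 1L
  }
  status <- if (nrow(pts) < minPoints) "rejected_min_points"
            else if (min(pts$viability) > minViabilityGate) "rejected_high_min_viability"
            else "pass"
  list(points = pts, qcStatus = status, nDropped = nDropped)
}

# The 4-parameter log-logistic curve used throughout:
# v(x) = c + (d - c) / (1 + exp(b * (ln x - ln e)))
llFun <- function(x, b, c, d, e) c + (d - c) / (1 + exp(b * (log(x) - log(e))))

# Least-squares fit of the log-logistic family with nPar free parameters
# (4: b,c,d,e; 3: c = 0; 2: c = 0, d = 1). Multi-start on e across the
# concentration range; polished with Gauss-Newton (nls/port). Failure =
# non-convergence, non-finite parameters, or a parameter at its bound.
.fitLL <- function(conc, viab, nPar) {
  lo <- c(b = 0.05, c = -0.5, d = 0.2, e = min(conc) / 100)
  hi <- c(b = 30, c = 0.95, d = 2.5, e = max(conc) * 100)
  free <- switch(as.character(nPar),
                 "4" = c("b", "c", "d", "e"), "3" = c("b", "d", "e"), "2" = c("b", "e"))
  fixed <- c(c = 0, d = 1)
  obj <- function(p) {
    q <- c(p, fixed[setdiff(names(fixed), names(p))])
    r <- viab - llFun(conc, q["b"], q["c"], q["d"], q["e"])
    sum(r^2)
  }
  starts <- expand.grid(b = c(0.5, 1, 2, 5),
                        e = 10^seq(log10(min(conc)), log10(max(conc)), length.out = 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(b = starts$b[i],
            if ("c" %in% free) c(c = max(lo["c"] + 1e-3, min(viab))),
            if ("d" %in% free) c(d = min(hi["d"] - 1e-3, max(max(viab), 0.3))),
            e = starts$e[i])
    names(p0) <- free
    opt <- try(optim(p0, obj, method = "L-BFGS-B",
                     lower = lo[free], upper = hi[free],
                     control = list(factr = 1e4, maxit = 500)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !all(is.finite(best$par))) return(NULL)
  # Gauss-Newton polish for tight convergence + covariance of free params
  df <- data.frame(x = conc, y = viab)
  form <- switch(as.character(nPar),
                 "4" = y ~ c + (d - c) / (1 + exp(b * (log(x) - log(e)))),
                 "3" = y ~ d / (1 + exp(b * (log(x) - log(e)))),
                 "2" = y ~ 1 / (1 + exp(b * (log(x) - log(e)))))
  fit <- try(suppressWarnings(
    nls(form, data = df, start = as.list(best$par), algorithm = "port",
        lower = lo[free], upper = hi[free],
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE))), silent = TRUE)
  if (inherits(fit, "try-error")) {
    par <- best$par; covm <- NULL; conv <- TRUE
  } else {
    par <- coef(fit)
    conv <- fit$convInfo$isConv || fit$convInfo$stopMessage %in%
      c("both X-convergence and relative convergence (5)",
        "X-convergence (3)", "relative convergence (4)",
        "singular convergence (7)")
    if (obj(par) > best$value + 1e-10) { par <- best$par; conv <- TRUE }
    covm <- try(suppressWarnings(vcov(fit)), silent = TRUE)
    if (inherits(covm, "try-error") || !all(is.finite(covm))) covm <- NULL
  }
  if (!all(is.finite(par)) || !conv) return(NULL)
  atBound <- any(par <= lo[free] + 1e-9) || any(par >= hi[free] - 1e-9)
  if (atBound) return(NULL)
  full <- c(par, fixed[setdiff(names(fixed), names(par))])[c("b", "c", "d", "e")]
  list(par = full, free = free, cov = covm, rss = obj(par),
       df = length(conc) - length(free))
}

#' Fit a log-logistic dose-response model with parameter-count fallback
#'
#' Fits \eqn{v(x) = c + (d - c)/(1 + \exp(b(\ln x - \ln e)))}. The
#' 4-parameter family is tried first; on optimizer failure a 3-parameter fit
#' (c = 0) and then a 2-parameter fit (c = 0, d = 1) are attempted. A
#' successful fit whose inflection e falls outside [1e-3, 300] uM is marked
#' `filtered_ec50_range`; if every family fails the status is `fit_failed`.
#'
#' @param points data.frame(concentration_um, viability) — normally the kept
#'   points returned by [qcCurve()].
#' @param fallback try the reduced-parameter families on failure.
#' @param ec50Range inflection filter bounds in uM (default `c(1e-3, 300)`).
#' @return a [DoseResponseFit-class].
#' @export
fitLogLogistic <- function(points, fallback = TRUE, ec50Range = c(1e-3, 300)) {
  stopifnot(is.data.frame(points), nrow(points) >= 3L)
  conc <- points$concentration_um
  viab <- points$viability
  fit <- NULL; used <- NA_integer_
  for (np in if (fallback) c(4L, 3L, 2L) else 4L) {
    fit <- .fitLL(conc, viab, np)
    if (!is.null(fit)) { used <- np; break }
  }
  if (is.null(fit)) {
    return(new("DoseResponseFit", b = NA_real_, cLower = NA_real_,
               dUpper = NA_real_, eMid = NA_real_, nParams = NA_integer_,
               pointsUsed = nrow(points), qcStatus = "fit_failed",
               covariance = NULL, residualDf = NA_real_, points = points))
  }
  status <- if (fit$par["e"] < ec50Range[1] || fit$par["e"] > ec50Range[2]) {
    "filtered_ec50_range"
  } else "pass"
  new("DoseResponseFit", b = unname(fit$par["b"]), cLower = unname(fit$par["c"]),
      dUpper = unname(fit$par["d"]), eMid = unname(fit$par["e"]),
      nParams = used, pointsUsed = nrow(points), qcStatus = status,
      covariance = if (!is.null(fit$cov)) as.matrix(fit$cov),
      residualDf = fit$df, points = points)
}

#' Absolute IC50 of a fitted dose-response curve
#'
#' The concentration at which the fitted curve crosses viability 0.5 in
#' absolute terms (not the midpoint between asymptotes). Returns NA when the
#' curve never crosses 0.5, i.e. when 0.5 is not strictly between the lower
#' and upper asymptotes.
#'
#' @param fit a passing [DoseResponseFit-class].
#' @return positive IC50 in uM, or NA.
#' @export
deriveIc50 <- function(fit) {
  b <- fit@b; cl <- fit@cLower; d <- fit@dUpper; e <- fit@eMid
  if (!all(is.finite(c(b, cl, d, e)))) return(NA_real_)
  ratio <- (d - 0.5) / (0.5 - cl)
  if (!is.finite(ratio) || ratio <= 0) return(NA_real_)
  exp(log(e) + log(ratio) / b)
}

#' Normalized area under a dose-response curve
#'
#' Trapezoidal integral of viability over log10(concentration), divided by
#' the log10 range, so that a flat curve at viability 1 has AUC exactly 1
#' and a flat curve at 0 has AUC 0.
#'
#' @param points data.frame(concentration_um, viability) with >= 2 points,
#'   or a passing [DoseResponseFit-class] (evaluated on `grid`).
#' @param grid evaluation grid when `points` is a fit.
#' @return scalar AUC.
#' @export
deriveAuc <- function(points, grid = defaultGrid()) {
  if (is(points, "DoseResponseFit")) {
    points <- data.frame(concentration_um = grid,
                         viability = llFun(grid, points@b, points@cLower,
                                           points@dUpper, points@eMid))
  }
  stopifnot(nrow(points) >= 2L)
  o <- order(points$concentration_um)
  lx <- log10(points$concentration_um[o])
  v <- points$viability[o]
  sum(diff(lx) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) / (max(lx) - min(lx))
}

#' Min-max scale AUCs per compound across a cohort
#'
#' Rescales each compound's AUCs to [0, 1] using that compound's minimum and
#' maximum across all samples, the normalization used before responder
#' thresholding.
#'
#' @param auc numeric vector of AUCs.
#' @param compoundId parallel compound identifiers.
#' @return numeric vector of scaled AUCs; NA for compounds observed in a
#'   single sample (scaling undefined).
#' @export
scaleAuc <- function(auc, compoundId) {
  stopifnot(length(auc) == length(compoundId))
  out <- rep(NA_real_, length(auc))
  for (cid in unique(compoundId)) {
    i <- which(compoundId == cid)
    if (length(i) < 2L) next
    rng <- range(auc[i])
    out[i] <- if (diff(rng) == 0) 0.5 else (auc[i] - rng[1]) / diff(rng)
  }
  out
}

#' Compare the median effective dose (ED50) of two fits
#'
#' Relative potency as the ratio of inflection concentrations e_a / e_b,
#' with a delta-method standard error on the log scale and a two-sided
#' t-test of log-ratio = 0 (df = combined residual df). Requires fit
#' covariances; without them only the ratio is returned.
#'
#' @param fitA,fitB passing [DoseResponseFit-class] objects.
#' @return list(ratio, se, tValue, pValue, df); se/t/p NA without covariance.
#' @export
compareEd50 <- function(fitA, fitB) {
  stopifnot(is(fitA, "DoseResponseFit"), is(fitB, "DoseResponseFit"))
  ratio <- fitA@eMid / fitB@eMid
  varLog <- function(fit) {
    if (is.null(fit@covariance)) return(NA_real_)
    idx <- which(colnames(fit@covariance) == "e")
    if (!length(idx)) return(NA_real_)
    fit@covariance[idx, idx] / fit@eMid^2  # delta method: var(log e) = var(e)/e^2
  }
  va <- varLog(fitA); vb <- varLog(fitB)
  if (!is.finite(va) || !is.finite(vb)) {
    return(list(ratio = ratio, se = NA_real_, tValue = NA_real_,
                pValue = NA_real_, df = NA_real_))
  }
  seLog <- sqrt(va + vb)
  df <- fitA@residualDf + fitB@residualDf
  tv <- if (seLog == 0) 0 else (log(fitA@eMid) - log(fitB@eMid)) / seLog
  list(ratio = ratio, se = seLog * ratio, tValue = tv,
       pValue = 2 * pt(-abs(tv), df), df = df)
}

#' Responder classification from a scaled AUC
#'
#' A sample is called a responder when its per-compound min-max scaled AUC is
#' at or below the decision threshold (lower predicted AUC = more sensitive);
#' the tie at the threshold is inclusive.
#'
#' @param aucScaled scaled AUC values in [0, 1].
#' @param threshold decision threshold in [0, 1].
#' @return character vector "responder"/"non_responder".
#' @export
classifyResponse <- function(aucScaled, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  stopifnot(all(aucScaled >= 0 & aucScaled <= 1, na.rm = TRUE))
  ifelse(aucScaled <= threshold, "responder", "non_responder")
}

#' Predict, QC and fit dose-response curves for many pairs
#'
#' Pipeline convenience: for every cell line x compound pair, predict the
#' curve on the grid, run the QC cascade, fit the log-logistic model, and
#' derive IC50 and AUC.
#'
#' @param model trained model or ensemble.
#' @param expression raw samples x genes matrix.
#' @param compounds compound table (compound_id, smiles).
#' @param fingerprints fingerprint matrix (rows = compound ids).
#' @param grid concentration grid.
#' @param ... QC arguments passed to [qcCurve()].
#' @return list(table = one row per pair with qc_status, n_params, b, c, d,
#'   e, ic50_um, auc; fits = named list of [DoseResponseFit-class]).
#' @export
fitCohortCurves <- function(model, expression, compounds, fingerprints,
                            grid = defaultGrid(), ...) {
  samples <- rownames(expression)
  rows <- list(); fits <- list()
  for (s in samples) {
    # predict all compounds x grid in one batch per sample
    nC <- nrow(compounds)
    ex <- data.frame(sample_id = s,
                     compound_id = rep(compounds$compound_id, each = length(grid)),
                     concentration_um = rep(grid, nC))
    pred <- predictExamples(model, expression, ex, fingerprints)
    for (i in seq_len(nC)) {
      cid <- compounds$compound_id[i]
      pts <- data.frame(concentration_um = grid,
                        viability = pred[ex$compound_id == cid])
      qc <- qcCurve(pts, ...)
      if (qc$qcStatus != "pass") {
        fit <- new("DoseResponseFit", b = NA_real_, cLower = NA_real_,
                   dUpper = NA_real_, eMid = NA_real_, nParams = NA_integer_,
                   pointsUsed = nrow(qc$points), qcStatus = qc$qcStatus,
                   covariance = NULL, residualDf = NA_real_, points = qc$points)
      } else {
        fit <- fitLogLogistic(qc$points)
      }
      key <- paste(s, cid, sep = "::")
      fits[[key]] <- fit
      rows[[key]] <- data.frame(
        sample_id = s, compound_id = cid, qc_status = fit@qcStatus,
        n_params = fit@nParams, b = fit@b, c = fit@cLower, d = fit@dUpper,
        e = fit@eMid,
        ic50_um = if (fit@qcStatus == "pass") deriveIc50(fit) else NA_real_,
        auc = deriveAuc(pts))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Export a cohort fit table as CSV
#' @param fitTable the `table` element of [fitCohortCurves()].
#' @param path output path.
#' @export
writeFits <- function(fitTable, path) {
  write.csv(fitTable, path, row.names = FALSE)
  invisible(path)
}
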