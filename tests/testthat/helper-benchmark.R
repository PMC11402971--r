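# The reference benchmark suite, trained once and cached for all acceptance
# tests. Two protocols share one seeded cohort: the five-variant comparison
# trains on the 16-point concentration subgrid; dose-response/attribution
# analyses use a film model trained on the full 32-point grid.

benchmarkSuite <- function() {
  memo("benchmarkSuite", {
    cohort <- generateCohort(benchmarkSyntheticConfig())
    expr <- cohortExpression(cohort)
    viab <- cohortViability(cohort)
    cmp <- cohortCompounds(cohort)
    fp <- filmSens:::compoundFingerprints(cmp)
    ho <- benchmarkHeldout()
    teEx <- viab[viab$sample_id %in% ho, , drop = FALSE]

    variants <- c("film", "scale", "shift", "concatenation", "straw")
    fits <- lapply(variants, function(v)
      trainBenchmarkModel(cohort, v, seed = 11L, fingerprints = fp))
    names(fits) <- variants
    r2 <- vapply(fits, `[[`, 0, "heldoutR2")

    # pipeline model: film on the full grid
    fullFilm <- trainBenchmarkModel(cohort, "film", seed = 11L,
                                    fingerprints = fp,
                                    concentrations = "full")

    # label-permutation control (subgrid protocol)
    trEx <- viab[!viab$sample_id %in% ho &
                   viab$concentration_um %in% benchmarkSubgrid(), , drop = FALSE]
    set.seed(filmSens:::deriveSeed(7L, "label-permutation"))
    permEx <- trEx
    permEx$viability <- sample(permEx$viability)
    mPerm <- trainModel(benchmarkModelConfig("film", seed = 51L),
                        expr[!rownames(expr) %in% ho, , drop = FALSE],
                        permEx, fp, benchmarkHyper())

    # dose-response fits + attribution on 24 evaluation lines
    evalLines <- c(sprintf("CL%02d", 1:16), ho)
    fitRes <- fitCohortCurves(fullFilm$model, expr[evalLines, , drop = FALSE], cmp, fp)
    tab <- fitRes$table
    tab$true_ic50 <- 10^cohort@groundTruth$logIc50[cbind(tab$sample_id, tab$compound_id)]

    raw <- attributeAtIc50(fullFilm$model, expr, tab, fp)
    adj <- adjustAttributions(raw)

    sndRand <- soundnessRandomInit(fullFilm$model, expr[evalLines, , drop = FALSE],
                                   tab, fp, raw, seed = 99L)
    permAttr <- attributeAtIc50(mPerm, expr[evalLines, , drop = FALSE], tab, fp)
    sndPerm <- filmSens:::.soundnessReport(raw, permAttr)

    list(cohort = cohort, expr = expr, viab = viab, cmp = cmp, fp = fp,
         ho = ho, teEx = teEx, r2 = r2, models = lapply(fits, `[[`, "model"),
         fullFilm = fullFilm$model, fullFilmR2 = fullFilm$heldoutR2,
         mPerm = mPerm, fitTable = tab, raw = raw, adj = adj,
         sndRand = sndRand, sndPerm = sndPerm, evalLines = evalLines)
  })
}

# sensitivity window: true IC50 within the central two decades of the grid
sensitiveMask <- function(trueIc50) {
  ctr <- mean(range(log10(defaultGrid())))
  abs(log10(trueIc50) - ctr) <= 1
}
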