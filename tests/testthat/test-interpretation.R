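# Statistical kernels (AMI, rank-sum, BH, hypergeometric), clustering, and
# interaction-graph analysis.

test_that("AMI is 1 for identical labelings and ~0 for independent ones", {
  lab <- rep(letters[1:4], each = 10)
  expect_equal(adjustedMutualInfo(lab, lab), 1)
  perm <- setNames(letters[4:1], letters[1:4])
  expect_equal(adjustedMutualInfo(lab, perm[lab]), 1)  # relabeling invariance
  set.seed(8)
  a <- sample(letters[1:5], 500, replace = TRUE)
  b <- sample(letters[1:5], 500, replace = TRUE)
  expect_lt(abs(adjustedMutualInfo(a, b)), 0.05)
})

test_that("AMI is symmetric and bounded above by 1", {
  set.seed(3)
  for (i in 1:8) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjustedMutualInfo(a, b), adjustedMutualInfo(b, a))
    expect_lte(adjustedMutualInfo(a, b), 1)
  }
})

test_that("AMI agrees with an independent reference implementation", {
  skip_if(Sys.which("python") == "", "no python available")
  set.seed(12)
  cases <- lapply(1:4, function(i) list(a = sample(1:4, 40, replace = TRUE),
                                        b = sample(1:3, 40, replace = TRUE)))
  inp <- tempfile(fileext = ".json")
  jsonlite::write_json(cases, inp, auto_unbox = FALSE)
  script <- paste(
    "import json,sys",
    "from sklearn.metrics import adjusted_mutual_info_score as ami",
    sprintf("cases = json.load(open(%s))", deparse(inp)),
    "print(json.dumps([ami(c['a'], c['b']) for c in cases]))",
    sep = "\n")
  ref <- jsonlite::fromJSON(system2("python", c("-c", shQuote(script)), stdout = TRUE))
  ours <- vapply(cases, function(c) adjustedMutualInfo(c$a, c$b), numeric(1))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("rank-sum p-values match exact enumeration on the tiny case", {
  # in-class {3,4} vs out-class {1,2}: 1 of C(4,2)=6 assignments is as
  # extreme in each direction -> two-sided p = 2/6 = 1/3
  expect_equal(filmSens:::ranksumTest(c(3, 4), c(1, 2))$p, 1 / 3)
})

test_that("BH adjustment reproduces the hand-applied step-up rule", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(5)
  p <- runif(20)
  q <- p.adjust(p, method = "BH")
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone after step-up
})

test_that("the control-compound-set filter keeps only qualifying classes", {
  # 3 cell lines; classA: 2 compounds everywhere (kept); classB: 2 compounds
  # but one missing in CL3 (dropped); classC: 1 compound (dropped)
  meta <- data.frame(
    cell_line_id = c(rep(c("CL1", "CL2", "CL3"), times = 2),       # a1, a2
                     rep(c("CL1", "CL2", "CL3"), times = 1),       # b1
                     c("CL1", "CL2"),                              # b2 (no CL3)
                     rep(c("CL1", "CL2", "CL3"), times = 1)),      # c1
    compound_id = c(rep(c("a1", "a2"), each = 3), rep("b1", 3),
                    rep("b2", 2), rep("c1", 3)))
  set.seed(1)
  am <- new("AttributionMatrix",
            values = matrix(rnorm(nrow(meta) * 4), nrow(meta), 4,
                            dimnames = list(NULL, paste0("g", 1:4))),
            meta = cbind(meta, ic50_um = 1), adjusted = TRUE)
  cmp <- data.frame(compound_id = c("a1", "a2", "b1", "b2", "c1"),
                    moa_class = c("A", "A", "B", "B", "C"))
  ccs <- buildCcs(am, cmp)
  expect_identical(ccs$classes, "A")
  expect_setequal(unique(attrMeta(ccs$attr)$compound_id), c("a1", "a2"))
  expect_identical(unique(ccs$labels), "A")
  cmp1 <- data.frame(compound_id = c("a1", "a2"), moa_class = c("A", "B"))
  expect_error(buildCcs(am, cmp1, minCompounds = 2), "MOA class")
})

test_that("K-means AMI is 1 on well-separated blobs and deterministic", {
  set.seed(4)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
  lab <- rep(c("p", "q"), each = 20)
  ami <- kmeansAmi(x, lab, k = 2, nTrials = 5, seed = 6)
  expect_length(ami, 5L)
  expect_true(all(ami == 1))
  expect_identical(ami, kmeansAmi(x, lab, k = 2, nTrials = 5, seed = 6))
})

test_that("AMI baseline comparison returns aligned distributions and tests", {
  set.seed(7)
  x <- rbind(matrix(rnorm(60, 0), 15), matrix(rnorm(60, 6), 15))
  lab <- rep(c("p", "q"), each = 15)
  noise <- matrix(rnorm(length(x)), nrow(x))
  out <- compareAmiBaselines(list(signal = x, noise = noise, signal2 = x),
                             lab, nTrials = 5, seed = 9)
  expect_named(out$ami, c("signal", "noise", "signal2"))
  expect_true(all(lengths(out$ami) == 5))
  # identical sources -> identical AMI distributions under identical seeds
  expect_identical(out$ami$signal, out$ami$signal2)
  expect_gt(median(out$ami$signal), median(out$ami$noise))
  expect_equal(nrow(out$tests), 3L)
  expect_error(compareAmiBaselines(list(a = x[1:10, ]), lab), "rows")
})

test_that("target attribution testing flags class-specific genes", {
  set.seed(10)
  n <- 40
  vals <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  labels <- rep(c("A", "B"), each = n / 2)
  vals[labels == "A", "g2"] <- vals[labels == "A", "g2"] + 3  # planted target
  am <- new("AttributionMatrix", values = vals,
            meta = data.frame(cell_line_id = rep(c("x", "y"), n / 2),
                              compound_id = paste0("c", seq_len(n)),
                              ic50_um = 1),
            adjusted = TRUE)
  res <- targetAttributionTest(am, labels,
                               list(A = c("g2", "gMissing"), B = "g5"))
  expect_true(res$q[res$moa_class == "A" & res$target == "g2"] < 0.01)
  expect_false(res$testable[res$target == "gMissing"])
  expect_gt(res$p[res$moa_class == "B" & res$target == "g5"], 0.05)
  expect_true(res$top_for_class[res$target == "g2"])
  expect_true(all(res$q[res$testable] >= res$p[res$testable]))
})

test_that("Leiden clustering separates planted blobs deterministically", {
  # blobs placed at opposing mean vectors so cosine similarity separates them
  set.seed(13)
  x <- rbind(matrix(rnorm(100, 5), 25), matrix(rnorm(100, -5), 25))
  cl <- leidenClusters(x, resolution = 1, k = 10, seed = 2)
  expect_length(unique(cl), 2L)
  expect_equal(adjustedMutualInfo(cl, rep(1:2, each = 25)), 1)
  expect_identical(cl, leidenClusters(x, resolution = 1, k = 10, seed = 2))
  # vanishing resolution collapses a *connected* similarity graph to one cluster
  xc <- matrix(rnorm(200, 3), 20)
  expect_length(unique(leidenClusters(xc, resolution = 1e-5, k = 10, seed = 2)), 1L)
})

test_that("differential attribution recovers planted cluster markers", {
  planted <- paste0("g", 1:10)
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    vals <- matrix(rnorm(30 * 40), 30, 40, dimnames = list(NULL, paste0("g", 1:40)))
    cl <- rep(c(1L, 2L), c(10L, 20L))
    vals[cl == 1L, planted] <- vals[cl == 1L, planted] + 2.5
    am <- new("AttributionMatrix", values = vals,
              meta = data.frame(cell_line_id = "cl", compound_id = paste0("c", 1:30),
                                ic50_um = 1), adjusted = TRUE)
    daa <- differentialAttribution(am, cl, 1L)
    hits <- hits + sum(planted %in% daa$top10)
    expect_true(all(daa$table$q >= daa$table$p - 1e-15))
  }
  expect_gte(hits / 5, 8)
})

test_that("a flat gene never outranks signal genes", {
  set.seed(20)
  vals <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(NULL, paste0("g", 1:12)))
  vals[, "g1"] <- 0.7                               # identical everywhere
  vals[1:10, paste0("g", 2:12)] <- vals[1:10, paste0("g", 2:12)] + 2
  am <- new("AttributionMatrix", values = vals,
            meta = data.frame(cell_line_id = "cl", compound_id = paste0("c", 1:20),
                              ic50_um = 1), adjusted = TRUE)
  daa <- differentialAttribution(am, rep(c(1L, 2L), each = 10), 1L)
  expect_false("g1" %in% daa$top10)
  expect_gt(daa$table$q[daa$table$gene == "g1"], 0.9)
  expect_error(differentialAttribution(am, rep(1L, 20), 1L), "complement")
})

test_that("cluster target profiles pick one seeded target per class", {
  cmp <- data.frame(compound_id = c("n1", "n2", "m1"),
                    moa_class = c("HER", "HER", "OTHER"))
  cmp$targets <- I(list(c("EGFR", "ERBB2"), c("EGFR", "ERBB2"), "KRAS"))
  cl <- c(1L, 1L, 1L)
  prof <- clusterTargetProfile(cl, cmp$compound_id, cmp, seed = 2)
  expect_lte(length(prof[["1"]]), 2L)
  expect_true(any(c("EGFR", "ERBB2") %in% prof[["1"]]))
  expect_true("KRAS" %in% prof[["1"]])
  expect_identical(prof, clusterTargetProfile(cl, cmp$compound_id, cmp, seed = 2))
})

test_that("subgraph connectivity is the induced edge density", {
  g <- toyGraph()  # high-confidence triangle A-B-C plus C-D; D-E filtered out
  expect_equal(as.numeric(subgraphConnectivity(g, c("A", "B", "C"))), 1)
  expect_equal(as.numeric(subgraphConnectivity(g, character(0))), 0)
  expect_equal(as.numeric(subgraphConnectivity(g, "A")), 0)
  expect_equal(as.numeric(subgraphConnectivity(g, c("A", "B", "Z1", "Z2"))),
               1 / 6)  # one edge among 6 possible pairs; absent nodes degree 0
  # invariance to node/edge ordering
  e2 <- g$edges[rev(seq_len(nrow(g$edges))), ]
  g2 <- interactionGraph(e2[, c("node_b", "node_a", "score")] |>
                           stats::setNames(c("node_a", "node_b", "score")),
                         scoreFilter = NULL)
  expect_equal(as.numeric(subgraphConnectivity(g2, c("C", "B", "A"))), 1)
})

test_that("a planted module exceeds its random-set null", {
  set.seed(14)
  genes <- paste0("G", 1:300)
  bg <- data.frame(node_a = sample(genes, 400, TRUE),
                   node_b = sample(genes, 400, TRUE),
                   score = 0.9)
  module <- paste0("M", 1:6)
  clique <- t(combn(module, 2))
  edges <- rbind(bg, data.frame(node_a = clique[, 1], node_b = clique[, 2], score = 0.95))
  g <- interactionGraph(edges, nodes = c(genes, module), scoreFilter = 0.7)
  nullRes <- connectivityNull(g, module, pool = genes, nDraws = 1000, seed = 15)
  expect_equal(nullRes$p, 1 / 1001)
  expect_gt(nullRes$observed, quantile(nullRes$null, 0.95))
  expect_identical(nullRes$p,
                   connectivityNull(g, module, pool = genes, nDraws = 1000, seed = 15)$p)
  expect_error(connectivityNull(g, module, pool = genes[1:3]), "pool")
})

test_that("interaction enrichment matches direct hypergeometric enumeration", {
  g <- toyGraph()
  # universe of 4 nodes -> 6 pairs; 4 high-confidence edges in the graph
  # (A-B, A-C, B-C, C-D); query {A,B,C} induces 3 of 3 possible pairs
  res <- interactionEnrichment(g, c("A", "B", "C"), backgroundSize = 4)
  expect_equal(res$totalEdges, 4)
  # P(X >= 3 | N=6 pairs, K=4 edges, n=3 drawn) = C(4,3)/C(6,3) = 0.2
  expect_equal(res$p, choose(4, 3) / choose(6, 3))
  # the spec's 3-edge toy: drop edge C-D by filtering to the triangle
  g3 <- interactionGraph(data.frame(node_a = c("A", "A", "B"),
                                    node_b = c("B", "C", "C"),
                                    score = 0.9),
                         nodes = c("A", "B", "C", "D"), scoreFilter = 0.7)
  expect_equal(interactionEnrichment(g3, c("A", "B", "C"), backgroundSize = 4)$p,
               1 / 20)
  # zero observed edges -> p = 1
  expect_equal(interactionEnrichment(g3, c("A", "D"), backgroundSize = 4)$p, 1)
  expect_error(interactionEnrichment(g3, "A"), ">= 2")
})

test_that("gene-set enrichment matches the hypergeometric tail", {
  bg <- paste0("g", 1:100)
  sets <- list(hit = paste0("g", 1:10), other = paste0("g", 90:95))
  query <- paste0("g", c(1:5, 50:54))  # overlap 5 with 'hit'
  res <- genesetEnrichment(query, sets, bg)
  pExpect <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(res$p[res$set == "hit"], pExpect)
  expect_equal(res$p[res$set == "other"],
               phyper(-1, 6, 94, 10, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(genesetEnrichment(character(0), sets, bg), "empty")
  # query equal to a set under a tight background is maximally enriched
  resFull <- genesetEnrichment(sets$hit, sets, bg)
  expect_equal(which.min(resFull$p), which(resFull$set == "hit"))
})

test_that("GMT and edge-list readers round-trip", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), gmt)
  sets <- readGmt(gmt)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"), setB = "g4"))
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(node_a = c("A", "B"), node_b = c("B", "B"),
                         score = c(900, 800)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- readInteractionGraph(tsv, scoreFilter = 0.7)
  expect_equal(nrow(g$edges), 1L)      # self-loop dropped, 0-1000 rescaled
  expect_equal(g$edges$score, 0.9)
})
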