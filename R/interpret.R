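# Interpretation of attribution matrices: clustering and agreement with MOA
# labels (AMI), per-target and per-gene rank-sum testing with BH correction,
# and protein-interaction module statistics (connectivity nulls,
# hypergeometric enrichment).

# Two-sided Wilcoxon rank-sum p-value: exact for small tie-free groups,
# normal approximation with tie correction otherwise (stats::wilcox.test).
ranksumTest <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied groups carry no evidence
  list(statistic = unname(wt$statistic), p = min(p, 1))
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance agreement under the permutation
#' (hypergeometric) model and normalized by the arithmetic mean of the two
#' entropies: AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI]). Symmetric in
#' its arguments, invariant to label renaming, 1 for identical partitions
#' and ~0 for independent ones.
#'
#' @param labelsA,labelsB vectors of equal length (any type; treated as
#'   categorical).
#' @return scalar AMI.
#' @export
adjustedMutualInfo <- function(labelsA, labelsB) {
  stopifnot(length(labelsA) == length(labelsB), length(labelsA) >= 1L)
  tab <- table(labelsA, labelsB)
  N <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  pa <- a / N; pb <- b / N
  hu <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hv <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (hu == 0 && hv == 0) return(1)
  pij <- tab / N
  mi <- sum(ifelse(tab > 0, pij * log(pij / outer(pa, pb)), 0))
  # E[MI] under the hypergeometric model of random contingency tables
  emi <- 0
  lfN <- lfactorial(N)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lowest <- max(1, a[i] + b[j] - N)
      highest <- min(a[i], b[j])
      if (highest < lowest) next
      nij <- lowest:highest
      term <- (nij / N) * log(N * nij / (a[i] * b[j]))
      lp <- lfactorial(a[i]) + lfactorial(b[j]) +
        lfactorial(N - a[i]) + lfactorial(N - b[j]) -
        lfN - lfactorial(nij) - lfactorial(a[i] - nij) -
        lfactorial(b[j] - nij) - lfactorial(N - a[i] - b[j] + nij)
      emi <- emi + sum(term * exp(lp))
    }
  }
  denom <- (hu + hv) / 2 - emi
  eps <- .Machine$double.eps
  denom <- if (denom < 0) min(denom, -eps) else max(denom, eps)
  (mi - emi) / denom
}

#' Filter attributions to the control compound set (CCS)
#'
#' Retains only MOA classes with at least `minCompounds` compounds
#' successfully attributed in every cell line present in the matrix, and
#' only the rows of those qualifying compounds — the filter that defines the
#' label baseline for attribution-similarity analysis.
#'
#' @param attrMat an [AttributionMatrix-class].
#' @param compounds compound table with compound_id and moa_class.
#' @param minCompounds minimum qualifying compounds per class (default 2).
#' @return list(attr = filtered [AttributionMatrix-class], labels = MOA class
#'   per kept row, classes = retained class names).
#' @export
buildCcs <- function(attrMat, compounds, minCompounds = 2L) {
  stopifnot(is(attrMat, "AttributionMatrix"))
  meta <- attrMat@meta
  moa <- stats::setNames(as.character(compounds$moa_class), compounds$compound_id)
  cells <- unique(meta$cell_line_id)
  nPerCompound <- table(meta$compound_id[!duplicated(paste(meta$compound_id, meta$cell_line_id))])
  fullCompounds <- names(nPerCompound)[nPerCompound == length(cells)]
  classOf <- moa[fullCompounds]
  keepClasses <- names(which(table(classOf) >= minCompounds))
  if (!length(keepClasses)) stopf("no MOA class has >= %d compounds attributed in all %d cell lines",
                                  minCompounds, length(cells))
  keepCompounds <- fullCompounds[classOf %in% keepClasses]
  keep <- meta$compound_id %in% keepCompounds
  filt <- new("AttributionMatrix", values = attrMat@values[keep, , drop = FALSE],
              meta = meta[keep, , drop = FALSE], adjusted = attrMat@adjusted)
  list(attr = filt, labels = unname(moa[filt@meta$compound_id]), classes = keepClasses)
}

#' K-means clustering agreement with true labels over repeated trials
#'
#' Runs K-means `nTrials` times with independent seeded initializations and
#' scores each clustering against the true labels with
#' [adjustedMutualInfo()].
#'
#' @param vectors rows x features numeric matrix.
#' @param trueLabels per-row labels.
#' @param k number of clusters (default: number of distinct true labels).
#' @param nTrials independent trials (default 5).
#' @param seed base seed.
#' @return numeric vector of AMI values, one per trial.
#' @export
kmeansAmi <- function(vectors, trueLabels, k = length(unique(trueLabels)),
                      nTrials = 5L, seed = 1L) {
  stopifnot(nrow(vectors) == length(trueLabels), k >= 2L, nrow(vectors) >= k)
  vapply(seq_len(nTrials), function(t) {
    set.seed(deriveSeed(seed, paste0("kmeans", t)))
    km <- suppressWarnings(kmeans(vectors, centers = k, nstart = 1L, iter.max = 50L))
    adjustedMutualInfo(km$cluster, trueLabels)
  }, numeric(1))
}

#' Compare AMI of attribution sources against baselines
#'
#' The attribution-similarity comparison: K-means AMI distributions (over
#' `nTrials` trials each) for trained-model adjusted attributions versus
#' compound fingerprints, random-initialization control attributions, and
#' label-permutation control attributions, all scored against the same MOA
#' labels, with pairwise two-sided Wilcoxon rank-sum tests.
#'
#' @param sources named list of row-aligned numeric matrices (e.g. trained,
#'   fingerprints, random_init, permuted).
#' @param labels per-row true labels shared by all sources.
#' @param k,nTrials,seed as in [kmeansAmi()].
#' @return list(ami = named list of AMI vectors, tests = data.frame of
#'   pairwise Wilcoxon p-values).
#' @export
compareAmiBaselines <- function(sources, labels, k = length(unique(labels)),
                                nTrials = 5L, seed = 1L) {
  stopifnot(is.list(sources), length(names(sources)) == length(sources))
  for (nm in names(sources)) {
    if (nrow(sources[[nm]]) != length(labels)) {
      stopf("source '%s' has %d rows but %d labels", nm, nrow(sources[[nm]]), length(labels))
    }
  }
  # all sources share the trial seeds, so identical sources give identical
  # AMI distributions
  ami <- lapply(names(sources), function(nm) {
    kmeansAmi(sources[[nm]], labels, k = k, nTrials = nTrials, seed = seed)
  })
  names(ami) <- names(sources)
  prs <- utils::combn(names(sources), 2L)
  tests <- data.frame(source_a = prs[1, ], source_b = prs[2, ],
                      p = apply(prs, 2L, function(pr) {
                        ranksumTest(ami[[pr[1]]], ami[[pr[2]]])$p
                      }))
  list(ami = ami, tests = tests)
}

#' Rank-sum tests of nominal-target attributions per MOA class
#'
#' For each MOA class and each of its nominal targets, tests that target
#' gene's attribution in class rows against all out-of-class rows (two-sided
#' Wilcoxon rank-sum), BH-adjusting across all tests. The target with the
#' largest mean attribution difference within each class is flagged.
#'
#' @param attrMat adjusted [AttributionMatrix-class].
#' @param labels per-row MOA class labels.
#' @param targetsByClass named list: class -> character vector of nominal
#'   target genes.
#' @return data.frame(moa_class, target, testable, statistic, p, q, effect,
#'   top_for_class), q BH-adjusted over testable rows.
#' @export
targetAttributionTest <- function(attrMat, labels, targetsByClass) {
  stopifnot(is(attrMat, "AttributionMatrix"), nrow(attrMat@values) == length(labels))
  vals <- attrMat@values
  rows <- list()
  for (cls in names(targetsByClass)) {
    inCls <- labels == cls
    if (!any(inCls) || all(inCls)) next
    for (tg in targetsByClass[[cls]]) {
      if (!tg %in% colnames(vals)) {
        rows[[length(rows) + 1L]] <- data.frame(
          moa_class = cls, target = tg, testable = FALSE,
          statistic = NA_real_, p = NA_real_, effect = NA_real_)
        next
      }
      x <- vals[inCls, tg]; y <- vals[!inCls, tg]
      rt <- ranksumTest(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        moa_class = cls, target = tg, testable = TRUE,
        statistic = rt$statistic, p = rt$p, effect = mean(x) - mean(y))
    }
  }
  if (!length(rows)) stopf("no testable (class, target) combination")
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$testable] <- p.adjust(out$p[out$testable], method = "BH")
  out$top_for_class <- FALSE
  for (cls in unique(out$moa_class)) {
    i <- which(out$moa_class == cls & out$testable)
    if (length(i)) out$top_for_class[i[which.max(abs(out$effect[i]))]] <- TRUE
  }
  out[, c("moa_class", "target", "testable", "statistic", "p", "q", "effect", "top_for_class")]
}

#' Leiden community detection on a similarity graph of rows
#'
#' Builds a cosine-similarity k-nearest-neighbor graph over the rows and
#' applies Leiden clustering (modularity objective). Deterministic given
#' `seed`.
#'
#' @param x rows x features numeric matrix.
#' @param resolution Leiden resolution parameter (default 1).
#' @param k neighbors per row (default 15, capped at n - 1).
#' @param seed RNG seed.
#' @return integer cluster labels, one per row.
#' @export
leidenClusters <- function(x, resolution = 1, k = 15L, seed = 1L) {
  stopifnot(nrow(x) >= 2L)
  k <- min(as.integer(k), nrow(x) - 1L)
  xn <- x / pmax(sqrt(rowSums(x^2)), 1e-12)
  sim <- xn %*% t(xn)
  diag(sim) <- -Inf
  edges <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    data.frame(from = i, to = nb, w = sim[i, nb])
  }))
  edges <- edges[edges$w > 0, , drop = FALSE]
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  keep <- !duplicated(paste(a, b))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep]), directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(x))))
  igraph::E(g)$weight <- edges$w[keep]
  set.seed(as.integer(seed))
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10L)
  as.integer(igraph::membership(cl))
}

#' Differential attribution analysis of a cluster
#'
#' Per-gene two-sided Wilcoxon rank-sum test of attributions in one cluster
#' (or a merged set of clusters) against all remaining rows, BH-adjusted
#' across genes; the top-10 markers are ordered by q then |mean difference|.
#'
#' @param attrMat adjusted [AttributionMatrix-class].
#' @param clusters per-row cluster labels.
#' @param clusterId cluster id, or several ids to merge before testing.
#' @return list(table = per-gene data.frame(gene, statistic, p, q, effect),
#'   top10 = character vector).
#' @export
differentialAttribution <- function(attrMat, clusters, clusterId) {
  stopifnot(is(attrMat, "AttributionMatrix"), nrow(attrMat@values) == length(clusters))
  inCl <- clusters %in% clusterId
  if (sum(inCl) < 2L) stopf("cluster has < 2 rows")
  if (sum(!inCl) < 2L) stopf("complement has < 2 rows")
  vals <- attrMat@values
  res <- lapply(colnames(vals), function(gn) {
    rt <- ranksumTest(vals[inCl, gn], vals[!inCl, gn])
    data.frame(gene = gn, statistic = rt$statistic, p = rt$p,
               effect = mean(vals[inCl, gn]) - mean(vals[!inCl, gn]))
  })
  tab <- do.call(rbind, res)
  tab$q <- p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$q, -abs(tab$effect)), c("gene", "statistic", "p", "q", "effect")]
  rownames(tab) <- NULL
  list(table = tab, top10 = utils::head(tab$gene, 10L))
}

#' Per-cluster nominal-target profile by random selection
#'
#' For every MOA class represented in a cluster, selects exactly one nominal
#' target uniformly at random (seeded) — avoiding over-connectivity bias
#' from pathway-adjacent multi-target annotations — and returns the union
#' per cluster.
#'
#' @param clusters per-row cluster labels.
#' @param compoundIds per-row compound identifiers.
#' @param compounds compound table with compound_id, moa_class and a
#'   `targets` list-column.
#' @param seed RNG seed.
#' @return named list: cluster id -> character vector of selected targets.
#' @export
clusterTargetProfile <- function(clusters, compoundIds, compounds, seed = 1L) {
  stopifnot(length(clusters) == length(compoundIds))
  moa <- stats::setNames(as.character(compounds$moa_class), compounds$compound_id)
  tgt <- stats::setNames(compounds$targets, compounds$compound_id)
  classTargets <- list()
  for (cid in names(moa)) {
    classTargets[[moa[cid]]] <- union(classTargets[[moa[cid]]], tgt[[cid]])
  }
  out <- list()
  for (cl in sort(unique(clusters))) {
    classes <- unique(moa[as.character(compoundIds[clusters == cl])])
    sel <- character(0)
    for (cls in sort(classes)) {
      pool <- classTargets[[cls]]
      if (is.null(pool) || !length(pool)) {
        warning(sprintf("MOA class '%s' has no annotated targets; skipped", cls))
        next
      }
      set.seed(deriveSeed(seed, paste0("ctp:", cl, ":", cls)))
      sel <- c(sel, if (length(pool) == 1L) pool else sample(pool, 1L))
    }
    out[[as.character(cl)]] <- unique(sel)
  }
  out
}

# ---- interaction graphs ----

#' Build an interaction graph from a weighted edge list
#'
#' Undirected weighted protein/gene interaction graph. Self-loops and
#' duplicate edges are removed; scores on a 0-1000 scale are auto-detected
#' and rescaled to (0, 1]; edges at or below `scoreFilter` are dropped
#' (the high-confidence subgraph convention keeps combined score > 0.7).
#'
#' @param edges data.frame(node_a, node_b, score).
#' @param nodes optional node universe (defaults to nodes seen in edges).
#' @param scoreFilter minimum score, exclusive (default 0.7; set NULL to
#'   keep all edges).
#' @return an interaction graph object (list with edges, nodes, adjacency).
#' @export
interactionGraph <- function(edges, nodes = NULL, scoreFilter = 0.7) {
  stopifnot(all(c("node_a", "node_b", "score") %in% names(edges)))
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (max(edges$score) > 1) edges$score <- edges$score / 1000
  if (!is.null(scoreFilter)) edges <- edges[edges$score > scoreFilter, , drop = FALSE]
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  a <- pmin(edges$node_a, edges$node_b); b <- pmax(edges$node_a, edges$node_b)
  keep <- !duplicated(paste(a, b))
  edges <- data.frame(node_a = a[keep], node_b = b[keep], score = edges$score[keep])
  nodes <- sort(unique(c(nodes, edges$node_a, edges$node_b)))
  ia <- match(edges$node_a, nodes); ib <- match(edges$node_b, nodes)
  adj <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                              x = rep(edges$score, 2L),
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
  structure(list(edges = edges, nodes = nodes, adj = adj),
            class = "filmSensGraph")
}

#' Read an interaction graph from a TSV edge list
#' @param path TSV with columns node_a, node_b, score (header optional names
#'   tolerated; 0-1000 scores auto-rescaled).
#' @param scoreFilter see [interactionGraph()].
#' @param nodes optional node universe.
#' @export
readInteractionGraph <- function(path, scoreFilter = 0.7, nodes = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("node_a", "node_b", "score")
  interactionGraph(df, nodes = nodes, scoreFilter = scoreFilter)
}

#' Induced-subgraph connectivity (edge density) of a node set
#'
#' Number of edges induced by the node set divided by the number of possible
#' pairs n(n-1)/2, so differently sized sets are comparable; nodes absent
#' from the graph count with degree 0, and sets with fewer than 2 nodes have
#' connectivity 0. The raw induced edge count is attached as an attribute.
#'
#' @param graph a [interactionGraph()] object.
#' @param nodes character vector of node names.
#' @return edge density in [0, 1] with `attr(, "edges")` the raw count.
#' @export
subgraphConnectivity <- function(graph, nodes) {
  nodes <- unique(as.character(nodes))
  n <- length(nodes)
  if (n < 2L) return(structure(0, edges = 0L))
  present <- intersect(nodes, graph$nodes)
  nEdges <- if (length(present) >= 2L) {
    sum(graph$adj[present, present] > 0) / 2
  } else 0
  structure(nEdges / (n * (n - 1) / 2), edges = as.integer(nEdges))
}

#' Empirical connectivity null for a node set
#'
#' Draws `nDraws` random same-size node sets from a candidate pool (e.g. the
#' annotated-target pool or all protein-coding genes), computes each draw's
#' induced edge density, and reports the one-sided empirical p-value of the
#' observed set with +1 smoothing: p = (1 + #(null >= obs)) / (nDraws + 1).
#' `ties = "randomized"` instead breaks ties between the observed value and
#' null draws uniformly at random, the construction under which the p-value
#' is exactly uniform for a discrete statistic.
#'
#' @param graph a [interactionGraph()] object.
#' @param nodes observed node set.
#' @param pool candidate pool to draw from (must be >= the set size).
#' @param nDraws number of null draws (default 1000).
#' @param seed RNG seed.
#' @param ties "deterministic" (default) or "randomized".
#' @return list(p, observed, null = numeric vector of null densities).
#' @export
connectivityNull <- function(graph, nodes, pool, nDraws = 1000L, seed = 1L,
                             ties = c("deterministic", "randomized")) {
  ties <- match.arg(ties)
  nodes <- unique(as.character(nodes))
  pool <- unique(as.character(pool))
  if (length(pool) < length(nodes)) stopf("pool (%d) smaller than node set (%d)",
                                          length(pool), length(nodes))
  obs <- as.numeric(subgraphConnectivity(graph, nodes))
  set.seed(deriveSeed(seed, "connectivity-null"))
  null <- vapply(seq_len(nDraws), function(i) {
    as.numeric(subgraphConnectivity(graph, sample(pool, length(nodes))))
  }, numeric(1))
  p <- if (ties == "deterministic") {
    (1 + sum(null >= obs)) / (nDraws + 1)
  } else {
    t <- sum(null == obs)
    (1 + sum(null > obs) + sample.int(t + 1L, 1L) - 1L) / (nDraws + 1)
  }
  list(p = p, observed = obs, null = null)
}

#' Hypergeometric protein-interaction enrichment of a node set
#'
#' Upper-tail probability of observing at least the induced edge count when
#' |pairs(nodes)| pairs are drawn from the background pair universe
#' containing the graph's total edge count as successes — the plain
#' hypergeometric network-enrichment test.
#'
#' @param graph a [interactionGraph()] object.
#' @param nodes node set (>= 2 nodes).
#' @param backgroundSize size of the background gene universe (default: the
#'   graph's node universe).
#' @return list(p, observedEdges, possiblePairs, totalEdges, universePairs).
#' @export
interactionEnrichment <- function(graph, nodes, backgroundSize = length(graph$nodes)) {
  nodes <- unique(as.character(nodes))
  if (length(nodes) < 2L) stopf("need >= 2 nodes")
  if (backgroundSize < length(nodes)) stopf("background smaller than the node set")
  conn <- subgraphConnectivity(graph, nodes)
  k <- attr(conn, "edges")
  nPairs <- length(nodes) * (length(nodes) - 1) / 2
  N <- backgroundSize * (backgroundSize - 1) / 2
  K <- nrow(graph$edges)
  if (K > N) stopf("graph has more edges than the background pair universe")
  p <- phyper(k - 1, K, N - K, nPairs, lower.tail = FALSE)
  list(p = p, observedEdges = k, possiblePairs = nPairs,
       totalEdges = K, universePairs = N)
}

#' Read gene sets from a GMT file
#' @param path GMT path (tab-separated: name, description, genes...).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1L))
}

#' Hypergeometric gene-set enrichment of a query gene list
#'
#' One-sided overlap enrichment of the query against each gene set
#' (equivalent to one-sided Fisher's exact), BH-adjusted across sets.
#'
#' @param queryGenes character vector (non-empty).
#' @param genesets named list of gene sets, or a GMT file path.
#' @param background character vector defining the gene universe.
#' @return data.frame(set, overlap, setSize, p, q) sorted by q.
#' @export
genesetEnrichment <- function(queryGenes, genesets, background) {
  if (is.character(genesets) && length(genesets) == 1L) genesets <- readGmt(genesets)
  queryGenes <- unique(queryGenes)
  if (!length(queryGenes)) stopf("empty query gene list")
  background <- unique(background)
  q <- intersect(queryGenes, background)
  res <- lapply(names(genesets), function(nm) {
    s <- intersect(genesets[[nm]], background)
    k <- length(intersect(q, s))
    p <- phyper(k - 1, length(s), length(background) - length(s), length(q),
                lower.tail = FALSE)
    data.frame(set = nm, overlap = k, setSize = length(s), p = p)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$q, out$p), ]
}
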