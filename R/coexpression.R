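## NPP-GPCR co-expression enrichment, the cascade network over enriched
## pairs, and autocrine-loop analysis.

#' One-sided co-expression enrichment for a gene pair
#'
#' Tests whether a precursor gene and a receptor gene co-occur in more
#' neurons than expected from their individual expression frequencies:
#' the one-sided (enrichment) Fisher exact test on the 2x2 table over the
#' neuron panel, computed as the hypergeometric upper tail.
#' \code{calibrated = TRUE} additionally randomizes over the point mass at
#' the observed table (the probability-integral-transform p-value), which
#' is exactly Uniform(0,1) under independence and is the form used for
#' calibration diagnostics; inference uses the standard exact p.
#'
#' @param expr a \linkS4class{PeptideExpression}.
#' @param npp,gpcr gene identifiers present in \code{expr}.
#' @param calibrated logical (default FALSE).
#' @return list with the 2x2 counts \code{n11}, \code{n10}, \code{n01},
#'   \code{n00} and the p-value \code{p}.
#' @export
fisherEnrichment <- function(expr, npp, gpcr, calibrated = FALSE) {
  a <- .exprVector(expr, npp)
  b <- .exprVector(expr, gpcr)
  N <- length(a)
  n11 <- sum(a & b)
  K <- sum(a)
  M <- sum(b)
  p <- phyper(n11 - 1, K, N - K, M, lower.tail = FALSE)
  if (calibrated)
    p <- p - runif(1) * dhyper(n11, K, N - K, M)
  list(n11 = n11, n10 = K - n11, n01 = M - n11, n00 = N - K - M + n11,
       p = p)
}

#' Co-expression enrichment across all candidate gene pairs
#'
#' Tests every NPP gene x GPCR gene combination drawn from the interaction
#' dataset's gene lists (not only cognate couples), applies
#' Benjamini-Hochberg FDR adjustment across all tests, and flags cognate
#' pairs (couples at the active EC50 threshold).
#'
#' @param expr a \linkS4class{PeptideExpression}.
#' @param interactions an \linkS4class{InteractionTable} defining the gene
#'   universe and the cognate flags.
#' @param alpha FDR level for the significant set (default 0.05).
#' @param ec50Max EC50 threshold (molar) for the cognate flag.
#' @return list with \code{tests} (all pairs: npp, gpcr, n11, n10, n01,
#'   n00, p, q, cognate) and \code{significant} (rows with q <= alpha).
#' @export
enrichedPairs <- function(expr, interactions, alpha = 0.05,
                          ec50Max = 5e-7) {
  stopifnot(alpha > 0, alpha < 1)
  e <- interactionEntries(interactions)
  X <- expressed(expr)
  nppGenes <- intersect(unique(e$npp), rownames(X))
  gpcrGenes <- intersect(unique(e$gpcr), rownames(X))
  if (!length(nppGenes) || !length(gpcrGenes))
    stop("no interaction genes found in the expression matrix")
  N <- ncol(X)
  Xn <- X[nppGenes, , drop = FALSE]
  Xg <- X[gpcrGenes, , drop = FALSE]
  n11 <- tcrossprod(1 * Xn, 1 * Xg)   # co-occurrence counts
  kN <- rowSums(Xn)
  kG <- rowSums(Xg)
  grid <- expand.grid(npp = nppGenes, gpcr = gpcrGenes,
                      stringsAsFactors = FALSE)
  cc <- n11[cbind(grid$npp, grid$gpcr)]
  K <- kN[grid$npp]
  M <- kG[grid$gpcr]
  p <- phyper(cc - 1, K, N - K, M, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  couples <- couplesAtThreshold(interactions, ec50Max)
  cog <- paste(grid$npp, grid$gpcr) %in% paste(couples$npp, couples$gpcr)
  tests <- data.frame(npp = grid$npp, gpcr = grid$gpcr,
                      n11 = as.integer(cc), n10 = as.integer(K - cc),
                      n01 = as.integer(M - cc),
                      n00 = as.integer(N - K - M + cc),
                      p = p, q = q, cognate = cog)
  tests <- tests[order(tests$q, tests$p, tests$npp, tests$gpcr), ]
  rownames(tests) <- NULL
  list(tests = tests, significant = tests[tests$q <= alpha, ])
}

#' Signaling-cascade network over enriched co-expression pairs
#'
#' Nodes are enriched (NPP, GPCR) co-expression pairs; a directed edge
#' runs from node u to node v when u's precursor gene activates v's
#' receptor gene at the active threshold (gene-level rule; peptide-level
#' linking via \code{level = "peptide"} requires any peptide of u's
#' precursor to activate v's receptor, which at gene granularity
#' coincides, so both use the couple set). Self-edges are excluded.
#'
#' @param enriched data.frame of significant pairs from [enrichedPairs()].
#' @param interactions an \linkS4class{InteractionTable}.
#' @param ec50Max EC50 threshold (molar).
#' @param level \code{"gene"} (default) or \code{"peptide"}.
#' @return list with \code{graph} (igraph), \code{nNodes}, \code{nEdges},
#'   \code{nComponents} (weak), \code{connected}.
#' @export
cascadeNetwork <- function(enriched, interactions, ec50Max = 5e-7,
                           level = c("gene", "peptide")) {
  level <- match.arg(level)
  nodes <- paste(enriched$npp, enriched$gpcr, sep = "~")
  act <- if (level == "gene") {
    cps <- couplesAtThreshold(interactions, ec50Max)
    unique(cps[c("npp", "gpcr")])
  } else {
    e <- interactionEntries(interactions)
    unique(e[e$ec50 <= ec50Max, c("npp", "gpcr")])
  }
  edges <- character(0)
  nn <- nrow(enriched)
  if (nn > 1) {
    actKey <- paste(act$npp, act$gpcr)
    for (u in seq_len(nn)) for (v in seq_len(nn)) {
      if (u == v) next
      if (paste(enriched$npp[u], enriched$gpcr[v]) %in% actKey)
        edges <- c(edges, nodes[u], nodes[v])
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, nn, name = nodes)
  if (length(edges)) g <- igraph::add_edges(g, match(edges, nodes))
  comps <- if (nn > 0)
    as.integer(igraph::count_components(g, mode = "weak")) else 0L
  list(graph = g, nNodes = nn, nEdges = as.integer(igraph::ecount(g)),
       nComponents = comps, connected = nn > 0 && comps == 1L)
}

#' Autocrine co-expression profiles
#'
#' A neuron harbors a putative autocrine connection for a cognate couple
#' when it co-expresses the couple's precursor and receptor genes
#' (a self-loop in the signaling network).
#'
#' @param expr a \linkS4class{PeptideExpression}.
#' @param couples data.frame from [couplesAtThreshold()].
#' @return list with \code{perNeuron} (data.frame neuron, type, count),
#'   \code{couplesPerNeuron} (named list of couple keys),
#'   \code{fractionAutocrine} (share of neurons with >= 1 loop),
#'   \code{byType} (per-type percentage of autocrine neurons) and
#'   \code{perCouple} (data.frame couple, nNeurons).
#' @export
autocrineProfiles <- function(expr, couples) {
  X <- expressed(expr)
  nm <- colnames(X)
  types <- colData(expr)$type
  keys <- paste(couples$npp, couples$gpcr, sep = "~")
  co <- matrix(FALSE, nrow(couples), ncol(X),
               dimnames = list(keys, nm))
  for (i in seq_len(nrow(couples)))
    co[i, ] <- X[couples$npp[i], ] & X[couples$gpcr[i], ]
  count <- colSums(co)
  perNeuron <- data.frame(neuron = nm, type = types,
                          count = as.integer(count))
  byType <- tapply(count > 0, types, mean) * 100
  list(perNeuron = perNeuron,
       couplesPerNeuron = apply(co, 2L, function(v) keys[v],
                                simplify = FALSE),
       fractionAutocrine = mean(count > 0),
       byType = byType,
       perCouple = data.frame(couple = keys,
                              nNeurons = as.integer(rowSums(co))))
}

#' Correlation of autocrine diversity with network degree
#'
#' Correlates the per-neuron count of autocrine couples with total, in-
#' and out-degree in one or more networks; an optional permutation test
#' shuffles the counts.
#'
#' @param profiles result of [autocrineProfiles()].
#' @param degreeList named list of degree tables (same roster).
#' @param nPerm permutations for the empirical p (0 to skip).
#' @param seed RNG seed for the permutations.
#' @return data.frame: network, measure (k/kIn/kOut), r, p (and permP).
#' @export
autocrineDegreeCorrelation <- function(profiles, degreeList, nPerm = 0L,
                                       seed = 42L) {
  cnt <- profiles$perNeuron$count
  rows <- list()
  if (nPerm > 0) set.seed(seed)
  for (nw in names(degreeList)) {
    dt <- degreeList[[nw]]
    stopifnot(identical(dt$neuron, profiles$perNeuron$neuron))
    for (ms in c("k", "kIn", "kOut")) {
      x <- dt[[ms]]
      if (var(x) == 0 || var(cnt) == 0) {
        row <- data.frame(network = nw, measure = ms, r = NA_real_,
                          p = NA_real_, degenerate = TRUE)
        if (nPerm > 0) row$permP <- NA_real_
        rows[[length(rows) + 1L]] <- row
        next
      }
      ct <- cor.test(cnt, x)
      row <- data.frame(network = nw, measure = ms,
                        r = unname(ct$estimate), p = ct$p.value,
                        degenerate = FALSE)
      if (nPerm > 0) {
        robs <- abs(row$r)
        rperm <- replicate(nPerm, abs(cor(sample(cnt), x)))
        row$permP <- (1 + sum(rperm >= robs)) / (nPerm + 1)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
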