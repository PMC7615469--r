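## Per-couple network construction, spatial diffusion filtering and
## aggregation into the weighted connectome.

.exprVector <- function(expr, gene) {
  X <- expressed(expr)
  if (!gene %in% rownames(X))
    stop("gene not in expression matrix: ", gene)
  X[gene, ]
}

#' Build the unfiltered (long-range) network of one couple
#'
#' The edge i -> j exists when neuron i expresses the precursor gene and
#' neuron j the receptor gene (outer product of the two expression vectors).
#' Self-loops are retained; they are the autocrine connections.
#'
#' @param expr a \linkS4class{PeptideExpression}.
#' @param couple one-row data.frame (or list) with \code{npp}, \code{gpcr}
#'   and optionally \code{minEC50}.
#' @return a \linkS4class{PairNetwork} with \code{model = "long"}.
#' @export
buildPairNetwork <- function(expr, couple) {
  send <- .exprVector(expr, couple$npp)
  recv <- .exprVector(expr, couple$gpcr)
  A <- outer(send, recv, `&`)
  new("PairNetwork", npp = couple$npp, gpcr = couple$gpcr,
      minEC50 = if (!is.null(couple$minEC50)) couple$minEC50 else NA_real_,
      model = "long", adjacency = A)
}

#' Pairwise spatial predicate matrix for a diffusion model
#'
#' Computes, for every ordered neuron pair, whether the diffusion model
#' permits signaling:
#' \describe{
#'   \item{long}{always permitted.}
#'   \item{mid}{same body region (head includes the pharynx), or any pair
#'     already permitted under the short model (processes sharing a bundle
#'     are by definition in a shared anatomical territory, so mid strictly
#'     contains short).}
#'   \item{short}{at least one shared process bundle, with the pharynx as a
#'     sealed compartment: pharyngeal neurons connect only to pharyngeal
#'     neurons.}
#'   \item{contact}{a shared nerve-ring stratum, or a shared thin
#'     (non-nerve-ring) bundle; always a subset of short.}
#' }
#' The diagonal is always TRUE (a neuron shares its own location).
#'
#' @param ann a \linkS4class{NeuronAnnotation}.
#' @param model one of \code{"long"}, \code{"mid"}, \code{"short"},
#'   \code{"contact"}.
#' @return logical n-by-n matrix in roster order.
#' @export
spatialPredicateMatrix <- function(ann,
                                   model = c("long", "mid", "short",
                                             "contact")) {
  model <- match.arg(model)
  nm <- ann@neuron
  n <- length(nm)
  if (model == "long") {
    M <- matrix(TRUE, n, n, dimnames = list(nm, nm))
    return(M)
  }
  # bundle incidence (neurons x bundles)
  B <- matrix(FALSE, n, length(ann@bundleUniverse),
              dimnames = list(nm, ann@bundleUniverse))
  for (i in seq_len(n)) B[i, ann@bundles[[i]]] <- TRUE
  shareBundle <- tcrossprod(B) > 0
  pharynx <- ann@inPharynx
  # the pharynx is sealed under short-range: a shared bundle only counts
  # when both or neither neuron is pharyngeal
  short <- shareBundle & outer(pharynx, pharynx, `==`)
  M <- switch(model,
    mid = outer(ann@region, ann@region, `==`) | short,
    short = short,
    contact = {
      nrIdx <- match(ann@nerveRing, ann@bundleUniverse)
      S <- matrix(FALSE, n, 4L)
      for (i in seq_len(n)) S[i, ann@strata[[i]][ann@strata[[i]] <= 4L]] <- TRUE
      shareStratum <- tcrossprod(S) > 0
      thin <- B
      if (!is.na(nrIdx)) thin[, nrIdx] <- FALSE
      shareThin <- tcrossprod(thin) > 0
      (shareStratum | shareThin) & short
    })
  diag(M) <- TRUE
  dimnames(M) <- list(nm, nm)
  M
}

#' Spatial predicate for a single neuron pair
#'
#' @param i,j neuron names.
#' @param model diffusion model.
#' @param ann a \linkS4class{NeuronAnnotation}.
#' @return logical.
#' @export
spatialPredicate <- function(i, j, model, ann) {
  if (!all(c(i, j) %in% ann@neuron))
    stop("missing annotation for: ",
         paste(setdiff(c(i, j), ann@neuron), collapse = ", "))
  spatialPredicateMatrix(ann, model)[i, j]
}

#' Filter a long-range pair network under a diffusion model
#'
#' Keeps edge (i, j) only when the spatial predicate holds. Self-loops
#' always pass (same neuron, same location).
#'
#' @param net a \linkS4class{PairNetwork} (any model at or above the target
#'   in the long > mid > short > contact nesting; typically \code{"long"}).
#' @param model target diffusion model.
#' @param ann a \linkS4class{NeuronAnnotation}.
#' @return a \linkS4class{PairNetwork} with the target model.
#' @export
applySpatialFilter <- function(net, model = c("long", "mid", "short",
                                              "contact"), ann) {
  model <- match.arg(model)
  if (model == "long") {
    net@model <- "long"
    return(net)
  }
  P <- spatialPredicateMatrix(ann, model)
  A <- net@adjacency & P[rownames(net@adjacency), colnames(net@adjacency)]
  new("PairNetwork", npp = net@npp, gpcr = net@gpcr, minEC50 = net@minEC50,
      model = model, adjacency = A)
}

#' Aggregate single-couple networks into the weighted connectome
#'
#' @param nets list of \linkS4class{PairNetwork}s sharing one model.
#' @param model the shared model (checked against each network).
#' @param dim n (roster size), required when \code{nets} is empty.
#' @param neuronNames roster names, required when \code{nets} is empty.
#' @return an \linkS4class{AggregateNetwork} whose weight entry counts the
#'   couples connecting each ordered pair.
#' @export
aggregateNetworks <- function(nets, model = NULL, dim = NULL,
                              neuronNames = NULL) {
  if (!length(nets)) {
    if (is.null(dim) || is.null(neuronNames))
      stop("empty network list needs dim and neuronNames")
    return(new("AggregateNetwork", model = model %||% "long",
               weights = matrix(0L, dim, dim,
                                dimnames = list(neuronNames, neuronNames)),
               couples = data.frame(npp = character(), gpcr = character(),
                                    minEC50 = numeric())))
  }
  models <- vapply(nets, networkModel, "")
  if (is.null(model)) model <- models[1L]
  if (!all(models == model))
    stop("all networks must share the model '", model, "'")
  W <- Reduce(`+`, lapply(nets, function(x) 1L * x@adjacency))
  storage.mode(W) <- "integer"
  couples <- data.frame(npp = vapply(nets, function(x) x@npp, ""),
                        gpcr = vapply(nets, function(x) x@gpcr, ""),
                        minEC50 = vapply(nets, function(x) x@minEC50, 1.0))
  new("AggregateNetwork", model = model, weights = W, couples = couples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary adjacency of an aggregate network
#'
#' @param agg an \linkS4class{AggregateNetwork}.
#' @param zeroDiagonal drop self-loops (default TRUE, the convention for
#'   every topology metric).
#' @return logical matrix.
#' @export
binarize <- function(agg, zeroDiagonal = TRUE) {
  A <- adjacency(agg) > 0
  if (zeroDiagonal) diag(A) <- FALSE
  A
}

#' Edge-weight histogram of the aggregate network
#'
#' Counts nonzero off-diagonal edge weights (number of couples per directed
#' neuron pair) and reports the heaviest edges.
#'
#' @param agg an \linkS4class{AggregateNetwork}.
#' @return list with \code{counts} (named integer vector over weights),
#'   \code{maxWeight} and \code{argmax} (data.frame pre/post of the
#'   heaviest edges).
#' @export
edgeWeightDistribution <- function(agg) {
  W <- adjacency(agg)
  diag(W) <- 0L
  w <- W[W > 0]
  if (!length(w))
    return(list(counts = integer(0), maxWeight = 0L,
                argmax = data.frame(pre = character(),
                                    post = character())))
  counts <- table(factor(w, levels = seq_len(max(w))))
  idx <- which(W == max(w), arr.ind = TRUE)
  list(counts = setNames(as.integer(counts), names(counts)),
       maxWeight = as.integer(max(w)),
       argmax = data.frame(pre = rownames(W)[idx[, 1]],
                           post = colnames(W)[idx[, 2]]))
}

#' Overlap between the peptidergic aggregate and a wired connectome
#'
#' Counts directed off-diagonal neuron pairs connected in both networks,
#' in the peptidergic network only, and in the wired network only.
#'
#' @param agg an \linkS4class{AggregateNetwork}.
#' @param wired a \linkS4class{WiredNetwork} on the same roster.
#' @return named integer vector \code{both}, \code{pept_only},
#'   \code{wired_only}.
#' @export
overlapWithWired <- function(agg, wired) {
  P <- binarize(agg)
  Wm <- adjacency(wired) > 0
  if (!identical(rownames(P), rownames(Wm)))
    stop("networks must share the roster")
  diag(Wm) <- FALSE
  c(both = sum(P & Wm), pept_only = sum(P & !Wm), wired_only = sum(!P & Wm))
}

#' Weakly connected components among participating neurons
#'
#' Counts the weakly connected components of a pair network after dropping
#' neurons with no incident edge (a couple's network graphs only the
#' neurons that participate in it).
#'
#' @param net a \linkS4class{PairNetwork} (or logical adjacency matrix).
#' @return integer component count (0 for an empty network).
#' @export
countComponents <- function(net) {
  A <- if (is(net, "PairNetwork")) adjacency(net) else net
  deg <- rowSums(A) + colSums(A)
  keep <- deg > 0
  if (!any(keep)) return(0L)
  g <- igraph::graph_from_adjacency_matrix(A[keep, keep, drop = FALSE],
                                           mode = "directed", diag = TRUE)
  as.integer(igraph::count_components(g, mode = "weak"))
}
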