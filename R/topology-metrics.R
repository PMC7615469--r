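## Directed-network statistics. Every function here works on a binary
## directed adjacency matrix and drops self-loops first: topology metrics
## are defined on the network with the diagonal zeroed.

.asBinaryAdj <- function(A) {
  if (is(A, "AggregateNetwork")) A <- adjacency(A) > 0
  if (is(A, "PairNetwork")) A <- adjacency(A)
  if (is(A, "WiredNetwork")) A <- adjacency(A) > 0
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  A <- A != 0
  diag(A) <- FALSE
  A
}

#' Degree table of a directed network
#'
#' @param A binary directed adjacency (or an aggregate/pair network, which
#'   is binarized with the diagonal zeroed).
#' @return data.frame with columns \code{neuron}, \code{kIn}, \code{kOut},
#'   \code{k} (total = in + out).
#' @export
degreeTable <- function(A) {
  A <- .asBinaryAdj(A)
  nm <- rownames(A)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(A)))
  data.frame(neuron = nm, kIn = as.integer(colSums(A)),
             kOut = as.integer(rowSums(A)),
             k = as.integer(colSums(A) + rowSums(A)))
}

#' Density of a directed network
#'
#' Fraction of present directed connections, K / (N^2 - N).
#'
#' @inheritParams degreeTable
#' @return numeric in [0, 1].
#' @export
networkDensity <- function(A) {
  A <- .asBinaryAdj(A)
  n <- nrow(A)
  if (n < 2) stop("density needs at least 2 nodes")
  sum(A) / (n^2 - n)
}

#' Directed transitivity (ratio of triangles to triples)
#'
#' Uses the directed clustering formulation: the triangle count around node
#' i is half the i-th diagonal entry of (A + t(A))^3, and the triple count
#' is k_i^tot (k_i^tot - 1) - 2 * sum_j A_ij A_ji.
#'
#' @inheritParams degreeTable
#' @return numeric in [0, 1] (0 for a network without triples).
#' @export
transitivityDirected <- function(A) {
  A <- .asBinaryAdj(A)
  S <- A + t(A)
  tri <- diag(S %*% S %*% S) / 2
  ktot <- rowSums(A) + colSums(A)
  recip <- diag(A %*% A)
  denom <- sum(ktot * (ktot - 1) - 2 * recip)
  if (denom == 0) return(0)
  sum(tri) / denom
}

#' Reciprocity of a directed network
#'
#' Fraction of edges that are reciprocated: each directed edge of a mutual
#' pair counts.
#'
#' @inheritParams degreeTable
#' @return numeric in [0, 1]; NA with a warning on an empty network.
#' @export
reciprocityDirected <- function(A) {
  A <- .asBinaryAdj(A)
  K <- sum(A)
  if (K == 0) {
    warning("reciprocity undefined on an empty network")
    return(NA_real_)
  }
  sum(A & t(A)) / K
}

#' All scalar metrics of a directed network
#'
#' @inheritParams degreeTable
#' @return list with \code{N}, \code{K}, \code{density},
#'   \code{transitivity}, \code{reciprocity}, \code{reciprocalEdges}.
#' @export
networkMetrics <- function(A) {
  A <- .asBinaryAdj(A)
  list(N = nrow(A), K = sum(A), density = networkDensity(A),
       transitivity = transitivityDirected(A),
       reciprocity = if (sum(A) > 0) reciprocityDirected(A) else NA_real_,
       reciprocalEdges = sum(A & t(A)))
}

#' Density of an induced subnetwork
#'
#' @param A binary directed adjacency (diagonal ignored).
#' @param nodes character names or integer indices, at least 2.
#' @return numeric density of the induced subgraph.
#' @export
subnetworkDensity <- function(A, nodes) {
  A <- .asBinaryAdj(A)
  if (length(nodes) < 2) stop("need at least 2 nodes")
  sub <- A[nodes, nodes, drop = FALSE]
  diag(sub) <- FALSE
  n <- nrow(sub)
  sum(sub) / (n^2 - n)
}

#' Correlation between two degree tables
#'
#' Product-moment correlation of total degrees over the shared roster, with
#' a two-sided p-value.
#'
#' @param d1,d2 degree tables from [degreeTable()] on the same roster.
#' @return list with \code{r}, \code{p}.
#' @export
degreeCorrelation <- function(d1, d2) {
  if (!identical(d1$neuron, d2$neuron))
    stop("degree tables must share the roster")
  if (var(d1$k) == 0 || var(d2$k) == 0)
    stop("degree correlation undefined: zero variance")
  ct <- cor.test(d1$k, d2$k, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
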