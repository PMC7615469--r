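## Degree-preserving null ensembles and rich-club analysis.

#' Degree-preserving null ensemble
#'
#' Randomizes a directed binary network by repeated edge swaps
#' (a->b, c->d) => (a->d, c->b), rejecting proposals that would create a
#' self-loop or duplicate an existing edge. The attempt budget is
#' \code{swapsPerEdge} times the edge count; rejected proposals count
#' toward the budget. In- and out-degree sequences (and hence the edge
#' count) are preserved exactly.
#'
#' @param A binary directed adjacency (diagonal dropped).
#' @param n number of null networks.
#' @param swapsPerEdge swap attempts per edge (default 10).
#' @param seed integer RNG seed.
#' @return list of logical adjacency matrices with attributes
#'   \code{realized} (successful swaps) and \code{attempts} on each; a
#'   warning is raised when a network is too small or dense to swap.
#' @export
degreePreservingNulls <- function(A, n = 100L, swapsPerEdge = 10L,
                                  seed = 42L) {
  A <- .asBinaryAdj(A)
  stopifnot(n >= 1)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    res <- .edgeSwapNull(A, as.integer(swapsPerEdge))
    nul <- res$adj
    dimnames(nul) <- dimnames(A)
    attr(nul, "realized") <- res$realized
    attr(nul, "attempts") <- res$attempts
    if (res$attempts > 0 && res$realized == 0)
      warning("no swap succeeded (network too small or dense); ",
              "null is a copy of the input")
    out[[i]] <- nul
  }
  out
}

# phi(k) curve for one network: phi = M_k / (N_k (N_k - 1)) where the
# level-k subnetwork keeps nodes of total degree > k. Computed in O(m)
# from the min endpoint degree of each edge.
.phiCurve <- function(A, deg, kGrid) {
  maxk <- max(kGrid) + 1L
  idx <- which(A, arr.ind = TRUE)
  Nk <- vapply(kGrid, function(k) sum(deg > k), 1L)
  if (nrow(idx)) {
    mn <- pmin(deg[idx[, 1]], deg[idx[, 2]])
    mTab <- tabulate(pmin(mn, maxk + 1L), nbins = maxk + 1L)
    cum <- rev(cumsum(rev(mTab)))
    Mk <- vapply(kGrid, function(k) {
      if (k + 1L > length(cum)) 0L else as.integer(cum[k + 1L])
    }, 1L)
  } else {
    Mk <- integer(length(kGrid))
  }
  phi <- ifelse(Nk >= 2, Mk / (Nk * (Nk - 1)), NA_real_)
  list(phi = phi, Mk = Mk, Nk = Nk)
}

#' Rich-club analysis with a degree-preserving null ensemble
#'
#' For every degree level k (1 to max total degree - 1) the subnetwork of
#' nodes with total degree > k is extracted and its rich-club coefficient
#' phi(k) = M_k / (N_k (N_k - 1)) computed, along with the mean and SD of
#' the same coefficient over \code{nNull} degree-preserving randomizations.
#' The normalized coefficient is phi / <phi_random>. The rich-club onset is
#' the smallest k with phi_norm(k) >= 1 + sigma(k); by default sigma is the
#' SD of the normalized coefficient across the ensemble
#' (SD(phi_rand) / <phi_rand>), with \code{sigmaBasis = "raw"} using
#' SD(phi_rand) directly. Members are the neurons with total degree
#' strictly greater than the onset.
#'
#' @param A binary directed adjacency (diagonal dropped), or an
#'   \linkS4class{AggregateNetwork}.
#' @param nNull ensemble size (default 100).
#' @param swapsPerEdge swap attempts per edge (default 10).
#' @param seed integer RNG seed.
#' @param sigmaBasis \code{"normalized"} (default) or \code{"raw"}.
#' @param nulls optional pre-computed ensemble from
#'   [degreePreservingNulls()] (then \code{nNull}/\code{swapsPerEdge}/
#'   \code{seed} describe it only).
#' @return a \linkS4class{RichClubCurve}.
#' @export
richClub <- function(A, nNull = 100L, swapsPerEdge = 10L, seed = 42L,
                     sigmaBasis = c("normalized", "raw"), nulls = NULL) {
  sigmaBasis <- match.arg(sigmaBasis)
  A <- .asBinaryAdj(A)
  nm <- rownames(A)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(A)))
  deg <- rowSums(A) + colSums(A)
  maxk <- max(deg)
  if (maxk < 2)
    stop("network has no node of degree 2; rich club undefined")
  kGrid <- seq_len(maxk - 1L)
  real <- .phiCurve(A, deg, kGrid)
  if (is.null(nulls))
    nulls <- degreePreservingNulls(A, n = nNull, swapsPerEdge = swapsPerEdge,
                                   seed = seed)
  nNull <- length(nulls)
  phiRand <- vapply(nulls, function(nul) {
    .phiCurve(nul, deg, kGrid)$phi
  }, numeric(length(kGrid)))
  if (is.null(dim(phiRand))) phiRand <- matrix(phiRand, nrow = 1L)
  mu <- rowMeans(phiRand, na.rm = TRUE)
  sdv <- apply(phiRand, 1L, sd, na.rm = TRUE)
  phiNorm <- ifelse(mu > 0, real$phi / mu, NA_real_)
  sigma <- if (sigmaBasis == "normalized") {
    ifelse(mu > 0, sdv / mu, NA_real_)
  } else {
    sdv
  }
  # strictly greater: a graph whose nulls are frozen copies of itself
  # (sigma 0, phi_norm exactly 1) carries no rich-club signal
  pass <- which(!is.na(phiNorm) & !is.na(sigma) & phiNorm > 1 + sigma)
  onsetK <- if (length(pass)) kGrid[min(pass)] else NA_integer_
  members <- if (is.na(onsetK)) character(0) else nm[deg > onsetK]
  new("RichClubCurve", k = as.integer(kGrid), phi = real$phi,
      phiRandMean = mu, phiRandSd = sdv, phiNorm = phiNorm, sigma = sigma,
      onsetK = as.integer(onsetK), members = members,
      nNull = as.integer(nNull), swapsPerEdge = as.integer(swapsPerEdge),
      seed = as.integer(seed), sigmaBasis = sigmaBasis)
}
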