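## Mesoscale structure: embed neurons by their incoming-connectivity
## profiles, cluster the embedding, and compare groups.

#' Pairwise distances between incoming-connection profiles
#'
#' @param F numeric matrix, rows = observations.
#' @param distance one of \code{"euclidean"}, \code{"chebychev"},
#'   \code{"cosine"}, \code{"mahalanobis"}.
#' @return an n-by-n symmetric distance matrix.
#' @export
profileDistance <- function(F, distance = c("euclidean", "chebychev",
                                            "cosine", "mahalanobis")) {
  distance <- match.arg(distance)
  D <- switch(distance,
    euclidean = as.matrix(dist(F, method = "euclidean")),
    chebychev = as.matrix(dist(F, method = "maximum")),
    cosine = {
      nrm <- sqrt(rowSums(F^2))
      nrm[nrm == 0] <- 1
      cs <- tcrossprod(F / nrm)
      D <- 1 - cs
      D[D < 0] <- 0
      diag(D) <- 0
      D
    },
    mahalanobis = {
      # whiten with the pseudo-inverse square root of the covariance
      C <- stats::cov(F)
      eg <- eigen(C, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      W <- eg$vectors[, pos, drop = FALSE] %*%
        diag(1 / sqrt(eg$values[pos]), sum(pos))
      Fw <- scale(F, center = TRUE, scale = FALSE) %*% W
      as.matrix(dist(Fw))
    })
  dimnames(D) <- list(rownames(F), rownames(F))
  D
}

# Exact t-SNE on a precomputed distance matrix. Conditional Gaussian
# affinities with per-point bandwidths tuned by bisection to the target
# perplexity; KL gradient descent with early exaggeration and momentum.
.tsne <- function(D, perplexity = 30, seed = 42L, maxIter = 500L,
                  eta = 200, exaggeration = 12, verbose = FALSE) {
  n <- nrow(D)
  if (perplexity >= n / 3) stop("perplexity must be below n / 3")
  D2 <- D^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0 } else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2
                        else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / max(sum(w), .Machine$double.eps)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  V <- matrix(0, n, 2)
  Pex <- P * exaggeration
  for (it in seq_len(maxIter)) {
    Pit <- if (it <= 100) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Pit - Q) * num
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    V <- mom * V - eta * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(D)
  colnames(Y) <- c("dim1", "dim2")
  Y
}

#' Embed neurons by incoming-connectivity profile
#'
#' Each neuron is described by the weighted vector of senders targeting it
#' (the transposed columns of the aggregate weight matrix; set
#' \code{features = "outgoing"} for the sensitivity view) and embedded in
#' two dimensions with t-SNE (default, perplexity 30, Euclidean distance)
#' or PCA. Deterministic given the seed.
#'
#' @param agg an \linkS4class{AggregateNetwork} (or a numeric matrix whose
#'   rows are already feature vectors).
#' @param method \code{"tsne"} or \code{"pca"}.
#' @param distance distance measure for t-SNE, see [profileDistance()].
#' @param perplexity t-SNE perplexity (default 30; must be < n/3).
#' @param seed integer RNG seed.
#' @param features \code{"incoming"} (default) or \code{"outgoing"}.
#' @param maxIter t-SNE iterations.
#' @return n-by-2 coordinate matrix with neuron rownames.
#' @export
embedNetwork <- function(agg, method = c("tsne", "pca"),
                         distance = "euclidean", perplexity = 30,
                         seed = 42L, features = c("incoming", "outgoing"),
                         maxIter = 500L) {
  method <- match.arg(method)
  features <- match.arg(features)
  F <- if (is(agg, "AggregateNetwork")) {
    W <- adjacency(agg)
    if (features == "incoming") t(W) else W
  } else {
    agg
  }
  storage.mode(F) <- "double"
  if (method == "pca") {
    pc <- prcomp(F, center = TRUE, scale. = FALSE)
    Y <- pc$x[, 1:2, drop = FALSE]
    colnames(Y) <- c("dim1", "dim2")
    return(Y)
  }
  if (perplexity >= nrow(F) / 3) stop("perplexity must be below n / 3")
  D <- profileDistance(F, distance)
  .tsne(D, perplexity = perplexity, seed = seed, maxIter = maxIter)
}

#' Density-based clustering of a 2-D embedding
#'
#' DBSCAN on the embedding coordinates: points with at least
#' \code{minPts} neighbors within \code{eps} seed clusters; unassigned
#' (low-density) points form the periphery. By default \code{eps} adapts to
#' the embedding scale (the 75th percentile of each point's distance to its
#' minPts-th neighbor). Cluster labels are ordered by decreasing size.
#'
#' @param coords n-by-2 matrix from [embedNetwork()].
#' @param eps neighborhood radius (default adaptive).
#' @param minPts minimum neighborhood size for a core point (default 5).
#' @param warnBelow warn when fewer than this many clusters are found
#'   (default 3, the expected core count).
#' @return factor of labels \code{cluster_1}, \code{cluster_2}, ...,
#'   \code{periphery}, named by neurons.
#' @export
clusterEmbedding <- function(coords, eps = NULL, minPts = 5L,
                             warnBelow = 3L) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  if (is.null(eps)) {
    kdist <- apply(D, 1L, function(d) sort(d)[minPts + 1L])
    eps <- unname(quantile(kdist, 0.75))
  }
  nb <- D <= eps
  core <- rowSums(nb) - 1L >= minPts
  labels <- integer(n)  # 0 = unassigned
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (!core[j]) next
      nbrs <- which(nb[j, ])
      newly <- nbrs[labels[nbrs] == 0L]
      labels[newly] <- cl
      queue <- c(queue, newly[core[newly]])
    }
  }
  if (cl < warnBelow)
    warning("only ", cl, " cluster(s) found; expected at least ", warnBelow)
  sizes <- if (cl > 0) tabulate(labels[labels > 0L], nbins = cl) else integer()
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(cl)
  remap[ord] <- seq_len(cl)
  lab <- ifelse(labels == 0L, "periphery",
                paste0("cluster_", remap[pmax(labels, 1L)]))
  lev <- c(paste0("cluster_", seq_len(max(cl, 0L))), "periphery")
  setNames(factor(lab, levels = lev), rownames(coords))
}

#' Name the cores by composition
#'
#' Maps generic cluster labels onto the semantic core names used for the
#' worm connectome: the cluster with the highest median indegree becomes
#' \code{hubs_core}; of the remaining two largest, the one with the larger
#' motor-neuron fraction becomes \code{motor_core} and the other
#' \code{sensory_core}; everything else (and the periphery) is
#' \code{periphery}.
#'
#' @param labels factor from [clusterEmbedding()].
#' @param degrees degree table from [degreeTable()] on the same roster.
#' @param types named character vector of neuron types.
#' @return factor with levels motor_core, hubs_core, sensory_core,
#'   periphery.
#' @export
nameCores <- function(labels, degrees, types) {
  stopifnot(identical(names(labels), degrees$neuron))
  clusters <- setdiff(levels(labels), "periphery")
  clusters <- clusters[clusters %in% labels]
  out <- setNames(rep("periphery", length(labels)), names(labels))
  if (length(clusters) >= 3L) {
    kIn <- setNames(degrees$kIn, degrees$neuron)
    medIn <- vapply(clusters, function(cl)
      median(kIn[names(labels)[labels == cl]]), 1.0)
    hubs <- clusters[which.max(medIn)]
    rest <- setdiff(clusters, hubs)
    sizes <- vapply(rest, function(cl) sum(labels == cl), 1L)
    rest <- rest[order(sizes, decreasing = TRUE)][1:2]
    motorFrac <- vapply(rest, function(cl)
      mean(types[names(labels)[labels == cl]] == "motor"), 1.0)
    motor <- rest[which.max(motorFrac)]
    sensory <- setdiff(rest, motor)
    out[labels == hubs] <- "hubs_core"
    out[labels == motor] <- "motor_core"
    out[labels == sensory] <- "sensory_core"
  }
  factor(out, levels = c("motor_core", "hubs_core", "sensory_core",
                         "periphery"))
}

#' Compare indegree between groups
#'
#' Kruskal-Wallis omnibus test on group indegrees followed by
#' Tukey-Kramer-style pairwise comparisons on rank means (studentized
#' range on the large-sample normal approximation, with tie correction).
#' Groups with fewer than 2 members are excluded with a warning.
#'
#' @param labels factor of group labels, named by neurons.
#' @param degrees degree table from [degreeTable()] on the same roster.
#' @param value which degree to compare (default \code{"kIn"}).
#' @return list with \code{medians}, \code{n}, \code{omnibus} (statistic,
#'   df, p) and \code{pairwise} (data.frame of group pairs with q and p).
#' @export
groupStatistics <- function(labels, degrees, value = "kIn") {
  stopifnot(identical(names(labels), degrees$neuron))
  x <- degrees[[value]]
  g <- factor(labels)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    x <- x[keep]
    g <- droplevels(g[keep])
  }
  kw <- kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  k <- nlevels(g)
  nG <- tapply(r, g, length)
  rBar <- tapply(r, g, mean)
  ties <- table(x)
  tieCorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  pairs <- utils::combn(levels(g), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  se <- sqrt((N * (N + 1) / 12 * tieCorr) *
             (1 / nG[pw$group1] + 1 / nG[pw$group2]))
  diffR <- abs(rBar[pw$group1] - rBar[pw$group2])
  q <- sqrt(2) * diffR / se
  pw$q <- unname(q)
  pw$p <- unname(ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE))
  list(medians = tapply(x, g, median), n = as.integer(sizes[levels(g)]),
       omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw)
}

#' Group-to-group connection densities
#'
#' Density of the binarized aggregate between every ordered pair of groups
#' (within-group densities exclude the diagonal).
#'
#' @param agg an \linkS4class{AggregateNetwork} (or binary matrix).
#' @param labels factor of group labels named by neurons (roster order).
#' @return k-by-k numeric matrix of densities.
#' @export
intergroupConnectivity <- function(agg, labels) {
  A <- .asBinaryAdj(agg)
  stopifnot(identical(names(labels), rownames(A)))
  lev <- levels(droplevels(labels))
  out <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (a in lev) for (b in lev) {
    ia <- which(labels == a)
    ib <- which(labels == b)
    sub <- A[ia, ib, drop = FALSE]
    possible <- if (a == b) length(ia) * (length(ia) - 1L)
                else length(ia) * length(ib)
    out[a, b] <- if (possible > 0) sum(sub) / possible else NA_real_
  }
  out
}

#' Clustering agreement across distance measures
#'
#' Reruns embedding + clustering under several distance measures and
#' reports pairwise adjusted-Rand agreement of the resulting labels,
#' mirroring the robustness check of clustering to the distance choice.
#'
#' @param agg an \linkS4class{AggregateNetwork}.
#' @param distances distance measures to compare.
#' @param ... passed to [embedNetwork()] / [clusterEmbedding()].
#' @param perplexity,seed see [embedNetwork()].
#' @return list with \code{labels} (per distance) and \code{ari} (matrix).
#' @export
clusterRobustness <- function(agg, distances = c("euclidean", "chebychev",
                                                 "cosine", "mahalanobis"),
                              perplexity = 30, seed = 42L, ...) {
  labs <- lapply(distances, function(d) {
    Y <- embedNetwork(agg, method = "tsne", distance = d,
                      perplexity = perplexity, seed = seed)
    suppressWarnings(clusterEmbedding(Y, ...))
  })
  names(labs) <- distances
  ari <- matrix(NA_real_, length(distances), length(distances),
                dimnames = list(distances, distances))
  for (a in distances) for (b in distances)
    ari[a, b] <- .adjustedRand(labs[[a]], labs[[b]])
  list(labels = labs, ari = ari)
}

# Adjusted Rand index (Hubert-Arabie) from the contingency table.
.adjustedRand <- function(l1, l2) {
  tab <- table(l1, l2)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
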