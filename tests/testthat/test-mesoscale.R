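# planted 4-group network: three blocks with coherent incoming profiles
# plus a diffuse noise cloud
plantedBlocks <- function(n = 120, pIn = 0.8, pNoise = 0.2, seed = 1) {
  set.seed(seed)
  stopifnot(n %% 4 == 0)
  q <- n / 4
  blocks <- rep(1:4, each = q)
  W <- matrix(0L, n, n)
  for (b in 1:3) {
    recv <- which(blocks == b)
    src <- which(blocks == b)
    W[src, recv] <- matrix(rbinom(q * q, 1, pIn), q)
  }
  W[, blocks == 4] <- matrix(rbinom(n * q, 1, pNoise), n)
  nm <- sprintf("N%03d", seq_len(n))
  dimnames(W) <- list(nm, nm)
  list(agg = new("AggregateNetwork", model = "long", weights = W,
                 couples = data.frame(npp = "a", gpcr = "b",
                                      minEC50 = 1e-9)),
       blocks = blocks)
}

meanSilhouette <- function(coords, groups) {
  D <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(coords)), function(i) {
    own <- groups == groups[i]
    a <- mean(D[i, own & seq_along(own) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(D[i, groups == g]), 1.0))
    (b - a) / max(a, b)
  }, 1.0)
  mean(sil)
}

test_that("neurons with identical incoming profiles embed together", {
  pb <- plantedBlocks(seed = 2)
  W <- adjacency(pb$agg)
  W[, 2] <- W[, 1]   # duplicate neuron 2's incoming profile onto 1's
  agg <- new("AggregateNetwork", model = "long", weights = W,
             couples = pb$agg@couples)
  for (m in c("tsne", "pca")) {
    Y <- embedNetwork(agg, m, perplexity = 15, seed = 4)
    span <- max(dist(Y))
    expect_lt(sqrt(sum((Y[1, ] - Y[2, ])^2)), 0.01 * span)
  }
})

test_that("planted blocks separate in the embedding and cluster out", {
  pb <- plantedBlocks(seed = 3)
  core <- pb$blocks < 4
  Ypca <- embedNetwork(pb$agg, "pca", seed = 1)
  expect_gt(meanSilhouette(Ypca[core, ], pb$blocks[core]), 0.5)
  Y <- embedNetwork(pb$agg, "tsne", perplexity = 15, seed = 1)
  expect_gt(meanSilhouette(Y[core, ], pb$blocks[core]), 0.5)
  lab <- clusterEmbedding(Y)
  # each planted block lands dominantly in one recovered cluster
  for (b in 1:3) {
    tab <- table(lab[pb$blocks == b])
    expect_gte(max(tab) / sum(tab), 0.9)
  }
})

test_that("degenerate embeddings yield one cluster and a warning", {
  W <- matrix(1L, 40, 40, dimnames = rep(list(sprintf("n%d", 1:40)), 2))
  agg <- new("AggregateNetwork", model = "long", weights = W,
             couples = data.frame(npp = "a", gpcr = "b", minEC50 = 1e-9))
  Y <- embedNetwork(agg, "pca", seed = 1)
  expect_warning(lab <- clusterEmbedding(Y), "cluster")
  expect_lte(length(setdiff(unique(as.character(lab)), "periphery")), 1L)
})

test_that("clustering is invariant to roster permutation up to relabeling", {
  pb <- plantedBlocks(seed = 5)
  Y1 <- embedNetwork(pb$agg, "pca", seed = 1)
  lab1 <- suppressWarnings(clusterEmbedding(Y1))
  set.seed(9)
  perm <- sample(nrow(adjacency(pb$agg)))
  W2 <- adjacency(pb$agg)[perm, perm]
  agg2 <- new("AggregateNetwork", model = "long", weights = W2,
              couples = pb$agg@couples)
  Y2 <- embedNetwork(agg2, "pca", seed = 1)
  lab2 <- suppressWarnings(clusterEmbedding(Y2))
  ari <- NeuroPepNet:::.adjustedRand(as.character(lab1)[perm],
                                     as.character(lab2))
  expect_equal(ari, 1)
})

test_that("group statistics reduce to the two-group rank test", {
  set.seed(11)
  x <- c(rnorm(25), rnorm(30, 1))
  g <- factor(rep(c("a", "b"), c(25, 30)))
  dt <- data.frame(neuron = sprintf("n%02d", 1:55), kIn = x, kOut = 0,
                   k = x)
  gs <- groupStatistics(setNames(g, dt$neuron), dt)
  wil <- wilcox.test(x ~ g, exact = FALSE, correct = FALSE)
  kw <- kruskal.test(x, g)
  expect_equal(gs$omnibus$p, kw$p.value)
  expect_equal(kw$p.value, wil$p.value, tolerance = 1e-10)
  # with two groups the Tukey-Kramer comparison agrees with the omnibus
  expect_equal(gs$pairwise$p, kw$p.value, tolerance = 1e-6)
})

test_that("undersized groups are excluded with a warning", {
  set.seed(12)
  x <- rnorm(41)
  g <- factor(c(rep("a", 20), rep("b", 20), "tiny"))
  dt <- data.frame(neuron = sprintf("n%02d", 1:41), kIn = x, kOut = 0,
                   k = x)
  expect_warning(gs <- groupStatistics(setNames(g, dt$neuron), dt),
                 "tiny")
  expect_false("tiny" %in% names(gs$medians))
})

test_that("a shifted group is detected with high power", {
  hits <- 0L
  for (s in 1:30) {
    set.seed(s)
    x <- c(rnorm(30), rnorm(30), rnorm(30) + 100)
    g <- factor(rep(c("a", "b", "c"), each = 30))
    dt <- data.frame(neuron = sprintf("n%02d", 1:90), kIn = x, kOut = 0,
                     k = x)
    gs <- groupStatistics(setNames(g, dt$neuron), dt)
    if (gs$omnibus$p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 30L * 0.99)
})

test_that("intergroup densities reflect block structure", {
  pb <- plantedBlocks(seed = 6, pNoise = 0)
  lab <- factor(paste0("g", pb$blocks))
  names(lab) <- rownames(adjacency(pb$agg))
  ig <- intergroupConnectivity(pb$agg, lab)
  expect_true(all(diag(ig)[1:3] > 0.7))
  offdiag <- ig[1:3, 1:3][row(ig[1:3, 1:3]) != col(ig[1:3, 1:3])]
  expect_true(all(offdiag == 0))
  # uniform random network: all 16 cells near the global density
  set.seed(13)
  n <- 120
  W <- matrix(rbinom(n * n, 1, 0.3), n, n)
  diag(W) <- 0L
  dimnames(W) <- rep(list(sprintf("m%03d", 1:n)), 2)
  aggU <- new("AggregateNetwork", model = "long", weights = W,
              couples = data.frame(npp = "a", gpcr = "b", minEC50 = 1e-9))
  labU <- factor(rep(c("a", "b", "c", "d"), each = 30))
  names(labU) <- rownames(W)
  igU <- intergroupConnectivity(aggU, labU)
  gd <- networkDensity(W)
  se <- sqrt(gd * (1 - gd) / (30 * 30))
  expect_true(all(abs(igU - gd) < 3.5 * se))
})

test_that("semantic core naming tracks indegree and composition", {
  pb <- plantedBlocks(seed = 7)
  n <- nrow(adjacency(pb$agg))
  lab <- factor(ifelse(pb$blocks == 4, "periphery",
                       paste0("cluster_", pb$blocks)),
                levels = c("cluster_1", "cluster_2", "cluster_3",
                           "periphery"))
  names(lab) <- rownames(adjacency(pb$agg))
  # inflate cluster_2's indegree so it becomes the hubs core
  W <- adjacency(pb$agg)
  W[, pb$blocks == 2] <- 1L
  diag(W) <- 0L
  aggH <- new("AggregateNetwork", model = "long", weights = W,
              couples = pb$agg@couples)
  deg <- degreeTable(aggH)
  types <- setNames(ifelse(pb$blocks == 1, "motor", "sensory"),
                    rownames(W))
  named <- nameCores(lab, deg, types)
  expect_true(all(named[pb$blocks == 2] == "hubs_core"))
  expect_true(all(named[pb$blocks == 1] == "motor_core"))
  expect_true(all(named[pb$blocks == 3] == "sensory_core"))
  expect_true(all(named[pb$blocks == 4] == "periphery"))
})

test_that("clustering agreement across distance measures is reported", {
  pb <- plantedBlocks(n = 80, seed = 8)
  rb <- clusterRobustness(pb$agg, distances = c("euclidean", "cosine"),
                          perplexity = 10, seed = 2)
  expect_identical(dim(rb$ari), c(2L, 2L))
  expect_equal(unname(diag(rb$ari)), c(1, 1))
  expect_gt(rb$ari["euclidean", "cosine"], 0.5)
})
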