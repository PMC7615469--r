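test_that("pair networks are the outer product of expression vectors", {
  nm <- sprintf("n%d", 1:6)
  X <- matrix(FALSE, 2, 6, dimnames = list(c("npp1", "rec1"), nm))
  X["npp1", c(1, 2)] <- TRUE
  X["rec1", c(2, 3)] <- TRUE
  expr <- toyExpression(X)
  net <- buildPairNetwork(expr, list(npp = "npp1", gpcr = "rec1"))
  A <- adjacency(net)
  # exhaustive oracle
  for (i in 1:6) for (j in 1:6)
    expect_identical(A[i, j], X["npp1", i] && X["rec1", j])
  expect_identical(sum(A), 4L)          # {1->2, 1->3, 2->2, 2->3}
  expect_true(A["n2", "n2"])            # self-loop kept
  # ligand expressed nowhere -> empty network
  X2 <- X; X2["npp1", ] <- FALSE
  netEmpty <- buildPairNetwork(toyExpression(X2),
                               list(npp = "npp1", gpcr = "rec1"))
  expect_identical(sum(adjacency(netEmpty)), 0L)
  expect_error(buildPairNetwork(expr, list(npp = "nope", gpcr = "rec1")),
               "nope")
})

test_that("spatial predicates encode the four diffusion models", {
  ann <- toyAnnotation()
  # head vs tail: mid false, long true
  expect_false(spatialPredicate("r1", "t1", "mid", ann))
  expect_true(spatialPredicate("r1", "t1", "long", ann))
  # nerve-ring sender to pharyngeal receiver: short false, mid true
  expect_false(spatialPredicate("r2", "p1", "short", ann))
  expect_true(spatialPredicate("r2", "p1", "mid", ann))
  # shared thin bundle (ventral cord): true under all four models
  for (m in c("contact", "short", "mid", "long"))
    expect_true(spatialPredicate("v1", "v2", m, ann))
  # shared nerve-ring stratum is contact; disjoint strata are not
  expect_true(spatialPredicate("r1", "r2", "contact", ann))
  expect_false(spatialPredicate("r1", "r3", "contact", ann))
  expect_true(spatialPredicate("r1", "r3", "short", ann))
  expect_error(spatialPredicate("r1", "nope", "mid", ann), "nope")
})

test_that("model edge sets nest: contact within short within mid within long", {
  for (seed in 1:4) {
    sim <- generateSynthetic(synthConfig(nNeurons = 60L, nNPP = 8L,
                                         nGPCR = 8L, nBundles = 8L,
                                         seed = seed))
    mats <- lapply(c("contact", "short", "mid", "long"),
                   spatialPredicateMatrix, ann = sim$ann)
    expect_true(all(mats[[1]] <= mats[[2]]))
    expect_true(all(mats[[2]] <= mats[[3]]))
    expect_true(all(mats[[3]] <= mats[[4]]))
  }
})

test_that("spatial filtering matches a per-pair brute-force re-filter", {
  sim <- generateSynthetic(synthConfig(nNeurons = 40L, nNPP = 5L,
                                       nGPCR = 5L, nBundles = 6L, seed = 3))
  cps <- couplesAtThreshold(sim$interactions)
  cp <- cps[1, ]
  long <- buildPairNetwork(sim$expr, cp)
  expect_identical(applySpatialFilter(long, "long", sim$ann)@adjacency,
                   long@adjacency)
  for (m in c("mid", "short", "contact")) {
    filt <- applySpatialFilter(long, m, sim$ann)
    P <- spatialPredicateMatrix(sim$ann, m)
    for (idx in which(long@adjacency)) {
      i <- (idx - 1) %% 40 + 1
      j <- (idx - 1) %/% 40 + 1
      expect_identical(filt@adjacency[i, j],
                       long@adjacency[i, j] && P[i, j])
    }
  }
  # a self-loop always survives filtering
  X <- expressed(sim$expr)
  co <- which(X[cp$npp, ] & X[cp$gpcr, ])
  for (i in co)
    expect_true(applySpatialFilter(long, "contact",
                                   sim$ann)@adjacency[i, i])
})

test_that("aggregation sums couple networks and conserves edge counts", {
  nm <- c("A", "B", "C")
  X <- matrix(FALSE, 2, 3, dimnames = list(c("g1", "g2"), nm))
  X["g1", 1] <- TRUE; X["g2", 2] <- TRUE
  expr <- toyExpression(X)
  net <- buildPairNetwork(expr, list(npp = "g1", gpcr = "g2"))
  agg <- aggregateNetworks(list(net, net))
  expect_identical(adjacency(agg)["A", "B"], 2L)
  expect_identical(sum(adjacency(agg)), 2L)
  # empty list -> zero matrix
  agg0 <- aggregateNetworks(list(), model = "short", dim = 3,
                            neuronNames = nm)
  expect_identical(sum(adjacency(agg0)), 0L)
  # weight conservation on a synthetic run
  sim <- generateSynthetic(synthConfig(nNeurons = 50L, seed = 9))
  cps <- couplesAtThreshold(sim$interactions)
  nets <- lapply(seq_len(nrow(cps)), function(i)
    applySpatialFilter(buildPairNetwork(sim$expr, cps[i, ]), "short",
                       sim$ann))
  aggS <- aggregateNetworks(nets, "short")
  expect_identical(sum(adjacency(aggS)),
                   sum(vapply(nets, function(x) sum(x@adjacency), 1L)))
  # mixed models refuse to aggregate
  netMid <- net
  netMid@model <- "mid"
  expect_error(aggregateNetworks(list(net, netMid)), "share the model")
})

test_that("binarized aggregate density grows from short to mid to long", {
  sim <- generateSynthetic(synthConfig(nNeurons = 80L, seed = 21))
  cps <- couplesAtThreshold(sim$interactions)
  dens <- vapply(c("short", "mid", "long"), function(m) {
    nets <- lapply(seq_len(nrow(cps)), function(i)
      applySpatialFilter(buildPairNetwork(sim$expr, cps[i, ]), m, sim$ann))
    networkDensity(aggregateNetworks(nets, m))
  }, 1.0)
  expect_true(dens["short"] <= dens["mid"])
  expect_true(dens["mid"] <= dens["long"])
})

test_that("edge-weight histograms count couples per directed pair", {
  nm <- c("A", "B")
  W0 <- matrix(0L, 2, 2, dimnames = list(nm, nm))
  agg0 <- new("AggregateNetwork", model = "long", weights = W0,
              couples = data.frame())
  ew0 <- edgeWeightDistribution(agg0)
  expect_length(ew0$counts, 0L)
  X <- matrix(FALSE, 2, 2, dimnames = list(c("g1", "g2"), nm))
  X["g1", 1] <- TRUE; X["g2", 2] <- TRUE
  expr <- toyExpression(X)
  net <- buildPairNetwork(expr, list(npp = "g1", gpcr = "g2"))
  agg <- aggregateNetworks(rep(list(net), 4))
  ew <- edgeWeightDistribution(agg)
  expect_identical(ew$maxWeight, 4L)
  expect_identical(unname(ew$counts[4]), 1L)
  expect_identical(ew$argmax$pre, "A")
  expect_identical(ew$argmax$post, "B")
})

test_that("overlap with wired networks counts shared directed pairs", {
  nm <- c("A", "B", "C")
  W <- matrix(0L, 3, 3, dimnames = list(nm, nm))
  W["A", "B"] <- 2L; W["B", "C"] <- 1L
  agg <- new("AggregateNetwork", model = "short", weights = W,
             couples = data.frame(npp = c("x", "y"), gpcr = c("u", "v"),
                                  minEC50 = c(1e-9, 1e-9)))
  S <- matrix(0, 3, 3, dimnames = list(nm, nm))
  S["A", "B"] <- 5; S["B", "C"] <- 1
  syn <- new("WiredNetwork", name = "synaptic", adjacency = S,
             directed = TRUE)
  ov <- overlapWithWired(agg, syn)
  expect_identical(unname(ov["both"]), 2L)
  expect_identical(unname(ov["pept_only"]), 0L)
  S2 <- matrix(0, 3, 3, dimnames = list(nm, nm))
  S2["C", "A"] <- 1
  ov2 <- overlapWithWired(agg, new("WiredNetwork", name = "synaptic",
                                   adjacency = S2, directed = TRUE))
  expect_identical(unname(ov2["both"]), 0L)
})

test_that("component counting ignores non-participating neurons", {
  nm <- sprintf("n%d", 1:8)
  A <- matrix(FALSE, 8, 8, dimnames = list(nm, nm))
  A["n1", "n2"] <- TRUE
  A["n3", "n4"] <- TRUE
  net <- new("PairNetwork", npp = "a", gpcr = "b", minEC50 = 1e-9,
             model = "short", adjacency = A)
  expect_identical(countComponents(net), 2L)
  A["n2", "n3"] <- TRUE
  net@adjacency <- A
  expect_identical(countComponents(net), 1L)
  expect_identical(countComponents(matrix(FALSE, 3, 3)), 0L)
})
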