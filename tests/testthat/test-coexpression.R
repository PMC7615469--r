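test_that("enrichment p-values equal the Fisher exact test", {
  for (s in 1:40) {
    set.seed(s)
    N <- sample(20:60, 1)
    k1 <- sample(N - 1, 1)
    k2 <- sample(N - 1, 1)
    X <- matrix(FALSE, 2, N,
                dimnames = list(c("p", "r"), sprintf("n%02d", 1:N)))
    X["p", sample(N, k1)] <- TRUE
    X["r", sample(N, k2)] <- TRUE
    expr <- toyExpression(X)
    fe <- fisherEnrichment(expr, "p", "r")
    tab <- matrix(c(fe$n11, fe$n01, fe$n10, fe$n00), 2)
    expect_equal(fe$p,
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_identical(fe$n11 + fe$n10 + fe$n01 + fe$n00, N)
  }
})

test_that("enrichment handles degenerate and perfect-overlap tables", {
  nm <- sprintf("n%03d", 1:302)
  X <- matrix(FALSE, 2, 302, dimnames = list(c("p", "r"), nm))
  X["r", 1:20] <- TRUE
  expr <- toyExpression(X)
  expect_equal(fisherEnrichment(expr, "p", "r")$p, 1)  # gene in 0 neurons
  X["p", 1:20] <- TRUE
  fe <- fisherEnrichment(toyExpression(X), "p", "r")
  # exhaustive enumeration over all attainable tables with these margins
  enum <- sum(dhyper(20:20, 20, 282, 20))
  expect_equal(fe$p, enum, tolerance = 1e-12)
  expect_error(fisherEnrichment(expr, "absent", "r"), "absent")
})

test_that("calibrated enrichment p-values are uniform under independence", {
  sim <- generateSynthetic(synthConfig(seed = 31))
  X <- expressed(sim$expr)
  set.seed(99)
  ps <- replicate(400, {
    g <- sample(rownames(X), 2)
    fisherEnrichment(sim$expr, g[1], g[2], calibrated = TRUE)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment is monotone and nested in alpha", {
  sim <- generateSynthetic(synthConfig(nNeurons = 80L, seed = 37))
  ep <- enrichedPairs(sim$expr, sim$interactions, alpha = 0.2)
  tests <- ep$tests
  expect_true(all(tests$q >= tests$p - 1e-12))
  ord <- order(tests$p)
  expect_true(all(diff(tests$q[ord]) >= -1e-12))
  sig20 <- paste(ep$significant$npp, ep$significant$gpcr)
  ep05 <- enrichedPairs(sim$expr, sim$interactions, alpha = 0.05)
  sig05 <- paste(ep05$significant$npp, ep05$significant$gpcr)
  expect_true(all(sig05 %in% sig20))
  expect_equal(tests$q, unname(p.adjust(tests$p, "BH")))
})

test_that("all-null inputs return an empty significant set", {
  nm <- sprintf("n%02d", 1:40)
  X <- matrix(FALSE, 2, 40, dimnames = list(c("p1", "r1"), nm))
  X["p1", 1:39] <- TRUE   # near-saturated: enrichment impossible
  X["r1", 1:40] <- TRUE
  tab <- InteractionTable(data.frame(peptide = "x", npp = "p1",
                                     gpcr = "r1", ec50 = 1e-9))
  ep <- enrichedPairs(toyExpression(X), tab, alpha = 0.05)
  expect_identical(nrow(ep$significant), 0L)
})

test_that("planted co-expressed pairs are recovered with cognate flags", {
  sim <- generateSynthetic(synthConfig(enrichedPairCount = 8L, seed = 41))
  ep <- enrichedPairs(sim$expr, sim$interactions, alpha = 0.05)
  sigKey <- paste(ep$significant$npp, ep$significant$gpcr)
  gtKey <- paste(sim$groundTruth$enriched$npp, sim$groundTruth$enriched$gpcr)
  expect_gte(sum(gtKey %in% sigKey), 7L)
  # planted pairs are non-cognate by construction (decoy interactions only)
  planted <- ep$significant[paste(ep$significant$npp,
                                  ep$significant$gpcr) %in% gtKey, ]
  expect_true(all(!planted$cognate))
})

test_that("cascade networks link enriched pairs through activation", {
  single <- data.frame(npp = "P1", gpcr = "R1")
  tab <- InteractionTable(data.frame(peptide = "x", npp = "P1",
                                     gpcr = "R1", ec50 = 1e-9))
  cn <- cascadeNetwork(single, tab)
  expect_identical(cn$nEdges, 0L)
  two <- data.frame(npp = c("P1", "P2"), gpcr = c("R1", "R2"))
  tab2 <- InteractionTable(data.frame(
    peptide = c("x", "y"), npp = c("P1", "P1"), gpcr = c("R1", "R2"),
    ec50 = c(1e-9, 1e-9)))
  cn2 <- cascadeNetwork(two, tab2)
  expect_identical(cn2$nEdges, 1L)
  el <- igraph::as_edgelist(cn2$graph)
  expect_identical(el[1, ], c("P1~R1", "P2~R2"))
  # a chain of activations yields a single weak component
  chain <- data.frame(npp = c("P1", "P2", "P3"),
                      gpcr = c("R1", "R2", "R3"))
  tab3 <- InteractionTable(data.frame(
    peptide = c("a", "b", "c"), npp = c("P1", "P2", "P3"),
    gpcr = c("R2", "R3", "R1"), ec50 = rep(1e-9, 3)))
  cn3 <- cascadeNetwork(chain, tab3)
  expect_true(cn3$connected)
})

test_that("autocrine profiles flag exactly the co-expressing neurons", {
  nm <- sprintf("n%02d", 1:30)
  X <- matrix(FALSE, 4, 30,
              dimnames = list(c("p1", "r1", "p2", "r2"), nm))
  X["p1", 1:10] <- TRUE
  X["r1", 6:15] <- TRUE          # co-expressed in 6..10
  X["p2", 20] <- TRUE            # precursor without its receptor
  expr <- toyExpression(X)
  couples <- data.frame(npp = c("p1", "p2"), gpcr = c("r1", "r2"),
                        minEC50 = c(1e-9, 1e-9))
  ap <- autocrineProfiles(expr, couples)
  expect_identical(ap$perNeuron$count[6:10], rep(1L, 5))
  expect_identical(ap$perNeuron$count[20], 0L)
  expect_equal(ap$fractionAutocrine, 5 / 30)
  expect_true(all(ap$perNeuron$count <= nrow(couples)))
  expect_equal(mean(ap$perNeuron$count > 0), ap$fractionAutocrine)
  expect_identical(ap$perCouple$nNeurons, c(5L, 0L))
})

test_that("planted autocrine loops are recovered exactly", {
  sim <- generateSynthetic(synthConfig(autocrineNeurons = 15L,
                                       excludeBackgroundAutocrine = TRUE,
                                       seed = 43))
  ap <- autocrineProfiles(sim$expr, couplesAtThreshold(sim$interactions))
  flagged <- ap$perNeuron$neuron[ap$perNeuron$count > 0]
  expect_setequal(flagged, sim$groundTruth$autocrineNeurons)
})

test_that("autocrine-degree correlations detect proportionality", {
  sim <- generateSynthetic(synthConfig(nNeurons = 60L, seed = 47))
  cps <- couplesAtThreshold(sim$interactions)
  ap <- autocrineProfiles(sim$expr, cps)
  cnt <- ap$perNeuron$count
  dt <- data.frame(neuron = ap$perNeuron$neuron, kIn = 2L * cnt,
                   kOut = 0L, k = 2L * cnt)
  res <- autocrineDegreeCorrelation(ap, list(prop = dt), nPerm = 200,
                                    seed = 1)
  rK <- res$r[res$measure == "k"]
  expect_equal(rK, 1)
  expect_lt(res$permP[res$measure == "k"], 0.05)
})
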