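test_that("topology classes follow the 50-neuron breadth rule", {
  nm <- sprintf("n%03d", 1:120)
  mk <- function(nN, nG) {
    X <- matrix(FALSE, 2, 120, dimnames = list(c("p", "r"), nm))
    X["p", seq_len(nN)] <- TRUE
    X["r", seq_len(nG)] <- TRUE
    toyExpression(X)
  }
  cp <- list(npp = "p", gpcr = "r")
  expect_identical(classifyTopology(mk(50, 50), cp)$class, "local")
  expect_identical(classifyTopology(mk(51, 51), cp)$class, "pervasive")
  expect_identical(classifyTopology(mk(5, 51), cp)$class, "broadcaster")
  expect_identical(classifyTopology(mk(51, 5), cp)$class, "integrative")
})

test_that("classification partitions the couple set", {
  sim <- generateSynthetic(synthConfig(seed = 13))
  cps <- couplesAtThreshold(sim$interactions)
  tc <- classifyAllCouples(sim$expr, cps)
  expect_identical(nrow(tc), nrow(cps))
  expect_true(all(tc$class %in% c("local", "pervasive", "broadcaster",
                                  "integrative")))
  expect_identical(sum(table(tc$class)), nrow(cps))
})

test_that("planted broadcaster and integrative couples classify correctly", {
  sim <- generateSynthetic(synthConfig(broadcasterCouples = 2L,
                                       integrativeCouples = 2L, seed = 17))
  gt <- sim$groundTruth
  for (i in seq_len(2))
    expect_identical(classifyTopology(sim$expr, gt$broadcasters[i, ])$class,
                     "broadcaster")
  for (i in seq_len(2))
    expect_identical(classifyTopology(sim$expr, gt$integrative[i, ])$class,
                     "integrative")
})

test_that("exclusive couples are one-to-one at the active threshold", {
  tab <- InteractionTable(data.frame(
    peptide = c("a", "b", "c"),
    npp = c("P1", "P1", "P2"), gpcr = c("R1", "R2", "R3"),
    ec50 = rep(1e-9, 3)))
  ex <- exclusiveCouples(tab)
  expect_identical(nrow(ex), 1L)
  expect_identical(ex$npp, "P2")
  expect_identical(ex$gpcr, "R3")
  empty <- InteractionTable(data.frame(peptide = character(),
                                       npp = character(),
                                       gpcr = character(),
                                       ec50 = numeric()))
  expect_identical(nrow(exclusiveCouples(empty)), 0L)
})

test_that("minimal range picks the smallest sufficient diffusion class", {
  ann <- toyAnnotation()
  nm <- ann@neuron
  mk <- function(nppNeurons, gpcrNeurons) {
    X <- matrix(FALSE, 2, length(nm), dimnames = list(c("p", "r"), nm))
    X["p", nppNeurons] <- TRUE
    X["r", gpcrNeurons] <- TRUE
    toyExpression(X)
  }
  cp <- list(npp = "p", gpcr = "r")
  # receptor on r2 shares stratum 1 with ligand on r1
  mr <- minimalRange(mk("r1", "r2"), cp, ann, "receiver_view")
  expect_identical(unname(mr["r2"]), "contact_stratum")
  # receptor on r3 (stratum 3) vs ligand on r1 (stratum 1): same bundle,
  # different strata -> short
  mr <- minimalRange(mk("r1", "r3"), cp, ann, "receiver_view")
  expect_identical(unname(mr["r3"]), "short")
  # thin shared bundle -> contact_thin_bundle
  mr <- minimalRange(mk("v1", "v2"), cp, ann, "receiver_view")
  expect_identical(unname(mr["v2"]), "contact_thin_bundle")
  # pharyngeal receiver of a nerve-ring ligand -> mid
  mr <- minimalRange(mk("r1", "p1"), cp, ann, "receiver_view")
  expect_identical(unname(mr["p1"]), "mid")
  # cross-region -> long; absent partner -> unreachable
  mr <- minimalRange(mk("r1", "t1"), cp, ann, "receiver_view")
  expect_identical(unname(mr["t1"]), "long")
  mr <- minimalRange(mk(character(0), "t1"), cp, ann, "receiver_view")
  expect_identical(unname(mr["t1"]), "unreachable")
})

test_that("minimal range matches a brute-force predicate search", {
  sim <- generateSynthetic(synthConfig(nNeurons = 50L, nNPP = 6L,
                                       nGPCR = 6L, nBundles = 7L,
                                       seed = 23))
  ann <- sim$ann
  cps <- couplesAtThreshold(sim$interactions)
  cp <- cps[1, ]
  mr <- minimalRange(sim$expr, cp, ann, "receiver_view")
  X <- expressed(sim$expr)
  partners <- which(X[cp$npp, ])
  mats <- lapply(c(short = "short", mid = "mid"),
                 spatialPredicateMatrix, ann = ann)
  n <- length(ann@neuron)
  S <- matrix(FALSE, n, 4L)
  for (i in seq_len(n)) S[i, ann@strata[[i]][ann@strata[[i]] <= 4L]] <- TRUE
  for (foc in names(mr)) {
    i <- match(foc, ann@neuron)
    classes <- vapply(partners, function(j) {
      shareStr <- any(S[i, ] & S[j, ]) || (i == j && any(S[i, ]))
      thin <- intersect(setdiff(ann@bundles[[i]], "nerve_ring"),
                        setdiff(ann@bundles[[j]], "nerve_ring"))
      pharOK <- ann@inPharynx[i] == ann@inPharynx[j]
      if (shareStr && (pharOK || i == j)) return(1L)
      if (length(thin) > 0 && (pharOK || i == j)) return(2L)
      if (i == j) return(2L)
      if (mats$short[i, j]) return(3L)
      if (mats$mid[i, j]) return(4L)
      5L
    }, 1L)
    expect_identical(unname(rankRange(mr[foc])), min(classes))
  }
})

test_that("merging regions never increases the minimal class", {
  sim <- generateSynthetic(synthConfig(nNeurons = 50L, nNPP = 6L,
                                       nGPCR = 6L, seed = 29))
  cps <- couplesAtThreshold(sim$interactions)
  cp <- cps[2, ]
  before <- minimalRange(sim$expr, cp, sim$ann, "receiver_view")
  merged <- sim$ann
  merged@region[merged@region == "midbody"] <- "head"
  after <- minimalRange(sim$expr, cp, merged, "receiver_view")
  expect_true(all(rankRange(after) <= rankRange(before)))
})

test_that("range summaries count genes needing more than contact or short", {
  allContact <- list(g1 = c(a = "contact_stratum"),
                     g2 = c(b = "contact_thin_bundle"))
  rs <- rangeSummary(allContact)
  expect_identical(rs$beyondContact, 0L)
  expect_identical(rs$beyondShort, 0L)
  mixed <- list(g1 = c(a = "contact_stratum", b = "short"),
                g2 = c(c = "mid"),
                g3 = c(d = "unreachable"))
  rs2 <- rangeSummary(mixed)
  expect_identical(rs2$beyondContact, 3L)
  expect_identical(rs2$beyondShort, 2L)
})
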