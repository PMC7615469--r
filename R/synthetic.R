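## Synthetic nervous systems with known ground truth. The generator
## emulates the statistical shape of the three real inputs -- binary
## expression with log-normal-like per-gene breadth, a peptide-receptor
## screen with log-uniform EC50s, promiscuous receptors and versatile
## ligands, and bundle/region/strata anatomy -- and can plant motifs
## (broadcaster/integrative couples, a rich-club hub set, enriched
## co-expressed pairs, autocrine loops) whose downstream signatures are
## recorded as ground truth.

#' Configuration for the synthetic generator
#'
#' Defaults mirror the scale of the real datasets: 302 neurons, 55
#' precursor and 56 receptor genes, around 150 gene couples carrying
#' around 460 peptide-level entries, EC50s log-uniform from 1 pM to 1 mM
#' (about 60 percent of couples fall at or below 500 nM), 27 bundles in
#' three body regions and a four-stratum nerve ring.
#'
#' @param nNeurons roster size.
#' @param nNPP,nGPCR background gene counts.
#' @param breadthMeanlog,breadthSdlog log-normal parameters of the
#'   per-gene expressing-neuron count (rounded, clipped to 1..nNeurons).
#' @param ec50Log10Range log10 molar range of couple-level EC50s.
#' @param entryEC50Jitter SD (log10) of peptide-level entries around their
#'   couple's EC50.
#' @param ligandsPerReceptorLambda receptor promiscuity: ligand count is
#'   1 + Poisson(lambda).
#' @param entriesPerCoupleLambda peptide entries per couple: 1 +
#'   Poisson(lambda).
#' @param nBundles,nStrata anatomy vocabulary sizes (pharynx and nerve
#'   ring are two of the bundles).
#' @param regionProps named proportions for head/midbody/tail.
#' @param extraBundleProb probability a neuron joins one extra bundle.
#' @param nerveRingWeight sampling weight multiplier for the nerve-ring
#'   bundle (most real neurons project into the nerve ring, so its
#'   occupancy far exceeds that of other fascicles).
#' @param pharynxFrac fraction of neurons in the pharynx.
#' @param broadcasterCouples,integrativeCouples planted couple counts.
#' @param plantedNarrow,plantedBroad breadths for planted couples
#'   (restricted and broad sides; broad defaults to
#'   max(51, 40 percent of neurons)).
#' @param richClubSize,richClubDensity planted hub set size h and target
#'   hub-hub connection density.
#' @param enrichedPairCount,enrichedOverlap planted co-expressed pairs and
#'   their shared neuron count.
#' @param autocrineNeurons neurons carrying a planted autocrine loop.
#' @param excludeBackgroundAutocrine strip chance cognate co-expression so
#'   planted autocrine loops are the only ones (used for exact-recovery
#'   experiments; incompatible with a planted rich club).
#' @param seed integer, mandatory.
#' @return list of class \code{synthConfig}.
#' @export
synthConfig <- function(nNeurons = 302L, nNPP = 55L, nGPCR = 56L,
                        breadthMeanlog = log(15), breadthSdlog = 1,
                        ec50Log10Range = c(-12, -3),
                        entryEC50Jitter = 0.3,
                        ligandsPerReceptorLambda = 1.6,
                        entriesPerCoupleLambda = 2.1,
                        nBundles = 27L, nStrata = 4L,
                        regionProps = c(head = 0.60, midbody = 0.15,
                                        tail = 0.25),
                        extraBundleProb = 0.3,
                        nerveRingWeight = 10,
                        pharynxFrac = 20 / 302,
                        broadcasterCouples = 0L, integrativeCouples = 0L,
                        plantedNarrow = 5L, plantedBroad = NULL,
                        richClubSize = 0L, richClubDensity = 0.9,
                        enrichedPairCount = 0L, enrichedOverlap = 20L,
                        autocrineNeurons = 0L,
                        excludeBackgroundAutocrine = FALSE,
                        seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (is.null(plantedBroad))
    plantedBroad <- max(51L, round(0.4 * nNeurons))
  cfg <- as.list(environment())
  if ((broadcasterCouples + integrativeCouples) > 0 &&
      plantedBroad >= nNeurons)
    stop("planted broad breadth exceeds the roster size")
  if (richClubSize >= nNeurons)
    stop("planted rich club exceeds the roster size")
  if (autocrineNeurons > nNeurons || enrichedOverlap > nNeurons)
    stop("planted motif demands exceed the roster size")
  class(cfg) <- "synthConfig"
  cfg
}

.breadthDraw <- function(n, cfg) {
  pmin(cfg$nNeurons,
       pmax(1L, round(rlnorm(n, cfg$breadthMeanlog, cfg$breadthSdlog))))
}

#' Generate a synthetic nervous system
#'
#' Produces an expression matrix, interaction table and anatomy loadable
#' by the package readers, plus a ground-truth record of every planted
#' motif. Byte-identical given the same config (the seed is part of the
#' config).
#'
#' @param cfg a [synthConfig()].
#' @return list with \code{roster}, \code{expr}
#'   (\linkS4class{PeptideExpression}), \code{interactions}
#'   (\linkS4class{InteractionTable}), \code{ann}
#'   (\linkS4class{NeuronAnnotation}), \code{groundTruth}, \code{config}.
#' @export
generateSynthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthConfig"))
  set.seed(cfg$seed)
  n <- cfg$nNeurons

  ## --- roster: mostly bilateral classes, a pharyngeal compartment ----
  nPhar <- round(n * cfg$pharynxFrac)
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, if (runif(1) < 0.8 && sum(sizes) + 2L <= n) 2L else 1L)
  }
  cls <- rep(sprintf("c%03d", seq_along(sizes)), sizes)
  suffix <- unlist(lapply(sizes, function(s) if (s == 2L) c("L", "R") else ""))
  nm <- paste0(cls, suffix)
  phar <- seq_len(n) <= nPhar
  typePool <- c("sensory", "interneuron", "motor")
  classType <- setNames(sample(typePool, length(sizes), replace = TRUE),
                        sprintf("c%03d", seq_along(sizes)))
  type <- unname(classType[cls])
  type[phar] <- "pharyngeal"
  roster <- NeuronRoster(nm, classOf = cls, typeOf = type)

  ## --- anatomy -------------------------------------------------------
  bundleNames <- c("pharynx", "nerve_ring",
                   sprintf("b%02d", seq_len(max(cfg$nBundles - 2L, 0L)) + 2L))
  bundleRegion <- setNames(c("head", "head",
                             sample(names(cfg$regionProps),
                                    length(bundleNames) - 2L, replace = TRUE,
                                    prob = cfg$regionProps)),
                           bundleNames)
  somatic <- setdiff(bundleNames, "pharynx")
  regionWeight <- cfg$regionProps[bundleRegion[somatic]] /
    table(bundleRegion[somatic])[bundleRegion[somatic]]
  regionWeight[somatic == "nerve_ring"] <-
    regionWeight[somatic == "nerve_ring"] * cfg$nerveRingWeight
  bundles <- vector("list", n)
  strata <- vector("list", n)
  region <- character(n)
  for (i in seq_len(n)) {
    if (phar[i]) {
      bundles[[i]] <- "pharynx"
      region[i] <- "head"
      strata[[i]] <- integer(0)
      next
    }
    primary <- sample(somatic, 1L, prob = regionWeight)
    bs <- primary
    if (runif(1) < cfg$extraBundleProb) {
      sameRegion <- setdiff(somatic[bundleRegion[somatic] ==
                                    bundleRegion[primary]], primary)
      if (length(sameRegion)) bs <- c(bs, sample(sameRegion, 1L))
    }
    bundles[[i]] <- bs
    region[i] <- unname(bundleRegion[primary])
    strata[[i]] <- if ("nerve_ring" %in% bs)
      sort(sample(seq_len(cfg$nStrata), sample(1:2, 1L))) else integer(0)
  }
  ann <- NeuronAnnotation(neuron = nm, bundles = bundles, region = region,
                          strata = strata, bundleUniverse = bundleNames)

  ## --- background expression ----------------------------------------
  nppGenes <- sprintf("npp%03d", seq_len(cfg$nNPP))
  gpcrGenes <- sprintf("gpcr%03d", seq_len(cfg$nGPCR))
  genes <- c(nppGenes, gpcrGenes)
  X <- matrix(FALSE, length(genes), n, dimnames = list(genes, nm))
  breadth <- .breadthDraw(length(genes), cfg)
  for (g in seq_along(genes))
    X[g, sample(n, breadth[g])] <- TRUE

  ## --- background interactions (promiscuity via preferential
  ##     attachment so some ligands become versatile) ------------------
  entries <- list()
  nppWeight <- rep(1, cfg$nNPP)
  for (r in seq_len(cfg$nGPCR)) {
    nLig <- min(cfg$nNPP, 1L + rpois(1L, cfg$ligandsPerReceptorLambda))
    ligs <- sample(cfg$nNPP, nLig, prob = nppWeight)
    nppWeight[ligs] <- nppWeight[ligs] + 1
    for (l in ligs) {
      base <- runif(1, cfg$ec50Log10Range[1], cfg$ec50Log10Range[2])
      nEnt <- 1L + rpois(1L, cfg$entriesPerCoupleLambda)
      for (pep in seq_len(nEnt)) {
        entries[[length(entries) + 1L]] <- data.frame(
          peptide = sprintf("%s_p%d", nppGenes[l], pep),
          npp = nppGenes[l], gpcr = gpcrGenes[r],
          ec50 = 10^(base + rnorm(1L, 0, cfg$entryEC50Jitter)))
      }
    }
  }
  entries <- do.call(rbind, entries)

  gt <- list(broadcasters = data.frame(npp = character(),
                                       gpcr = character()),
             integrative = data.frame(npp = character(),
                                      gpcr = character()),
             richClub = character(0),
             enriched = data.frame(npp = character(), gpcr = character()),
             autocrineNeurons = character(0),
             plantedGenes = character(0))

  addGene <- function(name, neuronsExpr) {
    row <- matrix(FALSE, 1L, n, dimnames = list(name, nm))
    row[1L, neuronsExpr] <- TRUE
    X <<- rbind(X, row)
    gt$plantedGenes <<- c(gt$plantedGenes, name)
  }
  addEntry <- function(npp, gpcr, ec50, peptide = paste0(npp, "_p1")) {
    entries <<- rbind(entries, data.frame(peptide = peptide, npp = npp,
                                          gpcr = gpcr, ec50 = ec50))
  }

  ## --- planted broadcaster / integrative couples ---------------------
  plantCouple <- function(idx, kind) {
    nppName <- sprintf("npp_%s%02d", substr(kind, 1, 4), idx)
    gpcrName <- sprintf("gpcr_%s%02d", substr(kind, 1, 4), idx)
    narrow <- sample(n, cfg$plantedNarrow)
    broad <- sample(n, cfg$plantedBroad)
    if (kind == "broadcaster") {
      addGene(nppName, narrow)
      addGene(gpcrName, broad)
    } else {
      addGene(nppName, broad)
      addGene(gpcrName, narrow)
    }
    addEntry(nppName, gpcrName, 1e-9)
    data.frame(npp = nppName, gpcr = gpcrName)
  }
  if (cfg$broadcasterCouples > 0)
    gt$broadcasters <- do.call(rbind, lapply(seq_len(cfg$broadcasterCouples),
                                             plantCouple,
                                             kind = "broadcaster"))
  if (cfg$integrativeCouples > 0)
    gt$integrative <- do.call(rbind, lapply(seq_len(cfg$integrativeCouples),
                                            plantCouple,
                                            kind = "integrative"))

  ## --- planted enriched co-expression pairs --------------------------
  if (cfg$enrichedPairCount > 0) {
    for (i in seq_len(cfg$enrichedPairCount)) {
      shared <- sample(n, cfg$enrichedOverlap)
      nppName <- sprintf("npp_enr%02d", i)
      gpcrName <- sprintf("gpcr_enr%02d", i)
      addGene(nppName, shared)
      addGene(gpcrName, shared)
      # weak decoy interactions put both genes in the tested universe
      # without creating a couple at the usual potency threshold
      addEntry(nppName, sample(gpcrGenes, 1L), 1e-4)
      addEntry(sample(nppGenes, 1L), gpcrName, 1e-4)
      gt$enriched <- rbind(gt$enriched,
                           data.frame(npp = nppName, gpcr = gpcrName))
    }
  }

  ## --- planted autocrine loops ---------------------------------------
  if (cfg$autocrineNeurons > 0) {
    loops <- sample(n, cfg$autocrineNeurons)
    addGene("npp_auto01", loops)
    addGene("gpcr_auto01", loops)
    addEntry("npp_auto01", "gpcr_auto01", 1e-9)
    gt$autocrineNeurons <- nm[sort(loops)]
  }

  sim <- list(roster = roster,
              expr = PeptideExpression(X, roster),
              interactions = InteractionTable(entries),
              ann = ann, groundTruth = gt, config = cfg)

  if (cfg$richClubSize > 0)
    sim <- plantRichClub(sim, cfg$richClubSize, cfg$richClubDensity)

  if (cfg$excludeBackgroundAutocrine)
    sim <- .stripBackgroundAutocrine(sim)
  sim
}

#' Plant a rich club of densely inter-wired hubs
#'
#' Designates h non-pharyngeal neurons as hubs, gives them a shared
#' nerve-ring stratum (so the wiring survives every diffusion model) and
#' adds cognate couples whose precursor and receptor are each expressed in
#' random 75-percent subsets of the hubs; enough couples are added for the
#' expected hub-to-hub connection probability to reach
#' \code{wiringDensity}.
#'
#' @param sim a [generateSynthetic()] result.
#' @param h hub count (0 returns the input unchanged).
#' @param wiringDensity target hub-hub density in (0, 1).
#' @return the modified simulation, with \code{groundTruth$richClub} set.
#' @export
plantRichClub <- function(sim, h, wiringDensity = 0.9) {
  if (h == 0) return(sim)
  cfg <- sim$config
  n <- cfg$nNeurons
  if (h >= n) stop("rich club exceeds the roster size")
  nm <- neurons(sim$roster)
  eligible <- which(!sim$ann@inPharynx)
  if (length(eligible) < h)
    stop("not enough non-pharyngeal neurons for the planted rich club")
  hubs <- sort(sample(eligible, h))
  ## anatomy: hubs join the nerve ring and share stratum 1
  ann <- sim$ann
  for (i in hubs) {
    if (!"nerve_ring" %in% ann@bundles[[i]])
      ann@bundles[[i]] <- c(ann@bundles[[i]], "nerve_ring")
    ann@strata[[i]] <- sort(unique(c(ann@strata[[i]], 1L)))
    ann@region[i] <- "head"
  }
  ## wiring genes: per couple, npp and gpcr each in a random 75% subset
  q <- 0.75
  pPer <- q * q
  m <- max(1L, ceiling(log(1 - wiringDensity) / log(1 - pPer)))
  X <- expressed(sim$expr)
  entries <- interactionEntries(sim$interactions)
  sub <- max(2L, round(q * h))
  nppSets <- lapply(seq_len(m), function(c) sample(hubs, sub))
  gpcrSets <- lapply(seq_len(m), function(c) sample(hubs, sub))
  # every hub must express at least one planted ligand and one planted
  # receptor, otherwise its degree is not guaranteed to exceed background
  for (i in hubs) {
    if (!any(vapply(nppSets, function(s) i %in% s, TRUE))) {
      c <- sample(m, 1L)
      nppSets[[c]] <- c(nppSets[[c]], i)
    }
    if (!any(vapply(gpcrSets, function(s) i %in% s, TRUE))) {
      c <- sample(m, 1L)
      gpcrSets[[c]] <- c(gpcrSets[[c]], i)
    }
  }
  for (c in seq_len(m)) {
    nppName <- sprintf("npp_hub%02d", c)
    gpcrName <- sprintf("gpcr_hub%02d", c)
    rowN <- matrix(FALSE, 1L, n, dimnames = list(nppName, nm))
    rowG <- matrix(FALSE, 1L, n, dimnames = list(gpcrName, nm))
    rowN[1L, nppSets[[c]]] <- TRUE
    rowG[1L, gpcrSets[[c]]] <- TRUE
    X <- rbind(X, rowN, rowG)
    entries <- rbind(entries,
                     data.frame(peptide = paste0(nppName, "_p1"),
                                npp = nppName, gpcr = gpcrName,
                                ec50 = 1e-9))
    sim$groundTruth$plantedGenes <- c(sim$groundTruth$plantedGenes,
                                      nppName, gpcrName)
  }
  sim$ann <- ann
  sim$expr <- PeptideExpression(X, sim$roster)
  sim$interactions <- InteractionTable(entries)
  sim$groundTruth$richClub <- nm[hubs]
  sim
}

# Remove chance cognate co-expression (keeps planted autocrine loops):
# for every couple at the default threshold, receptor expression is
# cleared in neurons that express the couple's precursor.
.stripBackgroundAutocrine <- function(sim) {
  X <- expressed(sim$expr)
  cps <- couplesAtThreshold(sim$interactions, 5e-7)
  keepKey <- c("npp_auto01~gpcr_auto01")
  for (i in seq_len(nrow(cps))) {
    if (paste(cps$npp[i], cps$gpcr[i], sep = "~") %in% keepKey) next
    both <- X[cps$npp[i], ] & X[cps$gpcr[i], ]
    X[cps$gpcr[i], both] <- FALSE
  }
  sim$expr <- PeptideExpression(X, sim$roster)
  sim
}

#' Write the synthetic inputs as delimited text
#'
#' Emits expression.csv, interactions.csv, anatomy.csv and
#' ground_truth.json under \code{dir}; the CSVs round-trip through the
#' package readers.
#'
#' @param sim a [generateSynthetic()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticInputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveExpression(sim$expr, file.path(dir, "expression.csv"))
  saveInteractions(sim$interactions, file.path(dir, "interactions.csv"))
  saveAnnotations(sim$ann, file.path(dir, "anatomy.csv"))
  jsonlite::write_json(sim$groundTruth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
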