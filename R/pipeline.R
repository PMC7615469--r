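## End-to-end orchestration: build -> metrics -> rich club -> classify ->
## mesoscale -> co-expression -> autocrine, with a machine-readable report.

#' Assemble a pipeline configuration
#'
#' @param expression a \linkS4class{PeptideExpression} or a path to an
#'   expression CSV.
#' @param interactions an \linkS4class{InteractionTable} or a path.
#' @param anatomy a \linkS4class{NeuronAnnotation} or a path.
#' @param roster a \linkS4class{NeuronRoster} (required when any input is
#'   a path; defaults to [defaultRoster()]).
#' @param ec50Max EC50 threshold in molar (default 500 nM).
#' @param model diffusion model for the aggregate.
#' @param nNull,swapsPerEdge rich-club null-ensemble settings.
#' @param perplexity mesoscale embedding perplexity.
#' @param alpha co-expression FDR level.
#' @param seed master seed; stage seeds are derived from it.
#' @param runRichClub,runMesoscale logical switches for the expensive
#'   stages.
#' @return list of class \code{npnRunConfig}.
#' @export
runConfig <- function(expression, interactions, anatomy, roster = NULL,
                      ec50Max = 5e-7, model = "short", nNull = 100L,
                      swapsPerEdge = 10L, perplexity = 30, alpha = 0.05,
                      seed = 42L, runRichClub = TRUE, runMesoscale = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "npnRunConfig"
  cfg
}

.resolveInputs <- function(cfg) {
  roster <- cfg$roster
  if (is.null(roster)) {
    roster <- if (is(cfg$expression, "PeptideExpression")) {
      nm <- neurons(cfg$expression)
      NeuronRoster(nm, classOf = colData(cfg$expression)$class,
                   typeOf = colData(cfg$expression)$type)
    } else {
      defaultRoster()
    }
  }
  expr <- if (is.character(cfg$expression))
    loadExpression(cfg$expression, roster) else cfg$expression
  inter <- if (is.character(cfg$interactions))
    loadInteractions(cfg$interactions) else cfg$interactions
  ann <- if (is.character(cfg$anatomy))
    loadAnnotations(cfg$anatomy, roster) else cfg$anatomy
  list(roster = roster, expr = expr, interactions = inter, ann = ann)
}

.tryStage <- function(name, report, fun) {
  res <- tryCatch(fun(), error = function(e) {
    warning("stage '", name, "' failed: ", conditionMessage(e))
    list(.failed = conditionMessage(e))
  })
  report$stages[[name]] <- res
  report
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order; a failure in one analysis
#' stage is logged in the report and does not abort independent stages.
#'
#' @param cfg a [runConfig()].
#' @return list of class \code{npnRunReport}: echoed parameters, per-stage
#'   results, and seeds.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "npnRunConfig"))
  inputs <- .resolveInputs(cfg)
  report <- list(parameters = list(ec50Max = cfg$ec50Max, model = cfg$model,
                                   nNull = cfg$nNull,
                                   swapsPerEdge = cfg$swapsPerEdge,
                                   perplexity = cfg$perplexity,
                                   alpha = cfg$alpha, seed = cfg$seed),
                 stages = list())
  couples <- couplesAtThreshold(inputs$interactions, cfg$ec50Max)
  report$stages$couples <- list(n = nrow(couples))

  nets <- lapply(seq_len(nrow(couples)), function(i)
    applySpatialFilter(buildPairNetwork(inputs$expr, couples[i, ]),
                       cfg$model, inputs$ann))
  agg <- aggregateNetworks(nets, cfg$model,
                           dim = length(neurons(inputs$roster)),
                           neuronNames = neurons(inputs$roster))
  report <- .tryStage("metrics", report, function() {
    m <- networkMetrics(agg)
    m$components <- vapply(nets, countComponents, 1L)
    m$singleComponent <- sum(m$components == 1L)
    m
  })
  report <- .tryStage("weights", report, function() {
    ew <- edgeWeightDistribution(agg)
    list(counts = ew$counts, maxWeight = ew$maxWeight)
  })
  degrees <- degreeTable(agg)
  report$stages$degrees <- list(
    meanK = mean(degrees$k),
    top10 = degrees$neuron[order(-degrees$k)][1:min(10, nrow(degrees))])

  if (cfg$runRichClub)
    report <- .tryStage("richClub", report, function() {
      rc <- richClub(binarize(agg), nNull = cfg$nNull,
                     swapsPerEdge = cfg$swapsPerEdge, seed = cfg$seed)
      list(onsetK = rc@onsetK, nMembers = length(rc@members),
           members = richClubMembers(rc),
           clubDensity = if (length(rc@members) >= 2)
             subnetworkDensity(binarize(agg), rc@members) else NA_real_)
    })

  report <- .tryStage("topologyClasses", report, function() {
    tc <- classifyAllCouples(inputs$expr, couples)
    list(counts = table(tc$class), table = tc)
  })

  if (cfg$runMesoscale)
    report <- .tryStage("mesoscale", report, function() {
      Y <- embedNetwork(agg, method = "tsne", perplexity = cfg$perplexity,
                        seed = cfg$seed)
      labels <- suppressWarnings(clusterEmbedding(Y))
      gs <- tryCatch(suppressWarnings(groupStatistics(labels, degrees)),
                     error = function(e) NULL)
      list(labels = setNames(as.character(labels), names(labels)),
           sizes = table(labels),
           omnibusP = if (!is.null(gs)) gs$omnibus$p else NA_real_)
    })

  report <- .tryStage("coexpression", report, function() {
    ep <- enrichedPairs(inputs$expr, inputs$interactions,
                        alpha = cfg$alpha, ec50Max = cfg$ec50Max)
    list(nTested = nrow(ep$tests), nSignificant = nrow(ep$significant),
         fracCognate = if (nrow(ep$significant))
           mean(ep$significant$cognate) else NA_real_)
  })

  report <- .tryStage("autocrine", report, function() {
    ap <- autocrineProfiles(inputs$expr, couples)
    list(fractionAutocrine = ap$fractionAutocrine, byType = ap$byType)
  })

  class(report) <- "npnRunReport"
  report
}

#' Write a pipeline report as JSON and hash its deterministic sections
#'
#' @param report a [runPipeline()] result.
#' @param path output JSON path.
#' @return named character: md5 hash of the written file.
#' @export
writeRunReport <- function(report, path) {
  rep2 <- unclass(report)
  # drop bulky per-neuron tables from the serialized form
  rep2$stages$topologyClasses$table <- NULL
  jsonlite::write_json(rep2, path, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  tools::md5sum(path)
}

#' Sensitivity comparison across EC50 thresholds and diffusion models
#'
#' @param cfg a [runConfig()].
#' @param ec50Values EC50 thresholds (molar) to compare.
#' @param models diffusion models to compare.
#' @return data.frame: ec50Max, model, nCouples, density, meanDegree,
#'   richClubSize.
#' @export
sensitivityRun <- function(cfg, ec50Values = c(5e-7, 1e-7),
                           models = c("short", "mid")) {
  rows <- list()
  for (ec in ec50Values) for (md in models) {
    sub <- cfg
    sub$ec50Max <- ec
    sub$model <- md
    sub$runMesoscale <- FALSE
    rep <- suppressWarnings(runPipeline(sub))
    rc <- rep$stages$richClub
    rows[[length(rows) + 1L]] <- data.frame(
      ec50Max = ec, model = md,
      nCouples = rep$stages$couples$n,
      density = rep$stages$metrics$density,
      meanDegree = rep$stages$degrees$meanK,
      richClubSize = if (!is.null(rc) && is.null(rc$.failed))
        rc$nMembers else NA_integer_)
  }
  do.call(rbind, rows)
}
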