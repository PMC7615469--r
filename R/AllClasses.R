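## Central S4 data containers.
##
## The package works on a fixed, ordered neuron roster (302 cells for the
## canonical C. elegans hermaphrodite); every matrix in the package indexes
## rows/columns in roster order so that adjacency matrices from different
## stages are directly comparable.

#' Ordered neuron roster
#'
#' Holds the ordered list of neuron identifiers, the anatomical class each
#' neuron belongs to (e.g. AVAL and AVAR both belong to class AVA) and the
#' functional type of each neuron (sensory, interneuron, motor or pharyngeal).
#' All adjacency and expression matrices in the package follow this order.
#'
#' @slot neurons character vector of unique neuron names, fixed order.
#' @slot classOf named character vector mapping neuron -> anatomical class.
#' @slot typeOf named character vector mapping neuron -> one of
#'   \code{"sensory"}, \code{"interneuron"}, \code{"motor"},
#'   \code{"pharyngeal"}.
#'
#' @seealso [defaultRoster()] for the canonical 302-neuron roster.
#' @export
setClass("NeuronRoster",
  representation(neurons = "character", classOf = "character",
                 typeOf = "character"))

setValidity("NeuronRoster", function(object) {
  msg <- character()
  if (anyDuplicated(object@neurons))
    msg <- c(msg, "neuron names must be unique")
  if (length(object@neurons) < 2L)
    msg <- c(msg, "roster needs at least 2 neurons")
  if (!identical(names(object@classOf), object@neurons))
    msg <- c(msg, "classOf must be named by the neurons, in roster order")
  if (!identical(names(object@typeOf), object@neurons))
    msg <- c(msg, "typeOf must be named by the neurons, in roster order")
  bad <- setdiff(unique(object@typeOf),
                 c("sensory", "interneuron", "motor", "pharyngeal"))
  if (length(bad))
    msg <- c(msg, paste0("unknown neuron type(s): ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Binary gene-by-neuron expression matrix
#'
#' A \linkS4class{SummarizedExperiment} carrying a single logical assay
#' \code{"expressed"} (genes in rows, neurons in columns, column order equal
#' to the roster order). \code{colData} carries the anatomical class and
#' functional type of each neuron; \code{metadata} records the expression
#' threshold level used upstream (a provenance tag only; the package never
#' re-thresholds counts).
#'
#' @slot thresholdLevel integer, stringency level of the upstream binary
#'   expression calls (1 = least, 4 = most stringent).
#' @export
setClass("PeptideExpression",
  contains = "SummarizedExperiment",
  representation(thresholdLevel = "integer"))

setValidity("PeptideExpression", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assays(object)
  if (!"expressed" %in% names(a))
    return("assay 'expressed' is required")
  x <- a[["expressed"]]
  if (!is.logical(x))
    msg <- c(msg, "assay 'expressed' must be a logical matrix")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (is.null(colnames(object)))
    msg <- c(msg, "neuron (column) names are required")
  if (length(msg)) msg else TRUE
})

#' Peptide-receptor interaction table
#'
#' Peptide-level ligand-receptor activation entries from an in vitro
#' deorphanization screen. Each row is one peptide tested against one
#' receptor with a measured EC50 (stored in molar units). Gene-level couples
#' are derived with [couplesAtThreshold()].
#'
#' @slot entries data.frame with columns \code{peptide}, \code{npp},
#'   \code{gpcr}, \code{ec50} (molar).
#' @export
setClass("InteractionTable", representation(entries = "data.frame"))

setValidity("InteractionTable", function(object) {
  e <- object@entries
  need <- c("peptide", "npp", "gpcr", "ec50")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) && (!is.numeric(e$ec50) || any(!is.finite(e$ec50)) ||
                  any(e$ec50 <= 0)))
    return("ec50 values must be finite and positive")
  if (nrow(e) && (any(!nzchar(e$npp)) || any(!nzchar(e$gpcr))))
    return("npp and gpcr gene ids must be non-empty")
  TRUE
})

#' Per-neuron anatomical annotation
#'
#' Process-bundle membership (up to 27 named fascicles), body region,
#' nerve-ring strata and pharynx membership for every neuron of the roster.
#' These drive the spatial diffusion models: mid-range signaling is confined
#' to a body region, short-range to a shared process bundle (with the pharynx
#' as a sealed system), and contact to a shared nerve-ring stratum or a
#' shared thin (non-nerve-ring) bundle.
#'
#' @slot neuron character, roster order.
#' @slot bundles list of character vectors, process bundles per neuron.
#' @slot region character, one of \code{"head"}, \code{"midbody"},
#'   \code{"tail"} per neuron (head includes the pharynx).
#' @slot strata list of integer vectors, nerve-ring strata (subset of 1:4;
#'   empty when the neuron has no nerve-ring process).
#' @slot inPharynx logical per neuron.
#' @slot bundleUniverse character, the full bundle vocabulary (27 names for
#'   the worm).
#' @slot nerveRing character scalar, the name of the nerve-ring bundle
#'   within \code{bundleUniverse}.
#' @export
setClass("NeuronAnnotation",
  representation(neuron = "character", bundles = "list", region = "character",
                 strata = "list", inPharynx = "logical",
                 bundleUniverse = "character", nerveRing = "character"))

setValidity("NeuronAnnotation", function(object) {
  msg <- character()
  n <- length(object@neuron)
  if (length(object@bundles) != n || length(object@region) != n ||
      length(object@strata) != n || length(object@inPharynx) != n)
    msg <- c(msg, "all per-neuron slots must have one entry per neuron")
  if (!all(object@region %in% c("head", "midbody", "tail")))
    msg <- c(msg, "region must be head, midbody or tail")
  if (any(vapply(object@bundles, length, 1L) == 0L))
    msg <- c(msg, "every neuron must belong to at least one bundle")
  allb <- unique(unlist(object@bundles))
  if (length(setdiff(allb, object@bundleUniverse)))
    msg <- c(msg, paste0("bundle(s) outside the vocabulary: ",
                         paste(setdiff(allb, object@bundleUniverse),
                               collapse = ", ")))
  if (!all(unlist(object@strata) %in% 1:8))
    msg <- c(msg, "strata must be small positive integers")
  if (length(msg)) msg else TRUE
})

#' Wired reference connectome
#'
#' A synaptic, gap-junction or monoamine network over the same roster, used
#' for comparison with the peptidergic aggregate. Gap-junction networks are
#' undirected and stored as symmetric matrices.
#'
#' @slot name character, one of \code{"synaptic"}, \code{"gap_junction"},
#'   \code{"monoamine"}.
#' @slot adjacency nonnegative numeric matrix in roster order.
#' @slot directed logical.
#' @export
setClass("WiredNetwork",
  representation(name = "character", adjacency = "matrix",
                 directed = "logical"))

setValidity("WiredNetwork", function(object) {
  msg <- character()
  A <- object@adjacency
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (any(A < 0)) msg <- c(msg, "adjacency must be nonnegative")
  if (!object@directed && !isTRUE(all.equal(A, t(A))))
    msg <- c(msg, "undirected network must have a symmetric matrix")
  if (length(msg)) msg else TRUE
})

#' Single-couple signaling network
#'
#' The directed binary network of one neuropeptide-receptor gene couple:
#' an edge i -> j exists when neuron i expresses the precursor gene and
#' neuron j the receptor gene, and the pair (i, j) passes the spatial
#' predicate of the diffusion model. Self-loops (autocrine connections) are
#' retained at construction; topology metrics zero the diagonal themselves.
#'
#' @slot npp,gpcr character, the gene couple.
#' @slot minEC50 numeric, lowest EC50 (molar) among the couple's entries.
#' @slot model character, one of \code{"long"}, \code{"mid"},
#'   \code{"short"}, \code{"contact"}.
#' @slot adjacency logical matrix, sender rows, receiver columns.
#' @export
setClass("PairNetwork",
  representation(npp = "character", gpcr = "character", minEC50 = "numeric",
                 model = "character", adjacency = "matrix"))

setValidity("PairNetwork", function(object) {
  msg <- character()
  if (!object@model %in% c("long", "mid", "short", "contact"))
    msg <- c(msg, "model must be long, mid, short or contact")
  if (!is.logical(object@adjacency))
    msg <- c(msg, "adjacency must be logical")
  if (nrow(object@adjacency) != ncol(object@adjacency))
    msg <- c(msg, "adjacency must be square")
  if (length(msg)) msg else TRUE
})

#' Aggregate peptidergic connectome
#'
#' Integer-weighted sum of single-couple networks under one diffusion
#' model; the weight of an edge is the number of distinct gene couples able
#' to signal along it.
#'
#' @slot model character, shared diffusion model of the contributing nets.
#' @slot weights nonnegative integer matrix in roster order.
#' @slot couples data.frame of contributing couples (npp, gpcr, minEC50).
#' @export
setClass("AggregateNetwork",
  representation(model = "character", weights = "matrix",
                 couples = "data.frame"))

setValidity("AggregateNetwork", function(object) {
  msg <- character()
  W <- object@weights
  if (nrow(W) != ncol(W)) msg <- c(msg, "weights must be square")
  if (any(W < 0) || any(W != round(W)))
    msg <- c(msg, "weights must be nonnegative integers")
  if (nrow(object@couples) && max(W) > nrow(object@couples))
    msg <- c(msg, "max weight cannot exceed the number of couples")
  if (length(msg)) msg else TRUE
})

#' Rich-club curve with null-ensemble normalization
#'
#' For each degree level k, the rich-club coefficient phi(k) of the
#' subnetwork of nodes with total degree > k, the mean and SD of the same
#' coefficient across a degree-preserving null ensemble, the normalized
#' curve, the detected onset and the member set.
#'
#' @slot k integer grid of degree levels.
#' @slot phi,phiRandMean,phiRandSd,phiNorm,sigma numeric curves on \code{k}.
#' @slot onsetK integer (NA when no rich club is detected).
#' @slot members character, neurons with total degree > onsetK.
#' @slot nNull,swapsPerEdge,seed integer provenance of the null ensemble.
#' @slot sigmaBasis character, \code{"normalized"} or \code{"raw"} (how the
#'   one-sigma onset band is measured; see the methods vignette).
#' @export
setClass("RichClubCurve",
  representation(k = "integer", phi = "numeric", phiRandMean = "numeric",
                 phiRandSd = "numeric", phiNorm = "numeric", sigma = "numeric",
                 onsetK = "integer", members = "character", nNull = "integer",
                 swapsPerEdge = "integer", seed = "integer",
                 sigmaBasis = "character"))

setValidity("RichClubCurve", function(object) {
  n <- length(object@k)
  if (!all(lengths(list(object@phi, object@phiRandMean, object@phiRandSd,
                        object@phiNorm, object@sigma)) == n))
    return("all curves must share the k grid length")
  TRUE
})
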