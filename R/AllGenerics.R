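#' Accessors for NeuroPepNet containers
#'
#' Small accessor generics: \code{neurons()} returns the ordered neuron
#' names, \code{adjacency()} the (logical or weighted) adjacency matrix,
#' \code{networkModel()} the diffusion model tag, and
#' \code{interactionEntries()} the peptide-level interaction rows.
#'
#' @param x an object.
#' @return See each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("neurons", function(x) standardGeneric("neurons"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("networkModel", function(x) standardGeneric("networkModel"))

#' @rdname accessors
#' @export
setGeneric("interactionEntries",
           function(x) standardGeneric("interactionEntries"))

#' @rdname accessors
#' @export
setGeneric("neuronTypes", function(x) standardGeneric("neuronTypes"))

#' @rdname accessors
#' @export
setGeneric("neuronClasses", function(x) standardGeneric("neuronClasses"))

#' @rdname accessors
#' @export
setMethod("neurons", "NeuronRoster", function(x) x@neurons)

#' @rdname accessors
#' @export
setMethod("neuronTypes", "NeuronRoster", function(x) x@typeOf)

#' @rdname accessors
#' @export
setMethod("neuronClasses", "NeuronRoster", function(x) x@classOf)

#' @rdname accessors
#' @export
setMethod("neurons", "PeptideExpression", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("neurons", "NeuronAnnotation", function(x) x@neuron)

#' @rdname accessors
#' @export
setMethod("neurons", "PairNetwork", function(x) rownames(x@adjacency))

#' @rdname accessors
#' @export
setMethod("neurons", "AggregateNetwork", function(x) rownames(x@weights))

#' @rdname accessors
#' @export
setMethod("adjacency", "PairNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setMethod("adjacency", "AggregateNetwork", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("adjacency", "WiredNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setMethod("networkModel", "PairNetwork", function(x) x@model)

#' @rdname accessors
#' @export
setMethod("networkModel", "AggregateNetwork", function(x) x@model)

#' @rdname accessors
#' @export
setMethod("interactionEntries", "InteractionTable", function(x) x@entries)

#' Expression calls as a logical matrix
#'
#' @param x a \linkS4class{PeptideExpression}.
#' @return logical genes-by-neurons matrix.
#' @export
expressed <- function(x) {
  stopifnot(is(x, "PeptideExpression"))
  assay(x, "expressed")
}

setMethod("show", "NeuronRoster", function(object) {
  cat("NeuronRoster with", length(object@neurons), "neurons,",
      length(unique(object@classOf)), "classes\n")
  tb <- table(object@typeOf)
  cat(" ", paste(names(tb), tb, sep = ": ", collapse = ", "), "\n")
})

setMethod("show", "PeptideExpression", function(object) {
  x <- assay(object, "expressed")
  cat("PeptideExpression:", nrow(x), "genes x", ncol(x), "neurons",
      sprintf("(threshold level %d); %.1f%% calls positive\n",
              object@thresholdLevel, 100 * mean(x)))
})

setMethod("show", "InteractionTable", function(object) {
  e <- object@entries
  cat("InteractionTable:", nrow(e), "peptide-receptor entries,",
      length(unique(paste(e$npp, e$gpcr))), "unique gene couples\n")
})

setMethod("show", "NeuronAnnotation", function(object) {
  cat("NeuronAnnotation for", length(object@neuron), "neurons;",
      length(object@bundleUniverse), "bundles;",
      sum(object@inPharynx), "pharyngeal\n")
})

setMethod("show", "PairNetwork", function(object) {
  cat(sprintf("PairNetwork %s -> %s [%s model]: %d edges\n",
              object@npp, object@gpcr, object@model,
              sum(object@adjacency)))
})

setMethod("show", "AggregateNetwork", function(object) {
  W <- object@weights
  diag(W) <- 0L
  cat(sprintf(
    "AggregateNetwork [%s model]: %d couples, %d edges, density %.4f\n",
    object@model, nrow(object@couples), sum(W > 0),
    sum(W > 0) / (nrow(W)^2 - nrow(W))))
})

setMethod("show", "WiredNetwork", function(object) {
  cat(sprintf("WiredNetwork '%s' (%s): %d nonzero entries\n", object@name,
              if (object@directed) "directed" else "undirected",
              sum(object@adjacency > 0)))
})

setMethod("show", "RichClubCurve", function(object) {
  cat("RichClubCurve over k =", min(object@k), "..", max(object@k), "\n")
  if (is.na(object@onsetK)) {
    cat("  no rich-club onset detected\n")
  } else {
    cat(sprintf("  onset k = %d; %d members (degree > onset)\n",
                object@onsetK, length(object@members)))
  }
  cat(sprintf("  nulls: n = %d, %d swaps/edge, seed %d, sigma basis '%s'\n",
              object@nNull, object@swapsPerEdge, object@seed,
              object@sigmaBasis))
})

#' Rich-club membership
#'
#' @param x a \linkS4class{RichClubCurve}.
#' @return character vector of member neurons (empty when no onset).
#' @export
richClubMembers <- function(x) {
  stopifnot(is(x, "RichClubCurve"))
  x@members
}

#' Rich-club curve as a data.frame
#'
#' @param x a \linkS4class{RichClubCurve}.
#' @return data.frame with columns k, phi, phiRandMean, phiRandSd, phiNorm,
#'   sigma.
#' @export
richClubTable <- function(x) {
  stopifnot(is(x, "RichClubCurve"))
  data.frame(k = x@k, phi = x@phi, phiRandMean = x@phiRandMean,
             phiRandSd = x@phiRandSd, phiNorm = x@phiNorm, sigma = x@sigma)
}
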