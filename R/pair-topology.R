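## Per-couple topology classes and diffusion-range diagnostics.

#' Classify a couple's network topology by expression breadth
#'
#' Uses the unfiltered expression breadth of the two genes (how many
#' neurons express each), not the filtered edges: \emph{local} when both
#' are restricted (<= 50 neurons), \emph{pervasive} when both are broad
#' (> 50), \emph{broadcaster} for broad receptor with restricted precursor
#' (few senders reaching many receivers) and \emph{integrative} for the
#' converse.
#'
#' @param expr a \linkS4class{PeptideExpression}.
#' @param couple one-row data.frame/list with \code{npp}, \code{gpcr}.
#' @param broadThreshold breadth above which expression counts as broad
#'   (default 50 neurons).
#' @return list with \code{class} (character), \code{nNPP}, \code{nGPCR}.
#' @export
classifyTopology <- function(expr, couple, broadThreshold = 50L) {
  nN <- sum(.exprVector(expr, couple$npp))
  nG <- sum(.exprVector(expr, couple$gpcr))
  broadN <- nN > broadThreshold
  broadG <- nG > broadThreshold
  cls <- if (broadN && broadG) "pervasive"
         else if (!broadN && !broadG) "local"
         else if (broadG) "broadcaster"
         else "integrative"
  list(class = cls, nNPP = nN, nGPCR = nG)
}

#' Classify all couples
#'
#' @param expr a \linkS4class{PeptideExpression}.
#' @param couples data.frame from [couplesAtThreshold()].
#' @param ann optional \linkS4class{NeuronAnnotation}; when given, the
#'   component count of each couple's network under \code{model} is added.
#' @param model diffusion model for the component count.
#' @param broadThreshold see [classifyTopology()].
#' @return data.frame with npp, gpcr, nNPP, nGPCR, class (and nComponents).
#' @export
classifyAllCouples <- function(expr, couples, ann = NULL, model = "short",
                               broadThreshold = 50L) {
  res <- lapply(seq_len(nrow(couples)), function(i) {
    cl <- classifyTopology(expr, couples[i, ], broadThreshold)
    row <- data.frame(npp = couples$npp[i], gpcr = couples$gpcr[i],
                      nNPP = cl$nNPP, nGPCR = cl$nGPCR, class = cl$class)
    if (!is.null(ann)) {
      net <- applySpatialFilter(buildPairNetwork(expr, couples[i, ]),
                                model, ann)
      row$nComponents <- countComponents(net)
    }
    row
  })
  do.call(rbind, res)
}

.rangeLevels <- c("contact_stratum", "contact_thin_bundle", "short", "mid",
                  "long", "unreachable")

#' Minimal diffusion range per expressing neuron
#'
#' For an exclusive one-to-one couple, determines for every neuron
#' expressing the focal gene the smallest diffusion class under which it
#' can communicate with at least one neuron expressing the partner gene.
#' The ordering is contact within a nerve-ring stratum < contact in a thin
#' (non-nerve-ring) bundle < short (same bundle) < mid (same region) <
#' long; \code{"unreachable"} marks a partner gene expressed nowhere.
#' A neuron co-expressing both genes reaches itself at contact range.
#'
#' @param expr a \linkS4class{PeptideExpression}.
#' @param couple one-row data.frame/list with \code{npp}, \code{gpcr}.
#' @param ann a \linkS4class{NeuronAnnotation}.
#' @param direction \code{"receiver_view"} (focal gene = receptor; can
#'   every receptor neuron be reached by a ligand source?) or
#'   \code{"sender_view"} (focal gene = precursor).
#' @return named character vector over focal-gene neurons with values in
#'   the ordered range classes.
#' @export
minimalRange <- function(expr, couple, ann,
                         direction = c("receiver_view", "sender_view")) {
  direction <- match.arg(direction)
  focalGene <- if (direction == "receiver_view") couple$gpcr else couple$npp
  partnerGene <- if (direction == "receiver_view") couple$npp else couple$gpcr
  focal <- which(.exprVector(expr, focalGene))
  partner <- which(.exprVector(expr, partnerGene))
  nm <- ann@neuron
  if (!length(focal)) return(setNames(character(0), character(0)))
  if (!length(partner))
    return(setNames(rep("unreachable", length(focal)), nm[focal]))
  # stratum / thin-bundle / bundle predicates (sender -> receiver symmetric
  # at the predicate level, so orientation does not matter here)
  contactM <- spatialPredicateMatrix(ann, "contact")
  shortM <- spatialPredicateMatrix(ann, "short")
  midM <- spatialPredicateMatrix(ann, "mid")
  # split contact into its stratum and thin-bundle parts
  n <- length(nm)
  S <- matrix(FALSE, n, 4L)
  for (i in seq_len(n)) S[i, ann@strata[[i]][ann@strata[[i]] <= 4L]] <- TRUE
  stratumM <- (tcrossprod(S) > 0) & shortM
  diag(stratumM) <- vapply(seq_len(n),
                           function(i) length(ann@strata[[i]]) > 0, TRUE)
  out <- vapply(focal, function(i) {
    p <- partner
    if (any(stratumM[i, p])) return("contact_stratum")
    if (any(contactM[i, p])) return("contact_thin_bundle")
    if (any(shortM[i, p])) return("short")
    if (any(midM[i, p])) return("mid")
    "long"
  }, "")
  setNames(out, nm[focal])
}

#' Range matrices for all exclusive couples
#'
#' @param expr a \linkS4class{PeptideExpression}.
#' @param exclusive data.frame from [exclusiveCouples()].
#' @param ann a \linkS4class{NeuronAnnotation}.
#' @param direction see [minimalRange()].
#' @return named list (by focal gene) of [minimalRange()] vectors.
#' @export
rangeMatrix <- function(expr, exclusive, ann,
                        direction = c("receiver_view", "sender_view")) {
  direction <- match.arg(direction)
  focal <- if (direction == "receiver_view") exclusive$gpcr
           else exclusive$npp
  out <- lapply(seq_len(nrow(exclusive)),
                function(i) minimalRange(expr, exclusive[i, ], ann,
                                         direction))
  names(out) <- focal
  out
}

#' Summarize diffusion-range requirements across genes
#'
#' Counts focal genes with at least one expressing neuron that needs more
#' than contact range (no contact with any partner neuron), and with at
#' least one neuron needing more than short range. Unreachable neurons
#' count toward both.
#'
#' @param ranges list from [rangeMatrix()].
#' @return list with \code{nGenes}, \code{beyondContact},
#'   \code{beyondShort} and the per-gene logical vectors.
#' @export
rangeSummary <- function(ranges) {
  beyondContact <- vapply(ranges, function(r)
    any(r %in% c("short", "mid", "long", "unreachable")), TRUE)
  beyondShort <- vapply(ranges, function(r)
    any(r %in% c("mid", "long", "unreachable")), TRUE)
  list(nGenes = length(ranges),
       beyondContact = sum(beyondContact),
       beyondShort = sum(beyondShort),
       perGeneBeyondContact = beyondContact,
       perGeneBeyondShort = beyondShort)
}
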