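#' Gene-level couples at an EC50 threshold
#'
#' Reduces peptide-level interaction entries to unique (NPP gene, GPCR gene)
#' couples with at least one entry at or below the potency threshold. The
#' default of 500 nM corresponds to the potency range validated in vivo;
#' 100 nM is the stricter sensitivity setting.
#'
#' @param interactions an \linkS4class{InteractionTable}.
#' @param ec50Max maximum EC50 in molar (default 5e-7, i.e. 500 nM).
#' @return data.frame with columns \code{npp}, \code{gpcr}, \code{minEC50},
#'   sorted by (npp, gpcr). \code{minEC50} is the minimum over all of the
#'   couple's entries (including ones above the threshold).
#' @examples
#' tab <- InteractionTable(data.frame(
#'   peptide = c("p1a", "p1b"), npp = "nppA", gpcr = "rec1",
#'   ec50 = c(1e-9, 6e-7)))
#' couplesAtThreshold(tab, 5e-7)  # one couple, minEC50 1e-9
#' @export
couplesAtThreshold <- function(interactions, ec50Max = 5e-7) {
  stopifnot(ec50Max > 0)
  e <- interactionEntries(interactions)
  if (!nrow(e))
    return(data.frame(npp = character(), gpcr = character(),
                      minEC50 = numeric()))
  key <- paste(e$npp, e$gpcr, sep = "\r")
  minAll <- tapply(e$ec50, key, min)
  passes <- tapply(e$ec50 <= ec50Max, key, any)
  keep <- names(passes)[passes]
  if (!length(keep))
    return(data.frame(npp = character(), gpcr = character(),
                      minEC50 = numeric()))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(npp = vapply(parts, `[`, "", 1L),
                    gpcr = vapply(parts, `[`, "", 2L),
                    minEC50 = unname(minAll[keep]))
  out <- out[order(out$npp, out$gpcr), ]
  rownames(out) <- NULL
  out
}

#' Exclusive one-to-one couples
#'
#' Couples where the receptor gene has exactly one ligand gene at the active
#' threshold and that ligand activates no other receptor gene. These
#' one-to-one pairs are the ones for which expression mismatches cleanly
#' diagnose the required diffusion range.
#'
#' @inheritParams couplesAtThreshold
#' @return data.frame (subset of [couplesAtThreshold()] rows).
#' @export
exclusiveCouples <- function(interactions, ec50Max = 5e-7) {
  cps <- couplesAtThreshold(interactions, ec50Max)
  if (!nrow(cps)) return(cps)
  nppDeg <- table(cps$npp)
  gpcrDeg <- table(cps$gpcr)
  keep <- nppDeg[cps$npp] == 1L & gpcrDeg[cps$gpcr] == 1L
  out <- cps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
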