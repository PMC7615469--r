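## Canonical 302-neuron hermaphrodite roster, constructed programmatically.
## Classes follow standard nomenclature (left/right and dorsal/ventral cells
## collapse onto one anatomical class); functional types follow the WormAtlas
## scheme with two deliberate resolutions of conflicting sources: URB is
## typed sensory and the DB class motor.

# classes whose D/V (and L/R) variants share one anatomical class name
.dvClass <- c(CEPD = "CEP", CEPV = "CEP", OLQD = "OLQ", OLQV = "OLQ",
              URYD = "URY", URYV = "URY", URAD = "URA", URAV = "URA",
              SAAD = "SAA", SAAV = "SAA", SIAD = "SIA", SIAV = "SIA",
              SIBD = "SIB", SIBV = "SIB", SMBD = "SMB", SMBV = "SMB",
              SMDD = "SMD", SMDV = "SMD", RMDD = "RMD", RMDV = "RMD",
              IL1D = "IL1", IL1V = "IL1", IL2D = "IL2", IL2V = "IL2",
              SABV = "SAB", SABD = "SAB", RMED = "RME", RMEV = "RME")

.classType <- local({
  sensory <- c("ADE", "ADF", "ADL", "AFD", "ALM", "ALN", "AQR", "ASE", "ASG",
               "ASH", "ASI", "ASJ", "ASK", "AVM", "AWA", "AWB", "AWC", "BAG",
               "CEP", "FLP", "IL2", "OLL", "OLQ", "PDE", "PHA", "PHB", "PHC",
               "PLM", "PLN", "PQR", "PVD", "PVM", "URB", "URX", "URY")
  motor <- c("AS", "DA", "DB", "DD", "VA", "VB", "VC", "VD", "PDA", "PDB",
             "DVB", "AVL", "HSN", "IL1", "RID", "RMD", "RME", "RMF", "RMH",
             "SAB", "SMB", "SMD", "URA")
  pharyngeal <- c("I1", "I2", "I3", "I4", "I5", "I6", "M1", "M2", "M3", "M4",
                  "M5", "MC", "MI", "NSM")
  inter <- c("ADA", "AIA", "AIB", "AIM", "AIN", "AIY", "AIZ", "ALA", "AUA",
             "AVA", "AVB", "AVD", "AVE", "AVF", "AVG", "AVH", "AVJ", "AVK",
             "BDU", "CAN", "DVA", "DVC", "LUA", "PVC", "PVN", "PVP", "PVQ",
             "PVR", "PVT", "PVW", "RIA", "RIB", "RIC", "RIF", "RIG", "RIH",
             "RIM", "RIP", "RIR", "RIS", "RIV", "RMG", "SAA", "SDQ", "SIA",
             "SIB")
  c(setNames(rep("sensory", length(sensory)), sensory),
    setNames(rep("motor", length(motor)), motor),
    setNames(rep("pharyngeal", length(pharyngeal)), pharyngeal),
    setNames(rep("interneuron", length(inter)), inter))
})

.rosterNames <- function() {
  pharynx <- c("I1L", "I1R", "I2L", "I2R", "I3", "I4", "I5", "I6", "M1",
               "M2L", "M2R", "M3L", "M3R", "M4", "M5", "MCL", "MCR", "MI",
               "NSML", "NSMR")
  lr <- c("ADA", "ADE", "ADF", "ADL", "AFD", "AIA", "AIB", "AIM", "AIN",
          "AIY", "AIZ", "ALM", "ALN", "ASE", "ASG", "ASH", "ASI", "ASJ",
          "ASK", "AUA", "AVA", "AVB", "AVD", "AVE", "AVF", "AVH", "AVJ",
          "AVK", "AWA", "AWB", "AWC", "BAG", "BDU", "CAN", "CEPD", "CEPV",
          "FLP", "HSN", "IL1D", "IL1", "IL1V", "IL2D", "IL2", "IL2V", "LUA",
          "OLL", "OLQD", "OLQV", "PDE", "PHA", "PHB", "PHC", "PLM", "PLN",
          "PVC", "PVD", "PVN", "PVP", "PVQ", "PVW", "RIA", "RIB", "RIC",
          "RIF", "RIG", "RIM", "RIP", "RIV", "RMD", "RMDD", "RMDV", "RME",
          "RMF", "RMG", "RMH", "SAAD", "SAAV", "SABV", "SDQ", "SIAD", "SIAV",
          "SIBD", "SIBV", "SMBD", "SMBV", "SMDD", "SMDV", "URAD", "URAV",
          "URB", "URX", "URYD", "URYV")
  singles <- c("ALA", "AQR", "AVG", "AVL", "AVM", "DVA", "DVB", "DVC", "PDA",
               "PDB", "PQR", "PVM", "PVR", "PVT", "RID", "RIH", "RIR", "RIS",
               "RMED", "RMEV", "SABD")
  vnc <- c(paste0("AS", 1:11), paste0("DA", 1:9), paste0("DB", 1:7),
           paste0("DD", 1:6), paste0("VA", 1:12), paste0("VB", 1:11),
           paste0("VC", 1:6), paste0("VD", 1:13))
  c(pharynx, paste0(rep(lr, each = 2), c("L", "R")), singles, vnc)
}

.classOfName <- function(nm) {
  # single neurons whose own name ends in L/R but carries no laterality
  keep <- c("AQR", "PQR", "PVR", "AVL", "RIR")
  base <- ifelse(nm %in% keep, nm, sub("[LR]$", "", nm))
  base <- sub("^(AS|DA|DB|DD|VA|VB|VC|VD)[0-9]+$", "\\1", base)
  # pharyngeal numbered classes keep their digits (I1, M2, ...)
  base <- ifelse(grepl("^(I[1-6]|M[1-5]|MC|MI|NSM)$", base), base, base)
  out <- ifelse(base %in% names(.dvClass), .dvClass[base], base)
  unname(out)
}

#' The canonical 302-neuron roster
#'
#' Builds the fixed roster of the 302 named hermaphrodite neurons in a
#' reproducible order (pharyngeal neurons, then the bilateral pairs, single
#' neurons and ventral-cord classes), together with the anatomical class and
#' WormAtlas-based functional type of each neuron. All package matrices use
#' this order. Two deliberate typing choices: URBL/URBR are typed sensory
#' and the DB motor-neuron class motor.
#'
#' @param order either \code{"canonical"} (construction order, default) or
#'   \code{"alphabetical"}.
#' @return a \linkS4class{NeuronRoster}.
#' @examples
#' r <- defaultRoster()
#' length(neurons(r))  # 302
#' @export
defaultRoster <- function(order = c("alphabetical", "canonical")) {
  order <- match.arg(order)
  nm <- .rosterNames()
  if (order == "alphabetical") nm <- sort(nm)
  cls <- .classOfName(nm)
  type <- unname(.classType[cls])
  if (anyNA(type))
    stop("internal: untyped classes ", paste(unique(cls[is.na(type)]),
                                             collapse = ", "))
  new("NeuronRoster", neurons = nm, classOf = setNames(cls, nm),
      typeOf = setNames(type, nm))
}

#' Construct a roster from scratch
#'
#' Used for synthetic nervous systems of arbitrary size.
#'
#' @param neurons character vector of unique neuron names.
#' @param classOf character vector (same length) of anatomical classes;
#'   defaults to one class per neuron.
#' @param typeOf character vector of functional types.
#' @return a \linkS4class{NeuronRoster}.
#' @export
NeuronRoster <- function(neurons, classOf = neurons,
                         typeOf = rep("interneuron", length(neurons))) {
  new("NeuronRoster", neurons = neurons,
      classOf = setNames(unname(classOf), neurons),
      typeOf = setNames(unname(typeOf), neurons))
}
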