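## Delimited-text readers and writers for the package's input tables.
## All tables are CSV/TSV with a header row; the delimiter is sniffed from
## the first line unless given.

.readDelim <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

.coerceBinary <- function(v, context) {
  if (is.logical(v)) return(v)
  ch <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(ch))
  out[ch %in% c("1", "true", "t")] <- TRUE
  out[ch %in% c("0", "false", "f")] <- FALSE
  if (anyNA(out))
    stop("non-binary expression values in ", context, ": ",
         paste(unique(ch[is.na(out)]), collapse = ", "))
  out
}

#' Load a binary expression table
#'
#' Reads a gene-by-neuron (or gene-by-class) table of binary expression
#' calls. The first column holds gene identifiers; remaining columns are
#' neuron names or anatomical class names. Class-level calls are broadcast
#' to every member neuron of the roster, matching how class-level
#' single-cell expression calls are applied to the full cell roster.
#'
#' @param path CSV/TSV file.
#' @param roster a \linkS4class{NeuronRoster}.
#' @param thresholdLevel integer provenance tag (stringency of the upstream
#'   binary calls), stored but never acted on.
#' @param sep optional field separator (sniffed by default).
#' @return a \linkS4class{PeptideExpression} with neurons in roster order.
#' @export
loadExpression <- function(path, roster, thresholdLevel = 4L, sep = NULL) {
  df <- .readDelim(path, sep)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  cols <- names(df)[-1L]
  nm <- neurons(roster)
  cls <- neuronClasses(roster)
  unknown <- setdiff(cols, c(nm, unique(cls)))
  if (length(unknown))
    stop("unknown neuron/class column(s): ", paste(unknown, collapse = ", "))
  X <- matrix(FALSE, nrow = length(genes), ncol = length(nm),
              dimnames = list(genes, nm))
  for (cn in cols) {
    v <- .coerceBinary(df[[cn]], paste0("column '", cn, "'"))
    targets <- if (cn %in% nm) cn else nm[cls == cn]
    X[, targets] <- X[, targets] | v
  }
  PeptideExpression(X, roster, thresholdLevel)
}

#' Construct a PeptideExpression from a logical matrix
#'
#' @param X logical genes-by-neurons matrix with dimnames.
#' @param roster a \linkS4class{NeuronRoster}; columns of \code{X} must be
#'   exactly the roster neurons (reordered if necessary).
#' @param thresholdLevel integer provenance tag.
#' @return a \linkS4class{PeptideExpression}.
#' @export
PeptideExpression <- function(X, roster, thresholdLevel = 4L) {
  nm <- neurons(roster)
  if (!setequal(colnames(X), nm))
    stop("expression columns must match the roster neurons")
  X <- X[, nm, drop = FALSE]
  storage.mode(X) <- "logical"
  se <- SummarizedExperiment(
    assays = list(expressed = X),
    colData = DataFrame(class = unname(neuronClasses(roster)[nm]),
                        type = unname(neuronTypes(roster)[nm]),
                        row.names = nm))
  new("PeptideExpression", se, thresholdLevel = as.integer(thresholdLevel))
}

#' Write a binary expression table (per-neuron columns)
#'
#' @param x a \linkS4class{PeptideExpression}.
#' @param path output CSV path.
#' @export
saveExpression <- function(x, path) {
  X <- expressed(x)
  df <- data.frame(gene = rownames(X), 1L * X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a peptide-receptor interaction table
#'
#' Expected columns: \code{peptide_id}, \code{npp_gene}, \code{gpcr_gene},
#' \code{ec50}. EC50 values are parsed as molar by default; screens often
#' report nanomolar, selected with \code{unit = "nM"}. Values are stored in
#' molar. Duplicate (peptide, receptor) rows are kept: deduplication happens
#' at the gene-couple level.
#'
#' @param path CSV/TSV file.
#' @param unit \code{"M"} (default) or \code{"nM"}.
#' @param sep optional field separator.
#' @return an \linkS4class{InteractionTable}.
#' @export
loadInteractions <- function(path, unit = c("M", "nM"), sep = NULL) {
  unit <- match.arg(unit)
  df <- .readDelim(path, sep)
  need <- c("peptide_id", "npp_gene", "gpcr_gene", "ec50")
  if (!all(need %in% names(df)))
    stop("interaction table must have columns: ",
         paste(need, collapse = ", "))
  ec <- suppressWarnings(as.numeric(df$ec50))
  bad <- which(!is.finite(ec) | ec <= 0)
  if (length(bad))
    stop("nonpositive or unparsable ec50 at row(s): ",
         paste(bad, collapse = ", "))
  if (unit == "nM") ec <- ec * 1e-9
  InteractionTable(data.frame(peptide = as.character(df$peptide_id),
                              npp = as.character(df$npp_gene),
                              gpcr = as.character(df$gpcr_gene),
                              ec50 = ec, stringsAsFactors = FALSE))
}

#' Construct an InteractionTable
#'
#' @param entries data.frame with columns peptide, npp, gpcr, ec50 (molar).
#' @return an \linkS4class{InteractionTable}.
#' @export
InteractionTable <- function(entries) {
  new("InteractionTable", entries = entries)
}

#' Write an interaction table
#'
#' @param x an \linkS4class{InteractionTable}.
#' @param path output CSV path (molar EC50s).
#' @export
saveInteractions <- function(x, path) {
  e <- interactionEntries(x)
  out <- data.frame(peptide_id = e$peptide, npp_gene = e$npp,
                    gpcr_gene = e$gpcr,
                    ec50 = format(e$ec50, digits = 17, scientific = TRUE,
                                  trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load per-neuron anatomical annotations
#'
#' Expected columns: \code{neuron}, \code{bundles} (semicolon-separated),
#' \code{region}, \code{strata} (semicolon-separated, may be empty). Every
#' roster neuron must appear exactly once. Pharynx membership is derived
#' from membership in the pharynx bundle.
#'
#' @param path CSV/TSV file.
#' @param roster a \linkS4class{NeuronRoster}.
#' @param bundleUniverse optional character vector of valid bundle names (the
#'   27 fascicles for the worm); defaults to the names present in the file.
#' @param nerveRing name of the nerve-ring bundle.
#' @param pharynxBundle name of the pharynx bundle.
#' @param sep optional field separator.
#' @return a \linkS4class{NeuronAnnotation} in roster order.
#' @export
loadAnnotations <- function(path, roster, bundleUniverse = NULL,
                            nerveRing = "nerve_ring",
                            pharynxBundle = "pharynx", sep = NULL) {
  df <- .readDelim(path, sep)
  need <- c("neuron", "bundles", "region", "strata")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "))
  nm <- neurons(roster)
  missing <- setdiff(nm, df$neuron)
  if (length(missing))
    stop("missing neuron(s): ", paste(head(missing, 10), collapse = ", "))
  if (anyDuplicated(df$neuron))
    stop("duplicated neuron rows")
  df <- df[match(nm, df$neuron), ]
  splitField <- function(v) strsplit(ifelse(is.na(v), "", as.character(v)),
                                     ";", fixed = TRUE)
  bundles <- lapply(splitField(df$bundles), function(b) b[nzchar(b)])
  strata <- lapply(splitField(df$strata),
                   function(s) as.integer(s[nzchar(s)]))
  if (is.null(bundleUniverse)) {
    bundleUniverse <- sort(unique(unlist(bundles)))
  } else {
    unknown <- setdiff(unique(unlist(bundles)), bundleUniverse)
    if (length(unknown))
      stop("unknown bundle(s): ", paste(unknown, collapse = ", "),
           "; valid names are: ", paste(bundleUniverse, collapse = ", "))
  }
  NeuronAnnotation(neuron = nm, bundles = bundles,
                   region = as.character(df$region), strata = strata,
                   bundleUniverse = bundleUniverse, nerveRing = nerveRing,
                   pharynxBundle = pharynxBundle)
}

#' Construct a NeuronAnnotation
#'
#' @param neuron character vector (roster order).
#' @param bundles list of character vectors.
#' @param region character vector.
#' @param strata list of integer vectors.
#' @param bundleUniverse valid bundle vocabulary.
#' @param nerveRing name of the nerve-ring bundle.
#' @param pharynxBundle name of the pharynx bundle; membership defines
#'   \code{inPharynx}.
#' @return a \linkS4class{NeuronAnnotation}.
#' @export
NeuronAnnotation <- function(neuron, bundles, region, strata,
                             bundleUniverse = sort(unique(unlist(bundles))),
                             nerveRing = "nerve_ring",
                             pharynxBundle = "pharynx") {
  inPharynx <- vapply(bundles, function(b) pharynxBundle %in% b, TRUE)
  new("NeuronAnnotation", neuron = neuron, bundles = bundles,
      region = region, strata = strata, inPharynx = inPharynx,
      bundleUniverse = bundleUniverse, nerveRing = nerveRing)
}

#' Write per-neuron annotations
#'
#' @param ann a \linkS4class{NeuronAnnotation}.
#' @param path output CSV path.
#' @export
saveAnnotations <- function(ann, path) {
  df <- data.frame(
    neuron = ann@neuron,
    bundles = vapply(ann@bundles, paste, "", collapse = ";"),
    region = ann@region,
    strata = vapply(ann@strata, paste, "", collapse = ";"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a wired connectome from a directed edge list
#'
#' Expected columns \code{pre}, \code{post}, \code{weight}. Gap-junction
#' networks are symmetrized by taking the maximum of the two directions.
#'
#' @param path CSV/TSV edge list.
#' @param name one of \code{"synaptic"}, \code{"gap_junction"},
#'   \code{"monoamine"}.
#' @param roster a \linkS4class{NeuronRoster}.
#' @param sep optional field separator.
#' @return a \linkS4class{WiredNetwork}.
#' @export
loadWired <- function(path, name = c("synaptic", "gap_junction", "monoamine"),
                      roster, sep = NULL) {
  name <- match.arg(name)
  df <- .readDelim(path, sep)
  need <- c("pre", "post", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  nm <- neurons(roster)
  unknown <- setdiff(unique(c(df$pre, df$post)), nm)
  if (length(unknown))
    stop("neuron(s) not in roster: ", paste(unknown, collapse = ", "))
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_len(nrow(df)))
    A[df$pre[i], df$post[i]] <- A[df$pre[i], df$post[i]] + df$weight[i]
  directed <- name != "gap_junction"
  if (!directed) A <- pmax(A, t(A))
  new("WiredNetwork", name = name, adjacency = A, directed = directed)
}

#' Write a network as a directed edge list
#'
#' @param A matrix (weights) or \linkS4class{AggregateNetwork} /
#'   \linkS4class{PairNetwork}.
#' @param path output CSV path with columns pre, post, weight.
#' @export
writeEdgeList <- function(A, path) {
  if (is(A, "AggregateNetwork") || is(A, "PairNetwork")) A <- adjacency(A)
  idx <- which(A != 0, arr.ind = TRUE)
  df <- data.frame(pre = rownames(A)[idx[, 1]], post = colnames(A)[idx[, 2]],
                   weight = as.numeric(A[idx]))
  df <- df[order(df$pre, df$post), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' @param A matrix or network object accepted by [writeEdgeList()].
#' @param path output .graphml path.
#' @export
writeGraphML <- function(A, path) {
  if (is(A, "AggregateNetwork") || is(A, "PairNetwork")) A <- adjacency(A)
  g <- igraph::graph_from_adjacency_matrix(1 * (A != 0), mode = "directed",
                                           diag = TRUE)
  el <- igraph::as_edgelist(g, names = TRUE)
  igraph::E(g)$weight <- A[cbind(el[, 1], el[, 2])]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write an adjacency matrix as CSV with a roster header
#'
#' @param A matrix or network object accepted by [writeEdgeList()].
#' @param path output CSV path.
#' @export
writeAdjacencyCSV <- function(A, path) {
  if (is(A, "AggregateNetwork") || is(A, "PairNetwork")) A <- adjacency(A)
  df <- data.frame(neuron = rownames(A), A * 1, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
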