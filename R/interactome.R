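# Loading and querying the signed directed protein network.

#' Load a signed directed network from edge and node tables
#'
#' Reads a tab-separated edge table (columns \code{source}, \code{target},
#' \code{sign}, optional \code{provenance}) or a SIF file (\code{source
#' relation target}, with \code{sifSignMap} translating relation labels to
#' signs) together with a tab-separated node table (column \code{gene_name},
#' optional \code{uniprot}, \code{motifs} semicolon-separated,
#' \code{effector}, \code{plasma}, \code{urine}).
#'
#' Undirected database entries should be supplied as two directed edges;
#' traversal in this package always follows edge direction, reflecting
#' directional signal flow.
#'
#' @param edgeFile path to the edge table (TSV with header, or SIF when
#'   \code{sifSignMap} is given).
#' @param nodeFile path to the node table (TSV with header).
#' @param sifSignMap named numeric vector mapping SIF relation labels to
#'   signs, e.g. \code{c(activates = 1, inhibits = -1, binds = 0)}. When
#'   \code{NULL} (default) the edge file is read as TSV.
#'
#' @return A validated [Interactome-class]. Edges referencing genes absent
#'   from the node table raise an error naming them; malformed rows are
#'   reported with their line numbers.
#' @export
loadNetwork <- function(edgeFile, nodeFile, sifSignMap = NULL) {
  nodes <- read.delim(nodeFile, stringsAsFactors = FALSE)
  if (is.null(sifSignMap)) {
    edges <- read.delim(edgeFile, stringsAsFactors = FALSE)
    need <- c("source", "target", "sign")
    if (!all(need %in% names(edges)))
      stop("edge table needs columns: ", paste(need, collapse = ", "))
    sgn <- suppressWarnings(as.numeric(edges$sign))
    bad <- which(!is.finite(sgn) | !(sgn %in% c(-1, 0, 1)))
    if (length(bad))
      stop("malformed edge sign on line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", edgeFile)
    edges$sign <- sgn
  } else {
    raw <- read.delim(edgeFile, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 3)
      stop("SIF file must have three columns: source relation target")
    unknown <- setdiff(unique(raw[[2]]), names(sifSignMap))
    if (length(unknown))
      stop("SIF relations missing from sifSignMap: ",
           paste(unknown, collapse = ", "))
    edges <- data.frame(source = raw[[1]], target = raw[[3]],
                        sign = unname(sifSignMap[raw[[2]]]),
                        provenance = raw[[2]],
                        stringsAsFactors = FALSE)
  }
  Interactome(edges, nodes)
}

#' Serialize an interactome to edge and node tables
#'
#' Writes the two TSV files read back by [loadNetwork()]; a load/write cycle
#' round-trips the tables exactly.
#'
#' @param net an [Interactome-class].
#' @param edgeFile,nodeFile output paths.
#' @return Invisibly, \code{net}.
#' @export
writeNetwork <- function(net, edgeFile, nodeFile) {
  nodes <- net@nodes
  nodes$motifs <- vapply(nodes$motifs, paste, character(1), collapse = ";")
  write.table(nodes, nodeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(net@edges, edgeFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(net)
}

#' Directed k-hop neighborhood of a protein
#'
#' All proteins reachable from \code{start} in at most \code{k} directed
#' hops, excluding \code{start} itself. With \code{directed = FALSE} edges
#' are followed in both directions (both adjacency conventions are supported
#' because database neighborhood counts are convention-dependent).
#'
#' @param net an [Interactome-class].
#' @param start gene name of the starting protein.
#' @param k maximum number of hops (\code{>= 1}).
#' @param directed follow edge direction (default) or not.
#' @return Character vector of gene names.
#' @examples
#' net <- Interactome(data.frame(source = c("A", "B"), target = c("B", "C"),
#'                               sign = 1),
#'                    data.frame(gene_name = c("A", "B", "C")))
#' kHopNeighborhood(net, "A", 1)  # "B"
#' kHopNeighborhood(net, "A", 3)  # "B" "C"
#' @export
kHopNeighborhood <- function(net, start, k, directed = TRUE) {
  if (!start %in% net@nodes$gene_name)
    stop("unknown start gene: ", start)
  if (k < 1) stop("'k' must be >= 1")
  nb <- igraph::ego(net@graph, order = k, nodes = start,
                    mode = if (directed) "out" else "all", mindist = 1)[[1]]
  sort(names(nb))
}

#' Direct connectivity between two motifs
#'
#' \code{TRUE} when at least one edge (in either direction) links a protein
#' of \code{motifA} to a protein of \code{motifB}. Distance-1 adjacency only:
#' two motifs connected through an intermediate protein are \emph{not}
#' directly connected, and a shared protein without a cross-edge does not
#' count either.
#'
#' @param net an [Interactome-class].
#' @param motifA,motifB motif identifiers; both must have at least one member
#'   protein (some pathophysiological processes cannot be defined at the
#'   protein level and have empty motifs, which is an error here).
#' @return Logical scalar.
#' @export
motifConnectivity <- function(net, motifA, motifB) {
  a <- motifProteins(net, motifA)
  b <- motifProteins(net, motifB)
  if (!length(a)) stop("motif has no member proteins: ", motifA)
  if (!length(b)) stop("motif has no member proteins: ", motifB)
  e <- net@edges
  any((e$source %in% a & e$target %in% b) |
      (e$source %in% b & e$target %in% a))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability \eqn{P(X \ge k)} that a draw of \code{setSize}
#' proteins from a universe of \code{universeSize} containing
#' \code{signatureSize} signature proteins contains at least
#' \code{hitsInSet} of them. Upper tail only: this tests
#' over-representation of the signature within the set.
#'
#' @param hitsInSet observed overlap count.
#' @param setSize size of the drawn set.
#' @param signatureSize number of signature proteins in the universe.
#' @param universeSize size of the protein universe.
#' @return p-value in \[0, 1\].
#' @examples
#' hypergeomEnrichment(4, 4, 5, 10)  # 5/210
#' @export
hypergeomEnrichment <- function(hitsInSet, setSize, signatureSize,
                                universeSize) {
  v <- c(hitsInSet, setSize, signatureSize, universeSize)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers")
  if (hitsInSet > min(setSize, signatureSize) ||
      max(setSize, signatureSize) > universeSize)
    stop("inconsistent counts: need hitsInSet <= min(setSize, signatureSize)",
         " <= universeSize")
  phyper(hitsInSet - 1, signatureSize, universeSize - signatureSize,
         setSize, lower.tail = FALSE)
}

#' Count k-protein combinations
#'
#' Number of unordered tuples of \code{size} proteins out of \code{n}. Used
#' to size classifier search spaces before enumerating them.
#'
#' @param n number of proteins.
#' @param size tuple size.
#' @return The exact count as a numeric scalar.
#' @examples
#' combinationCount(423, 2)  # 89253
#' combinationCount(423, 3)  # 12525171
#' @export
combinationCount <- function(n, size) {
  if (n < 0 || size < 0) stop("'n' and 'size' must be non-negative")
  if (size > n) return(0)
  round(choose(n, size))
}
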