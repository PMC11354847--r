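# Accessor generics and methods for the core classes.

#' Node annotation table of an interactome
#' @param x an [Interactome-class].
#' @return \code{data.frame} of per-protein annotations.
#' @export
setGeneric("interactomeNodes", function(x) standardGeneric("interactomeNodes"))

#' @rdname interactomeNodes
#' @export
setMethod("interactomeNodes", "Interactome", function(x) x@nodes)

#' Signed edge table of an interactome
#' @param x an [Interactome-class].
#' @return \code{data.frame} with \code{source}, \code{target}, \code{sign},
#'   \code{provenance}.
#' @export
setGeneric("interactomeEdges", function(x) standardGeneric("interactomeEdges"))

#' @rdname interactomeEdges
#' @export
setMethod("interactomeEdges", "Interactome", function(x) x@edges)

#' Gene names of an interactome
#' @param x an [Interactome-class].
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname geneNames
#' @export
setMethod("geneNames", "Interactome", function(x) x@nodes$gene_name)

#' Motif membership index
#'
#' @param x an [Interactome-class].
#' @return Named list: motif id to character vector of member gene names.
#'   Derived from the node annotations, so it is consistent with them by
#'   construction.
#' @export
setGeneric("motifIndex", function(x) standardGeneric("motifIndex"))

#' @rdname motifIndex
#' @export
setMethod("motifIndex", "Interactome", function(x) {
  m <- x@nodes$motifs
  if (!length(m) || !any(lengths(m) > 0)) return(list())
  idx <- split(rep(x@nodes$gene_name, lengths(m)), unlist(m))
  idx[order(names(idx))]
})

#' Proteins belonging to a motif
#' @param net an [Interactome-class].
#' @param motif motif identifier, e.g. \code{"M7"}.
#' @return Character vector of gene names (may be empty).
#' @export
motifProteins <- function(net, motif) {
  hit <- vapply(net@nodes$motifs, function(m) motif %in% m, logical(1))
  net@nodes$gene_name[hit]
}

#' Flag signature membership on an interactome
#'
#' Transfers a differential-expression signature (see [buildSignature()])
#' onto the node annotations.
#'
#' @param net an [Interactome-class].
#' @param signature \code{data.frame} with columns \code{gene_name} and
#'   \code{direction} (\code{"up"}/\code{"down"}).
#' @return The updated [Interactome-class].
#' @export
addSignature <- function(net, signature) {
  unknown <- setdiff(signature$gene_name, net@nodes$gene_name)
  if (length(unknown))
    stop("signature genes absent from the network: ",
         paste(unknown, collapse = ", "))
  i <- match(net@nodes$gene_name, signature$gene_name)
  net@nodes$in_signature <- !is.na(i)
  net@nodes$signature_direction <-
    ifelse(is.na(i), "none", as.character(signature$direction)[i])
  validObject(net)
  net
}

#' Activity values in solutions-by-proteins orientation
#' @param x an [ActivityMatrix-class].
#' @return Numeric matrix, solutions in rows and proteins in columns.
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' @rdname activityValues
#' @export
setMethod("activityValues", "ActivityMatrix", function(x)
  t(SummarizedExperiment::assay(x, "activity")))

#' Model name of an activity matrix
#' @param x an [ActivityMatrix-class].
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname modelName
#' @export
setMethod("modelName", "ActivityMatrix", function(x)
  S4Vectors::metadata(x)$model)

#' Per-solution seeds of an activity matrix
#' @param x an [ActivityMatrix-class].
#' @export
setGeneric("solutionSeeds", function(x) standardGeneric("solutionSeeds"))

#' @rdname solutionSeeds
#' @export
setMethod("solutionSeeds", "ActivityMatrix", function(x)
  SummarizedExperiment::colData(x)$seed)

#' Per-solution final losses of an activity matrix
#' @param x an [ActivityMatrix-class].
#' @export
setGeneric("solutionLosses", function(x) standardGeneric("solutionLosses"))

#' @rdname solutionLosses
#' @export
setMethod("solutionLosses", "ActivityMatrix", function(x)
  SummarizedExperiment::colData(x)$loss)

#' Cohort accessors
#' @param x a [CohortData-class].
#' @return Numeric solutions x proteins matrix.
#' @export
positiveCohort <- function(x) x@positive

#' @rdname positiveCohort
#' @export
negativeCohort <- function(x) x@negative
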