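#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats rnorm runif pnorm phyper pbinom wilcox.test cor glm
#'   binomial predict sd setNames quantile rbinom
#' @importFrom utils combn read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# Interactome
# ---------------------------------------------------------------------------

#' Signed directed protein-interaction network with node annotations
#'
#' An \code{Interactome} holds the protein nodes (with motif membership,
#' effector status, expression-signature membership and plasma/urine
#' measurability flags) and the signed directed edges between them, plus an
#' \pkg{igraph} representation used for traversal queries.
#'
#' Edge signs are \code{+1} (activation), \code{-1} (inhibition) or \code{0}
#' (unknown). Unknown signs propagate signal as \code{+1} but are kept as 0 in
#' the edge table so the uncertainty stays on record.
#'
#' @slot nodes \code{data.frame} with columns \code{gene_name},
#'   \code{uniprot}, \code{motifs} (list column of character vectors),
#'   \code{effector}, \code{in_signature}, \code{signature_direction}
#'   (\code{"up"}, \code{"down"} or \code{"none"}), \code{plasma},
#'   \code{urine}.
#' @slot edges \code{data.frame} with columns \code{source}, \code{target},
#'   \code{sign} (\code{-1}, \code{0}, \code{+1}) and \code{provenance}.
#' @slot graph internal \pkg{igraph} object mirroring \code{edges}.
#'
#' @seealso [Interactome()], [loadNetwork()], [kHopNeighborhood()],
#'   [motifConnectivity()], [hypergeomEnrichment()]
#' @export
setClass("Interactome",
  slots = c(nodes = "data.frame", edges = "data.frame", graph = "ANY"))

setValidity("Interactome", function(object) {
  nd <- object@nodes
  ed <- object@edges
  needN <- c("gene_name", "uniprot", "motifs", "effector", "in_signature",
             "signature_direction", "plasma", "urine")
  needE <- c("source", "target", "sign", "provenance")
  if (!all(needN %in% names(nd)))
    return(paste("node table misses columns:",
                 paste(setdiff(needN, names(nd)), collapse = ", ")))
  if (!all(needE %in% names(ed)))
    return(paste("edge table misses columns:",
                 paste(setdiff(needE, names(ed)), collapse = ", ")))
  dup <- nd$gene_name[duplicated(nd$gene_name)]
  if (length(dup))
    return(paste("duplicate gene_name:", paste(unique(dup), collapse = ", ")))
  unknown <- setdiff(unique(c(ed$source, ed$target)), nd$gene_name)
  if (length(unknown))
    return(paste("edges reference undeclared genes:",
                 paste(unknown, collapse = ", ")))
  if (nrow(ed) && !all(ed$sign %in% c(-1, 0, 1)))
    return("edge signs must be -1, 0 or +1")
  if (anyDuplicated(ed[c("source", "target", "sign")]))
    return("duplicate (source, target, sign) edges")
  if (!all(nd$signature_direction %in% c("up", "down", "none")))
    return("signature_direction must be 'up', 'down' or 'none'")
  if (any((nd$signature_direction == "none") != !nd$in_signature))
    return("signature_direction must be 'none' exactly for genes not in the signature")
  TRUE
})

#' Construct an Interactome from edge and node tables
#'
#' @param edges \code{data.frame} with columns \code{source}, \code{target},
#'   \code{sign} and optionally \code{provenance} (defaults to \code{""}).
#' @param nodes \code{data.frame} with column \code{gene_name} and optional
#'   annotation columns \code{uniprot}, \code{motifs} (either a list column or
#'   semicolon-separated strings), \code{effector}, \code{in_signature},
#'   \code{signature_direction}, \code{plasma}, \code{urine}. Missing
#'   annotations default to empty / \code{FALSE} / \code{"none"}.
#'
#' @return A validated [Interactome-class] object.
#' @examples
#' net <- Interactome(
#'   edges = data.frame(source = c("A", "B"), target = c("B", "C"),
#'                      sign = c(1, -1)),
#'   nodes = data.frame(gene_name = c("A", "B", "C")))
#' net
#' @export
Interactome <- function(edges, nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$gene_name)) stop("node table needs a 'gene_name' column")
  if (is.null(nodes$uniprot)) nodes$uniprot <- NA_character_
  if (is.null(nodes$motifs)) {
    nodes$motifs <- replicate(nrow(nodes), character(0), simplify = FALSE)
  } else if (!is.list(nodes$motifs)) {
    nodes$motifs <- lapply(strsplit(as.character(nodes$motifs), ";",
                                    fixed = TRUE),
                           function(m) m[nzchar(m)])
  }
  for (col in c("effector", "in_signature", "plasma", "urine"))
    nodes[[col]] <- if (is.null(nodes[[col]])) rep(FALSE, nrow(nodes))
                    else as.logical(nodes[[col]])
  if (is.null(nodes$signature_direction))
    nodes$signature_direction <- ifelse(nodes$in_signature, "up", "none")
  if (nrow(edges) == 0)
    edges <- data.frame(source = character(0), target = character(0),
                        sign = numeric(0), provenance = character(0))
  if (is.null(edges$provenance)) edges$provenance <- rep("", nrow(edges))
  edges$sign <- as.numeric(edges$sign)
  dup <- unique(nodes$gene_name[duplicated(nodes$gene_name)])
  if (length(dup))
    stop("duplicate gene_name: ", paste(dup, collapse = ", "))
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes$gene_name)
  if (length(unknown))
    stop("edges reference undeclared genes: ",
         paste(unknown, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges[c("source", "target")], directed = TRUE,
    vertices = nodes["gene_name"])
  new("Interactome", nodes = nodes, edges = edges, graph = g)
}

setMethod("show", "Interactome", function(object) {
  cat(sprintf("Interactome: %d proteins, %d signed directed edges\n",
              nrow(object@nodes), nrow(object@edges)))
  mi <- motifIndex(object)
  if (length(mi))
    cat("  motifs:",
        paste(sprintf("%s(%d)", names(mi), lengths(mi)), collapse = " "),
        "\n")
  cat(sprintf("  effectors: %d | in signature: %d | plasma: %d | urine: %d\n",
              sum(object@nodes$effector), sum(object@nodes$in_signature),
              sum(object@nodes$plasma), sum(object@nodes$urine)))
})

# ---------------------------------------------------------------------------
# ModelConfig
# ---------------------------------------------------------------------------

#' A disease-model configuration (stimulus / restrictions / response)
#'
#' One mathematical model is defined by three components: the \emph{stimulus}
#' (trigger proteins clamped to fixed activities), the \emph{restrictions}
#' (proteins with a required activity sign, e.g. from an expression
#' signature), and the \emph{response} (the motif combination whose effector
#' proteins must come out active).
#'
#' @slot name model name, e.g. \code{"GD1 with skeletal complications"}.
#' @slot stimulus named numeric vector of clamped activities in \[-1, 1\].
#' @slot restrictions \code{data.frame} with columns \code{gene} and
#'   \code{sign} (\code{+1}/\code{-1}).
#' @slot response character vector of motif identifiers.
#'
#' @seealso [enumerateModelConfigs()], [sampleSolutions()]
#' @export
setClass("ModelConfig",
  slots = c(name = "character", stimulus = "numeric",
            restrictions = "data.frame", response = "character"))

setValidity("ModelConfig", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  s <- object@stimulus
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      return("stimulus must be a named vector")
    if (any(!is.finite(s)) || any(abs(s) > 1))
      return("stimulus activities must lie in [-1, 1]")
  }
  r <- object@restrictions
  if (nrow(r)) {
    if (!all(c("gene", "sign") %in% names(r)))
      return("restrictions need 'gene' and 'sign' columns")
    if (!all(r$sign %in% c(-1, 1)))
      return("restriction signs must be -1 or +1")
  }
  TRUE
})

#' @describeIn ModelConfig-class constructor.
#' @param name,stimulus,restrictions,response see slot descriptions.
#' @export
ModelConfig <- function(name, stimulus = numeric(0),
                        restrictions = data.frame(gene = character(0),
                                                  sign = numeric(0)),
                        response = character(0)) {
  new("ModelConfig", name = name, stimulus = stimulus,
      restrictions = as.data.frame(restrictions), response = response)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig '%s'\n  response motifs: %s\n", object@name,
              paste(object@response, collapse = ", ")))
  cat(sprintf("  stimulus: %d clamped protein(s) | restrictions: %d\n",
              length(object@stimulus), nrow(object@restrictions)))
})

# ---------------------------------------------------------------------------
# ActivityMatrix
# ---------------------------------------------------------------------------

#' Solutions-by-proteins matrix of predicted activities
#'
#' An \code{ActivityMatrix} extends
#' \linkS4class{SummarizedExperiment}: the \code{"activity"} assay stores
#' predicted protein activities in \[-1, 1\] with proteins as rows and model
#' solutions as columns; \code{colData} records the per-solution seed, final
#' loss and failure flag; \code{metadata} records the model name, its response
#' motifs and the acceptance tolerance. [activityValues()] returns the
#' conventional solutions x proteins orientation.
#'
#' @seealso [sampleSolutions()], [generateEnsembleDataset()],
#'   [writeActivityMatrix()]
#' @export
setClass("ActivityMatrix", contains = "SummarizedExperiment")

setValidity("ActivityMatrix", function(object) {
  if (!"activity" %in% SummarizedExperiment::assayNames(object))
    return("an 'activity' assay is required")
  a <- SummarizedExperiment::assay(object, "activity")
  if (any(abs(a) > 1 + 1e-12, na.rm = TRUE))
    return("activities must lie in [-1, 1]")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("seed", "loss") %in% names(cd)))
    return("colData needs 'seed' and 'loss' columns")
  TRUE
})

#' Build an ActivityMatrix from a solutions x proteins matrix
#'
#' @param values numeric matrix, solutions in rows, proteins in columns
#'   (column names are gene names).
#' @param model model name stored in the metadata.
#' @param seeds integer vector of per-solution seeds (one per row).
#' @param losses numeric vector of final per-solution losses.
#' @param response character vector of response motif ids, if known.
#' @param tolerance solution acceptance tolerance used when sampling.
#'
#' @return An [ActivityMatrix-class].
#' @examples
#' am <- ActivityMatrix(matrix(0, 3, 2, dimnames = list(NULL, c("A", "B"))),
#'                      model = "toy")
#' activityValues(am)
#' @export
ActivityMatrix <- function(values, model = "model", seeds = NULL,
                           losses = NULL, response = character(0),
                           tolerance = NA_real_) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("'values' must have proteins as named columns")
  n <- nrow(values)
  if (is.null(seeds)) seeds <- rep(NA_integer_, n)
  if (is.null(losses)) losses <- rep(NA_real_, n)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = t(values)),
    colData = S4Vectors::DataFrame(seed = seeds, loss = losses,
                                   row.names = sprintf("sol%03d", seq_len(n))),
    metadata = list(model = model, response = response,
                    tolerance = tolerance))
  new("ActivityMatrix", se)
}

setMethod("show", "ActivityMatrix", function(object) {
  cat(sprintf("ActivityMatrix '%s': %d solutions x %d proteins\n",
              modelName(object), ncol(object), nrow(object)))
  rsp <- S4Vectors::metadata(object)$response
  if (length(rsp)) cat("  response motifs:", paste(rsp, collapse = ", "), "\n")
  ls <- SummarizedExperiment::colData(object)$loss
  if (!all(is.na(ls)))
    cat(sprintf("  losses: mean %.4g, max %.4g\n",
                mean(ls, na.rm = TRUE), max(ls, na.rm = TRUE)))
})

# ---------------------------------------------------------------------------
# CohortData
# ---------------------------------------------------------------------------

#' Pooled positive/negative cohorts of model solutions
#'
#' Rows of solution ensembles pooled by class, e.g. all solutions from
#' skeletal-complication models (positive) versus all solutions from the
#' remaining models (negative). Labels are implied by origin.
#'
#' @slot positive,negative numeric matrices (solutions x proteins) with
#'   identical protein columns.
#' @seealso [cohortData()], [cleanVariables()], [searchCandidates()]
#' @export
setClass("CohortData", slots = c(positive = "matrix", negative = "matrix"))

setValidity("CohortData", function(object) {
  if (nrow(object@positive) == 0 || nrow(object@negative) == 0)
    return("both cohorts must be non-empty")
  if (!identical(colnames(object@positive), colnames(object@negative)))
    return("cohorts must share identical protein columns")
  if (is.null(colnames(object@positive)))
    return("protein columns must be named")
  TRUE
})

#' Pool activity matrices into a two-cohort data set
#'
#' @param positive,negative an [ActivityMatrix-class], a plain solutions x
#'   proteins matrix, or a list of either; list elements are row-bound.
#' @return A [CohortData-class].
#' @export
cohortData <- function(positive, negative) {
  pool <- function(x) {
    if (is(x, "ActivityMatrix")) return(activityValues(x))
    if (is.matrix(x)) return(x)
    if (is.list(x)) return(do.call(rbind, lapply(x, pool)))
    stop("cohorts must be matrices, ActivityMatrix objects, or lists of them")
  }
  new("CohortData", positive = pool(positive), negative = pool(negative))
}

setMethod("show", "CohortData", function(object) {
  cat(sprintf("CohortData: %d positive / %d negative solutions, %d proteins\n",
              nrow(object@positive), nrow(object@negative),
              ncol(object@positive)))
})

# ---------------------------------------------------------------------------
# FilterConfig / FilterReport
# ---------------------------------------------------------------------------

#' Thresholds for the candidate prioritization cascade
#'
#' @slot referenceBacc cross-validated balanced accuracy of the best
#'   previously proposed biomarker; candidates must strictly exceed it.
#'   The default 0.5854 is the published benchmark set by the chemokine
#'   CCL4/MIP-1beta.
#' @slot minSensitivity,minPrecision minimum cross-validated sensitivity and
#'   precision (both default 0.65).
#' @slot unmodulatedFraction a candidate is discarded when any member protein
#'   is unmodulated in at least this fraction of solutions of either cohort
#'   (default 0.75).
#' @slot unmodulatedTolerance absolute activity below which a protein counts
#'   as unmodulated (default 0.05).
#' @seealso [filterConfig()], [applyFilterCascade()]
#' @export
setClass("FilterConfig",
  slots = c(referenceBacc = "numeric", minSensitivity = "numeric",
            minPrecision = "numeric", unmodulatedFraction = "numeric",
            unmodulatedTolerance = "numeric"))

setValidity("FilterConfig", function(object) {
  v <- c(object@referenceBacc, object@minSensitivity, object@minPrecision,
         object@unmodulatedFraction, object@unmodulatedTolerance)
  if (length(v) != 5 || any(!is.finite(v)) || any(v < 0) || any(v > 1))
    return("all thresholds must be single values in [0, 1]")
  TRUE
})

#' @describeIn FilterConfig-class constructor with the default thresholds.
#' @param referenceBacc,minSensitivity,minPrecision,unmodulatedFraction,unmodulatedTolerance
#'   see slot descriptions.
#' @export
filterConfig <- function(referenceBacc = 0.5854, minSensitivity = 0.65,
                         minPrecision = 0.65, unmodulatedFraction = 0.75,
                         unmodulatedTolerance = 0.05) {
  new("FilterConfig", referenceBacc = referenceBacc,
      minSensitivity = minSensitivity, minPrecision = minPrecision,
      unmodulatedFraction = unmodulatedFraction,
      unmodulatedTolerance = unmodulatedTolerance)
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(paste0("FilterConfig: BACC > %.4f, sensitivity >= %.2f, ",
                     "precision >= %.2f,\n  unmodulated = |activity| < %.2f ",
                     "in >= %.0f%% of either cohort\n"),
              object@referenceBacc, object@minSensitivity,
              object@minPrecision, object@unmodulatedTolerance,
              100 * object@unmodulatedFraction))
})

#' Outcome of the filter cascade
#'
#' @slot survivors \code{data.frame} of candidates passing every filter.
#' @slot rejected \code{data.frame} with columns \code{proteins} and
#'   \code{filter} naming, for each discarded candidate, the first filter it
#'   failed (\code{"reference_bacc"}, \code{"sensitivity_precision"},
#'   \code{"unmodulated"} or \code{"other_complications"}).
#' @slot config the [FilterConfig-class] that was applied.
#' @seealso [applyFilterCascade()], [annotateAndRank()]
#' @export
setClass("FilterReport",
  slots = c(survivors = "data.frame", rejected = "data.frame",
            config = "FilterConfig"))

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d survivor(s), %d rejected\n",
              nrow(object@survivors), nrow(object@rejected)))
  if (nrow(object@rejected)) {
    tab <- table(object@rejected$filter)
    cat("  rejections:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
})

#' @describeIn FilterReport-class candidates passing every filter.
#' @param object,x a \code{FilterReport}.
#' @export
survivors <- function(x) x@survivors

#' @describeIn FilterReport-class rejected candidates with the first failed
#'   filter each.
#' @export
rejections <- function(x) x@rejected

# ---------------------------------------------------------------------------
# SyntheticSpec
# ---------------------------------------------------------------------------

#' Parameters of the synthetic ground-truth generators
#'
#' Controls both generation tiers: the fast matrix tier
#' ([generateEnsembleDataset()], clipped-Gaussian activities with planted
#' between-cohort mean shifts) and the network tier
#' ([generateEndToEndDataset()], a full scale-free signed interactome with
#' motif annotations, model configurations, a differential-expression table
#' and measurability tables).
#'
#' @slot nProteins number of proteins (default 423, the size of the
#'   disease-related protein set explored by the study design).
#' @slot nSolutions solutions per cohort/model (default 250).
#' @slot plantedMarkers named numeric vector: per-marker effect size delta,
#'   the positive-cohort mean shift in activity units.
#' @slot noiseSigma activity noise s.d. (default 0.25, so the default
#'   delta = 0.5 is a 2-sigma gap with Bayes-optimal balanced accuracy
#'   \code{pnorm(1)}).
#' @slot baseline common activity mean before shifts (default 0).
#' @slot motifSizes named integer vector of motif sizes, or \code{"auto"} to
#'   scale the canonical motif proportions (6/24/12/21/43/85 for
#'   M1/M2/M3/M5/M6/M7) to \code{nProteins}.
#' @slot networkAttachment out-degree of the preferential-attachment overlay
#'   (default 2).
#' @slot negativeEdgeProb probability that an overlay edge is inhibitory
#'   (default 0.2).
#' @slot seed master seed; every generated artifact is reproducible from it.
#' @seealso [syntheticSpec()]
#' @export
setClass("SyntheticSpec",
  slots = c(nProteins = "numeric", nSolutions = "numeric",
            plantedMarkers = "numeric", noiseSigma = "numeric",
            baseline = "numeric", motifSizes = "ANY",
            networkAttachment = "numeric", negativeEdgeProb = "numeric",
            seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
  if (object@nProteins < 1) return("nProteins must be >= 1")
  if (object@nSolutions < 1) return("nSolutions must be >= 1")
  if (any(object@plantedMarkers < 0)) return("effect sizes must be >= 0")
  if (object@noiseSigma <= 0) return("noiseSigma must be > 0")
  if (object@negativeEdgeProb < 0 || object@negativeEdgeProb > 1)
    return("negativeEdgeProb must be in [0, 1]")
  ms <- object@motifSizes
  if (is.numeric(ms) && sum(ms) > object@nProteins)
    return("motif sizes must sum to at most nProteins")
  TRUE
})

#' @describeIn SyntheticSpec-class constructor.
#' @param nProteins,nSolutions,plantedMarkers,noiseSigma,baseline,motifSizes,networkAttachment,negativeEdgeProb,seed
#'   see slot descriptions.
#' @export
syntheticSpec <- function(nProteins = 423, nSolutions = 250,
                          plantedMarkers = c(MK_SKEL = 0.5),
                          noiseSigma = 0.25, baseline = 0,
                          motifSizes = "auto", networkAttachment = 2,
                          negativeEdgeProb = 0.2, seed = 1) {
  new("SyntheticSpec", nProteins = nProteins, nSolutions = nSolutions,
      plantedMarkers = plantedMarkers, noiseSigma = noiseSigma,
      baseline = baseline, motifSizes = motifSizes,
      networkAttachment = networkAttachment,
      negativeEdgeProb = negativeEdgeProb, seed = seed)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d proteins, %d solutions/cohort, ",
                     "sigma=%.3g, seed=%d\n"),
              object@nProteins, object@nSolutions, object@noiseSigma,
              as.integer(object@seed)))
  if (length(object@plantedMarkers))
    cat("  planted markers:",
        paste(sprintf("%s(delta=%.3g)", names(object@plantedMarkers),
                      object@plantedMarkers), collapse = " "), "\n")
})
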