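# Candidate search over 1-3 protein tuples and the full discovery pipeline.

.canonicalKey <- function(proteins) paste(sort(proteins), collapse = "+")

#' Search 1-3 protein classifier candidates
#'
#' Enumerates protein tuples, cross-validates every configured base
#' classifier on each, and keeps the best classifier per tuple by
#' cross-validated balanced accuracy. Single-protein candidates are explored
#' exhaustively by brute force; pairs and triples are explored over the
#' union of the mandatory feature-selection shortlists (mRMR, ReliefF,
#' Wilcoxon-with-correlation; see [rankFeatures()]) unless
#' \code{exhaustive = TRUE} enumerates all tuples. \code{maxTuples} caps
#' enumeration per size; when it bites, the result carries
#' \code{attr(, "truncated") = TRUE}.
#'
#' @param data a [CohortData-class]; constant columns are cleaned away
#'   first (see [cleanVariables()]).
#' @param sizes tuple sizes to explore, subset of \code{1:3}.
#' @param kinds1 base classifiers for single proteins (default linear
#'   threshold).
#' @param kindsMulti base classifiers for pairs/triples (default logistic
#'   and naive Bayes; \code{"small_mlp"} may be added).
#' @param k cross-validation folds (default 10).
#' @param seed seed for folds and feature ranking.
#' @param shortlistK per-method shortlist length for sizes 2-3 (default
#'   10).
#' @param exhaustive enumerate all tuples for sizes 2-3 instead of the
#'   shortlist union.
#' @param maxTuples enumeration budget per size (default 50000).
#' @return \code{data.frame} sorted by decreasing \code{bacc} (ties by
#'   protein key) with columns \code{proteins} (canonical
#'   \code{"A+B"} key), \code{size}, \code{model_kind}, \code{bacc},
#'   \code{sensitivity}, \code{specificity}, \code{precision}, \code{cv_p}.
#' @export
searchCandidates <- function(data, sizes = 1, kinds1 = "linear_threshold",
                             kindsMulti = c("logistic", "naive_bayes"),
                             k = 10, seed = 1, shortlistK = 10,
                             exhaustive = FALSE, maxTuples = 50000) {
  if (!length(sizes) || !all(sizes %in% 1:3))
    stop("'sizes' must be a non-empty subset of 1:3")
  data <- cleanVariables(data)
  proteins <- colnames(data@positive)
  truncated <- FALSE
  rows <- list()
  for (s in sort(sizes)) {
    if (s == 1) {
      tuples <- as.list(proteins)
      kinds <- kinds1
    } else {
      pool <- if (exhaustive || length(proteins) <= shortlistK) proteins
      else sort(unique(unlist(lapply(
        c("mrmr", "relieff", "wilcoxon_corr"), function(m)
          rankFeatures(data, m, k = min(shortlistK, length(proteins)),
                       seed = seed)))))
      if (length(pool) < s) next
      tuples <- combn(pool, s, simplify = FALSE)
      kinds <- kindsMulti
    }
    if (length(tuples) > maxTuples) {
      tuples <- tuples[seq_len(maxTuples)]
      truncated <- TRUE
    }
    for (tp in tuples) {
      best <- NULL
      for (kind in kinds) {
        m <- crossValidateCandidate(data, tp, kind, k = k, seed = seed)
        if (is.null(best) || (!is.na(m$bacc) && m$bacc > best$bacc))
          best <- m
      }
      rows[[length(rows) + 1L]] <- data.frame(
        proteins = .canonicalKey(tp), size = s,
        model_kind = best$model_kind, bacc = best$bacc,
        sensitivity = best$sensitivity, specificity = best$specificity,
        precision = best$precision, cv_p = best$cv_p,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(proteins = character(0), size = integer(0),
                         model_kind = character(0), bacc = numeric(0),
                         sensitivity = numeric(0), specificity = numeric(0),
                         precision = numeric(0), cv_p = numeric(0))
  out <- out[order(-out$bacc, out$proteins), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}

#' Run the full biomarker-discovery comparison pipeline
#'
#' Builds the three case-versus-rest comparisons (skeletal \code{M7},
#' bone-marrow \code{M5} and liver \code{M6} complications), searches
#' candidates in each, applies filters 1-3 per comparison, and finally
#' removes skeletal candidates that also pass filters 1-3 in the
#' bone-marrow or liver comparison (filter 4). For each comparison the
#' positive cohort pools the solutions of every model whose response
#' contains the motif, the negative cohort pools the rest.
#'
#' @param matrices list of [ActivityMatrix-class] objects (one per model),
#'   each carrying its response motifs in the metadata, as produced by
#'   [sampleSolutions()].
#' @param cfg a [FilterConfig-class].
#' @param sizes,kinds1,kindsMulti,k,seed,shortlistK passed to
#'   [searchCandidates()].
#' @return List with \code{report} (the final skeletal
#'   [FilterReport-class]), \code{candidates} (per-comparison candidate
#'   tables) and \code{survivorKeys} (per-comparison filter 1-3 survivor
#'   keys).
#' @export
biomarkerDiscovery <- function(matrices, cfg = filterConfig(), sizes = 1:2,
                               kinds1 = "linear_threshold",
                               kindsMulti = c("logistic", "naive_bayes"),
                               k = 10, seed = 1, shortlistK = 10) {
  responses <- lapply(matrices, function(m) S4Vectors::metadata(m)$response)
  comparisons <- c(skeletal = "M7", bm = "M5", liver = "M6")
  cands <- list()
  keys <- list()
  cohorts <- list()
  for (nm in names(comparisons)) {
    motif <- comparisons[[nm]]
    isPos <- vapply(responses, function(r) motif %in% r, logical(1))
    if (!any(isPos) || all(isPos))
      stop("comparison ", nm, ": need models both with and without ", motif)
    cd <- cohortData(matrices[isPos], matrices[!isPos])
    cohorts[[nm]] <- cd
    cands[[nm]] <- searchCandidates(cd, sizes = sizes, kinds1 = kinds1,
                                    kindsMulti = kindsMulti, k = k,
                                    seed = seed, shortlistK = shortlistK)
    rep13 <- applyFilterCascade(cands[[nm]], cfg,
                                positive = positiveCohort(cd),
                                negative = negativeCohort(cd))
    keys[[nm]] <- survivors(rep13)$proteins
  }
  final <- applyFilterCascade(
    cands$skeletal, cfg,
    positive = positiveCohort(cohorts$skeletal),
    negative = negativeCohort(cohorts$skeletal),
    otherSurvivors = list(bm = keys$bm, liver = keys$liver))
  list(report = final, candidates = cands, survivorKeys = keys)
}
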