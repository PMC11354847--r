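# Candidate prioritization: the four-filter cascade and measurability
# annotation.

.splitKey <- function(key) strsplit(key, "+", fixed = TRUE)[[1]]

.unmodulatedFraction <- function(mat, gene, tol) {
  if (!gene %in% colnames(mat))
    stop("activity matrix has no column for candidate protein: ", gene)
  mean(abs(mat[, gene]) < tol)
}

#' Apply the prioritization filter cascade
#'
#' Sequential filters over scored candidates:
#' \enumerate{
#'   \item \strong{reference_bacc}: cross-validated balanced accuracy must
#'     \emph{strictly} exceed \code{cfg@referenceBacc} (only candidates
#'     improving on the best previously proposed biomarker are retained);
#'   \item \strong{sensitivity_precision}: sensitivity and precision both at
#'     least their thresholds (default 65\%);
#'   \item \strong{unmodulated}: discard candidates containing a protein
#'     whose activity magnitude is below \code{cfg@unmodulatedTolerance} in
#'     at least \code{cfg@unmodulatedFraction} of the solutions of either
#'     cohort (heterogeneity guard: member proteins must be modulated
#'     homogeneously);
#'   \item \strong{other_complications}: discard candidates that also passed
#'     filters 1-3 for the bone-marrow or liver comparison (specificity for
#'     the skeletal comparison). Candidate identity is the unordered protein
#'     tuple.
#' }
#' Each rejected candidate is attributed to the \emph{first} filter it
#' fails. Filters 1-3 are pure per-candidate predicates, so the survivor
#' set does not depend on their order, only the rejection attribution does.
#'
#' @param candidates candidate \code{data.frame} as returned by
#'   [searchCandidates()] (columns \code{proteins}, \code{bacc},
#'   \code{sensitivity}, \code{precision}, ...).
#' @param cfg a [FilterConfig-class].
#' @param positive,negative solutions x proteins activity matrices of the
#'   two compared cohorts (for filter 3).
#' @param otherSurvivors list of character vectors of candidate keys that
#'   survived filters 1-3 in the other comparisons (e.g.
#'   \code{list(bm = ..., liver = ...)}); empty by default, which disables
#'   filter 4.
#' @return A [FilterReport-class].
#' @export
applyFilterCascade <- function(candidates, cfg, positive, negative,
                               otherSurvivors = list()) {
  stopifnot(is(cfg, "FilterConfig"))
  need <- c("proteins", "bacc", "sensitivity", "precision")
  if (!all(need %in% names(candidates)))
    stop("candidates need columns: ", paste(need, collapse = ", "))
  otherKeys <- unique(unlist(lapply(otherSurvivors, function(x) {
    if (is.data.frame(x)) x <- x$proteins
    vapply(x, function(k) .canonicalKey(.splitKey(k)), character(1))
  })))
  failedAt <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    genes <- .splitKey(candidates$proteins[i])
    failedAt[i] <-
      if (!(candidates$bacc[i] > cfg@referenceBacc)) "reference_bacc"
      else if (is.na(candidates$sensitivity[i]) ||
               is.na(candidates$precision[i]) ||
               candidates$sensitivity[i] < cfg@minSensitivity ||
               candidates$precision[i] < cfg@minPrecision)
        "sensitivity_precision"
      else if (any(vapply(genes, function(g)
        max(.unmodulatedFraction(positive, g, cfg@unmodulatedTolerance),
            .unmodulatedFraction(negative, g, cfg@unmodulatedTolerance)) >=
          cfg@unmodulatedFraction, logical(1)))) "unmodulated"
      else if (.canonicalKey(genes) %in% otherKeys) "other_complications"
      else ""
  }
  ok <- failedAt == ""
  surv <- candidates[ok, , drop = FALSE]
  rownames(surv) <- NULL
  rej <- data.frame(proteins = candidates$proteins[!ok],
                    filter = failedAt[!ok], stringsAsFactors = FALSE)
  new("FilterReport", survivors = surv, rejected = rej, config = cfg)
}

#' Annotate survivors with measurability and rank by balanced accuracy
#'
#' Looks each member protein up in the plasma and urine measurability
#' tables, flags candidates whose every member is measurable in plasma
#' (the most clinically actionable panels), and returns the table ranked
#' from lowest to highest cross-validated balanced accuracy.
#'
#' @param report a [FilterReport-class].
#' @param plasmaTable,urineTable named logical vectors: gene to
#'   measurable-in-plasma/urine. Genes missing from both tables are
#'   annotated \code{NA} with a warning.
#' @return \code{data.frame}: the survivor table plus \code{plasma} and
#'   \code{urine} (semicolon-separated per-protein \code{Yes}/\code{No}
#'   flags) and logical \code{all_plasma}, sorted ascending by
#'   \code{bacc}.
#' @export
annotateAndRank <- function(report, plasmaTable, urineTable) {
  surv <- survivors(report)
  if (!nrow(surv)) {
    surv$plasma <- character(0); surv$urine <- character(0)
    surv$all_plasma <- logical(0)
    return(surv)
  }
  fmt <- function(v) ifelse(is.na(v), "Unknown", ifelse(v, "Yes", "No"))
  plasma <- urine <- character(nrow(surv))
  allPlasma <- logical(nrow(surv))
  for (i in seq_len(nrow(surv))) {
    genes <- .splitKey(surv$proteins[i])
    pl <- unname(plasmaTable[genes])
    ur <- unname(urineTable[genes])
    missing <- genes[is.na(pl) & is.na(ur)]
    if (length(missing))
      warning("gene(s) missing from both measurability tables: ",
              paste(missing, collapse = ", "))
    plasma[i] <- paste(fmt(pl), collapse = ";")
    urine[i] <- paste(fmt(ur), collapse = ";")
    allPlasma[i] <- all(!is.na(pl) & pl)
  }
  surv$plasma <- plasma
  surv$urine <- urine
  surv$all_plasma <- allPlasma
  surv <- surv[order(surv$bacc, surv$proteins), , drop = FALSE]
  rownames(surv) <- NULL
  surv
}
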