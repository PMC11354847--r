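# Differential-expression signature construction.

#' Build a protein expression signature from differential-expression results
#'
#' Applies the two inclusive thresholds used throughout this package to a
#' table of per-gene differential-expression statistics: a gene enters the
#' signature when \code{adj_p <= alpha} \emph{and} \code{|log2fc| >=
#' minAbsLfc} \emph{and} it maps to a protein of the supplied universe. The
#' direction is \code{"up"} for positive and \code{"down"} for negative log2
#' fold changes.
#'
#' The input table must already be collapsed to one record per gene (probe
#' collapsing is a concern of the upstream expression analysis): duplicated
#' genes whose records disagree raise an error rather than being silently
#' merged; exact duplicate records are de-duplicated.
#'
#' @param records \code{data.frame} with columns \code{gene_name},
#'   \code{log2fc} and \code{adj_p}.
#' @param alpha adjusted p-value threshold (inclusive; default 0.05).
#' @param minAbsLfc minimum absolute log2 fold change (inclusive; default 1).
#' @param proteinUniverse character vector of gene names that map to
#'   proteins; genes outside it are excluded.
#' @return \code{data.frame} with columns \code{gene_name} and
#'   \code{direction} (\code{"up"}/\code{"down"}), ordered by gene name so
#'   the result is invariant to record order.
#' @examples
#' de <- data.frame(gene_name = c("G1", "G2", "G3", "G4"),
#'                  log2fc = c(1.5, -2, 3, 0.5),
#'                  adj_p = c(0.01, 0.04, 0.06, 0.01))
#' buildSignature(de, proteinUniverse = de$gene_name)
#' @export
buildSignature <- function(records, alpha = 0.05, minAbsLfc = 1.0,
                           proteinUniverse) {
  if (alpha <= 0 || minAbsLfc <= 0) stop("thresholds must be positive")
  if (missing(proteinUniverse) || !length(proteinUniverse))
    stop("'proteinUniverse' must be a non-empty set of gene names")
  need <- c("gene_name", "log2fc", "adj_p")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  records <- unique(records[need])
  if (any(!is.finite(records$log2fc)))
    stop("log2fc must be finite")
  if (any(records$adj_p < 0 | records$adj_p > 1))
    stop("adj_p must lie in [0, 1]")
  dup <- unique(records$gene_name[duplicated(records$gene_name)])
  if (length(dup))
    stop("conflicting records for gene(s): ", paste(dup, collapse = ", "),
         " (collapse probes upstream)")
  keep <- records$adj_p <= alpha &
    abs(records$log2fc) >= minAbsLfc &
    records$gene_name %in% proteinUniverse
  out <- data.frame(
    gene_name = records$gene_name[keep],
    direction = ifelse(records$log2fc[keep] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
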