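# Feature selection for 2-3 protein classifier shortlists.

.relevance <- function(X, y) abs(suppressWarnings(cor(X, as.numeric(y))))

.mrmr <- function(X, y, k) {
  p <- ncol(X)
  rel <- as.numeric(.relevance(X, y))
  rel[is.na(rel)] <- 0
  C <- abs(suppressWarnings(cor(X)))
  C[is.na(C)] <- 0
  sel <- integer(0)
  avail <- seq_len(p)
  for (step in seq_len(k)) {
    score <- if (!length(sel)) rel[avail]
             else rel[avail] - colMeans(C[sel, avail, drop = FALSE])
    pick <- avail[which.max(score)]    # which.max: lowest index on ties
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  sel
}

.relieff <- function(X, y, k, nNeighbors = 10, sampleFrac = 1) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) max(v) - min(v))
  rng[rng == 0] <- 1
  Xs <- sweep(X, 2, rng, "/")
  m <- max(2L, ceiling(sampleFrac * n))
  ridx <- if (m >= n) seq_len(n) else sample.int(n, m)
  W <- numeric(p)
  for (i in ridx) {
    d <- rowSums(sweep(Xs, 2, Xs[i, ], "-")^2)
    d[i] <- Inf
    hits <- which(y == y[i]); hits <- hits[hits != i]
    miss <- which(y != y[i])
    nh <- hits[order(d[hits])][seq_len(min(nNeighbors, length(hits)))]
    nm <- miss[order(d[miss])][seq_len(min(nNeighbors, length(miss)))]
    W <- W - colMeans(abs(sweep(Xs[nh, , drop = FALSE], 2, Xs[i, ], "-"))) +
             colMeans(abs(sweep(Xs[nm, , drop = FALSE], 2, Xs[i, ], "-")))
  }
  order(-W / length(ridx), seq_len(p))[seq_len(k)]
}

.wilcoxonCorr <- function(X, y, k, corCutoff = 0.8) {
  p <- ncol(X)
  pv <- vapply(seq_len(p), function(j)
    suppressWarnings(wilcox.test(X[y, j], X[!y, j],
                                 exact = FALSE)$p.value), numeric(1))
  pv[is.na(pv)] <- 1
  ord <- order(pv, seq_len(p))
  C <- abs(suppressWarnings(cor(X)))
  sel <- integer(0)
  for (j in ord) {
    if (length(sel) == k) break
    if (!length(sel) || all(C[j, sel] <= corCutoff | is.na(C[j, sel])))
      sel <- c(sel, j)
  }
  # top up with the remaining best-ranked features if the correlation
  # filter left fewer than k
  if (length(sel) < k)
    sel <- c(sel, setdiff(ord, sel)[seq_len(k - length(sel))])
  sel
}

#' Rank protein features for multivariate classifier shortlists
#'
#' Ranks the protein columns of a two-cohort data set by one of the
#' implemented feature-selection methods and returns the top \code{k}
#' genes. Implemented methods: \code{"mrmr"} (maximum relevance, minimum
#' redundancy: point-biserial relevance minus mean absolute correlation
#' with already-selected features), \code{"relieff"} (ReliefF with
#' nearest hits/misses on range-scaled features) and
#' \code{"wilcoxon_corr"} (rank-sum p-value ordering with a greedy
#' correlation filter at |r| > 0.8). \code{"chow_liu"},
#' \code{"rfe_linear"} and \code{"sffs"} are recognized method names
#' without an implementation here and raise a capability error.
#'
#' Rankings are deterministic given \code{seed}; ties break towards the
#' lower column index.
#'
#' @param data a [CohortData-class].
#' @param method feature-selection method (see above).
#' @param k number of genes to return (\code{0 <= k <=} column count).
#' @param seed seed for the stochastic parts (ReliefF sampling).
#' @return Character vector of \code{k} gene names, best first.
#' @export
rankFeatures <- function(data,
                         method = c("mrmr", "relieff", "wilcoxon_corr",
                                    "chow_liu", "rfe_linear", "sffs"),
                         k, seed = 1) {
  method <- match.arg(method)
  if (method %in% c("chow_liu", "rfe_linear", "sffs"))
    stop("feature-selection method '", method, "' is not implemented; ",
         "available: mrmr, relieff, wilcoxon_corr")
  X <- rbind(data@positive, data@negative)
  y <- rep(c(TRUE, FALSE), c(nrow(data@positive), nrow(data@negative)))
  if (k > ncol(X)) stop("'k' exceeds the number of protein columns")
  if (k == 0) return(character(0))
  set.seed(seed)
  idx <- switch(method,
                mrmr = .mrmr(X, y, k),
                relieff = .relieff(X, y, k),
                wilcoxon_corr = .wilcoxonCorr(X, y, k))
  colnames(X)[idx]
}
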