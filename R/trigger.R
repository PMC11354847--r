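# Trigger identification: signed-path coverage and minimal trigger sets.

# Breadth-first search over (node, path-sign) states. Returns, for every
# gene, the minimal number of directed hops at which it is reached with a
# positive and with a negative cumulative path sign (Inf when unreachable).
# Unknown edge signs (0) propagate as +1, matching the propagation rule.
.signedReach <- function(net, start, maxDistance) {
  genes <- net@nodes$gene_name
  n <- length(genes)
  e <- net@edges
  src <- match(e$source, genes)
  tgt <- match(e$target, genes)
  sgn <- ifelse(e$sign == 0, 1, e$sign)
  adj <- split(seq_len(nrow(e)), src)
  dist <- matrix(Inf, nrow = n, ncol = 2,
                 dimnames = list(genes, c("pos", "neg")))
  s0 <- match(start, genes)
  dist[s0, "pos"] <- 0
  frontier <- cbind(node = s0, sign = 1L)
  d <- 0L
  while (!is.null(frontier) && nrow(frontier) > 0 && d < maxDistance) {
    d <- d + 1L
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      eidx <- adj[[as.character(frontier[i, "node"])]]
      if (is.null(eidx)) next
      newSign <- frontier[i, "sign"] * sgn[eidx]
      col <- ifelse(newSign > 0, 1L, 2L)
      for (j in seq_along(eidx)) {
        v <- tgt[eidx[j]]
        if (dist[v, col[j]] > d) {
          dist[v, col[j]] <- d
          nxt <- rbind(nxt, cbind(node = v, sign = newSign[j]))
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' Signed coverage of target proteins by one effector
#'
#' A target counts as covered when it is reachable from the effector within
#' \code{maxDistance} directed hops along a path whose product of edge signs
#' is positive, i.e. when proximity to the effector is positively correlated
#' with target activation. Unknown signs count as positive. The effector
#' trivially covers itself when it belongs to the targets (it is the
#' stimulus). The coverage fraction is normalized by the number of targets,
#' so full coverage is 1 (100\%).
#'
#' @param net an [Interactome-class].
#' @param effector gene name of the candidate trigger.
#' @param targets non-empty character vector of target gene names.
#' @param maxDistance maximum path length in hops (default 3: distances 1, 2
#'   and 3 are examined).
#' @return List with elements \code{effector}, \code{covered} (sorted gene
#'   names), \code{coverage_fraction} and \code{per_distance} (named vector
#'   of cumulative covered counts at distances \code{1..maxDistance}).
#' @seealso [selectTriggerSet()]
#' @export
signedCoverage <- function(net, effector, targets, maxDistance = 3) {
  if (!effector %in% net@nodes$gene_name)
    stop("unknown effector gene: ", effector)
  if (!length(targets)) stop("'targets' must be non-empty")
  unknown <- setdiff(targets, net@nodes$gene_name)
  if (length(unknown))
    stop("unknown target gene(s): ", paste(unknown, collapse = ", "))
  dist <- .signedReach(net, effector, maxDistance)
  posDist <- dist[targets, "pos"]
  perDistance <- vapply(seq_len(maxDistance),
                        function(d) sum(posDist <= d), numeric(1))
  names(perDistance) <- as.character(seq_len(maxDistance))
  covered <- sort(targets[posDist <= maxDistance])
  list(effector = effector, covered = covered,
       coverage_fraction = length(covered) / length(targets),
       per_distance = perDistance)
}

# deterministic subset enumeration order: by size, then lexicographic on the
# (already sorted) candidate names
.bestSubset <- function(coverSets, targets, maxSize) {
  cand <- names(coverSets)
  maxCov <- sort(unique(unlist(coverSets)))
  bestLen <- length(intersect(maxCov, targets))
  for (s in seq_len(maxSize)) {
    combos <- combn(cand, s, simplify = FALSE)
    for (cc in combos) {
      un <- unique(unlist(coverSets[cc]))
      if (length(intersect(un, targets)) == bestLen)
        return(cc)
    }
  }
  cand
}

#' Select a minimal trigger set covering all targets
#'
#' Finds the smallest subset of candidate effectors whose united signed
#' coverage (see [signedCoverage()]) reaches every target. A chosen effector
#' covers itself when it is among the targets. Up to 20 candidates the
#' search is exact (subsets enumerated by size, ties broken by lexicographic
#' gene order); beyond that a greedy set-cover heuristic is used. When no
#' subset reaches 100\% coverage, the smallest subset achieving the best
#' attainable coverage is returned with an under-coverage flag.
#'
#' @param net an [Interactome-class].
#' @param candidateEffectors non-empty character vector of candidate genes.
#' @param targets non-empty character vector of target genes.
#' @param maxDistance maximum signed-path length (default 3).
#' @return List with \code{effectors} (the selected set),
#'   \code{coverage_fraction}, \code{full_coverage} (logical) and
#'   \code{uncovered} (targets no candidate reaches).
#' @export
selectTriggerSet <- function(net, candidateEffectors, targets,
                             maxDistance = 3) {
  if (!length(candidateEffectors)) stop("'candidateEffectors' is empty")
  if (!length(targets)) stop("'targets' is empty")
  candidateEffectors <- sort(unique(candidateEffectors))
  targets <- unique(targets)
  coverSets <- lapply(candidateEffectors, function(ef) {
    cov <- signedCoverage(net, ef, targets, maxDistance)$covered
    union(cov, intersect(ef, targets))
  })
  names(coverSets) <- candidateEffectors
  reachable <- sort(unique(unlist(coverSets)))
  uncovered <- setdiff(targets, reachable)

  if (length(candidateEffectors) <= 20) {
    sel <- .bestSubset(coverSets, targets, length(candidateEffectors))
  } else {
    sel <- character(0)
    left <- intersect(reachable, targets)
    while (length(left)) {
      gain <- vapply(coverSets, function(cs) length(intersect(cs, left)),
                     numeric(1))
      pick <- names(gain)[which.max(gain)]  # which.max: first = lexicographic
      sel <- c(sel, pick)
      left <- setdiff(left, coverSets[[pick]])
    }
  }
  covered <- intersect(unique(unlist(coverSets[sel])), targets)
  list(effectors = sort(sel),
       coverage_fraction = length(covered) / length(targets),
       full_coverage = length(uncovered) == 0 &&
         length(covered) == length(targets),
       uncovered = sort(uncovered))
}
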