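# Small networks and independent oracles shared across tests.

chainNet <- function(signs = c(1, 1)) {
  # A -> B -> C with the given edge signs
  Interactome(
    edges = data.frame(source = c("A", "B"), target = c("B", "C"),
                       sign = signs),
    nodes = data.frame(gene_name = c("A", "B", "C")))
}

starNet <- function(nLeaves = 5, signs = rep(1, nLeaves)) {
  leaves <- paste0("X", seq_len(nLeaves))
  Interactome(
    edges = data.frame(source = "hub", target = leaves, sign = signs),
    nodes = data.frame(gene_name = c("hub", leaves)))
}

randomNet <- function(n, pEdge = 0.25, pNeg = 0.3, seed = 1) {
  set.seed(seed)
  genes <- paste0("N", seq_len(n))
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < pEdge
  edges <- pairs[keep, ]
  edges$sign <- ifelse(runif(nrow(edges)) < pNeg, -1, 1)
  Interactome(edges, data.frame(gene_name = genes))
}

# exhaustive hypergeometric upper tail: enumerate every possible draw
bruteHypergeom <- function(hits, setSize, sigSize, universeSize) {
  if (setSize == 0) return(as.numeric(hits <= 0))
  draws <- combn(universeSize, setSize)
  mean(colSums(draws <= sigSize) >= hits)
}

# exhaustive linear-threshold oracle: best BACC over a dense cut grid and
# both directions, by direct counting
bruteLinearBacc <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  cuts <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  best <- 0.5
  for (t in cuts) {
    gt <- (mean(pos > t) + mean(neg <= t)) / 2
    best <- max(best, gt, 1 - gt)
  }
  best
}

# exhaustive two-cut oracle (inside/outside interval rules)
bruteQuadraticBacc <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  cuts <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  best <- 0.5
  for (i in seq_along(cuts)) for (j in seq_along(cuts)) {
    if (j <= i) next
    inside <- (mean(pos > cuts[i] & pos <= cuts[j]) +
                 mean(!(neg > cuts[i] & neg <= cuts[j]))) / 2
    best <- max(best, inside, 1 - inside)
  }
  best
}

# brute-force minimal covering subset over explicit cover sets
bruteMinCover <- function(coverSets, targets) {
  cand <- names(coverSets)
  for (s in seq_along(cand)) {
    for (cc in combn(cand, s, simplify = FALSE)) {
      if (all(targets %in% unlist(coverSets[cc]))) return(cc)
    }
  }
  NULL
}

# random candidate tables plus aligned activity matrices for cascade tests
randomCandidates <- function(nCand, genes, nSol = 20, seed = 1) {
  set.seed(seed)
  sens <- runif(nCand, 0.3, 1)
  spec <- runif(nCand, 0.3, 1)
  cands <- data.frame(
    proteins = vapply(seq_len(nCand), function(i)
      paste(sort(sample(genes, sample(1:3, 1))), collapse = "+"),
      character(1)),
    bacc = (sens + spec) / 2, sensitivity = sens, specificity = spec,
    precision = runif(nCand, 0.3, 1), cv_p = runif(nCand, 0, 0.2))
  cands <- cands[!duplicated(cands$proteins), ]
  pos <- matrix(runif(nSol * length(genes), -1, 1), nSol,
                dimnames = list(NULL, genes))
  neg <- matrix(runif(nSol * length(genes), -1, 1), nSol,
                dimnames = list(NULL, genes))
  # make a few genes unmodulated in one cohort
  off <- sample(genes, 2)
  pos[, off] <- runif(nSol * 2, -0.01, 0.01)
  list(cands = cands, pos = pos, neg = neg)
}

nullSpec <- function(n, nSolutions, seed)
  syntheticSpec(nProteins = n, nSolutions = nSolutions,
                plantedMarkers = setNames(numeric(0), character(0)),
                seed = seed)
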