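# Model-ensemble construction: configuration enumeration, constrained signal
# propagation, and solution sampling by simulated annealing over edge weights.

.motifLabels <- c(M5 = "BM", M6 = "liver", M7 = "skeletal")

#' Enumerate disease-model configurations
#'
#' One model per subset of the complication motifs (including the empty
#' subset), each with response = base motifs plus the subset. With the
#' defaults this yields the eight canonical models: the base disease model
#' plus every combination of bone-marrow (M5), liver (M6) and skeletal (M7)
#' complications. Subsets are enumerated by size and then lexicographically,
#' and names are deterministic (\code{"GD1 without complications"},
#' \code{"GD1 with BM and skeletal complications"}, ...).
#'
#' @param baseMotifs motifs present in every response (default \code{M2},
#'   inflammation/infiltration, and \code{M3}, iron accumulation).
#' @param complicationMotifs motifs toggled per model (default \code{M5},
#'   \code{M6}, \code{M7}).
#' @param stimulus,restrictions shared stimulus and restrictions copied into
#'   every configuration (see [ModelConfig()]); typically filled in later.
#' @return List of [ModelConfig-class] objects, length
#'   \code{2^length(complicationMotifs)}.
#' @examples
#' length(enumerateModelConfigs())  # 8
#' @export
enumerateModelConfigs <- function(baseMotifs = c("M2", "M3"),
                                  complicationMotifs = c("M5", "M6", "M7"),
                                  stimulus = numeric(0),
                                  restrictions = data.frame(
                                    gene = character(0), sign = numeric(0))) {
  if (length(intersect(baseMotifs, complicationMotifs)))
    stop("base and complication motif sets must be disjoint")
  complicationMotifs <- sort(complicationMotifs)
  subsets <- list(character(0))
  for (s in seq_along(complicationMotifs))
    subsets <- c(subsets, combn(complicationMotifs, s, simplify = FALSE))
  lapply(subsets, function(sub) {
    lab <- ifelse(sub %in% names(.motifLabels), .motifLabels[sub], sub)
    nm <- if (!length(sub)) "GD1 without complications"
          else paste0("GD1 with ",
                      paste(lab, collapse = if (length(lab) > 2) ", "
                            else " and "),
                      " complications")
    if (length(lab) > 2)
      nm <- sub(", ([^,]+) complications$", " and \\1 complications", nm)
    ModelConfig(name = nm, stimulus = stimulus,
                restrictions = restrictions,
                response = c(baseMotifs, sub))
  })
}

# edge keys used in user-facing weight vectors
.edgeKeys <- function(edges) paste0(edges$source, "->", edges$target)

# Fast propagation closure: takes a weight vector in edge-table order and
# returns the activity vector. Activities start at zero, stimulus nodes are
# clamped every step, all other nodes update synchronously from their
# weighted signed in-edges through the squashing function. Nodes with no
# path from the stimulus therefore stay at zero.
.buildPropagator <- function(net, stimulus, steps = 10, squash = tanh) {
  genes <- net@nodes$gene_name
  n <- length(genes)
  e <- net@edges
  src <- match(e$source, genes)
  tgt <- match(e$target, genes)
  sgn <- ifelse(e$sign == 0, 1, e$sign)
  idx <- (src - 1L) * n + tgt      # W[target, source]
  # parallel edges (same pair, different sign/provenance) contribute the
  # sum of their signed weights
  uidx <- sort(unique(idx))
  grp <- match(idx, uidx)
  clampIdx <- match(names(stimulus), genes)
  if (anyNA(clampIdx))
    stop("stimulus genes absent from network: ",
         paste(names(stimulus)[is.na(clampIdx)], collapse = ", "))
  clampVal <- unname(stimulus)
  W <- matrix(0, n, n)
  function(w) {
    W[uidx] <- rowsum(sgn * w, grp)
    x <- numeric(n)
    x[clampIdx] <- clampVal
    for (s in seq_len(steps)) {
      x <- squash(W %*% x)
      x[clampIdx] <- clampVal
    }
    setNames(as.numeric(x), genes)
  }
}

#' Propagate a clamped stimulus through the weighted signed network
#'
#' Synchronous signal propagation: activities initialize at zero, stimulus
#' proteins are held at their clamped values at every step, and every other
#' protein updates as \code{squash(sum over in-edges of sign * weight *
#' activity(source))}. The squashing function must be odd, map into
#' \[-1, 1\] and fix zero, so all activities stay bounded and proteins
#' unreachable from the stimulus remain at zero. Unknown edge signs (0)
#' propagate as +1.
#'
#' @param net an [Interactome-class].
#' @param weights named numeric vector of non-negative edge weights; names
#'   are \code{"source->target"} edge keys. Unnamed vectors of length equal
#'   to the edge count are taken in edge-table order. Keys that do not match
#'   an existing edge raise an error.
#' @param stimulus named numeric vector of clamped activities in \[-1, 1\].
#' @param steps number of synchronous update steps (default 10).
#' @param squash odd bounded squashing function (default \code{tanh}).
#' @return Named numeric vector of activities in \[-1, 1\].
#' @examples
#' net <- Interactome(data.frame(source = "A", target = "B", sign = -1),
#'                    data.frame(gene_name = c("A", "B")))
#' propagateSignal(net, c("A->B" = 1), c(A = 1))["B"]  # negative
#' @export
propagateSignal <- function(net, weights, stimulus, steps = 10,
                            squash = tanh) {
  keys <- .edgeKeys(net@edges)
  if (!is.null(names(weights))) {
    if (anyDuplicated(keys))
      stop("network has parallel edges sharing a source->target key; ",
           "pass unnamed weights in edge-table order")
    unknown <- setdiff(names(weights), keys)
    if (length(unknown))
      stop("weights given for non-existent edge(s): ",
           paste(unknown, collapse = ", "))
    w <- setNames(numeric(length(keys)), keys)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(keys))
      stop("unnamed 'weights' must have one entry per edge")
    w <- weights
  }
  .buildPropagator(net, stimulus, steps, squash)(unname(w))
}

#' Constraint-violation loss of a solution
#'
#' Zero exactly when every constrained protein has the required activity
#' sign with magnitude at least \code{floor}; otherwise the sum of hinge
#' penalties \code{max(0, floor - sign * activity)} over violated
#' constraints. An empty constraint set has zero loss.
#'
#' @param activities named numeric vector of activities.
#' @param constraints \code{data.frame} with columns \code{gene} and
#'   \code{sign} (required sign, \code{+1}/\code{-1}); typically the model's
#'   restrictions plus its response-effector requirements (see
#'   [responseConstraints()]).
#' @param floor activation floor: minimum activity magnitude that counts as
#'   a modulated, sign-correct response (default 0.1).
#' @return Non-negative numeric scalar.
#' @export
solutionLoss <- function(activities, constraints, floor = 0.1) {
  if (!nrow(constraints)) return(0)
  a <- activities[constraints$gene]
  if (anyNA(a))
    stop("constrained gene(s) missing from activities: ",
         paste(constraints$gene[is.na(a)], collapse = ", "))
  sum(pmax(0, floor - constraints$sign * a))
}

#' Full constraint set of a model configuration
#'
#' Combines the configuration's explicit restrictions with its response
#' requirements: every effector protein belonging to a response motif is
#' required to be active (sign \code{+1}). Duplicate constraints collapse;
#' a gene required to be both active and inactive makes the model
#' infeasible and raises an error.
#'
#' @param net an [Interactome-class].
#' @param config a [ModelConfig-class].
#' @return \code{data.frame} with columns \code{gene} and \code{sign}.
#' @export
responseConstraints <- function(net, config) {
  eff <- net@nodes$gene_name[net@nodes$effector]
  respGenes <- intersect(unlist(lapply(config@response, motifProteins,
                                       net = net)), eff)
  cons <- rbind(config@restrictions[c("gene", "sign")],
                if (length(respGenes))
                  data.frame(gene = respGenes, sign = 1))
  cons <- unique(cons)
  conflict <- unique(cons$gene[duplicated(cons$gene)])
  if (length(conflict))
    stop("infeasible model '", config@name, "': gene(s) required with ",
         "both signs: ", paste(conflict, collapse = ", "))
  rownames(cons) <- NULL
  cons
}

# Multi-source signed BFS from the stimulus with predecessor tracking.
# Returns, for each gene, the edge-index path of a shortest directed path
# whose cumulative sign is positive (pos) or negative (neg), within maxDepth
# hops; NULL where no such path exists.
.stimulusPaths <- function(net, stimulus, maxDepth) {
  genes <- net@nodes$gene_name
  n <- length(genes)
  e <- net@edges
  src <- match(e$source, genes)
  tgt <- match(e$target, genes)
  sgn <- ifelse(e$sign == 0, 1, e$sign)
  adj <- split(seq_len(nrow(e)), src)
  dist <- matrix(Inf, n, 2)          # columns: pos, neg path sign
  predEdge <- matrix(NA_integer_, n, 2)
  predNode <- matrix(NA_integer_, n, 2)
  predSign <- matrix(NA_integer_, n, 2)
  s0 <- match(names(stimulus), genes)
  sSgn <- ifelse(stimulus >= 0, 1L, -1L)
  frontier <- cbind(node = s0, sign = sSgn)
  dist[cbind(s0, ifelse(sSgn > 0, 1L, 2L))] <- 0
  d <- 0L
  while (!is.null(frontier) && nrow(frontier) > 0 && d < maxDepth) {
    d <- d + 1L
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      u <- frontier[i, "node"]; us <- frontier[i, "sign"]
      eidx <- adj[[as.character(u)]]
      if (is.null(eidx)) next
      for (ei in eidx) {
        v <- tgt[ei]
        vs <- us * sgn[ei]
        col <- if (vs > 0) 1L else 2L
        if (dist[v, col] > d) {
          dist[v, col] <- d
          predEdge[v, col] <- ei
          predNode[v, col] <- u
          predSign[v, col] <- us
          nxt <- rbind(nxt, cbind(node = v, sign = vs))
        }
      }
    }
    frontier <- nxt
  }
  walk <- function(v, s) {
    col <- if (s > 0) 1L else 2L
    if (!is.finite(dist[v, col])) return(NULL)
    path <- integer(0)
    while (is.finite(dist[v, col]) && dist[v, col] > 0) {
      path <- c(predEdge[v, col], path)
      u <- predNode[v, col]; us <- predSign[v, col]
      v <- u; col <- if (us > 0) 1L else 2L
    }
    path
  }
  out <- lapply(seq_len(n), function(v)
    list(pos = walk(v, 1), neg = walk(v, -1)))
  names(out) <- genes
  out
}

# constraint-aware weight initialization: boost a support path with the
# required sign into every constrained gene and damp its other in-edges,
# then let annealing clean up the interactions
.initWeights <- function(E, paths, cons, consIdx, inEdges) {
  w <- runif(E)
  for (k in sample(seq_len(nrow(cons)))) {
    p <- paths[[consIdx[k]]][[if (cons$sign[k] > 0) "pos" else "neg"]]
    if (is.null(p)) next
    w[p] <- runif(length(p), 0.6, 1)
    damp <- setdiff(inEdges[[k]]$edge, p)
    if (length(damp)) w[damp] <- runif(length(damp), 0, 0.15)
  }
  w
}

# one annealing run over edge weights; returns list(w, activities, loss)
.annealSolution <- function(prop, E, lossOf, inEdges, consIdx, consSgn,
                            tolerance, maxIter, floor = 0.1, temp0 = 0.25,
                            cooling = 0.995, sdProp = 0.15, w0 = NULL) {
  w <- if (is.null(w0)) runif(E) else w0
  x <- prop(w)
  L <- lossOf(x)
  Temp <- temp0
  it <- 0L
  nk <- max(1L, ceiling(0.05 * E))
  while (L > tolerance && it < maxIter) {
    it <- it + 1L
    w2 <- w
    if (runif(1) < 0.5 && length(consIdx)) {
      # repair move: push the in-edges of one violated constraint towards
      # the required sign, using current source activities
      viol <- which(consSgn * x[consIdx] < floor - 1e-12)
      if (length(viol)) {
        v <- if (length(viol) == 1) viol else sample(viol, 1)
        ie <- inEdges[[v]]
        if (length(ie$edge)) {
          benefit <- consSgn[v] * ie$sgn * x[ie$src]
          w2[ie$edge] <- pmin(1, pmax(0, w2[ie$edge] +
                                        0.3 * sign(benefit) *
                                        runif(length(ie$edge))))
        }
      } else {
        sel <- sample.int(E, nk)
        w2[sel] <- pmin(1, pmax(0, w2[sel] + rnorm(nk, 0, sdProp)))
      }
    } else {
      sel <- sample.int(E, nk)
      w2[sel] <- pmin(1, pmax(0, w2[sel] + rnorm(nk, 0, sdProp)))
    }
    x2 <- prop(w2)
    L2 <- lossOf(x2)
    if (L2 <= L || runif(1) < exp((L - L2) / Temp)) {
      w <- w2; x <- x2; L <- L2
    }
    Temp <- Temp * cooling
  }
  list(w = w, activities = x, loss = L, iterations = it)
}

#' Sample an ensemble of constraint-satisfying solutions
#'
#' Draws \code{n} independent solutions of one disease model. Each solution
#' is a stochastic search over the edge-weight vector (restart per solution)
#' that minimizes the hinge [solutionLoss()] of the propagated activities
#' until it drops to \code{tolerance}; the search combines simulated
#' annealing with targeted repair moves on violated constraints. The
#' ensemble of solutions explores the space of weight assignments compatible
#' with the model, and the across-solution mean activity summarizes the most
#' likely signal paths.
#'
#' Per-solution seeds derive from the master seed by a fixed affine scheme
#' (\code{(seed + 104729 * i) mod (2^31 - 1)}), so results are bit-for-bit
#' reproducible given \code{(seed, n)}.
#'
#' @param net an [Interactome-class].
#' @param config a [ModelConfig-class]; its stimulus must be non-empty.
#' @param n number of solutions (default 250).
#' @param tolerance loss level at which a solution is accepted (default
#'   0.05).
#' @param seed master seed.
#' @param steps propagation steps per evaluation (default 10).
#' @param floor activation floor of the loss (default 0.1).
#' @param maxIter annealing iteration cap per solution (default 2000); a
#'   solution still above tolerance at the cap is marked failed, and the
#'   whole matrix is rejected when more than \code{failLimit} of solutions
#'   fail.
#' @param squash squashing function (default \code{tanh}).
#' @param failLimit maximum tolerated failed-solution fraction (default
#'   0.1).
#' @return An [ActivityMatrix-class] with \code{n} solutions; per-solution
#'   seeds and final losses are in its \code{colData}.
#' @export
sampleSolutions <- function(net, config, n = 250, tolerance = 0.05,
                            seed = 1, steps = 10, floor = 0.1,
                            maxIter = 2000, squash = tanh,
                            failLimit = 0.1) {
  if (n < 1) stop("'n' must be >= 1")
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  if (!length(config@stimulus))
    stop("model '", config@name, "' has an empty stimulus")
  cons <- responseConstraints(net, config)
  genes <- net@nodes$gene_name
  prop <- .buildPropagator(net, config@stimulus, steps, squash)
  consIdx <- match(cons$gene, genes)
  if (anyNA(consIdx))
    stop("constrained gene(s) absent from network: ",
         paste(cons$gene[is.na(consIdx)], collapse = ", "))
  consSgn <- cons$sign
  lossOf <- function(x) sum(pmax(0, floor - consSgn * x[consIdx]))
  e <- net@edges
  E <- nrow(e)
  src <- match(e$source, genes)
  tgt <- match(e$target, genes)
  sgn <- ifelse(e$sign == 0, 1, e$sign)
  inEdges <- lapply(consIdx, function(g) {
    ie <- which(tgt == g)
    list(edge = ie, src = src[ie], sgn = sgn[ie])
  })
  paths <- .stimulusPaths(net, config@stimulus, maxDepth = steps)

  vals <- matrix(NA_real_, nrow = n, ncol = length(genes),
                 dimnames = list(NULL, genes))
  seeds <- integer(n)
  losses <- numeric(n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    seeds[i] <- as.integer((seed + 104729 * i) %% 2147483647)
    set.seed(seeds[i])
    sol <- NULL
    for (attempt in 1:3) {  # fresh re-initialization on a stuck search
      cand <- .annealSolution(prop, E, lossOf, inEdges, consIdx, consSgn,
                              tolerance, maxIter, floor,
                              w0 = .initWeights(E, paths, cons, consIdx,
                                                inEdges))
      if (is.null(sol) || cand$loss < sol$loss) sol <- cand
      if (sol$loss <= tolerance) break
    }
    vals[i, ] <- sol$activities
    losses[i] <- sol$loss
    failed[i] <- sol$loss > tolerance
  }
  if (mean(failed) > failLimit)
    stop(sprintf(paste0("model '%s': %d of %d solutions failed to reach ",
                        "tolerance %.3g (losses up to %.3g); the model may ",
                        "be ill-constrained for this network"),
                 config@name, sum(failed), n, tolerance,
                 max(losses)))
  am <- ActivityMatrix(vals[!failed, , drop = FALSE], model = config@name,
                       seeds = seeds[!failed], losses = losses[!failed],
                       response = config@response, tolerance = tolerance)
  am
}

#' Persist / restore an activity matrix as TSV plus JSON sidecar
#'
#' The TSV holds the solutions x proteins values with a header row; the JSON
#' sidecar (same path with extension \code{.json}) records model name,
#' response motifs, tolerance, per-solution seeds and losses.
#'
#' @param x an [ActivityMatrix-class].
#' @param file TSV path.
#' @return \code{writeActivityMatrix} invisibly returns \code{file};
#'   \code{readActivityMatrix} returns the restored
#'   [ActivityMatrix-class].
#' @export
writeActivityMatrix <- function(x, file) {
  write.table(activityValues(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  side <- list(model = modelName(x),
               response = S4Vectors::metadata(x)$response,
               tolerance = S4Vectors::metadata(x)$tolerance,
               seeds = solutionSeeds(x), losses = solutionLosses(x))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writeActivityMatrix
#' @param file TSV path written by \code{writeActivityMatrix}.
#' @export
readActivityMatrix <- function(file) {
  vals <- as.matrix(read.delim(file, check.names = FALSE))
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  ActivityMatrix(vals, model = side$model,
                 seeds = side$seeds, losses = side$losses,
                 response = side$response %||% character(0),
                 tolerance = side$tolerance %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
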