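# Synthetic ground-truth generators: a fast matrix tier for classifier and
# filter tests, and a network tier for end-to-end ensemble runs.

.motifProportions <- c(M1 = 6, M2 = 24, M3 = 12, M5 = 21, M6 = 43, M7 = 85)

#' Generate a two-cohort activity data set with planted markers
#'
#' Matrix-tier generator: activities are clipped Gaussians. Planted marker
#' proteins have positive-cohort mean \code{baseline + delta} and
#' negative-cohort mean \code{baseline}; null proteins draw from the same
#' \code{Normal(baseline, sigma)} distribution in both cohorts. All values
#' are clipped to \[-1, 1\] (a warning is raised when a planted mean falls
#' outside the range before clipping). With an effect gap of
#' \code{delta = 2 * sigma} the Bayes-optimal balanced accuracy of the
#' marker is \code{pnorm(1)}, about 0.8413, which makes the generator a
#' closed-form oracle for classifier tests. Fully reproducible from the
#' spec seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with \code{positive} and \code{negative}
#'   ([ActivityMatrix-class] each) and \code{truth} (planted markers,
#'   effect sizes, noise level and per-marker Bayes balanced accuracy).
#' @examples
#' ds <- generateEnsembleDataset(syntheticSpec(nProteins = 5,
#'                                             nSolutions = 20))
#' ds$truth$bayes_bacc
#' @export
generateEnsembleDataset <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  markers <- spec@plantedMarkers
  nNull <- spec@nProteins - length(markers)
  if (nNull < 0) stop("more planted markers than proteins")
  genes <- c(names(markers),
             if (nNull > 0) sprintf("NULL%03d", seq_len(nNull)))
  mu <- rep(spec@baseline, spec@nProteins)
  muPos <- mu
  muPos[seq_along(markers)] <- spec@baseline + markers
  if (any(abs(muPos) > 1))
    warning("planted mean(s) outside [-1, 1] before clipping: ",
            paste(genes[abs(muPos) > 1], collapse = ", "))
  draw <- function(mus) {
    m <- matrix(rnorm(spec@nSolutions * spec@nProteins,
                      mean = rep(mus, each = spec@nSolutions),
                      sd = spec@noiseSigma),
                nrow = spec@nSolutions,
                dimnames = list(NULL, genes))
    pmin(pmax(m, -1), 1)
  }
  pos <- draw(muPos)
  neg <- draw(mu)
  truth <- list(markers = names(markers), delta = unname(markers),
                sigma = spec@noiseSigma,
                bayes_bacc = pnorm(unname(markers) / (2 * spec@noiseSigma)))
  list(positive = ActivityMatrix(pos, model = "positive"),
       negative = ActivityMatrix(neg, model = "negative"),
       truth = truth)
}

.resolveMotifSizes <- function(spec, nAssignable) {
  ms <- spec@motifSizes
  if (is.character(ms) && identical(ms, "auto")) {
    prop <- .motifProportions / sum(.motifProportions)
    ms <- pmax(1, round(prop * nAssignable))
    names(ms) <- names(.motifProportions)
    while (sum(ms) > nAssignable) {
      i <- which.max(ms)
      ms[i] <- ms[i] - 1
    }
  }
  if (is.null(names(ms)) || any(!nzchar(names(ms))))
    stop("motifSizes must be a named vector or 'auto'")
  ms
}

#' Generate a full synthetic study: network, tables and model configurations
#'
#' Network-tier generator standing in for a proprietary interactome and
#' training compendium. It emulates, with known ground truth:
#' \itemize{
#'   \item a signed directed protein network: an all-positive "backbone"
#'     tree growing from three trigger proteins (every protein reachable
#'     from the stimulus within a bounded depth, so all model constraints
#'     are satisfiable) overlaid with preferential-attachment edges that are
#'     inhibitory with probability \code{negativeEdgeProb};
#'   \item motif annotations (sizes from \code{motifSizes}, or the canonical
#'     proportions scaled to \code{nProteins}); motif members are effectors;
#'   \item two planted marker proteins: \code{MK_SKEL}, restricted active in
#'     models whose response includes the skeletal motif \code{M7} and
#'     suppressed otherwise, and \code{MK_PAN}, restricted active when at
#'     least two complication motifs are in the response and suppressed
#'     otherwise (a compounded-complication-burden marker that should be
#'     caught by the cross-comparison specificity filter);
#'   \item a differential-expression table whose planted signature genes
#'     pass the signature thresholds by construction (plus decoy
#'     transcripts that map to no protein);
#'   \item plasma/urine measurability tables;
#'   \item the eight model configurations with the trigger stimulus and the
#'     marker restrictions filled in.
#' }
#' Everything is reproducible from the spec seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with \code{net} ([Interactome-class]), \code{deTable},
#'   \code{measurability} (list of named logical \code{plasma} and
#'   \code{urine}), \code{configs} (list of [ModelConfig-class]) and
#'   \code{truth} (triggers, planted markers, signature genes, motif
#'   sizes).
#' @export
generateEndToEndDataset <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  markers <- c("MK_SKEL", "MK_PAN")
  triggers <- c("TRG1", "TRG2", "TRG3")
  n <- spec@nProteins
  nOther <- n - length(markers) - length(triggers)
  if (nOther < 1) stop("nProteins too small for triggers and markers")
  ms <- .resolveMotifSizes(spec, nAssignable = n - length(markers))
  if (sum(ms) > n - length(markers))
    stop("motif sizes exceed the number of assignable proteins")
  if (!is.na(ms["M2"]) && ms["M2"] < length(triggers))
    stop("motif M2 must hold at least the ", length(triggers),
         " trigger proteins")
  genes <- c(triggers, sprintf("G%04d", seq_len(nOther)), markers)

  # motif assignment: triggers fill the first M2 slots, then contiguous
  # blocks; leftovers (and the markers) carry no motif
  motifs <- replicate(n, character(0), simplify = FALSE)
  names(motifs) <- genes
  assignable <- c(triggers, genes[!(genes %in% c(triggers, markers))])
  cursor <- length(triggers) + 1L
  for (m in names(ms)) {
    extra <- if (m == "M2") ms[m] - length(triggers) else ms[m]
    block <- if (extra > 0) assignable[seq(cursor, cursor + extra - 1L)]
             else character(0)
    cursor <- cursor + max(0, extra)
    take <- c(if (m == "M2") triggers, block)
    for (g in take) motifs[[g]] <- c(motifs[[g]], m)
  }

  # backbone tree: positive edges, bounded depth so propagation reaches
  # every protein within the default step budget
  maxDepth <- 6L
  depth <- setNames(rep(NA_integer_, n), genes)
  depth[triggers] <- 0L
  wired <- triggers
  edges <- data.frame(source = character(0), target = character(0),
                      sign = numeric(0), provenance = character(0))
  for (g in sample(setdiff(genes, triggers))) {
    # markers are backbone leaves: their restrictions flip sign between
    # models, so no response effector may depend on them
    shallow <- wired[depth[wired] < maxDepth & !(wired %in% markers)]
    parent <- if (length(shallow) == 1) shallow else sample(shallow, 1)
    edges <- rbind(edges, data.frame(source = parent, target = g, sign = 1,
                                     provenance = "backbone"))
    depth[g] <- depth[parent] + 1L
    wired <- c(wired, g)
  }
  # planted markers need an inhibitory route too (their restrictions flip
  # sign between models)
  for (mk in markers)
    edges <- rbind(edges, data.frame(source = sample(triggers, 1),
                                     target = mk, sign = -1,
                                     provenance = "backbone"))

  # scale-free overlay with random signs
  pa <- igraph::sample_pa(n, power = 1, m = spec@networkAttachment,
                          directed = TRUE)
  el <- igraph::as_edgelist(pa, names = FALSE)
  perm <- sample(genes)
  overlay <- data.frame(source = perm[el[, 1]], target = perm[el[, 2]],
                        sign = ifelse(runif(nrow(el)) <
                                        spec@negativeEdgeProb, -1, 1),
                        provenance = "overlay")
  edges <- rbind(edges, overlay)
  edges <- edges[!duplicated(edges[c("source", "target", "sign")]), ]
  edges <- edges[edges$source != edges$target, ]

  plasma <- setNames(runif(n) < 0.3, genes)
  urine <- setNames(runif(n) < 0.1, genes)
  plasma[markers] <- TRUE  # planted markers are blood-measurable

  nodes <- data.frame(
    gene_name = genes,
    uniprot = sprintf("P%05d", seq_len(n)),
    motifs = vapply(motifs, paste, character(1), collapse = ";"),
    effector = lengths(motifs) > 0,
    plasma = unname(plasma), urine = unname(urine),
    stringsAsFactors = FALSE)
  net <- Interactome(edges, nodes)

  # DE table: planted signature genes pass both thresholds by construction;
  # non-signature rows fail at least one; decoys pass but map to no protein
  sigPool <- setdiff(genes, c(triggers, markers))
  sigGenes <- sort(sample(sigPool, max(3L, round(0.15 * n))))
  nonSig <- setdiff(sigPool, sigGenes)
  nFail <- min(length(nonSig), length(sigGenes))
  failGenes <- sample(nonSig, nFail)
  half <- nFail %/% 2
  deTable <- rbind(
    data.frame(gene_name = sigGenes,
               log2fc = sample(c(-1, 1), length(sigGenes), TRUE) *
                 runif(length(sigGenes), 1, 2.5),
               adj_p = runif(length(sigGenes), 0, 0.05)),
    if (half > 0)
      data.frame(gene_name = failGenes[seq_len(half)],
                 log2fc = runif(half, 0, 0.95),
                 adj_p = runif(half, 0, 1)),
    if (nFail > half)
      data.frame(gene_name = failGenes[(half + 1):nFail],
                 log2fc = runif(nFail - half, 1, 3),
                 adj_p = runif(nFail - half, 0.051, 1)),
    data.frame(gene_name = c("DECOY_RNA1", "DECOY_RNA2"),
               log2fc = c(2.2, -1.8), adj_p = c(0.001, 0.01)))
  rownames(deTable) <- NULL

  configs <- lapply(
    enumerateModelConfigs(stimulus = setNames(rep(1, length(triggers)),
                                              triggers)),
    function(cfg) {
      nComp <- sum(c("M5", "M6", "M7") %in% cfg@response)
      cfg@restrictions <- data.frame(
        gene = markers,
        sign = c(if ("M7" %in% cfg@response) 1 else -1,
                 if (nComp >= 2) 1 else -1))
      validObject(cfg)
      cfg
    })

  sig <- buildSignature(deTable, proteinUniverse = genes)
  net <- addSignature(net, sig)

  list(net = net, deTable = deTable,
       measurability = list(plasma = plasma, urine = urine),
       configs = configs,
       truth = list(triggers = triggers, skeletalMarker = "MK_SKEL",
                    panMarker = "MK_PAN", signature = sigGenes,
                    motifSizes = ms))
}
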