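test_that("networks are constructed and validated from tables", {
  net <- Interactome(
    edges = data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                       sign = c(1, -1, 0)),
    nodes = data.frame(gene_name = c("A", "B", "C")))
  expect_s4_class(net, "Interactome")
  expect_equal(nrow(interactomeNodes(net)), 3)
  expect_equal(nrow(interactomeEdges(net)), 3)

  # edge referencing an undeclared node names it
  expect_error(
    Interactome(data.frame(source = "A", target = "D", sign = 1),
                data.frame(gene_name = c("A", "B"))),
    "D")

  # isolated nodes are fine
  empty <- Interactome(data.frame(source = character(0),
                                  target = character(0),
                                  sign = numeric(0)),
                       data.frame(gene_name = c("A", "B")))
  expect_equal(length(geneNames(empty)), 2)
  expect_equal(nrow(interactomeEdges(empty)), 0)

  # duplicate gene names are a validation error
  expect_error(
    Interactome(data.frame(source = "A", target = "B", sign = 1),
                data.frame(gene_name = c("A", "A", "B"))),
    "duplicate")
})

test_that("load/write round-trips tables through TSV and reads SIF", {
  dir <- withr::local_tempdir()
  ef <- file.path(dir, "edges.tsv")
  nf <- file.path(dir, "nodes.tsv")
  writeLines(c("source\ttarget\tsign\tprovenance",
               "A\tB\t1\tdb1", "B\tC\t-1\tdb2"), ef)
  writeLines(c("gene_name\tuniprot\tmotifs\teffector\tplasma\turine",
               "A\tP1\tM2;M3\tTRUE\tTRUE\tFALSE",
               "B\tP2\tM2\tTRUE\tFALSE\tFALSE",
               "C\tP3\t\tFALSE\tFALSE\tTRUE"), nf)
  net <- loadNetwork(ef, nf)
  expect_equal(sort(motifProteins(net, "M2")), c("A", "B"))
  expect_equal(motifIndex(net), list(M2 = c("A", "B"), M3 = "A"))

  ef2 <- file.path(dir, "edges2.tsv")
  nf2 <- file.path(dir, "nodes2.tsv")
  writeNetwork(net, ef2, nf2)
  net2 <- loadNetwork(ef2, nf2)
  expect_identical(interactomeEdges(net2), interactomeEdges(net))
  expect_identical(interactomeNodes(net2), interactomeNodes(net))

  # malformed sign reports the line
  writeLines(c("source\ttarget\tsign", "A\tB\t1", "B\tC\tstrong"), ef)
  expect_error(loadNetwork(ef, nf), "line")

  # SIF with a relation->sign mapping
  sif <- file.path(dir, "net.sif")
  writeLines(c("A\tactivates\tB", "B\tinhibits\tC"), sif)
  net3 <- loadNetwork(sif, nf, sifSignMap = c(activates = 1, inhibits = -1))
  expect_equal(interactomeEdges(net3)$sign, c(1, -1))
  expect_error(loadNetwork(sif, nf, sifSignMap = c(activates = 1)),
               "inhibits")
})

test_that("k-hop neighborhoods follow edge direction and grow with k", {
  chain <- chainNet()
  expect_equal(kHopNeighborhood(chain, "A", 1), "B")
  expect_equal(kHopNeighborhood(chain, "A", 3), c("B", "C"))
  star <- starNet()
  expect_equal(kHopNeighborhood(star, "X1", 3), character(0))
  expect_error(kHopNeighborhood(chain, "Z", 1), "Z")

  # monotone reach on random graphs
  net <- randomNet(12, seed = 7)
  for (g in geneNames(net)[1:4]) {
    for (k in 1:3) {
      expect_true(all(kHopNeighborhood(net, g, k) %in%
                        kHopNeighborhood(net, g, k + 1)))
    }
  }
})

test_that("motif connectivity means a direct cross-edge", {
  net <- Interactome(
    edges = data.frame(source = c("A", "B"), target = c("B", "C"), sign = 1),
    nodes = data.frame(gene_name = c("A", "B", "C"),
                       motifs = c("M1;M9", "M8", "M2;M9")))
  expect_true(motifConnectivity(net, "M1", "M8"))    # edge A -> B
  expect_false(motifConnectivity(net, "M1", "M2"))   # only via B
  # two motifs sharing protein A but with no cross-edge
  net2 <- Interactome(
    edges = data.frame(source = "B", target = "C", sign = 1),
    nodes = data.frame(gene_name = c("A", "B", "C"),
                       motifs = c("M1;M2", "", "")))
  expect_false(motifConnectivity(net2, "M1", "M2"))
  expect_error(motifConnectivity(net, "M1", "M4"), "M4")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  expect_equal(hypergeomEnrichment(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeomEnrichment(0, 4, 0, 10), 1.0)
  expect_equal(hypergeomEnrichment(5, 5, 5, 10), 1 / 252)
  expect_error(hypergeomEnrichment(6, 5, 5, 10), "inconsistent")
  expect_error(hypergeomEnrichment(2, 4, 5, 4), "inconsistent")

  set.seed(42)
  for (rep in 1:40) {
    N <- sample(3:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeomEnrichment(k, n, K, N),
                 bruteHypergeom(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("combination counts are exact", {
  expect_equal(combinationCount(5, 2), 10)
  expect_equal(combinationCount(5, 2), ncol(combn(5, 2)))
  expect_equal(combinationCount(30, 3), ncol(combn(30, 3)))
  expect_equal(combinationCount(3, 5), 0)
})
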