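test_that("model-configuration enumeration covers the complication subsets", {
  cfgs <- enumerateModelConfigs()
  expect_length(cfgs, 8)
  names8 <- vapply(cfgs, function(c) c@name, character(1))
  expect_equal(names8[1], "GD1 without complications")
  expect_true("GD1 with skeletal complications" %in% names8)
  expect_true("GD1 with BM, liver and skeletal complications" %in% names8)
  responses <- lapply(cfgs, function(c) c@response)
  # every response contains the base motifs
  expect_true(all(vapply(responses, function(r)
    all(c("M2", "M3") %in% r), logical(1))))
  # the 8 complication subsets are all distinct
  subsets <- vapply(responses, function(r)
    paste(sort(setdiff(r, c("M2", "M3"))), collapse = ","), character(1))
  expect_length(unique(subsets), 8)

  expect_length(enumerateModelConfigs(complicationMotifs = character(0)), 1)
  expect_length(enumerateModelConfigs(complicationMotifs = c("M6", "M7")), 4)
  expect_error(enumerateModelConfigs(baseMotifs = c("M2", "M5")), "disjoint")
})

test_that("propagation preserves sign, bounds and reachability", {
  posNet <- Interactome(data.frame(source = "A", target = "B", sign = 1),
                        data.frame(gene_name = c("A", "B", "C")))
  a <- propagateSignal(posNet, c("A->B" = 1), c(A = 1))
  expect_gt(a[["B"]], 0)
  expect_lte(a[["B"]], 1)
  expect_equal(a[["C"]], 0)          # unreachable from the stimulus

  negNet <- Interactome(data.frame(source = "A", target = "B", sign = -1),
                        data.frame(gene_name = c("A", "B")))
  expect_lt(propagateSignal(negNet, c("A->B" = 1), c(A = 1))[["B"]], 0)

  # all-zero weights: zero activity everywhere except the clamp
  net <- randomNet(8, seed = 2)
  E <- nrow(interactomeEdges(net))
  g1 <- geneNames(net)[1]
  a0 <- propagateSignal(net, rep(0, E), setNames(1, g1))
  expect_equal(unname(a0[g1]), 1)
  expect_true(all(a0[setdiff(names(a0), g1)] == 0))

  # boundedness: doubling steps keeps activities inside [-1, 1]
  w <- rep(1, E)
  a10 <- propagateSignal(net, w, setNames(1, g1), steps = 10)
  a20 <- propagateSignal(net, w, setNames(1, g1), steps = 20)
  expect_true(all(abs(a10) <= 1) && all(abs(a20) <= 1))

  expect_error(propagateSignal(posNet, c("A->Z" = 1), c(A = 1)), "A->Z")
})

test_that("solution loss is a hinge on signed activation floors", {
  acts <- c(A = 0.5, B = -0.4, C = 0.05)
  cons <- data.frame(gene = c("A", "B"), sign = c(1, -1))
  expect_equal(solutionLoss(acts, cons), 0)
  expect_gt(solutionLoss(acts, data.frame(gene = "B", sign = 1)), 0)
  expect_equal(solutionLoss(acts, data.frame(gene = "C", sign = 1)),
               0.1 - 0.05)
  expect_equal(solutionLoss(acts, cons[0, ]), 0)
  expect_error(solutionLoss(acts, data.frame(gene = "Z", sign = 1)), "Z")
})

test_that("response constraints merge restrictions with motif effectors", {
  net <- Interactome(
    data.frame(source = "A", target = "B", sign = 1),
    data.frame(gene_name = c("A", "B", "C"), motifs = c("M2", "M7", "M7"),
               effector = c(TRUE, TRUE, FALSE)))
  cfg <- ModelConfig("m", stimulus = c(A = 1),
                     restrictions = data.frame(gene = "C", sign = -1),
                     response = "M7")
  cons <- responseConstraints(net, cfg)
  # B is an M7 effector (required +), C is restricted (-); non-effector C's
  # motif membership does not add a response constraint
  expect_equal(cons$sign[cons$gene == "B"], 1)
  expect_equal(cons$sign[cons$gene == "C"], -1)
  bad <- ModelConfig("m", stimulus = c(A = 1),
                     restrictions = data.frame(gene = "B", sign = -1),
                     response = "M7")
  expect_error(responseConstraints(net, bad), "infeasible")
})

test_that("solution sampling is reproducible and satisfies its contract", {
  set.seed(99)
  e2e <- generateEndToEndDataset(
    syntheticSpec(nProteins = 40, nSolutions = 10, seed = 21,
                  motifSizes = c(M1 = 2, M2 = 5, M3 = 3, M5 = 3, M6 = 4,
                                 M7 = 6)))
  cfg <- e2e$configs[[4]]   # skeletal model
  am1 <- sampleSolutions(e2e$net, cfg, n = 10, seed = 7)
  am2 <- sampleSolutions(e2e$net, cfg, n = 10, seed = 7)
  expect_identical(activityValues(am1), activityValues(am2))
  expect_identical(solutionSeeds(am1), solutionSeeds(am2))

  v <- activityValues(am1)
  expect_true(all(abs(v) <= 1))
  expect_true(all(solutionLosses(am1) <= 0.05 + 1e-12))

  # across-solution mean of response effectors has the required sign
  cons <- responseConstraints(e2e$net, cfg)
  meanAct <- colMeans(v)[cons$gene]
  expect_true(all(cons$sign * meanAct > 0))

  # infeasible models are rejected with a diagnostic
  bad <- cfg
  bad@restrictions <- data.frame(gene = c("MK_SKEL", "MK_SKEL"),
                                 sign = c(1, -1))
  expect_error(sampleSolutions(e2e$net, bad, n = 2, seed = 1), "infeasible")

  # structurally unsatisfiable constraints reject the matrix
  noNet <- Interactome(data.frame(source = "A", target = "B", sign = -1),
                       data.frame(gene_name = c("A", "B"),
                                  motifs = c("", "M7"),
                                  effector = c(FALSE, TRUE)))
  hard <- ModelConfig("impossible", stimulus = c(A = 1), response = "M7")
  expect_error(sampleSolutions(noNet, hard, n = 4, seed = 1, maxIter = 50),
               "failed to reach")
})

test_that("activity matrices round-trip through TSV + JSON sidecar", {
  dir <- withr::local_tempdir()
  vals <- matrix(round(runif(12, -1, 1), 6), 3,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
  am <- ActivityMatrix(vals, model = "toy", seeds = 1:3,
                       losses = c(0, 0.01, 0), response = c("M2", "M3"),
                       tolerance = 0.05)
  f <- file.path(dir, "am.tsv")
  writeActivityMatrix(am, f)
  am2 <- readActivityMatrix(f)
  expect_equal(activityValues(am2), activityValues(am))
  expect_equal(modelName(am2), "toy")
  expect_equal(solutionSeeds(am2), 1:3)
  expect_equal(S4Vectors::metadata(am2)$response, c("M2", "M3"))
})

test_that("activity matrices validate their bounds", {
  expect_error(
    ActivityMatrix(matrix(2, 1, 1, dimnames = list(NULL, "A"))),
    "\\[-1, 1\\]")
})
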