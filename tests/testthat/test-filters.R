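test_that("the cascade applies its four filters in order", {
  genes <- c("P1", "P2", "P3")
  pos <- matrix(0.5, 10, 3, dimnames = list(NULL, genes))
  neg <- matrix(-0.5, 10, 3, dimnames = list(NULL, genes))
  cfg <- filterConfig()

  cands <- data.frame(
    proteins = c("P1", "P2", "P3", "P1+P2"),
    bacc = c(0.5854, 0.6669, 0.70, 0.72),       # P1 ties the reference
    sensitivity = c(0.9, 0.7114, 0.50, 0.80),    # P3 fails sensitivity
    specificity = c(0.9, 0.6224, 0.90, 0.80),
    precision = c(0.9, 0.6532, 0.90, 0.80),
    cv_p = 1e-10)
  rep <- applyFilterCascade(cands, cfg, pos, neg)
  rej <- rejections(rep)
  # equal to the reference is not an improvement: strict >
  expect_equal(rej$filter[rej$proteins == "P1"], "reference_bacc")
  expect_equal(rej$filter[rej$proteins == "P3"], "sensitivity_precision")
  expect_true(all(c("P2", "P1+P2") %in% survivors(rep)$proteins))

  # a protein flat in 80% of one cohort knocks its candidates out
  pos2 <- pos
  pos2[1:8, "P2"] <- 0
  rep2 <- applyFilterCascade(cands, cfg, pos2, neg)
  rej2 <- rejections(rep2)
  expect_equal(rej2$filter[rej2$proteins == "P2"], "unmodulated")
  expect_equal(rej2$filter[rej2$proteins == "P1+P2"], "unmodulated")

  # filter 4: identity is the unordered tuple
  rep3 <- applyFilterCascade(cands, cfg, pos, neg,
                             otherSurvivors = list(bm = "P2+P1"))
  rej3 <- rejections(rep3)
  expect_equal(rej3$filter[rej3$proteins == "P1+P2"], "other_complications")
  expect_true("P2" %in% survivors(rep3)$proteins)

  expect_error(
    applyFilterCascade(data.frame(proteins = "P9", bacc = 0.9,
                                  sensitivity = 0.9, specificity = 0.9,
                                  precision = 0.9),
                       cfg, pos, neg), "P9")
})

test_that("survivors equal the predicate intersection minus other-survivor sets", {
  cfg <- filterConfig(referenceBacc = 0.6, unmodulatedTolerance = 0.05,
                      unmodulatedFraction = 0.75)
  genes <- sprintf("G%02d", 1:8)
  for (seed in 1:8) {
    rc <- randomCandidates(25, genes, seed = seed)
    others <- list(bm = sample(rc$cands$proteins, 5),
                   liver = sample(rc$cands$proteins, 5))
    rep <- applyFilterCascade(rc$cands, cfg, rc$pos, rc$neg, others)

    # independent set-algebra oracle over pure predicates
    f1 <- rc$cands$bacc > cfg@referenceBacc
    f2 <- rc$cands$sensitivity >= cfg@minSensitivity &
      rc$cands$precision >= cfg@minPrecision
    f3 <- vapply(strsplit(rc$cands$proteins, "+", fixed = TRUE),
                 function(gs) all(vapply(gs, function(g)
                   max(mean(abs(rc$pos[, g]) < cfg@unmodulatedTolerance),
                       mean(abs(rc$neg[, g]) < cfg@unmodulatedTolerance)) <
                     cfg@unmodulatedFraction, logical(1))), logical(1))
    f4 <- !(rc$cands$proteins %in% unlist(others))
    oracle <- sort(rc$cands$proteins[f1 & f2 & f3 & f4])
    expect_equal(sort(survivors(rep)$proteins), oracle)

    # each rejection names exactly one filter; partition is complete
    expect_equal(nrow(survivors(rep)) + nrow(rejections(rep)),
                 nrow(rc$cands))
    expect_true(all(rejections(rep)$filter %in%
                      c("reference_bacc", "sensitivity_precision",
                        "unmodulated", "other_complications")))
  }
})

test_that("permuting the pure predicates never changes the survivor set", {
  cfg <- filterConfig(referenceBacc = 0.6)
  genes <- sprintf("G%02d", 1:6)
  rc <- randomCandidates(20, genes, seed = 42)
  base <- sort(survivors(applyFilterCascade(rc$cands, cfg, rc$pos,
                                            rc$neg))$proteins)
  # permute candidate row order (equivalent to reordering predicate checks
  # for pure per-candidate filters) and re-apply
  for (perm in 1:4) {
    shuffled <- rc$cands[sample(nrow(rc$cands)), ]
    got <- sort(survivors(applyFilterCascade(shuffled, cfg, rc$pos,
                                             rc$neg))$proteins)
    expect_equal(got, base)
  }
})

test_that("annotation flags plasma panels and ranks ascending by BACC", {
  cands <- data.frame(
    proteins = c("IL1R2", "MCL1+PDGFB", "GNAI3"),
    bacc = c(0.6754, 0.75, 0.7011),
    sensitivity = 0.7, specificity = 0.7, precision = 0.7, cv_p = 1e-5)
  rep <- new("FilterReport", survivors = cands,
             rejected = data.frame(proteins = character(0),
                                   filter = character(0)),
             config = filterConfig())
  plasma <- c(IL1R2 = TRUE, PDGFB = TRUE, MCL1 = FALSE, GNAI3 = FALSE)
  urine <- c(IL1R2 = FALSE, PDGFB = FALSE, MCL1 = FALSE, GNAI3 = TRUE)
  tab <- annotateAndRank(rep, plasma, urine)
  expect_equal(tab$proteins, c("IL1R2", "GNAI3", "MCL1+PDGFB"))  # ascending
  expect_equal(tab$all_plasma, c(TRUE, FALSE, FALSE))
  expect_equal(tab$plasma[tab$proteins == "MCL1+PDGFB"], "No;Yes")
  expect_equal(tab$urine[tab$proteins == "GNAI3"], "Yes")

  # a gene absent from both tables warns and annotates unknown
  rep2 <- new("FilterReport",
              survivors = data.frame(proteins = "ZZZ9", bacc = 0.7,
                                     sensitivity = 0.7, specificity = 0.7,
                                     precision = 0.7, cv_p = 1e-5),
              rejected = data.frame(proteins = character(0),
                                    filter = character(0)),
              config = filterConfig())
  expect_warning(tab2 <- annotateAndRank(rep2, plasma, urine), "ZZZ9")
  expect_equal(tab2$plasma, "Unknown")
  expect_false(tab2$all_plasma)
})
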