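# Gene-model construction, region lookup and codon arithmetic.

test_that("model construction rejects non-partitioning feature sets", {
  ft <- data.frame(kind = c("exon", "exon"), index = c(1L, 2L),
                   start = c(1L, 12L), end = c(9L, 20L))  # gap at 10..11
  expect_error(GeneModel("HLA-X", "class_I", strrep("A", 20), ft, 0L,
                         domainMap = c("1" = "leader_peptide",
                                       "2" = "antigen_binding_alpha1")),
               "partition")
  ft2 <- data.frame(kind = "exon", index = 1L, start = 1L, end = 10L)
  expect_error(GeneModel("HLA-X", "class_I", strrep("A", 10), ft2, 0L,
                         domainMap = c("1" = "leader_peptide")),
               "divisible by 3")
})

test_that("locateRegion returns the unique containing interval", {
  m <- exampleGeneModel("DPA1")
  r <- locateRegion(m, 79)
  expect_equal(r$kind, "exon")
  expect_equal(r$index, 1L)
  # boundary case: position 1 falls in the first feature
  first <- locateRegion(m, 1)
  expect_equal(first$start, 1L)
  expect_error(locateRegion(m, 0), "out of range")
  expect_error(locateRegion(m, length(modelSequence(m)) + 1L), "out of range")
})

test_that("locateRegion agrees with a linear-scan oracle on sampled positions", {
  set.seed(11)
  for (m in list(toyModel(), exampleGeneModel("B"), exampleGeneModel("DQA1"))) {
    ft <- modelFeatures(m)
    for (i in seq_len(nrow(ft))) {
      pos <- sample(seq.int(ft$start[i], ft$end[i]), 1L)
      expect_identical(locateRegion(m, pos), regionScanOracle(m, pos),
                       ignore_attr = TRUE)
    }
  }
})

test_that("genomicToCodon maps the leader nonsense position to codon -5", {
  m <- exampleGeneModel("DPA1")
  a <- genomicToCodon(m, 79)
  expect_equal(codonPosition(a), -5L)
  expect_equal(offsetInCodon(a), 0L)
  expect_equal(codonAt(m, -5L), "CGA")
})

test_that("a zero-leader model numbers the first CDS base as codon 1", {
  m <- toyModel(leader = 0L)
  a <- genomicToCodon(m, 1)
  expect_equal(codonPosition(a), 1L)
  expect_equal(offsetInCodon(a), 0L)
})

test_that("genomicToCodon rejects non-coding positions", {
  m <- toyModel()
  expect_error(genomicToCodon(m, 15), "not coding")
})

test_that("codon numbering skips zero and -1/+1 are 3 CDS bases apart", {
  m <- toyModel(leader = 2L)
  positions <- allExonicPositions(m)
  nums <- vapply(positions, function(p) codonPosition(genomicToCodon(m, p)),
                 integer(1))
  expect_false(any(nums == 0L))
  expect_setequal(unique(nums), c(-2L, -1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L))
  # CDS-order distance between the last -1 base and the first +1 base is 1
  lastNeg <- max(which(nums == -1L))
  firstPos <- min(which(nums == 1L))
  expect_equal(firstPos - lastNeg, 1L)
})

test_that("genomicToCodon matches the base-walk oracle on random exonic positions", {
  set.seed(42)
  models <- list(toyModel(), exampleGeneModel("DPA1"), exampleGeneModel("B"),
                 exampleGeneModel("C"), exampleGeneModel("DQA1"))
  draws <- 0L
  for (m in models) {
    all <- allExonicPositions(m)
    positions <- sample(all, min(50L, length(all)))
    for (pos in positions) {
      a <- genomicToCodon(m, pos)
      o <- codonWalkOracle(m, pos)
      expect_equal(codonPosition(a), o$codonPosition)
      expect_equal(offsetInCodon(a), o$offsetInCodon)
      draws <- draws + 1L
    }
  }
  expect_gte(draws, 200L)
})

test_that("codonSpan round-trips: the span of a position's codon contains it", {
  set.seed(7)
  m <- exampleGeneModel("B")
  for (pos in sample(allExonicPositions(m), 50L)) {
    a <- genomicToCodon(m, pos)
    expect_true(pos %in% codonSpan(m, codonPosition(a)))
  }
  # codons can straddle introns: exon1 of the toy model ends mid-codon
  tm <- toyModel()
  expect_equal(codonSpan(tm, 2L), c(40L, 41L, 42L))
})

test_that("partial-coverage models anchor numbering on the upstream offset", {
  # same toy CDS but the first 9 coding bases (3 codons) are not covered
  full <- toyModel(leader = 2L)
  ft <- data.frame(kind = c("exon", "intron", "exon"),
                   index = c(2L, 2L, 3L),
                   start = c(1L, 13L, 22L), end = c(12L, 21L, 30L))
  seqc <- paste0("GCTCGAACTAAA", "TTTTTTTTT", "TTAGGGCAT")
  part <- GeneModel("HLA-TOY", "class_II_alpha", seqc, ft, leaderLength = 2L,
                    domainMap = c("2" = "antigen_binding_alpha1",
                                  "3" = "extracellular_arm_alpha2"),
                    fullCDS = FALSE, upstreamCDSBases = 3L)
  # covered bases resume inside leader codon -1 (raw codon 2 of the gene)
  expect_equal(codonPosition(genomicToCodon(part, 1L)), -1L)
  expect_equal(codonPosition(genomicToCodon(part, 4L)), 1L)
  expect_equal(codonAt(part, 1L), "CGA")
})

test_that("translateCodon follows the standard code with stop rendered X", {
  expect_equal(translateCodon("CGA"), "R")
  expect_equal(aaThree(translateCodon("CGA")), "Arg")
  expect_equal(translateCodon("TGA"), "X")
  expect_equal(translateCodon(c("ACT", "GCT")), c("T", "A"))
  expect_error(translateCodon("ACN"), "unsupported base")
  expect_error(translateCodon("AC"), "3 nucleotides")
})

test_that("domainOf returns the class-specific domain map entries", {
  expect_equal(domainOf(exampleGeneModel("C"), 7L), "cytoplasmic_tail")
  expect_equal(domainOf(exampleGeneModel("DQA1"), 3L), "extracellular_arm_alpha2")
  expect_equal(domainOf(exampleGeneModel("B"), 4L), "extracellular_arm_alpha3")
  expect_equal(defaultDomainMap("class_II_beta")[["4"]], "transmembrane")
  expect_error(domainOf(exampleGeneModel("DQA1"), 9L), "no exon")
})

test_that("every genomic position maps to exactly one feature interval", {
  for (m in list(toyModel(), exampleGeneModel("DPA1"))) {
    ft <- modelFeatures(m)
    hits <- vapply(seq_len(length(modelSequence(m))), function(p)
      sum(ft$start <= p & ft$end >= p), integer(1))
    expect_true(all(hits == 1L))
  }
})

test_that("gene-model files round-trip and reject corrupt feature blocks", {
  m <- exampleGeneModel("DQA1")
  f <- tempfile(fileext = ".yaml")
  writeGeneModel(m, f)
  m2 <- readGeneModel(f)
  expect_equal(as.character(modelSequence(m2)), as.character(modelSequence(m)))
  expect_equal(modelFeatures(m2), modelFeatures(m))
  expect_equal(leaderLength(m2), leaderLength(m))
  expect_equal(hlaClass(m2), hlaClass(m))
  # corrupt the feature block so it no longer partitions the sequence
  doc <- yaml::read_yaml(f)
  doc$features[[2]]$start <- doc$features[[2]]$start + 5L
  f2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, f2)
  expect_error(readGeneModel(f2), "partition")
})
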