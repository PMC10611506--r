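# Synthetic gene models, induced mutations, and bundled-fixture integrity.

test_that("generation is deterministic in (seed, index)", {
  cfg <- SimulationConfig(seed = 7L)
  m1 <- makeGeneModel(cfg, 0L)
  m2 <- makeGeneModel(cfg, 0L)
  expect_equal(as.character(modelSequence(m1)), as.character(modelSequence(m2)))
  expect_equal(modelFeatures(m1), modelFeatures(m2))
  m3 <- makeGeneModel(cfg, 1L)
  expect_false(identical(as.character(modelSequence(m1)),
                         as.character(modelSequence(m3))))
})

test_that("a class II alpha config yields 4 exons with the alpha domain map", {
  cfg <- SimulationConfig(seed = 3L, classMix = c(class_II_alpha = 1))
  m <- makeGeneModel(cfg, 0L)
  expect_equal(hlaClass(m), "class_II_alpha")
  expect_equal(sum(modelFeatures(m)$kind == "exon"), 4L)
  expect_equal(domainOf(m, 2L), "antigen_binding_alpha1")
  expect_equal(domainOf(m, 4L), "transmembrane_cytoplasmic")
})

test_that("generated models satisfy the model invariants across many seeds", {
  for (seed in 1:100) {
    m <- makeGeneModel(SimulationConfig(seed = seed), 0L)
    expect_true(validObject(m, test = TRUE))
    cds <- as.character(cdsSequence(m))
    expect_equal(nchar(cds) %% 3L, 0L)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
    expect_lte(leaderLength(m) * 3L, nchar(cds))
  }
})

test_that("codon arithmetic matches the base-walk oracle on synthetic models", {
  # every exonic position of 100 generated models
  mismatches <- 0L
  for (seed in 1:100) {
    m <- makeGeneModel(SimulationConfig(seed = 200L + seed), 0L)
    for (pos in allExonicPositions(m)) {
      a <- genomicToCodon(m, pos)
      o <- codonWalkOracle(m, pos)
      if (codonPosition(a) != o$codonPosition ||
          offsetInCodon(a) != o$offsetInCodon)
        mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("induced mutations carry a truth record consistent by construction", {
  set.seed(31)
  m <- makeGeneModel(SimulationConfig(seed = 31L), 0L)
  sil <- induceMutation(m, "silent")
  expect_equal(sil$truth$refAa, sil$truth$altAa)
  non <- induceMutation(m, "nonsense")
  expect_equal(non$truth$altAa, "X")
  mis <- induceMutation(m, "missense")
  expect_false(mis$truth$refAa == mis$truth$altAa)
  intr <- induceMutation(m, "intronic")
  expect_equal(intr$truth$class, "intronic")
  # exactly one difference from the reference
  expect_equal(sum(strsplit(as.character(modelSequence(m)), "")[[1L]] !=
                   strsplit(non$consensus, "")[[1L]]), 1L)
})

test_that("induced mutations are recovered exactly by detect + characterize", {
  # 500 draws over mixed classes; position, bases and class must all match
  set.seed(123)
  classes <- c("missense", "silent", "nonsense", "intronic")
  failures <- 0L
  for (i in 1:500) {
    m <- makeGeneModel(SimulationConfig(seed = 1000L + (i %% 40L)), i %% 5L)
    target <- classes[1L + (i %% 4L)]
    draw <- induceMutation(m, target)
    vs <- detectVariants(as.character(modelSequence(m)), draw$consensus)
    ok <- length(vs) == 1L &&
      vs[[1L]]@pos == draw$variant@pos &&
      vs[[1L]]@refBase == draw$variant@refBase &&
      vs[[1L]]@altBase == draw$variant@altBase
    if (ok) {
      ch <- characterizeVariant(m, vs[[1L]])
      ok <- mutationClass(ch) == target
      if (ok && target != "intronic") {
        cc <- codonChange(ch)
        ok <- cc$codonPosition == draw$truth$codonPosition &&
          cc$refCodon == draw$truth$refCodon &&
          cc$altCodon == draw$truth$altCodon
      }
    }
    if (!ok) failures <- failures + 1L
  }
  expect_equal(failures, 0L)
})

test_that("bundled fixtures load with pinned row counts and consistency checks", {
  expect_equal(nrow(novelAlleleTable()), 29L)
  expect_equal(nrow(missenseScoreTable()), 16L)
  expect_equal(nrow(cohortSamples()), 41L)
  cohort <- bundledCohort()
  expect_equal(nrow(cohort), 41L)
  expect_false(anyNA(cohort$locus))
  # the classifier path reproduces the recorded mutation types
  chars <- characterizeFromTable()
  expect_equal(unname(vapply(chars, mutationClass, "")),
               novelAlleleTable()$mutation_type)
})

test_that("bundled fixture files are byte-pinned", {
  sums <- tools::md5sum(vapply(
    c("novel_alleles.tsv", "missense_scores.tsv", "cohort_samples.tsv",
      "aa_properties.tsv", "eplet_registry.tsv"),
    function(f) system.file("extdata", f, package = "novelHLA",
                            mustWork = TRUE),
    character(1)))
  expect_equal(unname(sums), c(
    "4a1b30146a585f2a6503d78b6b47d071", "d3838209c36415c3ed81e373a1fc5926",
    "5959e6e8c26a5c7780629ac3ffe0179e", "91746413fd1cfef63d10cc14293d40e9",
    "53feef7117eb86ad7cc3285d409d339e"))
})
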