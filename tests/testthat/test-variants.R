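# Variant detection, characterization, report sentences and QC flags.

test_that("detectVariants finds substitutions and is empty on identity", {
  ref <- as.character(modelSequence(exampleGeneModel("B")))
  expect_identical(detectVariants(ref, ref), list())
  obs <- ref
  substr(obs, 793, 793) <- "C"
  v <- detectVariants(ref, obs)
  expect_length(v, 1L)
  expect_equal(v[[1L]]@pos, 793L)
  expect_equal(v[[1L]]@refBase, "A")
  expect_equal(v[[1L]]@altBase, "C")
  expect_equal(v[[1L]]@kind, "snp")
  # two substitutions are both reported
  substr(obs, 100, 100) <- if (substr(ref, 100, 100) == "A") "G" else "A"
  expect_length(detectVariants(ref, obs), 2L)
})

test_that("detectVariants localizes a single short indel by trimming", {
  ref <- "ACGTACGTACGT"
  ins <- "ACGTAGGCGTACGT"  # GG inserted after position 5
  v <- detectVariants(ref, ins)
  expect_length(v, 1L)
  expect_equal(v[[1L]]@kind, "insertion")
  expect_equal(v[[1L]]@pos, 5L)
  expect_equal(v[[1L]]@altBase, "GG")
  del <- "ACGTCGTACGT"  # A at position 5 deleted (left-anchored)
  d <- detectVariants(ref, del)
  expect_equal(d[[1L]]@kind, "deletion")
  expect_equal(d[[1L]]@refBase, "A")
  # substitution co-occurring with an indel is out of regime
  expect_error(detectVariants("ACGTACGTACGT", "ACGTAGGCGTACCT"),
               "pre-called")
})

test_that("induced variants round-trip through detectVariants", {
  set.seed(5)
  m <- makeGeneModel(SimulationConfig(seed = 5L), 1L)
  draw <- induceMutation(m, "missense")
  v <- detectVariants(as.character(modelSequence(m)), draw$consensus)
  expect_length(v, 1L)
  expect_equal(v[[1L]]@pos, draw$variant@pos)
  expect_equal(v[[1L]]@altBase, draw$variant@altBase)
})

test_that("characterizeVariant reproduces the Thr228Ala worked example", {
  m <- exampleGeneModel("B")
  ch <- characterizeVariant(m, ObservedVariant(1701L, "A", "G"))
  expect_equal(ch@region$index, 4L)
  expect_equal(proteinDomain(ch), "extracellular_arm_alpha3")
  cc <- codonChange(ch)
  expect_equal(cc$codonPosition, 228L)
  expect_equal(cc$refCodon, "ACT")
  expect_equal(cc$altCodon, "GCT")
  expect_equal(cc$refAa, "T")
  expect_equal(cc$altAa, "A")
  expect_equal(mutationClass(ch), "missense")
  expect_false(keyExon(ch))
})

test_that("a leader stop-gain classifies as nonsense", {
  m <- exampleGeneModel("DPA1")
  ch <- characterizeVariant(m, ObservedVariant(79L, "C", "T"))
  expect_equal(ch@region$index, 1L)
  expect_equal(proteinDomain(ch), "leader_peptide")
  cc <- codonChange(ch)
  expect_equal(cc$codonPosition, -5L)
  expect_equal(cc$refCodon, "CGA")
  expect_equal(cc$altCodon, "TGA")
  expect_equal(cc$refAa, "R")
  expect_equal(cc$altAa, "X")
  expect_equal(mutationClass(ch), "nonsense")
})

test_that("intronic variants near an exon boundary are splice-proximal", {
  m <- exampleGeneModel("DQA1")
  ch <- characterizeVariant(m, ObservedVariant(4027L, "T", "C"))
  expect_equal(mutationClass(ch), "intronic")
  expect_true(spliceProximal(ch))
  expect_equal(length(codonChange(ch)), 0L)
  # deep intronic position is not proximal under the default window
  deep <- characterizeVariant(m, ObservedVariant(4200L, substr(
    as.character(modelSequence(m)), 4200, 4200), "N"))
  expect_false(spliceProximal(deep))
  # widening the window makes a distance-5 position proximal
  ch5 <- characterizeVariant(m, ObservedVariant(4030L, substr(
    as.character(modelSequence(m)), 4030, 4030), "N"), spliceWindow = 5L)
  expect_true(spliceProximal(ch5))
})

test_that("exonic indels classify by frame and UTR variants as utr", {
  m <- exampleGeneModel("B")
  fs <- characterizeVariant(m, ObservedVariant(210L, "", "G", "insertion"))
  expect_equal(mutationClass(fs), "frameshift")
  inframe <- characterizeVariant(m, ObservedVariant(210L, "", "GAT", "insertion"))
  expect_equal(mutationClass(inframe), "in_frame_indel")
  utr <- characterizeVariant(m, ObservedVariant(10L, "A", "C"))
  expect_equal(mutationClass(utr), "utr")
})

test_that("key-exon flag follows the class I 2/3, class II 2 rule", {
  b <- exampleGeneModel("B")     # class I
  q <- exampleGeneModel("DQA1")  # class II alpha
  expect_true(keyExon(characterizeVariant(b, ObservedVariant(793L, "A", "C"))))
  inExon2 <- ObservedVariant(3809L, "C", "T")
  expect_true(keyExon(characterizeVariant(q, inExon2)))
  inExon3 <- ObservedVariant(4548L, "C", "T")
  expect_false(keyExon(characterizeVariant(q, inExon3)))
})

test_that("every exonic SNP of a full-CDS model gets exactly one coding class", {
  set.seed(9)
  m <- toyModel()
  for (pos in allExonicPositions(m)) {
    ref <- substr(as.character(modelSequence(m)), pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ch <- characterizeVariant(m, ObservedVariant(pos, ref, alt))
      expect_true(mutationClass(ch) %in% c("missense", "silent", "nonsense"))
    }
  }
})

test_that("annotation is strand-consistent: mirrored input yields mirrored position", {
  ref <- as.character(modelSequence(exampleGeneModel("C")))
  obs <- ref
  substr(obs, 385, 385) <- "G"
  vFwd <- detectVariants(ref, obs)[[1L]]
  vRev <- detectVariants(revcompChr(ref), revcompChr(obs))[[1L]]
  expect_equal(vRev@pos, nchar(ref) - vFwd@pos + 1L)
  expect_equal(vRev@refBase, revcompChr(vFwd@refBase))
  expect_equal(vRev@altBase, revcompChr(vFwd@altBase))
})

test_that("describeMutation renders the report sentence for each class", {
  b <- exampleGeneModel("B")
  miss <- characterizeVariant(b, ObservedVariant(1701L, "A", "G"))
  expect_equal(
    describeMutation("VGH002", "B*48:01:01:01", miss),
    paste0("VGH002 has 1 nt change from B*48:01:01:01 at nt 1701 where ",
           "A > G (codon 228 ACT > GCT), resulting in a coding change ",
           "228 Thr is changed to Ala."))
  q <- exampleGeneModel("DQA1")
  sil <- characterizeVariant(q, ObservedVariant(3809L, "C", "T"))
  expect_match(describeMutation("VGH026", "DQA1*02:01:01", sil),
               "no coding change")
  d <- exampleGeneModel("DPA1")
  non <- characterizeVariant(d, ObservedVariant(79L, "C", "T"))
  sentence <- describeMutation("VGH014", "DPA1*01:03:01:02", non)
  expect_match(sentence, "codon -5 CGA > TGA", fixed = TRUE)
  expect_match(sentence, "stop codon")
})

test_that("flagSuspect emits the recognized QC indicators", {
  d <- exampleGeneModel("DPA1")
  one <- list(characterizeVariant(d, ObservedVariant(79L, "C", "T")))
  expect_identical(flagSuspect(one, "buccal", FALSE), character())
  expect_identical(flagSuspect(one, "peripheral_blood", TRUE),
                   "germline_confirmation_required")
  three <- rep(one, 3L)
  expect_identical(flagSuspect(three, "peripheral_blood", FALSE),
                   "multiple_exonic_novelties")
  expect_setequal(flagSuspect(three, "peripheral_blood", TRUE),
                  c("multiple_exonic_novelties", "germline_confirmation_required"))
})

test_that("characterizationTable mirrors the report columns", {
  d <- exampleGeneModel("DPA1")
  tab <- characterizationTable(
    list(characterizeVariant(d, ObservedVariant(79L, "C", "T"))),
    alleles = "DPA1*01:137N")
  expect_equal(tab$mutation_class, "nonsense")
  expect_equal(tab$exon, 1L)
  expect_equal(tab$nucleotide_change, "C > T")
  expect_equal(tab$genomic_position, 79L)
  expect_equal(tab$codon_change, "CGA > TGA")
})
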