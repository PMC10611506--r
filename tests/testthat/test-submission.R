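# Submission FASTA and five-column feature-table generation.

makeRecord <- function(sampleId = "VGH002") {
  m <- exampleGeneModel("B")
  seqc <- as.character(modelSequence(m))
  substr(seqc, 1701, 1701) <- "G"
  buildSubmission(sampleId, m, seqc, "B*48:01:01:01")
}

test_that("buildSubmission derives gene/mRNA/CDS features from the model", {
  rec <- makeRecord()
  expect_equal(seqId(rec), "VGH002")
  feats <- submissionFeatures(rec)
  kinds <- vapply(feats, `[[`, "", "kind")
  expect_equal(kinds, c("gene", "mRNA", "CDS"))
  gene <- feats[[1L]]
  expect_equal(unname(gene$intervals[1L, ]), c(1L, 5626L))
  m <- exampleGeneModel("B")
  ft <- modelFeatures(m)
  ex <- ft[ft$kind == "exon", ]
  cds <- feats[[which(kinds == "CDS")]]
  expect_equal(unname(cds$intervals[, 1L]), ex$start)
  expect_equal(unname(cds$intervals[, 2L]), ex$end)
  mrna <- feats[[which(kinds == "mRNA")]]
  utrex <- ft[ft$kind %in% c("five_prime_UTR", "exon", "three_prime_UTR"), ]
  expect_equal(unname(mrna$intervals[, 1L]), utrex$start)
  # interval conservation: CDS intervals sum to the CDS length,
  # mRNA = CDS + UTR intervals, disjoint
  expect_equal(sum(cds$intervals[, 2L] - cds$intervals[, 1L] + 1L),
               length(cdsSequence(m)))
  expect_equal(nrow(mrna$intervals), nrow(cds$intervals) + 2L)
})

test_that("a model without UTRs yields mRNA intervals equal to CDS intervals", {
  m <- toyModel()
  rec <- buildSubmission("VGH999", m, as.character(modelSequence(m)),
                         "TOY*01:01")
  feats <- submissionFeatures(rec)
  kinds <- vapply(feats, `[[`, "", "kind")
  expect_equal(feats[[which(kinds == "mRNA")]]$intervals,
               feats[[which(kinds == "CDS")]]$intervals)
})

test_that("buildSubmission rejects a consensus of the wrong span", {
  m <- exampleGeneModel("B")
  expect_error(buildSubmission("VGH002", m, "ACGT", "B*48:01:01:01"),
               "does not match the model span")
})

test_that("submission FASTA headers follow the SeqID/organism/descriptor dialect", {
  rec <- makeRecord()
  f <- tempfile(fileext = ".fasta")
  writeSubmissionFasta(list(rec), f)
  lines <- readLines(f)
  expect_match(lines[1L], "^>VGH002 \\[organism=Homo sapiens\\] ")
  expect_true(all(nchar(lines[-1L]) <= 70L))
  expect_error(writeSubmissionFasta(list(), tempfile()), "empty")
  expect_error(writeSubmissionFasta(list(rec, rec), tempfile()), "duplicate")
})

test_that("a multi-record FASTA round-trips to identical records", {
  recs <- list(makeRecord("VGH002"), makeRecord("VGH003"), makeRecord("VGH004"))
  f <- tempfile(fileext = ".fasta")
  writeSubmissionFasta(recs, f)
  back <- readSubmissionFasta(f)
  expect_length(back, 3L)
  expect_equal(vapply(back, seqId, ""), c("VGH002", "VGH003", "VGH004"))
  for (i in seq_along(recs)) {
    expect_equal(as.character(back[[i]]@sequence),
                 as.character(recs[[i]]@sequence))
    expect_equal(back[[i]]@description, recs[[i]]@description)
    expect_equal(back[[i]]@organism, recs[[i]]@organism)
  }
  # write -> read -> write is byte-identical
  f2 <- tempfile(fileext = ".fasta")
  x <- Biostrings::readDNAStringSet(f)
  recs2 <- lapply(back, function(r) {
    r@features <- submissionFeatures(makeRecord(seqId(r)))
    r
  })
  writeSubmissionFasta(recs2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("feature tables open with '>Feature SeqID' and round-trip byte-identically", {
  rec <- makeRecord()
  f <- tempfile(fileext = ".tbl")
  writeFeatureTable(rec, f)
  lines <- readLines(f)
  expect_equal(lines[1L], ">Feature VGH002")
  expect_equal(lines[2L], "1\t5626\tgene")
  back <- readFeatureTable(f)
  expect_equal(back$seqId, "VGH002")
  expect_length(back$features, 3L)
  for (i in 1:3) {
    expect_equal(back$features[[i]]$kind, rec@features[[i]]$kind)
    expect_equal(back$features[[i]]$intervals, rec@features[[i]]$intervals,
                 ignore_attr = TRUE)
    expect_equal(back$features[[i]]$qualifiers, rec@features[[i]]$qualifiers)
  }
  # re-write from the parsed form and compare bytes
  rec2 <- rec
  rec2@features <- back$features
  f2 <- tempfile(fileext = ".tbl")
  writeFeatureTable(rec2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("UTR intervals appear in the mRNA block but not the CDS block", {
  rec <- makeRecord()
  f <- tempfile(fileext = ".tbl")
  writeFeatureTable(rec, f)
  back <- readFeatureTable(f)
  kinds <- vapply(back$features, `[[`, "", "kind")
  mrna <- back$features[[which(kinds == "mRNA")]]$intervals
  cds <- back$features[[which(kinds == "CDS")]]$intervals
  expect_true(any(mrna[, 1L] == 1L))       # 5'UTR starts the mRNA
  expect_false(any(cds[, 1L] == 1L))       # CDS starts at the first exon
  expect_equal(nrow(mrna), nrow(cds) + 2L)
})

test_that("the manifest lists one row per record with the mutation sentence", {
  m <- exampleGeneModel("B")
  ch <- characterizeVariant(m, ObservedVariant(1701L, "A", "G"))
  rec <- makeRecord()
  f <- tempfile(fileext = ".tsv")
  writeSubmissionManifest(list(rec),
                          describeMutation("VGH002", "B*48:01:01:01", ch), f)
  df <- read.delim(f)
  expect_equal(nrow(df), 1L)
  expect_equal(df$seq_id, "VGH002")
  expect_match(df$mutation_sentence, "228 Thr is changed to Ala")
})
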