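# Independent oracles: brute-force implementations kept deliberately naive
# so they share no code path with the package's coordinate arithmetic.

# Walk the CDS base by base, assigning each exonic genomic position its codon
# number and offset directly.
codonWalkOracle <- function(model, pos) {
  ft <- modelFeatures(model)
  ex <- ft[ft$kind == "exon", , drop = FALSE]
  genomic <- unlist(lapply(seq_len(nrow(ex)), function(i)
    seq.int(ex$start[i], ex$end[i])))
  t <- which(genomic == pos) - 1L   # 0-based CDS offset
  if (length(t) != 1L) stop("oracle: position not exonic")
  t <- t + model@upstreamCDSBases
  raw <- 0L
  counted <- -1L
  repeat {
    raw <- raw + 1L
    counted <- counted + 3L
    if (counted >= t) break
  }
  leader <- leaderLength(model)
  mature <- if (raw > leader) raw - leader else raw - leader - 1L
  list(codonPosition = mature, offsetInCodon = t - (raw - 1L) * 3L)
}

# linear scan over the feature list
regionScanOracle <- function(model, pos) {
  ft <- modelFeatures(model)
  for (i in seq_len(nrow(ft)))
    if (pos >= ft$start[i] && pos <= ft$end[i]) return(ft[i, , drop = FALSE])
  stop("oracle: position outside model")
}

# a small hand-built 3-exon model with known arithmetic, used across files
toyModel <- function(leader = 2L) {
  # exon1 1..9 (9nt), intron1 10..39, exon2 40..51 (12nt), intron2 52..60,
  # exon3 61..69 (9nt); CDS 30nt = 10 codons
  cds <- c("ATG", "GCT", "CGA", "ACT", "AAA", "TTA", "GGG", "CAT", "TCC", "TGC")
  seqc <- paste0(
    paste(cds[1:3], collapse = ""),
    strrep("T", 30),
    paste(cds[4:7], collapse = ""),
    strrep("G", 9),
    paste(cds[8:10], collapse = "")
  )
  ft <- data.frame(
    kind = c("exon", "intron", "exon", "intron", "exon"),
    index = c(1L, 1L, 2L, 2L, 3L),
    start = c(1L, 10L, 40L, 52L, 61L),
    end = c(9L, 39L, 51L, 60L, 69L)
  )
  GeneModel("HLA-TOY", "class_II_alpha", seqc, ft, leaderLength = leader,
            domainMap = c("1" = "leader_peptide",
                          "2" = "antigen_binding_alpha1",
                          "3" = "extracellular_arm_alpha2"))
}

allExonicPositions <- function(model) {
  ft <- modelFeatures(model)
  ex <- ft[ft$kind == "exon", , drop = FALSE]
  unlist(lapply(seq_len(nrow(ex)), function(i) seq.int(ex$start[i], ex$end[i])))
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
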