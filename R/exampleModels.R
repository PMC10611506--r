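# Reconstructed reference models for the worked examples.
#
# True IMGT reference sequences are not redistributable here, so these models
# are synthetic reconstructions built to be self-consistent with the printed
# worked-example coordinates (e.g. DPA1 genomic position 79 <-> codon -5 CGA;
# HLA-B position 1701 <-> codon 228 ACT): the exon/intron geometry and the
# planted reference codons reproduce the published coordinate arithmetic,
# while all remaining bases are random. They are NOT authoritative IMGT
# sequences.

# evaluate expr under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(expr)
}

.NON_STOP_CODONS <- {
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1L, paste, collapse = "")
  all3[!all3 %in% c("TAA", "TAG", "TGA")]
}

.randomCodons <- function(n) sample(.NON_STOP_CODONS, n, replace = TRUE)

.randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Assemble a genomic sequence from a feature table, a codon vector for the
# CDS, and random fill for non-exonic features.
.assembleGenomic <- function(features, cdsCodons) {
  cds <- paste(cdsCodons, collapse = "")
  out <- character(nrow(features))
  used <- 0L
  for (i in seq_len(nrow(features))) {
    len <- features$end[i] - features$start[i] + 1L
    if (features$kind[i] == "exon") {
      out[i] <- substr(cds, used + 1L, used + len)
      used <- used + len
    } else {
      out[i] <- .randomBases(len)
    }
  }
  paste(out, collapse = "")
}

.featureTable <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(kind = r[[1L]],
               index = if (is.na(r[[2L]])) NA_integer_ else as.integer(r[[2L]]),
               start = as.integer(r[[3L]]), end = as.integer(r[[4L]]))))
}

.buildExampleModel <- function(seed, locusName, hlaClass, leaderLength,
                               features, plantedCodons = list(),
                               plantedBases = list()) {
  .withSeed(seed, {
    cdsLen <- sum(features$end[features$kind == "exon"] -
                  features$start[features$kind == "exon"] + 1L)
    codons <- .randomCodons(cdsLen %/% 3L)
    for (nm in names(plantedCodons)) codons[as.integer(nm)] <- plantedCodons[[nm]]
    seqc <- .assembleGenomic(features, codons)
    for (nm in names(plantedBases)) {
      p <- as.integer(nm)
      substr(seqc, p, p + nchar(plantedBases[[nm]]) - 1L) <- plantedBases[[nm]]
    }
    GeneModel(locusName, hlaClass, seqc, features, leaderLength)
  })
}

#' Reconstructed example gene models
#'
#' Deterministic synthetic reconstructions of four reference loci, built so
#' that the worked-example coordinates hold exactly:
#' \describe{
#'   \item{\code{"DPA1"}}{Class II alpha, leader 31 codons, exon 1 starting
#'     at genomic position 1 (the reference alignment starts in partial
#'     exon 1); position 79 is the first base of leader codon -5, reference
#'     triplet CGA, so the C>T novelty is the Arg-to-stop nonsense change.}
#'   \item{\code{"B"}}{Class I, leader 24 codons, 5626 bp total; position
#'     1701 is the first base of codon 228 (ACT, Thr) in exon 4, and position
#'     793 is the third base of codon 116 (TTA, Leu) in exon 3.}
#'   \item{\code{"C"}}{Class I, leader 24 codons; codons 17 (CGC, exon 2),
#'     60 (TGG, exon 2) and 340 (TGC, exon 7) are planted.}
#'   \item{\code{"DQA1"}}{Class II alpha, leader 23 codons; silent-change
#'     codons planted in exons 2 and 3, and intron 2 starts with the
#'     canonical GT donor at 4026-4027, two bases from the exon 2 boundary.}
#' }
#'
#' All other bases are random under a fixed per-model seed, so repeated calls
#' return identical models.
#'
#' @param name One of \code{"DPA1"}, \code{"B"}, \code{"C"}, \code{"DQA1"}.
#' @return A \linkS4class{GeneModel}.
#' @examples
#' m <- exampleGeneModel("DPA1")
#' codonAt(m, -5)  # "CGA"
#' @export
exampleGeneModel <- function(name = c("DPA1", "B", "C", "DQA1")) {
  name <- match.arg(name)
  switch(name,
    DPA1 = .buildExampleModel(
      seed = 101L, locusName = "HLA-DPA1", hlaClass = "class_II_alpha",
      leaderLength = 31L,
      features = .featureTable(
        list("exon", 1, 1, 93),
        list("intron", 1, 94, 3000),
        list("exon", 2, 3001, 3246),
        list("intron", 2, 3247, 4263),
        list("exon", 3, 4264, 4545),
        list("intron", 3, 4546, 4759),
        list("exon", 4, 4760, 5014),
        list("three_prime_UTR", NA, 5015, 5200)
      ),
      # raw codon index -> reference triplet
      plantedCodons = list(
        "27" = "CGA",   # leader codon -5 at genomic 79..81
        "180" = "CAT",  # codon 149 (His) at 4462..4464
        "194" = "GCC",  # silent-change codon, third base at 4506
        "255" = "CGG"   # codon 224 (Arg) at 4901..4903
      )
    ),
    B = .buildExampleModel(
      seed = 102L, locusName = "HLA-B", hlaClass = "class_I",
      leaderLength = 24L,
      features = .featureTable(
        list("five_prime_UTR", NA, 1, 60),
        list("exon", 1, 61, 133),
        list("intron", 1, 134, 203),
        list("exon", 2, 204, 473),
        list("intron", 2, 474, 716),
        list("exon", 3, 717, 992),
        list("intron", 3, 993, 1566),
        list("exon", 4, 1567, 1842),
        list("intron", 4, 1843, 2100),
        list("exon", 5, 2101, 2217),
        list("intron", 5, 2218, 2500),
        list("exon", 6, 2501, 2533),
        list("intron", 6, 2534, 5400),
        list("exon", 7, 5401, 5447),
        list("three_prime_UTR", NA, 5448, 5626)
      ),
      plantedCodons = list(
        "140" = "TTA",  # codon 116 (Leu), third base at genomic 793
        "252" = "ACT"   # codon 228 (Thr), first base at genomic 1701
      )
    ),
    C = .buildExampleModel(
      seed = 103L, locusName = "HLA-C", hlaClass = "class_I",
      leaderLength = 24L,
      features = .featureTable(
        list("exon", 1, 1, 73),
        list("intron", 1, 74, 208),
        list("exon", 2, 209, 478),
        list("intron", 2, 479, 599),
        list("exon", 3, 600, 875),
        list("intron", 3, 876, 1100),
        list("exon", 4, 1101, 1376),
        list("intron", 4, 1377, 1500),
        list("exon", 5, 1501, 1617),
        list("intron", 5, 1618, 1800),
        list("exon", 6, 1801, 1833),
        list("intron", 6, 1834, 2675),
        list("exon", 7, 2676, 2722),
        list("three_prime_UTR", NA, 2723, 2800)
      ),
      plantedCodons = list(
        "41" = "CGC",   # codon 17 (Arg) at genomic 256..258
        "84" = "TGG",   # codon 60 (Trp) at genomic 385..387
        "364" = "TGC"   # codon 340 (Cys) at genomic 2720..2722
      )
    ),
    DQA1 = .buildExampleModel(
      seed = 104L, locusName = "HLA-DQA1", hlaClass = "class_II_alpha",
      leaderLength = 23L,
      features = .featureTable(
        list("five_prime_UTR", NA, 1, 30),
        list("exon", 1, 31, 112),
        list("intron", 1, 113, 3800),
        list("exon", 2, 3801, 4025),
        list("intron", 2, 4026, 4500),
        list("exon", 3, 4501, 4782),
        list("intron", 3, 4783, 5000),
        list("exon", 4, 5001, 5179),
        list("three_prime_UTR", NA, 5180, 5300)
      ),
      plantedCodons = list(
        "31" = "CTG",   # silent C>T codon, first base at genomic 3809
        "86" = "CGC",   # silent C>A codon, third base at genomic 3976
        "119" = "CTA"   # silent C>T codon, first base at genomic 4548
      ),
      plantedBases = list("4026" = "GT")  # canonical splice donor
    )
  )
}
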