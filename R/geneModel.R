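# Gene-model construction and coordinate arithmetic.

#' Default exon-to-domain maps
#'
#' Domain maps name the protein domain each exon encodes. Defaults: class I -
#' 1 leader, 2 alpha-1 binding, 3 alpha-2 binding, 4 alpha-3 arm,
#' 5 transmembrane, 6-7 cytoplasmic tail; class II alpha - 1 leader,
#' 2 alpha-1 binding, 3 alpha-2 arm, 4 transmembrane/cytoplasmic; class II
#' beta - 1 leader, 2 beta-1 binding, 3 beta-2 arm, 4 transmembrane,
#' 5 cytoplasmic tail.
#'
#' @param hlaClass One of the three HLA class labels.
#' @return Named character vector, names are exon indices.
#' @export
defaultDomainMap <- function(hlaClass) {
  switch(hlaClass,
    class_I = c(
      "1" = "leader_peptide",
      "2" = "antigen_binding_alpha1",
      "3" = "antigen_binding_alpha2",
      "4" = "extracellular_arm_alpha3",
      "5" = "transmembrane",
      "6" = "cytoplasmic_tail",
      "7" = "cytoplasmic_tail"
    ),
    class_II_alpha = c(
      "1" = "leader_peptide",
      "2" = "antigen_binding_alpha1",
      "3" = "extracellular_arm_alpha2",
      "4" = "transmembrane_cytoplasmic"
    ),
    class_II_beta = c(
      "1" = "leader_peptide",
      "2" = "antigen_binding_beta1",
      "3" = "extracellular_arm_beta2",
      "4" = "transmembrane",
      "5" = "cytoplasmic_tail"
    ),
    stop("unknown HLA class: ", hlaClass)
  )
}

#' Construct a GeneModel
#'
#' @param locusName Locus label, e.g. \code{"HLA-DPA1"}.
#' @param hlaClass \code{"class_I"}, \code{"class_II_alpha"} or
#'   \code{"class_II_beta"}.
#' @param sequence Genomic sequence (character or
#'   \link[Biostrings]{DNAString}).
#' @param features \code{data.frame} with columns \code{kind}, \code{index},
#'   \code{start}, \code{end} partitioning the sequence (1-based inclusive).
#' @param leaderLength Leader-peptide length in codons.
#' @param domainMap Optional exon-to-domain map; defaults to
#'   \code{\link{defaultDomainMap}(hlaClass)} restricted to the model's exons.
#' @param fullCDS Whether the model covers the complete CDS.
#' @param upstreamCDSBases Coding bases upstream of the covered region
#'   (partial models only).
#' @return A validated \linkS4class{GeneModel}.
#' @examples
#' ft <- data.frame(
#'   kind = c("exon", "intron", "exon"),
#'   index = c(1L, 1L, 2L),
#'   start = c(1L, 10L, 40L), end = c(9L, 39L, 60L)
#' )
#' m <- GeneModel("HLA-TOY", "class_II_alpha",
#'                paste(rep("ACGTGGATCC", 6), collapse = ""), ft,
#'                leaderLength = 2L)
#' @export
GeneModel <- function(locusName, hlaClass, sequence, features,
                      leaderLength, domainMap = NULL,
                      fullCDS = TRUE, upstreamCDSBases = 0L) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  features$index <- as.integer(features$index)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  rownames(features) <- NULL
  if (is.null(domainMap)) {
    dm <- defaultDomainMap(hlaClass)
    ex <- as.character(features$index[features$kind == "exon"])
    if (!all(ex %in% names(dm)))
      stop("no default domain label for exon(s) ",
           paste(setdiff(ex, names(dm)), collapse = ", "),
           "; supply domainMap explicitly")
    domainMap <- dm[ex]
  }
  new("GeneModel", locusName = locusName, hlaClass = hlaClass,
      sequence = sequence, features = features,
      leaderLength = as.integer(leaderLength), domainMap = domainMap,
      fullCDS = fullCDS, upstreamCDSBases = as.integer(upstreamCDSBases))
}

#' @describeIn GeneModel Locus label.
#' @param x A \code{GeneModel}.
#' @export
setMethod("locusName", "GeneModel", function(x) x@locusName)

#' @describeIn GeneModel HLA class label.
#' @export
setMethod("hlaClass", "GeneModel", function(x) x@hlaClass)

#' @describeIn GeneModel Genomic sequence as a \code{DNAString}.
#' @export
setMethod("modelSequence", "GeneModel", function(x) x@sequence)

#' @describeIn GeneModel Feature-interval table.
#' @export
setMethod("modelFeatures", "GeneModel", function(x) x@features)

#' @describeIn GeneModel Leader length in codons.
#' @export
setMethod("leaderLength", "GeneModel", function(x) x@leaderLength)

#' @describeIn GeneModel Exon-to-domain map.
#' @export
setMethod("domainMap", "GeneModel", function(x) x@domainMap)

#' @describeIn GeneModel Spliced coding sequence (concatenated exons) as a
#'   \code{DNAString}.
#' @export
setMethod("cdsSequence", "GeneModel", function(x) {
  ex <- x@features[x@features$kind == "exon", , drop = FALSE]
  parts <- vapply(seq_len(nrow(ex)), function(i)
    as.character(Biostrings::subseq(x@sequence, ex$start[i], ex$end[i])),
    character(1))
  Biostrings::DNAString(paste(parts, collapse = ""))
})

setMethod("show", "GeneModel", function(object) {
  ft <- object@features
  cds <- sum(ft$end[ft$kind == "exon"] - ft$start[ft$kind == "exon"] + 1L)
  cat(sprintf("GeneModel %s (%s)\n", object@locusName, object@hlaClass))
  cat(sprintf("  %d bp genomic, %d features (%d exons), CDS %d nt (%s)\n",
              length(object@sequence), nrow(ft), sum(ft$kind == "exon"),
              cds, if (object@fullCDS) "full" else "partial"))
  cat(sprintf("  leader %d codons; mature codons 1..%d\n",
              object@leaderLength,
              (cds + object@upstreamCDSBases) %/% 3L - object@leaderLength))
})

#' Locate the feature interval containing a genomic position
#'
#' @param model A \linkS4class{GeneModel}.
#' @param pos 1-based genomic position.
#' @return One-row \code{data.frame} with \code{kind}, \code{index},
#'   \code{start}, \code{end}.
#' @examples
#' m <- exampleGeneModel("DPA1")
#' locateRegion(m, 79)  # exon 1
#' @export
setMethod("locateRegion", "GeneModel", function(model, pos) {
  pos <- as.integer(pos)
  if (length(pos) != 1L || is.na(pos) || pos < 1L ||
      pos > length(model@sequence))
    stop(sprintf("position out of range: must be in 1..%d",
                 length(model@sequence)))
  ft <- model@features
  hit <- which(ft$start <= pos & ft$end >= pos)
  ft[hit, , drop = FALSE]
})

# count of exonic bases strictly before pos (pos must be exonic)
.cdsOffset <- function(model, pos) {
  ex <- model@features[model@features$kind == "exon", , drop = FALSE]
  full <- ex$end < pos
  within <- ex$start <= pos & ex$end >= pos
  sum(ex$end[full] - ex$start[full] + 1L) +
    if (any(within)) pos - ex$start[within] else 0L
}

.rawToMature <- function(raw, leader) {
  ifelse(raw > leader, raw - leader, raw - leader - 1L)
}

.matureToRaw <- function(mature, leader) {
  ifelse(mature > 0L, mature + leader, mature + leader + 1L)
}

#' Map a genomic position to a codon address
#'
#' Computes the codon containing an exonic genomic position in mature-protein
#' numbering: leader codons are numbered -L..-1 and mature codons 1..M with
#' no codon 0 (-1 immediately precedes +1). The address is derived from the
#' count of exonic (CDS) bases strictly before the position; for
#' partial-coverage models the model's \code{upstreamCDSBases} anchor is
#' added first.
#'
#' @param model A \linkS4class{GeneModel}.
#' @param pos 1-based genomic position; must fall in an exon.
#' @return A \linkS4class{CodonAddress}.
#' @examples
#' m <- exampleGeneModel("DPA1")
#' genomicToCodon(m, 79)  # codon -5, offset 0
#' @export
setMethod("genomicToCodon", "GeneModel", function(model, pos) {
  pos <- as.integer(pos)
  region <- locateRegion(model, pos)
  if (region$kind != "exon")
    stop(sprintf("position %d is not coding (%s)", pos, region$kind))
  t <- model@upstreamCDSBases + .cdsOffset(model, pos)
  raw <- t %/% 3L + 1L
  new("CodonAddress",
      codonPosition = as.integer(.rawToMature(raw, model@leaderLength)),
      offsetInCodon = as.integer(t %% 3L),
      rawIndex = as.integer(raw))
})

#' @describeIn genomicToCodon Signed mature-protein codon number.
#' @param x A \code{CodonAddress}.
#' @export
setMethod("codonPosition", "CodonAddress", function(x) x@codonPosition)

#' @describeIn genomicToCodon Offset (0..2) of the base within its codon.
#' @export
setMethod("offsetInCodon", "CodonAddress", function(x) x@offsetInCodon)

setMethod("show", "CodonAddress", function(object) {
  cat(sprintf("CodonAddress: codon %d, offset %d\n",
              object@codonPosition, object@offsetInCodon))
})

#' Genomic span and reference triplet of a codon
#'
#' \code{codonSpan} returns the genomic positions of the three bases of a
#' codon given by its signed mature-protein number (the bases may straddle an
#' intron). \code{codonAt} returns the reference triplet.
#'
#' @param model A \linkS4class{GeneModel}.
#' @param codonPosition Signed codon number (no 0).
#' @return \code{codonSpan}: integer vector of 3 genomic positions;
#'   \code{codonAt}: the reference codon as a 3-character string.
#' @examples
#' m <- exampleGeneModel("DPA1")
#' codonAt(m, -5)    # "CGA"
#' codonSpan(m, -5)  # 79 80 81
#' @export
codonSpan <- function(model, codonPosition) {
  codonPosition <- as.integer(codonPosition)
  if (codonPosition == 0L) stop("codon 0 does not exist")
  raw <- .matureToRaw(codonPosition, model@leaderLength)
  localStart <- (raw - 1L) * 3L - model@upstreamCDSBases + 1L
  if (localStart < 1L)
    stop("codon not covered by this (partial) model")
  ex <- model@features[model@features$kind == "exon", , drop = FALSE]
  lens <- ex$end - ex$start + 1L
  if (localStart + 2L > sum(lens))
    stop("codon beyond the covered CDS")
  # genomic position of each CDS-local index
  cum <- cumsum(lens)
  vapply(localStart + 0:2, function(i) {
    j <- which(cum >= i)[1L]
    before <- if (j > 1L) cum[j - 1L] else 0L
    ex$start[j] + (i - before) - 1L
  }, integer(1))
}

#' @rdname codonSpan
#' @export
codonAt <- function(model, codonPosition) {
  span <- codonSpan(model, codonPosition)
  paste(vapply(span, function(p)
    as.character(Biostrings::subseq(model@sequence, p, p)), character(1)),
    collapse = "")
}

#' Protein domain encoded by an exon
#'
#' @param model A \linkS4class{GeneModel}.
#' @param exonIndex 1-based exon ordinal.
#' @return Protein-domain label.
#' @examples
#' domainOf(exampleGeneModel("C"), 7L)  # "cytoplasmic_tail"
#' @export
setMethod("domainOf", "GeneModel", function(model, exonIndex) {
  key <- as.character(as.integer(exonIndex))
  if (!key %in% names(model@domainMap))
    stop(sprintf("model %s has no exon %s", model@locusName, key))
  unname(model@domainMap[key])
})
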