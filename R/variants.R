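# Variant detection against a reference allele and full characterization of
# a single novelty: region, protein domain, codon change, mutation class,
# key-exon and splice-proximity flags, plus the written report sentence.

#' Construct an ObservedVariant
#'
#' @param pos 1-based position on the reference. Insertions are reported at
#'   the reference base immediately before the inserted material.
#' @param refBase Reference base (snp) or deleted string (deletion); ignored
#'   for insertions.
#' @param altBase Alternate base (snp) or inserted string (insertion);
#'   ignored for deletions.
#' @param kind \code{"snp"}, \code{"insertion"} or \code{"deletion"}.
#' @return An \linkS4class{ObservedVariant}.
#' @examples
#' ObservedVariant(79L, "C", "T")
#' @export
ObservedVariant <- function(pos, refBase = "", altBase = "", kind = "snp") {
  new("ObservedVariant", pos = as.integer(pos),
      refBase = toupper(refBase), altBase = toupper(altBase), kind = kind)
}

setMethod("show", "ObservedVariant", function(object) {
  cat(switch(object@kind,
    snp = sprintf("ObservedVariant: snp %s > %s at %d\n",
                  object@refBase, object@altBase, object@pos),
    insertion = sprintf("ObservedVariant: insertion of %s after %d\n",
                        object@altBase, object@pos),
    deletion = sprintf("ObservedVariant: deletion of %s at %d\n",
                       object@refBase, object@pos)))
})

.longestCommonPrefix <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq)) neq[1L] - 1L else n
}

#' Detect nucleotide differences between reference and consensus
#'
#' A purpose-built comparator for the desk-scale regime of novel-allele
#' review, where a consensus differs from its most related reference by point
#' substitutions or by a single short indel. Equal-length inputs are compared
#' position by position (all differences reported as SNPs); length-discrepant
#' inputs are reconciled by maximal common prefix/suffix trimming and must
#' reduce to exactly one insertion or deletion (left-anchored when the indel
#' sits in a repeat). Inputs that cannot be reconciled this way - e.g. a
#' substitution co-occurring with an indel - raise an error directing the
#' user to supply pre-called variants instead.
#'
#' @param reference,consensus Nucleotide strings (character or
#'   \link[Biostrings]{DNAString}).
#' @param maxIndel Largest supported indel length (default 50).
#' @return List of \linkS4class{ObservedVariant} (empty when identical).
#' @examples
#' detectVariants("ACGTACGT", "ACCTACGT")  # one snp at position 3
#' @export
detectVariants <- function(reference, consensus, maxIndel = 50L) {
  ref <- toupper(as.character(reference))
  obs <- toupper(as.character(consensus))
  if (!nzchar(ref) || !nzchar(obs))
    stop("reference and consensus must be non-empty")
  if (identical(ref, obs)) return(list())
  ra <- strsplit(ref, "", fixed = TRUE)[[1L]]
  oa <- strsplit(obs, "", fixed = TRUE)[[1L]]
  if (length(ra) == length(oa)) {
    at <- which(ra != oa)
    return(lapply(at, function(p) ObservedVariant(p, ra[p], oa[p], "snp")))
  }
  d <- length(oa) - length(ra)
  if (abs(d) > maxIndel)
    stop("sequences differ by more than one short indel; ",
         "supply pre-called variants instead")
  p <- .longestCommonPrefix(ra, oa)
  s <- .longestCommonPrefix(rev(ra), rev(oa))
  nmin <- min(length(ra), length(oa))
  if (p + s < nmin)
    stop("alignment unsupported: sequences do not reduce to substitutions ",
         "plus a single short indel; supply pre-called variants instead")
  if (d > 0L) {
    ins <- paste(oa[(p + 1L):(p + d)], collapse = "")
    list(ObservedVariant(max(p, 1L), "", ins, "insertion"))
  } else {
    del <- paste(ra[(p + 1L):(p - d)], collapse = "")
    list(ObservedVariant(p + 1L, del, "", "deletion"))
  }
}

#' Characterize a variant against a gene model
#'
#' Produces the full annotation of one novelty: the containing feature
#' interval, the protein domain encoded by the exon, the codon change with
#' mature-protein numbering (exonic SNPs), the mutation class, the key-exon
#' flag (exons 2/3 for class I, exon 2 for class II), and for intronic
#' variants a splice-proximity flag. Exonic indels are classified frameshift
#' when their length is not a multiple of 3, in-frame otherwise. A stop
#' gained anywhere in the CDS - including the leader peptide - classifies as
#' nonsense.
#'
#' @param model A \linkS4class{GeneModel}.
#' @param variant An \linkS4class{ObservedVariant}.
#' @param spliceWindow Intronic distance (in bases) to the nearest exon
#'   boundary at or under which \code{spliceProximal} is set; default 2, the
#'   canonical splice dinucleotides. The flag is advisory: expression
#'   suffixes (N/Q) are a reporting suggestion, never applied silently.
#' @return A \linkS4class{MutationCharacterization}.
#' @examples
#' m <- exampleGeneModel("DPA1")
#' characterizeVariant(m, ObservedVariant(79L, "C", "T"))  # nonsense at -5
#' @export
characterizeVariant <- function(model, variant, spliceWindow = 2L) {
  region <- locateRegion(model, variant@pos)
  domain <- NA_character_
  codonChange <- list()
  keyEx <- FALSE
  spliceProx <- FALSE
  if (region$kind == "exon") {
    domain <- domainOf(model, region$index)
    keyEx <- (model@hlaClass == "class_I" && region$index %in% c(2L, 3L)) ||
      (model@hlaClass != "class_I" && region$index == 2L)
    if (variant@kind == "snp") {
      addr <- genomicToCodon(model, variant@pos)
      refCodon <- codonAt(model, addr@codonPosition)
      at <- addr@offsetInCodon + 1L
      if (substr(refCodon, at, at) != variant@refBase)
        stop(sprintf(
          "reference base mismatch at %d: model has %s, variant says %s",
          variant@pos, substr(refCodon, at, at), variant@refBase))
      altCodon <- refCodon
      substr(altCodon, at, at) <- variant@altBase
      refAa <- translateCodon(refCodon)
      altAa <- translateCodon(altCodon)
      cls <- if (refAa == altAa) "silent"
             else if (altAa == "X") "nonsense"
             else if (refAa == "X") stop("stop-loss variants are not supported")
             else "missense"
      codonChange <- list(codonPosition = addr@codonPosition,
                          refCodon = refCodon, altCodon = altCodon,
                          refAa = refAa, altAa = altAa)
    } else {
      len <- if (variant@kind == "insertion") nchar(variant@altBase)
             else nchar(variant@refBase)
      cls <- if (len %% 3L != 0L) "frameshift" else "in_frame_indel"
    }
  } else if (region$kind == "intron") {
    cls <- "intronic"
    dist <- min(variant@pos - (region$start - 1L),
                (region$end + 1L) - variant@pos)
    spliceProx <- dist <= spliceWindow
  } else {
    cls <- "utr"
  }
  new("MutationCharacterization",
      variant = variant, region = region, domain = domain,
      codonChange = codonChange, mutationClass = cls, keyExon = keyEx,
      spliceProximal = spliceProx, locusName = model@locusName,
      hlaClass = model@hlaClass)
}

#' @describeIn characterizeVariant Mutation-class label.
#' @param x A \code{MutationCharacterization}.
#' @export
setMethod("mutationClass", "MutationCharacterization", function(x) x@mutationClass)

#' @describeIn characterizeVariant Codon-change list (empty for non-coding).
#' @export
setMethod("codonChange", "MutationCharacterization", function(x) x@codonChange)

#' @describeIn characterizeVariant Key-exon flag.
#' @export
setMethod("keyExon", "MutationCharacterization", function(x) x@keyExon)

#' @describeIn characterizeVariant Splice-proximity flag.
#' @export
setMethod("spliceProximal", "MutationCharacterization", function(x) x@spliceProximal)

#' @describeIn characterizeVariant Protein-domain label.
#' @export
setMethod("proteinDomain", "MutationCharacterization", function(x) x@domain)

#' @describeIn characterizeVariant The underlying variant.
#' @export
setMethod("variantOf", "MutationCharacterization", function(x) x@variant)

setMethod("show", "MutationCharacterization", function(object) {
  cat(sprintf("MutationCharacterization (%s, %s)\n",
              object@locusName, object@mutationClass))
  r <- object@region
  cat(sprintf("  %s%s at genomic %d%s\n", r$kind,
              if (!is.na(r$index)) paste0(" ", r$index) else "",
              object@variant@pos,
              if (!is.na(object@domain)) paste0(" (", object@domain, ")") else ""))
  cc <- object@codonChange
  if (length(cc))
    cat(sprintf("  codon %d %s > %s (%s > %s)%s\n", cc$codonPosition,
                cc$refCodon, cc$altCodon, cc$refAa, cc$altAa,
                if (object@keyExon) " [key exon]" else ""))
  if (object@spliceProximal) cat("  splice-proximal intronic variant\n")
})

#' Render the written mutation description
#'
#' Returns the one-sentence description used when requesting an official
#' allele name, e.g. \code{"VGH002 has 1 nt change from B*48:01:01:01 at nt
#' 1701 where A > G (codon 228 ACT > GCT), resulting in a coding change 228
#' Thr is changed to Ala."}. Silent changes end \code{"with no coding
#' change"}; nonsense changes end \code{"is changed to a stop codon"}.
#' Positions are printed without thousands separators.
#'
#' @param sampleId Sample identifier.
#' @param baseAllele The most related catalogued allele.
#' @param char A \linkS4class{MutationCharacterization}.
#' @param nChanges Number of nucleotide changes the sentence reports
#'   (default 1).
#' @return The description sentence.
#' @export
describeMutation <- function(sampleId, baseAllele, char, nChanges = 1L) {
  v <- char@variant
  stem <- sprintf("%s has %d nt change%s from %s at nt %d where %s > %s",
                  sampleId, nChanges, if (nChanges == 1L) "" else "s",
                  baseAllele, v@pos, v@refBase, v@altBase)
  cc <- char@codonChange
  switch(char@mutationClass,
    missense = sprintf(
      "%s (codon %d %s > %s), resulting in a coding change %d %s is changed to %s.",
      stem, cc$codonPosition, cc$refCodon, cc$altCodon,
      cc$codonPosition, aaThree(cc$refAa), aaThree(cc$altAa)),
    silent = sprintf("%s (codon %d %s > %s), with no coding change.",
                     stem, cc$codonPosition, cc$refCodon, cc$altCodon),
    nonsense = sprintf(
      "%s (codon %d %s > %s), resulting in a coding change %d %s is changed to a stop codon.",
      stem, cc$codonPosition, cc$refCodon, cc$altCodon,
      cc$codonPosition, aaThree(cc$refAa)),
    intronic = sprintf("%s (intron %d), a non-coding change.",
                       stem, char@region$index),
    utr = sprintf("%s (untranslated region), a non-coding change.", stem),
    sprintf("%s (%s).", stem, char@mutationClass)
  )
}

#' Quality-control flags for a sample's novelties
#'
#' Flags the recognized indicators of suspect novelty calls:
#' \code{"multiple_exonic_novelties"} when more than one exonic novelty is
#' observed in a single sample (accepted samples are expected to carry
#' exactly one), and \code{"germline_confirmation_required"} when the sample
#' came from peripheral blood of a patient with a hematological malignancy
#' (circulating malignant cells can carry somatic mutations that produce
#' false novelties; typing must be confirmed on germline material such as a
#' buccal swab).
#'
#' @param chars List of \linkS4class{MutationCharacterization} for one
#'   sample.
#' @param specimen \code{"peripheral_blood"} or \code{"buccal"}.
#' @param hasHemeMalignancy Logical.
#' @return Character vector of flags (possibly empty).
#' @export
flagSuspect <- function(chars, specimen = c("peripheral_blood", "buccal"),
                        hasHemeMalignancy = FALSE) {
  specimen <- match.arg(specimen)
  nExonic <- sum(vapply(chars, function(ch) ch@region$kind == "exon",
                        logical(1)))
  flags <- character()
  if (nExonic > 1L) flags <- c(flags, "multiple_exonic_novelties")
  if (isTRUE(hasHemeMalignancy) && specimen == "peripheral_blood")
    flags <- c(flags, "germline_confirmation_required")
  flags
}

#' Read a pre-called variant table
#'
#' Tab-separated input with columns \code{sample_id}, \code{allele},
#' \code{pos}, \code{ref}, \code{alt}, \code{kind}.
#'
#' @param path File path.
#' @return \code{data.frame}; build variants row-wise with
#'   \code{\link{ObservedVariant}}.
#' @export
readVariantTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "allele", "pos", "ref", "alt", "kind")
  if (!all(need %in% names(df)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Tabulate characterizations in report form
#'
#' Mirrors the columns of a clinical novelty report: allele, mutation type,
#' exon, protein location, nucleotide change and genomic position, plus the
#' codon change when present.
#'
#' @param chars List of \linkS4class{MutationCharacterization}.
#' @param alleles Optional character vector of allele names (recycled).
#' @return \code{data.frame} with one row per characterization.
#' @export
characterizationTable <- function(chars, alleles = NA_character_) {
  alleles <- rep_len(alleles, length(chars))
  do.call(rbind, lapply(seq_along(chars), function(i) {
    ch <- chars[[i]]
    cc <- ch@codonChange
    data.frame(
      allele = alleles[i],
      locus = ch@locusName,
      mutation_class = ch@mutationClass,
      region_kind = ch@region$kind,
      exon = if (ch@region$kind == "exon") ch@region$index else NA_integer_,
      protein_domain = ch@domain,
      nucleotide_change = if (ch@variant@kind == "snp")
        sprintf("%s > %s", ch@variant@refBase, ch@variant@altBase)
      else ch@variant@kind,
      genomic_position = ch@variant@pos,
      codon_position = if (length(cc)) cc$codonPosition else NA_integer_,
      codon_change = if (length(cc))
        sprintf("%s > %s", cc$refCodon, cc$altCodon) else NA_character_,
      key_exon = ch@keyExon,
      splice_proximal = ch@spliceProximal
    )
  }))
}
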