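#' @import methods
#' @importClassesFrom Biostrings DNAString
NULL

.HLA_CLASSES <- c("class_I", "class_II_alpha", "class_II_beta")

.FEATURE_KINDS <- c("five_prime_UTR", "exon", "intron", "three_prime_UTR")

.PROTEIN_DOMAINS <- c(
  "leader_peptide",
  "antigen_binding_alpha1", "antigen_binding_alpha2",
  "antigen_binding_beta1",
  "extracellular_arm_alpha2", "extracellular_arm_alpha3",
  "extracellular_arm_beta2",
  "transmembrane", "cytoplasmic_tail", "transmembrane_cytoplasmic"
)

.MUTATION_CLASSES <- c(
  "missense", "silent", "nonsense", "frameshift",
  "in_frame_indel", "intronic", "utr"
)

.VARIANT_KINDS <- c("snp", "insertion", "deletion")

.PATIENT_CATEGORIES <- c(
  "solid_organ_patient", "solid_organ_donor",
  "hsct_patient", "hsct_donor", "disease_association"
)

.ETHNICITIES <- c("AFA", "API", "CAU", "HIS", "NAM", "unknown")

#' GeneModel: an annotated HLA-like gene
#'
#' An S4 container for a single HLA (or HLA-like synthetic) gene: its genomic
#' sequence, an ordered set of feature intervals (5'UTR, exons, introns,
#' 3'UTR) that partition the sequence exactly, the length of the
#' signal-peptide leader in codons, and a map from exon index to the protein
#' domain that exon encodes.
#'
#' Coordinates are 1-based and inclusive on both ends. Codon numbering is
#' mature-protein numbering: leader codons are numbered -L..-1, mature codons
#' 1..M, and there is no codon 0.
#'
#' @slot locusName Locus label, e.g. \code{"HLA-DPA1"}.
#' @slot hlaClass One of \code{"class_I"}, \code{"class_II_alpha"},
#'   \code{"class_II_beta"}.
#' @slot sequence A \link[Biostrings]{DNAString} with the genomic sequence.
#' @slot features A \code{data.frame} with columns \code{kind}, \code{index},
#'   \code{start}, \code{end}; intervals must partition the sequence.
#' @slot leaderLength Integer count of leader-peptide codons.
#' @slot domainMap Named character vector mapping exon index (as character)
#'   to a protein-domain label.
#' @slot fullCDS Logical; \code{TRUE} when the model covers the complete
#'   coding sequence (CDS length then divisible by 3).
#' @slot upstreamCDSBases Integer count of coding bases upstream of the
#'   covered region, for partial-coverage models (0 for full models); codon
#'   numbering is anchored on this offset.
#'
#' @seealso \code{\link{GeneModel}}, \code{\link{genomicToCodon}},
#'   \code{\link{locateRegion}}, \code{\link{domainOf}}
#' @exportClass GeneModel
setClass("GeneModel",
  slots = c(
    locusName = "character",
    hlaClass = "character",
    sequence = "DNAString",
    features = "data.frame",
    leaderLength = "integer",
    domainMap = "character",
    fullCDS = "logical",
    upstreamCDSBases = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@locusName) != 1L || !nzchar(object@locusName))
    msg <- c(msg, "locusName must be a single non-empty string")
  if (length(object@hlaClass) != 1L || !object@hlaClass %in% .HLA_CLASSES)
    msg <- c(msg, sprintf("hlaClass must be one of %s",
                          paste(.HLA_CLASSES, collapse = ", ")))
  ft <- object@features
  need <- c("kind", "index", "start", "end")
  if (!all(need %in% names(ft))) {
    msg <- c(msg, "features must have columns kind, index, start, end")
    return(if (length(msg)) msg else TRUE)
  }
  L <- length(object@sequence)
  if (nrow(ft) == 0L) {
    msg <- c(msg, "features must be non-empty")
    return(msg)
  }
  if (!all(ft$kind %in% .FEATURE_KINDS))
    msg <- c(msg, "unknown feature kind")
  if (any(ft$start > ft$end))
    msg <- c(msg, "feature start must be <= end")
  if (ft$start[1L] != 1L)
    msg <- c(msg, "first feature must start at position 1")
  if (ft$end[nrow(ft)] != L)
    msg <- c(msg, "last feature must end at the sequence length")
  if (nrow(ft) > 1L && !all(ft$start[-1L] == ft$end[-nrow(ft)] + 1L))
    msg <- c(msg, "features must be adjacent and non-overlapping (partition)")
  for (k in c("exon", "intron")) {
    idx <- ft$index[ft$kind == k]
    if (any(is.na(idx)))
      msg <- c(msg, sprintf("%s features must carry an index", k))
    else if (length(idx) > 1L && any(diff(idx) <= 0L))
      msg <- c(msg, sprintf("%s indices must strictly increase", k))
  }
  if (any(!is.na(ft$index[ft$kind %in% c("five_prime_UTR", "three_prime_UTR")])))
    msg <- c(msg, "UTR features must not carry an index")
  cdsLen <- sum(ft$end[ft$kind == "exon"] - ft$start[ft$kind == "exon"] + 1L)
  if (object@leaderLength < 0L)
    msg <- c(msg, "leaderLength must be >= 0")
  if (isTRUE(object@fullCDS)) {
    if (object@upstreamCDSBases != 0L)
      msg <- c(msg, "a full-CDS model cannot have upstream CDS bases")
    if (cdsLen %% 3L != 0L)
      msg <- c(msg, "CDS length of a full-CDS model must be divisible by 3")
    if (object@leaderLength * 3L > cdsLen)
      msg <- c(msg, "leader cannot be longer than the CDS")
  }
  exIdx <- ft$index[ft$kind == "exon"]
  if (!all(as.character(exIdx) %in% names(object@domainMap)))
    msg <- c(msg, "domainMap must cover every exon index")
  if (!all(object@domainMap %in% .PROTEIN_DOMAINS))
    msg <- c(msg, "domainMap labels must be protein-domain labels")
  if (length(msg)) msg else TRUE
})

#' ObservedVariant: one nucleotide difference against a reference
#'
#' @slot pos 1-based genomic position on the reference. For insertions this is
#'   the reference base immediately before the inserted material.
#' @slot refBase Reference base(s); for insertions the anchor base context is
#'   not stored, \code{refBase} is \code{""}.
#' @slot altBase Alternate base (snp), inserted string (insertion), or
#'   \code{""} (deletion).
#' @slot kind One of \code{"snp"}, \code{"insertion"}, \code{"deletion"}.
#' @exportClass ObservedVariant
setClass("ObservedVariant",
  slots = c(pos = "integer", refBase = "character",
            altBase = "character", kind = "character")
)

setValidity("ObservedVariant", function(object) {
  msg <- character()
  if (length(object@pos) != 1L || is.na(object@pos) || object@pos < 1L)
    msg <- c(msg, "pos must be a single positive integer")
  if (!object@kind %in% .VARIANT_KINDS)
    msg <- c(msg, "kind must be snp, insertion or deletion")
  if (object@kind == "snp") {
    if (!nzchar(object@refBase) || !nzchar(object@altBase))
      msg <- c(msg, "snp needs ref and alt bases")
    else if (object@refBase == object@altBase)
      msg <- c(msg, "snp ref and alt bases must differ")
  }
  if (object@kind == "insertion" && !nzchar(object@altBase))
    msg <- c(msg, "insertion needs a non-empty inserted string")
  if (object@kind == "deletion" && !nzchar(object@refBase))
    msg <- c(msg, "deletion needs the deleted reference string")
  if (length(msg)) msg else TRUE
})

#' CodonAddress: a codon in mature-protein numbering
#'
#' @slot codonPosition Signed codon number: leader codons -L..-1, mature
#'   codons 1..M; never 0.
#' @slot offsetInCodon 0, 1 or 2 - position of the queried base within the
#'   codon.
#' @slot rawIndex 1-based codon index counted from the first coding base,
#'   ignoring the leader split.
#' @exportClass CodonAddress
setClass("CodonAddress",
  slots = c(codonPosition = "integer", offsetInCodon = "integer",
            rawIndex = "integer")
)

setValidity("CodonAddress", function(object) {
  msg <- character()
  if (object@codonPosition == 0L)
    msg <- c(msg, "codonPosition 0 does not exist in mature-protein numbering")
  if (!object@offsetInCodon %in% 0:2)
    msg <- c(msg, "offsetInCodon must be 0, 1 or 2")
  if (object@rawIndex < 1L)
    msg <- c(msg, "rawIndex must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MutationCharacterization: the full annotation of one novelty
#'
#' The per-variant annotation a clinical report needs: containing feature
#' interval, protein domain, codon change (for exonic SNPs), mutation class,
#' key-exon status, and splice proximity for intronic variants.
#'
#' @slot variant The \linkS4class{ObservedVariant}.
#' @slot region One-row \code{data.frame} (kind, index, start, end) of the
#'   containing feature.
#' @slot domain Protein-domain label, or \code{NA} for non-exonic variants.
#' @slot codonChange Named list with \code{codonPosition}, \code{refCodon},
#'   \code{altCodon}, \code{refAa}, \code{altAa} (one-letter, stop = "X"), or
#'   an empty list for non-coding variants and indels.
#' @slot mutationClass One of missense, silent, nonsense, frameshift,
#'   in_frame_indel, intronic, utr.
#' @slot keyExon TRUE iff the variant lies in an antigen-binding ("key") exon:
#'   exons 2 and 3 for class I, exon 2 for class II.
#' @slot spliceProximal TRUE for intronic variants within the configured
#'   distance of an exon boundary.
#' @slot locusName Locus of the annotated model.
#' @slot hlaClass HLA class of the annotated model.
#' @exportClass MutationCharacterization
setClass("MutationCharacterization",
  slots = c(
    variant = "ObservedVariant",
    region = "data.frame",
    domain = "character",
    codonChange = "list",
    mutationClass = "character",
    keyExon = "logical",
    spliceProximal = "logical",
    locusName = "character",
    hlaClass = "character"
  )
)

setValidity("MutationCharacterization", function(object) {
  msg <- character()
  if (!object@mutationClass %in% .MUTATION_CLASSES)
    msg <- c(msg, "unknown mutation class")
  cc <- object@codonChange
  if (length(cc)) {
    need <- c("codonPosition", "refCodon", "altCodon", "refAa", "altAa")
    if (!all(need %in% names(cc)))
      msg <- c(msg, "codonChange must carry codonPosition/refCodon/altCodon/refAa/altAa")
    else {
      if (object@mutationClass == "silent" && cc$refAa != cc$altAa)
        msg <- c(msg, "silent requires identical amino acids")
      if (object@mutationClass == "missense" &&
          (cc$refAa == cc$altAa || cc$refAa == "X" || cc$altAa == "X"))
        msg <- c(msg, "missense requires a change between two non-stop residues")
      if (object@mutationClass == "nonsense" &&
          (cc$altAa != "X" || cc$refAa == "X"))
        msg <- c(msg, "nonsense requires a gained stop")
    }
  } else if (object@mutationClass %in% c("missense", "silent", "nonsense")) {
    msg <- c(msg, "coding SNP classes require a codonChange")
  }
  if (length(msg)) msg else TRUE
})

#' ImpactScore: the four-criterion "+" score of a missense novelty
#'
#' Each missense novelty receives one "+" per satisfied criterion: (1) the
#' mutation changes the amino acid (always true for missense), (2) the basic
#' physicochemical property category of the residue changes, (3) the change
#' lies in the antigen-binding site (a key exon), (4) the change disrupts an
#' expressed eplet or introduces a new one.
#'
#' @slot aaChange Logical, criterion 1.
#' @slot propertyChange Logical, criterion 2.
#' @slot bindingSite Logical, criterion 3.
#' @slot epletEffect Logical, criterion 4.
#' @slot total Integer 1..4, count of satisfied criteria.
#' @slot rendered The "+" string, \code{nchar(rendered) == total}.
#' @exportClass ImpactScore
setClass("ImpactScore",
  slots = c(aaChange = "logical", propertyChange = "logical",
            bindingSite = "logical", epletEffect = "logical",
            total = "integer", rendered = "character")
)

setValidity("ImpactScore", function(object) {
  msg <- character()
  tot <- sum(object@aaChange, object@propertyChange,
             object@bindingSite, object@epletEffect)
  if (!isTRUE(object@aaChange))
    msg <- c(msg, "a scored (missense) mutation always has aaChange TRUE")
  if (object@total != tot)
    msg <- c(msg, "total must equal the count of satisfied criteria")
  if (object@total < 1L || object@total > 4L)
    msg <- c(msg, "total must be in 1..4")
  if (object@rendered != strrep("+", object@total))
    msg <- c(msg, "rendered must be '+' repeated total times")
  if (length(msg)) msg else TRUE
})

#' SubmissionRecord: one sequence ready for repository submission
#'
#' @slot seqId Sequence identifier (the sample ID in the FASTA header).
#' @slot organism Organism tag, default \code{"Homo sapiens"}.
#' @slot description Free-text descriptor following the organism tag.
#' @slot sequence The submitted consensus as a \link[Biostrings]{DNAString}.
#' @slot features List of feature entries; each a list with \code{kind}
#'   (gene/mRNA/CDS), \code{intervals} (two-column integer matrix of 1-based
#'   inclusive start/end pairs) and \code{qualifiers} (named character).
#' @exportClass SubmissionRecord
setClass("SubmissionRecord",
  slots = c(seqId = "character", organism = "character",
            description = "character", sequence = "DNAString",
            features = "list")
)

setValidity("SubmissionRecord", function(object) {
  msg <- character()
  if (length(object@seqId) != 1L || !nzchar(object@seqId))
    msg <- c(msg, "seqId must be a single non-empty string")
  L <- length(object@sequence)
  kinds <- vapply(object@features, function(f) f$kind, character(1))
  if (!all(kinds %in% c("gene", "mRNA", "CDS")))
    msg <- c(msg, "feature kinds must be gene, mRNA or CDS")
  gene <- object@features[kinds == "gene"]
  if (length(gene) == 1L) {
    iv <- gene[[1L]]$intervals
    if (!(nrow(iv) == 1L && iv[1L, 1L] == 1L && iv[1L, 2L] == L))
      msg <- c(msg, "gene feature must span position 1 to the sequence length")
  }
  for (f in object@features) {
    iv <- f$intervals
    if (!is.matrix(iv) || ncol(iv) != 2L || any(iv[, 1L] > iv[, 2L]) ||
        any(iv < 1L) || any(iv > L))
      msg <- c(msg, sprintf("invalid intervals in %s feature", f$kind))
  }
  if (length(msg)) msg else TRUE
})

#' CohortSummary: tallies and rates over a cohort of characterized novelties
#'
#' Allele-level tallies (mutation class, locus, exon) are computed over unique
#' novel alleles; sample-level tallies (patient category, ethnicity) over
#' samples. Rates are per month of the observation window.
#'
#' @slot nSamples Number of samples carrying a novelty.
#' @slot nUniqueAlleles Number of distinct novel alleles.
#' @slot months Observation window in months.
#' @slot byMutationClass Named integer vector (unique alleles).
#' @slot byLocus Named integer vector (unique alleles).
#' @slot byExon Named integer vector of raw exon-index counts (unique alleles).
#' @slot byExonCategory Named integer vector over key_exon / exon1_leader /
#'   exon3_nonkey / exon4 / exon7 / other (unique alleles).
#' @slot byPatientCategory Named integer vector (samples).
#' @slot byEthnicityPct Named numeric vector of integer-rounded percentages
#'   (samples).
#' @slot rateSamplesPerMonth Samples per month, one decimal.
#' @slot rateUniquePerMonth Unique novelties per month, one decimal.
#' @slot pctClassIIAlpha Integer-rounded share of unique alleles in class II
#'   alpha-chain loci.
#' @exportClass CohortSummary
setClass("CohortSummary",
  slots = c(
    nSamples = "integer", nUniqueAlleles = "integer", months = "numeric",
    byMutationClass = "integer", byLocus = "integer", byExon = "integer",
    byExonCategory = "integer", byPatientCategory = "integer",
    byEthnicityPct = "numeric", rateSamplesPerMonth = "numeric",
    rateUniquePerMonth = "numeric", pctClassIIAlpha = "numeric"
  )
)

#' SimulationConfig: parameters of the synthetic gene-model generator
#'
#' @slot seed Integer seed; identical seeds give byte-identical output.
#' @slot nModels Number of models to generate.
#' @slot classMix Named proportions over the three HLA classes (sums to 1).
#' @slot exonLengthRange Inclusive range of exon coding lengths (nt).
#' @slot intronLengthRange Inclusive range of intron lengths (nt).
#' @slot utrLengthRange Inclusive range of UTR lengths (nt).
#' @slot leaderLengthRange Inclusive range of leader lengths (codons).
#' @slot mutationClassWeights Named proportions over missense / silent /
#'   nonsense / intronic used when drawing induced mutations.
#' @slot nSamples Cohort size for simulated cohorts.
#' @slot months Observation window for simulated cohorts.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    seed = "integer", nModels = "integer", classMix = "numeric",
    exonLengthRange = "integer", intronLengthRange = "integer",
    utrLengthRange = "integer", leaderLengthRange = "integer",
    mutationClassWeights = "numeric", nSamples = "integer", months = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (abs(sum(object@classMix) - 1) > 1e-8)
    msg <- c(msg, "classMix proportions must sum to 1")
  if (!all(names(object@classMix) %in% .HLA_CLASSES))
    msg <- c(msg, "classMix names must be HLA classes")
  if (abs(sum(object@mutationClassWeights) - 1) > 1e-8)
    msg <- c(msg, "mutationClassWeights must sum to 1")
  for (s in c("exonLengthRange", "intronLengthRange", "utrLengthRange",
              "leaderLengthRange")) {
    r <- slot(object, s)
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L)
      msg <- c(msg, sprintf("%s must be a non-empty positive range", s))
  }
  if (length(msg)) msg else TRUE
})
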