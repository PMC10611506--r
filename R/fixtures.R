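# Loaders for the bundled study tables: the 29 unique novel alleles, the 16
# missense scoring rows, and the reconstructed 41-sample cohort. Loaders
# validate row counts and internal consistency on every load.

.extdata <- function(file) {
  system.file("extdata", file, package = "novelHLA", mustWork = TRUE)
}

#' Bundled cohort tables
#'
#' \code{novelAlleleTable} returns the 29 unique novel alleles of the bundled
#' 18-month detection cohort (locus, HLA class, mutation type, exon, protein
#' location, nucleotide change, genomic position, codon change).
#' \code{missenseScoreTable} returns its 16 missense rows with residues,
#' property categories and the assigned "+" scores.
#' \code{cohortSamples} returns the reconstructed 41-row sample table
#' (sample, allele, patient category, ethnicity, specimen).
#' \code{bundledCohort} joins samples with allele-level annotation into the
#' layout \code{\link{summarizeCohort}} expects.
#'
#' Loaders validate the expected row counts (29/16/41) and, for the allele
#' table, that each codon change is a single-base change matching the
#' reported nucleotide change.
#'
#' @return A \code{data.frame}.
#' @examples
#' nrow(novelAlleleTable())  # 29
#' @export
novelAlleleTable <- function() {
  df <- utils::read.delim(.extdata("novel_alleles.tsv"), comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) != 29L)
    stop("novel-allele table must have 29 rows, found ", nrow(df))
  for (i in seq_len(nrow(df))) {
    rc <- strsplit(df$ref_codon[i], "")[[1L]]
    ac <- strsplit(df$alt_codon[i], "")[[1L]]
    diff <- which(rc != ac)
    if (length(diff) != 1L || rc[diff] != df$ref_base[i] ||
        ac[diff] != df$alt_base[i])
      stop("inconsistent codon change for ", df$allele[i])
  }
  df
}

#' @rdname novelAlleleTable
#' @export
missenseScoreTable <- function() {
  df <- utils::read.delim(.extdata("missense_scores.tsv"), comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) != 16L)
    stop("missense score table must have 16 rows, found ", nrow(df))
  if (!all(nchar(df$score) ==
           df$aa_change + df$property_change + df$binding_site + df$eplet_effect))
    stop("score string inconsistent with its criteria")
  df
}

#' @rdname novelAlleleTable
#' @export
cohortSamples <- function() {
  df <- utils::read.delim(.extdata("cohort_samples.tsv"), comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) != 41L)
    stop("cohort sample table must have 41 rows, found ", nrow(df))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in cohort sample table")
  df
}

#' @rdname novelAlleleTable
#' @export
bundledCohort <- function() {
  samples <- cohortSamples()
  alleles <- novelAlleleTable()
  merged <- merge(samples,
                  alleles[, c("allele", "locus", "hla_class", "mutation_type",
                              "exon")],
                  by = "allele", all.x = TRUE, sort = FALSE)
  if (anyNA(merged$locus))
    stop("cohort sample table references unknown allele(s)")
  merged$mutation_class <- merged$mutation_type
  merged[order(merged$sample_id),
         c("sample_id", "allele", "locus", "hla_class", "mutation_class",
           "exon", "patient_category", "ethnicity", "specimen")]
}

#' Characterize novelties from the bundled allele table
#'
#' Rebuilds \linkS4class{MutationCharacterization} objects from the allele
#' table's codon-change fields, classifying each through the same
#' translation-based classifier the sequence pipeline uses (the mutation
#' class is computed, not copied from the table).
#'
#' @param df Allele table in the layout of \code{\link{novelAlleleTable}}
#'   (default: the bundled table).
#' @return Named list of \linkS4class{MutationCharacterization} (names are
#'   allele names).
#' @examples
#' chars <- characterizeFromTable()
#' mutationClass(chars[["DPA1*01:137N"]])  # "nonsense"
#' @export
characterizeFromTable <- function(df = novelAlleleTable()) {
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    refAa <- translateCodon(row$ref_codon)
    altAa <- translateCodon(row$alt_codon)
    cls <- if (refAa == altAa) "silent"
           else if (altAa == "X") "nonsense"
           else "missense"
    keyEx <- (row$hla_class == "class_I" && row$exon %in% c(2L, 3L)) ||
      (row$hla_class != "class_I" && row$exon == 2L)
    new("MutationCharacterization",
        variant = ObservedVariant(row$genomic_position, row$ref_base,
                                  row$alt_base, "snp"),
        region = data.frame(kind = "exon", index = as.integer(row$exon),
                            start = NA_integer_, end = NA_integer_),
        domain = unname(defaultDomainMap(row$hla_class)[as.character(row$exon)]),
        codonChange = list(codonPosition = as.integer(row$codon_position),
                           refCodon = row$ref_codon, altCodon = row$alt_codon,
                           refAa = refAa, altAa = altAa),
        mutationClass = cls, keyExon = keyEx, spliceProximal = FALSE,
        locusName = row$locus, hlaClass = row$hla_class)
  })
  names(out) <- df$allele
  out
}

#' Score the bundled missense novelties
#'
#' Recomputes the four-criterion "+" score for every row of the bundled
#' missense table against the packaged property table and eplet registry,
#' using the allele table for the key-exon rule.
#'
#' @return \code{data.frame} with the allele, the recomputed criteria and
#'   total, and the rendered "+" string.
#' @examples
#' scored <- scoreBundledMissense()
#' scored$rendered[scored$allele == "B*56:88"]  # "++++"
#' @export
scoreBundledMissense <- function() {
  scores <- missenseScoreTable()
  chars <- characterizeFromTable()
  table <- defaultPropertyTable()
  registry <- bundledEpletRegistry()
  do.call(rbind, lapply(seq_len(nrow(scores)), function(i) {
    ch <- chars[[scores$allele[i]]]
    s <- scoreImpact(ch, table = table, registry = registry)
    data.frame(allele = scores$allele[i],
               aa_change = s@aaChange, property_change = s@propertyChange,
               binding_site = s@bindingSite, eplet_effect = s@epletEffect,
               total = s@total, rendered = s@rendered)
  }))
}
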