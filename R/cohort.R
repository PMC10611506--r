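# Cohort summarization: tallies by mutation class, locus and exon category
# over unique novel alleles, patient-category and ethnicity tallies over
# samples, and per-month detection rates.
#
# The two tally bases differ deliberately: allele-level questions (what kinds
# of mutation were found?) deduplicate related samples carrying the same
# novelty, while demographic questions (who carried them?) count samples.

#' Exon category of a characterized novelty
#'
#' Buckets an exonic novelty the way detection cohorts are reported:
#' \code{key_exon} when the key-exon rule holds (exons 2/3 for class I, exon
#' 2 for class II), otherwise \code{exon1_leader}, \code{exon3_nonkey},
#' \code{exon4} or \code{exon7} by exon index; anything else (including
#' intronic/UTR input) is \code{other}.
#'
#' @param exon Integer exon index (NA for non-exonic).
#' @param hlaClass HLA class label. Vectorized over both arguments.
#' @return Character vector of categories.
#' @examples
#' exonCategory(3L, "class_I")         # "key_exon"
#' exonCategory(3L, "class_II_alpha")  # "exon3_nonkey"
#' @export
exonCategory <- function(exon, hlaClass) {
  n <- max(length(exon), length(hlaClass))
  exon <- rep_len(as.integer(exon), n)
  hlaClass <- rep_len(hlaClass, n)
  key <- (hlaClass == "class_I" & exon %in% c(2L, 3L)) |
         (hlaClass != "class_I" & exon == 2L)
  out <- rep("other", n)
  out[!is.na(exon) & exon == 1L] <- "exon1_leader"
  out[!is.na(exon) & exon == 3L] <- "exon3_nonkey"
  out[!is.na(exon) & exon == 4L] <- "exon4"
  out[!is.na(exon) & exon == 7L] <- "exon7"
  out[!is.na(key) & key] <- "key_exon"
  out
}

.countBy <- function(values, levels = NULL) {
  tab <- table(values)
  out <- stats::setNames(as.integer(tab), names(tab))
  if (!is.null(levels)) {
    full <- stats::setNames(integer(length(levels)), levels)
    full[names(out)] <- out
    out <- full[order(-full)]
  } else {
    out <- out[order(-out)]
  }
  out
}

#' Summarize a cohort of characterized novelties
#'
#' @param cohort \code{data.frame} with one row per sample:
#'   \code{sample_id}, \code{allele}, \code{locus}, \code{hla_class},
#'   \code{mutation_class}, \code{exon} (NA for non-exonic),
#'   \code{patient_category}, \code{ethnicity}. \code{\link{bundledCohort}}
#'   returns this layout.
#' @param months Observation window in months (> 0).
#' @return A \linkS4class{CohortSummary}. Rates are rounded to one decimal
#'   (round-half-even), percentages to integers.
#' @examples
#' summarizeCohort(bundledCohort(), months = 18)
#' @export
summarizeCohort <- function(cohort, months) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("empty cohort")
  if (!is.numeric(months) || months <= 0)
    stop("months must be > 0")
  need <- c("sample_id", "allele", "locus", "hla_class", "mutation_class",
            "exon", "patient_category", "ethnicity")
  if (!all(need %in% names(cohort)))
    stop("cohort is missing column(s): ",
         paste(setdiff(need, names(cohort)), collapse = ", "))
  if (anyDuplicated(cohort$sample_id))
    stop("sample_id must be unique within a cohort")
  alleles <- cohort[!duplicated(cohort$allele), , drop = FALSE]
  nS <- nrow(cohort)
  nU <- nrow(alleles)
  ethTab <- .countBy(cohort$ethnicity)
  ethPct <- round(100 * ethTab / nS)
  iiAlpha <- sum(alleles$hla_class == "class_II_alpha")
  new("CohortSummary",
    nSamples = nS, nUniqueAlleles = nU, months = months,
    byMutationClass = .countBy(alleles$mutation_class),
    byLocus = .countBy(alleles$locus),
    byExon = .countBy(paste0("exon", alleles$exon)[!is.na(alleles$exon)]),
    byExonCategory = .countBy(exonCategory(alleles$exon, alleles$hla_class)),
    byPatientCategory = .countBy(cohort$patient_category),
    byEthnicityPct = ethPct,
    rateSamplesPerMonth = round(nS / months, 1L),
    rateUniquePerMonth = round(nU / months, 1L),
    pctClassIIAlpha = round(100 * iiAlpha / nU)
  )
}

#' @describeIn summarizeCohort Number of samples.
#' @param x A \code{CohortSummary}.
#' @export
setMethod("nSamples", "CohortSummary", function(x) x@nSamples)

#' @describeIn summarizeCohort Number of unique novel alleles.
#' @export
setMethod("nUniqueAlleles", "CohortSummary", function(x) x@nUniqueAlleles)

#' @describeIn summarizeCohort Named counts (or percentages) by
#'   \code{"mutationClass"}, \code{"locus"}, \code{"exon"},
#'   \code{"exonCategory"}, \code{"patientCategory"} or
#'   \code{"ethnicityPct"}.
#' @param what Which tally to return.
#' @export
setMethod("countsBy", "CohortSummary", function(x, what) {
  switch(what,
    mutationClass = x@byMutationClass,
    locus = x@byLocus,
    exon = x@byExon,
    exonCategory = x@byExonCategory,
    patientCategory = x@byPatientCategory,
    ethnicityPct = x@byEthnicityPct,
    stop("unknown tally: ", what))
})

#' @describeIn summarizeCohort Unique novelties per month (one decimal).
#' @export
setMethod("rateUniquePerMonth", "CohortSummary", function(x) x@rateUniquePerMonth)

#' @describeIn summarizeCohort Samples per month (one decimal).
#' @export
setMethod("rateSamplesPerMonth", "CohortSummary", function(x) x@rateSamplesPerMonth)

#' @describeIn summarizeCohort Percentage of unique alleles in class II
#'   alpha-chain loci.
#' @export
setMethod("pctClassIIAlpha", "CohortSummary", function(x) x@pctClassIIAlpha)

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary: %d samples, %d unique novel alleles over %.3g months\n",
              object@nSamples, object@nUniqueAlleles, object@months))
  cat(sprintf("  rates: %.1f samples/month, %.1f unique novelties/month\n",
              object@rateSamplesPerMonth, object@rateUniquePerMonth))
  fmt <- function(v) paste(sprintf("%s %g", names(v), as.numeric(v)), collapse = ", ")
  cat("  mutation classes (alleles): ", fmt(object@byMutationClass), "\n", sep = "")
  cat("  loci (alleles): ", fmt(object@byLocus), "\n", sep = "")
  cat("  exon categories (alleles): ", fmt(object@byExonCategory), "\n", sep = "")
  cat(sprintf("  class II alpha share: %d%%\n", as.integer(object@pctClassIIAlpha)))
  cat("  patient categories (samples): ", fmt(object@byPatientCategory), "\n", sep = "")
  cat("  ethnicity (% of samples): ", fmt(object@byEthnicityPct), "\n", sep = "")
})
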