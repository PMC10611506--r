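# The four-criterion "+" impact score for missense novelties, with pluggable
# amino-acid property and eplet-registry data.

.AA_CATEGORIES <- c("nonpolar_aliphatic", "nonpolar_aromatic",
                    "polar_uncharged", "basic", "acidic")

#' Amino-acid basic-property table
#'
#' \code{defaultPropertyTable} returns the packaged five-category
#' classification of the 20 standard residues by polarity and charge
#' (nonpolar aliphatic, nonpolar aromatic, polar uncharged, basic, acidic).
#' \code{readPropertyTable} loads a user-supplied two-column
#' (residue, category) tab-separated file in the same form.
#'
#' @param path File path (for \code{readPropertyTable}).
#' @return Named character vector: three-letter residue -> category.
#' @examples
#' defaultPropertyTable()[["Lys"]]  # "basic"
#' @export
defaultPropertyTable <- function() {
  readPropertyTable(system.file("extdata", "aa_properties.tsv",
                                package = "novelHLA", mustWork = TRUE))
}

#' @rdname defaultPropertyTable
#' @export
readPropertyTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "category") %in% names(df)))
    stop("property table must have columns residue, category")
  tab <- stats::setNames(df$category, df$residue)
  missing <- setdiff(unname(.AA_THREE[names(.AA_THREE) != "X"]), names(tab))
  if (length(missing))
    stop("property table must cover all 20 standard residues; missing: ",
         paste(missing, collapse = ", "))
  if (!all(tab %in% .AA_CATEGORIES))
    stop("unknown property category: ",
         paste(setdiff(tab, .AA_CATEGORIES), collapse = ", "))
  tab
}

#' Basic-property category of a residue
#'
#' @param table Property table from \code{\link{defaultPropertyTable}} or
#'   \code{\link{readPropertyTable}}.
#' @param aa Residue, one- or three-letter.
#' @return Category label.
#' @examples
#' propertyCategory(defaultPropertyTable(), "Phe")  # "nonpolar_aromatic"
#' @export
propertyCategory <- function(table, aa) {
  if (any(aa %in% c("X", "Ter")))
    stop("a stop codon has no property category (not scorable)")
  key <- ifelse(nchar(aa) == 1L, aaThree(aa), aa)
  out <- unname(table[key])
  if (anyNA(out))
    stop("residue not in property table: ", paste(aa[is.na(out)], collapse = ", "))
  out
}

#' Did the basic property category change?
#'
#' Compared at the five-subcategory level: an aliphatic-to-aromatic change
#' within the nonpolar group counts as a property change.
#'
#' @inheritParams propertyCategory
#' @param refAa,altAa Original and novel residues.
#' @return Logical.
#' @examples
#' propertyChanged(defaultPropertyTable(), "Leu", "Phe")  # TRUE
#' propertyChanged(defaultPropertyTable(), "Arg", "His")  # FALSE
#' @export
propertyChanged <- function(table, refAa, altAa) {
  propertyCategory(table, refAa) != propertyCategory(table, altAa)
}

#' Eplet registries
#'
#' An eplet is a small patch of polymorphic residues (within roughly a
#' 3.0-3.5 Angstrom radius) forming an antibody-accessible HLA epitope. A
#' registry file has tab-separated columns \code{name}, \code{locus_group}
#' and \code{constituents}, the latter a comma-separated list of
#' \code{position:residue} tokens in mature-protein numbering (one-letter
#' residues). \code{bundledEpletRegistry} loads the packaged miniature
#' registry: a synthetic stand-in covering the eplet-positive positions of
#' the bundled cohort plus decoys, NOT a copy of the HLA Eplet Registry
#' (production use should supply a real registry file).
#'
#' @param path Registry file path.
#' @return \code{data.frame} with one row per constituent: \code{name},
#'   \code{locus_group}, \code{position}, \code{residue}.
#' @export
readEpletRegistry <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "locus_group", "constituents") %in% names(df)))
    stop("eplet registry must have columns name, locus_group, constituents")
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    toks <- strsplit(df$constituents[i], ",", fixed = TRUE)[[1L]]
    parts <- strsplit(trimws(toks), ":", fixed = TRUE)
    if (!length(parts)) stop("eplet ", df$name[i], " has no constituents")
    data.frame(name = df$name[i], locus_group = df$locus_group[i],
               position = as.integer(vapply(parts, `[`, "", 1L)),
               residue = vapply(parts, `[`, "", 2L))
  }))
  if (anyNA(out$position) || any(!nzchar(out$residue)))
    stop("malformed position:residue token in eplet registry")
  out
}

#' @rdname readEpletRegistry
#' @export
bundledEpletRegistry <- function() {
  readEpletRegistry(system.file("extdata", "eplet_registry.tsv",
                                package = "novelHLA", mustWork = TRUE))
}

#' Does a mutation affect an eplet?
#'
#' TRUE when the mutated position with the original residue is a constituent
#' of a registered eplet (the mutation disrupts an eplet expressed by the
#' original allele), or the position with the novel residue is (the mutation
#' introduces a new eplet). When \code{group} is given, only eplets of that
#' locus group are considered; otherwise the whole registry is searched.
#'
#' @param registry Registry \code{data.frame} from
#'   \code{\link{readEpletRegistry}}.
#' @param position Mature-protein position.
#' @param refAa,altAa Original and novel residues (one- or three-letter).
#' @param group Optional locus group (\code{"ABC"}, \code{"DRB"},
#'   \code{"DQ"}, \code{"DP"}).
#' @return Logical; FALSE for an empty registry.
#' @export
affectsEplet <- function(registry, position, refAa, altAa, group = NULL) {
  if (is.null(registry) || nrow(registry) == 0L) return(FALSE)
  if (!is.null(group) && !is.na(group))
    registry <- registry[registry$locus_group == group, , drop = FALSE]
  res <- c(aaOne(refAa), aaOne(altAa))
  any(registry$position == position & registry$residue %in% res)
}

#' Score a missense novelty with the four-criterion "+" score
#'
#' Each satisfied criterion contributes one "+": (1) amino-acid change -
#' satisfied by every missense mutation, so every score has at least one "+";
#' (2) change in the residue's basic property category (five-subcategory
#' comparison); (3) the change lies in the antigen-binding site, keyed on the
#' key-exon rule (exons 2/3 class I, exon 2 class II); (4) the change
#' disrupts or introduces a registered eplet at the mutated position. The
#' maximum is "++++". Non-missense mutations are reported but not scored.
#'
#' @param char A missense \linkS4class{MutationCharacterization}.
#' @param table Property table (default the packaged one).
#' @param registry Eplet registry \code{data.frame} (default none: the eplet
#'   criterion is then FALSE).
#' @param group Locus group used to filter the registry; defaults to the
#'   characterization's locus.
#' @return An \linkS4class{ImpactScore}.
#' @examples
#' m <- exampleGeneModel("B")
#' ch <- characterizeVariant(m, ObservedVariant(1701L, "A", "G"))
#' scoreImpact(ch)  # Thr228Ala: "++"
#' @export
scoreImpact <- function(char, table = defaultPropertyTable(),
                        registry = NULL, group = locusGroup(char@locusName)) {
  if (char@mutationClass != "missense")
    stop("only missense mutations are '+'-scored (got ",
         char@mutationClass, ")")
  cc <- char@codonChange
  prop <- propertyChanged(table, cc$refAa, cc$altAa)
  epl <- if (is.null(registry)) FALSE
         else affectsEplet(registry, cc$codonPosition, cc$refAa, cc$altAa,
                           group = group)
  total <- 1L + prop + char@keyExon + epl
  new("ImpactScore", aaChange = TRUE, propertyChange = prop,
      bindingSite = char@keyExon, epletEffect = epl,
      total = as.integer(total), rendered = strrep("+", total))
}

#' @describeIn scoreImpact Numeric total (1..4).
#' @param x An \code{ImpactScore}.
#' @export
setMethod("scoreTotal", "ImpactScore", function(x) x@total)

#' @describeIn scoreImpact The rendered "+" string.
#' @export
setMethod("scoreRendered", "ImpactScore", function(x) x@rendered)

#' @describeIn scoreImpact Named logical vector of the four criteria.
#' @export
setMethod("scoreCriteria", "ImpactScore", function(x) {
  c(aa_change = x@aaChange, property_change = x@propertyChange,
    binding_site = x@bindingSite, eplet_effect = x@epletEffect)
})

setMethod("show", "ImpactScore", function(object) {
  crit <- scoreCriteria(object)
  cat(sprintf("ImpactScore %s (%d/4): %s\n", object@rendered, object@total,
              paste(names(crit)[crit], collapse = ", ")))
})
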