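# Amino-acid naming helpers and codon translation.
#
# Residues travel through the package as one-letter codes with "X" as the
# stop sentinel (the rendering used in clinical alignment figures); reports
# and the property table use three-letter names.

.AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  X = "Ter"
)

#' Convert between one- and three-letter amino-acid codes
#'
#' The stop sentinel "X" maps to "Ter".
#'
#' @param aa Character vector of residues.
#' @return Character vector of the converted codes.
#' @examples
#' aaThree("R")   # "Arg"
#' aaOne("Thr")   # "T"
#' @export
aaThree <- function(aa) {
  out <- unname(.AA_THREE[aa])
  if (anyNA(out)) stop("unknown one-letter amino-acid code: ",
                       paste(aa[is.na(out)], collapse = ", "))
  out
}

#' @rdname aaThree
#' @export
aaOne <- function(aa) {
  if (all(aa %in% names(.AA_THREE))) return(aa)
  rev_map <- stats::setNames(names(.AA_THREE), .AA_THREE)
  out <- unname(rev_map[aa])
  if (anyNA(out)) stop("unknown amino-acid code: ",
                       paste(aa[is.na(out)], collapse = ", "))
  out
}

#' Translate a codon under the standard genetic code
#'
#' Stop codons are rendered as the sentinel \code{"X"}, matching the
#' convention used in allele alignment figures (e.g. an Arg-to-stop nonsense
#' change reads R > X).
#'
#' @param triplet A nucleotide triplet over \{A,C,G,T\} (vectorized).
#' @return One-letter amino-acid code(s), \code{"X"} for stop.
#' @examples
#' translateCodon("CGA")  # "R" (Arg)
#' translateCodon("TGA")  # "X" (stop)
#' @export
translateCodon <- function(triplet) {
  triplet <- toupper(triplet)
  if (any(nchar(triplet) != 3L))
    stop("a codon must be exactly 3 nucleotides")
  if (any(grepl("[^ACGT]", triplet)))
    stop("unsupported base in codon (alphabet is A, C, G, T)")
  aa <- unname(Biostrings::GENETIC_CODE[triplet])
  aa[aa == "*"] <- "X"
  aa
}

# locus -> eplet locus group (the grouping the eplet registry is organised by)
.LOCUS_GROUPS <- c(
  "HLA-A" = "ABC", "HLA-B" = "ABC", "HLA-C" = "ABC",
  "HLA-DRB1" = "DRB", "HLA-DRB3" = "DRB", "HLA-DRB4" = "DRB",
  "HLA-DRB5" = "DRB",
  "HLA-DQA1" = "DQ", "HLA-DQB1" = "DQ",
  "HLA-DPA1" = "DP", "HLA-DPB1" = "DP"
)

#' Eplet locus group of an HLA locus
#'
#' Maps a locus (or allele name) to the locus group eplet registries are
#' organised by: "ABC" (class I), "DRB", "DQ", "DP".
#'
#' @param locus Locus name such as \code{"HLA-DPA1"}, \code{"DPA1"}, or an
#'   allele name such as \code{"DPA1*01:03"}.
#' @return Character locus-group label, \code{NA} if unknown.
#' @export
locusGroup <- function(locus) {
  base <- sub("\\*.*$", "", locus)
  base <- ifelse(grepl("^HLA-", base), base, paste0("HLA-", base))
  unname(.LOCUS_GROUPS[base])
}
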