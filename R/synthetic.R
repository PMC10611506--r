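# Synthetic gene models and induced mutations of controlled class, so every
# other module is testable with no external reference data.
#
# Generated models are structurally realistic (exon counts pinned by the HLA
# class's domain map, an open reading frame free of internal stops, a leader
# within the covered CDS) but carry no real HLA polymorphism or haplotype
# structure.

#' Construct a SimulationConfig
#'
#' Defaults mirror the composition of the bundled detection cohort: the class
#' mix follows its unique-allele split across HLA classes (class II alpha
#' dominating), the mutation-class weights its 16/12/1 missense/silent/
#' nonsense split, and leader lengths span the range of the study loci
#' (23-31 codons).
#'
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @param nModels Number of models.
#' @param classMix Named proportions over the three HLA classes.
#' @param exonLengthRange,intronLengthRange,utrLengthRange Inclusive length
#'   ranges in nucleotides.
#' @param leaderLengthRange Inclusive leader range in codons.
#' @param mutationClassWeights Named proportions over missense, silent,
#'   nonsense, intronic.
#' @param nSamples,months Cohort-scale parameters for simulated cohorts.
#' @return A \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(seed = 1L, nModels = 10L,
                             classMix = c(class_I = 9, class_II_alpha = 15,
                                          class_II_beta = 5) / 29,
                             exonLengthRange = c(90L, 300L),
                             intronLengthRange = c(60L, 400L),
                             utrLengthRange = c(30L, 120L),
                             leaderLengthRange = c(23L, 31L),
                             mutationClassWeights = c(missense = 16, silent = 12,
                                                      nonsense = 1, intronic = 0) / 29,
                             nSamples = 41L, months = 18) {
  new("SimulationConfig", seed = as.integer(seed), nModels = as.integer(nModels),
      classMix = classMix, exonLengthRange = as.integer(exonLengthRange),
      intronLengthRange = as.integer(intronLengthRange),
      utrLengthRange = as.integer(utrLengthRange),
      leaderLengthRange = as.integer(leaderLengthRange),
      mutationClassWeights = mutationClassWeights,
      nSamples = as.integer(nSamples), months = months)
}

.N_EXONS <- c(class_I = 7L, class_II_alpha = 4L, class_II_beta = 5L)

.sampleRange <- function(r) sample(seq.int(r[1L], r[2L]), 1L)

#' Generate a synthetic gene model
#'
#' Deterministic in \code{(config@seed, index)}. The HLA class is drawn from
#' \code{classMix}; the exon count is then fixed by the class's domain map (7
#' for class I, 4 for class II alpha, 5 for class II beta). Exon, intron and
#' UTR lengths are drawn from the configured ranges, the total CDS is padded
#' to a multiple of 3, the CDS is sampled codon-wise from the 61 non-stop
#' codons (an open reading frame with no internal stop), and the leader is
#' drawn from \code{leaderLengthRange}, capped below the CDS length.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param index Model index (0-based offsets from the seed).
#' @return A \linkS4class{GeneModel} satisfying all model invariants.
#' @examples
#' m <- makeGeneModel(SimulationConfig(seed = 7L), 0L)
#' @export
makeGeneModel <- function(config, index = 0L) {
  validObject(config)
  .withSeed(config@seed * 1000L + as.integer(index), {
    cls <- sample(names(config@classMix), 1L, prob = config@classMix)
    nEx <- .N_EXONS[[cls]]
    exLens <- vapply(seq_len(nEx), function(i) .sampleRange(config@exonLengthRange),
                     integer(1))
    pad <- (3L - sum(exLens) %% 3L) %% 3L
    exLens[nEx] <- exLens[nEx] + pad
    nCodon <- sum(exLens) %/% 3L
    leader <- min(.sampleRange(config@leaderLengthRange), nCodon - 1L)
    inLens <- vapply(seq_len(nEx - 1L), function(i) .sampleRange(config@intronLengthRange),
                     integer(1))
    utr5 <- .sampleRange(config@utrLengthRange)
    utr3 <- .sampleRange(config@utrLengthRange)
    kinds <- c("five_prime_UTR",
               as.vector(rbind(rep("exon", nEx - 1L), rep("intron", nEx - 1L))),
               "exon", "three_prime_UTR")
    lens <- c(utr5, as.vector(rbind(exLens[-nEx], inLens)), exLens[nEx], utr3)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    idx <- rep(NA_integer_, length(kinds))
    idx[kinds == "exon"] <- seq_len(nEx)
    idx[kinds == "intron"] <- seq_len(nEx - 1L)
    features <- data.frame(kind = kinds, index = idx, start = starts, end = ends)
    codons <- .randomCodons(nCodon)
    seqc <- .assembleGenomic(features, codons)
    GeneModel(sprintf("SYN-%s-%d", toupper(cls), index), cls, seqc, features,
              leaderLength = leader)
  })
}

# substitutions of a codon reaching the requested class, as (offset, alt) rows
.classReachingSubs <- function(codon, targetClass) {
  refAa <- translateCodon(codon)
  if (refAa == "X") return(NULL)
  out <- NULL
  for (at in 1:3) {
    ref <- substr(codon, at, at)
    for (b in setdiff(c("A", "C", "G", "T"), ref)) {
      alt <- codon
      substr(alt, at, at) <- b
      altAa <- translateCodon(alt)
      ok <- switch(targetClass,
        silent = altAa == refAa,
        missense = altAa != refAa && altAa != "X",
        nonsense = altAa == "X")
      if (ok) out <- rbind(out, data.frame(offset = at - 1L, ref = ref,
                                           alt = b, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Induce a single mutation of a requested class
#'
#' Draws a random single-nucleotide change of the requested class
#' (\code{missense}, \code{silent}, \code{nonsense} or \code{intronic}) into
#' the model's sequence and returns the mutated consensus together with the
#' truth record the characterization pipeline must recover. Nonsense
#' induction searches codons reachable to TAA/TAG/TGA by one substitution,
#' in an order randomized under the caller's RNG state; an unreachable class
#' raises an error after a bounded search.
#'
#' @param model A \linkS4class{GeneModel}.
#' @param targetClass Requested mutation class.
#' @param maxTries Codon draws before giving up.
#' @return List with \code{consensus} (character), \code{variant}
#'   (\linkS4class{ObservedVariant}) and \code{truth} (list with
#'   \code{class}, and for coding classes \code{codonPosition},
#'   \code{refCodon}, \code{altCodon}, \code{refAa}, \code{altAa},
#'   \code{exonIndex}).
#' @examples
#' set.seed(1)
#' draw <- induceMutation(makeGeneModel(SimulationConfig(), 0L), "nonsense")
#' draw$truth$altAa  # "X"
#' @export
induceMutation <- function(model, targetClass = c("missense", "silent",
                                                  "nonsense", "intronic"),
                           maxTries = 500L) {
  targetClass <- match.arg(targetClass)
  seqc <- as.character(model@sequence)
  if (targetClass == "intronic") {
    introns <- model@features[model@features$kind == "intron", , drop = FALSE]
    if (nrow(introns) == 0L) stop("model has no introns")
    i <- sample(nrow(introns), 1L)
    pos <- sample(seq.int(introns$start[i], introns$end[i]), 1L)
    ref <- substr(seqc, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    substr(seqc, pos, pos) <- alt
    return(list(consensus = seqc,
                variant = ObservedVariant(pos, ref, alt, "snp"),
                truth = list(class = "intronic", intronIndex = introns$index[i])))
  }
  ex <- model@features[model@features$kind == "exon", , drop = FALSE]
  nCodon <- sum(ex$end - ex$start + 1L) %/% 3L
  for (try in seq_len(maxTries)) {
    raw <- sample(nCodon, 1L)
    mature <- .rawToMature(raw, model@leaderLength)
    codon <- codonAt(model, mature)
    subs <- .classReachingSubs(codon, targetClass)
    if (is.null(subs)) next
    pick <- subs[sample(nrow(subs), 1L), ]
    span <- codonSpan(model, mature)
    pos <- span[pick$offset + 1L]
    substr(seqc, pos, pos) <- pick$alt
    alt <- codon
    substr(alt, pick$offset + 1L, pick$offset + 1L) <- pick$alt
    exonIndex <- locateRegion(model, pos)$index
    return(list(
      consensus = seqc,
      variant = ObservedVariant(pos, pick$ref, pick$alt, "snp"),
      truth = list(class = targetClass, codonPosition = mature,
                   refCodon = codon, altCodon = alt,
                   refAa = translateCodon(codon), altAa = translateCodon(alt),
                   exonIndex = exonIndex)))
  }
  stop(sprintf("could not induce a %s mutation in %d tries (unreachable class)",
               targetClass, maxTries))
}
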