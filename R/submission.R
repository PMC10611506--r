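# Submission artifacts: the combined FASTA file, the per-sequence
# five-column feature table, and the sidecar manifest. The feature-table
# dialect is the standard tab-delimited layout: each feature opens with
# "start TAB end TAB kind", continuation intervals carry only "start TAB
# end", and qualifier lines are indented with three tabs as "key TAB value".
# The bundled reader re-parses the writer's output exactly (round-trip
# fidelity defines the dialect).

.productName <- function(hlaClass) {
  switch(hlaClass,
    class_I = "MHC class I antigen",
    class_II_alpha = "MHC class II antigen alpha chain",
    class_II_beta = "MHC class II antigen beta chain")
}

#' Build a submission record from a characterized sample
#'
#' Assembles the sequence entry submitted to a public repository: the sample
#' ID as SeqID, the organism tag, a descriptor naming the most related
#' allele, the consensus sequence carrying the novelty, and the feature
#' entries derived from the gene model - a \code{gene} feature spanning the
#' whole sequence, an \code{mRNA} feature whose intervals are the UTRs plus
#' exons, and a \code{CDS} feature carrying exon positions only.
#'
#' @param sampleId Sample identifier used as SeqID.
#' @param model The \linkS4class{GeneModel} the consensus was annotated on.
#' @param consensus Consensus nucleotide sequence (character or
#'   \link[Biostrings]{DNAString}); must match the model's span.
#' @param relatedAllele Name of the most related catalogued allele.
#' @param description Optional custom descriptor; by default
#'   \code{"<locus> gene, novel allele closely related to <relatedAllele>"}.
#' @param organism Organism tag, default \code{"Homo sapiens"}.
#' @return A \linkS4class{SubmissionRecord}.
#' @examples
#' m <- exampleGeneModel("B")
#' seqc <- as.character(modelSequence(m))
#' substr(seqc, 1701, 1701) <- "G"
#' rec <- buildSubmission("VGH002", m, seqc, "B*48:01:01:01")
#' @export
buildSubmission <- function(sampleId, model, consensus, relatedAllele,
                            description = NULL, organism = "Homo sapiens") {
  if (is.character(consensus)) consensus <- Biostrings::DNAString(consensus)
  if (length(consensus) != length(model@sequence))
    stop(sprintf("consensus length (%d) does not match the model span (%d)",
                 length(consensus), length(model@sequence)))
  if (is.null(description))
    description <- sprintf("%s gene, novel allele closely related to %s",
                           model@locusName, relatedAllele)
  ft <- model@features
  asIv <- function(rows) {
    unname(as.matrix(rows[, c("start", "end"), drop = FALSE]))
  }
  mrnaRows <- ft[ft$kind %in% c("five_prime_UTR", "exon", "three_prime_UTR"), ,
                 drop = FALSE]
  cdsRows <- ft[ft$kind == "exon", , drop = FALSE]
  features <- list(
    list(kind = "gene",
         intervals = matrix(c(1L, length(consensus)), ncol = 2L),
         qualifiers = c(gene = model@locusName)),
    list(kind = "mRNA", intervals = asIv(mrnaRows),
         qualifiers = c(gene = model@locusName,
                        product = .productName(model@hlaClass))),
    list(kind = "CDS", intervals = asIv(cdsRows),
         qualifiers = c(gene = model@locusName,
                        product = .productName(model@hlaClass)))
  )
  new("SubmissionRecord", seqId = sampleId, organism = organism,
      description = description, sequence = consensus, features = features)
}

#' @describeIn buildSubmission The SeqID.
#' @param x A \code{SubmissionRecord}.
#' @export
setMethod("seqId", "SubmissionRecord", function(x) x@seqId)

#' @describeIn buildSubmission The feature-entry list.
#' @export
setMethod("submissionFeatures", "SubmissionRecord", function(x) x@features)

setMethod("show", "SubmissionRecord", function(object) {
  cat(sprintf("SubmissionRecord %s [organism=%s]\n  %s\n  %d bp, %d features\n",
              object@seqId, object@organism, object@description,
              length(object@sequence), length(object@features)))
})

#' Write and read the combined submission FASTA
#'
#' One concatenated FASTA for the whole batch. Each header is
#' \code{">SeqID [organism=Homo sapiens] description"}; sequence lines are
#' wrapped at a fixed column width (default 70). Files written by
#' \code{writeSubmissionFasta} re-parse to identical records.
#'
#' @param records Non-empty list of \linkS4class{SubmissionRecord} with
#'   unique SeqIDs.
#' @param path Output path.
#' @param width Wrap column for sequence lines.
#' @return \code{writeSubmissionFasta}: \code{path}, invisibly.
#'   \code{readSubmissionFasta}: a list of \linkS4class{SubmissionRecord}
#'   (without feature entries, which live in the per-record feature tables).
#' @export
writeSubmissionFasta <- function(records, path, width = 70L) {
  if (length(records) == 0L)
    stop("empty submission batch")
  ids <- vapply(records, function(r) r@seqId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate SeqID in batch: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x <- Biostrings::DNAStringSet(lapply(records, function(r) r@sequence))
  names(x) <- vapply(records, function(r)
    sprintf("%s [organism=%s] %s", r@seqId, r@organism, r@description),
    character(1))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' @rdname writeSubmissionFasta
#' @export
readSubmissionFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(x), function(i) {
    hdr <- names(x)[i]
    m <- regmatches(hdr, regexec("^(\\S+) \\[organism=([^]]+)\\] (.*)$", hdr))[[1L]]
    if (length(m) != 4L)
      stop("header does not follow the submission dialect: ", hdr)
    new("SubmissionRecord", seqId = m[2L], organism = m[3L],
        description = m[4L], sequence = x[[i]], features = list())
  })
}

#' Write and read a five-column feature table
#'
#' The feature table opens with \code{">Feature SeqID"}; each feature entry
#' opens with \code{start<TAB>end<TAB>kind}, continuation intervals carry
#' only \code{start<TAB>end}, and qualifiers follow as
#' \code{<TAB><TAB><TAB>key<TAB>value} lines. Writing then reading then
#' writing again is byte-identical.
#'
#' @param record A \linkS4class{SubmissionRecord}.
#' @param path File path.
#' @return \code{writeFeatureTable}: \code{path}, invisibly.
#'   \code{readFeatureTable}: list with \code{seqId} and \code{features} (the
#'   feature-entry list).
#' @export
writeFeatureTable <- function(record, path) {
  validObject(record)
  lines <- sprintf(">Feature %s", record@seqId)
  for (f in record@features) {
    iv <- f$intervals
    lines <- c(lines, sprintf("%d\t%d\t%s", iv[1L, 1L], iv[1L, 2L], f$kind))
    if (nrow(iv) > 1L)
      lines <- c(lines, sprintf("%d\t%d", iv[-1L, 1L], iv[-1L, 2L]))
    for (k in names(f$qualifiers))
      lines <- c(lines, sprintf("\t\t\t%s\t%s", k, f$qualifiers[[k]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], ">Feature "))
    stop("not a feature table: first line must be '>Feature <SeqID>'")
  sid <- sub("^>Feature ", "", lines[1L])
  features <- list()
  cur <- NULL
  for (ln in lines[-1L]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 5L && all(parts[1:3] == "")) {
      if (is.null(cur)) stop("qualifier line before any feature")
      q <- stats::setNames(parts[5L], parts[4L])
      cur$qualifiers <- c(cur$qualifiers, q)
    } else if (length(parts) == 3L) {
      if (!is.null(cur)) features <- c(features, list(cur))
      cur <- list(kind = parts[3L],
                  intervals = matrix(as.integer(parts[1:2]), ncol = 2L),
                  qualifiers = character())
    } else if (length(parts) == 2L) {
      if (is.null(cur)) stop("continuation interval before any feature")
      cur$intervals <- rbind(cur$intervals, as.integer(parts))
    } else {
      stop("malformed feature-table line: ", ln)
    }
  }
  if (!is.null(cur)) features <- c(features, list(cur))
  list(seqId = sid, features = features)
}

#' Write the submission manifest
#'
#' A sidecar tab-separated manifest listing, per record, the SeqID, the
#' descriptor, and the written mutation sentence; optional demographic
#' metadata columns are carried here rather than in the FASTA.
#'
#' @param records List of \linkS4class{SubmissionRecord}.
#' @param sentences Character vector of mutation description sentences,
#'   parallel to \code{records}.
#' @param path Output path.
#' @param metadata Optional \code{data.frame} of extra columns (same order).
#' @return \code{path}, invisibly.
#' @export
writeSubmissionManifest <- function(records, sentences, path,
                                    metadata = NULL) {
  df <- data.frame(
    seq_id = vapply(records, function(r) r@seqId, character(1)),
    description = vapply(records, function(r) r@description, character(1)),
    mutation_sentence = sentences
  )
  if (!is.null(metadata)) df <- cbind(df, metadata)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
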