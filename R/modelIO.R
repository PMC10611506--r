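# Gene-model files: one YAML document per locus with the locus label, HLA
# class, leader length, genomic sequence and the feature block. The reader
# funnels through the GeneModel() constructor, so non-partitioning feature
# sets are rejected.

#' Read and write gene-model files
#'
#' A gene-model file is a YAML document with fields \code{locus},
#' \code{hla_class}, \code{leader_length}, \code{full_cds},
#' \code{upstream_cds_bases}, \code{sequence} and \code{features} (a list of
#' \code{kind}/\code{index}/\code{start}/\code{end} rows). Reading validates
#' the model, so feature sets that do not partition the sequence are
#' rejected.
#'
#' @param model A \linkS4class{GeneModel}.
#' @param path File path.
#' @return \code{readGeneModel} returns a \linkS4class{GeneModel};
#'   \code{writeGeneModel} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeGeneModel(exampleGeneModel("DPA1"), f)
#' m <- readGeneModel(f)
#' @export
writeGeneModel <- function(model, path) {
  ft <- model@features
  doc <- list(
    locus = model@locusName,
    hla_class = model@hlaClass,
    leader_length = model@leaderLength,
    full_cds = model@fullCDS,
    upstream_cds_bases = model@upstreamCDSBases,
    domain_map = as.list(model@domainMap),
    sequence = as.character(model@sequence),
    features = lapply(seq_len(nrow(ft)), function(i) {
      row <- list(kind = ft$kind[i], start = ft$start[i], end = ft$end[i])
      if (!is.na(ft$index[i])) row$index <- ft$index[i]
      row
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeGeneModel
#' @export
readGeneModel <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("locus", "hla_class", "leader_length", "sequence", "features")
  if (!all(need %in% names(doc)))
    stop("gene-model file is missing field(s): ",
         paste(setdiff(need, names(doc)), collapse = ", "))
  ft <- do.call(rbind, lapply(doc$features, function(row) {
    data.frame(kind = row$kind,
               index = if (is.null(row$index)) NA_integer_ else row$index,
               start = row$start, end = row$end)
  }))
  dm <- if (!is.null(doc$domain_map)) unlist(doc$domain_map) else NULL
  GeneModel(
    locusName = doc$locus, hlaClass = doc$hla_class,
    sequence = doc$sequence, features = ft,
    leaderLength = doc$leader_length, domainMap = dm,
    fullCDS = if (is.null(doc$full_cds)) TRUE else doc$full_cds,
    upstreamCDSBases = if (is.null(doc$upstream_cds_bases)) 0L
                       else doc$upstream_cds_bases
  )
}
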