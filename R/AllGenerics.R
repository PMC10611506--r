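#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))
#' @export
setGeneric("hlaClass", function(x) standardGeneric("hlaClass"))
#' @export
setGeneric("modelSequence", function(x) standardGeneric("modelSequence"))
#' @export
setGeneric("modelFeatures", function(x) standardGeneric("modelFeatures"))
#' @export
setGeneric("leaderLength", function(x) standardGeneric("leaderLength"))
#' @export
setGeneric("domainMap", function(x) standardGeneric("domainMap"))
#' @export
setGeneric("cdsSequence", function(x) standardGeneric("cdsSequence"))

#' @export
setGeneric("locateRegion", function(model, pos) standardGeneric("locateRegion"))
#' @export
setGeneric("genomicToCodon", function(model, pos) standardGeneric("genomicToCodon"))
#' @export
setGeneric("domainOf", function(model, exonIndex) standardGeneric("domainOf"))

#' @export
setGeneric("codonPosition", function(x) standardGeneric("codonPosition"))
#' @export
setGeneric("offsetInCodon", function(x) standardGeneric("offsetInCodon"))

#' @export
setGeneric("mutationClass", function(x) standardGeneric("mutationClass"))
#' @export
setGeneric("codonChange", function(x) standardGeneric("codonChange"))
#' @export
setGeneric("keyExon", function(x) standardGeneric("keyExon"))
#' @export
setGeneric("spliceProximal", function(x) standardGeneric("spliceProximal"))
#' @export
setGeneric("proteinDomain", function(x) standardGeneric("proteinDomain"))
#' @export
setGeneric("variantOf", function(x) standardGeneric("variantOf"))

#' @export
setGeneric("scoreTotal", function(x) standardGeneric("scoreTotal"))
#' @export
setGeneric("scoreRendered", function(x) standardGeneric("scoreRendered"))
#' @export
setGeneric("scoreCriteria", function(x) standardGeneric("scoreCriteria"))

#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' @export
setGeneric("submissionFeatures", function(x) standardGeneric("submissionFeatures"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("nUniqueAlleles", function(x) standardGeneric("nUniqueAlleles"))
#' @export
setGeneric("countsBy", function(x, what) standardGeneric("countsBy"))
#' @export
setGeneric("rateUniquePerMonth", function(x) standardGeneric("rateUniquePerMonth"))
#' @export
setGeneric("rateSamplesPerMonth", function(x) standardGeneric("rateSamplesPerMonth"))
#' @export
setGeneric("pctClassIIAlpha", function(x) standardGeneric("pctClassIIAlpha"))
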