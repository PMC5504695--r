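#' @rdname MetaproteomeExperiment-class
#' @export
setGeneric("balancedCounts", function(x) standardGeneric("balancedCounts"))

#' @rdname MetaproteomeExperiment-class
#' @export
setGeneric("runAbundance", function(x) standardGeneric("runAbundance"))

#' @rdname MetaproteomeExperiment-class
#' @export
setGeneric("sampleAbundance", function(x) standardGeneric("sampleAbundance"))

#' @rdname MetaproteomeExperiment-class
#' @export
setGeneric("proteinGroups", function(x) standardGeneric("proteinGroups"))

#' @rdname ModuleDefinition-class
#' @export
setGeneric("moduleId", function(x) standardGeneric("moduleId"))

#' @rdname ModuleDefinition-class
#' @export
setGeneric("moduleName", function(x) standardGeneric("moduleName"))

#' @rdname ModuleDefinition-class
#' @export
setGeneric("moduleSteps", function(x) standardGeneric("moduleSteps"))

#' @rdname ModuleDefinition-class
#' @export
setGeneric("moduleCategory", function(x) standardGeneric("moduleCategory"))

#' @rdname GenomeBin-class
#' @export
setGeneric("binId", function(x) standardGeneric("binId"))

#' @rdname GenomeBin-class
#' @export
setGeneric("taxonLabel", function(x) standardGeneric("taxonLabel"))

#' @rdname GenomeBin-class
#' @export
setGeneric("binProteins", function(x) standardGeneric("binProteins"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("communityBins", function(x) standardGeneric("communityBins"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("communityTruth", function(x) standardGeneric("communityTruth"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("communityProteins", function(x) standardGeneric("communityProteins"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("communityBinMap", function(x) standardGeneric("communityBinMap"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("communityAnnotations",
           function(x) standardGeneric("communityAnnotations"))

#' @rdname SyntheticCommunity-class
#' @export
setGeneric("communityModules", function(x) standardGeneric("communityModules"))
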