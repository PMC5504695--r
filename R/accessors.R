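#' @describeIn GenomeBin-class bin identifier.
#' @param x a `GenomeBin`.
#' @export
setMethod("binId", "GenomeBin", function(x) x@binId)

#' @describeIn GenomeBin-class taxon label.
#' @export
setMethod("taxonLabel", "GenomeBin", function(x) x@taxonLabel)

#' @describeIn GenomeBin-class named vector of predicted protein sequences.
#' @export
setMethod("binProteins", "GenomeBin", function(x) x@proteins)

setMethod("show", "GenomeBin", function(object) {
  cat("GenomeBin", object@binId, "(", object@taxonLabel, ") with",
      length(object@proteins), "predicted proteins\n")
})

#' @describeIn SyntheticCommunity-class list of genome bins.
#' @param x a `SyntheticCommunity`.
#' @export
setMethod("communityBins", "SyntheticCommunity", function(x) x@bins)

#' @describeIn SyntheticCommunity-class truth tables (empty list before
#'   [simulateAbundanceTrajectories()] is run).
#' @export
setMethod("communityTruth", "SyntheticCommunity", function(x) x@truth)

#' @describeIn SyntheticCommunity-class all protein sequences (microbial then
#'   human) as a named character vector.
#' @export
setMethod("communityProteins", "SyntheticCommunity", function(x) {
  c(unlist(unname(lapply(x@bins, slot, "proteins"))), x@humanProteins)
})

#' @describeIn SyntheticCommunity-class named vector accession -> bin id, with
#'   human proteins mapped to `"human"`.
#' @export
setMethod("communityBinMap", "SyntheticCommunity", function(x) {
  m <- unlist(lapply(x@bins, function(b)
    setNames(rep(b@binId, length(b@proteins)), names(b@proteins))))
  c(m, setNames(rep("human", length(x@humanProteins)), names(x@humanProteins)))
})

#' @describeIn SyntheticCommunity-class named vector accession -> ortholog id.
#' @export
setMethod("communityAnnotations", "SyntheticCommunity",
          function(x) x@annotations)

#' @describeIn SyntheticCommunity-class list of module definitions.
#' @export
setMethod("communityModules", "SyntheticCommunity", function(x) x@modules)

setMethod("show", "SyntheticCommunity", function(object) {
  nm <- sum(vapply(object@bins, function(b) length(b@proteins), integer(1)))
  cat("SyntheticCommunity:", length(object@bins), "bins,", nm,
      "microbial proteins,", length(object@humanProteins), "human proteins\n")
  cat("  shared cross-bin proteins:", nrow(object@sharedPairs),
      "| modules:", length(object@modules), "\n")
  if (length(object@truth))
    cat("  truth:", nrow(object@truth$samples), "samples for infant(s)",
        paste(unique(object@truth$samples$infant), collapse = ", "), "\n")
  else cat("  truth: not simulated yet\n")
})

#' @describeIn ModuleDefinition-class module identifier.
#' @param x a `ModuleDefinition`.
#' @export
setMethod("moduleId", "ModuleDefinition", function(x) x@moduleId)

#' @describeIn ModuleDefinition-class module name.
#' @export
setMethod("moduleName", "ModuleDefinition", function(x) x@name)

#' @describeIn ModuleDefinition-class list of alternative-ortholog sets.
#' @export
setMethod("moduleSteps", "ModuleDefinition", function(x) x@steps)

#' @describeIn ModuleDefinition-class category label or `NA`.
#' @export
setMethod("moduleCategory", "ModuleDefinition", function(x) x@category)

setMethod("show", "ModuleDefinition", function(object) {
  cat("ModuleDefinition", object@moduleId, "(", object@name, "):",
      length(object@steps), "steps, category",
      ifelse(is.na(object@category), "none", object@category), "\n")
})

#' @describeIn MetaproteomeExperiment-class balanced spectral counts (group x run).
#' @param x a `MetaproteomeExperiment`.
#' @export
setMethod("balancedCounts", "MetaproteomeExperiment",
          function(x) assay(x, "counts"))

#' @describeIn MetaproteomeExperiment-class normalized abundances (group x run).
#' @export
setMethod("runAbundance", "MetaproteomeExperiment",
          function(x) assay(x, "abundance"))

#' @describeIn MetaproteomeExperiment-class replicate-averaged normalized
#'   abundances (group x sample): the arithmetic mean of a sample's runs.
#' @export
setMethod("sampleAbundance", "MetaproteomeExperiment", function(x) {
  averageReplicates(assay(x, "abundance"), colData(x)$sample_id)
})

#' @describeIn MetaproteomeExperiment-class `DataFrame` of protein-group metadata.
#' @export
setMethod("proteinGroups", "MetaproteomeExperiment", function(x) rowData(x))

setMethod("show", "MetaproteomeExperiment", function(object) {
  callNextMethod()
  ns <- length(unique(colData(object)$sample_id))
  cat("protein groups:", nrow(object), "| runs:", ncol(object),
      "| samples:", ns, "\n")
})

# columnwise mean over replicate runs of the same sample
averageReplicates <- function(mat, sampleIds) {
  stopifnot(ncol(mat) == length(sampleIds))
  samples <- unique(as.character(sampleIds))
  out <- vapply(samples, function(s)
    rowMeans(mat[, sampleIds == s, drop = FALSE]), numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), samples))
  out
}
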