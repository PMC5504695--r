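#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' GenomeBin: a binned genome and its predicted protein inventory
#'
#' A species/strain genome separated from a metagenome assembly, carrying the
#' protein sequences predicted from it. Accessions are unique within a bin and
#' each maps back to this bin in the accompanying bin map.
#'
#' @slot binId single identifier of the bin.
#' @slot taxonLabel species/strain label used in profiles.
#' @slot proteins named character vector of amino-acid sequences; names are
#'   protein accessions.
#' @exportClass GenomeBin
setClass("GenomeBin",
  slots = c(binId = "character", taxonLabel = "character",
            proteins = "character"))

setValidity("GenomeBin", function(object) {
  msg <- NULL
  if (length(object@binId) != 1L || !nzchar(object@binId))
    msg <- c(msg, "'binId' must be a single non-empty string")
  if (is.null(names(object@proteins)) || anyDuplicated(names(object@proteins)))
    msg <- c(msg, "protein accessions must be unique and named")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticCommunity: a simulated multi-species gut community
#'
#' Container for a seed-controlled synthetic community: genome bins with
#' predicted proteins, a human protein background, proteins duplicated
#' verbatim across related strains, ortholog annotations, module definitions,
#' and (after trajectory simulation) the ground truth used to validate the
#' downstream pipeline.
#'
#' @slot bins list of [GenomeBin-class] objects.
#' @slot humanProteins named character vector of human protein sequences.
#' @slot sharedPairs data.frame with columns `bin_a`, `bin_b`, `accession_a`,
#'   `accession_b`: proteins duplicated byte-identically across two bins.
#' @slot annotations named character vector mapping each microbial protein
#'   accession to exactly one ortholog id.
#' @slot modules list of [ModuleDefinition-class] objects.
#' @slot truth list with elements `samples` (data.frame: sample_id, infant,
#'   day_of_life, human_fraction) and `abundance` (sample x bin matrix of
#'   relative abundances), filled by [simulateAbundanceTrajectories()].
#' @exportClass SyntheticCommunity
setClass("SyntheticCommunity",
  slots = c(bins = "list", humanProteins = "character",
            sharedPairs = "data.frame", annotations = "character",
            modules = "list", truth = "list"))

setValidity("SyntheticCommunity", function(object) {
  msg <- NULL
  if (!all(vapply(object@bins, is, logical(1), "GenomeBin")))
    msg <- c(msg, "'bins' must be a list of GenomeBin objects")
  seqs <- unlist(lapply(object@bins, slot, "proteins"))
  if (nrow(object@sharedPairs)) {
    sp <- object@sharedPairs
    ok <- seqs[sp$accession_a] == seqs[sp$accession_b]
    if (!all(ok, na.rm = FALSE) || anyNA(ok))
      msg <- c(msg, "shared proteins must be byte-identical in both bins")
  }
  micro <- names(seqs)
  if (length(object@annotations)) {
    if (!all(micro %in% names(object@annotations)))
      msg <- c(msg, "every microbial protein needs exactly one ortholog id")
  }
  if (length(object@truth)) {
    ab <- object@truth$abundance
    if (!is.null(ab) && any(abs(rowSums(ab) - 1) > 1e-9))
      msg <- c(msg, "truth abundances must sum to 1 per sample")
    hf <- object@truth$samples$human_fraction
    if (!is.null(hf) && any(hf < 0 | hf > 1))
      msg <- c(msg, "human fractions must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' TrajectoryConfig: sampling design for abundance trajectories
#'
#' Describes one infant's sampling time course: days of life, the linear
#' decline of the human spectral fraction, and per-bin log-normal random-walk
#' drift parameters.
#'
#' @slot infantId infant label attached to every sample.
#' @slot daysOfLife strictly increasing integer-valued days.
#' @slot humanFractionStart,humanFractionEnd human spectral fraction at the
#'   first and last day; linearly interpolated in between. Both in [0, 1].
#' @slot mu,sigma per-bin drift and step standard deviation of the log-scale
#'   random walk (recycled across bins).
#' @slot seed integer seed for the walk.
#' @exportClass TrajectoryConfig
setClass("TrajectoryConfig",
  slots = c(infantId = "character", daysOfLife = "numeric",
            humanFractionStart = "numeric", humanFractionEnd = "numeric",
            mu = "numeric", sigma = "numeric", seed = "integer"))

setValidity("TrajectoryConfig", function(object) {
  msg <- NULL
  d <- object@daysOfLife
  if (length(d) < 1L || any(diff(d) <= 0))
    msg <- c(msg, "'daysOfLife' must be non-empty and strictly increasing")
  for (f in c(object@humanFractionStart, object@humanFractionEnd))
    if (f < 0 || f > 1) msg <- c(msg, "human fractions must lie in [0, 1]")
  if (any(object@sigma < 0)) msg <- c(msg, "'sigma' must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' ModuleDefinition: one gut metabolic module
#'
#' An ordered series of enzymatic steps; each step is satisfied by any of a
#' set of alternative orthologs. Optionally tagged with a nutrient-source
#' category (carbohydrate, amino_acid, lipid) or a short-chain fatty acid
#' category (acetate, propionate, butyrate).
#'
#' @slot moduleId unique module identifier.
#' @slot name human-readable module name.
#' @slot steps list of character vectors; element i holds the alternative
#'   ortholog ids of step i.
#' @slot category one of the six category labels or `NA_character_`.
#' @exportClass ModuleDefinition
setClass("ModuleDefinition",
  slots = c(moduleId = "character", name = "character", steps = "list",
            category = "character"))

.moduleCategories <- c("carbohydrate", "amino_acid", "lipid",
                       "acetate", "propionate", "butyrate")

setValidity("ModuleDefinition", function(object) {
  msg <- NULL
  if (length(object@steps) < 1L)
    msg <- c(msg, "a module needs at least one step")
  for (s in object@steps) {
    if (!is.character(s) || length(s) < 1L)
      msg <- c(msg, "every step needs at least one alternative ortholog")
    if (anyDuplicated(s))
      msg <- c(msg, "ortholog ids must be unique within a step")
  }
  if (!is.na(object@category) && !object@category %in% .moduleCategories)
    msg <- c(msg, paste0("unknown category '", object@category, "'"))
  if (is.null(msg)) TRUE else unique(msg)
})

#' MetaproteomeExperiment: protein groups by runs
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose rows are inferred protein groups and whose columns are mass
#' spectrometric runs. Assays: `counts` (balanced spectral counts) and
#' `abundance` (counts normalized by the total collected spectra of the run).
#' `colData` carries `sample_id`, `total_spectra` and (optionally) infant and
#' day-of-life metadata; `rowData` carries group membership, origin
#' (human/microbial), distinct-peptide tallies and taxon attribution.
#'
#' @exportClass MetaproteomeExperiment
setClass("MetaproteomeExperiment", contains = "SummarizedExperiment")

setValidity("MetaproteomeExperiment", function(object) {
  msg <- NULL
  if (!all(c("counts", "abundance") %in% assayNames(object)))
    msg <- c(msg, "assays 'counts' and 'abundance' are required")
  else {
    if (any(assay(object, "counts") < 0))
      msg <- c(msg, "balanced counts must be non-negative")
    if (any(assay(object, "abundance") < 0))
      msg <- c(msg, "normalized abundances must be non-negative")
  }
  if (!all(c("sample_id", "total_spectra") %in% colnames(colData(object))))
    msg <- c(msg, "colData needs 'sample_id' and 'total_spectra'")
  if (is.null(msg)) TRUE else msg
})
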