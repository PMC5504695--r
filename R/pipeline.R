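#' Build and validate a pipeline configuration
#'
#' Holds the input paths and the analysis parameters. Defaults are the
#' study-standard values: 2% PSM-level FDR, 90% human / 100% microbial
#' grouping identity, 7 metaproteome clusters, and a 0.556 module coverage
#' cutoff.
#'
#' @param psmPaths character vector of PSM TSV paths.
#' @param fastaPath protein database FASTA (targets; decoys ignored).
#' @param binMapPath bin-map TSV.
#' @param annotationPath protein-to-ortholog TSV.
#' @param modulePath module-definition flat file.
#' @param metadataPath run/sample metadata TSV.
#' @param outDir output directory for result tables.
#' @param fdrThreshold PSM FDR threshold (default 0.02).
#' @param humanIdentity,microbialIdentity grouping thresholds (0.90 / 1.00).
#' @param clusterK number of metaproteome clusters (default 7).
#' @param coverageCutoff module coverage cutoff (default 0.556).
#' @param nPermutations permutation budget (default 10000).
#' @param seed root seed; all stage seeds derive from it.
#' @return validated configuration list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(psmPaths, fastaPath, binMapPath, annotationPath,
                           modulePath, metadataPath, outDir,
                           fdrThreshold = 0.02, humanIdentity = 0.90,
                           microbialIdentity = 1.00, clusterK = 7L,
                           coverageCutoff = 0.556, nPermutations = 10000L,
                           seed = 17L) {
  if (fdrThreshold <= 0 || fdrThreshold >= 1)
    stop("'fdrThreshold' must lie strictly between 0 and 1")
  for (v in c(humanIdentity, microbialIdentity))
    if (v <= 0 || v > 1) stop("identity thresholds must lie in (0, 1]")
  coverageCutoff <- assertFraction(coverageCutoff, "coverageCutoff", 0, 1)
  clusterK <- assertCount(clusterK, "clusterK", 1L)
  paths <- c(psmPaths, fastaPath, binMapPath, annotationPath, modulePath,
             metadataPath)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  structure(list(
    psmPaths = psmPaths, fastaPath = fastaPath, binMapPath = binMapPath,
    annotationPath = annotationPath, modulePath = modulePath,
    metadataPath = metadataPath, outDir = outDir,
    fdrThreshold = fdrThreshold, humanIdentity = humanIdentity,
    microbialIdentity = microbialIdentity, clusterK = clusterK,
    coverageCutoff = coverageCutoff,
    nPermutations = as.integer(nPermutations), seed = as.integer(seed)),
    class = "PipelineConfig")
}

#' Run the full metaproteomic pipeline
#'
#' Executes, in order: FDR filtering, protein grouping, peptide-graph
#' construction with the two-peptide rule, spectral-count balancing,
#' normalization/averaging, taxonomic attribution and profiles, proteome
#' coverage, ortholog aggregation, conserved-function sets, Spearman
#' correlation clustering, permutation differential abundance on TMM-scaled
#' counts, and gut metabolic module scoring with category tri-plot
#' coordinates. Every stage's table is written as TSV into the configured
#' output directory; a manifest and a run log are written last.
#'
#' @param config a [pipelineConfig()] object.
#' @return invisibly, a list with the in-memory results of every stage plus
#'   `manifest` (data.frame of written files and row counts).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log <<- c(log, line)
    message(line)
  }

  psms <- readPsmTables(config$psmPaths)
  database <- readProteinDatabase(config$fastaPath)
  binMap <- readBinMap(config$binMapPath)
  annotation <- readAnnotations(config$annotationPath)
  modules <- parseModuleDefinitions(config$modulePath)
  metadata <- readSampleMetadata(config$metadataPath)
  note("inputs: ", nrow(psms), " PSMs over ",
       length(unique(psms$run_id)), " runs; ", length(database),
       " database proteins; ", length(modules), " modules")

  if (!dir.exists(config$outDir))
    dir.create(config$outDir, recursive = TRUE)
  manifest <- NULL
  emit <- function(df, name) {
    p <- writeTsv(as.data.frame(df), file.path(config$outDir, name))
    manifest <<- rbind(manifest, data.frame(file = p, rows = nrow(df)))
  }

  filt <- filterPsmsByFdr(psms, config$fdrThreshold)
  note("FDR filtering at ", config$fdrThreshold, ": retained ",
       nrow(filt$psms), " target PSMs")
  emit(filt$cutoffs, "fdr_cutoffs.tsv")

  grouping <- groupProteinsByIdentity(database, binMap,
                                      config$humanIdentity,
                                      config$microbialIdentity)
  graph <- buildPeptideGraph(filt$psms, grouping)
  note("protein groups surviving two-peptide rule: ", nrow(graph$groups),
       " (", length(graph$droppedGroups), " dropped, ",
       graph$orphanPeptides, " orphan peptides)")

  balanced <- balanceSharedSpectralCounts(graph)
  runTotals <- filt$runTotals
  if ("n_spectra" %in% colnames(metadata)) {
    m <- match(runTotals$run_id, metadata$run_id)
    runTotals$total_spectra <- metadata$n_spectra[m]
  }
  mpe <- normalizeAndAverage(balanced, runTotals, graph$groups)
  emit(data.frame(group_id = rownames(balanced), as.data.frame(balanced),
                  check.names = FALSE), "balanced_counts.tsv")
  sampleAb <- sampleAbundance(mpe)
  emit(data.frame(group_id = rownames(sampleAb), as.data.frame(sampleAb),
                  check.names = FALSE), "abundance_by_sample.tsv")

  attribution <- assignGroupsToBins(graph$groups, binMap)
  taxProf <- speciesRelativeAbundance(sampleAb, attribution)
  emit(taxProf$profiles, "taxon_profiles.tsv")
  emit(taxProf$summary, "taxon_summary.tsv")

  cov <- proteomeCoverage(graph$groups, sampleAb, binMap)
  emit(data.frame(bin = rownames(cov$coverage), cov$coverage,
                  check.names = FALSE), "proteome_coverage.tsv")
  emit(cov$topOrganism, "coverage_top_organism.tsv")

  runAb <- runAbundance(mpe)
  orthRun <- aggregateByOrtholog(runAb, annotation, graph$groups)
  orthSample <- aggregateByOrtholog(sampleAb, annotation, graph$groups)
  emit(data.frame(ortholog = rownames(orthSample$matrix),
                  as.data.frame(orthSample$matrix), check.names = FALSE),
       "ortholog_abundance.tsv")

  infantOf <- setNames(
    metadata$infant[match(colnames(sampleAb),
                          metadata$sample_id)], colnames(sampleAb))
  conserved <- conservedFunctionSets(orthSample$matrix, infantOf)
  emit(conserved$venn, "venn_regions.tsv")
  emit(conserved$presence, "ortholog_presence.tsv")
  note("core orthologs (all samples): ", length(conserved$core),
       "; half-core: ", length(conserved$halfCore))

  orthMicro <- orthRun$matrix[
    !rownames(orthRun$matrix) %in% "UNANNOTATED", , drop = FALSE]
  k <- min(config$clusterK, ncol(orthMicro))
  if (k < config$clusterK)
    note("only ", ncol(orthMicro), " runs; clustering with k = ", k)
  clust <- correlationCluster(orthMicro, k)
  emit(data.frame(run_id = names(clust$assignments),
                  cluster = unname(clust$assignments)),
       "cluster_assignments.tsv")
  emit(data.frame(run_id = rownames(clust$correlation),
                  as.data.frame(clust$correlation), check.names = FALSE),
       "spearman_correlation.tsv")

  diffRes <- tryCatch(
    differentialAbundance(balanced, clust$assignments,
                          config$nPermutations, config$seed),
    error = function(e) {
      note("differential abundance skipped: ", conditionMessage(e))
      NULL
    })
  if (!is.null(diffRes)) {
    allPairs <- do.call(rbind, lapply(names(diffRes$results), function(nm) {
      df <- diffRes$results[[nm]]
      df$pair <- nm
      df
    }))
    emit(allPairs, "differential_abundance.tsv")
    top <- do.call(rbind, lapply(names(diffRes$topTables), function(nm) {
      df <- diffRes$topTables[[nm]]
      if (nrow(df)) df$pair <- nm
      df
    }))
    if (!is.null(top) && nrow(top)) emit(top, "differential_top25.tsv")
  }

  koSample <- orthSample$matrix
  scores <- scoreModules(koSample, modules, config$coverageCutoff)
  emit(scores, "module_scores.tsv")
  perTaxon <- do.call(rbind, lapply(modules, function(m)
    attributeModuleToTaxa(sampleAb, attribution, orthSample$groupOrtholog,
                          m, config$coverageCutoff)))
  if (!is.null(perTaxon)) emit(perTaxon, "module_scores_by_taxon.tsv")

  categoryMap <- setNames(
    vapply(modules, moduleCategory, character(1)),
    vapply(modules, moduleId, character(1)))
  categoryMap <- categoryMap[!is.na(categoryMap)]
  catProfile <- NULL
  triCoords <- NULL
  if (length(categoryMap)) {
    catProfile <- categoryAbundance(scores, categoryMap)
    triCoords <- triplotCoordinates(catProfile)
    emit(catProfile, "category_abundance.tsv")
    emit(triCoords, "triplot_coordinates.tsv")
  }

  note("seed: ", config$seed, "; thresholds: FDR ", config$fdrThreshold,
       ", identity ", config$humanIdentity, "/", config$microbialIdentity,
       ", k ", k, ", coverage cutoff ", config$coverageCutoff)
  writeLines(log, file.path(config$outDir, "run_log.txt"))
  rownames(manifest) <- NULL
  writeTsv(manifest, file.path(config$outDir, "manifest.tsv"))

  invisible(list(
    filtered = filt, grouping = grouping, graph = graph, mpe = mpe,
    attribution = attribution, taxonProfiles = taxProf, coverage = cov,
    orthologRun = orthRun, orthologSample = orthSample,
    conserved = conserved, clusters = clust, differential = diffRes,
    moduleScores = scores, moduleScoresByTaxon = perTaxon,
    categoryProfile = catProfile, triplot = triCoords,
    manifest = manifest, log = log))
}
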