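#' Write a complete analysis fixture bundle to disk
#'
#' Serializes a synthetic community and its simulated PSM tables into the
#' plain-text formats the pipeline consumes: a FASTA protein database (targets
#' plus `DECOY_`-prefixed reversed entries), a bin map, one PSM TSV per run,
#' ortholog annotations, module definitions, run metadata, and the ground
#' truth (per-sample abundances, human fractions, per-spectrum labels).
#'
#' @param community a [SyntheticCommunity-class] with truth.
#' @param psms PSM data.frame from [simulatePsmTables()].
#' @param outDir output directory (created if missing).
#' @return invisibly, a manifest data.frame with columns `file` and `rows`
#'   (FASTA rows = number of records).
#' @export
writeFixtureBundle <- function(community, psms, outDir) {
  stopifnot(is(community, "SyntheticCommunity"), is.data.frame(psms))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)

  seqs <- communityProteins(community)
  decoys <- setNames(reverseSequences(seqs), paste0("DECOY_", names(seqs)))
  fa <- Biostrings::AAStringSet(c(seqs, decoys))
  faPath <- file.path(outDir, "database.fasta")
  Biostrings::writeXStringSet(fa, faPath)
  manifest <- data.frame(file = faPath, rows = length(fa),
                         stringsAsFactors = FALSE)

  addTsv <- function(df, name) {
    p <- writeTsv(df, file.path(outDir, name))
    manifest <<- rbind(manifest,
                       data.frame(file = p, rows = nrow(df)))
    p
  }

  binMap <- communityBinMap(community)
  addTsv(data.frame(accession = names(binMap), bin = unname(binMap)),
         "bin_map.tsv")
  ann <- communityAnnotations(community)
  addTsv(data.frame(accession = names(ann), ortholog = unname(ann)),
         "annotations.tsv")

  psmCols <- c("spectrum_id", "run_id", "sample_id", "peptide",
               "protein_accessions", "is_decoy", "score")
  for (run in unique(psms$run_id))
    addTsv(psms[psms$run_id == run, psmCols],
           sprintf("psms_%s.tsv", run))
  addTsv(psms[, c("run_id", "spectrum_id", "is_correct")],
         "truth_psm_labels.tsv")

  truth <- communityTruth(community)
  runs <- unique(psms[, c("run_id", "sample_id")])
  meta <- merge(runs, truth$samples, by = "sample_id", sort = FALSE)
  meta$replicate <- as.integer(sub(".*_r", "", meta$run_id))
  meta$n_spectra <- as.integer(table(psms$run_id)[meta$run_id])
  addTsv(meta[, c("run_id", "sample_id", "infant", "day_of_life",
                  "replicate", "n_spectra")], "metadata.tsv")

  ab <- truth$abundance
  addTsv(data.frame(sample_id = rep(rownames(ab), ncol(ab)),
                    bin_id = rep(colnames(ab), each = nrow(ab)),
                    abundance = as.vector(ab)), "truth_abundance.tsv")
  addTsv(truth$samples[, c("sample_id", "human_fraction")],
         "truth_human_fraction.tsv")

  writeModuleDefinitions(communityModules(community),
                         file.path(outDir, "modules.tsv"))
  manifest <- rbind(manifest, data.frame(
    file = file.path(outDir, "modules.tsv"),
    rows = length(communityModules(community))))
  rownames(manifest) <- NULL
  invisible(manifest)
}

#' Read a protein database from FASTA
#'
#' @param path FASTA file.
#' @param dropDecoys drop `DECOY_`-prefixed records (default TRUE).
#' @return named character vector of sequences.
#' @export
readProteinDatabase <- function(path, dropDecoys = TRUE) {
  fa <- Biostrings::readAAStringSet(path)
  seqs <- setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
  if (dropDecoys) seqs <- seqs[!startsWith(names(seqs), "DECOY_")]
  seqs
}

#' Read a bin map (accession to genome bin or "human")
#' @param path two-column TSV `accession`, `bin`.
#' @return named character vector accession -> bin.
#' @export
readBinMap <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("accession", "bin") %in% colnames(df)))
  setNames(df$bin, df$accession)
}

#' Read PSM tables from one or more TSV files
#' @param paths character vector of PSM TSV paths.
#' @return combined PSM data.frame.
#' @export
readPsmTables <- function(paths) {
  need <- c("spectrum_id", "run_id", "sample_id", "peptide",
            "protein_accessions", "is_decoy", "score")
  out <- lapply(paths, function(p) {
    df <- readTsv(p, colClasses = c(peptide = "character"))
    missing <- setdiff(need, colnames(df))
    if (length(missing))
      stop("PSM table ", p, " lacks column(s): ",
           paste(missing, collapse = ", "))
    df$is_decoy <- as.logical(df$is_decoy)
    df
  })
  do.call(rbind, out)
}

#' Read protein-to-ortholog annotations
#' @param path two-column TSV `accession`, `ortholog`.
#' @return named character vector accession -> ortholog id.
#' @export
readAnnotations <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("accession", "ortholog") %in% colnames(df)))
  setNames(df$ortholog, df$accession)
}

#' Read run/sample metadata
#' @param path TSV with at least `run_id` and `sample_id`.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("run_id", "sample_id") %in% colnames(df)))
  df
}
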