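#' Build the peptide-protein graph and apply the two-peptide rule
#'
#' Connects every observed peptide to the protein groups whose members its
#' PSMs matched, then removes groups supported by fewer than `minPeptides`
#' distinct peptide sequences (charge/modification variants are already
#' collapsed to the bare sequence). Peptides left without any surviving group
#' are dropped and tallied.
#'
#' @param filteredPsms FDR-filtered target PSMs (see [filterPsmsByFdr()]).
#' @param grouping result of [groupProteinsByIdentity()].
#' @param minPeptides distinct peptides required per group (default 2).
#' @return list with:
#'   \describe{
#'     \item{edges}{data.frame `peptide`, `group_id` (bipartite edges);}
#'     \item{peptideCounts}{data.frame `peptide`, `run_id`, `n` spectral
#'       counts;}
#'     \item{groups}{surviving groups with `n_peptides` and their peptide
#'       sets (";"-separated);}
#'     \item{droppedGroups}{group ids removed by the rule;}
#'     \item{orphanPeptides}{number of peptides left without a group;}
#'     \item{runIds}{all run ids seen.}
#'   }
#' @export
buildPeptideGraph <- function(filteredPsms, grouping, minPeptides = 2L) {
  stopifnot(is.data.frame(filteredPsms),
            all(c("peptide", "run_id", "protein_accessions") %in%
                  colnames(filteredPsms)))
  minPeptides <- assertCount(minPeptides, "minPeptides", 1L)
  assignment <- grouping$assignment

  counts <- stats::aggregate(
    list(n = rep(1L, nrow(filteredPsms))),
    by = list(peptide = filteredPsms$peptide,
              run_id = filteredPsms$run_id), FUN = sum)

  # peptide -> union of groups over all its PSM accession lists
  first <- !duplicated(filteredPsms$peptide)
  accLists <- strsplit(filteredPsms$protein_accessions[first], ";",
                       fixed = TRUE)
  names(accLists) <- filteredPsms$peptide[first]
  # accession lists are identical across occurrences of a peptide by
  # construction of search output; union over the first is sufficient
  edges <- data.frame(
    peptide = rep(names(accLists), lengths(accLists)),
    accession = unlist(accLists, use.names = FALSE),
    stringsAsFactors = FALSE)
  edges$group_id <- assignment[edges$accession]
  edges <- unique(edges[!is.na(edges$group_id),
                        c("peptide", "group_id")])

  pepSets <- split(edges$peptide, edges$group_id)
  keep <- names(pepSets)[lengths(pepSets) >= minPeptides]
  dropped <- setdiff(names(pepSets), keep)
  edges <- edges[edges$group_id %in% keep, ]
  orphan <- setdiff(names(accLists), edges$peptide)
  counts <- counts[counts$peptide %in% edges$peptide, ]

  groups <- grouping$groups[grouping$groups$group_id %in% keep, ]
  pepSets <- pepSets[keep]
  groups$n_peptides <- lengths(pepSets)[groups$group_id]
  groups$peptides <- vapply(pepSets[groups$group_id], function(p)
    paste(sort(unique(p)), collapse = ";"), character(1))
  rownames(groups) <- NULL

  list(edges = edges, peptideCounts = counts, groups = groups,
       droppedGroups = dropped, orphanPeptides = length(orphan),
       runIds = sort(unique(filteredPsms$run_id)))
}

#' Balance shared-peptide spectral counts across protein groups
#'
#' Per run, spectra of peptides unique to one group accrue fully to it;
#' spectra of a peptide shared by k groups are split proportionally to the
#' groups' unique spectral counts in that run, or equally (1/k each) when all
#' k groups lack unique counts. The per-run sum of balanced counts equals the
#' number of PSMs attached to surviving groups exactly.
#'
#' @param graph result of [buildPeptideGraph()] (two-peptide rule applied).
#' @return numeric matrix of balanced counts, groups x runs.
#' @export
balanceSharedSpectralCounts <- function(graph) {
  edges <- graph$edges
  groupIds <- sort(unique(edges$group_id))
  runs <- graph$runIds
  k <- table(edges$peptide)              # groups per peptide
  out <- matrix(0, length(groupIds), length(runs),
                dimnames = list(groupIds, runs))
  for (r in runs) {
    cnt <- graph$peptideCounts[graph$peptideCounts$run_id == r, ]
    if (!nrow(cnt)) next
    cntVec <- setNames(cnt$n, cnt$peptide)
    uniq <- edges[k[edges$peptide] == 1L & edges$peptide %in% cnt$peptide, ]
    u <- setNames(numeric(length(groupIds)), groupIds)
    if (nrow(uniq)) {
      agg <- rowsum(cntVec[uniq$peptide], uniq$group_id)
      u[rownames(agg)] <- agg[, 1]
    }
    bal <- u
    sh <- edges[k[edges$peptide] > 1L & edges$peptide %in% cnt$peptide, ]
    if (nrow(sh)) {
      w <- u[sh$group_id]
      tot <- rowsum(w, sh$peptide)[sh$peptide, 1]
      kk <- as.numeric(k[sh$peptide])
      w <- ifelse(tot > 0, w / tot, 1 / kk)   # equal-split fallback
      share <- cntVec[sh$peptide] * w
      agg <- rowsum(share, sh$group_id)
      bal[rownames(agg)] <- bal[rownames(agg)] + agg[, 1]
    }
    out[, r] <- bal
  }
  out
}

#' Normalize balanced counts and assemble a MetaproteomeExperiment
#'
#' Divides each run's balanced spectral counts by the total number of spectra
#' collected in that run, and packages counts, normalized abundances, run
#' metadata and group metadata into a [MetaproteomeExperiment-class].
#' Replicate-averaged per-sample abundances (the arithmetic mean over a
#' sample's runs) are available via [sampleAbundance()]; the per-run matrix is
#' retained for clustering of individual measurements.
#'
#' @param balanced groups x runs matrix from [balanceSharedSpectralCounts()].
#' @param runTotals data.frame `run_id`, `sample_id`, `total_spectra` with a
#'   positive total for every run (from [filterPsmsByFdr()] or metadata).
#' @param groups optional group metadata data.frame (from the graph) keyed by
#'   `group_id`; stored as rowData.
#' @return a [MetaproteomeExperiment-class].
#' @export
normalizeAndAverage <- function(balanced, runTotals, groups = NULL) {
  stopifnot(is.matrix(balanced),
            all(c("run_id", "sample_id", "total_spectra") %in%
                  colnames(runTotals)))
  runs <- colnames(balanced)
  m <- match(runs, runTotals$run_id)
  if (anyNA(m))
    stop("run(s) missing from runTotals: ",
         paste(runs[is.na(m)], collapse = ", "))
  tot <- runTotals$total_spectra[m]
  bad <- is.na(tot) | tot <= 0
  if (any(bad))
    stop("zero or missing total spectra for run(s): ",
         paste(runs[bad], collapse = ", "))
  abundance <- sweep(balanced, 2, tot, "/")
  cd <- DataFrame(run_id = runs, sample_id = runTotals$sample_id[m],
                  total_spectra = tot, row.names = runs)
  rd <- NULL
  if (!is.null(groups)) {
    gm <- match(rownames(balanced), groups$group_id)
    rd <- DataFrame(groups[gm, , drop = FALSE],
                    row.names = rownames(balanced))
  }
  se <- SummarizedExperiment(
    assays = list(counts = balanced, abundance = abundance),
    colData = cd, rowData = rd)
  new("MetaproteomeExperiment", se)
}
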