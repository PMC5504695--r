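#' Aggregate protein-group abundances to ortholog level
#'
#' Annotates each group by majority vote over its members' ortholog
#' annotations (ties broken by the lexicographically smallest id); groups
#' whose members carry no annotation are collected under the reserved
#' `"UNANNOTATED"` row, which set analyses exclude. Ortholog abundance is the
#' sum of the abundances of its contributing groups, so column sums are
#' conserved.
#'
#' @param abundance groups x columns (runs or samples) matrix.
#' @param annotation named character vector accession -> ortholog id.
#' @param groups data.frame with `group_id` and `members`.
#' @return list with `matrix` (orthologs x columns), `provenance` (list
#'   ortholog -> contributing group ids) and `groupOrtholog` (named vector
#'   group_id -> ortholog).
#' @export
aggregateByOrtholog <- function(abundance, annotation, groups) {
  if (!length(annotation)) stop("empty annotation map")
  groups <- as.data.frame(groups)
  stopifnot(is.matrix(abundance),
            all(c("group_id", "members") %in% colnames(groups)))
  members <- strsplit(groups$members, ";", fixed = TRUE)
  vote <- vapply(members, function(m) {
    ann <- annotation[intersect(m, names(annotation))]
    ann <- ann[!is.na(ann)]
    if (!length(ann)) return("UNANNOTATED")
    tab <- table(ann)
    winners <- names(tab)[tab == max(tab)]
    min(winners)                      # tie: lexicographically smallest
  }, character(1))
  names(vote) <- groups$group_id
  orth <- vote[rownames(abundance)]
  if (anyNA(orth))
    stop("group(s) absent from 'groups': ",
         paste(rownames(abundance)[is.na(orth)], collapse = ", "))
  mat <- rowsum(abundance, orth)
  provenance <- split(names(orth), orth)
  list(matrix = mat, provenance = provenance, groupOrtholog = vote)
}

#' Conserved-function sets across infants and samples
#'
#' Presence is strictly positive abundance in a column. Returns per-infant
#' ortholog sets, all `2^k - 1` Venn region counts over the infants, the
#' per-ortholog presence count across columns, the core set (present in every
#' column) and the half-core (present in at least `ceiling(n/2)` columns).
#' The reserved `"UNANNOTATED"` row is excluded.
#'
#' @param abundance orthologs x samples matrix.
#' @param infantOf named character vector column -> infant id.
#' @return list `sets`, `venn` (data.frame `region`, `count`), `presence`
#'   (data.frame `ortholog`, `n_samples`), `core`, `halfCore`.
#' @export
conservedFunctionSets <- function(abundance, infantOf) {
  stopifnot(is.matrix(abundance),
            all(colnames(abundance) %in% names(infantOf)))
  abundance <- abundance[rownames(abundance) != "UNANNOTATED", ,
                         drop = FALSE]
  pres <- abundance > 0
  infants <- sort(unique(infantOf[colnames(abundance)]))
  sets <- lapply(infants, function(i) {
    cols <- colnames(abundance)[infantOf[colnames(abundance)] == i]
    rownames(pres)[rowSums(pres[, cols, drop = FALSE]) > 0]
  })
  names(sets) <- infants

  inInfant <- vapply(sets, function(s) rownames(pres) %in% s,
                     logical(nrow(pres)))
  if (nrow(pres) == 1L) inInfant <- matrix(inInfant, nrow = 1L,
                                           dimnames = list(rownames(pres),
                                                           infants))
  key <- apply(inInfant, 1, function(z)
    paste(infants[z], collapse = "&"))
  regions <- unlist(lapply(seq_along(infants), function(m)
    utils::combn(infants, m, paste, collapse = "&", simplify = TRUE)))
  venn <- data.frame(region = regions,
                     count = as.integer(table(factor(key[key != ""],
                                                     levels = regions))),
                     stringsAsFactors = FALSE)

  nPresent <- rowSums(pres)
  presence <- data.frame(ortholog = rownames(pres),
                         n_samples = as.integer(nPresent),
                         row.names = NULL)
  n <- ncol(pres)
  list(sets = sets, venn = venn, presence = presence,
       core = rownames(pres)[nPresent == n],
       halfCore = rownames(pres)[nPresent >= ceiling(n / 2)])
}

#' Cluster metaproteome measurements by Spearman correlation
#'
#' Spearman's rank correlation (average ranks for ties) between every pair of
#' runs over ortholog abundances; distance `1 - rho`; complete-linkage
#' agglomeration; tree cut into exactly `k` clusters.
#'
#' @param abundance orthologs x runs matrix (>= 3 orthologs, >= k runs).
#' @param k number of clusters (default 7).
#' @return list `correlation` (rho matrix), `linkage` (hclust), `k`,
#'   `assignments` (named integer vector run -> cluster).
#' @export
correlationCluster <- function(abundance, k = 7L) {
  k <- assertCount(k, "k", 1L)
  stopifnot(is.matrix(abundance))
  if (ncol(abundance) < k)
    stop("need at least k = ", k, " runs, got ", ncol(abundance))
  if (nrow(abundance) < 3L)
    stop("need at least 3 orthologs")
  constant <- apply(abundance, 2, function(x) length(unique(x)) == 1L)
  if (any(constant))
    stop("correlation undefined for constant run(s): ",
         paste(colnames(abundance)[constant], collapse = ", "))
  rho <- stats::cor(abundance, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "complete")
  assignments <- stats::cutree(hc, k = k)
  list(correlation = rho, linkage = hc, k = k, assignments = assignments)
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Between-run scaling factors for spectral count matrices, computed with the
#' standard TMM procedure: reference run chosen by upper-quartile closeness
#' to the mean, log-ratios (M) trimmed by 30% and average log-abundances (A)
#' by 5%, precision-weighted mean of the trimmed M values, and factors
#' rescaled to geometric mean 1. Delegates to
#' [edgeR::calcNormFactors()][edgeR::normLibSizes].
#'
#' @param counts non-negative counts, rows x runs (>= 2 runs).
#' @return named numeric vector of per-run factors (geometric mean 1).
#' @export
tmmFactors <- function(counts) {
  stopifnot(is.matrix(counts))
  if (ncol(counts) < 2L) stop("TMM needs at least two runs")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("run(s) with all-zero counts")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  if (any(!is.finite(f)) || any(f <= 0))
    stop("TMM factors are undefined; runs may share no non-zero rows")
  setNames(as.numeric(f), colnames(counts))
}
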