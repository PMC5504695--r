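#' Attribute protein groups to genome bins
#'
#' A group whose members all fall in one bin gets that bin's label; a group
#' spanning two or more microbial bins (identical proteins from closely
#' related strains are indistinguishable) gets a merged label joining the
#' sorted bin ids with `"+"`; human groups are labeled `"human"`. A group
#' mixing human and microbial members is a data-integrity error — the
#' grouping thresholds forbid it.
#'
#' @param groups data.frame of protein groups with `group_id` and `members`
#'   (";"-separated accessions), e.g. from [buildPeptideGraph()] or
#'   `proteinGroups()`.
#' @param binMap named character vector accession -> bin id / `"human"`.
#' @return named character vector group_id -> taxon label.
#' @export
assignGroupsToBins <- function(groups, binMap) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("group_id", "members") %in% colnames(groups)))
  members <- strsplit(groups$members, ";", fixed = TRUE)
  labels <- vapply(members, function(m) {
    missing <- setdiff(m, names(binMap))
    if (length(missing))
      stop("member accession(s) not in bin map: ",
           paste(missing, collapse = ", "))
    bins <- sort(unique(binMap[m]))
    if ("human" %in% bins) {
      if (length(bins) > 1L)
        stop("group mixes human and microbial members: ",
             paste(m, collapse = ";"))
      return("human")
    }
    paste(bins, collapse = "+")
  }, character(1))
  setNames(labels, groups$group_id)
}

#' Per-sample species relative abundance, diversity and human fraction
#'
#' Sums group abundances per taxon label and sample. Microbial taxon
#' fractions are normalized to the total microbial abundance of the sample;
#' the human spectral fraction is human abundance over all (human +
#' microbial) abundance. The Shannon index is computed from the microbial
#' fractions. Samples without any microbial signal yield no taxon rows and
#' are flagged.
#'
#' @param abundance groups x samples (or runs) matrix of normalized
#'   abundances, e.g. [sampleAbundance()] output.
#' @param attribution named character vector group_id -> taxon label from
#'   [assignGroupsToBins()]; must cover all rows.
#' @return list with:
#'   \describe{
#'     \item{profiles}{data.frame `sample_id`, `taxon`, `fraction`
#'       (microbial taxa only);}
#'     \item{summary}{data.frame `sample_id`, `shannon`, `human_fraction`,
#'       `no_microbial_signal` flag.}
#'   }
#' @export
speciesRelativeAbundance <- function(abundance, attribution) {
  stopifnot(is.matrix(abundance))
  miss <- setdiff(rownames(abundance), names(attribution))
  if (length(miss))
    stop("attribution missing for group(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  taxa <- attribution[rownames(abundance)]
  byTaxon <- rowsum(abundance, taxa)
  isHuman <- rownames(byTaxon) == "human"
  humanAb <- if (any(isHuman))
    setNames(as.numeric(byTaxon[which(isHuman), , drop = FALSE]),
             colnames(abundance)) else
    setNames(rep(0, ncol(abundance)), colnames(abundance))
  micro <- byTaxon[!isHuman, , drop = FALSE]

  profiles <- NULL
  summary <- NULL
  for (s in colnames(abundance)) {
    mTot <- sum(micro[, s])
    allTot <- mTot + humanAb[[s]]
    hf <- if (allTot > 0) humanAb[[s]] / allTot else NA_real_
    if (mTot <= 0) {
      warning("sample '", s, "' has no microbial abundance; ",
              "taxon fractions undefined")
      summary <- rbind(summary, data.frame(
        sample_id = s, shannon = NA_real_, human_fraction = hf,
        no_microbial_signal = TRUE))
      next
    }
    frac <- micro[, s] / mTot
    profiles <- rbind(profiles, data.frame(
      sample_id = s, taxon = rownames(micro), fraction = unname(frac),
      row.names = NULL))
    summary <- rbind(summary, data.frame(
      sample_id = s, shannon = shannonDiversity(frac[frac > 0]),
      human_fraction = hf, no_microbial_signal = FALSE))
  }
  list(profiles = profiles, summary = summary)
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` with `0 * ln(0) := 0`, over taxon proportions
#' that sum to one. Uses the natural logarithm.
#'
#' @param fractions non-negative proportions summing to 1 (within 1e-6).
#' @return the Shannon index H (>= 0).
#' @examples
#' shannonDiversity(rep(0.25, 4))  # ln(4)
#' @export
shannonDiversity <- function(fractions) {
  if (!length(fractions) || all(fractions == 0))
    stop("Shannon index undefined for all-zero input")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1 (within 1e-6)")
  as.numeric(vegan::diversity(fractions, index = "shannon"))
}

#' Organism-specific proteome coverage
#'
#' For every genome bin, the fraction of its predicted proteins that are
#' members of a surviving protein group with non-zero abundance in the
#' sample; the `total` column uses non-zero abundance in any sample. The
#' organism with the highest coverage per sample is reported alongside.
#'
#' @param groups data.frame with `group_id` and `members`.
#' @param abundance groups x samples matrix.
#' @param binMap named character vector accession -> bin (the bin's predicted
#'   proteome is every accession mapping to it; `"human"` is skipped).
#' @return list with `coverage` (data.frame bin x samples + `total`) and
#'   `topOrganism` (data.frame `sample_id`, `bin`, `coverage`).
#' @export
proteomeCoverage <- function(groups, abundance, binMap) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("group_id", "members") %in% colnames(groups)),
            is.matrix(abundance))
  bins <- setdiff(unique(binMap), "human")
  if (!length(bins)) stop("bin map holds no microbial bins")
  predicted <- split(names(binMap), binMap)[bins]
  if (any(lengths(predicted) == 0L))
    stop("bin(s) with zero predicted proteins: ",
         paste(bins[lengths(predicted) == 0L], collapse = ", "))

  members <- strsplit(groups$members, ";", fixed = TRUE)
  names(members) <- groups$group_id
  samples <- colnames(abundance)
  identifiedIn <- function(sampleCols) {
    gs <- rownames(abundance)[
      rowSums(abundance[, sampleCols, drop = FALSE] > 0) > 0]
    unique(unlist(members[intersect(gs, names(members))]))
  }
  cov <- matrix(0, length(bins), length(samples) + 1L,
                dimnames = list(bins, c(samples, "total")))
  for (s in samples) {
    ids <- identifiedIn(s)
    for (b in bins)
      cov[b, s] <- length(intersect(predicted[[b]], ids)) /
        length(predicted[[b]])
  }
  idsAll <- identifiedIn(samples)
  for (b in bins)
    cov[b, "total"] <- length(intersect(predicted[[b]], idsAll)) /
      length(predicted[[b]])

  top <- data.frame(
    sample_id = samples,
    bin = bins[apply(cov[, samples, drop = FALSE], 2, which.max)],
    coverage = apply(cov[, samples, drop = FALSE], 2, max),
    row.names = NULL)
  list(coverage = as.data.frame(cov), topOrganism = top)
}

#' Pearson correlation between two samples
#'
#' Correlation over the shared group universe of two abundance columns
#' (missing groups count as zero by matrix construction).
#'
#' @param abundance groups x samples (or runs) matrix.
#' @param sampleA,sampleB column names to compare.
#' @return Pearson r in [-1, 1].
#' @export
samplePearsonCorrelation <- function(abundance, sampleA, sampleB) {
  stopifnot(is.matrix(abundance),
            all(c(sampleA, sampleB) %in% colnames(abundance)))
  x <- abundance[, sampleA]
  y <- abundance[, sampleB]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero-variance abundance vector")
  stats::cor(x, y)
}
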