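#' Simulate decoy-contaminated PSM tables for every run
#'
#' For each sample in the community truth and each technical replicate, draws
#' `depth` spectra. A spectrum is, independently: a correct target match
#' (probability `1 - 2 * decoyRate`), an incorrect target match (probability
#' `decoyRate`), or a decoy match (probability `decoyRate`). Correct matches
#' sample peptides with probability proportional to the owning protein's bin
#' abundance (or the human fraction) times a per-peptide detectability weight
#' drawn once per peptide from a log-normal distribution. Incorrect target
#' matches hit a uniformly random target peptide, and decoy matches hit the
#' reversed sequence of a random target peptide under a `DECOY_`-prefixed
#' accession. Scores of correct matches are drawn from a unit-variance normal
#' shifted by `scoreShift`; incorrect and decoy scores come from the standard
#' normal null, so score thresholding (and decoy-based FDR estimation against
#' the exported `is_correct` truth labels) is meaningful.
#'
#' @param community a [SyntheticCommunity-class] with simulated truth.
#' @param depth spectra per run (>= 1000).
#' @param decoyRate fraction of spectra matched to decoys (0-0.2); the same
#'   fraction becomes incorrect target matches.
#' @param nReplicates technical replicates per sample (default 2).
#' @param seed integer seed.
#' @param scoreShift mean score separation (in null standard deviations)
#'   between correct and incorrect matches (default 2).
#' @param detectabilitySigma log-scale SD of per-peptide detectability
#'   weights (default 0.5).
#' @param minLen,maxLen,missedCleavages digestion parameters, see
#'   [digestProteome()].
#' @return data.frame of PSMs over all runs with columns `spectrum_id`,
#'   `run_id`, `sample_id`, `peptide`, `protein_accessions` (";"-separated),
#'   `is_decoy`, `score`, and the ground-truth label `is_correct`.
#' @export
simulatePsmTables <- function(community, depth = 20000L, decoyRate = 0.05,
                              nReplicates = 2L, seed = 17L, scoreShift = 2,
                              detectabilitySigma = 0.5, minLen = 6L,
                              maxLen = 50L, missedCleavages = 2L) {
  stopifnot(is(community, "SyntheticCommunity"))
  if (!length(community@truth))
    stop("community has no truth; run simulateAbundanceTrajectories() first")
  depth <- assertCount(depth, "depth", 1000L)
  decoyRate <- assertFraction(decoyRate, "decoyRate", 0, 0.2)
  nReplicates <- assertCount(nReplicates, "nReplicates", 1L)
  set.seed(deriveSeed(seed, 3L))

  seqs <- communityProteins(community)
  binMap <- communityBinMap(community)
  digest <- digestProteome(seqs, minLen = minLen, maxLen = maxLen,
                           missedCleavages = missedCleavages)
  npep <- lengths(digest)
  if (sum(npep) == 0L)
    stop("digestion produced no usable peptides")
  index <- data.frame(
    accession = rep(names(digest), npep),
    peptide = unlist(digest, use.names = FALSE),
    stringsAsFactors = FALSE)
  index$owner <- binMap[index$accession]

  # one detectability weight per distinct peptide sequence
  pepLevels <- unique(index$peptide)
  w <- stats::rlnorm(length(pepLevels), 0, detectabilitySigma)
  names(w) <- pepLevels
  index$w <- w[index$peptide]

  # accession list per peptide: every target protein containing the peptide
  accStr <- vapply(split(index$accession, index$peptide),
                   function(a) paste(sort(unique(a)), collapse = ";"),
                   character(1))

  truth <- community@truth
  out <- vector("list", nrow(truth$samples) * nReplicates)
  k <- 0L
  for (si in seq_len(nrow(truth$samples))) {
    sm <- truth$samples[si, ]
    h <- sm$human_fraction
    ab <- truth$abundance[sm$sample_id, ]
    ownerWeight <- c(ab * (1 - h), human = h)
    rowProb <- index$w * ownerWeight[index$owner]
    if (all(rowProb == 0)) rowProb <- index$w
    for (r in seq_len(nReplicates)) {
      k <- k + 1L
      runId <- sprintf("%s_r%d", sm$sample_id, r)
      type <- sample(c("correct", "incorrect", "decoy"), depth,
                     replace = TRUE,
                     prob = c(1 - 2 * decoyRate, decoyRate, decoyRate))
      rows <- integer(depth)
      nC <- sum(type == "correct")
      if (nC) rows[type == "correct"] <-
          sample.int(nrow(index), nC, replace = TRUE, prob = rowProb)
      nO <- depth - nC
      if (nO) rows[type != "correct"] <-
          sample.int(nrow(index), nO, replace = TRUE)
      pep <- index$peptide[rows]
      accs <- accStr[pep]
      isDecoy <- type == "decoy"
      if (any(isDecoy)) {
        pep[isDecoy] <- reverseSequences(pep[isDecoy])
        accs[isDecoy] <- paste0("DECOY_", index$accession[rows[isDecoy]])
      }
      score <- stats::rnorm(depth) + ifelse(type == "correct", scoreShift, 0)
      out[[k]] <- data.frame(
        spectrum_id = sprintf("%s_sp%06d", runId, seq_len(depth)),
        run_id = runId, sample_id = sm$sample_id, peptide = pep,
        protein_accessions = unname(accs), is_decoy = isDecoy,
        score = score, is_correct = type == "correct",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
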