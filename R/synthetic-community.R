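#' Generate a synthetic multi-species gut community
#'
#' Builds a seed-controlled stand-in for a binned metagenome: `nBins` genome
#' bins each holding `proteinsPerBin` random protein sequences, a human
#' protein background, a controlled fraction of microbial proteins duplicated
#' byte-identically into a second ("related strain") bin, one ortholog id per
#' microbial protein, and a small set of gut metabolic module definitions over
#' those orthologs.
#'
#' Sequences are uniform random strings over the twenty amino acids, 80-600
#' residues, always starting with M. A fixed fraction of the per-bin protein
#' slots carries a community-wide "core" ortholog id (the same id across all
#' bins), so conserved-function analyses downstream have a non-empty core;
#' the remaining proteins get bin-private ortholog ids. Roughly a third of
#' human proteins are close variants (about 5% substitutions) of an earlier
#' human protein, which exercises the 90%-identity human grouping rule.
#'
#' @param nBins number of genome bins (>= 1).
#' @param proteinsPerBin predicted proteins per bin (>= 5).
#' @param nHuman number of human background proteins (>= 0).
#' @param shareRate fraction (0-0.5) of microbial proteins duplicated verbatim
#'   into a second bin; exactly `floor(shareRate * nBins * proteinsPerBin)`
#'   duplications are made.
#' @param seed integer seed; identical seeds give byte-identical communities.
#' @return a [SyntheticCommunity-class] object (truth tables empty until
#'   [simulateAbundanceTrajectories()] is run).
#' @examples
#' cm <- generateCommunity(3, 20, 10, shareRate = 0.1, seed = 17)
#' cm
#' @export
generateCommunity <- function(nBins, proteinsPerBin, nHuman,
                              shareRate = 0.1, seed = 17L) {
  nBins <- assertCount(nBins, "nBins", 1L)
  proteinsPerBin <- assertCount(proteinsPerBin, "proteinsPerBin", 5L)
  nHuman <- assertCount(nHuman, "nHuman", 0L)
  shareRate <- assertFraction(shareRate, "shareRate", 0, 0.5)
  set.seed(deriveSeed(seed, 1L))

  taxa <- c("Enterococcus_faecalis", "Klebsiella_oxytoca",
            "Propionibacterium_sp", "Clostridium_sp", "Bifidobacterium_breve",
            "Escherichia_coli", "Staphylococcus_aureus",
            "Enterobacter_cloacae", "Haemophilus_parainfluenzae",
            "Klebsiella_pneumoniae", "Bacteroides_sp", "Clostridium_difficile")
  labels <- paste0(rep(taxa, length.out = nBins),
                   ifelse(seq_len(nBins) > length(taxa),
                          paste0("_", ceiling(seq_len(nBins) / length(taxa))),
                          ""))

  randomProtein <- function() {
    len <- sample(80:600, 1L)
    paste0("M", paste(sample(.AA20, len - 1L, replace = TRUE), collapse = ""))
  }

  nCore <- max(3L, round(0.4 * proteinsPerBin))
  bins <- vector("list", nBins)
  annotations <- character(0)
  for (i in seq_len(nBins)) {
    binId <- sprintf("bin%02d", i)
    acc <- sprintf("%s_p%04d", binId, seq_len(proteinsPerBin))
    seqs <- setNames(vapply(acc, function(a) randomProtein(), character(1)),
                     acc)
    bins[[i]] <- new("GenomeBin", binId = binId, taxonLabel = labels[i],
                     proteins = seqs)
    ort <- ifelse(seq_len(proteinsPerBin) <= nCore,
                  sprintf("ENOG_C%04d", seq_len(proteinsPerBin)),
                  sprintf("ENOG_%s_%04d", binId, seq_len(proteinsPerBin)))
    annotations <- c(annotations, setNames(ort, acc))
  }

  # duplicate a fixed number of proteins verbatim into a random partner bin
  nShared <- floor(shareRate * nBins * proteinsPerBin)
  if (nShared > 0L && nBins < 2L)
    stop("sharing proteins across bins needs at least two bins")
  shared <- data.frame(bin_a = character(0), bin_b = character(0),
                       accession_a = character(0), accession_b = character(0),
                       stringsAsFactors = FALSE)
  if (nShared > 0L) {
    srcBin <- sample.int(nBins, nShared, replace = TRUE)
    for (k in seq_len(nShared)) {
      a <- srcBin[k]
      b <- sample(setdiff(seq_len(nBins), a), 1L)
      accA <- sample(names(bins[[a]]@proteins), 1L)
      accB <- sprintf("%s_s%04d", bins[[b]]@binId, k)
      bins[[b]]@proteins[accB] <- bins[[a]]@proteins[[accA]]
      annotations[accB] <- annotations[[accA]]
      shared[k, ] <- list(bins[[a]]@binId, bins[[b]]@binId, accA, accB)
    }
  }

  human <- character(0)
  if (nHuman > 0L) {
    hacc <- sprintf("HUM_%04d", seq_len(nHuman))
    hseq <- character(nHuman)
    for (i in seq_len(nHuman)) {
      if (i > 1L && stats::runif(1) < 0.3) {
        # near-duplicate isoform: ~5% substitutions of an earlier protein
        base <- strsplit(hseq[sample.int(i - 1L, 1L)], "")[[1]]
        nmut <- max(1L, round(0.05 * length(base)))
        pos <- sample(seq_along(base)[-1], nmut)
        base[pos] <- sample(.AA20, nmut, replace = TRUE)
        hseq[i] <- paste(base, collapse = "")
      } else hseq[i] <- randomProtein()
    }
    human <- setNames(hseq, hacc)
  }

  modules <- defaultModuleSet(annotations)
  new("SyntheticCommunity", bins = bins, humanProteins = human,
      sharedPairs = shared, annotations = annotations, modules = modules,
      truth = list())
}

# six modules, one per nutrient / SCFA category, drawn from core orthologs
# (always) plus a few bin-private orthologs (sometimes), 3-5 steps each
defaultModuleSet <- function(annotations) {
  cats <- .moduleCategories
  core <- sort(unique(annotations[startsWith(annotations, "ENOG_C")]))
  other <- sort(unique(annotations[!startsWith(annotations, "ENOG_C")]))
  modules <- vector("list", length(cats))
  for (i in seq_along(cats)) {
    nSteps <- sample(3:5, 1L)
    steps <- lapply(seq_len(nSteps), function(s) {
      nAlt <- sample(1:3, 1L)
      pool <- if (length(other) && stats::runif(1) < 0.25) other else core
      sample(pool, min(nAlt, length(pool)))
    })
    modules[[i]] <- new("ModuleDefinition",
                        moduleId = sprintf("GMM%03d", i),
                        name = paste0(cats[i], "_metabolism"),
                        steps = steps, category = cats[i])
  }
  modules
}

#' In-silico tryptic digestion of protein sequences
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and emits
#' every peptide spanning at most `missedCleavages` internal cleavage sites
#' whose length falls within `[minLen, maxLen]`.
#'
#' @param sequences named character vector of protein sequences (names are
#'   accessions), or an [Biostrings::AAStringSet-class].
#' @param minLen,maxLen peptide length bounds (defaults 6 and 50).
#' @param missedCleavages maximum internal missed cleavage sites (default 2).
#' @return named list: accession -> character vector of peptides (unique per
#'   protein, in order of start position).
#' @examples
#' digestProteome(c(p1 = "MAAAAAAKRPGGGGGGK"), missedCleavages = 0)
#' @export
digestProteome <- function(sequences, minLen = 6L, maxLen = 50L,
                           missedCleavages = 2L) {
  if (is(sequences, "AAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("'sequences' must be a non-empty named character vector")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("'sequences' must be named by accession")
  minLen <- assertCount(minLen, "minLen", 1L)
  maxLen <- assertCount(maxLen, "maxLen", minLen)
  missedCleavages <- assertCount(missedCleavages, "missedCleavages", 0L)

  bad <- grepl(paste0("[^", paste(.AA_EXTENDED, collapse = ""), "]"),
               sequences)
  if (any(bad))
    stop("invalid amino-acid characters in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))

  lapply(sequences, function(s) {
    n <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    # cleavage after position p: residue K/R, next residue not P
    sites <- which(ch[-n] %in% c("K", "R") & ch[-1] != "P")
    bounds <- c(0L, sites, n)            # fragment boundaries
    nf <- length(bounds) - 1L
    peps <- character(0)
    for (i in seq_len(nf)) {
      jmax <- min(nf, i + missedCleavages)
      for (j in i:jmax) {
        len <- bounds[j + 1L] - bounds[i]
        if (len >= minLen && len <= maxLen)
          peps <- c(peps, substr(s, bounds[i] + 1L, bounds[j + 1L]))
      }
    }
    unique(peps)
  })
}

#' Construct a trajectory configuration
#'
#' @param infantId label attached to all samples of this time course.
#' @param daysOfLife strictly increasing days of life at sampling.
#' @param humanFractionStart,humanFractionEnd human spectral fraction at the
#'   first/last day; linearly interpolated by day in between.
#' @param mu,sigma log-scale drift and step standard deviation of the per-bin
#'   abundance random walk (recycled over bins).
#' @param seed integer seed.
#' @return a validated [TrajectoryConfig-class] object.
#' @export
TrajectoryConfig <- function(infantId = "I01",
                             daysOfLife = c(11, 15, 18, 21, 25),
                             humanFractionStart = 0.8,
                             humanFractionEnd = 0.2,
                             mu = 0, sigma = 0.35, seed = 17L) {
  new("TrajectoryConfig", infantId = as.character(infantId),
      daysOfLife = as.numeric(daysOfLife),
      humanFractionStart = assertFraction(humanFractionStart,
                                          "humanFractionStart"),
      humanFractionEnd = assertFraction(humanFractionEnd, "humanFractionEnd"),
      mu = as.numeric(mu), sigma = as.numeric(sigma),
      seed = as.integer(seed))
}

#' Simulate per-sample abundance trajectories
#'
#' Runs a log-normal random walk per bin over the configured days of life,
#' renormalizes to relative abundances per sample, and interpolates the human
#' spectral fraction linearly between its start and end values. The resulting
#' truth tables are stored in the community and drive
#' [simulatePsmTables()].
#'
#' @param community a [SyntheticCommunity-class].
#' @param config a [TrajectoryConfig-class] or a list of them (one per
#'   infant); sample ids are `<infant>_d<day>`.
#' @return the community with its `truth` slot filled.
#' @export
simulateAbundanceTrajectories <- function(community, config) {
  stopifnot(is(community, "SyntheticCommunity"))
  if (is(config, "TrajectoryConfig")) config <- list(config)
  stopifnot(all(vapply(config, is, logical(1), "TrajectoryConfig")))
  binIds <- vapply(community@bins, slot, character(1), "binId")
  nb <- length(binIds)

  allAb <- NULL
  allSamples <- NULL
  for (cf in config) {
    validObject(cf)
    set.seed(deriveSeed(cf@seed, 2L))
    days <- cf@daysOfLife
    mu <- rep_len(cf@mu, nb)
    sigma <- rep_len(cf@sigma, nb)
    logA <- stats::rnorm(nb, 0, 1)
    ab <- matrix(NA_real_, length(days), nb,
                 dimnames = list(NULL, binIds))
    for (t in seq_along(days)) {
      if (t > 1L) logA <- logA + stats::rnorm(nb, mu, sigma)
      ab[t, ] <- exp(logA) / sum(exp(logA))
    }
    hf <- if (length(days) == 1L) cf@humanFractionStart else
      cf@humanFractionStart + (cf@humanFractionEnd - cf@humanFractionStart) *
        (days - days[1]) / (days[length(days)] - days[1])
    ids <- sprintf("%s_d%02d", cf@infantId, days)
    rownames(ab) <- ids
    allAb <- rbind(allAb, ab)
    allSamples <- rbind(allSamples, data.frame(
      sample_id = ids, infant = cf@infantId, day_of_life = days,
      human_fraction = hf, stringsAsFactors = FALSE))
  }
  if (anyDuplicated(allSamples$sample_id))
    stop("duplicate sample ids across trajectory configs")
  community@truth <- list(samples = allSamples, abundance = allAb)
  validObject(community)
  community
}
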