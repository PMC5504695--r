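# shared fixtures, built in code at test time

# small two-infant community with truth and PSMs; memoised per session
smallFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cm <- generateCommunity(3, 20, 12, shareRate = 0.1, seed = 17)
    cm <- simulateAbundanceTrajectories(cm, list(
      TrajectoryConfig("I03", c(11, 15, 18), seed = 17),
      TrajectoryConfig("I19", c(12, 20, 26), seed = 23)))
    psms <- simulatePsmTables(cm, depth = 3000, decoyRate = 0.05, seed = 17)
    cache <<- list(community = cm, psms = psms)
    cache
  }
})

# run the inference chain on a PSM table, returning all intermediates
inferChain <- function(community, psms, fdr = 0.02) {
  filt <- filterPsmsByFdr(psms, fdr)
  grouping <- groupProteinsByIdentity(communityProteins(community),
                                      communityBinMap(community))
  graph <- buildPeptideGraph(filt$psms, grouping)
  balanced <- balanceSharedSpectralCounts(graph)
  mpe <- normalizeAndAverage(balanced, filt$runTotals, graph$groups)
  list(filt = filt, grouping = grouping, graph = graph,
       balanced = balanced, mpe = mpe)
}

# hand-made PSM table builder for targeted unit tests
psmRow <- function(peptide, accs, run = "r1", sample = "s1",
                   decoy = FALSE, score = 5, correct = !decoy, n = 1) {
  data.frame(
    spectrum_id = paste0(run, "_", peptide, "_", seq_len(n)),
    run_id = run, sample_id = sample, peptide = peptide,
    protein_accessions = paste(accs, collapse = ";"),
    is_decoy = decoy, score = score, is_correct = correct,
    stringsAsFactors = FALSE)
}

# independent TMM oracle, coded from the published recipe: reference column
# by upper-quartile closeness to the mean; M/A over rows non-zero in both;
# 30% M-trim, 5% A-trim; precision-weighted mean of trimmed M; factors
# rescaled to geometric mean 1
tmmOracle <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    if (k == ref) { f[k] <- 1; next }
    yk <- counts[, k]; yr <- counts[, ref]
    keep <- yk > 0 & yr > 0
    yk <- yk[keep]; yr <- yr[keep]
    M <- log2((yk / lib[k]) / (yr / lib[ref]))
    A <- 0.5 * log2((yk / lib[k]) * (yr / lib[ref]))
    v <- (lib[k] - yk) / (lib[k] * yk) + (lib[ref] - yr) / (lib[ref] * yr)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    f[k] <- 2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# orthologs x runs matrix with planted profile archetypes
plantedArchetypes <- function(nArch = 3, runsPer = 6, nOrth = 60,
                              noise = 0.25, seed = 1) {
  set.seed(seed)
  base <- matrix(rlnorm(nOrth * nArch, 0, 1.5), nOrth, nArch)
  mat <- matrix(0, nOrth, nArch * runsPer)
  labels <- integer(nArch * runsPer)
  for (a in seq_len(nArch)) for (r in seq_len(runsPer)) {
    j <- (a - 1) * runsPer + r
    mat[, j] <- base[, a] * rlnorm(nOrth, 0, noise)
    labels[j] <- a
  }
  dimnames(mat) <- list(sprintf("O%03d", seq_len(nOrth)),
                        sprintf("run%02d", seq_len(ncol(mat))))
  list(matrix = mat, labels = setNames(labels, colnames(mat)))
}

# negative-binomial count matrix for differential-abundance checks
nbCounts <- function(nRows = 1000, n1 = 6, n2 = 6, dispersion = 0.1,
                     nDiff = 0, fold = 4, seed = 1) {
  set.seed(seed)
  mu <- stats::runif(nRows, 50, 500)
  n <- n1 + n2
  mat <- matrix(stats::rnbinom(nRows * n, mu = mu, size = 1 / dispersion),
                nRows, n)
  isDiff <- seq_len(nRows) <= nDiff
  if (nDiff > 0) {
    up <- matrix(stats::rnbinom(nDiff * n2, mu = mu[isDiff] * fold,
                                size = 1 / dispersion), nDiff, n2)
    mat[isDiff, (n1 + 1):n] <- up
  }
  dimnames(mat) <- list(sprintf("g%04d", seq_len(nRows)),
                        sprintf("run%02d", seq_len(n)))
  list(counts = mat,
       clusters = setNames(rep(c("A", "B"), c(n1, n2)), colnames(mat)),
       isDiff = isDiff)
}
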