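#' Cluster-discriminating differential abundance by permutation
#'
#' For every pair of clusters with at least two runs each, tests each row of
#' a spectral count matrix for an abundance difference. Counts are scaled to
#' a common effective library size (library size times TMM factor), shifted
#' by a pseudo-count of 0.5 and log2-transformed. The per-row statistic is
#' studentized: difference of group means divided by (pooled standard error +
#' a stabilizer, the median pooled SE across rows). Group labels are permuted
#' — exhaustively when the number of distinct assignments is at most
#' `nPermutations`, otherwise by random sampling — and two-sided p-values are
#' read off a permutation null pooled across rows, which gives p-value
#' resolution of about 1/(rows x permutations) rather than 1/permutations.
#' Benjamini-Hochberg adjustment is applied across rows within each cluster
#' pair; the 25 most significant rows with p < 0.01 form the per-pair top
#' table.
#'
#' @param counts non-negative matrix, rows (protein groups or orthologs) x
#'   runs.
#' @param assignments named vector run -> cluster id covering all columns.
#' @param nPermutations permutation budget per pair (default 10000).
#' @param seed integer seed for sampled permutations.
#' @param pseudoCount added before log2 (default 0.5).
#' @return list with `pairs` (data.frame of compared pairs), `results`
#'   (named list per pair: data.frame `row`, `effect` log2 fold change,
#'   `statistic`, `p`, `q`), `topTables` (per pair, top 25 at p < 0.01),
#'   `factors` (TMM factors), `skipped` (clusters with < 2 runs).
#' @export
differentialAbundance <- function(counts, assignments, nPermutations = 10000L,
                                  seed = 17L, pseudoCount = 0.5) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)))
  assignments <- assignments[colnames(counts)]
  if (anyNA(assignments))
    stop("cluster assignment missing for some runs")
  nPermutations <- assertCount(nPermutations, "nPermutations", 100L)
  set.seed(deriveSeed(seed, 5L))

  factors <- tmmFactors(counts)
  eff <- colSums(counts) * factors
  norm <- sweep(counts, 2, mean(eff) / eff, "*")
  logMat <- log2(norm + pseudoCount)

  sizes <- table(assignments)
  usable <- names(sizes)[sizes >= 2L]
  skipped <- setdiff(names(sizes), usable)
  if (length(skipped))
    warning("cluster(s) with fewer than two runs skipped: ",
            paste(skipped, collapse = ", "))
  if (length(usable) < 2L)
    stop("need at least two clusters with >= 2 runs")

  pairs <- utils::combn(sort(usable), 2L)
  results <- list()
  topTables <- list()
  for (j in seq_len(ncol(pairs))) {
    c1 <- pairs[1, j]; c2 <- pairs[2, j]
    cols <- names(assignments)[assignments %in% c(c1, c2)]
    X <- logMat[, cols, drop = FALSE]
    grp1 <- assignments[cols] == c1
    res <- permutationTestPair(X, grp1, nPermutations)
    res <- data.frame(row = rownames(counts), effect = res$effect,
                      statistic = res$statistic, p = res$p,
                      q = stats::p.adjust(res$p, method = "BH"),
                      row.names = NULL, stringsAsFactors = FALSE)
    key <- paste(c1, c2, sep = "_vs_")
    results[[key]] <- res
    sig <- res[res$p < 0.01, ]
    sig <- sig[order(sig$p, -abs(sig$statistic)), ]
    topTables[[key]] <- utils::head(sig, 25L)
  }
  list(pairs = data.frame(cluster_a = pairs[1, ], cluster_b = pairs[2, ]),
       results = results, topTables = topTables, factors = factors,
       skipped = skipped)
}

# studentized mean-difference permutation test with a null pooled across rows
permutationTestPair <- function(X, grp1, nPermutations) {
  n <- ncol(X)
  n1 <- sum(grp1)
  n2 <- n - n1
  total <- choose(n, n1)
  if (total <= nPermutations) {
    sel <- utils::combn(n, n1)                # exhaustive labelings
  } else {
    sel <- vapply(seq_len(nPermutations - 1L),
                  function(i) sort(sample.int(n, n1)),
                  integer(n1))
    sel <- cbind(which(grp1), sel)            # include observed labeling
  }
  B <- ncol(sel)
  P <- matrix(0, B, n)
  P[cbind(rep(seq_len(B), each = n1), as.vector(sel))] <- 1

  rowTot <- rowSums(X)
  rowTotSq <- rowSums(X^2)
  S1 <- X %*% t(P)                            # rows x B group-1 sums
  Q1 <- (X^2) %*% t(P)
  m1 <- S1 / n1
  m2 <- (rowTot - S1) / n2
  v1 <- (Q1 - n1 * m1^2) / max(n1 - 1L, 1L)
  v2 <- ((rowTotSq - Q1) - n2 * m2^2) / max(n2 - 1L, 1L)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)) *
    sqrt(1 / n1 + 1 / n2)

  # observed column: the labeling identical to grp1
  obs <- which(apply(P, 1, function(z) all(as.logical(z) == grp1)))[1]
  diffs <- m1 - m2
  s0 <- stats::median(sp[, obs])
  denom <- sp + s0
  stat <- ifelse(denom > 0, diffs / denom,
                 ifelse(diffs == 0, 0, Inf * sign(diffs)))

  pooled <- sort(abs(as.vector(stat)))
  npool <- length(pooled)
  statObs <- stat[, obs]
  # p = fraction of pooled permuted |stat| at least as large as observed
  ge <- npool - findInterval(abs(statObs) - 1e-12, pooled)
  p <- pmax(ge, 1L) / npool
  list(effect = diffs[, obs], statistic = statObs, p = p)
}
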