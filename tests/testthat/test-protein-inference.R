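test_that("FDR prefix selection follows the decoy/target estimator", {
  # 1000 high-scoring targets, 10 decoys mixed in: estimated FDR 0.01
  psms <- rbind(psmRow("PEPTIDEA", "p1", n = 1),
                do.call(rbind, lapply(1:999, function(i)
                  psmRow(paste0("PEP", i, "AK"), "p1", score = 10 - i/1000))),
                do.call(rbind, lapply(1:10, function(i)
                  psmRow(paste0("YEDITPEP", i), "DECOY_p1", decoy = TRUE,
                         score = 9 - i/1000))))
  out <- filterPsmsByFdr(psms, 0.02)
  expect_identical(nrow(out$psms), 1000L)
  expect_equal(out$cutoffs$estimated_fdr, 0.01)

  # boundary: 2/100 = 0.02 is accepted (<= is inclusive)
  psms2 <- rbind(do.call(rbind, lapply(1:100, function(i)
    psmRow(paste0("AAAPEP", i), "p1", score = 10 - i/100))),
    psmRow("YEDITPEPX", "DECOY_p1", decoy = TRUE, score = 9.5),
    psmRow("YEDITPEPY", "DECOY_p1", decoy = TRUE, score = 0.5))
  out2 <- filterPsmsByFdr(psms2, 0.02)
  expect_identical(nrow(out2$psms), 100L)
  expect_equal(out2$cutoffs$estimated_fdr, 0.02)

  # the largest qualifying prefix is taken: the trailing decoy plus five
  # low-scoring targets still satisfy 2/105 <= 0.02
  psms3 <- rbind(psms2, do.call(rbind, lapply(1:5, function(i)
    psmRow(paste0("LOWPEP", i, "K"), "p1", score = 0.1))))
  expect_identical(nrow(filterPsmsByFdr(psms3, 0.02)$psms), 105L)
  # at a 1% threshold the trailing block is excluded
  expect_identical(nrow(filterPsmsByFdr(psms3, 0.01)$psms), 100L)

  expect_error(filterPsmsByFdr(psms[!psms$is_decoy, ]), "inestimable")
  expect_error(filterPsmsByFdr(psms, 1.5), "between 0 and 1")
  # per-run totals kept for normalization
  expect_identical(out$runTotals$total_spectra, 1010L)
})

test_that("per-run filtering chooses independent cutoffs; global pools", {
  fx <- smallFixture()
  perRun <- filterPsmsByFdr(fx$psms, 0.02)
  expect_identical(nrow(perRun$cutoffs), 12L)
  glob <- filterPsmsByFdr(fx$psms, 0.02, global = TRUE)
  expect_identical(nrow(glob$cutoffs), 1L)
  expect_true(all(perRun$cutoffs$estimated_fdr <= 0.02))
  expect_false(any(perRun$psms$is_decoy))
})

test_that("microbial grouping is exact-identity, human grouping greedy", {
  db <- c(m1 = "MAAAKGGGGRCCCC", m2 = "MAAAKGGGGRCCCC",
          m3 = "MAAAKGGGGRCCCD")
  bm <- c(m1 = "binA", m2 = "binB", m3 = "binA")
  g <- groupProteinsByIdentity(db, bm)
  expect_identical(g$assignment[["m1"]], g$assignment[["m2"]])
  expect_false(g$assignment[["m3"]] == g$assignment[["m1"]])

  # two length-10 human sequences differing at one position: identity 0.9
  db2 <- c(h1 = "MAAAAAAAAG", h2 = "MAAAAAAAAC")
  g2 <- groupProteinsByIdentity(db2, c(h1 = "human", h2 = "human"))
  expect_identical(unname(g2$assignment["h1"]), unname(g2$assignment["h2"]))

  expect_error(groupProteinsByIdentity(db, bm[-1]), "missing from bin map")
})

test_that("greedy centroid order groups A/B together and C apart", {
  set.seed(11)
  base <- paste(c("M", sample(c("A","G","L","S","T","V"), 49,
                              replace = TRUE)), collapse = "")
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- 1 + seq_len(k) * 3
    ch[pos] <- ifelse(ch[pos] == "C", "W", "C")
    paste(ch, collapse = "")
  }
  db <- c(A = base, B = mutate(base, 4), C = mutate(base, 10))  # 92% / 80%
  bm <- setNames(rep("human", 3), names(db))
  g <- groupProteinsByIdentity(db, bm, humanThreshold = 0.90)
  expect_identical(unname(g$assignment["A"]), unname(g$assignment["B"]))
  expect_false(g$assignment[["C"]] == g$assignment[["A"]])
})

test_that("grouping is idempotent on representatives", {
  fx <- smallFixture()
  db <- communityProteins(fx$community)
  bm <- communityBinMap(fx$community)
  g1 <- groupProteinsByIdentity(db, bm)
  reps <- g1$groups$representative
  g2 <- groupProteinsByIdentity(db[reps], bm[reps])
  # every representative founds its own group the second time
  expect_identical(nrow(g2$groups), nrow(g1$groups))
})

test_that("two-peptide rule keeps multi-peptide groups only", {
  db <- c(a = "MAAAAAAKGGGGGGK", b = "MCCCCCCKDDDDDDK")
  bm <- c(a = "binA", b = "binB")
  g <- groupProteinsByIdentity(db, bm)
  psms <- rbind(psmRow("MAAAAAAK", "a"), psmRow("GGGGGGK", "a"),
                psmRow("MCCCCCCK", "b", n = 5))
  graph <- buildPeptideGraph(psms, g)
  kept <- graph$groups
  expect_identical(nrow(kept), 1L)
  expect_identical(unname(g$assignment["a"]), kept$group_id)
  expect_identical(length(graph$droppedGroups), 1L)
  expect_identical(graph$orphanPeptides, 1L)
  expect_identical(kept$n_peptides, 2L)
})

test_that("shared spectral counts are balanced proportionally to unique", {
  db <- c(a = "MAAAAAAKGGGGGGKWWWWWWK", b = "MCCCCCCKDDDDDDKWWWWWWK")
  bm <- c(a = "binA", b = "binB")
  g <- groupProteinsByIdentity(db, bm)
  # A: 8 unique spectra, B: 2 unique, shared peptide with 10 spectra
  psms <- rbind(psmRow("MAAAAAAK", "a", n = 4), psmRow("GGGGGGK", "a", n = 4),
                psmRow("MCCCCCCK", "b", n = 1), psmRow("DDDDDDK", "b", n = 1),
                psmRow("WWWWWWK", c("a", "b"), n = 10))
  graph <- buildPeptideGraph(psms, g)
  bal <- balanceSharedSpectralCounts(graph)
  gA <- g$assignment[["a"]]; gB <- g$assignment[["b"]]
  expect_equal(bal[gA, "r1"], 8 + 8)
  expect_equal(bal[gB, "r1"], 2 + 2)
  expect_equal(sum(bal), nrow(psms) * 0 + 20)  # conservation

  # zero unique counts in run r2 but shared spectra present there: 1/k each
  psms3 <- rbind(psmRow("MAAAAAAK", "a"), psmRow("GGGGGGK", "a"),
                 psmRow("MCCCCCCK", "b"), psmRow("DDDDDDK", "b"),
                 psmRow("WWWWWWK", c("a", "b"), run = "r2", n = 10))
  graph3 <- buildPeptideGraph(psms3, g)
  bal3 <- balanceSharedSpectralCounts(graph3)
  expect_equal(bal3[gA, "r2"], 5)
  expect_equal(bal3[gB, "r2"], 5)
})

test_that("per-run balanced counts are conserved on simulated data", {
  fx <- smallFixture()
  ch <- inferChain(fx$community, fx$psms)
  retained <- ch$filt$psms
  # PSMs attached to surviving groups, per run
  pepOk <- retained$peptide %in% ch$graph$edges$peptide
  perRun <- table(retained$run_id[pepOk])
  sums <- colSums(ch$balanced)
  expect_equal(sums[names(perRun)], as.numeric(perRun) + sums * 0,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("normalization divides by run totals and averages replicates", {
  bal <- matrix(c(10, 0, 0, 30, 0, 0), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), c("r1", "r2")))
  rt <- data.frame(run_id = c("r1", "r2"), sample_id = c("s1", "s1"),
                   total_spectra = c(1000, 1000))
  mpe <- normalizeAndAverage(bal, rt)
  expect_equal(runAbundance(mpe)["g1", "r1"], 0.01)
  sa <- sampleAbundance(mpe)
  expect_equal(sa["g1", "s1"], mean(c(0.01, 0.03)))
  expect_equal(sa["g2", "s1"], 0)   # all-zero group stays zero

  rt$total_spectra[2] <- 0
  expect_error(normalizeAndAverage(bal, rt), "r2")
})

test_that("inferred groups recover true bin abundances", {
  fx <- smallFixture()
  ch <- inferChain(fx$community, fx$psms)
  attribution <- assignGroupsToBins(ch$graph$groups,
                                    communityBinMap(fx$community))
  sa <- sampleAbundance(ch$mpe)
  prof <- speciesRelativeAbundance(sa, attribution)
  truth <- communityTruth(fx$community)
  # merged labels are rare here; compare single-bin taxa by correlation
  for (s in rownames(truth$abundance)) {
    sub <- prof$profiles[prof$profiles$sample_id == s, ]
    single <- sub[!grepl("+", sub$taxon, fixed = TRUE), ]
    est <- setNames(single$fraction, single$taxon)
    tru <- truth$abundance[s, names(est)]
    expect_gt(cor(est, tru), 0.9)
  }
})
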