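test_that("community generation honors requested counts and sharing", {
  cm0 <- generateCommunity(3, 50, 20, shareRate = 0, seed = 17)
  micro <- unlist(lapply(communityBins(cm0), binProteins))
  expect_length(micro, 150)
  expect_length(cm0@humanProteins, 20)
  expect_identical(nrow(cm0@sharedPairs), 0L)

  cm <- generateCommunity(2, 10, 0, shareRate = 0.2, seed = 17)
  expect_identical(nrow(cm@sharedPairs), 4L)  # floor(0.2 * 20)
  seqs <- communityProteins(cm)
  expect_true(all(seqs[cm@sharedPairs$accession_a] ==
                    seqs[cm@sharedPairs$accession_b]))

  # every microbial protein annotated with exactly one ortholog
  expect_true(all(names(communityBinMap(cm0))[
    communityBinMap(cm0) != "human"] %in%
      names(communityAnnotations(cm0))))
  expect_error(generateCommunity(0, 10, 5), "nBins")
  expect_error(generateCommunity(2, 10, 5, shareRate = 0.7), "shareRate")
})

test_that("identical seeds give byte-identical communities and PSM tables", {
  make <- function() {
    cm <- generateCommunity(2, 8, 5, shareRate = 0.1, seed = 41)
    cm <- simulateAbundanceTrajectories(
      cm, TrajectoryConfig("I01", c(10, 20), seed = 41))
    psms <- simulatePsmTables(cm, depth = 1000, decoyRate = 0.05, seed = 41)
    list(cm = cm, psms = psms)
  }
  a <- make(); b <- make()
  expect_identical(a$cm, b$cm)
  expect_identical(a$psms, b$psms)
})

test_that("tryptic digestion applies the cleave-after-K/R-not-before-P rule", {
  out <- digestProteome(c(p = "MAAAAAAKRPGGGGGGK"), missedCleavages = 0)
  expect_setequal(out$p, c("MAAAAAAK", "RPGGGGGGK"))

  # both fragments shorter than minimum length
  expect_identical(digestProteome(c(p = "AAAKBBB"), minLen = 6,
                                  missedCleavages = 0)$p,
                   character(0))

  # one missed cleavage: both fragments plus the full-length peptide
  out <- digestProteome(c(p = "MAAAAAAKGGGGGGR"), missedCleavages = 1)
  expect_setequal(out$p, c("MAAAAAAK", "GGGGGGR", "MAAAAAAKGGGGGGR"))

  expect_error(digestProteome(c(bad = "MAAA1AAK")), "bad")
})

test_that("enumerated missed-cleavage peptides match a brute-force oracle", {
  # oracle: enumerate all substrings, keep those starting/ending at
  # cleavage boundaries with at most m internal sites
  oracle <- function(s, minLen, maxLen, m) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    sites <- which(ch[-n] %in% c("K", "R") & ch[-1] != "P")
    bounds <- c(0, sites, n)
    res <- character(0)
    for (i in seq_along(bounds)) for (j in seq_along(bounds)) {
      if (bounds[j] <= bounds[i]) next
      internal <- sum(sites > bounds[i] & sites < bounds[j])
      len <- bounds[j] - bounds[i]
      if (internal <= m && len >= minLen && len <= maxLen)
        res <- c(res, substr(s, bounds[i] + 1, bounds[j]))
    }
    sort(unique(res))
  }
  set.seed(7)
  for (rep in 1:10) {
    s <- paste0("M", paste(sample(c("A", "G", "K", "R", "P", "L"), 40,
                                  replace = TRUE), collapse = ""))
    got <- digestProteome(setNames(s, "x"), minLen = 4, maxLen = 30,
                          missedCleavages = 2)$x
    expect_identical(sort(unique(got)), oracle(s, 4, 30, 2))
  }
})

test_that("abundance trajectories renormalize and interpolate correctly", {
  cm <- generateCommunity(4, 8, 0, shareRate = 0, seed = 5)
  cfg <- TrajectoryConfig("I01", c(10, 20, 30), humanFractionStart = 0.8,
                          humanFractionEnd = 0.2, mu = 0, sigma = 0,
                          seed = 5)
  cm <- simulateAbundanceTrajectories(cm, cfg)
  tr <- communityTruth(cm)
  expect_equal(unname(rowSums(tr$abundance)), rep(1, 3), tolerance = 1e-9)
  # sigma 0, mu 0: constant relative abundances across samples
  expect_equal(tr$abundance[1, ], tr$abundance[3, ])
  expect_equal(tr$samples$human_fraction, c(0.8, 0.5, 0.2))
  expect_error(TrajectoryConfig(daysOfLife = c(10, 10)), "increasing")
  expect_error(TrajectoryConfig(humanFractionStart = 1.2), "humanFraction")
})

test_that("simulated PSM tables have controlled decoy content", {
  fx <- smallFixture()
  psms <- fx$psms
  runs <- unique(psms$run_id)
  expect_length(runs, 12)  # 6 samples x 2 replicates
  perSample <- table(unique(psms[, c("run_id", "sample_id")])$sample_id)
  expect_true(all(perSample == 2))

  # decoy count within Binomial(depth, rate) 99% interval per run
  for (r in runs) {
    nd <- sum(psms$is_decoy[psms$run_id == r])
    bounds <- qbinom(c(0.005, 0.995), 3000, 0.05)
    expect_gte(nd, bounds[1]); expect_lte(nd, bounds[2])
  }
  # decoy rows reference only decoy accessions, reversal is an involution
  dec <- psms[psms$is_decoy, ]
  expect_true(all(startsWith(dec$protein_accessions, "DECOY_")))
  seqs <- communityProteins(fx$community)
  rev2 <- function(x) vapply(strsplit(x, ""), function(c)
    paste(rev(c), collapse = ""), character(1))
  src <- sub("^DECOY_", "", dec$protein_accessions[1:20])
  expect_true(all(mapply(function(p, a) grepl(rev2(p), seqs[[a]],
                                              fixed = TRUE),
                         dec$peptide[1:20], src)))

  cmNoTruth <- generateCommunity(2, 8, 2, seed = 1)
  expect_error(simulatePsmTables(cmNoTruth, depth = 1000), "truth")

  zero <- simulatePsmTables(fx$community, depth = 1000, decoyRate = 0,
                            nReplicates = 1, seed = 3)
  expect_identical(sum(zero$is_decoy), 0L)
})

test_that("fixture bundles round-trip through their plain-text formats", {
  fx <- smallFixture()
  d <- withr::local_tempdir()
  man <- writeFixtureBundle(fx$community, fx$psms, d)
  expect_true(all(file.exists(man$file)))

  # FASTA: one decoy per target
  db <- readProteinDatabase(file.path(d, "database.fasta"),
                            dropDecoys = FALSE)
  targets <- db[!startsWith(names(db), "DECOY_")]
  expect_length(db, 2 * length(targets))
  expect_identical(unname(targets),
                   unname(communityProteins(fx$community)))

  # PSM round-trip reproduces the in-memory table (sans truth labels)
  back <- readPsmTables(list.files(d, "^psms_", full.names = TRUE))
  orig <- fx$psms[, setdiff(colnames(fx$psms), "is_correct")]
  back <- back[order(back$spectrum_id), ]
  orig <- orig[order(orig$spectrum_id), ]
  rownames(back) <- rownames(orig) <- NULL
  expect_equal(back, orig, tolerance = 1e-12)

  # bin map and annotations round-trip
  expect_identical(readBinMap(file.path(d, "bin_map.tsv")),
                   communityBinMap(fx$community))
  expect_identical(readAnnotations(file.path(d, "annotations.tsv")),
                   communityAnnotations(fx$community))

  # module definitions round-trip
  mods <- parseModuleDefinitions(file.path(d, "modules.tsv"))
  orig <- communityModules(fx$community)
  expect_identical(vapply(mods, moduleId, character(1)),
                   vapply(orig, moduleId, character(1)))
  expect_identical(lapply(mods, moduleSteps), lapply(orig, moduleSteps))
  expect_identical(vapply(mods, moduleCategory, character(1)),
                   vapply(orig, moduleCategory, character(1)))
})
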