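mkModule <- function(id = "M1", steps, category = NA_character_) {
  new("ModuleDefinition", moduleId = id, name = id, steps = steps,
      category = category)
}

test_that("module flat files parse blocks, steps and alternatives", {
  path <- withr::local_tempfile(lines = c(
    "MF001\tglycolysis\tcarbohydrate",
    "K00001,K00002",
    "K00003",
    "K00004",
    "///",
    "MF002\tbutyrate kinase route\tbutyrate",
    "K00005",
    "K00006,K00007"))
  mods <- parseModuleDefinitions(path)
  expect_length(mods, 2)
  expect_identical(moduleId(mods[[1]]), "MF001")
  expect_length(moduleSteps(mods[[1]]), 3)
  expect_identical(moduleSteps(mods[[1]])[[1]], c("K00001", "K00002"))
  expect_identical(moduleCategory(mods[[2]]), "butyrate")

  dup <- withr::local_tempfile(lines = c(
    "MF001\ta\t.", "K1", "///", "MF001\tb\t.", "K2"))
  expect_error(parseModuleDefinitions(dup), "duplicate module id")
  emptyMod <- withr::local_tempfile(lines = c("MF001\ta\t."))
  expect_error(parseModuleDefinitions(emptyMod), "no steps")
  badStep <- withr::local_tempfile(lines = c("MF001\ta\t.", "K1,K1"))
  expect_error(parseModuleDefinitions(badStep), "duplicate ortholog")
})

test_that("module scoring computes coverage, abundance and retention", {
  m3 <- mkModule(steps = list("K1", "K2", "K3"))
  # 2 of 3 steps detected: coverage 2/3, retained at the 0.556 cutoff
  sc <- scoreModule(c(K1 = 4, K2 = 10), m3)
  expect_equal(sc$coverage, 2 / 3, tolerance = 1e-9)
  expect_true(sc$retained)
  # 1 of 3: not retained
  sc1 <- scoreModule(c(K1 = 4), m3)
  expect_equal(sc1$coverage, 1 / 3, tolerance = 1e-9)
  expect_false(sc1$retained)
  # median aggregation over detected steps
  sc2 <- scoreModule(c(K1 = 4, K2 = 10, K3 = 6), m3)
  expect_equal(sc2$abundance, 6)
  expect_equal(sc2$coverage, 1)
  # alternatives within a step are summed
  mAlt <- mkModule(steps = list(c("K1", "K2"), "K3"))
  expect_equal(scoreModule(c(K1 = 1, K2 = 2, K3 = 9), mAlt)$abundance,
               median(c(3, 9)))
  # undetected module: zero abundance and coverage
  sc0 <- scoreModule(c(KX = 5), m3)
  expect_equal(sc0$coverage, 0)
  expect_equal(sc0$abundance, 0)
  expect_error(scoreModule(c(K1 = -1), m3), "non-negative")
  expect_error(scoreModule(c(K1 = 1), m3, coverageCutoff = 1.5),
               "coverageCutoff")
})

test_that("coverage is monotone in added ortholog abundance", {
  set.seed(4)
  m <- mkModule(steps = list(c("K1", "K2"), "K3", c("K4", "K5")))
  for (rep in 1:20) {
    v <- setNames(rpois(5, 1), paste0("K", 1:5))
    before <- scoreModule(v, m)$coverage
    v2 <- v; pick <- sample(5, 1); v2[pick] <- v2[pick] + 1
    expect_gte(scoreModule(v2, m)$coverage, before)
  }
})

test_that("per-taxon attribution partitions the community signal", {
  ab <- matrix(c(2, 4, 6, 0, 8, 0), nrow = 3,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  att <- c(g1 = "taxA", g2 = "taxB", g3 = "taxA")
  go <- c(g1 = "K1", g2 = "K1", g3 = "K2")
  m <- mkModule(steps = list("K1", "K2"))
  res <- attributeModuleToTaxa(ab, att, go, m, coverageCutoff = 0.5)
  expect_setequal(unique(res$taxon), c("taxA", "taxB"))
  a1 <- res[res$taxon == "taxA" & res$sample_id == "s1", ]
  expect_equal(a1$coverage, 1)
  b1 <- res[res$taxon == "taxB" & res$sample_id == "s1", ]
  expect_equal(b1$coverage, 0.5)
  # step-level additivity: taxon K1 contributions sum to community K1
  expect_equal(2 + 4, sum(ab[c("g1", "g2"), "s1"]))
  # community coverage >= per-taxon coverage
  comm <- scoreModule(c(K1 = 6, K2 = 6), m)
  expect_true(all(comm$coverage >= res$coverage))
})

test_that("category abundance divides by mapped module count", {
  scores <- data.frame(
    module_id = c("M1", "M2", "M3", "M4"),
    sample_id = "s1",
    coverage = c(1, 1, 0.2, 1),
    abundance = c(6, 2, 9, 5),
    retained = c(TRUE, TRUE, FALSE, TRUE))
  cmap <- c(M1 = "carbohydrate", M2 = "carbohydrate", M3 = "amino_acid",
            M4 = "lipid", M5 = "acetate", M6 = "propionate",
            M7 = "butyrate")
  prof <- categoryAbundance(scores, cmap)
  carb <- prof[prof$category == "carbohydrate", ]
  expect_equal(carb$abundance, (6 + 2) / 2)
  # unretained modules contribute nothing but still count in the divisor
  aa <- prof[prof$category == "amino_acid", ]
  expect_equal(aa$abundance, 0)
  expect_error(categoryAbundance(scores, cmap[1:3]), "lipid")

  # divisor uses mapped count even with unretained members
  scores2 <- data.frame(module_id = c("M1", "M2", "M3"), sample_id = "s1",
                        coverage = c(1, 0, 0), abundance = c(6, 0, 0),
                        retained = c(TRUE, FALSE, FALSE))
  cmap2 <- c(M1 = "carbohydrate", M2 = "carbohydrate", M3 = "carbohydrate",
             M4 = "amino_acid", M5 = "lipid", M6 = "acetate",
             M7 = "propionate", M8 = "butyrate")
  prof2 <- categoryAbundance(scores2, cmap2)
  expect_equal(prof2$abundance[prof2$category == "carbohydrate"], 2)
})

test_that("tri-plot coordinates are barycentric and scale-invariant", {
  prof <- data.frame(sample_id = "s1", triple = "nutrient",
                     category = c("carbohydrate", "amino_acid", "lipid"),
                     abundance = c(4, 4, 8))
  tc <- triplotCoordinates(prof)
  expect_equal(tc$coordinate, c(0.25, 0.25, 0.5))
  expect_equal(sum(tc$coordinate), 1, tolerance = 1e-9)

  corner <- prof; corner$abundance <- c(1, 0, 0)
  expect_equal(triplotCoordinates(corner)$coordinate, c(1, 0, 0))

  scaled <- prof; scaled$abundance <- prof$abundance * 37
  expect_equal(triplotCoordinates(scaled)$coordinate, tc$coordinate)

  zero <- prof; zero$abundance <- 0
  tz <- triplotCoordinates(zero)
  expect_true(all(tz$undefined))
  expect_true(all(is.na(tz$coordinate)))
  neg <- prof; neg$abundance[1] <- -1
  expect_error(triplotCoordinates(neg), "non-negative")
})
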