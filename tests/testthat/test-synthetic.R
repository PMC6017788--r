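test_that("genotype simulation is byte-identical under one seed", {
  sc <- epistasisScenario(nCases = 60L, nControls = 60L, nSnps = 6L,
                          mafRange = c(0.2, 0.4), missingRate = 0.02,
                          seed = 21)
  dir <- withr::local_tempdir()
  g1 <- simulateGenotypes(sc); writePlink(g1, file.path(dir, "a"))
  g2 <- simulateGenotypes(sc); writePlink(g2, file.path(dir, "b"))
  expect_identical(readLines(file.path(dir, "a.ped")),
                   readLines(file.path(dir, "b.ped")))
  expect_identical(readLines(file.path(dir, "a.map")),
                   readLines(file.path(dir, "b.map")))
})

test_that("simulated MAFs are binomially consistent with the scenario", {
  sc <- epistasisScenario(nCases = 500L, nControls = 500L, nSnps = 100L,
                          mafRange = c(0.3, 0.3), seed = 22)
  gm <- simulateGenotypes(sc)
  mafs <- apply(genotypeCalls(gm), 1, snpMaf)
  # mean observed MAF within 3 standard errors of 0.3
  se <- sd(mafs) / sqrt(length(mafs))
  expect_lt(abs(mean(mafs) - 0.3), 3 * se + 1e-12)
  # per-SNP genotypes are near HWE (no mass rejection)
  hwe <- apply(genotypeCalls(gm), 1, function(g)
    hweExactP(sum(g == 0), sum(g == 1), sum(g == 2)))
  expect_lt(mean(hwe < 0.001), 0.05)
})

test_that("a planted pair is reliably detected across seeds", {
  ok <- vapply(1:5, function(s) {
    sc <- epistasisScenario(
      nCases = 1000L, nControls = 1000L, nSnps = 12L,
      mafRange = c(0.3, 0.3),
      plantedPairs = data.frame(snp_i = 1L, snp_j = 2L,
                                beta_int = log(3)), seed = s)
    gm <- simulateGenotypes(sc)
    h <- scanAllPairs(gm, scanConfig(alpha = 1))
    h$snp_a[1] == "snp00001" && h$snp_b[1] == "snp00002" && h$p[1] < 1e-5
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("the drug universe is reproducible and planted as specified", {
  sc <- drugUniverseScenario(seed = 30)
  u1 <- simulateDrugUniverse(sc)
  u2 <- simulateDrugUniverse(sc)
  expect_identical(u1$drugTargets, u2$drugTargets)
  expect_identical(u1$network, u2$network)
  expect_identical(u1$combinations$components, u2$combinations$components)
  # every drug targets at least one gene
  expect_true(all(table(u1$drugTargets$drug_id) >= 1))
  expect_setequal(unique(u1$drugTargets$drug_id),
                  sprintf("d%04d", seq_len(sc$nDrugs)))
  # genes tile without overlap
  expect_true(all(GenomicRanges::countOverlaps(u1$genes, u1$genes) == 1))
  # active fraction near the scenario value
  act <- mean(vapply(u1$combinations$indications,
                     function(i) sc$diseaseLabel %in% i, logical(1)))
  expect_equal(act, sc$fracActiveCombos, tolerance = 0.01)
})

test_that("no active combinations means zero downstream enrichment ratio", {
  uni <- simulateDrugUniverse(drugUniverseScenario(fracActiveCombos = 0,
                                                   seed = 31))
  druggable <- sort(unique(uni$drugTargets$gene))
  pairs <- sampleGenePairs(druggable, 300, seed = 32)
  tp <- toTargetPairs(cbind(pairs, best_p = 1e-6, support = 1L),
                      uni$drugTargets)
  m <- matchCombinationDb(predictCombinations(tp), uni$combinations,
                          uni$diseaseLabel)
  expect_gt(nrow(m), 0)
  expect_equal(mean(m$anti_disease), 0)
})

test_that("network boost at 1 leaves filtration trend at chance", {
  diffs <- vapply(1:12, function(s) {
    uni <- simulateDrugUniverse(
      drugUniverseScenario(diseasePairEdgeBoost = 1, seed = 300 + s))
    druggable <- sort(unique(uni$drugTargets$gene))
    pairs <- sampleGenePairs(druggable, 600, seed = 400 + s)
    tp <- toTargetPairs(cbind(pairs, best_p = 1e-6, support = 1L),
                        uni$drugTargets)
    ratio <- function(p) {
      if (!nrow(p)) return(NA_real_)
      m <- matchCombinationDb(predictCombinations(p), uni$combinations,
                              uni$diseaseLabel)
      if (!nrow(m)) return(NA_real_)
      mean(m$anti_disease)
    }
    ratio(filterByNetwork(tp, uni$network)$pairs) - ratio(tp)
  }, numeric(1))
  # no systematic direction without the planted boost
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.12)
})

test_that("dose-response generation honors the median-effect model", {
  sc <- synergyScenario(noiseSd = 0, targetCi = 1,
                        mA = 1.5, mB = 1.5, DmA = 2, DmB = 2)
  dr <- simulateDoseResponse(sc)
  # identical agents at CI 1 -> the mixture curve equals the single curve
  expect_equal(dr$fa[dr$agent_id == "mix"], dr$fa[dr$agent_id == "A"],
               tolerance = 1e-12)
  # fa at D = Dm is exactly one half
  sc2 <- synergyScenario(noiseSd = 0, doses = c(2, 4), mA = 1.7, DmA = 2)
  dr2 <- simulateDoseResponse(sc2)
  expect_equal(dr2$fa[dr2$agent_id == "A" & dr2$dose_um == 2], 0.5)
  expect_error(synergyScenario(targetCi = 0), "positive")
})
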