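test_that("contingency cubes exclude missing samples and transpose cleanly", {
  calls <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, NA))
  rownames(calls) <- c("s1", "s2")
  gm <- GenotypeMatrix(
    calls,
    data.frame(snp_id = c("s1", "s2"), chrom = "1", pos_bp = c(1L, 2L),
               allele_minor = "A", allele_major = "G"),
    data.frame(sample_id = paste0("i", 1:4),
               phenotype = c("case", "case", "control", "control")))
  cube <- buildCube(gm, "s1", "s2")
  expect_identical(cube["case", "0", "0"], 2L)
  expect_identical(cube["control", "0", "0"], 1L) # 4th sample dropped
  expect_identical(sum(cube), 3L)
  # swapping the SNPs transposes the genotype dimensions
  cubeT <- buildCube(gm, "s2", "s1")
  expected <- aperm(cube, c(1, 3, 2))
  names(dimnames(expected)) <- c("phenotype", "gA", "gB")
  expect_identical(cubeT, expected)
  expect_error(buildCube(gm, "s1", "nope"), "unknown SNP")
})

test_that("both tests are null and symmetric on a no-interaction cube", {
  # identical case rate in all 9 cells
  ctrl <- matrix(20, 3, 3); case <- matrix(20, 3, 3)
  cube <- makeCube(ctrl, case)
  r1 <- genotypeLrt4(cube)
  expect_lt(r1$statistic, 1e-8)
  expect_gt(r1$p, 0.999)
  r2 <- dosageInteraction1(cube)
  expect_gt(r2$p, 0.999)

  set.seed(1)
  cube <- randomCube(800, interaction = 0.4)
  t1 <- genotypeLrt4(cube)$statistic
  t1T <- genotypeLrt4(aperm(cube, c(1, 3, 2)))$statistic
  expect_equal(t1, t1T, tolerance = 1e-9)
  t2 <- dosageInteraction1(cube)$statistic
  t2T <- dosageInteraction1(aperm(cube, c(1, 3, 2)))$statistic
  expect_equal(t2, t2T, tolerance = 1e-9)
})

test_that("statistics are invariant to allele relabeling", {
  set.seed(3)
  cube <- randomCube(700, interaction = 0.5)
  flipped <- cube[, 3:1, ] # relabel which allele is minor at SNP A
  dimnames(flipped)[[2]] <- 0:2
  expect_equal(genotypeLrt4(cube)$statistic,
               genotypeLrt4(flipped)$statistic, tolerance = 1e-8)
  expect_equal(dosageInteraction1(cube)$statistic,
               dosageInteraction1(flipped)$statistic, tolerance = 1e-6)
})

test_that("both tests agree with independent glm refits on random cubes", {
  set.seed(11)
  for (rep in 1:12) {
    cube <- randomCube(500, interaction = runif(1, 0, 0.8))
    mine <- genotypeLrt4(cube)
    orac <- oracleLrt4(cube)
    expect_equal(mine$statistic, orac$statistic, tolerance = 1e-6)
    expect_identical(mine$df, as.integer(orac$df))
    expect_equal(dosageInteraction1(cube)$statistic, oracleDosage1(cube),
                 tolerance = 1e-6)
  }
})

test_that("the LRT matches direct likelihood maximisation", {
  set.seed(1)
  cube <- randomCube(600, interaction = 0.6) # planted-interaction draw
  expect_equal(genotypeLrt4(cube)$statistic, oracleLrt4Optim(cube),
               tolerance = 1e-6)
})

test_that("degrees of freedom collapse with structurally empty cells", {
  ctrl <- matrix(30, 3, 3); case <- matrix(30, 3, 3)
  ctrl[3, 3] <- 0; case[3, 3] <- 0 # one empty interaction cell
  r <- genotypeLrt4(makeCube(ctrl, case))
  expect_identical(r$df, 3L)
  rn <- genotypeLrt4(makeCube(ctrl, case), minCellPolicy = "require_n",
                     minCellN = 5L)
  expect_true(is.nan(rn$p))
})

test_that("scan returns all pairs at alpha 1 and none on a null panel", {
  sc <- epistasisScenario(nCases = 250L, nControls = 250L, nSnps = 10L,
                          mafRange = c(0.2, 0.4), seed = 13)
  gm <- simulateGenotypes(sc)
  all <- scanAllPairs(gm, scanConfig(alpha = 1))
  expect_identical(nrow(all), 45L)
  # canonical pair order and p-sorted
  expect_true(all(all$snp_a < all$snp_b))
  expect_true(!is.unsorted(all$p))
  none <- scanAllPairs(gm, scanConfig(alpha = 1e-5))
  expect_identical(nrow(none), 0L)
  expect_error(scanAllPairs(gm[1, ], scanConfig()), "at least 2 SNPs")
})

test_that("a planted interaction dominates the scan", {
  sc <- epistasisScenario(
    nCases = 600L, nControls = 600L, nSnps = 15L, mafRange = c(0.3, 0.3),
    plantedPairs = data.frame(snp_i = 3L, snp_j = 9L, beta_int = log(3.5)),
    seed = 17)
  gm <- simulateGenotypes(sc)
  for (test in c("genotype_lrt4", "dosage_interaction1")) {
    hits <- scanAllPairs(gm, scanConfig(test = test, alpha = 1))
    expect_identical(c(hits$snp_a[1], hits$snp_b[1]),
                     c("snp00003", "snp00009"))
  }
})
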