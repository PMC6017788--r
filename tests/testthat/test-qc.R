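test_that("per-SNP missingness and MAF follow their definitions", {
  expect_equal(snpMissingRate(c(0L, 1L, 2L, NA)), 0.25)
  expect_equal(snpMissingRate(c(0L, 1L, 2L)), 0)
  expect_equal(snpMissingRate(c(NA_integer_, NA_integer_)), 1)
  expect_error(snpMissingRate(integer(0)), "empty")

  expect_equal(snpMaf(rep(c(0L, 1L), c(90, 10))), 0.05)
  expect_equal(snpMaf(rep(c(0L, 1L, 2L), c(25, 50, 25))), 0.5)
  expect_equal(snpMaf(c(2L, 2L, 2L, 2L)), 0) # folded
  expect_error(snpMaf(c(NA_integer_)), "all calls missing")
})

test_that("HWE exact test matches enumeration and known tables", {
  expect_equal(hweExactP(25, 50, 25), 1.0)
  expect_lt(hweExactP(50, 0, 50), 1e-20)
  expect_equal(hweExactP(0, 0, 10), 1.0)
  expect_error(hweExactP(-1, 0, 1), "negative")
})

test_that("HWE exact test agrees with the recurrence oracle", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(10:500, 1)
    p <- runif(1, 0.05, 0.5)
    g <- rbinom(n, 2, p)
    cnt <- tabulate(g + 1, 3)
    mine <- hweExactP(cnt[1], cnt[2], cnt[3])
    orac <- oracleHweP(cnt[1], cnt[2], cnt[3])
    expect_equal(mine, orac, tolerance = 1e-10)
  }
})

test_that("dosage r-squared captures perfect and null LD", {
  a <- c(0L, 1L, 2L, 0L, 1L, 2L)
  expect_equal(ldR2(a, a), 1)
  expect_equal(ldR2(a, 2L - a), 1) # perfect anticorrelation squares to 1
  set.seed(9)
  x <- rbinom(10000, 2, 0.3); y <- rbinom(10000, 2, 0.3)
  expect_lt(ldR2(x, y), 0.01)
  expect_error(ldR2(c(0L, 0L), c(0L, 1L)), "monomorphic")
})

test_that("QC filters attribute removals exclusively, in order", {
  sc <- epistasisScenario(nCases = 150L, nControls = 150L, nSnps = 12L,
                          mafRange = c(0.2, 0.4), seed = 5)
  gm <- simulateGenotypes(sc)
  calls <- genotypeCalls(gm)
  # SNP 1: 15% missing; SNP 2: rare (MAF ~ 0.01); SNP 3: HWE violation
  calls[1, seq_len(ceiling(0.15 * ncol(calls)))] <- NA
  calls[2, ] <- rbinom(ncol(calls), 2, 0.01)
  calls[3, ] <- sample(rep(c(0L, 2L), length.out = ncol(calls)))
  # SNP 5: duplicate of SNP 4 -> LD prune keeps the earlier one
  calls[5, ] <- calls[4, ]
  gm2 <- GenotypeMatrix(calls, snpInfo(gm),
                        data.frame(sample_id = colnames(calls),
                                   phenotype = as.character(phenotypes(gm))))
  res <- applyQc(gm2)
  stats <- res$report@stats
  expect_identical(stats$filter[1], "missingness")
  expect_identical(stats$filter[2], "maf")
  expect_identical(stats$filter[3], "hwe")
  expect_identical(stats$filter[4], "retained")
  expect_identical(stats$filter[5], "ld")
  # exclusive + exhaustive attribution
  expect_identical(sum(res$report@removed) + length(res$report@retained),
                   nrow(stats))
})

test_that("QC is idempotent and clean panels pass unchanged", {
  sc <- epistasisScenario(nCases = 200L, nControls = 200L, nSnps = 10L,
                          mafRange = c(0.25, 0.45), seed = 6)
  gm <- simulateGenotypes(sc)
  r1 <- applyQc(gm)
  expect_identical(sum(r1$report@removed), 0L)
  expect_identical(dim(r1$genotypes), dim(gm))
  r2 <- applyQc(r1$genotypes)
  expect_identical(genotypeCalls(r2$genotypes), genotypeCalls(r1$genotypes))
  expect_identical(sum(r2$report@removed), 0L)
})

test_that("QC errors when everything would be removed", {
  calls <- matrix(NA_integer_, 3, 10,
                  dimnames = list(paste0("s", 1:3), paste0("i", 1:10)))
  gm <- GenotypeMatrix(
    calls,
    data.frame(snp_id = paste0("s", 1:3), chrom = "1", pos_bp = 1:3,
               allele_minor = "A", allele_major = "G"),
    data.frame(sample_id = paste0("i", 1:10),
               phenotype = rep(c("case", "control"), 5)))
  expect_error(applyQc(gm), "review thresholds")
})
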