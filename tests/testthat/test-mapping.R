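makeGenes <- function(df) {
  GenomicRanges::GRanges(seqnames = df$chrom,
                         ranges = IRanges::IRanges(df$start, df$end),
                         symbol = df$symbol)
}

test_that("SNP-to-gene mapping respects intervals, flanks and overlaps", {
  genes <- makeGenes(data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(1000, 1400, 5000), end = c(2000, 2600, 6000),
    symbol = c("G1", "G2", "G3")))
  snps <- data.frame(snp_id = c("r1", "r2", "r3"),
                     chrom = "chr1", pos_bp = c(1500, 2100, 9000))
  m0 <- mapSnpsToGenes(snps, genes, flankBp = 0)
  expect_setequal(m0$r1, c("G1", "G2")) # inside two overlapping genes
  expect_setequal(m0$r2, "G2") # outside G1 without flank
  expect_identical(m0$r3, character(0))
  m200 <- mapSnpsToGenes(snps, genes, flankBp = 200)
  expect_true("G1" %in% m200$r2) # flank rescues the boundary SNP
})

test_that("gene pairs merge supporting SNP pairs with best p", {
  hits <- data.frame(snp_a = c("r1", "r2", "r3"),
                     snp_b = c("r4", "r5", "r6"),
                     p = c(1e-6, 1e-8, 1e-7))
  snpGenes <- list(r1 = c("G1", "G2"), r4 = "G2",
                   r2 = "G1", r5 = "G2",
                   r3 = "G3", r6 = character(0))
  gp <- pairsToGenePairs(hits, snpGenes)
  # r1-r4 yields (G1,G2) only (G2-G2 self pair dropped); r2-r5 repeats it;
  # r3-r6 maps to nothing
  expect_identical(nrow(gp), 1L)
  expect_identical(c(gp$gene_a, gp$gene_b), c("G1", "G2"))
  expect_equal(gp$best_p, 1e-8)
  expect_identical(gp$support, 2L)
})

test_that("druggability filtering keeps only doubly-targetable pairs", {
  gp <- data.frame(gene_a = c("G1", "G1"), gene_b = c("G2", "G3"),
                   best_p = c(1e-6, 1e-7), support = c(1L, 1L))
  dt <- data.frame(drug_id = c("d1", "d2", "d3"),
                   gene = c("G1", "G2", "G2"))
  tp <- toTargetPairs(gp, dt)
  expect_identical(nrow(tp), 1L) # G3 undruggable
  expect_identical(tp$drugs_a[[1]], "d1")
  expect_setequal(tp$drugs_b[[1]], c("d2", "d3"))
  expect_identical(nrow(toTargetPairs(gp[0, ], dt)), 0L)
})

test_that("combination prediction crosses drug sets without self-pairs", {
  tp <- data.frame(gene_a = "G1", gene_b = "G2",
                   best_p = 1e-6, support = 1L)
  tp$drugs_a <- I(list(c("d1", "d4")))
  tp$drugs_b <- I(list(c("d2", "d3", "d4")))
  pc <- predictCombinations(tp)
  keys <- canonicalPair(pc$drug_a, pc$drug_b)
  expect_true(all(pc$drug_a != pc$drug_b)) # (d4,d4) never emitted
  expect_setequal(keys, c("d1|d2", "d1|d3", "d1|d4", "d2|d4", "d3|d4"))

  # two target pairs producing the same drug pair are merged
  tp2 <- rbind(tp, transform(tp, gene_a = "G5", gene_b = "G6"))
  tp2$drugs_a <- I(list("d1", "d1")); tp2$drugs_b <- I(list("d2", "d2"))
  pc2 <- predictCombinations(tp2)
  expect_identical(nrow(pc2), 1L)
  expect_identical(pc2$n_support, 2L)
})

test_that("database matching uses subset semantics and disease flags", {
  pred <- data.frame(drug_a = c("d1", "d1"), drug_b = c("d2", "d4"))
  db <- data.frame(combo_id = c("c1", "c2"), status = "approved")
  db$components <- I(list(c("d1", "d2", "d3"), c("d2", "d3")))
  db$indications <- I(list("breast cancer", "other"))
  m <- matchCombinationDb(pred, db, "Breast  Cancer")
  expect_identical(m$combo_id, "c1") # subset rule; (d1,d4) matches nothing
  expect_true(m$anti_disease)
  mx <- matchCombinationDb(pred, db, "breast cancer", exactTwo = TRUE)
  expect_identical(nrow(mx), 0L) # c1 has 3 components
})

test_that("top-occurrence gene ranking uses ceil and alphabetical ties", {
  pairs <- data.frame(gene_a = c("G1", "G1"), gene_b = c("G2", "G3"))
  top <- geneOccurrenceTop(pairs, fraction = 0.5)
  expect_identical(top$gene, c("G1", "G2")) # ceil(1.5) = 2; G2 beats G3
  expect_identical(geneOccurrenceTop(pairs, 1.0)$gene, c("G1", "G2", "G3"))
  # the ceil rule returns 159 of 3180 distinct genes at 5%
  expect_identical(ceiling(0.05 * 3180), 159)
  expect_error(geneOccurrenceTop(pairs[0, ]), "no pairs")
})

test_that("shrinking alpha only shrinks the downstream sets", {
  sc <- epistasisScenario(
    nCases = 400L, nControls = 400L, nSnps = 12L, mafRange = c(0.25, 0.4),
    plantedPairs = data.frame(snp_i = 1L, snp_j = 2L, beta_int = log(4)),
    seed = 41)
  gm <- simulateGenotypes(sc)
  genes <- makeGenes(data.frame(chrom = "chr1",
                                start = 10000 * (1:12) - 2000,
                                end = 10000 * (1:12) + 2000,
                                symbol = sprintf("G%02d", 1:12)))
  dt <- data.frame(drug_id = rep(sprintf("d%02d", 1:12), 2),
                   gene = c(sprintf("G%02d", 1:12),
                            sprintf("G%02d", c(2:12, 1))))
  snpGenes <- mapSnpsToGenes(gm, genes, 0)
  sets <- lapply(c(0.05, 1e-4), function(a) {
    h <- scanAllPairs(gm, scanConfig(alpha = a))
    gp <- pairsToGenePairs(h, snpGenes)
    tp <- toTargetPairs(gp, dt)
    list(gp = gp, tp = tp, pc = predictCombinations(tp))
  })
  keyGp <- function(x) canonicalPair(x$gene_a, x$gene_b)
  expect_true(all(keyGp(sets[[2]]$gp) %in% keyGp(sets[[1]]$gp)))
  expect_true(all(keyGp(sets[[2]]$tp) %in% keyGp(sets[[1]]$tp)))
  expect_true(all(canonicalPair(sets[[2]]$pc$drug_a, sets[[2]]$pc$drug_b)
                  %in% canonicalPair(sets[[1]]$pc$drug_a,
                                     sets[[1]]$pc$drug_b)))
})
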