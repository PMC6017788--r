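#' SNP quality-control thresholds
#'
#' Defaults follow the conventional case-control GWAS filter set: missing
#' genotype rate < 0.1, MAF > 0.05, Hardy-Weinberg exact p > 0.001 and
#' pairwise r-squared < 0.8 within a sliding 50-SNP window advanced by 5
#' SNPs.
#'
#' @param maxMissingRate maximum per-SNP missing genotype rate (exclusive).
#' @param minMaf minimum minor allele frequency (exclusive).
#' @param minHweP minimum HWE exact-test p-value (exclusive).
#' @param maxR2 maximum pairwise dosage r-squared (exclusive; pairs at or
#'   above it are pruned).
#' @param r2WindowSnps LD-pruning window size in SNPs.
#' @param r2StepSnps LD-pruning window step in SNPs.
#' @param hweSamples compute HWE on `"controls"` (default) or `"all"`
#'   samples; control-only avoids discarding true disease associations.
#' @return a named list of thresholds.
#' @export
qcThresholds <- function(maxMissingRate = 0.1, minMaf = 0.05,
                         minHweP = 0.001, maxR2 = 0.8,
                         r2WindowSnps = 50L, r2StepSnps = 5L,
                         hweSamples = c("controls", "all")) {
  hweSamples <- match.arg(hweSamples)
  stopifnot(maxMissingRate >= 0, maxMissingRate <= 1,
            minMaf >= 0, minMaf <= 0.5,
            minHweP >= 0, minHweP <= 1,
            maxR2 >= 0, maxR2 <= 1,
            r2WindowSnps >= r2StepSnps, r2StepSnps >= 1)
  list(maxMissingRate = maxMissingRate, minMaf = minMaf, minHweP = minHweP,
       maxR2 = maxR2, r2WindowSnps = as.integer(r2WindowSnps),
       r2StepSnps = as.integer(r2StepSnps), hweSamples = hweSamples)
}

#' Per-SNP missing genotype rate
#'
#' @param column integer vector of dosage calls (0/1/2/NA).
#' @return fraction of missing calls in `[0, 1]`.
#' @export
snpMissingRate <- function(column) {
  if (!length(column)) stop("empty genotype column")
  mean(is.na(column))
}

#' Per-SNP minor allele frequency
#'
#' Minor-allele count over twice the non-missing sample count, folded to
#' `<= 0.5` (guards against panels coded on the major allele).
#'
#' @param column integer vector of dosage calls (0/1/2/NA).
#' @return frequency in `[0, 0.5]`.
#' @export
snpMaf <- function(column) {
  g <- column[!is.na(column)]
  if (!length(g)) stop("undefined statistic: all calls missing")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, sums the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. Probabilities are computed
#' in log space so large samples do not overflow.
#'
#' @param nAA,nAa,naa genotype counts (homozygous major, heterozygous,
#'   homozygous minor).
#' @return p-value in `(0, 1]`.
#' @export
hweExactP <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("parameter error: negative counts")
  n <- nAA + nAa + naa
  if (n == 0) stop("parameter error: no samples")
  nA <- 2 * nAA + nAa # count of the first allele
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(nAa = h | allele counts): log n! - log nAA! - log nAa! - log naa!
  #   + h log 2 - [log (2n)! - log nA! - log na!]
  logP <- function(h) {
    aa <- (rare - h) / 2
    AA <- n - aa - h
    lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(na + 1))
  }
  lp <- vapply(hets, logP, numeric(1))
  lp <- lp - logSumExp(lp) # renormalize to kill rounding drift
  obs <- lp[match(nAa, hets)]
  if (is.na(obs)) stop("parameter error: impossible heterozygote count")
  keep <- lp <= obs + 1e-10
  min(1, exp(logSumExp(lp[keep])))
}

#' Pairwise linkage disequilibrium r-squared on dosages
#'
#' Squared Pearson correlation between two dosage vectors on
#' pairwise-complete samples (composite LD; phase-free and well defined
#' with missing data).
#'
#' @param colA,colB integer vectors of dosage calls (0/1/2/NA).
#' @return r-squared in `[0, 1]`.
#' @export
ldR2 <- function(colA, colB) {
  ok <- !is.na(colA) & !is.na(colB)
  if (sum(ok) < 2) stop("undefined statistic: fewer than 2 complete samples")
  a <- colA[ok]; b <- colB[ok]
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("undefined statistic: monomorphic on complete subset")
  cor(a, b)^2
}

# Greedy windowed LD pruning; returns logical keep vector over SNP indices.
# Within each window, later-positioned members of any pair with r2 >= maxR2
# are dropped, then the window slides by step.
.ldPrune <- function(calls, maxR2, window, step) {
  m <- nrow(calls)
  keep <- rep(TRUE, m)
  if (m < 2) return(keep)
  starts <- seq(1, max(1, m - 1), by = step)
  for (s in starts) {
    e <- min(s + window - 1, m)
    idx <- seq(s, e)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    for (ii in seq_along(idx)[-length(idx)]) {
      i <- idx[ii]
      if (!keep[i]) next
      for (j in idx[(ii + 1):length(idx)]) {
        if (!keep[j]) next
        r2 <- tryCatch(ldR2(calls[i, ], calls[j, ]),
                       error = function(e) 0) # monomorphic pairs pass
        if (r2 >= maxR2) keep[j] <- FALSE
      }
    }
    if (e == m) break
  }
  keep
}

#' Apply SNP quality control to a GenotypeMatrix
#'
#' Filters are applied in fixed order: missingness, MAF, HWE, windowed
#' greedy LD pruning. Attribution is exclusive and exhaustive: each removed
#' SNP is attributed to the first filter it failed. HWE is computed on
#' control samples by default (see [qcThresholds()]). The LD pruner keeps
#' the earlier SNP in map order of any high-LD pair, making the result
#' deterministic given input order.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param thresholds a list from [qcThresholds()].
#' @return a list with elements `genotypes` (filtered
#'   [GenotypeMatrix-class]) and `report` (a [QcReport-class]).
#' @export
applyQc <- function(gm, thresholds = qcThresholds()) {
  calls <- genotypeCalls(gm)
  snps <- snpInfo(gm)
  ph <- phenotypes(gm)
  m <- nrow(calls)

  missRate <- rowMeans(is.na(calls))
  usable <- !is.na(ph)
  hweCols <- if (thresholds$hweSamples == "controls")
    which(ph == "control") else which(usable)

  maf <- hweP <- rep(NA_real_, m)
  filterHit <- rep(NA_character_, m)

  failMiss <- missRate >= thresholds$maxMissingRate
  filterHit[failMiss] <- "missingness"

  for (j in which(!failMiss)) {
    g <- calls[j, ]
    g <- g[!is.na(g)]
    maf[j] <- if (length(g)) sum(g) / (2 * length(g)) else NA_real_
    if (!is.na(maf[j])) maf[j] <- min(maf[j], 1 - maf[j])
  }
  failMaf <- !failMiss & (is.na(maf) | maf <= thresholds$minMaf)
  filterHit[failMaf] <- "maf"

  for (j in which(!failMiss & !failMaf)) {
    g <- calls[j, hweCols]
    g <- g[!is.na(g)]
    hweP[j] <- if (length(g))
      hweExactP(sum(g == 0), sum(g == 1), sum(g == 2)) else 1
  }
  failHwe <- !failMiss & !failMaf & !is.na(hweP) & hweP <= thresholds$minHweP
  filterHit[failHwe] <- "hwe"

  pass3 <- is.na(filterHit)
  idx3 <- which(pass3)
  if (length(idx3) >= 2) {
    keepLd <- .ldPrune(calls[idx3, , drop = FALSE], thresholds$maxR2,
                       thresholds$r2WindowSnps, thresholds$r2StepSnps)
    filterHit[idx3[!keepLd]] <- "ld"
  }

  retained <- is.na(filterHit)
  if (!any(retained))
    stop("pipeline error: QC removed every SNP; review thresholds")

  removed <- vapply(c("missingness", "maf", "hwe", "ld"),
                    function(f) sum(filterHit == f, na.rm = TRUE), integer(1))
  stats <- data.frame(
    snp_id = snps$snp_id, missing_rate = missRate, maf = maf, hwe_p = hweP,
    filter = ifelse(retained, "retained", filterHit),
    stringsAsFactors = FALSE
  )
  report <- new("QcReport", removed = removed,
                retained = snps$snp_id[retained], stats = stats,
                thresholds = thresholds)
  list(genotypes = gm[retained, ], report = report)
}
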