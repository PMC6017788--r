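#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GenotypeMatrix: case-control genotypes as a SummarizedExperiment
#'
#' Container for additive-coded case-control genotypes. SNPs are rows and
#' samples are columns, following the Bioconductor features-by-samples
#' convention. The single assay `"calls"` holds minor-allele dosages coded
#' 0/1/2 with `NA` for missing genotypes. `rowData` carries the SNP panel
#' (`snp_id`, `chrom`, `pos_bp`, `allele_minor`, `allele_major`); `colData`
#' carries `sample_id` and `phenotype`, a factor with levels
#' `c("control", "case")` where `NA` marks samples with unusable phenotype
#' codes (retained but excluded from association tests).
#'
#' @slot .Data inherited SummarizedExperiment slots.
#' @seealso [readPlink()], [simulateGenotypes()], [applyQc()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    calls <- SummarizedExperiment::assay(object, "calls")
    bad <- calls[!is.na(calls)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "calls must be 0, 1, 2 or NA")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("snp_id", "chrom", "pos_bp", "allele_minor", "allele_major")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(rd$snp_id)) msg <- c(msg, "snp_id must be unique")
    if (any(rd$pos_bp < 1)) msg <- c(msg, "pos_bp must be >= 1")
    if (!all(c(rd$allele_minor, rd$allele_major) %in% c("A", "C", "G", "T", "0")))
      msg <- c(msg, "alleles must be in {A,C,G,T,0}")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "phenotype") %in% colnames(cd)))
    msg <- c(msg, "colData must contain sample_id and phenotype")
  else if (!identical(levels(cd$phenotype), c("control", "case")))
    msg <- c(msg, "phenotype must be a factor with levels control, case")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix, SNPs x samples, values 0/1/2/NA.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_minor`, `allele_major`.
#' @param samples data.frame with columns `sample_id` and `phenotype`
#'   (`"case"`, `"control"` or `NA`).
#' @return a [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, snps, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(snps), ncol(calls) == nrow(samples))
  rownames(calls) <- snps$snp_id
  colnames(calls) <- samples$sample_id
  snps$allele_minor <- as.character(snps$allele_minor)
  snps$allele_major <- as.character(snps$allele_major)
  cd <- S4Vectors::DataFrame(
    sample_id = as.character(samples$sample_id),
    phenotype = factor(as.character(samples$phenotype),
                       levels = c("control", "case")),
    row.names = samples$sample_id
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls),
    rowData = S4Vectors::DataFrame(snps, row.names = snps$snp_id),
    colData = cd
  )
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix the dosage matrix (SNPs x samples).
#' @param x,object a GenotypeMatrix.
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @describeIn GenotypeMatrix SNP panel as a data.frame.
#' @export
snpInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn GenotypeMatrix phenotype factor (control/case, NA unusable).
#' @export
phenotypes <- function(x) SummarizedExperiment::colData(x)$phenotype

setMethod("show", "GenotypeMatrix", function(object) {
  ph <- phenotypes(object)
  cat("GenotypeMatrix:", nrow(object), "SNPs x", ncol(object), "samples\n")
  cat("  cases:", sum(ph == "case", na.rm = TRUE),
      " controls:", sum(ph == "control", na.rm = TRUE),
      " unusable:", sum(is.na(ph)), "\n")
  cat("  missing call rate:",
      signif(mean(is.na(genotypeCalls(object))), 3), "\n")
})

#' QcReport: bookkeeping of SNP quality-control filtering
#'
#' @slot removed named integer vector of SNPs removed per filter, in
#'   application order (`missingness`, `maf`, `hwe`, `ld`).
#' @slot retained character vector of surviving SNP ids.
#' @slot stats per-SNP statistics table (missing rate, MAF, HWE p, filter).
#' @slot thresholds the `QcThresholds` list applied.
#' @export
setClass("QcReport", representation(
  removed = "integer", retained = "character",
  stats = "data.frame", thresholds = "list"
))

setValidity("QcReport", function(object) {
  if (sum(object@removed) + length(object@retained) != nrow(object@stats))
    return("removed + retained must equal input SNP count")
  TRUE
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport:", nrow(object@stats), "SNPs in,",
      length(object@retained), "retained\n")
  for (f in names(object@removed))
    cat(sprintf("  removed by %-11s %d\n", paste0(f, ":"), object@removed[[f]]))
})

#' MedianEffectFit: parameters of a Chou-Talalay median-effect line
#'
#' The median-effect model is `fa/fu = (D/Dm)^m` with `fu = 1 - fa`;
#' linearized, `log10(fa/fu) = m log10(D) - m log10(Dm)`. `m` is the
#' sigmoidicity (Hill-type slope), `Dm` the median-effect dose in the dose
#' units of the input (micromolar throughout this package), and `r` the
#' Pearson correlation of the linearized fit.
#'
#' @slot agentId identifier of the agent or mixture.
#' @slot m slope (dimensionless, > 0 for ordinary inhibitors).
#' @slot Dm median-effect dose (same units as the doses).
#' @slot r correlation coefficient of the median-effect line.
#' @slot nPoints number of usable points in the fit.
#' @export
setClass("MedianEffectFit", representation(
  agentId = "character", m = "numeric", Dm = "numeric",
  r = "numeric", nPoints = "integer"
))

setValidity("MedianEffectFit", function(object) {
  msg <- character()
  if (object@Dm <= 0) msg <- c(msg, "Dm must be positive")
  if (object@nPoints < 2) msg <- c(msg, "at least 2 points required")
  if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "|r| must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MedianEffectFit", function(object) {
  cat(sprintf("MedianEffectFit [%s]: m = %.4g, Dm = %.4g uM, r = %.4f (n = %d)\n",
              object@agentId, object@m, object@Dm, object@r, object@nPoints))
})

#' EnrichmentResult: hypergeometric enrichment of a matched set
#'
#' @slot N population size. @slot K population successes.
#' @slot n sample size. @slot k sample successes.
#' @slot ratio `k/n`. @slot backgroundRatio `K/N`.
#' @slot pUpper upper-tail probability `P(X >= k)`.
#' @export
setClass("EnrichmentResult", representation(
  N = "integer", K = "integer", n = "integer", k = "integer",
  ratio = "numeric", backgroundRatio = "numeric", pUpper = "numeric"
))

setValidity("EnrichmentResult", function(object) {
  with_slots <- function(...) TRUE
  msg <- character()
  if (object@k > min(object@n, object@K) || object@k < 0)
    msg <- c(msg, "k must satisfy 0 <= k <= min(n, K)")
  if (object@n > object@N || object@K > object@N)
    msg <- c(msg, "n and K must not exceed N")
  if (object@pUpper <= 0 || object@pUpper > 1)
    msg <- c(msg, "pUpper must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d/%d (%.1f%%) vs background %d/%d (%.1f%%), p = %.3g\n",
              object@k, object@n, 100 * object@ratio,
              object@K, object@N, 100 * object@backgroundRatio, object@pUpper))
})

#' PermutationResult: empirical significance from a permutation null
#'
#' The empirical p-value uses the add-one estimator
#' `(1 + #\{permuted >= observed\}) / (1 + B)`, so it is never exactly zero;
#' with `B = 10000` and zero exceedances it is `1/10001 < 1e-4`.
#'
#' @slot observedStat observed statistic (a drug count).
#' @slot B number of permutations.
#' @slot countGE permuted statistics `>=` observed.
#' @slot pEmp add-one empirical p-value.
#' @slot seed RNG seed used.
#' @slot statistic which drug set was counted (`active_count` /
#'   `approved_count`).
#' @slot permStats the permuted statistics (length `B`).
#' @export
setClass("PermutationResult", representation(
  observedStat = "integer", B = "integer", countGE = "integer",
  pEmp = "numeric", seed = "integer", statistic = "character",
  permStats = "integer"
))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@countGE < 0 || object@countGE > object@B)
    msg <- c(msg, "countGE must be in [0, B]")
  if (object@pEmp <= 1 / (object@B + 1) - 1e-12 || object@pEmp > 1)
    msg <- c(msg, "pEmp must be in (1/(B+1), 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult [%s]: observed = %d, B = %d, p_emp = %.3g\n",
              object@statistic, object@observedStat, object@B, object@pEmp))
})

#' CIResult: combination index at one effect level
#'
#' The mutually exclusive Chou-Talalay index is
#' `CI = d1/Dx1 + d2/Dx2`, where `(d1, d2)` are the component doses in the
#' fixed-ratio mixture producing effect level `fa` and `Dx1`, `Dx2` the
#' single-agent doses for the same effect. `CI < 1` denotes synergism,
#' `CI = 1` additivity and `CI > 1` antagonism.
#'
#' @slot faLevel effect level in (0,1).
#' @slot d1,d2 component doses in the mixture (uM).
#' @slot Dx1,Dx2 single-agent doses for the effect (uM).
#' @slot ci the combination index.
#' @slot classification one of `synergistic`, `additive`, `antagonistic`.
#' @slot form `exclusive` or `nonexclusive`.
#' @export
setClass("CIResult", representation(
  faLevel = "numeric", d1 = "numeric", d2 = "numeric",
  Dx1 = "numeric", Dx2 = "numeric", ci = "numeric",
  classification = "character", form = "character"
))

setMethod("show", "CIResult", function(object) {
  cat(sprintf("CIResult: CI = %.4g at fa = %.2f (%s, %s form)\n",
              object@ci, object@faLevel, object@classification, object@form))
})
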