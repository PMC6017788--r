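#' Scan configuration for pairwise interaction testing
#'
#' @param test `"genotype_lrt4"` (4-df genotype likelihood-ratio test, the
#'   BOOST-family statistic) or `"dosage_interaction1"` (1-df Wald test of
#'   the dosage-product term, the PLINK/FastEpistasis-family statistic).
#' @param alpha significance threshold on the interaction p-value
#'   (default `1e-5`).
#' @param minCellPolicy `"collapse_df"` (reduce the LRT degrees of freedom
#'   by one per structurally empty genotype cell) or `"require_n"` (flag
#'   pairs with any cell below `minCellN`).
#' @param minCellN minimum cell count under `require_n`.
#' @param maxPairsReported cap on reported hits (`Inf` = unlimited).
#' @return a named list.
#' @export
scanConfig <- function(test = c("genotype_lrt4", "dosage_interaction1"),
                       alpha = 1e-5,
                       minCellPolicy = c("collapse_df", "require_n"),
                       minCellN = 5L, maxPairsReported = Inf) {
  stopifnot(alpha > 0, alpha <= 1)
  list(test = match.arg(test), alpha = alpha,
       minCellPolicy = match.arg(minCellPolicy),
       minCellN = as.integer(minCellN), maxPairsReported = maxPairsReported)
}

#' Build the 2x3x3 contingency cube for a SNP pair
#'
#' Cross-tabulates phenotype by the genotypes of two SNPs. Samples with an
#' unusable phenotype or a missing call at either SNP are excluded. The
#' cube is the sufficient statistic for both interaction tests.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param snpA,snpB SNP ids.
#' @return 2x3x3 integer array with dimnames
#'   `phenotype (control, case) x gA (0,1,2) x gB (0,1,2)`.
#' @export
buildCube <- function(gm, snpA, snpB) {
  snps <- rownames(gm)
  ia <- match(snpA, snps); ib <- match(snpB, snps)
  if (is.na(ia) || is.na(ib))
    stop("lookup error: unknown SNP id ",
         paste(c(snpA, snpB)[is.na(c(ia, ib))], collapse = ", "))
  calls <- genotypeCalls(gm)
  .buildCubeFast(calls[ia, ], calls[ib, ],
                 as.integer(phenotypes(gm)) - 1L)
}

# ga, gb: integer dosages with NA; ph: 0 control, 1 case, NA unusable
.buildCubeFast <- function(ga, gb, ph) {
  ok <- !is.na(ga) & !is.na(gb) & !is.na(ph)
  bin <- 1L + ga[ok] + 3L * gb[ok] + 9L * ph[ok]
  counts <- tabulate(bin, nbins = 18L)
  array(counts, dim = c(3, 3, 2),
        dimnames = list(gA = 0:2, gB = 0:2, phenotype = c("control", "case"))
  ) |> aperm(c(3, 1, 2))
}

# --- weighted logistic IRLS on grouped (cell) data -------------------------
# X: design matrix (cells x p), y: case counts, tot: cell totals.
# Returns beta, vcov, deviance-scale log-likelihood, convergence flag.
.irlsLogit <- function(X, y, tot, maxIter = 200L, tol = 1e-13) {
  p <- ncol(X)
  beta <- rep(0, p)
  llOld <- -Inf
  converged <- FALSE
  XtWX <- NULL
  for (iter in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    # guard saturation
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- tot * mu * (1 - mu)
    z <- eta + (y - tot * mu) / w
    XtWX <- crossprod(X, X * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(converged = FALSE, separation = TRUE))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, w * z)))
    ll <- sum(y * log(mu) + (tot - y) * log(1 - mu))
    if (is.finite(llOld) &&
        abs(ll - llOld) < tol * (abs(ll) + tol)) { converged <- TRUE; break }
    llOld <- ll
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (tot - y) * log(1 - mu))
  separation <- any(abs(beta) > 30)
  list(beta = drop(beta), vcov = chol2inv(chol(XtWX)), ll = ll,
       converged = converged, separation = separation)
}

# saturated grouped log-likelihood of a cube (cells fit their own rate)
.llSaturated <- function(y, tot) {
  p <- y / tot
  sum(ifelse(y > 0, y * log(p), 0) +
        ifelse(tot - y > 0, (tot - y) * log(1 - p), 0))
}

.cubeCells <- function(cube) {
  # returns data on non-empty genotype cells
  tot <- cube["control", , ] + cube["case", , ]
  idx <- which(tot > 0, arr.ind = TRUE)
  list(
    gA = idx[, 1] - 1L, gB = idx[, 2] - 1L,
    y = cube["case", , ][idx], tot = tot[idx]
  )
}

#' 4-df genotype likelihood-ratio interaction test
#'
#' Likelihood-ratio test comparing the saturated genotype model
#' `phenotype ~ factor(gA) * factor(gB)` with the main-effects model
#' `phenotype ~ factor(gA) + factor(gB)`, both logistic, fitted on the
#' contingency cube by iteratively reweighted least squares. With all nine
#' genotype cells occupied the reference distribution is chi-squared with
#' 4 degrees of freedom; under the `collapse_df` policy the degrees of
#' freedom shrink by one per structurally empty cell.
#'
#' @param cube a 2x3x3 array from [buildCube()].
#' @param minCellPolicy,minCellN see [scanConfig()].
#' @return list with `statistic`, `df`, `p` and a diagnostic `note`
#'   (`NA` when clean; non-convergence or separation yields `p = NaN`).
#' @export
genotypeLrt4 <- function(cube, minCellPolicy = "collapse_df", minCellN = 5L) {
  cc <- .cubeCells(cube)
  nCase <- sum(cc$y); nCtrl <- sum(cc$tot) - nCase
  if (nCase == 0 || nCtrl == 0)
    stop("parameter error: both phenotype classes required")
  if (length(unique(cc$gA)) < 2 || length(unique(cc$gB)) < 2)
    stop("parameter error: both SNPs must have >= 2 observed genotypes")
  if (minCellPolicy == "require_n" &&
      any(cube["control", , ] + cube["case", , ] < minCellN))
    return(list(statistic = NA_real_, df = NA_integer_, p = NaN,
                note = "cell below require_n minimum"))

  fA <- factor(cc$gA); fB <- factor(cc$gB)
  X <- stats::model.matrix(~ fA + fB)
  fit <- .irlsLogit(X, cc$y, cc$tot)
  if (isTRUE(fit$separation) || !isTRUE(fit$converged))
    return(list(statistic = NA_real_, df = NA_integer_, p = NaN,
                note = "main-effects fit did not converge"))
  llSat <- .llSaturated(cc$y, cc$tot)
  stat <- 2 * (llSat - fit$ll)
  if (stat < 0) {
    if (stat < -1e-8) return(list(statistic = NA_real_, df = NA_integer_,
                                  p = NaN, note = "negative deviance"))
    stat <- 0
  }
  df <- length(cc$y) - ncol(X)
  if (df < 1)
    return(list(statistic = stat, df = 0L, p = NaN,
                note = "no interaction degrees of freedom"))
  list(statistic = stat, df = as.integer(df),
       p = pchisq(stat, df, lower.tail = FALSE), note = NA_character_)
}

#' 1-df dosage interaction test
#'
#' Logistic regression on additive dosages,
#' `logit P(case) = b0 + b1 gA + b2 gB + b3 gA gB`, with a Wald chi-squared
#' test of `b3 = 0` (1 df). Collinear design columns are dropped; if the
#' interaction column itself is collinear the pair is flagged.
#'
#' @inheritParams genotypeLrt4
#' @return list with `statistic`, `df`, `p`, `note`.
#' @export
dosageInteraction1 <- function(cube, minCellPolicy = "collapse_df",
                               minCellN = 5L) {
  cc <- .cubeCells(cube)
  nCase <- sum(cc$y); nCtrl <- sum(cc$tot) - nCase
  if (nCase == 0 || nCtrl == 0)
    stop("parameter error: both phenotype classes required")
  if (length(unique(cc$gA)) < 2 || length(unique(cc$gB)) < 2)
    stop("parameter error: both SNPs must have >= 2 observed genotypes")
  if (minCellPolicy == "require_n" &&
      any(cube["control", , ] + cube["case", , ] < minCellN))
    return(list(statistic = NA_real_, df = NA_integer_, p = NaN,
                note = "cell below require_n minimum"))

  X <- cbind(1, cc$gA, cc$gB, cc$gA * cc$gB)
  colnames(X) <- c("b0", "gA", "gB", "gAxgB")
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  if (!(4 %in% keep))
    return(list(statistic = NA_real_, df = NA_integer_, p = NaN,
                note = "interaction column collinear"))
  X <- X[, sort(keep), drop = FALSE]
  fit <- .irlsLogit(X, cc$y, cc$tot)
  if (isTRUE(fit$separation) || !isTRUE(fit$converged))
    return(list(statistic = NA_real_, df = NA_integer_, p = NaN,
                note = "separation or non-convergence"))
  j <- which(colnames(X) == "gAxgB")
  stat <- fit$beta[j]^2 / fit$vcov[j, j]
  list(statistic = stat, df = 1L,
       p = pchisq(stat, 1, lower.tail = FALSE), note = NA_character_)
}

#' Exhaustive pairwise SNP-SNP interaction scan
#'
#' Tests every unordered SNP pair of the panel with the configured
#' statistic and returns the pairs significant at `alpha`, sorted by
#' p-value then canonical pair id. The scan is exact and exhaustive
#' (O(m^2) pairs); no screening heuristics are applied.
#'
#' @param gm a QC'd [GenotypeMatrix-class].
#' @param config a list from [scanConfig()].
#' @return data.frame of hits: `snp_a`, `snp_b` (canonical order), `test`,
#'   `statistic`, `df`, `p`, `n_used`, `note`.
#' @export
scanAllPairs <- function(gm, config = scanConfig()) {
  m <- nrow(gm)
  if (m < 2) stop("parameter error: need at least 2 SNPs")
  calls <- genotypeCalls(gm)
  ph <- as.integer(phenotypes(gm)) - 1L
  snpIds <- rownames(gm)
  testFun <- if (config$test == "genotype_lrt4") genotypeLrt4
             else dosageInteraction1

  nPairs <- choose(m, 2)
  outA <- outB <- character(nPairs)
  outStat <- outP <- numeric(nPairs)
  outDf <- outN <- integer(nPairs)
  outNote <- character(nPairs)
  k <- 0L
  for (i in seq_len(m - 1)) {
    gi <- calls[i, ]
    for (j in (i + 1):m) {
      k <- k + 1L
      cube <- .buildCubeFast(gi, calls[j, ], ph)
      res <- tryCatch(
        testFun(cube, config$minCellPolicy, config$minCellN),
        error = function(e) list(statistic = NA_real_, df = NA_integer_,
                                 p = NaN, note = conditionMessage(e)))
      pk <- canonicalPair(snpIds[i], snpIds[j], collapse = FALSE)
      outA[k] <- pk[1]; outB[k] <- pk[2]
      outStat[k] <- res$statistic
      outDf[k] <- if (is.null(res$df) || is.na(res$df)) NA_integer_
                  else as.integer(res$df)
      outP[k] <- res$p
      outN[k] <- sum(cube)
      outNote[k] <- if (is.na(res$note)) NA_character_ else res$note
    }
  }
  hits <- data.frame(
    snp_a = outA, snp_b = outB, test = config$test, statistic = outStat,
    df = outDf, p = outP, n_used = outN, note = outNote,
    stringsAsFactors = FALSE
  )
  flagged <- is.nan(hits$p)
  if (any(flagged))
    logMsg(sum(flagged), " pair(s) flagged (p = NaN): ",
           paste(unique(hits$note[flagged]), collapse = "; "))
  keep <- !is.na(hits$p) & !is.nan(hits$p) & hits$p < config$alpha
  hits <- hits[keep | flagged, , drop = FALSE]
  ord <- order(hits$p, canonicalPair(hits$snp_a, hits$snp_b))
  hits <- hits[ord, , drop = FALSE]
  if (is.finite(config$maxPairsReported) &&
      nrow(hits) > config$maxPairsReported)
    hits <- hits[seq_len(config$maxPairsReported), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
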