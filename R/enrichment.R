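#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` successes in `n` draws without replacement from a population
#' of `N` containing `K` successes. Computed by log-space summation of the
#' exact pmf terms `C(K,i) C(N-K,n-i) / C(N,n)` for `i = k .. min(n, K)`,
#' so extreme tails (down to ~1e-300) keep full relative precision.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size (draws).
#' @param k observed successes.
#' @return upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeomUpper(1363, 53, 617, 41)
#' @export
hypergeomUpper <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K)
  n <- as.integer(n); k <- as.integer(k)
  if (K > N || n > N || k < 0 || k > n)
    stop("parameter error: require K <= N, n <= N, 0 <= k <= n")
  if (k == 0) return(1)
  hi <- min(n, K)
  if (k > hi) stop("parameter error: k exceeds min(n, K)")
  i <- k:hi
  logTerms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(logSumExp(logTerms)))
}

#' Enrichment of a disease flag in a matched set
#'
#' Summarizes a matched record set against an explicit background: the
#' sample is the `n` matched records, successes are those flagged, and the
#' background `(K, N)` is supplied by the caller (backgrounds differ by
#' analysis, e.g. the whole combination database vs. an upstream matched
#' set, so they are never inferred).
#'
#' @param matched data.frame with a logical `anti_disease` column (see
#'   [matchCombinationDb()]), or an integer count `k` with `n` supplied.
#' @param backgroundK,backgroundN background successes and population size.
#' @param n sample size override when `matched` is a count.
#' @return an [EnrichmentResult-class].
#' @export
enrich <- function(matched, backgroundK, backgroundN, n = NULL) {
  if (is.data.frame(matched)) {
    n <- nrow(matched)
    k <- sum(matched$anti_disease)
  } else {
    k <- as.integer(matched)
    if (is.null(n)) stop("parameter error: n required with a count")
  }
  if (n == 0) stop("undefined statistic: empty matched set")
  new("EnrichmentResult",
      N = as.integer(backgroundN), K = as.integer(backgroundK),
      n = as.integer(n), k = as.integer(k),
      ratio = k / n, backgroundRatio = backgroundK / backgroundN,
      pUpper = hypergeomUpper(backgroundN, backgroundK, n, k))
}

#' Permutation null for drug hits on target pairs
#'
#' Assesses whether the number of distinct "success" drugs (clinically
#' active or approved for the disease) hitting the observed target pairs
#' could arise from random target pairing. Each of `B` permutations draws
#' the same number of distinct unordered gene pairs uniformly from the
#' druggable-gene universe; the statistic is the number of distinct
#' success drugs targeting at least one member of at least one drawn pair.
#' The empirical p-value uses the add-one estimator, so with `B = 10000`
#' and an observed value exceeding every permuted one it is
#' `1/10001 < 1e-4`.
#'
#' @param pairs observed pairs: data.frame with `gene_a`, `gene_b`.
#' @param drugTargets data.frame `drug_id`, `gene`.
#' @param successDrugs character vector of success drug ids (e.g. the
#'   clinically active, or the approved, drugs for the disease).
#' @param B number of permutations (default 10000).
#' @param seed RNG seed.
#' @param statistic label recorded in the result (`"active_count"` or
#'   `"approved_count"`).
#' @param universe optional explicit druggable-gene universe; defaults to
#'   all genes in `drugTargets`.
#' @return a [PermutationResult-class].
#' @export
permutationNull <- function(pairs, drugTargets, successDrugs, B = 10000L,
                            seed = 1L,
                            statistic = c("active_count", "approved_count"),
                            universe = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(universe)) universe <- sort(unique(drugTargets$gene))
  u <- length(universe)
  nPairs <- nrow(pairs)
  if (u < 2) stop("parameter error: universe must have >= 2 genes")
  if (nPairs < 1) stop("parameter error: need >= 1 observed pair")
  if (nPairs > choose(u, 2))
    stop("parameter error: more pairs than the universe supports")

  successDrugs <- unique(successDrugs)
  dt <- drugTargets[drugTargets$drug_id %in% successDrugs, , drop = FALSE]
  # per-gene integer ids of success drugs targeting it
  drugId <- match(dt$drug_id, successDrugs)
  byGene <- split(drugId, dt$gene)
  geneDrugs <- rep(list(integer(0)), u)
  names(geneDrugs) <- universe
  common <- intersect(names(byGene), universe)
  geneDrugs[common] <- lapply(byGene[common], unique)

  countHits <- function(genes) {
    length(unique(unlist(geneDrugs[genes], use.names = FALSE)))
  }
  observed <- countHits(intersect(unique(c(pairs$gene_a, pairs$gene_b)),
                                  universe))

  set.seed(seed)
  totalPairs <- choose(u, 2)
  permStats <- integer(B)
  for (b in seq_len(B)) {
    idx <- if (totalPairs <= .Machine$integer.max)
      sample.int(totalPairs, nPairs) else
        unique(ceiling(runif(nPairs * 2) * totalPairs))[seq_len(nPairs)]
    ij <- decodePairIndex(idx, u)
    permStats[b] <- countHits(universe[unique(as.vector(ij))])
  }
  countGE <- sum(permStats >= observed)
  new("PermutationResult",
      observedStat = as.integer(observed), B = as.integer(B),
      countGE = as.integer(countGE), pEmp = (1 + countGE) / (1 + B),
      seed = as.integer(seed), statistic = statistic,
      permStats = permStats)
}
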