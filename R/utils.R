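#' @importFrom methods new validObject is slot
#' @importFrom stats lm coef plogis qlogis rbinom runif rnorm setNames
#'   pchisq dhyper phyper cor complete.cases uniroot
#' @importFrom utils read.table read.csv write.table head combn
NULL

# Internal logging: everything informational goes to stderr so that result
# streams stay clean for composition.
logMsg <- function(...) message("[episynergy] ", ...)

#' Canonical key for an unordered pair
#'
#' All unordered pair types in the package (SNP pairs, gene pairs, drug
#' pairs, network edges) are stored with the lexicographically smaller
#' member first. This helper canonicalizes vectors of pairs and, optionally,
#' collapses them to a single string key.
#'
#' @param a,b character vectors of equal length.
#' @param collapse if `TRUE` return `"a|b"` keys, else a two-column matrix.
#' @return a character vector of keys, or a two-column character matrix.
#' @examples
#' canonicalPair("G2", "G1")
#' @export
canonicalPair <- function(a, b, collapse = TRUE) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  if (collapse) paste(lo, hi, sep = "|") else cbind(lo, hi)
}

#' Normalize a drug, gene or disease label
#'
#' Trims surrounding whitespace, collapses internal whitespace runs to one
#' space and case-folds to lower case. An optional synonym table (a
#' two-column data.frame `from`, `to`) is applied after normalization, so
#' free-text labels can be mapped onto a controlled vocabulary without a
#' full terminology service.
#'
#' @param x character vector of labels.
#' @param synonyms optional data.frame with columns `from` and `to`.
#' @return normalized character vector.
#' @export
normalizeLabel <- function(x, synonyms = NULL) {
  y <- tolower(trimws(gsub("[[:space:]]+", " ", as.character(x))))
  if (!is.null(synonyms)) {
    stopifnot(all(c("from", "to") %in% names(synonyms)))
    from <- tolower(trimws(gsub("[[:space:]]+", " ", synonyms$from)))
    to <- tolower(trimws(gsub("[[:space:]]+", " ", synonyms$to)))
    hit <- match(y, from)
    y[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  y
}

# log(sum(exp(x))) with the usual max shift; used by the exact tail sums.
logSumExp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Decode linear indices 1..choose(n,2) into (i,j) with i<j, row-major over i.
# Used to sample distinct unordered pairs uniformly without materializing
# the full pair list.
decodePairIndex <- function(idx, n) {
  # pairs are ordered (1,2),(1,3),...,(1,n),(2,3),...
  idx <- as.numeric(idx)
  i <- n - 1 - floor((sqrt(8 * (choose(n, 2) - idx) + 1) - 1) / 2)
  first <- choose(n, 2) - choose(n - i + 1, 2) # pairs before row i
  j <- i + (idx - first)
  cbind(as.integer(i), as.integer(j))
}
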