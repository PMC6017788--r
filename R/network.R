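#' Filter target pairs by a gene co-opening network
#'
#' Retains exactly the target pairs whose canonical gene pair is an edge of
#' the network (strict edge membership, no path relaxation). Genes absent
#' from the network remove their pairs; the report records how much of the
#' input gene set the network covers.
#'
#' @param pairs data.frame of target (or gene) pairs with `gene_a`,
#'   `gene_b`.
#' @param network canonical edge list from [readNetwork()].
#' @return list with `pairs` (the retained subset) and `report` (a list:
#'   `input_pairs`, `retained_pairs`, `coverage`).
#' @export
filterByNetwork <- function(pairs, network) {
  if (!nrow(network))
    stop("parameter error: empty network would silently remove every pair")
  edgeKeys <- canonicalPair(network$gene_a, network$gene_b)
  pairKeys <- canonicalPair(pairs$gene_a, pairs$gene_b)
  keep <- pairKeys %in% edgeKeys
  inputGenes <- unique(c(pairs$gene_a, pairs$gene_b))
  netGenes <- unique(c(network$gene_a, network$gene_b))
  coverage <- if (length(inputGenes))
    mean(inputGenes %in% netGenes) else 0
  if (length(inputGenes) && coverage == 0)
    warning("no input gene occurs in the network; all pairs removed")
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = out,
       report = list(input_pairs = nrow(pairs),
                     retained_pairs = nrow(out),
                     coverage = coverage))
}

#' Union of target-pair sets across scans
#'
#' Pools pair sets (e.g. the hits of several interaction tests) into one
#' deduplicated set, keeping the minimum `best_p` and summing `support`
#' per distinct pair.
#'
#' @param pairSets list of data.frames with `gene_a`, `gene_b` and
#'   optionally `best_p`, `support`.
#' @return deduplicated data.frame.
#' @export
unionPairs <- function(pairSets) {
  pairSets <- Filter(function(x) !is.null(x) && nrow(x) > 0, pairSets)
  if (!length(pairSets))
    return(data.frame(gene_a = character(), gene_b = character(),
                      best_p = numeric(), support = integer()))
  all <- do.call(rbind, lapply(pairSets, function(x) {
    data.frame(gene_a = x$gene_a, gene_b = x$gene_b,
               best_p = if ("best_p" %in% names(x)) x$best_p else NA_real_,
               support = if ("support" %in% names(x)) x$support else 1L,
               stringsAsFactors = FALSE)
  }))
  key <- canonicalPair(all$gene_a, all$gene_b)
  agg <- lapply(split(seq_len(nrow(all)), key), function(ix) {
    c(best_p = suppressWarnings(min(all$best_p[ix], na.rm = TRUE)),
      support = sum(all$support[ix]))
  })
  keys <- sort(names(agg))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  vals <- do.call(rbind, agg[keys])
  out <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                    best_p = ifelse(is.finite(vals[, "best_p"]),
                                    vals[, "best_p"], NA_real_),
                    support = as.integer(vals[, "support"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
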