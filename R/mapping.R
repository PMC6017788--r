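#' Map SNPs to genes by interval overlap with flanks
#'
#' A SNP maps to every gene on the same chromosome whose interval,
#' symmetrically extended by `flankBp`, contains the SNP position. The
#' default flank of 20 kb is a conservative proximity rule for assigning
#' regulatory variants to nearby genes; it is recorded in every report.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos_bp` (e.g.
#'   from [snpInfo()]), or a [GenotypeMatrix-class].
#' @param genes a `GRanges` with a `symbol` metadata column (see
#'   [readGeneIntervals()]).
#' @param flankBp non-negative flank in base pairs (default 20000).
#' @return named list: for each `snp_id`, a character vector of gene
#'   symbols (possibly empty).
#' @export
mapSnpsToGenes <- function(snps, genes, flankBp = 20000L) {
  stopifnot(flankBp >= 0)
  if (is(snps, "GenotypeMatrix")) snps <- snpInfo(snps)
  snpGr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos_bp, width = 1)
  )
  ext <- GenomicRanges::resize(genes,
                               width = GenomicRanges::width(genes) +
                                 2L * as.integer(flankBp),
                               fix = "center")
  ov <- suppressWarnings(GenomicRanges::findOverlaps(snpGr, ext))
  out <- rep(list(character(0)), nrow(snps))
  names(out) <- snps$snp_id
  if (length(ov)) {
    sp <- split(genes$symbol[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
    out[as.integer(names(sp))] <- lapply(sp, function(s) sort(unique(s)))
  }
  out
}

#' Collapse epistatic SNP pairs to gene pairs
#'
#' Each significant SNP pair contributes the cross product of the two SNPs'
#' gene sets; same-gene pairs are discarded; duplicate gene pairs across
#' SNP pairs are merged keeping the minimum p-value and counting the
#' supporting SNP pairs.
#'
#' @param hits data.frame from [scanAllPairs()] (columns `snp_a`, `snp_b`,
#'   `p`).
#' @param snpGenes named list from [mapSnpsToGenes()].
#' @return data.frame: `gene_a`, `gene_b` (canonical order), `best_p`,
#'   `support`.
#' @export
pairsToGenePairs <- function(hits, snpGenes) {
  if (!nrow(hits))
    return(data.frame(gene_a = character(), gene_b = character(),
                      best_p = numeric(), support = integer()))
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(hits))) {
    ga <- snpGenes[[hits$snp_a[r]]]
    gb <- snpGenes[[hits$snp_b[r]]]
    if (!length(ga) || !length(gb)) next
    grid <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (!nrow(grid)) next
    keys <- unique(canonicalPair(grid$a, grid$b))
    p <- hits$p[r]
    for (k in keys) {
      cur <- acc[[k]]
      if (is.null(cur)) acc[[k]] <- c(p, 1)
      else acc[[k]] <- c(min(cur[1], p), cur[2] + 1)
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(gene_a = character(), gene_b = character(),
                      best_p = numeric(), support = integer()))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  vals <- do.call(rbind, mget(keys, envir = acc))
  out <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                    best_p = vals[, 1], support = as.integer(vals[, 2]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$best_p, out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

#' Restrict gene pairs to druggable target pairs
#'
#' Keeps gene pairs in which both members are targeted by at least one
#' drug, attaching the targeting drug sets as list-columns.
#'
#' @param genePairs data.frame from [pairsToGenePairs()].
#' @param drugTargets data.frame with columns `drug_id`, `gene`.
#' @return data.frame: `gene_a`, `gene_b`, `best_p`, `support`, list
#'   columns `drugs_a`, `drugs_b`.
#' @export
toTargetPairs <- function(genePairs, drugTargets) {
  byGene <- split(drugTargets$drug_id, drugTargets$gene)
  da <- byGene[genePairs$gene_a]
  db <- byGene[genePairs$gene_b]
  keep <- lengths(da) > 0 & lengths(db) > 0
  out <- genePairs[keep, , drop = FALSE]
  out$drugs_a <- I(lapply(da[keep], function(x) sort(unique(x))))
  out$drugs_b <- I(lapply(db[keep], function(x) sort(unique(x))))
  rownames(out) <- NULL
  out
}

#' Predict drug combinations from target pairs
#'
#' For each target pair, every drug pair `(a, b)` with `a` targeting one
#' member and `b` the other (and `a != b`) is a predicted combination.
#' Predictions are canonicalized and deduplicated across target pairs,
#' with supporting target-pair keys unioned.
#'
#' @param targetPairs data.frame from [toTargetPairs()].
#' @return data.frame: `drug_a`, `drug_b` (canonical), `n_support`, and a
#'   list-column `supporting_pairs` of `gene_a|gene_b` keys.
#' @export
predictCombinations <- function(targetPairs) {
  if (!nrow(targetPairs))
    return(data.frame(drug_a = character(), drug_b = character(),
                      n_support = integer(),
                      supporting_pairs = I(list())))
  recs <- vector("list", nrow(targetPairs))
  for (r in seq_len(nrow(targetPairs))) {
    da <- targetPairs$drugs_a[[r]]; db <- targetPairs$drugs_b[[r]]
    grid <- expand.grid(a = da, b = db, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (!nrow(grid)) next
    recs[[r]] <- data.frame(
      key = unique(canonicalPair(grid$a, grid$b)),
      pair = canonicalPair(targetPairs$gene_a[r], targetPairs$gene_b[r]),
      stringsAsFactors = FALSE
    )
  }
  allRec <- do.call(rbind, recs)
  if (is.null(allRec) || !nrow(allRec))
    return(data.frame(drug_a = character(), drug_b = character(),
                      n_support = integer(),
                      supporting_pairs = I(list())))
  sup <- lapply(split(allRec$pair, allRec$key), function(x) sort(unique(x)))
  keys <- sort(names(sup))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(drug_a = parts[, 1], drug_b = parts[, 2],
             n_support = unname(lengths(sup[keys])),
             supporting_pairs = I(unname(sup[keys])),
             stringsAsFactors = FALSE)
}

#' Match predicted combinations against a combination database
#'
#' A database record matches when any predicted drug pair is a subset of
#' its component set ("contain" semantics; a two-drug prediction matches a
#' three-drug record that includes both). Each matched record is flagged
#' `anti_disease` when the queried disease label, after synonym
#' normalization, appears among its indications.
#'
#' @param predicted data.frame from [predictCombinations()].
#' @param db combination records from [readCombinations()].
#' @param diseaseLabel disease label of interest.
#' @param synonyms optional synonym table (see [normalizeLabel()]).
#' @param exactTwo if `TRUE`, only records with exactly the two predicted
#'   components match.
#' @return data.frame of matched records with an `anti_disease` logical
#'   column.
#' @export
matchCombinationDb <- function(predicted, db, diseaseLabel,
                               synonyms = NULL, exactTwo = FALSE) {
  label <- normalizeLabel(diseaseLabel, synonyms)
  predKeys <- character(0)
  if (nrow(predicted))
    predKeys <- unique(canonicalPair(predicted$drug_a, predicted$drug_b))
  predSet <- new.env(parent = emptyenv())
  for (k in predKeys) predSet[[k]] <- TRUE

  matched <- logical(nrow(db))
  for (r in seq_len(nrow(db))) {
    comp <- db$components[[r]]
    if (exactTwo && length(comp) != 2) next
    if (length(comp) < 2) next
    cmb <- combn(sort(comp), 2)
    keys <- paste(cmb[1, ], cmb[2, ], sep = "|")
    matched[r] <- any(vapply(keys, function(k)
      !is.null(predSet[[k]]), logical(1)))
  }
  out <- db[matched, , drop = FALSE]
  out$anti_disease <- vapply(out$indications, function(ind)
    label %in% normalizeLabel(ind, synonyms), logical(1))
  rownames(out) <- NULL
  out
}

#' Genes with the top fraction of pair occurrences
#'
#' Counts how often each gene occurs across pairs and returns the
#' `ceiling(fraction * distinct gene count)` most frequent genes,
#' descending by count with alphabetical tie-break.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param fraction fraction of distinct genes to return (default 0.05).
#' @return data.frame: `gene`, `count`, ranked.
#' @export
geneOccurrenceTop <- function(pairs, fraction = 0.05) {
  if (!nrow(pairs)) stop("parameter error: no pairs")
  stopifnot(fraction > 0, fraction <= 1)
  counts <- table(c(pairs$gene_a, pairs$gene_b))
  nTop <- ceiling(fraction * length(counts))
  tab <- data.frame(gene = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$gene), ]
  out <- head(tab, nTop)
  rownames(out) <- NULL
  out
}
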