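#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the PLINK whitespace-delimited text formats. The `.map` file must
#' have four columns (chromosome, SNP id, genetic distance, base-pair
#' position); the `.ped` file has six leading columns (family, individual,
#' father, mother, sex, phenotype) followed by two allele columns per SNP,
#' with `"0"` denoting a missing allele. Phenotype code 2 is read as case
#' and 1 as control; samples with any other code are retained with `NA`
#' phenotype and excluded from association tests.
#'
#' Dosages are coded as the count of the dataset-relative minor allele: the
#' minor allele is the rarer of the two observed alleles in the file itself,
#' ties broken alphabetically. A genotype with either allele missing is `NA`.
#'
#' @param pedPath,mapPath paths to the `.ped` and `.map` files.
#' @return a [GenotypeMatrix-class].
#' @export
readPlink <- function(pedPath, mapPath) {
  map <- read.table(mapPath, header = FALSE, colClasses = "character")
  if (ncol(map) != 4)
    stop("format error: .map must have 4 columns, found ", ncol(map),
         " in ", mapPath)
  names(map) <- c("chrom", "snp_id", "cM", "pos_bp")
  m <- nrow(map)

  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  expected <- 6 + 2 * m
  nf <- lengths(fields)
  if (any(nf != expected)) {
    bad <- which(nf != expected)[1]
    stop("format error: .ped line ", bad, " has ", nf[bad],
         " fields, expected ", expected, " for ", m, " SNPs")
  }
  ped <- do.call(rbind, fields)
  n <- nrow(ped)

  phenoCode <- ped[, 6]
  phenotype <- rep(NA_character_, n)
  phenotype[phenoCode == "2"] <- "case"
  phenotype[phenoCode == "1"] <- "control"
  sampleId <- ped[, 2]
  if (anyDuplicated(sampleId))
    sampleId <- paste(ped[, 1], ped[, 2], sep = "_")

  a1 <- ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE] # n x m
  a2 <- ped[, 6 + 2 * seq_len(m), drop = FALSE]
  okAllele <- c("A", "C", "G", "T", "0")
  if (!all(a1 %in% okAllele) || !all(a2 %in% okAllele)) {
    offending <- unique(c(a1[!a1 %in% okAllele], a2[!a2 %in% okAllele]))
    stop("format error: non-ACGT0 allele(s): ",
         paste(offending, collapse = ", "))
  }

  calls <- matrix(NA_integer_, nrow = m, ncol = n)
  minorAllele <- majorAllele <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) == 0) {
      minorAllele[j] <- "0"; majorAllele[j] <- "0"
      next
    }
    if (length(alleles) > 2)
      stop("format error: SNP ", map$snp_id[j], " has >2 alleles")
    counts <- table(factor(obs, levels = alleles))
    if (length(alleles) == 1) {
      majorAllele[j] <- alleles; minorAllele[j] <- "0"
      calls[j, !miss] <- 0L
    } else {
      # rarer allele is minor; exact tie broken alphabetically
      minor <- if (counts[1] <= counts[2]) alleles[1] else alleles[2]
      major <- setdiff(alleles, minor)
      minorAllele[j] <- minor; majorAllele[j] <- major
      calls[j, !miss] <- (x1[!miss] == minor) + (x2[!miss] == minor)
    }
  }

  snps <- data.frame(
    snp_id = map$snp_id, chrom = map$chrom,
    pos_bp = as.integer(map$pos_bp),
    allele_minor = minorAllele, allele_major = majorAllele,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = sampleId, phenotype = phenotype,
                        stringsAsFactors = FALSE)
  GenotypeMatrix(calls, snps, samples)
}

#' Write a GenotypeMatrix as PLINK text (.ped/.map)
#'
#' Inverse of [readPlink()]: dosage 0 becomes homozygous major, 1
#' heterozygous, 2 homozygous minor, `NA` becomes `0 0`. Phenotype is
#' written as 2 (case), 1 (control) or 0 (unusable).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(gm, prefix) {
  snps <- snpInfo(gm)
  calls <- genotypeCalls(gm)
  ph <- phenotypes(gm)
  map <- data.frame(snps$chrom, snps$snp_id, 0, snps$pos_bp)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  n <- ncol(calls); m <- nrow(calls)
  phCode <- ifelse(is.na(ph), "0", ifelse(ph == "case", "2", "1"))
  # allele strings per SNP x dosage level
  lines <- vapply(seq_len(n), function(i) {
    g <- calls[, i]
    x1 <- ifelse(is.na(g), "0",
                 ifelse(g >= 1, snps$allele_minor, snps$allele_major))
    x2 <- ifelse(is.na(g), "0",
                 ifelse(g == 2, snps$allele_minor, snps$allele_major))
    paste(c("FAM", colnames(calls)[i], "0", "0", "0", phCode[i],
            as.vector(rbind(x1, x2))), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read gene annotation intervals
#'
#' Reads gene intervals into a `GRanges` with a `symbol` metadata column.
#' Coordinates are 1-based inclusive internally; the `bed_0based` dialect
#' (0-based half-open) is converted on read by adding 1 to starts.
#' Duplicate rows (same symbol and coordinates) are dropped with a warning.
#'
#' @param path TSV file. For `tsv_1based` the columns are
#'   (chrom, start, end, symbol), header optional and auto-detected by the
#'   `chrom` header token; `bed_0based` expects headerless BED3+name.
#' @param dialect `"tsv_1based"` (default) or `"bed_0based"`.
#' @return a [GenomicRanges::GRanges] with `symbol` metadata.
#' @export
readGeneIntervals <- function(path, dialect = c("tsv_1based", "bed_0based")) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1)
  if (length(first) == 0 || !nzchar(trimws(first))) {
    warning("empty gene interval file: ", path)
    return(GenomicRanges::GRanges(symbol = character()))
  }
  hasHeader <- grepl("chrom", first, ignore.case = TRUE)
  tab <- read.table(path, header = hasHeader, sep = "\t",
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("no gene intervals in ", path)
    return(GenomicRanges::GRanges(symbol = character()))
  }
  names(tab)[1:4] <- c("chrom", "start", "end", "symbol")
  start <- as.integer(tab$start)
  end <- as.integer(tab$end)
  if (dialect == "bed_0based") start <- start + 1L
  if (any(start > end))
    stop("format error: interval start > end for ",
         tab$symbol[which(start > end)[1]])
  if (any(!nzchar(tab$symbol))) stop("format error: empty gene symbol")
  key <- paste(tab$chrom, start, end, tab$symbol)
  if (anyDuplicated(key)) {
    warning("dropped ", sum(duplicated(key)), " duplicate gene interval(s)")
    keep <- !duplicated(key)
    tab <- tab[keep, ]; start <- start[keep]; end <- end[keep]
  }
  GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    symbol = tab$symbol
  )
}

.readTsvChecked <- function(path, required) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("format error: ", path, " missing required column(s): ",
         paste(missing, collapse = ", "))
  tab
}

#' Read a drug-target table
#'
#' Expects a TSV with header columns `drug_id` and `gene`. Drug and gene
#' names are normalized (trim, case-fold, whitespace collapse; gene symbols
#' upper-cased) and duplicate (drug, gene) rows are dropped.
#'
#' @param path TSV path.
#' @param synonyms optional synonym data.frame passed to [normalizeLabel()].
#' @return data.frame with columns `drug_id`, `gene`.
#' @export
readDrugTargets <- function(path, synonyms = NULL) {
  tab <- .readTsvChecked(path, c("drug_id", "gene"))
  tab$drug_id <- normalizeLabel(tab$drug_id, synonyms)
  tab$gene <- toupper(normalizeLabel(tab$gene))
  tab <- unique(tab[, c("drug_id", "gene")])
  rownames(tab) <- NULL
  tab
}

#' Read a drug indication table
#'
#' TSV with header columns `drug_id`, `disease`, `status`.
#'
#' @inheritParams readDrugTargets
#' @return data.frame with normalized `drug_id` and `disease`.
#' @export
readIndications <- function(path, synonyms = NULL) {
  tab <- .readTsvChecked(path, c("drug_id", "disease", "status"))
  tab$drug_id <- normalizeLabel(tab$drug_id, synonyms)
  tab$disease <- normalizeLabel(tab$disease, synonyms)
  unique(tab)
}

#' Read a drug-combination database table
#'
#' TSV with header columns `combo_id`, `components` (`;`-separated drug
#' ids), `indications` (`;`-separated disease labels) and `status`
#' (`approved` / `investigational`). Combination components absent from a
#' supplied drug-target table trigger a referential warning, not an error.
#'
#' @inheritParams readDrugTargets
#' @param drugTargets optional drug-target data.frame for referential
#'   checking.
#' @return data.frame with list-columns `components` and `indications`.
#' @export
readCombinations <- function(path, synonyms = NULL, drugTargets = NULL) {
  tab <- .readTsvChecked(path, c("combo_id", "components", "indications",
                                 "status"))
  if (anyDuplicated(tab$combo_id)) stop("format error: duplicate combo_id")
  comp <- lapply(strsplit(tab$components, ";", fixed = TRUE),
                 function(x) sort(unique(normalizeLabel(x, synonyms))))
  if (any(lengths(comp) < 2))
    stop("format error: combination with fewer than 2 components: ",
         tab$combo_id[which(lengths(comp) < 2)[1]])
  ind <- lapply(strsplit(tab$indications, ";", fixed = TRUE),
                function(x) unique(normalizeLabel(x, synonyms)))
  if (!is.null(drugTargets)) {
    unknown <- setdiff(unique(unlist(comp)), unique(drugTargets$drug_id))
    if (length(unknown))
      warning(length(unknown),
              " combination component drug(s) absent from drug-target table")
  }
  data.frame(
    combo_id = tab$combo_id,
    components = I(comp),
    indications = I(ind),
    status = normalizeLabel(tab$status),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-gene network edge list
#'
#' TSV with header columns `gene_a`, `gene_b`. Edges are canonicalized
#' (lexicographically smaller symbol first), self-loops dropped with a
#' warning and duplicates merged.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_a`, `gene_b` (canonical).
#' @export
readNetwork <- function(path) {
  tab <- .readTsvChecked(path, c("gene_a", "gene_b"))
  a <- toupper(normalizeLabel(tab$gene_a))
  b <- toupper(normalizeLabel(tab$gene_b))
  self <- a == b
  if (any(self)) {
    warning("dropped ", sum(self), " self-loop(s)")
    a <- a[!self]; b <- b[!self]
  }
  pk <- canonicalPair(a, b, collapse = FALSE)
  edges <- unique(data.frame(gene_a = pk[, 1], gene_b = pk[, 2],
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  edges
}

#' Read a disease gene list
#'
#' TSV with a header column `gene`.
#' @param path TSV path.
#' @return character vector of upper-cased gene symbols.
#' @export
readDiseaseGenes <- function(path) {
  tab <- .readTsvChecked(path, "gene")
  sort(unique(toupper(normalizeLabel(tab$gene))))
}

#' Read dose-response measurements
#'
#' CSV with header columns `agent_id`, `dose_um`, `fa` (fraction affected).
#' Doses must be strictly positive and `fa` in `[0, 1]`.
#'
#' @param path CSV path.
#' @return data.frame with one row per measurement.
#' @export
readDoseResponse <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("agent_id", "dose_um", "fa"), names(tab))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(tab$dose_um <= 0)) stop("format error: doses must be positive")
  if (any(tab$fa < 0 | tab$fa > 1)) stop("format error: fa must be in [0,1]")
  tab
}
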