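#' Assemble a pipeline configuration
#'
#' Collects the input paths and stage parameters for [runPipeline()]. All
#' statistical defaults are the conventional ones used throughout the
#' package: QC thresholds (0.1 missingness, 0.05 MAF, 0.001 HWE, 0.8
#' r-squared), scan alpha `1e-5`, 20 kb SNP-to-gene flank and a
#' 10,000-draw permutation null.
#'
#' @param pedPath,mapPath PLINK text genotypes.
#' @param genesPath gene interval TSV.
#' @param drugTargetsPath,combinationsPath,networkPath,diseaseGenesPath
#'   resource TSVs (see the readers in this package for the headers).
#' @param diseaseLabel disease label for indication matching.
#' @param outDir output directory (created if absent).
#' @param thresholds [qcThresholds()] list.
#' @param scan [scanConfig()] list.
#' @param flankBp SNP-to-gene flank.
#' @param backgroundK,backgroundN enrichment background (successes,
#'   population).
#' @param permB,permSeed,permStatistic permutation-null settings.
#' @param seed global seed (used where a stage has no explicit seed).
#' @return a config list.
#' @export
pipelineConfig <- function(pedPath, mapPath, genesPath, drugTargetsPath,
                           combinationsPath, networkPath, diseaseGenesPath,
                           diseaseLabel, outDir,
                           thresholds = qcThresholds(),
                           scan = scanConfig(),
                           flankBp = 20000L,
                           backgroundK = NULL, backgroundN = NULL,
                           permB = 10000L, permSeed = NULL,
                           permStatistic = "active_count",
                           seed = 1L) {
  cfg <- list(pedPath = pedPath, mapPath = mapPath, genesPath = genesPath,
              drugTargetsPath = drugTargetsPath,
              combinationsPath = combinationsPath,
              networkPath = networkPath,
              diseaseGenesPath = diseaseGenesPath,
              diseaseLabel = diseaseLabel, outDir = outDir,
              thresholds = thresholds, scan = scan,
              flankBp = as.integer(flankBp),
              backgroundK = backgroundK, backgroundN = backgroundN,
              permB = as.integer(permB),
              permSeed = if (is.null(permSeed)) as.integer(seed)
                         else as.integer(permSeed),
              permStatistic = permStatistic, seed = as.integer(seed))
  .validatePipelineConfig(cfg)
  cfg
}

.validatePipelineConfig <- function(cfg) {
  paths <- c(cfg$pedPath, cfg$mapPath, cfg$genesPath, cfg$drugTargetsPath,
             cfg$combinationsPath, cfg$networkPath, cfg$diseaseGenesPath)
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop("config error: missing input file(s): ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

.writeTsv <- function(x, path) {
  flat <- x
  for (col in names(flat))
    if (is.list(flat[[col]]))
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ";")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the epistasis-to-combination pipeline end to end
#'
#' Stages, in order: SNP quality control; exhaustive pairwise interaction
#' scan; SNP-to-gene mapping and target-pair/combination construction
#' with database matching; hypergeometric enrichment of the matched set;
#' permutation null for drug hits; co-opening-network filtration; and
#' enrichment of the filtered matched set. Every stage writes a TSV under
#' `outDir`; the returned manifest records counts, seeds, thresholds and
#' an md5 checksum of every output, so identical configs yield identical
#' checksums.
#'
#' @param config list from [pipelineConfig()].
#' @return the run manifest (a list), invisibly classed
#'   `"episynergy_manifest"`.
#' @export
runPipeline <- function(config) {
  .validatePipelineConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  stages <- character(0)
  counts <- list()
  t0 <- Sys.time()
  stage <- function(name, expr) {
    logMsg("stage ", name, " ...")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  # qc
  gm <- readPlink(config$pedPath, config$mapPath)
  qc <- stage("qc", applyQc(gm, config$thresholds))
  writePlink(qc$genotypes, out("filtered"))
  .writeTsv(qc$report@stats, out("qc_report.tsv"))
  counts$snps_in <- nrow(gm)
  counts$snps_retained <- length(qc$report@retained)

  # scan
  hits <- stage("scan", scanAllPairs(qc$genotypes, config$scan))
  .writeTsv(hits[, setdiff(names(hits), "note")], out("hits.tsv"))
  counts$significant_pairs <- sum(!is.nan(hits$p))

  # map
  genes <- readGeneIntervals(config$genesPath)
  drugTargets <- readDrugTargets(config$drugTargetsPath)
  db <- readCombinations(config$combinationsPath, drugTargets = drugTargets)
  mapRes <- stage("map", {
    snpGenes <- mapSnpsToGenes(qc$genotypes, genes, config$flankBp)
    genePairs <- pairsToGenePairs(hits[!is.nan(hits$p), ], snpGenes)
    targetPairs <- toTargetPairs(genePairs, drugTargets)
    predicted <- predictCombinations(targetPairs)
    matched <- matchCombinationDb(predicted, db, config$diseaseLabel)
    list(genePairs = genePairs, targetPairs = targetPairs,
         predicted = predicted, matched = matched)
  })
  .writeTsv(mapRes$genePairs, out("gene_pairs.tsv"))
  .writeTsv(mapRes$targetPairs[, c("gene_a", "gene_b", "best_p", "support")],
            out("target_pairs.tsv"))
  .writeTsv(mapRes$predicted, out("predicted_combinations.tsv"))
  .writeTsv(mapRes$matched[, c("combo_id", "status", "anti_disease")],
            out("matched_db.tsv"))
  if (nrow(mapRes$genePairs))
    .writeTsv(geneOccurrenceTop(mapRes$genePairs), out("top_genes.tsv"))
  counts$gene_pairs <- nrow(mapRes$genePairs)
  counts$target_pairs <- nrow(mapRes$targetPairs)
  counts$predicted_combinations <- nrow(mapRes$predicted)
  counts$matched_combinations <- nrow(mapRes$matched)

  # enrich (unfiltered)
  bgK <- if (is.null(config$backgroundK))
    sum(vapply(db$indications, function(i)
      normalizeLabel(config$diseaseLabel) %in% i, logical(1)))
  else config$backgroundK
  bgN <- if (is.null(config$backgroundN)) nrow(db) else config$backgroundN
  enr <- stage("enrich", if (nrow(mapRes$matched))
    enrich(mapRes$matched, bgK, bgN) else NULL)
  counts$enrichment <- if (!is.null(enr))
    list(k = enr@k, n = enr@n, ratio = enr@ratio, p = enr@pUpper) else NULL

  # permutation null
  indic <- tryCatch(readCombinations(config$combinationsPath),
                    error = function(e) NULL)
  activeDrugs <- unique(unlist(db$components[vapply(db$indications,
    function(i) normalizeLabel(config$diseaseLabel) %in% i, logical(1))]))
  perm <- stage("permute", if (nrow(mapRes$targetPairs) &&
                               length(activeDrugs))
    permutationNull(mapRes$targetPairs, drugTargets, activeDrugs,
                    B = config$permB, seed = config$permSeed,
                    statistic = config$permStatistic) else NULL)
  counts$permutation <- if (!is.null(perm))
    list(observed = perm@observedStat, p_emp = perm@pEmp) else NULL

  # network filtration + enrichment of the filtered set
  network <- readNetwork(config$networkPath)
  filt <- stage("filter_network",
                filterByNetwork(mapRes$targetPairs, network))
  .writeTsv(filt$pairs[, c("gene_a", "gene_b", "best_p", "support")],
            out("filtered_pairs.tsv"))
  counts$filtered_pairs <- nrow(filt$pairs)

  enrF <- stage("enrich_filtered", {
    predF <- predictCombinations(filt$pairs)
    matchedF <- matchCombinationDb(predF, db, config$diseaseLabel)
    if (nrow(matchedF)) enrich(matchedF, bgK, bgN) else NULL
  })
  counts$enrichment_filtered <- if (!is.null(enrF))
    list(k = enrF@k, n = enrF@n, ratio = enrF@ratio, p = enrF@pUpper)
  else NULL

  outputs <- list.files(config$outDir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("episynergy")),
    started = format(t0), stages = stages, counts = counts,
    thresholds = config$thresholds, scan = config$scan,
    flankBp = config$flankBp, seed = config$seed,
    permSeed = config$permSeed,
    background = list(K = bgK, N = bgN),
    filter_report = filt$report,
    checksums = as.list(tools::md5sum(sort(outputs)))
  )
  class(manifest) <- "episynergy_manifest"
  invisible(manifest)
}

#' Human-readable pipeline summary
#'
#' Tabulates the counts at each stage of a completed run: SNPs retained,
#' significant pairs, gene and target pairs, predicted and matched
#' combinations, enrichment ratios with backgrounds and p-values, and the
#' permutation result.
#'
#' @param manifest a manifest from [runPipeline()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
pipelineReport <- function(manifest) {
  if (!inherits(manifest, "episynergy_manifest") ||
      length(manifest$stages) < 7)
    stop("reporting error: incomplete manifest")
  cnt <- manifest$counts
  fmtEnr <- function(e, label) {
    if (is.null(e)) return(sprintf("%s: 0/0 matched", label))
    sprintf("%s: %d/%d (%.1f%%) vs background %d/%d (%.1f%%), p = %.3g",
            label, e$k, e$n, 100 * e$ratio,
            manifest$background$K, manifest$background$N,
            100 * manifest$background$K / manifest$background$N, e$p)
  }
  lines <- c(
    sprintf("SNPs: %d in, %d retained after QC", cnt$snps_in,
            cnt$snps_retained),
    sprintf("Significant SNP pairs (alpha = %g): %d",
            manifest$scan$alpha, cnt$significant_pairs),
    sprintf("Gene pairs: %d", cnt$gene_pairs),
    sprintf("Druggable target pairs: %d", cnt$target_pairs),
    sprintf("Predicted drug combinations: %d",
            cnt$predicted_combinations),
    sprintf("Matched database combinations: %d",
            cnt$matched_combinations),
    fmtEnr(cnt$enrichment, "Enrichment (unfiltered)"),
    if (is.null(cnt$permutation))
      "Permutation null: not run (no pairs or no active drugs)"
    else sprintf("Permutation null: observed = %d, p_emp = %.3g",
                 cnt$permutation$observed, cnt$permutation$p_emp),
    sprintf("Network-filtered target pairs: %d", cnt$filtered_pairs),
    fmtEnr(cnt$enrichment_filtered, "Enrichment (filtered)")
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a complete synthetic study to disk
#'
#' Simulates genotypes with planted epistasis and a drug universe, writes
#' every input file the pipeline reads, and returns a ready
#' [pipelineConfig()]. Gene intervals are aligned with the genotype panel
#' so planted SNP pairs map into druggable genes.
#'
#' @param dir output directory.
#' @param seed seed for both generators.
#' @param nSnps,nCases,nControls genotype scenario overrides.
#' @param betaInt interaction log-odds of the single planted pair.
#' @param universe optional [drugUniverseScenario()] override.
#' @return a pipeline config list.
#' @export
writeDemoStudy <- function(dir, seed = 1L, nSnps = 30L, nCases = 400L,
                           nControls = 400L, betaInt = log(3),
                           universe = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gsc <- epistasisScenario(
    nCases = nCases, nControls = nControls, nSnps = nSnps,
    mafRange = c(0.2, 0.4),
    plantedPairs = data.frame(snp_i = 1L, snp_j = 2L, beta_int = betaInt),
    seed = seed
  )
  gm <- simulateGenotypes(gsc)
  writePlink(gm, file.path(dir, "study"))

  if (is.null(universe))
    universe <- drugUniverseScenario(seed = seed + 1L)
  uni <- simulateDrugUniverse(universe)

  # tile genes over the genotype panel's coordinates so SNPs map to genes
  snps <- snpInfo(gm)
  nG <- universe$nGenes
  geneRows <- data.frame(
    chrom = "chr1",
    start = 10000L * seq_len(nG) - 2000L,
    end = 10000L * seq_len(nG) + 2000L,
    symbol = sprintf("G%04d", seq_len(nG))
  )
  write.table(geneRows, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeTsv(uni$drugTargets, file.path(dir, "drug_targets.tsv"))
  .writeTsv(uni$indications, file.path(dir, "indications.tsv"))
  .writeTsv(uni$combinations, file.path(dir, "combinations.tsv"))
  .writeTsv(uni$network, file.path(dir, "network.tsv"))
  write.table(data.frame(gene = uni$diseaseGenes),
              file.path(dir, "disease_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  pipelineConfig(
    pedPath = file.path(dir, "study.ped"),
    mapPath = file.path(dir, "study.map"),
    genesPath = file.path(dir, "genes.tsv"),
    drugTargetsPath = file.path(dir, "drug_targets.tsv"),
    combinationsPath = file.path(dir, "combinations.tsv"),
    networkPath = file.path(dir, "network.tsv"),
    diseaseGenesPath = file.path(dir, "disease_genes.tsv"),
    diseaseLabel = uni$diseaseLabel,
    outDir = file.path(dir, "out"),
    scan = scanConfig(alpha = 1e-3),
    permB = 200L, seed = seed
  )
}
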