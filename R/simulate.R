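#' Scenario for simulating case-control genotypes with planted epistasis
#'
#' The default scenario mirrors the study design the pipeline targets: a
#' balanced case-control panel (1145 cases / 1142 controls at full scale;
#' smaller panels are passed explicitly for desk-scale work), common SNPs
#' with MAF drawn uniformly in `mafRange`, Hardy-Weinberg genotypes, and
#' purely epistatic disease risk (main effects default to zero so planted
#' signal is unambiguously an interaction).
#'
#' @param nCases,nControls sample sizes.
#' @param nSnps panel size.
#' @param mafRange MAF bounds, within (0, 0.5].
#' @param plantedPairs data.frame with columns `snp_i`, `snp_j` (1-based
#'   indices) and `beta_int` (interaction log-odds per dosage product), or
#'   `NULL`.
#' @param mainEffects numeric vector of per-SNP main-effect log-odds
#'   (recycled/`NULL` = 0).
#' @param missingRate independent per-call missingness probability.
#' @param seed RNG seed.
#' @return a scenario list.
#' @export
epistasisScenario <- function(nCases = 1000L, nControls = 1000L,
                              nSnps = 50L, mafRange = c(0.05, 0.5),
                              plantedPairs = NULL, mainEffects = NULL,
                              missingRate = 0, seed = 1L) {
  stopifnot(mafRange[1] > 0, mafRange[2] <= 0.5,
            mafRange[1] <= mafRange[2],
            missingRate >= 0, missingRate < 1)
  if (!is.null(plantedPairs)) {
    stopifnot(all(c("snp_i", "snp_j", "beta_int") %in% names(plantedPairs)),
              all(plantedPairs$snp_i != plantedPairs$snp_j),
              all(c(plantedPairs$snp_i, plantedPairs$snp_j) >= 1),
              all(c(plantedPairs$snp_i, plantedPairs$snp_j) <= nSnps))
  }
  list(nCases = as.integer(nCases), nControls = as.integer(nControls),
       nSnps = as.integer(nSnps), mafRange = mafRange,
       plantedPairs = plantedPairs, mainEffects = mainEffects,
       missingRate = missingRate, seed = as.integer(seed))
}

#' Simulate case-control genotypes (retrospective sampling)
#'
#' Simulates a prospective population — per-SNP genotypes as two
#' independent Bernoulli(MAF) alleles (Hardy-Weinberg), disease status from
#' the logistic model `logit P(case) = alpha + sum(beta_main g) +
#' sum(beta_int g_i g_j)` — then samples cases and controls retrospectively
#' until the requested counts are reached, exactly matching the
#' case-control design the interaction tests assume. The intercept `alpha`
#' is calibrated by bisection on a pilot population so the prevalence is
#' near the target case fraction. Missing calls are applied independently
#' at `missingRate`. Fully reproducible from the scenario seed.
#'
#' @param scenario list from [epistasisScenario()].
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(scenario) {
  set.seed(scenario$seed)
  m <- scenario$nSnps
  mafs <- runif(m, scenario$mafRange[1], scenario$mafRange[2])
  betaMain <- rep(0, m)
  if (!is.null(scenario$mainEffects))
    betaMain[seq_along(scenario$mainEffects)] <- scenario$mainEffects
  pp <- scenario$plantedPairs

  drawGeno <- function(n) {
    # n individuals x m SNPs of HWE dosages
    matrix(rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n)
  }
  linpred <- function(G) {
    lp <- drop(G %*% betaMain)
    if (!is.null(pp))
      for (r in seq_len(nrow(pp)))
        lp <- lp + pp$beta_int[r] * G[, pp$snp_i[r]] * G[, pp$snp_j[r]]
    lp
  }

  targetPrev <- scenario$nCases / (scenario$nCases + scenario$nControls)
  pilot <- linpred(drawGeno(4000L))
  alpha <- uniroot(function(a) mean(plogis(a + pilot)) - targetPrev,
                   c(-30, 30), tol = 1e-8)$root

  need <- c(control = scenario$nControls, case = scenario$nCases)
  got <- list(case = NULL, control = NULL)
  batch <- max(2000L, 2L * (scenario$nCases + scenario$nControls))
  for (attempt in 1:50) {
    G <- drawGeno(batch)
    status <- rbinom(batch, 1L, plogis(alpha + linpred(G)))
    for (cls in c("control", "case")) {
      want <- need[[cls]] - NROW(got[[cls]])
      if (want <= 0) next
      rows <- which(status == (cls == "case"))
      take <- rows[seq_len(min(want, length(rows)))]
      got[[cls]] <- rbind(got[[cls]], G[take, , drop = FALSE])
    }
    if (NROW(got$case) >= need["case"] && NROW(got$control) >= need["control"])
      break
    if (attempt == 50)
      stop("simulation error: could not reach requested case/control ",
           "counts; enlarge batches or moderate the effect sizes")
  }
  G <- rbind(got$control, got$case) # samples x snps
  phenotype <- rep(c("control", "case"), c(need["control"], need["case"]))

  if (scenario$missingRate > 0)
    G[runif(length(G)) < scenario$missingRate] <- NA_integer_

  calls <- t(G) # snps x samples
  # fold so the coded allele is the dataset-relative minor allele
  for (j in seq_len(m)) {
    g <- calls[j, ]
    if (mean(g, na.rm = TRUE) > 1) calls[j, ] <- 2L - g
  }
  snps <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chrom = "chr1", pos_bp = 10000L * seq_len(m),
    allele_minor = "A", allele_major = "G", stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sprintf("%s%05d", ifelse(phenotype == "case", "case", "ctrl"),
                        seq_along(phenotype)),
    phenotype = phenotype, stringsAsFactors = FALSE
  )
  GenotypeMatrix(calls, snps, samples)
}

#' Scenario for a synthetic drug-discovery universe
#'
#' Defines gene, drug, combination, disease-gene and co-opening-network
#' universes with a planted, disease-linked structure: network edges are
#' `diseasePairEdgeBoost` times denser between disease genes, and
#' disease-indicated ("active") combinations are drawn preferentially from
#' combinations whose both component drugs target disease genes — the
#' correlation that lets network filtration enrich for active
#' combinations downstream.
#'
#' @param nGenes,nDrugs,nCombinations universe sizes.
#' @param fracDiseaseGenes fraction of genes tied to the disease.
#' @param fracActiveCombos fraction of combinations indicated for the
#'   disease.
#' @param networkEdgeProb baseline edge probability.
#' @param diseasePairEdgeBoost multiplier (>= 1) on the edge probability
#'   when both endpoints are disease genes.
#' @param diseaseLabel indication label used for active combinations.
#' @param seed RNG seed.
#' @return a scenario list.
#' @export
drugUniverseScenario <- function(nGenes = 150L, nDrugs = 80L,
                                 nCombinations = 400L,
                                 fracDiseaseGenes = 0.25,
                                 fracActiveCombos = 0.15,
                                 networkEdgeProb = 0.06,
                                 diseasePairEdgeBoost = 5,
                                 diseaseLabel = "breast cancer",
                                 seed = 1L) {
  stopifnot(fracDiseaseGenes >= 0, fracDiseaseGenes <= 1,
            fracActiveCombos >= 0, fracActiveCombos <= 1,
            networkEdgeProb >= 0, networkEdgeProb <= 1,
            diseasePairEdgeBoost >= 1)
  list(nGenes = as.integer(nGenes), nDrugs = as.integer(nDrugs),
       nCombinations = as.integer(nCombinations),
       fracDiseaseGenes = fracDiseaseGenes,
       fracActiveCombos = fracActiveCombos,
       networkEdgeProb = networkEdgeProb,
       diseasePairEdgeBoost = diseasePairEdgeBoost,
       diseaseLabel = diseaseLabel, seed = as.integer(seed))
}

#' Simulate a drug-discovery universe
#'
#' Generates gene intervals tiled without overlap on synthetic
#' chromosomes, a drug-target table (targets per drug ~ 1 + geometric), a
#' combination database of random drug pairs with planted disease
#' indications, a disease-gene list, an indication table and a co-opening
#' network (see [drugUniverseScenario()] for the planted structure).
#'
#' @param scenario list from [drugUniverseScenario()].
#' @return list: `genes` (GRanges), `drugTargets`, `indications`,
#'   `combinations`, `diseaseGenes`, `network`, `diseaseLabel`.
#' @export
simulateDrugUniverse <- function(scenario) {
  set.seed(scenario$seed)
  nG <- scenario$nGenes
  if (nG < 2) stop("parameter error: need at least 2 genes to tile")
  perChrom <- 100L
  geneLen <- 2000L; gap <- 1000L
  idx <- seq_len(nG) - 1L
  chrom <- paste0("chr", idx %/% perChrom + 1L)
  slot <- idx %% perChrom
  start <- slot * (geneLen + gap) + 1L
  symbols <- sprintf("G%04d", seq_len(nG))
  genes <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = start + geneLen - 1L),
    symbol = symbols
  )

  diseaseGenes <- sort(sample(symbols,
                              round(scenario$fracDiseaseGenes * nG)))

  drugs <- sprintf("d%04d", seq_len(scenario$nDrugs))
  nTargets <- 1L + stats::rgeom(scenario$nDrugs, 0.3)
  nTargets <- pmin(nTargets, nG)
  drugTargets <- do.call(rbind, lapply(seq_along(drugs), function(i)
    data.frame(drug_id = drugs[i],
               gene = sample(symbols, nTargets[i]),
               stringsAsFactors = FALSE)))
  drugTargets <- unique(drugTargets)
  rownames(drugTargets) <- NULL

  # combinations: random distinct drug pairs
  nC <- scenario$nCombinations
  maxPairs <- choose(length(drugs), 2)
  if (nC > maxPairs) stop("parameter error: too many combinations")
  ij <- decodePairIndex(sample(maxPairs, nC), length(drugs))
  compA <- drugs[ij[, 1]]; compB <- drugs[ij[, 2]]

  # a combo is "disease-targeting" when both drugs hit >= 1 disease gene
  hitsDisease <- vapply(drugs, function(d)
    any(drugTargets$gene[drugTargets$drug_id == d] %in% diseaseGenes),
    logical(1))
  bothDisease <- hitsDisease[compA] & hitsDisease[compB]
  nActive <- round(scenario$fracActiveCombos * nC)
  weights <- ifelse(bothDisease, 20, 1)
  active <- logical(nC)
  if (nActive > 0)
    active[sample.int(nC, nActive, prob = weights)] <- TRUE

  status <- sample(c("approved", "investigational"), nC, replace = TRUE,
                   prob = c(0.25, 0.75))
  combinations <- data.frame(
    combo_id = sprintf("c%04d", seq_len(nC)),
    components = I(mapply(function(a, b) sort(c(a, b)), compA, compB,
                          SIMPLIFY = FALSE, USE.NAMES = FALSE)),
    indications = I(lapply(active, function(a)
      if (a) scenario$diseaseLabel else "other")),
    status = status, stringsAsFactors = FALSE
  )

  indications <- if (any(active)) unique(data.frame(
    drug_id = c(compA[active], compB[active]),
    disease = scenario$diseaseLabel,
    status = "active", stringsAsFactors = FALSE))
  else data.frame(drug_id = character(), disease = character(),
                  status = character(), stringsAsFactors = FALSE)

  # co-opening network with boosted disease-disease edges
  allPairs <- t(combn(symbols, 2))
  isDD <- allPairs[, 1] %in% diseaseGenes & allPairs[, 2] %in% diseaseGenes
  pEdge <- pmin(1, scenario$networkEdgeProb *
                  ifelse(isDD, scenario$diseasePairEdgeBoost, 1))
  draw <- runif(nrow(allPairs)) < pEdge
  network <- data.frame(gene_a = allPairs[draw, 1],
                        gene_b = allPairs[draw, 2],
                        stringsAsFactors = FALSE)

  list(genes = genes, drugTargets = drugTargets, indications = indications,
       combinations = combinations, diseaseGenes = diseaseGenes,
       network = network, diseaseLabel = scenario$diseaseLabel)
}

#' Sample distinct unordered gene pairs from a universe
#'
#' Utility used for permutation draws and for generating synthetic
#' "epistatic" target-pair sets at desk scale.
#'
#' @param genes character vector of gene symbols.
#' @param nPairs number of distinct pairs to draw.
#' @param seed optional RNG seed (`NULL` = use current RNG state).
#' @return data.frame `gene_a`, `gene_b` in canonical order.
#' @export
sampleGenePairs <- function(genes, nPairs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- length(genes)
  if (nPairs > choose(u, 2))
    stop("parameter error: more pairs than the universe supports")
  ij <- decodePairIndex(sample(choose(u, 2), nPairs), u)
  pk <- canonicalPair(genes[ij[, 1]], genes[ij[, 2]], collapse = FALSE)
  data.frame(gene_a = pk[, 1], gene_b = pk[, 2], stringsAsFactors = FALSE)
}

#' Scenario for synthetic dose-response curves
#'
#' @param mA,mB single-agent median-effect slopes (> 0).
#' @param DmA,DmB single-agent median-effect doses, micromolar.
#' @param ratioA,ratioB fixed mixture dose ratio.
#' @param targetCi combination index the mixture should exhibit at
#'   `fa = 0.5` (> 0; 1 = additivity).
#' @param doses dilution series (micromolar, strictly positive).
#' @param noiseSd Gaussian noise standard deviation on `fa`.
#' @param seed RNG seed.
#' @return a scenario list.
#' @export
synergyScenario <- function(mA = 1.5, mB = 2, DmA = 2, DmB = 5,
                            ratioA = 3, ratioB = 1, targetCi = 0.5,
                            doses = c(0.25, 0.5, 1, 2, 4, 8),
                            noiseSd = 0, seed = 1L) {
  if (targetCi <= 0) stop("parameter error: targetCi must be positive")
  stopifnot(mA > 0, mB > 0, DmA > 0, DmB > 0, ratioA > 0, ratioB > 0,
            all(doses > 0), noiseSd >= 0)
  list(mA = mA, mB = mB, DmA = DmA, DmB = DmB, ratioA = ratioA,
       ratioB = ratioB, targetCi = targetCi, doses = doses,
       noiseSd = noiseSd, seed = as.integer(seed))
}

#' Simulate dose-response curves for two agents and their mixture
#'
#' Single agents follow the median-effect model exactly:
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)`. The fixed-ratio mixture follows a
#' median-effect curve whose slope is the mean of the component slopes and
#' whose `Dm` is solved in closed form so that the mutually exclusive
#' combination index at `fa = 0.5` equals `targetCi`:
#' `Dm_mix = targetCi / (w1/Dm1 + w2/Dm2)` with `w` the mixture dose
#' fractions. Gaussian noise (sd `noiseSd`) is added to `fa` and clipped
#' to the open unit interval.
#'
#' @param scenario list from [synergyScenario()].
#' @return data.frame with columns `agent_id` (`"A"`, `"B"`, `"mix"`),
#'   `dose_um` (total dose for the mixture) and `fa`.
#' @export
simulateDoseResponse <- function(scenario) {
  set.seed(scenario$seed)
  w1 <- scenario$ratioA / (scenario$ratioA + scenario$ratioB)
  w2 <- 1 - w1
  DmMix <- scenario$targetCi / (w1 / scenario$DmA + w2 / scenario$DmB)
  mMix <- mean(c(scenario$mA, scenario$mB))
  curve <- function(D, m, Dm) {
    z <- (D / Dm)^m
    z / (1 + z)
  }
  mk <- function(id, m, Dm) {
    fa <- curve(scenario$doses, m, Dm)
    if (scenario$noiseSd > 0) {
      fa <- fa + rnorm(length(fa), 0, scenario$noiseSd)
      fa <- pmin(pmax(fa, 1e-6), 1 - 1e-6)
    }
    data.frame(agent_id = id, dose_um = scenario$doses, fa = fa,
               stringsAsFactors = FALSE)
  }
  rbind(mk("A", scenario$mA, scenario$DmA),
        mk("B", scenario$mB, scenario$DmB),
        mk("mix", mMix, DmMix))
}
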