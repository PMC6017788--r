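# Independent oracle implementations used to cross-check package internals.
# These deliberately take different code paths (stats::glm, stats::phyper,
# recurrence relations, direct optimisation) from the package.

# cube from explicit 3x3 case/control count matrices (rows gA, cols gB)
makeCube <- function(ctrl, case) {
  cube <- array(0L, dim = c(2, 3, 3),
                dimnames = list(phenotype = c("control", "case"),
                                gA = 0:2, gB = 0:2))
  cube["control", , ] <- as.matrix(ctrl)
  cube["case", , ] <- as.matrix(case)
  cube
}

# random 2x3x3 cube with both SNPs polymorphic and both classes present
randomCube <- function(n = 600, interaction = 0) {
  maf <- runif(2, 0.2, 0.45)
  ga <- rbinom(n, 2, maf[1]); gb <- rbinom(n, 2, maf[2])
  eta <- -0.2 + 0.3 * ga - 0.2 * gb + interaction * ga * gb
  y <- rbinom(n, 1, plogis(eta))
  cube <- array(0L, dim = c(2, 3, 3),
                dimnames = list(phenotype = c("control", "case"),
                                gA = 0:2, gB = 0:2))
  for (i in seq_len(n))
    cube[y[i] + 1, ga[i] + 1, gb[i] + 1] <-
      cube[y[i] + 1, ga[i] + 1, gb[i] + 1] + 1L
  cube
}

cubeToCells <- function(cube) {
  tot <- cube["control", , ] + cube["case", , ]
  idx <- which(tot > 0, arr.ind = TRUE)
  data.frame(gA = idx[, 1] - 1L, gB = idx[, 2] - 1L,
             y = cube["case", , ][idx], tot = tot[idx])
}

# glm-based oracle for the 4-df genotype LRT
oracleLrt4 <- function(cube) {
  d <- cubeToCells(cube)
  main <- glm(cbind(y, tot - y) ~ factor(gA) + factor(gB),
              family = binomial(), data = d)
  sat <- glm(cbind(y, tot - y) ~ factor(gA) * factor(gB),
             family = binomial(), data = d)
  list(statistic = main$deviance - sat$deviance,
       df = main$df.residual - sat$df.residual)
}

# glm-based oracle for the 1-df dosage Wald test
oracleDosage1 <- function(cube) {
  d <- cubeToCells(cube)
  fit <- glm(cbind(y, tot - y) ~ gA * gB, family = binomial(), data = d,
             control = glm.control(epsilon = 1e-13, maxit = 200))
  z <- summary(fit)$coefficients["gA:gB", "z value"]
  z^2
}

# direct likelihood maximisation over cell probabilities (optim), the
# "constrained numerical optimisation" route for the LRT
oracleLrt4Optim <- function(cube) {
  d <- cubeToCells(cube)
  X <- model.matrix(~ factor(gA) + factor(gB), data = d)
  nll <- function(beta) {
    p <- plogis(drop(X %*% beta))
    -sum(d$y * log(p) + (d$tot - d$y) * log(1 - p))
  }
  opt <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  pSat <- d$y / d$tot
  llSat <- sum(ifelse(d$y > 0, d$y * log(pSat), 0) +
                 ifelse(d$tot - d$y > 0,
                        (d$tot - d$y) * log(1 - pSat), 0))
  2 * (llSat + opt$value)
}

# HWE exact p by the mode-anchored recurrence over heterozygote counts
# (Wigginton-style), an algorithm independent of direct lgamma evaluation
oracleHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa; na <- 2 * naa + nAa
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- which.max(hets >= round(rare * (2 * n - rare) / (2 * n)))
  probs[mid] <- 1
  if (mid < length(hets)) for (i in mid:(length(hets) - 1)) {
    h <- hets[i]
    AA <- (rare - h) / 2 # rare homozygotes at h
    other <- n - AA - h
    # P(h+2)/P(h) = 4*AA*other / ((h+2)(h+1))
    probs[i + 1] <- probs[i] * 4 * AA * other / ((h + 2) * (h + 1))
  }
  if (mid > 1) for (i in mid:2) {
    h <- hets[i]
    AA <- (rare - h) / 2
    other <- n - AA - h
    # P(h-2)/P(h) = h(h-1) / (4*(AA+1)*(other+1))
    probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (AA + 1) * (other + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(nAa, hets)]
  sum(probs[probs <= obs * (1 + 1e-10)])
}

# write a tiny ped/map pair from explicit strings
writePedMap <- function(dir, pedLines, mapLines, prefix = "tiny") {
  ped <- file.path(dir, paste0(prefix, ".ped"))
  map <- file.path(dir, paste0(prefix, ".map"))
  writeLines(pedLines, ped)
  writeLines(mapLines, map)
  list(ped = ped, map = map)
}
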