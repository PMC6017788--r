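noiselessPoints <- function(m, Dm, doses) {
  z <- (doses / Dm)^m
  data.frame(agent_id = "A", dose_um = doses, fa = z / (1 + z))
}

test_that("median-effect fitting recovers noiseless parameters exactly", {
  fit <- fitMedianEffect(noiselessPoints(1.5, 2, c(1, 2, 4)))
  expect_equal(fit@m, 1.5, tolerance = 1e-9)
  expect_equal(fit@Dm, 2, tolerance = 1e-9)
  expect_equal(abs(fit@r), 1, tolerance = 1e-9)
  # a point at D = Dm (fa = 0.5) anchors Dm exactly
  fit2 <- fitMedianEffect(noiselessPoints(2.2, 5, c(5, 11)))
  expect_equal(fit2@Dm, 5, tolerance = 1e-9)
  # fa(Dm) = 0.5 by definition for any fit
  expect_equal(effectAtDose(fit, fit@Dm), 0.5, tolerance = 1e-12)
})

test_that("degenerate dose-response inputs are fit errors", {
  expect_error(fitMedianEffect(data.frame(dose_um = c(1, 2),
                                          fa = c(0, 1))), ">= 2 points")
  expect_error(fitMedianEffect(data.frame(dose_um = c(2, 2),
                                          fa = c(0.4, 0.6))),
               "zero dose variance")
  # out-of-range points are excluded, not clipped
  fit <- fitMedianEffect(data.frame(dose_um = c(0.5, 1, 2, 4),
                                    fa = c(0, 1 / 3, 0.5, 2 / 3)))
  expect_identical(fit@nPoints, 3L)
})

test_that("dose_for_effect inverts the fitted curve", {
  fit10 <- new("MedianEffectFit", agentId = "x", m = 1, Dm = 10,
               r = 1, nPoints = 3L)
  expect_equal(doseForEffect(fit10, 0.75), 30)
  expect_equal(doseForEffect(fit10, 0.5), 10)
  fit24 <- new("MedianEffectFit", agentId = "y", m = 2, Dm = 4,
               r = 1, nPoints = 3L)
  expect_equal(doseForEffect(fit24, 0.8), 8)
  # inverse property and monotonicity
  fas <- seq(0.05, 0.95, by = 0.05)
  dx <- doseForEffect(fit24, fas)
  expect_true(all(diff(dx) > 0))
  expect_equal(effectAtDose(fit24, dx), fas, tolerance = 1e-10)
  expect_error(doseForEffect(fit24, 1), "strictly inside")
})

test_that("classification follows the CI < 1 synergy rule", {
  expect_identical(classifyCi(0.439), "synergistic")
  expect_identical(classifyCi(1.0), "additive")
  expect_identical(classifyCi(1.288), "antagonistic")
  expect_identical(classifyCi(0.999, tol = 0.01), "additive")
  expect_error(classifyCi(-1), "positive")
})

test_that("self-combination yields CI 1 at any ratio and effect level", {
  fit <- fitMedianEffect(noiselessPoints(1.8, 3, c(1, 2, 4, 8)))
  for (ratio in list(c(1, 1), c(3, 1), c(1, 9))) {
    for (fa in c(0.2, 0.5, 0.9)) {
      ci <- combinationIndex(fit, fit, fit, ratio[1], ratio[2], fa)
      expect_equal(ci@ci, 1, tolerance = 1e-10)
      expect_identical(ci@classification, "additive")
    }
  }
})

test_that("the generative target CI is recovered through the full path", {
  sc <- synergyScenario(targetCi = 0.5, noiseSd = 0)
  dr <- simulateDoseResponse(sc)
  fits <- lapply(split(dr, dr$agent_id), fitMedianEffect)
  ci <- combinationIndex(fits$A, fits$B, fits$mix,
                         sc$ratioA, sc$ratioB, fa = 0.5)
  expect_equal(ci@ci, 0.5, tolerance = 1e-6)
  expect_identical(ci@classification, "synergistic")
  # CI invariant to swapping the drugs together with the ratio
  ciSwap <- combinationIndex(fits$B, fits$A, fits$mix,
                             sc$ratioB, sc$ratioA, fa = 0.5)
  expect_equal(ciSwap@ci, ci@ci, tolerance = 1e-12)
  # the CI identity d1/Dx1 + d2/Dx2 holds to machine precision
  expect_equal(ci@ci, ci@d1 / ci@Dx1 + ci@d2 / ci@Dx2, tolerance = 1e-12)
  # nonexclusive form adds the product term
  ciNe <- combinationIndex(fits$A, fits$B, fits$mix, sc$ratioA, sc$ratioB,
                           fa = 0.5, form = "nonexclusive")
  expect_equal(ciNe@ci, ci@ci + (ci@d1 * ci@d2) / (ci@Dx1 * ci@Dx2),
               tolerance = 1e-12)
})

test_that("parameter recovery under noise is accurate in the median", {
  errs <- vapply(1:200, function(s) {
    sc <- synergyScenario(noiseSd = 0.02, seed = s,
                          doses = c(0.25, 0.5, 1, 2, 4, 8))
    dr <- simulateDoseResponse(sc)
    fit <- fitMedianEffect(dr[dr$agent_id == "A", ])
    abs(fit@Dm - sc$DmA) / sc$DmA
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the fa-CI curve classifies consistently along the grid", {
  sc <- synergyScenario(targetCi = 1.4, noiseSd = 0,
                        mA = 1.5, mB = 1.5, DmA = 2, DmB = 2)
  dr <- simulateDoseResponse(sc)
  fits <- lapply(split(dr, dr$agent_id), fitMedianEffect)
  curve <- ciCurve(fits$A, fits$B, fits$mix, sc$ratioA, sc$ratioB)
  expect_equal(curve$ci[curve$fa == 0.5], 1.4, tolerance = 1e-6)
  expect_true(all(curve$classification == "antagonistic"))
})
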