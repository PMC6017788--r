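#' Fit the median-effect line to dose-response data
#'
#' Linearizes the median-effect model `fa/fu = (D/Dm)^m` (with
#' `fu = 1 - fa`) as `log10(fa/fu) = m log10(D) - m log10(Dm)` and fits it
#' by ordinary least squares. Points with `fa` at or outside the open unit
#' interval carry no information on the line and are excluded with a
#' logged warning rather than clipped, which would bias the fit.
#'
#' @param doseResponse data.frame with columns `dose_um` and `fa` (and
#'   optionally `agent_id`; rows of a single agent or fixed-ratio
#'   mixture).
#' @param agentId label stored in the fit; defaults to the table's
#'   `agent_id` if unique.
#' @return a [MedianEffectFit-class].
#' @export
fitMedianEffect <- function(doseResponse, agentId = NULL) {
  if (is.null(agentId)) {
    agentId <- if ("agent_id" %in% names(doseResponse) &&
                   length(unique(doseResponse$agent_id)) == 1)
      as.character(doseResponse$agent_id[1]) else "agent"
  }
  d <- doseResponse$dose_um
  fa <- doseResponse$fa
  if (any(d <= 0)) stop("fit error: doses must be strictly positive")
  usable <- fa > 0 & fa < 1
  if (any(!usable))
    logMsg("excluded ", sum(!usable), " point(s) with fa outside (0,1) [",
           agentId, "]")
  d <- d[usable]; fa <- fa[usable]
  if (length(d) < 2) stop("fit error: need >= 2 points with fa in (0,1)")
  x <- log10(d)
  if (max(x) - min(x) < 1e-12) stop("fit error: zero dose variance")
  y <- log10(fa / (1 - fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  b0 <- unname(coef(fit)[1])
  if (!is.finite(m) || m == 0) stop("fit error: degenerate slope")
  r <- if (stats::sd(y) < 1e-15) 1 else suppressWarnings(cor(x, y))
  new("MedianEffectFit", agentId = agentId, m = m, Dm = 10^(-b0 / m),
      r = r, nPoints = length(d))
}

#' Effect of a dose under a median-effect fit
#'
#' @param fit a [MedianEffectFit-class].
#' @param dose dose(s), same units as the fit.
#' @return fraction affected in (0, 1).
#' @export
effectAtDose <- function(fit, dose) {
  stopifnot(all(dose > 0))
  z <- (dose / fit@Dm)^fit@m
  z / (1 + z)
}

#' Dose required for a given effect level
#'
#' Inverts the median-effect equation: `Dx = Dm (fa/(1-fa))^(1/m)`. At
#' `fa = 0.5` this returns `Dm` for any slope.
#'
#' @param fit a [MedianEffectFit-class].
#' @param fa effect level(s), strictly inside (0, 1).
#' @return dose(s) in the fit's units.
#' @export
doseForEffect <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1))
    stop("parameter error: fa must be strictly inside (0, 1)")
  fit@Dm * (fa / (1 - fa))^(1 / fit@m)
}

#' Classify a combination index
#'
#' `CI < 1` synergistic, `CI = 1` (within `tol`) additive, `CI > 1`
#' antagonistic.
#'
#' @param ci positive combination index.
#' @param tol half-width of the additive band around 1 (default 0: strict
#'   comparisons).
#' @return one of `"synergistic"`, `"additive"`, `"antagonistic"`.
#' @export
classifyCi <- function(ci, tol = 0) {
  if (any(ci <= 0)) stop("parameter error: CI must be positive")
  ifelse(abs(ci - 1) <= tol, "additive",
         ifelse(ci < 1, "synergistic", "antagonistic"))
}

#' Chou-Talalay combination index for a fixed-ratio mixture
#'
#' At effect level `fa`, the mixture dose is read off the mixture fit and
#' split into component doses by the fixed ratio; the mutually exclusive
#' index is `CI = d1/Dx1 + d2/Dx2` with `Dx` the single-agent doses for
#' the same effect. The non-exclusive form adds `(d1 d2)/(Dx1 Dx2)`.
#'
#' @param fitA,fitB single-agent [MedianEffectFit-class] objects.
#' @param fitMix fit of the fixed-ratio mixture (dose = total dose).
#' @param ratioA,ratioB the fixed dose ratio (e.g. 3 and 1 for 3:1).
#' @param fa effect level (default 0.5, the median effect).
#' @param form `"exclusive"` (default, the classic two-term index) or
#'   `"nonexclusive"`.
#' @param tol additive-classification tolerance (see [classifyCi()]).
#' @return a [CIResult-class].
#' @export
combinationIndex <- function(fitA, fitB, fitMix, ratioA = 1, ratioB = 1,
                             fa = 0.5, form = c("exclusive", "nonexclusive"),
                             tol = 0) {
  form <- match.arg(form)
  stopifnot(ratioA > 0, ratioB > 0)
  if (fa <= 0 || fa >= 1)
    stop("parameter error: fa must be strictly inside (0, 1)")
  dMix <- doseForEffect(fitMix, fa)
  d1 <- dMix * ratioA / (ratioA + ratioB)
  d2 <- dMix * ratioB / (ratioA + ratioB)
  Dx1 <- doseForEffect(fitA, fa)
  Dx2 <- doseForEffect(fitB, fa)
  ci <- d1 / Dx1 + d2 / Dx2
  if (form == "nonexclusive") ci <- ci + (d1 * d2) / (Dx1 * Dx2)
  new("CIResult", faLevel = fa, d1 = d1, d2 = d2, Dx1 = Dx1, Dx2 = Dx2,
      ci = ci, classification = classifyCi(ci, tol), form = form)
}

#' Combination index over a grid of effect levels
#'
#' @inheritParams combinationIndex
#' @param faGrid vector of effect levels.
#' @return data.frame with columns `fa`, `ci`, `classification`.
#' @export
ciCurve <- function(fitA, fitB, fitMix, ratioA = 1, ratioB = 1,
                    faGrid = seq(0.1, 0.9, by = 0.1),
                    form = "exclusive", tol = 0) {
  rows <- lapply(faGrid, function(f)
    combinationIndex(fitA, fitB, fitMix, ratioA, ratioB, f, form, tol))
  data.frame(fa = faGrid,
             ci = vapply(rows, function(r) r@ci, numeric(1)),
             classification = vapply(rows, function(r) r@classification,
                                     character(1)))
}
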