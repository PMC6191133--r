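#' Mass constants for food-store estimation
#'
#' Per-area masses of capped honey and capped brood and the mass of an
#' empty drawn frame. These are apiary- and frame-type-specific literature
#' values; no defaults are provided, the user must supply them.
#'
#' @param honeyMassPerCm2 g of honey per cm^2 of capped honey, > 0.
#' @param broodMassPerCm2 g of brood per cm^2 of capped brood, > 0.
#' @param emptyFrameMass g, mass of an empty drawn frame (wood + wax), > 0.
#' @return a validated list of class `MassConstants`.
#' @export
massConstants <- function(honeyMassPerCm2, broodMassPerCm2, emptyFrameMass) {
  x <- list(honeyMassPerCm2 = as.numeric(honeyMassPerCm2),
            broodMassPerCm2 = as.numeric(broodMassPerCm2),
            emptyFrameMass = as.numeric(emptyFrameMass))
  if (any(vapply(x, function(v) length(v) != 1L || is.na(v) || v <= 0, TRUE)))
    cqStop("domain", "all mass constants must be positive scalars")
  structure(x, class = "MassConstants")
}

#' Honey mass from capped-honey surface
#'
#' Multiplies the measured capped-honey surface by the mass of honey
#' contained in one cm^2 of capped honey.
#'
#' @param cappedHoneyCm2 capped honey area in cm^2, >= 0.
#' @param constants a [massConstants()] object.
#' @return mass in g.
#' @export
honeyMassFromArea <- function(cappedHoneyCm2, constants) {
  stopifnot(inherits(constants, "MassConstants"))
  if (any(is.na(cappedHoneyCm2)) || any(cappedHoneyCm2 < 0))
    cqStop("domain", "capped honey area must be >= 0")
  cappedHoneyCm2 * constants$honeyMassPerCm2
}

#' Food-store mass from frame weight
#'
#' Estimates the mass of stored food (pollen plus uncapped and capped
#' honey) on a frame by subtracting the estimated brood mass and the empty
#' drawn-frame mass from the weighed frame mass. A negative result (frame
#' lighter than its presumed empty weight) is returned unchanged with a
#' warning.
#'
#' @param frameMassG weighed frame mass in g, >= 0.
#' @param cappedBroodCm2 capped brood area in cm^2, >= 0.
#' @param constants a [massConstants()] object.
#' @return mass in g (possibly negative, with a warning).
#' @export
foodMassFromFrameWeight <- function(frameMassG, cappedBroodCm2, constants) {
  stopifnot(inherits(constants, "MassConstants"))
  if (any(is.na(frameMassG)) || any(frameMassG < 0))
    cqStop("domain", "frame mass must be >= 0")
  if (any(is.na(cappedBroodCm2)) || any(cappedBroodCm2 < 0))
    cqStop("domain", "capped brood area must be >= 0")
  out <- frameMassG - cappedBroodCm2 * constants$broodMassPerCm2 -
    constants$emptyFrameMass
  if (any(out < 0))
    cqWarn("negative_mass",
           "estimated food mass is negative (frame lighter than empty weight)")
  out
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Small-sample exact test for paired measurements (e.g. per-operator
#' timings of two measurement methods). Differences `b - a` are formed,
#' zero differences dropped, absolute differences ranked with midranks for
#' ties, and the statistic V is the sum of the ranks of the positive
#' differences. The null distribution is the exact one induced by all
#' `2^n` equally likely sign assignments on the realized rank multiset
#' (explicit enumeration up to n = 15, an equivalent exact convolution
#' beyond); the two-sided p-value doubles the smaller tail and is capped
#' at 1. No normal approximation is ever used.
#'
#' @param a,b paired measurement vectors of equal length.
#' @param labelA,labelB names for the two conditions (reporting only).
#' @return an object of class `htest` with components `statistic` (V),
#'   `p.value` (two-sided), `p.value.onesided` (smaller tail), `n.used`
#'   (pairs after dropping zeros) and `null.distribution` (data.frame with
#'   columns `v`, `prob`).
#' @examples
#' exactSignedRankTest(c(1, 2, 3, 4, 5, 6), c(3, 5, 7, 9, 11, 13))
#' @export
exactSignedRankTest <- function(a, b, labelA = "a", labelB = "b") {
  if (length(a) != length(b) || length(a) < 1L)
    cqStop("domain", "need equal-length paired vectors with >= 1 pair")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    cqStop("domain", "all measurements must be finite")
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    cqStop("degenerate_sample", "all paired differences are zero")
  if (n > 25L)
    cqStop("domain", "exact enumeration supported up to n = 25 pairs")

  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks: integers
  V2 <- sum(r2[d > 0])

  if (n <= 15L) {
    m <- 2^n
    bits <- outer(0:(m - 1), 2^(0:(n - 1)),
                  function(i, b) bitwAnd(i, b) > 0)
    all2 <- as.vector(bits %*% r2)
    tab <- table(all2)
    support2 <- as.integer(names(tab))
    probs <- as.vector(tab) / m
  } else {
    S <- sum(r2)
    f <- numeric(S + 1); f[1] <- 1
    for (r in r2) {
      g <- f
      g[(r + 1):(S + 1)] <- g[(r + 1):(S + 1)] + f[1:(S + 1 - r)]
      f <- g
    }
    keep <- f > 0
    support2 <- (0:S)[keep]
    probs <- f[keep] / 2^n
  }

  pGE <- sum(probs[support2 >= V2])
  pLE <- sum(probs[support2 <= V2])
  pOne <- min(pGE, pLE)
  pTwo <- min(1, 2 * pOne)

  structure(list(
    statistic = c(V = V2 / 2),
    p.value = pTwo,
    p.value.onesided = pOne,
    n.used = n,
    alternative = "two.sided",
    method = "Exact paired Wilcoxon signed-rank test (full sign enumeration)",
    data.name = sprintf("%s vs %s (%d pairs, %d non-zero)",
                        labelA, labelB, length(a), n),
    null.distribution = data.frame(v = support2 / 2, prob = probs)
  ), class = "htest")
}

#' Agreement between two measurement methods
#'
#' Pearson product-moment correlation between paired measurements of the
#' same quantity by two methods, with significance from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, plus the mean difference.
#'
#' @param methodA,methodB equal-length numeric vectors (n >= 3) with
#'   non-zero variance.
#' @param labelA,labelB method names for reporting.
#' @return list of class `agreementReport`: `n`, `r`, `statistic` (t),
#'   `df`, `p.value`, `meanDifference` (B - A), and a one-row `summary`
#'   data.frame.
#' @export
agreementReport <- function(methodA, methodB, labelA = "method_a",
                            labelB = "method_b") {
  if (length(methodA) != length(methodB) || length(methodA) < 3L)
    cqStop("domain", "need equal-length vectors with at least 3 pairs")
  if (stats::sd(methodA) == 0 || stats::sd(methodB) == 0)
    cqStop("undefined_correlation",
           "correlation undefined: one method has zero variance")
  ct <- stats::cor.test(methodA, methodB, method = "pearson")
  out <- list(n = length(methodA),
              r = unname(ct$estimate),
              statistic = unname(ct$statistic),
              df = unname(ct$parameter),
              p.value = ct$p.value,
              meanDifference = mean(methodB - methodA),
              labelA = labelA, labelB = labelB)
  out$summary <- data.frame(label_a = labelA, label_b = labelB, n = out$n,
                            r = out$r, t = out$statistic, df = out$df,
                            p_value = out$p.value,
                            mean_difference = out$meanDifference)
  class(out) <- "agreementReport"
  out
}

#' @export
print.agreementReport <- function(x, ...) {
  cat(sprintf("Agreement %s vs %s: n = %d, r = %.4f (t = %.3f, df = %d, p = %.3g)\n",
              x$labelA, x$labelB, x$n, x$r, x$statistic, x$df, x$p.value))
  cat(sprintf("  mean difference (%s - %s): %.4g\n", x$labelB, x$labelA,
              x$meanDifference))
  invisible(x)
}
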