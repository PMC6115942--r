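#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Monte-Carlo machinery for the case-specificity score: group allele
## frequencies under a true odds ratio, carrier probabilities under an
## inheritance model, the empirical and exact distribution of
## Score1 = 10*X - 50*Y with X, Y binomial carrier counts, power surfaces
## over (tMAF, tOR), MAF-adjusted empirical p-values, and the Bernoulli
## enrichment null for case-unique variant counts.
## ---------------------------------------------------------------------------

#' Group allele frequencies implied by a true odds ratio
#'
#' The control group stands for the population: \code{AF_control = tMAF}.
#' The case-group frequency solves \code{odds(AF_case) = tOR * odds(tMAF)}.
#' With \code{interpretation = "allelic"} (default) the odds ratio acts on
#' the allele frequency itself; with \code{"carrier"} it acts on the carrier
#' probability under \code{model} and the case allele frequency is
#' back-solved from the carrier probability.
#'
#' @param tMAF true population minor allele frequency, in (0, 0.5].
#' @param tOR true odds ratio, >= 0 (0 gives AF_case = 0).
#' @param model "dominant" or "recessive" (used by the carrier
#'   interpretation only).
#' @param interpretation "allelic" or "carrier".
#' @return named numeric vector c(AF_control=, AF_case=).
#' @examples
#' deriveGroupAF(0.1, 2)   # AF_case = 0.2/1.1
#' @export
deriveGroupAF <- function(tMAF, tOR, model = "dominant",
                          interpretation = c("allelic", "carrier")) {
  interpretation <- match.arg(interpretation)
  if (!is.finite(tMAF) || tMAF <= 0 || tMAF > 0.5)
    stop("tMAF must lie in (0, 0.5], got ", tMAF)
  if (!is.finite(tOR) || tOR < 0)
    stop("tOR must be >= 0, got ", tOR)
  afControl <- tMAF
  if (interpretation == "allelic") {
    odds <- tOR * afControl / (1 - afControl)
    afCase <- odds / (1 + odds)
  } else {
    q0 <- carrierProbability(afControl, model)
    odds <- tOR * q0 / (1 - q0)
    q1 <- odds / (1 + odds)
    afCase <- switch(model,
      dominant = 1 - sqrt(1 - q1),
      recessive = sqrt(q1),
      stop("unknown model: ", model))
  }
  c(AF_control = afControl, AF_case = afCase)
}

#' Probability of carrying the risk genotype
#'
#' Under Hardy-Weinberg proportions at allele frequency \code{af}, the
#' probability of a non-reference genotype is \code{2*af - af^2} under the
#' dominant model (het or hom-alt) and \code{af^2} under the recessive model
#' (hom-alt only).
#'
#' @param af allele frequency in [0, 1].
#' @param model "dominant" or "recessive".
#' @return carrier probability.
#' @export
carrierProbability <- function(af, model = c("dominant", "recessive")) {
  model <- match.arg(model)
  stopifnot(all(af >= 0 & af <= 1))
  if (model == "dominant") 2 * af - af^2 else af^2
}

.scoreCoefs <- function(wCase = 10, wControl = 50) c(wCase = wCase, wControl = wControl)

#' Monte-Carlo distribution of the case-specificity score
#'
#' Draws carrier counts \code{X ~ Binomial(nCase, pCase)} and
#' \code{Y ~ Binomial(nControl, pControl)} and evaluates
#' \code{Score1 = 10*X - 50*Y} at each iteration.
#'
#' @param nCase,nControl group sizes.
#' @param pCase,pControl per-sample carrier probabilities.
#' @param iterations number of Monte-Carlo samples.
#' @param seed optional seed for reproducibility.
#' @param threshold positive-outcome score threshold (default 20, i.e. at
#'   least two case carriers more than covered by control penalties).
#' @param returnScores if TRUE, include the full vector of scores.
#' @return list(p_positive=, e_score=, iterations=, scores= (optional)).
#' @export
simulateScoreDistribution <- function(nCase, nControl, pCase, pControl,
                                      iterations = 1e5, seed = NULL,
                                      threshold = 20, returnScores = FALSE) {
  stopifnot(iterations >= 1, pCase >= 0, pCase <= 1,
            pControl >= 0, pControl <= 1)
  scores <- withSeed(seed, {
    x <- rbinom(iterations, nCase, pCase)
    y <- rbinom(iterations, nControl, pControl)
    10 * x - 50 * y
  })
  out <- list(p_positive = mean(scores >= threshold),
              e_score = mean(scores),
              iterations = iterations, threshold = threshold)
  if (returnScores) out$scores <- scores
  out
}

#' Exact tail probability of the case-specificity score
#'
#' Exact \eqn{P(10X - 50Y \ge t)} for independent binomial carrier counts,
#' by summation over the control count. Serves as the closed-form oracle for
#' [simulateScoreDistribution()] and as the analytic mode of
#' [mafAdjustedPvalue()].
#'
#' @inheritParams simulateScoreDistribution
#' @param threshold score threshold t.
#' @return exact probability.
#' @export
analyticScoreProbability <- function(nCase, nControl, pCase, pControl,
                                     threshold = 20) {
  stopifnot(nCase >= 0, nControl >= 0)
  y <- 0:nControl
  py <- dbinom(y, nControl, pControl)
  xmin <- ceiling((threshold + 50 * y) / 10)
  px <- ifelse(xmin > nCase,
               0,
               pbinom(pmax(xmin, 0) - 1, nCase, pCase, lower.tail = FALSE))
  sum(py * px)
}

#' Power surface of the scoring procedure over (tMAF, tOR)
#'
#' For each grid cell, derives group allele frequencies
#' ([deriveGroupAF()]), converts to carrier probabilities
#' ([carrierProbability()]) and runs [simulateScoreDistribution()]. The
#' default grid covers tMAF in [0.001, 0.1] (100 points) and tOR in [1, 7]
#' (70 points): 7000 parameter combinations.
#'
#' @param nCase,nControl group sizes (default 49 cases vs 61 controls, the
#'   T2D versus obesity+control comparison).
#' @param model inheritance model.
#' @param tMAF,tOR grid axes.
#' @param iterations Monte-Carlo iterations per cell (default 100000).
#' @param seed root seed; each cell uses a deterministic child seed.
#' @param threshold positive-outcome threshold.
#' @return a [PowerGrid-class].
#' @export
powerGrid <- function(nCase = 49, nControl = 61, model = "dominant",
                      tMAF = seq(0.001, 0.1, length.out = 100),
                      tOR = seq(1, 7, length.out = 70),
                      iterations = 1e5, seed = 1L, threshold = 20) {
  cells <- expand.grid(tMAF = tMAF, tOR = tOR, KEEP.OUT.ATTRS = FALSE)
  pPos <- eScore <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    af <- deriveGroupAF(cells$tMAF[i], cells$tOR[i], model)
    pc <- carrierProbability(af[["AF_case"]], model)
    pk <- carrierProbability(af[["AF_control"]], model)
    r <- simulateScoreDistribution(nCase, nControl, pc, pk, iterations,
                                   seed = childSeed(seed, i),
                                   threshold = threshold)
    pPos[i] <- r$p_positive
    eScore[i] <- r$e_score
  }
  new("PowerGrid",
      grid = data.frame(cells, p_positive = pPos, e_score = eScore),
      nCase = as.integer(nCase), nControl = as.integer(nControl),
      model = model, iterations = iterations, threshold = threshold,
      seed = as.integer(seed))
}

#' Heat-map of a power surface
#'
#' Renders p_positive (or e_score) over the (tMAF, tOR) grid with ggplot2.
#'
#' @param x a [PowerGrid-class].
#' @param what "p_positive" or "e_score".
#' @return a ggplot object.
#' @export
plotPowerGrid <- function(x, what = c("p_positive", "e_score")) {
  what <- match.arg(what)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- as.data.frame(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tMAF, y = .data$tOR,
                                   fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = "true population MAF", y = "true odds ratio")
}

#' MAF-adjusted empirical p-value for an observed score
#'
#' Resamples the score under the null model tMAF = panel MAF, tOR = 1 (both
#' groups at the carrier probability implied by the reference-panel MAF) and
#' reports the fraction of resampled scores at least as large as the
#' observed one. Default smoothing is add-one: \code{p = (k+1)/(N+1)}, so
#' the p-value is never zero; \code{smoothing = "min-one"} uses
#' \code{max(k,1)/N}. \code{method = "analytic"} returns the exact tail
#' probability via [analyticScoreProbability()] instead of resampling.
#'
#' @param observedScore observed Score1 value.
#' @param panelMAF reference-panel MAF of the variant, in (0, 1).
#' @param nCase,nControl sizes of the comparison the score came from.
#' @param model inheritance model.
#' @param iterations Monte-Carlo iterations (default 1e6).
#' @param seed optional seed.
#' @param method "montecarlo" or "analytic".
#' @param smoothing "add-one" or "min-one" (Monte-Carlo only).
#' @return adjusted p-value in (0, 1].
#' @export
mafAdjustedPvalue <- function(observedScore, panelMAF, nCase, nControl,
                              model = "dominant", iterations = 1e6,
                              seed = NULL,
                              method = c("montecarlo", "analytic"),
                              smoothing = c("add-one", "min-one")) {
  method <- match.arg(method)
  smoothing <- match.arg(smoothing)
  if (!is.finite(panelMAF) || panelMAF <= 0 || panelMAF >= 1)
    stop("panelMAF must lie in (0, 1); the null is undefined at ", panelMAF)
  p0 <- carrierProbability(panelMAF, model)
  if (method == "analytic")
    return(min(1, analyticScoreProbability(nCase, nControl, p0, p0,
                                           threshold = observedScore)))
  scores <- withSeed(seed, {
    10 * rbinom(iterations, nCase, p0) - 50 * rbinom(iterations, nControl, p0)
  })
  k <- sum(scores >= observedScore)
  if (smoothing == "add-one") (k + 1) / (iterations + 1) else max(k, 1) / iterations
}

#' Bernoulli resampling null for the number of case-unique variants
#'
#' For a set of variants with per-variant carrier counts \eqn{n_i}, a null
#' draw marks variant i "expected case-specific" with probability
#' \eqn{p^{n_i}} where p is the affected fraction of the cohort (each of the
#' \eqn{n_i} carriers is independently a case with probability p, and the
#' variant counts only when all carriers are cases). Variants with zero
#' carriers are excluded. Returns the empirical distribution of the null
#' count, its analytic mean, the empirical p-value for the observed count
#' (add-one smoothed) and two enrichment summaries.
#'
#' @param carrierCounts integer vector: carriers per variant (n_i).
#' @param affectedFraction fraction of the cohort that is affected (cases /
#'   cohort size).
#' @param observed observed number of case-unique variants in the set.
#' @param iterations null draws (default 10000).
#' @param seed optional seed.
#' @return an [EnrichmentNull-class].
#' @export
enrichmentNull <- function(carrierCounts, affectedFraction, observed,
                           iterations = 1e4, seed = NULL) {
  stopifnot(affectedFraction > 0, affectedFraction < 1, iterations >= 1)
  keep <- carrierCounts > 0
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(nDropped, " variant(s) with zero carriers excluded from the enrichment null")
  n <- carrierCounts[keep]
  pSpec <- affectedFraction^n
  nullCounts <- withSeed(seed, {
    vapply(seq_len(iterations),
           function(i) sum(stats::runif(length(pSpec)) < pSpec), numeric(1))
  })
  expectedMean <- sum(pSpec)
  p <- (sum(nullCounts >= observed) + 1) / (iterations + 1)
  nv <- length(n)
  oddsOf <- function(k) {
    k <- min(max(k, 1e-9), nv - 1e-9)  # guard degenerate 0 or all
    (k / nv) / (1 - k / nv)
  }
  new("EnrichmentNull",
      observed = observed, nullCounts = as.numeric(nullCounts),
      expectedMean = expectedMean, p = p,
      enrichmentRatio = observed / expectedMean,
      oddsRatio = oddsOf(observed) / oddsOf(expectedMean),
      iterations = iterations,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nVariants = nv)
}
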