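test_that("case allele frequency solves the allelic odds-ratio equation", {
  expect_equal(deriveGroupAF(0.1, 2)[["AF_case"]], 0.2 / 1.1)
  expect_equal(deriveGroupAF(0.1, 1)[["AF_case"]], 0.1)
  expect_equal(deriveGroupAF(0.3, 0)[["AF_case"]], 0)
  af <- deriveGroupAF(0.05, 3.7)
  odds <- function(p) p / (1 - p)
  expect_equal(odds(af[["AF_case"]]) / odds(af[["AF_control"]]), 3.7)
  expect_error(deriveGroupAF(0.6, 1), "tMAF")
  expect_error(deriveGroupAF(0.1, -1), "tOR")
})

test_that("carrier-level odds-ratio interpretation is available", {
  af <- deriveGroupAF(0.05, 3, "dominant", interpretation = "carrier")
  odds <- function(p) p / (1 - p)
  qc <- carrierProbability(af[["AF_case"]], "dominant")
  q0 <- carrierProbability(0.05, "dominant")
  expect_equal(odds(qc) / odds(q0), 3)
})

test_that("carrier probability follows Hardy-Weinberg collapsing", {
  expect_equal(carrierProbability(0.02, "dominant"), 0.0396)
  expect_equal(carrierProbability(0.1, "recessive"), 0.01)
  expect_equal(carrierProbability(0, "dominant"), 0)
  expect_equal(carrierProbability(1, "dominant"), 1)
})

test_that("exact score tail matches hand-computed cases", {
  # control side only: P(Y = 0) at p = 0.0396, n = 61
  expect_equal(analyticScoreProbability(0, 61, 0, 0.0396, threshold = 0),
               0.9604^61)
  # certain carriers among >= 2 cases, none among controls
  expect_equal(analyticScoreProbability(5, 61, 1, 0, threshold = 20), 1)
  # threshold 0 includes the all-zero outcome
  p <- analyticScoreProbability(10, 10, 0.1, 0.1, threshold = 0)
  expect_gte(p, dbinom(0, 10, 0.1) * dbinom(0, 10, 0.1))
  # brute-force double summation oracle on a small configuration
  brute <- 0
  for (x in 0:8) for (y in 0:6)
    if (10 * x - 50 * y >= 20)
      brute <- brute + dbinom(x, 8, 0.3) * dbinom(y, 6, 0.2)
  expect_equal(analyticScoreProbability(8, 6, 0.3, 0.2), brute)
})

test_that("degenerate carrier probabilities give degenerate scores", {
  r <- simulateScoreDistribution(49, 61, 0, 0, iterations = 100, seed = 1)
  expect_equal(r$p_positive, 0)
  expect_equal(r$e_score, 0)
})

test_that("Monte-Carlo mean score matches linearity of expectation", {
  p <- 0.0396
  r <- simulateScoreDistribution(49, 61, p, p, iterations = 2e5, seed = 42)
  expected <- 10 * 49 * p - 50 * 61 * p   # -101.376
  sdScore <- sqrt(p * (1 - p) * (100 * 49 + 2500 * 61))
  expect_lt(abs(r$e_score - expected), 3 * sdScore / sqrt(2e5))
})

test_that("Monte-Carlo positive-outcome probability matches the exact tail", {
  set.seed(77)
  for (i in 1:20) {
    nCase <- sample(10:80, 1); nControl <- sample(10:80, 1)
    pCase <- runif(1, 0, 0.3); pControl <- runif(1, 0, 0.3)
    exact <- analyticScoreProbability(nCase, nControl, pCase, pControl)
    mc <- simulateScoreDistribution(nCase, nControl, pCase, pControl,
                                    iterations = 2e4, seed = 1000 + i)
    se <- sqrt(exact * (1 - exact) / 2e4)
    expect_lt(abs(mc$p_positive - exact), 3 * se + 3 / 2e4)
  }
})

test_that("same seed reproduces the Monte-Carlo draw exactly", {
  a <- simulateScoreDistribution(49, 61, 0.1, 0.05, 1e4, seed = 5,
                                 returnScores = TRUE)
  b <- simulateScoreDistribution(49, 61, 0.1, 0.05, 1e4, seed = 5,
                                 returnScores = TRUE)
  expect_identical(a$scores, b$scores)
})

test_that("power surface rises with the odds ratio and vanishes at rare MAF", {
  pg <- powerGrid(nCase = 49, nControl = 61,
                  tMAF = c(0.001, 0.02, 0.05), tOR = c(1, 2, 4, 7),
                  iterations = 2e4, seed = 3)
  df <- as.data.frame(pg)
  for (m in unique(df$tMAF)) {
    p <- df$p_positive[df$tMAF == m][order(df$tOR[df$tMAF == m])]
    mcSlack <- 3 * sqrt(0.25 / 2e4)
    expect_true(all(diff(p) > -mcSlack))
  }
  expect_lt(df$p_positive[df$tMAF == 0.001 & df$tOR == 1], 0.01)
  # e_score increases with tOR at fixed tMAF
  e <- df$e_score[df$tMAF == 0.05][order(df$tOR[df$tMAF == 0.05])]
  expect_true(all(diff(e) > 0))
})

test_that("MAF-adjusted p-value agrees with the exact null tail", {
  exact <- analyticScoreProbability(49, 61, 0.0396, 0.0396, threshold = 20)
  pAdj <- mafAdjustedPvalue(20, 0.02, 49, 61, iterations = 1e5, seed = 9)
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_lt(abs(pAdj - exact), 3 * se + 2e-5)
  expect_equal(mafAdjustedPvalue(20, 0.02, 49, 61, method = "analytic"),
               exact)
})

test_that("MAF-adjusted p-value handles extreme observed scores", {
  # unbeatably low score: every draw is at least as large
  expect_equal(mafAdjustedPvalue(-50 * 61, 0.02, 49, 61,
                                 method = "analytic"), 1)
  # zero observed score: the all-zero draw always qualifies
  p0 <- mafAdjustedPvalue(0, 0.02, 49, 61, method = "analytic")
  expect_gte(p0, dbinom(0, 49, 0.0396) * dbinom(0, 61, 0.0396))
  # a full-case-sweep score at rare MAF is essentially impossible under null
  expect_lt(mafAdjustedPvalue(490, 0.001, 49, 61, method = "analytic"),
            1e-4)
  # Monte-Carlo smoothing keeps p strictly positive
  pMC <- mafAdjustedPvalue(490, 0.001, 49, 61, iterations = 1e4, seed = 2)
  expect_equal(pMC, 1 / (1e4 + 1))
  expect_error(mafAdjustedPvalue(20, 0, 49, 61), "panelMAF")
})

test_that("enrichment null mean equals the closed form sum of p^n", {
  # two singleton variants at affected fraction 1/2
  en <- enrichmentNull(c(1, 1), 0.5, observed = 2, iterations = 5000,
                       seed = 4)
  expect_equal(en@expectedMean, 1.0)
  expect_lt(abs(mean(en@nullCounts) - 1.0), 3 * 0.5 / sqrt(5000))
  # one variant with two carriers at the cohort affected fraction 70/110
  en2 <- enrichmentNull(2, 70 / 110, observed = 1, iterations = 5000,
                        seed = 5)
  pTrue <- (7 / 11)^2
  expect_equal(en2@expectedMean, pTrue)
  expect_lt(abs(mean(en2@nullCounts) - pTrue),
            3 * sqrt(pTrue * (1 - pTrue) / 5000))
})

test_that("observed count at the null mean gives a mid-range empirical p", {
  set.seed(6)
  n <- sample(1:4, 200, replace = TRUE)
  mu <- sum((70 / 110)^n)
  en <- enrichmentNull(n, 70 / 110, observed = round(mu),
                       iterations = 5000, seed = 7)
  expect_gt(en@p, 0.25)
  expect_lt(en@p, 0.75)
})

test_that("zero-carrier variants are excluded from the enrichment null", {
  expect_message(
    en <- enrichmentNull(c(0, 1, 2), 0.5, observed = 1, iterations = 100,
                         seed = 1),
    "zero carriers")
  expect_identical(en@nVariants, 2L)
})
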