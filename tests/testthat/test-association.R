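cmpT2D <- standardComparisons()$T2D_vs_C

test_that("symmetric allele tables give OR 1 and p 1", {
  # 10 cases with 5 het (5 alt / 15 ref), identical controls
  gt <- c(rep(1L, 5), rep(0L, 5), rep(1L, 5), rep(0L, 5))
  groups <- rep(c("T2D", "control"), each = 10)
  r <- singleVariantBinary(gt, groups, cmpT2D)
  expect_equal(r$p, 1)
  expect_equal(r$or_, 1)
  expect_equal(r$alt_case, 5)
  expect_equal(r$ref_case, 15)
})

test_that("monomorphic variants are reported as untestable", {
  gt <- rep(0L, 20)
  groups <- rep(c("T2D", "control"), each = 10)
  r <- singleVariantBinary(gt, groups, cmpT2D)
  expect_equal(r$p, 1)
  expect_true(is.na(r$or_))
})

test_that("exact p equals full hypergeometric enumeration", {
  # allele table 8/12 (cases) vs 1/19 (controls)
  gt <- c(rep(2L, 4), rep(0L, 6), 1L, rep(0L, 9))
  groups <- rep(c("T2D", "control"), each = 10)
  r <- singleVariantBinary(gt, groups, cmpT2D)
  expect_equal(r$alt_case, 8)
  expect_equal(r$alt_control, 1)
  expect_equal(r$p, enumFisherP(8, 12, 1, 19))
  # a second configuration, carriers mode
  r2 <- singleVariantBinary(gt, groups, cmpT2D, mode = "carrier")
  expect_equal(r2$p, enumFisherP(4, 6, 1, 9))
})

test_that("swapping case and control inverts the OR and keeps p", {
  gt <- c(rep(1L, 6), rep(0L, 4), rep(1L, 2), rep(0L, 8))
  groups <- rep(c("T2D", "control"), each = 10)
  fwd <- singleVariantBinary(gt, groups, cmpT2D)
  rev <- singleVariantBinary(gt, groups,
                             list(name = "rev", case = "control",
                                  control = "T2D"))
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$or_, 1 / rev$or_)
})

test_that("outlier trimming is single-pass at 3 SD", {
  # {0,0,0,0,100}: SD ~ 44.7, |100 - 20| = 80 < 3 SD, so all retained
  expect_true(all(trimOutliers(c(0, 0, 0, 0, 100))))
  # identical values: SD 0, nothing trimmed
  expect_true(all(trimOutliers(rep(5, 10))))
  # a genuine outlier goes
  x <- c(rnorm(100), 50)
  expect_false(trimOutliers(x)[101])
  # standard normal: about 0.27% outside 3 SD
  set.seed(55)
  x <- rnorm(10000)
  frac <- mean(!trimOutliers(x))
  expect_lt(abs(frac - 0.0027), 3 * sqrt(0.0027 * 0.9973 / 10000))
})

test_that("quantitative association recovers a noiseless linear effect", {
  n <- 60
  dosage <- rep(c(0L, 1L, 2L), n / 3)
  age <- rep(50, n); sex <- rep(0:1, n / 2)
  trait <- 2 * dosage + 7
  # noiseless fit: lm warns about the essentially perfect fit, by design here
  r <- suppressWarnings(quantitativeAssociation(trait, dosage, age, sex))
  expect_false(r$untestable)
  expect_equal(r$beta, 2, tolerance = 1e-10)
  expect_lt(r$p, 1e-12)
})

test_that("constant dosage and low MAF are flagged untestable", {
  n <- 40
  trait <- rnorm(n); age <- rnorm(n, 50); sex <- rep(0:1, n / 2)
  r <- quantitativeAssociation(trait, rep(1L, n), age, sex)
  expect_true(r$untestable)   # MAF = 0.5 is fine but variance is 0
  r2 <- quantitativeAssociation(trait, c(1L, rep(0L, n - 1)), age, sex)
  expect_true(r2$untestable)
  expect_match(r2$reason, "MAF")
})

test_that("the dosage slope is estimated without bias on synthetic traits", {
  est <- numeric(200)
  for (s in 1:200) {
    set.seed(s)
    dosage <- rbinom(110, 2, 0.3)
    age <- rnorm(110, 53, 10); sex <- rbinom(110, 1, 0.5)
    trait <- 25 + 1.5 * dosage + 0.05 * age + 0.3 * sex + rnorm(110)
    est[s] <- quantitativeAssociation(trait, dosage, age, sex)$beta
  }
  expect_lt(abs(mean(est) - 1.5), 0.1)
})

test_that("burden permutation p matches intuition on a two-sample cohort", {
  gt <- matrix(c(1L, 0L), 1, 2)
  co <- tinyCohort(gt, c("T2D", "control"), gene = "G1", panel_maf = 0.01)
  b <- burdenCaseUnique(co, cmpT2D, mafMax = 0.5, permutations = 2000,
                        seed = 3)
  # the single carrier is a case in half the label assignments
  expect_gt(b$p, 0.42)
  expect_lt(b$p, 0.58)
  expect_identical(b$observed, 1L)
})

test_that("no observed case-unique variants gives p = 1 within smoothing", {
  gt <- matrix(c(1L, 1L, 1L, 1L), 1, 4)  # carried by everyone
  co <- tinyCohort(gt, c("T2D", "T2D", "control", "control"),
                   panel_maf = 0.01)
  b <- suppressMessages(
    burdenCaseUnique(co, cmpT2D, mafMax = 0.5, permutations = 500,
                     seed = 8))
  expect_gte(b$p, 1 - 1e-9)
})

test_that("burden permutation p matches exhaustive enumeration", {
  set.seed(91)
  for (rep in 1:5) {
    nv <- sample(2:4, 1)
    gt <- matrix(sample(c(0L, 1L), nv * 8, replace = TRUE,
                        prob = c(0.6, 0.4)), nv, 8)
    while (!any(rowSums(gt) > 0))
      gt[] <- sample(c(0L, 1L), nv * 8, replace = TRUE)
    groups <- c(rep("T2D", 4), rep("control", 4))
    co <- tinyCohort(gt, groups, gene = "G1", panel_maf = 0.01)
    nPerm <- 4000
    b <- suppressMessages(
      burdenCaseUnique(co, cmpT2D, mafMax = 0.5, permutations = nPerm,
                       seed = rep))
    carriers <- gt >= 1L
    pEnum <- enumBurdenP(carriers, groups == "T2D")
    se <- sqrt(max(pEnum * (1 - pEnum), 1e-4) / nPerm)
    expect_lt(abs(b$p - pEnum), 3 * se + 2 / nPerm)
  }
})

test_that("single-variant tests are calibrated on a null cohort", {
  cfg <- simConfig(blocks = list(variantBlock(400, tMAF = 0.1, tOR = 1)),
                   seed = 71)
  co <- simulateCohort(cfg)
  groups <- sampleGroups(co)
  p <- vapply(seq_len(nrow(co)), function(i)
    singleVariantBinary(genotypes(co)[i, ], groups,
                        standardComparisons()$OBT2D_vs_C)$p, numeric(1))
  # exact tests are conservative: rejection rate at or below nominal + noise
  expect_lte(mean(p <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("replication lookup matches planted panel markers", {
  flagged <- 0L
  panel <- data.frame(chrom = "1", pos = 1010L, ref = "A", alt = "G",
                      rsid = "sim00001", trait = "T2D", source = "study")
  for (s in 1:20) {
    cfg <- simConfig(blocks = list(variantBlock(1, tMAF = 0.1, tOR = 5),
                                   variantBlock(1, tMAF = 0.1, tOR = 1)),
                     seed = 200 + s)
    co <- simulateCohort(cfg)
    groups <- sampleGroups(co)
    res <- do.call(rbind, lapply(1:2, function(i) {
      r <- singleVariantBinary(genotypes(co)[i, ], groups,
                               standardComparisons()$OBT2D_vs_C)
      cbind(chrom = rowData(co)$chrom[i], pos = rowData(co)$pos[i],
            ref = "A", alt = "G", rsid = rowData(co)$rsid[i], r)
    }))
    lk <- replicationLookup(res, panel)
    expect_identical(nrow(lk$matched), 1L)
    if (lk$matched$replicated) flagged <- flagged + 1L
  }
  expect_gte(flagged, 16L)   # strong planted effect: >= 80% of seeds
  # a panel variant absent from the data lands in the not-genotyped report
  lk2 <- replicationLookup(
    data.frame(chrom = "9", pos = 1L, ref = "A", alt = "G", rsid = ".",
               p = 0.5),
    panel)
  expect_identical(nrow(lk2$notGenotyped), 1L)
})

test_that("per-class significance thresholds are applied", {
  res <- data.frame(
    class = c("exome_wide_snp", "exome_wide_snp", "known_gene",
              "case_specific", "case_specific"),
    p = c(5e-7, 2e-6, 0.03, 0.5, 0.5),
    p_adj = c(NA, NA, NA, 0.005, 5e-4))
  out <- applySignificancePolicy(res)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_error(applySignificancePolicy(data.frame(class = "nope", p = 0.1)),
               "threshold")
})
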