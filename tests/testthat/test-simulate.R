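test_that("control genotypes follow Hardy-Weinberg proportions", {
  cfg <- simConfig(nControl = 10000, nOb = 0, nT2d = 0,
                   blocks = list(variantBlock(1, tMAF = 0.1)), seed = 11)
  gt <- simulateGenotypes(cfg)$genotypes
  counts <- tabulate(gt[1, ] + 1L, nbins = 3)
  # closed-form HWE proportions p^2, 2pq, q^2 at q = 0.1
  chi <- suppressWarnings(
    chisq.test(counts, p = c(0.81, 0.18, 0.01)))
  expect_gt(chi$p.value, 0.01)
})

test_that("simulated control allele frequency converges to tMAF", {
  cfg <- simConfig(nControl = 10000, nOb = 0, nT2d = 0,
                   blocks = list(variantBlock(1, tMAF = 0.05)), seed = 12)
  gt <- simulateGenotypes(cfg)$genotypes
  af <- mean(gt[1, ]) / 2
  se <- sqrt(0.05 * 0.95 / (2 * 10000))
  expect_lt(abs(af - 0.05), 3 * se)
})

test_that("tOR = 1 gives equal case and control carrier frequencies", {
  cfg <- simConfig(blocks = list(variantBlock(1000, tMAF = 0.1, tOR = 1)),
                   seed = 13)
  sim <- simulateGenotypes(cfg)
  expect_equal(sim$truth$AF_case, sim$truth$AF_control)
  groups <- rep(c("control", "OB", "T2D"), c(40, 21, 49))
  fCase <- mean(sim$genotypes[, groups != "control"] >= 1)
  fCtrl <- mean(sim$genotypes[, groups == "control"] >= 1)
  expect_lt(abs(fCase - fCtrl), 0.01)
})

test_that("same config and seed give identical output, VCF bytes included", {
  cfg <- simConfig(blocks = list(variantBlock(20, 0.05, tOR = 2)), seed = 7,
                   missingRate = 0.02)
  co1 <- simulateCohort(cfg)
  co2 <- simulateCohort(cfg)
  expect_identical(genotypes(co1), genotypes(co2))
  expect_identical(as.data.frame(colData(co1)), as.data.frame(colData(co2)))
  f1 <- tempfile(); f2 <- tempfile(); s <- tempfile()
  writeCohort(co1, f1, s); writeCohort(co2, f2, s)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid tMAF is rejected with a message naming the block", {
  expect_error(variantBlock(5, tMAF = 0.7, gene = "BADGENE"), "BADGENE")
  expect_error(variantBlock(5, tMAF = 0), "tMAF")
})

test_that("zero noise and zero betas give traits equal to group means", {
  tm <- defaultTraitModels()["bmi"]
  tm$bmi$groupSDs[] <- 0
  cfg <- simConfig(nControl = 3, nOb = 2, nT2d = 2,
                   blocks = list(variantBlock(2, 0.2)),
                   traitModels = tm, seed = 5)
  co <- simulateCohort(cfg)
  expected <- c(control = 22.56, OB = 43.05, T2D = 32.10)
  expect_equal(colData(co)$bmi,
               unname(expected[as.character(colData(co)$group)]))
})

test_that("configured BMI group means are recovered in large cohorts", {
  cfg <- simConfig(nControl = 2000, nOb = 2000, nT2d = 2000,
                   blocks = list(variantBlock(1, 0.2)), seed = 21)
  co <- simulateCohort(cfg)
  d <- colData(co)
  means <- tapply(d$bmi, as.character(d$group), mean)
  sds <- c(control = 1.85, OB = 5.70, T2D = 8.92)
  for (g in names(sds))
    expect_lt(abs(means[[g]] - c(control = 22.56, OB = 43.05,
                                 T2D = 32.10)[[g]]),
              3 * sds[[g]] / sqrt(2000))
})

test_that("a planted dosage effect on a trait is recovered by OLS", {
  hits <- 0L
  for (s in 1:100) {
    tm <- defaultTraitModels()["bmi"]
    tm$bmi$groupSDs[] <- 1
    tm$bmi$groupMeans[] <- 25
    cfg <- simConfig(blocks = list(variantBlock(1, 0.3)), seed = s,
                     traitModels = tm)
    sim <- simulateGenotypes(cfg)
    vid <- rownames(sim$genotypes)[1]
    cfg$traitModels$bmi$betaVariants <- setNames(2.0, vid)
    co <- simulateCohort(cfg)
    fit <- lm(colData(co)$bmi ~ genotypes(co)[1, ])
    ci <- confint(fit)[2, ]
    if (ci[1] <= 2.0 && 2.0 <= ci[2]) hits <- hits + 1L
  }
  # 95% CI should cover the true slope in at least 90 of 100 replicates
  expect_gte(hits, 90L)
})

test_that("trait model referencing an unknown variant is rejected", {
  tm <- defaultTraitModels()
  tm$bmi$betaVariants <- c(nosuchvariant = 1)
  cfg <- simConfig(blocks = list(variantBlock(2, 0.1)), traitModels = tm)
  expect_error(simulateCohort(cfg), "unknown variant")
})

test_that("panel-MAF noise perturbs the panel MAF but not the genotypes", {
  cfg <- simConfig(blocks = list(variantBlock(200, 0.05,
                                              panelMafNoise = 0.5)),
                   seed = 31)
  sim <- simulateGenotypes(cfg)
  pm <- sim$annotations$panel_maf
  expect_gt(sd(pm), 0)
  expect_true(all(pm > 0 & pm < 1))
  # median unchanged on the log-odds scale
  expect_lt(abs(median(qlogis(pm)) - qlogis(0.05)), 0.2)
})

test_that("missingness is injected at the configured rate", {
  cfg <- simConfig(blocks = list(variantBlock(100, 0.1)), seed = 41,
                   missingRate = 0.1)
  gt <- simulateGenotypes(cfg)$genotypes
  rate <- mean(is.na(gt))
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / length(gt)))
})
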