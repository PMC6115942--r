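#' @include null-models.R
NULL

## ---------------------------------------------------------------------------
## Synthetic cohort generator. Defaults emulate the study design this
## package targets: 40 controls, 21 non-diabetic obese, 49 obese T2D
## patients; Hardy-Weinberg genotypes with case-group allele frequencies
## induced by a per-block true odds ratio; annotation fields (gene, effect
## class, three pathogenicity calls, reference-panel MAF); and quantitative
## traits built from group means plus age/sex/dosage effects and Gaussian
## noise.
## ---------------------------------------------------------------------------

#' Define a block of simulated variants
#'
#' All variants in a block share a true population MAF (tMAF), a true
#' allelic odds ratio (tOR) applied to the designated case group(s), an
#' inheritance model, and annotation fields.
#'
#' @param count number of variants in the block.
#' @param tMAF true population minor allele frequency, in (0, 0.5].
#' @param tOR true odds ratio (>= 0) of the alternative allele in the case
#'   group(s); 1 = null variant.
#' @param model causal architecture, "dominant" or "recessive".
#' @param caseGroups which group(s) the odds ratio applies to; the remaining
#'   groups use the control (population) allele frequency.
#' @param effectClass effect annotation, one of [EFFECT_CLASSES].
#' @param damagingVotes for missense variants, how many of the three
#'   predictors (SIFT, PROVEAN, PolyPhen2) call the variant damaging (0-3).
#'   Ignored (predictors "unknown") for other effect classes.
#' @param gene gene symbol; NULL generates one symbol per block.
#' @param implicated whether the gene is on the known T2D/obesity gene list.
#' @param panelMafNoise SD of log-odds noise separating the reference-panel
#'   MAF from tMAF (default 0: panel MAF = tMAF).
#' @return a "VariantBlock" list.
#' @export
variantBlock <- function(count, tMAF, tOR = 1, model = "dominant",
                         caseGroups = c("OB", "T2D"),
                         effectClass = "missense", damagingVotes = 0,
                         gene = NULL, implicated = FALSE,
                         panelMafNoise = 0) {
  if (!is.finite(tMAF) || tMAF <= 0 || tMAF > 0.5)
    stop("variant block '", if (is.null(gene)) "?" else gene,
         "': tMAF must lie in (0, 0.5], got ", tMAF)
  if (tOR < 0) stop("tOR must be >= 0")
  if (!model %in% c("dominant", "recessive")) stop("unknown model: ", model)
  if (!effectClass %in% EFFECT_CLASSES)
    stop("effectClass must be one of: ", paste(EFFECT_CLASSES, collapse = ", "))
  if (!all(caseGroups %in% c("OB", "T2D")))
    stop("caseGroups must be a subset of OB, T2D")
  stopifnot(count >= 1, damagingVotes %in% 0:3, panelMafNoise >= 0)
  structure(list(count = as.integer(count), tMAF = tMAF, tOR = tOR,
                 model = model, caseGroups = caseGroups,
                 effectClass = effectClass,
                 damagingVotes = as.integer(damagingVotes),
                 gene = gene, implicated = isTRUE(implicated),
                 panelMafNoise = panelMafNoise),
            class = "VariantBlock")
}

#' Default trait generative models
#'
#' Group means for BMI follow the descriptive statistics of the emulated
#' three-group design (22.56 / 43.05 / 32.10 kg/m2 for control / OB / T2D,
#' residual SDs 1.85 / 5.70 / 8.92). WHR, fasting glucose (mmol/L) and
#' triglycerides (mmol/L) have no published group summaries in the emulated
#' design and use typical clinical values. Each trait is
#' group mean + betaAge*(age - 55) + betaSex*sex + sum(beta_v * dosage) +
#' Gaussian noise.
#'
#' @return named list of per-trait models.
#' @export
defaultTraitModels <- function() {
  list(
    bmi = list(groupMeans = c(control = 22.56, OB = 43.05, T2D = 32.10),
               groupSDs = c(control = 1.85, OB = 5.70, T2D = 8.92),
               betaAge = 0, betaSex = 0, betaVariants = numeric(0)),
    whr = list(groupMeans = c(control = 0.85, OB = 0.97, T2D = 0.95),
               groupSDs = c(control = 0.06, OB = 0.08, T2D = 0.08),
               betaAge = 0, betaSex = 0, betaVariants = numeric(0)),
    glucose = list(groupMeans = c(control = 5.1, OB = 5.6, T2D = 8.4),
                   groupSDs = c(control = 0.5, OB = 0.9, T2D = 2.4),
                   betaAge = 0, betaSex = 0, betaVariants = numeric(0)),
    tg = list(groupMeans = c(control = 1.2, OB = 1.9, T2D = 2.3),
              groupSDs = c(control = 0.5, OB = 0.9, T2D = 1.1),
              betaAge = 0, betaSex = 0, betaVariants = numeric(0))
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the emulated study design: 40 controls, 21 obese, 49
#' obese+T2D; ages Gaussian around the group means 56.44 / 55.76 / 50.21
#' years (SDs 10.8 / 8.6 / 10.82); male fractions 52.5% / 61.9% / 34.7%.
#'
#' @param nControl,nOb,nT2d group sizes.
#' @param blocks list of [variantBlock()]s.
#' @param seed RNG seed for the whole simulation.
#' @param traitModels per-trait generative models, see
#'   [defaultTraitModels()].
#' @param ageMeans,ageSDs,maleFractions per-group covariate parameters
#'   (named control/OB/T2D).
#' @param missingRate per-genotype missingness probability (default 0).
#' @return a "SimConfig" list.
#' @export
simConfig <- function(nControl = 40, nOb = 21, nT2d = 49,
                      blocks = list(variantBlock(100, tMAF = 0.05)),
                      seed = 1L,
                      traitModels = defaultTraitModels(),
                      ageMeans = c(control = 56.44, OB = 55.76, T2D = 50.21),
                      ageSDs = c(control = 10.8, OB = 8.6, T2D = 10.82),
                      maleFractions = c(control = 0.525, OB = 0.619, T2D = 0.347),
                      missingRate = 0) {
  stopifnot(nControl >= 0, nOb >= 0, nT2d >= 0,
            missingRate >= 0, missingRate < 1)
  if (!length(blocks) || !all(vapply(blocks, inherits, TRUE, "VariantBlock")))
    stop("blocks must be a non-empty list of variantBlock() objects")
  for (tm in traitModels) {
    if (any(tm$groupSDs < 0)) stop("trait residual SD must be >= 0")
  }
  structure(list(nControl = as.integer(nControl), nOb = as.integer(nOb),
                 nT2d = as.integer(nT2d), blocks = blocks,
                 seed = as.integer(seed), traitModels = traitModels,
                 ageMeans = ageMeans, ageSDs = ageSDs,
                 maleFractions = maleFractions, missingRate = missingRate),
            class = "SimConfig")
}

.groupVector <- function(config) {
  factor(rep(c("control", "OB", "T2D"),
             c(config$nControl, config$nOb, config$nT2d)),
         levels = GROUP_LEVELS)
}

#' Simulate genotypes for a configured cohort
#'
#' Each sample's genotype at each variant is a Hardy-Weinberg draw
#' (Binomial(2, AF)) at the group's allele frequency: the control frequency
#' equals the block's tMAF and the designated case group(s) use the
#' frequency implied by the block's tOR ([deriveGroupAF()]). Groups not
#' designated as cases for a block use the control frequency.
#'
#' @param config a [simConfig()].
#' @return list(genotypes = integer matrix (variants x samples),
#'   annotations = DataFrame, truth = data.frame with per-variant tMAF, tOR,
#'   model, case groups and the group allele frequencies used).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  groups <- .groupVector(config)
  nSamples <- length(groups)
  sampleIds <- sprintf("S%03d", seq_len(nSamples))
  nVariants <- sum(vapply(config$blocks, `[[`, 1L, "count"))
  withSeed(config$seed, {
    gt <- matrix(NA_integer_, nVariants, nSamples,
                 dimnames = list(NULL, sampleIds))
    ann <- vector("list", nVariants)
    truth <- vector("list", nVariants)
    v <- 0L
    for (b in seq_along(config$blocks)) {
      blk <- config$blocks[[b]]
      af <- deriveGroupAF(blk$tMAF, blk$tOR, blk$model)
      gene <- if (is.null(blk$gene)) sprintf("GENE%03d", b) else blk$gene
      isCase <- as.character(groups) %in% blk$caseGroups
      afVec <- ifelse(isCase, af[["AF_case"]], af[["AF_control"]])
      votes <- if (blk$effectClass == "missense") blk$damagingVotes else NA_integer_
      preds <- if (is.na(votes)) rep("unknown", 3)
               else c(rep("damaging", votes), rep("tolerated", 3 - votes))
      isIndel <- blk$effectClass %in% c("frameshift", "inframe_indel")
      for (j in seq_len(blk$count)) {
        v <- v + 1L
        gt[v, ] <- rbinom(nSamples, 2L, afVec)
        panelMAF <- if (blk$panelMafNoise > 0)
          plogis(qlogis(blk$tMAF) + rnorm(1, 0, blk$panelMafNoise))
        else blk$tMAF
        ann[[v]] <- data.frame(
          chrom = as.character(b), pos = 1000L + 10L * v,
          ref = if (isIndel) "AT" else "A",
          alt = if (isIndel && blk$effectClass == "frameshift") "A" else
                if (isIndel) "ATGC" else "G",
          rsid = sprintf("sim%05d", v),
          gene = gene, effect = blk$effectClass,
          sift = preds[1], provean = preds[2], pp2 = preds[3],
          panel_maf = panelMAF, implicated = blk$implicated,
          stringsAsFactors = FALSE)
        truth[[v]] <- data.frame(
          block = b, tMAF = blk$tMAF, tOR = blk$tOR, model = blk$model,
          caseGroups = paste(blk$caseGroups, collapse = "+"),
          AF_control = af[["AF_control"]], AF_case = af[["AF_case"]],
          stringsAsFactors = FALSE)
      }
    }
    if (config$missingRate > 0) {
      miss <- matrix(stats::runif(length(gt)) < config$missingRate,
                     nrow(gt), ncol(gt))
      gt[miss] <- NA_integer_
    }
    annotations <- do.call(rbind, ann)
    truth <- do.call(rbind, truth)
    rownames(gt) <- variantKey(annotations)
    truth <- cbind(variant = rownames(gt), truth)
    list(genotypes = gt, annotations = DataFrame(annotations), truth = truth)
  })
}

#' Simulate phenotypes and the sample sheet
#'
#' Assigns group labels by design, samples age and sex from the configured
#' per-group distributions, and builds each quantitative trait as
#' group mean + betaAge*(age - 55) + betaSex*sex + sum(beta_v * dosage) +
#' Gaussian residual.
#'
#' @param config a [simConfig()].
#' @param genotypes genotype matrix from [simulateGenotypes()] (used for
#'   per-variant trait effects; missing dosages count as 0 toward the trait).
#' @return DataFrame: sample_id, group, age, sex (0=female, 1=male) and one
#'   column per trait.
#' @export
simulatePhenotypes <- function(config, genotypes) {
  stopifnot(inherits(config, "SimConfig"))
  groups <- .groupVector(config)
  n <- length(groups)
  if (ncol(genotypes) != n)
    stop("genotype matrix does not match the configured cohort size")
  for (tm in config$traitModels) {
    unknown <- setdiff(names(tm$betaVariants), rownames(genotypes))
    if (length(unknown))
      stop("trait model references unknown variant(s): ",
           paste(unknown, collapse = ", "))
  }
  withSeed(childSeed(config$seed, 999L), {
    g <- as.character(groups)
    age <- rnorm(n, config$ageMeans[g], config$ageSDs[g])
    sex <- as.integer(stats::runif(n) < config$maleFractions[g])
    sheet <- DataFrame(sample_id = colnames(genotypes),
                       group = groups, age = age, sex = sex)
    for (trait in names(config$traitModels)) {
      tm <- config$traitModels[[trait]]
      y <- tm$groupMeans[g] + tm$betaAge * (age - 55) + tm$betaSex * sex
      for (vid in names(tm$betaVariants)) {
        dose <- genotypes[vid, ]
        dose[is.na(dose)] <- 0L
        y <- y + tm$betaVariants[[vid]] * dose
      }
      y <- y + rnorm(n, 0, tm$groupSDs[g])
      sheet[[trait]] <- unname(y)
    }
    sheet
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: [simulateGenotypes()] + [simulatePhenotypes()] +
#' [ExomeCohort()]. The truth table is stored in the cohort metadata.
#'
#' @param config a [simConfig()].
#' @return an [ExomeCohort-class] with \code{metadata(x)$truth}.
#' @export
simulateCohort <- function(config) {
  sim <- simulateGenotypes(config)
  design <- simulatePhenotypes(config, sim$genotypes)
  ExomeCohort(sim$genotypes, sim$annotations, design,
              metadata = list(truth = sim$truth, simConfig = config))
}

#' Write a cohort to a VCF (v4.2) and sample-sheet TSV
#'
#' Emits a biallelic VCF with INFO keys GENE, EFF, SIFT, PROVEAN, PP2,
#' PANEL_AF and GT genotypes (missing written as "./."). No file-date header
#' line is written, so identical cohorts yield byte-identical files. The
#' sample sheet carries sample_id, group, age, sex and the quantitative
#' traits.
#'
#' @param cohort an [ExomeCohort-class].
#' @param vcfPath,sheetPath output paths.
#' @return invisibly, the two paths.
#' @export
writeCohort <- function(cohort, vcfPath, sheetPath) {
  gt <- genotypes(cohort)
  ann <- rowData(cohort)
  design <- colData(cohort)
  if (!identical(colnames(gt), rownames(design)))
    stop("sample mismatch between genotype matrix and design")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=casespec",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT call\">",
    "##INFO=<ID=PROVEAN,Number=1,Type=String,Description=\"PROVEAN call\">",
    "##INFO=<ID=PP2,Number=1,Type=String,Description=\"PolyPhen2 call\">",
    "##INFO=<ID=PANEL_AF,Number=1,Type=Float,Description=\"Reference panel MAF\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  )
  gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  gtStr[is.na(gt)] <- "./."
  lines <- hdr
  if (nrow(gt) > 0) {
    info <- sprintf("GENE=%s;EFF=%s;SIFT=%s;PROVEAN=%s;PP2=%s;PANEL_AF=%s",
                    ann$gene, ann$effect, ann$sift, ann$provean, ann$pp2,
                    format(ann$panel_maf, digits = 10, scientific = FALSE,
                           trim = TRUE))
    rsid <- if ("rsid" %in% colnames(ann)) ann$rsid else rep(".", nrow(gt))
    body <- paste(ann$chrom, ann$pos, rsid, ann$ref, ann$alt, ".", "PASS",
                  info, "GT",
                  apply(gtStr, 1L, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, vcfPath)
  sheet <- as.data.frame(design)
  sheet$group <- as.character(sheet$group)
  write.table(sheet, sheetPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcfPath, sheet = sheetPath))
}

#' Write a known-gene list (one symbol per line)
#'
#' @param genes character vector of gene symbols.
#' @param path output path.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(unique(genes), path)
  invisible(path)
}
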