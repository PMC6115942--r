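#' @include scores.R
NULL

## ---------------------------------------------------------------------------
## Conventional association layer: exact single-variant tests on the four
## comparisons, covariate-adjusted quantitative-trait regression with
## single-pass outlier trimming, the case-unique gene burden permutation
## test, the replication-panel lookup, and the per-class significance
## policy.
## ---------------------------------------------------------------------------

#' Exact single-variant binary association test
#'
#' Two-sided Fisher exact test on the 2x2 table of alternative/reference
#' allele counts (default) or carrier/non-carrier counts between the
#' comparison's case and control samples. The reported odds ratio is the
#' sample cross-product, with 0.5 added to every cell when any cell is zero.
#' A variant monomorphic in both groups gets p = 1 and a missing OR.
#'
#' @param genotypeRow integer dosage vector (0/1/2/NA) over samples.
#' @param groups sample group labels.
#' @param comparison one comparison from [standardComparisons()].
#' @param mode "allele" (allele-count table) or "carrier" (dominant carrier
#'   table).
#' @return data.frame row: comparison, p, or_, n_used, a/b/c/d table cells.
#' @export
singleVariantBinary <- function(genotypeRow, groups, comparison,
                                mode = c("allele", "carrier")) {
  mode <- match.arg(mode)
  .checkComparison(comparison, groups)
  caseIdx <- groups %in% comparison$case & !is.na(genotypeRow)
  ctrlIdx <- groups %in% comparison$control & !is.na(genotypeRow)
  if (mode == "allele") {
    a <- sum(genotypeRow[caseIdx])          # alt alleles, cases
    b <- 2 * sum(caseIdx) - a               # ref alleles, cases
    cc <- sum(genotypeRow[ctrlIdx])         # alt alleles, controls
    d <- 2 * sum(ctrlIdx) - cc
  } else {
    carrier <- genotypeRow >= 1L
    a <- sum(carrier[caseIdx])
    b <- sum(caseIdx) - a
    cc <- sum(carrier[ctrlIdx])
    d <- sum(ctrlIdx) - cc
  }
  tab <- matrix(c(a, b, cc, d), 2L, byrow = TRUE)
  if ((a + cc) == 0 || (b + d) == 0) {     # monomorphic in both groups
    p <- 1; or_ <- NA_real_
  } else {
    p <- fisher.test(tab)$p.value
    if (any(tab == 0)) tab <- tab + 0.5
    or_ <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  data.frame(comparison = comparison$name, p = p, or_ = or_,
             n_used = sum(caseIdx) + sum(ctrlIdx),
             alt_case = a, ref_case = b, alt_control = cc, ref_control = d)
}

#' Single-pass outlier trimming
#'
#' Removes values more than 3 standard deviations from the mean, with mean
#' and SD computed once on the full vector (not iterated).
#'
#' @param values numeric vector (NAs are dropped).
#' @param nSD trim multiplier (default 3).
#' @return logical keep-mask over \code{values} (NA values get FALSE).
#' @export
trimOutliers <- function(values, nSD = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 2) return(ok)
  m <- mean(values[ok]); s <- sd(values[ok])
  keep <- ok & (s == 0 | abs(values - m) <= nSD * s)
  keep[is.na(keep)] <- FALSE
  keep
}

#' Covariate-adjusted quantitative-trait association
#'
#' Pools all study participants, trims trait outliers in a single pass
#' ([trimOutliers()]), and fits trait ~ dosage + age + sex by ordinary
#' least squares, reporting the dosage slope and its two-sided p. Variants
#' with dataset MAF at or below \code{mafMin} (computed over the supplied
#' dosages) are flagged untestable, as are fits with zero dosage variance
#' after trimming or fewer than \code{minN} retained samples.
#'
#' @param trait numeric trait values per sample.
#' @param dosage genotype dosages (0/1/2/NA) per sample.
#' @param age,sex covariates.
#' @param mafMin dataset-MAF lower bound (exclusive; default 0.05).
#' @param minN minimum retained samples (default 10).
#' @return data.frame row: beta, se, p, n_used, untestable, reason.
#' @export
quantitativeAssociation <- function(trait, dosage, age, sex,
                                    mafMin = 0.05, minN = 10) {
  res <- function(beta = NA_real_, se = NA_real_, p = NA_real_, n = 0L,
                  untestable = FALSE, reason = "") {
    data.frame(beta = beta, se = se, p = p, n_used = n,
               untestable = untestable, reason = reason)
  }
  maf <- datasetMAF(matrix(dosage, nrow = 1))[1]
  if (is.na(maf) || maf <= mafMin)
    return(res(untestable = TRUE, reason = "dataset MAF at or below threshold"))
  keep <- trimOutliers(trait) & !is.na(dosage) & !is.na(age) & !is.na(sex)
  if (sum(keep) < minN)
    return(res(untestable = TRUE, reason = "too few samples after trimming"))
  if (var(dosage[keep]) == 0)
    return(res(untestable = TRUE, reason = "zero dosage variance after trimming"))
  fit <- lm(trait[keep] ~ dosage[keep] + age[keep] + sex[keep])
  cf <- summary(fit)$coefficients
  res(beta = cf[2, 1], se = cf[2, 2], p = cf[2, 4], n = sum(keep))
}

#' Case-unique gene burden test with permutation null
#'
#' The per-gene statistic is the number of qualifying variants (dataset MAF
#' at most \code{mafMax}) whose carriers are exclusively cases (at least one
#' carrier, zero control carriers). The null permutes the case/control
#' labels of the comparison's samples; p = (permutations with statistic >=
#' observed + 1) / (permutations + 1).
#'
#' @param cohort an [ExomeCohort-class].
#' @param comparison one comparison from [standardComparisons()].
#' @param model inheritance model for carrier collapsing.
#' @param mafMax dataset-MAF upper bound (inclusive; default 0.05).
#' @param permutations label permutations (default 10000).
#' @param seed optional seed.
#' @return data.frame: gene, observed, p, n_variants.
#' @export
burdenCaseUnique <- function(cohort, comparison, model = "dominant",
                             mafMax = 0.05, permutations = 1e4,
                             seed = NULL) {
  groups <- sampleGroups(cohort)
  .checkComparison(comparison, groups)
  inCmp <- groups %in% c(comparison$case, comparison$control)
  keepVar <- !is.na(dataMAF(cohort)) & dataMAF(cohort) <= mafMax
  if (!any(keepVar)) {
    message("no variant passes the MAF filter; burden test skipped")
    return(data.frame(gene = character(), observed = integer(),
                      p = numeric(), n_variants = integer()))
  }
  carriers <- collapseGenotypes(cohort, model)[keepVar, inCmp, drop = FALSE]
  carriers[is.na(carriers)] <- FALSE   # missing genotype: not a carrier
  genes <- as.character(rowData(cohort)$gene[keepVar])
  anyCarrier <- rowSums(carriers) > 0
  geneLevels <- sort(unique(genes[!is.na(genes)]))
  geneF <- factor(genes, levels = geneLevels)
  isCase <- (groups[inCmp] %in% comparison$case)
  geneStat <- function(caseMask) {
    ctrlFree <- rowSums(carriers[, !caseMask, drop = FALSE]) == 0
    as.vector(tapply(anyCarrier & ctrlFree, geneF, sum, default = 0L))
  }
  obs <- geneStat(isCase)
  perm <- withSeed(seed, {
    vapply(seq_len(permutations),
           function(i) geneStat(sample(isCase)), numeric(length(obs)))
  })
  perm <- matrix(perm, nrow = length(obs))
  pvals <- (rowSums(perm >= obs) + 1) / (permutations + 1)
  out <- data.frame(gene = geneLevels, observed = as.integer(obs),
                    p = pvals,
                    n_variants = as.vector(table(geneF)),
                    row.names = NULL)
  geneHasCarrier <- as.vector(tapply(anyCarrier, geneF, any, default = FALSE))
  if (any(!geneHasCarrier))
    message(sum(!geneHasCarrier), " gene(s) without any carrier skipped: ",
            paste(head(geneLevels[!geneHasCarrier]), collapse = ", "))
  out[geneHasCarrier, , drop = FALSE]
}

#' Replication lookup against a known-marker panel
#'
#' Matches association results to panel variants by chrom/pos/ref/alt, with
#' rsid as fallback, and flags nominal significance at \code{alpha}.
#'
#' @param results data.frame with chrom, pos, ref, alt, rsid and p columns.
#' @param panel marker panel from [readMarkerPanel()].
#' @param alpha replication significance level (default 0.05).
#' @return list(matched = results subset with \code{replicated} flag,
#'   notGenotyped = panel rows absent from the results).
#' @export
replicationLookup <- function(results, panel, alpha = 0.05) {
  keyR <- paste(results$chrom, results$pos, results$ref, results$alt)
  keyP <- paste(panel$chrom, panel$pos, panel$ref, panel$alt)
  hit <- keyR %in% keyP
  if ("rsid" %in% colnames(results))
    hit <- hit | (results$rsid %in% panel$rsid & results$rsid != ".")
  matched <- results[hit, , drop = FALSE]
  if (nrow(matched)) matched$replicated <- matched$p < alpha
  inData <- keyP %in% keyR |
    (panel$rsid %in% results$rsid[results$rsid != "."])
  list(matched = matched, notGenotyped = panel[!inData, , drop = FALSE])
}

#' Default per-class significance thresholds
#' @export
significanceThresholds <- function() {
  c(exome_wide_snp = 1e-6, exome_wide_gene = 2.5e-6,
    known_gene = 0.05, case_specific = 0.001, replication = 0.05)
}

#' Apply the per-class significance policy
#'
#' Flags each result against its class threshold: exome-wide SNP tests at
#' 1e-6, gene-level tests at 2.5e-6, known-gene candidates at 0.05,
#' case-specific variants at 0.001 (on the MAF-adjusted p where present),
#' replication lookups at 0.05.
#'
#' @param results data.frame with a \code{class} column and \code{p} (and
#'   optionally \code{p_adj}) columns.
#' @param thresholds named vector, see [significanceThresholds()].
#' @return \code{results} with a logical \code{significant} column.
#' @export
applySignificancePolicy <- function(results,
                                    thresholds = significanceThresholds()) {
  if (!nrow(results)) {
    results$significant <- logical(0)
    return(results)
  }
  unknown <- setdiff(unique(results$class), names(thresholds))
  if (length(unknown))
    stop("no threshold for class(es): ", paste(unknown, collapse = ", "))
  pEff <- results$p
  if ("p_adj" %in% colnames(results)) {
    useAdj <- results$class == "case_specific" & !is.na(results$p_adj)
    pEff[useAdj] <- results$p_adj[useAdj]
  }
  results$significant <- pEff < thresholds[results$class]
  results
}
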