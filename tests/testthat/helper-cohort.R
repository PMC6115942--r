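# Shared fixtures, built in code.

tinyAnnotations <- function(n, gene = "GENEA", effect = "missense",
                            sift = "unknown", provean = "unknown",
                            pp2 = "unknown", panel_maf = 0.05,
                            implicated = FALSE) {
  df <- data.frame(chrom = "1", pos = 100L * seq_len(max(n, 1)), ref = "A",
                   alt = "G", rsid = sprintf("rs%d", seq_len(max(n, 1))),
                   gene = gene, effect = effect, sift = sift,
                   provean = provean, pp2 = pp2, panel_maf = panel_maf,
                   implicated = implicated, stringsAsFactors = FALSE)
  df[seq_len(n), , drop = FALSE]
}

tinyDesign <- function(groups) {
  n <- length(groups)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)), group = groups,
             age = 50 + seq_len(n) %% 10, sex = seq_len(n) %% 2,
             stringsAsFactors = FALSE)
}

tinyCohort <- function(gt, groups, ...) {
  gt <- as.matrix(gt)
  colnames(gt) <- sprintf("S%02d", seq_len(ncol(gt)))
  ExomeCohort(gt, tinyAnnotations(nrow(gt), ...), tinyDesign(groups))
}

# Independent brute-force scorer: per-sample iteration, no vectorization.
bruteForceScores <- function(gt, groups, caseGroups, controlGroups, model) {
  t(apply(gt, 1, function(row) {
    nCase <- 0L; nControl <- 0L
    for (j in seq_along(row)) {
      g <- row[j]
      if (is.na(g)) next
      carrier <- if (model == "dominant") g >= 1 else g == 2
      if (!carrier) next
      if (groups[j] %in% caseGroups) nCase <- nCase + 1L
      else if (groups[j] %in% controlGroups) nControl <- nControl + 1L
    }
    c(n_case = nCase, n_control = nControl,
      score1 = 10L * nCase - 50L * nControl,
      score2 = 10L * nControl - 50L * nCase)
  }))
}

# Exact two-sided Fisher p by enumeration over all tables with fixed margins.
enumFisherP <- function(a, b, c_, d) {
  rowTot <- a + b; colTot <- a + c_; n <- a + b + c_ + d
  ks <- max(0, colTot - (n - rowTot)):min(rowTot, colTot)
  probs <- dhyper(ks, rowTot, n - rowTot, colTot)
  pObs <- dhyper(a, rowTot, n - rowTot, colTot)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exhaustive burden-test p on a tiny cohort: enumerate every assignment of
# case labels over the samples (fixed case count), count genes' case-unique
# variants at least as extreme as observed.
enumBurdenP <- function(carriers, isCase) {
  n <- length(isCase); k <- sum(isCase)
  stat <- function(mask) {
    sum(apply(carriers, 1, function(r) any(r) && !any(r & !mask)))
  }
  obs <- stat(isCase)
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2, function(idx) {
    mask <- rep(FALSE, n); mask[idx] <- TRUE; stat(mask)
  })
  mean(stats >= obs)
}
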