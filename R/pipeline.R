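#' @include association.R filters.R simulate.R io.R
NULL

#' Pipeline run configuration
#'
#' Exactly one of \code{sim} (a [simConfig()]) or \code{paths} (named list
#' with \code{vcf}, \code{sheet}, optionally \code{geneList},
#' \code{markerPanel}) must be supplied.
#'
#' @param sim simulation block, a [simConfig()].
#' @param paths input-file block.
#' @param comparisons names of the standard comparisons to run (default all
#'   four).
#' @param model inheritance model for scoring and burden (default
#'   "dominant"; the recessive model can be scored alongside).
#' @param scoreThreshold case-specific selection threshold on Score1
#'   (default 20).
#' @param consensusK missense damaging-vote consensus (default 2 of 3).
#' @param knownGeneMafWindow exclusive panel-MAF window for the known-gene
#'   class (default 0.01-0.1).
#' @param caseSpecificMafMax exclusive panel-MAF upper bound for the
#'   case-specific class (default 0.1).
#' @param quantMafMin dataset-MAF lower bound for quantitative tests
#'   (default 0.05).
#' @param burdenMafMax dataset-MAF upper bound for the burden test
#'   (default 0.05).
#' @param traits quantitative traits to test.
#' @param adjustedPIterations Monte-Carlo iterations for the MAF-adjusted
#'   p-value (default 1e6).
#' @param adjustedPMethod "montecarlo" or "analytic".
#' @param enrichmentIterations draws for the enrichment null (default 1e4).
#' @param permutations burden-test permutations (default 1e4).
#' @param powerGridSpec list(tMAF=, tOR=, iterations=) for the power-surface
#'   artifact; NULL skips it. The default is a coarse 10 x 7 summary grid;
#'   use [powerGrid()] directly for the full 7000-cell surface.
#' @param thresholds per-class significance thresholds.
#' @param seed root seed; all Monte-Carlo stages derive child seeds from it.
#' @param outDir output directory (created if needed); NULL writes nothing.
#' @return a "RunConfig" list.
#' @export
runConfig <- function(sim = NULL, paths = NULL,
                      comparisons = names(standardComparisons()),
                      model = "dominant", scoreThreshold = 20,
                      consensusK = 2, knownGeneMafWindow = c(0.01, 0.1),
                      caseSpecificMafMax = 0.1, quantMafMin = 0.05,
                      burdenMafMax = 0.05,
                      traits = c("bmi", "whr", "glucose", "tg"),
                      adjustedPIterations = 1e6,
                      adjustedPMethod = "montecarlo",
                      enrichmentIterations = 1e4, permutations = 1e4,
                      powerGridSpec = list(
                        tMAF = seq(0.005, 0.1, length.out = 10),
                        tOR = 1:7, iterations = 2e4),
                      thresholds = significanceThresholds(),
                      seed = 1L, outDir = NULL) {
  if (is.null(sim) == is.null(paths))
    stop("supply exactly one of 'sim' or 'paths'")
  stopifnot(all(comparisons %in% names(standardComparisons())),
            adjustedPIterations >= 1, enrichmentIterations >= 1,
            permutations >= 1, scoreThreshold >= 0)
  structure(list(sim = sim, paths = paths, comparisons = comparisons,
                 model = model, scoreThreshold = scoreThreshold,
                 consensusK = consensusK,
                 knownGeneMafWindow = knownGeneMafWindow,
                 caseSpecificMafMax = caseSpecificMafMax,
                 quantMafMin = quantMafMin, burdenMafMax = burdenMafMax,
                 traits = traits,
                 adjustedPIterations = adjustedPIterations,
                 adjustedPMethod = adjustedPMethod,
                 enrichmentIterations = enrichmentIterations,
                 permutations = permutations,
                 powerGridSpec = powerGridSpec, thresholds = thresholds,
                 seed = as.integer(seed), outDir = outDir),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full prioritization pipeline
#'
#' Executes: load (or simulate) cohort -> variant filters -> case-
#' specificity scoring over the configured comparisons -> replication
#' lookup, exome-wide single-variant tests, quantitative-trait tests,
#' known-gene candidate class, case-specific class with MAF-adjusted
#' p-values, case-unique gene burden, enrichment null for case-unique
#' counts, and an optional power-surface artifact. When \code{outDir} is
#' set, every table is written as TSV along with a run-metadata YAML and a
#' filter ledger accounting for every variant.
#'
#' @param config a [runConfig()].
#' @return invisible list with elements cohort, scores, replication,
#'   exomeWide, quantitative, knownGene, caseSpecific, burden, enrichment,
#'   powerGrid, classification, ledger, metadata.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  rootSeed <- config$seed

  cohort <- .stage("load", {
    if (!is.null(config$sim)) simulateCohort(config$sim)
    else readCohort(config$paths$vcf, config$paths$sheet,
                    geneList = config$paths$geneList)
  })
  panel <- if (!is.null(config$paths$markerPanel))
    .stage("load", readMarkerPanel(config$paths$markerPanel)) else NULL
  ann <- rowData(cohort)
  groups <- sampleGroups(cohort)
  cmps <- standardComparisons()[config$comparisons]
  vkeys <- rownames(cohort)

  scores <- .stage("score",
    computeScores(cohort, cmps, model = config$model))

  ## -- exome-wide single-variant binary tests -----------------------------
  exomeWide <- .stage("exome_wide", {
    out <- list()
    for (cmp in cmps) {
      rows <- lapply(seq_along(vkeys), function(i)
        singleVariantBinary(genotypes(cohort)[i, ], groups, cmp))
      df <- do.call(rbind, rows)
      df <- cbind(variant = vkeys, chrom = ann$chrom, pos = ann$pos,
                  ref = ann$ref, alt = ann$alt,
                  rsid = if ("rsid" %in% colnames(ann)) ann$rsid else ".",
                  gene = ann$gene, df)
      out[[cmp$name]] <- df
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })

  replication <- if (!is.null(panel))
    .stage("replication", replicationLookup(exomeWide, panel,
                                            config$thresholds["replication"]))
  else NULL

  ## -- quantitative traits (pooled, covariate-adjusted) -------------------
  quantitative <- .stage("quantitative", {
    design <- colData(cohort)
    out <- list()
    for (trait in intersect(config$traits, colnames(design))) {
      for (i in seq_along(vkeys)) {
        r <- quantitativeAssociation(design[[trait]], genotypes(cohort)[i, ],
                                     design$age, design$sex,
                                     mafMin = config$quantMafMin)
        if (!r$untestable)
          out[[length(out) + 1L]] <- cbind(
            variant = vkeys[i], gene = ann$gene[i], trait = trait, r)
      }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(variant = character(), gene = character(),
                    trait = character(), beta = numeric(), se = numeric(),
                    p = numeric(), n_used = integer(),
                    untestable = logical(), reason = character())
  })

  ## -- candidate class (i): protein-altering in known genes ---------------
  knownGeneSel <- .stage("known_gene",
    selectKnownGeneCandidates(cohort, config$consensusK,
                              config$knownGeneMafWindow))
  knownGene <- exomeWide[exomeWide$variant %in% vkeys[knownGeneSel], ,
                         drop = FALSE]
  if (nrow(knownGene)) knownGene$class <- "known_gene"

  ## -- candidate class (ii): case-specific, low panel MAF ------------------
  caseSpecific <- .stage("case_specific", {
    sel <- selectSpecificVariants(scores, "case", config$scoreThreshold)
    pm <- panelMAF(cohort)[sel$variant]
    sel <- sel[!is.na(pm) & pm > 0 & pm < config$caseSpecificMafMax, ,
               drop = FALSE]
    if (nrow(sel)) {
      sizes <- vapply(cmps, function(cmp) {
        c(sum(groups %in% cmp$case), sum(groups %in% cmp$control))
      }, numeric(2))
      padj <- numeric(nrow(sel))
      for (i in seq_len(nrow(sel))) {
        sz <- sizes[, sel$comparison[i]]
        padj[i] <- mafAdjustedPvalue(
          sel$score1[i], panelMAF(cohort)[[sel$variant[i]]],
          nCase = sz[1], nControl = sz[2], model = sel$model[i],
          iterations = config$adjustedPIterations,
          seed = childSeed(rootSeed, 5000L + i),
          method = config$adjustedPMethod)
      }
      fisherP <- vapply(seq_len(nrow(sel)), function(i) {
        exomeWide$p[exomeWide$variant == sel$variant[i] &
                    exomeWide$comparison == sel$comparison[i]][1]
      }, numeric(1))
      df <- as.data.frame(sel)
      idx <- match(df$variant, vkeys)
      cbind(df[, c("variant", "comparison", "model", "n_case", "n_control",
                   "score1", "score2")],
            gene = ann$gene[idx], panel_maf = ann$panel_maf[idx],
            dataset_maf = ann$dataset_maf[idx],
            maf_bin = as.character(mafBin(ann$panel_maf[idx])),
            p = fisherP, p_adj = padj, class = "case_specific")
    } else data.frame()
  })

  ## -- case-unique gene burden --------------------------------------------
  burden <- .stage("burden", {
    out <- list()
    for (k in seq_along(cmps)) {
      b <- burdenCaseUnique(cohort, cmps[[k]], model = config$model,
                            mafMax = config$burdenMafMax,
                            permutations = config$permutations,
                            seed = childSeed(rootSeed, 100L + k))
      if (nrow(b)) out[[length(out) + 1L]] <-
        cbind(comparison = cmps[[k]]$name, b)
    }
    if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
    else data.frame(comparison = character(), gene = character(),
                    observed = integer(), p = numeric(),
                    n_variants = integer())
  })

  ## -- enrichment null for case-unique protein-altering variants ----------
  enrichment <- .stage("enrichment", {
    pa <- classifyProteinAltering(ann, config$consensusK)
    carriers <- collapseGenotypes(cohort, config$model)
    carriers[is.na(carriers)] <- FALSE
    affected <- groups %in% c("OB", "T2D")
    res <- list()
    for (set in c("implicated", "non_implicated")) {
      inSet <- pa & (if (set == "implicated") ann$implicated
                     else !ann$implicated)
      if (!any(inSet)) next
      n <- rowSums(carriers[inSet, , drop = FALSE])
      ctrlCarr <- rowSums(carriers[inSet, !affected, drop = FALSE])
      observed <- sum(n > 0 & ctrlCarr == 0)
      res[[set]] <- suppressMessages(enrichmentNull(
        n, mean(affected), observed,
        iterations = config$enrichmentIterations,
        seed = childSeed(rootSeed, if (set == "implicated") 201L else 202L)))
    }
    res
  })

  ## -- power surface artifact ---------------------------------------------
  pg <- if (!is.null(config$powerGridSpec)) .stage("power_grid", {
    sz <- .comparisonSizes(groups, cmps[[length(cmps)]])
    powerGrid(nCase = sz[1], nControl = sz[2], model = config$model,
              tMAF = config$powerGridSpec$tMAF,
              tOR = config$powerGridSpec$tOR,
              iterations = config$powerGridSpec$iterations,
              seed = childSeed(rootSeed, 300L),
              threshold = config$scoreThreshold)
  }) else NULL

  ## -- classification ledger: every variant in exactly one class ----------
  csVariants <- if (nrow(caseSpecific)) unique(caseSpecific$variant)
                else character()
  classification <- data.frame(
    variant = vkeys,
    class = ifelse(knownGeneSel, "known_gene",
            ifelse(vkeys %in% csVariants, "case_specific", "unselected")))
  ledger <- data.frame(
    stage = c("input", "protein_altering", "known_gene_class",
              "case_specific_class", "unselected"),
    n = c(length(vkeys), sum(classifyProteinAltering(ann, config$consensusK)),
          sum(knownGeneSel),
          sum(classification$class == "case_specific"),
          sum(classification$class == "unselected")))

  ## -- significance policy -------------------------------------------------
  if (nrow(knownGene))
    knownGene <- applySignificancePolicy(knownGene, config$thresholds)
  if (nrow(caseSpecific))
    caseSpecific <- applySignificancePolicy(caseSpecific, config$thresholds)
  ew <- cbind(exomeWide, class = "exome_wide_snp")
  ew <- applySignificancePolicy(ew, config$thresholds)
  bu <- if (nrow(burden))
    applySignificancePolicy(cbind(burden, class = "exome_wide_gene"),
                            config$thresholds) else burden

  metadata <- list(
    seed = rootSeed, comparisons = config$comparisons,
    model = config$model, score_threshold = config$scoreThreshold,
    consensus_k = config$consensusK,
    adjusted_p_iterations = config$adjustedPIterations,
    adjusted_p_method = config$adjustedPMethod,
    enrichment_iterations = config$enrichmentIterations,
    burden_permutations = config$permutations,
    n_variants = length(vkeys), n_samples = ncol(cohort),
    child_seeds = list(adjusted_p = "root + 5000 + variant index",
                       burden = "root + 100 + comparison index",
                       enrichment = c(201L, 202L), power_grid = 300L))

  result <- list(cohort = cohort, scores = scores,
                 replication = replication, exomeWide = ew,
                 quantitative = quantitative, knownGene = knownGene,
                 caseSpecific = caseSpecific, burden = bu,
                 enrichment = enrichment, powerGrid = pg,
                 classification = classification, ledger = ledger,
                 metadata = metadata)
  if (!is.null(config$outDir)) writeReportBundle(result, config$outDir)
  invisible(result)
}

.comparisonSizes <- function(groups, cmp) {
  c(sum(groups %in% cmp$case), sum(groups %in% cmp$control))
}

#' Write the pipeline report bundle
#'
#' Emits one TSV per table (replication, exome-wide, quantitative,
#' known-gene candidates, case-specific candidates, burden, enrichment
#' null, power grid, classification, filter ledger) plus run_metadata.yaml.
#' Output is deterministic: no timestamps are written.
#'
#' @param result list from [runPipeline()].
#' @param outDir output directory.
#' @return invisibly, the directory.
#' @export
writeReportBundle <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    write.table(as.data.frame(df), file.path(outDir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(result$scores, "scores.tsv")
  if (!is.null(result$replication)) {
    wt(result$replication$matched, "replication.tsv")
    wt(result$replication$notGenotyped, "replication_not_genotyped.tsv")
  }
  wt(result$exomeWide, "exome_wide.tsv")
  wt(result$quantitative, "quantitative.tsv")
  wt(result$knownGene, "known_gene_candidates.tsv")
  wt(result$caseSpecific, "case_specific.tsv")
  wt(result$burden, "burden.tsv")
  if (length(result$enrichment)) {
    en <- do.call(rbind, lapply(names(result$enrichment), function(s) {
      e <- result$enrichment[[s]]
      data.frame(set = s, observed = e@observed,
                 expected_mean = e@expectedMean, empirical_p = e@p,
                 enrichment_ratio = e@enrichmentRatio,
                 odds_ratio = e@oddsRatio, n_variants = e@nVariants)
    }))
    wt(en, "enrichment.tsv")
  }
  if (!is.null(result$powerGrid))
    wt(as.data.frame(result$powerGrid), "power_grid.tsv")
  wt(result$classification, "classification.tsv")
  wt(result$ledger, "filter_ledger.tsv")
  yaml::write_yaml(result$metadata, file.path(outDir, "run_metadata.yaml"))
  invisible(outDir)
}
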