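#' @include casespec-package.R
NULL

## Controlled vocabularies ---------------------------------------------------

#' Effect-class vocabulary
#'
#' Controlled vocabulary for the per-variant effect annotation (the EFF INFO
#' key). Mirrors the coarse consequence classes of standard effect
#' annotators.
#'
#' @export
EFFECT_CLASSES <- c(
  "missense", "stop_gained", "stop_lost", "start_lost", "frameshift",
  "inframe_indel", "splice_acceptor", "splice_donor", "synonymous",
  "intron", "other"
)

## Effects that alter the protein irrespective of missense predictions.
PROTEIN_ALTERING_DIRECT <- c(
  "stop_gained", "stop_lost", "start_lost", "frameshift",
  "inframe_indel", "splice_acceptor", "splice_donor"
)

PREDICTION_LEVELS <- c("damaging", "tolerated", "unknown")

GROUP_LEVELS <- c("control", "OB", "T2D")

.REQUIRED_ROWDATA <- c("chrom", "pos", "ref", "alt", "gene", "effect",
                       "sift", "provean", "pp2", "panel_maf", "dataset_maf")
.REQUIRED_COLDATA <- c("group", "age", "sex")

## ExomeCohort ---------------------------------------------------------------

#' ExomeCohort: genotypes, annotations and sample sheet in one container
#'
#' An \code{ExomeCohort} is a \linkS4class{SummarizedExperiment} with a
#' single integer assay \code{"GT"} (variants x samples; 0/1/2 alternative
#' allele dosage, \code{NA} = missing genotype), per-variant annotations in
#' \code{rowData} (variant key, gene symbol, effect class, three
#' pathogenicity calls, reference-panel MAF, dataset MAF) and the sample
#' sheet in \code{colData} (group, age, sex and quantitative traits).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases ExomeCohort-class
#' @exportClass ExomeCohort
setClass("ExomeCohort", contains = "SummarizedExperiment")

setValidity("ExomeCohort", function(object) {
  msg <- character()
  if (!"GT" %in% names(assays(object)))
    msg <- c(msg, "assay 'GT' is required")
  else {
    gt <- assay(object, "GT")
    bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
    if (any(bad))
      msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  }
  missRow <- setdiff(.REQUIRED_ROWDATA, colnames(rowData(object)))
  if (length(missRow))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(missRow, collapse = ", ")))
  missCol <- setdiff(.REQUIRED_COLDATA, colnames(colData(object)))
  if (length(missCol))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missCol, collapse = ", ")))
  if ("group" %in% colnames(colData(object))) {
    g <- as.character(colData(object)$group)
    if (!all(g %in% GROUP_LEVELS))
      msg <- c(msg, paste0("sample group labels must be one of: ",
                           paste(GROUP_LEVELS, collapse = ", ")))
  }
  if ("effect" %in% colnames(rowData(object))) {
    e <- as.character(rowData(object)$effect)
    if (!all(e %in% EFFECT_CLASSES))
      msg <- c(msg, "effect class outside the controlled vocabulary")
  }
  for (f in c("panel_maf", "dataset_maf")) {
    if (f %in% colnames(rowData(object))) {
      v <- rowData(object)[[f]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        msg <- c(msg, paste0(f, " must lie in [0, 1]"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExomeCohort
#'
#' @param genotypes integer matrix (variants x samples) of alternative-allele
#'   dosages 0/1/2, \code{NA} for missing. Row and column names are used as
#'   variant keys and sample ids.
#' @param annotations data.frame/DataFrame with one row per variant:
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene},
#'   \code{effect}, \code{sift}, \code{provean}, \code{pp2},
#'   \code{panel_maf}; optionally \code{rsid}.
#' @param design data.frame/DataFrame with one row per sample: \code{group}
#'   (control/OB/T2D), \code{age}, \code{sex} (0 = female, 1 = male) and any
#'   quantitative traits (bmi, whr, glucose, tg).
#' @param metadata optional list stored as object metadata.
#'
#' @return An [ExomeCohort-class]. \code{dataset_maf} is (re)computed from
#'   the genotype matrix as minor-allele count over twice the number of
#'   non-missing genotypes.
#' @export
ExomeCohort <- function(genotypes, annotations, design, metadata = list()) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  annotations <- DataFrame(annotations)
  design <- DataFrame(design)
  if (nrow(annotations) != nrow(genotypes))
    stop("annotations and genotype matrix disagree on variant count")
  if (nrow(design) != ncol(genotypes))
    stop("design and genotype matrix disagree on sample count")
  if (is.null(rownames(genotypes)) && nrow(genotypes) > 0)
    rownames(genotypes) <- variantKey(annotations)
  if (is.null(colnames(genotypes)) && "sample_id" %in% colnames(design))
    colnames(genotypes) <- design$sample_id
  annotations$dataset_maf <- datasetMAF(genotypes)
  rownames(annotations) <- rownames(genotypes)
  rownames(design) <- colnames(genotypes)
  design$group <- factor(as.character(design$group), levels = GROUP_LEVELS)
  obj <- SummarizedExperiment(
    assays = list(GT = genotypes),
    rowData = annotations, colData = design, metadata = metadata
  )
  new("ExomeCohort", obj)
}

#' @describeIn ExomeCohort canonical variant key "chrom:pos_ref/alt"
#' @param annotations annotation table with chrom/pos/ref/alt columns.
#' @export
variantKey <- function(annotations) {
  paste0(annotations$chrom, ":", annotations$pos, "_",
         annotations$ref, "/", annotations$alt)
}

#' Dataset minor allele frequency from a genotype matrix
#'
#' Minor-allele count divided by twice the number of non-missing genotypes,
#' per variant. Variants with no called genotype get \code{NA}.
#'
#' @param genotypes variants x samples dosage matrix (0/1/2/NA).
#' @return numeric vector of per-variant MAFs in [0, 0.5].
#' @export
datasetMAF <- function(genotypes) {
  n <- rowSums(!is.na(genotypes))
  alt <- rowSums(genotypes, na.rm = TRUE)
  af <- ifelse(n > 0, alt / (2 * n), NA_real_)
  pmin(af, 1 - af)
}

## Accessors ------------------------------------------------------------------

#' @rdname ExomeCohort
#' @param x an ExomeCohort.
#' @export
genotypes <- function(x) assay(x, "GT")

#' @rdname ExomeCohort
#' @export
variantAnnotations <- function(x) rowData(x)

#' @rdname ExomeCohort
#' @export
sampleSheet <- function(x) colData(x)

#' @rdname ExomeCohort
#' @export
sampleGroups <- function(x) setNames(as.character(colData(x)$group),
                                     rownames(colData(x)))

#' @rdname ExomeCohort
#' @export
panelMAF <- function(x) setNames(rowData(x)$panel_maf, rownames(x))

#' @rdname ExomeCohort
#' @export
dataMAF <- function(x) setNames(rowData(x)$dataset_maf, rownames(x))

setMethod("show", "ExomeCohort", function(object) {
  g <- table(factor(as.character(colData(object)$group),
                    levels = GROUP_LEVELS))
  cat("ExomeCohort:", nrow(object), "variants x", ncol(object), "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(g), g), collapse = " "), "\n")
  nm <- sum(is.na(assay(object, "GT")))
  cat("  missing genotypes:", nm, "\n")
  cat("  traits:", paste(setdiff(colnames(colData(object)),
                                 c("sample_id", .REQUIRED_COLDATA)),
                         collapse = ", "), "\n")
})

## PowerGrid -----------------------------------------------------------------

#' Monte-Carlo power surface over (tMAF, tOR)
#'
#' Result of [powerGrid()]: per grid cell, the empirical probability of a
#' positive scoring outcome P(Score1 >= threshold) and the mean Score1.
#'
#' @slot grid data.frame with columns tMAF, tOR, p_positive, e_score.
#' @slot nCase,nControl group sizes used for the binomial sampling.
#' @slot model inheritance model ("dominant"/"recessive").
#' @slot iterations Monte-Carlo iterations per cell.
#' @slot threshold positive-outcome score threshold.
#' @slot seed root seed.
#' @exportClass PowerGrid
setClass("PowerGrid", representation(
  grid = "data.frame", nCase = "integer", nControl = "integer",
  model = "character", iterations = "numeric", threshold = "numeric",
  seed = "integer"
))

setValidity("PowerGrid", function(object) {
  p <- object@grid$p_positive
  if (any(p < 0 | p > 1)) "p_positive must lie in [0,1]" else TRUE
})

setMethod("show", "PowerGrid", function(object) {
  cat("PowerGrid:", nrow(object@grid), "cells (",
      length(unique(object@grid$tMAF)), "tMAF x",
      length(unique(object@grid$tOR)), "tOR )\n")
  cat(sprintf("  n_case=%d n_control=%d model=%s iterations=%g threshold=%g\n",
              object@nCase, object@nControl, object@model,
              object@iterations, object@threshold))
  cat(sprintf("  p_positive range: [%.4g, %.4g]\n",
              min(object@grid$p_positive), max(object@grid$p_positive)))
})

#' @rdname PowerGrid-class
#' @param x a PowerGrid.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "PowerGrid",
          function(x, ...) x@grid)

## EnrichmentNull ------------------------------------------------------------

#' Bernoulli resampling null for case-unique variant counts
#'
#' Result of [enrichmentNull()]. Each variant carried by \eqn{n} samples is
#' "expected case-specific" in a null draw with probability \eqn{p^n}, with
#' \eqn{p} the affected fraction of the cohort.
#'
#' @slot observed observed number of case-unique variants.
#' @slot nullCounts empirical null distribution of that count.
#' @slot expectedMean analytic mean, sum over variants of p^n.
#' @slot p empirical p-value Pr(null >= observed), add-one smoothed.
#' @slot enrichmentRatio observed / expected-mean.
#' @slot oddsRatio odds ratio of (case-specific : not) observed vs null mean.
#' @slot iterations,seed sampling metadata.
#' @exportClass EnrichmentNull
setClass("EnrichmentNull", representation(
  observed = "numeric", nullCounts = "numeric", expectedMean = "numeric",
  p = "numeric", enrichmentRatio = "numeric", oddsRatio = "numeric",
  iterations = "numeric", seed = "integer", nVariants = "integer"
))

setValidity("EnrichmentNull", function(object) {
  if (object@p <= 0 || object@p > 1) "empirical p must lie in (0,1]" else TRUE
})

setMethod("show", "EnrichmentNull", function(object) {
  cat("EnrichmentNull over", object@nVariants, "variants\n")
  cat(sprintf("  observed case-unique: %g; null mean %.3f (analytic %.3f)\n",
              object@observed, mean(object@nullCounts), object@expectedMean))
  cat(sprintf("  empirical p = %.4g; obs/exp = %.3f; odds-style ratio = %.3f\n",
              object@p, object@enrichmentRatio, object@oddsRatio))
})
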