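#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Biologically motivated variant filters defining the two prioritized
## candidate classes: protein-altering variants in implicated genes within
## an intermediate panel-MAF window, and (downstream) highly case-specific
## variants at low panel MAF.
## ---------------------------------------------------------------------------

#' Protein-altering classification
#'
#' A variant is protein-altering when its effect class changes the protein
#' directly (stop gain/loss, start loss, frameshift, in-frame indel,
#' splice acceptor/donor), or when it is missense and at least
#' \code{consensusK} of the three pathogenicity predictors (SIFT, PROVEAN,
#' PolyPhen2) call it damaging. Synonymous, intronic and other classes are
#' never protein-altering; "unknown" predictions count as not damaging.
#'
#' @param annotations annotation DataFrame/data.frame (columns effect, sift,
#'   provean, pp2) or an [ExomeCohort-class].
#' @param consensusK minimum number of damaging calls for missense (1-3,
#'   default 2: majority vote).
#' @param spliceAltering whether splice acceptor/donor variants count as
#'   protein-altering (default TRUE).
#' @return logical vector, one element per variant.
#' @export
classifyProteinAltering <- function(annotations, consensusK = 2,
                                    spliceAltering = TRUE) {
  if (is(annotations, "ExomeCohort")) annotations <- rowData(annotations)
  stopifnot(consensusK %in% 1:3)
  direct <- PROTEIN_ALTERING_DIRECT
  if (!spliceAltering)
    direct <- setdiff(direct, c("splice_acceptor", "splice_donor"))
  eff <- as.character(annotations$effect)
  votes <- (annotations$sift == "damaging") +
           (annotations$provean == "damaging") +
           (annotations$pp2 == "damaging")
  unname(eff %in% direct | (eff == "missense" & votes >= consensusK))
}

#' Select protein-altering candidates in known genes
#'
#' The known-gene candidate class: implicated gene, protein-altering, and
#' reference-panel MAF strictly inside the (lower, upper) window (defaults
#' 0.01 and 0.1; boundaries exclusive).
#'
#' @param cohort an [ExomeCohort-class] (rowData must carry an
#'   \code{implicated} flag, see [readCohort()]).
#' @param consensusK passed to [classifyProteinAltering()].
#' @param mafWindow numeric length-2: exclusive (lower, upper) panel-MAF
#'   bounds.
#' @return logical selection vector over variants.
#' @export
selectKnownGeneCandidates <- function(cohort, consensusK = 2,
                                      mafWindow = c(0.01, 0.1)) {
  ann <- rowData(cohort)
  if (!"implicated" %in% colnames(ann))
    stop("annotations lack the 'implicated' flag; supply a gene list when reading")
  pa <- classifyProteinAltering(ann, consensusK)
  unname(ann$implicated & pa &
         ann$panel_maf > mafWindow[1] & ann$panel_maf < mafWindow[2])
}

#' Reference-panel MAF bin
#'
#' "rare" when panel MAF < rareMax (default 0.02), "intermediate" when
#' strictly between rareMax and intermediateMax (default 0.1),
#' "out_of_range" otherwise (including the boundaries, read as exclusive).
#'
#' @param panelMAF numeric vector of reference-panel MAFs (or an
#'   [ExomeCohort-class]).
#' @param rareMax,intermediateMax bin edges.
#' @return factor with levels rare, intermediate, out_of_range.
#' @export
mafBin <- function(panelMAF, rareMax = 0.02, intermediateMax = 0.1) {
  if (is(panelMAF, "ExomeCohort")) panelMAF <- rowData(panelMAF)$panel_maf
  out <- ifelse(panelMAF < rareMax, "rare",
         ifelse(panelMAF > rareMax & panelMAF < intermediateMax,
                "intermediate", "out_of_range"))
  factor(out, levels = c("rare", "intermediate", "out_of_range"))
}
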