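#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Case-specificity scoring: collapse genotypes to carrier status under an
## inheritance model, count carriers per group, and compute the additive
## scores Score1 = 10*n_case - 50*n_control (case-specificity) and
## Score2 = 10*n_control - 50*n_case (control-specificity) for each of the
## four standard comparisons.
## ---------------------------------------------------------------------------

#' The four standard case-control comparisons
#'
#' OB vs control; T2D vs control; T2D vs obesity+control; obesity+T2D vs
#' control.
#'
#' @return named list of comparisons, each
#'   list(name=, case = group set, control = group set).
#' @export
standardComparisons <- function() {
  list(
    OB_vs_C     = list(name = "OB_vs_C",     case = "OB",
                       control = "control"),
    T2D_vs_C    = list(name = "T2D_vs_C",    case = "T2D",
                       control = "control"),
    T2D_vs_OBC  = list(name = "T2D_vs_OBC",  case = "T2D",
                       control = c("OB", "control")),
    OBT2D_vs_C  = list(name = "OBT2D_vs_C",  case = c("OB", "T2D"),
                       control = "control")
  )
}

.checkComparison <- function(comparison, groups) {
  stopifnot(is.list(comparison),
            all(c("name", "case", "control") %in% names(comparison)))
  if (length(intersect(comparison$case, comparison$control)))
    stop("comparison '", comparison$name,
         "': case and control group sets overlap")
  nCase <- sum(groups %in% comparison$case)
  nControl <- sum(groups %in% comparison$control)
  if (nCase == 0 || nControl == 0)
    stop("comparison '", comparison$name, "' references an empty group")
  invisible(c(nCase = nCase, nControl = nControl))
}

#' Collapse genotypes to carrier status
#'
#' Dominant model: dosage 1 or 2 is a carrier; recessive: only dosage 2.
#' Missing genotypes stay missing (the sample is excluded from both the
#' numerator and the denominator of any carrier count).
#'
#' @param x genotype matrix (0/1/2/NA) or an [ExomeCohort-class].
#' @param model "dominant" or "recessive".
#' @return logical matrix (TRUE carrier, FALSE non-carrier, NA excluded).
#' @export
collapseGenotypes <- function(x, model = c("dominant", "recessive")) {
  model <- match.arg(model)
  gt <- if (is(x, "ExomeCohort")) genotypes(x) else x
  if (model == "dominant") gt >= 1L else gt == 2L
}

#' Case-specificity scores per variant
#'
#' Counts carriers among the comparison's case and control samples and
#' evaluates Score1 = wCase*n_case - wControl*n_control and
#' Score2 = wCase*n_control - wControl*n_case.
#'
#' @param cohort an [ExomeCohort-class] (or a carrier matrix from
#'   [collapseGenotypes()] together with \code{groups}).
#' @param comparisons list of comparisons (default all four standard ones,
#'   [standardComparisons()]).
#' @param model inheritance model(s) to score (default "dominant").
#' @param wCase,wControl score coefficients (default 10 and 50).
#' @param groups sample group labels; taken from the cohort when omitted.
#' @return [S4Vectors::DataFrame] with one row per
#'   variant x comparison x model: variant, comparison, model, n_case,
#'   n_control, score1, score2.
#' @export
computeScores <- function(cohort, comparisons = standardComparisons(),
                          model = "dominant", wCase = 10, wControl = 50,
                          groups = NULL) {
  if (is(cohort, "ExomeCohort")) {
    groups <- sampleGroups(cohort)
  } else if (is.null(groups)) {
    stop("groups must be given when scoring a raw matrix")
  }
  if (!is.list(comparisons[[1]])) comparisons <- list(comparisons)
  out <- list()
  for (m in model) {
    carriers <- collapseGenotypes(cohort, m)
    for (cmp in comparisons) {
      .checkComparison(cmp, groups)
      caseIdx <- groups %in% cmp$case
      ctrlIdx <- groups %in% cmp$control
      nCase <- rowSums(carriers[, caseIdx, drop = FALSE], na.rm = TRUE)
      nControl <- rowSums(carriers[, ctrlIdx, drop = FALSE], na.rm = TRUE)
      out[[length(out) + 1L]] <- DataFrame(
        variant = rownames(carriers) %||% as.character(seq_along(nCase)),
        comparison = cmp$name, model = m,
        n_case = as.integer(nCase), n_control = as.integer(nControl),
        score1 = as.integer(wCase * nCase - wControl * nControl),
        score2 = as.integer(wCase * nControl - wControl * nCase)
      )
    }
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select case- or control-specific variants
#'
#' Case-specific: score1 >= threshold; control-specific: score2 >=
#' threshold. The default threshold 20 corresponds to at least two case
#' carriers beyond what control penalties allow (scores are multiples of
#' 10, so ">= 20" and "> 10" select the same records).
#'
#' @param records score table from [computeScores()].
#' @param which "case" or "control".
#' @param threshold integer score threshold (default 20).
#' @return subset of \code{records}.
#' @export
selectSpecificVariants <- function(records, which = c("case", "control"),
                                   threshold = 20) {
  which <- match.arg(which)
  s <- if (which == "case") records$score1 else records$score2
  records[s >= threshold, , drop = FALSE]
}

#' Write a score table TSV
#'
#' @param records score table from [computeScores()].
#' @param path output path.
#' @export
writeScoreTable <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
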