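#' @include AllClasses.R
NULL

#' Read a cohort from a VCF and a sample sheet
#'
#' Parses a biallelic VCF v4.2 carrying the annotation INFO keys GENE, EFF,
#' SIFT, PROVEAN, PP2 and PANEL_AF, plus a TSV sample sheet with at least
#' sample_id, group, age, sex. Genotypes are collapsed to alternative-allele
#' dosage (0/1/2; "./." becomes NA). The dataset MAF is recomputed from the
#' genotype matrix.
#'
#' @param vcfPath path to the VCF.
#' @param sheetPath path to the sample sheet TSV.
#' @param geneList optional character vector (or path to a one-symbol-per-
#'   line file) of implicated genes; sets the per-variant implicated flag.
#' @return an [ExomeCohort-class].
#' @export
readCohort <- function(vcfPath, sheetPath, geneList = NULL) {
  vcf <- VariantAnnotation::readVcf(vcfPath, genome = "cohort")
  sheet <- read.table(sheetPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "age", "sex") %in% colnames(sheet)))
    stop("sample sheet must have columns sample_id, group, age, sex")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1L))
    stop("multi-allelic record(s) found: ",
         paste(head(names(vcf)[lengths(alt) != 1L]), collapse = ", "),
         " -- split records before reading")
  gtStr <- VariantAnnotation::geno(vcf)$GT
  vcfSamples <- colnames(gtStr)
  missingFromSheet <- setdiff(vcfSamples, sheet$sample_id)
  if (length(missingFromSheet))
    stop("sample(s) in VCF absent from sample sheet: ",
         paste(missingFromSheet, collapse = ", "))
  sheet <- sheet[match(vcfSamples, sheet$sample_id), , drop = FALSE]
  gt <- matrix(NA_integer_, nrow(gtStr), ncol(gtStr),
               dimnames = dimnames(gtStr))
  codes <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
             "." = NA_integer_, ".|." = NA_integer_)
  known <- gtStr %in% names(codes)
  if (!all(known))
    stop("unrecognized genotype string(s): ",
         paste(unique(gtStr[!known]), collapse = ", "))
  gt[] <- codes[gtStr]
  info <- VariantAnnotation::info(vcf)
  needed <- c("GENE", "EFF", "SIFT", "PROVEAN", "PP2", "PANEL_AF")
  missInfo <- setdiff(needed, colnames(info))
  if (length(missInfo))
    stop("VCF INFO lacks key(s): ", paste(missInfo, collapse = ", "))
  bad <- which(is.na(info$GENE) | is.na(info$EFF) | is.na(info$PANEL_AF))
  if (length(bad))
    stop("malformed INFO in record(s): ",
         paste(head(names(vcf)[bad]), collapse = ", "))
  ids <- names(vcf)
  rsid <- ifelse(grepl("^(rs|sim)", ids), ids, ".")
  ann <- DataFrame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt)),
    rsid = rsid,
    gene = info$GENE, effect = info$EFF,
    sift = info$SIFT, provean = info$PROVEAN, pp2 = info$PP2,
    panel_maf = as.numeric(info$PANEL_AF)
  )
  rownames(gt) <- variantKey(ann)
  if (!is.null(geneList)) {
    if (length(geneList) == 1L && file.exists(geneList))
      geneList <- readGeneList(geneList)
    ann$implicated <- ann$gene %in% geneList
  } else {
    ann$implicated <- FALSE
  }
  ExomeCohort(gt, ann, sheet)
}

#' Read a known-gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read a known-marker replication panel
#'
#' TSV with columns chrom, pos, ref, alt, rsid, trait, source.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readMarkerPanel <- function(path) {
  panel <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character"))
  needed <- c("chrom", "pos", "ref", "alt", "rsid")
  miss <- setdiff(needed, colnames(panel))
  if (length(miss))
    stop("marker panel lacks column(s): ", paste(miss, collapse = ", "))
  panel
}
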