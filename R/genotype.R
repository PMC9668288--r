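#' Genotype matrix container
#'
#' Bundles per-(sample, variant) allele dosages with per-call metrics. Dosages
#' are 0/1/2 alternate-allele copies with `NA` for missing; hemizygous
#' X-chromosome male calls are coded 2 (so the recessive machinery sees them as
#' two-copy) and are written/read as haploid VCF genotypes.
#'
#' @param dosage Integer matrix, samples x variants, dimnames required.
#' @param dp,gq,ad Optional matrices of read depth, genotype quality and
#'   alternate-read count with the same shape. When omitted the calls are
#'   treated as metric-free (QC passes them through).
#' @return A list with class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosage, dp = NULL, gq = NULL, ad = NULL) {
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage must carry sample rownames and variant colnames")
  for (m in list(dp, gq, ad)) {
    if (!is.null(m) && !identical(dim(m), dim(dosage)))
      stop("per-call metric dimensions must match dosage")
  }
  structure(list(dosage = dosage, dp = dp, gq = gq, ad = ad),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s call metrics)\n",
              nrow(x$dosage), ncol(x$dosage),
              if (is.null(x$dp)) "without" else "with"))
  invisible(x)
}

#' Gene-level carrier status under dominant and recessive coding
#'
#' Collapses qualifying variants to a per-sample carrier indicator for one
#' gene. Dominant: at least one qualifying alternate allele. Recessive: a
#' homozygous qualifying genotype, a hemizygous X-linked qualifying genotype in
#' a male, or at least two distinct heterozygous qualifying variants
#' (phase-blind putative compound heterozygote; variants sharing a position
#' count once). Missing genotypes contribute nothing.
#'
#' @param dosage Dosage matrix restricted to the gene's qualifying variants
#'   (samples x variants); may have zero columns.
#' @param zygosity `"dominant"` or `"recessive"`.
#' @param male Logical vector per sample (required for recessive X genes).
#' @param x_linked Is the gene on the X chromosome?
#' @param pos Variant positions (used to collapse same-position variants in
#'   compound-het counting); defaults to distinct.
#' @return Logical carrier vector; for recessive, with attribute `basis`
#'   (`"homozygous"`, `"hemizygous"`, `"compound_het"` or `NA`).
#' @export
carrier_status <- function(dosage, zygosity = c("dominant", "recessive"),
                           male = NULL, x_linked = FALSE, pos = NULL) {
  zygosity <- match.arg(zygosity)
  n <- nrow(dosage)
  if (ncol(dosage) == 0L) {
    out <- rep(FALSE, n)
    if (zygosity == "recessive") attr(out, "basis") <- rep(NA_character_, n)
    names(out) <- rownames(dosage)
    return(out)
  }
  if (zygosity == "dominant") {
    out <- rowSums(dosage > 0, na.rm = TRUE) >= 1
    names(out) <- rownames(dosage)
    return(out)
  }
  if (is.null(male)) stop("recessive coding requires the 'male' indicator")
  if (is.null(pos)) pos <- seq_len(ncol(dosage))
  hom_any <- rowSums(dosage == 2, na.rm = TRUE) >= 1
  # distinct het sites: count each position at most once
  het <- !is.na(dosage) & dosage == 1
  if (anyDuplicated(pos)) {
    agg <- sapply(split(seq_along(pos), pos), function(j)
      rowSums(het[, j, drop = FALSE]) > 0)
    n_het <- rowSums(matrix(agg, nrow = n))
  } else {
    n_het <- rowSums(het)
  }
  comp_het <- n_het >= 2
  hemi <- x_linked & male & hom_any
  hom <- hom_any & !hemi
  out <- hom | hemi | comp_het
  basis <- rep(NA_character_, n)
  basis[comp_het] <- "compound_het"
  basis[hom] <- "homozygous"
  basis[hemi] <- "hemizygous"
  attr(out, "basis") <- basis
  names(out) <- rownames(dosage)
  out
}

#' Build the gene x model carrier matrix
#'
#' @param geno A `genotype_matrix` (QC-filtered dosages are expected).
#' @param variants Variant annotation data frame aligned to `colnames(geno$dosage)`;
#'   must contain `gene`, `chrom`, `pos`.
#' @param qv_sets Named list (per model) of logical vectors over variants
#'   flagging qualifying status, e.g. from [qv_qualifies()].
#' @param male Logical per-sample male indicator.
#' @param registry Model registry giving each model's zygosity.
#' @return Named list (per model) of logical sample x gene matrices; recessive
#'   models carry a parallel `basis` character matrix attribute.
#' @export
build_carrier_matrix <- function(geno, variants, qv_sets, male,
                                 registry = qv_model_registry()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (length(male) != nrow(geno$dosage))
    stop("sample present in genotypes but absent from cohort (length mismatch)")
  genes <- unique(variants$gene)
  lapply(stats::setNames(names(qv_sets), names(qv_sets)), function(mod) {
    zyg <- registry[[mod]]$zygosity
    qv <- qv_sets[[mod]]
    cm <- matrix(FALSE, nrow(geno$dosage), length(genes),
                 dimnames = list(rownames(geno$dosage), genes))
    bm <- if (zyg == "recessive")
      matrix(NA_character_, nrow(geno$dosage), length(genes),
             dimnames = dimnames(cm))
    for (g in genes) {
      j <- which(variants$gene == g & qv)
      if (!length(j)) next
      st <- carrier_status(geno$dosage[, j, drop = FALSE], zyg, male = male,
                           x_linked = variants$chrom[j[1]] %in% c("X", "chrX"),
                           pos = variants$pos[j])
      cm[, g] <- st
      if (zyg == "recessive") bm[, g] <- attr(st, "basis")
    }
    if (zyg == "recessive") attr(cm, "basis") <- bm
    cm
  })
}
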