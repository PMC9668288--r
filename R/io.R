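# Cohort writer/reader. Genotypes go to VCF 4.2 with GT:DP:GQ:AD FORMAT
# fields (haploid GT for hemizygous X males); annotations, phenotypes and the
# truth table go to TSVs with headers. Numeric fields are printed with %.10g,
# which makes a write -> read -> write cycle byte-identical.

.fmt_num <- function(x) {
  if (is.integer(x)) return(ifelse(is.na(x), "NA", sprintf("%d", x)))
  if (is.numeric(x)) return(ifelse(is.na(x), "NA", sprintf("%.10g", x)))
  if (is.logical(x)) return(ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE")))
  ifelse(is.na(x), "NA", as.character(x))
}

.write_tsv <- function(df, path) {
  cols <- lapply(df, .fmt_num)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
}

.gt_string <- function(dosage, haploid) {
  out <- character(length(dosage))
  if (any(haploid)) {
    d <- dosage[haploid]
    out[haploid] <- ifelse(is.na(d), ".", ifelse(d >= 2, "1", "0"))
  }
  d <- dosage[!haploid]
  out[!haploid] <- ifelse(is.na(d), "./.",
                          c("0/0", "0/1", "1/1")[pmin(d, 2) + 1L])
  out
}

#' Write a simulated cohort to disk
#'
#' Emits `<prefix>.vcf` (GT, DP, GQ, AD FORMAT fields), `<prefix>.annotations.tsv`,
#' `<prefix>.phenotypes.tsv`, `<prefix>.truth_genes.tsv` and (when a haplotype
#' was simulated) `<prefix>.truth_haplotype.tsv`. A round trip through
#' [read_cohort()] reproduces dosages exactly and a second write is
#' byte-identical.
#'
#' @param sim A `sim_cohort` from [generate_cohort()], or a list with
#'   `samples`, `variants`, `genotypes` (and optionally `truth`).
#' @param prefix Output path prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(sim, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  samples <- sim$samples; variants <- sim$variants; geno <- sim$genotypes
  n <- nrow(samples); nv <- nrow(variants)
  male <- samples$sex == "male"
  is_x <- variants$chrom %in% c("X", "chrX")
  has_metrics <- !is.null(geno$dp)

  paths <- c(vcf = paste0(prefix, ".vcf"),
             annotations = paste0(prefix, ".annotations.tsv"),
             phenotypes = paste0(prefix, ".phenotypes.tsv"))

  hdr <- c("##fileformat=VCFv4.2",
           "##source=rvburden",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_metrics) hdr <- c(hdr,
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples$sample_id), collapse = "\t"))
  body <- vapply(seq_len(nv), function(j) {
    ds <- geno$dosage[, j]
    gt <- .gt_string(ds, haploid = is_x[j] & male)
    cells <- if (has_metrics) {
      ad_ref <- ifelse(is.na(ds), ".",
                       paste(geno$dp[, j] - geno$ad[, j], geno$ad[, j], sep = ","))
      paste(gt, ifelse(is.na(ds), ".", geno$dp[, j]),
            ifelse(is.na(ds), ".", geno$gq[, j]), ad_ref, sep = ":")
    } else gt
    paste(c(variants$chrom[j], variants$pos[j],
            paste(variants$chrom[j], variants$pos[j], variants$ref[j],
                  variants$alt[j], sep = "-"),
            variants$ref[j], variants$alt[j], .fmt_num(variants$qual[j]),
            variants$filter_status[j], ".",
            if (has_metrics) "GT:DP:GQ:AD" else "GT", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), paths["vcf"])

  .write_tsv(variants, paths["annotations"])
  .write_tsv(samples, paths["phenotypes"])
  if (!is.null(sim$truth)) {
    paths["truth_genes"] <- paste0(prefix, ".truth_genes.tsv")
    .write_tsv(sim$truth$genes, paths["truth_genes"])
    if (!is.null(sim$truth$haplotype)) {
      paths["truth_haplotype"] <- paste0(prefix, ".truth_haplotype.tsv")
      .write_tsv(sim$truth$haplotype, paths["truth_haplotype"])
    }
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' The VCF is parsed with `VariantAnnotation::readVcf`; haploid genotypes are
#' read back as dosage 2 (hemizygous coding), diploid as 0/1/2 with `./.`
#' missing.
#'
#' @param prefix Path prefix used at write time.
#' @return List with `samples`, `variants`, `genotypes` and (when present on
#'   disk) `truth`.
#' @export
read_cohort <- function(prefix) {
  vcf_path <- paste0(prefix, ".vcf")
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  samples <- utils::read.delim(paste0(prefix, ".phenotypes.tsv"),
                               stringsAsFactors = FALSE)
  variants <- utils::read.delim(paste0(prefix, ".annotations.tsv"),
                                stringsAsFactors = FALSE,
                                colClasses = c(chrom = "character",
                                               ref = "character",
                                               alt = "character"))
  vcf <- VariantAnnotation::readVcf(vcf_path)
  gt <- t(VariantAnnotation::geno(vcf)$GT)      # samples x variants
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dosage[gt == "0/0" | gt == "0"] <- 0L
  dosage[gt == "0/1" | gt == "1/0"] <- 1L
  dosage[gt == "1/1" | gt == "1"] <- 2L
  gn <- VariantAnnotation::geno(vcf)
  dp <- gq <- ad <- NULL
  if ("DP" %in% names(gn)) {
    dp <- t(gn$DP); gq <- t(gn$GQ)
    adr <- gn$AD
    if (is.list(adr)) {
      ad <- t(apply(adr, c(1, 2), function(x) {
        v <- if (is.list(x)) x[[1]] else x
        if (length(v) >= 2) v[2] else NA_integer_
      }))
    } else ad <- t(adr[, , 2])
    ad <- matrix(as.integer(ad), nrow(dosage), dimnames = dimnames(dosage))
    dp <- matrix(as.integer(dp), nrow(dosage), dimnames = dimnames(dosage))
    gq <- matrix(as.integer(gq), nrow(dosage), dimnames = dimnames(dosage))
  }
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "-")
  if (!identical(colnames(dosage), key))
    stop("annotation table and VCF records disagree")
  out <- list(samples = samples, variants = variants,
              genotypes = genotype_matrix(dosage, dp, gq, ad))
  tg <- paste0(prefix, ".truth_genes.tsv")
  if (file.exists(tg)) {
    out$truth <- list(genes = utils::read.delim(tg, stringsAsFactors = FALSE))
    th <- paste0(prefix, ".truth_haplotype.tsv")
    if (file.exists(th))
      out$truth$haplotype <- utils::read.delim(th, stringsAsFactors = FALSE)
  }
  out
}
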