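#' Haplotype-based linkage-disequilibrium r-squared
#'
#' Computes r2 between two loci directly from phased haplotype alleles
#' (0 = ref, 1 = alt): \code{r2 = (p_ab - p_a p_b)^2 / (p_a(1-p_a) p_b(1-p_b))}
#' where \code{p_ab} is the joint frequency of alt-alt haplotypes.  On
#' phased data this equals PLINK's haplotype-based r2 and the squared
#' Pearson correlation of the two allele vectors.  A monomorphic locus
#' makes r2 undefined (NA).
#'
#' @param a,b binary vectors of equal length (2N haplotypes over N phased
#'   individuals).
#' @return r2 in [0, 1], or NA.
#' @export
haplotype_r2 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  p_a <- mean(a); p_b <- mean(b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) return(NA_real_)
  p_ab <- mean(a == 1L & b == 1L)
  d <- p_ab - p_a * p_b
  # grouped so the value is bit-identical under argument exchange
  d * d / ((p_a * (1 - p_a)) * (p_b * (1 - p_b)))
}

#' Build a haplotype panel from a phased multi-sample VCF
#'
#' @param vcf_path phased VCF over the reference panel individuals.
#' @param samples optional subset of samples; default all.
#' @return object of class \code{haplotype_panel}: list with \code{alleles}
#'   (matrix, one row per SNP, 2N columns of 0/1) and \code{snps}
#'   (data.frame \code{snp_id}, \code{chrom}, \code{pos}).  Unphased or
#'   non-biallelic records are dropped.
#' @export
haplotype_panel_from_vcf <- function(vcf_path, samples = NULL) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  if (!is.null(samples)) vcf <- vcf[, samples]
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  phased <- apply(gt, 1, function(g) all(grepl("^[01]\\|[01]$", g)))
  biall <- S4Vectors::elementNROWS(rr$ALT) == 1L
  keep <- phased & biall
  gt <- gt[keep, , drop = FALSE]
  rr <- rr[keep]
  alleles <- t(apply(gt, 1, function(g) {
    as.integer(unlist(strsplit(g, "|", fixed = TRUE)))
  }))
  ids <- names(rr)
  ids[is.na(ids)] <- ""
  structure(list(
    alleles = alleles,
    snps = data.frame(snp_id = ids,
                      chrom = as.character(GenomeInfoDb::seqnames(rr)),
                      pos = BiocGenerics::start(rr),
                      stringsAsFactors = FALSE)),
    class = "haplotype_panel")
}

#' Load a GWAS catalog TSV
#'
#' Expects at least the columns \code{snp_id}, \code{chrom}, \code{pos},
#' \code{p_value}, \code{trait}.  Records at or above \code{p_max} are
#' dropped; duplicates by (snp_id, trait) are collapsed keeping the
#' smallest p-value.
#'
#' @param tsv_path catalog file.
#' @param p_max association p-value cutoff (default 1e-3).
#' @return data.frame of retained catalog records.
#' @export
load_gwas_catalog <- function(tsv_path, p_max = 1e-3) {
  cat_df <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, quote = "")
  need <- c("snp_id", "chrom", "pos", "p_value", "trait")
  miss <- setdiff(need, colnames(cat_df))
  if (length(miss)) stop("GWAS catalog lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(cat_df) == 0L) {
    warning("empty GWAS catalog")
    return(cat_df)
  }
  cat_df <- cat_df[cat_df$p_value < p_max, , drop = FALSE]
  cat_df <- cat_df[order(cat_df$p_value), ]
  cat_df <- cat_df[!duplicated(cat_df[, c("snp_id", "trait")]), , drop = FALSE]
  rownames(cat_df) <- NULL
  cat_df
}

#' Link splice-site SNPs to GWAS catalog SNPs through LD
#'
#' For every (splice-site SNP, GWAS SNP) candidate pair on the same
#' chromosome within \code{window_bp}, computes haplotype r2 on the panel
#' and emits pairs with \code{r2 > r2_min}, sorted by descending r2.  A
#' splice SNP that is itself a GWAS SNP links to itself with r2 = 1.
#' Candidates missing from the panel are skipped and tallied.
#'
#' @param splice_snps data.frame with \code{snp_id}, \code{chrom},
#'   \code{pos}.
#' @param catalog from \code{\link{load_gwas_catalog}}.
#' @param panel a \code{haplotype_panel} containing both SNPs of a usable
#'   pair.
#' @param r2_min LD threshold (default 0.8, strict inequality).
#' @param window_bp candidate window (default 1 Mb); \code{Inf} for
#'   genome-wide (same chromosome).
#' @return list with \code{links} (data.frame \code{splice_snp_id},
#'   \code{gwas_snp_id}, \code{r2}, \code{gwas_trait}, \code{gwas_pvalue})
#'   and \code{n_no_genotype} (pairs skipped for lack of panel genotypes).
#' @export
link_splice_snps <- function(splice_snps, catalog, panel, r2_min = 0.8,
                             window_bp = 1e6) {
  links <- list()
  n_no_geno <- 0L
  pk <- paste(panel$snps$chrom, panel$snps$pos)
  find_panel <- function(chrom, pos, id) {
    i <- which(panel$snps$snp_id == id & nzchar(id))
    if (length(i) == 0L) i <- which(pk == paste(chrom, pos))
    if (length(i) == 0L) NA_integer_ else i[1]
  }
  for (s in seq_len(nrow(splice_snps))) {
    ss <- splice_snps[s, ]
    cand <- catalog[catalog$chrom == ss$chrom &
                      abs(catalog$pos - ss$pos) <= window_bp, , drop = FALSE]
    if (nrow(cand) == 0L) next
    si <- find_panel(ss$chrom, ss$pos, ss$snp_id)
    for (g in seq_len(nrow(cand))) {
      gw <- cand[g, ]
      if (identical(gw$snp_id, ss$snp_id) ||
          (gw$chrom == ss$chrom && gw$pos == ss$pos)) {
        r2 <- 1.0  # the splice SNP is itself the GWAS SNP
      } else {
        gi <- find_panel(gw$chrom, gw$pos, gw$snp_id)
        if (is.na(si) || is.na(gi)) {
          n_no_geno <- n_no_geno + 1L
          next
        }
        r2 <- haplotype_r2(panel$alleles[si, ], panel$alleles[gi, ])
        if (is.na(r2)) next
      }
      if (r2 > r2_min) {
        links[[length(links) + 1L]] <- data.frame(
          splice_snp_id = ss$snp_id, gwas_snp_id = gw$snp_id, r2 = r2,
          gwas_trait = gw$trait, gwas_pvalue = gw$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(splice_snp_id = character(), gwas_snp_id = character(),
               r2 = numeric(), gwas_trait = character(),
               gwas_pvalue = numeric())
  links <- links[order(-links$r2), , drop = FALSE]
  rownames(links) <- NULL
  list(links = links, n_no_genotype = n_no_geno)
}
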