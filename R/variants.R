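#' Load phased biallelic SNVs for one sample from a VCF
#'
#' Reads a VCF (plain or bgzipped) and returns the subset of records usable
#' for genome personalization: biallelic, single-nucleotide, and phased
#' (pipe-separated genotype) for the requested sample.  Per-haplotype alleles
#' are resolved from the phased genotype, so a \code{0|1} record yields
#' \code{hap1 = REF}, \code{hap2 = ALT}.  All other records are counted as
#' skipped, broken down by reason.
#'
#' @param vcf_path Path to a VCF 4.x file.
#' @param sample_id Sample whose genotypes are used.  Missing from the VCF
#'   header is a hard error.
#' @return An object of class \code{phased_snps}: a list with
#'   \describe{
#'     \item{variants}{data.frame with columns \code{chrom}, \code{pos},
#'       \code{ref}, \code{alt}, \code{hap1}, \code{hap2}, \code{snp_id},
#'       \code{gt}.  \code{hap1}/\code{hap2} are each the ref or the alt
#'       allele as carried by that haplotype.}
#'     \item{skipped}{named integer vector with reasons \code{unphased},
#'       \code{nonsnv}, \code{multiallelic}, \code{badgt}.}
#'     \item{sample_id}{the sample.}
#'   }
#' @examples
#' vcf <- system.file("extdata", "example.vcf", package = "hiddensplice")
#' if (nzchar(vcf)) load_phased_snps(vcf, "S1")
#' @export
load_phased_snps <- function(vcf_path, sample_id) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  hdr_samples <- colnames(vcf)
  if (!sample_id %in% hdr_samples) {
    stop("sample '", sample_id, "' not found in VCF header (samples: ",
         paste(hdr_samples, collapse = ", "), ")")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, sample_id]
  ref <- as.character(rr$REF)
  altl <- rr$ALT  # DNAStringSetList (or CharacterList for symbolic alleles)

  n <- length(rr)
  skipped <- c(unphased = 0L, nonsnv = 0L, multiallelic = 0L, badgt = 0L)
  keep <- logical(n)
  alt <- character(n)
  hap1 <- character(n)
  hap2 <- character(n)

  n_alt <- S4Vectors::elementNROWS(altl)
  for (i in seq_len(n)) {
    if (n_alt[i] != 1L) {
      skipped["multiallelic"] <- skipped["multiallelic"] + 1L
      next
    }
    a <- as.character(altl[[i]])[1]
    if (nchar(ref[i]) != 1L || nchar(a) != 1L ||
        !ref[i] %in% c("A", "C", "G", "T") || !a %in% c("A", "C", "G", "T")) {
      skipped["nonsnv"] <- skipped["nonsnv"] + 1L
      next
    }
    g <- gt[i]
    if (is.na(g) || !grepl("|", g, fixed = TRUE)) {
      skipped["unphased"] <- skipped["unphased"] + 1L
      next
    }
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% c("0", "1"))) {
      # half-missing (".|1") or otherwise malformed phased GT
      skipped["badgt"] <- skipped["badgt"] + 1L
      next
    }
    keep[i] <- TRUE
    alt[i] <- a
    hap1[i] <- if (parts[1] == "1") a else ref[i]
    hap2[i] <- if (parts[2] == "1") a else ref[i]
  }

  ids <- names(rr)
  # VariantAnnotation synthesises "chr:pos_ref/alt" names for missing IDs
  ids[is.na(ids) | grepl(":", ids)] <- ""
  variants <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = ref[keep],
    alt = alt[keep],
    hap1 = hap1[keep],
    hap2 = hap2[keep],
    snp_id = ids[keep],
    gt = unname(gt[keep]),
    stringsAsFactors = FALSE
  )
  structure(list(variants = variants, skipped = skipped, sample_id = sample_id),
            class = "phased_snps")
}

#' @export
print.phased_snps <- function(x, ...) {
  cat("phased_snps: sample", x$sample_id, "-", nrow(x$variants),
      "phased biallelic SNVs;", sum(x$skipped), "records skipped (",
      paste(names(x$skipped), x$skipped, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}
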