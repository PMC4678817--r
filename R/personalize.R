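#' Build one haplotype genome by substituting phased SNV alleles
#'
#' Applies the alleles carried by one haplotype onto the reference sequences.
#' Only single-base substitutions are performed, so every output chromosome
#' has exactly the reference length and reference coordinates carry over
#' unchanged to the personal genome.  Soft-masked (lowercase) reference
#' input is accepted and REF alleles are checked case-insensitively; DNA
#' containers normalise sequence to uppercase, so output genomes are
#' uniformly uppercase.
#'
#' @param reference \code{DNAStringSet} of reference sequences.
#' @param variants data.frame as in the \code{variants} element of
#'   \code{\link{load_phased_snps}}.
#' @param haplotype 1 or 2: which haplotype's alleles to apply.
#' @return list with \code{genome} (\code{DNAStringSet}) and \code{build}, a
#'   one-row data.frame report: \code{haplotype}, \code{n_applied} (positions
#'   substituted with the alt allele), \code{n_ref} (variants where this
#'   haplotype carries the reference allele, nothing to do), and
#'   \code{n_skipped_refmismatch}.  A record whose stated reference allele
#'   disagrees with the genome base is skipped with a warning, not fatal:
#'   assembly patch / naming differences are common.  Two variants at the
#'   same position are a hard error.
#' @export
build_haplotype_fasta <- function(reference, variants, haplotype) {
  stopifnot(haplotype %in% c(1L, 2L))
  genome <- reference
  allele_col <- if (haplotype == 1L) "hap1" else "hap2"
  n_applied <- 0L
  n_ref <- 0L
  n_mismatch <- 0L

  if (nrow(variants) > 0L) {
    variants$chrom <- reconcile_chrom(variants$chrom, names(genome))
    dup <- duplicated(variants[, c("chrom", "pos")])
    if (any(dup)) {
      stop("multiple variants at the same position: ",
           paste(junction_key(variants$chrom[dup], variants$pos[dup],
                              variants$pos[dup])[1], collapse = ", "))
    }
    for (chrom in unique(variants$chrom)) {
      v <- variants[variants$chrom == chrom, ]
      v <- v[order(v$pos), ]
      if (any(v$pos < 1L) || any(v$pos > length(genome[[chrom]]))) {
        stop("variant position outside chromosome ", chrom)
      }
      at_base <- toupper(as.character(Biostrings::extractAt(
        genome[[chrom]], IRanges::IRanges(v$pos, v$pos))))
      ok <- at_base == toupper(v$ref)
      if (any(!ok)) {
        warning(sum(!ok), " variant(s) on ", chrom,
                " skipped: stated REF does not match the genome base")
        n_mismatch <- n_mismatch + sum(!ok)
        v <- v[ok, ]
      }
      carries_alt <- v[[allele_col]] == v$alt
      n_ref <- n_ref + sum(!carries_alt)
      v <- v[carries_alt, ]
      if (nrow(v) > 0L) {
        # replaceAt rewrites only the targeted bases
        genome[[chrom]] <- Biostrings::replaceAt(
          genome[[chrom]], IRanges::IRanges(v$pos, v$pos),
          Biostrings::DNAStringSet(toupper(v[[allele_col]])))
        n_applied <- n_applied + nrow(v)
      }
    }
  }
  build <- data.frame(haplotype = haplotype, n_applied = n_applied,
                      n_ref = n_ref, n_skipped_refmismatch = n_mismatch)
  list(genome = genome, build = build)
}

#' Personalize a sample: two haplotype FASTAs plus a build report
#'
#' Convenience wrapper around \code{\link{load_phased_snps}} and
#' \code{\link{build_haplotype_fasta}} that writes \code{hap1.fa},
#' \code{hap2.fa} (fixed 60-column FASTA for reproducible diffs) and a TSV
#' build report to \code{out_dir}.  Re-running produces byte-identical files.
#'
#' @param reference \code{DNAStringSet} or path to a reference FASTA.
#' @param vcf_path phased VCF for the sample.
#' @param sample_id sample name in the VCF.
#' @param out_dir writable output directory (created if needed).
#' @return invisibly, the build report data.frame (one row per haplotype,
#'   with the ingestion skip counts attached as columns).
#' @export
personalize_sample <- function(reference, vcf_path, sample_id, out_dir) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  snps <- load_phased_snps(vcf_path, sample_id)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- vector("list", 2L)
  for (h in 1:2) {
    res <- build_haplotype_fasta(reference, snps$variants, h)
    Biostrings::writeXStringSet(res$genome,
                                file.path(out_dir, paste0("hap", h, ".fa")),
                                width = 60L)
    reports[[h]] <- res$build
  }
  report <- do.call(rbind, reports)
  report <- cbind(sample = sample_id, report,
                  n_skipped_unphased = snps$skipped[["unphased"]],
                  n_skipped_nonsnv = snps$skipped[["nonsnv"]],
                  n_skipped_multiallelic = snps$skipped[["multiallelic"]],
                  n_skipped_badgt = snps$skipped[["badgt"]])
  utils::write.table(report, file.path(out_dir, "build_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
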