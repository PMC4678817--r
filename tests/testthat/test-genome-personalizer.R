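test_that("phased SNP loading resolves haplotype alleles and skips by reason", {
  recs <- data.frame(
    chrom = "chr1",
    pos = c(10L, 20L, 30L, 40L, 50L, 60L),
    id = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    ref = c("G", "A", "G", "C", "T", "A"),
    alt = c("T", "C", "GA", "G,T", "A", "C"),
    gt = c("0|1", "0/1", "0|1", "0|1", ".|1", "1|1"),
    stringsAsFactors = FALSE)
  vcf <- write_test_vcf(recs)
  snps <- load_phased_snps(vcf, "S1")

  expect_equal(nrow(snps$variants), 2L)
  v <- snps$variants[snps$variants$snp_id == "rs1", ]
  expect_equal(v$hap1, "G")  # 0|1: hap1 carries the reference allele
  expect_equal(v$hap2, "T")
  hom <- snps$variants[snps$variants$snp_id == "rs6", ]
  expect_equal(c(hom$hap1, hom$hap2), c("C", "C"))
  expect_equal(unname(snps$skipped["unphased"]), 1L)
  expect_equal(unname(snps$skipped["nonsnv"]), 1L)
  expect_equal(unname(snps$skipped["multiallelic"]), 1L)
  expect_equal(unname(snps$skipped["badgt"]), 1L)
  expect_equal(nrow(snps$variants) + sum(snps$skipped), nrow(recs))
  expect_error(load_phased_snps(vcf, "NOSUCH"), "not found")
})

test_that("haplotype construction substitutes only carried alleles and preserves coordinates", {
  set.seed(42)
  ref <- Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = ""),
    "chr1"))
  Biostrings::subseq(ref[["chr1"]], 7, 7) <- Biostrings::DNAString("C")
  variants <- data.frame(
    chrom = "chr1", pos = c(7L, 100L, 250L),
    ref = c("C", as.character(Biostrings::subseq(ref[["chr1"]], 100, 100)),
            as.character(Biostrings::subseq(ref[["chr1"]], 250, 250))),
    alt = c("G", "A", "T"), stringsAsFactors = FALSE)
  variants$alt[2] <- setdiff(c("A", "C", "G", "T"), variants$ref[2])[1]
  variants$alt[3] <- setdiff(c("A", "C", "G", "T"), variants$ref[3])[1]
  variants$hap1 <- c(variants$alt[1], variants$ref[2], variants$alt[3])
  variants$hap2 <- c(variants$alt[1], variants$alt[2], variants$ref[3])
  variants$snp_id <- c("s1", "s2", "s3")

  h1 <- build_haplotype_fasta(ref, variants, 1L)
  h2 <- build_haplotype_fasta(ref, variants, 2L)
  expect_equal(h1$build$n_applied, 2L)
  expect_equal(h2$build$n_applied, 2L)
  expect_equal(Biostrings::width(h1$genome), Biostrings::width(ref))

  # het consistency: position 100 is 0|1-like (hap1 ref, hap2 alt)
  at <- function(g, p) as.character(Biostrings::subseq(g[["chr1"]], p, p))
  expect_equal(at(h1$genome, 100), variants$ref[2])
  expect_equal(at(h2$genome, 100), variants$alt[2])
  # hom: both carry alt at 7
  expect_equal(at(h1$genome, 7), "G")
  expect_equal(at(h2$genome, 7), "G")

  # coordinate preservation at 1000 random non-variant positions
  pos <- sample(setdiff(1:500, variants$pos), 1000, replace = TRUE)
  for (g in list(h1$genome, h2$genome)) {
    expect_identical(
      as.character(Biostrings::extractAt(g[["chr1"]],
                                         IRanges::IRanges(pos, pos))),
      as.character(Biostrings::extractAt(ref[["chr1"]],
                                         IRanges::IRanges(pos, pos))))
  }

  # round trip: swapping ref/alt in a second pass recovers the reference
  swapped <- variants
  swapped$ref <- variants$hap1
  swapped$hap1 <- variants$ref
  swapped$alt <- variants$ref
  back <- build_haplotype_fasta(h1$genome, swapped, 1L)
  expect_identical(as.character(back$genome), as.character(ref))

  # empty variant set is the identity
  empty <- variants[0, ]
  expect_identical(as.character(build_haplotype_fasta(ref, empty, 1L)$genome),
                   as.character(ref))
})

test_that("soft-masked input matches case-insensitively; output is uppercase DNA", {
  # DNA containers normalise to uppercase at construction, so the contract
  # is: lowercase (soft-masked) input is accepted, REF checks are
  # case-insensitive, and emitted genomes are uniformly uppercase
  ref <- Biostrings::DNAStringSet(setNames("acgtacgtac", "chr1"))
  v <- data.frame(chrom = "chr1", pos = 3L, ref = "g", alt = "T",
                  hap1 = "T", hap2 = "T", snp_id = "s")
  out <- build_haplotype_fasta(ref, v, 1L)
  expect_equal(out$build$n_applied, 1L)
  expect_equal(out$build$n_skipped_refmismatch, 0L)
  expect_equal(as.character(out$genome[["chr1"]]), "ACTTACGTAC")
})

test_that("ref-mismatch records are skipped with a warning, duplicates are fatal", {
  ref <- Biostrings::DNAStringSet(setNames("AAAAAAAAAA", "chr1"))
  v <- data.frame(chrom = "chr1", pos = c(2L, 5L), ref = c("A", "C"),
                  alt = c("G", "T"), hap1 = c("G", "T"), hap2 = c("G", "T"),
                  snp_id = c("a", "b"))
  expect_warning(out <- build_haplotype_fasta(ref, v, 1L), "REF does not match")
  expect_equal(out$build$n_applied, 1L)
  expect_equal(out$build$n_skipped_refmismatch, 1L)

  dup <- v; dup$pos <- c(2L, 2L); dup$ref <- c("A", "A")
  expect_error(build_haplotype_fasta(ref, dup, 1L), "same position")
})

test_that("chr-prefix differences between VCF and FASTA are reconciled", {
  ref <- Biostrings::DNAStringSet(setNames("AAAAAAAAAA", "chr1"))
  v <- data.frame(chrom = "1", pos = 2L, ref = "A", alt = "G",
                  hap1 = "G", hap2 = "G", snp_id = "a")
  expect_message(out <- build_haplotype_fasta(ref, v, 1L), "chr")
  expect_equal(as.character(out$genome[["chr1"]]), "AGAAAAAAAA")
  v$chrom <- "chrUnknown"
  expect_error(suppressMessages(build_haplotype_fasta(ref, v, 1L)),
               "not present")
})

test_that("sample personalization writes byte-identical files on re-run", {
  recs <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                     id = paste0("rs", 1:4), ref = c("A", "A", "A", "A"),
                     alt = c("G", "G", "G", "G"),
                     gt = c("0|1", "1|0", "1|1", "0/1"))
  ref <- Biostrings::DNAStringSet(setNames(strrep("A", 100), "chr1"))
  vcf <- write_test_vcf(recs, contigs = c(chr1 = 100L))
  d1 <- tempfile(); d2 <- tempfile()
  rep1 <- personalize_sample(ref, vcf, "S1", d1)
  rep2 <- personalize_sample(ref, vcf, "S1", d2)
  for (f in c("hap1.fa", "hap2.fa", "build_report.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # 3 phased SNVs: hap1 carries alt at rs2, rs3; hap2 at rs1, rs3
  expect_equal(rep1$n_applied, c(2L, 2L))
  expect_equal(unique(rep1$n_skipped_unphased), 1L)
  expect_error(personalize_sample(ref, vcf, "S9", tempfile()), "not found")
})
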