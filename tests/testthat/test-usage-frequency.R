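test_that("relative usage is the exact PSJ fraction with the right edge cases", {
  expect_equal(relative_usage(5, 0), 1.0)
  expect_equal(relative_usage(0, 9), 0.0)
  expect_equal(relative_usage(13, 7), 0.65)
  expect_true(is.na(relative_usage(0, 0)))
  # strictly increasing in PSJ, strictly decreasing in OSJ
  expect_true(all(diff(relative_usage(1:20, 7)) > 0))
  expect_true(all(diff(relative_usage(7, 1:20)) < 0))
  expect_error(relative_usage(-1, 3))
})

test_that("overlapping annotated reads sum in the right genome and exclude self", {
  ann <- data.frame(chrom = "chr1",
                    intron_start = c(100L, 150L, 800L, 100L),
                    intron_end = c(200L, 260L, 900L, 250L),
                    strand = "+", stringsAsFactors = FALSE)
  jn <- data.frame(chrom = "chr1", intron_start = 100L, intron_end = 250L,
                   stringsAsFactors = FALSE)
  hap1_set <- jdf(c("chr1:100-200", "chr1:150-260", "chr1:100-250"),
                  distinct_reads = c(4L, 3L, 9L), genome_label = "hap1")
  ov <- overlapping_annotated_reads(jn, ann, hap1_set)
  expect_equal(ov$osj_reads, 7L)          # 4 + 3; self (100-250) excluded
  expect_equal(nrow(ov$overlapping), 2L)

  # annotated junction expressed only in the other haplotype's set: not counted
  hap2_only <- jdf("chr1:800-900", distinct_reads = 11L,
                   genome_label = "hap2")
  ov2 <- overlapping_annotated_reads(jn, ann, hap2_only)
  expect_equal(ov2$osj_reads, 0L)
})

test_that("alternative-splice-site subset enforces all three eligibility rules", {
  base <- data.frame(
    sample = "S1", chrom = "chr1",
    intron_start = c(100L, 300L, 500L, 700L),
    intron_end = c(200L, 400L, 600L, 800L),
    category = "hap1_specific",
    psj_reads = c(6L, 6L, 4L, 6L), osj_reads = c(6L, 6L, 5L, 6L),
    usage = 0.5, n_overlapping = c(1L, 2L, 1L, 1L),
    offset = c(5L, 5L, 5L, 5L), shared_site = "start",
    frameshift = TRUE, stringsAsFactors = FALSE)
  anns <- data.frame(chrom = "chr1",
                     intron_start = c(100L, 300L, 500L, 700L),
                     intron_end = c(200L, 400L, 600L, 800L),
                     gt = c("1|1", "1|1", "1|1", "0|1"),
                     stringsAsFactors = FALSE)
  out <- alt_ss_subset(base, anns, min_combined_reads = 10L)
  key <- paste0(out$intron_start, "-", out$intron_end)
  expect_equal(key, "100-200")
  # row 2: two overlapping junctions; row 3: 9 combined reads; row 4: het
})

test_that("detection frequency counts carriers and suppresses junctions without any", {
  ann_row <- function(sample) data.frame(
    chrom = "chr1", intron_start = 100L, intron_end = 200L,
    snp_id = "rsD", snp_pos = 100L, snp_ref = "A", snp_alt = "G",
    gt = "0|1", site = "donor", dinuc_reference = "GG",
    dinuc_personal = "GT", creates_canonical = TRUE,
    disrupts_reference_site = FALSE, nagnag = FALSE,
    stringsAsFactors = FALSE)
  catalogs <- list(
    A = structure(list(sample_id = "A", snp_annotations = ann_row("A")),
                  class = "psj_catalog"),
    B = structure(list(sample_id = "B", snp_annotations = NULL),
                  class = "psj_catalog"))
  genotypes <- data.frame(sample = c("A", "B", "C", "D"), snp_id = "rsD",
                          n_alt = c(1L, 2L, 1L, 1L))
  df <- detection_frequency(catalogs, genotypes)
  expect_equal(df$n_carriers, 4L)
  expect_equal(df$n_detected, 1L)
  expect_equal(df$detection_frequency, 0.25)

  all_det <- detection_frequency(
    list(A = catalogs$A,
         B = structure(list(sample_id = "B", snp_annotations = ann_row("B")),
                       class = "psj_catalog")),
    data.frame(sample = c("A", "B"), snp_id = "rsD", n_alt = 1L))
  expect_equal(all_det$detection_frequency, 1.0)

  expect_warning(
    none <- detection_frequency(catalogs,
                                data.frame(sample = "A", snp_id = "rsD",
                                           n_alt = 0L)),
    "no genotyped carriers")
  expect_equal(nrow(none), 0L)
})

test_that("frameshift predicate matches a translation-phase oracle for offsets 1..12", {
  # oracle: splice a coding transcript with the reference site and with the
  # alternative site offset nt away, translate both, and compare the protein
  # suffix downstream of the variable region
  set.seed(21)
  for (offset in 1:12) {
    exon1 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
    var_region <- paste(sample(c("A", "C", "G", "T"), offset,
                               replace = TRUE), collapse = "")
    exon2 <- paste(rep("GCTGAAGATCTTACT", 6), collapse = "")  # 90 nt suffix
    tx_ref <- paste0(exon1, var_region, exon2)
    tx_alt <- paste0(exon1, exon2)
    suffix_aa <- function(tx) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(tx, 1, 3 * (nchar(tx) %/% 3))),
        if.fuzzy.codon = "X"))
      substr(aa, nchar(aa) - 10, nchar(aa))
    }
    frame_preserved <- suffix_aa(tx_ref) == suffix_aa(tx_alt)
    expect_equal(frameshift_predicate(offset), !frame_preserved)
  }
  expect_true(frameshift_predicate(5))
  expect_false(frameshift_predicate(3))
  expect_true(frameshift_predicate(1))
  expect_true(frameshift_predicate(-5))
})

test_that("measured usage recovers rho/(1+rho) within binomial error over 100 replicates", {
  set.seed(77)
  rho <- 1.5
  p <- rho / (1 + rho)
  n_frag <- 24L
  usages <- numeric(100)
  genome <- Biostrings::DNAStringSet(setNames(paste0(
    strrep("A", 40), "GT", strrep("C", 151), "AG", strrep("A", 60)), "chrT"))
  # personal junction 41..194 shares its donor with the annotated 41..199
  ann <- data.frame(chrom = "chrT", intron_start = 41L, intron_end = 199L,
                    strand = "+", stringsAsFactors = FALSE)
  for (r in 1:100) {
    n_psj <- stats::rbinom(1, n_frag, p)
    n_osj <- n_frag - n_psj
    mk <- function(n, cigar_fn, tag) {
      if (n == 0L) return(NULL)
      starts <- sample(6:29, n, replace = FALSE)
      data.frame(read_id = sprintf("%s_%d", tag, seq_len(n)), flag = 0L,
                 chrom = "chrT", pos = starts, cigar = cigar_fn(starts),
                 paired = FALSE, flag_unmapped = FALSE, mate_unmapped = FALSE,
                 stringsAsFactors = FALSE)
    }
    reads <- rbind(
      mk(n_psj, function(s) paste0(41L - s, "M154N", 60L - (41L - s), "M"),
         "p"),
      mk(n_osj, function(s) paste0(41L - s, "M159N", 60L - (41L - s), "M"),
         "o"))
    js <- collect_junction_set(reads, genome, "hap1")
    jn <- data.frame(chrom = "chrT", intron_start = 41L, intron_end = 194L)
    psj <- js$distinct_reads[js$intron_end == 194L]
    if (length(psj) == 0L) psj <- 0L
    ov <- overlapping_annotated_reads(jn, ann, js)
    usages[r] <- relative_usage(psj, ov$osj_reads)
  }
  est <- mean(usages, na.rm = TRUE)
  se <- sqrt(p * (1 - p) / (100 * n_frag))
  expect_lt(abs(est - p), 4 * se + 0.01)
})

test_that("per-sample usage tables and the cohort summary agree with the simulator truth", {
  res <- default_pipeline()
  sc <- default_scenario()
  u <- res$usage
  tr <- sc$truth[sc$truth$has_splice_site_snp, ]
  m <- match(paste0(u$intron_start, "-", u$intron_end),
             paste0(tr$intron_start, "-", tr$intron_end))
  expect_false(anyNA(m))
  expect_equal(u$usage, tr$expected_usage[m])
  expect_equal(abs(u$offset), tr$offset[m])
  # in-frame only for the tandem-acceptor event
  expect_equal(u$frameshift, abs(u$offset) %% 3 != 0)

  summ <- cohort_usage_summary(list(u))
  expect_equal(nrow(summ), nrow(u))
  expect_equal(sort(summ$mean_usage), sort(u$usage))
  expect_true(all(summ$n_individuals == 1L))
})
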