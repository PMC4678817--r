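test_that("three-way comparison assigns each junction exactly one category", {
  ref <- jdf(c("chr1:100-200", "chr1:500-600", "chr1:900-980"),
             genome_label = "hg19")
  hap1 <- jdf(c("chr1:100-200", "chr1:300-400", "chr1:700-800"),
              genome_label = "hap1")
  hap2 <- jdf(c("chr1:100-200", "chr1:700-800", "chr1:500-600"),
              genome_label = "hap2")
  cat <- classify_specific_junctions(ref, hap1, hap2, "S1")
  j <- cat$junctions
  key <- paste0(j$chrom, ":", j$intron_start, "-", j$intron_end)
  expect_equal(j$category[key == "chr1:300-400"], "hap1_specific")
  expect_equal(j$category[key == "chr1:700-800"], "hap1hap2_specific")
  expect_equal(j$category[key == "chr1:100-200"], "shared")
  expect_equal(j$category[key == "chr1:500-600"], "shared")
  expect_equal(j$category[key == "chr1:900-980"], "hg19_specific")

  # partition: one category per junction, counts sum to the union size
  union_keys <- unique(c("chr1:100-200", "chr1:500-600", "chr1:900-980",
                         "chr1:300-400", "chr1:700-800"))
  expect_equal(nrow(j), length(union_keys))
  expect_equal(sum(table(j$category)), length(union_keys))
  expect_equal(nrow(personal_specific(cat)), 2L)
})

test_that("category partition holds on random three-way sets", {
  set.seed(33)
  for (rep in 1:25) {
    keys <- sprintf("chr1:%d-%d", seq(100, 5000, by = 100),
                    seq(150, 5050, by = 100))
    pick <- function() sample(keys, sample(3:15, 1))
    s <- lapply(1:3, function(i) jdf(pick()))
    cat <- classify_specific_junctions(s[[1]], s[[2]], s[[3]])
    j <- cat$junctions
    all_keys <- unique(c(
      with(s[[1]], paste0(chrom, ":", intron_start, "-", intron_end)),
      with(s[[2]], paste0(chrom, ":", intron_start, "-", intron_end)),
      with(s[[3]], paste0(chrom, ":", intron_start, "-", intron_end))))
    expect_equal(nrow(j), length(all_keys))
    expect_true(all(j$category %in% c("hap1_specific", "hap2_specific",
                                      "hap1hap2_specific", "shared",
                                      "hg19_specific")))
  }
})

test_that("minimum-support filter removes weak personal junctions only", {
  ref <- jdf("chr1:900-980", distinct_reads = 1L)
  hap1 <- jdf(c("chr1:300-400", "chr1:500-600"), distinct_reads = c(1L, 2L))
  cat <- classify_specific_junctions(ref, hap1, jdf(character(0)))
  out <- suppressMessages(filter_min_support(cat, 2L))
  key <- with(out$junctions, paste0(chrom, ":", intron_start, "-", intron_end))
  expect_false("chr1:300-400" %in% key)      # 1 distinct read: removed
  expect_true("chr1:500-600" %in% key)       # exactly 2: kept
  expect_true("chr1:900-980" %in% key)       # hg19-specific: untouched
  # min_distinct = 1 is the identity
  same <- filter_min_support(cat, 1L)
  expect_equal(nrow(same$junctions), nrow(cat$junctions))
})

test_that("splice-site SNP annotation reads the dinucleotides strand-aware", {
  # intron 21..60; reference donor dinuc is GG, the SNP makes it GT
  g_ref <- paste0(strrep("A", 20), "GG", strrep("C", 36), "AG", strrep("A", 20))
  g_per <- paste0(strrep("A", 20), "GT", strrep("C", 36), "AG", strrep("A", 20))
  ref <- Biostrings::DNAStringSet(setNames(g_ref, "chr1"))
  per <- Biostrings::DNAStringSet(setNames(g_per, "chr1"))
  variants <- data.frame(chrom = "chr1", pos = 22L, ref = "G", alt = "T",
                         hap1 = "T", hap2 = "G", snp_id = "rsX", gt = "1|0",
                         stringsAsFactors = FALSE)
  jn <- data.frame(chrom = "chr1", intron_start = 21L, intron_end = 60L,
                   strand = "+", stringsAsFactors = FALSE)
  ann <- annotate_splice_site_snp(jn, variants, ref, per)
  expect_equal(ann$site, "donor")
  expect_equal(ann$dinuc_reference, "GG")
  expect_equal(ann$dinuc_personal, "GT")
  expect_true(ann$creates_canonical)

  # a SNP five bases into the intron is not a splice-site SNP
  deep <- transform(variants, pos = 25L)
  expect_null(annotate_splice_site_snp(jn, deep, ref, per))
})

test_that("tandem NAGNAG acceptors are flagged", {
  # personal junction uses a downstream AG three bases after another AG
  g_per <- paste0(strrep("A", 20), "GT", strrep("C", 30), "AGC",
                  "AG", strrep("T", 20))
  g_ref <- paste0(strrep("A", 20), "GT", strrep("C", 30), "AGC",
                  "AA", strrep("T", 20))
  per <- Biostrings::DNAStringSet(setNames(g_per, "chr1"))
  ref <- Biostrings::DNAStringSet(setNames(g_ref, "chr1"))
  jn <- data.frame(chrom = "chr1", intron_start = 21L, intron_end = 57L,
                   strand = "+", stringsAsFactors = FALSE)
  variants <- data.frame(chrom = "chr1", pos = 57L, ref = "A", alt = "G",
                         hap1 = "G", hap2 = "G", snp_id = "rsN", gt = "1|1",
                         stringsAsFactors = FALSE)
  ann <- annotate_splice_site_snp(jn, variants, ref, per)
  expect_equal(ann$site, "acceptor")
  expect_true(ann$creates_canonical)
  expect_true(ann$nagnag)
})

test_that("a haplotype-specific junction with a homozygous splice-site SNP is flagged", {
  g_ref <- paste0(strrep("A", 20), "GG", strrep("C", 36), "AG", strrep("A", 20))
  g_per <- paste0(strrep("A", 20), "GT", strrep("C", 36), "AG", strrep("A", 20))
  ref <- Biostrings::DNAStringSet(setNames(g_ref, "chr1"))
  per <- Biostrings::DNAStringSet(setNames(g_per, "chr1"))
  variants <- data.frame(chrom = "chr1", pos = 22L, ref = "G", alt = "T",
                         hap1 = "T", hap2 = "T", snp_id = "rsH", gt = "1|1",
                         stringsAsFactors = FALSE)
  # the junction appears only in hap1's set, yet the SNP is hom: suspicious
  cat <- classify_specific_junctions(jdf(character(0)), jdf("chr1:21-60"),
                                     jdf(character(0)))
  expect_message(filter_splice_site_snp_junctions(cat, variants, ref, per,
                                                  per),
                 "homozygous")
  out <- suppressMessages(
    filter_splice_site_snp_junctions(cat, variants, ref, per, per))
  expect_true(out$snp_annotations$suspicious_zygosity)
  expect_equal(nrow(out$junctions), 1L)   # kept, not removed
})

test_that("known/novel labelling is exact-coordinate with strand tolerance", {
  ann <- data.frame(chrom = "chr1", intron_start = c(100L, 300L),
                    intron_end = c(200L, 400L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  j <- jdf(c("chr1:100-200", "chr1:100-201", "chr1:300-400"))
  out <- suppressWarnings(known_or_novel(j, ann))
  expect_equal(out$known, c(TRUE, FALSE, TRUE))   # 1 nt off is novel
  expect_true(out$strand_conflict[3])             # + junction on - intron
  none <- known_or_novel(j, ann[0, ])
  expect_false(any(none$known))
})

test_that("support and splice-site-SNP filters commute", {
  res <- default_pipeline()
  sc <- default_scenario()
  opts <- pipeline_options()
  genomes <- res$genomes
  raw <- classify_specific_junctions(res$sets$ref, res$sets$hap1,
                                     res$sets$hap2, sc$sample_id)
  a <- suppressMessages(filter_splice_site_snp_junctions(
    filter_min_support(raw, opts$min_distinct), res$variants,
    genomes$ref, genomes$hap1, genomes$hap2, res$annotation))
  b <- suppressMessages(filter_min_support(
    filter_splice_site_snp_junctions(raw, res$variants, genomes$ref,
                                     genomes$hap1, genomes$hap2,
                                     res$annotation),
    opts$min_distinct))
  ka <- with(a$junctions, paste0(chrom, ":", intron_start, "-", intron_end))
  kb <- with(b$junctions, paste0(chrom, ":", intron_start, "-", intron_end))
  expect_setequal(ka, kb)
})

test_that("reverse run is symmetric and empty on clean scenarios", {
  res <- default_pipeline()
  expect_equal(nrow(res$hg19_specific_reverse), 0L)

  # swapping roles twice returns the forward classification
  ref <- jdf(c("chr1:100-200", "chr1:900-980"))
  hap1 <- jdf(c("chr1:100-200", "chr1:300-400"))
  hap2 <- jdf("chr1:100-200")
  fwd <- classify_specific_junctions(ref, hap1, hap2)
  hg <- reverse_false_positive_run(ref, hap1, hap2)
  expect_equal(nrow(hg), 1L)
  expect_equal(hg$intron_start, 900L)
  back <- classify_specific_junctions(ref, hap1, hap2)
  expect_identical(fwd$junctions, back$junctions)
})

test_that("a reference site destroyed on both haplotypes surfaces as an hg19-specific junction", {
  cfg <- scenario_config(seed = 5, n_donor_create = 1L,
                         n_acceptor_create = 0L, n_nagnag = 0L, n_swap = 0L,
                         n_destroy = 1L, n_baseline = 1L)
  sc <- simulate_scenario(cfg)
  res <- suppressMessages(run_scenario_pipeline(sc, score = FALSE))
  destroyed <- sc$truth[sc$truth$type == "destroy", ]
  hg <- res$hg19_specific_reverse
  expect_equal(nrow(hg), 1L)
  expect_equal(hg$intron_start, destroyed$ref_intron_start)
  expect_equal(hg$intron_end, destroyed$ref_intron_end)
})

test_that("coordinate-identical junctions without splice-site SNPs are filtered out", {
  cfg <- scenario_config(seed = 9, n_donor_create = 1L,
                         n_acceptor_create = 0L, n_nagnag = 0L, n_swap = 0L,
                         n_elsewhere = 1L, n_baseline = 1L)
  sc <- simulate_scenario(cfg)
  res <- suppressMessages(run_scenario_pipeline(sc, score = FALSE))
  elsewhere <- sc$truth[sc$truth$type == "elsewhere", ]
  # before the SNP filter the junction is personal-specific (its reads all
  # carry the exonic alt allele and fail reference alignment) ...
  raw <- classify_specific_junctions(res$sets$ref, res$sets$hap1,
                                     res$sets$hap2, sc$sample_id)
  raw_keys <- with(personal_specific(raw),
                   paste0(chrom, ":", intron_start, "-", intron_end))
  ekey <- paste0(elsewhere$chrom, ":", elsewhere$ref_intron_start, "-",
                 elsewhere$ref_intron_end)
  expect_true(ekey %in% raw_keys)
  # ... and the splice-site SNP filter removes it
  kept <- with(personal_specific(res$catalog),
               paste0(chrom, ":", intron_start, "-", intron_end))
  expect_false(ekey %in% kept)
  # the planted donor-create junction survives
  ev <- truth_evaluation(res$catalog, sc$truth)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$precision, 1.0)
})
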