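#' Pipeline thresholds
#'
#' All stage thresholds with their standard defaults: personal-specific
#' junctions need at least 2 distinct supporting reads; spliced alignments
#' need 12 nt junction overhangs and introns of at most 300 kb; usage
#' comparisons in the alternative-splice-site subset need 10 combined
#' distinct reads; GWAS linkage uses catalog SNPs below p = 1e-3 and an LD
#' threshold of r2 > 0.8.
#'
#' @param min_distinct,min_overhang,max_intron,min_intron,max_hits,
#'   min_combined_reads,r2_min,gwas_p_max thresholds.
#' @return named list.
#' @export
pipeline_options <- function(min_distinct = 2L, min_overhang = 12L,
                             max_intron = 300000L, min_intron = 20L,
                             max_hits = 20L, min_combined_reads = 10L,
                             r2_min = 0.8, gwas_p_max = 1e-3) {
  as.list(environment())
}

#' Run the full discovery pipeline on a simulated scenario
#'
#' Executes every stage in dependency order: personalize (hap1/hap2 genome
#' construction from the phased VCF records), three-way alignment of all
#' read pairs with the exact-match toy aligner, junction-set extraction per
#' genome, three-way classification, the minimum-support and splice-site-SNP
#' filters, known/novel labelling against the scenario annotation, usage
#' quantification, splice-site scoring, and the reverse false-positive run
#' (reads unmappable to both personal genomes re-aligned to the reference).
#'
#' @param scenario from \code{\link{simulate_scenario}}.
#' @param opts from \code{\link{pipeline_options}}.
#' @param score whether to run the maximum-entropy scoring stage.
#' @return list with the junction sets, the filtered catalog, usage and
#'   score tables, the reverse-run hg19-specific junctions, and a manifest.
#' @export
run_scenario_pipeline <- function(scenario, opts = pipeline_options(),
                                  score = TRUE) {
  genome <- scenario$genome
  vcf_path <- tempfile(fileext = ".vcf")
  write_phased_vcf(scenario$vcf_records, scenario$sample_id, genome, vcf_path)
  snps <- load_phased_snps(vcf_path, scenario$sample_id)
  hap1 <- build_haplotype_fasta(genome, snps$variants, 1L)$genome
  hap2 <- build_haplotype_fasta(genome, snps$variants, 2L)$genome

  gtf_path <- tempfile(fileext = ".gtf")
  write_exon_gtf(scenario$gtf, gtf_path)
  ann <- annotation_introns_from_gtf(gtf_path)

  aln <- lapply(list(ref = genome, hap1 = hap1, hap2 = hap2), function(gm) {
    a <- align_reads(scenario$reads, gm, min_overhang = opts$min_overhang,
                     max_intron = opts$max_intron,
                     min_intron = opts$min_intron, max_hits = opts$max_hits)
    a[classify_read_mapping(a), , drop = FALSE]
  })
  sets <- list(
    ref = collect_junction_set(aln$ref, genome, "hg19",
                               opts$min_overhang, opts$max_intron,
                               opts$min_intron),
    hap1 = collect_junction_set(aln$hap1, hap1, "hap1",
                                opts$min_overhang, opts$max_intron,
                                opts$min_intron),
    hap2 = collect_junction_set(aln$hap2, hap2, "hap2",
                                opts$min_overhang, opts$max_intron,
                                opts$min_intron))

  catalog <- classify_specific_junctions(sets$ref, sets$hap1, sets$hap2,
                                         scenario$sample_id)
  catalog <- filter_min_support(catalog, opts$min_distinct)
  catalog <- filter_splice_site_snp_junctions(catalog, snps$variants,
                                              genome, hap1, hap2, ann)
  catalog$junctions <- known_or_novel(catalog$junctions, ann)

  usage <- usage_table(catalog, ann, sets$hap1, sets$hap2)
  if (score && nrow(usage) > 0L) {
    usage <- score_catalog(usage, catalog, genome, hap1, hap2)
  }

  # reverse direction: fragments unmappable to both personal genomes,
  # re-examined on the reference (aln$hap1/aln$hap2 hold the mapped records)
  unmappable <- setdiff(unique(scenario$reads$read_id),
                        union(aln$hap1$read_id, aln$hap2$read_id))
  rev_reads <- scenario$reads[scenario$reads$read_id %in% unmappable, ,
                              drop = FALSE]
  rev_set <- if (nrow(rev_reads) > 0L) {
    a <- align_reads(rev_reads, genome, min_overhang = opts$min_overhang,
                     max_intron = opts$max_intron,
                     min_intron = opts$min_intron, max_hits = opts$max_hits)
    collect_junction_set(a[classify_read_mapping(a), , drop = FALSE],
                         genome, "hg19", opts$min_overhang,
                         opts$max_intron, opts$min_intron)
  } else sets$ref[0, , drop = FALSE]
  hg19_specific <- reverse_false_positive_run(rev_set, sets$hap1, sets$hap2,
                                              opts$min_distinct)

  manifest <- list(
    tool = "hiddensplice", version = "0.1.0",
    sample = scenario$sample_id, seed = scenario$config$seed,
    thresholds = opts,
    n_reads = length(unique(scenario$reads$read_id)),
    n_variants = nrow(snps$variants),
    category_counts = as.list(table(catalog$junctions$category)),
    n_personal_specific = nrow(personal_specific(catalog)),
    n_hg19_specific_reverse = nrow(hg19_specific))

  list(sets = sets, catalog = catalog, usage = usage,
       hg19_specific_reverse = hg19_specific, annotation = ann,
       variants = snps$variants, genomes = list(ref = genome, hap1 = hap1,
                                                hap2 = hap2),
       manifest = manifest)
}

#' Run the pipeline from files on disk
#'
#' File-based front end over the same stages: reads the reference FASTA,
#' phased VCF, annotation GTF and either pre-computed SAM/BAM alignments
#' (one per genome) or a FASTQ pair to align with the toy aligner, and
#' writes the catalog, usage table and manifest to \code{out_dir}.
#'
#' @param ref_fa,vcf,gtf input paths.
#' @param sample_id sample in the VCF.
#' @param reads_fq1,reads_fq2 FASTQ pair (toy-aligner route), or
#' @param sam_ref,sam_hap1,sam_hap2 pre-aligned SAM/BAM triple.
#' @param out_dir output directory.
#' @param opts \code{\link{pipeline_options}}.
#' @return the result list of \code{\link{run_scenario_pipeline}},
#'   invisibly; outputs written to \code{out_dir}.
#' @export
run_all <- function(ref_fa, vcf, gtf, sample_id, out_dir,
                    reads_fq1 = NULL, reads_fq2 = NULL,
                    sam_ref = NULL, sam_hap1 = NULL, sam_hap2 = NULL,
                    opts = pipeline_options()) {
  genome <- Biostrings::readDNAStringSet(ref_fa)
  names(genome) <- sub("\\s.*$", "", names(genome))
  snps <- load_phased_snps(vcf, sample_id)
  hap1 <- build_haplotype_fasta(genome, snps$variants, 1L)$genome
  hap2 <- build_haplotype_fasta(genome, snps$variants, 2L)$genome
  ann <- annotation_introns_from_gtf(gtf)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(reads_fq1)) {
    rd1 <- Biostrings::readDNAStringSet(reads_fq1, format = "fastq")
    rd2 <- if (!is.null(reads_fq2))
      Biostrings::readDNAStringSet(reads_fq2, format = "fastq")
    reads <- rbind(
      data.frame(read_id = names(rd1), mate = 1L,
                 seq = as.character(rd1), stringsAsFactors = FALSE),
      if (!is.null(rd2))
        data.frame(read_id = names(rd2), mate = 2L,
                   seq = as.character(rd2), stringsAsFactors = FALSE))
    scenario <- list(genome = genome, reads = reads, sample_id = sample_id,
                     vcf_records = NULL, config = list(seed = NA))
    # reuse the in-memory driver with externally supplied inputs
    vcf_tmp <- vcf
    res <- local({
      sc <- scenario
      sc$gtf <- NULL
      # inline variant of run_scenario_pipeline with preloaded pieces
      aln <- lapply(list(ref = genome, hap1 = hap1, hap2 = hap2),
                    function(gm) {
        a <- align_reads(sc$reads, gm, min_overhang = opts$min_overhang,
                         max_intron = opts$max_intron,
                         min_intron = opts$min_intron,
                         max_hits = opts$max_hits)
        a[classify_read_mapping(a), , drop = FALSE]
      })
      sets <- list(
        ref = collect_junction_set(aln$ref, genome, "hg19",
                                   opts$min_overhang, opts$max_intron,
                                   opts$min_intron),
        hap1 = collect_junction_set(aln$hap1, hap1, "hap1",
                                    opts$min_overhang, opts$max_intron,
                                    opts$min_intron),
        hap2 = collect_junction_set(aln$hap2, hap2, "hap2",
                                    opts$min_overhang, opts$max_intron,
                                    opts$min_intron))
      catalog <- classify_specific_junctions(sets$ref, sets$hap1, sets$hap2,
                                             sample_id)
      catalog <- filter_min_support(catalog, opts$min_distinct)
      catalog <- filter_splice_site_snp_junctions(catalog, snps$variants,
                                                  genome, hap1, hap2, ann)
      catalog$junctions <- known_or_novel(catalog$junctions, ann)
      usage <- usage_table(catalog, ann, sets$hap1, sets$hap2)
      if (nrow(usage) > 0L) {
        usage <- score_catalog(usage, catalog, genome, hap1, hap2)
      }
      list(sets = sets, catalog = catalog, usage = usage)
    })
  } else {
    stopifnot(!is.null(sam_ref), !is.null(sam_hap1), !is.null(sam_hap2))
    sets <- list(
      ref = collect_junction_set(
        {a <- read_alignments(sam_ref); a[classify_read_mapping(a), ]},
        genome, "hg19", opts$min_overhang, opts$max_intron, opts$min_intron),
      hap1 = collect_junction_set(
        {a <- read_alignments(sam_hap1); a[classify_read_mapping(a), ]},
        hap1, "hap1", opts$min_overhang, opts$max_intron, opts$min_intron),
      hap2 = collect_junction_set(
        {a <- read_alignments(sam_hap2); a[classify_read_mapping(a), ]},
        hap2, "hap2", opts$min_overhang, opts$max_intron, opts$min_intron))
    catalog <- classify_specific_junctions(sets$ref, sets$hap1, sets$hap2,
                                           sample_id)
    catalog <- filter_min_support(catalog, opts$min_distinct)
    catalog <- filter_splice_site_snp_junctions(catalog, snps$variants,
                                                genome, hap1, hap2, ann)
    catalog$junctions <- known_or_novel(catalog$junctions, ann)
    usage <- usage_table(catalog, ann, sets$hap1, sets$hap2)
    if (nrow(usage) > 0L) {
      usage <- score_catalog(usage, catalog, genome, hap1, hap2)
    }
    res <- list(sets = sets, catalog = catalog, usage = usage)
  }

  write_catalog_tsv(res$catalog, file.path(out_dir, "catalog.tsv"))
  utils::write.table(res$usage, file.path(out_dir, "usage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(res$sets)) {
    write_junction_tsv(res$sets[[nm]],
                       file.path(out_dir, paste0(nm, ".junc.tsv")))
  }
  manifest <- list(tool = "hiddensplice", version = "0.1.0",
                   sample = sample_id, thresholds = opts,
                   inputs = list(ref_fa = unname(tools::md5sum(ref_fa)),
                                 vcf = unname(tools::md5sum(vcf)),
                                 gtf = unname(tools::md5sum(gtf))),
                   category_counts =
                     as.list(table(res$catalog$junctions$category)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
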