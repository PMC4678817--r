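# Deterministic scenario simulator.
#
# Generates a toy multi-gene genome with canonical GT-AG introns, plants
# splice-site-creating / destroying SNVs with a chosen zygosity mix, and
# produces paired-end junction-spanning reads from the transcripts each
# haplotype actually expresses.  Every planted event is recorded in a truth
# table so pipeline output can be evaluated exactly.

#' Scenario configuration
#'
#' Defaults describe the study conditions the pipeline is meant for: strict
#' exact-match alignment of short paired-end reads (60 nt, 140 nt
#' fragments), a 12 nt junction overhang, personal junctions expressed at a
#' 1:1 ratio with the overlapping reference junction, and 6 distinct
#' supporting read starts per junction.
#'
#' @param seed integer seed; identical (config, seed) gives byte-identical
#'   output.
#' @param n_donor_create,n_acceptor_create numbers of SNPs creating a novel
#'   donor (GT) / acceptor (AG) site at the offsets in \code{donor_offsets}
#'   / \code{acceptor_offsets} (nt between personal and reference site,
#'   cycled).
#' @param n_nagnag tandem-acceptor events: an exonic SNP 3 nt downstream of
#'   the reference acceptor creates a NAGNAG pair (in-frame).
#' @param n_swap site-swap events: the SNP simultaneously corrupts the
#'   reference acceptor (AG to AA) and creates a personal acceptor 1 nt
#'   downstream.
#' @param n_destroy SNPs (homozygous) destroying a reference donor with no
#'   replacement; their reference-transcript reads become unmappable to the
#'   personal genomes and surface in the reverse false-positive run.
#' @param n_elsewhere homozygous exonic SNPs near a reference junction; all
#'   junction reads carry the alt allele, so the (coordinate-identical)
#'   junction looks personal-specific but carries no splice-site SNP.
#' @param n_baseline genes with no planted SNP at all.
#' @param zygosity phased genotypes cycled over the create events.
#' @param coverage distinct read starts per planted personal junction.
#' @param rho personal:reference junction read ratio; the reference
#'   junction of a planted gene gets \code{round(coverage / rho)} distinct
#'   starts.
#' @param read_len,frag_len,min_overhang read geometry.
#' @param exon_len_range,intron_len_range,spacer_len gene geometry (nt).
#' @param n_dup_reads extra reads duplicating an existing start position
#'   (exercises distinct-start counting).
#' @return list of class \code{scenario_config}.
#' @export
scenario_config <- function(seed = 1L, n_donor_create = 2L,
                            n_acceptor_create = 2L, n_nagnag = 1L,
                            n_swap = 1L, n_destroy = 0L, n_elsewhere = 0L,
                            n_baseline = 2L,
                            donor_offsets = c(5L, 7L, 4L, 8L),
                            acceptor_offsets = c(5L, 7L, 2L, 10L),
                            zygosity = c("1|0", "0|1", "1|1"),
                            coverage = 6L, rho = 1,
                            read_len = 60L, frag_len = 140L,
                            min_overhang = 12L,
                            exon_len_range = c(130L, 180L),
                            intron_len_range = c(150L, 280L),
                            spacer_len = 200L, n_dup_reads = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

rand_dna <- function(n, probs = c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

set_bases <- function(seq, pos, bases) {
  b <- strsplit(bases, "")[[1]]
  for (i in seq_along(b)) substr(seq, pos + i - 1L, pos + i - 1L) <- b[i]
  seq
}

# internal: one gene in sense space.  Returns the edited reference sense
# sequence, exon/intron intervals, the event description (sense coords) and
# the transcripts to read from.
build_gene <- function(cfg, type, offset, gt, gene_id) {
  e_len <- sample(seq(cfg$exon_len_range[1], cfg$exon_len_range[2]), 3L,
                  replace = TRUE)
  i_len <- sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]), 2L,
                  replace = TRUE)
  L <- sum(e_len) + sum(i_len)
  seqs <- rand_dna(L)
  e1 <- c(1L, e_len[1])
  i1 <- c(e_len[1] + 1L, e_len[1] + i_len[1])
  e2 <- c(i1[2] + 1L, i1[2] + e_len[2])
  i2 <- c(e2[2] + 1L, e2[2] + i_len[2])
  e3 <- c(i2[2] + 1L, i2[2] + e_len[3])
  seqs <- set_bases(seqs, i1[1], "GT"); seqs <- set_bases(seqs, i1[2] - 1L, "AG")
  seqs <- set_bases(seqs, i2[1], "GT"); seqs <- set_bases(seqs, i2[2] - 1L, "AG")
  s <- i1[1]; e <- i1[2]

  snp <- NULL; personal_intron <- NULL; site <- NA_character_
  if (type == "donor_create") {
    stopifnot(offset >= 3L)
    seqs <- set_bases(seqs, s + offset, "GA")
    snp <- list(pos = s + offset + 1L, ref = "A", alt = "T")
    personal_intron <- c(s + offset, e)
    site <- "donor"
  } else if (type == "acceptor_create") {
    stopifnot(offset >= 2L)
    seqs <- set_bases(seqs, e - offset - 1L, "AA")
    snp <- list(pos = e - offset, ref = "A", alt = "G")
    personal_intron <- c(s, e - offset)
    site <- "acceptor"
  } else if (type == "nagnag") {
    offset <- 3L
    seqs <- set_bases(seqs, e + 2L, "AA")
    snp <- list(pos = e + 3L, ref = "A", alt = "G")
    personal_intron <- c(s, e + 3L)
    site <- "acceptor"
  } else if (type == "swap") {
    offset <- 1L
    seqs <- set_bases(seqs, e + 1L, "G")   # completes the shifted AG
    snp <- list(pos = e, ref = "G", alt = "A")  # corrupts the reference AG
    personal_intron <- c(s, e + 1L)
    site <- "acceptor"
  } else if (type == "destroy") {
    snp <- list(pos = s + 1L, ref = "T", alt = "G")
    site <- "donor"
  } else if (type == "elsewhere") {
    p <- e1[2] - 5L  # inside every junction-spanning read's left anchor
    ref_base <- substr(seqs, p, p)
    snp <- list(pos = p, ref = ref_base,
                alt = setdiff(c("A", "C", "G", "T"), ref_base)[1])
  }

  # transcripts (sense space)
  splice_seq <- function(sq, exons) {
    paste(vapply(exons, function(x) substr(sq, x[1], x[2]), character(1)),
          collapse = "")
  }
  ref_exons <- list(e1, e2, e3)
  personal_seq <- seqs
  if (!is.null(snp)) {
    personal_seq <- set_bases(personal_seq, snp$pos, snp$alt)
  }
  personal_exons <- NULL
  if (!is.null(personal_intron)) {
    # exon 2 keeps its reference end; intron 2 is still spliced out
    personal_exons <- list(c(1L, personal_intron[1] - 1L),
                           c(personal_intron[2] + 1L, e2[2]), e3)
  }
  list(gene_id = gene_id, type = type, offset = offset, gt = gt,
       seq = seqs, len = L,
       exons = ref_exons, introns = list(i1, i2),
       snp = snp, personal_intron = personal_intron, site = site,
       transcript_ref = splice_seq(seqs, ref_exons),
       transcript_ref_alt = splice_seq(personal_seq, ref_exons),
       transcript_personal = if (!is.null(personal_exons))
         splice_seq(personal_seq, personal_exons)
       else if (type == "elsewhere") splice_seq(personal_seq, ref_exons),
       exon1_ref_len = e_len[1])
}

# internal: paired junction-spanning reads from a transcript; mate 1 spans
# the junction at p_j with distinct jittered starts, mate 2 sits downstream
make_read_pairs <- function(transcript, p_j, n, cfg, prefix, n_dup = 0L) {
  lo <- max(1L, p_j + cfg$min_overhang - cfg$read_len + 1L)
  hi <- p_j - cfg$min_overhang + 1L
  starts <- sort(sample(seq(lo, hi), min(n, hi - lo + 1L)))
  if (n_dup > 0L) starts <- c(starts, rep(starts[1], n_dup))
  out <- vector("list", 2L * length(starts))
  for (i in seq_along(starts)) {
    st <- starts[i]
    m2s <- st + cfg$frag_len - cfg$read_len
    m1 <- substr(transcript, st, st + cfg$read_len - 1L)
    m2 <- revcomp_chr(substr(transcript, m2s, m2s + cfg$read_len - 1L))
    rid <- paste0(prefix, "_f", i)
    out[[2L * i - 1L]] <- data.frame(read_id = rid, mate = 1L, seq = m1,
                                     stringsAsFactors = FALSE)
    out[[2L * i]] <- data.frame(read_id = rid, mate = 2L, seq = m2,
                                stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a complete test scenario
#'
#' Builds the toy genome, the phased sample VCF, the reference-isoform
#' annotation, the read set and the truth table under one seed.  Genes
#' alternate between the plus and minus genomic strand (the sense-space
#' construction is reverse-complemented into the genome, so minus-strand
#' junction motifs read CT..AC on the forward strand).
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @param out_dir optional directory; when given, writes \code{ref.fa},
#'   \code{sample.vcf}, \code{annot.gtf}, \code{reads_1.fq},
#'   \code{reads_2.fq} and \code{truth.tsv}.
#' @return list with \code{genome} (DNAStringSet, one chromosome
#'   \code{chrS}), \code{vcf_records} (data.frame), \code{gtf}
#'   (data.frame of exon rows), \code{reads} (data.frame), \code{truth}
#'   (data.frame), \code{sample_id}, \code{config}, and (if written)
#'   \code{paths}.
#' @export
simulate_scenario <- function(cfg = scenario_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  events <- c(rep("donor_create", cfg$n_donor_create),
              rep("acceptor_create", cfg$n_acceptor_create),
              rep("nagnag", cfg$n_nagnag),
              rep("swap", cfg$n_swap),
              rep("destroy", cfg$n_destroy),
              rep("elsewhere", cfg$n_elsewhere),
              rep("baseline", cfg$n_baseline))
  don_off <- rep(cfg$donor_offsets, length.out = max(1L, cfg$n_donor_create))
  acc_off <- rep(cfg$acceptor_offsets,
                 length.out = max(1L, cfg$n_acceptor_create))
  zyg <- rep(cfg$zygosity, length.out = length(events))

  genes <- list()
  di <- 0L; ai <- 0L
  for (g in seq_along(events)) {
    type <- events[g]
    offset <- NA_integer_
    if (type == "donor_create") { di <- di + 1L; offset <- don_off[di] }
    if (type == "acceptor_create") { ai <- ai + 1L; offset <- acc_off[ai] }
    gt <- if (type %in% c("destroy", "elsewhere")) "1|1" else zyg[g]
    genes[[g]] <- build_gene(cfg, type, offset, gt,
                             sprintf("gene%02d", g))
  }

  # place genes on the single chromosome, alternating strand
  chrom <- "chrS"
  spacer <- rand_dna(cfg$spacer_len)
  genome_seq <- spacer
  tf_list <- list()
  for (g in seq_along(genes)) {
    gene <- genes[[g]]
    strand <- if (g %% 2L == 1L) "+" else "-"
    B <- nchar(genome_seq)
    block <- if (strand == "+") gene$seq else revcomp_chr(gene$seq)
    genome_seq <- paste0(genome_seq, block, rand_dna(cfg$spacer_len))
    tf_list[[g]] <- list(strand = strand, B = B, Lg = gene$len)
  }
  genome <- Biostrings::DNAStringSet(setNames(genome_seq, chrom))

  tf_interval <- function(g, iv) {
    t <- tf_list[[g]]
    if (t$strand == "+") c(t$B + iv[1], t$B + iv[2])
    else c(t$B + t$Lg - iv[2] + 1L, t$B + t$Lg - iv[1] + 1L)
  }
  tf_pos <- function(g, q) {
    t <- tf_list[[g]]
    if (t$strand == "+") t$B + q else t$B + t$Lg - q + 1L
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  vcf <- list(); gtf <- list(); reads <- list(); truth <- list()
  personal_cat <- c("1|0" = "hap1_specific", "0|1" = "hap2_specific",
                    "1|1" = "hap1hap2_specific")
  first_dup_done <- FALSE
  for (g in seq_along(genes)) {
    gene <- genes[[g]]
    strand <- tf_list[[g]]$strand
    # annotation: reference isoform exons
    for (x in gene$exons) {
      iv <- tf_interval(g, x)
      gtf[[length(gtf) + 1L]] <- data.frame(
        chrom = chrom, start = iv[1], end = iv[2], strand = strand,
        gene_id = gene$gene_id, transcript_id = paste0(gene$gene_id, ".t1"),
        stringsAsFactors = FALSE)
    }
    if (!is.null(gene$snp)) {
      p <- tf_pos(g, gene$snp$pos)
      ref_a <- if (strand == "+") gene$snp$ref else comp[[gene$snp$ref]]
      alt_a <- if (strand == "+") gene$snp$alt else comp[[gene$snp$alt]]
      vcf[[length(vcf) + 1L]] <- data.frame(
        chrom = chrom, pos = p, id = paste0("snp_", gene$gene_id),
        ref = ref_a, alt = alt_a, gt = gene$gt, stringsAsFactors = FALSE)
    }
    # reads
    ref_cov <- max(1L, round(cfg$coverage / cfg$rho))
    p_j_ref <- gene$exon1_ref_len
    if (gene$type %in% c("baseline", "destroy", "elsewhere")) {
      tr <- if (gene$type == "elsewhere") gene$transcript_personal
            else gene$transcript_ref
      reads[[length(reads) + 1L]] <- make_read_pairs(
        tr, p_j_ref, cfg$coverage, cfg, paste0(gene$gene_id, "_ref"))
    } else if (gene$type %in% c("donor_create", "acceptor_create", "nagnag",
                                "swap")) {
      p_j_per <- if (gene$type == "donor_create")
        gene$exon1_ref_len + gene$offset else gene$exon1_ref_len
      ndup <- if (!first_dup_done && cfg$n_dup_reads > 0L) cfg$n_dup_reads
              else 0L
      first_dup_done <- first_dup_done || ndup > 0L
      reads[[length(reads) + 1L]] <- make_read_pairs(
        gene$transcript_personal, p_j_per, cfg$coverage, cfg,
        paste0(gene$gene_id, "_psj"), n_dup = ndup)
      # the reference junction stays expressed (from the reference-allele
      # haplotype, or from the same haplotype when both sites coexist),
      # except for a homozygous site swap, where no reference site is left.
      # When the SNP is exonic for the reference junction (tandem acceptor)
      # and the individual is homozygous, those reads carry the alt allele.
      if (!(gene$type == "swap" && gene$gt == "1|1")) {
        ref_tr <- if (gene$type == "nagnag" && gene$gt == "1|1")
          gene$transcript_ref_alt else gene$transcript_ref
        reads[[length(reads) + 1L]] <- make_read_pairs(
          ref_tr, p_j_ref, ref_cov, cfg,
          paste0(gene$gene_id, "_ref"))
      }
    }
    # truth
    i1 <- tf_interval(g, gene$introns[[1]])
    per <- if (!is.null(gene$personal_intron))
      tf_interval(g, gene$personal_intron) else c(NA_integer_, NA_integer_)
    category <- switch(gene$type,
                       baseline = "shared",
                       destroy = "hg19_specific",
                       elsewhere = personal_cat[[gene$gt]],
                       personal_cat[[gene$gt]])
    truth[[length(truth) + 1L]] <- data.frame(
      gene = gene$gene_id, type = gene$type, strand = strand,
      chrom = chrom, intron_start = per[1], intron_end = per[2],
      ref_intron_start = i1[1], ref_intron_end = i1[2],
      snp_id = if (!is.null(gene$snp)) paste0("snp_", gene$gene_id)
               else NA_character_,
      snp_pos = if (!is.null(gene$snp)) tf_pos(g, gene$snp$pos)
                else NA_integer_,
      gt = gene$gt, category_expected = category,
      site = gene$site, offset = gene$offset,
      has_splice_site_snp = gene$type %in%
        c("donor_create", "acceptor_create", "nagnag", "swap"),
      # expected usage in the carrier haplotype: intronic-SNP events see the
      # reference junction's reads there; exonic-SNP events (tandem
      # acceptor, site swap) only when homozygous with the alt-allele reads
      expected_usage = {
        rr <- cfg$coverage /
          (cfg$coverage + max(1L, round(cfg$coverage / cfg$rho)))
        if (gene$type %in% c("donor_create", "acceptor_create")) rr
        else if (gene$type == "nagnag" && gene$gt == "1|1") rr
        else if (gene$type %in% c("nagnag", "swap")) 1.0
        else NA_real_
      },
      stringsAsFactors = FALSE)
  }

  scenario <- list(genome = genome,
                   vcf_records = do.call(rbind, vcf),
                   gtf = do.call(rbind, gtf),
                   reads = do.call(rbind, reads),
                   truth = do.call(rbind, truth),
                   sample_id = "S1", config = cfg)
  if (!is.null(out_dir)) {
    scenario$paths <- write_scenario(scenario, out_dir)
  }
  scenario
}

#' Write scenario files (FASTA, VCF, GTF, FASTQ, truth TSV)
#' @param scenario from \code{\link{simulate_scenario}}.
#' @param out_dir output directory (created).
#' @return named list of paths.
#' @export
write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    ref = file.path(out_dir, "ref.fa"),
    vcf = file.path(out_dir, "sample.vcf"),
    gtf = file.path(out_dir, "annot.gtf"),
    fq1 = file.path(out_dir, "reads_1.fq"),
    fq2 = file.path(out_dir, "reads_2.fq"),
    truth = file.path(out_dir, "truth.tsv"))
  Biostrings::writeXStringSet(scenario$genome, paths$ref, width = 60L)
  write_phased_vcf(scenario$vcf_records, scenario$sample_id,
                   scenario$genome, paths$vcf)
  write_exon_gtf(scenario$gtf, paths$gtf)
  for (m in 1:2) {
    r <- scenario$reads[scenario$reads$mate == m, ]
    sq <- Biostrings::DNAStringSet(setNames(r$seq, r$read_id))
    Biostrings::writeXStringSet(
      sq, paths[[paste0("fq", m)]], format = "fastq",
      qualities = Biostrings::BStringSet(
        vapply(Biostrings::width(sq),
               function(w) paste(rep("I", w), collapse = ""), character(1))))
  }
  utils::write.table(scenario$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

# internal: minimal phased single-sample VCF 4.2 writer (fixture output;
# read back through VariantAnnotation)
write_phased_vcf <- function(records, sample_id, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(genome), ",length=",
                  Biostrings::width(genome), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  body <- character(0)
  if (!is.null(records) && nrow(records) > 0L) {
    records <- records[order(records$chrom, records$pos), ]
    body <- with(records, paste(chrom, pos, id, ref, alt, ".", "PASS", ".",
                                "GT", gt, sep = "\t"))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# internal: exon-rows GTF writer via rtracklayer
write_exon_gtf <- function(gtf, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gtf$chrom,
    ranges = IRanges::IRanges(gtf$start, gtf$end),
    strand = gtf$strand)
  gr$type <- "exon"
  gr$source <- "hiddensplice-sim"
  gr$gene_id <- gtf$gene_id
  gr$transcript_id <- gtf$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Evaluate a catalog against a scenario truth table
#'
#' Exact-coordinate comparison of the filtered personal-specific junctions
#' with the planted truth.  Precision counts any reported junction not in
#' the truth as a false positive; recall counts every expressed planted
#' junction (with a splice-site SNP) that was missed.
#'
#' @param catalog filtered \code{psj_catalog}.
#' @param truth truth table from \code{\link{simulate_scenario}}.
#' @param reverse_hg19 optional data.frame from
#'   \code{\link{reverse_false_positive_run}} to report alongside.
#' @return list with \code{precision}, \code{recall}, \code{n_expected},
#'   \code{n_found}, \code{category_confusion} (data.frame expected vs
#'   observed category) and \code{n_hg19_specific_reverse}.
#' @export
truth_evaluation <- function(catalog, truth, reverse_hg19 = NULL) {
  expected <- truth[truth$has_splice_site_snp & !is.na(truth$intron_start), ,
                    drop = FALSE]
  ek <- junction_key(expected$chrom, expected$intron_start,
                     expected$intron_end)
  found <- personal_specific(catalog)
  fk <- junction_key(found$chrom, found$intron_start, found$intron_end)
  tp <- intersect(fk, ek)
  confusion <- data.frame(
    key = ek,
    expected = expected$category_expected,
    observed = found$category[match(ek, fk)],
    stringsAsFactors = FALSE)
  list(precision = if (length(fk)) length(tp) / length(fk) else NA_real_,
       recall = if (length(ek)) length(tp) / length(ek) else NA_real_,
       n_expected = length(ek), n_found = length(fk),
       category_confusion = confusion,
       n_hg19_specific_reverse = if (!is.null(reverse_hg19))
         nrow(reverse_hg19) else NA_integer_)
}
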