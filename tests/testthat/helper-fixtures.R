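# Shared fixtures, memoised so expensive scenario runs happen once per
# test session regardless of how many files use them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(expr)
  }
  .fixture_cache[[name]]
}

default_scenario <- function() {
  fixture("default_scenario", simulate_scenario(scenario_config(seed = 7)))
}

default_pipeline <- function() {
  fixture("default_pipeline",
          suppressMessages(run_scenario_pipeline(default_scenario())))
}

# noise-free scenario sized for the end-to-end acceptance check:
# >= 10 planted splice-site-SNP junctions, coverage >= 4 distinct starts
acceptance_scenario <- function(seed = 11L) {
  fixture(paste0("acceptance_scenario_", seed),
          simulate_scenario(scenario_config(
            seed = seed, n_donor_create = 4L, n_acceptor_create = 4L,
            n_nagnag = 1L, n_swap = 1L, n_baseline = 2L, coverage = 4L)))
}

acceptance_pipeline <- function(seed = 11L) {
  fixture(paste0("acceptance_pipeline_", seed),
          suppressMessages(run_scenario_pipeline(acceptance_scenario(seed))))
}

# write a small VCF from a record data.frame (chrom, pos, id, ref, alt, gt)
write_test_vcf <- function(records, samples = "S1", contigs = c(chr1 = 10000L),
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_cols <- records[, grepl("^gt", colnames(records)), drop = FALSE]
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], records$id[i], records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT",
            unlist(gt_cols[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# independent one-base-at-a-time reference-coordinate CIGAR walker: the
# oracle for junctions_from_cigar
naive_cigar_walk <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  cur <- pos
  introns <- list()
  for (o in ops) {
    n <- as.integer(sub("[A-Z=]$", "", o))
    op <- sub("^[0-9]+", "", o)
    if (op == "N") {
      first <- cur
      for (i in seq_len(n)) cur <- cur + 1L  # one base at a time
      introns[[length(introns) + 1L]] <- c(first, cur - 1L)
    } else if (op %in% c("M", "D", "=", "X")) {
      for (i in seq_len(n)) cur <- cur + 1L
    }
  }
  if (length(introns) == 0L) {
    data.frame(intron_start = integer(), intron_end = integer())
  } else {
    m <- do.call(rbind, introns)
    data.frame(intron_start = m[, 1], intron_end = m[, 2])
  }
}

random_cigar <- function() {
  n_ops <- sample(1:6, 1)
  ops <- character(0)
  prev_n <- TRUE  # cannot start with N
  for (i in seq_len(n_ops)) {
    op <- if (prev_n) "M" else sample(c("M", "I", "D", "N", "S"), 1)
    len <- sample(1:120, 1)
    ops <- c(ops, paste0(len, op))
    prev_n <- op %in% c("N", "I", "S", "D")
  }
  if (!grepl("M$", ops[length(ops)])) ops <- c(ops, paste0(sample(1:50, 1), "M"))
  paste(ops, collapse = "")
}

rand_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# simple junction data.frame builder for classifier tests
jdf <- function(keys, distinct_reads = 5L, strand = "+", motif = "GT-AG",
                genome_label = "hg19") {
  if (length(keys) == 0L) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      motif = character(), distinct_reads = integer(),
                      genome_label = character(), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "[:-]"))
  data.frame(chrom = parts[, 1], intron_start = as.integer(parts[, 2]),
             intron_end = as.integer(parts[, 3]),
             strand = strand, motif = motif,
             distinct_reads = rep_len(distinct_reads, length(keys)),
             genome_label = genome_label, stringsAsFactors = FALSE)
}
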