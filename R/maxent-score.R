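DONOR_REST_POS <- c(1:3, 6:9)    # 9-mer minus the consensus GT at +1,+2
ACC_REST_POS <- c(1:18, 21:23)   # 23-mer minus the consensus AG at -2,-1

check_site_seq <- function(seq, len, what) {
  if (!is.character(seq) || length(seq) != 1L) stop(what, " must be a single string")
  seq <- toupper(seq)
  if (nchar(seq) != len) {
    stop(what, " must be exactly ", len, " bases, got ", nchar(seq))
  }
  if (grepl("[^ACGT]", seq)) {
    stop(what, " contains a non-ACGT base (ambiguous bases are not scored)")
  }
  seq
}

bg_log2 <- function(models, seq) {
  sum(log2(models$bg[strsplit(seq, "")[[1]]]))
}

#' Score a 5' splice site (9-mer)
#'
#' Scores a donor site given as 3 exonic + 6 intronic bases.  The score is
#' \code{log2(P_model(seq) / P_background(seq))} in bits, where the model
#' factorises into consensus-position odds for the two first intronic bases
#' (the near-invariant GT) and a maximum-entropy distribution over the
#' remaining 7 positions.  Deterministic to machine precision.
#'
#' @param seq 9-mer over A/C/G/T (exon -3..-1, intron +1..+6), uppercase.
#' @param models from \code{\link{load_model_tables}} (default: bundled
#'   synthetic-trained tables).
#' @return score in bits (log2 odds); positive means stronger than
#'   background.
#' @export
score5 <- function(seq, models = load_model_tables()) {
  seq <- check_site_seq(seq, 9L, "5' site sequence")
  b <- strsplit(seq, "")[[1]]
  cons <- log2(models$donor$cons["4", b[4]] / models$bg[b[4]]) +
    log2(models$donor$cons["5", b[5]] / models$bg[b[5]])
  rest <- paste(b[DONOR_REST_POS], collapse = "")
  me <- models$donor$block$logp[kmer_index(rest)] / log(2)
  unname(cons + me - bg_log2(models, rest))
}

#' Score a 3' splice site (23-mer)
#'
#' Scores an acceptor site given as 20 intronic + 3 exonic bases.  The two
#' consensus positions (the AG at intron -2,-1) contribute odds factors;
#' the remaining 21 positions are scored by a maximum-entropy decomposition:
#' the product of five 7-mer block probabilities divided by the four
#' overlap-block probabilities, each relative to background.
#'
#' @param seq 23-mer over A/C/G/T (intron -20..-1, exon +1..+3), uppercase.
#' @param models from \code{\link{load_model_tables}}.
#' @return score in bits.
#' @export
score3 <- function(seq, models = load_model_tables()) {
  seq <- check_site_seq(seq, 23L, "3' site sequence")
  b <- strsplit(seq, "")[[1]]
  cons <- log2(models$acceptor$cons["19", b[19]] / models$bg[b[19]]) +
    log2(models$acceptor$cons["20", b[20]] / models$bg[b[20]])
  rest <- b[ACC_REST_POS]
  acc <- models$acceptor
  sc <- 0
  for (i in seq_along(ACC3_NUM_BLOCKS)) {
    blk <- ACC3_NUM_BLOCKS[[i]]
    kmer <- paste(rest[blk], collapse = "")
    sc <- sc + acc$num_lp[[i]][kmer_index(kmer)] / log(2) -
      bg_log2(models, kmer)
  }
  for (i in seq_along(ACC3_DEN_BLOCKS)) {
    blk <- ACC3_DEN_BLOCKS[[i]]
    kmer <- paste(rest[blk], collapse = "")
    sc <- sc - acc$den_lp[[i]][kmer_index(kmer)] / log(2) +
      bg_log2(models, kmer)
  }
  unname(cons + sc)
}

#' Scoring window of a junction end
#'
#' Extracts the splice-site scoring window around one end of a junction,
#' strand-aware and on the RNA sense strand: the 5' window is the last 3
#' exonic plus first 6 intronic bases (9-mer), the 3' window the last 20
#' intronic plus first 3 exonic bases (23-mer).  For a minus-strand
#' junction the window comes from the opposite genomic end and is
#' reverse-complemented.  A window crossing a contig edge is an error.
#'
#' @param junction one-row junction data.frame (chrom, intron_start,
#'   intron_end, strand).
#' @param side \code{"5prime"} or \code{"3prime"}.
#' @param genome \code{DNAStringSet}.
#' @return list of class \code{splice_site_window}: \code{seq},
#'   \code{chrom}, \code{g_start}, \code{g_end} (genomic window, always
#'   plus-strand coordinates), \code{strand}, \code{side}.
#' @export
site_window_from_junction <- function(junction, side, genome) {
  stopifnot(side %in% c("5prime", "3prime"))
  strand <- junction$strand
  if (!strand %in% c("+", "-")) {
    stop("junction strand must be '+' or '-' to extract a scoring window")
  }
  if (side == "5prime") {
    if (strand == "+") {
      g_start <- junction$intron_start - 3L; g_end <- junction$intron_start + 5L
    } else {
      g_start <- junction$intron_end - 5L; g_end <- junction$intron_end + 3L
    }
  } else {
    if (strand == "+") {
      g_start <- junction$intron_end - 19L; g_end <- junction$intron_end + 3L
    } else {
      g_start <- junction$intron_start - 3L; g_end <- junction$intron_start + 19L
    }
  }
  seq <- subseq_chr(genome, junction$chrom, g_start, g_end)
  if (strand == "-") seq <- revcomp_chr(seq)
  structure(list(seq = seq, chrom = junction$chrom, g_start = g_start,
                 g_end = g_end, strand = strand, side = side),
            class = "splice_site_window")
}

# internal: substitute one allele into a window, honouring strand
substitute_in_window <- function(window, pos, allele) {
  if (pos < window$g_start || pos > window$g_end) return(window)
  if (window$strand == "+") {
    i <- pos - window$g_start + 1L
    base <- allele
  } else {
    i <- window$g_end - pos + 1L
    base <- revcomp_chr(allele)
  }
  s <- window$seq
  substr(s, i, i) <- base
  window$seq <- s
  window$adjusted <- TRUE
  window
}

#' Splice-site score difference between a personal and a reference site
#'
#' Scores the personal site and the reference site with the same model and
#' returns their difference \code{delta = personal - reference}, so
#' \code{delta > 0} means the personal site is the stronger one.  When the
#' splice-site SNP position falls inside the reference site's scoring
#' window, the reference sequence is first modified to carry the personal
#' allele (\code{reference_adjusted_for_snp}): the comparison isolates the
#' choice of site, not the allele difference.
#'
#' @param personal_site,reference_site \code{splice_site_window}s of the
#'   same side (5prime or 3prime).
#' @param snp optional one-row variant (needs \code{pos} and the personal
#'   allele in \code{alt}); \code{NULL} to compare as-is.
#' @param models scoring models.
#' @return data.frame with \code{personal_score}, \code{reference_score},
#'   \code{delta}, \code{reference_adjusted_for_snp} (scores in bits).
#' @export
delta_ss_score <- function(personal_site, reference_site, snp = NULL,
                           models = load_model_tables()) {
  stopifnot(personal_site$side == reference_site$side)
  adjusted <- FALSE
  if (!is.null(snp) &&
      snp$pos >= reference_site$g_start && snp$pos <= reference_site$g_end) {
    reference_site <- substitute_in_window(reference_site, snp$pos, snp$alt)
    adjusted <- TRUE
  }
  scorer <- if (personal_site$side == "5prime") score5 else score3
  ps <- scorer(personal_site$seq, models)
  rs <- scorer(reference_site$seq, models)
  data.frame(personal_score = ps, reference_score = rs, delta = ps - rs,
             reference_adjusted_for_snp = adjusted,
             personal_seq = personal_site$seq,
             reference_seq = reference_site$seq,
             stringsAsFactors = FALSE)
}

#' Score the personal-specific junctions of a catalog
#'
#' For every personal-specific junction paired with exactly one reference
#' junction at a shared splice site (the alternative 5'/3' situation), the
#' personal site window is taken from the carrying haplotype genome and the
#' reference site window from the reference genome, SNP-adjusted when the
#' splice-site SNP lies inside it.
#'
#' @param usage usage table (\code{\link{usage_table}}), which records the
#'   paired reference junction via \code{offset}/\code{shared_site}.
#' @param catalog the filtered catalog (for SNP annotations).
#' @param ref_genome,hap1_genome,hap2_genome \code{DNAStringSet}s.
#' @param models scoring models.
#' @return usage table with score columns appended (NA where no unique
#'   paired reference junction exists).
#' @export
score_catalog <- function(usage, catalog, ref_genome, hap1_genome,
                          hap2_genome, models = load_model_tables()) {
  anns <- catalog$snp_annotations
  cols <- c("side", "personal_seq", "reference_seq", "personal_score",
            "reference_score", "delta", "reference_adjusted_for_snp")
  for (cl in cols) usage[[cl]] <- NA
  jtab <- catalog$junctions
  jk <- junction_key(jtab$chrom, jtab$intron_start, jtab$intron_end)
  ak <- if (!is.null(anns)) junction_key(anns$chrom, anns$intron_start,
                                         anns$intron_end) else character(0)
  for (i in seq_len(nrow(usage))) {
    if (is.na(usage$offset[i])) next
    key <- junction_key(usage$chrom[i], usage$intron_start[i],
                        usage$intron_end[i])
    jn <- jtab[match(key, jk), ]
    if (!jn$strand %in% c("+", "-")) next
    pg <- if (jn$category == "hap2_specific") hap2_genome else hap1_genome
    # which end moved determines which site is being compared
    moved_start <- usage$shared_site[i] == "end"
    side <- if ((jn$strand == "+") == moved_start) "5prime" else "3prime"
    ref_jn <- jn
    if (moved_start) {
      ref_jn$intron_start <- jn$intron_start - usage$offset[i]
    } else {
      ref_jn$intron_end <- jn$intron_end - usage$offset[i]
    }
    snp <- if (length(ak)) anns[match(key, ak), ] else NULL
    if (!is.null(snp) && is.na(snp$chrom[1])) snp <- NULL
    if (!is.null(snp)) snp <- data.frame(pos = snp$snp_pos, alt = snp$snp_alt)
    res <- tryCatch(
      delta_ss_score(site_window_from_junction(jn, side, pg),
                     site_window_from_junction(ref_jn, side, ref_genome),
                     snp, models),
      error = function(e) NULL)
    if (is.null(res)) next
    usage$side[i] <- side
    for (cl in cols[-1]) usage[[cl]][i] <- res[[cl]]
  }
  usage
}
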