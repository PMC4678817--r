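# Exact-match spliced toy aligner.
#
# Emulates the alignment contract the pipeline assumes from its production
# aligner, at desk scale and by brute force: a read aligns iff it matches the
# genome contiguously with zero mismatches, or across exactly one splice gap
# whose terminal dinucleotides form a canonical motif pair, with both anchors
# at least min_overhang bases and the gap within [min_intron, max_intron].
# Reads that cannot be fully explained are reported unmapped (the production
# aligner's truncation policy), as is either mate of a pair when the other
# mate fails.  Correctness over speed: its only job is to realise the mapping
# contract honestly on toy genomes.

CANONICAL_GAPS <- data.frame(
  donor = c("GT", "GC", "AT", "CT", "CT", "GT"),
  acceptor = c("AG", "AG", "AC", "AC", "GC", "AT"),
  stringsAsFactors = FALSE)

# internal: all exact-match spliced/contiguous alignments of one pattern
# (already oriented) against one chromosome; returns list of (pos, cigar)
align_pattern_chrom <- function(pat, chrom_seq, min_overhang, min_intron,
                                max_intron) {
  out <- list()
  L <- nchar(pat)
  patx <- Biostrings::DNAString(pat)
  contig <- Biostrings::start(Biostrings::matchPattern(patx, chrom_seq))
  for (p in contig) out[[length(out) + 1L]] <- list(pos = p,
                                                    cigar = paste0(L, "M"))
  # spliced: seed with the first min_overhang bases, extend, then try every
  # admissible split point at a canonical donor dinucleotide
  seed <- Biostrings::subseq(patx, 1L, min_overhang)
  seeds <- Biostrings::start(Biostrings::matchPattern(seed, chrom_seq))
  glen <- length(chrom_seq)
  pat_chars <- strsplit(pat, "")[[1]]
  for (p in seeds) {
    max_ext <- min(L, glen - p + 1L)
    gsub_chars <- strsplit(as.character(
      Biostrings::subseq(chrom_seq, p, p + max_ext - 1L)), "")[[1]]
    mism <- which(pat_chars[seq_len(max_ext)] != gsub_chars)
    ext <- if (length(mism)) mism[1] - 1L else max_ext
    if (ext >= L) next  # contiguous hit, already recorded
    for (k in seq.int(min_overhang, min(ext, L - min_overhang))) {
      dpos <- p + k
      if (dpos + 1L > glen) break
      donor <- as.character(Biostrings::subseq(chrom_seq, dpos, dpos + 1L))
      rows <- CANONICAL_GAPS[CANONICAL_GAPS$donor == donor, , drop = FALSE]
      if (nrow(rows) == 0L) next
      rest <- Biostrings::subseq(patx, k + 1L, L)
      win_lo <- dpos + min_intron
      win_hi <- min(glen, dpos + max_intron + (L - k))
      if (win_lo > win_hi) next
      occ <- Biostrings::start(Biostrings::matchPattern(
        rest, Biostrings::subseq(chrom_seq, win_lo, win_hi))) + win_lo - 1L
      for (o in occ) {
        ilen <- o - dpos
        if (ilen < min_intron || ilen > max_intron) next
        acceptor <- as.character(Biostrings::subseq(chrom_seq, o - 2L, o - 1L))
        if (!any(rows$acceptor == acceptor)) next
        out[[length(out) + 1L]] <- list(
          pos = p, cigar = paste0(k, "M", ilen, "N", L - k, "M"))
      }
    }
  }
  out
}

#' Align reads to a toy genome under the strict spliced-alignment contract
#'
#' Exact-match (zero mismatches) alignment of single reads or read pairs,
#' allowing at most one splice gap with canonical terminal dinucleotide
#' motifs (GT-AG, GC-AG, AT-AC on either strand) and \code{min_overhang}
#' anchors.  A read with no admissible alignment, or with more than
#' \code{max_hits} of them, is unmapped; with the pair policy on, an
#' unmapped mate makes the whole pair unmapped.
#'
#' @param reads data.frame with \code{read_id}, \code{seq} and optionally
#'   \code{mate} (1/2; mates share \code{read_id}).
#' @param genome \code{DNAStringSet}.
#' @param min_overhang,max_intron,min_intron,max_hits alignment contract
#'   parameters (defaults 12, 300000, 20, 20).
#' @param paired_policy drag pairs down when a mate fails (default TRUE).
#' @return alignment data.frame in the layout of
#'   \code{\link{read_alignments}} (one row per alignment, or one unmapped
#'   row per read).
#' @export
align_reads <- function(reads, genome, min_overhang = 12L,
                        max_intron = 300000L, min_intron = 20L,
                        max_hits = 20L, paired_policy = TRUE) {
  if (is.null(reads$mate)) reads$mate <- 1L
  paired <- any(reads$mate == 2L)
  recs <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    seq <- toupper(reads$seq[i])
    hits <- list()
    for (ori in c(0L, 16L)) {
      pat <- if (ori == 0L) seq else revcomp_chr(seq)
      for (chrom in names(genome)) {
        h <- align_pattern_chrom(pat, genome[[chrom]], min_overhang,
                                 min_intron, max_intron)
        for (x in h) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, pos = x$pos, cigar = x$cigar, rev = ori,
            stringsAsFactors = FALSE)
        }
      }
    }
    hits <- if (length(hits)) unique(do.call(rbind, hits)) else NULL
    base_flag <- if (paired) {
      1L + if (reads$mate[i] == 1L) 64L else 128L
    } else 0L
    if (is.null(hits) || nrow(hits) > max_hits) {
      recs[[i]] <- data.frame(
        read_id = reads$read_id[i], flag = base_flag + 4L,
        chrom = NA_character_, pos = NA_integer_, cigar = NA_character_,
        paired = paired, flag_unmapped = TRUE, mate_unmapped = FALSE,
        stringsAsFactors = FALSE)
    } else {
      recs[[i]] <- data.frame(
        read_id = reads$read_id[i], flag = base_flag + hits$rev,
        chrom = hits$chrom, pos = hits$pos, cigar = hits$cigar,
        paired = paired, flag_unmapped = FALSE, mate_unmapped = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  aln <- do.call(rbind, recs)
  if (paired && paired_policy) {
    bad <- tapply(aln$flag_unmapped, aln$read_id, any)
    drag <- as.vector(bad[aln$read_id]) & !aln$flag_unmapped
    if (any(drag)) {
      aln$flag[drag] <- bitwAnd(aln$flag[drag], bitwNot(16L)) + 4L
      aln$flag_unmapped[drag] <- TRUE
      aln$chrom[drag] <- NA_character_
      aln$pos[drag] <- NA_integer_
      aln$cigar[drag] <- NA_character_
      aln <- aln[!duplicated(aln[, c("read_id", "flag", "chrom", "pos",
                                     "cigar")]), , drop = FALSE]
    }
    mate_bad <- as.vector(bad[aln$read_id])
    aln$mate_unmapped <- mate_bad & !aln$flag_unmapped
    aln$flag <- aln$flag + ifelse(aln$mate_unmapped, 8L, 0L)
  }
  rownames(aln) <- NULL
  aln
}

#' Write alignments as SAM
#'
#' @param alignments data.frame from \code{\link{align_reads}}.
#' @param genome \code{DNAStringSet} (for the header's sequence dictionary).
#' @param path output SAM path.
#' @export
write_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  Biostrings::width(genome)))
  recs <- with(alignments, paste(
    read_id, flag,
    ifelse(is.na(chrom), "*", chrom),
    ifelse(is.na(pos), 0L, pos), 255L,
    ifelse(is.na(cigar), "*", cigar),
    "*", 0L, 0L, "*", "*", sep = "\t"))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
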