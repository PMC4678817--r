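#' Read spliced alignments from SAM or BAM
#'
#' Loads all alignment records (mapped and unmapped) into a plain data.frame
#' used by the downstream junction operations.  SAM input is converted to BAM
#' on the fly via Rsamtools.
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns \code{read_id}, \code{flag}, \code{chrom},
#'   \code{pos}, \code{cigar}, \code{paired}, \code{flag_unmapped},
#'   \code{mate_unmapped}.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, indexDestination = FALSE,
                             overwrite = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  data.frame(
    read_id = b$qname,
    flag = b$flag,
    chrom = as.character(b$rname),
    pos = b$pos,
    cigar = b$cigar,
    paired = bitwAnd(b$flag, 0x1L) != 0L,
    flag_unmapped = bitwAnd(b$flag, 0x4L) != 0L,
    mate_unmapped = bitwAnd(b$flag, 0x8L) != 0L,
    stringsAsFactors = FALSE
  )
}

#' Classify alignment records as mapped or unmapped under the truncation policy
#'
#' A record counts as unmapped when its SAM unmapped flag is set, when its
#' soft/hard-clipped length exceeds \code{max_clip} (the aligner "truncates"
#' a read it cannot extend; with the default \code{max_clip = 0} any clipping
#' means truncated), or -- when \code{paired_policy} is on -- when its mate is
#' unmapped or truncated.
#'
#' @param records data.frame from \code{\link{read_alignments}}.
#' @param max_clip maximum tolerated clipped bases (default 0).
#' @param paired_policy if TRUE, a truncated/unmapped mate drags the whole
#'   pair down to unmapped.
#' @return logical vector: TRUE where the record counts as mapped.
#' @export
classify_read_mapping <- function(records, max_clip = 0L, paired_policy = TRUE) {
  clipped <- integer(nrow(records))
  has_cig <- !is.na(records$cigar) & records$cigar != "*"
  if (any(has_cig)) {
    lens <- GenomicAlignments::explodeCigarOpLengths(
      records$cigar[has_cig], ops = c("S", "H"))
    clipped[has_cig] <- vapply(lens, sum, integer(1))
  }
  ok <- !records$flag_unmapped & clipped <= max_clip
  if (paired_policy && any(records$paired)) {
    pair_ok <- tapply(ok, records$read_id, all)
    ok <- ok & (!records$paired | as.vector(pair_ok[records$read_id]))
  }
  ok
}

#' Intron intervals spanned by one alignment
#'
#' Walks a CIGAR string in reference coordinates and returns one interval per
#' \code{N} (skipped region) operation: the 1-based positions of the first
#' and last intronic base.
#'
#' @param pos 1-based leftmost aligned position.
#' @param cigar CIGAR string.
#' @return data.frame with columns \code{intron_start}, \code{intron_end}
#'   (zero rows for an unspliced alignment).
#' @examples
#' junctions_from_cigar(100, "50M200N50M")   # intron 150..349
#' @export
junctions_from_cigar <- function(pos, cigar) {
  r <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = "N")[[1]]
  data.frame(intron_start = BiocGenerics::start(r),
             intron_end = BiocGenerics::end(r))
}

# internal: per-alignment junction table with flanking aligned-block lengths.
# Aligned anchors count M/=/X reference bases of the segment adjacent to each
# intron (the overhang the aligner guarantees on each side of a junction).
alignment_junctions <- function(records) {
  has <- grepl("N", records$cigar, fixed = TRUE)
  if (!any(has)) {
    return(data.frame(chrom = character(), pos = integer(),
                      intron_start = integer(), intron_end = integer(),
                      left_anchor = integer(), right_anchor = integer()))
  }
  idx <- which(has)
  ops_l <- GenomicAlignments::explodeCigarOps(records$cigar[idx])
  len_l <- GenomicAlignments::explodeCigarOpLengths(records$cigar[idx])
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    ops <- ops_l[[k]]; lens <- len_l[[k]]
    cur <- records$pos[idx[k]]
    seg_aligned <- 0L
    anchors <- integer(0)          # aligned length of each inter-intron segment
    introns <- matrix(0L, nrow = 0, ncol = 2)
    for (j in seq_along(ops)) {
      op <- ops[j]; ln <- lens[j]
      if (op == "N") {
        anchors <- c(anchors, seg_aligned)
        introns <- rbind(introns, c(cur, cur + ln - 1L))
        seg_aligned <- 0L
        cur <- cur + ln
      } else if (op %in% c("M", "=", "X")) {
        seg_aligned <- seg_aligned + ln
        cur <- cur + ln
      } else if (op == "D") {
        cur <- cur + ln
      }
      # I, S, H consume no reference
    }
    anchors <- c(anchors, seg_aligned)
    nj <- nrow(introns)
    out[[k]] <- data.frame(
      chrom = records$chrom[idx[k]], pos = records$pos[idx[k]],
      intron_start = introns[, 1], intron_end = introns[, 2],
      left_anchor = anchors[seq_len(nj)], right_anchor = anchors[-1][seq_len(nj)])
  }
  do.call(rbind, out)
}

# internal: classify an intron's terminal dinucleotides into a motif class
# and an inferred strand.  Plus-strand canonical pairs are GT-AG, GC-AG,
# AT-AC; their reverse complements seen on the forward genome strand are
# CT-AC, CT-GC, GT-AT and imply the minus strand.
motif_from_dinucs <- function(d5, d3) {
  plus <- c("GT AG" = "GT-AG", "GC AG" = "GC-AG", "AT AC" = "AT-AC")
  minus <- c("CT AC" = "GT-AG", "CT GC" = "GC-AG", "GT AT" = "AT-AC")
  key <- paste(d5, d3)
  on_plus <- key %in% names(plus)
  on_minus <- key %in% names(minus)
  motif <- ifelse(on_plus, plus[key], ifelse(on_minus, minus[key],
                                             "non-canonical"))
  strand <- ifelse(on_plus, "+", ifelse(on_minus, "-", "*"))
  # both-strand canonical matches are impossible for exact canonical classes,
  # but the resolution rule (plus wins, flagged) is kept for safety
  ambiguous <- on_plus & on_minus
  strand[ambiguous] <- "+"
  data.frame(motif = unname(motif), strand = unname(strand),
             ambiguous = ambiguous)
}

#' Collect the splice-junction set of one alignment run
#'
#' Aggregates spliced alignments into junctions with distinct-read support.
#' A read supports a junction only if the aligned block on each side of that
#' junction is at least \code{min_overhang} bases.  Support is counted as the
#' number of *distinct leftmost alignment positions* among supporting reads,
#' which deduplicates amplification stacks.  The splice-site motif is read
#' from the genome the reads were aligned to (\code{genome_label} names it)
#' and determines the inferred strand.
#'
#' @param records alignment data.frame (\code{\link{read_alignments}}),
#'   already restricted to mapped records (see
#'   \code{\link{classify_read_mapping}}).
#' @param genome \code{DNAStringSet} of the genome the alignments refer to.
#' @param genome_label one of \code{"hg19"}, \code{"hap1"}, \code{"hap2"}
#'   (free-form labels allowed).
#' @param min_overhang minimum aligned bases flanking the junction (12).
#' @param max_intron maximum intron length (300000); longer gaps dropped.
#' @param min_intron minimum intron length (20); shorter gaps are treated as
#'   deletions, not junctions.
#' @return data.frame with columns \code{chrom}, \code{intron_start},
#'   \code{intron_end}, \code{strand}, \code{motif}, \code{distinct_reads},
#'   \code{genome_label}.
#' @export
collect_junction_set <- function(records, genome, genome_label,
                                 min_overhang = 12L, max_intron = 300000L,
                                 min_intron = 20L) {
  jt <- alignment_junctions(records)
  empty <- data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      motif = character(), distinct_reads = integer(),
                      genome_label = character(), stringsAsFactors = FALSE)
  if (nrow(jt) == 0L) return(empty)
  ilen <- jt$intron_end - jt$intron_start + 1L
  jt <- jt[jt$left_anchor >= min_overhang & jt$right_anchor >= min_overhang &
             ilen <= max_intron & ilen >= min_intron, , drop = FALSE]
  if (nrow(jt) == 0L) return(empty)

  missing_chrom <- setdiff(unique(jt$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  }
  key <- junction_key(jt$chrom, jt$intron_start, jt$intron_end)
  distinct <- tapply(jt$pos, key, function(p) length(unique(p)))
  uniq <- jt[!duplicated(key), c("chrom", "intron_start", "intron_end")]
  ukey <- junction_key(uniq$chrom, uniq$intron_start, uniq$intron_end)

  d5 <- character(nrow(uniq)); d3 <- character(nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    d5[i] <- subseq_chr(genome, uniq$chrom[i], uniq$intron_start[i],
                        uniq$intron_start[i] + 1L)
    d3[i] <- subseq_chr(genome, uniq$chrom[i], uniq$intron_end[i] - 1L,
                        uniq$intron_end[i])
  }
  mot <- motif_from_dinucs(d5, d3)
  out <- data.frame(chrom = uniq$chrom, intron_start = uniq$intron_start,
                    intron_end = uniq$intron_end, strand = mot$strand,
                    motif = mot$motif,
                    distinct_reads = as.integer(distinct[ukey]),
                    genome_label = genome_label, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$intron_start, out$intron_end), ]
  rownames(out) <- NULL
  out
}

#' Write a junction set as TSV
#' @param junctions junction data.frame from \code{\link{collect_junction_set}}.
#' @param path output file.
#' @export
write_junction_tsv <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
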