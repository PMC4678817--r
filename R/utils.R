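#' @import methods
#' @importFrom stats setNames
NULL

# internal: canonical junction identity key (coordinates only, never strand/motif --
# the same coordinates can receive different motif calls on reference vs personal
# genomes, which is exactly the phenomenon under study)
junction_key <- function(chrom, intron_start, intron_end) {
  paste0(chrom, ":", intron_start, "-", intron_end)
}

# internal: reconcile "chr" prefix differences between two sets of sequence names.
# Any mismatch beyond the prefix is an error.
reconcile_chrom <- function(query, target_names) {
  out <- query
  miss <- !(out %in% target_names)
  if (any(miss)) {
    flipped <- ifelse(grepl("^chr", out[miss]), sub("^chr", "", out[miss]),
                      paste0("chr", out[miss]))
    ok <- flipped %in% target_names
    if (any(ok)) {
      message("reconciled 'chr' prefix for ", sum(ok), " chromosome name(s)")
      out[miss][ok] <- flipped[ok]
    }
    still <- !(out %in% target_names)
    if (any(still)) {
      stop("chromosome name(s) not present in genome: ",
           paste(unique(query[still]), collapse = ", "))
    }
  }
  out
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

subseq_chr <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome absent from genome: ", chrom)
  sq <- genome[[chrom]]
  if (start < 1L || end > length(sq)) {
    stop("window [", start, ",", end, "] crosses the edge of contig ", chrom)
  }
  toupper(as.character(Biostrings::subseq(sq, start, end)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
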