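#' Distinct-read count over overlapping annotated junctions
#'
#' For one personal junction, finds every annotated intron whose interval
#' overlaps the personal intron by at least one base, and sums the
#' distinct-read counts those annotated junctions have *in the junction set
#' of the same genome* where the personal junction was identified.  The
#' personal junction itself is excluded even if it happens to be annotated.
#'
#' @param junction one-row junction data.frame.
#' @param annotation_introns annotated introns
#'   (\code{\link{annotation_introns_from_gtf}}).
#' @param junction_set the junction set of the genome where the personal
#'   junction was identified.
#' @return list with \code{osj_reads} (integer) and \code{overlapping}
#'   (data.frame of the overlapping annotated junctions that are expressed,
#'   with their read counts).
#' @export
overlapping_annotated_reads <- function(junction, annotation_introns,
                                        junction_set) {
  self_key <- junction_key(junction$chrom, junction$intron_start,
                           junction$intron_end)
  ai <- annotation_introns[annotation_introns$chrom == junction$chrom, ,
                           drop = FALSE]
  ov <- ai[ai$intron_start <= junction$intron_end &
             ai$intron_end >= junction$intron_start, , drop = FALSE]
  ov <- ov[junction_key(ov$chrom, ov$intron_start, ov$intron_end) != self_key, ,
           drop = FALSE]
  if (nrow(ov) == 0L || nrow(junction_set) == 0L) {
    return(list(osj_reads = 0L, overlapping = ov[0, , drop = FALSE]))
  }
  sk <- junction_key(junction_set$chrom, junction_set$intron_start,
                     junction_set$intron_end)
  m <- match(junction_key(ov$chrom, ov$intron_start, ov$intron_end), sk)
  ov$distinct_reads <- junction_set$distinct_reads[m]
  expressed <- ov[!is.na(ov$distinct_reads) & ov$distinct_reads >= 1L, ,
                  drop = FALSE]
  rownames(expressed) <- NULL
  list(osj_reads = as.integer(sum(expressed$distinct_reads)),
       overlapping = expressed)
}

#' Relative usage frequency of a personal splice junction
#'
#' \code{psj / (psj + osj)}: the fraction of distinct junction-spanning
#' reads that use the personal junction rather than any overlapping
#' annotated junction.  Undefined (NA) when both counts are zero.
#'
#' @param psj_reads distinct-read count of the personal junction.
#' @param osj_reads summed distinct-read count of overlapping annotated
#'   junctions.
#' @return usage in [0, 1], or NA.
#' @examples
#' relative_usage(13, 7)  # 0.65
#' @export
relative_usage <- function(psj_reads, osj_reads) {
  stopifnot(all(psj_reads >= 0), all(osj_reads >= 0))
  tot <- psj_reads + osj_reads
  ifelse(tot == 0, NA_real_, psj_reads / tot)
}

#' Offset between two junctions sharing exactly one splice site
#'
#' For a personal junction and a reference junction forming an alternative
#' 5' or 3' splice-site pair (same chrom, one boundary equal, the other
#' different), returns the signed distance between the alternative splice
#' sites (personal minus reference coordinate at the non-shared boundary)
#' and which boundary is shared.  Junctions that share both or neither
#' boundary return NULL.
#'
#' @param personal,reference one-row junction data.frames.
#' @return list with \code{offset} and \code{shared} ("start" or "end"),
#'   or NULL.
#' @export
shared_site_offset <- function(personal, reference) {
  if (personal$chrom != reference$chrom) return(NULL)
  same_start <- personal$intron_start == reference$intron_start
  same_end <- personal$intron_end == reference$intron_end
  if (same_start == same_end) return(NULL)
  if (same_start) {
    list(offset = personal$intron_end - reference$intron_end, shared = "start")
  } else {
    list(offset = personal$intron_start - reference$intron_start,
         shared = "end")
  }
}

#' Is an alternative splice-site pair potentially frame-shifting?
#'
#' TRUE when the distance between the personal and reference splice sites is
#' not an exact multiple of three nucleotides, so use of the personal site
#' changes the reading frame of the downstream coding sequence.
#'
#' @param offset distance between the alternative splice sites (nt), as from
#'   \code{\link{shared_site_offset}}; may be signed.
#' @return logical.
#' @examples
#' frameshift_predicate(5)   # TRUE
#' frameshift_predicate(3)   # FALSE (NAGNAG-style single-codon difference)
#' frameshift_predicate(1)   # TRUE
#' @export
frameshift_predicate <- function(offset) {
  abs(offset) %% 3L != 0L
}

#' Usage table for the personal-specific junctions of one catalog
#'
#' Computes PSJ, OSJ and the relative usage frequency of every
#' personal-specific junction, counting in the junction set of the genome
#' where the junction was identified (hap1 for hap1- and hap1hap2-specific,
#' hap2 for hap2-specific).  Also records how many expressed annotated
#' junctions overlap, and -- when exactly one overlapping junction shares
#' exactly one splice site -- the alternative-splice-site offset and the
#' frame-shift call.
#'
#' @param catalog a filtered \code{psj_catalog} (with
#'   \code{snp_annotations}).
#' @param annotation_introns annotated introns.
#' @param hap1_set,hap2_set junction sets of the two haplotype alignments.
#' @return data.frame, one row per personal-specific junction.
#' @export
usage_table <- function(catalog, annotation_introns, hap1_set, hap2_set) {
  ps <- personal_specific(catalog)
  out <- vector("list", nrow(ps))
  for (i in seq_len(nrow(ps))) {
    jn <- ps[i, ]
    set <- if (jn$category == "hap2_specific") hap2_set else hap1_set
    psj <- if (jn$category == "hap2_specific") jn$dr_hap2 else jn$dr_hap1
    if (is.na(psj)) psj <- jn$distinct_reads
    ov <- overlapping_annotated_reads(jn, annotation_introns, set)
    # the alternative-site geometry is defined by the annotation; expression
    # of the partner junction only gates the usage-eligibility filter
    ai <- annotation_introns[annotation_introns$chrom == jn$chrom &
                               annotation_introns$intron_start <= jn$intron_end &
                               annotation_introns$intron_end >= jn$intron_start, ,
                             drop = FALSE]
    ai <- ai[junction_key(ai$chrom, ai$intron_start, ai$intron_end) !=
               junction_key(jn$chrom, jn$intron_start, jn$intron_end), ,
             drop = FALSE]
    offset <- NA_integer_; shared <- NA_character_; fs <- NA
    if (nrow(ai) == 1L) {
      so <- shared_site_offset(jn, ai[1, ])
      if (!is.null(so)) {
        offset <- so$offset; shared <- so$shared
        fs <- frameshift_predicate(so$offset)
      }
    }
    out[[i]] <- data.frame(
      sample = catalog$sample_id, chrom = jn$chrom,
      intron_start = jn$intron_start, intron_end = jn$intron_end,
      category = jn$category, psj_reads = psj, osj_reads = ov$osj_reads,
      usage = relative_usage(psj, ov$osj_reads),
      n_overlapping = nrow(ov$overlapping), offset = offset,
      shared_site = shared, frameshift = fs, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(sample = character(), chrom = character(),
                      intron_start = integer(), intron_end = integer(),
                      category = character(), psj_reads = integer(),
                      osj_reads = integer(), usage = numeric(),
                      n_overlapping = integer(), offset = integer(),
                      shared_site = character(), frameshift = logical()))
  }
  do.call(rbind, out)
}

#' Alternative-splice-site subset for usage-vs-strength comparisons
#'
#' Restricts a usage table to the instances where usage estimates are
#' interpretable: (a) the personal junction forms an alternative 5' or 3'
#' splice-site pair with *exactly one* expressed overlapping reference
#' junction; (b) the combined distinct-read count is at least
#' \code{min_combined_reads}; (c) the individual is homozygous for the
#' splice-site SNP (usage in a heterozygote is confounded by the
#' non-carrier haplotype).
#'
#' @param usage usage table from \code{\link{usage_table}}.
#' @param snp_annotations the catalog's \code{snp_annotations} (carries the
#'   genotype of the splice-site SNP).
#' @param min_combined_reads minimum \code{psj + osj} (default 10).
#' @return the filtered usage table, with the genotype attached.
#' @export
alt_ss_subset <- function(usage, snp_annotations, min_combined_reads = 10L) {
  if (nrow(usage) == 0L) return(cbind(usage, gt = character(0)))
  ak <- junction_key(snp_annotations$chrom, snp_annotations$intron_start,
                     snp_annotations$intron_end)
  uk <- junction_key(usage$chrom, usage$intron_start, usage$intron_end)
  usage$gt <- snp_annotations$gt[match(uk, ak)]
  hom <- !is.na(usage$gt) &
    vapply(strsplit(usage$gt, "|", fixed = TRUE),
           function(p) length(unique(p)) == 1L, logical(1))
  keep <- usage$n_overlapping == 1L & !is.na(usage$offset) &
    (usage$psj_reads + usage$osj_reads) >= min_combined_reads & hom
  out <- usage[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detection frequency of personal junctions among SNP carriers
#'
#' Across a cohort of per-sample catalogs, computes for every personal
#' junction the fraction of splice-site-SNP carriers (individuals with at
#' least one alt allele) in whom the junction was detected.
#'
#' @param catalogs named list of filtered \code{psj_catalog}s (names are
#'   sample ids).
#' @param genotypes data.frame with \code{sample}, \code{snp_id},
#'   \code{n_alt} (0/1/2) covering the cohort; a junction whose SNP has no
#'   genotyped carriers is suppressed with a warning.
#' @return data.frame with one row per junction: \code{snp_id},
#'   \code{n_carriers}, \code{n_detected}, \code{detection_frequency}.
#' @export
detection_frequency <- function(catalogs, genotypes) {
  anns <- lapply(names(catalogs), function(s) {
    a <- catalogs[[s]]$snp_annotations
    if (is.null(a)) return(NULL)
    cbind(sample = s, a)
  })
  anns <- do.call(rbind, anns)
  if (is.null(anns) || nrow(anns) == 0L) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), snp_id = character(),
                      n_carriers = integer(), n_detected = integer(),
                      detection_frequency = numeric()))
  }
  key <- junction_key(anns$chrom, anns$intron_start, anns$intron_end)
  out <- list()
  for (k in unique(key)) {
    rows <- anns[key == k, , drop = FALSE]
    snp <- rows$snp_id[1]
    carriers <- unique(genotypes$sample[genotypes$snp_id == snp &
                                          genotypes$n_alt >= 1L])
    detected <- unique(rows$sample)
    if (length(carriers) == 0L) {
      warning("junction ", k, " (SNP ", snp,
              ") has no genotyped carriers; record suppressed")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = rows$chrom[1], intron_start = rows$intron_start[1],
      intron_end = rows$intron_end[1], snp_id = snp,
      n_carriers = length(carriers),
      n_detected = length(intersect(detected, carriers)),
      detection_frequency =
        length(intersect(detected, carriers)) / length(carriers),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), snp_id = character(),
                      n_carriers = integer(), n_detected = integer(),
                      detection_frequency = numeric()))
  }
  do.call(rbind, out)
}

#' Cohort-level usage summary
#'
#' Per junction, the unweighted mean and standard deviation of the relative
#' usage frequency over the individuals in whom the junction was detected,
#' plus the number of such individuals.
#'
#' @param usage_tables list of per-sample usage tables.
#' @return data.frame with \code{mean_usage}, \code{sd_usage},
#'   \code{n_individuals} per junction.
#' @export
cohort_usage_summary <- function(usage_tables) {
  u <- do.call(rbind, usage_tables)
  if (is.null(u) || nrow(u) == 0L) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), mean_usage = numeric(),
                      sd_usage = numeric(), n_individuals = integer()))
  }
  key <- junction_key(u$chrom, u$intron_start, u$intron_end)
  agg <- lapply(split(u, key), function(g) {
    data.frame(chrom = g$chrom[1], intron_start = g$intron_start[1],
               intron_end = g$intron_end[1],
               mean_usage = mean(g$usage, na.rm = TRUE),
               sd_usage = if (sum(!is.na(g$usage)) > 1L)
                 stats::sd(g$usage, na.rm = TRUE) else 0,
               n_individuals = length(unique(g$sample)))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
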