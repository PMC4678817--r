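#' Three-way junction-set comparison
#'
#' Assigns every junction observed in any of the three alignment runs
#' (reference, hap1, hap2) to exactly one category.  Junction identity is
#' the coordinate triple (chrom, intron_start, intron_end) only -- never
#' strand or motif, because the same coordinates can receive different motif
#' calls on the reference versus a personal genome.
#'
#' Categories: \code{hap1_specific} (hap1 only), \code{hap2_specific}
#' (hap2 only), \code{hap1hap2_specific} (both haplotypes, absent from the
#' reference run), \code{hg19_specific} (reference run only) and
#' \code{shared} (present in the reference run and at least one haplotype).
#' Personal-specific = hap1 + hap2 + hap1hap2 specific.
#'
#' @param ref_set,hap1_set,hap2_set junction data.frames from
#'   \code{\link{collect_junction_set}} over the same read set aligned to
#'   the three genomes.
#' @param sample_id sample label carried into the catalog.
#' @return An object of class \code{psj_catalog}: list with
#'   \code{junctions} (one row per junction in the union, with per-genome
#'   distinct-read counts \code{dr_ref}, \code{dr_hap1}, \code{dr_hap2},
#'   the consolidated \code{distinct_reads} -- the maximum over the runs in
#'   which the junction was seen -- \code{strand}, \code{motif_personal},
#'   \code{motif_reference} and \code{category}) and \code{sample_id}.
#' @export
classify_specific_junctions <- function(ref_set, hap1_set, hap2_set,
                                        sample_id = "sample") {
  sets <- list(ref = ref_set, hap1 = hap1_set, hap2 = hap2_set)
  keys <- lapply(sets, function(s) {
    if (nrow(s) == 0L) character(0)
    else junction_key(s$chrom, s$intron_start, s$intron_end)
  })
  all_keys <- unique(unlist(keys))

  lookup <- function(s, k, col) {
    if (nrow(s) == 0L) return(rep(NA, length(k)))
    sk <- junction_key(s$chrom, s$intron_start, s$intron_end)
    s[[col]][match(k, sk)]
  }
  in_ref <- all_keys %in% keys$ref
  in_h1 <- all_keys %in% keys$hap1
  in_h2 <- all_keys %in% keys$hap2
  category <- ifelse(in_ref & !(in_h1 | in_h2), "hg19_specific",
              ifelse(in_ref, "shared",
              ifelse(in_h1 & in_h2, "hap1hap2_specific",
              ifelse(in_h1, "hap1_specific", "hap2_specific"))))

  parts <- do.call(rbind, strsplit(all_keys, "[:-]"))
  dr_ref <- lookup(sets$ref, all_keys, "distinct_reads")
  dr_h1 <- lookup(sets$hap1, all_keys, "distinct_reads")
  dr_h2 <- lookup(sets$hap2, all_keys, "distinct_reads")
  # consolidated support: the genome(s) where the junction was actually seen
  distinct_reads <- pmax(ifelse(is.na(dr_ref), 0L, dr_ref),
                         ifelse(is.na(dr_h1), 0L, dr_h1),
                         ifelse(is.na(dr_h2), 0L, dr_h2))
  strand_personal <- ifelse(!is.na(lookup(sets$hap1, all_keys, "strand")),
                            lookup(sets$hap1, all_keys, "strand"),
                            lookup(sets$hap2, all_keys, "strand"))
  motif_personal <- ifelse(!is.na(lookup(sets$hap1, all_keys, "motif")),
                           lookup(sets$hap1, all_keys, "motif"),
                           lookup(sets$hap2, all_keys, "motif"))
  junctions <- data.frame(
    chrom = parts[, 1],
    intron_start = as.integer(parts[, 2]),
    intron_end = as.integer(parts[, 3]),
    strand = ifelse(is.na(strand_personal),
                    lookup(sets$ref, all_keys, "strand"), strand_personal),
    motif_personal = motif_personal,
    motif_reference = lookup(sets$ref, all_keys, "motif"),
    category = category,
    dr_ref = dr_ref, dr_hap1 = dr_h1, dr_hap2 = dr_h2,
    distinct_reads = distinct_reads,
    stringsAsFactors = FALSE
  )
  junctions <- junctions[order(junctions$chrom, junctions$intron_start,
                               junctions$intron_end), ]
  rownames(junctions) <- NULL
  structure(list(junctions = junctions, sample_id = sample_id),
            class = "psj_catalog")
}

PERSONAL_CATEGORIES <- c("hap1_specific", "hap2_specific", "hap1hap2_specific")

#' Personal-specific junctions of a catalog
#' @param catalog a \code{psj_catalog}.
#' @return data.frame subset of the catalog's junction table.
#' @export
personal_specific <- function(catalog) {
  catalog$junctions[catalog$junctions$category %in% PERSONAL_CATEGORIES, ,
                    drop = FALSE]
}

#' Remove weakly supported personal-specific junctions
#'
#' Personal-specific junctions supported by fewer than \code{min_distinct}
#' distinct-start reads are dropped from the catalog (other categories are
#' untouched).
#'
#' @param catalog a \code{psj_catalog}.
#' @param min_distinct minimum distinct-read support (default 2).
#' @return the filtered catalog.
#' @export
filter_min_support <- function(catalog, min_distinct = 2L) {
  j <- catalog$junctions
  drop <- j$category %in% PERSONAL_CATEGORIES & j$distinct_reads < min_distinct
  if (any(drop)) {
    message(sum(drop), " personal-specific junction(s) below ", min_distinct,
            " distinct reads removed (", sum(!drop), " rows retained)")
  }
  catalog$junctions <- j[!drop, , drop = FALSE]
  rownames(catalog$junctions) <- NULL
  catalog
}

# internal: strand-aware splice-site dinucleotide positions of a junction.
# On '+' the donor is the first two intronic bases and the acceptor the last
# two; on '-' the roles swap ends.  Unknown strand checks all four positions
# under both interpretations.
splice_site_positions <- function(intron_start, intron_end, strand) {
  don_plus <- c(intron_start, intron_start + 1L)
  acc_plus <- c(intron_end - 1L, intron_end)
  if (strand == "+") {
    list(donor = don_plus, acceptor = acc_plus)
  } else if (strand == "-") {
    list(donor = acc_plus, acceptor = don_plus)
  } else {
    list(donor = don_plus, acceptor = acc_plus, unknown_strand = TRUE)
  }
}

#' Annotate the splice-site SNP of one junction
#'
#' Searches the sample's phased SNVs for one falling inside the junction's
#' splice-site dinucleotides (donor: first two intronic bases; acceptor:
#' last two; strand-aware).  When found, reports the reference and personal
#' dinucleotides at that site, whether the personal allele completes a
#' canonical motif that the reference lacks (\code{creates_canonical}), and
#' whether the same SNP corrupts a canonical site that an annotated
#' reference junction uses (\code{disrupts_reference_site}; requires
#' \code{annotation_introns}).
#'
#' @param junction one-row data.frame with \code{chrom}, \code{intron_start},
#'   \code{intron_end}, \code{strand}.
#' @param variants phased-variant data.frame (see
#'   \code{\link{load_phased_snps}}).
#' @param ref_genome,personal_genome \code{DNAStringSet}s.
#' @param annotation_introns optional annotated-intron data.frame (see
#'   \code{\link{annotation_introns_from_gtf}}) used for the disruption flag.
#' @return one-row data.frame annotation, or \code{NULL} when no SNP touches
#'   the splice-site dinucleotides.
#' @export
annotate_splice_site_snp <- function(junction, variants, ref_genome,
                                     personal_genome,
                                     annotation_introns = NULL) {
  v <- variants[variants$chrom == junction$chrom, , drop = FALSE]
  if (nrow(v) == 0L) return(NULL)
  sites <- splice_site_positions(junction$intron_start, junction$intron_end,
                                 junction$strand)
  for (site in c("donor", "acceptor")) {
    ps <- sites[[site]]
    hit <- v[v$pos %in% ps, , drop = FALSE]
    if (nrow(hit) == 0L) next
    hit <- hit[1, ]
    dinuc_ref <- subseq_chr(ref_genome, junction$chrom, ps[1], ps[2])
    dinuc_per <- subseq_chr(personal_genome, junction$chrom, ps[1], ps[2])
    # canonical on the transcribed strand
    orient <- function(d) if (identical(junction$strand, "-")) revcomp_chr(d) else d
    canon <- if (site == "donor") c("GT", "GC", "AT") else c("AG", "AC")
    creates <- orient(dinuc_per) %in% canon && !(orient(dinuc_ref) %in% canon)
    disrupts <- NA
    if (!is.null(annotation_introns)) {
      disrupts <- snp_disrupts_annotated_site(hit, annotation_introns,
                                              ref_genome, personal_genome)
    }
    # NAGNAG tandem acceptors: personal and reference AG 3 nt apart
    nagnag <- site == "acceptor" && {
      ctx_per <- if (identical(junction$strand, "-")) {
        revcomp_chr(subseq_chr(personal_genome, junction$chrom,
                               junction$intron_start, junction$intron_start + 4L))
      } else {
        subseq_chr(personal_genome, junction$chrom,
                   junction$intron_end - 4L, junction$intron_end)
      }
      substr(ctx_per, 1, 2) == "AG" && substr(ctx_per, 4, 5) == "AG"
    }
    return(data.frame(
      chrom = junction$chrom, intron_start = junction$intron_start,
      intron_end = junction$intron_end, snp_id = hit$snp_id,
      snp_pos = hit$pos, snp_ref = hit$ref, snp_alt = hit$alt, gt = hit$gt,
      site = site, dinuc_reference = dinuc_ref, dinuc_personal = dinuc_per,
      creates_canonical = creates, disrupts_reference_site = disrupts,
      nagnag = nagnag, stringsAsFactors = FALSE))
  }
  NULL
}

# internal: does this SNP corrupt a canonical dinucleotide used by an
# annotated reference intron (the OAS1-style site swap)?
snp_disrupts_annotated_site <- function(snp, annotation_introns, ref_genome,
                                        personal_genome) {
  ai <- annotation_introns[annotation_introns$chrom == snp$chrom, ,
                           drop = FALSE]
  if (nrow(ai) == 0L) return(FALSE)
  touches <- (snp$pos >= ai$intron_start & snp$pos <= ai$intron_start + 1L) |
             (snp$pos >= ai$intron_end - 1L & snp$pos <= ai$intron_end)
  for (i in which(touches)) {
    at_start <- snp$pos <= ai$intron_start[i] + 1L
    ps <- if (at_start) c(ai$intron_start[i], ai$intron_start[i] + 1L)
          else c(ai$intron_end[i] - 1L, ai$intron_end[i])
    d_ref <- subseq_chr(ref_genome, snp$chrom, ps[1], ps[2])
    d_per <- subseq_chr(personal_genome, snp$chrom, ps[1], ps[2])
    canon <- c("GT", "GC", "AT", "AG", "AC", "CT", "GT", "AT")  # either strand
    if (d_ref != d_per && d_ref %in% canon && !(d_per %in% canon)) return(TRUE)
  }
  FALSE
}

#' Keep only personal-specific junctions explained by a splice-site SNP
#'
#' Constrains the catalog to the effect of splice-site SNPs: every
#' personal-specific junction with no sample SNP at its splice-site
#' dinucleotide motifs is removed.  The annotations of the retained
#' junctions are attached to the catalog as \code{snp_annotations}.
#'
#' @param catalog a \code{psj_catalog}.
#' @param variants phased-variant data.frame.
#' @param ref_genome,hap1_genome,hap2_genome \code{DNAStringSet}s.
#' @param annotation_introns optional, for the disruption flag.
#' @param apply_to_hg19 also require hg19-specific junctions to carry a
#'   splice-site SNP (used by the symmetric reverse run; default TRUE for
#'   symmetry with the forward direction).
#' @return the filtered catalog with \code{snp_annotations} attached.
#' @export
filter_splice_site_snp_junctions <- function(catalog, variants, ref_genome,
                                             hap1_genome, hap2_genome,
                                             annotation_introns = NULL,
                                             apply_to_hg19 = FALSE) {
  j <- catalog$junctions
  targets <- j$category %in% PERSONAL_CATEGORIES
  if (apply_to_hg19) targets <- targets | j$category == "hg19_specific"
  keep <- rep(TRUE, nrow(j))
  anns <- list()
  for (i in which(targets)) {
    pg <- switch(j$category[i],
                 hap2_specific = hap2_genome,
                 hap1_genome)  # hap1, hap1hap2 and hg19-specific: hap1 carries
    ann <- annotate_splice_site_snp(j[i, ], variants, ref_genome, pg,
                                    annotation_introns)
    if (is.null(ann) && j$category[i] == "hap2_specific") {
      ann <- annotate_splice_site_snp(j[i, ], variants, ref_genome,
                                      hap1_genome, annotation_introns)
    } else if (is.null(ann) && j$category[i] != "hap2_specific") {
      ann <- annotate_splice_site_snp(j[i, ], variants, ref_genome,
                                      hap2_genome, annotation_introns)
    }
    if (is.null(ann)) {
      keep[i] <- FALSE
    } else {
      # a single-haplotype-specific junction whose splice-site SNP is
      # homozygous is suspicious (expected hap1hap2-specific): kept, flagged
      hom <- length(unique(strsplit(ann$gt, "|", fixed = TRUE)[[1]])) == 1L
      ann$suspicious_zygosity <-
        hom && j$category[i] %in% c("hap1_specific", "hap2_specific")
      if (ann$suspicious_zygosity) {
        message("junction ", junction_key(ann$chrom, ann$intron_start,
                                          ann$intron_end),
                " is ", j$category[i], " but its splice-site SNP ",
                ann$snp_id, " is homozygous")
      }
      anns[[length(anns) + 1L]] <- ann
    }
  }
  catalog$junctions <- j[keep, , drop = FALSE]
  rownames(catalog$junctions) <- NULL
  catalog$snp_annotations <- if (length(anns)) do.call(rbind, anns) else NULL
  catalog
}

#' Extract the annotated intron set from a GTF
#'
#' Builds a transcript database from the GTF's exon lines and derives the
#' intron of every transcript (the gap between consecutive exons), in the
#' same 1-based first/last-intronic-base convention used for junctions.
#'
#' @param gtf_path transcript annotation GTF.
#' @return data.frame with \code{chrom}, \code{intron_start},
#'   \code{intron_end}, \code{strand}, deduplicated.
#' @export
annotation_introns_from_gtf <- function(gtf_path) {
  txdb <- suppressWarnings(
    GenomicFeatures::makeTxDbFromGFF(gtf_path, format = "gtf"))
  introns <- unlist(GenomicFeatures::intronsByTranscript(txdb))
  if (length(introns) == 0L) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character()))
  }
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(introns)),
                    intron_start = BiocGenerics::start(introns),
                    intron_end = BiocGenerics::end(introns),
                    strand = as.character(BiocGenerics::strand(introns)),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(junction_key(out$chrom, out$intron_start,
                                      out$intron_end)), ]
  rownames(out) <- NULL
  out
}

#' Label junctions as known or novel against an annotation
#'
#' Known means the coordinate triple matches an annotated intron exactly.
#' A coordinate match whose strand disagrees with the annotation is still
#' called known, with \code{strand_conflict = TRUE}.
#'
#' @param junctions junction data.frame.
#' @param annotation_introns from \code{\link{annotation_introns_from_gtf}}.
#' @return the junction data.frame with \code{known} (logical) and
#'   \code{strand_conflict} columns added.
#' @export
known_or_novel <- function(junctions, annotation_introns) {
  if (nrow(junctions) == 0L) {
    junctions$known <- logical(0); junctions$strand_conflict <- logical(0)
    return(junctions)
  }
  jk <- junction_key(junctions$chrom, junctions$intron_start,
                     junctions$intron_end)
  ak <- junction_key(annotation_introns$chrom,
                     annotation_introns$intron_start,
                     annotation_introns$intron_end)
  m <- match(jk, ak)
  junctions$known <- !is.na(m)
  astr <- annotation_introns$strand[m]
  junctions$strand_conflict <- junctions$known & !is.na(astr) &
    junctions$strand != "*" & astr != junctions$strand
  if (any(junctions$strand_conflict)) {
    warning(sum(junctions$strand_conflict),
            " known junction(s) disagree with the annotated strand")
  }
  junctions
}

#' Reverse (false-positive) run: hg19-specific junctions
#'
#' The empirical false-positive yardstick: reads unmappable to both personal
#' genomes are re-aligned to the reference, and junctions reported solely in
#' that reference alignment are counted as hg19-specific.  This is the same
#' three-way set logic with the roles of reference and personal genomes
#' swapped; swapping twice returns the forward classification.
#'
#' @param ref_set junction set from the reverse-direction reference alignment.
#' @param hap1_set,hap2_set haplotype junction sets.
#' @param min_distinct minimum distinct-read support (default 2, as in the
#'   forward direction).
#' @return data.frame of hg19-specific junctions.
#' @export
reverse_false_positive_run <- function(ref_set, hap1_set, hap2_set,
                                       min_distinct = 2L) {
  cat <- classify_specific_junctions(ref_set, hap1_set, hap2_set)
  j <- cat$junctions
  hg <- j[j$category == "hg19_specific" & j$distinct_reads >= min_distinct, ,
          drop = FALSE]
  rownames(hg) <- NULL
  hg
}

#' @export
print.psj_catalog <- function(x, ...) {
  tab <- table(x$junctions$category)
  cat("psj_catalog:", x$sample_id, "-", nrow(x$junctions), "junctions (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Write a catalog's junction table (with annotations if present) as TSV
#' @param catalog a \code{psj_catalog}.
#' @param path output TSV.
#' @export
write_catalog_tsv <- function(catalog, path) {
  j <- catalog$junctions
  j <- cbind(sample = catalog$sample_id, j)
  if (!is.null(catalog$snp_annotations)) {
    a <- catalog$snp_annotations
    ak <- junction_key(a$chrom, a$intron_start, a$intron_end)
    jk <- junction_key(j$chrom, j$intron_start, j$intron_end)
    m <- match(jk, ak)
    j$snp_id <- a$snp_id[m]
    j$snp_site <- a$site[m]
  }
  utils::write.table(j, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
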