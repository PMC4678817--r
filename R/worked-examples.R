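#' Synthetic reconstructions of three published splice-site SNP geometries
#'
#' Builds three single-gene toy loci whose splice-site SNP geometry mirrors
#' well-characterised human cases of SNP-created splice sites:
#' \describe{
#'   \item{acceptor_shift}{an intronic C>G five nucleotides upstream of a
#'     reference 3' splice site creates a new AG acceptor; the SNP also sits
#'     inside the reference acceptor's scoring window (DHRS12 rs2296028
#'     pattern).}
#'   \item{donor_activation}{an intronic C>T converts a GC dinucleotide to
#'     GT, activating a novel 5' splice site inside the intron (ICA1
#'     rs6948664 pattern).}
#'   \item{acceptor_swap}{a G>A at the last intronic base destroys the
#'     reference AG acceptor and simultaneously creates a new AG one
#'     nucleotide downstream (OAS1 rs10774671 pattern).}
#' }
#' The flanking sequence context is synthetic (deterministically generated),
#' not the human genome: only the site geometry and alleles follow the
#' published cases, so site offsets and window mechanics are faithful while
#' absolute scores are properties of the bundled synthetic model.
#'
#' @return named list of loci; each holds \code{ref_genome},
#'   \code{personal_genome} (both \code{DNAStringSet}), \code{snp} (one-row
#'   data.frame), \code{junction_personal}, \code{junction_reference}
#'   (one-row junction data.frames) and \code{side}.
#' @export
worked_example_loci <- function() {
  set.seed(20151117L)
  mk_genome <- function(edit) {
    s <- rand_dna(600L)
    s <- set_bases(s, 101L, "GT")            # reference intron 101..400
    s <- set_bases(s, 399L, "AG")
    s <- edit(s)
    s
  }
  as_dss <- function(s) Biostrings::DNAStringSet(setNames(s, "chrW"))
  jn <- function(a, b) data.frame(chrom = "chrW", intron_start = a,
                                  intron_end = b, strand = "+",
                                  stringsAsFactors = FALSE)
  loci <- list()

  # intronic C>G creates an acceptor 5 nt upstream of the reference site
  ref <- mk_genome(function(s) set_bases(s, 394L, "AC"))
  snp <- data.frame(chrom = "chrW", pos = 395L, ref = "C", alt = "G",
                    hap1 = "G", hap2 = "G", snp_id = "acc_shift", gt = "1|1",
                    stringsAsFactors = FALSE)
  loci$acceptor_shift <- list(
    ref_genome = as_dss(ref),
    personal_genome = as_dss(set_bases(ref, 395L, "G")),
    snp = snp, junction_personal = jn(101L, 395L),
    junction_reference = jn(101L, 400L), side = "3prime")

  # intronic C>T activates a GC -> GT donor inside the intron
  ref <- mk_genome(function(s) set_bases(s, 240L, "GC"))
  snp <- data.frame(chrom = "chrW", pos = 241L, ref = "C", alt = "T",
                    hap1 = "T", hap2 = "T", snp_id = "don_act", gt = "1|1",
                    stringsAsFactors = FALSE)
  loci$donor_activation <- list(
    ref_genome = as_dss(ref),
    personal_genome = as_dss(set_bases(ref, 241L, "T")),
    snp = snp, junction_personal = jn(240L, 400L),
    junction_reference = jn(101L, 400L), side = "5prime")

  # G>A destroys the reference acceptor and creates one 1 nt downstream
  ref <- mk_genome(function(s) set_bases(s, 401L, "G"))
  snp <- data.frame(chrom = "chrW", pos = 400L, ref = "G", alt = "A",
                    hap1 = "A", hap2 = "A", snp_id = "acc_swap", gt = "1|1",
                    stringsAsFactors = FALSE)
  loci$acceptor_swap <- list(
    ref_genome = as_dss(ref),
    personal_genome = as_dss(set_bases(ref, 400L, "A")),
    snp = snp, junction_personal = jn(101L, 401L),
    junction_reference = jn(101L, 400L), side = "3prime")

  loci
}
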