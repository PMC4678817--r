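# Generates the bundled synthetic-trained splice-site model tables under
# inst/extdata/maxent_synthetic/.  The underlying generative models are
# defined here: position-specific base frequencies reflecting mammalian
# donor/acceptor consensus, plus explicit pairwise couplings.  The shipped
# tables are the *exact marginals* of these models, so the IPF fit performed
# by load_model_tables() recovers the generative distribution itself.
# Maintainer script; run from the package root:  Rscript data-raw/build_maxent_tables.R

pkgload::load_all(".", quiet = TRUE)

out_dir <- file.path("inst", "extdata", "maxent_synthetic")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

bases <- c("A", "C", "G", "T")

## ---- background: typical intronic base composition ----
bg <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)

## ---- donor (5') model ----
# 9-mer = exon -3..-1 | intron +1..+6; +1,+2 are consensus positions (GT).
# The remaining 7 positions carry a pairwise model with couplings between
# the exonic -1 and intronic +5 (the classic compensation between the two
# U1 snRNA pairing registers) and between adjacent intronic positions.
donor_pwm <- rbind(
  c(0.33, 0.37, 0.18, 0.12),   # -3
  c(0.60, 0.13, 0.14, 0.13),   # -2
  c(0.09, 0.03, 0.80, 0.08),   # -1
  c(0.59, 0.03, 0.35, 0.03),   # +3
  c(0.71, 0.08, 0.12, 0.09),   # +4
  c(0.05, 0.06, 0.84, 0.05),   # +5
  c(0.15, 0.17, 0.19, 0.49))   # +6
colnames(donor_pwm) <- bases

cpl <- function(...) {
  m <- matrix(c(...), 4, 4, byrow = TRUE, dimnames = list(bases, bases))
  m
}
# -1 vs +5: weak -1 (non-G) pushes +5 toward G; G at -1 relaxes +5
donor_J <- list(
  "3-6" = cpl( 0.00, 0.00, 0.45, 0.00,
               0.00, 0.00, 0.45, 0.00,
               0.10, 0.10, -0.25, 0.10,
               0.00, 0.00, 0.45, 0.00),
  "4-5" = cpl( 0.20, 0.00, -0.10, 0.00,
               0.00, 0.00, 0.00, 0.00,
              -0.10, 0.00, 0.20, 0.00,
               0.00, 0.00, 0.00, 0.00),
  "6-7" = cpl( 0.00, 0.00, 0.00, 0.00,
               0.00, 0.00, 0.00, 0.00,
               0.00, 0.00, 0.00, 0.25,
               0.00, 0.00, 0.00, -0.15))

states7 <- hiddensplice:::enumerate_states(7L)
h <- log(donor_pwm)
lp <- hiddensplice:::loglinear_logp(h, donor_J, states7)
p <- exp(lp)
donor_singles <- t(vapply(1:7, function(i)
  hiddensplice:::joint_marginal(p, states7, i), numeric(4)))
colnames(donor_singles) <- bases
donor_pairs <- lapply(names(donor_J), function(nm) {
  ij <- as.integer(strsplit(nm, "-")[[1]])
  matrix(hiddensplice:::joint_marginal(p, states7, ij), 4, 4, byrow = TRUE,
         dimnames = list(bases, bases))
})
names(donor_pairs) <- names(donor_J)

donor_cons <- rbind("4" = c(0.0020, 0.0010, 0.9950, 0.0020),
                    "5" = c(0.0020, 0.0020, 0.0030, 0.9930))
colnames(donor_cons) <- bases

## ---- acceptor (3') model ----
# 23-mer = intron -20..-1 | exon +1..+3; -2,-1 are consensus (AG).  The
# remaining 21 positions form an inhomogeneous Markov chain: a pyrimidine
# tract with run-reinforcing adjacent couplings, a C-rich -3, and a G-biased
# first exonic base.
acc_pwm <- matrix(0, 21, 4, dimnames = list(NULL, bases))
for (i in 1:14) acc_pwm[i, ] <- c(0.10, 0.31, 0.11, 0.48)   # -20..-7 tract
acc_pwm[15, ] <- c(0.12, 0.30, 0.10, 0.48)                  # -6
acc_pwm[16, ] <- c(0.08, 0.33, 0.07, 0.52)                  # -5
acc_pwm[17, ] <- c(0.22, 0.30, 0.10, 0.38)                  # -4
acc_pwm[18, ] <- c(0.05, 0.62, 0.02, 0.31)                  # -3
acc_pwm[19, ] <- c(0.25, 0.14, 0.50, 0.11)                  # +1
acc_pwm[20, ] <- c(0.25, 0.22, 0.25, 0.28)                  # +2
acc_pwm[21, ] <- c(0.22, 0.26, 0.24, 0.28)                  # +3

tract_tilt <- cpl(0.10, 0.00, 0.10, 0.00,
                  0.00, 0.25, 0.00, 0.15,
                  0.10, 0.00, 0.10, 0.00,
                  0.00, 0.15, 0.00, 0.25)
zero_tilt <- matrix(0, 4, 4)
acc_pairs <- lapply(1:20, function(i) {
  tilt <- if (i <= 15) tract_tilt else zero_tilt
  m <- hiddensplice:::tilted_pair(acc_pwm[i, ], acc_pwm[i + 1, ], tilt)
  dimnames(m) <- list(bases, bases)
  m
})
names(acc_pairs) <- paste(1:20, 2:21, sep = "-")
acc_singles <- rbind(rowSums(acc_pairs[[1]]),
                     t(vapply(acc_pairs, colSums, numeric(4))))
colnames(acc_singles) <- bases

acc_cons <- rbind("19" = c(0.9960, 0.0010, 0.0020, 0.0010),
                  "20" = c(0.0020, 0.0020, 0.9950, 0.0010))
colnames(acc_cons) <- bases

## ---- write tables ----
wt <- function(df, file) {
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     file.path(out_dir, file), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
wt(data.frame(base = bases, freq = unname(bg)), "background.tsv")
wt(data.frame(position = rownames(donor_cons), donor_cons,
              check.names = FALSE), "donor_consensus.tsv")
wt(data.frame(position = 1:7, donor_singles, check.names = FALSE),
   "donor_singles.tsv")
long_pairs <- function(pl) do.call(rbind, lapply(names(pl), function(nm) {
  g <- expand.grid(a = bases, b = bases, stringsAsFactors = FALSE)
  data.frame(pair = nm, a = g$a, b = g$b,
             value = pl[[nm]][cbind(g$a, g$b)])
}))
wt(long_pairs(donor_pairs), "donor_pairs.tsv")
wt(data.frame(position = rownames(acc_cons), acc_cons, check.names = FALSE),
   "acceptor_consensus.tsv")
wt(data.frame(position = 1:21, acc_singles, check.names = FALSE),
   "acceptor_singles.tsv")
wt(long_pairs(acc_pairs), "acceptor_pairs.tsv")

files <- c("background.tsv", "donor_consensus.tsv", "donor_singles.tsv",
           "donor_pairs.tsv", "acceptor_consensus.tsv",
           "acceptor_singles.tsv", "acceptor_pairs.tsv")
sums <- data.frame(file = files,
                   md5 = unname(tools::md5sum(file.path(out_dir, files))))
utils::write.table(sums, file.path(out_dir, "CHECKSUMS"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote", length(files), "tables to", out_dir, "\n")
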