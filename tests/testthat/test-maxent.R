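test_that("IPF fitting reproduces the constraints and the generating model", {
  set.seed(3)
  k <- 4L
  singles <- t(vapply(1:k, function(i) {
    p <- stats::runif(4, 0.05, 1); p / sum(p)
  }, numeric(4)))
  h <- log(singles)
  J <- list("1-3" = matrix(stats::rnorm(16, sd = 0.3), 4, 4),
            "2-3" = matrix(stats::rnorm(16, sd = 0.3), 4, 4),
            "3-4" = matrix(stats::rnorm(16, sd = 0.3), 4, 4))
  states <- hiddensplice:::enumerate_states(k)
  true_lp <- hiddensplice:::loglinear_logp(h, J, states)
  p <- exp(true_lp)
  tr_singles <- t(vapply(1:k, function(i)
    hiddensplice:::joint_marginal(p, states, i), numeric(4)))
  tr_pairs <- lapply(names(J), function(nm) {
    ij <- as.integer(strsplit(nm, "-")[[1]])
    matrix(hiddensplice:::joint_marginal(p, states, ij), 4, 4, byrow = TRUE)
  })
  names(tr_pairs) <- names(J)
  fit <- fit_maxent_block(tr_singles, tr_pairs)
  # the maxent distribution subject to the model's own marginals is the model
  expect_lt(max(abs(fit$logp - true_lp)), 1e-6)
  # fitted marginals match the constraints
  fp <- exp(fit$logp)
  for (i in 1:k) {
    expect_lt(max(abs(hiddensplice:::joint_marginal(fp, states, i) -
                        tr_singles[i, ])), 1e-8)
  }
})

test_that("model tables load with verified checksums and valid distributions", {
  m <- load_model_tables()
  expect_s3_class(m, "maxent_models")
  expect_lt(abs(sum(exp(m$donor$block$logp)) - 1), 1e-6)
  expect_match(m$version, "synthetic")

  # tampering with a table is a hard error naming the file
  src <- system.file("extdata", "maxent_synthetic", package = "hiddensplice")
  dir2 <- file.path(tempfile(), "maxent")
  dir.create(dir2, recursive = TRUE)
  file.copy(list.files(src, full.names = TRUE), dir2)
  f <- file.path(dir2, "donor_singles.tsv")
  writeLines(sub("0", "1", readLines(f)), f)
  expect_error(load_model_tables(dir2, use_cache = FALSE),
               "checksum mismatch.*donor_singles")
  file.remove(file.path(dir2, "acceptor_pairs.tsv"))
  file.remove(f)
  expect_error(load_model_tables(dir2, use_cache = FALSE),
               "missing model table file")
})

test_that("scoring is deterministic and rejects malformed windows", {
  m <- load_model_tables()
  s1 <- score5("CAGGTAAGT", m)
  expect_identical(s1, score5("CAGGTAAGT", m))
  expect_error(score5("CAGGTAAG", m), "exactly 9")
  expect_error(score5("CAGGTANGT", m), "non-ACGT")
  expect_error(score3(strrep("A", 22), m), "exactly 23")
  expect_error(score3(paste0(strrep("A", 20), "NGG"), m), "non-ACGT")
})

test_that("donor scores match the independent string-space oracle on a random panel", {
  m <- load_model_tables()
  blk <- m$donor$block
  set.seed(50)
  panel <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = ""),
    character(1))
  for (seq in panel) {
    expect_lt(abs(score5(seq, m) - oracle_score5(m, seq)), 0.01)
  }
})

test_that("acceptor decomposition equals the full chain joint probability", {
  # the 9-block product/quotient is the junction-tree factorisation of the
  # chain model, so it must reproduce the direct 21-mer joint probability:
  # an independent route through start-frequency x transition products
  m <- load_model_tables()
  ch <- m$acceptor$chain
  set.seed(51)
  panel <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE), collapse = ""),
    character(1))
  # include consensus-intact and consensus-broken (non-AG) cases
  panel[1] <- paste0(strrep("T", 18), "AG", "GTT")
  panel[2] <- paste0(strrep("T", 18), "AA", "GTT")   # degraded consensus
  for (seq in panel) {
    expect_lt(abs(score3(seq, m) - oracle_score3(m, seq)), 1e-9)
  }
})

test_that("frozen panel scores pin the bundled model against silent drift", {
  m <- load_model_tables()
  expect_equal(round(score5("CAGGTAAGT", m), 4), 12.9757)
  expect_equal(round(score5("TTTGTTTTT", m), 4), -6.7240)
  expect_equal(round(score3(paste0(strrep("T", 15), "TTCAG", "AGG"), m), 4),
               20.408)
  expect_equal(round(score3(paste0(strrep("G", 18), "AG", "GGG"), m), 4),
               -13.3107)
})

test_that("site windows are extracted strand-aware with edge errors", {
  genome <- Biostrings::DNAStringSet(setNames(paste0(
    "TTTCAG", "GTAAGA", strrep("C", 28), "TTTTTTTTTTTTTTCAG", "GCA"), "chr1"))
  # intron runs 7..57 (GT...AG), exons around it
  jn <- data.frame(chrom = "chr1", intron_start = 7L, intron_end = 57L,
                   strand = "+", stringsAsFactors = FALSE)
  w5 <- site_window_from_junction(jn, "5prime", genome)
  expect_equal(w5$seq, "CAGGTAAGA")
  expect_equal(c(w5$g_start, w5$g_end), c(4L, 12L))
  w3 <- site_window_from_junction(jn, "3prime", genome)
  expect_equal(nchar(w3$seq), 23L)
  expect_equal(substr(w3$seq, 19, 23), "AGGCA")

  # the same gene mirrored to the minus strand gives identical windows
  rc <- Biostrings::DNAStringSet(setNames(as.character(
    Biostrings::reverseComplement(genome[[1]])), "chr1"))
  L <- Biostrings::width(genome)[1]
  jn_m <- data.frame(chrom = "chr1", intron_start = L - 57L + 1L,
                     intron_end = L - 7L + 1L, strand = "-",
                     stringsAsFactors = FALSE)
  expect_equal(site_window_from_junction(jn_m, "5prime", rc)$seq, w5$seq)
  expect_equal(site_window_from_junction(jn_m, "3prime", rc)$seq, w3$seq)

  edge <- data.frame(chrom = "chr1", intron_start = 2L, intron_end = 57L,
                     strand = "+", stringsAsFactors = FALSE)
  expect_error(site_window_from_junction(edge, "5prime", genome),
               "crosses the edge")
})

test_that("delta scores adjust the reference window for the splice-site SNP", {
  m <- load_model_tables()
  mkwin <- function(seq, g_start, side, strand = "+") {
    structure(list(seq = seq, chrom = "chr1", g_start = g_start,
                   g_end = g_start + nchar(seq) - 1L, strand = strand,
                   side = side), class = "splice_site_window")
  }
  p <- mkwin("CAGGTAAGT", 100L, "5prime")
  r <- mkwin("CAGGTAAGT", 100L, "5prime")
  same <- delta_ss_score(p, r, NULL, m)
  expect_equal(same$delta, 0)
  expect_false(same$reference_adjusted_for_snp)

  # SNP outside the reference window: no adjustment
  snp_out <- data.frame(pos = 500L, alt = "T")
  out <- delta_ss_score(p, mkwin("CAGGTTTTT", 100L, "5prime"), snp_out, m)
  expect_false(out$reference_adjusted_for_snp)
  expect_gt(out$delta, 0)

  # SNP inside the reference window is applied before scoring
  snp_in <- data.frame(pos = 104L, alt = "C")   # +2 T -> C kills the GT
  adj <- delta_ss_score(p, mkwin("CAGGTAAGT", 100L, "5prime"), snp_in, m)
  expect_true(adj$reference_adjusted_for_snp)
  expect_equal(adj$reference_seq, "CAGGCAAGT")
  expect_equal(adj$reference_score, score5("CAGGCAAGT", m))
  expect_gt(adj$delta, 0)
})
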