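# Independent oracles for the maximum-entropy scorer.

# string-space evaluation of a pairwise log-linear model: explicit loops
# over character k-mers with its own normalisation -- shares no indexing
# machinery with the production scorer
naive_block_logp <- function(h, J, kmer) {
  bases <- c("A", "C", "G", "T")
  k <- nrow(h)
  score_one <- function(chars) {
    s <- 0
    for (i in seq_len(k)) s <- s + h[i, match(chars[i], bases)]
    for (nm in names(J)) {
      ij <- as.integer(strsplit(nm, "-")[[1]])
      s <- s + J[[nm]][match(chars[ij[1]], bases), match(chars[ij[2]], bases)]
    }
    s
  }
  all_kmers <- do.call(expand.grid,
                       c(rep(list(bases), k), stringsAsFactors = FALSE))
  logz <- log(sum(exp(apply(all_kmers, 1, function(r) score_one(r)))))
  score_one(strsplit(kmer, "")[[1]]) - logz
}

# donor oracle: full 9-mer score through the string-space route
oracle_score5 <- function(m, seq) {
  b <- strsplit(seq, "")[[1]]
  rest <- paste(b[c(1:3, 6:9)], collapse = "")
  log2(m$donor$cons["4", b[4]] / m$bg[b[4]]) +
    log2(m$donor$cons["5", b[5]] / m$bg[b[5]]) +
    naive_block_logp(m$donor$block$h, m$donor$block$J, rest) / log(2) -
    sum(log2(m$bg[strsplit(rest, "")[[1]]]))
}

# acceptor oracle: direct 21-mer chain joint (start frequency times
# transition products), bypassing the block decomposition entirely
oracle_score3 <- function(m, seq) {
  bases <- c("A", "C", "G", "T")
  b <- strsplit(seq, "")[[1]]
  rest <- b[c(1:18, 21:23)]
  idx <- match(rest, bases)
  ch <- m$acceptor$chain
  chain_lp <- log(ch$singles[[1]][idx[1]])
  for (i in 2:21) chain_lp <- chain_lp + log(ch$cond[[i - 1]][idx[i - 1],
                                                              idx[i]])
  log2(m$acceptor$cons["19", b[19]] / m$bg[b[19]]) +
    log2(m$acceptor$cons["20", b[20]] / m$bg[b[20]]) +
    chain_lp / log(2) - sum(log2(m$bg[rest]))
}
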