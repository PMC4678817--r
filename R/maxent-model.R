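BASES <- c("A", "C", "G", "T")

# internal: all 4^k base-index states as a (4^k x k) integer matrix, ordered
# so that row i corresponds to k-mer index i (A=0..T=3, first position most
# significant).  This ordering is the contract between kmer_index() and every
# lookup table in the scorer.
enumerate_states <- function(k) {
  n <- 4L^k
  m <- matrix(0L, nrow = n, ncol = k)
  idx <- 0:(n - 1)
  for (j in k:1) {
    m[, j] <- idx %% 4L + 1L
    idx <- idx %/% 4L
  }
  m
}

# internal: 1-based index of a k-mer (character scalar) into a 4^k table
kmer_index <- function(seq) {
  b <- match(strsplit(seq, "")[[1]], BASES)
  if (anyNA(b)) stop("ambiguous base in sequence: ", seq)
  sum((b - 1L) * 4L^(rev(seq_along(b)) - 1L)) + 1L
}

# internal: log joint over all states of a pairwise log-linear model
# h: k x 4 matrix; J: named list "i-j" -> 4 x 4 matrix
loglinear_logp <- function(h, J, states = NULL) {
  k <- nrow(h)
  if (is.null(states)) states <- enumerate_states(k)
  lp <- numeric(nrow(states))
  for (i in seq_len(k)) lp <- lp + h[i, states[, i]]
  for (nm in names(J)) {
    ij <- as.integer(strsplit(nm, "-")[[1]])
    lp <- lp + J[[nm]][cbind(states[, ij[1]], states[, ij[2]])]
  }
  lp - log(sum(exp(lp - max(lp)))) - max(lp)
}

# internal: marginal of a full joint over a subset of positions
joint_marginal <- function(p, states, positions) {
  if (length(positions) == 1L) {
    as.vector(tapply(p, states[, positions], sum))
  } else {
    key <- states[, positions[1]]
    for (j in positions[-1]) key <- (key - 1L) * 4L + states[, j]
    out <- numeric(4L^length(positions))
    agg <- tapply(p, key, sum)
    out[as.integer(names(agg))] <- agg
    out
  }
}

#' Fit a maximum-entropy sequence model by iterative proportional fitting
#'
#' Finds the maximum-entropy distribution over k-mers subject to the given
#' first-order (per-position base frequencies) and second-order (pairwise
#' joint frequencies) marginal constraints.  The solution is the unique
#' log-linear model on those cliques matching the constraints; it is found
#' by cycling IPF updates over the full 4^k state space until every
#' constrained marginal matches to within \code{tol}.
#'
#' @param singles k x 4 matrix of per-position base frequencies (rows sum
#'   to 1).
#' @param pairs named list of 4 x 4 pairwise joint frequency matrices; the
#'   name \code{"i-j"} gives the constrained position pair.  The pair
#'   marginals must be consistent with \code{singles}.
#' @param tol maximum absolute marginal error at convergence (1e-10).
#' @param max_iter maximum IPF sweeps.
#' @return object of class \code{mem_block}: list with \code{k}, \code{h},
#'   \code{J} (fitted log potentials) and \code{logp}, the full normalised
#'   log-probability vector indexed by k-mer index.
#' @export
fit_maxent_block <- function(singles, pairs = list(), tol = 1e-10,
                             max_iter = 500L) {
  k <- nrow(singles)
  stopifnot(k <= 8L)
  states <- enumerate_states(k)
  h <- matrix(0, nrow = k, ncol = 4L)
  J <- lapply(pairs, function(x) matrix(0, 4L, 4L))
  names(J) <- names(pairs)
  floor_log <- function(x) log(pmax(x, 1e-300))
  for (iter in seq_len(max_iter)) {
    lp <- loglinear_logp(h, J, states)
    p <- exp(lp)
    worst <- 0
    for (i in seq_len(k)) {
      cur <- joint_marginal(p, states, i)
      worst <- max(worst, max(abs(cur - singles[i, ])))
      h[i, ] <- h[i, ] + floor_log(singles[i, ]) - floor_log(cur)
      lp <- loglinear_logp(h, J, states); p <- exp(lp)
    }
    for (nm in names(pairs)) {
      ij <- as.integer(strsplit(nm, "-")[[1]])
      cur <- matrix(joint_marginal(p, states, ij), 4L, 4L, byrow = TRUE)
      worst <- max(worst, max(abs(cur - pairs[[nm]])))
      J[[nm]] <- J[[nm]] + floor_log(pairs[[nm]]) - floor_log(cur)
      lp <- loglinear_logp(h, J, states); p <- exp(lp)
    }
    if (worst < tol) break
  }
  structure(list(k = k, h = h, J = J, logp = loglinear_logp(h, J, states)),
            class = "mem_block")
}

# internal: conditional tables of an inhomogeneous Markov chain defined by
# consistent adjacent pair joints.  pair[[i]] is the joint of (i, i+1); the
# chain is the maximum-entropy distribution matching all adjacent pairs.
chain_from_pairs <- function(pairs) {
  n <- length(pairs) + 1L
  singles <- vector("list", n)
  singles[[1]] <- rowSums(pairs[[1]])
  for (i in seq_along(pairs)) singles[[i + 1L]] <- colSums(pairs[[i]])
  cond <- lapply(seq_along(pairs), function(i) {
    sweep(pairs[[i]], 1, pmax(singles[[i]], 1e-300), "/")
  })
  list(n = n, singles = singles, cond = cond)
}

# internal: log-probability lookup vector over the 4^len states of a
# contiguous block [a, a+len-1] of the chain (exact marginal: a Markov
# chain's contiguous-block marginal is start frequency times transition
# products)
chain_block_logp <- function(chain, a, len) {
  states <- enumerate_states(len)
  lp <- log(pmax(chain$singles[[a]], 1e-300))[states[, 1]]
  if (len > 1L) {
    for (j in 2:len) {
      tr <- chain$cond[[a + j - 2L]]
      lp <- lp + log(pmax(tr[cbind(states[, j - 1L], states[, j])], 1e-300))
    }
  }
  lp
}

# internal: fit a 4x4 joint with prescribed row and column marginals and a
# log-tilt matrix (2-D IPF; converges fast and is deterministic)
tilted_pair <- function(p_row, p_col, tilt = matrix(0, 4, 4), iters = 200L) {
  m <- outer(p_row, p_col) * exp(tilt)
  for (i in seq_len(iters)) {
    m <- m * (p_row / pmax(rowSums(m), 1e-300))
    m <- t(t(m) * (p_col / pmax(colSums(m), 1e-300)))
  }
  m / sum(m)
}

# block layout of the 3' site decomposition: the 23-mer minus the consensus
# AG (intron positions 19-20) leaves 21 positions; the score multiplies the
# five 7-mer block probabilities and divides by the four overlap blocks, the
# exact junction-tree factorisation for chain-structured dependence.
ACC3_NUM_BLOCKS <- list(1:7, 8:14, 15:21, 5:11, 12:18)
ACC3_DEN_BLOCKS <- list(5:7, 8:11, 12:14, 15:18)

maxent_cache <- new.env(parent = emptyenv())

#' Load the splice-site scoring model tables
#'
#' Reads the 5' (donor) and 3' (acceptor) maximum-entropy model tables from
#' a data directory, verifies their md5 checksums against the bundled
#' \code{CHECKSUMS} file (silent model drift is a hard error), fits the
#' donor block by IPF and assembles the acceptor chain, and returns scoring-
#' ready models.  The bundled tables are synthetic-trained: the parameters
#' are derived from a documented generative splice-site model, not from the
#' published human training sets (see the package vignette).
#'
#' @param data_dir directory holding the tables; defaults to the package's
#'   bundled \code{extdata/maxent_synthetic}.
#' @param use_cache reuse a previously loaded model for the same directory.
#' @return object of class \code{maxent_models}: list with \code{donor},
#'   \code{acceptor}, \code{bg}, \code{version}.
#' @export
load_model_tables <- function(data_dir = NULL, use_cache = TRUE) {
  if (is.null(data_dir)) {
    data_dir <- system.file("extdata", "maxent_synthetic",
                            package = "hiddensplice")
  }
  if (use_cache && !is.null(maxent_cache[[data_dir]])) {
    return(maxent_cache[[data_dir]])
  }
  needed <- c("background.tsv", "donor_consensus.tsv", "donor_singles.tsv",
              "donor_pairs.tsv", "acceptor_consensus.tsv",
              "acceptor_singles.tsv", "acceptor_pairs.tsv")
  present <- file.exists(file.path(data_dir, needed))
  if (!all(present)) {
    stop("missing model table file(s): ",
         paste(needed[!present], collapse = ", "))
  }
  sums_file <- file.path(data_dir, "CHECKSUMS")
  if (!file.exists(sums_file)) stop("missing CHECKSUMS file in ", data_dir)
  sums <- utils::read.table(sums_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  for (f in needed) {
    got <- unname(tools::md5sum(file.path(data_dir, f)))
    want <- sums$md5[sums$file == f]
    if (length(want) != 1L || got != want) {
      stop("checksum mismatch for model table file: ", f)
    }
  }
  read_tsv <- function(f) utils::read.table(file.path(data_dir, f),
                                            header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE)
  bg_tab <- read_tsv("background.tsv")
  bg <- setNames(bg_tab$freq, bg_tab$base)[BASES]

  dc <- read_tsv("donor_consensus.tsv")
  donor_cons <- as.matrix(dc[, BASES]); rownames(donor_cons) <- dc$position
  ds <- read_tsv("donor_singles.tsv")
  donor_singles <- as.matrix(ds[, BASES])
  dp <- read_tsv("donor_pairs.tsv")
  donor_pairs <- lapply(split(dp, dp$pair), function(g) {
    m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    m[cbind(g$a, g$b)] <- g$value
    m
  })
  donor_block <- fit_maxent_block(donor_singles, donor_pairs)

  ac <- read_tsv("acceptor_consensus.tsv")
  acc_cons <- as.matrix(ac[, BASES]); rownames(acc_cons) <- ac$position
  as_ <- read_tsv("acceptor_singles.tsv")
  acc_singles <- as.matrix(as_[, BASES])
  ap <- read_tsv("acceptor_pairs.tsv")
  acc_pairs <- lapply(split(ap, ap$pair), function(g) {
    m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    m[cbind(g$a, g$b)] <- g$value
    m
  })
  acc_pairs <- acc_pairs[order(as.integer(sub("-.*", "", names(acc_pairs))))]
  chain <- chain_from_pairs(unname(acc_pairs))
  stopifnot(chain$n == 21L)
  # marginal-consistency validation of the shipped chain tables
  for (i in seq_len(20L)) {
    if (max(abs(rowSums(acc_pairs[[i]]) - acc_singles[i, ])) > 1e-6 ||
        max(abs(colSums(acc_pairs[[i]]) - acc_singles[i + 1L, ])) > 1e-6) {
      stop("acceptor pair table ", names(acc_pairs)[i],
           " is inconsistent with the single-position tables")
    }
  }
  num_lp <- lapply(ACC3_NUM_BLOCKS, function(b)
    chain_block_logp(chain, b[1], length(b)))
  den_lp <- lapply(ACC3_DEN_BLOCKS, function(b)
    chain_block_logp(chain, b[1], length(b)))

  models <- structure(list(
    donor = list(cons = donor_cons, block = donor_block),
    acceptor = list(cons = acc_cons, chain = chain,
                    num_lp = num_lp, den_lp = den_lp),
    bg = bg,
    version = "hiddensplice-maxent-synthetic-1.0"
  ), class = "maxent_models")
  # sanity: each distribution sums to 1
  stopifnot(abs(sum(exp(donor_block$logp)) - 1) < 1e-6)
  for (lp in c(num_lp, den_lp)) stopifnot(abs(sum(exp(lp)) - 1) < 1e-6)
  if (use_cache) maxent_cache[[data_dir]] <- models
  models
}
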