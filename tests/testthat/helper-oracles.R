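# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

BASES <- c("A", "C", "G", "U")

# exact stationary chain probability of a word: pi(w1) * prod transitions
chain_prob_oracle <- function(model, kmer) {
  w <- strsplit(kmer, "")[[1]]
  p <- model$mono[w[1]]
  for (i in seq_len(length(w) - 1)) {
    p <- p * model$transition[w[i], w[i + 1]]
  }
  unname(p)
}

# random first-order model with stationary mononucleotide marginal
random_markov <- function() {
  Q <- matrix(rgamma(16, shape = 1), 4, 4)
  Q <- Q / rowSums(Q)
  markov_model(transition = Q)
}

all_hexamers <- function() {
  g <- expand.grid(BASES, BASES, BASES, BASES, BASES, BASES,
                   stringsAsFactors = FALSE)
  apply(g[, 6:1], 1, paste, collapse = "")
}

# brute-force single-linkage chaining of positions (all-pairs, quadratic)
chain_positions_oracle <- function(pos, max_gap) {
  pos <- sort(pos)
  grp <- seq_along(pos)
  repeat {
    changed <- FALSE
    for (i in seq_along(pos)) {
      for (j in seq_along(pos)) {
        if (grp[i] != grp[j] && abs(pos[i] - pos[j]) <= max_gap) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  unname(split(pos, grp))
}

# standard error of a sample SD via the fourth central moment
sd_standard_error <- function(x) {
  n <- length(x)
  s2 <- var(x)
  m4 <- mean((x - mean(x))^4)
  sqrt(max(m4 - s2^2, 0) / n) / (2 * sd(x))
}

# flanks wrapping plain equal-length sequences centred on the cleavage site
flanks_from_seqs <- function(seqs, up) {
  data.frame(site_id = seq_along(seqs),
             upstream = substr(seqs, 1, up),
             downstream = substr(seqs, up + 1, nchar(seqs)),
             up_trunc = FALSE, down_trunc = FALSE,
             stringsAsFactors = FALSE)
}

# small two-gene genome with hand-placed features, used by annotation tests
toy_gene_models <- function() {
  data.frame(
    gene_id = rep(c("gA", "gB"), c(7, 3)),
    transcript_id = rep(c("gA.t1", "gA.t2", "gB.t1"), c(4, 3, 3)),
    chrom = "chr1", strand = c(rep("+", 7), rep("-", 3)),
    type = c("exon", "CDS", "five_prime_UTR", "three_prime_UTR",
             "exon", "exon", "CDS",
             "exon", "CDS", "three_prime_UTR"),
    start = c(1000, 1100, 1000, 1901,
              1000, 1800, 1805,
              5000, 5101, 5000),
    end = c(2000, 1900, 1099, 2000,
            1500, 2000, 1900,
            5700, 5700, 5100),
    stringsAsFactors = FALSE)
}
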