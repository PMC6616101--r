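#' First-order Markov background model for poly(A) flank sequences
#'
#' Construct a background model from explicit frequencies or from a transition
#' matrix. The model stores the mononucleotide frequencies (`mono`), the
#' dinucleotide frequencies (`di`) and the row-normalised transition matrix
#' used for chain computations. When only a transition matrix is supplied the
#' mononucleotide frequencies default to its stationary distribution, which
#' makes the model internally consistent (the expected k-mer frequency then
#' equals the exact stationary chain probability).
#'
#' @param mono named numeric(4) of A/C/G/U frequencies (sums to 1).
#' @param di 4x4 matrix of dinucleotide frequencies (sums to 1), rows = first
#'   base, columns = second base.
#' @param transition 4x4 row-stochastic matrix; used instead of `mono`/`di`.
#' @param region optional label of the fitted region (bookkeeping only).
#' @return an object of class `markov_model`.
#' @export
markov_model <- function(mono = NULL, di = NULL, transition = NULL,
                         region = NULL) {
  if (!is.null(transition)) {
    Q <- as.matrix(transition)
    stopifnot(all(dim(Q) == c(4, 4)), all(Q >= 0))
    Q <- Q / rowSums(Q)
    dimnames(Q) <- list(APA_BASES, APA_BASES)
    if (is.null(mono)) mono <- stationary_distribution(Q)
    mono <- setNames(as.numeric(mono), APA_BASES)
    di <- Q * mono
  } else {
    stopifnot(!is.null(mono), !is.null(di))
    mono <- mono[APA_BASES]
    di <- as.matrix(di)[APA_BASES, APA_BASES]
    Q <- di / rowSums(di)
  }
  assert_that(abs(sum(mono) - 1) < 1e-9, "mono frequencies must sum to 1")
  assert_that(abs(sum(di) - 1) < 1e-9, "di frequencies must sum to 1")
  assert_that(all(mono >= 0) && all(di >= 0), "frequencies must be >= 0")
  structure(list(mono = mono, di = di, transition = Q, region = region),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("First-order Markov background model",
      if (!is.null(x$region)) sprintf("(region: %s)", x$region), "\n")
  cat("mono:", paste(sprintf("%s=%.4f", names(x$mono), x$mono),
                     collapse = " "), "\n")
  invisible(x)
}

stationary_distribution <- function(Q) {
  A <- rbind(t(Q) - diag(4), rep(1, 4))
  b <- c(rep(0, 4), 1)
  p <- qr.solve(A, b)
  setNames(pmax(p, 0) / sum(pmax(p, 0)), APA_BASES)
}

#' Fit a Markov background model from sequences
#'
#' Maximum-likelihood mono- and dinucleotide frequencies pooled over a set of
#' sequences. Dinucleotides are counted within sequences only (no wrap-around
#' and no joins across sequences); windows containing `N` are skipped.
#'
#' @param seqs character vector of RNA (or DNA) sequences.
#' @param region optional region label.
#' @return a `markov_model`.
#' @export
fit_markov <- function(seqs, region = NULL) {
  assert_that(length(seqs) > 0, "fit_markov: empty sequence set")
  ss <- Biostrings::RNAStringSet(rna(seqs))
  assert_that(sum(Biostrings::width(ss)) >= 2,
              "fit_markov: total sequence length must be >= 2")
  mono_c <- colSums(Biostrings::oligonucleotideFrequency(ss, 1))
  di_c <- colSums(Biostrings::oligonucleotideFrequency(ss, 2))
  assert_that(sum(di_c) > 0, "fit_markov: no dinucleotide windows")
  di <- matrix(di_c / sum(di_c), 4, 4, byrow = TRUE,
               dimnames = list(APA_BASES, APA_BASES))
  markov_model(mono = mono_c / sum(mono_c), di = di, region = region)
}

kmer_chars <- function(kmer) {
  w <- strsplit(rna(kmer), "")[[1]]
  assert_that(all(w %in% APA_BASES), sprintf("invalid k-mer '%s'", kmer))
  w
}

#' Expected per-position k-mer probability under the Markov background
#'
#' The product of the k-1 dinucleotide frequencies divided by the k-2 interior
#' mononucleotide frequencies. If any required frequency is zero the result is
#' 0 with attribute `degenerate = TRUE`.
#'
#' @param model a `markov_model`.
#' @param kmer k-mer string (k >= 2) over A/C/G/U.
#' @return expected per-position probability `f_e`.
#' @export
expected_kmer_freq <- function(model, kmer) {
  w <- kmer_chars(kmer)
  k <- length(w)
  assert_that(k >= 2, "expected_kmer_freq: k must be >= 2")
  dis <- model$di[cbind(w[-k], w[-1])]
  monos <- if (k > 2) model$mono[w[2:(k - 1)]] else 1
  if (any(dis == 0) || any(monos == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  prod(dis) / prod(monos)
}

#' Total number of scanned k-mer start positions
#'
#' @param lengths integer vector of sequence lengths.
#' @param k word length.
#' @return sum over sequences of max(l - k + 1, 0).
#' @export
total_positions <- function(lengths, k) {
  sum(pmax(lengths - k + 1, 0))
}

#' Expected number of k-mer occurrences
#'
#' @param f_e expected per-position probability.
#' @param lengths integer vector of sequence lengths; sequences shorter than
#'   `k` contribute zero positions.
#' @param k word length.
#' @return expected occurrence count `O_e = f_e * sum(l_i - k + 1)`.
#' @export
expected_occurrences <- function(f_e, lengths, k) {
  assert_that(f_e >= 0 && f_e <= 1, "f_e must be in [0,1]")
  f_e * total_positions(lengths, k)
}

#' Overlap-corrected standard deviation of a k-mer count
#'
#' Exact standard deviation of the total occurrence count of `kmer` over
#' independent stationary first-order Markov sequences of the given lengths.
#' The variance accounts for (a) the positive covariance of self-overlapping
#' occurrences at the word's overlap periods, (b) the negative covariance at
#' non-period overlapping distances (two occurrences closer than k that are
#' incompatible), and (c) the residual chain correlation between
#' non-overlapping occurrences, computed from powers of the transition matrix.
#'
#' @param model a `markov_model` (mono frequencies taken as the stationary
#'   position marginal).
#' @param kmer word over A/C/G/U.
#' @param lengths integer vector of sequence lengths being scanned.
#' @return standard deviation of the occurrence count.
#' @export
kmer_sd <- function(model, kmer, lengths) {
  w <- kmer_chars(kmer)
  k <- length(w)
  fe <- as.numeric(expected_kmer_freq(model, kmer))
  assert_that(fe > 0 && fe < 1, "kmer_sd: f_e must be in (0,1)")
  Q <- model$transition
  pi0 <- model$mono
  # joint occurrence probability at overlap distance d < k: only possible when
  # d is a period of the word, in which case the chain simply continues.
  periods <- logical(k - 1)
  cont <- numeric(k - 1)
  for (d in seq_len(k - 1)) {
    periods[d] <- all(w[seq_len(k - d)] == w[seq_len(k - d) + d])
    if (periods[d]) {
      idx <- (k - d):(k - 1)
      cont[d] <- prod(Q[cbind(w[idx], w[idx + 1])])
    }
  }
  tab <- table(lengths[lengths >= k])
  assert_that(length(tab) > 0, "kmer_sd: no sequence long enough")
  ls <- as.integer(names(tab))
  m_max <- max(ls) - k + 1
  # r_g = P(chain hits w1 again g steps after an occurrence ends) / pi(w1)
  g_max <- max(0L, m_max - k)
  rg <- numeric(g_max)
  wi <- match(w, APA_BASES)
  P <- diag(4)
  if (g_max > 0) {
    for (g in seq_len(g_max)) {
      P <- P %*% Q
      rg[g] <- P[wi[k], wi[1]] / pi0[w[1]]
    }
  }
  var_total <- 0
  for (j in seq_along(ls)) {
    m <- ls[j] - k + 1
    cov_sum <- 0
    if (m >= 2) {
      d <- seq_len(m - 1)
      pj <- numeric(m - 1)
      near <- d[d <= k - 1]
      pj[near] <- ifelse(periods[near], fe * cont[near], 0)
      far <- d[d >= k]
      if (length(far) > 0) pj[far] <- fe * fe * rg[far - k + 1]
      cov_sum <- sum((m - d) * (pj - fe^2))
    }
    var_l <- m * fe * (1 - fe) + 2 * cov_sum
    var_total <- var_total + as.integer(tab[j]) * var_l
  }
  sqrt(var_total)
}

#' Over-representation z-score
#'
#' @param O_o observed occurrence count.
#' @param O_e expected occurrence count.
#' @param SD overlap-corrected standard deviation (> 0).
#' @return `(O_o - O_e) / SD`.
#' @export
z_oe <- function(O_o, O_e, SD) {
  if (any(SD <= 0, na.rm = TRUE)) stop("z_oe: SD must be > 0")
  (O_o - O_e) / SD
}

#' Upper-tail cumulative binomial p-value for a k-mer count
#'
#' `P(X >= O_o)` with `X ~ Binomial(T, f_e)`, computed in log space so that
#' very small tail probabilities do not underflow prematurely.
#'
#' @param O_o observed count (0..T).
#' @param T_pos total scanned positions.
#' @param f_e per-position probability.
#' @param log10 if TRUE return log10 of the p-value.
#' @export
binom_pvalue <- function(O_o, T_pos, f_e, log10 = FALSE) {
  assert_that(all(f_e >= 0 & f_e <= 1), "binom_pvalue: f_e must be in [0,1]")
  assert_that(all(O_o >= 0 & O_o <= T_pos), "binom_pvalue: need 0 <= O_o <= T")
  lp <- pbinom(O_o - 1, T_pos, f_e, lower.tail = FALSE, log.p = TRUE)
  if (log10) lp / log(10) else exp(lp)
}

#' Simulate sequences from a Markov background model
#'
#' Stationary first-order chains: the first base is drawn from the model's
#' mononucleotide frequencies, subsequent bases from the transition matrix.
#'
#' @param model a `markov_model`.
#' @param n number of sequences.
#' @param len sequence length.
#' @param seed optional seed.
#' @return character vector of RNA sequences.
#' @export
simulate_markov <- function(model, n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- model$transition
  cum_pi <- cumsum(model$mono)
  cum_q <- t(apply(Q, 1, cumsum))
  M <- matrix(0L, nrow = n, ncol = len)
  u <- runif(n)
  cur <- 1L + (u > cum_pi[1]) + (u > cum_pi[2]) + (u > cum_pi[3])
  M[, 1] <- cur
  for (j in seq_len(len)[-1]) {
    u <- runif(n)
    cur <- 1L + (u > cum_q[cur, 1]) + (u > cum_q[cur, 2]) + (u > cum_q[cur, 3])
    M[, j] <- cur
  }
  chars <- matrix(APA_BASES[M], nrow = n)
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

#' Count (overlapping) occurrences of one word per sequence
#'
#' @param seqs character vector of RNA sequences.
#' @param kmer word to count.
#' @return integer vector of per-sequence occurrence counts.
#' @export
count_word <- function(seqs, kmer) {
  Biostrings::vcountPattern(rna(kmer), Biostrings::RNAStringSet(rna(seqs)))
}
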