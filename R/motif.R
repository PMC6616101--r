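#' Extract a relative-coordinate window from flank sequences
#'
#' Flanks are stored as upstream (-up..-1) and downstream (+1..+down) sense
#' sequences around the cleavage site; there is no position 0. Truncated
#' flanks (contig edges) are padded with `N` so that every window aligns on
#' the same relative coordinates; `N`-containing k-mer windows are skipped by
#' all counting routines.
#'
#' @param flanks data frame with columns `upstream`, `downstream` (see
#'   [extract_flank()]).
#' @param window integer(2): first and last relative coordinate (no 0).
#' @param up,down nominal flank extents.
#' @return character vector of window subsequences (one per flank).
#' @export
flank_window <- function(flanks, window, up = 300, down = 100) {
  stopifnot(length(window) == 2, window[1] <= window[2],
            window[1] != 0, window[2] != 0)
  assert_that(window[1] >= -up && window[2] <= down,
              "flank_window: window outside flank bounds")
  pad <- function(x, width, side) {
    need <- width - nchar(x)
    fill <- vapply(pmax(need, 0), function(n) strrep("N", n), "")
    if (side == "left") paste0(fill, x) else paste0(x, fill)
  }
  full <- paste0(pad(rna(flanks$upstream), up, "left"),
                 pad(rna(flanks$downstream), down, "right"))
  idx <- function(r) ifelse(r < 0, up + r + 1, up + r)
  substr(full, idx(window[1]), idx(window[2]))
}

#' Count all k-mers in a sequence set
#'
#' Overlapping occurrences are counted at every start position; windows
#' containing `N` are skipped.
#'
#' @param seqs character vector of RNA sequences.
#' @param k word length.
#' @return named integer vector over all 4^k words (lexicographic order).
#' @export
count_kmers <- function(seqs, k) {
  ss <- Biostrings::RNAStringSet(rna(seqs))
  colSums(Biostrings::oligonucleotideFrequency(ss, k))
}

#' Per-region k-mer over-representation table
#'
#' Observed counts, Markov-background expectations, overlap-corrected
#' z-scores and upper-tail binomial p-values for every k-mer in a relative
#' window of a flank set.
#'
#' @param flanks flank data frame (see [extract_flank()]).
#' @param window relative window, e.g. `c(-34, -13)`.
#' @param k word length (default 6).
#' @param model optional `markov_model`; defaults to a model fitted on the
#'   window sequences themselves.
#' @param sd_correct compute the overlap-corrected SD and z-score (set FALSE
#'   to skip the per-word variance computation).
#' @param up,down flank extents.
#' @return data frame: kmer, O_o, f_e, O_e, SD, z_oe, p_binom, log10_p.
#' @export
kmer_stats <- function(flanks, window, k = 6, model = NULL,
                       sd_correct = TRUE, up = 300, down = 100) {
  seqs <- flank_window(flanks, window, up = up, down = down)
  model <- model %||% fit_markov(seqs)
  counts <- count_kmers(seqs, k)
  T_pos <- sum(counts)
  lens <- rep(nchar(seqs[1]), length(seqs))
  fe <- vapply(names(counts), function(w) {
    as.numeric(expected_kmer_freq(model, w))
  }, numeric(1))
  Oe <- fe * T_pos
  SD <- rep(NA_real_, length(counts))
  if (sd_correct) {
    ok <- fe > 0 & fe < 1
    SD[ok] <- vapply(names(counts)[ok], function(w) {
      kmer_sd(model, w, lens)
    }, numeric(1))
  }
  z <- ifelse(!is.na(SD) & SD > 0, (counts - Oe) / SD, NA_real_)
  lp <- binom_pvalue(as.integer(counts), T_pos, fe, log10 = TRUE)
  data.frame(kmer = names(counts), O_o = as.integer(counts),
             f_e = fe, O_e = Oe, SD = SD, z_oe = z,
             p_binom = 10^lp, log10_p = lp,
             T_pos = T_pos, row.names = NULL, stringsAsFactors = FALSE)
}

# map window-substring indices back to relative coordinates
window_rel_positions <- function(window) rel_positions(window)

#' Positional statistics of a word within a relative window
#'
#' Mean and population SD of the relative start coordinates of all
#' (overlapping) occurrences of `kmer` whose span lies fully inside `window`,
#' pooled over all flanks.
#'
#' @inheritParams kmer_stats
#' @param kmer word to locate.
#' @return list with `mean_pos`, `pos_sd`, `n` (occurrence count). With zero
#'   occurrences the positions are `NA` and `n = 0`.
#' @export
positional_stats <- function(flanks, kmer, window, up = 300, down = 100) {
  seqs <- flank_window(flanks, window, up = up, down = down)
  rel <- rel_positions(window)
  hits <- Biostrings::vmatchPattern(rna(kmer), Biostrings::RNAStringSet(seqs))
  starts <- unlist(Biostrings::startIndex(hits), use.names = FALSE)
  if (is.null(starts) || length(starts) == 0) {
    return(list(mean_pos = NA_real_, pos_sd = NA_real_, n = 0L))
  }
  pos <- rel[starts]
  list(mean_pos = mean(pos), pos_sd = pop_sd(pos), n = length(pos))
}

#' Greedy selection of positionally coherent over-represented words
#'
#' Iteratively takes the most frequent k-mer in the current window set,
#' accepts it when its upper-tail binomial p-value is below `p_cut` and its
#' positional SD (always computed on the original, unmasked set) is at most
#' `sd_cut`, then removes every sequence containing the accepted word within
#' the window (or masks only the covered positions when
#' `removal = "mask"`). Words failing either rule are set aside and never
#' reconsidered. Ties on the count are broken lexicographically.
#'
#' @inheritParams kmer_stats
#' @param p_cut binomial p-value cutoff (default 1e-5).
#' @param sd_cut positional-SD cutoff in nt (default 7).
#' @param removal `"sequence"` (drop whole sequences, default) or `"mask"`.
#' @param pos_margin the dispersion statistics are computed on the window
#'   expanded by this many nt on each side. A scattered word cannot reach a
#'   positional SD above 7 inside a ~20-nt element window (a uniform spread
#'   there has SD ~5), so dispersion is judged on a wider scan; the default
#'   margin of 9 nt yields a ~40-nt scan in which a positionally coherent
#'   signal keeps its planted SD while a uniform decoy exceeds the cutoff.
#' @param min_count stop when the best remaining count falls below this.
#' @return data frame of accepted words in selection order with their
#'   original-set statistics (O_o, O_e, z_oe, p at selection, positional mean
#'   and SD, round number, sequences removed). Rejected candidates are kept
#'   in `attr(, "rejected")`.
#' @export
greedy_signal_selection <- function(flanks, window, k = 6, p_cut = 1e-5,
                                    sd_cut = 7, model = NULL,
                                    removal = c("sequence", "mask"),
                                    pos_margin = 9, min_count = 2L,
                                    up = 300, down = 100) {
  removal <- match.arg(removal)
  pos_win <- c(max(window[1] - pos_margin, -up),
               min(window[2] + pos_margin, down))
  if (pos_win[1] == 0) pos_win[1] <- 1
  if (pos_win[2] == 0) pos_win[2] <- -1
  orig <- flank_window(flanks, window, up = up, down = down)
  assert_that(nchar(orig[1]) >= k, "greedy_signal_selection: window too small")
  model <- model %||% fit_markov(orig)
  counts0 <- count_kmers(orig, k)
  T0 <- sum(counts0)
  lens0 <- rep(nchar(orig[1]), length(orig))
  fe_all <- vapply(names(counts0), function(w) {
    as.numeric(expected_kmer_freq(model, w))
  }, numeric(1))
  cur <- orig
  rejected <- character(0)
  rows <- list()
  round_i <- 0L
  # Between acceptances the count vector is unchanged, so rejected candidates
  # can be walked down in frequency order without recounting; only an
  # acceptance (which removes/masks sequences) triggers a recount. The cheap
  # binomial screen runs before the positional scan.
  repeat {
    if (length(cur) == 0) break
    counts <- count_kmers(cur, k)
    T_cur <- sum(counts)
    counts <- counts[setdiff(names(counts),
                             c(rejected, vapply(rows, `[[`, "", "kmer")))]
    counts <- counts[counts >= min_count]
    if (length(counts) == 0) break
    ord <- order(-counts, names(counts))
    found <- FALSE
    for (cand in names(counts)[ord]) {
      round_i <- round_i + 1L
      fe <- fe_all[[cand]]
      p_cur <- binom_pvalue(as.integer(counts[cand]), T_cur, fe)
      if (!is.finite(p_cur) || p_cur >= p_cut) {
        rejected <- c(rejected, cand)
        next
      }
      ps <- positional_stats(flanks, cand, pos_win, up = up, down = down)
      if (is.na(ps$pos_sd) || ps$pos_sd > sd_cut) {
        rejected <- c(rejected, cand)
        next
      }
      has <- count_word(cur, cand) > 0
      n_rm <- sum(has)
      if (removal == "sequence") {
        cur <- cur[!has]
      } else {
        hits <- Biostrings::vmatchPattern(rna(cand),
                                          Biostrings::RNAStringSet(cur))
        for (i in which(has)) {
          for (s in Biostrings::startIndex(hits)[[i]]) {
            substr(cur[i], s, s + k - 1) <- strrep("N", k)
          }
        }
      }
      Oe0 <- fe * T0
      SD0 <- if (fe > 0 && fe < 1) kmer_sd(model, cand, lens0) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        kmer = cand, O_o = as.integer(counts0[cand]), O_e = Oe0,
        z_oe = if (!is.na(SD0) && SD0 > 0) (counts0[cand] - Oe0) / SD0
               else NA_real_,
        p_binom = binom_pvalue(as.integer(counts0[cand]), T0, fe),
        p_at_selection = p_cur,
        mean_pos = ps$mean_pos, pos_sd = ps$pos_sd,
        coverage = mean(count_word(orig, cand) > 0),
        round = round_i, n_removed = n_rm,
        stringsAsFactors = FALSE)
      found <- TRUE
      break
    }
    if (!found) break
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kmer = character(0), O_o = integer(0), O_e = numeric(0),
               z_oe = numeric(0), p_binom = numeric(0),
               p_at_selection = numeric(0), mean_pos = numeric(0),
               pos_sd = numeric(0), coverage = numeric(0),
               round = integer(0), n_removed = integer(0))
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Two-proportion z statistic for strong-vs-weak word frequencies
#'
#' Compares the per-position occurrence rate of a word between the strong-site
#' and weak-site sequence sets using the pooled-proportion two-sample z. The
#' dimensionally inconsistent printed variant (raw count difference over the
#' proportion-scale standard error) is available via `printed_form = TRUE`.
#'
#' @param O_s,O_w occurrence counts in the strong and weak sets.
#' @param N_s,N_w total scanned positions in each set.
#' @param printed_form use the raw-count numerator variant.
#' @return data frame with pooled `p`, `z_sw` and two-sided normal `p_value`;
#'   `z_sw` is `NA` (flagged) when the pooled proportion is 0 or 1.
#' @export
z_sw <- function(O_s, O_w, N_s, N_w, printed_form = FALSE) {
  assert_that(all(N_s > 0) && all(N_w > 0), "z_sw: N_s and N_w must be > 0")
  assert_that(all(O_s <= N_s) && all(O_w <= N_w), "z_sw: counts exceed totals")
  p <- (O_s + O_w) / (N_s + N_w)
  se <- sqrt(p * (1 - p) * (1 / N_s + 1 / N_w))
  num <- if (printed_form) (O_s - O_w) else (O_s / N_s - O_w / N_w)
  z <- ifelse(p > 0 & p < 1, num / se, NA_real_)
  data.frame(p = p, z_sw = z, p_value = 2 * pnorm(-abs(z)))
}

#' Strong-vs-weak k-mer table for one signal region
#'
#' @param strong_flanks,weak_flanks flank data frames for the two site sets.
#' @inheritParams kmer_stats
#' @return data frame: kmer, O_s, O_w, N_s, N_w, pooled p, z_sw, p_value.
#' @export
strong_weak_stats <- function(strong_flanks, weak_flanks, window, k = 6,
                              up = 300, down = 100) {
  cs <- count_kmers(flank_window(strong_flanks, window, up, down), k)
  cw <- count_kmers(flank_window(weak_flanks, window, up, down), k)
  Ns <- sum(cs)
  Nw <- sum(cw)
  zz <- z_sw(as.integer(cs), as.integer(cw), Ns, Nw)
  data.frame(kmer = names(cs), O_s = as.integer(cs), O_w = as.integer(cw),
             N_s = Ns, N_w = Nw, p = zz$p, z_sw = zz$z_sw,
             p_value = zz$p_value, row.names = NULL,
             stringsAsFactors = FALSE)
}
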