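#' Classify poly(A) sites by usage within their gene
#'
#' Per gene (reads pooled over all samples): a single site is `unique`; a
#' site carrying strictly more than `threshold` (default 70%) of the gene's
#' reads is `strong` and its siblings are `weak`; multi-site genes without a
#' strong site have all sites `universal`. Genes with zero total reads leave
#' their sites unclassified (`NA`, flagged with a warning).
#'
#' @param sites data frame with columns `site_id`, `gene_id`, `reads`
#'   (total reads per site pooled over samples).
#' @param threshold strong-site read-share threshold (strict inequality).
#' @return data frame: site_id, gene_id, share, class.
#' @export
classify_sites <- function(sites, threshold = 0.7) {
  assert_that(all(c("site_id", "gene_id", "reads") %in% names(sites)),
              "classify_sites: need site_id, gene_id, reads columns")
  assert_that(all(sites$reads >= 0), "classify_sites: negative read counts")
  out <- sites[, c("site_id", "gene_id")]
  out$share <- NA_real_
  out$class <- NA_character_
  for (g in unique(sites$gene_id)) {
    idx <- which(sites$gene_id == g)
    tot <- sum(sites$reads[idx])
    if (tot == 0) {
      warning(sprintf("gene %s has zero total reads; sites unclassified", g))
      next
    }
    share <- sites$reads[idx] / tot
    out$share[idx] <- share
    if (length(idx) == 1) {
      out$class[idx] <- "unique"
    } else if (any(share > threshold)) {
      out$class[idx] <- ifelse(share > threshold, "strong", "weak")
    } else {
      out$class[idx] <- "universal"
    }
  }
  out
}

#' Sample control pseudo-sites at signal-bearing random genomic positions
#'
#' Finds genomic AAUAAA occurrences (both strands), keeps those with no real
#' poly(A) site within `exclusion` nt of the hexamer, and places a
#' pseudo-cleavage site so that the hexamer starts at relative position
#' `-signal_offset` of the control site (mirroring the observed signal
#' position upstream of true sites). Sampling is uniform without replacement.
#'
#' @param genome named `DNAStringSet` (or list of character sequences).
#' @param true_sites data frame with `chrom`, `position` of real sites.
#' @param n number of controls requested.
#' @param seed RNG seed (optional).
#' @param signal_offset relative start position of the hexamer (default 23,
#'   i.e. the hexamer occupies -23..-18).
#' @param exclusion no true site within this many nt of the hexamer start.
#' @return data frame: site_id, chrom, strand, position.
#' @export
sample_control_sites <- function(genome, true_sites, n, seed = NULL,
                                 signal_offset = 23, exclusion = 50) {
  assert_that(n >= 1, "sample_control_sites: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  genome <- as_genome(genome)
  cand <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    fwd <- Biostrings::start(Biostrings::matchPattern("AATAAA", subj))
    rev <- Biostrings::start(Biostrings::matchPattern("TTTATT", subj))
    true_pos <- true_sites$position[true_sites$chrom == chrom]
    keep_clear <- function(hex_start) {
      if (length(true_pos) == 0) return(rep(TRUE, length(hex_start)))
      vapply(hex_start, function(g) all(abs(true_pos - g) > exclusion),
             logical(1))
    }
    # '+' strand: sense hexamer starts at g; the pseudo-site sits so that the
    # hexamer start maps to relative -signal_offset (relative r<0 maps to
    # genomic p + r + 1), hence p = g + signal_offset - 1.
    if (length(fwd) > 0) {
      ok <- keep_clear(fwd)
      p <- fwd[ok] + signal_offset - 1
      valid <- p >= 1 & p <= length(subj)
      if (any(valid)) {
        cand[[length(cand) + 1]] <- data.frame(
          chrom = chrom, strand = "+", position = p[valid],
          stringsAsFactors = FALSE)
      }
    }
    # '-' strand: TTTATT at plus-strand start g is a sense AAUAAA whose first
    # sense base sits at plus coordinate g + 5; relative r<0 maps to genomic
    # p - r - 1, hence p = (g + 5) - signal_offset + 1.
    if (length(rev) > 0) {
      ok <- keep_clear(rev)
      p <- rev[ok] + 6 - signal_offset
      valid <- p >= 1 & p <= length(subj)
      if (any(valid)) {
        cand[[length(cand) + 1]] <- data.frame(
          chrom = chrom, strand = "-", position = p[valid],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) {
    warning("sample_control_sites: no qualifying AAUAAA occurrence")
    return(data.frame(site_id = character(0), chrom = character(0),
                      strand = character(0), position = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$chrom, cand$position, cand$strand), ]
  if (nrow(cand) < n) {
    warning(sprintf("only %d qualifying positions for %d requested controls",
                    nrow(cand), n))
    pick <- seq_len(nrow(cand))
  } else {
    pick <- sample.int(nrow(cand), n)
  }
  out <- cand[pick, ]
  out <- data.frame(site_id = sprintf("ctrl_%05d", seq_len(nrow(out))),
                    out, row.names = NULL, stringsAsFactors = FALSE)
  out
}
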