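# genome coercion: accept DNAStringSet, named character vector, or list
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(unlist(genome))
}

# sense-strand relative coordinate -> plus-strand genomic coordinate.
# Relative -1 is the cleavage (last templated) nucleotide at position p;
# there is no relative 0.
rel_to_genomic <- function(p, r, strand) {
  stopifnot(all(r != 0))
  n <- max(length(p), length(r), length(strand))
  p <- rep_len(p, n)
  r <- rep_len(r, n)
  strand <- rep_len(strand, n)
  ifelse(strand == "+",
         ifelse(r < 0, p + r + 1, p + r),
         ifelse(r < 0, p - r - 1, p - r))
}

#' Cluster cleavage events into poly(A) site clusters
#'
#' Single-linkage chaining per chromosome and strand: adjacent events at most
#' `max_gap` nt apart join the same cluster. The representative position is
#' the member with the highest total read count (ties broken towards the most
#' downstream member in the direction of transcription); per-stage counts are
#' summed over members.
#'
#' @param events data frame with `event_id`, `chrom`, `strand`, `position`.
#' @param counts numeric matrix of per-stage counts, rownames = event ids.
#' @param max_gap maximum gap between adjacent members (default 24).
#' @return list: `sites` (site_id, chrom, strand, position, n_events,
#'   total_reads), `counts` (site x stage), `members` (event_id -> site_id).
#' @export
cluster_cleavage_events <- function(events, counts, max_gap = 24) {
  assert_that(max_gap >= 0, "max_gap must be >= 0")
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0), "negative counts rejected")
  assert_that(!anyDuplicated(events[c("chrom", "strand", "position")]),
              "duplicate (chrom, strand, position) events")
  assert_that(all(events$position >= 1), "positions must be >= 1")
  counts <- counts[match(events$event_id, rownames(counts)), , drop = FALSE]
  assert_that(!anyNA(counts), "every event needs a count row")
  assert_that(all(rowSums(counts) > 0), "each event needs at least one read")

  ord <- order(events$chrom, events$strand, events$position)
  ev <- events[ord, ]
  cnt <- counts[ord, , drop = FALSE]
  key <- paste(ev$chrom, ev$strand)
  new_grp <- c(TRUE, key[-1] != key[-nrow(ev)] |
                 diff(ev$position) > max_gap)
  grp <- cumsum(new_grp)

  tot <- rowSums(cnt)
  site_rows <- lapply(split(seq_len(nrow(ev)), grp), function(idx) {
    strand <- ev$strand[idx[1]]
    t_i <- tot[idx]
    best <- which(t_i == max(t_i))
    # tie: most downstream in transcription direction
    rep_i <- if (strand == "+") best[length(best)] else best[1]
    data.frame(chrom = ev$chrom[idx[1]], strand = strand,
               position = ev$position[idx[rep_i]],
               n_events = length(idx), total_reads = sum(t_i),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_rows)
  sites <- data.frame(site_id = sprintf("PAC%06d", seq_len(nrow(sites))),
                      sites, row.names = NULL, stringsAsFactors = FALSE)
  site_counts <- rowsum(cnt, grp, reorder = TRUE)
  rownames(site_counts) <- sites$site_id
  members <- data.frame(event_id = ev$event_id,
                        site_id = sites$site_id[grp],
                        stringsAsFactors = FALSE)
  list(sites = sites, counts = site_counts, members = members)
}

# sense-strand downstream DNA window +1..+len of a site
downstream_window <- function(chrom_seq, position, strand, len = 10) {
  L <- nchar(chrom_seq)
  if (strand == "+") {
    from <- position + 1
    to <- min(position + len, L)
    if (from > L) return("")
    substr(chrom_seq, from, to)
  } else if (strand == "-") {
    from <- max(position - len, 1)
    to <- position - 1
    if (to < 1) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chrom_seq, from, to))))
  } else {
    stop(sprintf("unknown strand '%s'", strand))
  }
}

max_run <- function(chars, base = "A") {
  r <- rle(chars == base)
  m <- r$lengths[r$values]
  if (length(m) == 0) 0L else max(m)
}

#' Internal-priming (A-rich) filter for poly(A) site clusters
#'
#' Inspects the sense-strand 10-nt window immediately downstream (+1..+10) of
#' each representative position and reports, in order: `fail_ARS` when the
#' window holds six or more adenines; `fail_tetramer` when positions +1..+4
#' are exactly AAAA, AGAA, AAGA or AAAG; `fail_runA` when the window holds a
#' run of more than five consecutive adenines; otherwise `pass`. The first
#' failing rule is reported. Sites with fewer than 10 nt of downstream genome
#' are kept and flagged as edge cases.
#'
#' @param sites data frame with `site_id`, `chrom`, `strand`, `position`.
#' @param genome named DNAStringSet or character list.
#' @return data frame: site_id, filter_status, window (the inspected
#'   downstream sequence), edge (logical).
#' @export
filter_a_rich <- function(sites, genome) {
  genome <- as_genome(genome)
  chars <- lapply(as.character(genome), identity)
  assert_that(all(sites$strand %in% c("+", "-")), "unknown strand rejected")
  assert_that(all(sites$chrom %in% names(chars)),
              "site chromosome absent from genome")
  n <- nrow(sites)
  status <- character(n)
  win_out <- character(n)
  edge <- logical(n)
  tet <- c("AAAA", "AGAA", "AAGA", "AAAG")
  for (i in seq_len(n)) {
    win <- downstream_window(chars[[sites$chrom[i]]], sites$position[i],
                             sites$strand[i], 10)
    win_out[i] <- win
    if (nchar(win) < 10) {
      edge[i] <- TRUE
      status[i] <- "pass"
      next
    }
    wc <- strsplit(win, "")[[1]]
    if (sum(wc == "A") >= 6) {
      status[i] <- "fail_ARS"
    } else if (substr(win, 1, 4) %in% tet) {
      status[i] <- "fail_tetramer"
    } else if (max_run(wc, "A") >= 6) {
      status[i] <- "fail_runA"
    } else {
      status[i] <- "pass"
    }
  }
  data.frame(site_id = sites$site_id, filter_status = status,
             window = win_out, edge = edge, stringsAsFactors = FALSE)
}

#' Extract transcribed flanking sequence around poly(A) sites
#'
#' Returns the sense-strand sequence covering relative positions `-up..-1`
#' (upstream, ending at the cleavage nucleotide) and `+1..+down` (downstream)
#' for each site, reverse-complemented for minus-strand sites and transcribed
#' (T -> U). Flanks truncated at contig edges are shorter and flagged.
#'
#' @param sites data frame with `site_id`, `chrom`, `strand`, `position`.
#' @param genome named DNAStringSet or character list.
#' @param up,down flank extents (defaults 300 and 100).
#' @return data frame: site_id, upstream, downstream, up_trunc, down_trunc.
#' @export
extract_flank <- function(sites, genome, up = 300, down = 100) {
  genome <- as_genome(genome)
  missing <- setdiff(unique(sites$chrom), names(genome))
  assert_that(length(missing) == 0,
              sprintf("chromosome(s) absent from genome: %s",
                      paste(missing, collapse = ", ")))
  chars <- as.character(genome)
  n <- nrow(sites)
  upseq <- character(n)
  dnseq <- character(n)
  up_tr <- logical(n)
  dn_tr <- logical(n)
  rc <- function(x) {
    if (nchar(x) == 0) return(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  for (i in seq_len(n)) {
    cs <- chars[[sites$chrom[i]]]
    L <- nchar(cs)
    p <- sites$position[i]
    if (sites$strand[i] == "+") {
      uf <- max(p - up + 1, 1)
      upseq[i] <- substr(cs, uf, p)
      up_tr[i] <- uf > p - up + 1
      dt <- min(p + down, L)
      dnseq[i] <- if (p + 1 <= L) substr(cs, p + 1, dt) else ""
      dn_tr[i] <- dt < p + down
    } else {
      ut <- min(p + up - 1, L)
      upseq[i] <- rc(substr(cs, p, ut))
      up_tr[i] <- ut < p + up - 1
      df <- max(p - down, 1)
      dnseq[i] <- if (p - 1 >= 1) rc(substr(cs, df, p - 1)) else ""
      dn_tr[i] <- df > p - down
    }
  }
  data.frame(site_id = sites$site_id, upstream = rna(upseq),
             downstream = rna(dnseq), up_trunc = up_tr, down_trunc = dn_tr,
             stringsAsFactors = FALSE)
}
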