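SCHEMA_WINDOWS <- list(
  `3UTR` = data.frame(
    name = c("USE", "PE", "CEL", "CER", "DSE"),
    start = c(-100, -34, -12, 1, 34),
    end = c(-35, -13, -3, 33, 100), stringsAsFactors = FALSE),
  `5UTR` = data.frame(
    name = c("USE", "PE", "CE", "DSE"),
    start = c(-100, -40, -10, 10),
    end = c(-40, -10, 10, 100), stringsAsFactors = FALSE),
  CDS = data.frame(
    name = c("USE", "CE", "DSE"),
    start = c(-100, -30, 30),
    end = c(-30, 30, 100), stringsAsFactors = FALSE),
  intron = data.frame(
    name = c("USE", "PE", "CEL", "CER", "DSE"),
    start = c(-100, -40, -10, 1, 30),
    end = c(-40, -10, -1, 30, 100), stringsAsFactors = FALSE))

#' Signal-region windows for a genomic site class
#'
#' Returns the named signal windows (relative to the cleavage site, -1 = last
#' transcribed nucleotide) of the region model for 3'UTR, 5'UTR, CDS or
#' intronic poly(A) sites. 3'UTR sites use the five-element model (USE, PE,
#' CEL, CER, DSE); 5'UTR and CDS use merged cleavage elements.
#'
#' @param site_class one of `"3UTR"`, `"5UTR"`, `"CDS"`, `"intron"`.
#' @return data frame: name, start, end (relative offsets).
#' @export
segment_regions <- function(site_class) {
  assert_that(site_class %in% names(SCHEMA_WINDOWS),
              sprintf("unknown site class '%s'", site_class))
  out <- SCHEMA_WINDOWS[[site_class]]
  attr(out, "site_class") <- site_class
  out
}

#' Select significant hexamers by the (z_oe, z_sw) cutoff pair
#'
#' Keeps words whose over-representation z-score exceeds the region's
#' empirical upper `1 - zoe_pct` quantile (the distribution-based p < 0.01
#' screen by default) and, when strong/weak statistics are supplied, whose
#' strong-vs-weak z is at least `zsw_cut`.
#'
#' @param kstats output of [kmer_stats()].
#' @param swstats optional output of [strong_weak_stats()].
#' @param zoe_pct quantile of the z_oe distribution (default 0.99).
#' @param zoe_cut explicit z_oe cutoff overriding the quantile.
#' @param zsw_cut strong-vs-weak cutoff (default 1.96).
#' @return character vector of selected words.
#' @export
select_significant_hexamers <- function(kstats, swstats = NULL,
                                        zoe_pct = 0.99, zoe_cut = NULL,
                                        zsw_cut = 1.96) {
  if (nrow(kstats) == 0) return(character(0))
  thr <- zoe_cut %||% quantile(kstats$z_oe, zoe_pct, na.rm = TRUE,
                               names = FALSE)
  sel <- !is.na(kstats$z_oe) & kstats$z_oe >= thr & kstats$O_o > 0
  if (!is.null(swstats)) {
    zsw <- swstats$z_sw[match(kstats$kmer, swstats$kmer)]
    sel <- sel & !is.na(zsw) & zsw >= zsw_cut
  }
  kstats$kmer[sel]
}

#' Shift-penalised mismatch distance between two words
#'
#' `min` over relative shifts `s` in `-max_shift..max_shift` of (mismatches
#' in the overlapping positions + `shift_penalty * |s|`).
#'
#' @param a,b words (equal length not required).
#' @param max_shift maximum |shift| examined (default 3).
#' @param shift_penalty cost per shifted position (default 0.5).
#' @export
hexamer_distance <- function(a, b, max_shift = 3, shift_penalty = 0.5) {
  ca <- strsplit(rna(a), "")[[1]]
  cb <- strsplit(rna(b), "")[[1]]
  best <- Inf
  for (s in -max_shift:max_shift) {
    ia <- seq_along(ca)
    ib <- ia - s
    keep <- ib >= 1 & ib <= length(cb)
    if (!any(keep)) next
    d <- sum(ca[keep] != cb[ib[keep]]) + shift_penalty * abs(s)
    best <- min(best, d)
  }
  best
}

#' Group hexamers by average-linkage clustering of the shift distance
#'
#' @param hexamers character vector (>= 1 word).
#' @param cutoff tree height at which to cut (default 2.6).
#' @return list of character vectors (groups), largest first; within and
#'   across groups members are sorted so that the grouping is invariant to
#'   input order.
#' @export
cluster_hexamers <- function(hexamers, cutoff = 2.6) {
  hexamers <- sort(unique(hexamers))
  assert_that(length(hexamers) >= 1, "cluster_hexamers: no hexamers")
  if (length(hexamers) == 1) return(list(hexamers))
  n <- length(hexamers)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- hexamer_distance(hexamers[i], hexamers[j])
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  grp <- cutree(hc, h = cutoff)
  groups <- split(hexamers, grp)
  names(groups) <- NULL
  groups[order(-vapply(groups, length, integer(1)),
               vapply(groups, `[`, "", 1))]
}

IUPAC_RNA <- c(A = "A", C = "C", G = "G", U = "U",
               AG = "R", CU = "Y", GU = "K", AC = "M", CG = "S", AU = "W",
               CGU = "B", AGU = "D", ACU = "H", ACG = "V", ACGU = "N")

#' Align a hexamer group and build its consensus and PFM
#'
#' Members are aligned at their distance-minimising shift relative to the
#' group medoid (the member with the smallest total distance to the others;
#' shift ties resolved towards the smallest |shift|, then the left-most).
#' The position frequency matrix counts bases per alignment column; columns
#' covered by every member sum to the group size. The consensus takes the
#' per-column majority base, with ties encoded as IUPAC ambiguity codes.
#'
#' @param group character vector of words.
#' @param label element label (e.g. `"PE.1"`).
#' @return list: label, members, medoid, shifts, consensus, pfm (4 x columns
#'   matrix with A/C/G/U rows).
#' @export
align_and_consensus <- function(group, label = "") {
  assert_that(length(group) >= 1, "align_and_consensus: empty group")
  group <- sort(group)
  if (length(group) == 1) {
    shifts <- setNames(0L, group)
    medoid <- group
  } else {
    tot <- vapply(group, function(a) {
      sum(vapply(group, function(b) hexamer_distance(a, b), numeric(1)))
    }, numeric(1))
    medoid <- group[which.min(tot)]
    shifts <- vapply(group, function(b) {
      best_d <- Inf
      best_s <- 0L
      ca <- strsplit(medoid, "")[[1]]
      cb <- strsplit(b, "")[[1]]
      for (s in -3:3) {
        ia <- seq_along(cb)
        im <- ia + s
        keep <- im >= 1 & im <= length(ca)
        if (!any(keep)) next
        d <- sum(cb[keep] != ca[im[keep]]) + 0.5 * abs(s)
        better <- d < best_d - 1e-9 ||
          (abs(d - best_d) < 1e-9 &&
             (abs(s) < abs(best_s) || (abs(s) == abs(best_s) && s < best_s)))
        if (better) {
          best_d <- d
          best_s <- s
        }
      }
      # best_s: offset of the member's first base in medoid coordinates
      best_s
    }, numeric(1))
    shifts <- setNames(as.integer(shifts), group)
  }
  lo <- min(shifts)
  hi <- max(shifts + nchar(group) - 1)
  ncol_al <- hi - lo + 1
  pfm <- matrix(0L, 4, ncol_al, dimnames = list(APA_BASES, NULL))
  for (i in seq_along(group)) {
    chars <- strsplit(group[i], "")[[1]]
    cols <- shifts[i] - lo + seq_along(chars)
    for (j in seq_along(chars)) {
      pfm[chars[j], cols[j]] <- pfm[chars[j], cols[j]] + 1L
    }
  }
  consensus <- vapply(seq_len(ncol_al), function(j) {
    col <- pfm[, j]
    if (sum(col) == 0) return("-")
    top <- APA_BASES[col == max(col)]
    IUPAC_RNA[[paste(sort(top), collapse = "")]]
  }, "")
  list(label = label, members = group, medoid = medoid, shifts = shifts,
       consensus = paste(consensus, collapse = ""), pfm = pfm)
}

#' Per-position nucleotide profile of aligned flanks
#'
#' @param flanks flank data frame.
#' @param range relative range, default the full -300..+100 flank.
#' @param up,down flank extents.
#' @return data frame: position, A, C, G, U fractions (summing to 1 where
#'   covered), n (non-N coverage).
#' @export
nucleotide_profile <- function(flanks, range = c(-300, 100), up = 300,
                               down = 100) {
  seqs <- flank_window(flanks, range, up = up, down = down)
  rel <- rel_positions(range)
  M <- do.call(rbind, strsplit(seqs, ""))
  out <- data.frame(position = rel, A = NA_real_, C = NA_real_,
                    G = NA_real_, U = NA_real_, n = 0L)
  for (j in seq_along(rel)) {
    col <- M[, j]
    col <- col[col %in% APA_BASES]
    out$n[j] <- length(col)
    if (length(col) == 0) next
    for (b in APA_BASES) out[[b]][j] <- mean(col == b)
  }
  out
}

#' Build the full cis-element schema for one genomic site class
#'
#' For every signal window of the class: fit the Markov background on the
#' window sequences, compute the k-mer over-representation table, screen by
#' the (z_oe quantile, z_sw) cutoff pair, cluster the selected words, and
#' emit aligned consensus elements labelled `<WINDOW>.<rank>` (rank by member
#' count).
#'
#' @param flanks flanks of the class's sites.
#' @param site_class `"3UTR"`, `"5UTR"`, `"CDS"` or `"intron"`.
#' @param strong_flanks,weak_flanks optional flank sets for the
#'   strong-vs-weak screen (omit to screen on z_oe alone).
#' @param k word length (default 6).
#' @param zoe_pct,zsw_cut,cluster_cutoff screening/clustering parameters.
#' @param up,down flank extents.
#' @return list: `site_class`, `windows`, `elements` (data frame), `groups`
#'   (per-element alignment objects).
#' @export
build_schema <- function(flanks, site_class, strong_flanks = NULL,
                         weak_flanks = NULL, k = 6, zoe_pct = 0.99,
                         zsw_cut = 1.96, cluster_cutoff = 2.6,
                         up = 300, down = 100) {
  windows <- segment_regions(site_class)
  elements <- list()
  groups <- list()
  for (wi in seq_len(nrow(windows))) {
    win <- c(windows$start[wi], windows$end[wi])
    wname <- windows$name[wi]
    ks <- kmer_stats(flanks, win, k = k, up = up, down = down)
    sw <- if (!is.null(strong_flanks) && !is.null(weak_flanks)) {
      strong_weak_stats(strong_flanks, weak_flanks, win, k = k,
                        up = up, down = down)
    }
    sel <- select_significant_hexamers(ks, sw, zoe_pct = zoe_pct,
                                       zsw_cut = zsw_cut)
    if (length(sel) == 0) next
    grps <- cluster_hexamers(sel, cutoff = cluster_cutoff)
    for (gi in seq_along(grps)) {
      label <- sprintf("%s.%d", wname, gi)
      al <- align_and_consensus(grps[[gi]], label = label)
      groups[[label]] <- al
      elements[[length(elements) + 1]] <- data.frame(
        region = wname, label = label, n_members = length(grps[[gi]]),
        consensus = al$consensus,
        members = paste(grps[[gi]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  elements <- if (length(elements)) {
    do.call(rbind, c(elements, make.row.names = FALSE))
  } else {
    data.frame(region = character(0), label = character(0),
               n_members = integer(0), consensus = character(0),
               members = character(0))
  }
  list(site_class = site_class, windows = windows, elements = elements,
       groups = groups)
}
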