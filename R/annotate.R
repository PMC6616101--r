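#' Derive intron intervals per transcript from exon rows
#'
#' @param features gene-model data frame with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `type`, `start`, `end` (1-based
#'   inclusive; types include `exon`, `CDS`, `five_prime_UTR`,
#'   `three_prime_UTR`).
#' @return data frame of intron rows in the same layout (`type = "intron"`).
#' @export
derive_introns <- function(features) {
  ex <- features[features$type == "exon", ]
  out <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    out[[tx]] <- data.frame(
      gene_id = e$gene_id[1], transcript_id = tx, chrom = e$chrom[1],
      strand = e$strand[1], type = "intron",
      start = e$end[-nrow(e)] + 1, end = e$start[-1] - 1,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(features[0, c("gene_id", "transcript_id", "chrom", "strand",
                         "type", "start", "end")])
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

validate_gene_models <- function(features) {
  cds <- features[features$type == "CDS", ]
  ex <- features[features$type == "exon", ]
  for (tx in unique(cds$transcript_id)) {
    ci <- IRanges::IRanges(cds$start[cds$transcript_id == tx],
                           cds$end[cds$transcript_id == tx])
    ei <- IRanges::IRanges(ex$start[ex$transcript_id == tx],
                           ex$end[ex$transcript_id == tx])
    uncovered <- IRanges::setdiff(ci, ei)
    if (length(uncovered) > 0) {
      stop(sprintf("malformed gene model: CDS outside exons in gene %s",
                   cds$gene_id[cds$transcript_id == tx][1]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

features_granges <- function(features, type) {
  f <- features[features$type == type, ]
  f <- f[order(f$gene_id, f$transcript_id, f$start), ]
  GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end),
                         strand = f$strand, gene_id = f$gene_id)
}

#' Assign each poly(A) site to a genomic region
#'
#' Strand-specific assignment with precedence 3UTR > CDS > 5UTR > intron
#' across all overlapping same-strand transcripts. Sites outside every
#' transcript but within `extension` nt downstream of a same-strand gene 3'
#' end are `Ex_3UTR` (nearest gene, distance recorded); within `extension`
#' upstream of a 5' end, `Ex_5UTR`; otherwise `intergenic`.
#'
#' @param sites data frame with `site_id`, `chrom`, `strand`, `position`.
#' @param features gene-model data frame (see [derive_introns()]).
#' @param extension extension length in nt (default 1000).
#' @return data frame: site_id, gene_id (NA if intergenic), region,
#'   distance_to_end (Ex regions only).
#' @export
assign_region <- function(sites, features, extension = 1000) {
  validate_gene_models(features)
  introns <- derive_introns(features)
  feat <- rbind(features[, c("gene_id", "transcript_id", "chrom", "strand",
                             "type", "start", "end")], introns)
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$position,
                                                 sites$position),
                                strand = sites$strand)
  n <- nrow(sites)
  region <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  precedence <- c("3UTR" = "three_prime_UTR", "CDS" = "CDS",
                  "5UTR" = "five_prime_UTR", "intron" = "intron")
  for (lab in names(precedence)) {
    gr <- features_granges(feat, precedence[[lab]])
    if (length(gr) == 0) next
    hits <- GenomicRanges::findOverlaps(sgr, gr)
    qh <- queryHits(hits)
    first <- !duplicated(qh) & is.na(region[qh])
    sel <- qh[first]
    region[sel] <- lab
    gene[sel] <- gr$gene_id[subjectHits(hits)[first]]
  }
  # gene termini for extension assignment
  ex <- feat[feat$type == "exon", ]
  term <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  todo <- which(is.na(region))
  for (i in todo) {
    same <- term[term$chrom == sites$chrom[i] &
                   term$strand == sites$strand[i], ]
    if (nrow(same) > 0) {
      p <- sites$position[i]
      d3 <- if (sites$strand[i] == "+") p - same$end else same$start - p
      d5 <- if (sites$strand[i] == "+") same$start - p else p - same$end
      ok3 <- which(d3 >= 1 & d3 <= extension)
      ok5 <- which(d5 >= 1 & d5 <= extension)
      if (length(ok3) > 0) {
        j <- ok3[which.min(d3[ok3])]
        region[i] <- "Ex_3UTR"
        gene[i] <- same$gene_id[j]
        dist[i] <- d3[j]
        next
      }
      if (length(ok5) > 0) {
        j <- ok5[which.min(d5[ok5])]
        region[i] <- "Ex_5UTR"
        gene[i] <- same$gene_id[j]
        dist[i] <- d5[j]
        next
      }
    }
    region[i] <- "intergenic"
  }
  data.frame(site_id = sites$site_id, gene_id = gene, region = region,
             distance_to_end = dist, stringsAsFactors = FALSE)
}

#' APA gene category from the site count
#'
#' 0 sites = `non`, 1 = `rare`, 2-4 = `moderate`, 5 or more = `abundant`.
#'
#' @param total integer vector of per-gene APA site counts.
#' @export
apa_gene_category <- function(total) {
  assert_that(all(total >= 0), "total must be >= 0")
  cut(total, breaks = c(-0.5, 0.5, 1.5, 4.5, Inf),
      labels = c("non", "rare", "moderate", "abundant"))
}

#' Per-gene APA frequency statistics
#'
#' @param annotations output of [assign_region()].
#' @param features gene-model data frame.
#' @return data frame per gene: length, intron count, mean intron length,
#'   per-region site frequencies, proximal (5UTR+CDS+intron) and distal
#'   (3UTR+Ex_3UTR) frequencies, total, category.
#' @export
gene_apa_stats <- function(annotations, features) {
  introns <- derive_introns(features)
  ex <- features[features$type == "exon", ]
  genes <- unique(features$gene_id)
  regions <- c("3UTR", "Ex_3UTR", "5UTR", "Ex_5UTR", "CDS", "intron")
  tab <- table(factor(annotations$gene_id, levels = genes),
               factor(annotations$region, levels = regions))
  freq <- as.data.frame.matrix(tab)
  names(freq) <- paste0("freq_", regions)
  span <- vapply(genes, function(g) {
    e <- ex[ex$gene_id == g, ]
    max(e$end) - min(e$start) + 1
  }, numeric(1))
  n_intron <- vapply(genes, function(g) {
    sum(introns$gene_id == g)
  }, numeric(1))
  mean_intron <- vapply(genes, function(g) {
    ii <- introns[introns$gene_id == g, ]
    if (nrow(ii) == 0) 0 else mean(ii$end - ii$start + 1)
  }, numeric(1))
  out <- data.frame(gene_id = genes, length = span, n_introns = n_intron,
                    mean_intron_length = mean_intron, freq,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$proximal <- out$freq_5UTR + out$freq_CDS + out$freq_intron
  out$distal <- out$freq_3UTR + out$freq_Ex_3UTR
  out$total <- rowSums(out[paste0("freq_", regions)])
  out$category <- apa_gene_category(out$total)
  out
}

#' APA ratio of a region
#'
#' Number of sites assigned to `region` divided by the number of distinct
#' genes owning them.
#'
#' @param annotations output of [assign_region()].
#' @param region region label.
#' @return the ratio, or `NA` with a warning when no gene owns a site there.
#' @export
apa_ratio <- function(annotations, region) {
  sel <- annotations$region == region & !is.na(annotations$gene_id)
  n_genes <- length(unique(annotations$gene_id[sel]))
  if (n_genes == 0) {
    warning(sprintf("apa_ratio: no genes with sites in region %s", region))
    return(NA_real_)
  }
  sum(sel) / n_genes
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' @param stats data frame of per-gene statistics (see [gene_apa_stats()]).
#' @param vars columns to correlate; defaults to the APA frequency and gene
#'   architecture variables.
#' @return list of matrices `r`, `p`, plus `n`; zero-variance columns give
#'   `NA` entries and are listed in `attr(, "flagged")`.
#' @export
correlation_matrix <- function(stats, vars = NULL) {
  vars <- vars %||% intersect(
    c("total", "length", "n_introns", "mean_intron_length", "freq_3UTR",
      "freq_5UTR", "freq_CDS", "freq_intron", "proximal", "distal"),
    names(stats))
  assert_that(nrow(stats) >= 3, "correlation_matrix: need >= 3 genes")
  m <- as.matrix(stats[vars])
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- r
  flagged <- vars[apply(m, 2, function(x) stats::var(x) == 0)]
  for (i in seq_len(k)) {
    r[i, i] <- 1
    p[i, i] <- 0
    for (j in seq_len(k)) {
      if (j <= i) next
      if (vars[i] %in% flagged || vars[j] %in% flagged) next
      ct <- cor.test(m[, i], m[, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nrow(m)), flagged = flagged,
            class = "apa_cor")
}
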