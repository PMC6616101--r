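#' Write a genome to FASTA
#'
#' @param genome named `DNAStringSet` (or coercible).
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon, CDS and UTR rows (1-based inclusive coordinates)
#' with ID/Parent attributes.
#'
#' @param features gene-model data frame (see [derive_introns()]).
#' @param path output file.
#' @export
write_gff3 <- function(features, path) {
  rows <- list()
  for (g in unique(features$gene_id)) {
    fg <- features[features$gene_id == g, ]
    rows[[length(rows) + 1]] <- data.frame(
      seqid = fg$chrom[1], source = "apasignal", type = "gene",
      start = min(fg$start), end = max(fg$end), score = ".",
      strand = fg$strand[1], phase = ".",
      attributes = sprintf("ID=%s", g), stringsAsFactors = FALSE)
    for (tx in unique(fg$transcript_id)) {
      ft <- fg[fg$transcript_id == tx, ]
      rows[[length(rows) + 1]] <- data.frame(
        seqid = ft$chrom[1], source = "apasignal", type = "mRNA",
        start = min(ft$start), end = max(ft$end), score = ".",
        strand = ft$strand[1], phase = ".",
        attributes = sprintf("ID=%s;Parent=%s", tx, g),
        stringsAsFactors = FALSE)
      ft <- ft[order(match(ft$type, c("exon", "five_prime_UTR", "CDS",
                                      "three_prime_UTR")), ft$start), ]
      for (i in seq_len(nrow(ft))) {
        rows[[length(rows) + 1]] <- data.frame(
          seqid = ft$chrom[i], source = "apasignal", type = ft$type[i],
          start = ft$start[i], end = ft$end[i], score = ".",
          strand = ft$strand[i],
          phase = if (ft$type[i] == "CDS") "0" else ".",
          attributes = sprintf("ID=%s:%s:%d;Parent=%s", tx, ft$type[i], i,
                               tx),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file.
#' @return gene-model data frame (exon/CDS/UTR rows with gene and transcript
#'   ids).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  keep <- df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  tx2gene <- df$Parent[df$type == "mRNA"]
  tx2gene <- setNames(vapply(tx2gene, `[`, "", 1), df$ID[df$type == "mRNA"])
  sub <- df[keep, ]
  tx <- vapply(sub$Parent, `[`, "", 1)
  data.frame(gene_id = unname(tx2gene[tx]), transcript_id = tx,
             chrom = as.character(sub$seqnames),
             strand = as.character(sub$strand),
             type = as.character(sub$type),
             start = sub$start, end = sub$end,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write cleavage events as 6-column BED
#'
#' BED is 0-based half-open: a cleavage position `p` (1-based, last
#' transcribed nucleotide) becomes the interval `[p-1, p)`. Scores hold the
#' event's total read count.
#'
#' @param events events data frame (`event_id`, `chrom`, `strand`,
#'   `position`).
#' @param counts per-event count matrix (rownames = event ids).
#' @param path output file.
#' @export
write_events_bed <- function(events, counts, path) {
  tot <- rowSums(as.matrix(counts))[events$event_id]
  bed <- data.frame(chrom = events$chrom, start = events$position - 1,
                    end = events$position, name = events$event_id,
                    score = as.integer(tot), strand = events$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read cleavage events from 6-column BED
#'
#' @param path BED file written by [write_events_bed()].
#' @export
read_events_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"))
  data.frame(event_id = bed$name, chrom = bed$chrom, strand = bed$strand,
             position = bed$end, stringsAsFactors = FALSE)
}

#' Write / read a site-by-stage count matrix as TSV
#'
#' @param counts matrix with site-id rownames.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(site_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write position frequency matrices in JASPAR text format
#'
#' @param groups list of alignment objects from [align_and_consensus()].
#' @param path output file.
#' @export
write_pfms_jaspar <- function(groups, path) {
  con <- file(path, "w")
  for (g in groups) {
    writeLines(sprintf(">%s %s", g$label, g$consensus), con)
    for (b in APA_BASES) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(sprintf("%3d", g$pfm[b, ]), collapse = " ")),
                 con)
    }
  }
  close(con)
  invisible(path)
}

write_tsv_quiet <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
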