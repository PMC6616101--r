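#!/usr/bin/env Rscript

# Stage 2: poly(A) site clusters, internal-priming filter, region annotation.
#
# Reads the stage-1 files, chains cleavage events within 24 bp into poly(A)
# site clusters, drops clusters whose downstream window betrays oligo-dT
# internal priming, assigns each surviving site a genomic region, and
# summarises per-gene APA frequency against gene architecture.

suppressMessages(library(apasignal))

ind <- "results/data"
outdir <- "results/tables"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet(file.path(ind, "genome.fa"))
names(genome) <- sub("\\s.*", "", names(genome))
features <- read_gff3(file.path(ind, "models.gff3"))
events <- read_events_bed(file.path(ind, "events.bed"))
event_counts <- read_counts_tsv(file.path(ind, "event_counts.tsv"))

cl <- cluster_cleavage_events(events, event_counts, max_gap = 24)
cat(sprintf("%d events -> %d poly(A) site clusters\n",
            nrow(events), nrow(cl$sites)))

filt <- filter_a_rich(cl$sites, genome)
write.table(filt, file.path(outdir, "filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("internal-priming filter:",
    paste(sprintf("%s=%d", names(table(filt$filter_status)),
                  table(filt$filter_status)), collapse = ", "), "\n")
keep <- filt$filter_status == "pass"
sites <- cl$sites[keep, ]
counts <- cl$counts[keep, , drop = FALSE]
write.table(sites, file.path(outdir, "sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_counts_tsv(counts, file.path(outdir, "site_counts.tsv"))

ann <- assign_region(sites, features, extension = 1000)
write.table(ann, file.path(outdir, "annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("regions:", paste(sprintf("%s=%d", names(table(ann$region)),
                              table(ann$region)), collapse = ", "), "\n")

gs <- gene_apa_stats(ann, features)
write.table(gs, file.path(outdir, "gene_stats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("APA gene categories:",
    paste(sprintf("%s=%d", names(table(gs$category)), table(gs$category)),
          collapse = ", "), "\n")
for (r in c("3UTR", "intron", "CDS")) {
  cat(sprintf("APA ratio in %s: %.2f\n", r,
              suppressWarnings(apa_ratio(ann, r))))
}

cm <- correlation_matrix(gs)
write.table(data.frame(var = rownames(cm$r), round(cm$r, 3)),
            file.path(outdir, "correlation_r.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("corr(total APA frequency, gene length) = %.2f\n",
            cm$r["total", "length"]))
cat(sprintf("corr(total, proximal) = %.2f vs corr(total, distal) = %.2f\n",
            cm$r["total", "proximal"], cm$r["total", "distal"]))

# closed-loop check against the planted truth
truth <- read.table(file.path(ind, "truth.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
key_cl <- paste(cl$sites$chrom, cl$sites$strand, cl$sites$position)
key_tr <- paste(truth$chrom, truth$strand, truth$position)
idx <- match(key_cl, key_tr)
cat(sprintf("filter recall/precision vs planted artifacts: %.3f / %.3f\n",
            sum((filt$filter_status != "pass") & truth$artifact[idx]) /
              sum(truth$artifact),
            sum((filt$filter_status != "pass") & truth$artifact[idx]) /
              sum(filt$filter_status != "pass")))
cat(sprintf("region assignment agreement with truth: %.3f\n",
            mean(ann$region == truth$region[idx][keep])))
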