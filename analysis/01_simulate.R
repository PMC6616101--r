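#!/usr/bin/env Rscript

# Stage 1: generate the synthetic APA study.
#
# Produces a genome, gene models, cleavage events with per-stage counts and
# the planted truth table, then writes them in the standard exchange formats
# (FASTA / GFF3 / BED / TSV) under results/data so the downstream stages can
# run purely from files, the way they would on a real 3'-end dataset.

suppressMessages(library(apasignal))

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

config <- sim_config(n_genes = 300, artifact_rate = 0.1, seed = 20260926)
sim <- simulate_apa_study(config)

write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
write_gff3(sim$features, file.path(outdir, "models.gff3"))
write_events_bed(sim$events, sim$event_counts,
                 file.path(outdir, "events.bed"))
write_counts_tsv(sim$event_counts, file.path(outdir, "event_counts.tsv"))
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth_motifs, file.path(outdir, "truth_motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("genes: %d on %d chromosomes (%.2f Mb)\n",
            length(unique(sim$features$gene_id)), length(sim$genome),
            sum(Biostrings::width(sim$genome)) / 1e6))
cat(sprintf("planted sites: %d (%s)\n", nrow(sim$truth),
            paste(sprintf("%s=%d", names(table(sim$truth$region)),
                          table(sim$truth$region)), collapse = ", ")))
cat(sprintf("cleavage events: %d; internal-priming artifacts: %d (%.1f%%)\n",
            nrow(sim$events), sum(sim$truth$artifact),
            100 * mean(sim$truth$artifact)))
cat(sprintf("expression archetypes: %s\n",
            paste(sprintf("%s=%d", names(table(sim$truth$profile)),
                          table(sim$truth$profile)), collapse = ", ")))
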