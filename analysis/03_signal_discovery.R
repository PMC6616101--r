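#!/usr/bin/env Rscript

# Stage 3: poly(A) signal discovery.
#
# Extracts -300..+100 flanks around the filtered sites, classifies 3'UTR
# sites by usage (strong/weak/universal/unique), samples matched AAUAAA
# controls, runs the greedy positioning-element scan against the Markov
# background, and builds the per-region cis-element schema with consensus
# elements and PFMs.

suppressMessages(library(apasignal))

ind <- "results/data"
tabdir <- "results/tables"
outdir <- "results/signals"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet(file.path(ind, "genome.fa"))
names(genome) <- sub("\\s.*", "", names(genome))
sites <- read.table(file.path(tabdir, "sites.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
counts <- read_counts_tsv(file.path(tabdir, "site_counts.tsv"))
ann <- read.table(file.path(tabdir, "annotations.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)

flanks <- extract_flank(sites, genome)

# usage classes on genic sites, pooled reads over all stages
genic <- !is.na(ann$gene_id)
classes <- classify_sites(data.frame(site_id = sites$site_id[genic],
                                     gene_id = ann$gene_id[genic],
                                     reads = rowSums(counts)[genic]))
write.table(classes, file.path(outdir, "classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("usage classes:", paste(sprintf("%s=%d", names(table(classes$class)),
                                    table(classes$class)), collapse = ", "),
    "\n")

controls <- sample_control_sites(genome, sites, n = 200, seed = 20260926)
write.table(controls, file.path(outdir, "control_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("sampled %d AAUAAA-bearing control positions\n", nrow(controls)))

# greedy positioning-element scan on 3'UTR sites
fl3 <- flanks[ann$region == "3UTR", ]
pe_win <- c(-34, -13)
sel <- greedy_signal_selection(fl3, pe_win, k = 6, p_cut = 1e-5, sd_cut = 7)
write.table(sel, file.path(outdir, "pe_signals.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PE scan over %d 3'UTR flanks selected %d signals:\n",
            nrow(fl3), nrow(sel)))
for (i in seq_len(nrow(sel))) {
  cat(sprintf("  %s  O=%d  E=%.0f  pos %.1f +/- %.1f  coverage %.1f%%\n",
              sel$kmer[i], sel$O_o[i], sel$O_e[i], sel$mean_pos[i],
              sel$pos_sd[i], 100 * sel$coverage[i]))
}

# nucleotide profile around the cleavage site
prof <- nucleotide_profile(fl3)
write.table(prof, file.path(outdir, "nucleotide_profile_3UTR.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ya <- prof[prof$position %in% c(-2, -1), ]
cat(sprintf("cleavage dinucleotide: Y(-2)=%.2f (C+U), A(-1)=%.2f\n",
            sum(ya[ya$position == -2, c("C", "U")]),
            ya$A[ya$position == -1]))

# Per-class cis-element schema, screened on the over-representation z alone:
# the generator plants signals independently of usage class, so the
# strong-vs-weak screen would (correctly) report no usage-coupled word here.
for (cls in c("3UTR", "intron")) {
  idx <- ann$region == cls
  if (sum(idx) < 50) next
  sc <- build_schema(flanks[idx, ], cls)
  write.table(sc$elements,
              file.path(outdir, sprintf("schema_%s_elements.tsv", cls)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_pfms_jaspar(sc$groups,
                    file.path(outdir, sprintf("schema_%s_pfms.txt", cls)))
  cat(sprintf("%s schema: %d elements across %d windows\n",
              cls, nrow(sc$elements), nrow(sc$windows)))
  for (w in unique(sc$elements$region)) {
    top <- sc$elements[sc$elements$region == w, ][1, ]
    cat(sprintf("  %s top element %s: consensus %s (%d hexamers)\n",
                w, top$label, top$consensus, top$n_members))
  }
}
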