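test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_genes = 15, artifact_rate = 0.1, seed = 99)
  s1 <- simulate_apa_study(cfg)
  s2 <- simulate_apa_study(cfg)
  d <- withr::local_tempdir()
  write_genome_fasta(s1$genome, file.path(d, "a.fa"))
  write_genome_fasta(s2$genome, file.path(d, "b.fa"))
  expect_identical(readBin(file.path(d, "a.fa"), "raw", 1e7),
                   readBin(file.path(d, "b.fa"), "raw", 1e7))
  write_gff3(s1$features, file.path(d, "a.gff3"))
  write_gff3(s2$features, file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "a.gff3")),
                   readLines(file.path(d, "b.gff3")))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts, s2$counts)
})

test_that("degenerate and infeasible configurations are handled", {
  empty <- simulate_apa_study(sim_config(n_genes = 0, seed = 1))
  expect_equal(nrow(empty$features), 0)
  expect_gt(sum(Biostrings::width(empty$genome)), 0)
  expect_error(sim_config(gene_length_range = c(900, 1000),
                          intron_count_range = c(5, 5)),
               "infeasible geometry")
})

test_that("planted offsets match the configured distribution", {
  sim <- simulate_apa_study(sim_config(n_genes = 1500, apa_lambda = 0.3,
                                       seed = 101))
  pe <- sim$truth_motifs[sim$truth_motifs$element == "PE", ]
  pe <- pe[pe$motif %in% c("AAUAAA", "AUUAAA"), ]
  expect_gt(nrow(pe), 1000)
  expect_lt(abs(mean(pe$offset) + 23), 0.5)
  expect_lt(abs(sd(pe$offset) - 4), 0.5)
})

test_that("emitted flank sequences recover planted offsets exactly", {
  sim <- simulate_apa_study(sim_config(n_genes = 250, seed = 102))
  main <- sim$events[!duplicated(sim$events$site_id), ]
  sites <- data.frame(site_id = main$site_id, chrom = main$chrom,
                      strand = main$strand, position = main$position,
                      stringsAsFactors = FALSE)
  fl <- extract_flank(sites, sim$genome)
  tm <- sim$truth_motifs[sim$truth_motifs$element %in% c("PE", "CER"), ]
  expect_gt(nrow(tm), 400)
  hits <- 0L
  for (i in seq_len(nrow(tm))) {
    j <- match(tm$site_id[i], fl$site_id)
    full <- paste0(fl$upstream[j], fl$downstream[j])
    off <- tm$offset[i]
    idx <- nchar(fl$upstream[j]) + ifelse(off < 0, off + 1, off)
    if (substr(full, idx, idx + nchar(tm$motif[i]) - 1) == tm$motif[i]) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, nrow(tm))
})

test_that("internal-priming injection is exact and seed-driven", {
  cfg0 <- sim_config(n_genes = 40, artifact_rate = 0, seed = 103)
  s0 <- simulate_apa_study(cfg0)
  expect_equal(sum(s0$truth$artifact), 0)
  # rate 0 leaves the genome untouched
  gg <- generate_genome(sim_config(n_genes = 5, seed = 104))
  set.seed(104)
  pl <- plant_polya_sites(gg, sim_config(n_genes = 5, seed = 104))
  ip0 <- inject_internal_priming(pl$genome, pl$truth, 0)
  expect_identical(ip0$genome, pl$genome)

  # rate 1: every site later fails the filter
  cfg1 <- sim_config(n_genes = 40, artifact_rate = 1, seed = 105)
  s1 <- simulate_apa_study(cfg1)
  cl <- cluster_cleavage_events(s1$events, s1$event_counts)
  st <- filter_a_rich(cl$sites, s1$genome)
  expect_true(all(st$filter_status != "pass"))

  # the flagged count equals the realized Bernoulli draw in the truth table
  cfg <- sim_config(n_genes = 900, artifact_rate = 0.1, seed = 106)
  sim <- simulate_apa_study(cfg)
  expect_gt(nrow(sim$truth), 1500)
  cl2 <- cluster_cleavage_events(sim$events, sim$event_counts)
  st2 <- filter_a_rich(cl2$sites, sim$genome)
  key_cl <- paste(cl2$sites$chrom, cl2$sites$strand, cl2$sites$position)
  key_tr <- paste(sim$truth$chrom, sim$truth$strand, sim$truth$position)
  idx <- match(key_cl, key_tr)
  expect_false(anyNA(idx))
  removed <- st2$filter_status != "pass"
  expect_equal(sum(removed), sum(sim$truth$artifact))
  expect_true(all(removed == sim$truth$artifact[idx]))
})

test_that("stage archetypes shape the count matrix as configured", {
  cfg <- sim_config(n_genes = 150, seed = 107)
  sim <- simulate_apa_study(cfg)
  tr <- sim$truth
  spec <- which(tr$profile == "specific")
  expect_gt(length(spec), 20)
  for (i in spec) {
    k <- tr$specific_stage[i]
    expect_equal(unname(which.max(sim$counts[i, ])), k)
    off <- sim$counts[i, -k]
    expect_lt(mean(off), 5)  # background-level outside the hot stage
  }
  cons <- which(tr$profile == "constitutive")
  expect_gt(mean(sim$counts[cons, ] > 0), 0.9)
  # region-skewed quotas: constitutive sites concentrate in 3'UTR
  cons_3utr <- mean(tr$region[cons] %in% c("3UTR", "Ex_3UTR"))
  expect_gt(cons_3utr, 0.7)
})

test_that("cluster totals equal the planted per-site counts", {
  sim <- simulate_apa_study(sim_config(n_genes = 50, seed = 108))
  cl <- cluster_cleavage_events(sim$events, sim$event_counts)
  key_cl <- paste(cl$sites$chrom, cl$sites$strand, cl$sites$position)
  key_tr <- paste(sim$truth$chrom, sim$truth$strand, sim$truth$position)
  idx <- match(key_cl, key_tr)
  expect_false(anyNA(idx))
  expect_equal(unname(cl$counts), unname(sim$counts[idx, ]))
})

test_that("flank-level generator plants what it reports", {
  sf <- simulate_flanks(300, seed = 109)
  pe <- sf$truth[sf$truth$element == "PE", ]
  for (i in seq_len(nrow(pe))) {
    j <- match(pe$site_id[i], sf$flanks$site_id)
    full <- paste0(sf$flanks$upstream[j], sf$flanks$downstream[j])
    off <- pe$offset[i]
    idx <- 300 + ifelse(off < 0, off + 1, off)
    expect_equal(substr(full, idx, idx + 5), pe$motif[i])
  }
  # insertion probability 1 forces the motif into every flank window
  sf1 <- simulate_flanks(
    100, grammar = data.frame(element = "PE", motif = "AAUAAA",
                              region = "3UTR", mean_offset = -23,
                              sd_offset = 1, prob = 1), seed = 110)
  win <- flank_window(sf1$flanks, c(-34, -13))
  expect_true(all(count_word(win, "AAUAAA") >= 1))
})

test_that("stage-count generator is deterministic and proportioned", {
  sc1 <- simulate_stage_counts(500, sim_config(), seed = 111)
  sc2 <- simulate_stage_counts(500, sim_config(), seed = 111)
  expect_identical(sc1, sc2)
  tab <- table(sc1$truth$profile) / 500
  expect_equal(unname(tab["specific"]), 0.2, tolerance = 0.06)
  expect_equal(unname(tab["constitutive"]), 0.2, tolerance = 0.06)
})
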