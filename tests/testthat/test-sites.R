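mk_events <- function(pos, chrom = "chr1", strand = "+", reads = NULL) {
  ev <- data.frame(event_id = sprintf("e%d", seq_along(pos)), chrom = chrom,
                   strand = strand, position = pos,
                   stringsAsFactors = FALSE)
  cnt <- matrix(reads %||% rep(1, length(pos)), ncol = 1,
                dimnames = list(ev$event_id, "s1"))
  list(events = ev, counts = cnt)
}

test_that("cleavage events chain within the gap and split beyond it", {
  e <- mk_events(c(100, 110, 140))
  cl <- cluster_cleavage_events(e$events, e$counts, max_gap = 24)
  expect_equal(nrow(cl$sites), 2)
  expect_equal(sort(cl$sites$n_events), c(1, 2))

  e2 <- mk_events(c(100, 120, 144))
  cl2 <- cluster_cleavage_events(e2$events, e2$counts, max_gap = 24)
  expect_equal(nrow(cl2$sites), 1)

  e3 <- mk_events(500)
  cl3 <- cluster_cleavage_events(e3$events, e3$counts)
  expect_equal(cl3$sites$position, 500)
  expect_equal(cl3$sites$n_events, 1)
})

test_that("clustering matches the brute-force chaining oracle", {
  set.seed(421)
  for (rep in 1:20) {
    pos <- sort(sample(1:500, 30))
    e <- mk_events(pos)
    cl <- cluster_cleavage_events(e$events, e$counts, max_gap = 24)
    oracle <- chain_positions_oracle(pos, 24)
    got <- lapply(split(cl$members$event_id,
                        cl$members$site_id), function(ids) {
      sort(e$events$position[match(ids, e$events$event_id)])
    })
    expect_setequal(lapply(unname(got), identity), oracle)
  }
})

test_that("clustering is order-independent and sums counts", {
  set.seed(422)
  pos <- sample(1:300, 20)
  reads <- sample(1:50, 20)
  e <- mk_events(pos, reads = reads)
  cl <- cluster_cleavage_events(e$events, e$counts)
  perm <- sample(20)
  e2 <- list(events = e$events[perm, ], counts = e$counts[perm, , drop = FALSE])
  cl2 <- cluster_cleavage_events(e2$events, e2$counts)
  expect_equal(cl$sites$position, cl2$sites$position)
  expect_equal(sum(cl$counts), sum(reads))
})

test_that("representative is the read-maximal member, ties downstream", {
  e <- mk_events(c(100, 110), reads = c(5, 9))
  expect_equal(cluster_cleavage_events(e$events, e$counts)$sites$position,
               110)
  tie <- mk_events(c(100, 110), reads = c(7, 7))
  expect_equal(cluster_cleavage_events(tie$events, tie$counts)$sites$position,
               110)
  tie_minus <- mk_events(c(100, 110), strand = "-", reads = c(7, 7))
  expect_equal(
    cluster_cleavage_events(tie_minus$events, tie_minus$counts)$sites$position,
    100)
  neg <- mk_events(c(100), reads = -1)
  expect_error(cluster_cleavage_events(neg$events, neg$counts), "negative")
})

test_that("A-rich filter applies the three rules in order", {
  pre <- strrep("G", 50)
  genome <- list(chr1 = paste0(
    pre, "AAAAAACGTA",   # site 50: >= 6 A in 10 nt
    "AGAACCCCCC",        # site 60: leading AGAA tetramer
    "ACGTACGTAC",        # site 70: passes
    "CAAAAAACCC",        # site 80: 6-run, but ARS rule fires first
    strrep("G", 20)))
  sites <- data.frame(site_id = c("a", "b", "c", "d"), chrom = "chr1",
                      strand = "+", position = c(50, 60, 70, 80),
                      stringsAsFactors = FALSE)
  st <- filter_a_rich(sites, genome)
  expect_equal(st$filter_status,
               c("fail_ARS", "fail_tetramer", "pass", "fail_ARS"))
  # a run of exactly five adenines (5 A total) passes every rule
  g2 <- list(chr1 = paste0(pre, "CAAAAACGGG", strrep("G", 20)))
  s2 <- data.frame(site_id = "x", chrom = "chr1", strand = "+",
                   position = 50, stringsAsFactors = FALSE)
  expect_equal(filter_a_rich(s2, g2)$filter_status, "pass")
  # minus strand: downstream is upstream-reverse-complement
  g3 <- list(chr1 = paste0(strrep("G", 10), "TACGTTTTTT", strrep("G", 30)))
  s3 <- data.frame(site_id = "m", chrom = "chr1", strand = "-",
                   position = 21, stringsAsFactors = FALSE)
  expect_equal(filter_a_rich(s3, g3)$filter_status, "fail_ARS")
  # contig edge: kept and flagged
  s4 <- data.frame(site_id = "e", chrom = "chr1", strand = "+",
                   position = nchar(g3$chr1) - 3, stringsAsFactors = FALSE)
  st4 <- filter_a_rich(s4, g3)
  expect_equal(st4$filter_status, "pass")
  expect_true(st4$edge)
})

test_that("flank extraction is a strand-aware coordinate identity", {
  set.seed(423)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  genome <- list(chr1 = seq)
  sites <- data.frame(site_id = "p", chrom = "chr1", strand = "+",
                      position = 500, stringsAsFactors = FALSE)
  fl <- extract_flank(sites, genome, up = 20, down = 10)
  expect_equal(fl$upstream, chartr("T", "U", substr(seq, 481, 500)))
  expect_equal(fl$downstream, chartr("T", "U", substr(seq, 501, 510)))
  expect_false(fl$up_trunc || fl$down_trunc)

  # strand symmetry: flipping the genome and coordinates reproduces flanks
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  sites_m <- data.frame(site_id = "p", chrom = "chr1", strand = "-",
                        position = 1000 - 500 + 1, stringsAsFactors = FALSE)
  fl_m <- extract_flank(sites_m, list(chr1 = rc), up = 20, down = 10)
  expect_equal(fl_m$upstream, fl$upstream)
  expect_equal(fl_m$downstream, fl$downstream)

  # truncation at the contig edge is flagged
  s_edge <- data.frame(site_id = "q", chrom = "chr1", strand = "+",
                       position = 5, stringsAsFactors = FALSE)
  fe <- extract_flank(s_edge, genome, up = 20, down = 10)
  expect_true(fe$up_trunc)
  expect_equal(nchar(fe$upstream), 5)
  expect_error(extract_flank(
    data.frame(site_id = "z", chrom = "chrX", strand = "+", position = 1),
    genome), "chrX")
})

test_that("flanks of planted sites contain the planted motif", {
  sim <- simulate_apa_study(sim_config(n_genes = 25, seed = 424))
  main <- sim$events[!duplicated(sim$events$site_id), ]
  sites <- data.frame(site_id = main$site_id, chrom = main$chrom,
                      strand = main$strand, position = main$position,
                      stringsAsFactors = FALSE)
  fl <- extract_flank(sites, sim$genome)
  pe <- sim$truth_motifs[sim$truth_motifs$element == "PE", ]
  for (i in seq_len(nrow(pe))) {
    j <- match(pe$site_id[i], fl$site_id)
    full <- paste0(fl$upstream[j], fl$downstream[j])
    pos <- nchar(fl$upstream[j]) + pe$offset[i] + 1
    expect_equal(substr(full, pos, pos + 5), pe$motif[i])
  }
})
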