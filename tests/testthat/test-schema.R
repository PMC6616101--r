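test_that("region models reproduce the printed window boundaries", {
  s3 <- segment_regions("3UTR")
  expect_equal(s3$name, c("USE", "PE", "CEL", "CER", "DSE"))
  expect_equal(s3$start, c(-100, -34, -12, 1, 34))
  expect_equal(s3$end, c(-35, -13, -3, 33, 100))
  s5 <- segment_regions("5UTR")
  expect_equal(s5$name, c("USE", "PE", "CE", "DSE"))
  expect_equal(s5$start, c(-100, -40, -10, 10))
  expect_equal(s5$end, c(-40, -10, 10, 100))
  sc <- segment_regions("CDS")
  expect_equal(sc$name, c("USE", "CE", "DSE"))
  expect_equal(sc$start, c(-100, -30, 30))
  expect_equal(sc$end, c(-30, 30, 100))
  si <- segment_regions("intron")
  expect_equal(si$name, c("USE", "PE", "CEL", "CER", "DSE"))
  expect_equal(si$start, c(-100, -40, -10, 1, 30))
  expect_equal(si$end, c(-40, -10, -1, 30, 100))
  # windows cover the full -100..+100 span; the only offsets ever left out
  # are the cleavage-site dinucleotide positions (-2, -1) in the 3'UTR model
  for (cls in c("3UTR", "5UTR", "CDS", "intron")) {
    w <- segment_regions(cls)
    covered <- unique(unlist(lapply(seq_len(nrow(w)), function(i) {
      setdiff(seq(w$start[i], w$end[i]), 0)
    })))
    uncovered <- setdiff(setdiff(-100:100, 0), covered)
    expect_true(all(uncovered %in% c(-2, -1)))
  }
  expect_error(segment_regions("promoter"), "unknown")
})

test_that("hexamer distance enumerates shifts with the 0.5 penalty", {
  expect_equal(hexamer_distance("AAUAAA", "AAUAAA"), 0)
  expect_equal(hexamer_distance("AAUAAA", "AUAAAA"), 0.5)
  expect_gte(hexamer_distance("AAUAAA", "GGCGCC"), 2.6)
  # symmetric
  expect_equal(hexamer_distance("AAUAAA", "AUUAAA"),
               hexamer_distance("AUUAAA", "AAUAAA"))
  expect_equal(hexamer_distance("AAUAAA", "AUUAAA"), 1)
})

test_that("hexamer clustering groups shifted variants and splits others", {
  groups <- cluster_hexamers(c("AAUAAA", "AUAAAA", "GGCGCC"))
  expect_length(groups, 2)
  expect_setequal(groups[[1]], c("AAUAAA", "AUAAAA"))
  expect_equal(groups[[2]], "GGCGCC")
  expect_equal(cluster_hexamers("AAUAAA"), list("AAUAAA"))
  expect_length(cluster_hexamers(c("AAUAAA", "AAUAAA")), 1)
  # permutation invariance of memberships
  set.seed(461)
  hx <- c("AAUAAA", "AUUAAA", "UAUAAA", "GGCGCC", "GGCGCU", "UUUUUU")
  g1 <- cluster_hexamers(hx)
  g2 <- cluster_hexamers(sample(hx))
  expect_setequal(lapply(g1, sort), lapply(g2, sort))
})

test_that("group alignment yields majority consensus and count-sum PFMs", {
  single <- align_and_consensus("AAUAAA", label = "PE.1")
  expect_equal(single$consensus, "AAUAAA")
  expect_true(all(colSums(single$pfm) == 1))
  expect_equal(unname(single$pfm["U", 3]), 1L)

  g <- align_and_consensus(c("AAUAAA", "AUAAAA", "AAUAAU"))
  expect_true(all(colSums(g$pfm) <= 3))
  expect_true(any(colSums(g$pfm) == 3))
  expect_equal(ncol(g$pfm), max(g$shifts) - min(g$shifts) + 6)

  # one-substitution family votes back to the seed
  fam <- c("AAUAAA", "ACUAAA", "AGUAAA", "AAUACA", "AAUAAG")
  cons <- align_and_consensus(fam)$consensus
  expect_equal(cons, "AAUAAA")
})

test_that("nucleotide profiles are per-position base fractions", {
  fl <- flanks_from_seqs(rep(paste(rep("A", 30), collapse = ""), 5), 20)
  prof <- nucleotide_profile(fl, c(-20, 10), up = 20, down = 10)
  expect_true(all(prof$A == 1))
  expect_equal(nrow(prof), 30)

  set.seed(462)
  sf <- simulate_flanks(400, ya_prob = 1, seed = 462)
  prof2 <- nucleotide_profile(sf$flanks, c(-5, 5))
  sums <- rowSums(prof2[, c("A", "C", "G", "U")])
  expect_equal(sums, rep(1, nrow(prof2)), tolerance = 1e-12)
  # planted YA: pyrimidine-only at -2, adenine peak at -1
  expect_equal(prof2$A[prof2$position == -1], 1)
  expect_equal(prof2$G[prof2$position == -2] +
                 prof2$A[prof2$position == -2], 0)
})

test_that("schema construction recovers planted elements in their windows", {
  grammar <- data.frame(
    element = c("PE", "PE", "CER", "CER"),
    motif = c("AAUAAA", "AUUAAA", "UUGUUU", "UGUGUU"),
    region = "3UTR",
    mean_offset = c(-23, -23, 15, 15),
    sd_offset = c(3, 3, 4, 4),
    prob = c(0.55, 0.25, 0.45, 0.25), stringsAsFactors = FALSE)
  sf <- simulate_flanks(600, grammar = grammar, seed = 463)
  sc <- build_schema(sf$flanks, "3UTR")
  expect_equal(sc$windows, segment_regions("3UTR"))
  pe_members <- unlist(strsplit(
    sc$elements$members[sc$elements$region == "PE"], ","))
  cer_members <- unlist(strsplit(
    sc$elements$members[sc$elements$region == "CER"], ","))
  expect_true(all(c("AAUAAA", "AUUAAA") %in% pe_members))
  expect_true(all(c("UUGUUU", "UGUGUU") %in% cer_members))
  # the planted PE family does not dominate distal windows: the top-ranked
  # element there never carries AAUAAA (chance appearances in minor noise
  # groups are possible under the quantile screen)
  for (w in c("USE", "DSE")) {
    top <- sc$elements$members[sc$elements$region == w][1]
    expect_false(grepl("AAUAAA", top))
  }
  # the top PE element is the AAUAAA-led group
  pe_el <- sc$elements[sc$elements$region == "PE", ]
  expect_true(grepl("AAUAAA", pe_el$members[1]))
  # labels are ranked by member count within each window
  for (w in unique(sc$elements$region)) {
    nm <- sc$elements$n_members[sc$elements$region == w]
    expect_true(all(diff(nm) <= 0))
  }
  # paired run without the planting: no planted-family PE element
  sf0 <- simulate_flanks(600, grammar = grammar[0, ], seed = 463)
  sc0 <- build_schema(sf0$flanks, "3UTR")
  pe0 <- unlist(strsplit(sc0$elements$members[sc0$elements$region == "PE"],
                         ","))
  expect_lt(sum(c("AAUAAA", "AUUAAA") %in% pe0), 2)
})

test_that("the strong/weak screen keeps only usage-coupled words", {
  # strong sites carry extra U-richness in the left cleavage element; the
  # weak set does not. The joint (z_oe, z_sw) screen must keep the planted
  # word only when the coupling is planted.
  cel_grammar <- function(prob) data.frame(
    element = "CEL", motif = "UUUUUC", region = "3UTR",
    mean_offset = -10, sd_offset = 1, prob = prob, stringsAsFactors = FALSE)
  fs <- simulate_flanks(400, grammar = cel_grammar(0.7), seed = 465)$flanks
  fw <- simulate_flanks(400, grammar = cel_grammar(0.0), seed = 466)$flanks
  win <- c(-12, -3)
  ks <- kmer_stats(fs, win)
  sw <- strong_weak_stats(fs, fw, win)
  sel <- select_significant_hexamers(ks, sw)
  expect_true("UUUUUC" %in% sel)
  # paired run with the coupling off: both sets identical in distribution
  fs0 <- simulate_flanks(400, grammar = cel_grammar(0.0), seed = 467)$flanks
  ks0 <- kmer_stats(fs0, win)
  sw0 <- strong_weak_stats(fs0, fw, win)
  expect_false("UUUUUC" %in% select_significant_hexamers(ks0, sw0))
})

test_that("empty selections give a valid empty element table", {
  set.seed(464)
  m <- markov_model(transition = matrix(0.25, 4, 4))
  fl <- flanks_from_seqs(simulate_markov(m, 30, 400), 300)
  ks <- kmer_stats(fl, c(-34, -13))
  none <- select_significant_hexamers(ks, zoe_cut = Inf)
  expect_length(none, 0)
  all_of_them <- select_significant_hexamers(ks, zoe_cut = -Inf)
  expect_equal(sort(all_of_them), sort(ks$kmer[ks$O_o > 0]))
})
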