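test_that("region assignment follows the documented precedence", {
  gm <- toy_gene_models()
  sites <- data.frame(
    site_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    chrom = "chr1", strand = c("+", "+", "+", "+", "-", "+"),
    position = c(1950,  # 3'UTR of gA.t1
                 1600,  # CDS of gA.t1 but intron of gA.t2 -> CDS wins
                 1050,  # 5'UTR of t1, exon/not-CDS of t2 -> 5UTR
                 2400,  # 400 nt downstream of gA 3' end -> Ex_3UTR
                 4600,  # 400 nt downstream of gB (minus strand) 3' end
                 5200), # inside gB but wrong strand -> intergenic
    stringsAsFactors = FALSE)
  ann <- assign_region(sites, gm, extension = 1000)
  expect_equal(ann$region,
               c("3UTR", "CDS", "5UTR", "Ex_3UTR", "Ex_3UTR", "intergenic"))
  expect_equal(ann$gene_id[1:5], c("gA", "gA", "gA", "gA", "gB"))
  expect_equal(ann$distance_to_end[4], 400)
  expect_equal(ann$distance_to_end[5], 400)
  # beyond the extension it is intergenic
  far <- data.frame(site_id = "f", chrom = "chr1", strand = "+",
                    position = 3500, stringsAsFactors = FALSE)
  expect_equal(assign_region(far, gm, extension = 1000)$region, "intergenic")
  expect_equal(assign_region(far, gm, extension = 2000)$region, "Ex_3UTR")
})

test_that("assignments are invariant to transcript input order", {
  gm <- toy_gene_models()
  sites <- data.frame(site_id = sprintf("s%d", 1:30), chrom = "chr1",
                      strand = "+",
                      position = seq(1000, 2400, length.out = 30),
                      stringsAsFactors = FALSE)
  a1 <- assign_region(sites, gm)
  set.seed(431)
  a2 <- assign_region(sites, gm[sample(nrow(gm)), ])
  expect_equal(a1, a2)
})

test_that("malformed gene models (CDS outside exons) are rejected by name", {
  gm <- toy_gene_models()
  gm$end[gm$type == "CDS" & gm$transcript_id == "gA.t1"] <- 2500
  sites <- data.frame(site_id = "s", chrom = "chr1", strand = "+",
                      position = 1500, stringsAsFactors = FALSE)
  expect_error(assign_region(sites, gm), "gA")
})

test_that("intron derivation fills gaps between exons", {
  gm <- toy_gene_models()
  intr <- derive_introns(gm)
  expect_equal(nrow(intr), 1)
  expect_equal(intr$start, 1501)
  expect_equal(intr$end, 1799)
})

test_that("APA gene categories follow the 0/1/2-4/>4 boundaries", {
  expect_equal(as.character(apa_gene_category(c(0, 1, 2, 4, 5, 9))),
               c("non", "rare", "moderate", "moderate", "abundant",
                 "abundant"))
  expect_error(apa_gene_category(-1), ">= 0")
})

test_that("APA ratio divides sites by owning genes", {
  ann <- data.frame(site_id = 1:10, gene_id = rep(c("a", "b", "c", "d", "e"),
                                                  each = 2),
                    region = "3UTR", stringsAsFactors = FALSE)
  expect_equal(apa_ratio(ann, "3UTR"), 2)
  ann1 <- data.frame(site_id = 1:4, gene_id = letters[1:4], region = "3UTR")
  expect_equal(apa_ratio(ann1, "3UTR"), 1)
  expect_warning(r <- apa_ratio(ann1, "CDS"), "no genes")
  expect_true(is.na(r))
})

test_that("per-gene APA ratio matches the planted mean on synthetic truth", {
  sim <- simulate_apa_study(sim_config(n_genes = 40, seed = 432))
  tr <- sim$truth[sim$truth$region == "3UTR", ]
  ann <- data.frame(site_id = tr$site_id, gene_id = tr$gene_id,
                    region = tr$region, stringsAsFactors = FALSE)
  expect_equal(apa_ratio(ann, "3UTR"),
               nrow(tr) / length(unique(tr$gene_id)))
})

test_that("correlation matrix recovers a planted association", {
  set.seed(433)
  n <- 2000
  len <- runif(n, 1000, 20000)
  noise <- rnorm(n, 0, 3)
  stats <- data.frame(total = round(len / 1000) + noise, length = len)
  cm <- correlation_matrix(stats, vars = c("total", "length"))
  expect_equal(unname(diag(cm$r)), c(1, 1))
  r_target <- cor(round(len / 1000) + noise, len)
  expect_equal(cm$r["total", "length"], r_target, tolerance = 1e-12)
  # closed-form generator correlation: sd(len/1000) / sqrt(sd^2 + 9)
  sd_sig <- sd(len / 1000)
  expect_equal(unname(cm$r["total", "length"]),
               sd_sig / sqrt(sd_sig^2 + 9), tolerance = 0.05)
  # independent columns stay near zero
  ind <- data.frame(a = rnorm(1000), b = rnorm(1000))
  ci <- correlation_matrix(ind, vars = c("a", "b"))
  expect_lt(abs(ci$r["a", "b"]), 0.1)
  # zero-variance columns are flagged, not crashed
  zv <- data.frame(a = rnorm(10), b = rep(1, 10))
  cz <- correlation_matrix(zv, vars = c("a", "b"))
  expect_true(is.na(cz$r["a", "b"]))
  expect_equal(attr(cz, "flagged"), "b")
})

test_that("gene stats partition sites and are internally consistent", {
  sim <- simulate_apa_study(sim_config(n_genes = 30, seed = 434))
  main <- sim$events[!duplicated(sim$events$site_id), ]
  sites <- data.frame(site_id = main$site_id, chrom = main$chrom,
                      strand = main$strand, position = main$position,
                      stringsAsFactors = FALSE)
  ann <- assign_region(sites, sim$features)
  gs <- gene_apa_stats(ann, sim$features)
  expect_equal(sum(gs$total), sum(!is.na(ann$gene_id)))
  expect_equal(gs$total, gs$proximal + gs$distal + gs$freq_Ex_5UTR)
  expect_true(all(as.character(apa_gene_category(gs$total)) ==
                    as.character(gs$category)))
  # every site got exactly one region
  expect_false(anyNA(ann$region))
})
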