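test_that("Shannon entropy matches hand-computed profiles", {
  one_hot <- c(9, rep(0, 8))
  expect_equal(shannon_entropy(one_hot), 0)
  expect_equal(shannon_entropy(rep(4, 9)), log2(9), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(2, 1, 1, 0, 0, 0, 0, 0, 0)), 1.5,
               tolerance = 1e-12)
  expect_warning(h <- shannon_entropy(rep(0, 9)), "all-zero")
  expect_true(is.na(h))
  expect_error(shannon_entropy(c(-1, 2)), "negative")
})

test_that("one-step Tukey biweight is robust to a gross outlier", {
  expect_equal(tukey_biweight(rep(7, 9)), 7)
  expect_equal(tukey_biweight(c(1, 2, 3)), 2)
  # any symmetric 3-vector returns its median
  set.seed(451)
  for (i in 1:20) {
    m <- runif(1, 0, 100)
    d <- runif(1, 0, 10)
    expect_equal(tukey_biweight(c(m - d, m, m + d)), m, tolerance = 1e-9)
  }
  # MAD = 0 floors the scale: the outlier weight vanishes entirely
  expect_equal(tukey_biweight(c(rep(1, 8), 100)), 1)
})

test_that("mode entropy concentrates for one-hot and flags constants", {
  x <- c(rep(0, 8), 9)
  # T_bw = 0 (the outlier gets weight 0), so x' = x and modeH = 0
  expect_equal(tukey_biweight(x), 0)
  expect_equal(mode_entropy(x), 0)
  expect_warning(mh <- mode_entropy(rep(3, 9)), "constant")
  expect_equal(mh, log2(9))
  # near-uniform noisy profiles keep modeH near log2(9)
  set.seed(452)
  mh_vals <- replicate(50, mode_entropy(1000 + rnorm(9, 0, 10)))
  expect_gt(mean(mh_vals), 0.8 * log2(9))
})

test_that("H and modeH are scale invariant and bounded", {
  set.seed(453)
  for (i in 1:50) {
    x <- rgamma(9, shape = 0.5)
    expect_equal(shannon_entropy(x), shannon_entropy(x * 1000),
                 tolerance = 1e-9)
    # the eps floor in the biweight scale leaves a negligible wobble
    expect_equal(mode_entropy(x), mode_entropy(x * 1000), tolerance = 1e-3)
    expect_gte(shannon_entropy(x), 0)
    expect_lte(shannon_entropy(x), log2(9) + 1e-12)
    expect_gte(mode_entropy(x), 0)
    expect_lte(mode_entropy(x), log2(9) + 1e-12)
  }
})

test_that("specific/constitutive calls label the planted extremes", {
  n <- 400
  counts <- matrix(0L, n, 9, dimnames = list(sprintf("s%d", 1:n), NULL))
  truth <- rep(c("specific", "constitutive"), each = n / 2)
  set.seed(454)
  for (i in 1:(n / 2)) counts[i, sample(9, 1)] <- 500L
  for (i in (n / 2 + 1):n) counts[i, ] <- 200L + sample(-5:5, 9, TRUE)
  calls <- call_specific_constitutive(counts, pct = 40)
  expect_true(all(truth[calls$label == "specific"] == "specific"))
  expect_true(all(truth[calls$label == "constitutive"] == "constitutive"))
  expect_gt(sum(calls$label == "specific"), 0)
  expect_gt(sum(calls$label == "constitutive"), 0)
  cuts <- attr(calls, "cutoffs")
  expect_true(all(is.finite(cuts)))
  expect_error(call_specific_constitutive(counts, pct = 60), "pct")
})

test_that("low-expression sites are excluded from labelling", {
  counts <- matrix(50L, 20, 9, dimnames = list(sprintf("s%d", 1:20), NULL))
  counts[1, ] <- 0L
  counts[1, 5] <- 4L  # 4 < 5 total reads
  calls <- call_specific_constitutive(counts, pct = 10, min_reads = 5)
  expect_equal(calls$label[1], "low_expression")
  # a one-hot with enough reads would otherwise be maximally specific
  expect_equal(calls$total_reads[1], 4)
})

test_that("planted specific sites have lower entropy than constitutive", {
  sc <- simulate_stage_counts(1500, sim_config(), seed = 455)
  rec <- entropy_records(sc$counts)
  spec <- sc$truth$profile == "specific"
  cons <- sc$truth$profile == "constitutive"
  expect_lt(mean(rec$H[spec], na.rm = TRUE),
            mean(rec$H[cons], na.rm = TRUE))
})

test_that("stage summaries report specific stages and compositions", {
  n <- 60
  counts <- matrix(1L, n, 9,
                   dimnames = list(sprintf("s%d", 1:n), paste0("st", 1:9)))
  counts[1:30, 1] <- 1000L  # specific to stage 1
  counts[31:60, ] <- 100L
  calls <- call_specific_constitutive(counts, pct = 45)
  ann <- data.frame(site_id = rownames(counts),
                    gene_id = rep(sprintf("g%d", 1:30), 2),
                    region = rep(c("intron", "3UTR"), each = 30),
                    stringsAsFactors = FALSE)
  summ <- stage_summaries(calls, ann, counts)
  expect_equal(summ$per_stage$n_specific[1],
               sum(calls$label == "specific"))
  expect_equal(sum(summ$per_stage$n_specific[-1]), 0)
  expect_equal(summ$per_stage$n_period_expressed[2], n)
  rc <- summ$region_composition
  expect_equal(rc$fraction[rc$label == "specific" & rc$region == "intron"],
               1)
  ov <- summ$gene_overlap
  expect_equal(ov["st1", "st1"], length(unique(
    ann$gene_id[calls$label == "specific"])))
  # APA ratio of a one-site-per-gene set is 1
  expect_equal(summ$per_stage$apa_ratio_specific[1], 1)
})
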