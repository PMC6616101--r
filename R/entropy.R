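#' Shannon entropy of an expression profile (bits)
#'
#' `H = -sum p_k log2 p_k` with `p_k = x_k / sum(x)`; zero components
#' contribute 0. `H` lies in `[0, log2(n)]`.
#'
#' @param x non-negative numeric vector (one site across stages).
#' @return entropy in bits; `NA` (flagged via warning) for an all-zero vector.
#' @export
shannon_entropy <- function(x) {
  assert_that(all(x >= 0), "shannon_entropy: negative values")
  s <- sum(x)
  if (s == 0) {
    warning("shannon_entropy: all-zero vector, entropy undefined")
    return(NA_real_)
  }
  p <- x / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' One-step Tukey biweight location estimate
#'
#' Robust location: weights `w_i = (1 - u_i^2)^2` for `|u_i| < 1` (else 0)
#' with `u_i = (x_i - median) / (c * MAD + eps)`; the estimate is the weighted
#' mean. With a zero MAD the `eps` floor makes every off-median point an
#' outlier, so the estimate collapses to the median/mode of the data.
#'
#' @param x numeric vector.
#' @param c_tuning tuning constant (default 5).
#' @param eps floor added to `c * MAD` (default 1e-4).
#' @export
tukey_biweight <- function(x, c_tuning = 5, eps = 1e-4) {
  assert_that(length(x) >= 1, "tukey_biweight: empty vector")
  M <- median(x)
  S <- median(abs(x - M))
  u <- (x - M) / (c_tuning * S + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) {
    warning("tukey_biweight: all weights zero, falling back to median")
    return(M)
  }
  sum(w * x) / sum(w)
}

#' Outlier-adjusted ("mode") entropy
#'
#' Entropy of the residual profile `x' = |x - T_bw|` where `T_bw` is the
#' one-step Tukey biweight of `x`. A profile dominated by one stage leaves a
#' residual concentrated on that stage (modeH near 0); a flat noisy profile
#' leaves near-uniform residuals (modeH near log2 n). For a perfectly
#' constant profile `x'` is all-zero and modeH is defined as `log2(n)`
#' (maximal uniformity), with a warning.
#'
#' @inheritParams tukey_biweight
#' @export
mode_entropy <- function(x, c_tuning = 5, eps = 1e-4) {
  xp <- abs(x - tukey_biweight(x, c_tuning, eps))
  if (sum(xp) == 0) {
    warning("mode_entropy: constant profile, modeH set to log2(n)")
    return(log2(length(x)))
  }
  shannon_entropy(xp)
}

#' Library-size normalisation of a site-by-stage count matrix
#'
#' Counts per million within each stage column, so that entropy reflects
#' relative stage usage rather than sequencing depth.
#'
#' @param counts matrix (sites x stages) of non-negative counts.
#' @export
normalize_cpm <- function(counts) {
  libs <- colSums(counts)
  assert_that(all(libs > 0), "normalize_cpm: a stage has zero total counts")
  sweep(counts, 2, libs, "/") * 1e6
}

#' Entropy records for every poly(A) site
#'
#' @param counts site-by-stage count matrix (rownames = site ids).
#' @param normalize apply within-stage CPM scaling first (default TRUE).
#' @inheritParams tukey_biweight
#' @return data frame: site_id, total_reads (raw), H, modeH, T_bw.
#' @export
entropy_records <- function(counts, normalize = TRUE, c_tuning = 5,
                            eps = 1e-4) {
  counts <- as.matrix(counts)
  x <- if (normalize) normalize_cpm(counts) else counts
  n <- nrow(counts)
  H <- numeric(n)
  modeH <- numeric(n)
  tbw <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    if (sum(xi) == 0) {
      H[i] <- NA_real_
      modeH[i] <- NA_real_
      tbw[i] <- NA_real_
      next
    }
    H[i] <- shannon_entropy(xi)
    tbw[i] <- tukey_biweight(xi, c_tuning, eps)
    modeH[i] <- suppressWarnings(mode_entropy(xi, c_tuning, eps))
  }
  data.frame(site_id = rownames(counts) %||% as.character(seq_len(n)),
             total_reads = rowSums(counts), H = H, modeH = modeH,
             T_bw = tbw, stringsAsFactors = FALSE)
}

#' Call stage-specific and constitutive poly(A) sites
#'
#' Sites in the lowest `pct` percent of BOTH `H` and `modeH` among eligible
#' sites are called `specific`; sites in the highest `pct` percent of both are
#' called `constitutive` (low entropy = concentrated on few stages, the
#' ROKU convention). Sites with fewer than `min_reads` total raw reads are
#' labelled `low_expression` and excluded from the percentile pool.
#'
#' @param counts site-by-stage count matrix.
#' @param pct percentile (0 < pct < 50), default 5.
#' @param min_reads minimum total raw reads, default 5.
#' @inheritParams entropy_records
#' @return data frame from [entropy_records()] plus `label`; the realised
#'   cutoff values are in `attr(, "cutoffs")`.
#' @export
call_specific_constitutive <- function(counts, pct = 5, min_reads = 5,
                                       normalize = TRUE, c_tuning = 5,
                                       eps = 1e-4) {
  assert_that(pct > 0 && pct < 50, "pct must be in (0, 50)")
  rec <- entropy_records(counts, normalize, c_tuning, eps)
  eligible <- rec$total_reads >= min_reads & !is.na(rec$H)
  qlo <- pct / 100
  cuts <- c(H_lo = quantile(rec$H[eligible], qlo, names = FALSE),
            modeH_lo = quantile(rec$modeH[eligible], qlo, names = FALSE),
            H_hi = quantile(rec$H[eligible], 1 - qlo, names = FALSE),
            modeH_hi = quantile(rec$modeH[eligible], 1 - qlo, names = FALSE))
  label <- rep("neither", nrow(rec))
  label[!eligible] <- "low_expression"
  spec <- eligible & rec$H <= cuts["H_lo"] & rec$modeH <= cuts["modeH_lo"]
  cons <- eligible & rec$H >= cuts["H_hi"] & rec$modeH >= cuts["modeH_hi"]
  label[spec] <- "specific"
  label[cons] <- "constitutive"
  rec$label <- label
  attr(rec, "cutoffs") <- cuts
  rec
}

#' Per-stage summaries of specific and constitutive sites
#'
#' The stage of a specific site is the stage of its maximal normalised
#' expression. Period-expressed sites are those with any reads at a stage.
#' The APA ratio of a site set is (number of sites) / (number of distinct
#' genes owning them).
#'
#' @param calls output of [call_specific_constitutive()].
#' @param annotations data frame with `site_id`, `gene_id`, `region` (see
#'   [assign_region()]).
#' @param counts site-by-stage count matrix (same sites).
#' @return list: `per_stage` (stage, n_specific, n_period_expressed, APA
#'   ratios), `region_composition` (label x region fractions), `gene_overlap`
#'   (stage x stage counts of shared specific-site genes).
#' @export
stage_summaries <- function(calls, annotations, counts) {
  counts <- as.matrix(counts)
  stages <- colnames(counts) %||% paste0("stage_", seq_len(ncol(counts)))
  ann <- annotations[match(calls$site_id, annotations$site_id), ]
  norm <- normalize_cpm(counts)
  spec <- calls$label == "specific"
  cons <- calls$label == "constitutive"
  spec_stage <- rep(NA_integer_, nrow(calls))
  spec_stage[spec] <- apply(norm[spec, , drop = FALSE], 1, which.max)

  ratio <- function(idx) {
    g <- ann$gene_id[idx]
    g <- g[!is.na(g)]
    if (length(unique(g)) == 0) NA_real_ else
      length(idx) / length(unique(g))
  }
  per_stage <- do.call(rbind, lapply(seq_along(stages), function(s) {
    in_spec <- spec & spec_stage == s
    in_period <- counts[, s] > 0
    data.frame(stage = stages[s],
               n_specific = sum(in_spec, na.rm = TRUE),
               n_period_expressed = sum(in_period),
               apa_ratio_specific = ratio(which(in_spec)),
               apa_ratio_period = ratio(which(in_period)),
               stringsAsFactors = FALSE)
  }))

  comp <- function(idx, label) {
    if (length(idx) == 0) {
      return(data.frame(label = character(0), region = character(0),
                        fraction = numeric(0), stringsAsFactors = FALSE))
    }
    tab <- prop.table(table(factor(ann$region[idx])))
    data.frame(label = label, region = names(tab),
               fraction = as.numeric(tab), stringsAsFactors = FALSE)
  }
  region_composition <- rbind(comp(which(spec), "specific"),
                              comp(which(cons), "constitutive"))

  genes_by_stage <- lapply(seq_along(stages), function(s) {
    unique(stats::na.omit(ann$gene_id[which(spec & spec_stage == s)]))
  })
  ov <- outer(seq_along(stages), seq_along(stages),
              Vectorize(function(i, j) {
                length(intersect(genes_by_stage[[i]], genes_by_stage[[j]]))
              }))
  dimnames(ov) <- list(stages, stages)
  list(per_stage = per_stage, region_composition = region_composition,
       gene_overlap = ov)
}
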