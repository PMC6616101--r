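DEFAULT_STAGES <- c("embryo_6", "embryo_8", "embryo_11", "embryo_15",
                    "embryo_28", "young_female", "growing_female",
                    "young_male", "growing_male")

MIN_EXON <- 50L
MIN_INTRON <- 80L

#' Default planted signal grammar
#'
#' One row per (element, motif): the motif is inserted for sites of the given
#' region with probability `prob`, starting at a relative offset drawn from
#' `Normal(mean_offset, sd_offset)` (rounded). Motifs within one element are
#' mutually exclusive alternatives. Offsets are start coordinates on the
#' relative axis (-1 = cleavage nucleotide, no position 0). The defaults
#' emulate the canonical vertebrate landscape: an AAUAAA-dominated
#' positioning element ending upstream of the cleavage site and a GU/U-rich
#' downstream element.
#'
#' @export
default_signal_grammar <- function() {
  data.frame(
    element = c("PE", "PE", "CER", "CER", "PE", "PE"),
    motif = c("AAUAAA", "AUUAAA", "UUGUUU", "UGUGUU", "AAUAAA", "AAUAAA"),
    region = c("3UTR", "3UTR", "3UTR", "3UTR", "intron", "5UTR"),
    mean_offset = c(-23, -23, 15, 15, -23, -23),
    sd_offset = c(4, 4, 5, 5, 4, 4),
    prob = c(0.5, 0.2, 0.35, 0.15, 0.4, 0.4),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Validated parameter bundle for the synthetic APA study generator. The
#' defaults define the simulated study conditions: uniform background
#' composition, AAUAAA/AUUAAA positioning elements at -23 +/- 4, a YA
#' cleavage dinucleotide in 80% of sites, negative binomial stage counts with
#' dispersion 0.2 over 9 stages, and a 20%/20%/60%
#' specific/constitutive/background profile mixture.
#'
#' @param n_genes number of genes.
#' @param gene_length_range,intron_count_range gene geometry (nt / counts).
#' @param utr5_length_range,utr3_length_range UTR lengths (nt).
#' @param signal_grammar see [default_signal_grammar()].
#' @param base_comp named A/C/G/U composition of the background genome.
#' @param region_comp optional named list region -> composition overriding
#'   `base_comp` inside gene regions (`3UTR`, `5UTR`, `CDS`, `intron`).
#' @param ya_prob fraction of sites with a planted YA at (-2, -1).
#' @param apa_lambda Poisson mean of extra sites per gene (total = 1 + Pois).
#' @param max_sites cap on sites per gene.
#' @param region_weights sampling weights of extra-site regions.
#' @param artifact_rate fraction of sites rewritten as internal-priming
#'   artifacts.
#' @param n_stages number of developmental stages (>= 2).
#' @param stage_names stage labels (length `n_stages`).
#' @param prop_specific,prop_constitutive profile mixture proportions.
#' @param mu_specific,mu_constitutive,mu_background,mu_off negative binomial
#'   means: expressed stage(s) of each archetype and the off-stage floor.
#' @param dispersion negative binomial dispersion (size = 1/dispersion).
#' @param constitutive_3utr_frac fraction of constitutive sites drawn from
#'   3'UTR sites; @param specific_proximal_frac fraction of specific sites
#'   drawn from proximal (5UTR/CDS/intron) sites.
#' @param genes_per_chrom,spacer chromosome layout.
#' @param min_site_gap minimum distance between sites of one gene (nt).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       gene_length_range = c(2500, 6000),
                       intron_count_range = c(0, 5),
                       utr5_length_range = c(120, 300),
                       utr3_length_range = c(250, 450),
                       signal_grammar = default_signal_grammar(),
                       base_comp = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                       region_comp = NULL,
                       ya_prob = 0.8,
                       apa_lambda = 1.2,
                       max_sites = 6,
                       region_weights = c(`3UTR` = 0.3, intron = 0.3,
                                          CDS = 0.2, `5UTR` = 0.1,
                                          Ex_3UTR = 0.1),
                       artifact_rate = 0,
                       n_stages = 9,
                       stage_names = DEFAULT_STAGES,
                       prop_specific = 0.2,
                       prop_constitutive = 0.2,
                       mu_specific = 200,
                       mu_constitutive = 50,
                       mu_background = 20,
                       mu_off = 0.2,
                       dispersion = 0.2,
                       constitutive_3utr_frac = 0.85,
                       specific_proximal_frac = 0.7,
                       genes_per_chrom = 50,
                       spacer = 2000,
                       min_site_gap = 150,
                       seed = 1) {
  cfg <- as.list(environment())
  assert_that(n_genes >= 0, "n_genes must be >= 0")
  assert_that(all(diff(gene_length_range) >= 0) &&
                all(diff(intron_count_range) >= 0),
              "ranges must be non-empty (lo <= hi)")
  assert_that(abs(sum(base_comp) - 1) < 1e-9, "base_comp must sum to 1")
  probs <- c(ya_prob, artifact_rate, prop_specific, prop_constitutive,
             signal_grammar$prob, constitutive_3utr_frac,
             specific_proximal_frac)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  assert_that(prop_specific + prop_constitutive <= 1,
              "profile proportions exceed 1")
  assert_that(n_stages >= 2, "n_stages must be >= 2")
  assert_that(length(stage_names) >= n_stages, "not enough stage names")
  cfg$stage_names <- stage_names[seq_len(n_stages)]
  # motifs within one (element, region) are exclusive alternatives
  for (el in unique(signal_grammar$element)) {
    er <- signal_grammar[signal_grammar$element == el, ]
    for (reg in unique(er$region)) {
      assert_that(sum(er$prob[er$region == reg]) <= 1 + 1e-9,
                  sprintf("grammar element '%s' (%s): probs sum above 1",
                          el, reg))
    }
  }
  min_coding <- gene_length_range[1] - utr5_length_range[2] -
    utr3_length_range[2]
  need <- (intron_count_range[2] + 1) * MIN_EXON +
    intron_count_range[2] * MIN_INTRON
  assert_that(min_coding >= need,
              sprintf(paste("infeasible geometry: a %d nt gene cannot hold",
                            "%d introns plus UTRs"),
                      gene_length_range[1], intron_count_range[2]))
  structure(cfg, class = "sim_config")
}

sample_range <- function(rng, n = 1) {
  if (rng[1] == rng[2]) rep(rng[1], n) else
    sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

# random integer partition of `total` into `parts` non-negative cells
rand_partition <- function(total, parts) {
  if (parts == 0) return(integer(0))
  if (parts == 1) return(total)
  w <- diff(c(0, sort(runif(parts - 1)), 1))
  x <- floor(w * total)
  rem <- total - sum(x)
  if (rem > 0) x[seq_len(rem)] <- x[seq_len(rem)] + 1
  x
}

#' Generate a synthetic genome with gene models
#'
#' Lays out genes on chromosomes (`genes_per_chrom` per chromosome, separated
#' by intergenic spacers), each with a 5' UTR, a coding region split by the
#' requested number of introns, and a 3' UTR; background sequence is i.i.d.
#' from the configured composition. Strands are sampled at random.
#'
#' @param config a [sim_config()].
#' @return list: `genome` (list of per-chromosome character vectors),
#'   `features` (gene-model data frame), `gene_plan` (per-gene local region
#'   spans used by [plant_polya_sites()]).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  comp <- config$base_comp[APA_BASES]
  draw_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE, prob = comp),
                                collapse = "")
  n_genes <- config$n_genes
  gpc <- config$genes_per_chrom
  spacer <- config$spacer
  n_chrom <- max(1, ceiling(n_genes / gpc))
  genome <- list()
  features <- list()
  plan <- list()
  gi <- 0L
  for (ci in seq_len(n_chrom)) {
    chrom <- sprintf("chr%d", ci)
    n_here <- if (n_genes == 0) 0 else
      min(gpc, n_genes - (ci - 1) * gpc)
    cursor <- spacer
    rows <- list()
    for (j in seq_len(n_here)) {
      gi <- gi + 1L
      gene_id <- sprintf("g%05d", gi)
      repeat {
        L <- sample_range(config$gene_length_range)
        I <- sample_range(config$intron_count_range)
        u5 <- sample_range(config$utr5_length_range)
        u3 <- sample_range(config$utr3_length_range)
        C <- L - u5 - u3
        if (C >= (I + 1) * MIN_EXON + I * MIN_INTRON) break
      }
      spare <- C - (I + 1) * MIN_EXON - I * MIN_INTRON
      sp_in <- if (I > 0) round(spare * 0.5) else 0
      intron_len <- MIN_INTRON + rand_partition(sp_in, I)
      exon_len <- MIN_EXON + rand_partition(spare - sp_in, I + 1)
      # local sense coordinates
      cds_loc <- matrix(0L, I + 1, 2)
      intron_loc <- if (I > 0) matrix(0L, I, 2) else matrix(0L, 0, 2)
      cur <- u5
      for (e in seq_len(I + 1)) {
        cds_loc[e, ] <- c(cur + 1, cur + exon_len[e])
        cur <- cur + exon_len[e]
        if (e <= I) {
          intron_loc[e, ] <- c(cur + 1, cur + intron_len[e])
          cur <- cur + intron_len[e]
        }
      }
      strand <- sample(c("+", "-"), 1)
      start <- cursor + 1
      end <- cursor + L
      cursor <- cursor + L + spacer
      # local feature spans (sense), mapped to plus-strand coordinates below
      types <- c("five_prime_UTR", "three_prime_UTR", rep("CDS", I + 1))
      locs_a <- c(1, L - u3 + 1, cds_loc[, 1])
      locs_b <- c(u5, L, cds_loc[, 2])
      if (I == 0) {
        types <- c(types, "exon")
        locs_a <- c(locs_a, 1)
        locs_b <- c(locs_b, L)
      } else {
        types <- c(types, rep("exon", I + 1))
        locs_a <- c(locs_a, 1, cds_loc[-1, 1])
        locs_b <- c(locs_b, cds_loc[-(I + 1), 2], L)
      }
      if (strand == "+") {
        fs <- start + locs_a - 1
        fe <- start + locs_b - 1
      } else {
        fs <- end - locs_b + 1
        fe <- end - locs_a + 1
      }
      rows[[j]] <- data.frame(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
        chrom = chrom, strand = strand, type = types, start = fs, end = fe,
        stringsAsFactors = FALSE)
      plan[[gene_id]] <- list(gene_id = gene_id, chrom = chrom,
                              strand = strand, start = start, end = end,
                              L = L, u5 = u5, u3 = u3,
                              cds_loc = cds_loc, intron_loc = intron_loc)
    }
    clen <- cursor
    genome[[chrom]] <- draw_seq(clen)
    features[[chrom]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  features <- features[!vapply(features, is.null, logical(1))]
  features <- if (length(features)) {
    do.call(rbind, c(features, make.row.names = FALSE))
  }
  if (is.null(features)) {
    features <- data.frame(gene_id = character(0),
                           transcript_id = character(0),
                           chrom = character(0), strand = character(0),
                           type = character(0), start = integer(0),
                           end = integer(0))
  }
  # optional per-region composition overrides
  if (!is.null(config$region_comp)) {
    type_map <- c(`3UTR` = "three_prime_UTR", `5UTR` = "five_prime_UTR",
                  CDS = "CDS")
    intr <- derive_introns(features)
    for (reg in names(config$region_comp)) {
      rc <- config$region_comp[[reg]][APA_BASES]
      rows <- if (reg == "intron") intr else
        features[features$type == type_map[[reg]], ]
      for (r in seq_len(nrow(rows))) {
        w <- rows$end[r] - rows$start[r] + 1
        substr(genome[[rows$chrom[r]]], rows$start[r], rows$end[r]) <-
          paste(sample(c("A", "C", "G", "T"), w, replace = TRUE, prob = rc),
                collapse = "")
      }
    }
  }
  list(genome = genome, features = features, gene_plan = plan)
}

revcomp_dna <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# sense-strand write: put sense (RNA) string `s` so that its first character
# sits at relative offset r0 of site (p, strand). Chromosomes are plain
# strings; every edit is a contiguous genomic span (the relative axis skips 0
# but maps to contiguous coordinates). Returns the genomic positions written.
write_sense <- function(genome, chrom, p, strand, r0, s) {
  s <- dna(s)
  len <- nchar(s)
  rs <- setdiff(seq(r0, r0 + len), 0)[seq_len(len)]
  gs <- rel_to_genomic(p, rs, strand)
  if (strand == "-") s <- revcomp_dna(s)
  substr(genome[[chrom]], min(gs), max(gs)) <- s
  list(genome = genome, positions = gs)
}

read_sense <- function(genome, chrom, p, strand, r0, len) {
  rs <- setdiff(seq(r0, r0 + len), 0)[seq_len(len)]
  gs <- rel_to_genomic(p, rs, strand)
  gs <- gs[gs >= 1 & gs <= nchar(genome[[chrom]])]
  if (length(gs) == 0) return("")
  s <- substr(genome[[chrom]], min(gs), max(gs))
  if (strand == "-") s <- revcomp_dna(s)
  s
}

a_rich_status <- function(win) {
  if (nchar(win) < 10) return("edge")
  wc <- strsplit(win, "")[[1]]
  wc[wc == "U"] <- "T"
  if (sum(wc == "A") >= 6) return("fail_ARS")
  if (paste(wc[1:4], collapse = "") %in%
        c("AAAA", "AGAA", "AAGA", "AAAG")) return("fail_tetramer")
  if (max_run(wc, "A") >= 6) return("fail_runA")
  "pass"
}

draw_stage_counts <- function(profile, stage, cfg) {
  n <- cfg$n_stages
  size <- 1 / cfg$dispersion
  mu <- rep(cfg$mu_off, n)
  if (profile == "constitutive") {
    mu[] <- cfg$mu_constitutive
  } else if (startsWith(profile, "specific")) {
    mu[stage] <- cfg$mu_specific
  } else {
    on <- sample(seq_len(n), sample(2:6, 1))
    mu[on] <- cfg$mu_background
  }
  counts <- rnbinom(n, mu = mu, size = size)
  if (sum(counts) == 0) counts[which.max(mu)] <- 1L
  list(mu = mu, counts = counts)
}

#' Plant poly(A) sites, signal motifs and stage counts on a synthetic genome
#'
#' For each gene, places 1 + Poisson(`apa_lambda`) cleavage sites (the first
#' always in the 3' UTR, the rest sampled over regions), writes the YA
#' cleavage dinucleotide and the grammar motifs into the genome, assigns each
#' site an expression archetype (stage-specific / constitutive / background)
#' and draws its per-stage counts, emits cleavage events (a main event plus
#' optional minor events within 12 nt), and finally rewrites every clean
#' site's downstream +1..+10 window, where needed, so that it cannot trip the
#' internal-priming filter by chance (planted motif positions are never
#' touched).
#'
#' @param sim output of [generate_genome()].
#' @param config the same [sim_config()].
#' @return list: `genome` (modified), `events`, `event_counts`, `counts`
#'   (site x stage), `truth`, `truth_motifs`.
#' @export
plant_polya_sites <- function(sim, config) {
  genome <- sim$genome
  plan <- sim$gene_plan
  grammar <- config$signal_grammar
  stopifnot(nrow(sim$features) == 0 || length(plan) > 0)

  # --- place sites ---------------------------------------------------------
  place <- list()
  for (g in plan) {
    ns <- min(1 + rpois(1, config$apa_lambda), config$max_sites)
    regions <- "3UTR"
    if (ns > 1) {
      w <- config$region_weights
      if (nrow(g$intron_loc) == 0) w <- w[names(w) != "intron"]
      regions <- c(regions, sample(names(w), ns - 1, replace = TRUE,
                                   prob = w))
    }
    locs <- integer(0)
    keep_regions <- character(0)
    for (reg in regions) {
      rng <- switch(reg,
        `3UTR` = c(g$L - g$u3 + 16, g$L - 15),
        `5UTR` = c(16, g$u5 - 15),
        CDS = {
          ok <- which(g$cds_loc[, 2] - g$cds_loc[, 1] >= 40)
          e <- ok[sample.int(length(ok), 1)]
          c(g$cds_loc[e, 1] + 15, g$cds_loc[e, 2] - 15)
        },
        intron = {
          e <- sample.int(nrow(g$intron_loc), 1)
          c(g$intron_loc[e, 1] + 15, g$intron_loc[e, 2] - 15)
        },
        Ex_3UTR = c(g$L + 20, g$L + 500))
      if (rng[2] < rng[1]) next
      placed <- FALSE
      for (try in 1:20) {
        l <- sample_range(rng)
        if (all(abs(l - locs) >= config$min_site_gap)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      locs <- c(locs, l)
      keep_regions <- c(keep_regions, reg)
    }
    if (length(locs) == 0) next
    p <- if (g$strand == "+") g$start + locs - 1 else g$end - locs + 1
    place[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      local = locs, position = p, region = keep_regions,
      stringsAsFactors = FALSE)
  }
  if (length(place) == 0) {
    stop("plant_polya_sites: no sites could be placed", call. = FALSE)
  }
  truth <- do.call(rbind, c(place, make.row.names = FALSE))
  truth <- data.frame(site_id = sprintf("site_%05d", seq_len(nrow(truth))),
                      truth, stringsAsFactors = FALSE)

  # --- expression archetypes (region-skewed quotas) ------------------------
  n <- nrow(truth)
  profile <- rep("background", n)
  pool <- seq_len(n)
  n_cons <- round(n * config$prop_constitutive)
  n_spec <- round(n * config$prop_specific)
  pick_from <- function(candidates, k, pool) {
    cand <- intersect(candidates, pool)
    sample(cand, min(k, length(cand)))
  }
  utr3_sites <- which(truth$region %in% c("3UTR", "Ex_3UTR"))
  prox_sites <- which(truth$region %in% c("5UTR", "CDS", "intron"))
  cons <- pick_from(utr3_sites, round(n_cons * config$constitutive_3utr_frac),
                    pool)
  pool <- setdiff(pool, cons)
  cons2 <- pick_from(setdiff(seq_len(n), utr3_sites), n_cons - length(cons),
                     pool)
  cons <- c(cons, cons2)
  pool <- setdiff(pool, cons2)
  spec <- pick_from(prox_sites, round(n_spec * config$specific_proximal_frac),
                    pool)
  pool <- setdiff(pool, spec)
  spec2 <- pick_from(pool, n_spec - length(spec), pool)
  spec <- c(spec, spec2)
  profile[cons] <- "constitutive"
  profile[spec] <- "specific"
  truth$profile <- profile
  truth$specific_stage <- NA_integer_
  truth$specific_stage[spec] <- sample(seq_len(config$n_stages),
                                       length(spec), replace = TRUE)

  # --- counts --------------------------------------------------------------
  counts <- matrix(0L, n, config$n_stages,
                   dimnames = list(truth$site_id, config$stage_names))
  mus <- matrix(0, n, config$n_stages)
  for (i in seq_len(n)) {
    d <- draw_stage_counts(truth$profile[i], truth$specific_stage[i], config)
    counts[i, ] <- d$counts
    mus[i, ] <- d$mu
  }
  colnames(mus) <- paste0("mu_", config$stage_names)
  truth <- cbind(truth, mus)

  # --- motif + YA planting -------------------------------------------------
  # Edits run per chromosome on a local character vector so that the repeated
  # small writes mutate in place; site order follows the truth table so the
  # RNG stream (and hence the output) is independent of chromosome grouping
  # only in the sense that the per-chromosome order is the truth order.
  mot_site <- character(0)
  mot_el <- character(0)
  mot_motif <- character(0)
  mot_off <- integer(0)
  truth$ya <- runif(n) < config$ya_prob
  comp <- config$base_comp[APA_BASES]
  for (chrom in unique(truth$chrom)) {
    chars <- strsplit(genome[[chrom]], "")[[1]]
    protected <- integer(0)
    idx_sites <- which(truth$chrom == chrom)
    for (i in idx_sites) {
      p <- truth$position[i]
      strand <- truth$strand[i]
      minus <- strand == "-"
      if (truth$ya[i]) {
        y <- sample(c("T", "C"), 1)
        gs <- rel_to_genomic(p, c(-2, -1), strand)
        ya_chars <- c(y, "A")
        chars[gs] <- if (minus) chartr("ACGT", "TGCA", ya_chars) else ya_chars
      }
      greg <- if (truth$region[i] == "Ex_3UTR") "3UTR" else truth$region[i]
      rows <- grammar[grammar$region == greg, , drop = FALSE]
      for (el in unique(rows$element)) {
        er <- rows[rows$element == el, , drop = FALSE]
        u <- runif(1)
        cp <- cumsum(er$prob)
        j <- which(u <= cp)[1]
        if (is.na(j)) next
        motif <- er$motif[j]
        len <- nchar(motif)
        off <- NA
        for (try in 1:20) {
          cand <- round(rnorm(1, er$mean_offset[j], er$sd_offset[j]))
          if (cand == 0) next
          span <- setdiff(seq(cand, cand + len), 0)[seq_len(len)]
          if (span[1] >= -300 && span[len] <= 100) {
            off <- cand
            break
          }
        }
        if (is.na(off)) next
        rs <- setdiff(seq(off, off + len), 0)[seq_len(len)]
        gs <- rel_to_genomic(p, rs, strand)
        mc <- strsplit(dna(motif), "")[[1]]
        chars[gs] <- if (minus) chartr("ACGT", "TGCA", mc) else mc
        protected <- c(protected, gs)
        mot_site <- c(mot_site, truth$site_id[i])
        mot_el <- c(mot_el, el)
        mot_motif <- c(mot_motif, motif)
        mot_off <- c(mot_off, off)
      }
    }
    # sanitize clean downstream windows on this chromosome
    for (i in idx_sites) {
      p <- truth$position[i]
      strand <- truth$strand[i]
      minus <- strand == "-"
      gs <- rel_to_genomic(p, 1:10, strand)
      gs <- gs[gs >= 1 & gs <= length(chars)]
      if (length(gs) < 10) next
      free <- !(gs %in% protected)
      for (try in 1:50) {
        wc <- chars[gs]
        if (minus) wc <- chartr("ACGT", "TGCA", wc)
        if (a_rich_status(paste(wc, collapse = "")) == "pass") break
        if (!any(free)) break
        repl <- sample(c("A", "C", "G", "T"), sum(free), replace = TRUE,
                       prob = comp)
        if (try > 40) repl <- rep("C", sum(free))
        if (minus) repl <- chartr("ACGT", "TGCA", repl)
        chars[gs[free]] <- repl
      }
    }
    genome[[chrom]] <- paste(chars, collapse = "")
  }
  truth_motifs <- data.frame(site_id = mot_site, element = mot_el,
                             motif = mot_motif, offset = mot_off,
                             stringsAsFactors = FALSE)

  # --- cleavage events -----------------------------------------------------
  ev_site <- integer(0)
  ev_off <- integer(0)
  ev_counts <- list()
  for (i in seq_len(n)) {
    main <- counts[i, ]
    n_minor <- sample(0:2, 1)
    offs <- if (n_minor > 0) sample(c(-(3:12), 3:12), n_minor) else integer(0)
    keep_offs <- integer(0)
    minors <- list()
    for (o in offs) {
      mc <- rbinom(length(main), main, 0.08)
      if (sum(mc) == 0 || 2 * sum(mc) >= sum(main - mc)) next
      main <- main - mc
      keep_offs <- c(keep_offs, o)
      minors[[length(minors) + 1]] <- mc
    }
    ev_site <- c(ev_site, rep(i, 1 + length(keep_offs)))
    ev_off <- c(ev_off, 0L, keep_offs)
    ev_counts[[length(ev_counts) + 1]] <- main
    for (mc in minors) ev_counts[[length(ev_counts) + 1]] <- mc
  }
  events <- data.frame(
    event_id = sprintf("ev%06d", seq_along(ev_site)),
    site_id = truth$site_id[ev_site], chrom = truth$chrom[ev_site],
    strand = truth$strand[ev_site],
    position = truth$position[ev_site] + ev_off, stringsAsFactors = FALSE)
  event_counts <- do.call(rbind, ev_counts)
  rownames(event_counts) <- events$event_id
  colnames(event_counts) <- config$stage_names
  # guard against coincidental duplicate event coordinates
  dup <- duplicated(events[c("chrom", "strand", "position")])
  if (any(dup)) {
    keep <- !dup | events$position == truth$position[
      match(events$site_id, truth$site_id)]
    drop_minor <- dup & !keep
    events <- events[!drop_minor, ]
    event_counts <- event_counts[!drop_minor, , drop = FALSE]
  }

  list(genome = genome, events = events, event_counts = event_counts,
       counts = counts, truth = truth, truth_motifs = truth_motifs)
}

#' Rewrite a fraction of sites as internal-priming artifacts
#'
#' Each selected site's downstream +1..+10 sense window is rewritten to
#' satisfy one of the removal rules (chosen uniformly): six or more adenines
#' in the window, a leading AAAA/AGAA/AAGA/AAAG tetramer, or a run of six
#' consecutive adenines. Flags and the applied rule are recorded in the truth
#' table.
#'
#' @param genome per-chromosome character-vector genome.
#' @param truth truth table from [plant_polya_sites()].
#' @param rate fraction of sites to rewrite (in `[0, 1]`).
#' @param seed optional seed.
#' @return list: `genome`, `truth` (with `artifact`, `artifact_rule`).
#' @export
inject_internal_priming <- function(genome, truth, rate, seed = NULL) {
  assert_that(rate >= 0 && rate <= 1, "rate must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  flags <- runif(n) < rate
  rules <- rep(NA_character_, n)
  non_a <- c("C", "G", "T")
  for (i in which(flags)) {
    rule <- sample(c("ARS", "tetramer", "runA"), 1)
    win <- character(10)
    if (rule == "ARS") {
      nA <- sample(6:9, 1)
      apos <- sample(10, nA)
      win[apos] <- "A"
      win[-apos] <- sample(non_a, 10 - nA, replace = TRUE)
    } else if (rule == "tetramer") {
      tet <- sample(c("AAAA", "AGAA", "AAGA", "AAAG"), 1)
      win[1:4] <- strsplit(tet, "")[[1]]
      win[5:10] <- sample(non_a, 6, replace = TRUE)
    } else {
      s <- sample(1:5, 1)
      win[s:(s + 5)] <- "A"
      rest <- setdiff(1:10, s:(s + 5))
      win[rest] <- sample(non_a, length(rest), replace = TRUE)
    }
    res <- write_sense(genome, truth$chrom[i], truth$position[i],
                       truth$strand[i], 1, paste(win, collapse = ""))
    genome <- res$genome
    rules[i] <- rule
  }
  truth$artifact <- flags
  truth$artifact_rule <- rules
  truth
  list(genome = genome, truth = truth)
}

#' Run the full synthetic APA study generator
#'
#' Deterministic given the config (which includes the seed): genome and gene
#' models, planted sites with signal grammar and YA dinucleotides, stage
#' counts, cleavage events, and internal-priming artifacts.
#'
#' @param config a [sim_config()].
#' @return list: `genome` (named `DNAStringSet`), `features`, `events`,
#'   `event_counts`, `counts`, `truth`, `truth_motifs`, `config`.
#' @export
simulate_apa_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gg <- generate_genome(config)
  if (config$n_genes == 0) {
    return(list(genome = collapse_genome(gg$genome), features = gg$features,
                events = NULL, event_counts = NULL, counts = NULL,
                truth = NULL, truth_motifs = NULL, config = config))
  }
  pl <- plant_polya_sites(gg, config)
  ip <- inject_internal_priming(pl$genome, pl$truth, config$artifact_rate)
  list(genome = collapse_genome(ip$genome), features = gg$features,
       events = pl$events, event_counts = pl$event_counts,
       counts = pl$counts, truth = ip$truth,
       truth_motifs = pl$truth_motifs, config = config)
}

collapse_genome <- function(genome) {
  Biostrings::DNAStringSet(unlist(genome))
}

#' Simulate flank sequences with planted motifs (flank-level generator)
#'
#' A lighter-weight generator for motif-statistics studies: i.i.d. background
#' flanks with the signal grammar planted directly, plus an optional decoy
#' word scattered uniformly over the whole flank (no positional preference).
#'
#' @param n number of flanks.
#' @param grammar grammar rows (element, motif, mean_offset, sd_offset, prob);
#'   the `region` column is ignored here.
#' @param decoy optional list(motif =, prob =) of a uniformly placed word.
#' @param comp background composition.
#' @param up,down flank extents.
#' @param ya_prob fraction of flanks with YA at (-2, -1).
#' @param seed optional seed.
#' @return list: `flanks` (site_id, upstream, downstream), `truth` (planted
#'   motif offsets per flank).
#' @export
simulate_flanks <- function(n, grammar = default_signal_grammar(),
                            decoy = NULL,
                            comp = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                            up = 300, down = 100, ya_prob = 0.8,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  width <- up + down
  M <- matrix(sample(APA_BASES, n * width, replace = TRUE,
                     prob = comp[APA_BASES]),
              nrow = n)
  idx <- function(r) ifelse(r < 0, up + r + 1, up + r)
  ya <- runif(n) < ya_prob
  M[ya, idx(-2)] <- sample(c("U", "C"), sum(ya), replace = TRUE)
  M[ya, idx(-1)] <- "A"
  rows <- list()
  plant <- function(i, motif, r0, element) {
    len <- nchar(motif)
    span <- setdiff(seq(r0, r0 + len), 0)[seq_len(len)]
    M[i, idx(span)] <<- strsplit(motif, "")[[1]]
    rows[[length(rows) + 1]] <<- data.frame(
      site_id = sprintf("f%05d", i), element = element, motif = motif,
      offset = r0, stringsAsFactors = FALSE)
  }
  for (el in unique(grammar$element)) {
    er <- grammar[grammar$element == el, , drop = FALSE]
    er <- er[!duplicated(er$motif), , drop = FALSE]
    cp <- cumsum(er$prob)
    u <- runif(n)
    for (i in seq_len(n)) {
      j <- which(u[i] <= cp)[1]
      if (is.na(j)) next
      len <- nchar(er$motif[j])
      for (try in 1:20) {
        cand <- round(rnorm(1, er$mean_offset[j], er$sd_offset[j]))
        if (cand == 0) next
        span <- setdiff(seq(cand, cand + len), 0)[seq_len(len)]
        if (span[1] >= -up && span[len] <= down) {
          plant(i, er$motif[j], cand, el)
          break
        }
      }
    }
  }
  if (!is.null(decoy)) {
    len <- nchar(decoy$motif)
    starts <- setdiff(seq(-up, down - len), 0)
    starts <- starts[vapply(starts, function(s) {
      sp <- setdiff(seq(s, s + len), 0)[seq_len(len)]
      sp[len] <= down
    }, logical(1))]
    hit <- runif(n) < decoy$prob
    for (i in which(hit)) {
      plant(i, decoy$motif, sample(starts, 1), "decoy")
    }
  }
  upstream <- apply(M[, seq_len(up), drop = FALSE], 1, paste, collapse = "")
  downstream <- apply(M[, up + seq_len(down), drop = FALSE], 1, paste,
                      collapse = "")
  truth <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(site_id = character(0), element = character(0),
                    motif = character(0), offset = integer(0))
  list(flanks = data.frame(site_id = sprintf("f%05d", seq_len(n)),
                           upstream = upstream, downstream = downstream,
                           up_trunc = FALSE, down_trunc = FALSE,
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a site-by-stage count matrix with planted specificity labels
#'
#' @param n_sites number of sites.
#' @param config a [sim_config()] providing the stage/profile parameters.
#' @param seed optional seed.
#' @return list: `counts` (matrix), `truth` (site_id, profile,
#'   specific_stage).
#' @export
simulate_stage_counts <- function(n_sites, config = sim_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  profile <- sample(c("specific", "constitutive", "background"), n_sites,
                    replace = TRUE,
                    prob = c(config$prop_specific, config$prop_constitutive,
                             1 - config$prop_specific -
                               config$prop_constitutive))
  stage <- ifelse(profile == "specific",
                  sample(seq_len(config$n_stages), n_sites, replace = TRUE),
                  NA_integer_)
  counts <- matrix(0L, n_sites, config$n_stages,
                   dimnames = list(sprintf("s%05d", seq_len(n_sites)),
                                   config$stage_names))
  for (i in seq_len(n_sites)) {
    counts[i, ] <- draw_stage_counts(profile[i], stage[i], config)$counts
  }
  list(counts = counts,
       truth = data.frame(site_id = rownames(counts), profile = profile,
                          specific_stage = stage, stringsAsFactors = FALSE))
}
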