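#' Pipeline configuration
#'
#' Bundles every stage parameter with either a simulation config (synthetic
#' run) or input file paths (genome FASTA, gene models GFF3, cleavage events
#' BED, event count TSV).
#'
#' @param outdir output directory.
#' @param sim optional [sim_config()] (synthetic input).
#' @param genome_path,gff_path,events_path,counts_path input files, required
#'   when `sim` is NULL.
#' @param max_gap cleavage-event clustering gap (nt).
#' @param extension Ex_3UTR / Ex_5UTR extension (nt).
#' @param k word length for signal scans.
#' @param p_cut,sd_cut greedy-selection cutoffs.
#' @param zoe_pct,zsw_cut,cluster_cutoff schema screening parameters.
#' @param pct,min_reads entropy labelling parameters.
#' @param n_controls optional number of control pseudo-sites to sample.
#' @param seed pipeline seed.
#' @export
pipeline_config <- function(outdir, sim = NULL, genome_path = NULL,
                            gff_path = NULL, events_path = NULL,
                            counts_path = NULL, max_gap = 24,
                            extension = 1000, k = 6, p_cut = 1e-5,
                            sd_cut = 7, zoe_pct = 0.99, zsw_cut = 1.96,
                            cluster_cutoff = 2.6, pct = 5, min_reads = 5,
                            n_controls = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (is.null(sim)) {
    for (f in c("genome_path", "gff_path", "events_path", "counts_path")) {
      assert_that(!is.null(cfg[[f]]),
                  sprintf("pipeline_config: missing required field '%s'", f))
      assert_that(file.exists(cfg[[f]]),
                  sprintf("pipeline_config: %s does not exist: %s", f,
                          cfg[[f]]))
    }
  }
  structure(cfg, class = "apa_pipeline_config")
}

stage_log <- function(name, fmt, ...) {
  message(sprintf("[%s] %s", name, sprintf(fmt, ...)))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the end-to-end APA signal pipeline
#'
#' Simulate (or load) cleavage events; cluster them into poly(A) site
#' clusters; apply the internal-priming filter; extract flanks; annotate
#' genomic regions and gene-level APA statistics; classify 3'UTR sites by
#' usage; discover positioning-element signals (greedy selection) and build
#' per-class cis-element schemas; call stage-specific/constitutive sites and
#' summarise per stage. All tables are written under `config$outdir` along
#' with a JSON manifest (parameters, record counts, file checksums). On a
#' stage failure the partial outputs are moved to `outdir/quarantine` and the
#' error names the stage.
#'
#' @param config an [pipeline_config()] object.
#' @return invisible list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "apa_pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv_quiet(df, p)
    written <<- c(written, p)
    p
  }
  tryCatch(run_pipeline_impl(config, emit, environment()),
           error = function(e) {
             qdir <- file.path(outdir, "quarantine")
             dir.create(qdir, showWarnings = FALSE)
             for (p in written) file.rename(p, file.path(qdir, basename(p)))
             stop(e)
           })
}

run_pipeline_impl <- function(config, emit, written_env) {
  set.seed(config$seed)
  t0 <- Sys.time()

  # --- input ---------------------------------------------------------------
  inputs <- run_stage("input", {
    if (!is.null(config$sim)) {
      sim <- simulate_apa_study(config$sim)
      stage_log("input", "simulated %d genes, %d events",
                config$sim$n_genes, nrow(sim$events))
      list(genome = sim$genome, features = sim$features,
           events = sim$events, event_counts = sim$event_counts,
           truth = sim$truth)
    } else {
      genome <- Biostrings::readDNAStringSet(config$genome_path)
      names(genome) <- sub("\\s.*", "", names(genome))
      features <- read_gff3(config$gff_path)
      events <- read_events_bed(config$events_path)
      event_counts <- read_counts_tsv(config$counts_path)
      stage_log("input", "loaded %d events on %d chromosomes",
                nrow(events), length(genome))
      list(genome = genome, features = features, events = events,
           event_counts = event_counts, truth = NULL)
    }
  })

  # --- cluster -------------------------------------------------------------
  clusters <- run_stage("cluster", {
    cl <- cluster_cleavage_events(inputs$events, inputs$event_counts,
                                  max_gap = config$max_gap)
    stage_log("cluster", "%d events -> %d poly(A) site clusters",
              nrow(inputs$events), nrow(cl$sites))
    cl
  })

  # --- filter --------------------------------------------------------------
  filt <- run_stage("filter", {
    fr <- filter_a_rich(clusters$sites, inputs$genome)
    emit(fr, "filter_report.tsv")
    keep <- fr$filter_status == "pass"
    stage_log("filter", "%d/%d sites pass the internal-priming filter",
              sum(keep), nrow(fr))
    list(report = fr, sites = clusters$sites[keep, ],
         counts = clusters$counts[keep, , drop = FALSE])
  })
  emit(filt$sites, "sites.tsv")

  # --- flanks --------------------------------------------------------------
  flanks <- run_stage("flanks", {
    fl <- extract_flank(filt$sites, inputs$genome)
    stage_log("flanks", "extracted %d flanks", nrow(fl))
    fl
  })

  # --- annotate ------------------------------------------------------------
  ann <- run_stage("annotate", {
    a <- assign_region(filt$sites, inputs$features,
                       extension = config$extension)
    emit(a, "annotations.tsv")
    gs <- gene_apa_stats(a, inputs$features)
    emit(gs, "gene_stats.tsv")
    cm <- correlation_matrix(gs)
    emit(data.frame(var = rownames(cm$r), cm$r, check.names = FALSE),
         "correlation_r.tsv")
    emit(data.frame(var = rownames(cm$p), cm$p, check.names = FALSE),
         "correlation_p.tsv")
    stage_log("annotate", "regions: %s",
              paste(sprintf("%s=%d", names(table(a$region)),
                            table(a$region)), collapse = " "))
    list(annotations = a, gene_stats = gs, correlations = cm)
  })

  # --- classify ------------------------------------------------------------
  classes <- run_stage("classify", {
    genic <- !is.na(ann$annotations$gene_id)
    cls_in <- data.frame(
      site_id = filt$sites$site_id[genic],
      gene_id = ann$annotations$gene_id[genic],
      reads = rowSums(filt$counts)[genic])
    cls <- classify_sites(cls_in)
    emit(cls, "classes.tsv")
    stage_log("classify", "%s",
              paste(sprintf("%s=%d", names(table(cls$class)),
                            table(cls$class)), collapse = " "))
    cls
  })
  controls <- NULL
  if (!is.null(config$n_controls)) {
    controls <- run_stage("controls", {
      ctrl <- sample_control_sites(inputs$genome, filt$sites,
                                   config$n_controls)
      emit(ctrl, "control_sites.tsv")
      ctrl
    })
  }

  # --- signal discovery ----------------------------------------------------
  signals <- run_stage("signals", {
    ann3 <- ann$annotations$region == "3UTR"
    fl3 <- flanks[ann3, ]
    pe <- segment_regions("3UTR")
    pe_win <- c(pe$start[pe$name == "PE"], pe$end[pe$name == "PE"])
    sel <- greedy_signal_selection(fl3, pe_win, k = config$k,
                                   p_cut = config$p_cut,
                                   sd_cut = config$sd_cut)
    emit(sel, "pe_signals.tsv")
    stage_log("signals", "%d positioning-element signals selected",
              nrow(sel))
    schemas <- list()
    for (cls in c("3UTR", "5UTR", "CDS", "intron")) {
      idx <- ann$annotations$region == cls
      if (sum(idx) < 50) next
      strong_idx <- classes$class %in% "strong"
      weak_idx <- classes$class %in% "weak"
      strong_fl <- flanks[match(classes$site_id[strong_idx],
                                flanks$site_id), ]
      weak_fl <- flanks[match(classes$site_id[weak_idx], flanks$site_id), ]
      use_sw <- cls == "3UTR" && nrow(strong_fl) >= 50 && nrow(weak_fl) >= 50
      sc <- build_schema(flanks[idx, ], cls,
                         strong_flanks = if (use_sw) strong_fl,
                         weak_flanks = if (use_sw) weak_fl,
                         k = config$k, zoe_pct = config$zoe_pct,
                         zsw_cut = config$zsw_cut,
                         cluster_cutoff = config$cluster_cutoff)
      schemas[[cls]] <- sc
      emit(sc$elements, sprintf("schema_%s_elements.tsv", cls))
      ppath <- file.path(config$outdir, sprintf("schema_%s_pfms.txt", cls))
      write_pfms_jaspar(sc$groups, ppath)
      assign("written", c(get("written", written_env), ppath),
             envir = written_env)
    }
    prof <- nucleotide_profile(fl3)
    emit(prof, "nucleotide_profile_3UTR.tsv")
    list(pe = sel, schemas = schemas, profile = prof)
  })

  # --- entropy -------------------------------------------------------------
  entropy <- run_stage("entropy", {
    calls <- call_specific_constitutive(filt$counts, pct = config$pct,
                                        min_reads = config$min_reads)
    emit(calls, "entropy.tsv")
    summ <- stage_summaries(calls, ann$annotations, filt$counts)
    emit(summ$per_stage, "per_stage.tsv")
    emit(summ$region_composition, "region_composition.tsv")
    emit(data.frame(stage = rownames(summ$gene_overlap), summ$gene_overlap,
                    check.names = FALSE), "gene_overlap.tsv")
    stage_log("entropy", "%s",
              paste(sprintf("%s=%d", names(table(calls$label)),
                            table(calls$label)), collapse = " "))
    list(calls = calls, summaries = summ)
  })

  # --- manifest ------------------------------------------------------------
  run_stage("manifest", {
    written <- get("written", written_env)
    files <- data.frame(file = basename(written),
                        md5 = unname(tools::md5sum(written)),
                        stringsAsFactors = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("apasignal")),
      parameters = config[setdiff(names(config), c("sim", "outdir"))],
      n_events = nrow(inputs$events),
      n_clusters = nrow(clusters$sites),
      n_pass = nrow(filt$sites),
      n_genes = length(unique(inputs$features$gene_id)),
      wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      files = files)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(config$outdir,
                                               "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      saveRDS_free <- utils::capture.output(utils::str(manifest))
      writeLines(saveRDS_free, file.path(config$outdir, "manifest.txt"))
    }
  })
  stage_log("done", "outputs in %s", config$outdir)
  invisible(list(inputs = inputs, clusters = clusters, filter = filt,
                 flanks = flanks, annotation = ann, classes = classes,
                 controls = controls, signals = signals, entropy = entropy))
}
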