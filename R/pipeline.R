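#' Validate pipeline inputs
#'
#' Diagnostic (non-fatal) checks on a count matrix and its metadata, or on a
#' calorimetry trace: metadata completeness (group/ZT/replicate per sample),
#' count integrality for ASV tables, cadence regularity for traces.
#'
#' @param counts Optional feature x sample matrix.
#' @param metadata Optional sample metadata data frame.
#' @param trace Optional `calorimetry_trace`.
#' @param integer_counts Require integer counts (ASV tables).
#' @return Character vector of diagnostics (empty when everything is
#'   well-formed).
#' @export
validate_inputs <- function(counts = NULL, metadata = NULL, trace = NULL,
                            integer_counts = FALSE) {
  diag <- character(0)
  if (!is.null(counts) && !is.null(metadata)) {
    missing_samp <- setdiff(colnames(counts), metadata$sample)
    if (length(missing_samp))
      diag <- c(diag, paste0("samples without metadata: ",
                             paste(missing_samp, collapse = ", ")))
    for (col in c("group", "zt", "replicate")) {
      if (!col %in% names(metadata)) {
        diag <- c(diag, paste0("metadata lacks column '", col, "'"))
      } else if (anyNA(metadata[[col]])) {
        bad <- metadata$sample[is.na(metadata[[col]])]
        diag <- c(diag, paste0("sample(s) missing ", col, ": ",
                               paste(bad, collapse = ", ")))
      }
    }
    if (integer_counts && any(counts != round(counts)))
      diag <- c(diag, "non-integer counts in feature table")
    if (!is.null(counts) && any(counts < 0))
      diag <- c(diag, "negative counts in feature table")
  }
  if (!is.null(trace)) {
    dt <- diff(trace$data$time_min)
    if (length(unique(round(dt, 6))) > 1L)
      diag <- c(diag, "irregular calorimetry cadence")
  }
  diag
}

#' Default pipeline configuration
#'
#' A complete, bundled configuration that simulates the factorial study
#' design at reduced scale and runs every analysis arm. Any block can be
#' removed (that stage is then skipped) or overridden.
#'
#' @param seed Global seed; each stochastic stage receives a derived,
#'   recorded sub-seed.
#' @param outdir Output directory.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, outdir = tempfile("dielrun")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(
      transcripts = list(n_features = 300L, frac_oscillating = 0.2,
                         amplitude = 1.5, dispersion = 0.05),
      asv = list(n_features = 80L, frac_oscillating = 0.25, amplitude = 1.5,
                 depth_range = c(15000L, 40000L)),
      calorimetry = list(n_days = 4L, n_spikes = 20L)
    ),
    rhythm = list(n_null = 2000L, phase_step_h = 2, alpha = 0.05),
    partition = list(),
    micro = list(min_prevalence = 10L, epochs = 5000L,
                 learning_rate = 1e-4),
    network = list(n_permutations = 500L, p_threshold = 0.001,
                   r_threshold = 0.95, n_features = 40L),
    cal = list(k_sn = 3)
  )
}

derive_seed <- function(seed, offset) (as.integer(seed) * 97L + offset) %%
  2147483647L

#' Run the full diurnal analysis pipeline
#'
#' Orchestrates simulate -> rhythm detection -> factorial partitioning ->
#' microbiome composition -> coexpression network -> calorimetry from one
#' declarative config. Stage artifacts are written as TSV/JSON under the
#' configured output directory with md5 checksums; the returned report lists
#' seeds, thresholds and before/after counts of every filter, so the run is
#' fully reproducible from the config alone. A stage is skipped (and logged
#' as skipped) when its config block is absent.
#'
#' @param config A config list as from [default_config()], or the path of a
#'   YAML file holding one.
#' @return A run report list (also written to `report.json`): per-stage
#'   summaries and a `checksums` table of written artifacts.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$seed))
  outdir <- config$outdir %||% tempfile("dielrun")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, outdir = outdir, stages = list())
  art <- character(0)
  save_art <- function(x, name) {
    p <- file.path(outdir, name)
    if (is.matrix(x) || is.data.frame(x)) write_tsv(x, p)
    else jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    art <<- c(art, p)
    p
  }

  sim <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    sim <- list()
    if (!is.null(sc$transcripts)) {
      tcfg <- sc$transcripts
      design <- diurnal_design(seed = derive_seed(config$seed, 1L))
      truth <- oscillator_truth(tcfg$n_features,
                                frac_oscillating = tcfg$frac_oscillating,
                                amplitude = tcfg$amplitude,
                                dispersion = tcfg$dispersion,
                                seed = derive_seed(config$seed, 2L))
      sim$transcripts <- simulate_transcript_counts(design, truth,
        seed = derive_seed(config$seed, 3L))
      save_art(sim$transcripts$counts, "transcript_counts.tsv")
      save_art(sim$transcripts$samples, "transcript_metadata.tsv")
      save_art(truth, "transcript_truth.tsv")
    }
    if (!is.null(sc$asv)) {
      acfg <- sc$asv
      sdesign <- diurnal_design(groups = c("WT", "LKO"),
                                timepoints_h = c(2, 8, 14, 20),
                                n_replicates = 8L, n_cycles = 2L,
                                seed = derive_seed(config$seed, 4L))
      atruth <- oscillator_truth(acfg$n_features, groups = c("WT", "LKO"),
                                 frac_oscillating = acfg$frac_oscillating,
                                 oscillates_in = c("WT", "LKO"),
                                 amplitude = acfg$amplitude,
                                 seed = derive_seed(config$seed, 5L))
      sim$asv <- simulate_asv_table(sdesign, atruth,
                                    depth_range = acfg$depth_range,
                                    seed = derive_seed(config$seed, 6L))
      save_art(sim$asv$counts, "asv_counts.tsv")
      save_art(sim$asv$taxonomy, "asv_taxonomy.tsv")
    }
    if (!is.null(sc$calorimetry)) {
      sim$cal <- simulate_calorimetry_trace(
        n_days = sc$calorimetry$n_days,
        n_spikes = sc$calorimetry$n_spikes %||% 0L,
        seed = derive_seed(config$seed, 7L))
    }
    report$stages$simulate <- list(
      status = "done",
      seeds = list(design = derive_seed(config$seed, 1L),
                   truth = derive_seed(config$seed, 2L)))
  }

  rhythm_res <- NULL
  if (!is.null(config$rhythm) && !is.null(sim$transcripts)) {
    rc <- config$rhythm
    ex <- sim$transcripts
    rhythm_res <- lapply(unique(ex$samples$group), function(g) {
      cols <- ex$samples$sample[ex$samples$group == g]
      sub <- ex$counts[, cols, drop = FALSE]
      zt <- ex$samples$zt_mod[match(cols, ex$samples$sample)]
      wf <- build_reference_waveforms(zt, phase_step_h = rc$phase_step_h)
      ejtk_scan(log1p(sub), wf, n_null = rc$n_null,
                seed = derive_seed(config$seed, 10L), alpha = rc$alpha)
    })
    names(rhythm_res) <- unique(ex$samples$group)
    for (g in names(rhythm_res))
      save_art(rhythm_res[[g]], paste0("rhythm_", g, ".tsv"))
    report$stages$rhythm <- list(
      status = "done", n_null = rc$n_null,
      n_oscillating = vapply(rhythm_res, function(r) sum(r$oscillating),
                             integer(1)))
  } else {
    report$stages$rhythm <- list(status = "skipped")
  }

  if (!is.null(config$partition) && !is.null(rhythm_res) &&
      length(rhythm_res) == 4L) {
    calls <- vapply(rhythm_res, function(r) r$oscillating,
                    logical(nrow(rhythm_res[[1L]])))
    rownames(calls) <- rhythm_res[[1L]]$feature
    venn <- overlap_counts(calls)
    drivers <- classify_drivers(calls)
    save_art(drivers, "driver_classification.tsv")
    report$stages$partition <- list(
      status = "done",
      venn = as.list(venn),
      categories = as.list(table(drivers$category)))
  } else {
    report$stages$partition <- list(status = "skipped")
  }

  if (!is.null(config$micro) && !is.null(sim$asv)) {
    mc <- config$micro
    tab <- filter_samples_by_depth(sim$asv)
    tab <- filter_features_by_prevalence(tab,
                                         min_samples = mc$min_prevalence)
    wt_cols <- tab$samples$sample[tab$samples$group == "WT"]
    zt <- tab$samples$zt[match(wt_cols, tab$samples$sample)]
    diffs <- multinomial_differentials(
      tab$counts[, wt_cols, drop = FALSE], zt_labels = zt,
      reference_zt = as.character(min(zt)),
      epochs = mc$epochs, learning_rate = mc$learning_rate)
    save_art(diffs$differentials, "asv_differentials.tsv")
    report$stages$micro <- list(
      status = "done",
      filters = lapply(tab$filter_log, function(l)
        l[c("rule", "n_before", "n_after")]),
      differential_converged = diffs$converged)
  } else {
    report$stages$micro <- list(status = "skipped")
  }

  if (!is.null(config$network) && !is.null(sim$transcripts)) {
    nc <- config$network
    ex <- sim$transcripts
    g <- ex$samples$group[1L]
    cols <- ex$samples$sample[ex$samples$group == g]
    sub <- ex$counts[seq_len(min(nc$n_features, nrow(ex$counts))), cols,
                     drop = FALSE]
    tps <- ex$samples$zt_mod[match(cols, ex$samples$sample)]
    cfg <- network_config(n_permutations = nc$n_permutations,
                          p_threshold = nc$p_threshold,
                          r_threshold = nc$r_threshold,
                          seed = derive_seed(config$seed, 20L))
    filt <- filter_low_count_transcripts(sub, tps, cfg)
    av <- averaged_correlation_matrices(filt, tps, cfg)
    edges <- build_edge_table(av$r, av$p, cfg)
    summ <- network_summary(edges)
    save_art(edges, "network_edges.tsv")
    report$stages$network <- list(
      status = "done", group = g,
      n_features_in = nrow(sub), n_features_kept = nrow(filt),
      n_nodes = summ$n_nodes, n_edges = summ$n_edges)
  } else {
    report$stages$network <- list(status = "skipped")
  }

  if (!is.null(config$cal) && !is.null(sim$cal)) {
    tr <- annotate_trace(sim$cal, k = config$cal$k_sn %||% 3)
    agg <- period_aggregate(tr)
    bmr <- basal_metabolic_rate(tr$data$ee, tr$data$zt_h)
    save_art(agg, "calorimetry_periods.tsv")
    report$stages$cal <- list(
      status = "done", n_periods = nrow(agg),
      n_outliers_masked = sum(tr$outlier),
      bmr_kcal_h = bmr)
  } else {
    report$stages$cal <- list(status = "skipped")
  }

  report$checksums <- as.list(tools::md5sum(art))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
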