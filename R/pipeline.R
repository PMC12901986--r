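#' Default pipeline configuration
#'
#' Flat, stage-grouped key/value configuration covering every tunable default
#' of the simulator and the four analysis stages. Unknown keys are rejected so
#' typos fail loudly before any stage runs.
#'
#' @return a named list of stage parameter lists.
#' @export
default_run_config <- function() {
  list(
    simulate = list(
      n_transcripts = 60, n_spikeins = 12, seq_length_range = c(400, 2000),
      density = 1.5, n_molecules_scale = 1, timepoints = c(0, 200),
      depth = 1, full_length_prob = 0.97,
      n_genes_counts = 300, dispersion = 0.05, global_log2fc = -1,
      cq_n_molecules = 1000, cq_cut_fraction = 0.5, cq_noise_sd = 0.15,
      cq_replicates = 3),
    auc = list(enabled = TRUE, region = c(200, 1700), normalize = TRUE),
    integrity = list(enabled = TRUE),
    spikenorm = list(enabled = TRUE, pseudocount = 0.5, min_count = 5,
                     threshold = 2),
    dipcall = list(enabled = TRUE, smooth_window = 5, baseline_window = 50,
                   depth_ratio_threshold = 0.5, width_range = c(8, 30),
                   edge_exclusion = 25, min_mean_depth = 20,
                   upstream_search = 5, flank = 5),
    seed = 1L, log_level = "info")
}

#' Validate and merge a user configuration
#'
#' @param config named list overriding [default_run_config()] entries; unknown
#'   stage or key names are an error.
#' @return the merged configuration.
#' @export
parse_run_config <- function(config = list()) {
  base <- default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(base[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(base[[sec]]))
      if (length(bad)) {
        stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
      }
      base[[sec]] <- utils::modifyList(base[[sec]], config[[sec]])
    } else {
      base[[sec]] <- config[[sec]]
    }
  }
  base
}

#' Read a flat key/value configuration file
#'
#' Format: `stage.key value [value ...]`, one per line, `#` comments allowed.
#' Values are parsed as numbers where possible.
#'
#' @param path config file.
#' @return a configuration list for [parse_run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    key <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
    val <- parts[-1]
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (length(key) == 2) {
      cfg[[key[1]]][[key[2]]] <- val
    } else {
      cfg[[key[1]]] <- val
    }
  }
  cfg
}

#' Run the full simulate-and-analyze pipeline
#'
#' Generates a synthetic experiment (transcriptome, fragment pools per
#' timepoint, PAF alignments, spike-in count matrix, Cq tables,
#' electropherograms, ground-truth BED) and runs the configured analysis
#' stages, writing all artifacts plus a checksum manifest to `outdir`.
#' Identical configuration and seed reproduce identical checksums.
#'
#' @param config configuration (merged through [parse_run_config()]).
#' @param outdir output directory (created).
#' @param seed global seed; overrides `config$seed` when given.
#' @return data.frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config = list(), outdir, seed = NULL) {
  cfg <- parse_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    sim <- cfg$simulate
    tx <- build_transcriptome(n_transcripts = sim$n_transcripts,
                              n_spikeins = sim$n_spikeins,
                              seq_length_range = sim$seq_length_range,
                              seed = cfg$seed)
    model <- cleavage_model()
    sites <- plant_cleavage_sites(tx, model, density = sim$density, seed = cfg$seed)
    write_transcriptome_fasta(tx, file.path(outdir, "transcriptome.fasta"))
    truth <- do.call(rbind, lapply(names(sites), function(id) {
      s <- sites[[id]]
      if (nrow(s) == 0) return(NULL)
      data.frame(transcript_id = id, start = s$position, end = s$position + 1L,
                 position = s$position, stringsAsFactors = FALSE)
    }))
    write_sites_bed(if (is.null(truth)) data.frame(transcript_id = character(0),
                                                   start = integer(0), end = integer(0))
                    else truth,
                    file.path(outdir, "planted_sites.bed"))

    traces <- list()
    aln_by_tp <- list()
    for (tp in sim$timepoints) {
      pool <- simulate_fragment_pool(tx, sites, model, timepoint = tp,
                                     n_molecules_scale = sim$n_molecules_scale,
                                     seed = cfg$seed)
      aln <- simulate_read_alignments(pool, depth = sim$depth,
                                      full_length_prob = sim$full_length_prob,
                                      seed = substream_seed(cfg$seed, paste0("tp", tp)))
      write_paf(aln, file.path(outdir, sprintf("alignments_t%04d.paf", tp)))
      aln_by_tp[[as.character(tp)]] <- aln
      tr <- simulate_electropherogram(pool, sample_id = sprintf("t%04d", tp))
      traces[[sprintf("t%04d", tp)]] <- tr
      cq <- simulate_cq_table(
        samples = data.frame(
          sample = c(sprintf("empty_t%04d", tp), sprintf("targeting_t%04d", tp)),
          condition = c("empty", "targeting"),
          is_empty_control = c(TRUE, FALSE),
          n_molecules = sim$cq_n_molecules,
          cut_fraction_between = c(0, sim$cq_cut_fraction)),
        assay = list(target_id = "GAPDH", amplicon_5p = c(50, 150),
                     amplicon_3p = c(700, 800)),
        noise_sd = sim$cq_noise_sd, n_replicates = sim$cq_replicates,
        seed = substream_seed(cfg$seed, paste0("cq", tp)))
      write_cq_csv(cq, file.path(outdir, sprintf("cq_t%04d.csv", tp)),
                   file.path(outdir, sprintf("cq_samples_t%04d.csv", tp)))
    }

    stage <- "counts"
    design <- data.frame(
      sample = c(paste0("ctrl", 1:3), paste0("trt", 1:3)),
      condition = rep(c("non_targeting", "targeting"), each = 3))
    cm <- simulate_count_matrix(
      tx, depletion_spec = list(intercept = sim$global_log2fc),
      design = design, dispersion = sim$dispersion, seed = cfg$seed)
    write_counts_tsv(cm, file.path(outdir, "counts.tsv"))

    stage <- "auc"
    if (isTRUE(cfg$auc$enabled)) {
      tlist <- if (isTRUE(cfg$auc$normalize)) normalize_traces(traces) else traces
      auc_tab <- data.frame(
        sample = names(traces),
        total_auc = vapply(tlist, trace_total_auc, numeric(1)),
        region_auc = vapply(tlist, function(tr)
          region_auc(tr, cfg$auc$region)$area, numeric(1)))
      auc_tab$region_fraction <- auc_tab$region_auc / auc_tab$total_auc
      data.table::fwrite(auc_tab, file.path(outdir, "auc.tsv"), sep = "\t")
      for (nm in names(tlist)) {
        write_trace_tsv(tlist[[nm]], file.path(outdir, sprintf("trace_%s.tsv", nm)))
      }
    }

    stage <- "integrity"
    if (isTRUE(cfg$integrity$enabled)) {
      for (tp in sim$timepoints) {
        cq <- read_cq_csv(file.path(outdir, sprintf("cq_t%04d.csv", tp)),
                          file.path(outdir, sprintf("cq_samples_t%04d.csv", tp)))
        res_i <- integrity_analysis(cq)
        data.table::fwrite(res_i$per_condition,
                           file.path(outdir, sprintf("integrity_t%04d.tsv", tp)),
                           sep = "\t")
      }
    }

    stage <- "spikenorm"
    if (isTRUE(cfg$spikenorm$enabled)) {
      sf <- spikein_size_factors(cm)
      nm <- normalize_counts(cm, sf)
      fc <- fold_change_table(nm, targeting = design$sample[design$condition == "targeting"],
                              control = design$sample[design$condition != "targeting"],
                              spike_in = cm$spike_in, biotype = cm$biotype,
                              pseudocount = cfg$spikenorm$pseudocount,
                              min_count = cfg$spikenorm$min_count)
      fit <- abundance_depletion_fit(fc)
      sel <- select_outlier_transcripts(fit, threshold = cfg$spikenorm$threshold)
      data.table::fwrite(sel$table, file.path(outdir, "spikenorm_lfc.tsv"), sep = "\t")
    }

    stage <- "dipcall"
    if (isTRUE(cfg$dipcall$enabled)) {
      seqs <- setNames(tx$transcripts$sequence, tx$transcripts$id)
      tp_last <- as.character(max(sim$timepoints))
      calls <- call_cleavage_dips(
        aln_by_tp[[tp_last]], sequences = seqs,
        upstream_search = cfg$dipcall$upstream_search,
        smooth_window = cfg$dipcall$smooth_window,
        baseline_window = cfg$dipcall$baseline_window,
        depth_ratio_threshold = cfg$dipcall$depth_ratio_threshold,
        width_range = cfg$dipcall$width_range,
        edge_exclusion = cfg$dipcall$edge_exclusion,
        min_mean_depth = cfg$dipcall$min_mean_depth)
      write_sites_bed(calls, file.path(outdir, "dips.bed"))
      data.table::fwrite(calls, file.path(outdir, "dip_calls.tsv"), sep = "\t")
    }
    TRUE
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })

  cfg_lines <- utils::capture.output(utils::str(cfg, give.attr = FALSE))
  writeLines(cfg_lines, file.path(outdir, "run_config.txt"))
  files <- sort(setdiff(list.files(outdir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}
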