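# End-to-end orchestration: simulate -> match -> quantify -> localize ->
# kinase motifs -> promoter scan, from a single configuration, with a
# machine-readable JSON report.

#' Build a pipeline configuration
#'
#' All stage parameters with their defaults. Tolerances and thresholds
#' default to the workflow's standard values: 10 ppm mass tolerance, nMD
#' threshold 0.36 in fixed mode, target FLR 1%, two missed cleavages,
#' LOWESS span 0.4.
#'
#' @param outdir Output directory for all written tables and the report.
#' @param seed Master random seed; all stage seeds derive from it.
#' @param n_proteins,protein_length,n_sites,frac_regulated,effect_log2_sd
#'   Synthetic study size: proteome, planted phosphosites and regulation.
#' @param n_peptides Cap on simulated peptides.
#' @param noise Generator settings ([noise_config()]).
#' @param tol_ppm,rt_window Triplet matching tolerances.
#' @param span,iterations LOWESS normalization parameters.
#' @param fold_threshold,alpha,mt_correction Regulation flagging.
#' @param nmd_mode `"calibrated"` (calibrate the nMD threshold at
#'   `target_flr` on a labeled synthetic calibration set) or `"fixed"`
#'   (use `nmd_threshold` directly).
#' @param nmd_threshold Fixed-mode nMD threshold (default 0.36).
#' @param target_flr Calibration target FLR (default 0.01).
#' @param n_calibration_psms Size of the synthetic calibration PSM set.
#' @param flank_k Flanking-window half-width for motif scanning.
#' @param motif_library_path,pfm_path Kinase motif library and JASPAR PFM
#'   file (defaults: the packaged files).
#' @param n_genes,promoter_length,motif_plant_fraction Synthetic promoter
#'   panel for the PWM scan.
#' @param min_relative_score PWM hit threshold.
#' @param quiet Suppress stage banners.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("triplexquant_run_"),
                            seed = 1L,
                            n_proteins = 80L,
                            protein_length = c(150L, 400L),
                            n_sites = 200L,
                            frac_regulated = 0.25,
                            effect_log2_sd = 1,
                            n_peptides = 1500L,
                            noise = noise_config(),
                            tol_ppm = 10,
                            rt_window = 1,
                            span = 0.4,
                            iterations = 3L,
                            fold_threshold = 1.5,
                            alpha = 0.05,
                            mt_correction = "BH",
                            nmd_mode = c("calibrated", "fixed"),
                            nmd_threshold = 0.36,
                            target_flr = 0.01,
                            n_calibration_psms = 5000L,
                            flank_k = 6L,
                            motif_library_path = NULL,
                            pfm_path = NULL,
                            n_genes = 20L,
                            promoter_length = 500L,
                            motif_plant_fraction = 0.85,
                            min_relative_score = 0.8,
                            quiet = FALSE) {
  cfg <- as.list(environment())
  cfg$nmd_mode <- match.arg(nmd_mode)
  if (is.null(cfg$motif_library_path)) {
    cfg$motif_library_path <- system.file("extdata", "kinase_motifs.tsv",
                                          package = "triplexquant")
  }
  if (is.null(cfg$pfm_path)) {
    cfg$pfm_path <- system.file("extdata", "synthetic_tf_pfms.jaspar",
                                package = "triplexquant")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields not present in the file keep their [pipeline_config()] defaults;
#' the `noise` block is merged into [noise_config()] the same way.
#'
#' @param path YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  noise_args <- raw$noise
  raw$noise <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(noise_args)) {
    cfg$noise <- do.call(noise_config, noise_args)
  }
  cfg
}

.stage_msg <- function(quiet, ...) {
  if (!quiet) message("[triplexquant] ", ...)
}

# comparison label (timepoint ratio) for each experiment x ratio_name
.comparison_label <- function(experiment, ratio_name, design) {
  vapply(seq_along(experiment), function(i) {
    des <- design[design$experiment == experiment[i], ]
    tp <- stats::setNames(des$timepoint, des$channel)
    parts <- strsplit(ratio_name[i], "/", fixed = TRUE)[[1]]
    paste0(tp[[parts[1]]], "/", tp[[parts[2]]])
  }, character(1))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate, match, quantify, localize,
#' kinase motifs, promoter scan), writes every stage table plus a JSON run
#' report under `config$outdir`, and returns the report. A failing stage
#' aborts with the stage named. Output is reproducible for a fixed seed.
#'
#' @param config A `pipeline_config` object (or list coercible to one).
#' @return The run report (named list, class `triplex_report`), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config
  for (p in c(cfg$motif_library_path, cfg$pfm_path)) {
    if (!file.exists(p)) stop("configuration error: missing input file ", p)
  }
  if (cfg$nmd_threshold < 0 || cfg$nmd_threshold > 1 ||
      cfg$target_flr <= 0 || cfg$target_flr >= 1) {
    stop("configuration error: invalid localization thresholds")
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  run_stage <- function(name, fun) {
    .stage_msg(cfg$quiet, "stage: ", name)
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }
  wtsv <- function(x, name) {
    p <- file.path(cfg$outdir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  sim <- run_stage("simulate", function() {
    proteome <- generate_proteome(cfg$n_proteins, cfg$protein_length,
                                  seed = cfg$seed)
    sites <- plant_phosphosites(proteome, cfg$n_sites, seed = cfg$seed + 1L)
    profiles <- plant_regulation(proteome, cfg$frac_regulated,
                                 cfg$effect_log2_sd, seed = cfg$seed + 2L)
    s <- simulate_experiment(proteome, sites, profiles, noise = cfg$noise,
                             seed = cfg$seed + 3L, n_peptides = cfg$n_peptides)
    write_simulation(s, file.path(cfg$outdir, "sim"))
    s
  })

  matched <- run_stage("match", function() {
    per_exp <- lapply(split(sim$features, sim$features$experiment),
                      match_triplets, tol_ppm = cfg$tol_ppm,
                      rt_window = cfg$rt_window)
    triplets <- do.call(rbind, lapply(per_exp, `[[`, "triplets"))
    triplets$triplet_id <- sprintf("T%05d", seq_len(nrow(triplets)))
    rownames(triplets) <- NULL
    orphans <- do.call(rbind, lapply(per_exp, `[[`, "orphans"))
    rownames(orphans) <- NULL
    wtsv(triplets, "triplets.tsv")
    wtsv(orphans, "orphans.tsv")
    list(triplets = triplets, orphans = orphans)
  })

  quant <- run_stage("quantify", function() {
    ratios <- compute_ratios(matched$triplets, sim$features)
    ratios$comparison <- .comparison_label(ratios$experiment,
                                           ratios$ratio_name, sim$design)
    ratios <- lowess_normalize(ratios, span = cfg$span,
                               iterations = cfg$iterations,
                               by = c("experiment", "ratio_name"))
    pq <- rollup_proteins(ratios)
    pq <- flag_regulated(pq, cfg$fold_threshold, cfg$alpha, cfg$mt_correction)
    pq$comparison <- .comparison_label(pq$experiment, pq$ratio_name,
                                       sim$design)
    wtsv(ratios, "normalized_ratios.tsv")
    wtsv(pq, "protein_quant.tsv")
    list(ratios = ratios, protein_quant = pq)
  })

  loc <- run_stage("localize", function() {
    if (cfg$nmd_mode == "fixed") {
      threshold <- cfg$nmd_threshold
      calib <- NULL
    } else {
      cal_psms <- simulate_psm_scores(
        cfg$n_calibration_psms,
        frac_incorrect = cfg$noise$frac_incorrect,
        top_shape = cfg$noise$top_shape, top_rate = cfg$noise$top_rate,
        gap_mean_correct = cfg$noise$gap_mean_correct,
        gap_mean_incorrect = cfg$noise$gap_mean_incorrect,
        seed = cfg$seed + 101L)
      sc <- nmd_score(cal_psms$top_score, cal_psms$runner_up_score)
      calib <- calibrate_flr_threshold(sc$nmd, cal_psms$is_correct,
                                       cfg$target_flr)
      threshold <- calib$threshold
    }
    localized <- filter_localized(sim$psms, threshold)
    inv <- site_inventory(localized)
    wtsv(localized, "localized_sites.tsv")
    jsonlite::write_json(inv, file.path(cfg$outdir, "site_inventory.json"),
                         auto_unbox = TRUE, digits = NA)
    list(localized = localized, inventory = inv, threshold = threshold,
         calibration = calib)
  })

  motifs <- run_stage("motifs", function() {
    library <- read_kinase_motifs(cfg$motif_library_path)
    acc <- loc$localized[loc$localized$accepted, ]
    uni <- acc[!duplicated(paste(acc$protein_id, acc$position)), ]
    seqs <- stats::setNames(sim$proteome$sequence, sim$proteome$id)
    windows <- vapply(seq_len(nrow(uni)), function(i) {
      extract_flank(seqs[[uni$protein_id[i]]], uni$position[i], cfg$flank_k)
    }, character(1))
    hits <- scan_kinase_motifs(windows, library)
    summ <- kinase_summary(hits, length(windows), library)
    if (nrow(hits)) {
      hits$protein_id <- uni$protein_id[hits$window_index]
      hits$position <- uni$position[hits$window_index]
    }
    wtsv(hits, "kinase_hits.tsv")
    wtsv(summ, "kinase_summary.tsv")
    list(hits = hits, summary = summ, n_windows = length(windows))
  })

  tf <- run_stage("pwm_scan", function() {
    pfms <- read_pfm(cfg$pfm_path)
    pwms <- lapply(pfms, pfm_to_pwm)
    promoters <- generate_promoters(cfg$n_genes, cfg$promoter_length,
                                    seed = cfg$seed + 202L)
    for (k in seq_along(pwms)) {
      consensus <- paste(.DNA_BASES[apply(pfms[[k]]$counts, 2L, which.max)],
                         collapse = "")
      promoters <- plant_motif(promoters, consensus,
                               fraction = cfg$motif_plant_fraction,
                               seed = cfg$seed + 202L + k)$promoters
    }
    write_fasta(data.frame(id = promoters$gene_id,
                           sequence = promoters$sequence),
                file.path(cfg$outdir, "promoters.fasta"), type = "DNA")
    res <- gene_hit_fraction(promoters, pwms, cfg$min_relative_score)
    wtsv(res$fractions, "tf_hit_fractions.tsv")
    wtsv(res$per_gene, "tf_hits_per_gene.tsv")
    res
  })

  report <- structure(list(
    package = "triplexquant",
    version = as.character(utils::packageVersion("triplexquant")),
    seed = cfg$seed,
    stages_completed = stages,
    parameters = list(
      n_proteins = cfg$n_proteins, n_sites = cfg$n_sites,
      n_peptides = cfg$n_peptides, frac_regulated = cfg$frac_regulated,
      tol_ppm = cfg$tol_ppm, rt_window = cfg$rt_window,
      span = cfg$span, iterations = cfg$iterations,
      fold_threshold = cfg$fold_threshold, alpha = cfg$alpha,
      mt_correction = cfg$mt_correction,
      nmd_mode = cfg$nmd_mode, target_flr = cfg$target_flr,
      effective_nmd_threshold = loc$threshold,
      calibration_attainable = if (is.null(loc$calibration)) NA
                               else loc$calibration$attainable,
      flank_k = cfg$flank_k,
      min_relative_score = cfg$min_relative_score,
      motif_plant_fraction = cfg$motif_plant_fraction
    ),
    counts = list(
      n_features = nrow(sim$features),
      n_psms = nrow(sim$psms),
      n_triplets = nrow(matched$triplets),
      n_orphans = nrow(matched$orphans),
      n_ratio_records = nrow(quant$ratios),
      n_protein_quant = nrow(quant$protein_quant),
      n_up = sum(quant$protein_quant$regulated_flag == "up"),
      n_down = sum(quant$protein_quant$regulated_flag == "down"),
      n_localized_psms = nrow(loc$localized),
      n_accepted_psms = sum(loc$localized$accepted),
      n_motif_windows = motifs$n_windows
    ),
    site_inventory = loc$inventory,
    kinase_summary = motifs$summary,
    tf_hit_fractions = tf$fractions
  ), class = "triplex_report")
  jsonlite::write_json(unclass(report), file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  .stage_msg(cfg$quiet, "done: ", cfg$outdir)
  invisible(report)
}

#' @export
print.triplex_report <- function(x, ...) {
  cat("triplexquant run report\n")
  cat("  stages:", paste(x$stages_completed, collapse = " -> "), "\n")
  cat("  features:", x$counts$n_features,
      " triplets:", x$counts$n_triplets,
      " orphans:", x$counts$n_orphans, "\n")
  cat("  proteins quantified:", x$counts$n_protein_quant,
      " (up:", x$counts$n_up, " down:", x$counts$n_down, ")\n")
  cat("  accepted phospho-PSMs:", x$counts$n_accepted_psms,
      " unique sites:", x$site_inventory$n_unique_sites,
      " on", x$site_inventory$n_proteins, "proteins\n")
  cat("  effective nMD threshold:",
      format(x$parameters$effective_nmd_threshold, digits = 3),
      "(", x$parameters$nmd_mode, ")\n")
  invisible(x)
}
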