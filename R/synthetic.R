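# Synthetic-data generator: ground-truth proteomes, phosphosites, regulation
# profiles, per-channel XIC features and PSM scores emulating a two-triplex,
# five-timepoint induction design. Truth tables are kept separate from the
# observable tables; no downstream stage reads truth.

#' Two-triplex, five-timepoint experiment design
#'
#' Experiment 1 maps light/intermediate/heavy to 0 h / 10 min / 30 min of
#' induction; experiment 2 maps them to 30 min / 1 h / 2 h. The 30 min
#' timepoint appears in both triplexes and bridges the "early" and "late"
#' period groups.
#'
#' @return Data frame with columns `experiment`, `channel`, `timepoint`.
#' @export
experiment_design <- function() {
  data.frame(
    experiment = rep(1:2, each = 3L),
    channel = rep(c("light", "intermediate", "heavy"), 2L),
    timepoint = c("0h", "10min", "30min", "30min", "1h", "2h")
  )
}

.TIMEPOINTS <- c("0h", "10min", "30min", "1h", "2h")
.RATIO_STEPS <- c("10min/0h", "30min/10min", "1h/30min", "2h/1h")

#' Default noise and score-model configuration for the generator
#'
#' @param xic_log2_sd Log2-scale standard deviation of multiplicative XIC
#'   area noise per channel feature.
#' @param bias_amplitude Amplitude (log2 units) of the smooth
#'   intensity-dependent bias curve; a centered sigmoid of the peptide's
#'   mean log2 intensity, injected so that LOWESS normalization has a real
#'   trend to remove.
#' @param bias_center Center of the sigmoid on the log2-intensity axis
#'   (`NULL` = the baseline intensity mean).
#' @param bias_scale Width of the sigmoid (log2 units).
#' @param channel_bias Named multipliers applying the bias curve per channel
#'   (the light channel is the unbiased reference).
#' @param ppm_sd,ppm_max Mass-error model: truncated Gaussian with standard
#'   deviation `ppm_sd`, hard-bounded at `ppm_max` ppm.
#' @param missing_rate Probability that any single channel feature is absent
#'   (exercises triplet-matcher orphan paths).
#' @param miscleavage_rate Fraction of missed-cleavage peptides retained in
#'   addition to the fully cleaved ones.
#' @param frac_incorrect Fraction of PSMs whose phosphosite is assigned to a
#'   wrong residue.
#' @param top_shape,top_rate Gamma parameters of the top PSM score.
#' @param gap_mean_correct,gap_mean_incorrect Mean of the exponential
#'   top-minus-runner-up score gap for correctly and incorrectly localized
#'   PSMs; correct localizations have systematically larger gaps.
#' @param psms_per_site Maximum PSM count drawn per planted phosphosite.
#' @param baseline_mean,baseline_sd Log2 baseline intensity distribution.
#' @param rt_jitter Per-channel retention-time jitter (minutes).
#' @param pep_len_range Peptide length window retained for simulation.
#' @return Named list of generator settings.
#' @export
noise_config <- function(xic_log2_sd = 0.15,
                         bias_amplitude = 0.5,
                         bias_center = NULL,
                         bias_scale = 1.5,
                         channel_bias = c(light = 0, intermediate = 1, heavy = -0.7),
                         ppm_sd = 1,
                         ppm_max = 3,
                         missing_rate = 0.05,
                         miscleavage_rate = 0.05,
                         frac_incorrect = 0.1,
                         top_shape = 5,
                         top_rate = 1 / 6,
                         gap_mean_correct = 10,
                         gap_mean_incorrect = 3,
                         psms_per_site = 3L,
                         baseline_mean = 20,
                         baseline_sd = 2,
                         rt_jitter = 0.02,
                         pep_len_range = c(6L, 30L)) {
  as.list(environment())
}

.rtrunc_norm <- function(n, sd, bound) {
  if (sd <= 0 || n == 0L) return(rep(0, n))
  lo <- stats::pnorm(-bound, sd = sd)
  hi <- stats::pnorm(bound, sd = sd)
  stats::qnorm(stats::runif(n, lo, hi), sd = sd)
}

.bias_curve <- function(x, cfg, center) {
  cfg$bias_amplitude * (stats::plogis((x - center) / cfg$bias_scale) - 0.5)
}

#' Generate a random synthetic proteome
#'
#' Residues are drawn i.i.d.; the combined lysine + arginine frequency is a
#' parameter because it sets the tryptic peptide length scale (mean fully
#' cleaved peptide length is about `1 / kr_fraction`).
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer pair of min/max protein length.
#' @param seed Random seed (generation is fully reproducible).
#' @param kr_fraction Combined K+R frequency (split equally).
#' @param aa_freqs Optional named probability vector over the 20 residues,
#'   overriding the default composition.
#' @return Data frame with columns `id` and `sequence`.
#' @examples
#' generate_proteome(3, c(50, 80), seed = 7)
#' @export
generate_proteome <- function(n_proteins, length_range = c(100L, 500L),
                              seed = 1L, kr_fraction = 0.1, aa_freqs = NULL) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    stop("invalid length_range: expected increasing positive integer pair")
  }
  aa <- names(.AA_MONO)
  if (is.null(aa_freqs)) {
    aa_freqs <- stats::setNames(rep((1 - kr_fraction) / 18, 20L), aa)
    aa_freqs[c("K", "R")] <- kr_fraction / 2
  } else {
    if (!all(names(aa_freqs) %in% aa)) stop("aa_freqs has unknown residues")
    aa_freqs <- aa_freqs / sum(aa_freqs)
  }
  set.seed(seed)
  lens <- length_range[1] - 1L +
    sample.int(length_range[2] - length_range[1] + 1L, n_proteins,
               replace = TRUE)
  data.frame(
    id = sprintf("SYNP%04d", seq_len(n_proteins)),
    sequence = vapply(lens, function(L) {
      paste(sample(names(aa_freqs), L, replace = TRUE, prob = aa_freqs),
            collapse = "")
    }, character(1))
  )
}

#' Plant ground-truth phosphosites on a proteome
#'
#' Residue classes are drawn multinomially from `residue_probs` (default:
#' the canonical mammalian pS/pT/pY distribution 87.5% / 11.5% / 0.8%,
#' renormalized to sum to one) and positions are sampled without replacement
#' within each class.
#'
#' @param proteome Data frame from [generate_proteome()] or [read_fasta()].
#' @param n_sites Number of sites to plant.
#' @param residue_probs Named nonnegative weights for S, T, Y.
#' @param seed Random seed.
#' @return Data frame with columns `protein_id`, `position` (0-based
#'   protein offset) and `residue`.
#' @export
plant_phosphosites <- function(proteome, n_sites,
                               residue_probs = c(S = 0.875, T = 0.115, Y = 0.008),
                               seed = 1L) {
  if (any(residue_probs < 0) || sum(residue_probs) <= 0) {
    stop("residue_probs must be nonnegative with positive sum")
  }
  probs <- residue_probs[c("S", "T", "Y")]
  probs[is.na(probs)] <- 0
  probs <- probs / sum(probs)
  if (n_sites == 0L) {
    return(data.frame(protein_id = character(), position = integer(),
                      residue = character()))
  }
  pool <- lapply(c(S = "S", T = "T", Y = "Y"), function(res) {
    hits <- lapply(seq_len(nrow(proteome)), function(i) {
      pos <- which(strsplit(proteome$sequence[i], "", fixed = TRUE)[[1]] == res)
      if (!length(pos)) return(NULL)
      data.frame(protein_id = proteome$id[i], position = pos - 1L, residue = res)
    })
    do.call(rbind, hits)
  })
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1L, n_sites, probs))
  names(counts) <- c("S", "T", "Y")
  out <- lapply(c("S", "T", "Y"), function(res) {
    k <- counts[[res]]
    if (k == 0L) return(NULL)
    avail <- pool[[res]]
    if (is.null(avail) || nrow(avail) < k) {
      stop("insufficient ", res, " residues in proteome to plant ", k, " sites")
    }
    avail[sample.int(nrow(avail), k), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plant per-protein regulation profiles
#'
#' A fraction of proteins is regulated; each regulated protein receives an
#' independent log2 fold change for each consecutive timepoint ratio
#' (10min/0h, 30min/10min, 1h/30min, 2h/1h). Unregulated proteins carry
#' all-zero profiles.
#'
#' @param proteome Proteome data frame.
#' @param frac_regulated Fraction of proteins regulated.
#' @param effect_log2_sd Standard deviation of the regulated log2 folds
#'   (drawn from a centered Gaussian).
#' @param seed Random seed.
#' @return Data frame with columns `protein_id`, `regulated` and one
#'   `lf_<ratio>` column per consecutive ratio.
#' @export
plant_regulation <- function(proteome, frac_regulated = 0.25,
                             effect_log2_sd = 1, seed = 1L) {
  set.seed(seed)
  n <- nrow(proteome)
  reg <- stats::runif(n) < frac_regulated
  folds <- matrix(0, nrow = n, ncol = length(.RATIO_STEPS))
  folds[reg, ] <- stats::rnorm(sum(reg) * length(.RATIO_STEPS),
                               sd = effect_log2_sd)
  colnames(folds) <- paste0("lf_", gsub("/", "_", .RATIO_STEPS))
  cbind(data.frame(protein_id = proteome$id, regulated = reg), folds)
}

# cumulative log2 abundance offset per protein x timepoint
.cum_log2 <- function(profiles) {
  folds <- as.matrix(profiles[, paste0("lf_", gsub("/", "_", .RATIO_STEPS))])
  cum <- cbind(0, t(apply(folds, 1L, cumsum)))
  colnames(cum) <- .TIMEPOINTS
  rownames(cum) <- profiles$protein_id
  cum
}

#' Simulate PSM top and runner-up scores with known localization truth
#'
#' Two-component score-gap model: the top score is Gamma-distributed; the
#' gap to the runner-up is exponential with a larger mean for correctly
#' localized PSMs than for incorrect ones (gaps are capped at the top score
#' so runner-up scores stay nonnegative).
#'
#' @param n Number of PSMs.
#' @param frac_incorrect Fraction of incorrect localizations.
#' @param top_shape,top_rate Gamma parameters of the top score.
#' @param gap_mean_correct,gap_mean_incorrect Exponential gap means.
#' @param seed Random seed.
#' @return Data frame with columns `psm_id`, `top_score`,
#'   `runner_up_score`, `is_correct`.
#' @export
simulate_psm_scores <- function(n, frac_incorrect = 0.1,
                                top_shape = 5, top_rate = 1 / 6,
                                gap_mean_correct = 10,
                                gap_mean_incorrect = 3,
                                seed = 1L) {
  set.seed(seed)
  correct <- stats::runif(n) >= frac_incorrect
  top <- stats::rgamma(n, shape = top_shape, rate = top_rate)
  gap <- stats::rexp(n, rate = 1 / ifelse(correct, gap_mean_correct,
                                          gap_mean_incorrect))
  gap <- pmin(gap, top)
  data.frame(
    psm_id = sprintf("PSM%06d", seq_len(n)),
    top_score = top,
    runner_up_score = top - gap,
    is_correct = correct
  )
}

#' Simulate a full two-triplex labeling experiment
#'
#' Digests the proteome, selects quantifiable peptides, and emits
#' per-channel XIC features (areas carrying planted regulation, a smooth
#' intensity-dependent bias and log-normal noise; observed masses carrying
#' bounded ppm error over the exact labeled monoisotopic mass) plus a PSM
#' table for peptides covering planted phosphosites. Ground truth (site
#' table, regulation profiles, PSM correctness) is returned in a separate
#' `truth` element that no pipeline stage reads.
#'
#' @param proteome Proteome data frame.
#' @param sites Truth sites from [plant_phosphosites()].
#' @param profiles Regulation profiles from [plant_regulation()].
#' @param noise Generator settings from [noise_config()].
#' @param design Triplex design from [experiment_design()].
#' @param seed Random seed.
#' @param n_peptides Optional cap on the number of simulated peptides.
#' @return Object of class `triplex_sim`: a list with elements `features`,
#'   `psms`, `peptides`, `truth`, `proteome`, `design`, `config`, `seed`.
#' @export
simulate_experiment <- function(proteome, sites, profiles,
                                noise = noise_config(),
                                design = experiment_design(),
                                seed = 1L, n_peptides = NULL) {
  stopifnot(is.data.frame(proteome), is.data.frame(sites), is.data.frame(profiles))
  if (!all(sites$protein_id %in% proteome$id) ||
      !all(profiles$protein_id %in% proteome$id)) {
    stop("configuration error: truth tables reference proteins absent from the proteome")
  }
  if (!setequal(proteome$id, profiles$protein_id)) {
    stop("configuration error: every protein needs a regulation profile")
  }
  set.seed(seed)

  peps <- digest_proteome(proteome, max_missed = 2L)
  len <- nchar(peps$sequence)
  peps <- peps[len >= noise$pep_len_range[1] & len <= noise$pep_len_range[2], ]
  keep_mis <- peps$missed_cleavages == 0L |
    stats::runif(nrow(peps)) < noise$miscleavage_rate
  peps <- peps[keep_mis, ]
  # one protein per peptide sequence: drop shared/duplicated sequences
  peps <- peps[!duplicated(peps$sequence) &
                 !peps$sequence %in% peps$sequence[duplicated(peps$sequence)], ]
  if (!is.null(n_peptides) && n_peptides < nrow(peps)) {
    peps <- peps[sample.int(nrow(peps), n_peptides), ]
  }
  rownames(peps) <- NULL

  # phospho load: planted sites covered by each peptide
  pend <- peps$start + nchar(peps$sequence)
  site_key <- paste(sites$protein_id, sites$position)
  n_phospho <- integer(nrow(peps))
  covered <- vector("list", nrow(peps))
  if (nrow(sites)) {
    for (i in seq_len(nrow(peps))) {
      hit <- which(sites$protein_id == peps$protein_id[i] &
                     sites$position >= peps$start[i] &
                     sites$position < pend[i])
      n_phospho[i] <- length(hit)
      covered[[i]] <- hit
    }
  }
  peps$n_phospho <- n_phospho
  peps$n_label_sites <- count_label_sites(peps$sequence)

  cum <- .cum_log2(profiles)
  center <- if (is.null(noise$bias_center)) noise$baseline_mean else noise$bias_center
  channels <- label_channels()

  npep <- nrow(peps)
  feats <- vector("list", 2L)
  for (e in 1:2) {
    des <- design[design$experiment == e, ]
    baseline <- stats::rnorm(npep, noise$baseline_mean, noise$baseline_sd)
    rt0 <- stats::runif(npep, 10, 110)
    charge <- sample(2:3, npep, replace = TRUE)
    per_ch <- lapply(seq_len(nrow(des)), function(k) {
      ch <- des$channel[k]
      tp <- des$timepoint[k]
      true_l2 <- baseline + cum[peps$protein_id, tp]
      bias <- noise$channel_bias[[ch]] * .bias_curve(baseline, noise, center)
      obs_l2 <- true_l2 + bias + stats::rnorm(npep, sd = noise$xic_log2_sd)
      theo <- vapply(seq_len(npep), function(i) {
        peptide_mono_mass(peps$sequence[i], ch, peps$n_phospho[i])
      }, numeric(1))
      ppm <- .rtrunc_norm(npep, noise$ppm_sd, noise$ppm_max)
      data.frame(
        experiment = e,
        peptide = peps$sequence,
        protein_id = peps$protein_id,
        channel = ch,
        observed_mass = theo * (1 + ppm * 1e-6),
        mass_error_ppm = ppm,
        charge = charge,
        xic_area = 2^obs_l2,
        rt = rt0 + stats::rnorm(npep, sd = noise$rt_jitter)
      )
    })
    feats[[e]] <- do.call(rbind, per_ch)
  }
  features <- do.call(rbind, feats)
  if (noise$missing_rate > 0) {
    features <- features[stats::runif(nrow(features)) >= noise$missing_rate, ]
  }
  features$feature_id <- sprintf("F%06d", seq_len(nrow(features)))
  features <- features[, c("feature_id", "experiment", "peptide", "protein_id",
                           "channel", "observed_mass", "mass_error_ppm",
                           "charge", "xic_area", "rt")]
  rownames(features) <- NULL

  # PSM table for peptides covering planted sites
  psm_rows <- list()
  truth_rows <- list()
  phospho_idx <- which(peps$n_phospho > 0L)
  for (i in phospho_idx) {
    chars <- strsplit(peps$sequence[i], "", fixed = TRUE)[[1]]
    sty <- which(chars %in% c("S", "T", "Y"))
    for (s in covered[[i]]) {
      true_off <- sites$position[s] - peps$start[i] + 1L  # 1-based in peptide
      k <- sample.int(noise$psms_per_site, 1L)
      for (j in seq_len(k)) {
        correct <- stats::runif(1) >= noise$frac_incorrect
        alt <- setdiff(sty, true_off)
        if (!correct && !length(alt)) correct <- TRUE
        off <- if (correct) true_off else alt[sample.int(length(alt), 1L)]
        top <- stats::rgamma(1L, shape = noise$top_shape, rate = noise$top_rate)
        gap <- stats::rexp(1L, rate = 1 / if (correct) noise$gap_mean_correct
                           else noise$gap_mean_incorrect)
        gap <- min(gap, top)
        psm_rows[[length(psm_rows) + 1L]] <- data.frame(
          peptide = peps$sequence[i],
          protein_id = peps$protein_id[i],
          peptide_start = peps$start[i],
          assigned_site_1based = off,
          top_score = top,
          runner_up_score = top - gap,
          decoy = FALSE
        )
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          is_correct_localization = correct,
          true_position_1based = sites$position[s] + 1L
        )
      }
    }
  }
  if (length(psm_rows)) {
    psms <- do.call(rbind, psm_rows)
    psm_truth <- do.call(rbind, truth_rows)
    psms <- cbind(psm_id = sprintf("PSM%06d", seq_len(nrow(psms))), psms)
    psm_truth <- cbind(psm_id = psms$psm_id, psm_truth)
  } else {
    psms <- data.frame(psm_id = character(), peptide = character(),
                       protein_id = character(), peptide_start = integer(),
                       assigned_site_1based = integer(), top_score = numeric(),
                       runner_up_score = numeric(), decoy = logical())
    psm_truth <- data.frame(psm_id = character(),
                            is_correct_localization = logical(),
                            true_position_1based = integer())
  }
  rownames(psms) <- rownames(psm_truth) <- NULL

  structure(list(
    features = features,
    psms = psms,
    peptides = peps,
    truth = list(sites = sites, regulation = profiles, psms = psm_truth),
    proteome = proteome,
    design = design,
    config = noise,
    seed = seed
  ), class = "triplex_sim")
}

#' Generate random promoter sequences
#'
#' @param n_genes Number of promoters.
#' @param length Promoter length in nt (default 1000, i.e. 1 kb upstream).
#' @param seed Random seed.
#' @param base_probs Named probabilities over A, C, G, T.
#' @return Data frame with columns `gene_id` and `sequence`.
#' @export
generate_promoters <- function(n_genes, length = 1000L, seed = 1L,
                               base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  data.frame(
    gene_id = sprintf("GENE%03d", seq_len(n_genes)),
    sequence = vapply(seq_len(n_genes), function(i) {
      paste(sample(names(base_probs), length, replace = TRUE,
                   prob = base_probs), collapse = "")
    }, character(1))
  )
}

#' Plant a motif occurrence into a fraction of promoters
#'
#' @param promoters Data frame from [generate_promoters()].
#' @param motif DNA string to insert (replaces the same-length window).
#' @param fraction Fraction of genes that receive the motif.
#' @param seed Random seed.
#' @return List with elements `promoters` (modified table) and `planted`
#'   (gene_id, 0-based start of each insertion).
#' @export
plant_motif <- function(promoters, motif, fraction = 1, seed = 1L) {
  set.seed(seed)
  n <- nrow(promoters)
  k <- round(fraction * n)
  idx <- if (k > 0) sort(sample.int(n, k)) else integer()
  planted <- data.frame(gene_id = character(), start = integer())
  L <- nchar(motif)
  for (i in idx) {
    s <- nchar(promoters$sequence[i])
    if (s < L) stop("promoter shorter than motif")
    at <- sample.int(s - L + 1L, 1L)
    substr(promoters$sequence[i], at, at + L - 1L) <- motif
    planted <- rbind(planted,
                     data.frame(gene_id = promoters$gene_id[i], start = at - 1L))
  }
  list(promoters = promoters, planted = planted)
}

#' Write a simulated experiment to disk
#'
#' Writes the proteome FASTA, the observable feature and PSM TSV tables,
#' the disjoint truth TSV tables and a JSON metadata file recording the
#' seed and generator configuration.
#'
#' @param sim A `triplex_sim` object from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "triplex_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    proteome = file.path(dir, "proteome.fasta"),
    features = file.path(dir, "features.tsv"),
    psms = file.path(dir, "psms.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_regulation = file.path(dir, "truth_regulation.tsv"),
    truth_psms = file.path(dir, "truth_psms.tsv"),
    metadata = file.path(dir, "metadata.json")
  )
  write_fasta(sim$proteome, paths[["proteome"]])
  wtsv <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  wtsv(sim$features, paths[["features"]])
  wtsv(sim$psms, paths[["psms"]])
  wtsv(sim$truth$sites, paths[["truth_sites"]])
  wtsv(sim$truth$regulation, paths[["truth_regulation"]])
  wtsv(sim$truth$psms, paths[["truth_psms"]])
  jsonlite::write_json(
    list(seed = sim$seed, design = sim$design,
         config = sim$config[order(names(sim$config))]),
    paths[["metadata"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a feature or PSM TSV table written by [write_simulation()]
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
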