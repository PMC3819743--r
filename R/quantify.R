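# Channel ratio computation (MA representation), LOWESS normalization of
# the intensity-dependent ratio trend, and protein-level roll-up with
# one-sample significance testing.

.RATIO_NAMES <- c("intermediate/light", "heavy/intermediate")

#' Compute log2 channel ratios for matched triplets
#'
#' Emits both triplex ratios per triplet in MA form: `M` is the log2 ratio
#' of XIC areas, `A` the mean log2 abundance of the two channels.
#'
#' @param triplets Triplet table from [match_triplets()].
#' @param features Feature table supplying `xic_area` per `feature_id`.
#' @return Data frame with one row per triplet and ratio, columns
#'   `triplet_id`, `ratio_name`, `M`, `A` plus carried `peptide`,
#'   `protein_id`, `experiment` when present.
#' @export
compute_ratios <- function(triplets, features) {
  stopifnot(is.data.frame(triplets), is.data.frame(features))
  area <- stats::setNames(features$xic_area, features$feature_id)
  get_area <- function(ids) {
    a <- area[ids]
    if (anyNA(a)) stop("feature id(s) missing from feature table: ",
                       paste(ids[is.na(a)], collapse = ", "))
    bad <- a <= 0
    if (any(bad)) stop("nonpositive XIC area for feature(s): ",
                       paste(ids[bad], collapse = ", "))
    a
  }
  aL <- get_area(triplets$light_id)
  aI <- get_area(triplets$intermediate_id)
  aH <- get_area(triplets$heavy_id)
  one <- function(name, num, den) {
    out <- data.frame(
      triplet_id = triplets$triplet_id,
      ratio_name = name,
      M = log2(num / den),
      A = (log2(num) + log2(den)) / 2
    )
    for (col in c("peptide", "protein_id", "experiment")) {
      if (col %in% names(triplets)) out[[col]] <- triplets[[col]]
    }
    out
  }
  res <- rbind(one("intermediate/light", aI, aL),
               one("heavy/intermediate", aH, aI))
  rownames(res) <- NULL
  res
}

#' LOWESS-normalize log2 ratios against mean log2 abundance
#'
#' Fits a robust locally weighted regression of `M` on `A` within each
#' ratio group and subtracts the fitted trend, so that the expected ratio
#' of unregulated peptides is flat at zero across the intensity range (the
#' MA-plot equivalent of rescaling a ratio-versus-ratio scatter to unit
#' slope). Normalization is shift-only per record: the ranking of `M`
#' within any narrow `A` window is preserved.
#'
#' @param ratios Ratio table from [compute_ratios()].
#' @param span LOWESS smoother span (fraction of points; default 0.4).
#' @param iterations Robustness iterations downweighting outliers
#'   (default 3).
#' @param by Column names defining independent normalization groups
#'   (default `"ratio_name"`; the pipeline adds `"experiment"`).
#' @return `ratios` with an added `M_normalized` column.
#' @export
lowess_normalize <- function(ratios, span = 0.4, iterations = 3L,
                             by = "ratio_name") {
  stopifnot(is.data.frame(ratios), all(c("M", "A") %in% names(ratios)))
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  grp <- interaction(ratios[by], drop = TRUE)
  ratios$M_normalized <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 10L) {
      stop("too few records (", length(idx), ") in group '", g,
           "' for LOWESS normalization; need at least 10")
    }
    fit <- stats::lowess(ratios$A[idx], ratios$M[idx], f = span,
                         iter = iterations)
    fitted <- stats::approx(fit$x, fit$y, xout = ratios$A[idx],
                            rule = 2, ties = mean)$y
    ratios$M_normalized[idx] <- ratios$M[idx] - fitted
  }
  ratios
}

#' Roll peptide ratios up to protein-level estimates
#'
#' The protein log2 ratio is the arithmetic mean of its member peptide
#' normalized log2 ratios; dispersion is their standard deviation and
#' significance a two-sided one-sample t-test of the mean against zero
#' (proteins with a single peptide, or zero dispersion, get `p_value = NA`).
#'
#' @param ratios Normalized ratio table (needs `M_normalized`).
#' @param mapping Optional data frame `peptide` -> `protein_id`; not needed
#'   when `ratios` already carries `protein_id`. Every peptide must map to
#'   exactly one protein.
#' @param by Grouping columns in addition to `protein_id` (default
#'   `ratio_name`, plus `experiment` when present).
#' @return Data frame with columns `protein_id`, grouping columns,
#'   `n_peptides`, `mean_log2_ratio`, `sd_log2_ratio`, `p_value`.
#' @export
rollup_proteins <- function(ratios, mapping = NULL, by = NULL) {
  stopifnot(is.data.frame(ratios), "M_normalized" %in% names(ratios))
  if (is.null(by)) {
    by <- intersect(c("experiment", "ratio_name"), names(ratios))
  }
  if (!"protein_id" %in% names(ratios)) {
    if (is.null(mapping)) stop("no protein mapping available")
    if (anyDuplicated(mapping$peptide)) {
      dup <- unique(mapping$peptide[duplicated(mapping$peptide)])
      stop("peptide(s) mapped to more than one protein: ",
           paste(utils::head(dup, 5L), collapse = ", "))
    }
    m <- match(ratios$peptide, mapping$peptide)
    if (anyNA(m)) {
      stop("unmapped peptide(s): ",
           paste(utils::head(unique(ratios$peptide[is.na(m)]), 5L),
                 collapse = ", "))
    }
    ratios$protein_id <- mapping$protein_id[m]
  }
  key <- interaction(ratios[c("protein_id", by)], drop = TRUE)
  groups <- split(ratios, key)
  rows <- lapply(groups, function(g) {
    x <- g$M_normalized
    p <- NA_real_
    if (length(x) >= 2L && stats::sd(x) > 0) {
      p <- stats::t.test(x, mu = 0)$p.value
    }
    out <- g[1L, c("protein_id", by), drop = FALSE]
    out$n_peptides <- length(x)
    out$mean_log2_ratio <- mean(x)
    out$sd_log2_ratio <- if (length(x) >= 2L) stats::sd(x) else NA_real_
    out$p_value <- p
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$protein_id), , drop = FALSE]
}

#' Flag regulated proteins
#'
#' A protein is flagged `up` when its mean log2 ratio is at least
#' `log2(fold_threshold)` and its multiplicity-adjusted p-value is at most
#' `alpha`; `down` symmetrically. Adjustment is applied within each ratio
#' group.
#'
#' @param protein_quant Table from [rollup_proteins()].
#' @param fold_threshold Minimum fold change (default 1.5).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param mt_correction Multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`, Benjamini-Hochberg).
#' @param by Grouping columns for the adjustment (default `ratio_name`
#'   plus `experiment` when present).
#' @return `protein_quant` with added `p_adjusted` and `regulated_flag`
#'   (`"up"`, `"down"`, `"none"`).
#' @export
flag_regulated <- function(protein_quant, fold_threshold = 1.5, alpha = 0.05,
                           mt_correction = "BH", by = NULL) {
  stopifnot(is.data.frame(protein_quant))
  if (fold_threshold <= 0 || alpha <= 0) stop("thresholds must be positive")
  if (is.null(by)) {
    by <- intersect(c("experiment", "ratio_name"), names(protein_quant))
  }
  grp <- if (length(by)) interaction(protein_quant[by], drop = TRUE)
         else factor(rep(1L, nrow(protein_quant)))
  protein_quant$p_adjusted <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    protein_quant$p_adjusted[idx] <-
      stats::p.adjust(protein_quant$p_value[idx], method = mt_correction)
  }
  lfc <- log2(fold_threshold)
  sig <- !is.na(protein_quant$p_adjusted) & protein_quant$p_adjusted <= alpha
  flag <- rep("none", nrow(protein_quant))
  flag[sig & protein_quant$mean_log2_ratio >= lfc] <- "up"
  flag[sig & protein_quant$mean_log2_ratio <= -lfc] <- "down"
  protein_quant$regulated_flag <- flag
  protein_quant
}
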