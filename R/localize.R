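# Phosphosite localization by the normalized Mascot delta score
# (nMD-score) and calibration of the acceptance threshold at a target
# false localization rate (FLR).

#' Mascot delta score and its normalized form
#'
#' The MD-score is the difference between the top two site-assignment
#' scores of a spectrum; dividing by the top score gives the normalized
#' nMD-score in `[0, 1]`. A tie between the top two assignments carries no
#' localization evidence (nMD = 0).
#'
#' @param top_score Top (rank 1) score; must be positive.
#' @param runner_up_score Runner-up (rank 2) score; `0 <= runner_up <= top`.
#' @return Data frame with columns `md` and `nmd` (vectorized).
#' @examples
#' nmd_score(20, 10)   # md 10, nmd 0.5
#' @export
nmd_score <- function(top_score, runner_up_score) {
  if (any(top_score <= 0)) stop("undefined score: top_score must be > 0")
  if (any(runner_up_score < 0) || any(runner_up_score > top_score)) {
    stop("require top_score >= runner_up_score >= 0")
  }
  md <- top_score - runner_up_score
  data.frame(md = md, nmd = md / top_score)
}

#' Calibrate an nMD threshold at a target false localization rate
#'
#' Given calibration PSMs with known localization correctness, returns the
#' smallest threshold `t` such that among PSMs with `nmd >= t` the
#' incorrect fraction is at most `target_flr`. If no threshold attains the
#' target, the threshold is set to 1 with `attainable = FALSE` and a
#' warning.
#'
#' @param nmd Numeric nMD-scores of the calibration set.
#' @param is_correct Logical correctness labels (both classes required).
#' @param target_flr Target FLR (default 0.01, i.e. 1%).
#' @return List of class `flr_calibration`: `target_flr`, `threshold`,
#'   `confidence` (1 - empirical FLR at the threshold),
#'   `n_calibration_psms`, `attainable`.
#' @export
calibrate_flr_threshold <- function(nmd, is_correct, target_flr = 0.01) {
  stopifnot(length(nmd) == length(is_correct))
  if (any(nmd < 0 | nmd > 1)) stop("nmd scores must lie in [0, 1]")
  if (all(is_correct) && target_flr >= 0) {
    cand <- 0
  } else if (!any(is_correct) || !any(!is_correct)) {
    stop("calibration error: calibration set must contain both correct and incorrect localizations")
  } else {
    cand <- sort(unique(c(0, nmd)))
  }
  ord <- order(nmd, decreasing = TRUE)
  inc_sorted <- !is_correct[ord]
  nmd_sorted <- nmd[ord]
  cum_inc <- cumsum(inc_sorted)
  flr_at <- function(t) {
    k <- sum(nmd_sorted >= t)
    if (k == 0L) return(0)
    cum_inc[k] / k
  }
  for (t in cand) {
    if (flr_at(t) <= target_flr) {
      return(structure(list(
        target_flr = target_flr, threshold = t,
        confidence = 1 - flr_at(t),
        n_calibration_psms = length(nmd), attainable = TRUE
      ), class = "flr_calibration"))
    }
  }
  warning("target FLR ", target_flr,
          " unattainable on this calibration set; threshold set to 1")
  structure(list(
    target_flr = target_flr, threshold = 1, confidence = 1 - flr_at(1),
    n_calibration_psms = length(nmd), attainable = FALSE
  ), class = "flr_calibration")
}

#' Filter PSMs by nMD threshold and map sites to protein coordinates
#'
#' Computes MD/nMD scores from the PSM score columns, marks PSMs with
#' `nmd >= threshold` as accepted (the boundary value is retained: only
#' scores strictly below the threshold are discarded), and converts the
#' peptide-level site offset to a 1-based protein residue number.
#'
#' @param psms PSM table with columns `psm_id`, `peptide`, `protein_id`,
#'   `peptide_start` (0-based peptide offset in the protein),
#'   `assigned_site_1based` (1-based site offset within the peptide),
#'   `top_score`, `runner_up_score`.
#' @param threshold nMD acceptance threshold in `[0, 1]` (default 0.36).
#' @return Data frame of localized sites: `psm_id`, `protein_id`,
#'   `position` (1-based protein residue), `residue`, `peptide`, `md`,
#'   `nmd`, `accepted`.
#' @export
filter_localized <- function(psms, threshold = 0.36) {
  stopifnot(is.data.frame(psms))
  need <- c("psm_id", "peptide", "protein_id", "peptide_start",
            "assigned_site_1based", "top_score", "runner_up_score")
  if (!all(need %in% names(psms))) {
    stop("psms table must have columns: ", paste(need, collapse = ", "))
  }
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  n <- nrow(psms)
  if (n == 0L) {
    return(data.frame(psm_id = character(), protein_id = character(),
                      position = integer(), residue = character(),
                      peptide = character(), md = numeric(), nmd = numeric(),
                      accepted = logical()))
  }
  off <- psms$assigned_site_1based
  plen <- nchar(psms$peptide)
  if (any(off < 1 | off > plen)) {
    bad <- psms$psm_id[off < 1 | off > plen]
    stop("site offset outside peptide for PSM(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  residue <- substr(psms$peptide, off, off)
  if (any(!residue %in% c("S", "T", "Y"))) {
    bad <- psms$psm_id[!residue %in% c("S", "T", "Y")]
    stop("assigned site is not S/T/Y for PSM(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  sc <- nmd_score(psms$top_score, psms$runner_up_score)
  data.frame(
    psm_id = psms$psm_id,
    protein_id = psms$protein_id,
    position = psms$peptide_start + off,  # 1-based protein residue
    residue = residue,
    peptide = psms$peptide,
    md = sc$md,
    nmd = sc$nmd,
    accepted = sc$nmd >= threshold
  )
}

#' Inventory of accepted phosphosites
#'
#' Uniqueness is keyed on `(protein_id, position)`; residue-class fractions
#' are computed over unique sites.
#'
#' @param localized Table from [filter_localized()].
#' @param accepted_only Restrict to accepted rows (default `TRUE`).
#' @return List with `n_unique_sites`, `n_proteins` and `residue_fractions`
#'   (named S/T/Y).
#' @export
site_inventory <- function(localized, accepted_only = TRUE) {
  stopifnot(is.data.frame(localized))
  x <- if (accepted_only && "accepted" %in% names(localized)) {
    localized[localized$accepted, ]
  } else localized
  if (nrow(x) == 0L) {
    return(list(n_unique_sites = 0L, n_proteins = 0L,
                residue_fractions = c(S = 0, T = 0, Y = 0)))
  }
  uni <- x[!duplicated(paste(x$protein_id, x$position)), ]
  frac <- c(S = 0, T = 0, Y = 0)
  tab <- table(uni$residue) / nrow(uni)
  frac[names(tab)] <- as.numeric(tab)
  list(
    n_unique_sites = nrow(uni),
    n_proteins = length(unique(uni$protein_id)),
    residue_fractions = frac
  )
}
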