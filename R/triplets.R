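# Reassembly of light/intermediate/heavy features of the same peptide into
# quantifiable triplets, using the exact monoisotopic dimethyl channel
# deltas (not the nominal 4 Da) with a ppm tolerance.

.DELTA_IL <- 32.056407 - 28.031300  # intermediate - light, per label site
.DELTA_HI <- 36.075670 - 32.056407  # heavy - intermediate, per label site

# ppm error of an observed pair against an expected delta, relative to the
# heavier observed mass
.pair_ppm <- function(m_lo, m_hi, delta) {
  abs(m_hi - m_lo - delta) / m_hi * 1e6
}

#' Match channel features into quantifiable triplets
#'
#' Candidate (light, intermediate, heavy) triples are those whose observed
#' mass differences match `n * per-site channel deltas` (4.025107 and
#' 4.019263 Da per labeled amine) within `tol_ppm` for some label-site
#' count `n`, and whose retention times agree within `rt_window`.
#' Assignment is greedy by ascending combined (sum of pairwise) ppm error,
#' with ties broken by smaller retention-time spread, then by feature ids;
#' each feature is used at most once. Features left without a complete
#' triplet are reported as orphans, never silently dropped.
#'
#' @param features Data frame with columns `feature_id`, `channel`,
#'   `observed_mass`, `rt` (plus any carried columns such as `peptide`).
#' @param tol_ppm Pairwise mass tolerance in ppm (default 10, the usual
#'   precursor tolerance).
#' @param rt_window Maximum pairwise retention-time difference (minutes).
#' @param max_label_sites Largest label-site count tried when inferring `n`
#'   from the mass spacing.
#' @return List with elements `triplets` (one row per matched triplet:
#'   feature ids, inferred `n_label_sites`, pairwise and maximum ppm
#'   errors, `rt_spread`, and `peptide`/`protein_id`/`experiment` carried
#'   from the light feature when present) and `orphans` (unmatched feature
#'   rows).
#' @export
match_triplets <- function(features, tol_ppm = 10, rt_window = 1,
                           max_label_sites = 6L) {
  stopifnot(is.data.frame(features))
  need <- c("feature_id", "channel", "observed_mass", "rt")
  if (!all(need %in% names(features))) {
    stop("features table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(features$feature_id)) stop("duplicated feature ids")
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")

  by_ch <- split(features, features$channel)
  L <- by_ch[["light"]]; I <- by_ch[["intermediate"]]; H <- by_ch[["heavy"]]
  empty_triplets <- data.frame(
    triplet_id = character(), light_id = character(),
    intermediate_id = character(), heavy_id = character(),
    n_label_sites = integer(), err_il_ppm = numeric(),
    err_hi_ppm = numeric(), max_pairwise_ppm = numeric(),
    rt_spread = numeric())
  if (is.null(L) || is.null(I) || is.null(H)) {
    return(list(triplets = empty_triplets, orphans = features))
  }

  ordI <- order(I$observed_mass); Is <- I[ordI, ]
  ordH <- order(H$observed_mass); Hs <- H[ordH, ]

  find_partners <- function(mass, rt, sorted, delta, tol_ppm, rt_window) {
    target <- mass + delta
    tol <- tol_ppm * 1e-6 * target
    lo <- findInterval(target - tol, sorted$observed_mass) + 1L
    hi <- findInterval(target + tol, sorted$observed_mass)
    if (hi < lo) return(integer())
    cand <- lo:hi
    cand[abs(sorted$rt[cand] - rt) <= rt_window &
           .pair_ppm(mass, sorted$observed_mass[cand], delta) <= tol_ppm]
  }

  cand_list <- list()
  for (n in seq_len(max_label_sites)) {
    dIL <- n * .DELTA_IL
    dHI <- n * .DELTA_HI
    for (il in seq_len(nrow(L))) {
      js <- find_partners(L$observed_mass[il], L$rt[il], Is, dIL,
                          tol_ppm, rt_window)
      for (j in js) {
        ks <- find_partners(Is$observed_mass[j], Is$rt[j], Hs, dHI,
                            tol_ppm, rt_window)
        if (!length(ks)) next
        e1 <- .pair_ppm(L$observed_mass[il], Is$observed_mass[j], dIL)
        e2 <- .pair_ppm(Is$observed_mass[j], Hs$observed_mass[ks], dHI)
        rts <- rbind(L$rt[il], Is$rt[j], Hs$rt[ks])
        cand_list[[length(cand_list) + 1L]] <- data.frame(
          light_id = L$feature_id[il],
          intermediate_id = Is$feature_id[j],
          heavy_id = Hs$feature_id[ks],
          n_label_sites = n,
          err_il_ppm = e1,
          err_hi_ppm = e2,
          rt_spread = apply(rts, 2L, max) - apply(rts, 2L, min),
          light_row = il
        )
      }
    }
  }

  if (!length(cand_list)) {
    return(list(triplets = empty_triplets, orphans = features))
  }
  cand <- do.call(rbind, cand_list)
  cand$total_ppm <- cand$err_il_ppm + cand$err_hi_ppm
  cand <- cand[order(cand$total_ppm, cand$rt_spread, cand$light_id,
                     cand$intermediate_id, cand$heavy_id), ]

  used <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ids <- c(cand$light_id[i], cand$intermediate_id[i], cand$heavy_id[i])
    if (!any(ids %in% used)) {
      keep[i] <- TRUE
      used <- c(used, ids)
    }
  }
  sel <- cand[keep, ]
  triplets <- data.frame(
    triplet_id = sprintf("T%05d", seq_len(nrow(sel))),
    light_id = sel$light_id,
    intermediate_id = sel$intermediate_id,
    heavy_id = sel$heavy_id,
    n_label_sites = sel$n_label_sites,
    err_il_ppm = sel$err_il_ppm,
    err_hi_ppm = sel$err_hi_ppm,
    max_pairwise_ppm = pmax(sel$err_il_ppm, sel$err_hi_ppm),
    rt_spread = sel$rt_spread
  )
  for (col in c("peptide", "protein_id", "experiment")) {
    if (col %in% names(L)) {
      triplets[[col]] <- L[[col]][sel$light_row]
    }
  }
  rownames(triplets) <- NULL
  orphans <- features[!features$feature_id %in% used, ]
  rownames(orphans) <- NULL
  list(triplets = triplets, orphans = orphans)
}
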