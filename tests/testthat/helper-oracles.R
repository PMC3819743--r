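# Independent brute-force oracles used to cross-check the package's
# optimized implementations on small instances.

# exhaustive O(n^3) triplet matcher: enumerate every (light, intermediate,
# heavy) triple and label-site count, keep feasible ones, then greedily
# select by ascending total ppm error (ties: rt spread, then feature ids)
oracle_match_triplets <- function(features, tol_ppm = 10, rt_window = 1,
                                  max_label_sites = 6L) {
  dIL <- 32.056407 - 28.031300
  dHI <- 36.075670 - 32.056407
  L <- features[features$channel == "light", ]
  I <- features[features$channel == "intermediate", ]
  H <- features[features$channel == "heavy", ]
  cand <- list()
  for (n in seq_len(max_label_sites)) {
    for (a in seq_len(nrow(L))) for (b in seq_len(nrow(I))) {
      e1 <- abs(I$observed_mass[b] - L$observed_mass[a] - n * dIL) /
        I$observed_mass[b] * 1e6
      if (e1 > tol_ppm || abs(L$rt[a] - I$rt[b]) > rt_window) next
      for (cc in seq_len(nrow(H))) {
        e2 <- abs(H$observed_mass[cc] - I$observed_mass[b] - n * dHI) /
          H$observed_mass[cc] * 1e6
        if (e2 > tol_ppm || abs(I$rt[b] - H$rt[cc]) > rt_window) next
        rts <- c(L$rt[a], I$rt[b], H$rt[cc])
        cand[[length(cand) + 1L]] <- data.frame(
          light_id = L$feature_id[a],
          intermediate_id = I$feature_id[b],
          heavy_id = H$feature_id[cc],
          n_label_sites = n,
          total = e1 + e2,
          rt_spread = max(rts) - min(rts))
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(light_id = character(), intermediate_id = character(),
                      heavy_id = character(), n_label_sites = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$total, cand$rt_spread, cand$light_id,
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
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

# build a feature table of planted triplets: random labeled peptide masses,
# per-feature ppm error uniform in [-ppm_noise, ppm_noise]
make_planted_features <- function(n_triplets, seed = 1L, ppm_noise = 0,
                                  n_sites_max = 3L, rt_spread = 0.02) {
  set.seed(seed)
  dIL <- 32.056407 - 28.031300
  dHI <- 36.075670 - 32.056407
  base <- runif(n_triplets, 700, 3500)
  n <- sample.int(n_sites_max, n_triplets, replace = TRUE)
  rt <- runif(n_triplets, 10, 110)
  rows <- lapply(seq_len(n_triplets), function(i) {
    m <- c(base[i], base[i] + n[i] * dIL, base[i] + n[i] * (dIL + dHI))
    e <- runif(3, -ppm_noise, ppm_noise)
    data.frame(
      feature_id = sprintf("P%04d_%s", i, c("L", "I", "H")),
      channel = c("light", "intermediate", "heavy"),
      observed_mass = m * (1 + e * 1e-6),
      rt = rt[i] + runif(3, -rt_spread, rt_spread),
      planted = i)
  })
  do.call(rbind, rows)
}

# per-position set-membership motif check (mirror of the scan definition,
# evaluated one window and one motif at a time)
oracle_motif_hit <- function(window, tokens) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  for (p in seq_along(tokens)) {
    tok <- tokens[[p]]
    if (identical(tok, ".")) next
    if (!chars[p] %in% tok) return(FALSE)
  }
  TRUE
}

# column-sum rescoring of one DNA window against a log-odds matrix
oracle_window_score <- function(window, log_odds) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(log_odds[cbind(idx, seq_along(idx))])
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# exhaustive double-stranded PWM scan by per-window rescoring
oracle_scan_sequence <- function(seq, pwm, min_relative_score) {
  L <- ncol(pwm$log_odds)
  n <- nchar(seq)
  cut <- min_relative_score * pwm$max_score
  rows <- list()
  for (s in seq_len(n - L + 1L)) {
    win <- substr(seq, s, s + L - 1L)
    fs <- oracle_window_score(win, pwm$log_odds)
    if (!is.na(fs) && fs >= cut) {
      rows[[length(rows) + 1L]] <- data.frame(start = s - 1L, strand = "+",
                                              score = fs)
    }
    rs <- oracle_window_score(oracle_revcomp(win), pwm$log_odds)
    if (!is.na(rs) && rs >= cut) {
      rows[[length(rows) + 1L]] <- data.frame(start = s - 1L, strand = "-",
                                              score = rs)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), ]
}
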