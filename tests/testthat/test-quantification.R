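make_ratio_triplets <- function(areas) {
  # areas: data.frame(light, intermediate, heavy) per triplet
  n <- nrow(areas)
  feats <- data.frame(
    feature_id = c(sprintf("L%d", 1:n), sprintf("I%d", 1:n),
                   sprintf("H%d", 1:n)),
    xic_area = c(areas$light, areas$intermediate, areas$heavy))
  trip <- data.frame(
    triplet_id = sprintf("T%d", 1:n),
    light_id = sprintf("L%d", 1:n),
    intermediate_id = sprintf("I%d", 1:n),
    heavy_id = sprintf("H%d", 1:n))
  list(triplets = trip, features = feats)
}

test_that("log2 ratios and mean abundances follow their definitions", {
  x <- make_ratio_triplets(data.frame(light = c(100, 50, 8),
                                      intermediate = c(200, 50, 100),
                                      heavy = c(400, 50, 25)))
  r <- compute_ratios(x$triplets, x$features)
  il <- r[r$ratio_name == "intermediate/light", ]
  hi <- r[r$ratio_name == "heavy/intermediate", ]
  expect_equal(il$M, c(1, 0, log2(100 / 8)))
  expect_equal(hi$M, c(1, 0, -2))
  expect_equal(il$A, (log2(c(200, 50, 100)) + log2(c(100, 50, 8))) / 2)

  x$features$xic_area[1] <- 0
  expect_error(compute_ratios(x$triplets, x$features), "L1")
})

test_that("LOWESS removes a constant offset exactly and preserves local ranks", {
  set.seed(1)
  r <- data.frame(ratio_name = "intermediate/light",
                  A = rnorm(200, 20, 2), M = 0.7)
  out <- lowess_normalize(r)
  expect_equal(max(abs(out$M_normalized)), 0)

  # shift-only per record: records sharing the same A get the same shift,
  # so M-ranking among coincident-A records is preserved
  r2 <- data.frame(ratio_name = "x", A = rep(seq(15, 25, by = 0.5), 4),
                   M = rnorm(84, sd = 0.3))
  out2 <- lowess_normalize(r2)
  shift <- out2$M - out2$M_normalized
  for (a in unique(r2$A)) {
    expect_equal(diff(range(shift[r2$A == a])), 0)
  }
  expect_error(lowess_normalize(r[1:5, ]), "too few")
})

test_that("LOWESS trend agrees with an independent local-regression fit", {
  skip_if_not_installed("limma")
  set.seed(2)
  n <- 2000
  A <- rnorm(n, 20, 2)
  M <- 0.4 * (plogis((A - 20) / 1.5) - 0.5) + rnorm(n, sd = 0.25)
  r <- data.frame(ratio_name = "x", A = A, M = M)
  out <- lowess_normalize(r, span = 0.4, iterations = 3)
  trend_ours <- out$M - out$M_normalized
  fit <- limma::loessFit(M, A, span = 0.4, iterations = 4)
  expect_lt(mean(abs(trend_ours - fit$fitted)), 0.02)
})

test_that("planted intensity bias is removed to a near-zero median", {
  p <- generate_proteome(250, c(250, 400), seed = 41)
  sites <- plant_phosphosites(p, 5, seed = 41)
  prof <- plant_regulation(p, frac_regulated = 0, seed = 41)
  nc <- noise_config(xic_log2_sd = 0.15, bias_amplitude = 0.5,
                     missing_rate = 0)
  sim <- simulate_experiment(p, sites, prof, noise = nc, seed = 42,
                             n_peptides = 5000)
  res <- match_triplets(sim$features[sim$features$experiment == 1, ])
  r <- compute_ratios(res$triplets, sim$features)
  il <- r[r$ratio_name == "intermediate/light", ]
  # the planted sigmoid creates a real intensity-dependent trend ...
  lo <- il$A < quantile(il$A, 0.2); hi <- il$A > quantile(il$A, 0.8)
  raw_gap <- mean(il$M[hi]) - mean(il$M[lo])
  expect_gt(abs(raw_gap), 0.15)
  # ... which LOWESS flattens, leaving a near-zero median
  r <- lowess_normalize(r)
  for (rn in unique(r$ratio_name)) {
    expect_lt(abs(median(r$M_normalized[r$ratio_name == rn])), 0.05)
  }
  iln <- r[r$ratio_name == "intermediate/light", ]
  norm_gap <- mean(iln$M_normalized[hi]) - mean(iln$M_normalized[lo])
  expect_lt(abs(norm_gap), 0.05)
})

test_that("protein roll-up is the exact mean of member peptide ratios", {
  r <- data.frame(
    ratio_name = "intermediate/light",
    peptide = c("AAA", "BBB", "CCC", "DDD", "EEE"),
    protein_id = c("P1", "P1", "P1", "P2", "P2"),
    M_normalized = c(1, 1, 1, 1, -1))
  pq <- rollup_proteins(r)
  expect_equal(pq$mean_log2_ratio[pq$protein_id == "P1"], 1)
  expect_equal(pq$sd_log2_ratio[pq$protein_id == "P1"], 0)
  expect_true(is.na(pq$p_value[pq$protein_id == "P1"]))  # zero dispersion
  expect_equal(pq$mean_log2_ratio[pq$protein_id == "P2"], 0)

  set.seed(3)
  r2 <- data.frame(ratio_name = "x",
                   protein_id = sample(sprintf("P%d", 1:30), 300, TRUE),
                   M_normalized = rnorm(300))
  pq2 <- rollup_proteins(r2)
  for (i in seq_len(nrow(pq2))) {   # direct-summation oracle
    x <- r2$M_normalized[r2$protein_id == pq2$protein_id[i]]
    expect_equal(pq2$mean_log2_ratio[i], sum(x) / length(x))
  }

  expect_error(
    rollup_proteins(data.frame(ratio_name = "x", peptide = "AAA",
                               M_normalized = 0),
                    mapping = data.frame(peptide = "ZZZ",
                                         protein_id = "P1")),
    "unmapped")
})

test_that("planted 2-fold proteins are recovered with small error", {
  set.seed(4)
  n_reg <- 200; n_null <- 800; k <- 5
  prot <- c(sprintf("R%03d", seq_len(n_reg)), sprintf("N%03d", seq_len(n_null)))
  truth <- c(rep(1, n_reg), rep(0, n_null))
  A <- rnorm((n_reg + n_null) * k, 20, 2)
  r <- data.frame(
    ratio_name = "intermediate/light",
    protein_id = rep(prot, each = k),
    A = A,
    M = rep(truth, each = k) + 0.4 * (plogis((A - 20) / 1.5) - 0.5) +
      rnorm((n_reg + n_null) * k, sd = 0.2))
  r <- lowess_normalize(r)
  pq <- rollup_proteins(r)
  est <- pq$mean_log2_ratio[match(sprintf("R%03d", seq_len(n_reg)),
                                  pq$protein_id)]
  expect_lt(sqrt(mean((est - 1)^2)), 0.15)       # RMSE
  expect_lt(abs(mean(est - 1)), 0.05)            # near-unbiased
})

test_that("regulation flags respect fold and significance thresholds", {
  pq <- data.frame(
    ratio_name = "x",
    protein_id = c("P1", "P2", "P3"),
    n_peptides = 5,
    mean_log2_ratio = c(2.0, 0.1, -1.2),
    sd_log2_ratio = 0.2,
    p_value = c(1e-4, 1e-6, 2e-3))
  out <- flag_regulated(pq, fold_threshold = 1.5, alpha = 0.05)
  expect_equal(out$regulated_flag, c("up", "none", "down"))
})

test_that("no proteins are flagged beyond alpha on null data", {
  set.seed(5)
  n_prot <- 400; k <- 4
  r <- data.frame(ratio_name = "x",
                  protein_id = rep(sprintf("P%03d", seq_len(n_prot)), each = k),
                  M_normalized = rnorm(n_prot * k, sd = 0.2))
  pq <- flag_regulated(rollup_proteins(r), fold_threshold = 1, alpha = 0.05)
  fp <- mean(pq$regulated_flag != "none")
  expect_lte(fp, 0.05 + 3 * sqrt(0.05 * 0.95 / n_prot))
})
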