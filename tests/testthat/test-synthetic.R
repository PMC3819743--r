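test_that("proteome generation is seed-deterministic with bounded lengths", {
  a <- generate_proteome(1, c(50, 50), seed = 7)
  b <- generate_proteome(1, c(50, 50), seed = 7)
  expect_identical(a, b)
  expect_equal(nchar(a$sequence), 50)

  p <- generate_proteome(100, c(100, 500), seed = 1)
  expect_equal(nrow(p), 100)
  expect_true(all(nchar(p$sequence) >= 100 & nchar(p$sequence) <= 500))
  expect_error(generate_proteome(2, c(50, 10)), "length_range")
})

test_that("K+R frequency sets the tryptic peptide length scale", {
  p <- generate_proteome(60, c(300, 400), seed = 3, kr_fraction = 0.1)
  d <- digest_proteome(p, max_missed = 0)
  # geometric argument: mean fragment length ~ 1 / 0.1 = 10
  expect_equal(mean(nchar(d$sequence)), 10, tolerance = 0.2)
})

test_that("planted phosphosites respect residue classes and probabilities", {
  p <- generate_proteome(40, c(200, 400), seed = 5)
  all_s <- plant_phosphosites(p, 50, residue_probs = c(S = 1, T = 0, Y = 0),
                              seed = 1)
  expect_true(all(all_s$residue == "S"))
  expect_equal(nrow(plant_phosphosites(p, 0)), 0L)

  p <- generate_proteome(250, c(300, 500), seed = 5)
  st <- plant_phosphosites(p, 2000, seed = 2)
  # sites are unique and point at the stated residue
  expect_false(anyDuplicated(paste(st$protein_id, st$position)) > 0)
  seqs <- setNames(p$sequence, p$id)
  expect_true(all(substr(seqs[st$protein_id], st$position + 1,
                         st$position + 1) == st$residue))
  # class fractions converge to the configured distribution (3 binomial SE)
  probs <- c(S = 0.875, T = 0.115, Y = 0.008) / 0.998
  frac <- table(factor(st$residue, c("S", "T", "Y"))) / nrow(st)
  se <- sqrt(probs * (1 - probs) / nrow(st))
  expect_true(all(abs(as.numeric(frac) - probs) <= 3 * se))
})

test_that("noise-free simulation reproduces planted abundances exactly", {
  p <- generate_proteome(10, c(150, 250), seed = 8)
  sites <- plant_phosphosites(p, 10, seed = 8)
  prof <- plant_regulation(p, frac_regulated = 0, seed = 8)
  # plant a +1 log2 fold on the first ratio for one protein
  prof$lf_10min_0h[1] <- 1
  quiet <- noise_config(xic_log2_sd = 0, bias_amplitude = 0, ppm_sd = 0,
                        missing_rate = 0, rt_jitter = 0)
  sim <- simulate_experiment(p, sites, prof, noise = quiet, seed = 9)
  f1 <- sim$features[sim$features$experiment == 1, ]
  w <- reshape(f1[, c("peptide", "channel", "xic_area")],
               idvar = "peptide", timevar = "channel", direction = "wide")
  unreg <- w[!w$peptide %in% f1$peptide[f1$protein_id == prof$protein_id[1]], ]
  reg <- w[w$peptide %in% f1$peptide[f1$protein_id == prof$protein_id[1]], ]
  # unregulated proteins: all three channels identical
  expect_equal(unreg$xic_area.intermediate, unreg$xic_area.light)
  expect_equal(unreg$xic_area.heavy, unreg$xic_area.light)
  # planted log2 fold +1 on intermediate/light: area ratio exactly 2
  expect_equal(reg$xic_area.intermediate / reg$xic_area.light,
               rep(2, nrow(reg)))
})

test_that("log2 ratio noise matches the closed-form sd of a difference", {
  p <- generate_proteome(250, c(250, 400), seed = 11)
  sites <- plant_phosphosites(p, 5, seed = 11)
  prof <- plant_regulation(p, frac_regulated = 0, seed = 11)
  nc <- noise_config(xic_log2_sd = 0.1, bias_amplitude = 0, missing_rate = 0)
  sim <- simulate_experiment(p, sites, prof, noise = nc, seed = 12,
                             n_peptides = 5000)
  f1 <- sim$features[sim$features$experiment == 1, ]
  w <- reshape(f1[, c("peptide", "channel", "xic_area")],
               idvar = "peptide", timevar = "channel", direction = "wide")
  m <- log2(w$xic_area.intermediate / w$xic_area.light)
  # M = difference of two iid N(., 0.1) log2 areas => sd = sqrt(2) * 0.1
  expect_equal(sd(m), sqrt(2) * 0.1, tolerance = 0.1)
})

test_that("observed channel masses differ by exact label shifts before ppm noise", {
  p <- generate_proteome(6, c(120, 200), seed = 21)
  sites <- plant_phosphosites(p, 4, seed = 21)
  prof <- plant_regulation(p, seed = 21)
  nc <- noise_config(ppm_sd = 0, missing_rate = 0)
  sim <- simulate_experiment(p, sites, prof, noise = nc, seed = 22)
  f1 <- sim$features[sim$features$experiment == 1, ]
  w <- reshape(f1[, c("peptide", "channel", "observed_mass")],
               idvar = "peptide", timevar = "channel", direction = "wide")
  n_sites <- count_label_sites(w$peptide)
  expect_equal(w$observed_mass.intermediate - w$observed_mass.light,
               n_sites * (32.056407 - 28.031300))
  expect_equal(w$observed_mass.heavy - w$observed_mass.intermediate,
               n_sites * (36.075670 - 32.056407))
  # cross-check absolute masses against the chemistry module
  i <- which.min(nchar(w$peptide))
  pep <- sim$peptides[sim$peptides$sequence == w$peptide[i], ]
  expect_equal(w$observed_mass.light[i],
               peptide_mono_mass(pep$sequence, "light", pep$n_phospho))
})

test_that("simulation writes disjoint observable and truth tables plus metadata", {
  p <- generate_proteome(5, c(100, 150), seed = 31)
  sites <- plant_phosphosites(p, 6, seed = 31)
  prof <- plant_regulation(p, seed = 31)
  sim <- simulate_experiment(p, sites, prof, seed = 32)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  feats <- read_table_tsv(paths[["features"]])
  expect_equal(nrow(feats), nrow(sim$features))
  # observable tables never carry truth flags
  expect_false(any(c("is_correct_localization", "regulated") %in%
                     c(names(feats), names(read_table_tsv(paths[["psms"]])))))
  meta <- jsonlite::read_json(paths[["metadata"]])
  expect_equal(meta$seed, 32)
  # PSM scores are ordered and truth rows align with PSM ids
  expect_true(all(sim$psms$top_score >= sim$psms$runner_up_score))
  expect_true(all(sim$psms$runner_up_score >= 0))
  expect_identical(sim$truth$psms$psm_id, sim$psms$psm_id)
})
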