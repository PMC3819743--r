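pfm_path <- system.file("extdata", "synthetic_tf_pfms.jaspar",
                        package = "triplexquant")

test_that("JASPAR PFM parsing round-trips and rejects malformed input", {
  toy <- c(">M001 TOY", "A [ 1 2 ]", "C [ 3 4 ]", "G [ 5 6 ]", "T [ 7 8 ]")
  pfm <- read_pfm(text = toy)[[1]]
  expect_equal(ncol(pfm$counts), 2L)
  expect_equal(pfm$counts["T", ], c(7, 8))

  tmp <- withr::local_tempfile(fileext = ".jaspar")
  write_pfm(pfm, tmp)
  back <- read_pfm(tmp)[[1]]
  expect_equal(back$counts, pfm$counts)
  expect_equal(back$tf_name, "TOY")

  expect_error(read_pfm(text = c(">X A", "A [ -1 ]", "C [ 1 ]", "G [ 1 ]",
                                 "T [ 1 ]")), "negative")
  expect_error(read_pfm(text = c(">X A", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 ]",
                                 "T [ 1 ]")), "mismatch")

  pfms <- read_pfm(pfm_path)
  expect_setequal(names(pfms), c("SP1", "MYC", "NFKB"))
})

test_that("log-odds transform follows the pseudocount formula", {
  # uniform counts, uniform background -> zero information
  uni <- read_pfm(text = c(">U U", "A [ 5 5 ]", "C [ 5 5 ]", "G [ 5 5 ]",
                           "T [ 5 5 ]"))[[1]]
  expect_equal(max(abs(pfm_to_pwm(uni)$log_odds)), 0)

  one <- read_pfm(text = c(">O O", "A [ 100 ]", "C [ 0 ]", "G [ 0 ]",
                           "T [ 0 ]"))[[1]]
  pw <- pfm_to_pwm(one, pseudocount = 0.25)
  expect_equal(unname(pw$log_odds["A", 1]), log2((100.25 / 101) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pw$log_odds["A", 1]), 1.989, tolerance = 1e-3)

  # max_score equals scoring the consensus sequence
  pfm <- read_pfm(pfm_path)[["SP1"]]
  pw2 <- pfm_to_pwm(pfm)
  consensus <- paste(c("A", "C", "G", "T")[apply(pfm$counts, 2, which.max)],
                     collapse = "")
  expect_equal(oracle_window_score(consensus, pw2$log_odds), pw2$max_score)
  expect_error(pfm_to_pwm(pfm, background = c(A = 1, C = 1, G = 1, T = 1)),
               "background")
})

test_that("an embedded consensus is found once, on the right strand", {
  pfm <- read_pfm(pfm_path)[["NFKB"]]
  pw <- pfm_to_pwm(pfm)
  consensus <- paste(c("A", "C", "G", "T")[apply(pfm$counts, 2, which.max)],
                     collapse = "")
  set.seed(9)
  bg <- paste(sample(c("A", "T"), 400, TRUE), collapse = "")  # no G/C runs
  seq <- paste0(substr(bg, 1, 100), consensus, substr(bg, 101, 400))
  hits <- scan_sequence(seq, pw, min_relative_score = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 100L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$relative_score, 1)

  rc <- oracle_revcomp(consensus)
  seq2 <- paste0(substr(bg, 1, 100), rc, substr(bg, 101, 400))
  hits2 <- scan_sequence(seq2, pw, min_relative_score = 1)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$start, 100L)   # forward-strand coordinates
  expect_equal(hits2$strand, "-")
})

test_that("scanning equals exhaustive per-window rescoring on random promoters", {
  pwms <- lapply(read_pfm(pfm_path), pfm_to_pwm)
  proms <- generate_promoters(100, 500, seed = 10)
  # inject some Ns: windows containing them must be skipped, not scored
  substr(proms$sequence[1], 50, 60) <- "NNNNNNNNNNN"
  for (pw in pwms[c("SP1", "MYC")]) {
    for (i in c(1:10, 55, 100)) {
      got <- scan_sequence(proms$sequence[i], pw, min_relative_score = 0.75)
      want <- oracle_scan_sequence(proms$sequence[i], pw, 0.75)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_equal(got[, c("start", "strand", "score")], want,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  pw <- pfm_to_pwm(read_pfm(pfm_path)[["MYC"]])
  prom <- generate_promoters(1, 300, seed = 11)$sequence
  L <- ncol(pw$log_odds)
  h_fwd <- scan_sequence(prom, pw, 0.5)
  h_rc <- scan_sequence(oracle_revcomp(prom), pw, 0.5)
  expect_gt(nrow(h_fwd), 0)
  # a + hit at start s maps to a - hit at n - L - s in the reverse complement
  mirrored <- data.frame(start = nchar(prom) - L - h_fwd$start,
                         strand = ifelse(h_fwd$strand == "+", "-", "+"),
                         score = h_fwd$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(h_rc[, c("start", "strand", "score")], mirrored,
               ignore_attr = TRUE)
})

test_that("gene hit fractions reproduce a planted >= 80% design and are monotone", {
  pfm <- read_pfm(pfm_path)[["SP1"]]
  pw <- pfm_to_pwm(pfm)
  consensus <- paste(c("A", "C", "G", "T")[apply(pfm$counts, 2, which.max)],
                     collapse = "")
  proms <- generate_promoters(10, 300, seed = 12)
  planted <- plant_motif(proms, consensus, fraction = 0.8, seed = 13)
  res <- gene_hit_fraction(planted$promoters, pw, min_relative_score = 0.8)
  expect_gte(res$fractions$fraction, 0.8)

  # motif planted nowhere + strict threshold -> zero
  res0 <- gene_hit_fraction(generate_promoters(10, 300, seed = 14), pw,
                            min_relative_score = 1)
  expect_equal(res0$fractions$fraction, 0)

  # raising the threshold never increases the fraction
  grid <- c(0.6, 0.7, 0.8, 0.9, 1)
  fr <- vapply(grid, function(t) {
    gene_hit_fraction(planted$promoters, pw, t)$fractions$fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})
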