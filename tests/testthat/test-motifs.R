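test_that("seed size selection reproduces the 10-mer rule and is monotone", {
  expect_equal(select_seed_size(rep(1997, 25)), 10)
  # monotone in the median length, non-increasing in the threshold
  expect_lt(select_seed_size(rep(100, 5)), select_seed_size(rep(10000, 5)))
  expect_lte(select_seed_size(rep(2000, 5), occurrence_threshold = 0.01),
             select_seed_size(rep(2000, 5), occurrence_threshold = 0.001))
  expect_error(select_seed_size(numeric(0)), "empty")
  expect_error(select_seed_size(c(100, -5)), "positive")
})

test_that("the chance-occurrence formula matches Monte-Carlo frequencies", {
  L <- round(1997 * sqrt(10))
  n_seq <- 1500
  set.seed(99)
  pool <- paste(sample(c("A", "C", "G", "T"), n_seq * L, replace = TRUE),
                collapse = "")
  windows <- Biostrings::DNAStringSet(substring(
    pool, (seq_len(n_seq) - 1) * L + 1, seq_len(n_seq) * L))
  for (k in c(9, 10)) {
    probe <- paste(rep(c("A", "C", "G", "T"), length.out = k), collapse = "")
    phat <- mean(Biostrings::vcountPattern(probe, windows) > 0)
    p_theory <- kmer_chance_probability(L, k)
    expect_lt(abs(phat - p_theory),
              2.58 * sqrt(p_theory * (1 - p_theory) / n_seq) + 1e-3)
  }
  # the returned k is the first to dip under the threshold
  expect_lt(kmer_chance_probability(L, 10), 0.01)
  expect_gt(kmer_chance_probability(L, 9), 0.01)
})

test_that("length windows bound the pairwise ratio at 10", {
  keep <- length_window_filter(c(100, 1000, 10000))
  expect_identical(keep, c(FALSE, TRUE, FALSE))
  expect_true(length_window_filter(4000, mode = "fixed_400_4000"))
  expect_true(length_window_filter(400, mode = "fixed_400_4000"))
  expect_false(length_window_filter(399, mode = "fixed_400_4000"))
  set.seed(20)
  for (i in 1:5) {
    lens <- rlnorm(500, log(2000), runif(1, 0.5, 1.5))
    kept <- lens[length_window_filter(lens)]
    expect_lte(max(kept) / min(kept), 10)
  }
})

test_that("mutual information is non-negative and label-invariant", {
  set.seed(21)
  pres <- matrix(as.numeric(runif(200 * 5) < 0.4), 200, 5)
  bins <- fripflow:::equal_bins(rnorm(200), 3)
  mi <- fripflow:::mi_presence(pres, bins, 3)
  expect_true(all(mi >= 0))
  relabel <- c(2L, 3L, 1L)[bins]
  expect_equal(fripflow:::mi_presence(pres, relabel, 3), mi)
  # constant presence carries no information
  expect_equal(fripflow:::mi_presence(matrix(1, 200, 1), bins, 3)[1], 0)
})

test_that("an implanted motif effect is found and generalized sanely", {
  genes <- gen_gene_models(500, seed = 22)
  sq <- gen_sequences(genes, motif = "GATTACA", implant_rate = 1, seed = 23)
  stat <- sq$truth$implanted * 1 + rnorm(500, 0, 0.4)
  res <- mi_motif_scan(sq$sequences, stat, k_seed = 7, n_perm = 60,
                       seed = 24)
  expect_equal(res$seed_pattern[1], "GATTACA")
  expect_true(res$significant[1])
  expect_identical(res$direction[1], "enriched")
  expect_gt(res$z[1], 10)
  # generalized pattern still matches the implanted motif
  hits <- Biostrings::vcountPattern(res$pattern[1],
                                    Biostrings::DNAStringSet("GATTACA"),
                                    fixed = FALSE)
  expect_equal(hits, 1)
})

test_that("a statistic independent of sequence yields no significant motif", {
  for (s in 1:3) {
    genes <- gen_gene_models(300, seed = 30 + s)
    sq <- gen_sequences(genes, seed = 40 + s)
    res <- mi_motif_scan(sq$sequences, rnorm(300), k_seed = 5, n_perm = 100,
                         seed = 50 + s, generalize = FALSE)
    expect_equal(sum(res$significant), 0)
  }
})

test_that("motif scan validates its inputs", {
  genes <- gen_gene_models(30, seed = 1)
  sq <- gen_sequences(genes, seed = 2)
  expect_error(mi_motif_scan(sq$sequences, rnorm(30), n_bins = 1), "n_bins")
  expect_error(mi_motif_scan(sq$sequences, rnorm(30), k_seed = 3), "k_seed")
  expect_error(mi_motif_scan(sq$sequences, rnorm(10)), "aligned")
})

test_that("dose response is flat under the null and tracks implanted doses", {
  genes <- gen_gene_models(600, seed = 25)
  sq <- gen_sequences(genes, motif = "GATTACA", implant_rate = 1.2,
                      seed = 26)
  null_stat <- rnorm(600)
  dr0 <- motif_dose_response("GATTACA", sq$sequences, null_stat)
  expect_lt(max(abs(dr0$q50)), 0.35)

  stat <- 0.5 * sq$truth$implanted + rnorm(600, 0, 0.2)
  dr <- motif_dose_response("GATTACA", sq$sequences, stat)
  expect_true(all(diff(dr$q50) > 0))
  steps <- diff(dr$q50[1:3])  # one extra occurrence adds ~0.5
  expect_equal(unname(steps), c(0.5, 0.5), tolerance = 0.35)
  expect_true(all(dr$q25 <= dr$q50 & dr$q50 <= dr$q75))
})

test_that("dose-response percentiles match a sort-based brute force", {
  set.seed(27)
  seqs <- Biostrings::DNAStringSet(vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
          collapse = ""), character(1)))
  stat <- rnorm(50)
  counts <- Biostrings::vcountPattern("ACGT", seqs)
  dr <- motif_dose_response("ACGT", seqs, stat)
  for (r in seq_len(nrow(dr))) {
    lev <- dr$occurrences[r]
    sel <- if (lev == "3+") counts >= 3 else counts == as.integer(lev)
    x <- sort(stat[sel])
    expect_equal(dr$q50[r], unname(stats::quantile(x, 0.5)))
    expect_equal(dr$q25[r], unname(stats::quantile(x, 0.25)))
  }
  expect_error(motif_dose_response("QQ", seqs, stat), "IUPAC")
})
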