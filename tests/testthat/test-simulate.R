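test_that("gene model generation is deterministic and respects parameters", {
  g1 <- gen_gene_models(40, seed = 7)
  g2 <- gen_gene_models(40, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(g1, gen_gene_models(40, seed = 8)))

  # degenerate distributions: one exon, fixed length
  gf <- gen_gene_models(3, length_meanlog = log(1000), length_sdlog = 0,
                        exon_count_dist = function(n) rep(1L, n), seed = 1)
  for (g in unclass(gf)) {
    iso <- g$isoforms[[1]]
    expect_equal(nrow(iso$exons), 1)
    expect_equal(isoform_length(iso), 1000)
  }

  expect_error(gen_gene_models(0), "n_genes")
  expect_error(gen_gene_models(5, lnc_fraction = 1.5), "lnc_fraction")
  expect_error(gen_gene_models(5, length_sdlog = -1), "sdlog")
})

test_that("lncRNA fraction lands within binomial sampling error", {
  g <- gen_gene_models(500, lnc_fraction = 0.2, seed = 7)
  n_lnc <- sum(vapply(unclass(g), `[[`, character(1), "biotype") == "lncRNA")
  expect_gt(n_lnc, 100 - 3 * sqrt(500 * 0.2 * 0.8))
  expect_lt(n_lnc, 100 + 3 * sqrt(500 * 0.2 * 0.8))
})

test_that("sequences match transcript lengths, GC and implantation truth", {
  genes <- gen_gene_models(60, seed = 3)
  lens <- vapply(unclass(genes), function(g) isoform_length(g$isoforms[[1]]),
                 numeric(1))
  sq0 <- gen_sequences(genes, implant_rate = 0, seed = 4)
  expect_equal(unname(Biostrings::width(sq0$sequences)), unname(lens))
  expect_true(all(sq0$truth$implanted == 0))

  sq <- gen_sequences(genes, motif = "GATTACA", implant_rate = 2, seed = 4)
  expect_equal(mean(sq$truth$implanted), 2, tolerance = 0.15)
  # every recorded implant is present in the sequence
  found <- Biostrings::vcountPattern("GATTACA", sq$sequences)
  expect_true(all(found >= sq$truth$implanted))
  expect_true(all(vapply(seq_along(sq$positions), function(i) {
    pos <- sq$positions[[i]]
    is.null(pos) || max(pos) + 6 <= lens[i]
  }, logical(1))))

  gc6 <- gen_sequences(genes, gc = 0.6, seed = 5)
  freq <- Biostrings::alphabetFrequency(gc6$sequences, baseOnly = TRUE,
                                        collapse = TRUE)
  expect_equal(sum(freq[c("C", "G")]) / sum(freq), 0.6, tolerance = 0.02)

  expect_error(gen_sequences(genes, motif = "XYZ", implant_rate = 1),
               "IUPAC")
  expect_error(gen_sequences(genes, motif = strrep("A", 10000),
                             implant_rate = 1), "longer")
})

test_that("null experiment produces near-zero fold changes", {
  spec <- binding_spec("N", noise_sd = 0, intron_fraction = 0)
  qe <- quick_enrichment(400, spec, n_reps = 2, seed = 31,
                         library_size = 5e7)
  ok <- qe$res$tested
  expect_lt(abs(mean(qe$res$log2fc[ok])), 0.05)
  expect_lt(stats::sd(qe$res$log2fc[ok]), 0.6)
  expect_lt(unname(stats::quantile(abs(qe$res$log2fc[ok]), 0.95)), 1)
})

test_that("an exon-count effect is recovered with the correct sign", {
  spec <- binding_spec("E", beta_exon = 0.1)
  qe <- quick_enrichment(800, spec, seed = 17)
  ok <- qe$res$tested
  rho <- attribute_correlation(qe$res$log2fc[ok], qe$covs$exon_count[ok])
  expect_gt(rho$rho, 0.3)
  expect_lt(rho$p, 1e-6)
})

test_that("experiment requires sequences when motif effects are requested", {
  genes <- gen_gene_models(20, seed = 2)
  expect_error(gen_experiment(genes, list(binding_spec("M", beta_motif = 1)),
                              seed = 3), "sequences")
})

test_that("experiments are reproducible under a fixed seed", {
  genes <- gen_gene_models(30, seed = 5)
  e1 <- gen_experiment(genes, list(binding_spec("P")), seed = 6)
  e2 <- gen_experiment(genes, list(binding_spec("P")), seed = 6)
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$truth, e2$truth)
})

test_that("binding_spec validates its invariants", {
  expect_error(binding_spec("P", intron_fraction = 1.2), "intron_fraction")
  expect_error(binding_spec("P", noise_sd = -1), "noise_sd")
  expect_error(binding_spec("P", dispersion = 0), "dispersion")
})

test_that("chromatin scores follow the generating model", {
  genes <- gen_gene_models(600, seed = 12)
  fpkm <- stats::rlnorm(600, 1, 1.5)
  bound <- rep(c(TRUE, FALSE), 300)
  ch <- gen_chromatin(genes, fpkm, bound, mark_slope = 2, bound_shift = 0,
                      noise_sd = 0.2, seed = 13)
  expect_gt(stats::cor(ch$score, fpkm, method = "spearman"), 0.9)

  ch0 <- gen_chromatin(genes, fpkm, bound, mark_slope = 1, bound_shift = 0,
                       noise_sd = 0.1, seed = 14)
  gap0 <- lowess_gap(ch0$score, fpkm, bound, n_perm = 100, seed = 15)
  expect_lt(abs(gap0$gap), 0.05)

  expect_error(gen_chromatin(genes, fpkm[-1], bound), "all genes")
  expect_error(gen_chromatin(genes, fpkm, bound[-1]), "all genes")
})

test_that("TE annotations stay inside transcripts and respect families", {
  genes <- gen_gene_models(100, seed = 3)
  lens <- vapply(unclass(genes), function(g) isoform_length(g$isoforms[[1]]),
                 numeric(1))
  te <- gen_te_annotations(genes, families = c("Alu", "L1"), rate = 0.3,
                           seed = 4)
  expect_setequal(unique(te$family), c("Alu", "L1"))
  expect_true(all(te$start >= 0))
  expect_true(all(te$end <= lens[te$gene_id]))
})

test_that("simulated coverage reflects the positional bias parameter", {
  genes <- gen_gene_models(50, seed = 6)
  cv <- gen_coverage(genes, bias = 1, depth = 3, seed = 7)
  lens <- lengths(cv)
  glens <- vapply(unclass(genes), function(g) isoform_length(g$isoforms[[1]]),
                  numeric(1))
  expect_equal(unname(lens), unname(glens))
  mp <- metagene_profile(cv)
  expect_gt(mp$bias_index, 0.5)
})
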