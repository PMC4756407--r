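test_that("isoform and gene constructors validate their invariants", {
  expect_error(isoform("i1", rbind(c(10, 10))), "empty or inverted")
  expect_error(isoform("i1", rbind(c(0, 100), c(50, 200))), "overlapping")
  iso <- isoform("i1", rbind(c(200, 300), c(0, 100)))
  expect_equal(iso$exons[, "start"], c(0, 200))  # sorted on construction
  expect_equal(isoform_length(iso), 200)
  expect_equal(isoform_span(iso), c(0, 300))
  expect_error(gene_model("g", "chr1", "+", "mRNA", list()), ">= 1 isoform")
})

test_that("pre-RNA isoforms are added per unique (start, end) pair", {
  g <- toy_gene()  # t1 spans [1000,5000), t2 spans [1000,6000)
  g2 <- add_prerna_isoforms(g)
  pre <- Filter(function(i) i$cls == "preRNA", g2$isoforms)
  expect_length(pre, 2)
  spans <- sort(vapply(pre, function(i) diff(isoform_span(i)), numeric(1)))
  expect_equal(unname(spans), c(4000, 5000))
  expect_true(all(vapply(pre, function(i) nrow(i$exons) == 1, logical(1))))

  # two isoforms sharing start and end collapse to one pre-RNA isoform
  shared <- gene_model("gS", "chr1", "+", "mRNA", list(
    isoform("a", rbind(c(0, 100), c(900, 1000))),
    isoform("b", rbind(c(0, 50), c(500, 1000)))))
  expect_length(Filter(function(i) i$cls == "preRNA",
                       add_prerna_isoforms(shared)$isoforms), 1)

  # degenerate: single-exon gene gets a pre-RNA copy of itself
  single <- gene_model("g1", "chr1", "+", "mRNA",
                       list(isoform("g1.t1", rbind(c(100, 1100)))))
  s2 <- add_prerna_isoforms(single)
  pre1 <- Filter(function(i) i$cls == "preRNA", s2$isoforms)[[1]]
  expect_equal(unname(pre1$exons[1, ]), c(100, 1100))
})

test_that("add_prerna_isoforms is idempotent and preserves originals", {
  g2 <- add_prerna_isoforms(toy_gene())
  g3 <- add_prerna_isoforms(g2)
  expect_identical(names(g3$isoforms), names(g2$isoforms))
  expect_identical(g2$isoforms[["gX.t1"]], toy_gene()$isoforms[["gX.t1"]])
})

test_that("intron isoforms cover intron plus flanking exons", {
  single <- gene_model("g1", "chr1", "+", "mRNA",
                       list(isoform("t", rbind(c(0, 500)))))
  expect_length(Filter(function(i) i$cls == "intron_centered",
                       add_intron_isoforms(single)$isoforms), 0)

  g <- gene_model("g2", "chr1", "+", "mRNA", list(
    isoform("t", rbind(c(0, 100), c(200, 300), c(400, 500)))))
  g2 <- add_intron_isoforms(g)
  intr <- Filter(function(i) i$cls == "intron_centered", g2$isoforms)
  expect_length(intr, 2)  # introns = exons - 1
  spans <- t(vapply(intr, isoform_span, numeric(2)))
  expect_true(any(spans[, 1] == 0 & spans[, 2] == 300))
  expect_true(any(spans[, 1] == 200 & spans[, 2] == 500))
})

test_that("intron-isoform count equals exons - 1 across simulated genes", {
  genes <- gen_gene_models(30, seed = 4)
  aug <- add_intron_isoforms(genes)
  for (g in unclass(aug)) {
    spl <- Filter(function(i) i$cls == "spliced", g$isoforms)[[1]]
    intr <- Filter(function(i) i$cls == "intron_centered", g$isoforms)
    # duplicates collapse, but a single isoform per gene has none
    expect_length(intr, nrow(spl$exons) - 1)
  }
})

test_that("weighted gene attributes average isoforms by FPKM", {
  g <- gene_model("g", "chr1", "+", "mRNA", list(
    isoform("a", rbind(c(0, 1000))),
    isoform("b", rbind(c(0, 1500), c(2000, 3500)))))
  expect_equal(weighted_gene_attribute(g, c(a = 3, b = 1), "length"), 1500)
  expect_equal(weighted_gene_attribute(g, c(a = 1, b = 1), "length"), 2000)
  expect_equal(weighted_gene_attribute(g, c(a = 0, b = 0), "length"), 2000)
  expect_equal(weighted_gene_attribute(g, c(a = 1, b = 3), "exon_count"),
               1.75)
  one <- gene_model("g1", "chr1", "+", "mRNA",
                    list(isoform("x", rbind(c(0, 2000)))))
  expect_equal(weighted_gene_attribute(one, c(x = 5), "length"), 2000)
  expect_error(weighted_gene_attribute(g, c(a = 1, b = 1), "gc"))
})

test_that("exonic contribution splits gene FPKM between spliced and pre-RNA", {
  g <- add_prerna_isoforms(gene_model("g", "chr1", "+", "mRNA",
                                      list(isoform("t", rbind(c(0, 1000))))))
  pre_id <- names(Filter(function(i) i$cls == "preRNA", g$isoforms))
  fpkm <- c(t = 1, 3); names(fpkm)[2] <- pre_id
  expect_equal(exonic_contribution(g, fpkm), 25)
  expect_equal(exonic_contribution(g, fpkm * 17),
               exonic_contribution(g, fpkm))  # scale invariance
  all_spliced <- c(t = 4, 0); names(all_spliced)[2] <- pre_id
  expect_equal(exonic_contribution(g, all_spliced), 100)
  zero <- c(t = 0, 0); names(zero)[2] <- pre_id
  expect_true(is.na(exonic_contribution(g, zero)))
  expect_error(exonic_contribution(toy_gene(), c(gX.t1 = 1, gX.t2 = 1)),
               "pre-RNA")
})

test_that("simulated intron fraction is recovered as pre-RNA FPKM share", {
  genes <- gen_gene_models(300, seed = 8)
  spec <- binding_spec("P", intron_fraction = 0.9, noise_sd = 0.2)
  expm <- gen_experiment(genes, list(spec), n_reps = 2, seed = 9)
  ip <- expm$samples$sample[expm$samples$role == "fRIP"]
  fpkm <- rowMeans(expm$fpkm[, ip])
  aug <- unclass(expm$genes)
  contrib <- vapply(aug, exonic_contribution, numeric(1),
                    isoform_fpkm = fpkm)
  expect_equal(mean(contrib, na.rm = TRUE), 10, tolerance = 0.15)

  spec5 <- binding_spec("P", intron_fraction = 0.5, noise_sd = 0.2)
  expm5 <- gen_experiment(genes, list(spec5), n_reps = 2, seed = 9)
  fpkm5 <- rowMeans(expm5$fpkm[, ip])
  contrib5 <- vapply(unclass(expm5$genes), exonic_contribution, numeric(1),
                     isoform_fpkm = fpkm5)
  expect_equal(mean(contrib5, na.rm = TRUE), 50, tolerance = 0.1)
})
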