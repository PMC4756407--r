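test_that("hierarchical clustering groups replicate columns by protein", {
  set.seed(5)
  sig_a <- rnorm(80); sig_b <- rnorm(80)
  m <- cbind(a1 = sig_a + rnorm(80, 0, 0.3), a2 = sig_a + rnorm(80, 0, 0.3),
             a3 = sig_a + rnorm(80, 0, 0.3), b1 = sig_b + rnorm(80, 0, 0.3),
             b2 = sig_b + rnorm(80, 0, 0.3), b3 = sig_b + rnorm(80, 0, 0.3))
  hc <- hierarchical_cluster(m)
  grp <- stats::cutree(hc$col_tree, k = 2)
  expect_length(unique(grp[1:3]), 1)
  expect_length(unique(grp[4:6]), 1)
  expect_false(grp[1] == grp[4])
})

test_that("identical rows merge first at height zero", {
  set.seed(6)
  m <- matrix(rnorm(40), 10, 4)
  m[2, ] <- m[1, ]
  hc <- hierarchical_cluster(m)
  expect_equal(hc$row_tree$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(hc$row_tree$merge[1, ]), c(1, 2))
})

test_that("row clustering is invariant to column permutation", {
  set.seed(7)
  m <- matrix(rnorm(60), 12, 5)
  h1 <- hierarchical_cluster(m)
  h2 <- hierarchical_cluster(m[, c(3, 1, 5, 2, 4)])
  expect_equal(h1$row_tree$height, h2$row_tree$height)
  expect_equal(stats::cophenetic(h1$row_tree), stats::cophenetic(h2$row_tree))
})

test_that("zero-variance rows get unit distance instead of NA", {
  m <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(2, 1, 4, 3))
  expect_silent(hc <- hierarchical_cluster(m))
  d <- as.matrix(fripflow:::pearson_distance(m))
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "a"], 0)
})

test_that("k-medoids recovers well-separated blobs and handles edge cases", {
  set.seed(8)
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  m <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60, 0, 0.5), 20, 3), 2, centers[k, ], "+")))
  rownames(m) <- paste0("g", 1:60)
  km <- kmedoids_cluster(m, k = 3, seed = 1)
  truth <- rep(1:3, each = 20)
  expect_equal(length(unique(km$cluster)), 3)
  # perfect recovery: each found cluster is pure and complete (ARI = 1)
  expect_true(all(apply(table(truth, km$cluster) > 0, 1, sum) == 1))

  one <- kmedoids_cluster(m[1:5, ], k = 1, seed = 1)
  expect_true(all(one$cluster == 1))

  dup <- kmedoids_cluster(rbind(m, m), k = 3, seed = 1)
  expect_equal(unname(dup$cluster[1:60]), unname(dup$cluster[61:120]))

  expect_error(kmedoids_cluster(m, k = 0), "positive")
  expect_error(kmedoids_cluster(m, k = 60), "smaller")
})

test_that("specificity score matches its definition and symmetries", {
  for (len in 2:6) {
    onehot <- numeric(len); onehot[sample(len, 1)] <- 1
    expect_equal(specificity_score(onehot), 1)
  }
  expect_equal(specificity_score(c(1, 1)), 0.4421, tolerance = 1e-4)
  v <- c(4, 1, 0, 2.5)
  expect_equal(specificity_score(v), specificity_score(rev(v)))
  expect_equal(specificity_score(v), specificity_score(v * 10))
  expect_true(is.na(specificity_score(c(0, 0, 0))))
  expect_error(specificity_score(c(-1, 2)), "non-negative")
  expect_error(specificity_score(5), "length")
})

test_that("specificity orders one-hot-dominated sets above diffuse sets", {
  set.seed(9)
  diffuse <- matrix(rgamma(300 * 6, 2, 1), ncol = 6)        # mRNA-like
  sharp <- t(vapply(1:300, function(i) {
    v <- rgamma(6, 0.3, 1); v[sample(6, 1)] <- v[sample(6, 1)] + 5; v
  }, numeric(6)))                                            # lncRNA-like
  expect_gt(median(specificity_score(sharp)),
            median(specificity_score(diffuse)))
})

test_that("abundance matching reproduces the target distribution", {
  set.seed(10)
  cand <- rlnorm(4000, 1, 1)
  target <- rlnorm(400, 0, 1)   # shifted one decade down
  idx <- suppressWarnings(match_abundance_sample(cand, target, seed = 2))
  expect_gt(length(idx), 50)
  expect_lt(abs(mean(log10(cand[idx])) - mean(log10(target))), 0.15)
  ks <- suppressWarnings(stats::ks.test(log10(cand[idx]), log10(target)))
  expect_gt(ks$p.value, 0.05)

  # identical pools: everything is retained
  same <- match_abundance_sample(cand, cand, seed = 3)
  expect_equal(length(same), length(cand))

  expect_identical(suppressWarnings(match_abundance_sample(cand, target,
                                                           seed = 4)),
                   suppressWarnings(match_abundance_sample(cand, target,
                                                           seed = 4)))
  expect_warning(match_abundance_sample(rlnorm(100, 3, 0.1),
                                        c(rlnorm(50, 3, 0.1), 0.001)),
                 "dropped")
})

test_that("Mann-Whitney Z follows its sign convention and symmetries", {
  set.seed(11)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(compare_distributions(x, x)$Z, 0)
  ab <- compare_distributions(x, y); ba <- compare_distributions(y, x)
  expect_equal(ab$Z, -ba$Z)
  expect_equal(compare_distributions(rep(1, 10), rep(1, 12))$Z, 0)
  up <- compare_distributions(rnorm(40, 2), rnorm(40, 0))
  expect_gt(up$Z, 3)
})

test_that("Mann-Whitney p agrees with exact enumeration for small samples", {
  set.seed(12)
  for (sizes in list(c(8, 8), c(9, 7), c(8, 10))) {
    a <- rnorm(sizes[1]); b <- rnorm(sizes[2], 0.8)
    p_apx <- suppressWarnings(compare_distributions(a, b)$p)
    expect_lt(abs(p_apx - exact_mw_p(a, b)), 0.01)
  }
  # with ties
  a <- c(1, 2, 2, 3, 4, 4, 5, 6); b <- c(2, 3, 3, 4, 5, 6, 6, 7)
  expect_lt(abs(compare_distributions(a, b)$p - exact_mw_p(a, b)), 0.01)
  # tie-free n = 12 per side against the exact Wilcoxon distribution
  a <- qnorm((1:12) / 13); b <- qnorm((1:12) / 13) + 0.5
  r <- compare_distributions(a, b)
  u_all <- 0:(12 * 12)
  p_exact <- sum(dwilcox(u_all, 12, 12)[abs(u_all - 72) >= abs(r$U - 72)])
  expect_lt(abs(r$p - p_exact), 0.01)
})

test_that("metagene profiles report positional bias correctly", {
  flat <- replicate(30, rep(5, 400), simplify = FALSE)
  mp <- metagene_profile(flat, n_bins = 100)
  expect_equal(mp$bias_index, 0)
  expect_true(all(abs(mp$profile$mean_coverage - 1) < 1e-12))

  skew <- replicate(30, seq(1, 9, length.out = 400), simplify = FALSE)
  mp3 <- metagene_profile(skew, n_bins = 100)
  expect_gt(mp3$bias_index, 1)
  mp5 <- metagene_profile(lapply(skew, rev), n_bins = 100)
  expect_equal(mp5$bias_index, -mp3$bias_index, tolerance = 1e-9)

  withzero <- c(flat, list(rep(0, 100)))
  mpz <- metagene_profile(withzero)
  expect_equal(mpz$n_excluded, 1)
  expect_error(metagene_profile(flat, n_bins = 5), "n_bins")
})
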