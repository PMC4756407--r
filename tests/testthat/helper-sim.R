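# Shared fixture builders. Everything is generated in code at test time.

# A tiny hand-built two-isoform gene for annotation-augmentation tests.
toy_gene <- function() {
  gene_model("gX", chrom = "chr1", strand = "+", biotype = "mRNA",
             isoforms = list(
               isoform("gX.t1", rbind(c(1000, 1500), c(2000, 2500),
                                      c(4500, 5000))),
               isoform("gX.t2", rbind(c(1000, 1500), c(5500, 6000)))))
}

# Simulate one protein and run the enrichment path end to end; returns the
# enrichment table aligned with per-gene covariates.
quick_enrichment <- function(n_genes, spec, n_reps = 2, seed = 1,
                             sequences = NULL, ...) {
  genes <- gen_gene_models(n_genes, seed = seed)
  expm <- gen_experiment(genes, list(spec), sequences = sequences,
                         n_reps = n_reps, seed = seed + 1000, ...)
  gm <- gene_matrices(expm)
  input <- expm$samples$sample[expm$samples$role == "input"]
  ip <- expm$samples$sample[expm$samples$role == "fRIP"]
  fe <- effective_gene_fpkm(expm)
  res <- test_enrichment(gm$counts[, ip, drop = FALSE],
                         gm$counts[, input, drop = FALSE],
                         ip_fpkm = fe[, ip, drop = FALSE],
                         input_fpkm = fe[, input, drop = FALSE])
  covs <- expm$covariates[match(rownames(gm$counts),
                                expm$covariates$gene_id), ]
  truth <- expm$truth[match(rownames(gm$counts), expm$truth$gene_id), ]
  list(res = res, covs = covs, truth = truth, expm = expm, genes = genes,
       fpkm = fe, ip = ip, input = input, counts = gm$counts)
}

# Brute-force Jensen-Shannon specificity (independent of the implementation
# in R/profiles.R): explicit entropy sums over all one-hot references.
brute_specificity <- function(v) {
  p <- v / sum(v)
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  best <- Inf
  for (i in seq_along(p)) {
    e <- numeric(length(p)); e[i] <- 1
    m <- (p + e) / 2
    jsd <- H(m) - (H(p) + H(e)) / 2
    best <- min(best, sqrt(max(jsd, 0)))
  }
  1 - best
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (handles ties); feasible for small samples.
exact_mw_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  mU <- na * length(b) / 2
  obs <- abs(sum(r[seq_len(na)]) - na * (na + 1) / 2 - mU)
  idx <- utils::combn(length(pooled), na)
  u <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
  mean(abs(u - mU) >= obs - 1e-9)
}

# Spearman rho by the textbook rank formula (tie-free inputs only).
brute_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
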