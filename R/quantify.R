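#' Fragments per kilobase per million mapped fragments
#'
#' @param fragments Non-negative fragment counts per feature.
#' @param feature_length Feature lengths in nt (> 0).
#' @param total_fragments Total mapped fragments in the library (> 0).
#' @return Numeric FPKM vector.
#' @export
compute_fpkm <- function(fragments, feature_length, total_fragments) {
  if (any(feature_length <= 0)) stop("feature_length must be > 0")
  if (length(total_fragments) != 1 || total_fragments <= 0)
    stop("total_fragments must be a single positive count")
  if (any(fragments < 0)) stop("fragments must be non-negative")
  fragments / (feature_length / 1000) / (total_fragments / 1e6)
}

#' Log2 fold change with an FPKM pseudocount
#'
#' `log2((fpkm_ip + pseudocount) / (fpkm_input + pseudocount))`. A
#' pseudocount of 1 FPKM stabilises ratios for low-abundance genes.
#'
#' @param fpkm_ip,fpkm_input Non-negative FPKM values (vectorized).
#' @param pseudocount FPKM pseudocount (>= 0, default 1).
#' @return Numeric log2 ratios.
#' @export
log2_fold_change <- function(fpkm_ip, fpkm_input, pseudocount = 1) {
  if (length(pseudocount) != 1 || pseudocount < 0)
    stop("pseudocount must be a single non-negative value")
  if (any(fpkm_ip < 0) || any(fpkm_input < 0))
    stop("FPKM values must be non-negative")
  log2((fpkm_ip + pseudocount) / (fpkm_input + pseudocount))
}

# Pooled method-of-moments NB dispersion from size-normalized counts.
# Per-condition variances isolate biological/technical spread from real
# enrichment differences. Solves v = m + phi * m^2 across genes by
# iteratively reweighted least squares: the sampling variance of a per-gene
# variance estimate scales with (m + phi m^2)^2, so weighting by its inverse
# equalizes gene contributions instead of letting the largest genes dominate.
mom_dispersion <- function(norm_counts, group) {
  v <- 0; dfs <- 0
  for (g in unique(group)) {
    cols <- which(group == g)
    if (length(cols) < 2) next
    vg <- apply(norm_counts[, cols, drop = FALSE], 1, stats::var)
    v <- v + vg * (length(cols) - 1)
    dfs <- dfs + (length(cols) - 1)
  }
  if (dfs == 0) return(NA_real_)
  v <- v / dfs
  m <- rowMeans(norm_counts)
  ok <- is.finite(v) & m > 0
  v <- v[ok]; m <- m[ok]
  phi <- max(sum(v - m) / sum(m^2), 1e-4)
  for (it in 1:3) {
    w <- 1 / (m + phi * m^2)^2
    phi <- max(sum(w * (v - m) * m^2) / sum(w * m^4), 1e-4)
  }
  phi
}

#' Effective library sizes corrected for composition bias
#'
#' Library totals rescaled by edgeR's TMM normalization factors. Raw
#' per-million scaling is biased when the libraries differ in composition
#' (an IP library spends a large share of its fragments on long unspliced
#' isoforms); FPKM computed against effective sizes removes the resulting
#' global shift in fold changes.
#'
#' @param counts Feature x sample count matrix.
#' @param sizes Raw library totals (default column sums).
#' @return Numeric vector of effective library sizes.
#' @export
effective_library_sizes <- function(counts, sizes = colSums(counts)) {
  nf <- edgeR::calcNormFactors(as.matrix(counts), lib.size = sizes)
  sizes * nf
}

#' Replicate-aware negative-binomial enrichment test
#'
#' Tests each gene for fRIP/input enrichment or depletion with a two-sided
#' negative-binomial likelihood-ratio test on size-normalized counts, using a
#' single method-of-moments dispersion pooled across genes (estimated from
#' within-condition variances, so true enrichment does not inflate it). The
#' GLM fit is delegated to \pkg{edgeR} at the pooled
#' dispersion. Genes below the minimum-expression filter (FPKM below
#' `min_fpkm` in every sample, when `lengths` are supplied; otherwise
#' all-zero genes) are flagged untested and excluded from multiple-testing
#' correction.
#'
#' @param ip_counts,input_counts Gene x replicate count matrices with
#'   matching row order (rownames = gene ids).
#' @param ip_sizes,input_sizes Library totals per replicate (default column
#'   sums).
#' @param lengths Optional per-gene feature lengths (nt) enabling the
#'   FPKM-based testability filter and FPKM-based fold changes; FPKM is
#'   computed against TMM effective library sizes (see
#'   [effective_library_sizes()]).
#' @param min_fpkm Testability threshold: FPKM >= `min_fpkm` in at least one
#'   sample.
#' @param pseudocount FPKM pseudocount for the reported log2 fold change.
#' @param ip_fpkm,input_fpkm Optional precomputed gene x replicate FPKM
#'   matrices (e.g. isoform-level FPKM summed per gene); when supplied they
#'   define the testability filter and the reported fold change instead of
#'   the length-based internal computation.
#' @return data.frame(gene_id, log2fc, p, q, tested); `p`/`q` are `NA` for
#'   untested genes.
#' @export
test_enrichment <- function(ip_counts, input_counts,
                            ip_sizes = colSums(ip_counts),
                            input_sizes = colSums(input_counts),
                            lengths = NULL, min_fpkm = 1, pseudocount = 1,
                            ip_fpkm = NULL, input_fpkm = NULL) {
  ip_counts <- as.matrix(ip_counts)
  input_counts <- as.matrix(input_counts)
  if (nrow(ip_counts) != nrow(input_counts))
    stop("ip_counts and input_counts must cover the same genes")
  if (ncol(ip_counts) < 1 || ncol(input_counts) < 1)
    stop("need at least one replicate on each side")
  n <- nrow(ip_counts)
  gene_id <- rownames(ip_counts)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(n))
  counts <- cbind(input_counts, ip_counts)
  group <- c(rep("input", ncol(input_counts)), rep("ip", ncol(ip_counts)))
  sizes <- c(input_sizes, ip_sizes)
  if (any(sizes <= 0)) stop("library totals must be positive")

  if (!is.null(ip_fpkm) && !is.null(input_fpkm)) {
    ip_fpkm <- as.matrix(ip_fpkm); input_fpkm <- as.matrix(input_fpkm)
    if (nrow(ip_fpkm) != n || nrow(input_fpkm) != n)
      stop("FPKM matrices must cover the same genes as the counts")
    tested <- pmax(apply(ip_fpkm, 1, max), apply(input_fpkm, 1, max)) >=
      min_fpkm
    mean_in <- rowMeans(input_fpkm)
    mean_ip <- rowMeans(ip_fpkm)
  } else if (!is.null(lengths)) {
    if (length(lengths) != n) stop("lengths must match the gene count")
    eff <- effective_library_sizes(counts, sizes)
    fpkm <- vapply(seq_len(ncol(counts)), function(j)
      compute_fpkm(counts[, j], lengths, eff[j]), numeric(n))
    tested <- apply(fpkm, 1, max) >= min_fpkm
    mean_in <- rowMeans(fpkm[, group == "input", drop = FALSE])
    mean_ip <- rowMeans(fpkm[, group == "ip", drop = FALSE])
  } else {
    norm_all <- sweep(counts, 2, sizes / mean(sizes), "/")
    tested <- rowSums(counts) > 0
    mean_in <- rowMeans(norm_all[, group == "input", drop = FALSE])
    mean_ip <- rowMeans(norm_all[, group == "ip", drop = FALSE])
  }
  tested <- tested & rowSums(counts) > 0
  log2fc <- log2_fold_change(mean_ip, mean_in, pseudocount)

  p <- rep(NA_real_, n)
  if (any(tested)) {
    sub <- counts[tested, , drop = FALSE]
    norm <- sweep(sub, 2, sizes / mean(sizes), "/")
    phi <- mom_dispersion(norm, group)
    if (is.na(phi)) {
      warning("no condition has >= 2 replicates; using fallback dispersion 0.1")
      phi <- 0.1
    }
    y <- edgeR::DGEList(counts = sub, group = factor(group,
                                                     levels = c("input", "ip")),
                        lib.size = sizes)
    y <- edgeR::calcNormFactors(y)
    design <- stats::model.matrix(~y$samples$group)
    fit <- edgeR::glmFit(y, design, dispersion = phi)
    p[tested] <- edgeR::glmLRT(fit, coef = 2)$table$PValue
  }
  q <- rep(NA_real_, n)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(gene_id = gene_id, log2fc = log2fc, p = p, q = q,
             tested = tested, stringsAsFactors = FALSE)
}

#' Per-replicate linear fold changes over the mean input
#'
#' @param ip_fpkm Gene x replicate FPKM matrix for the IP library.
#' @param input_fpkm Gene x replicate FPKM matrix for the input library.
#' @param pseudocount FPKM pseudocount.
#' @return Gene x replicate matrix of linear fold changes.
#' @export
replicate_fold_changes <- function(ip_fpkm, input_fpkm, pseudocount = 1) {
  ip_fpkm <- as.matrix(ip_fpkm)
  base <- rowMeans(as.matrix(input_fpkm)) + pseudocount
  sweep(ip_fpkm + pseudocount, 1, base, "/")
}

#' Call bound genes
#'
#' A gene is bound when it is significantly enriched (BH q below
#' `q_threshold`) and enriched at greater than `fold_threshold`-fold over
#' input in at least one replicate.
#'
#' @param enrichment Output of [test_enrichment()].
#' @param per_replicate_fc Gene x replicate matrix of linear fold changes
#'   (see [replicate_fold_changes()]), rows aligned with `enrichment`.
#' @param q_threshold Significance threshold on BH q-values.
#' @param fold_threshold Linear fold-change threshold.
#' @return Logical vector of bound flags.
#' @export
call_bound <- function(enrichment, per_replicate_fc, q_threshold = 0.05,
                       fold_threshold = 2) {
  fc <- as.matrix(per_replicate_fc)
  if (nrow(fc) != nrow(enrichment))
    stop("per_replicate_fc rows must align with the enrichment table")
  sig <- enrichment$tested & !is.na(enrichment$q) &
    enrichment$q < q_threshold
  sig & apply(fc > fold_threshold, 1, any)
}

#' Classify genes as nuclear, cytoplasmic or neither
#'
#' Applies the enrichment test to nuclear versus whole-cell libraries with
#' the same significance and fold-change rule used for bound calls; the sign
#' of the change gives the direction.
#'
#' @param nuclear_counts,whole_counts Gene x replicate count matrices.
#' @param nuclear_sizes,whole_sizes Library totals.
#' @param lengths Per-gene feature lengths (nt), for FPKM.
#' @param q_threshold,fold_threshold,pseudocount As in [call_bound()].
#' @return Factor with levels nuclear, cytoplasmic, neither.
#' @export
localization_classes <- function(nuclear_counts, whole_counts,
                                 nuclear_sizes = colSums(nuclear_counts),
                                 whole_sizes = colSums(whole_counts),
                                 lengths = NULL, q_threshold = 0.05,
                                 fold_threshold = 2, pseudocount = 1) {
  res <- test_enrichment(nuclear_counts, whole_counts,
                         ip_sizes = nuclear_sizes, input_sizes = whole_sizes,
                         lengths = lengths, pseudocount = pseudocount)
  if (!is.null(lengths)) {
    nf <- vapply(seq_len(ncol(nuclear_counts)), function(j)
      compute_fpkm(nuclear_counts[, j], lengths, nuclear_sizes[j]),
      numeric(nrow(res)))
    wf <- vapply(seq_len(ncol(whole_counts)), function(j)
      compute_fpkm(whole_counts[, j], lengths, whole_sizes[j]),
      numeric(nrow(res)))
  } else {
    nf <- sweep(as.matrix(nuclear_counts), 2,
                nuclear_sizes / mean(c(nuclear_sizes, whole_sizes)), "/")
    wf <- sweep(as.matrix(whole_counts), 2,
                whole_sizes / mean(c(nuclear_sizes, whole_sizes)), "/")
  }
  up <- call_bound(res, replicate_fold_changes(nf, wf, pseudocount),
                   q_threshold, fold_threshold)
  down <- call_bound(data.frame(res[c("gene_id", "p", "q", "tested")],
                                log2fc = -res$log2fc),
                     replicate_fold_changes(wf, nf, pseudocount),
                     q_threshold, fold_threshold)
  factor(ifelse(up, "nuclear", ifelse(down, "cytoplasmic", "neither")),
         levels = c("nuclear", "cytoplasmic", "neither"))
}
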