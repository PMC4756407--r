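pearson_distance <- function(m) {
  cc <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - cc
  # zero-variance rows have undefined correlation; define their distance to
  # everything as 1 (self-distance stays 0)
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchically cluster an enrichment profile matrix
#'
#' Rows (genes) and columns (samples) are clustered with Pearson correlation
#' distance (1 - r) and Ward's agglomerative method. Zero-variance rows or
#' columns get distance 1 to everything.
#'
#' @param m Numeric matrix of log2 fold changes (genes x samples), at least
#'   2 x 2, finite values.
#' @return List with `row_order`, `col_order` (integer orderings) and
#'   `row_tree`, `col_tree` (`hclust` objects).
#' @export
hierarchical_cluster <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  if (!all(is.finite(m))) stop("profile matrix must be finite")
  rt <- stats::hclust(pearson_distance(m), method = "ward.D2")
  ct <- stats::hclust(pearson_distance(t(m)), method = "ward.D2")
  list(row_order = rt$order, col_order = ct$order,
       row_tree = rt, col_tree = ct)
}

#' Partition genes by k-medoid clustering of enrichment profiles
#'
#' PAM (partitioning around medoids) with Euclidean distance, run from the
#' default build initialization plus `n_restarts` seeded random medoid
#' starts, keeping the solution with the lowest objective. Intended for the
#' bound-gene profile matrix.
#'
#' @param m Numeric matrix (genes x samples).
#' @param k Number of clusters (1 <= k < nrow(m)).
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of random-start repetitions.
#' @return List with `cluster` (named integer vector), `medoids` (row
#'   indices) and `objective`.
#' @export
kmedoids_cluster <- function(m, k = 10, seed = 1, n_restarts = 10) {
  m <- as.matrix(m)
  if (k <= 0 || k != round(k)) stop("k must be a positive integer")
  if (k >= nrow(m)) stop("k must be smaller than the number of rows")
  best <- cluster::pam(m, k, metric = "euclidean")
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      start <- sample.int(nrow(m), k)
      fit <- cluster::pam(m, k, metric = "euclidean", medoids = start)
      if (fit$objective["swap"] < best$objective["swap"]) best <- fit
    }
  })
  cl <- best$clustering
  names(cl) <- rownames(m)
  list(cluster = cl, medoids = best$id.med,
       objective = unname(best$objective["swap"]))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

js_distance <- function(p, q) {
  m <- (p + q) / 2
  jsd <- entropy_bits(m) - (entropy_bits(p) + entropy_bits(q)) / 2
  sqrt(max(jsd, 0))
}

#' Jensen-Shannon binding specificity score
#'
#' Normalizes a non-negative binding profile over proteins to a probability
#' vector p and returns `1 - min_i JSdist(p, e_i)`, where `e_i` is the
#' one-hot profile concentrated on protein i and JSdist is the square root
#' of the base-2 Jensen-Shannon divergence. The score ranges from 0 to 1;
#' 1 means the transcript associates with a single protein. Negative log2
#' fold changes indicate depletion rather than binding, so profiles should
#' be linearized first (e.g. `pmax(log2fc, 0)`; see
#' [linearize_enrichment()]).
#'
#' @param profile Non-negative numeric vector (length >= 2) over proteins,
#'   or a matrix with one profile per row.
#' @return Score(s) in `[0, 1]`; `NA_real_` for all-zero profiles.
#' @export
specificity_score <- function(profile) {
  if (is.matrix(profile) || is.data.frame(profile))
    return(apply(as.matrix(profile), 1, specificity_score))
  if (length(profile) < 2) stop("profile must have length >= 2")
  if (any(profile < 0)) stop("profile must be non-negative")
  s <- sum(profile)
  if (s == 0) return(NA_real_)
  p <- profile / s
  d <- vapply(seq_along(p), function(i) {
    e <- numeric(length(p)); e[i] <- 1
    js_distance(p, e)
  }, numeric(1))
  1 - min(d)
}

#' Clamp log2 enrichment at zero for specificity profiles
#' @param log2fc Numeric vector/matrix of log2 fold changes.
#' @return `pmax(log2fc, 0)`.
#' @export
linearize_enrichment <- function(log2fc) pmax(log2fc, 0)

#' Sample candidates to match a target abundance distribution
#'
#' Stratified sampling on log10 FPKM bins: candidates are drawn so that the
#' sampled bin frequencies match the target's, at the largest sample size
#' the candidate pool supports. Used to compare mRNAs against lncRNAs
#' without abundance confounding.
#'
#' @param candidate_fpkms,target_fpkms Positive FPKM vectors.
#' @param seed Integer seed.
#' @param n_bins Number of equal-width log10 FPKM bins over the combined
#'   range.
#' @return Integer indices into `candidate_fpkms`.
#' @export
match_abundance_sample <- function(candidate_fpkms, target_fpkms, seed = 1,
                                   n_bins = 20) {
  if (any(candidate_fpkms <= 0) || any(target_fpkms <= 0))
    stop("FPKM values must be positive")
  lc <- log10(candidate_fpkms)
  lt <- log10(target_fpkms)
  br <- seq(min(c(lc, lt)), max(c(lc, lt)), length.out = n_bins + 1)
  br[1] <- br[1] - 1e-9; br[n_bins + 1] <- br[n_bins + 1] + 1e-9
  cb <- findInterval(lc, br, rightmost.closed = TRUE)
  tb <- findInterval(lt, br, rightmost.closed = TRUE)
  t_n <- tabulate(tb, n_bins)
  c_n <- tabulate(cb, n_bins)
  empty <- t_n > 0 & c_n == 0
  if (any(empty)) {
    warning(sum(t_n[empty]),
            " target observations fall in bins with no candidates; ",
            "their mass is dropped")
    t_n[empty] <- 0
  }
  tot <- sum(t_n)
  if (tot == 0) stop("no target mass overlaps the candidate range")
  nz <- which(t_n > 0)
  n_max <- floor(min(c_n[nz] * tot / t_n[nz]))
  take <- floor(n_max * t_n / tot)
  with_seed(seed, {
    idx <- integer(0)
    for (b in nz) {
      pool <- which(cb == b)
      idx <- c(idx, pool[sample.int(length(pool), min(take[b], length(pool)))])
    }
    sort(idx)
  })
}

#' Mann-Whitney U comparison of two fold-change distributions
#'
#' The Z score is the tie-corrected normal approximation; its sign
#' convention is Z > 0 when `fc_a` is stochastically larger than `fc_b`, and
#' all-tied data give Z = 0. The two-sided p-value is exact for small
#' samples: via the Wilcoxon null distribution when tie-free (both sizes
#' below 50, as in [stats::wilcox.test()]) or by full enumeration of group
#' assignments when tied and enumeration is feasible; larger samples use the
#' continuity-corrected normal approximation.
#'
#' @param fc_a,fc_b Numeric vectors (each length >= 8 for the approximation
#'   to be trustworthy; smaller inputs are allowed with a warning).
#' @return List with `U`, `Z`, `p`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(fc_a, fc_b) {
  fc_a <- fc_a[is.finite(fc_a)]
  fc_b <- fc_b[is.finite(fc_b)]
  na <- length(fc_a); nb <- length(fc_b)
  if (na < 8 || nb < 8)
    warning("fewer than 8 observations on one side; ",
            "normal approximation may be poor")
  r <- rank(c(fc_a, fc_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mU <- na * nb / 2
  N <- na + nb
  ties <- table(c(fc_a, fc_b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  s2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (s2 <= 0) return(list(U = U, Z = 0, p = 1, n_a = na, n_b = nb))
  Z <- (U - mU) / sqrt(s2)
  no_ties <- tie_term == 0
  if (no_ties && na < 50 && nb < 50) {
    u_all <- 0:(na * nb)
    p <- sum(stats::dwilcox(u_all, na, nb)[abs(u_all - mU) >=
                                             abs(U - mU) - 1e-9])
  } else if (choose(N, na) <= 1e5) {
    # tied small samples: exact permutation by full enumeration
    idx <- utils::combn(N, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mU) >= abs(U - mU) - 1e-9)
  } else {
    # continuity-corrected p; Z itself stays uncorrected so that swapping
    # the two samples negates it exactly
    p <- if (abs(U - mU) <= 0.5) 1 else
      min(2 * stats::pnorm(-(abs(U - mU) - 0.5) / sqrt(s2)), 1)
  }
  list(U = U, Z = Z, p = p, n_a = na, n_b = nb)
}

#' Positional metagene binding profile
#'
#' Each transcript's per-base coverage (5' to 3') is rescaled to unit mean,
#' binned into `n_bins` positional bins and averaged over transcripts.
#' The bias index is `log2(mean last-quartile bins / mean first-quartile
#' bins)`; positive values indicate 3'-weighted binding.
#'
#' @param coverages List of non-negative per-base coverage vectors in
#'   transcript orientation (strand already resolved).
#' @param n_bins Number of positional bins (>= 10).
#' @return List with `profile` (data.frame: bin, mean_coverage),
#'   `bias_index` and `n_excluded` (zero-coverage transcripts dropped).
#' @export
metagene_profile <- function(coverages, n_bins = 100) {
  if (n_bins < 10) stop("n_bins must be >= 10")
  keep <- vapply(coverages, function(v) length(v) > 0 && sum(v) > 0,
                 logical(1))
  n_excluded <- sum(!keep)
  coverages <- coverages[keep]
  if (length(coverages) == 0) stop("no transcripts with nonzero coverage")
  binned <- vapply(coverages, function(v) {
    v <- v / mean(v)
    L <- length(v)
    if (L >= n_bins) {
      bin <- ceiling(seq_len(L) * n_bins / L)
      as.vector(tapply(v, bin, mean))
    } else {
      stats::approx(seq(0, 1, length.out = L), v,
                    xout = (seq_len(n_bins) - 0.5) / n_bins, rule = 2)$y
    }
  }, numeric(n_bins))
  mc <- rowMeans(binned)
  qn <- max(floor(n_bins / 4), 1)
  first <- mean(mc[seq_len(qn)])
  last <- mean(mc[(n_bins - qn + 1):n_bins])
  list(profile = data.frame(bin = seq_len(n_bins), mean_coverage = mc),
       bias_index = log2(last / first), n_excluded = n_excluded)
}
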