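#' Smallest motif seed size rare by chance in long transcripts
#'
#' Transcripts are windowed to within a factor of sqrt(10) of the median
#' length (so all retained transcripts are within a factor of 10 of each
#' other) and the seed size is the smallest k for which a fixed k-mer is
#' expected to occur by chance in fewer than `occurrence_threshold` of
#' transcripts at the window's upper length bound `L = median * sqrt(10)`.
#' The chance-occurrence probability uses the Poisson-clumping
#' approximation `P = 1 - exp(-(L - k + 1) / 4^k)` under uniform base
#' composition.
#'
#' @param lengths Positive transcript lengths (nt).
#' @param occurrence_threshold Maximum tolerated chance-occurrence
#'   probability (default 0.01).
#' @param max_k Search bound.
#' @return Integer seed size k.
#' @export
select_seed_size <- function(lengths, occurrence_threshold = 0.01,
                             max_k = 24) {
  if (length(lengths) == 0) stop("empty length distribution")
  if (any(lengths <= 0)) stop("lengths must be positive")
  L <- stats::median(lengths) * sqrt(10)
  for (k in seq_len(max_k)) {
    p <- 1 - exp(-max(L - k + 1, 0) / 4^k)
    if (p < occurrence_threshold) return(k)
  }
  stop("no k <= ", max_k, " satisfies the threshold")
}

#' Chance occurrence probability of a fixed k-mer
#'
#' Poisson-clumping approximation `1 - exp(-(L - k + 1)/4^k)` for a sequence
#' of length `L` with uniform base composition.
#'
#' @param L Sequence length (nt).
#' @param k k-mer size.
#' @return Probability of at least one occurrence.
#' @export
kmer_chance_probability <- function(L, k) {
  1 - exp(-pmax(L - k + 1, 0) / 4^k)
}

#' Filter transcripts to a bounded length window
#'
#' `median_sqrt10` retains lengths within a factor of sqrt(10) of the median
#' (closed bounds), guaranteeing a maximum pairwise ratio of 10 among
#' retained transcripts; `fixed_400_4000` retains lengths in `[400, 4000]`
#' nt (the window appropriate for 8-mer-seeded searches).
#'
#' @param lengths Positive transcript lengths.
#' @param mode `"median_sqrt10"` or `"fixed_400_4000"`.
#' @return Logical vector: transcript retained.
#' @export
length_window_filter <- function(lengths,
                                 mode = c("median_sqrt10", "fixed_400_4000")) {
  mode <- match.arg(mode)
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (mode == "median_sqrt10") {
    med <- stats::median(lengths)
    lengths >= med / sqrt(10) & lengths <= med * sqrt(10)
  } else {
    lengths >= 400 & lengths <= 4000
  }
}

valid_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  length(chars) > 0 && all(chars %in% names(Biostrings::IUPAC_CODE_MAP))
}

as_dss <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) sequences
  else Biostrings::DNAStringSet(sequences)
}

# equal-population bin assignment of a statistic
equal_bins <- function(statistic, n_bins) {
  n <- length(statistic)
  ceiling(rank(statistic, ties.method = "first") * n_bins / n)
}

# mutual information (bits) between binary presence columns and a binned
# statistic; Npb = #present per bin (m x B), counts from n observations
mi_from_counts <- function(Npb, n_present, bin_n, n) {
  B <- length(bin_n)
  p1 <- Npb / n
  p0 <- sweep(-Npb, 2, bin_n, "+") / n
  pp <- n_present / n
  pb <- bin_n / n
  e1 <- outer(pp, pb)
  e0 <- outer(1 - pp, pb)
  xlog <- function(P, E) {
    out <- P * log2(P / E)
    out[P == 0] <- 0
    out
  }
  rowSums(xlog(p1, e1)) + rowSums(xlog(p0, e0))
}

mi_presence <- function(presence, bins, n_bins) {
  Bm <- outer(bins, seq_len(n_bins), "==") * 1
  n <- length(bins)
  if (is.null(dim(presence))) presence <- matrix(presence, ncol = 1)
  Npb <- crossprod(presence, Bm)
  mi_from_counts(Npb, colSums(presence), colSums(Bm), n)
}

iupac_supersets <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  base <- strsplit(map[[code]], "")[[1]]
  names(map)[vapply(map, function(s) {
    b <- strsplit(s, "")[[1]]
    all(base %in% b) && length(b) == length(base) + 1
  }, logical(1))]
}

generalize_motif <- function(pattern, seqs, statistic, n_bins, fold_id) {
  folds <- sort(unique(fold_id))
  fold_bins <- lapply(folds, function(f)
    equal_bins(statistic[fold_id == f], n_bins))
  score <- function(pat) {
    pres <- Biostrings::vcountPattern(pat, seqs, fixed = FALSE) > 0
    mean(vapply(seq_along(folds), function(i) {
      mi_presence((pres[fold_id == folds[i]]) * 1, fold_bins[[i]], n_bins)
    }, numeric(1)))
  }
  cur <- pattern
  cur_score <- score(cur)
  k <- nchar(pattern)
  for (step in seq_len(3 * k)) {
    best_pat <- NULL
    best_score <- cur_score
    chars <- strsplit(cur, "")[[1]]
    for (pos in seq_len(k)) {
      for (code in iupac_supersets(chars[pos])) {
        cand_chars <- chars
        cand_chars[pos] <- code
        cand <- paste(cand_chars, collapse = "")
        s <- score(cand)
        if (s > best_score + 1e-12) {
          best_score <- s
          best_pat <- cand
        }
      }
    }
    if (is.null(best_pat)) break
    cur <- best_pat
    cur_score <- best_score
  }
  cur
}

#' Mutual-information motif scan
#'
#' FIRE-style motif discovery: the per-gene enrichment statistic is
#' discretized into `n_bins` equal-population bins; every k-mer seed is
#' scored by the mutual information (bits) between its presence/absence in
#' the gene's transcript and the binned statistic. Significance comes from
#' permuting the statistic across genes: a per-seed z-score, a per-seed
#' empirical p-value, and an empirical FDR over the whole k-mer family (the
#' expected number of permuted MI values exceeding each observed MI divided
#' by the number of observed MI values exceeding it, made monotone).
#' Significant seeds are greedily generalized over
#' IUPAC degeneracies, accepting a degenerate code only while the mean MI
#' over three held-out thirds of the genes increases.
#'
#' @param sequences One transcript sequence per gene (character vector or
#'   [Biostrings::DNAStringSet]), typically the most expressed isoform.
#' @param statistic Finite per-gene enrichment statistic, aligned with
#'   `sequences`.
#' @param k_seed Seed k-mer size (>= 4; see [select_seed_size()]).
#' @param n_bins Number of equal-population statistic bins (>= 2).
#' @param n_perm Number of statistic permutations.
#' @param seed Integer seed for permutations and fold assignment.
#' @param fdr Empirical FDR threshold for calling a seed significant.
#' @param z_min Minimum permutation z-score for significance.
#' @param max_motifs Maximum number of motifs reported.
#' @param generalize Whether to IUPAC-generalize significant seeds.
#' @return data.frame (one row per reported motif, sorted by decreasing MI):
#'   pattern, seed_pattern, k, mi, z, p, q, direction, significant.
#' @export
mi_motif_scan <- function(sequences, statistic, k_seed = 7, n_bins = 3,
                          n_perm = 1000, seed = 1, fdr = 0.05, z_min = 3,
                          max_motifs = 10, generalize = TRUE) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (k_seed < 4) stop("k_seed must be >= 4")
  seqs <- as_dss(sequences)
  n <- length(seqs)
  if (n == 0) stop("no sequences")
  if (length(statistic) != n || !all(is.finite(statistic)))
    stop("statistic must be finite and aligned with sequences")

  P <- (Biostrings::oligonucleotideFrequency(seqs, width = k_seed) > 0) * 1
  bins <- equal_bins(statistic, n_bins)
  Bm <- outer(bins, seq_len(n_bins), "==") * 1
  bin_n <- colSums(Bm)
  n_present <- colSums(P)
  mi_obs <- mi_from_counts(crossprod(P, Bm), n_present, bin_n, n)

  m <- length(mi_obs)
  ord_mi <- order(mi_obs)
  os <- mi_obs[ord_mi]
  s1 <- numeric(m)
  s2 <- numeric(m)
  cnt <- numeric(m)
  exceed <- numeric(m)
  with_seed(seed, {
    for (t in seq_len(n_perm)) {
      mi_p <- mi_from_counts(crossprod(P, Bm[sample.int(n), , drop = FALSE]),
                             n_present, bin_n, n)
      s1 <- s1 + mi_p
      s2 <- s2 + mi_p^2
      cnt <- cnt + (mi_p >= mi_obs)
      # permuted MI values strictly above each observed threshold
      exceed <- exceed + (m - findInterval(os, sort(mi_p)))
    }
  })
  mu <- s1 / n_perm
  sdv <- sqrt(pmax(s2 / n_perm - mu^2, 0))
  z <- ifelse(sdv > 0, (mi_obs - mu) / sdv, 0)
  p_emp <- (1 + cnt) / (1 + n_perm)
  # empirical FDR over the whole k-mer family: expected permuted exceedances
  # at each observed MI threshold over observed exceedances, made monotone
  n_obs_ge <- m - seq_len(m) + 1
  q_sorted <- pmin(rev(cummin(rev(exceed / n_perm / n_obs_ge))), 1)
  q <- numeric(m)
  q[ord_mi] <- q_sorted

  mean_present <- as.vector(crossprod(P, statistic)) / pmax(n_present, 1)
  mean_absent <- (sum(statistic) - as.vector(crossprod(P, statistic))) /
    pmax(n - n_present, 1)
  direction <- ifelse(mean_present >= mean_absent, "enriched", "avoided")

  ord <- order(mi_obs, decreasing = TRUE)
  take <- utils::head(ord, max_motifs)
  res <- data.frame(pattern = colnames(P)[take],
                    seed_pattern = colnames(P)[take], k = k_seed,
                    mi = mi_obs[take], z = z[take], p = p_emp[take],
                    q = q[take], direction = direction[take],
                    significant = q[take] < fdr & z[take] >= z_min,
                    stringsAsFactors = FALSE)
  if (generalize && any(res$significant)) {
    fold_id <- with_seed(seed + 1L, sample(rep(1:3, length.out = n)))
    for (i in which(res$significant)) {
      gp <- generalize_motif(res$seed_pattern[i], seqs, statistic, n_bins,
                             fold_id)
      if (gp != res$seed_pattern[i]) {
        pres <- (Biostrings::vcountPattern(gp, seqs, fixed = FALSE) > 0) * 1
        res$pattern[i] <- gp
        res$mi[i] <- mi_presence(pres, bins, n_bins)
      }
    }
    res <- res[order(res$mi, decreasing = TRUE), ]
    rownames(res) <- NULL
  }
  res
}

#' Dose-response of an enrichment statistic on motif occurrences
#'
#' Counts motif occurrences per transcript (overlaps allowed, sense strand
#' only) and reports the 25th/50th/75th percentiles of the statistic for
#' genes with 0, 1, 2 and 3+ occurrences. Levels with no genes are omitted.
#'
#' @param pattern IUPAC motif.
#' @param sequences Per-gene transcript sequences.
#' @param statistic Per-gene enrichment statistic.
#' @param max_count Occurrence counts at or above this are pooled ("3+").
#' @return data.frame(occurrences, n, q25, q50, q75).
#' @export
motif_dose_response <- function(pattern, sequences, statistic,
                                max_count = 3) {
  if (!valid_iupac(pattern)) stop("invalid IUPAC pattern: ", pattern)
  seqs <- as_dss(sequences)
  if (length(statistic) != length(seqs))
    stop("statistic must be aligned with sequences")
  cnt <- Biostrings::vcountPattern(toupper(pattern), seqs, fixed = FALSE)
  lev <- pmin(cnt, max_count)
  labels <- c(as.character(seq_len(max_count) - 1L),
              paste0(max_count, "+"))
  out <- lapply(0:max_count, function(l) {
    x <- statistic[lev == l]
    if (length(x) == 0) return(NULL)
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(occurrences = labels[l + 1], n = length(x),
               q25 = qs[1], q50 = qs[2], q75 = qs[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
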