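#' Ridge regression of enrichment on k-mer composition
#'
#' Models a per-gene enrichment statistic as a linear function of k-mer
#' counts per kilobase (standardized), fit by ridge regression with the
#' penalty chosen by cross-validated mean squared error over a grid.
#' Reports, per k, the selected penalty, per-k-mer weights, and the variance
#' explained on held-out folds (which can be negative when the sequence
#' carries no signal).
#'
#' @param sequences Per-gene transcript sequences.
#' @param statistic Finite per-gene enrichment statistic.
#' @param k_range Integer k-mer sizes to fit (one model each).
#' @param alpha_grid Ridge penalty grid (glmnet lambda values).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @return Named list (`k4`, `k5`, ...) of `kmer_model` objects with fields
#'   `k`, `alpha`, `weights`, `variance_explained`, `cv_mse`.
#' @export
kmer_regression <- function(sequences, statistic, k_range = 4:7,
                            alpha_grid = 10^seq(-3, 3, length.out = 25),
                            folds = 5, seed = 1) {
  seqs <- as_dss(sequences)
  n <- length(seqs)
  if (length(statistic) != n || !all(is.finite(statistic)))
    stop("statistic must be finite and aligned with sequences")
  if (n < 10 * folds)
    stop("need at least ", 10 * folds, " genes for ", folds, "-fold CV")
  if (stats::var(statistic) == 0) stop("statistic is constant")
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  for (f in seq_len(folds)) {
    if (stats::var(statistic[fold_id == f]) == 0)
      warning("fold ", f, " has a constant statistic")
  }
  lambda <- sort(alpha_grid, decreasing = TRUE)
  kb <- Biostrings::width(seqs) / 1000
  out <- lapply(k_range, function(k) {
    X <- Biostrings::oligonucleotideFrequency(seqs, width = k) / kb
    cv <- glmnet::cv.glmnet(X, statistic, alpha = 0, lambda = lambda,
                            foldid = fold_id, standardize = TRUE)
    i <- which.min(cv$cvm)
    ve <- 1 - cv$cvm[i] / stats::var(statistic)
    w <- as.numeric(stats::coef(cv, s = cv$lambda[i]))[-1]
    names(w) <- colnames(X)
    structure(list(k = k, alpha = cv$lambda[i], weights = w,
                   variance_explained = ve, cv_mse = cv$cvm[i]),
              class = "kmer_model")
  })
  stats::setNames(out, paste0("k", k_range))
}

#' @export
print.kmer_model <- function(x, ...) {
  top <- names(sort(abs(x$weights), decreasing = TRUE))[1:3]
  cat(sprintf(
    "<kmer_model k=%d: held-out VE=%.3f, alpha=%.4g, top |weights|: %s>\n",
    x$k, x$variance_explained, x$alpha, paste(top, collapse = ", ")))
  invisible(x)
}

#' Transposable-element family association with enrichment
#'
#' For each TE family x orientation with at least `min_transcripts`
#' containing transcripts, compares the fold changes of transcripts
#' containing versus lacking the family with the Mann-Whitney Z of
#' [compare_distributions()] (Z > 0 means containing transcripts are more
#' enriched), with BH correction across tests.
#'
#' @param te_annotations BED-style data.frame with columns `gene_id`,
#'   `family`, `orientation` (transcript-relative intervals; `start`/`end`
#'   columns are allowed and ignored by the test).
#' @param fc Named per-gene fold-change vector (names = gene ids define the
#'   universe).
#' @param min_transcripts Minimum containing transcripts for a family to be
#'   tested.
#' @return data.frame(family, orientation, n_present, n_absent, U, Z, p, q);
#'   zero rows when nothing is testable.
#' @export
te_association <- function(te_annotations, fc, min_transcripts = 20) {
  need <- c("gene_id", "family", "orientation")
  if (!all(need %in% names(te_annotations)))
    stop("te_annotations must have columns: ", paste(need, collapse = ", "))
  if (is.null(names(fc))) stop("fc must be named by gene id")
  universe <- names(fc)
  combos <- unique(te_annotations[c("family", "orientation")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    fam <- combos$family[i]; ori <- combos$orientation[i]
    present <- intersect(unique(te_annotations$gene_id[
      te_annotations$family == fam & te_annotations$orientation == ori]),
      universe)
    if (length(present) < min_transcripts) next
    absent <- setdiff(universe, present)
    if (length(absent) < min_transcripts) next
    cmp <- compare_distributions(fc[present], fc[absent])
    rows[[length(rows) + 1]] <- data.frame(
      family = fam, orientation = ori, n_present = cmp$n_a,
      n_absent = cmp$n_b, U = cmp$U, Z = cmp$Z, p = cmp$p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(family = character(0), orientation = character(0),
                      n_present = integer(0), n_absent = integer(0),
                      U = numeric(0), Z = numeric(0), p = numeric(0),
                      q = numeric(0)))
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
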