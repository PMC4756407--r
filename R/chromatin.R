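#' Promoter windows around strand-aware transcription start sites
#'
#' For each spliced isoform, a window of `width` nt centered on the TSS
#' (genomic span start on `+` strand, span end on `-`), clamped at zero.
#' Emitted for audit of the promoter scoring.
#'
#' @param genes A [gene_model_set()].
#' @param width Window width in nt (default 3000).
#' @return BED-style data.frame(chrom, start, end, isoform_id, gene_id,
#'   strand), 0-based half-open.
#' @export
promoter_windows <- function(genes, width = 3000) {
  rows <- list()
  for (gene in unclass(genes)) {
    for (iso in isoforms_of_class(gene, "spliced")) {
      sp <- isoform_span(iso)
      tss <- if (gene$strand == "+") sp[1] else sp[2]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = gene$chrom, start = max(tss - width / 2, 0),
        end = tss + width / 2, isoform_id = iso$isoform_id,
        gene_id = gene$gene_id, strand = gene$strand,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-gene chromatin scores from ChIP/input region counts
#'
#' Each isoform region is scored
#' `log2((chip + eps)/chip_total) - log2((input + eps)/input_total)` with a
#' pseudocount of `eps` reads per window applied before depth normalization;
#' gene scores are the FPKM-weighted average over isoforms (unweighted when
#' all weights are zero). Pre-aggregated per-window scores such as RRBS
#' promoter methylation can be passed through the same interface by
#' supplying rates as counts with unit totals.
#'
#' @param region_counts data.frame with columns `gene_id`, `isoform_id`,
#'   `region` (e.g. promoter/body), `chip_count`, `input_count`.
#' @param chip_total,input_total Total mapped reads per experiment (> 0).
#' @param isoform_fpkm Named FPKM vector over the isoforms present.
#' @param pseudocount Reads added per window (default 1).
#' @return data.frame(gene_id, region, score).
#' @export
chip_gene_scores <- function(region_counts, chip_total, input_total,
                             isoform_fpkm, pseudocount = 1) {
  need <- c("gene_id", "isoform_id", "region", "chip_count", "input_count")
  if (!all(need %in% names(region_counts)))
    stop("region_counts must have columns: ", paste(need, collapse = ", "))
  if (chip_total <= 0 || input_total <= 0) stop("totals must be positive")
  if (anyNA(region_counts$input_count))
    stop("missing input coverage for some regions")
  rc <- region_counts
  if (!all(rc$isoform_id %in% names(isoform_fpkm)))
    stop("isoform_fpkm missing entries for some isoforms")
  rc$score <- log2((rc$chip_count + pseudocount) / chip_total) -
    log2((rc$input_count + pseudocount) / input_total)
  rc$w <- isoform_fpkm[rc$isoform_id]
  agg <- lapply(split(rc, list(rc$gene_id, rc$region), drop = TRUE),
                function(g) {
    s <- if (sum(g$w) > 0) sum(g$score * g$w) / sum(g$w) else mean(g$score)
    data.frame(gene_id = g$gene_id[1], region = g$region[1], score = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$gene_id, out$region), ]
}

lowess_curve <- function(x, y, span, iter) {
  lw <- stats::lowess(x, y, f = span, iter = iter)
  function(x0) stats::approx(lw$x, lw$y, xout = x0, rule = 2, ties = mean)$y
}

#' Abundance-normalized chromatin gap between bound and unbound genes
#'
#' Fits separate lowess regressions of chromatin score against log10 input
#' FPKM for fRIP-bound and unbound genes and integrates the difference
#' between the two curves over the empirical FPKM distribution: the gap is
#' the mean, over all genes' log10 FPKM values, of
#' `f_bound(x) - f_unbound(x)` (curves clamped to their boundary fit outside
#' the group's observed range). A permutation p-value comes from shuffling
#' the bound labels.
#'
#' @param chip_score Per-gene chromatin score.
#' @param input_fpkm Positive per-gene input FPKM.
#' @param bound Logical per-gene bound flags.
#' @param span Lowess span.
#' @param iter Lowess robustness iterations.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param min_group Minimum genes per group; below it the gap is `NA`.
#' @return List with `gap`, `p`, `n_bound`, `n_unbound`, `n_perm`.
#' @export
lowess_gap <- function(chip_score, input_fpkm, bound, span = 0.3, iter = 2,
                       n_perm = 500, seed = 1, min_group = 50) {
  ok <- is.finite(chip_score) & is.finite(input_fpkm) & input_fpkm > 0 &
    !is.na(bound)
  y <- chip_score[ok]; x <- log10(input_fpkm[ok]); b <- as.logical(bound[ok])
  nb <- sum(b); nu <- sum(!b)
  if (nb < min_group || nu < min_group)
    return(list(gap = NA_real_, p = NA_real_, n_bound = nb, n_unbound = nu,
                n_perm = 0L))
  gap_of <- function(lab) {
    fb <- lowess_curve(x[lab], y[lab], span, iter)
    fu <- lowess_curve(x[!lab], y[!lab], span, iter)
    mean(fb(x) - fu(x))
  }
  gap <- gap_of(b)
  exceed <- 0L
  with_seed(seed, {
    for (t in seq_len(n_perm)) {
      gp <- gap_of(sample(b))
      if (abs(gp) >= abs(gap)) exceed <- exceed + 1L
    }
  })
  list(gap = gap, p = (1 + exceed) / (1 + n_perm), n_bound = nb,
       n_unbound = nu, n_perm = n_perm)
}

#' Correlation between fRIP enrichment and chromatin score
#'
#' @param fc Per-gene fRIP/input fold changes.
#' @param chip_score Per-gene chromatin score.
#' @return As [attribute_correlation()].
#' @export
frip_chip_correlation <- function(fc, chip_score) {
  attribute_correlation(fc, chip_score)
}
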