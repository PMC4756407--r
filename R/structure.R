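#' Spearman correlation between enrichment and a gene attribute
#'
#' Rank correlation with tie handling; the p-value uses the asymptotic
#' approximation (ties make the exact null distribution unavailable).
#'
#' @param fc Per-gene fold changes (or any statistic).
#' @param attribute Per-gene attribute (e.g. input FPKM, length, exon
#'   count).
#' @return List with `rho`, `p`, `n`; `rho`/`p` are `NA` when either
#'   variable is constant.
#' @export
attribute_correlation <- function(fc, attribute) {
  ok <- is.finite(fc) & is.finite(attribute)
  fc <- fc[ok]; attribute <- attribute[ok]
  n <- length(fc)
  if (n < 10) stop("need at least 10 paired observations")
  if (stats::sd(attribute) == 0 || stats::sd(fc) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(stats::cor.test(fc, attribute, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Semipartial rank correlation
#'
#' Regresses `fc` on the controlled attribute `x1` (ordinary least squares
#' by default, rank-based optionally) and returns the Spearman correlation
#' of the residuals with the tested attribute `x2`. Used to disentangle
#' correlated structural covariates such as transcript length and exon
#' number.
#'
#' @param fc Response (per-gene enrichment statistic).
#' @param x1 Controlled attribute (regressed out).
#' @param x2 Tested attribute.
#' @param rank_based Regress on ranks instead of raw values.
#' @return List with `rho` (residual Spearman), `p`, `n`.
#' @export
semipartial_correlation <- function(fc, x1, x2, rank_based = FALSE) {
  ok <- is.finite(fc) & is.finite(x1) & is.finite(x2)
  fc <- fc[ok]; x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(fc)
  if (n < 30) stop("need at least 30 observations")
  if (rank_based) {
    fc <- rank(fc); x1 <- rank(x1)
  }
  fit <- stats::lm(fc ~ x1)
  if (anyNA(stats::coef(fit)))
    stop("regression on the controlled attribute is rank-deficient")
  r <- stats::residuals(fit)
  res <- attribute_correlation(r, x2)
  list(rho = res$rho, p = res$p, n = n)
}

#' Dependence of enrichment on input abundance
#'
#' Spearman correlation between the fold change and input FPKM plus a
#' locally weighted (lowess) trend of fold change against log10 FPKM,
#' evaluated on an evenly spaced grid. With fewer than `min_genes_trend`
#' genes the trend is suppressed and only the correlation is returned.
#'
#' @param fc Per-gene fold changes.
#' @param input_fpkm Positive per-gene input FPKM.
#' @param span Lowess smoother span.
#' @param grid_n Number of grid points for the trend.
#' @param min_genes_trend Minimum gene count for fitting the trend.
#' @return List with `rho`, `p`, `n` and `trend` (data.frame: log10_fpkm,
#'   fc_smooth, or `NULL`).
#' @export
fpkm_dependence <- function(fc, input_fpkm, span = 0.3, grid_n = 50,
                            min_genes_trend = 50) {
  ok <- is.finite(fc) & is.finite(input_fpkm) & input_fpkm > 0
  fc <- fc[ok]; lx <- log10(input_fpkm[ok])
  res <- attribute_correlation(fc, lx)
  trend <- NULL
  if (length(fc) >= min_genes_trend) {
    lw <- stats::lowess(lx, fc, f = span)
    grid <- seq(min(lx), max(lx), length.out = grid_n)
    trend <- data.frame(log10_fpkm = grid,
                        fc_smooth = stats::approx(lw$x, lw$y, xout = grid,
                                                  rule = 2, ties = mean)$y)
  }
  list(rho = res$rho, p = res$p, n = res$n, trend = trend)
}
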