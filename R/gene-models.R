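#' Construct an isoform
#'
#' An isoform is an ordered set of non-overlapping exon intervals on a
#' single strand. Coordinates are 0-based half-open throughout the package;
#' GTF input/output converts to and from the on-disk 1-based inclusive
#' convention.
#'
#' @param isoform_id Character scalar identifier.
#' @param exons Two-column numeric matrix (start, end), 0-based half-open.
#' @param cls Isoform class: `"spliced"` for annotated (exon-only) isoforms,
#'   `"preRNA"` for the synthetic unspliced isoform spanning the full
#'   genomic extent, `"intron_centered"` for an intron extended to include
#'   its flanking exons.
#' @return An object of class `isoform`.
#' @export
isoform <- function(isoform_id, exons,
                    cls = c("spliced", "preRNA", "intron_centered")) {
  cls <- match.arg(cls)
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("isoform '", isoform_id, "': empty or inverted exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("isoform '", isoform_id, "': overlapping exons")
  structure(list(isoform_id = as.character(isoform_id),
                 exons = exons, cls = cls),
            class = "isoform")
}

#' @export
print.isoform <- function(x, ...) {
  cat(sprintf("<isoform %s [%s], %d exon(s), %d nt>\n",
              x$isoform_id, x$cls, nrow(x$exons), isoform_length(x)))
  invisible(x)
}

#' Spliced length of an isoform (sum of exon widths, nt)
#' @param iso An `isoform`.
#' @return Integer-valued numeric scalar.
#' @export
isoform_length <- function(iso) sum(iso$exons[, 2] - iso$exons[, 1])

#' Genomic span of an isoform
#' @param iso An `isoform`.
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
isoform_span <- function(iso) c(min(iso$exons[, 1]), max(iso$exons[, 2]))

#' Construct a gene model
#'
#' @param gene_id Character scalar.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param biotype `"mRNA"` or `"lncRNA"`.
#' @param isoforms List of [isoform()] objects (at least one).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = c("+", "-"),
                       biotype = c("mRNA", "lncRNA"), isoforms) {
  strand <- match.arg(strand)
  biotype <- match.arg(biotype)
  if (length(isoforms) < 1L) stop("gene '", gene_id, "': needs >= 1 isoform")
  if (!all(vapply(isoforms, inherits, logical(1), "isoform")))
    stop("isoforms must be a list of isoform objects")
  names(isoforms) <- vapply(isoforms, `[[`, character(1), "isoform_id")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, biotype = biotype, isoforms = isoforms),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene %s (%s) %s:%s, %d isoform(s)>\n", x$gene_id, x$biotype,
              x$chrom, x$strand, length(x$isoforms)))
  invisible(x)
}

#' Bundle gene models into a set
#' @param genes List of [gene_model()] objects.
#' @return Named list of class `gene_model_set`.
#' @export
gene_model_set <- function(genes) {
  if (!all(vapply(genes, inherits, logical(1), "gene_model")))
    stop("all elements must be gene_model objects")
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(genes, class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  bt <- table(vapply(unclass(x), `[[`, character(1), "biotype"))
  cat(sprintf("<gene_model_set: %d genes (%s)>\n", length(x),
              paste(sprintf("%s %d", names(bt), bt), collapse = ", ")))
  invisible(x)
}

#' @export
`[.gene_model_set` <- function(x, i) {
  structure(unclass(x)[i], class = "gene_model_set")
}

isoforms_of_class <- function(gene, cls) {
  gene$isoforms[vapply(gene$isoforms, `[[`, character(1), "cls") == cls]
}

apply_gene_set <- function(genes, f, ...) {
  if (inherits(genes, "gene_model")) return(f(genes, ...))
  gene_model_set(lapply(unclass(genes), f, ...))
}

#' Add unspliced pre-RNA isoforms to a gene model
#'
#' For every unique (start, end) pair over a gene's spliced isoforms one
#' single-exon isoform spanning that full genomic extent is appended with
#' class `"preRNA"`. These synthetic isoforms capture intronic (unspliced
#' precursor) signal during quantification. The operation is idempotent:
#' spans already represented by a pre-RNA isoform are not duplicated.
#'
#' @param genes A `gene_model` or `gene_model_set`.
#' @return Object of the same class with pre-RNA isoforms appended.
#' @export
add_prerna_isoforms <- function(genes) {
  apply_gene_set(genes, function(gene) {
    spliced <- isoforms_of_class(gene, "spliced")
    if (length(spliced) == 0L) return(gene)
    spans <- unique(t(vapply(spliced, isoform_span, numeric(2))))
    have <- t(vapply(isoforms_of_class(gene, "preRNA"), isoform_span,
                     numeric(2)))
    new_i <- 0L
    for (r in seq_len(nrow(spans))) {
      sp <- spans[r, ]
      if (nrow(have) > 0 && any(have[, 1] == sp[1] & have[, 2] == sp[2]))
        next
      new_i <- new_i + 1L
      id <- sprintf("%s.pre%d", gene$gene_id,
                    length(isoforms_of_class(gene, "preRNA")) + new_i)
      gene$isoforms[[id]] <- isoform(id, matrix(sp, ncol = 2), cls = "preRNA")
    }
    gene
  })
}

#' Add intron-centered isoforms to a gene model
#'
#' For every intron of every spliced isoform, one single-exon isoform is
#' added covering the intron extended on both sides to include the adjacent
#' exons, i.e. spanning from the start of the upstream exon to the end of
#' the downstream exon. Duplicate spans (within a gene) are collapsed.
#' These isoforms give a higher-resolution view of intronic binding for
#' motif analysis.
#'
#' @inheritParams add_prerna_isoforms
#' @return Object of the same class with intron-centered isoforms appended.
#' @export
add_intron_isoforms <- function(genes) {
  apply_gene_set(genes, function(gene) {
    spans <- NULL
    for (iso in isoforms_of_class(gene, "spliced")) {
      n <- nrow(iso$exons)
      if (n < 2L) next
      for (j in seq_len(n - 1L))
        spans <- rbind(spans, c(iso$exons[j, 1], iso$exons[j + 1L, 2]))
    }
    if (is.null(spans)) return(gene)
    spans <- unique(spans)
    have <- t(vapply(isoforms_of_class(gene, "intron_centered"), isoform_span,
                     numeric(2)))
    k <- length(isoforms_of_class(gene, "intron_centered"))
    for (r in seq_len(nrow(spans))) {
      sp <- spans[r, ]
      if (nrow(have) > 0 && any(have[, 1] == sp[1] & have[, 2] == sp[2]))
        next
      k <- k + 1L
      id <- sprintf("%s.int%d", gene$gene_id, k)
      gene$isoforms[[id]] <- isoform(id, matrix(sp, ncol = 2),
                                     cls = "intron_centered")
    }
    gene
  })
}

#' FPKM-weighted structural attribute of a gene
#'
#' Computes the average of an isoform-level attribute over a gene's spliced
#' isoforms, weighting each isoform by its input abundance (FPKM). With all
#' weights zero the unweighted mean is returned.
#'
#' @param gene A `gene_model`.
#' @param isoform_fpkm Named numeric vector of FPKM over (at least) the
#'   gene's spliced isoforms.
#' @param attribute `"length"` (spliced length, nt) or `"exon_count"`.
#' @return Numeric scalar.
#' @export
weighted_gene_attribute <- function(gene, isoform_fpkm,
                                    attribute = c("length", "exon_count")) {
  attribute <- match.arg(attribute)
  spliced <- isoforms_of_class(gene, "spliced")
  ids <- names(spliced)
  if (!all(ids %in% names(isoform_fpkm)))
    stop("isoform_fpkm missing entries for: ",
         paste(setdiff(ids, names(isoform_fpkm)), collapse = ", "))
  w <- isoform_fpkm[ids]
  if (any(w < 0)) stop("FPKM must be non-negative")
  a <- switch(attribute,
              length = vapply(spliced, isoform_length, numeric(1)),
              exon_count = vapply(spliced, function(i) nrow(i$exons),
                                  numeric(1)))
  if (sum(w) == 0) mean(a) else sum(w * a) / sum(w)
}

#' Exonic contribution to gene abundance
#'
#' Percentage of a gene's total FPKM attributable to spliced (exon-only)
#' isoforms as opposed to unspliced pre-RNA isoforms, on an annotation
#' augmented with [add_prerna_isoforms()]. High values indicate binding (or
#' expression) dominated by mature transcripts; low values indicate
#' precursor/intronic signal.
#'
#' @param gene A `gene_model` carrying at least one pre-RNA isoform.
#' @param isoform_fpkm Named numeric FPKM over the gene's spliced and
#'   pre-RNA isoforms.
#' @return Percentage in `[0, 100]`, or `NA_real_` when the gene's total
#'   FPKM is zero.
#' @export
exonic_contribution <- function(gene, isoform_fpkm) {
  spl <- names(isoforms_of_class(gene, "spliced"))
  pre <- names(isoforms_of_class(gene, "preRNA"))
  if (length(pre) == 0L)
    stop("gene '", gene$gene_id,
         "' has no pre-RNA isoform; run add_prerna_isoforms() first")
  ids <- c(spl, pre)
  if (!all(ids %in% names(isoform_fpkm)))
    stop("isoform_fpkm missing entries for: ",
         paste(setdiff(ids, names(isoform_fpkm)), collapse = ", "))
  s <- sum(isoform_fpkm[spl])
  tot <- s + sum(isoform_fpkm[pre])
  if (tot == 0) return(NA_real_)
  100 * s / tot
}
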