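#' Read gene models from a GTF file
#'
#' Exon rows are grouped by `transcript_id` within `gene_id`. On-disk
#' coordinates are 1-based inclusive; in memory the package uses 0-based
#' half-open intervals. An `isoform_class` attribute, when present, restores
#' the spliced / pre-RNA / intron-centered classification written by
#' [write_gtf()]; otherwise isoforms are read as spliced.
#'
#' @param path Path to a GTF file with mandatory `gene_id` and
#'   `transcript_id` attributes on exon rows.
#' @return A [gene_model_set()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L))
    stop("malformed GTF (expected 9 tab-separated fields) at line ",
         which(body)[which(nf != 9L)[1]])
  is_exon <- grepl("\t(exon)\t", lines, perl = TRUE) & body
  miss <- is_exon & !(grepl("gene_id", lines) & grepl("transcript_id", lines))
  if (any(miss))
    stop("exon record without gene_id/transcript_id at line ", which(miss)[1])

  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon records in ", path)
  if (is.null(df$gene_biotype)) df$gene_biotype <- "mRNA"
  if (is.null(df$isoform_class)) df$isoform_class <- "spliced"
  df$isoform_class[is.na(df$isoform_class)] <- "spliced"
  df$gene_biotype[is.na(df$gene_biotype)] <- "mRNA"

  genes <- lapply(split(df, df$gene_id), function(g) {
    isos <- lapply(split(g, g$transcript_id), function(tr) {
      isoform(tr$transcript_id[1],
              cbind(tr$start - 1, tr$end),
              cls = tr$isoform_class[1])
    })
    gene_model(g$gene_id[1], chrom = as.character(g$seqnames[1]),
               strand = as.character(g$strand[1]),
               biotype = g$gene_biotype[1], isoforms = unname(isos))
  })
  gene_model_set(unname(genes))
}

#' Write gene models to a GTF file
#'
#' Emits one exon row per exon with `gene_id`, `transcript_id`,
#' `gene_biotype` and `isoform_class` attributes, converting the in-memory
#' 0-based half-open intervals to the 1-based inclusive GTF convention.
#'
#' @param genes A [gene_model_set()] (or single `gene_model`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  if (inherits(genes, "gene_model")) genes <- gene_model_set(list(genes))
  con <- file(path, "w")
  on.exit(close(con))
  for (gene in unclass(genes)) {
    for (iso in gene$isoforms) {
      for (r in seq_len(nrow(iso$exons))) {
        attrs <- sprintf(
          'gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; isoform_class "%s";',
          gene$gene_id, iso$isoform_id, gene$biotype, iso$cls)
        writeLines(paste(gene$chrom, "fripflow", "exon",
                         format(iso$exons[r, 1] + 1, scientific = FALSE),
                         format(iso$exons[r, 2], scientific = FALSE),
                         ".", gene$strand, ".", attrs, sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read a typed, schema-validated TSV table
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping required column names to one
#'   of `"character"`, `"numeric"`, `"count"` (non-negative integer-valued)
#'   or `"proportion"` (in `[0, 1]`). Columns not named in the schema are
#'   preserved untouched.
#' @return A `data.frame`.
#' @export
read_table <- function(path, schema = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in names(schema)) {
    type <- schema[[col]]
    x <- df[[col]]
    if (type %in% c("numeric", "count", "proportion")) {
      x <- suppressWarnings(as.numeric(x))
      if (anyNA(x) && !anyNA(df[[col]]))
        stop("column '", col, "' is not numeric")
      if (type == "count" && any(x < 0 | x != round(x), na.rm = TRUE))
        stop("column '", col, "' must contain non-negative integer counts")
      if (type == "proportion" && any(x < 0 | x > 1, na.rm = TRUE))
        stop("column '", col, "' must lie in [0, 1]")
      df[[col]] <- x
    } else {
      df[[col]] <- as.character(x)
    }
  }
  df
}

#' Write a table as TSV with a stable numeric format
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                scientific = FALSE,
                                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Run an expression with a locally seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
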