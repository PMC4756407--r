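#' Protein binding specification for the synthetic generator
#'
#' Encodes how a protein's true log2 fRIP/input enrichment of a gene depends
#' on the gene's input abundance, structure and sequence:
#' \deqn{e_g = \beta_0 + \beta_{abund}\,\log_{10} FPKM_g +
#'   \beta_{exon}\, x_g + \beta_{len}\,\log_{10} L_g +
#'   \beta_{motif}\, m_g + N(0, \sigma)}
#' where \eqn{x_g} is the exon count, \eqn{L_g} the spliced length (nt) and
#' \eqn{m_g} the number of implanted motif occurrences.
#'
#' @param protein_id Label.
#' @param beta0 Baseline log2 enrichment.
#' @param beta_abund Slope versus log10 input FPKM (negative values emulate
#'   intron binders that are relatively more enriched on low-abundance
#'   genes).
#' @param beta_exon Slope versus exon count.
#' @param beta_len Slope versus log10 spliced length (nt).
#' @param beta_motif Log2 enrichment per implanted motif occurrence.
#' @param intron_fraction Fraction in `[0, 1]` of the IP signal (on the FPKM
#'   scale) assigned to the gene's unspliced pre-RNA isoform.
#' @param noise_sd SD of per-gene log2 noise (>= 0).
#' @param dispersion Negative-binomial dispersion of replicate counts (> 0).
#' @return An object of class `binding_spec`.
#' @export
binding_spec <- function(protein_id, beta0 = 0, beta_abund = 0,
                         beta_exon = 0, beta_len = 0, beta_motif = 0,
                         intron_fraction = 0.1, noise_sd = 0.5,
                         dispersion = 0.05) {
  if (intron_fraction < 0 || intron_fraction > 1)
    stop("intron_fraction must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  structure(list(protein_id = as.character(protein_id), beta0 = beta0,
                 beta_abund = beta_abund, beta_exon = beta_exon,
                 beta_len = beta_len, beta_motif = beta_motif,
                 intron_fraction = intron_fraction, noise_sd = noise_sd,
                 dispersion = dispersion),
            class = "binding_spec")
}

#' @export
print.binding_spec <- function(x, ...) {
  cat(sprintf(
    "<binding_spec %s: b0=%g abund=%g exon=%g len=%g motif=%g intron=%g sd=%g phi=%g>\n",
    x$protein_id, x$beta0, x$beta_abund, x$beta_exon, x$beta_len,
    x$beta_motif, x$intron_fraction, x$noise_sd, x$dispersion))
  invisible(x)
}

#' Generate synthetic gene models
#'
#' Spliced transcript lengths are drawn log-normally (human mRNA lengths are
#' approximately log-normal with median near 2 kb), split into exons with a
#' minimum exon width, and placed sequentially along a synthetic chromosome
#' with log-normal intron lengths. Each gene carries one spliced isoform;
#' augmented isoforms are added later with [add_prerna_isoforms()] /
#' [add_intron_isoforms()].
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_meanlog,length_sdlog Log-normal parameters of spliced
#'   transcript length; defaults give a median of 1997 nt.
#' @param exon_count_dist Function of `(n, lengths)` returning `n` exon
#'   counts (>= 1). The default draws `1 + Poisson(lambda)` with
#'   `lambda = min(length, 10000)/250` times a log-normal factor (sdlog
#'   0.4), coupling exon number to transcript length as in real annotations
#'   (length-exon rank correlation around 0.85) while leaving genuine
#'   exon-count variation at fixed length. Functions of `n` alone are also
#'   accepted.
#' @param lnc_fraction Proportion of genes labelled `lncRNA`.
#' @param min_exon Minimum exon width (nt).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A [gene_model_set()].
#' @export
gen_gene_models <- function(n_genes,
                            length_meanlog = log(1997), length_sdlog = 0.9,
                            exon_count_dist = function(n, lengths)
                              1L + stats::rpois(n, pmin(lengths, 10000) / 250 *
                                                  exp(stats::rnorm(n, 0, 0.4))),
                            lnc_fraction = 0.2, min_exon = 30, seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (length_sdlog < 0) stop("length_sdlog must be >= 0")
  if (lnc_fraction < 0 || lnc_fraction > 1)
    stop("lnc_fraction must lie in [0, 1]")
  with_seed(seed, {
    lens <- pmax(round(stats::rlnorm(n_genes, length_meanlog, length_sdlog)),
                 2 * min_exon)
    n_ex <- if (length(formals(exon_count_dist)) >= 2)
      exon_count_dist(n_genes, lens) else exon_count_dist(n_genes)
    n_ex <- pmax(as.integer(n_ex), 1L)
    if (any(is.na(n_ex)) || any(n_ex < 1))
      stop("exon_count_dist must return positive integer counts")
    n_ex <- pmin(n_ex, pmax(lens %/% min_exon, 1L))
    is_lnc <- stats::runif(n_genes) < lnc_fraction
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    pos <- 10000
    genes <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      ne <- n_ex[i]
      spare <- lens[i] - min_exon * ne
      w <- as.vector(stats::rmultinom(1, spare, stats::rgamma(ne, 1) + 1e-9))
      exon_lens <- min_exon + w
      intron_lens <- if (ne > 1)
        pmax(round(stats::rlnorm(ne - 1, log(1500), 0.8)), 60) else numeric(0)
      starts <- pos + cumsum(c(0, exon_lens[-ne] + intron_lens))
      exons <- cbind(starts, starts + exon_lens)
      gid <- sprintf("g%05d", i)
      genes[[i]] <- gene_model(
        gid, chrom = "chrS1", strand = strands[i],
        biotype = if (is_lnc[i]) "lncRNA" else "mRNA",
        isoforms = list(isoform(paste0(gid, ".t1"), exons, cls = "spliced")))
      pos <- max(exons[, 2]) + 10000
    }
    gene_model_set(genes)
  })
}

iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) stop("invalid IUPAC code: ", code)
  strsplit(map[[code]], "")[[1]]
}

#' Generate transcript sequences with optional motif implantation
#'
#' One sequence per gene, of the spliced isoform's length, with i.i.d. bases
#' at the requested GC content. Motif occurrences are implanted by replacing
#' background bases in place (no length change, keeping length and exon
#' covariates independent of motif count); the per-gene occurrence number is
#' Poisson with mean `implant_rate` and is recorded as ground truth.
#'
#' @param genes A [gene_model_set()].
#' @param gc GC content in (0, 1).
#' @param motif IUPAC string to implant, or `NULL`.
#' @param implant_rate Mean implanted occurrences per transcript.
#' @param seed Integer seed.
#' @return List with `sequences` (named [Biostrings::DNAStringSet]),
#'   `truth` (data.frame: gene_id, implanted) and `positions` (named list of
#'   1-based implant start positions).
#' @export
gen_sequences <- function(genes, gc = 0.5, motif = NULL, implant_rate = 0,
                          seed = 1) {
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  gl <- unclass(genes)
  lens <- vapply(gl, function(g)
    isoform_length(isoforms_of_class(g, "spliced")[[1]]), numeric(1))
  if (!is.null(motif)) {
    motif <- toupper(motif)
    chars <- strsplit(motif, "")[[1]]
    if (!all(chars %in% names(Biostrings::IUPAC_CODE_MAP)))
      stop("motif is not a valid IUPAC string: ", motif)
    if (nchar(motif) > min(lens))
      stop("motif longer than the shortest transcript")
  }
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    n_occ <- rep(0L, length(seqs))
    positions <- vector("list", length(seqs))
    if (!is.null(motif) && implant_rate > 0) {
      k <- nchar(motif)
      chars <- strsplit(motif, "")[[1]]
      n_occ <- stats::rpois(length(seqs), implant_rate)
      for (i in seq_along(seqs)) {
        if (n_occ[i] == 0L) next
        L <- lens[i]
        slots <- max(L - k + 1, 1)
        pos <- integer(0)
        for (tries in seq_len(50 * n_occ[i])) {
          cand <- sample.int(slots, 1)
          if (all(abs(cand - pos) >= k)) pos <- c(pos, cand)
          if (length(pos) == n_occ[i]) break
        }
        n_occ[i] <- length(pos)
        positions[[i]] <- sort(pos)
        s <- strsplit(seqs[i], "")[[1]]
        for (p in pos) {
          inst <- vapply(chars, function(cc) {
            b <- iupac_bases(cc)
            if (length(b) == 1) b else sample(b, 1)
          }, character(1))
          s[p:(p + k - 1)] <- inst
        }
        seqs[i] <- paste(s, collapse = "")
      }
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- names(gl)
    list(sequences = dss,
         truth = data.frame(gene_id = names(gl), implanted = n_occ,
                            stringsAsFactors = FALSE),
         positions = stats::setNames(positions, names(gl)))
  })
}

#' Simulate a fRIP-Seq experiment with known ground truth
#'
#' Input gene abundances are log-normal (lncRNA genes shifted down by
#' `lnc_abund_shift` decades, emulating their lower abundance). Each
#' protein's true per-gene log2 enrichment follows its [binding_spec()];
#' the IP gene abundance is the input abundance scaled by the true fold
#' change, with `intron_fraction` of the IP FPKM assigned to the gene's
#' pre-RNA isoform and the remainder to the spliced isoform. Expected
#' fragments per isoform are FPKM * (length/1000) * (library_size/1e6) and
#' replicate counts are negative-binomial around them, so the simulator
#' exercises the same FPKM code path users run on real data.
#'
#' @param genes A [gene_model_set()] (pre-RNA isoforms added if absent).
#' @param binding_specs List of [binding_spec()] objects, one per protein.
#' @param sequences Output of [gen_sequences()], required when any spec has
#'   nonzero `beta_motif`.
#' @param n_reps Replicates per library (input and each fRIP), >= 1.
#' @param library_size Expected mapped fragments per library.
#' @param max_log2fc True log2 enrichments are clamped to
#'   `[-max_log2fc, max_log2fc]` (default 8, i.e. 256-fold).
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of input gene FPKM.
#' @param lnc_abund_shift Log10 shift applied to lncRNA input abundance.
#' @param input_intron_fraction Fraction of input FPKM on the pre-RNA
#'   isoform (default 0: input signal is fully spliced).
#' @param input_dispersion NB dispersion of input replicate counts.
#' @param seed Integer seed.
#' @return An object of class `frip_experiment`: list with isoform-level
#'   `counts` and `fpkm` matrices, `samples`, `features`, `genes`, `truth`
#'   (per gene x protein), `covariates` (per gene) and `specs`.
#' @export
gen_experiment <- function(genes, binding_specs, sequences = NULL,
                           n_reps = 2, library_size = 2e7,
                           fpkm_meanlog = 1, fpkm_sdlog = 1.5,
                           lnc_abund_shift = -1, input_intron_fraction = 0,
                           input_dispersion = 0.05, max_log2fc = 8,
                           seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (inherits(binding_specs, "binding_spec"))
    binding_specs <- list(binding_specs)
  if (!all(vapply(binding_specs, inherits, logical(1), "binding_spec")))
    stop("binding_specs must be a list of binding_spec objects")
  genes <- add_prerna_isoforms(genes)
  gl <- unclass(genes)
  n <- length(gl)
  gene_ids <- names(gl)

  spl_iso <- vapply(gl, function(g) names(isoforms_of_class(g, "spliced"))[1],
                    character(1))
  pre_iso <- vapply(gl, function(g) names(isoforms_of_class(g, "preRNA"))[1],
                    character(1))
  len_spl <- vapply(gl, function(g)
    isoform_length(g$isoforms[[spl_iso[g$gene_id]]]), numeric(1))
  len_pre <- vapply(gl, function(g)
    isoform_length(g$isoforms[[pre_iso[g$gene_id]]]), numeric(1))
  exon_n <- vapply(gl, function(g)
    nrow(g$isoforms[[spl_iso[g$gene_id]]]$exons), numeric(1))
  is_lnc <- vapply(gl, `[[`, character(1), "biotype") == "lncRNA"

  motif_n <- rep(0, n)
  if (!is.null(sequences)) {
    motif_n <- sequences$truth$implanted[match(gene_ids,
                                               sequences$truth$gene_id)]
    motif_n[is.na(motif_n)] <- 0
  } else if (any(vapply(binding_specs, `[[`, numeric(1), "beta_motif") != 0)) {
    stop("sequences required when any binding spec has beta_motif != 0")
  }

  with_seed(seed, {
    a <- stats::rlnorm(n, fpkm_meanlog, fpkm_sdlog) *
      10^(lnc_abund_shift * is_lnc)

    iso_ids <- c(rbind(spl_iso, pre_iso))
    iso_len <- c(rbind(len_spl, len_pre))
    iso_gene <- rep(gene_ids, each = 2)
    iso_cls <- rep(c("spliced", "preRNA"), n)

    mu_iso <- function(gene_fpkm, intron_frac) {
      fpkm_iso <- c(rbind((1 - intron_frac) * gene_fpkm,
                          intron_frac * gene_fpkm))
      fpkm_iso * (iso_len / 1000) * (library_size / 1e6)
    }

    samples <- data.frame(sample = character(0), role = character(0),
                          protein = character(0), rep = integer(0),
                          stringsAsFactors = FALSE)
    counts <- NULL
    truth <- NULL

    mu_in <- mu_iso(a, input_intron_fraction)
    for (r in seq_len(n_reps)) {
      counts <- cbind(counts, stats::rnbinom(length(mu_in), mu = mu_in,
                                             size = 1 / input_dispersion))
      samples <- rbind(samples, data.frame(
        sample = sprintf("input_rep%d", r), role = "input",
        protein = NA_character_, rep = r, stringsAsFactors = FALSE))
    }
    for (spec in binding_specs) {
      e <- spec$beta0 + spec$beta_abund * log10(a) +
        spec$beta_exon * exon_n + spec$beta_len * log10(len_spl) +
        spec$beta_motif * motif_n +
        stats::rnorm(n, 0, spec$noise_sd)
      # clamp to a realistic enrichment dynamic range (the strongest fRIP
      # enrichments observed in practice are tens-fold); also keeps NB means
      # finite for heavy-tailed covariates
      e <- pmax(pmin(e, max_log2fc), -max_log2fc)
      A_ip <- a * 2^e
      mu_ipv <- mu_iso(A_ip, spec$intron_fraction)
      for (r in seq_len(n_reps)) {
        counts <- cbind(counts, stats::rnbinom(length(mu_ipv), mu = mu_ipv,
                                               size = 1 / spec$dispersion))
        samples <- rbind(samples, data.frame(
          sample = sprintf("%s_rep%d", spec$protein_id, r), role = "fRIP",
          protein = spec$protein_id, rep = r, stringsAsFactors = FALSE))
      }
      truth <- rbind(truth, data.frame(
        gene_id = gene_ids, protein = spec$protein_id, true_log2fc = e,
        bound_truth = e >= 1, stringsAsFactors = FALSE))
    }
    rownames(counts) <- iso_ids
    colnames(counts) <- samples$sample

    totals <- colSums(counts)
    fpkm <- vapply(seq_len(ncol(counts)), function(j)
      compute_fpkm(counts[, j], iso_len, totals[j]), numeric(nrow(counts)))
    dimnames(fpkm) <- dimnames(counts)

    structure(list(
      counts = counts, fpkm = fpkm, samples = samples,
      features = data.frame(isoform_id = iso_ids, gene_id = iso_gene,
                            cls = iso_cls, length = iso_len,
                            stringsAsFactors = FALSE),
      genes = genes, truth = truth,
      covariates = data.frame(gene_id = gene_ids, input_fpkm_true = a,
                              length = len_spl, exon_count = exon_n,
                              motif_count = motif_n,
                              biotype = ifelse(is_lnc, "lncRNA", "mRNA"),
                              stringsAsFactors = FALSE),
      specs = binding_specs, library_sizes = totals),
      class = "frip_experiment")
  })
}

#' @export
print.frip_experiment <- function(x, ...) {
  cat(sprintf("<frip_experiment: %d genes, %d isoforms, %d samples (%s)>\n",
              length(unique(x$features$gene_id)), nrow(x$counts),
              ncol(x$counts),
              paste(unique(x$samples$sample), collapse = ", ")))
  invisible(x)
}

#' Gene-level count and FPKM matrices of a simulated experiment
#'
#' Sums isoform-level counts and FPKM over each gene (spliced + pre-RNA).
#'
#' @param experiment A `frip_experiment`.
#' @return List with `counts` and `fpkm` (gene x sample matrices).
#' @export
gene_matrices <- function(experiment) {
  g <- experiment$features$gene_id
  list(counts = rowsum(experiment$counts, g),
       fpkm = rowsum(experiment$fpkm, g))
}

#' Gene-level FPKM against TMM effective library sizes
#'
#' Recomputes isoform FPKM using composition-corrected library sizes
#' ([effective_library_sizes()]) and sums over each gene's isoforms. This is
#' the abundance matrix fold-change analyses should use: raw per-million
#' scaling is shifted when IP libraries spend much of their depth on long
#' pre-RNA isoforms.
#'
#' @param experiment A `frip_experiment`.
#' @return Gene x sample FPKM matrix.
#' @export
effective_gene_fpkm <- function(experiment) {
  eff <- effective_library_sizes(experiment$counts,
                                 experiment$library_sizes)
  fpkm <- vapply(seq_len(ncol(experiment$counts)), function(j)
    compute_fpkm(experiment$counts[, j], experiment$features$length, eff[j]),
    numeric(nrow(experiment$counts)))
  dimnames(fpkm) <- dimnames(experiment$counts)
  rowsum(fpkm, experiment$features$gene_id)
}

#' Simulate per-gene chromatin mark scores
#'
#' Chromatin scores follow
#' `score = intercept + mark_slope * log10(FPKM) + bound_shift * bound + noise`,
#' emulating marks that correlate strongly with expression plus an additive
#' shift on fRIP-bound genes that the lowess gap statistic should recover.
#'
#' @param genes A [gene_model_set()] (used for gene ids/ordering).
#' @param input_fpkm Positive per-gene input FPKM, aligned with `genes`.
#' @param bound_flags Logical per-gene bound indicator.
#' @param mark_slope Score units per decade of FPKM.
#' @param bound_shift Additive score shift on bound genes (score units).
#' @param noise_sd SD of Gaussian score noise.
#' @param intercept Baseline score.
#' @param seed Integer seed.
#' @return data.frame(gene_id, score, bound) with attribute `truth`
#'   recording the generating parameters.
#' @export
gen_chromatin <- function(genes, input_fpkm, bound_flags, mark_slope = 1,
                          bound_shift = 0, noise_sd = 0.3, intercept = 0,
                          seed = 1) {
  gene_ids <- names(unclass(genes))
  n <- length(gene_ids)
  if (length(input_fpkm) != n || length(bound_flags) != n)
    stop("input_fpkm and bound_flags must be defined for all genes")
  if (any(is.na(bound_flags))) stop("bound_flags must be non-missing")
  if (any(input_fpkm <= 0)) stop("input_fpkm must be positive")
  with_seed(seed, {
    score <- intercept + mark_slope * log10(input_fpkm) +
      bound_shift * bound_flags + stats::rnorm(n, 0, noise_sd)
    out <- data.frame(gene_id = gene_ids, score = score,
                      bound = as.logical(bound_flags),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(mark_slope = mark_slope,
                               bound_shift = bound_shift,
                               noise_sd = noise_sd, intercept = intercept)
    out
  })
}

#' Generate random transposable-element annotations
#'
#' Assigns TE intervals (transcript-relative, 0-based half-open) to
#' transcripts independently at the given per-family rate; used as the null
#' background for TE association tests.
#'
#' @param genes A [gene_model_set()].
#' @param families Character vector of family names.
#' @param rate Per-gene, per-family presence probability.
#' @param seed Integer seed.
#' @return BED-style data.frame(gene_id, start, end, family, orientation).
#' @export
gen_te_annotations <- function(genes, families = c("Alu", "ERV1", "L1"),
                               rate = 0.15, seed = 1) {
  gl <- unclass(genes)
  lens <- vapply(gl, function(g)
    isoform_length(isoforms_of_class(g, "spliced")[[1]]), numeric(1))
  with_seed(seed, {
    rows <- list()
    for (fam in families) {
      present <- which(stats::runif(length(gl)) < rate)
      for (i in present) {
        w <- min(sample(150:300, 1), lens[i])
        s <- sample.int(max(lens[i] - w, 1), 1) - 1
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = names(gl)[i], start = s, end = s + w, family = fam,
          orientation = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0)
      return(data.frame(gene_id = character(0), start = numeric(0),
                        end = numeric(0), family = character(0),
                        orientation = character(0)))
    do.call(rbind, rows)
  })
}

#' Simulate per-base transcript coverage with optional 3' bias
#'
#' Coverage at relative position `t` in `[0, 1]` is Poisson with mean
#' `depth * exp(bias * (t - 0.5))`; positive `bias` weights the 3' end.
#'
#' @param genes A [gene_model_set()].
#' @param bias Log-linear positional bias (0 = uniform).
#' @param depth Mean per-base coverage.
#' @param seed Integer seed.
#' @return Named list of per-base coverage vectors (5' to 3').
#' @export
gen_coverage <- function(genes, bias = 0, depth = 2, seed = 1) {
  gl <- unclass(genes)
  lens <- vapply(gl, function(g)
    isoform_length(isoforms_of_class(g, "spliced")[[1]]), numeric(1))
  with_seed(seed, {
    covs <- lapply(lens, function(L) {
      lam <- depth * exp(bias * ((seq_len(L) / L) - 0.5))
      stats::rpois(L, lam)
    })
    stats::setNames(covs, names(gl))
  })
}
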