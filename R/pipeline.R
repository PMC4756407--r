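config_error <- function(...) {
  stop(structure(class = c("fripflow_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Pipeline configuration
#'
#' Collects the tunable constants of the full analysis: the FPKM
#' pseudocount, significance and fold thresholds of the bound-gene rule,
#' the k of the k-medoid clustering, the promoter window width, the lowess
#' span, the synthetic-data generator settings and the master seed.
#'
#' @param out_dir Output directory for reports.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param n_genes,n_reps,library_size,lnc_fraction Generator settings.
#' @param binding_specs List of [binding_spec()] (default: an exon-count
#'   dependent chromatin protein and an abundance-dependent RBP).
#' @param motif,implant_rate Motif implanted by the generator.
#' @param pseudocount FPKM pseudocount (default 1).
#' @param q_threshold,fold_threshold Bound-call rule (default q < 0.05,
#'   > 2-fold in >= 1 replicate).
#' @param k_medoids k for the k-medoid clustering (default 10).
#' @param promoter_width Promoter window width, nt (default 3000).
#' @param smoother_span Lowess span (default 0.3).
#' @param mi_k,mi_nperm Motif-scan seed size and permutation count.
#' @param kmer_k k-mer regression sizes.
#' @param mark_slope,bound_shift,chromatin_noise Chromatin generator
#'   settings.
#' @param gtf Optional path to an existing GTF to use instead of simulated
#'   gene models (must exist).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_genes = 300, n_reps = 2,
                            library_size = 2e6, lnc_fraction = 0.2,
                            binding_specs = NULL, motif = "GATTACA",
                            implant_rate = 1, pseudocount = 1,
                            q_threshold = 0.05, fold_threshold = 2,
                            k_medoids = 10, promoter_width = 3000,
                            smoother_span = 0.3, mi_k = 5, mi_nperm = 100,
                            kmer_k = 4:5, mark_slope = 1, bound_shift = 0.8,
                            chromatin_noise = 0.3, gtf = NULL) {
  if (missing(out_dir) || !nzchar(out_dir))
    config_error("out_dir is required")
  for (v in c(pseudocount, q_threshold, fold_threshold, k_medoids,
              promoter_width, smoother_span))
    if (!is.finite(v) || v <= 0)
      config_error("all thresholds and widths must be positive")
  if (promoter_width %% 2 != 0)
    config_error("promoter_width must split evenly around the TSS")
  if (!is.null(gtf) && !file.exists(gtf))
    config_error("gtf path does not exist: ", gtf)
  if (is.null(binding_specs)) {
    binding_specs <- list(
      binding_spec("CAPX", beta0 = 0, beta_exon = 0.08, beta_motif = 1,
                   intron_fraction = 0.6, noise_sd = 0.4),
      binding_spec("RBPA", beta0 = 0.5, beta_abund = -0.4,
                   intron_fraction = 0.05, noise_sd = 0.4))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_genes = n_genes, n_reps = n_reps,
                 library_size = library_size, lnc_fraction = lnc_fraction,
                 binding_specs = binding_specs, motif = motif,
                 implant_rate = implant_rate, pseudocount = pseudocount,
                 q_threshold = q_threshold, fold_threshold = fold_threshold,
                 k_medoids = k_medoids, promoter_width = promoter_width,
                 smoother_span = smoother_span, mi_k = mi_k,
                 mi_nperm = mi_nperm, kmer_k = kmer_k,
                 mark_slope = mark_slope, bound_shift = bound_shift,
                 chromatin_noise = chromatin_noise, gtf = gtf),
            class = "pipeline_config")
}

log_stage <- function(name, t0) {
  message(sprintf("[fripflow] %-12s %.2fs", name,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full synthetic-to-report analysis pipeline
#'
#' Executes simulate -> quantify -> enrich -> profiles -> structure ->
#' sequence -> chromatin, writing TSV reports and a JSON run manifest
#' (package version, seeds, config, file checksums, stage timings) to the
#' configured output directory. Fully deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config_error("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    timings[[name]] <<- round(as.numeric(proc.time()[3] - t0), 3)
    log_stage(name, t0)
    res
  }
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_table(df, path)
    files[[name]] <<- path
    path
  }
  seed <- config$seed

  # --- simulate -------------------------------------------------------
  sim <- stage("simulate", {
    genes <- if (!is.null(config$gtf)) read_gtf(config$gtf) else
      gen_gene_models(config$n_genes, lnc_fraction = config$lnc_fraction,
                      seed = seed)
    seqres <- gen_sequences(genes, motif = config$motif,
                            implant_rate = config$implant_rate,
                            seed = seed + 1L)
    expm <- gen_experiment(genes, config$binding_specs, sequences = seqres,
                           n_reps = config$n_reps,
                           library_size = config$library_size,
                           seed = seed + 2L)
    list(genes = expm$genes, seqres = seqres, expm = expm)
  })
  expm <- sim$expm
  gm <- gene_matrices(expm)
  emit(data.frame(isoform_id = rownames(expm$counts), expm$counts,
                  check.names = FALSE), "counts.tsv")
  emit(data.frame(isoform_id = rownames(expm$fpkm), expm$fpkm,
                  check.names = FALSE), "fpkm.tsv")
  emit(expm$truth, "truth.tsv")
  write_gtf(expm$genes, file.path(config$out_dir, "annotation.gtf"))
  files[["annotation.gtf"]] <- file.path(config$out_dir, "annotation.gtf")

  # --- enrichment -----------------------------------------------------
  proteins <- vapply(config$binding_specs, `[[`, character(1), "protein_id")
  input_cols <- expm$samples$sample[expm$samples$role == "input"]
  fpkm_eff <- effective_gene_fpkm(expm)
  enr <- stage("enrich", {
    out <- list()
    for (pr in proteins) {
      ip_cols <- expm$samples$sample[expm$samples$role == "fRIP" &
                                       expm$samples$protein == pr]
      res <- test_enrichment(gm$counts[, ip_cols, drop = FALSE],
                             gm$counts[, input_cols, drop = FALSE],
                             pseudocount = config$pseudocount,
                             ip_fpkm = fpkm_eff[, ip_cols, drop = FALSE],
                             input_fpkm = fpkm_eff[, input_cols,
                                                   drop = FALSE])
      fc_rep <- replicate_fold_changes(fpkm_eff[, ip_cols, drop = FALSE],
                                       fpkm_eff[, input_cols, drop = FALSE],
                                       config$pseudocount)
      res$bound <- call_bound(res, fc_rep, config$q_threshold,
                              config$fold_threshold)
      res$protein <- pr
      out[[pr]] <- res
    }
    out
  })
  emit(do.call(rbind, lapply(enr, function(d)
    d[c("gene_id", "protein", "log2fc", "p", "q", "tested", "bound")])),
    "enrichment.tsv")

  # --- profiles -------------------------------------------------------
  prof <- stage("profiles", {
    fc_mat <- vapply(enr, `[[`, numeric(nrow(enr[[1]])), "log2fc")
    rownames(fc_mat) <- enr[[1]]$gene_id
    tested <- Reduce(`|`, lapply(enr, `[[`, "tested"))
    fc_mat <- fc_mat[tested, , drop = FALSE]
    hc <- if (ncol(fc_mat) >= 2 && nrow(fc_mat) >= 2)
      hierarchical_cluster(fc_mat) else NULL
    bound_any <- Reduce(`|`, lapply(enr, `[[`, "bound"))
    bm <- fc_mat[rownames(fc_mat) %in% enr[[1]]$gene_id[bound_any], ,
                 drop = FALSE]
    km <- NULL
    k <- min(config$k_medoids, nrow(bm) - 1)
    if (k >= 1 && nrow(bm) > 2)
      km <- kmedoids_cluster(bm, k = k, seed = seed + 3L)
    spec_scores <- specificity_score(linearize_enrichment(fc_mat))
    list(fc_mat = fc_mat, hc = hc, km = km, spec = spec_scores)
  })
  if (!is.null(prof$km))
    emit(data.frame(gene_id = names(prof$km$cluster),
                    cluster = prof$km$cluster), "clusters.tsv")
  emit(data.frame(gene_id = rownames(prof$fc_mat),
                  specificity = prof$spec), "specificity.tsv")

  # --- structure ------------------------------------------------------
  covs <- expm$covariates[match(rownames(gm$counts),
                                expm$covariates$gene_id), ]
  input_fpkm <- rowMeans(fpkm_eff[, input_cols, drop = FALSE])
  struct <- stage("structure", {
    rows <- lapply(proteins, function(pr) {
      d <- enr[[pr]]
      ok <- d$tested
      fc <- d$log2fc[ok]
      len <- covs$length[ok]; ex <- covs$exon_count[ok]
      fp <- input_fpkm[ok]
      sp_le <- tryCatch(semipartial_correlation(fc, ex, len),
                        error = function(e) list(rho = NA_real_))
      sp_el <- tryCatch(semipartial_correlation(fc, len, ex),
                        error = function(e) list(rho = NA_real_))
      data.frame(protein = pr,
                 rho_fpkm = fpkm_dependence(fc, fp,
                                            span = config$smoother_span)$rho,
                 rho_length = attribute_correlation(fc, len)$rho,
                 rho_exons = attribute_correlation(fc, ex)$rho,
                 sp_length_given_exons = sp_le$rho,
                 sp_exons_given_length = sp_el$rho,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  emit(struct, "structure.tsv")

  # --- sequence -------------------------------------------------------
  seqstage <- stage("sequence", {
    pr1 <- proteins[1]
    d <- enr[[pr1]]
    ok <- d$tested
    seqs <- sim$seqres$sequences[d$gene_id[ok]]
    stat <- d$log2fc[ok]
    motifs <- mi_motif_scan(seqs, stat, k_seed = config$mi_k,
                            n_perm = config$mi_nperm, seed = seed + 4L)
    dose <- motif_dose_response(motifs$pattern[1], seqs, stat)
    kms <- kmer_regression(seqs, stat, k_range = config$kmer_k,
                           seed = seed + 5L)
    tes <- gen_te_annotations(expm$genes, seed = seed + 6L)
    te_res <- te_association(tes, stats::setNames(stat, d$gene_id[ok]))
    list(motifs = motifs, dose = dose, kms = kms, te = te_res)
  })
  emit(seqstage$motifs, "motifs.tsv")
  emit(seqstage$dose, "motif_dose.tsv")
  emit(data.frame(k = vapply(seqstage$kms, `[[`, numeric(1), "k"),
                  alpha = vapply(seqstage$kms, `[[`, numeric(1), "alpha"),
                  variance_explained = vapply(seqstage$kms, `[[`,
                                              numeric(1),
                                              "variance_explained")),
       "kmers.tsv")
  if (nrow(seqstage$te) > 0) emit(seqstage$te, "te.tsv")

  # --- chromatin ------------------------------------------------------
  chrom <- stage("chromatin", {
    pr1 <- proteins[1]
    bound <- enr[[pr1]]$bound
    ch <- gen_chromatin(expm$genes, covs$input_fpkm_true, bound,
                        mark_slope = config$mark_slope,
                        bound_shift = config$bound_shift,
                        noise_sd = config$chromatin_noise, seed = seed + 7L)
    gap <- lowess_gap(ch$score, covs$input_fpkm_true, bound,
                      span = config$smoother_span, seed = seed + 8L,
                      min_group = 25)
    list(scores = ch, gap = gap)
  })
  emit(chrom$scores, "chromatin_scores.tsv")
  emit(data.frame(protein = proteins[1], gap = chrom$gap$gap,
                  p = chrom$gap$p, n_bound = chrom$gap$n_bound,
                  n_unbound = chrom$gap$n_unbound), "chromatin_gap.tsv")

  # --- metagene -------------------------------------------------------
  meta <- stage("metagene", {
    covl <- gen_coverage(expm$genes[seq_len(min(100, length(expm$genes)))],
                         bias = 0.5, seed = seed + 9L)
    metagene_profile(covl, n_bins = 100)
  })
  emit(meta$profile, "metagene.tsv")

  # --- manifest -------------------------------------------------------
  cfg_flat <- config
  cfg_flat$binding_specs <- lapply(config$binding_specs, unclass)
  manifest <- list(
    package = "fripflow",
    version = as.character(utils::packageVersion("fripflow")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(cfg_flat),
    timings_s = timings,
    files = lapply(files, function(f) unname(tools::md5sum(f))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files[["manifest.json"]] <- manifest_path
  invisible(files)
}
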