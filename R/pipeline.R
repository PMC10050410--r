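#' Pipeline parameters
#'
#' All tunables of the analysis with their default values: 501-bp peaks
#' (half-width 250), SPM >= 5 and support >= 2 for the reproducible peak
#' set, promoter window +/- 1 kb, log-CPM prior 5, TSS-enrichment pass
#' threshold 5, nucleosome-free bound 100 bp, common CREs at median >= 3
#' and variance <= 0.5, top 50,000 variable CREs, 3 tumour clusters and
#' 5 CRE modules (k-means, 100 iterations), DAR/DEG cutoffs
#' |log2FC| > 1 and FDR < 0.01, marker-score cutoff 0.4, and 50
#' background peak sets for motif deviations.
#'
#' @param half_width summit extension, bp.
#' @param min_spm,min_support reproducible-peak filters.
#' @param promoter_dist promoter window half-width, bp.
#' @param prior_count log-CPM prior.
#' @param tss_min TSS-enrichment QC threshold.
#' @param nfr_max_len nucleosome-free bound, bp (strict).
#' @param common_min_median,common_max_var common-CRE filters.
#' @param top_n_variable variable CREs used for clustering.
#' @param k_samples,k_modules cluster counts.
#' @param iter_max,n_init k-means control.
#' @param lfc_cut,fdr_cut differential cutoffs (strict).
#' @param score_cutoff marker-score split.
#' @param n_bg,bandwidth motif-deviation background matching.
#' @param nucleosome_free re-run harmonization/counting on fragments
#'   < `nfr_max_len` bp only.
#' @param seed seed for the pipeline's stochastic steps (k-means
#'   restarts, background peak sampling).
#' @return a named list of validated parameters.
#' @export
pipeline_params <- function(half_width = 250, min_spm = 5, min_support = 2,
                            promoter_dist = 1000, prior_count = 5,
                            tss_min = 5, nfr_max_len = 100,
                            common_min_median = 3, common_max_var = 0.5,
                            top_n_variable = 50000, k_samples = 3,
                            k_modules = 5, iter_max = 100, n_init = 10,
                            lfc_cut = 1, fdr_cut = 0.01, score_cutoff = 0.4,
                            n_bg = 50, bandwidth = 0.1,
                            nucleosome_free = FALSE, seed = 1) {
  as.list(environment())
}

# restrict an accessibility matrix to a region subset, keeping library
# sizes and normalization state
restrict_regions <- function(am, regions) {
  out <- am
  out$values <- am$values[rownames(am$values) %in% regions, , drop = FALSE]
  out
}

#' Run the full stratification pipeline on a cohort
#'
#' Executes the stages in order: peak harmonization; Tn5 correction,
#' counting, QC and normalization; promoter/distal + TME annotation and
#' deconvolution; tumour clustering and CRE modules; motif matching,
#' background-matched deviation scores and cluster phenotyping
#' (ERE-reduced vs ER-intact vs TNBC-like); differential accessibility
#' (A-like vs B-like) and differential expression for surrogate markers;
#' and the marker-score Kaplan-Meier analysis on the validation cohort.
#'
#' @param cohort a cohort list from [generate_cohort()] (or
#'   [read_cohort()]).
#' @param params see [pipeline_params()].
#' @param outdir optional directory; when given, the main outputs and a
#'   `report.json` are written there.
#' @return a `chromstrat_pipeline` list with all stage outputs and a
#'   run `report`.
#' @export
run_pipeline <- function(cohort, params = pipeline_params(), outdir = NULL) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    t0 <<- Sys.time()
  }

  ## 1. harmonize ------------------------------------------------------------
  sample_sets <- lapply(split(cohort$summits, cohort$summits$sample_id),
                        function(s) {
    s |>
      extend_summits(half_width = params$half_width,
                     chrom_sizes = cohort$chrom_sizes) |>
      filter_blacklist(cohort$blacklist) |>
      iterative_overlap_removal(rank_by = "score") |>
      score_per_million()
  })
  peaks <- merge_across_samples(sample_sets, min_spm = params$min_spm,
                                min_support = params$min_support)
  tick("harmonize")

  ## 2. counts + QC ----------------------------------------------------------
  fragments <- cohort$fragments
  if (isTRUE(params$nucleosome_free)) {
    fragments <- select_nucleosome_free(fragments, max_len = params$nfr_max_len)
  }
  insertions <- correct_insertions(fragments)
  qc <- tss_enrichment(insertions, cohort$tss,
                       qc_params(tss_min = params$tss_min,
                                 nfr_max_len = params$nfr_max_len))
  keep_samples <- qc$sample_id[qc$pass]
  if (any(!qc$pass)) {
    warn(sprintf("%d samples fail TSS-enrichment QC and are dropped",
                 sum(!qc$pass)))
  }
  insertions <- insertions[insertions$sample_id %in% keep_samples, , drop = FALSE]
  raw <- count_insertions(insertions, peaks, sample_ids = keep_samples)
  frag_hist <- fragment_length_histogram(fragments)
  norm <- normalize_matrix(raw, prior_count = params$prior_count)
  tick("counts_qc")

  ## 3. annotate -------------------------------------------------------------
  annotation <- annotate_peaks(peaks, cohort$tss,
                               promoter_dist = params$promoter_dist)
  overlaps <- overlap_reference_sets(peaks, cohort$tme_sets)
  distal_cancer <- derive_distal_cancer_cres(annotation, overlaps)
  decon <- bind_rows(lapply(names(cohort$tme_sets), function(s) {
    deconvolution_score(norm, overlaps, s)
  }))
  tick("annotate")

  ## 4. classify -------------------------------------------------------------
  dc_ids <- distal_cancer$peak_id
  variable_ids <- top_variable_cres(restrict_regions(norm, dc_ids),
                                    n = params$top_n_variable)
  clusters <- cluster_tumours(norm, regions = variable_ids, k = params$k_samples)
  common_ids <- common_accessible_cres(restrict_regions(norm, dc_ids),
                                       min_median = params$common_min_median,
                                       max_var = params$common_max_var)
  if (length(setdiff(dc_ids, common_ids))) {
    module_ids <- top_variable_cres(restrict_regions(norm, dc_ids),
                                    n = params$top_n_variable,
                                    exclude = common_ids)
  } else {
    warn("every distal cancer CRE passes the common filter; CRE modules use the variable set")
    module_ids <- variable_ids
  }
  modules <- kmeans_modules(norm, regions = module_ids, k = params$k_modules,
                            iter_max = params$iter_max, n_init = params$n_init,
                            seed = params$seed)
  pca <- pca_embed(norm, regions = variable_ids)
  tick("classify")

  ## 5. motifs ---------------------------------------------------------------
  peak_seqs <- get_peak_sequences(peaks, cohort$genome)
  matches <- motif_matches(peak_seqs, cohort$motifs)
  gc <- gc_content(peak_seqs)
  bg <- background_peaks(gc, rowMeans(raw$values), n_bg = params$n_bg,
                         bandwidth = params$bandwidth, seed = params$seed + 1L)
  deviations <- motif_deviations(raw, matches, bg)

  # phenotype the clusters: lowest mean ERE motif score = ERE-reduced
  # (B-like); of the rest, highest immune deconvolution = TNBC-like
  # (C-like); the remainder is ER-intact (A-like)
  lab <- clusters$labels
  z_ere <- deviations$z["ERE", lab$sample_id]
  mean_by_cluster <- tapply(z_ere, lab$cluster, mean)
  b_like <- names(which.min(mean_by_cluster))
  immune <- decon[decon$set %in% IMMUNE_SETS, , drop = FALSE]
  immune <- left_join(immune, lab, by = "sample_id")
  imm_by_cluster <- tapply(immune$score, immune$cluster, mean)
  c_like <- names(which.max(imm_by_cluster[setdiff(names(imm_by_cluster), b_like)]))
  a_like <- setdiff(unique(lab$cluster), c(b_like, c_like))[1]
  phenotypes <- tibble(
    cluster = c(a_like, b_like, c_like),
    phenotype = c("ER-intact", "ERE-reduced", "TNBC-like")
  )
  a_samples <- lab$sample_id[lab$cluster == a_like]
  b_samples <- lab$sample_id[lab$cluster == b_like]
  ere_test <- motif_score_test(deviations$z["ERE", a_samples],
                               deviations$z["ERE", b_samples])
  tick("motifs")

  ## 6. differential ---------------------------------------------------------
  ab_samples <- c(a_samples, b_samples)
  ab_groups <- factor(ifelse(ab_samples %in% a_samples, "A_like", "B_like"),
                      levels = c("A_like", "B_like"))
  raw_ab <- restrict_regions(raw, dc_ids)
  raw_ab$values <- raw_ab$values[, ab_samples, drop = FALSE]
  raw_ab$lib_sizes <- raw_ab$lib_sizes[ab_samples]
  dars <- call_differential(fit_nb_ql(raw_ab, ab_groups),
                            lfc_cut = params$lfc_cut, fdr_cut = params$fdr_cut)
  # A-specific CREs (more accessible in the ER-intact cluster) are the
  # canonical target for motif enrichment (FOXA1/ERE expected on top)
  a_specific <- dars$region[dars$call == "down"]
  enrichment <- NULL
  if (length(a_specific) && length(a_specific) < nrow(raw$values)) {
    enrichment <- motif_enrichment(matches, rownames(raw$values) %in% a_specific,
                                   gc, seed = params$seed + 2L)
  } else {
    warn("no A-specific DARs; motif enrichment skipped")
  }
  degs <- call_differential(
    fit_limma(cohort$expression[, ab_samples, drop = FALSE], ab_groups),
    lfc_cut = params$lfc_cut, fdr_cut = params$fdr_cut
  )
  markers <- degs$gene[degs$call == "up"]
  tick("differential")

  ## 7. survival -------------------------------------------------------------
  surv_result <- NULL
  if (length(markers)) {
    scores <- marker_score(cohort$validation$expression, markers)
    split <- split_by_cutoff(scores, cutoff = params$score_cutoff)
    surv_tab <- left_join(cohort$validation$survival,
                          split[, c("sample_id", "score", "group")],
                          by = c("sample" = "sample_id"))
    km <- km_estimate(surv_tab)
    lr <- if (length(unique(surv_tab$group)) >= 2) logrank_test(surv_tab) else NULL
    surv_result <- list(scores = split, km = km, logrank = lr)
  } else {
    warn("no surrogate marker genes found; survival stage skipped")
  }
  tick("survival")

  report <- list(
    params = params,
    n_samples = length(keep_samples),
    n_merged_peaks = nrow(peaks),
    n_promoter = sum(annotation$class == "promoter"),
    n_distal = sum(annotation$class == "distal"),
    n_tme_overlap = sum(overlaps$any_tme),
    n_distal_cancer = nrow(distal_cancer),
    n_common = length(common_ids),
    n_variable = length(variable_ids),
    cluster_sizes = as.list(table(lab$cluster)),
    cluster_phenotypes = phenotypes,
    n_dar_up = sum(dars$call == "up"),
    n_dar_down = sum(dars$call == "down"),
    top_motif = if (!is.null(enrichment)) enrichment$motif[1] else NA_character_,
    n_markers = length(markers),
    ere_test_p = ere_test$p_value,
    logrank_p = if (!is.null(surv_result$logrank)) surv_result$logrank$p_value else NA,
    timings = timings
  )

  result <- structure(list(
    peaks = peaks, qc = qc, fragment_lengths = frag_hist,
    raw = raw, norm = norm,
    annotation = annotation, overlaps = overlaps,
    distal_cancer = distal_cancer, deconvolution = decon,
    clusters = clusters, phenotypes = phenotypes, modules = modules, pca = pca,
    matches = matches, deviations = deviations, ere_test = ere_test,
    dars = dars, enrichment = enrichment, degs = degs, markers = markers,
    survival = surv_result,
    report = report
  ), class = "chromstrat_pipeline")

  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

#' @export
print.chromstrat_pipeline <- function(x, ...) {
  r <- x$report
  cat("<chromstrat_pipeline>\n")
  cat(sprintf("  %d samples, %d merged peaks (%d promoter / %d distal, %d distal cancer CREs)\n",
              r$n_samples, r$n_merged_peaks, r$n_promoter, r$n_distal,
              r$n_distal_cancer))
  cat(sprintf("  clusters: %s\n",
              paste(sprintf("%s=%d", names(r$cluster_sizes),
                            unlist(r$cluster_sizes)), collapse = ", ")))
  cat(sprintf("  DARs: %d up / %d down; markers: %d; ERE t-test p = %.3g\n",
              r$n_dar_up, r$n_dar_down, r$n_markers, r$ere_test_p))
  if (is.finite(suppressWarnings(as.numeric(r$logrank_p)))) {
    cat(sprintf("  marker-score log-rank p = %.3g\n", r$logrank_p))
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_bed(result$peaks[, c("chrom", "start", "end")],
            file.path(outdir, "merged_peaks.bed"))
  data.table::fwrite(result$annotation, file.path(outdir, "annotation.tsv"),
                     sep = "\t")
  data.table::fwrite(result$clusters$labels, file.path(outdir, "clusters.tsv"),
                     sep = "\t")
  data.table::fwrite(result$dars, file.path(outdir, "differential.tsv"),
                     sep = "\t")
  write_matrix_tsv(result$deviations$z, file.path(outdir, "motif_scores.tsv"),
                   id_name = "motif")
  rep <- result$report
  rep$cluster_phenotypes <- as.data.frame(rep$cluster_phenotypes)
  jsonlite::write_json(rep, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Write / read a generated cohort to plain-text files
#'
#' Serializes every cohort artifact in its interchange format:
#' per-sample fragment TSVs (BED3 + sample column) and narrowPeak summit
#' calls, TSS BED6, blacklist BED3, one BED3 per TME reference set plus
#' a YAML manifest, a JASPAR PFM file, genome and region FASTA,
#' expression TSVs, a survival CSV, and the planted truth as JSON.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "fragments"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "tme"), showWarnings = FALSE)
  for (s in unique(cohort$fragments$sample_id)) {
    data.table::fwrite(cohort$fragments[cohort$fragments$sample_id == s, ],
                       file.path(dir, "fragments", paste0(s, ".tsv")),
                       sep = "\t")
  }
  for (s in unique(cohort$summits$sample_id)) {
    x <- cohort$summits[cohort$summits$sample_id == s, ]
    write_narrowpeak(
      tibble(chrom = x$chrom, start = x$summit - 250L, end = x$summit + 251L,
             score = x$score, summit = x$summit),
      file.path(dir, "peaks", paste0(s, ".narrowPeak"))
    )
  }
  write_bed(tibble(chrom = cohort$tss$chrom, start = cohort$tss$position,
                   end = cohort$tss$position + 1L, name = cohort$tss$gene_name,
                   score = 0, strand = cohort$tss$strand),
            file.path(dir, "tss.bed"))
  write_bed(cohort$blacklist, file.path(dir, "blacklist.bed"))
  manifest <- list()
  for (s in names(cohort$tme_sets)) {
    path <- file.path("tme", paste0(s, ".bed"))
    write_bed(cohort$tme_sets[[s]], file.path(dir, path))
    manifest[[s]] <- path
  }
  yaml::write_yaml(manifest, file.path(dir, "tme_manifest.yaml"))
  write_jaspar_pfm(cohort$pfms, file.path(dir, "motifs.pfm"))
  write_fasta(cohort$genome, file.path(dir, "genome.fa"))
  write_fasta(cohort$region_seqs, file.path(dir, "regions.fa"))
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   id_name = "gene")
  write_matrix_tsv(cohort$validation$expression,
                   file.path(dir, "validation_expression.tsv"), id_name = "gene")
  write_survival_csv(cohort$validation$survival, file.path(dir, "survival.csv"))
  data.table::fwrite(
    data.table::data.table(chrom = names(cohort$chrom_sizes),
                           size = unname(cohort$chrom_sizes)),
    file.path(dir, "chrom_sizes.tsv"), sep = "\t")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  frag_files <- list.files(file.path(dir, "fragments"), full.names = TRUE)
  fragments <- bind_rows(lapply(frag_files, function(f) {
    as_tibble(data.table::fread(f, sep = "\t"))
  }))
  peak_files <- list.files(file.path(dir, "peaks"), full.names = TRUE)
  summits <- bind_rows(lapply(peak_files, function(f) {
    np <- read_narrowpeak(f)
    tibble(chrom = np$chrom, summit = np$summit, score = np$score,
           sample_id = sub("\\.narrowPeak$", "", basename(f)))
  }))
  tss_bed <- read_bed(file.path(dir, "tss.bed"))
  tss <- tibble(chrom = tss_bed$chrom, position = tss_bed$start,
                strand = tss_bed$strand, gene_name = tss_bed$name)
  manifest <- yaml::read_yaml(file.path(dir, "tme_manifest.yaml"))
  tme_sets <- lapply(manifest, function(p) read_bed(file.path(dir, p)))
  pfms <- read_jaspar_pfm(file.path(dir, "motifs.pfm"))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  sizes_dt <- data.table::fread(file.path(dir, "chrom_sizes.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  samples <- as_tibble(truth$groups)
  list(
    samples = samples,
    fragments = fragments,
    summits = summits,
    tss = tss,
    blacklist = read_bed(file.path(dir, "blacklist.bed")),
    tme_sets = tme_sets,
    pfms = pfms,
    motifs = setNames(lapply(names(pfms), function(n) motif_model(n, pfms[[n]])),
                      names(pfms)),
    genome = genome,
    region_seqs = read_fasta(file.path(dir, "regions.fa")),
    expression = read_matrix_tsv(file.path(dir, "expression.tsv")),
    validation = list(
      expression = read_matrix_tsv(file.path(dir, "validation_expression.tsv")),
      survival = read_survival_csv(file.path(dir, "survival.csv"))
    ),
    chrom_sizes = setNames(sizes_dt$size, sizes_dt$chrom),
    truth = truth
  )
}
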