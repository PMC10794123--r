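#' Run the full synthetic-study pipeline
#'
#' Generates all inputs under `config`, then executes the analysis end to
#' end: per-condition peak calling, stitching, signal quantification and
#' rank-cutoff classification; merging of condition catalogs; Poisson flow
#' classification of merged super-enhancers; contact annotation against
#' score-filtered interactions; per-class SNP enrichment; CVD trait
#' curation; expression integration; and refinement of the flow-sensitive,
#' CVD-SNP-containing super-enhancer set.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory: when given, the refined matrix and
#'   SE/TE BED files are written there.
#' @param min_score Interaction score retention threshold (default 5).
#' @param fc_threshold,p_threshold Flow-classification thresholds.
#' @return List of class `seflow_run` with elements `truth`, `catalog_uf`,
#'   `catalog_df`, `merged`, `flow_calls`, `flow_summary`, `contacts`,
#'   `enrichment`, `cvd_snps`, `expression`, `refined`, `refined_matrix`,
#'   `evaluation`.
#' @export
run_pipeline <- function(config = simulation_config(), outdir = NULL,
                         min_score = 5, fc_threshold = 1.2,
                         p_threshold = 1e-4) {
  sim <- simulate_tag_libraries(config)
  truth <- simulate_gene_models(config, sim$truth)
  interactions <- simulate_interactions(config, truth)
  snp <- simulate_snp_catalog(config, truth)
  expression <- simulate_expression(config, truth)

  peaks_uf <- call_peaks(sim$ip_uf, sim$input_uf, config$genome)
  peaks_df <- call_peaks(sim$ip_df, sim$input_df, config$genome)
  catalog_uf <- call_enhancer_catalog(peaks_uf, sim$ip_uf, sim$input_uf)
  catalog_df <- call_enhancer_catalog(peaks_df, sim$ip_df, sim$input_df)
  merged <- merge_condition_catalogs(catalog_uf, catalog_df,
                                     sim$ip_uf, sim$input_uf,
                                     sim$ip_df, sim$input_df)

  flow_calls <- classify_flow_ses(merged$super_enhancers, sim$ip_uf,
                                  sim$ip_df, fc_threshold, p_threshold)
  flow_summary <- partition_summary(flow_calls)

  strong <- interactions[interactions$score >= min_score, , drop = FALSE]
  contacts <- annotate_contacts(merged$super_enhancers, strong)

  enrichment <- enrich_catalog(snp$snps, merged$super_enhancers,
                               sum(config$genome), group_by = "trait_class")
  cvd_traits <- curate_cvd_traits(unique(snp$snps$trait))
  cvd_snps <- snp$snps[snp$snps$trait %in% cvd_traits, , drop = FALSE]

  refined <- refine_flow_ses(flow_calls, cvd_snps, contacts, expression)
  refined_matrix <- build_refined_matrix(refined)

  evaluation <- list(
    se_calls = evaluate_se_calls(merged$super_enhancers, truth),
    flow = evaluate_flow_calls(flow_calls, truth))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_bed(merged$super_enhancers, file.path(outdir, "super_enhancers.bed"))
    write_bed(merged$typical_enhancers,
              file.path(outdir, "typical_enhancers.bed"))
    write_refined_matrix(refined_matrix,
                         file.path(outdir, "refined_matrix.tsv"))
  }
  structure(list(truth = truth, catalog_uf = catalog_uf,
                 catalog_df = catalog_df, merged = merged,
                 flow_calls = flow_calls, flow_summary = flow_summary,
                 contacts = contacts, enrichment = enrichment,
                 cvd_snps = cvd_snps, expression = expression,
                 refined = refined, refined_matrix = refined_matrix,
                 evaluation = evaluation, interactions = interactions,
                 snp = snp, libraries = sim[c("ip_uf", "input_uf",
                                              "ip_df", "input_df")]),
            class = "seflow_run")
}

#' @export
print.seflow_run <- function(x, ...) {
  ev <- x$evaluation$se_calls
  cat(sprintf(paste0(
    "seflow_run: %d merged SEs, %d TEs | flow %d UF / %d DF / %d CORE | ",
    "SE recovery sens %.2f prec %.2f | %d refined SE(s)\n"),
    nrow(x$merged$super_enhancers), nrow(x$merged$typical_enhancers),
    x$flow_summary[["UF_ENRICHED"]], x$flow_summary[["DF_ENRICHED"]],
    x$flow_summary[["CORE"]], ev$sensitivity, ev$precision,
    nrow(x$refined$ses)))
  invisible(x)
}

#' Sensitivity and precision of SE calls against planted truth
#'
#' A planted SE site is recovered when overlapped (>= 1 bp) by a called
#' super-enhancer; a called super-enhancer is a true positive when it
#' overlaps a planted SE site.
#'
#' @param called_ses Interval data frame of called super-enhancers.
#' @param truth A `ground_truth`.
#' @return List: `sensitivity`, `precision`, `n_called`, `n_planted`.
#' @export
evaluate_se_calls <- function(called_ses, truth) {
  planted <- truth$se_sites
  sens <- if (nrow(planted) == 0) NA_real_ else
    mean(interval_overlaps(planted, called_ses))
  prec <- if (nrow(called_ses) == 0) NA_real_ else
    mean(interval_overlaps(called_ses, planted))
  list(sensitivity = sens, precision = prec,
       n_called = nrow(called_ses), n_planted = nrow(planted))
}

#' Recovery of planted flow labels
#'
#' Matches each planted flow-sensitive SE site to overlapping called SEs
#' and checks whether any carries the planted label (UF -> UF_ENRICHED,
#' DF -> DF_ENRICHED).
#'
#' @param flow_calls [classify_flow_ses()] output.
#' @param truth A `ground_truth`.
#' @return List: `recovery` (fraction of planted UF/DF sites recovered),
#'   `n_planted_flow`.
#' @export
evaluate_flow_calls <- function(flow_calls, truth) {
  planted <- truth$se_sites[truth$se_sites$flow_label %in% c("UF", "DF"),
                            , drop = FALSE]
  if (nrow(planted) == 0) return(list(recovery = NA_real_,
                                      n_planted_flow = 0L))
  ok <- vapply(seq_len(nrow(planted)), function(i) {
    hit <- flow_calls$chrom == planted$chrom[i] &
      flow_calls$start < planted$end[i] & flow_calls$end > planted$start[i]
    any(flow_calls$label[hit] ==
          paste0(planted$flow_label[i], "_ENRICHED"))
  }, logical(1))
  list(recovery = mean(ok), n_planted_flow = nrow(planted))
}
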