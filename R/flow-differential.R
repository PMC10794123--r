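#' Poisson enrichment p-value for differential tag counts
#'
#' One-sided test of whether `count_test` raw tags in the test library
#' exceed expectation given `count_ref` tags in the reference library. The
#' expectation is `lambda = (count_ref + 1) * total_test / total_ref` (the
#' +1 pseudocount avoids a zero rate), and the p-value is the Poisson upper
#' tail `P(X >= count_test)`.
#'
#' @param count_test,count_ref Raw tag counts (vectors recycle).
#' @param total_test,total_ref Library totals (> 0).
#' @return p-value(s) in (0, 1].
#' @export
poisson_enrichment_p <- function(count_test, count_ref, total_test,
                                 total_ref) {
  if (any(count_test < 0) || any(count_ref < 0))
    stop("negative tag counts")
  if (any(total_test <= 0) || any(total_ref <= 0))
    stop("library totals must be > 0")
  lambda <- (count_ref + 1) * total_test / total_ref
  stats::ppois(count_test - 1, lambda, lower.tail = FALSE)
}

#' Classify enhancers as flow-enriched or core
#'
#' A region is DF-enriched iff its normalized-count log2 fold change
#' (DF/UF) is at least `log2(fc_threshold)` and the one-sided Poisson
#' enrichment p-value of DF over UF is at most `p_threshold`; UF-enriched
#' symmetrically; everything else is core. The fold change uses
#' library-size-normalized counts (tags per `norm_total`) with a +1
#' pseudocount on both sides, so swapping the conditions negates the log2FC
#' exactly and exchanges the UF/DF labels.
#'
#' @param count_uf,count_df Raw tag counts per region (vectors).
#' @param total_uf,total_df Library totals.
#' @param fc_threshold Fold-change threshold (default 1.2, i.e. |log2FC| >=
#'   0.263).
#' @param p_threshold Poisson p-value threshold (default 1e-4).
#' @param norm_total Normalization total (default 1e7).
#' @return Data frame: `count_uf_norm`, `count_df_norm`, `log2fc`,
#'   `pvalue` (the p-value of the direction tested; min of the two for
#'   core), `label` in `{UF_ENRICHED, DF_ENRICHED, CORE}`.
#' @export
classify_flow <- function(count_uf, count_df, total_uf, total_df,
                          fc_threshold = 1.2, p_threshold = 1e-4,
                          norm_total = 1e7) {
  uf_norm <- count_uf * norm_total / total_uf
  df_norm <- count_df * norm_total / total_df
  log2fc <- log2((df_norm + 1) / (uf_norm + 1))
  p_df <- poisson_enrichment_p(count_df, count_uf, total_df, total_uf)
  p_uf <- poisson_enrichment_p(count_uf, count_df, total_uf, total_df)
  lfc_min <- log2(fc_threshold)
  label <- rep("CORE", length(log2fc))
  label[log2fc >= lfc_min & p_df <= p_threshold] <- "DF_ENRICHED"
  label[log2fc <= -lfc_min & p_uf <= p_threshold] <- "UF_ENRICHED"
  pvalue <- ifelse(label == "DF_ENRICHED", p_df,
                   ifelse(label == "UF_ENRICHED", p_uf, pmin(p_df, p_uf)))
  data.frame(count_uf_norm = uf_norm, count_df_norm = df_norm,
             log2fc = log2fc, pvalue = pvalue, label = label,
             stringsAsFactors = FALSE)
}

#' Flow-classify merged super-enhancers from tag libraries
#'
#' Counts raw IP tags over each merged super-enhancer hull in both
#' conditions and applies [classify_flow()].
#'
#' @param ses Merged super-enhancer data frame (`chrom`, `start`, `end`,
#'   `id`).
#' @param ip_uf,ip_df IP tag libraries for the two conditions.
#' @inheritParams classify_flow
#' @return `ses` with the [classify_flow()] columns appended.
#' @export
classify_flow_ses <- function(ses, ip_uf, ip_df, fc_threshold = 1.2,
                              p_threshold = 1e-4, norm_total = 1e7) {
  c_uf <- count_tags_in(ses, ip_uf)
  c_df <- count_tags_in(ses, ip_df)
  calls <- classify_flow(c_uf, c_df, ip_uf$total_tags, ip_df$total_tags,
                         fc_threshold, p_threshold, norm_total)
  cbind(ses, calls)
}

#' Tally flow-classification labels
#'
#' @param calls Data frame with a `label` column (one row per SE).
#' @return Named integer vector with entries `UF_ENRICHED`, `DF_ENRICHED`,
#'   `CORE`, summing to `nrow(calls)`.
#' @export
partition_summary <- function(calls) {
  lv <- c("UF_ENRICHED", "DF_ENRICHED", "CORE")
  out <- table(factor(calls$label, levels = lv))
  stats::setNames(as.integer(out), lv)
}
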