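#' Filter genes by expression under either flow condition
#'
#' A gene is kept iff its FPKM reaches `fpkm_min` under at least one of the
#' two flow conditions (`max(fpkm_uf, fpkm_df) >= fpkm_min`). Genes absent
#' from the expression table are dropped with a warning.
#'
#' @param genes Character vector of gene ids.
#' @param expression Expression data frame (see [read_expression()]).
#' @param fpkm_min Minimum FPKM (>= 0; 1 for contacted-gene lists, 12 for
#'   the stringent actively-expressed gating).
#' @return Character vector: the qualifying subset of `genes`.
#' @export
filter_expressed <- function(genes, expression, fpkm_min = 1) {
  if (fpkm_min < 0) stop("fpkm_min must be >= 0")
  m <- match(genes, expression$gene)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " gene(s) absent from expression table; dropped")
    genes <- genes[!is.na(m)]
    m <- m[!is.na(m)]
  }
  keep <- pmax(expression$fpkm_uf[m], expression$fpkm_df[m]) >= fpkm_min
  genes[keep]
}

#' Refine flow-sensitive super-enhancers by CVD SNPs, contacts and expression
#'
#' Keeps the super-enhancers that (i) are flow-sensitive (label UF_ENRICHED
#' or DF_ENRICHED), (ii) harbor at least one cardiovascular-trait SNP
#' within the merged hull (half-open), and (iii) physically contact at
#' least one gene promoter whose gene is expressed (FPKM >= `fpkm_min`
#' under either flow).
#'
#' @param flow_calls Data frame from [classify_flow_ses()] (`chrom`,
#'   `start`, `end`, `id`, `label`, ...).
#' @param cvd_snps SNP data frame already curated to cardiovascular traits.
#' @param contact_map A `contact_map` over the same super-enhancers.
#' @param expression Expression data frame.
#' @param fpkm_min Expression gate (default 1).
#' @return List of class `refined_ses`: `ses` (data frame `chrom`, `start`,
#'   `end`, `id`, `label`, `n_cvd_snps`, `snp_rsids`, `snp_traits`, sorted
#'   by chromosome then start) and `genes` (data frame `se_id`, `gene`,
#'   `log2fc`, `qvalue`, `fpkm_uf`, `fpkm_df`).
#' @export
refine_flow_ses <- function(flow_calls, cvd_snps, contact_map, expression,
                            fpkm_min = 1) {
  flow <- flow_calls[flow_calls$label %in% c("UF_ENRICHED", "DF_ENRICHED"),
                     , drop = FALSE]
  ses <- list(); genes <- list()
  for (i in seq_len(nrow(flow))) {
    inside <- cvd_snps$chrom == flow$chrom[i] &
      cvd_snps$pos >= flow$start[i] & cvd_snps$pos < flow$end[i]
    if (!any(inside)) next
    contacted <- contact_map$pairs$gene[
      contact_map$pairs$enhancer == flow$id[i]]
    expressed <- suppressWarnings(
      filter_expressed(unique(contacted), expression, fpkm_min))
    if (length(expressed) == 0) next
    snps_i <- cvd_snps[inside, , drop = FALSE]
    ses[[length(ses) + 1]] <- data.frame(
      chrom = flow$chrom[i], start = flow$start[i], end = flow$end[i],
      id = flow$id[i], label = flow$label[i], n_cvd_snps = nrow(snps_i),
      snp_rsids = paste(unique(snps_i$rsid), collapse = ";"),
      snp_traits = paste(unique(snps_i$trait), collapse = ";"),
      stringsAsFactors = FALSE)
    m <- match(expressed, expression$gene)
    genes[[length(genes) + 1]] <- data.frame(
      se_id = flow$id[i], gene = expressed,
      log2fc = expression$log2fc[m], qvalue = expression$qvalue[m],
      fpkm_uf = expression$fpkm_uf[m], fpkm_df = expression$fpkm_df[m],
      stringsAsFactors = FALSE)
  }
  empty_ses <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), id = character(0),
                          label = character(0), n_cvd_snps = integer(0),
                          snp_rsids = character(0), snp_traits = character(0),
                          stringsAsFactors = FALSE)
  empty_genes <- data.frame(se_id = character(0), gene = character(0),
                            log2fc = numeric(0), qvalue = numeric(0),
                            fpkm_uf = numeric(0), fpkm_df = numeric(0),
                            stringsAsFactors = FALSE)
  ses <- if (length(ses)) do.call(rbind, ses) else empty_ses
  genes <- if (length(genes)) do.call(rbind, genes) else empty_genes
  ord <- order(ses$chrom, ses$start)
  ses <- ses[ord, , drop = FALSE]
  rownames(ses) <- rownames(genes) <- NULL
  structure(list(ses = ses, genes = genes), class = "refined_ses")
}

#' @export
print.refined_ses <- function(x, ...) {
  cat(sprintf("refined_ses: %d flow-sensitive CVD-SNP super-enhancer(s), %d gene link(s)\n",
              nrow(x$ses), nrow(x$genes)))
  invisible(x)
}

#' Compare flow fold changes of UF- vs DF-SE-contacted genes
#'
#' Removes genes contacted by both flow classes, looks up the expression
#' log2 fold change (DF/UF) of each remaining gene, and reports per-set
#' medians plus a two-sided Student's t-test (pooled variance) between the
#' two log2FC samples. The t-test is skipped (NA, with a warning) when a
#' set has fewer than 2 genes with expression records.
#'
#' @param genes_uf,genes_df Character vectors: genes contacted by
#'   UF-enriched and DF-enriched super-enhancers.
#' @param expression Expression data frame.
#' @return List: `log2fc_uf`, `log2fc_df`, `median_uf`, `median_df`,
#'   `n_uf`, `n_df`, `t_statistic`, `pvalue`.
#' @export
flow_expression_summary <- function(genes_uf, genes_df, expression) {
  shared <- intersect(genes_uf, genes_df)
  genes_uf <- setdiff(genes_uf, shared)
  genes_df <- setdiff(genes_df, shared)
  lfc <- function(g) {
    m <- match(g, expression$gene)
    expression$log2fc[m[!is.na(m)]]
  }
  a <- lfc(genes_uf); b <- lfc(genes_df)
  t_stat <- p <- NA_real_
  if (length(a) < 2 || length(b) < 2) {
    warning("a gene set has fewer than 2 expression records; t-test skipped")
  } else {
    tt <- .pooled_t(a, b)
    t_stat <- tt$t; p <- tt$p
  }
  list(log2fc_uf = a, log2fc_df = b,
       median_uf = stats::median(a), median_df = stats::median(b),
       n_uf = length(a), n_df = length(b),
       t_statistic = t_stat, pvalue = p)
}

#' Build the tabular refined-SE report
#'
#' One row per (super-enhancer, contacted gene) with the SE locus, flow
#' label, CVD SNP count and traits, and the gene's expression statistics;
#' plus one summary row per SE (`row_type = "summary"`, gene fields empty).
#'
#' @param refined A [refine_flow_ses()] result.
#' @return Data frame with columns `row_type`, `se_id`, `chrom`, `start`,
#'   `end`, `label`, `n_cvd_snps`, `snp_traits`, `gene`, `log2fc`,
#'   `qvalue`.
#' @export
build_refined_matrix <- function(refined) {
  cols <- c("row_type", "se_id", "chrom", "start", "end", "label",
            "n_cvd_snps", "snp_traits", "gene", "log2fc", "qvalue")
  empty <- data.frame(row_type = character(0), se_id = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0),
                      n_cvd_snps = integer(0), snp_traits = character(0),
                      gene = character(0), log2fc = numeric(0),
                      qvalue = numeric(0), stringsAsFactors = FALSE)
  if (nrow(refined$ses) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(refined$ses))) {
    se <- refined$ses[i, ]
    g <- refined$genes[refined$genes$se_id == se$id, , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      row_type = "gene", se_id = se$id, chrom = se$chrom, start = se$start,
      end = se$end, label = se$label, n_cvd_snps = se$n_cvd_snps,
      snp_traits = se$snp_traits, gene = g$gene, log2fc = g$log2fc,
      qvalue = g$qvalue, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      row_type = "summary", se_id = se$id, chrom = se$chrom,
      start = se$start, end = se$end, label = se$label,
      n_cvd_snps = se$n_cvd_snps, snp_traits = se$snp_traits,
      gene = NA_character_, log2fc = NA_real_, qvalue = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)[, cols]
  rownames(out) <- NULL
  out
}

#' Write the refined-SE matrix
#' @param matrix Data frame from [build_refined_matrix()].
#' @param path Output path.
#' @export
write_refined_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#row_type\tse_id\tchrom\tstart\tend\tlabel\t",
                    "n_cvd_snps\tsnp_traits\tgene\tlog2fc\tqvalue"), con)
  if (nrow(matrix) > 0)
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s",
                       matrix$row_type, matrix$se_id, matrix$chrom,
                       as.integer(matrix$start), as.integer(matrix$end),
                       matrix$label, as.integer(matrix$n_cvd_snps),
                       matrix$snp_traits,
                       ifelse(is.na(matrix$gene), ".", matrix$gene),
                       ifelse(is.na(matrix$log2fc), ".",
                              sprintf("%.10g", matrix$log2fc)),
                       ifelse(is.na(matrix$qvalue), ".",
                              sprintf("%.10g", matrix$qvalue))), con)
  invisible(path)
}

#' Read a refined-SE matrix written by [write_refined_matrix()]
#' @param path Input path.
#' @return Data frame in the [build_refined_matrix()] layout.
#' @export
read_refined_matrix <- function(path) {
  tab <- .read_table_lines(path)
  empty <- build_refined_matrix(
    structure(list(ses = data.frame(), genes = data.frame()),
              class = "refined_ses"))
  if (length(tab$lines) == 0) return(empty)
  fields <- strsplit(tab$lines, "\t")
  get <- function(k) vapply(fields, `[`, character(1), k)
  num_or_na <- function(x) suppressWarnings(
    ifelse(x == ".", NA_real_, as.numeric(x)))
  data.frame(row_type = get(1), se_id = get(2), chrom = get(3),
             start = as.numeric(get(4)), end = as.numeric(get(5)),
             label = get(6), n_cvd_snps = as.integer(get(7)),
             snp_traits = get(8),
             gene = ifelse(get(9) == ".", NA_character_, get(9)),
             log2fc = num_or_na(get(10)), qvalue = num_or_na(get(11)),
             stringsAsFactors = FALSE)
}
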