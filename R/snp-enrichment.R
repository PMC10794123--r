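#' Expand lead SNPs with LD proxies
#'
#' Adds to the lead catalog every proxy with r-squared strictly above
#' `r2_min` lying within `window` bp of its lead, inheriting the lead's
#' trait and trait class. Output is deduplicated on (rsid, trait). Proxies
#' referencing an unknown lead are skipped with a warning.
#'
#' @param leads SNP data frame (see [read_snp_catalog()]); only `is_lead`
#'   rows are expanded but all rows are retained.
#' @param ld_pairs LD pair data frame (see [read_ld_pairs()]).
#' @param r2_min Strict lower bound on r-squared (default 0.8).
#' @param window Maximum lead-proxy distance in bp (default 1e5).
#' @return Deduplicated SNP data frame of leads plus qualifying proxies.
#' @export
expand_ld <- function(leads, ld_pairs, r2_min = 0.8, window = 1e5) {
  out <- leads
  if (nrow(ld_pairs) > 0) {
    m <- match(ld_pairs$lead_rsid, leads$rsid)
    unknown <- is.na(m)
    if (any(unknown)) {
      warning(sum(unknown), " LD pair(s) reference unknown leads; skipped")
      ld_pairs <- ld_pairs[!unknown, , drop = FALSE]
      m <- m[!unknown]
    }
    keep <- ld_pairs$r2 > r2_min &
      abs(ld_pairs$proxy_pos - leads$pos[m]) <= window
    ld_pairs <- ld_pairs[keep, , drop = FALSE]
    m <- m[keep]
    if (nrow(ld_pairs) > 0) {
      proxies <- data.frame(rsid = ld_pairs$proxy_rsid,
                            chrom = ld_pairs$proxy_chrom,
                            pos = ld_pairs$proxy_pos,
                            trait = leads$trait[m],
                            trait_class = leads$trait_class[m],
                            is_lead = FALSE, stringsAsFactors = FALSE)
      out <- rbind(out, proxies)
    }
  }
  out[!duplicated(out[, c("rsid", "trait")]), , drop = FALSE]
}

#' Binomial enrichment of SNPs in a region set
#'
#' Tests whether more SNPs fall inside the (merged) regions than expected
#' if the per-base probability of being a trait-associated SNP were the
#' same inside and outside: under the null each of the `m` SNPs lands
#' inside with probability `p0 = L_in / G`. The p-value is the exact
#' binomial upper tail `P(Bin(m, p0) >= k_in)`. The odds ratio compares the
#' SNP odds inside vs outside against the base-coverage odds:
#' `OR = k_in (G - L_in) / ((m - k_in) L_in)`, with a 0.5 continuity
#' correction on every factor only when some factor is zero. A SNP covered
#' by overlapping pre-merge regions counts once.
#'
#' @param snps SNP data frame.
#' @param regions Interval data frame (merged internally).
#' @param genome_size Total genome length G in bp.
#' @param label Label carried into the result.
#' @return One-row data frame: `label`, `k_in`, `m`, `L_in`, `G`, `pvalue`,
#'   `odds_ratio`.
#' @export
binomial_enrichment <- function(snps, regions, genome_size, label = "") {
  m <- nrow(snps)
  if (m == 0) stop("no SNPs for label ", label)
  merged <- merge_intervals(regions)
  L_in <- sum(merged$end - merged$start)
  if (genome_size <= L_in) stop("genome_size must exceed region coverage")
  pos_iv <- genomic_intervals(snps$chrom, snps$pos, snps$pos + 1)
  k_in <- sum(interval_overlaps(pos_iv, merged))
  p0 <- L_in / genome_size
  pvalue <- stats::pbinom(k_in - 1, m, p0, lower.tail = FALSE)
  num <- c(k_in, genome_size - L_in)
  den <- c(m - k_in, L_in)
  cc <- if (any(c(num, den) == 0)) 0.5 else 0
  odds_ratio <- prod(num + cc) / prod(den + cc)
  data.frame(label = label, k_in = k_in, m = m, L_in = L_in,
             G = genome_size, pvalue = pvalue, odds_ratio = odds_ratio,
             stringsAsFactors = FALSE)
}

#' Per-trait or per-class SNP enrichment with BH correction
#'
#' Runs [binomial_enrichment()] for every trait class (or trait) in the
#' catalog and applies Benjamini-Hochberg correction across the groups
#' tested in this run. A group is flagged significant when `qvalue < 0.05`
#' and `odds_ratio > 1`.
#'
#' @param snps SNP data frame with `trait` and `trait_class` columns.
#' @param regions Interval data frame.
#' @param genome_size Genome length in bp.
#' @param group_by `"trait_class"` (default) or `"trait"`.
#' @return Data frame of [binomial_enrichment()] rows plus `qvalue` and
#'   `significant`, ordered by `qvalue` then `label`.
#' @export
enrich_catalog <- function(snps, regions, genome_size,
                           group_by = c("trait_class", "trait")) {
  group_by <- match.arg(group_by)
  groups <- split(snps, snps[[group_by]])
  res <- do.call(rbind, lapply(names(groups), function(g)
    binomial_enrichment(groups[[g]], regions, genome_size, label = g)))
  res$qvalue <- stats::p.adjust(res$pvalue, method = "BH")
  res$significant <- res$qvalue < 0.05 & res$odds_ratio > 1
  res <- res[order(res$qvalue, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Keyword list used to curate cardiovascular-disease GWAS traits.
.cvd_keywords <- c("cardiovascular", "coronary artery", "coronary heart",
                   "myocardial infarction", "atherosclerosis", "plaque",
                   "thrombo", "stroke", "heart failure", "heart disease",
                   "heart defect", "ventricular", "atrial fibrillation",
                   "blood pressure", "hypertension", "valve", "carotid",
                   "peripheral")

#' Curate cardiovascular-disease traits by keyword
#'
#' Case-insensitive substring match of trait names against the standard
#' cardiovascular keyword list (cardiovascular, coronary artery/heart,
#' myocardial infarction, atherosclerosis, plaque, thrombo, stroke, heart
#' failure/disease/defect, ventricular, atrial fibrillation, blood
#' pressure, hypertension, valve, carotid, peripheral).
#'
#' @param traits Character vector of trait names.
#' @return The subset of `traits` matching at least one keyword.
#' @export
curate_cvd_traits <- function(traits) {
  hit <- Reduce(`|`, lapply(.cvd_keywords, function(k)
    grepl(k, traits, ignore.case = TRUE, fixed = FALSE)))
  traits[hit]
}
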