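#' Build an enhancer-to-gene contact map from promoter interactions
#'
#' An enhancer contacts a gene iff some interaction's other-end fragment
#' overlaps the enhancer by at least one base and the gene is among the
#' interaction's bait genes. Bait-side overlap with enhancers is ignored
#' (promoter fragments are baits by construction). Interactions are assumed
#' score-filtered upstream (see [read_interactions()]).
#'
#' @param enhancers Interval data frame with an `id` column.
#' @param interactions Interaction data frame (see [read_interactions()]).
#' @return An object of class `contact_map`: `pairs` (data frame
#'   `enhancer`, `gene`, `n_interactions` — distinct interaction records per
#'   pair) and `per_enhancer` (data frame `enhancer`, `n_records` — distinct
#'   interaction records hitting the enhancer, regardless of gene).
#' @export
annotate_contacts <- function(enhancers, interactions) {
  empty <- structure(list(
    pairs = data.frame(enhancer = character(0), gene = character(0),
                       n_interactions = integer(0), stringsAsFactors = FALSE),
    per_enhancer = data.frame(enhancer = character(0), n_records = integer(0),
                              stringsAsFactors = FALSE)), class = "contact_map")
  if (nrow(enhancers) == 0 || nrow(interactions) == 0) return(empty)
  oe <- genomic_intervals(interactions$oe_chrom, interactions$oe_start,
                          interactions$oe_end)
  # disjoint chromosome sets are a valid input, not a warning condition
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(oe), .as_granges(enhancers)))
  if (length(hits) == 0) return(empty)
  rec <- S4Vectors::queryHits(hits)     # interaction record index
  enh <- enhancers$id[S4Vectors::subjectHits(hits)]
  gene_lists <- strsplit(interactions$bait_genes[rec], ";", fixed = TRUE)
  reps <- lengths(gene_lists)
  long <- data.frame(enhancer = rep(enh, reps),
                     record = rep(rec, reps),
                     gene = unlist(gene_lists), stringsAsFactors = FALSE)
  long <- unique(long)
  agg <- stats::aggregate(record ~ enhancer + gene, data = long,
                          FUN = function(r) length(unique(r)))
  names(agg)[3] <- "n_interactions"
  agg <- agg[order(agg$enhancer, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  per_rec <- unique(data.frame(enhancer = enh, record = rec,
                               stringsAsFactors = FALSE))
  per_enh <- stats::aggregate(record ~ enhancer, data = per_rec, FUN = length)
  names(per_enh)[2] <- "n_records"
  structure(list(pairs = agg, per_enhancer = per_enh), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d enhancer-gene pairs over %d enhancer(s)\n",
              nrow(x$pairs), nrow(x$per_enhancer)))
  invisible(x)
}

#' Contacts per enhancer, compared between classes
#'
#' Counts the promoter-interaction records hitting each enhancer (zero for
#' enhancers without contacts) and compares the class means by a two-sided
#' Student's t-test (pooled variance).
#'
#' @param map_se,map_te `contact_map` objects for the two classes.
#' @param se,te Interval data frames defining the class memberships (ids).
#' @return List: `se_counts`, `te_counts`, `mean_se`, `mean_te`,
#'   `t_statistic`, `pvalue` (both `NA` with a warning when a class has
#'   fewer than 2 enhancers).
#' @export
contacts_per_enhancer <- function(map_se, map_te, se, te) {
  count_for <- function(map, ids) {
    m <- match(ids, map$per_enhancer$enhancer)
    n <- map$per_enhancer$n_records[m]
    n[is.na(n)] <- 0L
    n
  }
  se_counts <- count_for(map_se, se$id)
  te_counts <- count_for(map_te, te$id)
  t_stat <- p <- NA_real_
  if (length(se_counts) < 2 || length(te_counts) < 2) {
    warning("a class has fewer than 2 enhancers; t-test skipped")
  } else {
    tt <- .pooled_t(se_counts, te_counts)
    t_stat <- tt$t; p <- tt$p
  }
  list(se_counts = se_counts, te_counts = te_counts,
       mean_se = mean(se_counts), mean_te = mean(te_counts),
       t_statistic = t_stat, pvalue = p)
}

#' Distribution of repeated enhancer-promoter contacts
#'
#' The enhancer-gene contact frequency: over all (enhancer, gene) pairs in
#' a contact map, the normalized distribution of the number of distinct
#' interactions linking the pair.
#'
#' @param map A `contact_map`.
#' @return Named numeric vector (names = repeat count) summing to 1.
#' @export
contact_frequency_distribution <- function(map) {
  if (nrow(map$pairs) == 0) stop("empty contact map")
  tab <- table(map$pairs$n_interactions)
  out <- as.numeric(tab) / sum(tab)
  stats::setNames(out, names(tab))
}

#' Genes contacted by super-enhancers vs only by typical-enhancers
#'
#' @param map_se,map_te `contact_map` objects.
#' @return List: `se_contacted` (genes contacted by >= 1 SE), `te_only`
#'   (genes contacted by >= 1 TE but no SE).
#' @export
exclusive_gene_sets <- function(map_se, map_te) {
  se_genes <- unique(map_se$pairs$gene)
  te_genes <- unique(map_te$pairs$gene)
  list(se_contacted = sort(se_genes),
       te_only = sort(setdiff(te_genes, se_genes)))
}

#' Genes uniquely contacted by UF- vs DF-enriched super-enhancers
#'
#' @param map_uf,map_df `contact_map` objects restricted to UF- and
#'   DF-enriched super-enhancers.
#' @return List: `uf_only`, `df_only`, `shared`.
#' @export
flow_exclusive_gene_sets <- function(map_uf, map_df) {
  uf <- unique(map_uf$pairs$gene)
  df <- unique(map_df$pairs$gene)
  list(uf_only = sort(setdiff(uf, df)),
       df_only = sort(setdiff(df, uf)),
       shared = sort(intersect(uf, df)))
}

#' Restrict a contact map to a subset of enhancers
#'
#' @param map A `contact_map`.
#' @param ids Enhancer ids to keep.
#' @return A `contact_map` over the subset.
#' @export
subset_contact_map <- function(map, ids) {
  structure(list(
    pairs = map$pairs[map$pairs$enhancer %in% ids, , drop = FALSE],
    per_enhancer = map$per_enhancer[
      map$per_enhancer$enhancer %in% ids, , drop = FALSE]),
    class = "contact_map")
}
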