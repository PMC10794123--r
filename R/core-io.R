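#' Construct a set of genomic intervals
#'
#' The coordinate atom of the package: a data frame of half-open intervals
#' with columns `chrom`, `start`, `end` and an optional `id`. Coordinates are
#' 0-based, half-open (`start` inclusive, `end` exclusive), i.e. BED-native;
#' the interval length is `end - start`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer-like vector of 0-based inclusive start positions.
#' @param end Integer-like vector of exclusive end positions.
#' @param id Optional character vector of interval identifiers.
#' @return A data frame with columns `chrom`, `start`, `end`, `id`.
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  if (is.null(id)) id <- rep(NA_character_, length(chrom))
  data.frame(chrom = as.character(chrom), start = start, end = end,
             id = as.character(id), stringsAsFactors = FALSE)
}

# internal: 0-based half-open data frame -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# internal: GRanges -> 0-based half-open data frame
.from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             id = NA_character_, stringsAsFactors = FALSE)
}

#' Test each query interval for overlap with a subject interval set
#'
#' Overlap means at least one shared base under the half-open convention.
#'
#' @param query,subject Interval data frames (see [genomic_intervals()]).
#' @return Logical vector, one element per row of `query`.
#' @export
interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  suppressWarnings(  # disjoint chromosome sets are a valid input
    IRanges::overlapsAny(.as_granges(query), .as_granges(subject)))
}

#' Merge an interval set into disjoint intervals
#'
#' Intervals sharing at least one base are collapsed to their hull; abutting
#' intervals (zero overlap) stay separate.
#'
#' @param intervals Interval data frame.
#' @return Interval data frame of disjoint merged intervals, sorted.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  gr <- GenomicRanges::reduce(.as_granges(intervals), min.gapwidth = 0L)
  out <- .from_granges(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a tag library
#'
#' A tag library holds the 5' positions of mapped ChIP-seq tags, one sorted
#' numeric vector per chromosome, plus the total tag count used for
#' library-size normalization. Tags are single positions; fragment extension
#' is not modeled.
#'
#' @param tags Named list mapping chromosome name to a vector of 0-based tag
#'   positions (sorted internally).
#' @param label Condition/replicate label.
#' @return An object of class `TagLibrary`.
#' @export
tag_library <- function(tags, label = "") {
  if (!is.list(tags) || (length(tags) > 0 && is.null(names(tags))))
    stop("tags must be a named list of per-chromosome positions")
  tags <- lapply(tags, function(p) sort(as.numeric(p)))
  structure(list(tags = tags,
                 total_tags = sum(vapply(tags, length, integer(1))),
                 label = label),
            class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary '%s': %d tags on %d chromosome(s)\n",
              x$label, x$total_tags, length(x$tags)))
  invisible(x)
}

#' Count tags falling inside intervals
#'
#' For each interval, counts tag positions `p` with `start <= p < end` by
#' binary search on the per-chromosome sorted position vectors. A chromosome
#' absent from the library contributes zero.
#'
#' @param intervals Interval data frame.
#' @param library A [tag_library()].
#' @return Integer vector of tag counts, one per interval.
#' @export
count_tags_in <- function(intervals, library) {
  stopifnot(inherits(library, "TagLibrary"))
  n <- nrow(intervals)
  out <- integer(n)
  for (ch in unique(intervals$chrom)) {
    v <- library$tags[[ch]]
    if (is.null(v) || length(v) == 0) next
    idx <- which(intervals$chrom == ch)
    out[idx] <- findInterval(intervals$end[idx] - 0.5, v) -
      findInterval(intervals$start[idx] - 0.5, v)
  }
  out
}

.read_table_lines <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  list(lines = lines[keep], lineno = which(keep))
}

.split_fields <- function(lines) strsplit(lines, "[\t ]+")

#' Read a BED file of intervals
#'
#' Accepts BED3+ with whitespace- or tab-separated columns; lines starting
#' with `#` are skipped. The fourth column, when present, becomes the
#' interval `id`.
#'
#' @param path Path to a BED file.
#' @return Interval data frame in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- .read_table_lines(path)
  if (length(tab$lines) == 0)
    return(genomic_intervals(character(0), numeric(0), numeric(0))[0, ])
  fields <- .split_fields(tab$lines)
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 3))
    stop("fewer than 3 columns at line ", tab$lineno[which(n_col < 3)[1]])
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0)
  if (length(bad) > 0)
    stop("malformed coordinates at line ", tab$lineno[bad[1]])
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop("end <= start at line ", tab$lineno[bad[1]])
  id <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_,
               character(1))
  genomic_intervals(chrom, start, end, id)
}

#' Write intervals as BED
#'
#' @param intervals Interval data frame.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tid", con)
  if (nrow(intervals) > 0) {
    id <- ifelse(is.na(intervals$id), ".", intervals$id)
    writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                       as.integer(intervals$start), as.integer(intervals$end),
                       id), con)
  }
  invisible(path)
}

#' Read promoter interactions (ibed-like)
#'
#' Expects tab-separated columns: bait chrom/start/end, bait genes
#' (";"-separated), other-end chrom/start/end, interaction score. Records
#' below `min_score` are dropped on read, matching the practice of retaining
#' only strong (score >= 5) capture Hi-C interactions.
#'
#' @param path Path to interaction table.
#' @param min_score Minimum interaction confidence score to retain.
#' @return Data frame with columns `bait_chrom`, `bait_start`, `bait_end`,
#'   `bait_genes`, `oe_chrom`, `oe_start`, `oe_end`, `score`.
#' @export
read_interactions <- function(path, min_score = 5) {
  tab <- .read_table_lines(path)
  empty <- data.frame(bait_chrom = character(0), bait_start = numeric(0),
                      bait_end = numeric(0), bait_genes = character(0),
                      oe_chrom = character(0), oe_start = numeric(0),
                      oe_end = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(tab$lines) == 0) return(empty)
  fields <- strsplit(tab$lines, "\t")
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 8))
    stop("missing columns (need 8 incl. score) at line ",
         tab$lineno[which(n_col < 8)[1]])
  get <- function(k) vapply(fields, `[`, character(1), k)
  genes <- get(4)
  bad <- which(!nzchar(genes) | genes == ".")
  if (length(bad) > 0)
    stop("empty bait gene field at line ", tab$lineno[bad[1]])
  out <- data.frame(bait_chrom = get(1), bait_start = as.numeric(get(2)),
                    bait_end = as.numeric(get(3)), bait_genes = genes,
                    oe_chrom = get(5), oe_start = as.numeric(get(6)),
                    oe_end = as.numeric(get(7)), score = as.numeric(get(8)),
                    stringsAsFactors = FALSE)
  if (anyNA(out$score)) stop("non-numeric score in ", path)
  out[out$score >= min_score, , drop = FALSE]
}

#' Write promoter interactions
#' @param interactions Interaction data frame (see [read_interactions()]).
#' @param path Output path.
#' @export
write_interactions <- function(interactions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#baitChr\tbaitStart\tbaitEnd\tbaitGenes\t",
                    "oeChr\toeStart\toeEnd\tscore"), con)
  if (nrow(interactions) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%d\t%d\t%.6g",
                       interactions$bait_chrom,
                       as.integer(interactions$bait_start),
                       as.integer(interactions$bait_end),
                       interactions$bait_genes, interactions$oe_chrom,
                       as.integer(interactions$oe_start),
                       as.integer(interactions$oe_end),
                       interactions$score), con)
  invisible(path)
}

#' Read a trait-SNP catalog
#'
#' Tab-separated columns: rsid, chrom, pos (0-based), trait, trait class,
#' lead flag (0/1). Rows duplicated on (rsid, trait) are silently collapsed.
#'
#' @param path Path to SNP table.
#' @return Data frame with columns `rsid`, `chrom`, `pos`, `trait`,
#'   `trait_class`, `is_lead`.
#' @export
read_snp_catalog <- function(path) {
  tab <- .read_table_lines(path)
  empty <- data.frame(rsid = character(0), chrom = character(0),
                      pos = numeric(0), trait = character(0),
                      trait_class = character(0), is_lead = logical(0),
                      stringsAsFactors = FALSE)
  if (length(tab$lines) == 0) return(empty)
  fields <- strsplit(tab$lines, "\t")
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 6)) stop("need 6 columns at line ",
                           tab$lineno[which(n_col < 6)[1]])
  get <- function(k) vapply(fields, `[`, character(1), k)
  pos <- as.numeric(get(3))
  bad <- which(is.na(pos) | pos < 0)
  if (length(bad) > 0) stop("negative or malformed pos at line ",
                            tab$lineno[bad[1]])
  out <- data.frame(rsid = get(1), chrom = get(2), pos = pos,
                    trait = get(4), trait_class = get(5),
                    is_lead = get(6) %in% c("1", "TRUE", "true"),
                    stringsAsFactors = FALSE)
  out[!duplicated(out[, c("rsid", "trait")]), , drop = FALSE]
}

#' Write a trait-SNP catalog
#' @param snps SNP data frame (see [read_snp_catalog()]).
#' @param path Output path.
#' @export
write_snp_catalog <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#rsid\tchrom\tpos\ttrait\ttrait_class\tis_lead", con)
  if (nrow(snps) > 0)
    writeLines(sprintf("%s\t%s\t%d\t%s\t%s\t%d", snps$rsid, snps$chrom,
                       as.integer(snps$pos), snps$trait, snps$trait_class,
                       as.integer(snps$is_lead)), con)
  invisible(path)
}

#' Read an LD pair table
#'
#' Tab-separated columns: lead rsid, proxy rsid, proxy chrom, proxy pos, r2.
#' @param path Path to LD table.
#' @return Data frame `lead_rsid`, `proxy_rsid`, `proxy_chrom`, `proxy_pos`, `r2`.
#' @export
read_ld_pairs <- function(path) {
  tab <- .read_table_lines(path)
  empty <- data.frame(lead_rsid = character(0), proxy_rsid = character(0),
                      proxy_chrom = character(0), proxy_pos = numeric(0),
                      r2 = numeric(0), stringsAsFactors = FALSE)
  if (length(tab$lines) == 0) return(empty)
  fields <- strsplit(tab$lines, "\t")
  get <- function(k) vapply(fields, `[`, character(1), k)
  data.frame(lead_rsid = get(1), proxy_rsid = get(2), proxy_chrom = get(3),
             proxy_pos = as.numeric(get(4)), r2 = as.numeric(get(5)),
             stringsAsFactors = FALSE)
}

#' Write an LD pair table
#' @param ld_pairs LD pair data frame.
#' @param path Output path.
#' @export
write_ld_pairs <- function(ld_pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#lead_rsid\tproxy_rsid\tproxy_chrom\tproxy_pos\tr2", con)
  if (nrow(ld_pairs) > 0)
    writeLines(sprintf("%s\t%s\t%s\t%d\t%.4f", ld_pairs$lead_rsid,
                       ld_pairs$proxy_rsid, ld_pairs$proxy_chrom,
                       as.integer(ld_pairs$proxy_pos), ld_pairs$r2), con)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated columns: gene, FPKM under unidirectional flow, FPKM under
#' disturbed flow, log2 fold change (DF/UF), q-value.
#'
#' @param path Path to expression table.
#' @return Data frame `gene`, `fpkm_uf`, `fpkm_df`, `log2fc`, `qvalue`.
#' @export
read_expression <- function(path) {
  tab <- .read_table_lines(path)
  empty <- data.frame(gene = character(0), fpkm_uf = numeric(0),
                      fpkm_df = numeric(0), log2fc = numeric(0),
                      qvalue = numeric(0), stringsAsFactors = FALSE)
  if (length(tab$lines) == 0) return(empty)
  fields <- strsplit(tab$lines, "\t")
  get <- function(k) vapply(fields, `[`, character(1), k)
  out <- data.frame(gene = get(1), fpkm_uf = as.numeric(get(2)),
                    fpkm_df = as.numeric(get(3)), log2fc = as.numeric(get(4)),
                    qvalue = as.numeric(get(5)), stringsAsFactors = FALSE)
  if (any(out$fpkm_uf < 0 | out$fpkm_df < 0)) stop("negative FPKM in ", path)
  out
}

#' Write an expression table
#' @param expression Expression data frame.
#' @param path Output path.
#' @export
write_expression <- function(expression, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gene\tfpkm_uf\tfpkm_df\tlog2fc\tqvalue", con)
  if (nrow(expression) > 0)
    writeLines(sprintf("%s\t%.6g\t%.6g\t%.6g\t%.6g", expression$gene,
                       expression$fpkm_uf, expression$fpkm_df,
                       expression$log2fc, expression$qvalue), con)
  invisible(path)
}

#' Read gene models
#'
#' Tab-separated columns: gene, chrom, body start, body end, strand, TSS.
#' @param path Path to gene-model table.
#' @return Data frame `gene`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_gene_models <- function(path) {
  tab <- .read_table_lines(path)
  empty <- data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), tss = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(tab$lines) == 0) return(empty)
  fields <- strsplit(tab$lines, "\t")
  get <- function(k) vapply(fields, `[`, character(1), k)
  out <- data.frame(gene = get(1), chrom = get(2), start = as.numeric(get(3)),
                    end = as.numeric(get(4)), strand = get(5),
                    tss = as.numeric(get(6)), stringsAsFactors = FALSE)
  if (any(out$tss < out$start | out$tss > out$end))
    stop("TSS outside gene body in ", path)
  out
}

#' Write gene models
#' @param genes Gene-model data frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gene\tchrom\tstart\tend\tstrand\ttss", con)
  if (nrow(genes) > 0)
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s\t%d", genes$gene, genes$chrom,
                       as.integer(genes$start), as.integer(genes$end),
                       genes$strand, as.integer(genes$tss)), con)
  invisible(path)
}

#' Write a tag library
#'
#' Two-column tab-separated format (chrom, 0-based position) with a header
#' carrying the label and total count.
#' @param library A [tag_library()].
#' @param path Output path.
#' @export
write_tag_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#TagLibrary\tlabel=%s\ttotal=%d", library$label,
                     library$total_tags), con)
  writeLines("#chrom\tpos", con)
  for (ch in names(library$tags)) {
    p <- library$tags[[ch]]
    if (length(p) > 0)
      writeLines(sprintf("%s\t%d", ch, as.integer(p)), con)
  }
  invisible(path)
}

#' Read a tag library
#' @param path Path written by [write_tag_library()].
#' @return A [tag_library()].
#' @export
read_tag_library <- function(path) {
  lines <- readLines(path)
  label <- ""
  hdr <- grep("^#TagLibrary", lines, value = TRUE)
  if (length(hdr) == 1) {
    m <- regmatches(hdr, regexpr("label=[^\t]*", hdr))
    if (length(m) == 1) label <- sub("^label=", "", m)
  }
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (!any(keep)) return(tag_library(list(), label = label))
  fields <- strsplit(lines[keep], "\t")
  chrom <- vapply(fields, `[`, character(1), 1)
  pos <- as.numeric(vapply(fields, `[`, character(1), 2))
  tag_library(split(pos, chrom), label = label)
}
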