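#' Call peaks with a fixed-threshold binned caller
#'
#' A deliberately simple caller for the synthetic path: the genome is cut
#' into fixed-width bins, the input-normalized IP signal is computed per bin
#' (tags per `norm_total`), and bins exceeding `fold_min` times the global
#' background bin signal are merged into peaks. The background per-bin
#' signal is estimated from the median IP bin count, which is robust to the
#' small fraction of bins inside enhancers.
#'
#' @param ip,input IP and input [tag_library()] objects.
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 1000).
#' @param fold_min Minimum fold over background for a bin to be called.
#' @param norm_total Library normalization total (default 1e7).
#' @return Peak data frame: `chrom`, `start`, `end`, `id`, `summit`, `height`.
#' @export
call_peaks <- function(ip, input, genome, bin_size = 1000, fold_min = 1.5,
                       norm_total = 1e7) {
  if (ip$total_tags == 0 || input$total_tags == 0)
    stop("empty tag library")
  f_ip <- norm_total / ip$total_tags
  f_in <- norm_total / input$total_tags
  peaks <- list()
  for (ch in names(genome)) {
    n_bins <- ceiling(genome[[ch]] / bin_size)
    edges <- (0:n_bins) * bin_size
    v_ip <- ip$tags[[ch]]
    v_in <- input$tags[[ch]]
    c_ip <- if (is.null(v_ip)) rep(0, n_bins) else
      diff(findInterval(edges - 0.5, v_ip))
    c_in <- if (is.null(v_in)) rep(0, n_bins) else
      diff(findInterval(edges - 0.5, v_in))
    sig <- c_ip * f_ip - c_in * f_in
    bg <- stats::median(c_ip) * f_ip
    called <- sig > fold_min * max(bg, f_ip)  # floor guards empty chroms
    if (!any(called)) next
    r <- rle(called)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    for (j in which(r$values)) {
      b0 <- starts_idx[j]; b1 <- ends_idx[j]
      within <- b0:b1
      top <- within[which.max(c_ip[within])]
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, start = edges[b0], end = min(edges[b1 + 1], genome[[ch]]),
        id = NA_character_,
        summit = (edges[top] + min(edges[top + 1], genome[[ch]])) / 2,
        height = max(c_ip[within]), stringsAsFactors = FALSE)
    }
  }
  if (length(peaks) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), id = character(0),
                      summit = numeric(0), height = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, peaks)
  out$id <- sprintf("peak_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Stitch peaks into enhancer entities
#'
#' Peaks on the same chromosome whose gaps are at most `stitch_distance`
#' (default 12.5 kb) are chained into a single stitched enhancer spanning
#' their hull. Two peaks end up in the same enhancer iff they are connected
#' by a chain of gaps `<= stitch_distance`, where the gap is the distance
#' between the end of one peak and the start of the next. The operation is
#' idempotent and order-independent; output enhancers are disjoint, sorted,
#' and pairwise separated by more than `stitch_distance`.
#'
#' @param peaks Interval data frame (peaks; extra columns ignored).
#' @param stitch_distance Maximum gap in bp to bridge (default 12500).
#' @return Data frame of stitched enhancers: `chrom`, `start`, `end`, `id`,
#'   `n_peaks`, `peak_ids` (";"-joined ids of constituent peaks).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), id = character(0),
                      n_peaks = integer(0), peak_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) return(empty)
  if (is.null(peaks$id) || anyNA(peaks$id))
    peaks$id <- sprintf("peak_%d", seq_len(nrow(peaks)))
  out <- list()
  for (ch in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    cur_start <- p$start[1]; cur_end <- p$end[1]; ids <- p$id[1]
    flush <- function(s, e, ids) data.frame(
      chrom = ch, start = s, end = e, id = NA_character_,
      n_peaks = length(ids), peak_ids = paste(ids, collapse = ";"),
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(p))[-1]) {
      gap <- p$start[i] - cur_end
      if (gap <= stitch_distance) {
        cur_end <- max(cur_end, p$end[i])
        ids <- c(ids, p$id[i])
      } else {
        out[[length(out) + 1]] <- flush(cur_start, cur_end, ids)
        cur_start <- p$start[i]; cur_end <- p$end[i]; ids <- p$id[i]
      }
    }
    out[[length(out) + 1]] <- flush(cur_start, cur_end, ids)
  }
  out <- do.call(rbind, out)
  out$id <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                    as.integer(out$end))
  rownames(out) <- NULL
  out
}

#' Quantify input-normalized H3K27ac signal over enhancers
#'
#' Signal is the library-size-normalized IP tag count minus the normalized
#' input tag count over each enhancer interval, floored at zero:
#' `max(0, ip * norm_total/ip_total - input * norm_total/input_total)`.
#' Both libraries are scaled to `norm_total` tags (default 1e7), and the
#' input is subtracted per region.
#'
#' @param enhancers Interval data frame of stitched enhancers.
#' @param ip,input IP and input [tag_library()] objects.
#' @param norm_total Normalization total (tags; default 1e7).
#' @return `enhancers` with a `signal` column appended (or replaced).
#' @export
quantify_signal <- function(enhancers, ip, input, norm_total = 1e7) {
  if (ip$total_tags == 0 || input$total_tags == 0)
    stop("tag library with total_tags = 0")
  ip_c <- count_tags_in(enhancers, ip)
  in_c <- count_tags_in(enhancers, input)
  enhancers$signal <- pmax(0, ip_c * norm_total / ip$total_tags -
                              in_c * norm_total / input$total_tags)
  enhancers
}

#' Rank enhancer signals and locate the tangent cutoff
#'
#' Enhancer signals are sorted ascending and both axes rescaled to the unit
#' interval: `x_i = (i-1)/(n-1)`, `y_i = (s_i - s_1)/(s_n - s_1)`. The
#' cutoff is the discrete tangent point with slope 1, found as
#' `argmin_i (y_i - x_i)` with ties broken toward the larger index — for a
#' convex rank curve this is exactly where the forward slope first reaches 1.
#' Super-enhancers are the points strictly right of (above) the cutoff
#' signal.
#'
#' @param signals Numeric vector of enhancer signals (n >= 3, not constant).
#' @return An object of class `rank_curve`: `signals_sorted`, `x_scaled`,
#'   `y_scaled`, `cutoff_index`, `cutoff_signal`, `no_se_structure`.
#' @export
rank_and_cut <- function(signals) {
  n <- length(signals)
  if (n < 3 || diff(range(signals)) == 0)
    stop("degenerate rank curve (n < 3 or constant signals)")
  s <- sort(signals)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  d <- y - x
  i <- max(which(d == min(d)))
  structure(list(signals_sorted = s, x_scaled = x, y_scaled = y,
                 cutoff_index = i, cutoff_signal = s[i],
                 no_se_structure = min(d) > -1e-12),
            class = "rank_curve")
}

#' @export
print.rank_curve <- function(x, ...) {
  cat(sprintf(
    "rank_curve: n=%d, cutoff index %d (signal %.4g)%s\n",
    length(x$signals_sorted), x$cutoff_index, x$cutoff_signal,
    if (x$no_se_structure) " [no super-enhancer structure]" else ""))
  invisible(x)
}

#' Split enhancers into super- and typical-enhancers at the rank cutoff
#'
#' An enhancer is a super-enhancer iff its signal is strictly above the
#' cutoff signal; enhancers at or below the cutoff are typical-enhancers.
#'
#' @param enhancers Enhancer data frame with a `signal` column.
#' @param curve A [rank_and_cut()] result.
#' @return List of class `enhancer_catalog`: `super_enhancers`,
#'   `typical_enhancers` (data frames partitioning the input), `curve`.
#' @export
classify_enhancers <- function(enhancers, curve) {
  stopifnot(inherits(curve, "rank_curve"), !is.null(enhancers$signal))
  is_se <- enhancers$signal > curve$cutoff_signal
  structure(list(super_enhancers = enhancers[is_se, , drop = FALSE],
                 typical_enhancers = enhancers[!is_se, , drop = FALSE],
                 curve = curve),
            class = "enhancer_catalog")
}

#' @export
print.enhancer_catalog <- function(x, ...) {
  cat(sprintf("enhancer_catalog: %d super-enhancers, %d typical-enhancers\n",
              nrow(x$super_enhancers), nrow(x$typical_enhancers)))
  invisible(x)
}

#' Call an enhancer catalog for one condition
#'
#' Convenience wrapper: stitch peaks, quantify input-normalized signal,
#' rank and classify.
#'
#' @inheritParams stitch_peaks
#' @inheritParams quantify_signal
#' @return An `enhancer_catalog` (see [classify_enhancers()]).
#' @export
call_enhancer_catalog <- function(peaks, ip, input, stitch_distance = 12500,
                                  norm_total = 1e7) {
  enh <- stitch_peaks(peaks, stitch_distance)
  enh <- quantify_signal(enh, ip, input, norm_total)
  classify_enhancers(enh, rank_and_cut(enh$signal))
}

.merge_class <- function(a, b) {
  both <- rbind(a[, c("chrom", "start", "end"), drop = FALSE],
                b[, c("chrom", "start", "end"), drop = FALSE])
  merge_intervals(both)
}

#' Merge condition-wise enhancer catalogs
#'
#' Super-enhancers from the two flow conditions that overlap by at least one
#' base are merged into their hull; condition-unique ones pass through.
#' Typical-enhancers are merged the same way, and any merged
#' typical-enhancer that overlaps a merged super-enhancer is dropped from
#' the TE list. Per-condition signals are re-quantified over each merged
#' hull when the four tag libraries are supplied.
#'
#' @param catalog_uf,catalog_df `enhancer_catalog` objects for the
#'   unidirectional- and disturbed-flow conditions.
#' @param ip_uf,input_uf,ip_df,input_df Optional tag libraries used to
#'   re-quantify `signal_uf`/`signal_df` over merged hulls.
#' @param norm_total Normalization total.
#' @return List with `super_enhancers` and `typical_enhancers` data frames
#'   (columns `chrom`, `start`, `end`, `id`, and when libraries are given
#'   `signal_uf`, `signal_df`).
#' @export
merge_condition_catalogs <- function(catalog_uf, catalog_df,
                                     ip_uf = NULL, input_uf = NULL,
                                     ip_df = NULL, input_df = NULL,
                                     norm_total = 1e7) {
  se <- .merge_class(catalog_uf$super_enhancers, catalog_df$super_enhancers)
  te <- .merge_class(catalog_uf$typical_enhancers,
                     catalog_df$typical_enhancers)
  if (nrow(te) > 0 && nrow(se) > 0)
    te <- te[!interval_overlaps(te, se), , drop = FALSE]
  label <- function(df) {
    if (nrow(df) > 0)
      df$id <- sprintf("%s:%d-%d", df$chrom, as.integer(df$start),
                       as.integer(df$end))
    df
  }
  se <- label(se); te <- label(te)
  if (!is.null(ip_uf) && !is.null(input_uf) &&
      !is.null(ip_df) && !is.null(input_df)) {
    requant <- function(df) {
      if (nrow(df) == 0) { df$signal_uf <- df$signal_df <- numeric(0); return(df) }
      df$signal_uf <- quantify_signal(df, ip_uf, input_uf, norm_total)$signal
      df$signal_df <- quantify_signal(df, ip_df, input_df, norm_total)$signal
      df
    }
    se <- requant(se); te <- requant(te)
  }
  list(super_enhancers = se, typical_enhancers = te)
}

#' Genomic distribution of enhancers relative to gene models
#'
#' Each enhancer is assigned by its midpoint with precedence
#' promoter > intragenic > intergenic. The promoter window spans -1000 bp to
#' +100 bp around the TSS in the direction of transcription (strand-aware);
#' intragenic means the midpoint lies within a gene body.
#'
#' @param enhancers Interval data frame.
#' @param gene_models Gene-model data frame (see [read_gene_models()]).
#' @return Named numeric vector of fractions (`promoter`, `intragenic`,
#'   `intergenic`) summing to 1, with per-enhancer categories as attribute
#'   `category`.
#' @export
genomic_distribution <- function(enhancers, gene_models) {
  n <- nrow(enhancers)
  if (n == 0) stop("no enhancers")
  mid <- floor((enhancers$start + enhancers$end) / 2)
  cat_out <- rep("intergenic", n)
  if (nrow(gene_models) > 0) {
    plus <- gene_models$strand == "+"
    prom_start <- ifelse(plus, gene_models$tss - 1000, gene_models$tss - 99)
    prom_end <- ifelse(plus, gene_models$tss + 100, gene_models$tss + 1001)
    prom_start <- pmax(prom_start, 0)
    prom <- genomic_intervals(gene_models$chrom, prom_start, prom_end)
    body <- genomic_intervals(gene_models$chrom, gene_models$start,
                              gene_models$end)
    mids <- genomic_intervals(enhancers$chrom, mid, mid + 1)
    in_body <- interval_overlaps(mids, body)
    in_prom <- interval_overlaps(mids, prom)
    cat_out[in_body] <- "intragenic"
    cat_out[in_prom] <- "promoter"
  }
  frac <- c(promoter = mean(cat_out == "promoter"),
            intragenic = mean(cat_out == "intragenic"),
            intergenic = mean(cat_out == "intergenic"))
  attr(frac, "category") <- cat_out
  frac
}

#' Tag-count profile matrix around enhancer centers
#'
#' For each enhancer, tags are counted in fixed-width bins (window/bins bp,
#' 50 bp by default) across the enhancer center plus/minus half the window.
#' With `align_max_to_center`, each row is circularly shifted so that its
#' maximum bin (leftmost on ties) sits at the central bin, mirroring
#' max-aligned heatmap displays. The histogram is the per-bin column mean.
#'
#' @param enhancers Interval data frame.
#' @param library A [tag_library()].
#' @param window Total window width in bp (default 10000).
#' @param bins Number of bins (must divide `window`; default 200).
#' @param align_max_to_center Circularly align row maxima to the center bin.
#' @return List: `matrix` (n_enhancers x bins), `histogram` (length `bins`).
#' @export
profile_matrix <- function(enhancers, library, window = 10000, bins = 200,
                           align_max_to_center = FALSE) {
  if (window %% bins != 0) stop("window must be divisible by bins")
  bw <- window / bins
  n <- nrow(enhancers)
  mat <- matrix(0, nrow = n, ncol = bins)
  center_bin <- bins %/% 2
  for (i in seq_len(n)) {
    mid <- floor((enhancers$start[i] + enhancers$end[i]) / 2)
    edges <- mid - window / 2 + (0:bins) * bw
    v <- library$tags[[enhancers$chrom[i]]]
    row <- if (is.null(v)) rep(0, bins) else diff(findInterval(edges - 0.5, v))
    if (align_max_to_center && any(row > 0)) {
      shift <- center_bin - which.max(row)  # leftmost max on ties
      row <- row[((seq_len(bins) - 1 - shift) %% bins) + 1]
    }
    mat[i, ] <- row
  }
  list(matrix = mat, histogram = colMeans(mat))
}
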