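#' Fraction of enhancers containing a TF binding site
#'
#' TF evidence may be supplied either as a [tag_library()] of TF ChIP tags
#' ("contains a site" = at least one tag inside the enhancer) or as a peak
#' interval data frame (at least one overlapping base).
#'
#' @param enhancers Interval data frame (one enhancer class; non-empty).
#' @param tf TF evidence: a `TagLibrary` or an interval data frame.
#' @return Proportion in [0, 1].
#' @export
fraction_with_site <- function(enhancers, tf) {
  if (nrow(enhancers) == 0) stop("empty enhancer class")
  hit <- if (inherits(tf, "TagLibrary")) {
    count_tags_in(enhancers, tf) > 0
  } else {
    interval_overlaps(enhancers, tf)
  }
  mean(hit)
}

#' Length-normalized TF binding density per enhancer
#'
#' The library-size-normalized TF tag count within each enhancer (tags per
#' `norm_total`, the same convention as H3K27ac quantification) divided by
#' the enhancer length in bp.
#'
#' @param enhancers Interval data frame.
#' @param tf_library TF ChIP [tag_library()].
#' @param norm_total Normalization total (default 1e7).
#' @return Numeric vector of densities (normalized tags per bp).
#' @export
binding_density <- function(enhancers, tf_library, norm_total = 1e7) {
  len <- enhancers$end - enhancers$start
  if (any(len <= 0)) stop("zero-length enhancer interval")
  if (tf_library$total_tags == 0) return(rep(0, nrow(enhancers)))
  counts <- count_tags_in(enhancers, tf_library) *
    norm_total / tf_library$total_tags
  counts / len
}

#' Compare SE and TE binding-density distributions
#'
#' Bins both density vectors on a common grid, normalizes each histogram to
#' sum to 1, and reports the difference of medians (SE minus TE) as a
#' right-shift summary.
#'
#' @param se_densities,te_densities Non-empty numeric vectors.
#' @param bins Number of histogram bins (default 30).
#' @return List: `breaks`, `se_hist`, `te_hist` (each summing to 1),
#'   `median_diff`.
#' @export
density_histogram <- function(se_densities, te_densities, bins = 30) {
  if (length(se_densities) == 0 || length(te_densities) == 0)
    stop("both density vectors must be non-empty")
  rng <- range(c(se_densities, te_densities))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- function(x) {
    counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
    counts / sum(counts)
  }
  list(breaks = breaks, se_hist = h(se_densities), te_hist = h(te_densities),
       median_diff = stats::median(se_densities) -
         stats::median(te_densities))
}
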