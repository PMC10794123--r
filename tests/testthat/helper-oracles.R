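# Independent oracles used to cross-check the implementation. These are
# deliberately naive (linear scans, union-find, direct log-space summation)
# and share no code with the package internals.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# linear-scan tag counter
oracle_count_linear <- function(chrom, start, end, lib) {
  v <- lib$tags[[chrom]]
  if (is.null(v)) return(0L)
  sum(v >= start & v < end)
}

# union-find stitching: peaks connect when their interval distance <= d
oracle_stitch_unionfind <- function(peaks, d = 12500) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && peaks$chrom[i] == peaks$chrom[j]) {
      gap <- max(peaks$start[i], peaks$start[j]) -
        min(peaks$end[i], peaks$end[j])
      if (gap <= d) parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  out <- do.call(rbind, lapply(comp, function(idx) data.frame(
    chrom = peaks$chrom[idx[1]], start = min(peaks$start[idx]),
    end = max(peaks$end[idx]), n_peaks = length(idx),
    stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# first index whose forward discrete slope (unit-scaled) reaches 1
oracle_tangent_index <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  slopes <- diff(y) / diff(x)
  i <- which(slopes >= 1)[1]
  if (is.na(i)) n else i
}

# direct log-space Poisson upper tail P(X >= obs)
oracle_poisson_tail <- function(obs, lambda) {
  if (obs <= 0) return(1)
  k <- obs:(obs + 3000)
  exp(logsumexp(k * log(lambda) - lambda - lgamma(k + 1)))
}

# direct log-space binomial upper tail P(X >= k)
oracle_binom_tail <- function(k, m, p) {
  if (k <= 0) return(1)
  j <- k:m
  exp(logsumexp(lchoose(m, j) + j * log(p) + (m - j) * log1p(-p)))
}

# quadratic-scan contact map: pairs (enhancer, gene, n distinct records)
oracle_contact_pairs <- function(enhancers, interactions) {
  rows <- list()
  for (i in seq_len(nrow(enhancers))) for (j in seq_len(nrow(interactions))) {
    if (interactions$oe_chrom[j] == enhancers$chrom[i] &&
        interactions$oe_start[j] < enhancers$end[i] &&
        interactions$oe_end[j] > enhancers$start[i]) {
      for (g in strsplit(interactions$bait_genes[j], ";")[[1]])
        rows[[length(rows) + 1]] <- data.frame(
          enhancer = enhancers$id[i], record = j, gene = g,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(enhancer = character(0), gene = character(0),
                      n_interactions = integer(0), stringsAsFactors = FALSE))
  long <- unique(do.call(rbind, rows))
  agg <- aggregate(record ~ enhancer + gene, data = long, FUN = length)
  names(agg)[3] <- "n_interactions"
  agg <- agg[order(agg$enhancer, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# closed-form pooled-variance two-sided Student's t-test
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# random fixtures -----------------------------------------------------------

rand_library <- function(n_tags, genome = c(chr1 = 1e5, chr2 = 5e4)) {
  ch <- sample(names(genome), n_tags, replace = TRUE)
  tag_library(split(floor(runif(n_tags) * genome[ch]), ch))
}

rand_intervals <- function(n, genome = c(chr1 = 1e5, chr2 = 5e4),
                           max_width = 5000) {
  ch <- sample(names(genome), n, replace = TRUE)
  w <- floor(runif(n, 1, max_width))
  s <- floor(runif(n) * (genome[ch] - w))
  genomic_intervals(ch, s, s + w, sprintf("iv_%d", seq_len(n)))
}
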