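peak_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             id = sprintf("p%d", seq_along(start)), stringsAsFactors = FALSE)
}

test_that("stitching bridges gaps at or below 12.5 kb and splits larger ones", {
  near <- stitch_peaks(peak_df("chr1", c(100, 12000), c(600, 12400)))
  expect_equal(nrow(near), 1)
  expect_equal(c(near$start, near$end), c(100, 12400))
  expect_equal(near$n_peaks, 2)

  far <- stitch_peaks(peak_df("chr1", c(100, 13200), c(600, 13600)))
  expect_equal(nrow(far), 2)

  # exactly at the threshold: gap 12,500 stitches
  at <- stitch_peaks(peak_df("chr1", c(0, 13000), c(500, 13500)))
  expect_equal(nrow(at), 1)

  expect_equal(nrow(stitch_peaks(peak_df(character(0), numeric(0),
                                         numeric(0)))), 0)
})

test_that("stitching equals union-find on random peak sets and is idempotent", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    p <- rand_intervals(n, genome = c(chr1 = 3e5, chr2 = 2e5),
                        max_width = 8000)
    got <- stitch_peaks(p)
    want <- oracle_stitch_unionfind(p)
    expect_equal(got[, c("chrom", "start", "end", "n_peaks")], want,
                 ignore_attr = TRUE)
    # order independence
    shuffled <- p[sample(nrow(p)), , drop = FALSE]
    expect_equal(stitch_peaks(shuffled)[, c("chrom", "start", "end")],
                 got[, c("chrom", "start", "end")], ignore_attr = TRUE)
    # idempotence and gap invariant
    again <- stitch_peaks(got)
    expect_equal(again[, c("chrom", "start", "end")],
                 got[, c("chrom", "start", "end")], ignore_attr = TRUE)
    for (ch in unique(got$chrom)) {
      g <- got[got$chrom == ch, ]
      if (nrow(g) > 1)
        expect_true(all(g$start[-1] - g$end[-nrow(g)] > 12500))
    }
  }
})

test_that("signal quantification normalizes, subtracts input and floors at zero", {
  enh <- genomic_intervals("chr1", 0, 1000)
  set.seed(2)
  ip <- tag_library(list(chr1 = floor(seq(5, 995, length.out = 100)),
                         chr2 = floor(runif(999900) * 1e6)))
  input <- tag_library(list(chr1 = floor(seq(10, 990, length.out = 20)),
                            chr2 = floor(runif(999980) * 1e6)))
  got <- quantify_signal(enh, ip, input, norm_total = 1e7)$signal
  expect_equal(got, 100 * 1e7 / 1e6 - 20 * 1e7 / 1e6)  # 1000 - 200 = 800

  # floored when input exceeds IP after normalization
  got0 <- quantify_signal(enh, input, ip, norm_total = 1e7)$signal
  expect_equal(got0, 0)

  empty <- tag_library(list())
  expect_error(quantify_signal(enh, empty, input), "total_tags = 0")
})

test_that("rank curve puts the tangent cutoff at the slope-1 crossing", {
  curve <- rank_and_cut(c(1, 2, 3, 4, 100))
  expect_equal(curve$cutoff_index, 4)
  expect_equal(curve$cutoff_signal, 4)
  cat <- classify_enhancers(
    data.frame(chrom = "chr1", start = 0:4 * 1000, end = 0:4 * 1000 + 500,
               id = letters[1:5], signal = c(1, 2, 3, 4, 100)), curve)
  expect_equal(cat$super_enhancers$signal, 100)
  expect_equal(sort(cat$typical_enhancers$signal), c(1, 2, 3, 4))

  # perfectly linear signals: tie-break to the last index, flagged
  lin <- rank_and_cut(c(1, 2, 3, 4, 5))
  expect_equal(lin$cutoff_index, 5)
  expect_true(lin$no_se_structure)

  expect_error(rank_and_cut(c(1, 2)), "degenerate")
  expect_error(rank_and_cut(rep(3, 10)), "degenerate")
})

test_that("tangent cutoff matches the slope-crossing oracle on convex curves", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(50:500, 1)
    s <- cumsum(sort(rexp(n)))
    expect_equal(rank_and_cut(s)$cutoff_index, oracle_tangent_index(s))
  }
})

test_that("rank cutoff index is invariant to positive affine signal transforms", {
  set.seed(6)
  s <- cumsum(sort(rexp(100)))
  base <- rank_and_cut(s)$cutoff_index
  for (a in c(0.01, 3, 1e4)) for (b in c(-5, 0, 100))
    expect_equal(rank_and_cut(a * s + b)$cutoff_index, base)
})

test_that("classification at the cutoff boundary assigns equal signals to TEs", {
  curve <- rank_and_cut(c(1, 4, 4.5, 100))
  curve$cutoff_signal <- 4
  enh <- data.frame(chrom = "chr1", start = c(0, 10, 20) * 1000,
                    end = c(5, 15, 25) * 1000, id = c("a", "b", "c"),
                    signal = c(1, 4, 100))
  cat <- classify_enhancers(enh, curve)
  expect_equal(cat$super_enhancers$id, "c")
  expect_equal(sort(cat$typical_enhancers$id), c("a", "b"))
  expect_equal(nrow(cat$super_enhancers) + nrow(cat$typical_enhancers),
               nrow(enh))

  # all below the cutoff: no super-enhancers
  curve$cutoff_signal <- 1e6
  expect_equal(nrow(classify_enhancers(enh, curve)$super_enhancers), 0)
})

test_that("condition merging takes hulls of overlapping SEs and drops clashing TEs", {
  mk_cat <- function(se, te) structure(list(super_enhancers = se,
                                            typical_enhancers = te),
                                       class = "enhancer_catalog")
  se_uf <- genomic_intervals("chr1", 0, 10000, "u1")
  se_df <- genomic_intervals("chr1", 5000, 15000, "d1")
  te_uf <- genomic_intervals("chr1", 40000, 41000, "u2")
  te_df <- genomic_intervals("chr1", 12000, 13000, "d2")  # overlaps merged SE
  m <- merge_condition_catalogs(mk_cat(se_uf, te_uf), mk_cat(se_df, te_df))
  expect_equal(nrow(m$super_enhancers), 1)
  expect_equal(c(m$super_enhancers$start, m$super_enhancers$end), c(0, 15000))
  expect_equal(nrow(m$typical_enhancers), 1)
  expect_equal(m$typical_enhancers$start, 40000)

  # disjoint SE sets pass through
  m2 <- merge_condition_catalogs(
    mk_cat(genomic_intervals("chr1", 0, 1000), te_uf[0, ]),
    mk_cat(genomic_intervals("chr2", 0, 1000), te_uf[0, ]))
  expect_equal(nrow(m2$super_enhancers), 2)
})

test_that("condition merging equals a brute-force all-pairs overlap merge", {
  set.seed(9)
  for (rep in 1:10) {
    a <- rand_intervals(sample(3:40, 1), max_width = 20000)
    b <- rand_intervals(sample(3:40, 1), max_width = 20000)
    mk_cat <- function(se) structure(
      list(super_enhancers = se, typical_enhancers = se[0, ]),
      class = "enhancer_catalog")
    got <- merge_condition_catalogs(mk_cat(a), mk_cat(b))$super_enhancers
    want <- oracle_stitch_unionfind(rbind(a, b), d = -1)  # overlap only
    expect_equal(got[, c("chrom", "start", "end")],
                 want[, c("chrom", "start", "end")], ignore_attr = TRUE)
  }
})

test_that("genomic distribution applies promoter > intragenic > intergenic", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                      start = c(10000, 50000), end = c(30000, 80000),
                      strand = c("+", "-"), tss = c(10000, 80000),
                      stringsAsFactors = FALSE)
  enh <- genomic_intervals("chr1",
                           c(9400, 20000, 90000),  # mids 9500+100, in-body, far
                           c(9800, 20200, 90200))
  frac <- genomic_distribution(enh, genes)
  expect_equal(attr(frac, "category"), c("promoter", "intragenic",
                                         "intergenic"))
  expect_equal(sum(frac), 1)

  # no gene models: everything intergenic
  frac0 <- genomic_distribution(enh, genes[0, ])
  expect_equal(unname(frac0["intergenic"]), 1)

  # minus-strand promoter window sits downstream of the TSS coordinate
  enh_m <- genomic_intervals("chr1", 80400, 80600)  # mid 500 bp "upstream" of G2
  expect_equal(attr(genomic_distribution(enh_m, genes), "category"),
               "promoter")
})

test_that("profile rows conserve window tag counts and align maxima centrally", {
  enh <- genomic_intervals("chr1", 4000, 6000, "e1")  # center 5000
  lib <- tag_library(list(chr1 = c(5000)))
  pm <- profile_matrix(enh, lib, window = 10000, bins = 200)
  expect_equal(sum(pm$matrix), 1)
  expect_equal(sum(pm$matrix[1, ] > 0), 1)

  pm_c <- profile_matrix(enh, lib, window = 10000, bins = 200,
                         align_max_to_center = TRUE)
  expect_equal(which.max(pm_c$matrix[1, ]), 100)

  set.seed(13)
  lib2 <- rand_library(5000, genome = c(chr1 = 1e5))
  enh2 <- rand_intervals(20, genome = c(chr1 = 1e5), max_width = 3000)
  enh2 <- enh2[enh2$start > 6000 & enh2$end < 94000, , drop = FALSE]
  pm2 <- profile_matrix(enh2, lib2)
  centers <- floor((enh2$start + enh2$end) / 2)
  want <- count_tags_in(genomic_intervals(enh2$chrom, centers - 5000,
                                          centers + 5000), lib2)
  expect_equal(unname(rowSums(pm2$matrix)), as.numeric(want))
  expect_equal(pm2$histogram, colMeans(pm2$matrix))
})

test_that("synthetic catalogs keep the SE/TE partition invariants", {
  run <- default_run()
  for (cat in list(run$catalog_uf, run$catalog_df)) {
    se <- cat$super_enhancers; te <- cat$typical_enhancers
    expect_equal(nrow(se) + nrow(te), length(cat$curve$signals_sorted))
    if (nrow(se) > 0 && nrow(te) > 0)
      expect_gt(min(se$signal), max(te$signal))
    # SE minority: qualitative mirror of genome-wide SE scarcity
    expect_lt(nrow(se) / (nrow(se) + nrow(te)), 0.1)
  }
})
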