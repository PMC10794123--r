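# a reduced configuration for generator-level checks
small_config <- function(...) {
  args <- utils::modifyList(
    list(genome = c(chr1 = 2e6, chr2 = 2e6),
         n_enhancer_sites = 40, n_se_planted = 8,
         n_uf_planted = 2, n_df_planted = 2,
         library_size = 2e5, n_genes = 80,
         n_snps_per_trait = 200, n_decoy_interactions = 50,
         seed = 1),
    list(...))
  do.call(simulation_config, args)
}

test_that("configuration validation rejects inconsistent plantings", {
  expect_error(simulation_config(n_uf_planted = 15, n_df_planted = 10,
                                 n_se_planted = 20), "must not exceed")
  expect_error(simulation_config(n_se_planted = 300,
                                 n_enhancer_sites = 200), "must not exceed")
  expect_error(simulation_config(flow_fc = 0), "multipliers")
  expect_error(
    simulate_snp_catalog(small_config(planted_or = -1),
                         simulate_tag_libraries(small_config())$truth),
    "planted_or")
})

test_that("tag library generation is fully deterministic under a fixed seed", {
  cfg <- small_config()
  a <- simulate_tag_libraries(cfg)
  b <- simulate_tag_libraries(cfg)
  expect_identical(a$ip_uf$tags, b$ip_uf$tags)
  expect_identical(a$ip_df$tags, b$ip_df$tags)
  expect_identical(a$input_uf$tags, b$input_uf$tags)
  expect_identical(a$truth$se_sites, b$truth$se_sites)
  # and a different seed changes the draw
  c2 <- simulate_tag_libraries(small_config(seed = 2))
  expect_false(identical(a$ip_uf$tags, c2$ip_uf$tags))
})

test_that("tag libraries satisfy their structural invariants", {
  sim <- simulate_tag_libraries(small_config())
  for (lib in sim[c("ip_uf", "input_uf", "ip_df", "input_df")]) {
    expect_s3_class(lib, "TagLibrary")
    expect_true(all(vapply(lib$tags, function(p) !is.unsorted(p),
                           logical(1))))
    expect_equal(lib$total_tags, sum(lengths(lib$tags)))
  }
  labels <- c(sim$truth$se_sites$flow_label)
  expect_equal(sum(labels == "UF"), 2)
  expect_equal(sum(labels == "DF"), 2)
  expect_equal(sum(labels == "CORE"), 4)
})

test_that("a unit multiplier leaves planted sites at background intensity", {
  cfg <- small_config(se_signal_multiplier = 1.0001,
                      te_signal_multiplier = 1.0001, flow_fc = 1)
  sim <- simulate_tag_libraries(cfg)
  rate <- cfg$library_size / sum(cfg$genome)
  sites <- rbind(sim$truth$se_sites[, c("chrom", "start", "end")],
                 sim$truth$te_sites[, c("chrom", "start", "end")])
  counts <- count_tags_in(sites, sim$ip_uf)
  expected <- rate * (sites$end - sites$start)
  z <- (counts - expected) / sqrt(expected)
  expect_lt(abs(mean(z)), 3 / sqrt(nrow(sites)))
})

test_that("planted flow fold change appears in the DF/UF count ratio", {
  cfg <- simulation_config(seed = 4)  # default depth 1e6
  sim <- simulate_tag_libraries(cfg)
  df_sites <- sim$truth$se_sites[sim$truth$se_sites$flow_label == "DF", ]
  c_uf <- sum(count_tags_in(df_sites, sim$ip_uf))
  c_df <- sum(count_tags_in(df_sites, sim$ip_df))
  ratio <- (c_df / sim$ip_df$total_tags) / (c_uf / sim$ip_uf$total_tags)
  expect_equal(ratio, cfg$flow_fc, tolerance = 0.1)

  uf_sites <- sim$truth$se_sites[sim$truth$se_sites$flow_label == "UF", ]
  r_uf <- (sum(count_tags_in(uf_sites, sim$ip_df)) / sim$ip_df$total_tags) /
    (sum(count_tags_in(uf_sites, sim$ip_uf)) / sim$ip_uf$total_tags)
  expect_equal(r_uf, 1 / cfg$flow_fc, tolerance = 0.1)
})

test_that("too-shallow libraries are rejected with advice", {
  expect_error(simulate_tag_libraries(small_config(library_size = 300)),
               "increase library_size")
})

test_that("planted interactions always link SEs to promoters with score >= 5", {
  cfg <- small_config()
  sim <- simulate_tag_libraries(cfg)
  truth <- simulate_gene_models(cfg, sim$truth)
  inter <- simulate_interactions(cfg, truth)
  strong <- inter[inter$score >= 5, ]
  m <- annotate_contacts(truth$se_sites, strong)
  for (i in seq_len(nrow(truth$se_gene_links)))
    expect_true(any(m$pairs$enhancer == truth$se_gene_links$se_id[i] &
                      m$pairs$gene == truth$se_gene_links$gene[i]))

  # repeated-contact fraction 1: every planted link has >= 2 interactions
  cfg2 <- small_config(repeated_contact_fraction = 1)
  truth2 <- simulate_gene_models(cfg2, simulate_tag_libraries(cfg2)$truth)
  m2 <- annotate_contacts(truth2$se_sites,
                          simulate_interactions(cfg2, truth2))
  planted2 <- merge(m2$pairs, truth2$se_gene_links,
                    by.x = c("enhancer", "gene"),
                    by.y = c("se_id", "gene"))
  expect_true(all(planted2$n_interactions >= 2))

  # no planted SEs: only decoys remain
  cfg0 <- small_config(n_se_planted = 0, n_uf_planted = 0, n_df_planted = 0)
  truth0 <- simulate_gene_models(cfg0, simulate_tag_libraries(cfg0)$truth)
  inter0 <- simulate_interactions(cfg0, truth0)
  expect_equal(nrow(inter0), cfg0$n_decoy_interactions)
})

test_that("planted SNP enrichment realizes the requested odds ratio", {
  cfg <- small_config(n_snps_per_trait = 1000)
  sim <- simulate_tag_libraries(cfg)
  # null planting: inside/outside rates match coverage
  snp_null <- simulate_snp_catalog(small_config(planted_or = 1), sim$truth)
  res_null <- binomial_enrichment(
    snp_null$snps[snp_null$snps$trait_class == "Cardiovascular", ],
    sim$truth$se_sites, sum(cfg$genome))
  expect_gt(res_null$pvalue, 1e-3)

  # Monte-Carlo: pooled OR estimate near the planted value
  ors <- vapply(1:50, function(s) {
    snp <- simulate_snp_catalog(small_config(seed = s,
                                             n_snps_per_trait = 1000),
                                sim$truth)
    cls <- snp$snps[snp$snps$trait_class == "Cardiovascular", ]
    binomial_enrichment(cls, sim$truth$se_sites,
                        sum(cfg$genome))$odds_ratio
  }, numeric(1))
  expect_equal(mean(ors), 1.5, tolerance = 0.1)
})

test_that("LD proxies stay within 100 kb of their leads", {
  cfg <- small_config()
  snp <- simulate_snp_catalog(cfg, simulate_tag_libraries(cfg)$truth)
  m <- match(snp$ld_pairs$lead_rsid, snp$snps$rsid)
  expect_true(all(!is.na(m)))
  expect_true(all(abs(snp$ld_pairs$proxy_pos - snp$snps$pos[m]) <= 1e5))
})

test_that("expression fold changes track the contacting SE flow class", {
  cfg <- small_config()
  truth <- simulate_gene_models(cfg, simulate_tag_libraries(cfg)$truth)
  # average over many draws: DF-linked genes up, unlinked genes near zero
  lfc_df <- lfc_null <- numeric(0)
  for (s in 1:30) {
    cfg_s <- small_config(seed = s)
    expr <- simulate_expression(cfg_s, truth)
    df_genes <- truth$se_gene_links$gene[truth$se_gene_links$flow_label == "DF"]
    linked <- truth$se_gene_links$gene
    lfc_df <- c(lfc_df, expr$log2fc[expr$gene %in% df_genes])
    lfc_null <- c(lfc_null, expr$log2fc[!(expr$gene %in% linked)])
  }
  expect_gt(mean(lfc_df), 0)
  expect_lt(abs(mean(lfc_null)), 3 * sd(lfc_null) / sqrt(length(lfc_null)))
  expr <- simulate_expression(cfg, truth)
  expect_true(all(expr$fpkm_uf >= 0 & expr$fpkm_df >= 0))
  expect_equal(expr$log2fc,
               log2((expr$fpkm_df + 0.01) / (expr$fpkm_uf + 0.01)))
})

test_that("simulate_study writes a readable, consistent input bundle", {
  dir <- withr::local_tempdir()
  cfg <- small_config()
  sim <- simulate_study(cfg, dir)
  lib <- read_tag_library(file.path(dir, "tags_uf_ip.tsv"))
  expect_equal(lib$total_tags, sim$libraries$ip_uf$total_tags)
  expect_equal(nrow(read_snp_catalog(file.path(dir, "snp_catalog.tsv"))),
               nrow(sim$snp$snps))
  expect_equal(nrow(read_interactions(file.path(dir, "interactions.ibed"),
                                      min_score = 0)),
               nrow(sim$interactions))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$enriched_class, "Cardiovascular")
  expect_equal(length(truth$se_sites$id), nrow(sim$truth$se_sites))
})
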