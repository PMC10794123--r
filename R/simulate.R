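#' Simulation configuration with planted ground truth parameters
#'
#' Defines the synthetic study: a small genome carrying planted enhancer
#' sites (a minority of wide, high-signal super-enhancer sites and a
#' majority of narrower typical-enhancer sites), two-condition ChIP tag
#' libraries with condition-specific rate multipliers for flow-sensitive
#' sites, promoter-interaction lists preferentially linking planted SEs to
#' genes, trait-SNP catalogs with one class enriched inside SEs at a chosen
#' odds ratio, and expression tables whose flow fold changes track the
#' contacting SE class.
#'
#' Defaults are sized for a desk-scale run: a 2 x 10 Mb genome, 200
#' enhancer sites of which 12 are super-enhancers (20 kb, 5x background
#' rate; typical sites 2 kb, 3x), 3 UF- and 3 DF-enriched SEs at a 2-fold
#' flow rate change, 1e6 tags per library, and per-class SNP catalogs of
#' 5,000 with the cardiovascular class planted at odds ratio 1.5.
#'
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param n_enhancer_sites Total planted enhancer sites.
#' @param n_se_planted Number of planted super-enhancer sites.
#' @param se_signal_multiplier Tag-rate multiplier at SE sites vs background.
#' @param te_signal_multiplier Multiplier at typical-enhancer sites.
#' @param se_width,te_width Site widths in bp.
#' @param flow_fc Planted DF/UF rate ratio at flow-sensitive SEs.
#' @param n_uf_planted,n_df_planted Numbers of UF-/DF-enriched SEs
#'   (the remainder of the planted SEs are flow-insensitive CORE).
#' @param library_size Expected background tags per library.
#' @param n_genes Number of simulated genes.
#' @param trait_classes Trait classes in the SNP catalog.
#' @param n_traits_per_class Traits per class.
#' @param n_snps_per_trait SNPs per trait.
#' @param planted_or Odds ratio of per-base SNP probability inside vs
#'   outside SEs for the enriched class.
#' @param enriched_class The trait class carrying the planted enrichment.
#' @param interaction_score_range Score range for planted interactions
#'   (kept at/above the score-5 retention threshold).
#' @param n_decoy_interactions Random decoy interactions with scores on
#'   both sides of 5.
#' @param repeated_contact_fraction Fraction of planted SE-gene links that
#'   receive a second distinct other-end fragment.
#' @param expr_log2fc_mean Mean |log2FC| planted for genes linked to
#'   flow-sensitive SEs (negative for UF-linked, positive for DF-linked).
#' @param expr_log2fc_sd SD of the planted log2FC.
#' @param seed RNG seed (must be < 2^31 - 5; sub-generators use small
#'   fixed offsets).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome = c(chr1 = 1e7, chr2 = 1e7),
                              n_enhancer_sites = 200,
                              n_se_planted = 12,
                              se_signal_multiplier = 5,
                              te_signal_multiplier = 3,
                              se_width = 20000, te_width = 2000,
                              flow_fc = 2,
                              n_uf_planted = 3, n_df_planted = 3,
                              library_size = 1e6,
                              n_genes = 400,
                              trait_classes = c("Cardiovascular", "Metabolic",
                                                "Immune", "Neurological",
                                                "Cancer"),
                              n_traits_per_class = 5,
                              n_snps_per_trait = 1000,
                              planted_or = 1.5,
                              enriched_class = "Cardiovascular",
                              interaction_score_range = c(5, 10),
                              n_decoy_interactions = 300,
                              repeated_contact_fraction = 0.5,
                              expr_log2fc_mean = 1,
                              expr_log2fc_sd = 0.4,
                              seed = 1) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("n_enhancer_sites", "n_se_planted", "library_size",
                       "n_genes", "n_snps_per_trait")]) < 0))
    stop("counts must be >= 0")
  if (cfg$se_signal_multiplier <= 0 || cfg$te_signal_multiplier <= 0 ||
      cfg$flow_fc <= 0)
    stop("multipliers must be > 0")
  if (cfg$n_uf_planted + cfg$n_df_planted > cfg$n_se_planted)
    stop("n_uf_planted + n_df_planted must not exceed n_se_planted")
  if (cfg$n_se_planted > cfg$n_enhancer_sites)
    stop("n_se_planted must not exceed n_enhancer_sites")
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Only keys matching [simulation_config()] arguments may appear; `genome`
#' is a mapping chromosome -> length.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genome)) y$genome <- unlist(y$genome)
  if (!is.null(y$interaction_score_range))
    y$interaction_score_range <- as.numeric(y$interaction_score_range)
  bad <- setdiff(names(y), names(formals(simulation_config)))
  if (length(bad) > 0) stop("unknown config key(s): ",
                            paste(bad, collapse = ", "))
  do.call(simulation_config, y)
}

# internal: place non-overlapping sites with a clearance margin so that
# distinct sites never stitch together (margin > stitch distance).
.place_sites <- function(config, margin = 15000) {
  widths <- c(rep(config$se_width, config$n_se_planted),
              rep(config$te_width,
                  config$n_enhancer_sites - config$n_se_planted))
  chroms <- names(config$genome)
  n <- length(widths)
  chrom_of <- sample(chroms, n, replace = TRUE,
                     prob = config$genome / sum(config$genome))
  placed <- vector("list", n)
  occupied <- lapply(chroms, function(ch) matrix(numeric(0), ncol = 2))
  names(occupied) <- chroms
  for (i in order(-widths)) {        # widest first eases packing
    ch <- chrom_of[i]
    w <- widths[i]
    for (try in 1:2000) {
      s <- floor(stats::runif(1, margin, config$genome[[ch]] - w - margin))
      occ <- occupied[[ch]]
      if (nrow(occ) == 0 ||
          all(s - margin >= occ[, 2] | s + w + margin <= occ[, 1])) {
        occupied[[ch]] <- rbind(occ, c(s, s + w))
        placed[[i]] <- c(ch = ch, start = s, end = s + w)
        break
      }
      if (try == 2000) stop("could not place enhancer sites; genome too small")
    }
  }
  df <- data.frame(chrom = vapply(placed, `[[`, character(1), "ch"),
                   start = as.numeric(vapply(placed, `[[`, character(1),
                                             "start")),
                   end = as.numeric(vapply(placed, `[[`, character(1), "end")),
                   stringsAsFactors = FALSE)
  df$id <- sprintf("site_%03d", seq_len(nrow(df)))
  df$is_se <- seq_len(nrow(df)) <= config$n_se_planted
  df
}

# internal: sample a Poisson number of uniform tag positions per interval
.scatter_tags <- function(chrom, start, end, expected) {
  k <- stats::rpois(length(expected), expected)
  pos <- stats::runif(sum(k)) *
    rep(end - start, k) + rep(start, k)
  split(floor(pos), rep(chrom, k))
}

.merge_tag_lists <- function(a, b) {
  for (ch in names(b)) a[[ch]] <- c(a[[ch]], b[[ch]])
  a
}

#' Simulate two-condition ChIP tag libraries with planted enhancers
#'
#' Background tags are uniform over the genome at a rate chosen so the
#' expected background total equals `library_size`. Planted sites receive
#' additional Poisson tags so their total rate is `multiplier` times
#' background: `se_signal_multiplier` at SE sites, `te_signal_multiplier`
#' at TE sites, identical in both IP conditions except that flow-sensitive
#' SEs are further scaled in the DF IP library by `flow_fc` (DF-enriched)
#' or `1/flow_fc` (UF-enriched). Input libraries contain background only.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List: `ip_uf`, `input_uf`, `ip_df`, `input_df` (tag libraries)
#'   and `truth` (class `ground_truth`: `se_sites` with `flow_label` in
#'   `{UF, DF, CORE}`, `te_sites`, `genome`).
#' @export
simulate_tag_libraries <- function(config) {
  set.seed(config$seed)
  G <- sum(config$genome)
  rate <- config$library_size / G   # background tags per bp
  sites <- .place_sites(config)
  se <- sites[sites$is_se, , drop = FALSE]
  te <- sites[!sites$is_se, , drop = FALSE]
  flow <- rep("CORE", nrow(se))
  if (config$n_uf_planted > 0)
    flow[seq_len(config$n_uf_planted)] <- "UF"
  if (config$n_df_planted > 0)
    flow[config$n_uf_planted + seq_len(config$n_df_planted)] <- "DF"
  se$flow_label <- flow

  mult_uf <- c(rep(config$se_signal_multiplier, nrow(se)),
               rep(config$te_signal_multiplier, nrow(te)))
  mult_df <- mult_uf
  mult_df[seq_len(nrow(se))][flow == "DF"] <-
    config$se_signal_multiplier * config$flow_fc
  mult_df[seq_len(nrow(se))][flow == "UF"] <-
    config$se_signal_multiplier / config$flow_fc
  all_sites <- rbind(se[, c("chrom", "start", "end")],
                     te[, c("chrom", "start", "end")])
  width <- all_sites$end - all_sites$start

  exp_planted <- rate * pmin(mult_uf, mult_df) * width
  if (any(exp_planted[seq_len(nrow(se))] < 10))
    stop("library_size too small: expected planted tags < 10 per ",
         "super-enhancer site; increase library_size")

  bg <- function() {
    n <- stats::rpois(1, config$library_size)
    chrom <- sample(names(config$genome), n, replace = TRUE,
                    prob = config$genome / G)
    split(floor(stats::runif(n) * config$genome[chrom]), chrom)
  }
  lib <- function(mult, label) {
    tags <- bg()
    extra <- .scatter_tags(all_sites$chrom, all_sites$start, all_sites$end,
                           rate * (mult - 1) * width)
    tag_library(.merge_tag_lists(tags, extra), label = label)
  }
  out <- list(ip_uf = lib(mult_uf, "UF_IP"),
              input_uf = tag_library(bg(), label = "UF_input"),
              ip_df = lib(mult_df, "DF_IP"),
              input_df = tag_library(bg(), label = "DF_input"))
  out$truth <- structure(list(se_sites = se[, c("chrom", "start", "end",
                                                "id", "flow_label")],
                              te_sites = te[, c("chrom", "start", "end",
                                                "id")],
                              genome = config$genome),
                         class = "ground_truth")
  out
}

#' Simulate gene models and SE-gene links
#'
#' Places `n_genes` gene bodies (10-50 kb, random strand, TSS at the
#' transcription-start boundary) uniformly over the genome and links each
#' planted super-enhancer to 1-2 globally distinct target genes. The links
#' become part of the ground truth consumed by the interaction and
#' expression generators.
#'
#' @param config A [simulation_config()].
#' @param truth `ground_truth` from [simulate_tag_libraries()].
#' @return `truth` with `gene_models` (data frame) and `se_gene_links`
#'   (data frame `se_id`, `gene`, `flow_label`) added.
#' @export
simulate_gene_models <- function(config, truth) {
  set.seed(config$seed + 1L)
  chroms <- names(config$genome)
  chrom <- sample(chroms, config$n_genes, replace = TRUE,
                  prob = config$genome / sum(config$genome))
  width <- floor(stats::runif(config$n_genes, 1e4, 5e4))
  start <- floor(stats::runif(config$n_genes) *
                   (config$genome[chrom] - width))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- data.frame(gene = sprintf("GENE%03d", seq_len(config$n_genes)),
                      chrom = chrom, start = start, end = start + width,
                      strand = strand,
                      tss = ifelse(strand == "+", start, start + width),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  n_se <- nrow(truth$se_sites)
  links <- list()
  if (n_se > 0 && config$n_genes > 0) {
    n_links <- sample(1:2, n_se, replace = TRUE)
    pool <- sample(genes$gene, min(sum(n_links), config$n_genes))
    k <- 0
    for (i in seq_len(n_se)) {
      take <- min(n_links[i], length(pool) - k)
      if (take <= 0) break
      links[[i]] <- data.frame(se_id = truth$se_sites$id[i],
                               gene = pool[k + seq_len(take)],
                               flow_label = truth$se_sites$flow_label[i],
                               stringsAsFactors = FALSE)
      k <- k + take
    }
  }
  truth$gene_models <- genes
  truth$se_gene_links <- if (length(links)) do.call(rbind, links) else
    data.frame(se_id = character(0), gene = character(0),
               flow_label = character(0), stringsAsFactors = FALSE)
  rownames(truth$se_gene_links) <- NULL
  truth
}

#' Simulate promoter-capture interactions
#'
#' Every planted SE-gene link yields one interaction whose bait is a 2 kb
#' promoter fragment at the gene's TSS and whose other end is a 1 kb
#' fragment inside the SE, with a score drawn in
#' `interaction_score_range` (>= 5, so score filtering retains all planted
#' links). A configurable fraction of links receives a second, distinct
#' other-end fragment within the same SE to the same promoter, emulating
#' repeated enhancer-promoter contacts. Decoy interactions at random loci
#' carry scores uniform on (0, 10), i.e. on both sides of the retention
#' threshold.
#'
#' @param config A [simulation_config()].
#' @param truth `ground_truth` with gene models (see
#'   [simulate_gene_models()]).
#' @return Interaction data frame (see [read_interactions()] layout).
#' @export
simulate_interactions <- function(config, truth) {
  if (is.null(truth$gene_models))
    stop("truth must carry gene models; run simulate_gene_models() first")
  set.seed(config$seed + 2L)
  genes <- truth$gene_models
  links <- truth$se_gene_links
  rows <- list()
  mk_bait <- function(g) {
    m <- genes[genes$gene == g, ]
    s <- max(0, m$tss - 1000)
    c(chrom = m$chrom, start = s, end = s + 2000)
  }
  oe_frag <- function(se, avoid_start = -1) {
    for (k in 1:50) {
      s <- floor(stats::runif(1, se$start, se$end - 1000))
      if (abs(s - avoid_start) >= 1000) return(s)
    }
    s
  }
  score <- function(n) stats::runif(n, config$interaction_score_range[1],
                                    config$interaction_score_range[2])
  if (nrow(links) > 0) {
    repeated <- stats::runif(nrow(links)) < config$repeated_contact_fraction
    for (i in seq_len(nrow(links))) {
      se <- truth$se_sites[truth$se_sites$id == links$se_id[i], ]
      bait <- mk_bait(links$gene[i])
      s1 <- oe_frag(se)
      rows[[length(rows) + 1]] <- data.frame(
        bait_chrom = bait[["chrom"]], bait_start = as.numeric(bait[["start"]]),
        bait_end = as.numeric(bait[["end"]]), bait_genes = links$gene[i],
        oe_chrom = se$chrom, oe_start = s1, oe_end = s1 + 1000,
        score = score(1), stringsAsFactors = FALSE)
      if (repeated[i]) {
        s2 <- oe_frag(se, avoid_start = s1)
        rows[[length(rows) + 1]] <- data.frame(
          bait_chrom = bait[["chrom"]],
          bait_start = as.numeric(bait[["start"]]),
          bait_end = as.numeric(bait[["end"]]), bait_genes = links$gene[i],
          oe_chrom = se$chrom, oe_start = s2, oe_end = s2 + 1000,
          score = score(1), stringsAsFactors = FALSE)
      }
    }
  }
  n_decoy <- config$n_decoy_interactions
  if (n_decoy > 0 && nrow(genes) > 0) {
    decoy_gene <- sample(genes$gene, n_decoy, replace = TRUE)
    chroms <- names(config$genome)
    d_chrom <- sample(chroms, n_decoy, replace = TRUE,
                      prob = config$genome / sum(config$genome))
    d_start <- floor(stats::runif(n_decoy) * (config$genome[d_chrom] - 1000))
    baits <- do.call(rbind, lapply(decoy_gene, mk_bait))
    rows[[length(rows) + 1]] <- data.frame(
      bait_chrom = baits[, "chrom"],
      bait_start = as.numeric(baits[, "start"]),
      bait_end = as.numeric(baits[, "end"]), bait_genes = decoy_gene,
      oe_chrom = d_chrom, oe_start = d_start, oe_end = d_start + 1000,
      score = stats::runif(n_decoy, 0, 10), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a trait-SNP catalog with planted SE enrichment
#'
#' For the enriched trait class, each SNP falls inside the planted
#' super-enhancer regions with the probability that makes the expected
#' per-base odds ratio (inside vs outside) equal `planted_or`; SNPs of
#' control classes are uniform over the genome. Every lead SNP receives
#' 0-3 LD proxies placed within 100 kb, recorded in a companion LD-pair
#' table with r-squared drawn in (0.5, 1).
#'
#' @param config A [simulation_config()].
#' @param truth `ground_truth` from [simulate_tag_libraries()].
#' @return List: `snps` (lead SNP catalog), `ld_pairs` (companion table),
#'   `snp_in_se_ids` (rsids planted inside SEs).
#' @export
simulate_snp_catalog <- function(config, truth) {
  if (config$planted_or <= 0) stop("planted_or must be > 0")
  set.seed(config$seed + 3L)
  genome <- config$genome
  G <- sum(genome)
  se <- truth$se_sites
  L_in <- sum(se$end - se$start)
  q <- config$planted_or * L_in /
    (config$planted_or * L_in + (G - L_in))
  chroms <- names(genome)
  trait_names <- list(
    Cardiovascular = c("Coronary artery disease", "Systolic blood pressure",
                       "Stroke", "Atrial fibrillation",
                       "Myocardial infarction"),
    Metabolic = c("Type 2 diabetes", "Fasting glucose", "Body mass index",
                  "HDL cholesterol", "Triglycerides"),
    Immune = c("Crohn's disease", "Rheumatoid arthritis", "Asthma",
               "Ulcerative colitis", "Celiac disease"),
    Neurological = c("Alzheimer's disease", "Parkinson's disease",
                     "Epilepsy", "Migraine", "Multiple sclerosis"),
    Cancer = c("Breast carcinoma", "Prostate carcinoma", "Lung carcinoma",
               "Colorectal carcinoma", "Melanoma"))
  uniform_pos <- function(n) {
    ch <- sample(chroms, n, replace = TRUE, prob = genome / G)
    list(chrom = ch, pos = floor(stats::runif(n) * genome[ch]))
  }
  inside_pos <- function(n) {
    w <- se$end - se$start
    i <- sample(nrow(se), n, replace = TRUE, prob = w / sum(w))
    list(chrom = se$chrom[i],
         pos = floor(se$start[i] + stats::runif(n) * w[i]))
  }
  rows <- list()
  idx <- 0
  for (cls in config$trait_classes) {
    nm <- trait_names[[cls]]
    if (is.null(nm)) nm <- paste(cls, "trait", seq_len(config$n_traits_per_class))
    nm <- rep_len(nm, config$n_traits_per_class)
    for (tr in nm) {
      n <- config$n_snps_per_trait
      if (cls == config$enriched_class && L_in > 0) {
        in_se <- stats::runif(n) < q
        p_in <- inside_pos(sum(in_se))
        p_out <- uniform_pos(sum(!in_se))
        # rejection: keep "outside" draws out of the SE regions
        if (length(p_out$pos) > 0) {
          iv <- genomic_intervals(p_out$chrom, p_out$pos, p_out$pos + 1)
          redo <- which(interval_overlaps(iv, se))
          for (r in redo) {
            repeat {
              p <- uniform_pos(1)
              hit <- interval_overlaps(
                genomic_intervals(p$chrom, p$pos, p$pos + 1), se)
              if (!hit) { p_out$chrom[r] <- p$chrom; p_out$pos[r] <- p$pos
                break }
            }
          }
        }
        chrom <- c(p_in$chrom, p_out$chrom)
        pos <- c(p_in$pos, p_out$pos)
      } else {
        p <- uniform_pos(n)
        chrom <- p$chrom; pos <- p$pos
      }
      rows[[length(rows) + 1]] <- data.frame(
        rsid = sprintf("rs%07d", idx + seq_len(n)), chrom = chrom,
        pos = pos, trait = tr, trait_class = cls, is_lead = TRUE,
        stringsAsFactors = FALSE)
      idx <- idx + n
    }
  }
  snps <- do.call(rbind, rows)
  rownames(snps) <- NULL
  n_proxy <- sample(0:3, nrow(snps), replace = TRUE)
  has <- which(n_proxy > 0)
  ld <- if (length(has) > 0) {
    lead_idx <- rep(has, n_proxy[has])
    off <- floor(stats::runif(length(lead_idx), -1e5, 1e5 + 1))
    ppos <- pmax(0, snps$pos[lead_idx] + off)
    data.frame(lead_rsid = snps$rsid[lead_idx],
               proxy_rsid = sprintf("rs%07d", idx + seq_along(lead_idx)),
               proxy_chrom = snps$chrom[lead_idx], proxy_pos = ppos,
               r2 = stats::runif(length(lead_idx), 0.5, 1),
               stringsAsFactors = FALSE)
  } else {
    data.frame(lead_rsid = character(0), proxy_rsid = character(0),
               proxy_chrom = character(0), proxy_pos = numeric(0),
               r2 = numeric(0), stringsAsFactors = FALSE)
  }
  iv <- genomic_intervals(snps$chrom, snps$pos, snps$pos + 1)
  list(snps = snps, ld_pairs = ld,
       snp_in_se_ids = snps$rsid[interval_overlaps(iv, se)])
}

#' Simulate an expression table tracking SE flow labels
#'
#' Genes linked to UF-enriched SEs draw log2FC (DF/UF) from a negative-mean
#' normal, DF-linked genes from a positive-mean normal, and unlinked genes
#' from a zero-mean normal with small spread. FPKM values are lognormal
#' around 10 and split symmetrically so that `fpkm_df / fpkm_uf`
#' realizes the drawn fold change; the stored `log2fc` is recomputed as
#' `log2((fpkm_df + 0.01) / (fpkm_uf + 0.01))`. Planted flow genes get
#' small q-values.
#'
#' @param config A [simulation_config()].
#' @param truth `ground_truth` with `se_gene_links`.
#' @return Expression data frame (see [read_expression()] layout).
#' @export
simulate_expression <- function(config, truth) {
  if (is.null(truth$se_gene_links))
    stop("truth must carry SE-gene links; run simulate_gene_models() first")
  set.seed(config$seed + 4L)
  genes <- truth$gene_models$gene
  n <- length(genes)
  links <- truth$se_gene_links
  mu <- rep(0, n)
  sdv <- rep(0.2, n)
  planted <- rep(FALSE, n)
  m_uf <- genes %in% links$gene[links$flow_label == "UF"]
  m_df <- genes %in% links$gene[links$flow_label == "DF"]
  mu[m_uf] <- -config$expr_log2fc_mean
  mu[m_df] <- config$expr_log2fc_mean
  sdv[m_uf | m_df] <- config$expr_log2fc_sd
  planted[m_uf | m_df] <- TRUE
  lfc <- stats::rnorm(n, mu, sdv)
  base <- stats::rlnorm(n, meanlog = log(10), sdlog = 1)
  fpkm_uf <- base * 2^(-lfc / 2)
  fpkm_df <- base * 2^(lfc / 2)
  qv <- ifelse(planted, stats::runif(n, 1e-6, 1e-3),
               stats::runif(n, 0.05, 1))
  data.frame(gene = genes, fpkm_uf = fpkm_uf, fpkm_df = fpkm_df,
             log2fc = log2((fpkm_df + 0.01) / (fpkm_uf + 0.01)),
             qvalue = qv, stringsAsFactors = FALSE)
}

#' Simulate a full study and write all pipeline inputs
#'
#' Runs every generator under `config` and writes tag libraries, gene
#' models, interactions, SNP catalog, LD pairs, expression, and a
#' ground-truth JSON into `outdir`.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the list of simulated objects.
#' @export
simulate_study <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_tag_libraries(config)
  truth <- simulate_gene_models(config, sim$truth)
  interactions <- simulate_interactions(config, truth)
  snp <- simulate_snp_catalog(config, truth)
  expression <- simulate_expression(config, truth)
  p <- function(f) file.path(outdir, f)
  write_tag_library(sim$ip_uf, p("tags_uf_ip.tsv"))
  write_tag_library(sim$input_uf, p("tags_uf_input.tsv"))
  write_tag_library(sim$ip_df, p("tags_df_ip.tsv"))
  write_tag_library(sim$input_df, p("tags_df_input.tsv"))
  write_gene_models(truth$gene_models, p("gene_models.tsv"))
  write_interactions(interactions, p("interactions.ibed"))
  write_snp_catalog(snp$snps, p("snp_catalog.tsv"))
  write_ld_pairs(snp$ld_pairs, p("ld_pairs.tsv"))
  write_expression(expression, p("expression.tsv"))
  truth_json <- list(se_sites = truth$se_sites, te_sites = truth$te_sites,
                     se_gene_links = truth$se_gene_links,
                     genome = as.list(truth$genome),
                     enriched_class = config$enriched_class,
                     snp_in_se_ids = snp$snp_in_se_ids)
  jsonlite::write_json(truth_json, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(libraries = sim[c("ip_uf", "input_uf", "ip_df", "input_df")],
                 truth = truth, interactions = interactions, snp = snp,
                 expression = expression))
}
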