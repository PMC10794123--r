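# seflow

Super-enhancer calling and flow-sensitivity annotation from H3K27ac
ChIP-seq tag data, for regulatory genomics of the vascular endothelium.

Endothelial cells under athero-protective **unidirectional flow (UF)** and
athero-prone **disturbed flow (DF)** remodel their enhancer landscape.
`seflow` implements the complete downstream analysis for a two-condition
H3K27ac study of this kind:

1. **Super-enhancer calling.** Peaks within 12.5 kb are stitched into
   single entities; each entity's input-normalized signal (tags per 10⁷)
   is ranked, and both axes of the rank curve are rescaled to the unit
   interval. The SE/TE cutoff is the discrete tangent point with slope 1,
   `argmin_i (y_i − x_i)` on the scaled curve (ties toward the larger
   index). Entities strictly above the cutoff signal are super-enhancers
   (SEs); the rest are typical-enhancers (TEs). Per-condition catalogs are
   merged by ≥ 1 bp overlap into hulls.
2. **Flow classification.** For each merged SE with raw counts
   `c_UF`, `c_DF` and library totals `N_UF`, `N_DF`, two one-sided Poisson
   tests are run with `λ = (c_ref + 1)·N_test/N_ref`,
   `p = P(Pois(λ) ≥ c_test)`. A SE is DF-enriched iff
   `log2FC(DF/UF) ≥ log2(1.2) = 0.263` and `p ≤ 10⁻⁴`; UF-enriched
   symmetrically; otherwise core.
3. **Annotation.** TF-binding fractions and per-bp binding densities;
   promoter-capture Hi-C contact maps (interaction score ≥ 5, other-end
   overlap ≥ 1 bp) with enhancer–promoter contact frequencies; GWAS
   trait-SNP enrichment by exact binomial test against the genomic
   background, `p0 = L_in/G`, with odds ratios and Benjamini–Hochberg
   q-values per trait class or trait; LD expansion of lead SNPs
   (r² > 0.8 within 100 kb).
4. **Refinement.** Flow-sensitive SEs that harbor ≥ 1 cardiovascular
   (CVD) GWAS SNP and contact ≥ 1 expressed gene (FPKM ≥ 1 under either
   flow) form the refined candidate set, reported as a per-(SE, gene)
   matrix.

A synthetic-data generator (`simulation_config()`, `simulate_study()`,
`run_pipeline()`) plants ground-truth SEs, flow effects, SE–gene contacts,
SNP enrichment and expression shifts, so every statistical step can be
verified as a parameter-recovery exercise. See the vignette
(`vignettes/flow-sensitive-super-enhancers.Rmd`) for the model, parameter
choices and limitations.

## Worked example

```r
library(seflow)

cfg <- simulation_config(seed = 1)   # default synthetic study
run <- run_pipeline(cfg)
run
#> seflow_run: 13 merged SEs, 192 TEs | flow 4 UF / 3 DF / 6 CORE |
#>   SE recovery sens 1.00 prec 0.92 | 6 refined SE(s)
```

The default study plants 12 SEs (3 UF-, 3 DF-enriched, 6 core) among 200
enhancer sites on a 2 × 10 Mb genome. The run above recovers all 12
planted SEs (one extra call, hence precision 0.92), labels all six planted
flow-sensitive SEs correctly (one spurious UF call), and refines the six
flow-sensitive SEs that contain a CVD SNP and contact an expressed gene.

```r
run$enrichment[, c("label", "k_in", "m", "odds_ratio", "qvalue", "significant")]
#>            label k_in    m odds_ratio      qvalue significant
#> 1 Cardiovascular   87 5000  1.4161479 0.006561478        TRUE
#> 2         Immune   73 5000  1.1848856 0.217291919       FALSE
#> 3         Cancer   63 5000  1.0205012 0.566957028       FALSE
#> 4   Neurological   63 5000  1.0205012 0.566957028       FALSE
#> 5      Metabolic   59 5000  0.9549338 0.654979763       FALSE
```

Only the cardiovascular class — planted at a per-base odds ratio of 1.5
inside SEs — is flagged (estimate 1.42, q = 0.0066); the four control
classes sit at OR ≈ 1. The refined table lists each candidate SE with its
flow label and the number of CVD SNPs it harbors:

```r
head(run$refined$ses[, c("id", "label", "n_cvd_snps")])
#>                     id       label n_cvd_snps
#> 1 chr1:2691000-2711000 DF_ENRICHED          6
#> 2 chr1:5157000-5177000 UF_ENRICHED          6
#> 3 chr1:5614000-5635000 DF_ENRICHED          9
#> ...
```

File-based workflows use the same functions through a thin CLI
(`inst/cli/seflow.R`) with subcommands `simulate`, `call-se`,
`classify-flow`, `tf-overlap`, `annotate-contacts`, `snp-enrich`,
`refine` and `run`.

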