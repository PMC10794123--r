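---
title: "Calling flow-sensitive super-enhancers from H3K27ac tag data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling flow-sensitive super-enhancers from H3K27ac tag data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Vascular endothelial cells experience very different hemodynamics along the
arterial tree: unidirectional flow (UF) at straight segments is
athero-protective, while disturbed flow (DF) at curvatures and bifurcations
is athero-prone. Much of the transcriptional response to these forces is
driven by enhancers, and in particular by super-enhancers (SEs) — large
clusters of enhancers with exceptionally high H3K27ac signal that control
cell-identity and disease genes. `seflow` implements the computational
pipeline for this setting: it calls SEs from H3K27ac ChIP tag libraries in
the two flow conditions, classifies each SE as UF-enriched, DF-enriched or
core, annotates SEs with transcription-factor binding, promoter-capture
Hi-C contacts, GWAS-SNP enrichment and gene expression, and finally
refines the set of flow-sensitive SEs that harbor a cardiovascular-disease
(CVD) SNP and contact an expressed gene — the candidates most likely to be
functional in vascular disease.

Because the real study design rests on deep sequencing of primary
endothelial cells, the package pairs every analysis step with a
synthetic-data generator that plants a known ground truth. The generator
is first-class, tested code: it is the harness by which we demonstrate
that each statistical step recovers the effect sizes it was designed to
detect.

## The SE-calling model

Enhancer calling starts from peak intervals (the package deliberately does
not re-implement a production peak caller; a simple binned
fixed-threshold caller is provided for the synthetic path, where signal is
planted as clean Poisson rate multiples). The defined computation is:

1. **Stitching.** Peaks on one chromosome whose gaps are at most 12.5 kb
   are chained into a single stitched enhancer spanning their hull. The
   12.5 kb rule is the field-standard stitching distance for SE discovery.
   Stitching is idempotent and order-independent; output entities are
   pairwise more than 12.5 kb apart.
2. **Quantification.** Each stitched enhancer gets an input-normalized
   signal: IP and input tag counts are scaled to a common total
   (tags per 10^7 by default) and subtracted, floored at zero. Input
   subtraction is per region, and tags are single 5' positions (no
   fragment extension) — both choices recorded in output headers.
3. **Rank-curve cutoff.** Signals are sorted ascending and both axes are
   rescaled to the unit interval, `x_i = (i-1)/(n-1)`,
   `y_i = (s_i - s_1)/(s_n - s_1)`. The SE cutoff is the discrete tangent
   point where the curve's slope passes 1, computed as
   `argmin_i (y_i - x_i)` with ties broken toward the larger index. For a
   convex rank curve this is exactly the first index whose forward
   discrete slope reaches 1, and the formulation is invariant to positive
   affine transformations of the signal vector. Enhancers **strictly
   above** the cutoff signal are super-enhancers; an enhancer exactly at
   the cutoff is a typical-enhancer (TE). Perfectly linear curves are
   flagged as having no SE structure.
4. **Condition merging.** SEs called in the two conditions that overlap by
   at least one base are merged into their hull; per-condition signals are
   re-quantified over the merged hull (rather than summed from parts) so
   that downstream fold changes are defined on a single interval. Any
   merged TE overlapping a merged SE is dropped from the TE list.

## Flow classification

For each merged SE, raw IP tag counts in the two conditions are compared
by two one-sided Poisson tests, each direction using the other condition
as the expectation: `lambda = (count_ref + 1) * total_test / total_ref`,
p-value `P(Pois(lambda) >= count_test)`. The +1 pseudocount guards the
zero-count rate. A SE is DF-enriched when its normalized-count log2 fold
change (DF/UF, +1 pseudocount on both sides) is at least `log2(1.2)`
(0.263) **and** the DF-over-UF p-value is at most 1e-4; UF-enriched
symmetrically; all other SEs are core. Classification is exactly
antisymmetric under swapping the conditions. Fold change is computed on
library-size-normalized raw counts, not input-subtracted signal, because
the classification is defined on normalized tag counts; the input
libraries play no role at this step.

The Poisson model matches the data-generating process of the simulator
(no overdispersion), so the type-I error of the flow calls is calibrated
by construction and verified by a null simulation in the test suite.
Replicate-level dispersion modeling is deliberately out of scope: the
analysis operates on merged per-condition tag directories.

## Annotation layers

* **TF binding** (`fraction_with_site`, `binding_density`): an enhancer
  "contains a site" when at least one TF ChIP tag (or peak base) falls
  inside it; binding density is the library-normalized TF tag count
  divided by enhancer length in bp.
* **Promoter contacts** (`annotate_contacts`): interactions are retained
  at confidence score >= 5; an enhancer contacts a gene when an
  interaction's other-end fragment overlaps the enhancer by >= 1 bp and
  the gene is among the bait genes. Bait-side overlaps are ignored.
  Repeated distinct interactions between one enhancer and one promoter
  define the contact frequency. A promoter-overlapping enhancer is *not*
  credited with contacting its own gene unless an interaction record says
  so.
* **SNP enrichment** (`binomial_enrichment`, `enrich_catalog`): lead SNPs
  are LD-expanded (r^2 strictly > 0.8, within 100 kb). The null model is
  that each of a label's `m` SNPs falls into the merged region set with
  probability `L_in / G`; the p-value is the exact binomial upper tail
  (regions are merged first, so a SNP under overlapping regions counts
  once and the result is invariant to how the region set was split). The
  odds ratio compares SNP odds inside/outside with base-coverage odds; a
  0.5 continuity correction applies only when a factor is zero.
  Benjamini-Hochberg correction is applied across the groups tested in a
  run, and a group is flagged at q < 0.05 with OR > 1. The background is
  the whole genome minus the region set, not the complementary enhancer
  class.
* **Expression** (`filter_expressed`, `flow_expression_summary`): a gene
  is expressed at a threshold when its FPKM reaches it under *either*
  flow condition (1 for contacted-gene lists; 12 is the conventional
  stringent gate). When comparing log2 fold changes of genes exclusively
  contacted by UF- vs DF-enriched SEs, genes contacted by both classes
  are removed and the two samples are compared by a two-sided
  pooled-variance Student's t-test (not Welch), matching the convention
  of the field's reporting.

## Refinement

`refine_flow_ses` keeps a SE iff it is flow-sensitive (UF- or
DF-enriched), contains at least one CVD-trait SNP inside its merged hull
(half-open coordinates), and contacts at least one gene passing the
FPKM >= 1 gate. CVD traits are curated by a fixed case-insensitive keyword
list (cardiovascular, coronary artery/heart, myocardial infarction,
atherosclerosis, plaque, thrombo, stroke, heart failure/disease/defect,
ventricular, atrial fibrillation, blood pressure, hypertension, valve,
carotid, peripheral). RNA-seq q-values are reported verbatim in the
refined matrix without further filtering.

## The synthetic study

`simulation_config()` defines the study conditions; all defaults were
fixed once, on the following reasoning, and are exercised unchanged by the
test suite and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes x 10 Mb | desk-scale while large enough that planted sites never crowd |
| enhancer sites | 200 (12 SE + 188 TE) | SE fraction 6%, qualitatively mirroring the genome-wide scarcity of SEs (a few percent of enhancers) |
| SE width / TE width | 20 kb / 2 kb | typical size contrast between stitched SE clusters and single enhancers; gives SEs ~2% of genome coverage so region-enrichment tests have realistic denominators |
| SE / TE signal multiplier | 5x / 3x over background | a clear but not caricatured H3K27ac contrast |
| flow fold change | 2 (3 UF + 3 DF + 6 core SEs) | comfortably above the 1.2-fold calling threshold, as real flow-sensitive SEs are |
| library size | 1e6 tags per library | deep enough that a 20 kb SE carries thousands of tags, matching the regime where the Poisson test operates |
| SNP catalog | 5 classes x 5 traits x 1000 SNPs | the cardiovascular class is planted at per-base odds ratio 1.5 inside SEs; others uniform |
| interactions | every planted SE linked to 1-2 genes, scores in [5, 10]; 300 decoys with scores in (0, 10); half the links receive a second distinct other-end fragment | guarantees planted links survive score filtering while decoys straddle it |
| expression | linked genes log2FC ~ N(+/-1, 0.4); unlinked N(0, 0.2) | fold changes track the contacting SE class with realistic spread |

Tag counts are Poisson with no overdispersion — intentionally matched to
the differential test's assumption so that recovery tests are exact
calibration checks. The generator does **not** emulate replicate
structure, mappability, GC or capture bias, fragment-size effects,
LD-block correlation beyond simple proxy placement, or trans-chromosomal
contacts. Passing tests therefore demonstrate correctness and calibration
of the implemented statistics, not robustness to the full messiness of
real ChIP-seq/PCHi-C data.

Determinism: every generator seeds the RNG from `config$seed` plus a small
fixed offset per generator, so any subset of the generators can be rerun
reproducibly and the full pipeline is byte-identical across runs at a
fixed seed.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout (BED-native); printed loci
  are treated as half-open bounds. Tag membership is `start <= p < end`,
  counted by binary search and cross-checked against linear scans.
* `rank_and_cut` requires n >= 3 and non-constant signals; constant or
  tiny inputs raise a "degenerate rank curve" error rather than guessing.
* Poisson and binomial tail probabilities use R's `ppois`/`pbinom`
  upper tails; the test suite validates them against direct log-space
  summation oracles to 1e-12 / 1e-10 relative error.
* Log2 fold changes of expression add epsilon = 0.01 FPKM to numerator and
  denominator; for expressed genes (FPKM >= 1) the effect is negligible.
* Zero-variance t-test inputs are resolved explicitly (t = 0, p = 1 for
  equal means; infinite statistic otherwise) instead of erroring.
* The promoter window for genomic-distribution pie charts is -1000/+100 bp
  around the TSS in the direction of transcription, a common annotation
  default; precedence is promoter > intragenic > intergenic, assigned by
  enhancer midpoint.

## Problem sizes

The shipped test-suite and acceptance-script runs use the default
configuration above: 200 planted sites on 20 Mb at 1e6 tags per library,
100-replicate null simulations for flow-call calibration, 200 simulated
catalogs for enrichment calibration, and 100-instance randomized oracles
for stitching, tangent-cutoff and contact-map equivalence. These sizes
were chosen as the smallest at which the stochastic checks have
comfortable margins.

## Known limitations

* Peak calling is intentionally naive; real data should enter at the
  peak/tag-library interface from a production caller.
* Tag counts are raw 5' positions; fragment extension is not modeled.
* The Poisson flow test inherits the merged-library design: it cannot
  capture biological replicate variability (a negative-binomial extension
  would be the natural upgrade).
* Whether fold changes should use input-subtracted signal is ambiguous in
  the field; `seflow` uses raw normalized counts and records this in
  output headers.
* LD expansion trusts the supplied r^2 table; the package never computes
  linkage from genotypes.
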