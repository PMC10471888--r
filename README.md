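# hetmix

Single-cell heteroplasmy quantification and spike-and-slab mixture
inference for plate-sorted amplicon sequencing.

## The problem

Pathogenic mitochondrial DNA point variants (such as m.3243A>G) are
*heteroplasmic*: each cell carries a mixture of mutant and wild-type
mtDNA, and the mutant fraction — the per-cell variant allele fraction
(VAF) — varies from 0 to 1 across cells. In blood, a key quantity is the
**proportion of cells that have (nearly) cleared the variant**, and how
that proportion changes along differentiation gradients such as naïve →
central memory (CM) → effector memory (EM) T cells. `hetmix` provides
the full analysis path for plate-based single-cell amplicon assays of a
biallelic site:

1. **Synthetic cohorts with known truth** — 96-well sort plates (one
   negative-control well per plate), well barcodes, per-cell read depths,
   allele counts, and optional FASTQ, with every planted value exported
   so downstream stages have exact expected outcomes.
2. **Demultiplexing and allele counting** — exact barcode-prefix
   matching in both orientations, then per-base quality-filtered (Phred
   ≥ 28) counting of the reference (A) and variant (G) base at the
   target offset; VAF = alt / (ref + alt).
3. **Quality control** — per-batch lower read-depth thresholds, a
   high-depth doublet rule (depth > 1.5 × Q3 by default), and exclusion
   of plates whose negative control shows contamination.
4. **Spike-and-slab mixture inference** — the per-subset model

   ```
   Y ~ pi * N01(mu, sigma^2) + (1 - pi) * U(0,1)
   pi ~ pi0 * delta0 + (1 - pi0) * U(0,1)
   mu ~ U(0, 0.2),  sigma ~ Exp(5),  pi0 ~ U(0,1)
   ```

   where `N01` is a normal truncated to (0,1) (the near-zero "spike"),
   the slab is uniform, and `delta0` is a point mass at `pi = 0` so that
   `pi0` is the probability of no spike. The spike weight `pi` is the
   proportion of near-zero cells. A purpose-built trans-model MCMC
   sampler targets this posterior exactly (including the point mass),
   and an independent dense-quadrature oracle (`grid_posterior()`)
   validates it on small datasets.
5. **Summaries and comparisons** — posterior peak estimates (with the
   zero point mass and multimodality reported), equal-tailed credible
   intervals, and the pairwise rule "significant iff zero lies outside
   the 95% credible interval of the posterior difference of the two
   proportions", organized along a declared maturity order.
6. **mtDNA copy number** — qPCR standard curves (Ct on log10 plasmid
   copies), absolute copies per cell, plate normalization, and
   replicate-consistency exclusions (Ct SD > 0.3 or mean Ct > 30).

## Worked example

```r
library(hetmix)

# one synthetic subject: naive and effector-memory T cells
cohort <- list(
  subset_truth("P01", "naive", n_cells = 91, pi_true = 0.10),
  subset_truth("P01", "EM",    n_cells = 91, pi_true = 0.80))
sim <- simulate_cohort(cohort, sequencing_spec(contaminated_plate_rate = 0),
                       seed = 20)

qc <- apply_qc(sim$counts, qc_config(lower_depth_threshold = 200))
print(qc)
#> QC result: 182 cells in, 159 retained; 0 plate(s) excluded
#> retained read depth: median 1069 (IQR = 636.5, 1451.5; range = 258, 2434)

naive <- qc$retained[qc$retained$cell_type == "naive", ]
em    <- qc$retained[qc$retained$cell_type == "EM", ]
fit_naive <- fit_mcmc(naive$vaf, depth = naive$depth, seed = 21)
fit_em    <- fit_mcmc(em$vaf,    depth = em$depth,    seed = 22)
print(fit_em)
#> Spike-and-slab mixture fit: 82 cells, 4 chains x 5000 draws
#>   E[pi | Y] = 0.828   P(no spike | Y) = 0.000   R-hat(pi) = 1.000
#>   95% CrI for pi: [0.729, 0.909]
print(peak_estimates(fit_em))
#> Posterior peaks: 0.832 (P(pi = 0) = 0.000)
print(compare_pair(fit_naive, fit_em))
#> Difference in pi: mean -0.700, 95% CrI [-0.866, -0.497] -> significant
```

The EM subset was simulated with 80% of cells in the near-zero spike and
the naive subset with 10%; after QC the model recovers a spike
proportion of 0.83 (95% CrI 0.73–0.91) for EM, and the naive–EM
difference excludes zero, i.e. the planted enrichment of cleared cells
in memory cells is detected. `run_pipeline(pipeline_config(...), out)`
executes the same stages end to end and writes tables plus a JSON
manifest with seeds and file hashes.

## Vignette

`vignettes/heteroplasmy-mixture.Rmd` documents the model, the priors and
their consequences (including posterior multimodality), the synthetic
generator's assumptions, the QC rules and their ambiguities, and known
limitations.
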