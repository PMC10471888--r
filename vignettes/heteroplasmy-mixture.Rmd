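---
title: "Estimating the proportion of near-zero heteroplasmy cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the proportion of near-zero heteroplasmy cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`hetmix` analyses per-cell variant allele fractions (VAFs) of a
biallelic heteroplasmic mtDNA site measured by plate-based single-cell
amplicon sequencing. This vignette is the package's account of its
statistical machinery: the mixture model and its priors, the sampler and
its validation oracle, what the synthetic-data generator does and does
not emulate, the quality-control rules, the summary conventions, and the
numerical choices. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The spike-and-slab mixture

For one cell subset (one subject, one cell type) with VAFs
$y_1,\dots,y_n \in (0,1)$:

$$Y \sim \pi\, N_{01}(\mu, \sigma^2) + (1-\pi)\, U(0,1), \qquad
  \pi \sim \pi_0\, \delta_0 + (1-\pi_0)\, U(0,1),$$

with priors $\mu \sim U(0, 0.2)$, $\sigma \sim \mathrm{Exp}(5)$ and
$\pi_0 \sim U(0,1)$. $N_{01}$ is a normal truncated to $(0,1)$: the
"spike" of cells that have (nearly) cleared the variant. The slab is
uniform: cells at intermediate or high mutant load. $\delta_0$ is a
Dirac point mass, so $\pi_0$ is the probability that there is **no**
spike at all; the posterior therefore has a genuine atom at $\pi = 0$
and $P(\pi = 0 \mid Y)$ is a meaningful quantity, reported as
`p_no_spike`.

Assumptions worth stating plainly:

* Cells are exchangeable within a subset; there is no hierarchy across
  subjects or cell types. Comparisons between subsets are made on
  independent posteriors.
* The slab is flat. Real intermediate-load distributions need not be;
  the generator can plant beta-shaped slabs (`slab_beta()`) precisely so
  that this misspecification can be probed.
* The model is defined on the open interval. VAFs of exactly 0 or 1 do
  occur with finite read counts; see "Boundary values" below.
* VAFs are proportions in $[0,1]$. Percent scales are divided by 100 at
  the door.

### Integrating out $\pi_0$

The uniform prior on $\pi_0$ enters only through the prior probability
that a spike exists; marginally $P(\text{spike}) = E[1-\pi_0] = 1/2$.
The sampler therefore carries a binary spike indicator $s$ with prior
$P(s = 0) = 1/2$ instead of sampling $\pi_0$, which is exact and removes
one dimension. With no data, $P(s = 0 \mid \emptyset) = 1/2$ — a check
the test suite performs on both the sampler and the oracle.

## The sampler

`fit_mcmc()` runs, per chain and per sweep:

1. **Trans-model move** (attempted with probability 1/2 so the
   $s$-chain stays aperiodic even when the acceptance ratio is
   identically 1, as in prior sampling): a birth proposes
   $(\pi^*, \mu^*, \sigma^*)$ from the priors and accepts with the
   marginal-likelihood ratio
   $\min\{1, L(\pi^*, \mu^*, \sigma^*)\}$; a death accepts with
   $\min\{1, 1/L(\pi, \mu, \sigma)\}$. Here
   $L = \prod_i [\pi f(y_i; \mu, \sigma) + (1-\pi)]$ is the
   allocation-summed likelihood and the slab-only likelihood is
   identically 1, so the move is valid from any state and needs no
   reversible-jump dimension matching.
2. **Allocations** $z_i \mid \pi, \mu, \sigma$ (Bernoulli).
3. **Conjugate weight** $\pi \mid z \sim
   \mathrm{Beta}(n_{\text{spike}}+1, n_{\text{slab}}+1)$.
4. **Metropolis updates**: $\mu$ by a random walk reflected at
   $[0, 0.2]$ (reflection keeps the proposal symmetric); $\sigma$ by a
   random walk on $\log \sigma$ with the Jacobian and the
   $\mathrm{Exp}(5)$ prior in the ratio.

When $s = 0$, $(\mu, \sigma)$ are refreshed from their priors — their
full conditional, since the likelihood no longer involves them. Defaults
are 4 chains × 30,000 iterations, 10,000 burn-in, thinning 4 (20,000
retained draws), chain seeds derived from one master seed, and a
split-chain potential-scale-reduction screen on $\pi$ that warns above
1.05. The sampler is compiled (Rcpp) and uses R's RNG, so results are
reproducible from `set.seed()` alone.

## The quadrature oracle

`grid_posterior()` computes the same posterior deterministically, as an
independent check: midpoint grids in $\pi$ and $\mu$ and a
prior-quantile grid in $\sigma$ (every node carries equal prior weight),
with

$$P(s=0 \mid Y) = \frac{1/2}{1/2 + \bar{L}/2}, \qquad
  \bar{L} = E_{\text{prior}}[L(\pi, \mu, \sigma)].$$

Log-likelihood surfaces are max-subtracted before exponentiation.
Defaults (101 × 61 × 61) are sized for $n \lesssim 200$ cells; an
optional refinement self-check doubles every resolution and errors if
$P(s = 0 \mid Y)$ moves by more than a tolerance. The test suite closes
the loop with a third, fully independent route — importance weighting of
plain prior draws — and requires all three to agree within Monte-Carlo
error.

## Boundary values

With depth $d$ and counts $(0, d)$ or $(d, 0)$ the empirical VAF is
exactly 0 or 1, where both mixture components have zero density. Such
cells are mapped into the open interval by half a read,
$y \mapsto 1/(2d)$ or $1 - 1/(2d)$, before fitting: the offset is the
midpoint between the observed count and the nearest count the model can
distinguish, so deeper cells sit closer to the boundary. The count is
recorded (`n_boundary_nudged`). Depths must be supplied whenever
boundary values are present; there is no silent default.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the inference
assumes, with full ground truth:

* **Plates**: 96-well sort plates, one sort gate (subject × cell type)
  per plate, at most 95 cells plus exactly one cell-free
  negative-control well at a random position. Barcodes are random 8-mers
  kept at pairwise Hamming distance ≥ 3, so exact-prefix matching is
  unambiguous.
* **Heteroplasmy truth**: each cell is a spike draw (truncated normal;
  optionally exactly 0 via `spike = "hard_zero"`, emulating complete
  clearance) with probability `pi_true`, else a slab draw. Generator
  spike defaults are $\mu = 0.02$, $\sigma = 0.05$.
* **Depth**: log-normal, median 1,146, `sdlog` 0.69 (central 99% spans
  roughly 200–7,000), truncated below at one read — the depth profile
  typical of this assay class after pooling.
* **Counts**: $\text{alt} \sim \mathrm{Bin}(d,\, h(1-e) + (1-h)e)$ with
  per-base miscall rate $e$ (default 0.005), folding sequencing error
  into the observed allele fraction.
* **Artefacts**: doublet wells (default rate 0.02) receive two
  independent cells and the sum of their depths and counts; optional
  low-depth wells draw from a separate low-count law (the planted
  targets of the lower depth filter); with probability 0.05 a plate's
  negative control is contaminated and behaves like a cell.
* **FASTQ** (`emit_fastq()`): one file per plate; each read is barcode +
  template with the planted A/G base at the target offset,
  reverse-complemented with probability 0.5, Phred+33 qualities from a
  configurable law. Per-base errors are applied to template flanks only,
  never to the barcode or the target base, so planted counts are exactly
  recoverable when comparing against truth; error-rate 0 gives a
  byte-exact round trip through `demultiplex()` → `count_alleles()`.

What the generator does **not** emulate: haematopoietic lineage dynamics
or age trends (plant them explicitly via `pi_true` if needed), realistic
position- and context-dependent error profiles, barcode synthesis
errors, chimeric reads, or paired-end chemistry. Passing tests therefore
demonstrate correctness of the pipeline's logic under the model's own
assumptions, not robustness to every artefact of real instruments. The
assay's true error and doublet rates are not published; the defaults are
plausible placeholders, and every rate is a parameter.

## Quality control

Three rules, applied in order (`apply_qc()`):

1. **Negative-control screen**: a plate whose control well exceeds
   `negative_control_max_depth` (default 10 reads) is dropped entirely.
   No published numeric criterion exists for this; 10 reads is far above
   the ambient counts a clean control shows and far below any cell.
2. **Lower depth threshold**, per sequencing batch: a fixed value, or
   `"auto"` — the smallest observed depth at or above a floor (default
   200). The automatic rule is a reproducible stand-in for choosing each
   batch's cutoff by inspecting its depth distribution, which cannot be
   replayed algorithmically.
3. **Upper depth rule** (doublets): the phrase "1.5 times the upper
   boundary of the interquartile range" admits two readings, and both
   are implemented: `Q3_TIMES_K` (exclude depth > 1.5 × Q3; the literal
   reading, the default) and `TUKEY_FENCE` (exclude depth >
   Q3 + 1.5 × (Q3 − Q1)). Quartiles use linear interpolation between
   order statistics (R's type 7, the default convention of the original
   analysis environment); the convention is named in the report because
   exclusions near ties depend on it.

The QC report records per-plate bookkeeping (which always sums), the
thresholds used, the rule variant, and the retained-depth summary
(median, IQR, range) in the conventional reporting form.

## Posterior summaries and comparisons

* **Credible intervals** are equal-tailed by default (type-7 quantiles
  of the draws) — the plain reading of "95% credible interval". An HPD
  option exists because the atom at 0 can make equal-tailed intervals
  conservative near the boundary.
* **Peak estimates** (`peak_estimates()`): the atom at 0 is reported as
  a mode when $P(\pi = 0 \mid Y)$ exceeds a mass threshold (default
  0.05); continuous modes are local maxima of a Gaussian KDE reflected
  at both boundaries, kept when their height exceeds 10% of the global
  maximum. Bandwidth follows Silverman's rule (`bw.nrd0`), overridable:
  sharper plug-in selectors are unstable on heavily tied MCMC draws.
  Multiple reported modes flag a bi-/multimodal posterior.
* **Pairwise comparisons** (`compare_pair()`): difference draws are
  formed by pairing the two groups' draw sequences in stored iteration
  order, truncated to the shorter. The chains are independent, so any
  fixed pairing yields the correct marginal of the difference;
  iteration-order pairing is simply reproducible, and a seeded
  permutation option exists for sensitivity. "Significant" means zero
  lies outside the equal-tailed interval at the chosen level. No
  multiple-testing adjustment is applied across pairs; the report counts
  comparisons so users can adjust.
* **Gradient reports** (`gradient_report()`): peaks in a declared
  maturity order (naive → CM → EM → TEMRA) with comparisons restricted
  to declared groups (e.g. within the CD4 and CD8 compartments).

## mtDNA copy number

The qPCR module is deliberately plain: ordinary least squares of Ct on
$\log_{10}$ copies across a plasmid dilution series (flagged if $R^2 <
0.9992$ or the slope leaves $[-3.449, -3.264]$, the acceptance band of
a well-run assay); inversion to copies per reaction; division by cells
sorted and by the fraction of lysate in the reaction (`volume_factor`,
default 1/25 for a 1:5 dilution of which a fifth is loaded — the exact
bookkeeping varies by protocol, so this is a parameter, and it cancels
in plate-normalized values); plate normalization
$(\text{absolute}/\text{on-plate control}) \times \text{mean control}$;
and exclusion of samples with replicate SD > 0.3 or mean Ct > 30. The
within-triplicate outlier rule — undefined in most protocols — is: drop
one replicate if its removal brings the SD below 0.3 *and* it deviates
from the other two by more than three times their spread; the drop is
recorded.

## Validation studies and problem sizes

The `validate_*()` family runs the package's standard self-checks, all
deterministic given one master seed: sampler-versus-oracle agreement on
five datasets of 10–90 cells; coverage and posterior-mean RMSE over 20
datasets of 91 cells (the typical subset size of this assay class) with
true $\pi \in \{0, 0.2, 0.5, 0.8\}$; significance calibration over 20
null pairs ($\pi = 0.4$ both sides) and 20 separated pairs (0.1 vs
0.6); gradient recovery over 10 subjects with $\pi$ = 0.10 / 0.45 /
0.80 along naive → CM → EM; and an exact FASTQ round trip plus
planted-artefact QC on a 20-plate, 1,820-cell cohort. These sizes keep
each study in the minutes range on one CPU while leaving Monte-Carlo
error well below the effect sizes being checked.

## Known limitations

* **Posterior multimodality is intrinsic to the model.** With
  $\sigma \sim \mathrm{Exp}(5)$, spike standard deviations of ~0.3–0.5
  are not heavily penalised, and a truncated normal that broad is nearly
  flat on $(0,1)$ — almost indistinguishable from the slab. When the
  true spike weight is small and the slab cells happen to tilt low, the
  posterior of $\pi$ develops a second, high-$\pi$/large-$\sigma$ mode
  and a heavy upper tail. This is the true posterior (sampler,
  quadrature and importance sampling agree to Monte-Carlo error), and it
  has two practical consequences: posterior means can exceed a small
  true $\pi$ substantially on slab-dominated data, and pairwise
  credible-interval comparisons lose power — occasionally even for well
  separated spike weights. Peak estimates and $P(\pi = 0 \mid Y)$ are
  the more stable summaries in that regime, and multimodal posteriors
  are flagged by `peak_estimates()` reporting several modes.
* The sampler's trans-model birth proposes from the priors; with strong
  spikes the chain simply stays in the spike state (as it should), but
  $P(s = 0 \mid Y)$ estimates below ~$10^{-4}$ are limited by draw
  count, not by the method.
* Exact barcode matching performs no mismatch rescue; reads with
  barcode-region errors are unassigned rather than recovered.
* QC thresholds are per batch and assume depth distributions comparable
  within a batch; no cross-batch normalization is attempted.
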