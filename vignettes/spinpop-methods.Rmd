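---
title: "Models and methods behind spinpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinpop)
```

spinpop is a pipeline for population-genetic analysis of diploid biallelic
SNP panels of the kind produced by genotyping-by-sequencing (GBS), built
around the workflow used to characterize wild (*Spinacia turkestanica*) and
cultivated (*S. oleracea*) spinach collections: quality filtering of a raw
SNP matrix, model-based group structure, diversity and differentiation
statistics, linkage-disequilibrium (LD) decay, and a cross-population
composite-likelihood scan for selective sweeps. Every stage is exercised on
a built-in synthetic-data generator with known truth, so the whole pipeline
is testable without any external data. This vignette documents the models,
the defaults and why they were chosen, the numerical choices, and what the
synthetic experiments do and do not demonstrate.

## The synthetic genotype generator

`sim_config()` + `sim_panel()` draw a panel from the Balding–Nichols model:
for each locus an ancestral allele frequency $p$ is uniform on $[0.05,
0.95]$, and each of $K$ latent populations receives an independent
$\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$ frequency.
The drift parameter $F \in (0,1)$ is, in expectation, the panel's Fst — this
closed-form target is the reason Balding–Nichols was chosen, because it turns
every differentiation estimator into a parameter-recovery experiment.

Each individual belongs to a home population and carries admixture
proportions $q$ from an asymmetric Dirichlet in which the home component's
concentration is `admix_alpha + 1` and the others' `admix_alpha`. Small
`admix_alpha` therefore gives near-pure home ancestry while
`admix_alpha` $\to\infty$ gives uniform mixtures; the default 0.01 represents
collections of near-pure populations with rare admixture, the regime wild
germplasm collections typically occupy. Genotype dosages are
$\mathrm{Binomial}(2, \sum_k q_k p_{kl})$; missingness is completely at
random (`missing_rate`, default 2%) — real GBS missingness is
depth-dependent, which the generator does not attempt to model, since the
filter cascade only needs missingness to exist, not to be realistic.
Per-genotype read depths are negative binomial (mean 30, size 5) and site
qualities normal around `qual_mean = 60`, giving the filter cascade real
thresholds to bite on; `contaminant_fraction` interleaves indel and
multiallelic records into written VCFs for the same reason.

The default genome map is six 100-Mb chromosomes, matching the diploid
spinach karyotype (2n = 2x = 12). A sweep is injected at the frequency
level: within the affected population, each locus at distance $d$ from the
focal position is pushed toward fixation of the alternate allele with weight
$e^{-d/\text{strength}}$ *before* genotypes are drawn. This is deliberately
not a forward simulation — it is deterministic given the seed, cheap, and
produces exactly the local allele-frequency distortion a sweep scan must
detect. Its `strength` is a physical length scale in bp, not a selection
coefficient; consequences for interpretation are discussed under
"Limitations".

## The filter cascade

`filter_cascade()` applies, in a fixed order with per-step provenance:
remove indels; keep biallelic SNPs; minor-allele frequency (MAF) ≥ 0.05;
site quality ≥ 20; mask genotypes with depth < 10 to missing; drop sites
with > 20% missing genotypes; drop samples with > 20% missing; then a final
pass that raises the depth mask to 15, re-applies the 20% site-missingness
rule, and recomputes MAF ≥ 0.05 on the survivors. Depth thresholds mask
individual genotypes rather than dropping sites (the `--minDP` convention of
VCFtools-style tools), and the missingness filters act on the masked matrix.
MAF is always computed from non-missing alleles only. A fully filtered panel
is a valid empty result with complete provenance, not an error. Two details
were genuinely open and fixed here: a quality threshold printed as "< 20" in
the source workflow is read as ≥ 20 (the conventional direction), and when a
panel is split (e.g. per species), filtered and re-intersected with
`common_snps()`, MAF is applied within each split as given rather than
recomputed jointly.

LD pruning (`ld_prune()`) mirrors PLINK `--indep-pairwise 50 5 0.2`:
within 50-SNP windows stepped by 5, while any pair's genotypic $r^2$
exceeds 0.2, one SNP of the worst pair is removed. The removal tie-break
(lower MAF first, then the later position) is not specified by any of the
mirrored tools and was fixed for determinism.

## Diversity statistics

Per locus, with allele frequencies $p_i$ and $n$ non-missing **allele
copies** (twice the non-missing diploid samples):

* gene diversity $h = 1 - \sum_i p_i^2$ (biallelic maximum 0.5),
* PIC $= 1 - \sum_j p_j^2 - \sum_{j<k} 2 p_j^2 p_k^2$ (Botstein form;
  biallelic maximum 0.375),
* effective alleles $N_e = 1/\sum_i p_i^2$, observed alleles $N_a$,
* unbiased diversity $uh = \tfrac{n}{n-1} h$,
* Shannon's index $I = -\sum_i p_i \ln p_i$.

Two readings were possible for the $n$ in $uh$ (samples vs allele copies);
the allele-copy reading reproduces the reference implementation's published
group rows exactly (e.g. $h = 0.351$ with 33 samples gives
$\tfrac{66}{65}\cdot 0.351 = 0.356$) and is regression-tested, so it is the
one implemented. Shannon's index carries the conventional minus sign. Group
summaries are unweighted means over loci; the pooled row is reported under
both conventions — the unweighted mean of group rows and the statistics of
all grouped samples pooled — because the two differ for frequency-nonlinear
statistics and published tables mix them.

Windowed nucleotide diversity (`pi_windows()`) uses the unbiased per-site
heterozygosity $\tfrac{n}{n-1} 2p(1-p)$ summed within half-open 1-kb windows
and divided by the window length in bp, the convention of the standard
windowed-π tooling. Genome-wide means are taken over windows containing
data.

## Differentiation

`amova()` partitions molecular variance at the **allele level**: each
diploid sample contributes its two allele copies, and with binary allele
"profiles" the per-group sum of squared Euclidean distances reduces, per
locus, to $n\,p(1-p)$ over the group's non-missing copies. Variance
components follow the standard moment equations for unequal group sizes and
$\Phi_{PT} = \sigma^2_{\text{among}}/(\sigma^2_{\text{among}} +
\sigma^2_{\text{within}})$. The allele-level formulation was a deliberate
design decision: the inter-individual dosage-distance variant is
scale-invariant and estimates $2F/(1+F)$ rather than $F$ under
Balding–Nichols, so it can never agree with the Weir–Cockerham moment
estimator; at the allele level $\Phi_{PT}$ estimates Fst directly, and the
package's recovery experiments require exactly that agreement. Both
estimators are reported side by side by `pairwise_fst()`.

Significance comes from permuting whole samples between groups (the two
allele copies travel together, which is the correct exchangeability unit for
diploid data), with $p = (1 + \#\{\Phi^{perm} \ge \Phi^{obs}\})/(B+1)$ so
$p$ is never zero; $B$ defaults to 999.

Nei's unbiased statistics use per-locus gene identities $J_x = (2n_x \sum
p^2 - 1)/(2n_x - 1)$ within groups and $J_{xy} = \sum p_x p_y$ between, with
$I_d = \overline{J_{xy}} / \sqrt{\overline{J_x}\,\overline{J_y}}$ over loci
typed in both groups and $D = -\ln I_d$. Gene flow uses the island-model
inversion $N_m = \big(\tfrac{1}{F_{st}} - 1\big)/4$, reported as unbounded
(not an error) when $F_{st} \le 0$.

## Group structure

`fit_admixture()` fits the standard admixture likelihood — dosage
$g_{il} \sim \mathrm{Binomial}(2, \sum_k q_{ik} p_{kl})$ — by
maximum-likelihood EM rather than the MCMC of the original model-based
clustering tools. This is the package's central substitution: the same
likelihood model, but deterministic given a seed and fast enough that
multiple seeded restarts replace posterior sampling. Plain EM converges
slowly on this likelihood, so each cycle applies a squared-extrapolation
(SQUAREM-style) accelerator that falls back to the unaccelerated update
whenever extrapolation would reduce the likelihood; the recorded
log-likelihood trace is therefore non-decreasing, and that invariant is
asserted in the tests. Initialization is k-means on PCA coordinates,
perturbed by the seed. Frequencies are clamped to $[10^{-6}, 1-10^{-6}]$,
missing dosages are skipped in the likelihood, and non-convergence flags the
result rather than failing.

Model selection uses the Evanno second-difference statistic across a K range
fitted with replicate restarts ($\Delta K$ = mean over replicates of
$|L(K{+}1) - 2L(K) + L(K{-}1)|$ divided by the replicate standard deviation
of $L(K)$); zero replicate variance yields an infinite $\Delta K$ with a
warning rather than an error. Samples are assigned to their best group when
the maximum membership reaches $\tau = 0.75$ (the threshold used in the
mirrored workflow; the stricter 0.95 variant is just a different `tau`),
otherwise labelled admixed.

PCA uses the standard allele-frequency scaling (centre $2\hat p$, scale
$\sqrt{2\hat p(1-\hat p)}$, zero-impute after centring, drop monomorphic
loci) with a deterministic sign convention. Neighbor-joining trees are built
on the allele-sharing distance $d = \tfrac{1}{2}\,\overline{|x - y|}$ over
non-missing loci, with support values from resampling loci with replacement
(200 replicates by default) attached to bipartitions rather than node
positions.

## LD decay

Genotypic $r^2$ (squared Pearson correlation of dosage vectors over
pairwise-complete samples) is computed for same-chromosome pairs within
200 kb; phase is unknown in GBS data, so no haplotype-based measure is
attempted. Pairs with fewer than 4 complete samples or zero variance are
skipped. Bin means use 1-kb bins below 20 kb and 5-kb bins beyond, chosen to
resolve the short-range crossing typical of outcrossing species. The decay
distance at $r^2 = 0.2$ is read from the isotonic (monotone non-increasing)
regression of the bin means, linearly interpolated between bracketing bin
midpoints — the mirrored workflow plots a fitted curve without naming the
fit, and isotonic regression is the assumption-light deterministic choice. A
curve that never rises above the threshold decays at 0; one that never
falls below reports `Inf` with the examined range attached.

## The sweep scan

`scan_sweeps()` compares a query group against a reference group in sliding
windows (50 kb, stepped 10 kb, at most 50 SNPs per window, windows with
fewer than 2 SNPs skipped; over-full windows are downsampled with a fixed
seed so scans are reproducible). The neutral drift scale $\omega$ is
estimated by the method of moments as the ratio of means
$\overline{(p_q - p_r)^2} \,/\, \overline{p_r(1-p_r)}$ over loci polymorphic
in the reference. The ratio-of-means form was chosen over the mean of
per-locus ratios because the latter has heavy tails whenever the reference
frequency sits near a boundary (the Balding–Nichols beta density puts mass
there, and the per-locus ratio then has no finite expectation). When both
groups drift from a common ancestor with differentiation $F$, each
contributes $F p(1-p)$ of variance, so $\omega \approx 2F/(1-F)$ — the
actual spread of the query frequency around the observed reference
frequency, which is the quantity the neutral model needs.

The per-window score is a composite likelihood ratio in the spirit of
cross-population CLR sweep tests. Under neutrality the query frequency is
$\mathcal N(p_r, \omega\, p_r(1-p_r))$ truncated to $[0,1]$ and
renormalized. Under a sweep with selection parameter $s$, a SNP at distance
$d$ from the window centre escapes the sweep with probability
$c(d,s) = 1 - e^{-\rho d / s}$ ($\rho$ = recombination rate per bp, default
$10^{-8}$); with probability $1 - c$ its frequency instead follows a
hitchhiking density concentrated at the frequency boundaries. Because the
swept allele could be either the reference or the alternate, that density is
the symmetric mixture $\tfrac12\mathrm{Beta}(1/b, 1) +
\tfrac12\mathrm{Beta}(1, 1/b)$ with boundary bandwidth $b = 0.05$, which
makes the score invariant to allele relabelling. Each SNP's likelihood
integrates the binomial sampling of the observed query allele copies over
the relevant density; the composite log-likelihood is summed over the
window's SNPs and maximized over a 10-point logarithmic $s$ grid on
$[10^{-4}, 10^{-1}]$; the score is twice the likelihood-ratio, truncated at
zero (the neutral model is the $s \to 0$ boundary of the sweep model, so the
ratio is non-negative by construction). Integrals use a 400-point midpoint
rule on $(0,1)$; the tests check window scores against an independent
20,000-point quadrature.

Score equality with any external sweep-scan tool is *not* claimed — the
kernel is a simplified-but-faithful model with the same structure, and its
acceptance is property-based: nesting, null calibration, and localization
power. Region calling selects the top 1% of windows genome-wide (ties broken
by score then position; per-chromosome selection is not currently offered)
and merges selected windows on the same chromosome separated by less than
10 kb. Regions report both the merged window extent and the min/max member
SNP positions, because the data-supported extent can be much narrower than
the window extent — published sweep tables sometimes print the former, which
otherwise looks inconsistent with 50-kb windows.

## The pipeline

`run_pipeline()` chains the stages in workflow order — filter (with
optional LD pruning), structure (or an explicit group table), diversity,
differentiation, LD decay, sweep scan — writing per-stage TSVs, a run log,
and a plain-text report whose sections mirror the standard result tables
(AMOVA; pairwise Fst/D/Id/Nm; per-group Na/Ne/h/uh/I/π; sweep regions with
start, stop, SNP count and mean score). One global seed derives every stage
seed by fixed offsets, so a single integer reproduces a run byte-for-byte;
all report numbers are re-derivable from the stage TSVs.

## Problem sizes used in the automated experiments

The test and acceptance experiments use sizes chosen once as realistic
desk-scale study conditions:

* Fst recovery: $F \in \{0.05, 0.1\}$, 50 samples/population, 5,000 loci,
  10 seeds; the mean $\Phi_{PT}$ must lie within ±0.02 of $F$.
* Admixture recovery: 2 populations, 50/population, 2,000 loci,
  `admix_alpha = 0.3` (substantial admixture); Q-matrix RMSE < 0.05 after
  label alignment. Model selection: 30/population, 600 loci, K fitted 1–4
  with 3 replicates; $\Delta K$ must pick the true K in ≥ 8/10 seeds.
* Sweep scan: 2 chromosomes × 5 Mb with 4,000 loci (≈ 20 SNPs per 50-kb
  window, comparable to a dense GBS panel), sweep of strength 150 kb at
  2.5 Mb; the top-scoring merged region must contain the sweep position in
  ≥ 80% of 25 seeds, and windows of null scans must exceed the sweep runs'
  99th-percentile score at most 2% of the time.
* AMOVA calibration: 200 null panels (20 samples, 60 loci, 199
  permutations); the rejection rate at $\alpha = 0.05$ must sit inside the
  99% binomial band.

## Limitations

* The generator has no coalescent structure, no recombination-driven LD, no
  demographic history and no sequencing-error model. Passing recovery tests
  demonstrates correctness of the estimators under the stated generative
  model, not robustness to the full complexity of real GBS data.
* Sweep `strength` is a physical footprint scale, not a selection
  coefficient; the scan's $\hat s$ is comparable only within a run.
* Missingness is MCAR, while real GBS missingness correlates with depth and
  allele; the missingness filters are exercised, not stress-tested.
* The AMOVA is two-level (among/within groups); deeper hierarchies are out
  of scope.
* LD decay distances depend on the binning and smoothing choices documented
  above; published decay values obtained with other fitting conventions are
  context for comparison, not targets.
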