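---
title: "Methods and design of bomscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of bomscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bomscope` implements an integrated bulk + single-cell screen for gene
programs associated with bone metastasis (BoM). The study design it
supports is: (i) a two-tier bulk differential-expression contrast
(metastatic vs non-metastatic, then bone-metastatic vs other metastatic)
whose upregulated overlap defines a gene panel; (ii) single-cell
profiling of that panel across annotated cell subgroups; (iii) a
condition-stratified upregulation screen within subgroups of interest;
(iv) a five-step ligand-receptor (L-R) candidate screen between a
sender and a receiver subgroup; (v) Pearson-correlation validation of
candidate genes within subgroups and across bulk cancer-type cohorts;
and (vi) hypergeometric over-representation of the panel against
user-supplied gene sets. Upstream steps that require external services
or orthogonal machinery -- accession download, doublet removal, dataset
integration, clustering, embedding -- are out of scope: subgroup labels
and condition labels are *inputs*.

# Statistical models and procedures

## Bulk differential expression

Raw counts are normalized with median-of-ratios size factors: for
sample $j$, $s_j = \mathrm{median}_g\, c_{gj}/(\prod_k c_{gk})^{1/n}$
over genes with a positive geometric mean. Inside the test the factors
are rescaled to geometric mean 1 so the normalized scale is anchored.
Multiplying a single sample's column by a constant $c$ is absorbed by
its size factor up to the residual global factor $c^{1/n}$ inherent to
the geometric-mean reference; the Wald statistic is not *exactly*
invariant to that residual because the Poisson part of the NB variance
is genuinely scale-dependent (tripling one sample's reads really does
lower its relative shot noise -- no NB Wald test normalized this way,
including the reference tools, is exactly invariant). The test suite
asserts the attainable contract: factors absorb the multiplier exactly
up to $c^{1/n}$, z shifts stay below 0.05 (median below 0.01), and
significance calls are essentially unchanged.

Counts are modeled as negative binomial with
$\mathrm{Var} = \mu + \alpha\mu^2$. The gene-level dispersion $\alpha$
is estimated by the method of moments from pooled within-group sample
variances, floored at 1e-8. The effect is
$\log_2\mathrm{FC} = \log_2\frac{\bar y_2 + 0.5}{\bar y_1 + 0.5}$
(pseudo-count 0.5 against division by zero; negligible at moderate
counts), with a delta-method standard error
$\mathrm{SE} = \frac{1}{\ln 2}\sqrt{\sum_g \frac{\bar y_g + \alpha \bar
y_g^2}{n_g(\bar y_g + 0.5)^2}}$ and a two-sided normal p-value.
Benjamini-Hochberg adjustment is applied across genes and a gene is
called *up* when the adjusted p is below `alpha` (default 0.05) with a
positive fold change. This is deliberately a transparent,
moment-based approximation of the shrinkage-based reference tools: the
same null family and the same decision rule, but analytically
checkable. Dispersion shrinkage, outlier replacement, independent
filtering and multi-factor designs are non-goals. The panel is the
lexicographically ordered intersection of the two contrasts' up-sets.

## Single-cell statistics

Counts are log-normalized per cell:
$y_{gc} = \ln(1 + 10^4\, c_{gc}/T_c)$ with $T_c$ the cell's total
count; zero-total cells are dropped with a message.

*Dot profiles* report, per (subgroup, gene), the mean of $y$ and its
z-score across subgroups (sample SD, ddof = 1; genes with zero variance
across subgroups get z = 0 so profiles remain plottable), plus the
positive-expression ratio: the fraction of the subgroup's cells with
raw count > 0.

*Markers* are one-vs-rest two-sided Wilcoxon rank-sum tests on $y$,
restricted to positive candidates (in-subgroup detection $\ge$ 10%, ln
fold change of means $\ge$ 0.25 with pseudo-count 1e-9), with BH
adjustment per subgroup across its tested genes. The reference tool's
defaults are mirrored where its parameterization is not stated; the
family of the BH adjustment (per subgroup rather than global) is our
choice and is documented here because the source procedure does not
state one.

The rank-sum test uses the exact permutation distribution (an in-house
dynamic program over rank sums) when the pooled size is at most 16 and
there are no ties; otherwise the normal approximation with tie
correction and continuity correction. Two-sided exact p-values are
twice the smaller tail, capped at 1.

## Condition screen

Within one subgroup, cells are split into BoM-derived and all other
cells. Genes detected in more than `min_ratio` (default 10%) of the
subgroup's cells are tested (two-sided Wilcoxon on $y$); a gene is
`up_in_bom` when p (default: raw, matching the stated "p < 0.05" rule;
BH and Bonferroni are available) is below `alpha`, its mean $y$ is
higher in BoM cells, and its detection among BoM cells exceeds
`min_ratio`. Directionality is enforced by the sign of the mean
difference rather than a one-sided test. Multi-level sample-type
comparisons of a single gene use all pairwise Wilcoxon tests with
Bonferroni correction over the number of tested pairs and the usual
star coding (0.05 / 0.01 / 0.001).

Cell-level testing ignores per-sample nesting (2 vs 2 samples in the
default fixture); pseudobulk or mixed-model alternatives are an
acknowledged limitation, not implemented.

## Ligand-receptor screen

Against a simple-pair database (complexes must be pre-expanded), the
five steps are: take the database; test each database ligand in the
sender subgroup's BoM vs Other cells; keep significantly upregulated
ligands (raw p < `alpha`, positive mean difference) whose detection
*among BoM cells* (BoM-only denominator -- deliberately different from
the condition screen's subgroup-wide denominator, following the source
procedure's wording) exceeds `min_ratio`; screen receptors in the
receiver subgroup the same way; and admit database pairs whose two
genes both qualify. No multiplicity correction is applied inside the
screen by default. Tests use log-normalized values; a rank test is
invariant to monotone transforms within a cell but not across cells, so
this is a real (documented) choice.

## Correlation validation

Pearson r with the two-sided t-based p on $n-2$ degrees of freedom, r
clamped to $[-1, 1]$; zero variance yields an explicit degenerate
status rather than NaN. The high-correlation flag combines r >
`high_corr_threshold` (default 0.2) with p < `alpha`. Cells with zero
expression are retained by default (an expressing-cells-only mode
exists). In the pan-cancer bulk mode genes are z-scored within each
cancer-type cohort before correlating; z-scoring does not change r (it
is affine-invariant) and is kept only so emitted values are on a
comparable scale across cohorts.

## Over-representation

For a query of $n$ universe genes against a set with $K$ universe
members, $p = P(X \ge k)$ with
$X \sim \mathrm{Hypergeometric}(N, K, n)$, BH-adjusted across sets.
Gene identifiers are plain symbols; organism annotation databases and
identifier mapping are out of scope, so the universe defaults to the
genes of the supplied count matrix and gene sets come from a GMT file.

# The synthetic-data generator

The generator is first-class, tested code: it is the package's test
surface for every downstream stage, emitting a planted-truth ledger
(`sim_truth`) alongside the data.

**Bulk.** Three arms (nonMeta / Meta-nonBoM / Meta-BoM), default 20
samples each, 2,000 genes, NB dispersion 0.1, baseline mean 50,
log-normal library factors (sigma 0.15). 100 genes are planted up
(log2FC 2) in the Meta contrast, 60 in the BoM contrast, 30 in both --
a desk-scale analog of the cohort-scale funnel (thousands up in
metastasis, ~hundred up in bone metastasis, a few dozen overlapping).
One non-obvious construction: BoM-only genes have their nonMeta mean
raised to the Meta-arm average multiplier $(1 + 2^{lfc})/2$. At cohort
scale BoM samples are a sliver of the Meta arm and a BoM effect is
invisible to the Meta contrast; at 20/20/20 they are half of it and
would bleed through, making the "overlap = panel" ground truth false
for reasons unrelated to the methods. The balancing keeps each planted
set upregulated exactly in its designated contrast.

**Single cell.** Per (sample, subgroup) block, NB counts with gene
baseline means drawn log-normal (meanlog $\ln 0.5$, sdlog 1) and
rescaled once so the expected zero fraction matches the `sparsity`
target (default fixture: 0.85, a realistic droplet-data zero fraction).
Marker genes are elevated $2^{2} = 4\times$ in their subgroup
everywhere; condition effects and L-R programs apply only in BoM-derived
cells. Zeros arise from the NB itself -- there is no separate dropout
process -- which keeps every planted effect analytically checkable.

The default "breast-like" fixture mirrors a two-condition
xenograft/bone-metastasis design: 4 samples (2 PDX = Other, 2 BoM), 8
subgroups (one fibroblast-like sender, two tumor-like receivers, plus
myeloid/T/B/endothelial/stromal populations), 1,500 genes, ~4,000
cells, seed 42. Planted structure: 5 markers per subgroup; 150 genes up
(log2FC 3) in BoM fibroblast-like cells; 10 L-R programs
fibroblast-to-tumor at log2FC 2 with co-expression rho 0.5. All planted
genes are drawn from the expressed pool (expected detection rate >=
25%): a silent planted gene can never be recovered by ratio-filtered
screens, so planting it would test nothing. The 150-gene condition
program was sized a priori by a power/precision argument: with raw
p < 0.05 and directionality the null up-call rate is ~2.5% of the
~600-800 tested genes, so the planted fraction must dominate ~15-20
expected false calls for precision 0.9 to be achievable at all; the
source study's own screen called 723 genes in its fibroblast subgroup,
so a large planted fraction is also the realistic regime.

**L-R co-expression.** Each program adds a shared standard-normal
latent factor to the log-means of its two genes within BoM cells of
both endpoint subgroups. The amplitude is *calibrated numerically*: the
Pearson correlation of the two genes' log-normalized values is computed
under the full observation model (NB sampling, log1p compression,
zeros, and the latent factor's own mean inflation) on a Gaussian
quadrature grid, and the amplitude solving corr = rho is found by
bisection. A closed-form variance-ratio amplitude systematically
undershoots the target (observed r ~0.25 for a nominal 0.5) because
zeros and the log transform attenuate correlations; calibration against
the observation model is what makes "rho means rho" true. Planted
correlations are therefore stated for BoM cells of the endpoint
subgroups, and the truth ledger records the program genes as
condition-upregulated in both endpoint subgroups (they are).

**Decoy database.** `simulate_lr_db` samples decoy pairs uniformly
without replacement from ordered non-self pairs, excluding true pairs.
The default fixture database draws decoys from expressed genes
*excluding* planted-effect genes: a decoy built from two genes the
generator itself elevates in BoM cells is genuinely co-upregulated, and
calling it a false positive would misstate precision.

**What a green test does not establish.** The generator has no doublets,
ambient RNA, batch effects, UMI saturation, sample-level random
effects, or mean-variance trends beyond a single shared dispersion.
Recovery results on it validate the *screens' logic and calibration*,
not robustness to those real-data phenomena. Null-calibration bands
(e.g. type-I fraction in [0.03, 0.07]) are properties of this stated
world and were verified, not tuned.

# Numerical and design choices

- Deterministic ordering everywhere: screens sort by (p, gene id),
  panels and gene sets lexicographically (radix, locale-independent);
  reruns are byte-identical.
- Seeded generation restores the caller's RNG state afterwards.
- Exact Wilcoxon path only without ties and pooled n <= 16; ties fall
  back to the corrected normal approximation (exact p undefined under
  ties is an error if forced).
- Zero-variance z-scores are 0, zero-variance correlations are an
  explicit status, all-zero genes are `ns` with p = 1.
- The pipeline config is JSON-first (YAML supported when the yaml
  package is installed); every headline threshold (0.05, 10%, 0.2) is a
  named field with that default.
- Gene namespace harmonization upper-cases symbols and suffixes
  collisions.

# Known limitations

Cell-level tests ignore per-sample correlation; the NB Wald test has no
dispersion shrinkage and is slightly liberal at very small sample
sizes; the L-R screen scores marginal upregulation of the two genes,
not interaction per se (permutation-based interaction scoring is a
non-goal); enrichment is a plain hypergeometric ORA without ontology
topology. Reproducing the source study's absolute counts requires its
external accessions, original clustering and pinned database versions,
all out of scope; the acceptance suite is property-based instead.
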