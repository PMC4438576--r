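---
title: "Consensus signatures and druggable-target ranking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus signatures and druggable-target ranking: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetsig)
```

## The analysis problem

Rare tumors such as pediatric adamantinomatous craniopharyngioma (ACP) come
in small cohorts — here, 15 target samples profiled alongside roughly 195
reference samples spread over ~14 groups of other brain tumors, peripheral
pediatric tumors, normal brain and pituitary tissue. Two questions drive the
analysis:

1. Which genes form the *consensus signature* of the target tumor — genes
   differentially expressed against **every** reference group, in the same
   direction each time?
2. Among genes that are targets of existing oncology drugs, which are so
   consistently overexpressed in the target cohort that they are plausible
   candidates for repurposed therapy?

`targetsig` implements these two analyses plus their supporting stages
(probeset collapse, pre-filtering, sample clustering, gene-set
over-representation) and a synthetic-cohort generator that makes the whole
chain testable with known ground truth.

## Differential expression: the moderated t

Each pairwise comparison of the target group against one reference group is
an equal-variance two-group model on log2 intensities. With per-gene pooled
residual variance $s_g^2$ on $d$ degrees of freedom, the empirical-Bayes
model places a scaled-inverse-chi-square prior on the true variances,

$$\sigma_g^2 \sim d_0 s_0^2 / \chi^2_{d_0},$$

so that marginally $s_g^2 \sim s_0^2 F(d, d_0)$. The hyperparameters are
estimated by moment matching on $z_g = \log s_g^2$: the excess of
$\mathrm{var}(z)$ over $\psi'(d/2)$ identifies $d_0$ through the trigamma
function (solved by Newton iteration on the monotone trigamma inverse), and
the bias-corrected mean of $z$ identifies $s_0^2$. When the observed spread
is no larger than the sampling noise, $d_0 = \infty$ and all genes share
the scale $s_0^2$. The moderated statistic is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
  t_g = \frac{\bar x_A - \bar x_B}{\sqrt{\tilde s_g^2 (1/n_A + 1/n_B)}},$$

referred to a Student t on $d + d_0$ degrees of freedom. The test suite
verifies both limits ($d_0 \to 0$ reproduces the classical pooled t
exactly; $d_0 \to \infty$ gives the fixed-scale z-like statistic) and that
the whole per-comparison path matches an independent `limma` fit to
high precision on simulated data.

A numerical note: extremely large statistics (planted folds up to 800 with
small shrunken variances) underflow the double-precision t tail. Non-zero
p-values are floored at the smallest positive double so the pooled BH family
stays inside $(0, 1]$; rows with a zero posterior variance and non-zero
effect are flagged degenerate instead.

## Multiple testing within and across groups

All genes × all pairwise comparisons form **one** pooled
Benjamini–Hochberg family (`global_fdr()`), which is how a false discovery
rate can account for testing "within and across groups" at once. A
per-comparison family is available behind `fdr_scope = "per_comparison"`
for sensitivity analyses.

## The consensus signature rule

A gene enters the signature only if in *every* comparison: FDR ≤ 0.1, the
linear fold magnitude is ≥ 1.5, and the sign of the mean difference is the
same. Two deliberate readings, both configurable:

* **Fold scale.** "Mean fold difference ≥ 1.5" is interpreted on the linear
  scale, symmetric for downregulation (fold ≤ 1/1.5). Folds are always
  reported as $2^{\Delta}$ with the sign carried by $\Delta$.
* **Up-only variant.** The broader overexpression list (the analogue of an
  up-only screen at FDR < 0.05 with no fold floor) is
  `consensus_signature(tab, fdr_max = 0.05, fold_min = 1, direction = "up_only")`.

## Drug-target prioritization

For each gene, each target sample receives a percentile score within the
pooled reference distribution, with midrank tie handling:
$100\,(L + T/2)/N_{\mathrm{ref}}$ where $L$ references lie strictly below
and $T$ tie. The *consistency filter* requires the percentile to exceed 66
**strictly** in all target samples; near misses (down to two samples short
by default) stay visible in the ranked report. The reported fold and
p-value come from a single target-versus-pooled-rest moderated-t
comparison, matching the convention of quoting one fold change per gene
against "all other samples combined".

**Ranking key.** Candidates sort by consistency count (descending), then
average percentile (descending), then linear fold (descending), then gene
symbol. The fold key matters: with a small, tight reference panel many
strong genes saturate at percentile 100 in every sample, and without an
effect-size key the order among them would be alphabetical — whereas the
scientifically meaningful order is by magnitude of overexpression. On real
heterogeneous panels the average percentile virtually never ties, so the
fold key is inert there; the symbol remains the final, deterministic
tie-break.

## Clustering

Samples (columns) are the clustering objects. Genes are ranked by plain
variance across all samples — computed after probeset collapse — and the
top 30 % retained. Distances are $1 - \rho_{\mathrm{Spearman}}$ between
sample profiles (midrank ties; range $[0,2]$; a constant profile is an
error, not a silent NA). Agglomeration is complete linkage via the
Lance–Williams pairwise-maximum update; when two merges tie exactly on
height, the pair with the lexicographically smallest member labels merges
first, making trees identical across platforms. The Newick export writes
children smaller-label-first with branch lengths
(parent height − child height), and round-trips through `ape`.

## Gene-set over-representation

The signature's upregulated genes are tested against a user-supplied GMT
collection with the hypergeometric upper tail; the universe is **all genes
surviving the pre-filter**, not the genome, which is standard
over-representation practice when the assay itself restricts the candidate
pool. Terms with fewer than 3 in-universe members are skipped; BH runs
across tested terms; results rank by fold enrichment
$(k/n)/(K/N)$. The conservative one-hit-removed (EASE-style) variant is
opt-in (`method = "ease"`); because any external tool's term databases and
universe are proprietary to it, enrichment values from such tools are not
comparable targets and are not treated as such.

## The synthetic cohort generator

`synth_config()` defaults encode the study design the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| group sizes | 15 target + 14 reference groups totalling 195 | cohort structure |
| baseline | $N(6.0, 1.5^2)$ per gene | log2 intensity location |
| noise | $\sigma_g^2 \sim d_0 s_0^2/\chi^2_{d_0}$, $d_0 = 4$, $s_0^2 = 0.05$ | heteroscedastic per-gene noise |
| signature | 100 genes, $\delta \sim U(\log_2 1.5, \log_2 800)$ | planted target-specific overexpression |
| drug targets | 10 signature genes; one dominant at fold 800, the rest $U(\log_2 1.5, \log_2 8)$ | mirrors the one-dominant-target spread seen in real screens |
| decoys | 50 genes up in exactly one reference group | direction-consistency foils / group markers |
| probesets | 1–3 per gene, extras dimmer by 1.0 log2 per rank | makes "mean best-expressed" collapse testable with a unique answer |
| gene sets | one 20-gene term drawn from the signature + 24 random terms | enrichment ground truth |

The scaled-inverse-chi-square noise model is chosen so the moderated-t
prior is *exactly* correct, making hyperparameter recovery a sharp test
(recovered $d_0$ within 25 %, $s_0^2$ within 10 % at 5000 genes). One
global RNG stream is seeded per cohort and the caller's RNG state is
restored, so identical seeds give bit-identical cohorts.

What the generator does **not** emulate: probe-level artifacts, batch
effects, inter-group biological heterogeneity beyond the planted decoys,
heavy-tailed outlier samples, and correlated gene modules. Passing
recovery tests therefore demonstrates the machinery is correct under the
assumed model, not that real cohorts will behave as cleanly — in
particular, real reference panels produce a much richer spread of
percentile scores than the tight synthetic ones.

**Pre-filter in recovery runs.** The generator draws baselines from
$N(6, 1.5^2)$, so about half of all genes — planted ones included — sit
below the conventional log2(64) = 6 expression floor while still being
genuine signals by construction. Recovery experiments therefore run with
the pre-filter disabled (`min_max_expr = 0, min_variance = 0`); the floor
is meant to remove genes the assay never saw, a situation the generator
does not produce. On real data the defaults (6 and 0.01) apply.

**Cluster-recovery conditions.** Group recovery is assessed on a
"well-separated" configuration — 20 markers per reference group at folds
8–64 — because the default design deliberately gives reference groups no
distinguishing effects at all (they exist only to test false-positive
control), and no clustering method can recover structure that is not
there.

## Problem sizes and numerical conventions

Recovery experiments use the full default design (5000 genes, 210
samples); FDR-control checks use five 2000-gene null cohorts; oracle
equivalences use 1000 random two-group fixtures and 100 random 6-leaf
distance matrices. Other conventions: probeset-collapse ties break to the
lexicographically smaller probeset id; variance-ranking ties break by input
order; expression files serialize at 17 significant digits so read/write
round-trips are exact; the pipeline writes no timestamps, making reruns
byte-identical and the manifest (input checksums + config echo) sufficient
to reproduce a run bit-for-bit.

## Known limitations

* The equal-variance two-group model fits no covariates and no
  array/sample weights; variance–mean trend fitting is out of scope.
* The probeset collapse implements only the mean-brightest rule;
  alternatives (max-variance probeset, averaging) are deliberately not
  offered.
* Percentile scoring uses the full reference panel; no leave-one-out
  variant.
* Enrichment treats gene sets as flat; no ontology-graph propagation or
  term-redundancy clustering.
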