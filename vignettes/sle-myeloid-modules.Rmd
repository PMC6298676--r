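---
title: "Module-based analysis of myeloid-cell expression in SLE: models and methods"
author: "slemod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-based analysis of myeloid-cell expression in SLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slemod)
```

# The analysis

Systemic lupus erythematosus (SLE) flares are conventionally attributed to
B- and T-cell hyperactivity, but myeloid cells (monocytes/macrophages)
carry large transcriptional disturbances in *both* active and inactive
disease, with disease activity shifting the balance between the
proinflammatory (M1) and anti-inflammatory (M2) macrophage polarization
programs. `slemod` implements the full analysis chain used to establish
and exploit that observation:

1. **Preprocessing** — cohort assignment from the SLE Disease Activity
   Index (SLEDAI; below 6 is inactive disease, 6 or greater active),
   low-intensity probe filtering, vendor/custom annotation merging,
   duplicate-probe collapse by interquartile range (IQR), and
   batch-adjusted merging of datasets.
2. **Differential expression (DE)** — an empirical-Bayes moderated t per
   gene with Benjamini–Hochberg false-discovery-rate (FDR) control, gated
   at FDR < 0.2, and polarization scoring of the DE lists against M1/M2
   signature gene sets.
3. **Co-expression modules** — a weighted gene correlation network:
   soft-thresholded adjacency, topological overlap matrix (TOM),
   hierarchical clustering with branch cutting and eigengene merging,
   module membership (kME), and module–trait correlation (Pearson for
   continuous traits, point-biserial for dichotomies).
4. **Single-sample enrichment** — a Kolmogorov–Smirnov-like random-walk
   score per sample and gene set, and chi-squared functional-category
   enrichment of DE lists.
5. **Disease-activity classification** — elastic-net logistic regression
   on module enrichment scores with ROC/AUC evaluation and per-module
   odds ratios (OR) for active disease,
   $OR = \frac{e_a \, \bar e_i}{\bar e_a \, e_i}$ over the
   enrichment-by-activity 2×2 table.

Every stage is exercised on synthetic data with planted ground truth, so
the package's tests measure recovery, calibration, and power directly.

# The synthetic-data model

`generate_dataset()` draws

$$x_{gs} = \mu_g + \lambda_g f_{m(g),s} + \beta_{g,\mathrm{cohort}(s)} + \varepsilon_{gs},
\qquad \varepsilon_{gs} \sim N(0, \sigma^2),$$

with gene baselines $\mu_g \sim U(6, 10)$ (log2 scale) and residual SD
$\sigma$ = `noise_sd` (default 1, a typical log2 microarray residual
scale). Its components emulate the features of the real study design:

* **Cohorts and SLEDAI.** Healthy controls have SLEDAI 0; inactive SLE
  draws integers 0–5 and active SLE integers 6–20, matching the discrete
  clinical index and the activity cutoff at 6.
* **Modules.** Each `module_spec(size, factor_loading, trait_corr)`
  plants one latent factor per module. The factor is coupled to SLEDAI by
  a Gaussian copula on ranks: the normal-scores transform
  $z = \Phi^{-1}(\mathrm{rank}/(n+1))$ of SLEDAI is mixed with
  independent noise, with the mixing weight calibrated against the
  realized $\mathrm{cor}(z, \mathrm{SLEDAI})$ so the factor's Pearson
  correlation with SLEDAI hits `trait_corr` in expectation (the rank
  transform alone attenuates the correlation by a few percent because of
  the tie mass at SLEDAI 0; without the calibration the realized
  correlation would undershoot the target). Targets beyond the copula's
  attainable correlation are capped with a warning.
* **Polarization signatures.** M1 and M2 genes receive additive cohort
  shifts; the defaults (M1: +1.0 inactive, +2.0 active; M2: +1.5
  inactive, +0.4 active, log2 units) reproduce the observed ordering — M1
  up in both cohorts and larger in active disease, M2 up in both and
  larger in inactive disease. These are plain mean shifts, the simplest
  mechanism reproducing the ordering.
* **Batches.** `generate_collection()` re-samples the same gene structure
  in `n_datasets` datasets and adds an independent per-gene offset
  $N(0, \texttt{batch\_shift\_sd}^2)$ to each, emulating platform
  differences between merged cohorts.

What the generator does **not** emulate: probe-level noise and multi-probe
structure beyond the dedicated collapse fixture, mean–variance trends,
correlated residuals within samples, hierarchically nested modules, and
missing values. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under a clean factor model, not
robustness to every artefact of real microarray data.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| FDR gate | 0.2 (strict `<`) | — | deliberately permissive: downstream analyses tolerate false positives better than false negatives |
| soft power $\beta$ | chosen by scale-free fit | — | smallest power with $R^2 \ge 0.8$ *and* connectivity spread $\max k / \min k \ge 2$ |
| detection cut | 1 | tree height | upper bound on branch completion height |
| merge cut | 0.2 | $1 - \mathrm{cor(ME)}$ | eigengene dissimilarity below which modules fuse |
| `min_size` | 30 | genes | smaller branches dissolve to unassigned |
| `kme_attach` | 0.5 | correlation | final-membership rescue threshold for unassigned genes |
| mean-kME quality flag | 0.3 | correlation | below it a module is flagged low quality |
| KS-walk $\tau$ | 1 | — | weight exponent on the gene statistic |
| score mode | `diff` | — | $ES^+ - ES^-$; `maxabs` also provided |
| elastic-net $\alpha$ | 0.5 | — | equal ridge/lasso mixing; $\lambda$ by stratified CV with the 1-SE rule |
| enrichment-call threshold | 0 | score | a sample is enriched when direction × score exceeds it |

# Numerical and design choices

**Low-intensity threshold.** The interactive "pick the histogram trough"
step is automated as the first interior minimum of a kernel density
estimate of per-probe mean intensities, with a quantile fallback (and
warning) when the density is unimodal. The chosen threshold is always
recorded, so a filtering run is reproducible from its provenance log.

**Annotation merge.** Probes annotated only by the primary (vendor)
source keep it; probes annotated only by the custom source are rescued;
conflicts are excluded. When both sources agree we keep the primary
annotation — a least-surprise rule for a case the upstream procedure
leaves open.

**IQR collapse ties** break deterministically by lexicographic probe id,
making the collapse order-independent.

**Batch adjustment** is a one-step parametric empirical-Bayes
location/scale scheme: per-gene standardization against batch-structured
means and pooled variance, per-batch additive and multiplicative effect
estimates, shrinkage toward their across-gene means with a moment-matched
normal prior on location and inverse-gamma prior on scale, then removal
and back-transformation. A plain per-batch standardization mode
(`method = "standardize"`) is provided for debugging; it equals exact
per-gene batch mean-centering and scale matching. The EB mode
deliberately leaves gene-level sampling noise in place (that is the point
of shrinkage), so per-gene batch means coincide exactly only in the
plain mode. The test suite cross-checks the EB mode against an
independent reference implementation of the same model family.

**Moderated t.** Hyperparameters $(d_0, s_0^2)$ are moment-matched on
$\log s^2$ via digamma/trigamma inversion (Newton iteration for the
trigamma inverse). When the observed $\log s^2$ dispersion is at or below
what sampling alone implies, $d_0 = \infty$ and the prior variance is the
mean of the $s^2$. The reference df for p-values is
$\min(d + d_0,\, d \cdot G)$ — moderation can never claim more
information than the experiment pools across its $G$ genes. Zero-variance
genes are excluded from hyperparameter fitting but still receive a
positive posterior variance.

**Module detection.** The TOM dendrogram (average linkage on $1 -$ TOM)
is cut by a deterministic branch rule rather than a single static height:
a branch becomes a module candidate when it holds at least `min_size`
genes, completes below the detection cut, and is separated from the rest
of the tree on the topological-overlap similarity scale —
$(1 - h)/(1 - h_\mathrm{parent}) \ge 1.02$, where $h$ is the branch's
completion height and $h_\mathrm{parent}$ the height at which it merges
onwards. Chained background genes merge at ratios near 1 and never
qualify; the tree root never qualifies (a module must separate from
something). A literal static cut at height 1 is degenerate on these trees
(every merge sits below 1), which is why the branch rule replaces it.
Candidates are taken deepest-first; the over-splitting this can cause is
healed by the eigengene merge. A PAM-style pass then moves assigned genes
to the cluster with the smallest average $1-$TOM distance when strictly
closer than their own, and attaches unassigned genes to their nearest
cluster only when within that cluster's member distance range (mean + 2
SD) — without that guard the pass would absorb the entire background.
After eigengene merging, modules must pass a quality gate: the eigengene
has to explain at least twice the member-variance share expected of the
first principal component of a same-sized pure-noise matrix,
$(1+\sqrt{p/n})^2/p$. Finally, unassigned genes with kME of at least
`kme_attach` to some surviving module join it — final membership by
greatest correlation with the module eigengene, which is also how probes
representing the same gene are settled. Labels are colours in decreasing
size order; grey is reserved for unassigned genes.

**Soft-threshold selection.** The scale-free fit regresses
$\log_{10} p(k)$ on $\log_{10} k$ over 10 connectivity bins. A power only
qualifies when the connectivity distribution spans at least a factor of
2: without spread, a narrow near-Gaussian connectivity distribution can
fit a line with high $R^2$ while carrying no heavy-tail structure, and
module detection degrades badly at such powers. The network is unsigned
($|\mathrm{cor}|^\beta$), the historical default.

**Single-sample scores.** Gene-level statistics are
$\Phi^{-1}(\mathrm{rank}/(n+1))$ of each gene's values across samples
(midranks for ties), which makes scores invariant to any strictly
monotone per-gene transform. The walk ranks genes by *decreasing signed
statistic* with up-steps weighted by $|z|^\tau$: the signed ordering is
what lets the score distinguish coordinately up- from down-shifted
samples (ranking by magnitude alone places a shifted set at the top of
the list for samples shifted in either direction and destroys the
separation). Scores are bounded in $[-1, 1]$; both the `diff` and
`maxabs` score modes are provided since the choice between them is not
settled by the upstream description.

**Category tests** use the 1-df chi-squared statistic without continuity
correction over the DE-by-category 2×2 table, switching to Fisher's exact
test (flagged) when any expected cell falls below 1.

**Odds ratios** apply the printed cross-product formula directly; any
zero cell triggers the Haldane–Anscombe +0.5 correction (flagged), and
95% CIs come from the log-OR normal approximation.

**Classifier.** Elastic-net logistic regression (α = 0.5) with λ chosen
by stratified cross-validated deviance and the 1-SE rule, seeded fold
assignment, and held-out evaluation by stratified train/test split. ROC
is a full threshold sweep; AUC is the trapezoid integral and equals the
normalized Mann–Whitney U statistic, ties counted one half.

# Problem sizes used in tests

The test-suite and acceptance workloads were sized to exercise each
property at meaningful scale while keeping a full run in tens of seconds:
null FDR calibration uses 100 replicates of 2000 genes × 10 vs 10
samples; DE power uses 20 replicates with 100 of 2000 genes shifted 1.5
residual SDs; module recovery plants 5 modules × 100 genes among 2000 at
n = 40 with factor loading 0.8 and SLEDAI correlations (0.8, −0.6, 0.4,
0, −0.3); enrichment detection plants a 1-SD shift of a 50-gene set in
half of 200 samples; the classifier study uses 20 replicates of a
3-dataset collection (2 HC + 40 inactive + 40 active each, 600 genes, six
50-gene modules of which one is activity-linked at trait correlation
0.8); the OR oracle enumerates all 2×2 tables with cells up to 10.

# A note on the classifier ceiling

Under the generative model, all label information flows through the
linked module's factor, whose correlation with SLEDAI is 0.8 by design;
activity is a threshold of SLEDAI. Direct large-sample simulation of the
model puts the best achievable active-vs-inactive AUC of the *true*
factor near 0.90 (lower when healthy controls dilute the rank
transform). Any classifier on estimated module scores necessarily sits
at or slightly below this ceiling, and measured held-out AUCs
concentrate around 0.88–0.90. This is a property of the planted
conditions, not of the fitting machinery — raising `trait_corr` raises
the ceiling accordingly.

# Known limitations

* The branch-cut module detector is a deterministic simplification of
  the dynamic hybrid tree cut; very weak modules (loading well below the
  residual SD) fall under its quality gate and are left unassigned.
* The batch model is additive/multiplicative per gene; it does not model
  covariate-confounded batches, and merging cohorts whose case mix
  differs across batches will partially absorb biology into the batch
  effect (no covariates are fitted, matching the upstream procedure).
* DE contrasts are two-group mean differences; multi-factor designs,
  array weights, and variance trends are out of scope.
* Single-sample scores are relative within the scored cohort (rank-based
  across samples); scores are not comparable across independently scored
  matrices.
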