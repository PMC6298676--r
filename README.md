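# slemod

Module-based transcriptomic analysis of myeloid-cell gene expression in
systemic lupus erythematosus (SLE).

SLE disease activity is clinically scored by the SLE Disease Activity
Index (SLEDAI; a score of 6 or greater defines active disease). While B-
and T-cell abnormalities dominate in active disease, myeloid cells
(monocytes/macrophages) are transcriptionally disturbed in *both* active
and inactive SLE, and disease activity shifts their activation balance
toward the proinflammatory M1 polarization state. `slemod` is a tested,
reusable implementation of the analysis chain behind that kind of study,
for computational immunologists who want each step as a callable,
verifiable function:

* **Differential expression** — per-gene moderated t with empirical-Bayes
  variance shrinkage: pooled variance $s^2$ (df $d$) shrunk toward a
  moment-matched prior $(d_0, s_0^2)$,
  $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$,
  $t = \Delta / (\tilde s \sqrt{1/n_a + 1/n_b})$, Benjamini–Hochberg FDR,
  gated at FDR < 0.2; M1/M2 polarization scoring of the DE lists.
* **Co-expression modules** — unsigned weighted network
  $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ with $\beta$ from the
  scale-free fit; topological overlap
  $TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$;
  branch cutting with eigengene merging (merge cut 0.2), module
  eigengenes (first principal component), kME membership, mean-kME
  quality, and module–trait correlation (Pearson / point-biserial).
* **Single-sample enrichment** — a Kolmogorov–Smirnov-like random walk
  over rank-normal gene statistics, one score per sample and gene set,
  bounded in [−1, 1].
* **Disease-activity classification** — elastic-net logistic regression
  on module enrichment scores (cross-validated λ, 1-SE rule), ROC/AUC by
  threshold sweep, and per-module odds ratios for active disease:
  $OR = (e_a \cdot \bar e_i) / (\bar e_a \cdot e_i)$ with
  Haldane–Anscombe correction for zero cells.
* **Synthetic data with planted truth** — a latent-factor generator that
  plants co-expression modules with chosen SLEDAI correlations, M1/M2
  cohort effects, and per-dataset batch offsets, so recovery, calibration
  and power are measurable.

## Worked example

The `analysis/` directory holds the six-stage workflow; each stage is a
thin driver over package functions and writes its tables under
`results/`. Running them in order:

```sh
Rscript analysis/01_simulate.R     # synthetic study + 3-dataset collection
Rscript analysis/02_preprocess.R   # filtering, annotation, batch merge
Rscript analysis/03_diffexp.R      # DE vs healthy, polarization scoring
Rscript analysis/04_modules.R      # co-expression modules, module-trait
Rscript analysis/05_enrichment.R   # single-sample scores, categories
Rscript analysis/06_classify.R     # activity GLM, ROC, odds ratios
```

prints, among other things:

```
DE genes at FDR<0.2: active 269, inactive 130 (of 2000)
       cohort signature n_in_de n_up fraction_up
   SLE_active        M1      50   50           1
 SLE_inactive        M2      50   50           1
commonly upregulated genes: 63; median delta M1 +0.90, M2 -0.90

modules: blue 95, brown 92, green 33, turquoise 97, yellow 47 | unassigned: 1636
    module  trait  trait_kind           r            p  n
    yellow sledai  continuous  0.81682426 1.761692e-15 60
     brown sledai  continuous  0.75117899 4.726012e-12 60
 turquoise sledai  continuous -0.58704489 8.224477e-07 60

held-out AUC: 0.922 (test n = 72)
label-permutation AUC: 0.500
  module odds_ratio    ci_low   ci_high
 CT_mod1 15.6896552 8.3017290 29.652290
 CT_mod6  1.2631579 0.7608370  2.097122
```

Reading the output: both SLE cohorts carry substantial differential
expression versus healthy controls, with the planted asymmetry visible in
the polarization table (all M1 overlap genes up, with larger fold changes
in active disease — the positive median delta — and M2 the mirror
image). Module detection recovers the planted modules plus the two
signature blocks, and the SLEDAI-linked module (yellow, r = 0.82) is
found where it was planted. On the merged three-dataset collection, the
activity-linked module's enrichment score dominates both the classifier
(held-out AUC 0.92, permutation control at chance) and the odds-ratio
ranking (OR 15.7 vs ~1 for the null modules).

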