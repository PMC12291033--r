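---
title: "Integrating multiassay LC-MS data with multiblock PLS"
author: "crossassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating multiassay LC-MS data with multiblock PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossassay)
```

Untargeted LC-MS metabolomics rarely fits into one analytical assay: polar
metabolites need HILIC columns, lipids need reversed-phase, and many ions
are only seen in one polarity. A study therefore produces several
feature-intensity tables over the same samples, and a single metabolite
typically appears as *many* features — adducts, isotopologues, in-source
fragments — often spread across assays. `crossassay` models all blocks
jointly against a phenotype, selects the features that drive the
association, and then reassembles those features into compound-level
groups using exact-mass arithmetic.

## The multiblock PLS model

Each assay contributes a block $X_b$ ($N \times M_b$), and the response
$Y$ is a single column (continuous, or a binary outcome encoded 0/1 and
modeled by regression, the usual PLS-DA convention). Per latent variable
the algorithm iterates, starting from $u = Y$:

1. block weights $\tilde w_b = X_b^\top u / (u^\top u)$, normalized to
   $\lVert w_b \rVert = 1$;
2. block scores $t_b = X_b w_b$, collected into $T = [t_1 \dots t_B]$;
3. super weights $\tilde w_T = T^\top u / (u^\top u)$, normalized;
4. super scores $t_T = T w_T$;
5. $u$ updated from $Y$ and the y-loading $c = Y^\top t_T / (t_T^\top t_T)$.

For a univariate $Y$ the inner loop converges essentially immediately
(we still iterate to a $10^{-10}$ relative tolerance with a 500-iteration
cap, erroring with the component index on failure). After each component
every block *and* the response are deflated by the super score:
$X_b \leftarrow X_b - t_T p_b^\top$ with $p_b = X_b^\top t_T /
(t_T^\top t_T)$, and $Y \leftarrow Y - t_T c$.

Super-score deflation is a deliberate choice: the literature states the
deflation step for multiblock PLS in several variants, and this one makes
the model *exactly* equivalent to a single PLS on the column-concatenated
blocks whenever all blocks share one scaling. That equivalence is the
anchor of our test suite — the package's multiblock fit is compared
against an independently coded single-matrix NIPALS PLS at $10^{-8}$
relative tolerance (it agrees to ~$10^{-16}$ in practice), and it also
implies super scores are mutually orthogonal. Regression coefficients
$\beta$ on the concatenated scaled space are assembled from the standard
weight/loading recursion, so prediction is a single matrix product:
$\hat y = X_{\text{scaled}}\,\beta + \bar y$.

Blocks are always centered per feature; the default scale divisor is the
feature standard deviation (unit variance), with Pareto
($\sqrt{\text{sd}}$) and none as options, and a per-assay override map —
the point of a multiblock model is precisely that different assays may
need different scalings. Zero-variance features are an error, named.

**Block importance.** For block $b$ and component $r$ we take the
explained sum of squares of the rank-1 reconstruction
$\lVert t_{T,r} p_{b,r}^\top \rVert_F^2$ over the block's total scaled sum
of squares, divide by $M_b$ (so a block is not rewarded for merely being
wide), and renormalize each component across blocks to sum to one. The
per-feature normalization *before* renormalization is one admissible
reading of "normalized by the number of features"; we fixed it because it
makes equal-information blocks of different widths score equally.

## Feature importance and selection

The multiblock VIP of feature $j$ is

$$\mathrm{VIP}_j = \sqrt{M \,\frac{\sum_r \mathrm{SSY}_r\, v_{jr}^2}
{\sum_r \mathrm{SSY}_r}},$$

where $\mathrm{SSY}_r = c_r^2\, t_{T,r}^\top t_{T,r}$ is the
response variance captured by component $r$ and $v_r$ is the unit-norm
concatenation over blocks of $w_{T,b,r} w_{b,r}$. With one block this is
the classical PLS VIP, and under shared scaling it equals the VIP of the
concatenated-matrix PLS — both properties are tested, and
$\operatorname{mean}_j \mathrm{VIP}_j^2 = 1$ holds identically.

VIP has no analytic null, so p-values are empirical: the response rows
are permuted `n_permutations` times with a seeded generator, the model is
refit with the *same* component count and scaling (re-tuning per
permutation is possible but off by default — it multiplies cost and
rarely changes the selected set), and

$$p_j = \frac{1 + \#\{k : \mathrm{VIP}_j^{(k)} \ge \mathrm{VIP}_j^{\mathrm{obs}}\}}
{n_{\mathrm{perm}} + 1}.$$

The add-one estimator keeps $p_j \ge 1/(n_{\mathrm{perm}}+1)$; note the
practical consequence that a Bonferroni cutoff $0.05/M$ is unattainable
when $M > 0.05\,(n_{\mathrm{perm}}+1)$ — with 900 features you need well
over 18&thinsp;000 permutations for any feature to clear it. The cutoff
benchmark treats an empty selection as a skippable candidate (with a
warning), not an error. Permutations are drawn up front from the seed, so
results depend only on `(seed, n_permutations)`, never on execution
chunking.

**Choosing the cutoff.** Candidates default to 0.05, 0.01 and Bonferroni.
For each, the model is refit on the selected subset and evaluated by
MCCV; the chosen cutoff selects the fewest features among those whose
mean performance is at least the all-features baseline mean minus one
baseline CI half-width. The one-half-width slack operationalizes
"performs better or equally"; without some slack the rule would be
dominated by Monte Carlo noise. Ties go to the most stringent cutoff,
and if nothing qualifies the baseline (no selection) is returned with a
flag.

## Evaluation

- Latent-variable count: grid search with $k$-fold CV (default $k=5$,
  grid 1–8, folds stratified by class) scored by $Q^2$ or accuracy, then
  the **1-SE rule**: the smallest $R$ within one standard error of the
  best mean. PLS grids are cheap here because nested component counts
  reuse one fit per fold.
- Model evaluation: Monte Carlo CV, default 1000 random 80/20 splits
  (stratified for classification; a split with a one-class training set
  is redrawn and counted). Centering and scaling are learned on each
  training split only — a leakage canary test asserts this.
- $Q^2 = 1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$ with $SS_{\mathrm{tot}}$
  centered on the *training* mean (out-of-sample convention). AUC is the
  rank-based Mann-Whitney estimator; F1 is computed on the positive
  class, which is the lexicographically larger label unless configured.
- CIs default to $\bar m \pm z\,\mathrm{sd}/\sqrt{\text{repeats}}$ at 90%
  ($z = 1.645$); the tightness of SE-based intervals at 1000 repeats is
  why they are the default, with percentile intervals as an option.

## Correlation clustering

Selected features are clustered on $d_{ij} = |1 - r_{ij}|$ (Pearson by
default, Spearman optional). Note $|1 - r|$ maps $r = -1$ to the maximal
distance 2 — anti-correlated features are *not* near. Complete-linkage
hierarchical clustering is flattened at each $k$ in 2..min($M-1$, 30) and
the $k$ with the highest mean silhouette (computed from the same $d$,
never re-derived) wins; ties break toward fewer clusters for
interpretability. Fewer than three features returns one cluster with a
degenerate flag.

## Structural search

Within one assay, two features co-eluting within `rt_tol` (default 2 s)
are linked as **isotopologues** when their m/z difference is
$k \times 1.003355$ Da ($^{13}$C spacing, $k \le 3$) within `ppm_tol`
(default 5 ppm, relative to the lighter ion), and as **adducts** when
their de-adducted neutral masses agree under some pair of distinct
same-polarity rules. The shipped rule table covers [M+H]+, [M+Na]+,
[M+2Na−H]+, [M+H−H2O]+, [M−H]− and [M−H−H2O]− (proton 1.007276 Da,
Na 22.989218 Da), assuming singly charged ions — reasonable for
small-molecule and lipid assays, and multi-charge deconvolution is out of
scope. **Cross-assay** links compare candidate neutral masses only: HILIC
and RPC retention times are incomparable, so RT is deliberately not
gated across assays (an optional switch enables it for same-column
polarity pairs). When several rule pairs explain one mass difference the
lowest-ppm-error pair is primary and the rest are kept as alternatives.

Connected components of the union edge set are **structural groups** —
feature sets presumed to originate from one compound. Group summaries
record assays spanned, edge-type composition, and whether the group sits
inside a single correlation cluster. ROI tables (compound, reference m/z,
reference RT per chromatography; column names config-mapped because ROI
schemas vary between tools) provide putative level-3 annotations: a
direct match within tolerance annotates a feature, and the annotation
propagates to its whole structural group as an explicitly marked indirect
match; conflicting direct annotations within a group are all retained and
flagged.

## The synthetic-data generator

`simulate_multiassay()` emulates exactly the structure the workflow
assumes: several blocks over shared samples, a response driven by latent
structure, and planted compounds emitting correlated ion series.
Per compound, a neutral mass is drawn uniformly on 150–900 Da —
rejection-sampled so that no pair of compounds is within 0.05 Da of *any*
rule-delta/isotopologue combination, keeping the planted partition
identifiable at any sensible tolerance — plus one RT per assay (pairwise
separated by more than 6 s, so the co-elution gate cannot bridge
compounds). Ions follow the same rule table the search uses (one shared
source of truth): the identity adduct always, extra adducts and +1/+2
isotopologues with configurable probabilities, Dirichlet yields that let
the protonated/deprotonated form dominate, as in real adduct intensity
hierarchies. Intensities are lognormal:
$\log X = \text{base} + \log(\text{yield}) + b_c + \sigma \varepsilon$
with $b_c$ the compound signal.

For classification, $b_c = \Delta (y - 0.5) + e_c$ and the default
$\Delta = \sqrt{2(1+\sigma^2)}\,\Phi^{-1}(0.8) \approx 1.24$ makes every
planted ion's univariate AUC $\approx$ 0.8 — a realistic "clear but not
trivial" biomarker. For regression the compounds load on an
$R_{\mathrm{true}}$-dimensional latent score that also generates the
response. The default study conditions are $N = 200$ samples, three
blocks (two positive, one negative) of 300 features, and 8 planted
compounds; an optional anchor compound (neutral mass 584.2634 Da with an
[M+H]+/[M+Na]+ series across all assays, mirroring the classic bilirubin
adduct pattern) guarantees at least one cross-assay multi-adduct group
for testing.

What the generator does *not* emulate — and hence what passing tests do
not certify on real data: realistic isotopic abundance ratios (yields are
only monotone-decreasing), in-source fragmentation, ionization
suppression and detector saturation (both nonlinear), batch/run-order
drift, and missing values (the readers accept complete preprocessed
tables and offer only drop-or-fail policies, since imputation belongs
upstream).

## Numerical choices and degenerate inputs

- Everything is deterministic given the seed: same configuration, same
  bytes in every exported table (tested by checksum).
- Numeric outputs are formatted at 17 significant digits on export so
  feature tables round-trip bit-exactly.
- Inner-loop tolerance $10^{-10}$ on the super score; weight norms below
  $100 \times$ machine epsilon raise "no remaining covariance".
- Degenerate cases are contracts, not crashes: empty tables, disjoint
  sample sets, zero-variance or constant features, ROI references outside
  their own windows, and zero-feature cutoffs all have defined behavior.
- Test and acceptance problem sizes are the package's own defaults
  (N = 200, 3 × 300 features, 1000 permutations, 250 MCCV repeats for the
  benchmark); the full suite runs in about a minute on one core because
  permutation refits reuse pre-scaled blocks.

## Known limitations

MB-PLS is linear; saturated detectors or suppressed ionization bend the
intensity-phenotype relation in ways no linear latent model captures.
Empirical p-values are floor-limited by the permutation count, which
interacts with Bonferroni-type cutoffs as described above. The structural
search is rule-table-driven: an adduct not in the table is invisible, and
annotation is only as good as the ROI list (level 3 at best — no MS/MS
evidence). Cross-assay links are mass-only by design and can in principle
connect isobaric compounds that true co-analysis would separate.

```{r example, eval = FALSE}
sim <- simulate_multiassay(sim_spec(seed = 42))
ds  <- sim$dataset
R   <- select_n_components(ds, eval_config(seed = 42))$n_components
vip <- permutation_pvalues(ds, R, n_permutations = 1000, seed = 42)
bench <- benchmark_cutoff(ds, vip, eval_config(mccv_repeats = 250, seed = 42))
sel <- subset(dataset_features(ds), feature_id %in% bench$selected)
net <- build_structural_groups(
  rbind(do.call(rbind, lapply(split(sel, sel$assay), within_assay_links)),
        cross_assay_links(sel)),
  sel)
print(net)
```
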