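---
title: "Allometric deviation with a phylogenetic gate: model, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric deviation with a phylogenetic gate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodev)
```

## The model

`allodev` asks whether a designated target species deviates from the
allometric expectation set by a group of reference species. The data are
species-mean volumes (cc) of a brain structure and of the cerebral
hemispheres, plus a dated ultrametric phylogeny (branch lengths in
millions of years). The scaling model is the standard power law, linear
after log10 transformation:

$$\log_{10} V_{struct} = a + b \,\log_{10}(V_{hemi} - V_{struct}) + \varepsilon$$

The subtraction on the predictor side is the part-whole correction: a
structure regressed on a total containing itself produces spurious
correlation, so each species' own structure volume is removed from its
hemisphere volume before taking logs. Note the consequence that the
predictor differs between structures analyzed from the same specimens.

The residual $\varepsilon$ may carry phylogenetic signal. We model it
with Pagel's λ: residual covariance $\sigma^2 V_\lambda$, where
$V_\lambda$ keeps the Brownian-motion variances on the diagonal and
scales the shared-history off-diagonal entries by $\lambda \in [0, 1]$.

### The λ gate

λ is estimated by maximum likelihood: at each candidate λ the intercept,
slope and residual variance are re-estimated by GLS under $V_\lambda$,
and the profile is maximized by bounded scalar search (`optimize`,
tolerance 1e-6) with both endpoints evaluated explicitly, since the
profile often peaks at a boundary. Likelihood-ratio tests against λ = 0
and λ = 1 use the 50:50 mixture of a point mass and $\chi^2_1$, the
standard correction when the null value lies on the boundary of the
parameter space; the significance threshold is 0.05.

The gate then routes the downstream fit:

* λ̂ not significantly different from 0 → **OLS** on the species means;
* λ̂ not significantly different from 1 → **independent contrasts**
  (through-origin regression on Felsenstein's standardized contrasts,
  which is algebraically identical to GLS under the Brownian covariance
  — the test suite checks this equivalence to 1e-8);
* distinguishable from neither, or from both (possible at small n):
  the endpoint with the higher profile likelihood wins and a warning is
  issued. Small reference sets rarely have power to reject either
  endpoint, so this tie-break is exercised routinely at n = 7.

With only one estimated signal parameter and small species samples we
deliberately do not fit intermediate λ in the final regression: the gate
mirrors the two-regime practice common in comparative volumetrics, and
the estimate itself (plus both LRT p-values) is always recorded in the
model object for inspection.

### Prediction intervals and the deviation call

The target species is never part of the fit. Its expectation is a
*new-observation* prediction interval at its own $x_0$:

* **OLS mode** — the textbook interval
  $\hat y_0 \pm t_{n-2}\, s \sqrt{1 + 1/n + (x_0-\bar x)^2 / S_{xx}}$.
* **Contrasts mode** — the exact GLS conditional prediction under the
  Brownian covariance: conditional mean
  $\hat y_0 = x_0^\top\hat\beta + v_0^\top V^{-1}(y - X\hat\beta)$ and
  variance $s^2\,(v_{00} - v_0^\top V^{-1} v_0 + d^\top (X^\top V^{-1}
  X)^{-1} d)$ with $d = x_0 - X^\top V^{-1} v_0$, on $n-2$ degrees of
  freedom. The covariance $v_0$ between the new tip and the references
  comes either from the target's true position in the supplied tree
  (`attachment = "tip"`, the default when available) or from treating it
  as a fresh lineage branching at the root (`attachment = "root"`,
  $v_0 = 0$, $v_{00}$ = tree depth).

Historical software in this area produced somewhat inflated contrasts
intervals; we instead target *nominal coverage* as the contract and
verify it by simulation (below). Root attachment discards the shared
history between target and references and therefore over-covers
(~99% empirically at the 95% level); it is retained because it matches
the older convention and is the only option when the target is absent
from the tree.

Classification is by band position in log space — equivalent to
arithmetic space since the antilog is monotone, which the suite also
checks. The headline statistic is the percent residual
$[(Y_{obs} - Y_{pred})/Y_{obs}]\times 100$ on untransformed volumes:
bounded above by 100, unbounded below (a structure three times smaller
than predicted scores −200%, so large negative values read as "-fold
smaller"). A target inside the two-sided interval but beyond the
one-sided 95% bound is flagged as "upper tail"; published phrasing of
that situation was never operationalized numerically, so this definition
is ours and is reported as a flag, never as significance.

When several target individuals carry both volumes, a two-sided
one-sample t-test of the mean log10 residual (each individual predicted
at its own corrected hemisphere volume) provides a more sensitive
verdict. The t-test operates on log-space residuals; percent residuals
are reporting-only. The source analyses did not state which space their
t-tests used; log space is the scale on which the model is linear and
homoscedastic, which is why we chose it.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `level` | 0.95 | probability | the conventional prediction level |
| gate α | 0.05 | — | boundary-LRT significance threshold |
| minimum reference species | 4 (warn at 4) | count | below this the interval is meaningless; analyses that motivated the package required more than four |
| ultrametricity tolerance | 1e-6 × depth | relative | numerical slack for dated consensus trees |
| zero-branch floor | 1e-8 | My | avoids division by zero when standardizing contrasts across resolved polytomies |
| `attachment` | tip when possible | — | uses all shared-history information; root kept for comparability |

Reports round slopes/intercepts and interval bounds to 2 decimals and
percent residuals to integers, mirroring the summary-table convention;
the JSON companion retains full precision.

## The synthetic-data generator

`simulate_dataset()` emulates exactly the statistical structure the
analysis assumes, so every stage is testable without external data:

* hemisphere log-volumes evolve by Brownian motion on the tree, then are
  affinely rescaled to a configured range (default 1.8–2.8 log10 cc,
  ape-like; the anthropoid preset spans 0.5–2.8). Published sources do
  not print the regressor range, so the default is a choice of realism,
  made once: great-ape hemispheres are a few hundred cc.
* species structure means satisfy the *coupled* equation
  $\mu = a + b\log_{10}(10^h - 10^\mu) + r$, because the part-whole
  transform puts the structure on both sides. We solve it per species by
  fixed-point iteration to 1e-10 (the map is strongly contractive when
  structures are small relative to hemispheres); draws where the
  structure would not fit inside the hemisphere are resampled, with an
  error after 100 failures.
* residuals $r$ are Gaussian with covariance
  `bm_rate · V_λ + iid_sd² · I`, with `bm_rate = bm_sd_tip²/depth` so the
  Brownian component's tip s.d. is specified directly.
* the target species mean is shifted by δ log10 units
  (`target_shift`), i.e. multiplied by $10^\delta$; individuals are drawn
  lognormally around species means.

Presets loosely mimic the motivating analyses: `"hominoid"` (8 tips,
20 My, slope 0.78, intercept −1.87, two individuals per species),
`"anthropoid"` (26 tips, 40 My, slope 0.69, intercept −1.77, one
individual). A `sim_config` with its seed determines the dataset bit for
bit.

What the generator does **not** emulate: covariance among multiple
structures from the same brains (each structure is simulated
independently), measurement-method differences between datasets,
non-Gaussian within-species variation, and errors in the tree itself.
Passing calibration on synthetic data therefore shows the machinery is
correct and calibrated *under the model's own assumptions*, not that any
particular empirical dataset satisfies them.

## Calibration results the package checks about itself

The test suite and `scripts/acceptance.R` recompute (never hard-code)
these properties:

* **Coverage.** Contrasts-path 95% intervals for a held-out tip under
  pure Brownian simulation on a 26-tip tree contain the truth at the
  nominal rate (2000 replicates; binomial SE ≈ 0.5%). OLS coverage under
  iid noise behaves identically; coverage is monotone in `level`.
* **λ recovery.** Median λ̂ over 200 replicates is exactly 0 under iid
  residuals and exactly 1 under Brownian residuals (the estimates pile
  onto the boundaries).
* **Slope recovery.** Mean OLS slope over 500 replicates of a 7-species
  design with iid s.d. 0.03 is within ±0.02 of the generating slope.
* **Type-I error.** The mean-residual t-test rejects at ≈5% under a null
  with zero mean shift (2000 replicates).

Replicate counts are chosen so each experiment resolves its quantity to
well under the decision tolerances while the whole suite runs in about a
minute; they are package defaults, not ceilings.

## Numerical and design notes

* GLS is computed through the Cholesky factor of $V$ (whitening), never
  through explicit inversion; a non-positive-definite $V$ or constant
  predictor raises an error rather than a silent pseudo-inverse.
* Polytomies are resolved by `ape::multi2di(random = FALSE)` — a
  deterministic resolution with zero-length inserted branches. We rely on
  `ape`'s deterministic traversal rather than re-sorting children
  alphabetically; the result is reproducible for a given input file, and
  inserted branches are floored at 1e-8 My only inside contrast
  standardization.
* A basal multichotomy in Newick is indistinguishable from an unrooted
  tree; `read_phylo()` resolves it (deterministically) rather than
  rejecting, then requires the result to be rooted.
* Degenerate inputs: zero residual variance collapses the prediction
  band onto the line (and makes λ undefined — an error, since the gate
  question is meaningless); identical tip values yield all-zero
  contrasts; an all-identical residual set in the outlier screen returns
  an undefined F and no flags.
* Aggregation halves `bilateral_sum` structures per individual *before*
  averaging, so halving can never be applied twice; species means are
  unweighted arithmetic means (no weighting was specified by the sources
  the conventions come from).
* The outlier screen (one-way ANOVA on per-individual residuals, Tukey
  HSD, flag species differing from **all** others at 0.05, refit without
  them) requires at least three species with two or more individuals;
  Tukey's studentized-range procedure handles unbalanced groups via
  `stats::TukeyHSD`'s standard adjustment.
* No multiple-testing correction is applied across structures, matching
  the practice of the analyses this workflow formalizes; users scanning
  many structures should interpret isolated marginal calls accordingly.

## Known limitations

* The packaged volumetric tables ship **without** hemisphere volumes —
  those were never published at the individual level — so the packaged
  real-data fixtures exercise loading, aggregation and printed-bound
  classification, while full regressions require user-supplied hemisphere
  data or the synthetic generator.
* The packaged trees are hand-assembled approximations of consensus
  dated phylogenies, intended as editable examples; no quantitative
  claim in the package depends on their exact branch lengths.
* The Cavalieri utility is a plain formula
  (points × area-per-point × spacing, μm³ → cc); published stereological
  parameter tables are sometimes ambiguous about what "grid size" means,
  and the utility makes no attempt to guess.
* Contrast-based R² and p are those of the through-origin regression on
  n−1 contrasts (F on n−2 df); they are not numerically comparable to
  OLS R² across gates, only within a mode.
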