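---
title: "Targeted mixup augmentation for genomic prediction: model, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted mixup augmentation for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixupGS)
```

## The problem

In genomic selection the practically relevant lines are the best ones,
yet a model trained on the whole population allocates its fit evenly and
tends to shrink predictions toward the population mean — precisely the
wrong behavior in the top tail where selection happens. `mixupGS`
implements and evaluates a targeted remedy: discard all but the top
fraction of the training lines, densify that sparse region with synthetic
lines interpolated between real top lines (mixup), and train GBLUP on the
result. The package's experiment machinery quantifies the trade-off this
induces: worse calibration on the test set as a whole, better prediction
of the test set's own top fraction.

## Model and fitting

The phenotype of line $i$ is modeled as $y_i = \mu + g_i + \epsilon_i$
with $g \sim N(0, \sigma_g^2 G)$ and i.i.d. noise
$\epsilon_i \sim N(0, \sigma_e^2)$. $G$ is VanRaden's linear kernel
(method 1): with allele frequency $p_k$ estimated as half the column mean
of the dosage matrix, the centered matrix $W$ has columns
$x_k - 2p_k$ and

$$G = \frac{W W^\top}{2 \sum_k p_k (1 - p_k)}.$$

Frequencies are always taken from the matrix actually supplied, so for
the augmented method — whose training rows are real-valued convex
combinations — $G$ is computed from the stacked augmented-training plus
test-line matrix with its own frequencies. The alternative (centering
augmented rows with the original-data frequencies) is a defensible
reading, but estimating frequencies from the supplied matrix keeps the
kernel self-contained and exactly reproduces the "relationship matrix of
the inputs you train on" semantics; it is the package-wide rule.

Variance components are estimated by REML rather than MCMC. After one
eigendecomposition of the training block of $G$, the restricted
likelihood is a cheap 1-D function of the variance ratio
$\lambda = \sigma_g^2/\sigma_e^2$; we evaluate it on a 100-point log grid
spanning $[10^{-5}, 10^5]$ (covering heritabilities from essentially 0 to
essentially 1) and refine the best bracket with bounded scalar
minimization. This is deterministic, fast, and — for a single random
effect with known kernel — yields point predictions equivalent in
practice to Bayesian GBLUP posterior means, which is what matters here
because the augmentation strategy is agnostic to the fitting engine.
Unphenotyped lines are predicted by the conditional-expectation
projection $\hat g_{\mathrm{test}} = G_{\mathrm{test,train}}
G_{\mathrm{train,train}}^{-1} \hat g_{\mathrm{train}}$; linear solves add
a diagonal jitter of $10^{-8}\,\overline{\mathrm{diag}(G)}$, which is
never stored in $G$ itself.

## Augmentation

A synthetic line is $\tilde x = \lambda x_i + (1-\lambda) x_j$,
$\tilde y = \lambda y_i + (1-\lambda) y_j$ for two parents drawn from the
top fraction of the training lines. Defaults, with rationale:

| parameter | default | meaning / why |
|---|---|---|
| `lam` | 0.5 | equal-weight interpolation; the midpoint maximizes novelty per pair. A Beta-sampled λ per pair (the original mixup recipe) is deliberately not the default: at fixed 0.5 the augmented set is deterministic. |
| `top_fraction` | 0.2 | fraction of training lines used as parents (and the only real lines kept for training under "A") |
| `pair_scheme` | `all_pairs` | one synthetic line per unordered pair of parents, i.e. $\binom{m}{2}$ rows. At λ = 0.5 ordered pairs are redundant, so this is the maximal duplicate-free augmentation; it is also deterministic, which we prefer over `random_pairs` (available with `n_synthetic` and a seed) because the number of synthetic rows is otherwise a free and consequential knob. |
| `direction` | `high_is_top` | "top" means largest phenotype (yield-type traits); `low_is_top` covers disease scores where small is good |

Synthetic ids are `SYN_<parent_i>_<parent_j>`, unique and traceable via
the returned provenance table. Convexity gives two exact invariants the
tests rely on: synthetic values lie inside their parents' elementwise
intervals (so augmented dosages stay in $[0,2]$), and at λ = 0.5 under
`all_pairs` the mean synthetic phenotype equals the mean parent phenotype
because every parent appears in exactly $m-1$ pairs.

## Evaluation protocol

`make_folds()` implements repeated random subsampling (Monte-Carlo CV):
each of the 10 folds independently samples `round(0.2 n)` lines as the
test set. Ten *disjoint* folds of 20% are impossible, and repeated random
line partitions are the natural reading of a "random partition by line"
design; per-fold seeds derive from one master seed so a single integer
reproduces the whole experiment.

Metrics: $\mathrm{NRMSE} = \mathrm{RMSE}/\bar y$ (error on the scale of
the trait mean) and $\mathrm{MAAPE} = \frac1n\sum_i
\arctan\lvert(y_i - \hat y_i)/y_i\rvert$, bounded by $\pi/2$ and finite
even for near-zero observations (an observed zero contributes $\pi/2$
when missed, 0 when hit exactly). A non-positive mean makes NRMSE
meaningless, so it errors unless explicitly overridden to use
$|\bar y|$. Both are reported on the whole test set and on its top-20%
subset, defined per fold from *observed* test phenotypes by the
inclusive nearest-rank 80th percentile (ties at the threshold all enter;
membership by observed rather than predicted value is what "how well do
we predict the actually-best lines" means). Fold means per method are the
headline numbers; `summarize_metrics()` adds across-trait means and
C-vs-A gain columns, where the gain is the percent by which the worse
method's mean metric exceeds the better one's,
$100(\mathrm{worse}-\mathrm{better})/\mathrm{better}$, alongside a column
naming the winner.

## The simulator, and what passing tests do and do not show

`sim_genotypes()` draws, per marker, an allele frequency uniform on
$[0.05, 0.5]$ and independent Binomial(2, $p$) dosages per line —
unlinked markers, no LD, no population structure. `sim_phenotypes()`
picks `n_qtl` causal markers with normal effects, and rescales the
genetic and noise components so the *realized* variances are exactly
$h^2$ and $1-h^2$ (total phenotypic variance 1) over a baseline of 100.
Rescaling both components, rather than only the noise, makes the
identity exact at the endpoints too ($h^2=0$: pure noise; $h^2=1$:
noise-free) without any division by a vanishing variance, and it makes
parameter-recovery tests sharp: REML on such data should and does
recover $h^2$ to within sampling error. The baseline of 100 mirrors
positive-valued agronomic traits and keeps the NRMSE normalizer safely
positive.

What the simulator does **not** emulate: linkage disequilibrium, marker
ascertainment, family structure, genotype-by-environment effects, or
multi-environment BLUE pipelines. Passing tests therefore certify the
algebra, the protocol, and the qualitative mechanism of targeted
augmentation — not effect sizes on any real breeding population, where
LD and structure change both how informative $G$ is and how the top
fraction is related to the rest.

## Numerical and degenerate-input choices

- Ties in top-fraction selection break by ascending line id;
  `ceiling(fraction * n)` lines are always selected.
- Missing dosages are imputed by the marker-mean (the standard
  low-assumption choice in GS preprocessing); an all-missing marker is an
  error naming the marker, not a silent drop.
- Raw dosages outside $\{0,1,2\}$, duplicate line ids, disjoint
  marker/phenotype id sets, all-monomorphic marker matrices,
  zero-variance phenotypes, and top fractions yielding fewer than two
  parents all raise immediate errors rather than propagating numbers.
- Multiallelic VCF records are skipped with a warning; genotypes are
  counted as ALT-allele dosage.

## Problem sizes

The test suite runs its deepest checks at 200–500 lines and 600–2000
markers (for example, heritability recovery uses 20 replicates of a
500 × 1000 simulation), and `scripts/acceptance.R` runs the full C-vs-A
experiment at 300 lines × 1500 markers with 10 folds. These sizes are of
the same order as typical single-trial breeding datasets and large
enough for the VanRaden diagonal and REML recovery properties to
concentrate, while keeping a full run in seconds.

## Known limitations

- Single trait, single environment; multi-environment augmentation
  (augmenting within environment) is not modeled.
- The number of synthetic rows under `all_pairs` grows quadratically in
  the number of parents; for very large training sets use
  `pair_scheme = "random_pairs"` with an explicit `n_synthetic`.
- REML point estimation only: no posterior uncertainty on variance
  components, and no Bayesian-alphabet alternatives.
- Pearson correlation is intentionally not a headline metric: targeted
  augmentation reshapes the error distribution rather than the ranking,
  and the error metrics above are the quantities the method is designed
  to move.
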