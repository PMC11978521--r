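---
title: "Models and methods in spotdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spotdecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdecon)
```

# The problem

Sequencing-based spatial transcriptomics (ST) platforms such as Visium
capture whole-transcriptome counts at predefined circular spots of ~55 µm
diameter. Each spot covers several cells, typically of mixed type, and
roughly half the tissue section lies between spots and is not measured at
all. `spotdecon` addresses both losses: it estimates per-spot cell-type
composition from an annotated scRNA-seq reference (*deconvolution*),
splits each spot's per-gene counts among its constituent cells
(*decomposition*, producing inferred single-cell profiles, "iscRNA"), and
reconstructs the composition and expression of nuclei outside the capture
areas by spatial regression (*imputation*).

# Reference construction

The scRNA-seq reference $Y \in \mathbb{R}^{C \times G}$ is CPM-normalized
(each cell scaled to $10^6$ total counts). For every gene $g$ and type
$t$ we compute from the per-type mean CPM $\hat z_{t,g}$:

* the $v$-quantile $f_{g,t}(v)$ of the fold changes
  $\{\hat z_{t,g} / \hat z_{t',g} : t' \ne t\}$ (linear interpolation,
  type 7 — the most widespread quantile convention, documented so
  independent oracles agree). A ratio $0/0$ is defined as 1
  (uninformative), $x/0$ with $x>0$ as $+\infty$;
* one-sided Welch $z$-tests of $H_0: z_{t,g} \le z_{t',g}$ against every
  other type, on raw CPM values (log handling is a genuinely open choice;
  raw CPM is used and the statistic is exposed for inspection). When both
  sample variances vanish the $p$-value is 0.5 / 0 / 1 for equal / larger
  / smaller means;
* the coverage $w_{t,g}$, the fraction of type-$t$ cells with nonzero
  counts.

Gene $g$ is a marker candidate for type $t$ iff $f_{g,t}(v) >
l_\mathrm{fold}$, $\max_{t'} \lambda_{g,t,t'} < l_\lambda$ and $w_{t,g} >
l_\mathrm{cover}$. Candidates are ranked by $f_{g,t}(v)$ (ties broken by
gene id so the ranking is deterministic) and the top $n_\mathrm{select}$
kept per type; the marker panel is the union over types. Defaults
$l_\mathrm{fold}=1.5$, $l_\lambda=0.1$, $l_\mathrm{cover}=0.60$,
$v=0.15$, $n_\mathrm{select}=50$ are the method's standard setting.

The signature matrix $\Phi$ is the pooled maximum-likelihood estimator

$$\hat\varphi_{t,g} =
  \frac{\sum_{c:\tau(c)=t} y_{c,g}}{\sum_{c:\tau(c)=t}\sum_{g'} y_{c,g'}},$$

so each row is a per-type gene-proportion profile summing to 1. Alongside
$\Phi$ we record $\nu_t$, the mean library size of type-$t$ cells over the
same gene set; it converts transcript shares into cell-number shares
below. A marker-gene signature $\Phi^{(m)}$ drives deconvolution; a
full-gene $\Phi$ (same estimator, all shared genes) drives decomposition.

# The generative model

Spot counts over the $G_m$ marker genes are modeled as

$$x^{(m)}_s \mid Q, r, \Phi^{(m)} \sim
  \mathrm{Multinomial}\!\big(m'_s,\ \tilde\rho_s\big), \qquad
  \rho_{s,g} = \sum_t q_{s,t}\,\varphi^{(m)}_{t,g}, \qquad
  \tilde\rho_{s,g} =
  \frac{\rho_{s,g}2^{r_g}}{\sum_{g'}\rho_{s,g'}2^{r_{g'}}},$$

where $Q$ rows are gene-contribution scores on the simplex and $r_g$ is a
per-gene log2 batch factor absorbing platform differences between scRNA
and ST chemistry. The likelihood is invariant to a constant shift of $r$,
so the reported $\hat r$ is centered to mean zero.

**Inference.** Priors are $Q_s \sim \mathrm{Dirichlet}(1,\dots,1)$ and
$r_g \sim \mathcal N(0, 1)$ (both weakly informative and configurable).
The posterior mode is found by Adam on the exact analytic gradient of the
log posterior, with $Q$ parameterized by row-wise softmax logits started
at the uniform simplex and $r$ at zero — the fit is therefore fully
deterministic given the configuration. Defaults are 8000 iterations at
learning rate 0.01; the loss trace is returned and checked for smoothed
monotone convergence. (A stochastic variational treatment of the same
model is the natural extension; at the problem sizes this package
targets, the MAP estimate recovers simulated truth within all stated
tolerances, so it is the single shipped mode.)

**From transcript shares to cell numbers.** $q_{s,t}$ measures the share
of *transcripts*, not of *cells*: an mRNA-rich type contributes more
counts per cell. The default conversion divides by the per-type mean
marker library size, $p_{s,t} \propto q_{s,t}/\nu_t$, renormalized per
spot; an `identity` mode returns $Q$ unchanged for users who want the raw
contribution scores. Spots with zero total marker counts are excluded
from the likelihood and reported with uniform proportions and a warning.

# Decomposition

With a nucleus count $N_s$ per spot (from any segmenter; a toy
threshold-and-label segmenter is included purely to exercise image
fixtures), proportions become integer cell counts by solving

$$\min_{n_s} \sum_t \Big|\frac{n_{s,t}}{N_s} - p_{s,t}\Big| \quad
  \text{s.t.} \sum_t n_{s,t} = N_s$$

via largest-remainder apportionment (floor, then distribute remaining
cells by descending fractional remainder; ties broken by remainder, then
proportion, then type index). Largest remainder attains the L1 optimum —
the test suite certifies this against exhaustive search on every instance
with $T \le 4$, $N_s \le 12$. Without an image, types with $p_{s,t} <
l_p$ (default 0.05, never printed by the method's authors, hence
configurable) are zeroed and the survivors renormalized.

Each gene's count is then split across the present types with weights

$$\omega_{s,g,t} =
  \frac{\tilde p_{s,t}\varphi_{t,g}}{\sum_{t'}\tilde
  p_{s,t'}\varphi_{t',g}}, \qquad \hat u_{s,t,g} = x_{s,g}\,\omega_{s,g,t},$$

the posterior mean of a multinomial split. Conservation
$\sum_t \hat u_{s,t,g} = x_{s,g}$ is enforced bit-exactly by folding the
IEEE rounding residual of each gene into its dominant type. Genes with
zero signature mass in every surviving type are allocated proportionally
to $\tilde p_s$ (logged). Type rows are divided equally among that type's
cells (`expected` mode, the posterior-mean reading) or split
multinomially after largest-remainder integerization (`sampled` mode,
which conserves integer gene totals exactly). Within a spot, nuclei are
interchangeable, so which nucleus receives which type is a seeded uniform
permutation — a stated limitation of the underlying method, not of this
implementation.

# Imputation

Cell-type proportions vary smoothly at the 100 µm scale, which justifies
regressing them over space. One Gaussian process per type is fitted over
spot centers with an isotropic squared-exponential kernel and shared
hyperparameters; the prior mean is the type's training mean, so far-field
predictions decay to the slide-average composition. Predictions are
clipped to $[0,1]$ and renormalized to a simplex at every query point —
a pragmatic alternative to a joint simplex-valued GP. Defaults: length
scale $2\times$ the spot pitch (the scale over which neighboring spots
still inform each other), noise variance $10^{-4}$. Note that at the
$2\times$-pitch default the kernel Gram matrix is numerically
near-singular: exact interpolation experiments should set the length
scale to about one pitch. Out-spot nuclei draw their type categorically
from the predicted simplex (seeded). Expression for an out-spot nucleus
of type $t$ is the Gaussian-kernel-weighted mean of the expected per-cell
type-$t$ profiles $\hat u_{s,t}/n_{s,t}$ from the $k=10$ nearest spots
containing $t$ — kernel smoothing of per-cell profiles rather than a
per-gene GP, chosen for tractability (a GP per gene across the
transcriptome is quadratic in spots *per gene*), and operating on
per-cell units so cell-size effects do not leak into imputed profiles.
A zero-radius "spot" geometry (every nucleus its own spot) passes through
the same machinery unchanged, which covers single-nucleus platforms with
partial capture.

# The simulator and what a green test establishes

`generate_truth_pattern()` builds a hexagonal grid with Visium-like
constants (100 µm pitch, 55 µm spots, 0.75 µm/px), draws per-spot integer
type counts from a spatial pattern (`uniform`, overlapping-support
`blocks`, or smooth `gaussian-bumps`), and scatters one nucleus per cell
uniformly inside its spot plus out-spot nuclei in the gaps. Mean cells
per spot defaults to 6 — a typical Visium nuclei-per-spot figure —
drawn as Poisson with a floor of one cell. `simulate_spots()` samples
annotated cells with replacement (so small references can populate large
slides), sums their raw counts per spot, and corrupts the matrix in
order: gene-wise batch effects $2^{r_g}$, $r_g \sim \mathcal N(0,
\sigma_r)$; artificial zeros with probability $\pi_0$ per nonzero entry;
multiplicative log-normal noise with sdlog $\sigma_n$; final integer
rounding. The three severity presets (small $(0.1, 0.05, 0.05)$, medium
$(0.3, 0.10, 0.10)$, large $(0.5, 0.20, 0.20)$) were chosen once as
plausible severities for this method class; they are fixed, documented
defaults, not tuned values.

The simulator emulates composition mixing, platform batch effects,
dropout and overdispersion. It does **not** emulate spatially variable
expression within a cell type, transcript diffusion between spots,
segmentation errors, or doublet artifacts in the reference. A green
recovery test therefore establishes that the estimator inverts the
model's own generative process under realistic corruption — the standard
simulation-based evidence for this method class — and not performance on
any particular tissue.

# Evaluation metrics

Six per-spot metrics compare an estimated simplex $p$ with truth $p^*$:
absolute error $\sum_t|p_t - p^*_t|$ (0–2), square error, Jensen–Shannon
divergence $\sqrt{\tfrac12[D(p\|m) + D(p^*\|m)]}$ with $m = (p+p^*)/2$
and base-2 logs so disjoint compositions score exactly 1, Pearson
correlation with the constant centering $a = 1/T$ (identical to
mean-centering for simplex inputs, stated explicitly so oracles agree),
cosine similarity, and the fraction of cells correctly mapped
$\sum_t\min(p_t, p^*_t)$, which algebraically equals
$1 - \tfrac12\sum_t|p_t-p^*_t|$. A zero-variance vector leaves Pearson
undefined; it is reported as `NA` with a log message rather than a
fabricated value.

# Numerical and degenerate-input policy

* Readers validate rather than coerce: dimension mismatches, duplicate
  identifiers, missing columns and malformed JSON are errors naming the
  offending file.
* CPM refuses double normalization; all-zero rows stay zero with a
  warning.
* Fold-change conventions ($0/0 \to 1$, $x/0 \to \infty$) keep degenerate
  genes from crashing selection while never promoting them past the
  coverage gate.
* The gene universes of ST and reference matrices are intersected
  (case-sensitive) before modeling; dropped counts are logged.
* Empty spots: excluded from the likelihood, uniform proportions,
  warning. Empty threshold survivors: argmax type kept, logged.
* All stochastic stages take explicit seeds; `run_pipeline()` derives
  per-stage seeds from one master seed by stage-name hashing, so a rerun
  is byte-identical without bookkeeping.

# Known limitations

* MAP point estimates carry no posterior uncertainty; credible intervals
  on proportions would require the variational treatment.
* Independent per-type GPs with post-hoc renormalization can distort
  compositions where all types decay simultaneously (far outside the
  hull).
* The reference must contain every cell type present in the tissue;
  missing types are absorbed into their nearest transcriptional neighbor.
* Marker selection assumes the reference's type labels are reliable; no
  doublet or batch correction of the reference itself is attempted.
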