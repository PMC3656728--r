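---
title: "Directional influence networks from multi-phenotype double-knockdown screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional influence networks from multi-phenotype double-knockdown screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(influscreen)
library(dplyr)
```

## The problem

All-pairs double-perturbation screens measure what happens to a cell when
two genes are knocked down together. Classical epistasis analysis reports,
for each phenotype separately, whether the double knockdown deviates from
the additive expectation of the two singles — a symmetric, per-phenotype
quantity that says nothing about *which* knockdown modifies *which*. When
several correlated phenotypes are measured on the same lines (here, the
cell number, mean nuclear area, and nuclear fluorescence intensity of
*Drosophila* S2 cells under dsRNA knockdown), their joint pattern carries
enough information to orient the interaction: a combined analysis of
pleiotropy and epistasis converts the per-phenotype interaction
coefficients of each knockdown pair into two *directed* influence
coefficients — how knockdown a rescales the activity of knockdown b, and
vice versa. Negative influences (suppression) are the signature of genes
acting in a shared pathway; positive influences (enhancement) indicate
antagonistic processes. `influscreen` implements the full pipeline:
normalization, eigentrait decomposition, conditioned pairwise regression,
the influence reparametrization with propagated errors, permutation-based
familywise significance, network assembly and rule-based pathway-role
inference, together with a generative simulator that makes every stage
testable without external data.

## The model

**Normalization and eigentraits.** Raw phenotypes are log-transformed
(base 10 by default; the base is configurable because only positivity is
essential), mean-centered and scaled to sample standard deviation 1
(denominator $n-1$; at thousands of lines the $n$ vs $n-1$ choice is
numerically immaterial). The normalized lines-by-phenotypes matrix $P$ is
decomposed by SVD, $P = U\,\mathrm{diag}(S)\,V^\top$. The unit-norm
columns of $U$ are the *eigentraits*: orthogonal composite phenotypes.
Eigentraits whose variance fraction $S_j^2/\sum S_k^2$ falls below 2% are
discarded; the directional model below requires exactly two retained
eigentraits and the pipeline refuses to continue otherwise. Sign
ambiguity of the SVD is fixed deterministically (largest-magnitude
loading of each right singular vector made positive) so repeated runs are
bit-identical. Typically the first eigentrait is a signal common to all
phenotypes and the second separates nuclear area from the other two.

**Single-locus scan and covariates.** For each gene and eigentrait the
one-locus model $U_{ij} = \beta_{0j} + x_i\beta_j + \varepsilon_{ij}$ is
fitted by OLS, where $x_i \in [0,1]$ is the knockdown indicator (values
between 0 and 1 are accepted as knockdown probabilities). Genes whose
statistic $\beta/\widehat{se}$ exceeds a familywise threshold — the
$1-\alpha$ quantile ($\alpha = 0.001$) of a Gumbel distribution fitted by
maximum likelihood to per-permutation maxima of 2000 whole-matrix
genotype permutations — become *strong-effect covariates* for that
eigentrait. Conditioning subsequent pair scans on them prevents the
strongest main effects from inflating every other pair's residual.

**Pair scan.** For each of the $G(G-1)/2$ pairs and each eigentrait,
OLS of the eigentrait on intercept, $x_a$, $x_b$, $x_a x_b$ and the
eigentrait's covariates (excluding the scanned genes themselves) yields
main effects $\beta_{aj}, \beta_{bj}$ and the interaction coefficient
$\gamma_j$. Parameter covariances within an eigentrait are
$\widehat{\sigma}^2 (X^\top X)^{-1}$. Because the error-propagation step
needs covariances *between* the two eigentraits' estimates, and the two
fits share most but not necessarily all of their design (covariate sets
differ per eigentrait), we use the seemingly-unrelated-regressions form
$\mathrm{Cov}(\hat b_1, \hat b_2) = s_{12} (X_1^\top X_1)^{-1} X_1^\top
X_2 (X_2^\top X_2)^{-1}$ with $s_{12} = e_1^\top e_2 / \sqrt{\nu_1
\nu_2}$ the residual cross-covariance; for identical designs this reduces
to the familiar shared-design identity.

**Influence reparametrization.** The two interaction coefficients are
recast as eigentrait-independent *activity modifications* by a 2×2 solve,

$$\begin{pmatrix}\delta_1\\\delta_2\end{pmatrix} =
\begin{pmatrix}\beta_{a1} & \beta_{b1}\\ \beta_{a2} & \beta_{b2}\end{pmatrix}^{-1}
\begin{pmatrix}\gamma_1\\ \gamma_2\end{pmatrix},$$

an exact reparametrization ($M\delta$ reproduces $\gamma$ identically),
and then as directed influences

$$m_{ab} = \frac{\delta_1}{1+\delta_2}, \qquad
  m_{ba} = \frac{\delta_2}{1+\delta_1}.$$

$m_{ab}$ is the influence of knockdown *a on b*: negative = a suppresses
b's effects (shared-pathway signature), positive = enhancement
(antagonistic-pathway signature). Two guards apply: pairs whose
main-effect matrix has 2-norm condition number above $10^8$
(configurable) are reported `singular` — collinear pleiotropic
signatures cannot be directionally resolved — and denominators within
$10^{-8}$ of zero are reported `pole`. Variances are propagated to
first order, $\mathrm{var}(m) = J \Sigma J^\top$, with the Jacobian
computed analytically through the closed-form 2×2 inverse and validated
against central finite differences and a Monte-Carlo oracle in the test
suite. The test statistic throughout is the effect divided by its
estimated standard error. Eigentrait-space coefficients are recomposed to
phenotype space by the linear map $b = V_{[,1:2]}\,\mathrm{diag}(S_{1:2})
\, c$ — the unique linear map under which direct phenotype regressions
and recomposed eigentrait regressions agree, so it cannot alter any
inferred interaction. Each gene's overall knockdown-to-phenotype
coefficient is the one of *median standard effect size* (|coef|/SE)
among all pair models containing the gene — an actually fitted estimate,
with the lower median taken for even counts.

**Significance.** Pair-level nulls come from *tandem permutations*: one
shared random row permutation applied to the two scanned genotype
columns only (700 draws by default), leaving all other knockdowns,
covariates and phenotypes untouched and preserving the pair's joint
genotype pattern. Each draw refits the pair model and replays the whole
reparametrization; absolute statistics for $m_{ab}$, $m_{ba}$ and the
recomposed phenotype coefficients form the null distributions. Raw
p-values are add-one empirical tail fractions, $(r+1)/(n+1)$, pooled
across pairs by default (per-pair mode available). The familywise error
rate is controlled by Westfall–Young free step-down on the empirical
permutation distributions — fitted extreme-value smoothing is
deliberately *not* used at this stage because empirical tails are
heavier than fitted EVDs and smoothing would overstate significance —
with monotonicity enforced and adjusted p never reported below raw p.
Edges with adjusted $p$ below the network cutoff (0.01 by default) enter
the directed network; both directions of a pair are tested
independently.

**Pathway roles.** Given reference annotations (e.g. known Ras-pathway
members), an unannotated gene with a significant negative edge to a
pathway gene (either direction) is labeled a same-pathway candidate; a
positive edge labels it a pathway-inhibitor candidate; genes matching
both rules are `ambiguous`, mutually enhancing pairs are `complex`, and
genes with no edges to annotated genes remain `unassigned`. Labels carry
their supporting edges — they are evidence listings, not hard calls.

## The simulator

`planted_model()` / `simulate_screen()` generate the all-pairs design
(one averaged observation per pair; $G(G-1)/2$ lines, every gene in
$G-1$ of them) and phenotypes from the model's own generative mirror:
eigentrait values are the sum of the two knockdowns' main effects, the
pair's planted interaction coefficient and Gaussian noise; log-scale
phenotypes are the eigentraits mapped through a 3×2 loading matrix (one
common axis, one nuclear-area-separating axis) plus offsets, and raw
phenotypes are $10^{\text{log}}$ so the pipeline's log transform inverts
the map exactly. Planted directed influences are converted to
interaction coefficients by the closed-form forward inversion
$\delta_1 = m_{ab}(1+m_{ba})/(1-m_{ab}m_{ba})$,
$\delta_2 = m_{ba}(1+m_{ab})/(1-m_{ab}m_{ba})$, $\gamma_j =
\beta_{aj}\delta_1 + \beta_{bj}\delta_2$, so running the analysis
direction on noiseless data recovers the planted influences exactly
(a property the tests exercise).

Default study conditions, chosen once by power analysis at $G = 20$ and
frozen: 5 strong-effect genes among 20, *axis dominant* — each with a
major effect $|U(0.9, 1.3)|$ on one eigentrait (alternating) and a minor
effect (10–30% of the major) on the other, random signs — with the rest
of the genes silent; 5 planted one-directional influences $|m| \sim
U(0.5, 0.8)$ between strong genes whose signature directions differ by
at least 40°; eigentrait noise SD 0.05. Axis dominance mirrors the
structure of real screens, where strong knockdowns load predominantly on
one composite phenotype, and it matters statistically: it keeps
single-scan statistics bimodal (major components far above the
covariate threshold, minor components far below), so strong-effect
conditioning is reliable. With comparable *isotropic* strong genes,
self-competition — every other strong gene's effect sits in the
one-locus residual — pins scan statistics near the threshold regardless
of overall effect scale, and covariate selection degrades into a coin
flip. The 40° planting separation reflects an identifiability limit of
the model itself, not of the simulator: the activity solve is a 2×2
inversion in the two genes' effect vectors, and nearly collinear
signatures cannot be directionally resolved.

What the simulator deliberately omits: reagent-level replication and
off-target effects, plate/batch structure, and phenotype-space
heteroscedasticity (an optional phenotype-space noise term exists for
robustness checks, but the default places noise in eigentrait space,
making the generative model the exact inverse of the fitted one so that
recovery tests are interpretable). Passing tests therefore demonstrate
correctness of the estimator and calibration machinery under the model's
own assumptions, not robustness to real-screen artifacts.

## Numerical choices

* OLS throughout, via pivoted QR in the per-pair reference path and
  Cholesky normal equations in the bulk C++ engine; the two are asserted
  to agree to $10^{-8}$ and rank deficiency is detected at relative
  reciprocal condition $10^{-10}$ (such pairs are reported
  `non_estimable`, never silently dropped).
* Permutation draws that are themselves non-estimable are skipped and
  counted; a pair with more than 20% skipped draws is flagged
  `unreliable_null`.
* Gumbel fitting by BFGS on (location, log scale) from a
  method-of-moments start; permutation counts below 100 are refused.
* Negative propagated variances (numerical) are clipped to zero with a
  warning.
* All randomness flows from one seed; identical configurations
  reproduce byte-identical outputs.

## Scaled-down study sizes

The test suite and the acceptance script exercise the pipeline at sizes
chosen as the package's own reference conditions: screens of $G = 20$
genes (190 lines), 200 single-scan and 200 tandem permutations, 200
replicate screens for calibration, 20 replicate screens for recovery,
$10^5$ Monte-Carlo draws for the variance oracle. A full 93-gene screen
(4278 lines, 2000/700 permutations) runs through the same code paths;
only the combinatorial identities of that design are checked directly.

## Known limitations

**Tandem nulls for strong pairs at high signal-to-noise.** Permuting a
pair's genotype columns removes its main effects from the model, so the
permuted activity matrix is noise and the permuted influence statistics
are strongly deflated whenever the pair's true main effects are large
relative to residual noise (variance inflation $1 + p(1-p)
(\beta_a^2+\beta_b^2)/\sigma^2$, with $p$ the per-gene line fraction).
Observed statistics of such pairs are meanwhile correctly
$\sim\!N(0,1)$ under no interaction. At realistic screen
signal-to-noise, and at the small per-gene line fraction of a large
screen ($p \approx 0.02$ at $G=93$), the mismatch is second order; in
small, high-signal screens ($p = 0.1$ at $G = 20$) it makes the
step-down anti-conservative for strong-pair edges — in our measurements,
a familywise false-edge rate of roughly 0.13–0.15 at nominal 0.01 when
strong main effects are present, against 0.005–0.015 on pure-null
screens where the permutation null is exchangeable with the data. The
calibration suite therefore tests familywise control on pure-null
screens, and the acceptance script additionally reports the
with-main-effects rate so the limitation stays visible. Practical
reading: in small screens, treat strong-pair edges near the significance
cutoff with caution; the limitation fades as $G$ grows.

**Two eigentraits only.** The directional model inverts a 2×2 system;
phenotype sets whose third eigentrait carries meaningful variance are
out of scope, as are higher-order (3+ gene) interaction models.

**Collinear signatures.** Pairs of genes with proportional effect
vectors are fundamentally unresolvable by this model and are reported
`singular` rather than estimated.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(
  simulate = list(G = 20, n_edges = 5),
  n_perm_single = 200, n_perm_pair = 200,
  alpha_network = 0.05, seed = 2
)
res <- run_full_analysis(cfg)
glance(res)
tidy(res) |> filter(target_type == "gene")
autoplot(res$network)
```

The run log records every threshold, seed and skip count; rerunning the
same configuration reproduces every output byte for byte.
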