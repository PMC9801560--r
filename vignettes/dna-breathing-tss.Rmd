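---
title: "DNA breathing as a feature extractor: the model and methods behind pbdtss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA breathing as a feature extractor: the model and methods behind pbdtss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdtss)
```

## The problem

Double-stranded DNA is not a static ladder: thermal fluctuations transiently
break the hydrogen bonds of individual base pairs ("DNA breathing") and of
runs of consecutive pairs (denaturation bubbles). There is long-standing
evidence that these openings are sequence-dependent and enriched near
functional sites such as transcription start sites (TSSs). `pbdtss`
implements a two-part method built on that observation:

1. a statistical-mechanics engine that converts a base sequence into
   per-position equilibrium opening and bubble probabilities under the
   Peyrard–Bishop–Dauxois (PBD) mesoscopic model, and
2. a classification layer that fuses those probability profiles with
   weighted degree (WD) string kernels in a hybrid-kernel soft-margin SVM
   to predict TSSs, evaluated with imbalance-aware metrics.

## The physical model

Each base pair $n$ is reduced to a single stretching coordinate $y_n$ (Å).
The configurational energy of an $N$-base-pair chain is

$$U = V_1(y_1) + \sum_{i=2}^{N}\big[V_i(y_i) + W(y_i, y_{i-1})\big],$$

with an on-site potential per pair (Morse well plus an opening barrier that
models the entropic/solvent cost of re-closing a flipped-out base)

$$V(y) = D\big(e^{-\alpha y}-1\big)^2 +
  \Theta(y)\,\frac{b\,y^3}{\cosh^2\!\big[c(\alpha y - d\ln 2)\big]},$$

and an anharmonic stacking coupling between neighbours

$$W(y_i, y_{i-1}) = \tfrac{1}{2}K\big(1+\rho\,
  e^{-\delta(y_i+y_{i-1})}\big)(y_i-y_{i-1})^2 .$$

$D$, $\alpha$, $b$, $c$, $d$ differ between AT and GC pairs (a GC pair has a
deeper, narrower well — three hydrogen bonds); the stacking strength $K$ is
keyed by the ordered dimer, so sequence enters through both terms. The
effective stacking stiffness drops from $K(1+\rho)$ to $K$ when either pair
opens; this nonlinearity is what produces sharp, cooperative melting.
`pbd_params()` carries the published parameter set (defaults `rho = 25`,
`delta = 0.8` Å⁻¹); a pair is called *open* when $y > y_0$ with
`y0 = 1.5` Å, the average base separation at melting.

### Transfer-integral statistics

All reported quantities are ratios of constrained configuration integrals,
e.g. the probability that pair $j$ is closed in the double-stranded (dsDNA)
ensemble,

$$P_\mathrm{dsDNA}(j\ \mathrm{closed}) = \frac{Z(j\ \mathrm{closed})}{Z_I - Z_{II}},$$

where $Z_I$ is the unconstrained integral, $Z_{II}$ the weight of the fully
open states (excluded from the dsDNA ensemble), and the numerator restricts
$y_j < \xi$. Because the model is one-dimensional, each such integral
factorizes into an iterated one-dimensional quadrature: diagonal site
factors $w(y)e^{-\beta V_i(y)}$ alternating with dense transfer matrices
$e^{-\beta W(y, y')}$, evaluated by matrix–vector products — cost linear in
$N$ and quadratic in the number of abscissae. Boltzmann weights span
hundreds of orders of magnitude over a 300-base chain, so vectors are
renormalized at every step and an accumulated log-scale is carried; the
probabilities, being ratios, are invariant to this scaling.

Bubble statistics use the indicator machinery
$\theta_i = \Theta(y_i - y_0)$: a bubble of exact size $m$ centred at $k$
is $m$ consecutive open pairs with closed flanks (virtual closed flanks
beyond the chain ends; for even $m$ the centre is the base directly to the
left of the midpoint). `bubble_matrix()` tabulates
$P_\mathrm{bub}(k, m) = \langle\theta_k^{[m]}\rangle_\mu$ and
`participation_profile()` sums it into $P_\mathrm{part}(k, m)$, the
probability that pair $k$ lies in a bubble of size at least $m$.

### The fast participation route

Summing the full bubble matrix costs $O(N^2)$ constrained integrals —
fine for the short chains used in verification, infeasible for thousands of
300-base windows. `opening_profile()` instead uses the identity that pair
$k$ participates in a bubble of size $\ge m$ exactly when some window of
$m$ consecutive open pairs contains $k$. Ordering the candidate windows
left to right, the "first occurrence" decomposition telescopes the union
into all-open window weights of sizes $m$ and $m+1$ only:

$$P\Big(\bigcup_{a=s}^{t} A_a\Big) = P(A_s) +
 \sum_{a=s+1}^{t}\big[P(A_a) - P(A_a \cap A_{a-1})\big],$$

because $A_{a'} \cap A_a \subseteq A_{a-1} \cap A_a$ for $a' < a$ (nested
overlaps), and $A_a \cap A_{a-1}$ is itself an all-open window of size
$m+1$. All window weights come from one forward/backward sweep plus short
masked scans, so a whole profile is linear in $N$. The test-suite
cross-checks this route against the explicit bubble-matrix summation on
chains up to $N = 12$ (agreement to $10^{-9}$) and both against dense
$N$-dimensional quadrature on 2–3-bp chains (agreement to near machine
precision).

### Numerical choices

* **Quadrature.** The integrals run over a finite stretching domain with a
  cut-off; we use $y \in [-2, 50]$ Å (the Morse wall annihilates the
  integrand below $-2$; the open plateau is flat long before 50). The rule
  is a composite Gauss–Legendre grid with a panel boundary exactly at the
  open/closed threshold $\xi$, so that constraint masks align with
  quadrature panels rather than cutting through a panel; 70% of the points
  go to the closed panel, which contains the sharply peaked Morse well
  (width $\sigma \approx 0.14$ Å at 345 K). The package default is 600
  points; pipeline-scale runs use a 96-point grid, at which doubling the
  grid changes profile values by under $10^{-3}$, and from 192 points on
  by under $10^{-4}$ (asserted as a test invariant).
* **One threshold.** The open-state cutoff $\xi$ of the ensemble
  definitions and the open/closed indicator threshold $y_0$ are taken to
  be the same 1.5 Å — only one physical separation threshold is
  motivated, and the fully-open weight $Z_{II}$ is computed over the same
  finite domain as $Z_I$.
* **Temperature scale.** $\beta = 1/(k_B T)$ with
  $k_B = 8.617\times10^{-5}$ eV/K, matching the eV/Å parameter units.
* **Ties and edges.** $\Theta(0) = 1$ by convention (measure zero under
  quadrature, and no abscissa falls on $\xi$ by construction). Chain ends
  are free (no periodic wrap); virtual closed flanks beyond the ends exist
  only in the bubble bookkeeping. The even-$m$ participation sums follow
  the printed index ranges exactly, with out-of-chain centres contributing
  zero.
* **Windows.** Profiles are computed on 300-base windows (positions
  $-150\ldots+149$ around the candidate site — the inclusive
  $[-150, 150]$ interval has 301 positions, so the right end is shortened
  by one to honour the 300-base count) and trimmed by 50 values per side
  to discard free-end boundary artefacts, leaving 200 central
  probabilities. The classifier's sequence view uses the 201-base
  $[-100, +100]$ window.

At 345 K a poly(dA)·poly(dT) 300-mer is almost fully melted
($P_\mathrm{part}(k,1) \approx 0.98$) while poly(dG)·poly(dC) stays closed
($\approx 10^{-3}$); profiles increase monotonically in temperature and
AT-richness, which the suite asserts across 310–360 K.

## The classification layer

The sequence view uses the weighted degree kernel of order $d$,

$$k(\mathbf{s}_1, \mathbf{s}_2) = \sum_{k=1}^{d}\beta_k
  \sum_{l=1}^{L-k+1}\mathbb{I}\big(\mathbf{u}_{k,l}(\mathbf{s}_1) =
  \mathbf{u}_{k,l}(\mathbf{s}_2)\big),\qquad
  \beta_k = \frac{2(d-k+1)}{d(d+1)},$$

a position-anchored count of co-occurring k-mers ($\sum_k \beta_k = 1$; the
self-similarity is the closed form $\sum_k \beta_k (L-k+1)$). It is
evaluated via match run-lengths — a maximal run of $r$ matching positions
contributes $\sum_{k\le\min(r,d)}\beta_k(r-k+1)$ — so a Gram matrix costs
one pass over each pair. The shift-tolerant WDS variant is provided (with
unit position weights and a constant shift range, as no specific values
are established for them); it reduces exactly to WD at zero shift.

The physics view applies a Gaussian RBF kernel to the 200-value trimmed
profiles, with default width $\gamma = 1/(p\,\overline{\mathrm{var}})$
($p = 200$, pooled feature variance) since opening probabilities change
scale dramatically with temperature.

The hybrid kernel is the equal-weight average of the two Gram matrices,
each normalized to unit diagonal first — without normalization the
count-valued WD component (magnitude $\sim L$) would swamp the bounded RBF
component. Setting the weights to $(1, 0)$ reproduces the sequence-only
classifier exactly (a test invariant). Nonnegative combinations preserve
positive semidefiniteness, which the suite checks spectrally.

The SVM solves the usual soft-margin dual (box constraint $0 \le \alpha_i
\le C$, equality $\sum_i \alpha_i y_i = 0$) by SMO on the precomputed
kernel matrix; the test-suite verifies feasibility and objective agreement
with an independent interior-point QP solution. The bias is averaged over
all margin support vectors for robustness. Scores
$\sum_j \alpha_j y_j k(x_j, x) + b$ are the ROC threshold variable.

## Evaluation protocol

TSS datasets are heavily imbalanced (the emulated benchmark shape is
10 negatives per positive), so the package reports sensitivity,
specificity, their geometric mean (G-mean), and auROC. The ROC sweep
groups tied scores into single steps, making the trapezoidal area equal to
the Mann–Whitney pairwise statistic (asserted under injected ties).
Random undersampling of the majority class to a 1:1 ratio precedes any
learning; the undersampling is repeated (default 5 independent draws) and
the replicate spread is summarized as a normal-approximation 95% interval
($1.96\,s/\sqrt{n}$) — the replicate scheme behind such intervals is a
package choice, as no canonical one is established. Model selection is a
stratified 10-fold CV over the $3\times7$ grid
$d \in \{6, 12, 24\} \times C \in \{10^{-3},\ldots,10^{3}\}$ (21
combinations), maximizing mean validation auROC; CV ties resolve to the
smallest $C$, then the smallest $d$ (auROC rather than G-mean is the
selection target — both are reported, and auROC is threshold-free).
Evaluation uses a held-out stratified split that undersampling never
touches, mirroring a fixed test set rather than CV-only reporting.

## The synthetic benchmark generator

The real benchmark (dbTSS-derived human windows) requires external genome
downloads, so `make_synthetic()` emulates its *structure*: 201/300-base
window pairs, a 10:1 class imbalance, and positives that carry signal in
both views. Positives receive a TATA-like consensus motif planted 30 bases
upstream of the site with a mean per-position mutation rate of 0.65
(real core-promoter elements are at least this degenerate), and a
contiguous 31-base AT-rich block at a uniformly jittered offset
(±15 bases) around the site, scaled so the mean AT enrichment over the
central ±30 bases equals the nominal `at_bias`. The default bias 0.085
puts the AT-dominant windows' block at an AT fraction near 0.8 — strong
cooperative-bubble territory — while keeping the block's position-wise
match probability between two positives (0.25 + bias²) low enough that a
position-anchored kernel gains little from it. The block form matters twice
over: contiguity is what drives cooperative bubble formation — the PBD
engine amplifies AT *runs* far more than the same composition spread
thin — and the positional jitter mirrors how AT-rich,
nucleosome-depleted stretches vary in position relative to real TSSs.
Jitter also decouples the views: position-anchored k-mer matching dilutes
when the enriched stretch moves between instances, while the spatially
extended opening bump keeps the profiles of different positives
overlapping, so the physics view retains private signal the string kernel
cannot reach. On top of this, the two signals are *anticorrelated across
positives* (`complementarity = 0.8`): some windows are motif-dominant
with a weak AT block, others AT-dominant with a heavily degraded motif,
class means held at the nominal parameters. This heterogeneity mirrors
real promoters — only a fraction carry a recognizable TATA element — and
is what makes fusing the views profitable: neither alone ranks every
positive highly. Setting `at_bias = 0` and `mutation_rate = 1` yields an
exact null in which every classifier must fall to chance (asserted at
auROC $0.5 \pm 0.05$).

What the generator does *not* emulate: genomic background composition
(isochores, CpG islands), multiple TSSs per promoter, the spatial
correlation structure of real negatives (drawn from gene interiors), or
any biological relationship between motif and opening beyond co-location.
Passing the end-to-end tests therefore demonstrates that the pipeline
recovers planted signal of both kinds and fuses them without loss — not
that it attains any particular performance on real genomes.

## Problem sizes used in the checks

Verification sizes were chosen to keep each layer's check sharp: dense
quadrature oracles on 2–3-bp chains (the largest sizes where
$M^N$ enumeration is exact and fast), route-equivalence on 12-bp chains,
homopolymer physics on full 300-base windows across 310–360 K, and the
end-to-end experiment on 200 positives / 2000 negatives at a single
temperature (345 K, bubble size 8 — the configuration reported as best on
the real benchmark) with the 96-point grid, 5-fold CV over a
$3\times3$ grid, and 3 undersampling replicates.

## Known limitations

* Equilibrium only: the engine integrates the configurational ensemble;
  no opening kinetics or lifetimes (the momenta integrate out).
* The parameter set is taken as given; no re-fitting to melting curves.
* Ambiguity codes are rejected rather than imputed — the model is defined
  only for AT/GC pairs.
* `P_bub`/`P_part` are conditioned on the dsDNA ensemble; very close to
  full denaturation (denominator $Z_I - Z_{II} \to 0$) the engine signals
  a numerical-regime error instead of returning unstable ratios.
* The WDS kernel is provided for completeness but the pipeline's sequence
  view uses WD, which is what the headline protocol calls for.
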