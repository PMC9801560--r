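# pbdtss

Transcription start site (TSS) prediction from the physics of DNA
breathing, for computational biologists who want sequence-independent
structural features alongside classical string kernels.

Double-stranded DNA transiently opens under thermal fluctuations — single
base pairs "breathe" and runs of adjacent pairs form denaturation bubbles —
and these openings concentrate at functional sites such as promoters.
`pbdtss` turns that physics into classifier features:

1. **PBD engine.** Under the Peyrard–Bishop–Dauxois mesoscopic model each
   base pair is a stretching coordinate `y` with an on-site potential
   `V(y) = D(e^{-αy}-1)² + Θ(y)·b y³/cosh²[c(αy − d ln2)]` (Morse well plus
   re-closing barrier; AT and GC parameterized separately) and anharmonic
   stacking `W(y_i, y_{i-1}) = ½K(1+ρe^{-δ(y_i+y_{i-1})})(y_i−y_{i-1})²`
   with dimer-specific `K`. Constrained configuration integrals are
   evaluated by an iterative one-dimensional transfer-integral quadrature
   (linear in chain length), yielding the closed-pair probability
   `P(j closed) = Z(j closed)/(Z_I − Z_II)`, the bubble probability matrix
   `P_bub(k, m)`, and the participation profile `P_part(k, m)` (probability
   that base `k` sits in a bubble of ≥ m open pairs).
2. **Hybrid-kernel SVM.** 201-base sequence windows are compared with the
   weighted degree string kernel (order-d k-mer co-occurrence counts,
   weights `β_k = 2(d−k+1)/(d(d+1))`); 200-value trimmed opening profiles
   with a Gaussian RBF kernel; and the two unit-diagonal-normalized Gram
   matrices are averaged into a hybrid kernel for a soft-margin SVM.
   Evaluation uses sensitivity, specificity, G-mean = √(Sn·Sp), and auROC,
   with random undersampling to 1:1 before learning and grid-search CV
   over `d ∈ {6,12,24} × C ∈ {0.001..1000}`.

A seeded synthetic generator emulates the shape of TSS window benchmarks
(10:1 imbalance, positives carrying a degenerate TATA-like motif and a
position-jittered AT-rich block, anticorrelated across windows so the two
views are complementary), so the whole protocol runs self-contained.

## Worked example

```r
library(pbdtss)

# physics: opening profile of an AT-rich vs a GC-rich window
g <- quad_grid(96)                      # composite Gauss-Legendre, [-2, 50] A
closed_probability("ATATATAT", 345, g)
#> [1] 0.4990587 0.4561845 0.4517854 0.4350575 0.4350575 0.4517854 0.4561845 0.4990587
closed_probability("GCGCGCGC", 345, g)
#> [1] 0.9881666 0.9965560 0.9966790 0.9980505 0.9980505 0.9966790 0.9965560 0.9881666

# the AT 8-mer is ~56% open mid-chain at 345 K while GC stays ~99.8% closed:
# the engine sees composition (and the cooperative mid-chain melting of the
# AT tract) the way melting experiments do.

# end-to-end: synthetic benchmark, one temperature, all three kernels
ds  <- make_synthetic(n_pos = 200, n_neg = 2000, seed = 101)
cfg <- experiment_config(temperatures = 345, bubble_m = 8,
                         d_values = c(6, 12, 24), C_values = c(0.1, 1, 10),
                         folds = 5, replicates = 3, test_fraction = 0.5,
                         grid = quad_grid(96), seed = 101)
run_experiment(cfg, ds)[, c("kernel", "auroc", "auroc_ci", "gmean")]
#>        kernel   auroc    auroc_ci     gmean
#> 1 sequence-WD 0.79056 0.020348888 0.6992956
#> 2 profile-RBF 0.80776 0.008131071 0.7332562
#> 3      hybrid 0.83599 0.032157725 0.7488240
```

The report has one row per temperature × kernel: mean auROC and G-mean on
the untouched held-out split (1100 windows) over three undersampling
replicates, ±95% CI. Each single view separates well on its own — the
string kernel finds the degenerate motif, the physics view finds the
AT-rich opening bump — and the hybrid beats both because the planted
signals are complementary across positives. On the null construction
(`at_bias = 0`, `mutation_rate = 1`) every kernel falls to auROC ≈ 0.5.

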