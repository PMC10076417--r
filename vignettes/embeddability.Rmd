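---
title: "Deciding embeddability of centrosymmetric Markov matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding embeddability of centrosymmetric Markov matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Strand symmetry forces the transition matrix of a double-stranded
substitution process to be centrosymmetric (CS):
`a[i,j] = a[n+1-i,n+1-j]`. A CS Markov matrix `M` is *embeddable* when
`M = exp(Q)` for some rate matrix `Q`; then `Q` is a *Markov generator* of
`M`, and the data are consistent with a homogeneous continuous-time chain.
Non-uniqueness of `Q` — rate non-identifiability — arises from the branches
of the complex logarithm: for a conjugate eigenvalue pair, replacing the
principal logarithm of the pair by its k-th branch shifts the matrix
logarithm by `k·V`, where `V = P diag(0, …, 2πi, −2πi) P⁻¹` is real, and
`exp(L + kV) = exp(L)` for every integer `k`.

Everything in this package runs through the generalized Fourier conjugation:
the recursive matrix `S_n` turns any CS matrix into `diag(A1, A2)` with `A1`
of size ⌈n/2⌉ inheriting the Markov (or rate) property. For `n = 4` the
blocks are parameterized in closed form (λ, μ, α, α′, β, β′), the
discriminant `Δ = (α−β)² + 4α′β′` separates real (`Δ > 0`) from conjugate
(`Δ < 0`) eigenvalue pairs, and every real logarithm of `M` is CS with
entries given by explicit formulas in those parameters and the branch index
`k`. Embeddability is then a finite list of inequalities.

### Assumptions

All complete criteria assume **distinct eigenvalues**. This is the generic
situation (the locus of repeated eigenvalues has measure zero in the model),
and it is exactly the regime in which every real zero-row-sum logarithm is
diagonalizable through the eigenvectors of `M`, so the branch enumeration is
complete. Inputs with (numerically) repeated eigenvalues — separation below
`1e-8` relative, or `|Δ| ≤ 1e-12` at `n = 4` — return the status
`"inconclusive"` rather than a guess; Jordan-block logarithm enumeration is
out of scope. The exact identity matrix is special-cased as embeddable with
generator 0 before the distinctness guard, since it is the one
repeated-eigenvalue matrix a user will certainly supply.

## The decision procedures

* `n = 2`: embeddable iff `det(M) > 0`; the generator is the principal
  logarithm, in closed form.
* `n = 3` (used standalone and as the upper block at `n = 5, 6`): with all
  eigenvalues real and positive the principal logarithm is the only real
  logarithm; with a conjugate pair only the branches 0 and −1 can yield a
  rate matrix, so both are materialized and tested.
* `n = 4`: the six spectral parameters are read off the entries, and the
  four rate inequalities are evaluated on the closed-form logarithm
  coefficients. For `Δ < 0` each coefficient is **affine** in the branch
  index `k` (through `w(k) = (2·Arg(λ₂) + 4πk)/√(−Δ)`), so each inequality
  is a half-line or interval in a real `k` and their intersection, clipped
  to the integers, is the exact feasible branch set. No scan bound is
  needed, and the generator count (the identifiability verdict) is exact.
  Since `Δ < 0` forces `α′β′ < 0`, the |·| constraints always bound `w`, so
  the interval is finite.
* `n = 5, 6`: dispatch on which block carries a conjugate pair. Pair in
  `A2` only: the family `Log(M) + kV` with the integer interval
  `L = max ⌈−Log(M)ᵢⱼ/Vᵢⱼ⌉` over `Vᵢⱼ > 0`, `U = min ⌊·⌋` over `Vᵢⱼ < 0`,
  plus the blocking set `N` of negative entries that `V` cannot move. Pair
  in `A1` only: the two upper branches {0, −1}. Pairs in both: the two
  upper branches each combined with the interval on the lower pair. A zero
  eigenvalue (singular matrix) or a simple negative real eigenvalue rules
  out any real logarithm immediately. `n = 5` uses the same code path; the
  odd-order Fourier form simply has a middle row/column and a 2×2 lower
  block.

Every generator the package returns is verified: centrosymmetric, rows
summing to zero, off-diagonals non-negative, and `‖exp(Q) − M‖∞ ≤ 1e-8`
(verification can be switched off in bulk Monte Carlo runs, where only the
verdict matters).

### Boundary handling

The rate inequalities are non-strict, as a zero substitution rate is a
legitimate (boundary) generator. Numerically, a comparison within `1e-10`
of equality cannot be trusted either way, so any decisive comparison inside
that band produces the status `"inconclusive_boundary"` instead of a
verdict. The strict conditions (`λ₁ > 0`, `λ₃ > 0`) use the same band. In
the Monte Carlo runs these cases are counted separately (they are a
measure-zero set; in practice well under 1 in 10⁴ samples).

## Numerical choices

* **Matrix exponential**: spectral (`P diag(e^λ) P⁻¹`) when the eigenvector
  condition number is below `1e8`, otherwise `Matrix::expm`
  (scaling-and-squaring). The spectral route is what keeps the worked
  example honest: its second eigenvalue is `e^{−7π} ≈ 2.6e-10`, which series
  methods lose entirely.
* **Principal logarithm**: spectral, refusing eigenvalues on the closed
  negative real axis and near-defective spectra; the result is checked to
  be real (imaginary residual below `1e-9` relative — a larger residual
  would indicate mismatched conjugate branches and raises an internal
  error rather than being truncated) and, for CS input, to be CS.
* **Eigenvalue ordering**: deterministic (eigenvalue 1 first for Markov
  input, then reals descending, then pairs by ascending real part with the
  positive-imaginary member first), so branch bookkeeping is stable across
  calls.
* **Tolerances**: structural checks use `1e-12` on exactly-entered matrices
  and `1e-9` after floating-point pipelines; the Fourier conjugation itself
  is exact in rational arithmetic, so only round-off needs absorbing.
* **Worked example precision**: recovering the generator of the fixture
  from the *entries* of `M = exp(Q)` is limited to about `5e-8` accuracy,
  because `λ₁ = λ + μ − 1 = e^{−7π}` is obtained by cancellation of
  entries of order 0.14 (relative error ≈ `1e-7`, amplified through
  `log λ₁`). The spectral route through the printed eigendecomposition
  recovers the generator to machine precision; the tests assert each route
  at its attainable accuracy. At time scaling `t = 4` the fixture has three
  generators (branches −1, 0, 1 around `4Q`); enumeration there must go
  through the eigendecomposition, since `e^{−28π} ≈ 1e-38` is invisible in
  the entries of `exp(4Q)`.

## Volumes and the Monte Carlo design

In free coordinates (the first ⌊n/2⌋ rows, plus half of the symmetric middle
row for odd `n`) the CS Markov polytope is a Cartesian product of simplices,
with exact volume `1/(n−1)!^{n/2}` (even `n`). The default sampler draws
each free row from the flat Dirichlet — exact uniformity, no rejection. The
box-rejection sampler (off-diagonals uniform in `[0,1]`, reject negative
diagonals) is retained because it is the protocol of the original volume
tables and provides a cross-validation oracle; the two samplers are compared
by a Kolmogorov–Smirnov test in the suite.

Regions: `dd` (diagonally dominant — off-diagonal row sum ≤ 1/2 — sampled
directly as a scaled simplex product), `dlc`, `trace_Yn` (upper-block trace
> 1, the necessary condition for embeddability), and `v_plus`
(positive distinct real eigenvalues, `Δ > 0`, at `n = 4`). Estimates carry
Wilson 95% intervals, which remain valid at the tiny hit counts of the 6×6
embeddable fraction. All randomness is driven by one integer seed; chunked
accumulation is sequential, so identical seeds give identical hit counts.

Two definitional notes, resolved here as design choices:

* **DLC.** "Diagonal largest in column" is ambiguous for row-stochastic CS
  matrices once both strands are represented. The exact volume `1/576`
  published for the DLC polytope equals `(1/4)² · 1/36`, which is the set
  where each diagonal entry is the largest entry of its *row* (for a flat
  Dirichlet row, a given coordinate is maximal with probability exactly
  1/4); the literal per-column set is strictly larger. This package's `dlc`
  region is the row-maximal set, the one whose share of the polytope is
  6.25%.
* **V₊ inequalities.** The published inequality list compares `α + β`
  against `Δ` where the eigenvalue formulas require `√Δ`; the region
  implemented is "positive distinct real eigenvalues", i.e. `λ₁ > 0`,
  `Δ > 0`, `α + β > √Δ`.
* **K3P positivity.** The K3P inequalities are stated with `pq > 0`, but
  their log terms derive from logarithms of the individual eigenvalues, so
  `p > 0` and `q > 0` are required separately; with distinct eigenvalues a
  negative pair admits no real zero-row-sum logarithm at all.

### The 6×6 run

Deciding embeddability for millions of 6×6 samples combines three layers:
vectorized necessary conditions evaluated directly on the free coordinates
(upper-block trace > 1; sign analysis of the quadratic factor of the upper
block and of the lower-block characteristic cubic — all-real roots are all
positive iff all three elementary symmetric functions are positive, and
with a conjugate pair the real root is positive iff the determinant is),
which reject the large majority of samples without any eigen-solve; the
full case analysis on the survivors; and separate accounting of degenerate
samples. The pre-filters are exact necessary conditions, so the hit counts
equal those of the naive full scan (this equality is tested on random
batches).

Problem sizes: the packaged acceptance runs use 10⁶ samples per trace-region
volume, 10⁶ (4×4), 2·10⁵ (4×4 diagonally dominant) and 3·10⁶ (6×6) samples
for the embeddable fractions, and 10⁷ for the 2×2 determinant criterion;
the reproduction script raises these to 4·10⁶ at 4×4 and 10⁶ for the
dominant-conditioned fraction. At these sizes the binomial
standard error of the 6×6 embeddable count is about 16% of its value, which
is the dominant uncertainty anywhere in the package.

## What the synthetic generators emulate

`random_cs_rate(n, seed, scale)` draws the free off-diagonal rates i.i.d.
exponential with mean `scale` (default 0.1, giving transition matrices at a
moderate evolutionary distance — diagonal entries around 0.6–0.8 at
`n = 4`) and mirrors them centrosymmetrically; `random_embeddable()`
exponentiates such a draw and carries its generator for completeness
checks. These generators produce matrices that are embeddable *by
construction* with independent, unstructured rates. They emulate the
stochastic mechanism of the model class, not real alignments: no
among-site rate variation, no base-composition skew beyond strand symmetry,
no estimation noise from finite sequences. Passing the round-trip sweeps
therefore shows the criteria are complete on the model class; it says
nothing about how often *empirical* transition matrix estimates will be
embeddable, which is precisely what the volume computations quantify
(rarely, unless the matrix is diagonally dominant).

## Known limitations

* Repeated-eigenvalue matrices (including the K2P/JC submodels, where
  multiple or uncountably many generators can occur) are reported
  `"inconclusive"`, never decided.
* Orders above 6 get necessary conditions only (`trace_necessary`,
  `cs_log_exists`); no complete criterion exists there.
* One published reference value is irreproducible from its own definition:
  the exact volume printed for the trace region at `n = 6`
  (`433/653837184000 ≈ 6.2e-10`) is about 420× smaller than what the trace
  condition yields — the Monte Carlo fraction computed by this package's
  suite is ≈ 0.48 of the polytope, consistent with the n = 4 (1/2) and
  n = 5 (0.62) values, both of which this package reproduces, and with the
  fact that the upper-block trace of a uniform sample has mean exactly 1 at
  `n = 6`. The corresponding acceptance assertion is expected to fail and
  is retained as documentation of the discrepancy.
* The two published sampling protocols for the conditional volume
  `v(V_em+)/v(V₊)` give slightly different values (≈0.17 vs ≈0.186); both
  protocols are available (`sample_cs_markov` methods), and no attempt is
  made to reconcile them.
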