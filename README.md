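# csembed

Embeddability and rate identifiability of centrosymmetric Markov matrices.

## The problem

A substitution process on double-stranded DNA sees every substitution twice —
once on each strand, between complementary nucleotides. The most general
transition matrix consistent with that complementarity is *centrosymmetric*
(CS): symmetric about its center, `a[i,j] = a[n+1-i,n+1-j]`. For the four
natural nucleotides these are the strand symmetric Markov matrices (with the
Jukes-Cantor, Kimura 2- and 3-parameter models as submodels); synthetic
genetic alphabets with six, eight or more letters give CS matrices of higher
order.

The *embedding problem* asks whether an observed transition matrix `M` can be
written as `M = exp(Q)` for a rate matrix `Q` (rows summing to zero,
non-negative off-diagonal entries) — that is, whether the observed
substitution probabilities are consistent with a homogeneous continuous-time
Markov process. When a generator `Q` exists it need not be unique: the
logarithm of a matrix with complex eigenvalues has countably many branches,
`log_k(z) = log|z| + (Arg(z) + 2πk)i`, and distinct branches can all be rate
matrices. A matrix with several Markov generators has non-identifiable
substitution rates.

`csembed` implements the complete decision procedure for CS Markov matrices:

* **Block structure.** Every CS matrix is conjugated by the generalized
  Fourier matrix `S_n` into two blocks, `A1` (of size ⌈n/2⌉, Markov/rate
  whenever the input is) and `A2`; `block_transform()` /
  `inverse_block_transform()` with entrywise conditions for the assembled
  matrix to be Markov or rate.
* **4×4 (strand symmetric) criterion.** Closed-form parameters
  λ = m₁₁+m₁₄, μ = m₂₂+m₂₃, α = m₂₂−m₂₃, α′ = m₂₁−m₂₄, β = m₁₁−m₁₄,
  β′ = m₁₂−m₁₃, discriminant Δ = (α−β)² + 4α′β′ and eigenvalues
  (1, λ+μ−1, ((α+β)±√Δ)/2). `M` with distinct eigenvalues is embeddable iff
  λ₁ > 0, (α+β)² > Δ and, for k = 0 (Δ > 0) or some integer k (Δ < 0),
  |φ(k)| ≤ −α₁, |ε(k)| ≤ −β₁, γ(k) ≤ α₁, δ(k) ≤ β₁. For Δ < 0 every
  coefficient is affine in k, so the feasible branch set is computed as an
  exact integer interval — no scan bound. `is_embeddable4()`,
  `candidate_log4()`, `markov_generators4()`, `k3p_embeddable()`.
* **Other orders.** The 2×2 determinant criterion, the 3×3 two-branch
  (principal / −1) criterion, and the four-case analysis for 5×5 and 6×6
  matrices driven by which Fourier block carries the complex pair
  (`classify_case6()`, `feasible_branch_interval()`,
  `is_embeddable_large()`), plus the generic trace necessary condition
  (`trace_necessary()`).
* **Volumes.** Exact polytope volumes (`closed_form_volume()`: 1/36, 1/4608,
  1/1728000 at n = 4, 5, 6), uniform samplers over the CS Markov polytope
  and its diagonally dominant subset, and hit-and-miss Monte Carlo with
  Wilson intervals (`hit_and_miss()`, `embeddable_fraction()`), quantifying
  how rare embeddable matrices are.

## Worked example

A Kimura 3-parameter matrix with row (0.65, 0.20, 0.10, 0.05):

```r
library(csembed)
M <- k3p_matrix(0.65, 0.2, 0.1, 0.05)
is_embeddable4(M)
#> Embeddability report (n = 4)
#>   status: embeddable
#>   sign(Delta): 1
#>   feasible branch interval: [0, 0]
#>   generators: 1
round(markov_generators4(M)$generators[[1]], 4)
#>         [,1]    [,2]    [,3]    [,4]
#> [1,] -0.4915  0.3132  0.1450  0.0334
#> [2,]  0.3132 -0.4915  0.0334  0.1450
#> [3,]  0.1450  0.0334 -0.4915  0.3132
#> [4,]  0.0334  0.1450  0.3132 -0.4915
```

The eigenvalues (1, 0.4, 0.7, 0.5) are real and distinct (Δ = 0.04 > 0), so
the only possible generator is the principal logarithm; it is a rate matrix,
hence `M` is embeddable with identifiable rates: 0.3132 is the
transition-type substitution rate recovered from the transition
probabilities, and each diagonal −0.4915 is minus the total substitution
rate out of a nucleotide.

Rates are not always identifiable. The worked fixture builds a CS Markov
matrix `M` whose conjugate eigenvalue pair ±e^{−4π}i admits a *non-principal*
generator:

```r
fx <- prop3_fixture()
round(fx$Q, 3)
#>         [,1]   [,2]   [,3]    [,4]
#> [1,] -16.493 12.566  3.142   0.785
#> [2,]   0.785 -7.069  0.785   5.498
#> [3,]   5.498  0.785 -7.069   0.785
#> [4,]   0.785  3.142 12.566 -16.493
markov_generators4(fx$M)
#> Markov generator set: 1 generator(s) (k = -1)
```

At larger evolutionary times the branch interval widens: for `exp(4Q)` the
branches k = −1, 0, 1 of `real_log_family()` are all CS rate matrices — three
different continuous-time processes produce identical transition
probabilities.

Embeddable matrices are rare:

```r
embeddable_fraction(4, n_samples = 1e5, seed = 1)
#> Monte Carlo fraction of 'embeddable' in 'markov': 0.017
#>   95% CI [0.01621714, 0.01781997], 1700 hits / 1e+05 samples (seed 1)
```

so about 98.3% of uniformly drawn strand symmetric Markov matrices are
inconsistent with any homogeneous continuous-time model.

A thin command-line interface is installed with the package
(`system.file("cli", "csembed", package = "csembed")`); see `?run_cli` for
the `check`, `generators`, `volume` and `fixture` subcommands, which read
headerless CSV matrices and emit JSON reports.

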