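Package: csembed
Title: Embeddability and Rate Identifiability of Centrosymmetric Markov Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether a centrosymmetric (strand-symmetric) Markov matrix
    is the exponential of a rate matrix, i.e. whether observed substitution
    probabilities are consistent with a homogeneous continuous-time substitution
    process on double-stranded DNA or synthetic genetic alphabets. Provides the
    generalized Fourier block-diagonalization of centrosymmetric matrices,
    enumeration of all real logarithms and Markov generators through the
    branches of the matrix logarithm (including the closed-form 4x4 criterion
    and the case analysis for 5x5 and 6x6 matrices), the Kimura 3-parameter
    specialization, and Monte Carlo and closed-form volume computations
    quantifying how rare embeddable matrices are inside the centrosymmetric
    Markov polytope and its diagonally dominant and diagonally-largest-in-column
    subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
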