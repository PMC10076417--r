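# The worked identifiability example (a CS Markov matrix with two-plus CS
# Markov generators, built spectrally from an exact integer/complex
# eigenvector matrix) and random CS rate/Markov generators used throughout
# the tests.

#' Worked non-identifiability example
#'
#' Builds, from the exact eigenvector matrix
#' `P = rbind(c(1,-5,1-1i,1+1i), c(1,2,-1i,1i), c(1,2,1i,-1i),
#' c(1,-5,-1+1i,-1-1i))`, the CS Markov matrix
#' `M = P diag(1, exp(-7*pi), exp(-4*pi)*1i, -exp(-4*pi)*1i) P^{-1}`, its CS
#' Markov generator
#' `Q = P diag(0, -7*pi, -4*pi - 3*pi/2*1i, -4*pi + 3*pi/2*1i) P^{-1}` (the
#' branch `-1` logarithm), and the branch shift matrix
#' `V = P diag(0, 0, 2*pi*1i, -2*pi*1i) P^{-1}` with `exp(Q + V) = M`. All
#' matrices are materialized spectrally: the eigenvalue `exp(-7*pi)` is about
#' `2.6e-10` and would be destroyed by series exponentiation. The invariants
#' (M CS Markov, Q CS rate, exponential residuals) are verified at
#' construction.
#'
#' @param t Time scaling: the fixture for `exp(t * Q)`. Generator
#'   multiplicity appears for larger `t`: at `t = 1` the only generator is
#'   `Q`; from `t = 4` on, `t*Q - V`, `t*Q`, `t*Q + V` are all rate matrices.
#' @return A list of class `prop3_fixture` with `P` (complex), `M`, `Q`, `V`,
#'   `t`, and `decomposition` (a [spectral_decomposition()]-shaped object
#'   built from the exact `P`, usable with [real_log_family()]).
#' @export
prop3_fixture <- function(t = 1) {
  P <- matrix(c(1, -5, 1 - 1i, 1 + 1i,
                1, 2, -1i, 1i,
                1, 2, 1i, -1i,
                1, -5, -1 + 1i, -1 - 1i), 4, 4, byrow = TRUE)
  Pinv <- solve(P)
  dlogM <- c(0, -7 * pi, -4 * pi + (pi / 2) * 1i, -4 * pi - (pi / 2) * 1i) * t
  dQ <- c(0, -7 * pi, -4 * pi - 1.5 * pi * 1i, -4 * pi + 1.5 * pi * 1i) * t
  spectral <- function(d) {
    A <- P %*% diag(d, 4) %*% Pinv
    if (max(abs(Im(A))) > 1e-10) {
      stop("internal error: fixture matrix has imaginary residual ",
           format(max(abs(Im(A)))))
    }
    Re(A)
  }
  M <- spectral(exp(dlogM))
  Q <- spectral(dQ)
  V <- spectral(c(0, 0, 2i * pi, -2i * pi))
  if (!is_centrosymmetric(M, tol = 1e-12) || !is_markov_matrix(M, 1e-12)) {
    stop("internal error: fixture M failed the CS Markov check")
  }
  if (!is_centrosymmetric(Q, tol = 1e-10 * max(abs(Q))) ||
      !is_rate_matrix(Q, 1e-10 * max(abs(Q)))) {
    stop("internal error: fixture Q failed the CS rate check")
  }
  if (max(abs(mat_exp(Q) - M)) > 1e-8 || max(abs(mat_exp(Q + V) - M)) > 1e-8) {
    stop("internal error: fixture exponential residual too large")
  }
  # ordering: eigenvalue 1, then the real eigenvalue, then the pair (Im > 0
  # member first) -- matches P's columns after swapping 3 <-> 3 (already so)
  dec <- structure(list(values = as.complex(exp(dlogM)), vectors = P,
                        pairs = list(c(3L, 4L)), real_idx = 1:2,
                        distinct = TRUE, separation = 1,
                        condition = cond2(P)),
                   class = "spectral_decomposition")
  structure(list(P = P, M = M, Q = Q, V = V, t = t, decomposition = dec),
            class = "prop3_fixture")
}

#' @export
print.prop3_fixture <- function(x, ...) {
  cat("Non-identifiability fixture at t =", x$t, "\n")
  cat("  exp(Q) = M residual:", format(max(abs(mat_exp(x$Q) - x$M))), "\n")
  invisible(x)
}

#' Random centrosymmetric rate matrix
#'
#' Draws the free off-diagonal entries from an exponential distribution with
#' mean `scale`, mirrors them centrosymmetrically, and sets each diagonal
#' entry to minus its row sum. The exponential of any rate matrix is a Markov
#' matrix, so these are the natural generators of random embeddable CS Markov
#' matrices.
#'
#' @param n Matrix order.
#' @param seed Integer seed (fixed seed gives a bit-identical matrix).
#' @param scale Mean substitution rate per off-diagonal entry. The default
#'   0.1 gives transition matrices at a moderate evolutionary distance
#'   (diagonal entries around 0.6-0.8 at n = 4).
#' @return An `n x n` CS rate matrix.
#' @export
random_cs_rate <- function(n, seed = 1L, scale = 0.1) {
  n <- check_order(n)
  if (scale <= 0) stop("scale must be positive")
  set.seed(seed)
  k <- n %/% 2L
  Q <- matrix(0, n, n)
  for (i in seq_len(k)) {
    for (j in seq_len(n)) {
      if (j != i) {
        q <- stats::rexp(1, rate = 1 / scale)
        Q[i, j] <- q
        Q[n + 1L - i, n + 1L - j] <- q
      }
    }
  }
  if (n %% 2L == 1L) {
    m <- k + 1L
    for (j in seq_len(k)) {
      q <- stats::rexp(1, rate = 1 / scale)
      Q[m, j] <- q
      Q[m, n + 1L - j] <- q
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Random embeddable CS Markov matrix
#'
#' The exponential of a [random_cs_rate()] draw; the generating rate matrix
#' is attached as attribute `"generator"` so completeness tests can check
#' that the embeddability criteria recover it.
#'
#' @inheritParams random_cs_rate
#' @return A CS Markov matrix with attribute `generator`.
#' @export
random_embeddable <- function(n, seed = 1L, scale = 0.1) {
  Q <- random_cs_rate(n, seed = seed, scale = scale)
  M <- mat_exp(Q)
  # symmetrize away the last bits of round-off so validations are exact
  M <- (M + M[n:1, n:1, drop = FALSE]) / 2
  M <- M / rowSums(M)
  attr(M, "generator") <- Q
  M
}
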