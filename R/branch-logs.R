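# Scalar logarithm branches, ordered spectral decompositions, the principal
# matrix logarithm, and the enumeration of all real zero-row-sum logarithms of
# a Markov matrix with distinct eigenvalues (one branch index per conjugate
# eigenvalue pair; real eigenvalues are forced onto the principal branch).

# 2-norm condition number (works for complex matrices, unlike kappa())
cond2 <- function(X) {
  s <- svd(X, nu = 0, nv = 0)$d
  if (min(s) == 0) return(Inf)
  max(s) / min(s)
}

#' k-th branch of the complex logarithm
#'
#' `branch_log_scalar(z, k)` is `log|z| + (Arg(z) + 2*pi*k) * 1i` with the
#' principal argument `Arg(z)` in `(-pi, pi)`. It is defined away from the
#' closed negative real axis, where the argument is discontinuous.
#'
#' @param z A complex (or positive real) scalar not on `(-Inf, 0]`.
#' @param k Integer branch index.
#' @return A complex scalar `w` with `exp(w) == z` and
#'   `Im(w) == Arg(z) + 2*pi*k`.
#' @examples
#' branch_log_scalar(1i, -1)   # -3*pi/2 * 1i
#' @export
branch_log_scalar <- function(z, k = 0L) {
  z <- as.complex(z)
  if (length(z) != 1L || length(k) != 1L) stop("z and k must be scalars")
  if (k != round(k)) stop("branch index k must be an integer")
  if (Im(z) == 0 && Re(z) <= 0) {
    stop("log branch undefined for z on the closed negative real axis: z = ",
         format(z))
  }
  complex(real = log(Mod(z)), imaginary = Arg(z) + 2 * pi * k)
}

#' Ordered spectral decomposition
#'
#' Eigen-decomposition with a deterministic eigenvalue ordering used for
#' branch bookkeeping: the eigenvalue closest to 1 first when `markov = TRUE`,
#' then the remaining real eigenvalues in descending order, then complex
#' conjugate pairs by ascending real part with the positive-imaginary member
#' first. Eigenvalues whose imaginary part is below `tol * max(1, |lambda|)`
#' are treated as real.
#'
#' @param A A real square matrix.
#' @param markov If `TRUE`, pin the eigenvalue 1 (with the all-ones
#'   eigenvector) to the first slot.
#' @param tol Relative tolerance for classifying eigenvalues as real and for
#'   the distinctness guard.
#' @return A list of class `spectral_decomposition` with components `values`
#'   (complex, ordered), `vectors` (complex matrix), `pairs` (list of index
#'   pairs, positive-imaginary member first), `real_idx`, `distinct` (logical),
#'   and `condition` (condition number of the eigenvector matrix).
#' @export
spectral_decomposition <- function(A, markov = FALSE, tol = 1e-8) {
  A <- check_square(A)
  e <- eigen(A)
  vals <- as.complex(e$values)
  vecs <- e$vectors
  if (is.numeric(vecs)) vecs <- vecs + 0i
  scale <- pmax(1, Mod(vals))
  is_real <- abs(Im(vals)) <= tol * scale
  ord <- integer(0)
  used <- rep(FALSE, length(vals))

  if (markov) {
    cand <- which(is_real)
    if (length(cand) == 0L) stop("Markov matrix has no real eigenvalue")
    first <- cand[which.min(Mod(vals[cand] - 1))]
    ord <- first
    used[first] <- TRUE
  }
  real_rest <- which(is_real & !used)
  real_rest <- real_rest[order(Re(vals[real_rest]), decreasing = TRUE)]
  ord <- c(ord, real_rest)
  used[real_rest] <- TRUE

  pairs <- list()
  cplx <- which(!is_real & !used)
  cplx <- cplx[order(Re(vals[cplx]), Im(vals[cplx]))]
  while (length(cplx) > 0L) {
    i <- cplx[1]
    conj_i <- cplx[which.min(Mod(vals[cplx] - Conj(vals[i])))]
    if (conj_i == i && length(cplx) > 1L) conj_i <- cplx[2]
    pos <- if (Im(vals[i]) > 0) i else conj_i
    neg <- if (pos == i) conj_i else i
    k0 <- length(ord)
    ord <- c(ord, pos, neg)
    pairs[[length(pairs) + 1L]] <- c(k0 + 1L, k0 + 2L)
    cplx <- setdiff(cplx, c(i, conj_i))
  }

  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  # force reality on eigenvalues classified as real
  real_pos <- seq_len(length(ord) - 2L * length(pairs))
  vals[real_pos] <- complex(real = Re(vals[real_pos]), imaginary = 0)

  sep <- Inf
  nv <- length(vals)
  if (nv > 1L) {
    for (i in 1:(nv - 1)) {
      for (j in (i + 1):nv) {
        sep <- min(sep, Mod(vals[i] - vals[j]) / max(1, Mod(vals[i])))
      }
    }
  }
  condition <- tryCatch(cond2(vecs), error = function(e) Inf)
  structure(list(values = vals, vectors = vecs, pairs = pairs,
                 real_idx = real_pos, distinct = sep > tol,
                 separation = sep, condition = condition),
            class = "spectral_decomposition")
}

#' Matrix exponential
#'
#' Spectral exponential `P diag(exp(lambda)) P^{-1}` when the eigenvector
#' matrix is well conditioned (condition number below `1e8`), falling back to
#' scaling-and-squaring (`Matrix::expm`) otherwise. The spectral route keeps
#' tiny eigenvalue magnitudes (such as `exp(-7*pi)` in the worked
#' identifiability example) to full relative precision.
#'
#' @param A A real square matrix.
#' @return The real matrix `exp(A)`.
#' @export
mat_exp <- function(A) {
  A <- check_square(A)
  dec <- tryCatch(spectral_decomposition(A), error = function(e) NULL)
  if (!is.null(dec) && dec$condition < 1e8 && dec$separation > 1e-10) {
    E <- dec$vectors %*% diag(exp(dec$values), nrow(A)) %*% solve(dec$vectors)
    return(Re(E))
  }
  as.matrix(Matrix::expm(Matrix::Matrix(A)))
}

exp_residual <- function(Q, M) {
  max(abs(mat_exp(Q) - M)) / max(1, max(abs(M)))
}

#' Principal matrix logarithm
#'
#' The unique logarithm whose eigenvalues all have imaginary part in
#' `(-pi, pi)`, defined for matrices with no eigenvalue on the closed negative
#' real axis. Computed spectrally; matrices with (near-)repeated eigenvalues
#' are refused rather than risking a wrong branch assignment. The principal
#' logarithm of a centrosymmetric matrix is again centrosymmetric, which is
#' asserted as a post-check.
#'
#' @param A A real invertible square matrix with no eigenvalue on
#'   `(-Inf, 0]` and distinct eigenvalues.
#' @param tol Tolerance for the branch-cut and distinctness guards.
#' @return A real matrix `L` with `exp(L) == A` (up to round-off).
#' @export
principal_log_matrix <- function(A, tol = 1e-8) {
  A <- check_square(A)
  if (max(abs(A - diag(nrow(A)))) <= 1e-14) return(matrix(0, nrow(A), nrow(A)))
  dec <- spectral_decomposition(A, markov = FALSE, tol = tol)
  vals <- dec$values
  on_cut <- abs(Im(vals)) <= tol * pmax(1, Mod(vals)) & Re(vals) <= tol
  if (any(on_cut)) {
    stop("principal logarithm undefined: eigenvalue on the closed negative ",
         "real axis (", format(vals[on_cut][1]), ")")
  }
  if (!dec$distinct) {
    stop("inconclusive: (near-)repeated eigenvalues, separation ",
         format(dec$separation))
  }
  if (dec$condition > 1e8) {
    stop("inconclusive: eigenvector matrix condition ",
         format(dec$condition), " indicates a near-defective spectrum")
  }
  logs <- log(dec$values)  # principal complex log
  L <- dec$vectors %*% diag(logs, nrow(A)) %*% solve(dec$vectors)
  imag <- max(abs(Im(L)))
  if (imag > 1e-9 * max(1, max(abs(Re(L))))) {
    stop("internal error: principal log has imaginary residual ", format(imag))
  }
  L <- Re(L)
  if (is_centrosymmetric(A, tol = 1e-9 * max(1, max(abs(A)))) &&
      !is_centrosymmetric(L, tol = 1e-8 * max(1, max(abs(L))))) {
    stop("internal error: principal log of a CS matrix failed the CS post-check")
  }
  L
}

#' All real zero-row-sum logarithms of a Markov matrix
#'
#' For a Markov matrix `M` with positive determinant and distinct eigenvalues,
#' every real logarithm with rows summing to zero is obtained from the
#' eigen-decomposition by taking the principal logarithm on the real
#' eigenvalues (which must be positive), branch `k_j` on the
#' positive-imaginary member of the j-th conjugate pair, and the conjugate
#' branch on its partner. `branch_indices` supplies one integer per conjugate
#' pair, in the pair order of `decomposition`.
#'
#' @param M A Markov matrix with distinct eigenvalues.
#' @param branch_indices Integer vector, one entry per conjugate eigenvalue
#'   pair of `M` (may be empty when the spectrum is real).
#' @param decomposition Optional pre-computed [spectral_decomposition()] of
#'   `M` (with `markov = TRUE`); computed if missing.
#' @return A list of class `candidate_log` with components `matrix` (real),
#'   `branch_indices`, `is_rate`, and `residual` (`max |exp(Q) - M|`).
#' @export
real_log_family <- function(M, branch_indices = integer(0),
                            decomposition = NULL, tol = 1e-8) {
  M <- check_square(M)
  dec <- if (is.null(decomposition)) {
    spectral_decomposition(M, markov = TRUE, tol = tol)
  } else decomposition
  if (!dec$distinct) {
    stop("inconclusive: repeated eigenvalues (separation ",
         format(dec$separation), "); the branch enumeration assumes a ",
         "distinct spectrum")
  }
  if (length(branch_indices) != length(dec$pairs)) {
    stop("need one branch index per conjugate eigenvalue pair: got ",
         length(branch_indices), ", expected ", length(dec$pairs))
  }
  vals <- dec$values
  logs <- complex(length(vals))
  for (i in dec$real_idx) {
    lam <- Re(vals[i])
    if (abs(lam - 1) <= tol) {
      logs[i] <- 0
    } else if (lam <= 0) {
      stop("no real logarithm in this family: non-positive real eigenvalue ",
           format(lam))
    } else {
      logs[i] <- log(lam)
    }
  }
  for (j in seq_along(dec$pairs)) {
    p <- dec$pairs[[j]]
    lk <- branch_log_scalar(vals[p[1]], branch_indices[j])
    logs[p[1]] <- lk
    logs[p[2]] <- Conj(lk)
  }
  Q <- dec$vectors %*% diag(logs, nrow(M)) %*% solve(dec$vectors)
  imag <- max(abs(Im(Q)))
  if (imag > 1e-9 * max(1, max(abs(Re(Q))))) {
    stop("internal error: mismatched conjugate branches, imaginary residual ",
         format(imag))
  }
  Q <- Re(Q)
  structure(list(matrix = Q,
                 branch_indices = as.integer(branch_indices),
                 is_rate = is_rate_matrix(Q, tol = tol_float),
                 residual = max(abs(mat_exp(Q) - M))),
            class = "candidate_log")
}

#' Branch shift matrix for one conjugate eigenvalue pair
#'
#' `V = P diag(0, ..., 2*pi*1i, -2*pi*1i) P^{-1}` with the non-zero entries in
#' the slots of the targeted conjugate pair. Consecutive logarithm branches of
#' the pair differ by exactly `V`, and `exp(L + k V) == exp(L)` for every
#' integer `k`, which is what makes Markov generators non-unique.
#'
#' @param decomposition A [spectral_decomposition()].
#' @param pair Index (into `decomposition$pairs`) of the conjugate pair to
#'   shift.
#' @return A real matrix `V`.
#' @export
branch_shift_matrix <- function(decomposition, pair = 1L) {
  dec <- decomposition
  if (pair < 1 || pair > length(dec$pairs)) {
    stop("no conjugate pair with index ", pair)
  }
  d <- complex(length(dec$values))
  p <- dec$pairs[[pair]]
  d[p[1]] <- 2i * pi
  d[p[2]] <- -2i * pi
  V <- dec$vectors %*% diag(d, length(d)) %*% solve(dec$vectors)
  imag <- max(abs(Im(V)))
  if (imag > 1e-9 * max(1, max(abs(Re(V))))) {
    stop("internal error: branch shift matrix has imaginary residual ",
         format(imag))
  }
  Re(V)
}
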