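# Independent oracles and random-instance builders shared across the suite.
# The oracles deliberately avoid the code paths they check: matrix
# exponentials go through Matrix::expm (Ward's Pade scaling-and-squaring),
# logarithm branches through the eigen-solver route when checking the
# entry-based closed forms, and vice versa.

expm_oracle <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A)))
}

max_abs <- function(A) max(abs(A))

# brute-force set of branch indices k for which the eigen-based real
# logarithm of M is a rate matrix (single conjugate pair assumed)
brute_rate_branches <- function(M, krange = -50:50, tol = 1e-9) {
  dec <- spectral_decomposition(M, markov = TRUE)
  ks <- integer(0)
  for (k in krange) {
    cl <- real_log_family(M, k, decomposition = dec)
    if (cl$is_rate) ks <- c(ks, k)
  }
  ks
}

# random K3P Markov matrix (Dirichlet rows)
random_k3p <- function() {
  r <- rexp(4)
  r <- r / sum(r)
  k3p_matrix(r[1], r[2], r[3], r[4])
}

# random 4x4 CS Markov matrix with a complex conjugate eigenvalue pair
# (Delta < 0), by rejection from uniform sampling
random_delta_neg <- function(max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    r1 <- rexp(4); r1 <- r1 / sum(r1)
    r2 <- rexp(4); r2 <- r2 / sum(r2)
    M <- rbind(r1, r2, rev(r2), rev(r1))
    dimnames(M) <- NULL
    sp <- spectrum4(M)
    if (sp$Delta < -1e-6 && sp$lam + sp$mu - 1 > 1e-6) return(M)
  }
  stop("failed to draw a Delta < 0 matrix")
}

# real canonical form for a prescribed spectrum: real eigenvalues as
# scalars, conjugate pairs a +- b*i (positive-imaginary member first) as
# rotation blocks rbind(c(a, b), c(-b, a))
real_canonical <- function(ev) {
  m <- length(ev)
  D <- matrix(0, m, m)
  i <- 1L
  while (i <= m) {
    if (abs(Im(ev[i])) < 1e-14) {
      D[i, i] <- Re(ev[i])
      i <- i + 1L
    } else {
      stopifnot(i < m, Im(ev[i]) > 0,
                Mod(ev[i + 1] - Conj(ev[i])) < 1e-12)
      a <- Re(ev[i]); b <- Im(ev[i])
      D[i, i] <- a; D[i, i + 1L] <- b
      D[i + 1L, i] <- -b; D[i + 1L, i + 1L] <- a
      i <- i + 2L
    }
  }
  D
}

# 6x6 (or 5x5) CS Markov matrix with prescribed block spectra, built by
# spectral synthesis: real-canonical blocks conjugated by random real
# similarities, assembled through the inverse Fourier transform, with the
# lower block shrunk until the Markov compatibility conditions hold
synth_cs_markov <- function(n, upper_ev, lower_ev, seed = 1) {
  set.seed(seed)
  k1 <- ceiling(n / 2); k2 <- n %/% 2
  stopifnot(length(upper_ev) == k1 - 1, length(lower_ev) == k2)
  # upper block: Markov with eigenvalue 1 and the requested spectrum
  ones <- rep(1, k1)
  D1 <- rbind(c(1, rep(0, k1 - 1)),
              cbind(0, real_canonical(upper_ev)))
  tries <- 0
  repeat {
    N1 <- cbind(ones, matrix(rnorm(k1 * (k1 - 1)), k1))
    if (abs(det(N1)) < 0.1) next
    A1 <- N1 %*% D1 %*% solve(N1)
    if (min(A1) >= 0.02 && is_markov_matrix(A1, tol = 1e-10)) break
    tries <- tries + 1
    stopifnot(tries < 500)
  }
  repeat {
    N2 <- matrix(rnorm(k2 * k2), k2)
    if (abs(det(N2)) > 0.1) break
  }
  A2 <- N2 %*% real_canonical(lower_ev) %*% solve(N2)
  # shrink the lower block until the assembled matrix is Markov; scaling by
  # s > 0 keeps the real/complex character and positivity of its spectrum
  s <- 1
  repeat {
    M <- inverse_block_transform(A1, s * A2, n)
    if (isTRUE(attr(M, "is_markov"))) break
    s <- s * 0.7
    stopifnot(s > 1e-4)
  }
  M
}
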