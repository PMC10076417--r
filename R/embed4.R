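# The 4x4 (strand symmetric) machinery: closed-form model parameters,
# discriminant, eigenvalue labels, the explicit real-logarithm family, the
# embeddability criterion with an exact integer branch interval, generator
# enumeration, and the Kimura 3-parameter specialization.

#' Closed-form spectral parameters of a 4x4 CS Markov matrix
#'
#' For a strand-symmetric matrix `M = (m_ij)` the Fourier conjugation
#' `S^{-1} M S` is block diagonal with an upper Markov block parameterized by
#' `lambda = m11 + m14`, `mu = m22 + m23` and a lower block
#' `rbind(c(alpha, alpha'), c(beta', beta))` with `alpha = m22 - m23`,
#' `alpha' = m21 - m24`, `beta = m11 - m14`, `beta' = m12 - m13`. The
#' discriminant of the lower block, `Delta = (alpha - beta)^2 +
#' 4 alpha' beta'`, decides whether the non-unit eigenvalues
#' `lambda2, lambda3 = ((alpha + beta) +- sqrt(Delta)) / 2` are real
#' (`Delta > 0`) or a conjugate pair (`Delta < 0`); the remaining eigenvalue
#' is `lambda1 = lambda + mu - 1`.
#'
#' @param M A 4x4 centrosymmetric Markov matrix.
#' @param tol Structural tolerance for the CS/Markov validation.
#' @return A list of class `spectrum4` with fields `lam`, `mu`, `alpha`,
#'   `alpha_p`, `beta`, `beta_p`, `Delta` and `eigenvalues`
#'   (`c(1, lambda1, lambda2, lambda3)`, complex when `Delta < 0`).
#' @examples
#' spectrum4(k3p_matrix(0.65, 0.2, 0.1, 0.05))
#' @export
spectrum4 <- function(M, tol = tol_float) {
  M <- check_cs_markov(M, tol = tol, what = "M")
  if (nrow(M) != 4L) stop("spectrum4 expects a 4x4 matrix")
  lam <- M[1, 1] + M[1, 4]
  mu <- M[2, 2] + M[2, 3]
  alpha <- M[2, 2] - M[2, 3]
  alpha_p <- M[2, 1] - M[2, 4]
  beta <- M[1, 1] - M[1, 4]
  beta_p <- M[1, 2] - M[1, 3]
  Delta <- (alpha - beta)^2 + 4 * alpha_p * beta_p
  sqrtD <- sqrt(as.complex(Delta))
  ev <- c(1, lam + mu - 1,
          ((alpha + beta) + sqrtD) / 2,
          ((alpha + beta) - sqrtD) / 2)
  if (Delta >= 0) ev <- Re(ev)
  structure(list(lam = lam, mu = mu, alpha = alpha, alpha_p = alpha_p,
                 beta = beta, beta_p = beta_p, Delta = Delta,
                 eigenvalues = ev),
            class = "spectrum4")
}

# closed-form logarithm block coefficients at branch k. Returns NULL with an
# attribute "reason" when no real logarithm exists in this family.
log4_coefficients <- function(sp, k) {
  lam1 <- sp$lam + sp$mu - 1
  if (lam1 <= 0) return(NULL)
  x <- log(lam1)
  den <- 2 - sp$lam - sp$mu
  alpha1 <- (1 - sp$lam) * x / den
  beta1 <- (1 - sp$mu) * x / den
  ab <- sp$alpha + sp$beta
  if (sp$Delta > 0) {
    sD <- sqrt(sp$Delta)
    lam3 <- (ab - sD) / 2
    if (lam3 <= 0) return(NULL)
    if (k != 0L) stop("for Delta > 0 the only real branch is k = 0")
    y <- log((ab + sD) / 2)
    z <- log(lam3)
    w <- (y - z) / sD
    s <- y + z
  } else {
    sD <- sqrt(-sp$Delta)
    # lambda2 = (ab + 1i*sD)/2, the positive-imaginary member
    s <- log((ab^2 - sp$Delta) / 4)          # log|lambda2|^2 = Re(y + z)
    theta <- atan2(sD / 2, ab / 2)           # Arg(lambda2)
    w <- (2 * theta + 4 * pi * k) / sD       # (y_k - z_k) / sqrt(Delta)
  }
  t <- sp$alpha - sp$beta
  list(x = x, alpha1 = alpha1, beta1 = beta1, k = as.integer(k),
       delta = (s + t * w) / 2,
       eps = sp$alpha_p * w,
       phi = sp$beta_p * w,
       gamma = (s - t * w) / 2)
}

# assemble the CS logarithm from the closed-form coefficients
log4_assemble <- function(co) {
  q11 <- (co$alpha1 + co$gamma) / 2
  q12 <- (-co$alpha1 + co$phi) / 2
  q13 <- (-co$alpha1 - co$phi) / 2
  q14 <- (co$alpha1 - co$gamma) / 2
  q21 <- (-co$beta1 + co$eps) / 2
  q22 <- (co$beta1 + co$delta) / 2
  q23 <- (co$beta1 - co$delta) / 2
  q24 <- (-co$beta1 - co$eps) / 2
  matrix(c(q11, q12, q13, q14,
           q21, q22, q23, q24,
           q24, q23, q22, q21,
           q14, q13, q12, q11), 4, 4, byrow = TRUE)
}

#' Closed-form real logarithm of a 4x4 CS Markov matrix at branch k
#'
#' Assembles the real logarithm of `M` on branch `k` of the conjugate
#' eigenvalue pair directly from the entries of `M` (no eigen-solver). For
#' `Delta > 0` the only real branch is `k = 0`; for `Delta < 0` every integer
#' `k` gives one real logarithm, and consecutive branches differ by a constant
#' shift matrix. Every real logarithm of a CS Markov matrix is itself CS.
#'
#' @param M A 4x4 centrosymmetric Markov matrix with distinct eigenvalues.
#' @param k Integer branch index (must be 0 when `Delta > 0`).
#' @param tol Structural tolerance.
#' @return A `candidate_log` (see [real_log_family()]).
#' @export
candidate_log4 <- function(M, k = 0L, tol = tol_float) {
  sp <- spectrum4(M, tol = tol)
  if (abs(sp$Delta) <= 1e-12) {
    stop("inconclusive: discriminant Delta = ", format(sp$Delta),
         " is numerically zero (repeated eigenvalue or Jordan block)")
  }
  co <- log4_coefficients(sp, k)
  if (is.null(co)) {
    stop("no real logarithm: requires lambda1 > 0 and, for Delta > 0, ",
         "lambda3 > 0 (got eigenvalues ",
         paste(format(sp$eigenvalues, digits = 4), collapse = ", "), ")")
  }
  Q <- log4_assemble(co)
  structure(list(matrix = Q, branch_indices = as.integer(k),
                 is_rate = is_rate_matrix(Q, tol = tol_float),
                 residual = max(abs(mat_exp(Q) - M))),
            class = "candidate_log")
}

# Real feasible interval [wlo, whi] for the branch variable
# w(k) = (y_k - z_k)/sqrt(Delta) under the four rate inequalities
# (Delta < 0 case; all four are affine in w). alpha' beta' < 0 when
# Delta < 0, so the |.| constraints always bound w and the interval is finite.
k_interval4 <- function(sp, co0) {
  wlo <- -Inf; whi <- Inf; ok <- TRUE
  # |beta' w| <= -alpha1
  if (sp$beta_p != 0) {
    a <- -co0$alpha1 / abs(sp$beta_p)
    wlo <- max(wlo, -a); whi <- min(whi, a)
  }
  # |alpha' w| <= -beta1
  if (sp$alpha_p != 0) {
    a <- -co0$beta1 / abs(sp$alpha_p)
    wlo <- max(wlo, -a); whi <- min(whi, a)
  }
  ab <- sp$alpha + sp$beta
  s <- log((ab^2 - sp$Delta) / 4)
  t <- sp$alpha - sp$beta
  # gamma(k) <= alpha1  <=>  t*w >= s - 2*alpha1
  rhs <- s - 2 * co0$alpha1
  if (t > 0) wlo <- max(wlo, rhs / t)
  else if (t < 0) whi <- min(whi, rhs / t)
  else if (rhs > 0) ok <- FALSE
  # delta(k) <= beta1  <=>  t*w <= 2*beta1 - s
  rhs <- 2 * co0$beta1 - s
  if (t > 0) whi <- min(whi, rhs / t)
  else if (t < 0) wlo <- max(wlo, rhs / t)
  else if (rhs < 0) ok <- FALSE
  list(wlo = wlo, whi = whi, feasible = ok && wlo <= whi)
}

#' Embeddability of a 4x4 centrosymmetric Markov matrix
#'
#' Decides whether `M` is the exponential of a rate matrix. With distinct
#' eigenvalues the criterion is fully explicit: `lambda1 > 0`,
#' `(alpha + beta)^2 > Delta`, and for `k = 0` (`Delta > 0`) or some integer
#' `k` (`Delta < 0`) the four inequalities `|phi(k)| <= -alpha1`,
#' `|eps(k)| <= -beta1`, `gamma(k) <= alpha1`, `delta(k) <= beta1`. For
#' `Delta < 0` the coefficients are affine in `k`, so the feasible branch set
#' is computed exactly as an integer interval — no scan bound is needed.
#' Boundary cases (a comparison within `1e-10` of equality, i.e. a zero rate
#' entry) are reported as `"inconclusive_boundary"` rather than decided.
#'
#' @param M A 4x4 centrosymmetric Markov matrix.
#' @param tol Structural tolerance.
#' @return An object of class `embeddability_report`: a list with `status`
#'   (`"embeddable"`, `"not_embeddable"`, `"inconclusive"`, or
#'   `"inconclusive_boundary"`), `n`, `delta_sign`, `k_interval`, `generators`
#'   (each with `k`, `matrix`, `residual`), and `diagnostics` (the quick-reject
#'   necessary conditions and the eigenvalues).
#' @examples
#' is_embeddable4(k3p_matrix(0.65, 0.2, 0.1, 0.05))
#' @export
is_embeddable4 <- function(M, tol = tol_float) {
  M <- check_cs_markov(M, tol = tol, what = "M")
  if (nrow(M) != 4L) stop("is_embeddable4 expects a 4x4 matrix")
  band <- 1e-10
  if (max(abs(M - diag(4))) <= 1e-13) {
    # exact identity: embeddable with the zero generator, ahead of the
    # repeated-eigenvalue guard
    return(structure(list(status = "embeddable", n = 4L, delta_sign = 0,
                          k_interval = NULL,
                          generators = list(list(k = 0L,
                                                 matrix = matrix(0, 4, 4),
                                                 residual = 0)),
                          reason = NULL,
                          diagnostics = list(eigenvalues = rep(1, 4))),
                     class = "embeddability_report"))
  }
  sp <- spectrum4(M, tol = tol)
  diag_info <- list(
    necessary_trace = sp$lam + sp$mu > 1,
    necessary_det = sp$alpha * sp$beta > sp$alpha_p * sp$beta_p,
    eigenvalues = sp$eigenvalues)
  rep0 <- function(status, k_interval = NULL, generators = list(),
                   reason = NULL) {
    structure(list(status = status, n = 4L,
                   delta_sign = sign(sp$Delta),
                   k_interval = k_interval, generators = generators,
                   reason = reason, diagnostics = diag_info),
              class = "embeddability_report")
  }

  if (abs(sp$Delta) <= 1e-12) {
    return(rep0("inconclusive",
                reason = "discriminant numerically zero (repeated eigenvalue or Jordan block)"))
  }
  ev <- sp$eigenvalues
  seps <- outer(ev, ev, function(a, b) Mod(a - b))
  if (min(seps[upper.tri(seps)]) <= 1e-8) {
    return(rep0("inconclusive", reason = "repeated eigenvalues"))
  }
  lam1 <- Re(ev[2])
  if (lam1 <= band) {
    if (lam1 >= -band) return(rep0("inconclusive_boundary",
                                   reason = "lambda1 at zero"))
    return(rep0("not_embeddable", reason = "lambda1 <= 0"))
  }

  classify_candidate <- function(k) {
    co <- log4_coefficients(sp, k)
    Q <- log4_assemble(co)
    m <- min(Q[row(Q) != col(Q)])
    list(k = as.integer(k), matrix = Q, offmin = m,
         residual = max(abs(mat_exp(Q) - M)))
  }

  if (sp$Delta > 0) {
    lam3 <- Re(ev[4])
    if (lam3 <= band) {
      if (lam3 >= -band) return(rep0("inconclusive_boundary",
                                     reason = "lambda3 at zero"))
      return(rep0("not_embeddable",
                  reason = "lambda3 <= 0 (no real logarithm)"))
    }
    cand <- classify_candidate(0L)
    if (cand$offmin > band) {
      return(rep0("embeddable", k_interval = c(0L, 0L),
                  generators = list(cand[c("k", "matrix", "residual")])))
    }
    if (cand$offmin >= -band) {
      return(rep0("inconclusive_boundary", k_interval = c(0L, 0L),
                  reason = "principal log has a rate entry at zero"))
    }
    return(rep0("not_embeddable",
                reason = "principal logarithm is not a rate matrix"))
  }

  # Delta < 0: exact integer interval for the branch index
  co0 <- log4_coefficients(sp, 0L)
  ki <- k_interval4(sp, co0)
  if (!ki$feasible) {
    return(rep0("not_embeddable",
                reason = "empty feasible interval for the branch index"))
  }
  sD <- sqrt(-sp$Delta)
  theta <- atan2(sD / 2, (sp$alpha + sp$beta) / 2)
  klo <- (ki$wlo * sD - 2 * theta) / (4 * pi)
  khi <- (ki$whi * sD - 2 * theta) / (4 * pi)
  ks <- seq.int(floor(klo) - 1L, ceiling(khi) + 1L)
  cands <- lapply(ks, classify_candidate)
  offs <- vapply(cands, `[[`, numeric(1), "offmin")
  gen_idx <- which(offs > band)
  bdry_idx <- which(offs >= -band & offs <= band)
  if (length(gen_idx) > 0) {
    gens <- lapply(cands[gen_idx], `[`, c("k", "matrix", "residual"))
    kk <- vapply(gens, `[[`, integer(1), "k")
    return(rep0("embeddable", k_interval = range(kk), generators = gens))
  }
  if (length(bdry_idx) > 0) {
    return(rep0("inconclusive_boundary",
                reason = "rate inequalities active at the boundary"))
  }
  rep0("not_embeddable",
       reason = "no integer branch satisfies the rate inequalities")
}

#' Enumerate all Markov generators of a 4x4 CS Markov matrix
#'
#' Returns every rate matrix `Q` with `exp(Q) = M`. With distinct real
#' eigenvalues there is at most one (the principal logarithm); with a complex
#' conjugate pair there is one generator per integer in the feasible branch
#' interval, and matrices with two or more generators have non-identifiable
#' substitution rates. All generators of a CS Markov matrix are CS.
#'
#' @param M A 4x4 centrosymmetric Markov matrix.
#' @param tol Structural tolerance.
#' @return A list of class `generator_set` with `generators` (list of
#'   matrices), `k_values`, `count`, and the underlying `report`.
#' @export
markov_generators4 <- function(M, tol = tol_float) {
  rep <- is_embeddable4(M, tol = tol)
  gens <- lapply(rep$generators, `[[`, "matrix")
  structure(list(generators = gens,
                 k_values = vapply(rep$generators, `[[`, integer(1), "k"),
                 count = length(gens),
                 report = rep),
            class = "generator_set")
}

#' K3P embeddability criterion
#'
#' For a Kimura 3-parameter matrix with eigenvalues
#' `p = m11 + m12 - m13 - m14`, `q = m11 - m12 + m13 - m14`,
#' `r = m11 - m12 - m13 + m14`, embeddability reduces to the inequalities
#' `r > 0`, `p q > 0`, `|log(q/p)| <= -log(r)` and `log(p q) <= log(r)`.
#' Agrees with the general 4x4 criterion on K3P matrices with distinct
#' eigenvalues.
#'
#' @param M A 4x4 K3P Markov matrix (`m11 = m22`, `m12 = m21`, `m13 = m24`,
#'   `m14 = m23`).
#' @param tol Structural tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
k3p_embeddable <- function(M, tol = tol_float) {
  M <- check_cs_markov(M, tol = tol, what = "M")
  if (nrow(M) != 4L) stop("k3p_embeddable expects a 4x4 matrix")
  K <- k3p_matrix(M[1, 1], M[1, 2], M[1, 3], M[1, 4])
  if (max(abs(M - K)) > tol) {
    stop("matrix does not have the K3P symmetry pattern")
  }
  p <- M[1, 1] + M[1, 2] - M[1, 3] - M[1, 4]
  q <- M[1, 1] - M[1, 2] + M[1, 3] - M[1, 4]
  r <- M[1, 1] - M[1, 2] - M[1, 3] + M[1, 4]
  # p*q > 0 is stated jointly with log(p), log(q) terms, so both eigenvalues
  # must individually be positive (with distinct eigenvalues a negative pair
  # admits no real logarithm)
  if (r <= 0 || p <= 0 || q <= 0) return(FALSE)
  if (p == 1 && q == 1 && r == 1) return(TRUE)  # identity boundary
  abs(log(q / p)) <= -log(r) && log(p * q) <= log(r)
}

#' @export
print.embeddability_report <- function(x, ...) {
  cat("Embeddability report (n = ", x$n, ")\n", sep = "")
  cat("  status:", x$status, "\n")
  if (!is.null(x$case_id)) cat("  case:", x$case_id, "\n")
  if (!is.null(x$delta_sign)) cat("  sign(Delta):", x$delta_sign, "\n")
  if (!is.null(x$k_interval)) {
    cat("  feasible branch interval: [", x$k_interval[1], ", ",
        x$k_interval[2], "]\n", sep = "")
  }
  cat("  generators:", length(x$generators), "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' @export
print.generator_set <- function(x, ...) {
  cat("Markov generator set: ", x$count, " generator(s)",
      if (x$count) paste0(" (k = ", paste(x$k_values, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.spectrum4 <- function(x, ...) {
  cat("4x4 CS spectrum: lambda =", format(x$lam), " mu =", format(x$mu), "\n")
  cat("  alpha =", format(x$alpha), " alpha' =", format(x$alpha_p),
      " beta =", format(x$beta), " beta' =", format(x$beta_p), "\n")
  cat("  Delta =", format(x$Delta), "\n")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 6),
                              collapse = ", "), "\n")
  invisible(x)
}
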