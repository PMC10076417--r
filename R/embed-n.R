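# Embeddability beyond 4x4: the 2x2 determinant criterion, the 3x3 Markov
# two-branch criterion, the four-case analysis for 5x5 and 6x6
# centrosymmetric matrices (driven by which Fourier block carries a conjugate
# eigenvalue pair), the exact integer branch interval of the shift-matrix
# family, and generic-n necessary/structural conditions.

new_report <- function(n, status, ..., class_extra = NULL) {
  structure(c(list(status = status, n = as.integer(n)), list(...)),
            class = "embeddability_report")
}

#' Embeddability of a 2x2 Markov matrix
#'
#' A 2x2 Markov matrix is embeddable exactly when its determinant is positive
#' (equivalently its trace exceeds 1); the unique generator is the principal
#' logarithm `log(det(M)) / (det(M) - 1) * (M - I)`.
#'
#' @param M A 2x2 Markov matrix.
#' @param tol Structural tolerance.
#' @return An `embeddability_report`.
#' @export
is_embeddable2 <- function(M, tol = tol_float) {
  M <- check_square(M)
  if (nrow(M) != 2L) stop("is_embeddable2 expects a 2x2 matrix")
  if (!is_markov_matrix(M, tol = tol)) stop("M must be a Markov matrix")
  d <- M[1, 1] + M[2, 2] - 1  # det of a 2x2 Markov matrix
  band <- 1e-12
  if (d <= band) {
    status <- if (d >= -band) "inconclusive_boundary" else "not_embeddable"
    return(new_report(2L, status, determinant = d,
                      k_interval = NULL, generators = list()))
  }
  Q <- if (abs(d - 1) <= 1e-14) {
    matrix(0, 2, 2)
  } else {
    log(d) / (d - 1) * (M - diag(2))
  }
  new_report(2L, "embeddable", determinant = d, k_interval = c(0L, 0L),
             generators = list(list(k = 0L, matrix = Q,
                                    residual = max(abs(mat_exp(Q) - M)))))
}

# classify one real logarithm candidate by its minimal off-diagonal entry
classify_rate <- function(Q, M, k, verify = TRUE) {
  list(k = k, matrix = Q, offmin = min(Q[row(Q) != col(Q)]),
       residual = if (verify) max(abs(mat_exp(Q) - M)) else NA_real_)
}

#' Embeddability of a 3x3 Markov matrix with distinct eigenvalues
#'
#' With distinct positive real eigenvalues the only real logarithm is the
#' principal one, so `A` is embeddable iff `Log(A)` is a rate matrix. With a
#' conjugate eigenvalue pair, only the branches 0 and -1 of the pair can give
#' a rate matrix, so `A` is embeddable iff `Log(A)` or `Log_{-1}(A)` is a rate
#' matrix.
#'
#' @param A A 3x3 Markov matrix with distinct eigenvalues and at most one
#'   conjugate pair.
#' @param tol Structural tolerance.
#' @return An `embeddability_report`.
#' @export
is_embeddable3_markov <- function(A, tol = tol_float) {
  A <- check_square(A)
  if (nrow(A) != 3L) stop("is_embeddable3_markov expects a 3x3 matrix")
  if (!is_markov_matrix(A, tol = tol)) stop("A must be a Markov matrix")
  if (max(abs(A - diag(3))) <= 1e-13) {
    return(new_report(3L, "embeddable",
                      generators = list(list(k = 0L, matrix = matrix(0, 3, 3),
                                             residual = 0))))
  }
  dec <- spectral_decomposition(A, markov = TRUE)
  if (!dec$distinct) {
    return(new_report(3L, "inconclusive", reason = "repeated eigenvalues",
                      generators = list()))
  }
  band <- 1e-10
  vals <- dec$values
  if (any(Mod(vals) <= 1e-10)) {
    return(new_report(3L, "not_embeddable", reason = "singular matrix",
                      generators = list()))
  }
  real_rest <- Re(vals[dec$real_idx])
  if (any(real_rest < 0)) {
    return(new_report(3L, "not_embeddable",
                      reason = "simple negative real eigenvalue",
                      generators = list()))
  }
  branches <- if (length(dec$pairs) == 0L) list(integer(0)) else list(0L, -1L)
  cands <- lapply(branches, function(k) {
    cl <- real_log_family(A, k, decomposition = dec)
    classify_rate(cl$matrix, A, if (length(k)) k else 0L)
  })
  offs <- vapply(cands, `[[`, numeric(1), "offmin")
  gen_idx <- which(offs > band)
  if (length(gen_idx) > 0) {
    return(new_report(3L, "embeddable",
                      generators = lapply(cands[gen_idx], `[`,
                                          c("k", "matrix", "residual"))))
  }
  if (any(offs >= -band)) {
    return(new_report(3L, "inconclusive_boundary",
                      reason = "rate inequality active at the boundary",
                      generators = list()))
  }
  new_report(3L, "not_embeddable",
             reason = "neither the principal nor the -1 branch is a rate matrix",
             generators = list())
}

# combined, ordered spectral data of the two Fourier blocks
cs_block_spectra <- function(A, tol = tol_float) {
  bp <- block_transform(A, tol = tol)
  d1 <- spectral_decomposition(bp$upper, markov = TRUE)
  d2 <- spectral_decomposition(bp$lower, markov = FALSE)
  n <- bp$n
  k <- ceiling(n / 2)
  vals <- c(d1$values, d2$values)
  seps <- outer(vals, vals, function(a, b) Mod(a - b))
  sep_min <- min(seps[upper.tri(seps)])
  S <- fourier_matrix(n)$S
  N <- matrix(0i, n, n)
  N[seq_len(k), seq_len(k)] <- d1$vectors
  N[(k + 1L):n, (k + 1L):n] <- d2$vectors
  P <- S %*% N
  list(bp = bp, d1 = d1, d2 = d2, n = n, k = k, values = vals,
       P = P, Pinv = solve(P), sep_min = sep_min,
       upper_pair = if (length(d1$pairs)) d1$pairs[[1]] else NULL,
       lower_pair = if (length(d2$pairs)) d2$pairs[[1]] + k else NULL)
}

# real logarithm of A with branch k1 on the upper-block pair (if any) and
# k2 on the lower-block pair (if any)
cs_candidate_log <- function(sp, k1 = 0L, k2 = 0L) {
  logs <- complex(sp$n)
  for (i in seq_along(sp$values)) {
    v <- sp$values[i]
    if (abs(Im(v)) == 0) {
      logs[i] <- if (i == 1L) 0 else log(Re(v))
    }
  }
  if (!is.null(sp$upper_pair)) {
    p <- sp$upper_pair
    lk <- branch_log_scalar(sp$values[p[1]], k1)
    logs[p[1]] <- lk; logs[p[2]] <- Conj(lk)
  }
  if (!is.null(sp$lower_pair)) {
    p <- sp$lower_pair
    lk <- branch_log_scalar(sp$values[p[1]], k2)
    logs[p[1]] <- lk; logs[p[2]] <- Conj(lk)
  }
  Q <- sp$P %*% diag(logs, sp$n) %*% sp$Pinv
  imag <- max(abs(Im(Q)))
  if (imag > 1e-8 * max(1, max(abs(Re(Q))))) {
    stop("internal error: candidate log has imaginary residual ", format(imag))
  }
  Re(Q)
}

# shift matrix on the lower-block pair
cs_shift_matrix <- function(sp) {
  d <- complex(sp$n)
  p <- sp$lower_pair
  d[p[1]] <- 2i * pi
  d[p[2]] <- -2i * pi
  Re(sp$P %*% diag(d, sp$n) %*% sp$Pinv)
}

#' Classify a 5x5 or 6x6 CS Markov matrix into the embeddability cases
#'
#' The case analysis is driven by which Fourier block carries a complex
#' conjugate eigenvalue pair: `case1` — all eigenvalues real; `case2` — pair
#' in the lower block `A2` only; `case3` — pair in the upper (Markov) block
#' `A1` only; `case4` — pairs in both. Matrices with a zero eigenvalue or a
#' simple negative real eigenvalue admit no real logarithm and are
#' `not_embeddable`; repeated eigenvalues are `inconclusive`.
#'
#' @param A A 6x6 (or 5x5) centrosymmetric Markov matrix with distinct
#'   eigenvalues.
#' @param tol Structural tolerance.
#' @return A list of class `case_label` with `case_id`, `upper_complex`,
#'   `lower_complex`.
#' @export
classify_case6 <- function(A, tol = tol_float) {
  A <- check_cs_markov(A, tol = tol, what = "A")
  n <- nrow(A)
  if (!n %in% c(5L, 6L)) stop("case classification covers n = 5 and 6")
  sp <- cs_block_spectra(A, tol = tol)
  label <- function(case_id) {
    structure(list(case_id = case_id,
                   upper_complex = !is.null(sp$upper_pair),
                   lower_complex = !is.null(sp$lower_pair)),
              class = "case_label")
  }
  if (sp$sep_min <= 1e-8) return(label("inconclusive"))
  if (any(Mod(sp$values) <= 1e-10)) return(label("not_embeddable"))
  reals <- sp$values[abs(Im(sp$values)) == 0]
  if (any(Re(reals) < 0)) return(label("not_embeddable"))
  up <- !is.null(sp$upper_pair); lo <- !is.null(sp$lower_pair)
  label(if (!up && !lo) "case1" else if (!up && lo) "case2"
        else if (up && !lo) "case3" else "case4")
}

#' Integer feasibility interval of the affine logarithm family
#'
#' For the family `base_log + k * V` (all real logarithms sharing every
#' branch except the one shifted by `V`), the off-diagonal non-negativity
#' constraints are affine in `k`: entries with `V[i,j] > 0` give lower bounds
#' `k >= -base_log[i,j] / V[i,j]`, entries with `V[i,j] < 0` give upper
#' bounds, and entries with `V[i,j] = 0` must already be non-negative (the
#' blocking set `N`). The family contains a rate matrix iff `N` is empty and
#' `L <= U`.
#'
#' @param base_log Real logarithm at branch 0 of the targeted pair.
#' @param V The branch shift matrix of the pair.
#' @param tol Tolerance deciding when an entry of `V` counts as zero.
#' @return A list of class `k_feasibility` with integer bounds `L`, `U`
#'   (`-Inf`/`Inf` encode absent constraints) and `N`, a matrix of blocking
#'   index pairs (zero rows when empty).
#' @export
feasible_branch_interval <- function(base_log, V, tol = 1e-9) {
  base_log <- check_square(base_log)
  V <- check_square(V)
  stopifnot(nrow(base_log) == nrow(V))
  off <- row(V) != col(V)
  vz <- abs(V) <= tol * max(1, max(abs(V)))
  ratio <- -base_log / V
  lower_set <- off & !vz & V > 0
  upper_set <- off & !vz & V < 0
  L <- if (any(lower_set)) max(ceiling(ratio[lower_set] - 1e-9)) else -Inf
  U <- if (any(upper_set)) min(floor(ratio[upper_set] + 1e-9)) else Inf
  blocked <- off & vz & base_log < -1e-10
  N <- which(blocked, arr.ind = TRUE)
  structure(list(L = L, U = U, N = N), class = "k_feasibility")
}

#' Embeddability of 5x5 and 6x6 centrosymmetric Markov matrices
#'
#' Dispatches on [classify_case6()]: with an all-real spectrum the matrix is
#' embeddable iff its principal logarithm is a rate matrix; a conjugate pair
#' in the lower Fourier block contributes an exact integer interval of
#' branches via [feasible_branch_interval()]; a pair in the upper (Markov)
#' block contributes the two branches 0 and -1; with pairs in both blocks the
#' two mechanisms combine. Every returned generator is verified by its
#' exponential residual. The identity matrix is handled as an exact special
#' case (generator 0) ahead of the distinct-eigenvalue guard.
#'
#' @param A A 5x5 or 6x6 centrosymmetric Markov matrix.
#' @param tol Structural tolerance.
#' @param verify Verify each generator's exponential residual (disable only
#'   in bulk Monte Carlo runs, where the verdict alone is needed).
#' @return An `embeddability_report` with fields `case_id`, `upper_branch`,
#'   `k_interval` and `generators` (each with `k = c(upper, lower)` branch
#'   indices).
#' @export
is_embeddable_large <- function(A, tol = tol_float, verify = TRUE) {
  A <- check_cs_markov(A, tol = tol, what = "A")
  n <- nrow(A)
  if (!n %in% c(5L, 6L)) stop("is_embeddable_large covers n = 5 and 6")
  band <- 1e-10
  if (max(abs(A - diag(n))) <= 1e-13) {
    return(new_report(n, "embeddable", case_id = "identity",
                      k_interval = NULL,
                      generators = list(list(k = c(0L, 0L),
                                             matrix = matrix(0, n, n),
                                             residual = 0))))
  }
  sp <- cs_block_spectra(A, tol = tol)
  diag_info <- list(eigenvalues = sp$values,
                    trace_condition = trace_necessary(A)$value)
  if (sp$sep_min <= 1e-8) {
    return(new_report(n, "inconclusive", reason = "repeated eigenvalues",
                      generators = list(), diagnostics = diag_info))
  }
  if (any(Mod(sp$values) <= 1e-10)) {
    return(new_report(n, "not_embeddable", reason = "singular matrix",
                      generators = list(), diagnostics = diag_info))
  }
  reals <- sp$values[abs(Im(sp$values)) == 0]
  if (any(Re(reals) < 0)) {
    return(new_report(n, "not_embeddable",
                      reason = "simple negative real eigenvalue",
                      generators = list(), diagnostics = diag_info))
  }
  up <- !is.null(sp$upper_pair); lo <- !is.null(sp$lower_pair)
  case_id <- if (!up && !lo) "case1" else if (!up && lo) "case2"
             else if (up && !lo) "case3" else "case4"

  upper_branches <- if (up) c(0L, -1L) else 0L
  cands <- list()
  for (k1 in upper_branches) {
    base <- cs_candidate_log(sp, k1 = k1, k2 = 0L)
    if (lo) {
      V <- cs_shift_matrix(sp)
      ki <- feasible_branch_interval(base, V)
      if (nrow(ki$N) > 0) {
        worst <- min(base[ki$N])
        if (worst < -band) next  # blocked entries V cannot fix
      }
      if (ki$L > ki$U) {
        # examine the integers adjacent to the empty interval for boundary
        ks <- unique(c(max(ki$L - 1, -64), min(ki$U + 1, 64)))
      } else {
        ks <- seq.int(max(ki$L, -64) - 1L, min(ki$U, 64) + 1L)
      }
      for (k2 in ks) {
        cands[[length(cands) + 1L]] <-
          classify_rate(base + k2 * V, A, c(k1, as.integer(k2)),
                        verify = verify)
      }
    } else {
      cands[[length(cands) + 1L]] <- classify_rate(base, A, c(k1, 0L),
                                                   verify = verify)
    }
  }
  if (length(cands) == 0L) {
    return(new_report(n, "not_embeddable", case_id = case_id,
                      reason = "blocking entries outside the shifted pair",
                      generators = list(), diagnostics = diag_info))
  }
  offs <- vapply(cands, `[[`, numeric(1), "offmin")
  gen_idx <- which(offs > band)
  if (length(gen_idx) > 0) {
    gens <- lapply(cands[gen_idx], `[`, c("k", "matrix", "residual"))
    k2s <- vapply(gens, function(g) g$k[2], numeric(1))
    k1s <- vapply(gens, function(g) g$k[1], numeric(1))
    return(new_report(n, "embeddable", case_id = case_id,
                      upper_branch = sort(unique(k1s)),
                      k_interval = if (lo) range(k2s) else NULL,
                      generators = gens, diagnostics = diag_info))
  }
  if (any(offs >= -band)) {
    return(new_report(n, "inconclusive_boundary", case_id = case_id,
                      reason = "rate inequality active at the boundary",
                      generators = list(), diagnostics = diag_info))
  }
  new_report(n, "not_embeddable", case_id = case_id,
             reason = "no branch combination yields a rate matrix",
             generators = list(), diagnostics = diag_info)
}

#' Trace necessary condition for embeddability
#'
#' The trace of the upper Fourier block of a CS matrix equals
#' `sum_{j <= n/2} (a[j,j] + a[j, n-j+1])` (plus the central diagonal entry
#' once for odd `n`). For an embeddable CS Markov matrix with distinct
#' eigenvalues this sum must exceed 1 (the upper block is the exponential of
#' a rate matrix, so its trace is a sum of `exp` terms including
#' `exp(0) = 1`). Necessary but not sufficient; used as a fast pre-filter
#' and as the trace-region predicate in the volume computations.
#'
#' @param A A centrosymmetric Markov matrix of any order `n >= 2`.
#' @param tol Structural tolerance.
#' @return A list of class `trace_condition` with `value` and `passes`.
#' @export
trace_necessary <- function(A, tol = tol_float) {
  A <- check_square(A)
  n <- nrow(A)
  k <- n %/% 2L
  j <- seq_len(k)
  value <- sum(A[cbind(j, j)]) + sum(A[cbind(j, n + 1L - j)])
  if (n %% 2L == 1L) value <- value + A[k + 1L, k + 1L]
  structure(list(value = value, passes = value > 1),
            class = "trace_condition")
}

#' Existence of a centrosymmetric logarithm
#'
#' A CS matrix has a CS logarithm iff both of its Fourier blocks admit a
#' logarithm, which for real blocks holds exactly when they are invertible;
#' an invertible CS matrix in fact has infinitely many CS logarithms.
#'
#' @param A A centrosymmetric matrix.
#' @param tol Structural and singularity tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
cs_log_exists <- function(A, tol = tol_float) {
  bp <- block_transform(A, tol = tol)
  min_ev <- function(B) min(Mod(eigen(B, only.values = TRUE)$values))
  min_ev(bp$upper) > 1e-10 && min_ev(bp$lower) > 1e-10
}

#' @export
print.case_label <- function(x, ...) {
  cat("CS case label:", x$case_id,
      "(upper pair:", x$upper_complex, ", lower pair:", x$lower_complex, ")\n")
  invisible(x)
}

#' @export
print.trace_condition <- function(x, ...) {
  cat("Upper-block trace:", format(x$value),
      if (x$passes) "(> 1, necessary condition passes)" else
        "(<= 1, not embeddable with a CS generator)", "\n")
  invisible(x)
}
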