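# Uniform samplers over the centrosymmetric Markov polytope and its
# sub-regions (positive-spectrum, DLC, DD, trace region), the closed-form
# polytope volumes, and hit-and-miss Monte Carlo estimation with Wilson
# confidence intervals. The polytope is a Cartesian product of simplices (one
# per free row), so the default sampler is exact simplex-product sampling;
# box-rejection sampling is retained as the protocol used in the original
# volume tables and as a cross-validation oracle.

#' Closed-form volume of the CS Markov polytope
#'
#' In its free coordinates, the set of `n x n` CS Markov matrices is a
#' Cartesian product of `floor(n/2)` standard `(n-1)`-simplices (plus, for odd
#' `n`, the half-scaled simplex of the symmetric middle row), giving volume
#' `1 / (n-1)!^(n/2)` for even `n` and
#' `1 / (2^k * k! * (n-1)!^k)` with `k = floor(n/2)` for odd `n`.
#'
#' @param n Matrix order, `n >= 2`.
#' @return A list with `numerator`, `denominator` (exact integers as doubles)
#'   and `value`.
#' @examples
#' closed_form_volume(4)  # 1/36
#' @export
closed_form_volume <- function(n) {
  n <- check_order(n)
  if (n < 2L) stop("volume defined for n >= 2")
  k <- n %/% 2L
  denom <- if (n %% 2L == 0L) {
    factorial(n - 1)^k
  } else {
    2^k * factorial(k) * factorial(n - 1)^k
  }
  list(numerator = 1, denominator = denom, value = 1 / denom)
}

# ---- internal coordinate representation -----------------------------------
# A batch of CS Markov matrices is held as its free rows: `free[[i]]` is a
# count x n matrix (row i of each sample, i = 1..floor(n/2)); for odd n,
# `mid` is the count x n symmetric middle row.

sample_rows_simplex <- function(n, count) {
  k <- n %/% 2L
  free <- lapply(seq_len(k), function(i) {
    g <- matrix(stats::rexp(count * n), count, n)
    g / rowSums(g)
  })
  mid <- NULL
  if (n %% 2L == 1L) {
    g <- matrix(stats::rexp(count * (k + 1L)), count, k + 1L)
    y <- g / rowSums(g)
    x <- y[, seq_len(k), drop = FALSE] / 2
    mid <- cbind(x, y[, k + 1L], x[, k:1, drop = FALSE])
  }
  list(n = n, count = count, free = free, mid = mid)
}

# entry a[i, j] across a batch
rows_entry <- function(rows, i, j) {
  n <- rows$n
  k <- n %/% 2L
  if (i <= k) return(rows$free[[i]][, j])
  if (n %% 2L == 1L && i == k + 1L) return(rows$mid[, j])
  rows$free[[n + 1L - i]][, n + 1L - j]
}

rows_to_matrix <- function(rows, s) {
  n <- rows$n
  k <- n %/% 2L
  A <- matrix(0, n, n)
  for (i in seq_len(k)) A[i, ] <- rows$free[[i]][s, ]
  if (n %% 2L == 1L) A[k + 1L, ] <- rows$mid[s, ]
  for (i in seq_len(k)) A[n + 1L - i, ] <- A[i, n:1]
  A
}

# vectorized region membership over a batch of free rows
region_mask <- function(rows, region) {
  n <- rows$n
  k <- n %/% 2L
  switch(region,
    markov = rep(TRUE, rows$count),
    dd = {
      m <- rep(TRUE, rows$count)
      for (i in seq_len(k)) m <- m & rows$free[[i]][, i] >= 0.5
      if (n %% 2L == 1L) m <- m & rows$mid[, k + 1L] >= 0.5
      m
    },
    dlc = {
      row_max_others <- function(X, i) {
        do.call(pmax, lapply(seq_len(ncol(X))[-i], function(j) X[, j]))
      }
      m <- rep(TRUE, rows$count)
      for (i in seq_len(k)) {
        m <- m & rows$free[[i]][, i] >= row_max_others(rows$free[[i]], i)
      }
      if (n %% 2L == 1L) {
        m <- m & rows$mid[, k + 1L] >= row_max_others(rows$mid, k + 1L)
      }
      m
    },
    trace_Yn = {
      v <- rep(0, rows$count)
      for (j in seq_len(k)) {
        v <- v + rows$free[[j]][, j] + rows$free[[j]][, n + 1L - j]
      }
      if (n %% 2L == 1L) v <- v + rows$mid[, k + 1L]
      v > 1
    },
    v_plus = {
      if (n != 4L) stop("the v_plus region is defined for n = 4")
      sp <- spectrum4_rows(rows)
      sp$lam1 > 0 & sp$Delta > 0 & (sp$alpha + sp$beta) > sqrt(pmax(sp$Delta, 0))
    },
    stop("unknown region: ", region)
  )
}

# closed-form 4x4 spectral parameters over a batch
spectrum4_rows <- function(rows) {
  r1 <- rows$free[[1]]; r2 <- rows$free[[2]]
  lam <- r1[, 1] + r1[, 4]; mu <- r2[, 2] + r2[, 3]
  alpha <- r2[, 2] - r2[, 3]; alpha_p <- r2[, 1] - r2[, 4]
  beta <- r1[, 1] - r1[, 4]; beta_p <- r1[, 2] - r1[, 3]
  list(lam = lam, mu = mu, alpha = alpha, alpha_p = alpha_p,
       beta = beta, beta_p = beta_p,
       lam1 = lam + mu - 1,
       Delta = (alpha - beta)^2 + 4 * alpha_p * beta_p)
}

# Vectorized embeddability decision (the closed-form criterion) over a batch
# of 4x4 samples.
# Returns 1 (embeddable), 0 (not embeddable), NA (inconclusive: numerically
# zero discriminant or repeated eigenvalues; a measure-zero set).
embeddable4_mask <- function(rows) {
  sp <- spectrum4_rows(rows)
  count <- length(sp$lam)
  out <- integer(count)
  ab <- sp$alpha + sp$beta
  t <- sp$alpha - sp$beta
  sqD <- sqrt(abs(sp$Delta))
  lam2 <- (ab + ifelse(sp$Delta >= 0, sqD, 0)) / 2 +
    1i * ifelse(sp$Delta < 0, sqD / 2, 0)
  lam3 <- (ab - ifelse(sp$Delta >= 0, sqD, 0)) / 2 -
    1i * ifelse(sp$Delta < 0, sqD / 2, 0)
  sep <- pmin(Mod(1 - sp$lam1), Mod(1 - lam2), Mod(1 - lam3),
              Mod(sp$lam1 - lam2), Mod(sp$lam1 - lam3), Mod(lam2 - lam3))
  bad <- abs(sp$Delta) <= 1e-12 | sep <= 1e-8
  out[bad] <- NA_integer_

  live <- !bad & sp$lam1 > 0
  # Delta > 0: principal branch only, lambda3 must be positive
  pos <- live & sp$Delta > 0 & Re(lam3) > 0
  if (any(pos)) {
    x <- log(sp$lam1[pos])
    den <- 2 - sp$lam[pos] - sp$mu[pos]
    a1 <- (1 - sp$lam[pos]) * x / den
    b1 <- (1 - sp$mu[pos]) * x / den
    y <- log(Re(lam2[pos])); z <- log(Re(lam3[pos]))
    w <- (y - z) / sqD[pos]
    s <- y + z
    ok <- abs(sp$beta_p[pos] * w) <= -a1 &
      abs(sp$alpha_p[pos] * w) <= -b1 &
      (s - t[pos] * w) / 2 <= a1 &
      (s + t[pos] * w) / 2 <= b1
    out[pos][ok] <- 1L
  }
  # Delta < 0: exact integer feasibility interval for the branch index
  neg <- live & sp$Delta < 0
  if (any(neg)) {
    x <- log(sp$lam1[neg])
    den <- 2 - sp$lam[neg] - sp$mu[neg]
    a1 <- (1 - sp$lam[neg]) * x / den
    b1 <- (1 - sp$mu[neg]) * x / den
    tn <- t[neg]; abn <- ab[neg]; sqn <- sqD[neg]
    s <- log((abn^2 - sp$Delta[neg]) / 4)
    bp <- sp$beta_p[neg]; ap <- sp$alpha_p[neg]
    lim1 <- ifelse(bp != 0, -a1 / abs(bp), Inf)
    lim2 <- ifelse(ap != 0, -b1 / abs(ap), Inf)
    wlo <- pmax(-lim1, -lim2)
    whi <- pmin(lim1, lim2)
    rhs3 <- s - 2 * a1   # t*w >= rhs3
    rhs4 <- 2 * b1 - s   # t*w <= rhs4
    wlo <- ifelse(tn > 0, pmax(wlo, rhs3 / tn), wlo)
    whi <- ifelse(tn < 0, pmin(whi, rhs3 / tn), whi)
    whi <- ifelse(tn > 0, pmin(whi, rhs4 / tn), whi)
    wlo <- ifelse(tn < 0, pmax(wlo, rhs4 / tn), wlo)
    feas0 <- ifelse(tn == 0, rhs3 <= 0 & rhs4 >= 0, TRUE)
    theta <- atan2(sqn / 2, abn / 2)
    klo <- (wlo * sqn - 2 * theta) / (4 * pi)
    khi <- (whi * sqn - 2 * theta) / (4 * pi)
    ok <- feas0 & wlo <= whi & ceiling(klo - 1e-9) <= floor(khi + 1e-9)
    out[neg][ok] <- 1L
  }
  out
}

# vectorized 2x2 embeddability (determinant criterion) over uniform
# off-diagonal parameters
embeddable2_mask <- function(a, b) {
  as.integer(1 - a - b > 0)
}

# ---- public samplers -------------------------------------------------------

#' Sample uniformly from the CS Markov polytope
#'
#' `simplex_product` draws each free row uniformly on its simplex (exact, no
#' rejection); `box_rejection` draws the off-diagonal free coordinates
#' uniformly in `[0, 1]` (in `[0, 1/2]` for the middle row of odd `n`) and
#' rejects draws with a negative diagonal — the protocol of the original
#' Monte Carlo tables. Both target the same uniform law.
#'
#' @param n Matrix order.
#' @param count Number of matrices to return.
#' @param seed Integer seed.
#' @param method `"simplex_product"` or `"box_rejection"`.
#' @return A list of `count` CS Markov matrices; for `box_rejection` the
#'   attribute `acceptance` records `draws`, `accepted` and the acceptance
#'   fraction.
#' @export
sample_cs_markov <- function(n, count, seed = 1L,
                             method = c("simplex_product", "box_rejection")) {
  n <- check_order(n)
  method <- match.arg(method)
  set.seed(seed)
  if (method == "simplex_product") {
    rows <- sample_rows_simplex(n, count)
    return(lapply(seq_len(count), function(s) rows_to_matrix(rows, s)))
  }
  k <- n %/% 2L
  out <- vector("list", count)
  got <- 0L; draws <- 0L
  while (got < count) {
    batch <- max(1000L, 2L * (count - got))
    free <- lapply(seq_len(k), function(i) {
      off <- matrix(stats::runif(batch * (n - 1L)), batch, n - 1L)
      cbind(off[, seq_len(i - 1L), drop = FALSE],
            1 - rowSums(off),
            off[, seq.int(i, length.out = n - i), drop = FALSE])
    })
    keep <- rep(TRUE, batch)
    for (i in seq_len(k)) keep <- keep & free[[i]][, i] >= 0
    mid <- NULL
    if (n %% 2L == 1L) {
      x <- matrix(stats::runif(batch * k, 0, 0.5), batch, k)
      dmid <- 1 - 2 * rowSums(x)
      keep <- keep & dmid >= 0
      mid <- cbind(x, dmid, x[, k:1, drop = FALSE])
    }
    draws <- draws + batch
    idx <- which(keep)
    for (s in idx) {
      if (got >= count) break
      got <- got + 1L
      rows1 <- list(n = n, count = 1L,
                    free = lapply(free, function(f) f[s, , drop = FALSE]),
                    mid = if (is.null(mid)) NULL else mid[s, , drop = FALSE])
      out[[got]] <- rows_to_matrix(rows1, 1L)
    }
  }
  attr(out, "acceptance") <- list(draws = draws, accepted = count,
                                  fraction = count / draws)
  out
}

#' Sample uniformly from a sub-region of the CS Markov polytope
#'
#' The diagonally dominant region is sampled directly (diagonal dominance of a
#' Markov row is exactly "off-diagonal sum at most 1/2", a scaled simplex);
#' `dlc`, `v_plus` and `trace_Yn` are sampled by rejection from the full
#' polytope.
#'
#' @param region One of `"markov"`, `"dd"`, `"dlc"`, `"v_plus"`,
#'   `"trace_Yn"`.
#' @param n Matrix order.
#' @param count Number of matrices.
#' @param seed Integer seed.
#' @return A list of `count` CS Markov matrices in the region.
#' @export
sample_region <- function(region, n, count, seed = 1L) {
  n <- check_order(n)
  set.seed(seed)
  if (region == "markov") {
    rows <- sample_rows_simplex(n, count)
    return(lapply(seq_len(count), function(s) rows_to_matrix(rows, s)))
  }
  if (region == "dd") {
    rows <- sample_rows_dd(n, count)
    return(lapply(seq_len(count), function(s) rows_to_matrix(rows, s)))
  }
  out <- vector("list", count)
  got <- 0L
  while (got < count) {
    batch <- max(1000L, 4L * (count - got))
    rows <- sample_rows_simplex(n, batch)
    idx <- which(region_mask(rows, region))
    for (s in idx) {
      if (got >= count) break
      got <- got + 1L
      out[[got]] <- rows_to_matrix(rows, s)
    }
  }
  out
}

# each free row: off-diagonal vector uniform on the simplex scaled to sum
# <= 1/2, so the diagonal (= 1 - sum) is >= 1/2
sample_rows_dd <- function(n, count) {
  k <- n %/% 2L
  free <- lapply(seq_len(k), function(i) {
    g <- matrix(stats::rexp(count * n), count, n)
    y <- g / rowSums(g) / 2          # off-diagonal part, sums to <= 1/2
    d <- 1 - (rowSums(y) - y[, i])   # diagonal absorbs the rest
    y[, i] <- d
    y
  })
  mid <- NULL
  if (n %% 2L == 1L) {
    g <- matrix(stats::rexp(count * (k + 1L)), count, k + 1L)
    y <- g / rowSums(g)
    x <- y[, seq_len(k), drop = FALSE] / 4  # 2*sum(x) <= 1/2
    mid <- cbind(x, 1 - 2 * rowSums(x), x[, k:1, drop = FALSE])
  }
  list(n = n, count = count, free = free, mid = mid)
}

#' Region membership predicate
#'
#' Pure predicate deciding whether a CS Markov matrix lies in one of the
#' studied regions: `markov` (validity), `dd` (diagonally dominant), `dlc`
#' (each diagonal entry dominates the other entries of its line — the
#' identifiability-linked region whose exact relative volume is `(1/4)^2 =
#' 6.25%` at `n = 4`; ties, a measure-zero set, count as inside), `trace_Yn`
#' (the trace necessary condition), or `v_plus` (positive distinct real
#' eigenvalues with positive discriminant; `n = 4` only).
#'
#' @param A A CS Markov matrix.
#' @param region Region id.
#' @param tol Structural tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_region <- function(A, region, tol = tol_float) {
  A <- check_cs_markov(A, tol = tol, what = "A")
  n <- nrow(A)
  switch(region,
    markov = TRUE,
    dd = all(2 * diag(A) >= rowSums(A)),
    dlc = all(vapply(seq_len(n), function(i) A[i, i] >= max(A[i, -i]),
                     logical(1))),
    trace_Yn = trace_necessary(A)$value > 1,
    v_plus = {
      if (n != 4L) stop("the v_plus region is defined for n = 4")
      sp <- spectrum4(A, tol = tol)
      ev <- Re(sp$eigenvalues)
      sp$Delta > 0 && sp$lam + sp$mu - 1 > 0 && ev[4] > 0 &&
        min(abs(outer(ev, ev, "-")[upper.tri(diag(4))])) > 1e-8
    },
    stop("unknown region: ", region)
  )
}

wilson_ci <- function(hits, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- hits / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

new_volume_estimate <- function(estimate, ci, n_samples, hits, seed, region,
                                base, absolute = FALSE, inconclusive = 0L) {
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
                 n_samples = n_samples, hits = hits, seed = seed,
                 region = region, base = base, absolute = absolute,
                 inconclusive = inconclusive),
            class = "volume_estimate")
}

#' Hit-and-miss Monte Carlo volume estimation
#'
#' Samples `n_samples` matrices uniformly from `base` and reports the
#' fraction landing in `region`, with a 95% Wilson score interval (valid for
#' the very small hit counts that arise for embeddable 6x6 matrices). With
#' `absolute = TRUE` and `base = "markov"` the fraction is multiplied by the
#' closed-form polytope volume, giving an absolute Euclidean volume.
#'
#' @param region Target region id (see [evaluate_region()]).
#' @param base Base region to sample from (`"markov"` or `"dd"`).
#' @param n Matrix order.
#' @param n_samples Number of Monte Carlo samples.
#' @param seed Integer seed (identical seeds give identical hit counts).
#' @param absolute Report absolute volume instead of a fraction.
#' @return A `volume_estimate`.
#' @examples
#' hit_and_miss("dd", base = "markov", n = 4, n_samples = 1e4, seed = 1)
#' @export
hit_and_miss <- function(region, base = "markov", n = 4L, n_samples = 1e5,
                         seed = 1L, absolute = FALSE) {
  n <- check_order(n)
  set.seed(seed)
  hits <- 0L
  done <- 0L
  chunk <- 250000L
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    rows <- if (base == "markov") sample_rows_simplex(n, m)
            else if (base == "dd") sample_rows_dd(n, m)
            else stop("base region must be directly samplable: markov or dd")
    hits <- hits + sum(region_mask(rows, region))
    done <- done + m
  }
  est <- hits / n_samples
  ci <- wilson_ci(hits, n_samples)
  if (absolute) {
    v <- closed_form_volume(n)$value
    if (base != "markov") stop("absolute mode requires base = 'markov'")
    est <- est * v
    ci <- ci * v
  }
  new_volume_estimate(est, ci, n_samples, hits, seed, region, base, absolute)
}

#' Fraction of embeddable matrices in a region
#'
#' Samples uniformly from `base` at order `n` and decides embeddability of
#' each sample: the determinant criterion at `n = 2` (off-diagonal
#' parameters uniform on the unit square), the closed-form inequalities with
#' the exact integer branch interval at `n = 4`, and the four-case analysis
#' at `n = 5, 6` (accelerated by the exact trace necessary condition, which
#' filters out samples that cannot be embeddable before any eigen-solve).
#' Samples with numerically degenerate spectra (a measure-zero set) are
#' counted separately as `inconclusive`.
#'
#' @param n Matrix order, one of 2, 4, 5, 6.
#' @param base Base region (`"markov"`, `"dd"`, or for `n = 4` also `"dlc"`,
#'   `"v_plus"`).
#' @param n_samples Number of Monte Carlo samples.
#' @param seed Integer seed.
#' @return A `volume_estimate` whose `estimate` is the embeddable fraction of
#'   `base`.
#' @export
embeddable_fraction <- function(n, base = "markov", n_samples = 1e5,
                                seed = 1L) {
  n <- check_order(n)
  if (!n %in% c(2L, 4L, 5L, 6L)) {
    stop("full embeddability criteria are available for n in {2, 4, 5, 6}")
  }
  set.seed(seed)
  hits <- 0L; inc <- 0L; done <- 0L
  chunk <- 250000L
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    if (n == 2L) {
      a <- stats::runif(m); b <- stats::runif(m)
      res <- embeddable2_mask(a, b)
    } else {
      rows <- switch(base,
        markov = sample_rows_simplex(n, m),
        dd = sample_rows_dd(n, m),
        {
          if (n != 4L) stop("base ", base, " is supported at n = 4 only")
          mats <- NULL
          rws <- NULL
          got <- 0L
          free_acc <- NULL
          # rejection from the full polytope, keeping the row representation
          repeat {
            cand <- sample_rows_simplex(n, m)
            keep <- which(region_mask(cand, base))
            take <- keep[seq_len(min(length(keep), m - got))]
            sub <- list(n = n, count = length(take),
                        free = lapply(cand$free, function(f)
                          f[take, , drop = FALSE]),
                        mid = NULL)
            free_acc <- if (is.null(free_acc)) sub else
              list(n = n, count = free_acc$count + sub$count,
                   free = Map(rbind, free_acc$free, sub$free), mid = NULL)
            got <- free_acc$count
            if (got >= m) break
          }
          free_acc
        })
      if (n == 4L) {
        res <- embeddable4_mask(rows)
      } else {
        res <- embeddable_mask_large(rows)
      }
    }
    hits <- hits + sum(res == 1L, na.rm = TRUE)
    inc <- inc + sum(is.na(res))
    done <- done + m
  }
  est <- hits / n_samples
  new_volume_estimate(est, wilson_ci(hits, n_samples), n_samples, hits, seed,
                      region = "embeddable", base = base,
                      inconclusive = inc)
}

# Fourier block entries of a batch, as vectors over samples. a[i, j] is
# rows_entry(rows, i, j); the block formulas come from the even/odd block
# partition of a CS matrix (A1 = B1 + B2*J bordered by the middle row for
# odd n; A2 = J*B1*J - J*B2).
block_entries_vec <- function(rows) {
  n <- rows$n
  k <- n %/% 2L
  m1 <- ceiling(n / 2)
  A1 <- vector("list", m1 * m1); dim(A1) <- c(m1, m1)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) A1[[i, j]] <- rows$free[[i]][, j] +
        rows$free[[i]][, n + 1L - j]
  }
  if (n %% 2L == 1L) {
    for (i in seq_len(k)) A1[[i, k + 1L]] <- rows$free[[i]][, k + 1L]
    for (j in seq_len(k)) A1[[k + 1L, j]] <- 2 * rows$mid[, j]
    A1[[k + 1L, k + 1L]] <- rows$mid[, k + 1L]
  }
  A2 <- vector("list", k * k); dim(A2) <- c(k, k)
  for (i in seq_len(k)) {
    ii <- k + 1L - i
    for (j in seq_len(k)) {
      A2[[i, j]] <- rows_entry(rows, ii, k + 1L - j) -
        rows_entry(rows, ii, n - k + j)
    }
  }
  list(A1 = A1, A2 = A2)
}

# Vectorized necessary spectral conditions for embeddability at n = 5, 6:
# the upper-block trace must exceed 1, the quadratic factor of the (Markov)
# upper block must have positive-real or complex roots, and the lower-block
# characteristic polynomial must have no root on the closed negative real
# axis. TRUE = may be embeddable (needs the full case analysis), FALSE =
# certainly not, NA = numerically degenerate.
large_prefilter <- function(rows) {
  be <- block_entries_vec(rows)
  A1 <- be$A1; A2 <- be$A2
  # upper block: char poly (x - 1)(x^2 - p1 x + q1)
  tr1 <- A1[[1, 1]] + A1[[2, 2]] + A1[[3, 3]]
  det1 <- A1[[1, 1]] * (A1[[2, 2]] * A1[[3, 3]] - A1[[2, 3]] * A1[[3, 2]]) -
    A1[[1, 2]] * (A1[[2, 1]] * A1[[3, 3]] - A1[[2, 3]] * A1[[3, 1]]) +
    A1[[1, 3]] * (A1[[2, 1]] * A1[[3, 2]] - A1[[2, 2]] * A1[[3, 1]])
  p1 <- tr1 - 1
  q1 <- det1
  disc1 <- p1^2 - 4 * q1
  ok1 <- ifelse(disc1 > 0, p1 > 0 & q1 > 0, TRUE)
  na1 <- abs(disc1) <= 1e-12 | abs(q1) <= 1e-12
  if (nrow(A2) == 2L) {
    tr2 <- A2[[1, 1]] + A2[[2, 2]]
    det2 <- A2[[1, 1]] * A2[[2, 2]] - A2[[1, 2]] * A2[[2, 1]]
    disc2 <- tr2^2 - 4 * det2
    ok2 <- ifelse(disc2 > 0, tr2 > 0 & det2 > 0, TRUE)
    na2 <- abs(disc2) <= 1e-12 | abs(det2) <= 1e-12
  } else {
    # cubic x^3 - c1 x^2 + c2 x - c3: all-real roots are all positive iff
    # c1, c2, c3 > 0; with one conjugate pair the real root is positive iff
    # c3 > 0
    c1 <- A2[[1, 1]] + A2[[2, 2]] + A2[[3, 3]]
    c2 <- A2[[1, 1]] * A2[[2, 2]] - A2[[1, 2]] * A2[[2, 1]] +
      A2[[1, 1]] * A2[[3, 3]] - A2[[1, 3]] * A2[[3, 1]] +
      A2[[2, 2]] * A2[[3, 3]] - A2[[2, 3]] * A2[[3, 2]]
    c3 <- A2[[1, 1]] * (A2[[2, 2]] * A2[[3, 3]] - A2[[2, 3]] * A2[[3, 2]]) -
      A2[[1, 2]] * (A2[[2, 1]] * A2[[3, 3]] - A2[[2, 3]] * A2[[3, 1]]) +
      A2[[1, 3]] * (A2[[2, 1]] * A2[[3, 2]] - A2[[2, 2]] * A2[[3, 1]])
    disc2 <- 18 * c1 * c2 * c3 - 4 * c1^3 * c3 + c1^2 * c2^2 -
      4 * c2^3 - 27 * c3^2
    ok2 <- ifelse(disc2 > 0, c1 > 0 & c2 > 0 & c3 > 0, c3 > 0)
    na2 <- abs(disc2) <= 1e-14 | abs(c3) <= 1e-12
  }
  res <- p1 > 0 & ok1 & ok2
  res[na1 | na2] <- NA
  res
}

# decide embeddability for a batch at n = 5, 6: vectorized spectral
# pre-filters (exact necessary conditions), then the full case analysis on
# the surviving samples
embeddable_mask_large <- function(rows) {
  res <- integer(rows$count)
  pre <- large_prefilter(rows)
  res[is.na(pre)] <- NA_integer_
  for (s in which(pre)) {
    A <- rows_to_matrix(rows, s)
    rep <- is_embeddable_large(A, verify = FALSE)
    res[s] <- switch(rep$status,
                     embeddable = 1L,
                     not_embeddable = 0L,
                     NA_integer_)
  }
  res
}

#' @export
print.volume_estimate <- function(x, ...) {
  lab <- if (x$absolute) "absolute volume" else "fraction"
  cat("Monte Carlo ", lab, " of '", x$region, "' in '", x$base, "': ",
      format(x$estimate), "\n", sep = "")
  cat("  95% CI [", format(x$ci_low), ", ", format(x$ci_high), "], ",
      x$hits, " hits / ", x$n_samples, " samples (seed ", x$seed, ")\n",
      sep = "")
  if (x$inconclusive > 0) {
    cat("  inconclusive samples:", x$inconclusive, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.volume_estimate <- function(x, ...) {
  data.frame(region = x$region, base = x$base, estimate = x$estimate,
             ci_low = x$ci_low, ci_high = x$ci_high, hits = x$hits,
             n_samples = x$n_samples, inconclusive = x$inconclusive,
             seed = x$seed, absolute = x$absolute)
}
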