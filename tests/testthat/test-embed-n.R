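# Embeddability at the other orders: 2x2 determinant criterion, 3x3 Markov
# two-branch criterion, the 5x5/6x6 case analysis with the exact branch
# interval, and the generic necessary conditions.

test_that("2x2 embeddability is the positive-determinant criterion", {
  rI <- is_embeddable2(diag(2))
  expect_equal(rI$status, "embeddable")
  expect_equal(rI$generators[[1]]$matrix, matrix(0, 2, 2))
  r <- is_embeddable2(matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE))
  expect_equal(r$status, "embeddable")
  expect_equal(r$determinant, 0.5)
  expect_true(is_rate_matrix(r$generators[[1]]$matrix))
  expect_lt(r$generators[[1]]$residual, 1e-10)
  r2 <- is_embeddable2(matrix(c(0.4, 0.6, 0.7, 0.3), 2, byrow = TRUE))
  expect_equal(r2$status, "not_embeddable")
  expect_equal(r2$determinant, -0.3)
})

test_that("3x3 criterion covers the all-real and both complex-pair branches", {
  expect_equal(is_embeddable3_markov(diag(3))$status, "embeddable")
  set.seed(14)
  # round trip through mild rate matrices (principal branch)
  for (i in 1:40) {
    R <- matrix(rexp(9, rate = 8), 3); diag(R) <- 0; diag(R) <- -rowSums(R)
    A <- expm_oracle(R)
    rep <- is_embeddable3_markov(A)
    expect_equal(rep$status, "embeddable")
    hit <- min(vapply(rep$generators, function(g) max_abs(g$matrix - R),
                      numeric(1)))
    expect_lt(hit, 1e-7)
  }
  # a matrix embeddable only through the -1 branch: a rate matrix with
  # complex eigenvalue pair -a +- b*i, b in (pi, 2*pi), built by spectral
  # synthesis (frozen instance; its principal-branch logarithm has an
  # off-diagonal entry of about -0.25)
  N <- cbind(1, c(-1.0661, 1.2947, 0.7843), c(0.1356, -1.8165, 1.1505))
  rot <- matrix(c(-8.7285, 3.725, -3.725, -8.7285), 2, 2, byrow = TRUE)
  R <- N %*% rbind(0, cbind(0, rot)) %*% solve(N)
  expect_true(is_rate_matrix(R, tol = 1e-12))
  expect_gt(max(Im(eigen(R, only.values = TRUE)$values)), pi)
  A <- expm_oracle(R)
  rep <- is_embeddable3_markov(A)
  expect_equal(rep$status, "embeddable")
  expect_equal(vapply(rep$generators, `[[`, integer(1), "k"), -1L)
  expect_lt(min(vapply(rep$generators, function(g) max_abs(g$matrix - R),
                       numeric(1))), 1e-7)
  # principal log exists but is not a rate matrix here
  expect_false(is_rate_matrix(principal_log_matrix(A)))
  # negative simple eigenvalue
  B <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  B <- 0.9 * B + 0.1 / 3
  expect_equal(is_embeddable3_markov(B)$status, "not_embeddable")
})

test_that("case classification follows the block spectra", {
  # all-real spectra in both blocks
  M1 <- synth_cs_markov(6, upper_ev = c(0.65, 0.35),
                        lower_ev = c(0.6, 0.4, 0.25), seed = 1)
  expect_equal(classify_case6(M1)$case_id, "case1")
  # conjugate pair in the lower block only
  M2 <- synth_cs_markov(6, upper_ev = c(0.65, 0.35),
                        lower_ev = c(0.5, complex(real = 0.2, imaginary = 0.1),
                                     complex(real = 0.2, imaginary = -0.1)),
                        seed = 2)
  lab2 <- classify_case6(M2)
  expect_equal(lab2$case_id, "case2")
  expect_false(lab2$upper_complex); expect_true(lab2$lower_complex)
  # pair in the upper (Markov) block only
  M3 <- synth_cs_markov(6,
                        upper_ev = c(complex(real = 0.4, imaginary = 0.15),
                                     complex(real = 0.4, imaginary = -0.15)),
                        lower_ev = c(0.55, 0.3, 0.15), seed = 3)
  expect_equal(classify_case6(M3)$case_id, "case3")
  # pairs in both
  M4 <- synth_cs_markov(6,
                        upper_ev = c(complex(real = 0.4, imaginary = 0.15),
                                     complex(real = 0.4, imaginary = -0.15)),
                        lower_ev = c(0.5, complex(real = 0.2, imaginary = 0.1),
                                     complex(real = 0.2, imaginary = -0.1)),
                        seed = 4)
  expect_equal(classify_case6(M4)$case_id, "case4")
  # a simple negative eigenvalue anywhere blocks embeddability
  M5 <- synth_cs_markov(6, upper_ev = c(0.65, 0.35),
                        lower_ev = c(0.6, -0.3, 0.2), seed = 5)
  expect_equal(classify_case6(M5)$case_id, "not_embeddable")
  expect_equal(is_embeddable_large(M5)$status, "not_embeddable")
})

test_that("feasible branch interval matches its defining inequalities", {
  # V = 0 off-diagonal: unbounded interval, N records negative entries
  base <- matrix(c(-1, 1, 0.5, -0.5), 2, byrow = TRUE)
  ki <- feasible_branch_interval(base, matrix(0, 2, 2))
  expect_equal(ki$L, -Inf); expect_equal(ki$U, Inf)
  expect_equal(nrow(ki$N), 0L)
  base2 <- matrix(c(-1, -2, 0.5, -0.5), 2, byrow = TRUE)
  expect_equal(nrow(feasible_branch_interval(base2, matrix(0, 2, 2))$N), 1L)
  # hand-computed bounds
  V <- matrix(c(0, 2, -4, 0), 2, byrow = TRUE)
  base3 <- matrix(c(-3, -3, 9, -3), 2, byrow = TRUE)
  ki3 <- feasible_branch_interval(base3, V)
  expect_equal(ki3$L, ceiling(3 / 2))   # -(-3)/2
  expect_equal(ki3$U, floor(9 / 4))     # -9/(-4)
})

test_that("5x5 and 6x6 round trips recover the generating rate matrix", {
  set.seed(15)
  for (n in c(5L, 6L)) {
    for (i in 1:40) {
      M <- random_embeddable(n, seed = 400 * n + i, scale = 0.15)
      rep <- is_embeddable_large(M)
      if (rep$status %in% c("inconclusive", "inconclusive_boundary")) next
      expect_equal(rep$status, "embeddable")
      for (g in rep$generators) {
        expect_true(is_rate_matrix(g$matrix, tol = 1e-8))
        expect_true(is_centrosymmetric(g$matrix,
                                       tol = 1e-8 * max(1, max_abs(g$matrix))))
        expect_lt(g$residual, 1e-8)
      }
      Q <- attr(M, "generator")
      hit <- min(vapply(rep$generators, function(g) max_abs(g$matrix - Q),
                        numeric(1)))
      expect_lt(hit, 1e-7)
      # the trace necessary condition always holds on embeddable matrices
      expect_true(trace_necessary(M)$passes)
    }
  }
  expect_equal(is_embeddable_large(diag(6))$status, "embeddable")
})

test_that("case-2 interval agrees with a brute-force branch scan", {
  set.seed(16)
  tested <- 0
  for (i in 1:120) {
    M <- random_embeddable(6, seed = 9000 + i, scale = 0.6)
    lab <- classify_case6(M)
    if (lab$case_id != "case2") next
    rep <- is_embeddable_large(M)
    if (rep$status %in% c("inconclusive", "inconclusive_boundary")) next
    brute <- brute_rate_branches(M, -25:25)
    if (rep$status == "embeddable") {
      ks <- sort(vapply(rep$generators, function(g) g$k[2], numeric(1)))
      expect_equal(ks, sort(brute))
    } else {
      expect_equal(length(brute), 0L)
    }
    tested <- tested + 1
  }
  expect_gt(tested, 10)
})

test_that("case-3 embeddability needs only the 0 and -1 upper branches", {
  # lift a 3x3 cyclic-mix rate matrix (complex pair with |Im| in (pi, 2*pi),
  # no zero rates) into a 6x6 case-3 matrix; the lower block must sit well
  # below exp(diag(R3)) or the cross-block rate conditions fail
  R3 <- 4 * matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3, byrow = TRUE) +
    0.2 * matrix(c(-1, 0, 1, 1, -1, 0, 0, 1, -1), 3, byrow = TRUE)
  A1 <- expm_oracle(R3)
  A2 <- diag(c(0.012, 0.009, 0.006))
  M <- inverse_block_transform(A1, A2, 6)
  expect_true(attr(M, "is_markov"))
  lab <- classify_case6(M)
  expect_equal(lab$case_id, "case3")
  rep <- is_embeddable_large(M)
  expect_equal(rep$status, "embeddable")
  expect_true(all(vapply(rep$generators, function(g) g$k[1], numeric(1)) %in%
                    c(0, -1)))
  # scanning further upper branches can produce no additional real rate logs:
  # the eigen-based family over k in -3..3 finds rate logs only at -1/0
  found <- brute_rate_branches(M, -3:3)
  expect_true(all(found %in% c(-1L, 0L)))
  expect_equal(sort(unique(vapply(rep$generators, function(g) g$k[1],
                                  numeric(1)))), sort(found))
})

test_that("trace condition: value, J4 counterexample, embeddable sweep", {
  # the upper-block trace of the identity is ceiling(n/2)
  expect_equal(trace_necessary(diag(4))$value, 2)
  expect_equal(trace_necessary(diag(7))$value, 4)
  expect_true(trace_necessary(diag(7))$passes)
  tj <- trace_necessary(exchange_matrix(4))
  expect_equal(tj$value, 2)
  expect_true(tj$passes)  # passes the necessary condition...
  # ...yet J4 (repeated eigenvalues +-1) is refused by the criterion rather
  # than declared embeddable: the trace bound is necessary, not sufficient
  expect_equal(is_embeddable4(exchange_matrix(4))$status, "inconclusive")
  set.seed(17)
  for (i in 1:200) {
    n <- sample(c(4L, 5L, 6L), 1)
    M <- random_embeddable(n, seed = 700 + i, scale = 0.4)
    expect_true(trace_necessary(M)$passes)
  }
})

test_that("CS logarithm existence reduces to block invertibility", {
  expect_true(cs_log_exists(diag(5)))
  set.seed(18)
  A <- matrix(rnorm(16), 4); A <- (A + A[4:1, 4:1]) / 2 + 2 * diag(4)
  expect_true(cs_log_exists(A))
  # singular lower block by construction
  upper <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  lower <- matrix(c(0.2, 0.2, 0.1, 0.1), 2, byrow = TRUE)  # det = 0
  M <- inverse_block_transform(upper, lower, 4)
  expect_false(cs_log_exists(M))
})
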