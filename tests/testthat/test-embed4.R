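# The strand-symmetric (4x4) machinery: closed-form spectrum, the explicit
# real-logarithm family, the embeddability criterion with its exact branch
# interval, generator enumeration and the K3P specialization.

k3p_ex <- k3p_matrix(0.65, 0.2, 0.1, 0.05)

test_that("closed-form spectrum matches a direct eigen-solver", {
  sp <- spectrum4(k3p_ex)
  expect_equal(sp$lam, 0.7)
  expect_equal(sp$mu, 0.7)
  expect_equal(sp$alpha, 0.6)
  expect_equal(sp$alpha_p, 0.1)
  expect_equal(sp$beta, 0.6)
  expect_equal(sp$beta_p, 0.1)
  expect_equal(sp$Delta, 0.04)
  expect_equal(sort(Re(sp$eigenvalues)), c(0.4, 0.5, 0.7, 1))
  spI <- spectrum4(diag(4))
  expect_equal(spI$lam, 1); expect_equal(spI$Delta, 0)
  expect_equal(Re(spI$eigenvalues), rep(1, 4))
  # random sweep against eigen()
  set.seed(2)
  for (i in 1:200) {
    M <- sample_cs_markov(4, 1, seed = i)[[1]]
    sp <- spectrum4(M)
    direct <- sort(Re(eigen(M, only.values = TRUE)$values))
    expect_lt(max(abs(sort(Re(sp$eigenvalues)) - direct)), 1e-9)
  }
  expect_error(spectrum4(matrix(runif(16), 4)), "centrosymmetric")
})

test_that("the k = 0 closed-form logarithm equals the principal logarithm", {
  cl <- candidate_log4(k3p_ex, 0L)
  expect_lt(max_abs(cl$matrix - principal_log_matrix(k3p_ex)), 1e-9)
  expect_true(cl$is_rate)
  expect_lt(cl$residual, 1e-9)
  set.seed(4)
  for (i in 1:100) {
    M <- sample_cs_markov(4, 1, seed = 1000 + i)[[1]]
    sp <- spectrum4(M)
    lam1 <- sp$lam + sp$mu - 1
    if (abs(sp$Delta) < 1e-6 || lam1 < 1e-6) next
    if (sp$Delta > 0 && (sp$alpha + sp$beta - sqrt(sp$Delta)) / 2 < 1e-6) next
    expect_lt(max_abs(candidate_log4(M, 0L)$matrix - principal_log_matrix(M)),
              1e-7)
  }
})

test_that("closed-form branches reproduce the eigen-based family (Delta < 0)", {
  set.seed(6)
  for (i in 1:30) {
    M <- random_delta_neg()
    dec <- spectral_decomposition(M, markov = TRUE)
    for (k in -3:3) {
      closed <- candidate_log4(M, k)$matrix
      spectral <- real_log_family(M, k, decomposition = dec)$matrix
      expect_lt(max_abs(closed - spectral), 1e-7 * max(1, max_abs(closed)))
      expect_lt(max_abs(mat_exp(closed) - M), 1e-8)
    }
    # branch differences are k-independent
    d1 <- candidate_log4(M, 1L)$matrix - candidate_log4(M, 0L)$matrix
    d2 <- candidate_log4(M, -3L)$matrix - candidate_log4(M, -4L)$matrix
    expect_lt(max_abs(d1 - d2), 1e-8 * max(1, max_abs(d1)))
  }
})

test_that("embeddability criterion decides the worked K3P examples", {
  r <- is_embeddable4(k3p_ex)
  expect_equal(r$status, "embeddable")
  expect_equal(length(r$generators), 1L)  # distinct real eigenvalues
  expect_true(is_rate_matrix(r$generators[[1]]$matrix))
  expect_lt(r$generators[[1]]$residual, 1e-8)
  # negative simple eigenvalue r = -0.1
  r2 <- is_embeddable4(k3p_matrix(0.35, 0.35, 0.2, 0.1))
  expect_equal(r2$status, "not_embeddable")
  # identity: exact special case
  rI <- is_embeddable4(diag(4))
  expect_equal(rI$status, "embeddable")
  expect_equal(rI$generators[[1]]$matrix, matrix(0, 4, 4))
  # K2P-type repeated eigenvalues are inconclusive
  expect_equal(is_embeddable4(k3p_matrix(0.7, 0.1, 0.1, 0.1))$status,
               "inconclusive")
})

test_that("exact branch interval agrees with a brute-force scan", {
  set.seed(9)
  for (i in 1:60) {
    M <- random_delta_neg()
    rep <- is_embeddable4(M)
    if (rep$status == "inconclusive_boundary") next
    brute <- brute_rate_branches(M, -50:50)
    if (rep$status == "embeddable") {
      ks <- sort(vapply(rep$generators, `[[`, integer(1), "k"))
      expect_equal(ks, sort(brute))
    } else {
      expect_equal(length(brute), 0L)
    }
  }
})

test_that("declared-embeddable matrices always carry a verified CS generator", {
  set.seed(10)
  checked <- 0
  for (i in 1:300) {
    M <- sample_cs_markov(4, 1, seed = 5000 + i)[[1]]
    rep <- is_embeddable4(M)
    if (rep$status != "embeddable") next
    checked <- checked + 1
    for (g in rep$generators) {
      expect_true(is_rate_matrix(g$matrix, tol = 1e-9))
      expect_true(is_centrosymmetric(g$matrix, tol = 1e-9))
      expect_lt(g$residual, 1e-8)
    }
    # closed forms for the row sums of the generator blocks
    sp <- spectrum4(M)
    p <- log(sp$lam + sp$mu - 1)
    rho <- (1 - sp$lam) / (sp$lam + sp$mu - 2) * p
    sigma <- (1 - sp$mu) / (sp$lam + sp$mu - 2) * p
    Q <- rep$generators[[1]]$matrix
    expect_lt(abs(Q[1, 2] + Q[1, 3] - rho), 1e-8)
    expect_lt(abs(Q[2, 1] + Q[2, 4] - sigma), 1e-8)
  }
  expect_gt(checked, 2)
})

test_that("round-trip completeness: exponentials of CS rate matrices are embeddable", {
  set.seed(11)
  for (i in 1:150) {
    M <- random_embeddable(4, seed = 3000 + i, scale = 0.2)
    dec <- spectral_decomposition(M, markov = TRUE)
    if (!dec$distinct) next
    rep <- is_embeddable4(M)
    expect_true(rep$status %in% c("embeddable", "inconclusive_boundary",
                                  "inconclusive"))
    if (rep$status == "embeddable") {
      Q <- attr(M, "generator")
      hit <- min(vapply(rep$generators,
                        function(g) max_abs(g$matrix - Q), numeric(1)))
      expect_lt(hit, 1e-6)
    }
  }
})

test_that("K3P criterion is equivalent to the general criterion", {
  M <- k3p_ex
  expect_true(k3p_embeddable(M))
  expect_false(k3p_embeddable(k3p_matrix(0.35, 0.35, 0.2, 0.1)))
  expect_true(k3p_embeddable(diag(4)))
  expect_error(k3p_embeddable(sample_cs_markov(4, 1, seed = 2)[[1]]),
               "K3P")
  set.seed(13)
  for (i in 1:500) {
    K <- random_k3p()
    sp <- spectrum4(K)
    ev <- Re(sp$eigenvalues)
    if (min(abs(outer(ev, ev, "-")[upper.tri(diag(4))])) < 1e-4) next
    verdict <- is_embeddable4(K)$status
    if (verdict %in% c("inconclusive", "inconclusive_boundary")) next
    expect_equal(verdict == "embeddable", k3p_embeddable(K))
  }
})

test_that("generator counts reflect rate identifiability", {
  # unique generator under distinct real eigenvalues
  gs <- markov_generators4(k3p_ex)
  expect_equal(gs$count, 1L)
  # not embeddable: empty set
  expect_equal(markov_generators4(k3p_matrix(0.35, 0.35, 0.2, 0.1))$count, 0L)
  # the worked example has exactly the branch -1 generator at t = 1
  fx <- prop3_fixture()
  gs3 <- markov_generators4(fx$M)
  expect_equal(gs3$count, 1L)
  expect_equal(gs3$k_values, -1L)
  expect_lt(max_abs(gs3$generators[[1]] - fx$Q), 1e-6)
})
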