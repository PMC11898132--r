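test_that("trajectory variance is the quadratic form in the basis row", {
  b <- build_basis(2)
  expect_equal(variance_at(matrix(0, 3, 3), b$phi[1, ]), 0)
  expect_equal(variance_at(diag(3), b$phi[1, ]), 0.5 + 1.5 + 2.5)
  set.seed(1)
  for (i in 1:5) {
    M <- crossprod(matrix(rnorm(9), 3, 3))
    phi <- rnorm(3)
    brute <- sum(outer(phi, phi) * M)
    expect_equal(variance_at(M, phi), brute, tolerance = 1e-12)
  }
  expect_error(variance_at(diag(2), b$phi[1, ]), "dimension")
})

test_that("heritability and PE fraction reproduce printed table rows", {
  expect_equal(round(heritability_at(0.119, 0.076, 0.735), 2), 0.13)
  expect_equal(round(heritability_at(1.406, 1.130, 1.066), 2), 0.39)
  expect_equal(heritability_at(0, 0.3, 0.7), 0)
  expect_equal(round(pe_fraction_at(0.060, 0.582, 0.769), 2), 0.41)
  expect_equal(round(pe_fraction_at(0.422, 0.738, 1.003), 2), 0.34)
  expect_equal(pe_fraction_at(0.3, 0, 0.7), 0)
  expect_error(heritability_at(0, 0, 0), "zero total")
  expect_error(pe_fraction_at(0, 0, 0), "zero total")
})

test_that("genetic correlations follow the quadratic-form definition", {
  b <- build_basis(2)
  G <- crossprod(matrix(rnorm(9), 3, 3)) + diag(0.1, 3)
  expect_equal(genetic_correlation(G, b$phi[2, ], b$phi[2, ]), 1)
  v <- c(1, 0.5, -0.2)
  G1 <- tcrossprod(v)                          # rank one: |rg| = 1 everywhere
  for (t in 1:5) {
    r <- genetic_correlation(G1, b$phi[t, ], b$phi[t + 1, ])
    expect_equal(abs(r), 1, tolerance = 1e-9)
  }
  expect_true(is.na(genetic_correlation(matrix(0, 3, 3), b$phi[1, ], b$phi[2, ])))
})

test_that("genetic correlation matches a Monte-Carlo coefficient-draw oracle", {
  set.seed(2)
  b <- build_basis(2)
  G <- matrix(c(0.5, 0.2, 0.1, 0.2, 0.3, 0.05, 0.1, 0.05, 0.2), 3, 3)
  u <- t(chol(G)) %*% matrix(rnorm(3 * 1e6), 3)
  g2 <- as.vector(b$phi[2, ] %*% u)
  g5 <- as.vector(b$phi[5, ] %*% u)
  expect_equal(genetic_correlation(G, b$phi[2, ], b$phi[5, ]),
               stats::cor(g2, g5), tolerance = 0.01)
})

test_that("phenotypic correlation excludes residuals off the diagonal", {
  set.seed(3)
  b <- build_basis(2)
  G <- crossprod(matrix(rnorm(9), 3, 3)) / 3 + diag(0.05, 3)
  P <- crossprod(matrix(rnorm(9), 3, 3)) / 3 + diag(0.05, 3)
  s2 <- c(0.8, 1.0, 1.2)
  cm <- assign_residual_class(1:6, "prolific")
  rp1 <- phenotypic_correlation(G, P, s2, b$phi[1, ], b$phi[4, ], cm[1], cm[4])
  # doubling residuals shrinks |rp| but leaves rg untouched
  rp2 <- phenotypic_correlation(G, P, 2 * s2, b$phi[1, ], b$phi[4, ],
                                cm[1], cm[4])
  expect_lt(abs(rp2), abs(rp1))
  expect_equal(genetic_correlation(G, b$phi[1, ], b$phi[4, ]),
               genetic_correlation(G, b$phi[1, ], b$phi[4, ]))
  # Monte-Carlo record-simulation oracle
  n <- 1e6
  u <- t(chol(G)) %*% matrix(rnorm(3 * n), 3)
  v <- t(chol(P)) %*% matrix(rnorm(3 * n), 3)
  y1 <- as.vector(b$phi[1, ] %*% (u + v)) + rnorm(n, 0, sqrt(s2[cm[1]]))
  y4 <- as.vector(b$phi[4, ] %*% (u + v)) + rnorm(n, 0, sqrt(s2[cm[4]]))
  expect_equal(rp1, stats::cor(y1, y4), tolerance = 0.01)
})

test_that("trajectory parameters satisfy their structural invariants", {
  set.seed(4)
  b <- build_basis(2)
  cm <- assign_residual_class(1:6, "conventional")
  for (i in 1:5) {
    G <- crossprod(matrix(rnorm(9), 3, 3)) / 2 + diag(0.01, 3)
    P <- crossprod(matrix(rnorm(9), 3, 3)) / 2 + diag(0.01, 3)
    tp <- trajectory_params(G, P, c(1, 1.1, 0.9), b, cm)
    expect_equal(tp$rg, t(tp$rg))
    expect_equal(unname(diag(tp$rg)), rep(1, 6))
    expect_equal(unname(diag(tp$rp)), rep(1, 6))
    expect_true(all(abs(tp$rg) <= 1 + 1e-12))
    expect_true(all(abs(tp$rp) <= 1 + 1e-12))
    expect_true(all(tp$h2 >= 0 & tp$h2 <= 1))
    expect_true(all(tp$c2 >= 0 & tp$c2 <= 1))
    expect_true(all(tp$h2 + tp$c2 <= 1 + 1e-12))
  }
})

test_that("the repeatability configuration collapses to constant h2 and rg = 1", {
  b <- repeatability_basis()
  cm <- rep(1L, 6)
  tp <- trajectory_params(matrix(0.2, 1, 1), matrix(0.1, 1, 1), c(1, 1, 1),
                          b, cm)
  expect_equal(unname(tp$h2), rep(0.2 / 1.3, 6))
  expect_equal(unname(tp$rg), matrix(1, 6, 6), ignore_attr = TRUE)
  expect_equal(unname(tp$c2), rep(0.1 / 1.3, 6))
})

test_that("trajectory summaries on a constant chain equal that draw's parameters", {
  q <- 3
  G <- diag(c(0.3, 0.1, 0.05)) + 0.02
  P <- diag(c(0.2, 0.08, 0.03)) + 0.01
  ch <- structure(list(
    draws = list(G = matrix(as.vector(G), 30, q * q, byrow = TRUE),
                 P = matrix(as.vector(P), 30, q * q, byrow = TRUE),
                 sigma2e = matrix(rep(c(0.8, 0.7, 0.9), each = 30), 30, 3),
                 deviance = rep(0, 30), idx = 1:30),
    n_draws = 30L, tau = c(-Inf, 0, 1, Inf), n_categories = 3L,
    basis = build_basis(2), line = "prolific",
    config = model_config(n_iter = 30, burn_in = 0, thin = 1)),
    class = "litter_chain")
  s <- trajectory_summary(ch)
  cm <- assign_residual_class(1:6, "prolific")
  tp <- trajectory_params(G, P, c(0.8, 0.7, 0.9), build_basis(2), cm)
  for (t in 1:6) {
    expect_equal(s$mean[s$quantity == paste0("h2.", t)], unname(tp$h2[t]))
    expect_equal(s$mean[s$quantity == paste0("c2.", t)], unname(tp$c2[t]))
  }
  expect_equal(s$mean[s$quantity == "rg.2.5"], tp$rg["2", "5"])
  # mean c2 across parities is the average of the six per-parity values
  expect_equal(mean(s$mean[s$quantity %in% paste0("c2.", 1:6)]),
               mean(tp$c2))
})
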