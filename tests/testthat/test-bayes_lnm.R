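test_that("conjugate update reproduces closed-form examples", {
  # no data: posterior equals prior
  pr <- lnm_prior(D = 3, Q = 2)
  post0 <- fit_conjugate(matrix(0, 2, 0), matrix(0, 2, 0), pr)
  expect_equal(post0$Theta_post, pr$Theta)
  expect_equal(post0$Gamma_post, pr$Gamma)
  expect_equal(post0$Xi_post, pr$Xi)
  expect_equal(post0$nu_post, pr$nu)

  # single coordinate, intercept-only: posterior mean = sum(eta) / (N + 1)
  pr1 <- lnm_prior(D = 2, Q = 1, Gamma = matrix(1), nu = 3, Xi = matrix(1))
  post1 <- fit_conjugate(matrix(c(1, 3), 1, 2), matrix(1, 1, 2), pr1)
  expect_equal(drop(post1$Theta_post), 4 / 3, tolerance = 1e-12)
  expect_equal(post1$nu_post, 5)
})

test_that("posterior mean solves the generalized-ridge normal equations", {
  set.seed(10)
  for (i in 1:5) {
    p <- 3; Q <- 4; N <- 12
    eta <- matrix(rnorm(p * N), p, N)
    X <- rbind(1, matrix(rnorm((Q - 1) * N), Q - 1, N))
    G <- crossprod(matrix(rnorm(Q * Q), Q)) + diag(Q)
    Theta <- matrix(rnorm(p * Q, 0, 0.3), p, Q)
    pr <- lnm_prior(p + 1, Q, Theta = Theta, Gamma = G)
    post <- fit_conjugate(eta, X, pr)
    # independent oracle: per-row augmented least squares
    Gi <- solve(G)
    Rh <- chol(Gi)
    Xaug <- rbind(t(X), Rh)
    for (r in seq_len(p)) {
      yaug <- c(eta[r, ], drop(Rh %*% Theta[r, ]))
      bhat <- qr.solve(Xaug, yaug)
      expect_equal(unname(post$Theta_post[r, ]), unname(bhat),
                   tolerance = 1e-8)
    }
  }
})

test_that("posterior draws are seed-reproducible and match closed-form moments", {
  set.seed(20)
  p <- 2; Q <- 2; N <- 30
  X <- rbind(1, rnorm(N))
  eta <- matrix(c(0.5, -0.2), p, 1) %*% X[2, , drop = FALSE] +
    matrix(rnorm(p * N, 0, 0.5), p, N)
  post <- fit_conjugate(eta, X, lnm_prior(p + 1, Q))
  d1 <- sample_posterior(post, S = 200, seed = 42)
  d2 <- sample_posterior(post, S = 200, seed = 42)
  expect_identical(d1$Lambda, d2$Lambda)
  expect_identical(d1$Sigma, d2$Sigma)

  big <- sample_posterior(post, S = 20000, seed = 7)
  m <- draws_mean(big)
  sds <- apply(big$Lambda, c(1, 2), sd)
  expect_true(all(abs(m - post$Theta_post) <= 3 * sds / sqrt(20000)))
  # inverse-Wishart mean: Xi_post / (nu_post - p - 1)
  Sig_mean <- apply(big$Sigma, c(1, 2), mean)
  Sig_expect <- post$Xi_post / (post$nu_post - p - 1)
  expect_equal(Sig_mean, Sig_expect, tolerance = 0.05)
  # every Sigma draw symmetric positive-definite
  evs <- apply(big$Sigma[, , 1:200], 3, function(S)
    min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values))
  expect_true(all(evs > 0))
})

test_that("clr-converted draws have zero column sums and consistent means", {
  set.seed(30)
  p <- 3; N <- 40
  X <- matrix(1, 1, N)
  eta <- matrix(rnorm(p * N, mean = c(1, 0, -1)), p, N)
  post <- fit_conjugate(eta, X, lnm_prior(p + 1, 1))
  draws <- sample_posterior(post, S = 500, seed = 3)
  cd <- draws_to_clr(draws, feature_names = paste0("f", 1:4))
  expect_equal(dim(cd$Lambda)[1], 4L)
  sums <- apply(cd$Lambda, c(2, 3), sum)
  expect_true(all(abs(sums) < 1e-9))
  # intercept-only model: clr coefficient mean ~ clr of expected composition
  comp <- alr_inv(rowMeans(eta))
  expect_equal(unname(drop(apply(cd$Lambda, c(1, 2), mean))), clr(comp),
               tolerance = 0.1)
})

test_that("clr posterior means are invariant to the alr fitting reference", {
  # priors specified in clr space and mapped consistently into each alr system
  set.seed(40)
  D <- 4; Q <- 2; N <- 25
  X <- rbind(1, rnorm(N))
  comp <- t(apply(matrix(rexp(D * N), D, N), 1, identity))
  comp <- sweep(comp, 2, colSums(comp), "/")
  Theta_clr <- matrix(rnorm(D * Q, 0, 0.5), D, Q)
  Theta_clr <- sweep(Theta_clr, 2, colMeans(Theta_clr))
  nu <- D + 2
  res <- lapply(1:D, function(r) {
    Fmat <- diag(D)[-r, , drop = FALSE]
    Fmat[, r] <- Fmat[, r] - 1
    Theta_r <- Fmat %*% Theta_clr
    Xi_r <- (nu - D) * (Fmat %*% t(Fmat))  # maps identity clr scale
    pr <- lnm_prior(D, Q, Theta = Theta_r, nu = nu, Xi = Xi_r)
    post <- fit_conjugate(alr(comp, ref = r), X, pr)
    alr_to_clr_coeffs(post$Theta_post, ref = r)
  })
  for (r in 2:D) expect_equal(res[[r]], res[[1]], tolerance = 1e-8)
})

test_that("invalid priors and data are rejected", {
  expect_error(lnm_prior(3, 2, nu = 2), "nu")
  expect_error(lnm_prior(3, 2, Gamma = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  pr <- lnm_prior(3, 1)
  expect_error(fit_conjugate(matrix(c(1, NA), 2, 1), matrix(1, 1, 1), pr),
               "non-finite")
})
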