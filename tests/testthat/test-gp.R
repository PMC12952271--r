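test_that("kd_to_affinity is the base-10 log of 1 nM / Kd", {
  expect_identical(kd_to_affinity(1), 0)
  expect_equal(kd_to_affinity(0.04), log10(25))
  expect_equal(round(kd_to_affinity(0.04), 1), 1.4)
  expect_identical(kd_to_affinity(100), -2)
  expect_true(kd_to_affinity(1) > kd_to_affinity(2))  # monotone decreasing
  expect_error(kd_to_affinity(0), "> 0")
  expect_error(kd_to_affinity(-1), "> 0")
})

test_that("rbf kernel matches its closed form", {
  p <- kernel_params(delta = 2, lam = 1, sigma_n = 0)
  u <- c(1, 0); v <- c(0, 1)   # squared distance 2
  expect_equal(rbf_kernel(u, v, p), 2 * exp(-1))
  expect_identical(rbf_kernel(u, u, p), 2)
  expect_equal(rbf_kernel(u, v, p), rbf_kernel(v, u, p))
  expect_lt(rbf_kernel(c(0, 0), c(100, 100), p), 1e-12)
  expect_error(rbf_kernel(1:2, 1:3, p), "dimension")
  expect_error(kernel_params(delta = -1), "delta")
})

test_that("posterior reduces to the prior with no data and to the 1-point closed form", {
  p <- kernel_params(delta = 1.7, lam = 2, sigma_n = 0.4, C = 0.3)
  gp0 <- gp_model(NULL, numeric(0), p)
  post <- gp_posterior(gp0, c(1, 2))
  expect_identical(post$mu, p$C)
  expect_identical(post$sigma2, p$delta)
  # n = 1, query at the training point
  x1 <- c(0.5, -1); y1 <- 2.2
  gp1 <- gp_model(matrix(x1, 1), y1, p)
  post1 <- gp_posterior(gp1, x1)
  expect_equal(post1$mu, p$C + p$delta / (p$delta + p$sigma_n^2) * (y1 - p$C))
  expect_equal(post1$sigma2, p$delta - p$delta^2 / (p$delta + p$sigma_n^2))
  # noisy predictive variance adds sigma_n^2
  expect_equal(gp_posterior(gp1, x1, noisy = TRUE)$sigma2,
               post1$sigma2 + p$sigma_n^2)
})

test_that("posterior and marginal likelihood match a dense-solve oracle", {
  set.seed(31)
  n <- 30
  X <- matrix(rnorm(n * 4), n)
  Y <- rnorm(n)
  p <- kernel_params(delta = 1.3, lam = 1.8, sigma_n = 0.35, C = 0.2)
  gp <- gp_model(X, Y, p)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) rbf_kernel(X[i, ], X[j, ], p)))
  A <- K + diag(p$sigma_n^2, n)
  for (rep in 1:5) {
    z <- rnorm(4)
    kz <- vapply(seq_len(n), function(i) rbf_kernel(z, X[i, ], p), numeric(1))
    mu_o <- p$C + drop(crossprod(kz, solve(A, Y - p$C)))
    s2_o <- p$delta - drop(crossprod(kz, solve(A, kz)))
    post <- gp_posterior(gp, z)
    expect_equal(post$mu, mu_o, tolerance = 1e-8)
    expect_equal(post$sigma2, s2_o, tolerance = 1e-8)
  }
  mll_o <- -0.5 * drop(crossprod(Y - p$C, solve(A, Y - p$C))) -
    0.5 * determinant(A)$modulus[1] - n / 2 * log(2 * pi)
  expect_equal(gp_mll(gp), mll_o, tolerance = 1e-8)
})

test_that("posterior interpolates targets as noise vanishes and variance is bounded", {
  set.seed(32)
  X <- matrix(rnorm(10 * 3), 10)
  Y <- rnorm(10)
  p <- kernel_params(delta = 2, lam = 1.5, sigma_n = 1e-6, C = 0)
  gp <- gp_model(X, Y, p)
  post <- gp_posterior(gp, X)
  expect_lt(max(abs(post$mu - Y)), 1e-4)
  expect_true(all(post$sigma2 >= 0))
  expect_true(all(post$sigma2 <= p$delta + 1e-12))
  # permutation invariance of predictions
  perm <- sample.int(10)
  gp_p <- gp_model(X[perm, ], Y[perm], p)
  z <- rnorm(3)
  expect_equal(gp_posterior(gp, z)$mu, gp_posterior(gp_p, z)$mu,
               tolerance = 1e-9)
})

test_that("marginal-likelihood fitting improves the objective and recovers parameters", {
  set.seed(33)
  n <- 200; m <- 5
  X <- matrix(rnorm(n * m), n)
  p_true <- kernel_params(delta = 2, lam = 3, sigma_n = 0.3, C = 1)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) rbf_kernel(X[i, ], X[j, ], p_true)))
  Y <- p_true$C + drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) +
    rnorm(n, 0, p_true$sigma_n)
  fit <- gp_fit_mll(X, Y, steps = 600, lr = 1e-3)
  tr <- attr(fit, "mll_trace")
  expect_length(tr, 600)
  # smoothed trace is non-decreasing
  sm <- stats::filter(tr, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -1e-6))
  expect_gt(tail(tr, 1), tr[1])
  # broad recovery tolerance: within +/-50% on the length scale
  expect_gt(fit$params$lam, 0.5 * p_true$lam)
  expect_lt(fit$params$lam, 1.5 * p_true$lam)
  expect_lt(abs(fit$params$sigma_n - p_true$sigma_n), 0.15)
  expect_error(gp_fit_mll(X[1, , drop = FALSE], Y[1]), "n >= 2")
})

test_that("GP checkpoints round-trip through JSON", {
  set.seed(35)
  seqs <- replicate(8, paste(sample(aa_alphabet(), 4, TRUE), collapse = ""))
  enc <- get_encoder("onehot")
  X <- do.call(rbind, lapply(seqs, enc$encode))
  Y <- rnorm(8)
  gp <- gp_model(X, Y, kernel_params(1.4, 2.1, 0.3, -0.5))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_gp_checkpoint(gp, tmp, sequences = seqs, seed = 35)
  gp2 <- read_gp_checkpoint(tmp)
  z <- enc$encode(seqs[1])
  expect_equal(gp_posterior(gp2, z), gp_posterior(gp, z), tolerance = 1e-12)
})

test_that("acquisition interpolates between pessimism and optimism", {
  set.seed(34)
  X <- matrix(rnorm(20 * 3), 20)
  Y <- rnorm(20)
  gp <- gp_model(X, Y, kernel_params(1, 1.5, 0.3, 0))
  z <- rnorm(3)
  post <- gp_posterior(gp, z)
  expect_equal(gp_acquisition(gp, z, beta = 0), post$mu)
  vals <- vapply(c(-1, 0, 1, 2), function(b) gp_acquisition(gp, z, b),
                 numeric(1))
  expect_true(all(diff(vals) > 0))   # strictly increasing in beta
  expect_equal(diff(vals)[1], sqrt(post$sigma2))
})
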