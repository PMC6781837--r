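test_that("OLS solves the normal equations and matches a pseudoinverse oracle", {
  # identity design
  f <- fit_ols(diag(3) * 1.0, c(1, 2, 3))
  expect_equal(f$beta, c(1, 2, 3), tolerance = 1e-10)

  # noiseless recovery
  d <- rand_design(25, 4, seed = 1)
  b <- c(1.5, -2, 0.5, 3)
  y <- drop(d$X %*% b)
  expect_equal(fit_ols(d$X, y)$beta, b, tolerance = 1e-8)

  # random instance vs independent pseudoinverse (SVD) solve
  d2 <- rand_design(20, 5, sparsity = 3, seed = 2)
  s <- svd(d2$X)
  beta_pinv <- drop(s$v %*% ((t(s$u) %*% d2$y) / s$d))
  expect_equal(fit_ols(d2$X, d2$y)$beta, beta_pinv, tolerance = 1e-8)

  expect_error(fit_ols(matrix(rnorm(12), 3, 4), rnorm(3)), "n >= p")
  X_sing <- cbind(1:5, 2 * (1:5))
  expect_error(fit_ols(X_sing, rnorm(5)), "singular")
})

test_that("OLS error variance is RSS/(n - p) with explicit dof guard", {
  # X = ones, y = 2*X + [1,-1,1,-1]: residuals are exactly [1,-1,1,-1]
  X <- matrix(1, 4, 1)
  y <- 2 + c(1, -1, 1, -1)
  fit <- fit_ols(X, y)
  est <- estimate_error_variance(fit, X, y)
  expect_equal(est$sigma2_e, 4 / 3, tolerance = 1e-12)
  expect_equal(est$dof, 3)

  # perfect fit
  d <- rand_design(10, 2, seed = 3)
  yfit <- drop(d$X %*% c(1, 2))
  f2 <- fit_ols(d$X, yfit)
  expect_equal(estimate_error_variance(f2, d$X, yfit)$sigma2_e, 0,
               tolerance = 1e-12)

  # n = p has no residual dof
  Xsq <- ortho_design(3, seed = 4) + diag(3) * 0.1
  f3 <- structure(list(beta = rep(0, 3), method = "OLS"), class = "gw_fit")
  expect_error(estimate_error_variance(f3, Xsq, rnorm(3)), "n > p")
  expect_error(estimate_error_variance(fit_ridge(d$X, d$y, 1), d$X, d$y), "OLS")
})

test_that("ridge primal and dual routes agree and limits behave", {
  # p > n instance: dual route vs direct dense solve of (X'X + lam I)
  set.seed(5)
  X <- matrix(rnorm(5 * 8), 5, 8)
  y <- rnorm(5)
  lam <- 0.7
  beta_direct <- drop(solve(crossprod(X) + lam * diag(8), crossprod(X, y)))
  expect_equal(fit_ridge(X, y, lam)$beta, beta_direct, tolerance = 1e-8)

  # full rank, lam = 0 equals OLS
  d <- rand_design(30, 6, sparsity = 2, seed = 6)
  expect_equal(fit_ridge(d$X, d$y, 0)$beta, fit_ols(d$X, d$y)$beta,
               tolerance = 1e-8)

  # enormous penalty shrinks essentially to zero
  big <- fit_ridge(d$X, d$y, 1e12)
  expect_lt(max(abs(big$beta)), 1e-6 * max(abs(crossprod(d$X, d$y))))

  expect_error(fit_ridge(d$X, d$y, -1), ">= 0")
})

test_that("ridge estimates have smaller sampling variance than OLS at lam > 0", {
  set.seed(7)
  d <- rand_design(30, 5, seed = 7)
  beta_true <- c(1, -1, 0.5, 0, 2)
  mu <- drop(d$X %*% beta_true)
  B_ols <- B_rr <- matrix(0, 200, 5)
  for (r in 1:200) {
    y <- mu + rnorm(30)
    y <- y - mean(y)
    B_ols[r, ] <- fit_ols(d$X, y)$beta
    B_rr[r, ] <- fit_ridge(d$X, y, 5)$beta
  }
  expect_true(all(apply(B_rr, 2, var) < apply(B_ols, 2, var)))
})

test_that("GBLUP with G = XX' reproduces ridge predictions", {
  set.seed(8)
  for (r in 1:5) {
    n <- 6 + r; p <- n + 10
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n); y <- y - mean(y)
    lam <- runif(1, 0.1, 5)
    ghat <- fit_gblup(tcrossprod(X), y, lam)
    expect_equal(ghat, drop(X %*% fit_ridge(X, y, lam)$beta), tolerance = 1e-8)
  }
  # G = I gives scalar shrinkage y/2 at lam = 1
  expect_equal(fit_gblup(diag(4), c(1, 2, 3, 4), 1), c(1, 2, 3, 4) / 2,
               tolerance = 1e-12)
  # strong penalty drives predictions to zero
  expect_lt(max(abs(fit_gblup(diag(4), c(1, 2, 3, 4), 1e10))), 1e-8)
  expect_error(fit_gblup(matrix(1:4, 2, 2), rnorm(2), 1), "symmetric")
})

test_that("adaptive weights follow the marginal-covariance rule in both modes", {
  # construct X with known marginal covariances c = [0.1, 0.2]
  n <- 10
  set.seed(9)
  d <- rand_design(n, 2, seed = 9)
  y <- rnorm(n); y <- y - mean(y)
  cj <- abs(drop(crossprod(d$X, y))) / n
  expect_equal(alasso_weights(d$X, y, "inverse", eps = 0), 1 / cj,
               tolerance = 1e-12)
  expect_equal(alasso_weights(d$X, y, "literal", eps = 0), cj,
               tolerance = 1e-12)

  # orthogonal marker gets the maximal penalty under the default guard
  X <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1)) / sqrt(1)
  yv <- c(1, -1, 1, -1)  # exactly orthogonal to column 2
  w <- alasso_weights(X, yv, "inverse")
  expect_true(which.max(w) == 2L)
  expect_true(all(is.finite(w) & w > 0))
})

test_that("coordinate descent matches closed forms: null threshold, OLS limit, soft-thresholding", {
  d <- rand_design(40, 8, sparsity = 3, seed = 10)
  n <- 40
  lam_max <- max(abs(crossprod(d$X, d$y))) / n
  expect_equal(fit_lasso(d$X, d$y, lam_max)$beta, rep(0, 8))
  expect_equal(fit_lasso(d$X, d$y, lam_max * 1.5)$beta, rep(0, 8))

  # lam = 0 on a full-rank tall design equals OLS
  f0 <- fit_lasso(d$X, d$y, 0, tol = 1e-10)
  expect_equal(f0$beta, fit_ols(d$X, d$y)$beta, tolerance = 1e-6)

  # orthonormal design (X'X/n = I): exact soft-thresholding solution
  p <- 12
  Q <- ortho_design(p, seed = 11) * sqrt(p)   # columns have x'x = n = p
  yq <- rnorm(p); yq <- yq - mean(yq)
  lam <- 0.15
  w <- runif(p, 0.5, 2)
  z <- drop(crossprod(Q, yq)) / p
  beta_closed <- sign(z) * pmax(abs(z) - lam * w, 0)
  fq <- fit_lasso(Q, yq, lam, weights = w, tol = 1e-12)
  expect_equal(fq$beta, beta_closed, tolerance = 1e-10)

  expect_error(fit_lasso(d$X, d$y, 0.1, weights = rep(-1, 8)), "positive")
})

test_that("coordinate descent agrees with glmnet on shared objective scaling", {
  d <- rand_design(50, 12, sparsity = 4, seed = 12)
  lam <- 0.08
  gfit <- glmnet::glmnet(d$X, d$y, alpha = 1, lambda = lam, standardize = FALSE,
                         intercept = FALSE, thresh = 1e-14)
  beta_glmnet <- as.numeric(gfit$beta)
  ours <- fit_lasso(d$X, d$y, lam, tol = 1e-12)
  expect_equal(ours$beta, beta_glmnet, tolerance = 1e-4)
})

test_that("the coordinate-descent objective never increases across sweeps", {
  for (s in 1:5) {
    d <- rand_design(30, 15, sparsity = 5, seed = 100 + s)
    f <- fit_lasso(d$X, d$y, 0.02)
    tr <- attr(f, "objective_trace")
    expect_true(all(diff(tr) <= 1e-12))
    expect_true(f$converged)
  }
})

test_that("ALASSO with unit weights coincides with the LASSO", {
  d <- rand_design(35, 10, sparsity = 3, seed = 13)
  a <- fit_lasso(d$X, d$y, 0.05, weights = rep(1, 10))
  l <- fit_lasso(d$X, d$y, 0.05)
  expect_equal(a$beta, l$beta, tolerance = 1e-12)
  expect_identical(a$method, "ALASSO")
})

test_that("lambda grids are log-spaced from the null-model threshold", {
  d <- rand_design(30, 10, sparsity = 2, seed = 14)
  n <- 30
  lam_max <- max(abs(crossprod(d$X, d$y))) / n

  g2 <- lambda_grid(d$X, d$y, n_lambda = 2, min_ratio = 0.5)
  expect_equal(g2$values, c(lam_max, lam_max / 2), tolerance = 1e-12)

  g100 <- lambda_grid(d$X, d$y, n_lambda = 100, min_ratio = 0.01)
  expect_length(g100$values, 100)
  expect_true(all(diff(g100$values) < 0))
  ratios <- g100$values[-1] / g100$values[-100]
  expect_equal(ratios, rep(ratios[1], 99), tolerance = 1e-10)

  # the first grid value fits to the all-zero model
  expect_equal(fit_lasso(d$X, d$y, g100$values[1])$beta, rep(0, 10))

  # weighted threshold
  w <- runif(10, 0.5, 3)
  gw <- lambda_grid(d$X, d$y, weights = w, n_lambda = 5, min_ratio = 0.1)
  expect_equal(gw$values[1], max(abs(crossprod(d$X, d$y)) / (n * w)),
               tolerance = 1e-12)

  expect_error(lambda_grid(d$X, rep(0, 30)), "no signal")
  expect_error(lambda_grid(d$X, d$y, n_lambda = 1), "n_lambda")
})

test_that("warm-started path fits equal cold-start refits and shrink monotonically", {
  d <- rand_design(30, 10, sparsity = 3, seed = 15)
  path <- fit_path(d$X, d$y, "LASSO", n_lambda = 12, min_ratio = 0.05,
                   tol = 1e-9)
  for (k in seq_along(path$fits)) {
    cold <- fit_lasso(d$X, d$y, path$grid$values[k], tol = 1e-9)
    expect_equal(path$fits[[k]]$beta, cold$beta, tolerance = 1e-6)
  }
  # sparsity non-increasing in lambda (stored grid is decreasing)
  nz <- vapply(path$fits, function(f) sum(abs(f$beta) > 1e-10), integer(1))
  expect_true(all(diff(nz) >= 0))

  # ridge path: coefficient norm shrinks as lambda grows
  rp <- fit_path(d$X, d$y, "RR", n_lambda = 15)
  norms <- vapply(rp$fits, function(f) sqrt(sum(f$beta^2)), numeric(1))
  expect_true(all(diff(norms) > 0))  # decreasing lambda => growing norm

  # single-value grid at lambda_max yields the null fit
  g1 <- lambda_grid(d$X, d$y, n_lambda = 2, min_ratio = 0.99)
  g1$values <- g1$values[1]; g1$n_lambda <- 1L
  p1 <- fit_path(d$X, d$y, "LASSO", grid = g1)
  expect_equal(p1$fits[[1]]$beta, rep(0, 10))
})

test_that("a positive ridge penalty can beat OLS test error on orthonormal designs", {
  wins <- 0L
  for (r in 1:20) {
    set.seed(200 + r)
    p <- 25
    X <- ortho_design(p)                  # n = p, X'X = I
    beta_true <- rnorm(p, 0, 0.5)
    y <- drop(X %*% beta_true) + rnorm(p, 0, 1)
    Xte <- matrix(rnorm(50 * p), 50, p)
    yte <- drop(Xte %*% beta_true) + rnorm(50, 0, 1)
    beta_ols <- drop(crossprod(X, y))     # OLS on an orthonormal design
    mse_ols <- mean((yte - drop(Xte %*% beta_ols))^2)
    lams <- 10^seq(-2, 2, length.out = 25)
    mse_rr <- vapply(lams, function(l) {
      mean((yte - drop(Xte %*% fit_ridge(X, y, l)$beta))^2)
    }, numeric(1))
    if (min(mse_rr) < mse_ols) wins <- wins + 1L
  }
  expect_gte(wins, 15L)
})
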