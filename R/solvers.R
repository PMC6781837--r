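#' Fitted penalized-regression object
#'
#' All solvers return a `gw_fit`: coefficient vector (marker effects on the
#' standardized scale), penalty, method tag and convergence metadata. No
#' intercept is ever fitted — the design contract is a column-standardized
#' `X` and a centered `y` (see [standardize()]).
#'
#' @param beta Numeric coefficient vector.
#' @param lam Penalty value (on the solver's own scale; see Details of
#'   [fit_lasso()] and [fit_ridge()]).
#' @param method One of `"OLS"`, `"RR"`, `"LASSO"`, `"ALASSO"`, `"GBLUP"`.
#' @param weights Optional adaptive penalty weights (ALASSO).
#' @param n_iter,converged,objective Convergence metadata.
#' @return An object of class `gw_fit`.
#' @keywords internal
new_gw_fit <- function(beta, lam, method, weights = NULL, n_iter = 1L,
                       converged = TRUE, objective = NA_real_) {
  stopifnot(all(is.finite(beta)), lam >= 0)
  structure(list(beta = as.numeric(beta), lam = lam, method = method,
                 weights = weights, n_iter = n_iter, converged = converged,
                 objective = objective),
            class = "gw_fit")
}

#' @export
print.gw_fit <- function(x, ...) {
  cat(sprintf("<gw_fit %s: p = %d, lambda = %.4g, nonzero = %d%s>\n",
              x$method, length(x$beta), x$lam, sum(x$beta != 0),
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `gw_fit`.
#' @param newX Design matrix on the same standardized scale as the training
#'   design.
#' @param ... Unused.
#' @return Numeric vector of predictions `newX %*% beta`.
#' @export
predict.gw_fit <- function(object, newX, ...) {
  drop(as.matrix(newX) %*% object$beta)
}

#' Ordinary least squares on a standardized design
#'
#' Solves the normal equations `X'X beta = X'y` via QR. Valid only when
#' `n > p` and `X` is numerically full rank (condition number below
#' `cond_cap`); otherwise the caller is directed to the regularized methods.
#'
#' @param X Standardized design matrix (n x p, n > p).
#' @param y Centered response.
#' @param cond_cap Condition-number cap (default 1e12) above which the design
#'   is treated as singular.
#' @return A `gw_fit` with `method = "OLS"` and `lam = 0`.
#' @export
fit_ols <- function(X, y, cond_cap = 1e12) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p > n) {
    abort(sprintf(
      "OLS requires n >= p (got n = %d, p = %d): use fit_ridge(), fit_lasso() or fit_alasso().",
      n, p))
  }
  d <- svd(X, nu = 0, nv = 0)$d
  if (d[p] <= 0 || d[1] / d[p] > cond_cap) {
    abort("X'X is numerically singular: use a regularized method (fit_ridge / fit_lasso).")
  }
  beta <- qr.coef(qr(X), y)
  r <- y - drop(X %*% beta)
  new_gw_fit(beta, lam = 0, method = "OLS",
             objective = sum(r^2) / (2 * n))
}

#' OLS residual error variance
#'
#' `sigma2_e = RSS / (n - p)` from an OLS fit; the degrees of freedom are the
#' residual `n - p`, so the estimate exists only when `n > p`.
#'
#' @param fit A `gw_fit` with `method = "OLS"`.
#' @param X,y The design and response the fit was computed on.
#' @return A list of class `error_variance_estimate` with fields `sigma2_e`,
#'   `dof` and `rss`.
#' @export
estimate_error_variance <- function(fit, X, y) {
  stopifnot(inherits(fit, "gw_fit"))
  if (fit$method != "OLS") abort("Error variance is estimated from an OLS fit.")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort("sigma2_e = RSS/(n - p) requires n > p.")
  rss <- sum((y - drop(X %*% fit$beta))^2)
  structure(list(sigma2_e = rss / (n - p), dof = n - p, rss = rss),
            class = "error_variance_estimate")
}

#' Ridge regression
#'
#' Solves `(X'X + lam * I) beta = X'y` (the penalty on the raw
#' sum-of-squares scale). When `p > n` the solution is computed through the
#' dual identity `beta = X'(XX' + lam * I)^{-1} y`, which is algebraically
#' identical but works in n-dimensional space.
#'
#' @param X Standardized design matrix.
#' @param y Centered response.
#' @param lam Penalty, `lam > 0` (`lam = 0` allowed only for full-rank `X'X`,
#'   where it reduces to OLS).
#' @return A `gw_fit` with `method = "RR"`.
#' @export
fit_ridge <- function(X, y, lam) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0) {
    abort("`lam` must be a single value >= 0.")
  }
  n <- nrow(X); p <- ncol(X)
  if (lam == 0) {
    fit <- fit_ols(X, y)
    return(new_gw_fit(fit$beta, lam = 0, method = "RR", objective = fit$objective))
  }
  if (p <= n) {
    A <- crossprod(X)
    diag(A) <- diag(A) + lam
    beta <- drop(solve(A, crossprod(X, y)))
  } else {
    K <- tcrossprod(X)
    diag(K) <- diag(K) + lam
    beta <- drop(crossprod(X, solve(K, y)))
  }
  r <- y - drop(X %*% beta)
  new_gw_fit(beta, lam = lam, method = "RR",
             objective = sum(r^2) + lam * sum(beta^2))
}

#' GBLUP predictions from a genomic relationship matrix
#'
#' Genomic BLUP is ridge regression in its random-effects form: with
#' `G = XX'` and `lam = sigma2_e / sigma2_g`, the predicted genetic values
#' are `g_hat = G (G + lam * I)^{-1} y`, identical to the ridge predictions
#' `X beta_RR(lam)`.
#'
#' @param Gmat Symmetric positive semi-definite n x n genomic relationship
#'   matrix (typically `tcrossprod(X)`, optionally scaled).
#' @param y Centered response.
#' @param lam Ratio penalty, `lam > 0`.
#' @return Numeric vector of predicted genetic values, length n.
#' @export
fit_gblup <- function(Gmat, y, lam) {
  Gmat <- as.matrix(Gmat); y <- as.numeric(y)
  if (nrow(Gmat) != ncol(Gmat) ||
      max(abs(Gmat - t(Gmat))) > 1e-8 * max(1, max(abs(Gmat)))) {
    abort("`Gmat` must be a symmetric matrix.")
  }
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0) abort("`lam` must be > 0.")
  A <- Gmat
  diag(A) <- diag(A) + lam
  drop(Gmat %*% solve(A, y))
}

#' Adaptive-LASSO penalty weights from marginal covariances
#'
#' The marginal association of marker j is `c_j = |x_j' y| / n` (the absolute
#' marginal covariance on a standardized design). The default `"inverse"`
#' mode returns `w_j = 1 / (c_j + eps)`, so strongly associated markers are
#' penalized less — the adaptive-LASSO construction that reduces shrinkage
#' bias on large effects. The `"literal"` mode returns `w_j = c_j` itself
#' (floored at `eps` so weights stay positive), provided for sensitivity
#' analysis against the opposite reading of the weighting rule.
#'
#' @param X Standardized design matrix.
#' @param y Centered response.
#' @param mode `"inverse"` (default) or `"literal"`.
#' @param eps Guard added to (or flooring) the covariances; default
#'   `1e-8 * max(c_j)`.
#' @return Positive numeric weight vector, length p.
#' @export
alasso_weights <- function(X, y, mode = c("inverse", "literal"), eps = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  cj <- abs(drop(crossprod(X, y))) / n
  if (is.null(eps)) eps <- 1e-8 * max(cj, .Machine$double.eps)
  w <- switch(mode,
    inverse = 1 / (cj + eps),
    literal = pmax(cj, eps)
  )
  stopifnot(all(is.finite(w)), all(w > 0))
  w
}

#' LASSO / adaptive LASSO by cyclic coordinate descent
#'
#' Minimizes `(1/(2n)) ||y - X beta||^2 + lam * sum_j w_j |beta_j|` by cyclic
#' coordinate descent with the soft-thresholding update
#' `beta_j <- S(x_j' r_(-j) / n, lam * w_j) / (x_j' x_j / n)`. With unit
#' weights this is the LASSO; with [alasso_weights()] it is the adaptive
#' LASSO. The 1/(2n) loss scaling makes `lam_max = max_j |x_j'y| / (n w_j)`
#' the exact threshold above which the solution is identically zero, and
#' keeps lambda grids comparable across sample sizes (a penalty written as
#' `lam_raw * sum |beta_j|` against the unscaled RSS corresponds to
#' `lam_raw = 2 n * lam`).
#'
#' @param X Standardized design matrix.
#' @param y Centered response.
#' @param lam Penalty `>= 0` on the 1/(2n) loss scale.
#' @param weights Optional positive penalty weights, length p (default all 1).
#' @param beta_init Optional warm-start coefficients.
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep (default 1e-7).
#' @param max_sweeps Sweep cap (default 10000); if exceeded the fit is
#'   returned with `converged = FALSE` and a warning.
#' @return A `gw_fit` with `method = "LASSO"` (or `"ALASSO"` when weights are
#'   supplied), including the per-sweep objective trace in attribute
#'   `"objective_trace"`.
#' @export
fit_lasso <- function(X, y, lam, weights = NULL, beta_init = NULL,
                      tol = 1e-7, max_sweeps = 10000L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0) abort("`lam` must be >= 0.")
  method <- "LASSO"
  if (is.null(weights)) {
    w <- rep(1, p)
  } else {
    if (length(weights) != p) abort("`weights` must have length p.")
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      abort("`weights` must be positive and finite.")
    }
    w <- as.numeric(weights)
    method <- "ALASSO"
  }
  b0 <- if (is.null(beta_init)) rep(0, p) else as.numeric(beta_init)
  res <- .cd_lasso(X, y, lam, w, b0, tol, as.integer(max_sweeps))
  if (!res$converged) {
    warn(sprintf("Coordinate descent hit max_sweeps = %d without converging (lam = %.4g).",
                 max_sweeps, lam))
  }
  fit <- new_gw_fit(res$beta, lam = lam, method = method,
                    weights = if (method == "ALASSO") w else NULL,
                    n_iter = res$n_iter, converged = res$converged,
                    objective = res$objective)
  attr(fit, "objective_trace") <- res$objective_trace
  fit
}

#' @rdname fit_lasso
#' @param mode Weight mode passed to [alasso_weights()] when `weights` is
#'   NULL.
#' @export
fit_alasso <- function(X, y, lam, weights = NULL, mode = "inverse",
                       beta_init = NULL, tol = 1e-7, max_sweeps = 10000L) {
  if (is.null(weights)) weights <- alasso_weights(X, y, mode = mode)
  fit_lasso(X, y, lam, weights = weights, beta_init = beta_init,
            tol = tol, max_sweeps = max_sweeps)
}

#' Logarithmic lambda grid
#'
#' `lam_max = max_j |x_j' y| / (n w_j)` is the smallest penalty at which the
#' (weighted) LASSO solution is identically zero; the grid is `n_lambda`
#' log-spaced values from `lam_max` down to `lam_max * min_ratio`.
#'
#' @param X Standardized design matrix.
#' @param y Centered response.
#' @param weights Optional penalty weights (as in [fit_lasso()]).
#' @param n_lambda Number of grid values (default 100).
#' @param min_ratio `lam_min / lam_max`; default 0.01 when p > n and 1e-4
#'   otherwise.
#' @return An object of class `lambda_grid`: list with `values` (strictly
#'   decreasing), `n_lambda`, `min_ratio`.
#' @export
lambda_grid <- function(X, y, weights = NULL, n_lambda = 100L, min_ratio = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n_lambda < 2L) abort("`n_lambda` must be >= 2.")
  if (is.null(min_ratio)) min_ratio <- if (p > n) 0.01 else 1e-4
  if (min_ratio <= 0 || min_ratio >= 1) abort("`min_ratio` must be in (0, 1).")
  w <- if (is.null(weights)) rep(1, p) else as.numeric(weights)
  cj <- abs(drop(crossprod(X, y))) / (n * w)
  lam_max <- max(cj)
  if (lam_max == 0) abort("All marginal covariances are zero: no signal to build a grid from.")
  values <- exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_lambda))
  structure(list(values = values, n_lambda = as.integer(n_lambda),
                 min_ratio = min_ratio),
            class = "lambda_grid")
}

#' Fit a regularization path
#'
#' One fit per grid value, from `lam_max` downward. LASSO/ALASSO fits are
#' warm-started from the previous (more penalized) solution; ridge fits are
#' computed in closed form through a single eigendecomposition shared across
#' the whole grid. For ridge, the grid value `lam` (1/(2n) loss scale) maps
#' to the raw normal-equations penalty `n * lam`, and the default ridge grid
#' is inflated by `ridge_scale` because the ridge path never reaches an exact
#' null model.
#'
#' @param X Standardized training design.
#' @param y Centered training response.
#' @param method `"RR"`, `"LASSO"` or `"ALASSO"`.
#' @param grid A [lambda_grid()]; default built from `X`, `y` (and weights).
#' @param weights ALASSO penalty weights; computed via [alasso_weights()]
#'   with `mode` when NULL and `method = "ALASSO"`.
#' @param mode Weight mode for ALASSO (default `"inverse"`).
#' @param n_lambda,min_ratio Passed to [lambda_grid()] when `grid` is NULL.
#' @param ridge_scale Multiplier applied to the default grid for `"RR"`
#'   (default 1000, so the ridge path spans penalties strong enough to
#'   approach the null model).
#' @param tol,max_sweeps Coordinate-descent controls.
#' @return An object of class `gw_path`: list with `fits` (list of `gw_fit`),
#'   `grid`, `method`, `weights`.
#' @export
fit_path <- function(X, y, method = c("RR", "LASSO", "ALASSO"), grid = NULL,
                     weights = NULL, mode = "inverse", n_lambda = 100L,
                     min_ratio = NULL, ridge_scale = 1000,
                     tol = 1e-7, max_sweeps = 10000L) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (method == "ALASSO" && is.null(weights)) {
    weights <- alasso_weights(X, y, mode = mode)
  }
  if (is.null(grid)) {
    grid <- lambda_grid(X, y, weights = weights, n_lambda = n_lambda,
                        min_ratio = min_ratio)
    if (method == "RR") grid$values <- grid$values * ridge_scale
  }
  stopifnot(inherits(grid, "lambda_grid"))

  fits <- vector("list", length(grid$values))
  if (method == "RR") {
    # shared eigendecomposition: primal when p <= n, dual otherwise
    if (p <= n) {
      E <- eigen(crossprod(X), symmetric = TRUE)
      Vty <- drop(crossprod(E$vectors, crossprod(X, y)))
      for (k in seq_along(grid$values)) {
        lam_raw <- n * grid$values[k]
        beta <- drop(E$vectors %*% (Vty / (pmax(E$values, 0) + lam_raw)))
        fits[[k]] <- new_gw_fit(beta, lam = grid$values[k], method = "RR")
      }
    } else {
      E <- eigen(tcrossprod(X), symmetric = TRUE)
      Uty <- drop(crossprod(E$vectors, y))
      for (k in seq_along(grid$values)) {
        lam_raw <- n * grid$values[k]
        alpha <- drop(E$vectors %*% (Uty / (pmax(E$values, 0) + lam_raw)))
        fits[[k]] <- new_gw_fit(drop(crossprod(X, alpha)),
                                lam = grid$values[k], method = "RR")
      }
    }
  } else {
    beta <- rep(0, p)
    for (k in seq_along(grid$values)) {
      fit <- fit_lasso(X, y, grid$values[k], weights = weights,
                       beta_init = beta, tol = tol, max_sweeps = max_sweeps)
      beta <- fit$beta
      fits[[k]] <- fit
    }
  }
  structure(list(fits = fits, grid = grid, method = method, weights = weights),
            class = "gw_path")
}

#' @export
print.gw_path <- function(x, ...) {
  cat(sprintf("<gw_path %s: %d lambda values in [%.4g, %.4g]>\n",
              x$method, length(x$grid$values),
              min(x$grid$values), max(x$grid$values)))
  invisible(x)
}

#' @export
predict.gw_path <- function(object, newX, ...) {
  B <- vapply(object$fits, `[[`, numeric(length(object$fits[[1]]$beta)), "beta")
  as.matrix(newX) %*% B
}
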