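#' Test mean squared error
#'
#' `MSE = (1/n) sum_i (y_i - yhat_i)^2` on a hold-out set — the loss this
#' package recommends for model selection, because it is sensitive to both
#' the bias and the variance of the predictions.
#'
#' @param y Observed test responses.
#' @param yhat Predicted test responses.
#' @return A single non-negative number.
#' @export
mse <- function(y, yhat) {
  check_pair(y, yhat, min_n = 1L)
  mean((y - yhat)^2)
}

#' Squared Pearson correlation between observed and predicted
#'
#' `r2 = COV[y, yhat]^2 / (VAR[y] VAR[yhat])` with population (divide-by-n)
#' moments. This "predictive correlation accuracy" is invariant under affine
#' maps of the predictions (`a * yhat + b` gives the same r2), which is
#' precisely why it can rank a badly scaled model above a well calibrated
#' one. A constant predictor has no predictive correlation; by convention the
#' value is 0 with a warning.
#'
#' @inheritParams mse
#' @return A number in \[0, 1\].
#' @export
r2_pearson <- function(y, yhat) {
  check_pair(y, yhat, min_n = 2L)
  vy <- pop_var(y)
  if (vy <= 0) abort("r2_pearson needs var(y) > 0.")
  vh <- pop_var(yhat)
  if (vh <= 0) {
    warn("Constant predictions: r2_pearson defined as 0.",
         class = "gwpred_constant_predictor")
    return(0)
  }
  pop_cov(y, yhat)^2 / (vy * vh)
}

#' Coefficient of determination on the test set
#'
#' `R2 = 1 - sum (y_i - yhat_i)^2 / sum (y_i - ybar)^2`, with `ybar` the mean
#' of the supplied test responses. Unlike the squared Pearson correlation it
#' penalizes scale and location errors in the predictions, and it can be
#' negative when the model predicts worse than the test mean. For a fixed
#' test set it is a monotone decreasing transform of the test MSE.
#'
#' @inheritParams mse
#' @return A number `<= 1` (possibly negative).
#' @export
r2_determination <- function(y, yhat) {
  check_pair(y, yhat, min_n = 2L)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) abort("r2_determination needs a non-constant y.")
  1 - sum((y - yhat)^2) / tss
}

#' Full evaluation report for one model on one split
#'
#' Computes the three competing statistics and the moment decomposition of
#' the squared Pearson correlation in one pass: MSE, r2, R2, COV\[y, yhat\],
#' VAR\[y\] and VAR\[yhat\]. The decomposition makes the failure mode of r2
#' visible: regularization shrinks VAR\[yhat\] while VAR\[y\] is fixed, so r2
#' can stay high for a model whose predictions are badly shrunken.
#'
#' @inheritParams mse
#' @param moments `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1) for the COV/VAR cells; r2 itself is invariant to the
#'   choice.
#' @return A one-row tibble of class `gw_eval` with columns `mse`,
#'   `r2_pearson`, `r2_determination`, `cov_y_yhat`, `var_y`, `var_yhat`,
#'   `n_test`.
#' @export
decompose <- function(y, yhat, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  check_pair(y, yhat, min_n = 2L)
  denom_adj <- if (moments == "population") 1 else length(y) / (length(y) - 1)
  out <- tibble::tibble(
    mse = mse(y, yhat),
    r2_pearson = r2_pearson(y, yhat),
    r2_determination = r2_determination(y, yhat),
    cov_y_yhat = pop_cov(y, yhat) * denom_adj,
    var_y = pop_var(y) * denom_adj,
    var_yhat = pop_var(yhat) * denom_adj,
    n_test = length(y)
  )
  class(out) <- c("gw_eval", class(out))
  out
}

check_pair <- function(y, yhat, min_n) {
  if (length(y) != length(yhat)) {
    abort(sprintf("Length mismatch: y has %d values, yhat has %d.",
                  length(y), length(yhat)))
  }
  if (length(y) < min_n) abort(sprintf("Need at least %d observations.", min_n))
  invisible(TRUE)
}

pop_var <- function(x) mean((x - mean(x))^2)
pop_cov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Effective degrees of freedom of ridge regression
#'
#' `df(lam) = tr[X'X (X'X + lam I)^{-1}] = sum_i d_i / (d_i + lam)` over the
#' eigenvalues `d_i` of `X'X`. Decreases from `rank(X)` at `lam = 0` to 0 as
#' `lam -> Inf`.
#'
#' @param X Design matrix.
#' @param lam Raw ridge penalty `> 0` (normal-equations scale).
#' @return A single number.
#' @export
ridge_df <- function(X, lam) {
  X <- as.matrix(X)
  d <- svd(X, nu = 0, nv = 0)$d^2
  sum(d / (d + lam))
}

#' Unbiased-risk (Cp-style) tuning criterion for ridge regression
#'
#' `RSS(lam) - n * sigma2_e + 2 * sigma2_e * df(lam)`, with the effective
#' degrees of freedom `df(lam)` from [ridge_df()]. Requires an external
#' estimate of the error variance (an `n > p` sub-problem via
#' [estimate_error_variance()], or a known value), which is exactly what
#' limits Cp-style criteria in p >> n genomics — hold-out MSE does not.
#'
#' @param X Training design.
#' @param y Training response.
#' @param lam Raw ridge penalty `> 0`.
#' @param sigma2_e An `error_variance_estimate` or a single positive number.
#' @return The criterion value (smaller is better).
#' @export
ridge_cp_criterion <- function(X, y, lam, sigma2_e) {
  if (inherits(sigma2_e, "error_variance_estimate")) sigma2_e <- sigma2_e$sigma2_e
  if (!is.numeric(sigma2_e) || length(sigma2_e) != 1L || !is.finite(sigma2_e) ||
      sigma2_e < 0) {
    abort("A valid sigma2_e estimate is required (see estimate_error_variance()).")
  }
  if (lam <= 0) abort("`lam` must be > 0.")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  fit <- fit_ridge(X, y, lam)
  rss <- sum((y - drop(X %*% fit$beta))^2)
  rss - n * sigma2_e + 2 * sigma2_e * ridge_df(X, lam)
}

#' Evaluate every fit of a path on a test set
#'
#' @param path A `gw_path`.
#' @param X_test Test design on the training standardization scale.
#' @param y_test Centered test responses.
#' @param moments Moment convention for the COV/VAR columns (see
#'   [decompose()]).
#' @return A tibble with one row per lambda: `lambda`, `n_nonzero` and the
#'   [decompose()] columns.
#' @export
evaluate_path <- function(path, X_test, y_test, moments = "population") {
  stopifnot(inherits(path, "gw_path"))
  preds <- predict(path, X_test)
  purrr::map_dfr(seq_along(path$fits), function(k) {
    # the null model at lambda_max predicts a constant by design; its r2 = 0
    # convention needs no per-lambda warning here
    rep_k <- withCallingHandlers(
      decompose(y_test, preds[, k], moments = moments),
      gwpred_constant_predictor = function(w) invokeRestart("muffleWarning")
    )
    dplyr::bind_cols(
      tibble::tibble(lambda = path$grid$values[k],
                     n_nonzero = sum(path$fits[[k]]$beta != 0)),
      rep_k
    )
  })
}

#' Select the best penalty on a path under one criterion
#'
#' Scans the per-lambda test metrics and returns the extremal grid point:
#' smallest test MSE (`"min_mse"`), largest squared Pearson correlation
#' (`"max_r2"`), largest coefficient of determination (`"max_R2"`), or the
#' smallest Cp-style criterion (`"cp_variant"`, ridge only, needs
#' `sigma2_e`). Ties are broken toward the larger lambda (more
#' regularization).
#'
#' @param path A `gw_path`.
#' @param X_test,y_test Hold-out design and centered responses.
#' @param criterion One of `"min_mse"`, `"max_r2"`, `"max_R2"`,
#'   `"cp_variant"`.
#' @param sigma2_e Error-variance estimate, required for `"cp_variant"`.
#' @param X_train,y_train Training data, required for `"cp_variant"`.
#' @return An object of class `gw_selection`: list with `criterion`,
#'   `best_lambda`, `best_index`, `best_fit`, `best_report` (one-row tibble)
#'   and `metrics` (the full per-lambda tibble).
#' @export
select_model <- function(path, X_test, y_test,
                         criterion = c("min_mse", "max_r2", "max_R2", "cp_variant"),
                         sigma2_e = NULL, X_train = NULL, y_train = NULL) {
  criterion <- match.arg(criterion)
  metrics <- evaluate_path(path, X_test, y_test)
  score <- switch(criterion,
    min_mse = metrics$mse,
    max_r2 = -metrics$r2_pearson,
    max_R2 = -metrics$r2_determination,
    cp_variant = {
      if (is.null(sigma2_e) || is.null(X_train) || is.null(y_train)) {
        abort("cp_variant needs `sigma2_e`, `X_train` and `y_train`.")
      }
      n <- nrow(as.matrix(X_train))
      vapply(path$grid$values, function(l) {
        ridge_cp_criterion(X_train, y_train, n * l, sigma2_e)
      }, numeric(1))
    }
  )
  # grid is stored decreasing, so the first index among ties is the larger lambda
  best <- which(score <= min(score) + 0)[1L]
  structure(list(criterion = criterion,
                 best_lambda = path$grid$values[best],
                 best_index = best,
                 best_fit = path$fits[[best]],
                 best_report = metrics[best, ],
                 metrics = metrics),
            class = "gw_selection")
}

#' @export
print.gw_selection <- function(x, ...) {
  cat(sprintf("<gw_selection %s: lambda = %.4g (index %d), MSE = %.4g, r2 = %.3f, R2 = %.3f>\n",
              x$criterion, x$best_lambda, x$best_index,
              x$best_report$mse, x$best_report$r2_pearson,
              x$best_report$r2_determination))
  invisible(x)
}

#' Rank individuals by predicted value
#'
#' Top-k individuals by predicted phenotype / genomic value, descending;
#' ties are broken by ascending identifier so rankings are deterministic.
#'
#' @param yhat Predicted values.
#' @param ids Individual identifiers, same length.
#' @param k Number of individuals to return (`k <= length(yhat)`).
#' @return A tibble with columns `rank`, `id`, `predicted` (non-increasing).
#' @export
rank_individuals <- function(yhat, ids, k = 10L) {
  if (length(yhat) != length(ids)) abort("`yhat` and `ids` must have equal length.")
  if (anyDuplicated(ids)) abort("`ids` must be unique.")
  if (k > length(yhat)) abort(sprintf("k = %d exceeds the %d available individuals.",
                                      k, length(yhat)))
  ord <- order(-yhat, as.character(ids))
  top <- ord[seq_len(k)]
  tibble::tibble(rank = seq_len(k), id = as.character(ids)[top],
                 predicted = as.numeric(yhat)[top])
}

#' Agreement between two rankings
#'
#' Spearman's rho and Kendall's tau on the full orderings, plus the top-k
#' overlap fraction. Inputs may be ranking tibbles from [rank_individuals()]
#' (their common length sets k) or full orderings given as character vectors
#' of ids, best first.
#'
#' @param r1,r2 Rankings over the same set of identifiers.
#' @param k Top-k for the overlap fraction; defaults to the table length (or
#'   full length for plain orderings).
#' @return A list with `spearman`, `kendall`, `topk_overlap`.
#' @export
rank_agreement <- function(r1, r2, k = NULL) {
  tables <- is.data.frame(r1) || is.data.frame(r2)
  ids1 <- if (is.data.frame(r1)) r1$id else as.character(r1)
  ids2 <- if (is.data.frame(r2)) r2$id else as.character(r2)
  if (!tables && !setequal(ids1, ids2)) {
    abort("Rankings cover different sets of identifiers.")
  }
  if (is.null(k)) k <- min(length(ids1), length(ids2))
  full <- setequal(ids1, ids2) && length(ids1) == length(ids2)
  sp <- ke <- NA_real_
  if (full) {
    universe <- sort(unique(ids1))
    rk1 <- match(universe, ids1)
    rk2 <- match(universe, ids2)
    sp <- cor(rk1, rk2, method = "spearman")
    ke <- cor(rk1, rk2, method = "kendall")
  }
  ov <- length(intersect(head(ids1, k), head(ids2, k))) / k
  list(spearman = sp, kendall = ke, topk_overlap = ov)
}
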