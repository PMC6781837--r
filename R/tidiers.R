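#' Tidy a fitted model
#'
#' @param x A `gw_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate` and
#'   (for ALASSO) `weight`.
#' @method tidy gw_fit
#' @export
tidy.gw_fit <- function(x, ...) {
  out <- tibble::tibble(term = paste0("snp_", seq_along(x$beta)),
                        estimate = x$beta)
  if (!is.null(x$weights)) out$weight <- x$weights
  out
}

#' @rdname tidy.gw_fit
#' @method glance gw_fit
#' @export
glance.gw_fit <- function(x, ...) {
  tibble::tibble(method = x$method, lambda = x$lam,
                 n_nonzero = sum(x$beta != 0),
                 n_iter = x$n_iter, converged = x$converged,
                 objective = x$objective)
}

#' Tidy a regularization path
#'
#' @param x A `gw_path`.
#' @param ... Unused.
#' @return Long tibble: `lambda`, `term`, `estimate` (zero coefficients
#'   included).
#' @method tidy gw_path
#' @export
tidy.gw_path <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    dplyr::mutate(tidy(f), lambda = f$lam, .before = 1L)
  })
}

#' @rdname tidy.gw_path
#' @method glance gw_path
#' @export
glance.gw_path <- function(x, ...) {
  purrr::map_dfr(x$fits, glance)
}

#' @method tidy gw_selection
#' @export
tidy.gw_selection <- function(x, ...) x$metrics

#' @method glance gw_selection
#' @export
glance.gw_selection <- function(x, ...) {
  dplyr::mutate(x$best_report, criterion = x$criterion,
                best_lambda = x$best_lambda, .before = 1L)
}

#' @method tidy gw_experiment
#' @export
tidy.gw_experiment <- function(x, ...) x$metrics

#' @method glance gw_experiment
#' @export
glance.gw_experiment <- function(x, ...) x$table1
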