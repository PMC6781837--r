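#' Experiment configuration
#'
#' Describes one full model-comparison run: the data source (genotype +
#' phenotype files, or a [sim_config()] to simulate), the MAF threshold,
#' the fixed leading-train / trailing-test split, the methods and their path
#' settings, and the selection criteria to compare.
#'
#' @param genotypes,phenotypes File paths (ignored when `sim` is given).
#' @param sim Optional [sim_config()]; when supplied the data are simulated.
#' @param maf MAF threshold (default 0.01).
#' @param train_last Last training individual, 1-based (default 2326).
#' @param methods Methods to fit (default RR, LASSO, ALASSO).
#' @param criteria Selection criteria (default min_mse, max_r2, max_R2).
#' @param n_lambda Path length (default 100).
#' @param min_ratio Grid ratio; NULL = solver default.
#' @param weight_mode ALASSO weight mode (default "inverse").
#' @param stats_from `"all"` (standardization statistics from the whole
#'   matrix, the default, matching a single-matrix standardization) or
#'   `"train"` (training rows only; leakage-free).
#' @param moments Moment convention for the COV/VAR report columns.
#' @param top_k Ranking length for the per-criterion ranking table
#'   (default 10).
#' @param out_dir Optional directory for the CSV reports.
#' @param seed Seed (only consumed by the simulator).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(genotypes = NULL, phenotypes = NULL, sim = NULL,
                              maf = 0.01, train_last = 2326L,
                              methods = c("RR", "LASSO", "ALASSO"),
                              criteria = c("min_mse", "max_r2", "max_R2"),
                              n_lambda = 100L, min_ratio = NULL,
                              weight_mode = "inverse",
                              stats_from = c("all", "train"),
                              moments = "population", top_k = 10L,
                              out_dir = NULL, seed = 1L) {
  stats_from <- match.arg(stats_from)
  if (is.null(sim) && (is.null(genotypes) || is.null(phenotypes))) {
    abort("Provide either `sim` or both `genotypes` and `phenotypes`.")
  }
  if (length(methods) < 1L || length(criteria) < 1L) {
    abort("At least one method and one criterion are required.")
  }
  methods <- match.arg(methods, c("RR", "LASSO", "ALASSO"), several.ok = TRUE)
  criteria <- match.arg(criteria, c("min_mse", "max_r2", "max_R2"), several.ok = TRUE)
  structure(list(genotypes = genotypes, phenotypes = phenotypes, sim = sim,
                 maf = maf, train_last = as.integer(train_last),
                 methods = methods, criteria = criteria,
                 n_lambda = as.integer(n_lambda), min_ratio = min_ratio,
                 weight_mode = weight_mode, stats_from = stats_from,
                 moments = moments, top_k = as.integer(top_k),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full model-comparison experiment
#'
#' Load (or simulate) genotypes and phenotypes, MAF-filter, split into the
#' fixed leading-train / trailing-test sets, standardize, fit a
#' regularization path per method, evaluate every fit on the hold-out set,
#' select the best penalty under each criterion, and assemble the two
#' report tables: a method-by-metric grid (each metric at its own optimal
#' penalty, with the moment decomposition taken at the MSE-optimal fit) and
#' a method-by-criterion top-k ranking grid. Deterministic given the
#' configuration and seed. Note that within one method's path the
#' MSE-optimal and R2-optimal penalties coincide (R2 is a monotone transform
#' of MSE on a fixed test set), so any disagreement between criteria is a
#' cross-method phenomenon; the run asserts this identity.
#'
#' @param cfg An [experiment_config()].
#' @param quiet Suppress stage logging? Default TRUE.
#' @return An object of class `gw_experiment`: list with `paths`,
#'   `selections` (nested per method/criterion), `table1`, `table2`,
#'   `metrics` (per-method per-lambda tibble), `winners`, `split`, `config`,
#'   `provenance`.
#' @export
run_experiment <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf("[gwpred %s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))

  if (!is.null(cfg$sim)) {
    say("simulating data (seed %d)", cfg$sim$seed)
    simout <- simulate_qtlmas(cfg$sim)
    g <- simout$genotypes
    y_raw <- simout$phenotypes
  } else {
    say("reading %s", cfg$genotypes)
    g <- read_genotypes(cfg$genotypes)
    y_raw <- read_phenotypes(cfg$phenotypes)
  }
  say("loaded %d individuals x %d markers", nrow(g), ncol(g))

  g <- maf_filter(g, cfg$maf)
  say("MAF filter at %g retained %d markers", cfg$maf, ncol(g))

  split <- make_split(nrow(g), cfg$train_last)
  stats_rows <- if (cfg$stats_from == "train") split$train_index else NULL
  design <- standardize(g, y_raw, stats_from = stats_rows)
  X_tr <- design$X[split$train_index, , drop = FALSE]
  X_te <- design$X[split$test_index, , drop = FALSE]
  y_tr <- design$y[split$train_index]
  y_te <- design$y[split$test_index]
  test_ids <- rownames(g)[split$test_index]

  paths <- list(); selections <- list(); metric_rows <- list()
  for (m in cfg$methods) {
    say("fitting %s path (%d lambdas)", m, cfg$n_lambda)
    paths[[m]] <- fit_path(X_tr, y_tr, method = m, n_lambda = cfg$n_lambda,
                           min_ratio = cfg$min_ratio, mode = cfg$weight_mode)
    selections[[m]] <- list()
    for (cr in cfg$criteria) {
      selections[[m]][[cr]] <- select_model(paths[[m]], X_te, y_te, criterion = cr)
    }
    metric_rows[[m]] <- dplyr::mutate(selections[[m]][[1L]]$metrics, method = m,
                                      .before = 1L)
  }
  metrics <- dplyr::bind_rows(metric_rows)

  # within-path identity: min-MSE and max-R2 pick the same lambda
  if (all(c("min_mse", "max_R2") %in% cfg$criteria)) {
    for (m in cfg$methods) {
      stopifnot(selections[[m]][["min_mse"]]$best_index ==
                selections[[m]][["max_R2"]]$best_index)
    }
  }

  table1 <- purrr::map_dfr(cfg$methods, function(m) {
    met <- selections[[m]][[1L]]$metrics
    best_mse_i <- selections[[m]][["min_mse"]]$best_index %||%
      which.min(met$mse)[1L]
    at_mse <- met[best_mse_i, ]
    tibble::tibble(
      method = m,
      mse = min(met$mse),
      r2_pearson = max(met$r2_pearson),
      r2_determination = max(met$r2_determination),
      cov_y_yhat = at_mse$cov_y_yhat,
      var_yhat = at_mse$var_yhat,
      var_y = at_mse$var_y,
      lambda_min_mse = met$lambda[best_mse_i],
      n_nonzero_min_mse = at_mse$n_nonzero
    )
  })

  table2 <- purrr::map_dfr(cfg$methods, function(m) {
    purrr::map_dfr(cfg$criteria, function(cr) {
      sel <- selections[[m]][[cr]]
      yhat <- predict(sel$best_fit, X_te)
      rk <- rank_individuals(yhat, test_ids, k = min(cfg$top_k, length(yhat)))
      dplyr::mutate(rk, method = m, criterion = cr, .before = 1L)
    })
  })

  winners <- purrr::map_dfr(cfg$criteria, function(cr) {
    vals <- vapply(cfg$methods, function(m) {
      rep_ <- selections[[m]][[cr]]$best_report
      switch(cr, min_mse = rep_$mse, max_r2 = rep_$r2_pearson,
             max_R2 = rep_$r2_determination)
    }, numeric(1))
    best <- if (cr == "min_mse") names(which.min(vals)) else names(which.max(vals))
    tibble::tibble(criterion = cr, winner = best,
                   value = unname(vals[best]))
  })

  res <- structure(list(
    paths = paths, selections = selections, metrics = metrics,
    table1 = table1, table2 = table2, winners = winners,
    split = split,
    design_stats = list(col_means = design$col_means, col_sds = design$col_sds,
                        y_mean = design$y_mean),
    sim = if (!is.null(cfg$sim)) simout else NULL,
    config = cfg,
    provenance = list(seed = cfg$seed,
                      config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
                      package_version = as.character(utils::packageVersion("gwpred")),
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "gw_experiment")

  if (!is.null(cfg$out_dir)) {
    write_reports(res, cfg$out_dir)
    say("reports written to %s", cfg$out_dir)
  }
  res
}

#' @export
print.gw_experiment <- function(x, ...) {
  cat("<gw_experiment>\n")
  print(x$table1)
  cat("\nWinners per criterion:\n")
  print(x$winners)
  invisible(x)
}

#' Write the report tables as CSV
#'
#' Emits `table1.csv` (method-by-metric grid) and `table2.csv`
#' (method-by-criterion rankings), each preceded by `#`-prefixed header
#' lines carrying seed and configuration hash.
#'
#' @param res A `gw_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# seed: %d", res$provenance$seed),
           sprintf("# config_hash: %s", res$provenance$config_hash))
  for (nm in c("table1", "table2")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(res[[nm]], path, sep = ",", append = TRUE,
                                        row.names = FALSE, quote = FALSE))
  }
  invisible(dir)
}

#' Read a report table written by [write_reports()]
#'
#' @param path Path to the CSV.
#' @return A tibble (header comment lines are skipped).
#' @export
read_report <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = ",", header = TRUE,
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
}

#' Compare selection criteria across methods
#'
#' Summarizes, per criterion, the winning method, flags criterion pairs
#' whose winners differ (the failure mode of the squared Pearson
#' correlation), and measures the per-method top-k ranking agreement between
#' the MSE-optimal and r2-optimal fits.
#'
#' @param res A `gw_experiment` with at least two methods and two criteria.
#' @return A list with `winners` (tibble), `disagreements` (tibble of
#'   criterion pairs with differing winners) and `ranking_shifts` (tibble:
#'   per-method top-k overlap and rank correlations between the min-MSE and
#'   max-r2 selections, when both criteria are present).
#' @export
compare_criteria <- function(res) {
  stopifnot(inherits(res, "gw_experiment"))
  cfg <- res$config
  if (length(cfg$methods) < 2L || length(cfg$criteria) < 2L) {
    abort("compare_criteria() needs >= 2 methods and >= 2 criteria.")
  }
  w <- res$winners
  pairs <- utils::combn(w$criterion, 2L)
  disagreements <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    c1 <- pairs[1L, i]; c2 <- pairs[2L, i]
    w1 <- w$winner[w$criterion == c1]; w2 <- w$winner[w$criterion == c2]
    tibble::tibble(criterion_1 = c1, criterion_2 = c2,
                   winner_1 = w1, winner_2 = w2, disagree = w1 != w2)
  })
  ranking_shifts <- NULL
  if (all(c("min_mse", "max_r2") %in% cfg$criteria)) {
    ranking_shifts <- purrr::map_dfr(cfg$methods, function(m) {
      t2 <- res$table2
      rk1 <- t2[t2$method == m & t2$criterion == "min_mse", ]
      rk2 <- t2[t2$method == m & t2$criterion == "max_r2", ]
      agr <- rank_agreement(rk1, rk2)
      tibble::tibble(method = m, topk_overlap = agr$topk_overlap,
                     identical_order = identical(rk1$id, rk2$id))
    })
  }
  list(winners = w, disagreements = disagreements[disagreements$disagree, ],
       ranking_shifts = ranking_shifts)
}
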