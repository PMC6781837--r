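#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds biallelic SNP genotypes coded as minor-allele
#' counts (0, 1 or 2), one row per individual and one column per marker,
#' together with individual and marker identifiers. This is the container all
#' downstream filtering, standardization and model fitting operates on.
#'
#' @param codes Integer (or numeric whole-valued) matrix with entries in
#'   \{0, 1, 2\}; rows are individuals, columns are markers.
#' @param individual_ids Character vector of unique individual identifiers.
#'   Defaults to row names of `codes`, or `ind_1 ... ind_n`.
#' @param marker_ids Character vector of unique marker identifiers. Defaults
#'   to column names of `codes`, or `snp_1 ... snp_p`.
#'
#' @return An object of class `genotype_matrix`: the integer code matrix with
#'   identifiers stored as dimnames.
#' @export
genotype_matrix <- function(codes, individual_ids = NULL, marker_ids = NULL) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  if (nrow(codes) < 2L) abort("A genotype matrix needs at least 2 individuals.")
  if (ncol(codes) < 1L) abort("A genotype matrix needs at least 1 marker.")
  bad <- if (is.integer(codes)) {
    which(is.na(codes) | codes < 0L | codes > 2L)
  } else {
    which(!(codes %in% c(0, 1, 2)) | is.na(codes))
  }
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(codes)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(codes)) + 1L
    abort(sprintf(
      "Genotype codes must be 0, 1 or 2: invalid entry '%s' at individual %d, marker %d.",
      as.character(codes[bad[1L]]), i, j
    ))
  }
  storage.mode(codes) <- "integer"
  if (is.null(individual_ids)) {
    individual_ids <- rownames(codes) %||% paste0("ind_", seq_len(nrow(codes)))
  }
  if (is.null(marker_ids)) {
    marker_ids <- colnames(codes) %||% paste0("snp_", seq_len(ncol(codes)))
  }
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (length(individual_ids) != nrow(codes)) {
    abort("`individual_ids` length must equal the number of rows.")
  }
  if (length(marker_ids) != ncol(codes)) {
    abort("`marker_ids` length must equal the number of columns.")
  }
  if (anyDuplicated(individual_ids)) abort("Duplicated individual identifiers.")
  if (anyDuplicated(marker_ids)) abort("Duplicated marker identifiers.")
  dimnames(codes) <- list(individual_ids, marker_ids)
  class(codes) <- c("genotype_matrix", "matrix", "array")
  codes
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d individuals x %d markers>\n", nrow(x), ncol(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read genotypes from delimited text
#'
#' Reads an individuals-by-markers table of 0/1/2 codes. The
#' `"delimited-codes"` dialect is plain whitespace- or comma-separated text
#' with an optional header row of marker IDs and an optional first column of
#' individual IDs (both auto-detected). The `"plink-raw-like"` dialect expects
#' the six leading columns of a PLINK `.raw` export (FID IID PAT MAT SEX
#' PHENOTYPE) followed by per-marker allele counts.
#'
#' @param path Path to the text file.
#' @param dialect One of `"delimited-codes"` (default) or `"plink-raw-like"`.
#' @param sep Field separator; `NULL` (default) means any whitespace, with a
#'   comma auto-detected from the first line.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("delimited-codes", "plink-raw-like"),
                           sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("Genotype file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("Genotype file '%s' is empty.", path))
  if (is.null(sep)) sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else ""

  split_line <- function(x) {
    if (sep == "") strsplit(trimws(x), "[[:space:]]+")[[1L]]
    else trimws(strsplit(x, sep, fixed = TRUE)[[1L]])
  }
  tokens <- lapply(lines, split_line)

  if (dialect == "plink-raw-like") {
    header <- tokens[[1L]]
    if (length(header) <= 6L) abort("plink-raw-like file needs >6 columns.")
    marker_ids <- header[-(1:6)]
    body <- tokens[-1L]
    codes <- parse_code_rows(body, keep = -(1:6), n_expected = length(header),
                             line_offset = 1L)
    ind <- vapply(body, function(tk) tk[[2L]], character(1))
    return(genotype_matrix(codes, individual_ids = ind, marker_ids = marker_ids))
  }

  first <- tokens[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  body <- if (has_header) tokens[-1L] else tokens
  if (length(body) == 0L) abort("Genotype file has a header but no data rows.")
  # first column is IDs if any body row starts with a non-numeric token, or if
  # the header has one fewer field than the data rows
  first_col <- vapply(body, function(tk) tk[[1L]], character(1))
  has_ids <- anyNA(suppressWarnings(as.numeric(first_col)))
  n_fields <- length(body[[1L]])
  if (has_header && length(first) == n_fields - 1L) has_ids <- TRUE
  keep <- if (has_ids) -1L else TRUE
  codes <- parse_code_rows(body, keep = keep, n_expected = n_fields,
                           line_offset = if (has_header) 1L else 0L)
  marker_ids <- if (has_header) {
    if (has_ids && length(first) == ncol(codes) + 1L) first[-1L] else first
  } else NULL
  ind <- if (has_ids) first_col else NULL
  genotype_matrix(codes, individual_ids = ind, marker_ids = marker_ids)
}

parse_code_rows <- function(body, keep, n_expected, line_offset) {
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    tk <- body[[i]]
    if (length(tk) != n_expected) {
      abort(sprintf("Malformed genotype row at line %d: expected %d fields, found %d.",
                    i + line_offset, n_expected, length(tk)))
    }
    v <- suppressWarnings(as.numeric(if (isTRUE(keep)) tk else tk[keep]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      abort(sprintf("Non-numeric genotype code at line %d, field %d.",
                    i + line_offset, j))
    }
    rows[[i]] <- v
  }
  do.call(rbind, rows)
}

#' Read phenotypes (one value per line)
#'
#' @param path Path to a text file with one numeric phenotype per line, in the
#'   same individual order as the genotype file.
#' @return Numeric vector.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("Phenotype file not found: '%s'", path))
  scan(path, what = numeric(), quiet = TRUE)
}

#' Write genotypes / phenotypes as delimited text
#'
#' Round-trip partners of [read_genotypes()] and [read_phenotypes()].
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param sep Field separator (default single space).
#' @param ids Write the individual-ID column and marker-ID header? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, sep = " ", ids = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- unclass(g)
  if (ids) {
    # marker-id header has one fewer field than the data rows, which is how
    # the reader recognizes the leading individual-id column
    writeLines(paste(colnames(m), collapse = sep), con)
    body <- paste(rownames(m), apply(m, 1L, paste, collapse = sep), sep = sep)
  } else {
    body <- apply(m, 1L, paste, collapse = sep)
  }
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_genotypes
#' @param y Numeric phenotype vector.
#' @export
write_phenotypes <- function(y, path) {
  writeLines(format(y, digits = 17, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Load a zipped genotype/phenotype bundle
#'
#' Convenience loader for zip archives that bundle a single delimited table
#' whose first column(s) are phenotypes and remaining columns genotype codes
#' (the layout used by publicly deposited QTLMAS-style datasets), or separate
#' genotype and phenotype files.
#'
#' @param path Path to the zip archive.
#' @param phenotype_col Column index holding the phenotype when the archive
#'   contains one combined table (default 1). Use `NULL` if the archive holds
#'   separate genotype and phenotype files.
#' @param genotype_file,phenotype_file Optional member names when the archive
#'   holds separate files.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `phenotypes` (numeric vector).
#' @export
read_zip_bundle <- function(path, phenotype_col = 1L,
                            genotype_file = NULL, phenotype_file = NULL) {
  if (!file.exists(path)) abort(sprintf("Archive not found: '%s'", path))
  exdir <- tempfile("gwpred_zip_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  members <- utils::unzip(path, exdir = exdir)
  if (length(members) == 0L) abort("Empty zip archive.")
  if (!is.null(genotype_file) || is.null(phenotype_col)) {
    gpath <- if (is.null(genotype_file)) members[[1L]] else file.path(exdir, genotype_file)
    ppath <- if (is.null(phenotype_file)) members[[2L]] else file.path(exdir, phenotype_file)
    return(list(genotypes = read_genotypes(gpath), phenotypes = read_phenotypes(ppath)))
  }
  tab <- as.matrix(read.table(members[[1L]], header = FALSE))
  y <- as.numeric(tab[, phenotype_col])
  codes <- tab[, -phenotype_col, drop = FALSE]
  list(genotypes = genotype_matrix(codes), phenotypes = y)
}

#' Filter markers by minor allele frequency
#'
#' The observed allele frequency of marker j is `f_j = mean(codes_j) / 2`;
#' the marker is kept iff `min(f_j, 1 - f_j) >= threshold`. Marker order is
#' preserved. Monomorphic markers are always removed for any threshold > 0.
#'
#' @param g A [genotype_matrix()].
#' @param threshold MAF threshold in \[0, 0.5\].
#' @return The filtered [genotype_matrix()], with the retained column indices
#'   in attribute `"kept"`.
#' @export
maf_filter <- function(g, threshold) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 0.5) {
    abort("`threshold` must be a single value in [0, 0.5].")
  }
  f <- colMeans(unclass(g)) / 2
  maf <- pmin(f, 1 - f)
  keep <- unname(which(maf >= threshold))
  if (length(keep) == 0L) {
    abort(sprintf("MAF filter at %g removed every marker.", threshold))
  }
  out <- genotype_matrix(unclass(g)[, keep, drop = FALSE],
                         individual_ids = rownames(g),
                         marker_ids = colnames(g)[keep])
  attr(out, "kept") <- keep
  out
}

#' Column-standardize genotypes and center the phenotype
#'
#' Builds the design used by all solvers: each genotype column is transformed
#' to `(code - mean) / sd` with *population* (divide-by-n) standard
#' deviations, so that `x_j' x_j = n` exactly when statistics come from all
#' rows; the phenotype is centered to mean zero. Standardization statistics
#' are computed over the rows in `stats_from` (default: all rows, matching a
#' single-matrix standardization of the full data) and applied to every row,
#' so training-only standardization is available without leakage.
#'
#' @param g A [genotype_matrix()].
#' @param phenotypes Numeric vector, one value per individual.
#' @param stats_from Integer vector of row positions over which means and
#'   standard deviations are computed. Default `NULL` = all rows.
#' @return An object of class `standardized_design`: list with `X`, `y`,
#'   `col_means`, `col_sds`, `y_mean`, `stats_from`.
#' @export
standardize <- function(g, phenotypes, stats_from = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- unclass(g)
  n <- nrow(m)
  if (length(phenotypes) != n) {
    abort(sprintf("Phenotype length (%d) must equal number of individuals (%d).",
                  length(phenotypes), n))
  }
  rows <- if (is.null(stats_from)) seq_len(n) else as.integer(stats_from)
  if (any(rows < 1L | rows > n)) abort("`stats_from` positions out of range.")
  sub <- m[rows, , drop = FALSE]
  col_means <- colMeans(sub)
  col_sds <- sqrt(colMeans(sub^2) - col_means^2) # population convention
  zero_var <- which(col_sds <= 0 | !is.finite(col_sds))
  if (length(zero_var) > 0L) {
    abort(sprintf(
      "Zero-variance marker(s) over the standardization rows: %s. Apply maf_filter() first.",
      paste(colnames(m)[head(zero_var, 10L)], collapse = ", ")
    ))
  }
  X <- sweep(sweep(m + 0.0, 2L, col_means, "-"), 2L, col_sds, "/")
  y_mean <- mean(phenotypes[rows])
  structure(list(
    X = X, y = as.numeric(phenotypes - y_mean),
    col_means = col_means, col_sds = col_sds, y_mean = y_mean,
    stats_from = rows
  ), class = "standardized_design")
}

#' @export
print.standardized_design <- function(x, ...) {
  cat(sprintf("<standardized_design: %d x %d, phenotype centered at %.4g>\n",
              nrow(x$X), ncol(x$X), x$y_mean))
  invisible(x)
}

#' Reconstruct genotype codes from a standardized design
#'
#' Inverse of [standardize()]; used to verify the standardization is lossless.
#'
#' @param design A `standardized_design`.
#' @return Numeric matrix of reconstructed codes.
#' @export
unstandardize <- function(design) {
  stopifnot(inherits(design, "standardized_design"))
  sweep(sweep(design$X, 2L, design$col_sds, "*"), 2L, design$col_means, "+")
}

#' Leading train / trailing test split
#'
#' Individuals `1..train_last` form the training set and the remainder the
#' test set, matching the fixed single split used in genomic-prediction
#' experiments where generations are ordered in the file.
#'
#' @param n Total number of individuals.
#' @param train_last Position (1-based) of the last training individual;
#'   must satisfy `1 <= train_last < n`.
#' @return An object of class `train_test_split`: list with integer vectors
#'   `train_index` and `test_index`.
#' @export
make_split <- function(n, train_last) {
  n <- as.integer(n); train_last <- as.integer(train_last)
  if (is.na(n) || is.na(train_last) || train_last < 1L || train_last >= n) {
    abort(sprintf("`train_last` must satisfy 1 <= train_last < n (got train_last=%s, n=%s).",
                  train_last, n))
  }
  structure(list(train_index = seq_len(train_last),
                 test_index = seq.int(train_last + 1L, n)),
            class = "train_test_split")
}
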