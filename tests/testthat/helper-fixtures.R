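# Shared fixtures: all data are generated in code at test time.

# random design with population-standardized columns and centered response
rand_design <- function(n, p, sparsity = 0, beta = NULL, noise_sd = 1,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2L, colMeans(X), "-")
  X <- sweep(X, 2L, sqrt(colMeans(X^2)), "/")
  if (is.null(beta)) {
    beta <- numeric(p)
    if (sparsity > 0) beta[seq_len(sparsity)] <- rnorm(sparsity, 0, 2)
  }
  y <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  y <- y - mean(y)
  list(X = X, y = y, beta = beta)
}

# orthonormal design: n = p, X'X = I exactly
ortho_design <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(p * p), p, p)))
}

# small genotype matrix with controlled allele frequencies
rand_genotypes <- function(n, p, freq = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freq)) freq <- runif(p, 0.1, 0.9)
  codes <- sapply(freq, function(f) rbinom(n, 2L, f))
  # reroll monomorphic columns until polymorphic (tiny n can fix an allele)
  for (j in seq_len(p)) {
    while (length(unique(codes[, j])) == 1L) codes[, j] <- rbinom(n, 2L, freq[j])
  }
  genotype_matrix(codes)
}

# desk-scale simulation configuration used across simulator tests
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_individuals = 400L, n_founders = 40L, n_generations = 5L,
             n_markers = 600L, n_chromosomes = 6L, founder_pool = 12L,
             seed = seed, ...)
}

# --- minimal stored-entry ZIP writer -----------------------------------------
# The image has no external `zip` tool, so tests build archives directly:
# one uncompressed ("stored") member is enough to exercise the bundle loader.

.crc32_table <- local({
  vapply(0:255, function(n) {
    c <- as.integer(n)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    c
  }, integer(1))
})

.crc32 <- function(bytes) {
  c <- -1L
  for (x in as.integer(bytes)) {
    c <- bitwXor(.crc32_table[bitwAnd(bitwXor(c, x), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  bitwXor(c, -1L)
}

make_stored_zip <- function(zipfile, member_name, content) {
  data <- charToRaw(content)
  fname <- charToRaw(member_name)
  crc <- .crc32(data)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(zipfile, "wb")
  on.exit(close(con))
  # local file header
  writeBin(as.raw(c(0x50, 0x4b, 0x03, 0x04)), con)
  u16(20); u16(0); u16(0); u16(0); u16(0)
  u32(crc); u32(length(data)); u32(length(data))
  u16(length(fname)); u16(0)
  writeBin(fname, con); writeBin(data, con)
  cd_offset <- 30 + length(fname) + length(data)
  # central directory
  writeBin(as.raw(c(0x50, 0x4b, 0x01, 0x02)), con)
  u16(20); u16(20); u16(0); u16(0); u16(0); u16(0)
  u32(crc); u32(length(data)); u32(length(data))
  u16(length(fname)); u16(0); u16(0); u16(0); u16(0); u32(0); u32(0)
  writeBin(fname, con)
  cd_size <- 46 + length(fname)
  # end of central directory
  writeBin(as.raw(c(0x50, 0x4b, 0x05, 0x06)), con)
  u16(0); u16(0); u16(1); u16(1)
  u32(cd_size); u32(cd_offset); u16(0)
  invisible(zipfile)
}
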