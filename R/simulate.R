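#' Quantitative-trait architecture specification
#'
#' Describes the QTL classes of the simulated trait: two additive major
#' genes, three maternally imprinted genes, two epistatic pairs with no
#' marginal single-locus effects, 28 minor additive genes with effects drawn
#' from a truncated normal distribution, and one dominance, one
#' over-dominance and one under-dominance locus added on top (40 special
#' loci in total; the 37 QTLs proper are the majors, imprinted, epistatic
#' and minors). Effect sizes are configuration, not estimates: the defaults
#' give additive majors three times the minor-effect standard deviation and
#' moderate non-additive effects so that additive variance dominates and a
#' narrow-sense heritability of 0.45 is attainable.
#'
#' @param n_additive_major,n_imprinted,n_epistatic_pairs,n_minor QTL counts.
#' @param minor_mean,minor_sd,minor_bounds Truncated-normal spec for minor
#'   effects: `N(minor_mean, minor_sd^2)` truncated to
#'   `[minor_bounds[1], minor_bounds[2]]`.
#' @param major_effect Additive effect of each major gene.
#' @param imprinted_effect Effect per paternally inherited allele at each
#'   imprinted locus.
#' @param epistatic_effect Coefficient of each (residualized) pairwise
#'   interaction term.
#' @param dominance_a,dominance_d Additive and heterozygote values of the
#'   dominance locus (genotype map 0 -> 0, 1 -> d, 2 -> a).
#' @param overdominance_d Heterozygote advantage (map 0 -> 0, 1 -> d > 0,
#'   2 -> 0).
#' @param underdominance_d Heterozygote disadvantage (map 0 -> 0,
#'   1 -> d < 0, 2 -> 0).
#' @param min_qtl_maf Minimum MAF a marker must have to be eligible as a QTL.
#' @return An object of class `qtl_architecture`.
#' @export
qtl_architecture <- function(n_additive_major = 2L, n_imprinted = 3L,
                             n_epistatic_pairs = 2L, n_minor = 28L,
                             minor_mean = 0, minor_sd = 1, minor_bounds = c(-2, 2),
                             major_effect = 3, imprinted_effect = 2,
                             epistatic_effect = 2,
                             dominance_a = 2, dominance_d = 1,
                             overdominance_d = 2, underdominance_d = -2,
                             min_qtl_maf = 0.05) {
  stopifnot(n_additive_major >= 0, n_imprinted >= 0, n_epistatic_pairs >= 0,
            n_minor >= 0, minor_sd > 0, minor_bounds[1] < minor_bounds[2],
            overdominance_d > 0, underdominance_d < 0)
  structure(list(
    n_additive_major = as.integer(n_additive_major),
    n_imprinted = as.integer(n_imprinted),
    n_epistatic_pairs = as.integer(n_epistatic_pairs),
    n_minor = as.integer(n_minor),
    minor_mean = minor_mean, minor_sd = minor_sd, minor_bounds = minor_bounds,
    major_effect = major_effect, imprinted_effect = imprinted_effect,
    epistatic_effect = epistatic_effect,
    dominance_a = dominance_a, dominance_d = dominance_d,
    overdominance_d = overdominance_d, underdominance_d = underdominance_d,
    min_qtl_maf = min_qtl_maf,
    loci = NULL, effects = NULL
  ), class = "qtl_architecture")
}

#' Simulation configuration
#'
#' Study-scale defaults: 3,226 individuals in a five-generation pedigree
#' (100 founders, remaining individuals split evenly across four offspring
#' generations), 10,000 SNPs on 10 chromosomes of 1 Morgan each, founder
#' haplotypes drawn from a finite ancestral pool of 20 (which induces
#' linkage disequilibrium), the [qtl_architecture()] trait, and a target
#' narrow-sense heritability of 0.45.
#'
#' @param n_individuals Total pedigree size (default 3226).
#' @param n_founders Founder-generation size (default 100).
#' @param n_generations Pedigree depth including founders (default 5).
#' @param n_markers Number of SNPs (default 10000).
#' @param n_chromosomes Chromosome count (default 10); markers are spread
#'   evenly across chromosomes.
#' @param chrom_length_morgans Genetic length per chromosome (default 1).
#' @param founder_pool Number of distinct ancestral haplotypes founders are
#'   drawn from (default 20).
#' @param architecture A [qtl_architecture()].
#' @param target_h2 Target narrow-sense heritability in (0, 1\]; the residual
#'   variance is calibrated so Var(additive)/Var(phenotype) hits this value
#'   (default 0.45). `target_h2 = 1` means no residual noise.
#' @param seed Integer seed governing all randomness of the run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 3226L, n_founders = 100L,
                       n_generations = 5L, n_markers = 10000L,
                       n_chromosomes = 10L, chrom_length_morgans = 1,
                       founder_pool = 20L, architecture = qtl_architecture(),
                       target_h2 = 0.45, seed = 1L) {
  if (n_founders < 2L) abort("Need at least 2 founders.")
  if (n_generations < 1L) abort("Need at least 1 generation.")
  if (n_generations > 1L && n_individuals <= n_founders) {
    abort("`n_individuals` must exceed `n_founders` when there are offspring generations.")
  }
  if (target_h2 <= 0 || target_h2 > 1) abort("`target_h2` must be in (0, 1].")
  if (n_markers %% n_chromosomes != 0L) {
    abort("`n_markers` must be divisible by `n_chromosomes`.")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_morgans = chrom_length_morgans,
    founder_pool = as.integer(founder_pool),
    architecture = architecture,
    target_h2 = target_h2,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Founders (generation 1) have unknown parents; every later individual gets
#' a sire drawn from the males and a dam from the females of the previous
#' generation (no selfing by construction). Non-founder individuals are
#' split as evenly as possible across generations 2..n_generations. Sexes
#' are assigned alternately within each generation so every generation
#' contains both sexes.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `id`, `sire`, `dam`, `sex`, `generation`
#'   (founder parents are `NA`).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- generation_sizes(cfg)
  n <- sum(sizes)
  id <- seq_len(n)
  generation <- rep(seq_along(sizes), sizes)
  # alternate sexes so every generation has both
  sex <- unlist(lapply(sizes, function(s) rep_len(c("M", "F"), s)), use.names = FALSE)
  sire <- dam <- rep(NA_integer_, n)
  for (g in seq_along(sizes)[-1]) {
    prev <- id[generation == g - 1L]
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(males) == 0L || length(females) == 0L) {
      abort(sprintf("Generation %d has no possible matings (missing a sex).", g - 1L))
    }
    cur <- id[generation == g]
    sire[cur] <- sample(males, length(cur), replace = TRUE)
    dam[cur] <- sample(females, length(cur), replace = TRUE)
  }
  tibble::tibble(id = id, sire = sire, dam = dam, sex = sex,
                 generation = generation)
}

generation_sizes <- function(cfg) {
  if (cfg$n_generations == 1L) return(cfg$n_individuals)
  rest <- cfg$n_individuals - cfg$n_founders
  k <- cfg$n_generations - 1L
  base <- rest %/% k
  sizes <- rep(base, k)
  extra <- rest - base * k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 1L)) abort("Pedigree sizes infeasible: an offspring generation would be empty.")
  c(cfg$n_founders, sizes)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder haplotypes are sampled from a finite ancestral pool (the shared
#' ancestry induces linkage disequilibrium that decays with map distance).
#' Each meiosis places a Poisson number of crossovers (mean = chromosome
#' length in Morgans, i.e. Haldane's no-interference model) uniformly along
#' each chromosome and passes a mosaic of the parent's two haplotypes.
#' Parental origin is tracked: the returned `paternal` matrix holds the
#' allele each individual inherited from its sire (founders: their first
#' haplotype), `maternal` the allele from the dam.
#'
#' @param cfg A [sim_config()].
#' @param pedigree Output of [simulate_pedigree()].
#' @return A list with `genotypes` (a [genotype_matrix()]),
#'   `paternal` and `maternal` (0/1 integer matrices n x p), and
#'   `positions` (marker map: tibble with `chrom`, `pos_morgan`).
#' @export
simulate_genotypes <- function(cfg, pedigree) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$n_markers
  per_chr <- p %/% cfg$n_chromosomes
  chrom <- rep(seq_len(cfg$n_chromosomes), each = per_chr)
  pos <- rep(seq(0, cfg$chrom_length_morgans, length.out = per_chr),
             times = cfg$n_chromosomes)
  chr_index <- split(seq_len(p), chrom)

  # ancestral haplotype pool: per-marker allele frequencies spread over
  # (0.05, 0.95) so the realized MAF spectrum covers common and rare variants
  freq <- runif(p, 0.05, 0.95)
  pool <- matrix(rbinom(cfg$founder_pool * p, 1L, rep(freq, each = cfg$founder_pool)),
                 nrow = cfg$founder_pool, ncol = p)

  n <- nrow(pedigree)
  founders <- which(pedigree$generation == 1L)
  founder_pat <- pool[sample.int(cfg$founder_pool, length(founders), replace = TRUE), , drop = FALSE]
  founder_mat <- pool[sample.int(cfg$founder_pool, length(founders), replace = TRUE), , drop = FALSE]

  chrom_first <- vapply(chr_index, min, integer(1))
  chrom_last <- vapply(chr_index, max, integer(1))
  sire <- pedigree$sire; sire[is.na(sire)] <- 0L
  dam <- pedigree$dam; dam[is.na(dam)] <- 0L
  dropped <- .gene_drop(t(founder_pat), t(founder_mat), sire, dam,
                        chrom_first, chrom_last, pos,
                        cfg$chrom_length_morgans, n)
  pat <- t(dropped$paternal_t)
  mat <- t(dropped$maternal_t)

  g <- genotype_matrix(pat + mat,
                       individual_ids = as.character(pedigree$id),
                       marker_ids = paste0("snp_", seq_len(p)))
  list(genotypes = g, paternal = pat, maternal = mat,
       positions = tibble::tibble(chrom = chrom, pos_morgan = pos))
}

#' Assign QTL positions and effects
#'
#' Chooses distinct marker indices for every QTL class among markers with
#' MAF at or above the architecture's `min_qtl_maf`, and draws minor-gene
#' effects from the truncated normal spec (rejection sampling). Deterministic
#' given the RNG state.
#'
#' @param cfg A [sim_config()].
#' @param genotypes A [genotype_matrix()].
#' @return The architecture with `loci` (named list of index vectors) and
#'   `effects` (tibble: `index`, `type`, `effect`) filled in.
#' @export
assign_architecture <- function(cfg, genotypes) {
  arch <- cfg$architecture
  f <- colMeans(unclass(genotypes)) / 2
  eligible <- which(pmin(f, 1 - f) >= arch$min_qtl_maf)
  n_needed <- arch$n_additive_major + arch$n_imprinted +
    2L * arch$n_epistatic_pairs + arch$n_minor + 3L
  if (length(eligible) < n_needed) {
    abort(sprintf("Only %d polymorphic markers (MAF >= %g) but %d QTL loci needed.",
                  length(eligible), arch$min_qtl_maf, n_needed))
  }
  picked <- sample(eligible, n_needed)
  cuts <- cumsum(c(arch$n_additive_major, arch$n_imprinted,
                   2L * arch$n_epistatic_pairs, arch$n_minor, 3L))
  slice <- function(from, to) if (to < from) integer(0) else picked[seq.int(from, to)]
  loci <- list(
    additive_major = slice(1L, cuts[1]),
    imprinted = slice(cuts[1] + 1L, cuts[2]),
    epistatic = matrix(slice(cuts[2] + 1L, cuts[3]), ncol = 2L, byrow = TRUE),
    minor = slice(cuts[3] + 1L, cuts[4]),
    dominance = picked[cuts[4] + 1L],
    overdominance = picked[cuts[4] + 2L],
    underdominance = picked[cuts[4] + 3L]
  )
  minor_eff <- rtruncnorm(arch$n_minor, arch$minor_mean, arch$minor_sd,
                          arch$minor_bounds[1], arch$minor_bounds[2])
  arch$loci <- loci
  arch$effects <- dplyr::bind_rows(
    tibble::tibble(index = loci$additive_major, type = "additive_major",
                   effect = rep(arch$major_effect, arch$n_additive_major)),
    tibble::tibble(index = loci$imprinted, type = "imprinted",
                   effect = rep(arch$imprinted_effect, arch$n_imprinted)),
    tibble::tibble(index = as.integer(t(loci$epistatic)), type = "epistatic",
                   effect = rep(arch$epistatic_effect, 2L * arch$n_epistatic_pairs)),
    tibble::tibble(index = loci$minor, type = "minor", effect = minor_eff),
    tibble::tibble(index = c(loci$dominance, loci$overdominance, loci$underdominance),
                   type = c("dominance", "overdominance", "underdominance"),
                   effect = c(arch$dominance_a, arch$overdominance_d,
                              arch$underdominance_d))
  )
  arch
}

# truncated normal by rejection; bounds are on the sampled value itself
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate phenotypes from an assigned architecture
#'
#' Builds the trait as an exact sum of mean-centered components plus
#' Gaussian residual:
#' \itemize{
#'   \item additive: allele-count regression `sum_j a_j code_j` over major
#'     and minor QTLs;
#'   \item imprinted: the maternal copy is silenced, so the component is the
#'     effect times the paternally inherited allele count only;
#'   \item epistatic: for each pair, the product of centered allele codes,
#'     residualized against an intercept and both single-locus codings on
#'     the realized sample — so each locus of the pair has exactly zero
#'     marginal (linear) association with the component;
#'   \item dominance classes: genotype-value maps 0 -> 0 / 1 -> d / 2 -> a
#'     (dominance), 0 -> 0 / 1 -> d / 2 -> 0 with d > 0 (over-dominance) and
#'     d < 0 (under-dominance);
#'   \item residual: `N(0, sigma2_e)` with `sigma2_e` calibrated on the
#'     realized sample so that Var(additive) / Var(phenotype) equals the
#'     target narrow-sense heritability in expectation.
#' }
#'
#' @param cfg A [sim_config()].
#' @param genotypes A [genotype_matrix()].
#' @param paternal 0/1 matrix of paternally inherited alleles.
#' @param arch Architecture with loci/effects from [assign_architecture()].
#' @return An object of class `sim_output`: list with `genotypes`,
#'   `paternal_alleles`, `phenotypes`, `true_effects`, `components` (matrix
#'   with columns additive / imprinted / epistatic / dominance / residual),
#'   `realized_h2`, `architecture`, `config`.
#' @export
simulate_phenotypes <- function(cfg, genotypes, paternal, arch) {
  stopifnot(!is.null(arch$loci))
  codes <- unclass(genotypes) + 0.0
  dimnames(codes) <- NULL
  n <- nrow(codes)

  center <- function(x) x - mean(x)

  additive <- numeric(n)
  add_idx <- c(arch$loci$additive_major, arch$loci$minor)
  add_eff <- c(rep(arch$major_effect, arch$n_additive_major),
               arch$effects$effect[arch$effects$type == "minor"])
  if (length(add_idx) > 0L) {
    additive <- center(drop(codes[, add_idx, drop = FALSE] %*% add_eff))
  }

  imprinted <- numeric(n)
  if (arch$n_imprinted > 0L) {
    imprinted <- center(drop(paternal[, arch$loci$imprinted, drop = FALSE] %*%
                               rep(arch$imprinted_effect, arch$n_imprinted)))
  }

  epistatic <- numeric(n)
  if (arch$n_epistatic_pairs > 0L) {
    # residualize against every epistatic locus so the summed component has
    # exactly zero marginal (linear) association with each constituent locus
    epi_idx <- as.integer(arch$loci$epistatic)
    Xp <- cbind(1, codes[, epi_idx, drop = FALSE])
    qrXp <- qr(Xp)
    for (k in seq_len(arch$n_epistatic_pairs)) {
      j1 <- arch$loci$epistatic[k, 1L]; j2 <- arch$loci$epistatic[k, 2L]
      z <- center(codes[, j1]) * center(codes[, j2])
      z_res <- z - drop(Xp %*% qr.coef(qrXp, z))
      epistatic <- epistatic + arch$epistatic_effect * z_res
    }
    epistatic <- center(epistatic)
  }

  dom_map <- function(code, v0, v1, v2) {
    out <- numeric(length(code))
    out[code == 1] <- v1
    out[code == 2] <- v2
    out
  }
  dominance <- center(
    dom_map(codes[, arch$loci$dominance], 0, arch$dominance_d, arch$dominance_a) +
    dom_map(codes[, arch$loci$overdominance], 0, arch$overdominance_d, 0) +
    dom_map(codes[, arch$loci$underdominance], 0, arch$underdominance_d, 0)
  )

  var_add <- pop_var(additive)
  if (var_add <= 0) abort("Zero additive variance: cannot calibrate heritability.")
  genetic <- additive + imprinted + epistatic + dominance
  sigma2_e <- var_add / cfg$target_h2 - pop_var(genetic)
  if (sigma2_e < 0 && sigma2_e > -1e-10 * var_add) sigma2_e <- 0
  if (sigma2_e < 0) {
    abort(sprintf(
      "Non-additive variance too large for target h2 = %g (needed residual variance %.3g < 0); reduce non-additive effect sizes.",
      cfg$target_h2, sigma2_e))
  }
  residual <- if (sigma2_e == 0) numeric(n) else rnorm(n, 0, sqrt(sigma2_e))
  y <- genetic + residual

  structure(list(
    genotypes = genotypes,
    paternal_alleles = paternal,
    phenotypes = y,
    true_effects = arch$effects,
    components = cbind(additive = additive, imprinted = imprinted,
                       epistatic = epistatic, dominance = dominance,
                       residual = residual),
    realized_h2 = pop_var(additive) / pop_var(y),
    architecture = arch,
    config = cfg
  ), class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output: %d individuals x %d markers, realized h2 = %.3f>\n",
              nrow(x$genotypes), ncol(x$genotypes), x$realized_h2))
  invisible(x)
}

#' Run the full trait simulation
#'
#' Seeds the RNG from the configuration and chains
#' [simulate_pedigree()], [simulate_genotypes()], [assign_architecture()]
#' and [simulate_phenotypes()].
#'
#' @param cfg A [sim_config()].
#' @return A `sim_output` (with the pedigree attached as `$pedigree`).
#' @export
simulate_qtlmas <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(cfg, ped)
  arch <- assign_architecture(cfg, geno$genotypes)
  out <- simulate_phenotypes(cfg, geno$genotypes, geno$paternal, arch)
  out$pedigree <- ped
  out$positions <- geno$positions
  out
}

#' Export a simulation to delimited text files
#'
#' Writes `genotypes.txt` and `phenotypes.txt` in the format
#' [read_genotypes()] / [read_phenotypes()] read back exactly, plus
#' `true_effects.csv` (per-QTL index, type, effect) and `components.csv`
#' (per-individual genetic-value components) for parameter-recovery tests.
#'
#' @param sim A `sim_output`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.txt"))
  write_phenotypes(sim$phenotypes, file.path(dir, "phenotypes.txt"))
  utils::write.csv(sim$true_effects, file.path(dir, "true_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$components), file.path(dir, "components.csv"),
                   row.names = FALSE)
  invisible(dir)
}
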