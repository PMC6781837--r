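test_that("pedigrees have founders-first structure, both sexes, and no selfing", {
  cfg <- small_sim_config(seed = 1)
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 400)
  expect_equal(sort(unique(ped$generation)), 1:5)
  founders <- ped[ped$generation == 1, ]
  expect_true(all(is.na(founders$sire)) && all(is.na(founders$dam)))
  nonf <- ped[ped$generation > 1, ]
  expect_true(all(!is.na(nonf$sire) & !is.na(nonf$dam)))
  expect_true(all(nonf$sire != nonf$dam))        # no selfing
  # parents always come from the previous generation
  expect_true(all(ped$generation[nonf$sire] == nonf$generation - 1))
  expect_true(all(ped$generation[nonf$dam] == nonf$generation - 1))
  expect_true(all(ped$sex[nonf$sire] == "M"))
  expect_true(all(ped$sex[nonf$dam] == "F"))

  cfg1 <- sim_config(n_individuals = 10, n_founders = 10, n_generations = 1,
                     n_markers = 20, n_chromosomes = 2, seed = 1)
  set.seed(1)
  ped1 <- simulate_pedigree(cfg1)
  expect_true(all(ped1$generation == 1))
})

test_that("a founder pool of one haplotype makes every genotype homozygous", {
  cfg <- sim_config(n_individuals = 60, n_founders = 10, n_generations = 3,
                    n_markers = 100, n_chromosomes = 2, founder_pool = 1,
                    seed = 2)
  set.seed(2)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(cfg, ped)
  expect_true(all(unclass(geno$genotypes) %in% c(0L, 2L)))
})

test_that("zero map length means offspring chromosomes are exact parental copies", {
  cfg <- sim_config(n_individuals = 40, n_founders = 10, n_generations = 2,
                    n_markers = 60, n_chromosomes = 3,
                    chrom_length_morgans = 0, founder_pool = 8, seed = 3)
  set.seed(3)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(cfg, ped)
  per_chr <- 60 / 3
  chr_cols <- split(seq_len(60), rep(1:3, each = per_chr))
  for (i in which(ped$generation == 2)) {
    s <- ped$sire[i]
    for (cc in chr_cols) {
      child <- geno$paternal[i, cc]
      expect_true(identical(child, geno$paternal[s, cc]) ||
                    identical(child, geno$maternal[s, cc]))
    }
  }
})

test_that("linkage disequilibrium decays with map distance", {
  # founder-pool ancestry plus recombination: nearby markers should be in
  # stronger LD than distant ones, averaged over replicates
  near <- far <- numeric(20)
  for (r in 1:20) {
    cfg <- sim_config(n_individuals = 120, n_founders = 20, n_generations = 4,
                      n_markers = 120, n_chromosomes = 1, founder_pool = 6,
                      seed = 400 + r)
    set.seed(cfg$seed)
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(cfg, ped)
    M <- unclass(geno$genotypes)
    keep <- which(apply(M, 2, sd) > 0)
    M <- M[, keep]
    r2_at_gap <- function(gap) {
      j <- seq_len(ncol(M) - gap)
      mean(vapply(j, function(a) cor(M[, a], M[, a + gap])^2, numeric(1)))
    }
    near[r] <- r2_at_gap(1)
    far[r] <- r2_at_gap(min(60, ncol(M) - 1))
  }
  expect_gt(mean(near), mean(far))
})

test_that("architecture assignment picks 40 distinct eligible loci, reproducibly", {
  cfg <- small_sim_config(seed = 4)
  set.seed(4)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(cfg, ped)
  set.seed(99)
  arch <- assign_architecture(cfg, geno$genotypes)
  all_loci <- c(arch$loci$additive_major, arch$loci$imprinted,
                as.integer(arch$loci$epistatic), arch$loci$minor,
                arch$loci$dominance, arch$loci$overdominance,
                arch$loci$underdominance)
  expect_length(all_loci, 40)
  expect_equal(anyDuplicated(all_loci), 0L)
  expect_equal(nrow(arch$effects), 40)
  # eligibility: every chosen locus clears the MAF floor
  f <- colMeans(unclass(geno$genotypes)) / 2
  expect_true(all(pmin(f, 1 - f)[all_loci] >= arch$min_qtl_maf))
  # minor effects respect the truncation bounds
  minor <- arch$effects$effect[arch$effects$type == "minor"]
  expect_length(minor, 28)
  expect_true(all(minor >= arch$minor_bounds[1] & minor <= arch$minor_bounds[2]))

  set.seed(99)
  arch2 <- assign_architecture(cfg, geno$genotypes)
  expect_identical(arch$loci, arch2$loci)
  expect_equal(arch$effects, arch2$effects)

  cfg_small <- sim_config(n_individuals = 20, n_founders = 5,
                          n_generations = 2, n_markers = 30,
                          n_chromosomes = 3, seed = 5)
  set.seed(5)
  ped_s <- simulate_pedigree(cfg_small)
  geno_s <- simulate_genotypes(cfg_small, ped_s)
  expect_error(assign_architecture(cfg_small, geno_s$genotypes), "QTL loci")
})

test_that("phenotype components sum exactly and honour their contracts", {
  sim <- simulate_qtlmas(small_sim_config(seed = 6))
  # exact decomposition
  expect_lt(max(abs(sim$phenotypes - rowSums(sim$components))), 1e-12 *
              max(1, max(abs(sim$phenotypes))))

  codes <- unclass(sim$genotypes)
  arch <- sim$architecture
  # epistatic component has no marginal linear association with its loci
  for (j in as.integer(arch$loci$epistatic)) {
    expect_lt(abs(cor(sim$components[, "epistatic"], codes[, j])), 1e-10)
  }
  # the imprinted component is a function of paternal alleles only, so
  # shuffling maternal alleles at those loci cannot change it; recompute it
  imp <- sim$components[, "imprinted"]
  pat_part <- drop(sim$paternal_alleles[, arch$loci$imprinted] %*%
                     rep(arch$imprinted_effect, arch$n_imprinted))
  expect_equal(imp, pat_part - mean(pat_part), tolerance = 1e-12)
  # while permuting the paternal alleles does change it
  set.seed(1)
  pat_perm <- sim$paternal_alleles[sample(nrow(codes)), arch$loci$imprinted]
  perm_part <- drop(pat_perm %*% rep(arch$imprinted_effect, arch$n_imprinted))
  expect_gt(max(abs((perm_part - mean(perm_part)) - imp)), 0.1)

  # realized h2 is the additive share of phenotypic variance
  va <- mean((sim$components[, "additive"] - mean(sim$components[, "additive"]))^2)
  vy <- mean((sim$phenotypes - mean(sim$phenotypes))^2)
  expect_equal(sim$realized_h2, va / vy, tolerance = 1e-12)
})

test_that("one additive QTL with no noise gives phenotype = centered code", {
  cfg <- sim_config(
    n_individuals = 80, n_founders = 10, n_generations = 3, n_markers = 40,
    n_chromosomes = 2, founder_pool = 8, target_h2 = 1, seed = 7,
    architecture = qtl_architecture(n_additive_major = 1L, n_imprinted = 0L,
                                    n_epistatic_pairs = 0L, n_minor = 0L,
                                    major_effect = 1,
                                    dominance_a = 0, dominance_d = 0,
                                    overdominance_d = 1e-300,
                                    underdominance_d = -1e-300))
  sim <- simulate_qtlmas(cfg)
  qtl <- sim$architecture$loci$additive_major
  code <- unname(unclass(sim$genotypes)[, qtl])
  expect_equal(sim$phenotypes, code - mean(code), tolerance = 1e-10)
})

test_that("heritability calibration concentrates near its target at desk scale", {
  h2 <- vapply(1:8, function(s) simulate_qtlmas(small_sim_config(seed = s))$realized_h2,
               numeric(1))
  expect_lt(abs(mean(h2) - 0.45), 0.05)
  expect_true(all(h2 > 0.3 & h2 < 0.6))
})

test_that("simulation export round-trips through the data readers", {
  sim <- simulate_qtlmas(sim_config(n_individuals = 50, n_founders = 10,
                                    n_generations = 3, n_markers = 60,
                                    n_chromosomes = 3, seed = 8))
  dir <- withr::local_tempdir()
  export_sim(sim, dir)
  g2 <- read_genotypes(file.path(dir, "genotypes.txt"))
  expect_identical(unclass(g2), unclass(sim$genotypes))
  y2 <- read_phenotypes(file.path(dir, "phenotypes.txt"))
  expect_equal(y2, sim$phenotypes, tolerance = 1e-12)
  expect_equal(length(readLines(file.path(dir, "phenotypes.txt"))), 50L)
  eff <- read.csv(file.path(dir, "true_effects.csv"))
  expect_equal(nrow(eff), 40)
})

test_that("sparse strong signal favours L1 methods over ridge on hold-out MSE", {
  wins <- 0L
  for (r in 1:10) {
    cfg <- sim_config(n_individuals = 300, n_founders = 30, n_generations = 4,
                      n_markers = 400, n_chromosomes = 4, founder_pool = 10,
                      seed = 500 + r)
    sim <- simulate_qtlmas(cfg)
    g <- maf_filter(sim$genotypes, 0.01)
    split <- make_split(300, 225)
    d <- standardize(g, sim$phenotypes)
    Xtr <- d$X[split$train_index, ]; Xte <- d$X[split$test_index, ]
    ytr <- d$y[split$train_index]; yte <- d$y[split$test_index]
    mse_best <- function(m) {
      # pedigree LD makes some columns nearly collinear; give the descent room
      sel <- select_model(fit_path(Xtr, ytr, m, n_lambda = 25,
                                   max_sweeps = 50000L), Xte, yte, "min_mse")
      sel$best_report$mse
    }
    if (min(mse_best("LASSO"), mse_best("ALASSO")) < mse_best("RR")) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 6L)
})
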