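test_that("province frequencies follow the Balding-Nichols construction", {
  set.seed(1)
  cfg <- synthetic_config(seed = 1, fst = 1e-6)
  f <- sample_allele_frequencies(cfg)
  for (j in seq_len(cfg$n_loci)) {
    expect_equal(sum(f$global[[j]]), 1, tolerance = 1e-12)
    for (g in seq_len(cfg$n_provinces)) {
      expect_equal(sum(f$province[[g]][[j]]), 1, tolerance = 1e-12)
      # fst -> 0 limit: province frequencies collapse onto the global ones
      expect_lt(max(abs(f$province[[g]][[j]] - f$global[[j]])), 1e-2)
    }
  }
  cfg1 <- synthetic_config(seed = 2, n_loci = 1L, alleles_per_locus = 1L)
  f1 <- sample_allele_frequencies(cfg1)
  expect_equal(unname(f1$global[[1]]), 1)
  expect_error(synthetic_config(seed = 1, fst = 0), "fst")
})

test_that("differentiation of simulated frequencies matches the target fst", {
  # Monte-Carlo oracle: Weir-Cockerham-style estimate from province
  # frequency variance over many replicate biallelic loci
  set.seed(42)
  target <- 0.15
  cfg <- synthetic_config(seed = 42, n_loci = 2000L, alleles_per_locus = 2L,
                          freq_concentration = 2, fst = target)
  f <- sample_allele_frequencies(cfg)
  fst_hat <- vapply(seq_len(cfg$n_loci), function(j) {
    ps <- vapply(f$province, function(pr) pr[[j]][1], numeric(1))
    pbar <- mean(ps)
    if (pbar <= 0 || pbar >= 1) return(NA_real_)
    stats::var(ps) / (pbar * (1 - pbar))
  }, numeric(1))
  expect_lt(abs(mean(fst_hat, na.rm = TRUE) - target), 0.02)
})

test_that("ploidy structure of simulated genotypes is impossible to violate", {
  sim <- simulate_population(synthetic_config(
    seed = 5, n_accessions = 120L, triploid_fraction = 0,
    genotyping_error_rate = 0, missing_rate = 0))
  n_alleles <- lengths(sim$table$geno)
  expect_true(all(n_alleles <= 2L))  # no diploid can show 3 distinct alleles
  sim3 <- simulate_population(synthetic_config(
    seed = 5, n_accessions = 120L, triploid_fraction = 1, missing_rate = 0))
  expect_true(all(lengths(sim3$table$geno) <= 3L))
})

test_that("triploid share falls in the binomial 99% CI of the fraction", {
  cfg <- synthetic_config(seed = 9, n_accessions = 500L,
                          triploid_fraction = 0.25, clone_groups = NULL,
                          homonym_groups = NULL)
  sim <- simulate_population(cfg)
  k <- sum(sim$truth$ploidy == 3L)
  ci <- stats::qbinom(c(0.005, 0.995), 500L, 0.25)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("clone groups are exact pre-noise copies with aliased names", {
  cfg <- synthetic_config(seed = 2, n_accessions = 40L,
                          clone_groups = data.frame(size = 3L,
                                                    mode = "alias"),
                          homonym_groups = NULL, missing_rate = 0)
  sim <- simulate_population(cfg)
  members <- which(!is.na(sim$truth$clone_group))
  expect_length(members, 3L)
  expect_identical(sim$table$geno[members[1], ], sim$table$geno[members[2], ])
  expect_identical(sim$table$geno[members[1], ], sim$table$geno[members[3], ])
  norm <- vapply(sim$table$meta$name[members], normalize_name, character(1))
  expect_equal(length(unique(norm)), 3L)   # synonymy: three distinct names
  expect_error(simulate_population(synthetic_config(
    seed = 2, n_accessions = 4L,
    clone_groups = data.frame(size = 10L, mode = "alias"))),
    "exceed")
})

test_that("missingness injection matches its rate and never touches alleles", {
  sim <- simulate_population(small_config(1))
  t0 <- sim$table
  expect_identical(simulate_missingness(t0, 0), t0)
  t1 <- simulate_missingness(t0, 0.5, seed = 99)
  changed <- lengths(t1$geno) != lengths(t0$geno)
  kept <- lengths(t1$geno) > 0L
  expect_true(all(vapply(which(kept), function(k)
    identical(t1$geno[[k]], t0$geno[[k]]), logical(1))))
  n_cells <- length(t0$geno)
  ci <- stats::qbinom(c(0.005, 0.995), n_cells, 0.5)
  expect_gte(sum(changed), ci[1])
  expect_lte(sum(changed), ci[2])
})

test_that("per-locus sample sizes under the default missing rate look like a
           real panel", {
  cfg <- synthetic_config(seed = 21)   # 311 accessions, 1.1% missing cells
  sim <- simulate_population(cfg)
  ns <- locus_sample_sizes(sim$table)
  expect_true(all(ns >= 295L & ns <= 311L))
})

test_that("allele frequencies estimated from a large diploid panel recover
           the generator truth", {
  cfg <- synthetic_config(seed = 8, n_accessions = 1000L,
                          triploid_fraction = 0, clone_groups = NULL,
                          homonym_groups = NULL, missing_rate = 0,
                          fst = 1e-6)
  sim <- simulate_population(cfg)
  worst <- 0
  for (j in seq_len(cfg$n_loci)) {
    p_hat <- allele_frequencies(sim$table, j)
    p_true <- sim$truth$freqs$global[[j]]
    p_cmp <- p_true[names(p_true) %in% names(p_hat)]
    err <- max(abs(p_hat[names(p_cmp)] - p_cmp),
               max(p_true[!names(p_true) %in% names(p_hat)], 0))
    worst <- max(worst, err)
  }
  expect_lt(worst, 0.03)
})

test_that("cytometry histograms peak where ploidy says they should", {
  h2 <- simulate_cytometry(2, base_channel = 200, cv = 0.03,
                           n_events = 20000L, seed = 31)
  h3 <- simulate_cytometry(3, base_channel = 200, cv = 0.03,
                           n_events = 20000L, seed = 31)
  expect_lt(abs(h2$channel[which.max(h2$count)] - 200), 3)
  expect_lt(abs(h3$channel[which.max(h3$count)] - 300), 4)
  # generator/detector closed loop
  pk <- detect_g1_peaks(h2)
  expect_lt(abs(pk$channel[which.max(pk$height)] - 200), 2.5)
})
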