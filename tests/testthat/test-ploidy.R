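test_that("triallelic loci are counted per accession", {
  t <- toy_table()
  expect_equal(count_triallelic_loci(t, 1), 0L)
  expect_equal(count_triallelic_loci(t, "A005"), 2L)
  t1 <- make_table(rbind(c("134/138/142", "200/204")))
  expect_equal(count_triallelic_loci(t1, 1), 1L)
})

test_that("triallelic count distribution matches the analytic per-locus
           probability", {
  # P(3 distinct alleles among 2 maternal + 1 paternal draws) at one locus,
  # computed numerically from the frequency vector
  p_tri <- function(p) {
    s <- 0
    k <- length(p)
    for (a in seq_len(k)) for (b in seq_len(k)) for (c in seq_len(k))
      if (length(unique(c(a, b, c))) == 3L) s <- s + p[a] * p[b] * p[c]
    s
  }
  cfg <- synthetic_config(seed = 23, n_accessions = 600L,
                          n_loci = 3L, alleles_per_locus = c(6L, 10L, 15L),
                          triploid_fraction = 1, clone_groups = NULL,
                          homonym_groups = NULL, missing_rate = 0,
                          fst = 1e-6)
  sim <- simulate_population(cfg)
  for (j in 1:3) {
    expected <- p_tri(sim$truth$freqs$global[[j]])
    observed <- mean(vapply(seq_len(600L), function(i)
      length(sim$table$geno[[i, j]]) >= 3L, logical(1)))
    se <- sqrt(expected * (1 - expected) / 600)
    expect_lt(abs(observed - expected), 4 * se + 0.01)
  }
})

test_that("the SSR ploidy rule maps triallelic counts to calls", {
  t <- make_table(rbind(
    c("134/138", "200/204", "300"),
    c("134/138/142", "200/204", "300"),
    c("134/138/142", "200/204/208", "300/302/306")))
  calls <- classify_ploidy_ssr(t, min_loci = 2L)
  expect_equal(calls$call, c("diploid", "putative_triploid", "triploid"))
  expect_equal(calls$n_triallelic, c(0L, 1L, 3L))
  tally <- ploidy_tally(calls)
  expect_equal(tally$count, c(2L, 1L))
  expect_error(classify_ploidy_ssr(t, min_loci = 0L), "min_loci")
})

test_that("error-free diploids are never called triploid; sensitivity is
           monotone in the threshold", {
  sim <- simulate_population(synthetic_config(
    seed = 3, n_accessions = 150L, triploid_fraction = 0.3,
    clone_groups = NULL, homonym_groups = NULL))
  c1 <- classify_ploidy_ssr(sim$table, min_loci = 1L)
  c2 <- classify_ploidy_ssr(sim$table, min_loci = 2L)
  dip <- sim$truth$ploidy == 2L
  expect_true(all(c1$call[dip] == "diploid"))
  expect_true(all(c2$call[dip] == "diploid"))
  expect_gte(sum(c1$call == "triploid"), sum(c2$call == "triploid"))
})

test_that("G1 peaks are detected at their simulated positions", {
  h <- simulate_cytometry(2, base_channel = 200, cv = 0.03,
                          n_events = 20000L, seed = 12)
  pk <- detect_g1_peaks(h)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$channel - 200), 2.5)

  run <- simulate_pi_run(1.18, data.frame(name = "Raphanus sativus",
                                          ref_2c = 1.11),
                         seed = 4)
  pk2 <- detect_g1_peaks(run$hist)
  expect_equal(nrow(pk2), 2L)
  expect_true(all(diff(pk2$channel) > 0))

  flat <- fcm_histogram(1:100, rep(0, 100))
  pk0 <- detect_g1_peaks(flat)
  expect_equal(nrow(pk0), 0L)
  expect_true(attr(pk0, "flagged"))
})

test_that("DAPI ploidy windows classify peak ratios", {
  expect_equal(call_ploidy_dapi(200, 200)$call, "diploid")
  expect_equal(call_ploidy_dapi(300, 200)$call, "triploid")
  u <- call_ploidy_dapi(256, 200)   # ratio 1.28, between windows
  expect_equal(u$call, "unassigned")
  expect_match(u$note, "between")
  expect_warning(out <- call_ploidy_dapi(600, 200), "outside")
  expect_equal(out$call, "unassigned")
  tet <- call_ploidy_dapi(400, 200)
  expect_equal(tet$call, "unassigned")
  expect_match(tet$note, "tetraploid")
  # any positive reference compared with itself is diploid
  for (r in c(1, 57.3, 1024)) {
    expect_equal(call_ploidy_dapi(r, r)$call, "diploid")
  }
})

test_that("PI genome-size estimation is an exact fluorescence ratio", {
  std <- data.frame(name = "Raphanus sativus", peak = 160, ref_2c = 1.11)
  expect_equal(estimate_genome_size_pi(160, std)$combined_2c_pg, 1.11)
  expect_equal(estimate_genome_size_pi(240, std)$combined_2c_pg, 1.665)
  # exact linearity: doubling the sample peak doubles the estimate
  e1 <- estimate_genome_size_pi(130, std)$combined_2c_pg
  e2 <- estimate_genome_size_pi(260, std)$combined_2c_pg
  expect_equal(e2, 2 * e1)
  # two consistent standards average; inconsistent slopes warn
  std2 <- data.frame(name = c("Raphanus sativus", "Solanum lycopersicum"),
                     peak = c(111, 196) * 1.5, ref_2c = c(1.11, 1.96))
  est <- estimate_genome_size_pi(1.18 * 150, std2)
  expect_equal(est$combined_2c_pg, 1.18)
  bad <- data.frame(name = c("a", "b"), peak = c(100, 300),
                    ref_2c = c(1.11, 1.96))
  expect_warning(estimate_genome_size_pi(150, bad), "slopes")
})

test_that("peak assignment matches components to nearest detected peaks", {
  run <- simulate_pi_run(1.18, data.frame(
    name = c("Raphanus sativus", "Solanum lycopersicum"),
    ref_2c = c(1.11, 1.96)), seed = 7)
  pk <- detect_g1_peaks(run$hist)
  asg <- assign_peaks(pk, run$expected)
  expect_equal(nrow(asg), 3L)
  expect_true(all(abs(asg$peak - asg$channel) < 5))
})

test_that("concordance joins call sets and lists discordances", {
  ssr <- data.frame(accession_id = sprintf("A%02d", 1:4),
                    call = c("diploid", "triploid", "putative_triploid",
                             "diploid"))
  cyt <- data.frame(accession_id = sprintf("A%02d", 1:4),
                    call = c("diploid", "triploid", "diploid", "triploid"))
  cc <- concordance(ssr, cyt)
  expect_equal(cc$agreement, 0.75)
  expect_equal(cc$discordant$accession_id, "A04")
  # putative maps to diploid before comparison
  expect_equal(unname(cc$confusion["diploid", "diploid"]), 2L)
  ident <- concordance(ssr, data.frame(accession_id = ssr$accession_id,
                                       call = c("diploid", "triploid",
                                                "diploid", "diploid")))
  expect_equal(ident$agreement, 1)
  expect_error(concordance(ssr, data.frame(accession_id = "Z1",
                                           call = "diploid")),
               "shared")
})

test_that("a constructed 48-of-50 panel reports 96% agreement", {
  ids <- sprintf("S%02d", 1:50)
  truth <- rep(c("diploid", "triploid"), c(34, 16))
  ssr <- data.frame(accession_id = ids, call = truth)
  cyt_call <- truth
  cyt_call[c(7, 40)] <- rev(c("diploid", "triploid"))  # two discordances
  cyt <- data.frame(accession_id = ids, call = cyt_call)
  cc <- concordance(ssr, cyt)
  expect_equal(cc$agreement, 0.96)
  expect_equal(nrow(cc$discordant), 2L)
})
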