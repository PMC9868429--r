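test_that("distance kinds follow their definitions", {
  t <- make_table(rbind("134/138", "134/138", "134/140"))
  d2 <- distance_matrix(t, "band_mismatch")
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 3], 2)   # bands 138 and 140 mismatch
  S <- similarity_matrix(binarize(t))
  d1 <- distance_matrix(S, "one_minus_gs")
  expect_equal(d1[1, 3], 1 - S$gs[1, 3])
  expect_true(all(d2 >= 0) && all(diag(d2) == 0))
})

test_that("undefined pairs make AMOVA distances fatal", {
  t <- make_table(rbind(c("134", ""), c("", "150")))
  expect_error(distance_matrix(t), "impute or drop")
})

test_that("AMOVA equals the brute-force oracle on small matrices", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(n * 3), n)
    d2 <- as.matrix(dist(pts))^2
    groups <- sample(c("a", "b", if (n > 5) "c"), n, replace = TRUE)
    while (length(unique(groups)) < 2) groups <- sample(c("a", "b"), n, TRUE)
    a <- suppressWarnings(amova(d2, groups, n_perm = 0))
    o <- amova_brute(d2, groups)
    expect_equal(a$table$SS[1], o$ss_among, tolerance = 1e-9)
    expect_equal(a$table$SS[2], o$ss_within, tolerance = 1e-9)
    expect_equal(a$table$sigma2[1], o$sigma_a, tolerance = 1e-9)
    expect_equal(a$table$sigma2[2], o$sigma_w, tolerance = 1e-9)
    expect_equal(a$phi_st, o$phi, tolerance = 1e-9)
    expect_equal(sum(a$table$percent[1:2]), 100, tolerance = 1e-6)
    expect_equal(a$table$SS[3], a$table$SS[1] + a$table$SS[2],
                 tolerance = 1e-9)
  }
})

test_that("AMOVA sums of squares agree with an independent permutational
           MANOVA implementation", {
  skip_if_not_installed("vegan")
  set.seed(11)
  pts <- matrix(rnorm(30), 10)
  d <- dist(pts)
  groups <- rep(c("x", "y"), each = 5)
  a <- amova(as.matrix(d)^2, groups, n_perm = 0)
  v <- vegan::adonis2(d ~ g, data = data.frame(g = groups),
                      permutations = 0)
  expect_equal(a$table$SS[1], v$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(a$table$SS[2], v$SumOfSqs[2], tolerance = 1e-8)
})

test_that("two internally identical groups give 100% among-group variance", {
  d2 <- matrix(4, 6, 6)
  d2[1:3, 1:3] <- 0
  d2[4:6, 4:6] <- 0
  suppressWarnings(a <- amova(d2, rep(c("g1", "g2"), each = 3), n_perm = 99,
                              seed = 1))
  expect_equal(a$phi_st, 1)
  expect_equal(a$table$percent[1], 100)
})

test_that("AMOVA permutation p is seed-reproducible and label-invariant", {
  sim <- simulate_population(small_config(19))
  d2 <- distance_matrix(sim$table)
  g <- sim$table$meta$province
  a1 <- amova(d2, g, n_perm = 99, seed = 5)
  a2 <- amova(d2, g, n_perm = 99, seed = 5)
  expect_identical(a1$p_value, a2$p_value)
  relab <- paste0("zone_", g)
  a3 <- amova(d2, relab, n_perm = 99, seed = 5)
  expect_equal(a3$p_value, a1$p_value)
  expect_equal(a3$phi_st, a1$phi_st)
  expect_error(amova(d2, rep("one", nrow(d2))), "two groups")
})

test_that("PCoA of equidistant points and duplicated points behaves
           geometrically", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  p <- pcoa_ord(d)
  pos <- p$eigenvalues[p$eigenvalues > 1e-9]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  expect_lt(abs(p$eigenvalues[3]), 1e-9)

  # duplicated accession -> coincident coordinates
  d4 <- as.matrix(dist(rbind(c(0, 0), c(0, 0), c(3, 4))))
  p4 <- pcoa_ord(d4)
  expect_equal(p4$coordinates[1, ], p4$coordinates[2, ], tolerance = 1e-10)

  # all points identical -> rank 0
  d0 <- matrix(0, 4, 4)
  p0 <- pcoa_ord(d0)
  expect_equal(ncol(p0$coordinates), 0L)
})

test_that("PCoA reconstructs Euclidean-embeddable distances", {
  set.seed(3)
  pts <- matrix(rnorm(40), 10)
  d <- as.matrix(dist(pts))
  p <- pcoa_ord(d)
  expect_lt(max(abs(as.matrix(dist(p$coordinates)) - d)), 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA axes match an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(4)
  pts <- matrix(rnorm(36), 12)
  d <- as.matrix(dist(pts))
  mine <- pcoa_ord(d)
  ref <- ape::pcoa(as.dist(d))
  k <- min(3, ncol(mine$coordinates))
  for (ax in seq_len(k)) {
    expect_equal(abs(mine$coordinates[, ax]),
                 abs(ref$vectors[, ax]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("delta-K matches hand arithmetic on a 3-replicate K=1..4 table", {
  runs <- data.frame(
    K = rep(1:4, each = 3), replicate = rep(1:3, 4),
    lnP = c(-1000, -1002, -998,
            -900, -905, -895,
            -880, -884, -876,
            -870, -872, -868))
  ev <- evanno_delta_k(runs)
  # replicate-wise |L''| means: K=2: (80+76+84)/3 = 80; K=3: (10+9+11)/3 = 10
  # sd of L: K=2: 5; K=3: 4  =>  delta-K: 16 and 2.5
  dk <- ev$table$delta_k
  expect_equal(dk[ev$table$K == 2], 16)
  expect_equal(dk[ev$table$K == 3], 2.5)
  expect_true(all(is.na(dk[ev$table$K %in% c(1, 4)])))
  expect_equal(ev$best_k, 2L)
})

test_that("delta-K is near zero for linear lnP and invariant to constants", {
  set.seed(6)
  base <- data.frame(K = rep(1:5, each = 3), replicate = rep(1:3, 5))
  base$lnP <- -1000 + 50 * base$K + rnorm(nrow(base), 0, 0.5)
  ev <- evanno_delta_k(base)
  expect_true(all(ev$table$delta_k < 5, na.rm = TRUE))
  shifted <- base; shifted$lnP <- shifted$lnP + 12345
  ev2 <- evanno_delta_k(shifted)
  expect_equal(ev2$table$delta_k, ev$table$delta_k)

  # a single kink at K* dominates delta-K
  kink <- data.frame(K = rep(1:6, each = 3), replicate = rep(1:3, 6))
  kink$lnP <- ifelse(kink$K <= 3, -5000 + 400 * kink$K,
                     -5000 + 1200 + 20 * (kink$K - 3)) +
    rep(c(0, -6, 5), 6)
  ev3 <- evanno_delta_k(kink)
  expect_equal(ev3$best_k, 3L)
  gap <- data.frame(K = rep(c(1, 2, 4), each = 2), replicate = rep(1:2, 3),
                    lnP = -(1:6))
  expect_error(evanno_delta_k(gap), "contiguous")
})
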