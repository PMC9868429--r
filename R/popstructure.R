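#' Pairwise squared-distance matrix for AMOVA
#'
#' Two distance kinds are supported: `"band_mismatch"` (default), the number
#' of mismatching presence/absence bands between two accessions over
#' mutually scored columns - the squared Euclidean distance on the binary
#' encoding - and `"one_minus_gs"`, 1 minus the simple-matching similarity.
#'
#' @param x a [germplasm_table], band matrix from [binarize()], or
#'   `similarity_matrix` (required for `"one_minus_gs"` unless a table/band
#'   matrix is given)
#' @param kind `"band_mismatch"` or `"one_minus_gs"`
#' @return symmetric non-negative matrix with zero diagonal
#' @export
distance_matrix <- function(x, kind = c("band_mismatch", "one_minus_gs")) {
  kind <- match.arg(kind)
  if (inherits(x, "germplasm_table")) x <- binarize(x)
  if (inherits(x, "similarity_matrix")) {
    if (kind != "one_minus_gs")
      stop("band_mismatch distances need a band matrix or table")
    d <- 1 - x$gs
  } else {
    sim <- similarity_matrix(x)
    d <- if (kind == "one_minus_gs") 1 - sim$gs
         else (1 - sim$gs) * sim$shared   # mismatch count
  }
  if (anyNA(d))
    stop("undefined pairs (no mutually scored columns); ",
         "impute or drop those accessions before AMOVA")
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Distance-based analysis of molecular variance (AMOVA)
#'
#' Two-level AMOVA from a matrix of squared pairwise distances, partitioning
#' molecular variance among and within groups. Sums of squares follow the
#' classical distance formulation:
#' SS_total = (1/N) sum_\{i<j\} d2_ij;
#' SS_within = sum_g (1/n_g) sum_\{i<j in g\} d2_ij;
#' SS_among = SS_total - SS_within. Variance components are
#' sigma2_w = SS_within / (N - G) and
#' sigma2_a = (SS_among / (G - 1) - sigma2_w) / n0 with
#' n0 = (N - sum n_g^2 / N) / (G - 1); Phi_ST = sigma2_a /
#' (sigma2_a + sigma2_w). Significance is assessed by freely permuting
#' individuals among groups (group sizes preserved) and counting
#' permutations with Phi at least as large:
#' p = (count + 1) / (n_perm + 1).
#'
#' Negative variance components are reported as computed (no truncation),
#' with a warning; percentages then use the raw components.
#'
#' @param d2 symmetric matrix of squared distances, zero diagonal
#' @param groups group label per row of `d2` (>= 2 groups, each non-empty)
#' @param n_perm number of permutations (default 999; 0 skips the test)
#' @param seed RNG seed for the permutation test
#' @return list of class `amova_result`: `table` (data frame with df, SS,
#'   variance component and percent per level), `phi_st`, `p_value`,
#'   `n_perm`, `seed`
#' @export
amova <- function(d2, groups, n_perm = 999L, seed = 1L) {
  stopifnot(is.matrix(d2), nrow(d2) == ncol(d2),
            length(groups) == nrow(d2))
  n <- nrow(d2)
  groups <- as.character(groups)
  gl <- unique(groups)
  G <- length(gl)
  if (G < 2L) stop("AMOVA needs at least two groups")
  if (n < 3L) stop("AMOVA needs at least three individuals")
  ng <- as.vector(table(groups)[gl])

  ss <- function(grp) {
    # within-group sum: sum over groups of (1/n_g) * sum_{i<j in g} d2
    ind <- matrix(0, n, G)
    ind[cbind(seq_len(n), match(grp, gl))] <- 1
    within_tot <- diag(crossprod(ind, d2 %*% ind)) / 2   # per-group pair sums
    sum(within_tot / colSums(ind))
  }
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- ss(groups)
  ss_among <- ss_total - ss_within

  df_among <- G - 1L
  df_within <- n - G
  sigma_w <- ss_within / df_within
  n0 <- (n - sum(ng^2) / n) / df_among
  sigma_a <- (ss_among / df_among - sigma_w) / n0
  if (sigma_a < 0)
    warning("negative among-group variance component (reported untruncated)")
  tot <- sigma_a + sigma_w
  phi <- if (tot == 0) NA_real_ else sigma_a / tot
  if (tot == 0) warning("all distances zero; Phi_ST undefined")

  p <- NA_real_
  if (n_perm > 0 && !is.na(phi)) {
    set.seed(seed)
    phi_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      gperm <- groups[sample.int(n)]
      ssw <- ss(gperm)
      ssa <- ss_total - ssw
      sw <- ssw / df_within
      sa <- (ssa / df_among - sw) / n0
      phi_perm[b] <- sa / (sa + sw)
    }
    p <- (sum(phi_perm >= phi) + 1) / (n_perm + 1)
  }

  tab <- data.frame(
    source = c("among groups", "within groups", "total"),
    df = c(df_among, df_within, n - 1L),
    SS = c(ss_among, ss_within, ss_total),
    sigma2 = c(sigma_a, sigma_w, tot),
    percent = 100 * c(sigma_a, sigma_w, tot) / tot)
  structure(list(table = tab, phi_st = phi, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  tab <- x$table
  tab$SS <- round(tab$SS, 4); tab$sigma2 <- round(tab$sigma2, 6)
  tab$percent <- round(tab$percent, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Phi_ST = %.4f; permutation p = %s (%d permutations, seed %d)\n",
              x$phi_st, format(x$p_value), x$n_perm, x$seed))
  invisible(x)
}

#' Principal coordinate analysis
#'
#' Metric ordination of a distance matrix: Gower double-centering of
#' -d^2 / 2 followed by eigendecomposition. Axes with positive eigenvalues
#' carry the coordinates (column k scaled by sqrt(lambda_k)); negative
#' eigenvalues are reported but their axes dropped. Percent variance per
#' axis is relative to the sum of positive eigenvalues.
#'
#' @param d symmetric distance matrix with zero diagonal (not squared)
#' @param eps eigenvalues with |lambda| below `eps * max(|lambda|)` are
#'   treated as zero
#' @return list of class `pcoa_result`: `eigenvalues` (all, descending),
#'   `coordinates` (n x k matrix for the k positive axes), `percent`
#'   (variance explained per retained axis)
#' @export
pcoa_ord <- function(d, eps = 1e-9) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(d)
  B <- -0.5 * d^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values
  tol <- eps * max(abs(lam), 1)
  pos <- lam > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lam[pos]), sum(pos))
  dimnames(coords) <- list(rownames(d),
                           if (ncol(coords)) paste0("Axis",
                                                    seq_len(ncol(coords))))
  structure(list(eigenvalues = lam,
                 coordinates = coords,
                 percent = 100 * lam[pos] / sum(lam[pos]),
                 n_negative = sum(lam < -tol)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(5L, length(x$percent))
  cat(sprintf("PCoA: %d positive axes (%d negative eigenvalues dropped)\n",
              length(x$percent), x$n_negative))
  for (i in seq_len(k))
    cat(sprintf("  Axis %d: %.1f%% of the variation\n", i, x$percent[i]))
  invisible(x)
}

#' Evanno delta-K from clustering-run log-likelihoods
#'
#' For replicated clustering runs at contiguous K, per replicate r:
#' L'_r(K) = L_r(K) - L_r(K-1) and |L''_r(K)| = |L'_r(K+1) - L'_r(K)|;
#' then delta-K(K) = mean_r |L''_r(K)| / sd_r(L(K)). Delta-K is defined only
#' for interior K with a positive replicate standard deviation; all local
#' maxima are reported, since real collections often support more than one
#' clustering level.
#'
#' @param runs a `structure_runs` data frame (columns K, replicate, lnP)
#' @return list of class `evanno_result`: `table` (per K: n_rep, mean_lnP,
#'   sd_lnP, mean_Lp, mean_abs_Lpp, delta_k), `best_k` (argmax delta-K),
#'   `local_maxima` (all interior local maxima of delta-K)
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "replicate", "lnP") %in% names(runs)))
  tab <- table(runs$K)
  ks <- sort(as.integer(names(tab)))
  ks <- ks[tab[as.character(ks)] >= 2L]
  if (length(ks) < 3L)
    stop("delta-K needs >= 3 contiguous K values with >= 2 replicates each")
  if (any(diff(ks) != 1L))
    stop("K values must form a contiguous range (after dropping ",
         "single-replicate K)")
  reps <- sort(unique(runs$replicate))
  L <- matrix(NA_real_, nrow = length(reps), ncol = length(ks),
              dimnames = list(reps, ks))
  for (r in seq_along(reps))
    for (k in seq_along(ks)) {
      v <- runs$lnP[runs$replicate == reps[r] & runs$K == ks[k]]
      if (length(v) == 1L) L[r, k] <- v
    }
  mean_lnp <- colMeans(L, na.rm = TRUE)
  sd_lnp <- apply(L, 2, stats::sd, na.rm = TRUE)
  Lp <- t(apply(L, 1, diff))                       # L'(K), K = ks[-1]
  if (length(ks) == 2L) Lp <- matrix(Lp, nrow = nrow(L))
  Lpp <- t(apply(Lp, 1, diff))                     # L''(K), interior K
  if (ncol(Lp) == 2L) Lpp <- matrix(Lpp, nrow = nrow(L))
  mean_abs_lpp <- colMeans(abs(Lpp), na.rm = TRUE)
  interior <- ks[-c(1, length(ks))]
  dk <- rep(NA_real_, length(ks))
  names(dk) <- ks
  for (i in seq_along(interior)) {
    k <- interior[i]
    s <- sd_lnp[as.character(k)]
    dk[as.character(k)] <- if (is.na(s) || s == 0) NA_real_
                           else mean_abs_lpp[i] / s
  }
  res <- data.frame(K = ks, n_rep = as.vector(tab[as.character(ks)]),
                    mean_lnP = mean_lnp, sd_lnP = sd_lnp,
                    delta_k = dk, row.names = NULL)
  dkv <- dk[!is.na(dk)]
  best <- as.integer(names(dkv)[which.max(dkv)])
  locmax <- integer(0)
  dki <- dk[as.character(interior)]
  for (i in seq_along(interior)) {
    left <- if (i == 1) -Inf else dki[i - 1]
    right <- if (i == length(interior)) -Inf else dki[i + 1]
    if (!is.na(dki[i]) && dki[i] >= max(left, right, na.rm = TRUE))
      locmax <- c(locmax, interior[i])
  }
  structure(list(table = res, best_k = best, local_maxima = locmax),
            class = "evanno_result")
}

#' @export
print.evanno_result <- function(x, ...) {
  tab <- x$table
  tab$mean_lnP <- round(tab$mean_lnP, 2)
  tab$sd_lnP <- round(tab$sd_lnP, 3)
  tab$delta_k <- round(tab$delta_k, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("best K = %d; local delta-K maxima at K = %s\n", x$best_k,
              paste(x$local_maxima, collapse = ", ")))
  invisible(x)
}
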