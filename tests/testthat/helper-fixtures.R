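# Small in-code fixtures shared across test files.

# Build a germplasm_table from a character matrix of slash-separated calls.
make_table <- function(cells, names = NULL, provinces = NULL, loci = NULL) {
  m <- as.matrix(cells)
  n <- nrow(m)
  if (is.null(loci)) loci <- sprintf("SSR%02d", seq_len(ncol(m)))
  colnames(m) <- loci
  germplasm_table(m, data.frame(
    accession_id = sprintf("A%03d", seq_len(n)),
    name = if (is.null(names)) sprintf("Var %d", seq_len(n)) else names,
    province = if (is.null(provinces)) rep("FR", n) else provinces,
    stringsAsFactors = FALSE))
}

# A 6-accession, 3-locus table: one clone pair (rows 1-2, different names),
# one triploid (row 5), one accession with a missing locus (row 6).
toy_table <- function() {
  make_table(rbind(
    c("134/138", "200/204", "150"),
    c("134/138", "200/204", "150"),
    c("134/140", "200/202", "150/152"),
    c("136/138", "202/204", "152"),
    c("134/138/142", "200/204/208", "150/154"),
    c("134", "", "152/154")),
    names = c("Capattera FR", "Campanella LT", "Moscarola RM",
              "Cannellina RI", "Angina FR", "Pero 38"),
    provinces = c("FR", "LT", "RM", "RI", "FR", "FR"))
}

# Brute-force AMOVA oracle: explicit loops over the stated sums of squares.
amova_brute <- function(d2, groups) {
  n <- nrow(d2)
  gl <- unique(groups)
  G <- length(gl)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  ng <- numeric(G)
  for (g in seq_len(G)) {
    idx <- which(groups == gl[g])
    ng[g] <- length(idx)
    s <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d2[idx[a], idx[b]]
    ss_within <- ss_within + s / ng[g]
  }
  ss_among <- ss_total - ss_within
  sigma_w <- ss_within / (n - G)
  n0 <- (n - sum(ng^2) / n) / (G - 1)
  sigma_a <- (ss_among / (G - 1) - sigma_w) / n0
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       sigma_a = sigma_a, sigma_w = sigma_w,
       phi = sigma_a / (sigma_a + sigma_w))
}

# Small fast synthetic config for tests that loop over seeds.
small_config <- function(seed, missing_rate = 0, ...) {
  synthetic_config(seed = seed, n_accessions = 60L,
                   clone_groups = NULL,
                   homonym_groups = NULL,
                   missing_rate = missing_rate, ...)
}
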