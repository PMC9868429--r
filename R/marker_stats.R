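#' Allele frequencies at one locus
#'
#' Frequencies are estimated from diploid genotypes only (triploids are
#' excluded from per-locus statistics, as is standard when dosage at
#' triallelic profiles is unknown). An accession contributes at a locus if
#' its SSR ploidy call is not triploid and the cell is non-missing with at
#' most two distinct alleles; a single-allele call is counted as a homozygote
#' (two copies).
#'
#' @param table a [germplasm_table]
#' @param locus locus id or index
#' @param min_loci triallelic-locus threshold used to exclude triploids
#'   (see [classify_ploidy_ssr()]); default 2
#' @return named numeric vector of allele frequencies summing to 1, with
#'   attribute `n` (number of diploid genotypes used); `NULL` with a warning
#'   if no usable genotype exists
#' @export
allele_frequencies <- function(table, locus, min_loci = 2L) {
  stopifnot(inherits(table, "germplasm_table"))
  j <- if (is.character(locus)) match(locus, table$loci) else locus
  if (is.na(j)) stop("unknown locus: ", locus)
  keep <- diploid_mask(table, min_loci)
  counts <- integer(0)
  n_used <- 0L
  tallied <- new.env()
  for (i in which(keep)) {
    a <- table$geno[[i, j]]
    if (length(a) == 0L || length(a) > 2L) next
    if (length(a) == 1L) a <- c(a, a)
    n_used <- n_used + 1L
    for (al in a) {
      key <- as.character(al)
      tallied[[key]] <- (if (is.null(tallied[[key]])) 0L else tallied[[key]]) + 1L
    }
  }
  if (n_used == 0L) {
    warning("locus ", table$loci[j], ": no usable diploid genotypes")
    return(NULL)
  }
  keys <- ls(tallied)
  cnt <- vapply(keys, function(k) tallied[[k]], integer(1))
  ord <- order(as.integer(keys))
  p <- cnt[ord] / sum(cnt)
  names(p) <- keys[ord]
  attr(p, "n") <- n_used
  p
}

# accessions whose SSR ploidy call is not triploid
diploid_mask <- function(table, min_loci = 2L) {
  tri <- vapply(seq_len(nrow(table$geno)), function(i)
    count_triallelic_loci(table, i), integer(1))
  tri < min_loci
}

#' Per-locus SSR informativeness statistics
#'
#' For allele frequencies p at a locus with n diploid genotypes:
#' \itemize{
#'   \item Na: observed number of alleles (over the diploid subset)
#'   \item Ne: effective number of alleles, 1 / sum(p^2)
#'   \item Ho: observed heterozygosity, fraction of diploids with two
#'     distinct alleles
#'   \item PIC: Nei's gene diversity 1 - sum(p^2) (plug-in)
#'   \item He: expected heterozygosity with the unbiased small-sample
#'     correction, (2n / (2n - 1)) * (1 - sum(p^2))
#'   \item I: Shannon information index, -sum(p * log(p))
#' }
#' A monomorphic locus yields Ho = He = I = PIC = 0 and Ne = 1.
#'
#' @param table a [germplasm_table]
#' @param locus locus id or index
#' @param min_loci triploid-exclusion threshold (see [allele_frequencies()])
#' @return one-row data frame: locus, n, Na, Ne, Ho, He, I, PIC
#' @export
locus_stats <- function(table, locus, min_loci = 2L) {
  j <- if (is.character(locus)) match(locus, table$loci) else locus
  p <- allele_frequencies(table, j, min_loci)
  if (is.null(p))
    return(data.frame(locus = table$loci[j], n = 0L, Na = NA, Ne = NA,
                      Ho = NA, He = NA, I = NA, PIC = NA))
  n <- attr(p, "n")
  keep <- diploid_mask(table, min_loci)
  het <- 0L
  for (i in which(keep)) {
    a <- table$geno[[i, j]]
    if (length(a) == 2L) het <- het + 1L
  }
  sp2 <- sum(p^2)
  data.frame(locus = table$loci[j], n = n,
             Na = length(p),
             Ne = 1 / sp2,
             Ho = het / n,
             He = (2 * n / (2 * n - 1)) * (1 - sp2),
             I = -sum(ifelse(p > 0, p * log(p), 0)),
             PIC = 1 - sp2,
             stringsAsFactors = FALSE)
}

#' Panel-level summary of SSR statistics
#'
#' Computes [locus_stats()] for every locus, appends arithmetic column means
#' and standard deviations over the loci with defined statistics, and the
#' panel discrimination power over all accessions.
#'
#' @param table a [germplasm_table]
#' @param min_loci triploid-exclusion threshold
#' @param dp_missing how [discrimination_power()] treats accessions with
#'   missing loci
#' @return list of class `panel_stats`: `per_locus` (data frame), `mean` and
#'   `sd` (named numeric vectors over n, Na, Ho, He, I, PIC), `dp`
#'   (discrimination power), `dp_detail`, `excluded_loci`
#' @export
panel_summary <- function(table, min_loci = 2L,
                          dp_missing = c("drop", "match_any")) {
  per <- do.call(rbind, lapply(seq_along(table$loci),
                               function(j) locus_stats(table, j, min_loci)))
  ok <- !is.na(per$Na)
  ms <- summarize_locus_stats(per[ok, , drop = FALSE])
  dp <- discrimination_power(table, missing = match.arg(dp_missing))
  structure(list(per_locus = per, mean = ms$mean, sd = ms$sd,
                 dp = dp$dp, dp_detail = dp,
                 excluded_loci = per$locus[!ok]),
            class = "panel_stats")
}

#' Column means and standard deviations of a per-locus statistics table
#'
#' The summary row of a marker descriptive-statistics table: arithmetic means
#' and sample standard deviations of the numeric columns (sample size, Na,
#' Ho, He, I, PIC, and any others present).
#'
#' @param per_locus data frame with one row per locus; numeric columns are
#'   summarized
#' @return list with named vectors `mean` and `sd`
#' @export
summarize_locus_stats <- function(per_locus) {
  num <- vapply(per_locus, is.numeric, logical(1))
  cols <- per_locus[, num, drop = FALSE]
  list(mean = vapply(cols, mean, numeric(1)),
       sd = vapply(cols, stats::sd, numeric(1)))
}

#' @export
print.panel_stats <- function(x, ...) {
  df <- x$per_locus
  df[-(1:2)] <- lapply(df[-(1:2)], round, 3)
  print(df, row.names = FALSE)
  cat("Mean:", paste(sprintf("%s=%.3f", names(x$mean), x$mean),
                     collapse = " "), "\n")
  cat("S.D.:", paste(sprintf("%s=%.3f", names(x$sd), x$sd),
                     collapse = " "), "\n")
  cat(sprintf("Discrimination power (DP) = %.4f over %d accessions\n",
              x$dp, x$dp_detail$n_used))
  invisible(x)
}

#' Panel discrimination power
#'
#' DP = 1 - sum(p_i^2), where p_i is the frequency of the i-th distinct
#' multilocus genotype among all accessions (diploid and triploid alike).
#' Equivalently, the probability that two accessions drawn with replacement
#' carry different multilocus profiles. Genotype identity requires exact
#' equality of the allele sets at every locus; by default accessions with any
#' missing locus are excluded (`missing = "match_any"` instead lets a
#' missing locus match anything, merging compatible profiles greedily).
#'
#' @param table a [germplasm_table]
#' @param missing `"drop"` (default) or `"match_any"`
#' @return list: `dp`, `freqs` (genotype-frequency vector), `n_used`,
#'   `n_profiles`
#' @export
discrimination_power <- function(table, missing = c("drop", "match_any")) {
  missing <- match.arg(missing)
  keys <- profile_keys(table)
  miss <- rowSums(is_missing_cell(table)) > 0L
  if (missing == "drop") {
    keys <- keys[!miss]
  } else {
    # merge each missing-profile accession into the first compatible
    # complete profile, if unique; otherwise keep as its own profile
    complete <- keys[!miss]
    for (i in which(miss)) {
      cand <- unique(complete[compatible_profiles(table, i, which(!miss))])
      keys[i] <- if (length(cand) == 1L) cand else keys[i]
    }
  }
  if (length(keys) == 0L)
    return(list(dp = NA_real_, freqs = numeric(0), n_used = 0L,
                n_profiles = 0L))
  p <- as.vector(table(keys)) / length(keys)
  list(dp = 1 - sum(p^2), freqs = p, n_used = length(keys),
       n_profiles = length(p))
}

profile_keys <- function(table) {
  vapply(seq_len(nrow(table$geno)), function(i)
    paste(vapply(seq_along(table$loci),
                 function(j) format_allele_set(table$geno[[i, j]]),
                 character(1)), collapse = "|"),
    character(1))
}

compatible_profiles <- function(table, i, js) {
  vapply(js, function(k) {
    for (j in seq_along(table$loci)) {
      a <- table$geno[[i, j]]; b <- table$geno[[k, j]]
      if (length(a) && length(b) && !identical(a, b)) return(FALSE)
    }
    TRUE
  }, logical(1))
}
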