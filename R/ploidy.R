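#' Count triallelic loci for an accession
#'
#' The number of non-missing loci at which an accession shows three (or more)
#' distinct alleles. Triallelic loci in codominant SSR profiles are the
#' molecular signature of triploidy.
#'
#' @param table a [germplasm_table]
#' @param accession accession id or row index
#' @return integer count
#' @export
count_triallelic_loci <- function(table, accession) {
  i <- if (is.character(accession))
    match(accession, table$meta$accession_id) else accession
  if (is.na(i)) stop("unknown accession: ", accession)
  sum(vapply(seq_along(table$loci),
             function(j) length(table$geno[[i, j]]) >= 3L, logical(1)))
}

#' SSR-based ploidy classification
#'
#' An accession with `min_loci` or more triallelic loci is called triploid;
#' with exactly one triallelic locus (below the threshold) it is a putative
#' triploid - a single three-allele locus is not proof of triploidy, since
#' somatic mutations, chimerism or segmental duplications can generate a
#' spurious third allele - and with none it is diploid. Summaries report both
#' the >=1 and >=`min_loci` tallies.
#'
#' @param table a [germplasm_table]
#' @param min_loci triallelic loci required for a triploid call (default 2)
#' @return data frame of class `ploidy_calls`: accession_id, n_triallelic,
#'   call (`"diploid"`, `"putative_triploid"`, `"triploid"`), method
#' @export
classify_ploidy_ssr <- function(table, min_loci = 2L) {
  if (min_loci < 1L) stop("min_loci must be >= 1")
  n <- n_accessions(table)
  tri <- vapply(seq_len(n), function(i) count_triallelic_loci(table, i),
                integer(1))
  call <- ifelse(tri >= min_loci, "triploid",
                 ifelse(tri >= 1L, "putative_triploid", "diploid"))
  out <- data.frame(accession_id = table$meta$accession_id,
                    n_triallelic = tri, call = call, method = "ssr",
                    stringsAsFactors = FALSE)
  attr(out, "min_loci") <- as.integer(min_loci)
  class(out) <- c("ploidy_calls", class(out))
  out
}

#' Tally SSR ploidy calls at both thresholds
#'
#' @param calls output of [classify_ploidy_ssr()]
#' @return data frame: threshold (`">=1 triallelic locus"`,
#'   `">=min_loci triallelic loci"`), count, percent (of accessions)
#' @export
ploidy_tally <- function(calls) {
  n <- nrow(calls)
  ge1 <- sum(calls$n_triallelic >= 1L)
  min_loci <- attr(calls, "min_loci")
  gem <- sum(calls$call == "triploid")
  data.frame(threshold = c(">=1 triallelic locus",
                           sprintf(">=%d triallelic loci", min_loci)),
             count = c(ge1, gem),
             percent = 100 * c(ge1, gem) / n)
}

#' Detect G1 peaks in a fluorescence histogram
#'
#' Counts are smoothed with a centered moving average and local maxima
#' exceeding a prominence threshold (a fraction of the maximum smoothed
#' count) are reported in ascending channel order.
#'
#' @param hist a `fcm_histogram`
#' @param window moving-average window length in channels (odd; default 9)
#' @param min_prominence minimum peak height as a fraction of the maximum
#'   smoothed count (default 0.1)
#' @param min_distance minimum channel separation between reported peaks
#'   (default `window`)
#' @return data frame of class `peak_set`: channel, height; zero rows (with
#'   attribute `flagged = TRUE`) if nothing qualifies
#' @export
detect_g1_peaks <- function(hist, window = 9L, min_prominence = 0.1,
                            min_distance = window) {
  stopifnot(inherits(hist, "fcm_histogram"), window >= 1L)
  sm <- as.numeric(stats::filter(hist$count, rep(1 / window, window),
                                 sides = 2))
  sm[is.na(sm)] <- 0
  if (max(sm) <= 0) {
    out <- data.frame(channel = numeric(0), height = numeric(0))
    attr(out, "flagged") <- TRUE
    class(out) <- c("peak_set", class(out))
    return(out)
  }
  pk <- pracma::findpeaks(sm, minpeakheight = min_prominence * max(sm),
                          minpeakdistance = max(1L, as.integer(min_distance)))
  if (is.null(pk)) {
    out <- data.frame(channel = numeric(0), height = numeric(0))
    attr(out, "flagged") <- TRUE
  } else {
    ord <- order(pk[, 2])
    out <- data.frame(channel = hist$channel[pk[ord, 2]],
                      height = pk[ord, 1])
    attr(out, "flagged") <- FALSE
  }
  class(out) <- c("peak_set", class(out))
  out
}

#' Cytometric ploidy call from a G1 peak ratio
#'
#' DAPI fluorescence is proportional to DNA content, so the ratio of the
#' sample G1 peak to a known diploid reference peak determines ploidy:
#' a ratio within 1 +/- `halfwidth` is diploid, within 1.5 +/- `halfwidth`
#' triploid. Ratios outside both windows (or outside \[0.75, 2.25\] overall)
#' are left unassigned; a ratio near 2 is flagged as a tetraploid candidate
#' even though no tetraploid window is called by default.
#'
#' @param sample_peak sample G1 peak position (> 0)
#' @param reference_peak diploid reference G1 peak position (> 0)
#' @param halfwidth half-width of the ratio acceptance windows (default 0.1)
#' @return one-row data frame: ratio, call (`"diploid"`, `"triploid"`,
#'   `"unassigned"`), method, note
#' @export
call_ploidy_dapi <- function(sample_peak, reference_peak, halfwidth = 0.1) {
  stopifnot(sample_peak > 0, reference_peak > 0)
  r <- sample_peak / reference_peak
  note <- ""
  if (r < 0.75 || r > 2.25) {
    warning(sprintf("peak ratio %.3f outside the interpretable range", r))
    call <- "unassigned"
    note <- "ratio outside [0.75, 2.25]"
  } else if (abs(r - 1) <= halfwidth) {
    call <- "diploid"
  } else if (abs(r - 1.5) <= halfwidth) {
    call <- "triploid"
  } else {
    call <- "unassigned"
    note <- if (abs(r - 2) <= halfwidth) "tetraploid candidate"
            else "between ploidy windows"
  }
  data.frame(ratio = r, call = call, method = "cytometry", note = note,
             stringsAsFactors = FALSE)
}

#' Genome-size estimation against internal standards
#'
#' With propidium-iodide staining, fluorescence is proportional to DNA
#' content, so 2C_sample = 2C_standard * (sample peak / standard peak) for
#' each co-chopped reference standard; the combined estimate is the
#' arithmetic mean over standards. If the standards' implied channels-per-pg
#' slopes disagree by more than `slope_tol` (possible mis-assigned peaks), a
#' warning is raised.
#'
#' @param sample_peak sample G1 peak position
#' @param standards data frame with columns `name`, `peak` (channel) and
#'   `ref_2c` (known 2C content, pg)
#' @param slope_tol relative disagreement tolerated between standards'
#'   channel-per-pg slopes (default 0.1)
#' @return list of class `genome_size_estimate`: `per_standard` (data frame
#'   name, peak, ref_2c, est_2c_pg), `combined_2c_pg`
#' @export
estimate_genome_size_pi <- function(sample_peak, standards, slope_tol = 0.1) {
  stopifnot(sample_peak > 0, nrow(standards) >= 1L,
            all(c("name", "peak", "ref_2c") %in% names(standards)),
            all(standards$peak > 0), all(standards$ref_2c > 0))
  est <- standards$ref_2c * sample_peak / standards$peak
  slopes <- standards$peak / standards$ref_2c
  if (length(slopes) > 1L &&
      (max(slopes) - min(slopes)) / min(slopes) > slope_tol)
    warning("standards imply inconsistent channel-per-pg slopes; ",
            "check peak assignment")
  per <- data.frame(name = standards$name, peak = standards$peak,
                    ref_2c = standards$ref_2c, est_2c_pg = est)
  structure(list(per_standard = per, combined_2c_pg = mean(est)),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  print(x$per_standard, row.names = FALSE)
  cat(sprintf("combined 2C = %.3f pg\n", x$combined_2c_pg))
  invisible(x)
}

#' Assign detected peaks to expected histogram components
#'
#' When a sample is co-chopped with internal standards, the run's histogram
#' carries one G1 peak per component at roughly known relative positions.
#' Each expected component is matched greedily to the nearest unclaimed
#' detected peak; an ambiguous match (two components competing for one peak)
#' raises a warning.
#'
#' @param peaks a `peak_set` from [detect_g1_peaks()]
#' @param expected data frame with columns `name` and `channel` (expected
#'   peak positions)
#' @return `expected` with columns `peak` (matched channel) and `height`
#' @export
assign_peaks <- function(peaks, expected) {
  stopifnot(nrow(peaks) >= 1L, all(c("name", "channel") %in% names(expected)))
  expected$peak <- NA_real_
  expected$height <- NA_real_
  taken <- rep(FALSE, nrow(peaks))
  for (i in order(expected$channel)) {
    d <- abs(peaks$channel - expected$channel[i])
    d[taken] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) {
      warning("fewer detected peaks than expected components")
      next
    }
    if (sum(abs(d - d[j]) < 1e-9) > 1L)
      warning("ambiguous peak assignment for component ", expected$name[i])
    expected$peak[i] <- peaks$channel[j]
    expected$height[i] <- peaks$height[j]
    taken[j] <- TRUE
  }
  expected
}

#' SSR vs cytometry ploidy concordance
#'
#' Joins SSR and cytometric calls on accession id and tabulates agreement.
#' Putative triploids (one triallelic locus) are mapped to diploid before
#' comparison by default, since a single triallelic locus is not treated as
#' a final triploid call.
#'
#' @param ssr_calls a `ploidy_calls` data frame (method `"ssr"`)
#' @param cytometry_calls data frame with columns `accession_id`, `call`
#' @param putative_as what a putative triploid counts as (default
#'   `"diploid"`)
#' @return list of class `ploidy_concordance`: `confusion` (table,
#'   SSR x cytometry), `agreement` (fraction), `n`, `discordant`
#'   (data frame of disagreeing accessions)
#' @export
concordance <- function(ssr_calls, cytometry_calls,
                        putative_as = c("diploid", "triploid")) {
  putative_as <- match.arg(putative_as)
  ids <- intersect(ssr_calls$accession_id, cytometry_calls$accession_id)
  if (length(ids) == 0L) stop("no shared accession ids between call sets")
  s <- ssr_calls$call[match(ids, ssr_calls$accession_id)]
  s[s == "putative_triploid"] <- putative_as
  c_ <- cytometry_calls$call[match(ids, cytometry_calls$accession_id)]
  conf <- table(ssr = factor(s, levels = c("diploid", "triploid")),
                cytometry = factor(c_, levels = c("diploid", "triploid")))
  agree <- s == c_
  structure(list(confusion = conf, agreement = mean(agree),
                 n = length(ids),
                 discordant = data.frame(accession_id = ids[!agree],
                                         ssr = s[!agree],
                                         cytometry = c_[!agree])),
            class = "ploidy_concordance")
}

#' @export
print.ploidy_concordance <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("agreement: %d/%d (%.1f%%)\n", round(x$agreement * x$n),
              x$n, 100 * x$agreement))
  if (nrow(x$discordant)) {
    cat("discordant accessions:\n")
    print(x$discordant, row.names = FALSE)
  }
  invisible(x)
}
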