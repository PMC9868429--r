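#' Read a wide-format SSR genotype table
#'
#' Expects delimited text with one row per accession and columns
#' `accession_id`, `name`, `province`, followed by one column per locus
#' containing slash-separated allele sizes in base pairs ("134/138",
#' "134/138/142"; empty = missing). The field separator is comma by default
#' with tab auto-detection. Fractional sizes are rounded half-up at ingest.
#'
#' Accessions whose fraction of missing-or-unparseable loci exceeds
#' `max_missing_frac` are dropped with a logged reason (collections routinely
#' exclude a few samples for missing data); malformed cells are recorded as
#' missing and reported in the `issues` attribute with row/column coordinates.
#' A duplicated accession id is a fatal error.
#'
#' @param path path to the delimited text file
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#' @param max_missing_frac drop accessions with more than this fraction of
#'   missing loci (default 0.5)
#' @param max_alleles maximum distinct alleles per cell (default 3)
#' @return a [germplasm_table]; attributes `dropped` (data frame of excluded
#'   accessions and reasons) and `issues` (cell-level parse problems)
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, sep = NULL, max_missing_frac = 0.5,
                                max_alleles = 3L) {
  stopifnot(file.exists(path))
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 4L)
    stop("genotype table needs id, name, province plus >=1 locus column")
  names(df)[1:3] <- c("accession_id", "name", "province")
  loci <- names(df)[-(1:3)]
  ids <- df$accession_id
  if (anyDuplicated(ids))
    stop("duplicate accession_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  geno <- matrix(vector("list", nrow(df) * length(loci)), nrow = nrow(df),
                 dimnames = list(ids, loci))
  issues <- list()
  for (i in seq_len(nrow(df))) {
    for (j in seq_along(loci)) {
      cell <- df[[loci[j]]][i]
      a <- tryCatch(parse_allele_set(cell), error = function(e) NA)
      if (length(a) == 1L && is.na(a[1])) {
        issues[[length(issues) + 1L]] <- data.frame(
          row = i, accession_id = ids[i], locus = loci[j],
          value = cell, problem = "malformed allele token")
        a <- integer(0)
      } else if (length(a) > max_alleles) {
        issues[[length(issues) + 1L]] <- data.frame(
          row = i, accession_id = ids[i], locus = loci[j],
          value = cell, problem = sprintf(">%d alleles", max_alleles))
        a <- integer(0)
      }
      geno[[i, j]] <- a
    }
  }
  miss_frac <- rowMeans(matrix(lengths(geno) == 0L, nrow = nrow(df)))
  drop <- miss_frac > max_missing_frac
  dropped <- data.frame(accession_id = ids[drop],
                        missing_fraction = miss_frac[drop],
                        reason = rep("excluded due to missing data",
                                     sum(drop)))
  if (any(drop))
    message(sprintf("%d accession(s) excluded due to missing data: %s",
                    sum(drop), paste(ids[drop], collapse = ", ")))
  meta <- data.frame(accession_id = ids, name = df$name,
                     province = df$province, stringsAsFactors = FALSE)
  tab <- germplasm_table(geno[!drop, , drop = FALSE],
                         meta[!drop, , drop = FALSE],
                         max_alleles = max_alleles)
  attr(tab, "dropped") <- dropped
  attr(tab, "issues") <- if (length(issues)) do.call(rbind, issues) else NULL
  tab
}

#' Write a genotype table as delimited text
#'
#' Canonical serialization: UTF-8, comma-separated, header
#' `accession_id,name,province,<loci...>`, alleles slash-separated, missing
#' cells empty. `read_genotype_table(write_genotype_table(t))` round-trips.
#'
#' @param table a [germplasm_table]
#' @param path output file path
#' @param sep field separator (default comma)
#' @return `path`, invisibly
#' @export
write_genotype_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "germplasm_table"))
  cells <- apply(table$geno, c(1, 2), function(a) format_allele_set(a[[1]]))
  cells <- matrix(cells, nrow = nrow(table$geno))
  df <- cbind(table$meta[, c("accession_id", "name", "province")],
              as.data.frame(cells, stringsAsFactors = FALSE))
  names(df) <- c("accession_id", "name", "province", table$loci)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a genotype table in GenAlEx-style layout
#'
#' Two header rows (locus count, sample size) followed by codominant allele
#' columns, two (diploid) or three columns per locus; missing alleles coded 0.
#' Provided for interoperability with spreadsheet-based population-genetics
#' workflows.
#'
#' @param table a [germplasm_table]
#' @param path output file path
#' @param ploidy_columns columns emitted per locus (2 or 3; default 3 so
#'   triallelic profiles survive the export)
#' @return `path`, invisibly
#' @export
write_genalex <- function(table, path, ploidy_columns = 3L) {
  stopifnot(inherits(table, "germplasm_table"), ploidy_columns %in% 2:3)
  n <- n_accessions(table)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(length(table$loci), n, 1, n),
                   collapse = ","), con)
  hdr <- c("accession_id", "province",
           unlist(lapply(table$loci, function(l)
             c(l, rep("", ploidy_columns - 1L)))))
  writeLines(paste(hdr, collapse = ","), con)
  for (i in seq_len(n)) {
    row <- c(table$meta$accession_id[i], table$meta$province[i])
    for (j in seq_along(table$loci)) {
      a <- table$geno[[i, j]]
      if (length(a) == 1L) a <- c(a, a)   # homozygote convention
      a <- c(a, rep(0L, ploidy_columns))[seq_len(ploidy_columns)]
      row <- c(row, a)
    }
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' Read a table of external clustering-run log-likelihoods
#'
#' Parses delimited text with columns `K`, `replicate`, `lnP` (the estimated
#' log probability of the data for each run), the input consumed by the
#' Evanno delta-K computation. Rows with a missing or non-numeric `lnP` are
#' rejected with coordinates; K values with a single replicate trigger a
#' warning (they cannot contribute a standard deviation).
#'
#' @param path delimited text file; separator auto-detected (comma/tab)
#' @return data frame of class `structure_runs` with columns K, replicate,
#'   lnP; attribute `rejected` lists dropped rows
#' @export
read_structure_runs <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", strip.white = TRUE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("k", "replicate", "lnp") %in% names(df)))
  lnp <- suppressWarnings(as.numeric(df$lnp))
  k <- suppressWarnings(as.integer(df$k))
  rep_ <- suppressWarnings(as.integer(df$replicate))
  bad <- is.na(lnp) | is.na(k) | is.na(rep_) | k < 1L | rep_ < 1L
  rejected <- NULL
  if (any(bad)) {
    rejected <- data.frame(row = which(bad), K = df$k[bad],
                           replicate = df$replicate[bad], lnP = df$lnp[bad])
    warning(sprintf("%d record(s) rejected (rows: %s)", sum(bad),
                    paste(which(bad), collapse = ", ")))
  }
  out <- data.frame(K = k[!bad], replicate = rep_[!bad], lnP = lnp[!bad])
  singles <- names(which(table(out$K) < 2L))
  if (length(singles))
    warning("K with a single replicate (excluded from delta-K): ",
            paste(singles, collapse = ", "))
  attr(out, "rejected") <- rejected
  class(out) <- c("structure_runs", class(out))
  out
}

#' Read a flow-cytometry fluorescence histogram
#'
#' Two-column delimited text: fluorescence channel (strictly increasing) and
#' event count (non-negative).
#'
#' @param path delimited text file
#' @return a `fcm_histogram`: data frame with columns `channel`, `count`
#' @export
read_histogram <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE)
  names(df)[1:2] <- c("channel", "count")
  fcm_histogram(df$channel, df$count)
}

#' Construct/validate a fluorescence histogram
#' @param channel ascending numeric channel positions
#' @param count non-negative event counts, same length
#' @return data frame of class `fcm_histogram`
#' @export
fcm_histogram <- function(channel, count) {
  stopifnot(length(channel) == length(count))
  if (any(diff(channel) <= 0)) stop("channels must be strictly increasing")
  if (any(count < 0)) stop("counts must be non-negative")
  structure(data.frame(channel = channel, count = count),
            class = c("fcm_histogram", "data.frame"))
}

#' Write a histogram as two-column delimited text
#' @param hist a `fcm_histogram`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(hist, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
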