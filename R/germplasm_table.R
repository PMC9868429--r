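#' pearprint: SSR fingerprinting and diversity analysis for germplasm collections
#'
#' Molecular characterization of clonally propagated germplasm genotyped with
#' codominant SSR markers: marker informativeness statistics and discrimination
#' power, genotype-identity resolution (synonymy/homonymy), SSR- and
#' cytometry-based ploidy determination, and population-diversity analyses
#' (AMOVA, PCoA, Evanno delta-K), exercised end-to-end on a seeded synthetic
#' germplasm generator.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a germplasm genotype table
#'
#' A `germplasm_table` holds the multilocus SSR profiles of a set of
#' accessions: for each accession and locus, the set of distinct allele sizes
#' observed (integer base pairs, 1 to `max_alleles` per locus), with missing
#' data recorded per locus, plus accession metadata (name, province of
#' collection). It is the universal input of the pipeline.
#'
#' @param geno a list-matrix (accessions x loci) whose cells are sorted
#'   integer vectors of distinct allele sizes; `NULL` or empty means missing.
#'   Alternatively a character matrix of slash-separated sizes ("134/138",
#'   "" = missing).
#' @param meta data frame with columns `accession_id`, `name`, `province`,
#'   one row per accession, in the row order of `geno`.
#' @param max_alleles maximum number of distinct alleles allowed per cell
#'   (default 3, i.e. up to triploid profiles).
#' @return an object of class `germplasm_table` with components `geno`
#'   (list-matrix, dimnames = accession ids x locus ids), `meta`, and
#'   `loci` (ordered locus ids).
#' @export
germplasm_table <- function(geno, meta, max_alleles = 3L) {
  stopifnot(is.matrix(geno), is.data.frame(meta),
            all(c("accession_id", "name", "province") %in% names(meta)),
            nrow(geno) == nrow(meta))
  if (is.character(geno)) {
    g <- matrix(vector("list", length(geno)), nrow = nrow(geno),
                dimnames = dimnames(geno))
    for (i in seq_len(nrow(geno)))
      for (j in seq_len(ncol(geno)))
        g[[i, j]] <- parse_allele_set(geno[i, j])
    geno <- g
  }
  ids <- as.character(meta$accession_id)
  if (anyDuplicated(ids))
    stop("duplicate accession_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("L", seq_len(ncol(geno)))
  rownames(geno) <- ids
  for (i in seq_len(nrow(geno)))
    for (j in seq_len(ncol(geno))) {
      a <- geno[[i, j]]
      if (is.null(a) || length(a) == 0L) { geno[[i, j]] <- integer(0); next }
      a <- sort(unique(as.integer(a)))
      if (length(a) > max_alleles)
        stop(sprintf("accession '%s', locus '%s': %d alleles exceeds max_alleles = %d",
                     ids[i], colnames(geno)[j], length(a), max_alleles))
      geno[[i, j]] <- a
    }
  structure(list(geno = geno, meta = meta, loci = colnames(geno)),
            class = "germplasm_table")
}

#' @export
print.germplasm_table <- function(x, ...) {
  cat(sprintf("germplasm_table: %d accessions x %d loci\n",
              nrow(x$geno), length(x$loci)))
  cat("loci:", paste(x$loci, collapse = ", "), "\n")
  ns <- locus_sample_sizes(x)
  cat("per-locus non-missing:", paste(ns, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.germplasm_table` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_along(x$loci)
  germplasm_table(x$geno[i, j, drop = FALSE], x$meta[i, , drop = FALSE])
}

#' Number of accessions / loci in a table
#' @param table a [germplasm_table]
#' @return integer count
#' @export
n_accessions <- function(table) nrow(table$geno)

#' @rdname n_accessions
#' @export
n_loci <- function(table) length(table$loci)

#' Per-locus sample sizes
#'
#' Number of accessions with a non-missing allele set at each locus
#' (pairwise-deletion sample sizes, as tabulated in marker summary tables).
#'
#' @param table a [germplasm_table]
#' @return named integer vector, one entry per locus
#' @export
locus_sample_sizes <- function(table) {
  apply(table$geno, 2L, function(col) sum(lengths(col) > 0L))
}

#' Is a cell missing?
#' @keywords internal
is_missing_cell <- function(table) {
  matrix(lengths(table$geno) == 0L, nrow = nrow(table$geno),
         dimnames = dimnames(table$geno))
}

# Parse one slash-separated allele token ("134/138/142"; "" = missing).
# Fractional sizes are rounded half-up; duplicates collapse; sorted ascending.
parse_allele_set <- function(token) {
  token <- trimws(token)
  if (is.na(token) || token == "" || toupper(token) %in% c("NA", "-", "?"))
    return(integer(0))
  parts <- trimws(strsplit(token, "/", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) == 0L || anyNA(vals) || any(vals <= 0))
    stop("malformed allele token: '", token, "'")
  sort(unique(as.integer(floor(vals + 0.5))))
}

format_allele_set <- function(a) {
  if (length(a) == 0L) "" else paste(a, collapse = "/")
}
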