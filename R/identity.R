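#' Binarize multilocus SSR profiles into a band matrix
#'
#' Codominant allele calls are re-expressed as binary presence/absence bands,
#' one column per (locus, allele) pair over all alleles observed anywhere in
#' the table - the encoding used when SSR data are analyzed as binary
#' characters. A missing locus makes all of that locus's columns `NA` for the
#' accession.
#'
#' @param table a [germplasm_table]
#' @return integer matrix (accessions x bands) of 0/1/NA with column names
#'   `"locus:allele"`; attribute `locus` maps columns to loci
#' @export
binarize <- function(table) {
  stopifnot(inherits(table, "germplasm_table"))
  cols <- list()
  for (j in seq_along(table$loci)) {
    alleles <- sort(unique(unlist(table$geno[, j])))
    for (al in alleles)
      cols[[length(cols) + 1L]] <- c(j = j, allele = al)
  }
  m <- matrix(NA_integer_, nrow = nrow(table$geno), ncol = length(cols),
              dimnames = list(table$meta$accession_id,
                              vapply(cols, function(cc)
                                paste0(table$loci[cc["j"]], ":", cc["allele"]),
                                character(1))))
  locus_of <- vapply(cols, function(cc) table$loci[cc["j"]], character(1))
  for (i in seq_len(nrow(m))) {
    for (k in seq_along(cols)) {
      a <- table$geno[[i, cols[[k]]["j"]]]
      m[i, k] <- if (length(a) == 0L) NA_integer_
                 else as.integer(cols[[k]]["allele"] %in% a)
    }
  }
  attr(m, "locus") <- locus_of
  m
}

#' Simple-matching coefficient between two band rows
#'
#' SM = (n11 + n00) / (n11 + n10 + n01 + n00), computed over the columns
#' non-missing in both rows (shared absences count as matches).
#'
#' @param a,b 0/1/NA vectors of equal length
#' @return coefficient in \[0, 1\], with attribute `shared` (number of
#'   mutually scored columns); `NA` (flagged) if no column is shared
#' @export
simple_matching <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) {
    out <- NA_real_
    attr(out, "shared") <- 0L
    return(out)
  }
  out <- sum(a[ok] == b[ok]) / n
  attr(out, "shared") <- n
  out
}

#' Pairwise simple-matching similarity matrix
#'
#' All pairwise simple-matching coefficients between accessions, computed on
#' the binary band encoding with pairwise deletion of mutually missing
#' columns. Symmetric with unit diagonal; a pair with no mutually scored
#' column is `NA` (flagged).
#'
#' @param bands band matrix from [binarize()] (or a [germplasm_table], which
#'   is binarized first)
#' @return list of class `similarity_matrix`: `gs` (similarity matrix),
#'   `shared` (mutually scored column counts)
#' @export
similarity_matrix <- function(bands) {
  if (inherits(bands, "germplasm_table")) bands <- binarize(bands)
  M <- !is.na(bands)
  X <- bands; X[!M] <- 0L
  Y <- (1L - bands); Y[!M] <- 0L
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  storage.mode(M) <- "double"
  n11 <- tcrossprod(X)
  n00 <- tcrossprod(Y)
  shared <- tcrossprod(M)
  gs <- (n11 + n00) / shared
  gs[shared == 0] <- NA_real_
  diag(gs) <- 1
  structure(list(gs = gs, shared = shared), class = "similarity_matrix")
}

#' Collapse accessions into unique genotypes and report synonymies
#'
#' Accessions are grouped by the connected components of the graph whose
#' edges join pairs with genetic similarity >= `threshold` (default 1.0,
#' i.e. identical on all mutually scored loci). Each multi-member group is a
#' set of duplicate accessions (clones); a group whose members carry two or
#' more distinct normalized names is a synonymy case. With missing data,
#' GS = 1 is not a strict equivalence, so components (transitive closure) are
#' used and the shared-column counts are reported for audit.
#'
#' @param sim a `similarity_matrix` (or a [germplasm_table])
#' @param table the [germplasm_table] the matrix came from
#' @param threshold similarity required for an edge (default 1.0; lower
#'   values emit a warning since groups then mean similarity clusters, not
#'   identical genotypes)
#' @param anonymous_pattern regex identifying anonymous sample names
#'   (reported separately when they match a named genotype)
#' @return list of class `identity_report`: `membership` (group id per
#'   accession), `groups` (list of member indices), `n_genotypes`,
#'   `synonym_cases` (data frame: group, names, provinces, min_gs,
#'   min_shared), `anonymous_matches`
#' @export
collapse_genotypes <- function(sim, table, threshold = 1.0,
                               anonymous_pattern = "^(Pero|Unknown|Anon)\\b") {
  if (inherits(sim, "germplasm_table")) {
    table <- sim
    sim <- similarity_matrix(binarize(table))
  }
  stopifnot(inherits(sim, "similarity_matrix"),
            inherits(table, "germplasm_table"))
  if (threshold < 1)
    warning("threshold < 1: groups are similarity clusters, ",
            "not identical genotypes")
  gs <- sim$gs
  adj <- !is.na(gs) & gs >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(seq_along(comp), comp)
  names(groups) <- paste0("G", seq_along(groups))
  membership <- paste0("G", comp)

  syn <- list()
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    if (length(idx) < 2L) next
    nm <- table$meta$name[idx]
    norm <- vapply(nm, normalize_name, character(1))
    pair_gs <- gs[idx, idx]; pair_sh <- sim$shared[idx, idx]
    if (length(unique(norm)) >= 2L) {
      syn[[length(syn) + 1L]] <- data.frame(
        group = names(groups)[gi],
        size = length(idx),
        names = paste(nm, collapse = "; "),
        provinces = paste(table$meta$province[idx], collapse = "; "),
        min_gs = min(pair_gs[upper.tri(pair_gs)]),
        min_shared = min(pair_sh[upper.tri(pair_sh)]),
        stringsAsFactors = FALSE)
    }
  }
  syn <- if (length(syn)) do.call(rbind, syn)
         else data.frame(group = character(0), size = integer(0),
                         names = character(0), provinces = character(0),
                         min_gs = numeric(0), min_shared = numeric(0))

  anon <- grepl(anonymous_pattern, table$meta$name)
  anon_matches <- list()
  for (i in which(anon)) {
    mates <- setdiff(groups[[membership[i]]], i)
    named_mates <- mates[!anon[mates]]
    if (length(named_mates))
      anon_matches[[length(anon_matches) + 1L]] <- data.frame(
        accession_id = table$meta$accession_id[i],
        name = table$meta$name[i],
        matches = paste(table$meta$name[named_mates], collapse = "; "))
  }
  anon_matches <- if (length(anon_matches)) do.call(rbind, anon_matches)
                  else NULL

  structure(list(membership = stats::setNames(membership,
                                              table$meta$accession_id),
                 groups = groups, n_genotypes = length(groups),
                 synonym_cases = syn, anonymous_matches = anon_matches,
                 threshold = threshold),
            class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  n <- length(x$membership)
  multi <- sum(lengths(x$groups) >= 2L)
  cat(sprintf("%d accessions -> %d unique genotypes (threshold GS >= %g)\n",
              n, x$n_genotypes, x$threshold))
  cat(sprintf("%d shared-genotype group(s); %d cross-name synonymy case(s)\n",
              multi, nrow(x$synonym_cases)))
  if (nrow(x$synonym_cases)) print(x$synonym_cases, row.names = FALSE)
  if (!is.null(x$anonymous_matches)) {
    cat("anonymous samples matching a named genotype:\n")
    print(x$anonymous_matches, row.names = FALSE)
  }
  invisible(x)
}

#' Normalize a cultivar name for synonym/homonym comparison
#'
#' Case-folds, strips province-code suffix tokens and bare numeral tokens,
#' and collapses internal whitespace, so that "Spina 1 FR" and "Spina 2 RM"
#' both normalize to "spina" while "Spina Nerola RM" stays distinct
#' ("spina nerola"). If stripping empties the name, the case-folded raw name
#' is returned.
#'
#' @param raw_name the name as recorded
#' @param province_codes tokens to strip (default FR, LT, RI, RM, VT)
#' @return normalized key (character scalar)
#' @export
normalize_name <- function(raw_name,
                           province_codes = c("FR", "LT", "RI", "RM", "VT")) {
  stopifnot(is.character(raw_name), length(raw_name) == 1L,
            nchar(raw_name) > 0L)
  toks <- strsplit(trimws(tolower(raw_name)), "\\s+")[[1]]
  keep <- !(toupper(toks) %in% toupper(province_codes)) &
          !grepl("^[0-9]+$", toks)
  out <- paste(toks[keep], collapse = " ")
  if (nchar(out) == 0L) out <- paste(toks, collapse = " ")
  out
}

#' Find homonymy cases
#'
#' A homonymy is one denomination covering several genotypes: a normalized
#' name whose bearers fall in more than one genotype group. For each case the
#' groups involved and the minimum pairwise similarity across groups are
#' reported. Near-miss names sharing a first token with a homonym name (e.g.
#' a two-word variant of a one-word name) are logged in the `near_miss`
#' attribute but not merged.
#'
#' @param report an `identity_report` from [collapse_genotypes()]
#' @param table the [germplasm_table]
#' @param sim optional `similarity_matrix` for the min-GS column
#' @return data frame: name, n_groups, groups, accessions, min_gs
#' @export
find_homonyms <- function(report, table, sim = NULL) {
  stopifnot(inherits(report, "identity_report"))
  norm <- vapply(table$meta$name, normalize_name, character(1))
  out <- list()
  for (nm in unique(norm)) {
    idx <- which(norm == nm)
    grps <- unique(report$membership[idx])
    if (length(grps) < 2L) next
    min_gs <- NA_real_
    if (!is.null(sim)) {
      cross <- expand.grid(i = idx, j = idx)
      cross <- cross[report$membership[cross$i] !=
                       report$membership[cross$j], ]
      if (nrow(cross))
        min_gs <- min(sim$gs[cbind(cross$i, cross$j)], na.rm = TRUE)
    }
    out[[length(out) + 1L]] <- data.frame(
      name = nm, n_groups = length(grps),
      groups = paste(grps, collapse = "; "),
      accessions = paste(table$meta$accession_id[idx], collapse = "; "),
      min_gs = min_gs, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(name = character(0), n_groups = integer(0),
                         groups = character(0), accessions = character(0),
                         min_gs = numeric(0))
  first_tok <- vapply(strsplit(unique(norm), " "), `[`, character(1), 1)
  dup_first <- unique(norm)[first_tok %in%
                              first_tok[duplicated(first_tok)]]
  attr(res, "near_miss") <- setdiff(dup_first, res$name)
  res
}

#' Write a similarity matrix as delimited text
#'
#' @param sim a `similarity_matrix`
#' @param path output path
#' @param shape `"square"` or `"lower"` (lower-triangular)
#' @return `path`, invisibly
#' @export
write_similarity_matrix <- function(sim, path,
                                    shape = c("square", "lower")) {
  shape <- match.arg(shape)
  m <- sim$gs
  if (shape == "lower") m[upper.tri(m)] <- NA
  utils::write.table(round(m, 6), path, sep = ",", na = "",
                     row.names = TRUE, col.names = NA, quote = FALSE)
  invisible(path)
}
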