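#' Pipeline configuration
#'
#' Collects every setting of the characterization pipeline with the defaults
#' the package is calibrated around: triploid call at >= 2 triallelic loci,
#' genotype identity at GS = 1.0, AMOVA on band-mismatch distances with 999
#' permutations.
#'
#' @param genotype_path path to a genotype table (see
#'   [read_genotype_table()]); `NULL` if `table` is supplied to
#'   [run_pipeline()] directly
#' @param structure_runs_path optional path to clustering-run likelihoods for
#'   delta-K
#' @param output_dir directory for the report bundle
#' @param min_loci triallelic-locus threshold for the triploid call
#' @param gs_threshold similarity threshold for genotype identity
#' @param amova_kind distance kind for AMOVA (see [distance_matrix()])
#' @param amova_unique run AMOVA on unique genotypes only (`TRUE`) or all
#'   accessions (default `FALSE`; duplicated clones inflate within-group
#'   identity)
#' @param n_perm AMOVA permutations
#' @param seed RNG seed recorded in the manifest and used for the
#'   permutation test
#' @param province_codes tokens stripped by [normalize_name()]
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genotype_path = NULL,
                            structure_runs_path = NULL,
                            output_dir = tempfile("pearprint_run_"),
                            min_loci = 2L, gs_threshold = 1.0,
                            amova_kind = "band_mismatch",
                            amova_unique = FALSE,
                            n_perm = 999L, seed = 1L,
                            province_codes = c("FR", "LT", "RI",
                                               "RM", "VT")) {
  structure(list(genotype_path = genotype_path,
                 structure_runs_path = structure_runs_path,
                 output_dir = output_dir, min_loci = as.integer(min_loci),
                 gs_threshold = gs_threshold, amova_kind = amova_kind,
                 amova_unique = amova_unique, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 province_codes = province_codes),
            class = "pipeline_config")
}

#' Run the full characterization pipeline
#'
#' Sequences the analysis stages: marker statistics and discrimination
#' power, similarity matrix, genotype identity (synonymies and homonymies),
#' SSR ploidy calls, AMOVA by province, PCoA, and (if run likelihoods are
#' provided) Evanno delta-K. Every artifact is written as delimited text
#' under `config$output_dir` along with a run manifest recording the seed
#' and every setting in force; outputs are a pure function of
#' (inputs, config, seed) so repeated runs are byte-identical.
#'
#' @param config a [pipeline_config]
#' @param table optionally a [germplasm_table] already in memory (otherwise
#'   read from `config$genotype_path`)
#' @return invisibly, the report bundle: list with `table`, `stats`,
#'   `similarity`, `identity`, `homonyms`, `ploidy`, `tally`, `amova`,
#'   `pcoa`, `evanno` (or NULL), `config`, `failed_stage` (NULL on success)
#' @export
run_pipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  bundle <- list(config = config, failed_stage = NULL)

  stage <- function(name, expr) {
    if (!is.null(bundle$failed_stage)) return(NULL)
    tryCatch(expr, error = function(e) {
      bundle$failed_stage <<- paste0(name, ": ", conditionMessage(e))
      NULL
    })
  }

  if (is.null(table))
    table <- stage("read", read_genotype_table(config$genotype_path))
  bundle$table <- table
  if (!is.null(table))
    write_genotype_table(table, out("genotypes.csv"))

  bundle$stats <- stage("marker_stats", {
    st <- panel_summary(table, min_loci = config$min_loci)
    per <- st$per_locus
    mean_row <- c(locus = "Mean", as.list(st$mean))
    sd_row <- c(locus = "St.Dev.", as.list(st$sd))
    tab <- rbind(per,
                 as.data.frame(mean_row, stringsAsFactors = FALSE),
                 as.data.frame(sd_row, stringsAsFactors = FALSE))
    utils::write.table(format(tab, digits = 6), out("marker_stats.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    writeLines(c(sprintf("DP,%0.6f", st$dp),
                 sprintf("n_used,%d", st$dp_detail$n_used),
                 sprintf("n_profiles,%d", st$dp_detail$n_profiles)),
               out("discrimination_power.csv"))
    st
  })

  bundle$similarity <- stage("similarity", {
    sim <- similarity_matrix(table)
    write_similarity_matrix(sim, out("similarity_square.csv"), "square")
    write_similarity_matrix(sim, out("similarity_lower.csv"), "lower")
    sim
  })

  bundle$identity <- stage("identity", {
    rep_ <- collapse_genotypes(bundle$similarity, table,
                               threshold = config$gs_threshold)
    utils::write.table(
      data.frame(accession_id = names(rep_$membership),
                 group = rep_$membership,
                 name = table$meta$name, province = table$meta$province),
      out("genotype_groups.csv"), sep = ",", row.names = FALSE,
      quote = TRUE)
    utils::write.table(rep_$synonym_cases, out("synonym_cases.csv"),
                       sep = ",", row.names = FALSE, quote = TRUE)
    rep_
  })

  bundle$homonyms <- stage("homonyms", {
    h <- find_homonyms(bundle$identity, table, bundle$similarity)
    utils::write.table(h, out("homonym_cases.csv"), sep = ",",
                       row.names = FALSE, quote = TRUE)
    h
  })

  bundle$ploidy <- stage("ploidy", {
    calls <- classify_ploidy_ssr(table, min_loci = config$min_loci)
    utils::write.table(calls, out("ploidy_calls.csv"), sep = ",",
                       row.names = FALSE, quote = TRUE)
    calls
  })
  bundle$tally <- stage("ploidy_tally", {
    tl <- ploidy_tally(bundle$ploidy)
    utils::write.table(tl, out("ploidy_tally.csv"), sep = ",",
                       row.names = FALSE, quote = TRUE)
    tl
  })

  bundle$amova <- stage("amova", {
    tab_a <- table
    if (config$amova_unique && !is.null(bundle$identity)) {
      first <- vapply(bundle$identity$groups, `[`, integer(1), 1L)
      tab_a <- table[sort(first), ]
    }
    d2 <- distance_matrix(tab_a, kind = config$amova_kind)
    a <- amova(d2, tab_a$meta$province, n_perm = config$n_perm,
               seed = config$seed)
    utils::write.table(cbind(a$table,
                             phi_st = c(a$phi_st, NA, NA),
                             p = c(a$p_value, NA, NA)),
                       out("amova.csv"), sep = ",", row.names = FALSE,
                       quote = FALSE)
    a
  })

  bundle$pcoa <- stage("pcoa", {
    d <- sqrt(distance_matrix(table, kind = config$amova_kind))
    p <- pcoa_ord(d)
    utils::write.table(
      data.frame(axis = seq_along(p$percent),
                 eigenvalue = p$eigenvalues[seq_along(p$percent)],
                 percent = p$percent),
      out("pcoa_eigenvalues.csv"), sep = ",", row.names = FALSE,
      quote = FALSE)
    utils::write.table(round(p$coordinates[, seq_len(min(5, ncol(p$coordinates))),
                                           drop = FALSE], 6),
                       out("pcoa_coordinates.csv"), sep = ",",
                       row.names = TRUE, col.names = NA, quote = FALSE)
    p
  })

  bundle$evanno <- NULL
  if (!is.null(config$structure_runs_path)) {
    bundle$evanno <- stage("evanno", {
      runs <- read_structure_runs(config$structure_runs_path)
      ev <- evanno_delta_k(runs)
      utils::write.table(ev$table, out("delta_k.csv"), sep = ",",
                         row.names = FALSE, quote = FALSE)
      ev
    })
  }

  manifest <- c(
    sprintf("pearprint_version,%s",
            as.character(utils::packageVersion("pearprint"))),
    sprintf("seed,%d", config$seed),
    sprintf("min_loci,%d", config$min_loci),
    sprintf("gs_threshold,%g", config$gs_threshold),
    sprintf("amova_kind,%s", config$amova_kind),
    sprintf("amova_unique,%s", config$amova_unique),
    sprintf("n_perm,%d", config$n_perm),
    sprintf("province_codes,%s",
            paste(config$province_codes, collapse = "|")),
    sprintf("status,%s",
            if (is.null(bundle$failed_stage)) "complete"
            else paste("failed at", bundle$failed_stage)))
  writeLines(manifest, out("manifest.csv"))
  invisible(bundle)
}

#' Render a registry-style characterization report
#'
#' One section per accession (allele sizes per locus, ploidy call, genotype
#' group, synonym/homonym cross-references) plus a panel summary (marker
#' statistics, discrimination power, ploidy tallies, AMOVA). Sections whose
#' artifact is missing from the bundle are omitted with a notice.
#'
#' @param bundle the list returned by [run_pipeline()]
#' @return character vector of report lines (one element per line)
#' @export
render_report <- function(bundle) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  table <- bundle$table
  if (is.null(table)) return("[no genotype table in bundle]")
  add("GERMPLASM CHARACTERIZATION REPORT")
  add("%d accessions, %d SSR loci (%s)", n_accessions(table),
      n_loci(table), paste(table$loci, collapse = ", "))
  add("")

  if (!is.null(bundle$stats)) {
    add("PANEL SUMMARY")
    m <- bundle$stats$mean
    add("mean per-locus: n=%.0f Na=%.0f Ho=%.2f He=%.2f I=%.2f PIC=%.2f",
        m["n"], m["Na"], m["Ho"], m["He"], m["I"], m["PIC"])
    add("discrimination power DP = %.4f over %d complete profiles",
        bundle$stats$dp, bundle$stats$dp_detail$n_used)
  } else add("[marker statistics unavailable]")
  if (!is.null(bundle$identity))
    add("unique genotypes: %d; cross-name synonymy cases: %d",
        bundle$identity$n_genotypes, nrow(bundle$identity$synonym_cases))
  if (!is.null(bundle$homonyms))
    add("homonymy cases: %d", nrow(bundle$homonyms))
  if (!is.null(bundle$tally))
    for (i in seq_len(nrow(bundle$tally)))
      add("triploid tally (%s): %d (%.1f%%)", bundle$tally$threshold[i],
          bundle$tally$count[i], bundle$tally$percent[i])
  if (!is.null(bundle$amova)) {
    at <- bundle$amova$table
    add("AMOVA: %.1f%% among / %.1f%% within provinces (Phi_ST %.3f, p %s)",
        at$percent[1], at$percent[2], bundle$amova$phi_st,
        format(bundle$amova$p_value))
  }
  if (!is.null(bundle$evanno))
    add("delta-K maxima at K = %s",
        paste(bundle$evanno$local_maxima, collapse = ", "))
  add("")

  syn <- if (!is.null(bundle$identity)) bundle$identity$synonym_cases
         else NULL
  for (i in seq_len(n_accessions(table))) {
    id <- table$meta$accession_id[i]
    add("ACCESSION %s - %s (%s)", id, table$meta$name[i],
        table$meta$province[i])
    prof <- vapply(seq_along(table$loci), function(j)
      sprintf("%s:%s", table$loci[j],
              ifelse(length(table$geno[[i, j]]) == 0L, "-",
                     format_allele_set(table$geno[[i, j]]))),
      character(1))
    add("  profile: %s", paste(prof, collapse = "  "))
    if (!is.null(bundle$ploidy))
      add("  ploidy (SSR): %s (%d triallelic loci)",
          bundle$ploidy$call[i], bundle$ploidy$n_triallelic[i])
    if (!is.null(bundle$identity)) {
      grp <- bundle$identity$membership[i]
      add("  genotype group: %s", grp)
      mates <- setdiff(bundle$identity$groups[[grp]], i)
      if (length(mates))
        add("  same genotype as: %s",
            paste(table$meta$name[mates], collapse = "; "))
      if (!is.null(syn) && nrow(syn) && grp %in% syn$group)
        add("  synonymy case: %s", syn$names[syn$group == grp])
    }
  }
  lines
}
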