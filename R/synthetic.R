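#' Configuration for the synthetic germplasm generator
#'
#' Defaults reproduce the study conditions the pipeline was designed around:
#' a regional pear collection of 311 accessions from 5 provinces
#' (104/66/69/57/15), 9 SSR loci with observed allele counts
#' 12, 18, 11, 23, 19, 17, 9, 20, 15, very weak among-province
#' differentiation (Fst = 0.017), a true triploid fraction of 0.20
#' (triploids arise from an unreduced diploid egg fertilized by a haploid
#' pollen grain), 26 planted clone groups totalling 61 redundant copies
#' (so 250 unique genotypes), of which 14 groups carry cross-name aliases
#' (synonymies) and the rest share a name, plus shared-name non-clones
#' (homonymies), and a 1.1% per-cell missing rate.
#'
#' @param seed integer RNG seed; a single stream drives the whole simulation
#' @param n_loci number of SSR loci
#' @param alleles_per_locus integer vector (recycled) of allele counts per
#'   locus; default matches a well-characterized 9-locus pear panel
#' @param freq_concentration Dirichlet concentration for global allele
#'   frequencies (smaller = more skewed spectra)
#' @param n_provinces number of provinces (collection sub-origins)
#' @param province_weights relative collection sizes per province
#' @param fst among-province differentiation of allele frequencies, in (0,1)
#' @param n_accessions number of accessions in the table
#' @param triploid_fraction probability that a unique genotype is triploid
#' @param clone_groups data frame with columns `size` (>=2) and `mode`
#'   ("alias" = members carry different names, a synonymy; "shared" = members
#'   carry the same name)
#' @param homonym_groups data frame with columns `name` and `members`:
#'   `members` distinct genotypes deliberately labelled with the same base
#'   name (homonymy)
#' @param missing_rate per-cell probability that a locus call is missing
#' @param genotyping_error_rate per-allele probability of a mis-sized call
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(seed = 1L,
                             n_loci = 9L,
                             alleles_per_locus = c(12L, 18L, 11L, 23L, 19L,
                                                   17L, 9L, 20L, 15L),
                             freq_concentration = 0.3,
                             n_provinces = 5L,
                             province_weights = c(104, 66, 69, 57, 15),
                             fst = 0.017,
                             n_accessions = 311L,
                             triploid_fraction = 0.20,
                             clone_groups = default_clone_groups(),
                             homonym_groups = data.frame(
                               name = "Spina", members = 2L),
                             missing_rate = 0.011,
                             genotyping_error_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              alleles_per_locus = rep_len(as.integer(alleles_per_locus),
                                          n_loci),
              freq_concentration = freq_concentration,
              n_provinces = as.integer(n_provinces),
              province_weights = rep_len(province_weights, n_provinces),
              fst = fst, n_accessions = as.integer(n_accessions),
              triploid_fraction = triploid_fraction,
              clone_groups = clone_groups,
              homonym_groups = homonym_groups,
              missing_rate = missing_rate,
              genotyping_error_rate = genotyping_error_rate)
  stopifnot(cfg$n_loci >= 1L, cfg$n_provinces >= 1L, cfg$n_accessions >= 1L,
            all(cfg$alleles_per_locus >= 1L),
            cfg$triploid_fraction >= 0, cfg$triploid_fraction <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$genotyping_error_rate >= 0, cfg$genotyping_error_rate <= 1)
  if (cfg$fst <= 0 || cfg$fst >= 1) stop("fst must lie in (0, 1)")
  if (!is.null(cfg$clone_groups) && nrow(cfg$clone_groups) > 0) {
    stopifnot(all(cfg$clone_groups$size >= 2L),
              all(cfg$clone_groups$mode %in% c("alias", "shared")))
    if (sum(cfg$clone_groups$size) > cfg$n_accessions)
      stop("clone groups exceed n_accessions")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' @rdname synthetic_config
#' @export
default_clone_groups <- function() {
  data.frame(size = c(rep(2L, 12), rep(3L, 6), rep(4L, 4), 6L, 6L, 7L, 10L),
             mode = c(rep("alias", 14), rep("shared", 12)))
}

province_codes <- function(n) {
  codes <- c("FR", "LT", "RI", "RM", "VT")
  if (n <= 5L) codes[seq_len(n)] else c(codes, sprintf("P%02d", 6:n))[seq_len(n)]
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Sample global and per-province allele frequencies
#'
#' Global frequencies per locus are Dirichlet(`freq_concentration`) draws;
#' province frequencies follow the Balding-Nichols construction,
#' Dirichlet(p_global * (1 - Fst) / Fst), so that the expected among-province
#' differentiation equals `fst`.
#'
#' @param config a [synthetic_config]
#' @return list with `global` (list of per-locus frequency vectors, allele
#'   names = sizes in bp) and `province` (list of per-province lists of
#'   per-locus vectors); each vector sums to 1
#' @export
sample_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lam <- (1 - config$fst) / config$fst
  global <- vector("list", config$n_loci)
  prov <- replicate(config$n_provinces, vector("list", config$n_loci),
                    simplify = FALSE)
  for (j in seq_len(config$n_loci)) {
    k <- config$alleles_per_locus[j]
    # allele sizes: dinucleotide ladder starting at a locus-specific offset
    sizes <- 100L + 10L * j + 2L * seq_len(k)
    p <- rdirichlet1(rep(config$freq_concentration, k))
    names(p) <- sizes
    global[[j]] <- p
    for (g in seq_len(config$n_provinces)) {
      q <- rdirichlet1(p * lam)
      names(q) <- sizes
      prov[[g]][[j]] <- q
    }
  }
  names(prov) <- province_codes(config$n_provinces)
  list(global = global, province = prov)
}

draw_alleles <- function(freq, n) {
  as.integer(sample(names(freq), n, replace = TRUE, prob = freq))
}

#' Simulate a germplasm collection with ground truth
#'
#' Unique genotypes are drawn from their province's allele frequencies:
#' diploids as two independent gametes (random mating), triploids as an
#' unreduced diploid egg (itself a random-mating diploid genotype) plus one
#' haploid pollen allele. Clone groups are exact copies of a founder genotype
#' (vegetative propagation); their members may be recorded in different
#' provinces, as grafted material travels. Synonym groups give every member a
#' distinct cultivar name; shared-name groups and homonym pairs reuse a base
#' name with province/numeral suffixes.
#'
#' @param config a [synthetic_config]
#' @param freqs optional frequency object from [sample_allele_frequencies()];
#'   drawn from `config` if omitted
#' @return list with `table` (a [germplasm_table]) and `truth` (class
#'   `ground_truth`): per-accession true ploidy, clone-group id, province,
#'   plus the frequency object and the clone/homonym bookkeeping
#' @export
simulate_population <- function(config, freqs = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  if (is.null(freqs)) freqs <- sample_allele_frequencies(config)
  n <- config$n_accessions
  cg <- config$clone_groups
  n_copies <- if (is.null(cg) || nrow(cg) == 0) 0L else sum(cg$size - 1L)
  n_unique <- n - n_copies
  if (n_unique < max(1L, NROW(cg))) stop("clone groups exceed n_accessions")

  provs <- province_codes(config$n_provinces)
  w <- config$province_weights / sum(config$province_weights)
  # deterministic largest-remainder allocation of unique genotypes
  alloc <- floor(w * n_unique)
  rem <- n_unique - sum(alloc)
  if (rem > 0) {
    extra <- order(w * n_unique - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  g_prov <- sample(rep(provs, alloc))
  g_ploidy <- ifelse(stats::runif(n_unique) < config$triploid_fraction, 3L, 2L)

  draw_genotype <- function(prov, ploidy) {
    lapply(seq_len(config$n_loci), function(j) {
      f <- freqs$province[[prov]][[j]]
      a <- if (ploidy == 2L) draw_alleles(f, 2L)
           else c(draw_alleles(f, 2L), draw_alleles(f, 1L))
      sort(unique(a))
    })
  }
  genotypes <- lapply(seq_len(n_unique),
                      function(i) draw_genotype(g_prov[i], g_ploidy[i]))

  # expand clone groups: first nrow(cg) unique genotypes are founders
  acc_geno <- list(); acc_ploidy <- integer(0); acc_prov <- character(0)
  acc_clone <- integer(0); acc_unique <- integer(0)
  k_groups <- NROW(cg)
  for (i in seq_len(n_unique)) {
    copies <- if (i <= k_groups) cg$size[i] else 1L
    for (m in seq_len(copies)) {
      acc_geno[[length(acc_geno) + 1L]] <- genotypes[[i]]
      acc_ploidy <- c(acc_ploidy, g_ploidy[i])
      acc_prov <- c(acc_prov,
                    if (m == 1L) g_prov[i] else sample(provs, 1L, prob = w))
      acc_clone <- c(acc_clone, if (i <= k_groups) i else NA_integer_)
      acc_unique <- c(acc_unique, i)
    }
  }
  n_out <- length(acc_geno)
  stopifnot(n_out == n)

  # names: cultivar base names; aliases for synonym groups; shared names for
  # clone groups in "shared" mode; homonym pairs reuse a base name.
  base_pool <- sprintf("Cultivar%03d", seq_len(n_unique + n_copies + 50L))
  base_pool <- sample(base_pool)
  pool_i <- 0L
  next_name <- function() {
    pool_i <<- pool_i + 1L
    base_pool[pool_i]
  }
  names_out <- character(n_out)
  group_base <- character(n_unique)
  for (i in seq_len(n_unique)) group_base[i] <- next_name()
  hg <- config$homonym_groups
  homonym_of <- rep(NA_character_, n_unique)
  if (!is.null(hg) && nrow(hg) > 0) {
    # homonyms drawn from singleton genotypes (not clone-group founders)
    singles <- setdiff(seq_len(n_unique), seq_len(k_groups))
    for (h in seq_len(nrow(hg))) {
      m <- hg$members[h]
      if (length(singles) < m) stop("not enough singleton genotypes for homonyms")
      pick <- singles[seq_len(m)]
      singles <- setdiff(singles, pick)
      homonym_of[pick] <- hg$name[h]
    }
  }
  seen_counter <- new.env()
  for (a in seq_len(n_out)) {
    i <- acc_unique[a]
    if (!is.na(homonym_of[i])) {
      key <- homonym_of[i]
      cnt <- (if (is.null(seen_counter[[key]])) 0L else seen_counter[[key]]) + 1L
      seen_counter[[key]] <- cnt
      names_out[a] <- sprintf("%s %d %s", key, cnt, acc_prov[a])
    } else if (!is.na(acc_clone[a]) && cg$mode[acc_clone[a]] == "alias") {
      # every member of a synonym group gets its own cultivar name
      first <- min(which(acc_unique == i))
      names_out[a] <- if (a == first)
        sprintf("%s %s", group_base[i], acc_prov[a])
      else sprintf("%s %s", next_name(), acc_prov[a])
    } else {
      names_out[a] <- sprintf("%s %s", group_base[i], acc_prov[a])
    }
  }

  # genotyping error: each allele independently mis-sized by one repeat unit
  if (config$genotyping_error_rate > 0) {
    for (a in seq_len(n_out)) {
      for (j in seq_len(config$n_loci)) {
        al <- acc_geno[[a]][[j]]
        err <- stats::runif(length(al)) < config$genotyping_error_rate
        if (any(err)) {
          al[err] <- al[err] + sample(c(-2L, 2L), sum(err), replace = TRUE)
          acc_geno[[a]][[j]] <- sort(unique(al))
        }
      }
    }
  }

  geno <- matrix(vector("list", n_out * config$n_loci), nrow = n_out)
  for (a in seq_len(n_out))
    for (j in seq_len(config$n_loci))
      geno[[a, j]] <- acc_geno[[a]][[j]]
  colnames(geno) <- sprintf("SSR%02d", seq_len(config$n_loci))
  meta <- data.frame(accession_id = sprintf("A%04d", seq_len(n_out)),
                     name = names_out, province = acc_prov,
                     stringsAsFactors = FALSE)
  tab <- germplasm_table(geno, meta)
  truth <- structure(list(ploidy = acc_ploidy, clone_group = acc_clone,
                          unique_genotype = acc_unique,
                          province = acc_prov, freqs = freqs,
                          homonym_of = homonym_of,
                          n_unique = n_unique, config = config),
                     class = "ground_truth")
  tab <- simulate_missingness(tab, config$missing_rate)
  list(table = tab, truth = truth)
}

#' Inject per-cell missingness into a genotype table
#'
#' Each accession-by-locus cell is set to missing independently with
#' probability `rate`, emulating the variable per-locus sample sizes of real
#' marker panels. Clone copies can diverge only in missingness, never in
#' allele content.
#'
#' @param table a [germplasm_table]
#' @param rate per-cell missing probability in \[0, 1)
#' @param seed optional seed; if `NULL` the current RNG stream continues
#' @return the table with cells blanked
#' @export
simulate_missingness <- function(table, rate, seed = NULL) {
  stopifnot(inherits(table, "germplasm_table"), rate >= 0, rate < 1)
  if (rate == 0) return(table)
  if (!is.null(seed)) set.seed(seed)
  drop <- matrix(stats::runif(length(table$geno)) < rate,
                 nrow = nrow(table$geno))
  for (i in seq_len(nrow(table$geno)))
    for (j in seq_len(ncol(table$geno)))
      if (drop[i, j]) table$geno[[i, j]] <- integer(0)
  table
}

#' Simulate a flow-cytometry fluorescence histogram
#'
#' G1-phase nuclei fluoresce in proportion to DNA content: a sample of true
#' ploidy `p` peaks at `base_channel * p / 2` where `base_channel` is the
#' diploid G1 position. Events are Normal around the peak with coefficient of
#' variation `cv`; an optional uniform debris floor can be added.
#'
#' @param true_ploidy 2 or 3
#' @param base_channel diploid G1 peak position (channel units)
#' @param cv coefficient of variation of the fluorescence peak, in (0, 0.2)
#' @param n_events number of nuclei
#' @param seed optional RNG seed
#' @param n_channels histogram length (default 1024)
#' @param debris_fraction fraction of events drawn uniformly over all
#'   channels (default 0)
#' @return a `fcm_histogram`
#' @export
simulate_cytometry <- function(true_ploidy, base_channel = 200, cv = 0.03,
                               n_events = 20000L, seed = NULL,
                               n_channels = 1024L, debris_fraction = 0) {
  stopifnot(true_ploidy %in% 2:3, cv > 0, cv < 0.2, base_channel > 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- base_channel * true_ploidy / 2
  n_deb <- round(n_events * debris_fraction)
  x <- c(stats::rnorm(n_events - n_deb, mu, cv * mu),
         stats::runif(n_deb, 1, n_channels))
  counts <- tabulate(pmin(pmax(round(x), 1L), n_channels), nbins = n_channels)
  fcm_histogram(seq_len(n_channels), counts)
}

#' Simulate a co-chopped PI run (sample plus internal standards)
#'
#' Emulates a propidium-iodide genome-size run in which the sample's nuclei
#' are co-chopped with one or more reference standards of known 2C content;
#' all peaks share one channels-per-pg calibration.
#'
#' @param sample_2c true 2C DNA content of the sample (pg)
#' @param standards data frame with columns `name` and `ref_2c` (pg)
#' @param channels_per_pg calibration slope (default 300 channels/pg)
#' @param cv peak coefficient of variation
#' @param n_events events per component
#' @param seed optional RNG seed
#' @param n_channels histogram length
#' @return list: `hist` (a `fcm_histogram`), `expected` (data frame of
#'   component names and expected peak channels)
#' @export
simulate_pi_run <- function(sample_2c, standards, channels_per_pg = 300,
                            cv = 0.02, n_events = 10000L, seed = NULL,
                            n_channels = 1024L) {
  stopifnot(sample_2c > 0, all(standards$ref_2c > 0))
  if (!is.null(seed)) set.seed(seed)
  comp <- data.frame(name = c("sample", standards$name),
                     pg = c(sample_2c, standards$ref_2c))
  comp$channel <- comp$pg * channels_per_pg
  x <- unlist(lapply(comp$channel,
                     function(mu) stats::rnorm(n_events, mu, cv * mu)))
  counts <- tabulate(pmin(pmax(round(x), 1L), n_channels), nbins = n_channels)
  list(hist = fcm_histogram(seq_len(n_channels), counts), expected = comp)
}
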