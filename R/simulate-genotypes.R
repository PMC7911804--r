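# Mendelian gene drop with labeled allele sizes: founders draw from
# configured locus frequencies, descendants inherit one allele per
# parent, missing cells inserted at a configured rate.

#' Configuration for the genotype simulator
#'
#' @param loci named list of founder allele-frequency vectors (names =
#'   allele sizes in bp); defaults to the 21-locus reference panel of
#'   [greyhound_frequencies()].  Sets are renormalized.
#' @param missing_rate probability a (individual, locus) cell is set to
#'   missing, in [0, 1).
#' @return A `genotype_sim_config` list.
#' @export
genotype_sim_config <- function(loci = greyhound_frequencies(),
                                missing_rate = 0) {
  stopifnot(missing_rate >= 0, missing_rate < 1, length(loci) >= 1)
  loci <- lapply(loci, function(p) p / sum(p))
  structure(list(loci = loci, missing_rate = missing_rate),
            class = "genotype_sim_config")
}

#' Simulate STR genotypes down a pedigree
#'
#' Founders (and unknown parent slots) draw both alleles independently
#' from the locus's founder frequencies; every other animal inherits one
#' allele from each parent by Mendelian sampling.  Deterministic given
#' `seed`.
#'
#' @param ped a [pedigree].
#' @param cfg a [genotype_sim_config()].
#' @param ids individuals to report (default: all; e.g. a genotyped
#'   subsample).
#' @param seed integer seed.
#' @return A [genotype_table()] for `ids`.
#' @export
simulate_genotypes <- function(ped, cfg = genotype_sim_config(),
                               ids = ped$id, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  miss <- setdiff(ids, ped$id)
  if (length(miss)) stop("id not in pedigree: ", miss[1], call. = FALSE)
  n <- nrow(ped)
  pi <- parent_indices(ped)
  L <- length(cfg$loci)
  keep <- match(ids, ped$id)
  a1 <- matrix(NA_integer_, length(ids), L)
  a2 <- matrix(NA_integer_, length(ids), L)
  for (l in seq_len(L)) {
    p <- cfg$loci[[l]]
    sizes <- as.integer(names(p))
    A1 <- integer(n); A2 <- integer(n)
    for (i in seq_len(n)) {
      s <- pi$sire[i]
      A1[i] <- if (is.na(s)) sizes[sample.int(length(p), 1, prob = p)]
        else if (stats::runif(1) < 0.5) A1[s] else A2[s]
      d <- pi$dam[i]
      A2[i] <- if (is.na(d)) sizes[sample.int(length(p), 1, prob = p)]
        else if (stats::runif(1) < 0.5) A1[d] else A2[d]
    }
    a1[, l] <- A1[keep]; a2[, l] <- A2[keep]
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(a1)) < cfg$missing_rate, nrow(a1))
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  genotype_table(ids, names(cfg$loci), a1, a2)
}

# deterministic sub-stream seed per named component, below 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Write a matched synthetic fixture bundle
#'
#' Produces a pedigree CSV, a GenePop genotype file for a genotyped
#' subsample, and a JSON file of summary statistics recomputed from the
#' written files — a self-consistent, seed-stable test fixture.
#'
#' @param outdir writable directory (created if absent).
#' @param seed integer master seed; pedigree and genotypes use named
#'   sub-streams so either can be regenerated independently.
#' @param ped_cfg,geno_cfg generator configurations.
#' @param n_genotyped size of the genotyped subsample.
#' @param reps gene-drop replicates used for the bundled FGS.
#' @return Invisibly, the named file paths (`pedigree`, `genotypes`,
#'   `summary`).
#' @export
fixture_bundle <- function(outdir, seed = 1,
                           ped_cfg = pedigree_sim_config(
                             n_records = 250, years = 20, n_founders = 30,
                             n_both_unknown = 12, founder_years = 8),
                           geno_cfg = genotype_sim_config(
                             loci = greyhound_frequencies()[1:6],
                             missing_rate = 0.02),
                           n_genotyped = 80, reps = 2000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ped <- simulate_pedigree(ped_cfg, seed = substream_seed(seed, "pedigree"))
  set.seed(substream_seed(seed, "subsample"))
  ids <- sort(sample(ped$id, min(n_genotyped, nrow(ped))))
  g <- simulate_genotypes(ped, geno_cfg, ids = ids,
                          seed = substream_seed(seed, "genotypes"))
  ped_path <- file.path(outdir, "pedigree.csv")
  gen_path <- file.path(outdir, "genotypes.gen")
  sum_path <- file.path(outdir, "summary.json")
  write_pedigree(ped, ped_path)
  write_genotypes(g, gen_path, format = "genepop", title = "synthetic fixture")
  rep <- run_full_analysis(ped_path, gen_path,
                           seed = substream_seed(seed, "analysis"),
                           gene_drop_reps = reps, hwe = FALSE)
  jsonlite::write_json(report_numbers(rep), sum_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(pedigree = ped_path, genotypes = gen_path, summary = sum_path))
}
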