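# Full-pipeline report: pedigree statistics -> kinship/diversity ->
# gene drop, plus the STR panel table when genotypes are supplied.

#' Run the full variability analysis
#'
#' Executes the whole pipeline on a pedigree (file path or [pedigree])
#' and optionally a genotype file (path or [genotype_table()]):
#' founder accounting, completeness, generation interval, close-mating
#' and litter statistics, kinship-based diversity (F, AR, MK, GD, fge,
#' delta-F, Ne), gene-drop founder genome surviving, and the per-locus
#' STR panel summary with HWE tests.
#'
#' @param pedigree_input path to a pedigree CSV or a [pedigree].
#' @param genotype_input optional path to a genotype file or a
#'   [genotype_table()].
#' @param genotype_format file format for a genotype path.
#' @param census_n optional census size for Ne/N.
#' @param cohort optional id subset for mean-kinship and gene-drop
#'   scoring (default: all animals).
#' @param seed integer seed (gene drop and HWE chains).
#' @param gene_drop_reps gene-drop replicates.
#' @param hwe run HWE tests in the panel summary.
#' @param hwe_control settings passed to [hwe_test()].
#' @return An `analysis_report` list with elements `founders`,
#'   `completeness`, `interval`, `matings`, `litters`, `progeny`,
#'   `diversity`, `gene_drop`, `panel` (NULL without genotypes) and a
#'   `provenance` block (inputs, seed, settings, package version).
#' @export
run_full_analysis <- function(pedigree_input, genotype_input = NULL,
                              genotype_format = c("genepop", "long"),
                              census_n = NULL, cohort = NULL, seed = 1,
                              gene_drop_reps = 10000, hwe = TRUE,
                              hwe_control = list()) {
  genotype_format <- match.arg(genotype_format)
  ped <- if (inherits(pedigree_input, "pedigree")) pedigree_input
    else read_pedigree(pedigree_input)
  if (is.null(cohort)) cohort <- ped$id

  founders <- identify_founders(ped)
  comp <- completeness(ped)
  interval <- tryCatch(generation_interval(ped), error = function(e) NULL)
  matings <- classify_matings(ped)
  litters <- litter_statistics(ped)
  progeny <- progeny_statistics(ped, founders)

  K <- kinship_matrix(ped)
  Fstats <- inbreeding_coefficients(ped, K)
  AR <- average_relatedness(ped, K)
  mk <- mean_kinship_summary(K, cohort = cohort)
  dn <- tryCatch(delta_F_and_Ne(ped, census_n = census_n, K = K),
                 error = function(e) NULL)
  by_year <- inbreeding_by_year(ped, K)
  gd <- run_gene_drop(ped, cohort = cohort, reps = gene_drop_reps,
                      seed = substream_seed(seed, "genedrop"))

  panel <- NULL
  if (!is.null(genotype_input)) {
    g <- if (inherits(genotype_input, "genotype_table")) genotype_input
      else read_genotypes(genotype_input, format = genotype_format)
    hc <- utils::modifyList(list(seed = substream_seed(seed, "hwe")),
                            hwe_control)
    panel <- panel_summary(g, hwe = hwe, hwe_control = hc)
  }

  structure(list(
    founders = founders, completeness = comp, interval = interval,
    matings = matings, litters = litters, progeny = progeny,
    inbreeding = Fstats[setdiff(names(Fstats), "F")],
    average_relatedness = AR[setdiff(names(AR), "AR")],
    diversity = mk, delta_F_Ne = dn,
    inbreeding_by_year = by_year,
    gene_drop = gd, panel = panel,
    provenance = list(
      pedigree_input = if (is.character(pedigree_input)) pedigree_input
        else "<in-memory pedigree>",
      genotype_input = if (is.character(genotype_input)) genotype_input
        else if (is.null(genotype_input)) NULL else "<in-memory genotypes>",
      n_records = nrow(ped), cohort_size = length(cohort),
      census_n = census_n, seed = seed,
      gene_drop_reps = gene_drop_reps,
      package_version = as.character(utils::packageVersion("pedvar")))
  ), class = "analysis_report")
}

#' Flatten a report to its headline numbers
#'
#' @param report an [run_full_analysis()] result.
#' @return A named list of scalar statistics (suitable for JSON).
#' @export
report_numbers <- function(report) {
  out <- list(
    n_records = report$provenance$n_records,
    n_founders_any_unknown = report$founders$n_any_unknown,
    n_founders_both_unknown = report$founders$n_both_unknown,
    founder_breeding_use = report$founders$breeding_use,
    mean_max_generations = report$completeness$mean_max_gen,
    mean_complete_generations = report$completeness$mean_complete_gen,
    mean_equivalent_generations = report$completeness$mean_t,
    mean_F = report$inbreeding$mean, sd_F = report$inbreeding$sd,
    n_inbred = report$inbreeding$n_inbred,
    mean_AR = report$average_relatedness$mean,
    mean_kinship = report$diversity$mk,
    gene_diversity = report$diversity$gd,
    fge = report$diversity$fge,
    fgs = report$gene_drop$fgs, fgs_se = report$gene_drop$fgs_se,
    full_sib_matings = unname(report$matings$counts["full_sib"]),
    half_sib_matings = unname(report$matings$counts["half_sib"]),
    parent_offspring_matings =
      unname(report$matings$counts["parent_offspring"]),
    mean_litter_size = report$litters$litters$mean
  )
  if (!is.null(report$interval)) {
    out$generation_interval <- report$interval$mean
    out$generation_interval_se <- report$interval$se
  }
  if (!is.null(report$delta_F_Ne)) {
    out$delta_F <- report$delta_F_Ne$delta_F
    out$Ne <- report$delta_F_Ne$Ne
    out$Ne_dem <- report$delta_F_Ne$Ne_dem
    if (!is.null(report$delta_F_Ne$Ne_over_N))
      out$Ne_over_N <- report$delta_F_Ne$Ne_over_N
  }
  if (!is.null(report$panel)) {
    out$mean_pic <- unname(report$panel$means["pic"])
    out$mean_ho <- unname(report$panel$means["ho"])
    out$mean_he <- unname(report$panel$means["he"])
    out$mean_fis <- unname(report$panel$means["fis"])
    out$total_alleles <- report$panel$total_alleles
  }
  out
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (full precision), `per_individual.tsv` (id, F,
#' AR, t), `inbreeding_by_year.tsv`, `f_distribution.tsv` (inbreeding
#' histogram bins) and, when genotypes were analyzed,
#' `panel_summary.tsv`.
#'
#' @param report an [run_full_analysis()] result; must have been run on
#'   inputs this function can re-read.
#' @param ped the [pedigree] the report was computed from.
#' @param outdir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, ped, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  j <- file.path(outdir, "report.json")
  jsonlite::write_json(report_numbers(report), j, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, j)

  K <- kinship_matrix(ped)
  per <- data.frame(id = ped$id,
                    F = inbreeding_coefficients(ped, K)$F,
                    AR = average_relatedness(ped, K)$AR,
                    t = completeness(ped)$per_individual$t)
  p1 <- file.path(outdir, "per_individual.tsv")
  utils::write.table(per, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p1)

  p2 <- file.path(outdir, "inbreeding_by_year.tsv")
  utils::write.table(report$inbreeding_by_year, p2, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths <- c(paths, p2)

  br <- seq(0, 1, by = 0.05)
  hh <- hist(per$F, breaks = br, plot = FALSE)
  p3 <- file.path(outdir, "f_distribution.tsv")
  utils::write.table(data.frame(bin_low = head(br, -1), bin_high = br[-1],
                                n = hh$counts),
                     p3, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p3)

  if (!is.null(report$panel)) {
    p4 <- file.path(outdir, "panel_summary.tsv")
    utils::write.table(report$panel$per_locus, p4, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p4)
  }
  invisible(paths)
}
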