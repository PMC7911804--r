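test_that("simulator configs validate their inputs", {
  expect_error(pedigree_sim_config(n_founders = 5, n_both_unknown = 9))
  expect_error(pedigree_sim_config(breeding_age = c(3, 2)))
  expect_error(pedigree_sim_config(planted = data.frame(type = "cousin",
                                                        year = 3)))
  expect_error(genotype_sim_config(missing_rate = 1.2))
})

test_that("a tiny two-founder config yields one full-sib litter", {
  cfg <- pedigree_sim_config(n_records = 6, years = 6, n_founders = 2,
                             n_both_unknown = 2, founder_years = 1)
  ped <- simulate_pedigree(cfg, seed = 2)
  expect_equal(nrow(ped), 6)
  fr <- identify_founders(ped)
  expect_equal(fr$n_both_unknown, 2)
  sibs <- ped[!is.na(ped$sire), ]
  expect_equal(length(unique(paste(sibs$sire, sibs$dam))), 1)
})

test_that("planted close matings are recovered exactly by classification", {
  plant <- data.frame(type = c("full_sib", "half_sib", "parent_offspring"),
                      year = c(14, 12, 13))
  cfg <- pedigree_sim_config(n_records = 300, years = 20, n_founders = 30,
                             n_both_unknown = 15, founder_years = 6,
                             planted = plant)
  for (seed in c(3, 9)) {
    m <- classify_matings(simulate_pedigree(cfg, seed = seed))
    expect_equal(unname(m$counts), c(1L, 1L, 1L))
  }
})

test_that("infeasible plants fail with the plant named", {
  cfg <- pedigree_sim_config(n_records = 12, years = 6, n_founders = 4,
                             n_both_unknown = 4, founder_years = 1,
                             planted = data.frame(type = "full_sib", year = 2))
  expect_error(simulate_pedigree(cfg, seed = 1), "infeasible planted")
})

test_that("the study-scale config hits its structural targets", {
  ped <- simulate_pedigree(pedigree_sim_config(), seed = 77)
  expect_equal(nrow(ped), 912)
  fr <- identify_founders(ped)
  expect_equal(fr$n_any_unknown, 83)
  expect_equal(fr$n_both_unknown, 27)
  ls <- litter_statistics(ped)
  expect_gte(ls$litters$min, 2)
  expect_lte(ls$litters$max, 16)
  expect_lt(abs(ls$litters$mean - 6), 1)
  gi <- generation_interval(ped)
  expect_lt(abs(gi$mean - 5), 2 * max(gi$se, 0.5))
  # generator self-report vs independent parent-reference tally
  ps <- progeny_statistics(ped, fr)
  expect_equal(sum(ps$total_progeny),
               2 * sum(!is.na(ped$sire) & !is.na(ped$dam)) +
                 sum(xor(is.na(ped$sire), is.na(ped$dam))))
})

test_that("generated pedigrees survive a write/read/validate round trip", {
  ped <- simulate_pedigree(pedigree_sim_config(n_records = 150, years = 15,
                                               n_founders = 20,
                                               n_both_unknown = 10,
                                               founder_years = 5), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  back <- read_pedigree(path)
  expect_equal(nrow(back), nrow(ped))
  expect_setequal(back$id, ped$id)
})

test_that("genotype simulation is Mendelian and frequency-faithful", {
  # founders only: allele frequencies converge to configured values
  n <- 174
  founders <- pedigree(data.frame(id = sprintf("F%03d", 1:n),
                                  sire = NA, dam = NA))
  cfg <- genotype_sim_config(loci = greyhound_frequencies()["AHTk211"])
  g <- simulate_genotypes(founders, cfg, seed = 31)
  fr <- allele_frequencies(g, "AHTk211")
  p0 <- cfg$loci$AHTk211
  for (a in names(p0)) {
    se <- sqrt(p0[[a]] * (1 - p0[[a]]) / (2 * n))
    expect_lt(abs(fr$p[[a]] - p0[[a]]), 3.5 * se)
  }
  # offspring of two fixed, different homozygotes is always heterozygous
  trio <- pedigree(data.frame(id = c("A", "B", "C"),
                              sire = c(NA, NA, "A"), dam = c(NA, NA, "B")))
  cfg2 <- genotype_sim_config(loci = list(L = c(`100` = 0.5, `104` = 0.5)))
  forced <- replicate(30, {
    g2 <- simulate_genotypes(trio, cfg2, seed = sample.int(1e6, 1))
    i <- match(c("A", "B", "C"), g2$ids)
    hom <- g2$a1[i[1], 1] == g2$a2[i[1], 1] && g2$a1[i[2], 1] == g2$a2[i[2], 1]
    if (!hom || g2$a1[i[1], 1] == g2$a1[i[2], 1]) NA
    else g2$a1[i[3], 1] != g2$a2[i[3], 1]
  })
  expect_true(all(stats::na.omit(forced)))
  # Mendel: every child allele occurs in the matching parent
  ped <- simulate_pedigree(pedigree_sim_config(n_records = 80, years = 12,
                                               n_founders = 14,
                                               n_both_unknown = 8,
                                               founder_years = 4), seed = 3)
  g3 <- simulate_genotypes(ped, genotype_sim_config(
    loci = greyhound_frequencies()[1:3]), seed = 5)
  pidx <- match(ped$id, g3$ids)
  for (l in 1:3) for (i in seq_len(nrow(ped))) {
    s <- ped$sire[i]
    if (!is.na(s)) {
      si <- match(s, g3$ids)
      expect_true(g3$a1[pidx[i], l] %in% c(g3$a1[si, l], g3$a2[si, l]) ||
                  g3$a2[pidx[i], l] %in% c(g3$a1[si, l], g3$a2[si, l]))
    }
  }
  # missingness rate honored
  g4 <- simulate_genotypes(founders, genotype_sim_config(
    loci = greyhound_frequencies()[1:4], missing_rate = 0.1), seed = 7)
  rate <- mean(is.na(g4$a1))
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / length(g4$a1)))
})

test_that("the closed-population generator produces complete discrete generations", {
  ped <- simulate_closed_population(4, 4, 5, 16, seed = 6)
  expect_s3_class(ped, "pedigree")
  cr <- completeness(ped)$per_individual
  gen <- (ped$birth_year - 1) / 2
  expect_equal(cr$t, gen)   # fully known pedigree: t = generation index
})

test_that("fixture bundles are byte-stable and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- fixture_bundle(d1, seed = 4, n_genotyped = 30, reps = 400,
                       ped_cfg = pedigree_sim_config(n_records = 120,
                                                     years = 15,
                                                     n_founders = 16,
                                                     n_both_unknown = 8,
                                                     founder_years = 5),
                       geno_cfg = genotype_sim_config(
                         loci = greyhound_frequencies()[1:3]))
  p2 <- fixture_bundle(d2, seed = 4, n_genotyped = 30, reps = 400,
                       ped_cfg = pedigree_sim_config(n_records = 120,
                                                     years = 15,
                                                     n_founders = 16,
                                                     n_both_unknown = 8,
                                                     founder_years = 5),
                       geno_cfg = genotype_sim_config(
                         loci = greyhound_frequencies()[1:3]))
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  # stored summary equals recomputation on the written files
  stored <- jsonlite::read_json(p1[["summary"]], simplifyVector = TRUE)
  rep <- run_full_analysis(p1[["pedigree"]], p1[["genotypes"]],
                           seed = pedvar:::substream_seed(4, "analysis"),
                           gene_drop_reps = 400, hwe = FALSE)
  fresh <- report_numbers(rep)
  expect_equal(stored$mean_F, fresh$mean_F)
  expect_equal(stored$fgs, fresh$fgs)
  expect_equal(stored$total_alleles, fresh$total_alleles)
})
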