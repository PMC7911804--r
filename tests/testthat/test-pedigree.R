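test_that("a minimal trio parses, validates and orders correctly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,sex,birth_year",
               "C,A,B,M,2005",
               "A,NN,NN,M,2000",
               "B,,0,F,2001"), path)
  ped <- read_pedigree(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  # topological order: parents before offspring
  expect_true(match("A", ped$id) < match("C", ped$id))
  expect_true(match("B", ped$id) < match("C", ped$id))
  # all unknown tokens normalized
  expect_true(all(is.na(ped$sire[ped$id %in% c("A", "B")])))
})

test_that("structural violations are rejected with informative errors", {
  expect_error(pedigree(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
               "duplicate id: A")
  expect_error(pedigree(data.frame(id = "C", sire = "C", dam = NA)),
               "self-parent")
  expect_error(pedigree(data.frame(id = c("A", "B"), sire = c("B", "A"),
                                   dam = NA)),
               "cycle")
  expect_error(pedigree(data.frame(id = "C", sire = "A", dam = NA)),
               "parent not in pedigree: A")
  ped <- pedigree(data.frame(id = "C", sire = "A", dam = NA),
                  on_missing_parent = "phantom")
  expect_equal(nrow(ped), 2)
  expect_error(pedigree(data.frame(id = c("A", "C"), sire = c(NA, "A"),
                                   dam = NA, sex = c("F", "M"))),
               "female is used as sire")
  expect_error(pedigree(data.frame(id = c("A", "C"), sire = c(NA, "A"),
                                   dam = NA, birth_year = c(2005, 2000))),
               "born in or after")
})

test_that("founder identification splits any-unknown from both-unknown", {
  ped <- pedigree(data.frame(
    id = c("A", "B", "H", "C"),
    sire = c(NA, NA, "A", "A"),
    dam  = c(NA, NA, NA, "B"),
    sex = c("M", "F", "M", "F")))
  fr <- identify_founders(ped)
  expect_setequal(fr$founders_any_unknown, c("A", "B", "H"))
  expect_setequal(fr$founders_both_unknown, c("A", "B"))
  expect_true(all(fr$founders_both_unknown %in% fr$founders_any_unknown))
  # every record in exactly one class
  one_unknown <- setdiff(fr$founders_any_unknown, fr$founders_both_unknown)
  non_founder <- setdiff(ped$id, fr$founders_any_unknown)
  expect_setequal(c(fr$founders_both_unknown, one_unknown, non_founder),
                  ped$id)
  expect_equal(fr$breeding_use, 2 / 3)   # A and B bred, H did not
})

test_that("completeness metrics follow the ancestor-path definitions", {
  ped <- pedigree(data.frame(
    id = c("A", "B", "C", "H"),
    sire = c(NA, NA, "A", "A"),
    dam  = c(NA, NA, "B", NA)))
  cr <- completeness(ped)
  per <- cr$per_individual
  get <- function(id, col) per[per$id == id, col]
  expect_equal(get("A", "max_gen"), 0)
  expect_equal(get("A", "complete_gen"), 0)
  expect_equal(get("A", "t"), 0)
  expect_equal(get("C", "max_gen"), 1)          # both parents known founders
  expect_equal(get("C", "complete_gen"), 1)
  expect_equal(get("C", "t"), 1)
  expect_equal(get("H", "max_gen"), 1)          # known sire, unknown dam
  expect_equal(get("H", "complete_gen"), 0)
  expect_equal(get("H", "t"), 0.5)
  expect_true(all(per$complete_gen <= per$max_gen))
})

test_that("equivalent complete generations is monotone in pedigree knowledge", {
  base <- data.frame(id = c("A", "B", "C", "D"),
                     sire = c(NA, NA, "A", "C"),
                     dam  = c(NA, NA, NA, "B"))
  more <- base; more$dam[3] <- "B"   # reveal C's dam
  t0 <- completeness(pedigree(base))$per_individual
  t1 <- completeness(pedigree(more))$per_individual
  t1 <- t1[match(t0$id, t1$id), ]
  expect_true(all(t1$t >= t0$t))
})

test_that("generation interval averages parent ages with degenerate SE flagged", {
  ped <- pedigree(data.frame(id = c("S", "D", "P"),
                             sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
                             sex = c("M", "F", "M"),
                             birth_year = c(2000, 2002, 2006)))
  gi <- generation_interval(ped)
  expect_equal(gi$mean, 5)            # ages 6 and 4
  expect_equal(gi$n_pairs, 2)
  one <- pedigree(data.frame(id = c("S", "P"), sire = c(NA, "S"),
                             dam = NA, birth_year = c(2000, 2004)))
  gi1 <- generation_interval(one)
  expect_equal(gi1$se, 0)
  expect_equal(gi1$n_pairs, 1)
  undated <- pedigree(data.frame(id = c("S", "P"), sire = c(NA, "S"),
                                 dam = NA))
  expect_error(generation_interval(undated), "no dated parent-offspring")
})

test_that("close matings classify as parent-offspring, full-sib, half-sib", {
  ped <- pedigree(data.frame(
    id   = c("GS", "GD", "S1", "S2", "HD", "FS", "PO", "HS"),
    sire = c(NA,  NA,  "GS", "GS", NA,  "S1", "S1", "S1"),
    dam  = c(NA,  NA,  "GD", "GD", NA,  "S2", "GD", "HD"),
    sex  = c("M", "F", "M",  "F",  "F", "M",  "F", "M")))
  # FS: parents S1 x S2 are full sibs; PO: S1 x GD is son x mother;
  # HS's parents S1 x HD are unrelated -> HS is outbred; but make one:
  ped2 <- pedigree(data.frame(
    id   = c("GS", "GD", "D2", "S1", "S3", "X"),
    sire = c(NA,  NA,  NA,  "GS", "GS", "S1"),
    dam  = c(NA,  NA,  NA,  "GD", "D2", "S3"),
    sex  = c("M", "F", "F", "M",  "F",  "M")))
  m <- classify_matings(ped)
  cl <- m$classification
  expect_equal(cl$class[cl$id == "FS"], "full_sib")
  expect_equal(cl$class[cl$id == "PO"], "parent_offspring")
  m2 <- classify_matings(ped2)
  expect_equal(m2$classification$class[m2$classification$id == "X"],
               "half_sib")
  expect_equal(unname(m$counts["full_sib"]), 1L)
  expect_equal(unname(m$percent["full_sib"]), 100 / nrow(ped))
})

test_that("litters split full-sib groups by birth year", {
  ped <- pedigree(data.frame(
    id = c("S", "D", paste0("P", 1:5)),
    sire = c(NA, NA, rep("S", 5)),
    dam  = c(NA, NA, rep("D", 5)),
    sex = c("M", "F", rep("U", 5)),
    birth_year = c(2000, 2000, 2003, 2003, 2004, 2004, 2004)))
  lr <- litter_statistics(ped)
  expect_equal(lr$full_sib_groups$n_groups, 1)
  expect_equal(lr$full_sib_groups$n_individuals, 5)
  expect_setequal(lr$litters$sizes, c(2, 3))
  expect_equal(lr$litters$min, 2)
  expect_equal(lr$litters$max, 3)
  expect_equal(lr$litters$mean, 2.5)
})

test_that("progeny statistics tally parent references", {
  ped <- pedigree(data.frame(id = c("A", "B", "C"),
                             sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
                             sex = c("M", "F", "F")))
  ps <- progeny_statistics(ped)
  expect_equal(sum(ps$total_progeny), 2)   # C counted once per parent
  expect_equal(sum(ps$breeders), 2)
  expect_equal(sum(ps$non_breeders), 1)
})

test_that("statistics are invariant to record order", {
  ped <- random_test_pedigree(30, seed = 71)
  df <- as.data.frame(ped)
  set.seed(1)
  shuffled <- pedigree(df[sample.int(nrow(df)), ])
  f1 <- inbreeding_coefficients(ped)$F
  f2 <- inbreeding_coefficients(shuffled)$F
  expect_equal(f2[names(f1)], f1)
  expect_setequal(identify_founders(shuffled)$founders_any_unknown,
                  identify_founders(ped)$founders_any_unknown)
})

test_that("pedigree CSV writing round-trips through reading", {
  ped <- random_test_pedigree(25, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  back <- read_pedigree(path)
  expect_equal(as.data.frame(back)[c("id", "sire", "dam")],
               as.data.frame(ped)[c("id", "sire", "dam")])
})
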