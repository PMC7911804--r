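# Seeded pedigree simulator: overlapping generations over birth-year
# cohorts, founder influx with a both-unknown fraction, litters of 2-16,
# a breeding-age window, close-kin avoidance, and optionally planted
# close matings (generated as single-offspring litters so that planted
# mating counts equal classified offspring counts).

#' Configuration for the pedigree simulator
#'
#' Defaults emulate a small closed studbook breed registered over ~35
#' birth-year cohorts: 83 founders of which 27 have both parents
#' unknown, breeding ages 1.5-10 years, litter sizes 2-16 with mean
#' close to 6, and a target registry size of 912 with the observed sex
#' ratio.
#'
#' @param n_records target total number of records.
#' @param years number of birth-year cohorts (years 1:years).
#' @param n_founders total founders (>= 1 unknown parent).
#' @param n_both_unknown founders with both parents unknown (<=
#'   `n_founders`); the rest get one known parent drawn from the
#'   existing population.
#' @param founder_years cohorts over which founders are introduced.
#' @param breeding_age two-element numeric, minimum and maximum parent
#'   age in years at offspring birth (fractional years honored
#'   internally, output years are integers).
#' @param litter_lambda Poisson rate of `2 + min(rpois(lambda), 14)`
#'   litter sizes (default 4 gives mean ~5.97 on 2..16).
#' @param p_male probability a pup is male.
#' @param mating policy: `"avoid_close_kin"` (reject parent-offspring,
#'   full-sib and half-sib pairs; default) or `"random"`.
#' @param planted data frame with columns `type` (one of `"full_sib"`,
#'   `"half_sib"`, `"parent_offspring"`) and `year`, each row one
#'   planted close mating producing a single offspring.
#' @return A `pedigree_sim_config` list.
#' @export
pedigree_sim_config <- function(n_records = 912, years = 35,
                                n_founders = 83, n_both_unknown = 27,
                                founder_years = 12,
                                breeding_age = c(1.5, 10),
                                litter_lambda = 4,
                                p_male = 433 / 912,
                                mating = c("avoid_close_kin", "random"),
                                planted = NULL) {
  mating <- match.arg(mating)
  stopifnot(n_both_unknown <= n_founders, breeding_age[1] > 0,
            breeding_age[2] > breeding_age[1], n_records >= n_founders)
  if (!is.null(planted)) {
    stopifnot(all(c("type", "year") %in% names(planted)),
              all(planted$type %in% c("full_sib", "half_sib",
                                      "parent_offspring")))
  }
  structure(list(n_records = n_records, years = years,
                 n_founders = n_founders, n_both_unknown = n_both_unknown,
                 founder_years = founder_years, breeding_age = breeding_age,
                 litter_lambda = litter_lambda, p_male = p_male,
                 mating = mating, planted = planted),
            class = "pedigree_sim_config")
}

# structural relation of a candidate pair (by index), for close-kin
# avoidance and plant selection
pair_relation <- function(sire, dam, si, di, i, j) {
  if (!is.na(si[j]) && si[j] == i) return("parent_offspring")
  if (!is.na(di[j]) && di[j] == i) return("parent_offspring")
  if (!is.na(si[i]) && si[i] == j) return("parent_offspring")
  if (!is.na(di[i]) && di[i] == j) return("parent_offspring")
  ss <- !is.na(si[i]) && !is.na(si[j]) && si[i] == si[j]
  dd <- !is.na(di[i]) && !is.na(di[j]) && di[i] == di[j]
  if (ss && dd) return("full_sib")
  if (ss || dd) return("half_sib")
  "unrelated"
}

#' Simulate a studbook pedigree
#'
#' Runs the birth-year cohort model of [pedigree_sim_config()]:
#' founders enter over the early cohorts, litters are produced by pairs
#' sampled from the animals of breeding age (close kin avoided under the
#' default policy), and any planted close matings are injected in their
#' scheduled year as single-pup litters.  Deterministic given `seed`.
#'
#' @param cfg a [pedigree_sim_config()].
#' @param seed integer seed.
#' @return A validated [pedigree] with exactly `cfg$n_records` records.
#' @export
simulate_pedigree <- function(cfg = pedigree_sim_config(), seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  N <- cfg$n_records
  id <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); byear <- numeric(0)   # fractional internally
  si <- integer(0); di <- integer(0)          # parent indices
  n <- 0L
  add <- function(s_idx, d_idx, sx, by) {
    n <<- n + 1L
    id[n] <<- sprintf("PG%04d", n)
    sire[n] <<- if (is.na(s_idx)) NA_character_ else id[s_idx]
    dam[n]  <<- if (is.na(d_idx)) NA_character_ else id[d_idx]
    si[n] <<- s_idx; di[n] <<- d_idx
    sex[n] <<- sx; byear[n] <<- by
    n
  }
  draw_sex <- function() if (stats::runif(1) < cfg$p_male) "M" else "F"

  # founder schedule: spread over the first founder_years cohorts
  f_years <- sort(rep_len(seq_len(cfg$founder_years), cfg$n_founders))
  f_both <- rep(FALSE, cfg$n_founders)
  f_both[sample.int(cfg$n_founders, cfg$n_both_unknown)] <- TRUE
  # both-unknown founders first within each year so one-unknown founders
  # can pick a known parent
  ordv <- order(f_years, !f_both)
  f_years <- f_years[ordv]; f_both <- f_both[ordv]

  breedable <- function(year) {
    age <- year - byear[seq_len(n)]
    which(age >= cfg$breeding_age[1] & age <= cfg$breeding_age[2])
  }
  pick_pair <- function(cand, avoid, used_dams) {
    males <- cand[sex[cand] == "M"]
    females <- setdiff(cand[sex[cand] == "F"], used_dams)
    if (!length(males) || !length(females)) return(NULL)
    for (try in 1:50) {
      s <- males[sample.int(length(males), 1)]
      d <- females[sample.int(length(females), 1)]
      rel <- pair_relation(sire, dam, si, di, s, d)
      if (!avoid || rel == "unrelated") return(c(s, d))
    }
    NULL
  }

  plant_pair <- function(type, year) {
    cand <- breedable(year)
    males <- cand[sex[cand] == "M"]; females <- cand[sex[cand] == "F"]
    males <- males[sample.int(length(males))]
    females <- females[sample.int(length(females))]
    for (s in males) for (d in females) {
      if (pair_relation(sire, dam, si, di, s, d) == type) return(c(s, d))
    }
    stop("infeasible planted mating: ", type, " in year ", year,
         call. = FALSE)
  }

  planted <- cfg$planted
  avoid <- cfg$mating == "avoid_close_kin"
  for (year in seq_len(cfg$years)) {
    if (n >= N) break
    # founders scheduled this year; founder sexes alternate so a mating
    # pair always exists even in tiny configurations
    for (f in which(f_years == year)) {
      if (n >= N) break
      fsex <- if (f %% 2L == 1L) "M" else "F"
      if (f_both[f] || n == 0L) {
        add(NA_integer_, NA_integer_, fsex, year - stats::runif(1))
      } else {
        # one known parent, preferably old enough to breed by this year
        old_enough <- which(byear[seq_len(n)] <= year - cfg$breeding_age[1])
        known <- if (length(old_enough))
          old_enough[sample.int(length(old_enough), 1)] else sample.int(n, 1)
        by <- max(byear[known] + cfg$breeding_age[1], year - stats::runif(1))
        if (sex[known] == "M") add(known, NA_integer_, fsex, by)
        else                   add(NA_integer_, known, fsex, by)
      }
    }
    # planted matings scheduled this year: single-pup litters
    used_dams <- integer(0)      # one litter per dam per year
    if (!is.null(planted)) {
      for (r in which(planted$year == year)) {
        if (n >= N) break
        pr <- plant_pair(planted$type[r], year)
        add(pr[1], pr[2], draw_sex(), year)
        used_dams <- c(used_dams, pr[2])
      }
    }
    # ordinary litters: fill toward the pro-rata trajectory
    target_by_now <- ceiling(N * year / cfg$years)
    while (n < min(target_by_now, N)) {
      pr <- pick_pair(breedable(year), avoid, used_dams)
      if (is.null(pr)) break
      used_dams <- c(used_dams, pr[2])
      size <- min(2L + stats::rpois(1, cfg$litter_lambda), 16L, N - n)
      if (size < 1L) break
      for (p in seq_len(size)) add(pr[1], pr[2], draw_sex(), year)
    }
  }
  if (n < N) stop("simulation produced only ", n, " of ", N,
                  " records; widen the config", call. = FALSE)
  pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                      birth_year = as.integer(ceiling(byear)),
                      status = ifelse(is.na(sire) & is.na(dam),
                                      "founder", "bred"),
                      stringsAsFactors = FALSE))
}

#' Simulate a closed random-mating population with discrete generations
#'
#' An idealized population for rate-of-inbreeding calibration:
#' `n_males` sires and `n_females` dams per generation, parents drawn
#' uniformly with replacement, so the idealized effective size is about
#' `4 Nm Nf / (Nm + Nf)` and the expected per-generation increase in
#' inbreeding is about `1 / (2 Ne)`.
#'
#' @param n_males,n_females breeders per generation.
#' @param generations number of discrete offspring generations.
#' @param offspring_per_gen cohort size per generation.
#' @param seed integer seed.
#' @return A [pedigree]; founders in year 1, generation g born in year
#'   `2 g + 1` (keeps parent ages inside a 2-year interval).
#' @export
simulate_closed_population <- function(n_males = 10, n_females = 10,
                                       generations = 10,
                                       offspring_per_gen = 50, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  id <- sprintf("G00I%03d", seq_len(n_males + n_females))
  df <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                   sex = rep(c("M", "F"), c(n_males, n_females)),
                   birth_year = 1L, stringsAsFactors = FALSE)
  males <- df$id[df$sex == "M"]; females <- df$id[df$sex == "F"]
  for (g in seq_len(generations)) {
    sx <- rep(c("M", "F"), length.out = offspring_per_gen)
    new <- data.frame(id = sprintf("G%02dI%03d", g, seq_len(offspring_per_gen)),
                      sire = sample(males, offspring_per_gen, replace = TRUE),
                      dam = sample(females, offspring_per_gen, replace = TRUE),
                      sex = sx, birth_year = as.integer(2 * g + 1),
                      stringsAsFactors = FALSE)
    df <- rbind(df, new)
    males <- sample(new$id[new$sex == "M"], n_males)
    females <- sample(new$id[new$sex == "F"], n_females)
  }
  df$status <- "unknown"
  pedigree(df)
}
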