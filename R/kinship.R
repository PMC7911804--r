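# Coancestry and inbreeding via the tabular method, and the diversity
# summaries derived from the kinship matrix: average relatedness, mean
# kinship, gene diversity, founder genome equivalents, rate of
# inbreeding and effective population size.

#' Coancestry (kinship) matrix by the tabular method
#'
#' Computes the full pairwise coancestry matrix f(i, j): the probability
#' that alleles drawn at random, one from each animal, are identical by
#' descent.  The recursion runs over the topological order: for animal i
#' with parents s, d, `f(i, i) = 0.5 (1 + f(s, d))` and
#' `f(i, j) = 0.5 (f(s, j) + f(d, j))` for earlier j; an unknown parent
#' contributes 0 (each unknown slot is an unrelated, non-inbred phantom
#' founder).  All values are dyadic rationals, so double arithmetic is
#' exact.
#'
#' @param ped a [pedigree].
#' @param cohort optional ids to which the returned matrix is restricted
#'   (the recursion always runs on the full pedigree; truncation would
#'   change F).
#' @return A symmetric `kinship_matrix` with dimnames = ids; diagonal
#'   `0.5 (1 + F_i)`.
#' @export
#' @examples
#' trio <- pedigree(data.frame(id = c("A", "B", "C"),
#'                             sire = c(NA, NA, "A"),
#'                             dam  = c(NA, NA, "B")))
#' kinship_matrix(trio)
kinship_matrix <- function(ped, cohort = NULL) {
  n <- nrow(ped)
  pi <- parent_indices(ped)
  f <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (is.na(s)) 0 else f[s, j]) +
                    (if (is.na(d)) 0 else f[d, j]))
      f[i, j] <- row
      f[j, i] <- row
    }
    f[i, i] <- 0.5 * (1 + (if (is.na(s) || is.na(d)) 0 else f[s, d]))
  }
  if (!is.null(cohort)) {
    miss <- setdiff(cohort, ped$id)
    if (length(miss)) stop("cohort id not in pedigree: ", miss[1], call. = FALSE)
    f <- f[cohort, cohort, drop = FALSE]
  }
  class(f) <- c("kinship_matrix", "matrix", "array")
  f
}

#' Individual inbreeding coefficients
#'
#' F_i is the coancestry of the animal's parents (0 when either parent
#' is unknown): the probability that the animal's two alleles at a locus
#' are identical by descent.
#'
#' @param ped a [pedigree].
#' @param K optionally a precomputed full [kinship_matrix()].
#' @return List with the per-animal vector `F` (named by id), `mean`,
#'   `sd`, `n_inbred` (F > 0), and counts above 20% and 25%.
#' @export
inbreeding_coefficients <- function(ped, K = kinship_matrix(ped)) {
  F <- 2 * diag(K) - 1
  names(F) <- ped$id
  list(F = F, mean = mean(F), sd = stats::sd(F),
       n_inbred = sum(F > 0),
       n_over_20 = sum(F > 0.20), n_over_25 = sum(F > 0.25))
}

#' Average relatedness
#'
#' AR_i is the mean additive relationship a(i, j) = 2 f(i, j) of animal i
#' with every animal in the pedigree, itself included: the expected
#' representation of i's genome in the whole population.
#'
#' @inheritParams inbreeding_coefficients
#' @return List with per-animal `AR` (named), `mean`, and `n_over_25`
#'   (AR > 25%).
#' @export
average_relatedness <- function(ped, K = kinship_matrix(ped)) {
  AR <- rowMeans(2 * K)
  names(AR) <- ped$id
  list(AR = AR, mean = mean(AR), n_over_25 = sum(AR > 0.25))
}

#' Mean kinship, gene diversity and founder genome equivalents
#'
#' MK is the mean of f(i, j) over all ordered pairs in the cohort,
#' self-pairs included (the "mean kinship matrix" convention of captive
#' population management software); gene diversity GD = 1 - MK; founder
#' genome equivalents fge = 1 / (2 MK), the number of equally
#' contributing founders with no random allele loss that would give the
#' observed gene diversity.
#'
#' @param K a [kinship_matrix()].
#' @param cohort optional ids (default: all columns of `K`).
#' @param include_diagonal include self-kinship terms in the average
#'   (default TRUE); the alternative convention is available because the
#'   reference software's choice is not documented.
#' @return List `mk`, `gd`, `fge`, `n`.
#' @export
mean_kinship_summary <- function(K, cohort = NULL, include_diagonal = TRUE) {
  if (!is.null(cohort)) {
    miss <- setdiff(cohort, colnames(K))
    if (length(miss)) stop("cohort id not in kinship matrix: ", miss[1],
                           call. = FALSE)
    K <- K[cohort, cohort, drop = FALSE]
  }
  n <- ncol(K)
  if (n == 0) stop("empty cohort", call. = FALSE)
  mk <- if (include_diagonal) mean(K) else {
    if (n == 1) stop("cohort of 1 has no off-diagonal pairs", call. = FALSE)
    (sum(K) - sum(diag(K))) / (n * (n - 1))
  }
  list(mk = mk, gd = 1 - mk, fge = 1 / (2 * mk), n = n)
}

#' Rate of inbreeding and effective population size
#'
#' Uses the individual-increase formulation: for each animal with
#' equivalent complete generations t > 1,
#' `dF_i = 1 - (1 - F_i)^(1 / (t_i - 1))` (the animal's own generation is
#' discounted); the realized effective population size is
#' `Ne = 1 / (2 mean(dF))`.  A demographic alternative
#' `Ne_dem = 4 Nm Nf / (Nm + Nf)` is computed from the numbers of sires
#' and dams actually used.
#'
#' @param ped a [pedigree].
#' @param census_n optional census size for the Ne/N ratio.
#' @param K optionally a precomputed [kinship_matrix()].
#' @return List `delta_F` (mean), `delta_F_i` (per eligible animal),
#'   `Ne`, `Nm`, `Nf`, `Ne_dem`, and `Ne_over_N` when `census_n` given.
#' @export
delta_F_and_Ne <- function(ped, census_n = NULL, K = kinship_matrix(ped)) {
  F <- inbreeding_coefficients(ped, K)$F
  t <- completeness(ped)$per_individual$t
  ok <- t > 1
  if (!any(ok)) stop("pedigree too shallow: no individual with t > 1",
                     call. = FALSE)
  dFi <- 1 - (1 - F[ok])^(1 / (t[ok] - 1))
  dF <- mean(dFi)
  Nm <- length(unique(stats::na.omit(ped$sire)))
  Nf <- length(unique(stats::na.omit(ped$dam)))
  out <- list(delta_F = dF, delta_F_i = dFi,
              Ne = 1 / (2 * dF),
              Nm = Nm, Nf = Nf,
              Ne_dem = ne_demographic(Nm, Nf))
  if (!is.null(census_n)) out$Ne_over_N <- out$Ne / census_n
  out
}

#' Demographic effective population size
#'
#' The idealized-population estimator from breeder counts:
#' `Ne = 4 Nm Nf / (Nm + Nf)`.
#'
#' @param n_males,n_females numbers of breeding males and females.
#' @return Ne.
#' @export
#' @examples
#' ne_demographic(15, 23)   # ~36.32
ne_demographic <- function(n_males, n_females) {
  if (n_males + n_females == 0) return(NA_real_)
  4 * n_males * n_females / (n_males + n_females)
}

#' Mean inbreeding by birth-year cohort
#'
#' @param ped a [pedigree].
#' @param K optionally a precomputed [kinship_matrix()].
#' @return Data frame `year`, `n`, `mean_F`, one row per year that has
#'   births (years without births are absent, not zero-filled).
#' @export
inbreeding_by_year <- function(ped, K = kinship_matrix(ped)) {
  F <- inbreeding_coefficients(ped, K)$F
  ok <- !is.na(ped$birth_year)
  if (!any(ok)) return(data.frame(year = integer(0), n = integer(0),
                                  mean_F = numeric(0)))
  agg <- stats::aggregate(F[ok], list(year = ped$birth_year[ok]),
                          function(v) c(n = length(v), mean_F = mean(v)))
  data.frame(year = agg$year, n = as.integer(agg$x[, "n"]),
             mean_F = agg$x[, "mean_F"])
}
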