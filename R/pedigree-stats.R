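# Descriptive pedigree statistics: founder accounting, pedigree
# completeness, generation interval, close-mating classification, litter
# and progeny statistics.

#' Identify founders and summarize their breeding use
#'
#' A founder is an animal through which variation enters the pedigree.
#' Two definitions are supported and both sets are always reported:
#' `any_unknown` (at least one unknown parent, the studbook convention
#' this package defaults to) and `both_unknown` (the stricter subset with
#' no known parent).
#'
#' @param ped a [pedigree].
#' @param definition which set downstream founder counts refer to.
#' @return A `founder_report` list: id sets, per-founder progeny counts by
#'   sex, the number of founders without progeny and the breeding-use
#'   fraction (founders with progeny / founders under `definition`).
#' @export
identify_founders <- function(ped, definition = c("any_unknown", "both_unknown")) {
  definition <- match.arg(definition)
  any_unknown  <- ped$id[is.na(ped$sire) | is.na(ped$dam)]
  both_unknown <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  sel <- if (definition == "any_unknown") any_unknown else both_unknown
  n_prog <- progeny_counts(ped)
  tab <- data.frame(id = sel,
                    sex = ped$sex[match(sel, ped$id)],
                    n_progeny = n_prog[match(sel, ped$id)],
                    stringsAsFactors = FALSE)
  used <- sum(tab$n_progeny > 0)
  structure(list(
    definition = definition,
    founders_any_unknown = any_unknown,
    founders_both_unknown = both_unknown,
    n_any_unknown = length(any_unknown),
    n_both_unknown = length(both_unknown),
    progeny = tab,
    founders_without_progeny = sum(tab$n_progeny == 0),
    breeding_use = if (nrow(tab)) used / nrow(tab) else NA_real_
  ), class = "founder_report")
}

progeny_counts <- function(ped) {
  cnt <- table(factor(c(ped$sire, ped$dam), levels = ped$id))
  as.integer(cnt)
}

#' Pedigree completeness metrics
#'
#' For each animal: `max_gen`, the longest chain of known ancestors;
#' `complete_gen`, the deepest generation at which all ancestors are
#' known; and `t`, the equivalent complete generations, the sum of
#' (1/2)^g over all known-ancestor occurrences.  An animal with both
#' parents unknown scores (0, 0, 0).
#'
#' @param ped a [pedigree].
#' @return A `completeness_report`: per-animal data frame plus the
#'   population means `mean_max_gen`, `mean_complete_gen`, `mean_t`.
#' @export
completeness <- function(ped) {
  n <- nrow(ped)
  pi <- parent_indices(ped)
  max_gen <- integer(n); complete_gen <- integer(n); t <- numeric(n)
  for (i in seq_len(n)) {    # topological order: parents already done
    s <- pi$sire[i]; d <- pi$dam[i]
    mg_s <- if (is.na(s)) -1L else max_gen[s]
    mg_d <- if (is.na(d)) -1L else max_gen[d]
    max_gen[i] <- max(mg_s, mg_d) + 1L
    complete_gen[i] <- if (is.na(s) || is.na(d)) 0L else
      1L + min(complete_gen[s], complete_gen[d])
    t[i] <- 0.5 * ((if (is.na(s)) 0 else 1 + t[s]) +
                   (if (is.na(d)) 0 else 1 + t[d]))
  }
  per <- data.frame(id = ped$id, max_gen = max_gen,
                    complete_gen = complete_gen, t = t,
                    stringsAsFactors = FALSE)
  structure(list(per_individual = per,
                 mean_max_gen = mean(max_gen),
                 mean_complete_gen = mean(complete_gen),
                 mean_t = mean(t)),
            class = "completeness_report")
}

#' Generation interval
#'
#' Mean age of parents at the birth of their offspring, in years, over
#' all (parent, offspring) pairs with both birth years recorded.
#'
#' @param ped a [pedigree].
#' @return List with `mean`, `se` (0 with an `n = 1` flag when only one
#'   pair exists), `n_pairs` and `n_skipped` (pairs lacking a year).
#' @export
generation_interval <- function(ped) {
  pi <- parent_indices(ped)
  ages <- c(ped$birth_year - ped$birth_year[pi$sire],
            ped$birth_year - ped$birth_year[pi$dam])
  linked <- c(!is.na(pi$sire), !is.na(pi$dam))
  usable <- linked & !is.na(ages)
  if (!any(usable)) stop("no dated parent-offspring pairs", call. = FALSE)
  a <- ages[usable]
  list(mean = mean(a),
       se = if (length(a) > 1) stats::sd(a) / sqrt(length(a)) else 0,
       n_pairs = length(a),
       n_skipped = sum(linked) - length(a))
}

#' Classify close matings
#'
#' Each animal with two known parents is classified by the relation of
#' its parental pair: parent-offspring (one parent is the other's
#' parent), full-sib (the parents share both known parents), or half-sib
#' (exactly one shared known parent).  Parent-offspring is checked first,
#' then full-sib, then half-sib, so the classes are disjoint.
#' Percentages use the total number of records as denominator, the
#' studbook-report convention.
#'
#' @param ped a [pedigree].
#' @return A `mating_report`: per-class offspring counts and percentages,
#'   plus the per-animal classification.
#' @export
classify_matings <- function(ped) {
  pi <- parent_indices(ped)
  n <- nrow(ped)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    if (is.na(s) || is.na(d)) next
    po <- identical(ped$id[s], ped$sire[d]) || identical(ped$id[s], ped$dam[d]) ||
          identical(ped$id[d], ped$sire[s]) || identical(ped$id[d], ped$dam[s])
    if (po) { cls[i] <- "parent_offspring"; next }
    shared <- sum(c(!is.na(ped$sire[s]) && identical(ped$sire[s], ped$sire[d]),
                    !is.na(ped$dam[s])  && identical(ped$dam[s],  ped$dam[d])))
    cls[i] <- if (shared == 2) "full_sib"
      else if (shared == 1 ||
               (!is.na(ped$sire[s]) && identical(ped$sire[s], ped$dam[d])) ||
               (!is.na(ped$dam[s])  && identical(ped$dam[s],  ped$sire[d])))
        "half_sib" else "outbred_pair"
  }
  counts <- vapply(c("full_sib", "half_sib", "parent_offspring"),
                   function(k) sum(cls == k, na.rm = TRUE), integer(1))
  structure(list(counts = counts,
                 percent = 100 * counts / n,
                 denominator = n,
                 classification = data.frame(id = ped$id, class = cls,
                                             stringsAsFactors = FALSE)),
            class = "mating_report")
}

#' Full-sib group and litter statistics
#'
#' Full-sib groups share sire and dam; litters additionally share the
#' birth year.  Summary statistics follow the studbook convention of
#' restricting to groups of size >= 2; singletons are counted separately.
#'
#' @param ped a [pedigree].
#' @return A `litter_report` with group/litter size vectors, min, max and
#'   mean (over groups of size >= 2), the number of such groups and the
#'   total number of animals in them.
#' @export
litter_statistics <- function(ped) {
  known <- !is.na(ped$sire) & !is.na(ped$dam)
  grp <- paste(ped$sire, ped$dam)[known]
  lit <- paste(ped$sire, ped$dam, ped$birth_year)[known]
  gsz <- as.integer(table(grp))
  lsz <- as.integer(table(lit))
  summ <- function(x) {
    x2 <- x[x >= 2]
    list(sizes = x, n_groups = length(x2), n_singletons = sum(x == 1),
         n_individuals = sum(x2),
         min = if (length(x2)) min(x2) else NA_integer_,
         max = if (length(x2)) max(x2) else NA_integer_,
         mean = if (length(x2)) mean(x2) else NA_real_)
  }
  structure(list(full_sib_groups = summ(gsz), litters = summ(lsz)),
            class = "litter_report")
}

#' Breeder and progeny statistics
#'
#' Counts of animals with and without progeny, by sex and by founder
#' status, with total progeny per class.  An independent check on the
#' generator's realized breeding use.
#'
#' @param ped a [pedigree].
#' @param founder_report optionally a precomputed [identify_founders()]
#'   result.
#' @return A data frame with one row per (founder status, sex) cell:
#'   breeders, non-breeders and total progeny.
#' @export
progeny_statistics <- function(ped, founder_report = identify_founders(ped)) {
  n_prog <- progeny_counts(ped)
  is_f <- ped$id %in% founder_report$founders_any_unknown
  cells <- expand.grid(founder = c(TRUE, FALSE), sex = c("M", "F", "U"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    sel <- is_f == cells$founder[r] & ped$sex == cells$sex[r]
    data.frame(founder = cells$founder[r], sex = cells$sex[r],
               n = sum(sel),
               breeders = sum(sel & n_prog > 0),
               non_breeders = sum(sel & n_prog == 0),
               total_progeny = sum(n_prog[sel]))
  })
  out <- do.call(rbind, rows)
  out[out$n > 0, , drop = FALSE]
}
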