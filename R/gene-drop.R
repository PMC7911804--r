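# Monte-Carlo gene drop: founder alleles are uniquely labeled and
# transmitted down the pedigree to measure founder-allele retention and
# founder genome surviving (FGS).

#' Gene-drop simulation of founder-allele retention
#'
#' Each replicate labels the founder genome uniquely and drops it down
#' the pedigree: an animal with both parents unknown carries its own two
#' unique allele labels; every unknown parent slot of a partially known
#' record is a phantom founder with its own two labels, of which the
#' record inherits one uniformly at random; every known-parent side
#' transmits one of the parent's two alleles uniformly at random.
#' Retention of founder f, `r_f`, is the expected fraction of f's two
#' alleles present in the scoring cohort; founder genome surviving is
#' `FGS = sum(r_f)` over the scored founders.
#'
#' @param ped a [pedigree].
#' @param cohort ids in which survival is scored (default: all animals).
#' @param reps number of Monte-Carlo replicates.
#' @param seed integer seed; results are deterministic given the seed.
#' @param named_founders_only if TRUE, phantom founders still transmit
#'   genome but are excluded from retention scoring and FGS, so FGS
#'   accounts only for records with both parents unknown.  Default FALSE
#'   (phantoms participate, flagged in the output).
#' @return A `gene_drop_result`: `retention` (per-founder r_f, named;
#'   phantoms named `<id>.ps` / `<id>.pd` for the sire/dam slot),
#'   `is_phantom`, `fgs`, `fgs_se` (Monte-Carlo standard error of FGS),
#'   `surviving_counts` (per-replicate surviving allele counts),
#'   `reps`, `seed`.
#' @export
#' @examples
#' trio <- pedigree(data.frame(id = c("A", "B", "C"),
#'                             sire = c(NA, NA, "A"),
#'                             dam  = c(NA, NA, "B")))
#' run_gene_drop(trio, cohort = "C", reps = 200, seed = 1)$retention
run_gene_drop <- function(ped, cohort = ped$id, reps = 10000, seed = 1,
                          named_founders_only = FALSE) {
  if (reps < 1) stop("replicate count must be >= 1", call. = FALSE)
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  miss <- setdiff(cohort, ped$id)
  if (length(miss)) stop("cohort id not in pedigree: ", miss[1], call. = FALSE)

  n <- nrow(ped)
  pi <- parent_indices(ped)
  both_unknown <- is.na(pi$sire) & is.na(pi$dam)

  # founder entities, each owning one label pair (2f-1, 2f)
  founder_ids <- character(0); is_phantom <- logical(0)
  own_pair  <- rep(NA_integer_, n)            # both-unknown record's pair
  slot_pair <- matrix(NA_integer_, n, 2)      # phantom pair feeding a slot
  for (i in seq_len(n)) {
    if (both_unknown[i]) {
      founder_ids <- c(founder_ids, ped$id[i]); is_phantom <- c(is_phantom, FALSE)
      own_pair[i] <- length(founder_ids)
    } else {
      if (is.na(pi$sire[i])) {
        founder_ids <- c(founder_ids, paste0(ped$id[i], ".ps"))
        is_phantom <- c(is_phantom, TRUE)
        slot_pair[i, 1] <- length(founder_ids)
      }
      if (is.na(pi$dam[i])) {
        founder_ids <- c(founder_ids, paste0(ped$id[i], ".pd"))
        is_phantom <- c(is_phantom, TRUE)
        slot_pair[i, 2] <- length(founder_ids)
      }
    }
  }
  nf <- length(founder_ids)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  cohort_idx <- match(cohort, ped$id)
  pres <- matrix(0L, reps, nf)
  batch <- 2000L
  done <- 0L
  while (done < reps) {
    R <- min(batch, reps - done)
    A1 <- matrix(0L, R, n); A2 <- matrix(0L, R, n)
    for (i in seq_len(n)) {
      if (both_unknown[i]) {
        p <- own_pair[i]
        A1[, i] <- 2L * p - 1L
        A2[, i] <- 2L * p
        next
      }
      s <- pi$sire[i]
      A1[, i] <- if (is.na(s)) {
        p <- slot_pair[i, 1]
        ifelse(stats::runif(R) < 0.5, 2L * p - 1L, 2L * p)
      } else ifelse(stats::runif(R) < 0.5, A1[, s], A2[, s])
      d <- pi$dam[i]
      A2[, i] <- if (is.na(d)) {
        p <- slot_pair[i, 2]
        ifelse(stats::runif(R) < 0.5, 2L * p - 1L, 2L * p)
      } else ifelse(stats::runif(R) < 0.5, A1[, d], A2[, d])
    }
    for (r in seq_len(R)) {
      labs <- unique(c(A1[r, cohort_idx], A2[r, cohort_idx]))
      pres[done + r, ] <- tabulate((labs + 1L) %/% 2L, nbins = nf)
    }
    done <- done + R
  }

  scored <- if (named_founders_only) which(!is_phantom) else seq_len(nf)
  retention <- colMeans(pres[, scored, drop = FALSE]) / 2
  names(retention) <- founder_ids[scored]
  fgs_r <- rowSums(pres[, scored, drop = FALSE]) / 2
  structure(list(retention = retention,
                 is_phantom = is_phantom[scored],
                 fgs = mean(fgs_r),
                 fgs_se = if (reps > 1) stats::sd(fgs_r) / sqrt(reps) else 0,
                 surviving_counts = rowSums(pres[, scored, drop = FALSE]),
                 reps = reps, seed = seed,
                 n_founders = length(scored)),
            class = "gene_drop_result")
}

#' Distribution of surviving founder-allele counts
#'
#' Histogram of the per-replicate number of surviving founder alleles, a
#' convergence diagnostic for FGS.
#'
#' @param result a [run_gene_drop()] result.
#' @return Data frame `surviving`, `n_replicates`, `proportion`.
#' @export
allele_retention_curve <- function(result) {
  tab <- table(result$surviving_counts)
  data.frame(surviving = as.integer(names(tab)),
             n_replicates = as.integer(tab),
             proportion = as.numeric(tab) / result$reps)
}
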