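# Exact test of Hardy-Weinberg proportions conditional on allele counts:
# exhaustive enumeration of the fiber for small problems, Markov chain
# Monte Carlo with batch standard errors otherwise.

#' Genotype counts at a locus
#'
#' The sufficient statistics of the exact HWE test: a symmetric k x k
#' matrix of genotype counts (stored in the upper triangle, `[a, b]`
#' with a <= b in allele order) and the derived allele counts.
#'
#' @param g a [genotype_table()].
#' @param locus locus name.
#' @return A `genotype_counts` list: `counts` (k x k, upper triangle),
#'   `alleles` (bp sizes), `m` (allele counts), `n` (individuals).
#' @export
genotype_counts <- function(g, locus) {
  j <- match(locus, g$loci)
  if (is.na(j)) stop("unknown locus: ", locus, call. = FALSE)
  typed <- !is.na(g$a1[, j])
  a1 <- g$a1[typed, j]; a2 <- g$a2[typed, j]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  cnt <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  for (r in seq_along(lo)) cnt[lo[r], hi[r]] <- cnt[lo[r], hi[r]] + 1L
  m <- as.integer(2 * diag(cnt) + (rowSums(cnt) + colSums(cnt) - 2 * diag(cnt)))
  structure(list(counts = cnt, alleles = alleles, m = m, n = length(a1)),
            class = "genotype_counts")
}

make_genotype_counts <- function(cnt) {
  cnt <- as.matrix(cnt)
  k <- nrow(cnt)
  cnt[lower.tri(cnt)] <- 0L
  storage.mode(cnt) <- "integer"
  m <- as.integer(2 * diag(cnt) + (rowSums(cnt) + colSums(cnt) - 2 * diag(cnt)))
  al <- if (!is.null(rownames(cnt))) as.integer(rownames(cnt)) else seq_len(k)
  structure(list(counts = cnt, alleles = al, m = m, n = sum(cnt)),
            class = "genotype_counts")
}

#' Conditional probability of a genotype array under HWE
#'
#' Probability of the observed genotype counts given the allele counts,
#' under Hardy-Weinberg proportions:
#' `P = n! 2^h prod(m_a!) / ((2n)! prod(n_ab!))`, where h is the number
#' of heterozygous individuals.  Probabilities over all arrays sharing
#' the allele counts sum to 1.
#'
#' @param counts a [genotype_counts()].
#' @param log return the log probability.
#' @return Probability in (0, 1] (or its log).
#' @export
conditional_probability <- function(counts, log = FALSE) {
  cnt <- counts$counts
  h <- sum(cnt[upper.tri(cnt)])
  lp <- lgamma(counts$n + 1) + h * log(2) + sum(lgamma(counts$m + 1)) -
    lgamma(2 * counts$n + 1) - sum(lgamma(cnt[upper.tri(cnt, diag = TRUE)] + 1))
  if (log) lp else exp(lp)
}

# enumerate all genotype-count arrays with the given allele counts,
# calling fn(cnt) for each; returns number of states visited.
enumerate_fiber <- function(m, fn, max_states = 5e6) {
  k <- length(m)
  cnt <- matrix(0L, k, k)
  states <- 0L
  rec_allele <- function(a, rem) {
    if (a > k) {
      states <<- states + 1L
      if (states > max_states)
        stop("fiber exceeds enumeration bound; use the MCMC test",
             call. = FALSE)
      fn(cnt)
      return(invisible())
    }
    # allocate allele a's remaining count rem[a] among (a,a) and (a,b), b>a
    for (naa in 0:(rem[a] %/% 2L)) {
      cnt[a, a] <<- naa
      left <- rem[a] - 2L * naa
      if (a == k) {
        if (left == 0L) rec_allele(a + 1L, rem)
      } else {
        distribute(a, a + 1L, left, rem)
      }
    }
    invisible()
  }
  distribute <- function(a, b, left, rem) {
    if (b > k) { if (left == 0L) rec_allele(a + 1L, rem); return(invisible()) }
    hi <- min(left, rem[b])
    lo <- if (b == k) left else 0L
    if (lo > hi) return(invisible())
    for (x in lo:hi) {
      cnt[a, b] <<- x
      rem[b] <- rem[b] - x
      distribute(a, b + 1L, left - x, rem)
      rem[b] <- rem[b] + x
    }
    invisible()
  }
  rec_allele(1L, m)
  states
}

#' Exhaustive exact HWE test
#'
#' Enumerates every genotype array compatible with the observed allele
#' counts and sums the conditional probabilities of arrays no more
#' probable than the observed one (ties included in the tail, the
#' standard exact-test convention).  The oracle against which the MCMC
#' test is validated.
#'
#' @param counts a [genotype_counts()].
#' @param max_states refuse fibers larger than this (default 5e6).
#' @return An `hwe_result`: `p`, `se = 0`, `method = "exhaustive"`,
#'   `n_states`, and `total` (the fiber's probability sum, ~1).
#' @export
hwe_exhaustive <- function(counts, max_states = 5e6) {
  lp_obs <- conditional_probability(counts, log = TRUE)
  acc <- 0; tot <- 0
  n <- counts$n
  lconst <- lgamma(n + 1) + sum(lgamma(counts$m + 1)) - lgamma(2 * n + 1)
  states <- enumerate_fiber(counts$m, function(cnt) {
    h <- sum(cnt[upper.tri(cnt)])
    lp <- lconst + h * log(2) - sum(lgamma(cnt[upper.tri(cnt, diag = TRUE)] + 1))
    pr <- exp(lp)
    tot <<- tot + pr
    if (lp <= lp_obs + 1e-9) acc <<- acc + pr
  }, max_states = max_states)
  structure(list(p = min(acc, 1), se = 0, method = "exhaustive",
                 n_states = states, total = tot),
            class = "hwe_result")
}

#' MCMC exact HWE test
#'
#' Samples genotype arrays from the conditional distribution given the
#' allele counts with a Markov chain and reports the fraction with
#' conditional probability no greater than the observed array's.  The
#' chain operates on the underlying pairing of the 2n alleles, where the
#' stationary law is uniform, so every genotype-switch proposal (swap
#' one member between two random pairs) is accepted; the induced walk on
#' genotype arrays is the standard switch chain with its exact
#' Hastings ratio.  The p-value's standard error comes from the
#' between-batch variance.
#'
#' @param counts a [genotype_counts()].
#' @param batches number of batches (>= 2).
#' @param dememorization burn-in switches before sampling.
#' @param iters_per_batch sampled switches per batch.
#' @param seed integer seed; the chain is deterministic given the seed.
#' @return An `hwe_result`: `p`, `se`, `method = "mcmc"`, and the chain
#'   settings.
#' @export
hwe_mcmc <- function(counts, batches = 100, dememorization = 10000,
                     iters_per_batch = 5000, seed = 1) {
  if (batches < 2) stop("need at least 2 batches", call. = FALSE)
  if (dememorization < 0) stop("negative dememorization", call. = FALSE)
  k <- length(counts$m)
  if (k == 1 || counts$n < 2)
    return(structure(list(p = 1, se = 0, method = "mcmc",
                          batches = batches, dememorization = dememorization,
                          iters_per_batch = iters_per_batch, seed = seed),
                     class = "hwe_result"))
  batch_p <- hwe_mcmc_chain(counts$counts, as.integer(batches),
                            as.integer(dememorization),
                            as.integer(iters_per_batch),
                            as.integer(seed) %% .Machine$integer.max)
  structure(list(p = mean(batch_p),
                 se = stats::sd(batch_p) / sqrt(batches),
                 method = "mcmc", batches = batches,
                 dememorization = dememorization,
                 iters_per_batch = iters_per_batch, seed = seed),
            class = "hwe_result")
}

#' Exact HWE test, automatic method choice
#'
#' Uses exhaustive enumeration when the fiber is small enough, the MCMC
#' chain otherwise.
#'
#' @inheritParams hwe_mcmc
#' @param exhaustive_limit largest fiber enumerated exhaustively.
#' @return An `hwe_result`.
#' @export
hwe_test <- function(counts, batches = 100, dememorization = 10000,
                     iters_per_batch = 5000, seed = 1,
                     exhaustive_limit = 2e4) {
  est <- fiber_size_bound(counts$m)
  if (est <= exhaustive_limit)
    tryCatch(hwe_exhaustive(counts, max_states = exhaustive_limit),
             error = function(e)
               hwe_mcmc(counts, batches, dememorization, iters_per_batch, seed))
  else hwe_mcmc(counts, batches, dememorization, iters_per_batch, seed)
}

# crude upper bound on fiber size: product over cells of (n+1) capped
fiber_size_bound <- function(m) {
  k <- length(m)
  n <- sum(m) / 2
  ncells <- k * (k + 1) / 2
  # arrays are nonneg integer matrices with fixed margins; bound by
  # compositions of n into ncells parts
  choose(n + ncells - 1, ncells - 1)
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE exact test (%s): p = %.4g (SE %.2g)\n",
              x$method, x$p, x$se))
  invisible(x)
}
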