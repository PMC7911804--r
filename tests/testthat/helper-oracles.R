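# Independent oracles used to validate the package's implementations.
# These deliberately use different algorithms from the code under test.

# ---- Wright path-counting coancestry -------------------------------------
# f(i, j) = sum over common ancestors A and over pairs of ancestor paths
# (i -> A, j -> A) sharing no animal but A, of (1/2)^(l1 + l2 + 1) (1 + F_A).
# Paths are stored as bitmasks split into two 25-bit words (pedigrees up to
# 50 animals).  F_A itself is computed by the same path method in
# topological order, so the oracle never touches the tabular recursion.

oracle_paths <- function(si, di, n) {
  # for each animal: data frame of ancestor paths (top, len, lo, hi)
  paths <- vector("list", n)
  bit <- function(i) {
    w <- (i - 1) %/% 25L
    b <- (i - 1) %% 25L
    if (w == 0) c(bitwShiftL(1L, b), 0L) else c(0L, bitwShiftL(1L, b))
  }
  for (i in seq_len(n)) {
    b <- bit(i)
    own <- data.frame(top = i, len = 0L, lo = b[1], hi = b[2])
    ext <- list(own)
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        pp <- paths[[p]]
        ext[[length(ext) + 1]] <- data.frame(
          top = pp$top, len = pp$len + 1L,
          lo = bitwOr(pp$lo, b[1]), hi = bitwOr(pp$hi, b[2]))
      }
    }
    paths[[i]] <- do.call(rbind, ext)
  }
  paths
}

oracle_pair_f <- function(paths, Fvec, i, j) {
  pi <- paths[[i]]; pj <- paths[[j]]
  tops <- intersect(pi$top, pj$top)
  if (!length(tops)) return(0)
  total <- 0
  for (A in tops) {
    w <- (A - 1) %/% 25L; b <- (A - 1) %% 25L
    Abit <- bitwShiftL(1L, b)
    ai <- pi[pi$top == A, ]; aj <- pj[pj$top == A, ]
    shared_lo <- outer(ai$lo, aj$lo, bitwAnd)
    shared_hi <- outer(ai$hi, aj$hi, bitwAnd)
    ok <- if (w == 0) shared_lo == Abit & shared_hi == 0L
          else shared_lo == 0L & shared_hi == Abit
    wt <- outer(0.5^ai$len, 0.5^aj$len)
    total <- total + 0.5 * (1 + Fvec[A]) * sum(wt[ok])
  }
  total
}

# full coancestry matrix by path counting (ped must be a pedvar pedigree,
# already topologically sorted)
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  stopifnot(n <= 50)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  paths <- oracle_paths(si, di, n)
  Fvec <- numeric(n)
  for (i in seq_len(n)) {
    Fvec[i] <- if (is.na(si[i]) || is.na(di[i])) 0
      else oracle_pair_f(paths, Fvec, si[i], di[i])
  }
  f <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    f[i, i] <- 0.5 * (1 + Fvec[i])
    if (i > 1) for (j in seq_len(i - 1)) {
      f[i, j] <- f[j, i] <- oracle_pair_f(paths, Fvec, i, j)
    }
  }
  f
}

# ---- random pedigree for oracle equivalence ------------------------------
random_test_pedigree <- function(n, seed, p_unknown = 0.25) {
  set.seed(seed)
  id <- sprintf("X%02d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males) && runif(1) > p_unknown)
      sire[i] <- id[males[sample.int(length(males), 1)]]
    if (length(females) && runif(1) > p_unknown)
      dam[i] <- id[females[sample.int(length(females), 1)]]
  }
  pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                      stringsAsFactors = FALSE))
}

# ---- two-allele exact HWE (Levene) ---------------------------------------
# closed-form distribution over the heterozygote count h given allele
# counts (ma, mb): P(h) = n! ma! mb! 2^h / ((2n)! naa! h! nbb!).
levene_two_allele_p <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  ma <- 2 * naa + nab; mb <- 2 * nbb + nab
  hs <- seq(ma %% 2, min(ma, mb), by = 2)
  lp <- vapply(hs, function(h) {
    a <- (ma - h) / 2; b <- (mb - h) / 2
    lgamma(n + 1) + lgamma(ma + 1) + lgamma(mb + 1) + h * log(2) -
      lgamma(2 * n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1)
  }, numeric(1))
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[match(nab, hs)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# ---- misc ----------------------------------------------------------------
# genotype_counts straight from a pair of allele vectors
counts_from_alleles <- function(a, b) {
  g <- genotype_table(sprintf("i%d", seq_along(a)), "L",
                      matrix(a, ncol = 1), matrix(b, ncol = 1))
  genotype_counts(g, "L")
}

# simulate one locus of n HWE genotypes at given frequencies
simulate_hwe_locus <- function(p, n) {
  sizes <- as.integer(names(p))
  a <- sample(sizes, n, replace = TRUE, prob = p)
  b <- sample(sizes, n, replace = TRUE, prob = p)
  counts_from_alleles(a, b)
}
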