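# Per-locus STR diversity statistics: PIC, observed/expected
# heterozygosity, FIS, and the panel summary table.

check_freqs <- function(p, renormalize = TRUE) {
  if (any(p < 0)) stop("negative allele frequency", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-6) {
    if (!renormalize)
      stop("allele frequencies sum to ", format(s), ", not 1", call. = FALSE)
    warning("allele frequencies sum to ", format(s), "; renormalizing",
            call. = FALSE)
  }
  p / s
}

#' Polymorphic information content
#'
#' Botstein's marker-informativeness measure:
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.  Always <= expected
#' heterozygosity.  Frequency vectors that do not sum to 1 beyond 1e-6
#' (e.g. published tables rounded to 3 decimals) are renormalized with a
#' warning.
#'
#' @param p allele frequency vector.
#' @return PIC in [0, 1).
#' @export
#' @examples
#' pic(c(0.5, 0.5))   # 0.375
pic <- function(p) {
  p <- check_freqs(p)
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Expected heterozygosity from allele frequencies
#'
#' Plain (Hardy-Weinberg) expected heterozygosity `He = 1 - sum(p^2)`;
#' the small-sample unbiased variant multiplies by `2n / (2n - 1)`.
#'
#' @param p allele frequency vector.
#' @param n number of typed individuals (needed for `"unbiased"`).
#' @param estimator `"plain"` (default) or `"unbiased"`.
#' @return He in [0, 1).
#' @export
expected_heterozygosity <- function(p, n = NULL,
                                    estimator = c("plain", "unbiased")) {
  estimator <- match.arg(estimator)
  p <- check_freqs(p)
  he <- 1 - sum(p^2)
  if (estimator == "unbiased") {
    if (is.null(n)) stop("unbiased He needs the sample size n", call. = FALSE)
    he <- he * 2 * n / (2 * n - 1)
  }
  he
}

#' Observed and expected heterozygosity at a locus
#'
#' `Ho` is the heterozygote fraction among typed individuals; `He` comes
#' from [expected_heterozygosity()] on the sample allele frequencies.
#'
#' @param g a [genotype_table()].
#' @param locus locus name.
#' @param estimator He estimator, `"plain"` or `"unbiased"`.
#' @return List `ho`, `he`, `n`.
#' @export
heterozygosity <- function(g, locus, estimator = c("plain", "unbiased")) {
  estimator <- match.arg(estimator)
  j <- match(locus, g$loci)
  if (is.na(j)) stop("unknown locus: ", locus, call. = FALSE)
  typed <- !is.na(g$a1[, j])
  if (!any(typed)) stop("no typed genotypes at locus ", locus, call. = FALSE)
  ho <- mean(g$a1[typed, j] != g$a2[typed, j])
  fr <- allele_frequencies(g, locus)
  list(ho = ho,
       he = expected_heterozygosity(fr$p, n = fr$n, estimator = estimator),
       n = fr$n)
}

#' Within-population fixation index
#'
#' `FIS = 1 - Ho / He`: negative values indicate heterozygote excess.
#' Undefined (NA, with a warning) when He = 0.
#'
#' @param ho observed heterozygosity.
#' @param he expected heterozygosity.
#' @return FIS in (-Inf, 1], or NA when He = 0.
#' @export
fis <- function(ho, he) {
  if (he == 0) {
    warning("FIS undefined at a monomorphic locus (He = 0)", call. = FALSE)
    return(NA_real_)
  }
  1 - ho / he
}

#' Per-locus summary row
#'
#' Allele count, frequencies, PIC, Ho, He, FIS and (optionally) the
#' exact Hardy-Weinberg test p-value with its Monte-Carlo standard
#' error.
#'
#' @param g a [genotype_table()].
#' @param locus locus name.
#' @param estimator He estimator.
#' @param hwe run the HWE test (default TRUE).
#' @param hwe_control list of [hwe_mcmc()] settings: `batches`,
#'   `dememorization`, `iters_per_batch`, `seed`, `exhaustive_limit`.
#' @return A `locus_summary` list.
#' @export
locus_summary <- function(g, locus, estimator = c("plain", "unbiased"),
                          hwe = TRUE, hwe_control = list()) {
  estimator <- match.arg(estimator)
  fr <- allele_frequencies(g, locus)
  h <- heterozygosity(g, locus, estimator)
  out <- list(locus = locus, k = length(fr$p), p = fr$p, n = fr$n,
              pic = pic(fr$p), ho = h$ho, he = h$he,
              fis = fis(h$ho, h$he),
              hwe_p = NA_real_, hwe_se = NA_real_, hwe_method = NA_character_)
  if (hwe) {
    hw <- do.call(hwe_test, c(list(counts = genotype_counts(g, locus)),
                              hwe_control))
    out$hwe_p <- hw$p; out$hwe_se <- hw$se; out$hwe_method <- hw$method
  }
  structure(out, class = "locus_summary")
}

#' Multi-locus panel summary
#'
#' Per-locus rows plus unweighted arithmetic means of PIC, Ho, He and
#' FIS across loci and the total allele count — the shape of a published
#' STR-panel characterization table.
#'
#' @inheritParams locus_summary
#' @param loci loci to include (default: all in `g`).
#' @return A `panel_summary`: data frame `per_locus` (locus, k, n, pic,
#'   ho, he, fis, hwe_p, hwe_se), `means`, and `total_alleles`.
#' @export
panel_summary <- function(g, loci = g$loci, estimator = c("plain", "unbiased"),
                          hwe = TRUE, hwe_control = list()) {
  estimator <- match.arg(estimator)
  rows <- lapply(loci, function(L) {
    s <- locus_summary(g, L, estimator, hwe, hwe_control)
    data.frame(locus = L, k = s$k, n = s$n, pic = s$pic, ho = s$ho,
               he = s$he, fis = s$fis, hwe_p = s$hwe_p, hwe_se = s$hwe_se,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  structure(list(
    per_locus = per_locus,
    means = c(pic = mean(per_locus$pic), ho = mean(per_locus$ho),
              he = mean(per_locus$he), fis = mean(per_locus$fis)),
    total_alleles = sum(per_locus$k)
  ), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  df <- x$per_locus
  df[c("pic", "ho", "he", "fis")] <- lapply(df[c("pic", "ho", "he", "fis")],
                                            round, 3)
  print(df, row.names = FALSE)
  cat(sprintf("means: PIC %.3f  Ho %.3f  He %.3f  FIS %.3f;  %d alleles total\n",
              x$means["pic"], x$means["ho"], x$means["he"], x$means["fis"],
              x$total_alleles))
  invisible(x)
}
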