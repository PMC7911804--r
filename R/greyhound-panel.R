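# Reference allele-frequency sets for the 21-marker ISAG canine STR
# parentage panel, as observed in a sample of 174 Polish Greyhounds.
# Frequencies are printed to 3 decimals, so a few loci sum to 0.999-1.008;
# downstream code renormalizes.

.panel <- list(
  AHTk211   = c(`87` = 0.057, `89` = 0.445, `91` = 0.477, `95` = 0.020),
  CXX279    = c(`116` = 0.178, `118` = 0.431, `120` = 0.037, `124` = 0.055,
                `126` = 0.193, `130` = 0.106),
  REN169O18 = c(`158` = 0.009, `162` = 0.233, `164` = 0.293, `166` = 0.032,
                `168` = 0.040, `170` = 0.394),
  INU055    = c(`200` = 0.009, `210` = 0.718, `212` = 0.017, `214` = 0.014,
                `216` = 0.129, `218` = 0.092, `220` = 0.020),
  REN54P11  = c(`226` = 0.239, `228` = 0.052, `232` = 0.250, `234` = 0.026,
                `236` = 0.402, `238` = 0.032),
  INRA21    = c(`95` = 0.578, `97` = 0.017, `101` = 0.124, `103` = 0.282),
  AHT137    = c(`131` = 0.580, `133` = 0.221, `137` = 0.035, `143` = 0.023,
                `147` = 0.098, `153` = 0.043),
  REN169D01 = c(`202` = 0.328, `210` = 0.184, `212` = 0.014, `216` = 0.348,
                `218` = 0.052, `222` = 0.075),
  AHTh260   = c(`240` = 0.023, `244` = 0.072, `246` = 0.175, `248` = 0.351,
                `252` = 0.313, `254` = 0.066),
  AHTk253   = c(`286` = 0.011, `288` = 0.701, `290` = 0.121, `292` = 0.124,
                `294` = 0.034, `296` = 0.009),
  INU005    = c(`110` = 0.161, `122` = 0.011, `124` = 0.667, `126` = 0.029,
                `132` = 0.132),
  INU030    = c(`144` = 0.422, `148` = 0.009, `150` = 0.534, `152` = 0.034),
  FH2848    = c(`234` = 0.043, `236` = 0.029, `238` = 0.253, `240` = 0.279,
                `244` = 0.397),
  AHT121    = c(`94` = 0.167, `96` = 0.103, `98` = 0.029, `100` = 0.267,
                `104` = 0.112, `106` = 0.322),
  FH2054    = c(`152` = 0.029, `156` = 0.305, `160` = 0.210, `164` = 0.181,
                `168` = 0.264, `172` = 0.011),
  REN162C04 = c(`196` = 0.101, `202` = 0.242, `204` = 0.256, `206` = 0.359,
                `208` = 0.043),
  AHT171    = c(`217` = 0.342, `219` = 0.164, `221` = 0.109, `223` = 0.034,
                `225` = 0.259, `227` = 0.026, `229` = 0.011, `233` = 0.055),
  REN247M23 = c(`266` = 0.247, `268` = 0.632, `270` = 0.046, `278` = 0.075),
  REN64E19  = c(`139` = 0.170, `141` = 0.158, `145` = 0.158, `147` = 0.221,
                `149` = 0.006, `151` = 0.014, `155` = 0.273),
  AHTh130   = c(`121` = 0.091, `125` = 0.032, `127` = 0.773, `131` = 0.112),
  REN115LO3 = c(`227` = 0.187, `229` = 0.092, `233` = 0.322, `235` = 0.356,
                `239` = 0.017, `241` = 0.026)
)

# Published per-locus summary statistics for the same sample (3 d.p.).
.panel_stats <- data.frame(
  locus = names(.panel),
  k     = vapply(.panel, length, integer(1)),
  pic = c(0.477, 0.695, 0.648, 0.430, 0.667, 0.514, 0.560, 0.684, 0.696,
          0.446, 0.474, 0.432, 0.651, 0.739, 0.719, 0.692, 0.741, 0.476,
          0.767, 0.361, 0.678),
  ho  = c(0.580, 0.764, 0.684, 0.483, 0.707, 0.540, 0.638, 0.753, 0.759,
          0.529, 0.477, 0.580, 0.701, 0.810, 0.707, 0.787, 0.816, 0.529,
          0.764, 0.374, 0.793),
  he  = c(0.570, 0.731, 0.702, 0.458, 0.715, 0.577, 0.602, 0.730, 0.738,
          0.477, 0.513, 0.535, 0.705, 0.773, 0.760, 0.737, 0.773, 0.532,
          0.798, 0.384, 0.725),
  fis = c(-0.018, -0.046, 0.026, -0.055, 0.011, 0.064, -0.059, -0.031,
          -0.027, -0.108, 0.070, -0.086, 0.006, -0.048, 0.070, -0.068,
          -0.056, 0.005, 0.042, 0.026, -0.094),
  row.names = NULL, stringsAsFactors = FALSE
)

#' Reference allele frequencies for the 21-marker canine STR panel
#'
#' Allele frequencies of the 21 ISAG-recommended canine parentage
#' microsatellites observed in a sample of 174 Polish Greyhounds, a small
#' closed studbook breed.  Alleles are fragment lengths in base pairs;
#' frequencies are reported to three decimals (a few loci therefore sum to
#' 0.999--1.008 and are renormalized by consumers).  These sets are the
#' default founder frequencies of [simulate_genotypes()].
#'
#' @param locus optional locus name; if given, the single named frequency
#'   vector is returned.
#' @return A named list of named numeric vectors (names = allele sizes in
#'   bp), or one such vector when `locus` is given.
#' @seealso [greyhound_marker_stats()] for the published per-locus summary
#'   statistics of the same sample.
#' @export
#' @examples
#' p <- greyhound_frequencies("AHTk211")
#' expected_heterozygosity(p)
greyhound_frequencies <- function(locus = NULL) {
  if (is.null(locus)) return(.panel)
  if (!locus %in% names(.panel))
    stop("unknown locus: ", locus, call. = FALSE)
  .panel[[locus]]
}

#' Published summary statistics of the reference STR panel
#'
#' Per-locus polymorphic information content (PIC), observed and expected
#' heterozygosity and FIS published for the 174-dog Polish Greyhound
#' sample behind [greyhound_frequencies()], to three decimals.  Used as a
#' cross-check surface: recomputing He and PIC from the frequency sets
#' reproduces these columns to within the rounding of the inputs
#' (about +/- 0.005).
#'
#' @return A data frame with columns `locus`, `k` (allele count), `pic`,
#'   `ho`, `he`, `fis`.
#' @export
greyhound_marker_stats <- function() .panel_stats
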