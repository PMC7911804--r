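Package: pedvar
Title: Pedigree and Microsatellite Assessment of Genetic Variability in
    Small Closed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing genetic variability in small, closed
    animal populations (studbook breeds) from two complementary sources:
    the pedigree and a microsatellite (STR) marker panel.  Pedigree-side
    statistics include individual inbreeding coefficients via the tabular
    kinship method, average relatedness, mean kinship, gene diversity,
    founder genome equivalents, founder genome surviving via Monte-Carlo
    gene-drop simulation, rate of inbreeding from equivalent complete
    generations, and realized effective population size.  Marker-side
    statistics include allele frequencies, polymorphic information
    content, observed and expected heterozygosity, the within-population
    fixation index FIS, and an exact test of Hardy-Weinberg equilibrium
    (exhaustive enumeration for small problems, Markov chain Monte Carlo
    with batch standard errors otherwise).  Seeded generators produce
    synthetic pedigrees and genotype tables with the structure these
    analyses assume, so the full pipeline is testable without restricted
    studbook data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
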