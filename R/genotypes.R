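# Diploid STR genotype table: individuals x loci, alleles as fragment
# lengths in bp, stored as two canonically sorted integer matrices
# (a1 <= a2), NA = missing.

#' Construct a genotype table
#'
#' @param ids individual identifiers.
#' @param loci locus names.
#' @param a1,a2 integer matrices (length(ids) x length(loci)) of allele
#'   sizes in bp; pairs are stored sorted so a1 <= a2; both NA = missing.
#' @return A `genotype_table`.
#' @export
genotype_table <- function(ids, loci, a1, a2) {
  a1 <- matrix(as.integer(a1), length(ids), length(loci))
  a2 <- matrix(as.integer(a2), length(ids), length(loci))
  if (any((is.na(a1) != is.na(a2))))
    stop("half-missing genotype (one allele NA)", call. = FALSE)
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele sizes must be positive integers", call. = FALSE)
  swap <- !is.na(a1) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = as.character(ids), loci = as.character(loci),
                 a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals x", length(x$loci),
      "loci;", sum(is.na(x$a1)), "missing genotypes\n")
  invisible(x)
}

#' Read STR genotypes
#'
#' Two formats: `"long"` CSV with header `id,locus,allele1,allele2`
#' (blank or 0 alleles = missing), and `"genepop"` (title line, one
#' locus name per line or a comma-separated line, `Pop`, then
#' `id , <6-digit codes>` with 3-digit alleles; `000000` = missing).
#'
#' @param path file path.
#' @param format `"long"` or `"genepop"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("long", "genepop")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "long") read_genotypes_long(path) else read_genepop(path)
}

read_genotypes_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("long genotype CSV needs columns id,locus,allele1,allele2",
         call. = FALSE)
  ids <- unique(as.character(df$id)); loci <- unique(as.character(df$locus))
  a1 <- a2 <- matrix(NA_integer_, length(ids), length(loci))
  i <- match(as.character(df$id), ids); j <- match(as.character(df$locus), loci)
  v1 <- suppressWarnings(as.integer(df$allele1))
  v2 <- suppressWarnings(as.integer(df$allele2))
  v1[!is.na(v1) & v1 == 0] <- NA_integer_
  v2[!is.na(v2) & v2 == 0] <- NA_integer_
  miss <- is.na(v1) | is.na(v2)
  v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
  a1[cbind(i, j)] <- v1; a2[cbind(i, j)] <- v2
  genotype_table(ids, loci, a1, a2)
}

read_genepop <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  if (length(lines) < 3) stop("not a GenePop file: ", path, call. = FALSE)
  pop_at <- which(toupper(lines) == "POP")
  if (!length(pop_at)) stop("GenePop file has no Pop line", call. = FALSE)
  loc_lines <- lines[2:(pop_at[1] - 1)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[loci != ""]
  body <- lines[(pop_at[1] + 1):length(lines)]
  body <- body[toupper(body) != "POP"]    # single population assumed
  ids <- character(length(body))
  a1 <- a2 <- matrix(NA_integer_, length(body), length(loci))
  for (r in seq_along(body)) {
    parts <- strsplit(body[r], ",")[[1]]
    if (length(parts) < 2)
      stop("GenePop record without 'id ,' separator at line: ", body[r],
           call. = FALSE)
    ids[r] <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("GenePop record for ", ids[r], " has ", length(codes),
           " genotypes for ", length(loci), " loci", call. = FALSE)
    if (any(nchar(codes) != 6))
      stop("GenePop genotypes must be 6-digit (3-digit alleles): ", ids[r],
           call. = FALSE)
    x1 <- as.integer(substr(codes, 1, 3)); x2 <- as.integer(substr(codes, 4, 6))
    x1[x1 == 0] <- NA_integer_; x2[x2 == 0] <- NA_integer_
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[r, ] <- x1; a2[r, ] <- x2
  }
  genotype_table(ids, loci, a1, a2)
}

#' Write STR genotypes
#'
#' @param g a [genotype_table()].
#' @param path output path.
#' @param format `"long"` or `"genepop"` (alleles must be < 1000 bp for
#'   the 3-digit GenePop coding).
#' @param title GenePop title line.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("long", "genepop"),
                            title = "pedvar genotypes") {
  format <- match.arg(format)
  if (format == "long") {
    rows <- expand.grid(i = seq_along(g$ids), j = seq_along(g$loci))
    df <- data.frame(id = g$ids[rows$i], locus = g$loci[rows$j],
                     allele1 = g$a1[cbind(rows$i, rows$j)],
                     allele2 = g$a2[cbind(rows$i, rows$j)])
    df$allele1[is.na(df$allele1)] <- 0L
    df$allele2[is.na(df$allele2)] <- 0L
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (any(g$a1 > 999, na.rm = TRUE))
      stop("alleles exceed 3-digit GenePop coding", call. = FALSE)
    code <- function(a) sprintf("%03d", ifelse(is.na(a), 0L, a))
    recs <- vapply(seq_along(g$ids), function(i) {
      paste0(g$ids[i], " , ",
             paste0(code(g$a1[i, ]), code(g$a2[i, ]), collapse = " "))
    }, character(1))
    writeLines(c(title, g$loci, "Pop", recs), path)
  }
  invisible(path)
}

#' Allele frequencies at a locus
#'
#' `p_a` = count of allele a among typed genotypes / (2 n_L); missing
#' genotypes are excluded from `n_L`.
#'
#' @param g a [genotype_table()].
#' @param locus locus name.
#' @return List `p` (named frequency vector, names = allele bp) and `n`
#'   (typed individuals).
#' @export
allele_frequencies <- function(g, locus) {
  j <- match(locus, g$loci)
  if (is.na(j)) stop("unknown locus: ", locus, call. = FALSE)
  a <- c(g$a1[, j], g$a2[, j])
  a <- a[!is.na(a)]
  if (!length(a)) stop("no typed genotypes at locus ", locus, call. = FALSE)
  tab <- table(a)
  p <- as.numeric(tab) / length(a)
  names(p) <- names(tab)
  list(p = p, n = length(a) / 2)
}
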