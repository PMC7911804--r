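# Pedigree container: a data frame (id, sire, dam, sex, birth_year, status)
# sorted so parents precede offspring.  Unknown parents are NA internally
# and "NN" in files.

UNKNOWN_TOKENS <- c("", "NN", "0", "UNKNOWN", "NA")

#' Construct and validate a pedigree
#'
#' Builds a `pedigree` object from per-animal records, checks the
#' structural invariants (unique non-empty ids, no self-parentage, no
#' cycles, parent sex and birth-year consistency) and stores the records
#' in a topological order with parents before offspring.
#'
#' Unknown parents are represented as `NA`.  A parent named in a `sire`
#' or `dam` column but absent from `id` is an error by default; with
#' `on_missing_parent = "phantom"` a record with unknown parentage is
#' auto-created for it.
#'
#' @param df data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` ("M"/"F"/"U"), `birth_year` (integer), `status`.
#' @param on_missing_parent `"error"` or `"phantom"`.
#' @return A `pedigree`: the validated data frame, topologically sorted.
#' @export
#' @examples
#' trio <- pedigree(data.frame(id = c("A", "B", "C"),
#'                             sire = c(NA, NA, "A"),
#'                             dam  = c(NA, NA, "B")))
#' nrow(trio)
pedigree <- function(df, on_missing_parent = c("error", "phantom")) {
  on_missing_parent <- match.arg(on_missing_parent)
  stopifnot(is.data.frame(df), all(c("id", "sire", "dam") %in% names(df)))
  df$id   <- as.character(df$id)
  df$sire <- normalize_unknown(as.character(df$sire))
  df$dam  <- normalize_unknown(as.character(df$dam))
  if (!"sex" %in% names(df)) df$sex <- "U"
  df$sex <- toupper(as.character(df$sex))
  df$sex[is.na(df$sex) | !df$sex %in% c("M", "F")] <- "U"
  if (!"birth_year" %in% names(df)) df$birth_year <- NA_integer_
  df$birth_year <- as.integer(df$birth_year)
  if (!"status" %in% names(df)) df$status <- "unknown"
  df$status <- as.character(df$status)

  if (any(is.na(df$id) | df$id == ""))
    stop("empty animal id", call. = FALSE)
  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    stop("duplicate id: ", dup[1], call. = FALSE)
  self <- df$id == df$sire | df$id == df$dam
  if (any(self, na.rm = TRUE))
    stop("self-parent: ", df$id[which(self)[1]], call. = FALSE)

  named <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(named)) {
    if (on_missing_parent == "error")
      stop("parent not in pedigree: ", named[1], call. = FALSE)
    add <- df[0, ]
    add[seq_along(named), "id"] <- named
    add$sex <- "U"; add$status <- "unknown"
    df <- rbind(df, add)
  }

  # sire must not be recorded female, dam not male
  sire_sex <- df$sex[match(stats::na.omit(unique(df$sire)), df$id)]
  if (any(sire_sex == "F"))
    stop("animal recorded female is used as sire", call. = FALSE)
  dam_sex <- df$sex[match(stats::na.omit(unique(df$dam)), df$id)]
  if (any(dam_sex == "M"))
    stop("animal recorded male is used as dam", call. = FALSE)

  df <- toposort_pedigree(df)

  si <- match(df$sire, df$id); di <- match(df$dam, df$id)
  bad_year <- (!is.na(si) & !is.na(df$birth_year) & !is.na(df$birth_year[si]) &
                 df$birth_year[si] >= df$birth_year) |
              (!is.na(di) & !is.na(df$birth_year) & !is.na(df$birth_year[di]) &
                 df$birth_year[di] >= df$birth_year)
  if (any(bad_year))
    stop("parent born in or after offspring birth year: ",
         df$id[which(bad_year)[1]], call. = FALSE)

  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

normalize_unknown <- function(x) {
  x[is.na(x) | toupper(trimws(x)) %in% UNKNOWN_TOKENS] <- NA_character_
  x
}

# Kahn's algorithm; errors with a cycle member's id if cyclic.
toposort_pedigree <- function(df) {
  n <- nrow(df)
  si <- match(df$sire, df$id); di <- match(df$dam, df$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n)
    stop("pedigree cycle involving: ", df$id[setdiff(seq_len(n), ord)[1]],
         call. = FALSE)
  df[ord, , drop = FALSE]
}

parent_indices <- function(ped) {
  list(sire = match(ped$sire, ped$id), dam = match(ped$dam, ped$id))
}

#' Read a pedigree from CSV
#'
#' Expects a header with at least `id,sire,dam`; optional `sex`,
#' `birth_year`, `status`.  The unknown-parent tokens `""`, `"NN"`, `"0"`,
#' `"UNKNOWN"` and `"NA"` are all normalized to unknown.
#'
#' @inheritParams pedigree
#' @param path file path.
#' @return A validated [pedigree].
#' @export
read_pedigree <- function(path, on_missing_parent = c("error", "phantom")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  pedigree(df, on_missing_parent = on_missing_parent)
}

#' Write a pedigree to CSV
#'
#' Unknown parents are written as `"NN"`, the studbook notation for
#' animals of unknown origin.
#'
#' @param ped a [pedigree].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "NN"
  out$dam[is.na(out$dam)] <- "NN"
  utils::write.csv(out[c("id", "sire", "dam", "sex", "birth_year", "status")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x), "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "with both parents unknown\n")
  invisible(x)
}
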