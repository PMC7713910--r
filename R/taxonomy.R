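# Default rank ladder, most specific first. The rank set is configurable:
# any ordered character vector works as long as the mapping it describes is
# properly nested.
DEFAULT_RANKS <- c("species", "group", "genus", "subtribe", "tribe", "subfamily")

#' Construct a taxonomy table
#'
#' A taxonomy table maps every species to its label at each higher rank of
#' an ordered ladder (default: species, group, genus, subtribe, tribe,
#' subfamily). The mapping must be properly nested: two species that share
#' a label at some rank must share labels at every rank above it.
#'
#' @param df data.frame with one row per species and one column per rank,
#'   ordered most specific to least specific.
#' @param ranks character vector of rank names, most specific first.
#'   Defaults to the column names of `df`.
#' @return An object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df, ranks = names(df)) {
  stopifnot(is.data.frame(df), length(ranks) >= 1)
  if (!all(ranks %in% names(df))) {
    stop("ranks not present in table: ",
         paste(setdiff(ranks, names(df)), collapse = ", "))
  }
  df <- df[, ranks, drop = FALSE]
  for (r in ranks) df[[r]] <- as.character(df[[r]])

  sp <- df[[ranks[1]]]
  if (anyNA(df) || any(vapply(df, function(x) any(!nzchar(x)), logical(1)))) {
    stop("taxonomy has empty cells; fill intermediate ranks with the label ",
         "at the nearest lower rank")
  }
  dup <- sp[duplicated(sp)]
  if (length(dup) > 0) {
    stop("duplicate species rows: ", paste(unique(dup), collapse = ", "))
  }
  .check_nesting(df, ranks)

  structure(list(ranks = ranks, table = df), class = "taxonomy_table")
}

# Nesting: for consecutive ranks (child, parent), each child label must map
# to exactly one parent label. Pairwise-consecutive checks imply the full
# transitive property.
.check_nesting <- function(df, ranks) {
  for (i in seq_len(length(ranks) - 1)) {
    child <- df[[ranks[i]]]
    parent <- df[[ranks[i + 1]]]
    tab <- unique(data.frame(child = child, parent = parent,
                             stringsAsFactors = FALSE))
    bad <- tab$child[duplicated(tab$child)]
    if (length(bad) > 0) {
      offending <- tab[tab$child %in% bad, ]
      stop(sprintf(
        "taxonomy is not nested: %s label(s) %s appear under multiple %s labels (%s)",
        ranks[i], paste(unique(bad), collapse = ", "), ranks[i + 1],
        paste(unique(offending$parent), collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Load a taxonomy table from CSV
#'
#' The CSV must have a header row naming the ranks in order (most specific
#' first) and one data row per species. Cells must be non-empty; a species
#' with no label at an intermediate rank should carry the label of the
#' nearest lower rank as a placeholder.
#'
#' @param path path to a UTF-8 CSV file.
#' @param ranks optional rank names; defaults to the CSV header.
#' @return A `taxonomy_table`.
#' @export
load_taxonomy <- function(path, ranks = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (is.null(ranks)) ranks <- names(df)
  taxonomy_table(df, ranks = ranks)
}

#' Write a taxonomy table to CSV
#' @param tax a `taxonomy_table`.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.csv(tax$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.taxonomy_table <- function(x, ...) {
  counts <- vapply(x$ranks, function(r) length(unique(x$table[[r]])),
                   integer(1))
  cat("taxonomy_table:", nrow(x$table), "species;",
      paste(sprintf("%d %s", counts, x$ranks), collapse = ", "), "\n")
  invisible(x)
}

#' Species label at a higher rank
#'
#' @param species_label species name (exact, case-sensitive).
#' @param rank a rank name in `tax$ranks`.
#' @param tax a `taxonomy_table`.
#' @return The species' label at `rank`.
#' @export
ancestor <- function(species_label, rank, tax) {
  lift_labels(species_label, rank, tax)
}

#' Lift species labels to a higher rank
#'
#' Elementwise ancestor lookup: maps each species-level label to the
#' corresponding label at `rank`. Lifting to the species rank is the
#' identity.
#'
#' @param labels character vector of species labels present in `tax`.
#' @param rank target rank name.
#' @param tax a `taxonomy_table`.
#' @return Character vector of labels at `rank`, same length as `labels`.
#' @export
lift_labels <- function(labels, rank, tax) {
  stopifnot(inherits(tax, "taxonomy_table"))
  if (!rank %in% tax$ranks) {
    stop("unknown rank: ", rank, " (ranks: ",
         paste(tax$ranks, collapse = ", "), ")")
  }
  if (length(labels) == 0) return(character(0))
  labels <- as.character(labels)
  sp <- tax$table[[tax$ranks[1]]]
  idx <- match(labels, sp)
  if (anyNA(idx)) {
    stop("unknown species: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  tax$table[[rank]][idx]
}

#' Ranks at or above a given rank
#' @param tax a `taxonomy_table`.
#' @param from starting rank (default: most specific).
#' @return Character vector of rank names from `from` upward.
#' @export
ranks_from <- function(tax, from = tax$ranks[1]) {
  i <- match(from, tax$ranks)
  if (is.na(i)) stop("unknown rank: ", from)
  tax$ranks[i:length(tax$ranks)]
}
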