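#' Construct a validated count table
#'
#' A count table holds non-negative integer read counts for a set of samples
#' (rows) by a set of taxa (columns), optionally with a taxon-to-genus map
#' used for genus-level aggregation.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns; must carry
#'   unique row and column names and contain only non-negative integers.
#' @param taxonomy optional named character vector mapping taxon ids (names)
#'   to genus labels; every name must be a column of `counts`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy`.
#' @examples
#' m <- matrix(c(5, 1, 0, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' ct <- count_table(m)
#' sample_ids(ct)
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) stop_("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_("counts must have sample (row) and taxon (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop_("duplicate sample identifiers")
  if (anyDuplicated(colnames(counts))) stop_("duplicate taxon identifiers")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_("count cell [sample '%s', taxon '%s'] is not a non-negative integer",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop_("taxonomy must be a named vector")
    unknown <- setdiff(names(taxonomy), colnames(counts))
    if (length(unknown) > 0) {
      stop_("taxonomy refers to unknown taxa: %s",
            paste(head(unknown, 5), collapse = ", "))
    }
    taxonomy <- setNames(as.character(taxonomy), names(taxonomy))
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "count_table")
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' @rdname count_table
#' @export
sample_totals <- function(x) rowSums(x$counts)

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (!is.null(x$taxonomy)) {
    cat(sprintf("  taxonomy map for %d taxa\n", length(x$taxonomy)))
  }
  invisible(x)
}

#' @export
`==.count_table` <- function(e1, e2) {
  identical(unname(dimnames(e1$counts)), unname(dimnames(e2$counts))) &&
    identical(dimnames(e1$counts), dimnames(e2$counts)) &&
    all(e1$counts == e2$counts)
}

#' Read a count table from tab-separated text
#'
#' Expects samples in rows: the header row lists taxon ids, the first column
#' holds sample ids and the body holds integer read counts. An optional
#' two-column taxonomy file (taxon id, genus) attaches the genus map.
#'
#' @param path path to the tab-separated count file.
#' @param taxonomy_path optional path to a headerless two-column TSV mapping
#'   taxon id to genus.
#' @return A validated [count_table]. Ordering of samples and taxa is
#'   preserved from the file.
#' @export
read_count_table <- function(path, taxonomy_path = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2) stop_("count file needs a sample column plus taxa")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  if (anyDuplicated(ids)) stop_("duplicate sample identifiers in '%s'", path)
  if (anyDuplicated(colnames(body))) {
    stop_("duplicate taxon identifiers in '%s'", path)
  }
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)))
  )
  num <- matrix(num, nrow = nrow(body),
                dimnames = list(ids, colnames(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_("malformed count at sample '%s', taxon '%s' ('%s')",
          ids[bad[1, 1]], colnames(body)[bad[1, 2]],
          body[bad[1, 1], bad[1, 2]])
  }
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- read.table(taxonomy_path, header = FALSE, sep = "\t",
                     colClasses = "character", quote = "")
    taxonomy <- setNames(tx[[2]], tx[[1]])
  }
  count_table(num, taxonomy)
}

#' Write a count table as tab-separated text
#'
#' Inverse of [read_count_table()]: the written file reads back to an equal
#' table (identity round trip), preserving sample and taxon order.
#'
#' @param x a [count_table].
#' @param path output path.
#' @param taxonomy_path optional path for the genus map TSV.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, taxonomy_path = NULL) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    write.table(data.frame(names(x$taxonomy), unname(x$taxonomy)),
                taxonomy_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
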