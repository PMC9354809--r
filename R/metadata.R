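#' Read sample metadata with a declared column schema
#'
#' Metadata rows are keyed by sample id (first column). Every other column
#' must be declared either `"continuous"` (parsed as numeric) or
#' `"categorical"` (kept as a factor whose levels follow first appearance in
#' the file). Missing values are flagged, never imputed; complete-case
#' handling happens in the downstream tests, not here.
#'
#' @param path tab-separated file with a header row; first column = sample id.
#' @param schema named character vector, one entry per non-id column, each
#'   `"continuous"` or `"categorical"`.
#' @param na_marker string denoting a missing value (default `"NA"`).
#' @return A `data.frame` with row names set to the sample ids and columns
#'   typed per `schema`.
#' @export
read_metadata <- function(path, schema, na_marker = "NA") {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "", comment.char = "")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop_("duplicate sample row '%s' in metadata", ids[anyDuplicated(ids)])
  }
  vars <- df[, -1, drop = FALSE]
  missing_decl <- setdiff(colnames(vars), names(schema))
  if (length(missing_decl) > 0) {
    stop_("no schema declared for column(s): %s",
          paste(missing_decl, collapse = ", "))
  }
  out <- lapply(colnames(vars), function(v) {
    raw <- vars[[v]]
    raw[raw == na_marker] <- NA
    kind <- schema[[v]]
    if (kind == "continuous") {
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(num) & !is.na(raw))
      if (length(bad) > 0) {
        stop_("column '%s' declared continuous but sample '%s' has '%s'",
              v, ids[bad[1]], raw[bad[1]])
      }
      num
    } else if (kind == "categorical") {
      factor(raw, levels = unique(raw[!is.na(raw)]))
    } else {
      stop_("unknown column type '%s' for '%s'", kind, v)
    }
  })
  names(out) <- colnames(vars)
  res <- as.data.frame(out, check.names = FALSE)
  rownames(res) <- ids
  res
}
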