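# Structured result reports: one canonical JSON serialization plus a
# human-readable TSV summary of the hypothesis tests.

#' Assemble a single test result
#'
#' Common container for every hypothesis test in the package: the method
#' name, the statistic, raw and (optionally) adjusted p-values, and the
#' bookkeeping needed to rerun it (sample size, df or permutation count).
#'
#' @param method method label, e.g. `"permanova"`.
#' @param statistic numeric test statistic.
#' @param p_value raw p-value in (0, 1].
#' @param p_adjusted optional multiplicity-adjusted p-value.
#' @param n_used number of observations entering the test.
#' @param df degrees of freedom, if the reference distribution has any.
#' @param n_perm number of permutations, for permutation tests.
#' @param notes free-text qualifiers (e.g. "continuity correction").
#' @return A one-row `data.frame` of class `test_result`.
#' @export
test_result <- function(method, statistic, p_value, p_adjusted = NA_real_,
                        n_used = NA_integer_, df = NA_real_,
                        n_perm = NA_integer_, notes = "") {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop_("p-value %g outside [0, 1]", p_value)
  }
  # asymptotic approximations can underflow to 0; keep p in (0, 1]
  if (!is.na(p_value) && p_value == 0) p_value <- .Machine$double.xmin
  structure(
    data.frame(method = method, statistic = as.numeric(statistic),
               p_value = as.numeric(p_value),
               p_adjusted = as.numeric(p_adjusted),
               n_used = as.integer(n_used), df = as.numeric(df),
               n_perm = as.integer(n_perm), notes = notes,
               stringsAsFactors = FALSE),
    class = c("test_result", "data.frame"))
}

# Turn a supported result object into a plain, JSON-ready list.
report_entry <- function(x) UseMethod("report_entry")

#' @export
report_entry.test_result <- function(x) {
  as.list(as.data.frame(x)[1, , drop = FALSE])
}

#' @export
report_entry.data.frame <- function(x) {
  lapply(as.list(x), function(col) {
    if (is.factor(col)) as.character(col) else col
  })
}

#' @export
report_entry.enterotype_fit <- function(x) {
  list(kind = "enterotype_fit",
       k_grid = x$k_grid, ch_index = x$ch_index,
       mean_silhouette = x$mean_silhouette,
       prediction_strength = x$prediction_strength,
       chosen_k = x$chosen_k,
       labels = setNames(as.character(x$labels), names(x$labels)),
       medoids = x$medoids, driver_genus = x$driver_genus,
       low_biomass_class = x$low_biomass_class,
       low_biomass_samples = x$low_biomass_samples)
}

#' @export
report_entry.pcoa_result <- function(x) {
  list(kind = "pcoa",
       eigenvalues = x$eigenvalues,
       prop_explained = x$prop_explained,
       coordinates = apply(x$points, 1, as.numeric, simplify = FALSE),
       warnings = x$warnings)
}

#' @export
report_entry.default <- function(x) {
  if (is.list(x)) lapply(x, report_entry) else x
}

#' Write a structured analysis report
#'
#' Serializes a named collection of results (test results, enterotype fits,
#' ordinations, plain values) to JSON in a canonical, deterministic form, and
#' writes a TSV summary of all `test_result` entries alongside. Two runs on
#' identical inputs produce byte-identical files.
#'
#' @param results named list of result objects.
#' @param path output path for the JSON report.
#' @param tsv_path output path for the test summary TSV; default replaces the
#'   JSON extension with `_summary.tsv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path,
                         tsv_path = paste0(tools::file_path_sans_ext(path),
                                           "_summary.tsv")) {
  if (length(results) > 0 && is.null(names(results))) {
    stop_("results must be a named list")
  }
  entries <- lapply(results, report_entry)
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  tests <- Filter(function(x) inherits(x, "test_result"), results)
  summ <- if (length(tests) > 0) {
    cbind(name = names(tests), do.call(rbind, lapply(tests, as.data.frame)))
  } else {
    data.frame(name = character(), method = character(),
               statistic = numeric(), p_value = numeric())
  }
  write.table(summ, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @param path path of a JSON report written by [write_report()].
#' @return `read_report()` returns the parsed report as a named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
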