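# File interchange: cohort and mutation tables as comma-separated UTF-8
# text with a header row and empty fields for missing values; structured
# configuration as JSON; plain-text run logs echoing the resolved
# configuration and seed.

#' Read / write a cohort table
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @name cohort_io
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "")
}

#' @param cohort A subject-level tibble.  List columns (e.g.
#'   `recall_grid`) are dropped on write.
#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  drop <- vapply(cohort, is.list, logical(1))
  if (any(drop)) cohort <- cohort[!drop]
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read mutation records
#'
#' Expects columns `id`, `kind`, `exon_start`, `exon_end`.
#'
#' @param path CSV file path.
#' @return A tibble of mutation records.
#' @export
read_mutations <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, na = "")
  need <- c("kind", "exon_start", "exon_end")
  if (!all(need %in% names(m))) {
    stop("mutation table must have columns: id, kind, exon_start, exon_end",
         call. = FALSE)
  }
  m
}

#' Read / write a JSON run configuration
#'
#' @param path JSON file path.
#' @return `read_config()` returns a named list; `write_config()` returns
#'   `path` invisibly.
#' @name config_io
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @param config A named list.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a plain-text run log
#'
#' Echoes the seed, the fully resolved configuration and parameters, and
#' the package/R versions, so any result table can be regenerated.
#'
#' @param path Log file path.
#' @param seed The run seed (may be `NULL`).
#' @param ... Named configuration objects to echo (lists are deparsed
#'   field by field).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, seed = NULL, ...) {
  items <- list(...)
  lines <- c(
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("iblstroop version: %s",
            as.character(utils::packageVersion("iblstroop"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %s", if (is.null(seed)) "none" else format(seed))
  )
  for (nm in names(items)) {
    x <- items[[nm]]
    if (is.list(x)) {
      for (k in names(x)) {
        v <- x[[k]]
        lines <- c(lines, sprintf("%s.%s: %s", nm, k,
                                  if (is.null(v)) "unset"
                                  else paste(format(v), collapse = ", ")))
      }
    } else {
      lines <- c(lines, sprintf("%s: %s", nm, paste(format(x), collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
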