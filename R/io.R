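#' Read and write cohort tables and effect ledgers
#'
#' Cohorts are plain comma-separated text: header row, UTF-8, `.` decimal
#' separator, empty field for missing. Ledgers ([ground_truth_ledger()])
#' are JSON.
#'
#' @param cohort A cohort data frame.
#' @param ledger A `ground_truth_ledger`.
#' @param path File path.
#' @return Readers return a tibble / ledger; writers return `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "",
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  as_tibble(read.csv(path, na.strings = c("", "NA"),
                     stringsAsFactors = FALSE, fileEncoding = "UTF-8"))
}

#' @rdname write_cohort
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "ground_truth_ledger"))
  jsonlite::write_json(
    list(direct = as.data.frame(ledger$direct),
         indirect = as.data.frame(ledger$indirect),
         total = as.data.frame(ledger$total)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_ledger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(direct = as_tibble(x$direct), indirect = as_tibble(x$indirect),
         total = as_tibble(x$total)),
    class = "ground_truth_ledger"
  )
}
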