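#' Read and write reference z-score tables
#'
#' Reference tables drive age- and sex- (and, for blood pressure,
#' height-) conditional z-scoring. Two kinds are supported: `lms` rows carry
#' Box-Cox parameters (L, M, S); `mean_sd` rows carry (mu, sigma). Tables are
#' plain delimited text with header
#' `kind,sex,age_lo,age_hi,height_lo,height_hi,L,M,S,mu,sigma`; age bins (in
#' years) and height bins (in cm) are half-open `[lo, hi)`; unused fields are
#' empty. Classification cutpoints (percentiles, default 90 and 95) are
#' stored in a leading `#cutpoints:` comment line and round-trip through
#' read/write.
#'
#' The published growth and pediatric blood-pressure references are licensed
#' tables and are not shipped; any table in this format plugs in, and
#' [generate_reference_table()] builds toy stand-ins for testing.
#'
#' @param path File path.
#' @param table A reference-table tibble (as returned by `read_reference_table`
#'   or [generate_reference_table()]).
#' @return `read_reference_table()` returns a tibble of class
#'   `reference_table` with a `cutpoints` attribute; `write_reference_table()`
#'   returns `path` invisibly.
#' @export
read_reference_table <- function(path) {
  first <- readLines(path, n = 1L)
  cutpoints <- c(90, 95)
  skip <- 0L
  if (startsWith(first, "#cutpoints:")) {
    cutpoints <- as.numeric(strsplit(sub("^#cutpoints:", "", first), ",")[[1]])
    skip <- 1L
  }
  tab <- as_tibble(read.csv(path, skip = skip, stringsAsFactors = FALSE))
  for (cl in intersect(reference_numeric_cols, names(tab))) {
    tab[[cl]] <- as.numeric(tab[[cl]])
  }
  validate_reference_table(tab)
  attr(tab, "cutpoints") <- cutpoints
  class(tab) <- c("reference_table", class(tab))
  tab
}

reference_numeric_cols <- c("age_lo", "age_hi", "height_lo", "height_hi",
                            "L", "M", "S", "mu", "sigma")

#' @rdname read_reference_table
#' @export
write_reference_table <- function(table, path) {
  validate_reference_table(table)
  cp <- attr(table, "cutpoints") %||% c(90, 95)
  out <- as.data.frame(table)
  # %.17g preserves doubles exactly across the text round trip
  for (cl in intersect(reference_numeric_cols, names(out))) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), "", sprintf("%.17g", out[[cl]]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#cutpoints:", paste(cp, collapse = ",")), con)
  write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_reference_table <- function(tab) {
  needed <- c("kind", "sex", "age_lo", "age_hi")
  if (!all(needed %in% names(tab))) {
    abort(paste("reference table must have columns",
                paste(needed, collapse = ", ")),
          class = "pathmed_parse_error")
  }
  if (!all(tab$kind %in% c("lms", "mean_sd"))) {
    abort("reference table kind must be 'lms' or 'mean_sd'",
          class = "pathmed_parse_error")
  }
  lms <- tab[tab$kind == "lms", ]
  msd <- tab[tab$kind == "mean_sd", ]
  if (nrow(lms) > 0 && (any(lms$M <= 0) || any(lms$S <= 0))) {
    abort("LMS rows require M > 0 and S > 0", class = "pathmed_parse_error")
  }
  if (nrow(msd) > 0 && any(msd$sigma <= 0)) {
    abort("mean_sd rows require sigma > 0", class = "pathmed_parse_error")
  }
  invisible(tab)
}

lookup_reference_row <- function(table, sex, age, height = NA_real_) {
  hit <- table$sex == sex & table$age_lo <= age & age < table$age_hi
  has_height <- "height_lo" %in% names(table) && any(!is.na(table$height_lo))
  if (has_height) {
    hh <- !is.na(table$height_lo)
    hit <- hit & (!hh | (!is.na(height) & table$height_lo <= height &
                           height < table$height_hi))
  }
  idx <- which(hit)
  if (length(idx) == 0) {
    abort(sprintf(
      "no reference row covers sex = %s, age = %.3g%s (no extrapolation)",
      sex, age, if (is.na(height)) "" else sprintf(", height = %.3g", height)),
      class = "pathmed_range_error")
  }
  idx[1]
}

#' Reference z-score
#'
#' Looks up the reference row for each observation and computes the z-score:
#' for `lms` rows \eqn{z = ((x/M)^L - 1) / (L S)}, with the \eqn{L \to 0}
#' limit \eqn{z = \log(x/M)/S}; for `mean_sd` rows \eqn{z = (x - \mu)/\sigma}.
#' Keys outside the table's coverage raise an error — there is no
#' extrapolation.
#'
#' @param x Measured values (units of the reference median).
#' @param sex Sex codes matching the table's `sex` column.
#' @param age Age in years.
#' @param table A reference table (see [read_reference_table()]).
#' @param height Height in cm, required when the table is height-specific.
#' @return Numeric vector of z-scores (`NA` in, `NA` out).
#' @export
zscore <- function(x, sex, age, table, height = NULL) {
  validate_reference_table(table)
  n <- length(x)
  height <- height %||% rep(NA_real_, n)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i]) || is.na(age[i]) || is.na(sex[i])) next
    row <- table[lookup_reference_row(table, sex[i], age[i], height[i]), ]
    out[i] <- if (row$kind == "lms") {
      if (abs(row$L) < 1e-7) {
        log(x[i] / row$M) / row$S
      } else {
        ((x[i] / row$M)^row$L - 1) / (row$L * row$S)
      }
    } else {
      (x[i] - row$mu) / row$sigma
    }
  }
  out
}

#' Convert z-scores to reference percentiles
#'
#' @param z Numeric z-scores.
#' @return Percentiles in (0, 100) under the reference normal.
#' @export
z_to_percentile <- function(z) 100 * pnorm(z)

#' Derive analysis phenotypes for a cohort table
#'
#' Adds the derived columns the path models consume: BMI from weight and
#' height, BMI z-score (LMS reference), consolidated systolic/diastolic
#' pressures from up to three readings, their reference z-scores and
#' percentiles, the blood-pressure category, and the delta-5 desaturase
#' index. Expected input columns: `weight` (kg), `height` (cm), `age`
#' (years), `sex`, `sbp_1..sbp_3`, `dbp_1..dbp_3`, `ara`, `dgla`. Missing
#' inputs propagate as missing.
#'
#' @param data Cohort data frame.
#' @param bmi_reference LMS reference table for BMI.
#' @param bp_reference mean_sd (height-specific) reference table for blood
#'   pressure; its `cutpoints` attribute sets the classification cutpoints.
#' @return The input tibble with columns `bmi`, `bmi_z`, `sbp`, `dbp`,
#'   `sbp_z`, `dbp_z`, `bp_category`, `d5d` appended.
#' @export
derive_phenotypes <- function(data, bmi_reference, bp_reference) {
  d <- as_tibble(data)
  need <- c("weight", "height", "age", "sex")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(paste("missing cohort columns:", paste(miss, collapse = ", ")),
          class = "pathmed_data_error")
  }
  d$bmi <- bmi(d$weight, d$height / 100)
  d$bmi_z <- zscore(d$bmi, d$sex, d$age, bmi_reference)
  pick <- function(nm) if (nm %in% names(d)) d[[nm] ] else rep(NA_real_, nrow(d))
  d$sbp <- consolidate_bp(pick("sbp_1"), pick("sbp_2"), pick("sbp_3"))
  d$dbp <- consolidate_bp(pick("dbp_1"), pick("dbp_2"), pick("dbp_3"))
  d$sbp_z <- zscore(d$sbp, d$sex, d$age, bp_reference, height = d$height)
  d$dbp_z <- zscore(d$dbp, d$sex, d$age, bp_reference, height = d$height)
  cp <- attr(bp_reference, "cutpoints") %||% c(90, 95)
  d$bp_category <- classify_bp(z_to_percentile(d$sbp_z),
                               z_to_percentile(d$dbp_z), cutpoints = cp)
  if (all(c("ara", "dgla") %in% names(d))) {
    d$d5d <- d5d_index(d$ara, d$dgla)
  }
  d
}
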