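#' Specify a recursive linear path model
#'
#' Builds a path-model specification from a table of directed edges among
#' observed variables. A variable is endogenous if at least one edge points
#' into it; all other variables are exogenous. The directed graph must be
#' acyclic (a recursive model). Free parameters are: one regression slope per
#' edge, a variance per variable (residual variance for endogenous variables),
#' and covariances among exogenous variables (free by default, unless listed
#' in `fixed_zero`). Residual covariances among endogenous variables are fixed
#' to zero unless explicitly freed through `covariances`.
#'
#' @param edges Data frame with character columns `from` and `to`, one row per
#'   directed edge (regression of `to` on `from`).
#' @param variables Optional character vector fixing the variable set and
#'   order; must contain every variable named in `edges`. Extra names are
#'   included as isolated exogenous variables.
#' @param covariances Optional data frame (`from`, `to`) of residual
#'   covariances to estimate freely in addition to the defaults.
#' @param fixed_zero Optional data frame (`from`, `to`) of exogenous
#'   covariances to constrain to zero (the model-modification device used to
#'   zero covariances among, e.g., country indicators and sex).
#'
#' @return An object of class `path_model` with elements `variables`, `roles`,
#'   `edges`, `parameters` (a tibble with one row per free parameter) and
#'   `order` (a topological order of the variables).
#' @examples
#' m <- path_model(data.frame(
#'   from = c("snp", "snp", "fa", "fa", "bmi", "snp"),
#'   to   = c("fa", "bmi", "bmi", "bp", "bp", "bp")
#' ))
#' m$parameters
#' @export
path_model <- function(edges, variables = NULL, covariances = NULL,
                       fixed_zero = NULL) {
  edges <- check_edge_frame(edges)
  vars_seen <- unique(c(rbind(edges$from, edges$to)))
  if (is.null(variables)) {
    variables <- vars_seen
  } else {
    variables <- as.character(variables)
    if (!all(vars_seen %in% variables)) {
      abort("`variables` must include every variable named in `edges`",
            class = "pathmed_spec_error")
    }
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate parameter slot for edge %s -> %s",
                  edges$from[duplicated(key)][1], edges$to[duplicated(key)][1]),
          class = "pathmed_spec_error")
  }
  order <- topological_order(variables, edges)

  endogenous <- unique(edges$to)
  roles <- ifelse(variables %in% endogenous, "endogenous", "exogenous")
  names(roles) <- variables
  exo <- variables[roles == "exogenous"]

  fixed_zero <- if (is.null(fixed_zero)) {
    tibble(from = character(), to = character())
  } else {
    check_edge_frame(fixed_zero, "fixed_zero")
  }
  covariances <- if (is.null(covariances)) {
    tibble(from = character(), to = character())
  } else {
    check_edge_frame(covariances, "covariances")
  }
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  fz_key <- pair_key(fixed_zero$from, fixed_zero$to)

  pars <- list(
    tibble(
      type = "edge", row = edges$to, col = edges$from,
      label = paste0(edges$from, "->", edges$to)
    ),
    tibble(
      type = "variance", row = variables, col = variables,
      label = ifelse(roles == "endogenous",
                     paste0("resid_var(", variables, ")"),
                     paste0("var(", variables, ")"))
    )
  )
  if (length(exo) > 1) {
    cmb <- utils::combn(exo, 2)
    free <- !(pair_key(cmb[1, ], cmb[2, ]) %in% fz_key)
    if (any(free)) {
      pars <- c(pars, list(tibble(
        type = "covariance", row = cmb[2, free], col = cmb[1, free],
        label = paste0("cov(", cmb[1, free], ",", cmb[2, free], ")")
      )))
    }
  }
  if (nrow(covariances) > 0) {
    pars <- c(pars, list(tibble(
      type = "covariance", row = covariances$to, col = covariances$from,
      label = paste0("cov(", covariances$from, ",", covariances$to, ")")
    )))
  }
  parameters <- dplyr::bind_rows(pars)
  if (anyDuplicated(pair_key(parameters$row[parameters$type == "covariance"],
                             parameters$col[parameters$type == "covariance"]))) {
    abort("duplicate covariance parameter slot", class = "pathmed_spec_error")
  }

  structure(
    list(
      variables = variables,
      roles = roles,
      edges = as_tibble(edges[c("from", "to")]),
      fixed_zero = fixed_zero,
      parameters = parameters,
      order = order
    ),
    class = "path_model"
  )
}

#' @export
print.path_model <- function(x, ...) {
  cat("<path_model> ", length(x$variables), " variables, ",
      nrow(x$edges), " directed edges, ",
      nrow(x$parameters), " free parameters\n", sep = "")
  cat("endogenous:", paste(x$variables[x$roles == "endogenous"], collapse = ", "), "\n")
  cat("exogenous: ", paste(x$variables[x$roles == "exogenous"], collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a path-model specification file
#'
#' Model specifications are stored as JSON with fields `variables`, `edges`,
#' `covariances`, `fixed_zero` and optionally `categorical` (columns of the
#' cohort to expand into reference-coded indicators before fitting).
#'
#' @param path File path.
#' @param model A `path_model` object (for writing).
#' @param categorical Optional character vector of categorical cohort columns
#'   recorded in the file for use by [expand_categorical()].
#' @return `read_model_spec()` returns a `path_model` (with attribute
#'   `categorical`); `write_model_spec()` returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("edges", "covariances", "fixed_zero")) {
    if (!is.null(spec[[fld]]) && length(spec[[fld]]) == 0) spec[fld] <- list(NULL)
  }
  m <- path_model(
    edges = as.data.frame(spec$edges),
    variables = spec$variables,
    covariances = if (!is.null(spec$covariances)) as.data.frame(spec$covariances),
    fixed_zero = if (!is.null(spec$fixed_zero)) as.data.frame(spec$fixed_zero)
  )
  attr(m, "categorical") <- spec$categorical
  m
}

#' @rdname read_model_spec
#' @export
write_model_spec <- function(model, path, categorical = NULL) {
  stopifnot(inherits(model, "path_model"))
  jsonlite::write_json(
    list(
      variables = model$variables,
      edges = as.data.frame(model$edges),
      covariances = {
        cv <- model$parameters[model$parameters$type == "covariance", ]
        cv <- cv[cv$row %in% model$variables[model$roles == "endogenous"] |
                   cv$col %in% model$variables[model$roles == "endogenous"], ]
        data.frame(from = cv$col, to = cv$row)
      },
      fixed_zero = as.data.frame(model$fixed_zero),
      categorical = categorical %||% attr(model, "categorical")
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Expand categorical columns into reference-coded indicators
#'
#' A categorical column with k levels becomes k - 1 binary indicator columns
#' named `<col>_<level>`, omitting the reference (first) level — e.g. six
#' country categories become five indicators, three parental-education levels
#' become two.
#'
#' @param data A data frame.
#' @param cols Character vector of column names to expand.
#' @param reference Optional named character vector of reference levels
#'   (default: first factor level).
#' @return A tibble with `cols` replaced by their indicator columns.
#' @export
expand_categorical <- function(data, cols, reference = NULL) {
  out <- as_tibble(data)
  for (cl in cols) {
    if (!cl %in% names(out)) {
      abort(sprintf("column `%s` not found", cl), class = "pathmed_spec_error")
    }
    f <- factor(out[[cl]])
    ref <- reference[[cl]] %||% levels(f)[1]
    f <- stats::relevel(f, ref = ref)
    for (lev in levels(f)[-1]) {
      out[[paste0(cl, "_", lev)]] <- as.numeric(f == lev)
    }
    out[[cl]] <- NULL
  }
  out
}
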