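# Panel container, long-CSV interchange, packaged reference tables, and
# table aggregation helpers.

#' Construct a panel dataset
#'
#' A \code{panel_dataset} holds a balanced units-by-periods panel of DEA
#' inputs, DEA outputs, and (optionally) regression covariates. Inputs and
#' outputs must be strictly positive: the slacks-based efficiency measure
#' divides by each evaluated unit's own input and output levels, so zeros
#' are rejected at construction rather than imputed.
#'
#' @param units character vector of unit labels (length n).
#' @param periods integer vector of period labels, e.g. years (length T).
#' @param inputs numeric array n x m x T of DEA inputs.
#' @param outputs numeric array n x s x T of DEA outputs.
#' @param covariates optional numeric array n x p x T of covariates.
#' @return an object of class \code{panel_dataset}.
#' @export
panel_dataset <- function(units, periods, inputs, outputs, covariates = NULL) {
  units <- as.character(units)
  periods <- as.integer(periods)
  n <- length(units)
  Tt <- length(periods)
  if (anyDuplicated(units)) stop("duplicate unit labels")
  if (anyDuplicated(periods)) stop("duplicate period labels")
  check_arr <- function(a, what, strict_pos) {
    if (!is.array(a) || length(dim(a)) != 3L)
      stop(what, " must be an n x k x T array")
    if (dim(a)[1] != n || dim(a)[3] != Tt)
      stop(what, " dimensions do not match units/periods")
    if (anyNA(a)) {
      bad <- which(is.na(a), arr.ind = TRUE)[1, ]
      stop("missing cell in ", what, ": unit ", units[bad[1]],
           ", field ", bad[2], ", period ", periods[bad[3]])
    }
    if (strict_pos && any(a <= 0)) {
      bad <- which(a <= 0, arr.ind = TRUE)[1, ]
      stop("nonpositive value in ", what, " (unit ", units[bad[1]],
           ", field ", bad[2], ", period ", periods[bad[3]],
           "); the slacks-based measure requires strictly positive data")
    }
    a
  }
  inputs <- check_arr(inputs, "inputs", TRUE)
  outputs <- check_arr(outputs, "outputs", TRUE)
  if (!is.null(covariates)) covariates <- check_arr(covariates, "covariates", FALSE)
  dimnames(inputs)[[1]] <- dimnames(outputs)[[1]] <- units
  dimnames(inputs)[[3]] <- dimnames(outputs)[[3]] <- as.character(periods)
  if (!is.null(covariates)) {
    dimnames(covariates)[[1]] <- units
    dimnames(covariates)[[3]] <- as.character(periods)
  }
  structure(list(units = units, periods = periods, inputs = inputs,
                 outputs = outputs, covariates = covariates),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("panel_dataset:", length(x$units), "units x", length(x$periods),
      "periods;", dim(x$inputs)[2], "inputs,", dim(x$outputs)[2], "outputs",
      if (!is.null(x$covariates)) paste0(", ", dim(x$covariates)[2], " covariates"),
      "\n")
  invisible(x)
}

#' Read a panel from a long-format CSV
#'
#' The canonical interchange format is long: one row per unit-period, a
#' \code{unit} column, a \code{year} column, and one named column per input,
#' output, and covariate. \code{schema} maps column names onto roles.
#'
#' @param path CSV file path.
#' @param schema list with character elements \code{inputs}, \code{outputs},
#'   and optionally \code{covariates}, naming the columns in each role.
#' @return a \code{\link{panel_dataset}}.
#' @export
load_panel <- function(path, schema) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("unit", "year") %in% names(df)))
    stop("long-format panel CSV must have 'unit' and 'year' columns")
  for (role in c("inputs", "outputs"))
    if (is.null(schema[[role]]) || !length(schema[[role]]))
      stop("schema must name at least one column for role '", role, "'")
  needed <- unlist(schema[c("inputs", "outputs", "covariates")], use.names = FALSE)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("columns absent from CSV: ", paste(missing_cols, collapse = ", "))
  units <- unique(df$unit)
  periods <- sort(unique(df$year))
  key <- paste(df$unit, df$year)
  full <- as.vector(outer(units, periods, paste))
  absent <- setdiff(full, key)
  if (length(absent))
    stop("missing cell: no row for ", absent[1])
  if (anyDuplicated(key)) stop("duplicated unit-year rows")
  grab <- function(cols) {
    if (is.null(cols)) return(NULL)
    a <- array(NA_real_, c(length(units), length(cols), length(periods)),
               dimnames = list(units, cols, periods))
    for (ti in seq_along(periods)) {
      sub <- df[df$year == periods[ti], , drop = FALSE]
      sub <- sub[match(units, sub$unit), , drop = FALSE]
      a[, , ti] <- as.matrix(sub[, cols, drop = FALSE])
    }
    a
  }
  panel_dataset(units, periods, grab(schema$inputs), grab(schema$outputs),
                grab(schema$covariates))
}

#' Write a panel to a long-format CSV
#'
#' Inverse of \code{\link{load_panel}}: one row per unit-period, columns
#' named after the panel's field dimnames.
#'
#' @param panel a \code{\link{panel_dataset}}.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_dataset"))
  rows <- list()
  for (ti in seq_along(panel$periods)) {
    block <- data.frame(unit = panel$units, year = panel$periods[ti],
                        check.names = FALSE)
    add <- function(a) as.data.frame(a[, , ti, drop = FALSE][, , 1, drop = TRUE],
                                     check.names = FALSE)
    block <- cbind(block, add(panel$inputs), add(panel$outputs))
    if (!is.null(panel$covariates)) block <- cbind(block, add(panel$covariates))
    rows[[ti]] <- block
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Panel schema implied by a panel's own dimnames
#' @param panel a \code{\link{panel_dataset}}.
#' @return schema list usable with \code{\link{load_panel}}.
#' @export
panel_schema <- function(panel) {
  list(inputs = dimnames(panel$inputs)[[2]],
       outputs = dimnames(panel$outputs)[[2]],
       covariates = if (!is.null(panel$covariates)) dimnames(panel$covariates)[[2]])
}

#' Load a packaged reference table
#'
#' Four fixtures ship with the package, transcribed at their printed
#' 3-decimal precision from the published 29-province township-health-centre
#' study: \code{"table1_efficiency"} (29 x 10 super-SBM efficiency scores,
#' 2012-2021), \code{"table3_malmquist"} (29 x 3 per-province mean MI, EC,
#' TC), \code{"table4_moran"} (10 x 3 yearly global Moran's I with z and p),
#' and \code{"adjacency_rook29"} (the first-order rook contiguity edge list
#' over the 29 provinces, with Hainan linked to Guangdong so no unit is an
#' island).
#'
#' @param name fixture name, one of the four above.
#' @return for the three numeric tables, a numeric matrix with row and
#'   column labels; for the adjacency, a two-column character data frame of
#'   edges.
#' @export
load_fixture <- function(name) {
  valid <- c("table1_efficiency", "table3_malmquist", "table4_moran",
             "adjacency_rook29")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown fixture name; expected one of: ", paste(valid, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".csv"), package = "thcdea",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (name == "adjacency_rook29") {
    df$from <- as.character(df$from)
    df$to <- as.character(df$to)
    return(df)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' The 29 province labels, in fixture order
#' @return character vector of length 29.
#' @export
province_labels <- function() {
  rownames(load_fixture("table1_efficiency"))
}

#' Aggregate a labelled numeric table
#'
#' Arithmetic or geometric means along rows, columns, or over all cells.
#' Full double precision is kept internally; rounding to the 3 decimals of
#' the printed reference tables is left to the caller.
#'
#' @param values numeric matrix (labelled).
#' @param axis \code{"rows"} (one mean per row), \code{"columns"}, or
#'   \code{"all"} (grand mean).
#' @param method \code{"arithmetic"} or \code{"geometric"}.
#' @return named numeric vector, or a scalar for \code{axis = "all"}.
#' @export
aggregate_table <- function(values, axis = c("rows", "columns", "all"),
                            method = c("arithmetic", "geometric")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  values <- as.matrix(values)
  if (anyNA(values)) stop("table contains missing values")
  if (method == "geometric" && any(values <= 0))
    stop("geometric mean undefined for nonpositive entries")
  mfun <- if (method == "arithmetic") mean else function(v) exp(mean(log(v)))
  switch(axis,
         rows = apply(values, 1, mfun),
         columns = apply(values, 2, mfun),
         all = mfun(as.vector(values)))
}
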