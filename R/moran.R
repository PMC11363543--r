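# Contiguity weight matrices, global Moran's I with analytic or permutation
# inference, and Moran-scatter quadrant (cluster) classification.

#' Build a contiguity weight matrix from an edge list
#'
#' @param adjacency two-column data frame or matrix of undirected edges
#'   (\code{from}, \code{to}); each edge is entered symmetrically.
#' @param labels ordered character vector of unit labels fixing row and
#'   column order.
#' @return object of class \code{weight_matrix}: list with \code{labels},
#'   \code{binary} (symmetric 0/1 matrix, zero diagonal) and
#'   \code{row_standardized} (each row rescaled to sum to 1).
#' @export
build_weights <- function(adjacency, labels) {
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L) stop("adjacency must have two columns")
  labels <- as.character(labels)
  n <- length(labels)
  unknown <- setdiff(unique(as.vector(adjacency)), labels)
  if (length(unknown))
    stop("unknown label(s) in edge list: ", paste(unknown, collapse = ", "))
  if (any(adjacency[, 1] == adjacency[, 2])) stop("self-loop in edge list")
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (r in seq_len(nrow(adjacency))) {
    W[adjacency[r, 1], adjacency[r, 2]] <- 1
    W[adjacency[r, 2], adjacency[r, 1]] <- 1
  }
  deg <- rowSums(W)
  if (any(deg == 0))
    stop("isolated unit(s): ", paste(labels[deg == 0], collapse = ", "))
  structure(list(labels = labels, binary = W,
                 row_standardized = W / deg),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("weight_matrix:", length(x$labels), "units,",
      sum(x$binary) / 2, "undirected edges\n")
  invisible(x)
}

#' Rook contiguity weights for the 29-province panel
#'
#' Convenience wrapper building the packaged first-order rook adjacency
#' (Hainan joined to Guangdong so no province is isolated) over the 29
#' provinces in fixture order.
#' @return a \code{\link{build_weights}} result.
#' @export
rook29_weights <- function() {
  build_weights(load_fixture("adjacency_rook29"), province_labels())
}

pick_w <- function(W, standardization) {
  stopifnot(inherits(W, "weight_matrix"))
  switch(match.arg(standardization, c("row", "binary")),
         row = W$row_standardized, binary = W$binary)
}

#' Global Moran's I
#'
#' Computes
#' \deqn{I = \frac{\sum_i \sum_j w_{ij} (x_i - \bar x)(x_j - \bar x)}
#'                {S^2 \sum_i \sum_j w_{ij}}, \quad
#'       S^2 = \frac1n \sum_i (x_i - \bar x)^2,}
#' with a z-value and two-sided normal p-value under either the
#' randomization null (moments from the permutation distribution of the
#' observed values) or the normality null. An exact-style Monte-Carlo
#' permutation p-value is available via \code{n_perm}.
#'
#' @param values numeric vector, one value per unit, in weight-matrix order.
#' @param W a \code{\link{build_weights}} result.
#' @param standardization \code{"row"} (default) or \code{"binary"}.
#' @param null \code{"randomization"} (default) or \code{"normality"}.
#' @param n_perm if positive, also compute a permutation p-value from this
#'   many random permutations.
#' @param seed RNG seed used for the permutations.
#' @return object of class \code{moran_result}: list with \code{statistic},
#'   \code{expectation} (\eqn{-1/(n-1)}), \code{variance}, \code{z_value},
#'   \code{p_value}, and optionally \code{p_perm}.
#' @export
global_moran <- function(values, W, standardization = c("row", "binary"),
                         null = c("randomization", "normality"),
                         n_perm = 0L, seed = 1L) {
  null <- match.arg(null)
  Wm <- pick_w(W, standardization)
  n <- length(values)
  if (n != length(W$labels)) stop("values length does not match weights")
  if (n < 3L) stop("Moran's I needs at least 3 units")
  d <- values - mean(values)
  ssd <- sum(d^2)
  if (ssd <= 0) stop("degenerate variance: values are constant")
  S0 <- sum(Wm)
  I_of <- function(dd) sum(Wm * outer(dd, dd)) / (sum(dd^2) / n * S0)
  I <- I_of(d)
  S1 <- 0.5 * sum((Wm + t(Wm))^2)
  S2 <- sum((rowSums(Wm) + colSums(Wm))^2)
  EI <- -1 / (n - 1)
  VI <- if (null == "normality") {
    (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(d^4) / ssd^2
    (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
       b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  z <- (I - EI) / sqrt(VI)
  out <- list(statistic = I, expectation = EI, variance = VI,
              z_value = z, p_value = 2 * stats::pnorm(-abs(z)),
              standardization = match.arg(standardization), null = null)
  if (n_perm > 0L) {
    perm <- local({
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      replicate(n_perm, I_of(sample(d)))
    })
    out$p_perm <- (1 + sum(abs(perm - EI) >= abs(I - EI))) / (n_perm + 1)
    out$perm_var <- stats::var(perm)
  }
  structure(out, class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), z = %.3f, p = %.4f [%s null]\n",
              x$statistic, x$expectation, x$z_value, x$p_value, x$null))
  invisible(x)
}

#' Moran scatter quadrant classification
#'
#' Classifies each unit by the sign of its deviation from the mean
#' (\eqn{d_i}) and of the row-standardized spatial lag of deviations
#' (\eqn{l_i = \sum_j \tilde w_{ij} d_j}): HH when both are positive
#' (high-efficiency unit in a high-efficiency neighbourhood), LL when both
#' negative, LH and HL for the discordant cases. Exact zeros (never
#' observed in 3-decimal data) are assigned to the positive side. The
#' agglomeration share is the fraction of units in HH or LL.
#'
#' @param values numeric vector in weight-matrix order.
#' @param W a \code{\link{build_weights}} result.
#' @return object of class \code{quadrant_assignment}: data frame with
#'   columns \code{unit}, \code{deviation}, \code{lag}, \code{quadrant},
#'   and attribute \code{share_agglomeration}.
#' @export
moran_quadrants <- function(values, W) {
  Wm <- pick_w(W, "row")
  if (length(values) != length(W$labels))
    stop("values length does not match weights")
  d <- values - mean(values)
  l <- as.vector(Wm %*% d)
  hi_d <- d >= 0
  hi_l <- l >= 0
  quad <- ifelse(hi_d & hi_l, "HH",
          ifelse(!hi_d & !hi_l, "LL",
          ifelse(!hi_d & hi_l, "LH", "HL")))
  out <- data.frame(unit = W$labels, deviation = d, lag = l,
                    quadrant = quad, stringsAsFactors = FALSE)
  attr(out, "share_agglomeration") <- mean(quad %in% c("HH", "LL"))
  class(out) <- c("quadrant_assignment", "data.frame")
  out
}

#' Cluster table across years
#'
#' Assembles per-year Moran-scatter quadrant memberships into one table:
#' for each year and quadrant, the member units and their count.
#'
#' @param assignments named list of \code{\link{moran_quadrants}} results,
#'   one per year, sharing a label set.
#' @return data frame with columns \code{year}, \code{quadrant},
#'   \code{units} (comma-separated) and \code{count}.
#' @export
cluster_table <- function(assignments) {
  if (!length(assignments)) stop("no assignments given")
  labs <- assignments[[1]]$unit
  for (a in assignments)
    if (!identical(sort(a$unit), sort(labs)))
      stop("assignments do not share a label set")
  quads <- c("HH", "LL", "LH", "HL")
  rows <- lapply(names(assignments), function(yr) {
    a <- assignments[[yr]]
    data.frame(year = yr, quadrant = quads,
               units = vapply(quads, function(q)
                 paste(a$unit[a$quadrant == q], collapse = ", "), ""),
               count = vapply(quads, function(q)
                 sum(a$quadrant == q), integer(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Yearly global Moran table for a score panel
#'
#' Computes \code{\link{global_moran}} independently for every column
#' (year) of a units-by-years score matrix.
#'
#' @param scores n x T numeric matrix in weight-matrix row order.
#' @param W a \code{\link{build_weights}} result.
#' @param ... passed on to \code{\link{global_moran}}.
#' @return data frame with columns \code{year}, \code{I}, \code{Z}, \code{p}.
#' @export
moran_by_year <- function(scores, W, ...) {
  scores <- as.matrix(scores)
  res <- lapply(seq_len(ncol(scores)), function(ti)
    global_moran(scores[, ti], W, ...))
  data.frame(year = colnames(scores),
             I = vapply(res, `[[`, numeric(1), "statistic"),
             Z = vapply(res, `[[`, numeric(1), "z_value"),
             p = vapply(res, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE)
}
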