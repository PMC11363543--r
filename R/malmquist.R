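# Global-frontier Malmquist productivity index. Productivity change between
# adjacent periods is the ratio of SBM efficiencies measured against one
# pooled all-period reference technology, which makes the index transitive
# across periods; it decomposes multiplicatively into catch-up to the
# contemporaneous frontier (EC) and the frontier shift itself (TC).

#' SBM efficiency of a point against an arbitrary reference set
#'
#' Standard (non-super) non-oriented SBM of one observation measured
#' against a stated reference technology: either the contemporaneous
#' period's observations or the pooled all-period set. The evaluated point
#' need not be a member of the reference; if it lies outside the reference
#' envelope the program is infeasible and an error is raised.
#'
#' @param x input vector (length m) of the evaluated point.
#' @param y output vector (length s).
#' @param ref_inputs m x N reference input matrix.
#' @param ref_outputs s x N reference output matrix.
#' @param rts returns-to-scale, \code{"variable"} or \code{"constant"}.
#' @return the efficiency score (a positive scalar, \eqn{\le 1} whenever
#'   the point belongs to the reference set).
#' @export
efficiency_vs_reference <- function(x, y, ref_inputs, ref_outputs,
                                    rts = c("variable", "constant")) {
  rts <- match.arg(rts)
  Xr <- as.matrix(ref_inputs); Yr <- as.matrix(ref_outputs)
  if (any(Xr <= 0) || any(Yr <= 0) || any(x <= 0) || any(y <= 0))
    stop("SBM requires strictly positive data")
  m <- nrow(Xr); s <- nrow(Yr); n <- ncol(Xr)
  stopifnot(length(x) == m, length(y) == s, ncol(Yr) == n)
  # row normalisation by the evaluated point (units-invariance of SBM)
  Xn <- Xr / x
  Yn <- Yr / y
  cvec <- c(1, rep(0, n), -rep(1 / m, m), rep(0, s))
  A <- rbind(
    c(1, rep(0, n), rep(0, m), rep(1 / s, s)),
    cbind(rep(1, m), -Xn, -diag(m), matrix(0, m, s)),
    cbind(rep(1, s), -Yn, matrix(0, s, m), diag(s)))
  b <- c(1, rep(0, m + s))
  if (rts == "variable") {
    A <- rbind(A, c(-1, rep(1, n), rep(0, m + s)))
    b <- c(b, 0)
  }
  sol <- solve_lp(cvec, A, b, rep("=", length(b)))
  if (sol$status == "infeasible")
    stop("point lies outside the reference envelope (SBM infeasible)")
  if (sol$status != "optimal")
    stop("SBM linear program failed with status '", sol$status, "'")
  sol$value
}

#' Global Malmquist chain over a panel
#'
#' For every unit and every adjacent period pair (t, t+1) computes
#' \itemize{
#'   \item \code{mi}: ratio of efficiencies against the pooled all-period
#'     ("global") frontier, \eqn{E^g_{t+1} / E^g_t};
#'   \item \code{ec}: ratio of contemporaneous-frontier efficiencies,
#'     \eqn{E^{t+1}(x^{t+1},y^{t+1}) / E^t(x^t,y^t)};
#'   \item \code{tc}: the residual frontier-shift term \code{mi / ec}.
#' }
#' All efficiencies are standard (non-super) non-oriented SBM under the
#' requested returns to scale; every evaluated point is a member of its
#' reference set, so all programs are feasible.
#'
#' @param panel a \code{\link{panel_dataset}} with at least two periods.
#' @param rts returns-to-scale for all frontiers.
#' @return data frame with columns \code{unit}, \code{from}, \code{to},
#'   \code{mi}, \code{ec}, \code{tc}; the matrices of global and
#'   contemporaneous scores are attached as attributes \code{"global"} and
#'   \code{"contemporaneous"}.
#' @export
malmquist_chain <- function(panel, rts = c("variable", "constant")) {
  rts <- match.arg(rts)
  stopifnot(inherits(panel, "panel_dataset"))
  n <- length(panel$units)
  Tt <- length(panel$periods)
  if (Tt < 2L) stop("Malmquist chain needs at least two periods")
  per_X <- lapply(seq_len(Tt), function(ti)
    t(panel$inputs[, , ti, drop = FALSE][, , 1, drop = TRUE]))
  per_Y <- lapply(seq_len(Tt), function(ti)
    t(panel$outputs[, , ti, drop = FALSE][, , 1, drop = TRUE]))
  Xg <- do.call(cbind, per_X)
  Yg <- do.call(cbind, per_Y)
  Eg <- matrix(NA_real_, n, Tt, dimnames = list(panel$units, panel$periods))
  Et <- matrix(NA_real_, n, Tt, dimnames = list(panel$units, panel$periods))
  for (ti in seq_len(Tt)) {
    for (j in seq_len(n)) {
      Eg[j, ti] <- efficiency_vs_reference(per_X[[ti]][, j], per_Y[[ti]][, j],
                                           Xg, Yg, rts = rts)
      Et[j, ti] <- sbm_score(dea_problem(per_X[[ti]], per_Y[[ti]], j,
                                         rts = rts))$score
    }
  }
  res <- expand.grid(unit = panel$units, pair = seq_len(Tt - 1L),
                     stringsAsFactors = FALSE)
  res <- res[order(match(res$unit, panel$units), res$pair), ]
  res$from <- panel$periods[res$pair]
  res$to <- panel$periods[res$pair + 1L]
  idx <- cbind(match(res$unit, panel$units), res$pair)
  res$mi <- Eg[cbind(idx[, 1], idx[, 2] + 1L)] / Eg[idx]
  res$ec <- Et[cbind(idx[, 1], idx[, 2] + 1L)] / Et[idx]
  res$tc <- res$mi / res$ec
  res$pair <- NULL
  rownames(res) <- NULL
  attr(res, "global") <- Eg
  attr(res, "contemporaneous") <- Et
  res
}

#' Summarise a Malmquist chain
#'
#' Per-unit averages over the T-1 adjacent-period pairs use the geometric
#' mean (the standard average for multiplicative index numbers: it
#' preserves the identity MI = EC x TC). The national cross-unit means of
#' the per-unit averages are arithmetic.
#'
#' @param results data frame from \code{\link{malmquist_chain}}, with
#'   columns \code{unit}, \code{mi}, \code{ec}, \code{tc}.
#' @return list with \code{per_unit} (units x 3 matrix of MI, EC, TC) and
#'   \code{national} (named length-3 vector of arithmetic means).
#' @export
summarize_malmquist <- function(results) {
  stopifnot(all(c("unit", "mi", "ec", "tc") %in% names(results)))
  vals <- as.matrix(results[, c("mi", "ec", "tc")])
  if (anyNA(vals) || any(vals <= 0))
    stop("Malmquist components must be strictly positive")
  units <- unique(results$unit)
  per_unit <- t(vapply(units, function(u) {
    sub <- vals[results$unit == u, , drop = FALSE]
    exp(colMeans(log(sub)))
  }, numeric(3)))
  colnames(per_unit) <- c("MI", "EC", "TC")
  rownames(per_unit) <- units
  list(per_unit = per_unit, national = colMeans(per_unit))
}
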