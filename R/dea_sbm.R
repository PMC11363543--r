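# Slacks-based measure (SBM) DEA and its super-efficiency variant, both
# non-oriented and solved as linear programs after the Charnes-Cooper
# change of variables (every primal variable is multiplied by a scale
# factor t and the fractional objective's denominator is normalised to 1).

#' Construct a DEA problem
#'
#' @param input_matrix strictly positive m x n matrix (rows = inputs,
#'   columns = units).
#' @param output_matrix strictly positive s x n matrix.
#' @param evaluated integer index of the unit under evaluation.
#' @param rts returns-to-scale: \code{"variable"} (convexity constraint
#'   \eqn{\sum \lambda_j = 1}) or \code{"constant"}.
#' @return object of class \code{dea_problem}.
#' @export
dea_problem <- function(input_matrix, output_matrix, evaluated,
                        rts = c("variable", "constant")) {
  rts <- match.arg(rts)
  X <- as.matrix(input_matrix)
  Y <- as.matrix(output_matrix)
  if (ncol(X) != ncol(Y)) stop("input and output matrices must share units")
  if (any(X <= 0) || any(Y <= 0))
    stop("SBM requires strictly positive inputs and outputs")
  evaluated <- as.integer(evaluated)
  if (evaluated < 1L || evaluated > ncol(X)) stop("evaluated index out of range")
  structure(list(X = X, Y = Y, evaluated = evaluated, rts = rts),
            class = "dea_problem")
}

dea_solution <- function(score, lambdas, input_target, output_target,
                         input_slacks, output_slacks, feasible, stage) {
  structure(list(score = score, lambdas = lambdas,
                 input_target = input_target, output_target = output_target,
                 input_slacks = input_slacks, output_slacks = output_slacks,
                 feasible = feasible, stage = stage),
            class = "dea_solution")
}

#' @export
print.dea_solution <- function(x, ...) {
  cat(sprintf("dea_solution [%s]: score %.6f (%s)\n", x$stage, x$score,
              if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Standard (non-oriented) SBM efficiency score
#'
#' Solves, for the evaluated unit \eqn{(x_0, y_0)} against the full
#' reference set,
#' \deqn{\min \frac{1 - \frac1m \sum_i s^-_i / x_{i0}}
#'                 {1 + \frac1s \sum_k s^+_k / y_{k0}}}
#' subject to \eqn{x_0 = X\lambda + s^-}, \eqn{y_0 = Y\lambda - s^+},
#' \eqn{\sum_j \lambda_j = 1} (under variable returns), all variables
#' nonnegative. The score lies in (0, 1], with 1 meaning no feasible
#' reference combination improves on the unit in any input or output.
#'
#' @param problem a \code{\link{dea_problem}}.
#' @return a \code{dea_solution} with the optimal score, reference weights
#'   \code{lambdas}, slack vectors, and projection targets
#'   \eqn{\bar x = x_0 - s^-}, \eqn{\bar y = y_0 + s^+}.
#' @export
sbm_score <- function(problem) {
  stopifnot(inherits(problem, "dea_problem"))
  X <- problem$X; Y <- problem$Y
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  j0 <- problem$evaluated
  x0 <- X[, j0]; y0 <- Y[, j0]
  # normalise every row by the evaluated unit's own level: the SBM score is
  # units-invariant and the tableau becomes O(1), which keeps pivot
  # tolerances meaningful for data spanning many orders of magnitude
  Xn <- X / x0
  Yn <- Y / y0
  one_m <- rep(1, m); one_s <- rep(1, s)
  # variables: t, Lambda (n), S- (m), S+ (s), all scaled by t
  cvec <- c(1, rep(0, n), -rep(1 / m, m), rep(0, s))
  A <- rbind(
    c(1, rep(0, n), rep(0, m), rep(1 / s, s)),           # denominator = 1
    cbind(one_m, -Xn, -diag(m), matrix(0, m, s)),        # t*1 = Xn Lam + S-
    cbind(one_s, -Yn, matrix(0, s, m), diag(s)))         # t*1 = Yn Lam - S+
  b <- c(1, rep(0, m + s))
  if (problem$rts == "variable") {
    A <- rbind(A, c(-1, rep(1, n), rep(0, m + s)))       # sum Lam = t
    b <- c(b, 0)
  }
  sol <- solve_lp(cvec, A, b, rep("=", length(b)))
  if (sol$status != "optimal")
    stop("SBM linear program failed with status '", sol$status, "'")
  t_opt <- sol$x[1]
  if (t_opt <= 0) stop("degenerate Charnes-Cooper scale in SBM solution")
  lam <- sol$x[2:(n + 1)] / t_opt
  sm <- sol$x[(n + 2):(n + 1 + m)] / t_opt * x0
  sp <- sol$x[(n + 2 + m):(n + 1 + m + s)] / t_opt * y0
  dea_solution(score = sol$value, lambdas = lam,
               input_target = x0 - sm, output_target = y0 + sp,
               input_slacks = sm, output_slacks = sp,
               feasible = TRUE, stage = "sbm")
}

#' Super-efficiency SBM score
#'
#' Re-scores an SBM-efficient unit with itself removed from the reference
#' set, solving
#' \deqn{\min \frac{\frac1m \sum_i \bar x_i / x_{i0}}
#'                 {\frac1s \sum_k \bar y_k / y_{k0}}}
#' subject to \eqn{\bar x \ge \sum_{j \ne 0} \lambda_j x_j},
#' \eqn{\bar y \le \sum_{j \ne 0} \lambda_j y_j}, \eqn{\bar x \ge x_0},
#' \eqn{0 \le \bar y \le y_0}, and \eqn{\sum_{j \ne 0} \lambda_j = 1} under
#' variable returns. Scores are \eqn{\ge 1} for units on the frontier,
#' allowing efficient units to be ranked.
#'
#' @param problem a \code{\link{dea_problem}}; the evaluated unit is
#'   excluded from its reference set automatically.
#' @return a \code{dea_solution} with stage \code{"super_sbm"}. If the
#'   exclusion renders the program infeasible the solution carries
#'   \code{feasible = FALSE} and an \code{NA} score.
#' @export
super_sbm_score <- function(problem) {
  stopifnot(inherits(problem, "dea_problem"))
  X <- problem$X; Y <- problem$Y
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  if (n < 2L) stop("super-efficiency needs at least one other unit")
  j0 <- problem$evaluated
  x0 <- X[, j0]; y0 <- Y[, j0]
  # same row normalisation by the evaluated unit's levels as in sbm_score
  Xr <- (X / x0)[, -j0, drop = FALSE]; Yr <- (Y / y0)[, -j0, drop = FALSE]
  nr <- n - 1L
  one_m <- rep(1, m); one_s <- rep(1, s)
  # variables: t, Lambda (nr), Xbar (m), Ybar (s), all scaled by t
  cvec <- c(0, rep(0, nr), rep(1 / m, m), rep(0, s))
  A <- rbind(
    c(0, rep(0, nr), rep(0, m), rep(1 / s, s)),                 # denom = 1
    cbind(rep(0, m), Xr, -diag(m), matrix(0, m, s)),            # Xr Lam <= Xbar
    cbind(rep(0, s), Yr, matrix(0, s, m), -diag(s)),            # Yr Lam >= Ybar
    cbind(-one_m, matrix(0, m, nr), diag(m), matrix(0, m, s)),  # Xbar >= t*1
    cbind(-one_s, matrix(0, s, nr), matrix(0, s, m), diag(s)))  # Ybar <= t*1
  dir <- c("=", rep("<=", m), rep(">=", s), rep(">=", m), rep("<=", s))
  b <- rep(0, length(dir)); b[1] <- 1
  if (problem$rts == "variable") {
    A <- rbind(A, c(-1, rep(1, nr), rep(0, m + s)))
    dir <- c(dir, "=")
    b <- c(b, 0)
  }
  sol <- solve_lp(cvec, A, b, dir)
  if (sol$status == "infeasible")
    return(dea_solution(score = NA_real_, lambdas = rep(NA_real_, n),
                        input_target = rep(NA_real_, m),
                        output_target = rep(NA_real_, s),
                        input_slacks = rep(NA_real_, m),
                        output_slacks = rep(NA_real_, s),
                        feasible = FALSE, stage = "super_sbm"))
  if (sol$status != "optimal")
    stop("super-SBM linear program failed with status '", sol$status, "'")
  t_opt <- sol$x[1]
  if (t_opt <= 0) stop("degenerate Charnes-Cooper scale in super-SBM solution")
  lam_r <- sol$x[2:(nr + 1)] / t_opt
  xbar <- sol$x[(nr + 2):(nr + 1 + m)] / t_opt * x0
  ybar <- sol$x[(nr + 2 + m):(nr + 1 + m + s)] / t_opt * y0
  lam <- numeric(n)
  lam[-j0] <- lam_r
  dea_solution(score = sol$value, lambdas = lam,
               input_target = xbar, output_target = ybar,
               input_slacks = xbar - x0, output_slacks = y0 - ybar,
               feasible = TRUE, stage = "super_sbm")
}

#' Two-stage SBM / super-SBM score
#'
#' The standard SBM score caps at 1, so efficient units cannot be ranked.
#' This runs \code{\link{sbm_score}} first; units scoring at least
#' \code{1 - tol} are re-scored by \code{\link{super_sbm_score}}, producing
#' the familiar mix of values above and below 1. Should the super-efficiency
#' program be infeasible, the unit keeps its SBM score of 1 with the
#' infeasibility flagged in the returned certificate.
#'
#' @param problem a \code{\link{dea_problem}}.
#' @param tol efficiency classification threshold (default \code{1e-6},
#'   on the scale of LP solver tolerances).
#' @return a \code{dea_solution}.
#' @export
two_stage_score <- function(problem, tol = 1e-6) {
  base <- sbm_score(problem)
  if (base$score < 1 - tol) return(base)
  super <- super_sbm_score(problem)
  if (!super$feasible) {
    base$feasible <- FALSE
    base$stage <- "super_sbm"
    return(base)
  }
  super
}

#' Score every unit in every period of a panel
#'
#' Applies \code{\link{two_stage_score}} unit by unit within each period
#' separately, so each year defines its own frontier.
#'
#' @param panel a \code{\link{panel_dataset}}.
#' @param tol passed to \code{\link{two_stage_score}}.
#' @return an \code{efficiency_table}: list with \code{scores} (n x T
#'   matrix), \code{stage} (n x T character matrix), and
#'   \code{certificates} (list of lists of \code{dea_solution}s).
#' @export
score_panel <- function(panel, tol = 1e-6) {
  stopifnot(inherits(panel, "panel_dataset"))
  n <- length(panel$units)
  Tt <- length(panel$periods)
  scores <- matrix(NA_real_, n, Tt,
                   dimnames = list(panel$units, panel$periods))
  stage <- matrix(NA_character_, n, Tt,
                  dimnames = list(panel$units, panel$periods))
  certs <- vector("list", Tt)
  names(certs) <- as.character(panel$periods)
  for (ti in seq_len(Tt)) {
    X <- t(panel$inputs[, , ti, drop = FALSE][, , 1, drop = TRUE])
    Y <- t(panel$outputs[, , ti, drop = FALSE][, , 1, drop = TRUE])
    certs[[ti]] <- vector("list", n)
    for (j in seq_len(n)) {
      sol <- tryCatch(
        two_stage_score(dea_problem(X, Y, j), tol = tol),
        error = function(e) stop("scoring failed for unit ", panel$units[j],
                                 ", period ", panel$periods[ti], ": ",
                                 conditionMessage(e)))
      scores[j, ti] <- sol$score
      stage[j, ti] <- if (!sol$feasible) "infeasible" else sol$stage
      certs[[ti]][[j]] <- sol
    }
  }
  structure(list(scores = scores, stage = stage, certificates = certs),
            class = "efficiency_table")
}

#' @export
print.efficiency_table <- function(x, ...) {
  cat("efficiency_table:", nrow(x$scores), "units x", ncol(x$scores),
      "periods\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Format an efficiency table with mean row and column
#'
#' Reproduces the published layout: one row per unit, one column per year,
#' plus an arithmetic mean column per unit and mean row per year (the grand
#' mean sits in the corner). Values are rounded for display only.
#'
#' @param scores n x T numeric matrix (e.g. \code{score_panel(...)$scores}).
#' @param digits display rounding (default 3, matching the printed tables).
#' @return a numeric matrix with an extra \code{"Mean"} row and column.
#' @export
format_score_table <- function(scores, digits = 3) {
  scores <- as.matrix(scores)
  out <- cbind(scores, Mean = aggregate_table(scores, "rows"))
  out <- rbind(out, Mean = c(aggregate_table(scores, "columns"),
                             aggregate_table(scores, "all")))
  round(out, digits)
}
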