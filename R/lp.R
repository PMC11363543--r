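# Dense two-phase primal simplex. The DEA linear programs solved here are
# small (a dozen rows, a few hundred columns at most), heavily degenerate at
# the optimum, and equality-constrained after the Charnes-Cooper change of
# variables; Bland's anti-cycling rule keeps the method finite on them.

#' Solve a small linear program
#'
#' Minimises \code{c'x} subject to \code{A x (dir) b} and \code{x >= 0},
#' where each row's direction is one of \code{"<="}, \code{">="}, \code{"="}.
#' A plain dense two-phase simplex with Bland's rule, intended for the
#' moderate-size programs arising in slacks-based DEA.
#'
#' @param cvec objective coefficients (length = number of variables).
#' @param A constraint matrix.
#' @param b right-hand side vector.
#' @param dir character vector of row directions.
#' @param tol pivot tolerance.
#' @param max_iter iteration cap per phase.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded" or
#'   "maxiter"), and for optimal solutions \code{x} and \code{value}.
#' @keywords internal
solve_lp <- function(cvec, A, b, dir, tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == length(b), ncol(A) == length(cvec),
            length(dir) == length(b), all(dir %in% c("<=", ">=", "=")))
  m <- nrow(A)
  nv <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- ifelse(dir[neg] == "<=", ">=", ifelse(dir[neg] == ">=", "<=", "="))
  }
  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  slack_cols <- matrix(0, m, n_le)
  surp_cols <- matrix(0, m, n_ge)
  if (n_le) slack_cols[cbind(which(dir == "<="), seq_len(n_le))] <- 1
  if (n_ge) surp_cols[cbind(which(dir == ">="), seq_len(n_ge))] <- -1
  art_rows <- which(dir != "<=")
  n_art <- length(art_rows)
  art_cols <- matrix(0, m, n_art)
  if (n_art) art_cols[cbind(art_rows, seq_len(n_art))] <- 1
  Tab <- cbind(A, slack_cols, surp_cols, art_cols, b)
  ntot <- nv + n_le + n_ge + n_art
  basis <- integer(m)
  basis[dir == "<="] <- nv + seq_len(n_le)
  basis[art_rows] <- nv + n_le + n_ge + seq_len(n_art)

  pivot <- function(Tab, r, cj) {
    Tab[r, ] <- Tab[r, ] / Tab[r, cj]
    upd <- which(abs(Tab[, cj]) > 1e-13)
    upd <- upd[upd != r]
    if (length(upd))
      Tab[upd, ] <- Tab[upd, ] - outer(Tab[upd, cj], Tab[r, ])
    Tab
  }
  run_phase <- function(Tab, basis, obj, allowed) {
    for (it in seq_len(max_iter)) {
      cb <- obj[basis]
      red <- obj[allowed] - as.vector(crossprod(Tab[, allowed, drop = FALSE], cb))
      ent <- which(red < -tol)
      if (!length(ent)) return(list(Tab = Tab, basis = basis, ok = TRUE))
      cj <- allowed[min(ent)]               # Bland: lowest eligible index enters
      col <- Tab[, cj]
      rhs <- Tab[, ntot + 1L]
      cand <- which(col > tol)
      if (!length(cand)) return(list(ok = FALSE, unbounded = TRUE))
      ratio <- rhs[cand] / col[cand]
      rmin <- min(ratio)
      r <- cand[ratio <= rmin + tol]
      r <- r[which.min(basis[r])]           # Bland on the leaving variable too
      Tab <- pivot(Tab, r, cj)
      basis[r] <- cj
    }
    list(ok = FALSE, maxit = TRUE)
  }

  if (n_art) {
    obj1 <- c(rep(0, nv + n_le + n_ge), rep(1, n_art))
    ph1 <- run_phase(Tab, basis, obj1, seq_len(ntot))
    if (!ph1$ok) return(list(status = "maxiter"))
    Tab <- ph1$Tab
    basis <- ph1$basis
    if (sum(obj1[basis] * Tab[, ntot + 1L]) > 1e-7)
      return(list(status = "infeasible"))
    art_idx <- nv + n_le + n_ge + seq_len(n_art)
    for (r in which(basis %in% art_idx)) {
      cand <- which(abs(Tab[r, seq_len(nv + n_le + n_ge)]) > tol)
      if (length(cand)) {
        Tab <- pivot(Tab, r, cand[1])
        basis[r] <- cand[1]
      }
    }
    allowed <- seq_len(nv + n_le + n_ge)
  } else {
    allowed <- seq_len(ntot)
  }
  obj2 <- c(cvec, rep(0, ntot - nv))
  ph2 <- run_phase(Tab, basis, obj2, allowed)
  if (!ph2$ok)
    return(list(status = if (isTRUE(ph2$unbounded)) "unbounded" else "maxiter"))
  Tab <- ph2$Tab
  basis <- ph2$basis
  x <- numeric(ntot)
  x[basis] <- Tab[, ntot + 1L]
  list(status = "optimal", x = x[seq_len(nv)],
       value = sum(cvec * x[seq_len(nv)]))
}
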