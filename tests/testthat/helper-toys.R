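# Shared fixtures: tiny DEA instances with known solutions, and an
# enumeration oracle for the SBM objective over the lambda simplex.

# Single input, single output; A and B span the VRS frontier, C is
# dominated by A (same output from twice the input).
toy_abc <- function() {
  list(X = matrix(c(2, 4, 4), 1), Y = matrix(c(2, 4, 2), 1))
}

simplex_grid <- function(n, res) {
  if (n == 1) return(matrix(1, 1, 1))
  if (n == 2) {
    i <- 0:res
    return(cbind(i, res - i) / res)
  }
  if (n == 3) {
    g <- expand.grid(i = 0:res, j = 0:res)
    g <- g[g$i + g$j <= res, ]
    return(cbind(g$i, g$j, res - g$i - g$j) / res)
  }
  g <- expand.grid(i = 0:res, j = 0:res, k = 0:res)
  g <- g[g$i + g$j + g$k <= res, ]
  cbind(g$i, g$j, g$k, res - g$i - g$j - g$k) / res
}

# SBM objective for given lambda rows: slacks are determined by lambda
# (equality constraints), so each feasible lambda has a closed-form value.
sbm_obj_at <- function(L, X, Y, j0) {
  XL <- L %*% t(X)
  YL <- L %*% t(Y)
  x0 <- X[, j0]
  y0 <- Y[, j0]
  feas <- rowSums(sweep(XL, 2, x0, ">")) == 0 &
    rowSums(sweep(YL, 2, y0, "<")) == 0
  out <- rep(Inf, nrow(L))
  if (any(feas)) {
    sm <- sweep(-XL[feas, , drop = FALSE], 2, x0, "+")
    sp <- sweep(YL[feas, , drop = FALSE], 2, y0, "-")
    out[feas] <- (1 - rowMeans(sweep(sm, 2, x0, "/"))) /
      (1 + rowMeans(sweep(sp, 2, y0, "/")))
  }
  out
}

# Grid enumeration over the lambda simplex (resolution 1/res) followed by
# local grid refinement around the incumbent, as an LP-free oracle for the
# standard SBM score.
sbm_grid_oracle <- function(X, Y, j0, res = 200, refine = 4) {
  n <- ncol(X)
  L <- simplex_grid(n, res)
  v <- sbm_obj_at(L, X, Y, j0)
  best <- L[which.min(v), ]
  h <- 1 / res
  out <- min(v[is.finite(v)])
  for (r in seq_len(refine)) {
    offs <- as.matrix(do.call(expand.grid,
                              rep(list(seq(-h, h, length.out = 9)), n - 1)))
    cand <- sweep(offs, 2, best[-n], "+")
    cand <- cbind(cand, 1 - rowSums(cand))
    cand <- cand[rowSums(cand < 0) == 0, , drop = FALSE]
    if (!nrow(cand)) break
    v <- sbm_obj_at(cand, X, Y, j0)
    if (all(!is.finite(v))) break
    best <- cand[which.min(v), ]
    h <- h / 4
    out <- min(out, min(v[is.finite(v)]))
  }
  out
}

# Ring (cycle) adjacency over k labelled units.
ring_weights <- function(k) {
  labs <- sprintf("U%02d", seq_len(k))
  edges <- cbind(labs, labs[c(2:k, 1)])
  build_weights(edges, labs)
}
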