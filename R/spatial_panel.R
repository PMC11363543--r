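# Maximum-likelihood spatial panel econometrics: spatial Durbin (SDM),
# spatial lag (SAR) and spatial error (SEM) models with fixed effects
# absorbed by the within transformation, estimated by concentrating the
# log-likelihood in the spatial parameter. The log-determinant
# T ln|I - rho W| is evaluated from the eigenvalues of the (time-invariant)
# weight matrix. Specification tests (LM, robust LM, LR, Wald, Hausman) and
# the simulation-based direct/indirect effect decomposition follow the
# standard spatial econometrics toolkit conventions.

#' Two-way within transformation
#'
#' Subtracts unit means and/or period means (adding back the grand mean
#' when both are removed), absorbing additive unit and period effects.
#'
#' @param M numeric n x T matrix (units x periods), balanced.
#' @param effects which effects to absorb: \code{"both"}, \code{"individual"},
#'   \code{"time"}, or \code{"none"}.
#' @return the transformed matrix.
#' @export
demean_two_way <- function(M, effects = c("both", "individual", "time", "none")) {
  effects <- match.arg(effects)
  M <- as.matrix(M)
  if (anyNA(M)) stop("unbalanced panel: missing cells")
  switch(effects,
         both = M - rowMeans(M)[row(M)] - colMeans(M)[col(M)] + mean(M),
         individual = M - rowMeans(M)[row(M)],
         time = M - colMeans(M)[col(M)],
         none = M)
}

demean_array <- function(A, effects) {
  for (j in seq_len(dim(A)[3]))
    A[, , j] <- demean_two_way(A[, , j], effects)
  A
}

# Stack an n x T matrix period-major into a length-nT vector, and apply W
# within each period block ((I_T kron W) v).
stack_panel <- function(M) as.vector(M)
apply_W <- function(M, Wm) as.vector(Wm %*% M)

spatial_interval <- function(Wm) {
  om <- eigen(Wm, only.values = TRUE)$values
  om <- Re(om[abs(Im(om)) < 1e-8])
  if (!length(om) || all(abs(om) < 1e-12)) return(list(omega = 0, lo = -1, hi = 1))
  list(omega = om, lo = 1 / min(om) + 1e-6, hi = 1 - 1e-6)
}

build_design <- function(y, X, Wm, model, effects, transform = NULL) {
  n <- nrow(y); Tt <- ncol(y); k <- dim(X)[3]
  # spatial lags are formed on the raw data and only then transformed: the
  # within projector does not commute with a row-standardized W (its column
  # sums differ from 1), so W applied to demeaned data would mis-state the
  # profile likelihood of the dummy-variable model
  Wy_raw <- apply(y, 2, function(col) Wm %*% col)
  WX_raw <- X
  for (j in seq_len(k))
    WX_raw[, , j] <- apply(X[, , j], 2, function(col) Wm %*% col)
  tf <- if (is.null(transform)) function(M) demean_two_way(M, effects)
        else transform
  tf_array <- function(A) {
    for (j in seq_len(dim(A)[3])) A[, , j] <- tf(A[, , j])
    A
  }
  yd <- tf(y)
  Xd <- tf_array(X)
  WXd <- tf_array(WX_raw)
  Wyd <- tf(Wy_raw)
  yv <- stack_panel(yd)
  Wy <- stack_panel(Wyd)
  Xm <- matrix(Xd, n * Tt, k)
  WXm <- matrix(WXd, n * Tt, k)
  xn <- dimnames(X)[[2]]
  if (is.null(xn)) xn <- paste0("X", seq_len(k))
  Z <- if (model == "sdm") cbind(Xm, WXm) else Xm
  colnames(Z) <- if (model == "sdm") c(xn, paste0("W.", xn)) else xn
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop("singular regressor matrix after demeaning (constant column?)")
  list(yv = yv, Z = Z, Xm = Xm, WXm = WXm, Wy = Wy, n = n, Tt = Tt,
       k = k, xnames = xn, yd = yd, Xd = Xd)
}

#' Fit a spatial panel model by maximum likelihood
#'
#' Fits one of
#' \itemize{
#'   \item SDM: \eqn{y = \rho (I_T \otimes W) y + X\beta + (I_T \otimes W) X \theta + \epsilon},
#'   \item SAR: the same with \eqn{\theta = 0},
#'   \item SEM: \eqn{y = X\beta + u,\; u = \lambda (I_T \otimes W) u + \epsilon},
#' }
#' on within-transformed data, by quasi-maximum likelihood concentrated in
#' the spatial parameter. The spatial parameter is confined to the
#' admissible interval \eqn{(1/\omega_{\min}, 1)} given by the extreme
#' eigenvalues of the row-standardized weight matrix; the bounded
#' one-dimensional search uses tolerance \code{1e-8}. The covariance matrix
#' comes from the analytic information matrix; \eqn{R^2} is the squared
#' correlation of fitted and observed (transformed) responses. The
#' incidental-parameter (Lee-Yu) degrees-of-freedom correction of
#' \eqn{\sigma^2} for fixed-effects panels is available via \code{lee_yu}
#' but off by default.
#'
#' @param y n x T response matrix (units x periods).
#' @param X n x T x k covariate array.
#' @param W a \code{\link{build_weights}} result (row-standardized form is
#'   used).
#' @param model \code{"sdm"}, \code{"sar"} or \code{"sem"}.
#' @param effects fixed effects to absorb: \code{"both"} (default),
#'   \code{"individual"}, \code{"time"}, \code{"none"}, or
#'   \code{"random"} (individual random effects via quasi-demeaning, with
#'   variance components from a Swamy-Arora step; used by the Hausman test).
#' @param lee_yu apply the degrees-of-freedom correction to \eqn{\sigma^2}.
#' @return object of class \code{spatial_model_fit}: coefficients,
#'   \code{rho} (spatial parameter; the error parameter \eqn{\lambda} for
#'   SEM), \code{beta}, \code{theta} (SDM only), \code{sigma2},
#'   \code{loglik}, \code{vcov} (over coefficients, spatial parameter, and
#'   \eqn{\sigma^2}), \code{r2}, and a \code{coefficients} table with
#'   standard errors, z and p values.
#' @export
fit_spatial_panel <- function(y, X, W, model = c("sdm", "sar", "sem"),
                              effects = c("both", "individual", "time",
                                          "none", "random"),
                              lee_yu = FALSE) {
  model <- match.arg(model)
  effects <- match.arg(effects)
  y <- as.matrix(y)
  if (length(dim(X)) != 3L) stop("X must be an n x T x k array")
  Wm <- W$row_standardized
  n <- nrow(y); Tt <- ncol(y); k <- dim(X)[3]
  if (nrow(Wm) != n) stop("weight matrix dimension does not match panel")
  if (effects == "random") {
    # time fixed effects stay absorbed; individual effects treated as
    # random and removed by quasi-demeaning (applied after spatial lags
    # are formed, like the within transform)
    qd <- quasi_demean(y, X, Wm = Wm, model = model)
    transform <- function(M) {
      M <- demean_two_way(M, "time")
      M - qd$phi * rowMeans(M)
    }
    eff_used <- "none"
  } else {
    transform <- NULL
    eff_used <- effects
  }
  iv <- spatial_interval(Wm)
  no_w <- identical(iv$omega, 0)
  # with an all-zero weight matrix the Durbin terms vanish identically and
  # every model collapses to least squares; fit the regressor-only design
  # and pad the (zero) Durbin block back afterwards
  requested <- model
  if (no_w && model == "sdm") model <- "sar"
  d <- build_design(y, X, Wm, model, eff_used, transform = transform)
  ZtZ <- crossprod(d$Z)
  ZtZi <- solve(ZtZ)
  nT <- n * Tt
  # transformed-likelihood dimensions: with fixed effects absorbed, the
  # data live on an (n - 1)(T - 1)-dimensional subspace (or n(T - 1) /
  # (n - 1)T for one-way effects); the Lee-Yu option evaluates the exact
  # likelihood of the transformed model, removing the incidental-parameter
  # bias. For a row-stochastic W, cross-unit demeaning removes the unit
  # eigenvector, so ln|I - rho W| loses one ln(1 - rho) term.
  eff_n <- if (lee_yu && eff_used %in% c("both", "time")) n - 1L else n
  eff_T <- if (lee_yu && eff_used %in% c("both", "individual")) Tt - 1L else Tt
  dfree <- eff_n * eff_T
  drop_unit_eig <- lee_yu && eff_used %in% c("both", "time")

  if (model %in% c("sdm", "sar")) {
    conc <- function(rho) {
      r <- (d$yv - rho * d$Wy)
      e <- r - d$Z %*% (ZtZi %*% crossprod(d$Z, r))
      s2 <- sum(e^2) / dfree
      ld <- if (no_w) 0 else sum(log(1 - rho * iv$omega)) -
        (if (drop_unit_eig) log(1 - rho) else 0)
      -dfree / 2 * (log(2 * pi * s2) + 1) + eff_T * ld
    }
    if (no_w) {
      rho <- 0
    } else {
      op <- stats::optimize(conc, c(iv$lo, iv$hi), maximum = TRUE, tol = 1e-8)
      rho <- op$maximum
      if (rho <= iv$lo + 1e-5 || rho >= iv$hi - 1e-5)
        stop("spatial parameter at the boundary of the admissible interval")
    }
    r <- d$yv - rho * d$Wy
    delta <- as.vector(ZtZi %*% crossprod(d$Z, r))
    e <- as.vector(r - d$Z %*% delta)
    s2 <- sum(e^2) / dfree
    ll <- conc(rho)
    # analytic information matrix over (delta, rho, sigma2)
    kz <- ncol(d$Z)
    if (no_w) {
      Info <- rbind(cbind(ZtZ / s2, 0, 0),
                    c(rep(0, kz), 1, 0),
                    c(rep(0, kz), 0, nT / (2 * s2^2)))
    } else {
      Ai <- solve(diag(n) - rho * Wm)
      Wt <- Wm %*% Ai
      pvec <- numeric(nT)
      for (t in seq_len(Tt)) {
        idx <- (t - 1L) * n + seq_len(n)
        pvec[idx] <- Wt %*% (d$Z[idx, , drop = FALSE] %*% delta)
      }
      I1r <- crossprod(d$Z, pvec) / s2
      Irr <- eff_T * sum(diag(Wt %*% Wt + crossprod(Wt))) + sum(pvec^2) / s2
      Irs <- eff_T * sum(diag(Wt)) / s2
      Info <- rbind(cbind(ZtZ / s2, I1r, 0),
                    c(I1r, Irr, Irs),
                    c(rep(0, kz), Irs, dfree / (2 * s2^2)))
    }
    V <- solve(Info)
    pn <- c(colnames(d$Z), "rho", "sigma2")
    dimnames(V) <- list(pn, pn)
    fitted <- rho * d$Wy + d$Z %*% delta
    beta <- delta[seq_len(k)]
    theta <- if (model == "sdm") delta[k + seq_len(k)] else NULL
    est <- c(delta, rho)
    se <- sqrt(diag(V))[seq_along(est)]
  } else {
    conc <- function(lam) {
      B <- diag(n) - lam * Wm
      yt <- matrix(0, n, Tt)
      Xt <- array(0, c(n, Tt, k))
      for (t in seq_len(Tt)) {
        yt[, t] <- B %*% d$yd[, t]
        Xt[, t, ] <- B %*% matrix(d$Xd[, t, ], n)
      }
      Zt <- apply(Xt, 3, stack_panel)
      yv <- stack_panel(yt)
      bet <- qr.coef(qr(Zt), yv)
      e <- yv - Zt %*% bet
      s2 <- sum(e^2) / dfree
      ld <- if (no_w) 0 else sum(log(1 - lam * iv$omega)) -
        (if (drop_unit_eig) log(1 - lam) else 0)
      list(ll = -dfree / 2 * (log(2 * pi * s2) + 1) + eff_T * ld,
           bet = bet, s2 = s2, e = e, Zt = Zt)
    }
    if (no_w) {
      lam <- 0
    } else {
      op <- stats::optimize(function(l) conc(l)$ll, c(iv$lo, iv$hi),
                            maximum = TRUE, tol = 1e-8)
      lam <- op$maximum
      if (lam <= iv$lo + 1e-5 || lam >= iv$hi - 1e-5)
        stop("spatial parameter at the boundary of the admissible interval")
    }
    fin <- conc(lam)
    beta <- as.vector(fin$bet)
    s2 <- fin$s2
    ll <- fin$ll
    theta <- NULL
    if (no_w) {
      Irr <- 1; Irs <- 0
    } else {
      Bt <- Wm %*% solve(diag(n) - lam * Wm)
      Irr <- eff_T * sum(diag(Bt %*% Bt + crossprod(Bt)))
      Irs <- eff_T * sum(diag(Bt)) / s2
    }
    Info <- rbind(cbind(crossprod(fin$Zt) / s2, 0, 0),
                  c(rep(0, k), Irr, Irs),
                  c(rep(0, k), Irs, dfree / (2 * s2^2)))
    V <- solve(Info)
    pn <- c(d$xnames, "lambda", "sigma2")
    dimnames(V) <- list(pn, pn)
    fitted <- stack_panel(matrix(d$Xd, n * Tt, k) %*% beta)
    delta <- beta
    rho <- lam
    est <- c(beta, lam)
    se <- sqrt(diag(V))[seq_along(est)]
  }
  if (requested == "sdm" && model == "sar") {
    # re-expand the suppressed Durbin block as exact zeros
    theta <- rep(0, k)
    delta <- c(delta, theta)
    wn <- paste0("W.", d$xnames)
    pn <- c(d$xnames, wn, "rho", "sigma2")
    V2 <- matrix(0, 2 * k + 2, 2 * k + 2, dimnames = list(pn, pn))
    V2[c(seq_len(k), 2 * k + 1:2), c(seq_len(k), 2 * k + 1:2)] <- V
    V <- V2
    est <- c(est[seq_len(k)], theta, rho)
    se <- sqrt(diag(V))[seq_along(est)]
    model <- "sdm"
  }
  zval <- est / se
  coefs <- data.frame(estimate = est, std_error = se, z = zval,
                      p_value = 2 * stats::pnorm(-abs(zval)),
                      row.names = rownames(V)[seq_along(est)])
  r2 <- stats::cor(as.vector(fitted), d$yv)^2
  structure(list(model = model, effects = effects, rho = rho, beta = beta,
                 theta = theta, delta = delta, sigma2 = s2, loglik = ll,
                 vcov = V, r2 = r2, coefficients = coefs,
                 n = n, T = Tt, k = k, xnames = d$xnames,
                 lee_yu = lee_yu, dfree = dfree, n_par = nrow(V) - 1L),
            class = "spatial_model_fit")
}

#' @export
print.spatial_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s effects): %s = %.5f, sigma2 = %.6f, logLik = %.3f, R2 = %.3f\n",
              toupper(x$model), x$effects,
              if (x$model == "sem") "lambda" else "rho",
              x$rho, x$sigma2, x$loglik, x$r2))
  print(round(as.matrix(x$coefficients), 5))
  invisible(x)
}

# Swamy-Arora variance components for individual random effects. The
# auxiliary within/between regressions include the spatial lag of the
# response and the Durbin terms (all lags formed on raw data, then
# time-demeaned) so the components are estimated from the model the caller
# will fit, not from a misspecified aspatial one.
quasi_demean <- function(y, X, Wm = NULL, model = "sdm") {
  n <- nrow(y); Tt <- ncol(y); k <- dim(X)[3]
  vars <- lapply(seq_len(k), function(j) X[, , j])
  if (!is.null(Wm)) {
    Wy <- apply(y, 2, function(col) Wm %*% col)
    WX <- lapply(seq_len(k), function(j)
      apply(X[, , j], 2, function(col) Wm %*% col))
    vars <- if (model == "sdm") c(vars, WX, list(Wy)) else c(vars, list(Wy))
  }
  td <- function(M) demean_two_way(M, "time")
  yt <- td(y)
  vars <- lapply(vars, td)
  ka <- length(vars)
  Zw <- vapply(vars, function(M) as.vector(M - rowMeans(M)),
               numeric(n * Tt))
  ew <- stats::lm.fit(Zw, as.vector(yt - rowMeans(yt)))$residuals
  s2_nu <- sum(ew^2) / max(n * (Tt - 1) - ka, 1)
  Xb <- cbind(1, vapply(vars, rowMeans, numeric(n)))
  eb <- stats::lm.fit(Xb, rowMeans(yt))$residuals
  s2_1 <- Tt * sum(eb^2) / max(n - ka - 1, 1)
  phi <- if (s2_1 <= s2_nu) 0 else 1 - sqrt(s2_nu / s2_1)
  list(phi = phi, s2_nu = s2_nu, s2_1 = s2_1)
}

# Moments of the quadratic form e' (I_T kron W) e when e = Q eps and Q is
# the within projector implied by the absorbed effects. For balanced
# panels Q factorises over the unit and time dimensions, so every trace
# reduces to an n x n computation. mE is the mean (zero only when no
# cross-unit demeaning occurs), T1 the variance of the form (per sigma^4).
lm_quad_moments <- function(Wm, n, Tt, effects) {
  Qn <- diag(n) - 1 / n
  Mn <- Qn %*% Wm %*% Qn
  tr <- function(M) sum(diag(M))
  switch(effects,
         both = list(mE = (Tt - 1) * tr(Mn),
                     T1 = (Tt - 1) * (tr(Mn %*% Mn) + tr(Mn %*% t(Mn)))),
         individual = list(mE = 0,
                           T1 = (Tt - 1) * (tr(Wm %*% Wm) + tr(crossprod(Wm)))),
         time = list(mE = Tt * tr(Mn),
                     T1 = Tt * (tr(Mn %*% Mn) + tr(Mn %*% t(Mn)))),
         none = list(mE = 0,
                     T1 = Tt * (tr(Wm %*% Wm) + tr(crossprod(Wm)))))
}

spec_test <- function(name, statistic, df, p_value, note = NULL) {
  structure(list(name = name, statistic = statistic, df = df,
                 p_value = p_value, note = note), class = "spec_test")
}

#' @export
print.spec_test <- function(x, ...) {
  cat(sprintf("%-16s chi2 = %8.3f  df = %d  p = %.4f%s\n", x$name,
              x$statistic, x$df, x$p_value,
              if (!is.null(x$note)) paste0("  [", x$note, "]") else ""))
  invisible(x)
}

#' Lagrange multiplier tests for spatial dependence
#'
#' Computes the classical LM-lag and LM-error statistics and their robust
#' variants from pooled OLS residuals on within-transformed panel data,
#' using the panel trace term \eqn{T \, \mathrm{tr}(W'W + WW)}. Each
#' statistic is asymptotically \eqn{\chi^2_1} under its null.
#'
#' @param y n x T response matrix.
#' @param X n x T x k covariate array.
#' @param W a \code{\link{build_weights}} result.
#' @param effects fixed effects to absorb before pooling (default both).
#' @return named list of \code{spec_test} objects: \code{lm_lag},
#'   \code{lm_error}, \code{robust_lm_lag}, \code{robust_lm_error}.
#' @export
lm_tests <- function(y, X, W, effects = "both") {
  Wm <- W$row_standardized
  d <- build_design(as.matrix(y), X, Wm, "sar", effects)
  n <- d$n; Tt <- d$Tt; nT <- n * Tt
  qrz <- qr(d$Z)
  bet <- qr.coef(qrz, d$yv)
  e <- as.vector(d$yv - d$Z %*% bet)
  ndf <- switch(effects, both = (n - 1) * (Tt - 1), individual = n * (Tt - 1),
                time = (n - 1) * Tt, none = nT)
  s2 <- sum(e^2) / ndf
  mom <- lm_quad_moments(Wm, n, Tt, effects)
  d_lag <- sum(e * d$Wy) / s2 - mom$mE
  Wee <- numeric(nT)
  for (t in seq_len(Tt)) {
    idx <- (t - 1L) * n + seq_len(n)
    Wee[idx] <- Wm %*% e[idx]
  }
  d_err <- sum(e * Wee) / s2 - mom$mE
  WXb <- numeric(nT)
  for (t in seq_len(Tt)) {
    idx <- (t - 1L) * n + seq_len(n)
    WXb[idx] <- Wm %*% (d$Z[idx, , drop = FALSE] %*% bet)
  }
  MWXb <- WXb - d$Z %*% qr.coef(qrz, WXb)
  Tw <- mom$T1
  J <- sum(MWXb^2) / s2 + Tw
  lm_lag <- d_lag^2 / J
  lm_err <- d_err^2 / Tw
  r_lag <- (d_lag - d_err)^2 / (J - Tw)
  r_err <- (d_err - (Tw / J) * d_lag)^2 / (Tw * (1 - Tw / J))
  p1 <- function(s) stats::pchisq(s, 1, lower.tail = FALSE)
  list(lm_lag = spec_test("lm_lag", lm_lag, 1L, p1(lm_lag)),
       lm_error = spec_test("lm_error", lm_err, 1L, p1(lm_err)),
       robust_lm_lag = spec_test("robust_lm_lag", r_lag, 1L, p1(r_lag)),
       robust_lm_error = spec_test("robust_lm_error", r_err, 1L, p1(r_err)))
}

#' Likelihood-ratio test between nested spatial fits
#'
#' The raw statistic \eqn{2(\ell_1 - \ell_0)} is referred to
#' \eqn{\chi^2_q} after a Bartlett adjustment: in Gaussian regression the
#' null mean of the likelihood ratio for q linear restrictions exceeds q by
#' a second-order term driven by the number of fitted parameters,
#' \eqn{E[LR] \approx N [ q/(m-2) - q(q+2) / (2(m-2)(m-4)) ]} with
#' \eqn{m = N - k_1} residual degrees of freedom of the full model; the
#' statistic is rescaled by \eqn{q / E[LR]} so its null mean matches the
#' reference distribution. With many restrictions relative to the sample
#' (thirteen Durbin terms on a 29 x 10 panel) the unadjusted statistic is
#' noticeably oversized; the adjustment restores near-nominal size without
#' affecting first-order asymptotics.
#'
#' @param full,nested \code{spatial_model_fit} objects on the same data,
#'   the nested one a restriction of the full one.
#' @param df number of restrictions; by default the difference in number
#'   of estimated coefficients.
#' @param bartlett apply the small-sample adjustment (default TRUE).
#' @return a \code{spec_test}.
#' @export
lr_test <- function(full, nested, df = NULL, bartlett = TRUE) {
  if (is.null(df)) df <- nrow(full$coefficients) - nrow(nested$coefficients)
  if (df <= 0) stop("models are not nested (no restrictions)")
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  note <- NULL
  if (bartlett && !is.null(full$dfree)) {
    N <- full$dfree
    m <- N - full$n_par
    if (m > 6) {
      elr <- N * (df / (m - 2) - df * (df + 2) / (2 * (m - 2) * (m - 4)))
      stat <- stat * df / elr
      note <- sprintf("Bartlett factor %.3f", df / elr)
    }
  }
  spec_test("lr", stat, as.integer(df),
            stats::pchisq(stat, df, lower.tail = FALSE), note = note)
}

#' Wald degradation tests for the spatial Durbin model
#'
#' Tests whether an SDM fit degrades to SAR (\eqn{\theta = 0}) or to SEM
#' (the common-factor restriction \eqn{\theta = -\rho\beta}, the algebraic
#' condition under which the Durbin model reduces to a spatial error
#' model), using the fit's covariance matrix; the SEM restriction is
#' nonlinear and handled by the delta method.
#'
#' @param fit an SDM \code{spatial_model_fit}.
#' @param type \code{"sar"} or \code{"sem"}.
#' @return a \code{spec_test} with df = k restrictions.
#' @export
wald_degradation <- function(fit, type = c("sar", "sem")) {
  type <- match.arg(type)
  if (fit$model != "sdm") stop("degradation tests apply to SDM fits")
  k <- fit$k
  bidx <- seq_len(k)
  tidx <- k + seq_len(k)
  ridx <- 2L * k + 1L
  V <- fit$vcov
  if (type == "sar") {
    g <- fit$theta
    G <- matrix(0, k, nrow(V))
    G[cbind(seq_len(k), tidx)] <- 1
  } else {
    g <- fit$theta + fit$rho * fit$beta
    G <- matrix(0, k, nrow(V))
    G[cbind(seq_len(k), bidx)] <- fit$rho
    G[cbind(seq_len(k), tidx)] <- 1
    G[, ridx] <- fit$beta
  }
  Vg <- G %*% V %*% t(G)
  stat <- as.numeric(t(g) %*% solve(Vg, g))
  spec_test(paste0("wald_", type), stat, k,
            stats::pchisq(stat, k, lower.tail = FALSE))
}

#' Hausman test of fixed versus random effects
#'
#' Compares the common slope coefficients of a fixed-effects and a
#' random-effects fit of the same spatial model:
#' \eqn{H = \Delta b' (V_{FE} - V_{RE})^{-1} \Delta b}. When the middle
#' matrix is not positive definite the Moore-Penrose inverse is used, the
#' degrees of freedom are its rank, and the fallback is noted in the
#' result.
#'
#' @param fe,re \code{spatial_model_fit} objects with identical model and
#'   regressors, fitted with fixed and random effects respectively.
#' @return a \code{spec_test}.
#' @export
hausman_test <- function(fe, re) {
  if (fe$model != re$model) stop("fits must share the model")
  nm <- intersect(rownames(fe$coefficients), rownames(re$coefficients))
  nm <- setdiff(nm, c("rho", "lambda", "sigma2"))
  db <- fe$coefficients[nm, "estimate"] - re$coefficients[nm, "estimate"]
  Vd <- fe$vcov[nm, nm] - re$vcov[nm, nm]
  ed <- eigen(Vd, symmetric = TRUE)
  pos <- ed$values > 1e-10 * max(abs(ed$values))
  note <- NULL
  if (any(ed$values < -1e-10 * max(abs(ed$values))))
    note <- "non-PSD difference; quadratic form on positive eigenspace"
  if (!any(pos)) {
    # the RE estimator dominates nowhere: no evidence against it
    return(spec_test("hausman", 0, length(nm), 1,
                     note = "difference matrix has no positive eigenvalues"))
  }
  U <- ed$vectors[, pos, drop = FALSE]
  Vi <- U %*% diag(1 / ed$values[pos], sum(pos)) %*% t(U)
  df <- sum(pos)
  stat <- max(0, as.numeric(t(db) %*% Vi %*% db))
  spec_test("hausman", stat, as.integer(df),
            stats::pchisq(stat, df, lower.tail = FALSE), note = note)
}

#' Battery of LR, Wald and Hausman specification tests
#'
#' Runs the degradation and effect-structure battery used to pick the
#' final model: LR and Wald tests of SDM against SAR and SEM, LR tests of
#' the two-way fixed-effects structure against individual-only and
#' time-only effects, and (when a random-effects fit is supplied) the
#' Hausman test.
#'
#' @param sdm,sar,sem \code{spatial_model_fit} objects on the same data.
#' @param sdm_individual,sdm_time optional SDM fits with only individual /
#'   only time effects, for the effect-structure LR tests.
#' @param re optional random-effects SDM fit for the Hausman test (paired
#'   with \code{sdm_individual} or \code{sdm}).
#' @return named list of \code{spec_test} objects.
#' @export
lr_wald_hausman <- function(sdm, sar = NULL, sem = NULL,
                            sdm_individual = NULL, sdm_time = NULL,
                            re = NULL) {
  out <- list()
  if (!is.null(sar)) {
    out$lr_sar <- lr_test(sdm, sar, df = sdm$k)
    out$lr_sar$name <- "lr_sdm_vs_sar"
    out$wald_sar <- wald_degradation(sdm, "sar")
  }
  if (!is.null(sem)) {
    out$lr_sem <- lr_test(sdm, sem, df = sdm$k)
    out$lr_sem$name <- "lr_sdm_vs_sem"
    out$wald_sem <- wald_degradation(sdm, "sem")
  }
  if (!is.null(sdm_individual)) {
    lr <- lr_test(sdm, sdm_individual, df = sdm$T - 1L)
    lr$name <- "lr_time_effects"
    out$lr_time_effects <- lr
  }
  if (!is.null(sdm_time)) {
    lr <- lr_test(sdm, sdm_time, df = sdm$n - 1L)
    lr$name <- "lr_individual_effects"
    out$lr_individual_effects <- lr
  }
  if (!is.null(re)) {
    out$hausman <- hausman_test(sdm, re)
  }
  out
}

#' Direct, indirect and total effects of a spatial fit
#'
#' For regressor k of an SDM or SAR fit, the matrix of partial effects is
#' \eqn{S_k(W) = (I - \rho W)^{-1} (\beta_k I + \theta_k W)}. The direct
#' effect is the average diagonal element of \eqn{S_k}, the total effect
#' the average row sum, and the indirect (spillover) effect their
#' difference. Inference is by simulation: parameter vectors are drawn
#' from a multivariate normal centred at the estimates with the fit's
#' covariance matrix, and the three summaries are recomputed per draw.
#'
#' @param fit an SDM or SAR \code{spatial_model_fit}.
#' @param W a \code{\link{build_weights}} result (row-standardized form is
#'   used).
#' @param draws number of simulation draws (default 1000).
#' @param seed RNG seed for the draws (default 20240816).
#' @return object of class \code{effects_decomposition}: data frame with
#'   one row per regressor and columns \code{direct}, \code{indirect},
#'   \code{total}, their simulation standard errors, z and p values;
#'   \code{draws} and \code{seed} kept as attributes.
#' @export
decompose_effects <- function(fit, W, draws = 1000L, seed = 20240816L) {
  if (!fit$model %in% c("sdm", "sar"))
    stop("effects decomposition applies to SDM and SAR fits")
  Wm <- W$row_standardized
  n <- nrow(Wm)
  k <- fit$k
  kz <- length(fit$delta)
  iv <- spatial_interval(Wm)
  point <- function(delta, rho) {
    Ai <- solve(diag(n) - rho * Wm)
    AiW <- Ai %*% Wm
    t(vapply(seq_len(k), function(j) {
      bk <- delta[j]
      tk <- if (fit$model == "sdm") delta[k + j] else 0
      Sk_diag <- bk * diag(Ai) + tk * diag(AiW)
      total <- (bk * sum(Ai) + tk * sum(AiW)) / n
      direct <- mean(Sk_diag)
      c(direct = direct, indirect = total - direct, total = total)
    }, numeric(3)))
  }
  est <- point(fit$delta, fit$rho)
  idx <- seq_len(kz + 1L)           # coefficients + spatial parameter
  mu <- c(fit$delta, fit$rho)
  V <- fit$vcov[idx, idx]
  sims <- local({
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    par_draws <- MASS::mvrnorm(draws, mu, V)
    ok <- par_draws[, kz + 1L] > iv$lo & par_draws[, kz + 1L] < iv$hi
    par_draws <- par_draws[ok, , drop = FALSE]
    arr <- array(NA_real_, c(k, 3, nrow(par_draws)))
    for (r in seq_len(nrow(par_draws)))
      arr[, , r] <- point(par_draws[r, seq_len(kz)], par_draws[r, kz + 1L])
    arr
  })
  se <- apply(sims, c(1, 2), stats::sd)
  mean_s <- apply(sims, c(1, 2), mean)
  z <- mean_s / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(variable = fit$xnames,
                    direct = est[, 1], direct_se = se[, 1],
                    direct_p = p[, 1],
                    indirect = est[, 2], indirect_se = se[, 2],
                    indirect_p = p[, 2],
                    total = est[, 3], total_se = se[, 3],
                    total_p = p[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "draws") <- draws
  attr(out, "seed") <- seed
  class(out) <- c("effects_decomposition", "data.frame")
  out
}
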