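# Synthetic panel generators. These emulate the statistical structure the
# analysis pipeline assumes -- a 29-unit, 10-year panel with a 5-input,
# 4-output production technology under variable returns to scale, 13
# covariates at published magnitudes, and a spatial-lag outcome process
# with known parameters -- so every stage can be exercised and validated
# without any external data.

# Magnitude targets for the 13 covariates (means/sds of the published
# descriptive statistics). dist: "lognormal" for positive scale variables,
# "normal" (with clipping) for percentages and indices. The printed
# dispersion of X3 (an urban-population percentage with a stated maximum of
# 5042) is physically impossible; the generator uses a plausible spread and
# clips to [0, 100].
covariate_moments <- function() {
  data.frame(
    name = paste0("X", 1:13),
    mean = c(0.67, 309.44, 74.51, 39.30, 5.99, 54919.96, 3.24, 102.67,
             23800.33, 8.20, 1057.44, 61846.29, 10.81),
    sd = c(0.19, 264.59, 15.00, 6.83, 6.32, 22568.86, 0.56, 2.43,
           7804.61, 2.07, 489.26, 58028.25, 2.75),
    dist = c("normal", "lognormal", "normal", "normal", "lognormal",
             "lognormal", "normal", "normal", "lognormal", "normal",
             "lognormal", "lognormal", "normal"),
    lo = c(0.05, NA, 0, 0, NA, NA, 0.5, 95, NA, 0, NA, NA, 0),
    hi = c(1.3, NA, 100, 100, NA, NA, 6, 120, NA, 100, NA, NA, 100),
    stringsAsFactors = FALSE)
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a covariate panel at published magnitudes
#'
#' Draws 13 independent covariate series whose means and standard
#' deviations target the published descriptive statistics of the province
#' panel: log-normal for positive scale variables (population density,
#' GDP per head, incomes, expenditures, traffic volumes), normal for
#' percentages and indices, with percentage series clipped to [0, 100].
#' No cross-covariate correlation is imposed.
#'
#' Each series carries a persistent unit component (share \code{persistence}
#' of the total variance) plus year-to-year noise, mirroring the strong
#' within-province persistence of real socioeconomic series.
#'
#' @param n_units number of units (default 29).
#' @param n_periods number of periods (default 10).
#' @param persistence share of variance attributed to the time-invariant
#'   unit component, in [0, 1) (default 0.7).
#' @param seed RNG seed.
#' @return n x T x 13 array with covariate names on the second dimension.
#' @export
generate_covariates <- function(n_units = 29L, n_periods = 10L,
                                persistence = 0.7, seed = 1L) {
  stopifnot(persistence >= 0, persistence < 1)
  mom <- covariate_moments()
  with_seed(seed, {
    A <- array(NA_real_, c(n_units, n_periods, nrow(mom)),
               dimnames = list(NULL, NULL, mom$name))
    for (j in seq_len(nrow(mom))) {
      m <- mom$mean[j]; s <- mom$sd[j]
      base <- stats::rnorm(n_units, 0, sqrt(persistence))
      noise <- matrix(stats::rnorm(n_units * n_periods, 0,
                                   sqrt(1 - persistence)),
                      n_units, n_periods)
      zfield <- base + noise          # unit-persistent standard deviates
      v <- if (mom$dist[j] == "lognormal") {
        sl2 <- log(1 + (s / m)^2)
        exp(log(m) - sl2 / 2 + sqrt(sl2) * zfield)
      } else {
        m + s * zfield
      }
      if (!is.na(mom$lo[j])) v <- pmin(pmax(v, mom$lo[j]), mom$hi[j])
      A[, , j] <- v
    }
    A
  })
}

#' Generate a DEA panel with known inefficiency
#'
#' Places every unit-period on a concave variable-returns frontier and
#' then inflates its inputs by \eqn{\exp(u)}, \eqn{u \sim |N(0,
#' \sigma_u)|}, so the true inefficiency of every cell is known. The
#' frontier is a common technology: input requirements proportional to a
#' latent unit scale \eqn{z_j}, outputs proportional to
#' \eqn{z_j^{\gamma}} with curvature \eqn{0 < \gamma < 1} (decreasing
#' returns away from the middle of the scale range) shifted by a
#' period-to-period drift factor \eqn{e^{\mathrm{drift}\,(t-1)}}. Input
#' and output mixes follow the published magnitudes of the
#' township-health-centre panel (facility counts, beds, physicians,
#' nurses, pharmacists; visits, inpatients, discharges, bed utilisation).
#' With \code{inefficiency_scale = 0} every unit lies exactly on its
#' period frontier.
#'
#' @param n_units,n_periods panel dimensions (defaults 29 x 10).
#' @param n_inputs,n_outputs technology dimensions (defaults 5 and 4).
#' @param frontier_curvature concavity exponent \eqn{\gamma} (default 0.8).
#' @param inefficiency_scale half-normal scale of input inflation
#'   (default 0.3).
#' @param drift log frontier shift per period (default -0.03, a slowly
#'   regressing frontier).
#' @param seed RNG seed.
#' @return list with \code{panel} (a \code{\link{panel_dataset}}) and
#'   \code{true_inefficiency} (n x T matrix of the drawn \eqn{u}).
#' @export
generate_dea_panel <- function(n_units = 29L, n_periods = 10L,
                               n_inputs = 5L, n_outputs = 4L,
                               frontier_curvature = 0.8,
                               inefficiency_scale = 0.3,
                               drift = -0.03, seed = 1L) {
  stopifnot(frontier_curvature > 0, inefficiency_scale >= 0)
  in_mix <- c(1256.74, 43540.16, 16136.09, 11525.91, 2629.65)
  out_mix <- c(37200000, 1296595, 1292245, 51.32)
  a <- if (n_inputs <= 5) in_mix[seq_len(n_inputs)] else
    c(in_mix, rep(1000, n_inputs - 5))
  b <- if (n_outputs <= 4) out_mix[seq_len(n_outputs)] else
    c(out_mix, rep(1000, n_outputs - 4))
  with_seed(seed, {
    z <- stats::rlnorm(n_units, 0, 0.5)
    u <- matrix(abs(stats::rnorm(n_units * n_periods, 0, inefficiency_scale)),
                n_units, n_periods)
    inputs <- array(NA_real_, c(n_units, n_inputs, n_periods),
                    dimnames = list(NULL, paste0("x", seq_len(n_inputs)), NULL))
    outputs <- array(NA_real_, c(n_units, n_outputs, n_periods),
                     dimnames = list(NULL, paste0("y", seq_len(n_outputs)), NULL))
    for (ti in seq_len(n_periods)) {
      shift <- exp(drift * (ti - 1L))
      for (j in seq_len(n_units)) {
        inputs[j, , ti] <- a * z[j] * exp(u[j, ti])
        outputs[j, , ti] <- b * z[j]^frontier_curvature * shift
      }
    }
    units <- sprintf("U%02d", seq_len(n_units))
    panel <- panel_dataset(units, 2011L + seq_len(n_periods), inputs, outputs)
    dimnames(u) <- list(units, 2011L + seq_len(n_periods))
    list(panel = panel, true_inefficiency = u)
  })
}

#' Generate a spatial Durbin panel with known parameters
#'
#' Simulates the outcome process
#' \deqn{y_t = (I - \rho W)^{-1} (X_t \beta + W X_t \theta + \mu +
#'   \gamma_t \iota + \epsilon_t), \quad \epsilon_t \sim N(0, \sigma^2 I),}
#' with unit effects \eqn{\mu_i} and period effects \eqn{\gamma_t}. The
#' default parameters are the study conditions of the published province
#' panel: the 29-province rook contiguity matrix, T = 10, the spatial
#' autoregressive coefficient -0.1555403 and the 13 response-equation and
#' spatial-lag coefficients of the fitted Durbin model, with
#' \eqn{\sigma^2 = 0.0057875}; covariates come from
#' \code{\link{generate_covariates}}.
#'
#' @param W a \code{\link{build_weights}} result (default the packaged
#'   29-province rook matrix).
#' @param n_periods panel length (default 10).
#' @param rho spatial autoregressive coefficient.
#' @param beta regressor coefficients (length k).
#' @param theta spatial-lag regressor coefficients (length k; zero vector
#'   gives a SAR process).
#' @param sigma disturbance standard deviation.
#' @param effects which effects enter the DGP (\code{"both"},
#'   \code{"individual"}, \code{"time"}, \code{"none"}).
#' @param sd_mu,sd_gamma standard deviations of the unit and period
#'   effects (defaults 0.1).
#' @param X optional covariate array n x T x k; generated when omitted.
#' @param seed RNG seed.
#' @return list with \code{y} (n x T), \code{X} (n x T x k), \code{W} and
#'   the true parameters.
#' @export
generate_sdm_panel <- function(W = rook29_weights(), n_periods = 10L,
                               rho = -0.1555403,
                               beta = sdm_default_beta(),
                               theta = sdm_default_theta(),
                               sigma = sqrt(0.0057875),
                               effects = c("both", "individual", "time", "none"),
                               sd_mu = 0.1, sd_gamma = 0.1,
                               X = NULL, seed = 1L) {
  effects <- match.arg(effects)
  stopifnot(sigma > 0, length(beta) == length(theta))
  Wm <- W$row_standardized
  n <- nrow(Wm)
  iv <- spatial_interval(Wm)
  if (rho <= iv$lo || rho >= iv$hi)
    stop("rho outside the admissible interval (", round(iv$lo, 4), ", 1)")
  k <- length(beta)
  with_seed(seed, {
    if (is.null(X)) {
      X <- generate_covariates(n, n_periods, seed = seed + 1L)
      if (dim(X)[3] != k) {
        if (k < dim(X)[3]) X <- X[, , seq_len(k), drop = FALSE]
        else stop("beta longer than the 13 generated covariates; supply X")
      }
    }
    mu <- if (effects %in% c("both", "individual")) stats::rnorm(n, 0, sd_mu) else rep(0, n)
    ga <- if (effects %in% c("both", "time")) stats::rnorm(n_periods, 0, sd_gamma) else rep(0, n_periods)
    Ai <- solve(diag(n) - rho * Wm)
    y <- matrix(NA_real_, n, n_periods, dimnames = list(W$labels, NULL))
    for (t in seq_len(n_periods)) {
      Xt <- matrix(X[, t, ], n)
      xb <- Xt %*% beta + Wm %*% Xt %*% theta
      y[, t] <- Ai %*% (xb + mu + ga[t] + stats::rnorm(n, 0, sigma))
    }
    list(y = y, X = X, W = W,
         params = list(rho = rho, beta = beta, theta = theta, sigma = sigma,
                       mu = mu, gamma = ga, effects = effects))
  })
}

#' Default response-equation coefficients of the reference Durbin fit
#' @return numeric vector of length 13.
#' @export
sdm_default_beta <- function() {
  c(0.4398813, -0.0019767, 0.0000184, 0.0045304, -0.0036032, 0.0000026,
    -0.0439717, 0.0010251, 0.0000179, 0.0098407, -0.0003305, -0.0000003,
    0.0156813)
}

#' Default spatial-lag coefficients of the reference Durbin fit
#' @return numeric vector of length 13.
#' @export
sdm_default_theta <- function() {
  c(-0.0263782, 0.0041332, -0.0000498, 0.0012280, 0.0089168, 0.0000025,
    -0.2262410, 0.0055915, -0.0000489, 0.0557525, 0.0000410, 0.0000001,
    0.0251309)
}
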