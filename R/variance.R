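#' Design point for variance and information evaluation
#'
#' Bundles everything needed to evaluate the variance of the primary-endpoint
#' treatment effect at an interim time t: the follow-up schedule, recruitment
#' and correlation models, the allocation weight and the primary-outcome SD.
#' Evaluation requires \eqn{d_s < t \le d_s + T_R}, i.e. some primary outcome
#' data exist but follow-up is not yet complete (the final time gives the
#' end-of-study values).
#'
#' @param t Calendar time of evaluation.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @param rec A \code{\link{recruitment_model}}.
#' @param corr A \code{\link{correlation_model}}.
#' @param alloc An \code{\link{allocation_spec}} (default equal allocation).
#' @param sigma_s SD of the primary outcome (outcome units, > 0).
#' @return An object of class \code{"design_point"}.
#' @export
design_point <- function(t, sched, rec, corr, alloc = allocation_spec(0.5), sigma_s) {
  stopifnot(inherits(sched, "follow_up_schedule"), inherits(rec, "recruitment_model"),
            inherits(corr, "correlation_model"), inherits(alloc, "allocation_spec"))
  if (!is.numeric(sigma_s) || length(sigma_s) != 1L || sigma_s <= 0)
    stop("sigma_s must be a single positive number")
  d_s <- sched$d[sched$s]
  if (t <= d_s)
    stop("no primary outcome data: t must exceed the final follow-up time d_s")
  if (t > d_s + rec$T_R)
    t <- d_s + rec$T_R  # beyond end of follow-up everything is complete
  structure(list(t = t, sched = sched, rec = rec, corr = corr,
                 alloc = alloc, sigma_s = sigma_s),
            class = "design_point")
}

# per-occasion "harmonic" term (N0_r + N1_r) / (N0_r N1_r)
h_term <- function(N0, N1) (N0 + N1) / (N0 * N1)

# uniform-model determinant-ratio weights D_m = det(R_{m+1})/det(R_m)
d_weights <- function(alpha, s) {
  m <- seq_len(s - 1)
  (1 - alpha) * (1 + m * alpha) / (1 + (m - 1) * alpha)
}

#' Closed-form variance of the primary treatment effect from occasion counts
#'
#' Evaluates \eqn{var(\beta_s)}, the variance of the generalized least squares
#' estimator of the treatment effect at the primary endpoint, from the
#' per-arm participant counts at each occasion, under a uniform or exponential
#' working correlation. Writing
#' \eqn{h_r = (N0_r + N1_r)/(N0_r N1_r)}, the uniform model gives
#' \deqn{var(\beta_s) = \sigma_s^2 [ h_1 + \sum_m D_m (h_{m+1} - h_m) ],}
#' with determinant-ratio weights
#' \eqn{D_m = (1-\alpha)(1+m\alpha)/\{1+(m-1)\alpha\}}, and the exponential
#' model, with \eqn{c_r = \gamma^{2(d_s - d_r)}},
#' \deqn{var(\beta_s) = \sigma_s^2 [ h_1 c_1 + \sum_{r \ge 2} h_r (c_r - c_{r-1}) ].}
#' Both reduce at s = 2 to the familiar two-occasion form
#' \eqn{\sigma_2^2 [ h_2 (1 - \rho^2) + h_1 \rho^2 ]} and agree with the
#' general GLS information-matrix computation (\code{\link{gls_variance_oracle}}).
#'
#' @param N0,N1 Per-occasion counts in the control and treatment arm; each
#'   must be non-increasing in r with all entries positive (the monotone data
#'   structure of staggered recruitment).
#' @param corr A \code{\link{correlation_model}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @param sigma_s Primary-outcome SD.
#' @return The variance of \eqn{\beta_s} (outcome units squared).
#' @export
var_beta_counts <- function(N0, N1, corr, sched, sigma_s) {
  stopifnot(inherits(corr, "correlation_model"), inherits(sched, "follow_up_schedule"))
  s <- sched$s
  if (length(N0) != s || length(N1) != s)
    stop("counts must have one entry per follow-up occasion")
  if (any(N0 <= 0) || any(N1 <= 0) || any(diff(N0) > 0) || any(diff(N1) > 0))
    stop("counts must be positive and non-increasing across occasions")
  h <- h_term(N0, N1)
  p <- corr$param
  if (corr$kind == "uniform") {
    sigma_s^2 * (h[1] + sum(d_weights(p, s) * diff(h)))
  } else {
    cr <- p^(2 * (sched$d[s] - sched$d))  # c_r, with c_s = 1 (0^0 = 1)
    sigma_s^2 * (h[1] * cr[1] + sum(h[-1] * diff(cr)))
  }
}

#' Variance of the primary treatment effect at a design point
#'
#' Substitutes the recruitment model's expected occasion counts at time t
#' into the closed-form variance (\code{\link{var_beta_counts}}).
#'
#' @param point A \code{\link{design_point}}.
#' @return The variance of \eqn{\beta_s} at time \code{point$t}.
#' @export
var_beta_at <- function(point) {
  stopifnot(inherits(point, "design_point"))
  Nr <- vapply(seq_len(point$sched$s), function(r)
    n_with_outcome(point$rec, point$sched, point$t, r), numeric(1))
  phi <- point$alloc$phi
  var_beta_counts(phi * Nr, (1 - phi) * Nr, point$corr, point$sched, point$sigma_s)
}

#' Variance-reduction factor V from early outcomes
#'
#' \eqn{V_s(t) = var(\beta_s(t)) / var(\beta_s^0(t))}: the ratio of the
#' treatment-effect variance using the correlated early outcomes to the
#' variance using primary-outcome data alone. \eqn{1/V} is the proportionate
#' increase in information contributed by the early outcomes. Writing
#' \eqn{n_{sr}(t)} for the ratio of primary-outcome to occasion-r counts,
#' the uniform model gives
#' \eqn{V = n_{s1} + \sum_m D_m (n_{s,m+1} - n_{s,m})} and the exponential
#' model the analogous telescoped sum with weights
#' \eqn{c_r = \gamma^{2(d_s - d_r)}}. Always
#' \eqn{n_{s1}(t) \le V \le 1}, and V decreases monotonically in the
#' correlation parameter. For the uniform model the terminal weight
#' \eqn{D = D_{s-1}} is attached as attribute \code{"D"}.
#'
#' @param point A \code{\link{design_point}}.
#' @return V in (0, 1], with attribute \code{"D"} for the uniform model.
#' @examples
#' sched <- follow_up_schedule(c(1, 2, 4))
#' rec <- recruitment_model("fixed", 188, 8)
#' pt <- design_point(6, sched, rec, correlation_model("uniform", 0.5), sigma_s = 12)
#' v_factor(pt)  # 0.808
#' @export
v_factor <- function(point) {
  stopifnot(inherits(point, "design_point"))
  sched <- point$sched; s <- sched$s
  g <- accrual_g(point$rec, point$t, sched$d)
  if (g[s] <= 0) stop("no primary outcome data accrued at time t")
  n_sr <- g[s] / g
  p <- point$corr$param
  if (point$corr$kind == "uniform") {
    Dm <- d_weights(p, s)
    V <- n_sr[1] + sum(Dm * diff(n_sr))
    attr(V, "D") <- Dm[s - 1]
  } else {
    cr <- p^(2 * (sched$d[s] - sched$d))
    V <- n_sr[1] * cr[1] + sum(n_sr[-1] * diff(cr))
  }
  V
}

#' Analytic extrema of the uniform-model variance-reduction factor
#'
#' Over all admissible placements of the intermediate occasions
#' \eqn{d_2 < \dots < d_{s-1}} between fixed \eqn{d_1} and \eqn{d_s}, the
#' uniform-model V attains its minimum when all intermediate occasions move to
#' \eqn{d_1} (maximal early data),
#' \deqn{\min V = n_{s1} + D (1 - n_{s1}), \quad
#'       D = (1-\alpha)\{1+(s-1)\alpha\}/\{1+(s-2)\alpha\},}
#' and its maximum when they move to \eqn{d_s},
#' \deqn{\max V = n_{s1} + (1-\alpha^2)(1 - n_{s1}).}
#'
#' @param alpha Uniform correlation parameter in [0, 1).
#' @param s Number of occasions (>= 2). With s = 2 there are no intermediate
#'   occasions and the two bounds coincide.
#' @param n_s1 Ratio of primary-outcome to first-occasion counts at the
#'   evaluation time (see \code{\link{ratio_n}}).
#' @return Named vector \code{c(min =, max =)}.
#' @export
v_uniform_extrema <- function(alpha, s, n_s1) {
  if (s < 2) stop("s must be at least 2")
  D <- (1 - alpha) * (1 + (s - 1) * alpha) / (1 + (s - 2) * alpha)
  vmin <- n_s1 + D * (1 - n_s1)
  vmax <- n_s1 + (1 - alpha^2) * (1 - n_s1)
  if (s == 2) vmin <- vmax  # no intermediate occasions to move
  c(min = vmin, max = vmax)
}

#' Maximum of the exponential-model variance-reduction factor
#'
#' The exponential-model V is maximised when all intermediate occasions move
#' towards the earliest occasion \eqn{d_1}:
#' \deqn{\max V = n_{s1} + (1 - \gamma^{2(d_s - d_1)})(1 - n_{s1}).}
#'
#' @param gamma Exponential decay parameter in [0, 1).
#' @param d1,ds First and final occasion times.
#' @param n_s1 Count ratio at the evaluation time.
#' @return The maximum V.
#' @export
v_exp_max <- function(gamma, d1, ds, n_s1) {
  n_s1 + (1 - gamma^(2 * (ds - d1))) * (1 - n_s1)
}

#' Minimum of the exponential-model variance-reduction factor
#'
#' No closed form exists for the minimum of the exponential-model V over the
#' intermediate occasion times: moving occasions earlier increases the data
#' available but weakens their correlation with the primary outcome. The
#' minimum is found by linearly constrained quasi-Newton optimization
#' (\code{\link[stats]{constrOptim}}) over \eqn{d_2 < \dots < d_{s-1}} in
#' \eqn{(d_1, d_s)}, started at equal spacing, with analytic gradients
#' \deqn{\partial V/\partial d_m = (c_m - c_{m-1})\, g_s g'(u_m)/g_m^2
#'   - 2\ln\gamma\, (n_{sm} - n_{s,m+1})\, c_m,}
#' where \eqn{c_r = \gamma^{2(d_s - d_r)}}, \eqn{u_m = t - d_m} and g is the
#' recruitment accrual shape. Strict ordering is enforced with a minimum gap
#' between occasions.
#'
#' @param gamma Decay parameter in [0, 1).
#' @param s Number of occasions (>= 3).
#' @param d1,ds First and final occasion times.
#' @param t Evaluation time.
#' @param rec A \code{\link{recruitment_model}}.
#' @param gap Minimum separation enforced between successive occasions.
#' @param tol Convergence tolerance passed to the optimizer.
#' @return List with \code{min} (the minimised V) and \code{d} (the full
#'   schedule achieving it).
#' @export
v_exp_min <- function(gamma, s, d1, ds, t, rec, gap = 1e-6, tol = 1e-10) {
  stopifnot(inherits(rec, "recruitment_model"))
  if (s < 3) stop("s must be at least 3: with s = 2 there is nothing to optimize")
  if (gamma == 0) {
    # no correlation: V = 1 at any spacing
    return(list(min = 1, d = d1 + (ds - d1) * (seq_len(s) - 1) / (s - 1)))
  }
  fn <- function(x) v_exp_objective(x, gamma, d1, ds, t, rec)$value
  gr <- function(x) v_exp_objective(x, gamma, d1, ds, t, rec)$gradient
  k <- s - 2  # number of free intermediate times
  # ordering constraints: d1 + gap <= x_1, x_j + gap <= x_{j+1}, x_k + gap <= ds
  ui <- matrix(0, k + 1, k)
  ui[cbind(seq_len(k), seq_len(k))] <- 1
  if (k > 1) ui[cbind(2:k, 1:(k - 1))] <- -1
  ui[k + 1, k] <- -1
  ci <- c(d1 + gap, rep(gap, k - 1), -(ds - gap))
  x0 <- d1 + (ds - d1) * seq_len(k) / (s - 1)
  fit <- stats::constrOptim(x0, fn, gr, ui = ui, ci = ci, method = "BFGS",
                            outer.eps = tol,
                            control = list(reltol = tol, maxit = 500))
  if (fit$convergence != 0)
    stop("V minimization failed to converge: ", fit$convergence,
         " (", paste(fit$message, collapse = " "), ")")
  list(min = fit$value, d = c(d1, fit$par, ds))
}

# Internal: exponential-model V as a function of the free intermediate
# occasion times x = (d_2, ..., d_{s-1}), with its analytic gradient.
# Uses the telescoped form V = n_s1 c_1 + sum_{r>=2} n_sr (c_r - c_{r-1})
# with c_r = gamma^{2(d_s - d_r)}; each d_m (2 <= m <= s-1) enters through
# n_sm = g_s/g_m and through c_m, giving
#   dV/dd_m = (c_m - c_{m-1}) g_s g'(u_m)/g_m^2 - 2 log(gamma) (n_sm - n_s,m+1) c_m.
v_exp_objective <- function(x, gamma, d1, ds, t, rec) {
  s <- length(x) + 2L
  T_R <- rec$T_R
  d <- c(d1, x, ds)
  u <- pmin(pmax(t - d, 0), T_R)
  g <- g_shape(rec$model, u, T_R)
  n <- g[s] / g
  cr <- gamma^(2 * (ds - d))
  m <- seq(2L, s - 1L)
  dgdu <- g_shape_deriv(rec$model, u, T_R)
  dgdu[u <= 0 | u >= T_R] <- 0  # accrual clamped: no sensitivity
  dn <- g[s] * dgdu[m] / g[m]^2
  dc <- -2 * log(gamma) * cr[m]
  list(value = n[1] * cr[1] + sum(n[-1] * diff(cr)),
       gradient = (cr[m] - cr[m - 1]) * dn + (n[m] - n[m + 1]) * dc)
}

#' Information and information fraction at a design point
#'
#' Splits the information fraction at an interim time into the part coming
#' directly from primary-outcome data, \eqn{\tau_0(t) = N_s(t)/N}, and the
#' multiplier contributed by the correlated early outcomes, so that
#' \eqn{\tau(t) = \tau_0(t)/V_s(t)}. Also returns the variance of
#' \eqn{\beta_s} and its reciprocal, the statistical information
#' \eqn{I(t)}.
#'
#' @param point A \code{\link{design_point}}.
#' @return An object of class \code{"information_summary"}: a list with
#'   \code{var_beta}, \code{V}, \code{tau0}, \code{tau} and \code{info}.
#' @examples
#' sched <- follow_up_schedule(c(1, 2, 4))
#' rec <- recruitment_model("fixed", 188, 8)
#' pt <- design_point(6, sched, rec, correlation_model("uniform", 0.5), sigma_s = 12)
#' information_fraction(pt)  # tau0 = 0.25, tau = 0.309
#' @export
information_fraction <- function(point) {
  stopifnot(inherits(point, "design_point"))
  s <- point$sched$s
  tau0 <- n_with_outcome(point$rec, point$sched, point$t, s) / point$rec$N
  V <- as.numeric(v_factor(point))
  vb <- var_beta_at(point)
  structure(list(var_beta = vb, V = V, tau0 = tau0, tau = tau0 / V,
                 info = 1 / vb, t = point$t),
            class = "information_summary")
}

#' @export
print.information_summary <- function(x, ...) {
  cat(sprintf("t = %.4g: var(beta_s) = %.4g, I = %.4g, V = %.4g, tau0 = %.4g, tau = %.4g\n",
              x$t, x$var_beta, x$info, x$V, x$tau0, x$tau))
  invisible(x)
}

#' Matrix-based GLS variance of the primary treatment effect
#'
#' Direct evaluation of the generalized least squares variance
#' \eqn{(\sum_i X_i' \Sigma_i^{-1} X_i)^{-1}} for monotone longitudinal data,
#' summing the at most 2s distinct missingness-pattern-by-arm contributions.
#' Each participant observed through occasion r contributes a design matrix
#' of r occasion indicators (columns 1..s) and r occasion-by-treatment
#' indicators (columns s+1..2s, nonzero in the treatment arm only); the
#' primary treatment effect \eqn{\beta_s} is the last coefficient. This
#' routine makes no structural assumption on the correlation and is the
#' independent check on the closed-form \code{\link{var_beta_counts}};
#' it also accommodates occasion-specific outcome SDs.
#'
#' @param N0,N1 Per-occasion counts (non-increasing, positive); fractional
#'   expected counts are allowed and enter as weights.
#' @param corr A \code{\link{correlation_model}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @param sigma Outcome SD, a single value or one per occasion.
#' @return The variance of \eqn{\beta_s}: entry (2s, 2s) of the inverted
#'   information matrix.
#' @export
gls_variance_oracle <- function(N0, N1, corr, sched, sigma) {
  stopifnot(inherits(corr, "correlation_model"), inherits(sched, "follow_up_schedule"))
  s <- sched$s
  if (any(N0 <= 0) || any(N1 <= 0) || any(diff(N0) > 0) || any(diff(N1) > 0))
    stop("counts must be positive and non-increasing across occasions")
  Sigma <- cov_matrix(sigma, corr, sched)
  m0 <- c(-diff(N0), N0[s])  # participants observed through exactly occasion r
  m1 <- c(-diff(N1), N1[s])
  A <- matrix(0, 2 * s, 2 * s)
  for (r in seq_len(s)) {
    if (m0[r] == 0 && m1[r] == 0) next
    W <- solve(Sigma[seq_len(r), seq_len(r), drop = FALSE])
    X0 <- cbind(diag(1, r, s), matrix(0, r, s))
    X1 <- cbind(diag(1, r, s), diag(1, r, s))
    A <- A + m0[r] * crossprod(X0, W %*% X0) + m1[r] * crossprod(X1, W %*% X1)
  }
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular information matrix: some occasion has no participants in one arm"))
  Ainv[2 * s, 2 * s]
}
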