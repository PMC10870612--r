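#' Group sequential design object
#'
#' A design with K analyses at increasing information fractions
#' \eqn{\tau_1 < \dots < \tau_K = 1}, maximum information \eqn{I_{max}}, and
#' z-scale stopping boundaries: crossing below \eqn{l_k} stops for futility,
#' at or above \eqn{u_k} for efficacy. Before the final analysis
#' \eqn{u_k = +\infty} means no efficacy stopping at that look; at the final
#' analysis the bounds coincide (\eqn{l_K = u_K}) so the trial always
#' concludes. Testing is one-sided: rejection means crossing an upper bound.
#'
#' @param tau Information fractions, increasing, last equal to 1.
#' @param I_max Maximum statistical information (reciprocal outcome-units
#'   squared).
#' @param lower,upper z-scale boundaries per analysis.
#' @return An object of class \code{"gsd_design"}.
#' @examples
#' gsd_design(c(0.309, 0.419, 1), 0.326,
#'            lower = c(-0.706, 0.581, 1.907),
#'            upper = c(Inf, 3.090, 1.907))
#' @export
gsd_design <- function(tau, I_max, lower, upper) {
  K <- length(tau)
  if (K < 1L) stop("at least one analysis is required")
  if (any(diff(tau) <= 0) || any(tau <= 0) || abs(tau[K] - 1) > 1e-12)
    stop("tau must be strictly increasing with final value 1")
  if (!is.numeric(I_max) || length(I_max) != 1L || I_max <= 0)
    stop("I_max must be a single positive number")
  if (length(lower) != K || length(upper) != K)
    stop("lower and upper must have one bound per analysis")
  if (K > 1 && any(lower[-K] >= upper[-K]))
    stop("lower bounds must be below upper bounds before the final analysis")
  if (abs(lower[K] - upper[K]) > 1e-12)
    stop("final lower and upper bounds must coincide")
  structure(list(K = K, tau = tau, I_max = I_max,
                 lower = lower, upper = upper),
            class = "gsd_design")
}

#' @export
print.gsd_design <- function(x, ...) {
  cat(sprintf("Group sequential design: %d analyses, I_max = %g\n", x$K, x$I_max))
  print(data.frame(analysis = seq_len(x$K), tau = x$tau,
                   lower = x$lower, upper = x$upper), row.names = FALSE)
  invisible(x)
}

# Core recursion for first-exit probabilities of the canonical joint
# distribution: Z_k ~ N(delta * sqrt(I_k), 1), cov(Z_j, Z_k) = sqrt(I_j/I_k)
# for j <= k. Works on arbitrary increasing information levels I. The
# continuation density at each analysis is carried on a Simpson grid
# spanning the continuation region clipped to +/- `range` SDs around the
# marginal mean, `nodes` points per analysis (forced odd).
gsd_exit_probs <- function(I, lower, upper, delta, nodes = 1024L, range = 8) {
  nodes <- as.integer(nodes) + (as.integer(nodes) + 1L) %% 2L  # odd for Simpson
  K <- length(I)
  stopifnot(length(lower) == K, length(upper) == K, all(diff(I) > 0) || K == 1)
  p_lower <- p_upper <- numeric(K)
  mean1 <- delta * sqrt(I[1])
  p_lower[1] <- stats::pnorm(lower[1], mean = mean1)
  p_upper[1] <- stats::pnorm(upper[1], mean = mean1, lower.tail = FALSE)
  if (K == 1L)
    return(list(lower = p_lower, upper = p_upper,
                continuation = 1 - p_lower - p_upper))
  # continuation grid at analysis 1
  lo <- max(lower[1], mean1 - range)
  hi <- min(upper[1], mean1 + range)
  z <- seq(lo, hi, length.out = nodes)
  psi <- stats::dnorm(z, mean = mean1)          # sub-density of Z_1 on continuation
  wts <- simpson_weights(z)
  for (k in 2:K) {
    # Z_k | Z_{k-1} = z is normal with these moments
    rho <- sqrt(I[k - 1] / I[k])
    cm <- rho * z + delta * (I[k] - I[k - 1]) / sqrt(I[k])
    cs <- sqrt(1 - rho^2)
    p_lower[k] <- sum(wts * psi * stats::pnorm((lower[k] - cm) / cs))
    p_upper[k] <- sum(wts * psi * stats::pnorm((upper[k] - cm) / cs, lower.tail = FALSE))
    if (k < K) {
      meank <- delta * sqrt(I[k])
      lo <- max(lower[k], meank - range)
      hi <- min(upper[k], meank + range)
      znew <- seq(lo, hi, length.out = nodes)
      # propagate the sub-density to the new grid
      psi <- vapply(znew, function(zz)
        sum(wts * psi * stats::dnorm((zz - cm) / cs)) / cs, numeric(1))
      z <- znew
      wts <- simpson_weights(z)
    }
  }
  list(lower = p_lower, upper = p_upper,
       continuation = 1 - sum(p_lower) - sum(p_upper))
}

# composite Simpson weights on a uniform grid with an odd number of points
simpson_weights <- function(z) {
  n <- length(z)
  h <- (z[n] - z[1]) / (n - 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- w[n] <- 1
  w * h / 3
}

#' Boundary-crossing probabilities of a group sequential design
#'
#' Computes, by recursive numerical integration of the continuation density,
#' the probability that the sequence of z-statistics first exits through the
#' lower or upper boundary at each analysis, under the canonical joint
#' distribution: \eqn{Z_k \sim N(\delta\sqrt{\tau_k I_{max}}, 1)} with
#' \eqn{cov(Z_j, Z_k) = \sqrt{\tau_j/\tau_k}}. The final-analysis
#' continuation probability is zero, so the exit probabilities sum to 1.
#'
#' @param design A \code{\link{gsd_design}}.
#' @param delta Treatment difference on the outcome scale (the drift).
#' @param nodes Integration nodes per analysis (default 1024).
#' @return List with per-analysis vectors \code{lower} and \code{upper} of
#'   first-exit probabilities and the residual \code{continuation}
#'   probability (numerically zero).
#' @export
crossing_probabilities <- function(design, delta, nodes = 1024L) {
  stopifnot(inherits(design, "gsd_design"))
  gsd_exit_probs(design$tau * design$I_max, design$lower, design$upper,
                 delta, nodes = nodes)
}

#' Power of a group sequential design
#'
#' The probability of rejecting the null (crossing an upper boundary at any
#' analysis, including the final one) under treatment difference
#' \code{delta}. With \code{delta = 0} this is the one-sided type I error.
#'
#' @inheritParams crossing_probabilities
#' @return Rejection probability.
#' @examples
#' des <- gsd_design(c(0.309, 0.419, 1), 0.326,
#'                   lower = c(-0.706, 0.581, 1.907),
#'                   upper = c(Inf, 3.090, 1.907))
#' gsd_power(des, delta = 6)  # 0.906
#' @export
gsd_power <- function(design, delta, nodes = 1024L) {
  sum(crossing_probabilities(design, delta, nodes = nodes)$upper)
}

#' Solve z-scale boundaries from null crossing probabilities
#'
#' Sequentially root-solves the lower and upper boundary at each analysis so
#' that the first-exit probabilities under the null hypothesis match the
#' supplied targets (an error-spending specification by increments). A target
#' of zero gives a sentinel bound (\code{-Inf}/\code{Inf}: no stopping of
#' that kind at the analysis). At the final analysis the single shared bound
#' is solved from the upper (efficacy) target.
#'
#' @param tau Information fractions (increasing, final = 1).
#' @param I_max Maximum information.
#' @param p_lower_null,p_upper_null Per-analysis first-exit probabilities
#'   under the null; non-negative with total below 1.
#' @param nodes Integration nodes per analysis.
#' @return A \code{\link{gsd_design}} whose null crossing probabilities match
#'   the targets.
#' @export
solve_boundaries <- function(tau, I_max, p_lower_null, p_upper_null, nodes = 1024L) {
  K <- length(tau)
  stopifnot(length(p_lower_null) == K, length(p_upper_null) == K)
  if (any(p_lower_null < 0) || any(p_upper_null < 0) ||
      sum(p_lower_null) + sum(p_upper_null) > 1 + 1e-8)
    stop("infeasible targets: crossing probabilities must be non-negative with total < 1")
  I <- tau * I_max
  lower <- upper <- numeric(K)
  for (k in seq_len(K)) {
    lo_k <- c(lower[seq_len(k - 1)], -Inf)
    up_k <- c(upper[seq_len(k - 1)], Inf)
    exit_at <- function(bound, side) {
      if (side == "lower") lo_k[k] <- bound else up_k[k] <- bound
      pr <- gsd_exit_probs(I[seq_len(k)], lo_k, up_k, 0, nodes = nodes)
      if (side == "lower") pr$lower[k] else pr$upper[k]
    }
    if (k < K) {
      lower[k] <- if (p_lower_null[k] == 0) -Inf else
        stats::uniroot(function(b) exit_at(b, "lower") - p_lower_null[k],
                       c(-15, 15), tol = 1e-10)$root
      upper[k] <- if (p_upper_null[k] == 0) Inf else
        stats::uniroot(function(b) exit_at(b, "upper") - p_upper_null[k],
                       c(-15, 15), tol = 1e-10)$root
    } else {
      upper[k] <- stats::uniroot(function(b) exit_at(b, "upper") - p_upper_null[k],
                                 c(-15, 15), tol = 1e-10)$root
      lower[k] <- upper[k]
    }
  }
  gsd_design(tau, I_max, lower, upper)
}

#' Futility stopping probabilities with planned bounds held fixed
#'
#' Probability of stopping for futility at each of the first m analyses when
#' the planned z-scale lower bounds are held fixed while the realized
#' information levels vary (for example because the interim was moved or the
#' early-outcome correlation differs from the planning assumption). With no
#' efficacy stopping before the final analysis, the first analysis gives
#' \eqn{p_1 = \Phi(l_1 - \delta\sqrt{I_1})} and later analyses follow from
#' the canonical-joint-distribution recursion.
#'
#' @param lower Planned z-scale lower bounds, held fixed.
#' @param info Realized information levels \eqn{I_1 < \dots < I_m}.
#' @param delta Treatment difference.
#' @param nodes Integration nodes per analysis.
#' @return Vector of per-analysis futility stopping probabilities.
#' @export
futility_probability_fixed_bounds <- function(lower, info, delta, nodes = 1024L) {
  m <- length(lower)
  stopifnot(length(info) == m, all(info > 0), m == 1 || all(diff(info) > 0))
  gsd_exit_probs(info, lower, rep(Inf, m), delta, nodes = nodes)$lower
}

#' Smallest sample size achieving a target power
#'
#' Holds the boundary schedule fixed on the z-scale and rescales the maximum
#' information with the sample size, \eqn{I_{max}(N) = N\phi(1-\phi)/\sigma_s^2},
#' then searches for the smallest integer N whose design reaches the target
#' rejection probability under drift \code{delta}. Power is monotone in N
#' because the drift of every z-statistic scales with \eqn{\sqrt{I_{max}}}.
#'
#' @param tau Information fractions.
#' @param lower,upper z-scale boundaries (final bounds equal).
#' @param delta Treatment difference.
#' @param sigma_s Primary-outcome SD.
#' @param phi Allocation weight (default 0.5).
#' @param target Target power.
#' @param N_max Search ceiling.
#' @return The smallest integer N meeting the target.
#' @export
sample_size_for_power <- function(tau, lower, upper, delta, sigma_s,
                                  phi = 0.5, target = 0.9, N_max = 1e6) {
  pow_at <- function(N)
    gsd_power(gsd_design(tau, N * phi * (1 - phi) / sigma_s^2, lower, upper), delta)
  lo <- 1L; hi <- 2L
  while (pow_at(hi) < target) {
    lo <- hi; hi <- hi * 2L
    if (hi > N_max) stop("target power not reachable below N_max")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pow_at(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}
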