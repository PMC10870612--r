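#' Follow-up schedule
#'
#' Defines the ordered assessment occasions \eqn{d_1 < d_2 < \dots < d_s} at
#' which trial outcomes are observed, in abstract time units. Occasion
#' \eqn{s} is the primary endpoint time.
#'
#' @param d Numeric vector of assessment times, strictly increasing, all
#'   positive, length at least 2.
#' @return An object of class \code{"follow_up_schedule"} with elements
#'   \code{d} (the times) and \code{s} (the number of occasions).
#' @examples
#' follow_up_schedule(c(1, 2, 4))  # e.g. 3, 6 and 12 months in 3-month units
#' @export
follow_up_schedule <- function(d) {
  d <- as.numeric(d)
  if (length(d) < 2L) stop("a follow-up schedule needs at least two occasions")
  if (any(!is.finite(d)) || any(d <= 0)) stop("assessment times must be positive and finite")
  if (any(diff(d) <= 0)) stop("assessment times must be strictly increasing")
  structure(list(d = d, s = length(d)), class = "follow_up_schedule")
}

#' @export
print.follow_up_schedule <- function(x, ...) {
  cat("Follow-up schedule:", x$s, "occasions at d =",
      paste(format(x$d), collapse = ", "), "\n")
  invisible(x)
}

#' Rescale a follow-up schedule so the first occasion is at time 1
#'
#' Convenience rescaling for the exponential correlation model, where only the
#' relative spacings of the occasions matter: \code{d} is divided by its first
#' element so \eqn{d_1 = 1}. The correlation parameter must then be interpreted
#' per rescaled unit of time.
#'
#' @param sched A \code{\link{follow_up_schedule}}.
#' @return A rescaled \code{follow_up_schedule}.
#' @export
rescale_schedule <- function(sched) {
  stopifnot(inherits(sched, "follow_up_schedule"))
  follow_up_schedule(sched$d / sched$d[1L])
}

#' Allocation weight between trial arms
#'
#' @param phi Control-arm weight in (0, 1); the expected control-arm count at
#'   occasion r is \code{phi} times the total and the treatment-arm count is
#'   \code{1 - phi} times the total.
#' @return An object of class \code{"allocation_spec"}.
#' @export
allocation_spec <- function(phi = 0.5) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0 || phi >= 1)
    stop("phi must be a single number strictly between 0 and 1")
  structure(list(phi = phi), class = "allocation_spec")
}

#' Recruitment model
#'
#' Deterministic accrual models for trial planning. The expected number of
#' participants with data from occasion r at calendar time t is
#' \eqn{N_r(t) = k\,g_r(t, d_r)}, where the constant k and the accrual shape
#' g depend on the model:
#' \describe{
#'   \item{fixed}{constant rate \eqn{N/T_R}; \eqn{k = N/T_R}, \eqn{g = u} with
#'     \eqn{u = t - d_r}.}
#'   \item{increasing}{rate growing linearly in time;
#'     \eqn{k = N/\{T_R(T_R+1)\}}, \eqn{g = u(u+1)}.}
#'   \item{decreasing}{rate falling linearly in time;
#'     \eqn{k = N/\{T_R(T_R+1)\}}, \eqn{g = u(2T_R - u + 1)}.}
#' }
#' All three models recruit N participants in total over the recruitment
#' period \eqn{T_R} and share the same mean recruitment rate \eqn{N/T_R}.
#'
#' @param model One of \code{"fixed"}, \code{"increasing"}, \code{"decreasing"}.
#' @param N Planned total sample size (> 0).
#' @param T_R Recruitment period length, in the same units as the follow-up
#'   schedule.
#' @return An object of class \code{"recruitment_model"} with elements
#'   \code{model}, \code{N}, \code{T_R} and the normalising constant \code{k}.
#' @examples
#' rec <- recruitment_model("fixed", N = 188, T_R = 8)
#' n_with_outcome(rec, follow_up_schedule(c(1, 2, 4)), t = 6, r = 1)
#' @export
recruitment_model <- function(model = c("fixed", "increasing", "decreasing"), N, T_R) {
  model <- match.arg(model)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0)
    stop("N must be a single positive number")
  if (!is.numeric(T_R) || length(T_R) != 1L || !is.finite(T_R) || T_R <= 0)
    stop("T_R must be a single positive number")
  k <- if (model == "fixed") N / T_R else N / (T_R * (T_R + 1))
  structure(list(model = model, N = N, T_R = T_R, k = k),
            class = "recruitment_model")
}

#' @export
print.recruitment_model <- function(x, ...) {
  cat(sprintf("Recruitment model: %s rate, N = %g over T_R = %g\n",
              x$model, x$N, x$T_R))
  invisible(x)
}

# dimensionless accrual shape g(u) on 0 <= u <= T_R (no clamping)
g_shape <- function(model, u, T_R) {
  switch(model,
         fixed      = u,
         increasing = u * (u + 1),
         decreasing = u * (2 * T_R - u + 1))
}

# derivative dg/du, used by the exponential-model V minimiser
g_shape_deriv <- function(model, u, T_R) {
  switch(model,
         fixed      = rep(1, length(u)),
         increasing = 2 * u + 1,
         decreasing = 2 * T_R - 2 * u + 1)
}

#' Accrual function for one follow-up occasion
#'
#' Evaluates the dimensionless accrual shape \eqn{g_r(t, d_r)} for a
#' recruitment model: zero before outcome data from occasion r exist
#' (\eqn{t \le d_r}), increasing while data accumulate, and constant at its
#' \eqn{u = T_R} value once follow-up for the occasion is complete.
#'
#' @param spec A \code{\link{recruitment_model}}.
#' @param t Calendar time(s), non-negative.
#' @param d_r Occasion time, non-negative (0 denotes the recruitment event
#'   itself).
#' @return Accrual value(s), non-decreasing in \code{t}.
#' @export
accrual_g <- function(spec, t, d_r) {
  stopifnot(inherits(spec, "recruitment_model"))
  if (any(t < 0) || any(d_r < 0)) stop("t and d_r must be non-negative")
  u <- pmin(pmax(t - d_r, 0), spec$T_R)
  g_shape(spec$model, u, spec$T_R)
}

#' Expected number of participants with outcome data
#'
#' \eqn{N_r(t) = k\,g_r(t, d_r)}: the expected (possibly fractional) number of
#' participants with data from follow-up occasion r at calendar time t. With
#' \code{r = 0} it returns the cumulative number recruited.
#'
#' @param spec A \code{\link{recruitment_model}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @param t Calendar time(s).
#' @param r Occasion index, 0 to s (0 = recruitment itself).
#' @return Expected count(s) in [0, N].
#' @export
n_with_outcome <- function(spec, sched, t, r) {
  stopifnot(inherits(spec, "recruitment_model"), inherits(sched, "follow_up_schedule"))
  if (length(r) != 1L || r != round(r) || r < 0 || r > sched$s)
    stop("r must be a single integer between 0 and s")
  d_r <- if (r == 0) 0 else sched$d[r]
  spec$k * accrual_g(spec, t, d_r)
}

#' Instantaneous recruitment rate
#'
#' The model recruitment rate \eqn{\lambda(t)} in participants per unit time:
#' constant \eqn{N/T_R} for the fixed model, \eqn{2Nt/\{T_R(T_R+1)\}} for the
#' increasing model and \eqn{2N(T_R - t + 1)/\{T_R(T_R+1)\}} for the
#' decreasing model. All three average to \eqn{N/T_R} over t = 1, ..., T_R.
#'
#' @param spec A \code{\link{recruitment_model}}.
#' @param t Time(s) within the recruitment period.
#' @return Rate value(s).
#' @export
recruitment_rate <- function(spec, t) {
  stopifnot(inherits(spec, "recruitment_model"))
  N <- spec$N; T_R <- spec$T_R
  switch(spec$model,
         fixed      = rep(N / T_R, length(t)),
         increasing = 2 * N * t / (T_R * (T_R + 1)),
         decreasing = 2 * N * (T_R - t + 1) / (T_R * (T_R + 1)))
}

#' Calendar time at which a target proportion has primary outcome data
#'
#' Inverts the primary-endpoint accrual curve: returns the unique time
#' \eqn{t \in (d_s, d_s + T_R]} at which the proportion of participants with
#' final outcome data, \eqn{\tau_0(t) = N_s(t)/N}, equals \code{tau0}. The
#' fixed model inverts linearly; the increasing and decreasing models solve
#' the corresponding quadratic in \eqn{u = t - d_s}, taking the root inside
#' \eqn{(0, T_R]}.
#'
#' @param spec A \code{\link{recruitment_model}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @param tau0 Target proportion in (0, 1].
#' @return Calendar time t.
#' @examples
#' sched <- follow_up_schedule(c(1, 2, 4))
#' time_at_tau0(recruitment_model("fixed", 188, 8), sched, 0.25)       # 6
#' time_at_tau0(recruitment_model("decreasing", 188, 8), sched, 0.25)  # 5.13
#' @export
time_at_tau0 <- function(spec, sched, tau0) {
  stopifnot(inherits(spec, "recruitment_model"), inherits(sched, "follow_up_schedule"))
  if (!is.numeric(tau0) || length(tau0) != 1L || tau0 <= 0 || tau0 > 1)
    stop("tau0 must lie in (0, 1]")
  T_R <- spec$T_R
  d_s <- sched$d[sched$s]
  u <- switch(spec$model,
              fixed = tau0 * T_R,
              increasing = {
                cc <- tau0 * T_R * (T_R + 1)  # u(u+1) = cc
                (-1 + sqrt(1 + 4 * cc)) / 2
              },
              decreasing = {
                cc <- tau0 * T_R * (T_R + 1)  # u(2T_R + 1 - u) = cc
                b <- 2 * T_R + 1
                (b - sqrt(b^2 - 4 * cc)) / 2
              })
  d_s + u
}

#' Ratio of expected counts between two occasions
#'
#' \eqn{n_{rr'}(t) = N_r(t)/N_{r'}(t) = g_r(t,d_r)/g_{r'}(t,d_{r'})}, a
#' dimensionless quantity independent of N and of the allocation weight. The
#' ratio \eqn{n_{s1}(t)} drives the variance-reduction factor bounds.
#'
#' @param spec A \code{\link{recruitment_model}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @param t Calendar time.
#' @param r,r_prime Occasion indices (1 to s).
#' @return Dimensionless ratio.
#' @export
ratio_n <- function(spec, sched, t, r, r_prime) {
  num <- accrual_g(spec, t, sched$d[r])
  den <- accrual_g(spec, t, sched$d[r_prime])
  if (any(den == 0)) stop("denominator occasion has no accrued data at time t")
  num / den
}
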