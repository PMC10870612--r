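#' Within-participant correlation model
#'
#' Single-parameter working correlation structures for the longitudinal
#' outcome vector:
#' \describe{
#'   \item{uniform}{compound symmetry: every pair of occasions has
#'     correlation \eqn{\alpha}, whatever their separation. The natural model
#'     for outcomes driven by stable participant-level characteristics, and
#'     commonly seen with patient-reported outcome measures.}
#'   \item{exponential}{AR(1)-type decay:
#'     \eqn{\rho_{rr'} = \gamma^{|d_r - d_{r'}|}} falls towards zero as the
#'     time separation grows; \eqn{\gamma} is the correlation at unit
#'     separation in the schedule's time units.}
#' }
#' The parameter is restricted to [0, 1); at 1 the correlation matrix is
#' singular and the limiting behaviour is handled analytically by the
#' variance formulas instead.
#'
#' @param kind \code{"uniform"} or \code{"exponential"}.
#' @param param Correlation parameter in [0, 1) (\eqn{\alpha} for uniform,
#'   \eqn{\gamma} for exponential).
#' @return An object of class \code{"correlation_model"}.
#' @export
correlation_model <- function(kind = c("uniform", "exponential"), param) {
  kind <- match.arg(kind)
  if (!is.numeric(param) || length(param) != 1L || !is.finite(param) ||
      param < 0 || param >= 1)
    stop("correlation parameter must lie in [0, 1)")
  structure(list(kind = kind, param = param), class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  sym <- if (x$kind == "uniform") "alpha" else "gamma"
  cat(sprintf("Correlation model: %s, %s = %g\n", x$kind, sym, x$param))
  invisible(x)
}

#' Correlation matrix over a follow-up schedule
#'
#' @param spec A \code{\link{correlation_model}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @return The s x s correlation matrix R: unit diagonal, symmetric, positive
#'   definite for parameters in [0, 1).
#' @examples
#' sched <- follow_up_schedule(c(1, 2, 4, 6))
#' corr_matrix(correlation_model("exponential", 0.5^(1/3)), sched)
#' @export
corr_matrix <- function(spec, sched) {
  stopifnot(inherits(spec, "correlation_model"), inherits(sched, "follow_up_schedule"))
  s <- sched$s
  if (spec$kind == "uniform") {
    R <- matrix(spec$param, s, s)
    diag(R) <- 1
  } else {
    R <- spec$param^abs(outer(sched$d, sched$d, "-"))
    # 0^0 = 1 handles the gamma = 0 diagonal
  }
  R
}

#' Determinant of the uniform (compound-symmetry) correlation matrix
#'
#' Closed form \eqn{\det(R_m) = (1-\alpha)^{m-1}\{1 + (m-1)\alpha\}} for the
#' m x m matrix with unit diagonal and constant off-diagonal \eqn{\alpha}.
#' Ratios of successive determinants are the weights in the uniform-model
#' variance formula.
#'
#' @param m Matrix order (>= 1).
#' @param alpha Off-diagonal correlation in [0, 1).
#' @return Determinant value (positive).
#' @export
det_uniform <- function(m, alpha) {
  if (any(m < 1) || any(m != round(m))) stop("m must be a positive integer")
  (1 - alpha)^(m - 1) * (1 + (m - 1) * alpha)
}

#' Closed-form inverse of the correlation matrix
#'
#' For the uniform model,
#' \eqn{R^{-1} = \{I - \alpha J / (1 + (s-1)\alpha)\} / (1-\alpha)} with J the
#' all-ones matrix. For the exponential model the inverse is tridiagonal,
#' built from the adjacent-occasion correlations
#' \eqn{a_r = \gamma^{d_{r+1} - d_r}}: corner diagonal entries
#' \eqn{1/(1-a^2)}, interior diagonal entries
#' \eqn{(1 - a_{r-1}^2 a_r^2)/\{(1-a_{r-1}^2)(1-a_r^2)\}} and off-diagonal
#' entries \eqn{-a_r/(1-a_r^2)}. These closed forms are what make the
#' variance of the primary treatment effect analytically tractable.
#'
#' @param spec A \code{\link{correlation_model}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @return The s x s inverse correlation matrix.
#' @export
inv_corr_closed <- function(spec, sched) {
  stopifnot(inherits(spec, "correlation_model"), inherits(sched, "follow_up_schedule"))
  s <- sched$s
  p <- spec$param
  if (spec$kind == "uniform") {
    J <- matrix(1, s, s)
    (diag(s) - p / (1 + (s - 1) * p) * J) / (1 - p)
  } else {
    a <- p^diff(sched$d)               # adjacent correlations, length s - 1
    w <- 1 - a^2
    Rinv <- matrix(0, s, s)
    dg <- numeric(s)
    dg[1] <- 1 / w[1]
    dg[s] <- 1 / w[s - 1]
    if (s > 2) {
      r <- 2:(s - 1)
      dg[r] <- (1 - a[r - 1]^2 * a[r]^2) / (w[r - 1] * w[r])
    }
    diag(Rinv) <- dg
    for (r in seq_len(s - 1)) {
      Rinv[r, r + 1] <- Rinv[r + 1, r] <- -a[r] / w[r]
    }
    Rinv
  }
}

#' Calibrate the exponential decay parameter from a reference correlation
#'
#' Given a known or assumed correlation \code{rho_ref} between the outcomes at
#' two occasions, returns the per-unit decay parameter
#' \eqn{\gamma = \rho^{1/|d_r - d_{r'}|}} that reproduces it under the
#' exponential model.
#'
#' @param rho_ref Reference correlation in (0, 1).
#' @param d_r,d_r_prime The two occasion times (distinct).
#' @return The decay parameter \eqn{\gamma} in (0, 1).
#' @examples
#' gamma_from_reference(0.5, 1, 4)  # 0.5^(1/3)
#' @export
gamma_from_reference <- function(rho_ref, d_r, d_r_prime) {
  if (!is.numeric(rho_ref) || length(rho_ref) != 1L || rho_ref <= 0 || rho_ref >= 1)
    stop("rho_ref must lie strictly between 0 and 1")
  if (d_r == d_r_prime) stop("occasion times must differ")
  rho_ref^(1 / abs(d_r - d_r_prime))
}

#' Outcome covariance matrix
#'
#' Assembles \eqn{\Sigma = S^{1/2} R S^{1/2}} from occasion-specific outcome
#' standard deviations and a correlation model.
#'
#' @param sigma Vector of outcome SDs, one per occasion (all positive); a
#'   single value is recycled across occasions.
#' @param spec A \code{\link{correlation_model}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @return The s x s covariance matrix.
#' @export
cov_matrix <- function(sigma, spec, sched) {
  stopifnot(inherits(sched, "follow_up_schedule"))
  if (length(sigma) == 1L) sigma <- rep(sigma, sched$s)
  if (length(sigma) != sched$s || any(sigma <= 0))
    stop("sigma must be positive, with one value per occasion")
  R <- corr_matrix(spec, sched)
  outer(sigma, sigma) * R
}
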