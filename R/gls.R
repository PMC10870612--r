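# Internal: summarise a long-format monotone dataset into
# (pattern length r, arm) groups with sufficient statistics.
# Validates the prefix (monotone missingness) property.
pattern_groups <- function(data, s) {
  need <- c("id", "arm", "occasion", "y")
  if (!all(need %in% names(data)))
    stop("data must have columns id, arm, occasion, y")
  sp <- split(data[, c("arm", "occasion", "y")], data$id)
  groups <- list()
  for (di in sp) {
    r <- nrow(di)
    occ <- sort(di$occasion)
    if (!identical(as.integer(occ), seq_len(r)))
      stop("monotone missingness violated: occasions per participant must be a prefix 1..r")
    j <- di$arm[1]
    key <- paste(r, j, sep = ".")
    y <- di$y[order(di$occasion)]
    if (is.null(groups[[key]])) {
      groups[[key]] <- list(r = r, arm = j, n = 0L,
                            Sy = numeric(r), Syy = matrix(0, r, r))
    }
    g <- groups[[key]]
    g$n <- g$n + 1L
    g$Sy <- g$Sy + y
    g$Syy <- g$Syy + tcrossprod(y)
    groups[[key]] <- g
  }
  groups
}

# design matrix for a pattern of length r and arm j, on 2*s_use columns
pattern_X <- function(r, j, s_use) {
  X <- cbind(diag(1, r, s_use), matrix(0, r, s_use))
  if (j == 1) X[, s_use + seq_len(r)] <- diag(1, r, r)
  X
}

#' Generalized least squares fit for monotone longitudinal trial data
#'
#' Fits the cell-means longitudinal model with known covariance: for each
#' occasion a mean level (columns 1..s of the design matrix) and a
#' treatment-by-occasion effect (columns s+1..2s, active in the treatment arm
#' only), so that the final coefficient is \eqn{\beta_s}, the treatment
#' effect at the primary endpoint. The estimator is
#' \eqn{\hat\beta = (\sum_i X_i'\Sigma_i^{-1}X_i)^{-1}\sum_i X_i'\Sigma_i^{-1}y_i}
#' with \eqn{\Sigma_i} the leading submatrix of the supplied covariance for
#' participant i's observed prefix. Computation is grouped by missingness
#' pattern and arm (at most 2s distinct blocks), which is algebraically
#' identical to the per-participant sum.
#'
#' Occasions for which one arm has no observations are not identifiable;
#' their columns (and any later occasions, which by monotonicity have no
#' data either) are dropped, the fit is flagged through
#' \code{dropped_occasions}, and coefficients are returned as \code{NA}.
#'
#' @param data Long-format data frame with columns \code{id}, \code{arm}
#'   (0/1), \code{occasion}, \code{y}, e.g. from \code{\link{simulate_trial}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @param corr A \code{\link{correlation_model}} (known or plug-in).
#' @param sigma Outcome SD, single value or one per occasion.
#' @return An object of class \code{"gls_fit"}: \code{beta} (length 2s),
#'   \code{vcov} (2s x 2s), \code{z} = \eqn{\hat\beta_s/sd(\hat\beta_s)},
#'   \code{info} = \eqn{1/var(\hat\beta_s)}, \code{n_by_pattern} and
#'   \code{dropped_occasions}.
#' @export
gls_fit <- function(data, sched, corr, sigma) {
  stopifnot(inherits(sched, "follow_up_schedule"), inherits(corr, "correlation_model"))
  s <- sched$s
  Sigma <- cov_matrix(sigma, corr, sched)
  groups <- pattern_groups(data, s)
  # occasions usable: both arms observed there; monotonicity makes this a prefix
  max_r <- vapply(groups, function(g) g$r, integer(1))
  arm_g <- vapply(groups, function(g) g$arm, numeric(1))
  s_use <- min(max(max_r[arm_g == 0], 0), max(max_r[arm_g == 1], 0))
  if (s_use < 1)
    stop("identifiability error: no occasion has observations in both arms")
  A <- matrix(0, 2 * s_use, 2 * s_use)
  b <- numeric(2 * s_use)
  n_by_pattern <- data.frame(pattern = integer(0), arm = integer(0), n = integer(0))
  for (g in groups) {
    r <- min(g$r, s_use)  # truncate patterns beyond the identifiable prefix
    W <- solve(Sigma[seq_len(r), seq_len(r), drop = FALSE])
    X <- pattern_X(r, g$arm, s_use)
    A <- A + g$n * crossprod(X, W %*% X)
    b <- b + crossprod(X, W %*% g$Sy[seq_len(r)])
    n_by_pattern <- rbind(n_by_pattern,
                          data.frame(pattern = g$r, arm = g$arm, n = g$n))
  }
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("identifiability error: singular information matrix for occasions 1..", s_use))
  beta_use <- drop(Ainv %*% b)
  beta <- rep(NA_real_, 2 * s)
  beta[seq_len(s_use)] <- beta_use[seq_len(s_use)]
  beta[s + seq_len(s_use)] <- beta_use[s_use + seq_len(s_use)]
  vcov <- matrix(NA_real_, 2 * s, 2 * s)
  idx <- c(seq_len(s_use), s + seq_len(s_use))
  vcov[idx, idx] <- Ainv
  if (s_use == s) {
    var_bs <- Ainv[2 * s_use, 2 * s_use]
    z <- beta[2 * s] / sqrt(var_bs)
    info <- 1 / var_bs
  } else {
    z <- info <- NA_real_
  }
  structure(list(beta = beta, vcov = vcov, z = z, info = info,
                 n_by_pattern = n_by_pattern[order(n_by_pattern$pattern,
                                                   n_by_pattern$arm), ],
                 dropped_occasions = if (s_use < s) (s_use + 1):s else integer(0)),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  s <- length(x$beta) / 2
  cat(sprintf("GLS fit: beta_s = %.4g, sd = %.4g, z = %.4g, information = %.4g\n",
              x$beta[2 * s], sqrt(x$vcov[2 * s, 2 * s]), x$z, x$info))
  if (length(x$dropped_occasions))
    cat("dropped occasions (unidentifiable):",
        paste(x$dropped_occasions, collapse = ", "), "\n")
  invisible(x)
}

#' Monitoring z-statistic and information from a GLS fit
#'
#' The sequential test statistic \eqn{Z = \hat\beta_s / sd(\hat\beta_s)} and
#' the statistical information \eqn{I = 1/var(\hat\beta_s)} used to place an
#' interim analysis on the information scale. Comparing z with a design's
#' boundaries yields the stop/continue decision.
#'
#' @param fit A \code{\link{gls_fit}}.
#' @return List with elements \code{z} and \code{info}.
#' @export
monitoring_statistic <- function(fit) {
  stopifnot(inherits(fit, "gls_fit"))
  list(z = fit$z, info = fit$info)
}

#' Maximum likelihood estimation of the outcome covariance
#'
#' Estimates the correlation parameter and the occasion-specific outcome SDs
#' from accumulating monotone trial data by maximising the multivariate
#' normal likelihood, with the mean parameters profiled out by GLS at each
#' candidate covariance. The correlation parameter is kept inside [0, 1);
#' solutions on the boundary are flagged.
#'
#' @param data Long-format data as for \code{\link{gls_fit}}.
#' @param sched A \code{\link{follow_up_schedule}}.
#' @param kind Correlation family, \code{"uniform"} or \code{"exponential"}.
#' @return List with \code{param}, \code{se_param} (from the numerical
#'   Hessian at the optimum), \code{sigma}, \code{loglik}, \code{corr} (a
#'   fitted \code{\link{correlation_model}}) and \code{boundary} (TRUE if
#'   the estimate hit a parameter bound).
#' @export
estimate_covariance_ml <- function(data, sched, kind = c("uniform", "exponential")) {
  kind <- match.arg(kind)
  stopifnot(inherits(sched, "follow_up_schedule"))
  s <- sched$s
  groups <- pattern_groups(data, s)
  s_obs <- max(vapply(groups, function(g) g$r, integer(1)))
  # empirical per-occasion SDs as starting values
  sd0 <- vapply(seq_len(s), function(r) {
    yr <- data$y[data$occasion == r]
    if (length(yr) > 1) stats::sd(yr) else 1
  }, numeric(1))
  negll <- function(theta) {
    p <- theta[1]
    sig <- exp(theta[-1])
    Sigma <- cov_matrix(sig, correlation_model(kind, p), sched)
    # GLS profile of the mean parameters
    pats <- sort(unique(pmin(vapply(groups, function(g) g$r, integer(1)), s_obs)))
    Ws <- lds <- vector("list", s)
    for (r in pats) {
      Sr <- Sigma[seq_len(r), seq_len(r), drop = FALSE]
      Ws[[r]] <- solve(Sr)
      lds[[r]] <- determinant(Sr, logarithm = TRUE)$modulus
    }
    A <- matrix(0, 2 * s_obs, 2 * s_obs)
    b <- numeric(2 * s_obs)
    for (g in groups) {
      r <- g$r
      X <- pattern_X(r, g$arm, s_obs)
      A <- A + g$n * crossprod(X, Ws[[r]] %*% X)
      b <- b + crossprod(X, Ws[[r]] %*% g$Sy)
    }
    beta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    ll <- 0
    for (g in groups) {
      r <- g$r
      mu_g <- drop(pattern_X(r, g$arm, s_obs) %*% beta)
      quad <- sum(Ws[[r]] * g$Syy) - 2 * sum(mu_g * (Ws[[r]] %*% g$Sy)) +
        g$n * drop(crossprod(mu_g, Ws[[r]] %*% mu_g))
      ll <- ll - 0.5 * g$n * as.numeric(lds[[r]]) - 0.5 * quad
    }
    -ll
  }
  theta0 <- c(0.3, log(sd0))
  eps <- 1e-6
  fit <- stats::optim(theta0, negll, method = "L-BFGS-B",
                      lower = c(0, rep(log(1e-8), s)),
                      upper = c(1 - eps, rep(log(1e8), s)),
                      control = list(maxit = 500), hessian = TRUE)
  if (fit$convergence != 0)
    stop("covariance ML estimation failed to converge: ", fit$message)
  param <- fit$par[1]
  se_param <- tryCatch(sqrt(solve(fit$hessian)[1, 1]), error = function(e) NA_real_)
  list(param = param, se_param = se_param,
       sigma = exp(fit$par[-1]), loglik = -fit$value,
       corr = correlation_model(kind, min(param, 1 - eps)),
       boundary = param <= 1e-8 || param >= 1 - 2 * eps)
}
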