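# Shared builders and independent oracles for the test suite.

# three-occasion shoulder-trial configuration used throughout
sr_sched <- function() follow_up_schedule(c(1, 2, 4))
sr_rec <- function(model = "fixed") recruitment_model(model, N = 188, T_R = 8)
sr_imax <- function() 188 * 0.25 / 144

# random monotone positive per-arm occasion counts
rand_counts <- function(s, min_last = 3) {
  inc <- stats::runif(s, 0.5, 30)
  rev(cumsum(inc)) + min_last
}

# exact first-exit probabilities of the canonical joint distribution via
# multivariate-normal orthant probabilities (independent of the package's
# recursive-integration route)
exit_probs_mvn <- function(I, lower, upper, delta) {
  K <- length(I)
  m <- delta * sqrt(I)
  S <- outer(seq_len(K), seq_len(K), function(j, k) sqrt(pmin(I[j], I[k]) / pmax(I[j], I[k])))
  p_lower <- p_upper <- numeric(K)
  alg <- mvtnorm::Miwa(steps = 2048)  # deterministic, ~1e-7 accurate
  clip <- function(x) pmin(pmax(x, -38), 38)  # finite stand-in for +/-Inf
  lower <- clip(lower); upper <- clip(upper)
  for (k in seq_len(K)) {
    idx <- seq_len(k)
    lo <- c(lower[idx[-k]], -38); up <- c(upper[idx[-k]], lower[k])
    p_lower[k] <- mvtnorm::pmvnorm(lower = lo, upper = up, mean = m[idx],
                                   sigma = S[idx, idx, drop = FALSE],
                                   algorithm = alg)
    lo <- c(lower[idx[-k]], upper[k]); up <- c(upper[idx[-k]], 38)
    p_upper[k] <- mvtnorm::pmvnorm(lower = lo, upper = up, mean = m[idx],
                                   sigma = S[idx, idx, drop = FALSE],
                                   algorithm = alg)
  }
  list(lower = p_lower, upper = p_upper)
}

# naive per-participant GLS (no pattern grouping) as an independent check
gls_naive <- function(data, sched, corr, sigma) {
  s <- sched$s
  Sigma <- cov_matrix(sigma, corr, sched)
  A <- matrix(0, 2 * s, 2 * s)
  b <- numeric(2 * s)
  for (i in unique(data$id)) {
    di <- data[data$id == i, ]
    di <- di[order(di$occasion), ]
    r <- nrow(di)
    X <- cbind(diag(1, r, s), matrix(0, r, s))
    if (di$arm[1] == 1) X[, s + seq_len(r)] <- diag(1, r, r)
    W <- solve(Sigma[seq_len(r), seq_len(r), drop = FALSE])
    A <- A + crossprod(X, W %*% X)
    b <- b + crossprod(X, W %*% di$y)
  }
  Ainv <- solve(A)
  list(beta = drop(Ainv %*% b), vcov = Ainv)
}

# simulation spec for the shoulder-trial configuration
sr_sim_spec <- function(model = "fixed", N = 188, analysis_time = 6,
                        alpha = 0.5, delta = 6, sigma = 12) {
  sched <- sr_sched()
  simulation_spec(recruitment_model(model, N, 8), sched,
                  mu = cbind(rep(0, 3), c(delta / 3, delta / 2, delta)),
                  sigma = sigma,
                  corr = correlation_model("uniform", alpha),
                  analysis_time = analysis_time)
}
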