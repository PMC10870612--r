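#' Variance-reduction factor tables across designs
#'
#' Tabulates, for s = 2..6 occasions, the three recruitment models and three
#' interim timings ("early", "mid", "late" at primary-outcome proportions
#' \eqn{\tau_0} = 0.15, 0.30, 0.45), the count ratio \eqn{n_{s1}}, the
#' uniform-model weight D, the equal-spacing variance-reduction factor
#' \eqn{\tilde V} (schedule \eqn{d_r = 1 + (r-1)/(s-1)} on \eqn{[1, 2]}), and
#' the analytic minimum and maximum of V over the intermediate spacings.
#' Both correlation families are tabulated; the exponential decay parameter
#' is calibrated as \eqn{\gamma = \alpha^{1/(d_s - d_1)}} so that the two
#' families share the same first-to-final correlation (and hence the same
#' maximum). The recruitment period is \eqn{T_R = 4 d_s}.
#'
#' @param alpha Uniform-model correlation (default 0.5).
#' @param s_values Numbers of occasions to tabulate.
#' @param tau0_values Primary-outcome information fractions of the interim
#'   analyses.
#' @param tr_multiple Recruitment period as a multiple of \eqn{d_s}.
#' @return List of two data frames, \code{uniform} and \code{exponential},
#'   one row per (model, s, timing) combination with columns \code{n_s1},
#'   \code{D} (uniform only), \code{V_equal}, \code{V_min}, \code{V_max}.
#' @export
v_factor_tables <- function(alpha = 0.5, s_values = 2:6,
                            tau0_values = c(early = 0.15, mid = 0.30, late = 0.45),
                            tr_multiple = 4) {
  d1 <- 1; ds <- 2
  T_R <- tr_multiple * ds
  gamma <- alpha^(1 / (ds - d1))
  models <- c("fixed", "increasing", "decreasing")
  if (is.null(names(tau0_values)))
    names(tau0_values) <- paste0("t", seq_along(tau0_values))
  rows_u <- rows_e <- list()
  for (model in models) {
    rec <- recruitment_model(model, N = 100, T_R = T_R)  # N cancels in every ratio
    for (s in s_values) {
      sched <- follow_up_schedule(d1 + (ds - d1) * (seq_len(s) - 1) / (s - 1))
      for (w in seq_along(tau0_values)) {
        t_w <- time_at_tau0(rec, sched, tau0_values[[w]])
        n_s1 <- ratio_n(rec, sched, t_w, s, 1)
        pt_u <- design_point(t_w, sched, rec, correlation_model("uniform", alpha),
                             sigma_s = 1)
        Vu <- v_factor(pt_u)
        eu <- v_uniform_extrema(alpha, s, n_s1)
        rows_u[[length(rows_u) + 1L]] <- data.frame(
          model = model, s = s, timing = names(tau0_values)[w], t = t_w,
          n_s1 = n_s1, D = attr(Vu, "D"), V_equal = as.numeric(Vu),
          V_min = eu["min"], V_max = eu["max"])
        pt_e <- design_point(t_w, sched, rec, correlation_model("exponential", gamma),
                             sigma_s = 1)
        Ve <- as.numeric(v_factor(pt_e))
        emax <- v_exp_max(gamma, d1, ds, n_s1)
        emin <- if (s >= 3)
          v_exp_min(gamma, s, d1, ds, t_w, rec)$min else emax
        rows_e[[length(rows_e) + 1L]] <- data.frame(
          model = model, s = s, timing = names(tau0_values)[w], t = t_w,
          n_s1 = n_s1, V_equal = Ve, V_min = emin, V_max = emax)
      }
    }
  }
  uniform <- do.call(rbind, rows_u)
  exponential <- do.call(rbind, rows_e)
  rownames(uniform) <- rownames(exponential) <- NULL
  list(uniform = uniform, exponential = exponential)
}

#' Replan a three-occasion shoulder-surgery trial with closed forms
#'
#' End-to-end worked example: a two-arm trial with outcomes at 3, 6 and 12
#' months (schedule d = (1, 2, 4) in 3-month units), N = 188 participants
#' recruited over 24 months (T_R = 8), equal allocation, primary-outcome SD
#' 12, uniform correlation 0.5, and interim analyses when 25\% and 35\% of
#' participants have primary outcome data. For the chosen recruitment model
#' the function computes the interim times, expected occasion counts,
#' information, information fractions and the design power for a treatment
#' difference of 6 points, using supplied z-scale boundaries.
#'
#' @param model Recruitment model kind.
#' @param N Total sample size.
#' @param T_R Recruitment period.
#' @param d Follow-up schedule times.
#' @param sigma_s Primary-outcome SD.
#' @param alpha Uniform correlation.
#' @param tau0_targets Primary-outcome proportions triggering the interims.
#' @param lower,upper z-scale boundaries (interims then final).
#' @param delta Treatment difference for the power calculation.
#' @param phi Allocation weight.
#' @return An object of class \code{"planning_report"}: a list with the
#'   per-analysis \code{table} (time, expected counts, information, tau,
#'   bounds), \code{I_max} and \code{power}.
#' @examples
#' replan_start_reacts("fixed")
#' @export
replan_start_reacts <- function(model = c("fixed", "decreasing", "increasing"),
                                N = 188, T_R = 8, d = c(1, 2, 4), sigma_s = 12,
                                alpha = 0.5, tau0_targets = c(0.25, 0.35),
                                lower = c(-0.706, 0.581, 1.907),
                                upper = c(Inf, 3.090, 1.907),
                                delta = 6, phi = 0.5) {
  model <- match.arg(model)
  sched <- follow_up_schedule(d)
  rec <- recruitment_model(model, N, T_R)
  alloc <- allocation_spec(phi)
  corr <- correlation_model("uniform", alpha)
  I_max <- N * phi * (1 - phi) / sigma_s^2
  s <- sched$s
  K <- length(tau0_targets) + 1L
  if (length(lower) != K || length(upper) != K)
    stop("need one bound per interim plus the final analysis")
  t_k <- vapply(tau0_targets, function(x) time_at_tau0(rec, sched, x), numeric(1))
  rows <- lapply(seq_along(t_k), function(k) {
    infs <- information_fraction(design_point(t_k[k], sched, rec, corr, alloc, sigma_s))
    counts <- vapply(seq_len(s), function(r)
      n_with_outcome(rec, sched, t_k[k], r), numeric(1))
    data.frame(analysis = k, t = t_k[k], rbind(stats::setNames(counts, paste0("N_", seq_len(s)))),
               V = infs$V, info = infs$info, tau0 = infs$tau0, tau = infs$tau,
               lower = lower[k], upper = upper[k])
  })
  final <- data.frame(analysis = K, t = sched$d[s] + T_R,
                      rbind(stats::setNames(rep(N, s), paste0("N_", seq_len(s)))),
                      V = 1, info = I_max, tau0 = 1, tau = 1,
                      lower = lower[K], upper = upper[K])
  tab <- rbind(do.call(rbind, rows), final)
  rownames(tab) <- NULL
  design <- gsd_design(tab$tau, I_max, lower, upper)
  structure(list(model = model, table = tab, I_max = I_max,
                 design = design, delta = delta,
                 power = gsd_power(design, delta)),
            class = "planning_report")
}

#' @export
print.planning_report <- function(x, ...) {
  cat(sprintf("Planning report (%s recruitment): I_max = %.3f, power = %.1f%% at delta = %g\n",
              x$model, x$I_max, 100 * x$power, x$delta))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Futility stopping probability grid over interim timing and correlation
#'
#' For a grid of first-interim times \eqn{t_1} and uniform correlations
#' \eqn{\alpha}, computes the probabilities \eqn{p_1} and \eqn{p_2} of
#' stopping for futility at the first and second interim analysis under a
#' given (typically adverse) treatment difference, with the planned z-scale
#' lower bounds held fixed while the realized information varies with
#' \eqn{t_1} and \eqn{\alpha}. The second interim stays at its planned
#' calendar time. Information at each interim is
#' \eqn{I_k = \tau_k I_{max}} with \eqn{\tau_k = \tau_0(t_k)/V(t_k)} from the
#' uniform-model variance-reduction factor.
#'
#' @param t1 Vector of first-interim calendar times (each above \eqn{d_s}).
#' @param alpha Vector of uniform correlations in [0, 1).
#' @param delta Treatment difference (default -4, an adverse effect).
#' @param t2 Planned second-interim calendar time.
#' @param lower Planned lower bounds at the two interims.
#' @param model,N,T_R,d,sigma_s,phi Trial configuration, as in
#'   \code{\link{replan_start_reacts}}.
#' @return Data frame over the grid with columns \code{t1}, \code{alpha},
#'   \code{tau1}, \code{p1}, \code{p2}.
#' @examples
#' fig2_grid(t1 = c(4.5, 6.5), alpha = c(0, 0.8))
#' @export
fig2_grid <- function(t1, alpha, delta = -4, t2 = 6.8,
                      lower = c(-0.706, 0.581),
                      model = "fixed", N = 188, T_R = 8, d = c(1, 2, 4),
                      sigma_s = 12, phi = 0.5) {
  sched <- follow_up_schedule(d)
  rec <- recruitment_model(model, N, T_R)
  alloc <- allocation_spec(phi)
  I_max <- N * phi * (1 - phi) / sigma_s^2
  grid <- expand.grid(t1 = t1, alpha = alpha)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$alpha[i]
    tt <- grid$t1[i]
    if (tt >= t2) stop("first interim must precede the second (t1 < t2)")
    corr <- correlation_model("uniform", a)
    f1 <- information_fraction(design_point(tt, sched, rec, corr, alloc, sigma_s))
    f2 <- information_fraction(design_point(t2, sched, rec, corr, alloc, sigma_s))
    p <- futility_probability_fixed_bounds(lower, c(f1$tau, f2$tau) * I_max, delta)
    data.frame(t1 = tt, alpha = a, tau1 = f1$tau, p1 = p[1], p2 = p[2])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
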