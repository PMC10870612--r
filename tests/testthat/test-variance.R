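test_that("two-occasion closed form matches direct evaluation", {
  sched <- follow_up_schedule(c(1, 2))
  # rho = 0: only primary-outcome data matter
  v0 <- var_beta_counts(c(50, 25), c(50, 25),
                        correlation_model("uniform", 0), sched, 1)
  expect_equal(v0, 0.08)
  # rho = 0.5: h_2 (1 - rho^2) + h_1 rho^2
  v <- var_beta_counts(c(50, 25), c(50, 25),
                       correlation_model("uniform", 0.5), sched, 1)
  expect_equal(v, 0.08 * 0.75 + 0.04 * 0.25)
  # exponential with gamma^(d2-d1) = 0.5 gives the same value
  ve <- var_beta_counts(c(50, 25), c(50, 25),
                        correlation_model("exponential", 0.5), sched, 1)
  expect_equal(ve, v)
  expect_error(var_beta_counts(c(25, 50), c(50, 25),
                               correlation_model("uniform", 0.5), sched, 1),
               "non-increasing")
})

test_that("interim information at the shoulder-trial counts matches 0.101", {
  v <- var_beta_counts(c(117.5, 94, 47) / 2, c(117.5, 94, 47) / 2,
                       correlation_model("uniform", 0.5), sr_sched(), 12)
  expect_equal(1 / v, 0.101, tolerance = 5e-3)
  expect_equal(round(1 / v, 3), 0.101)
})

test_that("closed-form variance equals the GLS matrix oracle on random configs", {
  set.seed(101)
  for (i in 1:200) {
    s <- sample(2:5, 1)
    d <- sort(stats::runif(s, 0.5, 6))
    while (min(diff(d)) < 0.05) d <- sort(stats::runif(s, 0.5, 6))
    sched <- follow_up_schedule(d)
    kind <- if (i %% 2 == 0) "uniform" else "exponential"
    cm <- correlation_model(kind, stats::runif(1, 0, 0.95))
    N0 <- rand_counts(s); N1 <- rand_counts(s)
    sig <- stats::runif(1, 0.5, 15)
    closed <- var_beta_counts(N0, N1, cm, sched, sig)
    oracle <- gls_variance_oracle(N0, N1, cm, sched, sig)
    expect_equal(closed, oracle, tolerance = 1e-8)
  }
})

test_that("var(beta_s) does not depend on the early-outcome SDs", {
  # the GLS variance of the primary effect involves sigma_s and the
  # correlations only; heterogeneous early SDs cancel
  set.seed(7)
  sched <- follow_up_schedule(c(1, 2, 4))
  cm <- correlation_model("exponential", 0.6)
  N0 <- c(60, 40, 20); N1 <- c(55, 35, 18)
  base <- gls_variance_oracle(N0, N1, cm, sched, c(12, 12, 12))
  hetero <- gls_variance_oracle(N0, N1, cm, sched, c(3, 40, 12))
  expect_equal(base, hetero, tolerance = 1e-10)
  expect_equal(base, var_beta_counts(N0, N1, cm, sched, 12), tolerance = 1e-10)
})

test_that("variance limits: no correlation, complete data, perfect correlation", {
  sched <- sr_sched()
  rec <- sr_rec()
  # alpha = 0 reduces to primary-data-only variance sigma^2/(k phi(1-phi) g_s)
  pt0 <- design_point(6, sched, rec, correlation_model("uniform", 0), sigma_s = 12)
  expect_equal(var_beta_at(pt0), 144 / (rec$k * 0.25 * accrual_g(rec, 6, 4)))
  expect_equal(as.numeric(v_factor(pt0)), 1)
  # complete data: var = 4 sigma_s^2 / N for equal allocation, any correlation
  for (kind in c("uniform", "exponential")) {
    ptc <- design_point(12, sched, rec, correlation_model(kind, 0.5), sigma_s = 12)
    expect_equal(var_beta_at(ptc), 4 * 144 / 188)
  }
  # alpha -> 1: everything comes from the first early outcome
  N0 <- c(60, 40, 20); N1 <- c(60, 40, 20)
  v1 <- var_beta_counts(N0, N1, correlation_model("uniform", 1 - 1e-9), sched, 1)
  expect_equal(v1, (60 + 60) / (60 * 60), tolerance = 1e-6)
})

test_that("V matches the reported planning values and exposes D", {
  u <- correlation_model("uniform", 0.5)
  ptF <- design_point(6, sr_sched(), sr_rec("fixed"), u, sigma_s = 12)
  VF <- v_factor(ptF)
  expect_equal(round(as.numeric(VF), 3), 0.808)
  expect_equal(attr(VF, "D"), (1 - 0.5) * 2 / 1.5)
  recD <- sr_rec("decreasing")
  ptD <- design_point(time_at_tau0(recD, sr_sched(), 0.25), sr_sched(), recD, u,
                      sigma_s = 12)
  expect_equal(round(as.numeric(v_factor(ptD)), 3), 0.786)
  # exponential, equal spacing d = (1, 1.5, 2), fixed model, early interim
  sched3 <- follow_up_schedule(c(1, 1.5, 2))
  pt <- design_point(3.2, sched3, recruitment_model("fixed", 100, 8),
                     correlation_model("exponential", 0.5), sigma_s = 1)
  expect_equal(round(as.numeric(v_factor(pt)), 2), 0.81)
})

test_that("V is monotone non-increasing in the correlation parameter", {
  params <- seq(0, 0.95, by = 0.05)
  for (model in c("fixed", "increasing", "decreasing")) {
    rec <- recruitment_model(model, 100, 8)
    for (s in 2:6) {
      sched <- follow_up_schedule(1 + (seq_len(s) - 1) / (s - 1))
      tt <- time_at_tau0(rec, sched, 0.3)
      for (kind in c("uniform", "exponential")) {
        V <- vapply(params, function(p)
          as.numeric(v_factor(design_point(tt, sched, rec,
                                           correlation_model(kind, p),
                                           sigma_s = 1))), numeric(1))
        expect_true(all(diff(V) <= 1e-12))
        expect_equal(V[1], 1)
      }
    }
  }
})

test_that("analytic extrema bracket V under random intermediate spacings", {
  set.seed(202)
  rec <- recruitment_model("fixed", 100, 8)
  d1 <- 1; ds <- 2
  for (i in 1:200) {
    s <- sample(3:6, 1)
    dmid <- sort(stats::runif(s - 2, d1 + 1e-3, ds - 1e-3))
    sched <- follow_up_schedule(c(d1, dmid, ds))
    tt <- stats::runif(1, ds + 0.2, ds + 6)
    n_s1 <- ratio_n(rec, sched, tt, s, 1)
    a <- stats::runif(1, 0, 0.95)
    Vu <- as.numeric(v_factor(design_point(tt, sched, rec,
                                           correlation_model("uniform", a), sigma_s = 1)))
    eu <- v_uniform_extrema(a, s, n_s1)
    expect_true(Vu >= eu["min"] - 1e-10 && Vu <= eu["max"] + 1e-10)
    expect_true(Vu >= n_s1 - 1e-12 && Vu <= 1 + 1e-12)
    g <- stats::runif(1, 0, 0.95)
    Ve <- as.numeric(v_factor(design_point(tt, sched, rec,
                                           correlation_model("exponential", g), sigma_s = 1)))
    expect_true(Ve <= v_exp_max(g, d1, ds, n_s1) + 1e-10)
    expect_true(Ve >= n_s1 - 1e-12 && Ve <= 1 + 1e-12)
  }
})

test_that("uniform extrema: degenerate cases and tabulated values", {
  expect_equal(v_uniform_extrema(0, 4, 0.55), c(min = 1, max = 1))
  e2 <- v_uniform_extrema(0.5, 2, 0.55)
  expect_equal(unname(e2["min"]), unname(e2["max"]))
  rec <- recruitment_model("fixed", 100, 8)
  sched2 <- follow_up_schedule(c(1, 2))
  n_s1 <- ratio_n(rec, sched2, 3.2, 2, 1)
  e3 <- v_uniform_extrema(0.5, 3, n_s1)
  expect_equal(round(unname(e3), 2), c(0.85, 0.89))
  # D is decreasing in s towards (1 - alpha)
  D <- vapply(2:10, function(s) (1 - 0.5) * (1 + (s - 1) * 0.5) / (1 + (s - 2) * 0.5),
              numeric(1))
  expect_true(all(diff(D) < 0))
  expect_equal(round(D[1], 2), 0.75)
  expect_equal(round(D[5], 2), 0.58)
  expect_gt(min(D), 0.5)
})

test_that("exponential maximum formula agrees with dense grid search", {
  rec <- recruitment_model("fixed", 100, 8)
  n_s1 <- ratio_n(rec, follow_up_schedule(c(1, 2)), 3.2, 2, 1)
  expect_equal(round(v_exp_max(0.5, 1, 2, n_s1), 2), 0.89)
  expect_equal(v_exp_max(0, 1, 2, 0.3), 1)
  # s = 4: dense grid over the two intermediate times
  g <- 0.5; tt <- 3.2
  grid <- seq(1.001, 1.999, length.out = 60)
  vals <- c()
  for (a in grid) for (b in grid) if (b > a + 1e-6) {
    sched <- follow_up_schedule(c(1, a, b, 2))
    vals <- c(vals, as.numeric(v_factor(design_point(tt, sched, rec,
                                                     correlation_model("exponential", g), sigma_s = 1))))
  }
  expect_equal(max(vals), v_exp_max(g, 1, 2, ratio_n(rec, follow_up_schedule(c(1, 2)), tt, 2, 1)),
               tolerance = 2e-3)
})

test_that("exponential minimum optimizer agrees with dense grid search", {
  # s = 3, fixed model, early interim: printed 0.80
  recF <- recruitment_model("fixed", 100, 8)
  tF <- time_at_tau0(recF, follow_up_schedule(c(1, 2)), 0.15)
  mF <- v_exp_min(0.5, 3, 1, 2, tF, recF)
  expect_equal(round(mF$min, 2), 0.80)
  grid <- seq(1.0005, 1.9995, length.out = 2000)
  gridV <- vapply(grid, function(a)
    as.numeric(v_factor(design_point(tF, follow_up_schedule(c(1, a, 2)), recF,
                                     correlation_model("exponential", 0.5), sigma_s = 1))),
    numeric(1))
  expect_equal(mF$min, min(gridV), tolerance = 1e-4)
  # s = 4, decreasing model, early interim: printed 0.69
  recD <- recruitment_model("decreasing", 100, 8)
  tD <- time_at_tau0(recD, follow_up_schedule(c(1, 2)), 0.15)
  mD <- v_exp_min(0.5, 4, 1, 2, tD, recD)
  expect_equal(round(mD$min, 2), 0.69)
  g2 <- seq(1.002, 1.998, length.out = 150)
  best <- Inf
  for (a in g2) for (b in g2) if (b > a + 1e-6) {
    v <- as.numeric(v_factor(design_point(tD, follow_up_schedule(c(1, a, b, 2)), recD,
                                          correlation_model("exponential", 0.5), sigma_s = 1)))
    if (v < best) best <- v
  }
  expect_equal(mD$min, best, tolerance = 1e-4)
  # the minimum never exceeds the equal-spacing value
  veq <- as.numeric(v_factor(design_point(tD, follow_up_schedule(c(1, 4/3, 5/3, 2)), recD,
                                          correlation_model("exponential", 0.5), sigma_s = 1)))
  expect_lte(mD$min, veq + 1e-12)
})

test_that("analytic gradients of the exponential V match finite differences", {
  set.seed(33)
  for (model in c("fixed", "increasing", "decreasing")) {
    rec <- recruitment_model(model, 100, 8)
    for (rep in 1:5) {
      s <- sample(3:6, 1)
      x <- sort(stats::runif(s - 2, 1.05, 1.95))
      g <- stats::runif(1, 0.05, 0.95)
      tt <- stats::runif(1, 2.2, 7)
      obj <- earlygsd:::v_exp_objective
      ana <- obj(x, g, 1, 2, tt, rec)$gradient
      h <- 1e-6
      num <- vapply(seq_along(x), function(j) {
        xp <- x; xm <- x
        xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
        (obj(xp, g, 1, 2, tt, rec)$value - obj(xm, g, 1, 2, tt, rec)$value) / (2 * h)
      }, numeric(1))
      expect_equal(ana, num, tolerance = 1e-5)
    }
  }
})

test_that("information fractions split into tau0 and the early-outcome gain", {
  u <- correlation_model("uniform", 0.5)
  f <- information_fraction(design_point(6, sr_sched(), sr_rec(), u, sigma_s = 12))
  expect_equal(f$tau0, 0.25)
  expect_equal(round(f$tau, 3), 0.309)
  expect_equal(f$info, 1 / f$var_beta)
  expect_equal(f$tau, f$tau0 / f$V)
  # zero correlation: tau = tau0
  f0 <- information_fraction(design_point(6, sr_sched(), sr_rec(),
                                          correlation_model("uniform", 0), sigma_s = 12))
  expect_equal(f0$tau, f0$tau0)
  # decreasing model interim
  recD <- sr_rec("decreasing")
  fD <- information_fraction(design_point(time_at_tau0(recD, sr_sched(), 0.25),
                                          sr_sched(), recD, u, sigma_s = 12))
  expect_equal(round(fD$tau, 3), 0.318)
})
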