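# Printed 2-dp reference grids for the V-factor tables at alpha = gamma = 0.5
# and the cell-sweep comparator shared by the planning and acceptance tests.
table1_ref <- list(
  fixed = list(
    D = c(0.75, 0.67, 0.62, 0.60, 0.58),
    early = rbind(c(0.55, NA, 0.89, 0.89), c(0.55, 0.86, 0.85, 0.89),
                  c(0.55, 0.85, 0.83, 0.89), c(0.55, 0.84, 0.82, 0.89),
                  c(0.55, 0.83, 0.81, 0.89)),
    mid   = rbind(c(0.71, NA, 0.93, 0.93), c(0.71, 0.91, 0.90, 0.93),
                  c(0.71, 0.90, 0.89, 0.93), c(0.71, 0.90, 0.88, 0.93),
                  c(0.71, 0.89, 0.88, 0.93)),
    late  = rbind(c(0.78, NA, 0.95, 0.95), c(0.78, 0.94, 0.93, 0.95),
                  c(0.78, 0.93, 0.92, 0.95), c(0.78, 0.92, 0.91, 0.95),
                  c(0.78, 0.92, 0.91, 0.95))),
  increasing = list(
    D = c(0.75, 0.67, 0.62, 0.60, 0.58),
    early = rbind(c(0.59, NA, 0.90, 0.90), c(0.59, 0.88, 0.86, 0.90),
                  c(0.59, 0.86, 0.84, 0.90), c(0.59, 0.85, 0.83, 0.90),
                  c(0.59, 0.85, 0.83, 0.90)),
    mid   = rbind(c(0.68, NA, 0.92, 0.92), c(0.68, 0.90, 0.89, 0.92),
                  c(0.68, 0.89, 0.88, 0.92), c(0.68, 0.89, 0.87, 0.92),
                  c(0.68, 0.88, 0.87, 0.92)),
    late  = rbind(c(0.72, NA, 0.93, 0.93), c(0.72, 0.92, 0.91, 0.93),
                  c(0.72, 0.91, 0.90, 0.93), c(0.72, 0.90, 0.89, 0.93),
                  c(0.72, 0.90, 0.88, 0.93))),
  decreasing = list(
    D = c(0.75, 0.67, 0.62, 0.60, 0.58),
    early = rbind(c(0.42, NA, 0.86, 0.86), c(0.42, 0.82, 0.81, 0.86),
                  c(0.42, 0.80, 0.78, 0.86), c(0.42, 0.79, 0.77, 0.86),
                  c(0.42, 0.78, 0.76, 0.86)),
    mid   = rbind(c(0.62, NA, 0.91, 0.91), c(0.62, 0.88, 0.87, 0.91),
                  c(0.62, 0.87, 0.86, 0.91), c(0.62, 0.86, 0.85, 0.91),
                  c(0.62, 0.86, 0.84, 0.91)),
    late  = rbind(c(0.74, NA, 0.93, 0.93), c(0.74, 0.92, 0.91, 0.93),
                  c(0.74, 0.91, 0.90, 0.93), c(0.74, 0.91, 0.89, 0.93),
                  c(0.74, 0.90, 0.89, 0.93))))

table2_ref <- list(
  fixed = list(
    early = rbind(c(0.55, NA, 0.89, 0.89), c(0.55, 0.81, 0.80, 0.89),
                  c(0.55, 0.78, 0.78, 0.89), c(0.55, 0.77, 0.76, 0.89),
                  c(0.55, 0.76, 0.75, 0.89)),
    mid   = rbind(c(0.71, NA, 0.93, 0.93), c(0.71, 0.88, 0.88, 0.93),
                  c(0.71, 0.87, 0.86, 0.93), c(0.71, 0.86, 0.85, 0.93),
                  c(0.71, 0.85, 0.85, 0.93)),
    late  = rbind(c(0.78, NA, 0.95, 0.95), c(0.78, 0.92, 0.91, 0.95),
                  c(0.78, 0.90, 0.90, 0.95), c(0.78, 0.90, 0.90, 0.95),
                  c(0.78, 0.89, 0.89, 0.95))),
  increasing = list(
    early = rbind(c(0.59, NA, 0.90, 0.90), c(0.59, 0.83, 0.83, 0.90),
                  c(0.59, 0.81, 0.80, 0.90), c(0.59, 0.80, 0.79, 0.90),
                  c(0.59, 0.79, 0.79, 0.90)),
    mid   = rbind(c(0.68, NA, 0.92, 0.92), c(0.68, 0.87, 0.87, 0.92),
                  c(0.68, 0.85, 0.85, 0.92), c(0.68, 0.84, 0.84, 0.92),
                  c(0.68, 0.84, 0.84, 0.92)),
    late  = rbind(c(0.72, NA, 0.93, 0.93), c(0.72, 0.89, 0.89, 0.93),
                  c(0.72, 0.88, 0.87, 0.93), c(0.72, 0.87, 0.87, 0.93),
                  c(0.72, 0.86, 0.86, 0.93))),
  decreasing = list(
    early = rbind(c(0.42, NA, 0.86, 0.86), c(0.42, 0.75, 0.73, 0.86),
                  c(0.42, 0.71, 0.69, 0.86), c(0.42, 0.69, 0.68, 0.86),
                  c(0.42, 0.67, 0.67, 0.86)),
    mid   = rbind(c(0.62, NA, 0.91, 0.91), c(0.62, 0.84, 0.84, 0.91),
                  c(0.62, 0.82, 0.82, 0.91), c(0.62, 0.81, 0.80, 0.91),
                  c(0.62, 0.80, 0.80, 0.91)),
    late  = rbind(c(0.74, NA, 0.93, 0.93), c(0.74, 0.89, 0.89, 0.93),
                  c(0.74, 0.88, 0.88, 0.93), c(0.74, 0.87, 0.87, 0.93),
                  c(0.74, 0.87, 0.86, 0.93))))

check_table <- function(tab, ref, has_D) {
  tol <- 0.0151  # 2-dp printing plus rounding-rule slack
  for (model in names(ref)) {
    for (timing in c("early", "mid", "late")) {
      for (j in seq_along(2:6)) {
        s <- (2:6)[j]
        row <- tab[tab$model == model & tab$timing == timing & tab$s == s, ]
        expect_equal(nrow(row), 1L)
        cells <- ref[[model]][[timing]][j, ]
        expect_equal(row$n_s1, cells[1], tolerance = tol)
        if (s > 2) expect_equal(row$V_equal, cells[2], tolerance = tol)
        expect_equal(row$V_min, cells[3], tolerance = tol)
        expect_equal(row$V_max, cells[4], tolerance = tol)
        if (has_D)
          expect_equal(row$D, ref[[model]]$D[j], tolerance = tol)
      }
    }
  }
}

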