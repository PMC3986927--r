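test_that("%RSI follows the stress/control ratio with an eps guard", {
  expect_equal(percent_rsi(60, 60)$percent_rsi, 100)
  expect_equal(percent_rsi(30, 60)$percent_rsi, 50)
  g <- percent_rsi(30, 0.5, eps = 1)
  expect_true(g$low_control)
  expect_equal(g$percent_rsi, 0)
  expect_error(percent_rsi(-1, 60), "non-negative")
  # scale invariance (controls kept above the eps guard at every scale)
  set.seed(5)
  for (c in c(0.1, 1, 10)) {
    s <- runif(20, 15, 70); k <- runif(20, 15, 70)
    expect_equal(percent_rsi(c * s, c * k)$percent_rsi,
                 percent_rsi(s, k)$percent_rsi, tolerance = 1e-12)
  }
})

make_sat_curve <- function(strain, cond, value, run_hours = 96) {
  t <- seq(0, run_hours, by = 0.25)
  # strictly rising towards the plateau, already baseline-anchored at 0
  pm_series(strain, cond, "mean", t, value * (1 - exp(-t / 5)))
}

test_that("score_study scores every strain x stress pair at its endpoint", {
  conds <- as_pm_conditions(data.frame(
    condition_id = c("ctrl30", "sorb10", "heat40"),
    stressor = c("glucose", "sorbitol", "temperature"),
    dose = c(6, 10, 0), unit = c("%w/v", "%w/v", ""),
    temperature_C = c(30, 30, 40), endpoint_hours = c(50, 50, 24),
    control_id = c("", "ctrl30", "ctrl30"), stringsAsFactors = FALSE))
  curves <- list(
    make_sat_curve("A", "ctrl30", 60), make_sat_curve("A", "sorb10", 30),
    make_sat_curve("A", "heat40", 20, run_hours = 24),
    make_sat_curve("B", "ctrl30", 50), make_sat_curve("B", "sorb10", 40))
  sc <- score_study(curves, conds)
  expect_equal(nrow(sc), 3L)   # A x sorb10, A x heat40, B x sorb10
  a_sorb <- sc[sc$strain_id == "A" & sc$condition_id == "sorb10", ]
  expect_equal(a_sorb$percent_rsi, 50, tolerance = 1e-9)
  # the 40 C condition is read at 24 h on BOTH curves
  a_heat <- sc[sc$strain_id == "A" & sc$condition_id == "heat40", ]
  mu <- function(v, t) v * (1 - exp(-t / 5))
  expect_equal(a_heat$percent_rsi, 100 * mu(20, 24) / mu(60, 24),
               tolerance = 1e-9)
  # B lacks a heat40 curve: skipped and recorded, not dropped silently
  expect_equal(attr(sc, "skipped")$strain_id, "B")
  # a stress condition with no control curve at all is an error
  expect_error(score_study(list(make_sat_curve("A", "sorb10", 30)), conds),
               "no control curve")
})

test_that("noiseless synthetic %RSI equals the closed-form logistic ratio", {
  spec <- synthetic_spec(n_strains = 5, replicates = 1, noise_sd = 0,
                         n_tolerant = 2, n_sensitive = 1, seed = 99)
  res <- suppressMessages(run_pipeline(pm_config(synthetic = spec,
                                                 outdir = tempfile())))
  conds <- spec$conditions
  for (i in seq_len(nrow(res$scores))) {
    row <- res$scores[i, ]
    th <- res$truth$theta[res$truth$strain_id == row$strain_id &
                          res$truth$condition_id == row$condition_id]
    t_end <- conds$endpoint_hours[conds$condition_id == row$condition_id]
    # analytic ratio of baseline-subtracted logistic endpoints (the
    # amplitude cancels between stress and control; A = 1 w.l.o.g.)
    num <- logistic_mu(t_end, 1, spec$rate, spec$midpoint_h, theta = th) -
           logistic_mu(0, 1, spec$rate, spec$midpoint_h, theta = th)
    den <- logistic_mu(t_end, 1, spec$rate, spec$midpoint_h) -
           logistic_mu(0, 1, spec$rate, spec$midpoint_h)
    expect_equal(row$percent_rsi, 100 * num / den, tolerance = 1e-9)
  }
})

test_that("ranking is descending with deterministic tie-breaks", {
  sc <- data.frame(strain_id = c("A", "B", "C"),
                   condition_id = "eth10",
                   rsi_stress = c(48, 72, 48), rsi_control = 60,
                   percent_rsi = c(80, 120, 80),
                   low_control = FALSE)
  class(sc) <- c("pm_scores", "data.frame")
  expect_equal(rank_strains(sc)$strain_id, c("B", "A", "C"))
  tie <- sc; tie$percent_rsi <- 90
  expect_equal(rank_strains(tie)$strain_id, c("A", "B", "C"))
  # low-control strains go last regardless of their (zeroed) score
  lc <- sc; lc$low_control <- c(TRUE, FALSE, FALSE)
  expect_equal(rank_strains(lc)$strain_id, c("B", "C", "A"))
  mixed <- sc; mixed$condition_id <- c("eth10", "eth10", "sorb10")
  expect_error(rank_strains(mixed), "single condition")
})

test_that("rank order is invariant under monotone transforms of %RSI and
           permutes the input strains", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    sc <- data.frame(strain_id = sprintf("S%02d", sample(n)),
                     condition_id = "x", rsi_stress = 1, rsi_control = 1,
                     percent_rsi = runif(n, 0, 150), low_control = FALSE)
    class(sc) <- c("pm_scores", "data.frame")
    rk <- rank_strains(sc)
    expect_setequal(rk$strain_id, sc$strain_id)
    tr <- sc; tr$percent_rsi <- exp(tr$percent_rsi / 40)  # monotone map
    expect_equal(rank_strains(tr)$strain_id, rk$strain_id)
  }
})

test_that("extreme classification mirrors the summary-table layout", {
  mk_rank <- function(n) {
    sc <- data.frame(strain_id = sprintf("S%02d", 1:n), condition_id = "x",
                     rsi_stress = 1, rsi_control = 1,
                     percent_rsi = seq(150, 10, length.out = n),
                     low_control = FALSE)
    class(sc) <- c("pm_scores", "data.frame")
    rank_strains(sc)
  }
  cls <- classify_extremes(mk_rank(20))$class
  expect_equal(as.vector(table(factor(cls,
    c("tolerant", "intermediate", "sensitive")))), c(10, 5, 5))
  expect_equal(cls[1:10], rep("tolerant", 10))
  expect_equal(cls[16:20], rep("sensitive", 5))
  expect_equal(unique(classify_extremes(mk_rank(6), 0, 0)$class),
               "intermediate")
  expect_equal(classify_extremes(mk_rank(3), 1, 1)$class,
               c("tolerant", "intermediate", "sensitive"))
  expect_error(classify_extremes(mk_rank(10), 6, 6), "exceed")
})

test_that("log-ratio matrix is referenced, clipped and flagged", {
  sc <- data.frame(
    strain_id = rep(c("S288C", "A", "B", "C"), each = 2),
    condition_id = rep(c("c1", "c2"), 4),
    rsi_stress = 1, rsi_control = 1,
    percent_rsi = c(50, 40, 50, 320, 400, 40, 0, 40),
    low_control = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  class(sc) <- c("pm_scores", "data.frame")
  lr <- log_ratio_matrix(sc)
  expect_equal(unname(lr["S288C", ]), c(0, 0))
  expect_equal(lr["A", "c1"], 0)                    # same %RSI as reference
  expect_equal(lr["A", "c2"], 3)                    # 8x ratio: at the clip
  expect_equal(lr["B", "c1"], 3)                    # 16x ratio: clipped
  expect_true(is.na(lr["C", "c1"]))                 # low-control cell
  expect_true(all(abs(lr[!is.na(lr)]) <= 3))
  expect_error(log_ratio_matrix(sc, reference_id = "Z"), "reference")
})

test_that("condition correlations match the textbook Pearson formula", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 1, 3))
  expect_equal(condition_correlation(m, "a", "b"), 0.5)
  m2 <- cbind(a = c(1, 5, 9, 2), b = 2 * c(1, 5, 9, 2) + 5,
              c = -c(1, 5, 9, 2))
  expect_equal(condition_correlation(m2, "a", "a"), 1)
  expect_equal(condition_correlation(m2, "a", "b"), 1)
  expect_equal(condition_correlation(m2, "a", "c"), -1)
  set.seed(77)
  for (i in 1:25) {
    m3 <- cbind(x = rnorm(10), y = rnorm(10))
    expect_equal(condition_correlation(m3, "x", "y"),
                 brute_pearson(m3[, "x"], m3[, "y"]), tolerance = 1e-12)
  }
  flat <- cbind(x = rep(1, 5), y = rnorm(5))
  expect_warning(r <- condition_correlation(flat, "x", "y"), "undefined")
  expect_true(is.na(r))
  expect_error(condition_correlation(cbind(x = 1:2, y = 2:1), "x", "y"),
               "at least 3")
})
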