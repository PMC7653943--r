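test_that("single-mode model evaluates the (n-1)/n capture law", {
  expect_equal(single_gate_motion(20, 2), 10)
  expect_equal(single_gate_motion(12.5, 1), 0)
  expect_equal(single_gate_motion(14.1, 5), 11.28)
  expect_error(single_gate_motion(10, 0), class = "gateopt_invalid_gate_count")
})

test_that("dual model sums independent respiratory and cardiac captures", {
  expect_equal(dual_gate_motion(10, 0, r = 3, p = 1), 10 * 2 / 3)
  expect_equal(dual_gate_motion(14.1, 3.8, r = 1, p = 1), 0)
  expect_equal(dual_gate_motion(14.1, 3.8, r = 5, p = 4), 14.1 * 0.8 + 3.8 * 0.75)
  expect_error(dual_gate_motion(1, 1, r = 0, p = 2),
               class = "gateopt_invalid_gate_count")
})

test_that("Dawood model evaluates a + b exp(c/r), nonzero at r = 1", {
  expect_equal(dawood_motion(5, -5, 0, r = 3), 0)
  expect_equal(dawood_motion(0, 1, 1, r = 1), exp(1))
  expect_lt(abs(dawood_motion(10, -10, -1, r = 10000)), 1e-3)
})

test_that("both models vanish at one gate and rise monotonically to m_est", {
  for (c in c(0.5, 7.3, 14.1, 20)) {
    f <- single_gate_motion(c, 1:50)
    expect_equal(f[1], 0)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f <= c))
    expect_lt(c - single_gate_motion(c, 10000), c * 2e-4)
  }
  g <- outer(1:20, 1:20, function(r, p) dual_gate_motion(14.1, 3.8, r, p))
  expect_equal(g[1, 1], 0)
  expect_true(all(apply(g, 1, diff) >= 0))
  expect_true(all(apply(g, 2, diff) >= 0))
  expect_true(all(g <= 14.1 + 3.8))
})

test_that("single-model fit is exact on model data and matches the grid oracle", {
  expect_equal(fit_single_model(data.frame(n = 2:4, motion_mm = c(6, 8, 9)))$coef[["c"]], 12)
  expect_equal(fit_single_model(data.frame(n = 2, motion_mm = 5))$coef[["c"]], 10)

  withr::with_seed(42, {
    n <- sample(2:10, 20, replace = TRUE)
    y <- single_gate_motion(14.1, n) + rnorm(20, sd = 0.3)
  })
  fit <- fit_single_model(data.frame(n = n, motion_mm = y))
  expect_lt(abs(fit$coef[["c"]] - 14.1), 0.3)
  expect_lt(abs(fit$coef[["c"]] - oracle_grid_c(n, y)), 1e-6)
  expect_equal(fit$m_est, fit$coef[["c"]])

  expect_error(fit_single_model(data.frame(n = c(1, 1), motion_mm = c(0, 0))),
               class = "gateopt_unidentifiable")
})

test_that("dual-model fit interpolates exact data and matches the 2-D oracle", {
  d <- expand.grid(n_resp = 1:5, n_card = c(1, 4, 6))
  d$motion_mm <- dual_gate_motion(12, 10, d$n_resp, d$n_card)
  fit <- fit_dual_model(d)
  expect_equal(unname(fit$coef), c(12, 10), tolerance = 1e-10)
  expect_equal(fit$m_est, 22, tolerance = 1e-10)

  all_p1 <- data.frame(n_resp = 1:4, n_card = 1, motion_mm = c(0, 5, 6, 7))
  expect_error(fit_dual_model(all_p1), class = "gateopt_unidentifiable")

  withr::with_seed(7, {
    d2 <- expand.grid(n_resp = 1:6, n_card = c(1, 4, 6, 8, 10))[sample(30, 30), ]
    d2$motion_mm <- dual_gate_motion(14.1, 3.8, d2$n_resp, d2$n_card) +
      rnorm(30, sd = 0.3)
  })
  fit2 <- fit_dual_model(d2)
  expect_lt(abs(fit2$coef[["a"]] - 14.1), 0.5)
  expect_lt(abs(fit2$coef[["b"]] - 3.8), 0.5)
  oracle <- oracle_grid_ab(d2$n_resp, d2$n_card, d2$motion_mm)
  expect_lt(max(abs(unname(fit2$coef) - oracle)), 1e-6)
})

test_that("Dawood fit recovers exact parameters and rejects underdetermined data", {
  n <- c(1:8, 10, 12)
  y <- dawood_motion(15, -15, -2, n)
  fit <- fit_dawood_model(data.frame(n = n, motion_mm = y))
  expect_equal(unname(fit$coef), c(15, -15, -2), tolerance = 1e-4)
  expect_equal(fit$m_est, 0, tolerance = 1e-4)
  expect_error(fit_dawood_model(data.frame(n = c(2, 3), motion_mm = c(1, 2))),
               class = "gateopt_unidentifiable")
})

test_that("negative fitted amplitudes are clamped to zero with a warning", {
  d <- data.frame(n = c(2, 3), motion_mm = c(-4, -5))
  expect_warning(fit <- fit_single_model(d), "clamped")
  expect_equal(fit$coef[["c"]], 0)
})

test_that("optimal gate counts equal the brute-force half-resolution scan", {
  sc <- scanner_spec()
  fit_for <- function(c) {
    fit_single_model(data.frame(n = 2:6, motion_mm = single_gate_motion(c, 2:6)))
  }
  expect_equal(optimal_gates(fit_for(14.1), sc), 6)
  expect_equal(optimal_gates(fit_for(2.5), sc), 1)
  expect_equal(optimal_gates(fit_for(10), sc), 4)
  for (c in seq(2.7, 50, by = 0.1)) {
    expect_equal(optimal_gates(fit_for(c), sc), oracle_smallest_n(c, 5.2))
  }
})

test_that("dual optimum applies the half-resolution rule componentwise", {
  sc <- scanner_spec()
  fit_for <- function(a, b) {
    d <- expand.grid(n_resp = 1:6, n_card = c(1, 4, 6))
    d$motion_mm <- dual_gate_motion(a, b, d$n_resp, d$n_card)
    fit_dual_model(d)
  }
  s1 <- optimal_gates(fit_for(14.1, 3.8), sc)
  expect_equal(c(s1$n_resp, s1$n_card), c(6, 2))
  suppressWarnings(s2 <- optimal_gates(fit_for(2.5, 5.5), sc))
  expect_equal(c(s2$n_resp, s2$n_card), c(1, 3))
  suppressWarnings(s3 <- optimal_gates(fit_for(0, 0), sc))
  expect_equal(c(s3$n_resp, s3$n_card), c(1, 1))
})

test_that("motion-minimisation threshold subtracts half resolution per component", {
  expect_equal(threshold_from_motion(14.1, 3.8), 12.7)
  expect_equal(threshold_from_motion(2.6, 2.6), 0)
  expect_equal(threshold_from_motion(12, 10), 16.8)
})

test_that("published linear models reproduce the worked gate-count examples", {
  expect_identical(eval_gate_count_line(gate_count_models$dual, 22, "up"), 20L)
  expect_identical(eval_gate_count_line(gate_count_models$respiratory, 12, "nearest"), 5L)
  expect_equal(eval_gate_count_line(gate_count_models$cardiac, 0, "none"), 0.718)
  expect_error(eval_gate_count_line(gate_count_models$dual, 5, "up"),
               class = "gateopt_domain_error")
  sch <- resolve_gate_combination(20, 5)
  expect_equal(c(sch$n_resp, sch$n_card), c(5, 4))
})

test_that("resolve_gate_combination takes the ceiling quotient", {
  expect_equal(resolve_gate_combination(7, 7)$n_card, 1)
  expect_equal(resolve_gate_combination(10, 3)$n_card, 4)
  expect_error(resolve_gate_combination(5, 6),
               class = "gateopt_invalid_combination")
})

test_that("gate-count line fitting recovers known lines with R^2", {
  m <- c(2, 5, 9, 14, 20)
  exact <- fit_gate_count_line(data.frame(motion_mm = m,
                                          n_gates = 0.35 * m + 1.005))
  expect_equal(exact$slope, 0.35, tolerance = 1e-10)
  expect_equal(exact$intercept, 1.005, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1, tolerance = 1e-10)

  two <- fit_gate_count_line(data.frame(motion_mm = c(0, 10), n_gates = c(1, 5)))
  expect_equal(two$slope, 0.4)
  expect_equal(two$intercept, 1)

  expect_error(fit_gate_count_line(data.frame(motion_mm = c(3, 3),
                                              n_gates = c(1, 2))),
               class = "gateopt_degenerate_fit")
})

test_that("MD and RMSE match hand arithmetic and satisfy RMSE >= MD", {
  expect_equal(md(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(md(c(0, 0), c(1, 3)), 2)
  expect_equal(rmse(c(0, 0), c(1, 3)), sqrt(5))
  withr::with_seed(99, {
    for (i in 1:20) {
      x <- rnorm(sample(2:40, 1))
      y <- rnorm(length(x), sd = runif(1, 0.1, 3))
      expect_gte(rmse(x, y), md(x, y))
    }
  })
  expect_error(md(1:3, 1:4), class = "gateopt_input_error")
  expect_error(rmse(numeric(0), numeric(0)), class = "gateopt_input_error")
})

test_that("tidy and glance expose fit parameters and agreement metrics", {
  fit <- fit_single_model(data.frame(n = 2:4, motion_mm = c(6, 8, 9)))
  td <- tidy(fit)
  expect_equal(td$term, "c")
  expect_equal(td$estimate, 12)
  gl <- glance(fit)
  expect_equal(gl$m_est, 12)
  expect_equal(gl$rmse, 0)
  expect_gte(gl$rmse, gl$md)
})
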