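test_that("joint moments: unit variance and zero pre-test covariance at omega*", {
  d <- ft_design()
  p <- stage_plan(d)
  mom <- joint_moments(scenario_means(0.275, 0, 0), p, margin = 0.22)
  expect_equal(mom$var_s1, 1, tolerance = 1e-12)
  expect_equal(mom$cov_ept_s1, 0, tolerance = 1e-12)
  expect_lte(abs(mom$cov_ept_s2), 1 / sqrt(2) + 1e-12)
  # a non-optimal weight inflates the stage-1 variance and decorrelation fails
  mom2 <- joint_moments(scenario_means(0.275, 0, 0), p, margin = 0.22, weight = 0.5)
  expect_gt(mom2$var_s1, 1)
  expect_true(abs(mom2$cov_ept_s1) > 0)
})

test_that("pre-test/stage-2 covariance attains its structural limits", {
  d <- fiu_design(0.3, n_h = 500, margin = 0.2)
  cov_of <- function(n_c, n_c2, n_h) {
    dd <- fiu_design(0.3, n_h = n_h, margin = 0.2)
    p <- make_plan(n_c, n_c, n_c2, n_c2, dd)
    joint_moments(scenario_means(0, 0, 0), p, margin = 0.2)$cov_ept_s2
  }
  # equal stage allocation, huge historical pool: |cov| -> 1/2
  expect_equal(abs(cov_of(100, 100, 10^7)), 0.5, tolerance = 1e-3)
  # vanishing stage 2: |cov| -> 1/sqrt(2); huge stage 2: |cov| -> 0
  expect_equal(abs(cov_of(100, 1, 10^7)), 1 / sqrt(2), tolerance = 0.01)
  expect_lt(abs(cov_of(100, 10^5, 10^7)), 0.05)
  # formula against the empirical covariance of a simulation
  p <- stage_plan(d)
  set.seed(3)
  R <- 100000
  m_c <- rnorm(R, 0, 1 / sqrt(p$n_c)); m_h <- rnorm(R, 0.1, 1 / sqrt(500))
  m_c2 <- rnorm(R, 0, 1 / sqrt(p$n_c2)); m_e <- rnorm(R, 0, 1 / sqrt(p$cap_n_e))
  full_c <- (p$n_c * m_c + p$n_c2 * m_c2) / p$cap_n_c
  z_d <- (m_c - m_h) / sqrt(1 / p$n_c + 1 / 500)
  z2 <- (m_e - full_c) / sqrt(1 / p$cap_n_e + 1 / p$cap_n_c)
  emp <- cov(z_d, z2)
  mom <- joint_moments(scenario_means(0, 0, 0.1), p, margin = 0.2)
  expect_equal(emp, mom$cov_ept_s2, tolerance = 0.02)
})

test_that("empirical correlations of the statistics match the theory", {
  d <- ft_design(alpha_ept = 0.2, margin = 0.15)
  p <- stage_plan(d)
  set.seed(11)
  R <- 50000
  # control separation far from the fold so that |ybar_C - ybar_H| is linear
  m_e <- rnorm(R, 0, 1 / sqrt(p$n_e)); m_c <- rnorm(R, 0, 1 / sqrt(p$n_c))
  m_h <- rnorm(R, -0.6, 1 / sqrt(500))
  w <- optimal_weight(500, p$n_c)
  z_ept_v <- (abs(m_c - m_h) - 0.15) / sqrt(1 / p$n_c + 1 / 500)
  z1 <- (m_e - (w * m_h + (1 - w) * m_c)) / sqrt(1 / p$n_e + 1 / (500 + p$n_c))
  m_e2 <- rnorm(R, 0, 1 / sqrt(p$n_e2)); m_c2 <- rnorm(R, 0, 1 / sqrt(p$n_c2))
  z2 <- ((p$n_e * m_e + p$n_e2 * m_e2) / p$cap_n_e -
           (p$n_c * m_c + p$n_c2 * m_c2) / p$cap_n_c) /
    sqrt(1 / p$cap_n_e + 1 / p$cap_n_c)
  se_cor <- 1 / sqrt(R)
  expect_lt(abs(cor(z_ept_v, z1)), 3 * se_cor)
  mom <- joint_moments(scenario_means(0, 0, -0.6), p, margin = 0.15)
  expect_lt(abs(abs(cor(z_ept_v, z2)) - abs(mom$cov_ept_s2)), 3 * se_cor)
})

test_that("error rate and power components are additive for every method", {
  d <- ft_design(alpha_ept = 0.2, margin = 0.15)
  p <- stage_plan(d)
  sc <- scenario_means(-0.1, 0, -0.15)
  for (m in c("normal-approx", "exact-folded", "monte-carlo")) {
    e <- fwer(sc, p, method = m, replicates = 5000, seed = 5)
    expect_equal(e$value, e$component_a + e$component_b, tolerance = 1e-12)
    pw <- overall_power(scenario_means(0.275, 0, 0), p, method = m,
                        replicates = 5000, seed = 5)
    expect_equal(pw$value, 1 - (pw$component_a + pw$component_b),
                 tolerance = 1e-12)
  }
})

test_that("a margin below the never-reject bound collapses to the stage-2 branch", {
  d <- ft_design(alpha_ept = 0.05, margin = 0.05)  # far below the bound
  p <- stage_plan(d)
  e <- fwer(scenario_means(0, 0, 0.05), p, method = "exact-folded")
  expect_identical(e$component_a, 0)
  expect_equal(e$value, 0.05, tolerance = 1e-8)    # marginal level of S2
  # overall power then equals the marginal power of the stage-2 z-test
  pw <- overall_power(scenario_means(0.275, 0, 0), p, method = "exact-folded")
  se2 <- sqrt(1 / p$cap_n_e + 1 / p$cap_n_c)
  expect_equal(pw$value, pnorm(qnorm(0.95) - 0.275 / se2, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("linearized approximation converges to the exact rate away from the fold", {
  d <- ft_design(alpha_ept = 0.2, margin = 0.15)
  p <- stage_plan(d)
  se_d <- sqrt(1 / p$n_c + 1 / 500)
  # |mu_C - mu_H| at 5+ pre-test standard errors: folding is negligible
  for (sep in c(0.6, -0.6)) {
    sc <- scenario_means(0, 0, sep)
    ex <- fwer(sc, p, method = "exact-folded")
    ap <- fwer(sc, p, method = "normal-approx")
    expect_lt(abs(ex$value - ap$value), 1e-4)
  }
  # at the boundary they differ substantially (the documented discrepancy)
  sc0 <- scenario_means(-optimal_weight(500, p$n_c) * 0.15, 0, -0.15)
  ex0 <- fwer(sc0, p, method = "exact-folded")$value
  expect_gt(fwer(sc0, p, method = "normal-approx")$value, 1.5 * ex0)
  expect_gt(fwer(sc0, p, method = "normal-approx", cov_sign = "positive")$value,
            2 * ex0)
})

test_that("Monte-Carlo and exact integration agree across a scenario panel", {
  d <- ft_design(alpha_ept = 0.2, margin = 0.15)
  p <- stage_plan(d)
  panel <- list(scenario_means(0, 0, 0.45), scenario_means(0, 0, -0.15),
                scenario_means(-0.1, 0, -0.3), scenario_means(0.275, 0, 0))
  for (sc in panel) {
    ex <- fwer(sc, p, method = "exact-folded")
    mc <- fwer(sc, p, method = "monte-carlo", replicates = 100000, seed = 2)
    tol <- 3 * sqrt(max(ex$value * (1 - ex$value), 1e-6) / 100000)
    expect_lt(abs(mc$value - ex$value), tol)
  }
})

test_that("the error-rate surface dips at the margin and respects the level", {
  d <- fiu_design(0.5, alpha_ept = 0.2, n_h = 500, margin = 0.44)
  p <- stage_plan(d)
  grid_d <- c(seq(-2.5, -0.5, by = 0.1), -0.44)
  surf <- fwer_surface(p, d, diff_ept = grid_d, diff_s1 = c(-0.2, -0.1, 0))
  expect_true(all(surf$fwer <= 0.05 + 1e-6))
  top <- surf[surf$diff_s1 == 0, ]
  expect_equal(top$diff_ept[which.min(top$fwer)], -0.44)
  # monotone increase away from the margin along the zero-effect line
  ord <- top[order(top$diff_ept, decreasing = TRUE), "fwer"]
  expect_true(all(diff(ord) >= -1e-9))
  expect_equal(max_fwer(p, d), 0.05, tolerance = 1e-3)
  expect_error(fwer_surface(p, d, diff_ept = numeric(0)), "non-empty")
})

test_that("the supremum search finds the boundary-limit error rate", {
  d <- ft_design(alpha_ept = 0.05, margin = 0.22)
  p <- stage_plan(d)
  expect_equal(max_fwer(p, d), 0.05, tolerance = 1e-3)
  # scenario-I-type boundary configuration sits far below the cap
  sI <- scenario_preset("scenario-I", d, p, seed = 1)$scenario
  expect_lt(fwer(sI, p, method = "exact-folded")$value, 0.01)
})
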