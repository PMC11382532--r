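test_that("one-step sample sizes reproduce the standard z-test formula", {
  # per-group sizes frozen from the harmonic-mean formula with per-group ceiling
  cases <- list(list(delta = 0.5, n = 50L), list(delta = 0.275, n = 164L),
                list(delta = 0.8, n = 20L), list(delta = 0.2, n = 310L))
  for (cs in cases) {
    n <- one_step_sample_size(cs$delta, 0.05, 0.2)
    expect_identical(n, cs$n)
    # smallest such integer: n meets the information requirement, n-1 does not
    need <- (qnorm(0.95) + qnorm(0.8))^2 / cs$delta^2
    expect_gte(n / 2, need)
    expect_lt((n - 1) / 2, need)
  }
  expect_error(one_step_sample_size(-0.1), "positive")
})

test_that("balanced stage-1 fraction matches the information-matching root", {
  for (cs in list(c(164, 500), c(51, 500), c(62, 500), c(69, 500),
                  c(100, 50), c(20, 2000))) {
    expect_equal(gamma_balanced(cs[1], cs[2]), gamma_oracle(cs[1], cs[2]),
                 tolerance = 1e-9)
  }
  expect_equal(gamma_balanced(164, 500), 0.5799058, tolerance = 1e-6)
  expect_identical(ceiling(gamma_balanced(164, 500) * 164), 96)
})

test_that("stage-1 fraction is bounded, monotone in n_h, and 1 without history", {
  for (N in c(5, 51, 164, 1000)) {
    expect_equal(gamma_balanced(N, 0), 1)
    gs <- vapply(c(0, 1, 10, 100, 1000, 1e5), function(h) gamma_balanced(N, h),
                 numeric(1))
    expect_true(all(diff(gs) < 0))
    expect_true(all(gs >= 0.5 & gs <= 1))
    expect_equal(gamma_balanced(N, 1e9), 0.5, tolerance = 1e-6)
  }
})

test_that("general stage-1 fraction reduces to the balanced closed form", {
  d <- fiu_design(0.275, n_h = 500)
  expect_equal(gamma_general(d, 164, 164), gamma_balanced(164, 500),
               tolerance = 1e-12)
  expect_equal(gamma_general(d, 164, 164, n_h = 0), 1)
  # unequal levels: the returned root still solves the information equation
  d2 <- fiu_design(0.275, alpha_s1 = 0.1, alpha_s2 = 0.05, beta_s1 = 0.3,
                   beta_s2 = 0.2, n_h = 300)
  g <- gamma_general(d2, 150, 180)
  q <- ((qnorm(0.9) + qnorm(0.7)) / (qnorm(0.95) + qnorm(0.8)))^2
  lhs <- (150 + 180) / (150 * 180) *
    (g * 150 * (300 + g * 180)) / (g * (150 + 180) + 300)
  expect_equal(lhs, q, tolerance = 1e-8)
  expect_true(all(g > 0 & g <= 1))
  # a stage-1 test demanding more information than the full design carries
  d3 <- fiu_design(0.275, alpha_s1 = 0.025, alpha_s2 = 0.05, beta_s1 = 0.1,
                   beta_s2 = 0.2, n_h = 300)
  expect_error(gamma_general(d3, 150, 180), "infeasible")
})

test_that("stage plans reproduce the planning chain and never under-power", {
  cases <- list(
    list(delta = 0.275, power = 0.80, n_fiu = 328L, s1 = 192L),
    list(delta = 0.5,   power = 0.81, n_fiu = 102L, s1 = 54L),
    list(delta = 0.5,   power = 0.90, n_fiu = 138L, s1 = 74L),
    list(delta = 0.5,   power = 0.87, n_fiu = 124L, s1 = 66L),
    list(delta = 0.5,   power = 0.80, n_fiu = 100L, s1 = 54L))
  for (cs in cases) {
    d <- fiu_design(cs$delta, n_h = 500, beta_s1 = 1 - cs$power,
                    beta_s2 = 1 - cs$power)
    p <- stage_plan(d)
    expect_identical(p$n_fiu, cs$n_fiu)
    expect_identical(p$n_e + p$n_c, cs$s1)
    expect_identical(p$cap_n_e, p$n_e + p$n_e2)
    expect_identical(p$n_fiu, p$cap_n_e + p$cap_n_c)
    # planned stage-1 information covers the requested power of the pooled test
    info <- p$n_e * (500 + p$n_c) / (p$n_e + 500 + p$n_c)
    expect_gte(info, (qnorm(1 - d$alpha_s1) + qnorm(1 - d$beta_s1))^2 / d$delta^2)
    expect_true(p$gamma >= 0.5 && p$gamma <= 1)
  }
  # medium-effect plans put 52-55% of the maximum size into stage 1
  fr <- vapply(cases[-1], function(cs) {
    p <- stage_plan(fiu_design(cs$delta, n_h = 500, beta_s1 = 1 - cs$power,
                               beta_s2 = 1 - cs$power))
    (p$n_e + p$n_c) / p$n_fiu
  }, numeric(1))
  expect_true(all(fr >= 0.52 & fr <= 0.55))
})

test_that("margin bounds reproduce the admissible-margin formula", {
  cases <- list(list(n_c = 27, a = 0.01, lo = 0.4596),
                list(n_c = 33, a = 0.10, lo = 0.2303),
                list(n_c = 27, a = 0.20, lo = 0.1663))
  for (cs in cases) {
    mb <- margin_bounds(cs$n_c, 500, cs$a, 0.5)
    expect_equal(round(mb$lower, 4), cs$lo)
    expect_true(mb$feasible)
    expect_identical(mb$upper, 0.5)
  }
  # two-sided variant is wider and flags infeasibility against a small delta
  mb2 <- margin_bounds(27, 500, 0.01, 0.5, sided = "two")
  expect_gt(mb2$lower, margin_bounds(27, 500, 0.01, 0.5)$lower)
  expect_false(margin_bounds(27, 500, 0.01, 0.3)$feasible)
})

test_that("optimal weight minimizes the pooled-control variance", {
  expect_equal(optimal_weight(500, 96), 500 / 596)
  expect_equal(optimal_weight(0, 50), 0)
  for (cs in list(c(500, 96), c(500, 27), c(10, 90), c(1, 1))) {
    w <- optimal_weight(cs[1], cs[2])
    expect_equal(w, weight_oracle(cs[1], cs[2]), tolerance = 1e-4)
    expect_equal(w^2 / cs[1] + (1 - w)^2 / cs[2], 1 / sum(cs), tolerance = 1e-12)
  }
})

test_that("average sample size follows the per-group ceiling convention", {
  avn_for <- function(delta, power, a_ept) {
    stage_plan(fiu_design(delta, alpha_ept = a_ept, n_h = 500,
                          beta_s1 = 1 - power, beta_s2 = 1 - power))$avn
  }
  expect_identical(avn_for(0.5, 0.80, 0.01), 100L)
  expect_identical(avn_for(0.5, 0.90, 0.05), 136L)
  expect_identical(avn_for(0.5, 0.87, 0.10), 120L)
  expect_identical(avn_for(0.5, 0.81, 0.20), 94L)
  p <- stage_plan(fiu_design(0.275, n_h = 500))
  expect_identical(vapply(c(0.01, 0.05, 0.1, 0.2),
                          function(a) average_sample_size(p, a), integer(1)),
                   c(328L, 322L, 316L, 302L))
  # bracketing: stage-1 total <= AVN <= maximum total
  expect_true(all(p$n_e + p$n_c <= p$avn, p$avn <= p$n_fiu))
})

test_that("design constructor validates its inputs", {
  expect_error(fiu_design(0), "positive")
  expect_error(fiu_design(0.5, alpha_ept = 1.2), "between 0 and 1")
  expect_error(fiu_design(0.5, n_h = -3), "non-negative")
  expect_error(fiu_design(0.5, margin = -0.1), "positive")
  expect_s3_class(fiu_design(0.5, n_h = 500), "fiu_design")
})
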