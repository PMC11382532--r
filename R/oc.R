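# Family-wise error rate and overall power of the procedure from the joint
# distribution of (Z_Ept, Z_S1, Z_S2): exact integration over the folded
# pre-test difference, the linearized Gaussian approximation of the pre-test
# statistic, and Monte-Carlo delegation. Bivariate-normal rejection
# probabilities are computed by one-dimensional Gaussian quadrature over the
# conditioning variable (the conditional distributions are normal in closed
# form); stats::integrate with rel.tol 1e-8 keeps them well below the 1e-6
# documentation tolerance.

#' True group means of a simulation/evaluation scenario
#'
#' @param mu_e,mu_c,mu_h Expected responses of the experimental, randomized
#'   control and historical control groups (finite reals).
#' @return Object of class `fiu_scenario`.
#' @export
scenario_means <- function(mu_e, mu_c, mu_h) {
  stopifnot(is.finite(mu_e), is.finite(mu_c), is.finite(mu_h))
  structure(list(mu_e = mu_e, mu_c = mu_c, mu_h = mu_h), class = "fiu_scenario")
}

#' @export
print.fiu_scenario <- function(x, ...) {
  cat(sprintf("Scenario means: mu_E = %g, mu_C = %g, mu_H = %g\n",
              x$mu_e, x$mu_c, x$mu_h))
  invisible(x)
}

# P(X < a, Y > b) for standard-variance bivariate normal with means mu1, mu2
# and correlation rho.
.p_lower_upper <- function(a, mu1, b, mu2, rho) {
  if (abs(rho) < 1e-12)
    return(stats::pnorm(a, mu1) * stats::pnorm(b, mu2, lower.tail = FALSE))
  s <- sqrt(max(1 - rho^2, 1e-12))
  f <- function(x)
    stats::dnorm(x, mu1) *
      stats::pnorm((b - mu2 - rho * (x - mu1)) / s, lower.tail = FALSE)
  stats::integrate(f, -Inf, a, rel.tol = 1e-8, abs.tol = 1e-10)$value
}

.resolve_weight <- function(weight, n_h, n_c) {
  if (is.null(weight)) optimal_weight(n_h, n_c) else weight
}

#' Moments of the joint distribution of the three test statistics
#'
#' Means of \eqn{Z_{Ept}}, \eqn{Z_{S_1}}, \eqn{Z_{S_2}} at the scenario
#' means, the variance of the weighted stage-1 statistic for a general weight
#' (standardized by the optimal-pooling denominator, so it equals 1 at
#' \eqn{\omega^*}), and the covariances of the pre-test statistic with the two
#' superiority statistics. Covariances are reported for the fixed orientation
#' \eqn{(\bar y_C - \bar y_H,\; \cdot)}; the linearized pre-test statistic
#' flips its sign with \eqn{\mathrm{sign}(\mu_C - \mu_H)}, which the
#' integration routines handle via their `cov_sign` argument.
#'
#' @param scenario A [scenario_means()].
#' @param plan A [stage_plan()] (carries the design and `n_h`).
#' @param margin Equivalence margin \eqn{\Delta > 0}.
#' @param weight Historical-control weight; default \eqn{\omega^*}.
#' @return List with `mu_ept`, `mu_s1`, `mu_s2`, `var_s1`, `cov_ept_s1`,
#'   `cov_ept_s2` and the standard errors used.
#' @export
joint_moments <- function(scenario, plan, margin, weight = NULL) {
  stopifnot(inherits(scenario, "fiu_scenario"), inherits(plan, "fiu_plan"),
            margin > 0)
  n_h <- plan$design$n_h
  n_e <- plan$n_e; n_c <- plan$n_c
  N_e <- plan$cap_n_e; N_c <- plan$cap_n_c
  w <- .resolve_weight(weight, n_h, n_c)
  se_d <- sqrt(1 / n_c + 1 / n_h)
  se1_opt <- sqrt(1 / n_e + 1 / (n_h + n_c))
  se1_w <- sqrt(1 / n_e + (if (w > 0) w^2 / n_h else 0) +
                  (if (w < 1) (1 - w)^2 / n_c else 0))
  se2 <- sqrt(1 / N_e + 1 / N_c)
  mu_ept <- (abs(scenario$mu_c - scenario$mu_h) - margin) / se_d
  mu_s1 <- weighted_effect(scenario$mu_e, scenario$mu_c, scenario$mu_h, w) / se1_opt
  mu_s2 <- (scenario$mu_e - scenario$mu_c) / se2
  var_s1 <- (se1_w / se1_opt)^2
  # Cov(ybar_C - ybar_H, -(w ybar_H + (1-w) ybar_C)) / (se_d * se1_opt)
  cov_ept_s1 <- (w / n_h - (1 - w) / n_c) / (se_d * se1_opt)
  # Cov(ybar_C - ybar_H, ybar'_E - ybar'_C) = -Cov(ybar_C, ybar'_C) = -1/N_C
  cov_ept_s2 <- -(1 / N_c) / (se_d * se2)
  list(mu_ept = mu_ept, mu_s1 = mu_s1, mu_s2 = mu_s2,
       var_s1 = var_s1, cov_ept_s1 = cov_ept_s1, cov_ept_s2 = cov_ept_s2,
       se_d = se_d, se_s1 = se1_opt, se_s2 = se2, weight = w)
}

.fiu_oc <- function(type, comp_a, comp_b, method) {
  total <- comp_a + comp_b
  structure(list(type = type, total = total,
                 value = if (type == "fwer") total else 1 - total,
                 component_a = comp_a, component_b = comp_b, method = method),
            class = "fiu_oc")
}

#' @export
print.fiu_oc <- function(x, ...) {
  if (x$type == "fwer") {
    cat(sprintf("Family-wise error rate (%s): %.5f\n", x$method, x$value))
    cat(sprintf("  P(pool and reject S1)      : %.5f\n", x$component_a))
    cat(sprintf("  P(extend and reject S2)    : %.5f\n", x$component_b))
  } else {
    cat(sprintf("Overall power (%s): %.5f\n", x$method, x$value))
    cat(sprintf("  beta component (Ept, S1)   : %.5f\n", x$component_a))
    cat(sprintf("  beta component (Ept^c, S2) : %.5f\n", x$component_b))
  }
  invisible(x)
}

.cov_sign_rho <- function(cov_sign, mu_c, mu_h, cov_fixed) {
  switch(cov_sign,
         auto = if (mu_c >= mu_h) cov_fixed else -cov_fixed,
         positive = abs(cov_fixed),
         negative = -abs(cov_fixed),
         stop("unknown `cov_sign`: ", cov_sign, call. = FALSE))
}

# Linearized-Gaussian approximation of the pre-test: joint rejection
# probabilities of the two branches. Returns c(a = P(reject Ept & S1-event),
# b = P(not reject Ept & S2-event)); the events are "Z > crit" for error
# rates, or their complements within each branch when complement = TRUE
# (type-II components).
.branch_probs <- function(mom, design, cov_sign, scenario, complement = FALSE) {
  zc <- stats::qnorm(1 - design$alpha_ept / 2)
  c1 <- stats::qnorm(1 - design$alpha_s1)
  c2 <- stats::qnorm(1 - design$alpha_s2)
  sd1 <- sqrt(mom$var_s1)
  rho2 <- .cov_sign_rho(cov_sign, scenario$mu_c, scenario$mu_h, mom$cov_ept_s2)
  rho1 <- .cov_sign_rho(cov_sign, scenario$mu_c, scenario$mu_h, mom$cov_ept_s1) / sd1
  p_rej <- stats::pnorm(-zc, mom$mu_ept)
  if (abs(rho1) < 1e-10) {
    a_hit <- p_rej * stats::pnorm(c1 / sd1, mom$mu_s1 / sd1, lower.tail = FALSE)
  } else {
    a_hit <- .p_lower_upper(-zc, mom$mu_ept, c1 / sd1, mom$mu_s1 / sd1, rho1)
  }
  b_hit <- stats::pnorm(c2, mom$mu_s2, lower.tail = FALSE) -
    .p_lower_upper(-zc, mom$mu_ept, c2, mom$mu_s2, rho2)
  if (!complement) return(c(a = a_hit, b = b_hit))
  c(a = p_rej - a_hit, b = (1 - p_rej) - b_hit)
}

# Exact computation over the folded pre-test difference D = ybar_C - ybar_H.
# reject Ept  <=>  |D| < cthr  with cthr = margin - z_{1-a/2} * se_d.
.branch_probs_exact <- function(mom, design, margin, scenario,
                                complement = FALSE) {
  if (abs(mom$cov_ept_s1) > 1e-10)
    stop("method 'exact-folded' requires the optimal pooling weight", call. = FALSE)
  zc <- stats::qnorm(1 - design$alpha_ept / 2)
  c1 <- stats::qnorm(1 - design$alpha_s1)
  c2 <- stats::qnorm(1 - design$alpha_s2)
  p_s1_hit <- stats::pnorm(c1, mom$mu_s1, lower.tail = FALSE)
  mu_d <- scenario$mu_c - scenario$mu_h
  se_d <- mom$se_d
  cthr <- margin - zc * se_d
  if (cthr <= 0) {
    p_rej <- 0
    b_hit <- stats::pnorm(c2, mom$mu_s2, lower.tail = FALSE)
  } else {
    p_rej <- stats::pnorm((cthr - mu_d) / se_d) - stats::pnorm((-cthr - mu_d) / se_d)
    # conditional law of Z_S2 given D = d (jointly normal, exact):
    c0 <- mom$cov_ept_s2 * se_d            # Cov(D, Z_S2)
    s_c <- sqrt(max(1 - (c0 / se_d)^2, 1e-12))
    tail <- function(lo, hi) {
      f <- function(d) {
        m <- mom$mu_s2 + (c0 / se_d^2) * (d - mu_d)
        stats::dnorm(d, mu_d, se_d) * stats::pnorm((c2 - m) / s_c, lower.tail = FALSE)
      }
      stats::integrate(f, lo, hi, rel.tol = 1e-8, abs.tol = 1e-10)$value
    }
    b_hit <- tail(-Inf, -cthr) + tail(cthr, Inf)
  }
  a_hit <- p_rej * p_s1_hit               # Z_S1 independent of D at omega*
  if (!complement) return(c(a = a_hit, b = b_hit))
  c(a = p_rej - a_hit, b = (1 - p_rej) - b_hit)
}

.oc_compute <- function(scenario, plan, design, margin, method, cov_sign,
                        weight, complement, replicates, seed, engine) {
  mom <- joint_moments(scenario, plan, margin, weight)
  if (method == "monte-carlo") {
    cfg <- simulation_config(scenario, plan, design, replicates = replicates,
                             seed = seed, margin = margin)
    res <- monte_carlo_oc(cfg, engine = engine, cov_sign = cov_sign)
    if (!complement)
      return(c(a = res$rate_ept_s1, b = res$rate_eptc_s2))
    return(c(a = res$borrow_rate - res$rate_ept_s1,
             b = (1 - res$borrow_rate) - res$rate_eptc_s2))
  }
  if (method == "exact-folded")
    return(.branch_probs_exact(mom, design, margin, scenario, complement))
  if (method == "normal-approx")
    return(.branch_probs(mom, design, cov_sign, scenario, complement))
  stop("unknown method: ", method, call. = FALSE)
}

#' Family-wise error rate of the fill-it-up procedure
#'
#' \eqn{E(\psi_{FIU}) = \alpha_{Ept,S_1} + \alpha_{Ept^c,S_2}}: the
#' probability of pooling and rejecting with the stage-1 test plus the
#' probability of extending and rejecting with the stage-2 test, evaluated at
#' the supplied scenario means. The caller is responsible for the scenario
#' lying in the composite null of interest.
#'
#' Methods: `"exact-folded"` integrates the two-tailed pre-test event over
#' the distribution of \eqn{\bar y_C - \bar y_H} (exact); `"normal-approx"`
#' treats \eqn{Z_{Ept}} as Gaussian with mean \eqn{\mu_{Ept}} and unit
#' variance (the linearization underlying the published operating
#' characteristics; at the equivalence boundary it rejects with probability
#' \eqn{\alpha_{Ept}/2} where the exact pre-test rejects far less);
#' `"monte-carlo"` delegates to [monte_carlo_oc()].
#'
#' @param scenario A [scenario_means()].
#' @param plan A [stage_plan()].
#' @param design The [fiu_design()]; its margin must be set unless `margin`
#'   is supplied.
#' @param method One of `"normal-approx"`, `"exact-folded"`, `"monte-carlo"`.
#' @param margin Equivalence margin; defaults to `design$margin`.
#' @param cov_sign Orientation of the pre-test/stage-2 covariance in the
#'   linearized approximation: `"auto"` (branch-consistent,
#'   \eqn{-\mathrm{sign}(\mu_C-\mu_H)\,|cov|}), `"positive"` or `"negative"`
#'   (fixed sign, as used by published evaluations).
#' @param weight Stage-1 pooling weight; default \eqn{\omega^*}.
#' @param replicates,seed,engine Passed to the Monte-Carlo method.
#' @return An object of class `fiu_oc` with `value` (= `component_a +
#'   component_b`), the two components, and the method.
#' @export
fwer <- function(scenario, plan, design = plan$design,
                 method = c("normal-approx", "exact-folded", "monte-carlo"),
                 margin = design$margin, cov_sign = "auto", weight = NULL,
                 replicates = 10000L, seed = 1L, engine = "sufficient") {
  method <- match.arg(method)
  if (is.null(margin)) stop("an equivalence margin is required", call. = FALSE)
  p <- .oc_compute(scenario, plan, design, margin, method, cov_sign, weight,
                   complement = FALSE, replicates, seed, engine)
  .fiu_oc("fwer", p[["a"]], p[["b"]], method)
}

#' Overall power of the fill-it-up procedure
#'
#' \eqn{1 - \beta_{FIU} = 1 - (\beta_{Ept,S_1} + \beta_{Ept^c,S_2})}: one
#' minus the probability of pooling but failing the stage-1 test plus the
#' probability of extending but failing the stage-2 test. Same methods and
#' arguments as [fwer()].
#'
#' @inheritParams fwer
#' @return An object of class `fiu_oc`; `value` is the overall power,
#'   `total = component_a + component_b` the overall type-II error.
#' @export
overall_power <- function(scenario, plan, design = plan$design,
                          method = c("normal-approx", "exact-folded", "monte-carlo"),
                          margin = design$margin, cov_sign = "auto", weight = NULL,
                          replicates = 10000L, seed = 1L, engine = "sufficient") {
  method <- match.arg(method)
  if (is.null(margin)) stop("an equivalence margin is required", call. = FALSE)
  p <- .oc_compute(scenario, plan, design, margin, method, cov_sign, weight,
                   complement = TRUE, replicates, seed, engine)
  .fiu_oc("power", p[["a"]], p[["b"]], method)
}

#' Error-rate surface over the null region
#'
#' Evaluates the family-wise error rate on a grid of control-group
#' separations `diff_ept` (\eqn{\mu_H - \mu_C \le -\Delta}, the pre-test
#' null) and weighted treatment differences `diff_s1` (\eqn{\le 0}, the
#' superiority null). The second coordinate is used as the noncentrality of
#' whichever terminal superiority statistic runs (stage-1 scale
#' `diff_s1/se_s1`, stage-2 scale `diff_s1/se_s2`): the worst
#' case within the stage-2 null, under which the surface approaches
#' \eqn{\alpha_{S_2}} for large separations and attains its minimum where the
#' separation equals the margin.
#'
#' @param plan A [stage_plan()].
#' @param design The [fiu_design()] (margin must be set unless supplied).
#' @param diff_ept Grid of \eqn{\mu_H - \mu_C} values (non-positive).
#' @param diff_s1 Grid of weighted treatment differences (non-positive).
#' @param margin Equivalence margin; defaults to `design$margin`.
#' @param cov_sign See [fwer()].
#' @param out Optional path: the surface is also written as CSV.
#' @return A data.frame with columns `diff_ept`, `diff_s1`, `alpha_ept`,
#'   `fwer`, `component_a`, `component_b`.
#' @export
fwer_surface <- function(plan, design = plan$design,
                         diff_ept = seq(-2.5, -margin, by = 0.05),
                         diff_s1 = c(-0.2, -0.15, -0.1, -0.05, 0),
                         margin = design$margin, cov_sign = "auto", out = NULL) {
  if (is.null(margin)) stop("an equivalence margin is required", call. = FALSE)
  if (length(diff_ept) == 0L || length(diff_s1) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  grid <- expand.grid(diff_ept = diff_ept, diff_s1 = diff_s1,
                      KEEP.OUT.ATTRS = FALSE)
  base <- joint_moments(scenario_means(0, 0, 0.0), plan, margin)
  zc <- stats::qnorm(1 - design$alpha_ept / 2)
  c1 <- stats::qnorm(1 - design$alpha_s1)
  c2 <- stats::qnorm(1 - design$alpha_s2)
  res <- t(vapply(seq_len(nrow(grid)), function(i) {
    d <- grid$diff_ept[i]; t_eff <- grid$diff_s1[i]
    mu_ept <- (abs(d) - margin) / base$se_d
    mu_s1 <- t_eff / base$se_s1
    mu_s2 <- t_eff / base$se_s2
    # mu_H - mu_C = d <= 0 means mu_C >= mu_H: branch-consistent sign
    rho2 <- .cov_sign_rho(cov_sign, mu_c = 0, mu_h = d, base$cov_ept_s2)
    a <- stats::pnorm(-zc, mu_ept) * stats::pnorm(c1, mu_s1, lower.tail = FALSE)
    b <- stats::pnorm(c2, mu_s2, lower.tail = FALSE) -
      .p_lower_upper(-zc, mu_ept, c2, mu_s2, rho2)
    c(a = a, b = b)
  }, c(a = 0, b = 0)))
  outdf <- data.frame(diff_ept = grid$diff_ept, diff_s1 = grid$diff_s1,
                      alpha_ept = design$alpha_ept,
                      fwer = res[, "a"] + res[, "b"],
                      component_a = res[, "a"], component_b = res[, "b"])
  if (!is.null(out)) utils::write.csv(outdf, out, row.names = FALSE)
  outdf
}

#' Supremum of the error rate over the null region
#'
#' Coarse grid search over the null region followed by a one-dimensional
#' refinement along the worst weighted difference, using the same evaluation
#' scheme as [fwer_surface()].
#'
#' @inheritParams fwer_surface
#' @param lower_sep Most negative control separation searched.
#' @return The estimated supremum (a probability).
#' @export
max_fwer <- function(plan, design = plan$design, margin = design$margin,
                     cov_sign = "auto", lower_sep = -2.5) {
  surf <- fwer_surface(plan, design,
                       diff_ept = seq(lower_sep, -margin, length.out = 25),
                       diff_s1 = seq(-0.2, 0, length.out = 5),
                       margin = margin, cov_sign = cov_sign)
  best <- surf[which.max(surf$fwer), ]
  f <- function(d) fwer_surface(plan, design, diff_ept = d,
                                diff_s1 = best$diff_s1, margin = margin,
                                cov_sign = cov_sign)$fwer
  opt <- stats::optimize(f, lower = lower_sep, upper = -margin, maximum = TRUE,
                         tol = 1e-4)
  max(best$fwer, opt$objective)
}
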