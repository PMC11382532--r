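# Monte-Carlo engines for the two-stage procedure: a patient-level replicate
# simulator, a vectorized sufficient-statistic engine (identical sampling
# distribution: group means are normal with variance 1/n), and a
# statistic-level engine drawing (Z_Ept, Z_S1, Z_S2) from the linearized
# Gaussian joint distribution used by the published operating
# characteristics.

#' Margins used in the error-rate simulation study
#'
#' The equivalence margins paired with each pre-test level in the
#' small-effect simulation setting (`delta = 0.275`, 500 historical
#' controls). They are fixed study constants and do not follow a single
#' quantile/rounding convention.
#'
#' @return Named numeric vector: margins indexed by `alpha_ept`.
#' @export
simulation_margins <- function() {
  c("0.01" = 0.27, "0.05" = 0.22, "0.1" = 0.19, "0.2" = 0.15)
}

#' Configuration of a Monte-Carlo run
#'
#' @param scenario A [scenario_means()].
#' @param plan A [stage_plan()].
#' @param design The [fiu_design()].
#' @param replicates Number of replicates (>= 1).
#' @param seed Integer seed; required for reproducibility.
#' @param margin Equivalence margin; defaults to `design$margin`.
#' @return Object of class `fiu_sim_config`.
#' @export
simulation_config <- function(scenario, plan, design = plan$design,
                              replicates = 50000L, seed, margin = design$margin) {
  stopifnot(inherits(scenario, "fiu_scenario"), inherits(plan, "fiu_plan"),
            inherits(design, "fiu_design"), replicates >= 1)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer `seed` is required", call. = FALSE)
  if (is.null(margin) || margin <= 0)
    stop("a positive equivalence margin is required", call. = FALSE)
  structure(list(scenario = scenario, plan = plan, design = design,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 margin = margin),
            class = "fiu_sim_config")
}

#' Preset truth scenarios of the error-rate simulation study
#'
#' Scenario I (minimum case): the control groups differ by exactly the
#' margin, \eqn{\mu_C = 0}, \eqn{\mu_H = -\Delta}, and the experimental mean
#' \eqn{\mu_E = -\omega^*\Delta} makes the weighted stage-1 treatment
#' difference zero (\eqn{\omega^*} from the stage-1 control counts).
#' Scenario II (maximum case): no treatment difference and strongly
#' discrepant controls, \eqn{\mu_C = \mu_E = 0}, \eqn{\mu_H = 3\Delta}.
#'
#' @param name `"scenario-I"` or `"scenario-II"`.
#' @param design A [fiu_design()]. If its margin is unset, the preset margin
#'   paired with `design$alpha_ept` by [simulation_margins()] is used.
#' @param plan A [stage_plan()]; defaults to `stage_plan(design)`.
#' @param replicates,seed Passed to [simulation_config()].
#' @param weight Weight used in the Scenario-I experimental mean; default
#'   \eqn{\omega^*} at the stage-1 control counts.
#' @return A `fiu_sim_config`.
#' @export
scenario_preset <- function(name = c("scenario-I", "scenario-II"), design,
                            plan = stage_plan(design), replicates = 50000L,
                            seed = 1L, weight = NULL) {
  name <- match.arg(name)
  margin <- design$margin
  if (is.null(margin)) {
    key <- as.character(design$alpha_ept)
    margin <- simulation_margins()[key]
    if (is.na(margin))
      stop("no preset margin for alpha_ept = ", design$alpha_ept,
           "; set design$margin explicitly", call. = FALSE)
    margin <- unname(margin)
  }
  w <- if (is.null(weight)) optimal_weight(design$n_h, plan$n_c) else weight
  scen <- switch(name,
                 "scenario-I" = scenario_means(mu_e = -w * margin, mu_c = 0,
                                               mu_h = -margin),
                 "scenario-II" = scenario_means(mu_e = 0, mu_c = 0,
                                                mu_h = 3 * margin))
  simulation_config(scen, plan, design, replicates = replicates, seed = seed,
                    margin = margin)
}

#' Simulate one replicate of the two-stage trial at the patient level
#'
#' Draws unit-variance normal responses for the stage-1 randomized groups and
#' the historical controls at the scenario means, runs the equivalence
#' pre-test, and then either the pooled stage-1 superiority test (on
#' rejection) or recruits the stage-2 patients and runs the full-data test.
#'
#' @param config A [simulation_config()].
#' @param rep Replicate index; the replicate's RNG stream is seeded with
#'   `config$seed + rep` so individual replicates are reproducible.
#' @return List with `decision` (0/1), `branch` (`"S1"` or `"S2"`),
#'   `n_new` (newly recruited patients), and the `fiu_test` objects run.
#' @export
simulate_trial <- function(config, rep = 1L) {
  stopifnot(inherits(config, "fiu_sim_config"))
  plan <- config$plan; sc <- config$scenario; des <- config$design
  set.seed(config$seed + as.integer(rep))
  y_e <- stats::rnorm(plan$n_e, sc$mu_e)
  y_c <- stats::rnorm(plan$n_c, sc$mu_c)
  y_h <- stats::rnorm(des$n_h, sc$mu_h)
  summ <- group_summary(mean_e = mean(y_e), mean_c = mean(y_c), mean_h = mean(y_h),
                        n_e = plan$n_e, n_c = plan$n_c, n_h = des$n_h)
  ept <- z_ept(summ, config$margin, des$alpha_ept)
  if (ept$reject == 1L) {
    s1 <- z_s1(summ, alpha_s1 = des$alpha_s1)
    return(list(decision = decide_fill_it_up(ept, s1 = s1), branch = "S1",
                n_new = plan$n_e + plan$n_c, tests = list(ept = ept, s1 = s1)))
  }
  y_e2 <- stats::rnorm(plan$n_e2, sc$mu_e)
  y_c2 <- stats::rnorm(plan$n_c2, sc$mu_c)
  summ$mean_e2 <- mean(c(y_e, y_e2)); summ$mean_c2 <- mean(c(y_c, y_c2))
  summ$n_e2_total <- plan$cap_n_e; summ$n_c2_total <- plan$cap_n_c
  s2 <- z_s2(summ, alpha_s2 = des$alpha_s2)
  list(decision = decide_fill_it_up(ept, s2 = s2), branch = "S2",
       n_new = plan$n_fiu, tests = list(ept = ept, s2 = s2))
}

#' Monte-Carlo operating characteristics
#'
#' Aggregates replicates of the two-stage procedure into empirical rejection
#' and borrowing rates and the average newly recruited sample size.
#'
#' Engines: `"sufficient"` (default) draws the group means directly from
#' their exact sampling distribution (normal, variance `1/n`) and vectorizes
#' over replicates — identical in distribution to the patient-level engine;
#' `"patient"` loops over [simulate_trial()]; `"approx"` draws the three test
#' statistics from the linearized Gaussian joint distribution of
#' [joint_moments()] (the published evaluation scheme), with the pre-test
#' covariance orientation controlled by `cov_sign` as in [fwer()].
#'
#' @param config A [simulation_config()].
#' @param engine `"sufficient"`, `"patient"` or `"approx"`.
#' @param cov_sign Covariance orientation for the `"approx"` engine.
#' @return Object of class `fiu_sim`: `reject_rate`, `borrow_rate`, `asn`,
#'   `mc_se`, branch-specific rejection rates `rate_ept_s1`/`rate_eptc_s2`,
#'   and the configuration echo.
#' @export
monte_carlo_oc <- function(config, engine = c("sufficient", "patient", "approx"),
                           cov_sign = "auto") {
  stopifnot(inherits(config, "fiu_sim_config"))
  engine <- match.arg(engine)
  plan <- config$plan; sc <- config$scenario; des <- config$design
  R <- config$replicates
  zc <- stats::qnorm(1 - des$alpha_ept / 2)
  c1 <- stats::qnorm(1 - des$alpha_s1)
  c2 <- stats::qnorm(1 - des$alpha_s2)

  if (engine == "patient") {
    reps <- lapply(seq_len(R), function(i) simulate_trial(config, rep = i))
    borrow <- vapply(reps, function(r) r$branch == "S1", logical(1))
    dec <- vapply(reps, function(r) r$decision == 1L, logical(1))
  } else if (engine == "sufficient") {
    set.seed(config$seed)
    m_e <- stats::rnorm(R, sc$mu_e, 1 / sqrt(plan$n_e))
    m_c <- stats::rnorm(R, sc$mu_c, 1 / sqrt(plan$n_c))
    m_h <- stats::rnorm(R, sc$mu_h, 1 / sqrt(des$n_h))
    se_d <- sqrt(1 / plan$n_c + 1 / des$n_h)
    z_e <- (abs(m_c - m_h) - config$margin) / se_d
    borrow <- z_e < -zc
    w <- optimal_weight(des$n_h, plan$n_c)
    z1 <- (m_e - (w * m_h + (1 - w) * m_c)) /
      sqrt(1 / plan$n_e + 1 / (des$n_h + plan$n_c))
    m_e2 <- stats::rnorm(R, sc$mu_e, 1 / sqrt(plan$n_e2))
    m_c2 <- stats::rnorm(R, sc$mu_c, 1 / sqrt(plan$n_c2))
    full_e <- (plan$n_e * m_e + plan$n_e2 * m_e2) / plan$cap_n_e
    full_c <- (plan$n_c * m_c + plan$n_c2 * m_c2) / plan$cap_n_c
    z2 <- (full_e - full_c) / sqrt(1 / plan$cap_n_e + 1 / plan$cap_n_c)
    dec <- ifelse(borrow, z1 > c1, z2 > c2)
  } else {                                    # statistic-level approximation
    mom <- joint_moments(sc, plan, config$margin)
    rho <- .cov_sign_rho(cov_sign, sc$mu_c, sc$mu_h, mom$cov_ept_s2)
    set.seed(config$seed)
    z_e <- stats::rnorm(R, mom$mu_ept)
    z1 <- stats::rnorm(R, mom$mu_s1)          # uncorrelated at omega*
    z2 <- mom$mu_s2 + rho * (z_e - mom$mu_ept) +
      sqrt(1 - rho^2) * stats::rnorm(R)
    borrow <- z_e < -zc
    dec <- ifelse(borrow, z1 > c1, z2 > c2)
  }

  p <- mean(dec)
  structure(list(
    reject_rate = p,
    borrow_rate = mean(borrow),
    asn = mean(ifelse(borrow, plan$n_e + plan$n_c, plan$n_fiu)),
    mc_se = sqrt(p * (1 - p) / R),
    rate_ept_s1 = mean(dec & borrow),
    rate_eptc_s2 = mean(dec & !borrow),
    replicates = R, seed = config$seed, engine = engine,
    config = config), class = "fiu_sim")
}

#' @export
print.fiu_sim <- function(x, ...) {
  cat(sprintf("Monte-Carlo operating characteristics (%s engine, R = %d, seed %d)\n",
              x$engine, x$replicates, x$seed))
  cat(sprintf("  rejection rate : %.4f (MC se %.4f)\n", x$reject_rate, x$mc_se))
  cat(sprintf("  borrowing rate : %.4f\n", x$borrow_rate))
  cat(sprintf("  average newly recruited sample size: %.1f\n", x$asn))
  invisible(x)
}
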