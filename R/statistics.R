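# The three z statistics of the procedure, their decision functions, the TOST
# formulation of the pre-test, the weighted effect size, and the combined
# decision rule.

#' Group summary statistics of a fill-it-up trial
#'
#' Sample means and counts of the historical (`h`), experimental (`e`) and
#' randomized control (`c`) groups. Stage-1 means/counts feed the pre-test and
#' the pooled superiority test; full-data means over `n_e2_total`/`n_c2_total`
#' patients (stage 1 + stage 2) feed the continued-randomization test and are
#' only required for that step.
#'
#' @param mean_e,mean_c,mean_h Stage-1 (and historical) sample means.
#' @param n_e,n_c,n_h Corresponding counts.
#' @param mean_e2,mean_c2 Full-data means over all randomized patients.
#' @param n_e2_total,n_c2_total Full-data counts (>= stage-1 counts).
#' @return Object of class `fiu_summary`.
#' @export
group_summary <- function(mean_e = NA_real_, mean_c = NA_real_, mean_h = NA_real_,
                          n_e = 0L, n_c = 0L, n_h = 0L,
                          mean_e2 = NA_real_, mean_c2 = NA_real_,
                          n_e2_total = 0L, n_c2_total = 0L) {
  used <- function(m, n, lab) {
    if (!is.na(m) && n < 1)
      stop("count for ", lab, " must be >= 1 when its mean is supplied", call. = FALSE)
  }
  used(mean_e, n_e, "E"); used(mean_c, n_c, "C"); used(mean_h, n_h, "H")
  used(mean_e2, n_e2_total, "full-data E"); used(mean_c2, n_c2_total, "full-data C")
  if (n_e2_total > 0 && n_e2_total < n_e)
    stop("full-data count for E cannot be below the stage-1 count", call. = FALSE)
  if (n_c2_total > 0 && n_c2_total < n_c)
    stop("full-data count for C cannot be below the stage-1 count", call. = FALSE)
  structure(list(mean_e = mean_e, mean_c = mean_c, mean_h = mean_h,
                 n_e = as.integer(n_e), n_c = as.integer(n_c), n_h = as.integer(n_h),
                 mean_e2 = mean_e2, mean_c2 = mean_c2,
                 n_e2_total = as.integer(n_e2_total),
                 n_c2_total = as.integer(n_c2_total)),
            class = "fiu_summary")
}

fiu_test_result <- function(statistic, critical, reject, test_id, alpha,
                            weight = NULL) {
  structure(list(statistic = statistic, critical = critical,
                 reject = as.integer(reject), test_id = test_id,
                 alpha = alpha, weight = weight),
            class = "fiu_test")
}

#' @export
print.fiu_test <- function(x, ...) {
  lab <- c(Ept = "equivalence pre-test",
           S1 = "pooled superiority test (stage 1)",
           S2 = "superiority test (full randomized data)")[x$test_id]
  cat(sprintf("%s\n  Z = %.4f, critical value %.4f (level %g)%s\n  decision: %s\n",
              lab, x$statistic, x$critical, x$alpha,
              if (!is.null(x$weight)) sprintf(", weight %.4f", x$weight) else "",
              if (x$reject == 1L) "reject H0" else "do not reject H0"))
  invisible(x)
}

#' @export
format.fiu_test <- function(x, ...) {
  sprintf("%s: Z=%.4f crit=%.4f reject=%d", x$test_id, x$statistic, x$critical, x$reject)
}

#' Serialize a test result to JSON
#'
#' @param x A `fiu_test` object.
#' @param ... Passed to [jsonlite::toJSON()].
#' @return A JSON string with statistic, critical value, level and decision.
#' @export
test_result_json <- function(x, ...) {
  stopifnot(inherits(x, "fiu_test"))
  out <- x[c("test_id", "statistic", "critical", "alpha", "reject")]
  if (!is.null(x$weight)) out$weight <- x$weight
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, ...)
}

#' Equivalence pre-test of historical versus randomized controls
#'
#' Tests \eqn{H_0: |\mu_C - \mu_H| \ge \Delta} against equivalence using
#' \deqn{Z_{Ept} = \frac{|\bar y_C - \bar y_H| - \Delta}{\sqrt{1/n_C + 1/n_H}},}
#' rejecting when \eqn{Z_{Ept} < -z_{1-\alpha_{Ept}/2}}. With `tost = TRUE`
#' the equivalent two-one-sided-tests formulation is used (both shifted
#' statistics must fall in their rejection regions); the decision is
#' identical.
#'
#' @param summary A [group_summary()] with control and historical entries.
#' @param margin Equivalence margin \eqn{\Delta > 0}.
#' @param alpha_ept Two-sided level of the pre-test.
#' @param tost Use the two-one-sided-tests formulation of the decision.
#' @return A `fiu_test` (`test_id = "Ept"`). For `tost = TRUE` the reported
#'   statistic is the shifted statistic further from its rejection bound.
#' @export
z_ept <- function(summary, margin, alpha_ept = 0.05, tost = FALSE) {
  stopifnot(inherits(summary, "fiu_summary"))
  if (!is.numeric(margin) || length(margin) != 1L || !is.finite(margin) || margin <= 0)
    stop("`margin` must be a single positive number", call. = FALSE)
  if (summary$n_c < 1 || summary$n_h < 1)
    stop("pre-test needs at least one randomized and one historical control", call. = FALSE)
  se <- sqrt(1 / summary$n_c + 1 / summary$n_h)
  d <- summary$mean_c - summary$mean_h
  crit <- stats::qnorm(1 - alpha_ept / 2)
  if (tost) {
    z_up <- (d - margin) / se    # H0: mu_C - mu_H >= Delta, reject small
    z_lo <- (d + margin) / se    # H0: mu_C - mu_H <= -Delta, reject large
    reject <- (z_up < -crit) && (z_lo > crit)
    stat <- if (abs(z_up) < z_lo) z_up else -z_lo  # least favorable, on Z_Ept scale
    return(fiu_test_result(stat, -crit, reject, "Ept", alpha_ept))
  }
  stat <- (abs(d) - margin) / se
  fiu_test_result(stat, -crit, stat < -crit, "Ept", alpha_ept)
}

#' Pooled superiority test with historical controls (stage 1)
#'
#' Weighted z statistic comparing the experimental mean to the
#' \eqn{\omega}-weighted mix of historical and randomized control means,
#' \deqn{Z_{S_1} = \frac{\bar y_E - (\omega \bar y_H + (1-\omega)\bar y_C)}
#'   {\sqrt{1/n_E + \omega^2/n_H + (1-\omega)^2/n_C}},}
#' rejecting when \eqn{Z_{S_1} > z_{1-\alpha_{S_1}}} (strict). With the
#' variance-minimizing weight [optimal_weight()] (the default) this is the
#' ordinary two-sample z test of E against the pooled control sample, with
#' squared denominator \eqn{1/n_E + 1/(n_H + n_C)}.
#'
#' @param summary A [group_summary()].
#' @param weight Historical-control weight \eqn{\omega \in [0,1]}; default
#'   \eqn{\omega^*} computed from the realized counts.
#' @param alpha_s1 One-sided level.
#' @return A `fiu_test` (`test_id = "S1"`) carrying the weight used.
#' @export
z_s1 <- function(summary, weight = NULL,
                 alpha_s1 = 0.05) {
  stopifnot(inherits(summary, "fiu_summary"))
  if (is.null(weight)) weight <- optimal_weight(summary$n_h, summary$n_c)
  if (weight < 0 || weight > 1) stop("`weight` must lie in [0, 1]", call. = FALSE)
  pooled <- weight * summary$mean_h + (1 - weight) * summary$mean_c
  v <- 1 / summary$n_e
  if (weight > 0) v <- v + weight^2 / summary$n_h
  if (weight < 1) v <- v + (1 - weight)^2 / summary$n_c
  stat <- (summary$mean_e - pooled) / sqrt(v)
  crit <- stats::qnorm(1 - alpha_s1)
  fiu_test_result(stat, crit, stat > crit, "S1", alpha_s1, weight = weight)
}

#' Superiority test on the full randomized data (stage 2)
#'
#' Plain two-sample z statistic on all randomized patients,
#' \eqn{Z_{S_2} = (\bar y'_E - \bar y'_C)/\sqrt{1/N_E + 1/N_C}}, rejecting
#' when \eqn{Z_{S_2} > z_{1-\alpha_{S_2}}} (strict); historical controls are
#' discarded.
#'
#' @param summary A [group_summary()] with full-data entries.
#' @param alpha_s2 One-sided level.
#' @return A `fiu_test` (`test_id = "S2"`).
#' @export
z_s2 <- function(summary, alpha_s2 = 0.05) {
  stopifnot(inherits(summary, "fiu_summary"))
  if (summary$n_e2_total < 1 || summary$n_c2_total < 1)
    stop("stage-2 test needs full-data counts of at least 1 per group", call. = FALSE)
  stat <- (summary$mean_e2 - summary$mean_c2) /
    sqrt(1 / summary$n_e2_total + 1 / summary$n_c2_total)
  crit <- stats::qnorm(1 - alpha_s2)
  fiu_test_result(stat, crit, stat > crit, "S2", alpha_s2)
}

#' Weighted effect size actually tested by the pooled superiority test
#'
#' \eqn{t = \delta + \omega(\mu_C - \mu_H)} with \eqn{\delta = \mu_E - \mu_C}:
#' the treatment difference against the \eqn{\omega}-weighted control mix.
#'
#' @param mu_e,mu_c,mu_h True group means.
#' @param weight Historical-control weight \eqn{\omega}.
#' @return The weighted effect size.
#' @export
weighted_effect <- function(mu_e, mu_c, mu_h, weight) {
  (mu_e - mu_c) + weight * (mu_c - mu_h)
}

#' Combined decision of the fill-it-up procedure
#'
#' \eqn{\psi_{FIU} = \max(\varphi_{Ept}\varphi_{S_1},
#' (1-\varphi_{Ept})\varphi_{S_2})}: the trial claims superiority either by
#' the pooled stage-1 test after a successful pre-test, or by the full-data
#' test after an unsuccessful one. Exactly the branch consistent with the
#' pre-test decision must be supplied.
#'
#' @param ept Pre-test result (`fiu_test`, id `"Ept"`).
#' @param s1,s2 Exactly one of the two superiority-test results.
#' @return 0 or 1, the overall decision.
#' @export
decide_fill_it_up <- function(ept, s1 = NULL, s2 = NULL) {
  stopifnot(inherits(ept, "fiu_test"), ept$test_id == "Ept")
  if (is.null(s1) == is.null(s2))
    stop("exactly one of `s1` and `s2` must be supplied", call. = FALSE)
  if (ept$reject == 1L) {
    if (is.null(s1))
      stop("protocol violation: pre-test rejected, the pooled test (s1) is required",
           call. = FALSE)
    stopifnot(inherits(s1, "fiu_test"), s1$test_id == "S1")
    return(s1$reject)
  }
  if (is.null(s2))
    stop("protocol violation: pre-test did not reject, the stage-2 test (s2) is required",
         call. = FALSE)
  stopifnot(inherits(s2, "fiu_test"), s2$test_id == "S2")
  s2$reject
}
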