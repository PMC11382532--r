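# Closed-form planning of the two-stage fill-it-up design: one-step sample
# sizes, stage allocation, equivalence-margin bounds, pooling weight, average
# sample size. All responses are standardized (sigma^2 = 1 in every group).

#' Design specification for a fill-it-up trial
#'
#' Collects the planning-time parameters of a two-arm superiority trial with a
#' normal endpoint (unit variance in all groups) that may borrow `n_h`
#' historical controls through an equivalence pre-test.
#'
#' @param delta Anticipated effect size \eqn{\mu_E - \mu_C} in standardized
#'   units. Must be positive.
#' @param alpha_ept Nominal two-sided level of the equivalence pre-test.
#' @param alpha_s1,alpha_s2 One-sided levels of the pooled (stage-1) and
#'   continued-randomization (stage-2) superiority tests.
#' @param beta_s1,beta_s2 Type-II error probabilities of the two superiority
#'   tests; the planned power of each test is `1 - beta`.
#' @param n_h Number of historical controls available (non-negative integer).
#' @param margin Equivalence margin \eqn{\Delta > 0}; may be left `NULL` at
#'   the sample-size stage and set later (e.g. after [margin_bounds()]).
#' @return An object of class `fiu_design`.
#' @examples
#' d <- fiu_design(delta = 0.275, n_h = 500, margin = 0.22)
#' stage_plan(d)
#' @export
fiu_design <- function(delta, alpha_ept = 0.05, alpha_s1 = 0.05,
                       alpha_s2 = 0.05, beta_s1 = 0.2, beta_s2 = 0.2,
                       n_h = 0L, margin = NULL) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("`delta` must be a single positive number", call. = FALSE)
  for (nm in c("alpha_ept", "alpha_s1", "alpha_s2", "beta_s1", "beta_s2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      stop("`", nm, "` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(n_h) || length(n_h) != 1L || n_h < 0 || n_h != round(n_h))
    stop("`n_h` must be a non-negative integer", call. = FALSE)
  if (!is.null(margin)) {
    if (!is.numeric(margin) || length(margin) != 1L || !is.finite(margin) || margin <= 0)
      stop("`margin` must be a single positive number", call. = FALSE)
  }
  structure(
    list(delta = delta, alpha_ept = alpha_ept, alpha_s1 = alpha_s1,
         alpha_s2 = alpha_s2, beta_s1 = beta_s1, beta_s2 = beta_s2,
         n_h = as.integer(n_h), margin = margin),
    class = "fiu_design")
}

#' @export
print.fiu_design <- function(x, ...) {
  cat("Fill-it-up design specification\n")
  cat(sprintf("  effect size delta       : %g\n", x$delta))
  cat(sprintf("  historical controls n_H : %d\n", x$n_h))
  cat(sprintf("  alpha (Ept, two-sided)  : %g\n", x$alpha_ept))
  cat(sprintf("  alpha (S1, S2 one-sided): %g, %g\n", x$alpha_s1, x$alpha_s2))
  cat(sprintf("  power (S1, S2)          : %g, %g\n", 1 - x$beta_s1, 1 - x$beta_s2))
  cat(sprintf("  equivalence margin Delta: %s\n",
              if (is.null(x$margin)) "<unset>" else format(x$margin)))
  invisible(x)
}

#' One-step per-group sample size of a z-test for superiority
#'
#' Smallest integer per-group size `n` (balanced allocation) such that
#' \eqn{n/2 \ge (z_{1-\alpha}+z_{1-\beta})^2/\delta^2}, i.e. the harmonic-mean
#' sample-size formula of the one-sided two-sample z-test with unit variances.
#' The trial total is `2 * n`.
#'
#' @param delta Effect size to detect (> 0).
#' @param alpha One-sided significance level.
#' @param beta Type-II error probability (power is `1 - beta`).
#' @return Integer per-group sample size.
#' @examples
#' one_step_sample_size(0.5, 0.05, 0.2)    # 50 per group, 100 in total
#' one_step_sample_size(0.275, 0.05, 0.2)  # 164 per group, 328 in total
#' @export
one_step_sample_size <- function(delta, alpha = 0.05, beta = 0.2) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("`delta` must be a single positive number", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  need <- (stats::qnorm(1 - alpha) + stats::qnorm(1 - beta))^2 / delta^2
  as.integer(ceiling(2 * need))
}

#' Stage-1 fraction for balanced allocation and equal test levels
#'
#' Closed-form fraction \eqn{\gamma} of the per-group maximum size `N` to be
#' randomized in stage 1 so that the pooled stage-1 test and the full stage-2
#' test carry the same power:
#' \deqn{\gamma = \frac{N - n_H + \sqrt{N^2 + n_H^2}}{2N}.}
#' It always satisfies \eqn{1/2 \le \gamma \le 1}, equals 1 when `n_h = 0`,
#' and decreases towards 1/2 as `n_h` grows.
#'
#' @param n_per_group Per-group maximum sample size `N` (>= 1).
#' @param n_h Number of historical controls (>= 0).
#' @return The stage-1 fraction, a number in `[1/2, 1]`.
#' @examples
#' gamma_balanced(164, 500)  # ~0.580
#' @export
gamma_balanced <- function(n_per_group, n_h) {
  stopifnot(is.numeric(n_per_group), length(n_per_group) == 1L, n_per_group >= 1,
            is.numeric(n_h), length(n_h) == 1L, n_h >= 0)
  N <- n_per_group
  (N - n_h + sqrt(N^2 + n_h^2)) / (2 * N)
}

#' Stage-1 fraction for general levels and allocation
#'
#' Roots in `(0, 1]` of the quadratic in \eqn{\gamma} obtained by equating the
#' information of the pooled stage-1 test to that of the full stage-2 test for
#' possibly unequal significance levels, type-II errors and group totals.
#' With equal levels and balanced totals this reduces to [gamma_balanced()].
#'
#' @param design A [fiu_design()] supplying the four quantile ratios.
#' @param cap_n_e,cap_n_c Planned totals \eqn{N_E, N_C} per group (>= 1).
#' @param n_h Historical-control count; defaults to `design$n_h`.
#' @return Numeric vector of admissible roots in `(0, 1]` (usually length 1).
#' @export
gamma_general <- function(design, cap_n_e, cap_n_c, n_h = design$n_h) {
  stopifnot(inherits(design, "fiu_design"), cap_n_e >= 1, cap_n_c >= 1, n_h >= 0)
  q <- ((stats::qnorm(1 - design$alpha_s1) + stats::qnorm(1 - design$beta_s1)) /
        (stats::qnorm(1 - design$alpha_s2) + stats::qnorm(1 - design$beta_s2)))^2
  h <- n_h / cap_n_c
  disc <- (h - q)^2 + 4 * n_h / (cap_n_e + cap_n_c) * q
  roots <- 0.5 * (-h + q + c(1, -1) * sqrt(disc))
  adm <- roots[roots > 1e-12 & roots <= 1 + 1e-12]
  if (length(adm) == 0L)
    stop("no admissible stage-1 fraction in (0, 1]: design is infeasible", call. = FALSE)
  pmin(adm, 1)
}

#' Variance-minimizing weight of the historical controls
#'
#' The weight \eqn{\omega^* = n_H/(n_H + n_C)} minimizing the variance of the
#' pooled control mean \eqn{\omega \bar y_H + (1-\omega)\bar y_C}; the
#' minimized variance is \eqn{1/(n_H + n_C)} (simple pooling by sample size).
#'
#' @param n_h Historical-control count.
#' @param n_c Randomized stage-1 control count.
#' @return Weight in `[0, 1]`.
#' @examples
#' optimal_weight(500, 96)  # ~0.839
#' @export
optimal_weight <- function(n_h, n_c) {
  stopifnot(n_h >= 0, n_c >= 0)
  if (n_h + n_c < 1) stop("`n_h + n_c` must be at least 1", call. = FALSE)
  n_h / (n_h + n_c)
}

#' Average sample size of the fill-it-up design
#'
#' Design-time expected number of newly recruited patients: stage 1 is always
#' recruited, stage 2 with probability \eqn{1 - \alpha_{Ept}} (the pre-test
#' rejects its null at most at its nominal level on the equivalence boundary).
#' Rounded up per group and summed, matching
#' \eqn{AVN = \gamma N_{FIU} + (1-\alpha_{Ept})(N_{FIU} - \gamma N_{FIU})}
#' up to the per-group ceiling.
#'
#' @param plan A [stage_plan()] result.
#' @param alpha_ept Two-sided level of the pre-test; defaults to the design's.
#' @return Integer average total sample size.
#' @export
average_sample_size <- function(plan, alpha_ept = plan$design$alpha_ept) {
  stopifnot(inherits(plan, "fiu_plan"), alpha_ept > 0, alpha_ept < 1)
  per_e <- ceiling(plan$n_e + (1 - alpha_ept) * plan$n_e2)
  per_c <- ceiling(plan$n_c + (1 - alpha_ept) * plan$n_c2)
  as.integer(per_e + per_c)
}

#' Stage sizes of the fill-it-up design
#'
#' Chains the one-step sample size (per-group ceiling), the balanced stage-1
#' fraction, and the per-group ceiling of the stage-1 sizes:
#' `n_E = n_C = ceiling(gamma * N)`, stage-2 remainders `N - n_1`, and the
#' average sample size.
#'
#' @param design A [fiu_design()]; the margin may still be unset.
#' @return An object of class `fiu_plan` with elements `n_e`, `n_c` (stage-1
#'   per-group sizes), `n_e2`, `n_c2` (stage-2 additions), `cap_n_e`,
#'   `cap_n_c` (totals per group), `n_fiu` (maximum total), `gamma`, `avn`,
#'   and the originating `design`.
#' @examples
#' stage_plan(fiu_design(delta = 0.275, n_h = 500))  # N_FIU = 328, stage 1 = 192
#' @export
stage_plan <- function(design) {
  stopifnot(inherits(design, "fiu_design"))
  n_pg <- one_step_sample_size(design$delta, design$alpha_s2, design$beta_s2)
  gam <- gamma_balanced(n_pg, design$n_h)
  n1 <- as.integer(ceiling(gam * n_pg))
  plan <- structure(
    list(n_e = n1, n_c = n1, n_e2 = n_pg - n1, n_c2 = n_pg - n1,
         cap_n_e = n_pg, cap_n_c = n_pg, n_fiu = 2L * n_pg,
         gamma = gam, avn = NA_integer_, design = design),
    class = "fiu_plan")
  plan$avn <- average_sample_size(plan, design$alpha_ept)
  plan
}

#' @export
print.fiu_plan <- function(x, ...) {
  cat("Fill-it-up stage plan (balanced allocation)\n")
  cat(sprintf("  maximum total N_FIU          : %d (%d per group)\n", x$n_fiu, x$cap_n_e))
  cat(sprintf("  stage-1 total gamma*N_FIU    : %d (%d per group)\n", x$n_e + x$n_c, x$n_e))
  cat(sprintf("  stage-2 additions            : %d per group\n", x$n_e2))
  cat(sprintf("  stage-1 fraction gamma       : %.4f\n", x$gamma))
  cat(sprintf("  average sample size AVN      : %d\n", x$avn))
  cat(sprintf("  historical controls n_H      : %d\n", x$design$n_h))
  invisible(x)
}

#' Admissible range of the equivalence margin
#'
#' Lower bound below which the pre-test null can never be rejected for any
#' data, \eqn{z \cdot \sqrt{1/n_H + 1/n_C}}, and the (exclusive) upper bound
#' \eqn{\delta}. The quantile convention for the bound is one-sided
#' (\eqn{z_{1-\alpha_{Ept}}}) by default; the decision rule of [z_ept()] uses
#' the two-sided quantile \eqn{z_{1-\alpha_{Ept}/2}}, which can be requested
#' here with `sided = "two"`.
#'
#' @param n_c Stage-1 randomized control count (>= 1).
#' @param n_h Historical-control count (>= 1).
#' @param alpha_ept Two-sided level of the pre-test.
#' @param delta Effect size, the exclusive upper bound for the margin.
#' @param sided `"one"` (default) or `"two"`: quantile used for the bound.
#' @return Object of class `fiu_margin_bounds`: `lower`, `upper`, `feasible`.
#' @examples
#' margin_bounds(27, 500, 0.01, 0.5)  # lower ~0.4596
#' @export
margin_bounds <- function(n_c, n_h, alpha_ept, delta, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(n_c >= 1, n_h >= 1, alpha_ept > 0, alpha_ept < 1, delta > 0)
  z <- if (sided == "one") stats::qnorm(1 - alpha_ept) else stats::qnorm(1 - alpha_ept / 2)
  lower <- z * sqrt(1 / n_h + 1 / n_c)
  structure(list(lower = lower, upper = delta, feasible = lower < delta,
                 sided = sided),
            class = "fiu_margin_bounds")
}

#' @export
print.fiu_margin_bounds <- function(x, ...) {
  cat(sprintf("Equivalence margin range (%s-sided quantile): [%.4f, %.4f)%s\n",
              x$sided, x$lower, x$upper,
              if (x$feasible) "" else "  ** infeasible: lower bound >= delta **"))
  invisible(x)
}
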