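# Patient-level dataset format, CSV I/O with validation, synthetic-data
# generation, and the step-wise analysis workflow (pre-test, pooled test,
# full-data test) with information-fraction reporting.

.fiu_groups <- c("H", "E", "C")
.fiu_recruitment <- c("historical", "initial", "further")

.validate_trial_data <- function(df, where = "dataset") {
  problems <- character(0)
  line <- function(i) i + 1L   # header is line 1
  if (nrow(df) == 0L) stop("empty ", where, ": no patient records", call. = FALSE)
  if (anyDuplicated(df$PatID)) {
    dup <- which(duplicated(df$PatID))
    problems <- c(problems, sprintf("line %d: duplicate PatID '%s'",
                                    line(dup), df$PatID[dup]))
  }
  bad_g <- which(!df$Group %in% .fiu_groups)
  if (length(bad_g))
    problems <- c(problems, sprintf("line %d: unknown group code '%s'",
                                    line(bad_g), df$Group[bad_g]))
  bad_r <- which(!df$Recruitment %in% .fiu_recruitment)
  if (length(bad_r))
    problems <- c(problems, sprintf("line %d: unknown recruitment code '%s'",
                                    line(bad_r), df$Recruitment[bad_r]))
  bad_resp <- which(!is.finite(df$Response))
  if (length(bad_resp))
    problems <- c(problems, sprintf("line %d: non-numeric or missing response",
                                    line(bad_resp)))
  mism <- which((df$Group == "H") != (df$Recruitment == "historical"))
  if (length(mism))
    problems <- c(problems,
                  sprintf("line %d: group %s is inconsistent with recruitment '%s'",
                          line(mism), df$Group[mism], df$Recruitment[mism]))
  if (length(problems))
    stop("invalid ", where, ":\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(df)
}

.as_trial_data <- function(df, where = "dataset") {
  df$Group <- toupper(trimws(as.character(df$Group)))
  df$Recruitment <- tolower(trimws(as.character(df$Recruitment)))
  df$Response <- suppressWarnings(as.numeric(df$Response))
  .validate_trial_data(df, where)
  class(df) <- c("fiu_data", "data.frame")
  df
}

#' Read a patient-level trial dataset
#'
#' CSV with header exactly `PatID,Group,Recruitment,Response`; groups are
#' `H`/`E`/`C`, recruitment codes `historical`/`initial`/`further`
#' (case-insensitive on input, canonical case on output). Group `H` must and
#' may only carry recruitment `historical`. Malformed rows are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return A `fiu_data` data.frame.
#' @export
read_trial_data <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "character", "character"))
  if (!identical(names(df), c("PatID", "Group", "Recruitment", "Response")))
    stop("header must be exactly PatID,Group,Recruitment,Response", call. = FALSE)
  .as_trial_data(df, where = paste0("dataset '", path, "'"))
}

#' Write a patient-level trial dataset
#'
#' @param data A `fiu_data` (or conforming data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path) {
  data <- .as_trial_data(as.data.frame(data))
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic patient-level trial dataset
#'
#' Draws unit-variance normal responses at the scenario means. Stage 1 emits
#' the historical controls plus the initially randomized E/C patients;
#' `stage = 2` appends the further-recruited stage-2 patients. Deterministic
#' given `seed`.
#'
#' @param scenario A [scenario_means()].
#' @param plan A [stage_plan()].
#' @param n_h Historical-control count; defaults to the plan's design.
#' @param seed Integer seed.
#' @param stage 1 (stage-1 data only) or 2 (full dataset).
#' @return A `fiu_data` data.frame.
#' @export
generate_trial_data <- function(scenario, plan, n_h = plan$design$n_h, seed,
                                stage = 1L) {
  stopifnot(inherits(scenario, "fiu_scenario"), inherits(plan, "fiu_plan"),
            n_h >= 0, stage %in% c(1L, 2L))
  if (missing(seed)) stop("an integer `seed` is required", call. = FALSE)
  set.seed(as.integer(seed))
  blocks <- list(
    data.frame(Group = "H", Recruitment = "historical",
               Response = stats::rnorm(n_h, scenario$mu_h)),
    data.frame(Group = "C", Recruitment = "initial",
               Response = stats::rnorm(plan$n_c, scenario$mu_c)),
    data.frame(Group = "E", Recruitment = "initial",
               Response = stats::rnorm(plan$n_e, scenario$mu_e)))
  if (stage == 2L) {
    blocks <- c(blocks, list(
      data.frame(Group = "C", Recruitment = "further",
                 Response = stats::rnorm(plan$n_c2, scenario$mu_c)),
      data.frame(Group = "E", Recruitment = "further",
                 Response = stats::rnorm(plan$n_e2, scenario$mu_e))))
  }
  df <- do.call(rbind, blocks)
  df <- data.frame(PatID = as.character(seq_len(nrow(df))), df,
                   stringsAsFactors = FALSE)
  .as_trial_data(df, where = "generated dataset")
}

.group_stats <- function(data, group, recruitment = NULL) {
  sel <- data$Group == group
  if (!is.null(recruitment)) sel <- sel & data$Recruitment %in% recruitment
  y <- data$Response[sel]
  list(mean = if (length(y)) mean(y) else NA_real_, n = length(y))
}

#' Summarize a trial dataset into group means and counts
#'
#' @param data A `fiu_data`.
#' @return A [group_summary()] with stage-1 and (if further-recruited
#'   patients are present) full-data entries.
#' @export
summarize_trial_data <- function(data) {
  data <- .as_trial_data(as.data.frame(data))
  h <- .group_stats(data, "H")
  e1 <- .group_stats(data, "E", "initial")
  c1 <- .group_stats(data, "C", "initial")
  e_all <- .group_stats(data, "E", c("initial", "further"))
  c_all <- .group_stats(data, "C", c("initial", "further"))
  has_stage2 <- any(data$Recruitment == "further")
  group_summary(mean_e = e1$mean, mean_c = c1$mean, mean_h = h$mean,
                n_e = e1$n, n_c = c1$n, n_h = h$n,
                mean_e2 = if (has_stage2) e_all$mean else NA_real_,
                mean_c2 = if (has_stage2) c_all$mean else NA_real_,
                n_e2_total = if (has_stage2) e_all$n else 0L,
                n_c2_total = if (has_stage2) c_all$n else 0L)
}

#' Run one analysis step of the fill-it-up workflow
#'
#' `"pretest"` runs the equivalence pre-test of historical versus initially
#' randomized controls; `"s1"` runs the pooled superiority test with the
#' optimal weight (warning if the pre-test on the same data did not reject);
#' `"s2"` runs the full-data superiority test on all randomized patients,
#' discarding the historical controls. The attached report states the
#' information fractions contributed by randomized versus historical
#' patients, in percent.
#'
#' @param data A `fiu_data`.
#' @param design A [fiu_design()] with its margin set (pre-test step).
#' @param step `"pretest"`, `"s1"` or `"s2"`.
#' @return The `fiu_test` of the step, with a `report` attribute (character)
#'   and an `information` attribute (named fractions).
#' @export
analyze_step <- function(data, design, step = c("pretest", "s1", "s2")) {
  step <- match.arg(step)
  stopifnot(inherits(design, "fiu_design"))
  summ <- summarize_trial_data(data)
  if (step == "pretest") {
    if (is.null(design$margin))
      stop("the design's equivalence margin must be set for the pre-test",
           call. = FALSE)
    res <- z_ept(summ, design$margin, design$alpha_ept)
    info <- c(historical = summ$n_h / (summ$n_h + summ$n_c),
              randomized = summ$n_c / (summ$n_h + summ$n_c))
    rep_txt <- sprintf(
      "Equivalence pre-test on %d randomized vs %d historical controls (margin %.4g): Z = %.4f, %s. Control information: %.1f%% historical, %.1f%% randomized.",
      summ$n_c, summ$n_h, design$margin, res$statistic,
      if (res$reject == 1L) "equivalence established" else "equivalence not established",
      100 * info[["historical"]], 100 * info[["randomized"]])
  } else if (step == "s1") {
    if (summ$n_h < 1) stop("no historical controls in the dataset", call. = FALSE)
    if (!is.null(design$margin)) {
      pre <- z_ept(summ, design$margin, design$alpha_ept)
      if (pre$reject != 1L)
        warning("protocol violation: pooled test requested although the pre-test does not reject",
                call. = FALSE)
    }
    res <- z_s1(summ, alpha_s1 = design$alpha_s1)
    info <- c(historical = summ$n_h / (summ$n_h + summ$n_c),
              randomized = summ$n_c / (summ$n_h + summ$n_c))
    rep_txt <- sprintf(
      "Pooled superiority test (weight %.4f) of %d experimental patients vs %d pooled controls: Z = %.4f, %s. Control information: %.1f%% historical, %.1f%% randomized.",
      res$weight, summ$n_e, summ$n_h + summ$n_c, res$statistic,
      if (res$reject == 1L) "superiority shown" else "superiority not shown",
      100 * info[["historical"]], 100 * info[["randomized"]])
  } else {
    if (summ$n_e2_total < 1 || summ$n_c2_total < 1)
      stop("stage-2 analysis requires further-recruited patients", call. = FALSE)
    res <- z_s2(summ, alpha_s2 = design$alpha_s2)
    info <- c(historical = 0, randomized = 1)
    rep_txt <- sprintf(
      "Full-data superiority test on %d vs %d randomized patients (historical controls discarded): Z = %.4f, %s. Control information: 100.0%% randomized.",
      summ$n_e2_total, summ$n_c2_total, res$statistic,
      if (res$reject == 1L) "superiority shown" else "superiority not shown")
  }
  attr(res, "report") <- rep_txt
  attr(res, "information") <- info
  res
}

#' Full fill-it-up analysis of a patient-level dataset
#'
#' Runs the pre-test and then the branch the procedure prescribes (pooled
#' test after a successful pre-test; otherwise the full-data test, which
#' requires the further-recruited patients to be present).
#'
#' @param data A `fiu_data`.
#' @param design A [fiu_design()] with margin set.
#' @return List with the overall `decision` (0/1), the `branch`, the
#'   component `fiu_test`s and the step reports.
#' @export
analyze_trial <- function(data, design) {
  ept <- analyze_step(data, design, "pretest")
  if (ept$reject == 1L) {
    s1 <- analyze_step(data, design, "s1")
    dec <- decide_fill_it_up(ept, s1 = s1)
    return(list(decision = dec, branch = "S1",
                tests = list(ept = ept, s1 = s1),
                reports = c(attr(ept, "report"), attr(s1, "report"))))
  }
  s2 <- analyze_step(data, design, "s2")
  dec <- decide_fill_it_up(ept, s2 = s2)
  list(decision = dec, branch = "S2", tests = list(ept = ept, s2 = s2),
       reports = c(attr(ept, "report"), attr(s2, "report")))
}
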