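#' Shapiro-Wilk normality gate
#'
#' @param values Numeric vector, n >= 3, non-constant.
#' @param alpha Flagging level.
#' @return List with `W`, `p` and `normal` (TRUE if p >= alpha). Non-normal
#'   arms are reported, not auto-switched to a different test.
#' @export
normality_check <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("normality check requires n >= 3")
  if (stats::sd(values) == 0) stop("degenerate (constant) sample")
  s <- stats::shapiro.test(values)
  list(W = unname(s$statistic), p = s$p.value, normal = s$p.value >= alpha)
}

#' Compare a reference and a comparison arm with the study's t-tests
#'
#' Two designs: `unpaired_two_tailed` (different subjects, classic pooled-
#' variance Student's t-test; Welch available via `var_equal = FALSE`) and
#' `paired_one_tailed` (same subjects at two time points; equal lengths, and
#' matching subject keys if supplied). Percent difference is
#' `100 * (comparison - reference) / reference` on the arm means. No
#' multiple-testing correction is applied (none was used across the 60
#' ROIs); callers can post-correct using the number of tests they ran.
#'
#' @param reference,comparison Numeric vectors (e.g. AGA and FGR arms, or
#'   initial and final acquisitions).
#' @param design Test design.
#' @param alternative One-tailed direction for the paired design, on
#'   `comparison - reference` (default `"greater"`: accumulation).
#' @param var_equal Pooled variance (TRUE, Student) or Welch.
#' @param subjects_reference,subjects_comparison Optional pairing keys; they
#'   must match element-wise for the paired design.
#' @param alpha Significance level (0.05).
#' @param variable,tissue,group Optional labels carried into the result.
#' @return One-row data frame of class `comparison_result`.
#' @export
compare_groups <- function(reference, comparison,
                           design = c("unpaired_two_tailed", "paired_one_tailed"),
                           alternative = "greater", var_equal = TRUE,
                           subjects_reference = NULL, subjects_comparison = NULL,
                           alpha = 0.05, variable = NA_character_,
                           tissue = NA_character_, group = NA_character_) {
  design <- match.arg(design)
  if (length(reference) < 2 || length(comparison) < 2) stop("each arm needs n >= 2")
  if (design == "paired_one_tailed") {
    if (length(reference) != length(comparison)) {
      stop("paired design requires equal arm lengths")
    }
    if (!is.null(subjects_reference) || !is.null(subjects_comparison)) {
      if (!identical(subjects_reference, subjects_comparison)) {
        stop("mismatched pairing keys")
      }
    }
    tt <- stats::t.test(comparison, reference, paired = TRUE,
                        alternative = alternative)
  } else {
    tt <- stats::t.test(comparison, reference, var.equal = var_equal,
                        alternative = "two.sided")
  }
  sw <- function(v) if (length(v) >= 3 && stats::sd(v) > 0)
    stats::shapiro.test(v)$p.value else NA_real_
  m_ref <- mean(reference); m_cmp <- mean(comparison)
  out <- data.frame(
    variable = variable, tissue = tissue, group = group, design = design,
    n_reference = length(reference), n_comparison = length(comparison),
    mean_reference = m_ref, sd_reference = stats::sd(reference),
    mean_comparison = m_cmp, sd_comparison = stats::sd(comparison),
    percent_difference = 100 * (m_cmp - m_ref) / m_ref,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    normality_p_reference = sw(reference),
    normality_p_comparison = sw(comparison),
    significant = tt$p.value < alpha,
    stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Two-sample pooled-variance t-test from printed summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Arm summaries.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Linear HRMAS time-drift fit
#'
#' Ordinary least squares of area against acquisition time.
#'
#' @param t_h Acquisition times (hours); >= 3 points spanning > 1 h.
#' @param area Areas at those times.
#' @param metabolite Optional label.
#' @return List of class `drift_fit`: `slope` (a.u./h), `intercept`, `r2`,
#'   `duration_h`, `n`.
#' @export
fit_drift <- function(t_h, area, metabolite = NA_character_) {
  if (length(t_h) < 3) stop("drift fit requires >= 3 time points")
  if (diff(range(t_h)) <= 1) stop("time axis degenerate (span must exceed 1 h)")
  fit <- stats::lm(area ~ t_h)
  ss_tot <- sum((area - mean(area))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(metabolite = metabolite,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, duration_h = diff(range(t_h)), n = length(t_h)),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("<drift_fit> %s: slope %.4g a.u./h over %.1f h (R2 = %.3f, n = %d)\n",
              x$metabolite, x$slope, x$duration_h, x$r2, x$n))
  invisible(x)
}

#' Initial-versus-final CPMG comparison (HRMAS accumulation)
#'
#' Pairs the initial and final quantification tables by sample and variable
#' and runs a paired one-tailed test per variable in the accumulation
#' direction (final >= initial). Samples present in only one table are
#' excluded with a warning.
#'
#' @param initial,final Data frames with columns `sample_id`, `variable`,
#'   `value` (e.g. per-sample CPMG areas at session start and end).
#' @return List with `comparisons` (one `comparison_result` row per
#'   variable) and `differences` (per-sample final - initial table).
#' @export
initial_vs_final <- function(initial, final) {
  key_i <- paste(initial$sample_id, initial$variable)
  key_f <- paste(final$sample_id, final$variable)
  common <- intersect(key_i, key_f)
  dropped <- union(setdiff(key_i, key_f), setdiff(key_f, key_i))
  if (length(dropped)) {
    warning("unmatched sample/variable pairs excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) " ...")
  }
  ini <- initial[match(common, key_i), ]
  fin <- final[match(common, key_f), ]
  diffs <- data.frame(sample_id = ini$sample_id, variable = ini$variable,
                      initial = ini$value, final = fin$value,
                      difference = fin$value - ini$value,
                      stringsAsFactors = FALSE)
  comps <- lapply(split(seq_len(nrow(diffs)), diffs$variable), function(idx) {
    d <- diffs[idx, ]
    if (nrow(d) < 2) return(NULL)
    compare_groups(d$initial, d$final, design = "paired_one_tailed",
                   alternative = "greater",
                   subjects_reference = d$sample_id,
                   subjects_comparison = d$sample_id,
                   variable = d$variable[1])
  })
  comps <- do.call(rbind, comps[!vapply(comps, is.null, logical(1))])
  rownames(comps) <- NULL
  list(comparisons = comps, differences = diffs)
}
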