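#' Positional 13C enrichment relative to the non-infused control group
#'
#' Enrichment is computed from normalized ROI integrals as
#' `(I_infused - I_control) / I_control`, i.e. the labeled excess expressed
#' relative to the 1.1% natural-abundance signal measured in the CTR group,
#' so the positional enrichment in percent is `1.1 x` that ratio. For
#' 1-13C-glucose the de-novo pool is only 50% labeled (glycolytic C1/C6
#' symmetry), so the total de-novo percentage applies a correction factor of
#' 2; for 2-13C-acetate the factor is 1.
#'
#' @param i_inf Normalized ROI volume of the infused sample.
#' @param i_ctr_mean CTR-group mean normalized volume for the same ROI and
#'   tissue; must be positive.
#' @param substrate `"glc_1_13C"` or `"ace_2_13C"`.
#' @param natural_abundance_pct Natural abundance in percent (1.1).
#' @return Data frame (one row) with `ratio_excess`,
#'   `positional_enrichment_pct` and `denovo_total_pct`.
#' @export
positional_enrichment <- function(i_inf, i_ctr_mean,
                                  substrate = c("glc_1_13C", "ace_2_13C"),
                                  natural_abundance_pct = 1.1) {
  substrate <- match.arg(substrate)
  if (any(i_ctr_mean <= 0)) stop("control mean must be positive (no natural-abundance reference)")
  correction <- if (substrate == "glc_1_13C") 2 else 1
  ratio <- (i_inf - i_ctr_mean) / i_ctr_mean
  pos <- natural_abundance_pct * ratio
  data.frame(i_inf = i_inf, i_ctr_mean = i_ctr_mean, ratio_excess = ratio,
             positional_enrichment_pct = pos, correction = correction,
             denovo_total_pct = correction * pos)
}

#' Glycolytic / TCA-cycle partition of labeled lactate
#'
#' `Lac C3' = Lac C3 - Lac C2` (pyruvate-C3-derived, i.e. glycolytic) and
#' `Lac C2C3 = 2 * Lac C2` (derived from the symmetric malate C2/C3 pool
#' shuttled out of the mitochondria). A negative partition is floored at 0
#' and flagged; the raw difference is kept in `raw_c3_prime` so that the
#' per-sample identity remains available.
#'
#' @param lac_c3_pct,lac_c2_pct Lac C3 and Lac C2 incorporation percentages
#'   (must be >= 0).
#' @param floor Floor a negative partition at zero (default TRUE).
#' @return List with `lac_c3_prime`, `lac_c2c3`, `raw_c3_prime`, `flagged`.
#' @export
lac_partition <- function(lac_c3_pct, lac_c2_pct, floor = TRUE) {
  if (any(c(lac_c3_pct, lac_c2_pct) < 0)) stop("inputs must be >= 0")
  raw <- lac_c3_pct - lac_c2_pct
  list(lac_c3_prime = if (floor) pmax(raw, 0) else raw,
       lac_c2c3 = 2 * lac_c2_pct,
       raw_c3_prime = raw,
       flagged = raw < 0)
}

#' TCA-cycle fraction of total labeling
#'
#' Sum of the Glx isotopomer percentages plus `2 * Lac C2` (the
#' malate-derived lactate pool).
#'
#' @param glx_pcts Named vector containing `Gln C4`, `Glu C4`, `Glu C3`,
#'   `Glu C2` percentages.
#' @param lac_c2_pct Lac C2 percentage.
#' @return TCAc percentage.
#' @export
tcac_fraction <- function(glx_pcts, lac_c2_pct) {
  need <- c("Gln C4", "Glu C4", "Glu C3", "Glu C2")
  missing <- setdiff(need, names(glx_pcts))
  if (length(missing)) stop("missing Glx isotopomer(s): ", paste(missing, collapse = ", "))
  sum(glx_pcts[need]) + 2 * lac_c2_pct
}

#' Per-sample incorporation fractions and the summary incorporation table
#'
#' For each sample the labeled excess of every quantified ROI is
#' `max(I - I_ctr_mean, 0)` and percentages are taken over the quantified
#' set (so they sum to 100 per sample). The summary reports mean +/- SD over
#' samples for the seven headline isotopomers plus the derived rows
#' SUM(Ala+Lac+Glx), Glycolysis (Lac C3') and TCAc (Glx + LacC2C3); derived
#' rows are computed per sample from the exact footnote identities
#' (unfloored, so the identities hold row-wise) and then averaged.
#'
#' @param quant Long quantification table with columns `sample_id`, `roi`,
#'   `norm_area` (one tissue/group cell).
#' @param ctr_means Named vector of CTR-group mean normalized volumes per ROI
#'   (same tissue); must cover the quantified set.
#' @param isotopomer_set ROIs forming the quantified set (percentages sum to
#'   100 over this set).
#' @param table_isotopomers The isotopomers reported as table rows.
#' @return List with `per_sample` (wide data frame of percentages and derived
#'   rows), `summary` (mean/sd per row), and `excluded` (samples with
#'   all-zero excess).
#' @export
incorporation_fractions <- function(quant, ctr_means,
                                    isotopomer_set = c(
                                      "Ala C3", "Lac C3", "Lac C2", "Gln C4",
                                      "Glu C4", "Glu C3", "Glu C2",
                                      "AcCarn CH3", "Mal C2", "Mal C3", "Pyr C3"),
                                    table_isotopomers = c(
                                      "Ala C3", "Lac C3", "Lac C2", "Gln C4",
                                      "Glu C4", "Glu C3", "Glu C2")) {
  missing <- setdiff(isotopomer_set, names(ctr_means))
  if (length(missing)) stop("CTR means missing for: ", paste(missing, collapse = ", "))
  samples <- unique(quant$sample_id)
  rows <- list(); excluded <- character()
  for (s in samples) {
    q <- quant[quant$sample_id == s & quant$roi %in% isotopomer_set, ]
    vols <- stats::setNames(q$norm_area, q$roi)[isotopomer_set]
    excess <- pmax(vols - ctr_means[isotopomer_set], 0)
    tot <- sum(excess, na.rm = TRUE)
    if (!is.finite(tot) || tot <= 0) {
      excluded <- c(excluded, s)
      next
    }
    pct <- 100 * excess / tot
    part <- lac_partition(pct[["Lac C3"]], pct[["Lac C2"]], floor = FALSE)
    row <- c(pct[table_isotopomers],
             SUM = sum(pct[table_isotopomers]),
             Glycolysis = part$lac_c3_prime,
             TCAc = tcac_fraction(pct, pct[["Lac C2"]]))
    rows[[s]] <- data.frame(sample_id = s, t(row), check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(list(per_sample = NULL, summary = NULL, excluded = excluded))
  }
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL
  num <- per_sample[, -1, drop = FALSE]
  summary <- data.frame(row = colnames(num),
                        mean = vapply(num, mean, numeric(1)),
                        sd = vapply(num, stats::sd, numeric(1)),
                        n = nrow(num), row.names = NULL,
                        stringsAsFactors = FALSE)
  list(per_sample = per_sample, summary = summary, excluded = excluded)
}

#' Relative flux ratio estimators (glucose infusion)
#'
#' `pc_over_pdh = (Glu C2 - Glu C3) / Glu C4`: pyruvate carboxylase places
#' pyruvate C3 label on OAA C3 (hence Glu C2) without passing the symmetric
#' succinate step, while cycle carbon arrives symmetrized, so the C2-C3
#' asymmetry normalized by the acetyl-CoA-derived C4 label estimates the
#' anaplerotic fraction. `pc_over_me` divides the same PC proxy by the
#' malic-enzyme proxy `Lac C2C3 = 2 * Lac C2` (malate-derived lactate). Both
#' formulas are returned as metadata so results are auditable; they estimate
#' flux relative to the citrate synthase flux and are validated against the
#' propagation model.
#'
#' @param enrichments Named vector with `Glu C2`, `Glu C3`, `Glu C4` and
#'   `Lac C2` positional enrichments (or excess fractions).
#' @return List with `pc_over_pdh`, `pc_over_me`, `flagged`, `formulas`.
#' @export
flux_ratios <- function(enrichments) {
  need <- c("Glu C2", "Glu C3", "Glu C4", "Lac C2")
  missing <- setdiff(need, names(enrichments))
  if (length(missing)) stop("missing enrichment(s): ", paste(missing, collapse = ", "))
  e <- enrichments
  asym <- e[["Glu C2"]] - e[["Glu C3"]]
  flagged <- FALSE
  if (e[["Glu C4"]] <= 0) {
    pc_pdh <- NA_real_; flagged <- TRUE
  } else {
    pc_pdh <- asym / e[["Glu C4"]]
  }
  me_proxy <- 2 * e[["Lac C2"]]
  pc_me <- if (me_proxy > 0) asym / me_proxy else NA_real_
  list(pc_over_pdh = unname(pc_pdh), pc_over_me = unname(pc_me),
       flagged = flagged,
       formulas = c(pc_over_pdh = "(GluC2 - GluC3) / GluC4",
                    pc_over_me = "(GluC2 - GluC3) / (2 * LacC2)"))
}

#' Glutamine synthetase relative activity
#'
#' Primary estimator `Gln C4 / Glu C4` (label transfer efficiency from the
#' glutamate to the glutamine pool); the alternative compositional form
#' `Gln C4 / (Gln C4 + Glu C4)` is reported alongside.
#'
#' @param gln_c4,glu_c4 Gln C4 and Glu C4 labeled levels (same units).
#' @return List with `ratio`, `ratio_compositional`, `flagged`.
#' @export
gs_relative_activity <- function(gln_c4, glu_c4) {
  if (any(glu_c4 <= 0)) {
    return(list(ratio = NA_real_, ratio_compositional = NA_real_, flagged = TRUE))
  }
  list(ratio = gln_c4 / glu_c4,
       ratio_compositional = gln_c4 / (gln_c4 + glu_c4),
       flagged = FALSE)
}

#' Total and labeled lactate pools from the CPMG deconvolution
#'
#' The labeled pool is estimated as twice the right satellite (only the right
#' satellite is fitted; the left overlaps alanine) and the total pool as the
#' parent CH3 doublet plus the labeled pool.
#'
#' @param deconv Result of [deconvolve_lactate()].
#' @return List with `lac_13c`, `lac_total`, `flagged`.
#' @export
pools_from_cpmg <- function(deconv) {
  lac13 <- 2 * deconv$lac_13ch3_right
  list(lac_13c = lac13,
       lac_total = deconv$lac_ch3 + lac13,
       flagged = isTRUE(deconv$flagged))
}
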