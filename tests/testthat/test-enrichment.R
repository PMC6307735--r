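test_that("positional enrichment applies the 50%-labeling correction for glucose", {
  # 2.4% positional -> 4.8% total de novo; 8% -> 16%
  for (target in c(2.4, 8)) {
    i_inf <- 1 + target / 1.1      # control mean 1
    rec <- positional_enrichment(i_inf, 1, "glc_1_13C")
    expect_equal(rec$positional_enrichment_pct, target, tolerance = 1e-9)
    expect_equal(rec$denovo_total_pct, 2 * target, tolerance = 1e-9)
  }
  ace <- positional_enrichment(3, 1, "ace_2_13C")
  expect_equal(ace$denovo_total_pct, ace$positional_enrichment_pct)
  expect_equal(positional_enrichment(1, 1, "glc_1_13C")$positional_enrichment_pct, 0)
  expect_error(positional_enrichment(1, 0, "glc_1_13C"), "positive")
  # ratio-based: invariant to common rescaling of all spectra
  a <- positional_enrichment(3.2, 1.1, "ace_2_13C")
  b <- positional_enrichment(3.2 * 7, 1.1 * 7, "ace_2_13C")
  expect_equal(a$positional_enrichment_pct, b$positional_enrichment_pct)
})

test_that("lactate partition follows the footnote identities with flooring flags", {
  p <- lac_partition(12.1, 11.1)
  expect_equal(p$lac_c3_prime, 1.0, tolerance = 1e-9)
  expect_equal(p$lac_c2c3, 22.2, tolerance = 1e-9)
  p2 <- lac_partition(3.7, 2.4)
  expect_equal(p2$lac_c3_prime, 1.3, tolerance = 1e-9)
  expect_equal(p2$lac_c2c3, 4.8, tolerance = 1e-9)
  p3 <- lac_partition(5, 0)
  expect_equal(p3$lac_c3_prime, 5)
  expect_equal(p3$lac_c2c3, 0)
  neg <- lac_partition(1, 2)
  expect_equal(neg$lac_c3_prime, 0)
  expect_equal(neg$raw_c3_prime, -1)
  expect_true(neg$flagged)
  expect_error(lac_partition(-1, 0), ">= 0")
})

test_that("the TCAc fraction sums Glx and the malate-derived lactate", {
  glx <- c("Gln C4" = 1.0, "Glu C4" = 10.8, "Glu C3" = 3.8, "Glu C2" = 5.0)
  expect_equal(tcac_fraction(glx, 0.9), 22.4, tolerance = 1e-9)
  expect_equal(tcac_fraction(glx * 0, 0), 0)
  expect_error(tcac_fraction(glx[-1], 0.9), "Gln C4")
})

test_that("incorporation percentages sum to 100 and obey the derived-row identities per sample", {
  set.seed(41)
  rois <- c("Ala C3", "Lac C3", "Lac C2", "Gln C4", "Glu C4", "Glu C3",
            "Glu C2", "AcCarn CH3", "Mal C2", "Mal C3", "Pyr C3")
  ctr <- stats::setNames(rep(1, length(rois)), rois)
  quant <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(sample_id = paste0("s", i), roi = rois,
               norm_area = 1 + stats::runif(length(rois), 0, 2))
  }))
  inc <- incorporation_fractions(quant, ctr)
  ps <- inc$per_sample
  seven <- c("Ala C3", "Lac C3", "Lac C2", "Gln C4", "Glu C4", "Glu C3", "Glu C2")
  for (i in seq_len(nrow(ps))) {
    expect_equal(ps$SUM[i], sum(as.numeric(ps[i, seven])), tolerance = 1e-9)
    expect_equal(ps$Glycolysis[i], ps[["Lac C3"]][i] - ps[["Lac C2"]][i],
                 tolerance = 1e-9)
    expect_equal(ps$TCAc[i],
                 sum(as.numeric(ps[i, c("Gln C4", "Glu C4", "Glu C3", "Glu C2")])) +
                   2 * ps[["Lac C2"]][i], tolerance = 1e-9)
  }
  # full-set percentages sum to 100: SUM + remainder rows
  rest <- c("AcCarn CH3", "Mal C2", "Mal C3", "Pyr C3")
  quant_w <- quant[quant$sample_id == "s1", ]
  excess <- quant_w$norm_area - 1
  expect_equal(ps$SUM[1] + 100 * sum(excess[quant_w$roi %in% rest]) / sum(excess),
               100, tolerance = 1e-9)
})

test_that("a single labeled isotopomer takes 100% and all-zero excess is excluded", {
  rois <- c("Ala C3", "Lac C3", "Lac C2", "Gln C4", "Glu C4", "Glu C3",
            "Glu C2", "AcCarn CH3", "Mal C2", "Mal C3", "Pyr C3")
  ctr <- stats::setNames(rep(1, length(rois)), rois)
  one <- data.frame(sample_id = "s1", roi = rois,
                    norm_area = ifelse(rois == "Gln C4", 2, 1))
  inc <- incorporation_fractions(one, ctr)
  expect_equal(inc$per_sample[["Gln C4"]], 100)
  flat <- data.frame(sample_id = "s2", roi = rois, norm_area = rep(1, length(rois)))
  inc2 <- incorporation_fractions(flat, ctr)
  expect_equal(inc2$excluded, "s2")
  expect_null(inc2$per_sample)
  expect_error(incorporation_fractions(one, ctr[-1]), "CTR means missing")
})

test_that("the PC/PDH estimator is monotone and recovers the flux ratio without back-exchange", {
  ests <- vapply(c(0.1, 0.2, 0.4), function(r) {
    p <- propagate("glc_1_13C",
                   flux_params(pc = r, me = 0, dilution_unlabeled = 0,
                               scrambling = 0, glu_turnover = 1))
    flux_ratios(profile_fractions(p)[c("Glu C2", "Glu C3", "Glu C4",
                                       "Lac C2")])$pc_over_pdh
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
  expect_equal(ests[2], 0.2, tolerance = 0.2)
  # no PC: no C2/C3 asymmetry
  p0 <- propagate("glc_1_13C", flux_params(pc = 0, scrambling = 0))
  e0 <- flux_ratios(profile_fractions(p0)[c("Glu C2", "Glu C3", "Glu C4",
                                            "Lac C2")])
  expect_equal(e0$pc_over_pdh, 0, tolerance = 1e-6)
  expect_error(flux_ratios(c("Glu C2" = 1)), "missing enrichment")
  flagged <- flux_ratios(c("Glu C2" = 1, "Glu C3" = 0.5, "Glu C4" = 0,
                           "Lac C2" = 0.2))
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$pc_over_pdh))
  expect_match(e0$formulas[["pc_over_pdh"]], "GluC2")
  # default glucose brain calibration keeps the anaplerotic read-out in the
  # 0.1-0.3 band reported for control fetal brains
  pdef <- propagate("glc_1_13C", default_flux_params("glc_1_13C", "brain_cortex"))
  edef <- flux_ratios(profile_fractions(pdef)[c("Glu C2", "Glu C3", "Glu C4",
                                                "Lac C2")])
  expect_gt(edef$pc_over_pdh, 0.1)
  expect_lt(edef$pc_over_pdh, 0.3)
})

test_that("GS relative activity reproduces the printed-mean ratio and scales with the effect", {
  expect_equal(gs_relative_activity(14.6, 17.0)$ratio, 0.8588, tolerance = 1e-3)
  expect_equal(gs_relative_activity(0, 10)$ratio, 0)
  expect_true(gs_relative_activity(1, 0)$flagged)
  base <- gs_relative_activity(10, 20)$ratio
  scaled <- gs_relative_activity(10 * 0.77, 20)$ratio
  expect_equal(scaled / base, 0.77, tolerance = 1e-9)
})

test_that("lactate pool arithmetic from the deconvolution is exact", {
  fake <- list(lac_ch3 = 90, lac_13ch3_right = 5, flagged = FALSE)
  p <- pools_from_cpmg(fake)
  expect_equal(p$lac_13c, 10)
  expect_equal(p$lac_total, 100)
  expect_false(p$flagged)
  fake$lac_13ch3_right <- 0
  expect_equal(pools_from_cpmg(fake)$lac_total, fake$lac_ch3)
  fake$flagged <- TRUE
  expect_true(pools_from_cpmg(fake)$flagged)
})

test_that("CTR samples pass through quantification to enrichment compatible with zero", {
  tm <- default_roi_template()
  sams <- lapply(1:6, function(i) quick_sample(paste0("ctr", i), "CTR"))
  quants <- lapply(seq_along(sams), function(i) {
    st <- assign_true_state(sams[[i]], seed = 500 + i)
    set.seed(900 + i)
    integrate_roi(render_hsqc(st, tm, noise_sd = 3,
                              scale = sams[[i]]$net_tissue_weight_mg),
                  tm, sams[[i]])
  })
  q <- do.call(rbind, quants)
  rois <- c("Lac C3", "Lac C2", "Glu C4", "Gln C4")
  ctr_mean <- tapply(q$norm_area, q$roi, mean)
  for (r in rois) {
    e <- positional_enrichment(q$norm_area[q$roi == r], ctr_mean[[r]],
                               "ace_2_13C")
    se <- stats::sd(e$positional_enrichment_pct) / sqrt(nrow(e))
    expect_lt(abs(mean(e$positional_enrichment_pct)), 3 * se + 1e-9)
  }
})
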