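test_that("ROI integration recovers rendered HSQC volumes within 2% at zero noise", {
  sm <- quick_sample()
  st <- assign_true_state(sm, seed = 31)
  tm <- default_roi_template()
  q <- integrate_roi(render_hsqc(st, tm, noise_sd = 0, scale = sm$net_tissue_weight_mg),
                     tm, sm)
  truth <- st$pools * st$labeled
  met <- tm$name[!tm$is_noise]
  rel <- abs(q$norm_area[match(met, q$roi)] - truth[met]) / truth[met]
  expect_lt(max(rel), 0.02)
})

test_that("ROI integration handles degenerate spectra and out-of-range ROIs", {
  sm <- quick_sample()
  tm <- default_roi_template()
  h <- seq(5.6, 0.5, by = -0.01); cc <- seq(105, 5, by = -0.5)
  zero <- spectrum2d(h, cc, matrix(0, length(h), length(cc)))
  q <- integrate_roi(zero, tm, sm)
  expect_true(all(q$raw_area == 0))
  # ROI beyond the spectral width: missing value plus warning, not failure
  narrow <- spectrum2d(seq(3, 1, by = -0.01), cc,
                       matrix(0, 201, length(cc)))
  wn <- capture_warnings(qn <- integrate_roi(narrow, tm, sm))
  expect_true(any(grepl("outside spectrum", wn)))
  expect_true(any(is.na(qn$raw_area)))
  expect_true(all(qn$flag[is.na(qn$raw_area)] == "outside_spectrum"))
})

test_that("noise regions integrate to zero within 3 SD and low-SNR peaks get flagged", {
  sm <- quick_sample()
  st <- assign_true_state(sm, seed = 32)
  tm <- default_roi_template()
  set.seed(5)
  sp <- render_hsqc(st, tm, noise_sd = 4, scale = sm$net_tissue_weight_mg)
  q <- integrate_roi(sp, tm, sm)
  noise_rows <- q[q$roi %in% tm$name[tm$is_noise], ]
  cell <- 0.004 * 0.2
  n_px <- round(0.08 / 0.004) * round(2 / 0.2)
  n_border <- 2 * (round(0.08 / 0.004) + round(2 / 0.2)) - 4
  # variance of the sum plus the subtracted border-median plane
  sd_vol <- 4 * cell * sqrt(n_px + (pi / 2) * n_px^2 / n_border)
  expect_true(all(abs(noise_rows$raw_area) < 3.5 * sd_vol))
  # drown a weak peak in noise: kept but flagged
  st$pools[["Fum C2C3"]] <- 1e-4
  set.seed(6)
  q2 <- integrate_roi(render_hsqc(st, tm, noise_sd = 4), tm, sm)
  expect_equal(q2$flag[q2$roi == "Fum C2C3"], "low_snr")
})

test_that("lactate deconvolution recovers the labeled fraction within 1% at zero noise", {
  st <- assign_true_state(quick_sample(), seed = 33)
  sp <- render_cpmg(st, noise_sd = 0)
  dv <- deconvolve_lactate(sp)
  f <- st$labeled[["Lac C3"]]
  est <- dv$lac_13ch3_right / (dv$lac_ch3 + 2 * dv$lac_13ch3_right)
  expect_equal(est, f / 2, tolerance = 0.01)
  expect_true(dv$converged)
  expect_false(dv$flagged)
  # total labeled pool is reported as twice the right satellite
  p <- pools_from_cpmg(dv)
  expect_equal(p$lac_13c, 2 * dv$lac_13ch3_right)
  expect_equal(p$lac_total, dv$lac_ch3 + p$lac_13c)
  expect_equal(p$lac_total, st$pools[["Lac C3"]], tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("deconvolution is unbiased over noisy replicates", {
  st <- assign_true_state(quick_sample(), seed = 34)
  f <- st$labeled[["Lac C3"]]
  set.seed(77)
  errs <- replicate(40, {
    sp <- render_cpmg(st, noise_sd = 20, scale = 50)
    d <- deconvolve_lactate(sp)
    d$lac_13ch3_right / (d$lac_ch3 + 2 * d$lac_13ch3_right) - f / 2
  })
  expect_lt(abs(mean(errs)), 3 * stats::sd(errs) / sqrt(length(errs)) + 1e-6)
})

test_that("unlabeled lactate yields a vanishing satellite area", {
  st <- assign_true_state(quick_sample(group = "CTR"), seed = 35)
  st$labeled[["Lac C3"]] <- 0
  dv <- deconvolve_lactate(render_cpmg(st, noise_sd = 0))
  expect_lt(dv$lac_13ch3_right, 1e-3 * dv$lac_ch3)
})

test_that("glutamine integration matches the in-window analytic area and excludes succinate", {
  st <- assign_true_state(quick_sample(), seed = 36)
  sp <- render_cpmg(st, noise_sd = 0)
  got <- integrate_glutamine(sp)
  A <- st$pools[["Gln C4"]]
  fw <- 1.5 / 400.13
  truth <- (A / 2) * (oracle_lorentz_window(2.42, 2.48, 2.445, fw) +
                        oracle_lorentz_window(2.42, 2.48, 2.455, fw))
  expect_equal(got, truth, tolerance = 0.03, ignore_attr = TRUE)
  # succinate alone contributes almost nothing inside 2.48-2.42
  st2 <- st
  st2$pools[setdiff(names(st2$pools), "Succ C2C3")] <- 0
  st2$labeled[] <- 0.011
  sp2 <- render_cpmg(st2, noise_sd = 0, mm_areas = c(0, 0))
  expect_lt(abs(integrate_glutamine(sp2)), 0.06 * st2$pools[["Succ C2C3"]])
  # flat spectrum integrates to zero; truncated window errors
  flat <- spectrum1d(seq(2.6, 1.0, by = -5e-4), rep(0, 3201))
  expect_equal(integrate_glutamine(flat), 0)
  short <- spectrum1d(seq(2.45, 1.0, by = -5e-4),
                      rep(0, length(seq(2.45, 1.0, by = -5e-4))))
  expect_error(integrate_glutamine(short), "truncated")
})

test_that("31P quantification recovers brain pools within 3% and flags PC in heart", {
  smb <- quick_sample(tissue = "brain_cortex")
  stb <- assign_true_state(smb, seed = 37)
  qb <- quantify_p31(render_p31(stb, noise_sd = 0), "brain_cortex")
  for (nm in c("PE", "PC", "GPE", "GPC", "Pi")) {
    expect_equal(qb$areas[[nm]], stb$p31_pools[[nm]], tolerance = 0.03,
                 label = nm)
  }
  smh <- quick_sample(tissue = "heart_apex")
  sth <- assign_true_state(smh, seed = 38)
  qh <- quantify_p31(render_p31(sth, noise_sd = 0), "heart_apex")
  expect_true(is.na(qh$areas[["PC"]]))
  expect_equal(qh$areas[["GPE"]], sth$p31_pools[["GPE"]], tolerance = 0.03)
  # undetectable GPE reference: cannot reference the spectrum
  sth0 <- sth
  sth0$p31_pools[] <- 0
  expect_error(quantify_p31(render_p31(sth0, noise_sd = 0), "heart_apex"),
               "GPE reference")
})

test_that("FGR and CTR hearts carry ~1.5x the AGA phosphodiester signal at default effects", {
  ratios <- vapply(1:20, function(i) {
    a <- assign_true_state(quick_sample("a", "ACE", "AGA", "heart_apex"),
                           seed = 100 + i)
    f <- assign_true_state(quick_sample("f", "ACE", "FGR", "heart_apex"),
                           seed = 200 + i)
    qa <- quantify_p31(render_p31(a, noise_sd = 0), "heart_apex")
    qf <- quantify_p31(render_p31(f, noise_sd = 0), "heart_apex")
    sum(qf$areas[c("GPE", "GPC")]) / sum(qa$areas[c("GPE", "GPC")])
  }, numeric(1))
  expect_equal(mean(ratios), 1.5, tolerance = 0.1)
})

test_that("the pH estimator has the Henderson-Hasselbalch properties", {
  cal <- p31_calibration()
  mid <- (cal$delta_acid + cal$delta_base) / 2
  expect_equal(estimate_ph(mid), cal$pka)
  d <- seq(cal$delta_acid + 0.05, cal$delta_base - 0.05, length.out = 50)
  expect_true(all(diff(vapply(d, estimate_ph, numeric(1))) > 0))
  expect_error(estimate_ph(cal$delta_acid - 0.1), "titration")
  expect_error(estimate_ph(cal$delta_base + 0.1), "titration")
  expect_error(pi_shift_from_ph(5.0), "titration")
})

test_that("weight normalization is exact and invariant to doubled tissue", {
  sm <- quick_sample(net_mg = 50)
  expect_equal(normalize_to_weight(100, quick_sample(net_mg = 50)), 2.0)
  expect_equal(normalize_to_weight(100, sm),
               normalize_to_weight(200, quick_sample(net_mg = 100)))
  expect_error(normalize_to_weight(1, quick_sample(net_mg = NA)), "weight")
  bad <- quick_sample(); bad$net_tissue_weight_mg <- 0
  expect_error(normalize_to_weight(1, bad), "positive")
})

test_that("ROI integration is additive over disjoint ROIs and baseline-invariant", {
  sm <- quick_sample()
  st <- assign_true_state(sm, seed = 39)
  tm <- default_roi_template()
  sp <- render_hsqc(st, tm, noise_sd = 0)
  q1 <- integrate_roi(sp, tm, sm)
  sp2 <- sp
  sp2$intensity <- sp2$intensity + 7.5   # constant offset
  q2 <- integrate_roi(sp2, tm, sm)
  expect_equal(q2$raw_area, q1$raw_area, tolerance = 1e-8)
})
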