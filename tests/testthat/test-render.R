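test_that("true states encode the design: CTR at natural abundance, FGR effects applied", {
  ctr <- assign_true_state(quick_sample("c1", group = "CTR"), seed = 1)
  expect_true(all(ctr$labeled == 0.011))
  aga <- assign_true_state(quick_sample("a1", group = "ACE", horn = "AGA"), seed = 2)
  expect_gt(aga$labeled[["Gln C4"]], 0.011)
  expect_error(
    assign_true_state(quick_sample("x", group = "ACE", horn = "FGR"),
                      effects = effect_spec(labeled_factors = list(
                        ACE = list(brain_cortex = c("NotAMetab C9" = 0.5)),
                        GLC = list())), seed = 3),
    "unknown metabolite key")
  # multiplicative FGR factor acts on the labeled excess in expectation
  eff <- effect_spec(cv_excess = c("Lac C2" = 0), cv_excess_default = 0,
                     cv_pool = 0)
  a <- assign_true_state(quick_sample("a", "ACE", "AGA"), effects = eff, seed = 4)
  f <- assign_true_state(quick_sample("f", "ACE", "FGR"), effects = eff, seed = 5)
  expect_equal((f$labeled[["Lac C2"]] - 0.011) / (a$labeled[["Lac C2"]] - 0.011),
               0.77, tolerance = 1e-9)
  # all-unity factors make the horns exchangeable
  eff1 <- effect_spec(labeled_factors = list(ACE = list(), GLC = list()),
                      cv_excess = c("Lac C2" = 0), cv_excess_default = 0,
                      cv_pool = 0)
  a1 <- assign_true_state(quick_sample("a", "ACE", "AGA"), effects = eff1, seed = 6)
  f1 <- assign_true_state(quick_sample("f", "ACE", "FGR"), effects = eff1, seed = 7)
  expect_equal(a1$labeled, f1$labeled)
})

test_that("CPMG renders lactate satellites with area fraction f/2 of the methyl total", {
  st <- assign_true_state(quick_sample(), seed = 42)
  st0 <- st
  st0$labeled[["Lac C3"]] <- 0
  sp <- render_cpmg(st, noise_sd = 0)
  sp0 <- render_cpmg(st0, noise_sd = 0)
  f <- st$labeled[["Lac C3"]]
  # right satellite isolated as the difference from the unlabeled render,
  # integrated on the grid; the oracle integrates the peak model numerically
  # over the same window (satellite doublet minus the parent-area deficit)
  sat_c <- 1.32 - 0.5 * 127 / 400.13
  sat_lo <- sat_c - 0.03; sat_hi <- sat_c + 0.03
  sel <- sp$ppm >= sat_lo & sp$ppm <= sat_hi
  step <- abs(diff(sp$ppm[1:2]))
  sat_area <- sum((sp$intensity - sp0$intensity)[sel]) * step
  pool <- st$pools[["Lac C3"]]
  jhh <- 6.9 / 400.13; fw <- 1.5 / 400.13
  win <- function(center, area) {
    (area / 2) * (oracle_lorentz_window(sat_lo, sat_hi, center - jhh / 2, fw) +
                    oracle_lorentz_window(sat_lo, sat_hi, center + jhh / 2, fw))
  }
  expected <- win(sat_c, pool * f / 2) +          # right satellite
    win(1.32, -pool * f) +                        # parent pool deficit tail
    win(1.32 + 0.5 * 127 / 400.13, pool * f / 2)  # left satellite tail
  expect_equal(sat_area, expected, tolerance = 0.01)
  # and the in-window expectation is itself f/2 of the methyl total within 5%
  expect_equal(sat_area / (pool * f / 2), 1, tolerance = 0.05)
})

test_that("drift accumulates glutamine linearly with acquisition time", {
  st <- assign_true_state(quick_sample(), seed = 8)
  a0 <- integrate_glutamine(render_cpmg(st, noise_sd = 0, t_h = 0))
  a26 <- integrate_glutamine(render_cpmg(st, noise_sd = 0, t_h = 2.6))
  a52 <- integrate_glutamine(render_cpmg(st, noise_sd = 0, t_h = 5.2))
  expect_equal(a52 / a0, 1.10, tolerance = 0.005)   # ~10% over a full session
  expect_equal(a26 - a0, (a52 - a26), tolerance = 1e-6)  # linear
})

test_that("renderers validate their inputs", {
  st <- assign_true_state(quick_sample(), seed = 9)
  expect_error(render_cpmg(st, noise_sd = -1), "noise_sd")
  expect_error(render_cpmg(st, window = c(1.2, 2.6)), "1.14")
  bad <- default_roi_template()
  bad$h_ppm[1] <- 9.0
  bad <- roi_template(as.data.frame(bad))
  expect_error(render_hsqc(st, bad), bad$name[1])
  st$tissue_ph <- 5.0
  expect_error(render_p31(st), "titration")
})

test_that("HSQC volumes are linear in pools and labeled fractions", {
  st <- assign_true_state(quick_sample(group = "CTR"), seed = 10)
  tm <- default_roi_template()
  sm <- quick_sample(group = "CTR")
  q1 <- integrate_roi(render_hsqc(st, tm, noise_sd = 0), tm, sm)
  st2 <- st
  st2$labeled[] <- st$labeled * 2
  q2 <- integrate_roi(render_hsqc(st2, tm, noise_sd = 0), tm, sm)
  met <- !tm$is_noise
  expect_equal(q2$raw_area[match(tm$name[met], q2$roi)],
               2 * q1$raw_area[match(tm$name[met], q1$roi)], tolerance = 1e-6)
  # CTR: every ROI volume proportional to 0.011 * pool
  expect_equal(q1$norm_area[match(tm$name[met], q1$roi)],
               unname(0.011 * st$pools[tm$name[met]]) / sm$net_tissue_weight_mg,
               tolerance = 0.02)
})

test_that("31P rendering encodes pH in the Pi shift and supports zero pools", {
  for (ph_true in c(6.44, 6.35)) {
    st <- assign_true_state(quick_sample(tissue = "heart_apex"), seed = 11)
    st$tissue_ph <- ph_true
    sp <- render_p31(st, noise_sd = 0)
    q <- quantify_p31(sp, "heart_apex")
    expect_equal(estimate_ph(q$pi_shift_ppm + p31_calibration()$gpe_offset),
                 ph_true, tolerance = 0.01)
  }
  st0 <- assign_true_state(quick_sample(), seed = 12)
  st0$p31_pools[] <- 0
  sp0 <- render_p31(st0, noise_sd = 0)
  expect_equal(max(abs(sp0$intensity)), 0)
})

test_that("renderers are deterministic under a fixed seed", {
  st <- assign_true_state(quick_sample(), seed = 13)
  tm <- default_roi_template()
  set.seed(99); a <- render_cpmg(st, noise_sd = 10)
  set.seed(99); b <- render_cpmg(st, noise_sd = 10)
  expect_identical(a, b)
  set.seed(99); h1 <- render_hsqc(st, tm, noise_sd = 3)
  set.seed(99); h2 <- render_hsqc(st, tm, noise_sd = 3)
  expect_identical(h1, h2)
})

test_that("spectra round-trip through their ASCII formats", {
  st <- assign_true_state(quick_sample(), seed = 14)
  sp <- render_p31(st, noise_sd = 0)
  f <- tempfile(fileext = ".txt")
  write_spectrum1d(sp, f)
  back <- read_spectrum1d(f, nucleus = "31P", freq_mhz = sp$freq_mhz)
  expect_equal(back$ppm, sp$ppm, tolerance = 1e-9)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-6)
  tm_full <- default_roi_template()
  keep <- as.data.frame(tm_full)[tm_full$h_ppm > 1.1 & tm_full$h_ppm < 2.5 &
                                   tm_full$c_ppm > 17 & tm_full$c_ppm < 43, ]
  tm <- roi_template(keep[, c("name", "metabolite", "carbon", "h_ppm",
                              "c_ppm", "is_noise")])
  h <- render_hsqc(st, tm, noise_sd = 0, h_range = c(1.0, 2.6),
                   c_range = c(15, 45))
  f2 <- tempfile(fileext = ".txt")
  write_spectrum2d(h, f2)
  back2 <- read_spectrum2d(f2)
  expect_equal(back2$c_ppm, h$c_ppm, tolerance = 1e-6)
  expect_equal(back2$intensity[, 1], h$intensity[, 1],
               tolerance = 1e-6, ignore_attr = TRUE)
  f3 <- tempfile(fileext = ".jdx")
  write_jcamp(sp, f3)
  expect_true(any(grepl("XYDATA", readLines(f3))))
})
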