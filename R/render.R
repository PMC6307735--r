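#' Render a 1D 1H-CPMG spectrum from a ground-truth state
#'
#' Renders the aliphatic window used for lactate deconvolution and glutamine
#' integration: the lactate CH3 doublet at 1.32 ppm (J = 6.9 Hz) for the
#' unlabeled pool, two 13C satellite doublets displaced +/- 1JCH/2 for the
#' labeled pool (1JCH default 127 Hz, a literature methyl value), the alanine
#' CH3 doublet at 1.47 ppm, a compact glutamine C4-H2 multiplet at 2.45 ppm,
#' a glutamate C4-H2 multiplet at 2.34 ppm, the succinate singlet at 2.41 ppm
#' and two broad lipid/macromolecule Gaussians under 1.54-1.14 ppm (CPMG does
#' not fully suppress them). Lines are Lorentzian (default FWHM 1.5 Hz).
#'
#' Drifting pools (Gln C4, Lac C2, Lac C3) accumulate linearly with the
#' acquisition time `t_h`.
#'
#' @param state A `true_metabolic_state`.
#' @param noise_sd Additive Gaussian noise SD (intensity units); must be >= 0.
#' @param window ppm window, default `c(1.0, 2.6)` (covers 1.14-2.50).
#' @param t_h Acquisition time in hours since session start.
#' @param scale Overall intensity scale (e.g. net tissue weight in mg, so
#'   that weight normalization is meaningful downstream).
#' @param freq_mhz 1H frequency (400.13 MHz).
#' @param fwhm_hz Lorentzian FWHM of narrow lines (Hz).
#' @param j_hh_hz CH3 doublet coupling (6.9 Hz).
#' @param j_ch_hz One-bond 13C-1H coupling for the satellites (configurable).
#' @param mm_areas Areas of the two macromolecule Gaussians (a.u. per mg).
#' @param step_ppm Axis step.
#' @return A [spectrum1d()].
#' @export
render_cpmg <- function(state, noise_sd = 0, window = c(1.0, 2.6), t_h = 0,
                        scale = 1, freq_mhz = 400.13, fwhm_hz = 1.5,
                        j_hh_hz = 6.9, j_ch_hz = 127,
                        mm_areas = c(25, 18), step_ppm = 5e-4) {
  stopifnot(inherits(state, "true_metabolic_state"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  lo <- min(window); hi <- max(window)
  if (lo > 1.14 || hi < 2.50) stop("window must cover 1.14-2.50 ppm")
  ppm <- seq(hi, lo, by = -step_ppm)
  fwhm <- fwhm_hz / freq_mhz
  jhh <- j_hh_hz / freq_mhz
  sat_off <- 0.5 * j_ch_hz / freq_mhz
  na_bg <- state$meta$natural_abundance

  drifted <- function(nm) {
    p <- state$pools[[nm]]
    if (nm %in% names(state$drift_rates)) p <- p + state$drift_rates[[nm]] * t_h
    p
  }
  y <- numeric(length(ppm))
  doublet <- function(center, area, width = fwhm) {
    (area / 2) * (.lorentz(ppm, center - jhh / 2, width) +
                    .lorentz(ppm, center + jhh / 2, width))
  }
  # lactate CH3: unlabeled parent doublet + two 13C satellite doublets
  lac_pool <- drifted("Lac C3")
  f_lac <- state$labeled[["Lac C3"]]
  y <- y + doublet(1.32, lac_pool * (1 - f_lac))
  y <- y + doublet(1.32 - sat_off, lac_pool * f_lac / 2)   # right (low-ppm)
  y <- y + doublet(1.32 + sat_off, lac_pool * f_lac / 2)   # left, under Ala
  # alanine CH3 (satellites negligible at these enrichments)
  y <- y + doublet(1.47, state$pools[["Ala C3"]])
  # glutamine / glutamate C4-H2 compact multiplets; succinate singlet
  gln_pool <- drifted("Gln C4")
  y <- y + (gln_pool / 2) * (.lorentz(ppm, 2.445, fwhm) + .lorentz(ppm, 2.455, fwhm))
  glu_pool <- state$pools[["Glu C4"]]
  y <- y + (glu_pool / 2) * (.lorentz(ppm, 2.335, fwhm) + .lorentz(ppm, 2.345, fwhm))
  y <- y + state$pools[["Succ C2C3"]] * .lorentz(ppm, 2.41, fwhm)
  # broad macromolecule/lipid background under the lactate region
  y <- y + mm_areas[1] * .gauss(ppm, 1.25, 40 / freq_mhz) +
    mm_areas[2] * .gauss(ppm, 1.43, 40 / freq_mhz)

  y <- y * scale
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  spectrum1d(ppm, y, nucleus = "1H", freq_mhz = freq_mhz,
             meta = list(kind = "cpmg", t_h = t_h, scale = scale,
                         fwhm_hz = fwhm_hz, j_hh_hz = j_hh_hz,
                         j_ch_hz = j_ch_hz, noise_sd = noise_sd,
                         natural_abundance = na_bg))
}

#' Render a 2D 1H-13C HSQC spectrum from a ground-truth state
#'
#' Every metabolite ROI of the template contributes a 2D Gaussian peak at its
#' center with volume `pool * labeled_fraction * scale` (HSQC detects protons
#' on 13C, so volumes are proportional to positional labeling; unlabeled
#' positions still show the 1.1% natural-abundance signal). Noise regions
#' contain only noise.
#'
#' @inheritParams render_cpmg
#' @param template An [roi_template()].
#' @param h_range,c_range Spectral ranges (ppm).
#' @param h_step,c_step Grid steps (ppm).
#' @param h_fwhm,c_fwhm Peak FWHM along each axis (ppm).
#' @return A [spectrum2d()].
#' @export
render_hsqc <- function(state, template = default_roi_template(), noise_sd = 0,
                        scale = 1, h_range = c(0.5, 5.6), c_range = c(5, 105),
                        h_step = 0.004, c_step = 0.2,
                        h_fwhm = 0.01, c_fwhm = 0.5) {
  stopifnot(inherits(state, "true_metabolic_state"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  h <- seq(max(h_range), min(h_range), by = -h_step)
  cc <- seq(max(c_range), min(c_range), by = -c_step)
  m <- matrix(0, length(h), length(cc))
  hs <- h_fwhm / (2 * sqrt(2 * log(2)))
  cs <- c_fwhm / (2 * sqrt(2 * log(2)))
  mets <- template[!template$is_noise, ]
  for (i in seq_len(nrow(mets))) {
    nm <- mets$name[i]
    h0 <- mets$h_ppm[i]; c0 <- mets$c_ppm[i]
    if (h0 < min(h_range) || h0 > max(h_range) ||
        c0 < min(c_range) || c0 > max(c_range)) {
      stop("peak center outside spectral width for ROI: ", nm)
    }
    pool <- state$pools[[nm]]
    if (is.null(pool)) next
    vol <- pool * state$labeled[[nm]] * scale
    if (vol <= 0) next
    ih <- which(abs(h - h0) < 6 * hs)
    ic <- which(abs(cc - c0) < 6 * cs)
    if (!length(ih) || !length(ic)) next
    m[ih, ic] <- m[ih, ic] +
      vol * outer(stats::dnorm(h[ih], h0, hs), stats::dnorm(cc[ic], c0, cs))
  }
  if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
  spectrum2d(h, cc, m,
             meta = list(kind = "hsqc", scale = scale, h_step = h_step,
                         c_step = c_step, h_fwhm = h_fwhm, c_fwhm = c_fwhm,
                         noise_sd = noise_sd))
}

#' 31P chemical-shift and pH calibration constants
#'
#' The inorganic-phosphate shift follows a Henderson-Hasselbalch titration
#' between the acid and base limit shifts (referenced to phosphocreatine at
#' 0 ppm); spectra are displayed referenced to GPE at 1.00 ppm, an offset of
#' `gpe_offset` ppm. The calibration source is not specified by the study;
#' these are standard literature constants and are configurable.
#'
#' @param pka Apparent pKa of inorganic phosphate.
#' @param delta_acid,delta_base Acid/base limiting shifts (ppm, PCr scale).
#' @param gpe_offset Offset subtracted to reference GPE to 1.00 ppm.
#' @return Named list of constants.
#' @export
p31_calibration <- function(pka = 6.75, delta_acid = 3.27, delta_base = 5.69,
                            gpe_offset = 2.50) {
  list(pka = pka, delta_acid = delta_acid, delta_base = delta_base,
       gpe_offset = gpe_offset,
       # phosphomonoester/diester positions on the GPE = 1.00 ppm scale
       positions = c(PE = 4.28, PC = 3.74, GPE = 1.00, GPC = 0.45),
       dpg_positions = c(3.62, 3.86))
}

#' Inorganic phosphate shift from pH (inverse titration)
#'
#' @param ph Tissue pH; must lie in \[5.5, 7.8\] (the titration range).
#' @param cal [p31_calibration()] constants.
#' @return Pi chemical shift on the PCr = 0 ppm scale.
#' @export
pi_shift_from_ph <- function(ph, cal = p31_calibration()) {
  if (any(ph < 5.5 | ph > 7.8)) stop("pH outside titration range [5.5, 7.8]")
  r <- 10^(ph - cal$pka)
  cal$delta_acid + (cal$delta_base - cal$delta_acid) * r / (1 + r)
}

#' Render a 1D 31P spectrum from a ground-truth state
#'
#' Lorentzian peaks for PE, PC, GPE (1.00 ppm reference), GPC and Pi, the Pi
#' position computed from tissue pH by the inverse of [estimate_ph()]. Heart
#' spectra add two 2,3-diphosphoglycerate components overlapping the PC
#' region, which is why PC is not quantifiable in heart tissue.
#'
#' @inheritParams render_cpmg
#' @param window ppm window on the GPE = 1.00 ppm scale.
#' @param freq_mhz 31P frequency (162.0 MHz at 9.4 T).
#' @param fwhm_ppm Lorentzian FWHM (ppm).
#' @param cal [p31_calibration()] constants.
#' @param step_ppm Axis step.
#' @return A [spectrum1d()] with nucleus `"31P"`.
#' @export
render_p31 <- function(state, noise_sd = 0, window = c(-1.0, 5.2), scale = 1,
                       freq_mhz = 162.0, fwhm_ppm = 0.03,
                       cal = p31_calibration(), step_ppm = 2e-3) {
  stopifnot(inherits(state, "true_metabolic_state"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (state$tissue_ph < 5.5 || state$tissue_ph > 7.8) {
    stop("pH outside titration range [5.5, 7.8]")
  }
  ppm <- seq(max(window), min(window), by = -step_ppm)
  y <- numeric(length(ppm))
  pools <- state$p31_pools
  for (nm in c("PE", "PC", "GPE", "GPC")) {
    if (!nm %in% names(pools)) next
    y <- y + pools[[nm]] * .lorentz(ppm, cal$positions[[nm]], fwhm_ppm)
  }
  pi_pos <- pi_shift_from_ph(state$tissue_ph, cal) - cal$gpe_offset
  y <- y + pools[["Pi"]] * .lorentz(ppm, pi_pos, fwhm_ppm)
  if (state$meta$tissue == "heart_apex" && "DPG" %in% names(pools)) {
    y <- y + (pools[["DPG"]] / 2) * (.lorentz(ppm, cal$dpg_positions[1], fwhm_ppm) +
                                       .lorentz(ppm, cal$dpg_positions[2], fwhm_ppm))
  }
  y <- y * scale
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  spectrum1d(ppm, y, nucleus = "31P", freq_mhz = freq_mhz,
             meta = list(kind = "p31", tissue = state$meta$tissue,
                         scale = scale, fwhm_ppm = fwhm_ppm,
                         noise_sd = noise_sd, true_ph = state$tissue_ph))
}
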