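#' Integrate HSQC ROI volumes against a template
#'
#' Each ROI volume is the sum of grid intensities inside its window times the
#' grid cell area, minus a local plane baseline estimated as the median
#' intensity of the ROI border pixels (robust against smooth background).
#' Volumes are normalized to net tissue weight; SNR is the ROI peak height
#' over the pooled SD of the noise-region pixels. ROIs outside the spectrum
#' give a missing value with a warning, not a failure.
#'
#' @param spec A [spectrum2d()].
#' @param template An [roi_template()].
#' @param sample Manifest row supplying `sample_id` and
#'   `net_tissue_weight_mg`.
#' @param snr_threshold Peaks below this SNR are kept but flagged.
#' @return A quantification table: data frame with columns `sample_id`,
#'   `roi`, `raw_area`, `norm_area`, `snr`, `method`, `flag`.
#' @export
integrate_roi <- function(spec, template, sample, snr_threshold = 3) {
  stopifnot(inherits(spec, "spectrum2d"), inherits(template, "roi_template"))
  cell <- abs(diff(spec$h_ppm[1:2])) * abs(diff(spec$c_ppm[1:2]))
  idx <- function(lo, hi, axis) which(axis >= lo & axis < hi)

  noise_px <- unlist(lapply(which(template$is_noise), function(i) {
    ih <- idx(template$h_lo[i], template$h_hi[i], spec$h_ppm)
    ic <- idx(template$c_lo[i], template$c_hi[i], spec$c_ppm)
    as.numeric(spec$intensity[ih, ic])
  }))
  noise_sd <- if (length(noise_px) > 1) stats::sd(noise_px) else NA_real_

  rows <- lapply(seq_len(nrow(template)), function(i) {
    ih <- idx(template$h_lo[i], template$h_hi[i], spec$h_ppm)
    ic <- idx(template$c_lo[i], template$c_hi[i], spec$c_ppm)
    out_of_range <- template$h_hi[i] > max(spec$h_ppm) + 1e-9 ||
      template$h_lo[i] < min(spec$h_ppm) - 1e-9 ||
      template$c_hi[i] > max(spec$c_ppm) + 1e-9 ||
      template$c_lo[i] < min(spec$c_ppm) - 1e-9
    if (out_of_range || !length(ih) || !length(ic)) {
      warning("ROI outside spectrum: ", template$name[i])
      return(data.frame(sample_id = sample$sample_id, roi = template$name[i],
                        raw_area = NA_real_, norm_area = NA_real_,
                        snr = NA_real_, method = "integration",
                        flag = "outside_spectrum", stringsAsFactors = FALSE))
    }
    block <- spec$intensity[ih, ic, drop = FALSE]
    border <- c(block[1, ], block[nrow(block), ], block[, 1], block[, ncol(block)])
    base <- stats::median(border)
    vol <- (sum(block) - base * length(block)) * cell
    snr <- if (is.na(noise_sd) || noise_sd == 0) Inf else
      (max(block) - base) / noise_sd
    flag <- if (!template$is_noise[i] && is.finite(snr) && snr < snr_threshold)
      "low_snr" else ""
    data.frame(sample_id = sample$sample_id, roi = template$name[i],
               raw_area = vol,
               norm_area = normalize_to_weight(vol, sample),
               snr = snr, method = "integration", flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Constrained deconvolution of the lactate methyl region
#'
#' Nonlinear least squares over 1.54-1.14 ppm with the components the visual
#' deconvolution uses: the lactate CH3 doublet (1.32 ppm, J = 6.9 Hz), the
#' right-hand 13C satellite doublet at -1JCH/2, the alanine CH3 doublet
#' (which also absorbs the left satellite, so the left satellite is not
#' fitted independently), and two broad macromolecule Gaussians. Doublet
#' positions are constrained to +/- 0.01 ppm of nominal and narrow lines
#' share one linewidth, keeping the fit identifiable at low SNR.
#'
#' @param spec A [spectrum1d()] 1H spectrum covering the window.
#' @param window Deconvolution window (ppm).
#' @param j_hh_hz,j_ch_hz Doublet and one-bond couplings (Hz).
#' @param snr_threshold Satellite SNR below which the record is flagged.
#' @return List with areas `lac_ch3`, `lac_13ch3_right`, `ala_ch3`,
#'   `baseline` (the two Gaussian areas), `positions`, `fwhm_hz`, `flagged`,
#'   `converged` and `rss`.
#' @export
deconvolve_lactate <- function(spec, window = c(1.14, 1.54),
                               j_hh_hz = 6.9, j_ch_hz = 127,
                               snr_threshold = 3) {
  stopifnot(inherits(spec, "spectrum1d"))
  sel <- spec$ppm >= min(window) & spec$ppm <= max(window)
  if (sum(sel) < 50) stop("window not present in spectrum")
  x <- spec$ppm[sel]; y <- spec$intensity[sel]
  fq <- spec$freq_mhz
  jhh <- j_hh_hz / fq
  sat <- 0.5 * j_ch_hz / fq

  doublet <- function(center, area, fwhm) {
    (area / 2) * (.lorentz(x, center - jhh / 2, fwhm) +
                    .lorentz(x, center + jhh / 2, fwhm))
  }
  model <- function(p) {
    # the left satellite is tied to the right (symmetric 13C satellites), not
    # fitted independently: it overlaps the alanine doublet
    doublet(p["p_lac"], p["a_lac"], p["w"]) +
      doublet(p["p_lac"] - sat, p["a_sat"], p["w"]) +
      doublet(p["p_lac"] + sat, p["a_sat"], p["w"]) +
      doublet(p["p_ala"], p["a_ala"], p["w"]) +
      p["a_mm1"] * .gauss(x, p["p_mm1"], p["w_mm"]) +
      p["a_mm2"] * .gauss(x, p["p_mm2"], p["w_mm"])
  }
  peak <- max(y)
  start <- c(a_lac = peak * 0.01, a_sat = peak * 1e-4, a_ala = peak * 0.003,
             a_mm1 = peak * 0.01, a_mm2 = peak * 0.01,
             p_lac = 1.32, p_ala = 1.47, p_mm1 = 1.25, p_mm2 = 1.43,
             w = 1.5 / fq, w_mm = 40 / fq)
  lower <- c(0, 0, 0, 0, 0, 1.31, 1.46, 1.22, 1.40, 0.5 / fq, 20 / fq)
  upper <- c(rep(Inf, 5), 1.33, 1.48, 1.28, 1.46, 5 / fq, 90 / fq)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(p) y - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 400,
                                                            ftol = 1e-12,
                                                            ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(lac_ch3 = NA_real_, lac_13ch3_right = NA_real_,
                ala_ch3 = NA_real_, baseline = c(NA_real_, NA_real_),
                positions = NULL, fwhm_hz = NA_real_, flagged = TRUE,
                converged = FALSE, rss = NA_real_))
  }
  p <- stats::coef(fit)
  # areas enter the model linearly: refine them by an exact linear solve at
  # the fitted positions/linewidths (variable projection), clipping at zero
  shapes <- cbind(
    lac = (.lorentz(x, p["p_lac"] - jhh / 2, p["w"]) +
             .lorentz(x, p["p_lac"] + jhh / 2, p["w"])) / 2,
    sat = (.lorentz(x, p["p_lac"] - sat - jhh / 2, p["w"]) +
             .lorentz(x, p["p_lac"] - sat + jhh / 2, p["w"]) +
             .lorentz(x, p["p_lac"] + sat - jhh / 2, p["w"]) +
             .lorentz(x, p["p_lac"] + sat + jhh / 2, p["w"])) / 2,
    ala = (.lorentz(x, p["p_ala"] - jhh / 2, p["w"]) +
             .lorentz(x, p["p_ala"] + jhh / 2, p["w"])) / 2,
    mm1 = .gauss(x, p["p_mm1"], p["w_mm"]),
    mm2 = .gauss(x, p["p_mm2"], p["w_mm"]))
  beta <- tryCatch(stats::coef(stats::lm.fit(shapes, y)),
                   error = function(e) NULL)
  neg_clip <- FALSE
  if (!is.null(beta) && all(is.finite(beta))) {
    neg_clip <- any(beta < 0)
    p[c("a_lac", "a_sat", "a_ala", "a_mm1", "a_mm2")] <- pmax(beta, 0)
  }
  resid <- y - model(p)
  resid_sd <- stats::sd(resid)
  sat_height <- p["a_sat"] / 2 * .lorentz(0, 0, p["w"])
  flagged <- fit$info > 4 || neg_clip ||
    (is.finite(resid_sd) && resid_sd > 0 && sat_height / resid_sd < snr_threshold)
  areas <- pmax(p[c("a_lac", "a_sat", "a_ala", "a_mm1", "a_mm2")], 0)
  list(lac_ch3 = unname(areas[1]), lac_13ch3_right = unname(areas[2]),
       ala_ch3 = unname(areas[3]), baseline = unname(areas[4:5]),
       positions = p[c("p_lac", "p_ala", "p_mm1", "p_mm2")],
       fwhm_hz = unname(p["w"] * fq), flagged = flagged,
       converged = fit$info %in% 1:4, rss = sum(resid^2))
}

#' Baseline-corrected glutamine integration
#'
#' Integrates exactly 2.48-2.42 ppm (trapezoid rule) after subtracting a
#' linear baseline fitted to flanking regions on either side; the window is
#' chosen to exclude the succinate singlet at 2.41 ppm.
#'
#' @param spec A [spectrum1d()] 1H spectrum.
#' @param window Integration window (ppm).
#' @param flank_left,flank_right ppm ranges used for the baseline (the right
#'   flank sits below succinate).
#' @return Integrated area (a.u.).
#' @export
integrate_glutamine <- function(spec, window = c(2.42, 2.48),
                                flank_left = c(2.49, 2.53),
                                flank_right = c(2.368, 2.388)) {
  stopifnot(inherits(spec, "spectrum1d"))
  rng <- range(spec$ppm)
  if (min(window) < rng[1] || max(window) > rng[2] ||
      min(flank_right) < rng[1] || max(flank_left) > rng[2]) {
    stop("integration window (or its baseline flanks) truncated by spectrum")
  }
  mid <- function(r) mean(r)
  lev <- function(r) stats::median(spec$intensity[spec$ppm >= min(r) & spec$ppm <= max(r)])
  x1 <- mid(flank_left); y1 <- lev(flank_left)
  x2 <- mid(flank_right); y2 <- lev(flank_right)
  slope <- (y1 - y2) / (x1 - x2)
  sel <- spec$ppm >= min(window) & spec$ppm <= max(window)
  x <- spec$ppm[sel]; y <- spec$intensity[sel] - (y2 + slope * (x - x2))
  o <- order(x)
  sum(diff(x[o]) * (y[o][-1] + y[o][-length(y)]) / 2)
}

#' Quantify 31P phospholipid intermediates and inorganic phosphate
#'
#' Local Lorentzian deconvolution of PE, PC, GPE (the 1.00 ppm reference),
#' GPC and Pi. The GPE reference peak must be detectable, otherwise the
#' spectrum cannot be referenced and an error is raised. In heart tissue the
#' PC region overlaps 2,3-diphosphoglycerate, so PC is reported as missing
#' (the DPG components are fitted but not reported).
#'
#' @param spec A [spectrum1d()] 31P spectrum on the GPE = 1.00 ppm scale.
#' @param tissue `"brain_cortex"` or `"heart_apex"`.
#' @param cal [p31_calibration()] constants.
#' @return List with `areas` (named PE, PC, GPE, GPC, Pi; PC is `NA` for
#'   heart), `pi_shift_ppm` (GPE scale), `fwhm_ppm`, `converged`, `rss`.
#' @export
quantify_p31 <- function(spec, tissue = c("brain_cortex", "heart_apex"),
                         cal = p31_calibration()) {
  tissue <- match.arg(tissue)
  stopifnot(inherits(spec, "spectrum1d"))
  x <- spec$ppm; y <- spec$intensity
  gpe_sel <- x >= 0.85 & x <= 1.15
  baseline_sd <- stats::sd(y[x < -0.4])
  if (!any(gpe_sel) ||
      max(y[gpe_sel]) < max(5 * baseline_sd, 1e-12, na.rm = TRUE)) {
    stop("GPE reference peak (1.00 ppm) not detectable; cannot reference spectrum")
  }
  heart <- tissue == "heart_apex"
  pos <- cal$positions
  npk <- c("PE", "PC", "GPE", "GPC")
  model <- function(p) {
    out <- p["a_Pi"] * .lorentz(x, p["p_Pi"], p["w"])
    for (nm in npk) {
      out <- out + p[paste0("a_", nm)] * .lorentz(x, p[paste0("p_", nm)], p["w"])
    }
    if (heart) {
      out <- out + (p["a_DPG"] / 2) * (.lorentz(x, cal$dpg_positions[1], p["w"]) +
                                         .lorentz(x, cal$dpg_positions[2], p["w"]))
    }
    out
  }
  # Pi initialised at the pH ~6.4 position typical of post-mortem tissue
  pk <- max(y)
  start <- c(a_PE = pk * 0.02, a_PC = pk * 0.02, a_GPE = pk * 0.02,
             a_GPC = pk * 0.02, a_Pi = pk * 0.03, a_DPG = pk * 0.02,
             p_PE = pos[["PE"]], p_PC = pos[["PC"]], p_GPE = pos[["GPE"]],
             p_GPC = pos[["GPC"]], p_Pi = 1.6, w = 0.03)
  lower <- c(rep(0, 6), pos[["PE"]] - 0.05, pos[["PC"]] - 0.05,
             pos[["GPE"]] - 0.05, pos[["GPC"]] - 0.05, 1.1, 0.01)
  upper <- c(rep(Inf, 6), pos[["PE"]] + 0.05, pos[["PC"]] + 0.05,
             pos[["GPE"]] + 0.05, pos[["GPC"]] + 0.05, 3.0, 0.12)
  if (!heart) {
    start <- start[names(start) != "a_DPG"]
    lower <- lower[-6]; upper <- upper[-6]
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  areas <- c(PE = unname(p["a_PE"]),
             PC = if (heart) NA_real_ else unname(p["a_PC"]),
             GPE = unname(p["a_GPE"]), GPC = unname(p["a_GPC"]),
             Pi = unname(p["a_Pi"]))
  list(areas = areas, pi_shift_ppm = unname(p["p_Pi"]),
       fwhm_ppm = unname(p["w"]), converged = fit$info %in% 1:4,
       rss = sum(fit$fvec^2))
}

#' Tissue pH from the inorganic phosphate chemical shift
#'
#' Henderson-Hasselbalch form
#' `pH = pKa + log10((delta - delta_acid) / (delta_base - delta))` with
#' configurable literature constants (the study does not state its
#' calibration).
#'
#' @param delta_pi Pi shift on the PCr = 0 ppm scale; must lie strictly
#'   between the acid and base limits.
#' @param cal [p31_calibration()] constants.
#' @return pH (units).
#' @export
estimate_ph <- function(delta_pi, cal = p31_calibration()) {
  if (any(delta_pi <= cal$delta_acid | delta_pi >= cal$delta_base)) {
    stop(sprintf("Pi shift outside titration limits (%.2f, %.2f) ppm",
                 cal$delta_acid, cal$delta_base))
  }
  cal$pka + log10((delta_pi - cal$delta_acid) / (cal$delta_base - delta_pi))
}

#' Normalize a raw area to net tissue weight
#'
#' @param raw_area Raw integrated area (a.u.).
#' @param sample Manifest row with `net_tissue_weight_mg` (D2O already
#'   excluded in the manifest).
#' @return Area per mg tissue.
#' @export
normalize_to_weight <- function(raw_area, sample) {
  w <- sample$net_tissue_weight_mg
  if (is.null(w) || length(w) != 1 || is.na(w)) stop("missing net tissue weight")
  if (w <= 0) stop("net tissue weight must be positive")
  raw_area / w
}
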