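#' Configuration for an end-to-end pipeline run
#'
#' The `"study_default"` scenario reproduces the study design: 9 mothers
#' (2 CTR, 4 GLC, 3 ACE), HRMAS sub-cohort of 3 CTR AGA + 6/6 GLC + 6/6 ACE
#' fetuses, brain and heart sampled per fetus, and 3 samples dropped at
#' random (rotor-loading failures). A `"ctr_only"` scenario keeps only the
#' non-infused group. All randomness derives from `seed`.
#'
#' @param scenario `"study_default"` or `"ctr_only"`.
#' @param seed Master seed.
#' @param out_dir Output directory for [run_pipeline()] (`NULL` for none).
#' @param noise Named noise SDs: `hsqc`, `cpmg`, `p31`.
#' @param drift Render the final CPMG after `session_h` hours of linear
#'   accumulation (TRUE) or at t = 0 (FALSE).
#' @param session_h HRMAS session length (hours).
#' @param lactate_method `"deconvolution"` or `"integration"` for the
#'   lactate read-out.
#' @param drop_samples Samples dropped at random from the manifest.
#' @param write_spectra Also write every rendered spectrum as ASCII (off by
#'   default: the spectra are large and regenerable from the config).
#' @param effects An [effect_spec()].
#' @param substrate_enrichment Passed to [assign_true_state()].
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(scenario = c("study_default", "ctr_only"), seed = 1L,
                       out_dir = NULL,
                       noise = c(hsqc = 5, cpmg = 20, p31 = 30),
                       drift = TRUE, session_h = 3.4,
                       lactate_method = c("deconvolution", "integration"),
                       drop_samples = 3L, write_spectra = FALSE,
                       effects = effect_spec(), substrate_enrichment = 0.17) {
  structure(list(scenario = match.arg(scenario), seed = as.integer(seed),
                 out_dir = out_dir, noise = noise, drift = drift,
                 session_h = session_h,
                 lactate_method = match.arg(lactate_method),
                 drop_samples = as.integer(drop_samples),
                 write_spectra = write_spectra, effects = effects,
                 substrate_enrichment = substrate_enrichment),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' A run directory always contains the exact configuration used, so any run
#' can be reproduced from its directory alone.
#'
#' @param config A [run_config()].
#' @param file YAML path.
#' @export
write_run_config <- function(config, file) {
  x <- unclass(config)
  eff <- unclass(x$effects)
  # named atomic vectors must become maps, or YAML drops the names
  eff$labeled_factors <- lapply(eff$labeled_factors, function(g)
    lapply(g, as.list))
  eff$pdiester_factor <- as.list(eff$pdiester_factor)
  eff$cv_excess <- as.list(eff$cv_excess)
  x$effects <- eff
  x$noise <- as.list(x$noise)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  x <- yaml::read_yaml(file)
  eff <- x$effects
  eff$labeled_factors <- lapply(eff$labeled_factors, function(g)
    lapply(g, function(t) unlist(t)))
  x$effects <- do.call(effect_spec, list(
    labeled_factors = eff$labeled_factors,
    pdiester_factor = unlist(eff$pdiester_factor),
    cv_excess = unlist(eff$cv_excess),
    cv_excess_default = eff$cv_excess_default,
    cv_pool = eff$cv_pool, cv_p31 = eff$cv_p31))
  x$noise <- unlist(x$noise)
  do.call(run_config, x[c("scenario", "seed", "out_dir", "noise", "drift",
                          "session_h", "lactate_method", "drop_samples",
                          "write_spectra", "effects", "substrate_enrichment")])
}

.study_manifest <- function(config) {
  seed <- config$seed
  groups <- if (config$scenario == "ctr_only") {
    list(cohort_config("CTR", n_mothers = 2, seed = seed + 1L))
  } else {
    list(cohort_config("CTR", n_mothers = 2, seed = seed + 1L),
         cohort_config("GLC", n_mothers = 4, seed = seed + 2L),
         cohort_config("ACE", n_mothers = 3, seed = seed + 3L))
  }
  fetuses <- do.call(rbind, lapply(groups, make_cohort))
  design <- if (config$scenario == "ctr_only") {
    data.frame(group = "CTR", horn = "AGA", n = 3L)
  } else {
    data.frame(group = c("CTR", "GLC", "GLC", "ACE", "ACE"),
               horn = c("AGA", "AGA", "FGR", "AGA", "FGR"),
               n = c(3L, 6L, 6L, 6L, 6L))
  }
  sel <- select_hrmas_subcohort(fetuses, design, seed = seed + 11L)
  cfg0 <- groups[[1]]
  manifest <- make_samples(sel, cfg0)
  if (config$drop_samples > 0 && config$drop_samples < nrow(manifest)) {
    set.seed(.unit_seed(seed, 97L))
    manifest <- manifest[-sample.int(nrow(manifest), config$drop_samples), ]
  }
  rownames(manifest) <- NULL
  manifest
}

.quantify_sample <- function(sample, state, config, template, run_seed, idx) {
  scale <- sample$net_tissue_weight_mg
  set.seed(.unit_seed(run_seed + 101L, idx))
  hsqc <- render_hsqc(state, template, noise_sd = config$noise[["hsqc"]],
                      scale = scale)
  set.seed(.unit_seed(run_seed + 102L, idx))
  cpmg0 <- render_cpmg(state, noise_sd = config$noise[["cpmg"]], t_h = 0,
                       scale = scale)
  set.seed(.unit_seed(run_seed + 103L, idx))
  cpmg1 <- render_cpmg(state, noise_sd = config$noise[["cpmg"]],
                       t_h = if (config$drift) config$session_h else 0,
                       scale = scale)
  set.seed(.unit_seed(run_seed + 104L, idx))
  p31 <- render_p31(state, noise_sd = config$noise[["p31"]], scale = scale)

  quant <- integrate_roi(hsqc, template, sample)
  deconv <- deconvolve_lactate(cpmg0)
  lacpools <- pools_from_cpmg(deconv)
  gln0 <- integrate_glutamine(cpmg0)
  gln1 <- integrate_glutamine(cpmg1)
  lac1 <- deconvolve_lactate(cpmg1)
  p31q <- quantify_p31(p31, sample$tissue)
  ph <- estimate_ph(p31q$pi_shift_ppm + p31_calibration()$gpe_offset)

  norm <- function(a) normalize_to_weight(a, sample)
  scalars <- data.frame(
    sample_id = sample$sample_id,
    variable = c("lac_total", "lac_13c", "ala_ch3", "gln_area_initial",
                 "gln_area_final", "lac_ch3_final", "ph", "PE", "PC",
                 "GPE", "GPC", "Pi", "gpc_gpe"),
    value = c(norm(lacpools$lac_total), norm(lacpools$lac_13c),
              norm(deconv$ala_ch3), norm(gln0), norm(gln1),
              norm(lac1$lac_ch3 + 2 * lac1$lac_13ch3_right), ph,
              norm(p31q$areas[["PE"]]), norm(p31q$areas[["PC"]]),
              norm(p31q$areas[["GPE"]]), norm(p31q$areas[["GPC"]]),
              norm(p31q$areas[["Pi"]]),
              norm(p31q$areas[["GPE"]] + p31q$areas[["GPC"]])),
    stringsAsFactors = FALSE)
  list(quant = quant, scalars = scalars,
       flagged = isTRUE(deconv$flagged) && config$lactate_method == "deconvolution")
}

#' Run the full simulate -> quantify -> analyze -> compare pipeline
#'
#' Deterministic given the config seed. Per sample the HRMAS protocol order
#' is emulated (initial CPMG, 31P, HSQC, final CPMG after `session_h` hours
#' of drift). Outputs (written to `config$out_dir` when set): manifest,
#' quantification tables, enrichment and incorporation tables, flux ratios,
#' FGR-vs-AGA comparisons, initial-vs-final comparisons and a plain-text
#' report of significant contrasts. Per-sample quantification failures are
#' isolated; the run fails only if more than 20% of samples are flagged.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all tables (`manifest`, `quant`,
#'   `scalars`, `enrichment`, `incorporation`, `flux_ratios`, `comparisons`,
#'   `initial_final`, `report`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  template <- default_roi_template()
  manifest <- .study_manifest(config)
  n <- nrow(manifest)

  quant_l <- list(); scal_l <- list(); flags <- logical(n)
  for (i in seq_len(n)) {
    sm <- manifest[i, ]
    state <- assign_true_state(sm, effects = config$effects,
                               template = template,
                               substrate_enrichment = config$substrate_enrichment,
                               seed = .unit_seed(config$seed + 17L, i))
    res <- tryCatch(
      .quantify_sample(sm, state, config, template, config$seed, i),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("sample ", sm$sample_id, " failed: ", conditionMessage(res))
      flags[i] <- TRUE
      next
    }
    flags[i] <- res$flagged
    quant_l[[i]] <- res$quant
    scal_l[[i]] <- res$scalars
  }
  if (mean(flags) > 0.2) stop("more than 20% of samples flagged; aborting run")
  quant <- do.call(rbind, quant_l)
  scalars <- do.call(rbind, scal_l)

  iso_rois <- c("Ala C3", "Lac C3", "Lac C2", "Gln C4", "Glu C4", "Glu C3",
                "Glu C2", "AcCarn CH3", "Mal C2", "Mal C3", "Pyr C3")
  meta <- manifest[, c("sample_id", "group", "horn", "tissue")]
  qm <- merge(quant, meta, by = "sample_id")

  ctr_means <- lapply(split(qm[qm$group == "CTR", ], qm$tissue[qm$group == "CTR"]),
                      function(d) tapply(d$norm_area, d$roi, mean))
  infused <- setdiff(unique(qm$group), "CTR")

  enr_l <- list(); inc_l <- list()
  for (g in infused) {
    substrate <- if (g == "GLC") "glc_1_13C" else "ace_2_13C"
    for (ts in unique(qm$tissue)) {
      cm <- ctr_means[[ts]]
      if (is.null(cm)) next
      d <- qm[qm$group == g & qm$tissue == ts & qm$roi %in% iso_rois, ]
      if (!nrow(d)) next
      e <- positional_enrichment(d$norm_area, cm[d$roi], substrate)
      enr_l[[paste(g, ts)]] <- cbind(d[, c("sample_id", "roi", "horn")],
                                     group = g, tissue = ts, e)
      inc <- incorporation_fractions(d, cm)
      if (!is.null(inc$summary)) {
        inc$summary$group <- g; inc$summary$tissue <- ts
        inc_l[[paste(g, ts)]] <- inc$summary
      }
    }
  }
  enrichment <- if (length(enr_l)) do.call(rbind, enr_l) else NULL
  incorporation <- if (length(inc_l)) do.call(rbind, inc_l) else NULL
  if (!is.null(enrichment)) rownames(enrichment) <- NULL
  if (!is.null(incorporation)) rownames(incorporation) <- NULL

  fluxes <- NULL
  if ("GLC" %in% infused && "brain_cortex" %in% names(ctr_means)) {
    d <- enrichment[enrichment$group == "GLC" & enrichment$tissue == "brain_cortex", ]
    if (!is.null(d) && nrow(d)) {
      mean_enr <- tapply(d$positional_enrichment_pct, d$roi, mean)
      fr <- flux_ratios(mean_enr)
      fluxes <- data.frame(tissue = "brain_cortex", group = "GLC",
                           pc_over_pdh = fr$pc_over_pdh,
                           pc_over_me = fr$pc_over_me,
                           formula_pc_pdh = fr$formulas[["pc_over_pdh"]],
                           formula_pc_me = fr$formulas[["pc_over_me"]],
                           stringsAsFactors = FALSE)
    }
  }

  sm <- merge(scalars, meta, by = "sample_id")
  comp_l <- list()
  for (g in infused) {
    for (ts in unique(qm$tissue)) {
      # 13C labeled levels: CTR-referenced excess (the natural-abundance
      # background is common to both horns and would dilute the contrast)
      d <- enrichment[enrichment$group == g & enrichment$tissue == ts &
                        enrichment$roi %in% iso_rois[1:7], ]
      for (r in unique(d$roi)) {
        aga <- d$positional_enrichment_pct[d$roi == r & d$horn == "AGA"]
        fgr <- d$positional_enrichment_pct[d$roi == r & d$horn == "FGR"]
        if (length(aga) >= 2 && length(fgr) >= 2) {
          comp_l[[paste(g, ts, r)]] <- compare_groups(aga, fgr,
            variable = r, tissue = ts, group = g)
        }
      }
      # scalar read-outs (pools, pH, phosphodiesters)
      ds <- sm[sm$group == g & sm$tissue == ts, ]
      for (v in c("lac_total", "lac_13c", "gln_area_initial", "gpc_gpe", "ph")) {
        aga <- ds$value[ds$variable == v & ds$horn == "AGA"]
        fgr <- ds$value[ds$variable == v & ds$horn == "FGR"]
        if (length(aga) >= 2 && length(fgr) >= 2) {
          comp_l[[paste(g, ts, v)]] <- compare_groups(aga, fgr,
            variable = v, tissue = ts, group = g)
        }
      }
    }
  }
  comparisons <- if (length(comp_l)) do.call(rbind, comp_l) else NULL
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  ini <- sm[sm$variable == "gln_area_initial", c("sample_id", "value")]
  fin <- sm[sm$variable == "gln_area_final", c("sample_id", "value")]
  ini$variable <- "gln_area"; fin$variable <- "gln_area"
  inifin <- initial_vs_final(ini, fin)

  report <- c(sprintf("hrmasflux pipeline report (scenario %s, seed %d)",
                      config$scenario, config$seed),
              sprintf("samples: %d (%d flagged)", n, sum(flags)), "")
  if (!is.null(comparisons)) {
    sig <- comparisons[comparisons$significant, ]
    report <- c(report, "Significant FGR-vs-AGA contrasts (p < 0.05):",
                if (nrow(sig)) sprintf("  %s %s %s: %+.1f%% (p = %.4f)",
                                       sig$group, sig$tissue, sig$variable,
                                       sig$percent_difference, sig$p_value)
                else "  none")
  } else {
    report <- c(report, "No infused groups; no enrichment comparisons.")
  }
  if (!is.null(inifin$comparisons)) {
    report <- c(report, "", "Initial vs final acquisition (paired, one-tailed):",
                sprintf("  %s: %+.1f%% (p = %.4f)",
                        inifin$comparisons$variable,
                        inifin$comparisons$percent_difference,
                        inifin$comparisons$p_value))
  }

  out <- list(manifest = manifest, quant = quant, scalars = scalars,
              enrichment = enrichment, incorporation = incorporation,
              flux_ratios = fluxes, comparisons = comparisons,
              initial_final = inifin, report = report, config = config,
              flagged = manifest$sample_id[flags])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(config$out_dir, f), row.names = FALSE)
    wr(manifest, "manifest.csv"); wr(quant, "quant.csv")
    wr(scalars, "scalars.csv"); wr(enrichment, "enrichment.csv")
    wr(incorporation, "incorporation.csv"); wr(fluxes, "flux_ratios.csv")
    wr(comparisons, "comparisons.csv")
    wr(inifin$comparisons, "initial_final.csv")
    writeLines(report, file.path(config$out_dir, "report.txt"))
    write_run_config(config, file.path(config$out_dir, "config.yaml"))
  }
  invisible(out)
}
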