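test_that("atom maps conserve carbon up to declared CO2 losses", {
  reg <- atom_map_registry()
  expect_true(all(c("glycolysis", "pdh", "pc", "cs_to_akg", "succinate",
                    "me", "gs") %in% names(reg)))
  for (m in reg) {
    w <- tapply(m$transfers$weight, paste(m$transfers$to_met,
                                          m$transfers$to_carbon), sum)
    expect_true(all(w <= 1 + 1e-12), info = m$reaction)
  }
  # duplicate source for one product carbon above weight 1 is rejected
  expect_error(atom_map("bad", data.frame(from_met = c("A", "B"),
                                          from_carbon = c(1, 1),
                                          to_met = "C", to_carbon = 1,
                                          weight = c(0.8, 0.4))),
               "exceed")
})

test_that("first acetate turn labels Glu C4 only, second turn spreads to C2/C3 equally", {
  f1 <- flux_params(n_turns = 1, acetate_uptake = 1, dilution_unlabeled = 0, me = 0)
  p1 <- propagate("ace_2_13C", f1)
  expect_gt(p1$Glu[["c4"]], 0)
  expect_identical(unname(p1$Glu[c("c2", "c3")]), c(0, 0))
  f2 <- flux_params(n_turns = 2, acetate_uptake = 1, dilution_unlabeled = 0, me = 0)
  p2 <- propagate("ace_2_13C", f2)
  expect_gt(p2$Glu[["c2"]], 0)
  expect_equal(p2$Glu[["c2"]], p2$Glu[["c3"]], tolerance = 1e-12)
})

test_that("glucose C1 labels half of glycolytic lactate C3 and nothing at C2 without PC/ME", {
  p <- propagate("glc_1_13C", flux_params(pc = 0, me = 0, dilution_unlabeled = 0))
  expect_equal(p$Lac[["c3"]], 0.5, tolerance = 1e-9)
  expect_equal(p$Lac[["c2"]], 0)
  expect_equal(p$Ala[["c3"]], p$Lac[["c3"]])
})

test_that("infinite unlabeled dilution drives all fractions to zero excess", {
  p <- propagate("glc_1_13C", flux_params(dilution_unlabeled = 1e9))
  expect_lt(max(unlist(p[c("Glu", "Gln", "OAA", "Mal", "aKG")])), 1e-6)
})

test_that("steady state matches a long finite iteration and is deterministic", {
  fl_ss <- flux_params(pc = 0.3, me = 0.2, dilution_unlabeled = 0.4)
  fl_fin <- flux_params(pc = 0.3, me = 0.2, dilution_unlabeled = 0.4, n_turns = 200)
  expect_equal(profile_fractions(propagate("glc_1_13C", fl_ss)),
               profile_fractions(propagate("glc_1_13C", fl_fin)),
               tolerance = 1e-7)
  expect_identical(propagate("ace_2_13C", fl_ss), propagate("ace_2_13C", fl_ss))
})

test_that("propagation agrees with the molecule-level Monte-Carlo oracle within 3 SE", {
  cases <- list(
    list(substrate = "glc_1_13C",
         flux = flux_params(pc = 0.3, me = 0.2, dilution_unlabeled = 0.5,
                            scrambling = 1, n_turns = 2)),
    list(substrate = "ace_2_13C",
         flux = flux_params(acetate_uptake = 1, pdh = 0.6, me = 0.3,
                            dilution_unlabeled = 0.4, scrambling = 0.5,
                            n_turns = 3)),
    list(substrate = "glc_1_13C",
         flux = flux_params(pc = 0.4, me = 0, dilution_unlabeled = 0.2,
                            scrambling = 0, n_turns = 2)))
  set.seed(2024)
  for (cs in cases) {
    an <- propagate(cs$substrate, cs$flux)
    mc <- mc_propagate(cs$substrate, cs$flux, n_mol = 1e5,
                       n_turns = cs$flux$n_turns)
    for (met in c("Lac", "Glu", "Gln")) {
      for (pos in names(mc[[met]])) {
        p_mc <- mc[[met]][[pos]]
        p_an <- an[[met]][[pos]]
        se <- mc_se(p_an, mc$n_mol)
        expect_lt(abs(p_mc - p_an), 3 * se + 1e-9,
                  label = sprintf("%s %s %s (MC %.4f vs analytic %.4f)",
                                  cs$substrate, met, pos, p_mc, p_an))
      }
    }
  }
})

test_that("Glu C4 is monotone in acetate uptake and Lac C2 in malic enzyme flux", {
  g4 <- vapply(c(0.2, 0.5, 1, 2), function(a)
    propagate("ace_2_13C", flux_params(acetate_uptake = a))$Glu[["c4"]],
    numeric(1))
  expect_true(all(diff(g4) > 0))
  l2 <- vapply(c(0, 0.1, 0.3, 0.6), function(m)
    propagate("glc_1_13C", flux_params(me = m))$Lac[["c2"]], numeric(1))
  expect_true(all(diff(l2) > 0))
})

test_that("glutamine labeling never exceeds glutamate at full Glu turnover, but can above the gs threshold", {
  # with complete Glu pool turnover GS can only dilute
  p <- propagate("ace_2_13C", flux_params(glu_turnover = 1, gs = 50,
                                          acetate_uptake = 1))
  expect_true(all(p$Gln <= p$Glu + 1e-12))
  # with partial Glu turnover (default 0.7) the threshold is
  # gs > glu_turnover * gln_exchange / (1 - glu_turnover) = 0.7
  lo <- propagate("ace_2_13C", flux_params(gs = 0.3, acetate_uptake = 1))
  hi <- propagate("ace_2_13C", flux_params(gs = 1.6, acetate_uptake = 1))
  expect_lt(lo$Gln[["c4"]], lo$Glu[["c4"]])
  expect_gt(hi$Gln[["c4"]], hi$Glu[["c4"]])
})

test_that("invalid flux parameters and non-label configurations are rejected", {
  expect_error(flux_params(pdh = -1), ">= 0")
  expect_error(flux_params(scrambling = 2), "scrambling")
  expect_error(propagate("ace_2_13C", flux_params(pdh = 0, acetate_uptake = 0)),
               "pdh")
})

test_that("predicted ROI volumes follow pool x max(fraction, natural abundance)", {
  p <- propagate("glc_1_13C", flux_params())
  pools <- c("Lac C3" = 10, "Lac C2" = 20, "Cr CH3" = 5)
  v <- predict_roi_volumes(p, pools)
  fr <- profile_fractions(p)
  expect_equal(v$volume[v$roi == "Lac C3"], 10 * (0.011 + fr[["Lac C3"]]))
  expect_equal(v$volume[v$roi == "Cr CH3"], 5 * 0.011)   # pool-only position
  v2 <- predict_roi_volumes(p, pools * 2)
  expect_equal(v2$volume, v$volume * 2)
  expect_error(predict_roi_volumes(p, pools, allow_unlabeled = FALSE),
               "missing from the profile")
  # with overwhelming mitochondrial dilution, TCA-cycle positions fall back
  # to the CTR (natural abundance) expectation
  pna <- propagate("glc_1_13C", flux_params(dilution_unlabeled = 1e9))
  pools_tca <- c("Glu C4" = 10, "Gln C4" = 20, "Cr CH3" = 5)
  vna <- predict_roi_volumes(pna, pools_tca)
  expect_equal(vna$volume, unname(pools_tca) * 0.011, tolerance = 1e-5)
})

test_that("acetate default fluxes put most label in the TCA-cycle products", {
  p <- propagate("ace_2_13C", default_flux_params("ace_2_13C", "brain_cortex"))
  glx <- sum(p$Glu) + sum(p$Gln)
  expect_gt(glx, p$Lac[["c3"]] + p$Ala[["c3"]])
  expect_gt(p$Gln[["c4"]], p$Glu[["c4"]])  # glial acetate -> glutamine
})
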