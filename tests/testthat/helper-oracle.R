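# Independent oracles used by the tests.
#
# mc_propagate: molecule-by-molecule Monte-Carlo simulator of the same flux
# network as propagate(), drawing every molecule's full carbon ancestry
# independently (no shared pools), so estimates are genuinely independent
# Bernoulli draws and binomial standard errors apply.

mc_propagate <- function(substrate, flux, n_mol = 1e5, n_turns = 2) {
  glc_c1 <- if (substrate == "glc_1_13C") 1 else 0
  ace_c2 <- if (substrate == "ace_2_13C") 1 else 0
  g <- flux$glycolysis; me <- flux$me; pdh <- flux$pdh
  au <- flux$acetate_uptake; d <- flux$dilution_unlabeled
  pc <- flux$pc; s <- flux$scrambling
  v_cs <- pdh + au + d
  v_ret <- v_cs - me

  draw_pyr <- function(n, t) {
    c2 <- logical(n); c3 <- logical(n)
    if (n == 0 || t < 1) return(list(c2 = c2, c3 = c3))
    from_gly <- stats::runif(n) < g / (g + me)
    n_gly <- sum(from_gly)
    c3[from_gly] <- stats::runif(n_gly) < 0.5 * glc_c1
    n_me <- n - n_gly
    if (n_me > 0) {
      m <- draw_mal(n_me, t - 1)
      c2[!from_gly] <- m$c2; c3[!from_gly] <- m$c3
    }
    list(c2 = c2, c3 = c3)
  }
  draw_accoa <- function(n, t) {
    c1 <- logical(n); c2 <- logical(n)
    if (n == 0 || t < 1) return(list(c1 = c1, c2 = c2))
    src <- sample.int(3, n, replace = TRUE, prob = c(pdh, au, d))
    n1 <- sum(src == 1)
    if (n1 > 0) {
      p <- draw_pyr(n1, t)
      c2[src == 1] <- p$c3; c1[src == 1] <- p$c2
    }
    c2[src == 2] <- stats::runif(sum(src == 2)) < ace_c2
    list(c1 = c1, c2 = c2)
  }
  draw_akg <- function(n, t) {
    if (n == 0 || t < 1) return(list(c2 = logical(n), c3 = logical(n),
                                     c4 = logical(n)))
    o <- draw_oaa(n, t - 1)
    ac <- draw_accoa(n, t)
    list(c2 = o$c3, c3 = o$c2, c4 = ac$c2)
  }
  draw_mal <- function(n, t) {
    if (n == 0 || t < 1) return(list(c2 = logical(n), c3 = logical(n)))
    a <- draw_akg(n, t)
    flip <- stats::runif(n) < 0.5        # molecular symmetry of succinate
    list(c2 = ifelse(flip, a$c4, a$c3), c3 = ifelse(flip, a$c3, a$c4))
  }
  draw_oaa <- function(n, t) {
    c2 <- logical(n); c3 <- logical(n)
    if (n == 0 || t < 1) return(list(c2 = c2, c3 = c3))
    src <- sample.int(3, n, replace = TRUE, prob = c(v_ret, pc, d))
    n1 <- sum(src == 1)
    if (n1 > 0) {
      m <- draw_mal(n1, t)
      c2[src == 1] <- m$c2; c3[src == 1] <- m$c3
    }
    n2 <- sum(src == 2)
    if (n2 > 0) {
      p <- draw_pyr(n2, t)
      c2[src == 2] <- p$c2; c3[src == 2] <- p$c3
    }
    # fumarate back-exchange randomizes the orientation of a fraction s
    flip <- (stats::runif(n) < s) & (stats::runif(n) < 0.5)
    tmp <- c2[flip]; c2[flip] <- c3[flip]; c3[flip] <- tmp
    list(c2 = c2, c3 = c3)
  }

  pyr <- draw_pyr(n_mol, n_turns)
  akg <- draw_akg(n_mol, n_turns)
  gln_p <- if (flux$gs + flux$gln_exchange > 0)
    flux$gs / (flux$gs + flux$gln_exchange) else 0
  new_glu <- stats::runif(n_mol) < flux$glu_turnover
  new_gln <- stats::runif(n_mol) < gln_p
  list(
    Lac = c(c2 = mean(pyr$c2), c3 = mean(pyr$c3)),
    Glu = c(c2 = mean(akg$c2 & new_glu), c3 = mean(akg$c3 & new_glu),
            c4 = mean(akg$c4 & new_glu)),
    Gln = c(c2 = mean(akg$c2 & new_gln), c3 = mean(akg$c3 & new_gln),
            c4 = mean(akg$c4 & new_gln)),
    n_mol = n_mol)
}

mc_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)

# numeric integral of a unit-area Lorentzian over a window (oracle for the
# windowed-integration quantifiers; written independently of the package)
oracle_lorentz_window <- function(lo, hi, center, fwhm_ppm) {
  f <- function(x) (fwhm_ppm / (2 * pi)) / ((x - center)^2 + (fwhm_ppm / 2)^2)
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
}
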