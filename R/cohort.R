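#' Configuration for one experimental group of the synthetic cohort
#'
#' Models the uterine-horn ligation design: each mother carries an AGA
#' (control) horn and, except in the non-infused CTR group, an FGR (ligated)
#' horn. Stillbirth is Bernoulli per fetus; birth and placental weights are
#' truncated normals (>= 5 g and >= 0.5 g respectively).
#'
#' Default weight distributions are the reported live-pup summaries
#' (AGA 47.2 +/- 7.1 g, FGR 34.9 +/- 7.2 g; placentas 5.6 +/- 1.3 vs
#' 4.5 +/- 1.5 g) and default stillbirth probabilities are the reported rates
#' (55% FGR, 14% AGA).
#'
#' @param group `"CTR"`, `"GLC"` or `"ACE"`.
#' @param n_mothers Mothers in the group.
#' @param fetuses_per_horn Named count vector `c(aga = , fgr = )`.
#' @param stillbirth_prob_fgr,stillbirth_prob_aga Bernoulli stillbirth
#'   probabilities per fetus.
#' @param birthweight_aga,birthweight_fgr,placental_aga,placental_fgr
#'   Length-2 `c(mean, sd)` in grams.
#' @param net_tissue_weight `c(mean, sd)` of net tissue per rotor (mg).
#' @param seed Master seed; identical seed gives an identical cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group = c("GLC", "ACE", "CTR"), n_mothers = 3,
                          fetuses_per_horn = c(aga = 5, fgr = 7),
                          stillbirth_prob_fgr = 0.55, stillbirth_prob_aga = 0.14,
                          birthweight_aga = c(47.2, 7.1),
                          birthweight_fgr = c(34.9, 7.2),
                          placental_aga = c(5.6, 1.3),
                          placental_fgr = c(4.5, 1.5),
                          net_tissue_weight = c(49.7, 3.0),
                          seed = 1L) {
  group <- match.arg(group)
  probs <- c(stillbirth_prob_fgr, stillbirth_prob_aga)
  if (any(probs < 0 | probs > 1)) stop("stillbirth probabilities must be in [0, 1]")
  if (n_mothers < 1 || any(fetuses_per_horn < 1)) stop("counts must be >= 1")
  sds <- c(birthweight_aga[2], birthweight_fgr[2], placental_aga[2],
           placental_fgr[2], net_tissue_weight[2])
  if (any(sds < 0)) stop("SDs must be >= 0")
  structure(list(group = group, n_mothers = as.integer(n_mothers),
                 fetuses_per_horn = fetuses_per_horn,
                 stillbirth_prob_fgr = stillbirth_prob_fgr,
                 stillbirth_prob_aga = stillbirth_prob_aga,
                 birthweight_aga = birthweight_aga,
                 birthweight_fgr = birthweight_fgr,
                 placental_aga = placental_aga,
                 placental_fgr = placental_fgr,
                 net_tissue_weight = net_tissue_weight,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic per-unit RNG substream: cohorts are extensible without
# reshuffling earlier draws
.unit_seed <- function(master, index) {
  as.integer((as.double(master) * 1000003 + as.double(index) * 7919) %% 2147483629)
}

.rtruncnorm1 <- function(mean, sd, lower) {
  if (sd == 0) return(max(mean, lower))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
  lower
}

#' Generate the fetus table for one experimental group
#'
#' Stillborn fetuses are excluded from the returned table (they are counted in
#' the `stillbirths` attribute). Horns in which no fetus survived are flagged
#' in the `empty_horns` attribute rather than raising an error. CTR mothers
#' carry an AGA horn only.
#'
#' @param config A [cohort_config()].
#' @return Data frame of live fetuses (`fetus_id`, `mother_id`, `group`,
#'   `horn`, `birthweight_g`, `placental_weight_g`), with attributes
#'   `stillbirths` (per-horn counts) and `empty_horns`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  horns <- if (config$group == "CTR") "AGA" else c("AGA", "FGR")
  rows <- list()
  still <- c(AGA = 0L, FGR = 0L)
  total <- c(AGA = 0L, FGR = 0L)
  empty <- list()
  idx <- 0L
  for (m in seq_len(config$n_mothers)) {
    mother_id <- sprintf("%s_M%02d", config$group, m)
    for (horn in horns) {
      n_f <- unname(config$fetuses_per_horn[[tolower(horn)]])
      p_still <- if (horn == "FGR") config$stillbirth_prob_fgr else config$stillbirth_prob_aga
      bw <- if (horn == "FGR") config$birthweight_fgr else config$birthweight_aga
      pw <- if (horn == "FGR") config$placental_fgr else config$placental_aga
      survivors <- 0L
      for (f in seq_len(n_f)) {
        idx <- idx + 1L
        set.seed(.unit_seed(config$seed, idx))
        total[horn] <- total[horn] + 1L
        if (stats::runif(1) < p_still) {
          still[horn] <- still[horn] + 1L
          next
        }
        survivors <- survivors + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          fetus_id = sprintf("%s_%s_F%02d", mother_id, horn, f),
          mother_id = mother_id, group = config$group, horn = horn,
          birthweight_g = .rtruncnorm1(bw[1], bw[2], 5),
          placental_weight_g = .rtruncnorm1(pw[1], pw[2], 0.5),
          stringsAsFactors = FALSE)
      }
      if (survivors == 0L) {
        empty[[length(empty) + 1L]] <- data.frame(mother_id = mother_id,
                                                  horn = horn,
                                                  stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fetus_id = character(), mother_id = character(),
               group = character(), horn = character(),
               birthweight_g = numeric(), placental_weight_g = numeric())
  rownames(out) <- NULL
  attr(out, "stillbirths") <- data.frame(horn = names(still),
                                         stillborn = as.integer(still),
                                         total = as.integer(total))
  attr(out, "empty_horns") <- if (length(empty)) do.call(rbind, empty) else NULL
  out
}

#' Expand live fetuses into rotor-loaded tissue samples
#'
#' Each fetus yields at most one brain-cortex and one heart-apex sample. The
#' rotor bookkeeping uses a constant empty-rotor weight and the constant
#' 2.22 mg D2O addition, so `net = rotor_total - empty_rotor - 2.22 > 0`.
#'
#' @param fetuses Output of [make_cohort()] (or a subset of it).
#' @param config The [cohort_config()] used (for weights and seed).
#' @param tissues Tissues sampled per fetus.
#' @param empty_rotor_mg Constant empty-rotor weight.
#' @return Sample manifest data frame (one row per sample).
#' @export
make_samples <- function(fetuses, config,
                         tissues = c("brain_cortex", "heart_apex"),
                         empty_rotor_mg = 550) {
  rows <- lapply(seq_len(nrow(fetuses)), function(i) {
    set.seed(.unit_seed(config$seed + 7L, i))
    net <- vapply(tissues, function(t) {
      .rtruncnorm1(config$net_tissue_weight[1], config$net_tissue_weight[2], 5)
    }, numeric(1))
    data.frame(sample_id = paste0(fetuses$fetus_id[i], "_",
                                  substr(tissues, 1, 1), seq_along(tissues)),
               fetus_id = fetuses$fetus_id[i], mother_id = fetuses$mother_id[i],
               group = fetuses$group[i], horn = fetuses$horn[i],
               tissue = tissues,
               rotor_total_weight_mg = empty_rotor_mg + 2.22 + net,
               d2o_weight_mg = 2.22, net_tissue_weight_mg = net,
               birthweight_g = fetuses$birthweight_g[i],
               placental_weight_g = fetuses$placental_weight_g[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the HRMAS sub-cohort used by the study design
#'
#' Randomly selects fetuses per group/horn to match the published design
#' (CTR: 3 AGA; GLC and ACE: 6 AGA + 6 FGR each) and optionally drops samples
#' at random to mirror rotor-loading failures.
#'
#' @param fetuses Combined fetus table across groups.
#' @param design Data frame `group`, `horn`, `n`; default the published
#'   sub-cohort counts.
#' @param seed Selection seed.
#' @return The selected fetus rows.
#' @export
select_hrmas_subcohort <- function(fetuses,
                                   design = data.frame(
                                     group = c("CTR", "GLC", "GLC", "ACE", "ACE"),
                                     horn = c("AGA", "AGA", "FGR", "AGA", "FGR"),
                                     n = c(3L, 6L, 6L, 6L, 6L)),
                                   seed = 1L) {
  picks <- lapply(seq_len(nrow(design)), function(i) {
    pool <- fetuses[fetuses$group == design$group[i] & fetuses$horn == design$horn[i], ]
    if (nrow(pool) < design$n[i]) {
      stop(sprintf("not enough live %s/%s fetuses (%d < %d)",
                   design$group[i], design$horn[i], nrow(pool), design$n[i]))
    }
    set.seed(.unit_seed(seed + 13L, i))
    pool[sample.int(nrow(pool), design$n[i]), ]
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

#' Read / write a sample manifest CSV
#'
#' @param manifest Sample manifest data frame from [make_samples()].
#' @param file CSV path.
#' @export
write_manifest <- function(manifest, file) {
  utils::write.csv(manifest, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
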