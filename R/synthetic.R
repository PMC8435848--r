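# Synthetic experiment generator.
#
# All invented ground-truth constants live in default_ground_truth() so that
# sensitivity runs have a single source of truth. Values are chosen to place
# the dynamics in realistic ranges for coastal diatom/dinoflagellate
# cultures: batch maximal growth rates 0.3-1.2 /d, carrying capacities
# 10-300 x1e4 cells/mL, per-cell quotas of order 1e2-1e4 fmol.

#' Ground truth of the synthetic factorial experiment
#'
#' Parameter surfaces and chemical signatures that the generator uses:
#' intrinsic growth rates per temperature, carrying capacities per nutrient
#' level, the interaction-coefficient surfaces over temperature and nitrate,
#' per-cell C/N/P quotas, and per-cell lipid signatures. The alpha surface
#' is positive at low nutrient concentrations (dinoflagellate superiority),
#' negative at high concentrations (diatom superiority), and turns positive
#' again only at 24 degrees C and the highest nitrate concentrations; its
#' amplitude over the design's nitrate span decreases with temperature.
#' The diatom has the lower cellular N:P quota, carries
#' brassicasterol but no dinosterol, and is enriched in 16:1n-7 and EPA;
#' the dinoflagellate carries dinosterol and is enriched in DHA.
#'
#' @return List of class `ground_truth`.
#' @export
default_ground_truth <- function() {
  fa_diatom <- setNames(c(
    0.50, 1.00, 1.80, 0.35, 0.30, 1.30, 0.30,      # seven major components
    rep(0.02, 15)
  ), FA_NAMES)
  fa_dino <- setNames(c(
    2.0, 8.0, 0.60, 2.5, 1.2, 2.0, 6.5,
    rep(0.20, 15)
  ), FA_NAMES)
  structure(list(
    # intrinsic growth rates (1/d) by temperature (degC); the diatom peaks
    # near 18-20 degC and declines above its optimum, the dinoflagellate
    # keeps increasing toward 24 degC
    r_diatom = c("12" = 0.60, "18" = 0.90, "24" = 0.70),
    r_dino = c("12" = 0.30, "18" = 0.45, "24" = 0.55),
    # carrying capacities (1e4 cells/mL) by nutrient level
    K_diatom = c(low = 30, normal = 100, high = 250),
    K_dino = c(low = 10, normal = 30, high = 80),
    # alpha(T, x) = a0 - a1 log10(x) + a2 max(0, log10(x) - knot)^2,
    # x = nitrate (umol/L); a2 > 0 only at 24 degC
    alpha_coef = list(
      "12" = c(a0 = 2.5, a1 = 1.2, a2 = 0),
      "18" = c(a0 = 1.6, a1 = 0.8, a2 = 0),
      "24" = c(a0 = 1.0, a1 = 0.5, a2 = 2.2)
    ),
    alpha_knot = 3.0,
    # beta(T, x) = b0(T) + b1 log10(x): weak, positive diatom-on-dino effect
    beta_coef = list(
      "12" = c(b0 = 0.60, b1 = -0.05),
      "18" = c(b0 = 0.50, b1 = -0.05),
      "24" = c(b0 = 0.40, b1 = -0.05)
    ),
    # per-cell quotas, fmol/cell; diatom N:P quota (10.6) < dino (18.3)
    quota_diatom = c(C = 800, N = 106, P = 10),
    quota_dino = c(C = 8000, N = 1100, P = 60),
    # lipid signatures, ug per 1e6 cells
    fa_diatom = fa_diatom,
    fa_dino = fa_dino,
    brassicasterol_diatom = 0.60, dinosterol_diatom = 0,
    brassicasterol_dino = 0, dinosterol_dino = 2.2,
    # supply-N:P modifier of the cellular N quota at the two lower nutrient
    # levels (luxury N uptake saturates at the high level)
    np_quota_slope = 0.004, np_quota_ref = 24,
    # temperature modifier of the EPA signature (per degC from 18)
    epa_temp_slope = 0.02, epa_temp_ref = 18
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic-experiment ground truth\n")
  cat("  r_diatom:", paste(sprintf("%g/d@%sC", x$r_diatom,
                                   names(x$r_diatom)), collapse = " "), "\n")
  cat("  r_dino:  ", paste(sprintf("%g/d@%sC", x$r_dino,
                                   names(x$r_dino)), collapse = " "), "\n")
  cat("  K_diatom:", paste(sprintf("%s=%g", names(x$K_diatom), x$K_diatom),
                           collapse = " "), " (1e4 cells/mL)\n")
  cat("  alpha surface: a0 - a1*log10(nitrate) + a2*max(0, log10 - knot)^2\n")
  invisible(x)
}

#' True interaction coefficient alpha over the design surface
#'
#' Parametric surface `alpha(T, x) = a0(T) - a1(T) log10(x) +
#' a2(T) max(0, log10(x) - knot)^2` with the quadratic rebound active only
#' at 24 degrees C, so that alpha decreases with nitrate at 12 and 18
#' degrees C but becomes positive again at the very highest nitrate
#' concentrations at 24 degrees C. The amplitude over the design's nitrate
#' span decreases with temperature.
#'
#' @param temperature one of 12, 18, 24 (degC).
#' @param nitrate nitrate concentration, umol/L; positive. Vectorized.
#' @param truth a `ground_truth` list.
#' @return True alpha value(s).
#' @export
alpha_surface <- function(temperature, nitrate,
                          truth = default_ground_truth()) {
  key <- as.character(temperature)
  if (length(key) != 1 || !key %in% names(truth$alpha_coef)) {
    stop_invalid("`temperature` must be one of 12, 18, 24")
  }
  if (any(!is.finite(nitrate)) || any(nitrate <= 0)) {
    stop_invalid("`nitrate` must be positive")
  }
  cf <- truth$alpha_coef[[key]]
  l <- log10(nitrate)
  cf["a0"] - cf["a1"] * l + cf["a2"] * pmax(0, l - truth$alpha_knot)^2
}

#' @rdname alpha_surface
#' @export
beta_surface <- function(temperature, nitrate,
                         truth = default_ground_truth()) {
  key <- as.character(temperature)
  if (length(key) != 1 || !key %in% names(truth$beta_coef)) {
    stop_invalid("`temperature` must be one of 12, 18, 24")
  }
  cf <- truth$beta_coef[[key]]
  unname(cf["b0"] + cf["b1"] * log10(nitrate))
}

#' True community parameters for one treatment
#'
#' @param treatment one row of [build_design()].
#' @param truth a `ground_truth` list.
#' @return A [community_params()] object.
#' @export
params_for_treatment <- function(treatment, truth = default_ground_truth()) {
  tkey <- as.character(treatment$temperature_C)
  lev <- treatment$nutrient_level
  community_params(
    r_diatom = unname(truth$r_diatom[tkey]),
    r_dino = unname(truth$r_dino[tkey]),
    K_diatom = unname(truth$K_diatom[lev]),
    K_dino = unname(truth$K_dino[lev]),
    alpha = unname(alpha_surface(treatment$temperature_C,
                                 treatment$nitrate_umol_L, truth)),
    beta = unname(beta_surface(treatment$temperature_C,
                               treatment$nitrate_umol_L, truth))
  )
}

#' Observation-noise configuration
#'
#' `counting_volume_ul` is the effective hemocytometer volume scored per
#' daily count; at the default 20 uL a density of 1 (1e4 cells/mL, i.e. 10
#' cells/uL) yields an expected count of 200 cells, hence a Poisson counting
#' CV of about 7%. `process_cv` is day-to-day multiplicative biological
#' variability of the latent density; `chemistry_cv` is per-analyte
#' multiplicative measurement error of the composition samples.
#'
#' @param counting_volume_ul effective counted volume, uL; positive.
#' @param process_cv,chemistry_cv coefficients of variation; non-negative.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(counting_volume_ul = 20, process_cv = 0.05,
                         chemistry_cv = 0.08) {
  if (counting_volume_ul <= 0) stop_invalid("`counting_volume_ul` must be > 0")
  if (process_cv < 0 || chemistry_cv < 0) stop_invalid("CVs must be >= 0")
  structure(list(counting_volume_ul = counting_volume_ul,
                 process_cv = process_cv, chemistry_cv = chemistry_cv),
            class = "noise_config")
}

# mean-one multiplicative lognormal factor
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a hemocytometer count of a culture density
#'
#' Optional multiplicative lognormal process noise is applied to the latent
#' density first; the counted cells are then Poisson with mean equal to the
#' latent density times the counted volume, and the observed density is the
#' count divided by the counted volume.
#'
#' @param true_density latent density, 1e4 cells/mL; non-negative
#'   (vectorized).
#' @param cfg a [noise_config()].
#' @return Observed densities, 1e4 cells/mL. Uses the global RNG stream.
#' @export
generate_counts <- function(true_density, cfg = noise_config()) {
  if (any(!is.finite(true_density)) || any(true_density < 0)) {
    stop_invalid("`true_density` must be finite and >= 0")
  }
  cells_per_unit <- 10 * cfg$counting_volume_ul  # 1 unit = 10 cells/uL
  latent <- true_density * lognormal_factor(length(true_density),
                                            cfg$process_cv)
  counts <- rpois(length(latent), latent * cells_per_unit)
  counts / cells_per_unit
}

#' Synthesize a steady-state composition sample from community densities
#'
#' Bulk pools are the density-weighted sums of the per-cell signatures
#' (two-end-member mixing), with the treatment's supply-N:P modifier applied
#' to cellular N at the two lower nutrient levels and the temperature
#' modifier applied to EPA, then multiplicative lognormal measurement error
#' per analyte.
#'
#' @param n_diatom,n_dino densities, 1e4 cells/mL; not both zero.
#' @param treatment one row of [build_design()].
#' @param truth a `ground_truth` list.
#' @param cfg a [noise_config()]; set `chemistry_cv = 0` for noiseless
#'   samples.
#' @return List with `poc`, `pon`, `pop` (umol/L), `fa` (named ug/L),
#'   `brassicasterol_epi`, `dinosterol` (ug/L), `filtered_volume_ml`.
#' @export
generate_composition <- function(n_diatom, n_dino, treatment,
                                 truth = default_ground_truth(),
                                 cfg = noise_config()) {
  if (any(!is.finite(c(n_diatom, n_dino))) || n_diatom < 0 || n_dino < 0) {
    stop_invalid("densities must be finite and >= 0")
  }
  if (n_diatom == 0 && n_dino == 0) {
    stop_invalid("at least one species must be present")
  }
  # density unit 1e4 cells/mL = 1e7 cells/L: fmol/cell -> umol/L is x 0.01,
  # ug/1e6 cells -> ug/L is x 10
  nmod <- if (treatment$nutrient_level %in% c("low", "normal")) {
    1 + truth$np_quota_slope *
      (np_ratio_numeric(treatment$np_label) - truth$np_quota_ref)
  } else 1
  emod <- 1 + truth$epa_temp_slope *
    (treatment$temperature_C - truth$epa_temp_ref)

  q1 <- truth$quota_diatom; q2 <- truth$quota_dino
  poc <- 0.01 * (n_diatom * q1[["C"]] + n_dino * q2[["C"]])
  pon <- 0.01 * nmod * (n_diatom * q1[["N"]] + n_dino * q2[["N"]])
  pop <- 0.01 * (n_diatom * q1[["P"]] + n_dino * q2[["P"]])

  fa <- 10 * (n_diatom * truth$fa_diatom + n_dino * truth$fa_dino)
  fa["20:5n-3"] <- fa["20:5n-3"] * emod
  bra <- 10 * (n_diatom * truth$brassicasterol_diatom +
                 n_dino * truth$brassicasterol_dino)
  dino_sterol <- 10 * (n_diatom * truth$dinosterol_diatom +
                         n_dino * truth$dinosterol_dino)

  noise <- lognormal_factor(length(fa) + 5, cfg$chemistry_cv)
  fa <- fa * noise[seq_along(fa)]
  rest <- noise[length(fa) + 1:5]
  list(
    poc = poc * rest[1], pon = pon * rest[2], pop = pop * rest[3],
    fa = fa, brassicasterol_epi = bra * rest[4],
    dinosterol = dino_sterol * rest[5],
    filtered_volume_ml = 20
  )
}

# deterministic per-unit RNG substream (kept below 2^31)
substream_seed <- function(seed, unit, stage = 0) {
  ((abs(seed) %% 1000003) * 1831 + unit * 131 + stage * 17) %% 2147483629
}

# first day of early stationary phase: daily log growth < threshold
early_stationary_day <- function(traj, column = "n_diatom",
                                 threshold = 0.05) {
  n <- traj[[column]]
  g <- diff(log(pmax(n, DETECTION_FLOOR)))
  idx <- which(g < threshold)
  if (!length(idx)) length(n) - 1 else traj$day[idx[1] + 1]
}

#' Generate a complete synthetic competition experiment
#'
#' For every treatment of the factorial design and each of three replicates,
#' simulates the batch phase of the two monocultures and the biculture,
#' estimates the batch maximal growth rate from the noiseless latent
#' trajectory, switches to the semi-continuous phase at early stationary
#' (judged on the diatom in bicultures, per protocol) with the renewal
#' fraction `D = 1 - exp(-0.2 mu_max)`, applies daily hemocytometer counting
#' noise to the recorded densities, and emits a steady-state composition
#' sample per culture. Replicate variability enters through lognormal
#' perturbation of the initial densities plus the counting/process noise.
#'
#' @param truth a `ground_truth` list.
#' @param cfg a [noise_config()].
#' @param seed integer seed; the full output is bit-reproducible from
#'   `(truth, cfg, seed)`.
#' @param design the treatment table (default [build_design()]).
#' @param days_semi length of the semi-continuous phase, days (>= 20).
#' @param batch_max longest allowed batch phase, days.
#' @param step RK4 integration step, days.
#' @param noiseless if `TRUE`, all noise terms are disabled (the latent
#'   dynamics are reported exactly).
#' @return List of class `synthetic_experiment` with `design`,
#'   `trajectories`, `composition`, `units` (per-culture metadata including
#'   the true alpha/beta and the renewal fraction used), `truth`,
#'   `provenance`.
#' @export
generate_experiment <- function(truth = default_ground_truth(),
                                cfg = noise_config(), seed = 1,
                                design = build_design(), days_semi = 25,
                                batch_max = 30, step = 0.01,
                                noiseless = FALSE) {
  if (days_semi < 20) stop_invalid("`days_semi` must be >= 20")
  if (noiseless) cfg <- noise_config(cfg$counting_volume_ul, 0, 0)

  traj_list <- list(); comp_list <- list(); unit_list <- list()
  unit_counter <- 0L

  for (ti in seq_len(nrow(design))) {
    tr <- design[ti, ]
    pars <- params_for_treatment(tr, truth)
    for (rep_i in 1:3) {
      for (ctype in c("mono_diatom", "mono_dino", "biculture")) {
        unit_counter <- unit_counter + 1L
        set.seed(substream_seed(seed, unit_counter))
        culture_id <- sprintf("%s_%s_rep%d", tr$id, ctype, rep_i)

        jit <- if (noiseless) c(1, 1) else lognormal_factor(2, 0.1)
        n0 <- switch(ctype,
          mono_diatom = c(0.5 * jit[1], 0),
          mono_dino = c(0, 0.5 * jit[2]),
          biculture = c(0.5 * jit[1], 0.5 * jit[2])
        )
        batch <- simulate_batch(pars, n0[1], n0[2], batch_max, step)
        ref_col <- if (ctype == "mono_dino") "n_dino" else "n_diatom"
        switch_day <- early_stationary_day(batch, ref_col)
        switch_day <- max(switch_day, 5)  # guarantee a usable batch window
        batch <- batch[batch$day <= switch_day, ]

        # mu_max from the noiseless latent batch series of the reference
        # species (the diatom sets D in bicultures)
        mu_sp <- if (ctype == "mono_dino") "dino" else "diatom"
        mu_max <- estimate_mu_max(batch, mu_sp)$mu_max
        mu <- gross_growth_target(max(mu_max, 0))
        D <- renewal_rate(mu, 1)

        last <- batch[nrow(batch), ]
        semi <- simulate_semicontinuous(pars, last$n_diatom, last$n_dino,
                                        D, days_semi, step)
        semi$day <- semi$day + switch_day

        latent <- rbind(
          data.frame(batch, stringsAsFactors = FALSE),
          data.frame(semi[-1, ], stringsAsFactors = FALSE)
        )
        obs1 <- generate_counts(latent$n_diatom, cfg)
        obs2 <- generate_counts(latent$n_dino, cfg)
        if (noiseless) { obs1 <- latent$n_diatom; obs2 <- latent$n_dino }

        traj_list[[unit_counter]] <- data.frame(
          culture_id = culture_id, treatment_id = tr$id,
          culture_type = ctype, replicate = rep_i,
          day = latent$day, phase = latent$phase,
          post_dilution = latent$post_dilution,
          n_diatom = obs1, n_dino = obs2,
          n_diatom_latent = latent$n_diatom, n_dino_latent = latent$n_dino,
          stringsAsFactors = FALSE
        )

        # steady-state latent densities (final post-dilution state)
        fin <- latent[nrow(latent), ]
        washout <- fin$n_diatom <= DETECTION_FLOOR &
          fin$n_dino <= DETECTION_FLOOR
        comp <- if (!washout) {
          generate_composition(max(fin$n_diatom, 0), max(fin$n_dino, 0),
                               tr, truth, cfg)
        } else NULL
        if (!is.null(comp)) {
          comp_list[[length(comp_list) + 1L]] <- data.frame(
            culture_id = culture_id, treatment_id = tr$id,
            culture_type = ctype, replicate = rep_i,
            poc_umol_L = comp$poc, pon_umol_L = comp$pon,
            pop_umol_L = comp$pop,
            as.list(setNames(comp$fa, fa_col(names(comp$fa)))),
            brassicasterol_ug_L = comp$brassicasterol_epi,
            dinosterol_ug_L = comp$dinosterol,
            # steady-state densities as observed (counted), not latent:
            # a washed-out competitor yields a zero count and the unit
            # drops out of ratio-based analyses, as in real count data
            n_diatom_ss = obs1[length(obs1)], n_dino_ss = obs2[length(obs2)],
            stringsAsFactors = FALSE, check.names = FALSE
          )
        }

        unit_list[[unit_counter]] <- data.frame(
          culture_id = culture_id, treatment_id = tr$id,
          culture_type = ctype, replicate = rep_i,
          mu_max = mu_max, mu_target = mu, D = D,
          batch_end_day = switch_day, washout = washout,
          alpha_true = pars$alpha, beta_true = pars$beta,
          r_diatom_true = pars$r_diatom, r_dino_true = pars$r_dino,
          K_diatom_true = pars$K_diatom, K_dino_true = pars$K_dino,
          stringsAsFactors = FALSE
        )
      }
    }
  }

  structure(list(
    design = design,
    trajectories = do.call(rbind, traj_list),
    composition = do.call(rbind, comp_list),
    units = do.call(rbind, unit_list),
    truth = truth,
    provenance = list(seed = seed, noise = unclass(cfg),
                      days_semi = days_semi, batch_max = batch_max,
                      step = step, noiseless = noiseless,
                      version = as.character(utils::packageVersion("bicompete")))
  ), class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic bi-algal competition experiment\n")
  cat(sprintf("  %d treatments x 3 replicates: %d culture units\n",
              nrow(x$design), nrow(x$units)))
  cat(sprintf("  trajectories: %d daily records; composition samples: %d\n",
              nrow(x$trajectories), nrow(x$composition)))
  cat(sprintf("  seed %s, noiseless = %s\n", x$provenance$seed,
              x$provenance$noiseless))
  invisible(x)
}

#' Write a synthetic experiment to plain-text fixture files
#'
#' Writes `design.csv`, `trajectory.csv`, `composition.csv`, `units.csv`,
#' `ground_truth.json` and `manifest.json` (seed, configuration and a hash
#' of both) into `directory`.
#'
#' @param experiment a `synthetic_experiment`.
#' @param directory output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(experiment, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_design(experiment$design, p("design.csv"))
  traj <- experiment$trajectories
  traj_out <- data.frame(
    culture_id = traj$culture_id, day = traj$day, phase = traj$phase,
    post_dilution = traj$post_dilution,
    n_diatom_1e4_per_ml = traj$n_diatom,
    n_dino_1e4_per_ml = traj$n_dino,
    stringsAsFactors = FALSE
  )
  write.csv(traj_out, p("trajectory.csv"), row.names = FALSE, quote = FALSE)
  write.csv(experiment$composition, p("composition.csv"), row.names = FALSE)
  write.csv(experiment$units, p("units.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(experiment$truth), p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_json <- jsonlite::toJSON(experiment$provenance, auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    seed = experiment$provenance$seed,
    config = experiment$provenance,
    config_hash = unname(tools::md5sum(tmp))
  )
  unlink(tmp)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(directory)
}
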