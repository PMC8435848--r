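# Shared fixtures, all generated in code.

# reference community used across inference tests: diatom faster and denser
# than the dinoflagellate, as in the study system
ref_params <- function(alpha = 0, beta = 0) {
  community_params(r_diatom = 0.9, r_dino = 0.45,
                   K_diatom = 100, K_dino = 30,
                   alpha = alpha, beta = beta)
}

# monoculture logistic trajectory as a plain data.frame
logistic_traj <- function(r, K, n0, days, species = "diatom") {
  day <- 0:days
  n <- closed_form_logistic(r, K, n0, day)
  out <- data.frame(day = day, phase = "batch", post_dilution = FALSE,
                    n_diatom = 0, n_dino = 0)
  out[[paste0("n_", species)]] <- n
  out
}

# full single-unit protocol: batch biculture -> D from the diatom's mu_max
# -> semi-continuous phase; optionally noisy counts
run_biculture <- function(alpha_true, beta_true = 0.3, noise_cfg = NULL,
                          days_semi = 25) {
  p <- ref_params(alpha_true, beta_true)
  bb <- simulate_batch(p, 0.5, 0.5, 15)
  mu <- gross_growth_target(estimate_mu_max(bb, "diatom")$mu_max)
  D <- renewal_rate(mu)
  last <- bb[nrow(bb), ]
  s <- simulate_semicontinuous(p, last$n_diatom, last$n_dino, D, days_semi)
  if (!is.null(noise_cfg)) {
    s$n_diatom <- generate_counts(s$n_diatom, noise_cfg)
    s$n_dino <- generate_counts(s$n_dino, noise_cfg)
  }
  s
}

# monoculture growth fits of the reference community, optionally noisy
ref_mono_fits <- function(noise_cfg = NULL) {
  pm <- ref_params()
  b1 <- simulate_batch(pm, 0.5, 0, 20)
  b2 <- simulate_batch(pm, 0, 0.5, 30)
  if (!is.null(noise_cfg)) {
    b1$n_diatom <- generate_counts(b1$n_diatom, noise_cfg)
    b2$n_dino <- generate_counts(b2$n_dino, noise_cfg)
  }
  list(diatom = fit_logistic_mono(b1, "diatom"),
       dino = fit_logistic_mono(b2, "dino"))
}

# end-to-end alpha/beta recovery for one true alpha
recover_interaction <- function(alpha_true, beta_true = 0.3,
                                noise_cfg = NULL, fits = NULL) {
  s <- run_biculture(alpha_true, beta_true, noise_cfg)
  if (is.null(fits)) fits <- ref_mono_fits(noise_cfg)
  estimate_interaction(per_capita_rates(s), fits$diatom, fits$dino)
}
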