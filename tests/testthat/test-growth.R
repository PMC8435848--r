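test_that("mu_max is the log-linear slope of the exponential phase", {
  # exact exponential: slope recovered to near machine precision
  tr <- data.frame(day = 0:6, n_diatom = 2 * exp(0.4 * (0:6)), n_dino = 0)
  fit <- estimate_mu_max(tr, "diatom")
  expect_lt(abs(fit$mu_max - 0.4), 1e-12)
  expect_equal(fit$window, c(0, 6))  # ties resolved to earlier/longer

  # constant series
  const <- data.frame(day = 0:6, n_diatom = rep(3, 7), n_dino = 0)
  expect_equal(estimate_mu_max(const, "diatom")$mu_max, 0)

  # logistic trajectory: early window gives mu_max close to r
  p <- community_params(0.8, 0.4, 100, 40, 0, 0)
  traj <- simulate_batch(p, 0.5, 0, 25)
  est <- estimate_mu_max(traj, "diatom")$mu_max
  expect_lt(abs(est - 0.8) / 0.8, 0.1)

  expect_error(estimate_mu_max(const[1:3, ], "diatom"),
               class = "bicompete_insufficient_data")
})

test_that("logistic fits recover noiseless parameters almost exactly", {
  tr <- logistic_traj(0.6, 80, 1, 20)
  fit <- fit_logistic_mono(tr, "diatom")
  expect_lt(abs(fit$r - 0.6), 1e-6)
  expect_lt(abs(fit$K - 80), 1e-4)
  expect_true(fit$r_se >= 0 || is.na(fit$r_se))
})

test_that("logistic fits are robust to 5% multiplicative noise", {
  day <- 0:20
  true <- closed_form_logistic(0.6, 80, 1, day)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    obs <- true * rlnorm(length(true), 0, sqrt(log(1 + 0.05^2)))
    tr <- data.frame(day = day, n_diatom = obs, n_dino = 0)
    f <- fit_logistic_mono(tr, "diatom")
    c(abs(f$r - 0.6) / 0.6, abs(f$K - 80) / 80)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("degenerate monoculture series signal a fit failure", {
  zero <- data.frame(day = 0:10, n_diatom = 0, n_dino = 0)
  expect_error(fit_logistic_mono(zero, "diatom"),
               class = "bicompete_fit_failure")
})

test_that("per-capita rates restore dilution losses", {
  # steady state: g equals -log(1-D), here exactly 0.2 /d
  D <- 1 - exp(-0.2)
  traj <- data.frame(day = 0:9, phase = "semicontinuous",
                     post_dilution = TRUE, n_diatom = 40, n_dino = 8)
  ser <- per_capita_rates(traj, D = D)
  expect_equal(unique(ser$per_capita_rate), 0.2)

  # D = 0: plain log difference
  traj2 <- data.frame(day = 0:3, phase = "semicontinuous",
                      post_dilution = TRUE,
                      n_diatom = c(1, 2, 4, 8), n_dino = 1)
  ser2 <- per_capita_rates(traj2, D = 0)
  expect_equal(ser2$per_capita_rate[ser2$species == "diatom"],
               rep(log(2), 3))

  # days at the detection floor are excluded and logged
  traj3 <- traj
  traj3$n_dino[5] <- 0
  ser3 <- per_capita_rates(traj3, D = D)
  excl <- attr(ser3, "excluded")
  expect_equal(nrow(excl), 2)  # both intervals touching the zero day
  expect_equal(sum(ser3$species == "diatom"), 7)
})

test_that("per-capita series matches the simulated growth term", {
  s <- run_biculture(alpha_true = 0.8)
  ser <- per_capita_rates(s)
  dia <- ser[ser$species == "diatom", ]
  p <- ref_params(0.8, 0.3)
  rhs <- p$r_diatom * (p$K_diatom - dia$n_diatom - p$alpha * dia$n_dino) /
    p$K_diatom
  # endpoint-based averages leave only a small curvature error
  expect_lt(max(abs(dia$per_capita_rate - rhs)), 0.02)
})

test_that("point-wise alpha follows the algebraic rearrangement", {
  ser <- data.frame(
    day = rep(1:3, 2), species = rep(c("diatom", "dino"), each = 3),
    per_capita_rate = 0, n_diatom = 50, n_dino = 25,
    stringsAsFactors = FALSE
  )
  fits <- list(r = 1, K = 100, r_se = NA_real_, K_se = NA_real_)
  est <- estimate_interaction(ser, fits, list(r = 1, K = 100,
                                              r_se = NA_real_,
                                              K_se = NA_real_),
                              refine = FALSE)
  expect_equal(est$alpha_pointwise, rep(2, 3))  # (100(1-0)-50)/25
})

test_that("noiseless bicultures recover the true interaction coefficients", {
  fits <- ref_mono_fits()
  est <- recover_interaction(0.5, 0.3, fits = fits)
  expect_lt(abs(est$alpha - 0.5), 0.01)
  expect_lt(abs(est$beta - 0.3), 0.01)

  # null community: estimates within 2 SE of zero
  est0 <- recover_interaction(0, 0, fits = fits)
  expect_lt(abs(est0$alpha), 2 * est0$alpha_se + 1e-6)
  expect_lt(abs(est0$beta), 2 * est0$beta_se + 1e-6)
})

test_that("interaction estimates are equivariant under density rescaling", {
  s <- run_biculture(1.2, 0.3)
  fits <- ref_mono_fits()
  est <- estimate_interaction(per_capita_rates(s), fits$diatom, fits$dino)
  # rescale densities and carrying capacities by the same factor
  f <- 10
  s2 <- s
  s2$n_diatom <- s$n_diatom * f
  s2$n_dino <- s$n_dino * f
  fits2 <- lapply(fits, function(g) {
    g$K <- g$K * f
    if (is.finite(g$K_se)) g$K_se <- g$K_se * f
    g
  })
  est2 <- estimate_interaction(per_capita_rates(s2), fits2$diatom,
                               fits2$dino)
  expect_equal(est2$alpha, est$alpha, tolerance = 1e-8)
  expect_equal(est2$beta, est$beta, tolerance = 1e-8)
})

test_that("interaction estimation demands competitor presence and data", {
  ser <- data.frame(
    day = rep(1:5, 2), species = rep(c("diatom", "dino"), each = 5),
    per_capita_rate = 0.1, n_diatom = 50, n_dino = 0,
    stringsAsFactors = FALSE
  )
  fits <- list(r = 1, K = 100, r_se = NA_real_, K_se = NA_real_)
  expect_error(estimate_interaction(ser, fits, fits, refine = FALSE),
               class = "bicompete_invalid_argument")
  expect_error(estimate_interaction(ser[c(1, 6), ], fits, fits,
                                    refine = FALSE),
               class = "bicompete_insufficient_data")
})

test_that("competitive superiority follows the sign of alpha", {
  expect_equal(classify_superiority(0.5), "dinoflagellate")
  expect_equal(classify_superiority(-0.3), "diatom")
  expect_equal(classify_superiority(0), "neutral")
  expect_equal(classify_superiority(0.05, tol = 0.1), "neutral")
  expect_error(classify_superiority(NaN),
               class = "bicompete_invalid_argument")
})
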