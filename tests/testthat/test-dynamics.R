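test_that("Lotka-Volterra derivatives reduce correctly in limiting cases", {
  p <- community_params(1, 0.5, 100, 40, alpha = 2, beta = 0.5)
  # no competitor: pure logistic term
  d <- lv_derivative(10, 0, p)
  expect_equal(unname(d["dn_diatom"]), 1 * 10 * (100 - 10) / 100)
  expect_equal(unname(d["dn_dino"]), 0)
  # logistic equilibrium
  expect_equal(unname(lv_derivative(100, 0, p)["dn_diatom"]), 0)
  # competition exactly cancels growth: K1 - N1 - alpha N2 = 0
  expect_equal(unname(lv_derivative(50, 25, p)["dn_diatom"]), 0)
  expect_error(lv_derivative(-1, 0, p),
               class = "bicompete_invalid_argument")
})

test_that("interaction-free RK4 matches the closed-form logistic", {
  for (r in c(0.2, 0.6, 1.2)) {
    p <- community_params(r, r, 100, 100, 0, 0)
    tr <- simulate_batch(p, 1, 0, 30)
    expected <- closed_form_logistic(r, 100, 1, tr$day)
    expect_lt(max(abs(tr$n_diatom - expected) / expected), 1e-6)
  }
})

test_that("RK4 agrees with an independent ODE solver on a biculture", {
  skip_if_not_installed("deSolve")
  p <- community_params(0.8, 0.4, 120, 50, alpha = 1.2, beta = 0.4)
  tr <- simulate_batch(p, 0.5, 0.5, 25)
  rhs <- function(t, y, parms) {
    list(c(p$r_diatom * y[1] * (p$K_diatom - y[1] - p$alpha * y[2]) /
             p$K_diatom,
           p$r_dino * y[2] * (p$K_dino - y[2] - p$beta * y[1]) / p$K_dino))
  }
  ref <- deSolve::ode(c(0.5, 0.5), 0:25, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$n_diatom - ref[, 2])), 1e-5)
  expect_lt(max(abs(tr$n_dino - ref[, 3])), 1e-5)
})

test_that("closed-form logistic hits its boundary values", {
  expect_equal(closed_form_logistic(0.5, 100, 3, 0), 3)
  expect_lt(abs(closed_form_logistic(0.5, 100, 1, 1e3) - 100), 1e-8)
  expect_equal(closed_form_logistic(0.5, 100, 1, 10),
               100 * exp(5) / (100 + (exp(5) - 1)))
})

test_that("an absent species stays absent and growth is monotone below K", {
  p <- community_params(0.7, 0.3, 80, 30, 1, 1)
  tr <- simulate_batch(p, 2, 0, 20)
  expect_true(all(tr$n_dino == 0))
  expect_true(all(diff(tr$n_diatom) > 0))
  expect_true(all(tr$n_diatom >= 0))
})

test_that("dilution scales densities and composes multiplicatively", {
  expect_equal(apply_dilution(c(10, 4), 0.5), c(5, 2))
  expect_equal(apply_dilution(c(10, 4), 0), c(10, 4))
  s <- c(7, 3)
  two <- apply_dilution(apply_dilution(s, 0.2), 0.3)
  one <- apply_dilution(s, 1 - (1 - 0.2) * (1 - 0.3))
  expect_equal(two, one)
  expect_error(apply_dilution(c(1, 1), 1),
               class = "bicompete_invalid_argument")
})

test_that("semi-continuous culture with D = 0 reproduces the batch run", {
  p <- community_params(0.6, 0.3, 60, 25, 0.5, 0.2)
  b <- simulate_batch(p, 1, 1, 15)
  s <- simulate_semicontinuous(p, 1, 1, 0, 15)
  post <- s[s$post_dilution, ]
  expect_equal(post$n_diatom, b$n_diatom)
  expect_equal(post$n_dino, b$n_dino)
})

test_that("monoculture under dilution settles where log growth balances D", {
  p <- community_params(0.9, 0.45, 100, 30, 0, 0)
  D <- renewal_rate(gross_growth_target(0.9))
  s <- simulate_semicontinuous(p, 50, 0, D, 60)
  post <- s[s$post_dilution & s$day > 0, ]
  g <- diff(log(post$n_diatom))
  expect_lt(abs(tail(g, 1) - 0), 1e-6)  # post-dilution fixed point
  ser <- per_capita_rates(s[s$day >= 40, ], D = D)
  expect_lt(max(abs(ser$per_capita_rate[ser$species == "diatom"] -
                      (-log(1 - D)))), 1e-6)
})

test_that("a species slower than the dilution loss washes out", {
  p <- community_params(0.1, 0.45, 1e6, 30, 0, 0)  # K not binding
  D <- 0.3  # -log(1-D) = 0.357 > r = 0.1
  s <- simulate_semicontinuous(p, 5, 0, D, 60)
  post <- s[s$post_dilution, ]
  expect_lt(tail(post$n_diatom, 1), 1e-4)
  expect_true(all(diff(log(post$n_diatom[post$n_diatom > 0])) < 0))
})

test_that("steady-state detection finds stable windows and rejects growth", {
  p <- community_params(0.9, 0.45, 100, 30, 0, 0)
  D <- renewal_rate(gross_growth_target(0.9))
  s <- simulate_semicontinuous(p, 50, 0, D, 40)
  day <- detect_steady_state(s, window = 5, cv_tol = 0.05)
  expect_true(is.finite(day))
  expect_lte(day, 40)

  # constant series: first eligible day is the window-th day
  const <- data.frame(day = 0:10, phase = "semicontinuous",
                      post_dilution = TRUE, n_diatom = 5, n_dino = 2)
  expect_equal(detect_steady_state(const, window = 5, cv_tol = 0.05), 5)

  # pure exponential growth never qualifies
  gro <- data.frame(day = 0:10, phase = "semicontinuous",
                    post_dilution = TRUE, n_diatom = 2^(0:10), n_dino = 1)
  expect_true(is.na(detect_steady_state(gro, window = 5, cv_tol = 0.05)))
  expect_error(detect_steady_state(const[1:3, ], window = 5),
               class = "bicompete_invalid_argument")
})

test_that("with alpha = beta = 0 the two species are fully decoupled", {
  p <- community_params(0.7, 0.35, 90, 40, 0, 0)
  a <- simulate_semicontinuous(p, 1, 1, 0.15, 20)
  b <- simulate_semicontinuous(p, 1, 7, 0.15, 20)  # perturb dino n0 only
  expect_identical(a$n_diatom, b$n_diatom)
})

test_that("raising alpha never raises the diatom's biculture density", {
  finals <- vapply(seq(-1, 3, by = 0.5), function(a) {
    p <- community_params(0.9, 0.45, 100, 30, a, 0.3)
    s <- simulate_semicontinuous(p, 50, 5, 0.15, 40)
    tail(s$n_diatom[s$post_dilution], 1)
  }, numeric(1))
  expect_true(all(diff(finals) <= 1e-9))
})

test_that("halving the integration step leaves day densities unchanged", {
  p <- community_params(1.2, 0.5, 100, 40, 1.5, 0.5)
  a <- simulate_batch(p, 0.5, 0.5, 20, step = 0.01)
  b <- simulate_batch(p, 0.5, 0.5, 20, step = 0.005)
  rel <- abs(a$n_diatom - b$n_diatom) / pmax(b$n_diatom, 1e-12)
  expect_lt(max(rel[-1]), 1e-6)
})

test_that("integrator trouble surfaces as a clamp warning, never silently", {
  p <- community_params(1, 0.5, 10, 30, alpha = 60, beta = 0)
  expect_warning(simulate_batch(p, 1, 10, 3, step = 0.1), "clamped")
})
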