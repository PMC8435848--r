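test_that("AICc matches the hand formula and its limits", {
  # -2l + 2k = 100 at k = 3, n = 20: correction 2*3*4/16 = 1.5
  ll <- -(100 - 2 * 3) / 2
  expect_equal(aicc(ll, 3, 20), 101.5)
  expect_equal(aicc(-50, 0, 10), 100)  # k = 0: just -2l
  expect_lt(abs(aicc(-50, 3, 1e9) - (100 + 6)), 1e-6)  # AIC limit
  expect_error(aicc(-50, 5, 6), class = "bicompete_invalid_argument")
})

test_that("AICc is monotone in loglik and in k", {
  lls <- seq(-60, -40, by = 5)
  expect_true(all(diff(vapply(lls, aicc, numeric(1), k = 3, n = 30)) < 0))
  ks <- 1:5
  expect_true(all(diff(vapply(ks, function(k) aicc(-50, k, 30),
                              numeric(1))) > 0))
})

test_that("GLM fits recover exact linear structure", {
  d <- expand.grid(temperature = c(12, 18, 24), np_ratio = c(10, 24, 63),
                   nitrate = c(100, 1000, 4000))
  d$y <- 2 + 0.5 * d$temperature - 0.02 * d$np_ratio + 0.001 * d$nitrate
  fit <- fit_glm(d, "y", order = 1)
  expect_equal(fit$coefficients$estimate,
               c(2, 0.5, -0.02, 0.001), tolerance = 1e-8)
  expect_true(all(fit$coefficients$p[-1] < 1e-8))

  # intercept-only model returns the response mean
  fit0 <- fit_glm(d, "y", terms = character(0))
  expect_equal(fit0$coefficients$estimate, mean(d$y))

  # rank-deficient designs are signalled with the aliased terms named
  d$nitrate2 <- d$nitrate
  expect_error(fit_glm(d, "y", terms = c("nitrate", "nitrate2")),
               class = "bicompete_invalid_argument")
})

test_that("GLM coefficients equal the brute-force normal-equation solve", {
  set.seed(11)
  d <- expand.grid(temperature = c(12, 24), np_ratio = c(10, 63),
                   nitrate = c(100, 4000))
  d <- d[rep(1:8, 3), ]
  d$y <- rnorm(nrow(d))
  fit <- fit_glm(d, "y", order = 1)
  X <- cbind(1, d$temperature, d$np_ratio, d$nitrate)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-10)
})

test_that("model selection applies the 10-unit and simpler-model rules", {
  fake_fit <- function(aicc, k, order, int_p = NULL) {
    co <- data.frame(term = "x", estimate = 1, se = 1, t = 1, p = 0.5)
    if (!is.null(int_p)) {
      co <- rbind(co, data.frame(term = "x:z", estimate = 1, se = 1, t = 1,
                                 p = int_p))
    }
    structure(list(aicc = aicc, k = k, order = order, coefficients = co),
              class = "glm_fit")
  }
  # complex wins with a 15-unit improvement
  sel <- select_model(list(fake_fit(100, 4, 1), fake_fit(85, 7, 2)))
  expect_equal(sel$chosen$order, 2)
  expect_equal(sel$rule, "aicc_improvement")
  # improvement below 10 units: simpler model
  sel2 <- select_model(list(fake_fit(100, 4, 1), fake_fit(95, 7, 2, 0.4)))
  expect_equal(sel2$chosen$order, 1)
  expect_equal(sel2$rule, "simplest")
  # unless the complex model holds a significant interaction
  sel3 <- select_model(list(fake_fit(100, 4, 1), fake_fit(95, 7, 2, 0.01)))
  expect_equal(sel3$chosen$order, 2)
  expect_equal(sel3$rule, "significant_interaction")
  # ties go to the simpler model
  sel4 <- select_model(list(fake_fit(100, 4, 1), fake_fit(100, 7, 2)))
  expect_equal(sel4$chosen$order, 1)
  # invariant to candidate ordering
  sel5 <- select_model(list(fake_fit(95, 7, 2, 0.4), fake_fit(100, 4, 1)))
  expect_equal(sel5$chosen$order, sel2$chosen$order)
  expect_error(select_model(list()), class = "bicompete_invalid_argument")
})

test_that("smoothing splines reproduce linear signals exactly", {
  x <- seq(0, 1, length.out = 50)
  g <- fit_gam_1d(x, 2 * x)
  expect_gte(g$deviance_explained, 0.999)
  # centered partial curve is the centered line
  expect_lt(max(abs(g$partial_curve$s -
                      (2 * g$partial_curve$x -
                         mean(2 * g$partial_curve$x)))), 1e-4)
})

test_that("the penalty limit collapses the smooth to its null space", {
  set.seed(3)
  x <- seq(0, 1, length.out = 60)
  y <- sin(6 * x) + rnorm(60, 0, 0.2)
  ginf <- fit_gam_1d(x, y, lambda_grid = 1e12)
  expect_lt(abs(ginf$edf - 2), 0.01)  # intercept + linear trend
  # edf non-increasing in lambda; GCV pick beats the infinite-penalty fit
  lams <- 10^seq(-4, 8, by = 2)
  edfs <- vapply(lams, function(l) fit_gam_1d(x, y, lambda_grid = l)$edf,
                 numeric(1))
  expect_true(all(diff(edfs) <= 1e-6))
  gsel <- fit_gam_1d(x, y)
  rss <- function(f) sum((f$fit$y - f$fit$fitted.values)^2)
  expect_lte(rss(gsel), rss(ginf) + 1e-10)
})

test_that("white-noise responses show little spurious structure", {
  devs <- vapply(1:50, function(s) {
    set.seed(s)
    fit_gam_1d(runif(100), rnorm(100))$deviance_explained
  }, numeric(1))
  expect_lt(median(devs), 0.15)
})

test_that("response amplitude measures the partial-effect span", {
  x <- seq(0, 2, length.out = 40)
  flat <- fit_gam_1d(x, rep(1, 40) + 1e-12 * x)
  expect_lt(response_amplitude(flat), 1e-6)
  lin <- fit_gam_1d(x, 3 * x)
  expect_equal(response_amplitude(lin), 3 * 2, tolerance = 1e-3)
  shifted <- fit_gam_1d(x, 3 * x + 100)
  expect_equal(response_amplitude(shifted), response_amplitude(lin),
               tolerance = 1e-6)
})

test_that("OLS regression matches closed forms and handles degeneracy", {
  x <- c(1, 2, 3, 4, 5, 6)
  exact <- suppressWarnings(ols_regression(x, 3 * x + 1))
  expect_equal(exact[c("slope", "intercept", "r2")],
               list(slope = 3, intercept = 1, r2 = 1))
  cst <- ols_regression(x, rep(2, 6))
  expect_equal(cst$slope, 0)
  expect_equal(cst$r2, 0)
  # brute-force normal equations on a small fixed table
  set.seed(21)
  y <- rnorm(6)
  f <- ols_regression(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(f$intercept, f$slope), as.numeric(beta), tolerance = 1e-10)
  expect_error(ols_regression(rep(1, 5), rnorm(5)),
               class = "bicompete_invalid_argument")
  expect_error(ols_regression(1:2, 1:2),
               class = "bicompete_insufficient_data")
})
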