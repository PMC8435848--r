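# Lotka-Volterra biculture dynamics with daily dilution events.
#
# Densities are in units of 1e4 cells/mL throughout. Dilution is modeled as
# an instantaneous event once per renewal interval (the protocol replaces a
# fixed medium fraction once per day), not as continuous outflow.

# density below which a species is treated as absent (1e4 cells/mL units);
# mimics the hemocytometer detection limit and avoids log(0) downstream.
DETECTION_FLOOR <- 1e-6

#' Community parameters of the two-species Lotka-Volterra model
#'
#' Bundles the monoculture logistic parameters of the diatom and the
#' dinoflagellate with the two interaction coefficients. `alpha` scales the
#' per-capita impact of the dinoflagellate on the diatom, `beta` the impact
#' of the diatom on the dinoflagellate; their signs are unconstrained
#' (facilitation is allowed).
#'
#' @param r_diatom,r_dino intrinsic growth rates, 1/day; positive.
#' @param K_diatom,K_dino carrying capacities, 1e4 cells/mL; positive.
#' @param alpha,beta interaction coefficients, dimensionless; finite.
#' @return An object of class `community_params`.
#' @export
community_params <- function(r_diatom, r_dino, K_diatom, K_dino,
                             alpha = 0, beta = 0) {
  vals <- c(r_diatom = r_diatom, r_dino = r_dino,
            K_diatom = K_diatom, K_dino = K_dino,
            alpha = alpha, beta = beta)
  if (!all(is.finite(vals))) stop_invalid("all parameters must be finite")
  if (r_diatom <= 0 || r_dino <= 0) stop_invalid("growth rates must be > 0")
  if (K_diatom <= 0 || K_dino <= 0) {
    stop_invalid("carrying capacities must be > 0")
  }
  structure(as.list(vals), class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat("Lotka-Volterra community parameters\n")
  cat(sprintf("  diatom: r = %.4g /d, K = %.4g x1e4 cells/mL\n",
              x$r_diatom, x$K_diatom))
  cat(sprintf("  dino:   r = %.4g /d, K = %.4g x1e4 cells/mL\n",
              x$r_dino, x$K_dino))
  cat(sprintf("  alpha (dino on diatom) = %.4g, beta (diatom on dino) = %.4g\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Lotka-Volterra derivatives
#'
#' Instantaneous per-volume growth rates of the competitive Lotka-Volterra
#' system: `dN1/dt = r1 N1 (K1 - N1 - alpha N2)/K1` for the diatom and
#' symmetrically with `beta` for the dinoflagellate.
#'
#' @param n_diatom,n_dino densities, 1e4 cells/mL; non-negative.
#' @param params a [community_params()] object.
#' @return Named numeric vector `c(dn_diatom, dn_dino)`, 1e4 cells/mL/day.
#' @export
lv_derivative <- function(n_diatom, n_dino, params) {
  if (!is_scalar_num(n_diatom) || !is_scalar_num(n_dino) ||
      n_diatom < 0 || n_dino < 0) {
    stop_invalid("densities must be finite and >= 0")
  }
  with(params, c(
    dn_diatom = r_diatom * n_diatom * (K_diatom - n_diatom - alpha * n_dino) /
      K_diatom,
    dn_dino = r_dino * n_dino * (K_dino - n_dino - beta * n_diatom) / K_dino
  ))
}

#' Closed-form logistic growth curve
#'
#' Solution of the single-species logistic equation, used as the analytic
#' oracle for the interaction-free limit of the simulator and as the model
#' function for monoculture fits.
#'
#' @param r intrinsic growth rate, 1/day.
#' @param K carrying capacity, 1e4 cells/mL.
#' @param n0 initial density, 1e4 cells/mL.
#' @param t time, days (vectorized).
#' @return Density at time `t`.
#' @export
closed_form_logistic <- function(r, K, n0, t) {
  e <- exp(r * t)
  K * n0 * e / (K + n0 * (e - 1))
}

new_trajectory <- function(day, n_diatom, n_dino, phase, post_dilution,
                           D = 0) {
  out <- data.frame(
    day = day, phase = phase, post_dilution = post_dilution,
    n_diatom = n_diatom, n_dino = n_dino,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("trajectory", "data.frame"), D = D)
}

run_lv <- function(params, n0_diatom, n0_dino, days, step, D) {
  if (!is_scalar_num(n0_diatom) || !is_scalar_num(n0_dino) ||
      n0_diatom < 0 || n0_dino < 0) {
    stop_invalid("initial densities must be finite and >= 0")
  }
  if (!is_scalar_num(step) || step <= 0 || step > 0.1) {
    stop_invalid("`step` must be in (0, 0.1]")
  }
  if (!is_scalar_num(days) || days < 1) stop_invalid("`days` must be >= 1")
  res <- .lv_run_cpp(n0_diatom, n0_dino,
                     params$r_diatom, params$r_dino,
                     params$K_diatom, params$K_dino,
                     params$alpha, params$beta,
                     as.integer(days), step, D)
  if (res$clamped > 0) {
    warning(sprintf("integrator clamped %d negative densities to 0",
                    res$clamped))
  }
  res
}

#' Simulate a batch culture
#'
#' Integrates the Lotka-Volterra system with a fixed-step 4th-order
#' Runge-Kutta scheme and no dilution, recording densities at integer days.
#'
#' @param params a [community_params()] object.
#' @param n0_diatom,n0_dino initial densities, 1e4 cells/mL.
#' @param duration length of the batch phase, days.
#' @param step integration step, days; default 0.01.
#' @return A `trajectory` data.frame with columns `day`, `phase`,
#'   `post_dilution`, `n_diatom`, `n_dino`.
#' @export
simulate_batch <- function(params, n0_diatom, n0_dino, duration, step = 0.01) {
  res <- run_lv(params, n0_diatom, n0_dino, duration, step, D = 0)
  days <- 0:duration
  new_trajectory(days, res$post[, 1], res$post[, 2],
                 phase = "batch", post_dilution = FALSE)
}

#' Apply one dilution event
#'
#' Replaces a fraction `D` of the culture with cell-free medium: both
#' densities are multiplied by `1 - D`.
#'
#' @param state numeric vector of densities (any length).
#' @param D renewal fraction in `[0, 1)`.
#' @return Diluted densities.
#' @export
apply_dilution <- function(state, D) {
  if (!is_scalar_num(D) || D < 0 || D >= 1) {
    stop_invalid("`D` must lie in [0, 1)")
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop_invalid("densities must be finite and >= 0")
  }
  state * (1 - D)
}

#' Simulate a semi-continuous culture
#'
#' Each day the Lotka-Volterra system is integrated over the renewal
#' interval (1 d) and a dilution event of fraction `D` is then applied.
#' Densities immediately before and after each dilution are both recorded
#' (one `post_dilution = FALSE` and one `post_dilution = TRUE` row per day).
#'
#' @inheritParams simulate_batch
#' @param D daily renewal fraction in `[0, 1)`.
#' @param days number of semi-continuous days.
#' @return A `trajectory` data.frame; attribute `"D"` stores the renewal
#'   fraction.
#' @export
simulate_semicontinuous <- function(params, n0_diatom, n0_dino, D, days,
                                    step = 0.01) {
  if (!is_scalar_num(D) || D < 0 || D >= 1) {
    stop_invalid("`D` must lie in [0, 1)")
  }
  res <- run_lv(params, n0_diatom, n0_dino, days, step, D)
  # interleave pre/post rows for days 1..days; day 0 is the (post) start state
  day <- c(0, rep(1:days, each = 2))
  idx <- rep(2:(days + 1), each = 2)
  pre_flag <- c(TRUE, rep(c(FALSE, TRUE), days))
  n1 <- c(res$post[1, 1], ifelse(pre_flag[-1], res$post[idx, 1],
                                 res$pre[idx, 1]))
  n2 <- c(res$post[1, 2], ifelse(pre_flag[-1], res$post[idx, 2],
                                 res$pre[idx, 2]))
  new_trajectory(day, n1, n2, phase = "semicontinuous",
                 post_dilution = pre_flag, D = D)
}

#' Detect steady state of a semi-continuous trajectory
#'
#' Scans post-dilution densities for the earliest day whose trailing window
#' has a coefficient of variation below `cv_tol` for every species whose
#' density is above the detection floor. Species at or below the floor are
#' treated as absent and do not veto steady state.
#'
#' @param trajectory a `trajectory` from [simulate_semicontinuous()].
#' @param window trailing window length, days; at least 3.
#' @param cv_tol coefficient-of-variation tolerance (e.g. 0.05).
#' @param floor detection floor, 1e4 cells/mL.
#' @return The earliest qualifying day (numeric), or `NA` if never reached.
#' @export
detect_steady_state <- function(trajectory, window = 5, cv_tol = 0.05,
                                floor = DETECTION_FLOOR) {
  if (window < 3) stop_invalid("`window` must be >= 3")
  post <- trajectory[trajectory$post_dilution & trajectory$day > 0, ]
  if (nrow(post) < window) {
    stop_invalid("trajectory shorter than `window`")
  }
  dens <- as.matrix(post[, c("n_diatom", "n_dino")])
  for (i in window:nrow(post)) {
    win <- dens[(i - window + 1):i, , drop = FALSE]
    ok <- TRUE
    for (j in 1:2) {
      col <- win[, j]
      if (all(col <= floor)) next  # absent species
      cv <- sd(col) / mean(col)
      if (!is.finite(cv) || cv >= cv_tol) { ok <- FALSE; break }
    }
    if (ok) return(post$day[i])
  }
  NA_real_
}
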