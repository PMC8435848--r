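#' Factorial design of the bi-algal competition experiment
#'
#' Builds the full 3 x 3 x 3 factorial design: three temperatures (12, 18,
#' 24 degrees C), three nutrient concentration levels (low, normal, high) and
#' three N:P molar supply ratios (10:1, 24:1, 63:1). Nitrate and phosphate
#' concentrations are the published medium recipes; the realized molar N:P of
#' each recipe is within 3% of its nominal label. Silicate is identical
#' (880 umol/L) in every treatment so that it never limits the diatom.
#'
#' @return A data.frame with one row per treatment and columns
#'   `id`, `temperature_C`, `nutrient_level`, `np_label`,
#'   `nitrate_umol_L`, `phosphate_umol_L`, `silicate_umol_L`.
#'   Treatment ids are stable strings of the form `"T{temp}_L{level}_R{ratio}"`
#'   usable as join keys across output tables.
#' @examples
#' d <- build_design()
#' nrow(d)                     # 27
#' unique(d$silicate_umol_L)   # 880
#' @export
build_design <- function() {
  temperatures <- c(12, 18, 24)
  levels <- c("low", "normal", "high")
  ratios <- c("10:1", "24:1", "63:1")

  # medium recipes, umol/L, indexed [level, ratio]
  nitrate <- matrix(
    c(35.2, 88, 88,
      352, 880, 880,
      1760, 4400, 4400),
    nrow = 3, byrow = TRUE, dimnames = list(levels, ratios)
  )
  phosphate <- matrix(
    c(3.6, 3.6, 1.4,
      36, 36, 14,
      180, 180, 70),
    nrow = 3, byrow = TRUE, dimnames = list(levels, ratios)
  )

  grid <- expand.grid(
    np_label = ratios, nutrient_level = levels, temperature_C = temperatures,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out <- data.frame(
    id = sprintf("T%d_L%s_R%s", grid$temperature_C, grid$nutrient_level,
                 sub(":", "-", grid$np_label)),
    temperature_C = grid$temperature_C,
    nutrient_level = grid$nutrient_level,
    np_label = grid$np_label,
    nitrate_umol_L = nitrate[cbind(grid$nutrient_level, grid$np_label)],
    phosphate_umol_L = phosphate[cbind(grid$nutrient_level, grid$np_label)],
    silicate_umol_L = 880,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Numeric N:P label of a treatment
#'
#' @param np_label character, one of "10:1", "24:1", "63:1".
#' @return The labeled molar ratio as a number.
#' @export
np_ratio_numeric <- function(np_label) {
  as.numeric(sub(":1$", "", np_label))
}

#' Daily renewal fraction of a semi-continuous culture
#'
#' The fraction of culture volume replaced per renewal so that dilution
#' losses balance a target gross growth rate `mu` over the renewal interval
#' `t`: `D = 1 - exp(-mu * t)`.
#'
#' @param mu gross growth rate, 1/day; non-negative.
#' @param t renewal interval, days; positive (the experiment used 1 d).
#' @return Renewal fraction in `[0, 1)`, strictly increasing in both
#'   arguments.
#' @export
renewal_rate <- function(mu, t = 1) {
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu < 0)) {
    stop_invalid("`mu` must be finite and >= 0")
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop_invalid("`t` must be finite and > 0")
  }
  1 - exp(-mu * t)
}

#' Volume of medium replaced at one renewal
#'
#' @param D renewal fraction in `[0, 1)`.
#' @param volume culture volume, mL (200 mL in the experiment).
#' @return `D * volume`, mL.
#' @export
renewal_volume <- function(D, volume = 200) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0) || any(D >= 1)) {
    stop_invalid("`D` must lie in [0, 1)")
  }
  if (!is.numeric(volume) || any(volume <= 0)) {
    stop_invalid("`volume` must be > 0")
  }
  D * volume
}

#' Gross growth rate target of the semi-continuous phase
#'
#' The semi-continuous protocol sets the gross growth rate to 20% of the
#' maximal growth rate observed in batch culture.
#'
#' @param mu_max maximal batch growth rate, 1/day; non-negative.
#' @param fraction fraction of `mu_max` to sustain (default 0.2).
#' @return `fraction * mu_max`, 1/day.
#' @export
gross_growth_target <- function(mu_max, fraction = 0.2) {
  if (!is.numeric(mu_max) || any(!is.finite(mu_max)) || any(mu_max < 0)) {
    stop_invalid("`mu_max` must be finite and >= 0")
  }
  fraction * mu_max
}

#' Net growth rate under dilution
#'
#' `r = mu - D`: at steady state of a semi-continuous monoculture gross
#' growth balances the renewal loss and `r` is zero.
#'
#' @param mu gross growth rate, 1/day.
#' @param D daily renewal fraction (treated as a loss rate over the 1-day
#'   interval, as in the experimental protocol).
#' @return `mu - D`, 1/day.
#' @export
net_growth_rate <- function(mu, D) {
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu < 0)) {
    stop_invalid("`mu` must be finite and >= 0")
  }
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0)) {
    stop_invalid("`D` must be finite and >= 0")
  }
  mu - D
}

#' Write or read the design table
#'
#' @param design data.frame from [build_design()].
#' @param path file path for `design.csv`.
#' @return `write_design` returns `path` invisibly; `read_design` returns the
#'   design data.frame.
#' @export
write_design <- function(design, path) {
  write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  need <- c("id", "temperature_C", "nutrient_level", "np_label",
            "nitrate_umol_L", "phosphate_umol_L", "silicate_umol_L")
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop_invalid(paste("design file missing columns:",
                       paste(missing, collapse = ", ")))
  }
  d[, need]
}

#' Default culture configuration
#'
#' Fixed protocol constants: 200 mL culture volume, 1-day renewal interval,
#' gross growth at 20% of the batch maximal rate. Salinity and light are
#' metadata only (held constant in the experiment).
#'
#' @return Named list of protocol constants.
#' @export
default_culture_config <- function() {
  list(
    volume_ml = 200,
    renewal_interval_d = 1,
    mu_fraction = 0.2,
    salinity_psu = 37,
    light_umol_photons_m2_s = 100
  )
}
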