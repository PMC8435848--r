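# Pipeline orchestration: generate/load -> growth fits -> interaction
# estimates -> composition indices -> statistical layer -> report bundle.

PIPELINE_KEYS <- c(
  "mode", "input_dir", "seed", "days_semi", "noiseless",
  "counting_volume_ul", "process_cv", "chemistry_cv",
  "dilution_corrected", "superiority_tol",
  "glm_family", "basis_size", "lambda_grid", "out_dir"
)

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected so that typos never silently fall back to
#' defaults. `mode` is `"synthetic"` (generate the experiment from the
#' ground truth under `seed`) or `"csv"` (read fixture tables from
#' `input_dir`).
#'
#' @param ... configuration values overriding the defaults, or a single
#'   named list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  unknown <- setdiff(names(user), PIPELINE_KEYS)
  if (length(unknown)) {
    stop_invalid(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- list(
    mode = "synthetic", input_dir = NULL, seed = 1, days_semi = 25,
    noiseless = FALSE, counting_volume_ul = 20, process_cv = 0.05,
    chemistry_cv = 0.08, dilution_corrected = TRUE, superiority_tol = 0,
    glm_family = "gaussian", basis_size = 10, lambda_grid = NULL,
    out_dir = NULL
  )
  cfg[names(user)] <- user
  if (!cfg$mode %in% c("synthetic", "csv")) {
    stop_invalid('`mode` must be "synthetic" or "csv"')
  }
  if (cfg$mode == "csv" && is.null(cfg$input_dir)) {
    stop_invalid('`input_dir` is required when mode = "csv"')
  }
  if (!cfg$glm_family %in% c("gaussian", "gamma_log")) {
    stop_invalid('`glm_family` must be "gaussian" or "gamma_log"')
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with keys understood by [pipeline_config()].
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Load culture tables from a fixture directory
#'
#' Reads and validates `design.csv`, `trajectory.csv`, `composition.csv`
#' and `units.csv` as written by [write_fixture()]. Negative densities are
#' rejected with row references; unknown extra columns produce a warning
#' only.
#'
#' @param directory path containing the fixture files.
#' @return List with `design`, `trajectories`, `composition`, `units`.
#' @export
load_cultures <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("design.csv", "trajectory.csv", "composition.csv"))
    if (!file.exists(p(f))) stop_invalid(paste("missing file:", f))
  design <- read_design(p("design.csv"))

  traj <- read.csv(p("trajectory.csv"), stringsAsFactors = FALSE)
  need <- c("culture_id", "day", "phase", "post_dilution",
            "n_diatom_1e4_per_ml", "n_dino_1e4_per_ml")
  missing <- setdiff(need, names(traj))
  if (length(missing)) {
    stop_invalid(paste("trajectory.csv missing columns:",
                       paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(traj), need)
  if (length(extra)) {
    warning(paste("trajectory.csv: ignoring unknown columns:",
                  paste(extra, collapse = ", ")))
  }
  bad <- which(traj$n_diatom_1e4_per_ml < 0 | traj$n_dino_1e4_per_ml < 0)
  if (length(bad)) {
    stop_invalid(paste("negative density in trajectory.csv rows:",
                       paste(head(bad, 10), collapse = ", ")))
  }
  names(traj)[names(traj) == "n_diatom_1e4_per_ml"] <- "n_diatom"
  names(traj)[names(traj) == "n_dino_1e4_per_ml"] <- "n_dino"
  # recover unit structure from culture ids: <treatment>_<type>_rep<i>
  traj$culture_type <- ifelse(grepl("mono_diatom", traj$culture_id),
                              "mono_diatom",
                       ifelse(grepl("mono_dino", traj$culture_id),
                              "mono_dino", "biculture"))
  traj$replicate <- as.integer(sub(".*_rep(\\d+)$", "\\1", traj$culture_id))
  traj$treatment_id <- sub("_(mono_diatom|mono_dino|biculture)_rep\\d+$",
                           "", traj$culture_id)

  comp <- read.csv(p("composition.csv"), stringsAsFactors = FALSE,
                   check.names = FALSE)
  units <- if (file.exists(p("units.csv"))) {
    read.csv(p("units.csv"), stringsAsFactors = FALSE)
  } else NULL
  list(design = design, trajectories = traj, composition = comp,
       units = units)
}

glm_family_object <- function(name) {
  switch(name, gaussian = gaussian(), gamma_log = Gamma(link = "log"))
}

#' Run the full analysis pipeline
#'
#' Executes generate/load, monoculture growth fitting, interaction
#' inference, composition indexing and the statistical layer, and returns a
#' machine-readable report bundle. Per-unit failures (non-convergent fits,
#' washed-out cultures, too few usable days) are recorded in
#' `report$exclusions`, never silently dropped.
#'
#' @param config a [pipeline_config()] (or arguments for one).
#' @return List of class `report_bundle` with `interaction` (alpha/beta per
#'   biculture unit), `gam` (per-temperature and joined smoothing-spline
#'   summaries plus response amplitudes), `glm` (AICc candidate tables and
#'   selected model per response), `regressions` (composition indices vs
#'   community ratios), `exclusions`, `manifest`. If `config$out_dir` is
#'   set, CSV/JSON reports are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)

  if (config$mode == "synthetic") {
    experiment <- generate_experiment(
      truth = default_ground_truth(),
      cfg = noise_config(config$counting_volume_ul, config$process_cv,
                         config$chemistry_cv),
      seed = config$seed, days_semi = config$days_semi,
      noiseless = config$noiseless
    )
    design <- experiment$design
    traj <- experiment$trajectories
    comp <- experiment$composition
    units <- experiment$units
  } else {
    loaded <- load_cultures(config$input_dir)
    design <- loaded$design; traj <- loaded$trajectories
    comp <- loaded$composition; units <- loaded$units
  }

  exclusions <- list()
  note_exclusion <- function(unit, stage, reason) {
    exclusions[[length(exclusions) + 1L]] <<- data.frame(
      culture_id = unit, stage = stage, reason = reason,
      stringsAsFactors = FALSE)
  }

  # ---- monoculture growth fits -------------------------------------------
  mono <- traj[traj$culture_type != "biculture", ]
  growth_rows <- list(); growth_fits <- list()
  for (id in unique(mono$culture_id)) {
    tt <- mono[mono$culture_id == id, ]
    sp <- if (tt$culture_type[1] == "mono_diatom") "diatom" else "dino"
    batch <- tt[tt$phase == "batch", ]
    fit <- tryCatch(fit_logistic_mono(batch, sp),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      note_exclusion(id, "growth_fit", fit)
      next
    }
    key <- paste(tt$treatment_id[1], tt$replicate[1], sp, sep = "|")
    growth_fits[[key]] <- fit
    growth_rows[[length(growth_rows) + 1L]] <- data.frame(
      culture_id = id, treatment_id = tt$treatment_id[1],
      replicate = tt$replicate[1], species = sp,
      r = fit$r, r_se = fit$r_se, K = fit$K, K_se = fit$K_se,
      mu_max = fit$mu_max, n_points = fit$n_points,
      stringsAsFactors = FALSE
    )
  }
  growth_table <- do.call(rbind, growth_rows)

  # ---- interaction inference ---------------------------------------------
  bi <- traj[traj$culture_type == "biculture", ]
  D_lookup <- if (!is.null(units)) {
    setNames(units$D, units$culture_id)
  } else NULL
  inter_rows <- list()
  for (id in unique(bi$culture_id)) {
    tt <- bi[bi$culture_id == id, ]
    semi <- tt[tt$phase == "semicontinuous", ]
    D <- if (!is.null(D_lookup) && id %in% names(D_lookup)) {
      unname(D_lookup[id])
    } else NA_real_
    if (!is.finite(D)) {
      note_exclusion(id, "interaction", "renewal fraction D unavailable")
      next
    }
    dia_key <- paste(tt$treatment_id[1], tt$replicate[1], "diatom", sep = "|")
    dino_key <- paste(tt$treatment_id[1], tt$replicate[1], "dino", sep = "|")
    if (is.null(growth_fits[[dia_key]]) || is.null(growth_fits[[dino_key]])) {
      note_exclusion(id, "interaction", "matching monoculture fit missing")
      next
    }
    est <- tryCatch({
      series <- per_capita_rates(semi, D = D,
                                 dilution_corrected = config$dilution_corrected)
      estimate_interaction(series, growth_fits[[dia_key]],
                           growth_fits[[dino_key]])
    }, error = function(e) conditionMessage(e))
    if (is.character(est)) {
      note_exclusion(id, "interaction", est)
      next
    }
    inter_rows[[length(inter_rows) + 1L]] <- data.frame(
      culture_id = id, treatment_id = tt$treatment_id[1],
      replicate = tt$replicate[1],
      alpha = est$alpha, alpha_se = est$alpha_se,
      beta = est$beta, beta_se = est$beta_se, n_points = est$n_points,
      superiority = classify_superiority(est$alpha, config$superiority_tol),
      stringsAsFactors = FALSE
    )
  }
  interaction_table <- do.call(rbind, inter_rows)
  if (!is.null(interaction_table)) {
    interaction_table <- merge(
      interaction_table,
      design[, c("id", "temperature_C", "nutrient_level", "np_label",
                 "nitrate_umol_L")],
      by.x = "treatment_id", by.y = "id", sort = FALSE
    )
    interaction_table <- interaction_table[
      order(interaction_table$treatment_id, interaction_table$replicate), ]
    rownames(interaction_table) <- NULL
  }

  # ---- composition indices for bicultures --------------------------------
  comp_bi <- comp[comp$culture_type == "biculture", ]
  idx_rows <- list()
  for (i in seq_len(nrow(comp_bi))) {
    row <- comp_bi[i, ]
    fa <- setNames(as.numeric(row[fa_col(FA_NAMES)]), FA_NAMES)
    idx <- withCallingHandlers(
      composition_indices(row$poc_umol_L, row$pon_umol_L, row$pop_umol_L,
                          fa, row$brassicasterol_ug_L, row$dinosterol_ug_L),
      warning = function(w) {
        if (inherits(w, "bicompete_undefined_ratio")) {
          note_exclusion(row$culture_id, "composition", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      }
    )
    dd <- if ("n_dino_ss" %in% names(row) && row$n_dino_ss > DETECTION_FLOOR &&
              row$n_diatom_ss > DETECTION_FLOOR) {
      row$n_diatom_ss / row$n_dino_ss
    } else NA_real_
    dfrac <- if ("n_diatom_ss" %in% names(row)) {
      tot <- row$n_diatom_ss + row$n_dino_ss
      if (tot > 0) row$n_diatom_ss / tot else NA_real_
    } else NA_real_
    idx_rows[[i]] <- cbind(
      data.frame(culture_id = row$culture_id,
                 treatment_id = row$treatment_id,
                 replicate = row$replicate, stringsAsFactors = FALSE),
      idx,
      data.frame(diatom_dino_ratio = dd, diatom_fraction = dfrac)
    )
  }
  indices_table <- do.call(rbind, idx_rows)

  # ---- statistical layer --------------------------------------------------
  stats_input <- NULL
  if (!is.null(interaction_table)) {
    stats_input <- data.frame(
      culture_id = interaction_table$culture_id,
      alpha = interaction_table$alpha,
      temperature = interaction_table$temperature_C,
      np_ratio = np_ratio_numeric(interaction_table$np_label),
      nitrate = interaction_table$nitrate_umol_L,
      stringsAsFactors = FALSE
    )
    if (!is.null(indices_table)) {
      stats_input <- merge(
        stats_input,
        indices_table[, c("culture_id", "poc_pon", "pon_pop",
                          "r_16_1_16_0", "epa_dha", "b_over_bd")],
        by = "culture_id", all.x = TRUE
      )
    }
  }

  fam <- glm_family_object(config$glm_family)
  responses <- intersect(
    c("alpha", "poc_pon", "pon_pop", "r_16_1_16_0", "epa_dha", "b_over_bd"),
    names(stats_input %||% data.frame())
  )
  glm_report <- list()
  for (resp in responses) {
    glm_report[[resp]] <- tryCatch({
      # gamma-log requires positive responses; alpha can be negative
      f <- if (config$glm_family == "gamma_log" &&
               any(stats_input[[resp]] <= 0, na.rm = TRUE)) gaussian() else fam
      sel <- select_glm(stats_input, resp, family = f)
      list(chosen_order = sel$chosen$order, rule = sel$rule,
           aicc_table = sel$table, coefficients = sel$chosen$coefficients,
           n = sel$chosen$n)
    }, error = function(e) list(error = conditionMessage(e)))
  }

  gam_report <- list()
  if (!is.null(stats_input)) {
    for (grp in c("12", "18", "24", "joined")) {
      sub <- if (grp == "joined") stats_input else
        stats_input[stats_input$temperature == as.numeric(grp), ]
      gam_report[[grp]] <- tryCatch({
        g <- fit_gam_1d(sub$nitrate, sub$alpha,
                        basis_size = config$basis_size,
                        lambda_grid = config$lambda_grid)
        list(intercept = g$intercept, intercept_se = g$intercept_se,
             edf = g$edf_smooth, p = g$p_smooth, gcv = g$gcv,
             r2_adj = g$r2_adj,
             deviance_explained_pct = 100 * g$deviance_explained,
             amplitude = response_amplitude(g), n = g$n)
      }, error = function(e) list(error = conditionMessage(e)))
    }
  }

  # composition indices vs community structure; the diatom/dino cell ratio
  # spans several decades across the design, so those regressions use the
  # log10 ratio (the sign of the slope is unchanged by the monotone
  # transform); the sterol index is regressed on the bounded diatom fraction
  regressions <- list()
  if (!is.null(indices_table)) {
    lr <- log10(indices_table$diatom_dino_ratio)
    reg_spec <- list(
      pon_pop = list(x = lr, name = "log10_diatom_dino_ratio",
                     y = "pon_pop"),
      r_16_1_16_0 = list(x = lr, name = "log10_diatom_dino_ratio",
                         y = "r_16_1_16_0"),
      epa_dha = list(x = lr, name = "log10_diatom_dino_ratio",
                     y = "epa_dha"),
      b_over_bd = list(x = indices_table$diatom_fraction,
                       name = "diatom_fraction", y = "b_over_bd")
    )
    for (nm in names(reg_spec)) {
      sp <- reg_spec[[nm]]
      regressions[[nm]] <- tryCatch({
        f <- ols_regression(sp$x, indices_table[[sp$y]])
        list(predictor = sp$name, slope = f$slope, intercept = f$intercept,
             r2 = f$r2, p = f$p, n = f$n)
      }, error = function(e) list(error = conditionMessage(e)))
    }
  }

  exclusions_table <- if (length(exclusions)) {
    do.call(rbind, exclusions)
  } else {
    data.frame(culture_id = character(), stage = character(),
               reason = character(), stringsAsFactors = FALSE)
  }

  report <- structure(list(
    interaction = interaction_table,
    growth = growth_table,
    indices = indices_table,
    glm = glm_report,
    gam = gam_report,
    regressions = regressions,
    exclusions = exclusions_table,
    manifest = list(config = unclass(config)[setdiff(PIPELINE_KEYS,
                                                     c("out_dir"))],
                    n_units = length(unique(traj$culture_id)),
                    n_interaction = if (is.null(interaction_table)) 0L else
                      nrow(interaction_table))
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Competition-pipeline report\n")
  cat(sprintf("  interaction estimates: %d bicultures (%d excluded records)\n",
              if (is.null(x$interaction)) 0L else nrow(x$interaction),
              nrow(x$exclusions)))
  if (!is.null(x$interaction)) {
    tab <- table(x$interaction$superiority)
    cat("  superiority: ",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  for (nm in names(x$regressions)) {
    r <- x$regressions[[nm]]
    if (!is.null(r$slope)) {
      cat(sprintf("  %s ~ %s: slope %.4g (p = %.3g, n = %d)\n",
                  nm, r$predictor, r$slope, r$p, r$n))
    }
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `interaction.csv`, `growth.csv`, `indices.csv`, `exclusions.csv`
#' and `stats_report.json` under `directory`.
#'
#' @param report a `report_bundle` from [run_pipeline()].
#' @param directory output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  if (!is.null(report$interaction)) {
    write.csv(report$interaction, p("interaction.csv"), row.names = FALSE)
  }
  if (!is.null(report$growth)) {
    write.csv(report$growth, p("growth.csv"), row.names = FALSE)
  }
  if (!is.null(report$indices)) {
    write.csv(report$indices, p("indices.csv"), row.names = FALSE)
  }
  write.csv(report$exclusions, p("exclusions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(glm = report$glm, gam = report$gam,
         regressions = report$regressions, manifest = report$manifest),
    p("stats_report.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE,
    force = TRUE
  )
  invisible(directory)
}
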