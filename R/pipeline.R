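## End-to-end orchestration: simulate (or load) a cohort, derive
## geometry, process flow, compute hydrodynamic numbers, predict
## catheter flow reduction, run the statistical battery, and aggregate
## a study report with group mean +/- SD summaries.

param_units <- function() {
  c(A_d = "mm^2", A_c = "mm^2", A_sas = "mm^2",
    P_d = "mm", P_c = "mm", P_sas = "mm", D_h = "mm",
    alpha = "-", Re = "-",
    U_peak_sys = "cm/s", U_peak_dia = "cm/s",
    Q_a = "mL/s", SV = "mL", PWV = "m/s",
    V_sas = "mL", V_c = "mL", V_d = "mL",
    SA_c = "cm^2", SA_d = "cm^2", SA_sas = "cm^2")
}

## along-spine parameter profiles for one subject at one timepoint,
## interpolated onto fractional stations of the subject's own spine
subject_parameter_profiles <- function(profile, flow_summary, hydro, stations) {
  L <- profile$grid$L_sas
  zs <- stations * L
  gi <- function(v) approx(profile$grid$z, v, xout = zs, rule = 2)$y
  fz <- flow_summary$profile$z
  fi <- function(v) approx(fz, v, xout = zs, rule = 2)$y
  data.frame(
    station = stations,
    A_d = gi(profile$A_d), A_c = gi(profile$A_c), A_sas = gi(profile$A_sas),
    P_d = gi(profile$P_d), P_c = gi(profile$P_c), P_sas = gi(profile$P_sas),
    D_h = gi(profile$D_h),
    alpha = fi(hydro$profile$alpha), Re = fi(hydro$profile$Re),
    U_peak_sys = fi(hydro$profile$U_sys), U_peak_dia = fi(hydro$profile$U_dia),
    Q_a = fi(flow_summary$profile$Q_a), SV = fi(flow_summary$profile$SV))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates (or accepts) a cohort, then for every subject and
#' timepoint: derives the SAS profile, normalizes the cardiac cycle,
#' fits the spatio-temporal flow surface, extracts peaks, stroke volume
#' and pulse wave velocity, and computes the dimensionless
#' hydrodynamic numbers. Group-level outputs are mean +/- SD summary
#' records for all 13 battery parameters plus PWV and the geometry
#' summaries, per-group Hagen-Poiseuille flow-reduction predictions,
#' and (optionally) the linear mixed-effects comparison battery.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed governing all randomness.
#' @param cohort Optional pre-generated \code{csf_cohort} (overrides
#'   \code{config}/\code{seed} for data generation).
#' @param stats Logical; run the 13 x 7 mixed-model battery.
#' @param smoothing Smoothing control for [fit_spatiotemporal()].
#' @param n_stations Axial stations per subject entering the long
#'   table.
#' @param fluid A [fluid_properties()].
#' @param nr A [nerve_root_model()].
#' @param out_dir Optional directory; writes the summary table,
#'   battery CSV and a JSON run manifest.
#' @return An object of class \code{csf_report}: \code{summary}
#'   (group summary records), \code{pooled} (grand means),
#'   \code{reduction} (per-group predicted flow reduction),
#'   \code{pwv} (per subject/timepoint), \code{battery} (or
#'   \code{NULL}), \code{instability}, \code{long_table} and
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = synthetic_config(), seed = 1L, cohort = NULL,
                         stats = TRUE, smoothing = "gcv", n_stations = 19L,
                         fluid = fluid_properties(), nr = nerve_root_model(),
                         out_dir = NULL) {
  warnings_log <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (is.null(cohort)) cohort <- generate_cohort(config, seed) else config <- cohort$config
  md <- cohort$metadata
  stations <- seq(0.05, 0.95, length.out = n_stations)
  timepoints <- names(cohort$profiles)

  values <- list(); scalar_rows <- list(); pwv_rows <- list()
  hydro_last <- NULL
  for (tp in timepoints) {
    for (id in md$id) {
      prof <- cohort$profiles[[tp]][[id]]
      if (is.null(prof$D_h)) prof <- derive_sas_profile(prof)
      geo <- summarize_geometry(prof)
      waves <- lapply(cohort$waveforms[[tp]][[id]], normalize_cycle, T_ref = fluid$T_ref)
      field <- collect(fit_spatiotemporal(waves, smoothing = smoothing))
      fs <- summarize_flow(field)
      A_at_fz <- approx(prof$grid$z, prof$A_sas, xout = fs$profile$z, rule = 2)$y
      D_at_fz <- approx(prof$grid$z, prof$D_h, xout = fs$profile$z, rule = 2)$y
      uv <- mean_velocities(fs$profile$Q_sys, fs$profile$Q_dia, A_at_fz)
      hyd <- dimensionless_numbers(uv$U_sys, D_at_fz, fluid = fluid, nr = nr)
      hyd$profile$U_dia <- uv$U_dia
      hydro_last <- hyd
      pp <- subject_parameter_profiles(prof, fs, hyd, stations)
      long <- do.call(rbind, lapply(setdiff(names(pp), "station"), function(pm) {
        data.frame(id = id, timepoint = tp, z = pp$station * config$L_mean,
                   parameter = pm, value = pp[[pm]])
      }))
      values[[paste(tp, id)]] <- long
      means <- vapply(setdiff(names(pp), "station"), function(pm) mean(pp[[pm]]),
                      numeric(1))
      scalar_rows[[paste(tp, id)]] <- data.frame(
        id = id, timepoint = tp,
        parameter = c(names(means), "PWV", "V_sas", "SA_sas"),
        value = c(unname(means), fs$PWV, geo$V_sas, geo$SA_sas))
      pwv_rows[[paste(tp, id)]] <- data.frame(id = id, timepoint = tp, PWV = fs$PWV)
    }
  }
  values <- do.call(rbind, values)
  scalars <- do.call(rbind, scalar_rows)
  scalars$group <- md$group[match(scalars$id, md$id)]

  units <- param_units()
  cells <- split(scalars, list(scalars$parameter, scalars$group, scalars$timepoint),
                 drop = TRUE)
  summary_records <- do.call(rbind, lapply(cells, function(d) {
    data.frame(parameter = d$parameter[1L],
               unit = unname(units[d$parameter[1L]]),
               group = d$group[1L], timepoint = d$timepoint[1L],
               mean = mean(d$value), sd = sd(d$value))
  }))
  rownames(summary_records) <- NULL
  pooled <- pooled_summary(summary_records)

  reduction <- vapply(split(md$id, md$group), function(ids) {
    mean(unlist(cohort$truth$reduction[ids]))
  }, numeric(1))

  battery <- NULL
  if (isTRUE(stats)) {
    table <- assemble_long_table(values, md)
    battery <- collect(run_battery(table))
  } else {
    table <- NULL
  }

  manifest <- list(seed = cohort$seed,
                   config = unclass(config),
                   n_subjects = nrow(md),
                   timepoints = timepoints,
                   n_stations = n_stations,
                   smoothing = smoothing,
                   package_version = as.character(utils::packageVersion("csfdyn")),
                   warnings = warnings_log)
  report <- structure(list(summary = summary_records, pooled = pooled,
                           reduction = reduction,
                           pwv = do.call(rbind, pwv_rows),
                           battery = battery,
                           instability = instability_assessment(hydro_last),
                           long_table = table,
                           manifest = manifest),
                      class = "csf_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_summary_table(summary_records, file.path(out_dir, "group_summary.csv"))
    if (!is.null(battery)) {
      write.csv(battery$p, file.path(out_dir, "battery_p_values.csv"))
      write.csv(battery$stars, file.path(out_dir, "battery_stars.csv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.csf_report <- function(x, ...) {
  cat("<csf_report>\n")
  cat(sprintf("  %d summary cells over %d parameters\n",
              nrow(x$summary), length(unique(x$summary$parameter))))
  for (g in names(x$reduction)) {
    cat(sprintf("  predicted flow reduction (%s): %.1f%%\n", g, 100 * x$reduction[[g]]))
  }
  cat(sprintf("  pooled PWV: %.3f m/s\n",
              x$pooled$pooled_mean[x$pooled$parameter == "PWV"]))
  if (!is.null(x$battery)) {
    cat(sprintf("  battery: %d tests, threshold %.3g, %d significant\n",
                x$battery$n_tests, x$battery$threshold,
                sum(x$battery$p < x$battery$threshold, na.rm = TRUE)))
  }
  invisible(x)
}
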