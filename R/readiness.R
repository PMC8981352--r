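#' Estimate emergency obstetric readiness for a facility cohort
#'
#' The central entry point: scores every facility under both readiness models
#' (signal-function tracers / SRI item average, and the three-stage clinical
#' cascade with cumulative logic) and aggregates the profiles into the full
#' indicator family -- per-emergency and pooled readiness proportions,
#' tracer-versus-cascade overestimation, stage-wise drop-offs with pooled
#' means and sample SDs, and stratified variants.
#'
#' @param cohort an `emoc_cohort` from [read_inventory()], [facility_cohort()],
#'   [build_paper_replica()] or [generate_random()].
#' @param definitions an `emoc_definitions` (default: the packaged default
#'   config, [default_definitions()]).
#' @param strata facility attributes to stratify by; defaults to
#'   caesarean-section capability, ownership and country.
#' @return an object of class `emoc_readiness` with components `profiles`
#'   (per-facility scores), `tables` (see [build_tables()]), `n`, `cohort` and
#'   `definitions`.
#' @examples
#' fit <- emoc_readiness(build_paper_replica(), replica_definitions())
#' print(fit)
#' summary(fit)
#' @export
emoc_readiness <- function(cohort, definitions = default_definitions(),
                           strata = c("csec_capable", "ownership", "country")) {
  stopifnot(inherits(cohort, "emoc_cohort"), inherits(definitions, "emoc_definitions"))
  profiles <- score_cohort(cohort, definitions)
  tables <- build_tables(cohort, definitions, strata = strata, profiles = profiles)
  structure(list(cohort = cohort, definitions = definitions, profiles = profiles,
                 tables = tables, n = profiles$n, strata = strata),
            class = "emoc_readiness")
}

#' @export
print.emoc_readiness <- function(x, ...) {
  comp <- x$tables$comparison
  ov <- comp[comp$group == "pooled_overall", ]
  cat("Emergency obstetric readiness (", x$n, " facilities, definitions ",
      x$definitions$version, ")\n", sep = "")
  cat("  pooled signal-function readiness: ", fmt1(ov$signal_pct), "%\n", sep = "")
  cat("  pooled cascade stage-2 readiness: ", fmt1(ov$cascade_pct), "%\n", sep = "")
  cat("  pooled tracer overestimation:     ", fmt1(ov$overestimation_pct),
      " percentage points\n", sep = "")
  cat("  pooled mean stage drop-off:       ", fmt1(x$tables$dropoff$overall$mean),
      "% (SD ", fmt1(x$tables$dropoff$overall$sd), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.emoc_readiness <- function(object, ...) {
  structure(list(fit = object), class = "summary.emoc_readiness")
}

#' @export
print.summary.emoc_readiness <- function(x, ...) {
  fit <- x$fit
  comp <- fit$tables$comparison
  cat("Tracer vs cascade readiness (n = ", fit$n, "):\n", sep = "")
  disp <- data.frame(` ` = comp$row,
                     signal = fmt1(comp$signal_pct),
                     cascade_stage2 = fmt1(comp$cascade_pct),
                     overestimation = fmt1(comp$overestimation_pct),
                     check.names = FALSE)
  print(disp, row.names = FALSE, right = FALSE)
  d <- fit$tables$dropoff
  cat("\nStage-wise drop-off by emergency:\n")
  disp2 <- data.frame(` ` = d$per_emergency$label,
                      identify = fmt1(d$per_emergency$identify_drop),
                      treat = fmt1(d$per_emergency$treat_drop),
                      monitor_modify = fmt1(d$per_emergency$monitor_modify_drop),
                      mean = fmt1(d$per_emergency$mean_drop),
                      sd = fmt1(d$per_emergency$sd_drop),
                      check.names = FALSE)
  print(disp2, row.names = FALSE, right = FALSE)
  cat("Pooled by stage: ", paste(sprintf("%s %s%%", d$per_stage$stage,
                                         fmt1(d$per_stage$pooled_mean_drop)),
                                 collapse = ", "), "\n", sep = "")
  cat("Overall: pooled mean ", fmt1(d$overall$mean), "% (SD ", fmt1(d$overall$sd),
      "; mean of per-emergency SDs ", fmt1(d$overall$mean_of_sds), ")\n", sep = "")
  invisible(x)
}

#' Plot cumulative cascade readiness by stage
#'
#' One line per emergency: the percentage of facilities ready through each
#' cascade stage, starting from the 100% skill baseline. The vertical distance
#' between consecutive points is the stage drop-off.
#'
#' @param x an `emoc_readiness` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.emoc_readiness <- function(x, ...) {
  emergencies <- dimnames(x$profiles$cascade)[[2]]
  ready <- vapply(emergencies, function(e)
    c(100, vapply(1:3, function(k)
      proportion_ready(x$profiles, paste0("cascade:", e, ":", k))$percent, 0)),
    numeric(4))
  graphics::matplot(0:3, ready, type = "b", pch = 16, lty = 1,
                    xlab = "Cascade stage (0 = skill baseline)",
                    ylab = "Facilities ready through stage (%)",
                    ylim = c(0, 100), xaxt = "n", ...)
  graphics::axis(1, at = 0:3, labels = c("skill", "identify", "treat", "monitor-modify"))
  graphics::legend("bottomleft", legend = emergencies, col = seq_along(emergencies),
                   lty = 1, pch = 16, cex = 0.8, bty = "n")
  invisible(x)
}

#' Write the result tables of a readiness analysis to CSV files
#'
#' Writes `table1_readiness.csv` (tracer-versus-cascade comparison),
#' `table3_dropoff.csv` (stage-wise drop-offs), and for each stratification
#' attribute `table2_<attribute>.csv` / `table4_<attribute>.csv`
#' (per-stratum overestimation and mean drop-off columns), plus
#' `facility_profiles.csv` (the 0/1 facility-by-indicator matrix).
#'
#' @param fit an `emoc_readiness` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_readiness_tables <- function(fit, dir) {
  stopifnot(inherits(fit, "emoc_readiness"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "table1_readiness.csv")
  write_table(fit$tables$comparison, p)
  paths <- c(paths, p)

  d <- fit$tables$dropoff
  drop_df <- d$per_emergency
  overall_row <- data.frame(emergency = "pooled", label = "Pooled across emergencies",
                            identify_drop = d$per_stage$pooled_mean_drop[1],
                            treat_drop = d$per_stage$pooled_mean_drop[2],
                            monitor_modify_drop = d$per_stage$pooled_mean_drop[3],
                            mean_drop = d$overall$mean, sd_drop = d$overall$sd,
                            stringsAsFactors = FALSE)
  sd_row <- data.frame(emergency = "sd", label = "SD across emergencies",
                       identify_drop = d$per_stage$sd_drop[1],
                       treat_drop = d$per_stage$sd_drop[2],
                       monitor_modify_drop = d$per_stage$sd_drop[3],
                       mean_drop = NA_real_, sd_drop = d$overall$mean_of_sds,
                       stringsAsFactors = FALSE)
  p <- file.path(dir, "table3_dropoff.csv")
  write_table(rbind(drop_df, overall_row, sd_row), p)
  paths <- c(paths, p)

  for (attr_name in names(fit$tables$stratified)) {
    strat <- fit$tables$stratified[[attr_name]]
    comp_all <- fit$tables$comparison
    t2 <- data.frame(row = comp_all$row, all_pct = comp_all$overestimation_pct,
                     stringsAsFactors = FALSE)
    t4 <- data.frame(row = c(fit$tables$dropoff$per_emergency$label, "Overall mean", "SD"),
                     all_pct = c(fit$tables$dropoff$per_emergency$mean_drop,
                                 fit$tables$dropoff$overall$mean,
                                 fit$tables$dropoff$overall$sd),
                     stringsAsFactors = FALSE)
    for (lev in names(strat)) {
      t2[[paste0(lev, "_pct")]] <- strat[[lev]]$comparison$overestimation_pct
      t4[[paste0(lev, "_pct")]] <- c(strat[[lev]]$dropoff$per_emergency$mean_drop,
                                     strat[[lev]]$dropoff$overall$mean,
                                     strat[[lev]]$dropoff$overall$sd)
    }
    p <- file.path(dir, paste0("table2_", attr_name, ".csv"))
    write_table(t2, p)
    paths <- c(paths, p)
    p <- file.path(dir, paste0("table4_", attr_name, ".csv"))
    write_table(t4, p)
    paths <- c(paths, p)
  }

  p <- file.path(dir, "facility_profiles.csv")
  write_table(profile_matrix(fit$profiles), p)
  paths <- c(paths, p)
  invisible(paths)
}
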