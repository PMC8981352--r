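#' Readiness estimate from exact counts
#'
#' @param numerator facility count satisfying the indicator.
#' @param denominator cohort size.
#' @return object of class `emoc_estimate` with fields `numerator`,
#'   `denominator`, `percent` (carried at full precision; rounded only at
#'   display).
#' @export
readiness_estimate <- function(numerator, denominator) {
  if (denominator < 1)
    abort("readiness estimate is undefined on an empty cohort", "emoc_empty_cohort_error")
  if (numerator < 0 || numerator > denominator)
    abort("numerator must lie in [0, denominator]", "emoc_structural_error")
  structure(list(numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 percent = pct(numerator, denominator)),
            class = "emoc_estimate")
}

#' @export
print.emoc_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %s%%\n", x$numerator, x$denominator, fmt1(x$percent)))
  invisible(x)
}

#' Proportion of facilities satisfying an indicator
#'
#' @param profiles an `emoc_profiles` object from [score_cohort()].
#' @param indicator either `"signal:<function_id>"` or
#'   `"cascade:<emergency_id>:<stage 1|2|3>"` (cascade stages are cumulative:
#'   stage 2 means ready through stages 1 and 2).
#' @return an `emoc_estimate`.
#' @export
proportion_ready <- function(profiles, indicator) {
  stopifnot(inherits(profiles, "emoc_profiles"))
  parts <- strsplit(indicator, ":", fixed = TRUE)[[1]]
  flags <- switch(parts[1],
    signal = {
      if (!parts[2] %in% colnames(profiles$signal))
        abort(paste0("unknown signal function: ", parts[2]), "emoc_referential_error")
      profiles$signal[, parts[2]]
    },
    cascade = {
      if (!parts[2] %in% dimnames(profiles$cascade)[[2]])
        abort(paste0("unknown emergency: ", parts[2]), "emoc_referential_error")
      profiles$cascade[, parts[2], as.integer(parts[3])]
    },
    abort(paste0("indicator must start with 'signal:' or 'cascade:': ", indicator),
          "emoc_schema_error"))
  readiness_estimate(sum(flags), profiles$n)
}

#' Stage-wise readiness drop-offs for one emergency
#'
#' Drop-off at stage 1 is 100 minus ready-through-stage-1 readiness (skill is
#' assumed universal, so the baseline is 100%); drop-off at stage k > 1 is the
#' ready-through-stage-(k-1) percentage minus the ready-through-stage-k
#' percentage. All arithmetic is on exact count fractions, so the three drops
#' plus the final stage-3 readiness telescope to exactly 100.
#'
#' @param profiles an `emoc_profiles` object.
#' @param emergency_id emergency identifier.
#' @return named numeric vector `c(identify, treat, monitor_modify)` of
#'   percentage-point drops.
#' @export
dropoff_by_stage <- function(profiles, emergency_id) {
  r <- vapply(1:3, function(k)
    proportion_ready(profiles, paste0("cascade:", emergency_id, ":", k))$percent, 0)
  out <- c(100 - r[1], r[1] - r[2], r[2] - r[3])
  names(out) <- STAGES
  out
}

#' Unweighted pooled mean and sample standard deviation
#'
#' Pooling across emergencies or stages is unweighted (each emergency counts
#' equally). The SD uses the n-1 denominator.
#'
#' @param values numeric vector of percentages.
#' @param sd compute the SD (default TRUE; requires at least two values).
#' @return list with `mean` and `sd` (`sd` is `NULL` when not requested).
#' @export
pooled_mean_sd <- function(values, sd = TRUE) {
  if (length(values) < 1L)
    abort("pooled mean requires at least one value", "emoc_structural_error")
  out <- list(mean = mean(values), sd = NULL)
  if (sd) {
    if (length(values) < 2L)
      abort("sample SD is undefined for a single value", "emoc_structural_error")
    out$sd <- stats::sd(values)
  }
  out
}

#' Tracer overestimation of cascade readiness
#'
#' Signal-function readiness minus cascade ready-through-stage-2 readiness for
#' the linked emergency, in percentage points, computed on exact fractions and
#' rounded only at display. Positive values mean the tracer view overstates
#' practical readiness to identify and treat the emergency.
#'
#' @param profiles an `emoc_profiles` object.
#' @param defs the `emoc_definitions` the profiles were scored under.
#' @param function_id signal-function identifier.
#' @return percentage points (numeric scalar, full precision).
#' @export
overestimation <- function(profiles, defs, function_id) {
  sf <- defs$signal_functions[[function_id]]
  if (is.null(sf))
    abort(paste0("unknown signal function: ", function_id), "emoc_referential_error")
  proportion_ready(profiles, paste0("signal:", function_id))$percent -
    proportion_ready(profiles, paste0("cascade:", sf$linked_emergency_id, ":2"))$percent
}

#' Partition a cohort by a facility attribute
#'
#' @param cohort an `emoc_cohort`.
#' @param attribute one of `"csec_capable"`, `"ownership"`, `"country"` (any
#'   attribute column works).
#' @return named list of sub-cohorts (disjoint, exhaustive; sizes sum to the
#'   cohort size). Names are the attribute values (`"TRUE"`/`"FALSE"` for
#'   logical attributes).
#' @export
stratify <- function(cohort, attribute) {
  stopifnot(inherits(cohort, "emoc_cohort"))
  if (!attribute %in% names(cohort$attributes))
    abort(paste0("unknown stratification attribute: ", attribute), "emoc_schema_error")
  vals <- cohort$attributes[[attribute]]
  if (anyNA(vals))
    abort(paste0("attribute '", attribute, "' is missing for facility: ",
                 paste(cohort$attributes$facility_id[is.na(vals)], collapse = ", ")),
          "emoc_schema_error")
  lapply(split(seq_along(vals), as.character(vals)), function(idx)
    facility_cohort(cohort$attributes[idx, , drop = FALSE],
                    cohort$presence[idx, , drop = FALSE],
                    provenance = paste0(cohort$provenance, " [", attribute, " stratum]")))
}

## ---- table assembly ----------------------------------------------------

# identifiers of emergencies linked from signal functions, in config order,
# split by function type
sf_pairs <- function(defs) {
  data.frame(
    function_id = vapply(defs$signal_functions, `[[`, "", "function_id"),
    emergency_id = vapply(defs$signal_functions, `[[`, "", "linked_emergency_id"),
    type = vapply(defs$signal_functions, `[[`, "", "function_type"),
    label = paste0("Manage ",
                   vapply(defs$signal_functions, function(sf)
                     defs$cascades[[sf$linked_emergency_id]]$label, ""),
                   " (", vapply(defs$signal_functions, `[[`, "", "label"), ")"),
    stringsAsFactors = FALSE, row.names = NULL)
}

comparison_table <- function(profiles, defs) {
  pairs <- sf_pairs(defs)
  n <- profiles$n
  per <- lapply(seq_len(nrow(pairs)), function(i) {
    sig <- proportion_ready(profiles, paste0("signal:", pairs$function_id[i]))
    casc <- proportion_ready(profiles, paste0("cascade:", pairs$emergency_id[i], ":2"))
    data.frame(row = pairs$label[i], group = pairs$type[i],
               signal_n = sig$numerator, cascade_n = casc$numerator, denominator = n,
               signal_pct = sig$percent, cascade_pct = casc$percent,
               overestimation_pct = sig$percent - casc$percent,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  pool <- function(rows, label, group) {
    data.frame(row = label, group = group, signal_n = NA_integer_,
               cascade_n = NA_integer_, denominator = n,
               signal_pct = mean(rows$signal_pct),
               cascade_pct = mean(rows$cascade_pct),
               overestimation_pct = mean(rows$signal_pct) - mean(rows$cascade_pct),
               stringsAsFactors = FALSE)
  }
  med <- per[per$group == "medical_treatment", , drop = FALSE]
  man <- per[per$group == "manual_procedure", , drop = FALSE]
  out <- rbind(
    med,
    if (nrow(med)) pool(med, "Medical readiness, overall mean (pooled)", "pooled_medical"),
    man,
    if (nrow(man)) pool(man, "Manual readiness, overall mean (pooled)", "pooled_manual"),
    pool(per, "Overall mean readiness (pooled)", "pooled_overall"))
  rownames(out) <- NULL
  out
}

dropoff_table <- function(profiles, defs) {
  emergencies <- names(defs$cascades)
  drops <- t(vapply(emergencies, function(e) dropoff_by_stage(profiles, e),
                    numeric(3)))
  per <- data.frame(
    emergency = emergencies,
    label = vapply(defs$cascades, `[[`, "", "label"),
    identify_drop = drops[, 1], treat_drop = drops[, 2], monitor_modify_drop = drops[, 3],
    mean_drop = rowMeans(drops),
    sd_drop = apply(drops, 1, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL)
  stages <- data.frame(
    stage = STAGES,
    pooled_mean_drop = colMeans(drops),
    sd_drop = apply(drops, 2, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_emergency = per, per_stage = stages,
       overall = list(mean = mean(per$mean_drop),
                      sd = stats::sd(per$mean_drop),
                      mean_of_sds = mean(per$sd_drop)))
}

#' Build the full family of readiness result tables
#'
#' Assembles: the tracer-versus-cascade comparison table (per emergency, with
#' medical, manual and overall pooled rows); the stage-wise drop-off table
#' (per-emergency drops with mean and sample SD, per-stage pooled means and
#' SDs, and the overall statistics: pooled mean of the per-emergency means,
#' sample SD of the per-emergency means, and mean of the per-emergency SDs);
#' and, for each requested attribute, stratified versions of both.
#'
#' @param cohort an `emoc_cohort`.
#' @param defs an `emoc_definitions`.
#' @param strata character vector of attribute names to stratify by (default:
#'   caesarean-section capability, ownership, country). Strata with no
#'   facilities yield NA rows rather than errors.
#' @param profiles optionally, pre-computed [score_cohort()] output.
#' @return list with elements `comparison`, `dropoff` and `stratified` (a list
#'   keyed by attribute; each entry has per-stratum `comparison` tables,
#'   per-stratum overall drop-off summaries, and stratum sizes).
#' @export
build_tables <- function(cohort, defs, strata = c("csec_capable", "ownership", "country"),
                         profiles = NULL) {
  if (is.null(profiles)) profiles <- score_cohort(cohort, defs)
  out <- list(comparison = comparison_table(profiles, defs),
              dropoff = dropoff_table(profiles, defs),
              stratified = list())
  for (attr_name in strata) {
    subs <- stratify(cohort, attr_name)
    strat <- lapply(subs, function(sub) {
      p <- score_cohort(sub, defs)
      list(n = p$n, comparison = comparison_table(p, defs),
           dropoff = dropoff_table(p, defs))
    })
    out$stratified[[attr_name]] <- strat
  }
  out
}
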