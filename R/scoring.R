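#' Evaluate a resource requirement against an inventory
#'
#' A requirement is satisfied when every alternative group contains at least
#' one resource the facility possesses. A skill-only requirement (no groups)
#' is always satisfied: commodity-based readiness assessment assumes clinician
#' skill to be universally present because it cannot be measured from a
#' physical inventory. Satisfaction is monotone -- adding resources to an
#' inventory can never un-satisfy a requirement.
#'
#' @param inv either a character vector of present resource_ids, or an
#'   `emoc_cohort` together with `facility_id`.
#' @param req an `emoc_requirement`.
#' @param facility_id facility to look up when `inv` is a cohort.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_requirement <- function(inv, req, facility_id = NULL) {
  stopifnot(inherits(req, "emoc_requirement"))
  present <- if (inherits(inv, "emoc_cohort")) present_resources(inv, facility_id)
             else as.character(inv)
  if (req$skill_only) return(TRUE)
  all(vapply(req$groups, function(g) any(g$alternatives %in% present), TRUE))
}

#' Cumulative cascade readiness profile for one facility
#'
#' Stage readiness is cumulative: a facility is ready through stage k only if
#' it satisfies the requirements of stages 1..k. A facility holding every
#' treatment commodity but unable to identify the emergency is therefore not
#' ready at any stage.
#'
#' @param inv character vector of present resource_ids (or an `emoc_cohort`
#'   plus `facility_id`).
#' @param cascade one element of `defs$cascades`.
#' @param facility_id facility to look up when `inv` is a cohort.
#' @return named logical vector `c(stage1, stage2, stage3)` of
#'   ready-through-stage flags (weakly decreasing).
#' @export
cascade_profile <- function(inv, cascade, facility_id = NULL) {
  sat <- vapply(STAGES, function(st)
    evaluate_requirement(inv, cascade$stages[[st]], facility_id), TRUE)
  out <- cumprod(sat) == 1
  names(out) <- c("stage1", "stage2", "stage3")
  out
}

#' Signal-function tracer readiness for one facility
#'
#' @param inv character vector of present resource_ids (or an `emoc_cohort`
#'   plus `facility_id`).
#' @param sf one element of `defs$signal_functions`.
#' @param facility_id facility to look up when `inv` is a cohort.
#' @return `TRUE` iff the tracer requirement is satisfied.
#' @export
signal_readiness <- function(inv, sf, facility_id = NULL) {
  evaluate_requirement(inv, sf$tracer, facility_id)
}

#' Service Readiness Index item average for one facility
#'
#' The WHO SRI variant of readiness: the fraction of all tracer
#' alternative-groups (across every signal function) that the facility
#' satisfies, in [0, 1]. This is the item-average counterpart of the binary
#' per-function readiness reported by [signal_readiness()].
#'
#' @param inv character vector of present resource_ids (or an `emoc_cohort`
#'   plus `facility_id`).
#' @param defs an `emoc_definitions`.
#' @param facility_id facility to look up when `inv` is a cohort.
#' @return fraction in [0, 1].
#' @export
sri_index <- function(inv, defs, facility_id = NULL) {
  stopifnot(inherits(defs, "emoc_definitions"))
  groups <- unlist(lapply(defs$signal_functions, function(sf) sf$tracer$groups),
                   recursive = FALSE)
  if (length(groups) == 0L)
    abort("sri_index is undefined: no tracer groups declared", "emoc_structural_error")
  present <- if (inherits(inv, "emoc_cohort")) present_resources(inv, facility_id)
             else as.character(inv)
  mean(vapply(groups, function(g) any(g$alternatives %in% present), TRUE))
}

#' Score every facility in a cohort under both readiness models
#'
#' @param cohort an `emoc_cohort`.
#' @param defs an `emoc_definitions`.
#' @return an object of class `emoc_profiles`: a list with
#'   \describe{
#'     \item{cascade}{logical array facility x emergency x stage of cumulative
#'       ready-through-stage flags}
#'     \item{signal}{logical matrix facility x signal function}
#'     \item{sri}{numeric vector of per-facility SRI item averages}
#'     \item{n}{cohort size}
#'   }
#' @export
score_cohort <- function(cohort, defs) {
  stopifnot(inherits(cohort, "emoc_cohort"), inherits(defs, "emoc_definitions"))
  fids <- cohort$attributes$facility_id
  emergencies <- names(defs$cascades)
  fns <- names(defs$signal_functions)
  casc <- array(FALSE, dim = c(length(fids), length(emergencies), 3L),
                dimnames = list(fids, emergencies, c("stage1", "stage2", "stage3")))
  sig <- matrix(FALSE, nrow = length(fids), ncol = length(fns),
                dimnames = list(fids, fns))
  sri <- numeric(length(fids))
  names(sri) <- fids
  for (f in fids) {
    present <- colnames(cohort$presence)[cohort$presence[f, ]]
    for (e in emergencies)
      casc[f, e, ] <- cascade_profile(present, defs$cascades[[e]])
    for (s in fns)
      sig[f, s] <- signal_readiness(present, defs$signal_functions[[s]])
    sri[f] <- sri_index(present, defs)
  }
  structure(list(cascade = casc, signal = sig, sri = sri, n = length(fids),
                 facility_id = fids),
            class = "emoc_profiles")
}

#' Facility-by-indicator 0/1 profile matrix
#'
#' Flattens scored profiles into a data.frame (one row per facility) suitable
#' for [write_table()]: cascade ready-through-stage flags per emergency,
#' per-function signal readiness, and the SRI item average.
#'
#' @param profiles an `emoc_profiles` object from [score_cohort()].
#' @return data.frame with `facility_id`, one 0/1 column per indicator, and
#'   `sri_index`.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(inherits(profiles, "emoc_profiles"))
  out <- data.frame(facility_id = profiles$facility_id, stringsAsFactors = FALSE)
  for (e in dimnames(profiles$cascade)[[2]])
    for (st in 1:3)
      out[[paste0("cascade_", e, "_stage", st)]] <-
        as.integer(profiles$cascade[, e, st])
  for (s in colnames(profiles$signal))
    out[[paste0("signal_", s)]] <- as.integer(profiles$signal[, s])
  out$sri_index <- profiles$sri
  out
}
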