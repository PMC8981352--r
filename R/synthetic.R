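#' Recover an integer count from a printed one-decimal percentage
#'
#' Published tables print facility proportions as one-decimal percentages over
#' a known denominator. For small n (consecutive fractions over n = 23 differ
#' by about 4.35 points) the printed value identifies the underlying count
#' uniquely; this inverts the rounding by exhaustive scan.
#'
#' @param percent_printed percentage as printed (1 decimal).
#' @param n cohort size.
#' @return the unique integer k in 0..n with
#'   `round_half_up(100 * k / n, 1) == percent_printed`.
#' @export
recover_count <- function(percent_printed, n) {
  if (n < 1) abort("n must be at least 1", "emoc_structural_error")
  hits <- which(abs(round_half_up(pct(0:n, n), 1) - percent_printed) < 1e-6) - 1L
  if (length(hits) == 0L)
    abort(sprintf("no count k in 0..%d prints as %.1f%% -- inconsistent table value",
                  n, percent_printed), "emoc_inconsistency_error")
  if (length(hits) > 1L)
    abort(sprintf("printed value %.1f%% is ambiguous for n = %d", percent_printed, n),
          "emoc_inconsistency_error")
  hits
}

# Printed one-decimal inputs from which the replica counts are recovered:
# per-function tracer percentages, per-emergency identify-stage drops,
# stage-2 readiness percentages and monitor-stage drops, each over n = 23.
# Stage-1 counts come from 100 minus the identify drop; stage-3 counts from
# the stage-2 count minus the count difference recovered from the
# monitor-stage drop (drops are exact count differences over n, so a printed
# drop identifies the count step the same way a printed level does).
replica_printed <- list(
  n = 23L,
  tracer_pct = c(antibiotic = 69.6, uterotonic = 60.9, anticonvulsant = 78.3,
                 retained_placenta_removal = 69.6, rpoc_removal = 69.6),
  identify_drop = c(sepsis = 26.1, haemorrhage = 0.0, hypertension = 69.6,
                    retained_placenta = 0.0, incomplete_abortion = 0.0),
  stage2_pct = c(sepsis = 47.8, haemorrhage = 60.9, hypertension = 26.1,
                 retained_placenta = 43.5, incomplete_abortion = 56.5),
  monitor_drop = c(sepsis = 17.4, haemorrhage = 47.8, hypertension = 13.0,
                   retained_placenta = 34.8, incomplete_abortion = 47.8),
  attributes = c(csec = 10L, private = 4L, uganda = 6L)
)

#' Replica count specification recovered from printed percentages
#'
#' Applies [recover_count()] to the published one-decimal percentages to
#' recover, over n = 23: each signal function's tracer-possession count and
#' each emergency's cumulative ready-through-stage counts (weakly decreasing
#' by construction of the cumulative cascade).
#'
#' @return list with `n`, `tracers` (named integer vector), `stages` (5 x 3
#'   integer matrix, rows = emergencies), `attributes` (named counts: 10
#'   C-section capable, 4 private, 6 Ugandan).
#' @export
replica_count_spec <- function() {
  p <- replica_printed
  n <- p$n
  tracers <- vapply(p$tracer_pct, recover_count, 0L, n = n)
  emergencies <- names(p$identify_drop)
  stages <- t(vapply(emergencies, function(e) {
    k1 <- recover_count(100 - p$identify_drop[[e]], n)
    k2 <- recover_count(p$stage2_pct[[e]], n)
    k3 <- k2 - recover_count(p$monitor_drop[[e]], n)
    c(k1, k2, k3)
  }, integer(3)))
  colnames(stages) <- c("stage1", "stage2", "stage3")
  if (any(stages[, 1] < stages[, 2]) || any(stages[, 2] < stages[, 3]))
    abort("recovered stage counts are not weakly decreasing", "emoc_inconsistency_error")
  if (any(stages < 0L | stages > n))
    abort("recovered count outside 0..n", "emoc_inconsistency_error")
  list(n = n, tracers = tracers, stages = stages, attributes = p$attributes)
}

#' Definition set for the replica fixture (synthetic)
#'
#' The replica uses disjoint abstract resource bundles per emergency and per
#' signal function (e.g. `hypertension_treat_bundle`) rather than the real
#' shared commodities, because the cross-emergency sharing pattern of the
#' source facilities is not recoverable from published marginal percentages.
#' Each cascade stage requirement is a single one-alternative group on its
#' bundle; the identify stages of the haemorrhage and retained-placenta
#' cascades are skill-only, matching the model in which those emergencies are
#' identified by clinical observation alone.
#'
#' @return an `emoc_definitions` object (version `replica-synthetic-1`).
#' @export
replica_definitions <- function() {
  spec <- replica_count_spec()
  emergencies <- rownames(spec$stages)
  labels <- c(sepsis = "Sepsis—infection", haemorrhage = "Haemorrhage",
              hypertension = "Hypertensive emergency",
              retained_placenta = "Retained placenta",
              incomplete_abortion = "Incomplete abortion")
  sf_labels <- c(antibiotic = "Antibiotic", uterotonic = "Uterotonics",
                 anticonvulsant = "Anticonvulsant",
                 retained_placenta_removal = "Removal of retained placenta",
                 rpoc_removal = "Removal of retained products of conception")
  sf_types <- c(antibiotic = "medical_treatment", uterotonic = "medical_treatment",
                anticonvulsant = "medical_treatment",
                retained_placenta_removal = "manual_procedure",
                rpoc_removal = "manual_procedure")
  sf_link <- c(antibiotic = "sepsis", uterotonic = "haemorrhage",
               anticonvulsant = "hypertension",
               retained_placenta_removal = "retained_placenta",
               rpoc_removal = "incomplete_abortion")
  skill_identify <- c("haemorrhage", "retained_placenta")

  res <- list()
  cascades <- list()
  for (e in emergencies) {
    stages <- list()
    for (st in STAGES) {
      if (st == "identify" && e %in% skill_identify) {
        stages[[st]] <- resource_requirement()
      } else {
        rid <- paste0(e, "_", st, "_bundle")
        res[[length(res) + 1L]] <- data.frame(
          resource_id = rid,
          label = paste0("Synthetic ", st, " bundle for ", e), category = "consumable",
          stringsAsFactors = FALSE)
        stages[[st]] <- resource_requirement(list(alt_group(rid)))
      }
    }
    cascades[[e]] <- list(emergency_id = e, label = labels[[e]], stages = stages)
  }
  sfs <- list()
  for (s in names(spec$tracers)) {
    rid <- paste0(s, "_tracer_bundle")
    res[[length(res) + 1L]] <- data.frame(
      resource_id = rid, label = paste0("Synthetic tracer bundle for ", s),
      category = "consumable", stringsAsFactors = FALSE)
    sfs[[s]] <- list(function_id = s, label = sf_labels[[s]],
                     function_type = sf_types[[s]], linked_emergency_id = sf_link[[s]],
                     tracer = resource_requirement(list(alt_group(rid))))
  }
  definition_set(do.call(rbind, res), cascades, sfs, version = "replica-synthetic-1")
}

#' Deterministic 23-facility replica cohort (synthetic)
#'
#' Builds the fixture whose scored output reproduces the published
#' all-facility readiness tables exactly. Resources are assigned by nested
#' prefixes: a bundle whose recovered target count is k is present in
#' facilities 1..k, which is one consistent completion of the (unpublished)
#' facility-level joint distribution and guarantees the cumulative cascade
#' counts. Attributes: facilities 1-10 are C-section capable, 1-4 private,
#' 5-10 Ugandan (so all six Ugandan facilities report C-section capability and
#' four Kenyan facilities do).
#'
#' @param defs the replica definition set; defaults to [replica_definitions()].
#' @return an `emoc_cohort` of 23 facilities.
#' @export
build_paper_replica <- function(defs = replica_definitions()) {
  spec <- replica_count_spec()
  n <- spec$n
  fids <- sprintf("F%02d", seq_len(n))

  targets <- integer(0)
  for (e in rownames(spec$stages))
    for (j in 1:3) {
      rid <- paste0(e, "_", STAGES[j], "_bundle")
      if (rid %in% defs$resources$resource_id)
        targets[rid] <- spec$stages[e, j]
    }
  for (s in names(spec$tracers))
    targets[paste0(s, "_tracer_bundle")] <- spec$tracers[[s]]

  missing <- setdiff(defs$resources$resource_id, names(targets))
  if (length(missing))
    abort(paste0("no target count for replica resource(s): ",
                 paste(missing, collapse = ", ")), "emoc_inconsistency_error")

  presence <- matrix(FALSE, n, length(targets),
                     dimnames = list(fids, names(targets)))
  for (rid in names(targets))
    presence[seq_len(targets[[rid]]), rid] <- TRUE

  att <- data.frame(
    facility_id = fids,
    country = ifelse(seq_len(n) %in% 5:10, "Uganda", "Kenya"),
    ownership = ifelse(seq_len(n) <= spec$attributes[["private"]],
                       "private", "government"),
    csec_capable = seq_len(n) <= spec$attributes[["csec"]],
    stringsAsFactors = FALSE)
  facility_cohort(att, presence,
                  provenance = "synthetic replica (counts recovered from printed percentages, n = 23)")
}

#' Configuration for the random cohort generator
#'
#' @param n_facilities number of facilities (>= 1).
#' @param marginals named numeric vector of per-resource marginal availability
#'   probabilities in [0, 1]; names must cover every declared resource of the
#'   definition set the cohort will be generated for. A single unnamed value
#'   is recycled to all resources at generation time.
#' @param mode `"nested_threshold"` (default): each facility draws a latent
#'   capacity u ~ U(0,1) and possesses resource r iff u <= marginal(r), so
#'   better-resourced facilities possess supersets of worse-resourced ones --
#'   the nested structure the replica fixture also uses. `"independent"`:
#'   independent per-facility, per-resource coin flips.
#' @param seed integer random seed; fixes the generated cohort exactly.
#' @return a validated list of class `emoc_generator_config`.
#' @export
generator_config <- function(n_facilities, marginals = 0.7,
                             mode = c("nested_threshold", "independent"),
                             seed = 20160101L) {
  mode <- match.arg(mode)
  if (!is.numeric(n_facilities) || length(n_facilities) != 1L || n_facilities < 1)
    abort("n_facilities must be a single integer >= 1", "emoc_config_error")
  if (any(marginals < 0 | marginals > 1) || anyNA(marginals))
    abort("marginal probabilities must lie in [0, 1]", "emoc_config_error")
  structure(list(n_facilities = as.integer(n_facilities), marginals = marginals,
                 mode = mode, seed = as.integer(seed)),
            class = "emoc_generator_config")
}

#' Generate a seeded synthetic facility cohort
#'
#' Emulates a physical-inventory facility survey: per-resource presence flags
#' plus facility attributes. Attribute frequencies follow the study setting
#' (10/23 C-section capable, 4/23 private, 6/23 Ugandan, with Ugandan
#' facilities drawn from the C-section-capable ones). Under nested-threshold
#' mode, readiness is monotone in the facility's latent capacity.
#'
#' @param config an [generator_config()] object.
#' @param defs an `emoc_definitions`.
#' @return an `emoc_cohort`; identical for identical `config` (seed included).
#' @export
generate_random <- function(config, defs) {
  stopifnot(inherits(config, "emoc_generator_config"),
            inherits(defs, "emoc_definitions"))
  n <- config$n_facilities
  rids <- defs$resources$resource_id
  m <- config$marginals
  if (is.null(names(m))) {
    if (length(m) != 1L)
      abort("unnamed marginals must be a single probability", "emoc_config_error")
    m <- stats::setNames(rep(m, length(rids)), rids)
  }
  miss <- setdiff(rids, names(m))
  if (length(miss))
    abort(paste0("no marginal availability for resource(s): ",
                 paste(miss, collapse = ", ")), "emoc_config_error")
  m <- m[rids]

  set.seed(config$seed)
  fids <- sprintf("S%03d", seq_len(n))
  presence <- matrix(FALSE, n, length(rids), dimnames = list(fids, rids))
  if (config$mode == "nested_threshold") {
    u <- stats::runif(n)
    for (j in seq_along(rids)) presence[, j] <- u <= m[j]
  } else {
    presence[] <- stats::runif(n * length(rids)) <= rep(m, each = n)
  }

  n_csec <- round(n * 10 / 23)
  n_private <- round(n * 4 / 23)
  n_uganda <- min(round(n * 6 / 23), n_csec)
  csec <- sample(seq_len(n), n_csec)
  uganda <- if (n_uganda > 0) sample(csec, n_uganda) else integer(0)
  private <- sample(seq_len(n), n_private)
  att <- data.frame(
    facility_id = fids,
    country = ifelse(seq_len(n) %in% uganda, "Uganda", "Kenya"),
    ownership = ifelse(seq_len(n) %in% private, "private", "government"),
    csec_capable = seq_len(n) %in% csec,
    stringsAsFactors = FALSE)
  facility_cohort(att, presence,
                  provenance = sprintf("generate_random(mode = %s, seed = %d)",
                                       config$mode, config$seed))
}
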