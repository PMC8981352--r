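#' @title Requirement and definition-set constructors
#' @description
#' The unit of "has what is needed" is a resource requirement: a conjunction
#' of alternative-groups of resource identifiers. A facility satisfies a group
#' when it possesses ANY one of the group's alternatives (this is how proxy
#' substitutions such as electrical power standing in for refrigeration are
#' encoded -- the proxy is an extra alternative inside the group, not a
#' separate substitution pass), and satisfies the requirement when ALL groups
#' are satisfied. A requirement with no groups is `skill_only`: it models a
#' stage that depends on clinician skill alone, which commodity-based surveys
#' assume to be universally present, so it is always satisfied.
#' @name requirements
NULL

#' Alternative group of interchangeable resources
#'
#' @param alternatives character vector of resource identifiers; possession of
#'   any one satisfies the group.
#' @param note optional free text documenting why the alternatives are
#'   interchangeable (e.g. a proxy rationale).
#' @return an object of class `emoc_group`.
#' @export
alt_group <- function(alternatives, note = NULL) {
  alternatives <- as.character(unlist(alternatives, use.names = FALSE))
  if (length(alternatives) == 0L || any(!nzchar(alternatives)) || anyNA(alternatives))
    abort("an alternative group must list at least one non-empty resource_id",
          "emoc_schema_error")
  structure(list(alternatives = unique(alternatives),
                 note = if (is.null(note)) NULL else as.character(note)),
            class = "emoc_group")
}

#' Resource requirement (conjunction of alternative groups)
#'
#' @param groups list of [alt_group()] objects (or lists coercible to them).
#'   An empty list yields a skill-only requirement that every inventory
#'   satisfies.
#' @return an object of class `emoc_requirement` with fields `groups` and
#'   `skill_only` (`TRUE` exactly when `groups` is empty).
#' @export
resource_requirement <- function(groups = list()) {
  groups <- lapply(groups, function(g) {
    if (inherits(g, "emoc_group")) g else alt_group(g$alternatives %||% g, g$note)
  })
  structure(list(groups = groups, skill_only = length(groups) == 0L),
            class = "emoc_requirement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

req_tokens <- function(req) unique(unlist(lapply(req$groups, `[[`, "alternatives")))

CATEGORIES <- c("drug", "consumable", "durable", "protocol")
STAGES <- c("identify", "treat", "monitor_modify")
FUNCTION_TYPES <- c("medical_treatment", "manual_procedure")

#' Assemble and validate a definition set
#'
#' A definition set bundles the declared resources, the per-emergency clinical
#' cascades (exactly three ordered stage requirements: identify, treat,
#' monitor-modify) and the signal-function tracer definitions. Referential
#' integrity (every referenced resource_id is declared; every signal
#' function's linked emergency exists) is enforced here, so downstream scoring
#' can assume it.
#'
#' @param resources data.frame with columns `resource_id`, `label`,
#'   `category` (one of drug, consumable, durable, protocol).
#' @param cascades named list; each element has `emergency_id`, optional
#'   `label`, and `stages`, a list of three `emoc_requirement`s named
#'   `identify`, `treat`, `monitor_modify`.
#' @param signal_functions named list; each element has `function_id`,
#'   optional `label`, `function_type` (medical_treatment or
#'   manual_procedure), `linked_emergency_id` and `tracer` (an
#'   `emoc_requirement`).
#' @param version character version tag for provenance.
#' @return an object of class `emoc_definitions`.
#' @export
definition_set <- function(resources, cascades, signal_functions, version = "unversioned") {
  resources <- as.data.frame(resources, stringsAsFactors = FALSE)
  need <- c("resource_id", "label", "category")
  if (!all(need %in% names(resources)))
    abort(paste0("resources table must have columns: ", paste(need, collapse = ", ")),
          "emoc_schema_error")
  if (anyNA(resources$resource_id) || any(!nzchar(resources$resource_id)))
    abort("resource_id must be non-empty", "emoc_schema_error")
  dup <- resources$resource_id[duplicated(resources$resource_id)]
  if (length(dup))
    abort(paste0("duplicate resource_id: ", paste(unique(dup), collapse = ", ")),
          "emoc_schema_error")
  bad <- setdiff(unique(resources$category), CATEGORIES)
  if (length(bad))
    abort(paste0("unknown resource category: ", paste(bad, collapse = ", "),
                 " (field 'category' must be one of ", paste(CATEGORIES, collapse = ", "), ")"),
          "emoc_schema_error")

  if (anyDuplicated(vapply(cascades, `[[`, "", "emergency_id")))
    abort("duplicate emergency_id in cascades", "emoc_schema_error")
  for (cd in cascades) {
    if (!identical(names(cd$stages), STAGES) || length(cd$stages) != 3L)
      abort(paste0("cascade '", cd$emergency_id,
                   "' must have exactly 3 stages named identify, treat, monitor_modify"),
            "emoc_structural_error")
  }
  if (anyDuplicated(vapply(signal_functions, `[[`, "", "function_id")))
    abort("duplicate function_id in signal_functions", "emoc_schema_error")
  for (sf in signal_functions) {
    if (!sf$function_type %in% FUNCTION_TYPES)
      abort(paste0("signal function '", sf$function_id, "': function_type must be one of ",
                   paste(FUNCTION_TYPES, collapse = ", ")), "emoc_schema_error")
    if (!sf$linked_emergency_id %in% vapply(cascades, `[[`, "", "emergency_id"))
      abort(paste0("signal function '", sf$function_id, "' links to undeclared emergency '",
                   sf$linked_emergency_id, "'"), "emoc_referential_error")
  }

  # referential integrity across every requirement
  declared <- resources$resource_id
  dangling <- character(0)
  for (cd in cascades)
    for (st in STAGES)
      dangling <- c(dangling, setdiff(req_tokens(cd$stages[[st]]), declared))
  for (sf in signal_functions)
    dangling <- c(dangling, setdiff(req_tokens(sf$tracer), declared))
  dangling <- unique(dangling)
  if (length(dangling))
    abort(paste0("undeclared resource_id referenced: ", paste(dangling, collapse = ", ")),
          "emoc_referential_error")

  names(cascades) <- vapply(cascades, `[[`, "", "emergency_id")
  names(signal_functions) <- vapply(signal_functions, `[[`, "", "function_id")
  structure(list(resources = resources, cascades = cascades,
                 signal_functions = signal_functions, version = as.character(version)),
            class = "emoc_definitions")
}

#' @export
print.emoc_definitions <- function(x, ...) {
  cat("Emergency readiness definition set (version ", x$version, ")\n", sep = "")
  cat("  resources:        ", nrow(x$resources), "\n", sep = "")
  cat("  cascades:         ", length(x$cascades), " (",
      paste(names(x$cascades), collapse = ", "), ")\n", sep = "")
  cat("  signal functions: ", length(x$signal_functions), " (",
      paste(names(x$signal_functions), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

## ---- config file io ---------------------------------------------------

req_from_config <- function(x, where) {
  if (is.null(x))
    abort(paste0("missing stage/tracer requirement at ", where), "emoc_schema_error")
  if (isTRUE(x$skill_only)) {
    if (length(x$groups %||% list()))
      abort(paste0(where, ": skill_only requirement must not list groups"),
            "emoc_schema_error")
    return(resource_requirement())
  }
  groups <- x$groups
  if (is.null(groups))
    abort(paste0(where, ": requirement needs either 'groups' or 'skill_only: true'"),
          "emoc_schema_error")
  resource_requirement(lapply(groups, function(g) {
    if (is.null(g$alternatives))
      abort(paste0(where, ": group is missing field 'alternatives'"), "emoc_schema_error")
    alt_group(g$alternatives, g$note)
  }))
}

#' Load a definition set from a YAML or JSON config file
#'
#' The config has top-level keys `version`, `resources`, `cascades` and
#' `signal_functions`; resource lists are data, never code. See the packaged
#' default at `system.file("extdata", "definitions_default.yaml",
#' package = "emocascade")` for the documented schema.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `emoc_definitions` object.
#' @seealso [definition_set()], [write_definitions()], [default_definitions()]
#' @export
load_definitions <- function(path) {
  if (!file.exists(path))
    abort(paste0("definitions file not found: ", path), "emoc_io_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) abort(paste0("cannot parse ", path, ": ",
                                              conditionMessage(e)), "emoc_schema_error"))
  }
  for (key in c("resources", "cascades", "signal_functions"))
    if (is.null(raw[[key]]))
      abort(paste0("config is missing top-level field '", key, "'"), "emoc_schema_error")

  resources <- do.call(rbind, lapply(raw$resources, function(r) {
    for (f in c("id", "label", "category"))
      if (is.null(r[[f]]))
        abort(paste0("resource entry is missing field '", f, "'"), "emoc_schema_error")
    data.frame(resource_id = r$id, label = r$label, category = r$category,
               stringsAsFactors = FALSE)
  }))
  cascades <- lapply(raw$cascades, function(cd) {
    if (is.null(cd$emergency))
      abort("cascade entry is missing field 'emergency'", "emoc_schema_error")
    if (is.null(cd$stages) || !all(STAGES %in% names(cd$stages)) ||
        length(cd$stages) != 3L)
      abort(paste0("cascade '", cd$emergency,
                   "' must declare exactly the stages identify, treat, monitor_modify"),
            "emoc_structural_error")
    stages <- lapply(STAGES, function(st)
      req_from_config(cd$stages[[st]], paste0("cascade '", cd$emergency, "' stage '", st, "'")))
    names(stages) <- STAGES
    list(emergency_id = cd$emergency, label = cd$label %||% cd$emergency, stages = stages)
  })
  sfs <- lapply(raw$signal_functions, function(sf) {
    for (f in c("id", "type", "emergency", "tracer"))
      if (is.null(sf[[f]]))
        abort(paste0("signal function entry is missing field '", f, "'"), "emoc_schema_error")
    list(function_id = sf$id, label = sf$label %||% sf$id, function_type = sf$type,
         linked_emergency_id = sf$emergency,
         tracer = req_from_config(sf$tracer, paste0("signal function '", sf$id, "' tracer")))
  })
  definition_set(resources, cascades, sfs, version = raw$version %||% "unversioned")
}

#' The packaged default definition set
#'
#' Loads the default config shipped with the package: five clinical cascades
#' (sepsis, haemorrhage, hypertensive emergency, retained placenta, incomplete
#' abortion) and the five measurable signal functions (parenteral antibiotics,
#' uterotonics, anticonvulsants; removal of retained placenta, removal of
#' retained products of conception). Assisted vaginal delivery is absent: its
#' tracer items are not measurable from commodity inventories of this kind.
#'
#' @return an `emoc_definitions` object.
#' @export
default_definitions <- function() {
  load_definitions(system.file("extdata", "definitions_default.yaml",
                               package = "emocascade"))
}

req_to_config <- function(req) {
  if (req$skill_only) return(list(skill_only = TRUE))
  list(groups = lapply(req$groups, function(g) {
    out <- list(alternatives = as.list(g$alternatives))
    if (!is.null(g$note)) out$note <- g$note
    out
  }))
}

defs_to_config <- function(defs) {
  list(
    version = defs$version,
    resources = lapply(seq_len(nrow(defs$resources)), function(i)
      list(id = defs$resources$resource_id[i], label = defs$resources$label[i],
           category = defs$resources$category[i])),
    cascades = lapply(unname(defs$cascades), function(cd) {
      stages <- lapply(cd$stages, req_to_config)
      list(emergency = cd$emergency_id, label = cd$label, stages = stages)
    }),
    signal_functions = lapply(unname(defs$signal_functions), function(sf)
      list(id = sf$function_id, label = sf$label, type = sf$function_type,
           emergency = sf$linked_emergency_id, tracer = req_to_config(sf$tracer)))
  )
}

#' Serialise a definition set back to YAML or JSON
#'
#' `load_definitions(write_definitions(defs, path))` round-trips to a
#' definition set equal to `defs`.
#'
#' @param defs an `emoc_definitions` object.
#' @param path output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_definitions <- function(defs, path) {
  stopifnot(inherits(defs, "emoc_definitions"))
  cfg <- defs_to_config(defs)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Flat CSV export of a definition set for audit
#'
#' One row per (scope, emergency-or-function, stage, group, alternative), so
#' the full conjunction-of-disjunctions structure can be reviewed in a
#' spreadsheet. Skill-only stages export a single row with empty group and
#' alternative columns.
#'
#' @param defs an `emoc_definitions` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_definitions_csv <- function(defs, path) {
  stopifnot(inherits(defs, "emoc_definitions"))
  rows <- list()
  add <- function(scope, id, stage, req) {
    if (req$skill_only) {
      rows[[length(rows) + 1L]] <<- data.frame(
        scope = scope, emergency_or_function = id, stage = stage,
        group_index = NA_integer_, alternative_resource_id = "",
        stringsAsFactors = FALSE)
      return(invisible())
    }
    for (i in seq_along(req$groups))
      for (alt in req$groups[[i]]$alternatives)
        rows[[length(rows) + 1L]] <<- data.frame(
          scope = scope, emergency_or_function = id, stage = stage,
          group_index = i, alternative_resource_id = alt,
          stringsAsFactors = FALSE)
  }
  for (cd in defs$cascades)
    for (st in STAGES) add("cascade", cd$emergency_id, st, cd$stages[[st]])
  for (sf in defs$signal_functions) add("signal_function", sf$function_id, "tracer", sf$tracer)
  write_table(do.call(rbind, rows), path)
}

#' Check the three-drug antibiotic tracer definition
#'
#' Readiness to administer parenteral antibiotics is operationalised as the
#' WHO three-step obstetric antibiotic escalation sequence: the facility must
#' stock ampicillin AND gentamicin AND metronidazole. This check asserts that
#' the antibiotic tracer in a loaded definition set is exactly that
#' conjunction of three single-drug groups.
#'
#' @param defs an `emoc_definitions` object.
#' @param function_id identifier of the antibiotic signal function (default
#'   `"antibiotic"`).
#' @return a list of class `emoc_antibiotic_check` with fields `pass`,
#'   `n_groups`, `missing` (required drugs absent) and `unexpected` (extra
#'   drug groups beyond the three-step sequence).
#' @export
validate_antibiotic_definition <- function(defs, function_id = "antibiotic") {
  stopifnot(inherits(defs, "emoc_definitions"))
  required <- c("ampicillin", "gentamicin", "metronidazole")
  sf <- defs$signal_functions[[function_id]]
  if (is.null(sf))
    abort(paste0("no signal function '", function_id, "' in definition set"),
          "emoc_referential_error")
  groups <- lapply(sf$tracer$groups, `[[`, "alternatives")
  covered <- required[vapply(required, function(d) any(vapply(groups, function(g)
    identical(g, d) || (length(g) == 1L && g == d), TRUE)), TRUE)]
  missing <- setdiff(required, covered)
  unexpected <- Filter(function(g) !(length(g) == 1L && g %in% required), groups)
  out <- list(pass = length(missing) == 0L && length(unexpected) == 0L &&
                length(groups) == 3L,
              n_groups = length(groups), missing = missing,
              unexpected = vapply(unexpected, paste, "", collapse = "|"))
  class(out) <- "emoc_antibiotic_check"
  out
}

#' @export
print.emoc_antibiotic_check <- function(x, ...) {
  cat("Antibiotic tracer check:", if (x$pass) "PASS" else "FAIL",
      sprintf("(%d group%s)\n", x$n_groups, if (x$n_groups == 1L) "" else "s"))
  if (length(x$missing)) cat("  missing drug(s):", paste(x$missing, collapse = ", "), "\n")
  if (length(x$unexpected)) cat("  unexpected group(s):", paste(x$unexpected, collapse = "; "), "\n")
  invisible(x)
}
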