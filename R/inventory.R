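#' Construct a facility cohort
#'
#' @param attributes data.frame with columns `facility_id`, `country`,
#'   `ownership` (government/private), `csec_capable` (logical; reported
#'   caesarean-section capability, the proxy for CEmOC designation).
#' @param presence logical matrix, facilities x resources, with rownames equal
#'   to `attributes$facility_id` and colnames drawn from the declared
#'   resources of the active definition set. `TRUE` means the resource was
#'   observed anywhere in the facility (presence is facility-level regardless
#'   of unit).
#' @param provenance free-text note recording where the cohort came from.
#' @return an object of class `emoc_cohort`.
#' @export
facility_cohort <- function(attributes, presence, provenance = "constructed in R") {
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  need <- c("facility_id", "country", "ownership", "csec_capable")
  miss <- setdiff(need, names(attributes))
  if (length(miss))
    abort(paste0("attributes are missing column(s): ", paste(miss, collapse = ", ")),
          "emoc_schema_error")
  if (nrow(attributes) == 0L)
    abort("a cohort must contain at least one facility", "emoc_schema_error")
  if (anyDuplicated(attributes$facility_id))
    abort("facility_id must be unique within a cohort", "emoc_schema_error")
  attributes$facility_id <- as.character(attributes$facility_id)
  attributes$csec_capable <- as_flag(attributes$csec_capable, "csec_capable")
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  if (is.null(rownames(presence)) ||
      !identical(sort(rownames(presence)), sort(attributes$facility_id)))
    abort("presence matrix rownames must match attributes$facility_id", "emoc_schema_error")
  presence <- presence[attributes$facility_id, , drop = FALSE]
  structure(list(attributes = attributes, presence = presence,
                 provenance = provenance),
            class = "emoc_cohort")
}

as_flag <- function(x, field) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  if (is.character(x)) {
    lx <- tolower(trimws(x))
    ok <- lx %in% c("true", "false", "0", "1", "yes", "no")
    if (all(ok)) return(lx %in% c("true", "1", "yes"))
  }
  abort(paste0("column '", field, "' must be 0/1 or TRUE/FALSE"), "emoc_schema_error")
}

#' @export
print.emoc_cohort <- function(x, ...) {
  cat("Facility cohort: n =", nrow(x$attributes), "facilities,",
      ncol(x$presence), "tracked resources\n")
  cat("  C-section capable:", sum(x$attributes$csec_capable), "|",
      "countries:", paste(sort(unique(x$attributes$country)), collapse = ", "), "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Resources present at one facility
#'
#' @param cohort an `emoc_cohort`.
#' @param facility_id facility identifier.
#' @return character vector of present resource_ids.
#' @export
present_resources <- function(cohort, facility_id) {
  stopifnot(inherits(cohort, "emoc_cohort"))
  if (!facility_id %in% rownames(cohort$presence))
    abort(paste0("unknown facility_id: ", facility_id), "emoc_referential_error")
  colnames(cohort$presence)[cohort$presence[facility_id, ]]
}

#' Read a facility cohort from inventory and attribute CSV files
#'
#' Accepts either long form (columns `facility_id, resource_id, present` with
#' present in 0/1) or wide form (`facility_id` plus one 0/1 column per
#' resource); the form is auto-detected from the header. Duplicate
#' (facility, resource) records -- e.g. the same drug recorded in two units --
#' collapse to a single facility-level presence flag; duplicates with
#' conflicting flags are an error. Declared resources never mentioned in the
#' file are treated as not present, with a coverage warning, because an absent
#' record is not a measured absence.
#'
#' @param resources_path CSV of resource presence (long or wide form).
#' @param attributes_path CSV with columns `facility_id, country, ownership,
#'   csec_capable`.
#' @param defs the active `emoc_definitions`; presence columns are aligned to
#'   its declared resources.
#' @param unknown_policy what to do with resource tokens not declared in
#'   `defs`: `"error"` (default) rejects the file listing the tokens;
#'   `"warn_drop"` drops them with a warning.
#' @return an `emoc_cohort`.
#' @export
read_inventory <- function(resources_path, attributes_path, defs,
                           unknown_policy = c("error", "warn_drop")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(defs, "emoc_definitions"))
  attributes <- utils::read.csv(attributes_path, stringsAsFactors = FALSE)
  need <- c("facility_id", "country", "ownership", "csec_capable")
  miss <- setdiff(need, names(attributes))
  if (length(miss))
    abort(paste0("attributes file is missing column(s): ", paste(miss, collapse = ", ")),
          "emoc_schema_error")
  attributes$facility_id <- as.character(attributes$facility_id)

  inv <- utils::read.csv(resources_path, stringsAsFactors = FALSE)
  long <- setequal(names(inv), c("facility_id", "resource_id", "present"))
  if (!long && !"facility_id" %in% names(inv))
    abort("inventory file must be long form (facility_id, resource_id, present) or wide form (facility_id + one column per resource)",
          "emoc_schema_error")

  if (long) {
    inv$facility_id <- as.character(inv$facility_id)
    if (nrow(inv) && !all(inv$present %in% c(0, 1)))
      abort("presence flags must be 0 or 1", "emoc_schema_error")
    long_df <- inv
  } else {
    res_cols <- setdiff(names(inv), "facility_id")
    vals <- unlist(inv[res_cols], use.names = FALSE)
    if (length(vals) && !all(vals %in% c(0, 1)))
      abort("presence flags must be 0 or 1", "emoc_schema_error")
    long_df <- data.frame(
      facility_id = rep(as.character(inv$facility_id), times = length(res_cols)),
      resource_id = rep(res_cols, each = nrow(inv)),
      present = unlist(inv[res_cols], use.names = FALSE),
      stringsAsFactors = FALSE)
  }

  declared <- defs$resources$resource_id
  unknown <- setdiff(unique(long_df$resource_id), declared)
  if (length(unknown)) {
    if (unknown_policy == "error")
      abort(paste0("unknown resource token(s) not in the definition set: ",
                   paste(unknown, collapse = ", ")), "emoc_referential_error")
    warning("dropping unknown resource token(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    long_df <- long_df[long_df$resource_id %in% declared, , drop = FALSE]
  }

  extra_fac <- setdiff(unique(long_df$facility_id), attributes$facility_id)
  if (length(extra_fac))
    abort(paste0("inventory mentions facilities absent from the attributes file: ",
                 paste(extra_fac, collapse = ", ")), "emoc_referential_error")

  # collapse unit-level duplicates; conflicting flags are a data error
  if (nrow(long_df)) {
    key <- paste(long_df$facility_id, long_df$resource_id, sep = "\r")
    agg_min <- tapply(long_df$present, key, min)
    agg_max <- tapply(long_df$present, key, max)
    conflict <- names(agg_min)[agg_min != agg_max]
    if (length(conflict)) {
      fac <- unique(vapply(strsplit(conflict, "\r", fixed = TRUE), `[[`, "", 1L))
      abort(paste0("conflicting presence flags for facility: ",
                   paste(fac, collapse = ", ")), "emoc_schema_error")
    }
  }

  presence <- matrix(FALSE, nrow = nrow(attributes), ncol = length(declared),
                     dimnames = list(attributes$facility_id, declared))
  pres_rows <- long_df[long_df$present == 1, , drop = FALSE]
  if (nrow(pres_rows))
    presence[cbind(pres_rows$facility_id, pres_rows$resource_id)] <- TRUE

  unreported <- setdiff(declared, unique(long_df$resource_id))
  if (length(unreported))
    warning("declared resource(s) never reported in the inventory file are treated as absent: ",
            paste(unreported, collapse = ", "), call. = FALSE)

  facility_cohort(attributes, presence,
                  provenance = paste0("read_inventory(", basename(resources_path), ")"))
}

#' Write a cohort back to attribute and long-form inventory CSVs
#'
#' Reading the written pair with [read_inventory()] round-trips presence flags
#' exactly.
#'
#' @param cohort an `emoc_cohort`.
#' @param resources_path,attributes_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, resources_path, attributes_path) {
  stopifnot(inherits(cohort, "emoc_cohort"))
  att <- cohort$attributes
  att$csec_capable <- as.integer(att$csec_capable)
  write_table(att, attributes_path)
  long_df <- data.frame(
    facility_id = rep(rownames(cohort$presence), times = ncol(cohort$presence)),
    resource_id = rep(colnames(cohort$presence), each = nrow(cohort$presence)),
    present = as.integer(cohort$presence),
    stringsAsFactors = FALSE)
  long_df <- long_df[order(long_df$facility_id, long_df$resource_id), ]
  write_table(long_df, resources_path)
  invisible(c(resources_path, attributes_path))
}

#' Write a result table as a deterministic CSV
#'
#' Percentage columns (any numeric column whose name ends in `_pct` or that is
#' listed in `pct_cols`) are written at 1 decimal with half-away-from-zero
#' rounding; integer-valued columns are written as integers. Byte output is
#' deterministic for fixed input (fixed column order, LF line endings, UTF-8).
#'
#' @param table a data.frame.
#' @param path output path.
#' @param pct_cols extra column names to format as percentages.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, pct_cols = character(0)) {
  stopifnot(is.data.frame(table))
  df <- table
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.numeric(x)) {
      if (grepl("_pct$", nm) || nm %in% pct_cols || grepl("_sd$|_mean$|_drop$", nm)) {
        df[[nm]] <- fmt1(x)
      } else if (all(is.na(x) | x == floor(x))) {
        df[[nm]] <- ifelse(is.na(x), "NA", format(x, scientific = FALSE, trim = TRUE))
      } else {
        df[[nm]] <- ifelse(is.na(x), "NA", format(x, scientific = FALSE, trim = TRUE,
                                                  digits = 15))
      }
    } else if (is.logical(x)) {
      df[[nm]] <- ifelse(is.na(x), "NA", ifelse(x, "1", "0"))
    } else {
      df[[nm]] <- ifelse(is.na(x), "NA", as.character(x))
    }
  }
  quote_field <- function(x) {
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  df[] <- lapply(df, quote_field)
  lines <- c(paste(quote_field(names(df)), collapse = ","),
             if (nrow(df)) do.call(paste, c(unname(df), sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
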