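# Small in-code fixtures shared across tests.

toy_defs <- function() {
  resources <- data.frame(
    resource_id = c("a", "b", "c", "d", "e", "f"),
    label = paste("Item", c("a", "b", "c", "d", "e", "f")),
    category = c("drug", "drug", "consumable", "durable", "protocol", "durable"),
    stringsAsFactors = FALSE)
  cascades <- list(
    list(emergency_id = "em1", label = "Emergency one", stages = list(
      identify = resource_requirement(list(alt_group("a"))),
      treat = resource_requirement(list(alt_group(c("b", "c")), alt_group("d"))),
      monitor_modify = resource_requirement(list(alt_group("e"))))),
    list(emergency_id = "em2", label = "Emergency two", stages = list(
      identify = resource_requirement(),   # skill-only
      treat = resource_requirement(list(alt_group("f"))),
      monitor_modify = resource_requirement(list(alt_group("e"))))))
  sfs <- list(
    list(function_id = "sf1", label = "Tracer one", function_type = "medical_treatment",
         linked_emergency_id = "em1",
         tracer = resource_requirement(list(alt_group(c("b", "c"))))),
    list(function_id = "sf2", label = "Tracer two", function_type = "manual_procedure",
         linked_emergency_id = "em2",
         tracer = resource_requirement(list(alt_group("f")))))
  definition_set(resources, cascades, sfs, version = "toy-1")
}

toy_cohort <- function(present, defs = toy_defs(),
                       country = "Kenya", ownership = "government",
                       csec = TRUE) {
  fids <- names(present)
  rids <- defs$resources$resource_id
  presence <- matrix(FALSE, length(fids), length(rids),
                     dimnames = list(fids, rids))
  for (f in fids) presence[f, intersect(present[[f]], rids)] <- TRUE
  att <- data.frame(facility_id = fids,
                    country = rep_len(country, length(fids)),
                    ownership = rep_len(ownership, length(fids)),
                    csec_capable = rep_len(csec, length(fids)),
                    stringsAsFactors = FALSE)
  facility_cohort(att, presence, provenance = "test fixture")
}

# Independent oracle for requirement satisfaction: build the boolean formula
# as an R expression over per-resource logicals and eval() it, rather than
# reusing the package's set arithmetic.
oracle_requirement <- function(req, present, universe) {
  if (length(req$groups) == 0L) return(TRUE)
  env <- list2env(as.list(stats::setNames(universe %in% present, universe)),
                  parent = baseenv())
  expr <- paste(vapply(req$groups, function(g)
    paste0("(", paste(g$alternatives, collapse = " | "), ")"), ""),
    collapse = " & ")
  eval(parse(text = expr), envir = env)
}

# random requirement over tokens r1..rk with <= 12 total alternatives
rand_requirement <- function(tokens) {
  k <- length(tokens)
  n_groups <- sample(1:3, 1)
  left <- sample(tokens)
  groups <- list()
  for (i in seq_len(n_groups)) {
    take <- sample(1:min(3, length(left)), 1)
    groups[[i]] <- alt_group(left[seq_len(take)])
    left <- left[-seq_len(take)]
    if (!length(left)) break
  }
  resource_requirement(groups)
}

write_yaml_config <- function(text) {
  path <- tempfile(fileext = ".yaml")
  writeLines(text, path)
  path
}

replica_fixture_paths <- function() {
  c(inventory = system.file("extdata", "replica_inventory_synthetic.csv",
                            package = "emocascade"),
    attributes = system.file("extdata", "replica_attributes_synthetic.csv",
                             package = "emocascade"),
    definitions = system.file("extdata", "definitions_replica_synthetic.yaml",
                              package = "emocascade"))
}
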