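test_that("requirement evaluation: skill-only, conjunctions and proxy alternatives", {
  # skill-only requirements are satisfied by any inventory, including an empty one
  skill <- resource_requirement()
  expect_true(evaluate_requirement(character(0), skill))
  expect_true(evaluate_requirement(c("anything"), skill))

  # conjunction of three single-drug groups: two of three is not enough
  abx <- resource_requirement(list(alt_group("ampicillin"), alt_group("gentamicin"),
                                   alt_group("metronidazole")))
  expect_false(evaluate_requirement(c("ampicillin", "gentamicin"), abx))
  expect_true(evaluate_requirement(c("ampicillin", "gentamicin", "metronidazole"), abx))

  # a proxy is an extra alternative inside the group: power satisfies refrigeration
  fridge <- resource_requirement(list(alt_group(c("refrigeration", "electricity"))))
  expect_true(evaluate_requirement("electricity", fridge))
  expect_false(evaluate_requirement("flashlight", fridge))
})

test_that("requirement evaluation agrees with a brute-force boolean oracle on all inventory subsets", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    tokens <- paste0("r", seq_len(k))
    req <- rand_requirement(tokens)
    for (bits in 0:(2^k - 1)) {
      present <- tokens[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0]
      expect_identical(evaluate_requirement(present, req),
                       oracle_requirement(req, present, tokens))
    }
  }
})

test_that("readiness is monotone: adding a resource never flips any output to FALSE", {
  defs <- default_definitions()
  rids <- defs$resources$resource_id
  set.seed(7)
  for (rep in 1:40) {
    present <- sample(rids, sample(0:length(rids), 1))
    extra <- if (length(setdiff(rids, present))) sample(setdiff(rids, present), 1) else character(0)
    bigger <- c(present, extra)
    for (cd in defs$cascades) {
      before <- cascade_profile(present, cd)
      after <- cascade_profile(bigger, cd)
      expect_true(all(after >= before))
    }
    for (sf in defs$signal_functions)
      expect_true(signal_readiness(bigger, sf) >= signal_readiness(present, sf))
    expect_true(sri_index(bigger, defs) >= sri_index(present, defs))
  }
})

test_that("cascade readiness is cumulative", {
  defs <- default_definitions()
  # a facility holding every stage-2 sepsis item but no thermometer fails all stages
  sepsis <- defs$cascades$sepsis
  treat_only <- c("ampicillin", "gentamicin", "metronidazole", "syringes_needles",
                  "iv_infusion_set", "iv_fluids", "gloves")
  expect_identical(unname(cascade_profile(treat_only, sepsis)), c(FALSE, FALSE, FALSE))

  # full inventory is ready through every stage of every cascade
  everything <- defs$resources$resource_id
  for (cd in defs$cascades)
    expect_identical(unname(cascade_profile(everything, cd)), c(TRUE, TRUE, TRUE))

  # haemorrhage identification needs skill alone: an empty facility is ready
  # through stage 1 and nothing further
  expect_identical(unname(cascade_profile(character(0), defs$cascades$haemorrhage)),
                   c(TRUE, FALSE, FALSE))

  # ready-through-stage flags are weakly decreasing for random inventories
  set.seed(11)
  for (rep in 1:30) {
    present <- sample(everything, sample(0:length(everything), 1))
    for (cd in defs$cascades) {
      p <- cascade_profile(present, cd)
      expect_true(all(diff(as.integer(p)) <= 0))
    }
  }
})

test_that("signal-function readiness follows the tracer requirement", {
  defs <- default_definitions()
  expect_true(signal_readiness(c("ampicillin", "gentamicin", "metronidazole"),
                               defs$signal_functions$antibiotic))
  expect_false(signal_readiness(c("ampicillin", "metronidazole"),
                                defs$signal_functions$antibiotic))
  expect_true(signal_readiness("oxytocin", defs$signal_functions$uterotonic))
  expect_true(signal_readiness("magnesium_sulfate", defs$signal_functions$anticonvulsant))
})

test_that("SRI item average is the satisfied fraction of tracer groups", {
  defs <- toy_defs()   # two tracer groups: (b|c) and (f)
  expect_equal(sri_index(c("b", "f"), defs), 1.0)
  expect_equal(sri_index(character(0), defs), 0.0)
  expect_equal(sri_index("c", defs), 0.5)

  no_tracers <- toy_defs()
  no_tracers$signal_functions <- list()
  expect_error(sri_index("b", no_tracers), class = "emoc_structural_error")

  # default config: 8 tracer groups, all satisfied by the full inventory
  full <- default_definitions()
  expect_equal(sri_index(full$resources$resource_id, full), 1.0)
})

test_that("in the default config every tracer set is a subset of the stage-1/2 groups, so stage-2 readiness implies signal readiness", {
  defs <- default_definitions()
  group_key <- function(g) paste(sort(g$alternatives), collapse = "|")
  for (sf in defs$signal_functions) {
    cd <- defs$cascades[[sf$linked_emergency_id]]
    stage12 <- vapply(c(cd$stages$identify$groups, cd$stages$treat$groups), group_key, "")
    tracer <- vapply(sf$tracer$groups, group_key, "")
    expect_true(all(tracer %in% stage12),
                label = paste0("tracer groups of '", sf$function_id,
                               "' within stage-1/2 groups"))
  }
  # consequence, checked behaviourally on random inventories
  set.seed(3)
  rids <- defs$resources$resource_id
  for (rep in 1:40) {
    present <- sample(rids, sample(0:length(rids), 1))
    for (sf in defs$signal_functions) {
      stage2 <- cascade_profile(present, defs$cascades[[sf$linked_emergency_id]])[["stage2"]]
      if (stage2) expect_true(signal_readiness(present, sf))
    }
  }
})

test_that("score_cohort assembles per-facility profiles and a 0/1 export matrix", {
  defs <- toy_defs()
  cohort <- toy_cohort(list(H1 = c("a", "b", "d", "e", "f"), H2 = "f", H3 = character(0)),
                       defs)
  prof <- score_cohort(cohort, defs)
  expect_equal(prof$n, 3)
  expect_identical(unname(prof$cascade["H1", "em1", ]), c(TRUE, TRUE, TRUE))
  expect_identical(unname(prof$cascade["H2", "em1", ]), c(FALSE, FALSE, FALSE))
  expect_identical(unname(prof$cascade["H2", "em2", ]), c(TRUE, TRUE, FALSE))
  expect_identical(unname(prof$cascade["H3", "em2", ]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(prof$sri), c(1, 0.5, 0))

  m <- profile_matrix(prof)
  expect_equal(nrow(m), 3)
  expect_equal(m$cascade_em1_stage2, c(1, 0, 0))
  expect_equal(m$signal_sf2, c(1, 1, 0))
})
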