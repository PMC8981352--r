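replica_profiles <- function() {
  defs <- replica_definitions()
  list(defs = defs, prof = score_cohort(build_paper_replica(defs), defs))
}

test_that("readiness proportions come from exact counts over the cohort size", {
  rp <- replica_profiles()
  sep2 <- proportion_ready(rp$prof, "cascade:sepsis:2")
  expect_equal(sep2$numerator, 11)
  expect_equal(sep2$denominator, 23)
  expect_equal(round_half_up(sep2$percent), 47.8)

  hyp1 <- proportion_ready(rp$prof, "cascade:hypertension:1")
  expect_equal(hyp1$numerator, 7)
  expect_equal(round_half_up(hyp1$percent), 30.4)

  # an indicator satisfied by nobody
  empty <- toy_cohort(list(H1 = character(0), H2 = character(0)))
  p <- score_cohort(empty, toy_defs())
  expect_equal(proportion_ready(p, "signal:sf1")$percent, 0)

  expect_error(readiness_estimate(1, 0), class = "emoc_empty_cohort_error")
  expect_error(proportion_ready(rp$prof, "cascade:nosuch:1"),
               class = "emoc_referential_error")
})

test_that("stage drop-offs telescope: drops sum to 100 minus final readiness, exactly", {
  rp <- replica_profiles()
  haem <- dropoff_by_stage(rp$prof, "haemorrhage")
  expect_equal(round_half_up(haem), c(identify = 0.0, treat = 39.1, monitor_modify = 47.8))
  hyp <- dropoff_by_stage(rp$prof, "hypertension")
  expect_equal(round_half_up(hyp[["identify"]]), 69.6)
  # exact fractions give 100*(7-6)/23 = 4.3 at display for the treat stage
  expect_equal(hyp[["treat"]], 100 / 23)

  for (e in names(rp$defs$cascades)) {
    drops <- dropoff_by_stage(rp$prof, e)
    r3 <- proportion_ready(rp$prof, paste0("cascade:", e, ":3"))$percent
    expect_equal(sum(drops) + r3, 100, tolerance = 1e-12)
    expect_true(all(drops >= 0))
  }
})

test_that("pooled mean and sample SD match the published summary arithmetic", {
  # sepsis stage drops as printed
  s <- pooled_mean_sd(c(26.1, 26.1, 17.4))
  expect_equal(round_half_up(s$mean), 23.2)
  expect_equal(round_half_up(s$sd), 5.0)

  expect_equal(pooled_mean_sd(c(4, 4, 4))$sd, 0)

  # identify-stage drops across the five emergencies, as printed
  i <- pooled_mean_sd(c(26.1, 0.0, 69.6, 0.0, 0.0))
  expect_equal(round_half_up(i$mean), 19.1)
  expect_equal(round_half_up(i$sd), 30.4)

  expect_error(pooled_mean_sd(42), class = "emoc_structural_error")
  expect_equal(pooled_mean_sd(42, sd = FALSE)$mean, 42)
  expect_error(pooled_mean_sd(numeric(0), sd = FALSE), class = "emoc_structural_error")
})

test_that("sample SD agrees with an explicit two-pass formula to 1e-12", {
  set.seed(99)
  for (rep in 1:50) {
    x <- runif(sample(2:30, 1), 0, 100)
    two_pass <- sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))
    expect_equal(pooled_mean_sd(x)$sd, two_pass, tolerance = 1e-12)
  }
})

test_that("overestimation is signal minus cascade stage-2 on exact fractions", {
  rp <- replica_profiles()
  expect_equal(overestimation(rp$prof, rp$defs, "antibiotic"), 100 * 5 / 23)
  expect_equal(round_half_up(overestimation(rp$prof, rp$defs, "antibiotic")), 21.7)
  expect_equal(overestimation(rp$prof, rp$defs, "uterotonic"), 0)

  # tracer identical to the stage-1/2 requirement set: overestimation 0 by construction
  defs <- toy_defs()
  defs$signal_functions$sf2$tracer <- defs$cascades$em2$stages$treat
  cohort <- toy_cohort(list(H1 = "f", H2 = character(0), H3 = c("a", "f")), defs)
  p <- score_cohort(cohort, defs)
  expect_equal(overestimation(p, defs, "sf2"), 0)
})

test_that("stratification partitions the cohort exhaustively with the study margins", {
  cohort <- build_paper_replica()
  by_country <- stratify(cohort, "country")
  expect_equal(nrow(by_country$Kenya$attributes), 17)
  expect_equal(nrow(by_country$Uganda$attributes), 6)
  by_csec <- stratify(cohort, "csec_capable")
  expect_equal(nrow(by_csec$`TRUE`$attributes), 10)
  expect_equal(nrow(by_csec$`FALSE`$attributes), 13)
  by_own <- stratify(cohort, "ownership")
  expect_equal(nrow(by_own$government$attributes), 19)
  expect_equal(nrow(by_own$private$attributes), 4)
  for (part in list(by_country, by_csec, by_own))
    expect_equal(sum(vapply(part, function(s) nrow(s$attributes), 0)), 23)

  broken <- cohort
  broken$attributes$country[3] <- NA
  err <- expect_error(stratify(broken, "country"), class = "emoc_schema_error")
  expect_match(conditionMessage(err), broken$attributes$facility_id[3])
})

test_that("assembled tables carry the pooled rows and footnote statistics", {
  defs <- replica_definitions()
  cohort <- build_paper_replica(defs)
  tabs <- build_tables(cohort, defs)

  comp <- tabs$comparison
  overall <- comp[comp$group == "pooled_overall", ]
  expect_equal(round_half_up(c(overall$signal_pct, overall$cascade_pct,
                               overall$overestimation_pct)),
               c(69.6, 47.0, 22.6))
  med <- comp[comp$group == "pooled_medical", ]
  expect_equal(round_half_up(c(med$signal_pct, med$cascade_pct, med$overestimation_pct)),
               c(69.6, 44.9, 24.6))
  man <- comp[comp$group == "pooled_manual", ]
  expect_equal(round_half_up(c(man$signal_pct, man$cascade_pct, man$overestimation_pct)),
               c(69.6, 50.0, 19.6))
  # pooled overestimation = pooled signal - pooled cascade = mean of per-emergency diffs
  per <- comp[comp$group %in% c("medical_treatment", "manual_procedure"), ]
  expect_equal(overall$overestimation_pct, mean(per$overestimation_pct), tolerance = 1e-12)
  expect_equal(overall$overestimation_pct, overall$signal_pct - overall$cascade_pct,
               tolerance = 1e-12)

  d <- tabs$dropoff
  expect_equal(round_half_up(d$overall$mean), 28.4)
  expect_equal(round_half_up(d$overall$sd), 3.0)
  expect_equal(round_half_up(d$overall$mean_of_sds), 24.2)
  expect_equal(round_half_up(d$per_stage$pooled_mean_drop), c(19.1, 33.9, 32.2))

  # stratified tables exist for the default attributes and stratum ns sum to 23
  expect_named(tabs$stratified, c("csec_capable", "ownership", "country"))
  for (attr_name in names(tabs$stratified)) {
    ns <- vapply(tabs$stratified[[attr_name]], `[[`, 0, "n")
    expect_equal(sum(ns), 23)
  }
})
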