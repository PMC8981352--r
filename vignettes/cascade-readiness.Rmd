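---
title: "Clinical cascades versus signal functions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical cascades versus signal functions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emocascade)
```

## The measurement problem

Facility surveys of emergency obstetric care readiness have traditionally
relied on signal-function tracer items: a facility counts as ready to perform
a clinical action (administer parenteral antibiotics, uterotonics or
anticonvulsants; remove a retained placenta or retained products of
conception) if the tracer commodity for that action is present on the day of
assessment. The clinical cascade model refines this into three ordered stages
per emergency — *identify*, *treat*, *monitor–modify* — each with its own
resource requirement, evaluated **cumulatively**: a facility is ready through
stage *k* only if it satisfies stages 1..k. The package computes readiness
under both models from the same inventory, so the tracer view's
overestimation of practical readiness, and the stage at which readiness is
lost, can be quantified.

## Model and assumptions

**Requirement semantics.** Every requirement is a conjunction of
alternative-groups of resource identifiers (`evaluate_requirement()`). Proxy
substitutions are modelled as extra alternatives inside a group — e.g. the
refrigeration group is `{refrigeration, electricity}` and the light-source
group `{electricity, flashlight}` — which keeps satisfaction a pure
conjunction-of-disjunctions with a single, easily tested semantics. The model
is monotone: adding a resource to an inventory can never remove readiness
(property-tested, and guaranteed structurally).

**Skill.** Commodity inventories cannot measure clinician skill, so
skill-only stages (the identify stages of the haemorrhage and
retained-placenta cascades carry no commodities) are represented as
requirements with zero groups and are always satisfied. Readiness estimates
are therefore about *resources*, conditional on universally assumed skill —
an explicit, and optimistic, assumption.

**Binary stages, binary functions.** A stage or tracer set is satisfied or
not; there is no partial credit. The WHO Service Readiness Index item average
(`sri_index()`, the satisfied fraction of all tracer groups) is provided
separately as the graded variant; per-function readiness used in the
comparison tables is the binary "all tracer groups present".

**Aggregation.** Readiness proportions are exact count fractions `k/n`.
Pooling across emergencies is an unweighted mean (each emergency counts
equally). Stage drop-offs are `100 − R₁`, then successive differences of the
cumulative readiness percentages; by construction the three drops plus the
final stage-3 readiness telescope to exactly 100 and each drop is
non-negative. Dispersion is the sample standard deviation (n−1). The
drop-off table reports, per emergency, the mean and SD of its three stage
drops; per stage, the pooled mean and SD across emergencies; and overall, the
mean of the five per-emergency means, the sample SD of those five means
(which is what "SD across stages and emergencies" reproduces — the SD of all
15 cells does not), and the mean of the five per-emergency SDs.

**Rounding.** All arithmetic is carried at full precision; display rounding
is half-away-from-zero to one decimal (`round_half_up()`), applied only when
printing or writing CSVs. This matters: the pooled per-emergency difference
of exact fractions is not the difference of the rounded percentages (e.g.
`(16−11)/23` rounds to 21.7 although `69.6 − 47.8 = 21.8`). Published tables
rounded this way contain a few cells where independent roundings disagree by
one display unit (0.1); the package never adjusts exact values to match a
printed cell.

## Configuration as data

Resource lists, cascades, proxies and tracer sets live in a YAML/JSON config
(`load_definitions()`), with a flat CSV export for audit
(`write_definitions_csv()`) and full serialisation round-tripping
(`write_definitions()`). The shipped default
(`inst/extdata/definitions_default.yaml`) is a documented reconstruction from
the published operational definitions — the three-drug antibiotic escalation
sequence (ampicillin AND gentamicin AND metronidazole, checked by
`validate_antibiotic_definition()`), oxytocin as the uterotonic tracer,
magnesium sulfate as the anticonvulsant tracer (WHO first line; the config is
free to add alternatives such as antihypertensives, but the default keeps the
single first-line drug because tracer drugs are otherwise underspecified in
the signal-function model), and the two proxy groups above. In the default
config every tracer set is a subset of the linked cascade's stage-1/2 groups,
so stage-2 readiness implies signal readiness and overestimation is
non-negative; this is asserted as a config-level test, not assumed by the
engine. An assisted-vaginal-delivery cascade is deliberately absent (its
tracers are not measurable from this kind of inventory); the engine accepts
one if a user adds it.

## The synthetic data module

Two generators make the pipeline testable without any data download.

**The replica fixture** (`build_paper_replica()`). Published all-facility
tables report one-decimal percentages over n = 23; because consecutive
fractions over 23 differ by ≈4.35 points, each printed value identifies its
integer count uniquely, and `recover_count()` inverts the display rounding by
exhaustive scan. Counts are recovered from the tracer percentages, the
identify-stage drops (stage 1 = 100 − drop), the stage-2 percentages, and the
monitor-stage drops (as count differences) — recovering stage 2 by
telescoping the printed drops instead would fail, because sums of
independently rounded cells can print values no count produces. Facilities
are then assigned resources by **nested prefixes**: a bundle with target
count k is present in facilities 1..k. The fixture uses disjoint abstract
bundles per emergency and function (e.g. `hypertension_treat_bundle`) rather
than real shared commodities, because the cross-emergency sharing pattern of
the source facilities is not recoverable from printed marginals; shared-
commodity behaviour is covered by unit tests on the scoring engine against
the default config instead. Attributes are fixed (facilities 1–10 C-section
capable, 1–4 private, 5–10 Ugandan), matching the published margins
(10/13, 19/4, 17/6, all Ugandan facilities C-section capable). The joint
distribution of attributes and readiness is *not* constrained — it is
unpublished — so stratified outputs on the replica are regression-tested
against themselves, never against published stratified cells. The fixture is
shipped both as code and as committed CSVs
(`inst/extdata/replica_*_synthetic.csv`), tested byte-equivalent.

**The random generator** (`generate_random()`). Emulates a physical-inventory
survey: per-resource marginal availability probabilities, seeded (default
seed 20160101, the study's baseline year, recorded in every manifest), with
attribute frequencies at the study margins. Its `nested_threshold` mode draws
one latent capacity u per facility and grants resource r iff u ≤ marginal(r),
producing the nested readiness structure real facility data approximate
(better-resourced facilities hold supersets); `independent` mode flips
independent coins. Neither mode emulates stock-out dynamics, resource
functionality or within-country commodity naming differences, so passing
tests demonstrate correctness of scoring and aggregation, not realism of any
particular correlation structure.

## Numerical and design choices

* Exact fractions everywhere; rounding only at display (above).
* `recover_count()` uses a 1e-6 comparison slack when matching printed values
  — far below the ≈4.35-point spacing of candidate values at n = 23 — and
  raises an inconsistency error when no count matches, which doubles as a
  transcription check on table inputs.
* Degenerate inputs: empty cohorts are rejected at construction; a stratum
  value simply absent from the data yields no stratum rather than an error;
  SD on fewer than two values is an error, not NA, to keep silent NA
  propagation out of published tables; `sri_index()` with zero declared
  tracer groups is an error.
* Duplicate (facility, resource) records collapse to facility-level presence
  (presence anywhere in the facility counts); *conflicting* duplicates are a
  data error naming the facility. Resources never mentioned in an inventory
  file are scored as absent with a coverage warning, because absence of a
  record is not a measured absence.
* Problem sizes: tests run the 23-facility fixture, generated cohorts of
  12–50 facilities, and exhaustive boolean enumeration up to 2^10 subsets —
  the scale at which the brute-force oracles are exact and the whole suite
  runs in well under a minute.

## Limitations

Resource presence on one day is a weak proxy for sustained readiness; skill
is assumed, not measured; proxies can misclassify (a kerosene-powered
refrigerator scores as no refrigeration when electricity is the proxy). The
replica fixture is one consistent completion of the published marginals — the
true facility-level overlap between tracer possession and cascade readiness
is unknowable from printed tables — so facility-level conclusions should come
from real inventories scored with `read_inventory()` + `emoc_readiness()`,
not from the fixture.
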