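# emocascade

Measuring whether a health facility is actually ready to manage the obstetric
emergencies that drive maternal mortality — haemorrhage, sepsis, hypertensive
emergencies (pre-eclampsia/eclampsia), retained placenta and incomplete
abortion — is usually done with WHO-style **signal-function tracer items**: if
the key commodity for a clinical action is on the shelf (e.g. oxytocin for
uterotonic treatment), the facility counts as ready for that action. The
**clinical cascade** model argues this overstates practical readiness: managing
an emergency requires the full set of resources to *identify* it (stage 1),
*treat* it (stage 2) and *monitor–modify* therapy (stage 3), evaluated
cumulatively — a facility that cannot identify an emergency is not ready to
treat it, whatever is on the shelf.

`emocascade` is an R package for analysts of facility surveys (emergency
obstetric and newborn care assessments, SARA/SPA-style inventories) that scores
facility resource inventories under both models and quantifies the gap between
them.

## The models

A resource requirement is a conjunction of alternative-groups over resource
identifiers: the facility must satisfy **every** group, and a group is
satisfied by **any** of its alternatives (this encodes proxy substitution, e.g.
electrical power standing in for refrigeration). For facility *i* with resource
set *R&#7522;* and a requirement with groups *G₁…G&#8344;*:

    satisfied(i) = AND_j [ R_i ∩ G_j ≠ ∅ ]       (skill-only: m = 0 ⇒ TRUE)

* **Signal functions:** per function *f*, readiness is the proportion of
  facilities satisfying the tracer requirement; the SRI item average (fraction
  of all tracer groups satisfied) is also available per facility.
* **Clinical cascade:** per emergency *e* and stage *k*, ready-through-stage-k
  requires satisfying the requirements of stages 1…k (cumulative, hence weakly
  decreasing in *k*). Stage-wise **drop-off** is `100 − R₁` for stage 1 and
  `R₍ₖ₋₁₎ − Rₖ` thereafter, so the three drops plus final readiness telescope
  to exactly 100.
* **Overestimation:** signal-function readiness minus cascade stage-2
  readiness, in percentage points, per emergency and pooled (unweighted mean
  across emergencies). All arithmetic is on exact count fractions; display
  rounding (half away from zero, 1 decimal) happens only at output.

Definitions (resources, cascades, proxies, tracers) are data, loaded from a
YAML/JSON config; the package ships a documented default plus a deterministic
23-facility **replica cohort** whose integer counts are recovered from
published one-decimal percentages, so the published all-facility tables can be
regenerated from scratch in seconds.

## Worked example

```r
library(emocascade)

defs   <- replica_definitions()        # synthetic replica definition set
cohort <- build_paper_replica(defs)    # 23 facilities, nested prefix assignment
fit    <- emoc_readiness(cohort, defs)
print(fit)
#> Emergency obstetric readiness (23 facilities, definitions replica-synthetic-1)
#>   pooled signal-function readiness: 69.6%
#>   pooled cascade stage-2 readiness: 47.0%
#>   pooled tracer overestimation:     22.6 percentage points
#>   pooled mean stage drop-off:       28.4% (SD 3.0)
```

So the tracer view calls 69.6% of facilities ready on average, but only 47.0%
have everything needed to identify *and* treat the average emergency — a 22.6
percentage-point overestimate. Readiness drains away along the stages of care
(28.4% mean drop-off per stage across the five emergencies, and remarkably
uniformly: SD 3.0). `summary(fit)` prints the per-emergency comparison and
drop-off tables, `plot(fit)` draws the stage curves, and
`write_readiness_tables(fit, "out/")` writes the CSV table family, including
versions stratified by C-section capability (the CEmOC proxy), ownership and
country.

Real data go through `load_definitions()` + `read_inventory()` (long or wide
CSV plus a facility attributes CSV). There is also a shell interface:

```sh
inst/exec/emocascade simulate --replica --out fixtures/
inst/exec/emocascade report --inventory fixtures/inventory_long.csv \
    --attributes fixtures/attributes.csv \
    --definitions fixtures/definitions_replica.yaml --by country --out out/
```

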