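# famenu

Knowledge-based weekly menu planning for families on the Mediterranean
diet (MD).

Families struggle to keep children's and adults' meals simultaneously
healthy, varied and coordinated — especially when weekday lunches are fixed
by a school menu. `famenu` implements a two-engine recommender for this
setting, plus the compliance auditor used to validate it:

* **Child weekly planner** — a constraint-satisfaction solver over the
  7 × 5 grid of a week's meal slots (breakfast, morning snack, lunch,
  afternoon snack, dinner). School-provided lunches are pinned and their
  food-group portions counted against expert-style daily and weekly
  frequency rules (e.g. pulses 4–5/week with per-subcategory quotas, fruit
  ≥ 3/day and 21–28/week, at most one portion of red or processed meat per
  week, colour variety in vegetables). Each rule has a *preferred* and,
  where relaxable, a *less-restrictive* bound; when no feasible week exists
  the solver climbs a relaxation ladder (drop colour rules → drop pulse
  subcategory rules → drop white-meat subcategory rules → widen the
  limiting bounds, one or two rules at a time) and records every step.
  Milk-allergic children get dairy-free plans with the dairy rules replaced
  by identical bounds on plant-based substitutes; an intervention snack can
  be inserted three times a week; adolescent siblings receive the same meal
  ids with age-group-scaled ingredient portions.
* **Adult family recommender** — the children's seven dinners and two
  weekend lunches are fixed *shared family meals*. For each day, 100,000
  random combinations of the free slots are sampled and scored with the
  daily nutritional plan score `DNPS = CS + PS + FS + FVS`:

  - `CS = max(0, 1 − |kcal − DER| / (0.3·DER))` (calories vs. the user's
    daily energy requirement, `DER = BMR × PAL`, Mifflin–St Jeor BMR),
  - `PS`, `FS`: 1 inside the guideline bands (protein 15–20 % of DER,
    fat 25–40 % of DER, Atwater 4/9 kcal g⁻¹), linear ramps outside,
  - `FVS`: 1 for 5–10 fruit-and-vegetable servings per day.

  Ranked daily lists are then assembled into a week that satisfies the MD
  diversity rules (egg ≤ 1/day, turkey ≤ 1/week, red meat ≤ 2/week, …, no
  meal repeated more than twice a week or on consecutive days) by staged
  depth-first search over the rank order.
* **Auditor** — an independent code path that recounts every portion of the
  delivered plans and reproduces per-rule compliance percentages
  (preferred vs. less-restrictive variants, by country) and the adult
  accuracy statistics (mean caloric agreement, share of days within the
  fat / protein / fruit-and-vegetable bands).
* **Synthetic data** — a seeded generator for dish/meal datasets with
  food-group flags and nutrition, dated school menus (optionally engineered
  to break the weekly red-meat rule), cafeteria proposals and family
  profiles, so the whole pipeline runs reproducibly without any external
  data.

## Worked example

```r
library(famenu)

cfg   <- synth_config(seed = 1)
ds    <- generate_dataset(cfg)            # two-country dish/meal dataset
menus <- generate_school_menus(cfg, ds)

req  <- child_week_request("autumn", "Spain", week_start = "2025-09-08",
                           school = "Spain school 1", seed = 7)
plan <- solve_child_week(req, ds, menus)
plan
#> weekly_plan: Spain autumn week of 2025-09-08 (feasible)
#>   Mon: 3[gen] 12[gen] 24[sch] 19[gen] 41[gen]
#>   Tue: 4[gen] 11[gen] 36[sch] 16[gen] 48[gen]
#>   Wed: 2[gen] 15[gen] 31[sch] 18[gen] 38[gen]
#>   Thu: 5[gen] 14[gen] 29[sch] 17[gen] 40[gen]
#>   Fri: 1[gen] 10[gen] 37[sch] 19[gen] 41[gen]
#>   Sat: 5[gen] 12[gen] 27[gen] 21[gen] 44[gen]
#>   Sun: 9[gen] 11[gen] 35[gen] 20[gen] 45[gen]

child_plan_violations(plan, ds)       # the full audit of the delivered week
#>                 rule_id horizon observed min max direction
#> red_meat_any w_red_meat    week        2  NA   1     above
nrow(generated_meal_violations(plan, ds))
#> [1] 0

adult <- adult_profile("female", 1985, 1.65, 62, pal = 1.375,
                       country = "Spain")
fam <- plan_family_week(ds, adult, plan, "autumn", seed = 7)
fam
#> family_weekly_plan: MD-compliant
#>   mean DNPS: 3.88
round(fam$der)
#> [1] 1774
```

A feasible plan prints the meal id and provenance (`sch`ool, `gen`erated,
`caf`eteria, …) of all 35 slots. This particular school menu happens to
serve red meat twice — over the weekly limit of one — so the full audit
reports that excess on the delivered week, while
`generated_meal_violations()` confirms the planner itself added none: fixed
school lunches are accepted verbatim and their excess only clamps the
remaining budget. The adult plan shares all seven dinners (and both
weekend lunches) with the child plan by meal id; `fam$der` is the user's
daily energy requirement (kcal/day) and `fam$scores` holds the per-day
score breakdown.

A command-line interface wrapping the same functions ships in
`inst/scripts/famenu` (subcommands `synth-data`, `validate-dataset`,
`plan-child`, `plan-family`, `audit`; exit codes 0 = success,
2 = infeasible, 1 = input error).

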