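---
title: "Methods: family menu planning under Mediterranean-diet rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family menu planning under Mediterranean-diet rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famenu)
```

## The problem

A family's week has 35 meal slots per person: seven days times five slot
types (breakfast, morning snack, lunch, afternoon snack, dinner). Children
aged roughly 3–11 often have their weekday lunches fixed by a school menu
or chosen from a school cafeteria's pool; the remaining slots must be
filled so that the week respects food-group frequency rules derived from
Mediterranean-diet (MD) principles and national dietary guidance. Adults
in the same family should share meals with the children — here the seven
dinners and the two weekend lunches — while additionally meeting personal
energy and macronutrient targets and MD diversity rules. `famenu`
implements both planners and, separately, the auditor that verifies their
output.

## The child planner as constraint satisfaction

The child week is a constraint-satisfaction problem over the 35 slots.
Variables are the free slots; domains are the candidate meals of the
matching type, country, season and child audience (minus all dairy-flagged
meals for a milk-allergic child); constraints are:

* **frequency rules** at two horizons. Daily rules cap or floor the
  portions of a food group within one day (e.g. bread ≤ 3, fruit ≥ 3,
  all meat — white, red and processed combined — ≤ 1); weekly rules bound
  the whole week (e.g. pulses 4–5 with per-subcategory quotas, fish 2–4,
  red meat ≤ 1, fruit 21–28, carbohydrates 21–35 summed over bread, pasta,
  rice, tubers and cereals). A *portion* is one flagged dish: each dish
  contributes one portion to every food-group flag and colour it carries,
  and multi-flag dishes count once towards a macro category (a dish
  flagged both `chicken` and `white_meat` is one white-meat portion).
  Gram-accurate portioning is deliberately out of scope — the portion
  system itself is acknowledged to deviate slightly from reference
  portions, so the flag count is the honest unit.
* **structural rules**: a meal id may appear at most twice a week and
  never on consecutive days; a dish id at most three times a week
  (configurable — the repetition caps for dishes are stated without a
  number in the source guidance, so three is a package default).

Search is backtracking in (day, slot-type) order with forward checking:
the solver keeps incremental day and week portion counts and prunes any
assignment that exceeds an active maximum or leaves a minimum unreachable
given optimistic suffix potentials (the column-wise maximum contribution of
every remaining slot). Candidate order is a seeded shuffle — the plan is a
deterministic function of the request seed — refined by two heuristics:
candidates covering portions still owed to a minimum are tried first, and
candidates consuming nearly exhausted maxima are deferred. Because
backtracking search has heavy-tailed run times, each rule state gets
several short seeded restarts (reshuffled candidate order, 8,000 nodes
each, 6 restarts by default) rather than one long run; a restart is skipped
when a completed search has already proven the instance infeasible.

**School menus.** Dated menus pin the five weekday lunches; cafeteria
proposals provide an unordered pool that the search places freely.
Fixed lunches are counted into the budgets but cannot be altered: when a
menu already exceeds a bound (say two red-meat lunches against a weekly
maximum of one), the effective bound is raised to the fixed contribution
and the remaining budget is simply zero, so no further red meat is
generated. Such excess is excluded from the solver's violation count but
fully visible to the auditor — delivered plans can therefore show
compliance below 100 % even though the solver did nothing wrong.

**Cross-rule conflicts.** Minimum/maximum interactions between a macro
category and its subcategories (the week already holds four pulse portions
from school lunches, yet the subcategory quotas still owe four more) defeat
per-key pruning; an arithmetic pre-check detects them and fails the state
immediately. The check assumes distinct subcategory quotas are covered by
distinct dishes; a dish flagged with two pulse subcategories at once could
make it conservative, which would cost one unnecessary relaxation step,
never a wrong plan.

**Relaxation ladder.** Every rule carries a preferred and, where
relaxable, a less-restrictive bound; colour rules and the pulse and
white-meat subcategory rules may also be dropped entirely. On failure the
solver inspects which rules caused the most pruning and takes one step:
drop the implicated droppable class (colours, then pulse subcategories,
then white-meat subcategories), else switch the one or two most implicated
relaxable rules to their wider bounds. The ladder terminates when nothing
relaxable remains; the plan is then returned infeasible with the limiting
rules named. Every step is recorded in the plan, and the audit evaluates
each plan under exactly the rule state it was accepted under.

**Snack insertion and adolescents.** When requested, an intervention
snack (a dairy-free fruit-and-nut item) is placed three times a week on
distinct days, in mid-morning or afternoon position; several seeded
placements are tried before any rule is relaxed, since a placement is a
solver choice, not a constraint. The snack is exempt from the
meal-repetition cap (it is intentionally served three times). Adolescent
siblings receive the same meal ids with ingredient grams read from their
age-group column of the dish table.

## The adult recommender

Per-user quantities: BMI = weight/height²; BMR by Mifflin–St Jeor
(`10 w + 6.25 h_cm − 5 age + (+5 | −161)`), with revised Harris–Benedict
selectable — the energy model behind the published system is not printed,
so the package states its own and isolates it behind one function; DER =
BMR × PAL with PAL restricted to the five standard multipliers
(1.2, 1.375, 1.55, 1.725, 1.9). Age derives from the birth year only, as
that is all the profile collects. BMI is computed and reported but does
not modulate DER — how it should is not specified anywhere, so the package
does not guess.

For each day, 100,000 combinations of the free slots are sampled uniformly
with replacement and deduplicated (when the full Cartesian product is
smaller it is enumerated instead). Each candidate day is scored:

* caloric score `CS = max(0, 1 − |kcal − DER|/(0.3·DER))`;
* protein score `PS` and fat score `FS`: 1 inside the guideline bands
  (protein 15–20 % of DER, fat 25–40 % of DER, converted at 4 and
  9 kcal g⁻¹), linearly decreasing by 1 per 10 percentage points outside;
* fruit-and-vegetable score `FVS`: 1 for 5–10 servings, decreasing by 1
  per 5 servings of deficit or excess.

The in-band targets are the guideline bands; the ramp widths (0.3·DER,
10 pp, 5 servings) are package constants, and the audit statistics do not
depend on them inside the bands. Ties in `DNPS = CS+PS+FS+FVS` break by
caloric distance and then the meal-id tuple, making the ranking
deterministic.

**Weekly assembly.** One candidate per day must jointly satisfy the MD
and diversity rules (egg ≤ 1/day; turkey and rabbit ≤ 1/week; red meat,
chicken, the bean subcategories and processed meat ≤ 2/week; chickpeas,
lentils, rice and pasta ≤ 3/week; red+white meat ≤ 4/week; pulses and fish
≤ 6/week with fish at most 3 as main and 4 as side dish; fruit salad
≤ 1/day and ≤ 2/week; at most one repeated dish id per day; white meat,
red meat, pork, fish and pasta each at most once per day across lunch and
dinner; meal ids ≤ 2/week, never consecutive). The assembler is staged
depth-first search over the ranked lists: top-8 per day, then top-64, then
top-512, then two deterministically perturbed rank-biased orders of the
top-512, then a final deep pass — widening only on failure avoids
exhausting one day's whole list against a jointly blocking top choice,
and the perturbed passes reach compliant weeks that are sparse at the very
top but plentiful slightly deeper. Lists short enough to enumerate are
explored completely, which is what the exhaustive-verification tests rely
on. Once any compliant week is found, a local-improvement sweep lifts each
day's selection back up its ranked list while preserving compliance, so
the returned week is near-greedy-optimal regardless of which pass found
it. Two fail-fast checks precede the search: a day none of whose
candidates passes the daily rules, or a weekly cap exceeded even by the
per-day minimum contributions, proves that the fixed child meals alone are
incompatible — such weeks are flagged failures, exactly how shared-meal
conflicts are counted in validation. The search budget (20 million listed
candidates by default) bounds the worst case; exhaustion returns the
best-ranked week flagged non-compliant.

Both adults of a family are planned independently against the same fixed
child meals; the children's weekday school lunches are never shared.

## The auditor

The auditor never reuses solver state: it recounts every portion from the
exported plan and re-evaluates every rule. Child compliance is reported
per rule, country and variant as *n plans evaluated / n compliant /
percent* — daily rules over daily plans, weekly rules over weekly plans —
with dairy rules skipped for milk-allergic owners (whose plant-based
substitutes are audited instead) and the delta between variants attached.
Adult accuracy is reported per country and overall: mean caloric agreement
`100·(1 − |kcal − DER|/DER)` across daily plans of rule-compliant weeks,
plus the share of daily plans within the fat, protein and
fruit-and-vegetable bands. "Accuracy" is reported both as the mean
agreement (the headline column) and as the share of days at agreement
≥ 90 %, since either reading of the word is defensible.

## What the synthetic data emulates — and what it does not

The generator builds meals from composition templates that mirror how
Mediterranean family menus are structured: a dairy (or plant-based) item
plus a carbohydrate plus fruit at breakfast; fruit snacks; a protein main,
carbohydrate side, vegetable side and fruit dessert at lunch; a protein
main, vegetables and a carbohydrate at dinner. Protein mains rotate over
the pulse subcategories, fish, eggs, cheese (plant cheese for the
dairy-free line) and the meats, so the preferred child rules are
attainable by construction every week — which is what makes
"solver output audits clean" a meaningful end-to-end test. Default scale:
9 breakfasts, 6 morning snacks, 8 afternoon snacks, 14 lunches and 14
dinners per country (~100 meals, ~310 dishes), three schools per country
(the last offering a cafeteria pool), 32 families.

Per-meal calorie ranges (breakfast 250–650, snacks 80–350, lunch 400–1100,
dinner 350–1000 kcal) span daily totals of roughly 1,200–3,450 kcal, wide
enough to cover the energy requirements of most adult profiles, matching
the broadened energy spectrum the reference dataset is described to cover;
per-dish macronutrients are drawn around 17 % protein and 30 % fat of dish
energy. A configurable fraction of school menus is engineered to hold two
red-meat lunches (breaking the weekly cap) to exercise budget clamping,
and `fruit_enabled = FALSE` produces a provably infeasible instance.

What the synthetic data does **not** capture: real recipes and gram-level
nutrition (macros are drawn from smooth distributions, so macronutrient
accuracy statistics on synthetic data are cleaner than reality); seasonal
menu cycles and school-menu idiosyncrasies; correlated preferences within
families; and any behavioural feedback. Passing tests therefore certify
the algorithms — counting, solving, scoring, auditing — not claims about
real families' diets.

A structural property worth knowing: because the child planner ignores
adult rules (mirroring the published system, which defers a negotiation
protocol between the two engines to future work), child dinner sequences
sometimes fix portions that no adult week can absorb — several rice sides,
four fish mains, a repeated dinner adjacent to a weekend lunch. Those
weeks are flagged `md_ok = FALSE` and excluded from accuracy statistics,
which is how shared-meal conflicts are counted in validation; with the
synthetic defaults they are markedly more frequent than in a full-size
curated dataset, because a small menu library offers the child solver far
fewer conflict-avoiding alternatives (the acceptance script reports the
realised share). Adults whose energy requirement sits at
the edge of the dataset's caloric range also keep slightly depressed
protein-within-range shares: the shared child dinners anchor a large part
of the day's calories. The same mechanisms — smaller menus for one
country, shared-meal anchoring — are visible in the published per-country
accuracy spread.

## Numerical and design choices

* Portions are integers; all rule arithmetic is exact, no tolerances.
* The solver returns the first feasible plan under the least-relaxed rule
  state — no objective function is defined beyond rule satisfaction, so
  "best possible" is read as "least relaxed, then first found".
* Dish roles map `unique → main`, `semi → side`, anything else
  `unspecified`; unspecified fish dishes count toward the overall fish cap
  but neither the main- nor side-dish sub-cap.
* The 26th food-group flag: the flag vocabulary carries `bread` (regulated
  by the rules but absent from the published boolean list) and splits
  dairy substitutes into `plant_beverage_yogurt` / `plant_cheese`, since
  the rules constrain them separately. `soups` is loaded but unconstrained.
* Weeks run Monday–Sunday (ISO dates); school menus cover Monday–Friday.
* Candidate sampling, pool shuffling and snack placement all derive from
  the request seed; identical requests reproduce identical plans byte for
  byte.
* Test and acceptance problem sizes are package choices balancing coverage
  against runtime: 200 two-day toy instances for exhaustive solver
  verification, 1,000 seeded solver-vs-auditor runs, 1,000 milk-allergy
  runs, and a 20-adult accuracy rerun at the full 100,000 candidates per
  day.

## Known limitations

* One child plan drives the family's shared meals; families with several
  children on different school menus are not reconciled.
* The adult assembler is budget-bounded: a compliant week that exists only
  very deep in the ranked lists can be missed and flagged as a failure
  (the flag is honest — the plan is returned with its violations).
* Child plans are rule-frequency based only; no energy or nutrient
  computation is attempted for children, by design.
* The BMR equation is a stated package choice; swapping it changes DER and
  hence every adult score.
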