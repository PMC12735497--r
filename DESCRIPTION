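Package: famenu
Title: Knowledge-Based Weekly Menu Planning for Families on the Mediterranean Diet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans weekly family menus under expert-style Mediterranean-diet
    food-frequency rules. A constraint-satisfaction child planner completes
    school-provided lunches under daily and weekly food-group frequency rules
    with a preferred-to-less-restrictive relaxation ladder, milk-allergy
    substitution, snack insertion and adolescent portion scaling. An adult
    family recommender samples and scores daily meal combinations against
    personal energy requirements (BMI, basal metabolic rate, daily energy
    requirement) and assembles a week around the children's shared meals under
    Mediterranean-diet diversity rules. A compliance auditor reproduces
    per-rule compliance percentages and adult accuracy statistics, and a
    synthetic-data module generates realistic dish/meal datasets, school menus
    and family profiles for fully reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
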