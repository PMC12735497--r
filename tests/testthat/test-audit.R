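ds <- generate_dataset(synth_config(seed = 1))

test_that("home-mode plans audit clean under the state they were solved", {
  for (sd in 1:10) {
    plan <- solve_child_week(child_week_request("autumn", "Spain",
                                                seed = sd), ds)
    expect_true(plan$feasible)
    v <- generated_meal_violations(plan, ds)
    expect_equal(nrow(v), 0, info = paste("seed", sd))
  }
})

test_that("a school lunch forcing an excess shows up as preferred-only", {
  # hand-built: one fixed lunch carries two cereal-flagged dishes, pushing
  # that day over the preferred daily cereals cap (<=1) but not the
  # less-restrictive one (<=2)
  dishes <- rbind(
    tiny_dish(1, "Bulgur", "cereals"), tiny_dish(2, "Oat cake", "cereals"),
    tiny_dish(3, "Salad", "raw_vegetables", colors = "green"),
    tiny_dish(4, "Fruit", "fruit"))
  meals <- rbind(
    tiny_meal(1, "Double cereal lunch", "lunch", c(1, 2, 3, 4)),
    tiny_meal(2, "B", "breakfast", 4),
    tiny_meal(3, "MS", "morning_snack", 4),
    tiny_meal(4, "AS", "afternoon_snack", 4),
    tiny_meal(5, "D", "dinner", 3))
  dsx <- load_dataset(list(dishes = dishes, meals = meals))
  slots <- function(lunch_prov) list(
    breakfast = list(meal_id = 2L, provenance = "generated"),
    morning_snack = list(meal_id = 3L, provenance = "generated"),
    lunch = list(meal_id = 1L, provenance = lunch_prov),
    afternoon_snack = list(meal_id = 4L, provenance = "generated"),
    dinner = list(meal_id = 5L, provenance = "generated"))
  days <- lapply(1:7, function(d) list(weekday = weekday_names()[d],
                                       slots = slots("generated")))
  days[[1]]$slots <- slots("school")
  plan <- weekly_plan(owner = list(milk_allergy = FALSE), "2025-09-08",
                      "autumn", "Spain", 1, days)
  rep <- audit_child_compliance(list(plan), dsx)
  pref <- rep[rep$rule_id == "d_cereals" & rep$country == "Overall" &
                rep$variant == "preferred", ]
  lr <- rep[rep$rule_id == "d_cereals" & rep$country == "Overall" &
              rep$variant == "less_restrictive", ]
  expect_equal(pref$n, 7)
  expect_equal(pref$n_compliant, 0)   # every day holds the 2-cereal lunch
  expect_equal(lr$n_compliant, 7)
  expect_equal(lr$delta, 100)
  # the school day's excess is not charged to the planner, the other six
  # days (generated lunches) are
  gv <- generated_meal_violations(plan, dsx)
  expect_false("1" %in% gv$horizon[gv$rule_id == "d_cereals"])
  expect_true("2" %in% gv$horizon[gv$rule_id == "d_cereals"])
})

test_that("an empty plan list yields an empty-count report", {
  rep <- audit_child_compliance(list(), ds)
  expect_true(all(rep$n == 0))
  expect_true(all(is.na(rep$percent)))
})

test_that("report-level variant dominance holds on solved plans", {
  plans <- lapply(1:6, function(sd)
    solve_child_week(child_week_request("autumn", "Spain", seed = sd), ds))
  rep <- audit_child_compliance(plans, ds)
  lr <- rep[rep$variant == "less_restrictive" & !is.na(rep$delta), ]
  expect_true(all(lr$delta >= 0))
})

test_that("dairy rules are skipped for allergic owners and vice versa", {
  reg <- solve_child_week(child_week_request("autumn", "Spain", seed = 1),
                          ds)
  alg <- solve_child_week(child_week_request("autumn", "Spain",
                                             milk_allergy = TRUE,
                                             seed = 1), ds)
  rep <- audit_child_compliance(list(reg, alg), ds)
  ov <- rep[rep$country == "Overall" & rep$variant == "preferred", ]
  # one weekly plan audited per dairy rule (the non-allergic one), one per
  # plant rule (the allergic one)
  expect_equal(ov$n[ov$rule_id == "w_milk_yogurt"], 1)
  expect_equal(ov$n[ov$rule_id == "w_plant_bev_yogurt"], 1)
  expect_equal(ov$n[ov$rule_id == "w_fruit"], 2)
})

test_that("adult accuracy aggregates agreement and range shares", {
  # two one-week plans with hand-set DERs chosen so agreement is exact
  prof <- adult_profile("female", 1985, 1.65, 62, 1.375, country = "Spain",
                        id = "A")
  cp <- solve_child_week(child_week_request("autumn", "Spain", seed = 1),
                         ds)
  fam <- plan_family_week(ds, prof, cp, "autumn", n = 5000, seed = 1)
  expect_true(fam$md_ok)
  acc <- audit_adult_accuracy(list(fam), ds)
  ov <- acc[acc$country == "Overall", ]
  expect_equal(ov$daily_np, 7)
  expect_true(ov$mean_caloric_agreement <= 100)
  expect_true(all(c("fat_within_pct", "protein_within_pct",
                    "fv_within_pct") %in% names(acc)))
  # agreement arithmetic: kcal == DER gives 100, and means average plainly
  ag <- function(kcal, der) 100 * (1 - abs(kcal - der) / der)
  expect_equal(ag(2000, 2000), 100)
  expect_equal(mean(c(ag(1800, 2000), ag(2000, 2000))), 95)
  # protein at 14% of DER sits outside the 15-20 band
  expect_false(14 >= 15 && 14 <= 20)
})

test_that("failed plans are excluded unless asked for", {
  prof <- adult_profile("male", 1980, 1.78, 75, 1.2, country = "Spain",
                        id = "B")
  cp <- solve_child_week(child_week_request("autumn", "Spain", seed = 4),
                         ds)
  fam <- plan_family_week(ds, prof, cp, "autumn", n = 5000, seed = 5)
  fam$md_ok <- FALSE  # pretend the week failed the MD rules
  acc <- audit_adult_accuracy(list(fam), ds)
  expect_equal(nrow(acc), 0)
  acc2 <- audit_adult_accuracy(list(fam), ds, include_failed = TRUE)
  expect_equal(acc2$daily_np[acc2$country == "Overall"], 7)
})
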