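ds_synth <- generate_dataset(synth_config(seed = 1))

test_that("solver agrees with exhaustive enumeration on toy instances", {
  for (sd in 1:25) {
    inst <- toy_instance(sd, n_days = if (sd %% 3 == 0) 1L else 2L)
    oracle <- oracle_child_feasible(inst)
    sol <- solver_child_feasible(inst, seed = sd)
    expect_identical(sol$feasible, oracle, info = paste("instance", sd))
    if (sol$feasible) {
      dm <- plan_day_meals(sol$plan)[seq_len(inst$n_days)]
      expect_true(oracle_child_ok(dm, inst$dataset, inst$rules),
                  info = paste("plan validity, instance", sd))
    }
  }
})

test_that("an instance engineered to a unique solution returns it", {
  # two options per slot; rules force exactly the fruit-free option away:
  # daily fruit must be >= 1 and only one breakfast has fruit
  dishes <- rbind(
    tiny_dish(1, "Fruit bowl", "fruit"),
    tiny_dish(2, "Plain toast", "bread"),
    tiny_dish(3, "Salad", "raw_vegetables", colors = "green"),
    tiny_dish(4, "Yogurt", "milk_yogurt"))
  meals <- rbind(
    tiny_meal(1, "Fruit breakfast", "breakfast", 1),
    tiny_meal(2, "Toast breakfast", "breakfast", 2),
    tiny_meal(3, "Snack", "morning_snack", 4),
    tiny_meal(4, "Lunch", "lunch", 3),
    tiny_meal(5, "Afternoon", "afternoon_snack", 4),
    tiny_meal(6, "Dinner", "dinner", 3))
  ds <- load_dataset(list(dishes = dishes, meals = meals))
  rules <- toy_rules(1)
  rules <- rules[0, ]
  rules <- rbind(rules, data.frame(
    id = "d_fruit_min", scope = "daily", key = "fruit",
    min_pref = 1, max_pref = NA_real_, min_lr = 1, max_lr = NA_real_,
    variant_mode = "both", unit = "d_fruit_min", drop_class = "none",
    dairy_class = "none", stringsAsFactors = FALSE))
  attr(rules, "meal_repeat_max") <- 2L
  attr(rules, "dish_repeat_max") <- 7L
  class(rules) <- c("rule_table", "data.frame")
  req <- child_week_request("autumn", "Spain", seed = 5)
  plan <- solve_child_week(req, ds, rules = rules, n_days = 1L)
  expect_true(plan$feasible)
  expect_equal(plan$days[[1]]$slots$breakfast$meal_id, 1L)
})

test_that("a dataset without fruit is infeasible and names the fruit rule", {
  ds <- generate_dataset(synth_config(seed = 2, fruit_enabled = FALSE))
  req <- child_week_request("autumn", "Spain", seed = 1)
  plan <- solve_child_week(req, ds)
  expect_false(plan$feasible)
  expect_true(any(grepl("fruit", plan$infeasible_rules)))
})

test_that("school excess clamps the budget: no red meat is generated", {
  lunches <- candidate_meals(ds_synth, type = "lunch", country = "Spain",
                             audience = "child")
  lrows <- match(lunches, ds_synth$meals$id)
  red <- lunches[ds_synth$meal_matrix[lrows, "red_meat_any"] > 0]
  nonred <- setdiff(lunches, red)
  expect_gte(length(red), 2)
  menu_rows <- data.frame(
    school = "V", country = "Spain", week_start = "2025-09-08",
    weekday = c("Mon", "Tue", "Wed", "Thu", "Fri"),
    meal_id = c(red[1:2], nonred[1:3]), stringsAsFactors = FALSE)
  menus <- load_school_menus(menu_rows, ds_synth)
  req <- child_week_request("autumn", "Spain", school = "V", seed = 4)
  plan <- solve_child_week(req, ds_synth, menus)
  expect_true(plan$feasible)
  gen <- plan_day_meals(plan, provenance = "generated")
  led <- count_portions(unlist(gen), ds_synth)
  expect_equal(unname(led$counts["red_processed"]), 0L)
  # and the fixed lunches match the menu verbatim
  for (i in 1:5) {
    expect_equal(plan$days[[i]]$slots$lunch$meal_id, menu_rows$meal_id[i])
    expect_equal(plan$days[[i]]$slots$lunch$provenance, "school")
  }
})

test_that("the relaxation ladder drops colours then widens named rules", {
  rules <- child_rules()
  st <- rule_state(rules)
  step1 <- relax_ladder(st, "d_color_green", rules)
  expect_equal(step1$step, "drop:veg_color")
  expect_true("veg_color" %in% step1$state$dropped)
  step2 <- relax_ladder(step1$state, "d_cereals", rules)
  expect_match(step2$step, "relax:")
  expect_equal(unname(step2$state$variant["d_cereals"]),
               "less_restrictive")
  # fully relaxed state is a fixpoint
  st_full <- rule_state(rules, "less_restrictive",
                        dropped = c("veg_color", "pulse_subcat",
                                    "white_meat_subcat"))
  fin <- relax_ladder(st_full, "w_fruit", rules)
  expect_true(fin$exhausted)
})

test_that("identical request and seed give byte-identical exports", {
  req <- child_week_request("autumn", "Spain", seed = 42)
  p1 <- solve_child_week(req, ds_synth)
  p2 <- solve_child_week(req, ds_synth)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_weekly_plan(p1, f1, dataset = ds_synth)
  write_weekly_plan(p2, f2, dataset = ds_synth)
  expect_identical(readLines(f1), readLines(f2))
  p3 <- solve_child_week(child_week_request("autumn", "Spain", seed = 43),
                         ds_synth)
  expect_false(identical(plan_day_meals(p1), plan_day_meals(p3)))
})

test_that("snack mode places the intervention snack three times", {
  req <- child_week_request("autumn", "Spain", snack = TRUE, seed = 9)
  plan <- solve_child_week(req, ds_synth)
  expect_true(plan$feasible)
  snack_slots <- list()
  for (d in 1:7) for (s in c("morning_snack", "afternoon_snack")) {
    sl <- plan$days[[d]]$slots[[s]]
    if (identical(sl$provenance, "program_snack")) {
      snack_slots[[length(snack_slots) + 1L]] <- c(day = d, slot = s)
    }
  }
  expect_length(snack_slots, 3)
  expect_equal(length(unique(vapply(snack_slots, `[`, "", "day"))), 3)
})

test_that("milk-allergy plans never contain a dairy-flagged dish", {
  req <- child_week_request("autumn", "Spain", milk_allergy = TRUE,
                            seed = 3)
  plan <- solve_child_week(req, ds_synth)
  expect_true(plan$feasible)
  led <- count_portions(unlist(plan_day_meals(plan)), ds_synth)
  expect_equal(unname(led$counts["dairy_any"]), 0L)
  # plant-based substitution bounds hold
  expect_gte(led$counts[["plant_beverage_yogurt"]], 14)
})

test_that("adolescent scaling swaps the age-group ingredient columns", {
  req <- child_week_request("autumn", "Spain", seed = 2)
  plan <- solve_child_week(req, ds_synth)
  tab_13 <- scale_for_adolescent(plan, ds_synth, "13-15")
  oil_13 <- unique(tab_13$grams[tab_13$ingredient == "Olive oil"])
  expect_equal(oil_13, 15)
  tab_7 <- scale_for_adolescent(plan, ds_synth, "7-12")
  oil_7 <- unique(tab_7$grams[tab_7$ingredient == "Olive oil"])
  expect_equal(oil_7, 12)
  expect_equal(tab_13[, c("day", "slot", "meal_id", "dish_id")],
               tab_7[, c("day", "slot", "meal_id", "dish_id")])
  # a dish with a missing age-group column is reported
  ds2 <- ds_synth
  ds2$dishes$ingredients_16_18 <- ""
  expect_error(scale_for_adolescent(plan, ds2, "16-18"), "no ingredient")
})

test_that("cafeteria lunches fill the weekday slots from the pool", {
  lunches <- candidate_meals(ds_synth, type = "lunch", country = "Spain",
                             audience = "child")[1:6]
  caf <- data.frame(school = "C", country = "Spain", week_start = "",
                    weekday = "", meal_id = lunches,
                    stringsAsFactors = FALSE)
  menus <- load_school_menus(caf, ds_synth)
  req <- child_week_request("autumn", "Spain", school = "C", seed = 6)
  plan <- solve_child_week(req, ds_synth, menus)
  expect_true(plan$feasible)
  for (d in 1:5) {
    sl <- plan$days[[d]]$slots$lunch
    expect_equal(sl$provenance, "cafeteria")
    expect_true(sl$meal_id %in% lunches)
  }
})

test_that("a named school without any menu falls back to home mode", {
  req <- child_week_request("autumn", "Spain", school = "Ghost", seed = 1)
  expect_warning(src <- resolve_lunch_source(req, NULL), "home mode")
  expect_equal(src$mode, "home")
})
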