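ds <- generate_dataset(synth_config(seed = 1))
child_plan <- solve_child_week(child_week_request("autumn", "Spain",
                                                  seed = 1), ds)
spain_prof <- adult_profile("female", 1985, 1.65, 62, 1.375,
                            country = "Spain", id = "A1")

test_that("meal filtering respects country, season and allergy", {
  pools <- filter_meals(ds, spain_prof, "autumn")
  all_ids <- unlist(pools)
  rows <- match(all_ids, ds$meals$id)
  expect_true(all(ds$meals$country[rows] == "Spain"))
  expect_true(all(vapply(ds$meal_seasons[rows],
                         function(s) "autumn" %in% s, logical(1))))
  allergic <- adult_profile("female", 1985, 1.65, 62, 1.375,
                            milk_allergy = TRUE, country = "Spain")
  pools_a <- filter_meals(ds, allergic, "autumn")
  rows_a <- match(unlist(pools_a), ds$meals$id)
  expect_true(all(ds$meal_matrix[rows_a, "dairy_any"] == 0))
})

test_that("fixed child meals are the 7 dinners plus 2 weekend lunches", {
  fx <- fixed_child_meals(child_plan)
  expect_length(fx$dinners, 7)
  expect_length(fx$weekend_lunches, 2)
  expect_equal(fx$dinners,
               vapply(child_plan$days,
                      function(d) as.integer(d$slots$dinner$meal_id),
                      integer(1)))
  expect_identical(fixed_child_meals(child_plan), fx)  # pure
  broken <- child_plan
  broken$days[[7]]$slots$dinner$meal_id <- NA_integer_
  expect_error(fixed_child_meals(broken), "missing")
  infeasible <- child_plan
  infeasible$feasible <- FALSE
  expect_error(fixed_child_meals(infeasible), "not feasible")
})

test_that("daily scores hit the documented bands and edges", {
  # all-in-band synthetic day: build from raw numbers via a fake dataset
  dishes <- rbind(
    tiny_dish(1, "B", "bread"), tiny_dish(2, "F", "fruit"),
    tiny_dish(3, "V", "raw_vegetables", colors = "red"),
    tiny_dish(4, "F2", "fruit"), tiny_dish(5, "F3", "fruit"),
    tiny_dish(6, "V2", "cooked_vegetables", colors = "green"),
    tiny_dish(7, "V3", "cooked_vegetables", colors = "white"))
  der <- 2000
  # per-dish macros: protein 17% and fat 30% of energy by construction
  dishes$kcal <- der / 7
  dishes$protein_g <- 0.17 * dishes$kcal / 4
  dishes$fat_g <- 0.30 * dishes$kcal / 9
  dishes$carbs_g <- 0.53 * dishes$kcal / 4
  meals <- rbind(
    tiny_meal(1, "B", "breakfast", c(1, 2)),
    tiny_meal(2, "MS", "morning_snack", 4),
    tiny_meal(3, "L", "lunch", c(3, 6)),
    tiny_meal(4, "AS", "afternoon_snack", 5),
    tiny_meal(5, "D", "dinner", 7))
  dsx <- load_dataset(list(dishes = dishes, meals = meals))
  br <- score_daily_plan(1:5, dsx, der)
  expect_equal(br$cs, 1)
  expect_equal(br$ps, 1)
  expect_equal(br$fs, 1)
  expect_equal(br$fvs, 1)  # 3 fruit + 3 vegetables = 6 servings
  expect_equal(br$dnps, 4)
  expect_equal(br$fv_servings, 6L)
  # caloric ramp hits zero at 30% deviation
  br_hi <- score_daily_plan(1:5, dsx, der / 1.3)
  expect_equal(br_hi$cs, 0, tolerance = 1e-9)
  # zero fruit/vegetable servings floor the score
  expect_equal(famenu:::band_score(0, 5, 10, 5), 0)
})

test_that("the caloric score is symmetric and non-increasing in deviation", {
  der <- 1800
  dev <- seq(0, 0.4 * der, by = 50)
  up <- pmax(0, 1 - abs((der + dev) - der) / (0.3 * der))
  down <- pmax(0, 1 - abs((der - dev) - der) / (0.3 * der))
  expect_equal(up, down)
  expect_true(all(diff(up) <= 1e-12))
})

test_that("candidate generation enumerates small pools and ranks by DNPS", {
  pools <- filter_meals(ds, spain_prof, "autumn")
  small <- lapply(pools, function(p) p[seq_len(min(2, length(p)))])
  fx <- fixed_child_meals(child_plan)
  der <- energy_requirements(spain_prof, 2025)$der
  cand <- generate_daily_candidates(small, fx, 1, ds, der, n = 100000,
                                    seed = 1)
  expect_lte(nrow(cand$slots), 16)  # full product of 2^4 free slots
  expect_equal(nrow(unique(cand$slots)), nrow(cand$slots))
  expect_true(all(diff(cand$scores$dnps) <= 1e-12))
  expect_true(all(cand$slots[, "dinner"] == fx$dinners[1]))
  # weekend day fixes lunch as well
  wknd <- generate_daily_candidates(small, fx, 6, ds, der, n = 10,
                                    seed = 1)
  expect_true(all(wknd$slots[, "lunch"] == fx$weekend_lunches[1]))
  expect_lte(nrow(wknd$slots), 10)
  one <- generate_daily_candidates(small, fx, 2, ds, der, n = 1, seed = 2)
  expect_equal(nrow(one$slots), 1)
  expect_false(anyNA(one$slots))
})

test_that("identical seeds give identical candidate rankings", {
  pools <- filter_meals(ds, spain_prof, "autumn")
  fx <- fixed_child_meals(child_plan)
  der <- energy_requirements(spain_prof, 2025)$der
  c1 <- generate_daily_candidates(pools, fx, 3, ds, der, n = 5000,
                                  seed = 7)
  c2 <- generate_daily_candidates(pools, fx, 3, ds, der, n = 5000,
                                  seed = 7)
  expect_identical(c1$slots, c2$slots)
})

test_that("weekly assembly backtracks past a blocking top candidate", {
  # day 1 offers two candidates; the higher-ranked one repeats day 2's
  # lunch on a consecutive day, so only the runner-up yields a compliant
  # selection and the builder must backtrack to it
  pools <- filter_meals(ds, spain_prof, "autumn")
  pick <- function(type, n) pools[[type]][seq_len(n)]
  b <- pick("breakfast", 2); m <- pick("morning_snack", 2)
  l <- pick("lunch", 3); a <- pick("afternoon_snack", 2)
  dn <- pick("dinner", 2)
  mk_day <- function(slot_rows, dnps) {
    slots <- do.call(rbind, slot_rows)
    colnames(slots) <- meal_types()
    list(day = 1, slots = slots,
         scores = data.frame(cs = dnps / 4, ps = dnps / 4, fs = dnps / 4,
                             fvs = dnps / 4, dnps = dnps,
                             kcal_total = 1800, protein_pct = 17,
                             fat_pct = 30, fv_servings = 6))
  }
  day1 <- mk_day(list(c(b[1], m[1], l[1], a[1], dn[1]),
                      c(b[1], m[1], l[2], a[1], dn[1])), c(4, 3))
  day2 <- mk_day(list(c(b[2], m[2], l[1], a[2], dn[2])), 4)
  # sanity: each candidate alone passes the daily rules
  for (cand in list(day1$slots[1, ], day1$slots[2, ], day2$slots[1, ])) {
    one <- list(as.list(stats::setNames(as.integer(cand), names(cand))))
    v <- adult_week_violations(one, ds)
    expect_equal(nrow(v[v$horizon != "week", , drop = FALSE]), 0)
  }
  fam <- build_weekly_plan(list(day1, day2), ds)
  expect_true(fam$md_ok)
  expect_equal(fam$day_slots[[1]]$lunch, l[2])  # the 2nd-ranked candidate
  oracle <- oracle_adult_compliant_exists(list(day1, day2), ds)
  expect_true(oracle)
})

test_that("builder finds a compliant selection iff one exists", {
  # short horizons with two options in two slots keep the product space
  # enumerable while still engaging the repetition and frequency rules
  pools_all <- filter_meals(ds, spain_prof, "autumn")
  cp <- solve_child_week(child_week_request("autumn", "Spain", seed = 1),
                         ds)
  fx_full <- fixed_child_meals(cp)
  n_true <- 0; n_false <- 0
  for (sd in 1:10) {
    set.seed(sd)
    small <- lapply(pools_all, function(p) sample(p, 2))
    fx <- list(dinners = sample(pools_all$dinner, 7, replace = FALSE),
               weekend_lunches = fx_full$weekend_lunches)
    daily <- lapply(1:2, function(d)
      generate_daily_candidates(small, fx, d, ds, der = 1800, n = 1e5,
                                seed = sd))
    fam <- build_weekly_plan(daily, ds)
    oracle <- oracle_adult_compliant_exists(daily, ds, max_enum = 500)
    expect_equal(fam$md_ok, oracle, info = paste("instance", sd))
    if (isTRUE(oracle)) n_true <- n_true + 1 else n_false <- n_false + 1
  }
  # an engineered conflict: the same dinner fixed on consecutive days can
  # never satisfy the repetition rules
  same <- list(dinners = rep(pools_all$dinner[1], 7),
               weekend_lunches = fx_full$weekend_lunches)
  set.seed(99)
  small <- lapply(pools_all, function(p) sample(p, 2))
  daily <- lapply(1:2, function(d)
    generate_daily_candidates(small, same, d, ds, der = 1800, n = 1e5,
                              seed = 99))
  fam <- build_weekly_plan(daily, ds)
  expect_false(fam$md_ok)
  expect_false(isTRUE(oracle_adult_compliant_exists(daily, ds,
                                                    max_enum = 500)))
  expect_gt(n_true, 0)  # the compliant branch must actually occur too
})

test_that("fixed child meals that violate the rules flag the week", {
  # force a day where the fixed dinner alone breaks the daily egg rule
  dishes <- rbind(
    tiny_dish(1, "Omelette", "eggs"), tiny_dish(2, "Egg salad", "eggs"),
    tiny_dish(3, "Veg", "raw_vegetables", colors = "green"),
    tiny_dish(4, "Fruit", "fruit"))
  meals <- rbind(
    tiny_meal(1, "Double egg dinner", "dinner", c(1, 2)),
    tiny_meal(2, "B", "breakfast", 4),
    tiny_meal(3, "MS", "morning_snack", 4),
    tiny_meal(4, "L", "lunch", 3),
    tiny_meal(5, "AS", "afternoon_snack", 4),
    tiny_meal(6, "Veg dinner", "dinner", 3),
    tiny_meal(7, "L2", "lunch", 4))
  dsx <- load_dataset(list(dishes = dishes, meals = meals))
  fx <- list(dinners = c(1L, rep(6L, 3), 1L, 6L, 6L),
             weekend_lunches = c(4L, 7L))
  pools <- list(breakfast = 2L, morning_snack = 3L, lunch = c(4L, 7L),
                afternoon_snack = 5L, dinner = c(1L, 6L))
  daily <- lapply(1:7, function(d)
    generate_daily_candidates(pools, fx, d, dsx, 1500, n = 100, seed = 1))
  fam <- build_weekly_plan(daily, dsx)
  expect_false(fam$md_ok)
  expect_true("a_eggs_day" %in% fam$violations$rule_id)
})
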