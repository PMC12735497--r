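# Hand-built fixtures and brute-force oracles used across the suite.

# A minimal dataset: one dish per food situation, ids stable, full
# nutrition so meals work for both audiences.
tiny_dish <- function(id, name, groups, colors = "", kcal = 200,
                      role = "unspecified", fruit_salad = 0) {
  data.frame(id = id, name = name, role = role, kcal = kcal,
             fat_g = round(0.30 * kcal / 9, 2),
             protein_g = round(0.17 * kcal / 4, 2),
             carbs_g = round(0.53 * kcal / 4, 2),
             groups = groups, colors = colors, fruit_salad = fruit_salad,
             ingredients_3_6 = paste0(name, "=80;Olive oil=10"),
             ingredients_7_12 = paste0(name, "=100;Olive oil=12"),
             ingredients_13_15 = paste0(name, "=120;Olive oil=15"),
             ingredients_16_18 = paste0(name, "=130;Olive oil=15"),
             ingredients_adult = paste0(name, "=120;Olive oil=15"),
             recipe = "mix", tip = "eat well", stringsAsFactors = FALSE)
}

tiny_meal <- function(id, name, type, dish_ids, country = "Spain",
                      seasons = "winter;spring;summer;autumn",
                      audience = "both", program_snack = 0) {
  data.frame(id = id, name = name, type = type, country = country,
             seasons = seasons,
             dish_ids = paste(dish_ids, collapse = ";"),
             audience = audience, program_snack = program_snack,
             stringsAsFactors = FALSE)
}

tiny_dataset <- function() {
  dishes <- rbind(
    tiny_dish(1, "Banana", "fruit", kcal = 114),
    tiny_dish(2, "Scrambled eggs with prawns and asparagus",
              "eggs;fish_seafood;cooked_vegetables", colors = "green",
              kcal = 211),
    tiny_dish(3, "Milk", "milk_yogurt", kcal = 120),
    tiny_dish(4, "Bread", "bread", kcal = 150),
    tiny_dish(5, "Lentil stew", "pulses;lentils", kcal = 300,
              role = "main"),
    tiny_dish(6, "Grilled hake", "fish_seafood", kcal = 250, role = "main"),
    tiny_dish(7, "Beef fillet", "red_meat", kcal = 320, role = "main"),
    tiny_dish(8, "Tomato salad", "raw_vegetables", colors = "red",
              kcal = 60),
    tiny_dish(9, "Fruit salad", "fruit", kcal = 90, fruit_salad = 1),
    tiny_dish(10, "Soy yogurt", "plant_beverage_yogurt", kcal = 110),
    tiny_dish(11, "Rice", "rice", kcal = 180, role = "side"),
    tiny_dish(12, "Cheese platter", "cheese", kcal = 220))
  meals <- rbind(
    tiny_meal(1, "Banana breakfast", "breakfast", c(3, 4, 1)),
    tiny_meal(2, "Eggs and prawns lunch", "lunch", c(2, 11, 8)),
    tiny_meal(3, "Lentil lunch", "lunch", c(5, 8, 1)),
    tiny_meal(4, "Hake lunch", "lunch", c(6, 11, 8)),
    tiny_meal(5, "Beef lunch", "lunch", c(7, 11, 8)),
    tiny_meal(6, "Fruit snack", "morning_snack", 1),
    tiny_meal(7, "Yogurt snack", "afternoon_snack", c(3, 4)),
    tiny_meal(8, "Fish dinner", "dinner", c(6, 8, 4)),
    tiny_meal(9, "Cheese dinner", "dinner", c(12, 8, 4)),
    tiny_meal(10, "Plant snack", "afternoon_snack", c(10, 4)),
    tiny_meal(11, "Fruit salad snack", "morning_snack", 9),
    tiny_meal(12, "Turkish breakfast", "breakfast", c(3, 4, 1),
              country = "Turkiye"))
  load_dataset(list(dishes = dishes, meals = meals))
}

# --- toy instances for exhaustive child-solver verification ---------------

# a toy ruleset over a handful of directly-flagged keys, with seeded random
# small bounds; every rule is fixed-variant so preferred == the whole set
toy_rules <- function(seed) {
  keys <- c("fruit", "bread", "milk_yogurt", "fish_seafood", "red_meat",
            "raw_vegetables")
  rows <- list()
  set.seed(seed)
  for (k in sample(keys, sample(3:4, 1))) {
    scope <- sample(c("daily", "weekly"), 1)
    if (scope == "daily") {
      lo <- if (runif(1) < 0.1) 1 else NA
      hi <- sample(2:4, 1)
    } else {
      lo <- if (runif(1) < 0.25) 1 else NA
      hi <- sample(3:8, 1)
    }
    if (!is.na(lo) && !is.na(hi) && lo > hi) hi <- lo
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(substr(scope, 1, 1), "_", k), scope = scope, key = k,
      min_pref = as.numeric(lo), max_pref = as.numeric(hi),
      min_lr = as.numeric(lo), max_lr = as.numeric(hi),
      variant_mode = "both", unit = paste0(substr(scope, 1, 1), "_", k),
      drop_class = "none", dairy_class = "none",
      stringsAsFactors = FALSE)
  }
  rules <- do.call(rbind, rows)
  attr(rules, "meal_repeat_max") <- 2L
  attr(rules, "dish_repeat_max") <- 3L
  attr(rules, "version") <- "toy"
  class(rules) <- c("rule_table", "data.frame")
  rules
}

# a toy dataset: 1-3 single-dish meals per slot type, random flags
toy_instance <- function(seed, n_days = 2L, max_pool = 3L) {
  set.seed(seed)
  flags <- c("fruit", "bread", "milk_yogurt", "fish_seafood", "red_meat",
             "raw_vegetables")
  dishes <- list(); meals <- list(); id <- 0L
  for (tp in meal_types()) {
    for (j in seq_len(sample(seq_len(max_pool), 1))) {
      id <- id + 1L
      g <- sample(flags, sample(1:2, 1))
      dishes[[id]] <- tiny_dish(id, paste0(tp, "-", j),
                                paste(g, collapse = ";"),
                                colors = if ("raw_vegetables" %in% g)
                                  "red" else "")
      meals[[id]] <- tiny_meal(id, paste0(tp, "-", j), tp, id)
    }
  }
  ds <- load_dataset(list(dishes = do.call(rbind, dishes),
                          meals = do.call(rbind, meals)))
  list(dataset = ds, rules = toy_rules(seed + 1000L), n_days = n_days)
}

# exhaustive oracle over all assignments, fully vectorised for 1- or 2-day
# instances: enumerate each day's meal combinations, check daily bounds,
# then combine the days (weekly bounds via outer sums; the meal-repetition
# rules reduce, for adjacent days, to "no meal shared between the days",
# tested with bitmasks). Independent of the solver's search machinery.
oracle_child_feasible <- function(inst) {
  ds <- inst$dataset
  rules <- inst$rules
  n_days <- inst$n_days
  stopifnot(n_days %in% c(1L, 2L))
  act <- active_rules(rules, "preferred")
  dl <- act[act$scope == "daily", , drop = FALSE]
  wk <- act[act$scope == "weekly", , drop = FALSE]
  pools <- lapply(meal_types(), function(tp)
    candidate_meals(ds, type = tp, country = "Spain"))
  grid <- as.matrix(expand.grid(pools, KEEP.OUT.ATTRS = FALSE))
  rows <- matrix(match(grid, ds$meals$id), nrow = nrow(grid))
  keyvals <- function(key) rowSums(matrix(ds$meal_matrix[rows, key],
                                          nrow = nrow(grid)))
  counts <- vapply(unique(c(dl$key, wk$key)), keyvals,
                   numeric(nrow(grid)))
  if (nrow(grid) == 1L) counts <- matrix(counts, nrow = 1,
                                         dimnames = list(NULL,
                                           unique(c(dl$key, wk$key))))
  dayok <- rep(TRUE, nrow(grid))
  for (i in seq_len(nrow(dl))) {
    x <- counts[, dl$key[i]]
    if (!is.na(dl$min[i])) dayok <- dayok & x >= dl$min[i]
    if (!is.na(dl$max[i])) dayok <- dayok & x <= dl$max[i]
  }
  if (n_days == 1L) {
    weekok <- rep(TRUE, nrow(grid))
    for (i in seq_len(nrow(wk))) {
      x <- counts[, wk$key[i]]
      if (!is.na(wk$min[i])) weekok <- weekok & x >= wk$min[i]
      if (!is.na(wk$max[i])) weekok <- weekok & x <= wk$max[i]
    }
    return(any(dayok & weekok))
  }
  mask <- integer(nrow(grid))
  for (j in 1:5) mask <- bitwOr(mask, bitwShiftL(1L, rows[, j]))
  ok_pair <- outer(dayok, dayok, "&") &
    outer(mask, mask, function(a, b) bitwAnd(a, b) == 0L)
  for (i in seq_len(nrow(wk))) {
    tot <- outer(counts[, wk$key[i]], counts[, wk$key[i]], "+")
    if (!is.na(wk$min[i])) ok_pair <- ok_pair & tot >= wk$min[i]
    if (!is.na(wk$max[i])) ok_pair <- ok_pair & tot <= wk$max[i]
  }
  any(ok_pair)
}

oracle_child_ok <- function(day_meals, ds, rules) {
  day_led <- lapply(day_meals, count_portions, dataset = ds,
                    horizon = "day")
  week_led <- count_portions(unlist(day_meals), ds, "week")
  v <- evaluate_rules(day_led, week_led, rules, "preferred")
  if (nrow(v) > 0) return(FALSE)
  rv <- repetition_violations(day_meals, ds,
                              attr(rules, "meal_repeat_max"),
                              attr(rules, "dish_repeat_max"))
  nrow(rv) == 0
}

# solve + audit one toy instance with the real solver (node budget large
# enough that the search is complete on these tiny instances)
solver_child_feasible <- function(inst, seed = 1L) {
  req <- child_week_request("autumn", "Spain", seed = seed)
  plan <- solve_child_week(req, inst$dataset, rules = inst$rules,
                           n_days = inst$n_days,
                           control = cnr_control(max_backtracks = 200000L,
                                                 n_restarts = 1L))
  pref <- plan$feasible && length(plan$relaxations) == 0
  list(feasible = pref, plan = plan)
}

# --- adult builder oracle -------------------------------------------------

# enumerate the product of candidate lists and ask the public evaluator
oracle_adult_compliant_exists <- function(daily_lists, ds,
                                          rules = adult_rules(),
                                          max_enum = 5000L) {
  sizes <- vapply(daily_lists, function(x) nrow(x$slots), integer(1))
  if (prod(sizes) > max_enum) return(NA)
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  for (i in seq_len(nrow(grid))) {
    day_slots <- lapply(seq_along(daily_lists), function(d) {
      ids <- daily_lists[[d]]$slots[grid[i, d], ]
      as.list(stats::setNames(as.integer(ids), names(ids)))
    })
    if (nrow(adult_week_violations(day_slots, ds, rules)) == 0) {
      return(TRUE)
    }
  }
  FALSE
}

# small synthetic config used in most integration tests
test_config <- function(seed = 1, ...) synth_config(seed = seed, ...)
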