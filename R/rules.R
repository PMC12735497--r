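rule_row <- function(id, scope, key, min_pref = NA, max_pref = NA,
                     min_lr = NULL, max_lr = NULL,
                     variant_mode = "both", unit = id,
                     drop_class = "none", dairy_class = "none") {
  if (is.null(min_lr)) min_lr <- min_pref
  if (is.null(max_lr)) max_lr <- max_pref
  data.frame(id = id, scope = scope, key = key,
             min_pref = as.numeric(min_pref), max_pref = as.numeric(max_pref),
             min_lr = as.numeric(min_lr), max_lr = as.numeric(max_lr),
             variant_mode = variant_mode, unit = unit,
             drop_class = drop_class, dairy_class = dairy_class,
             stringsAsFactors = FALSE)
}

#' Child frequency rules
#'
#' The expert-style daily and weekly food-group frequency rules used by the
#' child planner, each with a preferred and (where the rule may be relaxed) a
#' less-restrictive bound. Colour rules and the pulse / white-meat
#' subcategory rules are additionally droppable: when too restrictive they
#' may be excluded entirely and only the macro category enforced.
#'
#' Dairy rules (`dairy_class = "dairy"`) apply to non-allergic children; for
#' milk-allergic children they are replaced by the plant-based rules
#' (`dairy_class = "plant"`) with the same bounds.
#'
#' Structural limits that are not simple frequency bounds — a meal id at most
#' twice a week and never on consecutive days, a dish id at most
#' `dish_repeat_max` times a week — are carried as attributes
#' (`meal_repeat_max`, `dish_repeat_max`).
#'
#' @return A `rule_table` data frame; see [evaluate_rules()].
#' @export
child_rules <- function() {
  w <- rbind(
    rule_row("w_pulses", "weekly", "pulses_any", 4, 5, 4, 6),
    rule_row("w_white_red_beans", "weekly", "white_red_beans", 1, 1, 1, 2,
             drop_class = "pulse_subcat"),
    rule_row("w_other_pulses", "weekly", "other_pulses", 1, 1, 1, 2,
             drop_class = "pulse_subcat"),
    rule_row("w_lentils", "weekly", "lentils", 1, 2, 1, 3,
             drop_class = "pulse_subcat"),
    rule_row("w_chickpeas", "weekly", "chickpeas", 1, 2, 1, 3,
             drop_class = "pulse_subcat"),
    rule_row("w_milk_yogurt", "weekly", "milk_yogurt", 14, 21,
             dairy_class = "dairy"),
    rule_row("w_cheese", "weekly", "cheese", 2, 3, 2, 4,
             dairy_class = "dairy"),
    rule_row("w_plant_bev_yogurt", "weekly", "plant_beverage_yogurt", 14, 21,
             dairy_class = "plant"),
    rule_row("w_plant_cheese", "weekly", "plant_cheese", 2, 3, 2, 4,
             dairy_class = "plant"),
    rule_row("w_fish", "weekly", "fish_seafood", 2, 4, 2, 5),
    rule_row("w_white_meat", "weekly", "white_meat_any", NA, 2),
    rule_row("w_turkey", "weekly", "turkey", NA, 1,
             drop_class = "white_meat_subcat"),
    rule_row("w_rabbit", "weekly", "rabbit", NA, 1,
             drop_class = "white_meat_subcat"),
    rule_row("w_chicken", "weekly", "chicken", NA, 2,
             drop_class = "white_meat_subcat"),
    rule_row("w_red_meat", "weekly", "red_meat_any", NA, 1,
             variant_mode = "pref_only", unit = "w_red_processed"),
    rule_row("w_processed_meat", "weekly", "processed_meat", NA, 1,
             variant_mode = "pref_only", unit = "w_red_processed"),
    rule_row("w_red_processed", "weekly", "red_processed", NA, NA, NA, 2,
             variant_mode = "lr_only", unit = "w_red_processed"),
    rule_row("w_eggs", "weekly", "eggs", 1, 3),
    rule_row("w_carbs", "weekly", "carbs", 21, 35),
    rule_row("w_bread", "weekly", "bread", NA, 14),
    rule_row("w_tubers", "weekly", "tubers", NA, 7, NA, 14),
    rule_row("w_rice", "weekly", "rice", NA, 7, NA, 14),
    rule_row("w_cereals", "weekly", "cereals", NA, 7, NA, 14),
    rule_row("w_pasta", "weekly", "pasta", NA, 7),
    rule_row("w_fruit", "weekly", "fruit", 21, 28),
    rule_row("w_vegetables", "weekly", "vegetables", 14, 21, 14, 28)
  )
  d <- rbind(
    rule_row("d_pulses", "daily", "pulses_any", NA, 2),
    rule_row("d_milk_yogurt", "daily", "milk_yogurt", NA, 3,
             dairy_class = "dairy"),
    rule_row("d_cheese", "daily", "cheese", NA, 1, dairy_class = "dairy"),
    rule_row("d_plant_bev_yogurt", "daily", "plant_beverage_yogurt", NA, 3,
             dairy_class = "plant"),
    rule_row("d_plant_cheese", "daily", "plant_cheese", NA, 1,
             dairy_class = "plant"),
    rule_row("d_fish", "daily", "fish_seafood", NA, 1),
    rule_row("d_all_meat", "daily", "all_meat", NA, 1),
    rule_row("d_eggs", "daily", "eggs", NA, 1),
    rule_row("d_bread", "daily", "bread", NA, 3),
    rule_row("d_pasta", "daily", "pasta", NA, 1),
    rule_row("d_tubers", "daily", "tubers", NA, 1, NA, 2),
    rule_row("d_rice", "daily", "rice", NA, 1, NA, 2),
    rule_row("d_cereals", "daily", "cereals", NA, 1, NA, 2),
    rule_row("d_fruit", "daily", "fruit", 3, NA),
    rule_row("d_vegetables", "daily", "vegetables", 2, NA)
  )
  col <- do.call(rbind, lapply(veg_colors(), function(cc) {
    rule_row(paste0("d_color_", cc), "daily", paste0("color_", cc),
             NA, 2, NA, 3, drop_class = "veg_color")
  }))
  rules <- rbind(w, d, col)
  attr(rules, "meal_repeat_max") <- 2L
  attr(rules, "dish_repeat_max") <- 3L
  attr(rules, "version") <- "child-1.0"
  class(rules) <- c("rule_table", "data.frame")
  rules
}

#' Adult Mediterranean-diet and diversity rules
#'
#' Weekly and daily frequency maxima for adults, plus the
#' diversity rules: fruit salad at most once a day and twice a week, at most
#' one repeated dish per day, a meal id at most twice a week (never on
#' consecutive days), and per-day lunch-or-dinner caps on white meat, red
#' meat, pork, fish and pasta. Fish is additionally capped at three weekly
#' occurrences as a main dish and four as a side dish.
#'
#' @return A data frame of frequency rules (`id`, `horizon` in
#'   `day`/`week`/`ld_day`, `key`, `max`) with structural limits as
#'   attributes.
#' @export
adult_rules <- function() {
  r <- function(id, horizon, key, max) {
    data.frame(id = id, horizon = horizon, key = key, max = max,
               stringsAsFactors = FALSE)
  }
  rules <- rbind(
    r("a_eggs_day", "day", "eggs", 1),
    r("a_turkey_week", "week", "turkey", 1),
    r("a_rabbit_week", "week", "rabbit", 1),
    r("a_red_meat_week", "week", "red_meat_any", 2),
    r("a_chicken_week", "week", "chicken", 2),
    r("a_white_red_beans_week", "week", "white_red_beans", 2),
    r("a_other_pulses_week", "week", "other_pulses", 2),
    r("a_processed_meat_week", "week", "processed_meat", 2),
    r("a_chickpeas_week", "week", "chickpeas", 3),
    r("a_lentils_week", "week", "lentils", 3),
    r("a_rice_week", "week", "rice", 3),
    r("a_pasta_week", "week", "pasta", 3),
    r("a_red_white_meat_week", "week", "red_white_meat", 4),
    r("a_pulses_week", "week", "pulses_any", 6),
    r("a_fish_week", "week", "fish_seafood", 6),
    r("a_fish_main_week", "week", "fish_main", 3),
    r("a_fish_side_week", "week", "fish_side", 4),
    r("a_fruit_salad_day", "day", "fruit_salad", 1),
    r("a_fruit_salad_week", "week", "fruit_salad", 2),
    r("a_ld_white_meat_day", "ld_day", "white_meat_any", 1),
    r("a_ld_red_meat_day", "ld_day", "red_meat_any", 1),
    r("a_ld_pork_day", "ld_day", "pork", 1),
    r("a_ld_fish_day", "ld_day", "fish_seafood", 1),
    r("a_ld_pasta_day", "ld_day", "pasta", 1)
  )
  attr(rules, "meal_repeat_max") <- 2L
  attr(rules, "dish_repeat_day_max") <- 1L  # at most one dish id repeated/day
  attr(rules, "version") <- "adult-1.0"
  rules
}

#' Relaxation state of a child rule table
#'
#' A state records, per relaxation unit, whether the preferred or the
#' less-restrictive variant is active, and which droppable rule classes
#' (vegetable colours, pulse subcategories, white-meat subcategories) have
#' been excluded entirely.
#'
#' @param rules A [child_rules()] table.
#' @param variant `"preferred"` or `"less_restrictive"` applied to every
#'   unit.
#' @param dropped Character vector of dropped classes.
#' @return A `rule_state` list.
#' @export
rule_state <- function(rules = child_rules(), variant = "preferred",
                       dropped = character()) {
  variant <- match.arg(variant, c("preferred", "less_restrictive"))
  units <- unique(rules$unit)
  structure(list(variant = stats::setNames(rep(variant, length(units)),
                                           units),
                 dropped = dropped),
            class = "rule_state")
}

#' Active rules under a relaxation state
#'
#' Resolves a [child_rules()] table against a [rule_state()] and a
#' milk-allergy flag: dropped classes are removed, dairy or plant-based rules
#' are selected by allergy, and each remaining rule takes the bounds of its
#' active variant.
#'
#' @inheritParams rule_state
#' @param state A `rule_state`, or `"preferred"`/`"less_restrictive"`.
#' @param milk_allergy If `TRUE`, dairy rules are replaced by the plant-based
#'   rules (same bounds).
#' @return Data frame with `id`, `scope`, `key`, `min`, `max`, `variant`.
#' @export
active_rules <- function(rules = child_rules(), state = "preferred",
                         milk_allergy = FALSE) {
  if (is.character(state)) state <- rule_state(rules, state)
  keep <- !(rules$drop_class %in% state$dropped)
  keep <- keep & if (milk_allergy) rules$dairy_class != "dairy" else
    rules$dairy_class != "plant"
  v <- state$variant[rules$unit]
  keep <- keep & ifelse(rules$variant_mode == "pref_only", v == "preferred",
                 ifelse(rules$variant_mode == "lr_only",
                        v == "less_restrictive", TRUE))
  act <- rules[keep, , drop = FALSE]
  vv <- state$variant[act$unit]
  data.frame(id = act$id, scope = act$scope, key = act$key,
             min = ifelse(vv == "preferred", act$min_pref, act$min_lr),
             max = ifelse(vv == "preferred", act$max_pref, act$max_lr),
             variant = vv, stringsAsFactors = FALSE, row.names = NULL)
}

#' Count food-group portions of a list of meals
#'
#' Each dish contributes exactly one portion to every food-group flag it
#' carries and one to every colour it carries; macro categories (all meat,
#' pulses, vegetables, carbohydrates, ...) are deduplicated per dish. The
#' ledger is additive over disjoint meal lists.
#'
#' @param meal_ids Integer vector of meal ids (may be empty).
#' @param dataset A `meal_dataset`.
#' @param horizon `"day"` or `"week"` (metadata only).
#' @return A `portion_ledger`: list with `counts` (named integer over all
#'   counting keys), `meal_ids` and `dish_ids` occurrence tables.
#' @export
count_portions <- function(meal_ids, dataset, horizon = "week") {
  keys <- colnames(dataset$meal_matrix)
  if (length(meal_ids) == 0) {
    counts <- stats::setNames(integer(length(keys)), keys)
    return(structure(list(horizon = horizon, counts = counts,
                          meal_ids = integer(0), dish_ids = integer(0)),
                     class = "portion_ledger"))
  }
  rows <- meal_row(dataset, meal_ids)
  counts <- colSums(dataset$meal_matrix[rows, , drop = FALSE])
  dish_ids <- unlist(dataset$meal_dish_ids[rows], use.names = FALSE)
  structure(list(horizon = horizon,
                 counts = stats::setNames(as.integer(counts), keys),
                 meal_ids = table(meal_ids),
                 dish_ids = table(dish_ids)),
            class = "portion_ledger")
}

#' @export
print.portion_ledger <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("portion_ledger (", x$horizon, "): ", sep = "")
  if (length(nz) == 0) cat("empty\n") else
    cat(paste0(names(nz), "=", nz, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate frequency rules against day and week ledgers
#'
#' @param day_ledgers List of per-day `portion_ledger`s (or `NULL` to check
#'   weekly rules only).
#' @param week_ledger Week-horizon `portion_ledger` (or `NULL`).
#' @param rules A [child_rules()] table.
#' @param state A [rule_state()] or a variant name.
#' @param milk_allergy Selects dairy vs plant-based rules.
#' @return Data frame of violations: `rule_id`, `horizon` (`"week"` or day
#'   index), `observed`, `min`, `max`, `direction`. Zero rows iff compliant.
#' @export
evaluate_rules <- function(day_ledgers, week_ledger, rules = child_rules(),
                           state = "preferred", milk_allergy = FALSE) {
  act <- active_rules(rules, state, milk_allergy)
  out <- list()
  check <- function(counts, sub, horizon) {
    obs <- counts[sub$key]
    below <- !is.na(sub$min) & obs < sub$min
    above <- !is.na(sub$max) & obs > sub$max
    hit <- below | above
    if (!any(hit)) return(NULL)
    data.frame(rule_id = sub$id[hit], horizon = horizon,
               observed = as.integer(obs[hit]),
               min = sub$min[hit], max = sub$max[hit],
               direction = ifelse(below[hit], "below", "above"),
               stringsAsFactors = FALSE)
  }
  wk <- act[act$scope == "weekly", , drop = FALSE]
  if (!is.null(week_ledger) && nrow(wk)) {
    out[[length(out) + 1L]] <- check(week_ledger$counts, wk, "week")
  }
  dl <- act[act$scope == "daily", , drop = FALSE]
  if (!is.null(day_ledgers) && nrow(dl)) {
    for (d in seq_along(day_ledgers)) {
      out[[length(out) + 1L]] <- check(day_ledgers[[d]]$counts, dl,
                                       as.character(d))
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(rule_id = character(), horizon = character(),
                      observed = integer(), min = numeric(), max = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Remaining food-group budgets given portions already fixed
#'
#' For every active rule, computes how many portions are still owed to reach
#' the minimum and how many may still be added before hitting the maximum
#' (floored at zero: portions fixed by school menus may already exceed a
#' bound; such excess is accepted, and the remaining budget is simply
#' exhausted).
#'
#' @param rules A [child_rules()] table.
#' @param ledger `portion_ledger` of the fixed portion counts.
#' @inheritParams active_rules
#' @param scope Restrict to `"daily"`/`"weekly"` rules (default both).
#' @return Data frame with `id`, `key`, `scope`, `observed`, `still_owed`,
#'   `still_allowed` (`Inf` when the rule has no maximum).
#' @export
remaining_budgets <- function(rules, ledger, state = "preferred",
                              milk_allergy = FALSE,
                              scope = c("daily", "weekly")) {
  act <- active_rules(rules, state, milk_allergy)
  act <- act[act$scope %in% scope, , drop = FALSE]
  obs <- ledger$counts[act$key]
  data.frame(
    id = act$id, key = act$key, scope = act$scope,
    observed = as.integer(obs),
    still_owed = pmax(0, ifelse(is.na(act$min), 0, act$min - obs)),
    still_allowed = ifelse(is.na(act$max), Inf, pmax(0, act$max - obs)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Meal-repetition violations
#'
#' Checks the structural repetition limits shared by the child and adult
#' rule sets: a meal id may appear at most `meal_repeat_max` times per week
#' and never on consecutive days; a dish id at most `dish_repeat_max` times
#' per week (child rules only).
#'
#' @param day_meals List (one element per day) of integer meal-id vectors.
#' @param dataset A `meal_dataset`.
#' @param meal_repeat_max,dish_repeat_max Weekly caps (`NA` to skip).
#' @param exempt_meals Meal ids exempt from the caps (the intervention snack
#'   is deliberately served three times a week).
#' @return Data frame of violations (`rule_id`, `id`, `observed`).
#' @export
repetition_violations <- function(day_meals, dataset, meal_repeat_max = 2L,
                                  dish_repeat_max = 3L,
                                  exempt_meals = integer(0)) {
  all_meals <- unlist(day_meals, use.names = FALSE)
  all_meals <- all_meals[!all_meals %in% exempt_meals]
  out <- list()
  if (!is.na(meal_repeat_max) && length(all_meals)) {
    tab <- table(all_meals)
    over <- tab[tab > meal_repeat_max]
    if (length(over)) {
      out[[length(out) + 1L]] <- data.frame(
        rule_id = "meal_repeat_week", id = as.integer(names(over)),
        observed = as.integer(over), stringsAsFactors = FALSE)
    }
    # consecutive days
    for (d in seq_len(length(day_meals) - 1L)) {
      a <- setdiff(day_meals[[d]], exempt_meals)
      b <- setdiff(day_meals[[d + 1L]], exempt_meals)
      rep_ids <- intersect(a, b)
      if (length(rep_ids)) {
        out[[length(out) + 1L]] <- data.frame(
          rule_id = "meal_repeat_consecutive", id = rep_ids,
          observed = 2L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.na(dish_repeat_max) && length(all_meals)) {
    rows <- meal_row(dataset, all_meals)
    dish_ids <- unlist(dataset$meal_dish_ids[rows], use.names = FALSE)
    tab <- table(dish_ids)
    over <- tab[tab > dish_repeat_max]
    if (length(over)) {
      out[[length(out) + 1L]] <- data.frame(
        rule_id = "dish_repeat_week", id = as.integer(names(over)),
        observed = as.integer(over), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(rule_id = character(), id = integer(),
                      observed = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Evaluate the adult weekly plan against the Mediterranean-diet rules
#'
#' Applies every [adult_rules()] frequency rule (daily, weekly, and
#' lunch-or-dinner daily caps), the fish main/side split, the repeated-dish
#' rule (at most one dish id may occur more than once within a day), and the
#' meal-repetition limits.
#'
#' @param day_slots List of 7 named vectors
#'   (`breakfast`, `morning_snack`, `lunch`, `afternoon_snack`, `dinner`)
#'   of meal ids.
#' @param dataset A `meal_dataset`.
#' @param rules An [adult_rules()] table.
#' @return Data frame of violations (`rule_id`, `horizon`, `observed`,
#'   `max`). Zero rows iff the week is fully compliant.
#' @export
adult_week_violations <- function(day_slots, dataset, rules = adult_rules()) {
  out <- list()
  all_meals <- unlist(lapply(day_slots, function(s) unname(unlist(s))),
                      use.names = FALSE)
  week <- count_portions(all_meals, dataset, "week")
  wk <- rules[rules$horizon == "week", , drop = FALSE]
  obs <- week$counts[wk$key]
  over <- obs > wk$max
  if (any(over)) {
    out[[length(out) + 1L]] <- data.frame(
      rule_id = wk$id[over], horizon = "week",
      observed = as.integer(obs[over]), max = wk$max[over],
      stringsAsFactors = FALSE)
  }
  dr <- rules[rules$horizon == "day", , drop = FALSE]
  ld <- rules[rules$horizon == "ld_day", , drop = FALSE]
  for (d in seq_along(day_slots)) {
    slots <- day_slots[[d]]
    day_meals <- unname(unlist(slots))
    dl <- count_portions(day_meals, dataset, "day")
    obs <- dl$counts[dr$key]
    over <- obs > dr$max
    if (any(over)) {
      out[[length(out) + 1L]] <- data.frame(
        rule_id = dr$id[over], horizon = as.character(d),
        observed = as.integer(obs[over]), max = dr$max[over],
        stringsAsFactors = FALSE)
    }
    ld_meals <- unname(unlist(slots[c("lunch", "dinner")]))
    ldl <- count_portions(ld_meals[!is.na(ld_meals)], dataset, "day")
    obs <- ldl$counts[ld$key]
    over <- obs > ld$max
    if (any(over)) {
      out[[length(out) + 1L]] <- data.frame(
        rule_id = ld$id[over], horizon = as.character(d),
        observed = as.integer(obs[over]), max = ld$max[over],
        stringsAsFactors = FALSE)
    }
    # at most one dish id may appear more than once within a day
    if (length(day_meals)) {
      rows <- meal_row(dataset, day_meals)
      dish_tab <- table(unlist(dataset$meal_dish_ids[rows],
                               use.names = FALSE))
      n_repeated <- sum(dish_tab > 1)
      if (n_repeated > attr(rules, "dish_repeat_day_max")) {
        out[[length(out) + 1L]] <- data.frame(
          rule_id = "a_repeat_dish_day", horizon = as.character(d),
          observed = as.integer(n_repeated),
          max = attr(rules, "dish_repeat_day_max"),
          stringsAsFactors = FALSE)
      }
    }
  }
  rep_v <- repetition_violations(
    lapply(day_slots, function(s) unname(unlist(s))), dataset,
    meal_repeat_max = attr(rules, "meal_repeat_max"),
    dish_repeat_max = NA)
  if (nrow(rep_v)) {
    out[[length(out) + 1L]] <- data.frame(
      rule_id = paste0("a_", rep_v$rule_id), horizon = "week",
      observed = rep_v$observed, max = attr(rules, "meal_repeat_max"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(rule_id = character(), horizon = character(),
                      observed = integer(), max = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
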