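# Synthetic dataset / school-menu / profile generator. Meals are built from
# composition templates that mirror how the curated Mediterranean dataset is
# structured (a dairy + carbohydrate + fruit breakfast; fruit snacks; a
# protein main + carbohydrate side + vegetable side + fruit dessert lunch;
# a protein main + vegetable + carbohydrate dinner), with protein mains
# rotating over pulses subcategories, fish, eggs, cheese and meats so that
# the preferred child frequency rules are attainable every week.

#' Synthetic-data configuration
#'
#' Defaults are chosen to emulate a realistic two-country dataset: per-type
#' meal counts comparable (scaled down) to a curated family menu library,
#' per-meal-type caloric ranges spanning typical Mediterranean meals so that
#' daily totals (~1200–3450 kcal) cover the energy requirements of most
#' adult profiles, and per-dish macronutrient fractions centred on
#' 17% protein / 30% fat of dish energy.
#'
#' @param seed Integer seed; generation is deterministic given the config.
#' @param n_breakfast,n_morning_snack,n_afternoon_snack,n_lunch,n_dinner
#'   Meals per type and country.
#' @param kcal_ranges Named list of c(min, max) kcal per meal type.
#' @param n_schools Schools per country (the last Turkish school offers a
#'   cafeteria proposal instead of dated menus).
#' @param n_families Families to generate profiles for.
#' @param allergy_rate,snack_rate Bernoulli rates for milk allergy and the
#'   intervention snack.
#' @param menu_violation_fraction Fraction of dated school menus built to
#'   break the weekly red-meat rule (two red-meat lunches), exercising
#'   budget clamping.
#' @param weeks Character vector of ISO Monday dates to generate dated
#'   menus for.
#' @param fruit_enabled Set `FALSE` to generate a dataset without any
#'   fruit-flagged dish (a provably infeasible instance for the child
#'   planner).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_breakfast = 9L, n_morning_snack = 6L,
                         n_afternoon_snack = 8L, n_lunch = 14L,
                         n_dinner = 14L,
                         kcal_ranges = list(
                           breakfast = c(250, 650),
                           morning_snack = c(80, 350),
                           lunch = c(400, 1100),
                           afternoon_snack = c(80, 350),
                           dinner = c(350, 1000)),
                         n_schools = 3L, n_families = 32L,
                         allergy_rate = 0.1, snack_rate = 0.5,
                         menu_violation_fraction = 0.2,
                         weeks = "2025-09-08",
                         fruit_enabled = TRUE) {
  stopifnot(allergy_rate >= 0, allergy_rate <= 1,
            snack_rate >= 0, snack_rate <= 1,
            all(vapply(kcal_ranges, function(r) all(r > 0) && r[1] <= r[2],
                       logical(1))))
  structure(list(seed = as.integer(seed), n_breakfast = n_breakfast,
                 n_morning_snack = n_morning_snack,
                 n_afternoon_snack = n_afternoon_snack, n_lunch = n_lunch,
                 n_dinner = n_dinner, kcal_ranges = kcal_ranges,
                 n_schools = n_schools, n_families = n_families,
                 allergy_rate = allergy_rate, snack_rate = snack_rate,
                 menu_violation_fraction = menu_violation_fraction,
                 weeks = weeks, fruit_enabled = fruit_enabled),
            class = "synth_config")
}

# age-group ingredient scaling (the oil portion follows the published
# 10/12/15/15 mL bands; other ingredients scale smoothly)
ingredient_cell <- function(main_name, main_g, factor_oil, factor_main) {
  paste0(main_name, "=", round(main_g * factor_main, 1),
         ";Olive oil=", factor_oil)
}

#' Generate a synthetic meal/dish dataset
#'
#' @param config A [synth_config()].
#' @return A validated `meal_dataset` (both countries).
#' @export
generate_dataset <- function(config = synth_config()) {
  with_seed(config$seed, {
    env <- new.env()
    env$dishes <- list()
    env$meals <- list()
    env$dish_id <- 0L
    env$meal_id <- 0L
    age_factors <- c(`3_6` = 0.65, `7_12` = 0.8, `13_15` = 1.0,
                     `16_18` = 1.05, adult = 1.0)
    oil_bands <- c(`3_6` = 10, `7_12` = 12, `13_15` = 15, `16_18` = 15,
                   adult = 15)

    add_dish <- function(name, groups, kcal, colors = character(),
                         role = "unspecified", fruit_salad = 0L,
                         main_g = 120) {
      if (!config$fruit_enabled) groups <- setdiff(groups, "fruit")
      env$dish_id <- env$dish_id + 1L
      pf <- min(0.25, max(0.10, stats::rnorm(1, 0.17, 0.02)))
      ff <- min(0.45, max(0.15, stats::rnorm(1, 0.30, 0.04)))
      ing <- vapply(names(age_factors), function(ag)
        ingredient_cell(name, main_g, oil_bands[ag], age_factors[ag]),
        character(1))
      env$dishes[[env$dish_id]] <- data.frame(
        id = env$dish_id, name = name, role = role,
        kcal = round(kcal, 2), fat_g = round(ff * kcal / 9, 2),
        protein_g = round(pf * kcal / 4, 2),
        carbs_g = round(max(0, kcal * (1 - pf - ff)) / 4, 2),
        groups = paste(groups, collapse = ";"),
        colors = paste(colors, collapse = ";"),
        fruit_salad = fruit_salad,
        ingredients_3_6 = ing[["3_6"]], ingredients_7_12 = ing[["7_12"]],
        ingredients_13_15 = ing[["13_15"]],
        ingredients_16_18 = ing[["16_18"]],
        ingredients_adult = ing[["adult"]],
        recipe = paste("Prepare the", tolower(name), "simply."),
        tip = "Choose seasonal, local produce.",
        stringsAsFactors = FALSE)
      env$dish_id
    }
    add_meal <- function(name, type, country, dish_ids,
                         seas = seasons(), audience = "both",
                         program_snack = 0L) {
      env$meal_id <- env$meal_id + 1L
      env$meals[[env$meal_id]] <- data.frame(
        id = env$meal_id, name = name, type = type, country = country,
        seasons = paste(seas, collapse = ";"),
        dish_ids = paste(dish_ids, collapse = ";"), audience = audience,
        program_snack = program_snack, stringsAsFactors = FALSE)
      env$meal_id
    }
    runif1 <- function(range) stats::runif(1, range[1], range[2])

    color_cycle <- veg_colors()
    for (country in countries()) {
      kc <- config$kcal_ranges
      # breakfasts: dairy (or plant) drink + carbohydrate + fruit
      for (i in seq_len(config$n_breakfast)) {
        kcal <- runif1(kc$breakfast)
        plant <- i > config$n_breakfast - 4L  # last 4 are dairy-free
        carb <- if (i %% 3 == 0) "bread" else "cereals"
        d1 <- add_dish(
          if (plant) paste("Soy yogurt", i) else paste("Milk with honey", i),
          if (plant) "plant_beverage_yogurt" else "milk_yogurt",
          0.35 * kcal, main_g = 200)
        d2 <- add_dish(paste(if (carb == "bread") "Wholegrain bread"
                             else "Oat flakes", i), carb, 0.40 * kcal,
                       main_g = 60)
        d3 <- add_dish(paste("Seasonal fruit bowl", i), "fruit",
                       0.25 * kcal, main_g = 150)
        add_meal(paste0(if (plant) "Plant breakfast " else "Breakfast ",
                        i, " (", country, ")"),
                 "breakfast", country, c(d1, d2, d3))
      }
      # morning snacks: fruit, some with nuts; 3-season availability
      for (i in seq_len(config$n_morning_snack)) {
        kcal <- runif1(kc$morning_snack)
        ids <- add_dish(paste("Fresh fruit", i), "fruit", kcal,
                        main_g = 160)
        if (i %% 3 == 0) {
          ids <- c(ids, add_dish(paste("Mixed nuts", i), "nuts",
                                 0.4 * kcal, main_g = 25))
        }
        excl <- seasons()[(i - 1L) %% 4L + 1L]
        add_meal(paste0("Morning snack ", i, " (", country, ")"),
                 "morning_snack", country, ids,
                 seas = setdiff(seasons(), excl))
      }
      # afternoon snacks: yogurt (or plant yogurt) + bread
      for (i in seq_len(config$n_afternoon_snack)) {
        kcal <- runif1(kc$afternoon_snack)
        plant <- i > config$n_afternoon_snack - 4L
        d1 <- add_dish(
          if (plant) paste("Plant yogurt", i) else paste("Yogurt", i),
          if (plant) "plant_beverage_yogurt" else "milk_yogurt",
          0.6 * kcal, main_g = 125)
        d2 <- add_dish(paste("Bread with olive oil", i), "bread",
                       0.4 * kcal, main_g = 40)
        add_meal(paste0(if (plant) "Plant afternoon snack "
                        else "Afternoon snack ", i, " (", country, ")"),
                 "afternoon_snack", country, c(d1, d2))
      }
      # lunches: protein main + carbohydrate side + vegetable side + fruit
      lunch_mains <- list(
        list(nm = "White bean stew", g = c("pulses", "white_red_beans")),
        list(nm = "Red bean salad", g = c("pulses", "white_red_beans")),
        list(nm = "Pea and soy mince pot", g = c("pulses", "other_pulses")),
        list(nm = "Broad bean saute", g = c("pulses", "other_pulses")),
        list(nm = "Lentil stew", g = c("pulses", "lentils")),
        list(nm = "Lentil salad", g = c("pulses", "lentils")),
        list(nm = "Chickpea stew", g = c("pulses", "chickpeas")),
        list(nm = "Hummus plate", g = c("pulses", "chickpeas")),
        list(nm = "Grilled sea bass", g = "fish_seafood", role = "main"),
        list(nm = "Baked hake", g = "fish_seafood", role = "main"),
        list(nm = "Roast chicken", g = c("white_meat", "chicken")),
        list(nm = "Chicken skewers", g = c("white_meat", "chicken")),
        list(nm = "Beef stew", g = "red_meat"),
        list(nm = "Pork loin", g = c("red_meat", "pork")))
      carb_sides <- c("pasta", "rice", "tubers")
      for (i in seq_len(config$n_lunch)) {
        main_tmpl <- lunch_mains[[(i - 1L) %% length(lunch_mains) + 1L]]
        kcal <- runif1(kc$lunch)
        d_main <- add_dish(paste(main_tmpl$nm, i), main_tmpl$g, 0.45 * kcal,
                           role = main_tmpl$role %||% "main", main_g = 150)
        carb <- carb_sides[(i - 1L) %% 3L + 1L]
        d_carb <- add_dish(paste("Side of", carb, i), carb, 0.25 * kcal,
                           role = "side", main_g = 70)
        col <- color_cycle[(i - 1L) %% 6L + 1L]
        veg_kind <- if (i %% 2 == 0) "raw_vegetables" else
          "cooked_vegetables"
        d_veg <- add_dish(paste("Vegetable side", i), veg_kind, 0.15 * kcal,
                          colors = col, role = "side", main_g = 140)
        fs <- as.integer(i %% 7 == 0)
        d_fruit <- add_dish(paste(if (fs) "Fruit salad" else "Fruit dessert",
                                  i), "fruit", 0.15 * kcal,
                            fruit_salad = fs, main_g = 150)
        add_meal(paste0("Lunch ", i, " (", country, ")"), "lunch", country,
                 c(d_main, d_carb, d_veg, d_fruit))
      }
      # dinners: main + vegetable side + carbohydrate side (+ dessert)
      dinner_mains <- list(
        list(nm = "Grilled sardines", g = "fish_seafood", role = "main",
             dessert = "dairy"),
        list(nm = "Fish soup", g = c("fish_seafood", "soups"),
             role = "main", dessert = "none"),
        list(nm = "Baked cod", g = "fish_seafood", role = "main",
             dessert = "dairy"),
        list(nm = "Vegetable omelette", g = c("eggs", "cooked_vegetables"),
             cols = "multicolor", dessert = "dairy"),
        list(nm = "Boiled eggs with greens",
             g = c("eggs", "cooked_vegetables"), cols = "green",
             dessert = "none"),
        list(nm = "Scrambled eggs", g = "eggs", dessert = "dairy"),
        list(nm = "Fresh cheese platter", g = "cheese", dessert = "none"),
        list(nm = "Cheese and tomato toast", g = c("cheese", "bread"),
             dessert = "none"),
        list(nm = "Plant cheese platter", g = "plant_cheese",
             dessert = "plant"),
        list(nm = "Plant cheese wrap", g = c("plant_cheese", "cereals"),
             dessert = "plant"),
        list(nm = "Lentil soup", g = c("pulses", "lentils", "soups"),
             dessert = "plant"),
        list(nm = "Chickpea soup", g = c("pulses", "chickpeas", "soups"),
             dessert = "none"),
        list(nm = "Turkey fillet", g = c("white_meat", "turkey"),
             dessert = "none"),
        list(nm = "Potato and vegetable stew",
             g = c("tubers", "cooked_vegetables", "soups"), cols = "white",
             dessert = "plant"))
      dinner_carbs <- c("bread", "tubers", "bread", "tubers", "rice")
      for (i in seq_len(config$n_dinner)) {
        main_tmpl <- dinner_mains[[(i - 1L) %% length(dinner_mains) + 1L]]
        kcal <- runif1(kc$dinner)
        d_main <- add_dish(paste(main_tmpl$nm, i), main_tmpl$g, 0.5 * kcal,
                           colors = main_tmpl$cols %||% character(),
                           role = main_tmpl$role %||% "main", main_g = 150)
        col <- color_cycle[(i + 2L) %% 6L + 1L]
        d_veg <- add_dish(paste("Dinner vegetables", i),
                          if (i %% 2 == 0) "cooked_vegetables" else
                            "raw_vegetables",
                          0.2 * kcal, colors = col, role = "side",
                          main_g = 130)
        ids <- c(d_main, d_veg)
        if (!"tubers" %in% main_tmpl$g && !"bread" %in% main_tmpl$g) {
          carb <- dinner_carbs[(i - 1L) %% length(dinner_carbs) + 1L]
          ids <- c(ids, add_dish(paste("Dinner side of", carb, i), carb,
                                 0.15 * kcal, role = "side", main_g = 50))
        }
        dess <- main_tmpl$dessert %||% "none"
        if (dess == "dairy") {
          ids <- c(ids, add_dish(paste("Yogurt dessert", i), "milk_yogurt",
                                 0.15 * kcal, main_g = 125))
        } else if (dess == "plant") {
          ids <- c(ids, add_dish(paste("Soy dessert", i),
                                 "plant_beverage_yogurt", 0.15 * kcal,
                                 main_g = 125))
        }
        add_meal(paste0("Dinner ", i, " (", country, ")"), "dinner",
                 country, ids)
      }
      # the intervention snack: a packaged fruit-and-nut bar, dairy-free,
      # placeable at either snack position
      d_bar <- add_dish(paste("Fruit and nut bar", country),
                        c("fruit", "nuts"), 150, main_g = 35)
      add_meal(paste0("Intervention snack (", country, ")"),
               "morning_snack", country, d_bar, audience = "child",
               program_snack = 1L)
    }
    build_dataset(do.call(rbind, env$dishes), do.call(rbind, env$meals))
  })
}

#' Generate school menus and a cafeteria proposal
#'
#' Builds dated Monday–Friday menus for each school and week from the
#' dataset's child-eligible lunches. A configurable fraction of menus is
#' deliberately non-compliant, holding two red-meat lunches in one week
#' (the weekly red-meat limit is one), to exercise the planner's budget
#' clamping. The last school of each country offers an undated cafeteria
#' proposal of six lunches instead.
#'
#' @param config A [synth_config()].
#' @param dataset Dataset from [generate_dataset()].
#' @return A `school_menus` object; school names are
#'   `"<country> school <i>"`.
#' @export
generate_school_menus <- function(config, dataset) {
  with_seed(config$seed + 1L, {
    rows <- list()
    for (country in countries()) {
      lunches <- candidate_meals(dataset, type = "lunch", country = country,
                                 audience = "child")
      lrows <- meal_row(dataset, lunches)
      red <- lunches[dataset$meal_matrix[lrows, "red_meat_any"] > 0]
      nonred <- setdiff(lunches, red)
      for (s in seq_len(config$n_schools)) {
        school <- paste(country, "school", s)
        if (s == config$n_schools) {
          pool <- sample(nonred, 6)
          rows[[length(rows) + 1L]] <- data.frame(
            school = school, country = country, week_start = "",
            weekday = "", meal_id = pool, stringsAsFactors = FALSE)
          next
        }
        for (wk in config$weeks) {
          violate <- stats::runif(1) < config$menu_violation_fraction &&
            length(red) >= 2
          ids <- if (violate) {
            c(sample(red, 2), sample(nonred, 3))
          } else {
            sample(nonred, 5)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            school = school, country = country, week_start = wk,
            weekday = weekday_names()[1:5], meal_id = sample(ids),
            stringsAsFactors = FALSE)
        }
      }
    }
    load_school_menus(do.call(rbind, rows), dataset)
  })
}

#' Generate synthetic family profiles
#'
#' Families with one or two adults and one or two children. Adult
#' anthropometrics are drawn from realistic distributions (BMI ~ N(25, 3),
#' sex-specific heights), activity levels from the five permitted values
#' with probabilities skewed towards sedentary/lightly-active, and milk
#' allergy / snack participation at the configured rates.
#'
#' @param config A [synth_config()].
#' @return List of families as in [read_profiles()].
#' @export
generate_family_profiles <- function(config = synth_config()) {
  with_seed(config$seed + 2L, {
    pal_probs <- c(0.35, 0.30, 0.20, 0.10, 0.05)
    lapply(seq_len(config$n_families), function(f) {
      country <- if (f %% 3 == 0) "Turkiye" else "Spain"
      n_adults <- if (stats::runif(1) < 0.7) 2L else 1L
      sex1 <- sample(c("male", "female"), 1)
      adults <- lapply(seq_len(n_adults), function(a) {
        sex <- if (a == 1) sex1 else setdiff(c("male", "female"), sex1)
        height <- stats::rnorm(1, if (sex == "male") 1.76 else 1.63, 0.06)
        height <- min(2.05, max(1.45, height))
        bmi <- min(38, max(18.5, stats::rnorm(1, 25, 3)))
        adult_profile(
          sex = sex, birth_year = sample(1970:1995, 1),
          height_m = round(height, 2),
          weight_kg = round(bmi * height^2, 1),
          pal = sample(unname(pal_levels()), 1, prob = pal_probs),
          milk_allergy = stats::runif(1) < config$allergy_rate,
          country = country, id = sprintf("F%02d-A%d", f, a))
      })
      n_children <- if (stats::runif(1) < 0.5) 2L else 1L
      children <- lapply(seq_len(n_children), function(ch) {
        school_lunch <- stats::runif(1) < 0.7
        n_dated <- max(1L, config$n_schools - 1L)
        child_profile(
          age_group = sample(age_groups(), 1,
                             prob = c(0.3, 0.4, 0.2, 0.1)),
          school = if (school_lunch)
            paste(country, "school", sample(n_dated, 1)) else NULL,
          school_lunch = school_lunch,
          milk_allergy = stats::runif(1) < config$allergy_rate,
          snack = stats::runif(1) < config$snack_rate,
          country = country, id = sprintf("F%02d-C%d", f, ch))
      })
      list(family_id = sprintf("F%02d", f), adults = adults,
           children = children)
    })
  })
}
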