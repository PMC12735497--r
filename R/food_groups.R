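#' Closed vocabulary of food-group flags
#'
#' Every dish carries a set of boolean food-group flags drawn from a closed,
#' case-normalised vocabulary. Subcategories (e.g. `chicken`) coexist with
#' their macro category (`white_meat`); frequency rules that span several
#' flags count a dish at most once (see [count_portions()]).
#'
#' @return Character vector of the valid food-group tokens.
#' @export
food_groups <- function() {
  c(
    "processed_meat", "white_meat", "chicken", "turkey", "rabbit",
    "red_meat", "pork", "fish_seafood",
    "pulses", "chickpeas", "lentils", "white_red_beans", "other_pulses",
    "dairy", "milk_yogurt", "cheese",
    "plant_beverage_yogurt", "plant_cheese",
    "eggs", "pasta", "rice", "tubers", "soups", "cereals", "bread",
    "fruit", "nuts", "raw_vegetables", "cooked_vegetables"
  )
}

#' Vegetable colour vocabulary
#'
#' Dishes flagged `raw_vegetables` or `cooked_vegetables` may carry one or
#' more colours; colour variety is regulated by the child daily colour rules.
#'
#' @return Character vector of valid colour tokens.
#' @export
veg_colors <- function() {
  c("red", "green", "white", "yellow", "purple", "multicolor")
}

# Derived counting keys. A dish contributes at most 1 portion to each key,
# however many of the member flags it carries (subcategory implies macro,
# deduplicated per dish).
macro_groups <- function() {
  list(
    white_meat_any = c("white_meat", "chicken", "turkey", "rabbit"),
    red_meat_any   = c("red_meat", "pork"),
    all_meat       = c("white_meat", "chicken", "turkey", "rabbit",
                       "red_meat", "pork", "processed_meat"),
    red_processed  = c("red_meat", "pork", "processed_meat"),
    red_white_meat = c("white_meat", "chicken", "turkey", "rabbit",
                       "red_meat", "pork"),
    pulses_any     = c("pulses", "chickpeas", "lentils", "white_red_beans",
                       "other_pulses"),
    vegetables     = c("raw_vegetables", "cooked_vegetables"),
    carbs          = c("bread", "pasta", "rice", "tubers", "cereals"),
    dairy_any      = c("dairy", "milk_yogurt", "cheese"),
    plant_dairy_any = c("plant_beverage_yogurt", "plant_cheese")
  )
}

# All keys a portion ledger tracks: raw flags, macro keys, colour keys and
# the fruit-salad tag used by the adult diversity rules.
count_keys <- function() {
  c(food_groups(), names(macro_groups()),
    paste0("color_", veg_colors()), "fruit_salad",
    "fish_main", "fish_side")
}

meal_types <- function() {
  c("breakfast", "morning_snack", "lunch", "afternoon_snack", "dinner")
}

countries <- function() c("Spain", "Turkiye")

seasons <- function() c("winter", "spring", "summer", "autumn")

age_groups <- function() c("3-6", "7-12", "13-15", "16-18")

weekday_names <- function() {
  c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
}
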