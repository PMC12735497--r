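#' @keywords internal
split_list_cell <- function(x) {
  x <- as.character(x)
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_list_cell <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

norm_country <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("Türkiye", "Turkey", "turkiye", "TR")] <- "Turkiye"
  x[x %in% c("spain", "ES")] <- "Spain"
  x
}

#' Load a meal/dish dataset
#'
#' Reads the CSV dialect used throughout the package: `dishes.csv` and
#' `meals.csv` in one directory (UTF-8, list-valued cells `;`-delimited,
#' booleans 0/1). Performs full referential validation and builds the lookup
#' indices and per-meal food-group contribution matrix used by the planners.
#'
#' Dish columns: `id`, `name`, `role` (`main`/`side`/`unspecified`, mapped
#' from the source "unique"/"semi" dish types), `kcal`, `fat_g`, `protein_g`,
#' `carbs_g` (empty when the dish is child-only), `groups` (`;`-list of
#' [food_groups()] tokens), `colors` (`;`-list of [veg_colors()]),
#' `fruit_salad` (0/1), per-age-group ingredient lists
#' (`ingredients_3_6` ... `ingredients_adult`, `name=grams` pairs), `recipe`,
#' `tip`. Meal columns: `id`, `name`, `type`, `country`, `seasons`,
#' `dish_ids`, `audience` (`adult`/`child`/`both`), `program_snack` (0/1).
#'
#' @param path Directory containing `dishes.csv` and `meals.csv`, or a named
#'   list with `dishes` and `meals` data frames.
#' @param country Optional country filter (`"Spain"` or `"Turkiye"`).
#' @return A `meal_dataset` object (list with `dishes`, `meals`, indices and
#'   contribution matrices).
#' @export
load_dataset <- function(path, country = NULL) {
  if (is.character(path)) {
    dish_file <- file.path(path, "dishes.csv")
    meal_file <- file.path(path, "meals.csv")
    for (f in c(dish_file, meal_file)) {
      if (!file.exists(f)) stop("dataset file not found: ", f, call. = FALSE)
    }
    dishes <- utils::read.csv(dish_file, stringsAsFactors = FALSE,
                              encoding = "UTF-8")
    meals <- utils::read.csv(meal_file, stringsAsFactors = FALSE,
                             encoding = "UTF-8")
  } else if (is.list(path) && all(c("dishes", "meals") %in% names(path))) {
    dishes <- as.data.frame(path$dishes)
    meals <- as.data.frame(path$meals)
  } else {
    stop("path must be a directory or a list(dishes=, meals=)", call. = FALSE)
  }
  build_dataset(dishes, meals, country = country)
}

#' @keywords internal
build_dataset <- function(dishes, meals, country = NULL) {
  dishes$id <- as.integer(dishes$id)
  meals$id <- as.integer(meals$id)
  if (anyDuplicated(dishes$id)) {
    stop("duplicate dish id(s): ",
         paste(unique(dishes$id[duplicated(dishes$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meals$id)) {
    stop("duplicate meal id(s): ",
         paste(unique(meals$id[duplicated(meals$id)]), collapse = ", "),
         call. = FALSE)
  }
  meals$country <- norm_country(meals$country)
  meals$type <- tolower(trimws(meals$type))
  bad_type <- !meals$type %in% meal_types()
  if (any(bad_type)) {
    stop("unknown meal type in meal(s) ",
         paste(meals$id[bad_type], collapse = ", "), call. = FALSE)
  }
  if (is.null(meals$audience)) meals$audience <- "both"
  if (is.null(meals$program_snack)) meals$program_snack <- 0L
  if (is.null(dishes$fruit_salad)) dishes$fruit_salad <- 0L
  if (is.null(dishes$role)) dishes$role <- "unspecified"

  group_sets <- split_list_cell(tolower(dishes$groups))
  color_sets <- split_list_cell(tolower(dishes$colors))
  known <- food_groups()
  bad <- vapply(group_sets, function(g) any(!g %in% known), logical(1))
  if (any(bad)) {
    stop("unknown food-group token(s) in dish row(s): ",
         paste(dishes$id[bad], collapse = ", "), call. = FALSE)
  }
  badc <- vapply(color_sets, function(g) any(!g %in% veg_colors()), logical(1))
  if (any(badc)) {
    stop("unknown vegetable colour in dish row(s): ",
         paste(dishes$id[badc], collapse = ", "), call. = FALSE)
  }
  veg_flag <- vapply(group_sets, function(g)
    any(g %in% c("raw_vegetables", "cooked_vegetables")), logical(1))
  has_color <- lengths(color_sets) > 0
  if (any(has_color & !veg_flag)) {
    stop("dish(es) carry colours without a vegetable flag: ",
         paste(dishes$id[has_color & !veg_flag], collapse = ", "),
         call. = FALSE)
  }
  for (col in c("kcal", "fat_g", "protein_g", "carbs_g")) {
    dishes[[col]] <- suppressWarnings(as.numeric(dishes[[col]]))
    if (any(dishes[[col]] < 0, na.rm = TRUE)) {
      stop("negative ", col, " in dish table", call. = FALSE)
    }
  }

  seasons_sets <- split_list_cell(tolower(meals$seasons))
  bads <- vapply(seasons_sets, function(s)
    length(s) == 0 || any(!s %in% seasons()), logical(1))
  if (any(bads)) {
    stop("invalid seasons in meal(s) ",
         paste(meals$id[bads], collapse = ", "), call. = FALSE)
  }
  dish_id_sets <- lapply(split_list_cell(meals$dish_ids), as.integer)
  n_dish <- lengths(dish_id_sets)
  if (any(n_dish < 1 | n_dish > 10)) {
    stop("meal(s) with fewer than 1 or more than 10 dishes: ",
         paste(meals$id[n_dish < 1 | n_dish > 10], collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(meals))) {
    missing <- setdiff(dish_id_sets[[i]], dishes$id)
    if (length(missing)) {
      stop("meal ", meals$id[i], " references unknown dish id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  # adult-audience meals must have complete nutrition on every dish
  match_dish <- function(ids) match(ids, dishes$id)
  nutr_ok <- !is.na(dishes$kcal) & !is.na(dishes$fat_g) &
    !is.na(dishes$protein_g) & !is.na(dishes$carbs_g)
  adult_aud <- meals$audience %in% c("adult", "both")
  for (i in which(adult_aud)) {
    rows <- match_dish(dish_id_sets[[i]])
    if (!all(nutr_ok[rows])) {
      stop("adult-audience meal ", meals$id[i],
           " has dishes without nutrition values", call. = FALSE)
    }
  }

  if (!is.null(country)) {
    country <- norm_country(country)
    keep <- meals$country == country
    meals <- meals[keep, , drop = FALSE]
    seasons_sets <- seasons_sets[keep]
    dish_id_sets <- dish_id_sets[keep]
  }

  # per-dish indicator over all counting keys (macro keys deduplicated)
  keys <- count_keys()
  dmat <- matrix(0L, nrow = nrow(dishes), ncol = length(keys),
                 dimnames = list(NULL, keys))
  for (i in seq_len(nrow(dishes))) {
    g <- group_sets[[i]]
    if (length(g)) dmat[i, g] <- 1L
    for (mk in names(macro_groups())) {
      if (any(g %in% macro_groups()[[mk]])) dmat[i, mk] <- 1L
    }
    cc <- color_sets[[i]]
    if (length(cc)) dmat[i, paste0("color_", cc)] <- 1L
  }
  dmat[, "fruit_salad"] <- as.integer(dishes$fruit_salad %in% c(1, "1", TRUE))
  role <- tolower(trimws(as.character(dishes$role)))
  role[role %in% c("unique", "main")] <- "main"
  role[role %in% c("semi", "side")] <- "side"
  role[!role %in% c("main", "side")] <- "unspecified"
  dishes$role <- role
  dmat[, "fish_main"] <- dmat[, "fish_seafood"] * (role == "main")
  dmat[, "fish_side"] <- dmat[, "fish_seafood"] * (role == "side")

  # per-meal contribution = sum of its dishes' indicators
  mmat <- matrix(0L, nrow = nrow(meals), ncol = length(keys),
                 dimnames = list(NULL, keys))
  meal_kcal <- meal_fat <- meal_protein <- numeric(nrow(meals))
  for (i in seq_len(nrow(meals))) {
    rows <- match(dish_id_sets[[i]], dishes$id)
    mmat[i, ] <- as.integer(colSums(dmat[rows, , drop = FALSE]))
    meal_kcal[i] <- sum(dishes$kcal[rows])
    meal_fat[i] <- sum(dishes$fat_g[rows])
    meal_protein[i] <- sum(dishes$protein_g[rows])
  }

  ds <- list(
    dishes = dishes, meals = meals,
    dish_groups = group_sets, dish_colors = color_sets,
    meal_seasons = seasons_sets, meal_dish_ids = dish_id_sets,
    dish_matrix = dmat, meal_matrix = mmat,
    meal_kcal = meal_kcal, meal_fat = meal_fat, meal_protein = meal_protein
  )
  class(ds) <- "meal_dataset"
  ds
}

#' @export
print.meal_dataset <- function(x, ...) {
  cat("meal_dataset:", nrow(x$meals), "meals,", nrow(x$dishes), "dishes\n")
  tab <- table(x$meals$type, x$meals$country)
  print(tab)
  invisible(x)
}

meal_row <- function(dataset, meal_ids) {
  rows <- match(meal_ids, dataset$meals$id)
  if (anyNA(rows)) {
    stop("unresolvable meal id(s): ",
         paste(meal_ids[is.na(rows)], collapse = ", "), call. = FALSE)
  }
  rows
}

#' Does a meal contain any dairy-flagged dish?
#' @keywords internal
meal_has_dairy <- function(dataset, rows) {
  dataset$meal_matrix[rows, "dairy_any"] > 0
}

#' Select candidate meals
#'
#' Filters the meal table by slot type, country, season, audience and (for
#' milk-allergic users) the absence of any dairy-flagged dish.
#'
#' @param dataset A `meal_dataset`.
#' @param type Slot type, one of [meal_types()]; `NULL` for all.
#' @param country,season Filters; `NULL` to skip.
#' @param audience `"child"` or `"adult"`: keeps meals whose audience is that
#'   value or `"both"`. `NULL` keeps everything.
#' @param milk_allergy If `TRUE`, meals containing dairy-flagged dishes are
#'   removed.
#' @param include_program_snack Keep meals flagged as the intervention snack
#'   (default `FALSE`: the snack is placed explicitly, not sampled).
#' @return Integer vector of meal ids.
#' @export
candidate_meals <- function(dataset, type = NULL, country = NULL,
                            season = NULL, audience = NULL,
                            milk_allergy = FALSE,
                            include_program_snack = FALSE) {
  keep <- rep(TRUE, nrow(dataset$meals))
  if (!is.null(type)) keep <- keep & dataset$meals$type == type
  if (!is.null(country)) {
    keep <- keep & dataset$meals$country == norm_country(country)
  }
  if (!is.null(season)) {
    season <- tolower(season)
    keep <- keep & vapply(dataset$meal_seasons, function(s) season %in% s,
                          logical(1))
  }
  if (!is.null(audience)) {
    keep <- keep & dataset$meals$audience %in% c(audience, "both")
  }
  if (milk_allergy) {
    keep <- keep & dataset$meal_matrix[, "dairy_any"] == 0
  }
  if (!include_program_snack) {
    keep <- keep & !(dataset$meals$program_snack %in% c(1, "1", TRUE))
  }
  dataset$meals$id[keep]
}

#' Write a dataset back to CSV
#'
#' Inverse of [load_dataset()]; `load_dataset(write_dataset(ds, dir))` is the
#' identity on the dish and meal tables.
#'
#' @param dataset A `meal_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$dishes, file.path(dir, "dishes.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$meals, file.path(dir, "meals.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load school menus and cafeteria proposals
#'
#' Reads `school_menus.csv` (long format: `school`, `country`, `week_start`
#' ISO date or empty, `weekday` Mon..Fri or empty, `meal_id`). Rows with a
#' `week_start` and `weekday` form dated school menus (exactly five weekday
#' lunches per school-week); rows without dates form undated cafeteria
#' proposals (at least five lunches, order preserved).
#'
#' @param path CSV file, or a data frame in the same layout.
#' @param dataset `meal_dataset` used to check that every id resolves to a
#'   lunch-type meal.
#' @return A `school_menus` object.
#' @export
load_school_menus <- function(path, dataset) {
  df <- if (is.character(path)) {
    if (!file.exists(path)) stop("menu file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    as.data.frame(path)
  }
  df$country <- norm_country(df$country)
  df$meal_id <- as.integer(df$meal_id)
  rows <- match(df$meal_id, dataset$meals$id)
  if (anyNA(rows)) {
    stop("school menu references unknown meal id(s): ",
         paste(df$meal_id[is.na(rows)], collapse = ", "), call. = FALSE)
  }
  not_lunch <- dataset$meals$type[rows] != "lunch"
  if (any(not_lunch)) {
    stop("school menu meal id(s) are not lunches: ",
         paste(df$meal_id[not_lunch], collapse = ", "), call. = FALSE)
  }
  df$week_start <- as.character(df$week_start)
  df$weekday <- as.character(df$weekday)
  dated <- !is.na(df$week_start) & nzchar(df$week_start)
  menus <- list()
  if (any(dated)) {
    dd <- df[dated, , drop = FALSE]
    key <- paste(dd$school, dd$country, dd$week_start, sep = "|")
    for (k in unique(key)) {
      sub <- dd[key == k, , drop = FALSE]
      if (nrow(sub) != 5 ||
          !setequal(sub$weekday, weekday_names()[1:5])) {
        stop("dated school menu ", k,
             " must have exactly the five weekday lunches", call. = FALSE)
      }
      lunches <- sub$meal_id[match(weekday_names()[1:5], sub$weekday)]
      names(lunches) <- weekday_names()[1:5]
      menus[[length(menus) + 1L]] <- structure(
        list(school = sub$school[1], country = sub$country[1],
             week_start = sub$week_start[1], lunches = lunches),
        class = "school_menu")
    }
  }
  proposals <- list()
  if (any(!dated)) {
    ud <- df[!dated, , drop = FALSE]
    key <- paste(ud$school, ud$country, sep = "|")
    for (k in unique(key)) {
      sub <- ud[key == k, , drop = FALSE]
      if (nrow(sub) < 5) {
        stop("cafeteria proposal ", k,
             " needs at least 5 lunches to fill a school week",
             call. = FALSE)
      }
      proposals[[length(proposals) + 1L]] <- structure(
        list(school = sub$school[1], country = sub$country[1],
             lunches = sub$meal_id),
        class = "cafeteria_proposal")
    }
  }
  structure(list(menus = menus, proposals = proposals),
            class = "school_menus")
}

#' Find the lunch source for a school and week
#'
#' Returns the dated menu matching `(school, country, week_start)` when one
#' exists, else the school's cafeteria proposal, else `NULL` (the planner
#' then runs in home mode).
#'
#' @param menus A `school_menus` object (or `NULL`).
#' @param school School name (or `NULL` for home mode).
#' @param country,week_start Match keys.
#' @return A `school_menu`, a `cafeteria_proposal`, or `NULL`.
#' @export
find_school_menu <- function(menus, school, country, week_start) {
  if (is.null(menus) || is.null(school)) return(NULL)
  country <- norm_country(country)
  for (m in menus$menus) {
    if (m$school == school && m$country == country &&
        m$week_start == as.character(week_start)) {
      return(m)
    }
  }
  for (p in menus$proposals) {
    if (p$school == school && p$country == country) return(p)
  }
  NULL
}
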