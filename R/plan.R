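#' Construct a weekly plan object
#'
#' A weekly plan holds 7 ordered days of 5 slots, each slot a meal id plus a
#' provenance tag (`school`, `cafeteria`, `child_fixed`, `generated`,
#' `program_snack`), together with the request context, the relaxation
#' record and the feasibility flag.
#'
#' @param owner List describing the owner (id, type, country, milk_allergy,
#'   ...).
#' @param week_start ISO date string of the plan's Monday.
#' @param season,country Request context.
#' @param seed Integer seed the plan was solved under.
#' @param days List of day records; each has `weekday` and `slots`, a named
#'   list mapping each of [meal_types()] to `list(meal_id, provenance)`.
#' @param relaxations Character vector of relaxation steps applied (rule ids
#'   / dropped classes, in ladder order).
#' @param feasible Logical.
#' @param ruleset_version Version string of the rule table used.
#' @param relaxed_units Relaxation units switched to their less-restrictive
#'   variant when the plan was accepted. Together with `dropped` this
#'   reproduces the solver's final rule state (see [plan_rule_state()]).
#' @param dropped Character vector of dropped rule classes.
#' @return A `weekly_plan` object.
#' @export
weekly_plan <- function(owner, week_start, season, country, seed, days,
                        relaxations = character(), feasible = TRUE,
                        ruleset_version = "child-1.0",
                        relaxed_units = character(), dropped = character()) {
  structure(list(owner = owner, week_start = as.character(week_start),
                 season = season, country = norm_country(country),
                 seed = as.integer(seed), feasible = isTRUE(feasible),
                 ruleset_version = ruleset_version,
                 relaxed_units = as.character(relaxed_units),
                 dropped = as.character(dropped),
                 relaxations = as.character(relaxations), days = days),
            class = "weekly_plan")
}

#' Rule state a plan was accepted under
#'
#' Reconstructs the [rule_state()] (variant per relaxation unit, dropped
#' classes) recorded in a solved plan, so that an independent audit can
#' evaluate the plan exactly as the solver did.
#'
#' @param plan A `weekly_plan`.
#' @param rules The [child_rules()] table the plan was solved with.
#' @return A `rule_state`.
#' @export
plan_rule_state <- function(plan, rules = child_rules()) {
  st <- rule_state(rules, "preferred", dropped = plan$dropped)
  st$variant[intersect(plan$relaxed_units, names(st$variant))] <-
    "less_restrictive"
  st
}

#' Meal ids of a plan, by day
#'
#' @param plan A `weekly_plan`.
#' @param slots Which slot types to keep (default all five).
#' @param provenance Optional filter on slot provenance.
#' @return List (one element per day) of integer meal-id vectors.
#' @export
plan_day_meals <- function(plan, slots = meal_types(), provenance = NULL) {
  lapply(plan$days, function(day) {
    ids <- integer(0)
    for (s in slots) {
      sl <- day$slots[[s]]
      if (is.null(sl) || is.null(sl$meal_id) || is.na(sl$meal_id)) next
      if (!is.null(provenance) && !sl$provenance %in% provenance) next
      ids <- c(ids, as.integer(sl$meal_id))
    }
    ids
  })
}

#' @export
print.weekly_plan <- function(x, ...) {
  cat("weekly_plan:", x$country, x$season, "week of", x$week_start,
      if (x$feasible) "(feasible)" else "(INFEASIBLE)", "\n")
  for (i in seq_along(x$days)) {
    day <- x$days[[i]]
    parts <- vapply(meal_types(), function(s) {
      sl <- day$slots[[s]]
      if (is.null(sl) || is.na(sl$meal_id)) "-" else
        paste0(sl$meal_id, "[", substr(sl$provenance, 1, 3), "]")
    }, character(1))
    cat(sprintf("  %s: %s\n", day$weekday, paste(parts, collapse = " ")))
  }
  if (length(x$relaxations)) {
    cat("  relaxations:", paste(x$relaxations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a weekly plan's invariants
#'
#' Checks the structural invariants: 7 days with the five slot types, known
#' provenance tags; if a school menu is supplied, slots with `school`
#' provenance must match it verbatim; if a dataset is supplied and the owner
#' is milk-allergic, no dish may carry a dairy flag, and all meals must match
#' the owner's country and the requested season.
#'
#' @param plan A `weekly_plan`.
#' @param dataset Optional `meal_dataset` for content checks.
#' @param menu Optional `school_menu` the plan was solved against.
#' @return `TRUE` invisibly; stops with a message on the first breach.
#' @export
validate_weekly_plan <- function(plan, dataset = NULL, menu = NULL) {
  if (length(plan$days) != 7) stop("plan must have 7 days", call. = FALSE)
  provs <- c("school", "cafeteria", "child_fixed", "generated",
             "program_snack")
  for (day in plan$days) {
    if (!all(meal_types() %in% names(day$slots))) {
      stop("day ", day$weekday, " is missing slot types", call. = FALSE)
    }
    for (s in meal_types()) {
      sl <- day$slots[[s]]
      if (!is.null(sl) && !is.na(sl$meal_id) && !sl$provenance %in% provs) {
        stop("unknown provenance '", sl$provenance, "'", call. = FALSE)
      }
    }
  }
  if (!is.null(menu) && inherits(menu, "school_menu")) {
    for (i in 1:5) {
      sl <- plan$days[[i]]$slots$lunch
      if (!is.null(sl) && identical(sl$provenance, "school") &&
          sl$meal_id != menu$lunches[[i]]) {
        stop("school lunch on ", weekday_names()[i],
             " does not match the school menu (plan ", sl$meal_id,
             ", menu ", menu$lunches[[i]], ")", call. = FALSE)
      }
    }
  }
  if (!is.null(dataset)) {
    ids <- unlist(plan_day_meals(plan), use.names = FALSE)
    rows <- meal_row(dataset, ids)
    if (isTRUE(plan$owner$milk_allergy)) {
      # school-provided lunches are outside the planner's control and are
      # accepted verbatim; the allergy guarantee covers everything else
      own_ids <- unlist(plan_day_meals(
        plan, provenance = c("generated", "child_fixed", "program_snack",
                             "cafeteria")), use.names = FALSE)
      if (length(own_ids)) {
        own_rows <- meal_row(dataset, own_ids)
        bad <- meal_has_dairy(dataset, own_rows)
        if (any(bad)) {
          stop("milk-allergy plan contains dairy-flagged meal(s): ",
               paste(unique(own_ids[bad]), collapse = ", "), call. = FALSE)
        }
      }
    }
    wrong_c <- dataset$meals$country[rows] != plan$country
    if (any(wrong_c)) {
      stop("meal(s) from the wrong country: ",
           paste(unique(ids[wrong_c]), collapse = ", "), call. = FALSE)
    }
    ok_season <- vapply(dataset$meal_seasons[rows],
                        function(s) tolower(plan$season) %in% s, logical(1))
    if (!all(ok_season)) {
      stop("meal(s) outside the requested season: ",
           paste(unique(ids[!ok_season]), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Export a weekly plan to JSON
#'
#' Re-validates the plan before writing (a plan whose fixed school lunches
#' were edited after solving is refused). `read_weekly_plan()` restores an
#' identical object.
#'
#' @inheritParams validate_weekly_plan
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weekly_plan <- function(plan, path, dataset = NULL, menu = NULL) {
  validate_weekly_plan(plan, dataset = dataset, menu = menu)
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a weekly plan from JSON
#' @param path File written by [write_weekly_plan()].
#' @return A `weekly_plan`.
#' @export
read_weekly_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  days <- lapply(x$days, function(day) {
    slots <- lapply(day$slots, function(sl) {
      if (is.null(sl)) return(NULL)
      list(meal_id = if (is.null(sl$meal_id)) NA_integer_ else
        as.integer(sl$meal_id), provenance = sl$provenance)
    })
    list(weekday = day$weekday, slots = slots)
  })
  weekly_plan(owner = x$owner, week_start = x$week_start, season = x$season,
              country = x$country, seed = x$seed, days = days,
              relaxations = unlist(x$relaxations) %||% character(),
              feasible = isTRUE(x$feasible),
              ruleset_version = x$ruleset_version,
              relaxed_units = unlist(x$relaxed_units) %||% character(),
              dropped = unlist(x$dropped) %||% character())
}
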