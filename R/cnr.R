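# Child weekly planner: backtracking constraint solver over (day, slot)
# positions with forward checking against remaining food-group budgets, a
# relaxation ladder from preferred to less-restrictive rule variants, and
# structural repetition limits.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a child weekly-plan request
#'
#' @param season One of [seasons()].
#' @param country `"Spain"` or `"Turkiye"`.
#' @param week_start ISO date string of the plan's Monday.
#' @param school School name, or `NULL` for home mode.
#' @param milk_allergy Logical: exclude dairy and enforce the plant-based
#'   substitution rules.
#' @param snack Logical: insert the intervention snack three times a week in
#'   mid-morning or afternoon position.
#' @param seed Integer seed (recorded in the plan).
#' @param age_group Child age group, used for portion scaling.
#' @param owner_id Optional owner identifier.
#' @return A `child_week_request`.
#' @export
child_week_request <- function(season, country, week_start = "2025-09-08",
                               school = NULL, milk_allergy = FALSE,
                               snack = FALSE, seed = 1L,
                               age_group = "7-12", owner_id = NA_character_) {
  season <- match.arg(tolower(season), seasons())
  structure(list(season = season, country = norm_country(country),
                 week_start = as.character(week_start), school = school,
                 milk_allergy = isTRUE(milk_allergy), snack = isTRUE(snack),
                 seed = as.integer(seed),
                 age_group = match.arg(age_group, age_groups()),
                 owner_id = owner_id),
            class = "child_week_request")
}

#' Resolve where weekday lunches come from
#'
#' Dated school menus pin the five weekday lunches; an undated cafeteria
#' proposal provides a pool the solver orders freely; with no school (or a
#' school that has no menu on file, which raises a warning) the planner runs
#' in home mode and all lunches are free.
#'
#' @param request A [child_week_request()].
#' @param menus A `school_menus` object or `NULL`.
#' @return List with `mode` (`"school"`, `"cafeteria"`, `"home"`) and
#'   `menu` (the matched menu/proposal or `NULL`).
#' @export
resolve_lunch_source <- function(request, menus = NULL) {
  if (is.null(request$school)) return(list(mode = "home", menu = NULL))
  m <- find_school_menu(menus, request$school, request$country,
                        request$week_start)
  if (is.null(m)) {
    warning("no school menu or cafeteria proposal for school '",
            request$school, "'; falling back to home mode", call. = FALSE)
    return(list(mode = "home", menu = NULL))
  }
  if (inherits(m, "school_menu")) list(mode = "school", menu = m)
  else list(mode = "cafeteria", menu = m)
}

#' Solver control parameters
#'
#' @param max_backtracks Node budget per search attempt; together with
#'   `n_restarts` this caps the work per ladder state before the next
#'   relaxation step is attempted.
#' @param n_restarts Seeded random restarts (reshuffled candidate order)
#'   per ladder state; restarts escape the heavy-tailed behaviour of
#'   backtracking search.
#' @param dish_repeat_max Weekly cap on dish-id occurrences.
#' @param n_snacks Number of intervention snacks per week when requested.
#' @return List of control values.
#' @export
cnr_control <- function(max_backtracks = 8000L, n_restarts = 6L,
                        dish_repeat_max = 3L, n_snacks = 3L) {
  list(max_backtracks = as.integer(max_backtracks),
       n_restarts = as.integer(n_restarts),
       dish_repeat_max = as.integer(dish_repeat_max),
       n_snacks = as.integer(n_snacks))
}

# Collapse active rules into per-key bound vectors over `keys`; rules sharing
# a key combine to the tightest bounds. Returns also key->rule-id maps for
# failure evidence.
rule_bounds <- function(act, keys, scope) {
  sub <- act[act$scope == scope, , drop = FALSE]
  min_v <- stats::setNames(rep(0, length(keys)), keys)
  max_v <- stats::setNames(rep(Inf, length(keys)), keys)
  ids <- stats::setNames(rep(NA_character_, length(keys)), keys)
  for (i in seq_len(nrow(sub))) {
    k <- sub$key[i]
    if (!k %in% keys) next
    if (!is.na(sub$min[i])) min_v[k] <- max(min_v[k], sub$min[i])
    if (!is.na(sub$max[i])) max_v[k] <- min(max_v[k], sub$max[i])
    ids[k] <- sub$id[i]
  }
  list(min = min_v, max = max_v, ids = ids)
}

#' One step of the relaxation ladder
#'
#' Given the failure evidence of the previous solve attempt (rule ids,
#' ordered most limiting first), produces the next rule state: droppable
#' rules tied to the limiting category are excluded first (vegetable colours,
#' then pulse subcategories, then white-meat subcategories), then the
#' limiting rules are switched to their less-restrictive variants, one or two
#' at a time. When everything relaxable is exhausted the state is returned
#' unchanged with `exhausted = TRUE`.
#'
#' @param state Current [rule_state()].
#' @param evidence Character vector of limiting rule ids (most limiting
#'   first); may be empty.
#' @param rules The [child_rules()] table.
#' @return List with `state`, `step` (description of the action taken) and
#'   `exhausted`.
#' @export
relax_ladder <- function(state, evidence, rules = child_rules()) {
  drop_order <- c("veg_color", "pulse_subcat", "white_meat_subcat")
  ev_rows <- rules[match(intersect(evidence, rules$id), rules$id), ,
                   drop = FALSE]
  # 1. drop a droppable class implicated by the evidence
  ev_classes <- intersect(drop_order, ev_rows$drop_class)
  ev_classes <- setdiff(ev_classes, state$dropped)
  if (length(ev_classes)) {
    cl <- ev_classes[1]
    state$dropped <- c(state$dropped, cl)
    return(list(state = state, step = paste0("drop:", cl),
                exhausted = FALSE))
  }
  # 2. relax implicated rules still at their preferred variant
  relaxable_units <- unique(rules$unit[is_relaxable_row(rules)])
  ev_units <- unique(ev_rows$unit)
  cand <- ev_units[ev_units %in% relaxable_units &
                     state$variant[ev_units] == "preferred"]
  if (length(cand)) {
    take <- cand[seq_len(min(2L, length(cand)))]
    state$variant[take] <- "less_restrictive"
    return(list(state = state,
                step = paste0("relax:", paste(take, collapse = "+")),
                exhausted = FALSE))
  }
  # 3. no usable evidence: drop the next class, then relax remaining rules
  next_cl <- setdiff(drop_order, state$dropped)
  if (length(next_cl)) {
    state$dropped <- c(state$dropped, next_cl[1])
    return(list(state = state, step = paste0("drop:", next_cl[1]),
                exhausted = FALSE))
  }
  left <- relaxable_units[state$variant[relaxable_units] == "preferred"]
  left <- left[!is.na(left)]
  if (length(left)) {
    take <- left[seq_len(min(2L, length(left)))]
    state$variant[take] <- "less_restrictive"
    return(list(state = state,
                step = paste0("relax:", paste(take, collapse = "+")),
                exhausted = FALSE))
  }
  list(state = state, step = "exhausted", exhausted = TRUE)
}

is_relaxable_row <- function(rules) {
  diff_min <- !(is.na(rules$min_pref) & is.na(rules$min_lr)) &
    !mapply(identical, rules$min_pref, rules$min_lr)
  diff_max <- !(is.na(rules$max_pref) & is.na(rules$max_lr)) &
    !mapply(identical, rules$max_pref, rules$max_lr)
  diff_min | diff_max | rules$variant_mode != "both"
}

#' Solve a child weekly plan
#'
#' Formulates the week as a constraint-satisfaction problem over
#' `n_days x 5` slots. School or cafeteria lunches are fixed (their
#' food-group portions are counted and the remaining budgets clamped; excess
#' contributed by fixed lunches alone is accepted), the intervention snack is
#' placed three times a week when requested, and the remaining slots are
#' filled by seeded backtracking search with forward checking. When no
#' feasible assignment exists under the current rules the relaxation ladder
#' is climbed; if it is exhausted the plan is returned with
#' `feasible = FALSE` and the tightest violated rules named.
#'
#' @param request A [child_week_request()].
#' @param dataset A `meal_dataset`.
#' @param menus Optional `school_menus`.
#' @param rules A [child_rules()] table.
#' @param n_days Number of days to plan (7 for a real week; smaller horizons
#'   are supported for exhaustive verification).
#' @param control See [cnr_control()].
#' @return A `weekly_plan` (with `feasible = FALSE` and an
#'   `infeasible_rules` field if the ladder was exhausted).
#' @export
solve_child_week <- function(request, dataset, menus = NULL,
                             rules = child_rules(), n_days = 7L,
                             control = cnr_control()) {
  source <- resolve_lunch_source(request, menus)
  state <- rule_state(rules, "preferred")
  relaxations <- character()
  with_seed(request$seed, {
    pools <- lapply(stats::setNames(meal_types(), meal_types()), function(tp)
      candidate_meals(dataset, type = tp, country = request$country,
                      season = request$season, audience = "child",
                      milk_allergy = request$milk_allergy))
    # seeded shuffle of each pool: the search order (and so the plan) is a
    # deterministic function of the seed
    pools <- lapply(pools, function(p) if (length(p) > 1) sample(p) else p)

    # fixed slots ---------------------------------------------------------
    n_slots <- 5L * n_days
    fixed_meal <- rep(NA_integer_, n_slots)
    prov <- matrix("generated", nrow = n_days, ncol = 5,
                   dimnames = list(NULL, meal_types()))
    pos_of <- function(day, slot) (day - 1L) * 5L + match(slot, meal_types())
    if (source$mode == "school") {
      if (n_days < 5) stop("school mode needs at least 5 days", call. = FALSE)
      for (d in 1:5) {
        fixed_meal[pos_of(d, "lunch")] <- source$menu$lunches[[d]]
        prov[d, "lunch"] <- "school"
      }
    }
    snack_id <- NA_integer_
    placements <- list(NULL)
    if (request$snack) {
      cand <- dataset$meals$id[
        dataset$meals$program_snack %in% c(1, "1", TRUE) &
          dataset$meals$country == request$country &
          (!request$milk_allergy | dataset$meal_matrix[, "dairy_any"] == 0)]
      if (length(cand) == 0) {
        stop("dataset has no intervention snack meal for ", request$country,
             call. = FALSE)
      }
      snack_id <- cand[1]
      # several seeded placements of the 3 weekly snacks (distinct days,
      # mid-morning or afternoon position): the solver tries each before
      # conceding a relaxation step
      n_snk <- min(control$n_snacks, n_days)
      placements <- lapply(1:4, function(j) {
        list(days = sort(sample(seq_len(n_days), n_snk)),
             pos = sample(c("morning_snack", "afternoon_snack"), n_snk,
                          replace = TRUE))
      })
    }
    cafeteria_pool <- NULL
    if (source$mode == "cafeteria") {
      cafeteria_pool <- source$menu$lunches
      if (request$milk_allergy) {
        rows <- meal_row(dataset, cafeteria_pool)
        cafeteria_pool <- cafeteria_pool[!meal_has_dairy(dataset, rows)]
      }
      if (length(cafeteria_pool) < 5) {
        stop("cafeteria proposal has fewer than 5 usable lunches",
             call. = FALSE)
      }
    }

    # instance = fixed slots + per-position candidate lists for one snack
    # placement -----------------------------------------------------------
    base_fixed <- fixed_meal
    base_prov <- prov
    make_instance <- function(pl) {
      fixed <- base_fixed
      pv <- base_prov
      if (!is.null(pl)) {
        for (i in seq_along(pl$days)) {
          fixed[pos_of(pl$days[i], pl$pos[i])] <- snack_id
          pv[pl$days[i], pl$pos[i]] <- "program_snack"
        }
      }
      slot_cands <- vector("list", n_slots)
      for (d in seq_len(n_days)) {
        for (s in meal_types()) {
          p <- pos_of(d, s)
          if (!is.na(fixed[p])) next
          if (s == "lunch" && d <= 5 && source$mode == "cafeteria") {
            slot_cands[[p]] <- cafeteria_pool
            pv[d, "lunch"] <- "cafeteria"
          } else {
            cc <- pools[[s]]
            rot <- (d - 1L) %% length(cc)
            if (rot > 0L) cc <- c(cc[-seq_len(rot)], cc[seq_len(rot)])
            slot_cands[[p]] <- cc
          }
        }
      }
      free_pos <- which(is.na(fixed))
      if (any(lengths(slot_cands[free_pos]) == 0)) {
        empty <- meal_types()[(free_pos[
          lengths(slot_cands[free_pos]) == 0] - 1L) %% 5L + 1L]
        stop("no candidate meals for slot type(s): ",
             paste(unique(empty), collapse = ", "), call. = FALSE)
      }
      exempt_pos <- which(as.vector(t(pv))[seq_len(n_slots)] ==
                            "program_snack")
      list(fixed = fixed, prov = pv, slot_cands = slot_cands,
           exempt = exempt_pos)
    }

    attempt <- NULL
    inst <- NULL
    repeat {
      found <- FALSE
      for (pl in placements) {
        inst_try <- make_instance(pl)
        for (restart in seq_len(max(1L, control$n_restarts))) {
          if (restart > 1L) {
            # diversify: reshuffle the free-slot candidate orders
            inst_try$slot_cands <- lapply(inst_try$slot_cands, function(cc)
              if (length(cc) > 1) sample(cc) else cc)
          }
          attempt <- cnr_attempt(request, dataset, rules, state, n_days,
                                 inst_try$fixed, inst_try$slot_cands,
                                 control, inst_try$exempt)
          if (attempt$ok) break
          # a completed (non-aborted) search proved this instance
          # infeasible: further restarts cannot change the answer
          if (!isTRUE(attempt$aborted)) break
        }
        if (attempt$ok) {
          inst <- inst_try
          found <- TRUE
          break
        }
        if (isTRUE(attempt$conflict)) break  # placement-independent
      }
      if (found) break
      inst <- inst_try
      step <- relax_ladder(state, attempt$evidence, rules)
      if (step$exhausted) break
      state <- step$state
      relaxations <- c(relaxations, step$step)
    }
    fixed_meal <- inst$fixed
    prov <- inst$prov

    owner <- list(id = request$owner_id, type = "child",
                  age_group = request$age_group,
                  milk_allergy = request$milk_allergy,
                  country = request$country)
    days <- vector("list", 7)
    wdays <- weekday_names()
    for (d in 1:7) {
      slots <- stats::setNames(vector("list", 5), meal_types())
      for (s in meal_types()) {
        if (d <= n_days && attempt$ok) {
          p <- pos_of(d, s)
          slots[[s]] <- list(meal_id = unname(attempt$assign[p]),
                             provenance = unname(prov[d, s]))
        } else if (d <= n_days && !attempt$ok) {
          p <- pos_of(d, s)
          mid <- if (!is.na(fixed_meal[p])) fixed_meal[p] else NA_integer_
          slots[[s]] <- list(meal_id = unname(mid),
                             provenance = unname(prov[d, s]))
        } else {
          slots[[s]] <- list(meal_id = NA_integer_,
                             provenance = "generated")
        }
      }
      days[[d]] <- list(weekday = wdays[d], slots = slots)
    }
    plan <- weekly_plan(
      owner = owner, week_start = request$week_start,
      season = request$season, country = request$country,
      seed = request$seed, days = days, relaxations = relaxations,
      feasible = attempt$ok,
      ruleset_version = attr(rules, "version") %||% "custom",
      relaxed_units = names(state$variant)[
        state$variant == "less_restrictive"],
      dropped = state$dropped)
    if (!attempt$ok) plan$infeasible_rules <- attempt$evidence
    plan$n_days <- n_days
    plan
  })
}

# One backtracking attempt under a fixed rule state. Returns list(ok,
# assign, evidence) where evidence names the limiting rule ids.
cnr_attempt <- function(request, dataset, rules, state, n_days, fixed_meal,
                        slot_cands, control, exempt_pos = integer(0)) {
  act <- active_rules(rules, state, request$milk_allergy)
  keys <- colnames(dataset$meal_matrix)
  db <- rule_bounds(act, keys, "daily")
  wb <- rule_bounds(act, keys, "weekly")
  # arithmetic conflict pre-check: portions owed to subcategory minima all
  # consume their macro-category budget; if, even with the fixed lunches
  # counted, the owed subcategory portions exceed what the macro maximum
  # still allows, no assignment exists and the ladder can be climbed
  # without burning the search budget
  fixed_full <- numeric(length(keys))
  names(fixed_full) <- keys
  fx <- which(!is.na(fixed_meal))
  if (length(fx)) {
    frows <- match(fixed_meal[fx], dataset$meals$id)
    fixed_full <- colSums(dataset$meal_matrix[frows, , drop = FALSE])
  }
  for (mk in names(macro_groups())) {
    if (!is.finite(wb$max[mk])) next
    members <- intersect(macro_groups()[[mk]], keys)
    owed <- pmax(0, wb$min[members] - fixed_full[members])
    allowance <- max(wb$max[mk], fixed_full[mk]) - fixed_full[mk]
    if (sum(owed) > allowance) {
      ev <- unique(stats::na.omit(c(wb$ids[members][owed > 0],
                                    wb$ids[mk])))
      return(list(ok = FALSE, assign = rep(NA_integer_, 5L * n_days),
                  evidence = as.character(ev), nodes = 0L,
                  aborted = FALSE, conflict = TRUE))
    }
  }

  # restrict to keys that any bound touches
  used <- which(db$min > 0 | is.finite(db$max) | wb$min > 0 |
                  is.finite(wb$max))
  if (length(used) == 0) used <- 1L  # unconstrained: keep one inert key
  keys_u <- keys[used]
  MT <- t(dataset$meal_matrix[, used, drop = FALSE])  # K x n_meals
  mrow <- function(ids) match(ids, dataset$meals$id)
  n_slots <- 5L * n_days
  K <- length(used)

  d_min <- db$min[used]; d_max <- db$max[used]
  w_min <- wb$min[used]; w_max <- wb$max[used]

  # fixed contributions raise the effective bounds (school menus are
  # accepted even when they already break a rule)
  fixed_day <- matrix(0, nrow = n_days, ncol = K)
  fixed_week <- numeric(K)
  for (p in which(!is.na(fixed_meal))) {
    d <- (p - 1L) %/% 5L + 1L
    v <- MT[, mrow(fixed_meal[p])]
    fixed_day[d, ] <- fixed_day[d, ] + v
    fixed_week <- fixed_week + v
  }
  d_max_eff <- lapply(seq_len(n_days), function(d)
    pmax(fixed_day[d, ], d_max))
  w_max_eff <- pmax(w_max, fixed_week)

  # per-position contribution upper bound (for minima lookahead)
  P <- matrix(0, nrow = n_slots, ncol = K)
  for (p in seq_len(n_slots)) {
    if (!is.na(fixed_meal[p])) {
      P[p, ] <- MT[, mrow(fixed_meal[p])]
    } else {
      sub <- MT[, mrow(slot_cands[[p]]), drop = FALSE]
      P[p, ] <- apply(sub, 1, max)
    }
  }
  # suffix potentials: week-wide and within-day, stored row-per-position
  W_suf <- apply(P[n_slots:1, , drop = FALSE], 2, cumsum)[n_slots:1, ,
                                                          drop = FALSE]
  W_suf <- rbind(W_suf, 0)  # row p: potential from position p to end
  D_suf <- matrix(0, nrow = n_slots + 1L, ncol = K)
  for (d in seq_len(n_days)) {
    idx <- ((d - 1L) * 5L + 1L):(d * 5L)
    block <- P[idx, , drop = FALSE]
    suf <- apply(block[5:1, , drop = FALSE], 2, cumsum)[5:1, , drop = FALSE]
    D_suf[idx, ] <- suf
  }
  W_suf_l <- lapply(seq_len(n_slots + 1L), function(p) W_suf[p, ])
  D_suf_l <- lapply(seq_len(n_slots + 1L), function(p) D_suf[p, ])
  zero_k <- numeric(K)

  cand_rows <- lapply(slot_cands, function(cc)
    if (is.null(cc)) integer(0) else mrow(cc))
  cand_sub <- lapply(cand_rows, function(rr)
    if (length(rr)) MT[, rr, drop = FALSE] else NULL)
  meal_dish_rows <- lapply(dataset$meal_dish_ids, match,
                           table = dataset$dishes$id)
  n_meals <- nrow(dataset$meals)
  n_dishes <- nrow(dataset$dishes)

  assign <- rep(NA_integer_, n_slots)     # meal id per position
  meal_use <- integer(n_meals)
  meal_last_day <- rep(-1L, n_meals)      # last day used (-1 = never)
  dish_use <- integer(n_dishes)
  week_cnt <- numeric(K)
  day_cnt <- lapply(seq_len(n_days), function(d) numeric(K))
  prune_max <- numeric(K)
  prune_min <- numeric(K)
  nodes <- 0L
  aborted <- FALSE
  fixed_rows <- ifelse(is.na(fixed_meal), NA_integer_, mrow(fixed_meal))
  dish_cap <- control$dish_repeat_max
  node_cap <- control$max_backtracks

  try_pos <- function(p) {
    if (p > n_slots) return(TRUE)
    d <- (p - 1L) %/% 5L + 1L
    day_end <- (p %% 5L) == 0L
    d_suf_next <- if (day_end) zero_k else D_suf_l[[p + 1L]]
    w_suf_next <- W_suf_l[[p + 1L]]
    if (!is.na(fixed_meal[p])) {
      r <- fixed_rows[p]
      v <- MT[, r]
      nd <- day_cnt[[d]] + v
      nw <- week_cnt + v
      # a fixed slot cannot break a maximum (effective bounds absorb fixed
      # excess) but the minima must still be reachable downstream
      short <- (nd + d_suf_next < d_min) | (nw + w_suf_next < w_min)
      if (any(short)) {
        prune_min[short] <<- prune_min[short] + 1
        return(FALSE)
      }
      track <- !(p %in% exempt_pos)
      old_last <- meal_last_day[r]
      if (track) {
        meal_use[r] <<- meal_use[r] + 1L
        meal_last_day[r] <<- d
      }
      day_cnt[[d]] <<- nd
      week_cnt <<- nw
      drs <- meal_dish_rows[[r]]
      dish_use[drs] <<- dish_use[drs] + 1L
      ok <- try_pos(p + 1L)
      day_cnt[[d]] <<- day_cnt[[d]] - v
      week_cnt <<- week_cnt - v
      dish_use[drs] <<- dish_use[drs] - 1L
      if (track) {
        meal_use[r] <<- meal_use[r] - 1L
        meal_last_day[r] <<- old_last
      }
      return(ok)
    }
    cand <- slot_cands[[p]]
    rows <- cand_rows[[p]]
    sub <- cand_sub[[p]]
    dcnt <- day_cnt[[d]]
    # value ordering: prefer candidates that cover portions still owed to a
    # minimum, stable within the seeded shuffle
    owed <- pmax(0, w_min - week_cnt) + pmax(0, d_min - dcnt)
    if (length(cand) > 1) {
      # cover still-owed minima first; among equals, spare the nearly
      # exhausted maxima budgets
      tight <- (w_max_eff - week_cnt) <= 1
      need_sc <- any(owed > 0)
      need_pen <- any(tight)
      if (need_sc || need_pen) {
        sc <- if (need_sc) colSums(pmin(sub, owed)) else
          numeric(length(cand))
        pen <- if (need_pen) colSums(sub * tight) else
          numeric(length(cand))
        ord <- order(-sc, pen)
        cand <- cand[ord]
        rows <- rows[ord]
      }
    }
    for (ci in seq_along(cand)) {
      if (aborted) return(FALSE)
      r <- rows[ci]
      if (meal_use[r] >= 2L) next
      last <- meal_last_day[r]
      if (last == d - 1L || last == d) next
      drs <- meal_dish_rows[[r]]
      if (any(dish_use[drs] >= dish_cap)) next
      v <- MT[, r]
      nd <- dcnt + v
      over_d <- nd > d_max_eff[[d]]
      if (any(over_d)) {
        prune_max[over_d] <<- prune_max[over_d] + 1
        next
      }
      nw <- week_cnt + v
      over_w <- nw > w_max_eff
      if (any(over_w)) {
        prune_max[over_w] <<- prune_max[over_w] + 1
        next
      }
      # minima lookahead: can the rest of the day / week still reach them?
      short <- (nd + d_suf_next < d_min) | (nw + w_suf_next < w_min)
      if (any(short)) {
        prune_min[short] <<- prune_min[short] + 1
        next
      }
      nodes <<- nodes + 1L
      if (nodes > node_cap) {
        aborted <<- TRUE
        return(FALSE)
      }
      # commit
      assign[p] <<- cand[ci]
      meal_use[r] <<- meal_use[r] + 1L
      meal_last_day[r] <<- d
      dish_use[drs] <<- dish_use[drs] + 1L
      day_cnt[[d]] <<- nd
      week_cnt <<- nw
      if (try_pos(p + 1L)) return(TRUE)
      # undo
      assign[p] <<- NA_integer_
      meal_use[r] <<- meal_use[r] - 1L
      meal_last_day[r] <<- last
      dish_use[drs] <<- dish_use[drs] - 1L
      day_cnt[[d]] <<- dcnt
      week_cnt <<- week_cnt - v
    }
    FALSE
  }
  ok <- try_pos(1L)
  if (ok) {
    assign[!is.na(fixed_meal)] <- fixed_meal[!is.na(fixed_meal)]
    return(list(ok = TRUE, assign = assign, nodes = nodes))
  }
  # evidence: rule ids behind the most frequent prunes
  pr <- prune_max + prune_min
  names(pr) <- keys_u
  pr <- sort(pr[pr > 0], decreasing = TRUE)
  ev <- character(0)
  for (k in names(pr)) {
    for (ids in list(db$ids[k], wb$ids[k])) {
      if (!is.na(ids)) ev <- c(ev, ids)
    }
  }
  list(ok = FALSE, assign = assign, evidence = unique(ev), nodes = nodes,
       prune = pr, aborted = aborted)
}

#' Scale a child plan's ingredient portions to an adolescent age group
#'
#' Keeps the meal ids identical and reads each dish's ingredient list from
#' the requested age-group column (the dataset carries per-age-group gram
#' portions for every dish).
#'
#' @param plan A feasible child `weekly_plan`.
#' @param dataset A `meal_dataset`.
#' @param age_group Target group, one of [age_groups()].
#' @return Data frame with `day`, `slot`, `meal_id`, `dish_id`,
#'   `ingredient`, `grams`.
#' @export
scale_for_adolescent <- function(plan, dataset, age_group) {
  if (!isTRUE(plan$feasible)) stop("plan is not feasible", call. = FALSE)
  age_group <- match.arg(age_group, age_groups())
  col <- paste0("ingredients_", gsub("-", "_", age_group))
  if (!col %in% names(dataset$dishes)) {
    stop("dataset has no ingredient column for age group ", age_group,
         call. = FALSE)
  }
  out <- list()
  for (d in seq_along(plan$days)) {
    for (s in meal_types()) {
      sl <- plan$days[[d]]$slots[[s]]
      if (is.null(sl) || is.na(sl$meal_id)) next
      r <- meal_row(dataset, sl$meal_id)
      for (dish_id in dataset$meal_dish_ids[[r]]) {
        dr <- match(dish_id, dataset$dishes$id)
        cell <- dataset$dishes[[col]][dr]
        if (is.na(cell) || !nzchar(cell)) {
          stop("dish ", dish_id, " has no ingredient portions for age group ",
               age_group, call. = FALSE)
        }
        ing <- parse_ingredients(cell)
        out[[length(out) + 1L]] <- data.frame(
          day = d, slot = s, meal_id = sl$meal_id, dish_id = dish_id,
          ingredient = ing$name, grams = ing$grams,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

parse_ingredients <- function(cell) {
  parts <- strsplit(cell, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  kv <- strsplit(parts, "=", fixed = TRUE)
  grams <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  if (any(is.na(grams)) || any(grams <= 0)) {
    stop("malformed ingredient cell: ", cell, call. = FALSE)
  }
  data.frame(name = vapply(kv, `[`, character(1), 1), grams = grams,
             stringsAsFactors = FALSE)
}
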