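# Adult family recommender: filter the meal pool, fix the children's shared
# meals (7 dinners, 2 weekend lunches), sample daily combinations, score
# them against the user's daily energy requirement, and assemble a week that
# satisfies the Mediterranean-diet diversity rules.

#' Candidate meal pools for an adult
#'
#' Filters the dataset to adult-audience meals of the profile's country and
#' the requested season, removing dairy-flagged meals for milk-allergic
#' users, and splits the result by slot type.
#'
#' @param dataset A `meal_dataset`.
#' @param profile An [adult_profile()].
#' @param season One of [seasons()].
#' @return Named list (one integer vector of meal ids per slot type).
#' @export
filter_meals <- function(dataset, profile, season) {
  pools <- lapply(stats::setNames(meal_types(), meal_types()), function(tp)
    candidate_meals(dataset, type = tp, country = profile$country,
                    season = season, audience = "adult",
                    milk_allergy = profile$milk_allergy))
  empty <- names(pools)[lengths(pools) == 0]
  if (length(empty)) {
    stop("empty adult candidate pool for slot type(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  pools
}

#' Extract the fixed family meals from a child plan
#'
#' The adult plan shares nine meals with the child plan: the seven daily
#' dinners and the two weekend lunches. Weekday lunches are not shared
#' (children eat those at school).
#'
#' @param child_plan A feasible child `weekly_plan`.
#' @return List with `dinners` (length 7) and `weekend_lunches` (Sat, Sun).
#' @export
fixed_child_meals <- function(child_plan) {
  if (!isTRUE(child_plan$feasible)) {
    stop("child plan is not feasible", call. = FALSE)
  }
  dinners <- vapply(child_plan$days, function(day) {
    id <- day$slots$dinner$meal_id
    if (is.null(id)) NA_integer_ else as.integer(id)
  }, integer(1))
  lunches <- vapply(child_plan$days[6:7], function(day) {
    id <- day$slots$lunch$meal_id
    if (is.null(id)) NA_integer_ else as.integer(id)
  }, integer(1))
  if (anyNA(dinners) || anyNA(lunches)) {
    stop("child plan is missing a dinner or weekend lunch", call. = FALSE)
  }
  list(dinners = dinners, weekend_lunches = lunches)
}

#' Score one daily plan against a user's energy requirement
#'
#' The daily nutritional plan score (DNPS) is the sum of four partial scores
#' in \[0, 1\]:
#' \itemize{
#'   \item caloric score `cs = max(0, 1 - |kcal - DER| / (0.3 DER))`;
#'   \item protein score: 1 when protein energy (4 kcal/g) is within
#'     15–20\% of DER, else a linear ramp losing 1 per 10 percentage points;
#'   \item fat score: as above on 25–40\% of DER (9 kcal/g);
#'   \item fruit & vegetable score: 1 when the day has 5–10 fruit/vegetable
#'     servings, else a ramp losing 1 per 5 servings of deficit or excess.
#' }
#' The in-band targets are nutritional guidelines; the ramp widths are
#' package constants.
#'
#' @param meal_ids The day's 5 meal ids.
#' @param dataset A `meal_dataset`.
#' @param der Daily energy requirement in kcal.
#' @return A list (`score_breakdown`): `cs`, `ps`, `fs`, `fvs`, `dnps`,
#'   `kcal_total`, `protein_pct`, `fat_pct`, `fv_servings`.
#' @export
score_daily_plan <- function(meal_ids, dataset, der) {
  rows <- meal_row(dataset, meal_ids)
  kcal <- sum(dataset$meal_kcal[rows])
  if (anyNA(kcal)) stop("missing nutrition on a dish", call. = FALSE)
  protein_g <- sum(dataset$meal_protein[rows])
  fat_g <- sum(dataset$meal_fat[rows])
  fv <- sum(dataset$meal_matrix[rows, "fruit"] +
              dataset$meal_matrix[rows, "vegetables"])
  protein_pct <- 100 * 4 * protein_g / der
  fat_pct <- 100 * 9 * fat_g / der
  cs <- max(0, 1 - abs(kcal - der) / (0.3 * der))
  ps <- band_score(protein_pct, 15, 20, 10)
  fs <- band_score(fat_pct, 25, 40, 10)
  fvs <- band_score(fv, 5, 10, 5)
  structure(list(cs = cs, ps = ps, fs = fs, fvs = fvs,
                 dnps = cs + ps + fs + fvs, kcal_total = kcal,
                 protein_pct = protein_pct, fat_pct = fat_pct,
                 fv_servings = as.integer(fv)),
            class = "score_breakdown")
}

band_score <- function(x, lo, hi, ramp) {
  gap <- ifelse(x < lo, lo - x, ifelse(x > hi, x - hi, 0))
  pmax(0, 1 - gap / ramp)
}

#' Generate and rank daily candidate plans
#'
#' Builds `n` random daily meal combinations for one day (uniform sampling
#' with replacement from the free-slot pools, deduplicated; when the full
#' Cartesian product of the pools is no larger than `n` it is enumerated
#' exhaustively instead), pairs them with the fixed child meals, scores each
#' and sorts by DNPS (ties: closeness of calories to the DER, then the
#' meal-id tuple, for a deterministic order).
#'
#' On weekdays the dinner is fixed and breakfast, both snacks and lunch are
#' free; at weekends lunch and dinner are both fixed.
#'
#' @param pools Named pools from [filter_meals()].
#' @param fixed List from [fixed_child_meals()].
#' @param day Day index 1–7 (6–7 are the weekend).
#' @param dataset A `meal_dataset`.
#' @param der Daily energy requirement (kcal).
#' @param n Number of sampled combinations (default 100,000).
#' @param seed Integer seed.
#' @return A `daily_candidates` object: list with `day`, `slots` (matrix of
#'   meal ids, one row per candidate, columns the five slot types) and
#'   `scores` (data frame of the score breakdowns, same order).
#' @export
generate_daily_candidates <- function(pools, fixed, day, dataset, der,
                                      n = 100000L, seed = 1L) {
  weekend <- day >= 6L
  free <- if (weekend) c("breakfast", "morning_snack", "afternoon_snack")
  else c("breakfast", "morning_snack", "lunch", "afternoon_snack")
  fixed_slots <- list(dinner = fixed$dinners[day])
  if (weekend) fixed_slots$lunch <- fixed$weekend_lunches[day - 5L]
  sizes <- lengths(pools[free])
  if (any(sizes == 0)) {
    stop("empty pool for slot(s): ",
         paste(free[sizes == 0], collapse = ", "), call. = FALSE)
  }
  with_seed(seed + day, {
    if (prod(sizes) <= n) {
      grid <- as.matrix(expand.grid(pools[free], KEEP.OUT.ATTRS = FALSE))
    } else {
      grid <- matrix(vapply(free, function(s)
        sample(pools[[s]], n, replace = TRUE), integer(n)),
        nrow = n, dimnames = list(NULL, free))
      grid <- grid[!duplicated(grid), , drop = FALSE]
    }
    colnames(grid) <- free
    slots <- matrix(NA_integer_, nrow = nrow(grid), ncol = 5,
                    dimnames = list(NULL, meal_types()))
    slots[, free] <- grid
    for (s in names(fixed_slots)) slots[, s] <- fixed_slots[[s]]
    rows <- matrix(meal_row(dataset, as.vector(slots)), nrow = nrow(slots))
    kcal <- rowSums(matrix(dataset$meal_kcal[rows], nrow = nrow(slots)))
    protein <- rowSums(matrix(dataset$meal_protein[rows],
                              nrow = nrow(slots)))
    fat <- rowSums(matrix(dataset$meal_fat[rows], nrow = nrow(slots)))
    fv <- rowSums(matrix(dataset$meal_matrix[rows, "fruit"] +
                           dataset$meal_matrix[rows, "vegetables"],
                         nrow = nrow(slots)))
    protein_pct <- 100 * 4 * protein / der
    fat_pct <- 100 * 9 * fat / der
    cs <- pmax(0, 1 - abs(kcal - der) / (0.3 * der))
    ps <- band_score(protein_pct, 15, 20, 10)
    fs <- band_score(fat_pct, 25, 40, 10)
    fvs <- band_score(fv, 5, 10, 5)
    dnps <- cs + ps + fs + fvs
    ord <- do.call(order, c(list(-dnps, abs(kcal - der)),
                            lapply(seq_len(ncol(slots)),
                                   function(j) slots[, j])))
    structure(list(
      day = day,
      slots = slots[ord, , drop = FALSE],
      scores = data.frame(cs = cs, ps = ps, fs = fs, fvs = fvs,
                          dnps = dnps, kcal_total = kcal,
                          protein_pct = protein_pct, fat_pct = fat_pct,
                          fv_servings = fv)[ord, , drop = FALSE]),
      class = "daily_candidates")
  })
}

#' Assemble a Mediterranean-diet-compliant weekly plan from ranked daily
#' candidate lists
#'
#' Depth-first selection of one candidate per day, in rank order, with
#' incremental checking of the adult weekly rules; the first fully compliant
#' week is returned. Daily-rule-violating candidates can never take part in
#' a compliant week and are skipped — unless the violation is caused by the
#' fixed child meals alone, in which case no compliant week exists and the
#' best-ranked week is returned flagged `md_ok = FALSE` with its violations
#' (such weeks count as failures in validation).
#'
#' @param daily_lists List of 7 `daily_candidates` (from
#'   [generate_daily_candidates()]), each sorted by DNPS descending.
#' @param dataset A `meal_dataset`.
#' @param rules An [adult_rules()] table.
#' @param max_nodes Search budget; when exhausted the best-effort plan is
#'   returned flagged `md_ok = FALSE`.
#' @return A `family_weekly_plan`: list with `day_slots` (list of 7 named
#'   meal-id vectors), `scores` (per-day score rows), `md_ok`, `violations`.
#' @export
build_weekly_plan <- function(daily_lists, dataset, rules = adult_rules(),
                              max_nodes = 2e7) {
  n_days <- length(daily_lists)
  wk <- rules[rules$horizon == "week", , drop = FALSE]
  mm <- dataset$meal_matrix
  meal_cap <- attr(rules, "meal_repeat_max")

  # pairwise dish-overlap between meals, for the repeated-dish rule
  n_meals <- nrow(dataset$meals)
  dish_ids_all <- sort(unique(unlist(dataset$meal_dish_ids)))
  D01 <- matrix(0L, nrow = n_meals, ncol = length(dish_ids_all))
  for (i in seq_len(n_meals)) {
    D01[i, match(dataset$meal_dish_ids[[i]], dish_ids_all)] <- 1L
  }
  overlap <- tcrossprod(D01)

  day_ok <- vector("list", n_days)
  day_contrib <- vector("list", n_days)
  rows_list <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    slots <- daily_lists[[d]]$slots
    nr <- nrow(slots)
    rowsm <- matrix(meal_row(dataset, as.vector(slots)), nrow = nr)
    sum_key <- function(key, cols = 1:5) {
      rowSums(matrix(mm[rowsm[, cols], key], nrow = nr))
    }
    contrib <- vapply(wk$key, sum_key, numeric(nr))
    if (nr == 1L) contrib <- matrix(contrib, nrow = 1,
                                    dimnames = list(NULL, wk$key))
    dr <- rules[rules$horizon == "day", , drop = FALSE]
    ok <- rep(TRUE, nr)
    for (j in seq_len(nrow(dr))) {
      ok <- ok & sum_key(dr$key[j]) <= dr$max[j]
    }
    ld_cols <- match(c("lunch", "dinner"), colnames(slots))
    ldr <- rules[rules$horizon == "ld_day", , drop = FALSE]
    for (j in seq_len(nrow(ldr))) {
      ok <- ok & sum_key(ldr$key[j], ld_cols) <= ldr$max[j]
    }
    # repeated dishes: pairwise overlap across the day's 5 meals
    pairsum <- numeric(nr)
    for (a in 1:4) for (b in (a + 1):5) {
      pairsum <- pairsum + overlap[cbind(rowsm[, a], rowsm[, b])]
    }
    cap <- attr(rules, "dish_repeat_day_max")
    # pairsum > cap usually means too many repeats; the exact per-dish count
    # is only needed then (a dish shared by 3+ meals inflates pairsum)
    suspect <- which(pairsum > cap & ok)
    for (i in suspect) {
      tab <- table(unlist(dataset$meal_dish_ids[rowsm[i, ]]))
      ok[i] <- sum(tab > 1) <= cap
    }
    day_ok[[d]] <- ok
    day_contrib[[d]] <- contrib
    rows_list[[d]] <- rowsm
  }

  # a day with no daily-rule-compliant candidate means the fixed child meals
  # alone violate the rules: no compliant week exists
  usable <- lapply(seq_len(n_days), function(d) which(day_ok[[d]]))
  if (any(lengths(usable) == 0)) {
    return(finish_family_plan(rep(1L, n_days), daily_lists, dataset, rules,
                              FALSE))
  }
  # fail fast on unavoidable weekly excess: every candidate of a day embeds
  # the fixed child meals, so if even the per-day minimum contributions sum
  # beyond a weekly cap, no selection can comply
  lb <- Reduce(`+`, lapply(seq_len(n_days), function(d) {
    sub <- day_contrib[[d]][usable[[d]], , drop = FALSE]
    apply(sub, 2, min)
  }))
  if (any(lb > wk$max)) {
    return(finish_family_plan(rep(1L, n_days), daily_lists, dataset, rules,
                              FALSE))
  }

  nodes <- 0L
  node_budget <- 0L
  depth_cap <- 0L
  sel_idx <- integer(n_days)
  wcount <- numeric(nrow(wk))
  n_meals <- nrow(dataset$meals)
  meal_use <- integer(n_meals)
  meal_last <- rep(-9L, n_meals)

  dfs <- function(d) {
    if (d > n_days) return(TRUE)
    cand_idx <- usable_pass[[d]]
    if (length(cand_idx) > depth_cap) cand_idx <- cand_idx[1:depth_cap]
    # one vectorised weekly-cap filter per day entry; the whole listed set
    # is charged against the node budget (it is the work actually done)
    nodes <<- nodes + length(cand_idx)
    if (nodes > node_budget) return(FALSE)
    allowed <- wk$max - wcount
    sub <- day_contrib[[d]][cand_idx, , drop = FALSE]
    cand_idx <- cand_idx[rowSums(sub > rep(allowed, each = nrow(sub))) == 0]
    rowsm <- rows_list[[d]]
    for (i in cand_idx) {
      r5 <- rowsm[i, ]
      if (any(meal_use[r5] >= meal_cap) || any(meal_last[r5] == d - 1L)) {
        next
      }
      old_last <- meal_last[r5]
      meal_use[r5] <<- meal_use[r5] + 1L
      meal_last[r5] <<- d
      wcount <<- wcount + day_contrib[[d]][i, ]
      sel_idx[d] <<- i
      if (dfs(d + 1L)) return(TRUE)
      wcount <<- wcount - day_contrib[[d]][i, ]
      meal_use[r5] <<- meal_use[r5] - 1L
      meal_last[r5] <<- old_last
      if (nodes > node_budget) return(FALSE)
    }
    FALSE
  }
  # staged deepening over candidate rank: a compliant week usually exists
  # among the top-ranked candidates; widening only on failure avoids the
  # pathology of exhausting one day's whole list while the others sit on a
  # jointly blocking top choice. Very large ranked lists are only explored
  # down to rank 512 (small lists are enumerated in full, so exhaustive
  # verification on enumerable instances is unaffected). When the ordered
  # stages fail, extra passes re-explore the deepest stage in
  # deterministically perturbed, rank-biased orders: compliant weeks are
  # sparse near the very top but plentiful slightly deeper, and a different
  # traversal order reaches them within the same node budget.
  max_usable <- max(lengths(usable))
  depth_limit <- if (max_usable <= 2048L) max_usable else 512L
  passes <- list(list(depth = min(8L, depth_limit), perturb = 0L,
                      share = 0.05),
                 list(depth = min(64L, depth_limit), perturb = 0L,
                      share = 0.10),
                 list(depth = depth_limit, perturb = 1L, share = 0.10),
                 list(depth = depth_limit, perturb = 2L, share = 0.10),
                 list(depth = depth_limit, perturb = 0L, share = 0.65))
  found <- FALSE
  for (pass in passes) {
    depth_cap <- pass$depth
    if (pass$perturb == 0L) {
      usable_pass <- usable
    } else {
      usable_pass <- lapply(usable, function(uu) {
        uu <- uu[seq_len(min(depth_cap, length(uu)))]
        r <- seq_along(uu)
        key <- r * (1 + ((r * 2654435761 + pass$perturb * 7919) %%
                           1009) / 1009)
        uu[order(key)]
      })
    }
    node_budget <- nodes + max(5000L, as.integer(pass$share * max_nodes))
    wcount <- numeric(nrow(wk))
    meal_use <- integer(n_meals)
    meal_last <- rep(-9L, n_meals)
    if (dfs(1L)) {
      found <- TRUE
      break
    }
  }
  if (found) {
    # local improvement: try to lift every day's choice back up its ranked
    # list while keeping the whole week compliant, so that the returned
    # week is near-greedy-optimal whichever pass found the initial one
    for (sweep in 1:3) {
      improved <- FALSE
      for (d in seq_len(n_days)) {
        cur <- sel_idx[d]
        cur_rank <- match(cur, usable[[d]])
        if (is.na(cur_rank) || cur_rank == 1L) next
        others <- setdiff(seq_len(n_days), d)
        base <- Reduce(`+`, lapply(others, function(dd)
          day_contrib[[dd]][sel_idx[dd], ]))
        other_rows <- lapply(others, function(dd)
          rows_list[[dd]][sel_idx[dd], ])
        use_tab <- table(unlist(other_rows))
        for (jr in seq_len(cur_rank - 1L)) {
          j <- usable[[d]][jr]
          if (any(base + day_contrib[[d]][j, ] > wk$max)) next
          r5 <- rows_list[[d]][j, ]
          cnt <- use_tab[as.character(r5)]
          cnt[is.na(cnt)] <- 0L
          if (any(cnt + 1L > meal_cap)) next
          adj <- others[abs(others - d) == 1L]
          conflict <- FALSE
          for (dd in adj) {
            if (any(rows_list[[dd]][sel_idx[dd], ] %in% r5)) {
              conflict <- TRUE
              break
            }
          }
          if (conflict) next
          sel_idx[d] <- j
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    finish_family_plan(sel_idx, daily_lists, dataset, rules, TRUE)
  } else {
    finish_family_plan(rep(1L, n_days), daily_lists, dataset, rules, FALSE)
  }
}

finish_family_plan <- function(sel_idx, daily_lists, dataset, rules,
                               claimed_ok) {
  n_days <- length(daily_lists)
  day_slots <- lapply(seq_len(n_days), function(d) {
    ids <- daily_lists[[d]]$slots[sel_idx[d], ]
    as.list(stats::setNames(as.integer(ids), names(ids)))
  })
  viol <- adult_week_violations(day_slots, dataset, rules)
  scores <- do.call(rbind, lapply(seq_len(n_days), function(d)
    daily_lists[[d]]$scores[sel_idx[d], , drop = FALSE]))
  rownames(scores) <- weekday_names()[seq_len(n_days)]
  structure(list(day_slots = day_slots, scores = scores,
                 md_ok = claimed_ok && nrow(viol) == 0, violations = viol),
            class = "family_weekly_plan")
}

#' @export
print.family_weekly_plan <- function(x, ...) {
  cat("family_weekly_plan:", if (x$md_ok) "MD-compliant" else
    paste0("NOT compliant (", nrow(x$violations), " violation(s))"), "\n")
  cat("  mean DNPS:", round(mean(x$scores$dnps), 3), "\n")
  invisible(x)
}

#' Plan an adult's week around the child's shared meals
#'
#' Convenience pipeline: filter the meal pools, extract the fixed child
#' meals, generate and rank daily candidates for each day, and assemble the
#' weekly plan.
#'
#' @param dataset A `meal_dataset`.
#' @param profile An [adult_profile()].
#' @param child_plan Feasible child `weekly_plan` of the same family.
#' @param season One of [seasons()].
#' @param reference_year Year for age computation.
#' @param n Candidates sampled per day.
#' @param seed Integer seed.
#' @param rules Adult rule table.
#' @return A `family_weekly_plan` with the owner's `der` attached.
#' @export
plan_family_week <- function(dataset, profile, child_plan, season,
                             reference_year = 2025L, n = 100000L,
                             seed = 1L, rules = adult_rules()) {
  pools <- filter_meals(dataset, profile, season)
  fixed <- fixed_child_meals(child_plan)
  der <- energy_requirements(profile, reference_year)$der
  daily <- lapply(1:7, function(d)
    generate_daily_candidates(pools, fixed, d, dataset, der, n = n,
                              seed = seed))
  plan <- build_weekly_plan(daily, dataset, rules)
  plan$der <- der
  plan$owner <- profile$id
  plan$country <- profile$country
  plan
}
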