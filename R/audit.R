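# Compliance auditor. Deliberately a separate code path from the planners:
# it recounts portions from the delivered plans and re-evaluates every rule
# from scratch, so solver-vs-auditor agreement is a meaningful check.

#' Frequency-rule violations of a child plan, recomputed from scratch
#'
#' Counts the plan's daily and weekly portions with [count_portions()] and
#' evaluates them against a rule state. Used both by the compliance report
#' and as the independent check that solver output is rule-clean.
#'
#' @param plan A child `weekly_plan`.
#' @param dataset A `meal_dataset`.
#' @param rules A [child_rules()] table.
#' @param state A [rule_state()] or variant name; defaults to the state the
#'   plan was accepted under.
#' @param include_structural Also check meal/dish repetition limits
#'   (the intervention snack is exempt).
#' @return Data frame of violations as in [evaluate_rules()].
#' @export
child_plan_violations <- function(plan, dataset, rules = child_rules(),
                                  state = NULL,
                                  include_structural = TRUE) {
  if (is.null(state)) state <- plan_rule_state(plan, rules)
  n_days <- plan$n_days %||% 7L
  day_meals <- plan_day_meals(plan)[seq_len(n_days)]
  day_ledgers <- lapply(day_meals, count_portions, dataset = dataset,
                        horizon = "day")
  week_ledger <- count_portions(unlist(day_meals, use.names = FALSE),
                                dataset, "week")
  viol <- evaluate_rules(day_ledgers, week_ledger, rules, state,
                         milk_allergy = isTRUE(plan$owner$milk_allergy))
  if (include_structural) {
    snack_ids <- unique(unlist(plan_day_meals(
      plan, provenance = "program_snack"), use.names = FALSE))
    rv <- repetition_violations(
      day_meals, dataset,
      meal_repeat_max = attr(rules, "meal_repeat_max") %||% 2L,
      dish_repeat_max = attr(rules, "dish_repeat_max") %||% 3L,
      exempt_meals = snack_ids)
    if (nrow(rv)) {
      viol <- rbind(viol, data.frame(
        rule_id = rv$rule_id, horizon = "week", observed = rv$observed,
        min = NA_real_, max = NA_real_, direction = "above",
        stringsAsFactors = FALSE))
    }
  }
  viol
}

#' Violations attributable to generated meals only
#'
#' School-provided lunches cannot be altered; excess contributed solely by
#' them is accepted. A violation is charged to the planner only if removing
#' the school-provenance meals removes the violation direction "above", or
#' if it is a "below" violation (fixed meals only ever add portions).
#'
#' @inheritParams child_plan_violations
#' @return Data frame of violations not explained by fixed school lunches.
#' @export
generated_meal_violations <- function(plan, dataset, rules = child_rules(),
                                      state = NULL) {
  if (is.null(state)) state <- plan_rule_state(plan, rules)
  n_days <- plan$n_days %||% 7L
  all_viol <- child_plan_violations(plan, dataset, rules, state,
                                    include_structural = FALSE)
  if (nrow(all_viol) == 0) return(all_viol)
  own <- plan_day_meals(plan, provenance = c("generated", "cafeteria",
                                             "child_fixed",
                                             "program_snack"))[
                                               seq_len(n_days)]
  own_day <- lapply(own, count_portions, dataset = dataset, horizon = "day")
  own_week <- count_portions(unlist(own, use.names = FALSE), dataset,
                             "week")
  act <- active_rules(rules, state, isTRUE(plan$owner$milk_allergy))
  keep <- logical(nrow(all_viol))
  for (i in seq_len(nrow(all_viol))) {
    v <- all_viol[i, ]
    if (v$direction == "below") { keep[i] <- TRUE; next }
    key <- act$key[match(v$rule_id, act$id)]
    own_obs <- if (v$horizon == "week") own_week$counts[key] else
      own_day[[as.integer(v$horizon)]]$counts[key]
    # planner is at fault only if its own meals alone break the maximum
    keep[i] <- !is.na(v$max) && own_obs > v$max
  }
  all_viol[keep, , drop = FALSE]
}

#' Per-rule compliance report for child plans
#'
#' Reproduces the shape of the published validation tables: for every
#' frequency rule, country and variant, the number of nutritional plans
#' evaluated (daily plans for daily rules, weekly plans for weekly rules),
#' the number compliant and the percentage, plus the delta between the
#' preferred and less-restrictive variants. Dairy rules are skipped for
#' milk-allergic owners (the plant-based rules are audited instead, and only
#' for them), mirroring how the validation tables separate the two groups.
#'
#' @param plans List of child `weekly_plan`s.
#' @param dataset A `meal_dataset`.
#' @param rules A [child_rules()] table.
#' @return A `compliance_report` data frame: `rule_id`, `scope`, `country`,
#'   `variant`, `n`, `n_compliant`, `percent`, `delta` (less restrictive
#'   minus preferred, `NA` on the preferred rows and for fixed rules).
#' @export
audit_child_compliance <- function(plans, dataset, rules = child_rules()) {
  variants <- c("preferred", "less_restrictive")
  rows <- list()
  countries <- unique(vapply(plans, function(p) p$country, character(1)))
  for (ctry in c(countries, "Overall")) {
    sel <- if (ctry == "Overall") plans else
      Filter(function(p) p$country == ctry, plans)
    for (variant in variants) {
      tallies <- audit_tally(sel, dataset, rules, variant)
      for (i in seq_len(nrow(tallies))) {
        rows[[length(rows) + 1L]] <- data.frame(
          rule_id = tallies$rule_id[i], scope = tallies$scope[i],
          country = ctry, variant = variant, n = tallies$n[i],
          n_compliant = tallies$n_compliant[i],
          percent = if (tallies$n[i] > 0)
            100 * tallies$n_compliant[i] / tallies$n[i] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  rep <- do.call(rbind, rows)
  rep$delta <- NA_real_
  lr <- rep$variant == "less_restrictive"
  key <- paste(rep$rule_id, rep$country)
  pref_pct <- rep$percent[!lr][match(key[lr], key[!lr])]
  rep$delta[lr] <- rep$percent[lr] - pref_pct
  class(rep) <- c("compliance_report", "data.frame")
  rep
}

# count compliant daily/weekly NPs per rule for one variant
audit_tally <- function(plans, dataset, rules, variant) {
  act_all <- active_rules(rules, variant, milk_allergy = FALSE)
  act_all <- rbind(act_all,
                   active_rules(rules, variant, milk_allergy = TRUE))
  act_all <- act_all[!duplicated(act_all$id), , drop = FALSE]
  n <- stats::setNames(integer(nrow(act_all)), act_all$id)
  n_ok <- n
  for (p in plans) {
    allergy <- isTRUE(p$owner$milk_allergy)
    act <- active_rules(rules, variant, milk_allergy = allergy)
    n_days <- p$n_days %||% 7L
    day_meals <- plan_day_meals(p)[seq_len(n_days)]
    day_led <- lapply(day_meals, count_portions, dataset = dataset,
                      horizon = "day")
    week_led <- count_portions(unlist(day_meals, use.names = FALSE),
                               dataset, "week")
    for (i in seq_len(nrow(act))) {
      id <- act$id[i]; key <- act$key[i]
      lo <- act$min[i]; hi <- act$max[i]
      if (act$scope[i] == "weekly") {
        obs <- week_led$counts[key]
        n[id] <- n[id] + 1L
        n_ok[id] <- n_ok[id] +
          as.integer((is.na(lo) || obs >= lo) && (is.na(hi) || obs <= hi))
      } else {
        for (dl in day_led) {
          obs <- dl$counts[key]
          n[id] <- n[id] + 1L
          n_ok[id] <- n_ok[id] +
            as.integer((is.na(lo) || obs >= lo) && (is.na(hi) || obs <= hi))
        }
      }
    }
  }
  data.frame(rule_id = act_all$id, scope = act_all$scope,
             n = as.integer(n[act_all$id]),
             n_compliant = as.integer(n_ok[act_all$id]),
             stringsAsFactors = FALSE)
}

#' Adult accuracy report
#'
#' For every daily nutritional plan of the supplied family weekly plans,
#' computes the caloric agreement `100 (1 - |kcal - DER| / DER)` and whether
#' fat (25–40\% of DER), protein (15–20\% of DER) and fruit & vegetable
#' servings (5–10) fall within the guideline bands, then aggregates by
#' country and overall: mean caloric agreement and the percentage of daily
#' plans within each range. Both the mean-agreement and the
#' share-above-90\% readings of "caloric accuracy" are reported.
#'
#' @param plans List of `family_weekly_plan`s (each carrying `der` and
#'   `country`, as returned by [plan_family_week()]).
#' @param dataset A `meal_dataset`.
#' @param include_failed Include plans flagged `md_ok = FALSE` (default
#'   FALSE: failed plans are not eligible for validation).
#' @return An `adult_accuracy_report` data frame with one row per country
#'   plus `Overall`: `weekly_np`, `daily_np`, `mean_caloric_agreement`,
#'   `caloric_agreement_ge90_pct`, `fat_within_pct`, `protein_within_pct`,
#'   `fv_within_pct`.
#' @export
audit_adult_accuracy <- function(plans, dataset, include_failed = FALSE) {
  if (!include_failed) plans <- Filter(function(p) isTRUE(p$md_ok), plans)
  per_day <- list()
  for (p in plans) {
    if (is.null(p$der)) stop("plan carries no DER", call. = FALSE)
    for (d in 1:7) {
      ids <- unlist(p$day_slots[[d]], use.names = FALSE)
      br <- score_daily_plan(ids, dataset, p$der)
      per_day[[length(per_day) + 1L]] <- data.frame(
        country = p$country %||% "Unknown",
        agreement = 100 * (1 - abs(br$kcal_total - p$der) / p$der),
        fat_in = br$fat_pct >= 25 & br$fat_pct <= 40,
        protein_in = br$protein_pct >= 15 & br$protein_pct <= 20,
        fv_in = br$fv_servings >= 5 & br$fv_servings <= 10,
        stringsAsFactors = FALSE)
    }
  }
  if (length(per_day) == 0) {
    return(structure(data.frame(), class = c("adult_accuracy_report",
                                             "data.frame")))
  }
  df <- do.call(rbind, per_day)
  weekly_n <- table(vapply(plans, function(p) p$country %||% "Unknown",
                           character(1)))
  agg <- function(sub, label, wn) {
    data.frame(country = label, weekly_np = wn, daily_np = nrow(sub),
               mean_caloric_agreement = mean(sub$agreement),
               caloric_agreement_ge90_pct = 100 * mean(sub$agreement >= 90),
               fat_within_pct = 100 * mean(sub$fat_in),
               protein_within_pct = 100 * mean(sub$protein_in),
               fv_within_pct = 100 * mean(sub$fv_in),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(weekly_n), function(ct)
    agg(df[df$country == ct, , drop = FALSE], ct, as.integer(weekly_n[ct]))))
  out <- rbind(out, agg(df, "Overall", length(plans)))
  class(out) <- c("adult_accuracy_report", "data.frame")
  out
}

#' Write a report as CSV
#' @param report A report data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
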