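#' Physical activity levels
#'
#' The five fixed physical-activity multipliers accepted by the planner:
#' sedentary 1.2, lightly active 1.375, moderately active 1.55, very active
#' 1.725, extra active 1.9.
#'
#' @return Named numeric vector of the five levels.
#' @export
pal_levels <- function() {
  c(sedentary = 1.2, lightly_active = 1.375, moderately_active = 1.55,
    very_active = 1.725, extra_active = 1.9)
}

#' Construct an adult profile
#'
#' @param sex `"male"` or `"female"`.
#' @param birth_year Year of birth (only the year is collected).
#' @param height_m Height in metres (0.5–2.5).
#' @param weight_kg Weight in kg (20–300).
#' @param pal Physical-activity multiplier, one of [pal_levels()].
#' @param milk_allergy Logical, milk-protein allergy.
#' @param country `"Spain"` or `"Turkiye"`.
#' @param id Optional identifier.
#' @return An `adult_profile` object.
#' @export
adult_profile <- function(sex, birth_year, height_m, weight_kg, pal,
                          milk_allergy = FALSE, country = "Spain",
                          id = NA_character_) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(height_m > 0.5, height_m < 2.5, weight_kg > 20, weight_kg < 300)
  if (!isTRUE(any(abs(pal - pal_levels()) < 1e-9))) {
    stop("pal must be one of ", paste(pal_levels(), collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = id, sex = sex, birth_year = as.integer(birth_year),
                 height_m = height_m, weight_kg = weight_kg, pal = pal,
                 milk_allergy = isTRUE(milk_allergy),
                 country = norm_country(country)),
            class = "adult_profile")
}

#' Construct a child profile
#'
#' @param age_group One of `"3-6"`, `"7-12"`, `"13-15"`, `"16-18"`.
#' @param school School name, required when `school_lunch` is `TRUE`.
#' @param school_lunch Does the child eat school-provided lunches?
#' @param milk_allergy Logical.
#' @param snack Does the child receive the intervention snack (3x/week)?
#' @param country `"Spain"` or `"Turkiye"`.
#' @param id Optional identifier.
#' @return A `child_profile` object.
#' @export
child_profile <- function(age_group, school = NULL, school_lunch = FALSE,
                          milk_allergy = FALSE, snack = FALSE,
                          country = "Spain", id = NA_character_) {
  age_group <- match.arg(age_group, age_groups())
  if (isTRUE(school_lunch) && (is.null(school) || !nzchar(school))) {
    stop("school_lunch = TRUE requires a school name", call. = FALSE)
  }
  structure(list(id = id, age_group = age_group, school = school,
                 school_lunch = isTRUE(school_lunch),
                 milk_allergy = isTRUE(milk_allergy), snack = isTRUE(snack),
                 country = norm_country(country)),
            class = "child_profile")
}

#' Body mass index
#'
#' @param weight_kg Weight in kg (> 0).
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight_kg / height_m^2
}

#' Basal metabolic rate
#'
#' Mifflin-St Jeor by default:
#' \deqn{BMR = 10 w + 6.25 h_{cm} - 5\,age + (+5\ male\ |\ -161\ female)}
#' Harris-Benedict (revised) is available as an alternative equation.
#'
#' @param profile An `adult_profile`.
#' @param reference_year Year used to derive age from the profile's year of
#'   birth (age = reference_year - birth_year; must be >= 18).
#' @param equation `"mifflin"` (default) or `"harris_benedict"`.
#' @return BMR in kcal/day.
#' @export
compute_bmr <- function(profile, reference_year,
                        equation = c("mifflin", "harris_benedict")) {
  equation <- match.arg(equation)
  age <- reference_year - profile$birth_year
  if (age < 18) {
    stop("adult energy model requires age >= 18 (got ", age, ")",
         call. = FALSE)
  }
  h_cm <- profile$height_m * 100
  w <- profile$weight_kg
  if (equation == "mifflin") {
    10 * w + 6.25 * h_cm - 5 * age + if (profile$sex == "male") 5 else -161
  } else {
    if (profile$sex == "male") {
      88.362 + 13.397 * w + 4.799 * h_cm - 5.677 * age
    } else {
      447.593 + 9.247 * w + 3.098 * h_cm - 4.330 * age
    }
  }
}

#' Daily energy requirement
#'
#' DER = BMR x PAL, with PAL restricted to the five listed activity levels.
#'
#' @param bmr Basal metabolic rate in kcal/day.
#' @param pal One of [pal_levels()].
#' @return DER in kcal/day.
#' @export
compute_der <- function(bmr, pal) {
  if (!isTRUE(any(abs(pal - pal_levels()) < 1e-9))) {
    stop("pal must be one of ", paste(pal_levels(), collapse = ", "),
         call. = FALSE)
  }
  bmr * pal
}

#' Energy requirements for an adult profile
#'
#' Convenience wrapper returning age, BMI, BMR and DER together.
#'
#' @inheritParams compute_bmr
#' @return List with `age`, `bmi`, `bmr`, `der`.
#' @export
energy_requirements <- function(profile, reference_year,
                                equation = "mifflin") {
  bmr <- compute_bmr(profile, reference_year, equation)
  list(age = reference_year - profile$birth_year,
       bmi = compute_bmi(profile$weight_kg, profile$height_m),
       bmr = bmr, der = compute_der(bmr, profile$pal))
}

#' Read family profiles from JSON
#'
#' The profiles file is a JSON array of families, each with `family_id`,
#' `adults` and `children` arrays whose fields match [adult_profile()] and
#' [child_profile()].
#'
#' @param path JSON file.
#' @return List of families; each family has `family_id`, `adults` (list of
#'   `adult_profile`) and `children` (list of `child_profile`).
#' @export
read_profiles <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(fam) {
    list(
      family_id = fam$family_id,
      adults = lapply(fam$adults, function(a) {
        adult_profile(a$sex, a$birth_year, a$height_m, a$weight_kg, a$pal,
                      isTRUE(a$milk_allergy), a$country,
                      id = a$id %||% NA_character_)
      }),
      children = lapply(fam$children, function(ch) {
        child_profile(ch$age_group, ch$school, isTRUE(ch$school_lunch),
                      isTRUE(ch$milk_allergy), isTRUE(ch$snack), ch$country,
                      id = ch$id %||% NA_character_)
      })
    )
  })
}

#' Write family profiles to JSON
#' @param families List of families as returned by [read_profiles()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(families, path) {
  out <- lapply(families, function(fam) {
    list(family_id = fam$family_id,
         adults = lapply(fam$adults, unclass),
         children = lapply(fam$children, unclass))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
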