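#' Friedewald estimate of LDL cholesterol
#'
#' LDL = total cholesterol - HDL - triglycerides/5, all in mg/dL. The
#' estimate is only valid for triglycerides below 400 mg/dL (the standard
#' validity bound of the formula); above that, fasting chylomicrons make the
#' TG/5 approximation of VLDL cholesterol unreliable.
#'
#' Because the formula is linear, applying it to group means gives the group
#' mean of LDL.
#'
#' @param total_chol,hdl,tg Numeric vectors in mg/dL (recycled).
#' @param tg_limit Validity bound on triglycerides (mg/dL), default 400.
#' @param strict If `TRUE` (default) an out-of-validity triglyceride value is
#'   an error; if `FALSE`, it yields `NA` with a warning (batch use).
#' @return Numeric vector of LDL cholesterol, mg/dL.
#' @examples
#' friedewald_ldl(203.23, 60.01, 113.72)  # 120.48 (cohort means in, mean LDL out)
#' @export
friedewald_ldl <- function(total_chol, hdl, tg, tg_limit = 400, strict = TRUE) {
  n <- max(length(total_chol), length(hdl), length(tg))
  total_chol <- rep_len(as.double(total_chol), n)
  hdl <- rep_len(as.double(hdl), n)
  tg <- rep_len(as.double(tg), n)
  neg <- which(total_chol < 0 | hdl < 0 | tg < 0)
  if (length(neg) > 0) rlang::abort("lipid inputs must be non-negative")
  invalid <- !is.na(tg) & tg >= tg_limit
  if (any(invalid)) {
    if (strict) {
      rlang::abort(paste0("Friedewald invalid: triglycerides >= ", tg_limit,
                          " mg/dL (", sum(invalid), " value(s))"))
    }
    rlang::warn(paste0("Friedewald invalid for ", sum(invalid),
                       " record(s) with triglycerides >= ", tg_limit,
                       " mg/dL; returning NA"))
  }
  ldl <- total_chol - hdl - tg / 5
  ldl[invalid] <- NA_real_
  ldl
}

#' Weekly MET-minutes of physical activity
#'
#' Converts self-reported daily minutes and weekly frequency of walking,
#' moderate and vigorous activity into metabolic-equivalent minutes per week:
#' `MET-min/week = multiplier x min/day x days/week` per intensity category,
#' plus their total. Default multipliers (walking 3.3, moderate 4.0,
#' vigorous 8.0 MET) follow the standard convention of validated activity
#' questionnaires.
#'
#' @param walking_min,moderate_min,vigorous_min Minutes per day (>= 0).
#' @param walking_days,moderate_days,vigorous_days Days per week (0-7).
#' @param multipliers Named numeric vector with positive entries `walking`,
#'   `moderate`, `vigorous`.
#' @return A tibble with columns `walking`, `moderate`, `vigorous`, `total`
#'   (MET-minutes/week).
#' @examples
#' weekly_met_minutes(walking_min = 30, walking_days = 7)  # walking = 693
#' @export
weekly_met_minutes <- function(walking_min = 0, walking_days = 0,
                               moderate_min = 0, moderate_days = 0,
                               vigorous_min = 0, vigorous_days = 0,
                               multipliers = c(walking = 3.3, moderate = 4,
                                               vigorous = 8)) {
  if (any(multipliers <= 0) ||
      !all(c("walking", "moderate", "vigorous") %in% names(multipliers))) {
    rlang::abort("multipliers must be positive and named walking/moderate/vigorous")
  }
  n <- max(lengths(list(walking_min, walking_days, moderate_min, moderate_days,
                        vigorous_min, vigorous_days)))
  mins <- list(walking = rep_len(walking_min, n),
               moderate = rep_len(moderate_min, n),
               vigorous = rep_len(vigorous_min, n))
  days <- list(walking = rep_len(walking_days, n),
               moderate = rep_len(moderate_days, n),
               vigorous = rep_len(vigorous_days, n))
  for (cat in names(mins)) {
    if (any(mins[[cat]] < 0, na.rm = TRUE)) {
      rlang::abort(paste0("negative minutes for ", cat, " activity"))
    }
    if (any(days[[cat]] < 0 | days[[cat]] > 7, na.rm = TRUE)) {
      rlang::abort(paste0("days per week for ", cat, " must be within 0-7"))
    }
  }
  out <- tibble::tibble(
    walking = multipliers[["walking"]] * mins$walking * days$walking,
    moderate = multipliers[["moderate"]] * mins$moderate * days$moderate,
    vigorous = multipliers[["vigorous"]] * mins$vigorous * days$vigorous
  )
  out$total <- out$walking + out$moderate + out$vigorous
  out
}

#' ATP III metabolic syndrome assessment
#'
#' Evaluates the five ATP III criteria exactly as defined for this screening
#' use: (1) blood pressure >= 130/85 mmHg (systolic OR diastolic at
#' threshold), (2) triglycerides >= 150 mg/dL, (3) HDL < 40 (males) /
#' < 50 (females) mg/dL, (4) fasting glucose > 100 mg/dL, (5) waist
#' circumference > 102 (males) / > 88 (females) cm. Three or more criteria
#' give metabolic syndrome (`mes`), one or two give `preclinical`, none gives
#' `normal`.
#'
#' @param sbp,dbp Systolic/diastolic blood pressure, mmHg.
#' @param tg Triglycerides, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param glucose Fasting glucose, mg/dL.
#' @param waist Waist circumference, cm.
#' @param sex Character vector, `"male"` or `"female"`.
#' @return A tibble with logical columns `bp`, `tg`, `hdl`, `glucose`,
#'   `waist`, integer `count`, and factor `status`
#'   (normal/preclinical/mes).
#' @examples
#' assess_mes(135, 80, 160, 35, 95, 100, "male")  # 3 criteria -> mes
#' @export
assess_mes <- function(sbp, dbp, tg, hdl, glucose, waist, sex) {
  n <- max(lengths(list(sbp, dbp, tg, hdl, glucose, waist, sex)))
  sbp <- rep_len(as.double(sbp), n); dbp <- rep_len(as.double(dbp), n)
  tg <- rep_len(as.double(tg), n); hdl <- rep_len(as.double(hdl), n)
  glucose <- rep_len(as.double(glucose), n)
  waist <- rep_len(as.double(waist), n)
  sex <- rep_len(tolower(as.character(sex)), n)
  bad_sex <- setdiff(unique(sex[!is.na(sex)]), c("male", "female"))
  if (length(bad_sex) > 0) {
    rlang::abort(paste0("unknown sex value(s): ", paste(bad_sex, collapse = ", ")))
  }
  vals <- cbind(sbp, dbp, tg, hdl, glucose, waist)
  if (any(vals <= 0, na.rm = TRUE)) {
    rlang::abort("all clinical inputs must be positive")
  }
  crit <- tibble::tibble(
    bp = sbp >= 130 | dbp >= 85,
    tg = tg >= 150,
    hdl = ifelse(sex == "male", hdl < 40, hdl < 50),
    glucose = glucose > 100,
    waist = ifelse(sex == "male", waist > 102, waist > 88)
  )
  count <- rowSums(crit)
  status <- factor(
    dplyr::case_when(count == 0 ~ "normal",
                     count <= 2 ~ "preclinical",
                     TRUE ~ "mes"),
    levels = c("normal", "preclinical", "mes")
  )
  dplyr::mutate(crit, count = as.integer(count), status = status)
}

#' Add derived clinical columns to a cohort
#'
#' Convenience mutate that appends, per respondent, the Friedewald LDL
#' (`ldl`), weekly MET-minutes (`met_walk`, `met_mod`, `met_vig`,
#' `met_total`) and ATP III metabolic syndrome status (`mes_count`,
#' `mes_status`). Column names of the inputs are configurable; respondents
#' with triglycerides outside the Friedewald validity bound get `NA` LDL with
#' a warning rather than an error.
#'
#' @param data A cohort tibble containing the input columns.
#' @param cols Named character vector mapping roles to column names; defaults
#'   cover `total_chol`, `hdl`, `triglycerides`, `glucose`, `sbp`, `dbp`,
#'   `waist`, `sex`, `walking_min`, `walking_days`, `moderate_min`,
#'   `moderate_days`, `vigorous_min`, `vigorous_days`.
#' @param multipliers MET multipliers, see [weekly_met_minutes()].
#' @return `data` with the derived columns appended.
#' @export
add_derived_measures <- function(data,
                                 cols = c(total_chol = "total_chol", hdl = "hdl",
                                          triglycerides = "triglycerides",
                                          glucose = "glucose", sbp = "sbp",
                                          dbp = "dbp", waist = "waist",
                                          sex = "sex",
                                          walking_min = "walking_min",
                                          walking_days = "walking_days",
                                          moderate_min = "moderate_min",
                                          moderate_days = "moderate_days",
                                          vigorous_min = "vigorous_min",
                                          vigorous_days = "vigorous_days"),
                                 multipliers = c(walking = 3.3, moderate = 4,
                                                 vigorous = 8)) {
  need <- unname(cols[c("total_chol", "hdl", "triglycerides", "glucose",
                        "sbp", "dbp", "waist", "sex")])
  missing_c <- setdiff(need, names(data))
  if (length(missing_c) > 0) {
    rlang::abort(paste0("missing column(s): ", paste(missing_c, collapse = ", ")))
  }
  data$ldl <- friedewald_ldl(data[[cols[["total_chol"]]]],
                             data[[cols[["hdl"]]]],
                             data[[cols[["triglycerides"]]]], strict = FALSE)
  act_cols <- cols[c("walking_min", "walking_days", "moderate_min",
                     "moderate_days", "vigorous_min", "vigorous_days")]
  if (all(act_cols %in% names(data))) {
    met <- weekly_met_minutes(
      data[[act_cols[["walking_min"]]]], data[[act_cols[["walking_days"]]]],
      data[[act_cols[["moderate_min"]]]], data[[act_cols[["moderate_days"]]]],
      data[[act_cols[["vigorous_min"]]]], data[[act_cols[["vigorous_days"]]]],
      multipliers = multipliers
    )
    data$met_walk <- met$walking
    data$met_mod <- met$moderate
    data$met_vig <- met$vigorous
    data$met_total <- met$total
  }
  mes <- assess_mes(data[[cols[["sbp"]]]], data[[cols[["dbp"]]]],
                    data[[cols[["triglycerides"]]]], data[[cols[["hdl"]]]],
                    data[[cols[["glucose"]]]], data[[cols[["waist"]]]],
                    data[[cols[["sex"]]]])
  data$mes_count <- mes$count
  data$mes_status <- mes$status
  data
}
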