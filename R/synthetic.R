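#' Configuration for the synthetic questionnaire cohort
#'
#' Collects every knob of the generator with defaults that emulate a
#' workplace health-promotion survey of office workers: two independent
#' latent perception factors (stress, control) driving four ordinal
#' perception scales; three independent latent lifestyle factors (activity,
#' smoking, alcohol) driving nine lifestyle variables with a simple-structure
#' loading pattern; sex-differentiated biochemistry, blood pressure and
#' anthropometrics; right-skewed zero-inflated absenteeism correlated with
#' the stress factor; and an injected 5 + 1 outlier structure (five joint
#' heavy smoker-drinkers plus one extreme absentee reporting 300 lost
#' working days).
#'
#' @param n Number of respondents (default 683).
#' @param male_fraction Proportion of males (default 495/683).
#' @param perception_items Tibble with columns `item`, `latent`
#'   (`stress`/`control`), `loading`, `n_categories` for the ordinal
#'   perception scales.
#' @param lifestyle_items Tibble with columns `item`, `latent`
#'   (`activity`/`smoking`/`alcohol`), `loading`, `n_categories` (`NA` for
#'   numeric MET variables), `mean`, `sd` (numeric items only).
#' @param biochem_params Tibble with per-sex means/SDs of the clinical
#'   fields (columns `variable`, `male_mean`, `male_sd`, `female_mean`,
#'   `female_sd`).
#' @param marginal_probs Optional named list of category-probability vectors
#'   overriding the equal-probability thresholds of specific ordinal items
#'   (e.g. a 70% nonsmoker spike).
#' @param absenteeism List: `zero_inflation` (extra-zero probability),
#'   `nb_size`, `nb_mu` (negative-binomial dispersion and mean of lost
#'   working days), `copula_rho` (Gaussian-copula weight of the stress
#'   factor; the remainder loads on an idiosyncratic absenteeism factor).
#' @param typology_spec `NULL`, or a list with `centroids` (k x 6 matrix in
#'   the space stress/control/activity/smoking/alcohol/absenteeism) and
#'   `weights` (mixing proportions) planting cluster structure in the latent
#'   classification space.
#' @param outlier_spec `NULL` to disable, or a list with `n_absentee`,
#'   `absentee_days`, `n_lifestyle` and `lifestyle_shift` (named latent
#'   offsets for the heavy smoker-drinker group).
#' @param seed Default seed used by [generate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 683,
                          male_fraction = 495 / 683,
                          perception_items = default_perception_items(),
                          lifestyle_items = default_lifestyle_items(),
                          biochem_params = default_biochem_params(),
                          marginal_probs = NULL,
                          absenteeism = list(zero_inflation = 0.3,
                                             nb_size = 0.35, nb_mu = 8,
                                             copula_rho = 0.35),
                          typology_spec = NULL,
                          outlier_spec = default_outlier_spec(),
                          seed = NULL) {
  if (n < 1) rlang::abort("n must be positive")
  if (male_fraction < 0 || male_fraction > 1) {
    rlang::abort("male_fraction must be in [0, 1]")
  }
  if (any(abs(c(perception_items$loading, lifestyle_items$loading)) > 1,
          na.rm = TRUE)) {
    rlang::abort("item loadings must lie in [-1, 1]")
  }
  if (any(c(biochem_params$male_sd, biochem_params$female_sd) <= 0)) {
    rlang::abort("biochemistry SDs must be positive")
  }
  if (!is.null(typology_spec)) {
    if (!all(abs(sum(typology_spec$weights) - 1) < 1e-8)) {
      rlang::abort("typology mixing weights must sum to 1")
    }
    if (ncol(typology_spec$centroids) != 6) {
      rlang::abort("typology centroids must have 6 columns")
    }
  }
  structure(list(n = n, male_fraction = male_fraction,
                 perception_items = perception_items,
                 lifestyle_items = lifestyle_items,
                 biochem_params = biochem_params,
                 marginal_probs = marginal_probs,
                 absenteeism = absenteeism,
                 typology_spec = typology_spec,
                 outlier_spec = outlier_spec,
                 seed = seed),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_perception_items <- function() {
  tibble::tribble(
    ~item,            ~latent,    ~loading, ~n_categories,
    "four_sq",        "stress",   0.885,    7,
    "stress_scale",   "stress",   0.870,    7,
    "fatigue_scale",  "stress",   0.885,    7,
    "control_scale",  "control",  0.949,    7
  )
}

#' @rdname cohort_config
#' @export
default_lifestyle_items <- function() {
  tibble::tribble(
    ~item,             ~latent,     ~loading, ~n_categories, ~mean, ~sd,
    "smoking_habit",   "smoking",   0.961,    7,             NA,    NA,
    "intend_quit",     "smoking",   0.958,    4,             NA,    NA,
    "met_walk",        "activity",  0.571,    NA,            436.17, 451.37,
    "met_mod",         "activity",  0.710,    NA,            378.38, 445.24,
    "met_vig",         "activity",  0.773,    NA,            551.59, 822.88,
    "activity_freq",   "activity",  0.716,    7,             NA,    NA,
    "wine_beer",       "alcohol",   0.816,    7,             NA,    NA,
    "alcohol_spirits", "alcohol",   0.802,    4,             NA,    NA
  )
}

#' @rdname cohort_config
#' @export
default_biochem_params <- function() {
  tibble::tribble(
    ~variable,        ~male_mean, ~male_sd, ~female_mean, ~female_sd,
    "total_chol",        203.92,    38.76,      201.43,      36.07,
    "hdl",                56.68,    23.13,       68.79,      21.70,
    "triglycerides",     123.16,    74.44,       88.88,      53.91,
    "glucose",            91.89,    17.79,       85.34,      11.90,
    "sbp",               124.51,    10.17,      118.06,      12.50,
    "dbp",                79.44,     7.20,       76.15,       9.12,
    "heart_rate",         69.22,    10.15,       72.37,       9.70,
    "weight",             79.72,    11.57,       63.55,      11.43,
    "height",            176.02,     6.00,      164.78,       6.18,
    "waist",              93.76,    10.30,       81.63,      11.98
  )
}

#' @rdname cohort_config
#' @export
default_typology_spec <- function() {
  # seven typologies, each displaced along its defining classification
  # variable(s); sizes follow the shares typical of such cohorts (one
  # dominant "in-control" group, a small absenteeism group)
  centroids <- rbind(
    alcohol        = c(0,    0,    0,    0,   4,   0),
    smoking        = c(0,    0,   -1,    4,   0,   0),
    high_stress    = c(3.5, -1.5, -1.5,  0,   0,   0),
    activity       = c(-1.5, 0,    4,    0,   0,   0),
    high_control   = c(-0.5, 3,    0,    0,   0,   0),
    low_stress_ctl = c(-1.5, -2.5, 0,    0,   0,   0),
    absenteeism    = c(0,    0,   -1,    0,   0,   4.5)
  )
  colnames(centroids) <- c("stress", "control", "activity", "smoking",
                           "alcohol", "absent")
  list(centroids = centroids,
       weights = c(90, 98, 88, 57, 194, 130, 20) / 677)
}

#' @rdname cohort_config
#' @export
default_outlier_spec <- function() {
  list(n_absentee = 1, absentee_days = 300,
       n_lifestyle = 5,
       lifestyle_shift = c(alcohol = 8, smoking = 4.5, stress = 2.2,
                           absent = 1.5))
}

#' Generate a synthetic questionnaire cohort with ground truth
#'
#' Draws a full mixed-type cohort from a [cohort_config()]: latent factors
#' (optionally a planted cluster mixture), ordinal items by thresholding
#' loading-weighted latent Gaussians, numeric MET variables as truncated
#' linear transforms of the activity factor (with the weekly total as the
#' sum of its components), per-sex clinical fields, zero-inflated
#' negative-binomial absenteeism tied to the stress factor by a Gaussian
#' copula, and injected outlier rows. Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @return A list of class `generated_cohort` with elements `table`
#'   (validated cohort tibble with attached schema), `schema`, `truth`
#'   (tibble: `row_id`, the six latent factor values, `typology`, `outlier`,
#'   `outlier_group`) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  if (!inherits(config, "cohort_config")) rlang::abort("config must be a cohort_config")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- config$n

  # latent classification factors
  latent_names <- c("stress", "control", "activity", "smoking", "alcohol",
                    "absent")
  if (is.null(config$typology_spec)) {
    L <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, latent_names))
    typology <- rep(NA_integer_, n)
  } else {
    ts <- config$typology_spec
    k <- nrow(ts$centroids)
    typology <- sample.int(k, n, replace = TRUE, prob = ts$weights)
    L <- ts$centroids[typology, , drop = FALSE] + matrix(rnorm(n * 6), n, 6)
    dimnames(L) <- list(NULL, latent_names)
  }

  # outlier injection: override latent positions of designated rows
  outlier <- rep(FALSE, n)
  outlier_group <- rep(NA_character_, n)
  os <- config$outlier_spec
  days_override <- rep(NA_real_, n)
  if (!is.null(os) && (os$n_absentee + os$n_lifestyle) > 0) {
    rows <- sample.int(n, os$n_absentee + os$n_lifestyle)
    ab_rows <- head(rows, os$n_absentee)
    ls_rows <- utils::tail(rows, os$n_lifestyle)
    if (length(ab_rows) > 0) {
      L[ab_rows, "stress"] <- 3.3
      L[ab_rows, "activity"] <- -1.1
      L[ab_rows, "absent"] <- 6
      days_override[ab_rows] <- os$absentee_days
      outlier[ab_rows] <- TRUE
      outlier_group[ab_rows] <- "absentee"
    }
    if (length(ls_rows) > 0) {
      shift <- os$lifestyle_shift
      L[ls_rows, "alcohol"] <- shift[["alcohol"]] + rnorm(length(ls_rows), 0, 0.3)
      L[ls_rows, "smoking"] <- shift[["smoking"]] + rnorm(length(ls_rows), 0, 0.3)
      L[ls_rows, "stress"] <- shift[["stress"]] + rnorm(length(ls_rows), 0, 0.5)
      L[ls_rows, "absent"] <- shift[["absent"]] + rnorm(length(ls_rows), 0, 0.5)
      outlier[ls_rows] <- TRUE
      outlier_group[ls_rows] <- "lifestyle"
    }
  }

  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")

  # personal data, with marginal distributions typical of an office cohort
  work_category <- sample(c("blue_collar", "junior_white_collar",
                            "senior_white_collar", "manager"), n,
                          replace = TRUE, prob = c(0.037, 0.546, 0.375, 0.042))
  age_group <- sample(c("<35", "35-44", "45-54", ">54"), n, replace = TRUE,
                      prob = c(0.119, 0.280, 0.470, 0.132))
  illness <- sample(c("none", "functional", "organic"), n, replace = TRUE,
                    prob = c(0.633, 0.120, 0.247))

  # ordinal items: threshold loading-weighted latents plus noise
  make_ordinal <- function(latent, loading, n_cat, item) {
    y <- loading * L[, latent] + sqrt(max(0, 1 - loading^2)) * rnorm(n)
    probs <- config$marginal_probs[[item]]
    if (is.null(probs)) probs <- rep(1 / n_cat, n_cat)
    cuts <- stats::qnorm(cumsum(probs)[-n_cat])
    as.character(findInterval(y, cuts) + 1L)
  }
  items <- list()
  for (i in seq_len(nrow(config$perception_items))) {
    it <- config$perception_items[i, ]
    items[[it$item]] <- make_ordinal(it$latent, it$loading, it$n_categories,
                                     it$item)
  }
  met <- list()
  for (i in seq_len(nrow(config$lifestyle_items))) {
    it <- config$lifestyle_items[i, ]
    if (is.na(it$n_categories)) {
      y <- it$loading * L[, it$latent] +
        sqrt(max(0, 1 - it$loading^2)) * rnorm(n)
      met[[it$item]] <- pmax(0, it$mean + it$sd * y)
    } else {
      items[[it$item]] <- make_ordinal(it$latent, it$loading,
                                       it$n_categories, it$item)
    }
  }
  met_total <- Reduce(`+`, met)

  # per-sex clinical fields, clipped to plausibility bounds
  ranges <- default_plausible_ranges()
  biochem <- purrr::pmap(config$biochem_params,
                         function(variable, male_mean, male_sd,
                                  female_mean, female_sd) {
    mu <- ifelse(sex == "male", male_mean, female_mean)
    s <- ifelse(sex == "male", male_sd, female_sd)
    x <- rnorm(n, mu, s)
    ri <- match(variable, ranges$name)
    if (!is.na(ri)) {
      x <- pmin(pmax(x, ranges$range_lo[ri]), ranges$range_hi[ri])
    }
    x
  })
  names(biochem) <- config$biochem_params$variable

  # absenteeism: zero-inflated negative binomial, monotone in a copula score
  # mixing the stress factor with an idiosyncratic absenteeism factor
  ap <- config$absenteeism
  eta <- ap$copula_rho * L[, "stress"] +
    sqrt(max(0, 1 - ap$copula_rho^2)) * L[, "absent"]
  u <- pnorm(eta)  # eta is standard normal when latents are unstructured
  pi0 <- ap$zero_inflation
  lost_days <- numeric(n)
  pos <- u > pi0
  lost_days[pos] <- qnbinom(pmin((u[pos] - pi0) / (1 - pi0), 1 - 1e-12),
                            size = ap$nb_size, mu = ap$nb_mu)
  lost_days[!is.na(days_override)] <- days_override[!is.na(days_override)]

  table <- tibble::tibble(
    row_id = seq_len(n),
    sex = sex, work_category = work_category, age_group = age_group,
    illness = illness,
    !!!items,
    met_walk = met$met_walk, met_mod = met$met_mod, met_vig = met$met_vig,
    met_total = met_total,
    !!!biochem,
    lost_days = as.double(lost_days)
  )

  schema <- ht_synthetic_schema(config)
  truth <- dplyr::bind_cols(
    tibble::tibble(row_id = seq_len(n)),
    tibble::as_tibble(L),
    tibble::tibble(typology = typology, outlier = outlier,
                   outlier_group = outlier_group)
  )
  structure(list(table = as_cohort(table, schema), schema = schema,
                 truth = truth, config = config),
            class = "generated_cohort")
}

ht_synthetic_schema <- function(config) {
  ranges <- default_plausible_ranges()
  ord_items <- dplyr::bind_rows(
    config$perception_items[c("item", "n_categories")],
    dplyr::filter(config$lifestyle_items,
                  !is.na(.data$n_categories))[c("item", "n_categories")]
  )
  specs <- list(
    cohort_schema("sex", "nominal", list(c("male", "female"))),
    cohort_schema("work_category", "nominal",
                  list(c("blue_collar", "junior_white_collar",
                         "senior_white_collar", "manager"))),
    cohort_schema("age_group", "ordinal",
                  list(c("<35", "35-44", "45-54", ">54"))),
    cohort_schema("illness", "nominal",
                  list(c("none", "functional", "organic")))
  )
  for (i in seq_len(nrow(ord_items))) {
    specs[[length(specs) + 1]] <-
      cohort_schema(ord_items$item[i], "ordinal",
                    list(as.character(seq_len(ord_items$n_categories[i]))))
  }
  for (v in c("met_walk", "met_mod", "met_vig", "met_total")) {
    specs[[length(specs) + 1]] <-
      cohort_schema(v, "numeric", units = "MET-min/week", range_lo = 0,
                    range_hi = Inf)
  }
  for (v in config$biochem_params$variable) {
    ri <- match(v, ranges$name)
    specs[[length(specs) + 1]] <- cohort_schema(
      v, "numeric",
      units = if (!is.na(ri)) ranges$units[ri] else NA_character_,
      range_lo = if (!is.na(ri)) ranges$range_lo[ri] else NA_real_,
      range_hi = if (!is.na(ri)) ranges$range_hi[ri] else NA_real_
    )
  }
  specs[[length(specs) + 1]] <-
    cohort_schema("lost_days", "numeric", units = "days/year",
                  range_lo = 0, range_hi = 366)
  out <- dplyr::bind_rows(specs)
  class(out) <- c("cohort_schema", class(out))
  out
}

#' Ground-truth classification variables of a generated cohort
#'
#' Convenience accessor returning the six latent classification variables
#' (stress, control, activity, smoking, alcohol, absenteeism) of a generated
#' cohort -- the noise-free counterparts of the indicators the pipeline
#' recovers. Useful for testing the clustering stage in isolation from the
#' optimal-scaling stage.
#'
#' @param generated A `generated_cohort`.
#' @return A tibble with `row_id` and the six latent columns.
#' @export
classification_truth <- function(generated) {
  stopifnot(inherits(generated, "generated_cohort"))
  dplyr::select(generated$truth, "row_id", "stress", "control", "activity",
                "smoking", "alcohol", absenteeism = "absent")
}

#' Recovery metrics of pipeline outputs against generator ground truth
#'
#' Given the outputs of the analysis pipeline on a generated cohort, returns
#' (a) for every latent factor, the best absolute correlation between the
#' factor and the supplied indicator columns, (b) the adjusted Rand index of
#' the recovered partition against the planted typologies, and (c) the
#' recall/precision of the detected outliers against the injected ones.
#' Metrics whose inputs are not supplied are omitted.
#'
#' @param generated A `generated_cohort`.
#' @param indicators Optional tibble/data frame of indicator scores with a
#'   `row_id` column (or in generation row order).
#' @param assignments Optional tibble with `row_id` and `cluster` columns
#'   (e.g. from `tidy()` of a typology result).
#' @param outlier_row_ids Optional vector of detected outlier `row_id`s.
#' @return A tibble with columns `metric`, `detail`, `value`.
#' @export
recovery_harness <- function(generated, indicators = NULL, assignments = NULL,
                             outlier_row_ids = NULL) {
  stopifnot(inherits(generated, "generated_cohort"))
  truth <- generated$truth
  out <- list()
  if (!is.null(indicators)) {
    ind <- tibble::as_tibble(indicators)
    if (!"row_id" %in% names(ind)) ind$row_id <- truth$row_id
    merged <- dplyr::inner_join(truth, ind, by = "row_id",
                                suffix = c("_truth", ""))
    if (nrow(merged) != nrow(ind)) rlang::abort("row_id mismatch with truth")
    ind_cols <- setdiff(names(ind), "row_id")
    for (lat in c("stress", "control", "activity", "smoking", "alcohol")) {
      lat_col <- if (lat %in% names(ind)) paste0(lat, "_truth") else lat
      cors <- purrr::map_dbl(ind_cols, function(cc) {
        abs(cor(merged[[lat_col]], merged[[cc]]))
      })
      out[[length(out) + 1]] <- tibble::tibble(
        metric = "indicator_cor", detail = lat,
        value = max(cors)
      )
    }
  }
  if (!is.null(assignments)) {
    asg <- tibble::as_tibble(assignments)
    merged <- dplyr::inner_join(truth[c("row_id", "typology")], asg,
                                by = "row_id")
    merged <- merged[!is.na(merged$typology), ]
    if (nrow(merged) == 0) rlang::abort("no planted typologies to compare against")
    out[[length(out) + 1]] <- tibble::tibble(
      metric = "ari", detail = NA_character_,
      value = mclust::adjustedRandIndex(merged$typology, merged$cluster)
    )
  }
  if (!is.null(outlier_row_ids)) {
    true_out <- truth$row_id[truth$outlier]
    hit <- length(intersect(outlier_row_ids, true_out))
    out[[length(out) + 1]] <- tibble::tibble(
      metric = c("outlier_recall", "outlier_precision"),
      detail = NA_character_,
      value = c(if (length(true_out) > 0) hit / length(true_out) else NA_real_,
                if (length(outlier_row_ids) > 0) {
                  hit / length(outlier_row_ids)
                } else {
                  NA_real_
                })
    )
  }
  dplyr::bind_rows(out)
}
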