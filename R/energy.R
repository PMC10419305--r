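# Energy balance: basal metabolic rate, total energy expenditure, calorie
# intake under external-factor pressure and dieting, and the monthly
# intake-minus-expenditure weight update.

#' Energy-expenditure coefficient tables
#'
#' Linear BMR coefficients by gender and age band,
#' `BMR = alpha + beta * height + gamma * weight` (kcal/day, height in
#' metres, weight in kg), plus the physical-activity-level multipliers.
#' The defaults are Henry-equation-style dietary reference values
#' (weight-and-height form, converted from MJ/day at 239 kcal/MJ) and the
#' conventional low/medium/high PAL multipliers 1.49/1.63/1.78.
#'
#' @param bmr_table data frame with columns `gender, age_min, age_max,
#'   alpha, beta, gamma` covering every (gender, age) the simulation can
#'   produce.
#' @param pal_table named numeric vector of PAL multipliers per category.
#' @return list of class `obesnet_energy_coeffs`.
#' @export
energy_coefficients <- function(bmr_table = default_bmr_table(),
                                pal_table = c(low = 1.49, medium = 1.63,
                                              high = 1.78)) {
  need <- c("gender", "age_min", "age_max", "alpha", "beta", "gamma")
  missing <- setdiff(need, names(bmr_table))
  if (length(missing) > 0) {
    stopf("energy coefficients: bmr_table missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (any(bmr_table$gamma <= 0)) {
    stopf("energy coefficients: gamma (kcal/day per kg) must be > 0")
  }
  if (any(pal_table < 1.0 | pal_table > 2.5)) {
    stopf("energy coefficients: PAL multipliers must lie in [1.0, 2.5]")
  }
  structure(list(bmr_table = bmr_table, pal_table = pal_table),
            class = "obesnet_energy_coeffs")
}

#' @rdname energy_coefficients
#' @export
default_bmr_table <- function() {
  # Henry weight+height equations, MJ/day -> kcal/day (x 239)
  mj <- function(w, h, c0) c(alpha = c0 * 239, beta = h * 239, gamma = w * 239)
  rows <- rbind(
    data.frame(gender = "male", age_min = 16, age_max = 18,
               t(mj(0.0651, 1.11, 1.25))),
    data.frame(gender = "male", age_min = 18, age_max = 30,
               t(mj(0.0600, 1.31, 0.473))),
    data.frame(gender = "male", age_min = 30, age_max = 60,
               t(mj(0.0476, 2.26, -0.574))),
    data.frame(gender = "male", age_min = 60, age_max = Inf,
               t(mj(0.0478, 2.26, -1.070))),
    data.frame(gender = "female", age_min = 16, age_max = 18,
               t(mj(0.0393, 1.04, 1.93))),
    data.frame(gender = "female", age_min = 18, age_max = 30,
               t(mj(0.0433, 2.57, -1.180))),
    data.frame(gender = "female", age_min = 30, age_max = 60,
               t(mj(0.0342, 2.10, -0.0486))),
    data.frame(gender = "female", age_min = 60, age_max = Inf,
               t(mj(0.0356, 1.76, 0.0448)))
  )
  rows
}

#' Read a BMR coefficient table from CSV
#'
#' Columns `gender, age_min, age_max, alpha, beta, gamma` (kcal/day units).
#'
#' @param path CSV file.
#' @return data frame suitable for [energy_coefficients()].
#' @export
read_bmr_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Row index of the BMR band for each agent; errors naming the missing band.
bmr_band_index <- function(agents, bmr_table) {
  idx <- integer(nrow(agents))
  for (g in unique(agents$gender)) {
    sel <- agents$gender == g
    rows <- which(bmr_table$gender == g)
    if (length(rows) == 0) stopf("bmr(): no coefficient bands for gender %s", g)
    rows <- rows[order(bmr_table$age_min[rows])]
    j <- findInterval(agents$age[sel], bmr_table$age_min[rows])
    bad <- j == 0 | agents$age[sel] >= bmr_table$age_max[rows][pmax(j, 1)]
    if (any(bad)) {
      stopf("bmr(): no coefficient band for gender %s, age %.1f",
            g, agents$age[sel][bad][1])
    }
    idx[sel] <- rows[j]
  }
  idx
}

#' Basal metabolic rate
#'
#' `BMR = alpha + beta * height + gamma * weight` with the coefficients of
#' the agent's gender and age band.
#'
#' @param agents agent data frame.
#' @param coeffs [energy_coefficients()].
#' @return kcal/day vector.
#' @export
bmr <- function(agents, coeffs) {
  tb <- coeffs$bmr_table
  j <- bmr_band_index(agents, tb)
  tb$alpha[j] + tb$beta[j] * agents$height + tb$gamma[j] * agents$weight
}

#' Total energy expenditure
#'
#' `TEE = PAL x BMR`, with the multiplier looked up from the agent's
#' physical-activity category.
#'
#' @inheritParams bmr
#' @return kcal/day vector.
#' @export
tee <- function(agents, coeffs) {
  mult <- coeffs$pal_table[agents$pal]
  if (any(is.na(mult))) {
    stopf("tee(): unknown PAL category: %s",
          paste(unique(agents$pal[is.na(mult)]), collapse = ", "))
  }
  as.numeric(mult) * bmr(agents, coeffs)
}

#' External-factor (APCCC) series
#'
#' The national average per-capita calorie consumption proxy for the
#' external environment, one value per calendar year. Intake responds to
#' the deviation of the current year's value from the baseline year.
#'
#' @param years integer vector of calendar years (contiguous).
#' @param kcal_per_day APCCC values, each in (1000, 5000); recycled.
#' @param baseline_year year whose value anchors intake at TEE (default:
#'   first year).
#' @return list of class `obesnet_ef_series`.
#' @export
external_factor_series <- function(years, kcal_per_day = 3400,
                                   baseline_year = years[1]) {
  kcal <- rep_len(kcal_per_day, length(years))
  if (any(kcal <= 1000 | kcal >= 5000)) {
    stopf("external factor series: values must lie in (1000, 5000) kcal/day")
  }
  if (!all(diff(years) == 1)) {
    stopf("external factor series: years must be contiguous")
  }
  if (!baseline_year %in% years) {
    stopf("external factor series: baseline_year %d not in series", baseline_year)
  }
  structure(list(years = years, kcal = setNames(kcal, years),
                 baseline_year = baseline_year),
            class = "obesnet_ef_series")
}

apccc <- function(ef, year) {
  v <- ef$kcal[as.character(year)]
  if (any(is.na(v))) stopf("APCCC series has no value for year %s", year)
  as.numeric(v)
}

#' Read an APCCC series from CSV (columns `year, kcal_per_day`)
#'
#' @param path CSV file.
#' @param baseline_year optional baseline (default: first year).
#' @return an [external_factor_series()].
#' @export
read_apccc_csv <- function(path, baseline_year = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "kcal_per_day") %in% names(raw))) {
    stopf("APCCC CSV %s must have columns year, kcal_per_day", path)
  }
  external_factor_series(raw$year, raw$kcal_per_day,
                         baseline_year %||% raw$year[1])
}

#' Daily calorie intake
#'
#' In the NORMAL state intake is anchored at the agent's TEE plus the
#' external-factor response:
#' `TEE + theta_extFactor[gender, agegroup] * (APCCC(year) - APCCC(baseline))`.
#' While DIETING the agent applies the fractional restriction
#' `(1 - diet_restriction)` to the NORMAL intake with probability
#' `adherence_prob` each month, and lapses to the unrestricted value
#' otherwise — producing the cyclical loss/plateau pattern of real diets.
#'
#' Adherence draws consume the caller's RNG stream.
#'
#' @param agents agent data frame (the `state` column selects the regime).
#' @param year calendar year (must be covered by `ef`).
#' @param ef [external_factor_series()].
#' @param theta_extFactor 2 x 6 matrix (gender x age group) of kcal/day
#'   response per kcal/day of APCCC deviation.
#' @param coeffs [energy_coefficients()].
#' @param behaviour [behaviour_params()] (restriction and adherence).
#' @return kcal/day vector.
#' @export
intake <- function(agents, year, ef, theta_extFactor, coeffs, behaviour) {
  g <- match(agents$gender, GENDERS)
  a <- as.integer(age_group(agents$age))
  dev <- apccc(ef, year) - apccc(ef, ef$baseline_year)
  normal <- tee(agents, coeffs) + theta_extFactor[cbind(g, a)] * dev
  dieting <- agents$state == "DIETING"
  if (any(dieting)) {
    adhere <- runif(sum(dieting)) < behaviour$adherence_prob
    normal[dieting] <- normal[dieting] *
      ifelse(adhere, 1 - behaviour$diet_restriction, 1)
  }
  normal
}

#' Default external-factor response gains
#'
#' The calibrated APCCC response, split by gender and age group: the male
#' response declines with age and exceeds the female response at every age.
#'
#' @return 2 x 6 matrix (male/female x age groups).
#' @export
default_ext_factor <- function() {
  out <- rbind(male   = c(0.29, 0.31, 0.24, 0.256, 0.22, 0.22),
               female = c(0.20, 0.22, 0.22, 0.20, 0.21, 0.20))
  colnames(out) <- AGE_GROUPS
  out
}

#' Monthly weight update from energy balance
#'
#' `delta_weight_kg = (intake - tee) * 30.44 / 7700` (one model month is
#' 30.44 days; 7700 kcal per kg of body-weight change). Weight is clamped
#' so BMI stays inside (10, 80).
#'
#' @param agents agent data frame.
#' @param intake_kcal_day,tee_kcal_day kcal/day vectors.
#' @return agents with updated `weight`.
#' @export
weight_update <- function(agents, intake_kcal_day, tee_kcal_day) {
  dw <- (intake_kcal_day - tee_kcal_day) * DAYS_PER_MONTH / KCAL_PER_KG
  w <- agents$weight + dw
  h2 <- agents$height^2
  w <- pmin(pmax(w, 10.001 * h2), 79.999 * h2)
  agents$weight <- w
  agents
}
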