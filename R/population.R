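# Synthetic population generation and population-table I/O.
#
# The generator emulates the statistical shape of national health-survey
# individual records: an adult age pyramid (16-90), two genders, BMI normal
# within age x gender strata with means rising through mid-life, and
# gender-specific heights. "Balanced for age, gender and BMI" is realised as
# stratified sampling over age-group x gender x BMI-tertile cells.

#' Default population profile
#'
#' Distributional configuration consumed by [generate_population()]: the age
#' pyramid (probability per age group), gender split, per-stratum BMI mean/sd,
#' gender-specific height distributions, education probabilities, the
#' entrant BMI spread and the rule assigning physical-activity-level (PAL)
#' categories from BMI and age.
#'
#' The numeric defaults are chosen to look like the published adult BMI
#' aggregates for England in the 2000s: mean BMI rises from the mid-24s at
#' ages 16-20 to roughly 28 in late middle age and falls back slightly in
#' the oldest group, with a within-stratum spread of 4-5 BMI units.
#'
#' @param age_probs probabilities per age group (length 6, sums to 1).
#' @param gender_split probability that an agent is male.
#' @param bmi_mean,bmi_sd 2 x 6 matrices (rows male/female, columns age
#'   groups) of stratum BMI means and standard deviations.
#' @param height_mean,height_sd named vectors (`male`, `female`), metres.
#' @param entrant_bmi_sd BMI spread of 16-year-old entrants.
#' @param education_probs probabilities of education levels 1..5.
#' @return a list of class `obesnet_profile`.
#' @export
default_profile <- function(age_probs = rep(1 / 6, 6),
                            gender_split = 0.5,
                            bmi_mean = rbind(
                              male   = c(24.2, 25.8, 27.2, 27.9, 27.9, 26.8),
                              female = c(24.6, 26.0, 26.9, 27.6, 27.8, 26.5)
                            ),
                            bmi_sd = rbind(
                              male   = c(4.6, 4.4, 4.3, 4.2, 4.1, 3.9),
                              female = c(5.2, 5.0, 4.9, 4.8, 4.6, 4.4)
                            ),
                            height_mean = c(male = 1.75, female = 1.62),
                            height_sd = c(male = 0.07, female = 0.065),
                            entrant_bmi_sd = 3.5,
                            education_probs = c(0.10, 0.25, 0.30, 0.20, 0.15)) {
  profile <- list(
    age_probs = age_probs, gender_split = gender_split,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    height_mean = height_mean, height_sd = height_sd,
    entrant_bmi_sd = entrant_bmi_sd,
    education_probs = education_probs
  )
  class(profile) <- "obesnet_profile"
  validate_profile(profile)
  profile
}

validate_profile <- function(profile) {
  p <- profile
  if (length(p$age_probs) != 6 || any(p$age_probs < 0) ||
      abs(sum(p$age_probs) - 1) > 1e-8) {
    stopf("profile: age_probs must be 6 non-negative values summing to 1")
  }
  if (p$gender_split < 0 || p$gender_split > 1) {
    stopf("profile: gender_split must lie in [0, 1]")
  }
  for (nm in c("bmi_mean", "bmi_sd")) {
    m <- p[[nm]]
    if (!is.matrix(m) || !identical(dim(m), c(2L, 6L))) {
      stopf("profile: %s must be a 2 x 6 matrix (male/female x age groups)", nm)
    }
  }
  if (any(p$bmi_sd < 0)) stopf("profile: negative BMI standard deviation")
  if (any(p$height_sd < 0)) stopf("profile: negative height standard deviation")
  if (any(p$bmi_mean <= 10 | p$bmi_mean >= 80)) {
    stopf("profile: stratum BMI means must lie inside (10, 80)")
  }
  if (length(p$education_probs) != 5 || any(p$education_probs < 0) ||
      abs(sum(p$education_probs) - 1) > 1e-8) {
    stopf("profile: education_probs must be 5 non-negative values summing to 1")
  }
  invisible(profile)
}

# PAL category from BMI and age: one of three activity classes, lower
# activity for higher BMI and older age.
pal_category <- function(bmi, age) {
  out <- rep("medium", length(bmi))
  out[bmi < 25 & age < 45] <- "high"
  out[bmi >= 30 | age >= 65] <- "low"
  out
}

# Upper age bound used when drawing ages inside the open-ended 76+ group.
MAX_AGE <- 90

# Draw a within-tertile BMI value: u is uniform on the tertile of the normal
# distribution, giving stratified (balanced) coverage of the BMI range.
draw_bmi_tertile <- function(n, mean, sd, tertile) {
  u <- runif(n, (tertile - 1) / 3, tertile / 3)
  pmin(pmax(qnorm(u, mean, sd), 12), 65)
}

new_agents <- function(n) {
  data.frame(
    id = integer(n), age = numeric(n), gender = character(n),
    height = numeric(n), weight = numeric(n),
    education = integer(n), pal = character(n),
    pos_x = numeric(n), pos_y = numeric(n),
    intention = numeric(n), behaviour = numeric(n),
    state = rep("NORMAL", n), diet_months_remaining = integer(n),
    diet_start_weight = rep(NA_real_, n),
    success_score = numeric(n), alive = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic agent population
#'
#' Stratified over age-group x gender x BMI-tertile cells so that the
#' requested marginals are reproduced ("balanced for age, gender and BMI").
#' Positions are uniform on the `[0, Z]` square; behavioural stocks start at
#' zero and every agent starts in the NORMAL (non-dieting) state.
#'
#' @param n number of agents (>= 1).
#' @param year calendar start year (bookkeeping only).
#' @param seed integer seed; the same `(n, seed, profile)` always produces a
#'   byte-identical table.
#' @param profile a profile from [default_profile()].
#' @param Z side length of the square map that positions are drawn on.
#' @return data frame with one row per agent.
#' @export
#' @examples
#' pop <- generate_population(100, 2004, seed = 1)
#' table(pop$gender)
generate_population <- function(n, year = 2004, seed = 1,
                                profile = default_profile(), Z = 1) {
  if (n < 1) stopf("generate_population(): n must be >= 1")
  validate_profile(profile)
  with_seed(seed, {
    # largest-remainder allocation over 12 age x gender strata
    target <- outer(c(profile$gender_split, 1 - profile$gender_split),
                    profile$age_probs) * n
    counts <- floor(target)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- target - counts
      idx <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[idx] <- counts[idx] + 1
    }
    agents <- new_agents(n)
    row <- 1L
    for (gi in 1:2) {
      for (ai in 1:6) {
        m <- counts[gi, ai]
        if (m == 0) next
        rows <- row:(row + m - 1L)
        gender <- GENDERS[gi]
        lo <- AGE_BREAKS[ai]
        hi <- min(AGE_BREAKS[ai + 1], MAX_AGE)
        agents$age[rows] <- runif(m, lo, hi)
        agents$gender[rows] <- gender
        # BMI balanced across tertiles of the stratum distribution
        tert <- rep_len(1:3, m)
        agents$weight[rows] <- NA_real_ # placeholder until height drawn
        bmi <- draw_bmi_tertile(m, profile$bmi_mean[gi, ai],
                                profile$bmi_sd[gi, ai], tert)
        h <- pmax(rnorm(m, profile$height_mean[gender],
                        profile$height_sd[gender]), 1.3)
        agents$height[rows] <- h
        agents$weight[rows] <- bmi * h^2
        row <- row + m
      }
    }
    agents$id <- seq_len(n)
    agents$education <- sample.int(5, n, replace = TRUE,
                                   prob = profile$education_probs)
    agents$pal <- pal_category(bmi_of(agents), agents$age)
    agents$pos_x <- runif(n, 0, Z)
    agents$pos_y <- runif(n, 0, Z)
    attr(agents, "year") <- year
    attr(agents, "Z") <- Z
    agents
  })
}

#' Draw a 16-year-old entrant
#'
#' New agents join the simulated population at age 16 with BMI drawn around
#' the (scenario-dependent) adolescent entrant mean, and a fresh uniform
#' position on the map.
#'
#' @param year calendar year of entry.
#' @param entrant_bmi_mean mean entrant BMI, must lie in (12, 60).
#' @param profile population profile (supplies the entrant BMI spread,
#'   heights, education probabilities).
#' @param Z map side length.
#' @param seed optional integer seed; by default the draw consumes the
#'   caller's RNG stream (as inside the simulator).
#' @return single-row agent data frame (id 0; the simulator re-assigns ids).
#' @export
sample_entrant <- function(year, entrant_bmi_mean,
                           profile = default_profile(), Z = 1, seed = NULL) {
  if (entrant_bmi_mean <= 12 || entrant_bmi_mean >= 60) {
    stopf("sample_entrant(): entrant_bmi_mean must lie in (12, 60)")
  }
  draw <- function() {
    a <- new_agents(1L)
    a$id <- 0L
    a$age <- 16
    a$gender <- if (runif(1) < profile$gender_split) "male" else "female"
    a$height <- pmax(rnorm(1, profile$height_mean[a$gender],
                           profile$height_sd[a$gender]), 1.3)
    bmi <- rnorm(1, entrant_bmi_mean, profile$entrant_bmi_sd)
    bmi <- pmin(pmax(bmi, 12), 65)
    a$weight <- bmi * a$height^2
    a$education <- sample.int(5, 1, prob = profile$education_probs)
    a$pal <- pal_category(bmi, 16)
    a$pos_x <- runif(1, 0, Z)
    a$pos_y <- runif(1, 0, Z)
    a
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

POP_CSV_COLUMNS <- c("id", "age", "gender", "height_m", "weight_kg",
                     "education", "pal")

#' Read / write population tables
#'
#' Population CSVs carry the columns `id, age, gender, height_m, weight_kg,
#' education, pal` (UTF-8, header required). Reading checks the header and
#' reports malformed rows by line number; writing and re-reading a table is
#' the identity on those fields.
#'
#' @param path file path.
#' @return `read_population_csv()` returns an agent data frame (positions and
#'   behavioural stocks initialised to defaults; positions are assigned by
#'   the simulator).
#' @export
read_population_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(POP_CSV_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stopf("population CSV %s: missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) return(new_agents(0L))
  for (col in c("age", "height_m", "weight_kg")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stopf("population CSV %s: non-numeric '%s' at data row %d (file line %d)",
            path, col, bad[1], bad[1] + 1L)
    }
    raw[[col]] <- v
  }
  bad_gender <- which(!raw$gender %in% GENDERS)
  if (length(bad_gender) > 0) {
    stopf("population CSV %s: unknown gender at data row %d", path, bad_gender[1])
  }
  agents <- new_agents(nrow(raw))
  agents$id <- as.integer(raw$id)
  agents$age <- raw$age
  agents$gender <- raw$gender
  agents$height <- raw$height_m
  agents$weight <- raw$weight_kg
  agents$education <- as.integer(raw$education)
  agents$pal <- raw$pal
  agents$pos_x <- NA_real_
  agents$pos_y <- NA_real_
  agents
}

#' @param agents agent data frame.
#' @rdname read_population_csv
#' @export
write_population_csv <- function(agents, path) {
  out <- data.frame(
    id = agents$id, age = agents$age, gender = agents$gender,
    height_m = agents$height, weight_kg = agents$weight,
    education = agents$education, pal = agents$pal,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference-series CSV I/O
#'
#' Reference series (mean and median BMI by year x gender x age group) are
#' exchanged as CSVs with columns `year, gender, age_group, mean_bmi,
#' median_bmi`.
#'
#' @param path file path.
#' @param series reference-series data frame.
#' @export
read_reference_csv <- function(path) {
  cols <- c("year", "gender", "age_group", "mean_bmi", "median_bmi")
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    stopf("reference CSV %s: missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  raw[cols]
}

#' @rdname read_reference_csv
#' @export
write_reference_csv <- function(series, path) {
  write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
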