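#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif qnorm rgeom median sd cor setNames aggregate
#' @importFrom utils read.csv write.csv write.table head tail
NULL

# Age-group partition used throughout: 16-20, 21-30, 31-45, 46-60, 61-75, 76+.
AGE_BREAKS <- c(16, 21, 31, 46, 61, 76, Inf)
AGE_GROUPS <- c("16-20", "21-30", "31-45", "46-60", "61-75", "76+")
GENDERS <- c("male", "female")

# days per model month used by the energy-balance step
DAYS_PER_MONTH <- 30.44
# kcal per kg of body-weight change
KCAL_PER_KG <- 7700

#' Map ages to the six model age groups
#'
#' The simulation partitions the adult age range into six groups
#' (16-20, 21-30, 31-45, 46-60, 61-75, 76+); every agent belongs to
#' exactly one group.
#'
#' @param age numeric vector of ages in years (>= 16).
#' @return factor with levels `"16-20"`, `"21-30"`, `"31-45"`, `"46-60"`,
#'   `"61-75"`, `"76+"`.
#' @export
#' @examples
#' age_group(c(16, 20.9, 45, 80))
age_group <- function(age) {
  if (any(age < 16, na.rm = TRUE)) {
    stop("age_group(): ages below 16 are outside the model population", call. = FALSE)
  }
  cut(age, breaks = AGE_BREAKS, labels = AGE_GROUPS, right = FALSE)
}

#' Body mass index of an agent table
#'
#' @param agents agent data frame with `weight` (kg) and `height` (m) columns.
#' @return numeric vector, kg/m^2.
#' @export
bmi_of <- function(agents) agents$weight / agents$height^2

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All seeded operations go through this so
# that they are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive independent sub-stream seeds from a master seed, kept within the
# 32-bit integer range expected by set.seed().
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
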