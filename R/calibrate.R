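# SPSA calibration: the flattened parameter vector with bound transforms,
# the sum-of-squared-errors loss on mean/median BMI series, the
# simultaneous-perturbation descent, median-of-tail finalisation,
# replicated testing and the manual cascade split operation.

#' SPSA configuration
#'
#' Gain and perturbation schedules `a_k = a / (A + k + 1)^alpha_gain`,
#' `c_k = c / (k + 1)^gamma_gain`, with the standard coefficient choices
#' a = 0.16, A = 100, c = 0.1, alpha = 0.602, gamma = 0.101 and 3000
#' iterations per descent; finalisation takes the elementwise median of
#' the last `tail` iterates.
#'
#' @param a gain numerator.
#' @param A stability constant.
#' @param c perturbation numerator.
#' @param alpha_gain,gamma_gain schedule exponents in (0, 1\].
#' @param iterations descent length (>= tail).
#' @param tail finalisation window.
#' @param seed seed for the perturbation stream.
#' @param common_rn share the simulation seed between the two perturbed
#'   loss evaluations of each step (variance reduction); disable to use
#'   independent seeds.
#' @return list of class `obesnet_spsa_config`.
#' @export
spsa_config <- function(a = 0.16, A = 100, c = 0.1,
                        alpha_gain = 0.602, gamma_gain = 0.101,
                        iterations = 3000, tail = 100, seed = 1,
                        common_rn = TRUE) {
  if (a <= 0 || c <= 0) stopf("spsa: a and c must be > 0")
  if (alpha_gain <= 0 || alpha_gain > 1 || gamma_gain <= 0 || gamma_gain > 1) {
    stopf("spsa: gain exponents must lie in (0, 1]")
  }
  if (iterations < tail || tail < 1) {
    stopf("spsa: need iterations >= tail >= 1")
  }
  structure(list(a = a, A = A, c = c, alpha_gain = alpha_gain,
                 gamma_gain = gamma_gain, iterations = iterations,
                 tail = tail, seed = seed, common_rn = common_rn),
            class = "obesnet_spsa_config")
}

#' Gain and perturbation magnitudes at iteration k
#'
#' @param k iteration count (>= 0).
#' @param cfg [spsa_config()].
#' @return list with `a_k` and `c_k`.
#' @export
gain_sequences <- function(k, cfg = spsa_config()) {
  list(a_k = cfg$a / (cfg$A + k + 1)^cfg$alpha_gain,
       c_k = cfg$c / (k + 1)^cfg$gamma_gain)
}

#' Sum-of-squared-errors loss between two BMI series
#'
#' Sum over every (year, gender, age-group) cell of the squared error in
#' mean BMI plus the squared error in median BMI; mean and median cells
#' weight equally. Cells empty on either side are dropped.
#'
#' @param sim,ref reference-series data frames sharing shape.
#' @return non-negative scalar.
#' @export
sse_loss <- function(sim, ref) {
  m <- merge(sim, ref, by = c("year", "gender", "age_group"),
             suffixes = c("_sim", "_ref"))
  if (nrow(m) != nrow(ref)) {
    stopf("sse_loss(): simulated and reference series do not share shape")
  }
  ok <- stats::complete.cases(m[, c("mean_bmi_sim", "mean_bmi_ref",
                                    "median_bmi_sim", "median_bmi_ref")])
  sum((m$mean_bmi_sim[ok] - m$mean_bmi_ref[ok])^2 +
        (m$median_bmi_sim[ok] - m$median_bmi_ref[ok])^2)
}

# ---- parameter vector ------------------------------------------------------

pv_entry <- function(name, values, lower, upper, split = "global") {
  list(name = name, values = values, lower = lower, upper = upper,
       split = split)
}

#' Flattened calibratable parameter vector
#'
#' Collects every calibratable theta from a configuration into a flat,
#' named, bounded vector: the norms gains (2 x 6), the pbc and attitude
#' gains, the external-factor gains (2 x 6), the satisficing scale, the
#' activation lag, the mean diet time, and the network homophily/memory/
#' range parameters (trigger, the four gender-pair BMI weights, memory
#' gain, social range). Bounded values are optimised through a scaled
#' logit transform so perturbed evaluations always stay feasible.
#'
#' @param config [simulation_config()] supplying current values.
#' @return list of class `obesnet_pv`.
#' @export
parameter_vector <- function(config = simulation_config()) {
  b <- config$behaviour
  n <- config$network
  grid_names <- as.vector(outer(GENDERS, AGE_GROUPS, paste, sep = "."))
  grid_vals <- function(m) setNames(as.vector(m), grid_names)
  entries <- list(
    pv_entry("theta_norms", grid_vals(b$theta_norms), 0, 10, "both"),
    pv_entry("theta_pbc", c(value = b$theta_pbc), 0, 5),
    pv_entry("theta_attitude", c(value = b$theta_attitude), 0, 5),
    pv_entry("theta_extFactor", grid_vals(config$theta_extFactor), 0, 1, "both"),
    pv_entry("theta_sv", c(value = b$theta_sv), 0, 5),
    pv_entry("theta_lag", c(value = b$theta_lag), 0, 6),
    pv_entry("theta_dietTime", c(value = b$theta_dietTime), 1, 12),
    pv_entry("theta_trigger", c(value = n$theta_trigger), 0.01, 10),
    pv_entry("theta_bmiadj", n$theta_bmiadj, 0, 5, "pair"),
    pv_entry("theta_mem", c(value = n$theta_mem), 0, 5),
    pv_entry("theta_range", c(value = n$Ra), 1e-3, 1.5 * n$Z)
  )
  names(entries) <- vapply(entries, `[[`, "", "name")
  structure(list(entries = entries), class = "obesnet_pv")
}

pv_flat_names <- function(pv) {
  unlist(lapply(pv$entries, function(e) paste(e$name, names(e$values), sep = ":")),
         use.names = FALSE)
}

#' @param pv an `obesnet_pv`.
#' @rdname parameter_vector
#' @export
pv_values <- function(pv) {
  setNames(unlist(lapply(pv$entries, `[[`, "values"), use.names = FALSE),
           pv_flat_names(pv))
}

#' Pack / unpack the parameter vector through its bound transform
#'
#' `pv_pack()` maps the bounded values to unconstrained space through a
#' scaled logit (clipping a hair inside the bounds); `pv_unpack()` is its
#' inverse. SPSA operates entirely in the unconstrained space so that
#' perturbed evaluations always stay feasible.
#'
#' @param pv an `obesnet_pv`.
#' @param u named numeric vector in unconstrained space.
#' @return `pv_pack()`: a named numeric vector; `pv_unpack()`: an
#'   `obesnet_pv` with updated values.
#' @export
pv_pack <- function(pv) {
  out <- numeric(0)
  for (e in pv$entries) {
    z <- (e$values - e$lower) / (e$upper - e$lower)
    z <- pmin(pmax(z, 1e-6), 1 - 1e-6)
    out <- c(out, stats::qlogis(z))
  }
  setNames(out, pv_flat_names(pv))
}

#' @rdname pv_pack
#' @export
pv_unpack <- function(pv, u) {
  nm <- pv_flat_names(pv)
  if (length(u) != length(nm)) {
    stopf("pv_unpack(): expected %d values, got %d", length(nm), length(u))
  }
  pos <- 1L
  for (i in seq_along(pv$entries)) {
    e <- pv$entries[[i]]
    k <- length(e$values)
    z <- stats::plogis(u[pos:(pos + k - 1L)])
    pv$entries[[i]]$values <- setNames(e$lower + z * (e$upper - e$lower),
                                       names(e$values))
    pos <- pos + k
  }
  pv
}

# Expand an entry's values to a full 2 x 6 (gender x age-group) matrix,
# whatever its split level.
pv_entry_grid <- function(e) {
  v <- e$values
  out <- matrix(NA_real_, 2, 6, dimnames = list(GENDERS, AGE_GROUPS))
  switch(e$split,
    global = {out[, ] <- v[[1]]},
    gender = {out["male", ] <- v[["male"]]; out["female", ] <- v[["female"]]},
    age_group = {for (a in AGE_GROUPS) out[, a] <- v[[a]]},
    both = {
      for (g in GENDERS) for (a in AGE_GROUPS)
        out[g, a] <- v[[paste(g, a, sep = ".")]]
    },
    stopf("cannot grid-expand split level '%s'", e$split))
  out
}

#' Write a parameter vector back into a configuration
#'
#' The inverse of [parameter_vector()]: structured components are rebuilt
#' from the (possibly split) flat entries. The activation lag is rounded
#' to whole months.
#'
#' @param config [simulation_config()].
#' @param pv an `obesnet_pv`.
#' @return updated configuration.
#' @export
apply_parameter_vector <- function(config, pv) {
  e <- pv$entries
  scalar_or_grid <- function(en) {
    if (en$split == "global") unname(en$values[[1]]) else pv_entry_grid(en)
  }
  config$behaviour$theta_norms <- pv_entry_grid(e$theta_norms)
  config$behaviour$theta_pbc <- scalar_or_grid(e$theta_pbc)
  config$behaviour$theta_attitude <- scalar_or_grid(e$theta_attitude)
  config$theta_extFactor <- pv_entry_grid(e$theta_extFactor)
  config$behaviour$theta_sv <- scalar_or_grid(e$theta_sv)
  config$behaviour$theta_lag <- as.integer(round(unname(e$theta_lag$values[[1]])))
  config$behaviour$theta_dietTime <- scalar_or_grid(e$theta_dietTime)
  config$network$theta_trigger <- unname(e$theta_trigger$values[[1]])
  config$network$theta_bmiadj <- e$theta_bmiadj$values
  config$network$theta_mem <- unname(e$theta_mem$values[[1]])
  config$network$Ra <- unname(e$theta_range$values[[1]])
  config
}

# Parameters whose per-(gender, age-group) split the simulator supports.
PV_SPLITTABLE <- c("theta_norms", "theta_pbc", "theta_attitude",
                   "theta_extFactor", "theta_sv", "theta_dietTime")

#' Split a parameter by gender, age group or both
#'
#' The manual cascade operation: replaces a scalar (or partially split)
#' parameter with per-category copies initialised to the parent values, so
#' the loss is unchanged immediately after the split. The structural
#' network parameters and the activation lag are global by construction
#' and cannot be split.
#'
#' @param pv an `obesnet_pv`.
#' @param name parameter name.
#' @param axis `"gender"`, `"age_group"` or `"both"`.
#' @return updated `obesnet_pv`.
#' @export
split_parameter <- function(pv, name, axis = c("gender", "age_group", "both")) {
  axis <- match.arg(axis)
  if (!name %in% names(pv$entries)) stopf("split_parameter(): unknown parameter '%s'", name)
  if (!name %in% PV_SPLITTABLE) {
    stopf("split_parameter(): '%s' is structural and cannot be split", name)
  }
  e <- pv$entries[[name]]
  has_gender <- e$split %in% c("gender", "both")
  has_age <- e$split %in% c("age_group", "both")
  want_gender <- axis %in% c("gender", "both")
  want_age <- axis %in% c("age_group", "both")
  if ((want_gender && has_gender) || (want_age && has_age)) {
    stopf("split_parameter(): '%s' is already split on axis '%s'", name, axis)
  }
  grid <- pv_entry_grid(e)
  new_split <- if ((has_gender || want_gender) && (has_age || want_age)) "both"
    else if (has_gender || want_gender) "gender" else "age_group"
  vals <- switch(new_split,
    gender = setNames(grid[, 1], GENDERS),
    age_group = setNames(grid[1, ], AGE_GROUPS),
    both = setNames(as.vector(grid),
                    as.vector(outer(GENDERS, AGE_GROUPS, paste, sep = "."))))
  pv$entries[[name]]$values <- vals
  pv$entries[[name]]$split <- new_split
  pv
}

# ---- descent ---------------------------------------------------------------

#' Build a simulation loss function for SPSA
#'
#' Returns `function(u, seed)` mapping an unbounded parameter vector to
#' the sum-of-squared-errors loss of a fresh simulation against the
#' reference series.
#'
#' @param config base [simulation_config()] (problem size, horizon,
#'   non-calibrated settings).
#' @param reference target reference-series data frame.
#' @param pv parameter-vector layout (defaults to the config's).
#' @return loss closure.
#' @export
make_sim_loss <- function(config, reference, pv = parameter_vector(config)) {
  function(u, seed) {
    cfg <- apply_parameter_vector(config, pv_unpack(pv, u))
    cfg$seed <- seed
    cfg$snapshot_every <- 0
    cfg$record_raw <- FALSE
    sse_loss(run_simulation(cfg)$series, reference)
  }
}

#' One SPSA iteration
#'
#' Draws a Rademacher (+1/-1) perturbation, evaluates the loss at
#' `theta +/- c_k * delta` and takes the estimated-gradient step
#' `theta - a_k * ghat`. A non-finite loss rejects the step, leaving
#' `theta` unchanged.
#'
#' Consumes the caller's RNG stream for the perturbation.
#'
#' @param theta named unbounded parameter values.
#' @param k iteration count (0-based).
#' @param loss_fn `function(u, seed)`.
#' @param cfg [spsa_config()].
#' @return list with `theta`, `loss_plus`, `loss_minus`, `ghat`,
#'   `rejected`.
#' @export
spsa_step <- function(theta, k, loss_fn, cfg = spsa_config()) {
  gk <- gain_sequences(k, cfg)
  delta <- sample(c(-1, 1), length(theta), replace = TRUE)
  seed_p <- derive_seed(cfg$seed, 2L * k + 1L)
  seed_m <- if (cfg$common_rn) seed_p else derive_seed(cfg$seed, 2L * k + 2L)
  lp <- loss_fn(theta + gk$c_k * delta, seed_p)
  lm <- loss_fn(theta - gk$c_k * delta, seed_m)
  if (!is.finite(lp) || !is.finite(lm)) {
    return(list(theta = theta, loss_plus = lp, loss_minus = lm,
                ghat = rep(NA_real_, length(theta)), rejected = TRUE))
  }
  ghat <- (lp - lm) / (2 * gk$c_k) * (1 / delta)
  list(theta = setNames(theta - gk$a_k * ghat, names(theta)),
       loss_plus = lp, loss_minus = lm, ghat = ghat, rejected = FALSE)
}

#' Run an SPSA descent
#'
#' Iterates [spsa_step()] `cfg$iterations` times from `theta0`; the final
#' estimate is the elementwise median of the last `cfg$tail` iterates
#' (taken in bounded space when a layout is supplied, damping the
#' stochastic wobble of individual iterations).
#'
#' @param theta0 named unbounded starting vector (e.g. `pv_pack(pv)`).
#' @param loss_fn `function(u, seed)`.
#' @param cfg [spsa_config()].
#' @param pv optional `obesnet_pv` layout; when given, the trajectory and
#'   the final estimate are also reported in bounded parameter space.
#' @return list with `trajectory` (data frame: k, loss, rejected, one
#'   column per parameter), `final` (named unbounded vector), and when
#'   `pv` is given `final_pv` / `final_values`.
#' @export
spsa_run <- function(theta0, loss_fn, cfg = spsa_config(), pv = NULL) {
  theta <- theta0
  p <- length(theta)
  iters <- cfg$iterations
  losses <- numeric(iters)
  rejected <- logical(iters)
  track <- matrix(NA_real_, iters, p,
                  dimnames = list(NULL, names(theta0)))
  with_seed(derive_seed(cfg$seed, 999983L), {
    for (k in seq_len(iters)) {
      st <- spsa_step(theta, k - 1L, loss_fn, cfg)
      theta <- st$theta
      losses[k] <- mean(c(st$loss_plus, st$loss_minus))
      rejected[k] <- st$rejected
      track[k, ] <- if (is.null(pv)) theta else
        pv_values(pv_unpack(pv, theta))
    }
  })
  tail_rows <- track[(iters - cfg$tail + 1L):iters, , drop = FALSE]
  final_bounded <- apply(tail_rows, 2, median)
  out <- list(
    trajectory = cbind(data.frame(k = seq_len(iters), loss = losses,
                                  rejected = rejected), as.data.frame(track)),
    final = theta
  )
  if (!is.null(pv)) {
    fin <- pv
    pos <- 1L
    for (i in seq_along(fin$entries)) {
      kk <- length(fin$entries[[i]]$values)
      fin$entries[[i]]$values <- setNames(
        final_bounded[pos:(pos + kk - 1L)], names(fin$entries[[i]]$values))
      pos <- pos + kk
    }
    out$final_pv <- fin
    out$final_values <- pv_values(fin)
    out$final <- pv_pack(fin)
  } else {
    out$final_values <- final_bounded
  }
  out$tail_loss_first <- median(losses[seq_len(cfg$tail)])
  out$tail_loss_last <- median(losses[(iters - cfg$tail + 1L):iters])
  out
}

#' Replicated testing of a calibrated parameter set
#'
#' Runs `n_reps` simulations with fresh random populations, pools the
#' per-agent BMI values cell by cell into one combined series, and
#' combines the per-replicate losses into a single representative value by
#' taking their median.
#'
#' @param config calibrated [simulation_config()].
#' @param reference reference series for the loss.
#' @param n_reps number of replicates (>= 1).
#' @param seed base seed; replicate r runs with a seed derived from it.
#' @return list with `losses`, `combined_loss`, `combined_series`.
#' @export
replicated_test <- function(config, reference, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stopf("replicated_test(): n_reps must be >= 1")
  losses <- numeric(n_reps)
  raws <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    cfg$record_raw <- TRUE
    cfg$snapshot_every <- 0
    res <- run_simulation(cfg)
    losses[r] <- sse_loss(res$series, reference)
    raws[[r]] <- res$raw
  }
  pooled <- do.call(rbind, raws)
  agg <- aggregate(bmi ~ year + gender + age_group, data = pooled,
                   FUN = function(x) c(mean = mean(x), median = median(x)))
  combined <- data.frame(year = agg$year, gender = agg$gender,
                         age_group = agg$age_group,
                         mean_bmi = agg$bmi[, "mean"],
                         median_bmi = agg$bmi[, "median"],
                         stringsAsFactors = FALSE)
  combined <- combined[order(combined$year, combined$gender,
                             match(combined$age_group, AGE_GROUPS)), ]
  rownames(combined) <- NULL
  list(losses = losses, combined_loss = median(losses),
       combined_series = combined)
}

#' Paired homophily ablation
#'
#' Evaluates the calibrated configuration against a reference twice per
#' seed — once as-is and once with all four gender-pair BMI-homophily
#' weights pinned to zero (homophily disabled) — and reports the paired
#' loss scores.
#'
#' @param config [simulation_config()].
#' @param reference reference series.
#' @param seeds integer vector of replicate seeds.
#' @return data frame `seed, loss_homophily, loss_no_homophily`.
#' @export
run_homophily_ablation <- function(config, reference, seeds = 1:5) {
  no_h <- config
  no_h$network$theta_bmiadj <- c(mm = 0, mf = 0, ff = 0, fm = 0)
  out <- data.frame(seed = seeds, loss_homophily = NA_real_,
                    loss_no_homophily = NA_real_)
  for (i in seq_along(seeds)) {
    for (variant in 1:2) {
      cfg <- if (variant == 1) config else no_h
      cfg$seed <- seeds[i]
      cfg$snapshot_every <- 0
      cfg$record_raw <- FALSE
      l <- sse_loss(run_simulation(cfg)$series, reference)
      if (variant == 1) out$loss_homophily[i] <- l else
        out$loss_no_homophily[i] <- l
    }
  }
  out
}
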