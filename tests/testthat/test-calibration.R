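test_that("gain sequences follow the power schedules exactly", {
  cfg <- spsa_config()
  g0 <- gain_sequences(0, cfg)
  expect_identical(g0$c_k, 0.1)                      # 0.1 / 1^0.101
  expect_equal(g0$a_k, 0.16 / 101^0.602)
  for (k in 0:10) {
    g <- gain_sequences(k, cfg)
    expect_equal(g$a_k, 0.16 / (100 + k + 1)^0.602, tolerance = 1e-15)
    expect_equal(g$c_k, 0.1 / (k + 1)^0.101, tolerance = 1e-15)
  }
  a_seq <- vapply(0:50, function(k) gain_sequences(k, cfg)$a_k, numeric(1))
  c_seq <- vapply(0:50, function(k) gain_sequences(k, cfg)$c_k, numeric(1))
  expect_true(all(diff(a_seq) < 0))
  expect_true(all(diff(c_seq) < 0))
})

test_that("the SSE loss sums squared mean and median errors per cell", {
  cfg <- simulation_config(n_initial = 40, horizon_months = 12, seed = 2)
  ref <- make_reference(cfg)
  expect_identical(sse_loss(ref, ref), 0)
  off <- ref
  off$mean_bmi[5] <- off$mean_bmi[5] + 2
  off$median_bmi[5] <- off$median_bmi[5] + 2
  expect_equal(sse_loss(off, ref), 8)
  shuffled <- off[sample(nrow(off)), ]
  expect_equal(sse_loss(shuffled, ref), 8)
  expect_error(sse_loss(ref[-1, ], ref), "shape")
})

test_that("spsa_step takes the simultaneous-perturbation gradient step", {
  cfg <- spsa_config(seed = 5)
  # constant loss: zero gradient estimate, theta unchanged
  theta <- c(a = 1, b = -2, c = 0.5)
  set.seed(1)
  st <- spsa_step(theta, 0, function(u, seed) 7, cfg)
  expect_identical(st$theta, theta)
  expect_false(st$rejected)

  # 1-d quadratic: the step moves toward the minimum for either delta sign
  for (s in 1:4) {
    set.seed(s)
    st <- spsa_step(c(x = 2), 0, function(u, seed) sum(u^2), cfg)
    expect_lt(abs(st$theta), 2)
  }

  # perturbations are Rademacher: components exactly +/- 1
  seen <- new.env(); seen$u <- list()
  probe <- function(u, seed) { seen$u[[length(seen$u) + 1]] <- u; 0 }
  theta0 <- c(p = 0.3, q = -1, r = 2, s = 0)
  set.seed(9)
  st <- spsa_step(theta0, 0, probe, cfg)
  c0 <- gain_sequences(0, cfg)$c_k
  delta <- (seen$u[[1]] - theta0) / c0
  expect_true(all(abs(abs(delta) - 1) < 1e-12))
  expect_equal(seen$u[[2]], theta0 - c0 * delta, tolerance = 1e-12)

  # non-finite loss rejects the step
  set.seed(2)
  st <- spsa_step(c(x = 1), 0, function(u, seed) NaN, cfg)
  expect_true(st$rejected)
  expect_identical(st$theta, c(x = 1))
})

test_that("spsa_run converges on a quadratic bowl and records the trajectory", {
  target <- c(1, -1, 0.5)
  loss <- function(u, seed) sum((u - target)^2)
  cfg <- spsa_config(iterations = 500, tail = 50, seed = 3)
  run <- spsa_run(c(x = 3, y = 3, z = 3), loss, cfg)
  expect_equal(nrow(run$trajectory), 500)
  err0 <- sqrt(sum((c(3, 3, 3) - target)^2))
  err1 <- sqrt(sum((run$final_values - target)^2))
  expect_lt(err1, 0.2 * err0)
  expect_lt(run$tail_loss_last, run$tail_loss_first)

  one <- spsa_run(c(x = 2), loss = function(u, seed) sum(u^2),
                  spsa_config(iterations = 1, tail = 1, seed = 1))
  expect_equal(nrow(one$trajectory), 1)
  expect_equal(unname(one$final_values), one$trajectory$x[1])
})

test_that("the parameter vector packs and unpacks losslessly", {
  cfg <- simulation_config()
  pv <- parameter_vector(cfg)
  v <- pv_values(pv)
  # full calibratable roster: 12 + 1 + 1 + 12 + 1 + 1 + 1 + 1 + 4 + 1 + 1
  expect_length(v, 36)
  u <- obesnet:::pv_pack(pv)
  back <- pv_values(obesnet:::pv_unpack(pv, u))
  expect_equal(back, v, tolerance = 1e-6)
  # applying the unpacked vector reproduces the config parameters
  cfg2 <- apply_parameter_vector(cfg, obesnet:::pv_unpack(pv, u))
  expect_equal(cfg2$behaviour$theta_norms, cfg$behaviour$theta_norms,
               tolerance = 1e-6)
  expect_equal(cfg2$network$theta_bmiadj, cfg$network$theta_bmiadj,
               tolerance = 1e-6)
  expect_equal(cfg2$theta_extFactor, cfg$theta_extFactor, tolerance = 1e-6)
})

test_that("cascade splits copy the parent and leave the loss unchanged", {
  cfg <- simulation_config(n_initial = 40, horizon_months = 12,
                           warmup_months = 2, seed = 4)
  pv <- parameter_vector(cfg)
  sp <- split_parameter(pv, "theta_pbc", "gender")
  expect_equal(sp$entries$theta_pbc$split, "gender")
  expect_equal(unname(sp$entries$theta_pbc$values),
               rep(cfg$behaviour$theta_pbc, 2))
  both <- split_parameter(pv, "theta_attitude", "both")
  expect_length(both$entries$theta_attitude$values, 12)
  expect_error(split_parameter(sp, "theta_pbc", "gender"), "already split")
  expect_error(split_parameter(pv, "theta_norms", "both"), "already split")
  expect_error(split_parameter(pv, "theta_mem", "gender"), "structural")
  expect_error(split_parameter(pv, "nonsense", "gender"), "unknown")

  # identical copies -> identical simulated behaviour -> identical loss
  ref <- make_reference(cfg)
  loss_a <- make_sim_loss(cfg, ref, pv)(obesnet:::pv_pack(pv), seed = 11)
  loss_b <- make_sim_loss(cfg, ref, sp)(obesnet:::pv_pack(sp), seed = 11)
  expect_equal(loss_a, loss_b, tolerance = 1e-9)
  # gender split then age split lands on the full grid
  full <- split_parameter(sp, "theta_pbc", "age_group")
  expect_equal(full$entries$theta_pbc$split, "both")
  expect_length(full$entries$theta_pbc$values, 12)
})

test_that("replicated testing pools agents and medians the losses", {
  cfg <- simulation_config(n_initial = 40, horizon_months = 12,
                           warmup_months = 2, seed = 8)
  ref <- make_reference(cfg)
  one <- replicated_test(cfg, ref, n_reps = 1, seed = 2)
  direct <- run_simulation({c2 <- cfg; c2$seed <- obesnet:::derive_seed(2, 1); c2})
  expect_equal(one$combined_loss, sse_loss(direct$series, ref))
  # pooling a single replicate reproduces that replicate's aggregates
  merged <- merge(one$combined_series, direct$series,
                  by = c("year", "gender", "age_group"))
  expect_equal(merged$mean_bmi.x, merged$mean_bmi.y, tolerance = 1e-9)
  expect_equal(merged$median_bmi.x, merged$median_bmi.y, tolerance = 1e-9)

  three <- replicated_test(cfg, ref, n_reps = 3, seed = 2)
  expect_length(three$losses, 3)
  expect_true(three$combined_loss %in% three$losses)   # odd count: median is one of them
})
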