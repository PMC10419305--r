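test_that("satisficing value interpolates its anchors quadratically", {
  expect_identical(satisficing_value(20), 0)
  expect_identical(satisficing_value(30), 1)
  expect_identical(satisficing_value(40), 4)
  expect_equal(satisficing_value(25), 0.25)
  expect_equal(satisficing_value(18), 0)      # flat below BMI 20
  expect_equal(satisficing_value(30, theta_sv = 2), 2)
  b <- seq(20, 50, by = 0.5)
  expect_true(all(diff(satisficing_value(b)) >= 0))
  expect_error(satisficing_value(-1), "bmi")
})

test_that("the norms flow is gated by the satisficing value", {
  params <- behaviour_params()
  me <- agents_at(0, 0, bmi = 34, gender = "male", age = 35)
  nobody <- agents_at(numeric(0), numeric(0))
  expect_equal(norms_inflow(me, nobody, params), 0)
  other_gender <- agents_at(0, 0, bmi = 20, gender = "female", age = 35)
  expect_equal(norms_inflow(me, other_gender, params), 0)
  same_bmi <- agents_at(0, 0, bmi = 34, gender = "male", age = 35)
  expect_equal(norms_inflow(me, same_bmi, params), 0)

  # BMI 34 vs weighted mean 30: gap 4 > sv(34) = 1.96, so the flow opens
  nb <- agents_at(c(0, 0), c(0, 0), bmi = c(28, 32), gender = "male",
                  age = 35)
  expect_equal(norms_inflow(me, nb, params),
               params$theta_norms["male", "31-45"] * 4)
  # age weighting: a distant-age neighbour counts for less
  nb2 <- agents_at(c(0, 0), c(0, 0), bmi = c(28, 32), gender = "male",
                   age = c(35, 85))
  w <- 1 / (1 + c(0, 50) / 10)
  m <- sum(w * c(28, 32)) / sum(w)
  expect_equal(norms_inflow(me, nb2, params),
               params$theta_norms["male", "31-45"] * (34 - m))
})

test_that("the gate holds exhaustively over a BMI x gap grid", {
  params <- behaviour_params()
  for (b in 20:45) {
    for (d in -5:10) {
      me <- agents_at(0, 0, bmi = b, gender = "female", age = 50)
      nb <- agents_at(0, 0, bmi = b - d, gender = "female", age = 50)
      flow <- norms_inflow(me, nb, params)
      if (d <= satisficing_value(b)) {
        expect_identical(flow, 0)
      } else {
        expect_gt(flow, 0)
      }
    }
  }
})

test_that("norms response is monotone in the gap above the gate", {
  params <- behaviour_params()
  flows <- vapply(seq(3, 10, by = 0.5), function(d) {
    me <- agents_at(0, 0, bmi = 32, gender = "male", age = 25)
    nb <- agents_at(0, 0, bmi = 32 - d, gender = "male", age = 25)
    norms_inflow(me, nb, params)
  }, numeric(1))
  expect_true(all(diff(flows) >= 0))
})

test_that("attitudes flow scales with education and overweight", {
  params <- behaviour_params(theta_attitude = 0.8)
  lean <- agents_at(0, 0, bmi = 22, education = 5)
  expect_equal(attitudes_inflow(lean, params), 0)
  obese <- agents_at(0, 0, bmi = 31, education = 5)
  expect_equal(attitudes_inflow(obese, params), 0.8)
  half <- agents_at(0, 0, bmi = 27.5, education = 5)
  expect_equal(attitudes_inflow(half, params), 0.8 * 0.5)
  bad <- agents_at(0, 0, bmi = 31)
  bad$education <- 0L
  expect_error(attitudes_inflow(bad, params), "education")
})

test_that("pbc flow saturates with the success history", {
  params <- behaviour_params(theta_pbc = 0.3, pbc_default = 1.5)
  neutral <- agents_at(0, 0)
  expect_equal(pbc_inflow(neutral, params), 0.3 * 1.5)
  winner <- agents_at(0, 0); winner$success_score <- 1e6
  expect_equal(pbc_inflow(winner, params), 2 * 0.3 * 1.5)
  loser <- agents_at(0, 0); loser$success_score <- -1e6
  expect_equal(pbc_inflow(loser, params), 0, tolerance = 1e-12)
})

test_that("stock updates decay, accumulate and stay non-negative", {
  params <- behaviour_params(theta_lag = 0L, activation_fraction = 0)
  s <- init_stocks(params, intention = 10)
  s1 <- update_stocks(s, 0, params)
  expect_equal(s1$intention, 10 * 0.9)

  # constant inflow, no activation: geometric approach to F / decay
  s <- init_stocks(params)
  for (k in 1:500) s <- update_stocks(s, 2, params)
  expect_equal(s$intention, 2 / params$intention_decay, tolerance = 1e-3)

  # non-negativity under any non-negative inflows
  params2 <- behaviour_params(theta_lag = 2L, activation_fraction = 1)
  s <- init_stocks(params2, intention = 5)
  for (k in 1:50) {
    s <- update_stocks(s, runif(1, 0, 3), params2)
    expect_gte(s$intention, 0)
    expect_gte(s$behaviour, 0)
  }
})

test_that("the activation lag delays behaviour by exactly theta_lag months", {
  for (lag in c(0L, 1L, 3L, 6L)) {
    params <- behaviour_params(theta_lag = lag)
    s <- init_stocks(params, intention = 4)
    first_hit <- NA
    for (month in 1:12) {
      s <- update_stocks(s, 0, params)
      if (is.na(first_hit) && s$behaviour > 0) first_hit <- month
    }
    expect_equal(first_hit, lag + 1, info = sprintf("lag %d", lag))
  }
  # wrong buffer length is a hard error
  params <- behaviour_params(theta_lag = 3L)
  expect_error(update_stocks(list(intention = 1, behaviour = 0,
                                  activation_buffer = numeric(1)),
                             0, params), "buffer")
})

test_that("dieting starts only when both trigger conditions hold", {
  params <- behaviour_params(behaviour_threshold = 2, theta_dietTime = 1)
  nb <- agents_at(0, 0, bmi = 28, gender = "male", age = 40)

  calm <- agents_at(0, 0, bmi = 34, gender = "male", age = 40)
  calm$behaviour <- 1.9
  expect_equal(maybe_transition(calm, nb, params)$state, "NORMAL")

  # threshold met but not perceived overweight relative to contacts
  slim <- agents_at(0, 0, bmi = 27, gender = "male", age = 40)
  slim$behaviour <- 5
  fat_nb <- agents_at(0, 0, bmi = 35, gender = "male", age = 40)
  expect_equal(maybe_transition(slim, fat_nb, params)$state, "NORMAL")

  ready <- agents_at(0, 0, bmi = 34, gender = "male", age = 40)
  ready$behaviour <- 5
  set.seed(8)
  out <- maybe_transition(ready, nb, params)
  expect_equal(out$state, "DIETING")
  expect_gte(out$diet_months_remaining, 1)
  expect_equal(out$behaviour, 0)
  expect_equal(out$diet_start_weight, ready$weight)

  # the network-off counterfactual drops the neighbourhood condition
  set.seed(8)
  out2 <- maybe_transition(slim, fat_nb, params, require_gap = FALSE)
  expect_equal(out2$state, "DIETING")
})

test_that("with all flow gains zero no agent ever starts dieting", {
  params <- behaviour_params(theta_norms = matrix(0, 2, 6), theta_pbc = 0,
                             theta_attitude = 0)
  nb <- agents_at(0, 0, bmi = 20, gender = "male", age = 40)
  me <- agents_at(0, 0, bmi = 38, gender = "male", age = 40)
  s <- init_stocks(params)
  for (month in 1:60) {
    inflow <- norms_inflow(me, nb, params) + attitudes_inflow(me, params) +
      pbc_inflow(me, params)
    s <- update_stocks(s, inflow, params)
    me$behaviour <- s$behaviour
    me <- maybe_transition(me, nb, params)
    expect_equal(me$state, "NORMAL")
  }
})
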