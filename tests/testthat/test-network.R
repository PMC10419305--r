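test_that("propinquity sets match a brute-force distance table", {
  solo <- agents_at(0.5, 0.5)
  expect_length(propinquity_set(1, solo, Ra = 0.2), 0)

  pair <- agents_at(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(propinquity_set(1, pair, Ra = 0.1), 2L)
  expect_equal(propinquity_set(2, pair, Ra = 0.1), 1L)

  # 3 x 3 unit grid: diagonal sqrt(2) < 1.5, so the centre sees all 8
  grid <- expand.grid(x = 0:2, y = 0:2)
  ag <- agents_at(grid$x, grid$y)
  centre <- which(grid$x == 1 & grid$y == 1)
  got <- propinquity_set(centre, ag, Ra = 1.5)
  d <- sqrt((grid$x - 1)^2 + (grid$y - 1)^2)
  expect_setequal(got, setdiff(which(d < 1.5), centre))
  expect_length(got, 8)
  # dead agents are never in range
  ag$alive[1] <- FALSE
  expect_false(1L %in% propinquity_set(centre, ag, Ra = 1.5))
})

test_that("homophily thresholding follows the gender-pair weights", {
  w <- c(mm = 1, mf = 1.6, ff = 1, fm = 1.6)
  expect_equal(homophily_indicator(30, 30, "male", "male", 0.5, w), 1L)
  w0 <- c(mm = 0, mf = 0, ff = 0, fm = 0)
  expect_equal(homophily_indicator(20, 45, "male", "female", 0.5, w0), 1L)
  w1 <- c(mm = 1, mf = 1, ff = 1, fm = 1)
  expect_equal(homophily_indicator(30, 36, "male", "male", 5, w1), 0L)
  expect_equal(homophily_indicator(30, 35, "male", "male", 5, w1), 1L)
  # asymmetric directed weights
  wa <- c(mm = 1, mf = 2, ff = 1, fm = 0.5)
  expect_equal(homophily_indicator(30, 33, "male", "female", 5, wa), 0L)
  expect_equal(homophily_indicator(33, 30, "female", "male", 5, wa), 1L)
})

test_that("memory probability is the capped linear form and non-decreasing", {
  expect_equal(memory_probability(0, 0.6, 0.1), 0.1)
  expect_equal(memory_probability(0.5, 0.6, 0.1), 0.4)
  expect_equal(memory_probability(1, 100, 0.1), 1)
  alphas <- seq(0, 1, by = 0.05)
  p <- memory_probability(alphas, 0.7, 0.2)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p <= 1 & p >= 0))
})

test_that("degenerate slots produce no interactions", {
  ag <- agents_at(c(0.1, 0.11, 0.5), c(0.1, 0.1, 0.9))
  p0 <- network_params(Ra = 0.2, S = 0, theta_trigger = 10, baseline_prob = 1)
  st <- init_network(ag, p0, init_slots = 0)
  set.seed(1)
  out <- step_network(ag, p0, st)
  expect_equal(nrow(out), 0)
  expect_true(all(st$C == 0))

  # all pairwise distances beyond range
  far <- agents_at(c(0, 1, 2), c(0, 0, 0))
  pr <- network_params(Ra = 0.5, S = 5, theta_trigger = 10, baseline_prob = 1)
  str <- init_network(far, pr, init_slots = 3)
  expect_true(all(str$C == 0))
})

test_that("a willing in-range pair links and both histories record it", {
  ag <- agents_at(c(0.5, 0.52), c(0.5, 0.5))
  p <- network_params(Ra = 0.1, S = 2, M = 3, offers_per_step = 1,
                      theta_trigger = 10, baseline_prob = 1, theta_mem = 0)
  st <- init_network(ag, p, init_slots = 0)
  set.seed(2)
  out <- step_network(ag, p, st)
  expect_gt(nrow(out), 0)
  expect_equal(st$C[1, 2], st$C[2, 1])
  expect_gt(st$C[1, 2], 0)
  expect_equal(neighbourhood(1, ag, st), 2L)
  expect_equal(neighbourhood(2, ag, st), 1L)
})

test_that("capacity S bounds acceptances per slot and locality holds", {
  set.seed(30)
  n <- 60
  ag <- agents_at(runif(n, 0, 0.4), runif(n, 0, 0.4),
                  bmi = rnorm(n, 27, 3),
                  gender = rep(c("male", "female"), length.out = n))
  p <- network_params(Ra = 0.15, S = 2, M = 4, offers_per_step = 4,
                      theta_trigger = 3, baseline_prob = 0.9, theta_mem = 0.5)
  st <- init_network(ag, p, init_slots = 0)
  b <- bmi_of(ag)
  w <- matrix(c(1, 1.6, 1.6, 1), 2, 2)  # [offerer, offeree], m=1 f=2
  g <- ifelse(ag$gender == "male", 1, 2)
  for (slot in 1:6) {
    edges <- step_network(ag, p, st)
    if (nrow(edges) == 0) next
    # capacity: no agent accepts more than S offers in one slot
    expect_lte(max(table(edges[, "to"])), p$S)
    # locality: every interaction is in range and homophily-eligible
    d <- sqrt((ag$pos_x[edges[, 1]] - ag$pos_x[edges[, 2]])^2 +
                (ag$pos_y[edges[, 1]] - ag$pos_y[edges[, 2]])^2)
    expect_true(all(d < p$Ra))
    wij <- w[cbind(g[edges[, 1]], g[edges[, 2]])]
    expect_true(all(wij * abs(b[edges[, 1]] - b[edges[, 2]]) <=
                      p$theta_trigger))
  }
})

test_that("the neighbourhood window truncates at M slots", {
  ag <- agents_at(c(0.5, 0.52), c(0.5, 0.5))
  p <- network_params(Ra = 0.1, S = 2, M = 3, offers_per_step = 1,
                      theta_trigger = 10, baseline_prob = 1, theta_mem = 0)
  st <- init_network(ag, p, init_slots = 0)
  set.seed(4)
  step_network(ag, p, st)
  expect_equal(neighbourhood(1, ag, st), 2L)
  # silence all further offers; the contact ages out of the window
  p_silent <- p
  p_silent$offers_per_step <- 0
  for (k in 1:2) step_network(ag, p_silent, st)
  expect_equal(neighbourhood(1, ag, st), 2L)   # still inside the window
  step_network(ag, p_silent, st)
  expect_length(neighbourhood(1, ag, st), 0)   # M + 1 slots ago: forgotten
  # dead partners are excluded even with fresh contacts
  set.seed(5)
  step_network(ag, p, st)
  ag$alive[2] <- FALSE
  expect_length(neighbourhood(1, ag, st), 0)
})

test_that("metrics match hand counts on canonical small graphs", {
  ag3 <- agents_at(c(0, 1, 2), c(0, 0, 0), bmi = c(22, 25, 31))
  tri <- state_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  m <- compute_metrics(ag3, tri)
  expect_equal(m$clustering, 1)
  expect_equal(m$transitivity, 1)
  expect_equal(m$average_degree, 2)

  path <- state_from_edges(3, rbind(c(1, 2), c(2, 3)))
  m <- compute_metrics(ag3, path)
  expect_equal(m$transitivity, 0)
  expect_equal(m$average_degree, 4 / 3)
  expect_equal(m$clustering, 0)  # degree-<2 vertices count as 0

  ag4 <- agents_at(rep(0, 4), rep(0, 4), bmi = c(22, 25, 31, 28))
  star <- state_from_edges(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  m <- compute_metrics(ag4, star)
  expect_equal(m$degree_assortativity, -1)

  # degenerate cases flag undefined rather than inventing a number
  one <- agents_at(0, 0)
  expect_true(is.na(compute_metrics(one, state_from_edges(1, matrix(0, 0, 2)))$clustering))
  same_bmi <- agents_at(c(0, 1, 2), c(0, 0, 0), bmi = 25)
  expect_true(is.na(compute_metrics(same_bmi, tri)$bmi_assortativity))
})

test_that("compute_metrics agrees with brute-force enumeration (oracle)", {
  for (seed in 1:25) {
    A <- random_adjacency(seed)
    bmi <- runif(nrow(A), 20, 40)
    got <- compute_metrics(NULL, graph_from_adjacency_bmi(A, bmi))
    want <- brute_metrics(A, bmi)
    for (metric in names(want)) {
      expect_equal(got[[metric]], want[[metric]], tolerance = 1e-10,
                   info = sprintf("seed %d metric %s", seed, metric))
    }
  }
})

test_that("network export round-trips and classifies BMI colours", {
  ag <- agents_at(c(0, 1, 2), c(0, 0, 0), bmi = c(22, 33, 42))
  tri <- state_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3)), M = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(ag, tri, path, format = "edgelist")
  el <- read_edgelist(path)
  expect_equal(nrow(el), 3)
  expect_equal(sort(names(el)), sort(c("source_id", "target_id", "weight")))
  expect_equal(el$weight, rep(0.5, 3))  # 1 contact in a 2-slot window

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(ag, tri, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::V(g)$bmi_class, c("green", "red", "black"))
  expect_error(export_network(ag, tri, path, format = "dot"), "arg")
})

test_that("the stationary network stays dynamic: edges churn every slot", {
  set.seed(77)
  ag <- generate_population(1000, seed = 77, Z = 1)
  p <- network_fingerprint_preset()
  st <- init_network(ag, p)
  for (k in 1:10) step_network(ag, p, st)
  edge_key <- function(st) {
    el <- which(st$C > 0 & upper.tri(st$C), arr.ind = TRUE)
    paste(el[, 1], el[, 2])
  }
  churn <- numeric(5)
  before <- edge_key(st)
  for (k in 1:5) {
    step_network(ag, p, st)
    after <- edge_key(st)
    churn[k] <- length(setdiff(union(before, after),
                               intersect(before, after)))
    before <- after
  }
  expect_true(all(churn > 0))
})

test_that("average degree plateaus under stationary conditions", {
  fp <- run_network_fingerprint(n = 300, months = 50, warmup_months = 60,
                                params = network_fingerprint_preset(),
                                seed = 99)
  snaps <- fp$snapshots
  fit <- stats::lm(average_degree ~ slot, data = snaps)
  pval <- suppressWarnings(summary(fit)$coefficients["slot", "Pr(>|t|)"])
  expect_gt(pval, 0.05)
})
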