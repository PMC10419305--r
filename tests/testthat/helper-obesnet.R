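# Shared fixtures: hand-built agent tables, explicit network states, and an
# independent brute-force implementation of the topography metrics used as
# the oracle for compute_metrics().

# Minimal agent table at explicit positions.
agents_at <- function(x, y, bmi = 25, gender = "male", age = 30,
                      height = 1.7, education = 3L, pal = "medium",
                      alive = TRUE) {
  n <- length(x)
  data.frame(
    id = seq_len(n), age = rep_len(age, n),
    gender = rep_len(gender, n), height = rep_len(height, n),
    weight = rep_len(bmi, n) * rep_len(height, n)^2,
    education = rep_len(as.integer(education), n), pal = rep_len(pal, n),
    pos_x = x, pos_y = y,
    intention = rep_len(0, n), behaviour = rep_len(0, n),
    state = rep_len("NORMAL", n),
    diet_months_remaining = rep_len(0L, n),
    diet_start_weight = rep_len(NA_real_, n),
    success_score = rep_len(0, n), alive = rep_len(alive, n),
    stringsAsFactors = FALSE
  )
}

# Network state holding exactly the given undirected edges (one contact
# each, all in the most recent slot of a window of length M).
state_from_edges <- function(n, edges, M = 1) {
  st <- new.env(parent = emptyenv())
  st$C <- matrix(0L, n, n)
  edges <- matrix(as.integer(edges), ncol = 2)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    st$C[i, j] <- st$C[i, j] + 1L
    st$C[j, i] <- st$C[j, i] + 1L
  }
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  st$ring <- c(rep(list(empty), M - 1), list(cbind(from = edges[, 1],
                                                   to = edges[, 2])))
  st$slot <- M
  st$inrange <- NULL
  st
}

# ---- brute-force metric oracle --------------------------------------------
# Direct triplet enumeration and edge-end correlations on an adjacency
# matrix; deliberately naive and independent of igraph.

brute_local_clustering <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ])
    k <- length(nb)
    if (k < 2) { out[v] <- 0; next }
    links <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (A[nb[i], nb[j]]) links <- links + 1
    }
    out[v] <- links / (k * (k - 1) / 2)
  }
  out
}

brute_transitivity <- function(A) {
  n <- nrow(A)
  closed <- 0; total <- 0
  for (v in seq_len(n)) {
    nb <- which(A[v, ])
    k <- length(nb)
    if (k < 2) next
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      total <- total + 1
      if (A[nb[i], nb[j]]) closed <- closed + 1
    }
  }
  if (total == 0) return(NA_real_)
  closed / total
}

# Pearson correlation of a vertex attribute across edge ends (each edge
# counted in both orientations); NA when degenerate.
brute_edge_correlation <- function(A, values) {
  el <- which(A & upper.tri(A), arr.ind = TRUE)
  if (nrow(el) < 1) return(NA_real_)
  x <- c(values[el[, 1]], values[el[, 2]])
  y <- c(values[el[, 2]], values[el[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

brute_metrics <- function(A, bmi) {
  deg <- rowSums(A)
  list(clustering = mean(brute_local_clustering(A)),
       transitivity = brute_transitivity(A),
       degree_assortativity = brute_edge_correlation(A, deg),
       bmi_assortativity = brute_edge_correlation(A, bmi),
       average_degree = mean(deg))
}

# Random simple graph on up to n_max nodes as a symmetric adjacency matrix.
random_adjacency <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  p <- runif(1, 0.15, 0.75)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A[i, j] <- A[j, i] <- runif(1) < p
  }
  A
}

graph_from_adjacency_bmi <- function(A, bmi) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$bmi <- bmi
  g
}
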