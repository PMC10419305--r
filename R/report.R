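# Topography reports, parameter-table rendering and run manifests.

spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok], method = "spearman")
}

# BMI assortativity of the subgraph induced by an agent's closed
# neighbourhood (the agent plus its network neighbours): Pearson
# correlation of BMI across that subgraph's edges; NA when degenerate.
local_bmi_assortativity <- function(i, agents, A, bmi) {
  nb <- which(A[, i])
  nodes <- c(i, nb)
  if (length(nodes) < 3) return(NA_real_)
  sub <- A[nodes, nodes, drop = FALSE]
  el <- which(sub & upper.tri(sub), arr.ind = TRUE)
  if (nrow(el) < 2) return(NA_real_)
  x <- bmi[nodes[el[, 1]]]
  y <- bmi[nodes[el[, 2]]]
  if (sd(c(x, y)) == 0) return(NA_real_)
  suppressWarnings(cor(c(x, y), c(y, x)))
}

#' Network topography report
#'
#' Summarises the per-snapshot topography metrics of a simulation result
#' (median, mean and standard deviation across snapshots) and computes the
#' two per-agent diagnostics on the final network state: the Spearman
#' correlation of agent age with the BMI assortativity of the agent's own
#' network neighbourhood, and the Spearman correlation of agent BMI with
#' neighbourhood size. Correlations that are undefined (zero variance)
#' are reported as `NA`.
#'
#' @param result an `obesnet_result` with at least 2 network snapshots.
#' @return list of class `obesnet_metrics_report`: `summary` (data frame
#'   metric/median/mean/sd), `snapshots`, `cor_age_bmi_assort`,
#'   `cor_bmi_neighbourhood_size`.
#' @export
topography_report <- function(result) {
  snaps <- result$metrics
  if (is.null(snaps) || nrow(snaps) < 2) {
    stopf("topography_report(): need at least 2 network snapshots")
  }
  metric_cols <- setdiff(names(snaps), "month")
  summary <- data.frame(
    metric = metric_cols,
    median = vapply(snaps[metric_cols], median, numeric(1), na.rm = TRUE),
    mean = vapply(snaps[metric_cols], mean, numeric(1), na.rm = TRUE),
    sd = vapply(snaps[metric_cols], sd, numeric(1), na.rm = TRUE),
    row.names = NULL
  )
  agents <- result$agents
  state <- result$state
  live <- which(agents$alive)
  A <- neighbourhood_adjacency(agents, state)
  b <- bmi_of(agents)
  nb_size <- colSums(A)
  lba <- vapply(live, local_bmi_assortativity, numeric(1),
                agents = agents, A = A, bmi = b)
  structure(list(
    summary = summary,
    snapshots = snaps,
    cor_age_bmi_assort = spearman(agents$age[live], lba),
    cor_bmi_neighbourhood_size = spearman(b[live], nb_size[live])
  ), class = "obesnet_metrics_report")
}

#' Render a split parameter as a gender x age-group table
#'
#' Lays a per-(gender, age-group) parameter out in the conventional
#' two-row (Male/Female), six-column (age ranges) grid used for reporting
#' calibrated parameter values. Numeric values round-trip losslessly
#' through the CSV writer.
#'
#' @param values 2 x 6 matrix (rows male/female).
#' @param path optional CSV output path.
#' @return data frame with an `age_range` header column layout.
#' @export
render_parameter_table <- function(values, path = NULL) {
  if (!is.matrix(values) || !identical(dim(values), c(2L, 6L))) {
    stopf("render_parameter_table(): values must be a 2 x 6 matrix")
  }
  out <- data.frame(gender = c("Male", "Female"), values,
                    stringsAsFactors = FALSE)
  names(out) <- c("gender", AGE_GROUPS)
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Render a metrics report as a table
#'
#' @param report an `obesnet_metrics_report`.
#' @param path optional CSV output path.
#' @return the summary data frame (possibly header-only).
#' @export
render_metrics_table <- function(report, path = NULL) {
  out <- if (inherits(report, "obesnet_metrics_report")) report$summary
    else as.data.frame(report)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Write a machine-readable run manifest
#'
#' Records what produced a set of outputs: a digest of the configuration,
#' the seed, the package version and a timestamp.
#'
#' @param config the configuration used.
#' @param path output JSON path.
#' @param extra optional named list folded into the manifest.
#' @export
write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    package = "obesnet",
    version = as.character(utils::packageVersion("obesnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed %||% NA,
    config_hash = config_hash(config)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, give.attr = FALSE)),
             collapse = "\n")
  # small stable checksum without extra dependencies
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% 2147483647
}

#' @export
print.obesnet_result <- function(x, ...) {
  yrs <- sort(unique(x$series$year))
  cat(sprintf("<obesnet simulation: %d agents alive, years %d-%d>\n",
              sum(x$agents$alive), min(yrs), max(yrs)))
  cat(sprintf("  diet episodes started: %d; births: %d; deaths: %d\n",
              nrow(x$events$diet_start), nrow(x$events$births),
              nrow(x$events$deaths)))
  invisible(x)
}

#' @export
print.obesnet_metrics_report <- function(x, ...) {
  cat("<obesnet topography report>\n")
  print(x$summary, digits = 3)
  cat(sprintf("  Spearman(age, neighbourhood BMI assortativity): %.3f\n",
              x$cor_age_bmi_assort))
  cat(sprintf("  Spearman(BMI, neighbourhood size): %.3f\n",
              x$cor_bmi_neighbourhood_size))
  invisible(x)
}
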