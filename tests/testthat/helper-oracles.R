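# Independent oracles used against the package implementations. These are
# deliberately naive (loops, brute force, closed forms) and share no code
# with the functions they check.

# trapezoid area computed point by point
hand_trapezoid <- function(x, y) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  total
}

# textbook Pearson correlation
hand_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# dense grid search minimiser for the fixed-asymptote logistic curve
grid_search_logistic <- function(log_conc, viability,
                                 b_grid = seq(0.1, 5, by = 0.005),
                                 e_grid = NULL) {
  if (is.null(e_grid)) {
    e_grid <- seq(min(log_conc), max(log_conc), by = 0.005)
  }
  best <- list(sse = Inf)
  for (b in b_grid) {
    pred <- outer(log_conc, e_grid, function(x, e) 100 / (1 + exp(b * (x - e))))
    sse <- colSums((viability - pred)^2)
    i <- which.min(sse)
    if (sse[i] < best$sse) best <- list(slope = b, ec50_log = e_grid[i], sse = sse[i])
  }
  best
}

# competition rank as a count of strictly smaller elements
counting_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + 1L, integer(1))
}

# brute-force GSEA running-sum walk, weight exponent 1
brute_walk_es <- function(ranks, set) {
  ord <- order(ranks, decreasing = TRUE)
  genes <- names(ranks)[ord]
  vals <- unname(ranks[ord])
  in_set <- genes %in% set
  nr <- sum(abs(vals[in_set]))
  n_out <- sum(!in_set)
  running <- 0
  best <- 0
  for (i in seq_along(genes)) {
    if (in_set[i]) {
      running <- running + if (nr > 0) abs(vals[i]) / nr else 1 / sum(in_set)
    } else {
      running <- running - 1 / n_out
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# memoised scenarios so expensive fixtures build once per run
.scenario_cache <- new.env(parent = emptyenv())

small_manifest <- function(seed = 7) {
  scenario_manifest(seed = seed, n_genes = 300, n_cell_lines = 12,
                    n_knockdowns = 60, n_planted = 5, n_decoys = 5)
}

small_scenario <- function() {
  if (is.null(.scenario_cache$small)) {
    .scenario_cache$small <- make_scenario(small_manifest())
  }
  .scenario_cache$small
}

small_pipeline <- function() {
  if (is.null(.scenario_cache$small_run)) {
    cfg <- default_config(seed = 7,
                          simulate = list(n_genes = 300, n_cell_lines = 12,
                                          n_knockdowns = 60, n_planted = 5,
                                          n_decoys = 5))
    .scenario_cache$small_run <- suppressMessages(run_pipeline(cfg))
  }
  .scenario_cache$small_run
}

example_path <- function(name) {
  system.file("extdata", name, package = "deathmark", mustWork = TRUE)
}
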