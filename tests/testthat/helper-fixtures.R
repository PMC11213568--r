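# Shared fixtures, built once per test run and cached: a standard agent on
# the default task, with prediction errors, plus small utilities used
# across files. All fixtures are generated in code under fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

std_params <- function() qlearn_params(0.3, 0.2, 0.1)

# prediction-error table for one synthetic subject; n_sessions sessions
fixture_pe <- function(n_sessions = 5, seed = 11) {
  key <- paste0("pe_", n_sessions, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    task <- generate_task(task_config(n_sessions = n_sessions), seed = seed)
    tr <- simulate_agent(task, std_params(), seed = seed + 1)
    .fixture_cache[[key]] <- compute_prediction_errors(tr, std_params())
  }
  .fixture_cache[[key]]
}

# exactly n reward-condition trials from the standard agent
fixture_pe_reward <- function(n = 200, seed = 11) {
  pe <- fixture_pe(n_sessions = ceiling(n / 48) + 1, seed = seed)
  pe_r <- pe[pe$condition == "reward", ]
  stopifnot(nrow(pe_r) >= n)
  pe_r[seq_len(n), ]
}

# index of the sample closest to a given time on an axis
t_index <- function(time, t) which.min(abs(time - t))

# AR(1) noise matrix built independently of the package internals
test_ar1 <- function(n_trials, n_time, ar = 0.9, sd = 1) {
  innov <- matrix(rnorm(n_trials * n_time, sd = sd * sqrt(1 - ar^2)),
                  n_time, n_trials)
  t(matrix(as.numeric(stats::filter(innov, ar, method = "recursive")),
           n_time, n_trials))
}

# plug-in histogram MI (bits) on median-discretized data: brute-force
# oracle for coupling-ladder comparisons
histogram_mi2 <- function(x, y) {
  bx <- x > stats::median(x)
  by <- y > stats::median(y)
  tab <- table(bx, by) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (tab[i, j] > 0) {
      mi <- mi + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
    }
  }
  mi
}
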