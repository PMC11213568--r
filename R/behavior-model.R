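#' Q-learning model parameters
#'
#' Bundles the three free parameters of the instrumental-learning model:
#' the learning rate `alpha` weighting new experiences, the softmax choice
#' temperature `beta` (a divisor: larger values mean more exploration), and
#' the perseveration bonus `theta` added to the expected value of the
#' option chosen on the previous trial of the same cue pair.
#'
#' @param alpha Learning rate, in `[0, 1]`.
#' @param beta Choice temperature, strictly positive.
#' @param theta Perseveration bonus, finite (value units).
#' @return A `qlearn_params` list.
#' @export
qlearn_params <- function(alpha, beta, theta = 0) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].")
  }
  if (!is.numeric(beta) || beta <= 0) abort("`beta` must be > 0.")
  if (!is.numeric(theta) || !is.finite(theta)) abort("`theta` must be finite.")
  structure(list(alpha = alpha, beta = beta, theta = theta),
            class = "qlearn_params")
}

#' Single Q-value update
#'
#' Rescorla-Wagner style delta rule: the prediction error is the outcome
#' minus the current expectation, and the expectation moves toward the
#' outcome by a fraction `alpha` of that error. Only the chosen cue's
#' Q-value is ever updated.
#'
#' @param q Current expected value of the chosen cue.
#' @param outcome Received reinforcement, in `{-1, 0, 1}` euros.
#' @param alpha Learning rate in `[0, 1]`.
#' @return A list with `q_next` and `delta` (the prediction error).
#' @examples
#' q_update(0, 1, 0.5)   # q_next = 0.5, delta = 1
#' q_update(0.5, 0, 0.2) # q_next = 0.4, delta = -0.5
#' @export
q_update <- function(q, outcome, alpha) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  delta <- outcome - q
  list(q_next = q + alpha * delta, delta = delta)
}

#' Softmax choice probability with perseveration
#'
#' Probability of choosing option `a` over option `b` given their expected
#' values. The perseveration bonus `theta` is added to the exponent
#' numerator of whichever option was chosen on the previous trial of the
#' same pair (neither, on a pair's first trial); the sum is divided by the
#' temperature `beta`. Computed on the logit scale so extreme temperatures
#' do not overflow.
#'
#' @param q_a,q_b Expected values of the two options.
#' @param params A [qlearn_params()] object.
#' @param prev Which option was chosen on the pair's previous trial:
#'   `"a"`, `"b"` or `"none"`.
#' @return `P(choose a)`, in (0, 1); `P(a) + P(b) = 1` by construction.
#' @examples
#' choice_prob(1, 0, qlearn_params(0.5, 1))            # e / (e + 1)
#' choice_prob(0, 0, qlearn_params(0.5, 1, 0.5), "a")  # exp(0.5)/(exp(0.5)+1)
#' @export
choice_prob <- function(q_a, q_b, params, prev = c("none", "a", "b")) {
  prev <- match.arg(prev)
  if (params$beta <= 0) abort("`beta` must be > 0.")
  za <- q_a + if (prev == "a") params$theta else 0
  zb <- q_b + if (prev == "b") params$theta else 0
  stats::plogis((za - zb) / params$beta)
}

# Internal: 0-based consecutive pair key unique per (subject, session, pair),
# used to reset Q-values at each new pair.
pair_key <- function(trials) {
  key <- paste(trials$subject, trials$session, trials$pair, sep = "\r")
  as.integer(factor(key, levels = unique(key))) - 1L
}

# Internal: check the trial-table contract shared by all behavioral ops.
validate_trials <- function(trials, need_choices = TRUE) {
  req <- c("subject", "session", "trial", "pair", "condition")
  if (need_choices) req <- c(req, "chosen", "outcome")
  missing <- setdiff(req, names(trials))
  if (length(missing)) {
    abort(paste0("trial table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(trials) == 0) abort("trial table is empty.")
  if (!all(trials$condition %in% c("reward", "punishment"))) {
    abort("`condition` must be 'reward' or 'punishment'.")
  }
  if (need_choices) {
    if (!all(trials$chosen %in% c(1L, 2L))) abort("`chosen` must be 1 or 2.")
    rew <- trials$condition == "reward"
    if (!all(trials$outcome[rew] %in% c(0, 1))) {
      abort("reward-pair outcomes must be 0 or +1.")
    }
    if (!all(trials$outcome[!rew] %in% c(-1, 0))) {
      abort("punishment-pair outcomes must be -1 or 0.")
    }
  }
  cond_per_pair <- tapply(trials$condition,
                          paste(trials$subject, trials$session, trials$pair),
                          function(x) length(unique(x)))
  if (any(cond_per_pair != 1)) {
    abort("each pair id must map to exactly one condition.")
  }
  invisible(trials)
}

#' Negative log-likelihood of observed choices
#'
#' Sequentially replays the Q-learning model over a completed trial table
#' (Q-values reset to 0 at each new pair) and accumulates
#' `-sum(log P(choice))` under the softmax rule, in nats. Choice
#' probabilities are floored at `1e-12` so a single surprising choice
#' cannot produce an infinite objective.
#'
#' @param trials Trial table with choices and outcomes (see
#'   [simulate_agent()] for the column contract).
#' @param params A [qlearn_params()] object.
#' @return Negative log-likelihood in nats (non-negative).
#' @export
qlearn_nll <- function(trials, params) {
  validate_trials(trials)
  key <- pair_key(trials)
  n_pairs <- max(key) + 1L
  q <- matrix(0, n_pairs, 2)
  prev <- integer(n_pairs)
  nll <- 0
  for (i in seq_len(nrow(trials))) {
    k <- key[i] + 1L
    za <- q[k, 1] + if (prev[k] == 1L) params$theta else 0
    zb <- q[k, 2] + if (prev[k] == 2L) params$theta else 0
    pa <- stats::plogis((za - zb) / params$beta)
    p <- if (trials$chosen[i] == 1L) pa else 1 - pa
    nll <- nll - log(max(p, 1e-12))
    ch <- trials$chosen[i]
    q[k, ch] <- q[k, ch] + params$alpha * (trials$outcome[i] - q[k, ch])
    prev[k] <- ch
  }
  nll
}

#' Simulate an agent performing the learning task
#'
#' Fills a task layout (from [generate_task()]) with choices sampled from
#' the softmax rule and outcomes sampled from each pair's reciprocal
#' contingencies. Q-values start at 0 for every pair, and only the chosen
#' cue's value is updated. Cue 1 of each pair is by convention the
#' favourable one (higher probability of the better outcome).
#'
#' @param task Task layout tibble from [generate_task()].
#' @param params A [qlearn_params()] object.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return The task tibble completed with `chosen` (1 or 2), `outcome`
#'   and `prev_chosen_same_pair` (0 when none) columns.
#' @export
simulate_agent <- function(task, params, seed) {
  validate_trials(task, need_choices = FALSE)
  if (!"p_good" %in% names(task)) {
    abort("task layout lacks the `p_good` contingency column.")
  }
  key <- pair_key(task)
  n_pairs <- max(key) + 1L
  n <- nrow(task)
  chosen <- integer(n)
  outcome <- numeric(n)
  prev_col <- integer(n)
  withr::with_seed(seed, {
    q <- matrix(0, n_pairs, 2)
    prev <- integer(n_pairs)
    u_choice <- runif(n)
    u_out <- runif(n)
    for (i in seq_len(n)) {
      k <- key[i] + 1L
      za <- q[k, 1] + if (prev[k] == 1L) params$theta else 0
      zb <- q[k, 2] + if (prev[k] == 2L) params$theta else 0
      pa <- stats::plogis((za - zb) / params$beta)
      ch <- if (u_choice[i] < pa) 1L else 2L
      p_fav <- if (ch == 1L) task$p_good[i] else 1 - task$p_good[i]
      fav <- u_out[i] < p_fav
      out <- if (task$condition[i] == "reward") {
        if (fav) 1 else 0
      } else {
        if (fav) 0 else -1
      }
      chosen[i] <- ch
      outcome[i] <- out
      prev_col[i] <- prev[k]
      q[k, ch] <- q[k, ch] + params$alpha * (out - q[k, ch])
      prev[k] <- ch
    }
  })
  dplyr::mutate(task, chosen = chosen, outcome = outcome,
                prev_chosen_same_pair = prev_col)
}

#' Fit the Q-learning model by multistart maximum likelihood
#'
#' Minimizes [qlearn_nll()] over `(alpha, beta, theta)` with bounded
#' L-BFGS-B, restarted from `n_starts` points drawn uniformly within the
#' bounds (deterministic given `seed`). The best start is returned; if no
#' start converges the best incumbent is still returned with
#' `converged = FALSE`.
#'
#' @param trials Completed trial table (one or more sessions).
#' @param n_starts Number of random starting points (default 10).
#' @param bounds Named list with two-element `alpha`, `beta`, `theta`
#'   ranges. Defaults: alpha in `[0, 1]`, beta in `[1e-6, 10]`, theta in
#'   `[-2, 2]`.
#' @param seed Integer seed for the starting points.
#' @return A `qlearn_fit` object; see [tidy.qlearn_fit()] and
#'   [glance.qlearn_fit()].
#' @export
fit_qlearning <- function(trials, n_starts = 10,
                          bounds = list(alpha = c(0, 1),
                                        beta = c(1e-6, 10),
                                        theta = c(-2, 2)),
                          seed = 1) {
  validate_trials(trials)
  if (n_starts < 1) abort("`n_starts` must be >= 1.")
  key <- pair_key(trials)
  chosen <- as.integer(trials$chosen)
  outcome <- as.numeric(trials$outcome)
  lower <- vapply(bounds, `[`, numeric(1), 1)[c("alpha", "beta", "theta")]
  upper <- vapply(bounds, `[`, numeric(1), 2)[c("alpha", "beta", "theta")]
  obj <- function(p) {
    qlearn_nll_cpp(key, chosen, outcome, p[1], p[2], p[3], 1e-12)
  }
  starts <- withr::with_seed(seed, {
    matrix(runif(3 * n_starts, rep(lower, each = n_starts),
                 rep(upper, each = n_starts)), ncol = 3)
  })
  fits <- lapply(seq_len(n_starts), function(i) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(res)) return(list(par = starts[i, ], value = obj(starts[i, ]),
                                  convergence = 1L))
    res
  })
  nlls <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(nlls)]]
  structure(list(
    params = qlearn_params(best$par[1], best$par[2], best$par[3]),
    nll = best$value,
    n_starts = n_starts,
    n_trials = nrow(trials),
    converged = vapply(fits, function(f) f$convergence == 0L, logical(1)),
    starts = tibble::tibble(
      start = seq_len(n_starts),
      alpha = vapply(fits, function(f) f$par[1], numeric(1)),
      beta = vapply(fits, function(f) f$par[2], numeric(1)),
      theta = vapply(fits, function(f) f$par[3], numeric(1)),
      nll = nlls,
      converged = vapply(fits, function(f) f$convergence == 0L, logical(1)))
  ), class = "qlearn_fit")
}

#' @export
print.qlearn_fit <- function(x, ...) {
  cat("Q-learning fit\n")
  cat(sprintf("  alpha = %.4f, beta = %.4f, theta = %.4f\n",
              x$params$alpha, x$params$beta, x$params$theta))
  cat(sprintf("  nll = %.2f nats over %d trials (%d/%d starts converged)\n",
              x$nll, x$n_trials, sum(x$converged), x$n_starts))
  invisible(x)
}

#' Tidy a Q-learning fit
#'
#' @param x A `qlearn_fit` object.
#' @param ... Unused.
#' @return One row per parameter with the best-fit estimate.
#' @export
tidy.qlearn_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta", "theta"),
                 estimate = c(x$params$alpha, x$params$beta, x$params$theta))
}

#' One-row summary of a Q-learning fit
#'
#' @param x A `qlearn_fit` object.
#' @param ... Unused.
#' @return Tibble with the negative log-likelihood (nats), trial count,
#'   starts and convergence.
#' @export
glance.qlearn_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, nll_per_trial = x$nll / x$n_trials,
                 n_trials = x$n_trials, n_starts = x$n_starts,
                 converged = any(x$converged))
}

#' Trial-wise prediction errors under fitted parameters
#'
#' Replays the Q-value updates over the table and records the prediction
#' error `delta = outcome - Q(chosen)` at each trial (Q evaluated before
#' the update, so the first trial of any pair has `delta = outcome`). The
#' error is split by condition into reward (`rpe`) and punishment (`ppe`)
#' prediction errors; the two subsets are disjoint and together cover all
#' trials.
#'
#' @param trials Completed trial table.
#' @param params A [qlearn_params()] object (typically from a fit).
#' @return The trial tibble with `q_chosen`, `delta`, `rpe` and `ppe`
#'   columns (`rpe`/`ppe` are `NA` off-condition).
#' @export
compute_prediction_errors <- function(trials, params) {
  validate_trials(trials)
  key <- pair_key(trials)
  n_pairs <- max(key) + 1L
  q <- matrix(0, n_pairs, 2)
  n <- nrow(trials)
  delta <- numeric(n)
  q_chosen <- numeric(n)
  for (i in seq_len(n)) {
    k <- key[i] + 1L
    ch <- trials$chosen[i]
    q_chosen[i] <- q[k, ch]
    delta[i] <- trials$outcome[i] - q[k, ch]
    q[k, ch] <- q[k, ch] + params$alpha * delta[i]
  }
  dplyr::mutate(trials, q_chosen = q_chosen, delta = delta,
                rpe = ifelse(.data$condition == "reward", delta, NA_real_),
                ppe = ifelse(.data$condition == "punishment", delta, NA_real_))
}

#' Read / write trial tables
#'
#' CSV round-trip for trial tables using the standard column set
#' (`subject, session, trial, pair, condition, chosen, outcome,
#' prev_chosen_same_pair`, plus any extra columns present).
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns the
#'   path invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
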