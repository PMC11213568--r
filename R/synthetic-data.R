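#' Task configuration for the probabilistic learning task
#'
#' Describes one or more sessions of the two-alternative instrumental
#' learning task: 4 cue pairs per session (half leading to rewards of
#' +1/0 euro, half to punishments of -1/0 euro), 24 repetitions per pair
#' presented in randomized intermingled order, and reciprocal outcome
#' contingencies (default 0.75/0.25) within each pair. A training session
#' has 2 pairs shown 8 times each (16 trials).
#'
#' @param n_sessions Number of sessions.
#' @param pairs_per_session Cue pairs per session (even; half reward).
#' @param reps_per_pair Presentations of each pair per session.
#' @param contingency Probability of the favourable outcome for the better
#'   cue, in (0.5, 1).
#' @param training If `TRUE`, overrides to the 2-pair, 8-rep training
#'   layout.
#' @return A `task_config` list.
#' @export
task_config <- function(n_sessions = 1, pairs_per_session = 4,
                        reps_per_pair = 24, contingency = 0.75,
                        training = FALSE) {
  if (training) {
    pairs_per_session <- 2
    reps_per_pair <- 8
  }
  if (contingency <= 0.5 || contingency >= 1) {
    abort("`contingency` must lie in (0.5, 1).")
  }
  if (reps_per_pair < 1) abort("`reps_per_pair` must be >= 1.")
  if (pairs_per_session %% 2 != 0) {
    abort("`pairs_per_session` must be even (half reward, half punishment).")
  }
  structure(list(n_sessions = n_sessions,
                 pairs_per_session = pairs_per_session,
                 reps_per_pair = reps_per_pair,
                 contingency = contingency,
                 training = training),
            class = "task_config")
}

#' Generate a task layout
#'
#' Builds the trial-by-trial layout of the task for one subject: pair
#' identities and conditions, randomized intermingled presentation order,
#' counterbalanced left/right position of the favourable cue, and the
#' outcome contingency of each pair. Choices and outcomes are filled in by
#' [simulate_agent()].
#'
#' @param config A [task_config()].
#' @param seed Integer seed (presentation order and counterbalancing).
#' @param subject Subject id stamped on every row.
#' @return Tibble with columns `subject, session, trial, pair, condition,
#'   trial_in_pair, good_side, p_good`.
#' @export
generate_task <- function(config = task_config(), seed = 1, subject = 1L) {
  withr::with_seed(seed, {
    sessions <- lapply(seq_len(config$n_sessions), function(s) {
      np <- config$pairs_per_session
      reps <- config$reps_per_pair
      cond <- rep(c("reward", "punishment"), each = np / 2)
      order_idx <- sample(rep(seq_len(np), reps))
      # counterbalanced side of the favourable cue within each pair
      side_pool <- lapply(seq_len(np), function(p) {
        sample(rep(c("left", "right"), length.out = reps))
      })
      taken <- integer(np)
      side <- character(length(order_idx))
      tin <- integer(length(order_idx))
      for (i in seq_along(order_idx)) {
        p <- order_idx[i]
        taken[p] <- taken[p] + 1L
        side[i] <- side_pool[[p]][taken[p]]
        tin[i] <- taken[p]
      }
      tibble::tibble(subject = as.integer(subject), session = s,
                     trial = seq_along(order_idx), pair = order_idx,
                     condition = cond[order_idx], trial_in_pair = tin,
                     good_side = side, p_good = config$contingency)
    })
    dplyr::bind_rows(sessions)
  })
}

#' Draw outcomes for repeatedly choosing one cue of a pair
#'
#' Samples from the pair's outcome contingency as if the given cue were
#' chosen on every trial: the favourable outcome (+1 for reward pairs, 0
#' for punishment pairs) occurs with probability `p_good` for the good
#' cue and `1 - p_good` for the bad cue; otherwise the unfavourable
#' outcome (0 or -1) is delivered. This is the same sampling rule
#' [simulate_agent()] applies trial by trial.
#'
#' @param n Number of draws.
#' @param condition `"reward"` or `"punishment"`.
#' @param cue `"good"` (the higher-probability cue) or `"bad"`.
#' @param config A [task_config()] supplying the contingency.
#' @param seed Integer seed.
#' @return Numeric vector of outcomes.
#' @export
draw_outcomes <- function(n, condition = c("reward", "punishment"),
                          cue = c("good", "bad"), config = task_config(),
                          seed = 1) {
  condition <- match.arg(condition)
  cue <- match.arg(cue)
  p_fav <- if (cue == "good") config$contingency else 1 - config$contingency
  fav <- withr::with_seed(seed, runif(n) < p_fav)
  if (condition == "reward") ifelse(fav, 1, 0) else ifelse(fav, 0, -1)
}

#' Coupling specification for synthetic neural epochs
#'
#' Describes how a simulated contact (or pair of contacts) is coupled to
#' prediction-error signals: which PE it tracks, with what gain, at what
#' post-outcome latency and temporal width, on top of AR(1) background
#' noise. For directed pairs, `lag` sets the sample-to-sample transfer
#' delay and `condition` optionally gates the coupling to reward or
#' punishment trials only.
#'
#' @param target `"none"`, `"RPE"`, `"PPE"` or `"both"` (condition-
#'   appropriate PE on every trial, i.e. the full signed PE).
#' @param mode `"local"`, `"redundant_pair"`, `"synergistic_pair"` or
#'   `"directed_pair"`.
#' @param gain Coupling amplitude, in units of noise SD per PE unit.
#' @param latency,width Center (s, post-outcome) and SD (s) of the
#'   Gaussian response kernel.
#' @param lag Transfer delay (s) for directed pairs.
#' @param ar AR(1) coefficient of the background noise, in `[0, 1)`.
#' @param noise_sd Stationary SD of the background noise.
#' @param shared_frac Fraction of the PE-driven source shared by a
#'   redundant pair.
#' @param condition Optional gating condition for directed pairs.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(target = c("none", "RPE", "PPE", "both"),
                          mode = c("local", "redundant_pair",
                                   "synergistic_pair", "directed_pair"),
                          gain = 1, latency = 0.5, width = 0.15,
                          lag = 0.15, ar = 0.9, noise_sd = 1,
                          shared_frac = 0.8, condition = NULL) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  if (gain < 0) abort("`gain` must be >= 0.")
  if (ar < 0 || ar >= 1) abort("`ar` must lie in [0, 1).")
  structure(list(target = target, mode = mode, gain = gain,
                 latency = latency, width = width, lag = lag, ar = ar,
                 noise_sd = noise_sd, shared_frac = shared_frac,
                 condition = condition),
            class = "coupling_spec")
}

#' Default outcome-locked epoch time axis
#'
#' -0.5 to +1.5 s around outcome onset at 256 Hz, the rate the analysis
#' operates at.
#'
#' @param sfreq Sampling rate in Hz.
#' @param t_min,t_max Window edges in seconds.
#' @return Numeric time axis including `t = 0`.
#' @export
default_epoch_time <- function(sfreq = 256, t_min = -0.5, t_max = 1.5) {
  seq(t_min, t_max, by = 1 / sfreq)
}

# n_trials x n_time matrix of AR(1) noise with stationary SD `sd`
ar1_noise <- function(n_trials, n_time, ar, sd = 1) {
  innov <- matrix(rnorm(n_trials * n_time, sd = sd * sqrt(1 - ar^2)),
                  n_time, n_trials)
  x <- stats::filter(innov, ar, method = "recursive")
  t(matrix(as.numeric(x), n_time, n_trials))
}

# per-trial coupling amplitude for a target PE; 0 off-condition
target_amplitude <- function(pe, target, gain) {
  amp <- switch(target,
    none = rep(0, nrow(pe)),
    RPE = ifelse(pe$condition == "reward", pe$delta, 0),
    PPE = ifelse(pe$condition == "punishment", pe$delta, 0),
    both = pe$delta)
  gain * amp
}

gauss_kernel <- function(time, latency, width) {
  exp(-(time - latency)^2 / (2 * width^2))
}

#' Construct an epoch array
#'
#' Container for outcome-locked single-trial power: a contacts x trials x
#' time array plus its time axis, sampling rate and per-contact metadata.
#'
#' @param power 3-D numeric array, dimensions (contact, trial, time).
#' @param time Time axis in seconds relative to outcome onset.
#' @param sfreq Sampling rate (Hz).
#' @param contacts Tibble of contact metadata (one row per contact;
#'   typically `contact`, `subject`, `roi`).
#' @return An `epoch_array` object.
#' @export
epoch_array <- function(power, time, sfreq,
                        contacts = tibble::tibble(contact = seq_len(dim(power)[1]))) {
  stopifnot(length(dim(power)) == 3, dim(power)[3] == length(time),
            dim(power)[1] == nrow(contacts))
  structure(list(power = power, time = time, sfreq = sfreq,
                 contacts = tibble::as_tibble(contacts)),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("epoch_array: %d contact(s) x %d trial(s) x %d samples @ %g Hz, t in [%.3g, %.3g] s\n",
              d[1], d[2], d[3], x$sfreq, min(x$time), max(x$time)))
  invisible(x)
}

#' @export
as_tibble.epoch_array <- function(x, ...) {
  d <- dim(x$power)
  out <- tibble::tibble(
    contact = rep(x$contacts$contact, times = d[2] * d[3]),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time = rep(x$time, each = d[1] * d[2]),
    power = as.numeric(x$power))
  out
}

#' Generate outcome-locked gamma-power surrogate epochs
#'
#' Each contact's single-trial signal is AR(1) noise plus a Gaussian
#' temporal kernel at the contact's response latency whose per-trial
#' amplitude is `gain * PE` for the contact's target (identity coupling;
#' any monotone transform is equivalent for the rank-based estimators
#' downstream). Contacts with `target = "none"` carry noise only.
#'
#' @param pe Prediction-error table from [compute_prediction_errors()]
#'   (one subject).
#' @param specs A [coupling_spec()] or list of them, one per contact.
#' @param time Epoch time axis (s), spanning the response latency.
#' @param sfreq Sampling rate (Hz).
#' @param seed Integer seed; identical seeds give identical arrays.
#' @param contacts Optional contact metadata tibble.
#' @return An [epoch_array()] with `length(specs)` contacts.
#' @export
generate_epochs <- function(pe, specs, time = default_epoch_time(),
                            sfreq = 256, seed = 1, contacts = NULL) {
  if (inherits(specs, "coupling_spec")) specs <- list(specs)
  n_trials <- nrow(pe)
  n_time <- length(time)
  for (sp in specs) {
    if (sp$latency < min(time) || sp$latency > max(time)) {
      abort("coupling latency outside the epoch window.")
    }
  }
  power <- array(0, c(length(specs), n_trials, n_time))
  withr::with_seed(seed, {
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      amp <- target_amplitude(pe, sp$target, sp$gain)
      kern <- gauss_kernel(time, sp$latency, sp$width)
      power[j, , ] <- ar1_noise(n_trials, n_time, sp$ar, sp$noise_sd) +
        outer(amp, kern)
    }
  })
  if (is.null(contacts)) {
    contacts <- tibble::tibble(contact = seq_along(specs),
                               subject = pe$subject[1],
                               target = vapply(specs, `[[`, "", "target"))
  }
  epoch_array(power, time, sfreq, contacts)
}

#' Redundant pair: two contacts sharing one PE-driven source
#'
#' Both contacts receive the same PE-driven response (scaled by
#' `shared_frac`) plus independent AR(1) noise, so they carry overlapping
#' information about the PE: their interaction information about it is
#' negative by construction at the response latency. With
#' `shared_frac = 0` the pair is pure noise.
#'
#' @inheritParams generate_epochs
#' @param spec A [coupling_spec()] (mode `"redundant_pair"`).
#' @return A two-contact [epoch_array()].
#' @export
make_redundant_pair <- function(pe, spec, time = default_epoch_time(),
                                sfreq = 256, seed = 1) {
  n_trials <- nrow(pe)
  n_time <- length(time)
  amp <- spec$shared_frac * target_amplitude(pe, spec$target, spec$gain)
  kern <- gauss_kernel(time, spec$latency, spec$width)
  sig <- outer(amp, kern)
  withr::with_seed(seed, {
    power <- array(0, c(2, n_trials, n_time))
    power[1, , ] <- sig + ar1_noise(n_trials, n_time, spec$ar, spec$noise_sd)
    power[2, , ] <- sig + ar1_noise(n_trials, n_time, spec$ar, spec$noise_sd)
  })
  epoch_array(power, time, sfreq,
              tibble::tibble(contact = 1:2, subject = pe$subject[1],
                             target = spec$target))
}

#' Synergistic pair: signal-plus-noise and the shared noise itself
#'
#' Contact 1 carries the PE-driven response buried in a shared AR(1) noise
#' source; contact 2 carries (mostly) that same noise. Alone, contact 2
#' tells nothing about the PE, but conditioning on it denoises contact 1,
#' so the joint information exceeds the sum of the parts: interaction
#' information is positive by construction at the latency.
#'
#' @inheritParams make_redundant_pair
#' @param own_sd SD of each contact's private noise on top of the shared
#'   source.
#' @return A two-contact [epoch_array()].
#' @export
make_synergistic_pair <- function(pe, spec, time = default_epoch_time(),
                                  sfreq = 256, seed = 1, own_sd = 0.3) {
  n_trials <- nrow(pe)
  n_time <- length(time)
  amp <- target_amplitude(pe, spec$target, spec$gain)
  kern <- gauss_kernel(time, spec$latency, spec$width)
  sig <- outer(amp, kern)
  withr::with_seed(seed, {
    shared <- ar1_noise(n_trials, n_time, spec$ar, spec$noise_sd)
    power <- array(0, c(2, n_trials, n_time))
    power[1, , ] <- sig + shared + ar1_noise(n_trials, n_time, spec$ar, own_sd)
    power[2, , ] <- shared + ar1_noise(n_trials, n_time, spec$ar, own_sd)
  })
  epoch_array(power, time, sfreq,
              tibble::tibble(contact = 1:2, subject = pe$subject[1],
                             target = spec$target))
}

#' Directed pair: lagged within-trial drive from X to Y
#'
#' Contact Y reproduces contact X delayed by `spec$lag` (scaled by
#' `spec$gain`) plus its own AR(1) noise, within every epoch; transfer
#' entropy from X to Y therefore exceeds the reverse direction, and the
#' delay profile peaks at the generating lag. When `spec$condition` is
#' set, the drive applies only on trials of that condition
#' (condition-gated information flow).
#'
#' @inheritParams make_redundant_pair
#' @param conditions Optional per-trial condition labels (required when
#'   `spec$condition` is set); usually `pe$condition`.
#' @param n_trials Number of trials (defaults to `length(conditions)`).
#' @return A two-contact [epoch_array()] (contact 1 = source X,
#'   contact 2 = target Y).
#' @export
make_directed_pair <- function(spec, n_trials = NULL, conditions = NULL,
                               time = default_epoch_time(), sfreq = 256,
                               seed = 1) {
  if (is.null(n_trials)) n_trials <- length(conditions)
  if (n_trials < 1) abort("`n_trials` (or `conditions`) required.")
  lag_smp <- round(spec$lag * sfreq)
  n_time <- length(time)
  if (lag_smp < 1 || lag_smp >= n_time) {
    abort("directed-pair lag outside the epoch window.")
  }
  a <- rep(spec$gain, n_trials)
  if (!is.null(spec$condition)) {
    if (is.null(conditions)) {
      abort("`conditions` needed for condition-gated coupling.")
    }
    a <- ifelse(conditions == spec$condition, spec$gain, 0)
  }
  withr::with_seed(seed, {
    x <- ar1_noise(n_trials, n_time, spec$ar, spec$noise_sd)
    y <- ar1_noise(n_trials, n_time, spec$ar, spec$noise_sd)
    shift <- cbind(matrix(0, n_trials, lag_smp),
                   x[, seq_len(n_time - lag_smp), drop = FALSE])
    y <- y + a * shift
  })
  power <- array(0, c(2, n_trials, n_time))
  power[1, , ] <- x
  power[2, , ] <- y
  epoch_array(power, time, sfreq,
              tibble::tibble(contact = 1:2, subject = 1L,
                             role = c("source", "target")))
}

# 1/f ("pink") noise via FFT amplitude shaping
pink_noise <- function(n, sd = 1) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)              # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  sd * x / sd(x)
}

#' Generate raw trial-locked voltage traces with a known gamma envelope
#'
#' A 75 Hz carrier (random phase per trial) amplitude-modulated by a
#' ground-truth envelope, on top of 1/f background noise. Serves as a test
#' input for the spectral chain: multitaper gamma power on these traces
#' should recover the envelope.
#'
#' @param envelope Numeric vector (length of `time`) or function of time
#'   giving the nonnegative modulation envelope.
#' @param n_trials Number of trials.
#' @param time Time axis (s).
#' @param sfreq Sampling rate (512 or 1024 Hz acquisition rates are
#'   typical).
#' @param carrier_freq Carrier frequency (Hz, default 75 = gamma band
#'   center).
#' @param noise_sd SD of the 1/f background.
#' @param seed Integer seed.
#' @return List with `traces` (trials x time), `envelope`, `time`,
#'   `sfreq`.
#' @export
generate_raw_lfp <- function(envelope, n_trials = 50,
                             time = seq(0, 1, by = 1 / 1024), sfreq = 1024,
                             carrier_freq = 75, noise_sd = 0.1, seed = 1) {
  env <- if (is.function(envelope)) envelope(time) else envelope
  if (length(env) != length(time)) {
    abort("`envelope` must match the time axis length.")
  }
  n_time <- length(time)
  withr::with_seed(seed, {
    phases <- runif(n_trials, 0, 2 * pi)
    traces <- t(vapply(seq_len(n_trials), function(i) {
      env * sin(2 * pi * carrier_freq * time + phases[i]) +
        pink_noise(n_time, noise_sd)
    }, numeric(n_time)))
  })
  list(traces = traces, envelope = env, time = time, sfreq = sfreq)
}

#' Simulate a multi-subject cohort with known coupling structure
#'
#' For each subject: a task is generated, an agent simulated, prediction
#' errors computed, and epochs built from a list of coupling entries.
#' Each entry is a list with a `spec` ([coupling_spec()]) and `roi`
#' (single ROI for local mode, length-2 for pair modes); pair modes add
#' two contacts (one per ROI).
#'
#' @param n_subjects Number of subjects.
#' @param couplings List of coupling entries (see details above).
#' @param config A [task_config()].
#' @param params Agent [qlearn_params()].
#' @param time,sfreq Epoch time axis and rate.
#' @param seed Master seed; per-subject and per-stage seeds are derived
#'   from it.
#' @return Tibble with one row per subject and list-columns `trials`,
#'   `pe`, `epochs`.
#' @export
simulate_cohort <- function(n_subjects, couplings,
                            config = task_config(),
                            params = qlearn_params(0.3, 0.2, 0.1),
                            time = default_epoch_time(), sfreq = 256,
                            seed = 1) {
  subjects <- lapply(seq_len(n_subjects), function(s) {
    s_seed <- derive_seed(seed, s)
    task <- generate_task(config, seed = s_seed, subject = s)
    trials <- simulate_agent(task, params, seed = s_seed + 1L)
    pe <- compute_prediction_errors(trials, params)
    parts <- lapply(seq_along(couplings), function(j) {
      cp <- couplings[[j]]
      sp <- cp$spec
      ep_seed <- derive_seed(s_seed, j + 1L)
      ep <- switch(sp$mode,
        local = generate_epochs(pe, sp, time, sfreq, seed = ep_seed),
        redundant_pair = make_redundant_pair(pe, sp, time, sfreq,
                                             seed = ep_seed),
        synergistic_pair = make_synergistic_pair(pe, sp, time, sfreq,
                                                 seed = ep_seed),
        directed_pair = make_directed_pair(sp, conditions = pe$condition,
                                           time = time, sfreq = sfreq,
                                           seed = ep_seed))
      roi <- rep(cp$roi, length.out = dim(ep$power)[1])
      ep$contacts$roi <- roi
      ep$contacts$subject <- s
      ep$contacts$coupling <- j
      ep
    })
    power <- array(0, c(sum(vapply(parts, function(p) dim(p$power)[1], 0L)),
                        nrow(pe), length(time)))
    contacts <- dplyr::bind_rows(lapply(parts, `[[`, "contacts"))
    k <- 0L
    for (p in parts) {
      nc <- dim(p$power)[1]
      power[k + seq_len(nc), , ] <- p$power
      k <- k + nc
    }
    contacts$contact <- seq_len(nrow(contacts))
    list(trials = trials, pe = pe,
         epochs = epoch_array(power, time, sfreq, contacts))
  })
  tibble::tibble(subject = seq_len(n_subjects),
                 trials = lapply(subjects, `[[`, "trials"),
                 pe = lapply(subjects, `[[`, "pe"),
                 epochs = lapply(subjects, `[[`, "epochs"))
}

#' Write / read epoch arrays as text
#'
#' Long-format CSV of the power values plus a JSON sidecar holding the
#' time axis, sampling rate and contact metadata, so arrays round-trip
#' through plain-text files.
#'
#' @param x An [epoch_array()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `read_epochs()` returns an `epoch_array`; `write_epochs()` the
#'   path, invisibly.
#' @export
write_epochs <- function(x, path) {
  write.csv(as_tibble.epoch_array(x), path, row.names = FALSE)
  meta <- list(time = x$time, sfreq = x$sfreq, contacts = x$contacts)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  contacts <- tibble::as_tibble(meta$contacts)
  n_c <- nrow(contacts)
  n_tr <- max(df$trial)
  n_t <- length(meta$time)
  power <- array(df$power, c(n_c, n_tr, n_t))
  epoch_array(power, meta$time, meta$sfreq, contacts)
}
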