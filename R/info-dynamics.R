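# Time-resolved, across-trials information measures on epoch arrays.
# At every time sample the across-trial distribution of gamma power is
# copula-normalized, so all estimators inherit the rank properties of the
# Gaussian-copula framework (monotone-transform invariance, bias
# correction). Closed-form log-determinant paths (gcmi.R) make whole time
# axes and permutation sets vectorizable.

# rank-normalize each column of an n x T matrix across trials, then center
normalize_trials <- function(mat) {
  n <- nrow(mat)
  r <- apply(mat, 2, rank, ties.method = "average")
  z <- qnorm(r / (n + 1))
  sweep(z, 2, colMeans(z))
}

new_info_series <- function(values, null, time, units, measure, target,
                            n_perm, seed) {
  structure(list(values = values, null = null, time = time,
                 units = units, measure = measure, target = target,
                 n_perm = n_perm, seed = seed),
            class = "info_series")
}

#' @export
print.info_series <- function(x, ...) {
  cat(sprintf("info_series [%s, target %s]: %d unit(s) x %d times, %d permutation(s)\n",
              x$measure, x$target, nrow(x$values), ncol(x$values), x$n_perm))
  invisible(x)
}

#' @export
as_tibble.info_series <- function(x, ...) {
  u <- x$units
  tibble::tibble(
    unit = rep(u$unit, times = length(x$time)),
    time = rep(x$time, each = nrow(u)),
    bits = as.numeric(x$values)) |>
    dplyr::left_join(u, by = "unit")
}

#' Plot an information time course
#'
#' Mean across units with a shaded SEM ribbon, against time from outcome
#' onset; the dashed line marks the mean of the permutation null.
#'
#' @param object An `info_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.info_series <- function(object, ...) {
  m <- colMeans(object$values)
  s <- apply(object$values, 2, sd) / sqrt(max(1, nrow(object$values)))
  df <- tibble::tibble(time = object$time, mean = m, sem = s)
  null_mean <- if (object$n_perm > 0) mean(object$null) else 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = null_mean, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, color = "grey60") +
    ggplot2::labs(x = "time from outcome (s)",
                  y = sprintf("%s (bits)", object$measure),
                  title = sprintf("%s about %s", object$measure,
                                  object$target))
}

#' Permutation scheme for information nulls
#'
#' Returns the trial-permutation index matrix used to build null
#' distributions: mutual information and interaction information shuffle
#' the prediction-error variable across trials; transfer entropy shuffles
#' the source signal's trials. Reproducible given the seed.
#'
#' @param n_trials Number of trials.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return `n_trials` x `n_perm` integer matrix of permuted indices.
#' @export
build_permutation_null <- function(n_trials, n_perm, seed = 1) {
  perm_indices(n_trials, n_perm, seed)
}

select_target_trials <- function(pe, target) {
  sel <- switch(target,
    RPE = which(pe$condition == "reward"),
    PPE = which(pe$condition == "punishment"),
    PE = seq_len(nrow(pe)))
  if (length(sel) < 20) {
    abort("fewer than 20 trials available for this target.")
  }
  sel
}

#' Time course of mutual information between power and prediction errors
#'
#' At each time sample, the Gaussian-copula MI between the across-trial
#' gamma power of each contact and the prediction error of the target
#' condition (RPE on reward trials, PPE on punishment trials), in bits.
#' The permutation null shuffles the PE across trials and re-estimates
#' with the same machinery.
#'
#' @param epochs An [epoch_array()] for one subject.
#' @param pe Prediction-error table aligned with the epoch trials.
#' @param target `"RPE"` or `"PPE"`.
#' @param n_perm Number of permutations for the null (0 to skip).
#' @param seed Seed for the permutation scheme.
#' @param bias_correct Apply the small-sample MI bias correction.
#' @return An `info_series` with one unit per contact.
#' @export
mi_timecourse <- function(epochs, pe, target = c("RPE", "PPE"),
                          n_perm = 1000, seed = 1, bias_correct = TRUE) {
  target <- match.arg(target)
  sel <- select_target_trials(pe, target)
  n <- length(sel)
  s <- copula_normalize(pe$delta[sel])
  s <- s - mean(s)
  vs <- sum(s^2) / (n - 1)
  n_c <- dim(epochs$power)[1]
  n_t <- length(epochs$time)
  values <- matrix(0, n_c, n_t)
  null <- array(0, c(n_c, n_t, max(n_perm, 0)))
  s_perm <- NULL
  if (n_perm > 0) {
    perms <- build_permutation_null(n, n_perm, seed)
    s_perm <- matrix(s[perms], n, n_perm)
  }
  for (cc in seq_len(n_c)) {
    gn <- normalize_trials(epochs$power[cc, sel, ])
    vx <- colSums(gn^2) / (n - 1)
    vxs <- drop(crossprod(gn, s)) / (n - 1)
    values[cc, ] <- mi11_bits(vx, vs, vxs, n, bias_correct)
    if (n_perm > 0) {
      vxs_p <- crossprod(gn, s_perm) / (n - 1)
      null[cc, , ] <- mi11_bits(vx, vs, vxs_p, n, bias_correct)
    }
  }
  units <- dplyr::mutate(epochs$contacts, unit = .data$contact,
                         .before = 1)
  new_info_series(values, null, epochs$time, units, "MI", target,
                  n_perm, seed)
}

default_pairs <- function(epochs) {
  contacts <- epochs$contacts
  cmb <- utils::combn(contacts$contact, 2)
  tibble::tibble(contact1 = cmb[1, ], contact2 = cmb[2, ])
}

#' Time course of interaction information for contact pairs
#'
#' For each pair of same-subject contacts and each time sample, the
#' interaction information `II = I(g1, g2; S) - I(g1; S) - I(g2; S)`
#' about the target prediction error, with the joint term computed on the
#' two-dimensional copula sample. Negative II means the pair carries
#' overlapping (redundant) information about the PE; positive II means
#' the joint carries more than the sum (synergy). Target `"PE"` uses all
#' trials with the signed prediction error (reward and punishment
#' concatenated).
#'
#' @inheritParams mi_timecourse
#' @param pairs Tibble with `contact1`, `contact2` columns (defaults to
#'   all within-subject pairs).
#' @param target `"RPE"`, `"PPE"` or `"PE"`.
#' @return An `info_series` with one unit per pair.
#' @export
interaction_information <- function(epochs, pe, pairs = NULL,
                                    target = c("RPE", "PPE", "PE"),
                                    n_perm = 1000, seed = 1,
                                    bias_correct = TRUE) {
  target <- match.arg(target)
  if (is.null(pairs)) pairs <- default_pairs(epochs)
  contacts <- epochs$contacts
  if ("subject" %in% names(contacts)) {
    subj <- contacts$subject[match(pairs$contact1, contacts$contact)]
    subj2 <- contacts$subject[match(pairs$contact2, contacts$contact)]
    if (any(subj != subj2)) {
      abort("pairs must be formed within a single subject.")
    }
  }
  sel <- select_target_trials(pe, target)
  n <- length(sel)
  s <- copula_normalize(pe$delta[sel])
  s <- s - mean(s)
  vs <- sum(s^2) / (n - 1)
  n_t <- length(epochs$time)
  n_pairs <- nrow(pairs)
  values <- matrix(0, n_pairs, n_t)
  null <- array(0, c(n_pairs, n_t, max(n_perm, 0)))
  s_perm <- NULL
  if (n_perm > 0) {
    perms <- build_permutation_null(n, n_perm, seed)
    s_perm <- matrix(s[perms], n, n_perm)
  }
  cache <- new.env(parent = emptyenv())
  get_norm <- function(cid) {
    key <- as.character(cid)
    if (is.null(cache[[key]])) {
      idx <- match(cid, contacts$contact)
      cache[[key]] <- normalize_trials(epochs$power[idx, sel, ])
    }
    cache[[key]]
  }
  for (p in seq_len(n_pairs)) {
    g1 <- get_norm(pairs$contact1[p])
    g2 <- get_norm(pairs$contact2[p])
    v11 <- colSums(g1^2) / (n - 1)
    v22 <- colSums(g2^2) / (n - 1)
    v12 <- colSums(g1 * g2) / (n - 1)
    v1s <- drop(crossprod(g1, s)) / (n - 1)
    v2s <- drop(crossprod(g2, s)) / (n - 1)
    values[p, ] <- mi21_bits(v11, v22, v12, vs, v1s, v2s, n, bias_correct) -
      mi11_bits(v11, vs, v1s, n, bias_correct) -
      mi11_bits(v22, vs, v2s, n, bias_correct)
    if (n_perm > 0) {
      v1s_p <- crossprod(g1, s_perm) / (n - 1)
      v2s_p <- crossprod(g2, s_perm) / (n - 1)
      null[p, , ] <-
        mi21_bits(v11, v22, v12, vs, v1s_p, v2s_p, n, bias_correct) -
        mi11_bits(v11, vs, v1s_p, n, bias_correct) -
        mi11_bits(v22, vs, v2s_p, n, bias_correct)
    }
  }
  units <- dplyr::mutate(pairs, unit = seq_len(n_pairs), .before = 1)
  if ("roi" %in% names(contacts)) {
    units$roi1 <- contacts$roi[match(pairs$contact1, contacts$contact)]
    units$roi2 <- contacts$roi[match(pairs$contact2, contacts$contact)]
  }
  if ("subject" %in% names(contacts)) {
    units$subject <- contacts$subject[match(pairs$contact1,
                                            contacts$contact)]
  }
  new_info_series(values, null, epochs$time, units, "II", target,
                  n_perm, seed)
}

#' Delay window for transfer entropy
#'
#' The interval of past delays the transfer entropy is averaged over
#' (default 116-236 ms, the empirically selected transfer interval), in
#' steps of `step` samples at the epoch rate.
#'
#' @param d1,d2 Window edges in seconds, `0 < d1 < d2`.
#' @param step Delay grid step in samples.
#' @return A `delay_window` list.
#' @export
delay_window <- function(d1 = 0.116, d2 = 0.236, step = 1L) {
  if (d1 <= 0 || d2 <= d1) abort("need 0 < d1 < d2.")
  structure(list(d1 = d1, d2 = d2, step = as.integer(step)),
            class = "delay_window")
}

# internal core: TE time courses for one ordered pair on given trial rows.
# Returns list(values = numeric(n_t), null = n_t x n_perm).
te_core <- function(gx, gy, delays_smp, valid_t, n, n_t, n_perm, perms,
                    bias_correct) {
  values <- rep(NA_real_, n_t)
  null <- if (n_perm > 0) matrix(NA_real_, n_t, n_perm) else NULL
  for (it in valid_t) {
    y_t <- gy[, it]
    xp <- gx[, it - delays_smp, drop = FALSE]
    yp <- gy[, it - delays_smp, drop = FALSE]
    vy <- sum(y_t^2) / (n - 1)
    vx <- colSums(xp^2) / (n - 1)
    vz <- colSums(yp^2) / (n - 1)
    vxy <- drop(crossprod(xp, y_t)) / (n - 1)
    vxz <- colSums(xp * yp) / (n - 1)
    vyz <- drop(crossprod(yp, y_t)) / (n - 1)
    values[it] <- mean(cmi111_bits(vx, vy, vz, vxy, vxz, vyz, n,
                                   bias_correct))
    if (n_perm > 0) {
      for (p in seq_len(n_perm)) {
        xs <- xp[perms[, p], , drop = FALSE]
        vxy_p <- drop(crossprod(xs, y_t)) / (n - 1)
        vxz_p <- colSums(xs * yp) / (n - 1)
        null[it, p] <- mean(cmi111_bits(vx, vy, vz, vxy_p, vxz_p, vyz, n,
                                        bias_correct))
      }
    }
  }
  list(values = values, null = null)
}

#' Delay-averaged transfer entropy between contact pairs
#'
#' Directed information flow under the Wiener-Granger principle: at each
#' target time `t` and each delay `d` in the window, the Gaussian-copula
#' conditional MI `I(x[t-d]; y[t] | y[t-d])` is estimated across trials,
#' and the reported TE at `t` is the mean over delays. Computed for each
#' ordered pair in `pairs` (source -> target). Restrict `condition` to
#' estimate `TE_Rew` / `TE_Pun` separately. Times whose earliest delayed
#' sample falls before the epoch start are returned as `NA`. The
#' permutation null shuffles the source signal across trials.
#'
#' @inheritParams mi_timecourse
#' @param pairs Tibble with `source`, `target` contact columns.
#' @param pe Trial table with a `condition` column (needed when
#'   `condition` is set).
#' @param condition Optional `"reward"` or `"punishment"` trial subset.
#' @param window A [delay_window()].
#' @param times Optional subset of time samples (indices into the epoch
#'   time axis) at which to evaluate; default all valid samples.
#' @return An `info_series` with one unit per directed pair.
#' @export
transfer_entropy <- function(epochs, pairs, pe = NULL, condition = NULL,
                             window = delay_window(), n_perm = 0,
                             seed = 1, times = NULL, bias_correct = TRUE) {
  contacts <- epochs$contacts
  sfreq <- epochs$sfreq
  delays_smp <- seq(ceiling(window$d1 * sfreq), floor(window$d2 * sfreq),
                    by = window$step)
  n_t <- length(epochs$time)
  if (max(delays_smp) >= n_t) abort("delay window longer than the epoch.")
  sel <- seq_len(dim(epochs$power)[2])
  if (!is.null(condition)) {
    if (is.null(pe)) abort("`pe` needed to subset trials by condition.")
    sel <- which(pe$condition == condition)
  }
  n <- length(sel)
  if (n < 20) abort("fewer than 20 trials in the requested subset.")
  valid_t <- seq(max(delays_smp) + 1L, n_t)
  if (!is.null(times)) valid_t <- intersect(valid_t, times)
  perms <- if (n_perm > 0) build_permutation_null(n, n_perm, seed) else NULL
  cache <- new.env(parent = emptyenv())
  get_norm <- function(cid) {
    key <- as.character(cid)
    if (is.null(cache[[key]])) {
      idx <- match(cid, contacts$contact)
      cache[[key]] <- normalize_trials(epochs$power[idx, sel, ])
    }
    cache[[key]]
  }
  n_pairs <- nrow(pairs)
  values <- matrix(NA_real_, n_pairs, n_t)
  null <- array(NA_real_, c(n_pairs, n_t, max(n_perm, 0)))
  for (p in seq_len(n_pairs)) {
    res <- te_core(get_norm(pairs$source[p]), get_norm(pairs$target[p]),
                   delays_smp, valid_t, n, n_t, n_perm, perms,
                   bias_correct)
    values[p, ] <- res$values
    if (n_perm > 0) null[p, , ] <- res$null
  }
  units <- dplyr::mutate(pairs, unit = seq_len(n_pairs), .before = 1)
  if ("roi" %in% names(contacts)) {
    units$roi_source <- contacts$roi[match(pairs$source, contacts$contact)]
    units$roi_target <- contacts$roi[match(pairs$target, contacts$contact)]
  }
  if ("subject" %in% names(contacts)) {
    units$subject <- contacts$subject[match(pairs$source,
                                            contacts$contact)]
  }
  new_info_series(values, null, epochs$time, units, "TE",
                  condition %||% "all", n_perm, seed)
}

#' Delay profile of transfer entropy
#'
#' Evaluates the per-delay TE (no averaging) on a delay grid at the
#' requested times, averaged over those times, and locates the peak
#' delay for each ordered pair. On lagged fixtures the profile peaks at
#' the generating lag.
#'
#' @inheritParams transfer_entropy
#' @param delays_s Numeric vector of delays to probe (s).
#' @param times Time-sample indices over which profiles are averaged.
#' @return List with `profile` (tibble: pair, delay, te) and `peak`
#'   (tibble: pair, peak delay in seconds and samples).
#' @export
te_delay_profile <- function(epochs, pairs, delays_s, times,
                             pe = NULL, condition = NULL,
                             bias_correct = TRUE) {
  contacts <- epochs$contacts
  sfreq <- epochs$sfreq
  delays_smp <- sort(unique(round(delays_s * sfreq)))
  delays_smp <- delays_smp[delays_smp >= 1]
  n_t <- length(epochs$time)
  sel <- seq_len(dim(epochs$power)[2])
  if (!is.null(condition)) {
    if (is.null(pe)) abort("`pe` needed to subset trials by condition.")
    sel <- which(pe$condition == condition)
  }
  n <- length(sel)
  times <- times[times > max(delays_smp)]
  if (!length(times)) abort("no valid time samples for this delay grid.")
  prof <- list()
  for (p in seq_len(nrow(pairs))) {
    ix <- match(pairs$source[p], contacts$contact)
    iy <- match(pairs$target[p], contacts$contact)
    gx <- normalize_trials(epochs$power[ix, sel, ])
    gy <- normalize_trials(epochs$power[iy, sel, ])
    te_d <- matrix(0, length(times), length(delays_smp))
    for (k in seq_along(times)) {
      it <- times[k]
      y_t <- gy[, it]
      xp <- gx[, it - delays_smp, drop = FALSE]
      yp <- gy[, it - delays_smp, drop = FALSE]
      te_d[k, ] <- cmi111_bits(
        colSums(xp^2) / (n - 1), sum(y_t^2) / (n - 1),
        colSums(yp^2) / (n - 1),
        drop(crossprod(xp, y_t)) / (n - 1),
        colSums(xp * yp) / (n - 1),
        drop(crossprod(yp, y_t)) / (n - 1), n, bias_correct)
    }
    prof[[p]] <- tibble::tibble(pair = p, source = pairs$source[p],
                                target = pairs$target[p],
                                delay_smp = delays_smp,
                                delay_s = delays_smp / sfreq,
                                te = colMeans(te_d))
  }
  profile <- dplyr::bind_rows(prof)
  peak <- profile |>
    dplyr::group_by(.data$pair, .data$source, .data$target) |>
    dplyr::slice_max(.data$te, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("pair", "source", "target",
                  peak_delay_smp = "delay_smp", peak_delay_s = "delay_s")
  list(profile = profile, peak = peak)
}

#' Combine information series across subjects
#'
#' Stacks per-subject `info_series` objects (same measure, target, time
#' axis and permutation count) into one series whose units span the
#' cohort, ready for random-effects group statistics.
#'
#' @param series List of `info_series` objects.
#' @return A single `info_series`.
#' @export
bind_info_series <- function(series) {
  stopifnot(length(series) >= 1)
  t0 <- series[[1]]$time
  for (s in series) {
    if (!isTRUE(all.equal(s$time, t0)) || s$n_perm != series[[1]]$n_perm) {
      abort("series must share time axis and permutation count.")
    }
  }
  values <- do.call(rbind, lapply(series, `[[`, "values"))
  n_perm <- series[[1]]$n_perm
  null <- array(0, c(nrow(values), length(t0), max(n_perm, 0)))
  k <- 0L
  units <- list()
  for (i in seq_along(series)) {
    nu <- nrow(series[[i]]$values)
    if (n_perm > 0) null[k + seq_len(nu), , ] <- series[[i]]$null
    u <- series[[i]]$units
    units[[i]] <- u
    k <- k + nu
  }
  units <- dplyr::bind_rows(units)
  units$unit <- seq_len(nrow(units))
  new_info_series(values, null, t0, units, series[[1]]$measure,
                  series[[1]]$target, n_perm, series[[1]]$seed)
}
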