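#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` Slepian tapers of length `n` with time half-
#' bandwidth product `nw`, as eigenvectors of the standard symmetric
#' tridiagonal formulation of the spectral-concentration problem. Tapers
#' are unit-energy and mutually orthogonal.
#'
#' @param n Taper length in samples.
#' @param nw Time half-bandwidth product (e.g. 5 for 9 tapers).
#' @param k Number of tapers (at most `2 * nw - 1` are well concentrated).
#' @return An `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  t_idx <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  diag_off <- t_idx[-1] * (n - t_idx[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    # polarity convention: positive mean (even orders) or positive initial
    # slope (odd orders); irrelevant for power but keeps output stable
    if (sum(v) < 0 || (abs(sum(v)) < 1e-8 && v[2] - v[1] < 0)) v <- -v
    tapers[, j] <- v
  }
  tapers
}

# complex "same"-length convolution via FFT
conv_same <- function(x, kern) {
  n <- length(x)
  w <- length(kern)
  m <- n + w - 1
  y <- fft(fft(c(x, rep(0, w - 1))) * fft(c(kern, rep(0, n - 1))),
           inverse = TRUE) / m
  half <- (w - 1) %/% 2
  y[half + seq_len(n)]
}

#' Single-trial multitaper gamma-band power
#'
#' Band power centered at `f_center` (default 75 Hz) from a sliding
#' multitaper estimate: 200 ms windows multiplied by 9 orthogonal Slepian
#' tapers (time-bandwidth 10, i.e. +/- 25 Hz smoothing covering
#' 50-100 Hz), demodulated at the center frequency and averaged over
#' tapers. Each output sample is the power of the window centered on it;
#' the half-window at each edge cannot be centered and is returned as
#' `NA`.
#'
#' @param traces Numeric vector (one trial) or matrix (trials x time).
#' @param sfreq Sampling rate in Hz (>= 256).
#' @param f_center Band center frequency (Hz).
#' @param t_window Window duration in seconds (default 0.2, i.e. 15
#'   cycles at 75 Hz).
#' @param time_bandwidth Taper time-bandwidth parameter (window duration
#'   times full bandwidth; 10 gives 9 usable tapers).
#' @param n_tapers Number of Slepian tapers.
#' @return Power time course(s), same shape as the input, nonnegative
#'   where defined, `NA` in the half-window edges.
#' @export
multitaper_gamma_power <- function(traces, sfreq, f_center = 75,
                                   t_window = 0.2, time_bandwidth = 10,
                                   n_tapers = 9) {
  vec_in <- is.null(dim(traces))
  x <- if (vec_in) matrix(traces, nrow = 1) else as.matrix(traces)
  n_time <- ncol(x)
  win <- round(t_window * sfreq)
  if (win %% 2 == 0) win <- win + 1L
  if (n_time < win) abort("trace shorter than one multitaper window.")
  tapers <- dpss_tapers(win, time_bandwidth / 2, n_tapers)
  s <- seq_len(win) - (win + 1) / 2
  kernels <- tapers * exp(-1i * 2 * pi * f_center * s / sfreq)
  half <- (win - 1) %/% 2
  out <- matrix(NA_real_, nrow(x), n_time)
  for (tr in seq_len(nrow(x))) {
    acc <- numeric(n_time)
    for (k in seq_len(n_tapers)) {
      acc <- acc + Mod(conv_same(x[tr, ], rev(kernels[, k])))^2
    }
    p <- acc / n_tapers
    p[seq_len(half)] <- NA_real_
    p[n_time - seq_len(half) + 1] <- NA_real_
    out[tr, ] <- p
  }
  if (vec_in) drop(out) else out
}

#' Bipolar derivation between adjacent contacts
#'
#' Differences between adjacent contacts of one electrode: derivation `k`
#' is `contact[k + 1] - contact[k]`, rejecting signals common to both
#' (volume conduction) and localizing activity between the two leads. An
#' electrode with `n` contacts yields `n - 1` derivations.
#'
#' @param traces Matrix (contacts x time) or 3-D array (contacts x trials
#'   x time), contacts ordered by their index along the electrode.
#' @param labels Optional per-contact labels used to name the derivations.
#' @return List with `traces` (same shape, one fewer contact) and `pairs`
#'   (tibble naming the contact pair behind each derivation). A single-
#'   contact electrode gives an empty result with a warning.
#' @export
bipolar_reference <- function(traces, labels = NULL) {
  d <- dim(traces)
  n_c <- d[1]
  if (is.null(labels)) labels <- as.character(seq_len(n_c))
  if (n_c < 2) {
    warn("electrode has a single contact: no bipolar derivation possible.")
    empty <- if (length(d) == 3) array(0, c(0, d[2], d[3])) else
      matrix(0, 0, d[2])
    return(list(traces = empty,
                pairs = tibble::tibble(anode = character(),
                                       cathode = character())))
  }
  idx_hi <- 2:n_c
  idx_lo <- 1:(n_c - 1)
  out <- if (length(d) == 3) {
    traces[idx_hi, , , drop = FALSE] - traces[idx_lo, , , drop = FALSE]
  } else {
    traces[idx_hi, , drop = FALSE] - traces[idx_lo, , drop = FALSE]
  }
  list(traces = out,
       pairs = tibble::tibble(anode = labels[idx_hi],
                              cathode = labels[idx_lo]))
}

#' Downsample a power time course with anti-alias filtering
#'
#' Decimates to the target rate (default 256 Hz, the rate all information
#' analyses run at). Integer ratios use zero-phase FIR low-pass filtering
#' followed by sample picking; the picked samples are phase-aligned so
#' that `t = 0` remains on the output grid when a time axis is supplied.
#' Non-integer ratios fall back to polyphase resampling with a warning.
#'
#' @param power Numeric vector or matrix (trials x time), no `NA`s (trim
#'   the multitaper edge samples first).
#' @param sfreq Source sampling rate (Hz, >= `target`).
#' @param target Target rate (Hz).
#' @param time Optional source time axis; when given, the output is a
#'   list with `power` and the downsampled `time`.
#' @return Downsampled power (and time axis if supplied).
#' @export
downsample_power <- function(power, sfreq, target = 256, time = NULL) {
  vec_in <- is.null(dim(power))
  x <- if (vec_in) matrix(power, nrow = 1) else as.matrix(power)
  if (sfreq < target) abort("source rate below target rate.")
  if (sfreq == target) {
    out <- if (vec_in) drop(x) else x
    return(if (is.null(time)) out else list(power = out, time = time))
  }
  q <- sfreq / target
  n <- ncol(x)
  if (abs(q - round(q)) < 1e-9) {
    q <- as.integer(round(q))
    start <- 1L
    if (!is.null(time)) {
      i0 <- which.min(abs(time))
      start <- ((i0 - 1L) %% q) + 1L
    }
    b <- signal::fir1(30, 1 / q)
    keep <- seq(start, n, by = q)
    out <- t(apply(x, 1, function(row) {
      signal::filtfilt(as.numeric(b), 1, row)[keep]
    }))
    if (length(keep) == 1) out <- matrix(out, nrow = nrow(x))
  } else {
    warn("non-integer decimation ratio: using polyphase resampling.")
    frac <- round(target * 1000)
    num <- frac / gcd_int(frac, round(sfreq * 1000))
    den <- round(sfreq * 1000) / gcd_int(frac, round(sfreq * 1000))
    out <- t(apply(x, 1, function(row) signal::resample(row, num, den)))
    keep <- seq(1, n, length.out = ncol(out))
  }
  out <- if (vec_in) drop(out) else out
  if (is.null(time)) out else list(power = out, time = time[keep])
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Savitzky-Golay smoothing of power time courses
#'
#' Order-3 polynomial smoothing over an 11-sample window (the classical
#' odd-window formulation closest to a 10-point filter). Reproduces cubic
#' trends exactly while attenuating sample-to-sample noise.
#'
#' @param power Numeric vector or matrix (trials x time).
#' @param window Filter length in samples (odd).
#' @param order Polynomial order.
#' @return Smoothed power, same shape.
#' @export
smooth_power <- function(power, window = 11, order = 3) {
  vec_in <- is.null(dim(power))
  x <- if (vec_in) matrix(power, nrow = 1) else as.matrix(power)
  if (ncol(x) < window) abort("series shorter than the smoothing window.")
  out <- t(apply(x, 1, function(row) {
    signal::sgolayfilt(row, p = order, n = window)
  }))
  if (vec_in) drop(out) else out
}
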