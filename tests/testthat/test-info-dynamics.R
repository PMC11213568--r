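test_that("MI time courses localize coupling and respect their null", {
  pe <- fixture_pe_reward(200)
  tm <- default_epoch_time()
  i_lat <- t_index(tm, 0.5)
  peaks <- vapply(1:10, function(s) {
    ep <- generate_epochs(pe, coupling_spec("RPE", gain = 2), seed = s)
    mi <- mi_timecourse(ep, pe, "RPE", n_perm = 0)
    tm[which.max(mi$values[1, ])]
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 0.5), 0.05)
  expect_true(all(abs(peaks - 0.5) < 0.15))
  # uncoupled contact stays below its permutation null nearly everywhere
  ep0 <- generate_epochs(pe, coupling_spec("none"), seed = 31)
  mi0 <- mi_timecourse(ep0, pe, "RPE", n_perm = 200, seed = 32)
  null95 <- apply(mi0$null[1, , ], 1, quantile, 0.95)
  expect_gte(mean(mi0$values[1, ] < null95), 0.9)
  # coupled contact clears the null at the latency
  ep1 <- generate_epochs(pe, coupling_spec("RPE", gain = 2), seed = 33)
  mi1 <- mi_timecourse(ep1, pe, "RPE", n_perm = 200, seed = 34)
  expect_gt(mi1$values[1, i_lat],
            quantile(mi1$null[1, i_lat, ], 0.95))
  # trial-count precondition
  expect_error(mi_timecourse(ep1, pe[1:10, ], "RPE"), "20 trials")
})

test_that("all estimators are invariant to monotone transforms of power", {
  pe <- fixture_pe_reward(80)
  tms <- seq(-0.1, 0.8, by = 1 / 256)
  ep <- generate_epochs(pe, list(coupling_spec("RPE", gain = 1),
                                 coupling_spec("RPE", gain = 0.5)),
                        time = tms, seed = 41)
  ep_exp <- ep
  ep_exp$power <- exp(ep$power)           # strictly increasing transform
  mi_a <- mi_timecourse(ep, pe, "RPE", n_perm = 0)
  mi_b <- mi_timecourse(ep_exp, pe, "RPE", n_perm = 0)
  expect_equal(mi_a$values, mi_b$values)
  ii_a <- interaction_information(ep, pe, target = "RPE", n_perm = 0)
  ii_b <- interaction_information(ep_exp, pe, target = "RPE", n_perm = 0)
  expect_equal(ii_a$values, ii_b$values)
  times <- seq(t_index(tms, 0.4), t_index(tms, 0.7), by = 4)
  te_a <- transfer_entropy(ep, tibble::tibble(source = 1, target = 2),
                           times = times)
  te_b <- transfer_entropy(ep_exp, tibble::tibble(source = 1, target = 2),
                           times = times)
  expect_equal(te_a$values, te_b$values)
})

test_that("interaction information is symmetric and handles duplicates", {
  pe <- fixture_pe_reward(200)
  tm <- default_epoch_time()
  i_lat <- t_index(tm, 0.5)
  red <- make_redundant_pair(pe, coupling_spec("RPE", "redundant_pair",
                                               gain = 2), seed = 51)
  ii_ab <- interaction_information(red, pe, target = "RPE", n_perm = 0)
  ii_ba <- interaction_information(red, pe,
                                   pairs = tibble::tibble(contact1 = 2,
                                                          contact2 = 1),
                                   target = "RPE", n_perm = 0)
  expect_equal(ii_ab$values, ii_ba$values)
  # near-duplicate sources: II collapses to -I(g1; S)
  ep <- generate_epochs(pe, coupling_spec("RPE", gain = 2), seed = 52)
  jit <- withr::with_seed(53, array(rnorm(length(ep$power), sd = 0.02),
                                    dim(ep$power)))
  dup <- epoch_array(array(c(ep$power, ep$power + jit),
                           c(2, dim(ep$power)[2], dim(ep$power)[3])),
                     ep$time, ep$sfreq,
                     tibble::tibble(contact = 1:2))
  # build the two-contact array explicitly (contact 2 = jittered copy)
  dup$power[1, , ] <- ep$power[1, , ]
  dup$power[2, , ] <- ep$power[1, , ] + jit[1, , ]
  ii_dup <- interaction_information(dup, pe, target = "RPE", n_perm = 0)
  mi <- mi_timecourse(ep, pe, "RPE", n_perm = 0)
  expect_equal(ii_dup$values[1, i_lat], -mi$values[1, i_lat],
               tolerance = 0.1)
  # cross-subject pairs are rejected
  bad <- dup
  bad$contacts <- tibble::tibble(contact = 1:2, subject = c(1, 2))
  expect_error(interaction_information(bad, pe, target = "RPE"),
               "single subject")
})

test_that("interaction information matches the Gaussian co-information closed form", {
  # x_i = s + e_i: II = 0.5 * (log2(1 + 2r) - 2 log2(1 + r)), r = var_s/var_e
  n <- 10000
  r <- 1
  withr::with_seed(61, {
    s <- rnorm(n)
    x1 <- s + rnorm(n)
    x2 <- s + rnorm(n)
  })
  cx1 <- copula_normalize(x1)
  cx2 <- copula_normalize(x2)
  cs <- copula_normalize(s)
  ii <- c(mi_gg(cbind(cx1, cx2), cs)) - c(mi_gg(cx1, cs)) -
    c(mi_gg(cx2, cs))
  ii_true <- 0.5 * (log2(1 + 2 * r) - 2 * log2(1 + r))
  expect_lt(abs(ii - ii_true), 0.02)
})

test_that("transfer entropy is directional and flips under time reversal", {
  tm <- default_epoch_time()
  times <- seq(t_index(tm, 0.4), t_index(tm, 1.2), by = 16)
  dp <- make_directed_pair(coupling_spec(mode = "directed_pair", gain = 0.8,
                                         lag = 0.15), n_trials = 200,
                           seed = 71)
  fw <- transfer_entropy(dp, tibble::tibble(source = 1, target = 2),
                         times = times)
  rv <- transfer_entropy(dp, tibble::tibble(source = 2, target = 1),
                         times = times)
  expect_gt(mean(fw$values[1, times]), mean(rv$values[1, times]))
  # early samples without a full delayed past are flagged invalid
  expect_true(all(is.na(fw$values[1, 1:30])))
  # time reversal exchanges the dominant direction
  dp_rev <- dp
  dp_rev$power <- dp$power[, , rev(seq_along(tm))]
  fw_r <- transfer_entropy(dp_rev, tibble::tibble(source = 1, target = 2),
                           times = times)
  rv_r <- transfer_entropy(dp_rev, tibble::tibble(source = 2, target = 1),
                           times = times)
  expect_gt(mean(rv_r$values[1, times], na.rm = TRUE),
            mean(fw_r$values[1, times], na.rm = TRUE))
  # independent pair stays inside its permutation null
  dp0 <- make_directed_pair(coupling_spec(mode = "directed_pair", gain = 0),
                            n_trials = 150, seed = 72)
  te0 <- transfer_entropy(dp0, tibble::tibble(source = 1, target = 2),
                          n_perm = 100, seed = 73, times = times[1:5])
  for (it in times[1:5]) {
    expect_lt(te0$values[1, it], quantile(te0$null[1, it, ], 0.99))
  }
})

test_that("transfer entropy matches the Gaussian-Granger closed form", {
  # y_t = a x_{t-lag} + n_t with x, n independent AR(1) processes:
  # the covariance of (x_{t-d}, y_t, y_{t-d}) at d = lag has a closed form,
  # from which the conditional MI follows analytically.
  a <- 0.8
  ar <- 0.9
  lag <- 8
  n_tr <- 10000
  n_time <- 40
  withr::with_seed(81, {
    x <- test_ar1(n_tr, n_time, ar)
    nn <- test_ar1(n_tr, n_time, ar)
  })
  y <- nn
  y[, (lag + 1):n_time] <- y[, (lag + 1):n_time] +
    a * x[, 1:(n_time - lag)]
  it <- n_time
  xp <- x[, it - lag]
  yt <- y[, it]
  yp <- y[, it - lag]
  est <- c(gcmi(xp, yt, yp))
  # analytic covariance entries (unit-variance AR(1), cov(x_t, x_{t+k}) = ar^k)
  vx <- 1
  vy <- a^2 + 1
  c_xp_yt <- a
  c_xp_yp <- a * ar^lag
  c_yt_yp <- a^2 * ar^lag + ar^lag
  S <- matrix(c(vx, c_xp_yt, c_xp_yp,
                c_xp_yt, vy, c_yt_yp,
                c_xp_yp, c_yt_yp, vy), 3, 3)
  det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2]^2
  cmi_true <- 0.5 * log2(det2(S[c(1, 3), c(1, 3)]) * det2(S[c(2, 3), c(2, 3)]) /
                           (S[3, 3] * det(S)))
  expect_lt(abs(est - cmi_true), 0.02)
})

test_that("delay profiles peak at the generating lags", {
  tm <- default_epoch_time()
  times <- seq(t_index(tm, 0.4), t_index(tm, 1.2), by = 16)
  dp <- make_directed_pair(coupling_spec(mode = "directed_pair", gain = 0.8,
                                         lag = 0.15), n_trials = 200,
                           seed = 91)
  prof <- te_delay_profile(dp, tibble::tibble(source = 1, target = 2),
                           delays_s = seq(0.02, 0.4, by = 1 / 256),
                           times = times)
  expect_lte(abs(prof$peak$peak_delay_smp - round(0.15 * 256)), 2)
  # two couplings at 100 and 200 ms: bimodal profile
  n_tr <- 300
  withr::with_seed(92, {
    x <- test_ar1(n_tr, length(tm))
    nn <- test_ar1(n_tr, length(tm))
  })
  l1 <- round(0.1 * 256)
  l2 <- round(0.2 * 256)
  y <- nn
  y[, (l2 + 1):length(tm)] <- y[, (l2 + 1):length(tm)] +
    0.7 * x[, 1:(length(tm) - l2)]
  y[, (l1 + 1):length(tm)] <- y[, (l1 + 1):length(tm)] +
    0.7 * x[, 1:(length(tm) - l1)]
  pow <- array(0, c(2, n_tr, length(tm)))
  pow[1, , ] <- x
  pow[2, , ] <- y
  bi <- epoch_array(pow, tm, 256)
  prof2 <- te_delay_profile(bi, tibble::tibble(source = 1, target = 2),
                            delays_s = seq(0.05, 0.3, by = 1 / 256),
                            times = times)
  te_curve <- prof2$profile$te
  d_smp <- prof2$profile$delay_smp
  # local maxima within 2 samples of each generating lag
  is_peak <- which(diff(sign(diff(te_curve))) == -2) + 1
  peak_delays <- d_smp[is_peak]
  expect_true(any(abs(peak_delays - l1) <= 2))
  expect_true(any(abs(peak_delays - l2) <= 2))
})

test_that("permutation nulls are unbiased, exceeded by true effects, and reproducible", {
  pe <- fixture_pe_reward(200)
  tms <- seq(0.3, 0.7, by = 1 / 256)
  ep <- generate_epochs(pe, coupling_spec("RPE", gain = 2),
                        time = tms, sfreq = 256, seed = 101)
  mi <- mi_timecourse(ep, pe, "RPE", n_perm = 1000, seed = 102)
  # null centered at zero after bias correction
  expect_lt(abs(mean(mi$null)), 0.005)
  # the observed coupled MI clears the null 95th percentile at the latency
  i_lat <- t_index(tms, 0.5)
  expect_gt(mi$values[1, i_lat], quantile(mi$null[1, i_lat, ], 0.95))
  # identical seed, identical null
  mi2 <- mi_timecourse(ep, pe, "RPE", n_perm = 1000, seed = 102)
  expect_identical(mi$null, mi2$null)
  expect_error(build_permutation_null(100, 0), "n_perm")
})

test_that("info series bind across subjects and convert to tibbles", {
  pe <- fixture_pe_reward(60)
  tms <- seq(0, 0.4, by = 1 / 256)
  ep1 <- generate_epochs(pe, coupling_spec("RPE", latency = 0.2),
                         time = tms, seed = 111)
  ep2 <- generate_epochs(pe, coupling_spec("none", latency = 0.2),
                         time = tms, seed = 112)
  m1 <- mi_timecourse(ep1, pe, "RPE", n_perm = 10, seed = 1)
  m2 <- mi_timecourse(ep2, pe, "RPE", n_perm = 10, seed = 2)
  b <- bind_info_series(list(m1, m2))
  expect_equal(dim(b$values), c(2, length(tms)))
  expect_equal(b$values[2, ], m2$values[1, ])
  tb <- tibble::as_tibble(b)
  expect_equal(nrow(tb), 2 * length(tms))
  m3 <- mi_timecourse(ep2, pe, "RPE", n_perm = 5, seed = 2)
  expect_error(bind_info_series(list(m1, m3)), "permutation count")
  p <- autoplot(m1)
  expect_s3_class(p, "ggplot")
})
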