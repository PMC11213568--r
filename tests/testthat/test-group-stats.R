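# Synthetic info_series with Gaussian unit values and nulls, used to test
# the group machinery independently of the estimators.
fake_series <- function(n_units = 15, n_t = 100, n_perm = 200, seed = 1,
                        effect = NULL) {
  withr::with_seed(seed, {
    null <- array(rnorm(n_units * n_t * n_perm), c(n_units, n_t, n_perm))
    values <- matrix(rnorm(n_units * n_t), n_units, n_t)
  })
  if (!is.null(effect)) {
    values[, effect$window] <- values[, effect$window] + effect$size
  }
  infolearn:::new_info_series(values, null, seq_len(n_t) / 256,
                              tibble::tibble(unit = seq_len(n_units)),
                              "MI", "RPE", n_perm, seed)
}

test_that("group t statistics behave at the null and under injected effects", {
  s <- fake_series(seed = 2)
  # degenerate case: every unit exactly equals its permutation mean
  s0 <- s
  pm <- rowMeans(s0$null, dims = 2)
  s0$values <- pm
  for (p in seq_len(s0$n_perm)) s0$null[, , p] <- pm
  gt0 <- group_t_perm(s0)
  expect_true(all(gt0$t_obs[[1]] == 0))
  # permutation t distribution is centered on zero
  gt <- group_t_perm(s)
  expect_lt(abs(mean(gt$t_perm[[1]])), 0.1)
  # a uniform +3 null-SD effect in 20 units exceeds the cluster threshold
  se <- fake_series(n_units = 20, seed = 3,
                    effect = list(window = 40:60, size = 3))
  gte <- group_t_perm(se)
  thr <- quantile(gte$t_perm[[1]], 0.95)
  expect_true(all(gte$t_obs[[1]][40:60] > thr))
  # a single unit cannot form a group
  s1 <- fake_series(n_units = 1, seed = 4)
  expect_error(group_t_perm(s1), "at least 2 units")
})

test_that("cluster correction finds true windows and stays calibrated", {
  se <- fake_series(n_units = 20, n_t = 150, seed = 5,
                    effect = list(window = 30:106, size = 2.5))  # 300 ms
  gte <- group_t_perm(se)
  cl <- cluster_correct(gte$t_obs[[1]], gte$t_perm[[1]],
                        time = se$time)
  expect_gte(nrow(cl), 1)
  best <- cl[which.max(cl$mass), ]
  overlap <- length(intersect(best$start:best$end, 30:106)) / 77
  expect_gte(overlap, 0.8)
  expect_true(best$significant)
  # corrected p is monotone non-increasing in cluster mass
  if (nrow(cl) > 1) {
    o <- order(cl$mass, decreasing = TRUE)
    expect_true(all(diff(cl$p[o]) >= 0))
  }
  # sub-threshold series produce an empty cluster list
  s0 <- fake_series(seed = 6)
  gt0 <- group_t_perm(s0)
  cl0 <- cluster_correct(gt0$t_obs[[1]] * 0, gt0$t_perm[[1]])
  expect_equal(nrow(cl0), 0)
  # type-I calibration of the max-cluster correction on pure-null runs
  fp <- vapply(1:200, function(s) {
    sn <- fake_series(n_units = 12, n_t = 60, n_perm = 100, seed = 1000 + s)
    gtn <- group_t_perm(sn)
    cln <- cluster_correct(gtn$t_obs[[1]], gtn$t_perm[[1]])
    any(cln$significant)
  }, logical(1))
  expect_gte(mean(fp), 0.01)
  expect_lte(mean(fp), 0.10)
})

test_that("contact categorization recovers planted selectivity proportions", {
  pe <- fixture_pe(n_sessions = 2, seed = 120)
  tms <- seq(-0.25, 1, by = 1 / 256)
  specs <- c(replicate(6, coupling_spec("RPE", gain = 1.5), simplify = FALSE),
             replicate(6, coupling_spec("PPE", gain = 1.5), simplify = FALSE),
             replicate(3, coupling_spec("both", gain = 1.5), simplify = FALSE),
             replicate(15, coupling_spec("none"), simplify = FALSE))
  ep <- generate_epochs(pe, specs, time = tms, seed = 121)
  mir <- mi_timecourse(ep, pe, "RPE", n_perm = 200, seed = 122)
  mip <- mi_timecourse(ep, pe, "PPE", n_perm = 200, seed = 123)
  sel <- categorize_contacts(mir, mip)
  # proportions sum to one at every time point
  sums <- tapply(sel$proportions$prop,
                 sel$proportions$time, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # peak proportions within 10 points of the planted 20/20/10/50 percent
  peak <- vapply(c("RPE", "PPE", "Both"), function(l) {
    max(sel$proportions$prop[sel$proportions$label == l])
  }, numeric(1))
  expect_lt(abs(peak[["RPE"]] - 0.2), 0.1)
  expect_lt(abs(peak[["PPE"]] - 0.2), 0.1)
  expect_lt(abs(peak[["Both"]] - 0.1), 0.1)
  # overall labels recover the planted structure up to a few errors
  lab <- sel$contact_labels$label
  expect_gte(sum(lab[1:6] == "RPE"), 5)
  expect_gte(sum(lab[7:12] == "PPE"), 5)
  expect_gte(sum(lab[13:15] == "Both"), 2)
  # the all-null block stays mostly irrelevant (nominal false positives)
  expect_gte(mean(lab[16:30] == "Irrelevant"), 0.7)
  p <- autoplot(sel)
  expect_s3_class(p, "ggplot")
  # missing null is refused
  mir0 <- mi_timecourse(ep, pe, "RPE", n_perm = 0)
  expect_error(categorize_contacts(mir0, mip), "null")
})

test_that("II binning by selectivity isolates the planted categories", {
  # pair-level II values: strong positive synergy planted only in the
  # PPE-RPE and Mixed categories, noise elsewhere
  labels <- tibble::tibble(contact = 1:8,
                           label = c("RPE", "RPE", "PPE", "PPE",
                                     "Both", "Both", "RPE", "PPE"))
  pairs <- tibble::tibble(contact1 = c(1, 2, 3, 3, 7, 1, 5, 5, 6, 2),
                          contact2 = c(2, 7, 4, 8, 4, 3, 6, 1, 4, 8))
  n_t <- 50
  withr::with_seed(130, {
    vals <- matrix(rnorm(10 * n_t, sd = 0.005), 10, n_t)
  })
  cat_true <- c("RPE-RPE", "RPE-RPE", "PPE-PPE", "PPE-PPE", "PPE-RPE",
                "PPE-RPE", "Mixed", "Mixed", "Mixed", "PPE-RPE")
  planted <- cat_true %in% c("PPE-RPE", "Mixed")
  vals[planted, ] <- vals[planted, ] + 0.2
  ii <- infolearn:::new_info_series(
    vals, array(0, c(10, n_t, 0)), seq_len(n_t) / 256,
    tibble::tibble(unit = 1:10, contact1 = pairs$contact1,
                   contact2 = pairs$contact2),
    "II", "PE", 0, 1)
  res <- bin_ii_by_selectivity(ii, labels, window = c(0, 1))
  expect_setequal(res$category,
                  c("RPE-RPE", "PPE-PPE", "PPE-RPE", "Mixed"))
  expect_true(all(res$significant[res$category %in% c("PPE-RPE", "Mixed")]))
  expect_false(any(res$significant[res$category %in%
                                     c("RPE-RPE", "PPE-PPE")]))
  # pure-noise II: no category significant
  ii_null <- ii
  ii_null$values <- withr::with_seed(131,
                                     matrix(rnorm(10 * n_t, sd = 0.005),
                                            10, n_t))
  res_null <- bin_ii_by_selectivity(ii_null, labels, window = c(0, 1))
  expect_false(any(res_null$significant))
  # pairs with an irrelevant contact are excluded entirely
  lab_na <- labels
  lab_na$label[1] <- "Irrelevant"
  res_na <- bin_ii_by_selectivity(ii, lab_na, window = c(0, 1))
  expect_true(sum(res_na$n_pairs) < sum(res$n_pairs))
})

test_that("condition contrasts detect gated transfer and stay calibrated", {
  tm <- default_epoch_time()
  times <- seq(t_index(tm, 0.3), t_index(tm, 1.2), by = 16)
  # punishment-gated directed coupling, several subjects
  fw_pun <- list()
  fw_rew <- list()
  for (s in 1:6) {
    pe <- fixture_pe(n_sessions = 2, seed = 140 + s)
    dp <- make_directed_pair(coupling_spec(mode = "directed_pair",
                                           gain = 0.8,
                                           condition = "punishment"),
                             conditions = pe$condition, seed = 150 + s)
    pr <- tibble::tibble(source = 1, target = 2)
    fw_pun[[s]] <- transfer_entropy(dp, pr, pe = pe,
                                    condition = "punishment",
                                    times = times)
    fw_rew[[s]] <- transfer_entropy(dp, pr, pe = pe, condition = "reward",
                                    times = times)
  }
  te_pun <- bind_info_series(fw_pun)
  te_rew <- bind_info_series(fw_rew)
  ct <- condition_contrast(te_pun, te_rew, n_perm = 200, seed = 160)
  expect_true(any(ct$a_gt_b$significant))
  expect_false(any(ct$b_gt_a$significant))
  # identical series: no clusters at all
  ct0 <- condition_contrast(te_pun, te_pun, n_perm = 100, seed = 161)
  expect_equal(nrow(ct0$a_gt_b), 0)
  expect_equal(nrow(ct0$b_gt_a), 0)
  # calibration on null paired data, per direction
  fp_a <- fp_b <- logical(200)
  for (s in 1:200) {
    sa <- fake_series(n_units = 10, n_t = 60, n_perm = 1, seed = 2000 + s)
    sb <- fake_series(n_units = 10, n_t = 60, n_perm = 1, seed = 3000 + s)
    ctn <- condition_contrast(sa, sb, n_perm = 100, seed = s)
    fp_a[s] <- any(ctn$a_gt_b$significant)
    fp_b[s] <- any(ctn$b_gt_a$significant)
  }
  expect_gte(mean(fp_a), 0.005)
  expect_lte(mean(fp_a), 0.10)
  expect_lte(mean(fp_b), 0.10)
  # mismatched units are refused
  s_small <- fake_series(n_units = 4, seed = 9)
  expect_error(condition_contrast(te_pun, s_small), "units")
})

test_that("subject reproducibility counts subjects with an effect", {
  units <- tibble::tibble(unit = 1:12,
                          subject = rep(1:6, each = 2),
                          roi = rep(c("aINS", "dlPFC"), 6))
  # effect present in every subject
  rep_all <- subject_reproducibility(rep(TRUE, 12), units)
  expect_true(all(rep_all$proportion == 1))
  # effect in half the subjects (subjects 1-3 only)
  sig_half <- units$subject <= 3
  rep_half <- subject_reproducibility(sig_half, units)
  expect_true(all(abs(rep_half$proportion - 0.5) <= 1 / 6))
  # no effects anywhere
  rep_none <- subject_reproducibility(rep(FALSE, 12), units)
  expect_true(all(rep_none$proportion == 0))
  expect_error(subject_reproducibility(rep(TRUE, 12),
                                       dplyr::select(units, -subject)),
               "subject")
})
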