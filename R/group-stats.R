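# Random-effects group inference on information time courses. Units
# (contacts for MI, pairs for II/TE) are treated as replicates; each unit
# brings its own permutation null, and the group statistic is a one-sample
# t against the permutation mean, cluster-corrected over time against the
# max-cluster-mass permutation distribution.

#' Group-level t statistics against the permutation mean
#'
#' At each time point, the observed statistic is a one-sample t of the
#' units' values minus their own permutation means; the identical
#' statistic computed on every permutation slice builds the null t
#' distribution used for cluster correction.
#'
#' @param series An `info_series` (from [mi_timecourse()],
#'   [interaction_information()] or [transfer_entropy()]) with a
#'   permutation null attached.
#' @param by Optional name of a grouping column in `series$units`
#'   (e.g. `"roi"`); default treats all units as one group.
#' @return A `group_t` object: tibble of groups with list-columns
#'   `t_obs` (numeric over time) and `t_perm` (time x permutation
#'   matrix).
#' @export
group_t_perm <- function(series, by = NULL) {
  if (series$n_perm < 1) abort("series carries no permutation null.")
  groups <- if (is.null(by)) {
    rep("all", nrow(series$values))
  } else {
    as.character(series$units[[by]])
  }
  perm_mean <- rowMeans(series$null, dims = 2)
  d_obs <- series$values - perm_mean
  n_t <- ncol(series$values)
  n_perm <- series$n_perm
  one_group <- function(idx) {
    k <- length(idx)
    if (k < 2) abort("grouped t-test needs at least 2 units per group.")
    t_of <- function(m) {
      mu <- colMeans(m)
      s2 <- (colSums(m^2) - k * mu^2) / (k - 1)
      out <- mu / sqrt(s2 / k)
      out[mu == 0 & s2 <= 0] <- 0  # degenerate: no deviation at all
      out
    }
    t_obs <- t_of(d_obs[idx, , drop = FALSE])
    t_perm <- matrix(0, n_t, n_perm)
    pm <- perm_mean[idx, , drop = FALSE]
    for (p in seq_len(n_perm)) {
      slice <- series$null[idx, , p, drop = FALSE]
      dim(slice) <- dim(slice)[1:2]
      t_perm[, p] <- t_of(slice - pm)
    }
    list(t_obs = t_obs, t_perm = t_perm)
  }
  glist <- split(seq_along(groups), groups)
  res <- lapply(glist, one_group)
  structure(tibble::tibble(
    group = names(glist),
    n_units = vapply(glist, length, integer(1)),
    t_obs = lapply(res, `[[`, "t_obs"),
    t_perm = lapply(res, `[[`, "t_perm")),
    time = series$time, class = c("group_t", "tbl_df", "tbl", "data.frame"))
}

run_clusters <- function(stat, threshold) {
  above <- !is.na(stat) & stat > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(start = starts[keep], end = ends[keep],
                 mass = vapply(keep, function(i) {
                   sum(stat[starts[i]:ends[i]])
                 }, numeric(1)))
}

#' Cluster-based permutation correction of a t time series
#'
#' The cluster-forming threshold is the `percentile`-th percentile of the
#' pooled permutation t-values; contiguous supra-threshold runs in the
#' observed series form clusters whose mass is the summed t. Corrected
#' p-values compare each observed mass with the distribution of maximum
#' cluster masses across permutations. Use `tail = "neg"` to test
#' negative deflections (e.g. redundancy-dominated interaction
#' information); the series is sign-flipped internally and masses are
#' reported on the flipped scale.
#'
#' @param t_obs Observed t values over time.
#' @param t_perm Time x permutation matrix of null t values.
#' @param time Optional time axis for reporting cluster extents in
#'   seconds.
#' @param alpha Significance level for the `significant` flag.
#' @param percentile Cluster-forming percentile of the null t
#'   distribution.
#' @param tail `"pos"` or `"neg"`.
#' @return A `cluster_result`: tibble of clusters (`start`, `end` sample
#'   indices, `t_start`/`t_end` seconds when `time` given, `mass`, `p`,
#'   `significant`) with the threshold and permutation count as
#'   attributes. Empty when nothing exceeds threshold.
#' @export
cluster_correct <- function(t_obs, t_perm, time = NULL, alpha = 0.05,
                            percentile = 95, tail = c("pos", "neg")) {
  tail <- match.arg(tail)
  if (tail == "neg") {
    t_obs <- -t_obs
    t_perm <- -t_perm
  }
  threshold <- quantile(t_perm, percentile / 100, na.rm = TRUE, names = FALSE)
  obs <- run_clusters(t_obs, threshold)
  max_null <- apply(t_perm, 2, function(col) {
    cl <- run_clusters(col, threshold)
    if (nrow(cl)) max(cl$mass) else 0
  })
  n_perm <- ncol(t_perm)
  obs$p <- vapply(obs$mass, function(m) {
    (1 + sum(max_null >= m)) / (1 + n_perm)
  }, numeric(1))
  obs$significant <- obs$p < alpha
  if (!is.null(time)) {
    obs$t_start <- time[obs$start]
    obs$t_end <- time[obs$end]
  }
  structure(obs, threshold = threshold, n_perm = n_perm, alpha = alpha,
            tail = tail,
            class = c("cluster_result", class(tibble::tibble())))
}

#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' Cluster test of a whole information series, per group
#'
#' Convenience composition of [group_t_perm()] and [cluster_correct()]:
#' one cluster result per group of units.
#'
#' @inheritParams group_t_perm
#' @inheritParams cluster_correct
#' @return Named list of `cluster_result`s, one per group.
#' @export
group_cluster_test <- function(series, by = NULL, alpha = 0.05,
                               percentile = 95, tail = "pos") {
  gt <- group_t_perm(series, by = by)
  out <- lapply(seq_len(nrow(gt)), function(i) {
    cluster_correct(gt$t_obs[[i]], gt$t_perm[[i]],
                    time = attr(gt, "time"), alpha = alpha,
                    percentile = percentile, tail = tail)
  })
  names(out) <- gt$group
  out
}

# per-contact significance mask: cluster correction of the contact's own
# information values against its own permutation null
contact_sig_mask <- function(series, alpha = 0.05, percentile = 95) {
  n_u <- nrow(series$values)
  n_t <- ncol(series$values)
  sig <- matrix(FALSE, n_u, n_t)
  for (u in seq_len(n_u)) {
    cl <- cluster_correct(series$values[u, ],
                          series$null[u, , ], alpha = alpha,
                          percentile = percentile, tail = "pos")
    for (i in seq_len(nrow(cl))) {
      if (cl$significant[i]) sig[u, cl$start[i]:cl$end[i]] <- TRUE
    }
  }
  sig
}

#' Categorize contacts by prediction-error selectivity
#'
#' Each contact is tested against its own permutation null (cluster
#' correction over time) separately for the RPE and the PPE series; the
#' combination of significances assigns, per contact and time point, one
#' of four labels: RPE-specific, PPE-specific, Both, or Irrelevant.
#' Per-ROI label proportions over time (summing to 1) and an overall
#' per-contact label (significant anywhere for one target, the other, or
#' both) are also returned.
#'
#' @param mi_rpe,mi_ppe `info_series` for the two targets on the same
#'   contacts, with permutation nulls.
#' @param alpha Contact-level significance level.
#' @param percentile Cluster-forming percentile.
#' @return A `selectivity` object: list with `labels` (contact x time
#'   character matrix), `proportions` (tibble roi x time x label),
#'   `contact_labels` (tibble with one row per contact) and the two
#'   significance masks.
#' @export
categorize_contacts <- function(mi_rpe, mi_ppe, alpha = 0.05,
                                percentile = 95) {
  if (mi_rpe$n_perm < 1 || mi_ppe$n_perm < 1) {
    abort("both series need permutation nulls.")
  }
  if (nrow(mi_rpe$values) != nrow(mi_ppe$values)) {
    abort("both targets must be estimated on the same contacts.")
  }
  sig_r <- contact_sig_mask(mi_rpe, alpha, percentile)
  sig_p <- contact_sig_mask(mi_ppe, alpha, percentile)
  labels <- matrix("Irrelevant", nrow(sig_r), ncol(sig_r))
  labels[sig_r & !sig_p] <- "RPE"
  labels[!sig_r & sig_p] <- "PPE"
  labels[sig_r & sig_p] <- "Both"
  units <- mi_rpe$units
  roi <- if ("roi" %in% names(units)) units$roi else rep("all", nrow(units))
  lv <- c("RPE", "PPE", "Both", "Irrelevant")
  props <- lapply(unique(roi), function(r) {
    idx <- which(roi == r)
    counts <- vapply(lv, function(l) colMeans(labels[idx, , drop = FALSE] == l),
                     numeric(ncol(labels)))
    tibble::tibble(roi = r,
                   time = rep(mi_rpe$time, times = length(lv)),
                   label = rep(lv, each = length(mi_rpe$time)),
                   prop = as.numeric(counts))
  })
  any_r <- rowSums(sig_r) > 0
  any_p <- rowSums(sig_p) > 0
  overall <- dplyr::case_when(any_r & any_p ~ "Both",
                              any_r ~ "RPE",
                              any_p ~ "PPE",
                              TRUE ~ "Irrelevant")
  structure(list(labels = labels,
                 proportions = dplyr::bind_rows(props),
                 contact_labels = dplyr::mutate(units, label = overall),
                 sig_rpe = sig_r, sig_ppe = sig_p,
                 time = mi_rpe$time),
            class = "selectivity")
}

#' Plot selectivity proportions over time
#'
#' @param object A `selectivity` object.
#' @param ... Unused.
#' @return A ggplot of stacked label proportions per ROI.
#' @export
autoplot.selectivity <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$time, y = .data$prop,
                               fill = .data$label)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "time from outcome (s)", y = "proportion of contacts")
}

#' Bin pairwise interaction information by local selectivity
#'
#' Partitions the pairs of a full-PE interaction-information series into
#' four categories according to the selectivity labels of their two
#' contacts (RPE-RPE, PPE-PPE, PPE-RPE, and Mixed for any combination
#' involving a Both-selective contact); pairs with an Irrelevant contact
#' are dropped. Within each category the per-pair mean II over the given
#' time window is tested against 0 (one-sample t), and p-values are
#' Benjamini-Hochberg corrected across the categories present.
#'
#' @param ii An `info_series` of interaction information (one unit per
#'   pair, with `contact1`/`contact2` unit columns).
#' @param selectivity A `selectivity` object (or its `contact_labels`
#'   tibble) covering the paired contacts.
#' @param window Two-element time range (s) over which II is averaged.
#' @param alpha Significance level after FDR.
#' @return Tibble with one row per non-empty category: pair count, mean
#'   II, t statistic, dof, raw and FDR-corrected p, significance.
#' @export
bin_ii_by_selectivity <- function(ii, selectivity, window,
                                  alpha = 0.05) {
  labels <- if (inherits(selectivity, "selectivity")) {
    selectivity$contact_labels
  } else {
    selectivity
  }
  lab <- labels$label[match(ii$units$contact1, labels$contact)]
  lab2 <- labels$label[match(ii$units$contact2, labels$contact)]
  category <- dplyr::case_when(
    lab == "Irrelevant" | lab2 == "Irrelevant" ~ NA_character_,
    lab == "Both" | lab2 == "Both" ~ "Mixed",
    lab == lab2 & lab == "RPE" ~ "RPE-RPE",
    lab == lab2 & lab == "PPE" ~ "PPE-PPE",
    TRUE ~ "PPE-RPE")
  win_idx <- which(ii$time >= window[1] & ii$time <= window[2])
  pair_mean <- rowMeans(ii$values[, win_idx, drop = FALSE])
  keep <- !is.na(category)
  df <- tibble::tibble(category = category[keep], ii = pair_mean[keep])
  res <- df |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_ii = mean(.data$ii),
                     sd_ii = sd(.data$ii), .groups = "drop") |>
    dplyr::filter(.data$n_pairs >= 2) |>
    dplyr::mutate(t = .data$mean_ii / (.data$sd_ii / sqrt(.data$n_pairs)),
                  dof = .data$n_pairs - 1,
                  p = 2 * pt(abs(.data$t), .data$dof, lower.tail = FALSE),
                  p_fdr = p.adjust(.data$p, method = "BH"),
                  significant = .data$p_fdr < alpha)
  res
}

#' Paired condition contrast with cluster correction
#'
#' Tests, per time point, the paired difference between two information
#' series estimated on the same units under two conditions (e.g.
#' `TE_Pun` vs `TE_Rew`). The null exchanges the condition labels within
#' units at random (sign flips of the paired differences), and cluster
#' correction is applied separately to each direction of the contrast.
#'
#' @param series_a,series_b `info_series` on identical units.
#' @param n_perm Number of label exchanges.
#' @param seed Seed for the exchanges.
#' @param alpha,percentile Cluster-correction settings.
#' @return List with `a_gt_b` and `b_gt_a` `cluster_result`s and the
#'   observed t series.
#' @export
condition_contrast <- function(series_a, series_b, n_perm = 1000,
                               seed = 1, alpha = 0.05, percentile = 95) {
  if (nrow(series_a$values) != nrow(series_b$values)) {
    abort("the two series must share their units.")
  }
  d <- series_a$values - series_b$values
  keep_t <- which(colSums(is.na(d)) == 0)
  k <- nrow(d)
  if (k < 2) abort("paired contrast needs at least 2 units.")
  t_of <- function(m) {
    mu <- colMeans(m)
    s2 <- (colSums(m^2) - k * mu^2) / (k - 1)
    out <- mu / sqrt(s2 / k)
    out[mu == 0 & s2 <= 0] <- 0
    out
  }
  n_t_all <- ncol(d)
  t_obs <- rep(NA_real_, n_t_all)
  t_obs[keep_t] <- t_of(d[, keep_t, drop = FALSE])
  flips <- withr::with_seed(seed, {
    matrix(sample(c(-1, 1), k * n_perm, replace = TRUE), k, n_perm)
  })
  t_perm <- matrix(NA_real_, n_t_all, n_perm)
  for (p in seq_len(n_perm)) {
    t_perm[keep_t, p] <- t_of(flips[, p] * d[, keep_t, drop = FALSE])
  }
  list(a_gt_b = cluster_correct(t_obs, t_perm, time = series_a$time,
                                alpha = alpha, percentile = percentile,
                                tail = "pos"),
       b_gt_a = cluster_correct(t_obs, t_perm, time = series_a$time,
                                alpha = alpha, percentile = percentile,
                                tail = "neg"),
       t_obs = t_obs, time = series_a$time)
}

#' Inter-subject reproducibility of an effect
#'
#' Fraction of subjects contributing at least one significant unit, per
#' ROI (or any grouping column of the unit table).
#'
#' @param significant Logical vector, one entry per unit.
#' @param units Unit tibble with a `subject` column.
#' @param by Grouping column name (default `"roi"` when present).
#' @return Tibble with group, number of subjects sampled, number with an
#'   effect, and the proportion.
#' @export
subject_reproducibility <- function(significant, units, by = NULL) {
  if (!"subject" %in% names(units)) abort("unit table lacks `subject`.")
  if (is.null(by)) by <- if ("roi" %in% names(units)) "roi" else NULL
  grp <- if (is.null(by)) rep("all", nrow(units)) else
    as.character(units[[by]])
  tibble::tibble(group = grp, subject = units$subject,
                 significant = significant) |>
    dplyr::group_by(.data$group, .data$subject) |>
    dplyr::summarise(any_sig = any(.data$significant), .groups = "drop") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     n_with_effect = sum(.data$any_sig),
                     proportion = mean(.data$any_sig), .groups = "drop")
}
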