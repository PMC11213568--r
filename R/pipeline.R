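#' Configuration for a full simulated-cohort analysis run
#'
#' Bundles every stage's options: the task layout, the generating agent
#' parameters, the coupling structure of the synthetic cohort, fitting
#' options, estimator settings and the master seed from which each
#' stage's seed is derived deterministically. The configuration
#' round-trips through JSON unchanged.
#'
#' @param task A [task_config()].
#' @param params Generating agent [qlearn_params()].
#' @param couplings List of coupling entries (see [simulate_cohort()]).
#' @param n_subjects Number of simulated subjects.
#' @param n_perm Permutations for information nulls.
#' @param alpha Significance level for cluster tests.
#' @param seed Master seed.
#' @param stages Character subset of
#'   `c("simulate", "fit", "analyze", "group")`.
#' @param measures Which estimators the analyze stage runs
#'   (`"mi"`, `"ii"`, `"te"`).
#' @param fit_starts Multistart count for the fitting stage.
#' @param window TE [delay_window()].
#' @param te_time_range,te_time_step Time range (s) and step (samples)
#'   of the TE evaluation grid.
#' @param time Epoch time axis.
#' @param sfreq Epoch sampling rate.
#' @return A `run_config` list.
#' @export
run_config <- function(task = task_config(n_sessions = 2),
                       params = qlearn_params(0.3, 0.2, 0.1),
                       couplings = list(),
                       n_subjects = 8, n_perm = 200, alpha = 0.05,
                       seed = 1,
                       stages = c("simulate", "fit", "analyze", "group"),
                       measures = c("mi", "ii", "te"),
                       fit_starts = 5,
                       window = delay_window(),
                       te_time_range = c(0, 1), te_time_step = 4L,
                       time = default_epoch_time(), sfreq = 256) {
  bad <- setdiff(stages, c("simulate", "fit", "analyze", "group"))
  if (length(bad)) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  structure(list(task = task, params = params, couplings = couplings,
                 n_subjects = n_subjects, n_perm = n_perm, alpha = alpha,
                 seed = seed, stages = stages, measures = measures,
                 fit_starts = fit_starts, window = window,
                 te_time_range = te_time_range,
                 te_time_step = as.integer(te_time_step),
                 time = time, sfreq = sfreq),
            class = "run_config")
}

pair_mode <- function(sp) sp$mode %in% c("redundant_pair",
                                         "synergistic_pair",
                                         "directed_pair")

#' Run the simulate / fit / analyze / group pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort:
#' simulation of behavior and epochs, per-subject Q-learning fits
#' (prediction errors are recomputed under the fitted parameters when
#' the fit stage is enabled), information estimation (MI per contact;
#' II and TE per configured pair coupling), and group-level cluster
#' statistics with a qualitative sign summary per coupling. Fully
#' deterministic given the config's master seed. When `out_dir` is
#' given, tabular results and a manifest (config hash, derived seeds,
#' file checksums, versions) are written as CSV/JSON.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A `pipeline_result` list with elements `cohort`, `fits`,
#'   `mi`, `ii`, `te`, `group`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stages <- config$stages
  res <- list(config = config)

  cohort <- simulate_cohort(config$n_subjects, config$couplings,
                            config = config$task, params = config$params,
                            time = config$time, sfreq = config$sfreq,
                            seed = derive_seed(config$seed, 1))
  res$cohort <- cohort

  if ("fit" %in% stages) {
    fits <- lapply(seq_len(config$n_subjects), function(s) {
      fit_qlearning(cohort$trials[[s]], n_starts = config$fit_starts,
                    seed = derive_seed(config$seed, 100 + s))
    })
    res$fits <- dplyr::bind_rows(lapply(seq_along(fits), function(s) {
      dplyr::mutate(tidy(fits[[s]]), subject = s, .before = 1)
    }))
    # prediction errors under the per-subject fitted parameters
    cohort$pe <- lapply(seq_len(config$n_subjects), function(s) {
      compute_prediction_errors(cohort$trials[[s]], fits[[s]]$params)
    })
    res$cohort <- cohort
  }

  if ("analyze" %in% stages) {
    n_perm <- config$n_perm
    if ("mi" %in% config$measures) {
      mi <- lapply(c(RPE = "RPE", PPE = "PPE"), function(tg) {
        bind_info_series(lapply(seq_len(config$n_subjects), function(s) {
          mi_timecourse(cohort$epochs[[s]], cohort$pe[[s]], target = tg,
                        n_perm = n_perm,
                        seed = derive_seed(config$seed, 200 + s))
        }))
      })
      res$mi <- mi
    }
    pair_ids <- which(vapply(config$couplings,
                             function(cp) pair_mode(cp$spec), logical(1)))
    ii <- list()
    te <- list()
    for (j in pair_ids) {
      sp <- config$couplings[[j]]$spec
      pair_of <- function(s) {
        cts <- cohort$epochs[[s]]$contacts
        ids <- cts$contact[cts$coupling == j]
        tibble::tibble(contact1 = ids[1], contact2 = ids[2])
      }
      if (sp$mode %in% c("redundant_pair", "synergistic_pair") &&
          "ii" %in% config$measures) {
        targets <- if (sp$mode == "synergistic_pair") "PE" else
          c("RPE", "PPE")
        ii[[as.character(j)]] <- lapply(
          stats::setNames(targets, targets), function(tg) {
            bind_info_series(lapply(seq_len(config$n_subjects), function(s) {
              interaction_information(cohort$epochs[[s]], cohort$pe[[s]],
                                      pairs = pair_of(s), target = tg,
                                      n_perm = n_perm,
                                      seed = derive_seed(config$seed,
                                                         300 + s))
            }))
          })
      }
      if (sp$mode == "directed_pair" && "te" %in% config$measures) {
        t_idx <- which(config$time >= config$te_time_range[1] &
                         config$time <= config$te_time_range[2])
        t_idx <- t_idx[seq(1, length(t_idx), by = config$te_time_step)]
        dirs <- list(fwd = c(1, 2), rev = c(2, 1))
        te[[as.character(j)]] <- lapply(dirs, function(dd) {
          lapply(c(reward = "reward", punishment = "punishment"),
                 function(cond) {
            bind_info_series(lapply(seq_len(config$n_subjects),
                                    function(s) {
              cts <- cohort$epochs[[s]]$contacts
              ids <- cts$contact[cts$coupling == j]
              transfer_entropy(cohort$epochs[[s]],
                               tibble::tibble(source = ids[dd[1]],
                                              target = ids[dd[2]]),
                               pe = cohort$pe[[s]], condition = cond,
                               window = config$window, n_perm = 0,
                               times = t_idx)
            }))
          })
        })
      }
    }
    res$ii <- ii
    res$te <- te
  }

  if ("group" %in% stages) {
    group <- list()
    summary_rows <- list()
    for (j_chr in names(res$ii %||% list())) {
      j <- as.integer(j_chr)
      sp <- config$couplings[[j]]$spec
      sets <- res$ii[[j_chr]]
      if (sp$mode == "redundant_pair") {
        cl <- lapply(sets, function(s) {
          group_cluster_test(s, alpha = config$alpha, tail = "neg")$all
        })
        group[[paste0("ii_", j)]] <- cl
        other <- setdiff(c("RPE", "PPE"), sp$target)
        summary_rows[[length(summary_rows) + 1]] <- tibble::tibble(
          coupling = j, mode = sp$mode, target = sp$target,
          check = "redundant, target-specific",
          pass = any(cl[[sp$target]]$significant) &&
            !any(cl[[other]]$significant))
      } else {
        cl <- group_cluster_test(sets$PE, alpha = config$alpha,
                                 tail = "pos")$all
        group[[paste0("ii_", j)]] <- list(PE = cl)
        summary_rows[[length(summary_rows) + 1]] <- tibble::tibble(
          coupling = j, mode = sp$mode, target = "PE",
          check = "synergistic full-PE",
          pass = any(cl$significant))
      }
    }
    for (j_chr in names(res$te %||% list())) {
      j <- as.integer(j_chr)
      sp <- config$couplings[[j]]$spec
      fwd <- res$te[[j_chr]]$fwd
      ct <- condition_contrast(fwd$punishment, fwd$reward,
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, 400 + j),
                               alpha = config$alpha)
      group[[paste0("te_", j)]] <- ct
      gated <- sp$condition %||% "punishment"
      pass <- if (gated == "punishment") {
        any(ct$a_gt_b$significant) && !any(ct$b_gt_a$significant)
      } else {
        any(ct$b_gt_a$significant) && !any(ct$a_gt_b$significant)
      }
      summary_rows[[length(summary_rows) + 1]] <- tibble::tibble(
        coupling = j, mode = sp$mode, target = gated,
        check = "condition-gated information flow",
        pass = pass)
    }
    res$group <- group
    res$summary <- dplyr::bind_rows(summary_rows)
  }

  res$manifest <- build_manifest(config, res, out_dir)
  if (!is.null(out_dir)) write_outputs(res, out_dir)
  structure(res, class = "pipeline_result")
}

build_manifest <- function(config, res, out_dir) {
  list(package = "infolearn",
       version = as.character(utils::packageVersion("infolearn")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       config_hash = rlang::hash(config),
       seed = config$seed,
       stage_seeds = list(simulate = derive_seed(config$seed, 1),
                          fit = derive_seed(config$seed, 101),
                          analyze = derive_seed(config$seed, 201)),
       stages = config$stages,
       summary_pass = if (!is.null(res$summary)) res$summary$pass else NULL)
}

write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  trials <- dplyr::bind_rows(res$cohort$trials)
  f <- file.path(out_dir, "trials.csv")
  write_trials(trials, f)
  files <- c(files, f)
  pe <- dplyr::bind_rows(res$cohort$pe)
  f <- file.path(out_dir, "prediction_errors.csv")
  write.csv(pe, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(res$fits)) {
    f <- file.path(out_dir, "fits.json")
    jsonlite::write_json(res$fits, f, digits = NA)
    files <- c(files, f)
  }
  if (!is.null(res$summary)) {
    f <- file.path(out_dir, "summary.csv")
    write.csv(res$summary, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- res$manifest
  manifest$files <- lapply(files, function(f) {
    list(path = basename(f),
         hash = rlang::hash(readBin(f, "raw", file.info(f)$size)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$config$n_subjects, "subject(s), stages:",
      paste(x$config$stages, collapse = " > "), "\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
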