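#' Configuration of a full pipeline run
#'
#' Bundles every knob of the end-to-end analysis: the input (a path to a
#' long per-window table, or a [synthetic_config()] to generate one),
#' which stages to run, and the statistical defaults -- 10,000
#' permutations and bootstrap resamples, 5 folds, 4 selected features,
#' thresholds 3..18, alpha 0.05.  A serialized copy of the effective
#' config accompanies every output bundle, and the master seed
#' deterministically derives all stage seeds.
#'
#' @param input path to a per-window CSV, or `NULL` to generate a
#'   synthetic cohort.
#' @param synthetic a `lingmark_synth_config` used when `input` is NULL.
#' @param stages subset of `c("summarize", "between", "pls", "within")`.
#' @param alpha family-wise error level.
#' @param n_perm permutations for [max_stat_permutation()].
#' @param n_boot resamples for [bootstrap_select_features()].
#' @param ci_boot resamples for confidence intervals.
#' @param k_folds,max_ncomp cross-validation layout.
#' @param k_features restricted-model size.
#' @param n_min_range thresholds for the within-subject sweep.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @return list of class `lingmark_run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       stages = c("summarize", "between", "pls", "within"),
                       alpha = 0.05, n_perm = 10000L, n_boot = 10000L,
                       ci_boot = 1000L, k_folds = 5L, max_ncomp = 10L,
                       k_features = 4L, n_min_range = 3:18, seed = 1L,
                       out_dir = tempfile("lingmark_run_")) {
  bad <- setdiff(stages, c("summarize", "between", "pls", "within"))
  if (length(bad)) lm_stop("stages", paste("unknown stage:", bad[1]))
  if (is.null(input) && is.null(synthetic))
    synthetic <- synthetic_config(n_participants = 40, seed = derive_seed(seed, 0))
  structure(list(input = input, synthetic = synthetic, stages = stages,
                 alpha = check_prob(alpha, "alpha"),
                 n_perm = check_count(n_perm, "n_perm"),
                 n_boot = check_count(n_boot, "n_boot"),
                 ci_boot = check_count(ci_boot, "ci_boot", min = 0L),
                 k_folds = check_count(k_folds, "k_folds", min = 2L),
                 max_ncomp = check_count(max_ncomp, "max_ncomp"),
                 k_features = check_count(k_features, "k_features"),
                 n_min_range = as.integer(n_min_range),
                 seed = check_count(seed, "seed", min = 0L),
                 out_dir = out_dir),
            class = "lingmark_run_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Loads or generates a cohort, restricts it to the analysable final
#' sample, then runs the requested stages: activity summary,
#' between-subject mass screening with permutation correction and
#' bootstrap CIs, per-target and combined PLS modelling (CV component
#' selection, bootstrap feature selection, restricted refit,
#' predicted-vs-observed report), and the within-subject
#' generalizability sweep.  Each stage writes its CSV/JSON outputs into
#' `config$out_dir` together with a run log recording seeds and
#' exclusion counts; a stage failure is logged and its dependent stages
#' are skipped.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of each stage
#'   (`cohort`, `activity`, `between`, `pls`, `within`, `log`,
#'   `errors`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "lingmark_run_config"))
    lm_stop("config", "must be created by run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  errors <- list()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  fail <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    note("stage %s FAILED: %s", stage, conditionMessage(e))
  }
  out <- function(name) file.path(config$out_dir, name)
  cfg_doc <- unclass(config)
  cfg_doc$synthetic <- if (!is.null(config$synthetic)) unclass(config$synthetic)
  jsonlite::write_json(cfg_doc, out("run_config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  # ---- load / generate ------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$input)) {
      note("reading cohort from %s", config$input)
      read_individual_data(config$input)
    } else {
      note("generating synthetic cohort (seed %d)", config$synthetic$seed)
      generate_cohort(config$synthetic)
    }
  }, error = function(e) { fail("load", e); NULL })
  if (is.null(cohort)) {
    writeLines(log_lines, out("run_log.txt"))
    return(invisible(list(errors = errors, log = log_lines)))
  }
  n_all <- length(unique(cohort$data$participant_id))
  cohort <- filter_final_sample(cohort, quiet = TRUE)
  note("final sample: %d of %d participants (%d removed)",
       length(unique(cohort$data$participant_id)), n_all,
       attr(cohort, "n_removed"))
  write_individual_data(cohort, out("individual_data.csv"))

  res <- list(cohort = cohort)
  xsec <- cross_section(cohort)
  write_mean_data(xsec, out("mean_data.csv"))
  targets_ok <- names(lm_targets)[colSums(!is.na(xsec[names(lm_targets)])) >= 3]

  # ---- summarize ------------------------------------------------------
  if ("summarize" %in% config$stages) {
    act <- tryCatch(summarize_activity(cohort),
                    error = function(e) { fail("summarize", e); NULL })
    if (!is.null(act)) {
      utils::write.csv(act$per_participant, out("activity_per_participant.csv"),
                       row.names = FALSE)
      utils::write.csv(act$cohort, out("activity_cohort.csv"), row.names = FALSE)
      write_activity_json(act, out("activity_summary.json"))
      res$activity <- act
    }
  }

  # ---- between-subject screening -------------------------------------
  if ("between" %in% config$stages) {
    res$between <- tryCatch({
      mc <- mass_correlations(xsec, cohort$feature_names, targets_ok,
                              n_boot = config$ci_boot,
                              seed = derive_seed(config$seed, 1))
      perm <- max_stat_permutation(xsec, cohort$feature_names, targets_ok,
                                   n_perm = config$n_perm,
                                   alpha = config$alpha,
                                   seed = derive_seed(config$seed, 2),
                                   results = mc)
      note("between: %d tests, |rho| threshold %.3f at alpha %g",
           nrow(perm$results), perm$null$threshold, config$alpha)
      utils::write.csv(format_table3(perm$results), out("correlation_table.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(n_perm = perm$null$n_perm, alpha = perm$null$alpha,
             threshold = perm$null$threshold, seed = perm$null$seed,
             joint = perm$null$joint),
        out("permutation_null.json"), auto_unbox = TRUE, digits = NA)
      perm
    }, error = function(e) { fail("between", e); NULL })
  }

  # ---- PLS modelling --------------------------------------------------
  if ("pls" %in% config$stages) {
    res$pls <- tryCatch({
      if (!length(targets_ok))
        lm_stop("targets", "no target observed for at least 3 participants")
      X <- as.matrix(xsec[, cohort$feature_names, drop = FALSE])
      pls_out <- list()
      for (tg in targets_ok) {
        y <- xsec[[tg]]
        keep <- !is.na(y)
        cv_full <- cv_select_ncomp(X[keep, , drop = FALSE], y[keep],
                                   k_folds = config$k_folds,
                                   max_ncomp = config$max_ncomp,
                                   seed = derive_seed(config$seed, 10))
        full <- fit_pls(X[keep, , drop = FALSE], y[keep],
                        n_components = max(cv_full$selected_ncomp, 1L))
        sel <- bootstrap_select_features(X[keep, , drop = FALSE], y[keep],
                                         n_boot = config$n_boot,
                                         k = config$k_features,
                                         seed = derive_seed(config$seed, 11))
        Xr <- X[keep, sel$selected, drop = FALSE]
        cv_restr <- cv_select_ncomp(Xr, y[keep], k_folds = config$k_folds,
                                    max_ncomp = min(config$max_ncomp,
                                                    config$k_features),
                                    seed = derive_seed(config$seed, 12))
        restr <- fit_pls(Xr, y[keep],
                         n_components = max(cv_restr$selected_ncomp, 1L),
                         restricted = TRUE)
        pvo <- predicted_vs_observed(restr, Xr, y[keep],
                                     n_boot = config$ci_boot,
                                     seed = derive_seed(config$seed, 13))
        pvo$target <- tg
        note("pls[%s]: full CV ncomp %d (%+.1f%%); restricted {%s} CV ncomp %d (%+.1f%%); r = %.2f",
             tg, cv_full$selected_ncomp, cv_full$relative_change_vs_zero,
             paste(sel$selected, collapse = ","), cv_restr$selected_ncomp,
             cv_restr$relative_change_vs_zero, pvo$r[1])
        write_model_json(restr, out(sprintf("model_%s_restricted.json", tg)))
        pls_out[[tg]] <- list(cv_full = cv_full, full = full, selection = sel,
                              cv_restricted = cv_restr, restricted = restr,
                              predicted_vs_observed = pvo)
      }
      cv_tab <- do.call(rbind, lapply(targets_ok, function(tg) {
        cf <- pls_out[[tg]]$cv_full; cr <- pls_out[[tg]]$cv_restricted
        data.frame(target = tg, model = c("full", "restricted"),
                   selected_ncomp = c(cf$selected_ncomp, cr$selected_ncomp),
                   mse_change_pct = c(cf$relative_change_vs_zero,
                                      cr$relative_change_vs_zero))
      }))
      utils::write.csv(cv_tab, out("cv_summary.csv"), row.names = FALSE)
      utils::write.csv(do.call(rbind, lapply(pls_out, `[[`,
                                             "predicted_vs_observed")),
                       out("predicted_vs_observed.csv"), row.names = FALSE)
      seltab <- do.call(rbind, lapply(targets_ok, function(tg)
        data.frame(target = tg, feature = names(pls_out[[tg]]$selection$z_by_feature),
                   z = pls_out[[tg]]$selection$z_by_feature,
                   selected = names(pls_out[[tg]]$selection$z_by_feature) %in%
                     pls_out[[tg]]$selection$selected)))
      utils::write.csv(seltab, out("feature_selection.csv"), row.names = FALSE)
      if (length(targets_ok) == 3L) {
        Yall <- as.matrix(xsec[, targets_ok])
        keep <- stats::complete.cases(Yall)
        mt <- fit_multitarget(X[keep, , drop = FALSE], Yall[keep, ],
                              k_folds = config$k_folds,
                              max_ncomp = config$max_ncomp,
                              seed = derive_seed(config$seed, 14))
        note("pls[combined]: CV ncomp %d (%+.1f%%)",
             mt$cv$selected_ncomp, mt$cv$relative_change_vs_zero)
        write_model_json(mt$model, out("model_combined.json"))
        pls_out$combined <- mt
      }
      pls_out
    }, error = function(e) { fail("pls", e); NULL })
  }

  # ---- within-subject generalizability --------------------------------
  if ("within" %in% config$stages) {
    if (is.null(res$pls)) {
      note("stage within skipped: requires the pls stage")
    } else {
      res$within <- tryCatch({
        within_out <- list()
        for (tg in intersect(targets_ok, names(res$pls))) {
          ws <- within_subject_analysis(res$pls[[tg]]$restricted, cohort,
                                        target = tg,
                                        n_min_range = config$n_min_range)
          note("within[%s]: %d participants usable, %d excluded",
               tg, sum(ws$per_participant$usable), ws$n_excluded)
          utils::write.csv(ws$per_participant,
                           out(sprintf("within_per_participant_%s.csv", tg)),
                           row.names = FALSE)
          utils::write.csv(ws$aggregates,
                           out(sprintf("within_aggregates_%s.csv", tg)),
                           row.names = FALSE)
          within_out[[tg]] <- ws
        }
        within_out
      }, error = function(e) { fail("within", e); NULL })
    }
  }

  res$log <- log_lines
  res$errors <- errors
  writeLines(log_lines, out("run_log.txt"))
  invisible(res)
}
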