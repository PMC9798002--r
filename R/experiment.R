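#' Experiment configuration
#'
#' Bundles everything one comparison run needs: the synthetic cohort
#' (paradigm, signal model, number of subjects and sessions), the condition
#' grid, the cross-validation protocol sizes, and the mandatory root seed.
#' `preset = "full-grid"` enumerates the full comparison grid — window
#' sizes 0.5/1/2 s plus the whole 3-s trial, slides 0.125/0.25/0.5 s, both
#' interaction measures, both classifiers (48 conditions); `preset =
#' "smoke"` is a minimal end-to-end run (2 subjects, 1 round, 1 condition).
#'
#' @param n_subjects,sessions_per_subject cohort size.
#' @param paradigm a [paradigm_config()].
#' @param model a [signal_model()].
#' @param conditions list of [mi_condition()]s.
#' @param rounds,folds,inner_folds CV protocol sizes.
#' @param seed root integer seed (mandatory).
#' @param preset optional name expanding to a full configuration;
#'   explicitly supplied arguments override the preset's values.
#' @return an object of class `"experiment_config"`.
#' @export
experiment_config <- function(n_subjects = 9L, sessions_per_subject = 3L,
                              paradigm = paradigm_config(),
                              model = signal_model(),
                              conditions = NULL,
                              rounds = 5L, folds = 3L, inner_folds = 4L,
                              seed, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full-grid", "smoke"))
    if (preset == "full-grid") {
      if (is.null(conditions)) conditions <- full_grid_conditions()
    } else {
      if (missing(n_subjects)) n_subjects <- 2L
      if (missing(sessions_per_subject)) sessions_per_subject <- 1L
      if (missing(paradigm))
        paradigm <- paradigm_config(n_runs = 1L,
                                    trials_per_class_per_run = 12L)
      if (missing(rounds)) rounds <- 1L
      if (is.null(conditions))
        conditions <- list(mi_condition("lda", "correlation",
                                        lda_lambda_grid = 1e-2))
    }
  }
  if (missing(seed)) stop_config("a root seed is mandatory")
  if (is.null(conditions))
    conditions <- list(mi_condition("lda", "none"),
                       mi_condition("lda", "correlation"),
                       mi_condition("lda", "jaccard"))
  stopifnot(inherits(paradigm, "paradigm_config"),
            inherits(model, "signal_model"))
  if (!all(vapply(conditions, inherits, TRUE, "mi_condition")))
    stop_config("conditions must be mi_condition objects")
  if (n_subjects < 1L || sessions_per_subject < 1L || rounds < 1L)
    stop_config("n_subjects, sessions_per_subject and rounds must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 paradigm = paradigm, model = model, conditions = conditions,
                 rounds = as.integer(rounds), folds = as.integer(folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @export
full_grid_conditions <- function() {
  # windows 0.5/1/2 s plus the whole 3-s trial, crossed with all slides:
  # 4 x 3 x 2 measures x 2 classifiers = 48 conditions
  out <- list()
  for (clf in c("lda", "hcrf"))
    for (mode in c("correlation", "jaccard"))
      for (w in c(0.5, 1, 2, 3))
        for (s in c(0.125, 0.25, 0.5))
          out <- c(out, list(mi_condition(clf, mode, window_s = w,
                                          slide_s = s)))
  out
}

config_digest <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            4294967296)
}

#' Run a full synthetic comparison experiment
#'
#' Generates the cohort, evaluates every condition by nested
#' cross-validation, runs the blocked ANOVA comparing interaction modes
#' within each classifier, and writes all results under `out_dir`:
#' `results.csv` (the blocked accuracy table), per-classifier
#' `anova_*.csv` / `posthoc_*.csv`, and `manifest.json` recording the
#' configuration digest, seed and package version.  Rerunning with the
#' same configuration reproduces identical CSVs.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @param write_cohort also dump the cohort as per-session CSV files.
#' @param quiet suppress stage-boundary log lines.
#' @return invisibly, a list with the results table and the per-classifier
#'   ANOVA objects.
#' @export
run_experiment <- function(config, out_dir, write_cohort = FALSE,
                           quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3]
  say("[generate] cohort: %d subjects x %d sessions (seed %d)",
      config$n_subjects, config$sessions_per_subject, config$seed)
  cohort <- generate_cohort(config$n_subjects, config$sessions_per_subject,
                            config$paradigm, config$model,
                            seed = derive_seed(config$seed, 101L))
  if (write_cohort) write_cohort_csv(cohort, file.path(out_dir, "cohort"))
  say("[evaluate] %d conditions x %d subjects (%.1f s elapsed)",
      length(config$conditions), config$n_subjects, proc.time()[3] - t0)
  results <- run_condition_grid(cohort, config$conditions,
                                seed = derive_seed(config$seed, 202L),
                                rounds = config$rounds, folds = config$folds,
                                inner_folds = config$inner_folds,
                                csv = file.path(out_dir, "results.csv"))
  say("[stats] blocked ANOVA per classifier (%.1f s elapsed)",
      proc.time()[3] - t0)
  anovas <- list()
  for (clf in unique(results$classifier)) {
    sub <- results[results$classifier == clf, , drop = FALSE]
    if (length(unique(sub$interaction_mode)) >= 2L &&
        all(table(sub$interaction_mode, sub$subject) == 1L)) {
      an <- rb_anova_oneway(sub, "interaction_mode")
      ph <- level_vs_overall(an)
      write_stats_report(an, ph, out_dir, prefix = paste0("anova_", clf))
      anovas[[clf]] <- list(anova = an, posthoc = ph)
    }
  }
  manifest <- list(config_digest = config_digest(config),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("mieeg")),
                   n_conditions = length(config$conditions))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("[done] results in %s (%.1f s total)", out_dir, proc.time()[3] - t0)
  invisible(list(results = results, anovas = anovas))
}

#' Render per-subject accuracy tables from a completed run
#'
#' Reads the stored `results.csv` and post-hoc CSVs of [run_experiment()]
#' and renders, per classifier and interaction measure, a
#' subject-by-condition accuracy table with `Average` and
#' `Standard deviation` rows and the post-hoc p-value (values below 0.001
#' rendered as `<0.001`).
#'
#' @param results_dir directory written by [run_experiment()].
#' @return character vector of formatted report lines (also printed).
#' @export
report_experiment <- function(results_dir) {
  path <- file.path(results_dir, "results.csv")
  if (!file.exists(path)) stop_config("no results.csv under ", results_dir)
  res <- utils::read.csv(path, stringsAsFactors = FALSE)
  lines <- character(0)
  emit <- function(...) lines <<- c(lines, sprintf(...))
  for (clf in unique(res$classifier)) {
    sub <- res[res$classifier == clf, , drop = FALSE]
    modes <- setdiff(unique(sub$interaction_mode), "none")
    if (length(modes) == 0L) {
      warning("classifier '", clf, "' has no interaction condition; omitted")
      next
    }
    ph_path <- file.path(results_dir, paste0("anova_", clf, "_posthoc.csv"))
    ph <- if (file.exists(ph_path))
      utils::read.csv(ph_path, stringsAsFactors = FALSE) else NULL
    emit("== %s classifier: accuracy by interaction features ==",
         toupper(clf))
    emit("%-10s %s", "Subject",
         paste(sprintf("%18s", paste0(modes, " | none")), collapse = " "))
    subjects <- unique(sub$subject)
    get_acc <- function(mode, s)
      mean(sub$accuracy[sub$interaction_mode == mode & sub$subject == s])
    for (s in subjects) {
      cells <- vapply(modes, function(m)
        sprintf("%8.3f | %6.3f", get_acc(m, s), get_acc("none", s)), "")
      emit("%-10s %s", s, paste(cells, collapse = " "))
    }
    avg <- vapply(modes, function(m)
      sprintf("%8.3f | %6.3f",
              mean(sub$accuracy[sub$interaction_mode == m]),
              mean(sub$accuracy[sub$interaction_mode == "none"])), "")
    sdv <- vapply(modes, function(m)
      sprintf("%8.3f | %6.3f",
              stats::sd(sub$accuracy[sub$interaction_mode == m]),
              stats::sd(sub$accuracy[sub$interaction_mode == "none"])), "")
    emit("%-10s %s", "Average", paste(avg, collapse = " "))
    emit("%-10s %s", "Standard deviation", paste(sdv, collapse = " "))
    if (!is.null(ph)) {
      pv <- vapply(ph$level, function(l) format_p(ph$p_adj[ph$level == l]),
                   "")
      emit("%-10s %s", "P-value",
           paste(sprintf("%s: %s", ph$level, pv), collapse = "  "))
    }
    emit("")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
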