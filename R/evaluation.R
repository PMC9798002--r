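#' Confusion matrix and accuracy
#'
#' `confusion_matrix` tabulates true classes (rows) against predictions
#' (columns); `accuracy` is the trace divided by the total count — the
#' fraction of correctly classified trials, in `[0, 1]`.
#'
#' @param true,pred label vectors of equal length.
#' @param classes ordered label set; defaults to the sorted union.
#' @return `confusion_matrix`: a K x K integer matrix; `accuracy`: scalar.
#' @examples
#' H <- confusion_matrix(c("l", "l", "r"), c("l", "r", "r"))
#' accuracy(H)
#' @export
confusion_matrix <- function(true, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(true, pred)))
  as.matrix(table(factor(true, classes), factor(pred, classes)))
}

#' @rdname confusion_matrix
#' @param H a confusion matrix.
#' @export
accuracy <- function(H) {
  n <- sum(H)
  if (n == 0) stop_config("empty confusion matrix")
  sum(diag(H)) / n
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `k` folds so that fold sizes differ by at
#' most one within every class (class ratios preserved to within one
#' trial).  Deterministic under `seed`.
#'
#' @param labels class label per trial.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      ix <- which(labels == cl)
      if (length(ix) < k)
        stop_config("class '", cl, "' has ", length(ix),
                    " trials; need at least k = ", k)
      fold[ix] <- sample(rep_len(sample(k), length(ix)))
    }
  })
  fold
}

#' Experimental condition
#'
#' One cell of the comparison grid: a classifier (`"lda"` static or
#' `"hcrf"` dynamic), an interaction mode (`"none"`, `"correlation"`,
#' `"jaccard"`), a sliding-window size and slide, and the hyperparameter
#' grids searched by the inner cross-validation.
#'
#' @param classifier `"lda"` or `"hcrf"`.
#' @param interaction_mode `"none"`, `"correlation"` or `"jaccard"`.
#' @param window_s,slide_s sliding-window size and displacement in seconds;
#'   `window_s = NULL` means one whole-trial window.
#' @param lda_lambda_grid shrinkage candidates for the discriminant.
#' @param hcrf_m_grid,hcrf_reg_grid hidden-state and L2 candidates for the
#'   HCRF.
#' @param hcrf_restarts random restarts per HCRF fit.
#' @return an object of class `"mi_condition"`.
#' @export
mi_condition <- function(classifier = c("lda", "hcrf"),
                         interaction_mode = c("none", "correlation",
                                              "jaccard"),
                         window_s = NULL, slide_s = NULL,
                         lda_lambda_grid = c(0, 1e-3, 1e-2, 1e-1),
                         hcrf_m_grid = c(2L, 3L, 4L),
                         hcrf_reg_grid = c(0.1, 1, 10),
                         hcrf_restarts = 3L) {
  classifier <- match.arg(classifier)
  interaction_mode <- match.arg(interaction_mode)
  structure(list(classifier = classifier,
                 interaction_mode = interaction_mode,
                 window_s = window_s, slide_s = slide_s,
                 lda_lambda_grid = lda_lambda_grid,
                 hcrf_m_grid = hcrf_m_grid, hcrf_reg_grid = hcrf_reg_grid,
                 hcrf_restarts = hcrf_restarts),
            class = "mi_condition")
}

condition_id <- function(cond) {
  sprintf("%s_%s_w%s_s%s", cond$classifier, cond$interaction_mode,
          cond$window_s %||% "full", cond$slide_s %||% "full")
}

# Seed stream independent of a condition's position in any list: hash the
# condition id into the counter.
condition_counter <- function(cond) {
  sum(utf8ToInt(condition_id(cond)) * seq_along(utf8ToInt(condition_id(cond))))
}

# Hyperparameter candidates in tie-preference order (preferred first):
# smallest hidden-state count, then strongest regularization.
condition_grid <- function(cond) {
  if (cond$classifier == "lda") {
    lapply(sort(cond$lda_lambda_grid, decreasing = TRUE),
           function(l) list(lambda = l))
  } else {
    out <- list()
    for (m in sort(cond$hcrf_m_grid))
      for (r in sort(cond$hcrf_reg_grid, decreasing = TRUE))
        out <- c(out, list(list(m = as.integer(m), reg = r)))
    out
  }
}

bp_cols <- function() seq_len(2L * length(mi_channels))

scale_from_train <- function(seqs, ix) {
  fit_power_scale(unlist(lapply(seqs[ix], function(s)
    unclass(s)[, bp_cols(), drop = FALSE])))
}

apply_scale_seqs <- function(seqs, scale) {
  lapply(seqs, function(s) {
    s[, bp_cols()] <- apply_power_scale(scale, s[, bp_cols(), drop = FALSE])
    s
  })
}

fit_predict <- function(cond, hyper, seqs, labels, train_ix, test_ix, seed) {
  scale <- scale_from_train(seqs, train_ix)
  sc_seqs <- apply_scale_seqs(seqs, scale)
  if (cond$classifier == "lda") {
    xtr <- t(vapply(sc_seqs[train_ix], flatten_features,
                    numeric(nrow(seqs[[1]]) * ncol(seqs[[1]]))))
    xte <- t(vapply(sc_seqs[test_ix], flatten_features, numeric(ncol(xtr))))
    fit <- mi_lda(xtr, labels[train_ix], lambda = hyper$lambda)
    pred <- predict(fit, xte)
  } else {
    fit <- mi_hcrf(sc_seqs[train_ix], labels[train_ix], m = hyper$m,
                   reg = hyper$reg, seed = seed,
                   restarts = cond$hcrf_restarts)
    pred <- predict(fit, sc_seqs[test_ix])
  }
  list(pred = pred, scale_factor = scale$factor)
}

#' Nested cross-validation for one condition
#'
#' The evaluation protocol: `rounds` independently seeded rounds of
#' stratified `folds`-fold cross-validation; within every outer training
#' set, a stratified `inner_folds`-fold grid search selects the condition's
#' hyperparameters by highest mean inner accuracy (ties resolved towards
#' the smallest hidden-state count / strongest regularization), after which
#' the model is refit on the full outer training set and scored on the held
#' -out fold.  All band-power scaling is fitted on the training side of
#' whichever split is in force — never on held-out trials.  Defaults follow
#' the protocol of five rounds of 3-fold CV with an inner 4-fold search.
#'
#' @param trials list of `mi_trial`s (one subject's pooled trials).
#' @param condition an [mi_condition()].
#' @param seed integer root seed; rounds are reseeded as seed + round
#'   counter, so results are reproducible and rounds independent.
#' @param rounds,folds,inner_folds protocol sizes.
#' @return an object of class `"cv_result"`: a per-fold data.frame
#'   (`round`, `fold`, `accuracy`, selected hyperparameters, scale factor),
#'   the per-fold confusion matrices, and `mean_accuracy`.
#' @export
nested_cv <- function(trials, condition, seed = 1L, rounds = 5L, folds = 3L,
                      inner_folds = 4L) {
  stopifnot(inherits(condition, "mi_condition"))
  labels <- vapply(trials, `[[`, "", "label")
  classes <- sort(unique(labels))
  min_per_class <- folds * inner_folds
  if (any(table(labels) < min_per_class))
    stop_config("each class needs >= ", min_per_class,
                " trials for ", folds, "-fold outer x ", inner_folds,
                "-fold inner CV")
  spec <- if (is.null(condition$window_s)) NULL else
    window_spec(condition$window_s, condition$slide_s %||%
                  condition$window_s)
  seqs <- lapply(trials, extract_features, spec = spec,
                 interaction_mode = condition$interaction_mode)
  grid <- condition_grid(condition)
  cseed <- derive_seed(seed, condition_counter(condition))
  rows <- list(); confusions <- list()
  for (r in seq_len(rounds)) {
    fold_id <- stratified_folds(labels, folds, derive_seed(cseed, c(1L, r)))
    for (f in seq_len(folds)) {
      train_ix <- which(fold_id != f)
      test_ix <- which(fold_id == f)
      hyper <- grid[[1]]
      if (length(grid) > 1L) {
        inner_id <- stratified_folds(labels[train_ix], inner_folds,
                                     derive_seed(cseed, c(2L, r, f)))
        mean_acc <- vapply(grid, function(h) {
          accs <- vapply(seq_len(inner_folds), function(g) {
            itr <- train_ix[inner_id != g]
            ite <- train_ix[inner_id == g]
            pr <- fit_predict(condition, h, seqs, labels, itr, ite,
                              derive_seed(cseed, c(3L, r, f, g)))
            accuracy(confusion_matrix(labels[ite], pr$pred, classes))
          }, 0)
          mean(accs)
        }, 0)
        hyper <- grid[[which.max(mean_acc)]]  # first max = preferred
      }
      res <- fit_predict(condition, hyper, seqs, labels, train_ix, test_ix,
                         derive_seed(cseed, c(4L, r, f)))
      H <- confusion_matrix(labels[test_ix], res$pred, classes)
      rows[[length(rows) + 1L]] <- data.frame(
        round = r, fold = f, accuracy = accuracy(H),
        hyperparameters = as.character(jsonlite::toJSON(hyper,
                                                        auto_unbox = TRUE)),
        scale_factor = res$scale_factor, stringsAsFactors = FALSE)
      confusions[[length(confusions) + 1L]] <- H
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(folds = tab, confusions = confusions,
                 mean_accuracy = mean(tab$accuracy),
                 condition = condition, rounds = rounds, k = folds,
                 inner_folds = inner_folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean accuracy %.4f over %d rounds x %d folds\n",
              condition_id(x$condition), x$mean_accuracy, x$rounds, x$k))
  invisible(x)
}

#' Blocked accuracy table over a condition grid
#'
#' Runs [nested_cv()] for every subject x condition cell and returns one
#' mean accuracy per cell — the blocked table consumed by the
#' randomized-blocks ANOVA.  Each condition draws its own seed stream
#' (derived from the condition's identity, not its list position), so
#' adding conditions never changes existing rows.
#'
#' @param cohort an `mi_cohort` (all of a subject's sessions are pooled).
#' @param conditions list of [mi_condition()]s.
#' @param seed root seed.
#' @param rounds,folds,inner_folds protocol sizes passed to [nested_cv()].
#' @param csv optional path; when given the table is also written as CSV.
#' @return data.frame with columns `subject`, `classifier`,
#'   `interaction_mode`, `window_s`, `slide_s`, `accuracy`, ordered by
#'   subject then condition id.
#' @export
run_condition_grid <- function(cohort, conditions, seed = 1L, rounds = 5L,
                               folds = 3L, inner_folds = 4L, csv = NULL) {
  if (inherits(conditions, "mi_condition")) conditions <- list(conditions)
  rows <- list()
  for (s in seq_along(cohort)) {
    trials <- cohort_trials(cohort, s)
    for (cond in conditions) {
      cv <- nested_cv(trials, cond,
                      seed = derive_seed(seed, c(s, condition_counter(cond))),
                      rounds = rounds, folds = folds,
                      inner_folds = inner_folds)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = names(cohort)[s] %||% as.character(s),
        classifier = cond$classifier,
        interaction_mode = cond$interaction_mode,
        window_s = cond$window_s %||% NA_real_,
        slide_s = cond$slide_s %||% NA_real_,
        accuracy = cv$mean_accuracy, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(out$subject, out$classifier, out$interaction_mode,
               out$window_s, out$slide_s)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
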