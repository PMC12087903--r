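# Evaluation protocols: within-subject (first m trials source, remaining
# trials unlabeled target, per subject) and cross-subject leave-one-subject-
# out (each subject once as the unlabeled target domain).

subject_ids <- function(dataset) {
  vapply(dataset$trials, `[[`, "", "subject_id")
}

# benchmark split conventions: 9/15 and 16/24 leading source trials
default_m <- function(n_trials) {
  if (n_trials == 15L) 9L
  else if (n_trials == 24L) 16L
  else as.integer(ceiling(0.6 * n_trials))
}

windows_for_trials <- function(dataset, trial_idx, d, domain) {
  unlist(lapply(trial_idx, function(i) {
    make_windows(dataset$trials[[i]], d = d, domain = domain,
                 trial_uid = sprintf("trial%04d", i))
  }), recursive = FALSE)
}

make_eval_report <- function(per_fold, fold_names, confusion, config,
                             per_fold_trial = NULL) {
  structure(list(per_fold_accuracy = stats::setNames(per_fold, fold_names),
                 mean_accuracy = mean(per_fold),
                 std_accuracy = stats::sd(per_fold),
                 per_fold_trial_accuracy =
                   if (is.null(per_fold_trial)) NULL
                   else stats::setNames(per_fold_trial, fold_names),
                 confusion = confusion,
                 config_echo = unclass(config)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds: mean accuracy %.2f%% (sd %.2f)\n",
              length(x$per_fold_accuracy), x$mean_accuracy,
              if (is.na(x$std_accuracy)) 0 else x$std_accuracy))
  for (nm in names(x$per_fold_accuracy)) {
    cat(sprintf("  %-12s %.2f%%\n", nm, x$per_fold_accuracy[[nm]]))
  }
  invisible(x)
}

#' Within-subject cross-validation
#'
#' For each subject: train on the windows of the first `m` trials (labeled
#' source) with that subject's remaining trials as the unlabeled target
#' domain, then evaluate window-level accuracy on the target windows.
#'
#' @param dataset an [eeg_dataset()].
#' @param config a [model_config()].
#' @param m number of leading source trials per subject. Defaults to 9 for
#'   15-trial subjects and 16 for 24-trial subjects (the two benchmark
#'   conventions), else `ceiling(0.6 * n_trials)`.
#' @return An `eval_report` with one fold per subject.
#' @export
run_within_subject <- function(dataset, config = model_config(), m = NULL) {
  subs <- subject_ids(dataset)
  uniq <- unique(subs)
  per_fold <- numeric(0)
  per_fold_trial <- numeric(0)
  fold_names <- character(0)
  confusion <- NULL
  for (s in uniq) {
    idx <- which(subs == s)
    n_tr <- length(idx)
    m_s <- m %||% default_m(n_tr)
    if (m_s >= n_tr) {
      if (has_ablation(config, "no_discriminator")) {
        stop(sprintf(
          "subject %s: m=%d leaves no target trials; hold out evaluation trials by passing m < n_trials",
          s, m_s), call. = FALSE)
      }
      stop(sprintf("subject %s: m=%d leaves no target trials (n=%d)",
                   s, m_s, n_tr), call. = FALSE)
    }
    src_idx <- idx[seq_len(m_s)]
    tgt_idx <- idx[(m_s + 1L):n_tr]
    src <- tryCatch(
      windows_for_trials(dataset, src_idx, config$d, "source"),
      error = function(e) NULL)
    tgt <- tryCatch(
      windows_for_trials(dataset, tgt_idx, config$d, "target"),
      error = function(e) NULL)
    if (is.null(src) || is.null(tgt)) {
      warning(sprintf("subject %s skipped: trials too short for d=%d",
                      s, config$d), call. = FALSE)
      next
    }
    fit <- train_model(src, tgt, config,
                       n_classes = length(dataset$class_names))
    ev <- evaluate_model(fit, tgt)
    per_fold <- c(per_fold, ev$accuracy)
    per_fold_trial <- c(per_fold_trial, ev$trial_accuracy)
    fold_names <- c(fold_names, s)
    confusion <- if (is.null(confusion)) ev$confusion else confusion + ev$confusion
  }
  if (length(per_fold) == 0L) {
    stop("no subject could be evaluated", call. = FALSE)
  }
  make_eval_report(per_fold, fold_names, confusion, config, per_fold_trial)
}

#' Leave-one-subject-out cross-subject cross-validation
#'
#' Each subject serves exactly once as the unlabeled target domain while
#' all remaining subjects' windows form the labeled source domain;
#' accuracy is measured on the held-out subject.
#'
#' @param dataset an [eeg_dataset()] with at least two subjects.
#' @param config a [model_config()].
#' @return An `eval_report` with one fold per subject.
#' @export
run_cross_subject <- function(dataset, config = model_config()) {
  subs <- subject_ids(dataset)
  uniq <- unique(subs)
  if (length(uniq) < 2L) {
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  }
  per_fold <- numeric(0)
  per_fold_trial <- numeric(0)
  confusion <- NULL
  for (s in uniq) {
    src <- windows_for_trials(dataset, which(subs != s), config$d, "source")
    tgt <- windows_for_trials(dataset, which(subs == s), config$d, "target")
    fit <- train_model(src, tgt, config,
                       n_classes = length(dataset$class_names))
    ev <- evaluate_model(fit, tgt)
    per_fold <- c(per_fold, ev$accuracy)
    per_fold_trial <- c(per_fold_trial, ev$trial_accuracy)
    confusion <- if (is.null(confusion)) ev$confusion else confusion + ev$confusion
  }
  make_eval_report(per_fold, uniq, confusion, config, per_fold_trial)
}
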