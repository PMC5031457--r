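#' Classifier specification for the experiment protocols
#'
#' `opf_spec()` configures the package's own Optimum-Path Forest;
#' [baseline_spec()] configures the comparison classifiers. Both are
#' accepted everywhere an `algorithms` argument appears.
#'
#' @param metric One of [OPF_METRICS].
#' @return An `opf_spec` list.
#' @export
opf_spec <- function(metric = "euclidean") {
  metric <- match.arg(metric, OPF_METRICS)
  structure(list(algo = paste0("opf_", metric), metric = metric),
            class = "opf_spec")
}

# uniform train/predict over opf_spec and baseline_spec
train_classifier <- function(spec, features, labels, seed = 1L) {
  if (inherits(spec, "opf_spec")) {
    opf_fit(features, labels, metric = spec$metric)
  } else if (inherits(spec, "baseline_spec")) {
    spec$seed <- as.integer(seed)
    train_baseline(spec, features, labels)
  } else {
    stop("unknown classifier spec", call. = FALSE)
  }
}

#' Stratified train/test split of a feature table
#'
#' Per class, `ceiling(train_fraction * n_i)` samples go to the training
#' side (capped so each side keeps at least one sample per class); the
#' rest are the test set. Stratification guarantees every class appears on
#' both sides, so the class-balanced metrics are always defined.
#'
#' @param features A feature tibble with a `label` column.
#' @param train_fraction Fraction of each class assigned to training,
#'   in (0, 1).
#' @param seed Integer seed; the partition is a pure function of
#'   `(seed, train_fraction)` and the row order.
#' @return A list with tibbles `train` and `test` (disjoint, union = input).
#' @export
stratified_split <- function(features, train_fraction, seed = 1L) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  counts <- table(features$label)
  if (any(counts < 2L)) {
    stop("every class needs >= 2 samples; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in names(counts)) {
    idx <- which(features$label == cl)
    n_train <- min(length(idx) - 1L, max(1L, ceiling(train_fraction * length(idx))))
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = features[train_idx, , drop = FALSE],
       test = features[-train_idx, , drop = FALSE])
}

#' Repeated-holdout sweep over training fractions
#'
#' The core experiment protocol: for each algorithm, training fraction and
#' repetition, the feature table is stratified-split (repetition `r` uses
#' seed `base_seed + r`, identical across algorithms so every classifier
#' sees the same partitions), the classifier is trained and the held-out
#' samples are scored with the class-balanced accuracy and macro-F1.
#' Results are aggregated as mean and standard error of the mean over
#' repetitions; confusion matrices are accumulated as counts.
#'
#' @param features Feature tibble with `label` column.
#' @param algorithms Named list of [opf_spec()] / [baseline_spec()] objects
#'   (names become the `algorithm` column; unnamed entries use their
#'   `algo` field).
#' @param fractions Training fractions; default `seq(0.1, 0.9, by = 0.1)`.
#' @param reps Repetitions per cell; default 100.
#' @param base_seed Base of the seed ladder.
#' @return An `experiment_result` with `results` (per-repetition tibble),
#'   `summary` (mean +/- SEM tibble) and `confusions` (accumulated count
#'   matrices per algorithm x fraction).
#' @export
run_sweep <- function(features, algorithms, fractions = seq(0.1, 0.9, by = 0.1),
                      reps = 100L, base_seed = 42L) {
  stopifnot(all(fractions > 0 & fractions < 1), reps >= 1L)
  if (reps == 1L) warning("reps = 1: SEM will be reported as 0")
  if (is.null(names(algorithms)) || any(names(algorithms) == "")) {
    nm <- vapply(algorithms, function(s) s$algo, character(1))
    names(algorithms) <- nm
  }
  class_names <- sort(unique(features$label))
  rows <- list()
  confusions <- list()
  for (a in names(algorithms)) {
    for (fr in fractions) {
      cm_acc <- matrix(0L, length(class_names), length(class_names),
                       dimnames = list(true = class_names,
                                       predicted = class_names))
      for (r in seq_len(reps)) {
        seed <- base_seed + r
        res <- tryCatch({
          sp <- stratified_split(features, fr, seed = seed)
          fit <- train_classifier(algorithms[[a]], sp$train,
                                  sp$train$label, seed = seed)
          t0 <- proc.time()[["elapsed"]]
          pred <- predict(fit, sp$test)
          elapsed <- proc.time()[["elapsed"]] - t0
          cm <- confusion_matrix(sp$test$label, pred, class_names)
          list(cm = cm, acc = papa_accuracy(cm), f1 = macro_f1(cm),
               time_ms = 1000 * elapsed / nrow(sp$test))
        }, error = function(e) {
          stop("sweep failed [algorithm=", a, ", fraction=", fr,
               ", rep=", r, ", seed=", seed, "]: ", conditionMessage(e),
               call. = FALSE)
        })
        cm_acc <- cm_acc + unclass(res$cm)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          algorithm = a, fraction = fr, rep = r, seed = seed,
          acc = res$acc, macro_f1 = res$f1, time_ms = res$time_ms)
      }
      confusions[[paste(a, fr, sep = "@")]] <- cm_acc
    }
  }
  results <- dplyr::bind_rows(rows)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  summary <- results |>
    dplyr::group_by(.data$algorithm, .data$fraction) |>
    dplyr::summarise(
      acc_mean = mean(.data$acc), acc_sem = sem(.data$acc),
      f1_mean = mean(.data$macro_f1), f1_sem = sem(.data$macro_f1),
      time_ms_mean = mean(.data$time_ms), .groups = "drop")
  structure(list(results = results, summary = summary,
                 confusions = confusions, reps = reps,
                 base_seed = base_seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d algorithm(s) x %d fraction(s), %d reps\n",
              length(unique(x$summary$algorithm)),
              length(unique(x$summary$fraction)), x$reps))
  print(x$summary, n = 20)
  invisible(x)
}

#' @rdname run_sweep
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @export
tidy.experiment_result <- function(x, ...) x$summary

#' Collapse sub-class labels to the eight principal call types
#'
#' Maps `Phee-2`/`Phee-3`/`Phee-4` to `Phee` and `Tsik`/`Tsik-ek` to
#' `Tsik`, leaving the other six call types unchanged.
#'
#' @param labels Character vector of 11-type labels.
#' @return Character vector of principal-class labels.
#' @export
merge_principal_labels <- function(labels) {
  out <- as.character(labels)
  out[out %in% c("Phee-2", "Phee-3", "Phee-4")] <- "Phee"
  out[out %in% c("Tsik", "Tsik-ek")] <- "Tsik"
  out
}

#' Hierarchical classification of the 11 call types
#'
#' Two-stage protocol: the 11 labels are collapsed to 8 principal classes
#' (Phee sub-types merged, Tsik sub-types merged) for a principal
#' classifier; dedicated sub-classifiers are then trained on the Phee
#' exemplars (3 sub-classes) and the Tsik exemplars (2 sub-classes). Each
#' repetition stratifies the split on the full 11-type labels so every
#' sub-class is present on both sides. Confusion matrices are accumulated
#' over repetitions; the compounded accuracy of a sub-class is the product
#' of its principal class's sensitivity and its own sub-class sensitivity.
#'
#' @param features Feature tibble whose `label` column uses the 11 call
#'   types.
#' @param algorithm An [opf_spec()] or [baseline_spec()].
#' @param train_fraction Training fraction per repetition; default 0.9.
#' @param reps Repetitions; default 100.
#' @param base_seed Seed-ladder base.
#' @return A `hierarchical_result` with accumulated confusion matrices
#'   `principal_cm` (8 classes), `phee_cm` (3 sub-classes), `tsik_cm`
#'   (2 sub-classes) and a tibble `compounded` with per-sub-class parent,
#'   child and compounded sensitivities.
#' @export
hierarchical_eval <- function(features, algorithm = opf_spec("euclidean"),
                              train_fraction = 0.9, reps = 100L,
                              base_seed = 42L) {
  phee_sub <- c("Phee-2", "Phee-3", "Phee-4")
  tsik_sub <- c("Tsik", "Tsik-ek")
  missing <- setdiff(c(phee_sub, tsik_sub), unique(features$label))
  if (length(missing) > 0L) {
    stop("dataset lacks required sub-class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  principal_names <- sort(unique(merge_principal_labels(features$label)))
  cm_p <- matrix(0L, length(principal_names), length(principal_names),
                 dimnames = list(true = principal_names,
                                 predicted = principal_names))
  cm_phee <- matrix(0L, 3, 3, dimnames = list(true = phee_sub,
                                              predicted = phee_sub))
  cm_tsik <- matrix(0L, 2, 2, dimnames = list(true = tsik_sub,
                                              predicted = tsik_sub))
  for (r in seq_len(reps)) {
    seed <- base_seed + r
    sp <- stratified_split(features, train_fraction, seed = seed)

    fit_p <- train_classifier(algorithm, sp$train,
                              merge_principal_labels(sp$train$label),
                              seed = seed)
    pred_p <- predict(fit_p, sp$test)
    cm_p <- cm_p + unclass(confusion_matrix(
      merge_principal_labels(sp$test$label), pred_p, principal_names))

    tr_phee <- sp$train[sp$train$label %in% phee_sub, , drop = FALSE]
    te_phee <- sp$test[sp$test$label %in% phee_sub, , drop = FALSE]
    fit_phee <- train_classifier(algorithm, tr_phee, tr_phee$label,
                                 seed = seed)
    cm_phee <- cm_phee + unclass(confusion_matrix(
      te_phee$label, predict(fit_phee, te_phee), phee_sub))

    tr_tsik <- sp$train[sp$train$label %in% tsik_sub, , drop = FALSE]
    te_tsik <- sp$test[sp$test$label %in% tsik_sub, , drop = FALSE]
    fit_tsik <- train_classifier(algorithm, tr_tsik, tr_tsik$label,
                                 seed = seed)
    cm_tsik <- cm_tsik + unclass(confusion_matrix(
      te_tsik$label, predict(fit_tsik, te_tsik), tsik_sub))
  }
  recall <- function(cm) diag(cm) / rowSums(cm)
  se_p <- recall(cm_p)
  compounded <- dplyr::bind_rows(
    tibble::tibble(sub_class = phee_sub, parent = "Phee",
                   parent_se = se_p[["Phee"]], child_se = recall(cm_phee)),
    tibble::tibble(sub_class = tsik_sub, parent = "Tsik",
                   parent_se = se_p[["Tsik"]], child_se = recall(cm_tsik))
  ) |>
    dplyr::mutate(compounded = compounded_accuracy(.data$parent_se,
                                                   .data$child_se))
  structure(list(principal_cm = cm_p, phee_cm = cm_phee, tsik_cm = cm_tsik,
                 compounded = compounded, reps = reps),
            class = "hierarchical_result")
}

#' @export
print.hierarchical_result <- function(x, ...) {
  cat(sprintf("<hierarchical_result> over %d repetitions\n", x$reps))
  cat(sprintf("principal balanced accuracy: %.1f%%\n",
              balanced_accuracy(x$principal_cm) * 100))
  cat(sprintf("Phee sub-class balanced accuracy: %.1f%%\n",
              balanced_accuracy(x$phee_cm) * 100))
  cat(sprintf("Tsik sub-class balanced accuracy: %.1f%%\n",
              balanced_accuracy(x$tsik_cm) * 100))
  print(x$compounded)
  invisible(x)
}
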