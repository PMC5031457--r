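#' Build a confusion matrix
#'
#' Counts with rows = true class, columns = predicted class.
#'
#' @param truth,estimate Label vectors of equal length (character, factor or
#'   integer ids).
#' @param class_names Ordered class names defining the matrix layout. When
#'   omitted, the sorted union of observed labels is used.
#' @return A `confusion_matrix`: an integer K x K matrix with `dimnames`
#'   `(true, predicted)`.
#' @export
confusion_matrix <- function(truth, estimate, class_names = NULL) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  if (is.null(class_names)) {
    class_names <- sort(unique(as.character(c(truth, estimate))))
  }
  class_names <- as.character(class_names)
  t_f <- factor(as.character(truth), levels = class_names)
  e_f <- factor(as.character(estimate), levels = class_names)
  if (length(truth) > 0L && (anyNA(t_f) || anyNA(e_f))) {
    stop("labels outside `class_names` encountered", call. = FALSE)
  }
  counts <- table(true = t_f, predicted = e_f)
  out <- matrix(as.integer(counts), nrow = length(class_names),
                dimnames = list(true = class_names, predicted = class_names))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' @export
print.confusion_matrix <- function(x, percent = TRUE, digits = 1, ...) {
  if (percent) {
    cat("Confusion matrix (row-normalized %, rows = true class):\n")
    print(round(row_normalize(x), digits))
  } else {
    cat("Confusion matrix (counts, rows = true class):\n")
    print(unclass(x))
  }
  invisible(x)
}

#' Row-normalize a confusion matrix to percent
#'
#' @param cm A confusion matrix (counts or already-normalized numbers).
#' @return A numeric matrix whose rows sum to 100.
#' @export
row_normalize <- function(cm) {
  cm <- as.matrix(unclass(cm))
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("row with zero total: class absent from test set",
                         call. = FALSE)
  sweep(cm, 1, rs, "/") * 100
}

#' Class-balanced accuracy (false-positive + false-negative penalized)
#'
#' A restrictive accuracy for unequal class sizes: for each class `i`, the
#' false-positive rate is normalized by the out-of-class test size and the
#' false-negative rate by the in-class size,
#' `E_i = FP_i / (N - N_i) + FN_i / N_i`, and the accuracy is
#' `1 - sum(E_i) / (2K)`. An always-majority-class predictor therefore
#' scores 0.5 on two balanced classes rather than its raw hit rate.
#'
#' @param cm A [confusion_matrix()] of counts.
#' @return A single number in \[0, 1\].
#' @export
papa_accuracy <- function(cm) {
  cm <- as.matrix(unclass(cm))
  K <- nrow(cm)
  n_i <- rowSums(cm)
  total <- sum(cm)
  if (any(n_i == 0)) {
    stop("undefined: class absent from test set (empty row)", call. = FALSE)
  }
  if (any(n_i == total)) {
    stop("undefined: single-class test set", call. = FALSE)
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- n_i - tp
  e1 <- fp / (total - n_i)
  e2 <- fn / n_i
  1 - sum(e1 + e2) / (2 * K)
}

#' Per-class sensitivity, precision and F1
#'
#' Sensitivity (recall) is `TP / (TP + FN)`, positive predictive value
#' (precision) is `TP / (TP + FP)`, F1 their harmonic mean. A class never
#' predicted gets `PPV = 0` and `F1 = 0` with a warning. The unweighted
#' mean of per-class F1 (macro-F1) is attached and also returned by
#' [macro_f1()].
#'
#' @param cm A [confusion_matrix()] of counts.
#' @return A tibble with columns `class`, `n`, `se`, `ppv`, `f1` and
#'   attribute `macro_f1`.
#' @export
class_metrics <- function(cm) {
  m <- as.matrix(unclass(cm))
  tp <- diag(m)
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  se <- ifelse(row_tot > 0, tp / row_tot, NA_real_)
  if (any(col_tot == 0)) {
    warning("class(es) never predicted: ",
            paste(rownames(m)[col_tot == 0], collapse = ", "),
            "; their PPV and F1 are set to 0")
  }
  ppv <- ifelse(col_tot > 0, tp / col_tot, 0)
  f1 <- ifelse(se + ppv > 0, 2 * se * ppv / (se + ppv), 0)
  out <- tibble::tibble(
    class = rownames(m) %||% as.character(seq_along(tp)),
    n = unname(row_tot),
    se = unname(se), ppv = unname(ppv), f1 = unname(f1)
  )
  attr(out, "macro_f1") <- mean(f1)
  out
}

#' @rdname class_metrics
#' @export
macro_f1 <- function(cm) {
  attr(class_metrics(cm), "macro_f1")
}

#' Mean per-class recall (diagonal of the row-normalized matrix)
#'
#' The "overall accuracy" of a normalized confusion table: the unweighted
#' mean over classes of the fraction of each class classified correctly.
#' Accepts either raw counts or an already row-normalized (percent) table;
#' the result is on the same scale as the input rows (fraction for counts,
#' percent for a percent table).
#'
#' @param cm Confusion matrix (counts or percent).
#' @return Mean of `cm[i, i] / sum(cm[i, ])` over classes, times 100 if the
#'   rows sum to 100.
#' @export
balanced_accuracy <- function(cm) {
  m <- as.matrix(unclass(cm))
  rs <- rowSums(m)
  if (any(rs == 0)) stop("undefined: empty row in confusion matrix", call. = FALSE)
  scale <- if (isTRUE(all.equal(unname(rs), rep(100, nrow(m)), tolerance = 1e-6))) 100 else 1
  mean(diag(m) / rs) * scale
}

#' Compounded hierarchical accuracy
#'
#' In a two-stage (principal class, then sub-class) classifier, the chance
#' that a call is routed to its principal class and then to its sub-class is
#' the product of the two sensitivities.
#'
#' @param parent_se Sensitivity of the principal class, in \[0, 1\].
#' @param child_se Sensitivity of the sub-class, in \[0, 1\].
#' @return `parent_se * child_se`.
#' @export
compounded_accuracy <- function(parent_se, child_se) {
  stopifnot(all(parent_se >= 0 & parent_se <= 1),
            all(child_se >= 0 & child_se <= 1))
  parent_se * child_se
}

#' Full metrics report for one evaluation
#'
#' @param cm A [confusion_matrix()] of counts.
#' @return A tibble with one row: `acc` (class-balanced accuracy),
#'   `balanced_acc` (mean per-class recall), `macro_f1`, and a `per_class`
#'   list-column holding the [class_metrics()] table.
#' @export
metrics_report <- function(cm) {
  per_class <- class_metrics(cm)
  tibble::tibble(
    acc = papa_accuracy(cm),
    balanced_acc = balanced_accuracy(cm),
    macro_f1 = attr(per_class, "macro_f1"),
    per_class = list(per_class)
  )
}
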