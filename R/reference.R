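#' Reference confusion matrices for the real marmoset corpus
#'
#' Row-normalized (percent, rows = true class) confusion matrices reported
#' for the real marmoset call corpus: the eight principal classes, the
#' three Phee sub-classes and the two Tsik sub-classes, each from OPF
#' classifiers trained on 90% of the corpus and accumulated over 100
#' repetitions. Shipped as plain CSV so the hierarchical-accuracy
#' arithmetic ([balanced_accuracy()], [compounded_accuracy()]) can be
#' exercised and demonstrated without the audio corpus itself.
#'
#' @return A list of three `confusion_matrix` objects (percent scale):
#'   `principal` (8 x 8), `phee` (3 x 3), `tsik` (2 x 2).
#' @examples
#' ref <- reference_confusions()
#' balanced_accuracy(ref$tsik)  # 83
#' @export
reference_confusions <- function() {
  read_cm <- function(name) {
    path <- system.file("extdata", name, package = "callforest",
                        mustWork = TRUE)
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(true = df$true, predicted = colnames(m))
    class(m) <- c("confusion_matrix", class(m))
    m
  }
  list(
    principal = read_cm("reference_cm_principal.csv"),
    phee = read_cm("reference_cm_phee.csv"),
    tsik = read_cm("reference_cm_tsik.csv")
  )
}

#' Hierarchical compounded accuracies from the reference tables
#'
#' Combines the principal-class sensitivities (Phee and Tsik rows of the
#' principal reference table) with the sub-class sensitivities (diagonals
#' of the Phee and Tsik reference tables) into per-sub-class compounded
#' accuracies.
#'
#' @return A tibble with `sub_class`, `parent_se`, `child_se` and
#'   `compounded`, all as fractions.
#' @export
reference_compounded <- function() {
  ref <- reference_confusions()
  parent_se <- diag(ref$principal) / rowSums(ref$principal)
  tibble::tibble(
    sub_class = c(rownames(ref$phee), rownames(ref$tsik)),
    parent = rep(c("Phee", "Tsik"), c(nrow(ref$phee), nrow(ref$tsik))),
    parent_se = c(rep(parent_se[["Phee"]], nrow(ref$phee)),
                  rep(parent_se[["Tsik"]], nrow(ref$tsik))),
    child_se = unname(c(diag(ref$phee) / rowSums(ref$phee),
                        diag(ref$tsik) / rowSums(ref$tsik)))
  ) |>
    dplyr::mutate(compounded = compounded_accuracy(.data$parent_se,
                                                   .data$child_se))
}
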