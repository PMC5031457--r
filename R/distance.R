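#' Distance metrics for the OPF graph
#'
#' The five arc-weight functions the classifier supports. All are symmetric
#' and non-negative with `d(x, x) = 0`. Because LPC coefficients are signed,
#' the three metrics defined for non-negative data use explicit conventions:
#' Canberra terms with `|x_i| + |y_i| = 0` are skipped; chi-square is
#' `sum (x_i - y_i)^2 / |x_i + y_i|` with zero-denominator terms skipped;
#' Bray-Curtis is `sum|x_i - y_i| / sum(|x_i| + |y_i|)`.
#'
#' @format NULL
#' @name opf_metrics
NULL

#' @rdname opf_metrics
#' @export
OPF_METRICS <- c("euclidean", "manhattan", "canberra", "chi_square",
                 "bray_curtis")

#' Distance between two feature vectors
#'
#' @param x,y Equal-length numeric vectors.
#' @param metric One of [OPF_METRICS].
#' @return A single non-negative number.
#' @export
compute_distance <- function(x, y, metric = "euclidean") {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y), call. = FALSE)
  }
  metric <- match.arg(metric, OPF_METRICS)
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    canberra = {
      den <- abs(x) + abs(y)
      keep <- den > 0
      sum(abs(x - y)[keep] / den[keep])
    },
    chi_square = {
      den <- abs(x + y)
      keep <- den > 0
      sum(((x - y)^2)[keep] / den[keep])
    },
    bray_curtis = {
      den <- sum(abs(x) + abs(y))
      if (den == 0) 0 else sum(abs(x - y)) / den
    }
  )
}

#' Pairwise distance matrix
#'
#' @param x Feature matrix (rows = samples) or feature tibble.
#' @param y Optional second matrix; defaults to `x`.
#' @param metric One of [OPF_METRICS].
#' @return An `nrow(x)` x `nrow(y)` matrix of distances.
#' @export
distance_matrix <- function(x, y = NULL, metric = "euclidean") {
  x <- feature_matrix(x)$x
  y <- if (is.null(y)) x else feature_matrix(y)$x
  metric <- match.arg(metric, OPF_METRICS)
  if (metric == "euclidean") {
    # |x - y|^2 = |x|^2 + |y|^2 - 2 x.y, clamped against rounding
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d <- sqrt(pmax(d2, 0))
    if (identical(dim(x), dim(y)) && all(x == y)) diag(d) <- 0
    return(d)
  }
  out <- matrix(0, nrow(x), nrow(y))
  for (j in seq_len(nrow(y))) {
    yj <- y[j, ]
    out[, j] <- switch(metric,
      manhattan = rowSums(abs(sweep(x, 2, yj))),
      canberra = {
        den <- sweep(abs(x), 2, abs(yj), "+")
        num <- abs(sweep(x, 2, yj))
        rowSums(ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0))
      },
      chi_square = {
        den <- abs(sweep(x, 2, yj, "+"))
        num <- sweep(x, 2, yj)^2
        rowSums(ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0))
      },
      bray_curtis = {
        num <- rowSums(abs(sweep(x, 2, yj)))
        den <- rowSums(abs(x)) + sum(abs(yj))
        ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
      }
    )
  }
  out
}
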