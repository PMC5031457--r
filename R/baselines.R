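#' Specification of a comparison classifier
#'
#' The six comparison families are configured here with the hyperparameter
#' protocols used throughout: k-NN searches odd `k` in `[1, floor(m/5)]` by
#' 5-fold cross-validation; the SVMs search `C` over `2^{-5}, 2^{-3}, ...,
#' 2^15` and the RBF width parameter over `2^{-15}, ..., 2^3` (exponent
#' step 2, an 11 x 10 grid) by 5-fold cross-validation; the MLP is a fixed
#' two-hidden-layer (8, 16) softmax network trained by limited-memory BFGS;
#' logistic regression is L2-regularized one-against-all; AdaBoost is the
#' SAMME.R real-boosting algorithm over shallow decision trees; the
#' Bayesian classifier uses per-class full-covariance Gaussian likelihoods
#' with empirical priors.
#'
#' @param algo One of `"bayes_gaussian"`, `"mlp"`, `"svm_rbf"`,
#'   `"svm_linear"`, `"svm_poly"`, `"knn"`, `"logreg"`, `"adaboost"`.
#' @param seed Integer seed fixed per training run (fold assignment,
#'   weight initialization).
#' @param ... Overrides of per-algorithm settings (e.g. `n_rounds`,
#'   `max_depth` for adaboost; `lambda` for logreg; `maxit` for mlp).
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(algo = c("bayes_gaussian", "mlp", "svm_rbf",
                                   "svm_linear", "svm_poly", "knn",
                                   "logreg", "adaboost"),
                          seed = 1L, ...) {
  algo <- match.arg(algo)
  structure(list(algo = algo, seed = as.integer(seed), opts = list(...)),
            class = "baseline_spec")
}

#' The SVM cross-validation grid
#'
#' @return A data frame of all `(C, gamma)` pairs searched: `C = 2^e` for
#'   `e` in `-5, -3, ..., 15` and `gamma = 2^e` for `e` in `-15, ..., 3`.
#' @export
svm_grid <- function() {
  expand.grid(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' The k-NN search grid
#'
#' @param m Number of training samples.
#' @return Odd values `1, 3, ...` up to `floor(m / 5)`.
#' @export
knn_grid <- function(m) {
  seq(1L, max(1L, m %/% 5L), by = 2L)
}

# stratified k-fold assignment; shrinks below `k` folds (with a warning)
# when the rarest class has fewer members than folds
make_folds <- function(labels, k = 5L) {
  min_class <- min(table(labels))
  if (min_class < k) {
    k <- max(2L, min_class)
    warning("shrinking cross-validation to ", k,
            " folds (smallest class has ", min_class, " samples)")
  }
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train a comparison classifier
#'
#' @param spec A [baseline_spec()].
#' @param features Feature tibble or matrix of training samples.
#' @param labels Class labels (taken from `features$label` when omitted).
#' @return A `baseline_model` handle with a [predict()] method returning
#'   labels.
#' @export
train_baseline <- function(spec, features, labels = NULL) {
  stopifnot(inherits(spec, "baseline_spec"))
  fm <- feature_matrix(features)
  x <- fm$x
  labels <- labels %||% fm$label
  f <- as.factor(labels)
  if (nlevels(f) < 2L) stop("need >= 2 classes", call. = FALSE)
  set.seed(spec$seed)
  fit <- switch(spec$algo,
    bayes_gaussian = .fit_bayes_gaussian(x, f, spec$opts),
    mlp = .fit_mlp(x, f, spec$opts),
    svm_rbf = .fit_svm(x, f, kernel = "radial", spec$opts),
    svm_linear = .fit_svm(x, f, kernel = "linear", spec$opts),
    svm_poly = .fit_svm(x, f, kernel = "polynomial", spec$opts),
    knn = .fit_knn(x, f, spec$opts),
    logreg = .fit_logreg(x, f, spec$opts),
    adaboost = .fit_adaboost(x, f, spec$opts)
  )
  structure(list(algo = spec$algo, seed = spec$seed, fit = fit,
                 class_names = levels(f)),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %s, %d classes\n", x$algo,
              length(x$class_names)))
  invisible(x)
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)$x
  set.seed(object$seed)  # e.g. k-NN distance-tie resolution
  pred <- switch(object$algo,
    bayes_gaussian = .predict_bayes_gaussian(object$fit, x),
    mlp = .predict_mlp(object$fit, x),
    svm_rbf = ,
    svm_linear = ,
    svm_poly = as.character(predict(object$fit$model, x)),
    knn = as.character(class::knn(object$fit$x, x, object$fit$y,
                                  k = object$fit$k)),
    logreg = .predict_logreg(object$fit, x),
    adaboost = .predict_adaboost(object$fit, x)
  )
  as.character(pred)
}

## ---- Gaussian Bayes ------------------------------------------------------

.fit_bayes_gaussian <- function(x, f, opts) {
  reg <- opts$reg %||% 1e-6
  classes <- levels(f)
  fits <- lapply(classes, function(cl) {
    xi <- x[f == cl, , drop = FALSE]
    mu <- colMeans(xi)
    sigma <- if (nrow(xi) > 1L) stats::cov(xi) else diag(ncol(x))
    # regularize toward a scaled identity until the Cholesky succeeds
    scale <- mean(diag(sigma))
    if (scale <= 0) scale <- 1
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch) || min(diag(ch))^2 < reg * scale) {
      warning("degenerate covariance for class ", cl,
              "; regularized toward identity")
      lambda <- reg
      repeat {
        ch <- tryCatch(chol(sigma + lambda * scale * diag(ncol(x))),
                       error = function(e) NULL)
        if (!is.null(ch)) break
        lambda <- lambda * 10
      }
    }
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         log_prior = log(sum(f == cl) / length(f)))
  })
  names(fits) <- classes
  fits
}

.predict_bayes_gaussian <- function(fit, x) {
  scores <- sapply(fit, function(cl) {
    z <- backsolve(cl$chol, t(x) - cl$mu, transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * cl$logdet + cl$log_prior
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  names(fit)[max.col(scores, ties.method = "first")]
}

## ---- two-hidden-layer MLP (8, 16), L-BFGS --------------------------------

.fit_mlp <- function(x, f, opts) {
  hidden <- opts$hidden %||% c(8L, 16L)
  maxit <- opts$maxit %||% 2000L
  K <- nlevels(f)
  y <- diag(K)[as.integer(f), , drop = FALSE]
  mu <- colMeans(x); sd <- apply(x, 2, stats::sd); sd[sd == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")

  sizes <- c(ncol(x), hidden, K)
  shapes <- lapply(seq_len(length(sizes) - 1L),
                   function(i) c(sizes[i], sizes[i + 1L]))
  n_par <- sum(vapply(shapes, function(s) s[1] * s[2] + s[2], numeric(1)))
  unpack <- function(theta) {
    out <- vector("list", length(shapes)); pos <- 0L
    for (i in seq_along(shapes)) {
      s <- shapes[[i]]; nw <- s[1] * s[2]
      out[[i]] <- list(W = matrix(theta[pos + seq_len(nw)], s[1], s[2]),
                       b = theta[pos + nw + seq_len(s[2])])
      pos <- pos + nw + s[2]
    }
    out
  }
  forward <- function(layers) {
    a <- xs; acts <- list()
    for (i in seq_along(layers)) {
      z <- sweep(a %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
      a <- if (i < length(layers)) tanh(z) else z
      acts[[i]] <- a
    }
    zmax <- apply(a, 1, max)
    p <- exp(a - zmax); p <- p / rowSums(p)
    list(acts = acts, p = p)
  }
  obj <- function(theta) {
    p <- forward(unpack(theta))$p
    -sum(y * log(pmax(p, 1e-12))) / nrow(xs)
  }
  grad <- function(theta) {
    layers <- unpack(theta)
    fw <- forward(layers)
    delta <- (fw$p - y) / nrow(xs)
    g <- numeric(length(theta)); pos_end <- length(theta)
    for (i in rev(seq_along(layers))) {
      a_prev <- if (i == 1L) xs else fw$acts[[i - 1L]]
      gW <- crossprod(a_prev, delta); gb <- colSums(delta)
      nw <- length(gW)
      g[(pos_end - nw - length(gb) + 1L):pos_end] <- c(gW, gb)
      pos_end <- pos_end - nw - length(gb)
      if (i > 1L) {
        delta <- (delta %*% t(layers[[i]]$W)) * (1 - fw$acts[[i - 1L]]^2)
      }
    }
    g
  }
  theta0 <- stats::runif(n_par, -0.5, 0.5)
  res <- stats::optim(theta0, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  if (res$convergence != 0) {
    warning("MLP optimizer did not converge within ", maxit, " iterations")
  }
  list(layers = unpack(res$par), mu = mu, sd = sd, levels = levels(f))
}

.predict_mlp <- function(fit, x) {
  a <- sweep(sweep(x, 2, fit$mu), 2, fit$sd, "/")
  for (i in seq_along(fit$layers)) {
    z <- sweep(a %*% fit$layers[[i]]$W, 2, fit$layers[[i]]$b, "+")
    a <- if (i < length(fit$layers)) tanh(z) else z
  }
  fit$levels[max.col(a, ties.method = "first")]
}

## ---- SVM (libsvm via e1071), 5-fold CV grid search -----------------------

.fit_svm <- function(x, f, kernel, opts) {
  grid <- svm_grid()
  fold <- make_folds(f, 5L)
  k <- max(fold)
  best <- NULL; best_acc <- -1
  for (g in seq_len(nrow(grid))) {
    acc <- 0
    for (i in seq_len(k)) {
      m <- e1071::svm(x[fold != i, , drop = FALSE], f[fold != i],
                      kernel = kernel, cost = grid$C[g],
                      gamma = grid$gamma[g], scale = FALSE)
      acc <- acc + mean(predict(m, x[fold == i, , drop = FALSE]) == f[fold == i])
    }
    acc <- acc / k
    if (acc > best_acc) { best_acc <- acc; best <- grid[g, ] }
  }
  model <- e1071::svm(x, f, kernel = kernel, cost = best$C,
                      gamma = best$gamma, scale = FALSE)
  list(model = model, C = best$C, gamma = best$gamma, cv_acc = best_acc)
}

## ---- k-NN, CV over odd k -------------------------------------------------

.fit_knn <- function(x, f, opts) {
  ks <- knn_grid(nrow(x))
  fold <- make_folds(f, 5L)
  nf <- max(fold)
  accs <- vapply(ks, function(k) {
    mean(vapply(seq_len(nf), function(i) {
      pred <- class::knn(x[fold != i, , drop = FALSE],
                         x[fold == i, , drop = FALSE],
                         f[fold != i], k = min(k, sum(fold != i)))
      mean(pred == f[fold == i])
    }, numeric(1)))
  }, numeric(1))
  list(x = x, y = f, k = ks[which.max(accs)], cv_acc = max(accs))
}

## ---- L2 one-against-all logistic regression ------------------------------

.fit_logreg <- function(x, f, opts) {
  lambda <- opts$lambda %||% 1e-3
  classes <- levels(f)
  fits <- lapply(classes, function(cl) {
    glmnet::glmnet(x, as.integer(f == cl), family = "binomial",
                   alpha = 0, lambda = lambda)
  })
  names(fits) <- classes
  list(fits = fits, lambda = lambda)
}

.predict_logreg <- function(fit, x) {
  scores <- sapply(fit$fits, function(m) {
    as.numeric(predict(m, x, type = "link"))
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  names(fit$fits)[max.col(scores, ties.method = "first")]
}

## ---- AdaBoost SAMME.R over shallow rpart trees ---------------------------

.fit_adaboost <- function(x, f, opts) {
  n_rounds <- opts$n_rounds %||% 50L
  max_depth <- opts$max_depth %||% 3L
  K <- nlevels(f)
  n <- nrow(x)
  df <- data.frame(y = f, x, check.names = FALSE)
  w <- rep(1 / n, n)
  y_code <- matrix(-1 / (K - 1), n, K)
  y_code[cbind(seq_len(n), as.integer(f))] <- 1
  stages <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    tree <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = max_depth, cp = 0, minsplit = 2,
                           xval = 0))
    p <- .rpart_probs(tree, df, levels(f))
    logp <- log(pmax(p, 1e-10))
    stages[[r]] <- tree
    # reweight toward samples the stage's probability estimate gets wrong
    w <- w * exp(-(K - 1) / K * rowSums(y_code * logp))
    s <- sum(w)
    if (!is.finite(s) || s <= 0) { stages <- stages[seq_len(r)]; break }
    w <- w / s
  }
  list(stages = stages[!vapply(stages, is.null, logical(1))],
       levels = levels(f), K = K)
}

.rpart_probs <- function(tree, df, levels) {
  p_raw <- predict(tree, df, type = "prob")
  p <- matrix(0, nrow(df), length(levels), dimnames = list(NULL, levels))
  p[, colnames(p_raw)] <- p_raw
  p
}

.predict_adaboost <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  K <- fit$K
  h <- matrix(0, nrow(df), K)
  for (tree in fit$stages) {
    logp <- log(pmax(.rpart_probs(tree, df, fit$levels), 1e-10))
    h <- h + (K - 1) * (logp - rowMeans(logp))
  }
  fit$levels[max.col(h, ties.method = "first")]
}
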