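# Independent oracles and fixture builders used across the suite.

# Bottleneck (minimax) distance closure by iterated min-max dynamic
# programming: B[i,j] = min over intermediates of the max arc. Independent
# of the package's priority-queue propagation.
minimax_closure <- function(d) {
  b <- d
  m <- nrow(d)
  repeat {
    b_new <- b
    for (k in seq_len(m)) {
      b_new <- pmin(b_new, outer(b_new[, k], b_new[k, ], pmax))
    }
    if (isTRUE(all.equal(b, b_new))) break
    b <- b_new
  }
  diag(b) <- 0
  b
}

# Exhaustive enumeration of all simple paths from any prototype to each
# node, recording the minimax cost. Only feasible for tiny m.
enumerate_minimax <- function(d, protos) {
  m <- nrow(d)
  best <- rep(Inf, m)
  best[protos] <- 0
  recurse <- function(node, visited, cost) {
    if (cost < best[node]) best[node] <<- cost
    for (nxt in seq_len(m)[-visited]) {
      nc <- max(cost, d[node, nxt])
      if (nc < best[nxt] || nc < max(best)) {
        recurse(nxt, c(visited, nxt), nc)
      }
    }
  }
  for (p in protos) recurse(p, p, 0)
  best
}

# Naive classification: full scan of min_s max(C(s), d(s, t)) with the
# lower-node-index tie rule; no early stopping, no cost ordering.
naive_opf_predict <- function(model, x) {
  x <- as.matrix(x)
  apply(x, 1, function(row) {
    d <- vapply(seq_len(nrow(model$train_features)), function(s) {
      compute_distance(row, model$train_features[s, ], model$metric)
    }, numeric(1))
    vals <- pmax(model$cost, d)
    model$class_names[model$root_label[which.min(vals)]]
  })
}

# Feature tibble of well-separated Gaussian clusters with random center
# directions (avoids collinear-center degeneracies).
make_clusters <- function(K = 2, n_per = 20, dim = 5, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(K * dim), K, dim)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  x <- do.call(rbind, lapply(seq_len(K), function(k) {
    sweep(matrix(rnorm(n_per * dim), n_per, dim), 2, centers[k, ], "+")
  }))
  colnames(x) <- paste0("c", seq_len(dim))
  dplyr::bind_cols(
    tibble::tibble(label = rep(LETTERS[seq_len(K)], each = n_per)),
    tibble::as_tibble(x)
  )
}

# Random small training set for oracle-equivalence sweeps.
random_training_set <- function(seed) {
  set.seed(seed)
  m <- sample(4:10, 1)
  K <- sample(2:4, 1)
  dim <- sample(2:5, 1)
  x <- matrix(stats::runif(m * dim, -2, 2), m, dim)
  labels <- c(seq_len(K), sample(seq_len(K), m - K, replace = TRUE))
  list(x = x, labels = LETTERS[labels])
}

rms <- function(x) sqrt(mean(x^2))

counts_cm <- function(m, class_names = NULL) {
  class_names <- class_names %||% as.character(seq_len(nrow(m)))
  m <- matrix(as.numeric(m), nrow(m),
              dimnames = list(true = class_names, predicted = class_names))
  class(m) <- c("confusion_matrix", class(m))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
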