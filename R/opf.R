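#' Minimum spanning tree of a distance matrix
#'
#' Prim's algorithm with a deterministic tie rule: nodes are admitted in
#' index order among equal connection costs, and a node's tree parent is
#' only replaced on a strict improvement. On an all-ties graph this yields
#' the edge set with the lexicographically smallest `(i, j)` indices, so
#' prototype election (and hence the whole forest) is reproducible.
#'
#' @param dist An `m` x `m` symmetric matrix of finite non-negative
#'   distances, `m >= 2`.
#' @return An `(m - 1)` x 2 integer matrix of edges, each row `(i, j)` with
#'   `i < j`, ordered by insertion; total weight is minimal.
#' @export
build_mst <- function(dist) {
  m <- nrow(dist)
  if (is.null(m) || m < 2L || ncol(dist) != m) {
    stop("`dist` must be a square matrix with at least 2 nodes", call. = FALSE)
  }
  if (!all(is.finite(dist))) stop("distances must be finite", call. = FALSE)
  in_tree <- logical(m)
  best_cost <- rep(Inf, m)
  parent <- rep(NA_integer_, m)
  best_cost[1L] <- 0
  edges <- matrix(NA_integer_, m - 1L, 2L)
  for (step in seq_len(m)) {
    cand <- which(!in_tree)
    u <- cand[which.min(best_cost[cand])]   # which.min takes first = lowest index
    in_tree[u] <- TRUE
    if (step > 1L) {
      edges[step - 1L, ] <- sort(c(parent[u], u))
    }
    improve <- !in_tree & dist[u, ] < best_cost
    best_cost[improve] <- dist[u, improve]
    parent[improve] <- u
  }
  edges
}

#' Elect OPF prototypes from the MST
#'
#' Prototypes are the competing roots of the optimum-path forest. They are
#' placed where classification errors concentrate: every endpoint of an MST
#' edge whose two endpoints carry different class labels becomes a
#' prototype, so each side of every class frontier is represented.
#'
#' @param mst_edges Edge matrix from [build_mst()].
#' @param labels Integer or factor class labels, one per node.
#' @return Sorted integer vector of prototype node indices (non-empty).
#' @export
select_prototypes <- function(mst_edges, labels) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2L) {
    stop("OPF requires >= 2 classes in the training set", call. = FALSE)
  }
  crossing <- labels[mst_edges[, 1L]] != labels[mst_edges[, 2L]]
  sort(unique(as.integer(mst_edges[crossing, ])))
}

#' Fit a supervised Optimum-Path Forest classifier
#'
#' Trains the complete-graph OPF variant. The training samples form a fully
#' connected graph whose arcs are weighted by `metric`; prototypes elected
#' on the class frontiers of the minimum spanning tree compete for the
#' remaining samples under the bottleneck path cost (a path costs its
#' maximum arc weight; a sample's optimum cost `C(s)` is the minimum such
#' value over all paths from any prototype). The propagation is a
#' priority-queue minimax variant of Dijkstra seeded at the prototypes with
#' cost 0; ties are broken toward the lower node index.
#'
#' @param features Feature tibble (with `label` column used when `labels`
#'   is missing) or numeric matrix, rows = training samples.
#' @param labels Class labels, one per row; taken from `features$label`
#'   when omitted.
#' @param metric One of [OPF_METRICS]; default `"euclidean"`.
#' @return An object of class `opf_model` with elements `train_features`,
#'   `train_labels` (integer ids), `class_names`, `cost`, `root_label`,
#'   `prototype`, `ordered_index` (node ids by ascending cost) and `metric`.
#' @seealso [predict.opf_model()], [tidy.opf_model()], [write_opf()]
#' @export
opf_fit <- function(features, labels = NULL, metric = "euclidean") {
  fm <- feature_matrix(features)
  x <- fm$x
  labels <- labels %||% fm$label
  if (is.null(labels)) stop("no labels supplied", call. = FALSE)
  if (length(labels) != nrow(x)) stop("one label per row required", call. = FALSE)
  m <- nrow(x)
  if (m < 2L) stop("need at least 2 training samples", call. = FALSE)
  metric <- match.arg(metric, OPF_METRICS)

  f <- as.factor(labels)
  y <- as.integer(f)
  if (nlevels(f) < 2L) {
    stop("OPF requires >= 2 classes in the training set", call. = FALSE)
  }

  d <- distance_matrix(x, metric = metric)
  if (any(d[upper.tri(d)] == 0)) {
    ij <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
    if (any(y[ij[, 1L]] != y[ij[, 2L]])) {
      warning("duplicate feature vectors across classes; both become prototypes")
    }
  }
  protos <- select_prototypes(build_mst(d), y)

  cost <- rep(Inf, m)
  root_label <- rep(NA_integer_, m)
  cost[protos] <- 0
  root_label[protos] <- y[protos]

  done <- logical(m)
  for (step in seq_len(m)) {
    cand <- which(!done)
    u <- cand[which.min(cost[cand])]
    done[u] <- TRUE
    new_cost <- pmax(cost[u], d[u, ])
    improve <- !done & new_cost < cost
    cost[improve] <- new_cost[improve]
    root_label[improve] <- root_label[u]
  }

  structure(
    list(
      train_features = x,
      train_labels = y,
      class_names = levels(f),
      cost = cost,
      root_label = root_label,
      prototype = seq_len(m) %in% protos,
      ordered_index = order(cost),
      metric = metric
    ),
    class = "opf_model"
  )
}

#' @export
print.opf_model <- function(x, ...) {
  cat(sprintf(
    "<opf_model> %d training samples, %d classes, %d prototypes, %s distance\n",
    nrow(x$train_features), length(x$class_names), sum(x$prototype), x$metric))
  invisible(x)
}

#' Classify samples with a fitted OPF model
#'
#' Each test sample is conceptually appended to the forest: it takes the
#' label of the training node minimizing `max(C(s), d(s, t))`. The search
#' walks the cost-ordered node index and stops as soon as the next stored
#' cost can no longer improve the best value found — the efficient
#' classification step of the complete-graph OPF.
#'
#' @param object A fitted `opf_model`.
#' @param newdata Feature tibble or matrix (a single vector is taken as one
#'   sample); a `label` column, if present, is ignored.
#' @param type `"class"` (default) for labels on the training label scale,
#'   `"cost"` to also return the optimum path cost of each sample.
#' @param ... Unused.
#' @return A vector of predicted labels, or a tibble with `.pred` and
#'   `.cost` when `type = "cost"`.
#' @export
predict.opf_model <- function(object, newdata, type = c("class", "cost"), ...) {
  type <- match.arg(type)
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  x <- feature_matrix(newdata)$x
  if (ncol(x) != ncol(object$train_features)) {
    stop("newdata has ", ncol(x), " features; model expects ",
         ncol(object$train_features), call. = FALSE)
  }
  d_all <- distance_matrix(x, object$train_features, metric = object$metric)
  ord <- object$ordered_index
  cost_ord <- object$cost[ord]
  root_ord <- object$root_label[ord]

  n <- nrow(x)
  pred <- integer(n)
  pcost <- numeric(n)
  for (i in seq_len(n)) {
    d <- d_all[i, ]
    best <- max(cost_ord[1L], d[ord[1L]])
    best_root <- root_ord[1L]
    j <- 2L
    while (j <= length(ord) && cost_ord[j] < best) {
      val <- max(cost_ord[j], d[ord[j]])
      if (val < best) {
        best <- val
        best_root <- root_ord[j]
      }
      j <- j + 1L
    }
    pred[i] <- best_root
    pcost[i] <- best
  }
  labels <- object$class_names[pred]
  if (type == "class") labels else tibble::tibble(.pred = labels, .cost = pcost)
}

#' Classify a single feature vector
#'
#' Thin wrapper over [predict.opf_model()] for one sample.
#'
#' @param model A fitted `opf_model`.
#' @param x Numeric feature vector.
#' @return The predicted label (character).
#' @export
opf_predict <- function(model, x) {
  predict(model, matrix(as.numeric(x), nrow = 1L))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted OPF model
#'
#' One row per training node with its label, optimum path cost, conquering
#' root's label and prototype status.
#'
#' @param x An `opf_model`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `label`, `cost`, `root_label`,
#'   `prototype`.
#' @export
tidy.opf_model <- function(x, ...) {
  tibble::tibble(
    node = seq_along(x$cost),
    label = x$class_names[x$train_labels],
    cost = x$cost,
    root_label = x$class_names[x$root_label],
    prototype = x$prototype
  )
}

#' One-row summary of a fitted OPF model
#'
#' @param x An `opf_model`.
#' @param ... Unused.
#' @return A tibble with `n_train`, `n_classes`, `n_prototypes`, `metric`,
#'   `max_cost`.
#' @export
glance.opf_model <- function(x, ...) {
  tibble::tibble(
    n_train = nrow(x$train_features),
    n_classes = length(x$class_names),
    n_prototypes = sum(x$prototype),
    metric = x$metric,
    max_cost = max(x$cost)
  )
}

#' Serialize / restore an OPF model
#'
#' Writes the full model (arrays, class names, metric, format version) to a
#' single self-describing JSON file and reads it back.
#'
#' @param model An `opf_model`.
#' @param path File path.
#' @return `write_opf()` returns `path` invisibly; `read_opf()` returns the
#'   restored `opf_model`.
#' @export
write_opf <- function(model, path) {
  stopifnot(inherits(model, "opf_model"))
  payload <- list(
    format = "callforest-opf",
    version = 1L,
    metric = model$metric,
    class_names = model$class_names,
    train_labels = model$train_labels,
    cost = model$cost,
    root_label = model$root_label,
    prototype = model$prototype,
    ordered_index = model$ordered_index,
    n_features = ncol(model$train_features),
    train_features = as.vector(t(model$train_features))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_opf
#' @export
read_opf <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "callforest-opf")) {
    stop("'", path, "' is not a callforest OPF model file", call. = FALSE)
  }
  structure(
    list(
      train_features = matrix(p$train_features, ncol = p$n_features, byrow = TRUE),
      train_labels = as.integer(p$train_labels),
      class_names = p$class_names,
      cost = p$cost,
      root_label = as.integer(p$root_label),
      prototype = as.logical(p$prototype),
      ordered_index = as.integer(p$ordered_index),
      metric = p$metric
    ),
    class = "opf_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
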