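test_that("distance metrics satisfy their defining identities", {
  expect_equal(compute_distance(c(0, 0), c(3, 4), "euclidean"), 5)
  expect_equal(compute_distance(c(1, 2), c(4, 6), "manhattan"), 7)
  expect_equal(compute_distance(c(1, -1), c(1, 1), "canberra"), 1)
  # chi-square with |x + y| denominators, zero terms skipped
  expect_equal(compute_distance(c(1, -1), c(1, 1), "chi_square"), 0)
  expect_equal(compute_distance(c(0, 2), c(2, 0), "chi_square"), 4)
  expect_equal(compute_distance(c(1, 0), c(0, 1), "bray_curtis"), 1)

  set.seed(2)
  for (metric in OPF_METRICS) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(compute_distance(x, y, metric),
                 compute_distance(y, x, metric))
    expect_equal(compute_distance(x, x, metric), 0)
    expect_gte(compute_distance(x, y, metric), 0)
  }
  expect_error(compute_distance(1:3, 1:4), "length mismatch")
})

test_that("distance_matrix agrees with compute_distance pairwise", {
  set.seed(4)
  x <- matrix(rnorm(7 * 5), 7, 5)
  for (metric in OPF_METRICS) {
    d <- distance_matrix(x, metric = metric)
    ref <- outer(1:7, 1:7, Vectorize(function(i, j) {
      compute_distance(x[i, ], x[j, ], metric)
    }))
    expect_equal(d, ref, tolerance = 1e-7)
  }
})

test_that("build_mst returns a minimum spanning tree with deterministic ties", {
  # 1-D points {0, 1, 3}: edges (1,2) and (2,3), total weight 3
  d <- as.matrix(dist(c(0, 1, 3)))
  edges <- build_mst(d)
  expect_equal(nrow(edges), 2L)
  expect_setequal(apply(edges, 1, paste, collapse = "-"), c("1-2", "2-3"))

  # two nodes: the single edge
  expect_equal(build_mst(as.matrix(dist(c(0, 5)))), matrix(c(1L, 2L), 1))

  # equilateral tie: lexicographically smallest edge set, minimal weight
  d_eq <- matrix(1, 3, 3); diag(d_eq) <- 0
  e_eq <- build_mst(d_eq)
  expect_equal(e_eq, matrix(c(1L, 1L, 2L, 3L), 2))
  expect_equal(sum(d_eq[e_eq]), 2)

  expect_error(build_mst(matrix(0, 1, 1)), "at least 2")
})

test_that("MST total weight matches an independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(8)
  for (i in 1:20) {
    m <- sample(3:12, 1)
    x <- matrix(rnorm(m * 3), m, 3)
    d <- as.matrix(dist(x))
    edges <- build_mst(d)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    ref <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(sum(d[edges]), ref, tolerance = 1e-10)
  }
})

test_that("prototypes are the endpoints of class-frontier MST edges", {
  # chain A A | B B with unit spacing: the middle edge crosses
  d <- as.matrix(dist(c(0, 1, 2, 3)))
  expect_equal(select_prototypes(build_mst(d), c("A", "A", "B", "B")),
               c(2L, 3L))

  # alternating chain: every edge crosses, all nodes prototypes
  expect_equal(select_prototypes(build_mst(d), c("A", "B", "A", "B")), 1:4)

  # three classes on a line: two frontier edges, four prototypes
  d6 <- as.matrix(dist(c(0, 1, 2, 3, 4, 5)))
  expect_equal(select_prototypes(build_mst(d6), rep(c("A", "B", "C"), each = 2)),
               2:5)

  expect_error(select_prototypes(build_mst(d), rep("A", 4)), ">= 2 classes")
})

test_that("opf_fit reproduces the hand-computed chain forest", {
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  m <- opf_fit(x, c("A", "A", "B", "B"))
  expect_equal(m$cost, c(1, 0, 0, 1))
  expect_equal(m$class_names[m$root_label], c("A", "A", "B", "B"))
  expect_equal(which(m$prototype), c(2L, 3L))
  expect_equal(m$cost[m$ordered_index], sort(m$cost))
  # prototypes have cost exactly 0
  expect_true(all(m$cost[m$prototype] == 0))
  # Eq-2 hand evaluation: x = 1.4 is conquered by the node at 1 (cost 0.4)
  expect_equal(opf_predict(m, 1.4), "A")
  expect_error(opf_fit(x, rep("A", 4)), ">= 2 classes")
  expect_error(opf_fit(x[1, , drop = FALSE], "A"), "at least 2")
})

test_that("training costs equal exhaustive minimax-path enumeration (all metrics)", {
  for (metric in OPF_METRICS) {
    for (seed in 1:12) {
      ts <- random_training_set(seed * 100 + match(metric, OPF_METRICS))
      model <- opf_fit(ts$x, ts$labels, metric = metric)
      d <- distance_matrix(ts$x, metric = metric)
      protos <- which(model$prototype)
      expect_equal(model$cost, enumerate_minimax(d, protos),
                   tolerance = 1e-12,
                   info = paste(metric, "seed", seed))
    }
  }
})

test_that("early-stopping classification equals the naive full scan", {
  set.seed(21)
  for (metric in OPF_METRICS) {
    df <- make_clusters(K = 3, n_per = 15, dim = 4, sep = 4,
                        seed = match(metric, OPF_METRICS))
    sp <- stratified_split(df, 0.6, seed = 1)
    model <- opf_fit(sp$train, metric = metric)
    pred_fast <- predict(model, sp$test)
    pred_naive <- naive_opf_predict(model, feature_matrix(sp$test)$x)
    expect_equal(pred_fast, unname(pred_naive))
  }
})

test_that("predicting the training set returns the training labels", {
  set.seed(33)
  for (i in 1:5) {
    ts <- random_training_set(400 + i)
    model <- opf_fit(ts$x, ts$labels)
    expect_equal(predict(model, ts$x), ts$labels)
  }
})

test_that("predictions are invariant to squaring the distances", {
  # f_max and the Eq-2 argmin are order statistics of the arc weights
  set.seed(12)
  df <- make_clusters(K = 3, n_per = 10, dim = 3, sep = 3, seed = 7)
  sp <- stratified_split(df, 0.7, seed = 2)
  m1 <- opf_fit(sp$train, metric = "euclidean")
  m2 <- m1
  # manually rebuild with squared euclidean: same MST, same order structure
  x <- feature_matrix(sp$train)$x
  d2 <- distance_matrix(x, metric = "euclidean")^2
  protos <- select_prototypes(build_mst(d2), m1$train_labels)
  expect_equal(protos, which(m1$prototype))
  b <- minimax_closure(d2)
  cost2 <- apply(b[protos, , drop = FALSE], 2, min)
  expect_equal(cost2, m1$cost^2, tolerance = 1e-10)
  # label assignment unchanged on held-out data
  xt <- feature_matrix(sp$test)$x
  pred1 <- predict(m1, xt)
  pred2 <- apply(xt, 1, function(row) {
    d <- colSums((t(x) - row)^2)
    m1$class_names[m1$root_label[which.min(pmax(cost2, d))]]
  })
  expect_equal(pred1, unname(pred2))
})

test_that("well-separated clusters are classified perfectly", {
  df <- make_clusters(K = 2, n_per = 30, dim = 5, sep = 12, seed = 9)
  sp <- stratified_split(df, 0.5, seed = 3)
  model <- opf_fit(sp$train)
  expect_equal(mean(predict(model, sp$test) == sp$test$label), 1.0)
})

test_that("duplicate feature vectors across classes trigger a warning, not a failure", {
  x <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), 4, 2)
  expect_warning(m <- opf_fit(x, c("A", "B", "A", "B")), "duplicate")
  expect_s3_class(m, "opf_model")
})

test_that("OPF models serialize and restore losslessly", {
  dir <- withr::local_tempdir()
  df <- make_clusters(K = 2, n_per = 8, dim = 3, sep = 6, seed = 14)
  model <- opf_fit(df, metric = "manhattan")
  path <- file.path(dir, "model.json")
  write_opf(model, path)
  back <- read_opf(path)
  expect_equal(back$cost, model$cost)
  expect_equal(back$metric, model$metric)
  expect_equal(predict(back, df), predict(model, df))
})

test_that("tidy and glance summarize a fitted forest", {
  df <- make_clusters(K = 2, n_per = 6, dim = 3, sep = 6, seed = 15)
  model <- opf_fit(df)
  td <- tidy(model)
  expect_equal(nrow(td), 12L)
  expect_true(all(td$cost[td$prototype] == 0))
  expect_equal(td$label, td$root_label)  # zero training error
  gl <- glance(model)
  expect_equal(gl$n_train, 12L)
  expect_equal(gl$n_classes, 2L)
  expect_equal(gl$n_prototypes, sum(td$prototype))
})
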