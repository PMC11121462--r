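test_that("min-max normalization scales, degenerates and inverts correctly", {
  tab <- make_samples(3, glu = c(2, 4, 6), fru = c(10, 10, 10),
                      suc = c(0.5, 1, 1.5), acid = c(5, 10, 20),
                      econd = c(0.1, 0.4, 0.7), mc = c(14, 16, 18),
                      dia = c(9, 12, 15), ins = c(0, 0.01, 0.02))
  nf <- normalize_features(tab)
  expect_equal(unname(nf$X[, "glu"]), c(0, 0.5, 1))
  expect_equal(unname(nf$X[, "fru"]), c(0, 0, 0))  # constant feature -> 0
  expect_true(all(nf$X >= 0 & nf$X <= 1))

  raw <- denormalize_features(nf$X, nf$scaling)
  keep <- mlp_features()[apply(as.matrix(tab[, mlp_features()]), 2, sd) > 0]
  expect_lt(max(abs(raw[, keep] - as.matrix(tab[, keep]))), 1e-12)

  # stored scaling reapplies to unseen data
  nf2 <- normalize_features(make_samples(1, glu = 4), nf$scaling)
  expect_equal(unname(nf2$X[1, "glu"]), 0.5)
})

test_that("forward pass is a proper softmax network", {
  set.seed(31)
  # random models: probabilities positive, rows sum to 1 within 1e-9
  for (i in 1:20) {
    w <- list(W1 = matrix(rnorm(96, sd = 3), 8, 12), b1 = rnorm(12, sd = 3),
              W2 = matrix(rnorm(72, sd = 3), 12, 6), b2 = rnorm(6, sd = 3))
    X <- matrix(runif(40), 5, 8)
    P <- forward_probabilities(w, X)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= 0))
  }

  # all-zero parameters give the uniform distribution
  w0 <- list(W1 = matrix(0, 8, 12), b1 = rep(0, 12),
             W2 = matrix(0, 12, 6), b2 = rep(0, 6))
  expect_equal(unname(forward_probabilities(w0, runif(8))[1, ]),
               rep(1 / 6, 6))
})

test_that("a 2-2-2 toy network reproduces a hand-computed forward pass", {
  w <- list(W1 = matrix(c(1, -1, 0.5, 2), 2, 2), b1 = c(0.1, -0.2),
            W2 = matrix(c(1, 0, -1, 1), 2, 2), b2 = c(0, 0.3))
  x <- c(0.4, 0.6)
  # hand arithmetic: z1 = (0.4 - 0.6 + 0.1, 0.2 + 1.2 - 0.2) = (-0.1, 1.2)
  h <- 1 / (1 + exp(-c(-0.1, 1.2)))
  z2 <- c(h[1], -h[1] + h[2] + 0.3)
  p_hand <- exp(z2) / sum(exp(z2))
  P <- forward_probabilities(
    list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2), x)
  expect_equal(unname(P[1, ]), p_hand, tolerance = 1e-6)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(17)
  X <- matrix(runif(10 * 8), 10, 8)
  Y <- diag(6)[sample(1:6, 10, replace = TRUE), ]
  fn <- honeyaudit:::mlp_loss_fn(X, Y, 12L)
  gr <- honeyaudit:::mlp_grad_fn(X, Y, 12L)
  theta <- rnorm(186, sd = 0.5)
  g <- gr(theta)
  h <- 1e-5
  idx <- sample(186, 40)
  for (j in idx) {
    e <- rep(0, 186); e[j] <- h
    fd <- (fn(theta + e) - fn(theta - e)) / (2 * h)
    expect_lt(abs(g[j] - fd) / max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("stratified split keeps every class in training", {
  labels <- c(rep("polyfloral", 100), rep("monofloral", 3), rep("acacia", 40))
  sp <- stratified_split(labels, 0.7, seed = 2)
  expect_setequal(unique(labels[sp$train]), unique(labels))
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_identical(sp, stratified_split(labels, 0.7, seed = 2))
  expect_error(stratified_split(labels, 1.2), "fraction")
})

test_that("training separates well-separated classes and is deterministic", {
  set.seed(55)
  n <- 50
  tab <- make_samples(
    2 * n,
    sample_id = sprintf("T%03d", 1:(2 * n)),
    declared_type = rep(c("acacia", "linden"), each = n),
    glu = c(rnorm(n, 20, 1), rnorm(n, 40, 1)),   # 4+ SD apart
    fru = c(rnorm(n, 30, 1), rnorm(n, 46, 1)),
    econd = runif(2 * n, 0.2, 0.6)
  )
  tab$final_type <- tab$declared_type
  fit <- train_classifier(tab, restarts = 3L, maxit = 200L)
  expect_equal(fit$evaluation$train$accuracy, 100)

  fit2 <- train_classifier(tab, restarts = 3L, maxit = 200L)
  expect_identical(fit$model$weights, fit2$model$weights)

  expect_error(train_classifier(make_final(), restarts = 1L), "two classes")
})

test_that("evaluation reports confusion, per-class rates and accuracy", {
  tab <- make_samples(6, sample_id = sprintf("E%d", 1:6))
  tab$final_type <- c("acacia", "acacia", "linden", "linden", "honeydew",
                      "honeydew")
  # degenerate model predicting the uniform argmax (first class) for all
  w0 <- list(W1 = matrix(0, 8, 12), b1 = rep(0, 12),
             W2 = matrix(0, 12, 6), b2 = rep(0, 6))
  model <- structure(list(weights = w0,
                          scaling = normalize_features(tab)$scaling,
                          classes = honey_types()), class = "mlp_model")
  ev <- evaluate_classifier(model, tab)
  expect_equal(sum(ev$confusion), 6)
  expect_equal(unname(ev$per_class_rate[["acacia"]]), 100)
  expect_equal(ev$accuracy, 2 / 6 * 100)
  # per-class rate is diagonal over row sum by definition
  expect_equal(unname(ev$per_class_rate["honeydew"]),
               ev$confusion["honeydew", "honeydew"] /
                 sum(ev$confusion["honeydew", ]) * 100)
  expect_error(evaluate_classifier(model, tab[0, ]), "empty")
})
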