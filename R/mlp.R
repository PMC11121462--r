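#' Feature normalization for the honey-type classifier
#'
#' The classifier reads eight physicochemical inputs — glucose, fructose,
#' sucrose, acidity, electrical conductivity, moisture, diastase activity
#' and insoluble matter (5-HMF is excluded: it marks processing damage, not
#' botanical origin) — each min-max scaled to \[0, 1\]. A constant feature
#' maps to 0. The scaling parameters are kept with the model so unseen
#' samples are scaled identically at inference.
#'
#' @param table a sample table.
#' @param scaling optional previously fitted scaling (named list with `min`
#'   and `max` vectors); when NULL it is fitted on `table`.
#' @return A list: `X` (n x 8 matrix in \[0, 1\] for fitted scaling),
#'   `scaling`.
#' @export
normalize_features <- function(table, scaling = NULL) {
  feats <- mlp_features()
  X <- as.matrix(table[, feats])
  if (is.null(scaling)) {
    scaling <- list(min = apply(X, 2L, min), max = apply(X, 2L, max))
  }
  rng <- scaling$max - scaling$min
  Xs <- sweep(X, 2L, scaling$min, "-")
  Xs <- sweep(Xs, 2L, ifelse(rng == 0, 1, rng), "/")
  Xs[, rng == 0] <- 0
  list(X = Xs, scaling = scaling)
}

#' @rdname normalize_features
#' @export
mlp_features <- function() {
  c("glu", "fru", "suc", "acid", "econd", "mc", "dia", "ins")
}

#' @rdname normalize_features
#' @param X scaled matrix.
#' @return `denormalize_features`: the raw-scale matrix.
#' @export
denormalize_features <- function(X, scaling) {
  rng <- scaling$max - scaling$min
  sweep(sweep(X, 2L, rng, "*"), 2L, scaling$min, "+")
}

logistic <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# pack/unpack the 186 parameters of the 8-12-6 network
mlp_unpack <- function(theta, n_in = 8L, n_hid = 12L, n_out = 6L) {
  stopifnot(length(theta) == n_in * n_hid + n_hid + n_hid * n_out + n_out)
  i <- 0L
  W1 <- matrix(theta[i + seq_len(n_in * n_hid)], n_in, n_hid)
  i <- i + n_in * n_hid
  b1 <- theta[i + seq_len(n_hid)]; i <- i + n_hid
  W2 <- matrix(theta[i + seq_len(n_hid * n_out)], n_hid, n_out)
  i <- i + n_hid * n_out
  b2 <- theta[i + seq_len(n_out)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_pack <- function(w) c(w$W1, w$b1, w$W2, w$b2)

#' Forward pass of the multilayer perceptron
#'
#' `h = logistic(W1' x + b1)`, `p = softmax(W2' h + b2)`; the softmax rows
#' sum to one for any parameter values.
#'
#' @param model an `mlp_model` (from [train_classifier()]) or a raw weight
#'   list with `W1`, `b1`, `W2`, `b2`.
#' @param X matrix of scaled feature rows (or a single vector).
#' @return Matrix of class probabilities, one row per input.
#' @export
forward_probabilities <- function(model, X) {
  w <- if (inherits(model, "mlp_model")) model$weights else model
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  H <- logistic(sweep(X %*% w$W1, 2L, w$b1, "+"))
  softmax_rows(sweep(H %*% w$W2, 2L, w$b2, "+"))
}

# mean categorical cross-entropy on a fixed design (closure)
mlp_loss_fn <- function(X, Y, n_hid) {
  n_in <- ncol(X); n_out <- ncol(Y); n <- nrow(X)
  function(theta) {
    w <- mlp_unpack(theta, n_in, n_hid, n_out)
    P <- forward_probabilities(w, X)
    -mean(rowSums(Y * log(pmax(P, 1e-300))))
  }
}

mlp_grad_fn <- function(X, Y, n_hid) {
  n_in <- ncol(X); n_out <- ncol(Y); n <- nrow(X)
  function(theta) {
    w <- mlp_unpack(theta, n_in, n_hid, n_out)
    H <- logistic(sweep(X %*% w$W1, 2L, w$b1, "+"))
    P <- softmax_rows(sweep(H %*% w$W2, 2L, w$b2, "+"))
    D2 <- (P - Y) / n                      # softmax + cross-entropy delta
    gW2 <- t(H) %*% D2
    gb2 <- colSums(D2)
    D1 <- (D2 %*% t(w$W2)) * H * (1 - H)   # logistic derivative
    gW1 <- t(X) %*% D1
    gb1 <- colSums(D1)
    mlp_pack(list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
  }
}

#' Stratified train/test split
#'
#' Splits row indices into a training fraction per class, so every class
#' present in the table is represented in the training subset (guarding
#' small classes). With `stratify = FALSE` the split is a plain random
#' permutation.
#'
#' @param labels class label vector.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @param stratify logical.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, fraction = 0.7, seed = 1L,
                             stratify = TRUE) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  idx <- seq_along(labels)
  if (stratify) {
    train <- integer(0)
    for (cl in unique(labels)) {
      cl_idx <- idx[labels == cl]
      n_tr <- max(1L, round(length(cl_idx) * fraction))
      train <- c(train, sort(sample(cl_idx, n_tr)))
    }
    train <- sort(train)
  } else {
    train <- sort(sample(idx, round(length(idx) * fraction)))
  }
  list(train = train, test = setdiff(idx, train))
}

#' Train the 8-12-6 honey-type classifier
#'
#' Multilayer perceptron with a logistic hidden layer and softmax output,
#' trained by minimizing mean categorical cross-entropy with the BFGS
#' quasi-Newton optimizer (analytic backpropagation gradient). Several
#' random initializations are run (weights uniform in \[-0.5, 0.5\] scaled
#' by 1/sqrt(fan-in)) and the fit with the lowest loss on the held-out
#' subset is kept. Fully deterministic given the seeds.
#'
#' @param table a sample table with `final_type` set (the training label).
#' @param hidden hidden-layer width (default 12).
#' @param split_fraction training fraction (default 0.70).
#' @param split_seed,init_seed integer seeds for the split and the weight
#'   initializations.
#' @param restarts number of random initializations (default 10).
#' @param maxit BFGS iteration cap per restart (default 500).
#' @param reltol BFGS relative convergence tolerance.
#' @param stratify stratify the split by class (default TRUE).
#' @return A list with `model` (`mlp_model`: weights, scaling, classes,
#'   training metadata) and `evaluation` (train/test [evaluate_classifier()]
#'   reports).
#' @export
train_classifier <- function(table, hidden = 12L, split_fraction = 0.7,
                             split_seed = 1L, init_seed = 2L,
                             restarts = 10L, maxit = 500L, reltol = 1e-10,
                             stratify = TRUE) {
  if (!"final_type" %in% names(table)) stop("final_type must be set")
  classes <- honey_types()
  labels <- table$final_type
  present <- unique(labels)
  if (length(present) < 2L) stop("need at least two classes")
  split <- stratified_split(labels, split_fraction, split_seed, stratify)
  if (!all(present %in% labels[split$train])) {
    stop("a class is absent from the training split; use stratify = TRUE")
  }
  norm <- normalize_features(table)
  X <- norm$X
  Y <- outer(labels, classes, "==") * 1
  n_in <- ncol(X); n_out <- length(classes)
  fn <- mlp_loss_fn(X[split$train, , drop = FALSE],
                    Y[split$train, , drop = FALSE], hidden)
  gr <- mlp_grad_fn(X[split$train, , drop = FALSE],
                    Y[split$train, , drop = FALSE], hidden)
  val_fn <- mlp_loss_fn(X[split$test, , drop = FALSE],
                        Y[split$test, , drop = FALSE], hidden)
  n_par <- n_in * hidden + hidden + hidden * n_out + n_out
  set.seed(as.integer(init_seed))
  best <- NULL
  chunk <- 20L
  for (r in seq_len(restarts)) {
    theta <- c(stats::runif(n_in * hidden, -0.5, 0.5) / sqrt(n_in),
               rep(0, hidden),
               stats::runif(hidden * n_out, -0.5, 0.5) / sqrt(hidden),
               rep(0, n_out))
    stopifnot(length(theta) == n_par)
    # BFGS in short chunks, retaining the iterate with the lowest held-out
    # loss seen along the path (validation-error minimization); the raw
    # training loss is monotone non-increasing across accepted steps.
    r_best <- list(par = theta, val = val_fn(theta), train_loss = fn(theta))
    done <- 0L
    while (done < maxit) {
      opt <- stats::optim(theta, fn, gr, method = "BFGS",
                          control = list(maxit = min(chunk, maxit - done),
                                         reltol = reltol))
      theta <- opt$par
      done <- done + chunk
      v <- val_fn(theta)
      if (v < r_best$val) {
        r_best <- list(par = theta, val = v, train_loss = opt$value)
      }
      if (opt$convergence == 0L) break
    }
    if (is.null(best) || r_best$val < best$val) {
      best <- c(r_best, restart = r)
    }
  }
  model <- structure(list(
    weights = mlp_unpack(best$par, n_in, hidden, n_out),
    scaling = norm$scaling,
    classes = classes,
    hidden = hidden,
    train_loss = best$train_loss,
    validation_loss = best$val,
    chosen_restart = best$restart,
    split = split,
    config = list(split_fraction = split_fraction, split_seed = split_seed,
                  init_seed = init_seed, restarts = restarts, maxit = maxit)
  ), class = "mlp_model")
  evaluation <- list(
    train = evaluate_classifier(model, table[split$train, ]),
    test = evaluate_classifier(model, table[split$test, ])
  )
  list(model = model, evaluation = evaluation)
}

#' Predict honey types
#'
#' @param model an `mlp_model`.
#' @param table a sample table sharing the feature schema.
#' @return Character vector of predicted classes (argmax probability,
#'   first-index tie-break).
#' @export
predict_types <- function(model, table) {
  X <- normalize_features(table, model$scaling)$X
  P <- forward_probabilities(model, X)
  model$classes[max.col(P, ties.method = "first")]
}

#' Evaluate the classifier on a labeled table
#'
#' @param model an `mlp_model`.
#' @param table a sample table with `final_type` labels.
#' @return A list: `confusion` (6 x 6 true x predicted counts),
#'   `per_class_rate` (diagonal / row sum, %; `NaN` for absent classes),
#'   `accuracy` (%), `n`.
#' @export
evaluate_classifier <- function(model, table) {
  if (nrow(table) == 0L) stop("cannot evaluate on an empty table")
  pred <- predict_types(model, table)
  truth <- factor(table$final_type, levels = model$classes)
  predf <- factor(pred, levels = model$classes)
  confusion <- table(truth, predf, dnn = c("true", "predicted"))
  rate <- diag(confusion) / rowSums(confusion) * 100
  list(confusion = unclass(confusion),
       per_class_rate = rate,
       accuracy = sum(diag(confusion)) / nrow(table) * 100,
       n = nrow(table))
}
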