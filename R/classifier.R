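#' Stratified train/validation split of a feature matrix
#'
#' Partitions runs 70-30 (by default), stratified by species so each class
#' keeps its share on both sides (within one row). In grouped mode all
#' replicates of one specimen land on the same side, the leak-aware
#' alternative to the study's run-level split.
#'
#' @param feats A `melt_features` object.
#' @param train_fraction Fraction of rows assigned to training.
#' @param seed Integer seed; the split is a pure function of it.
#' @param group_by_specimen Keep a specimen's replicates together.
#' @return List of class `corpus_split` with `train` and `validation`
#'   `melt_features`.
#' @export
split_corpus <- function(feats, train_fraction = 0.7, seed = 1,
                         group_by_specimen = FALSE) {
  stopifnot(inherits(feats, "melt_features"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  set.seed(as.integer(seed))
  meta <- feats$meta
  take <- logical(nrow(meta))
  if (group_by_specimen) {
    units <- dplyr::distinct(meta, .data$specimen_id, .data$species)
    key <- units$species; id <- units$specimen_id
  } else {
    key <- meta$species; id <- meta$run_id
  }
  for (cls in sort(unique(key))) {
    members <- id[key == cls]
    n <- length(members)
    if (n == 1) {
      warning("stratum `", cls, "` has a single unit; assigned to train")
      chosen <- members
    } else {
      n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
      chosen <- sample(members, n_train)
    }
    if (group_by_specimen) {
      take[meta$specimen_id %in% chosen] <- TRUE
    } else {
      take[meta$run_id %in% chosen] <- TRUE
    }
  }
  structure(list(train = features_subset(feats, which(take)),
                 validation = features_subset(feats, which(!take))),
            class = "corpus_split")
}

#' Network hyperparameter configuration
#'
#' Architecture and optimisation settings for the feedforward classifier:
#' hidden layer sizes, rectifier or tanh activation, epochs, learning rate
#' with momentum, minibatch size, and the l1 (sparsity) and l2 (weight
#' decay) penalties used to combat overfitting.
#'
#' @param hidden Integer vector of hidden layer sizes (>= 1 layer).
#' @param activation `"relu"` or `"tanh"`.
#' @param epochs Training epochs.
#' @param learning_rate SGD step size.
#' @param momentum Classical momentum coefficient.
#' @param batch_size Minibatch size.
#' @param l1,l2 Regularization penalties (>= 0).
#' @param standardize Standardize features to zero mean / unit s.d. using
#'   training statistics.
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @return A list of class `net_config`.
#' @export
net_config <- function(hidden = c(64, 32), activation = c("relu", "tanh"),
                       epochs = 50L, learning_rate = 0.003, momentum = 0.9,
                       batch_size = 16L, l1 = 0, l2 = 1e-4,
                       standardize = TRUE, seed = 1L) {
  activation <- match.arg(activation)
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || any(hidden < 1))
    stop("at least one hidden layer with >= 1 unit is required")
  if (l1 < 0 || l2 < 0) stop("penalties must be >= 0")
  structure(list(hidden = hidden, activation = activation,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 l1 = l1, l2 = l2, standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "net_config")
}

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) * 1),
         tanh = list(f = tanh, df = function(z, a) 1 - a^2))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

fann_forward <- function(W, b, act, x) {
  L <- length(W)
  a <- x
  zs <- vector("list", L); as <- vector("list", L + 1)
  as[[1]] <- a
  for (l in seq_len(L)) {
    z <- a %*% W[[l]] + matrix(b[[l]], nrow(a), length(b[[l]]), byrow = TRUE)
    zs[[l]] <- z
    a <- if (l < L) act$f(z) else softmax_rows(z)
    as[[l + 1]] <- a
  }
  list(zs = zs, as = as, scores = a)
}

fann_metrics <- function(scores, y_onehot) {
  pred <- max.col(scores, ties.method = "first")
  truth <- max.col(y_onehot, ties.method = "first")
  list(accuracy = 100 * mean(pred == truth),
       rmse = sqrt(mean((scores - y_onehot)^2)))
}

#' Train the feedforward species-assignment network
#'
#' A multi-layer feedforward artificial neural network with a softmax
#' output over the species labels, trained by minibatch stochastic gradient
#' descent with backpropagation on the multinomial cross-entropy objective,
#' with l1 (sparsity) and l2 (weight decay) regularization. Per-epoch
#' training and validation accuracy and RMSE (on one-hot targets vs the
#' score vectors) are logged. Fully deterministic given the config seed.
#'
#' @param train,validation `melt_features` with >= 2 species in `train`.
#' @param config A [net_config()].
#' @return An object of class `fann_model`: the config, learned weights,
#'   class labels, feature standardization, per-epoch `history`, and final
#'   training/validation accuracy (percent) and RMSE.
#' @export
train_fann <- function(train, validation = NULL, config = net_config()) {
  stopifnot(inherits(train, "melt_features"))
  classes <- sort(unique(train$meta$species))
  if (length(classes) < 2) stop("training data must cover at least 2 classes")
  x <- train$x
  if (!is.null(validation) && ncol(validation$x) != ncol(x))
    stop("validation feature width differs from training")
  mu <- if (config$standardize) colMeans(x) else numeric(ncol(x))
  sdev <- if (config$standardize) {
    s <- apply(x, 2, stats::sd); s[s < 1e-12] <- 1; s
  } else rep(1, ncol(x))
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  y <- match(train$meta$species, classes)
  y_onehot <- diag(length(classes))[y, , drop = FALSE]
  xv <- NULL; yv_onehot <- NULL
  if (!is.null(validation)) {
    xv <- sweep(sweep(validation$x, 2, mu), 2, sdev, "/")
    yv <- match(validation$meta$species, classes)
    if (anyNA(yv)) stop("validation contains species absent from training")
    yv_onehot <- diag(length(classes))[yv, , drop = FALSE]
  }

  sizes <- c(ncol(x), config$hidden, length(classes))
  L <- length(sizes) - 1
  set.seed(config$seed)
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  vW <- lapply(W, function(w) w * 0)
  vb <- lapply(b, function(x) x * 0)
  act <- act_fun(config$activation)
  n <- nrow(xs)
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      xb <- xs[bt, , drop = FALSE]
      yb <- y_onehot[bt, , drop = FALSE]
      fw <- fann_forward(W, b, act, xb)
      if (!all(is.finite(fw$scores)))
        stop("non-finite loss during training; lower the learning rate")
      m <- length(bt)
      delta <- (fw$scores - yb) / m           # softmax + cross-entropy
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$as[[l]], delta) +
          config$l2 * W[[l]] + config$l1 * sign(W[[l]])
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * act$df(fw$zs[[l - 1]], fw$as[[l]])
        }
        vW[[l]] <- config$momentum * vW[[l]] - config$learning_rate * gW
        vb[[l]] <- config$momentum * vb[[l]] - config$learning_rate * gb
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    tr <- fann_metrics(fann_forward(W, b, act, xs)$scores, y_onehot)
    va <- if (!is.null(xv))
      fann_metrics(fann_forward(W, b, act, xv)$scores, yv_onehot)
    else list(accuracy = NA_real_, rmse = NA_real_)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_accuracy = tr$accuracy, train_rmse = tr$rmse,
      validation_accuracy = va$accuracy, validation_rmse = va$rmse)
  }
  history <- purrr::list_rbind(history)
  last <- history[nrow(history), ]
  structure(list(config = config, weights = list(W = W, b = b),
                 classes = classes, feature_names = colnames(x),
                 mu = mu, sd = sdev, history = history,
                 train_accuracy = last$train_accuracy,
                 train_rmse = last$train_rmse,
                 validation_accuracy = last$validation_accuracy,
                 validation_rmse = last$validation_rmse),
            class = "fann_model")
}

#' @export
print.fann_model <- function(x, ...) {
  cat(sprintf(
    "<fann_model> %s, hidden [%s], %d classes\n  train acc %.2f%% rmse %.4f | validation acc %s rmse %s\n",
    x$config$activation, paste(x$config$hidden, collapse = ", "),
    length(x$classes), x$train_accuracy, x$train_rmse,
    ifelse(is.na(x$validation_accuracy), "-",
           sprintf("%.2f%%", x$validation_accuracy)),
    ifelse(is.na(x$validation_rmse), "-", sprintf("%.4f", x$validation_rmse))))
  invisible(x)
}

#' @method tidy fann_model
#' @export
tidy.fann_model <- function(x, ...) x$history

#' @method glance fann_model
#' @export
glance.fann_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = length(x$feature_names),
    hidden = paste(x$config$hidden, collapse = "x"),
    epochs = x$config$epochs, l1 = x$config$l1, l2 = x$config$l2,
    train_accuracy = x$train_accuracy, train_rmse = x$train_rmse,
    validation_accuracy = x$validation_accuracy,
    validation_rmse = x$validation_rmse)
}

#' Predict species for new runs
#'
#' Softmax class scores and the argmax assignment; exact ties break towards
#' the alphabetically first species (relevant for the configured
#' identical-signature pairs at zero noise). Deterministic given the model
#' and input.
#'
#' @param object A trained `fann_model`.
#' @param newdata A `melt_features` object or a numeric matrix with the
#'   model's feature width.
#' @param ... Unused.
#' @return A tibble: `run_id`, `predicted`, `score` (winning class score),
#'   `margin` (gap to the runner-up), then one score column per species.
#'   Scores are non-negative and each row sums to one.
#' @export
predict.fann_model <- function(object, newdata, ...) {
  if (inherits(newdata, "melt_features")) {
    x <- newdata$x
    ids <- newdata$meta$run_id
  } else {
    x <- as.matrix(newdata)
    ids <- rownames(x) %||% paste0("row", seq_len(nrow(x)))
  }
  if (ncol(x) != length(object$feature_names))
    stop("feature width ", ncol(x), " does not match the model (",
         length(object$feature_names), ")")
  xs <- sweep(sweep(x, 2, object$mu), 2, object$sd, "/")
  act <- act_fun(object$config$activation)
  scores <- fann_forward(object$weights$W, object$weights$b, act, xs)$scores
  colnames(scores) <- object$classes   # classes are sorted: ties go alphabetical
  pick <- max.col(scores, ties.method = "first")
  top2 <- apply(scores, 1, function(s) sort(s, decreasing = TRUE)[1:2])
  out <- tibble::tibble(
    run_id = ids,
    predicted = object$classes[pick],
    score = unname(top2[1, ]),
    margin = unname(top2[1, ] - top2[2, ]))
  dplyr::bind_cols(out, tibble::as_tibble(scores, .name_repair = "minimal"))
}
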