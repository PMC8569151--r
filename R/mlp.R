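# Small fully-connected regression network trained by full-batch
# backpropagation with classical momentum. Deliberately minimal: the point is
# a deterministic, seeded re-implementation of the reference multilayer
# perceptron (3 hidden layers of 5/4/3 sigmoid nodes, linear output).

#' Multilayer perceptron configuration
#'
#' Defaults mirror the reference training setup: hidden layers of 5, 4 and 3
#' sigmoid nodes, learning rate 0.001, momentum 0.99, 10,000 full-batch
#' epochs. Initial weights are drawn uniform(-0.5, 0.5) from the given seed,
#' so training is fully deterministic.
#'
#' @param hidden_layers integer node counts per hidden layer.
#' @param learning_rate gradient-descent step size (> 0).
#' @param momentum classical momentum coefficient in [0, 1).
#' @param epochs number of full-batch epochs (>= 0).
#' @param seed integer RNG seed for weight initialization.
#' @return an object of class \code{mlp_config}.
#' @export
mlp_config <- function(hidden_layers = c(5L, 4L, 3L), learning_rate = 0.001,
                       momentum = 0.99, epochs = 10000L, seed = 1L) {
  hidden_layers <- as.integer(hidden_layers)
  if (any(hidden_layers < 1L)) stop("all hidden layer sizes must be >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  if (momentum < 0 || momentum >= 1) stop("`momentum` must be in [0, 1)")
  if (epochs < 0) stop("`epochs` must be >= 0")
  structure(list(hidden_layers = hidden_layers,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "mlp_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

with_local_seed <- function(seed, expr) {
  force(seed)  # must evaluate before snapshotting the caller's RNG state
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Train the multilayer perceptron
#'
#' Inputs are standardized per feature and the response is standardized to
#' zero mean, unit variance; both scalings are stored in the model and undone
#' at prediction. The loss is half the mean squared error on the standardized
#' response; weights are updated once per epoch (full batch) with classical
#' momentum.
#'
#' @param table data.frame holding feature and trait columns.
#' @param features feature column names.
#' @param trait response column name.
#' @param config an \code{mlp_config}.
#' @return an object of class \code{mlp_model} with weights, biases, scalers
#'   and the per-epoch \code{loss_path}.
#' @export
train_mlp <- function(table, features, trait, config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"))
  missing_f <- setdiff(c(features, trait), names(table))
  if (length(missing_f))
    stop(sprintf("missing column(s): %s", paste(missing_f, collapse = ", ")))
  x <- as.matrix(table[, features, drop = FALSE])
  y <- as.numeric(table[[trait]])
  if (!is.numeric(x)) stop("all features must be numeric")
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 training rows")
  x_mean <- colMeans(x)
  x_sd <- apply(x, 2L, stats::sd)
  x_sd[x_sd == 0] <- 1
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) y_sd <- 1
  xs <- sweep(sweep(x, 2L, x_mean), 2L, x_sd, "/")
  ys <- matrix((y - y_mean) / y_sd, ncol = 1)

  sizes <- c(ncol(x), config$hidden_layers, 1L)
  L <- length(sizes) - 1L
  init <- with_local_seed(config$seed, {
    lapply(seq_len(L), function(l) {
      list(w = matrix(stats::runif(sizes[l] * sizes[l + 1], -0.5, 0.5),
                      sizes[l], sizes[l + 1]),
           b = stats::runif(sizes[l + 1], -0.5, 0.5))
    })
  })
  w <- lapply(init, `[[`, "w")
  b <- lapply(init, `[[`, "b")
  vw <- lapply(w, function(m) m * 0)
  vb <- lapply(b, function(v) v * 0)

  loss_path <- numeric(config$epochs)
  lr <- config$learning_rate; mom <- config$momentum
  for (epoch in seq_len(config$epochs)) {
    # forward
    a <- vector("list", L + 1L)
    a[[1]] <- xs
    for (l in seq_len(L)) {
      z <- sweep(a[[l]] %*% w[[l]], 2L, b[[l]], "+")
      a[[l + 1]] <- if (l < L) .sigmoid(z) else z
    }
    res <- a[[L + 1]] - ys
    loss <- 0.5 * mean(res^2)
    if (!is.finite(loss))
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
    loss_path[epoch] <- loss
    # backward
    delta <- res / n
    for (l in rev(seq_len(L))) {
      gw <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(w[[l]])) * a[[l]] * (1 - a[[l]])
      vw[[l]] <- mom * vw[[l]] - lr * gw
      vb[[l]] <- mom * vb[[l]] - lr * gb
      w[[l]] <- w[[l]] + vw[[l]]
      b[[l]] <- b[[l]] + vb[[l]]
    }
  }
  structure(list(weights = w, biases = b, features = features, trait = trait,
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
                 config = config, loss_path = loss_path),
            class = "mlp_model")
}

#' Predict traits with a trained multilayer perceptron
#'
#' @param table data.frame holding the model's feature columns.
#' @param model an \code{mlp_model}.
#' @return numeric trait predictions on the original trait scale.
#' @export
predict_mlp <- function(table, model) {
  stopifnot(inherits(model, "mlp_model"))
  missing_f <- setdiff(model$features, names(table))
  if (length(missing_f))
    stop(sprintf("missing feature(s): %s", paste(missing_f, collapse = ", ")))
  x <- as.matrix(table[, model$features, drop = FALSE])
  a <- sweep(sweep(x, 2L, model$x_mean), 2L, model$x_sd, "/")
  L <- length(model$weights)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$weights[[l]], 2L, model$biases[[l]], "+")
    a <- if (l < L) .sigmoid(z) else z
  }
  unname(drop(a)) * model$y_sd + model$y_mean
}

#' @export
print.mlp_model <- function(x, ...) {
  sizes <- c(length(x$x_mean), x$config$hidden_layers, 1L)
  cat(sprintf("<mlp_model> %s ~ %s; layers %s; %d epochs, final loss %.4g\n",
              x$trait, paste(x$features, collapse = "+"),
              paste(sizes, collapse = "-"), x$config$epochs,
              if (length(x$loss_path)) utils::tail(x$loss_path, 1) else NA))
  invisible(x)
}
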