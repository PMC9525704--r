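# Subtype classification behind a pluggable interface. The main model is a
# self-organising stacked auto-encoder: encoder layers are grown greedily
# (units then layers) while the relative validation-loss improvement exceeds
# a tolerance, each new layer is pretrained as an auto-encoder on the
# activations below it, and the whole stack plus a softmax head is fine-tuned
# end to end. A single-hidden-layer MLP and a nearest-centroid model are
# available as baselines/oracles under the identical fit/predict contract.

#' Classifier configuration
#'
#' @param max_layers Maximum number of encoding layers grown.
#' @param max_units Maximum units in the first encoding layer.
#' @param tolerance Relative validation-loss improvement below which growth
#'   stops.
#' @param pretrain_epochs Epochs of layer-wise auto-encoder pretraining.
#' @param finetune_epochs Epochs of end-to-end fine-tuning.
#' @param learning_rate Adam step size.
#' @param seed Integer seed; fixes initialisation and training exactly.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(max_layers = 3L, max_units = 64L, tolerance = 1e-3,
                              pretrain_epochs = 100L, finetune_epochs = 400L,
                              learning_rate = 0.02, seed = 1L) {
  stopifnot(max_layers >= 1, max_units >= 1, tolerance > 0,
            pretrain_epochs >= 1, finetune_epochs >= 1, learning_rate > 0)
  structure(list(max_layers = as.integer(max_layers),
                 max_units = as.integer(max_units), tolerance = tolerance,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Fit a subtype classifier on the training partition of a split cohort
#'
#' @param data A cohort tibble with a `partition` column; values are expected
#'   min-max scaled to [0, 1]. Training uses the `train` rows; the `sodae`
#'   growth loop and model selection use the `validation` rows.
#' @param features Character vector of panel feature IDs to train on.
#' @param model_kind `"sodae"` (self-organising stacked auto-encoder),
#'   `"mlp_baseline"` (single-hidden-layer MLP) or `"nearest_centroid"`.
#' @param config A [classifier_config()].
#' @return A `subtype_classifier` object with a [predict][predict.subtype_classifier]
#'   method.
#' @export
fit_classifier <- function(data, features = feature_names(data),
                           model_kind = c("sodae", "mlp_baseline", "nearest_centroid"),
                           config = classifier_config()) {
  model_kind <- match.arg(model_kind)
  .assert_cohort(data)
  if (length(features) == 0) abort("panel is empty")
  if (!"partition" %in% names(data)) abort("data needs a partition column (see split_holdout)")
  train <- dplyr::filter(data, .data$partition == "train")
  val <- dplyr::filter(data, .data$partition == "validation")
  classes <- sort(unique(train$subtype))
  if (length(classes) < 2) abort("training data holds a single class; nothing to classify")
  x <- cohort_matrix(train, features)
  y <- .one_hot(train$subtype, classes)
  xv <- cohort_matrix(val, features)
  yv <- .one_hot(val$subtype, classes)

  model <- with_seed(config$seed, switch(
    model_kind,
    sodae = .fit_sodae(x, y, xv, yv, config),
    mlp_baseline = .fit_mlp(x, y, config),
    nearest_centroid = .fit_centroid(x, train$subtype, classes)
  ))
  structure(list(kind = model_kind, model = model, features = features,
                 classes = classes, config = config),
            class = "subtype_classifier")
}

.one_hot <- function(labels, classes) {
  y <- matrix(0, nrow = length(labels), ncol = length(classes),
              dimnames = list(NULL, classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}

# ---- small dense-network machinery (sigmoid hidden layers) ------------------

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

.init_layer <- function(n_in, n_out) {
  list(w = matrix(rnorm(n_in * n_out, sd = sqrt(1 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

.net_forward <- function(layers, x, out = c("softmax", "sigmoid")) {
  out <- match.arg(out)
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  for (l in seq_along(layers)) {
    z <- acts[[l]] %*% layers[[l]]$w + rep(layers[[l]]$b, each = nrow(x))
    acts[[l + 1]] <- if (l == length(layers) && out == "softmax") .softmax(z) else .sigmoid(z)
  }
  acts
}

# Full-batch Adam on a stack of dense layers. loss = "ce" (softmax cross
# entropy on the last layer) or "mse" (sigmoid output, squared error).
.net_train <- function(layers, x, y, epochs, lr, loss = c("ce", "mse")) {
  loss <- match.arg(loss)
  out <- if (loss == "ce") "softmax" else "sigmoid"
  n <- nrow(x)
  mom <- lapply(layers, function(l) list(mw = 0 * l$w, vw = 0 * l$w,
                                         mb = 0 * l$b, vb = 0 * l$b))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    acts <- .net_forward(layers, x, out)
    yhat <- acts[[length(acts)]]
    delta <- if (loss == "ce") (yhat - y) / n else 2 * (yhat - y) * yhat * (1 - yhat) / n
    for (l in rev(seq_along(layers))) {
      gw <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        a <- acts[[l]]
        delta <- (delta %*% t(layers[[l]]$w)) * a * (1 - a)
      }
      m <- mom[[l]]
      m$mw <- b1 * m$mw + (1 - b1) * gw; m$vw <- b2 * m$vw + (1 - b2) * gw^2
      m$mb <- b1 * m$mb + (1 - b1) * gb; m$vb <- b2 * m$vb + (1 - b2) * gb^2
      mom[[l]] <- m
      corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
      layers[[l]]$w <- layers[[l]]$w - lr * (m$mw / corr1) / (sqrt(m$vw / corr2) + eps)
      layers[[l]]$b <- layers[[l]]$b - lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
    }
  }
  layers
}

.ce_loss <- function(p, y) -mean(rowSums(y * log(pmax(p, 1e-12))))

# Greedy structure growth: encoder layers are added (sizes d*2/3, then halved)
# while the relative validation-loss improvement exceeds the tolerance; every
# candidate stack is pretrained layer-wise and fine-tuned with a softmax head;
# the stack with the best validation accuracy wins (ties -> fewer layers).
.fit_sodae <- function(x, y, xv, yv, config) {
  d <- ncol(x)
  sizes <- integer(0)
  h <- min(config$max_units, max(4L, ceiling(d * 2 / 3)))
  encoders <- list()
  best <- NULL
  prev_loss <- Inf
  act <- x
  for (depth in seq_len(config$max_layers)) {
    sizes <- c(sizes, h)
    # pretrain the new layer as an auto-encoder on the activations below it
    ae <- list(.init_layer(ncol(act), h), .init_layer(h, ncol(act)))
    ae <- .net_train(ae, act, act, config$pretrain_epochs, config$learning_rate, "mse")
    encoders[[depth]] <- ae[[1]]
    act <- .net_forward(ae[1], act, "sigmoid")[[2]]
    # fine-tune the full stack with a softmax head
    layers <- c(encoders[seq_len(depth)], list(.init_layer(h, ncol(y))))
    layers <- .net_train(layers, x, y, config$finetune_epochs, config$learning_rate, "ce")
    pv <- .net_forward(layers, xv, "softmax")[[depth + 2]]
    vloss <- .ce_loss(pv, yv)
    vacc <- mean(max.col(pv) == max.col(yv))
    if (is.null(best) || vacc > best$val_accuracy) {
      best <- list(layers = layers, sizes = sizes, val_accuracy = vacc,
                   val_loss = vloss)
    }
    improvement <- (prev_loss - vloss) / max(abs(prev_loss), 1e-12)
    if (depth > 1 && (!is.finite(improvement) || improvement <= config$tolerance)) break
    prev_loss <- vloss
    h <- max(4L, ceiling(h / 2))
  }
  best
}

.fit_mlp <- function(x, y, config) {
  size <- min(config$max_units, max(4L, ceiling(ncol(x) / 2)))
  fit <- nnet::nnet(x = x, y = y, size = size, softmax = TRUE,
                    maxit = config$finetune_epochs, decay = 1e-4,
                    MaxNWts = 1e6, trace = FALSE)
  list(fit = fit)
}

.fit_centroid <- function(x, labels, classes) {
  centroids <- t(vapply(classes, function(cls) colMeans(x[labels == cls, , drop = FALSE]),
                        numeric(ncol(x))))
  rownames(centroids) <- classes
  list(centroids = centroids)
}

#' Predict subtypes or class probabilities
#'
#' @param object A `subtype_classifier`.
#' @param newdata Cohort tibble on the same scale the model was trained on.
#' @param type `"class"` for hard labels, `"prob"` for a probability matrix.
#' @param ... Unused.
#' @return Character vector of labels, or a samples-by-classes matrix of
#'   scores in [0, 1].
#' @export
predict.subtype_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- cohort_matrix(newdata, object$features)
  p <- switch(
    object$kind,
    sodae = {
      acts <- .net_forward(object$model$layers, x, "softmax")
      acts[[length(acts)]]
    },
    mlp_baseline = predict(object$model$fit, x, type = "raw"),
    nearest_centroid = {
      d2 <- outer(rowSums(x^2), rep(1, nrow(object$model$centroids))) -
        2 * x %*% t(object$model$centroids) +
        outer(rep(1, nrow(x)), rowSums(object$model$centroids^2))
      .softmax(-sqrt(pmax(d2, 0)))
    }
  )
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}
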