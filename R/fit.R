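# Model fitting: preprocessing of scan datasets into fixed-size
# normalized clouds, the Adam training loop with best-validation
# checkpointing, and the S3 modelling interface around the fitted nets.

.augment_mat <- function(m, jitter_sd = 0.02) {
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m <- m %*% R
  if (jitter_sd > 0) m <- m + rnorm(length(m), 0, jitter_sd)
  m
}

.normalize_mat <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  r <- sqrt(max(rowSums(m^2)))
  if (r > 0) m / r else m
}

# One item per scene: the source point matrix plus its labels (per-point
# 0/1 for segmentation; for classification the source is the ground-truth
# back surface and the label the identity). Items are resampled to the
# model's input size by .draw_item -- freshly at every training pass, as
# part of the dynamic augmentation, and once (under the caller's seed)
# for validation and evaluation.
.prep_items <- function(dataset, task, npoints, seed) {
  set.seed(seed)
  items <- lapply(seq_along(dataset$scenes), function(i) {
    sc <- dataset$scenes[[i]]
    m <- .as_cloud_matrix(sc$cloud)
    if (task == "classification")
      list(src = m[sc$part_labels == 1L, , drop = FALSE],
           src_labels = NULL, labels = sc$identity)
    else list(src = m, src_labels = sc$part_labels, labels = NULL)
  })
  # fixed evaluation draw per item
  for (i in seq_along(items)) {
    it <- .draw_item(items[[i]], npoints)
    items[[i]]$cloud <- it$cloud
    if (is.null(items[[i]]$labels)) items[[i]]$labels <- it$labels
    items[[i]]$eval_labels <- it$labels
  }
  items
}

.draw_item <- function(it, npoints) {
  idx <- sample.int(nrow(it$src), npoints, replace = npoints > nrow(it$src))
  list(cloud = .normalize_mat(it$src[idx, , drop = FALSE]),
       labels = if (is.null(it$src_labels)) it$labels
                else it$src_labels[idx])
}

.eval_items <- function(net, items, idx) {
  loss <- 0
  correct <- 0
  total <- 0
  for (i in idx) {
    it <- items[[i]]
    fw <- net_forward(net, it$cloud)
    loss <- loss + nll_loss(fw$logp, it$labels)
    pred <- max.col(fw$logp) - 1L
    correct <- correct + sum(pred == it$labels)
    total <- total + length(it$labels)
  }
  list(loss = loss / length(idx), acc = correct / total)
}

#' Fit a point-cloud segmentation or identification model
#'
#' Trains a hierarchical point-cloud network on a labelled scan dataset
#' with Adam on the negative log-likelihood loss. Training items are
#' fixed-size random resamples of each scene, normalized to the unit
#' ball; during training each item is augmented with a random rotation
#' about the vertical axis and Gaussian coordinate jitter (sd 0.02 in
#' unit-ball units). Per-epoch training loss and validation loss/accuracy
#' are recorded and the parameters of the best validation epoch are
#' retained.
#'
#' For `task = "segmentation"` the model labels every point back (1) or
#' background (0); for `task = "classification"` the input is the
#' ground-truth back surface of each scene and the label its identity.
#'
#' @param dataset a `scan_dataset` from [make_dataset()] with a
#'   train/validation split.
#' @param task `"classification"` or `"segmentation"`.
#' @param variant grouping strategy of the classifier: `"lgg"`
#'   (local-global), `"msg"`, `"ssg"` or `"pointnet"`; ignored for
#'   segmentation.
#' @param scale `"small"` (desk-scale geometry, default) or `"full"`.
#' @param npoints points per training cloud (default 600 small / 2500
#'   full).
#' @param epochs training epochs; defaults to 50 for segmentation and 150
#'   for classification.
#' @param batch_size minibatch size (default 8).
#' @param lr Adam learning rate (default 0.001).
#' @param augment apply training-time augmentation.
#' @param seed integer seed controlling initialization, resampling,
#'   shuffling, augmentation and dropout; fixed seed gives identical
#'   runs.
#' @param config optional explicit [cls_model_config()] /
#'   [seg_model_config()] overriding `variant`/`scale`.
#' @param warmup number of optimizer steps over which the learning rate is
#'   ramped up linearly from zero (0 disables warmup).
#' @param clip global gradient-norm clipping threshold (`Inf` disables).
#' @param verbose print per-epoch progress.
#' @return a `pointnetpp_fit` object with `net`, `history` (per-epoch
#'   curves), `best_epoch`, and the training settings.
#' @export
fit_pointnetpp <- function(dataset,
                           task = c("classification", "segmentation"),
                           variant = c("lgg", "msg", "ssg", "pointnet"),
                           scale = c("small", "full"), npoints = NULL,
                           epochs = NULL, batch_size = 8L, lr = 1e-3,
                           augment = TRUE, seed = 1L, config = NULL,
                           warmup = 0L, clip = Inf, verbose = FALSE) {
  task <- match.arg(task)
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  stopifnot(inherits(dataset, "scan_dataset"))
  K <- if (task == "segmentation") 2L else length(unique(dataset$identity))
  if (is.null(npoints))
    npoints <- if (scale == "full") 2500L else 600L
  if (is.null(config))
    config <- if (task == "segmentation")
      seg_model_config(npoints, scale)
    else cls_model_config(variant, K = K, npoints = npoints, scale = scale)
  if (is.null(epochs))
    epochs <- if (task == "segmentation") 50L else 150L
  tr <- which(dataset$split == 0L)
  va <- which(dataset$split == 1L)
  if (length(tr) == 0L || length(va) == 0L)
    .invalid_argument("dataset needs non-empty train and validation splits")

  set.seed(seed)
  items <- .prep_items(dataset, task, npoints,
                       seed = sample.int(2^31 - 2, 1))
  net <- pointnetpp_net(config, seed = sample.int(2^31 - 2, 1))
  probe <- lapply(tr[seq_len(min(4L, length(tr)))],
                  function(i) items[[i]]$cloud)
  .calibrate_net(net, probe)
  st <- .adam_init(net$params)
  history <- vector("list", epochs)
  best <- list(acc = -1, params = NULL, epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    tloss <- 0
    nb <- 0L
    for (bstart in seq.int(1L, length(ord), by = batch_size)) {
      bidx <- ord[bstart:min(bstart + batch_size - 1L, length(ord))]
      G <- .zero_grads(net$params)
      bl <- 0
      for (i in bidx) {
        it <- .draw_item(items[[i]], npoints)
        xyz <- if (augment) .augment_mat(it$cloud) else it$cloud
        fw <- net_forward(net, xyz, train = TRUE, keep_cache = TRUE)
        bl <- bl + nll_loss(fw$logp, it$labels)
        .net_backward(net, fw, it$labels, G, scale = 1 / length(bidx))
      }
      lr_t <- if (warmup > 0L && st$t < warmup)
        lr * (st$t + 1L) / warmup else lr
      .clip_grads(G, clip)
      .adam_step(net$params, G, st, lr_t)
      tloss <- tloss + bl / length(bidx)
      nb <- nb + 1L
    }
    ev <- .eval_items(net, items, va)
    history[[ep]] <- data.frame(epoch = ep, train_loss = tloss / nb,
                                val_loss = ev$loss, val_accuracy = ev$acc)
    if (ev$acc >= best$acc)
      best <- list(acc = ev$acc, params = as.list(net$params), epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val acc %.4f",
                      ep, tloss / nb, ev$loss, ev$acc))
  }
  for (nm in names(best$params)) net$params[[nm]] <- best$params[[nm]]
  structure(list(net = net, config = config, task = task,
                 variant = if (task == "classification") config$variant
                           else "ssg",
                 K = K, npoints = as.integer(npoints),
                 history = do.call(rbind, history),
                 best_epoch = best$epoch, best_val_accuracy = best$acc,
                 classes = sort(unique(dataset$identity)),
                 seed = as.integer(seed), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment = augment,
                 call = match.call()),
            class = "pointnetpp_fit")
}

#' @export
print.pointnetpp_fit <- function(x, ...) {
  cat(sprintf("pointnetpp_fit: %s (%s), %d classes, %d input points\n",
              x$task, x$variant, x$K, x$npoints))
  cat(sprintf("  trained %d epochs (batch %d, lr %g), best epoch %d, val accuracy %.4f\n",
              x$epochs, x$batch_size, x$lr, x$best_epoch,
              x$best_val_accuracy))
  invisible(x)
}

#' @export
summary.pointnetpp_fit <- function(object, ...) {
  print(object)
  h <- object$history
  cat("\nTraining history (last 5 epochs):\n")
  print(tail(h, 5), row.names = FALSE, digits = 4)
  np <- sum(vapply(ls(object$net$params),
                   function(nm) length(object$net$params[[nm]]), numeric(1)))
  cat(sprintf("\n%d trainable parameters in %d MLP blocks\n", np,
              count_mlps(object$net)))
  invisible(object)
}

#' @export
coef.pointnetpp_fit <- function(object, ...) {
  as.list(object$net$params)
}

#' @export
plot.pointnetpp_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
       ylab = "validation accuracy", main = x$variant, ...)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1:2, col = 1, xlab = "epoch", ylab = "loss")
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Predict from a fitted model
#'
#' For classification, `newdata` is a `point_cloud` or a list of clouds
#' (each one animal's back surface); each cloud is resampled to the
#' model's input size, normalized and classified. For segmentation,
#' prediction is delegated to [segment_cloud()], which labels clouds of
#' any size.
#'
#' @param object a `pointnetpp_fit`.
#' @param newdata a `point_cloud` or list of clouds.
#' @param type `"class"` (0-based labels), `"prob"` or `"logprob"`.
#' @param seed seed for the resampling of oversized clouds.
#' @param ... unused.
#' @return classification: a vector of classes or a matrix of
#'   (log-)probabilities, one row per cloud; segmentation: a list of
#'   per-point label vectors (or probability matrices).
#' @export
predict.pointnetpp_fit <- function(object, newdata,
                                   type = c("class", "prob", "logprob"),
                                   seed = 1L, ...) {
  type <- match.arg(type)
  clouds <- if (inherits(newdata, "point_cloud")) list(newdata) else newdata
  if (object$task == "segmentation") {
    out <- lapply(seq_along(clouds), function(i)
      segment_cloud(object, clouds[[i]], seed = seed + i - 1L,
                    type = type))
    return(if (inherits(newdata, "point_cloud")) out[[1]] else out)
  }
  lp <- matrix(NA_real_, length(clouds), object$K)
  set.seed(seed)
  for (i in seq_along(clouds)) {
    m <- .as_cloud_matrix(clouds[[i]])
    if (nrow(m) != object$npoints) {
      idx <- sample.int(nrow(m), object$npoints,
                        replace = object$npoints > nrow(m))
      m <- m[idx, , drop = FALSE]
    }
    lp[i, ] <- net_forward(object$net, .normalize_mat(m))$logp
  }
  switch(type,
         class = max.col(lp) - 1L,
         prob = exp(lp),
         logprob = lp)
}

#' Segment a cloud of any size
#'
#' Clouds larger than the model's training size are labelled by tiling:
#' random fixed-size subsets (each normalized like a training item) are
#' drawn, preferring still-unlabelled points, until every point has been
#' labelled at least once; per-point predictions are combined by majority
#' vote over all draws.
#'
#' @param fit a segmentation `pointnetpp_fit`.
#' @param cloud a `point_cloud`.
#' @param seed seed for the subset draws.
#' @param type `"class"` for 0/1 labels, `"prob"` for the per-point
#'   back-probability.
#' @return integer labels (0 background, 1 back) or probabilities, one
#'   per input point.
#' @export
segment_cloud <- function(fit, cloud, seed = 1L,
                          type = c("class", "prob")) {
  stopifnot(inherits(fit, "pointnetpp_fit"), fit$task == "segmentation")
  type <- match.arg(type)
  m <- .as_cloud_matrix(cloud)
  n <- fit$npoints
  N <- nrow(m)
  set.seed(seed)
  votes <- matrix(0, N, 2)
  seen <- logical(N)
  repeat {
    todo <- which(!seen)
    idx <- if (length(todo) >= n) sample(todo, n)
           else if (N >= n) c(todo, sample(which(seen), n - length(todo)))
           else sample.int(N, n, replace = TRUE)
    fw <- net_forward(fit$net, .normalize_mat(m[idx, , drop = FALSE]))
    pred <- max.col(fw$logp)
    votes[, 1] <- votes[, 1] + tabulate(idx[pred == 1L], nbins = N)
    votes[, 2] <- votes[, 2] + tabulate(idx[pred == 2L], nbins = N)
    seen[idx] <- TRUE
    if (all(seen)) break
  }
  if (type == "prob") votes[, 2] / pmax(rowSums(votes), 1)
  else as.integer(votes[, 2] > votes[, 1])
}
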