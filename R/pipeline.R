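# End-to-end orchestration: load an input frame or cloud, segment the
# animal's back, and classify the individual; plus model evaluation and
# checkpoint handling used by the command-line interface.

.obj_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 3))
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Evaluate a fitted model on a dataset split
#'
#' Recomputes predictions for every scene of the chosen split and
#' summarizes them as a confusion matrix and the derived metrics.
#' Segmentation models are scored per point, classification models per
#' cloud (using each scene's ground-truth back surface as input, as in
#' training).
#'
#' @param fit a `pointnetpp_fit`.
#' @param dataset a `scan_dataset`.
#' @param split `"val"`, `"train"` or `"all"`.
#' @param seed seed for the per-scene resampling.
#' @return list with `metrics` (a `metrics_report`) and `confusion`.
#' @export
evaluate_model <- function(fit, dataset, split = c("val", "train", "all"),
                           seed = 1L) {
  stopifnot(inherits(fit, "pointnetpp_fit"), inherits(dataset, "scan_dataset"))
  split <- match.arg(split)
  idx <- switch(split, val = which(dataset$split == 1L),
                train = which(dataset$split == 0L),
                all = seq_along(dataset$scenes))
  if (length(idx) == 0L) .invalid_argument("empty dataset split")
  if (fit$task == "classification" &&
      length(unique(dataset$identity)) > fit$K)
    .invalid_argument("dataset has more classes than the model")
  items <- local({
    set.seed(seed)
    .prep_items(dataset, fit$task, fit$npoints,
                seed = sample.int(2^31 - 2, 1))
  })
  truth <- integer(0)
  pred <- integer(0)
  for (i in idx) {
    fw <- net_forward(fit$net, items[[i]]$cloud)
    truth <- c(truth, items[[i]]$labels)
    pred <- c(pred, max.col(fw$logp) - 1L)
  }
  cm <- confusion_matrix(truth, pred, fit$K)
  list(metrics = metrics_from_confusion(cm), confusion = cm)
}

#' Identify the individual in an overhead scan
#'
#' Runs the full two-stage pipeline: convert a depth frame to a point
#' cloud (when needed), label every point back/background with the
#' segmentation model, keep the back points, resample them to the
#' classifier's input size, normalize, and classify the individual. The
#' classifier is never shown background: its input is exclusively the
#' segmentation-positive points. If segmentation retains fewer than a
#' tenth of the classifier's input size, a `no_animal` error is raised
#' instead of forcing a classification.
#'
#' @param input a `point_cloud`, a [depth_image()], or a path to a
#'   PLY/PCD cloud or PGM/PNG depth frame.
#' @param seg_fit segmentation `pointnetpp_fit`.
#' @param cls_fit classification `pointnetpp_fit`.
#' @param intr [camera_intrinsics()], required for depth-frame input.
#' @param seed seed for the resampling steps.
#' @return an `identification_result`: `identity` (0-based class),
#'   `probabilities`, `back_points` (retained count) and `provenance`
#'   (input description, seed and model hashes).
#' @export
identify_pig <- function(input, seg_fit, cls_fit, intr = NULL, seed = 1L) {
  stopifnot(inherits(seg_fit, "pointnetpp_fit"),
            seg_fit$task == "segmentation",
            inherits(cls_fit, "pointnetpp_fit"),
            cls_fit$task == "classification")
  src <- "point_cloud"
  if (is.character(input)) {
    src <- input
    ext <- tolower(tools::file_ext(input))
    input <- if (ext %in% c("ply", "pcd")) read_cloud(input)$cloud
             else read_depth(input)
  }
  if (inherits(input, "depth_image")) {
    if (is.null(intr))
      .invalid_argument("camera intrinsics required for depth input")
    input <- depth_to_cloud(input, intr)
  }
  cloud <- .as_cloud_matrix(input)
  # canonicalize the vertical axis: in camera coordinates depth grows
  # toward the ground plane, so the animal is the minority of points with
  # *small* z and the z distribution is left-skewed; flip so the back
  # rises in +z like the scenes the models are trained on
  zc <- cloud[, 3] - mean(cloud[, 3])
  if (mean(zc^3) < 0) cloud[, 3] <- -cloud[, 3]
  labels <- segment_cloud(seg_fit, point_cloud(cloud), seed = seed)
  back <- cloud[labels == 1L, , drop = FALSE]
  n <- cls_fit$npoints
  if (nrow(back) < n / 10)
    stop(structure(class = c("no_animal", "error", "condition"),
                   list(message = sprintf(
                     "no animal found: segmentation retained %d points (< %d)",
                     nrow(back), ceiling(n / 10)), call = sys.call(-1))))
  set.seed(seed)
  idx <- sample.int(nrow(back), n, replace = n > nrow(back))
  fw <- net_forward(cls_fit$net, .normalize_mat(back[idx, , drop = FALSE]))
  probs <- as.numeric(exp(fw$logp))
  structure(list(identity = which.max(probs) - 1L, probabilities = probs,
                 back_points = nrow(back),
                 provenance = list(input = src, seed = as.integer(seed),
                                   seg_model = .obj_hash(coef(seg_fit)),
                                   cls_model = .obj_hash(coef(cls_fit)))),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("identified individual: class %d (p = %.3f), %d back points\n",
              x$identity, max(x$probabilities), x$back_points))
  invisible(x)
}

#' Save or load a fitted model checkpoint
#'
#' Checkpoints carry the configuration, the weights and the training
#' history; loading restores a fully functional `pointnetpp_fit`.
#'
#' @param fit a `pointnetpp_fit`.
#' @param path checkpoint file path.
#' @return `load_model` returns the restored `pointnetpp_fit`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "pointnetpp_fit"))
  obj <- fit
  obj$net <- list(cfg = fit$net$cfg, params = as.list(fit$net$params))
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pointnetpp_fit"))
    .format_error("not a pointnetpp_fit checkpoint")
  P <- new.env(parent = emptyenv())
  for (nm in names(obj$net$params)) P[[nm]] <- obj$net$params[[nm]]
  obj$net <- structure(list(cfg = obj$net$cfg, params = P),
                       class = "pnpp_net")
  obj
}
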