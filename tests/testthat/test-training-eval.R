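# Loss, confusion-matrix bookkeeping, the derived metrics, and the
# training loop contracts.

test_that("negative log-likelihood loss follows its closed forms", {
  onehot <- log(matrix(c(1 - 1e-12, 1e-12), 1))
  expect_equal(nll_loss(onehot, 0L), 0, tolerance = 1e-9)
  unif10 <- matrix(log(rep(0.1, 10)), 1)
  expect_equal(nll_loss(unif10, 3L), log(10), tolerance = 1e-12)
  set.seed(1)
  lp <- t(apply(matrix(rnorm(50), 10, 5), 1, function(z) z - log(sum(exp(z)))))
  labs <- sample(0:4, 10, replace = TRUE)
  per_item <- vapply(1:10, function(i) nll_loss(lp[i, , drop = FALSE],
                                                labs[i]), numeric(1))
  expect_equal(nll_loss(lp, labs), mean(per_item))
  expect_error(nll_loss(lp, rep(9L, 10)), class = "invalid_argument")
})

test_that("confusion matrices count true rows against predicted columns", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), K = 2)
  expect_equal(unname(unclass(cm)), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  allright <- confusion_matrix(0:4, 0:4, K = 5)
  expect_equal(unname(unclass(allright)), diag(1L, 5))
  # per-class TP/FP/FN/TN reconcile with independent tallies
  set.seed(2)
  truth <- sample(0:3, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.3, sample(0:3, 200, replace = TRUE), truth)
  cm2 <- confusion_matrix(truth, pred, 4)
  rep <- metrics_from_confusion(cm2)
  for (k in 0:3) {
    expect_equal(rep$per_class$tp[k + 1], sum(truth == k & pred == k))
    expect_equal(rep$per_class$fp[k + 1], sum(truth != k & pred == k))
    expect_equal(rep$per_class$fn[k + 1], sum(truth == k & pred != k))
    expect_equal(rep$per_class$tn[k + 1], sum(truth != k & pred != k))
  }
  expect_equal(rep$accuracy, mean(truth == pred))
  expect_error(confusion_matrix(0:2, c(0, 1, 3), K = 3),
               class = "invalid_argument")
})

test_that("F1 is the harmonic mean with the printed-table behaviour", {
  expect_equal(round(f1_from_pr(97.92, 99.73), 2), 98.82)
  expect_equal(round(f1_from_pr(95.51, 95.53), 2), 95.52)
  expect_equal(round(f1_from_pr(83.22, 76.16), 2), 79.53)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_equal(f1_from_pr(0.7, 0), 0)
  expect_equal(f1_from_pr(0, 0), 0)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(3)
  for (rep_i in 1:20) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, 8), K, K)
    class(cm) <- c("confusion_matrix", class(matrix()))
    r <- metrics_from_confusion(cm)
    expect_equal(r$miou, mean(r$per_class$iou))
    expect_true(all(unlist(r[c("accuracy", "miou", "macro_precision",
                               "macro_recall", "macro_f1")]) >= 0))
    # binary IoU identity: IoU = 1 / (1/P + 1/R - 1) when P, R > 0
    ok <- r$per_class$precision > 0 & r$per_class$recall > 0
    expect_equal(r$per_class$iou[ok],
                 1 / (1 / r$per_class$precision[ok] +
                        1 / r$per_class$recall[ok] - 1),
                 tolerance = 1e-12)
    # micro precision = micro recall = accuracy for single-label data
    expect_equal(sum(r$per_class$tp) / sum(r$per_class$tp + r$per_class$fp),
                 r$accuracy)
    expect_equal(sum(r$per_class$tp) / sum(r$per_class$tp + r$per_class$fn),
                 r$accuracy)
    # invariance under simultaneous relabelling
    perm <- sample(K)
    cmp <- cm[perm, perm]
    class(cmp) <- class(cm)
    rp <- metrics_from_confusion(cmp)
    expect_equal(rp$accuracy, r$accuracy)
    expect_equal(rp$miou, r$miou)
    expect_equal(sort(rp$per_class$f1), sort(r$per_class$f1))
  }
  # 0/0 ratios reported as 0 and flagged
  degen <- confusion_matrix(c(0, 0), c(0, 0), K = 2)
  rd <- metrics_from_confusion(degen)
  expect_equal(rd$per_class$precision[2], 0)
  expect_true(rd$per_class$undefined[2])
})

test_that("training decreases the loss, is deterministic, and augmentation changes it", {
  ds <- tiny_dataset(ids = c(1, 10), frames = 6, seed = 42)
  f1 <- fit_pointnetpp(ds, "classification", "ssg", npoints = 300,
                       epochs = 6, seed = 7, augment = FALSE, lr = 5e-4)
  h <- f1$history
  expect_lt(mean(tail(h$train_loss, 2)), mean(head(h$train_loss, 2)))
  f2 <- fit_pointnetpp(ds, "classification", "ssg", npoints = 300,
                       epochs = 6, seed = 7, augment = FALSE, lr = 5e-4)
  expect_equal(f1$history, f2$history)
  expect_equal(coef(f1), coef(f2))
  f3 <- fit_pointnetpp(ds, "classification", "ssg", npoints = 300,
                       epochs = 6, seed = 7, augment = TRUE, lr = 5e-4)
  expect_false(isTRUE(all.equal(f3$history$train_loss, f1$history$train_loss)))
})

test_that("evaluation reports reconcile with direct tallies and export", {
  ds <- tiny_dataset(ids = c(1, 10), frames = 5, seed = 43)
  f <- fit_pointnetpp(ds, "classification", "pointnet", npoints = 300,
                      epochs = 3, seed = 1, augment = FALSE)
  ev <- evaluate_model(f, ds, "val", seed = 5)
  expect_s3_class(ev$metrics, "metrics_report")
  expect_equal(nrow(ev$metrics$per_class), 2L)
  expect_equal(ev$metrics$accuracy,
               sum(diag(unclass(ev$confusion))) / sum(ev$confusion))
  expect_equal(ev$metrics$n, sum(ds$split == 1L))
  pre <- tempfile()
  files <- write_metrics(ev$metrics, ev$confusion, pre)
  expect_true(all(file.exists(paste0(pre, c("_metrics.json", "_metrics.csv",
                                            "_confusion.csv")))))
  csv <- utils::read.csv(paste0(pre, "_metrics.csv"))
  expect_equal(nrow(csv), 3L)  # per-class rows plus overall
  cmcsv <- utils::read.csv(paste0(pre, "_confusion.csv"), row.names = 1)
  expect_equal(unname(rowSums(cmcsv)),
               unname(rowSums(unclass(ev$confusion))))
  unlink(paste0(pre, c("_metrics.json", "_metrics.csv", "_confusion.csv")))
})

test_that("model checkpoints roundtrip through save_model/load_model", {
  ds <- tiny_dataset(ids = c(1, 10), frames = 4, seed = 44)
  f <- fit_pointnetpp(ds, "classification", "pointnet", npoints = 200,
                      epochs = 2, seed = 3, augment = FALSE)
  ck <- tempfile(fileext = ".rds")
  save_model(f, ck)
  g <- load_model(ck)
  cl <- normalize_unit_ball(rand_cloud(200, seed = 1))
  expect_equal(net_forward(g$net, cl)$logp, net_forward(f$net, cl)$logp)
  expect_error(load_model({saveRDS(1:3, ck); ck}), class = "format_error")
  unlink(ck)
})
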