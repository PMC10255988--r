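# Point-cloud model architectures: hierarchical set abstraction with
# ball-query grouping (single-scale, multi-scale, or local-global with the
# adaptive global radius), feature propagation with inverse-distance
# interpolation for segmentation, and the flat PointNet baseline.

# ---- set abstraction ------------------------------------------------------

.init_sa <- function(P, prefix, indim, sa, norm = FALSE) {
  out <- 0L
  for (b in seq_along(sa$widths)) {
    .init_mlp(P, paste0(prefix, ".b", b), indim, sa$widths[[b]],
              norm = norm)
    out <- out + sa$widths[[b]][length(sa$widths[[b]])]
  }
  out
}

.sa_fwd <- function(xyz, feats, sa, prefix, P, train = FALSE,
                    fps_start = 1L, norm = FALSE) {
  m <- sa$m
  if (nrow(xyz) < m) .invalid_argument("fewer points than centroids")
  sel <- fps_cpp(xyz, m, fps_start)
  cent <- xyz[sel, , drop = FALSE]
  rfst <- if (anyNA(sa$grouping$radii)) max_pairwise_dist_cpp(cent)
  nb <- length(sa$grouping$radii)
  radii <- sa$grouping$radii
  radii[is.na(radii)] <- rfst
  groups <- ball_query_multi_cpp(xyz, cent, radii, sa$grouping$caps)
  pooled <- vector("list", nb)
  branches <- vector("list", nb)
  for (b in seq_len(nb)) {
    cap <- sa$grouping$caps[b]
    flat <- as.vector(t(groups[[b]]))
    rel <- xyz[flat, , drop = FALSE] -
      cent[rep(seq_len(m), each = cap), , drop = FALSE]
    inX <- if (is.null(feats)) rel
           else cbind(rel, feats[flat, , drop = FALSE])
    mc <- .mlp_fwd(inX, paste0(prefix, ".b", b), sa$widths[[b]], P,
                   final_act = TRUE, train = train, norm = norm)
    pl <- .pool_fwd(mc$out, m, cap)
    pooled[[b]] <- pl$M
    branches[[b]] <- list(mlp = mc, argmax = pl$argmax, nrow_h = m * cap,
                          width = ncol(pl$M), flat = flat)
  }
  list(xyz = cent, f = do.call(cbind, pooled), sel = sel, rfst = rfst,
       branches = branches,
       nfeat_in = if (is.null(feats)) 0L else ncol(feats),
       npts_in = nrow(xyz))
}

.sa_bwd <- function(dF, cache, P, G) {
  dfeats <- if (cache$nfeat_in > 0L)
    matrix(0, cache$npts_in, cache$nfeat_in)
  col0 <- 0L
  for (b in seq_along(cache$branches)) {
    br <- cache$branches[[b]]
    C <- br$width
    dM <- dF[, (col0 + 1L):(col0 + C), drop = FALSE]
    col0 <- col0 + C
    dH <- .pool_bwd(dM, br$argmax, br$nrow_h)
    dIn <- .mlp_bwd(dH, br$mlp, P, G)
    if (!is.null(dfeats))
      dfeats <- .scatter_add(dfeats, br$flat,
                             dIn[, 4:ncol(dIn), drop = FALSE])
  }
  dfeats
}

# ---- feature propagation --------------------------------------------------

# Inverse-distance-squared weighted interpolation of coarse features onto
# fine points over the k nearest coarse neighbours, concatenated with the
# skip features, then a stage MLP. A fine point coinciding with a coarse
# point receives that point's feature exactly (the d -> 0 limit).
.fp_fwd <- function(fine_xyz, coarse_xyz, coarse_f, skip_f, k, prefix,
                    widths, P, train = FALSE, norm = FALSE) {
  kn <- knn_cpp(fine_xyz, coarse_xyz, as.integer(k))
  w <- 1 / pmax(kn$dist, 1e-12)^2
  zero <- kn$dist[, 1] < 1e-10
  if (any(zero)) {
    w[zero, ] <- 0
    w[zero, 1] <- 1
  }
  wn <- w / rowSums(w)
  interp <- matrix(0, nrow(fine_xyz), ncol(coarse_f))
  for (j in seq_len(ncol(wn)))
    interp <- interp + wn[, j] * coarse_f[kn$idx[, j], , drop = FALSE]
  X <- if (is.null(skip_f)) interp else cbind(interp, skip_f)
  mc <- .mlp_fwd(X, prefix, widths, P, final_act = TRUE, train = train,
                 norm = norm)
  list(out = mc$out, mlp = mc, wn = wn, idx = kn$idx,
       nc = nrow(coarse_f), ci = ncol(coarse_f),
       nskip = if (is.null(skip_f)) 0L else ncol(skip_f))
}

.fp_bwd <- function(dY, cache, P, G) {
  dX <- .mlp_bwd(dY, cache$mlp, P, G)
  ci <- cache$ci
  dI <- dX[, seq_len(ci), drop = FALSE]
  dskip <- if (cache$nskip > 0L)
    dX[, (ci + 1L):(ci + cache$nskip), drop = FALSE]
  dC <- matrix(0, cache$nc, ci)
  for (j in seq_len(ncol(cache$idx)))
    dC <- .scatter_add(dC, cache$idx[, j], dI * cache$wn[, j])
  list(dcoarse = dC, dskip = dskip)
}

#' Interpolate features from a coarse onto a fine point set
#'
#' Standalone inverse-distance-weighted k-nearest-neighbour interpolation,
#' the upsampling rule used by the segmentation model's feature
#' propagation stages: each fine point's feature is the weighted average
#' of its k nearest coarse features with weights `1 / d^2`. A fine point
#' coinciding with a coarse point receives that coarse feature exactly.
#'
#' @param fine,coarse point clouds (or matrices) of query and source
#'   points.
#' @param coarse_features numeric matrix, one row per coarse point.
#' @param k number of neighbours (`k <= nrow(coarse)`).
#' @return numeric matrix of interpolated features, one row per fine point.
#' @export
interpolate_features <- function(fine, coarse, coarse_features, k = 3L) {
  fx <- if (inherits(fine, "point_cloud")) .as_cloud_matrix(fine)
        else as.matrix(fine)
  cx <- if (inherits(coarse, "point_cloud")) .as_cloud_matrix(coarse)
        else as.matrix(coarse)
  Fm <- as.matrix(coarse_features)
  if (k > nrow(cx)) .invalid_argument("k exceeds the number of coarse points")
  kn <- knn_cpp(fx, cx, as.integer(k))
  w <- 1 / pmax(kn$dist, 1e-12)^2
  zero <- kn$dist[, 1] < 1e-10
  if (any(zero)) {
    w[zero, ] <- 0
    w[zero, 1] <- 1
  }
  wn <- w / rowSums(w)
  out <- matrix(0, nrow(fx), ncol(Fm))
  for (j in seq_len(k)) out <- out + wn[, j] * Fm[kn$idx[, j], , drop = FALSE]
  out
}

# ---- model configurations -------------------------------------------------

.sa_level <- function(m, radii, caps, widths) {
  list(m = as.integer(m), grouping = grouping_config(radii, caps),
       widths = widths)
}

#' Classification model configuration
#'
#' Builds the architecture description of an individual-identification
#' model. Variants: `"ssg"` (single-scale grouping), `"msg"` (multi-scale
#' grouping), `"lgg"` (multi-scale plus the adaptive global radius at both
#' abstraction levels, with a wider final feature), and `"pointnet"` (flat
#' shared MLP + max-pool baseline). At `scale = "full"` the standard
#' geometry is used: 2500 input points are abstracted to 512 and then 128
#' centroids; the MSG level-2 feature is 640-dimensional (643 with the
#' centroid coordinates); the LGG variant has 9 MLPs (4 branch MLPs per
#' level plus the final one) and a 2048-dimensional global feature.
#' `scale = "small"` is a proportionally thinned geometry for desk-scale
#' experiments on a few hundred points.
#'
#' @param variant one of `"lgg"`, `"msg"`, `"ssg"`, `"pointnet"`.
#' @param K number of identities.
#' @param npoints expected input cloud size.
#' @param scale `"full"` or `"small"`.
#' @param dropout dropout rate between fully-connected head layers;
#'   defaults to 0.4 at full scale and 0 for the thin small-scale heads,
#'   which dropout starves.
#' @return a `pnpp_config` list.
#' @export
cls_model_config <- function(variant = c("lgg", "msg", "ssg", "pointnet"),
                             K = 10L, npoints = if (scale == "full") 2500L
                                               else 600L,
                             scale = c("full", "small"), dropout = NULL) {
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  if (is.null(dropout)) dropout <- if (scale == "full") 0.4 else 0
  cfg <- list(task = "classification", variant = variant, K = as.integer(K),
              npoints = as.integer(npoints), scale = scale,
              dropout = dropout)
  if (scale == "full") {
    msg1 <- list(c(32, 32, 64), c(64, 64, 128), c(64, 96, 128))
    msg2 <- list(c(64, 64, 128), c(128, 128, 256), c(128, 128, 256))
    if (variant == "ssg") {
      cfg$sa1 <- .sa_level(512, 0.2, 32, list(c(64, 64, 128)))
      cfg$sa2 <- .sa_level(128, 0.4, 64, list(c(128, 128, 256)))
      cfg$global <- c(256, 512, 1024)
    } else if (variant == "msg") {
      cfg$sa1 <- .sa_level(512, c(0.1, 0.2, 0.4), c(16, 32, 128), msg1)
      cfg$sa2 <- .sa_level(128, c(0.2, 0.4, 0.8), c(32, 64, 128), msg2)
      cfg$global <- c(256, 512, 1024)
    } else if (variant == "lgg") {
      cfg$sa1 <- .sa_level(512, c(0.1, 0.2, 0.4, NA), c(16, 32, 128, 256),
                           c(msg1, list(c(64, 96, 128))))
      cfg$sa2 <- .sa_level(128, c(0.2, 0.4, 0.8, NA), c(32, 64, 128, 128),
                           c(msg2, list(c(128, 128, 256))))
      cfg$global <- c(512, 1024, 2048)
    } else {
      cfg$shared <- c(64, 128, 1024)
    }
    cfg$head <- c(512, 256)
  } else {
    msg1 <- list(c(8, 8, 16), c(16, 16, 32), c(16, 24, 32))
    msg2 <- list(c(16, 16, 32), c(32, 32, 64), c(32, 32, 64))
    if (variant == "ssg") {
      cfg$sa1 <- .sa_level(128, 0.2, 16, list(c(16, 16, 32)))
      cfg$sa2 <- .sa_level(32, 0.4, 16, list(c(32, 32, 64)))
      cfg$global <- c(128, 256)
    } else if (variant == "msg") {
      cfg$sa1 <- .sa_level(128, c(0.1, 0.2, 0.4), c(4, 8, 16), msg1)
      cfg$sa2 <- .sa_level(32, c(0.2, 0.4, 0.8), c(8, 16, 16), msg2)
      cfg$global <- c(128, 256)
    } else if (variant == "lgg") {
      cfg$sa1 <- .sa_level(128, c(0.1, 0.2, 0.4, NA), c(4, 8, 16, 16),
                           c(msg1, list(c(16, 24, 32))))
      cfg$sa2 <- .sa_level(32, c(0.2, 0.4, 0.8, NA), c(8, 16, 16, 16),
                           c(msg2, list(c(32, 32, 64))))
      cfg$global <- c(128, 384)
    } else {
      cfg$shared <- c(32, 64, 256)
    }
    cfg$head <- c(128, 64)
  }
  structure(cfg, class = "pnpp_config")
}

#' Segmentation model configuration
#'
#' Two set-abstraction levels with single-scale grouping, two feature
#' propagation stages with inverse-distance interpolation (k nearest
#' neighbours) and skip links, and a per-point head producing two
#' log-probabilities (back vs background) per point.
#'
#' @param npoints expected input cloud size.
#' @param scale `"full"` (2500-point geometry) or `"small"` (desk-scale).
#' @param k interpolation neighbourhood size.
#' @param dropout dropout rate in the per-point head; defaults to 0.4 at
#'   full scale and 0 at small scale.
#' @return a `pnpp_config` list.
#' @export
seg_model_config <- function(npoints = if (scale == "full") 2500L else 600L,
                             scale = c("full", "small"), k = 3L,
                             dropout = NULL) {
  scale <- match.arg(scale)
  if (is.null(dropout)) dropout <- if (scale == "full") 0.4 else 0
  cfg <- list(task = "segmentation", variant = "ssg", K = 2L,
              npoints = as.integer(npoints), scale = scale, k = as.integer(k),
              dropout = dropout)
  if (scale == "full") {
    cfg$sa1 <- .sa_level(512, 0.2, 32, list(c(64, 64, 128)))
    cfg$sa2 <- .sa_level(128, 0.4, 64, list(c(128, 128, 256)))
    cfg$fp1 <- c(256, 128)
    cfg$fp2 <- c(128, 128)
    cfg$head <- 128
  } else {
    cfg$sa1 <- .sa_level(96, 0.2, 16, list(c(16, 16, 32)))
    cfg$sa2 <- .sa_level(24, 0.4, 16, list(c(32, 32, 64)))
    cfg$fp1 <- c(64, 64)
    cfg$fp2 <- c(64, 32)
    cfg$head <- 32
  }
  structure(cfg, class = "pnpp_config")
}

# ---- model construction ---------------------------------------------------

.sa_out_width <- function(sa)
  sum(vapply(sa$widths, function(w) w[length(w)], numeric(1)))

#' Instantiate a network from a configuration
#'
#' Initializes all weights (uniform fan-in scaled) deterministically under
#' `seed`.
#'
#' @param cfg a [cls_model_config()] or [seg_model_config()].
#' @param seed integer seed for the weight initialization.
#' @return a `pnpp_net` object holding the configuration and parameters.
#' @export
pointnetpp_net <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "pnpp_config"))
  set.seed(seed)
  P <- new.env(parent = emptyenv())
  if (cfg$task == "classification" && cfg$variant == "pointnet") {
    .init_mlp(P, "pn", 3L, cfg$shared)
    .init_mlp(P, "head", cfg$shared[length(cfg$shared)],
              c(cfg$head, cfg$K))
  } else if (cfg$task == "classification") {
    d1 <- .init_sa(P, "sa1", 6L, cfg$sa1, norm = isTRUE(cfg$norm))
    d2 <- .init_sa(P, "sa2", 3L + d1, cfg$sa2, norm = isTRUE(cfg$norm))
    .init_mlp(P, "glob", 3L + d2, cfg$global)
    .init_mlp(P, "head", cfg$global[length(cfg$global)],
              c(cfg$head, cfg$K))
  } else {
    nrm <- isTRUE(cfg$norm)
    d1 <- .init_sa(P, "sa1", 6L, cfg$sa1, norm = nrm)
    d2 <- .init_sa(P, "sa2", 3L + d1, cfg$sa2, norm = nrm)
    .init_mlp(P, "fp1", d2 + d1, cfg$fp1, norm = nrm)
    .init_mlp(P, "fp2", cfg$fp1[length(cfg$fp1)] + 3L, cfg$fp2,
              norm = nrm)
    .init_mlp(P, "seghead", cfg$fp2[length(cfg$fp2)], c(cfg$head, 2L),
              norm = nrm, final_act = FALSE)
  }
  structure(list(cfg = cfg, params = P), class = "pnpp_net")
}

#' @export
print.pnpp_net <- function(x, ...) {
  np <- sum(vapply(ls(x$params), function(nm) length(x$params[[nm]]),
                   numeric(1)))
  cat(sprintf("pnpp_net: %s %s (%s scale), %d parameters\n",
              x$cfg$task, x$cfg$variant, x$cfg$scale, np))
  invisible(x)
}

#' Count the MLP blocks of a network
#'
#' Each set-abstraction branch MLP counts as one block, as does the final
#' global MLP; the fully-connected classification head is not an MLP
#' block. The local-global variant therefore has 4 + 4 + 1 = 9.
#'
#' @param net a `pnpp_net`.
#' @return integer count.
#' @export
count_mlps <- function(net) {
  cfg <- net$cfg
  if (cfg$task == "classification" && cfg$variant == "pointnet") return(1L)
  if (cfg$task == "classification")
    return(length(cfg$sa1$widths) + length(cfg$sa2$widths) + 1L)
  length(cfg$sa1$widths) + length(cfg$sa2$widths) + 3L  # 2 FP + head
}

# ---- forward / backward ---------------------------------------------------

#' Run a network forward
#'
#' @param net a `pnpp_net`.
#' @param cloud a `point_cloud` (classification: the whole cloud is one
#'   sample; segmentation: one label per point).
#' @param train training mode (enables dropout; requires the caller to
#'   manage the RNG).
#' @param fps_start start index for the first-level farthest point
#'   sampling; pinning it to a fixed input point makes the output
#'   invariant (classification) or equivariant (segmentation) under input
#'   permutation.
#' @param keep_cache retain intermediate activations for a backward pass.
#' @return list with `logp` (classification: 1 x K; segmentation: n x 2
#'   log-probabilities), `dims` (realized layer widths) and, if requested,
#'   `cache`.
#' @export
net_forward <- function(net, cloud, train = FALSE, fps_start = 1L,
                        keep_cache = FALSE) {
  stopifnot(inherits(net, "pnpp_net"))
  xyz <- .as_cloud_matrix(cloud)
  cfg <- net$cfg
  P <- net$params
  if (cfg$task == "classification") {
    if (cfg$variant == "pointnet") {
      mc <- .mlp_fwd(xyz, "pn", cfg$shared, P, TRUE, train = train)
      pl <- .pool_fwd(mc$out, 1L, nrow(xyz))
      g <- pl$M
      hd <- .mlp_fwd(g, "head", c(cfg$head, cfg$K), P, final_act = FALSE,
                     dropout = cfg$dropout, train = train)
      logp <- .log_softmax(hd$out)
      dims <- list(global_width = ncol(g))
      cache <- if (keep_cache) list(pn = mc, gA = pl$argmax, hd = hd,
                                    n = nrow(xyz))
    } else {
      s1 <- .sa_fwd(xyz, xyz, cfg$sa1, "sa1", P, train, fps_start,
                    norm = isTRUE(cfg$norm))
      s2 <- .sa_fwd(s1$xyz, s1$f, cfg$sa2, "sa2", P, train,
                    norm = isTRUE(cfg$norm))
      Xg <- cbind(s2$xyz, s2$f)
      gm <- .mlp_fwd(Xg, "glob", cfg$global, P, TRUE, train = train)
      pl <- .pool_fwd(gm$out, 1L, nrow(Xg))
      g <- pl$M
      hd <- .mlp_fwd(g, "head", c(cfg$head, cfg$K), P, final_act = FALSE,
                     dropout = cfg$dropout, train = train)
      logp <- .log_softmax(hd$out)
      dims <- list(sa1_width = ncol(s1$f), sa2_width = ncol(s2$f),
                   global_in = ncol(Xg), global_width = ncol(g),
                   rfst1 = s1$rfst, rfst2 = s2$rfst)
      cache <- if (keep_cache) list(s1 = s1, s2 = s2, gm = gm, Xg = Xg,
                                    gA = pl$argmax, hd = hd)
    }
  } else {
    nrm <- isTRUE(cfg$norm)
    s1 <- .sa_fwd(xyz, xyz, cfg$sa1, "sa1", P, train, fps_start,
                  norm = nrm)
    s2 <- .sa_fwd(s1$xyz, s1$f, cfg$sa2, "sa2", P, train, norm = nrm)
    f1 <- .fp_fwd(s1$xyz, s2$xyz, s2$f, s1$f, cfg$k, "fp1", cfg$fp1, P,
                  train, norm = nrm)
    f2 <- .fp_fwd(xyz, s1$xyz, f1$out, xyz, cfg$k, "fp2", cfg$fp2, P,
                  train, norm = nrm)
    hd <- .mlp_fwd(f2$out, "seghead", c(cfg$head, 2L), P,
                   final_act = FALSE, dropout = cfg$dropout, train = train,
                   norm = nrm)
    logp <- .log_softmax(hd$out)
    dims <- list(sa1_width = ncol(s1$f), sa2_width = ncol(s2$f),
                 out_shape = dim(logp))
    cache <- if (keep_cache) list(s1 = s1, s2 = s2, f1 = f1, f2 = f2,
                                  hd = hd)
  }
  list(logp = logp, dims = dims, cache = cache)
}

# Collect every shared-MLP cache of a forward pass (for calibration).
.collect_mlps <- function(cfg, cc) {
  if (cfg$task == "classification" && cfg$variant == "pointnet")
    return(list(cc$pn, cc$hd))
  sa <- c(lapply(cc$s1$branches, `[[`, "mlp"),
          lapply(cc$s2$branches, `[[`, "mlp"))
  if (cfg$task == "classification") c(sa, list(cc$gm, cc$hd))
  else c(sa, list(cc$f1$mlp, cc$f2$mlp, cc$hd))
}

# Variance-calibrated initialization: after random init, each linear
# layer is rescaled -- sequentially, front to back, re-running the
# forward pass after every adjustment -- so that its output has unit
# standard deviation on a handful of probe clouds. This keeps activations
# on a common scale across branches with very different grouping radii
# and depths, which fixed fan-in scaling alone does not achieve for this
# architecture family. Normalized layers are already scale-free and are
# skipped.
.calibrate_net <- function(net, probe_clouds) {
  P <- net$params
  fw <- net_forward(net, probe_clouds[[1]], keep_cache = TRUE)
  mcs <- .collect_mlps(net$cfg, fw$cache)
  targets <- list()
  for (b in seq_along(mcs))
    for (l in seq_len(mcs[[b]]$nl))
      if (is.null(mcs[[b]]$layers[[l]]$xhat))
        targets[[length(targets) + 1L]] <- c(b, l)
  for (tg in targets) {
    sds <- vapply(probe_clouds, function(cl) {
      fw <- net_forward(net, cl, keep_cache = TRUE)
      mc <- .collect_mlps(net$cfg, fw$cache)[[tg[1]]]
      out <- if (tg[2] == mc$nl) mc$out else mc$layers[[tg[2] + 1]]$X
      stats::sd(as.vector(out))
    }, numeric(1))
    s <- mean(sds)
    nm <- paste0(mcs[[tg[1]]]$prefix, ".W", tg[2])
    if (is.finite(s) && s > 1e-8) P[[nm]] <- P[[nm]] / s
  }
  invisible(net)
}

# Accumulate parameter gradients of nll_loss(forward(cloud), labels) into
# G, scaled by `scale` (used to average over a batch).
.net_backward <- function(net, fw, labels, G, scale = 1) {
  cfg <- net$cfg
  P <- net$params
  cc <- fw$cache
  dZ <- .nll_logsoftmax_bwd(fw$logp, labels, scale)
  if (cfg$task == "classification") {
    dg <- .mlp_bwd(dZ, cc$hd, P, G)
    if (cfg$variant == "pointnet") {
      dH <- .pool_bwd(dg, cc$gA, cc$n)
      .mlp_bwd(dH, cc$pn, P, G)
    } else {
      dGm <- .pool_bwd(dg, cc$gA, nrow(cc$Xg))
      dXg <- .mlp_bwd(dGm, cc$gm, P, G)
      df2 <- dXg[, 4:ncol(dXg), drop = FALSE]
      df1 <- .sa_bwd(df2, cc$s2, P, G)
      .sa_bwd(df1, cc$s1, P, G)
    }
  } else {
    dF2 <- .mlp_bwd(dZ, cc$hd, P, G)
    b2 <- .fp_bwd(dF2, cc$f2, P, G)
    b1 <- .fp_bwd(b2$dcoarse, cc$f1, P, G)
    df1m <- .sa_bwd(b1$dcoarse, cc$s2, P, G)
    .sa_bwd(df1m + b1$dskip, cc$s1, P, G)
  }
  invisible(NULL)
}
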