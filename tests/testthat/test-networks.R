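# Model architectures: pooling semantics, interpolation, output
# contracts, architecture pins and gradient correctness.

ns <- asNamespace("pigback3d")

tiny_cls_cfg <- function(variant = "lgg", K = 3L, nontrunc = FALSE) {
  cfg <- cls_model_config(variant, K = K, npoints = 24, scale = "small",
                          dropout = 0)
  if (variant != "pointnet") {
    cfg$sa1 <- ns$.sa_level(8, if (variant == "ssg") 0.4 else c(0.3, NA),
                            if (variant == "ssg") 4 else c(3, 5),
                            if (variant == "ssg") list(c(5, 6))
                            else list(c(4, 4), c(4, 5)))
    cfg$sa2 <- ns$.sa_level(3, 0.6, 3, list(c(6, 6)))
    if (nontrunc) {
      # caps at the cloud size: padding may repeat members but never
      # truncates, so grouping is a pure function of the point set and
      # the forward pass is exactly permutation invariant
      cfg$sa1$grouping$caps <- rep(24L, length(cfg$sa1$grouping$caps))
      cfg$sa2$grouping$caps <- rep(8L, length(cfg$sa2$grouping$caps))
    }
    cfg$global <- 7
    cfg$head <- 5
  } else {
    cfg$shared <- c(6, 8)
    cfg$head <- 5
  }
  cfg
}

test_that("max-pooled set features ignore duplicates and member order", {
  set.seed(1)
  H <- matrix(rnorm(12 * 5), 12, 5)  # 3 groups of cap 4
  pl <- ns$.pool_fwd(H, 3L, 4L)
  expect_equal(dim(pl$M), c(3L, 5L))
  # permuting members within a group leaves the pooled value unchanged
  perm <- c(4, 2, 1, 3, 8, 5, 7, 6, 9, 12, 10, 11)
  pl2 <- ns$.pool_fwd(H[perm, ], 3L, 4L)
  expect_equal(pl2$M, pl$M)
  # duplicating the max member changes nothing (max is idempotent)
  H3 <- H
  H3[2, ] <- H[1, ]
  expect_equal(ns$.pool_fwd(H3, 3L, 4L)$M[1, ],
               pmax(H[1, ], H[3, ], H[4, ]))
  # singleton groups pass features through
  one <- ns$.pool_fwd(H, 12L, 1L)
  expect_equal(one$M, H)
})

test_that("feature interpolation matches the inverse-distance formula", {
  # coincident fine point -> exact coarse feature (d -> 0 limit)
  coarse <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  feats <- matrix(c(10, 20, 30), 3, 1)
  out <- interpolate_features(coarse[2, , drop = FALSE], coarse, feats, k = 2)
  expect_equal(out[1, 1], 20)
  # two equidistant coarse points, features 0 and 1 -> 0.5
  mid <- matrix(c(0.5, 0, 0), 1)
  out2 <- interpolate_features(mid, coarse[1:2, ], matrix(c(0, 1), 2, 1),
                               k = 2)
  expect_equal(out2[1, 1], 0.5)
  # random configurations against the direct-formula oracle
  for (s in 1:20) {
    set.seed(400 + s)
    fine <- matrix(rnorm(15 * 3), 15, 3)
    crs <- matrix(rnorm(8 * 3), 8, 3)
    f <- matrix(rnorm(8 * 4), 8, 4)
    expect_equal(interpolate_features(fine, crs, f, k = 3),
                 idw_oracle(fine, crs, f, 3), tolerance = 1e-12)
  }
  expect_error(interpolate_features(coarse, coarse, feats, k = 9),
               class = "invalid_argument")
})

test_that("classification outputs are normalized probability vectors", {
  cl <- normalize_unit_ball(rand_cloud(24, seed = 2))
  for (variant in c("ssg", "msg", "lgg", "pointnet")) {
    cfg <- if (variant %in% c("ssg", "lgg", "pointnet"))
      tiny_cls_cfg(variant) else cls_model_config("msg", K = 3,
                                                  npoints = 600,
                                                  scale = "small")
    if (variant == "msg") next  # covered at study scale below
    net <- pointnetpp_net(cfg, seed = 3)
    lp <- net_forward(net, cl)$logp
    expect_equal(dim(lp), c(1L, 3L))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-5)
  }
})

test_that("classification is permutation invariant with a pinned FPS start", {
  cl <- normalize_unit_ball(rand_cloud(24, seed = 4))
  net <- pointnetpp_net(tiny_cls_cfg("lgg", nontrunc = TRUE), seed = 5)
  base <- net_forward(net, cl, fps_start = 7L)$logp
  set.seed(6)
  perm <- sample(nrow(cl))
  lp <- net_forward(net, point_cloud(unclass(cl)[perm, ]),
                    fps_start = which(perm == 7L))$logp
  expect_equal(lp, base, tolerance = 1e-9)
  # the flat baseline is permutation invariant regardless of the start
  pn <- pointnetpp_net(tiny_cls_cfg("pointnet"), seed = 5)
  expect_equal(net_forward(pn, point_cloud(unclass(cl)[perm, ]))$logp,
               net_forward(pn, cl)$logp, tolerance = 1e-9)
})

test_that("segmentation output is n x 2 and permutation equivariant", {
  cl <- normalize_unit_ball(rand_cloud(40, seed = 7))
  cfg <- seg_model_config(npoints = 40, scale = "small", dropout = 0)
  cfg$sa1 <- ns$.sa_level(10, 0.3, 40, list(c(6, 6)))
  cfg$sa2 <- ns$.sa_level(3, 0.6, 10, list(c(8, 8)))
  cfg$fp1 <- c(6)
  cfg$fp2 <- c(6)
  cfg$head <- 5
  net <- pointnetpp_net(cfg, seed = 8)
  fw <- net_forward(net, cl, fps_start = 3L)
  expect_equal(dim(fw$logp), c(40L, 2L))
  expect_equal(rowSums(exp(fw$logp)), rep(1, 40), tolerance = 1e-5)
  set.seed(9)
  perm <- sample(40)
  fw2 <- net_forward(net, point_cloud(unclass(cl)[perm, ]),
                     fps_start = which(perm == 3L))
  expect_equal(fw2$logp, fw$logp[perm, ], tolerance = 1e-9)
})

test_that("full-scale architecture honours the published dimension pins", {
  cl <- normalize_unit_ball(rand_cloud(2500, seed = 10))
  # MSG: level-2 concatenated feature 640 wide, 643 with coordinates
  msg <- pointnetpp_net(cls_model_config("msg", K = 10, scale = "full"),
                        seed = 1)
  dm <- net_forward(msg, cl)$dims
  expect_equal(dm$sa2_width, 640L)
  expect_equal(dm$global_in, 643L)
  expect_equal(dm$global_width, 1024L)
  # LGG: 9 MLP blocks and a 2048-wide final feature
  lgg <- pointnetpp_net(cls_model_config("lgg", K = 10, scale = "full"),
                        seed = 1)
  expect_equal(count_mlps(lgg), 9L)
  fwl <- net_forward(lgg, cl)
  expect_equal(fwl$dims$global_width, 2048L)
  expect_equal(ncol(fwl$logp), 10L)
  expect_equal(sum(exp(fwl$logp)), 1, tolerance = 1e-5)
  # segmentation: n x 2 per-point output
  seg <- pointnetpp_net(seg_model_config(scale = "full"), seed = 1)
  expect_equal(dim(net_forward(seg, cl)$logp), c(2500L, 2L))
})

test_that("the LGG grouping reduces to MSG when the global branch is removed", {
  cl <- normalize_unit_ball(rand_cloud(200, seed = 11))
  lgg <- pointnetpp_net(cls_model_config("lgg", K = 4, npoints = 200,
                                         scale = "small", dropout = 0),
                        seed = 12)
  msgc <- cls_model_config("msg", K = 4, npoints = 200, scale = "small",
                           dropout = 0)
  msg <- pointnetpp_net(msgc, seed = 99)
  # share the three local level-1 branches (level-2 inputs necessarily
  # differ in width once the global branch widens the level-1 feature)
  for (b in 1:3) for (nm in ls(lgg$params)) {
    pre <- paste0("sa1.b", b, ".")
    if (startsWith(nm, pre)) msg$params[[nm]] <- lgg$params[[nm]]
  }
  c_lgg <- net_forward(lgg, cl, keep_cache = TRUE)$cache$s1
  c_msg <- net_forward(msg, cl, keep_cache = TRUE)$cache$s1
  expect_identical(c_msg$sel, c_lgg$sel)
  for (b in 1:3) {
    expect_identical(c_msg$branches[[b]]$flat, c_lgg$branches[[b]]$flat)
    expect_equal(c_msg$branches[[b]]$mlp$out, c_lgg$branches[[b]]$mlp$out,
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match numeric central differences", {
  set.seed(42)
  xyz <- ns$.normalize_mat(matrix(rnorm(20 * 3), 20, 3))
  check <- function(cfg, labels) {
    net <- pointnetpp_net(cfg, seed = 7)
    P <- net$params
    # move biases off the ReLU kinks that zero-init places them on
    for (nm in ls(P)) P[[nm]] <- P[[nm]] + rnorm(length(P[[nm]]), 0, 0.05)
    G <- ns$.zero_grads(P)
    fw <- net_forward(net, xyz, keep_cache = TRUE)
    ns$.net_backward(net, fw, labels, G, scale = 1)
    f <- function() nll_loss(net_forward(net, xyz)$logp, labels)
    for (nm in ls(P)) {
      for (j in sample(length(P[[nm]]), min(3, length(P[[nm]])))) {
        eps <- 1e-5
        old <- P[[nm]][j]
        P[[nm]][j] <- old + eps
        fp <- f()
        P[[nm]][j] <- old - eps
        fm <- f()
        P[[nm]][j] <- old
        num <- (fp - fm) / (2 * eps)
        ana <- if (is.null(G[[nm]])) 0 else G[[nm]][j]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
  cfg <- tiny_cls_cfg("lgg")
  check(cfg, 1L)
  segc <- seg_model_config(npoints = 20, scale = "small", dropout = 0)
  segc$sa1 <- ns$.sa_level(8, 0.3, 3, list(c(4, 4)))
  segc$sa2 <- ns$.sa_level(3, 0.6, 3, list(c(6, 6)))
  segc$fp1 <- 5
  segc$fp2 <- 5
  segc$head <- 4
  check(segc, sample(0:1, 20, replace = TRUE))
  # normalized-layer path
  cfgn <- tiny_cls_cfg("ssg")
  cfgn$norm <- TRUE
  check(cfgn, 0L)
})
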