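# Minimal dense-network machinery used by the point-cloud models: shared
# MLPs (linear + ReLU stacks applied row-wise), group max-pooling,
# log-softmax with negative log-likelihood loss, and Adam. Parameters and
# gradients live in environments keyed by "<prefix>.W<l>" / "<prefix>.b<l>"
# so the training loop can treat every model uniformly. Backpropagation is
# written out by hand; coordinates are fixed inputs (centroids are always
# subsets of the input cloud), so gradients only flow through features.

.init_linear <- function(P, prefix, l, nin, nout, bias = TRUE) {
  lim <- sqrt(6 / nin)  # He-style uniform fan-in init
  P[[paste0(prefix, ".W", l)]] <- matrix(runif(nin * nout, -lim, lim),
                                         nin, nout)
  if (bias) P[[paste0(prefix, ".b", l)]] <- numeric(nout)
  invisible(NULL)
}

.init_mlp <- function(P, prefix, nin, widths, norm = FALSE,
                      final_act = TRUE) {
  for (l in seq_along(widths)) {
    normed <- norm && (final_act || l < length(widths))
    .init_linear(P, prefix, l, nin, widths[l], bias = !normed)
    if (normed) {
      P[[paste0(prefix, ".g", l)]] <- rep(1, widths[l])
      P[[paste0(prefix, ".be", l)]] <- numeric(widths[l])
    }
    nin <- widths[l]
  }
  invisible(NULL)
}

# Forward through a stack of shared linear layers applied row-wise.
# ReLU after every layer, or after all but the last when
# `final_act = FALSE`. With `norm = TRUE` each activated layer inserts a
# per-channel normalization over the rows (the points) with a learnable
# gain/shift before the ReLU -- the standardization role batch norm plays
# in GPU point-cloud stacks, but computed per sample, so inference is
# batch-independent and deterministic. Optional inverted dropout between
# layers (training only). The backward pass recovers the ReLU mask from
# each layer's output (output > 0 iff pre-activation > 0), so only
# inputs, normalization statistics and dropout masks are cached.
.mlp_fwd <- function(X, prefix, widths, P, final_act = TRUE, dropout = 0,
                     train = FALSE, norm = FALSE) {
  nl <- length(widths)
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    act <- final_act || l < nl
    if (norm && act) {
      Z <- X %*% P[[paste0(prefix, ".W", l)]]
      mu <- colMeans(Z)
      Z <- Z - rep(mu, each = nrow(Z))
      sg <- sqrt(colMeans(Z^2) + 1e-5)
      xhat <- Z / rep(sg, each = nrow(Z))
      Z <- bias_act_cpp(xhat * rep(P[[paste0(prefix, ".g", l)]],
                                   each = nrow(Z)),
                        P[[paste0(prefix, ".be", l)]], TRUE)
      ly <- list(X = X, xhat = xhat, sg = sg, dmask = NULL)
    } else {
      Z <- bias_act_cpp(X %*% P[[paste0(prefix, ".W", l)]],
                        P[[paste0(prefix, ".b", l)]], act)
      ly <- list(X = X, xhat = NULL, sg = NULL, dmask = NULL)
    }
    if (act && dropout > 0 && train) {
      ly$dmask <- matrix((runif(length(Z)) >= dropout) / (1 - dropout),
                         nrow(Z), ncol(Z))
      Z <- Z * ly$dmask
    }
    layers[[l]] <- ly
    X <- Z
  }
  list(out = X, layers = layers, prefix = prefix, nl = nl,
       final_act = final_act)
}

# Backward pass; accumulates parameter gradients into environment G
# (entries created on first touch) and returns the gradient w.r.t. the
# input matrix.
.mlp_bwd <- function(dY, cache, P, G) {
  acc <- function(nm, g) G[[nm]] <- if (is.null(G[[nm]])) g else G[[nm]] + g
  for (l in rev(seq_len(cache$nl))) {
    ly <- cache$layers[[l]]
    if (!is.null(ly$dmask)) dY <- dY * ly$dmask
    if (cache$final_act || l < cache$nl) {
      out <- if (l == cache$nl) cache$out else cache$layers[[l + 1]]$X
      dY <- dY * (out > 0)
    }
    wn <- paste0(cache$prefix, ".W", l)
    if (!is.null(ly$xhat)) {
      n <- nrow(dY)
      acc(paste0(cache$prefix, ".g", l), colSums(dY * ly$xhat))
      acc(paste0(cache$prefix, ".be", l), colSums(dY))
      dxh <- dY * rep(P[[paste0(cache$prefix, ".g", l)]], each = n)
      dZ <- (dxh - rep(colMeans(dxh), each = n) -
             ly$xhat * rep(colMeans(dxh * ly$xhat), each = n)) /
        rep(ly$sg, each = n)
      acc(wn, crossprod(ly$X, dZ))
      dY <- tcrossprod(dZ, P[[wn]])
    } else {
      acc(wn, crossprod(ly$X, dY))
      acc(paste0(cache$prefix, ".b", l), colSums(dY))
      dY <- tcrossprod(dY, P[[wn]])
    }
  }
  dY
}

# Max over each centroid's cap contiguous rows. Returns the pooled m x C
# matrix and the argmax rows needed by the backward pass.
.pool_fwd <- function(H, m, cap) pool_max_cpp(H, m, cap)

# Route each pooled gradient entry to the row that achieved the maximum.
# Padded duplicate members are copies of the same upstream quantity, so
# first-argmax routing yields the exact parameter gradient.
.pool_bwd <- function(dM, argmax, nrow_h) {
  dH <- matrix(0, nrow_h, ncol(dM))
  dH[cbind(as.vector(argmax),
           rep(seq_len(ncol(dM)), each = nrow(dM)))] <- as.vector(dM)
  dH
}

.log_softmax <- function(Z) {
  zmax <- do.call(pmax, as.data.frame(Z))
  Z <- Z - zmax
  Z - log(rowSums(exp(Z)))
}

#' Negative log-likelihood loss on log-probabilities
#'
#' The mean over items of minus the log-probability assigned to the true
#' class. Inputs are rows of log-probabilities, as produced by the models'
#' log-softmax output layer.
#'
#' @param log_probs numeric matrix (items x classes) of log-probabilities,
#'   or a single vector for one item.
#' @param labels 0-based integer class labels, one per row.
#' @return the scalar mean loss.
#' @export
nll_loss <- function(log_probs, labels) {
  lp <- if (is.matrix(log_probs)) log_probs else matrix(log_probs, nrow = 1)
  labels <- as.integer(labels)
  if (length(labels) != nrow(lp))
    .invalid_argument("one label per row of log_probs required")
  if (any(labels < 0L | labels >= ncol(lp)))
    .invalid_argument("label out of range")
  -mean(lp[cbind(seq_len(nrow(lp)), labels + 1L)])
}

# Gradient of nll_loss(log_softmax(Z), labels) w.r.t. Z, scaled by `scale`
# (softmax minus one-hot over the item mean).
.nll_logsoftmax_bwd <- function(logp, labels, scale = 1) {
  S <- exp(logp)
  S[cbind(seq_len(nrow(S)), as.integer(labels) + 1L)] <-
    S[cbind(seq_len(nrow(S)), as.integer(labels) + 1L)] - 1
  S * (scale / nrow(S))
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(P) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- new.env(parent = emptyenv())
  st$v <- new.env(parent = emptyenv())
  for (nm in ls(P)) {
    st$m[[nm]] <- P[[nm]] * 0
    st$v[[nm]] <- P[[nm]] * 0
  }
  st
}

.adam_step <- function(P, G, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in ls(G)) {
    g <- G[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (st$m[[nm]] / c1) /
      (sqrt(st$v[[nm]] / c2) + eps)
  }
  invisible(NULL)
}

.zero_grads <- function(P) new.env(parent = emptyenv())

# Scatter-add rows of dX into an N x C accumulator by 1-based index.
.scatter_add <- function(acc, idx, dX) {
  rs <- rowsum(dX, idx, reorder = FALSE)
  tgt <- as.integer(rownames(rs))
  acc[tgt, ] <- acc[tgt, , drop = FALSE] + rs
  acc
}

# Scale all gradients down to a global L2 norm of at most `clip`.
.clip_grads <- function(G, clip) {
  if (!is.finite(clip)) return(invisible(NULL))
  tot <- 0
  for (nm in ls(G)) tot <- tot + sum(G[[nm]]^2)
  tot <- sqrt(tot)
  if (tot > clip) {
    f <- clip / tot
    for (nm in ls(G)) G[[nm]] <- G[[nm]] * f
  }
  invisible(NULL)
}
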