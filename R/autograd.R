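# Minimal reverse-mode automatic differentiation over dense arrays.
#
# Every value in a computation graph is a "node": an environment holding the
# forward value (`v`), an accumulated gradient (`g`), the parent nodes and a
# backward closure that maps the node's output gradient to gradients for each
# parent. Nodes are created in topological order (a monotone counter), so the
# backward pass is a single reverse sweep over the creation order.
#
# Activations are arrays dim c(H, W, C) or batched c(H, W, C, N); pooled
# quantities are length-C vectors or C x N matrices. Elementwise ops are
# shape-agnostic; the structured ops accept both layouts. Only the handful of
# operations the segmentation network needs are implemented.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  .ag$counter <- .ag$counter + 1L
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  n$parents <- parents
  n$backward <- backward
  n$idx <- .ag$counter
  class(n) <- "ag_node"
  n
}

#' @noRd
ag_const <- function(value) ag_node(value)

is_ag <- function(x) inherits(x, "ag_node")

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

ag_value <- function(x) if (is_ag(x)) x$v else x

accumulate_grad <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

# Reverse sweep from a scalar root. Gradients accumulate in each node's `g`;
# callers read them off the parameter leaves they kept references to.
ag_backward <- function(root) {
  stopifnot(is_ag(root), length(root$v) == 1L)
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack) > 0L) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$idx)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$idx, integer(1)), decreasing = TRUE)
  root$g <- 1
  for (n in nodes[ord]) {
    if (is.null(n$g) || is.null(n$backward)) next
    grads <- n$backward(n$g)
    for (k in seq_along(grads)) {
      if (!is.null(grads[[k]])) accumulate_grad(n$parents[[k]], grads[[k]])
    }
  }
  invisible(root)
}

# Activation dims as c(H, W, C, N), padding N = 1 for unbatched arrays.
act_dim4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) c(d, 1L) else d
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

stable_sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- elementwise / reduction primitives -------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$v + b$v, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$v - b$v, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$v; bv <- b$v
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$v; bv <- b$v
  ag_node(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

ag_scale <- function(a, k) {
  a <- as_ag(a)
  ag_node(a$v * k, list(a), function(g) list(g * k))
}

ag_add_scalar <- function(a, k) {
  a <- as_ag(a)
  ag_node(a$v + k, list(a), function(g) list(g))
}

ag_sqrt <- function(a) {
  a <- as_ag(a)
  s <- sqrt(a$v)
  ag_node(s, list(a), function(g) list(g / (2 * s)))
}

# Concatenate two pooled vectors (or C x N column batches) along the
# feature dimension.
ag_concat_v <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  if (is.matrix(a$v)) {
    na <- nrow(a$v)
    ag_node(rbind(a$v, b$v), list(a, b), function(g) {
      list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
    })
  } else {
    na <- length(a$v)
    ag_node(c(a$v, b$v), list(a, b), function(g) {
      list(g[seq_len(na)], g[-seq_len(na)])
    })
  }
}

ag_square <- function(a) {
  a <- as_ag(a)
  av <- a$v
  ag_node(av * av, list(a), function(g) list(2 * g * av))
}

ag_relu <- function(a) {
  a <- as_ag(a)
  mask <- a$v > 0
  ag_node(a$v * mask, list(a), function(g) list(g * mask))
}

# Hard clamp to [0, 1] with gradient rescue: inside the box the gradient
# passes unchanged; at a saturated bound it passes only when it points back
# into the box, so no unit can die in a saturated state.
ag_clamp01 <- function(a) {
  a <- as_ag(a)
  av <- a$v
  y <- pmin(pmax(av, 0), 1)
  dim(y) <- dim_or_len(av)
  ag_node(y, list(a), function(g) {
    pass <- (av > 0 & av < 1) | (av <= 0 & g < 0) | (av >= 1 & g > 0)
    list(g * pass)
  })
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  s <- stable_sigmoid(a$v)
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_mean <- function(a) {
  a <- as_ag(a)
  n <- length(a$v)
  ag_node(mean(a$v), list(a), function(g) list(array(g / n, dim_or_len(a$v))))
}

ag_sum <- function(a) {
  a <- as_ag(a)
  ag_node(sum(a$v), list(a), function(g) list(array(g, dim_or_len(a$v))))
}

# ---- structured primitives ---------------------------------------------------

# 2-D convolution of an (H, W, Cin[, N]) activation with a
# (kh, kw, Cin, Cout) kernel; batched over N in compiled code.
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 1L) {
  x <- as_ag(x); w <- as_ag(w)
  xd <- act_dim4(x$v); wd <- dim(w$v)
  stopifnot(length(wd) == 4L, xd[3] == wd[3])
  batched <- length(dim(x$v)) == 4L
  kh <- wd[1]; kw <- wd[2]; cout <- wd[4]
  wm <- matrix(w$v, nrow = kh * kw * wd[3], ncol = cout)
  bv <- if (is.null(b)) NULL else as_ag(b)
  y <- cpp_conv2d_fw(x$v, xd, wm, if (is.null(bv)) rep(0, cout) else bv$v,
                     kh, kw, stride, pad)
  if (!batched) dim(y) <- dim(y)[1:3]
  parents <- if (is.null(bv)) list(x, w) else list(x, w, bv)
  ag_node(y, parents, function(g) {
    bw <- cpp_conv2d_bw(x$v, xd, wm, g, kh, kw, stride, pad)
    dx <- bw$dx
    if (!batched) dim(dx) <- dim(dx)[1:3]
    out <- list(dx, array(bw$dw, dim = wd))
    if (length(parents) == 3L) out[[3]] <- as.numeric(bw$db)
    out
  })
}

# Per-channel uniform box filter with *valid* support (used by SSIM).
ag_boxfilter <- function(x, k) {
  x <- as_ag(x)
  xd <- act_dim4(x$v)
  stopifnot(xd[1] - k + 1L >= 1L, xd[2] - k + 1L >= 1L)
  kern <- matrix(1 / (k * k), nrow = k * k, ncol = 1)
  # depthwise: run the conv kernel over C*N single-channel slabs
  xi <- x$v; dim(xi) <- c(xd[1], xd[2], 1L, xd[3] * xd[4])
  y <- cpp_conv2d_fw(xi, dim(xi), kern, 0, k, k, 1L, 0L)
  yd <- dim(y)
  newdim <- c(yd[1], yd[2], xd[3], xd[4])
  dim(y) <- if (length(dim(x$v)) == 3L) newdim[1:3] else newdim
  ag_node(y, list(x), function(g) {
    dim(g) <- c(yd[1], yd[2], 1L, xd[3] * xd[4])
    dx <- cpp_conv2d_bw(xi, dim(xi), kern, g, k, k, 1L, 0L)$dx
    dim(dx) <- dim_or_len(x$v)
    list(dx)
  })
}

# Instance normalisation: per-channel, per-sample standardisation over
# H x W, then a learned affine transform shared across the batch.
# (Column stats are expanded with rep() rather than sweep(): the aperm
# inside sweep dominates the profile otherwise.)
ag_instnorm <- function(x, gamma, beta, eps = 1e-12) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  xd0 <- dim_or_len(x$v)
  xd <- act_dim4(x$v)
  N <- xd[1] * xd[2]; CN <- xd[3] * xd[4]
  gv <- rep(gamma$v, times = xd[4]); bv <- rep(beta$v, times = xd[4])
  if (N == 1L) {
    # a 1x1 map standardises to zero; fall back to the plain affine so the
    # bottleneck keeps carrying signal on very small inputs
    y <- x$v * gv + bv  # recycling is exact: one value per (channel, sample)
    dim(y) <- xd0
    return(ag_node(y, list(x, gamma, beta), function(g) {
      fold <- function(z) if (xd[4] == 1L) z else rowSums(matrix(z, xd[3], xd[4]))
      dx <- as.numeric(g) * gv
      dim(dx) <- xd0
      list(dx, fold(as.numeric(g) * as.numeric(x$v)), fold(as.numeric(g)))
    }))
  }
  fw <- cpp_instnorm_fw(x$v, N, CN, gv, bv, eps)
  y <- fw$y
  dim(y) <- xd0
  ag_node(y, list(x, gamma, beta), function(g) {
    bw <- cpp_instnorm_bw(fw$xhat, fw$istd, g, gv, N, CN)
    fold <- function(z) if (xd[4] == 1L) z else rowSums(matrix(z, xd[3], xd[4]))
    dx <- bw$dx
    dim(dx) <- xd0
    list(dx, fold(as.numeric(bw$dgamma)), fold(as.numeric(bw$dbeta)))
  })
}

# Nearest-neighbour 2x upsampling (batched via the C*N slice trick).
ag_upsample2 <- function(x) {
  x <- as_ag(x)
  xd0 <- dim_or_len(x$v); xd <- act_dim4(x$v)
  xi <- x$v; dim(xi) <- c(xd[1], xd[2], xd[3] * xd[4])
  y <- cpp_upsample2(xi)
  dim(y) <- c(2L * xd[1], 2L * xd[2], xd0[-(1:2)])
  ag_node(y, list(x), function(g) {
    dim(g) <- c(2L * xd[1], 2L * xd[2], xd[3] * xd[4])
    dx <- cpp_downsum2(g)
    dim(dx) <- xd0
    list(dx)
  })
}

ag_concat_c <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ad <- act_dim4(a$v); bd <- act_dim4(b$v)
  stopifnot(all(ad[c(1, 2, 4)] == bd[c(1, 2, 4)]))
  ca <- ad[3]; cb <- bd[3]
  y <- array(0, dim = c(ad[1], ad[2], ca + cb, ad[4]))
  y[, , seq_len(ca), ] <- a$v
  y[, , ca + seq_len(cb), ] <- b$v
  if (length(dim(a$v)) == 3L) dim(y) <- dim(y)[1:3]
  ag_node(y, list(a, b), function(g) {
    dim(g) <- c(ad[1], ad[2], ca + cb, ad[4])
    ga <- g[, , seq_len(ca), , drop = FALSE]
    gb <- g[, , ca + seq_len(cb), , drop = FALSE]
    if (length(dim(a$v)) == 3L) { dim(ga) <- dim(a$v); dim(gb) <- dim(b$v) }
    list(ga, gb)
  })
}

# Multiply an (H, W, C[, N]) activation by a single-channel (H, W, 1[, N])
# gate, broadcasting over channels.
ag_mul_gate <- function(x, psi) {
  x <- as_ag(x); psi <- as_ag(psi)
  xd <- act_dim4(x$v)
  expand <- function(p) {
    # (H, W, 1, N) -> (H, W, C, N)
    dim(p) <- c(xd[1] * xd[2], xd[4])
    out <- p[, rep(seq_len(xd[4]), each = xd[3]), drop = FALSE]
    # columns are ordered (c within n); reorder to (H,W,C,N) layout
    array(out, dim = xd)
  }
  pfull <- expand(psi$v)
  dim(pfull) <- dim_or_len(x$v)
  y <- x$v * pfull
  ag_node(y, list(x, psi), function(g) {
    dx <- g * pfull
    dim(dx) <- dim_or_len(x$v)
    gx <- g * x$v
    dim(gx) <- c(xd[1] * xd[2] * xd[3], xd[4])
    dpsi <- vapply(seq_len(xd[4]), function(n)
      rowSums(matrix(gx[, n], xd[1] * xd[2], xd[3])),
      numeric(xd[1] * xd[2]))
    dim(dpsi) <- c(xd[1], xd[2], 1L, xd[4])
    if (length(dim(psi$v)) == 3L) dim(dpsi) <- dim(dpsi)[1:3]
    list(dx, dpsi)
  })
}

# Global average pool: (H, W, C) -> length-C vector, batched -> C x N.
ag_gap <- function(x) {
  x <- as_ag(x)
  xd <- act_dim4(x$v)
  N <- xd[1] * xd[2]
  pooled <- colMeans(matrix(x$v, nrow = N, ncol = xd[3] * xd[4]))
  y <- if (xd[4] == 1L) pooled else matrix(pooled, xd[3], xd[4])
  ag_node(y, list(x), function(g) {
    list(array(rep(as.numeric(g) / N, each = N), dim = dim_or_len(x$v)))
  })
}

# Affine map: W x + b for a length-n vector or an n x N matrix of columns.
ag_dense <- function(x, W, b) {
  x <- as_ag(x); W <- as_ag(W); b <- as_ag(b)
  if (is.matrix(x$v)) {
    y <- W$v %*% x$v + b$v  # b recycles down columns
    ag_node(y, list(x, W, b), function(g) {
      list(crossprod(W$v, g), tcrossprod(g, x$v), rowSums(g))
    })
  } else {
    ag_node(drop(W$v %*% x$v) + b$v, list(x, W, b), function(g) {
      list(drop(crossprod(W$v, g)), outer(g, x$v), g)
    })
  }
}

# ---- loss primitives ---------------------------------------------------------

# Numerically stable binary cross-entropy with logits, mean over elements.
ag_bce_logits <- function(z, target) {
  z <- as_ag(z)
  zv <- z$v
  n <- length(zv)
  l <- mean(pmax(zv, 0) - zv * target + log1p(exp(-abs(zv))))
  ag_node(l, list(z), function(g) {
    dz <- g * (stable_sigmoid(zv) - target) / n
    dim(dz) <- dim(zv)
    list(dz)
  })
}

# Softmax cross-entropy of a logit vector (or K x N column batch) against a
# matching target distribution; mean over columns.
ag_softmax_ce <- function(z, target) {
  z <- as_ag(z)
  zv <- if (is.matrix(z$v)) z$v else matrix(z$v, ncol = 1)
  tv <- if (is.matrix(target)) target else matrix(target, ncol = 1)
  m <- apply(zv, 2, max)
  lse <- m + log(colSums(exp(sweep(zv, 2, m))))
  l <- mean(lse - colSums(tv * zv))
  ag_node(l, list(z), function(g) {
    p <- exp(sweep(zv, 2, lse))
    dz <- g * (p - tv) / ncol(zv)
    if (!is.matrix(z$v)) dz <- drop(dz)
    list(dz)
  })
}

ag_mse <- function(a, b) ag_mean(ag_square(ag_sub(a, b)))
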