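# Minimal reverse-mode tape used by the image-regression network.
#
# Feature maps are stored as dense matrices with one row per (pixel, batch
# sample) and one column per channel; rows run over (h, w, n) with h
# fastest.  Spatial kernels (3x3 im2col convolution, 2x2 max pooling,
# nearest upsampling) are compiled (src/ops.cpp); matrix products go
# through BLAS.  Each op appends a node holding its value and a backward
# closure; backprop walks the tape in reverse creation order.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t
}

tape_node <- function(tape, value, parents = list(), backward = NULL,
                      H = NULL, W = NULL, N = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$H <- H; n$W <- W; n$N <- N
  tape$nodes[[length(tape$nodes) + 1L]] <- n
  n
}

leaf_node <- function(tape, value) tape_node(tape, value)

accum_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

backprop <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (n in rev(tape$nodes)) {
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n)
  }
  invisible(NULL)
}

# ---- layout conversion ----------------------------------------------------

# (H, W, C, N) array -> (H*W*N) x C matrix, rows over (h, w, n), h fastest
arr_to_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

mat_to_arr <- function(m, H, W, N) {
  C <- ncol(m)
  dim(m) <- c(H, W, N, C)
  aperm(m, c(1L, 2L, 4L, 3L))
}

# ---- convolution ----------------------------------------------------------

# 3x3 (zero pad 1) or 1x1 convolution.  For 3x3 the weight matrix has
# 9 * Cin rows ordered offset-fastest: row = offset + 9 * (cin - 1).
op_conv <- function(tape, x, w, b, kernel = 3L) {
  H <- x$H; W <- x$W; N <- x$N
  hwn <- H * W * N
  C <- ncol(x$value)
  cols <- if (kernel == 3L) cpp_im2col3(x$value, H, W, N) else x$value
  ym <- cols %*% w$value
  ym <- ym + rep(b$value, each = hwn)
  tape_node(
    tape, ym, list(x = x, w = w, b = b), H = H, W = W, N = N,
    backward = function(self) {
      dy <- self$grad
      accum_grad(w, crossprod(cols, dy))
      accum_grad(b, colSums(dy))
      dcols <- dy %*% t(w$value)
      if (kernel == 3L) {
        accum_grad(x, cpp_col2im3(dcols, H, W, N, C))
      } else {
        accum_grad(x, dcols)
      }
    }
  )
}

# ---- batch normalization --------------------------------------------------

# Per-channel batch norm over all rows (i.e. over H, W and the batch).  In
# training mode batch statistics are used and updated running statistics
# are reported through `upd`; in eval mode the stored running stats apply.
op_bn <- function(tape, x, gamma, beta, rmean, rvar, training, upd = NULL,
                  name = NULL, momentum = 0.1, eps = 1e-5) {
  xm <- x$value
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    va <- pmax(colMeans(xm * xm) - mu * mu, 0)
    if (!is.null(upd)) {
      upd[[name]] <- list(
        mean = (1 - momentum) * rmean$value + momentum * mu,
        var = (1 - momentum) * rvar$value + momentum * va * m / max(m - 1, 1)
      )
    }
  } else {
    mu <- rmean$value
    va <- rvar$value
  }
  invs <- 1 / sqrt(va + eps)
  xhat <- cpp_axpb_cols(xm, invs, -mu * invs)
  ym <- cpp_axpb_cols(xhat, gamma$value, beta$value)
  zero <- numeric(length(mu))
  tape_node(
    tape, ym, list(x = x, gamma = gamma, beta = beta),
    H = x$H, W = x$W, N = x$N,
    backward = function(self) {
      dym <- self$grad
      accum_grad(gamma, colSums(dym * xhat))
      accum_grad(beta, colSums(dym))
      dxhat <- cpp_axpb_cols(dym, gamma$value, zero)
      if (training) {
        dxm <- cpp_bn_bwd(dxhat, xhat, invs, colMeans(dxhat),
                          colMeans(dxhat * xhat))
      } else {
        dxm <- cpp_axpb_cols(dxhat, invs, zero)
      }
      accum_grad(x, dxm)
    }
  )
}

# ---- elementwise and shape ops -------------------------------------------

op_relu <- function(tape, x) {
  mask <- x$value > 0
  tape_node(tape, x$value * mask, list(x = x), H = x$H, W = x$W, N = x$N,
            backward = function(self) accum_grad(x, self$grad * mask))
}

op_clamp01 <- function(tape, x) {
  mask <- x$value > 0 & x$value < 1
  tape_node(tape, pmin(pmax(x$value, 0), 1), list(x = x),
            H = x$H, W = x$W, N = x$N,
            backward = function(self) accum_grad(x, self$grad * mask))
}

op_add <- function(tape, a, b) {
  tape_node(tape, a$value + b$value, list(a = a, b = b),
            H = a$H, W = a$W, N = a$N,
            backward = function(self) {
              accum_grad(a, self$grad)
              accum_grad(b, self$grad)
            })
}

op_concat <- function(tape, a, b) {
  ca <- ncol(a$value)
  tape_node(tape, cbind(a$value, b$value), list(a = a, b = b),
            H = a$H, W = a$W, N = a$N,
            backward = function(self) {
              accum_grad(a, self$grad[, seq_len(ca), drop = FALSE])
              accum_grad(b, self$grad[, ca + seq_len(ncol(b$value)), drop = FALSE])
            })
}

op_maxpool2 <- function(tape, x) {
  H <- x$H; W <- x$W; N <- x$N
  fwd <- cpp_pool2_fwd(x$value, H, W, N)
  tape_node(tape, fwd$y, list(x = x), H = H %/% 2L, W = W %/% 2L, N = N,
            backward = function(self) {
              accum_grad(x, cpp_pool2_bwd(self$grad, fwd$which, H, W, N))
            })
}

op_upsample2 <- function(tape, x) {
  H <- x$H; W <- x$W; N <- x$N
  tape_node(tape, cpp_up2_fwd(x$value, H, W, N), list(x = x),
            H = 2L * H, W = 2L * W, N = N,
            backward = function(self) {
              accum_grad(x, cpp_up2_bwd(self$grad, H, W, N))
            })
}

# mean squared error against a fixed target matrix
op_mse <- function(tape, pred, target) {
  diff <- pred$value - target
  nel <- length(diff)
  tape_node(tape, mean(diff^2), list(pred = pred),
            backward = function(self) {
              accum_grad(pred, self$grad * 2 * diff / nel)
            })
}

op_sum_scalars <- function(tape, nodes) {
  tape_node(tape, sum(vapply(nodes, function(n) n$value, numeric(1))), nodes,
            backward = function(self) {
              for (n in nodes) accum_grad(n, self$grad)
            })
}
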