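# Compact residual-U-block encoder-decoder ("nested U") image regressor
# with deep supervision: each encoder/decoder stage is itself a small
# U-shaped block of conv / batch-norm / ReLU chains with down- and
# up-sampling and a residual skip.  Single-channel input and output, output
# clamped to [0, 1] to match the normalized SUV targets.

#' Network configuration
#'
#' @param n_stages encoder depth (1-6; default 3 at desk scale).
#' @param base_channels channels per stage (default 8).
#' @param rsu_inner_depth levels inside each residual U-block (default 2;
#'   each block downsamples `rsu_inner_depth - 1` times internally).
#' @param deep_supervision attach an L2 term to every side output (default
#'   `TRUE`).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param weight_decay decoupled weight decay (default 0.0001).
#' @param batch_size mini-batch size (default 4).
#' @param epochs default number of training epochs.
#' @param lr_schedule `"constant"` or `"cosine"` (cosine annealing of the
#'   learning rate over the epochs of a training call).
#' @param grad_clip global L2 norm bound on the per-step gradient over all
#'   trainable parameters (`Inf` disables; a finite bound stabilizes
#'   training at higher learning rates).
#' @param seed seed for parameter initialization and data shuffling.
#' @return a `network_config`.
#' @export
network_config <- function(n_stages = 3L, base_channels = 8L,
                           rsu_inner_depth = 2L, deep_supervision = TRUE,
                           learning_rate = 0.001, weight_decay = 0.0001,
                           batch_size = 4L, epochs = 10L,
                           lr_schedule = c("constant", "cosine"),
                           grad_clip = Inf, seed = 0L) {
  if (n_stages < 1 || n_stages > 6) stop_invalid("n_stages must be in 1..6")
  if (base_channels < 1) stop_invalid("base_channels must be >= 1")
  if (rsu_inner_depth < 1) stop_invalid("rsu_inner_depth must be >= 1")
  if (learning_rate <= 0) stop_invalid("learning_rate must be > 0")
  structure(list(
    n_stages = as.integer(n_stages),
    base_channels = as.integer(base_channels),
    rsu_inner_depth = as.integer(rsu_inner_depth),
    deep_supervision = isTRUE(deep_supervision),
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    lr_schedule = match.arg(lr_schedule),
    grad_clip = grad_clip,
    seed = as.integer(seed)
  ), class = "network_config")
}

# ---- parameter manifest ---------------------------------------------------

cbr_defs <- function(prefix, cin, cout) {
  list(
    list(name = paste0(prefix, ".w"), dims = c(9L * cin, cout), trainable = TRUE,
         init = "kaiming", fan_in = 9L * cin),
    list(name = paste0(prefix, ".b"), dims = cout, trainable = TRUE, init = "zero"),
    list(name = paste0(prefix, ".g"), dims = cout, trainable = TRUE, init = "one"),
    list(name = paste0(prefix, ".be"), dims = cout, trainable = TRUE, init = "zero"),
    list(name = paste0(prefix, ".rm"), dims = cout, trainable = FALSE, init = "zero"),
    list(name = paste0(prefix, ".rv"), dims = cout, trainable = FALSE, init = "one")
  )
}

# 1x1 output heads; bias starts mid-range so the [0, 1] clamp does not
# silence gradients on the first steps
conv1_defs <- function(prefix, cin, cout) {
  list(
    list(name = paste0(prefix, ".w"), dims = c(cin, cout), trainable = TRUE,
         init = "kaiming", fan_in = cin),
    list(name = paste0(prefix, ".b"), dims = cout, trainable = TRUE, init = "quarter")
  )
}

rsu_defs <- function(prefix, cin, cout, L, M) {
  defs <- cbr_defs(paste0(prefix, ".in"), cin, cout)
  defs <- c(defs, cbr_defs(paste0(prefix, ".e1"), cout, M))
  if (L >= 2) {
    for (i in 2:L) defs <- c(defs, cbr_defs(paste0(prefix, ".e", i), M, M))
  }
  defs <- c(defs, cbr_defs(paste0(prefix, ".bt"), M, M))
  for (i in L:1) {
    defs <- c(defs, cbr_defs(paste0(prefix, ".d", i), 2L * M,
                             if (i == 1L) cout else M))
  }
  defs
}

net_param_defs <- function(config) {
  S <- config$n_stages
  B <- config$base_channels
  L <- config$rsu_inner_depth
  M <- max(2L, B %/% 2L)
  defs <- list()
  for (s in seq_len(S)) {
    defs <- c(defs, rsu_defs(sprintf("en%d", s), if (s == 1L) 1L else B, B, L, M))
  }
  if (S >= 2) {
    for (s in (S - 1L):1L) {
      defs <- c(defs, rsu_defs(sprintf("de%d", s), 2L * B, B, L, M))
    }
  }
  for (s in seq_len(S)) {
    defs <- c(defs, conv1_defs(sprintf("side%d", s), B, 1L))
  }
  defs <- c(defs, conv1_defs("fuse", S, 1L))
  defs
}

#' Build an initialized network
#'
#' Constructs the parameter set for the configured architecture with
#' He-initialized convolution weights (seeded, so two builds with the same
#' seed are identical) plus batch-norm scale/shift and running statistics.
#'
#' @param config a [network_config()].
#' @return a `fedasc_net` (list with `params`, `trainable`, `config`).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  defs <- net_param_defs(config)
  params <- with_seed(config$seed, {
    lapply(defs, function(d) {
      n <- prod(d$dims)
      v <- switch(d$init,
        kaiming = rnorm(n, 0, sqrt(2 / d$fan_in)),
        zero = rep(0, n),
        one = rep(1, n),
        quarter = rep(0.25, n)
      )
      if (length(d$dims) > 1L) dim(v) <- d$dims
      v
    })
  })
  names(params) <- vapply(defs, `[[`, "", "name")
  trainable <- vapply(defs, `[[`, TRUE, "trainable")
  names(trainable) <- names(params)
  structure(list(params = params, trainable = trainable, config = config),
            class = "fedasc_net")
}

#' @export
print.fedasc_net <- function(x, ...) {
  cat(sprintf(
    "<fedasc_net: %d stages, %d channels, %d parameters (%d trainable)>\n",
    x$config$n_stages, x$config$base_channels,
    length(flatten_params(x)$vector),
    sum(count_parameters(x, trainable_only = TRUE))
  ))
  invisible(x)
}

#' Total parameter count
#' @param net a `fedasc_net`.
#' @param trainable_only count only trainable entries.
#' @return integer count.
#' @export
count_parameters <- function(net, trainable_only = FALSE) {
  n <- vapply(net$params, length, integer(1))
  if (trainable_only) sum(n[net$trainable[names(n)]]) else sum(n)
}

#' Flatten network parameters to a single vector
#'
#' The flat vector (with its shape manifest) is the unit of federated
#' exchange, clipping and noising.  Batch-norm running statistics are
#' included as non-trainable entries.  `unflatten_params()` is the exact
#' inverse.
#'
#' @param net a `fedasc_net`.
#' @return list with `vector`, `manifest` (tibble: name, n, trainable,
#'   offset) and `trainable_mask` (logical vector over entries).
#' @export
flatten_params <- function(net) {
  lens <- vapply(net$params, length, integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  manifest <- tibble::tibble(
    name = names(net$params), n = unname(lens),
    trainable = unname(net$trainable[names(net$params)]),
    offset = unname(offs)
  )
  list(
    vector = unlist(net$params, use.names = FALSE),
    manifest = manifest,
    trainable_mask = rep(manifest$trainable, manifest$n)
  )
}

#' @rdname flatten_params
#' @param vector flat numeric vector from `flatten_params()`.
#' @export
unflatten_params <- function(net, vector) {
  if (length(vector) != sum(vapply(net$params, length, integer(1)))) {
    stop_shape("flat vector length does not match the network manifest")
  }
  pos <- 0L
  for (nm in names(net$params)) {
    n <- length(net$params[[nm]])
    v <- vector[pos + seq_len(n)]
    dim(v) <- dim(net$params[[nm]])
    net$params[[nm]] <- v
    pos <- pos + n
  }
  net
}

# ---- forward pass ---------------------------------------------------------

net_divisor <- function(config) {
  2L^(config$n_stages + config$rsu_inner_depth - 2L)
}

# leaf-node cache so every parameter becomes exactly one tape leaf
param_leaves <- function(tape, net) {
  cache <- new.env(parent = emptyenv())
  list(
    get = function(name) {
      if (is.null(cache[[name]])) {
        cache[[name]] <- leaf_node(tape, net$params[[name]])
      }
      cache[[name]]
    },
    all = function() as.list(cache)
  )
}

cbr_fwd <- function(tape, x, pl, prefix, training, upd) {
  y <- op_conv(tape, x, pl$get(paste0(prefix, ".w")), pl$get(paste0(prefix, ".b")),
               kernel = 3L)
  y <- op_bn(tape, y, pl$get(paste0(prefix, ".g")), pl$get(paste0(prefix, ".be")),
             pl$get(paste0(prefix, ".rm")), pl$get(paste0(prefix, ".rv")),
             training = training, upd = upd, name = prefix)
  op_relu(tape, y)
}

rsu_fwd <- function(tape, x, pl, prefix, L, training, upd) {
  xin <- cbr_fwd(tape, x, pl, paste0(prefix, ".in"), training, upd)
  e <- vector("list", L)
  e[[1]] <- cbr_fwd(tape, xin, pl, paste0(prefix, ".e1"), training, upd)
  if (L >= 2) {
    for (i in 2:L) {
      e[[i]] <- cbr_fwd(tape, op_maxpool2(tape, e[[i - 1]]), pl,
                        paste0(prefix, ".e", i), training, upd)
    }
  }
  bt <- cbr_fwd(tape, e[[L]], pl, paste0(prefix, ".bt"), training, upd)
  d <- cbr_fwd(tape, op_concat(tape, bt, e[[L]]), pl,
               paste0(prefix, ".d", L), training, upd)
  if (L >= 2) {
    for (i in (L - 1):1) {
      d <- cbr_fwd(tape, op_concat(tape, op_upsample2(tape, d), e[[i]]), pl,
                   paste0(prefix, ".d", i), training, upd)
    }
  }
  op_add(tape, d, xin)
}

# pad a (H,W,C,N) array with zeros to multiples of `div`
net_pad_input <- function(x, div) {
  d <- dim(x)
  H2 <- as.integer(ceiling(d[1] / div) * div)
  W2 <- as.integer(ceiling(d[2] / div) * div)
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, orig = d[1:2]))
  out <- array(0, c(H2, W2, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = out, orig = d[1:2])
}

# Full forward pass.  Returns tape, fused output node, side nodes, and the
# original spatial dims (outputs include internal padding; crop with
# `net_crop`).
net_forward <- function(tape, net, x, training = FALSE, upd = NULL) {
  config <- net$config
  S <- config$n_stages
  L <- config$rsu_inner_depth
  div <- net_divisor(config)
  if (any(dim(x)[1:2] < div)) {
    stop_shape(sprintf("input %dx%d smaller than the network stride %d",
                       dim(x)[1], dim(x)[2], div))
  }
  padded <- net_pad_input(x, div)
  dp <- dim(padded$x)
  pl <- param_leaves(tape, net)
  inp <- tape_node(tape, arr_to_mat(padded$x), H = dp[1], W = dp[2], N = dp[4])
  enc <- vector("list", S)
  cur <- inp
  for (s in seq_len(S)) {
    enc[[s]] <- rsu_fwd(tape, cur, pl, sprintf("en%d", s), L, training, upd)
    if (s < S) cur <- op_maxpool2(tape, enc[[s]])
  }
  dec_at <- list()
  dec_at[[S]] <- enc[[S]]
  if (S >= 2) {
    d <- enc[[S]]
    for (s in (S - 1):1) {
      d <- rsu_fwd(tape, op_concat(tape, op_upsample2(tape, d), enc[[s]]), pl,
                   sprintf("de%d", s), L, training, upd)
      dec_at[[s]] <- d
    }
  }
  sides <- vector("list", S)
  for (s in seq_len(S)) {
    sd <- op_conv(tape, dec_at[[s]], pl$get(sprintf("side%d.w", s)),
                  pl$get(sprintf("side%d.b", s)), kernel = 1L)
    if (s >= 2) for (k in seq_len(s - 1)) sd <- op_upsample2(tape, sd)
    sides[[s]] <- sd
  }
  cat_sides <- sides[[1]]
  if (S >= 2) {
    for (s in 2:S) cat_sides <- op_concat(tape, cat_sides, sides[[s]])
  }
  fused <- op_conv(tape, cat_sides, pl$get("fuse.w"), pl$get("fuse.b"),
                   kernel = 1L)
  # the [0, 1] clamp is the output activation; training losses attach to the
  # pre-clamp values (for targets in [0, 1] this fits the same optimum and
  # avoids dead zero-gradient pixels when an initialization saturates)
  list(
    fused = op_clamp01(tape, fused),
    sides = lapply(sides, function(s) op_clamp01(tape, s)),
    fused_raw = fused,
    sides_raw = sides,
    leaves = pl,
    orig = padded$orig,
    padded_dim = dp
  )
}

# node value (flat matrix) -> (H, W, 1, N) array cropped to the original dims
net_node_to_arr <- function(node, orig) {
  arr <- mat_to_arr(node$value, node$H, node$W, node$N)
  arr[seq_len(orig[1]), seq_len(orig[2]), , , drop = FALSE]
}

#' Predict with a trained network
#'
#' Runs the network in inference mode (batch-norm uses running statistics)
#' and returns the fused output, optionally with the per-stage side
#' outputs.  All outputs are clamped to `[0, 1]`.
#'
#' @param net a `fedasc_net`.
#' @param x input matrix (H x W) or array (H, W, 1, N).
#' @param sides also return side outputs.
#' @return matrix (or list of matrices / arrays when `sides = TRUE`).
#' @export
predict_net <- function(net, x, sides = FALSE) {
  was_mat <- is.matrix(x)
  if (was_mat) {
    dim(x) <- c(dim(x), 1L, 1L)
  }
  tape <- new_tape()
  fw <- net_forward(tape, net, x, training = FALSE)
  fused <- net_node_to_arr(fw$fused, fw$orig)
  if (!sides) {
    if (was_mat) return(fused[, , 1L, 1L]) else return(fused)
  }
  out_sides <- lapply(fw$sides, function(s) {
    v <- net_node_to_arr(s, fw$orig)
    if (was_mat) v[, , 1L, 1L] else v
  })
  list(fused = if (was_mat) fused[, , 1L, 1L] else fused, sides = out_sides)
}

#' Deep-supervision L2 loss
#'
#' Mean squared error of the fused output plus (when deep supervision is
#' enabled) the MSE of every side output, with equal weights.
#'
#' @param predictions list with `fused` and `sides` as returned by
#'   [predict_net()] with `sides = TRUE` (matrices or arrays).
#' @param target target matrix / array, same shape as the fused output.
#' @param deep_supervision include side-output terms.
#' @return scalar loss.
#' @export
net_loss <- function(predictions, target, deep_supervision = TRUE) {
  fused <- predictions$fused
  if (!all(dim(as.array(fused)) == dim(as.array(target)))) {
    stop_shape("prediction and target shapes differ")
  }
  total <- mean((fused - target)^2)
  if (deep_supervision) {
    for (s in predictions$sides) {
      if (!all(dim(as.array(s)) == dim(as.array(target)))) {
        stop_shape("side output and target shapes differ")
      }
      total <- total + mean((s - target)^2)
    }
  }
  total
}

# ---- training -------------------------------------------------------------

new_train_state <- function(net, shuffle_seed) {
  old <- get_rng_state()
  set.seed(shuffle_seed)
  rng_state <- get_rng_state()
  set_rng_state(old)
  list(
    adam = list(m = NULL, v = NULL, t = 0L),
    rng = rng_state
  )
}

# dataset: list of list(x = matrix, y = matrix) all with equal dims
stack_dataset <- function(dataset) {
  d <- dim(dataset[[1]]$x)
  n <- length(dataset)
  xs <- array(0, c(d[1], d[2], 1L, n))
  ys <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    xs[, , 1L, i] <- dataset[[i]]$x
    ys[, , 1L, i] <- dataset[[i]]$y
  }
  list(x = xs, y = ys, n = n)
}

#' Train a network for a number of epochs
#'
#' Mini-batch AdamW (Adam with decoupled weight decay) on the
#' deep-supervision L2 loss.  Fully deterministic for a fixed seed and data
#' order; the optimizer moments, step counter and shuffle RNG stream live
#' in `state`, so training can be resumed (or interleaved with federated
#' rounds) without losing determinism.
#'
#' @param net a `fedasc_net`.
#' @param dataset list of `list(x =, y =)` matrices in `[0, 1]`.
#' @param epochs number of passes; defaults to `net$config$epochs`.
#' @param state optional training state from a previous call.
#' @param lr optional learning-rate override (fine-tuning uses a scaled
#'   rate).
#' @param shuffle_seed seed for the shuffle stream when `state` is `NULL`
#'   (defaults to a child of the config seed).
#' @return list with `net`, `trace` (per-epoch mean training loss) and
#'   `state`.
#' @export
train_epochs <- function(net, dataset, epochs = NULL, state = NULL, lr = NULL,
                         shuffle_seed = NULL) {
  stopifnot(inherits(net, "fedasc_net"))
  if (length(dataset) == 0) stop_invalid("dataset is empty")
  config <- net$config
  if (is.null(epochs)) epochs <- config$epochs
  if (is.null(lr)) lr <- config$learning_rate
  if (is.null(state)) {
    if (is.null(shuffle_seed)) shuffle_seed <- child_seed(config$seed, 1L)
    state <- new_train_state(net, shuffle_seed)
  }
  if (epochs == 0L) {
    return(list(net = net, trace = numeric(0), state = state))
  }
  stacked <- stack_dataset(dataset)
  bs <- max(1L, min(config$batch_size, stacked$n))
  trainable_names <- names(net$params)[net$trainable[names(net$params)]]
  adam <- state$adam
  if (is.null(adam$m)) {
    adam$m <- lapply(net$params[trainable_names], function(p) p * 0)
    adam$v <- lapply(net$params[trainable_names], function(p) p * 0)
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)
  rng_state <- state$rng
  cosine <- identical(config$lr_schedule, "cosine")
  lr_base <- lr
  for (ep in seq_len(epochs)) {
    if (cosine) lr <- lr_base * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
    sh <- with_rng_state(rng_state, sample.int(stacked$n))
    rng_state <- sh$state
    order_idx <- sh$value
    batch_starts <- seq(1L, stacked$n, by = bs)
    losses <- numeric(length(batch_starts))
    for (bi in seq_along(batch_starts)) {
      idx <- order_idx[batch_starts[bi]:min(batch_starts[bi] + bs - 1L, stacked$n)]
      xb <- stacked$x[, , , idx, drop = FALSE]
      yb <- stacked$y[, , , idx, drop = FALSE]
      tape <- new_tape()
      upd <- new.env(parent = emptyenv())
      fw <- net_forward(tape, net, xb, training = TRUE, upd = upd)
      ypad <- arr_to_mat(net_pad_input(yb, net_divisor(config))$x)
      terms <- list(op_mse(tape, fw$fused_raw, ypad))
      if (config$deep_supervision) {
        terms <- c(terms, lapply(fw$sides_raw, function(s) op_mse(tape, s, ypad)))
      }
      loss_node <- op_sum_scalars(tape, terms)
      backprop(tape, loss_node)
      losses[bi] <- loss_node$value
      leaves <- fw$leaves$all()
      adam$t <- adam$t + 1L
      bc1 <- 1 - b1^adam$t
      bc2 <- 1 - b2^adam$t
      gscale <- 1
      if (is.finite(config$grad_clip)) {
        gnorm2 <- 0
        for (nm in trainable_names) {
          lf <- leaves[[nm]]
          if (!is.null(lf) && !is.null(lf$grad)) gnorm2 <- gnorm2 + sum(lf$grad^2)
        }
        gnorm <- sqrt(gnorm2)
        if (gnorm > config$grad_clip) gscale <- config$grad_clip / gnorm
      }
      for (nm in trainable_names) {
        lf <- leaves[[nm]]
        if (is.null(lf) || is.null(lf$grad)) next
        g <- lf$grad * gscale
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g^2
        step <- (adam$m[[nm]] / bc1) / (sqrt(adam$v[[nm]] / bc2) + eps)
        net$params[[nm]] <- net$params[[nm]] - lr * step -
          lr * config$weight_decay * net$params[[nm]]
      }
      for (nm in names(upd)) {
        net$params[[paste0(nm, ".rm")]] <- upd[[nm]]$mean
        net$params[[paste0(nm, ".rv")]] <- upd[[nm]]$var
      }
    }
    trace[ep] <- mean(losses)
  }
  state$adam <- adam
  state$rng <- rng_state
  list(net = net, trace = trace, state = state)
}
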