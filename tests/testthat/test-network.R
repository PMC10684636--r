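# Network construction, forward contract, loss, and training behaviour.

test_that("builds are deterministic and flatten/unflatten is a bijection", {
  cfg <- tiny_net_config()
  n1 <- build_network(cfg)
  n2 <- build_network(cfg)
  expect_identical(flatten_params(n1)$vector, flatten_params(n2)$vector)
  flat <- flatten_params(n1)
  n3 <- unflatten_params(n1, flat$vector)
  expect_identical(flatten_params(n3)$vector, flat$vector)
  perturbed <- flat$vector + seq_along(flat$vector) * 1e-6
  n4 <- unflatten_params(n1, perturbed)
  expect_equal(max(abs(flatten_params(n4)$vector - perturbed)), 0)
  expect_error(unflatten_params(n1, perturbed[-1]), class = "fedasc_shape_error")
})

# independent layer-by-layer count of the parameter manifest
expected_param_count <- function(S, B, L, trainable_only = FALSE) {
  M <- max(2, B %/% 2)
  per_bn <- if (trainable_only) 2 else 4 # gamma/beta (+ running mean/var)
  cbr <- function(cin, cout) 9 * cin * cout + cout + per_bn * cout
  rsu <- function(cin, cout) {
    total <- cbr(cin, cout) + cbr(cout, M) # in + e1
    if (L >= 2) total <- total + (L - 1) * cbr(M, M) # e2..eL
    total <- total + cbr(M, M) # bottom
    total <- total + sum(vapply(seq_len(L), function(i) {
      cbr(2 * M, if (i == 1) cout else M)
    }, numeric(1)))
    total
  }
  total <- rsu(1, B) + (S - 1) * rsu(B, B) # encoders
  if (S >= 2) total <- total + (S - 1) * rsu(2 * B, B) # decoders
  total <- total + S * (B + 1) # side heads
  total + S + 1 # fusion head
}

test_that("parameter counts match an independent arithmetic oracle", {
  for (cfg in list(tiny_net_config(),
                   network_config(n_stages = 1, base_channels = 2,
                                  rsu_inner_depth = 1),
                   network_config(n_stages = 3, base_channels = 4,
                                  rsu_inner_depth = 2))) {
    net <- build_network(cfg)
    expect_equal(count_parameters(net),
                 expected_param_count(cfg$n_stages, cfg$base_channels,
                                      cfg$rsu_inner_depth))
    expect_equal(count_parameters(net, trainable_only = TRUE),
                 expected_param_count(cfg$n_stages, cfg$base_channels,
                                      cfg$rsu_inner_depth, TRUE))
  }
})

test_that("forward pass produces a fused output and one side per stage, all in [0, 1]", {
  net <- build_network(tiny_net_config())
  x <- matrix(runif(40 * 24), 40, 24)
  out <- predict_net(net, x, sides = TRUE)
  expect_equal(dim(out$fused), c(40, 24))
  expect_length(out$sides, 2)
  for (s in out$sides) expect_equal(dim(s), c(40, 24))
  vals <- c(out$fused, unlist(out$sides))
  expect_true(all(vals >= 0 & vals <= 1))
  # odd sizes are padded internally and cropped back
  x_odd <- matrix(runif(33 * 21), 33, 21)
  expect_equal(dim(predict_net(net, x_odd)), c(33, 21))
  expect_error(predict_net(net, matrix(0, 1, 1)), class = "fedasc_shape_error")
})

test_that("deep-supervision loss has its closed form", {
  target <- matrix(runif(12 * 12), 12)
  preds <- list(fused = target, sides = list(target, target))
  expect_equal(net_loss(preds, target), 0)
  delta <- 0.07
  off <- list(fused = target + delta,
              sides = list(target + delta, target + delta))
  expect_equal(net_loss(off, target), 3 * delta^2, tolerance = 1e-12)
  expect_equal(net_loss(off, target, deep_supervision = FALSE), delta^2,
               tolerance = 1e-12)
  expect_error(net_loss(list(fused = matrix(0, 2, 2), sides = list()), target),
               class = "fedasc_shape_error")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_net_config(seed = 8)
  net <- build_network(cfg)
  set.seed(21)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  y <- fedasc:::arr_to_mat(array(runif(16 * 16), c(16, 16, 1, 1)))
  loss_at <- function(vec) {
    n <- unflatten_params(net, vec)
    tape <- fedasc:::new_tape()
    fw <- fedasc:::net_forward(tape, n, x, training = TRUE)
    terms <- c(list(fedasc:::op_mse(tape, fw$fused_raw, y)),
               lapply(fw$sides_raw, function(s) fedasc:::op_mse(tape, s, y)))
    fedasc:::op_sum_scalars(tape, terms)$value
  }
  flat <- flatten_params(net)
  tape <- fedasc:::new_tape()
  fw <- fedasc:::net_forward(tape, net, x, training = TRUE)
  terms <- c(list(fedasc:::op_mse(tape, fw$fused_raw, y)),
             lapply(fw$sides_raw, function(s) fedasc:::op_mse(tape, s, y)))
  ln <- fedasc:::op_sum_scalars(tape, terms)
  fedasc:::backprop(tape, ln)
  leaves <- fw$leaves$all()
  grads <- unlist(lapply(names(net$params), function(nm) {
    lf <- leaves[[nm]]
    g <- if (!is.null(lf) && !is.null(lf$grad)) lf$grad else net$params[[nm]] * 0
    as.numeric(g)
  }))
  idx <- sample(which(flat$trainable_mask & abs(grads) > 1e-7), 12)
  for (i in idx) {
    v1 <- flat$vector; v1[i] <- v1[i] + 1e-5
    v2 <- flat$vector; v2[i] <- v2[i] - 1e-5
    fd <- (loss_at(v1) - loss_at(v2)) / 2e-5
    expect_equal(grads[i], fd, tolerance = 1e-4)
  }
})

test_that("training is deterministic, resumable and respects zero epochs", {
  cfg <- tiny_net_config(seed = 4)
  ds <- toy_dataset(n = 3)
  f1 <- train_epochs(build_network(cfg), ds, epochs = 3)
  f2 <- train_epochs(build_network(cfg), ds, epochs = 3)
  expect_identical(f1$trace, f2$trace)
  expect_identical(flatten_params(f1$net)$vector, flatten_params(f2$net)$vector)
  f0 <- train_epochs(build_network(cfg), ds, epochs = 0)
  expect_identical(flatten_params(f0$net)$vector,
                   flatten_params(build_network(cfg))$vector)
  expect_error(train_epochs(build_network(cfg), list()),
               class = "fedasc_invalid_argument")
  # chunked training with threaded state equals one continuous run
  fa <- train_epochs(build_network(cfg), ds, epochs = 2)
  fb <- train_epochs(fa$net, ds, epochs = 2, state = fa$state)
  fc <- train_epochs(build_network(cfg), ds, epochs = 4)
  expect_identical(flatten_params(fb$net)$vector, flatten_params(fc$net)$vector)
  expect_identical(c(fa$trace, fb$trace), fc$trace)
})

test_that("a single pair is memorized (loss collapses)", {
  cfg <- network_config(n_stages = 2, base_channels = 4, rsu_inner_depth = 1,
                        batch_size = 1, learning_rate = 0.02, seed = 5)
  ds <- toy_dataset(n = 1)
  fit <- train_epochs(build_network(cfg), ds, epochs = 50)
  expect_true(all(diff(fit$trace[1:10]) < 0))
  expect_lt(fit$trace[50], 0.1 * fit$trace[1])
})

test_that("training behaviour is unchanged when input and target shift together", {
  cfg <- network_config(n_stages = 2, base_channels = 4, rsu_inner_depth = 1,
                        batch_size = 1, learning_rate = 0.02, seed = 5)
  base <- toy_dataset(n = 1)[[1]]
  pad <- function(m) {
    out <- matrix(0, 24, 24)
    out[5:20, 5:20] <- m[1:16, 1:16]
    out
  }
  orig <- list(list(x = base$x, y = base$y))
  shifted <- list(list(x = pad(base$x), y = pad(base$y)))
  f1 <- train_epochs(build_network(cfg), orig, epochs = 25)
  f2 <- train_epochs(build_network(cfg), shifted, epochs = 25)
  # no coordinate leakage: both memorize comparably
  expect_lt(f1$trace[25], 0.35 * f1$trace[1])
  expect_lt(f2$trace[25], 0.35 * f2$trace[1])
})

test_that("checkpoints round-trip through disk", {
  net <- build_network(tiny_net_config(seed = 12))
  prefix <- file.path(withr::local_tempdir(), "ckpt")
  save_network(net, prefix)
  rt <- load_network(prefix)
  expect_identical(flatten_params(rt)$vector, flatten_params(net)$vector)
  expect_equal(rt$config, net$config)
  expect_error(load_network(file.path(tempdir(), "nope")),
               class = "fedasc_io_error")
})
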