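# Learning scenarios, DP mechanism and the Gaussian-DP accountant.

test_that("clip_update enforces the L2 bound exactly", {
  v <- c(3, 4) # norm 5
  expect_identical(clip_update(v, 10), v)
  clipped <- clip_update(v, 2.5)
  expect_equal(sqrt(sum(clipped^2)), 2.5, tolerance = 1e-12)
  # non-trainable entries pass through
  mask <- c(TRUE, TRUE, FALSE)
  out <- clip_update(c(3, 4, 100), 2.5, mask)
  expect_equal(out[3], 100)
  expect_equal(sqrt(sum(out[1:2]^2)), 2.5, tolerance = 1e-12)
  expect_error(clip_update(v, 0), class = "fedasc_invalid_argument")
})

test_that("clip_update norm bound holds over random draws (property)", {
  set.seed(30)
  for (i in 1:1000) {
    v <- rnorm(20, sd = runif(1, 0.1, 10))
    cc <- runif(1, 0.1, 5)
    expect_lte(sqrt(sum(clip_update(v, cc)^2)), cc + 1e-9)
  }
})

test_that("dp_aggregate is exact without noise and validates weights", {
  u <- list(c(1, 2, 3), c(4, 5, 6))
  dp_off <- dp_config(enabled = FALSE)
  expect_equal(dp_aggregate(u, c(0.5, 0.5), dp_off), c(2.5, 3.5, 4.5))
  expect_equal(dp_aggregate(u, c(1, 0), dp_config(clip_norm = 100,
                                                  noise_multiplier = 0)),
               u[[1]])
  same <- list(c(0.3, 0.4), c(0.3, 0.4))
  agg <- dp_aggregate(same, c(0.5, 0.5),
                      dp_config(clip_norm = 10, noise_multiplier = 0))
  expect_equal(agg, c(0.3, 0.4))
  expect_error(dp_aggregate(u, c(0.7, 0.7), dp_off),
               class = "fedasc_invalid_argument")
  expect_error(dp_aggregate(list(), numeric(0), dp_off),
               class = "fedasc_invalid_argument")
})

test_that("server noise SD matches z * C * max(w) empirically", {
  set.seed(31)
  dp <- dp_config(clip_norm = 0.8, noise_multiplier = 1.5)
  w <- c(0.7, 0.3)
  u <- list(rep(0, 50), rep(0, 50))
  draws <- vapply(1:2000, function(i) dp_aggregate(u, w, dp), numeric(50))
  sd_emp <- sqrt(mean(apply(draws, 1, stats::var)))
  expect_lt(abs(sd_emp - 1.5 * 0.8 * 0.7) / (1.5 * 0.8 * 0.7), 0.05)
})

test_that("mu-GDP conversion matches the normal-CDF oracle and is monotone", {
  # independent oracle: numerically integrate the standard normal density
  phi_int <- function(z) {
    0.5 + stats::integrate(stats::dnorm, 0, z)$value * sign(1)
  }
  oracle <- phi_int(0.5) - phi_int(-0.5)
  expect_equal(gdp_to_eps_delta(1, 0), oracle, tolerance = 1e-9)
  expect_equal(gdp_to_eps_delta(1, 0), 0.3829249, tolerance = 1e-6)
  eps <- seq(0, 6, by = 0.25)
  d <- gdp_to_eps_delta(1.3, eps)
  expect_true(all(diff(d) < 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_lt(gdp_to_eps_delta(1e-6, 1), 1e-8)
  expect_error(gdp_to_eps_delta(0, 1), class = "fedasc_invalid_argument")
})

test_that("privacy composition is root-sum-square and DP-off is explicit", {
  sp <- privacy_spend(rep(0.5, 4))
  expect_equal(sp$mu_total, 1.0)
  expect_equal(unname(sp$delta["eps_0.5"]), gdp_to_eps_delta(1, 0.5))
  off <- privacy_spend(numeric(0), guaranteed = FALSE)
  expect_false(off$guaranteed)
  expect_true(is.na(off$mu_total))
  g <- glance(off)
  expect_false(g$guaranteed)
})

test_that("centre-based training is independent and seed-deterministic", {
  cfg <- tiny_net_config(seed = 6)
  ds <- toy_dataset(n = 4)
  same <- train_ceba(list(a = ds, b = ds), cfg, epochs = 2)
  expect_identical(flatten_params(same$a$net)$vector,
                   flatten_params(same$b$net)$vector)
  other <- toy_dataset(n = 4, seed = 99)
  diff_ds <- train_ceba(list(a = ds, b = other), cfg, epochs = 2)
  expect_false(identical(flatten_params(diff_ds$a$net)$vector,
                         flatten_params(diff_ds$b$net)$vector))
  expect_error(train_ceba(list(a = list()), cfg),
               class = "fedasc_invalid_argument")
})

test_that("centralized training on one centre equals centre-based training", {
  cfg <- tiny_net_config(seed = 7)
  ds <- toy_dataset(n = 4)
  ceba <- train_ceba(list(a = ds), cfg, epochs = 3)
  ceze <- train_ceze(list(a = ds), cfg, epochs = 3)
  expect_identical(flatten_params(ceba$a$net)$vector,
                   flatten_params(ceze$net)$vector)
  expect_identical(ceba$a$trace, ceze$trace)
  expect_length(ceze$trace, 3)
})

test_that("one client with DP off reproduces centralized training bit for bit", {
  cfg <- tiny_net_config(seed = 9)
  ds <- toy_dataset(n = 5)
  cent <- train_ceze(list(a = ds), cfg, epochs = 4)
  fed <- run_federated_rounds(list(a = ds), cfg,
                              fl_config(n_rounds = 2, local_epochs = 2, seed = 1),
                              dp_config(enabled = FALSE))
  expect_identical(flatten_params(fed$net)$vector,
                   flatten_params(cent$net)$vector)
  expect_false(fed$spend$guaranteed)
  expect_equal(nrow(fed$round_log), 2)
})

test_that("federated rounds record per-round privacy cost mu = 1/z", {
  cfg <- tiny_net_config(seed = 10)
  ds <- toy_dataset(n = 2)
  fed <- run_federated_rounds(
    list(a = ds, b = ds), cfg,
    fl_config(n_rounds = 4, local_epochs = 1, seed = 3),
    dp_config(clip_norm = 0.5, noise_multiplier = 2)
  )
  expect_equal(fed$spend$mu_per_round, rep(0.5, 4))
  expect_equal(fed$spend$mu_total, 1.0) # sqrt(4) / 2
  expect_true(all(c("round_idx", "centre", "local_loss",
                    "update_norm_pre_clip", "clipped_flag") %in%
                    names(fed$round_log)))
  expect_equal(nrow(fed$round_log), 8)
})

test_that("huge noise yields a vanishing privacy cost and a noise-dominated model", {
  cfg <- tiny_net_config(seed = 13)
  ds <- toy_dataset(n = 2)
  fed <- run_federated_rounds(
    list(a = ds), cfg, fl_config(n_rounds = 1, local_epochs = 1, seed = 3),
    dp_config(clip_norm = 0.1, noise_multiplier = 1e4)
  )
  expect_equal(fed$spend$mu_total, 1e-4)
  theta0 <- flatten_params(build_network(cfg))
  theta1 <- flatten_params(fed$net)
  move <- abs(theta1$vector - theta0$vector)[theta0$trainable_mask]
  # the movement is almost entirely server noise (SD = z * C = 1e3)
  expect_gt(stats::median(move), 100)
})

test_that("fine-tuning starts from the global model and never worsens it", {
  cfg <- tiny_net_config(seed = 14)
  ds <- toy_dataset(n = 4)
  global <- train_ceze(list(a = ds), cfg, epochs = 1)$net
  same <- fine_tune(global, ds, fl = fl_config(fine_tune_epochs = 0))
  expect_identical(flatten_params(same$net)$vector,
                   flatten_params(global)$vector)
  for (s in 1:3) {
    ft <- fine_tune(global, ds, val_set = ds,
                    fl = fl_config(fine_tune_epochs = 2, seed = s))
    expect_lte(fedasc:::eval_loss(ft$net, ds),
               fedasc:::eval_loss(global, ds) + 1e-12)
  }
  # with a learning rate that actually moves the toy loss and enough epochs
  # for the batch-norm running statistics to settle (eval-mode validation
  # loss lags the training loss until they do), fine-tuning on different
  # centres yields distinct personalized models
  cfg_hot <- tiny_net_config(seed = 14, learning_rate = 0.02)
  global_hot <- train_ceze(list(a = ds), cfg_hot, epochs = 1)$net
  other <- toy_dataset(n = 4, seed = 55)
  fl_hot <- fl_config(fine_tune_epochs = 15, fine_tune_lr_scale = 1)
  ft_a <- fine_tune(global_hot, ds, fl = fl_hot)
  ft_b <- fine_tune(global_hot, other, fl = fl_hot)
  expect_false(identical(flatten_params(ft_a$net)$vector,
                         flatten_params(ft_b$net)$vector))
  expect_error(fine_tune(global, list()), class = "fedasc_invalid_argument")
})
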