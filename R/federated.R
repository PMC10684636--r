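# Learning scenarios: centre-based (CeBa), centralized (CeZe) and
# differentially private federated transfer learning (DP-FedAvg rounds plus
# per-centre fine-tuning), with a Gaussian differential privacy accountant.

#' Federated-learning configuration
#'
#' @param n_rounds number of federated rounds (>= 1).
#' @param local_epochs local epochs per round (>= 1).
#' @param client_weighting `"by_n"` (weights proportional to the local
#'   training-set size; weighted federated averaging) or `"uniform"`.
#' @param fine_tune_epochs per-centre fine-tuning epochs after the global
#'   model is built.
#' @param fine_tune_lr_scale learning-rate multiplier during fine-tuning
#'   (default 0.1).
#' @param seed seed for the server noise stream.
#' @return an `fl_config`.
#' @export
fl_config <- function(n_rounds = 10L, local_epochs = 1L,
                      client_weighting = c("by_n", "uniform"),
                      fine_tune_epochs = 5L, fine_tune_lr_scale = 0.1,
                      seed = 0L) {
  if (n_rounds < 1) stop_invalid("n_rounds must be >= 1")
  if (local_epochs < 1) stop_invalid("local_epochs must be >= 1")
  structure(list(
    n_rounds = as.integer(n_rounds),
    local_epochs = as.integer(local_epochs),
    client_weighting = match.arg(client_weighting),
    fine_tune_epochs = as.integer(fine_tune_epochs),
    fine_tune_lr_scale = fine_tune_lr_scale,
    seed = as.integer(seed)
  ), class = "fl_config")
}

#' Differential-privacy configuration
#'
#' @param clip_norm L2 clipping bound `C` applied to each client's
#'   trainable-parameter update.
#' @param noise_multiplier `z`; the server adds Gaussian noise with SD
#'   `z * C * max(w_k)` per trainable coordinate.
#' @param enabled with `FALSE`, aggregation is exact weighted averaging and
#'   the accountant reports an explicit "no guarantee" spend.
#' @return a `dp_config`.
#' @export
dp_config <- function(clip_norm = 1.0, noise_multiplier = 1.0, enabled = TRUE) {
  if (clip_norm <= 0) stop_invalid("clip_norm must be > 0")
  if (noise_multiplier < 0) stop_invalid("noise_multiplier must be >= 0")
  structure(list(clip_norm = clip_norm, noise_multiplier = noise_multiplier,
                 enabled = isTRUE(enabled)), class = "dp_config")
}

#' Clip a parameter update to an L2 bound
#'
#' Scales the trainable entries of `delta` by `min(1, C / ||delta||_2)`
#' (norm over trainable entries only); non-trainable entries (batch-norm
#' running statistics) pass through unchanged.
#'
#' @param delta numeric update vector.
#' @param clip_norm bound `C > 0`.
#' @param trainable_mask logical vector; defaults to all `TRUE`.
#' @return clipped vector.
#' @export
clip_update <- function(delta, clip_norm, trainable_mask = NULL) {
  if (clip_norm <= 0) stop_invalid("clip_norm must be > 0")
  if (is.null(trainable_mask)) trainable_mask <- rep(TRUE, length(delta))
  nrm <- sqrt(sum(delta[trainable_mask]^2))
  if (nrm > clip_norm) {
    delta[trainable_mask] <- delta[trainable_mask] * (clip_norm / nrm)
  }
  delta
}

#' Differentially private server aggregation
#'
#' With DP enabled, each client update is L2-clipped and the weighted sum is
#' perturbed per trainable coordinate with Gaussian noise of SD
#' `z * C * max(w_k)` (calibrated to replace-one-client sensitivity
#' `max(w_k) * C`).  Non-trainable entries are averaged without clipping or
#' noise.  With DP disabled the weighted sum is returned exactly.
#'
#' @param updates list of equal-length update vectors.
#' @param weights client weights summing to 1.
#' @param dp a [dp_config()].
#' @param trainable_mask logical mask over vector entries.
#' @return aggregated update vector.
#' @export
dp_aggregate <- function(updates, weights, dp, trainable_mask = NULL) {
  if (length(updates) < 1) stop_invalid("need at least one update")
  if (abs(sum(weights) - 1) > 1e-9) stop_invalid("weights must sum to 1")
  if (length(weights) != length(updates)) {
    stop_invalid("one weight per update is required")
  }
  if (is.null(trainable_mask)) trainable_mask <- rep(TRUE, length(updates[[1]]))
  if (!dp$enabled) {
    out <- updates[[1]] * weights[1]
    for (k in seq_along(updates)[-1]) out <- out + weights[k] * updates[[k]]
    return(out)
  }
  clipped <- lapply(updates, clip_update, clip_norm = dp$clip_norm,
                    trainable_mask = trainable_mask)
  out <- clipped[[1]] * weights[1]
  for (k in seq_along(clipped)[-1]) out <- out + weights[k] * clipped[[k]]
  if (dp$noise_multiplier > 0) {
    sdv <- dp$noise_multiplier * dp$clip_norm * max(weights)
    noise <- rnorm(sum(trainable_mask), 0, sdv)
    out[trainable_mask] <- out[trainable_mask] + noise
  }
  out
}

#' Convert a mu-GDP guarantee to (epsilon, delta)
#'
#' `delta(eps) = Phi(-eps/mu + mu/2) - exp(eps) * Phi(-eps/mu - mu/2)` with
#' `Phi` the standard normal CDF.
#'
#' @param mu Gaussian-DP parameter (> 0).
#' @param eps privacy parameter epsilon (vectorized).
#' @return delta values in `[0, 1]`.
#' @export
gdp_to_eps_delta <- function(mu, eps) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop_invalid("mu must be a single positive number")
  }
  pnorm(-eps / mu + mu / 2) - exp(eps) * pnorm(-eps / mu - mu / 2)
}

#' Privacy spend of a federated run
#'
#' Collects per-round mu-GDP costs; composition is root-sum-square.  When DP
#' was disabled (or the noise multiplier was zero) the object reports an
#' explicit absence of any guarantee rather than a numeric mu.
#'
#' @param mu_per_round numeric vector of per-round mu values.
#' @param guaranteed whether a guarantee exists.
#' @param eps_grid epsilons at which reference deltas are reported.
#' @return a `privacy_spend`.
#' @export
privacy_spend <- function(mu_per_round, guaranteed = TRUE,
                          eps_grid = c(0.5, 1, 2, 4, 8)) {
  total <- if (guaranteed) sqrt(sum(mu_per_round^2)) else NA_real_
  structure(list(
    mu_per_round = mu_per_round,
    mu_total = total,
    guaranteed = guaranteed,
    eps_grid = eps_grid,
    delta = if (guaranteed && length(mu_per_round)) {
      stats::setNames(gdp_to_eps_delta(total, eps_grid),
                      paste0("eps_", eps_grid))
    } else {
      NULL
    }
  ), class = "privacy_spend")
}

#' @export
print.privacy_spend <- function(x, ...) {
  if (!x$guaranteed) {
    cat("<privacy_spend: differential privacy disabled - no guarantee>\n")
  } else {
    cat(sprintf("<privacy_spend: mu = %.4f over %d rounds>\n",
                x$mu_total, length(x$mu_per_round)))
    if (!is.null(x$delta)) print(round(x$delta, 6))
  }
  invisible(x)
}

# evaluation-mode mean L2 loss of the fused output over a dataset
eval_loss <- function(net, dataset) {
  mean(vapply(dataset, function(d) mean((predict_net(net, d$x) - d$y)^2),
              numeric(1)))
}

#' Centre-based training (CeBa)
#'
#' Each centre trains its own model from a fresh seeded initialization on
#' its local data only; nothing crosses centres.
#'
#' @param datasets named list (per centre) of training sets, each a list of
#'   `list(x =, y =)` pairs.
#' @param config a [network_config()].
#' @param epochs epochs per centre (defaults to `config$epochs`).
#' @return named list of `list(net, trace)` per centre.
#' @export
train_ceba <- function(datasets, config, epochs = NULL) {
  if (!length(datasets) || any(!vapply(datasets, length, 1L))) {
    stop_invalid("every centre needs a nonempty training set")
  }
  purrr::map(datasets, function(ds) {
    fit <- train_epochs(build_network(config), ds, epochs = epochs)
    list(net = fit$net, trace = fit$trace)
  })
}

#' Centralized training (CeZe)
#'
#' Pools every centre's training set at a (virtual) core site and trains a
#' single model.
#'
#' @inheritParams train_ceba
#' @return `list(net, trace)`.
#' @export
train_ceze <- function(datasets, config, epochs = NULL) {
  pooled <- purrr::flatten(unname(datasets))
  if (!length(pooled)) stop_invalid("pooled training set is empty")
  fit <- train_epochs(build_network(config), pooled, epochs = epochs)
  list(net = fit$net, trace = fit$trace)
}

#' Differentially private federated rounds (DP-FedAvg)
#'
#' Round `r`: the server broadcasts the global parameters, every centre runs
#' `local_epochs` of local training (keeping its own optimizer moments and
#' shuffle stream between rounds), updates are clipped and aggregated with
#' the Gaussian mechanism, and the global model moves by the aggregate.
#' With DP disabled the new global parameters are the exact weighted average
#' of the client parameters.  When DP is enabled with `z > 0`, each round
#' costs `mu = 1/z` (replace-one-client sensitivity `max_k w_k * C` against
#' noise SD `z * C * max_k w_k`); rounds compose by root-sum-square.
#'
#' @param datasets named list (per centre) of training sets.
#' @param config a [network_config()].
#' @param fl an [fl_config()].
#' @param dp a [dp_config()].
#' @return list with `net` (global model), `spend` (a [privacy_spend()]),
#'   `round_log` (tibble) and `client_states`.
#' @export
run_federated_rounds <- function(datasets, config, fl, dp = dp_config(enabled = FALSE)) {
  if (!length(datasets)) stop_invalid("need at least one centre")
  if (any(!vapply(datasets, length, 1L))) {
    stop_invalid("every centre needs a nonempty training set")
  }
  k <- length(datasets)
  n_k <- vapply(datasets, length, integer(1))
  weights <- if (fl$client_weighting == "by_n") n_k / sum(n_k) else rep(1 / k, k)
  global <- build_network(config)
  flat0 <- flatten_params(global)
  mask <- flat0$trainable_mask
  states <- purrr::imap(datasets, function(ds, nm) NULL)
  client_idx <- seq_len(k)
  noise_rng <- {
    old <- get_rng_state()
    set.seed(child_seed(fl$seed, 424242L))
    st <- get_rng_state()
    set_rng_state(old)
    st
  }
  log_rows <- list()
  mu_round <- numeric(0)
  for (r in seq_len(fl$n_rounds)) {
    theta <- flatten_params(global)$vector
    client_vecs <- vector("list", k)
    for (ci in client_idx) {
      local_net <- unflatten_params(global, theta)
      if (is.null(states[[ci]])) {
        states[[ci]] <- new_train_state(local_net, child_seed(config$seed, ci))
      }
      fit <- train_epochs(local_net, datasets[[ci]], epochs = fl$local_epochs,
                          state = states[[ci]])
      states[[ci]] <- fit$state
      client_vecs[[ci]] <- flatten_params(fit$net)$vector
      delta_norm <- sqrt(sum((client_vecs[[ci]] - theta)[mask]^2))
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        round_idx = r, centre = names(datasets)[ci],
        local_loss = fit$trace[length(fit$trace)],
        update_norm_pre_clip = delta_norm,
        clipped_flag = dp$enabled && delta_norm > dp$clip_norm
      )
    }
    if (dp$enabled) {
      deltas <- lapply(client_vecs, function(v) v - theta)
      agg <- with_rng_state(noise_rng,
                            dp_aggregate(deltas, weights, dp, mask))
      noise_rng <- agg$state
      theta_new <- theta + agg$value
      if (dp$noise_multiplier > 0) {
        mu_round <- c(mu_round, 1 / dp$noise_multiplier)
      }
    } else {
      # exact weighted parameter average (bitwise-faithful FedAvg)
      theta_new <- client_vecs[[1]] * weights[1]
      if (k >= 2) {
        for (ci in 2:k) theta_new <- theta_new + weights[ci] * client_vecs[[ci]]
      }
    }
    global <- unflatten_params(global, theta_new)
  }
  guaranteed <- dp$enabled && dp$noise_multiplier > 0
  spend <- privacy_spend(if (guaranteed) mu_round else numeric(0),
                         guaranteed = guaranteed)
  list(net = global, spend = spend,
       round_log = dplyr::bind_rows(log_rows), client_states = states)
}

#' Per-centre fine-tuning of a global model (the transfer step of FTL)
#'
#' Continues training from the global parameters on one centre's data at
#' `fine_tune_lr_scale` times the base learning rate, and returns the
#' checkpoint with the lowest validation loss (the state after any whole
#' epoch, including the starting model).
#'
#' @param global_net the global `fedasc_net`.
#' @param train_set centre training pairs.
#' @param val_set validation pairs used for best-epoch selection (falls
#'   back to `train_set` when empty).
#' @param fl an [fl_config()].
#' @return `list(net, trace, val_trace, best_epoch)`.
#' @export
fine_tune <- function(global_net, train_set, val_set = NULL, fl = fl_config()) {
  if (!length(train_set)) stop_invalid("centre training split is empty")
  if (fl$fine_tune_epochs == 0L) {
    return(list(net = global_net, trace = numeric(0), val_trace = numeric(0),
                best_epoch = 0L))
  }
  if (is.null(val_set) || !length(val_set)) val_set <- train_set
  lr <- global_net$config$learning_rate * fl$fine_tune_lr_scale
  best_net <- global_net
  best_val <- eval_loss(global_net, val_set)
  val_trace <- numeric(fl$fine_tune_epochs)
  trace <- numeric(fl$fine_tune_epochs)
  state <- NULL
  net <- global_net
  best_epoch <- 0L
  for (ep in seq_len(fl$fine_tune_epochs)) {
    fit <- train_epochs(net, train_set, epochs = 1L, state = state, lr = lr,
                        shuffle_seed = child_seed(fl$seed, 77L))
    net <- fit$net
    state <- fit$state
    trace[ep] <- fit$trace
    val_trace[ep] <- eval_loss(net, val_set)
    if (val_trace[ep] < best_val) {
      best_val <- val_trace[ep]
      best_net <- net
      best_epoch <- ep
    }
  }
  list(net = best_net, trace = trace, val_trace = val_trace,
       best_epoch = best_epoch)
}

#' Full federated transfer learning scenario
#'
#' DP-FedAvg rounds to build a global model, then per-centre fine-tuning to
#' produce personalized models.
#'
#' @param datasets named list (per centre) of training sets.
#' @param val_sets optional named list of validation sets per centre.
#' @param config a [network_config()].
#' @param fl an [fl_config()].
#' @param dp a [dp_config()].
#' @return list with `global`, `personalized` (named list of nets), `spend`,
#'   `round_log`.
#' @export
train_ftl <- function(datasets, val_sets = NULL, config = network_config(),
                      fl = fl_config(), dp = dp_config(enabled = FALSE)) {
  fed <- run_federated_rounds(datasets, config, fl, dp)
  personalized <- purrr::imap(datasets, function(ds, nm) {
    fine_tune(fed$net, ds, val_sets[[nm]], fl)$net
  })
  list(global = fed$net, personalized = personalized, spend = fed$spend,
       round_log = fed$round_log)
}
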