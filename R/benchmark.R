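# Canonical desk-scale study designs: the three-centre scenario comparison
# (CeBa vs DP federated transfer learning) and the halo disentanglement
# experiment.  Both are pure functions of their seeds; the methods vignette
# discusses the problem sizes.

#' Default profiles for the heterogeneous three-centre study
#'
#' Three 64-pixel centres with distinct blur, noise and tracer, emulating
#' cross-centre scanner heterogeneity at desk scale.
#'
#' @param n_clean clean patients per centre (default 20).
#' @param n_artefact artefact patients per centre.
#' @param seed profile seed.
#' @return list of `centre_profile`.
#' @export
benchmark_profiles <- function(n_clean = 20L, n_artefact = 0L, seed = 0L) {
  make_centre_profiles(
    3, seed = seed, n_clean = n_clean, n_artefact = n_artefact,
    matrix_size = 64,
    tracer = c("PSMA", "PSMA", "DOTATATE"),
    psf_fwhm = c(1.4, 2.2, 2.8),
    noise_scale = c(0.02, 0.05, 0.03)
  )
}

# preprocess a cohort and carve it into per-centre train/val/test lists
prepare_benchmark_data <- function(cohort, seed, target = c(64L, 48L)) {
  pp <- preprocess_cohort(cohort, target = target)
  split <- split_cohort(cohort$manifest, seed = seed)
  pick <- function(sub) {
    d <- split[split$subset == sub, ]
    by_c <- base::split(d$patient_id, d$centre_id)
    purrr::map(by_c, function(pids) purrr::map(pids, function(p) pp[[p]]))
  }
  list(train = pick("train"), validation = pick("validation"),
       test = pick("test"), all = pp, split = split)
}

#' Three-centre scenario comparison (CeBa vs FTL)
#'
#' For each seed: generate a fresh heterogeneous three-centre cohort
#' (64 x 48 after preprocessing), train per-centre models (CeBa) and the
#' differentially private federated transfer scenario (global DP-FedAvg
#' rounds + per-centre fine-tuning), and measure per-patient test MAE.
#' Training budgets are matched: CeBa trains for as many local epochs as
#' FTL spends in federated rounds plus fine-tuning.
#'
#' @param seeds integer vector of study replicate seeds.
#' @param n_clean clean patients per centre.
#' @param n_rounds,fine_tune_epochs FTL budget (CeBa gets the sum).
#' @param net_template a function `seed -> network_config` for the tiny
#'   regressor.
#' @param dp a [dp_config()]; default mild Gaussian DP.
#' @param progress emit progress messages.
#' @return tibble with seed, scenario, centre_id, patient_id, mae
#'   (normalized domain) plus attribute `spends` (per-seed privacy spends).
#' @export
scenario_benchmark <- function(seeds = 1:5, n_clean = 20L, n_rounds = 15L,
                               fine_tune_epochs = 5L,
                               net_template = benchmark_net_config,
                               dp = dp_config(clip_norm = 1.5,
                                              noise_multiplier = 0.005),
                               progress = FALSE) {
  rows <- list()
  spends <- list()
  for (s in seeds) {
    if (progress) message(sprintf("scenario benchmark: seed %d", s))
    profiles <- benchmark_profiles(n_clean = n_clean, seed = s)
    cohort <- generate_cohort(profiles, seed = s)
    data <- prepare_benchmark_data(cohort, seed = s)
    cfg <- net_template(s)
    budget <- n_rounds + fine_tune_epochs
    ceba <- train_ceba(data$train, cfg, epochs = budget)
    fl <- fl_config(n_rounds = n_rounds, local_epochs = 1L,
                    fine_tune_epochs = fine_tune_epochs,
                    fine_tune_lr_scale = 0.3, seed = s)
    ftl <- train_ftl(data$train, data$validation, cfg, fl, dp)
    spends[[as.character(s)]] <- ftl$spend
    models <- list(
      ceba = purrr::map(ceba, "net"),
      ftl = ftl$personalized
    )
    for (scen in names(models)) {
      for (cid in names(data$test)) {
        net <- models[[scen]][[cid]]
        for (p in data$test[[cid]]) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            seed = s, scenario = scen, centre_id = cid,
            patient_id = p$patient_id,
            mae = mean(abs(predict_net(net, p$x)[p$mask] - p$y[p$mask]))
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "spends") <- spends
  out
}

#' Default tiny network for the desk-scale benchmarks
#' @param seed initialization / shuffle seed.
#' @return a [network_config()].
#' @export
benchmark_net_config <- function(seed = 0L) {
  network_config(
    n_stages = 2L, base_channels = 8L, rsu_inner_depth = 2L,
    batch_size = 4L, learning_rate = 0.008, lr_schedule = "constant",
    seed = seed
  )
}

#' Halo disentanglement experiment
#'
#' Trains a model on one centre's clean pairs only and applies it to
#' halo-injected patients of the same centre.  Because the halo lives in
#' the corrected image while the network input is the uncorrected one, a
#' well-trained direct-correction model reproduces the clean reference and
#' the artefact is disentangled.  The per-phantom error reduction is
#' `1 - MAE(model, clean) / MAE(artefacted, clean)` inside the halo annulus.
#'
#' @param seed study seed.
#' @param n_clean clean training patients.
#' @param n_halo halo-injected evaluation patients.
#' @param epochs training epochs.
#' @param net_template function `seed -> network_config`.
#' @return tibble with one row per halo phantom (patient_id, mae_model,
#'   mae_artefact, reduction) plus attribute `net`.
#' @export
halo_benchmark <- function(seed = 7L, n_clean = 20L, n_halo = 12L,
                           epochs = 100L,
                           net_template = benchmark_net_config) {
  prof <- make_centre_profiles(1, seed = seed, matrix_size = 64,
                               n_clean = n_clean, n_artefact = n_halo,
                               psf_fwhm = 1.6, noise_scale = 0.02)
  cohort <- generate_cohort(prof, seed = seed, artefact_type = "halo")
  pp <- preprocess_cohort(cohort, target = c(64L, 48L))
  man <- cohort$manifest
  clean_ids <- unique(man$patient_id[man$artefact_labels == ""])
  halo_ids <- unique(man$patient_id[man$artefact_labels == "halo"])
  n_train <- floor(0.8 * length(clean_ids))
  train <- purrr::map(clean_ids[seq_len(n_train)], function(p) pp[[p]])
  fit <- train_epochs(build_network(net_template(seed)), train,
                      epochs = epochs)
  rows <- purrr::map(halo_ids, function(pid) {
    p <- pp[[pid]]
    m <- p$artefacts$halo & p$mask
    pred <- predict_net(fit$net, p$x)
    mae_model <- mean(abs(pred[m] - p$y_clean[m]))
    mae_art <- mean(abs(p$y[m] - p$y_clean[m]))
    tibble::tibble(patient_id = pid, mae_model = mae_model,
                   mae_artefact = mae_art,
                   reduction = 1 - mae_model / mae_art)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "net") <- fit$net
  out
}
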