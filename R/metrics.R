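# Image-quality metrics between predicted and reference CT-ASC images and
# their per-group aggregation.

#' Image-quality metrics (MAE / MSE / SSIM / PSNR)
#'
#' Voxel-wise metrics between a predicted and a reference image, computed
#' inside the body mask (background zeros would deflate the error).  PSNR
#' uses the reference dynamic range; SSIM uses an 11-pixel Gaussian window
#' (SD 1.5) with stabilizers `k1 = 0.01`, `k2 = 0.03` on the joint dynamic
#' range of the two images (which makes it symmetric in its arguments).
#'
#' @param pred predicted matrix.
#' @param ref reference matrix, same shape.
#' @param mask logical matrix of pixels to include; defaults to `ref > 0`
#'   (the body support).
#' @param domain `"normalized"` or `"suv"`; with `"suv"` both images are
#'   denormalized with the CT-ASC divisor before the metrics.
#' @param scenario,centre_id,patient_id provenance columns for the record.
#' @return one-row tibble (a `MetricsRecord`).
#' @export
compute_metrics <- function(pred, ref, mask = NULL,
                            domain = c("normalized", "suv"),
                            scenario = NA_character_, centre_id = NA,
                            patient_id = NA_character_) {
  domain <- match.arg(domain)
  if (!all(dim(pred) == dim(ref))) {
    stop_shape(sprintf("prediction %s and reference %s shapes differ",
                       dim_str(pred), dim_str(ref)))
  }
  if (domain == "suv") {
    pred <- denormalize_suv(pred, "ct_asc")
    ref <- denormalize_suv(ref, "ct_asc")
  }
  if (is.null(mask)) mask <- ref > 0
  if (!any(mask)) stop_degenerate("empty evaluation mask")
  dp <- pred[mask] - ref[mask]
  mae <- mean(abs(dp))
  mse <- mean(dp^2)
  l_ref <- diff(range(ref[mask]))
  psnr <- if (mse == 0) Inf else 10 * log10(l_ref^2 / mse)
  ssim <- ssim_index(pred, ref, mask = mask)
  tibble::tibble(
    centre_id = centre_id, patient_id = patient_id, scenario = scenario,
    domain = domain, mae = mae, mse = mse, ssim = ssim, psnr = psnr
  )
}

#' Structural similarity index
#'
#' Windowed SSIM with an 11-pixel Gaussian window of SD 1.5, averaged over
#' the mask.  The stabilizer range `L` is the joint dynamic range of both
#' images, so `ssim_index(a, b) == ssim_index(b, a)`.
#'
#' @param a,b matrices of the same shape.
#' @param mask logical matrix (default: everywhere).
#' @param k1,k2 stabilizer constants.
#' @param win_sd Gaussian window SD in pixels.
#' @param win_size window diameter in pixels (odd).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim_index <- function(a, b, mask = NULL, k1 = 0.01, k2 = 0.03,
                       win_sd = 1.5, win_size = 11L) {
  if (!all(dim(a) == dim(b))) stop_shape("ssim inputs must have equal shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  radius <- (win_size - 1L) %/% 2L
  g <- function(x) gaussian_blur(x, win_sd, radius = radius)
  l_rng <- max(max(a[mask]), max(b[mask])) - min(min(a[mask]), min(b[mask]))
  if (l_rng == 0) l_rng <- 1
  c1 <- (k1 * l_rng)^2
  c2 <- (k2 * l_rng)^2
  mu_a <- g(a); mu_b <- g(b)
  var_a <- g(a^2) - mu_a^2
  var_b <- g(b^2) - mu_b^2
  cov_ab <- g(a * b) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2)
  mean((num / den)[mask])
}

#' Group summary in "mean +/- SD (CI 95%)" form
#'
#' Normal-approximation 95% confidence intervals
#' (`mean +/- 1.96 * SD / sqrt(n)`); groups of size 1 get a warning and no
#' interval.
#'
#' @param records tibble of metric records.
#' @param group_by character vector of grouping columns (default
#'   `"scenario"`).
#' @param value name of the value column to summarize (default `"mae"`).
#' @return tibble sorted by group key with mean, SD, n and CI bounds.
#' @export
summarize_metrics <- function(records, group_by = "scenario", value = "mae") {
  out <- records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) %>%
    dplyr::summarise(
      mean_value = mean(.data[[value]]),
      sd_value = stats::sd(.data[[value]]),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      ci_lo = .data$mean_value - 1.96 * .data$sd_value / sqrt(.data$n),
      ci_hi = .data$mean_value + 1.96 * .data$sd_value / sqrt(.data$n)
    ) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(group_by)))
  if (any(out$n < 2)) {
    rlang::warn("groups with fewer than 2 records: CI omitted")
    out$ci_lo[out$n < 2] <- NA_real_
    out$ci_hi[out$n < 2] <- NA_real_
    out$sd_value[out$n < 2] <- NA_real_
  }
  names(out)[names(out) == "mean_value"] <- paste0("mean_", value)
  names(out)[names(out) == "sd_value"] <- paste0("sd_", value)
  out
}

#' Evaluate trained models on per-centre test sets
#'
#' Applies each scenario's model to every test pair of the matching centre
#' and computes the metric records in both the normalized and SUV domains.
#'
#' @param models named list: each element either a single `fedasc_net`
#'   (applied to all centres, e.g. CeZe) or a named list of per-centre nets
#'   (CeBa, FTL personalized models).
#' @param test_sets named list (per centre) of preprocessed pairs
#'   (`list(x =, y =, mask =)`).
#' @return tibble of metric records.
#' @export
evaluate_scenarios <- function(models, test_sets) {
  rows <- purrr::imap(models, function(model, scen) {
    purrr::imap(test_sets, function(pairs, cid) {
      net <- if (inherits(model, "fedasc_net")) model else model[[cid]]
      purrr::map(pairs, function(p) {
        pred <- predict_net(net, p$x)
        dplyr::bind_rows(
          compute_metrics(pred, p$y, mask = p$mask, domain = "normalized",
                          scenario = scen, centre_id = cid,
                          patient_id = p$patient_id),
          compute_metrics(pred, p$y, mask = p$mask, domain = "suv",
                          scenario = scen, centre_id = cid,
                          patient_id = p$patient_id)
        )
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  class(rows) <- c("fedasc_metrics", class(rows))
  rows
}
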