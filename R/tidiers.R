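# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a statistical test result
#' @param x a `fedasc_stat`.
#' @param ... unused.
#' @return the underlying tibble.
#' @export
tidy.fedasc_stat <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fedasc_stat")
  out
}

#' One-row summary of a network
#' @param x a `fedasc_net`.
#' @param ... unused.
#' @export
glance.fedasc_net <- function(x, ...) {
  tibble::tibble(
    n_stages = x$config$n_stages,
    base_channels = x$config$base_channels,
    rsu_inner_depth = x$config$rsu_inner_depth,
    n_parameters = count_parameters(x),
    n_trainable = count_parameters(x, trainable_only = TRUE),
    learning_rate = x$config$learning_rate,
    weight_decay = x$config$weight_decay
  )
}

#' Per-round privacy spend
#' @param x a `privacy_spend`.
#' @param ... unused.
#' @export
tidy.privacy_spend <- function(x, ...) {
  tibble::tibble(
    round_idx = seq_along(x$mu_per_round),
    mu = x$mu_per_round
  )
}

#' One-row privacy summary with reference (epsilon, delta) pairs
#' @param x a `privacy_spend`.
#' @param ... unused.
#' @export
glance.privacy_spend <- function(x, ...) {
  base <- tibble::tibble(guaranteed = x$guaranteed, mu_total = x$mu_total,
                         n_rounds = length(x$mu_per_round))
  if (!is.null(x$delta)) {
    base <- dplyr::bind_cols(base, tibble::as_tibble(as.list(x$delta)))
  }
  base
}

#' Bar chart of metric records by scenario and centre
#'
#' Mean with a normal-approximation 95% confidence interval, grouped the
#' way multi-centre scenario comparisons are usually displayed.
#'
#' @param object a `fedasc_metrics` tibble.
#' @param metric column to plot (default `"mae"`).
#' @param domain_filter metric domain (default `"suv"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fedasc_metrics <- function(object, metric = "mae",
                                    domain_filter = "suv", ...) {
  d <- object %>% dplyr::filter(.data$domain == domain_filter)
  summ <- summarize_metrics(d, group_by = c("scenario", "centre_id"),
                            value = metric)
  mean_col <- paste0("mean_", metric)
  ggplot2::ggplot(summ, ggplot2::aes(
    x = factor(.data$centre_id), y = .data[[mean_col]],
    fill = .data$scenario
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::labs(x = "centre", y = sprintf("%s (%s)", toupper(metric),
                                            domain_filter),
                  fill = "scenario") +
    ggplot2::theme_minimal()
}

#' Line plot of training loss traces
#'
#' @param traces named list of numeric per-epoch loss vectors (one per
#'   centre or scenario).
#' @return a ggplot object.
#' @export
plot_loss_traces <- function(traces) {
  d <- purrr::imap(traces, function(tr, nm) {
    tibble::tibble(group = nm, epoch = seq_along(tr), loss = tr)
  }) %>% dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss", colour = NULL) +
    ggplot2::theme_minimal()
}
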