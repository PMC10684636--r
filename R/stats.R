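# Statistical comparison machinery: paired Wilcoxon signed-rank with exact
# enumeration, Benjamini-Hochberg correction, two-way mixed ICC, McNemar
# and Stuart-Maxwell marginal homogeneity, plus rating dichotomization.

stat_result <- function(test_name, statistic, p_value, n, notes = "",
                        q_value = NA_real_) {
  out <- tibble::tibble(
    test_name = test_name, statistic = statistic, p_value = p_value,
    q_value = q_value, n = n, notes = notes
  )
  class(out) <- c("fedasc_stat", class(out))
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples.  Zero differences are
#' dropped; tied absolute differences receive average ranks.  `mode =
#' "exact"` enumerates the full null distribution of the rank sum over all
#' `2^n` sign assignments (collapsed by convolution over the rank values,
#' so ties are handled exactly); `mode = "approx"` uses the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param mode `"exact"` (n <= 30 after dropping zeros) or `"approx"`.
#' @return a `fedasc_stat` tibble (statistic = positive-rank sum `V`).
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop_invalid("x and y must be paired")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 3) stop_degenerate("fewer than 3 nonzero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (mode == "exact") {
    if (n > 30) stop_invalid("exact mode supports n <= 30; use approx")
    # distribution of the positive-rank sum over all sign assignments;
    # double the ranks so average ranks become integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- rep(0, total + 1L)
    cnt[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(total + 1L - ri)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * w))
    p_lo <- sum(probs[seq_len(w2 + 1L)])
    p_hi <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_lo, p_hi))
    notes <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    notes <- sprintf("normal approximation, z = %.4f", z)
  }
  stat_result("wilcoxon_signed_rank", w, p, n, notes)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment: `q_(i) = min_{j >= i} m * p_(j) / j`, reported in the
#' original input order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  q_sorted <- rev(cummin(rev(m * p_sorted / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

icc_label <- function(v) {
  if (v < 0.40) "poor" else if (v < 0.60) "fair" else if (v < 0.75) "good" else "excellent"
}

#' Intraclass correlation from a two-way mixed-effects model
#'
#' Single-rater consistency form ICC(3,1) =
#' `(MSR - MSE) / (MSR + (k - 1) * MSE)` from the two-way ANOVA mean
#' squares (subjects random, raters fixed); the absolute-agreement variant
#' adds the rater variance term.  The reproducibility label follows the
#' conventional bands: poor (< 0.40), fair (0.40-0.59), good (0.60-0.74),
#' excellent (0.75-1.00).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns, no
#'   missing cells.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return a `fedasc_stat` tibble with the ICC as statistic, an F-test
#'   p-value and the label in `notes`.
#' @export
icc_two_way_mixed <- function(ratings, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop_invalid("missing cells are not supported (no imputation)")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2) stop_invalid("need at least 2 raters")
  if (n < 5) stop_invalid("need at least 5 subjects")
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm_ <- colMeans(ratings)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  resid <- sweep(sweep(ratings, 1, rm_), 2, cm_) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- if (msr == 0 && mse == 0) {
    NA_real_
  } else if (type == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  if (is.na(icc)) stop_degenerate("no variance between subjects or residuals")
  f <- if (mse == 0) Inf else msr / mse
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  stat_result(paste0("icc_3_1_", type), icc, p, n,
              notes = sprintf("label: %s; F = %.4g", icc_label(icc), f))
}

#' McNemar test on a paired 2x2 table
#'
#' Exact binomial version on the discordant cells `(b, c)`: two-sided
#' p-value from `Binomial(b + c, 1/2)`.  The continuity-corrected
#' chi-square version is reported in `notes`.
#'
#' @param counts 2x2 matrix of paired classifications (rows: method 1,
#'   columns: method 2).
#' @return a `fedasc_stat` tibble (statistic = continuity-corrected
#'   chi-square, p_value = exact binomial).
#' @export
mcnemar_paired <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_invalid("counts must be a nonnegative integer 2x2 table")
  }
  b <- counts[1, 2]
  cc <- counts[2, 1]
  nd <- b + cc
  if (nd == 0) stop_degenerate("no discordant pairs")
  p_exact <- min(1, 2 * pbinom(min(b, cc), nd, 0.5))
  chi <- (abs(b - cc) - 1)^2 / nd
  p_chi <- stats::pchisq(chi, 1, lower.tail = FALSE)
  stat_result("mcnemar_exact", chi, p_exact, sum(counts),
              notes = sprintf("discordant b = %d, c = %d; chi2 p = %.4g", b, cc, p_chi))
}

#' Stuart-Maxwell marginal homogeneity test
#'
#' Chi-square test that the row and column margins of a paired K x K table
#' agree, using the generalized inverse of the marginal-difference
#' covariance; degrees of freedom equal its rank.  For K = 2 it reduces to
#' the McNemar chi-square without continuity correction.
#'
#' @param counts K x K matrix of paired classifications.
#' @return a `fedasc_stat` tibble.
#' @export
stuart_maxwell <- function(counts) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (k < 2 || ncol(counts) != k) stop_invalid("counts must be a K x K table, K >= 2")
  off <- counts
  diag(off) <- 0
  if (sum(off) == 0) stop_degenerate("no off-diagonal counts")
  d_full <- rowSums(counts) - colSums(counts)
  s_full <- -(counts + t(counts))
  diag(s_full) <- rowSums(counts) + colSums(counts) - 2 * diag(counts)
  keep <- seq_len(k - 1)
  d <- d_full[keep]
  s <- s_full[keep, keep, drop = FALSE]
  s_inv <- MASS::ginv(s)
  stat <- as.numeric(t(d) %*% s_inv %*% d)
  df <- qr(s)$rank
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  stat_result("stuart_maxwell", stat, p, sum(counts),
              notes = sprintf("df = %d", df))
}

#' Dichotomize 5-point ratings into paired 2x2 tables
#'
#' Scores at or above `threshold` count as "high".  For every
#' (region, category) stratum, paired CT-ASC vs FTL-ASC classifications per
#' (image, reader) are cross-tabulated; images missing one of the two
#' methods are excluded with a warning count.
#'
#' @param records tibble with columns reader_id, image_id, method
#'   (`"CT_ASC"` / `"FTL_ASC"`), region, category, score (1-5).
#' @param threshold "high" cut-point (default 4).
#' @return tibble with columns region, category, n_pairs, n_excluded and a
#'   `table` list-column of 2x2 matrices (rows: CT-ASC high/low, columns:
#'   FTL-ASC high/low).
#' @export
dichotomize_ratings <- function(records, threshold = 4) {
  if (any(!records$score %in% 1:5)) stop_invalid("scores must be integers 1..5")
  wide <- records %>%
    dplyr::mutate(high = .data$score >= threshold) %>%
    dplyr::select("reader_id", "image_id", "method", "region", "category", "high") %>%
    tidyr::pivot_wider(names_from = "method", values_from = "high")
  missing_cols <- setdiff(c("CT_ASC", "FTL_ASC"), names(wide))
  for (mc in missing_cols) wide[[mc]] <- NA
  n_excl <- sum(is.na(wide$CT_ASC) | is.na(wide$FTL_ASC))
  if (n_excl > 0) {
    rlang::warn(sprintf("%d unpaired (image, reader) records excluded", n_excl))
  }
  wide <- wide %>% dplyr::filter(!is.na(.data$CT_ASC), !is.na(.data$FTL_ASC))
  wide %>%
    dplyr::group_by(.data$region, .data$category) %>%
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_excluded = n_excl,
      table = list(matrix(
        c(sum(.data$CT_ASC & .data$FTL_ASC), sum(.data$CT_ASC & !.data$FTL_ASC),
          sum(!.data$CT_ASC & .data$FTL_ASC), sum(!.data$CT_ASC & !.data$FTL_ASC)),
        2, 2, byrow = TRUE,
        dimnames = list(ct_asc = c("high", "low"), ftl_asc = c("high", "low"))
      )),
      .groups = "drop"
    )
}

#' Pairwise scenario comparison of image metrics
#'
#' Paired Wilcoxon signed-rank tests between every pair of scenarios for a
#' metric, with Benjamini-Hochberg correction across the comparisons.
#'
#' @param records metric records (one row per patient x scenario x domain).
#' @param metric metric column (default `"mae"`).
#' @param domain_filter metric domain to compare (default `"suv"`).
#' @param mode passed to [wilcoxon_signed_rank()].
#' @return tibble of comparisons with p- and q-values.
#' @export
compare_scenarios <- function(records, metric = "mae", domain_filter = "suv",
                              mode = "approx") {
  d <- records %>% dplyr::filter(.data$domain == domain_filter)
  wide <- d %>%
    dplyr::select("centre_id", "patient_id", "scenario",
                  dplyr::all_of(metric)) %>%
    tidyr::pivot_wider(names_from = "scenario",
                       values_from = dplyr::all_of(metric))
  scens <- setdiff(names(wide), c("centre_id", "patient_id"))
  combos <- utils::combn(scens, 2, simplify = FALSE)
  rows <- purrr::map(combos, function(pr) {
    res <- wilcoxon_signed_rank(wide[[pr[1]]], wide[[pr[2]]], mode = mode)
    tibble::tibble(
      comparison = paste(pr, collapse = " vs "),
      metric = metric, statistic = res$statistic, p_value = res$p_value,
      n = res$n
    )
  }) %>% dplyr::bind_rows()
  rows$q_value <- bh_fdr(rows$p_value)
  rows
}
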