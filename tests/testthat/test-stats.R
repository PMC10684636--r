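# Statistical machinery: signed-rank, BH, ICC, McNemar, Stuart-Maxwell.

test_that("exact signed-rank p-value for uniformly signed differences", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + 0.5
  res <- wilcoxon_signed_rank(x, y, mode = "exact")
  expect_equal(res$p_value, 2 / 2^6)
  expect_equal(res$n, 6)
})

test_that("exact signed-rank agrees with the base-R implementation when tie-free", {
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(9)
    y <- rnorm(9)
    ours <- wilcoxon_signed_rank(x, y, mode = "exact")
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("normal approximation tracks the exact test at n = 12", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(12)
    y <- rnorm(12, 0.3)
    pe <- wilcoxon_signed_rank(x, y, mode = "exact")$p_value
    pa <- wilcoxon_signed_rank(x, y, mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("signed-rank degenerate input signals", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5),
               class = "fedasc_degenerate_input")
  expect_error(wilcoxon_signed_rank(1:3, 1:4),
               class = "fedasc_invalid_argument")
})

test_that("signed-rank type-I error is calibrated under the null", {
  set.seed(12)
  n_sim <- 10000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    d <- rnorm(20)
    rejections <- rejections +
      (wilcoxon_signed_rank(d, rep(0, 20), mode = "approx")$p_value < 0.05)
  }
  rate <- rejections / n_sim
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("BH step-up reproduces the hand computation and base R", {
  expect_equal(bh_fdr(0.2), 0.2)
  # step-up: sorted p (0.01, 0.03, 0.04) -> q3 = 0.04, q2 = min(0.045, 0.04),
  # q1 = min(0.03, ...); agreeing with stats::p.adjust
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:15, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(sort(q)[order(order(p))] - 0) >= -1)) # sanity
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "fedasc_invalid_argument")
})

test_that("q-values never fall below p-values (property)", {
  set.seed(14)
  for (i in 1:1000) {
    p <- runif(sample(1:8, 1))
    expect_true(all(bh_fdr(p) >= p))
  }
})

test_that("ICC(3,1) is 1 for identical rater columns and labels follow the bands", {
  subj <- c(1, 3, 2, 5, 4, 2.5)
  res <- icc_two_way_mixed(cbind(subj, subj, subj))
  expect_equal(res$statistic, 1)
  expect_match(res$notes, "excellent")
  lab <- fedasc:::icc_label
  expect_equal(lab(0.39), "poor")
  expect_equal(lab(0.55), "fair")
  expect_equal(lab(0.70), "good")
  expect_equal(lab(0.80), "excellent")
})

test_that("ICC matches an independent ANOVA mean-square computation", {
  set.seed(15)
  m <- matrix(rnorm(12, 5), 6, 2)
  res <- icc_two_way_mixed(m)
  d <- data.frame(
    value = as.vector(m),
    subject = factor(rep(1:6, 2)),
    rater = factor(rep(1:2, each = 6))
  )
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; mse <- ms[3]
  expect_equal(res$statistic, (msr - mse) / (msr + mse), tolerance = 1e-10)
  expect_error(icc_two_way_mixed(m[1:4, ]), class = "fedasc_invalid_argument")
  m_na <- m; m_na[2, 1] <- NA
  expect_error(icc_two_way_mixed(m_na), class = "fedasc_invalid_argument")
})

test_that("ICC recovers the variance ratio on simulated two-way data", {
  set.seed(16)
  tau2 <- 1.5
  sigma2 <- 1.0
  n <- 2000
  s <- rnorm(n, 0, sqrt(tau2))
  m <- cbind(s + rnorm(n, 0, sqrt(sigma2)), s + rnorm(n, 0, sqrt(sigma2)))
  res <- icc_two_way_mixed(m)
  expect_lt(abs(res$statistic - tau2 / (tau2 + sigma2)), 0.03)
})

test_that("McNemar exact binomial handles balanced and extreme tables", {
  for (bc in 1:5) {
    tab <- matrix(c(10, bc, bc, 10), 2)
    expect_gte(mcnemar_paired(tab)$p_value, 0.99)
  }
  res <- mcnemar_paired(matrix(c(7, 10, 0, 3), 2, byrow = TRUE))
  expect_equal(res$p_value, 2 * (1 / 2)^10)
  # concordant cells do not matter
  a <- mcnemar_paired(matrix(c(1, 6, 2, 1), 2))
  b <- mcnemar_paired(matrix(c(50, 6, 2, 90), 2))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, b$statistic)
  # chi-square version agrees with stats::mcnemar.test
  tab <- matrix(c(12, 8, 3, 9), 2)
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(mcnemar_paired(tab)$statistic, unname(ref$statistic))
  expect_error(mcnemar_paired(matrix(c(3, 0, 0, 5), 2)),
               class = "fedasc_degenerate_input")
})

test_that("Stuart-Maxwell vanishes on symmetric tables and reduces to McNemar at K = 2", {
  sym <- matrix(c(5, 3, 2, 3, 7, 4, 2, 4, 6), 3)
  res <- stuart_maxwell(sym)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  k2 <- matrix(c(10, 1, 5, 8), 2) # b = 5, c = 1
  expect_equal(stuart_maxwell(k2)$statistic, 16 / 6, tolerance = 1e-12)
})

test_that("Stuart-Maxwell matches an independent linear-algebra route", {
  tab <- matrix(c(20, 5, 3,
                  2, 30, 6,
                  8, 4, 25), 3, byrow = TRUE)
  res <- stuart_maxwell(tab)
  # independent computation dropping the *last* category and using solve()
  d <- (rowSums(tab) - colSums(tab))[1:2]
  s <- matrix(0, 2, 2)
  for (i in 1:2) {
    s[i, i] <- rowSums(tab)[i] + colSums(tab)[i] - 2 * tab[i, i]
  }
  s[1, 2] <- s[2, 1] <- -(tab[1, 2] + tab[2, 1])
  expect_equal(res$statistic, as.numeric(t(d) %*% solve(s) %*% d),
               tolerance = 1e-10)
  expect_error(stuart_maxwell(diag(3)), class = "fedasc_degenerate_input")
})

test_that("rating dichotomization builds the expected paired tables", {
  rec <- tidyr::expand_grid(
    reader_id = c("r1", "r2"), image_id = sprintf("i%02d", 1:10),
    method = c("CT_ASC", "FTL_ASC"), region = "all", category = "quality"
  )
  rec$score <- 5L
  tabs <- dichotomize_ratings(rec)
  expect_equal(tabs$table[[1]]["high", "high"], 20)
  expect_equal(sum(tabs$table[[1]]), 20)
  tabs1 <- dichotomize_ratings(dplyr::mutate(rec, score = sample(1:5, nrow(rec), TRUE)),
                               threshold = 1)
  expect_equal(tabs1$table[[1]]["high", "high"], 20)
  # unpaired images are excluded with a warning
  expect_warning(
    dichotomize_ratings(rec[rec$method == "CT_ASC" | rec$image_id != "i01", ]),
    "unpaired"
  )
})

test_that("dichotomization recovers a known discordance rate", {
  set.seed(17)
  n <- 500
  ct_high <- rep(TRUE, n)
  flip <- runif(n) < 0.2
  rec <- tibble::tibble(
    reader_id = "r1", image_id = sprintf("i%04d", rep(1:n, 2)),
    method = rep(c("CT_ASC", "FTL_ASC"), each = n),
    region = "all", category = "quality",
    score = c(ifelse(ct_high, 5L, 1L), ifelse(xor(ct_high, flip), 5L, 1L))
  )
  tab <- dichotomize_ratings(rec)$table[[1]]
  bc <- tab["high", "low"] + tab["low", "high"]
  expect_gte(bc, qbinom(0.025, n, 0.2))
  expect_lte(bc, qbinom(0.975, n, 0.2))
})
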