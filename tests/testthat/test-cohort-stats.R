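test_that("iov_summary computes dispersion indices", {
  s <- iov_summary(c(1, 2, 3))
  expect_equal(s$sd, 1.0)
  expect_equal(s$cv, 0.5)
  expect_equal(s$mvr, 3.0)
  expect_equal(s$n, 3)
  flat <- iov_summary(c(650, 650, 650))
  expect_equal(flat$sd, 0)
  expect_equal(flat$cv, 0)
  expect_equal(flat$mvr, 1)
  # permutation invariance
  set.seed(1)
  v <- runif(10, 400, 900)
  expect_equal(unclass(iov_summary(v)), unclass(iov_summary(sample(v))))
})

test_that("iov_summary rejects degenerate cohorts", {
  expect_error(iov_summary(650), class = "ce_insufficient_data")
  expect_error(iov_summary(c(650, -1)), class = "ce_invalid_data")
  expect_error(iov_summary(c(650, 0)), class = "ce_invalid_data")
})

test_that("the printed extreme volume range gives a 1.86-fold ratio", {
  cohort <- c(481.95, 620.1, 700.4, 896.48, 655.2)
  expect_equal(round(iov_summary(cohort)$mvr, 2), 1.86)
})

test_that("wilcoxon signed-rank matches wilcox.test's normal approximation", {
  set.seed(11)
  for (i in 1:6) {
    pre <- round(rnorm(12, 10, 2), 1)
    post <- round(pre + rnorm(12, 0.8, 1.5), 1)
    got <- wilcoxon_signed_rank(pre, post)
    ref <- suppressWarnings(wilcox.test(pre, post, paired = TRUE,
                                        exact = FALSE, correct = FALSE))
    expect_equal(got$W, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("wilcoxon normal approximation tracks exact enumeration at small n", {
  # without continuity correction the normal approximation estimates the
  # exact *mid*-p; at n of 5-8 it stays within a few hundredths of it
  set.seed(12)
  checked <- 0
  for (i in 1:20) {
    d <- round(rnorm(8, 0.5, 1), 1)
    d <- d[d != 0]
    if (length(d) < 5) next
    pre <- rep(0, length(d))
    got <- wilcoxon_signed_rank(pre, pre - d) # differences pre - post = d
    expect_lt(abs(got$p_value - bf_wilcoxon_exact_midp(d)), 0.075)
    # and the ordinary exact p is approached from below by at most one atom
    expect_lt(abs(got$p_value - bf_wilcoxon_exact_p(d)), 0.15)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("wilcoxon handles one-sided shifts, zero drops and antisymmetry", {
  pre <- 1:10
  post <- pre + 3
  res <- wilcoxon_signed_rank(pre, post)
  expect_equal(res$W, 0) # all differences negative
  expect_lt(res$z, 0)
  swapped <- wilcoxon_signed_rank(post, pre)
  expect_equal(swapped$z, -res$z)
  expect_equal(swapped$p_value, res$p_value)
  # zero differences are dropped before ranking
  pre2 <- c(pre, 20, 21); post2 <- c(post, 20, 21)
  expect_equal(wilcoxon_signed_rank(pre2, post2)$n, 10)
  expect_error(wilcoxon_signed_rank(pre, pre), class = "ce_degenerate_data")
  expect_error(wilcoxon_signed_rank(1:4, 2:5), class = "ce_insufficient_data")
})

test_that("paired_t matches the textbook statistic", {
  post <- c(5, 6, 7, 8); pre <- post - c(1, 2, 3, 4)
  res <- paired_t(pre, post)
  d <- c(-1, -2, -3, -4)
  expect_equal(res$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(res$df, 3)
  # differences with zero mean give t = 0, p = 1
  res0 <- paired_t(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)
  swapped <- paired_t(post, pre)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  expect_error(paired_t(1:5, 1:5 + 2), class = "ce_degenerate_data")
})

test_that("effect sizes reproduce printed values from printed statistics", {
  # Wilcoxon r = |Z|/sqrt(n)
  expect_lt(abs(effect_size_r(-2.950, 17) - 0.716), 1e-3)
  expect_equal(round(effect_size_r(-3.516, 16), 3), 0.879)
  expect_equal(effect_size_r(0, 25), 0)
  # paired-t d = |t|/sqrt(n)
  expect_equal(round(effect_size_d(-2.971, 19), 3), 0.682)
  expect_equal(round(effect_size_d(-2.500, 16), 3), 0.625)
  expect_equal(effect_size_d(0, 9), 0)
  expect_error(effect_size_r(1.5, 0), class = "ce_invalid_parameter")
  expect_error(effect_size_d(1.5, 0), class = "ce_invalid_parameter")
})

test_that("the normality gate selects the expected test", {
  set.seed(21)
  normal_picks <- replicate(20, {
    pre <- rnorm(30); post <- pre + rnorm(30)
    paired_compare(pre, post)$test_used
  })
  expect_gt(mean(normal_picks == "paired_t"), 0.8)
  skew_picks <- replicate(20, {
    pre <- rnorm(30); post <- pre + rexp(30, 1 / 2)
    paired_compare(pre, post)$test_used
  })
  expect_gt(mean(skew_picks == "wilcoxon"), 0.8)
})

test_that("paired_compare's effect size matches the test it ran", {
  set.seed(22)
  for (i in 1:10) {
    pre <- rnorm(15); post <- pre + rnorm(15, 0.5, i %% 3 + 0.5)^3
    res <- paired_compare(pre, post, metric_name = "m")
    if (res$test_used == "wilcoxon") {
      expect_equal(res$effect_kind, "r")
      expect_identical(res$effect_size, effect_size_r(res$z, res$n))
    } else {
      expect_equal(res$effect_kind, "d")
      expect_identical(res$effect_size, effect_size_d(res$statistic, res$n))
    }
  }
  expect_error(paired_compare(1:6, 1:6), class = "ce_degenerate_data")
})

test_that("spearman_rho matches rank-then-Pearson and handles ties", {
  expect_equal(spearman_rho(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_rho(1:8, -(1:8)^3)$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 7)
  y <- c(2, 1, 4, 4, 6, 8, 7)
  expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(3, 5), 1:5), class = "ce_undefined_correlation")
  expect_error(spearman_rho(1:2, 2:1), class = "ce_insufficient_data")
})

test_that("directional adjustment flips lower-is-better metrics and is an involution", {
  expect_equal(directional_adjust("asd", 0.4), -0.4)
  expect_equal(directional_adjust("dsc", 0.4), 0.4)
  expect_equal(directional_adjust("rvd", -0.2), 0.2)
  for (m in c("hd95", "asd", "dc", "rvd"))
    expect_equal(directional_adjust(m, directional_adjust(m, 0.37)), 0.37)
  for (m in c("dsc", "ci", "inclusion"))
    expect_equal(directional_adjust(m, 0.37), 0.37)
  expect_equal(directional_adjust("asd_mm", 0.4), -0.4) # unit suffix accepted
  expect_error(directional_adjust("volume", 0.1), class = "ce_invalid_parameter")
  expect_error(directional_adjust("banana", 0.1), class = "ce_invalid_parameter")
})

fake_metrics <- function(scores, f, structures = "CTV") {
  # builds a metrics table whose post values are a function of the score
  rows <- list()
  for (st in structures) {
    for (i in seq_along(scores)) {
      for (phase in c("pre", "post")) {
        v <- if (phase == "post") f(scores[i]) else 0.5
        rows[[length(rows) + 1]] <- tibble::tibble(
          observer_id = sprintf("o%02d", i), case_id = "c1", phase = phase,
          structure = st, dsc = v, ci = v, inclusion = v, rvd = v,
          asd_mm = v, dc_mm = v, hd95_mm = v, volume_cm3 = 600 + v)
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("correlation matrix recovers a monotone association with adjustment", {
  scores <- c(1, 2, 3, 4, 5, 2, 3, 4, 1, 5)
  likert <- tibble::tibble(observer_id = sprintf("o%02d", seq_along(scores)),
                           item_id = "confidence", pre = 1L,
                           post = as.integer(scores))
  metrics <- fake_metrics(scores, function(s) 0.5 + 0.05 * s)
  cm <- correlation_matrix(likert, metrics, mode = "post")
  expect_equal(nrow(cm), 7)
  expect_equal(cm$rho, rep(1, 7)) # raw rho is +1 for every metric
  adj <- cm$rho_adjusted[match(c("dsc", "ci", "inclusion"), cm$metric)]
  expect_equal(adj, rep(1, 3))
  neg <- cm$rho_adjusted[match(c("rvd", "asd", "dc", "hd95"), cm$metric)]
  expect_equal(neg, rep(-1, 4)) # lower-is-better metrics are negated
})

test_that("independent inputs give small mean correlation and delta degeneracy errors", {
  set.seed(31)
  n <- 30
  likert <- tibble::tibble(observer_id = sprintf("o%02d", 1:n),
                           item_id = "confidence",
                           pre = sample(1:5, n, TRUE),
                           post = sample(1:5, n, TRUE))
  rows <- list()
  for (i in 1:n) for (phase in c("pre", "post")) {
    v <- runif(1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      observer_id = sprintf("o%02d", i), case_id = "c1", phase = phase,
      structure = "CTV", dsc = runif(1), ci = runif(1), inclusion = runif(1),
      rvd = runif(1), asd_mm = runif(1), dc_mm = runif(1), hd95_mm = runif(1),
      volume_cm3 = 600)
  }
  metrics <- dplyr::bind_rows(rows)
  cm <- correlation_matrix(likert, metrics, mode = "post")
  expect_lt(mean(abs(cm$rho)), 0.35)
  # identical pre and post metric values make delta-mode correlations undefined
  const <- metrics
  const[const$phase == "post", 5:12] <- const[const$phase == "pre", 5:12]
  expect_error(correlation_matrix(likert, const, mode = "delta"),
               class = "ce_undefined_correlation")
})

test_that("likert tables are validated", {
  bad <- tibble::tibble(observer_id = "a", item_id = "x", pre = 0L, post = 3L)
  expect_error(contoureval:::check_likert(bad), class = "ce_invalid_data")
  bad2 <- tibble::tibble(observer_id = "a", item_id = "x", pre = 2.5, post = 3)
  expect_error(contoureval:::check_likert(bad2), class = "ce_invalid_data")
})
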