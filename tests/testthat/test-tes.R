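single_exp_table <- function(presyn, postsyn, axons = NULL, condition = "hOlig",
                             div = 21) {
  comp <- c("presyn", "postsyn", if (!is.null(axons)) "axons")
  tibble::tibble(
    experiment_id = "E1", condition = condition, div = div,
    compartment = comp, signal = c(presyn, postsyn, axons)
  )
}

test_that("excess is signal minus background, unclipped", {
  expect_equal(excess(1.0), 0)
  expect_equal(excess(1.10), 0.10)
  expect_equal(excess(0.98), -0.02)
})

test_that("TES reproduces the printed worked examples", {
  # fibrils at DIV14: 21-fold presyn, +10% postsyn -> 0.10/20 = 0.5%
  t1 <- compute_tes(single_exp_table(21, 1.10, condition = "hFib", div = 14),
    pair = "presyn_postsyn"
  )
  expect_equal(t1$tes, 0.10 / 20)

  # oligomers at DIV21: 7.3-fold presyn, +3.2% postsyn -> ~0.51%
  t2 <- compute_tes(single_exp_table(7.3, 1.032), pair = "presyn_postsyn")
  expect_equal(t2$tes, 0.032 / 6.3)
  expect_equal(round(100 * t2$tes, 1), 0.5)

  # control-level postsyn signal: TES exactly 0
  t3 <- compute_tes(single_exp_table(7.3, 1.0), pair = "presyn_postsyn")
  expect_equal(t3$tes, 0)

  # all three pair variants on demand
  t4 <- compute_tes(single_exp_table(4.5, 1.10, axons = 1.95,
    condition = "hOlig", div = 14
  ))
  expect_setequal(
    t4$pair,
    c("presyn_postsyn", "presyn_axons", "axons_postsyn")
  )
  expect_equal(
    t4$tes[t4$pair == "presyn_axons"], 0.95 / 3.5
  )
  expect_equal(
    t4$tes[t4$pair == "axons_postsyn"], 0.10 / 0.95
  )
})

test_that("the denominator spans experiments of the same condition", {
  tbl <- dplyr::bind_rows(
    single_exp_table(6, 1.02),
    dplyr::mutate(single_exp_table(8, 1.04), experiment_id = "E2")
  )
  out <- compute_tes(tbl, "presyn_postsyn")
  expect_equal(unique(out$source_mean_excess), mean(c(5, 7)))
  expect_equal(unique(out$n_source_experiments), 2L)
  expect_equal(out$tes, c(0.02, 0.04) / 6)
})

test_that("device rows aggregate to experiment means before TES", {
  tbl <- tibble::tibble(
    experiment_id = "E1", condition = "hFib", div = 14,
    compartment = rep(c("presyn", "postsyn"), each = 2),
    signal = c(20, 22, 1.08, 1.12)
  )
  expect_equal(compute_tes(tbl, "presyn_postsyn")$tes, 0.10 / 20)
})

test_that("weak source excess errors; an explicit denominator overrides", {
  tbl <- single_exp_table(1.04, 1.01)
  expect_error(
    compute_tes(tbl, "presyn_postsyn"),
    "indistinguishable"
  )
  ov <- compute_tes(tbl, "presyn_postsyn", denominator_excess = 3.5)
  expect_equal(ov$tes, 0.01 / 3.5)
})

test_that("TES is linear in the target excess and gain-invariant end to end", {
  cond <- condition_spec("hOlig", 14)
  tbl <- gen_signal_table(4, 3, cond, seed = 9)
  base <- compute_tes(tbl, "presyn_postsyn")
  doubled <- dplyr::mutate(tbl,
    signal = ifelse(compartment == "postsyn", 1 + 2 * (signal - 1), signal)
  )
  expect_equal(compute_tes(doubled, "presyn_postsyn")$tes, 2 * base$tes)

  # gain invariance through the normalization chain
  raw <- tibble::tibble(
    device_id = sprintf("d%d", 1:6), session_id = "s1",
    condition = rep(c("ctrl", "hFib"), each = 3),
    compartment = "postsyn",
    raw_mean = c(9, 10, 11, 30, 31, 29)
  )
  n1 <- normalize_session(raw)$normalized
  n2 <- normalize_session(dplyr::mutate(raw, raw_mean = raw_mean * 17))$normalized
  expect_equal(n1, n2)
})

test_that("control-only tables give TES centred on zero", {
  ctrl <- condition_spec("ctrl", 14)
  tes_means <- vapply(1:200, function(s) {
    tbl <- gen_signal_table(4, 2, ctrl, seed = s)
    mean(compute_tes(tbl, "presyn_postsyn", denominator_excess = 3.5)$tes)
  }, numeric(1))
  expect_lt(
    abs(mean(tes_means)),
    2 * sd(tes_means) / sqrt(length(tes_means))
  )
})

test_that("aggregate_tes reports mean, SEM and n per group", {
  profs <- tibble::tibble(
    experiment_id = c("E1", "E2"), condition = "hOlig", div = 14,
    pair = "presyn_postsyn", tes = c(0.01, 0.03)
  )
  agg <- aggregate_tes(profs)
  expect_equal(agg$mean_tes, 0.02)
  expect_equal(agg$sem_tes, 0.01)
  expect_equal(agg$n_experiments, 2L)

  one <- aggregate_tes(profs[1, ])
  expect_equal(one$mean_tes, 0.01)
  expect_true(is.na(one$sem_tes))
})

test_that("experiment-level confidence intervals cover the true TES", {
  # 20 experiments at true TES 0.5% under the generator's stated noise
  cond <- condition_spec("hOlig", 21) # implied TES = 0.032/6.3
  true_tes <- 0.032 / 6.3
  covered <- vapply(1:200, function(s) {
    tbl <- gen_signal_table(20, 2, cond, seed = s)
    tes <- compute_tes(tbl, "presyn_postsyn")$tes
    ci <- mean(tes) + c(-1, 1) * stats::qt(0.975, length(tes) - 1) *
      sd(tes) / sqrt(length(tes))
    ci[1] <= true_tes && true_tes <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("one-sample t against 1 matches the closed form", {
  # all values at the null
  r0 <- one_sample_t_vs_unity(c(1, 1, 1))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  vals <- c(1.08, 1.10, 1.12)
  r <- one_sample_t_vs_unity(vals)
  t_expected <- 0.10 / (0.02 / sqrt(3))
  expect_equal(r$statistic, t_expected)
  expect_equal(r$p_value, 2 * stats::pt(-t_expected, df = 2))

  expect_error(one_sample_t_vs_unity(1.1), "at least 2")
  expect_error(one_sample_t_vs_unity(c(1.1, 1.1)), "zero variance")
})

test_that("Welch t matches the textbook closed form with Satterthwaite df", {
  ra <- welch_t(c(1, 2, 3), c(4, 5, 6))
  # t = (2 - 5) / sqrt(1/3 + 1/3) = -3 * sqrt(3/2) = -3.674
  expect_equal(ra$statistic, -3 * sqrt(1.5))
  expect_equal(ra$df, 4)
  expect_equal(ra$p_value, 2 * stats::pt(-abs(ra$statistic), 4))
  expect_equal(round(ra$p_value, 4), 0.0213)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # unequal variances shrink the df below the pooled nA + nB - 2
  set.seed(2)
  a <- rnorm(8, 0, 0.1)
  b <- rnorm(8, 0, 5)
  expect_lt(welch_t(a, b)$df, 14)

  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_s3_class(tidy(ra), "tbl_df")
})

test_that("the normality gate routes as the protocol prescribes", {
  set.seed(4)
  big_normal <- rnorm(200)
  expect_equal(normality_gate(list(big_normal, rnorm(50)))$route, "parametric")

  bimodal <- c(rnorm(60, -4, 0.2), rnorm(60, 4, 0.2))
  expect_equal(normality_gate(list(big_normal, bimodal))$route, "nonparametric")

  const <- normality_gate(list(rep(2, 10)))
  expect_equal(const$route, "nonparametric")
  expect_match(const$note, "zero-variance")

  expect_warning(
    g <- normality_gate(list(c(1, 2), c(2, 3))),
    "too small"
  )
  expect_equal(g$route, "parametric")

  # gated comparison delegates to the rank-sum path for non-normal groups
  res <- compare_two_groups(bimodal, bimodal + 10)
  expect_equal(res$test_name, "mann_whitney")
})
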