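make_table <- function(a_eff, b_eff, ab_eff = NULL, n = 10, sd = 1,
                       seed = 1) {
  set.seed(seed)
  a <- length(a_eff); b <- length(b_eff)
  d <- tidyr::expand_grid(A = factor(seq_len(a)), B = factor(seq_len(b)),
                          rep = seq_len(n))
  mu <- a_eff[as.integer(d$A)] + b_eff[as.integer(d$B)]
  if (!is.null(ab_eff)) mu <- mu + ab_eff[cbind(as.integer(d$A),
                                                as.integer(d$B))]
  d$y <- mu + rnorm(nrow(d), 0, sd)
  d
}

test_that("a constant response yields zero F for every term", {
  d <- make_table(c(0, 0), c(0, 0, 0), n = 3)
  d$y <- 5
  out <- anova_two_way(d, y, A, B)
  expect_equal(out$statistic[out$term != "Residuals"], c(0, 0, 0))
  expect_equal(out$sumsq, c(0, 0, 0, 0))
})

test_that("purely additive cell means give exactly zero interaction SS", {
  d <- tidyr::expand_grid(A = factor(1:2), B = factor(1:3), rep = 1:3)
  # identical replicate pattern in every cell keeps the interaction
  # contrast exactly orthogonal while the error SS stays positive
  d$y <- c(2, -1)[as.integer(d$A)] + c(0, 1, 3)[as.integer(d$B)] +
    c(0.1, -0.1, 0)[d$rep]
  out <- anova_two_way(d, y, A, B)
  expect_equal(out$sumsq[out$term == "A:B"], 0, tolerance = 1e-12)
  expect_gt(out$sumsq[out$term == "Residuals"], 0)
})

test_that("balanced two-way ANOVA matches the textbook SS oracle", {
  for (seed in 1:5) {
    d <- make_table(c(0, 1.5), c(0, 0.5, 2), ab_eff = matrix(
      c(0, 0, 0, 0, 0.8, -0.4), nrow = 2), n = 6, seed = seed)
    out <- anova_two_way(d, y, A, B)
    want <- oracle_anova2(d$y, d$A, d$B)
    expect_equal(out$sumsq, want$sumsq, tolerance = 1e-10)
    expect_equal(out$statistic[1:3], want$statistic[1:3], tolerance = 1e-10)
    expect_equal(out$p.value[1:3], want$p.value[1:3], tolerance = 1e-10)
    # SS decomposition identity
    expect_equal(sum(out$sumsq), want$ss_total, tolerance = 1e-9)
  }
})

test_that("statistics are invariant to row permutation", {
  d <- make_table(c(0, 2), c(0, 1, 2), n = 5, seed = 9)
  out1 <- anova_two_way(d, y, A, B)
  set.seed(1)
  out2 <- anova_two_way(d[sample.int(nrow(d)), ], y, A, B)
  expect_equal(out1, out2)
})

test_that("empty design cells are refused with a diagnostic", {
  d <- make_table(c(0, 1), c(0, 1), n = 3)
  d <- d[!(d$A == "2" & d$B == "1"), ]
  expect_error(anova_two_way(d, y, A, B), "empty design cell: 2:1")
})

test_that("unbalanced tables fall back to Type-II sums of squares", {
  d <- make_table(c(0, 3), c(0, 1, 2), n = 6, seed = 4)
  d <- d[-(1:3), ] # drop replicates from one cell
  expect_warning(out <- anova_two_way(d, y, A, B), "Type-II")
  fitII <- car::Anova(stats::lm(y ~ A * B, data = d), type = 2)
  expect_equal(out$sumsq[out$term == "A"], fitII["A", "Sum Sq"])
})

test_that("simple main effects are gated and Bonferroni-corrected", {
  # strong interaction: the A effect exists only within B level 1
  ab <- matrix(c(0, 4, 0, 0, 0, 0), nrow = 2)
  d <- make_table(c(0, 0), c(0, 0, 0), ab_eff = ab, n = 10, sd = 0.5,
                  seed = 7)
  sme <- simple_main_effects(d, y, A, B)
  a_within_b <- sme[sme$factor == "A", ]
  expect_equal(a_within_b$significant, c(TRUE, FALSE, FALSE))
  # Bonferroni divisor = number of levels of the conditioning factor
  expect_equal(a_within_b$p.adjusted, pmin(1, a_within_b$p.value * 3))
  b_within_a <- sme[sme$factor == "B", ]
  expect_equal(b_within_a$p.adjusted, pmin(1, b_within_a$p.value * 2))
  # gate: refuse when the interaction is not significant
  d_null <- make_table(c(0, 0), c(0, 0, 0), n = 10, sd = 1, seed = 12)
  expect_error(simple_main_effects(d_null, y, A, B), "not applicable")
})

test_that("pairwise Tukey tests match a studentized-range oracle", {
  d <- make_table(c(0, 0), c(0, 0, 3), n = 10, sd = 0.8, seed = 5)
  expect_error(tukey_pairwise(d, y, A), "more than 2 levels")
  out <- tukey_pairwise(d, y, B, alpha = 0.01)
  expect_equal(nrow(out), 3)
  want <- oracle_tukey(d$y, d$B)
  expect_equal(out$adj.p.value, unname(want$adj.p.value), tolerance = 1e-8)
  expect_equal(out$estimate, unname(want$estimate), tolerance = 1e-10)
  expect_equal(out$significant, c(FALSE, TRUE, TRUE))
  # identical groups: nothing significant
  d0 <- make_table(c(0, 0), c(0, 0, 0), n = 10, sd = 1, seed = 6)
  expect_false(any(tukey_pairwise(d0, y, B)$significant))
})

test_that("the decision pipeline follows the interaction branch rules", {
  # injected interaction -> simple main effects, no additive refit
  ab <- matrix(c(0, 5, 0, 0, 0, 0), nrow = 2)
  d_int <- make_table(c(0, 0), c(0, 0, 0), ab_eff = ab, n = 10, sd = 0.5,
                      seed = 8)
  res <- decision_pipeline(d_int, y, A, B)
  expect_equal(res$branch, "interaction")
  expect_false(is.null(res$simple_effects))
  expect_true(any(grepl(":", res$anova$term)))
  expect_true(all(res$tukey$within %in% levels(d_int$A)))
  # additive effects -> refit without interaction, full-data Tukey
  d_add <- make_table(c(0, 2), c(0, 1, 3), n = 10, sd = 0.5, seed = 9)
  res2 <- decision_pipeline(d_add, y, A, B)
  expect_equal(res2$branch, "additive")
  expect_null(res2$simple_effects)
  expect_false(any(grepl(":", res2$anova$term)))
  expect_true(all(res2$tukey$within == "(all)"))
  # glance/tidy accessors
  expect_equal(glance(res2)$branch, "additive")
  expect_equal(tidy(res2), res2$anova)
})

test_that("an age-only variability table flags age and not volume", {
  # synthetic variability-design table: age mode shifts the metric,
  # volume mode does not, with no interaction
  set.seed(11)
  d <- tidyr::expand_grid(volume_mode = c("constant", "normal"),
                          age_mode = c("zero", "uniform"), rep = 1:10)
  d$growth_rate <- 2 + ifelse(d$age_mode == "uniform", -0.6, 0) +
    rnorm(nrow(d), 0, 0.2)
  res <- decision_pipeline(d, growth_rate, volume_mode, age_mode)
  expect_equal(res$branch, "additive")
  p <- stats::setNames(res$anova$p.value, res$anova$term)
  expect_lt(p[["age_mode"]], 0.05)
  expect_gt(p[["volume_mode"]], 0.05)
  # cross-check the branch decision against the brute-force oracle
  want <- oracle_anova2(d$growth_rate, d$volume_mode, d$age_mode)
  expect_gt(want$p.value[3], 0.05)
})
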