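balanced_2x2 <- function(values) {
  data.frame(fe = values,
             particle = rep(c("a1", "a2"), each = 4),
             dose = rep(rep(c("b1", "b2"), each = 2), 2),
             stringsAsFactors = FALSE)
}

test_that("two-way ANOVA matches a manual sums-of-squares decomposition", {
  dat <- balanced_2x2(c(10, 12, 20, 22, 30, 32, 40, 42))
  res <- two_way_anova(dat, transform = "none")
  orc <- oracle_two_way_ss(dat$fe, dat$particle, dat$dose)
  expect_equal(res$table$F[1], orc$F_a)
  expect_equal(res$table$F[2], orc$F_b)
  expect_equal(res$table$F[3], orc$F_int)
  expect_equal(res$table$df, orc$df)
  # and on a random balanced table
  set.seed(31)
  dat2 <- balanced_2x2(rnorm(8))
  res2 <- two_way_anova(dat2, transform = "none")
  orc2 <- oracle_two_way_ss(dat2$fe, dat2$particle, dat2$dose)
  expect_equal(res2$table$F[1:3], c(orc2$F_a, orc2$F_b, orc2$F_int))
})

test_that("constant responses give zero F for every term", {
  dat <- balanced_2x2(rep(5, 8))
  res <- two_way_anova(dat, transform = "none")
  expect_equal(res$table$F[1:3], c(0, 0, 0))
})

test_that("the rank path equals running the raw path on ranks", {
  set.seed(8)
  dat <- balanced_2x2(rexp(8))
  ranked <- dat; ranked$fe <- rank(ranked$fe)
  res_rank <- two_way_anova(dat, transform = "rank")
  res_none <- two_way_anova(ranked, transform = "none")
  expect_equal(res_rank$table$F, res_none$table$F)
  expect_equal(res_rank$transform, "rank")
})

test_that("rank transform is invariant to monotone response transforms", {
  set.seed(9)
  dat <- balanced_2x2(runif(8, 1, 2))
  f1 <- two_way_anova(dat, transform = "rank")$table$F
  dat$fe <- exp(dat$fe^3)
  f2 <- two_way_anova(dat, transform = "rank")$table$F
  expect_equal(f1, f2)
})

test_that("ANOVA F is invariant to shifting and scaling responses", {
  set.seed(12)
  dat <- balanced_2x2(rnorm(8))
  f0 <- two_way_anova(dat, transform = "none")$table$F
  dat_shift <- dat; dat_shift$fe <- dat_shift$fe + 100
  dat_scale <- dat; dat_scale$fe <- dat_scale$fe * 3.7
  expect_equal(two_way_anova(dat_shift, transform = "none")$table$F, f0)
  expect_equal(two_way_anova(dat_scale, transform = "none")$table$F, f0)
})

test_that("unbalanced or single-replicate designs are rejected", {
  dat <- balanced_2x2(rnorm(8))[-1, ]
  expect_error(two_way_anova(dat, transform = "none"), "unbalanced")
  one_rep <- data.frame(fe = rnorm(4),
                        particle = rep(c("a1", "a2"), each = 2),
                        dose = rep(c("b1", "b2"), 2))
  expect_error(two_way_anova(one_rep, transform = "none"), "replicates")
})

test_that("one-way ANOVA matches hand computation and rejects bad designs", {
  res <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(res$table$F[1], 13.5)
  expect_equal(res$table$df, c(1, 4))

  same <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(same$table$F[1], 0)

  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), ">= 2 observations")
  expect_error(one_way_anova(list(a = c(1, 2))), ">= 2 groups")
})

test_that("one-way ANOVA type-I error is calibrated at the nominal level", {
  reject <- 0L
  n_sim <- 1000L
  for (s in seq_len(n_sim)) {
    set.seed(s)
    groups <- split(rnorm(15), rep(1:3, each = 5))
    if (one_way_anova(groups)$table$p[1] < 0.05) reject <- reject + 1L
  }
  expect_gt(reject / n_sim, 0.03)
  expect_lt(reject / n_sim, 0.07)
})

test_that("Holm-Sidak matches the closed form with monotonicity", {
  expect_equal(holm_sidak(0.03), 0.03)
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak(c(0.02, 0.02, 0.02)), rep(1 - 0.98^3, 3))

  set.seed(14)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    p <- runif(m)
    adj <- holm_sidak(p)
    # inline re-derivation
    o <- order(p)
    expected <- pmin(cummax(1 - (1 - p[o])^(m - seq_len(m) + 1)), 1)
    expect_equal(adj[o], expected)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[o]) >= -1e-12))
    # never above Bonferroni-Holm
    expect_true(all(adj <= p.adjust(p, "holm") + 1e-12))
  }
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("treatment-vs-control comparisons carry adjusted p-values", {
  set.seed(16)
  values <- c(rnorm(6, 0), rnorm(6, 3), rnorm(6, 0.2))
  group <- rep(c("control", "hit", "dud"), each = 6)
  cmp <- adjusted_comparisons(values, group, control = "control")
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$adj_p >= cmp$raw_p))
  expect_equal(cmp$group1[1], "hit")
  all_pairs <- adjusted_comparisons(values, group, family = "all_pairs")
  expect_equal(nrow(all_pairs), 3)
  expect_error(adjusted_comparisons(values, group, control = "nope"),
               "control")
})
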