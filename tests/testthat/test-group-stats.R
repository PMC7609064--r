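test_that("D'Agostino-Pearson matches frozen reference values", {
  # reference values computed once with an independent implementation of
  # the published transformations (scipy.stats) on deterministic fixtures
  x <- sqrt(1:30) + sin(1:30)
  r <- dagostino_test(x)
  expect_equal(r$z_skew, -0.4415337502, tolerance = 1e-9)
  expect_equal(r$z_kurt, -1.2241499279, tolerance = 1e-9)
  expect_equal(r$statistic, 1.6934950985, tolerance = 1e-9)
  expect_equal(r$p_value, 0.4288073411, tolerance = 1e-9)
  y <- exp(seq(0, 2, length.out = 25))
  r2 <- dagostino_test(y)
  expect_equal(r2$statistic, 2.9172566187, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.2325550496, tolerance = 1e-9)
  expect_error(dagostino_test(1:5), "n >= 8")
})

test_that("the two-group decision tree follows the normality/variance gates", {
  set.seed(88)
  # well-behaved Gaussian, equal variance: Student t in most replicates
  picks <- replicate(20, {
    choose_two_group_test(stats::rnorm(50), stats::rnorm(50))$chosen_test
  })
  expect_gte(mean(picks == "t"), 0.8)
  # heavy-tailed group triggers Mann-Whitney
  picks_ln <- replicate(20, {
    choose_two_group_test(exp(stats::rnorm(50)), stats::rnorm(50, 2))$chosen_test
  })
  expect_gte(mean(picks_ln == "mann_whitney"), 0.9)
  # 5x variance ratio triggers Welch
  picks_w <- replicate(20, {
    choose_two_group_test(stats::rnorm(50, 0, sqrt(5)),
                          stats::rnorm(50))$chosen_test
  })
  expect_gte(mean(picks_w == "welch_t"), 0.9)
  # below the normality floor: nonparametric with a warning
  expect_warning(
    d <- choose_two_group_test(stats::rnorm(5), stats::rnorm(5)),
    "floor")
  expect_identical(d$chosen_test, "mann_whitney")
})

test_that("decisions are deterministic and p-values are proper", {
  set.seed(12)
  a <- stats::rnorm(30); b <- stats::rnorm(30, 0.5)
  d1 <- choose_two_group_test(a, b)
  d2 <- choose_two_group_test(a, b)
  expect_identical(d1$chosen_test, d2$chosen_test)
  expect_identical(d1$p_value, d2$p_value)
  expect_gte(d1$p_value, 0); expect_lte(d1$p_value, 1)
})

test_that("type-I error of the decision chain is calibrated", {
  set.seed(202)
  rej_g <- mean(replicate(400, {
    suppressWarnings(choose_two_group_test(stats::rnorm(20),
                                           stats::rnorm(20))$p_value) < 0.05
  }))
  rej_ln <- mean(replicate(400, {
    suppressWarnings(choose_two_group_test(exp(stats::rnorm(20)),
                                           exp(stats::rnorm(20)))$p_value) < 0.05
  }))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gte(rej_g, ci[1]); expect_lte(rej_g, ci[2])
  expect_gte(rej_ln, ci[1]); expect_lte(rej_ln, ci[2])
})

test_that("interaction ANOVA reports the crossed term and post hocs", {
  set.seed(5)
  df <- expand.grid(f1 = c("MM", "MF"), f2 = c("fed", "dep"),
                    rep = 1:20)
  df$y <- stats::rnorm(nrow(df), 100)
  df$y[df$f1 == "MF" & df$f2 == "fed"] <- df$y[df$f1 == "MF" & df$f2 == "fed"] - 8
  ia <- interaction_anova(df, "y", "f1", "f2", posthoc = "sidak")
  expect_lt(ia$interaction_p, 0.01)
  expect_true(all(c("contrast", "p.value") %in% names(ia$contrasts)))
  ia_t <- interaction_anova(df, "y", "f1", "f2", posthoc = "tukey")
  expect_equal(nrow(ia_t$contrasts), 6L)  # all pairs of 4 cells
  ia_d <- interaction_anova(df, "y", "f1", "f2", posthoc = "dunnett")
  expect_equal(nrow(ia_d$contrasts), 3L)  # vs control cell
  # empty cell is a hard error
  expect_error(interaction_anova(df[!(df$f1 == "MM" & df$f2 == "dep"), ],
                                 "y", "f1", "f2"), "empty design cell")
})

test_that("jointly permuting factor labels preserves the interaction p", {
  set.seed(6)
  df <- expand.grid(f1 = c("a", "b"), f2 = c("u", "v"), rep = 1:10)
  df$y <- stats::rnorm(nrow(df))
  p1 <- interaction_anova(df, "y", "f1", "f2", posthoc = "none")$interaction_p
  df2 <- df
  df2$f1 <- factor(df2$f1, levels = c("b", "a"))
  df2$f2 <- factor(df2$f2, levels = c("v", "u"))
  p2 <- interaction_anova(df2, "y", "f1", "f2", posthoc = "none")$interaction_p
  expect_equal(p1, p2)
})

test_that("the screen-hit rule requires both controls with the same sign", {
  set.seed(42)
  uas <- stats::rnorm(30, 500, 60)
  mk <- function(mu) stats::rnorm(30, mu, 60)
  lines <- list(
    null_line = list(experimental = mk(500), gal4_control = mk(500)),
    true_hit = list(experimental = mk(330), gal4_control = mk(500)),
    between = list(experimental = mk(575), gal4_control = mk(660)))
  res <- screen_hits(lines, uas, alpha = 0.05)
  expect_false(res$hit[res$line == "null_line"])
  expect_true(res$hit[res$line == "true_hit"])
  # between-controls line differs from both but with opposite signs
  expect_false(res$hit[res$line == "between"])
  expect_equal(res$delta_vs_uas[res$line == "true_hit"],
               mean(lines$true_hit$experimental) - mean(uas))
  # missing control: skipped with a warning
  expect_warning(
    res2 <- screen_hits(c(lines, list(bad = list(experimental = mk(1)))), uas),
    "skipped")
  expect_false("bad" %in% res2$line)
})

test_that("stats JSON reports carry the documented fields", {
  set.seed(1)
  d <- choose_two_group_test(stats::rnorm(20), stats::rnorm(20, 1))
  rep <- write_stats_json(d)
  expect_true(all(c("test", "statistic", "p", "effect") %in% names(rep)))
  path <- withr::local_tempfile(fileext = ".json")
  write_stats_json(d, path)
  expect_equal(jsonlite::read_json(path)$test, d$chosen_test)
})
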