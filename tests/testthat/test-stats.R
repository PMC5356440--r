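# Statistics decision tree: normality test, routing, Dunn's post test, bud
# distributions and percent change.

test_that("D'Agostino-Pearson matches frozen reference values", {
  # reference values computed independently with an established
  # implementation of the same published test
  r1 <- dagostino_pearson(sin(1:20))
  expect_equal(r1$statistic, 8.828599767, tolerance = 1e-8)
  expect_equal(r1$p_value, 0.01210302469, tolerance = 1e-8)
  x2 <- c(2.1, -0.9, 0.3, 1.7, -1.2, 0.5, 0.9, -0.4, 1.1, 0.2,
          -0.6, 1.4, 0.7, -1.5, 0.05, 0.65, -0.25, 1.9, -1.1, 0.45)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 0.841340951, tolerance = 1e-8)
  expect_equal(r2$p_value, 0.6566064337, tolerance = 1e-8)
  r3 <- dagostino_pearson(exp(seq(0, 3, length.out = 15)))
  expect_equal(r3$statistic, 4.119175443, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})

test_that("Dunn's test matches frozen reference values with and without ties", {
  d <- dunn_test(c(1, 3, 2, 5, 4, 8, 7, 6, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(d$z, c(-1.639783183, -2.385139176, -0.7453559925),
               tolerance = 1e-8)
  expect_equal(d$p_value, c(0.1010502559, 0.01707266109, 0.4560565403),
               tolerance = 1e-8)
  expect_equal(d$p_adjusted, c(0.3031507678, 0.05121798328, 1),
               tolerance = 1e-8)
  dt <- dunn_test(c(1, 2, 2, 3, 5, 5, 5, 7, 8, 9, 2, 4),
                  rep(c("a", "b", "c"), each = 4))
  expect_equal(dt$z, c(-2.188097298, -1.989179362, 0.1989179362),
               tolerance = 1e-8)
  expect_equal(dt$p_adjusted, c(0.08598754716, 0.1400442272, 1),
               tolerance = 1e-8)
})

test_that("normal data route to the parametric branch", {
  g <- withr::with_seed(21, list(a = rnorm(50), b = rnorm(50)))
  cmp <- choose_and_run_test(g)
  expect_equal(cmp$test, "t-test")
  expect_true(all(cmp$normality$p_normality > 0.05))
  ident <- choose_and_run_test(list(a = g$a, b = g$a))
  expect_gt(ident$p_value, 0.9)
  g3 <- withr::with_seed(26, list(a = rnorm(50), b = rnorm(50),
                                  c = rnorm(50)))
  expect_equal(choose_and_run_test(g3)$test, "one-way ANOVA")
})

test_that("non-normal data route to the nonparametric branch", {
  g <- withr::with_seed(23, list(a = rexp(50), b = rexp(50)))
  # the seeds are chosen blind; verify the premise (normality rejected)
  expect_lt(min(dagostino_pearson(g$a)$p_value,
                dagostino_pearson(g$b)$p_value), 0.05)
  cmp <- choose_and_run_test(g)
  expect_equal(cmp$test, "Mann-Whitney U")
  g3 <- withr::with_seed(24, list(a = rexp(50), b = rexp(50), c = rexp(50)))
  cmp3 <- choose_and_run_test(g3)
  expect_equal(cmp3$test, "Kruskal-Wallis")
  expect_s3_class(cmp3$posthoc, "tbl_df")
})

test_that("small groups route directly to nonparametric", {
  g <- list(a = c(1.2, 3.1, 2.2, 4.0, 2.8), b = c(5.1, 6.2, 5.8, 7.0, 6.5))
  cmp <- choose_and_run_test(g)
  expect_equal(cmp$test, "Mann-Whitney U")
  expect_true(any(grepl("too small", cmp$trace)))
  expect_error(choose_and_run_test(list(a = 1:2, b = 1:5)), "n >= 3")
  expect_error(choose_and_run_test(list(a = 1:5)), "2 groups")
})

test_that("Dunn flags exactly the shifted group, permutation cross-check", {
  g <- withr::with_seed(31, {
    base <- rexp(50)
    list(a = rexp(50), b = rexp(50), c = rexp(50) + 2 * sd(base))
  })
  cmp <- choose_and_run_test(g)
  expect_equal(cmp$test, "Kruskal-Wallis")
  expect_lt(cmp$p_value, 0.001)
  ph <- cmp$posthoc
  flag <- ph$p_adjusted < 0.05
  involved <- (ph$group1 == "c") | (ph$group2 == "c")
  expect_true(all(flag[involved]))
  expect_false(any(flag[!involved]))
  # independent permutation oracle on the mean difference per pair
  perm_p <- function(x, y, n_perm = 1e4) {
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    n <- length(x)
    hits <- withr::with_seed(77, {
      sum(vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pool), n)
        abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
      }, logical(1)))
    })
    (hits + 1) / (n_perm + 1)
  }
  expect_lt(perm_p(g$a, g$c), 0.001)
  expect_lt(perm_p(g$b, g$c), 0.001)
  expect_gt(perm_p(g$a, g$b), 0.05)
})

test_that("constant data fall back to the nonparametric branch", {
  g <- list(a = rep(1, 10), b = rep(1, 10))
  expect_warning(cmp <- choose_and_run_test(g), "constant")
  expect_equal(cmp$test, "Mann-Whitney U")
})

test_that("bud distributions fold counts into the 0/1/2/3/4+ categories", {
  buds <- tibble::tibble(
    genotype = "WT", day = 2, region = "r1",
    buds = c(rep(0, 5), rep(1, 3), 2, 3))
  out <- bud_distribution(buds)
  expect_equal(out$regions$percentage, c(50, 30, 10, 10, 0))
  expect_equal(sum(out$regions$percentage), 100)
  none <- bud_distribution(tibble::tibble(genotype = "KO", day = 4,
                                          region = "r1", buds = rep(0, 7)))
  expect_equal(none$regions$percentage[none$regions$category == "0"], 100)
  many <- bud_distribution(tibble::tibble(genotype = "WT", day = 6,
                                          region = "r1", buds = c(4, 5, 7)))
  expect_equal(many$regions$percentage[many$regions$category == "4+"], 100)
  expect_error(bud_distribution(tibble::tibble(genotype = "WT", day = 2,
                                               region = "r", buds = -1)),
               "non-negative")
})

test_that("region percentages average into the genotype x day summary", {
  buds <- tibble::tibble(
    genotype = "WT", day = 2,
    region = rep(c("r1", "r2"), each = 4),
    buds = c(0, 0, 1, 2, 0, 1, 1, 3))
  out <- bud_distribution(buds)
  s0 <- out$summary$percentage[out$summary$category == "0"]
  expect_equal(s0, mean(c(50, 25)))
  expect_equal(out$summary$n_regions[1], 2L)
  fit <- bud_anova(bud_distribution(tibble::tibble(
    genotype = rep(c("WT", "KO"), each = 8),
    day = rep(c(2, 4), times = 8),
    region = rep(paste0("r", 1:8), each = 2),
    buds = c(0, 1, 0, 2, 1, 0, 0, 1, 3, 4, 2, 5, 4, 3, 2, 4)))$regions)
  expect_s3_class(fit, "aov")
})

test_that("percent change reports reductions with the right sign", {
  expect_equal(percent_change(c(1, 2, 3), c(1, 2, 3))$percent_change, 0)
  pc <- percent_change(rep(100, 3), rep(43, 3))
  expect_equal(pc$percent_change, -57)
  expect_match(pc$formatted, "57.0% reduction")
  expect_equal(percent_change(rep(100, 3), rep(0, 3))$percent_change, -100)
  expect_error(percent_change(c(0, 0), c(1, 1)), "zero")
})
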