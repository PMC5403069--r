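make_table <- function(x, g) data.frame(value = x, stage = g)

test_that("Kruskal-Wallis comparison reproduces the rank-formula oracle", {
  # perfectly separated groups: H = 7.2, chi-square p on 2 df
  tab <- make_table(1:9, rep(c("mild", "moderate", "severe"), each = 3))
  r <- compare_groups(tab, "value")
  expect_equal(r$statistic, 7.2)
  expect_equal(r$p_value, pchisq(7.2, df = 2, lower.tail = FALSE))
  expect_equal(r$groups$n, c(3L, 3L, 3L))
  expect_equal(r$groups$mean, c(2, 5, 8))
  # random data with ties against the independent H oracle
  set.seed(33)
  for (i in 1:20) {
    x <- sample(1:6, 10, replace = TRUE)
    g <- sample(c("a", "b", "c"), 10, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(x)) < 2) next
    r <- compare_groups(make_table(x, g), "value")
    expect_equal(r$statistic, kw_H_oracle(x, g), tolerance = 1e-12)
    expect_equal(r$p_value,
                 pchisq(kw_H_oracle(x, g), length(unique(g)) - 1,
                        lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("all-tied groups give H = 0, p = 1 with a warning", {
  tab <- make_table(rep(5, 6), rep(c("a", "b", "c"), each = 2))
  expect_warning(r <- compare_groups(tab, "value"), "tied")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  set.seed(8)
  x <- rnorm(10); y <- rnorm(10) + 0.6
  tab <- make_table(c(x, y), rep(c("a", "b"), each = 10))
  r <- compare_groups(tab, "value")
  mw <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$statistic, qnorm(mw$p.value / 2)^2, tolerance = 1e-10)
  expect_equal(r$p_value, mw$p.value, tolerance = 1e-10)
})

test_that("empty groups are excluded with a warning", {
  tab <- data.frame(value = c(1, 2, 3, 4),
                    stage = factor(c("a", "a", "b", "b"),
                                   levels = c("a", "b", "c")))
  expect_warning(r <- compare_groups(tab, "value"), "empty group")
  expect_equal(nrow(r$groups), 2L)
})

test_that("Fisher exact comparison matches hypergeometric enumeration", {
  tab22 <- data.frame(value = rep(c("x", "y"), times = c(4, 4)),
                      stage = c("a", "a", "a", "b", "a", "b", "b", "b"))
  r <- compare_groups_categorical(tab22, "value")
  expect_equal(r$p_value, fisher_2x2_exact_p(3, 1, 1, 3), tolerance = 1e-10)
  expect_equal(r$p_value, 0.4857143, tolerance = 1e-6)
  # complete separation
  tabsep <- data.frame(value = rep(c("x", "y"), each = 10),
                       stage = rep(c("a", "b"), each = 10))
  r2 <- compare_groups_categorical(tabsep, "value")
  expect_equal(r2$p_value, fisher_2x2_exact_p(10, 0, 0, 10), tolerance = 1e-10)
  expect_equal(r2$p_value, 1.082509e-05, tolerance = 1e-6)
  # random 2x2 and 2x3 tables against the enumeration / fisher.test route
  set.seed(5)
  for (i in 1:10) {
    a <- sample(0:5, 1); b <- sample(1:5, 1)
    c <- sample(1:5, 1); d <- sample(0:5, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    tab <- data.frame(
      value = rep(c("x", "x", "y", "y"), times = c(a, c, b, d)),
      stage = rep(c("g1", "g2", "g1", "g2"), times = c(a, c, b, d)))
    r <- compare_groups_categorical(tab, "value")
    expect_equal(r$p_value, fisher_2x2_exact_p(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("degenerate categorical input returns p = 1 with a warning", {
  tab <- data.frame(value = rep("x", 6), stage = rep(c("a", "b"), 3))
  expect_warning(r <- compare_groups_categorical(tab, "value"), "degenerate")
  expect_equal(r$p_value, 1)
  # all-zero level dropped: factor with an unobserved level
  tab2 <- data.frame(value = factor(rep(c("x", "y"), 4),
                                    levels = c("x", "y", "z")),
                     stage = rep(c("a", "b"), each = 4))
  expect_warning(compare_groups_categorical(tab2, "value"), "all-zero")
})

test_that("univariate screen: Spearman for continuous, Mann-Whitney for binary", {
  set.seed(21)
  n <- 30
  tab <- data.frame(outcome = rnorm(n), cont = rnorm(n),
                    bin = rbinom(n, 1, 0.5))
  tab$self <- tab$outcome
  tab$inv <- -tab$outcome
  scr <- univariate_screen(tab, "outcome", c("self", "inv", "cont", "bin"))
  expect_equal(scr$statistic[scr$covariate == "self"], 1.0)
  expect_equal(scr$statistic[scr$covariate == "inv"], -1.0)
  expect_equal(scr$type[scr$covariate == "bin"], "mann_whitney")
  # agreement with the base tests it wraps
  ct <- cor.test(tab$cont, tab$outcome, method = "spearman")
  expect_equal(scr$p_value[scr$covariate == "cont"], ct$p.value)
  wt <- wilcox.test(tab$outcome[tab$bin == 1], tab$outcome[tab$bin == 0])
  expect_equal(scr$p_value[scr$covariate == "bin"], wt$p.value)
})

test_that("screen p-values match exact permutation enumeration at small n", {
  set.seed(9)
  for (i in 1:3) {
    x <- sample(1:100, 7)
    y <- sample(1:100, 7)
    tab <- data.frame(outcome = y, x = x)
    scr <- univariate_screen(tab, "outcome", "x")
    expect_equal(scr$p_value, spearman_exact_p(x, y), tolerance = 1e-10)
  }
  for (i in 1:3) {
    y <- sample(1:100, 9)
    b <- c(rep(0, 4), rep(1, 5))
    tab <- data.frame(outcome = y, b = b)
    scr <- univariate_screen(tab, "outcome", "b")
    expect_equal(scr$p_value, mw_exact_p(y[b == 1], y[b == 0]),
                 tolerance = 1e-10)
  }
})

test_that("constant covariates are skipped with a warning", {
  tab <- data.frame(outcome = rnorm(10), flat = rep(1, 10))
  expect_warning(scr <- univariate_screen(tab, "outcome", "flat"), "constant")
  expect_equal(nrow(scr), 0L)
})

test_that("backward elimination keeps true effects and drops noise", {
  set.seed(4)
  n <- 100
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  tab <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- fit_multivariate(tab, "y", candidates = c("x1", "x2"),
                          log_transform = "off")
  expect_true("x1" %in% fit$retained$term)
  expect_false("x2" %in% fit$retained$term)
  est <- fit$retained$estimate[fit$retained$term == "x1"]
  se <- fit$retained$se[fit$retained$term == "x1"]
  expect_lt(abs(est - 2), 2 * se)
  expect_equal(fit$trace$dropped, "x2")
})

test_that("a single significant candidate is retained with an empty trace", {
  set.seed(6)
  x <- rnorm(50); y <- x + rnorm(50, sd = 0.3)
  fit <- fit_multivariate(data.frame(y = y, x = x), "y", candidates = "x",
                          log_transform = "off")
  expect_true("x" %in% fit$retained$term)
  expect_equal(nrow(fit$trace), 0L)
})

test_that("a constant outcome reduces to the intercept-only model", {
  set.seed(7)
  tab <- data.frame(y = rep(3, 30), x1 = rnorm(30), x2 = rnorm(30))
  fit <- suppressWarnings(  # lm warns about the perfect (zero-variance) fit
    fit_multivariate(tab, "y", candidates = c("x1", "x2"),
                     log_transform = "off"))
  expect_equal(fit$retained$term, "(Intercept)")
  expect_equal(nrow(fit$trace), 2L)
})

test_that("the elimination trace is deterministic and ties break by order", {
  set.seed(11)
  n <- 60
  tab <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  f1 <- fit_multivariate(tab, "y", candidates = c("a", "b", "c"),
                         log_transform = "off")
  f2 <- fit_multivariate(tab, "y", candidates = c("a", "b", "c"),
                         log_transform = "off")
  expect_identical(f1$trace, f2$trace)
  # an exactly duplicated covariate is collinear: the later one is dropped
  tab$b2 <- tab$b
  expect_warning(
    f3 <- fit_multivariate(tab, "y", candidates = c("b", "b2", "a"),
                           log_transform = "off"),
    "collinear")
  expect_equal(f3$trace$dropped[1], "b2")
})

test_that("log transformation is applied automatically on skewed outcomes", {
  set.seed(13)
  n <- 80
  x <- rnorm(n)
  y <- exp(1 + 2 * x + rnorm(n, sd = 0.4))  # log-normal outcome
  fit <- fit_multivariate(data.frame(y = y, x = x), "y", candidates = "x")
  expect_equal(fit$transformation, "log")
  est <- fit$retained$estimate[fit$retained$term == "x"]
  expect_lt(abs(est - 2), 0.3)
  fit_off <- fit_multivariate(data.frame(y = y, x = x), "y", candidates = "x",
                              log_transform = "off")
  expect_equal(fit_off$transformation, "identity")
})

test_that("candidate selection applies the entry threshold to the screen", {
  set.seed(17)
  n <- 120
  x1 <- rnorm(n)
  tab <- data.frame(y = 1.5 * x1 + rnorm(n), x1 = x1, noise = rnorm(n))
  names(tab) <- c("npi", "hba1c_percent", "age")  # screened covariate names
  fit <- fit_multivariate(tab, "npi", log_transform = "off")
  expect_true("hba1c_percent" %in% fit$candidates)
  expect_true("hba1c_percent" %in% fit$retained$term)
})
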